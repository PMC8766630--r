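#' Left/right sinus class pairs for horizontal flips
#'
#' In the 9-class table the frontal and sphenoid sinuses come in
#' left/right pairs that a horizontal flip exchanges (the combined
#' maxillary class maps to itself under the bilateral-symmetry
#' assumption).
#'
#' @return Two-column integer matrix of class-id pairs.
#' @export
sinus_lr_pairs <- function() {
  tab <- head_class_table()
  rbind(c(tab[["frontal_sinus_left"]], tab[["frontal_sinus_right"]]),
        c(tab[["sphenoid_sinus_left"]], tab[["sphenoid_sinus_right"]]))
}

# mean absolute pairwise difference of the sinus pixel counts
mean_abs_pairwise_diff <- function(counts) {
  if (length(counts) < 2) return(0)
  mean(abs(outer(counts, counts, "-"))[lower.tri(diag(length(counts)))])
}

sinus_pixel_counts <- function(ds, sinus_ids) {
  vapply(sinus_ids, function(s)
    sum(vapply(ds$Y, function(y) sum(y[, , s + 1L]), numeric(1))),
    numeric(1))
}

flip_slice <- function(x, y_onehot, lr_pairs) {
  xf <- x[, rev(seq_len(ncol(x))), drop = FALSE]
  yf <- y_onehot[, rev(seq_len(ncol(x))), , drop = FALSE]
  for (r in seq_len(nrow(lr_pairs))) {
    a <- lr_pairs[r, 1] + 1L; b <- lr_pairs[r, 2] + 1L
    tmp <- yf[, , a]
    yf[, , a] <- yf[, , b]
    yf[, , b] <- tmp
  }
  list(x = xf, y = yf)
}

translate_slice <- function(x, y_onehot, shift, fill_class) {
  d <- dim(x)
  xs <- matrix(0, d[1], d[2])
  S <- dim(y_onehot)[3]
  ys <- array(0, dim(y_onehot))
  ys[, , fill_class + 1L] <- 1
  si <- shift[1]; sj <- shift[2]
  src_i <- seq_len(d[1]) - si; src_j <- seq_len(d[2]) - sj
  ok_i <- src_i >= 1 & src_i <= d[1]; ok_j <- src_j >= 1 & src_j <= d[2]
  xs[ok_i, ok_j] <- x[src_i[ok_i], src_j[ok_j]]
  for (s in seq_len(S)) {
    plane <- matrix(0, d[1], d[2])
    if (s == fill_class + 1L) plane[] <- 1
    plane[ok_i, ok_j] <- y_onehot[src_i[ok_i], src_j[ok_j], s]
    ys[, , s] <- plane
  }
  list(x = xs, y = ys)
}

#' Balance the sinus classes of a training set by oversampling
#'
#' Iteratively determines the least-dominant sinus segment (smallest
#' total pixel count), picks a slice containing it, applies either a
#' horizontal flip (exchanging the left/right sinus labels, assuming
#' bilateral symmetry) or a random translation (up to 10% of the ROI,
#' zero-filled images, labels shifted identically), and appends the copy.
#' The loop stops when the mean absolute pairwise difference between the
#' sinus pixel counts stops decreasing, or when the dataset has grown to
#' `max_factor` times its original size. Original slices are never
#' modified.
#'
#' @param ds a [slice_dataset()].
#' @param sinus_ids class ids of the sinus segments to balance.
#' @param seed RNG seed (slice pick, flip/translate choice, shift).
#' @param max_factor growth cap as a multiple of the original size.
#' @param patience appends tolerated without a new best imbalance before
#'   stopping; the dataset is trimmed back to the best state, so the
#'   returned imbalance is the minimum reached.
#' @param lr_pairs left/right class-id pairs exchanged by flips.
#' @param fill_class class id assigned to label pixels shifted in from
#'   outside the ROI.
#' @return The augmented [slice_dataset()]; attribute `balance_history`
#'   records the mean absolute pairwise difference per step.
#' @export
balance_training_set <- function(ds, sinus_ids = c(0L, 1L, 2L, 3L, 4L),
                                 seed = 1L, max_factor = 10,
                                 patience = 25L,
                                 lr_pairs = sinus_lr_pairs(),
                                 fill_class = head_class_table()[["air_outside"]]) {
  stopifnot(inherits(ds, "slice_dataset"))
  set.seed(seed)
  present <- vapply(sinus_ids, function(s)
    any(vapply(ds$Y, function(y) any(y[, , s + 1L] > 0), logical(1))),
    logical(1))
  if (!all(present)) {
    warning("sinus class(es) absent from every slice, excluded from balancing: ",
            paste(sinus_ids[!present], collapse = ", "))
    sinus_ids <- sinus_ids[present]
  }
  if (length(sinus_ids) < 2) return(ds)
  n_orig <- ds$N
  counts <- sinus_pixel_counts(ds, sinus_ids)
  best_madp <- mean_abs_pairwise_diff(counts)
  best_n <- ds$N
  hist <- best_madp
  max_n <- ceiling(max_factor * n_orig)
  max_shift <- max(1L, floor(0.1 * min(ds$roi)))
  stalled <- 0L
  while (ds$N < max_n && stalled < patience) {
    target <- sinus_ids[which.min(counts)]
    cand <- which(vapply(ds$Y, function(y) any(y[, , target + 1L] > 0),
                         logical(1)))
    if (!length(cand)) break
    pick <- cand[sample.int(length(cand), 1)]
    if (stats::runif(1) < 0.5) {
      tr <- flip_slice(ds$X[[pick]], ds$Y[[pick]], lr_pairs)
    } else {
      shift <- sample(seq(-max_shift, max_shift), 2, replace = TRUE)
      tr <- translate_slice(ds$X[[pick]], ds$Y[[pick]], shift, fill_class)
    }
    ds$X[[ds$N + 1L]] <- tr$x
    ds$Y[[ds$N + 1L]] <- tr$y
    ds$N <- ds$N + 1L
    counts <- counts + vapply(sinus_ids, function(s)
      sum(tr$y[, , s + 1L]), numeric(1))
    madp <- mean_abs_pairwise_diff(counts)
    hist <- c(hist, madp)
    if (madp < best_madp) {
      best_madp <- madp
      best_n <- ds$N
      stalled <- 0L
    } else {
      stalled <- stalled + 1L
    }
  }
  # keep the prefix with the smallest imbalance (madp stopped decreasing)
  if (ds$N > best_n) {
    ds$X <- ds$X[seq_len(best_n)]
    ds$Y <- ds$Y[seq_len(best_n)]
    ds$N <- best_n
    hist <- hist[seq_len(best_n - n_orig + 1L)]
  }
  attr(ds, "balance_history") <- hist
  ds
}
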