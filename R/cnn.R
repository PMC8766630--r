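#' Construct a slice dataset for segmentation training
#'
#' @param X list of 2-D intensity matrices, values scaled to \[0,1\];
#'   all slices must share the same ROI size.
#' @param Y list of label matrices (integer class ids `0..S-1`) or
#'   one-hot H x W x S arrays, one per slice.
#' @param n_classes number of classes S (2 for binary air/non-air,
#'   9 for the full anatomical table).
#' @return An object of class `slice_dataset` with one-hot label stacks.
#' @export
slice_dataset <- function(X, Y, n_classes) {
  stopifnot(length(X) == length(Y), length(X) > 0)
  d <- dim(X[[1]])
  for (x in X) if (!identical(dim(x), d)) stop("all slices must share ROI size")
  onehot <- lapply(Y, function(y) {
    if (is.null(dim(y)) && length(y) == prod(d)) dim(y) <- d
    if (length(dim(y)) == 3) {
      if (!all(abs(apply(y, c(1, 2), sum) - 1) < 1e-12))
        stop("labels are not one-hot")
      return(y)
    }
    if (any(y < 0 | y >= n_classes)) stop("label id outside 0..S-1")
    oh <- array(0, c(dim(y), n_classes))
    for (s in seq_len(n_classes)) oh[, , s] <- (y == s - 1L)
    oh
  })
  structure(list(X = X, Y = onehot, n_classes = n_classes,
                 N = length(X), roi = d),
            class = "slice_dataset")
}

#' @export
print.slice_dataset <- function(x, ...) {
  cat(sprintf("<slice_dataset> %d slices, %dx%d px, %d classes\n",
              x$N, x$roi[1], x$roi[2], x$n_classes))
  invisible(x)
}

#' CNN architecture specification
#'
#' Small segmentation networks: 1 to 4 convolutional layers of 5 to 20
#' filters each (3x3 kernels), every layer followed by ReLU and 2x2 max
#' pooling (stride 2, zero padding), each pooled branch passed through a
#' specialized 3x3 convolution + ReLU, bilinearly resized (no corner
#' alignment) back to the full ROI and concatenated into a feature
#' volume; a per-class 1x1 linear combination forms the prediction stack,
#' with a sigmoid head for binary and a softmax along the class dimension
#' for multi-class segmentation.
#'
#' @param n_conv_layers number of convolutional blocks, 1..4.
#' @param filters_per_layer filters per convolution, 5..20.
#' @param n_classes 2 (binary, sigmoid head) or 9 (softmax head).
#' @param learning_rate fixed Adam learning rate.
#' @param batch_size training batch size (1).
#' @param init_sd standard deviation of the truncated normal initializer
#'   (truncated at +-2 sd).
#' @return An object of class `cnn_spec`.
#' @export
cnn_spec <- function(n_conv_layers = 2, filters_per_layer = 8,
                     n_classes = 2, learning_rate = 0.01, batch_size = 1,
                     init_sd = 0.1) {
  if (n_conv_layers < 1 || n_conv_layers > 4)
    stop("n_conv_layers must be in 1..4")
  if (filters_per_layer < 5 || filters_per_layer > 20)
    stop("filters_per_layer must be in 5..20")
  if (!n_classes %in% c(2L, 9L, 10L))
    stop("n_classes must be 2, 9 or 10")
  structure(list(n_conv_layers = as.integer(n_conv_layers),
                 filters_per_layer = as.integer(filters_per_layer),
                 kernel = 3L, n_classes = as.integer(n_classes),
                 learning_rate = learning_rate,
                 batch_size = as.integer(batch_size), init_sd = init_sd),
            class = "cnn_spec")
}

#' Loss configuration
#'
#' @param mode `"cbce"` (class-balanced cross entropy, binary) or
#'   `"bfl"` (balanced focal loss, multi-class).
#' @param gamma focal modulating exponent (>= 0, `bfl` only).
#' @param eps probability clamp in (0, 1e-3).
#' @return An object of class `loss_config`.
#' @export
loss_config <- function(mode = c("cbce", "bfl"), gamma = 2, eps = 1e-7) {
  mode <- match.arg(mode)
  if (gamma < 0) stop("gamma must be >= 0")
  if (eps <= 0 || eps >= 1e-3) stop("eps must be in (0, 1e-3)")
  structure(list(mode = mode, gamma = gamma, eps = eps),
            class = "loss_config")
}

# truncated normal init, mean 0, truncation at +-2 sd
trunc_normal <- function(n, sd) {
  u <- stats::runif(n, stats::pnorm(-2), stats::pnorm(2))
  stats::qnorm(u) * sd
}

#' Build a segmentation CNN
#'
#' Allocates and initializes the network weights for the architecture
#' described in [cnn_spec()]. The parameter count is independent of the
#' ROI size (all layers are convolutional).
#'
#' @param spec a [cnn_spec()].
#' @param seed RNG seed for the truncated-normal initialization.
#' @return An object of class `cnn_model`.
#' @export
build_cnn <- function(spec, seed = 1L) {
  stopifnot(inherits(spec, "cnn_spec"))
  set.seed(seed)
  L <- spec$n_conv_layers
  Fh <- spec$filters_per_layer
  nout <- if (spec$n_classes == 2) 1L else spec$n_classes
  params <- list(conv = vector("list", L), spec_conv = vector("list", L))
  cin <- 1L
  for (l in seq_len(L)) {
    params$conv[[l]] <- list(
      W = array(trunc_normal(9 * cin * Fh, spec$init_sd), c(9 * cin, Fh)),
      b = numeric(Fh), cin = cin)
    params$spec_conv[[l]] <- list(
      W = array(trunc_normal(9 * Fh * Fh, spec$init_sd), c(9 * Fh, Fh)),
      b = numeric(Fh), cin = Fh)
    cin <- Fh
  }
  params$head <- list(
    W = matrix(trunc_normal(L * Fh * nout, spec$init_sd), L * Fh, nout),
    b = numeric(nout))
  structure(list(spec = spec, params = params, n_out = nout),
            class = "cnn_model")
}

#' Number of trainable parameters of a CNN
#' @param model a `cnn_model`.
#' @return Integer parameter count.
#' @export
cnn_n_params <- function(model) {
  cnt <- 0L
  for (l in seq_along(model$params$conv)) {
    cnt <- cnt + length(model$params$conv[[l]]$W) +
      length(model$params$conv[[l]]$b) +
      length(model$params$spec_conv[[l]]$W) +
      length(model$params$spec_conv[[l]]$b)
  }
  cnt + length(model$params$head$W) + length(model$params$head$b)
}

# --- layer primitives ---------------------------------------------------

im2col3 <- function(x) {
  d <- dim(x)
  H <- d[1]; W <- d[2]; C <- d[3]
  pad <- array(0, c(H + 2, W + 2, C))
  pad[2:(H + 1), 2:(W + 1), ] <- x
  cols <- matrix(0, H * W, 9 * C)
  k <- 0L
  for (j in 1:3) for (i in 1:3) {
    cols[, (k * C + 1):((k + 1) * C)] <-
      matrix(pad[i:(i + H - 1), j:(j + W - 1), , drop = FALSE], H * W, C)
    k <- k + 1L
  }
  cols
}

col2im3 <- function(dcols, H, W, C) {
  pad <- array(0, c(H + 2, W + 2, C))
  k <- 0L
  for (j in 1:3) for (i in 1:3) {
    blk <- array(dcols[, (k * C + 1):((k + 1) * C)], c(H, W, C))
    pad[i:(i + H - 1), j:(j + W - 1), ] <-
      pad[i:(i + H - 1), j:(j + W - 1), , drop = FALSE] + blk
    k <- k + 1L
  }
  pad[2:(H + 1), 2:(W + 1), , drop = FALSE]
}

conv_fwd <- function(x, W, b) {
  d <- dim(x)
  cols <- im2col3(x)
  y <- sweep(cols %*% W, 2, b, "+")
  list(y = array(y, c(d[1], d[2], ncol(W))), cols = cols)
}

conv_bwd <- function(dy, cache_cols, W, H, Wd, Cin) {
  dym <- matrix(dy, ncol = ncol(W))
  list(dW = crossprod(cache_cols, dym),
       db = colSums(dym),
       dx = col2im3(dym %*% t(W), H, Wd, Cin))
}

pool_fwd <- function(x) {
  d <- dim(x)
  H2 <- ceiling(d[1] / 2); W2 <- ceiling(d[2] / 2)
  pe <- array(0, c(2 * H2, 2 * W2, d[3]))
  pe[1:d[1], 1:d[2], ] <- x
  io <- seq(1, 2 * H2, 2); jo <- seq(1, 2 * W2, 2)
  s <- list(pe[io, jo, , drop = FALSE], pe[io + 1, jo, , drop = FALSE],
            pe[io, jo + 1, , drop = FALSE], pe[io + 1, jo + 1, , drop = FALSE])
  m <- pmax(s[[1]], s[[2]], s[[3]], s[[4]])
  taken <- array(FALSE, dim(m))
  masks <- vector("list", 4)
  for (k in 1:4) {
    mk <- (s[[k]] == m) & !taken
    taken <- taken | mk
    masks[[k]] <- mk
  }
  list(y = m, masks = masks, in_dim = d, H2 = H2, W2 = W2)
}

pool_bwd <- function(dy, cache) {
  d <- cache$in_dim
  H2 <- cache$H2; W2 <- cache$W2
  pe <- array(0, c(2 * H2, 2 * W2, d[3]))
  io <- seq(1, 2 * H2, 2); jo <- seq(1, 2 * W2, 2)
  pe[io, jo, ] <- dy * cache$masks[[1]]
  pe[io + 1, jo, ] <- dy * cache$masks[[2]]
  pe[io, jo + 1, ] <- dy * cache$masks[[3]]
  pe[io + 1, jo + 1, ] <- dy * cache$masks[[4]]
  pe[1:d[1], 1:d[2], , drop = FALSE]
}

# bilinear interpolation weight matrix (align_corners = FALSE)
bilinear_matrix <- function(n_out, n_in) {
  A <- matrix(0, n_out, n_in)
  scale <- n_in / n_out
  for (i in seq_len(n_out)) {
    src <- (i - 0.5) * scale - 0.5  # 0-based source coordinate
    i0 <- floor(src)
    frac <- src - i0
    i0 <- min(max(i0, 0), n_in - 1)
    i1 <- min(i0 + 1, n_in - 1)
    if (src < 0) { i0 <- i1 <- 0; frac <- 0 }
    A[i, i0 + 1] <- A[i, i0 + 1] + (1 - frac)
    A[i, i1 + 1] <- A[i, i1 + 1] + frac
  }
  A
}

resize_fwd <- function(x, A, B) {
  d <- dim(x)
  y <- array(0, c(nrow(A), nrow(B), d[3]))
  for (c_ in seq_len(d[3])) y[, , c_] <- A %*% x[, , c_] %*% t(B)
  y
}

resize_bwd <- function(dy, A, B, in_dim) {
  dx <- array(0, c(in_dim[1], in_dim[2], in_dim[3]))
  for (c_ in seq_len(in_dim[3])) dx[, , c_] <- t(A) %*% dy[, , c_] %*% B
  dx
}

# --- forward / backward -------------------------------------------------

cnn_forward <- function(model, x) {
  if (is.matrix(x)) x <- array(x, c(dim(x), 1L))
  L <- model$spec$n_conv_layers
  roi <- dim(x)[1:2]
  cache <- list(layers = vector("list", L), roi = roi)
  u <- x
  branches <- vector("list", L)
  for (l in seq_len(L)) {
    lc <- list()
    cv <- conv_fwd(u, model$params$conv[[l]]$W, model$params$conv[[l]]$b)
    lc$conv_cols <- cv$cols; lc$conv_pre <- cv$y; lc$in_dim <- dim(u)
    a <- pmax(cv$y, 0)
    pl <- pool_fwd(a)
    lc$pool <- pl
    sv <- conv_fwd(pl$y, model$params$spec_conv[[l]]$W,
                   model$params$spec_conv[[l]]$b)
    lc$spec_cols <- sv$cols; lc$spec_pre <- sv$y
    sb <- pmax(sv$y, 0)
    lc$A <- bilinear_matrix(roi[1], dim(sb)[1])
    lc$B <- bilinear_matrix(roi[2], dim(sb)[2])
    lc$spec_dim <- dim(sb)
    branches[[l]] <- resize_fwd(sb, lc$A, lc$B)
    cache$layers[[l]] <- lc
    u <- pl$y
  }
  feat <- array(unlist(branches), c(roi[1], roi[2],
                                    L * model$spec$filters_per_layer))
  fm <- matrix(feat, ncol = dim(feat)[3])
  z <- sweep(fm %*% model$params$head$W, 2, model$params$head$b, "+")
  cache$feat <- fm
  z <- array(z, c(roi[1], roi[2], model$n_out))
  if (model$n_out == 1L) {
    P <- 1 / (1 + exp(-z[, , 1]))
  } else {
    zm <- matrix(z, ncol = model$n_out)
    zm <- zm - apply(zm, 1, max)
    ez <- exp(zm)
    P <- array(ez / rowSums(ez), dim(z))
  }
  list(P = P, z = z, cache = cache)
}

cnn_backward <- function(model, fwd, dz) {
  L <- model$spec$n_conv_layers
  Fh <- model$spec$filters_per_layer
  roi <- fwd$cache$roi
  grads <- list(conv = vector("list", L), spec_conv = vector("list", L))
  dzm <- matrix(dz, ncol = model$n_out)
  grads$head <- list(dW = crossprod(fwd$cache$feat, dzm), db = colSums(dzm))
  dfeat <- array(dzm %*% t(model$params$head$W),
                 c(roi[1], roi[2], L * Fh))
  du_next <- NULL
  for (l in rev(seq_len(L))) {
    lc <- fwd$cache$layers[[l]]
    dbr <- dfeat[, , ((l - 1) * Fh + 1):(l * Fh), drop = FALSE]
    dsb <- resize_bwd(dbr, lc$A, lc$B, lc$spec_dim)
    dsb <- dsb * (lc$spec_pre > 0)
    sb_bwd <- conv_bwd(dsb, lc$spec_cols, model$params$spec_conv[[l]]$W,
                       lc$spec_dim[1], lc$spec_dim[2], Fh)
    grads$spec_conv[[l]] <- list(dW = sb_bwd$dW, db = sb_bwd$db)
    dp <- sb_bwd$dx
    if (!is.null(du_next)) dp <- dp + du_next
    da <- pool_bwd(dp, lc$pool)
    da <- da * (lc$conv_pre > 0)
    cin <- model$params$conv[[l]]$cin
    cv_bwd <- conv_bwd(da, lc$conv_cols, model$params$conv[[l]]$W,
                       lc$in_dim[1], lc$in_dim[2], cin)
    grads$conv[[l]] <- list(dW = cv_bwd$dW, db = cv_bwd$db)
    du_next <- cv_bwd$dx
  }
  grads
}

# --- Adam ---------------------------------------------------------------

# walks params/grads/state in parallel; returns list(params, state)
adam_step <- function(params, grads, state, lr, t,
                      b1 = 0.9, b2 = 0.999, eps = 1e-8) {
  upd <- function(p, g, s) {
    s$m <- b1 * s$m + (1 - b1) * g
    s$v <- b2 * s$v + (1 - b2) * g^2
    mh <- s$m / (1 - b1^t)
    vh <- s$v / (1 - b2^t)
    list(p = p - lr * mh / (sqrt(vh) + eps), s = s)
  }
  for (l in seq_along(params$conv)) {
    for (part in c("W", "b")) {
      gname <- paste0("d", part)
      r <- upd(params$conv[[l]][[part]], grads$conv[[l]][[gname]],
               state$conv[[l]][[part]])
      params$conv[[l]][[part]] <- r$p; state$conv[[l]][[part]] <- r$s
      r <- upd(params$spec_conv[[l]][[part]], grads$spec_conv[[l]][[gname]],
               state$spec_conv[[l]][[part]])
      params$spec_conv[[l]][[part]] <- r$p; state$spec_conv[[l]][[part]] <- r$s
    }
  }
  for (part in c("W", "b")) {
    r <- upd(params$head[[part]], grads$head[[paste0("d", part)]],
             state$head[[part]])
    params$head[[part]] <- r$p; state$head[[part]] <- r$s
  }
  list(params = params, state = state)
}

# --- training -----------------------------------------------------------

#' Train a segmentation CNN
#'
#' Stochastic training with the Adam optimizer at a fixed learning rate
#' and batch size 1. Convergence is declared when the residual — the
#' absolute change of the window-5 smoothed training cost between
#' iterations — stays below `tol` for `patience` consecutive iterations.
#'
#' @param model a `cnn_model` from [build_cnn()].
#' @param ds a [slice_dataset()] whose class count matches the model.
#' @param cfg a [loss_config()] (`cbce` for binary models, `bfl` for
#'   multi-class).
#' @param max_iter iteration cap.
#' @param tol,patience convergence rule parameters.
#' @param seed RNG seed controlling the slice visit order.
#' @param verbose print progress every 100 iterations.
#' @return A list with the trained `model` and a `history` data.frame
#'   (`iteration`, `cost`), plus `converged` and `convergence_iteration`.
#' @export
train_cnn <- function(model, ds, cfg, max_iter = 2000, tol = 1e-5,
                      patience = 30, seed = 1L, verbose = FALSE) {
  stopifnot(inherits(model, "cnn_model"), inherits(ds, "slice_dataset"),
            inherits(cfg, "loss_config"))
  if (model$n_out == 1L && ds$n_classes != 2L)
    stop("binary model requires a 2-class dataset")
  if (model$n_out > 1L && ds$n_classes != model$n_out)
    stop("dataset class count does not match the model")
  set.seed(seed)
  lr <- model$spec$learning_rate
  state <- NULL
  costs <- numeric(max_iter)
  consec <- 0L
  converged <- FALSE
  conv_iter <- NA_integer_
  order_pool <- integer(0)
  smooth_prev <- NA_real_
  it <- 0L
  while (it < max_iter) {
    it <- it + 1L
    if (!length(order_pool)) order_pool <- sample.int(ds$N)
    n <- order_pool[1L]; order_pool <- order_pool[-1L]
    fwd <- cnn_forward(model, ds$X[[n]])
    if (cfg$mode == "cbce") {
      Y <- ds$Y[[n]][, , 2]
      cost <- class_balanced_cross_entropy(fwd$P, Y, cfg$eps)
      dz <- array(cbce_logit_grad(fwd$P, Y, cfg$eps), c(dim(Y), 1L))
    } else {
      cost <- balanced_focal_loss(fwd$P, ds$Y[[n]], cfg$gamma, cfg$eps)
      dz <- bfl_logit_grad(fwd$P, ds$Y[[n]], cfg$gamma, cfg$eps)
    }
    if (!is.finite(cost)) {
      warning("training aborted: cost diverged")
      costs <- costs[seq_len(it - 1L)]
      break
    }
    costs[it] <- cost
    grads <- cnn_backward(model, fwd, dz)
    if (is.null(state)) state <- adam_state_like(grads)
    r <- adam_step(model$params, grads, state, lr, it)
    model$params <- r$params; state <- r$state
    w <- costs[max(1L, it - 4L):it]
    smooth <- mean(w)
    if (!is.na(smooth_prev)) {
      if (abs(smooth - smooth_prev) < tol) consec <- consec + 1L
      else consec <- 0L
      if (consec >= patience && !converged) {
        converged <- TRUE
        conv_iter <- it
        costs <- costs[seq_len(it)]
        break
      }
    }
    smooth_prev <- smooth
    if (verbose && it %% 100 == 0)
      message(sprintf("iter %d cost %.5g", it, cost))
  }
  if (!converged) costs <- costs[seq_len(min(it, length(costs)))]
  list(model = model,
       history = data.frame(iteration = seq_along(costs), cost = costs),
       converged = converged, convergence_iteration = conv_iter)
}

adam_state_like <- function(grads) {
  zero_of <- function(g) list(m = g * 0, v = g * 0)
  st <- list(conv = lapply(grads$conv, function(l)
               list(W = zero_of(l$dW), b = zero_of(l$db))),
             spec_conv = lapply(grads$spec_conv, function(l)
               list(W = zero_of(l$dW), b = zero_of(l$db))),
             head = list(W = zero_of(grads$head$dW),
                         b = zero_of(grads$head$db)))
  st
}

#' Predict a label volume from a CT-like intensity volume
#'
#' Runs the network slice by slice over the configured ROI window
#' (a centered crop by default) and stacks the per-pixel class decisions:
#' argmax over the softmax probabilities for multi-class models (ties
#' break to the lowest class id), sigmoid threshold 0.5 for binary
#' models.
#'
#' @param model a trained `cnn_model`.
#' @param volume 3-D intensity array (slices along dim 3), values in
#'   \[0,1\], or a single 2-D matrix.
#' @param roi ROI side length in px (default: full slice).
#' @param roi_offset top-left offset of the ROI window (default
#'   centered).
#' @return 3-D integer array of class ids for the ROI region.
#' @export
predict_segmentation <- function(model, volume, roi = NULL,
                                 roi_offset = NULL) {
  if (is.matrix(volume)) volume <- array(volume, c(dim(volume), 1L))
  d <- dim(volume)
  if (is.null(roi)) roi <- min(d[1], d[2])
  if (roi > d[1] || roi > d[2]) stop("ROI exceeds slice extent")
  if (is.null(roi_offset))
    roi_offset <- floor(c(d[1] - roi, d[2] - roi) / 2)
  i0 <- roi_offset[1]; j0 <- roi_offset[2]
  if (i0 + roi > d[1] || j0 + roi > d[2]) stop("ROI exceeds slice extent")
  out <- array(0L, c(roi, roi, d[3]))
  for (z in seq_len(d[3])) {
    sl <- volume[(i0 + 1):(i0 + roi), (j0 + 1):(j0 + roi), z]
    fwd <- cnn_forward(model, sl)
    if (model$n_out == 1L) {
      out[, , z] <- (fwd$P > 0.5) * 1L
    } else {
      Pm <- matrix(fwd$P, ncol = model$n_out)
      out[, , z] <- max.col(Pm, ties.method = "first") - 1L
    }
  }
  out
}
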