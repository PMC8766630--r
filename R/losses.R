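#' Class-balanced cross entropy for binary segmentation
#'
#' `C = -beta * sum_{Y+} log P - (1-beta) * sum_{Y-} log(1-P)` with the
#' per-image balancing multiplier `beta = |Y-|/|Y|`, natural logarithm.
#' `Y+` is the set of pixels labeled 1 and `Y-` the set labeled 0;
#' the multiplier downweights whichever set dominates the image.
#'
#' @param P matrix of per-pixel probabilities for label 1 (in (0,1),
#'   clamped at `eps`).
#' @param Y binary label matrix of the same shape.
#' @param eps probability clamp applied before taking logs.
#' @return The (summed) cost value for this image.
#' @export
class_balanced_cross_entropy <- function(P, Y, eps = 1e-7) {
  if (length(P) == 0) stop("empty image")
  if (!identical(dim(P), dim(Y)) && length(P) != length(Y))
    stop("P and Y shapes differ")
  if (any(P < 0 | P > 1)) stop("probabilities outside [0,1]")
  if (!all(Y %in% c(0, 1))) stop("Y must be binary")
  P <- pmin(pmax(P, eps), 1 - eps)
  beta <- sum(Y == 0) / length(Y)
  pos <- Y == 1
  -beta * sum(log(P[pos])) - (1 - beta) * sum(log(1 - P[!pos]))
}

# gradient of CBCE w.r.t. the pre-sigmoid logits
cbce_logit_grad <- function(P, Y, eps = 1e-7) {
  P <- pmin(pmax(P, eps), 1 - eps)
  beta <- sum(Y == 0) / length(Y)
  g <- ifelse(Y == 1, -beta * (1 - P), (1 - beta) * P)
  dim(g) <- dim(Y)
  g
}

#' Per-image balancing multipliers of the focal loss
#'
#' `beta_s = exp(-|X_s|/|X|)`: segments with a small pixel share in the
#' image get weights close to 1, dominant segments are damped.
#'
#' @param Y_onehot H x W x S one-hot label array.
#' @return Numeric vector of S multipliers.
#' @export
bfl_class_weights <- function(Y_onehot) {
  n <- dim(Y_onehot)[1] * dim(Y_onehot)[2]
  exp(-apply(Y_onehot, 3, sum) / n)
}

#' Balanced focal loss for multi-class segmentation
#'
#' `BFL = -sum_s sum_{j in Y_s} beta_s (1-P)^gamma log P` where `P` is the
#' predicted probability of the true class of pixel `j`,
#' `beta_s = exp(-|X_s|/|X|)` weights less-dominant segments up, and the
#' modulating factor `(1-P)^gamma` shifts focus to pixels that are
#' misclassified or only weakly correct.
#'
#' @param P H x W x S array of per-pixel class probabilities (summing to 1
#'   over the class dimension).
#' @param Y_onehot H x W x S one-hot labels.
#' @param gamma modulating exponent, `>= 0`.
#' @param eps probability clamp.
#' @param weights optional override of the per-class multipliers
#'   (e.g. `rep(1, S)` turns the loss into plain cross entropy at
#'   `gamma = 0`); default [bfl_class_weights()].
#' @return The (summed) cost value for this image.
#' @export
balanced_focal_loss <- function(P, Y_onehot, gamma = 2, eps = 1e-7,
                                weights = NULL) {
  stopifnot(length(dim(P)) == 3, identical(dim(P), dim(Y_onehot)))
  if (any(P < 0 | P > 1)) stop("probabilities outside [0,1]")
  if (gamma < 0) stop("gamma must be >= 0")
  beta <- weights %||% bfl_class_weights(Y_onehot)
  S <- dim(P)[3]
  tot <- 0
  for (s in seq_len(S)) {
    sel <- Y_onehot[, , s] == 1
    if (!any(sel)) next
    p <- pmin(pmax(P[, , s][sel], eps), 1 - eps)
    tot <- tot - beta[s] * sum((1 - p)^gamma * log(p))
  }
  tot
}

#' Mean balanced focal loss over a dataset
#'
#' @param P_list list of probability arrays.
#' @param Y_list list of one-hot label arrays.
#' @param gamma,eps see [balanced_focal_loss()].
#' @return Mean cost over the dataset.
#' @export
balanced_focal_loss_mean <- function(P_list, Y_list, gamma = 2, eps = 1e-7) {
  stopifnot(length(P_list) == length(Y_list), length(P_list) > 0)
  mean(mapply(balanced_focal_loss, P_list, Y_list,
              MoreArgs = list(gamma = gamma, eps = eps)))
}

# gradient of the BFL w.r.t. pre-softmax logits (H x W x S)
bfl_logit_grad <- function(P, Y_onehot, gamma, eps = 1e-7) {
  d <- dim(P)
  beta <- bfl_class_weights(Y_onehot)
  S <- d[3]
  Pm <- matrix(P, ncol = S)
  Ym <- matrix(Y_onehot, ncol = S)
  true_s <- max.col(Ym, ties.method = "first")
  p_true <- pmin(pmax(Pm[cbind(seq_len(nrow(Pm)), true_s)], eps), 1 - eps)
  omp <- 1 - p_true
  # dL/dP_true for L = -beta (1-P)^g log P
  dLdP <- if (gamma > 0)
    -beta[true_s] * (-gamma * omp^(gamma - 1) * log(p_true) +
                       omp^gamma / p_true)
  else
    -beta[true_s] / p_true
  ps <- Pm[cbind(seq_len(nrow(Pm)), true_s)]
  # chain through softmax: dP_s/dz_k = P_s (delta_sk - P_k)
  G <- -(dLdP * ps) * Pm
  G[cbind(seq_len(nrow(Pm)), true_s)] <-
    G[cbind(seq_len(nrow(Pm)), true_s)] + dLdP * ps
  array(G, d)
}
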