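#' Soft Jaccard (IoU) loss
#'
#' Sum over classes of `1 - (I_c + eps) / (U_c + eps)` where
#' `I_c = sum(p_c * g_c)` is the soft intersection between the predicted
#' class-c probabilities and the one-hot target, and
#' `U_c = sum(p_c) + sum(g_c) - I_c` the soft union. The sum runs over all
#' classes including background, so background leakage is penalised too.
#' Zero iff the prediction is exactly the one-hot target (up to the epsilon
#' smoothing), bounded above by the number of classes, and differentiable in
#' the probabilities.
#'
#' @param prob_map per-class probability array `(H, W, n_classes)` or
#'   `(H, W, n_classes, N)`, per-pixel probabilities summing to 1.
#' @param target integer label mask `(H, W)` or `(H, W, N)` with classes
#'   `0 .. n_classes-1`.
#' @param smooth_eps smoothing constant added to numerator and denominator.
#' @return single nonnegative number.
#' @export
#' @examples
#' m <- matrix(c(0L, 1L, 2L, 0L), 2, 2)
#' p <- array(0, c(2, 2, 3))
#' for (k in 0:2) p[, , k + 1] <- (m == k)   # perfect one-hot prediction
#' jaccard_loss(p, m)                         # ~0
jaccard_loss <- function(prob_map, target, smooth_eps = 1e-6) {
  d <- dim(prob_map)
  nc <- if (length(d) == 3) d[3] else d[3]
  n_img <- if (length(d) == 4) d[4] else 1L
  if (length(dim(target)) == 2) dim(target) <- c(dim(target), 1L)
  if (!all(dim(target)[1:2] == d[1:2]) || dim(target)[3] != n_img) {
    stop_ctrseg("prob_map and target shapes disagree", "ctrseg_shape_error")
  }
  Pm <- matrix(aperm(array(prob_map, c(d[1], d[2], nc, n_img)), c(1, 2, 4, 3)),
               ncol = nc)
  G <- one_hot_mat(as.vector(target), nc)
  jaccard_terms(Pm, G, smooth_eps)$loss
}

one_hot_mat <- function(labels, nc) {
  G <- matrix(0, length(labels), nc)
  G[cbind(seq_along(labels), labels + 1L)] <- 1
  G
}

# loss and gradient w.r.t. the probability matrix (pixels x classes)
jaccard_terms <- function(Pm, G, eps) {
  I <- colSums(Pm * G)
  U <- colSums(Pm) + colSums(G) - I
  loss <- sum(1 - (I + eps) / (U + eps))
  list(loss = loss, I = I, U = U)
}

jaccard_grad <- function(Pm, G, eps) {
  I <- colSums(Pm * G)
  U <- colSums(Pm) + colSums(G) - I
  # d/dp of -(I+eps)/(U+eps): -(g*(U+eps) - (I+eps)*(1-g)) / (U+eps)^2
  den <- (U + eps)^2
  dP <- -(G * rep(U + eps, each = nrow(G)) -
            (1 - G) * rep(I + eps, each = nrow(G))) / rep(den, each = nrow(G))
  dP
}
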