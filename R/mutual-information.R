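# Mutual-information estimators used by the incremental learner selection:
# a plug-in estimate on the joint empirical distribution for discrete
# (label) outputs and a Kraskov-type k-nearest-neighbour estimate for
# continuous outputs, both in nats.

#' Plug-in discrete mutual information
#'
#' Mutual information (natural log, nats) between two discrete vectors under
#' their joint empirical distribution. Zero for constant predictions;
#' symmetric; bounded by the smaller marginal entropy. Multi-learner joint
#' outputs can be passed as a matrix `pred`, whose rows are treated as joint
#' symbols.
#'
#' @param pred Discrete prediction vector, or a matrix of predictions (one
#'   column per learner) taken jointly.
#' @param truth Discrete truth vector of the same length.
#' @return MI estimate in nats, >= 0.
#' @export
discrete_mutual_information <- function(pred, truth) {
  if (is.matrix(pred) || is.data.frame(pred)) {
    pred <- apply(as.matrix(pred), 1L, paste, collapse = "\r")
  }
  if (length(pred) != length(truth)) stop("length mismatch", call. = FALSE)
  n <- length(truth)
  if (n < 1L) stop("empty input", call. = FALSE)
  joint <- table(pred, truth) / n
  px <- rowSums(joint)
  py <- colSums(joint)
  mi <- 0
  for (i in seq_along(px)) {
    for (j in seq_along(py)) {
      p <- joint[i, j]
      if (p > 0) mi <- mi + p * log(p / (px[i] * py[j]))
    }
  }
  max(0, unname(mi))
}

#' Shannon entropy of a discrete vector (nats)
#'
#' @param x Discrete vector.
#' @return Entropy in nats.
#' @export
discrete_entropy <- function(x) {
  p <- table(x) / length(x)
  -sum(p[p > 0] * log(p[p > 0]))
}

#' k-nearest-neighbour continuous mutual information
#'
#' Kraskov-Stoegbauer-Grassberger (first variant) estimator between a
#' continuous (possibly multivariate) prediction and a continuous truth:
#' `MI = psi(k) + psi(N) - mean(psi(n_x + 1) + psi(n_y + 1))` with max-norm
#' neighbourhoods in the joint space. Negative estimates are clamped to 0.
#' Constant (degenerate) columns receive a deterministic seeded jitter of
#' 1e-10 before estimation.
#'
#' @param pred Numeric vector or matrix (columns = learners, taken jointly).
#' @param truth Numeric truth vector.
#' @param k Number of neighbours (default 3).
#' @param jitter_seed Seed for the degenerate-input jitter.
#' @return MI estimate in nats, >= 0.
#' @export
continuous_mutual_information <- function(pred, truth, k = 3L,
                                          jitter_seed = 1L) {
  x <- as.matrix(pred)
  y <- matrix(as.numeric(truth), ncol = 1L)
  n <- nrow(y)
  if (nrow(x) != n) stop("length mismatch", call. = FALSE)
  if (n < k + 2L) stop("need at least k + 2 observations", call. = FALSE)
  local_rng(jitter_seed)
  dejitter <- function(m) {
    for (j in seq_len(ncol(m))) {
      if (stats::var(m[, j]) == 0) m[, j] <- m[, j] + stats::rnorm(n, 0, 1e-10)
    }
    m
  }
  x <- dejitter(x)
  y <- dejitter(y)

  dx <- maxnorm_dist(x)
  dy <- maxnorm_dist(y)
  dz <- pmax(dx, dy)
  diag(dz) <- Inf
  nx <- numeric(n)
  ny <- numeric(n)
  for (i in seq_len(n)) {
    eps <- sort(dz[i, ], partial = k)[k]
    nx[i] <- sum(dx[i, -i] < eps)
    ny[i] <- sum(dy[i, -i] < eps)
  }
  mi <- digamma(k) + digamma(n) - mean(digamma(nx + 1) + digamma(ny + 1))
  max(0, mi)
}

# pairwise Chebyshev (max-norm) distance matrix
maxnorm_dist <- function(m) {
  n <- nrow(m)
  out <- matrix(0, n, n)
  for (j in seq_len(ncol(m))) {
    out <- pmax(out, abs(outer(m[, j], m[, j], `-`)))
  }
  out
}
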