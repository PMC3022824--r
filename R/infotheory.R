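# Information-theoretic primitives used by the sequential information
# bottleneck. All quantities are in bits (base-2 logs), with 0*log(0) := 0.

xlog2x <- function(p) ifelse(p > 0, p * log2(p), 0)

check_dist <- function(p, tol = 1e-6) {
  if (any(p < 0)) stop("distribution has negative mass")
  if (abs(sum(p) - 1) > tol) stop("distribution is not normalized")
  invisible(p)
}

#' Shannon entropy of a discrete distribution (bits)
#'
#' @param p probability vector (non-negative, sums to 1 within 1e-6).
#' @return Entropy in bits.
#' @export
entropy <- function(p) {
  check_dist(p)
  -sum(xlog2x(p))
}

#' Mutual information of a joint probability table (bits)
#'
#' @param joint matrix of joint probabilities p(x, y), summing to 1 within
#'   1e-6.
#' @return `I(X; Y) = H(X) + H(Y) - H(X, Y)` in bits; always >= 0 up to
#'   rounding.
#' @export
mutual_information <- function(joint) {
  joint <- as.matrix(joint)
  check_dist(joint)
  px <- rowSums(joint); py <- colSums(joint)
  sum(xlog2x(joint)) - sum(xlog2x(px)) - sum(xlog2x(py))
}

#' Weighted Jensen-Shannon divergence (bits)
#'
#' `JS_w(p, q) = w1 KL(p || m) + w2 KL(q || m)` with `m = w1 p + w2 q`.
#'
#' @param p,q probability vectors over the same support.
#' @param weights positive pair summing to 1 (default `c(0.5, 0.5)`).
#' @return Divergence in bits, in `[0, H(weights)]`.
#' @export
js_divergence <- function(p, q, weights = c(0.5, 0.5)) {
  check_dist(p); check_dist(q)
  if (length(p) != length(q)) stop("p and q must share a support")
  if (length(weights) != 2L || any(weights <= 0) || abs(sum(weights) - 1) > 1e-6)
    stop("weights must be two positive numbers summing to 1")
  m <- weights[1] * p + weights[2] * q
  kl <- function(a) {
    i <- a > 0
    sum(a[i] * (log2(a[i]) - log2(m[i])))
  }
  weights[1] * kl(p) + weights[2] * kl(q)
}
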