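#' Fisher linear discriminant for case-control genotype codes
#'
#' The classical two-class Fisher rule: project onto
#' `w = S_w^{-1} (mu_case - mu_control)`, where `S_w` is the pooled
#' (unbiased, class-mean-centered) within-class covariance, and threshold at
#' the midpoint of the projected class means (equal priors). A small ridge
#' `eps * trace(S_w) / d` stabilises the solve and is escalated tenfold until
#' the system is solvable (degenerate features such as monomorphic SNPs make
#' `S_w` singular). Scores on the boundary are called case.
#'
#' @param X numeric matrix, samples x features (genotype codes as reals).
#' @param y per-sample 1/0 labels; both classes must be present.
#' @param ridge_eps relative ridge epsilon (default 1e-8).
#' @return A list of class `lda_model`: `weights`, `threshold`,
#'   `class_means`, `ridge`.
#' @export
lda_fit <- function(X, y, ridge_eps = 1e-8) {
  X <- as.matrix(X); storage.mode(X) <- "double"
  y <- as.integer(y)
  if (nrow(X) != length(y)) stop("X rows must match length(y)")
  if (!all(0:1 %in% y)) stop("both classes must be present in y")
  X1 <- X[y == 1L, , drop = FALSE]
  X0 <- X[y == 0L, , drop = FALSE]
  mu1 <- colMeans(X1); mu0 <- colMeans(X0)
  d <- ncol(X); n <- nrow(X)
  C1 <- crossprod(sweep(X1, 2L, mu1))
  C0 <- crossprod(sweep(X0, 2L, mu0))
  Sw <- (C1 + C0) / max(n - 2L, 1L)
  base <- ridge_eps * sum(diag(Sw)) / d
  if (base <= 0) base <- ridge_eps           # zero-variance features: absolute fallback
  ridge <- base
  w <- NULL
  repeat {
    w <- tryCatch(solve(Sw + diag(ridge, d), mu1 - mu0),
                  error = function(e) NULL)
    if (!is.null(w)) break
    ridge <- if (ridge > 0) ridge * 10 else .Machine$double.eps
    if (!is.finite(ridge)) stop("LDA ridge escalation failed")
  }
  structure(list(weights = as.numeric(w),
                 threshold = sum(w * (mu1 + mu0)) / 2,
                 class_means = list(case = mu1, control = mu0),
                 ridge = ridge),
            class = "lda_model")
}

#' @rdname lda_fit
#' @param model a fitted `lda_model`.
#' @return `lda_predict`: integer 1/0 predictions (1 = case), boundary
#'   scores map to case.
#' @export
lda_predict <- function(model, X) {
  stopifnot(inherits(model, "lda_model"))
  X <- as.matrix(X); storage.mode(X) <- "double"
  if (ncol(X) != length(model$weights)) stop("feature count mismatch")
  scores <- as.vector(X %*% model$weights)
  as.integer(scores >= model$threshold)
}
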