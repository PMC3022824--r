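#' Classifier specification for the wrapper searches
#'
#' A small handle naming the classifier wrapped by the subset searches plus
#' its hyper-parameters. `"lda"` is the Fisher discriminant on genotype
#' codes; `"sib"` is the sequential information bottleneck with dominant-
#' class cluster labelling.
#'
#' @param method `"lda"` or `"sib"`.
#' @param K,beta,n_restarts,max_sweeps sIB settings (see [sib_fit()]).
#' @param ridge_eps LDA ridge epsilon (see [lda_fit()]).
#' @return A list of class `classifier_spec`.
#' @export
classifier_spec <- function(method = c("lda", "sib"), K = 2L, beta = 10,
                            n_restarts = 10L, max_sweeps = 50L,
                            ridge_eps = 1e-8) {
  method <- match.arg(method)
  structure(list(method = method, K = as.integer(K), beta = beta,
                 n_restarts = as.integer(n_restarts),
                 max_sweeps = as.integer(max_sweeps),
                 ridge_eps = ridge_eps),
            class = "classifier_spec")
}

#' Fit / predict through a classifier spec
#'
#' @param spec a [classifier_spec()].
#' @param G a complete [genotype_matrix()].
#' @param y per-sample 1/0 labels.
#' @param subset SNP ids or indices.
#' @param seed seed for any classifier randomness (sIB restarts).
#' @return `fit_classifier`: a fitted model wrapper; `predict_classifier`:
#'   integer 1/0 predictions.
#' @export
fit_classifier <- function(spec, G, y, subset, seed = 1L) {
  stopifnot(inherits(spec, "classifier_spec"))
  if (spec$method == "lda") {
    X <- subset_genotypes(G, snps = subset)$codes
    model <- lda_fit(X, y, ridge_eps = spec$ridge_eps)
  } else {
    prof <- build_sample_profiles(G, subset)
    model <- sib_fit(prof, y, K = spec$K, beta = spec$beta,
                     n_restarts = spec$n_restarts,
                     max_sweeps = spec$max_sweeps, seed = seed)
  }
  structure(list(spec = spec, subset = subset, model = model),
            class = "fitted_classifier")
}

#' @rdname fit_classifier
#' @param fitted a `fitted_classifier` from [fit_classifier()].
#' @export
predict_classifier <- function(fitted, G) {
  stopifnot(inherits(fitted, "fitted_classifier"))
  if (fitted$spec$method == "lda") {
    lda_predict(fitted$model, subset_genotypes(G, snps = fitted$subset)$codes)
  } else {
    sib_predict(fitted$model, build_sample_profiles(G, fitted$subset))
  }
}

# stable 32-bit FNV-1a hash of a tag string, folded with the master seed;
# keeps every stage's seed deterministic, documented, and < 2^31
derive_seed <- function(master_seed, tag) {
  bytes <- utf8ToInt(paste0(tag, ":", master_seed))
  h <- 2166136261
  for (b in bytes) {
    low <- h %% 256
    h <- h - low + bitwXor(as.integer(low), as.integer(b))
    # 32-bit modular multiply kept exact in doubles by splitting into halves
    h <- ((((h %/% 65536) * 16777619) %% 65536) * 65536 +
            (h %% 65536) * 16777619) %% 4294967296
  }
  as.integer(h %% 2147483647) + 1L
}
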