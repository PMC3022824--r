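#' Build sample token profiles for the information bottleneck
#'
#' The bottleneck's relevance variable Y ranges over genotype feature tokens,
#' one token per (SNP, genotype category) pair — mirroring the document/word
#' construction of classical sIB document clustering. For an s-SNP subset,
#' each sample's profile p(y|x) puts mass 1/s on the token of its observed
#' category at each subset SNP; samples carry uniform prior mass
#' p(x) = 1/n.
#'
#' @param G a complete (imputed) [genotype_matrix()].
#' @param subset SNP ids or column indices defining the subset (non-empty).
#' @param samples optional sample selector (ids or indices; default all).
#' @return An object of class `sib_profiles`: `codes` (n x s integer
#'   matrix), `snp_ids`, `tokens` (length 3s, `"rs123:0"` style), `n`.
#' @export
build_sample_profiles <- function(G, subset, samples = NULL) {
  stopifnot(inherits(G, "genotype_matrix"))
  if (!length(subset)) stop("SNP subset must be non-empty")
  Gs <- subset_genotypes(G, snps = subset, samples = samples)
  if (anyNA(Gs$codes)) stop("profiles need complete genotypes; impute first")
  s <- ncol(Gs$codes)
  structure(list(codes = Gs$codes,
                 snp_ids = Gs$snp_ids,
                 tokens = paste0(rep(Gs$snp_ids, each = 3L), ":", 0:2),
                 n = nrow(Gs$codes)),
            class = "sib_profiles")
}

#' Dense profile matrix p(y|x) of a `sib_profiles` object
#'
#' @param profiles a [build_sample_profiles()] result.
#' @return n x 3s matrix; each row sums to 1.
#' @export
profile_masses <- function(profiles) {
  stopifnot(inherits(profiles, "sib_profiles"))
  s <- ncol(profiles$codes)
  n <- profiles$n
  M <- matrix(0, n, 3L * s, dimnames = list(NULL, profiles$tokens))
  for (k in seq_len(s))
    M[cbind(seq_len(n), 3L * (k - 1L) + profiles$codes[, k] + 1L)] <- 1 / s
  M
}

#' Information bottleneck objective of a hard partition
#'
#' Evaluates `L = I(C;X) - beta * I(C;Y)` from scratch. Under hard
#' assignment with uniform p(x), `I(C;X) = H(C)`; `I(C;Y)` comes from the
#' induced joint `p(c, y) = sum_{x in c} p(x) p(y|x)`. This direct
#' recomputation is the audit path against the incremental objective
#' maintained inside [sib_fit()].
#'
#' @param partition integer cluster index per sample (1..K).
#' @param profiles a [build_sample_profiles()] result.
#' @param beta bottleneck trade-off multiplier (> 0).
#' @return The objective value in bits.
#' @export
ib_objective <- function(partition, profiles, beta) {
  stopifnot(inherits(profiles, "sib_profiles"))
  partition <- as.integer(partition)
  n <- profiles$n
  if (length(partition) != n) stop("partition must cover every profile")
  K <- max(partition)
  M <- profile_masses(profiles)
  joint <- matrix(0, K, ncol(M))
  for (c in seq_len(K)) {
    i <- partition == c
    if (any(i)) joint[c, ] <- colSums(M[i, , drop = FALSE]) / n
  }
  pc <- rowSums(joint)
  entropy(pc) - beta * mutual_information(joint)
}

#' Fit a sequential information bottleneck clustering for classification
#'
#' Hard sIB: starting from a random partition into K clusters, samples are
#' repeatedly drawn in a seeded random order, removed from their cluster and
#' reinserted into the cluster minimizing the exact change of
#' `L = I(C;X) - beta I(C;Y)` (ties to the lowest cluster index); a restart
#' converges when a full sweep moves nothing. The best of `n_restarts`
#' random restarts (minimal L) is kept. Clusters are then labelled by their
#' majority training class (ties label control), which turns the
#' unsupervised partition into a classifier.
#'
#' @param profiles a [build_sample_profiles()] result (training samples).
#' @param labels per-sample 1/0 training labels; both classes required.
#' @param K number of clusters (default 2).
#' @param beta bottleneck multiplier (default 10): large beta weights
#'   relevance I(C;Y) over compression.
#' @param n_restarts random restarts (default 10).
#' @param max_sweeps cap on sweeps per restart (default 50).
#' @param seed integer seed; fits are bit-reproducible given it.
#' @param record_trace keep the objective after every reassignment (for
#'   monotonicity audits).
#' @return An object of class `sib_model` with the partition, per-cluster
#'   mass `p(c)`, conditional profiles `p(y|c)`, binary cluster labels
#'   (`NA` for empty clusters), the final objective, and the fit settings.
#' @export
sib_fit <- function(profiles, labels, K = 2L, beta = 10, n_restarts = 10L,
                    max_sweeps = 50L, seed = 1L, record_trace = FALSE) {
  stopifnot(inherits(profiles, "sib_profiles"))
  labels <- as.integer(labels)
  n <- profiles$n
  if (length(labels) != n) stop("labels must match the number of profiles")
  if (!all(0:1 %in% labels)) stop("both classes must be present in labels")
  if (K > n) stop("K must not exceed the number of samples")
  fit <- .sib_fit_cpp(profiles$codes, as.integer(K), as.double(beta),
                      as.integer(n_restarts), as.integer(max_sweeps),
                      as.double(seed), record_trace)
  sizes <- fit$cluster_sizes
  cluster_label <- rep(NA_integer_, K)
  for (c in seq_len(K)) {
    if (sizes[c] == 0L) next
    lc <- labels[fit$assignment == c]
    cluster_label[c] <- if (sum(lc == 1L) > sum(lc == 0L)) 1L else 0L  # tie -> control
  }
  prof <- fit$cluster_token_sums
  cluster_profile <- prof / ifelse(sizes > 0L, sizes, 1L)
  colnames(cluster_profile) <- profiles$tokens
  structure(list(K = as.integer(K), beta = beta,
                 assignment = fit$assignment,
                 cluster_mass = sizes / n,
                 cluster_sizes = sizes,
                 cluster_token_sums = fit$cluster_token_sums,
                 cluster_profile = cluster_profile,
                 cluster_label = cluster_label,
                 objective = fit$objective,
                 restart_objectives = fit$restart_objectives,
                 best_restart = fit$best_restart,
                 trace = fit$trace, trace_restart = fit$trace_restart,
                 tokens = profiles$tokens, snp_ids = profiles$snp_ids,
                 n_train = n,
                 n_restarts = as.integer(n_restarts),
                 max_sweeps = as.integer(max_sweeps),
                 seed = as.integer(seed)),
            class = "sib_model")
}

#' @export
print.sib_model <- function(x, ...) {
  cat(sprintf("sIB model: K=%d, beta=%g, L=%.6f bits, cluster sizes [%s], labels [%s]\n",
              x$K, x$beta, x$objective,
              paste(x$cluster_sizes, collapse = ", "),
              paste(x$cluster_label, collapse = ", ")))
  invisible(x)
}

#' Predict case-control labels with a frozen sIB model
#'
#' Each new sample is assigned to the non-empty cluster minimizing the
#' weighted Jensen-Shannon insertion cost
#' `(p_x + p(c)) * JS(p(y|x), p(y|c))` with nominal mass `p_x = 1/n_train`
#' (the model is not updated), and receives that cluster's label.
#'
#' @param model a fitted [sib_fit()] model.
#' @param profiles new-sample profiles over the same SNP subset.
#' @return Integer 1/0 predictions.
#' @export
sib_predict <- function(model, profiles) {
  stopifnot(inherits(model, "sib_model"), inherits(profiles, "sib_profiles"))
  if (!identical(profiles$tokens, model$tokens))
    stop("token space mismatch: profiles were built on a different SNP subset")
  cl <- .sib_assign_cpp(profiles$codes, model$cluster_token_sums,
                        model$cluster_sizes, model$n_train)
  model$cluster_label[cl]
}

#' Serialize a fitted model to JSON text
#'
#' Writes every field of an `sib_model` or `lda_model` to a JSON file for
#' audit and frozen-model prediction; [read_model()] restores it.
#'
#' @param model an `sib_model` or `lda_model`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_model <- function(model, path) {
  cls <- class(model)[1]
  if (!cls %in% c("sib_model", "lda_model"))
    stop("only sib_model and lda_model can be serialized")
  payload <- c(list(.class = cls), unclass(model))
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       null = "null", na = "null")
  invisible(path)
}

#' @rdname write_model
#' @export
read_model <- function(path) {
  payload <- jsonlite::read_json(path, simplifyVector = TRUE)
  cls <- payload$.class
  payload$.class <- NULL
  if (cls == "sib_model") {
    payload$cluster_token_sums <- as.matrix(payload$cluster_token_sums)
    payload$cluster_profile <- as.matrix(payload$cluster_profile)
    payload$cluster_label <- as.integer(payload$cluster_label)
    payload$cluster_sizes <- as.integer(payload$cluster_sizes)
  }
  if (cls == "lda_model")
    payload$class_means <- lapply(payload$class_means, as.numeric)
  structure(payload, class = cls)
}
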