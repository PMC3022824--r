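#' Stratified cross-validation folds
#'
#' Splits samples into `k` non-overlapping folds, stratified by class so
#' that per-class fold sizes differ by at most one and both classes appear
#' in every fold.
#'
#' @param labels per-sample 1/0 labels.
#' @param k number of folds (default 5).
#' @param seed seed for the within-class shuffles.
#' @return A list of class `fold_split`: `fold` (per-sample fold index 1..k)
#'   and `k`.
#' @export
make_folds <- function(labels, k = 5L, seed = 1L) {
  labels <- as.integer(labels)
  k <- as.integer(k)
  n1 <- sum(labels == 1L); n0 <- sum(labels == 0L)
  if (min(n1, n0) < k)
    stop(sprintf("each class needs at least k=%d members (have %d cases, %d controls)",
                 k, n1, n0))
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  fold <- integer(length(labels))
  for (cls in c(1L, 0L)) {
    idx <- which(labels == cls)
    idx <- idx[sample.int(length(idx))]
    fold[idx] <- rep_len(seq_len(k), length(idx))
  }
  structure(list(fold = fold, k = k), class = "fold_split")
}

subset_key <- function(subset) paste(sort(as.character(subset)), collapse = ",")

#' Cross-validated evaluation of one SNP subset
#'
#' For each used fold the classifier is fitted on the remaining folds and
#' predicts the held-out fold; all out-of-fold predictions are pooled into a
#' single confusion table, whose HMSS is the search criterion (pooling keeps
#' the criterion defined even when a fold is class-thin).
#'
#' @param spec a [classifier_spec()].
#' @param G complete training [genotype_matrix()].
#' @param y training labels.
#' @param subset SNP ids or indices (non-empty).
#' @param folds a [make_folds()] split of `y`.
#' @param master_seed seed root; each fold fit derives its own seed from
#'   `(subset, fold)` so runs are reproducible.
#' @param use_folds which folds to rotate through (default all; `1` gives
#'   the single 4+1 split reading of the design).
#' @param cache optional environment memoising results by subset.
#' @return A list: `hmss`, `total_acc`, `case_acc`, `control_acc`,
#'   `confusion`, and the pooled `y_true` / `y_pred`.
#' @export
cv_eval <- function(spec, G, y, subset, folds, master_seed = 1L,
                    use_folds = seq_len(folds$k), cache = NULL) {
  key <- subset_key(subset)
  if (!is.null(cache) && !is.null(cache[[key]])) return(cache[[key]])
  y <- as.integer(y)
  Gs <- subset_genotypes(G, snps = subset)   # restrict SNPs once, up front
  yt <- integer(0); yp <- integer(0)
  for (f in use_folds) {
    hold <- folds$fold == f
    seed_f <- derive_seed(master_seed, paste0("cv:", key, ":fold", f))
    fit <- fit_classifier(spec, subset_genotypes(Gs, samples = which(!hold)),
                          y[!hold], Gs$snp_ids, seed = seed_f)
    yt <- c(yt, y[hold])
    yp <- c(yp, predict_classifier(fit, subset_genotypes(Gs, samples = which(hold))))
  }
  cc <- confusion(yt, yp)
  out <- list(hmss = hmss(cc), total_acc = total_accuracy(cc),
              case_acc = group_accuracy(cc, "cases"),
              control_acc = group_accuracy(cc, "controls"),
              confusion = cc, y_true = yt, y_pred = yp)
  if (!is.null(cache)) cache[[key]] <- out
  out
}

#' @rdname cv_eval
#' @return `cv_hmss`: a list with the pooled out-of-fold `hmss` and the
#'   pooled `predictions` data frame.
#' @export
cv_hmss <- function(spec, G, y, subset, folds, master_seed = 1L,
                    use_folds = seq_len(folds$k)) {
  ev <- cv_eval(spec, G, y, subset, folds, master_seed, use_folds)
  list(hmss = ev$hmss,
       predictions = data.frame(y_true = ev$y_true, y_pred = ev$y_pred))
}

#' Single-SNP LDA-HMSS filter ranking
#'
#' The first-stage filter: every SNP is scored by the resubstitution
#' (training) HMSS of a single-feature Fisher discriminant fitted on the
#' full training cohort, and the `top_k` highest-scoring SNPs are returned.
#' Ties break by smaller chi-square association p-value, then by rs id —
#' all test-blind and deterministic.
#'
#' @param G complete training [genotype_matrix()].
#' @param y training labels.
#' @param top_k number of SNPs to keep (default 1000; capped at the SNP
#'   count).
#' @return Data frame ranked best-first: `snp_id`, `train_hmss`, `chisq_p`.
#' @export
filter_rank <- function(G, y, top_k = 1000L) {
  stopifnot(inherits(G, "genotype_matrix"))
  if (anyNA(G$codes)) stop("filter_rank needs a complete (imputed) matrix")
  y <- as.integer(y)
  m <- length(G$snp_ids)
  score <- numeric(m)
  for (j in seq_len(m)) {
    fit <- lda_fit(G$codes[, j, drop = FALSE], y)
    score[j] <- hmss(confusion(y, lda_predict(fit, G$codes[, j, drop = FALSE])))
  }
  pvals <- chi_square_scan(G, y)$p_value
  ord <- order(-score, pvals, G$snp_ids)
  keep <- ord[seq_len(min(as.integer(top_k), m))]
  data.frame(snp_id = G$snp_ids[keep],
             train_hmss = score[keep],
             chisq_p = pvals[keep],
             stringsAsFactors = FALSE)
}

as_candidates <- function(candidates, G, y) {
  if (is.data.frame(candidates)) {
    stopifnot(all(c("snp_id", "train_hmss") %in% names(candidates)))
    if (is.null(candidates$chisq_p)) candidates$chisq_p <- NA_real_
    return(candidates)
  }
  # plain id vector: score them so tie-breaks stay defined
  filter_rank(subset_genotypes(G, snps = candidates), y,
              top_k = length(candidates))
}

# deterministic, test-blind ordering of candidate additions:
# higher single-SNP training HMSS first, then smaller chi-square p, then rs id
candidate_order <- function(cand) order(-cand$train_hmss, cand$chisq_p, cand$snp_id)

new_trace_env <- function() new.env(parent = emptyenv())

#' Forward selection of a SNP subset by cross-validated HMSS
#'
#' Greedy wrapper search: starting from the empty set, each step adds the
#' candidate whose inclusion maximizes the pooled out-of-fold HMSS
#' (candidate ties break by single-SNP training HMSS, then chi-square p,
#' then rs id). Test-cohort metrics are attached to the per-size records
#' after the search finishes and never influence selection.
#'
#' @param spec a [classifier_spec()].
#' @param candidates ranked candidate data frame from [filter_rank()] (or a
#'   vector of SNP ids).
#' @param G_train,y_train,G_test,y_test complete cohorts.
#' @param folds a [make_folds()] split of `y_train`.
#' @param max_size largest subset size to reach (default 40).
#' @param master_seed seed root for fold fits and bootstrap CIs.
#' @param n_boot bootstrap iterations for the reported CIs (default 200).
#' @param use_folds folds rotated through (see [cv_eval()]).
#' @return A `search_trace`: list with `table` (one row per size) and
#'   `records` (full [evaluate_on_test()] records per size).
#' @export
forward_selection <- function(spec, candidates, G_train, y_train,
                              G_test, y_test, folds, max_size = 40L,
                              master_seed = 1L, n_boot = 200L,
                              use_folds = seq_len(folds$k)) {
  cand <- as_candidates(candidates, G_train, y_train)
  max_size <- as.integer(max_size)
  if (max_size > nrow(cand)) stop("max_size exceeds the number of candidates")
  cache <- new_trace_env()
  current <- character(0)
  sizes <- list()
  pref <- candidate_order(cand)
  for (size in seq_len(max_size)) {
    remaining <- setdiff(cand$snp_id, current)
    # evaluate candidates in deterministic preference order; strict > keeps
    # the earliest (preferred) candidate on ties
    best_snp <- NULL; best_cv <- -Inf
    for (snp in cand$snp_id[pref]) {
      if (!(snp %in% remaining)) next
      ev <- cv_eval(spec, G_train, y_train, c(current, snp), folds,
                    master_seed, use_folds, cache)
      if (ev$hmss > best_cv) { best_cv <- ev$hmss; best_snp <- snp }
    }
    current <- c(current, best_snp)
    sizes[[size]] <- list(subset = current, cv_hmss = best_cv)
  }
  build_trace(spec, sizes, G_train, y_train, G_test, y_test, folds,
              master_seed, n_boot, use_folds, cache, search_tag = "fs")
}

#' Sequential forward floating selection (SFFS) by cross-validated HMSS
#'
#' Starts from the best 2-SNP subset found by exhaustively evaluating all
#' candidate pairs, then alternates inclusion (best single addition by CV
#' HMSS) with conditional exclusions: the element whose removal maximizes CV
#' HMSS is dropped only when the reduced subset strictly beats the best
#' subset known at that size; exclusions repeat until none is accepted.
#' A best-per-size table is maintained and reported; the search stops once
#' size `max_size` is reached after an inclusion.
#'
#' @inheritParams forward_selection
#' @param max_size largest subset size (default 35, must be >= 2).
#' @return A `search_trace` over sizes 2..`max_size`.
#' @export
sffs <- function(spec, candidates, G_train, y_train, G_test, y_test,
                 folds, max_size = 35L, master_seed = 1L, n_boot = 200L,
                 use_folds = seq_len(folds$k)) {
  cand <- as_candidates(candidates, G_train, y_train)
  max_size <- as.integer(max_size)
  if (nrow(cand) < 2L) stop("SFFS needs at least two candidates")
  if (max_size < 2L) stop("max_size must be >= 2 for SFFS")
  if (max_size > nrow(cand)) stop("max_size exceeds the number of candidates")
  cache <- new_trace_env()
  pref <- candidate_order(cand)
  ids_pref <- cand$snp_id[pref]

  eval_cv <- function(subset)
    cv_eval(spec, G_train, y_train, subset, folds, master_seed, use_folds,
            cache)$hmss

  # best-per-size table
  best <- vector("list", max_size)
  note_best <- function(subset, score) {
    k <- length(subset)
    if (k >= 1L && k <= max_size &&
        (is.null(best[[k]]) || score > best[[k]]$cv_hmss))
      best[[k]] <<- list(subset = subset, cv_hmss = score)
    invisible(NULL)
  }

  # exhaustive pair initialization
  n_cand <- nrow(cand)
  for (i in seq_len(n_cand - 1L)) for (j in (i + 1L):n_cand) {
    pair <- c(ids_pref[i], ids_pref[j])
    note_best(pair, eval_cv(pair))
  }
  current <- best[[2L]]$subset

  repeat {
    # inclusion
    add_best <- NULL; add_cv <- -Inf
    for (snp in ids_pref) {
      if (snp %in% current) next
      sc <- eval_cv(c(current, snp))
      if (sc > add_cv) { add_cv <- sc; add_best <- snp }
    }
    current <- c(current, add_best)
    note_best(current, add_cv)
    if (length(current) >= max_size) break
    # conditional exclusions
    repeat {
      if (length(current) <= 2L) break
      drop_best <- NULL; drop_cv <- -Inf
      for (snp in intersect(ids_pref, current)) {
        sc <- eval_cv(setdiff(current, snp))
        if (sc > drop_cv) { drop_cv <- sc; drop_best <- snp }
      }
      k <- length(current) - 1L
      if (!is.null(best[[k]]) && drop_cv > best[[k]]$cv_hmss) {
        current <- setdiff(current, drop_best)
        note_best(current, drop_cv)
      } else break
    }
  }

  sizes <- best[2L:max_size]
  names(sizes) <- NULL
  build_trace(spec, sizes, G_train, y_train, G_test, y_test, folds,
              master_seed, n_boot, use_folds, cache, search_tag = "sffs",
              sizes_are = 2L:max_size)
}

#' Exhaustive small-subset search by cross-validated HMSS
#'
#' Evaluates every candidate subset of the requested sizes (1 and/or 2 by
#' default; larger sizes need `allow_large = TRUE` — the combinatorics grow
#' fast) and ranks them by pooled out-of-fold HMSS with deterministic,
#' input-order-invariant tie-breaks. Test metrics with bootstrap CIs are
#' computed for the top `report_top` subsets per size.
#'
#' @inheritParams forward_selection
#' @param sizes subset sizes to enumerate (default `c(1, 2)`).
#' @param allow_large set TRUE to permit sizes >= 3.
#' @param report_top how many top subsets per size get full test records
#'   (default 1).
#' @return A list: `table` (all evaluated subsets, ranked), `records`
#'   (full records for the reported top subsets).
#' @export
exhaustive_search <- function(spec, candidates, G_train, y_train,
                              G_test, y_test, folds, sizes = c(1L, 2L),
                              allow_large = FALSE, report_top = 1L,
                              master_seed = 1L, n_boot = 200L,
                              use_folds = seq_len(folds$k)) {
  cand <- as_candidates(candidates, G_train, y_train)
  sizes <- sort(unique(as.integer(sizes)))
  if (any(sizes >= 3L) && !allow_large)
    stop("sizes >= 3 require allow_large = TRUE (combinatorial cost)")
  cache <- new_trace_env()
  ids_pref <- cand$snp_id[candidate_order(cand)]
  rows <- list()
  for (k in sizes) {
    combos <- utils::combn(ids_pref, k, simplify = FALSE)
    for (subset in combos) {
      ev <- cv_eval(spec, G_train, y_train, subset, folds, master_seed,
                    use_folds, cache)
      rows[[length(rows) + 1L]] <-
        data.frame(size = k, snp_ids = paste(subset, collapse = ";"),
                   cv_hmss = ev$hmss, cv_total_acc = ev$total_acc,
                   cv_case_acc = ev$case_acc, cv_control_acc = ev$control_acc,
                   stringsAsFactors = FALSE)
    }
  }
  tab <- do.call(rbind, rows)
  # rank by CV HMSS; ties by enumeration order, which itself follows the
  # deterministic candidate preference order (input-order invariant)
  tab <- tab[order(-tab$cv_hmss), , drop = FALSE]
  rownames(tab) <- NULL
  records <- list()
  for (k in sizes) {
    tk <- tab[tab$size == k, , drop = FALSE]
    for (r in seq_len(min(report_top, nrow(tk)))) {
      subset <- strsplit(tk$snp_ids[r], ";", fixed = TRUE)[[1]]
      records[[length(records) + 1L]] <-
        evaluate_on_test(spec, subset, G_train, y_train, G_test, y_test,
                         folds = folds, master_seed = master_seed,
                         n_boot = n_boot, use_folds = use_folds,
                         cache = cache,
                         search_tag = sprintf("exhaustive_%d", k))
    }
  }
  list(table = tab, records = records)
}

#' Constrained group-accuracy search
#'
#' Over all candidate subsets of the given sizes, keeps those whose
#' cross-validated accuracy in the constrained group (cases or controls) is
#' at least `min_acc`, ranks the survivors by CV accuracy in the other
#' group, takes the top `top_n`, computes their test group accuracies with
#' bootstrap CIs, and reports them ranked by test accuracy in the other
#' group. Answers questions of the form "how well can controls be predicted
#' when case accuracy must stay >= 0.4".
#'
#' @inheritParams exhaustive_search
#' @param constrained_group `"cases"` or `"controls"`: the group whose CV
#'   accuracy must reach `min_acc`.
#' @param min_acc constraint level (default 0.4).
#' @param top_n candidates carried to test evaluation (default 20).
#' @return A list: `table` (top_n rows with CV and test group accuracies,
#'   ranked by test accuracy in the unconstrained group), `records`, and
#'   `status` (`"ok"` or `"empty"` when no subset satisfies the constraint).
#' @export
constrained_search <- function(spec, candidates, G_train, y_train,
                               G_test, y_test, folds,
                               constrained_group = c("cases", "controls"),
                               min_acc = 0.4, top_n = 20L,
                               sizes = c(1L, 2L), allow_large = FALSE,
                               master_seed = 1L, n_boot = 200L,
                               use_folds = seq_len(folds$k)) {
  constrained_group <- match.arg(constrained_group)
  other_group <- if (constrained_group == "cases") "controls" else "cases"
  cand <- as_candidates(candidates, G_train, y_train)
  sizes <- sort(unique(as.integer(sizes)))
  if (any(sizes >= 3L) && !allow_large)
    stop("sizes >= 3 require allow_large = TRUE (combinatorial cost)")
  cache <- new_trace_env()
  ids_pref <- cand$snp_id[candidate_order(cand)]
  con_col <- if (constrained_group == "cases") "cv_case_acc" else "cv_control_acc"
  oth_col <- if (constrained_group == "cases") "cv_control_acc" else "cv_case_acc"
  rows <- list()
  for (k in sizes) {
    for (subset in utils::combn(ids_pref, k, simplify = FALSE)) {
      ev <- cv_eval(spec, G_train, y_train, subset, folds, master_seed,
                    use_folds, cache)
      rows[[length(rows) + 1L]] <-
        data.frame(size = k, snp_ids = paste(subset, collapse = ";"),
                   cv_hmss = ev$hmss, cv_case_acc = ev$case_acc,
                   cv_control_acc = ev$control_acc, stringsAsFactors = FALSE)
    }
  }
  tab <- do.call(rbind, rows)
  ok <- tab[[con_col]] >= min_acc
  if (!any(ok))
    return(list(table = tab[0, ], records = list(), status = "empty",
                constrained_group = constrained_group, min_acc = min_acc))
  tab <- tab[ok, , drop = FALSE]
  tab <- tab[order(-tab[[oth_col]]), , drop = FALSE]
  tab <- tab[seq_len(min(top_n, nrow(tab))), , drop = FALSE]
  records <- list()
  test_oth <- test_oth_lo <- test_oth_hi <- test_con <- numeric(nrow(tab))
  for (r in seq_len(nrow(tab))) {
    subset <- strsplit(tab$snp_ids[r], ";", fixed = TRUE)[[1]]
    rec <- evaluate_on_test(spec, subset, G_train, y_train, G_test, y_test,
                            folds = folds, master_seed = master_seed,
                            n_boot = n_boot, use_folds = use_folds,
                            cache = cache, search_tag = "constrained")
    records[[r]] <- rec
    oth_m <- if (other_group == "cases") rec$test$case_acc else rec$test$control_acc
    con_m <- if (constrained_group == "cases") rec$test$case_acc else rec$test$control_acc
    test_oth[r] <- oth_m$point; test_oth_lo[r] <- oth_m$ci_low
    test_oth_hi[r] <- oth_m$ci_high; test_con[r] <- con_m$point
  }
  tab$test_other_acc <- test_oth
  tab$test_other_ci_low <- test_oth_lo
  tab$test_other_ci_high <- test_oth_hi
  tab$test_constrained_acc <- test_con
  ord <- order(-tab$test_other_acc)
  tab <- tab[ord, , drop = FALSE]
  rownames(tab) <- NULL
  list(table = tab, records = records[ord], status = "ok",
       constrained_group = constrained_group, min_acc = min_acc)
}

#' Full evaluation of one SNP subset
#'
#' Fits the classifier once on the full training cohort, predicts the test
#' cohort, and reports HMSS, total and group accuracies on both the pooled
#' out-of-fold CV predictions (classifier frozen per fold) and the test
#' cohort, each with a stratified bootstrap mean and 95% percentile CI.
#'
#' @inheritParams forward_selection
#' @param subset SNP ids (non-empty).
#' @param cache optional CV memo environment (internal reuse).
#' @param search_tag label recorded on the result.
#' @return A `subset_record`: list with `snp_ids`, `classifier_tag`,
#'   `search_tag`, and `cv` / `test` lists of [bootstrap_ci()] results
#'   (`hmss`, `total_acc`, `case_acc`, `control_acc`).
#' @export
evaluate_on_test <- function(spec, subset, G_train, y_train, G_test, y_test,
                             folds = NULL, master_seed = 1L, n_boot = 200L,
                             use_folds = if (is.null(folds)) NULL else seq_len(folds$k),
                             cache = NULL, search_tag = "manual") {
  if (!length(subset)) stop("subset must be non-empty")
  key <- subset_key(subset)
  metric_block <- function(yt, yp, tag) {
    list(hmss = bootstrap_ci(yt, yp, stat_hmss, n_boot,
                             seed = derive_seed(master_seed, paste0(tag, ":hmss:", key))),
         total_acc = bootstrap_ci(yt, yp, stat_total_accuracy, n_boot,
                                  seed = derive_seed(master_seed, paste0(tag, ":tot:", key))),
         case_acc = bootstrap_ci(yt, yp, stat_case_accuracy, n_boot,
                                 seed = derive_seed(master_seed, paste0(tag, ":case:", key))),
         control_acc = bootstrap_ci(yt, yp, stat_control_accuracy, n_boot,
                                    seed = derive_seed(master_seed, paste0(tag, ":ctrl:", key))))
  }
  cv <- NULL
  if (!is.null(folds)) {
    ev <- cv_eval(spec, G_train, y_train, subset, folds, master_seed,
                  use_folds, cache)
    cv <- metric_block(ev$y_true, ev$y_pred, "cvboot")
  }
  fit <- fit_classifier(spec, G_train, y_train, subset,
                        seed = derive_seed(master_seed, paste0("final:", key)))
  y_hat <- predict_classifier(fit, G_test)
  test <- metric_block(as.integer(y_test), y_hat, "testboot")
  structure(list(snp_ids = as.character(subset),
                 classifier_tag = spec$method,
                 search_tag = search_tag,
                 cv = cv, test = test,
                 model = fit$model),
            class = "subset_record")
}

# assemble a search trace: per-size best subsets -> full records + table
build_trace <- function(spec, sizes, G_train, y_train, G_test, y_test,
                        folds, master_seed, n_boot, use_folds, cache,
                        search_tag, sizes_are = seq_along(sizes)) {
  records <- vector("list", length(sizes))
  rows <- vector("list", length(sizes))
  for (i in seq_along(sizes)) {
    rec <- evaluate_on_test(spec, sizes[[i]]$subset, G_train, y_train,
                            G_test, y_test, folds = folds,
                            master_seed = master_seed, n_boot = n_boot,
                            use_folds = use_folds, cache = cache,
                            search_tag = search_tag)
    records[[i]] <- rec
    rows[[i]] <- data.frame(
      size = sizes_are[i],
      snp_ids = paste(sizes[[i]]$subset, collapse = ";"),
      cv_hmss = sizes[[i]]$cv_hmss,
      cv_hmss_boot = rec$cv$hmss$boot_mean,
      cv_hmss_ci_low = rec$cv$hmss$ci_low,
      cv_hmss_ci_high = rec$cv$hmss$ci_high,
      test_hmss = rec$test$hmss$point,
      test_hmss_boot = rec$test$hmss$boot_mean,
      test_hmss_ci_low = rec$test$hmss$ci_low,
      test_hmss_ci_high = rec$test$hmss$ci_high,
      cv_total_acc = rec$cv$total_acc$point,
      test_total_acc = rec$test$total_acc$point,
      stringsAsFactors = FALSE)
  }
  structure(list(table = do.call(rbind, rows), records = records,
                 classifier_tag = spec$method, search_tag = search_tag),
            class = "search_trace")
}

#' @export
print.search_trace <- function(x, ...) {
  cat(sprintf("search_trace (%s, %s): sizes %s\n", x$classifier_tag,
              x$search_tag, paste(range(x$table$size), collapse = "..")))
  print(x$table[, c("size", "snp_ids", "cv_hmss", "test_hmss")], ...)
  invisible(x)
}
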