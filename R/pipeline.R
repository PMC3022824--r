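#' Configuration of a full two-stage analysis run
#'
#' Bundles the fixed design settings of the analysis — top-1000 single-SNP
#' filter, five-fold stratified cross-validation, 200 bootstrap iterations,
#' alpha 0.05 — with the classifier and search choices. Every stochastic
#' stage derives its seed from `master_seed` plus a stable operation tag, so
#' a run is exactly reproducible from its config alone.
#'
#' @param classifier a [classifier_spec()] (default sIB with K = 2,
#'   beta = 10).
#' @param filter_top_k SNPs kept by the first-stage filter (default 1000).
#' @param k_folds cross-validation folds (default 5).
#' @param k_rotations how many folds to rotate through as evaluation fold
#'   (default `k_folds`; 1 reproduces a single 4+1 split).
#' @param searches character subset of
#'   `c("fs", "sffs", "exhaustive", "constrained")`.
#' @param fs_max_size,sffs_max_size wrapper search depth (defaults 40, 35).
#' @param exhaustive_sizes sizes for the exhaustive search (default 1:2).
#' @param constrained_min_acc,constrained_top_n constrained-search settings
#'   (defaults 0.4, 20).
#' @param n_boot bootstrap iterations (default 200).
#' @param alpha family-wise significance level (default 0.05).
#' @param chisq_top how many top-ranked SNPs get chi-square reporting
#'   (default 20).
#' @param master_seed integer root seed.
#' @return A list of class `run_config`.
#' @export
run_config <- function(classifier = classifier_spec("sib"),
                       filter_top_k = 1000L, k_folds = 5L,
                       k_rotations = k_folds,
                       searches = c("fs", "sffs", "exhaustive", "constrained"),
                       fs_max_size = 40L, sffs_max_size = 35L,
                       exhaustive_sizes = c(1L, 2L),
                       constrained_min_acc = 0.4, constrained_top_n = 20L,
                       n_boot = 200L, alpha = 0.05, chisq_top = 20L,
                       master_seed = 1L) {
  searches <- match.arg(searches, several.ok = TRUE)
  stopifnot(k_rotations >= 1L, k_rotations <= k_folds)
  structure(list(classifier = classifier,
                 filter_top_k = as.integer(filter_top_k),
                 k_folds = as.integer(k_folds),
                 k_rotations = as.integer(k_rotations),
                 searches = searches,
                 fs_max_size = as.integer(fs_max_size),
                 sffs_max_size = as.integer(sffs_max_size),
                 exhaustive_sizes = as.integer(exhaustive_sizes),
                 constrained_min_acc = constrained_min_acc,
                 constrained_top_n = as.integer(constrained_top_n),
                 n_boot = as.integer(n_boot), alpha = alpha,
                 chisq_top = as.integer(chisq_top),
                 master_seed = as.integer(master_seed)),
            class = "run_config")
}

#' Run the full two-stage SNP selection analysis
#'
#' Encode-and-impute is assumed done (pass complete matrices); the stages
#' are: single-SNP LDA-HMSS filter, the requested wrapper searches around
#' the configured classifier, full test-cohort evaluation of each recorded
#' subset, and a chi-square association table for the top SNPs by training
#' HMSS with the Bonferroni threshold at the genotyped SNP count.
#'
#' @param G_train,y_train,G_test,y_test complete cohorts (see
#'   [impute_missing()]).
#' @param config a [run_config()].
#' @return A list of class `run_result`: `ranked` (filter table), `folds`,
#'   one entry per requested search (`fs`, `sffs`, `exhaustive`,
#'   `constrained_cases`, `constrained_controls`), `chisq` (association
#'   table with significance flags), and the echoed `config`.
#' @export
run_two_stage <- function(G_train, y_train, G_test, y_test, config = run_config()) {
  stopifnot(inherits(config, "run_config"))
  if (anyNA(G_train$codes) || anyNA(G_test$codes))
    stop("stage 'input': matrices must be imputed before analysis")
  ms <- config$master_seed
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)), call. = FALSE))
  }
  ranked <- stage("filter_rank", filter_rank(G_train, y_train, config$filter_top_k))
  folds <- stage("folds", make_folds(y_train, config$k_folds,
                                     seed = derive_seed(ms, "folds")))
  use_folds <- seq_len(config$k_rotations)
  spec <- config$classifier
  out <- list(ranked = ranked, folds = folds, config = config)

  if ("fs" %in% config$searches)
    out$fs <- stage("forward_selection",
      forward_selection(spec, ranked, G_train, y_train, G_test, y_test,
                        folds, max_size = min(config$fs_max_size, nrow(ranked)),
                        master_seed = ms, n_boot = config$n_boot,
                        use_folds = use_folds))
  if ("sffs" %in% config$searches)
    out$sffs <- stage("sffs",
      sffs(spec, ranked, G_train, y_train, G_test, y_test, folds,
           max_size = min(config$sffs_max_size, nrow(ranked)),
           master_seed = ms, n_boot = config$n_boot, use_folds = use_folds))
  if ("exhaustive" %in% config$searches)
    out$exhaustive <- stage("exhaustive_search",
      exhaustive_search(spec, ranked, G_train, y_train, G_test, y_test,
                        folds, sizes = config$exhaustive_sizes,
                        master_seed = ms, n_boot = config$n_boot,
                        use_folds = use_folds))
  if ("constrained" %in% config$searches) {
    out$constrained_cases <- stage("constrained_search",
      constrained_search(spec, ranked, G_train, y_train, G_test, y_test,
                         folds, constrained_group = "cases",
                         min_acc = config$constrained_min_acc,
                         top_n = config$constrained_top_n,
                         sizes = config$exhaustive_sizes,
                         master_seed = ms, n_boot = config$n_boot,
                         use_folds = use_folds))
    out$constrained_controls <- stage("constrained_search",
      constrained_search(spec, ranked, G_train, y_train, G_test, y_test,
                         folds, constrained_group = "controls",
                         min_acc = config$constrained_min_acc,
                         top_n = config$constrained_top_n,
                         sizes = config$exhaustive_sizes,
                         master_seed = ms, n_boot = config$n_boot,
                         use_folds = use_folds))
  }

  out$chisq <- stage("chisq", {
    top <- ranked$snp_id[seq_len(min(config$chisq_top, nrow(ranked)))]
    scan <- chi_square_scan(subset_genotypes(G_train, snps = top), y_train)
    scan$train_hmss <- ranked$train_hmss[match(scan$snp_id, ranked$snp_id)]
    cutoff <- bonferroni_threshold(config$alpha, length(G_train$snp_ids))
    scan$bonferroni_cutoff <- cutoff
    scan$significant <- scan$p_value < cutoff
    scan[order(-scan$train_hmss), ]
  })
  class(out) <- "run_result"
  out
}

#' Write the report tables of a run
#'
#' Emits plain TSV artifacts: `ranked_snps.tsv`, `trace_fs.tsv`,
#' `trace_sffs.tsv`, `optimal_subsets.tsv`, `constrained.tsv`,
#' `chisq_top.tsv`, plus `config_echo.txt` (enough to reproduce the run).
#'
#' @param result a [run_two_stage()] result.
#' @param dir output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_run_reports <- function(result, dir) {
  stopifnot(inherits(result, "run_result"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character(0)
  wt <- function(tab, name) {
    p <- file.path(dir, name)
    utils::write.table(tab, p, sep = "\t", quote = FALSE, row.names = FALSE)
    paths <<- c(paths, p)
  }
  wt(result$ranked, "ranked_snps.tsv")
  if (!is.null(result$fs)) wt(result$fs$table, "trace_fs.tsv")
  if (!is.null(result$sffs)) wt(result$sffs$table, "trace_sffs.tsv")
  if (!is.null(result$exhaustive)) {
    recs <- result$exhaustive$records
    wt(do.call(rbind, lapply(recs, record_row)), "optimal_subsets.tsv")
  }
  cons <- list(cases = result$constrained_cases,
               controls = result$constrained_controls)
  cons <- cons[!vapply(cons, is.null, TRUE)]
  if (length(cons)) {
    tabs <- lapply(names(cons), function(g) {
      tab <- cons[[g]]$table
      if (nrow(tab)) cbind(constrained_group = g, tab)
      else data.frame(constrained_group = g, status = "empty")
    })
    all_cols <- unique(unlist(lapply(tabs, names)))
    tabs <- lapply(tabs, function(t) { t[setdiff(all_cols, names(t))] <- NA; t[all_cols] })
    wt(do.call(rbind, tabs), "constrained.tsv")
  }
  wt(result$chisq, "chisq_top.tsv")
  cfg <- result$config
  echo <- c(sprintf("classifier=%s", cfg$classifier$method),
            sprintf("K=%d beta=%g n_restarts=%d max_sweeps=%d",
                    cfg$classifier$K, cfg$classifier$beta,
                    cfg$classifier$n_restarts, cfg$classifier$max_sweeps),
            sprintf("filter_top_k=%d", cfg$filter_top_k),
            sprintf("k_folds=%d k_rotations=%d", cfg$k_folds, cfg$k_rotations),
            sprintf("searches=%s", paste(cfg$searches, collapse = ",")),
            sprintf("n_boot=%d alpha=%g", cfg$n_boot, cfg$alpha),
            sprintf("master_seed=%d", cfg$master_seed))
  writeLines(echo, file.path(dir, "config_echo.txt"))
  invisible(c(paths, file.path(dir, "config_echo.txt")))
}

# flatten a subset_record into one table row
record_row <- function(rec) {
  fmt <- function(m) if (is.null(m)) rep(NA_real_, 4) else
    c(m$point, m$boot_mean, m$ci_low, m$ci_high)
  cvh <- fmt(rec$cv$hmss); cvt <- fmt(rec$cv$total_acc)
  teh <- fmt(rec$test$hmss); tet <- fmt(rec$test$total_acc)
  data.frame(search = rec$search_tag, classifier = rec$classifier_tag,
             size = length(rec$snp_ids),
             snp_ids = paste(rec$snp_ids, collapse = ";"),
             cv_hmss = cvh[1], cv_hmss_boot = cvh[2],
             cv_hmss_ci_low = cvh[3], cv_hmss_ci_high = cvh[4],
             cv_total_acc = cvt[1],
             test_hmss = teh[1], test_hmss_boot = teh[2],
             test_hmss_ci_low = teh[3], test_hmss_ci_high = teh[4],
             test_total_acc = tet[1], test_total_acc_boot = tet[2],
             test_total_acc_ci_low = tet[3], test_total_acc_ci_high = tet[4],
             stringsAsFactors = FALSE)
}

#' Human-readable summary of a run
#'
#' Prints the best subset per search with HMSS point estimates, bootstrap
#' means and 95% CIs, mirroring the layout of an optimal-subsets results
#' table.
#'
#' @param result a [run_two_stage()] result.
#' @return Invisibly, the summary lines.
#' @export
summarize_run <- function(result) {
  stopifnot(inherits(result, "run_result"))
  fmt_m <- function(m) sprintf("%.3f(%.3f, %.3f-%.3f)",
                               m$point, m$boot_mean, m$ci_low, m$ci_high)
  lines <- sprintf("Two-stage analysis: classifier=%s, %d candidate SNPs",
                   result$config$classifier$method, nrow(result$ranked))
  best_of_trace <- function(tr) tr$records[[which.max(tr$table$test_hmss)]]
  show_rec <- function(rec, label)
    sprintf("%-14s %-28s CV HMSS %s | test HMSS %s", label,
            paste(rec$snp_ids, collapse = ";"),
            if (is.null(rec$cv)) "-" else fmt_m(rec$cv$hmss),
            fmt_m(rec$test$hmss))
  if (!is.null(result$fs))
    lines <- c(lines, show_rec(best_of_trace(result$fs), "FS"))
  if (!is.null(result$sffs))
    lines <- c(lines, show_rec(best_of_trace(result$sffs), "SFFS"))
  if (!is.null(result$exhaustive))
    for (rec in result$exhaustive$records)
      lines <- c(lines, show_rec(rec, rec$search_tag))
  for (g in c("cases", "controls")) {
    cs <- result[[paste0("constrained_", g)]]
    if (is.null(cs)) next
    if (cs$status == "empty") {
      lines <- c(lines, sprintf("constrained(%s>=%.2f): no subset satisfies the constraint",
                                g, cs$min_acc))
    } else {
      other <- if (g == "cases") "controls" else "cases"
      lines <- c(lines, sprintf(
        "constrained(%s>=%.2f): best test accuracy among %s %.3f (%s)",
        g, cs$min_acc, other, cs$table$test_other_acc[1], cs$table$snp_ids[1]))
    }
  }
  n_sig <- sum(result$chisq$significant)
  lines <- c(lines, sprintf(
    "chi-square: %d of %d top SNPs below the Bonferroni cutoff %.3g",
    n_sig, nrow(result$chisq), result$chisq$bonferroni_cutoff[1]))
  cat(lines, sep = "\n")
  invisible(lines)
}
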