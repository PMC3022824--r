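test_that("folds are stratified, exhaustive and seed-stable", {
  y <- rep(c(1L, 0L), each = 10)
  f <- make_folds(y, k = 5, seed = 3)
  expect_identical(sort(unique(f$fold)), 1:5)
  for (k in 1:5) {
    expect_identical(sum(f$fold == k & y == 1L), 2L)
    expect_identical(sum(f$fold == k & y == 0L), 2L)
  }
  expect_identical(f, make_folds(y, k = 5, seed = 3))
  expect_false(identical(f$fold, make_folds(y, k = 5, seed = 4)$fold))
  expect_error(make_folds(c(1L, 1L, 0L, 0L), k = 3), "at least k")
})

test_that("pooled out-of-fold HMSS matches a hand-rolled 2-fold computation", {
  # 8 samples, 1 perfectly separating SNP and 1 noise SNP
  codes <- cbind(c(0L, 0L, 0L, 0L, 2L, 2L, 2L, 2L),
                 c(1L, 0L, 1L, 0L, 1L, 0L, 1L, 0L))
  G <- toy_genotypes(codes)
  y <- c(1L, 1L, 1L, 1L, 0L, 0L, 0L, 0L)
  folds <- make_folds(y, k = 2, seed = 1)
  spec <- classifier_spec("lda")
  got <- cv_hmss(spec, G, y, "rs001", folds, master_seed = 5)
  # hand computation: fit LDA on each half, predict the other half, pool
  preds <- integer(8)
  for (f in 1:2) {
    hold <- folds$fold == f
    fit <- lda_fit(codes[!hold, 1, drop = FALSE], y[!hold])
    preds[hold] <- lda_predict(fit, codes[hold, 1, drop = FALSE])
  }
  expect_equal(got$hmss, hmss(confusion(y, preds)))
  expect_equal(got$hmss, 1)          # separating SNP classifies perfectly
  # a label-independent constant SNP predicts one class -> HMSS 0
  Gc <- toy_genotypes(matrix(1L, 8, 1))
  expect_equal(cv_hmss(spec, Gc, y, "rs001", folds)$hmss, 0)
})

test_that("filter ranking equals exhaustive single-SNP training evaluation", {
  sim <- quick_sim(n_snps = 12, n_train = c(30, 30), seed = 2)
  G <- sim$train$G; y <- sim$train$labels
  fr <- filter_rank(G, y, top_k = 12)
  # oracle: evaluate every SNP by resubstitution HMSS directly
  direct <- vapply(seq_len(12), function(j) {
    fit <- lda_fit(G$codes[, j, drop = FALSE], y)
    hmss(confusion(y, lda_predict(fit, G$codes[, j, drop = FALSE])))
  }, numeric(1))
  expect_equal(fr$train_hmss, sort(direct, decreasing = TRUE))
  expect_setequal(fr$snp_id, G$snp_ids)
  # top_k larger than m returns everything, smaller truncates
  expect_identical(nrow(filter_rank(G, y, top_k = 100)), 12L)
  expect_identical(nrow(filter_rank(G, y, top_k = 3)), 3L)

  # a monomorphic SNP scores HMSS 0 and ranks last among non-ties
  codes <- cbind(G$codes[, 1:3], mono = 2L)
  G2 <- toy_genotypes(codes, c(G$snp_ids[1:3], "rs_mono"))
  fr2 <- filter_rank(G2, y, top_k = 4)
  expect_equal(fr2$train_hmss[fr2$snp_id == "rs_mono"], 0)
})

test_that("the planted causal SNP wins the filter in most seeds", {
  wins <- vapply(1:10, function(s) {
    cfg <- sim_config(n_cases_train = 800, n_controls_train = 800,
                      n_cases_test = 5, n_controls_test = 5,
                      n_snps = 201, causal_indices = 101L,
                      causal_log_odds = 1.5, causal_maf = 0.3,
                      missing_rate = 0, seed = s)
    sim <- simulate_cohorts(cfg)
    fr <- filter_rank(sim$train$G, sim$train$labels, top_k = 201)
    fr$snp_id[1] == sim$truth$causal_snp_ids
  }, logical(1))
  expect_gte(sum(wins), 9L)
})

test_that("forward selection nests subsets and starts at the size-1 optimum", {
  sim <- quick_sim(n_snps = 12, n_train = c(40, 40), n_test = c(30, 30), seed = 5)
  spec <- classifier_spec("lda")
  folds <- make_folds(sim$train$labels, k = 5, seed = 2)
  cand <- filter_rank(sim$train$G, sim$train$labels, top_k = 8)
  tr <- forward_selection(spec, cand, sim$train$G, sim$train$labels,
                          sim$test$G, sim$test$labels, folds,
                          max_size = 4, master_seed = 7, n_boot = 50)
  subs <- strsplit(tr$table$snp_ids, ";", fixed = TRUE)
  for (k in 2:4) expect_true(all(subs[[k - 1]] %in% subs[[k]]))
  # step 1 equals the exhaustive size-1 CV argmax
  ex <- exhaustive_search(spec, cand, sim$train$G, sim$train$labels,
                          sim$test$G, sim$test$labels, folds, sizes = 1L,
                          master_seed = 7, n_boot = 50)
  expect_equal(tr$table$cv_hmss[1], max(ex$table$cv_hmss))
  expect_identical(subs[[1]], strsplit(ex$table$snp_ids[1], ";")[[1]])
  expect_error(forward_selection(spec, cand, sim$train$G, sim$train$labels,
                                 sim$test$G, sim$test$labels, folds,
                                 max_size = 99), "max_size")
})

test_that("forward selection finds both strong causal SNPs early", {
  hits <- vapply(1:10, function(s) {
    cfg <- sim_config(n_cases_train = 300, n_controls_train = 300,
                      n_cases_test = 50, n_controls_test = 50,
                      n_snps = 50, causal_indices = c(1L, 2L),
                      causal_log_odds = c(1.5, 1.5), causal_maf = 0.3,
                      missing_rate = 0, seed = s)
    sim <- simulate_cohorts(cfg)
    folds <- make_folds(sim$train$labels, 5, seed = s)
    cand <- filter_rank(sim$train$G, sim$train$labels, top_k = 50)
    tr <- forward_selection(classifier_spec("lda"), cand,
                            sim$train$G, sim$train$labels,
                            sim$test$G, sim$test$labels, folds,
                            max_size = 4, master_seed = s, n_boot = 10)
    sel <- strsplit(tr$table$snp_ids[4], ";")[[1]]
    all(sim$truth$causal_snp_ids %in% sel)
  }, logical(1))
  expect_gte(sum(hits), 8L)
})

test_that("SFFS starts from the exhaustive pair optimum and beats it per size", {
  sim <- quick_sim(n_snps = 10, n_train = c(40, 40), n_test = c(30, 30), seed = 8)
  spec <- classifier_spec("lda")
  folds <- make_folds(sim$train$labels, k = 5, seed = 1)
  cand <- filter_rank(sim$train$G, sim$train$labels, top_k = 6)
  tr <- sffs(spec, cand, sim$train$G, sim$train$labels,
             sim$test$G, sim$test$labels, folds, max_size = 3,
             master_seed = 3, n_boot = 20)
  ex <- exhaustive_search(spec, cand, sim$train$G, sim$train$labels,
                          sim$test$G, sim$test$labels, folds, sizes = 2L,
                          master_seed = 3, n_boot = 20)
  expect_equal(tr$table$cv_hmss[tr$table$size == 2], max(ex$table$cv_hmss))
  # best-per-size CV HMSS is bounded by the brute-force optimum per size
  brute3 <- max(vapply(utils::combn(cand$snp_id, 3, simplify = FALSE),
                       function(sub) cv_eval(spec, sim$train$G,
                                             sim$train$labels, sub, folds,
                                             master_seed = 3)$hmss,
                       numeric(1)))
  expect_lte(tr$table$cv_hmss[tr$table$size == 3], brute3 + 1e-12)
  expect_error(sffs(spec, cand, sim$train$G, sim$train$labels,
                    sim$test$G, sim$test$labels, folds, max_size = 1),
               "max_size")
})

test_that("exhaustive search enumerates C(n,k) subsets order-invariantly", {
  sim <- quick_sim(n_snps = 8, n_train = c(30, 30), n_test = c(20, 20), seed = 9)
  spec <- classifier_spec("lda")
  folds <- make_folds(sim$train$labels, k = 5, seed = 4)
  cand <- filter_rank(sim$train$G, sim$train$labels, top_k = 3)
  ex <- exhaustive_search(spec, cand, sim$train$G, sim$train$labels,
                          sim$test$G, sim$test$labels, folds, sizes = 2L,
                          master_seed = 2, n_boot = 20)
  expect_identical(nrow(ex$table), 3L)           # C(3,2)
  # shuffling candidate input order leaves the ranking identical
  ex2 <- exhaustive_search(spec, cand[c(3, 1, 2), ], sim$train$G,
                           sim$train$labels, sim$test$G, sim$test$labels,
                           folds, sizes = 2L, master_seed = 2, n_boot = 20)
  expect_identical(ex$table, ex2$table)
  expect_error(exhaustive_search(spec, cand, sim$train$G, sim$train$labels,
                                 sim$test$G, sim$test$labels, folds,
                                 sizes = 3L), "allow_large")
})

test_that("the constrained search honours its accuracy floor", {
  sim <- quick_sim(n_snps = 15, n_train = c(50, 50), n_test = c(40, 40),
                   seed = 10)
  spec <- classifier_spec("lda")
  folds <- make_folds(sim$train$labels, k = 5, seed = 6)
  cand <- filter_rank(sim$train$G, sim$train$labels, top_k = 5)
  cs <- constrained_search(spec, cand, sim$train$G, sim$train$labels,
                           sim$test$G, sim$test$labels, folds,
                           constrained_group = "cases", min_acc = 0.4,
                           top_n = 5, sizes = c(1L, 2L), master_seed = 4,
                           n_boot = 20)
  if (cs$status == "ok") {
    expect_true(all(cs$table$cv_case_acc >= 0.4))
    expect_identical(order(-cs$table$test_other_acc), seq_len(nrow(cs$table)))
  }
  # vacuous constraint reduces to unconstrained maximization over the
  # other group's CV accuracy
  cs0 <- constrained_search(spec, cand, sim$train$G, sim$train$labels,
                            sim$test$G, sim$test$labels, folds,
                            constrained_group = "cases", min_acc = 0,
                            top_n = 50, sizes = 1L, master_seed = 4,
                            n_boot = 20)
  ex <- exhaustive_search(spec, cand, sim$train$G, sim$train$labels,
                          sim$test$G, sim$test$labels, folds, sizes = 1L,
                          master_seed = 4, n_boot = 20)
  expect_equal(max(cs0$table$cv_control_acc), max(ex$table$cv_control_acc))
  # an impossible floor reports an empty result
  cs_none <- constrained_search(spec, cand, sim$train$G, sim$train$labels,
                                sim$test$G, sim$test$labels, folds,
                                constrained_group = "cases", min_acc = 1.01,
                                sizes = 1L, master_seed = 4, n_boot = 20)
  expect_identical(cs_none$status, "empty")
})

test_that("test evaluation equals resubstitution when test is the training set", {
  sim <- quick_sim(n_snps = 8, n_train = c(30, 30), seed = 11)
  spec <- classifier_spec("lda")
  rec <- evaluate_on_test(spec, sim$train$G$snp_ids[1:2],
                          sim$train$G, sim$train$labels,
                          sim$train$G, sim$train$labels,
                          master_seed = 9, n_boot = 30)
  fit <- fit_classifier(spec, sim$train$G, sim$train$labels,
                        sim$train$G$snp_ids[1:2])
  resub <- hmss(confusion(sim$train$labels,
                          predict_classifier(fit, sim$train$G)))
  expect_equal(rec$test$hmss$point, resub)
  # fixed seeds give bit-identical records
  rec2 <- evaluate_on_test(spec, sim$train$G$snp_ids[1:2],
                           sim$train$G, sim$train$labels,
                           sim$train$G, sim$train$labels,
                           master_seed = 9, n_boot = 30)
  expect_identical(rec[names(rec) != "model"], rec2[names(rec2) != "model"])
})

test_that("a clearly separable subset reaches high test HMSS", {
  cfg <- sim_config(n_cases_train = 400, n_controls_train = 400,
                    n_cases_test = 200, n_controls_test = 200,
                    n_snps = 10, causal_indices = c(1L, 2L),
                    causal_log_odds = c(3, 3), causal_maf = 0.35,
                    missing_rate = 0, seed = 12)
  sim <- simulate_cohorts(cfg)
  rec <- evaluate_on_test(classifier_spec("lda"), c("rs000001", "rs000002"),
                          sim$train$G, sim$train$labels,
                          sim$test$G, sim$test$labels,
                          master_seed = 1, n_boot = 30)
  expect_gt(rec$test$hmss$point, 0.75)
})

test_that("LDA forward selection stays at chance under permuted labels", {
  vals <- vapply(1:20, function(s) {
    cfg <- sim_config(n_snps = 50, seed = s)
    sim <- simulate_cohorts(cfg)
    tr <- impute_missing(sim$train$G)
    te <- impute_missing(sim$test$G, reference = sim$train$G)
    set.seed(s + 2000)
    y_tr <- sample(sim$train$labels); y_te <- sample(sim$test$labels)
    cand <- filter_rank(tr, y_tr, top_k = 15)
    folds <- make_folds(y_tr, 5, seed = s)
    fs <- forward_selection(classifier_spec("lda"), cand, tr, y_tr, te, y_te,
                            folds, max_size = 3, master_seed = s, n_boot = 10)
    fs$table$test_hmss[which.max(fs$table$cv_hmss)]
  }, numeric(1))
  expect_gte(mean(vals), 0.40)
  expect_lte(mean(vals), 0.60)
})

test_that("selection decisions are blind to the test cohort", {
  sim <- quick_sim(n_snps = 12, n_train = c(40, 40), n_test = c(30, 30),
                   seed = 13)
  spec <- classifier_spec("sib", n_restarts = 4)
  folds <- make_folds(sim$train$labels, k = 5, seed = 2)
  cand <- filter_rank(sim$train$G, sim$train$labels, top_k = 5)
  y_test_perm <- sample(sim$test$labels)
  run_all <- function(y_test) {
    fs <- forward_selection(spec, cand, sim$train$G, sim$train$labels,
                            sim$test$G, y_test, folds, max_size = 3,
                            master_seed = 5, n_boot = 10)
    sf <- sffs(spec, cand, sim$train$G, sim$train$labels, sim$test$G,
               y_test, folds, max_size = 3, master_seed = 5, n_boot = 10)
    ex <- exhaustive_search(spec, cand, sim$train$G, sim$train$labels,
                            sim$test$G, y_test, folds, sizes = c(1L, 2L),
                            master_seed = 5, n_boot = 10)
    list(fs = fs$table$snp_ids, sffs = sf$table$snp_ids,
         ex = ex$table$snp_ids, ex_cv = ex$table$cv_hmss)
  }
  a <- run_all(sim$test$labels)
  b <- run_all(y_test_perm)
  expect_identical(a, b)
})
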