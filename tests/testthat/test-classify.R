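test_that("entropy, mutual information and JS divergence match hand values", {
  expect_equal(entropy(c(0.5, 0.5)), 1)
  expect_equal(entropy(c(1, 0)), 0)
  # independent uniform 2x2
  expect_equal(mutual_information(matrix(0.25, 2, 2)), 0)
  # perfect dependence
  expect_equal(mutual_information(diag(2) * 0.5), 1)
  # direct summation of p * log2(p / (px py)) for [[0.4,0.1],[0.1,0.4]]
  expect_equal(mutual_information(matrix(c(0.4, 0.1, 0.1, 0.4), 2, 2)),
               0.27807, tolerance = 1e-5)
  expect_error(mutual_information(matrix(c(0.9, 0.2, -0.1, 0), 2, 2)),
               "negative")
  # JS of identical distributions is 0; of disjoint ones it is H(weights)
  expect_equal(js_divergence(c(0.3, 0.7), c(0.3, 0.7)), 0)
  expect_equal(js_divergence(c(1, 0), c(0, 1), c(0.25, 0.75)),
               entropy(c(0.25, 0.75)), tolerance = 1e-12)
})

test_that("sample profiles put mass 1/s on each subset SNP's token", {
  G <- toy_genotypes(matrix(c(2L, 0L, 1L, 1L), 2, 2))
  p1 <- build_sample_profiles(G, 1L)
  M1 <- profile_masses(p1)
  expect_equal(unname(M1[1, ]), c(0, 0, 1))        # code 2 -> third token
  p2 <- build_sample_profiles(G, c(1L, 2L))
  M2 <- profile_masses(p2)
  expect_equal(rowSums(M2), c(1, 1))
  expect_equal(sum(M2[1, ] == 0.5), 2L)            # mass split across 2 tokens
  # identical codes give identical profiles
  G2 <- toy_genotypes(matrix(c(1L, 1L, 0L, 0L), 2, 2))
  M <- profile_masses(build_sample_profiles(G2, 1:2))
  expect_equal(M[1, ], M[2, ])
  expect_error(build_sample_profiles(G, integer(0)), "non-empty")
  Gna <- toy_genotypes(matrix(c(1L, NA), 2, 1))
  expect_error(build_sample_profiles(Gna, 1L), "impute")
})

test_that("the bottleneck objective matches direct evaluation on toys", {
  # all profiles identical: I(C;Y) = 0 so L = H(C)
  G <- toy_genotypes(matrix(1L, 4, 1))
  prof <- build_sample_profiles(G, 1L)
  expect_equal(ib_objective(c(1, 1, 2, 2), prof, beta = 5), 1)
  expect_equal(ib_objective(c(1, 1, 1, 2), prof, beta = 5),
               entropy(c(0.75, 0.25)))
  # K = 1: both terms vanish
  expect_equal(ib_objective(rep(1, 4), prof, beta = 7), 0)
  # 2 + 2 samples on distinct tokens, partition = token groups, beta = 1:
  # I(C;Y) = 1 bit and H(C) = 1 bit so L = 0
  G2 <- toy_genotypes(matrix(c(0L, 0L, 2L, 2L), 4, 1))
  prof2 <- build_sample_profiles(G2, 1L)
  expect_equal(ib_objective(c(1, 1, 2, 2), prof2, beta = 1), 0,
               tolerance = 1e-12)
})

test_that("sIB separates a pure two-genotype toy and is reproducible", {
  # cases all code 0, controls all code 2: the genotype partition uniquely
  # minimizes L (brute-force enumeration over all 2-block partitions)
  G <- toy_genotypes(matrix(c(0L, 0L, 2L, 2L), 4, 1))
  prof <- build_sample_profiles(G, 1L)
  y <- c(1L, 1L, 0L, 0L)
  fit <- sib_fit(prof, y, K = 2, beta = 10, n_restarts = 8, seed = 2)
  expect_equal(fit$objective, ib_bruteforce_min(prof, 10), tolerance = 1e-9)
  expect_identical(fit$assignment[1], fit$assignment[2])
  expect_identical(fit$assignment[3], fit$assignment[4])
  expect_false(fit$assignment[1] == fit$assignment[3])
  # labels are pure and training predictions perfect
  expect_identical(sib_predict(fit, prof), y)
  # the reported objective equals the from-scratch recomputation
  expect_equal(fit$objective, ib_objective(fit$assignment, prof, 10),
               tolerance = 1e-9)
  # bit-reproducible under a fixed seed
  fit2 <- sib_fit(prof, y, K = 2, beta = 10, n_restarts = 8, seed = 2)
  expect_identical(fit[names(fit) != "trace"], fit2[names(fit2) != "trace"])
})

test_that("sIB on identical samples predicts the majority label", {
  G <- toy_genotypes(matrix(1L, 6, 1))
  prof <- build_sample_profiles(G, 1L)
  y <- c(1L, 0L, 0L, 0L, 1L, 0L)
  fit <- sib_fit(prof, y, K = 2, beta = 10, n_restarts = 4, seed = 1)
  expect_true(all(sib_predict(fit, prof) == 0L))
  expect_error(sib_fit(prof, rep(1L, 6)), "both classes")
  expect_error(sib_fit(prof, y, K = 7), "K must not exceed")
})

test_that("sIB reaches the enumerated global optimum on seeded toys", {
  hits <- 0L; total <- 30L
  set.seed(2024)
  for (i in seq_len(total)) {
    n <- sample(5:9, 1)
    s <- sample(1:3, 1)
    codes <- matrix(sample(0:2, n * s, replace = TRUE), n, s)
    prof <- build_sample_profiles(toy_genotypes(codes), seq_len(s))
    y <- c(1L, 0L, sample(0:1, n - 2, replace = TRUE))
    fit <- sib_fit(prof, y, K = 2, beta = 10, n_restarts = 8, seed = i)
    if (abs(fit$objective - ib_bruteforce_min(prof, 10)) < 1e-9)
      hits <- hits + 1L
  }
  expect_gte(hits / total, 0.95)
})

test_that("the objective never increases along sequential reassignments", {
  set.seed(7)
  for (i in 1:5) {
    n <- 40
    codes <- matrix(sample(0:2, n * 2, replace = TRUE), n, 2)
    prof <- build_sample_profiles(toy_genotypes(codes), 1:2)
    y <- rep(c(1L, 0L), n / 2)
    fit <- sib_fit(prof, y, K = 3, beta = 10, n_restarts = 5, seed = i,
                   record_trace = TRUE)
    for (r in unique(fit$trace_restart)) {
      tr <- fit$trace[fit$trace_restart == r]
      expect_true(all(diff(tr) <= 1e-9))
    }
  }
})

test_that("mutual information respects its entropy bounds in fitted models", {
  sim <- quick_sim(n_snps = 6, n_train = c(25, 25), seed = 4)
  prof <- build_sample_profiles(sim$train$G, 1:3)
  fit <- sib_fit(prof, sim$train$labels, K = 2, beta = 10, seed = 1)
  M <- profile_masses(prof)
  joint <- matrix(0, fit$K, ncol(M))
  for (c in seq_len(fit$K))
    if (any(fit$assignment == c))
      joint[c, ] <- colSums(M[fit$assignment == c, , drop = FALSE]) / prof$n
  icy <- mutual_information(joint)
  expect_gte(icy, 0)
  expect_lte(icy, entropy(rowSums(joint)) + 1e-9)
  expect_lte(icy, entropy(colSums(joint)) + 1e-9)
})

test_that("unseen samples take the label of their nearest cluster", {
  G <- toy_genotypes(matrix(c(0L, 0L, 2L, 2L), 4, 1))
  prof <- build_sample_profiles(G, 1L)
  y <- c(1L, 1L, 0L, 0L)
  fit <- sib_fit(prof, y, K = 2, beta = 10, n_restarts = 8, seed = 2)
  # a new case-genotype sample lands in the case cluster at zero JS cost
  new_case <- build_sample_profiles(toy_genotypes(matrix(0L, 1, 1)), 1L)
  expect_identical(sib_predict(fit, new_case), 1L)
  new_ctrl <- build_sample_profiles(toy_genotypes(matrix(2L, 1, 1)), 1L)
  expect_identical(sib_predict(fit, new_ctrl), 0L)
  # heterozygote: equidistant in support, assigned deterministically
  het <- build_sample_profiles(toy_genotypes(matrix(1L, 1, 1)), 1L)
  expect_identical(sib_predict(fit, het), sib_predict(fit, het))
  # token space mismatch is refused
  wrong <- build_sample_profiles(toy_genotypes(matrix(0L, 1, 1), "rsX"), 1L)
  expect_error(sib_predict(fit, wrong), "token space")
})

test_that("LDA matches hand geometry and a reference implementation", {
  # symmetric 1-feature separation: midpoint rule, perfect training fit
  X <- matrix(c(0, 0, 2, 2), 4, 1)
  y <- c(0L, 0L, 1L, 1L)
  fit <- lda_fit(X, y)
  expect_identical(lda_predict(fit, X), y)
  expect_identical(lda_predict(fit, matrix(c(0.9, 1.1), 2, 1)), c(0L, 1L))

  # identical class means: all scores tie with the threshold -> all case
  Xd <- matrix(c(0, 2, 0, 2), 4, 1)
  fd <- lda_fit(Xd, c(1L, 1L, 0L, 0L))
  expect_identical(lda_predict(fd, Xd), rep(1L, 4))

  # oracle agreement with MASS's Fisher discriminant on random
  # well-conditioned 2-feature problems (equal priors)
  set.seed(5)
  for (i in 1:20) {
    n <- 30
    y2 <- rep(c(1L, 0L), each = n / 2)
    X2 <- cbind(stats::rnorm(n, y2 * 1.5), stats::rnorm(n, -y2))
    ours <- lda_predict(lda_fit(X2, y2), X2)
    ref <- MASS::lda(X2, grouping = factor(y2, levels = c(0, 1)),
                     prior = c(0.5, 0.5))
    theirs <- as.integer(as.character(stats::predict(ref, X2)$class))
    expect_identical(ours, theirs)
  }
})

test_that("LDA decisions are invariant to affine rescaling of a feature", {
  set.seed(8)
  n <- 40
  y <- rep(c(1L, 0L), each = n / 2)
  X <- cbind(stats::rnorm(n, y), stats::rnorm(n, 0.5 * y))
  base <- lda_predict(lda_fit(X, y, ridge_eps = 0), X)
  Xs <- X; Xs[, 2] <- X[, 2] * 37 + 5
  expect_identical(lda_predict(lda_fit(Xs, y, ridge_eps = 0), Xs), base)
})

test_that("fitted models serialize to JSON and back", {
  sim <- quick_sim(n_snps = 5, n_train = c(20, 20), seed = 6)
  prof <- build_sample_profiles(sim$train$G, 1:2)
  fit <- sib_fit(prof, sim$train$labels, seed = 3)
  path <- tempfile(fileext = ".json")
  write_model(fit, path)
  back <- read_model(path)
  expect_s3_class(back, "sib_model")
  expect_equal(back$objective, fit$objective)
  expect_equal(unname(back$cluster_token_sums),
               unname(fit$cluster_token_sums))
  expect_identical(sib_predict(back, prof), sib_predict(fit, prof))

  lfit <- lda_fit(matrix(c(0, 0, 2, 2), 4, 1), c(0L, 0L, 1L, 1L))
  write_model(lfit, path)
  lback <- read_model(path)
  expect_equal(lback$weights, lfit$weights)
  expect_equal(lback$threshold, lfit$threshold)
})
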