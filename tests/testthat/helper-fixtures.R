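# shared fixtures: everything is generated in code at test time

# tiny deterministic genotype matrix from explicit codes
toy_genotypes <- function(codes, snp_ids = NULL) {
  codes <- as.matrix(codes)
  if (is.null(snp_ids)) snp_ids <- sprintf("rs%03d", seq_len(ncol(codes)))
  genotype_matrix(codes, sprintf("s%03d", seq_len(nrow(codes))), snp_ids)
}

# small simulated two-cohort study used across select/pipeline tests
quick_sim <- function(n_snps = 30, n_train = c(60, 60), n_test = c(40, 40),
                      causal = c(1L, 2L), log_odds = rep(1.1, length(causal)),
                      missing_rate = 0, seed = 1) {
  cfg <- sim_config(n_cases_train = n_train[1], n_controls_train = n_train[2],
                    n_cases_test = n_test[1], n_controls_test = n_test[2],
                    n_snps = n_snps, causal_indices = causal,
                    causal_log_odds = log_odds,
                    missing_rate = missing_rate, seed = seed)
  sim <- simulate_cohorts(cfg)
  sim$train$G <- impute_missing(sim$train$G)
  sim$test$G <- impute_missing(sim$test$G, reference = sim$train$G)
  sim
}

# brute-force information-bottleneck oracle: global minimum of L over all
# partitions of n samples into at most 2 non-empty blocks (sample 1 pinned
# to block 1 to kill the labelling symmetry)
ib_bruteforce_min <- function(profiles, beta) {
  n <- profiles$n
  best <- Inf
  for (mask in 0:(2^(n - 1) - 1)) {
    part <- c(1L, as.integer(bitwAnd(mask %/% 2^(0:(n - 2)), 1)) + 1L)
    if (n == 1L) part <- 1L
    best <- min(best, ib_objective(part, profiles, beta))
  }
  best
}

# brute-force Pearson chi-square over a 2 x r table
chisq_bruteforce <- function(tab) {
  tab <- tab[, colSums(tab) > 0, drop = FALSE]
  if (ncol(tab) <= 1) return(list(statistic = 0, df = 0, p_value = 1))
  E <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  stat <- sum((tab - E)^2 / E)
  df <- ncol(tab) - 1
  list(statistic = stat, df = df,
       p_value = stats::pchisq(stat, df, lower.tail = FALSE))
}
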