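test_that("the gamma rule partitions proportion differences with an excluded band", {
  expect_identical(partition_by_gamma(c(0.001, -0.3, 0.25, 0.05), 0.2),
                   c(0L, 1L, 2L, NA_integer_))
  expect_identical(partition_by_gamma(0, 0.1), 0L)
  # boundary is strict: d exactly at gamma stays excluded
  expect_identical(partition_by_gamma(c(0.2, -0.2), 0.2),
                   c(NA_integer_, NA_integer_))
  expect_error(partition_by_gamma(0.1, 0.005), "gamma")
  expect_error(partition_by_gamma(0.1, 0.001), "gamma")
})

test_that("gamma presets reproduce the calibrated group proportions", {
  f1 <- gamma_group_fractions(0.01)
  expect_equal(unname(f1), c(1 - 0.4328 - 0.2944, 0.4328, 0.2944))
  f2 <- gamma_group_fractions(0.2)
  expect_equal(unname(f2), c(0.895, 0.059, 0.046))
  expect_error(gamma_group_fractions(0.07), "preset")
})

test_that("true proportions honour group structure and pool means", {
  des <- simulation_design(n_loci = 10000, gamma = 0.2,
                           group_fractions = c(0.2, 0.4, 0.4),
                           proportion_pools = parametric_pools(
                             hypo_means = c(0.2, 0.6),
                             hyper_means = c(0.6, 0.2)))
  set.seed(31)
  lab <- draw_truth_labels(des)
  pr <- draw_true_proportions(des, lab)
  expect_identical(pr$p_case[lab == 0L], pr$p_control[lab == 0L])
  expect_true(all(pr$p_case[lab == 1L] < pr$p_control[lab == 1L] - 0.2))
  expect_true(all(pr$p_case[lab == 2L] > pr$p_control[lab == 2L] + 0.2))
  # law of large numbers on the directional pool means (truncation shifts
  # them slightly apart, so the check is loose but directional)
  expect_lt(abs(mean(pr$p_case[lab == 1L]) - 0.2), 0.05)
  expect_lt(abs(mean(pr$p_control[lab == 1L]) - 0.6), 0.05)
})

test_that("subject effect concentrates on the locus proportion as dispersion vanishes", {
  des <- simulation_design(n_loci = 500, gamma = 0.2,
                           subject_effect = TRUE,
                           subject_concentration = 1e6)
  set.seed(5)
  lab <- draw_truth_labels(des)
  pr <- draw_true_proportions(des, lab)
  expect_lt(max(abs(pr$p_case_rep - pr$p_case)), 0.01)
  # moderate concentration produces genuine replicate variation
  des$subject_concentration <- 50
  set.seed(5)
  pr2 <- draw_true_proportions(des, lab)
  expect_gt(max(abs(pr2$p_case_rep - pr2$p_case)), 0.01)
})

test_that("binomial count generation matches its parameters", {
  des <- simulation_design(n_loci = 200, gamma = 0.2)
  # degenerate proportions give degenerate counts
  set.seed(1)
  p0 <- list(p_case = rep(0, 200), p_control = rep(1, 200))
  sim <- simulate_counts(p0, des)
  expect_true(all(sim$meth_case == 0))
  expect_true(all(sim$meth_control == sim$cov_control))
  expect_true(all(sim$cov_case >= 1))
  # binomial mean at p = 0.3
  des2 <- simulation_design(n_loci = 5000, gamma = 0.2,
                            coverage_model = list(type = "empirical", values = 50))
  set.seed(2)
  sim2 <- simulate_counts(list(p_case = rep(0.3, 5000),
                               p_control = rep(0.3, 5000)), des2)
  phat <- mean(sim2$meth_case / sim2$cov_case)
  se <- sqrt(0.3 * 0.7 / (50 * 10000))
  expect_lt(abs(phat - 0.3), 3 * se)
})

test_that("evaluation metrics reproduce hand-enumerated definitions", {
  ev <- evaluate_calls(c(0, 1, 2, 1), c(1, 1, 2, 2))
  expect_equal(ev$fdr, 1 / 4)
  expect_equal(ev$mdfdr, 2 / 4)
  expect_equal(ev$tpr, 1)
  expect_equal(ev$tpr_hypo, 1 / 2)
  expect_equal(ev$tpr_hyper, 1)
  expect_equal(sum(ev$confusion), 4)
  # all-null calls: FDR undefined, not zero
  ev0 <- evaluate_calls(c(0, 1, 2), c(0, 0, 0))
  expect_true(is.na(ev0$fdr) && is.na(ev0$mdfdr))
  expect_equal(ev0$tpr, 0)
  # perfect calls
  evp <- evaluate_calls(c(0, 1, 2, 2), c(0, 1, 2, 2))
  expect_equal(evp$fdr, 0); expect_equal(evp$mdfdr, 0)
  expect_equal(evp$tpr, 1); expect_equal(evp$tpr_hypo, 1); expect_equal(evp$tpr_hyper, 1)
  # permissive directional reading counts any discovery
  evd <- evaluate_calls(c(1, 1), c(2, 1), directional = FALSE)
  expect_equal(evd$tpr_hypo, 1)
  expect_error(evaluate_calls(c(0, 3), c(0, 0)), "labels")
  expect_error(evaluate_calls(c(0, 1), c(0, 1, 2)), "lengths")
})

test_that("mdFDR never falls below FDR, with equality iff no direction errors", {
  set.seed(41)
  for (i in 1:30) {
    truth <- sample(0:2, 60, replace = TRUE)
    calls <- sample(0:2, 60, replace = TRUE)
    ev <- evaluate_calls(truth, calls)
    if (!is.na(ev$fdr)) {
      expect_gte(ev$mdfdr, ev$fdr)
      n_dir_err <- sum(calls != 0 & truth != 0 & calls != truth)
      if (n_dir_err == 0) expect_equal(ev$mdfdr, ev$fdr)
      else expect_gt(ev$mdfdr, ev$fdr)
    }
  }
  # joint permutation invariance
  truth <- sample(0:2, 40, replace = TRUE)
  calls <- sample(0:2, 40, replace = TRUE)
  perm <- sample(40)
  expect_identical(evaluate_calls(truth, calls)[1:5],
                   evaluate_calls(truth[perm], calls[perm])[1:5])
})

test_that("the benchmark harness is deterministic and validates methods", {
  des <- simulation_design(n_loci = 120, gamma = 0.2,
                           group_fractions = c(0.6, 0.2, 0.2))
  b1 <- run_benchmark(des, n_reps = 2, methods = c("bayes", "ztest"),
                      n_sweeps = 300, seed = 99)
  b2 <- run_benchmark(des, n_reps = 2, methods = c("bayes", "ztest"),
                      n_sweeps = 300, seed = 99)
  expect_identical(b1$summary, b2$summary)
  expect_identical(b1$matched_fdr_level, b2$matched_fdr_level)
  expect_error(run_benchmark(des, n_reps = 1, methods = c("bayes", "dss")),
               "unknown method")
  expect_error(run_benchmark(des, n_reps = 1, methods = "ztest",
                             fdr_matching = TRUE), "requires")
})

test_that("noise-free zero-one proportions yield perfect recovery", {
  # every true proportion is 0 or 1, so the counts are deterministic and
  # every locus is unambiguous
  pools <- empirical_pools(p_case = c(0, 1, 0, 1), p_control = c(0, 1, 1, 0),
                           gamma = 0.5, p_pooled = c(0, 1, 0.5, 0.5))
  des <- simulation_design(n_loci = 150, gamma = 0.5,
                           group_fractions = c(0.4, 0.3, 0.3),
                           coverage_model = list(type = "empirical", values = 40),
                           proportion_pools = pools, seed = 77)
  sim <- simulate_dataset(des)
  post <- run_chain(sim$counts, config = chain_config(n_sweeps = 500, seed = 78))
  ev <- evaluate_calls(sim$truth, post$call)
  expect_equal(ev$tpr, 1)
  expect_equal(ev$fdr, 0)
  expect_equal(ev$mdfdr, 0)
})

test_that("power increases with effect size for every method", {
  design_with <- function(hypo_means) {
    simulation_design(n_loci = 400, gamma = 0.1,
                      group_fractions = c(0.6, 0.2, 0.2),
                      coverage_model = list(type = "shifted_poisson", lambda = 25),
                      proportion_pools = parametric_pools(
                        hypo_means = hypo_means, hyper_means = rev(hypo_means),
                        concentration = 200))
  }
  weak <- design_with(c(0.3, 0.5))
  strong <- design_with(c(0.1, 0.9))
  bw <- run_benchmark(weak, n_reps = 5, methods = c("bayes", "ztest"),
                      n_sweeps = 600, seed = 11)
  bs <- run_benchmark(strong, n_reps = 5, methods = c("bayes", "ztest"),
                      n_sweeps = 600, seed = 11)
  for (m in c("bayes", "ztest")) {
    tw <- bw$summary$tpr[bw$summary$method == m]
    ts <- bs$summary$tpr[bs$summary$method == m]
    expect_lte(tw, ts)
  }
})

test_that("simulation designs validate their inputs", {
  expect_error(simulation_design(n_loci = 0), "positive")
  expect_error(simulation_design(gamma = 0.001), "gamma")
  expect_error(simulation_design(group_fractions = c(0.5, 0.4, 0.2)), "summing")
  expect_error(simulation_design(coverage_model = list(type = "normal")),
               "coverage model")
  expect_error(parametric_pools(hypo_means = c(0.6, 0.2)))
  pool <- empirical_pools(c(0.1, 0.5, 0.9), c(0.5, 0.5, 0.5), gamma = 0.2)
  expect_identical(nrow(pool$hypo), 1L)
  expect_identical(nrow(pool$hyper), 1L)
  expect_identical(length(pool$equal), 1L)
})
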