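test_that("beta_order_probability matches closed forms and is exchangeable", {
  expect_equal(beta_order_probability(1, 2, 2, 1), 5 / 6, tolerance = 1e-10)
  # exchangeability: identical laws give exactly 1/2
  for (sh in list(c(1, 1), c(3, 7), c(0.4, 2.3)))
    expect_equal(beta_order_probability(sh[1], sh[2], sh[1], sh[2]), 0.5,
                 tolerance = 1e-9)
  # small integer shapes (exact path) against direct quadrature
  q <- integrate(function(t) dbeta(t, 4, 9) * pbeta(t, 7, 3, lower.tail = FALSE),
                 0, 1, abs.tol = 1e-12)$value
  expect_equal(beta_order_probability(4, 9, 7, 3), q, tolerance = 1e-10)
  # large integer shapes (quadrature path) against the finite sum
  expect_equal(beta_order_probability(30, 25, 20, 40),
               closed_form_order_prob(30, 25, 20, 40), tolerance = 1e-10)
  # Monte-Carlo oracle at skewed shapes
  set.seed(11)
  x <- rbeta(1e6, 30, 5); y <- rbeta(1e6, 5, 30)
  phat <- mean(x < y)
  se <- sqrt(phat * (1 - phat) / 1e6) + 1e-9
  expect_lt(abs(beta_order_probability(30, 5, 5, 30) - phat), 3 * se)
  expect_error(beta_order_probability(-1, 2, 1, 1), "positive")
})

test_that("complementary order probabilities sum to one", {
  set.seed(4)
  for (i in 1:20) {
    sh <- runif(4, 0.3, 60)
    expect_equal(beta_order_probability(sh[1], sh[2], sh[3], sh[4]) +
                   beta_order_probability(sh[3], sh[4], sh[1], sh[2]),
                 1, tolerance = 1e-10)
  }
})

test_that("collapsed marginals reproduce worked examples", {
  lc <- locus_counts(1, 1, 1, 0)
  expect_equal(log_marginal_equal(lc, include_coefficients = TRUE),
               log(1 / 6), tolerance = 1e-12)
  # empty data contributes a unit factor
  z <- locus_counts(c(0, 0), c(0, 0), c(0, 0), c(0, 0))
  expect_identical(log_marginal_equal(z), 0)
  expect_equal(log_marginal_hypo(z), log(2) + log(0.5), tolerance = 1e-12)
  # hypo worked example and its hyper mirror
  expect_equal(log_marginal_hypo(locus_counts(1, 0, 1, 1),
                                 include_coefficients = TRUE),
               log(5 / 12), tolerance = 1e-12)
  expect_equal(log_marginal_hyper(locus_counts(1, 1, 1, 0),
                                  include_coefficients = TRUE),
               log(5 / 12), tolerance = 1e-12)
  expect_error(log_marginal_equal(lc, hyperparameters(alpha1 = 0)), "positive")
})

test_that("symmetric data gives equal hypo and hyper marginals; ordered data orders them", {
  sym <- locus_counts(c(4, 3), c(2, 1), c(4, 3), c(2, 1))
  expect_equal(log_marginal_hypo(sym), log_marginal_hyper(sym), tolerance = 1e-12)
  hypo_data <- locus_counts(c(20, 20), c(1, 2), c(20, 20), c(18, 19))
  expect_gt(log_marginal_hypo(hypo_data), log_marginal_hyper(hypo_data))
  hyper_data <- locus_counts(c(20, 20), c(18, 19), c(20, 20), c(1, 2))
  expect_gt(log_marginal_hyper(hyper_data), log_marginal_equal(hyper_data))
})

test_that("label-swap exchanges the hypo and hyper marginals exactly", {
  set.seed(21)
  for (i in 1:20) {
    l <- random_small_locus()
    ls <- swap_conditions(l)
    expect_equal(log_marginal_hypo(l), log_marginal_hyper(ls), tolerance = 1e-12)
    expect_equal(log_marginal_hyper(l), log_marginal_hypo(ls), tolerance = 1e-12)
    expect_equal(log_marginal_equal(l), log_marginal_equal(ls), tolerance = 1e-12)
  }
})

test_that("marginals agree with direct quadrature of prior times likelihood", {
  skip_if_not_installed("pracma")
  set.seed(33)
  n_checked <- 0
  for (i in 1:55) {
    l <- random_small_locus()
    qe <- quad_marginal_equal(l)
    expect_equal(log_marginal_equal(l, include_coefficients = TRUE), log(qe),
                 tolerance = 1e-6)
    qh <- quad_marginal_ordered(l, "hypo")
    expect_equal(log_marginal_hypo(l, include_coefficients = TRUE), log(qh),
                 tolerance = 1e-6)
    qg <- quad_marginal_ordered(l, "hyper")
    expect_equal(log_marginal_hyper(l, include_coefficients = TRUE), log(qg),
                 tolerance = 1e-6)
    n_checked <- n_checked + 1
  }
  expect_gte(n_checked, 50)
})

test_that("directional evidence is monotone in count separation", {
  # fixed coverage 20+20 per condition; shift methylated mass from case
  # to control: the hypo-vs-hyper log ratio must not decrease
  prev <- -Inf
  for (m in 20:0) {
    l <- locus_counts(c(10, 10), c(ceiling(m / 2), floor(m / 2)),
                      c(10, 10), c(ceiling((20 - m) / 2), floor((20 - m) / 2)))
    ratio <- log_marginal_hypo(l) - log_marginal_hyper(l)
    expect_gte(ratio, prev - 1e-12)
    prev <- ratio
  }
})

test_that("partition prior normalises and matches hand values", {
  expect_identical(log_partition_prior(c(0, 0, 0)), 0)
  expect_equal(log_partition_prior(c(1, 0, 0)), log(1 / 3), tolerance = 1e-12)
  expect_equal(log_partition_prior(c(2, 0, 0)), log(1 / 6), tolerance = 1e-12)
  # sum over all 3^L assignments is 1 for several L and non-flat k
  for (hyp in list(hyperparameters(), hyperparameters(k0 = 2, k1 = 0.5, k2 = 1.3))) {
    for (L in c(2, 4, 6)) {
      states <- as.matrix(expand.grid(rep(list(0:2), L)))
      tot <- sum(apply(states, 1, function(m)
        exp(log_partition_prior(tabulate(m + 1L, 3L), hyp))))
      expect_equal(tot, 1, tolerance = 1e-10)
    }
  }
  expect_error(log_partition_prior(c(-1, 0, 0)), "non-negative")
})

test_that("unnormalised log posterior composes cache and prior", {
  l <- locus_counts(c(3, 2), c(1, 2), c(4, 1), c(0, 1))
  cache <- compute_log_marginals(list(l))
  expect_equal(log_posterior_unnormalized(partition_state(0), cache),
               unname(cache[1, 1]) + log(1 / 3), tolerance = 1e-12)
  # permutation invariance
  set.seed(5)
  loci <- replicate(5, random_small_locus(), simplify = FALSE)
  cache <- compute_log_marginals(loci)
  memb <- c(0L, 1L, 2L, 0L, 1L)
  perm <- sample(5)
  expect_equal(log_posterior_unnormalized(partition_state(memb), cache),
               log_posterior_unnormalized(partition_state(memb[perm]),
                                          cache[perm, , drop = FALSE]),
               tolerance = 1e-12)
  expect_error(log_posterior_unnormalized(partition_state(c(0, 1)), cache),
               "match")
})

test_that("cache agrees with the single-locus marginal functions", {
  set.seed(8)
  loci <- replicate(10, random_small_locus(), simplify = FALSE)
  hyp <- hyperparameters(alpha2 = 2, beta2 = 1.5, alpha3 = 0.7, beta3 = 1.2)
  cache <- compute_log_marginals(loci, hyp)
  for (i in seq_along(loci)) {
    expect_equal(unname(cache[i, 1]), log_marginal_equal(loci[[i]], hyp), tolerance = 1e-10)
    expect_equal(unname(cache[i, 2]), log_marginal_hypo(loci[[i]], hyp), tolerance = 1e-10)
    expect_equal(unname(cache[i, 3]), log_marginal_hyper(loci[[i]], hyp), tolerance = 1e-10)
  }
})

test_that("exact enumeration returns coherent coupled marginals", {
  sym <- list(locus_counts(c(3, 4), c(1, 2), c(3, 4), c(1, 2)))
  pr <- enumerate_exact_posterior(sym)
  expect_equal(unname(pr[1, "hypo"]), unname(pr[1, "hyper"]), tolerance = 1e-12)
  expect_equal(unname(sum(pr[1, ])), 1, tolerance = 1e-12)
  # adding a strongly hypo locus changes the marginals of an unrelated
  # locus: the partition prior couples loci through the group counts
  base <- list(locus_counts(c(5, 5), c(2, 3), c(5, 5), c(2, 2)),
               locus_counts(c(5, 5), c(1, 1), c(5, 5), c(2, 3)))
  pr2 <- enumerate_exact_posterior(base)
  strong <- c(base, list(locus_counts(c(20, 20), c(0, 1), c(20, 20), c(19, 20))))
  pr3 <- enumerate_exact_posterior(strong)
  expect_gt(max(abs(pr3[1:2, ] - pr2)), 1e-4)
  # rows always sum to 1
  expect_equal(rowSums(pr3), rep(1, 3), tolerance = 1e-12)
  expect_error(enumerate_exact_posterior(replicate(11, random_small_locus(),
                                                   simplify = FALSE)),
               "cap")
})

test_that("case-control swap exchanges hypo and hyper posteriors at enumeration level", {
  set.seed(13)
  loci <- replicate(4, random_small_locus(), simplify = FALSE)
  swapped <- lapply(loci, swap_conditions)
  a <- enumerate_exact_posterior(loci)
  b <- enumerate_exact_posterior(swapped)
  expect_equal(unname(a[, "equal"]), unname(b[, "equal"]), tolerance = 1e-12)
  expect_equal(unname(a[, "hypo"]), unname(b[, "hyper"]), tolerance = 1e-12)
  expect_equal(unname(a[, "hyper"]), unname(b[, "hypo"]), tolerance = 1e-12)
})
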