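# Shared fixtures and independent numerical oracles.

# Fixed 6-locus oracle fixture: 2+2 samples, coverages <= 6, strongly
# identified directional loci (at this coverage only directional loci have
# concentrated posteriors, which is what a finite-sample frequency
# estimator can be checked against tightly).
oracle_fixture <- function() {
  list(
    locus_counts(c(6, 6), c(0, 0), c(6, 6), c(6, 6)),  # strong hypo
    locus_counts(c(6, 6), c(6, 6), c(6, 6), c(0, 0)),  # strong hyper
    locus_counts(c(6, 5), c(1, 1), c(6, 6), c(5, 4)),  # moderate hypo
    locus_counts(c(5, 6), c(4, 5), c(6, 5), c(1, 1)),  # moderate hyper
    locus_counts(c(6, 6), c(0, 1), c(6, 6), c(6, 5)),  # clear hypo
    locus_counts(c(6, 6), c(5, 6), c(6, 6), c(1, 0)))  # clear hyper
}

# random small-count locus (2+2 samples, coverage <= cmax)
random_small_locus <- function(cmax = 5) {
  C1 <- sample.int(cmax, 2, replace = TRUE)
  C2 <- sample.int(cmax, 2, replace = TRUE)
  locus_counts(C1, rbinom(2, C1, runif(1)), C2, rbinom(2, C2, runif(1)))
}

# swap the case and control blocks of a locus
swap_conditions <- function(l) {
  locus_counts(l$coverage_control, l$meth_control,
               l$coverage_case, l$meth_case)
}

# --- independent quadrature oracles (prior x likelihood, coefficients in) ---

# shared-proportion marginal: 1-D integral of the binomial likelihood of
# all replicates against the Beta prior density
quad_marginal_equal <- function(l, a = 1, b = 1) {
  f <- function(p) {
    v <- sapply(p, function(pp)
      prod(dbinom(c(l$meth_case, l$meth_control),
                  c(l$coverage_case, l$coverage_control), pp)))
    v * dbeta(p, a, b)
  }
  integrate(f, 0, 1, abs.tol = 1e-12, rel.tol = 1e-10)$value
}

# ordered-pair marginal: 2-D integral of the truncated product prior
# (factor 2, region p1 < p2 for hypo, p1 > p2 for hyper) times the
# per-condition binomial likelihoods
quad_marginal_ordered <- function(l, direction = c("hypo", "hyper"),
                                  a = 1, b = 1) {
  direction <- match.arg(direction)
  lik <- function(p1, p2) {
    v1 <- vapply(p1, function(pp)
      prod(dbinom(l$meth_case, l$coverage_case, pp)), 0)
    v2 <- vapply(p2, function(pp)
      prod(dbinom(l$meth_control, l$coverage_control, pp)), 0)
    2 * v1 * v2 * dbeta(p1, a, b) * dbeta(p2, a, b)
  }
  f <- function(x, y) {
    dim_in <- dim(x)
    v <- lik(as.vector(x), as.vector(y))
    if (!is.null(dim_in)) dim(v) <- dim_in
    v
  }
  if (direction == "hypo") {
    pracma::integral2(f, 0, 1, function(x) x, 1, reltol = 1e-10)$Q
  } else {
    pracma::integral2(f, 0, 1, 0, function(x) x, reltol = 1e-10)$Q
  }
}

# finite-sum order probability for integer Y shapes, written independently
# of the package's internals
closed_form_order_prob <- function(ax, bx, ay, by) {
  n <- ay + by - 1
  j <- ay:n
  1 - sum(choose(n, j) * beta(ax + j, bx + n - j) / beta(ax, bx))
}

extdata <- function(f) system.file("extdata", f, package = "methpart")
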