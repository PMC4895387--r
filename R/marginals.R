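#' Probability that one Beta variable is below another
#'
#' Computes P(X < Y) for independent X ~ Beta(ax, bx) and Y ~ Beta(ay, by).
#' This is the directional evidence term in the collapsed marginal
#' likelihoods of the hypo- and hyper-methylated groups, where X and Y are
#' the Beta posterior laws of the case and control methylation proportions.
#'
#' For integer shapes with both shape sums at most 50 an exact finite sum
#' is used (the Beta CDF at integer shapes is a binomial tail, and each
#' term integrates in closed form against the Beta density); otherwise the
#' integral of `dbeta(t, ax, bx) * pbeta(t, ay, by, lower.tail = FALSE)`
#' is evaluated by adaptive quadrature to absolute tolerance 1e-10.
#'
#' @param ax,bx shapes of X (positive).
#' @param ay,by shapes of Y (positive).
#' @return P(X < Y), a number in `[0, 1]`.
#' @examples
#' beta_order_probability(1, 2, 2, 1)  # 5/6
#' beta_order_probability(3, 3, 3, 3)  # 1/2 by exchangeability
#' @export
beta_order_probability <- function(ax, bx, ay, by) {
  shapes <- c(ax, bx, ay, by)
  if (any(!is.finite(shapes)) || any(shapes <= 0))
    stop("Beta shapes must be positive and finite")
  is_int <- function(v) abs(v - round(v)) < 1e-9
  if (all(is_int(shapes)) && ax + bx <= 50 && ay + by <= 50) {
    # F_Y(t) = sum_{j=ay}^{n} C(n,j) t^j (1-t)^(n-j), n = ay + by - 1;
    # integrating term-wise against dbeta(t, ax, bx):
    n <- round(ay + by - 1)
    j <- round(ay):n
    terms <- exp(lchoose(n, j) + lbeta(ax + j, bx + n - j) - lbeta(ax, bx))
    p <- 1 - sum(terms)
  } else {
    q <- integrate(function(t) dbeta(t, ax, bx) * pbeta(t, ay, by, lower.tail = FALSE),
                   lower = 0, upper = 1,
                   abs.tol = 1e-10, rel.tol = 1e-10,
                   subdivisions = 500L, stop.on.error = FALSE)
    if (!q$message %in% c("OK", "roundoff error was detected"))
      stop("order-probability quadrature failed: ", q$message)
    p <- q$value
  }
  min(max(p, 0), 1)
}

# clamp before log: strongly ordered data can underflow P(X<Y) to 0, and
# the MH ratio needs all three per-locus factors finite
.log_clamped <- function(p) log(min(max(p, 1e-300), 1 - 1e-16))

#' Collapsed log marginal likelihood, equal-methylated group
#'
#' Log of the single-locus factor of the collapsed marginal likelihood
#' under the equal-methylated hypothesis: the binomial counts of both
#' conditions share one methylation proportion with a Beta(alpha1, beta1)
#' prior, integrated out analytically, giving
#' `B(alpha1 + sum M, beta1 + sum N) / B(alpha1, beta1)` with sums over
#' all replicates of both conditions (N = C - M).
#'
#' Binomial coefficients are identical across the three group hypotheses
#' and cancel in every posterior ratio; they are included only when
#' `include_coefficients = TRUE` (needed when comparing against direct
#' numerical integration of prior times likelihood).
#'
#' @param locus a [locus_counts] object.
#' @param hyper a [hyperparameters] object.
#' @param include_coefficients include the log binomial coefficients?
#' @return a finite log probability factor.
#' @examples
#' lc <- locus_counts(1, 1, 1, 0)
#' log_marginal_equal(lc, include_coefficients = TRUE)  # log(1/6)
#' @export
log_marginal_equal <- function(locus, hyper = hyperparameters(),
                               include_coefficients = FALSE) {
  hyper <- .as_hyper(hyper)
  s <- .locus_sums(locus)
  v <- lbeta(hyper$alpha1 + s$M1 + s$M2, hyper$beta1 + s$N1 + s$N2) -
    lbeta(hyper$alpha1, hyper$beta1)
  if (include_coefficients) v <- v + .locus_log_coef(locus)
  v
}

#' Collapsed log marginal likelihood, hypo-methylated group
#'
#' Single-locus factor under the hypo-methylated hypothesis: independent
#' Beta(alpha2, beta2) priors on the case and control proportions,
#' truncated to the ordered region (case below control) with normalising
#' factor 2.  Integrating the proportions out gives one Beta-function
#' ratio per condition times `2 * P(X < Y)` where X and Y are the Beta
#' posterior laws of the case and control proportions.  The order
#' probability is clamped away from 0 before the log so the factor stays
#' finite for strongly anti-ordered data.
#'
#' @inheritParams log_marginal_equal
#' @return a finite log probability factor.
#' @examples
#' lc <- locus_counts(1, 0, 1, 1)
#' log_marginal_hypo(lc, include_coefficients = TRUE)  # log(5/12)
#' @export
log_marginal_hypo <- function(locus, hyper = hyperparameters(),
                              include_coefficients = FALSE) {
  hyper <- .as_hyper(hyper)
  s <- .locus_sums(locus)
  a <- hyper$alpha2; b <- hyper$beta2
  v <- lbeta(s$M1 + a, s$N1 + b) + lbeta(s$M2 + a, s$N2 + b) - 2 * lbeta(a, b) +
    log(2) + .log_clamped(beta_order_probability(a + s$M1, b + s$N1,
                                                 a + s$M2, b + s$N2))
  if (include_coefficients) v <- v + .locus_log_coef(locus)
  v
}

#' Collapsed log marginal likelihood, hyper-methylated group
#'
#' As [log_marginal_hypo] with shapes `(alpha3, beta3)` and the order of
#' the comparison reversed: the factor is `2 * P(X > Y)` with X the case
#' and Y the control Beta posterior law.
#'
#' @inheritParams log_marginal_equal
#' @return a finite log probability factor.
#' @export
log_marginal_hyper <- function(locus, hyper = hyperparameters(),
                               include_coefficients = FALSE) {
  hyper <- .as_hyper(hyper)
  s <- .locus_sums(locus)
  a <- hyper$alpha3; b <- hyper$beta3
  v <- lbeta(s$M1 + a, s$N1 + b) + lbeta(s$M2 + a, s$N2 + b) - 2 * lbeta(a, b) +
    log(2) + .log_clamped(beta_order_probability(a + s$M2, b + s$N2,
                                                 a + s$M1, b + s$N1))
  if (include_coefficients) v <- v + .locus_log_coef(locus)
  v
}

#' Per-locus log marginal cache
#'
#' Computes the L x 3 matrix of collapsed log marginal factors (columns:
#' equal, hypo, hyper; binomial coefficients excluded) for every locus of
#' a count table.  The sampler evaluates all posterior ratios from this
#' cache; the likelihood factorises over loci given the membership vector,
#' so the cache is computed once.
#'
#' @param x a `meth_counts` table (see [read_counts], [simulate_dataset])
#'   or a list of [locus_counts].
#' @param hyper a [hyperparameters] object.
#' @return numeric matrix with L rows and columns `equal`, `hypo`, `hyper`.
#' @export
compute_log_marginals <- function(x, hyper = hyperparameters()) {
  hyper <- .as_hyper(hyper)
  if (inherits(x, "meth_counts")) {
    M1 <- rowSums(x$meth_case); C1 <- rowSums(x$cov_case)
    M2 <- rowSums(x$meth_control); C2 <- rowSums(x$cov_control)
  } else {
    M1 <- vapply(x, function(l) sum(l$meth_case), 0)
    C1 <- vapply(x, function(l) sum(l$coverage_case), 0)
    M2 <- vapply(x, function(l) sum(l$meth_control), 0)
    C2 <- vapply(x, function(l) sum(l$coverage_control), 0)
  }
  N1 <- C1 - M1; N2 <- C2 - M2
  L <- length(M1)
  g <- matrix(NA_real_, L, 3, dimnames = list(NULL, c("equal", "hypo", "hyper")))
  g[, 1] <- lbeta(hyper$alpha1 + M1 + M2, hyper$beta1 + N1 + N2) -
    lbeta(hyper$alpha1, hyper$beta1)
  a2 <- hyper$alpha2; b2 <- hyper$beta2
  a3 <- hyper$alpha3; b3 <- hyper$beta3
  p_lt <- vapply(seq_len(L), function(i)
    beta_order_probability(a2 + M1[i], b2 + N1[i], a2 + M2[i], b2 + N2[i]), 0)
  g[, 2] <- lbeta(M1 + a2, N1 + b2) + lbeta(M2 + a2, N2 + b2) -
    2 * lbeta(a2, b2) + log(2) +
    vapply(p_lt, .log_clamped, 0)
  if (a2 == a3 && b2 == b3) {
    p_gt <- 1 - p_lt  # continuous laws: P(X > Y) = 1 - P(X < Y)
  } else {
    p_gt <- vapply(seq_len(L), function(i)
      beta_order_probability(a3 + M2[i], b3 + N2[i], a3 + M1[i], b3 + N1[i]), 0)
  }
  g[, 3] <- lbeta(M1 + a3, N1 + b3) + lbeta(M2 + a3, N2 + b3) -
    2 * lbeta(a3, b3) + log(2) +
    vapply(p_gt, .log_clamped, 0)
  g
}

#' Log prior of a three-group partition
#'
#' The multinomial membership prior with its Dirichlet(k0, k1, k2)
#' probability vector integrated out:
#' `log B(k0 + l0, k1 + l1, k2 + l2) - log B(k0, k1, k2)` with the
#' three-argument Beta function, evaluated via log-gamma.
#'
#' @param counts integer triple `(l0, l1, l2)` of group sizes.
#' @param hyper a [hyperparameters] object (uses `k0`, `k1`, `k2`).
#' @return the log prior mass of any single membership vector with those
#'   group counts.
#' @examples
#' log_partition_prior(c(1, 0, 0))  # log(1/3): one locus, flat prior
#' @export
log_partition_prior <- function(counts, hyper = hyperparameters()) {
  hyper <- .as_hyper(hyper)
  if (length(counts) != 3L || any(!is.finite(counts)) || any(counts < 0))
    stop("counts must be three non-negative group sizes")
  k <- c(hyper$k0, hyper$k1, hyper$k2)
  sum(lgamma(k + counts)) - lgamma(sum(k + counts)) -
    (sum(lgamma(k)) - lgamma(sum(k)))
}

#' Unnormalised log posterior of a membership vector
#'
#' Sum of the cached per-locus log marginal factors picked out by the
#' membership labels, plus the partition log prior.  Equal, up to the
#' constant binomial-coefficient product, to the log of the unnormalised
#' posterior of the membership vector.
#'
#' @param state a [partition_state].
#' @param cache L x 3 matrix from [compute_log_marginals].
#' @param hyper a [hyperparameters] object.
#' @return a real number.
#' @export
log_posterior_unnormalized <- function(state, cache, hyper = hyperparameters()) {
  if (!inherits(state, "partition_state")) state <- partition_state(state)
  L <- length(state$membership)
  if (nrow(cache) != L) stop("cache rows must match membership length")
  sum(cache[cbind(seq_len(L), state$membership + 1L)]) +
    log_partition_prior(state$group_counts, hyper)
}

#' Exact posterior membership probabilities by enumeration
#'
#' Enumerates all `3^L` membership vectors, normalises the unnormalised
#' posterior, and returns the exact marginal membership probability triple
#' of every locus.  A brute-force oracle for validating the sampler;
#' refuses more than `max_loci` loci.
#'
#' @param data a `meth_counts` table or list of [locus_counts].
#' @param hyper a [hyperparameters] object.
#' @param max_loci enumeration cap (default 10).
#' @return L x 3 matrix of probabilities (columns equal/hypo/hyper), each
#'   row summing to 1.
#' @export
enumerate_exact_posterior <- function(data, hyper = hyperparameters(),
                                      max_loci = 10L) {
  cache <- compute_log_marginals(data, hyper)
  L <- nrow(cache)
  if (L > max_loci)
    stop("refusing to enumerate ", L, " loci (3^L states); cap is ", max_loci)
  n_states <- 3L^L
  # base-3 digit matrix: states x loci
  digits <- matrix(0L, n_states, L)
  idx <- 0:(n_states - 1)
  for (i in seq_len(L)) {
    digits[, i] <- idx %% 3L
    idx <- idx %/% 3L
  }
  lp <- numeric(n_states)
  for (s in seq_len(n_states)) {
    memb <- digits[s, ]
    counts <- tabulate(memb + 1L, nbins = 3L)
    lp[s] <- sum(cache[cbind(seq_len(L), memb + 1L)]) +
      log_partition_prior(counts, hyper)
  }
  w <- exp(lp - max(lp))
  w <- w / sum(w)
  out <- matrix(0, L, 3, dimnames = list(NULL, c("equal", "hypo", "hyper")))
  for (g in 0:2)
    out[, g + 1L] <- colSums(w * (digits == g))
  out
}
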