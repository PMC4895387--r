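#' Pooled two-proportion z-test for one locus
#'
#' Pools sequencing reads over the replicates of each condition and tests
#' equality of the two pooled methylation proportions with the standard
#' two-proportion z statistic:
#' `z = (p1 - p2) / sqrt(p (1 - p) (1/C1 + 1/C2))` with `p` the overall
#' pooled proportion.  When the overall pooled proportion is 0 or 1 the
#' standard error degenerates; the result is flagged and its p-value is 1.
#'
#' @param locus a [locus_counts] object.
#' @return a list with `statistic`, `p_value`, `estimated_difference`
#'   (pooled case minus control proportion), `direction` (1 if the
#'   difference is negative, 2 if positive, 0 if zero) and `degenerate`.
#' @examples
#' z_test_pooled(locus_counts(10, 9, 10, 1))
#' @export
z_test_pooled <- function(locus) {
  s <- .locus_sums(locus)
  C1 <- s$M1 + s$N1; C2 <- s$M2 + s$N2
  if (C1 <= 0 || C2 <= 0) stop("pooled coverage must be positive in both conditions")
  p1 <- s$M1 / C1; p2 <- s$M2 / C2
  d <- p1 - p2
  p_pool <- (s$M1 + s$M2) / (C1 + C2)
  if (p_pool <= 0 || p_pool >= 1) {
    return(list(statistic = 0, p_value = 1, estimated_difference = d,
                direction = .sign_direction(d), degenerate = TRUE))
  }
  z <- d / sqrt(p_pool * (1 - p_pool) * (1 / C1 + 1 / C2))
  list(statistic = z, p_value = 2 * pnorm(-abs(z)), estimated_difference = d,
       direction = .sign_direction(d), degenerate = FALSE)
}

.sign_direction <- function(d) if (d < 0) 1L else if (d > 0) 2L else 0L

#' Per-locus binomial logistic regression test
#'
#' Fits `logit(p) = b0 + b1 * condition` to the per-replicate
#' (methylated, unmethylated) counts of one locus and tests `b1 = 0` by
#' the Wald test.  When the fit is separated or otherwise unstable
#' (fitted proportions at the boundary, inflated standard error) the
#' p-value falls back to the likelihood-ratio test; non-convergence is
#' flagged with p-value 1.
#'
#' @param locus a [locus_counts] object.
#' @return a list as in [z_test_pooled] plus `method` (`"wald"`, `"lrt"`
#'   or `"none"`).
#' @export
logistic_regression_test <- function(locus) {
  s <- .locus_sums(locus)
  if (s$M1 + s$N1 <= 0 || s$M2 + s$N2 <= 0)
    stop("pooled coverage must be positive in both conditions")
  M <- c(locus$meth_case, locus$meth_control)
  U <- c(locus$coverage_case - locus$meth_case,
         locus$coverage_control - locus$meth_control)
  cond <- c(rep(1, length(locus$meth_case)), rep(0, length(locus$meth_control)))
  keep <- (M + U) > 0
  d <- s$M1 / (s$M1 + s$N1) - s$M2 / (s$M2 + s$N2)

  fit <- tryCatch(
    suppressWarnings(glm(cbind(M, U) ~ cond, family = binomial(), subset = keep,
                         control = list(epsilon = 1e-12, maxit = 100))),
    error = function(e) NULL)
  if (is.null(fit) || !fit$converged || is.na(coef(fit)["cond"])) {
    return(list(statistic = 0, p_value = 1, estimated_difference = d,
                direction = .sign_direction(d), degenerate = TRUE,
                method = "none"))
  }
  sm <- summary(fit)$coefficients
  se <- sm["cond", "Std. Error"]
  b1 <- sm["cond", "Estimate"]
  separated <- !is.finite(se) || se > 1e3 || abs(b1) > 15
  if (!separated) {
    z <- b1 / se
    p <- 2 * pnorm(-abs(z))
    method <- "wald"
  } else {
    null_fit <- suppressWarnings(glm(cbind(M, U) ~ 1, family = binomial(),
                                     subset = keep))
    lr <- null_fit$deviance - fit$deviance
    z <- sign(b1) * sqrt(max(lr, 0))
    p <- pchisq(max(lr, 0), df = 1, lower.tail = FALSE)
    method <- "lrt"
  }
  list(statistic = z, p_value = p, estimated_difference = d,
       direction = .sign_direction(d), degenerate = FALSE, method = method)
}

#' Storey q-values
#'
#' Computes q-values with the null proportion estimated at a single
#' tuning point lambda = 0.5: `pi0 = min(1, #{p > 0.5} / (0.5 m))`, then
#' `q = pi0 x` the Benjamini-Hochberg step-up adjustment, which enforces
#' monotonicity in the sorted p-value order.  Forcing `pi0 = 1`
#' reproduces BH adjusted p-values exactly.
#'
#' @param p_values numeric vector of p-values in `[0, 1]`.
#' @param pi0 optional fixed null proportion (e.g. 1 for plain BH);
#'   `NULL` estimates it at lambda = 0.5.
#' @return q-value vector of the same length.
#' @examples
#' qvalue_adjust(c(0.01, 0.02, 0.9, 0.95), pi0 = 1)  # BH: 0.04 0.04 0.95 0.95
#' @export
qvalue_adjust <- function(p_values, pi0 = NULL) {
  if (any(!is.finite(p_values)) || any(p_values < 0 | p_values > 1))
    stop("p-values must lie in [0, 1]")
  lambda <- 0.5
  if (is.null(pi0))
    pi0 <- min(1, mean(p_values > lambda) / (1 - lambda))
  pmin(1, pi0 * p.adjust(p_values, method = "BH"))
}

#' Sign-based direction call for a baseline test
#'
#' The frequentist comparators only decide differentially methylated or
#' not; the direction is then read off the sign of the estimated pooled
#' proportion difference.  A locus that is not a discovery gets 0; a
#' discovery with an exactly zero difference cannot be oriented and also
#' gets 0.
#'
#' @param result a test result from [z_test_pooled] or
#'   [logistic_regression_test].
#' @param discovery logical: did the locus pass the multiplicity
#'   threshold?
#' @return a label in 0 (no call), 1 (hypo), 2 (hyper).
#' @export
call_direction <- function(result, discovery) {
  if (!isTRUE(discovery)) return(0L)
  .sign_direction(result$estimated_difference)
}

#' Run a baseline test over a count table
#'
#' Applies [z_test_pooled] or [logistic_regression_test] to every locus,
#' adjusts p-values to q-values, and makes sign-based directional calls
#' at `q <= fdr_level`.  `method = "external"` skips testing and applies
#' the q-value/direction machinery to a supplied p-value vector (for
#' comparing against methods computed outside the package).
#'
#' @param x a `meth_counts` table.
#' @param method `"ztest"`, `"logistic"` or `"external"`.
#' @param fdr_level nominal FDR level for the q-value threshold.
#' @param pi0 passed to [qvalue_adjust] (`1` for plain BH).
#' @param external_p p-value vector for `method = "external"`.
#' @param min_coverage optional per-sample minimum coverage pre-filter for
#'   the logistic baseline (0 disables; 10 reproduces the common
#'   logistic-regression filtering practice): loci failing it are kept in
#'   the output but never called.
#' @return a data.frame with columns `chrom`, `pos`, `statistic`, `p`,
#'   `q`, `d_hat`, `call`.
#' @export
run_baseline <- function(x, method = c("ztest", "logistic", "external"),
                         fdr_level = 0.05, pi0 = NULL, external_p = NULL,
                         min_coverage = 0) {
  method <- match.arg(method)
  stopifnot(inherits(x, "meth_counts"))
  L <- length(x$pos)
  d_hat <- rowSums(x$meth_case) / rowSums(x$cov_case) -
    rowSums(x$meth_control) / rowSums(x$cov_control)
  eligible <- rep(TRUE, L)
  if (method == "logistic" && min_coverage > 0)
    eligible <- apply(cbind(x$cov_case, x$cov_control) >= min_coverage, 1L, all)

  if (method == "external") {
    if (is.null(external_p) || length(external_p) != L)
      stop("method 'external' needs an external_p vector of length L")
    stat <- rep(NA_real_, L)
    pv <- external_p
  } else {
    testfun <- if (method == "ztest") z_test_pooled else logistic_regression_test
    stat <- numeric(L); pv <- numeric(L)
    for (i in seq_len(L)) {
      r <- testfun(.locus_at(x, i))
      stat[i] <- r$statistic; pv[i] <- r$p_value
    }
  }
  qv <- qvalue_adjust(pv, pi0 = pi0)
  disc <- eligible & qv <= fdr_level
  call <- integer(L)
  call[disc & d_hat < 0] <- 1L
  call[disc & d_hat > 0] <- 2L
  data.frame(chrom = x$chrom, pos = x$pos, statistic = stat, p = pv,
             q = qv, d_hat = d_hat, call = call,
             stringsAsFactors = FALSE)
}
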