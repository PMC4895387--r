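#' Three-group truth labels from estimated proportion differences
#'
#' The rule used to partition loci into simulation truth groups from a
#' table of estimated methylation proportion differences
#' `d_hat = p_case - p_control`: `|d_hat| < 0.005` is equal-methylated
#' (0), `d_hat > gamma` hyper-methylated (2), `d_hat < -gamma`
#' hypo-methylated (1).  Loci in the boundary band
#' `0.005 <= |d_hat| <= gamma` belong to no group (returned as `NA`) and
#' are excluded from proportion pools; `gamma` tunes the effect sizes.
#'
#' @param d_hat numeric vector of proportion differences.
#' @param gamma positive tuning parameter, must exceed 0.005.
#' @return integer vector of labels 0/1/2 with `NA` for excluded loci.
#' @examples
#' partition_by_gamma(c(0.001, -0.3, 0.25, 0.05), gamma = 0.2)
#' @export
partition_by_gamma <- function(d_hat, gamma) {
  if (!is.numeric(gamma) || length(gamma) != 1L || gamma <= 0.005)
    stop("gamma must exceed 0.005 (the equal-group half-width)")
  lab <- rep(NA_integer_, length(d_hat))
  lab[abs(d_hat) < 0.005] <- 0L
  lab[d_hat < -gamma] <- 1L
  lab[d_hat > gamma] <- 2L
  lab
}

#' Group fractions at the two calibrated gamma anchors
#'
#' Returns the `(equal, hypo, hyper)` fractions associated with the two
#' gamma values for which reference proportions are available:
#' gamma = 0.01 gives 43.28 % hypo and 29.44 % hyper; gamma = 0.2 gives
#' 5.9 % hypo and 4.6 % hyper.
#'
#' @param gamma 0.01 or 0.2.
#' @return numeric triple summing to 1.
#' @export
gamma_group_fractions <- function(gamma) {
  presets <- list("0.01" = c(hypo = 0.4328, hyper = 0.2944),
                  "0.2" = c(hypo = 0.059, hyper = 0.046))
  key <- format(gamma)
  if (!key %in% names(presets))
    stop("no preset fractions for gamma = ", gamma,
         "; supply group_fractions explicitly (presets: 0.01, 0.2)")
  p <- presets[[key]]
  c(equal = 1 - sum(p), p)
}

#' Parametric proportion pools
#'
#' Distributions from which true methylation proportions are drawn when
#' no empirical proportion table is supplied.  The equal-group pool is a
#' bimodal Beta mixture mimicking the U-shaped methylation landscape of
#' reduced-representation bisulfite data (most CpGs near 0 or 1).  The
#' directional pools draw the case and control proportions from Beta
#' laws with the given means and concentration (shapes `mean * conc` and
#' `(1 - mean) * conc`), resampling until the pair satisfies the same
#' gamma rule that defines the truth group.
#'
#' @param hypo_means length-2 means `(case, control)` for the hypo pool.
#' @param hyper_means means for the hyper pool.
#' @param concentration Beta concentration of the directional pools.
#' @param equal_weights,equal_shapes mixture weights and a 3 x 2 shape
#'   matrix for the equal-group pool.
#' @return a pool specification list (`type = "parametric"`).
#' @export
parametric_pools <- function(hypo_means = c(0.2, 0.6),
                             hyper_means = c(0.6, 0.2),
                             concentration = 10,
                             equal_weights = c(0.4, 0.4, 0.2),
                             equal_shapes = rbind(c(1, 10), c(10, 1), c(2, 2))) {
  stopifnot(length(hypo_means) == 2L, length(hyper_means) == 2L,
            hypo_means[1] < hypo_means[2], hyper_means[1] > hyper_means[2],
            concentration > 0,
            length(equal_weights) == nrow(equal_shapes))
  list(type = "parametric",
       hypo_means = hypo_means, hyper_means = hyper_means,
       concentration = concentration,
       equal_weights = equal_weights / sum(equal_weights),
       equal_shapes = equal_shapes)
}

#' Empirical proportion pools
#'
#' Builds per-group pools from a user-supplied table of per-locus
#' methylation proportion estimates, reproducing the empirical-pool
#' procedure: apply the gamma rule to `p_case - p_control`, then use the
#' pooled estimates of equal loci as the equal pool and the (case,
#' control) pairs of the directional loci as the hypo/hyper pools.
#'
#' @param p_case,p_control per-locus proportion estimates.
#' @param gamma the partition tuning parameter.
#' @param p_pooled pooled estimate used for equal-group draws; defaults
#'   to the mean of the two condition estimates.
#' @return a pool specification list (`type = "empirical"`).
#' @export
empirical_pools <- function(p_case, p_control, gamma,
                            p_pooled = (p_case + p_control) / 2) {
  lab <- partition_by_gamma(p_case - p_control, gamma)
  pools <- list(type = "empirical",
                equal = p_pooled[!is.na(lab) & lab == 0L],
                hypo = cbind(p_case, p_control)[!is.na(lab) & lab == 1L, , drop = FALSE],
                hyper = cbind(p_case, p_control)[!is.na(lab) & lab == 2L, , drop = FALSE])
  pools
}

#' Simulation design
#'
#' Controls for the synthetic bisulfite-count generator.  Defaults match
#' the benchmark conditions used throughout: 20,000 loci, two replicates
#' per condition, gamma = 0.2 with its preset group fractions (5.9 %
#' hypo, 4.6 % hyper), read coverage drawn as 1 + Poisson(20), parametric
#' proportion pools, no subject effect.
#'
#' @param n_loci number of CpG loci.
#' @param n_case,n_control replicates per condition.
#' @param gamma effect-size tuning parameter (> 0.005).
#' @param group_fractions `(equal, hypo, hyper)` fractions summing to 1;
#'   `NULL` uses [gamma_group_fractions] at `gamma`.
#' @param coverage_model `list(type = "shifted_poisson", lambda = 20)` or
#'   `list(type = "empirical", values = <coverage vector>)`.
#' @param proportion_pools a [parametric_pools] or [empirical_pools]
#'   specification.
#' @param subject_effect draw per-replicate proportions around the locus
#'   proportion (biological variation within condition)?
#' @param subject_concentration Beta concentration of the subject effect
#'   (per-replicate p ~ Beta(p s, (1 - p) s); larger = less variation).
#' @param seed integer seed used by [simulate_dataset].
#' @return An object of class `simulation_design`.
#' @export
simulation_design <- function(n_loci = 20000L, n_case = 2L, n_control = 2L,
                              gamma = 0.2, group_fractions = NULL,
                              coverage_model = list(type = "shifted_poisson",
                                                    lambda = 20),
                              proportion_pools = parametric_pools(),
                              subject_effect = FALSE,
                              subject_concentration = 50,
                              seed = NULL) {
  if (n_loci < 1L || n_case < 1L || n_control < 1L)
    stop("n_loci and replicate counts must be positive")
  if (gamma <= 0.005) stop("gamma must exceed 0.005")
  if (is.null(group_fractions)) group_fractions <- gamma_group_fractions(gamma)
  group_fractions <- as.numeric(group_fractions)
  if (length(group_fractions) != 3L || any(group_fractions < 0) ||
      any(group_fractions > 1) || abs(sum(group_fractions) - 1) > 1e-12)
    stop("group_fractions must be three proportions summing to 1")
  if (!coverage_model$type %in% c("shifted_poisson", "empirical"))
    stop("unknown coverage model type: ", coverage_model$type)
  structure(list(n_loci = as.integer(n_loci), n_case = as.integer(n_case),
                 n_control = as.integer(n_control), gamma = gamma,
                 group_fractions = group_fractions,
                 coverage_model = coverage_model,
                 proportion_pools = proportion_pools,
                 subject_effect = isTRUE(subject_effect),
                 subject_concentration = subject_concentration,
                 seed = seed),
            class = "simulation_design")
}

#' Draw truth labels for a design
#'
#' Assigns each locus to equal/hypo/hyper truth independently with the
#' design's group fractions.
#'
#' @param design a [simulation_design].
#' @return integer vector of labels 0/1/2 of length `n_loci`.
#' @export
draw_truth_labels <- function(design) {
  sample(0:2, design$n_loci, replace = TRUE, prob = design$group_fractions)
}

.draw_equal_pool <- function(pools, n) {
  if (pools$type == "empirical") {
    if (length(pools$equal) == 0L) stop("empirical equal pool is empty")
    return(sample(pools$equal, n, replace = TRUE))
  }
  comp <- sample.int(length(pools$equal_weights), n, replace = TRUE,
                     prob = pools$equal_weights)
  rbeta(n, pools$equal_shapes[comp, 1], pools$equal_shapes[comp, 2])
}

# directional pair draw honoring the gamma rule (d < -gamma for hypo,
# d > gamma for hyper); parametric pools resample until satisfied
.draw_pair_pool <- function(pools, group, n, gamma) {
  if (pools$type == "empirical") {
    pool <- if (group == 1L) pools$hypo else pools$hyper
    if (nrow(pool) == 0L) stop("empirical pool for group ", group, " is empty")
    pool[sample.int(nrow(pool), n, replace = TRUE), , drop = FALSE]
  } else {
    m <- if (group == 1L) pools$hypo_means else pools$hyper_means
    s <- pools$concentration
    out <- matrix(NA_real_, n, 2)
    todo <- seq_len(n)
    for (iter in 1:1000) {
      k <- length(todo)
      if (k == 0L) break
      p1 <- rbeta(k, m[1] * s, (1 - m[1]) * s)
      p2 <- rbeta(k, m[2] * s, (1 - m[2]) * s)
      ok <- if (group == 1L) (p1 - p2) < -gamma else (p1 - p2) > gamma
      out[todo[ok], ] <- cbind(p1[ok], p2[ok])
      todo <- todo[!ok]
    }
    if (length(todo) > 0L)
      stop("parametric pool cannot satisfy the gamma rule for group ", group,
           " (means too close for gamma = ", gamma, ")")
    out
  }
}

#' Draw true methylation proportions
#'
#' For each locus, draws the pair of true proportions `(p_case,
#' p_control)` from its truth group's pool: equal-group loci share a
#' single proportion; directional loci get ordered pairs satisfying the
#' gamma rule.  With the subject effect on, per-replicate proportions are
#' additionally drawn from a Beta with mean equal to the locus proportion
#' and the design's subject concentration.
#'
#' @param design a [simulation_design].
#' @param labels integer truth labels from [draw_truth_labels].
#' @return a list with `p_case`, `p_control` (per-locus), and, when the
#'   subject effect is on, matrices `p_case_rep`, `p_control_rep`
#'   (loci x replicates).
#' @export
draw_true_proportions <- function(design, labels) {
  L <- design$n_loci
  if (length(labels) != L) stop("labels length must equal n_loci")
  pools <- design$proportion_pools
  p1 <- numeric(L); p2 <- numeric(L)
  eq <- labels == 0L
  if (any(eq)) p1[eq] <- p2[eq] <- .draw_equal_pool(pools, sum(eq))
  for (g in 1:2) {
    sel <- labels == g
    if (any(sel)) {
      pr <- .draw_pair_pool(pools, g, sum(sel), design$gamma)
      p1[sel] <- pr[, 1]; p2[sel] <- pr[, 2]
    }
  }
  out <- list(p_case = p1, p_control = p2)
  if (design$subject_effect) {
    s <- design$subject_concentration
    draw_rep <- function(p, n_rep) {
      m <- matrix(rep(p, n_rep), ncol = n_rep)
      v <- rbeta(length(m), pmax(m, 1e-12) * s, pmax(1 - m, 1e-12) * s)
      v[m <= 0] <- 0; v[m >= 1] <- 1
      matrix(v, ncol = n_rep)
    }
    out$p_case_rep <- draw_rep(p1, design$n_case)
    out$p_control_rep <- draw_rep(p2, design$n_control)
  }
  out
}

.draw_coverage <- function(model, n) {
  cov <- switch(model$type,
    shifted_poisson = 1L + rpois(n, model$lambda),
    empirical = sample(model$values, n, replace = TRUE),
    stop("unknown coverage model type: ", model$type))
  pmax(as.integer(cov), 1L)
}

#' Simulate binomial methylation counts
#'
#' Draws per-replicate read coverages from the design's coverage model
#' and methylated counts as Binomial(C, p), with p the locus proportion
#' (or the per-replicate proportion when the subject effect is on).
#'
#' @param props proportions from [draw_true_proportions].
#' @param design a [simulation_design].
#' @return a `meth_counts` table.
#' @export
simulate_counts <- function(props, design) {
  L <- design$n_loci
  draw_block <- function(p_locus, p_rep, n_rep) {
    C <- matrix(.draw_coverage(design$coverage_model, L * n_rep), L, n_rep)
    P <- if (!is.null(p_rep)) p_rep else matrix(rep(p_locus, n_rep), ncol = n_rep)
    M <- matrix(rbinom(L * n_rep, as.vector(C), as.vector(P)), L, n_rep)
    list(C = C, M = M)
  }
  case <- draw_block(props$p_case, props$p_case_rep, design$n_case)
  ctrl <- draw_block(props$p_control, props$p_control_rep, design$n_control)
  meth_counts(chrom = rep("sim", L), pos = seq_len(L),
              meth_case = case$M, cov_case = case$C,
              meth_control = ctrl$M, cov_control = ctrl$C)
}

#' Simulate a full dataset with truth
#'
#' Seeds the RNG from the design, draws truth labels, true proportions
#' and binomial counts, and returns them together.
#'
#' @param design a [simulation_design].
#' @return a list with `counts` (a `meth_counts`), `truth` (labels
#'   0/1/2), and `proportions`.
#' @examples
#' sim <- simulate_dataset(simulation_design(n_loci = 100, seed = 7))
#' table(sim$truth)
#' @export
simulate_dataset <- function(design) {
  if (!is.null(design$seed)) set.seed(design$seed)
  truth <- draw_truth_labels(design)
  props <- draw_true_proportions(design, truth)
  counts <- simulate_counts(props, design)
  list(counts = counts, truth = truth, proportions = props, design = design)
}
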