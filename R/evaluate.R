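#' Evaluate three-way calls against simulation truth
#'
#' Computes the five benchmark measures.  Discoveries are loci called 1
#' or 2.  FDR is the fraction of truly equal loci among discoveries; the
#' mixed-directional FDR (mdFDR) additionally counts wrong-direction
#' calls (truly hypo called hyper and vice versa) as false discoveries.
#' TPR is the fraction of truly differential loci called differential in
#' either direction; TPR_hypo and TPR_hyper are per-direction and, by
#' default, require the call to match the true direction (set
#' `directional = FALSE` to count any differential call).  Ratios whose
#' denominator is zero are reported as `NA`, not 0.
#'
#' @param truth integer truth labels 0/1/2.
#' @param calls integer calls 0/1/2 of the same length.
#' @param directional must directional TPRs match the true direction?
#' @return a list with `fdr`, `mdfdr`, `tpr`, `tpr_hypo`, `tpr_hyper`
#'   and the 3 x 3 `confusion` table (rows truth, columns call).
#' @examples
#' evaluate_calls(c(0, 1, 2, 1), c(1, 1, 2, 2))
#' @export
evaluate_calls <- function(truth, calls, directional = TRUE) {
  truth <- as.integer(truth); calls <- as.integer(calls)
  if (length(truth) != length(calls)) stop("truth and calls lengths differ")
  if (any(is.na(truth)) || any(is.na(calls)) ||
      any(truth < 0L | truth > 2L) || any(calls < 0L | calls > 2L))
    stop("labels must be in {0, 1, 2}")
  confusion <- table(factor(truth, levels = 0:2),
                     factor(calls, levels = 0:2))
  dimnames(confusion) <- list(truth = c("equal", "hypo", "hyper"),
                              call = c("equal", "hypo", "hyper"))
  disc <- calls != 0L
  n_disc <- sum(disc)
  ratio <- function(num, den) if (den == 0) NA_real_ else num / den
  fdr <- ratio(sum(disc & truth == 0L), n_disc)
  mdfdr <- ratio(sum(disc & (truth == 0L | truth != calls)), n_disc)
  tpr <- ratio(sum(truth != 0L & disc), sum(truth != 0L))
  hit <- function(g) if (directional) calls == g else disc
  tpr_hypo <- ratio(sum(truth == 1L & hit(1L)), sum(truth == 1L))
  tpr_hyper <- ratio(sum(truth == 2L & hit(2L)), sum(truth == 2L))
  list(fdr = fdr, mdfdr = mdfdr, tpr = tpr,
       tpr_hypo = tpr_hypo, tpr_hyper = tpr_hyper,
       confusion = confusion)
}

#' Benchmark the Bayesian caller against the frequentist baselines
#'
#' Simulates `n_reps` datasets from a design, runs each requested method,
#' and averages the five evaluation measures over replicates.  With
#' `fdr_matching = TRUE`, the realized FDR of the Bayesian caller
#' (averaged over replicates) is used as the nominal q-value level for
#' the baselines, so power is compared at matched false discovery rates;
#' otherwise `nominal_fdr` is used.
#'
#' @param design a [simulation_design].
#' @param n_reps number of replicate datasets.
#' @param methods subset of `"bayes"`, `"ztest"`, `"logistic"`.
#' @param fdr_matching match baseline FDR to the realized Bayesian FDR?
#' @param nominal_fdr fallback q-value level.
#' @param n_sweeps,burn_in_fraction sampler settings for the Bayesian
#'   caller.
#' @param seed integer seed driving all replicates.
#' @param directional passed to [evaluate_calls].
#' @return a list with `summary` (one row of averaged metrics per
#'   method), `per_rep` (per-method matrices of per-replicate metrics)
#'   and `matched_fdr_level`.
#' @export
run_benchmark <- function(design, n_reps = 10L,
                          methods = c("bayes", "ztest", "logistic"),
                          fdr_matching = TRUE, nominal_fdr = 0.05,
                          n_sweeps = 2000L, burn_in_fraction = 0.5,
                          seed = NULL, directional = TRUE) {
  known <- c("bayes", "ztest", "logistic")
  if (length(methods) < 1L || !all(methods %in% known))
    stop("unknown method name(s): ",
         paste(setdiff(methods, known), collapse = ", "))
  if (!is.null(seed)) set.seed(seed)
  rep_seeds <- sample.int(.Machine$integer.max - 1L, 2L * n_reps)

  sims <- vector("list", n_reps)
  for (r in seq_len(n_reps)) {
    d <- design; d$seed <- rep_seeds[r]
    sims[[r]] <- simulate_dataset(d)
  }

  metric_names <- c("fdr", "mdfdr", "tpr", "tpr_hypo", "tpr_hyper")
  per_rep <- lapply(setNames(methods, methods), function(m)
    matrix(NA_real_, n_reps, 5L, dimnames = list(NULL, metric_names)))

  if ("bayes" %in% methods) {
    for (r in seq_len(n_reps)) {
      cfg <- chain_config(n_sweeps = n_sweeps,
                          burn_in_fraction = burn_in_fraction,
                          seed = rep_seeds[n_reps + r])
      post <- run_chain(sims[[r]]$counts, config = cfg)
      ev <- evaluate_calls(sims[[r]]$truth, post$call, directional = directional)
      per_rep$bayes[r, ] <- unlist(ev[metric_names])
    }
  }
  level <- nominal_fdr
  if (fdr_matching) {
    if (!"bayes" %in% methods)
      stop("fdr_matching requires the Bayesian caller among the methods")
    realized <- per_rep$bayes[, "fdr"]
    if (all(is.na(realized))) {
      level <- nominal_fdr
    } else {
      level <- mean(realized, na.rm = TRUE)
    }
  }

  for (m in setdiff(methods, "bayes")) {
    for (r in seq_len(n_reps)) {
      res <- run_baseline(sims[[r]]$counts, method = m, fdr_level = level)
      ev <- evaluate_calls(sims[[r]]$truth, res$call, directional = directional)
      per_rep[[m]][r, ] <- unlist(ev[metric_names])
    }
  }

  summary <- do.call(rbind, lapply(methods, function(m) {
    data.frame(method = m,
               t(colMeans(per_rep[[m]], na.rm = TRUE)),
               stringsAsFactors = FALSE)
  }))
  list(summary = summary, per_rep = per_rep, matched_fdr_level = level)
}
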