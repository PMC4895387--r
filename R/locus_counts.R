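#' Per-locus read counts for one CpG
#'
#' Holds, for a single CpG locus, the read coverage and methylated-read
#' count of every replicate in the case and control conditions.
#'
#' @param coverage_case,meth_case integer vectors, one entry per case
#'   replicate: total reads and methylated reads.
#' @param coverage_control,meth_control same for the control replicates.
#' @return An object of class `locus_counts`.
#' @examples
#' locus_counts(c(10, 12), c(3, 5), c(9, 11), c(8, 10))
#' @export
locus_counts <- function(coverage_case, meth_case,
                         coverage_control, meth_control) {
  x <- list(coverage_case = as.numeric(coverage_case),
            meth_case = as.numeric(meth_case),
            coverage_control = as.numeric(coverage_control),
            meth_control = as.numeric(meth_control))
  if (length(x$coverage_case) < 1L || length(x$coverage_control) < 1L)
    stop("need at least one replicate per condition")
  if (length(x$meth_case) != length(x$coverage_case) ||
      length(x$meth_control) != length(x$coverage_control))
    stop("coverage and methylated-count vectors must have equal length")
  for (side in c("case", "control")) {
    C <- x[[paste0("coverage_", side)]]
    M <- x[[paste0("meth_", side)]]
    if (any(!is.finite(C)) || any(!is.finite(M)) || any(C < 0) || any(M < 0))
      stop("counts must be finite and non-negative")
    if (any(M > C)) stop("methylated count exceeds coverage")
  }
  structure(x, class = "locus_counts")
}

#' @export
print.locus_counts <- function(x, ...) {
  cat("case:    M =", paste(x$meth_case, collapse = ","),
      " C =", paste(x$coverage_case, collapse = ","), "\n")
  cat("control: M =", paste(x$meth_control, collapse = ","),
      " C =", paste(x$coverage_control, collapse = ","), "\n")
  invisible(x)
}

# Pooled sums used throughout: M/N totals per condition.
.locus_sums <- function(locus) {
  list(M1 = sum(locus$meth_case),
       N1 = sum(locus$coverage_case) - sum(locus$meth_case),
       M2 = sum(locus$meth_control),
       N2 = sum(locus$coverage_control) - sum(locus$meth_control))
}

# Sum of log binomial coefficients over all replicates of both conditions;
# identical across the three group hypotheses, so excluded from cached
# marginals by default.
.locus_log_coef <- function(locus) {
  sum(lchoose(locus$coverage_case, locus$meth_case)) +
    sum(lchoose(locus$coverage_control, locus$meth_control))
}

#' Latent partition state
#'
#' The genome-wide membership vector I, with entries 0 (equal), 1 (hypo),
#' 2 (hyper), plus the derived group counts (l0, l1, l2).
#'
#' @param membership integer vector with entries in `{0, 1, 2}`.
#' @return An object of class `partition_state` with elements `membership`
#'   and `group_counts`.
#' @examples
#' partition_state(c(0, 0, 1, 2, 0))
#' @export
partition_state <- function(membership) {
  membership <- as.integer(membership)
  if (length(membership) < 1L) stop("membership must be non-empty")
  if (any(is.na(membership)) || any(membership < 0L | membership > 2L))
    stop("membership entries must be in {0, 1, 2}")
  counts <- tabulate(membership + 1L, nbins = 3L)
  structure(list(membership = membership,
                 group_counts = counts),
            class = "partition_state")
}
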