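#' Genome-wide methylation count table
#'
#' The package's central container: one row per CpG locus, with coverage
#' and methylated-read count matrices for the case and control replicates.
#'
#' @param chrom character vector of chromosome names.
#' @param pos 1-based integer positions.
#' @param meth_case,cov_case L x n1 matrices of methylated counts and
#'   coverages for the case replicates.
#' @param meth_control,cov_control L x n2 matrices for the control
#'   replicates.
#' @param strand optional character vector (`"+"`/`"-"`).
#' @param samples_case,samples_control optional sample identifiers.
#' @return An object of class `meth_counts`.
#' @export
meth_counts <- function(chrom, pos, meth_case, cov_case,
                        meth_control, cov_control, strand = NULL,
                        samples_case = NULL, samples_control = NULL) {
  meth_case <- as.matrix(meth_case); cov_case <- as.matrix(cov_case)
  meth_control <- as.matrix(meth_control); cov_control <- as.matrix(cov_control)
  L <- length(pos)
  if (length(chrom) != L) stop("chrom and pos lengths differ")
  dims <- vapply(list(meth_case, cov_case, meth_control, cov_control), nrow, 0L)
  if (any(dims != L)) stop("count matrices must have one row per locus")
  if (ncol(meth_case) != ncol(cov_case) || ncol(meth_control) != ncol(cov_control))
    stop("meth and coverage matrices must have matching replicate columns")
  if (ncol(cov_case) < 1L || ncol(cov_control) < 1L)
    stop("need at least one replicate per condition")
  if (any(meth_case > cov_case) || any(meth_control > cov_control))
    stop("methylated count exceeds coverage")
  if (any(meth_case < 0) || any(meth_control < 0) ||
      any(cov_case < 0) || any(cov_control < 0))
    stop("counts must be non-negative")
  key <- paste(chrom, pos, if (is.null(strand)) "" else strand)
  if (anyDuplicated(key)) stop("duplicate locus (chrom, pos, strand)")
  if (is.null(samples_case))
    samples_case <- paste0("case", seq_len(ncol(cov_case)))
  if (is.null(samples_control))
    samples_control <- paste0("control", seq_len(ncol(cov_control)))
  structure(list(chrom = as.character(chrom), pos = as.integer(pos),
                 strand = strand,
                 meth_case = meth_case, cov_case = cov_case,
                 meth_control = meth_control, cov_control = cov_control,
                 samples_case = samples_case,
                 samples_control = samples_control),
            class = "meth_counts")
}

#' @export
print.meth_counts <- function(x, ...) {
  cat("meth_counts:", length(x$pos), "loci,",
      ncol(x$cov_case), "case +", ncol(x$cov_control), "control replicates\n")
  invisible(x)
}

#' @export
length.meth_counts <- function(x) length(x$pos)

# single-locus view
.locus_at <- function(x, i) {
  locus_counts(x$cov_case[i, ], x$meth_case[i, ],
               x$cov_control[i, ], x$meth_control[i, ])
}

# row subset
.subset_loci <- function(x, keep) {
  meth_counts(x$chrom[keep], x$pos[keep],
              x$meth_case[keep, , drop = FALSE], x$cov_case[keep, , drop = FALSE],
              x$meth_control[keep, , drop = FALSE],
              x$cov_control[keep, , drop = FALSE],
              strand = if (is.null(x$strand)) NULL else x$strand[keep],
              samples_case = x$samples_case,
              samples_control = x$samples_control)
}
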