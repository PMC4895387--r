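#' Sample sheet
#'
#' Maps sample identifiers to conditions and, for per-sample input files,
#' to file paths.
#'
#' @param sample_id unique sample identifiers.
#' @param condition `"case"` or `"control"` per sample.
#' @param path optional per-sample file paths (bismark-coverage-style
#'   input).
#' @return a data.frame of class `sample_sheet`.
#' @export
sample_sheet <- function(sample_id, condition, path = NULL) {
  condition <- match.arg(condition, c("case", "control"), several.ok = TRUE)
  if (length(condition) != length(sample_id))
    stop("sample_id and condition lengths differ")
  if (anyDuplicated(sample_id)) stop("sample ids must be unique")
  if (!all(c("case", "control") %in% condition))
    stop("need at least one sample per condition")
  df <- data.frame(sample_id = as.character(sample_id),
                   condition = condition, stringsAsFactors = FALSE)
  if (!is.null(path)) df$path <- as.character(path)
  class(df) <- c("sample_sheet", "data.frame")
  df
}

#' Read a methylation count table
#'
#' Two input layouts are supported.  (i) A merged TSV with columns
#' `chrom`, `pos`, optional `strand`, then one `<sample>.meth` and
#' `<sample>.total` column pair per sample named in the sheet.  (ii)
#' Per-sample bismark-coverage-style files (columns: chromosome, start,
#' end, methylation percentage, count methylated, count unmethylated;
#' 1-based start), one path per sheet row, joined on position with loci
#' missing from a sample filled as coverage 0.
#'
#' @param x path to a merged TSV, or `NULL` when the sheet carries
#'   per-sample paths.
#' @param sheet a [sample_sheet].
#' @return a validated `meth_counts` table.
#' @export
read_counts <- function(x = NULL, sheet) {
  if (!inherits(sheet, "sample_sheet")) stop("sheet must be a sample_sheet")
  if (!is.null(x)) .read_merged(x, sheet) else .read_bismark_set(sheet)
}

.read_merged <- function(path, sheet) {
  if (!file.exists(path)) stop("file not found: ", path)
  dt <- data.table::fread(path, sep = "\t", header = TRUE,
                          data.table = FALSE)
  if (!all(c("chrom", "pos") %in% names(dt)))
    stop("merged table must have 'chrom' and 'pos' columns")
  strand <- if ("strand" %in% names(dt)) as.character(dt$strand) else NULL
  get_mat <- function(cond, suffix) {
    ids <- sheet$sample_id[sheet$condition == cond]
    cols <- paste0(ids, ".", suffix)
    missing <- setdiff(cols, names(dt))
    if (length(missing) > 0L)
      stop("missing column(s): ", paste(missing, collapse = ", "))
    as.matrix(dt[, cols, drop = FALSE])
  }
  M1 <- get_mat("case", "meth"); C1 <- get_mat("case", "total")
  M2 <- get_mat("control", "meth"); C2 <- get_mat("control", "total")
  bad <- which(rowSums(M1 > C1) + rowSums(M2 > C2) > 0)
  if (length(bad) > 0L)
    stop("methylated count exceeds coverage at data line ", bad[1],
         " (", dt$chrom[bad[1]], ":", dt$pos[bad[1]], ")")
  meth_counts(dt$chrom, dt$pos, M1, C1, M2, C2, strand = strand,
              samples_case = sheet$sample_id[sheet$condition == "case"],
              samples_control = sheet$sample_id[sheet$condition == "control"])
}

.read_bismark_one <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  dt <- data.table::fread(path, sep = "\t", header = FALSE,
                          data.table = FALSE)
  if (ncol(dt) != 6L)
    stop("bismark coverage file must have 6 columns: ", path)
  names(dt) <- c("chrom", "start", "end", "pct", "n_meth", "n_unmeth")
  if (any(dt$n_meth < 0 | dt$n_unmeth < 0))
    stop("negative counts in ", path, " at line ",
         which(dt$n_meth < 0 | dt$n_unmeth < 0)[1])
  data.frame(chrom = as.character(dt$chrom), pos = as.integer(dt$start),
             M = dt$n_meth, C = dt$n_meth + dt$n_unmeth,
             stringsAsFactors = FALSE)
}

.read_bismark_set <- function(sheet) {
  if (is.null(sheet$path)) stop("sheet must carry per-sample file paths")
  per <- lapply(sheet$path, .read_bismark_one)
  keys <- unique(do.call(rbind, lapply(per, function(d) d[c("chrom", "pos")])))
  keys <- keys[order(keys$chrom, keys$pos), , drop = FALSE]
  key_id <- paste(keys$chrom, keys$pos)
  L <- nrow(keys)
  fill <- function(d) {
    if (anyDuplicated(paste(d$chrom, d$pos)))
      stop("duplicate locus within one bismark file")
    idx <- match(paste(d$chrom, d$pos), key_id)
    M <- numeric(L); C <- numeric(L)
    M[idx] <- d$M; C[idx] <- d$C
    cbind(M = M, C = C)
  }
  mats <- lapply(per, fill)
  pick <- function(cond, col)
    do.call(cbind, lapply(mats[sheet$condition == cond], function(m) m[, col]))
  meth_counts(keys$chrom, keys$pos,
              pick("case", "M"), pick("case", "C"),
              pick("control", "M"), pick("control", "C"),
              samples_case = sheet$sample_id[sheet$condition == "case"],
              samples_control = sheet$sample_id[sheet$condition == "control"])
}

#' Write a methylation count table
#'
#' Writes the merged TSV layout accepted by [read_counts] (columns
#' `chrom`, `pos`, optional `strand`, then `<sample>.meth` /
#' `<sample>.total` pairs); reading it back reproduces the table
#' bit-exactly.
#'
#' @param x a `meth_counts` table.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_counts <- function(x, path) {
  stopifnot(inherits(x, "meth_counts"))
  df <- data.frame(chrom = x$chrom, pos = x$pos, stringsAsFactors = FALSE)
  if (!is.null(x$strand)) df$strand <- x$strand
  add <- function(df, ids, M, C) {
    for (j in seq_along(ids)) {
      df[[paste0(ids[j], ".meth")]] <- as.integer(M[, j])
      df[[paste0(ids[j], ".total")]] <- as.integer(C[, j])
    }
    df
  }
  df <- add(df, x$samples_case, x$meth_case, x$cov_case)
  df <- add(df, x$samples_control, x$meth_control, x$cov_control)
  data.table::fwrite(df, path, sep = "\t")
  invisible(path)
}

#' Remove uninformative loci before analysis
#'
#' Drops loci that carry no differential-methylation information: loci
#' where every sample with positive coverage is fully methylated
#' (M = C), loci where every such sample is unmethylated (M = 0), and
#' loci with zero pooled coverage in either condition (counted
#' separately).
#'
#' @param x a `meth_counts` table.
#' @return a list with `table` (the filtered `meth_counts`), `n_removed`,
#'   and the per-category counts `n_fully_methylated`,
#'   `n_non_methylated`, `n_zero_coverage`.
#' @export
filter_uninformative_loci <- function(x) {
  stopifnot(inherits(x, "meth_counts"))
  L <- length(x$pos)
  if (L == 0L)
    return(list(table = x, n_removed = 0L, n_fully_methylated = 0L,
                n_non_methylated = 0L, n_zero_coverage = 0L))
  C <- cbind(x$cov_case, x$cov_control)
  M <- cbind(x$meth_case, x$meth_control)
  zero_cov <- rowSums(x$cov_case) == 0 | rowSums(x$cov_control) == 0
  obs <- C > 0
  fully <- !zero_cov & rowSums(obs & (M < C)) == 0
  none <- !zero_cov & rowSums(obs & (M > 0)) == 0
  drop <- zero_cov | fully | none
  list(table = .subset_loci(x, !drop),
       n_removed = sum(drop),
       n_fully_methylated = sum(fully),
       n_non_methylated = sum(none),
       n_zero_coverage = sum(zero_cov))
}

#' One-step three-way methylation calling
#'
#' The package's main entry point: filters uninformative loci, runs the
#' Metropolis-Hastings sampler on the rest, and returns per-locus
#' posterior membership probabilities, the highest-posterior call, and
#' the pooled proportion difference estimate.
#'
#' @param x a `meth_counts` table.
#' @param hyper a [hyperparameters] object.
#' @param config a [chain_config].
#' @param filter apply [filter_uninformative_loci] first?
#' @param verbose log filter counts and the acceptance rate?
#' @return a data.frame with columns `chrom`, `pos`, `p_equal`, `p_hypo`,
#'   `p_hyper`, `call` (0/1/2), `d_hat`; the posterior summary and filter
#'   counts are attached as attributes `posterior` and `filter`.
#' @examples
#' sim <- simulate_dataset(simulation_design(n_loci = 50, seed = 3))
#' head(call_loci(sim$counts, config = chain_config(n_sweeps = 200, seed = 4)))
#' @export
call_loci <- function(x, hyper = hyperparameters(), config = chain_config(),
                      filter = TRUE, verbose = FALSE) {
  stopifnot(inherits(x, "meth_counts"))
  flt <- NULL
  if (filter) {
    flt <- filter_uninformative_loci(x)
    if (verbose)
      message("filtered ", flt$n_removed, " loci (",
              flt$n_fully_methylated, " fully methylated, ",
              flt$n_non_methylated, " unmethylated, ",
              flt$n_zero_coverage, " zero coverage); ",
              length(flt$table$pos), " retained")
    x <- flt$table
  }
  t0 <- proc.time()[["elapsed"]]
  post <- run_chain(x, hyper = hyper, config = config)
  if (verbose)
    message(sprintf("sampler: %d sweeps, acceptance rate %.3f, %.1f s",
                    config$n_sweeps, post$acceptance_rate,
                    proc.time()[["elapsed"]] - t0))
  d_hat <- rowSums(x$meth_case) / rowSums(x$cov_case) -
    rowSums(x$meth_control) / rowSums(x$cov_control)
  out <- data.frame(chrom = x$chrom, pos = x$pos,
                    p_equal = post$membership_probability[, 1],
                    p_hypo = post$membership_probability[, 2],
                    p_hyper = post$membership_probability[, 3],
                    call = post$call, d_hat = d_hat,
                    stringsAsFactors = FALSE)
  attr(out, "posterior") <- post
  attr(out, "filter") <- flt
  out
}
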