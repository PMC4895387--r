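#' Sampler configuration
#'
#' One sweep is L single-move Metropolis-Hastings proposals (L = number of
#' loci); one membership snapshot is recorded per post-burn-in sweep.
#'
#' @param n_sweeps number of recorded sweeps (default 2000).
#' @param burn_in_fraction fraction of sweeps discarded as burn-in, in
#'   `[0, 1)` (default 0.5).
#' @param seed integer seed for the sampler's RNG; `NULL` leaves the
#'   current RNG state untouched.
#' @param init_mode `"random-uniform"` (each locus starts in a uniformly
#'   random group), `"all-equal"`, or `"user"` (supply `init`).
#' @param init integer vector of starting labels when `init_mode = "user"`.
#' @return An object of class `chain_config`.
#' @export
chain_config <- function(n_sweeps = 2000L, burn_in_fraction = 0.5,
                         seed = NULL,
                         init_mode = c("random-uniform", "all-equal", "user"),
                         init = NULL) {
  init_mode <- match.arg(init_mode)
  n_sweeps <- as.integer(n_sweeps)
  if (is.na(n_sweeps) || n_sweeps < 1L) stop("n_sweeps must be a positive integer")
  if (!is.numeric(burn_in_fraction) || burn_in_fraction < 0 || burn_in_fraction >= 1)
    stop("burn_in_fraction must be in [0, 1)")
  n_burn <- floor(n_sweeps * burn_in_fraction)
  if (n_sweeps - n_burn < 1L) stop("post-burn-in sample count must be >= 1")
  if (init_mode == "user" && is.null(init)) stop("init_mode 'user' needs init")
  structure(list(n_sweeps = n_sweeps, burn_in_fraction = burn_in_fraction,
                 n_burn = as.integer(n_burn), seed = seed,
                 init_mode = init_mode, init = init),
            class = "chain_config")
}

#' Propose a single Metropolis-Hastings move
#'
#' Draws one move from the sampler's proposal kernel: with probability 1/2
#' each, a relabel move (pick a non-empty group uniformly, a locus in it
#' uniformly, and one of the two alternative labels uniformly) or an
#' exchange move (pick an unordered pair of distinct non-empty groups
#' uniformly, one locus from each uniformly, and swap their labels).  When
#' fewer than two groups are non-empty the relabel move is forced.
#' Returns the move together with the exact log Hastings transition ratio
#' `log p(new -> old) - log p(old -> new)` under these selection rules.
#'
#' This is a plain-R statement of the kernel; [run_chain] executes the
#' same kernel in compiled code.  Uses R's RNG.
#'
#' @param state a [partition_state].
#' @return a list with elements `kind` (`"relabel"` or `"exchange"`),
#'   `loci`, `old_labels`, `new_labels`, `log_transition_ratio`.
#' @export
propose_move <- function(state) {
  if (!inherits(state, "partition_state")) state <- partition_state(state)
  l <- state$group_counts
  memb <- state$membership
  nonempty <- which(l > 0L) - 1L   # labels 0..2, ascending
  G <- length(nonempty)
  if (G == 0L) stop("empty partition state")

  do_exchange <- FALSE
  if (G >= 2L) do_exchange <- runif(1) < 0.5

  if (!do_exchange) {
    a <- nonempty[floor(runif(1) * G) + 1]
    in_a <- which(memb == a)
    i <- in_a[floor(runif(1) * length(in_a)) + 1]
    alts <- setdiff(0:2, a)
    b <- alts[floor(runif(1) * 2) + 1]
    Gnew <- G - (l[a + 1L] == 1L) + (l[b + 1L] == 0L)
    mf <- if (G >= 2L) 0.5 else 1
    mr <- if (Gnew >= 2L) 0.5 else 1
    ltr <- log(mr) - log(mf) + log(G) - log(Gnew) +
      log(l[a + 1L]) - log(l[b + 1L] + 1)
    list(kind = "relabel", loci = i, old_labels = a, new_labels = b,
         log_transition_ratio = ltr)
  } else {
    pairs <- utils::combn(nonempty, 2L)
    p <- floor(runif(1) * ncol(pairs)) + 1
    a <- pairs[1L, p]; b <- pairs[2L, p]
    in_a <- which(memb == a); in_b <- which(memb == b)
    i <- in_a[floor(runif(1) * length(in_a)) + 1]
    j <- in_b[floor(runif(1) * length(in_b)) + 1]
    list(kind = "exchange", loci = c(i, j), old_labels = c(a, b),
         new_labels = c(b, a), log_transition_ratio = 0)
  }
}

#' Metropolis-Hastings acceptance probability
#'
#' `min(1, exp(log_post_new - log_post_old + log_transition_ratio))`.
#'
#' @param log_post_new,log_post_old unnormalised log posterior of the
#'   proposed and current states.
#' @param log_transition_ratio log Hastings ratio
#'   `log p(new -> old) - log p(old -> new)`.
#' @return a probability in `[0, 1]`.
#' @export
acceptance_probability <- function(log_post_new, log_post_old,
                                   log_transition_ratio = 0) {
  v <- log_post_new - log_post_old + log_transition_ratio
  if (is.na(v)) stop("NaN in acceptance probability inputs")
  min(1, exp(v))
}

#' Sample the posterior of the membership vector
#'
#' Precomputes the per-locus collapsed log marginals, runs `n_sweeps`
#' sweeps of L Metropolis-Hastings proposals each (relabel and exchange
#' kernels, see [propose_move]), and summarises the post-burn-in sweeps
#' into per-locus membership frequencies and a highest-posterior-
#' probability call per locus.  With a fixed seed, configuration and data
#' the output is bit-identical across runs.
#'
#' @param data a `meth_counts` table or list of [locus_counts].
#' @param hyper a [hyperparameters] object.
#' @param config a [chain_config].
#' @param track_state_counts record the visit count of every one of the
#'   `3^L` states after each post-burn-in proposal (diagnostics; L <= 12).
#' @return An object of class `methpart_posterior`: a list with
#'   `membership_probability` (L x 3 matrix, rows sum to 1),
#'   `membership_counts` (integer snapshot counts over a common
#'   denominator `n_samples_used`), `call` (per-locus label in 0/1/2),
#'   `acceptance_rate`, `n_samples_used`, and optionally `state_counts`.
#' @examples
#' set.seed(1)
#' sim <- simulate_dataset(simulation_design(n_loci = 20, seed = 1))
#' post <- run_chain(sim$counts, config = chain_config(n_sweeps = 200, seed = 2))
#' table(post$call)
#' @export
run_chain <- function(data, hyper = hyperparameters(),
                      config = chain_config(), track_state_counts = FALSE) {
  hyper <- .as_hyper(hyper)
  if (!inherits(config, "chain_config")) stop("config must be a chain_config")
  cache <- compute_log_marginals(data, hyper)
  L <- nrow(cache)
  if (L < 1L) stop("no loci to sample")

  if (!is.null(config$seed)) set.seed(config$seed)
  init <- switch(config$init_mode,
    "random-uniform" = sample(0:2, L, replace = TRUE),
    "all-equal" = rep(0L, L),
    "user" = {
      ini <- as.integer(config$init)
      if (length(ini) != L || any(ini < 0L | ini > 2L))
        stop("user init must be length-L labels in {0,1,2}")
      ini
    })

  res <- mh_chain_cpp(cache, c(hyper$k0, hyper$k1, hyper$k2),
                      as.integer(init),
                      config$n_sweeps, config$n_burn, L,
                      isTRUE(track_state_counts))
  n_used <- config$n_sweeps - config$n_burn
  probs <- res$freq / n_used
  colnames(probs) <- c("equal", "hypo", "hyper")
  out <- list(membership_probability = probs,
              membership_counts = res$freq,
              call = classify_counts(res$freq),
              acceptance_rate = res$accepted / res$proposed,
              n_samples_used = n_used)
  if (track_state_counts) out$state_counts <- res$state_counts
  structure(out, class = "methpart_posterior")
}

#' @export
print.methpart_posterior <- function(x, ...) {
  cat("Posterior membership summary over", nrow(x$membership_probability),
      "loci (", x$n_samples_used, "post-burn-in sweeps )\n")
  cat("calls:", paste(sprintf("%s=%d", c("equal", "hypo", "hyper"),
                              tabulate(x$call + 1L, 3L)), collapse = " "), "\n")
  cat(sprintf("acceptance rate: %.3f\n", x$acceptance_rate))
  invisible(x)
}

# argmax over integer snapshot counts so ties are exact
classify_counts <- function(counts) {
  apply(counts, 1L, function(r) {
    m <- max(r)
    winners <- which(r == m) - 1L
    if (length(winners) > 1L) 0L else winners
  })
}

#' Three-way call from a posterior summary
#'
#' Each locus is called as the membership group with the highest posterior
#' probability.  Exact ties involving the equal group resolve to equal,
#' and a hypo-hyper tie also resolves to equal: no directional call is
#' made without a strict winner.
#'
#' @param summary a `methpart_posterior` from [run_chain], or an L x 3
#'   probability matrix.
#' @return integer vector of per-locus calls (0 equal, 1 hypo, 2 hyper).
#' @export
classify_loci <- function(summary) {
  if (inherits(summary, "methpart_posterior"))
    return(classify_counts(summary$membership_counts))
  classify_counts(as.matrix(summary))
}
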