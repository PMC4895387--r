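#' Prior hyperparameters
#'
#' Bundles the Beta prior shapes for the three methylation groups and the
#' Dirichlet parameters for the group probabilities.  `alpha1`/`beta1`
#' parameterise the shared Beta prior of the equal-methylated group,
#' `alpha2`/`beta2` the ordered product-Beta prior of the hypo-methylated
#' group, `alpha3`/`beta3` that of the hyper-methylated group, and
#' `k0`/`k1`/`k2` the Dirichlet prior on the partition probabilities.
#' All nine default to 1 (flat priors), the model's non-informative choice.
#'
#' @param alpha1,beta1 Beta shapes, equal group. Positive.
#' @param alpha2,beta2 Beta shapes, hypo group. Positive.
#' @param alpha3,beta3 Beta shapes, hyper group. Positive.
#' @param k0,k1,k2 Dirichlet parameters for the equal/hypo/hyper partition
#'   probabilities. Positive.
#' @return An object of class `methpart_hyper` (a named list).
#' @examples
#' hyperparameters()
#' @export
hyperparameters <- function(alpha1 = 1, beta1 = 1,
                            alpha2 = 1, beta2 = 1,
                            alpha3 = 1, beta3 = 1,
                            k0 = 1, k1 = 1, k2 = 1) {
  h <- list(alpha1 = alpha1, beta1 = beta1,
            alpha2 = alpha2, beta2 = beta2,
            alpha3 = alpha3, beta3 = beta3,
            k0 = k0, k1 = k1, k2 = k2)
  for (nm in names(h)) {
    v <- h[[nm]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v <= 0)
      stop("hyperparameter '", nm, "' must be a single positive number")
  }
  structure(h, class = "methpart_hyper")
}

.as_hyper <- function(hyper) {
  if (inherits(hyper, "methpart_hyper")) return(hyper)
  do.call(hyperparameters, as.list(hyper))
}

#' @export
print.methpart_hyper <- function(x, ...) {
  cat("Beta priors: equal (", x$alpha1, ",", x$beta1,
      ") hypo (", x$alpha2, ",", x$beta2,
      ") hyper (", x$alpha3, ",", x$beta3, ")\n")
  cat("Dirichlet partition prior: (", x$k0, ",", x$k1, ",", x$k2, ")\n")
  invisible(x)
}
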