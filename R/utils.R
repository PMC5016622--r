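# Draw n uniforms from a dedicated stream without disturbing the caller's
# RNG state; every stochastic component of the package funnels through an
# explicit seed via this helper (the C++ ray tracer keeps its own streams).
rng_stream <- function(seed, n, rnorm_sd = NULL) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  if (is.null(rnorm_sd)) stats::runif(n) else stats::rnorm(n, sd = rnorm_sd)
}

#' Goodness of fit between measured and estimated series
#'
#' Coefficient of determination `R^2 = 1 - SS_res/SS_tot` with the measured
#' series as reference, and root mean square error in the series' units.
#' Pairs with missing values are dropped.
#'
#' @param measured,estimated Numeric vectors of equal length.
#' @return A list with `r_squared`, `rmse` and `n` (pairs used).
#' @export
#' @examples
#' goodness_of_fit(c(1, 2, 3), c(1, 2, 4))
goodness_of_fit <- function(measured, estimated) {
  stopifnot(length(measured) == length(estimated))
  ok <- is.finite(measured) & is.finite(estimated)
  m <- measured[ok]; e <- estimated[ok]
  ss_res <- sum((m - e)^2)
  ss_tot <- sum((m - mean(m))^2)
  list(r_squared = 1 - ss_res / ss_tot,
       rmse = sqrt(mean((m - e)^2)),
       n = sum(ok))
}
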