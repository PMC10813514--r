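#' Round half away from zero
#'
#' Base R's `round()` rounds half to even; detection-limit reporting uses the
#' conventional half-up rule instead.
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return rounded numeric vector.
#' @keywords internal
round_half_up <- function(x, digits = 0) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

# Log-normal draws parameterised by arithmetic mean and coefficient of
# variation on the natural scale; cv = 0 degenerates to the mean exactly.
rlnorm_mean_cv <- function(n, mean, cv) {
  stopifnot(all(mean > 0), cv >= 0)
  if (cv == 0) {
    return(rep_len(mean, n))
  }
  sdlog <- sqrt(log(1 + cv^2))
  stats::rlnorm(n, meanlog = log(mean) - sdlog^2 / 2, sdlog = sdlog)
}

# Multiplicative log-normal noise factors with unit mean and given CV.
lnorm_noise <- function(n, cv) rlnorm_mean_cv(n, 1, cv)

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_qmp <- function(..., call. = FALSE) stop(..., call. = call.)
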