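#' @keywords internal
"_PACKAGE"

# classed condition helpers so callers can distinguish failure modes
cc_stop <- function(msg, class, call = sys.call(-1)) {
  stop(errorCondition(msg, class = c(class, "cetacond_error"),
                      call = call))
}

cc_warn <- function(msg, class) {
  warning(warningCondition(msg, class = c(class, "cetacond_warning")))
}

#' Second-order Akaike information criterion
#'
#' AICc adds the small-sample correction `2k(k+1)/(n-k-1)` to the ordinary
#' AIC, where `k` counts all estimated parameters (including dispersion and
#' random-effect variances) and `n` is the number of observations.
#'
#' @param fit A fitted model with `logLik()` and `nobs()` methods.
#' @return The AICc value (numeric scalar); `Inf` when `n <= k + 1`.
#' @export
aicc <- function(fit) {
  ll <- stats::logLik(fit)
  k <- attr(ll, "df")
  n <- stats::nobs(fit)
  if (n - k - 1 <= 0) return(Inf)
  stats::AIC(fit) + 2 * k * (k + 1) / (n - k - 1)
}

# inverse-CDF truncated normal draw; deterministic under the active RNG state
rtruncnorm <- function(n, mean, sd, lower = -Inf, upper = Inf) {
  plo <- stats::pnorm(lower, mean, sd)
  phi <- stats::pnorm(upper, mean, sd)
  stats::qnorm(stats::runif(n, plo, phi), mean, sd)
}

# md5 of a canonical JSON rendering; used in run manifests
config_hash <- function(config) {
  tf <- tempfile(fileext = ".json")
  on.exit(unlink(tf))
  writeLines(jsonlite::toJSON(config, auto_unbox = TRUE, digits = NA,
                              force = TRUE), tf)
  unname(tools::md5sum(tf))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
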