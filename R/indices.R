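# The ten morphometric condition indices and the allometric fits behind
# them. Simple indices are direct ratios of measured quantities; the
# model-based ones (relative condition, residual index, scaled mass index)
# come from log-scale OLS and standardized major axis fits of mass on
# length, and the nonlinear mass-length model mass = delta + alpha*L^beta
# supplies the scaling exponent used by the size-independence diagnostic.

#' Names of the ten condition indices
#' @return Character vector of index names in reporting order.
#' @export
index_names <- function() {
  c("ventral_blubber", "blubber_over_girth", "blubber_over_length",
    "girth_over_length", "mass_over_length", "fulton_K", "quetelet",
    "relative_condition", "residual_index", "scaled_mass")
}

# formula-based indices: fields needed and the ratio computed
SIMPLE_INDEX_DEFS <- list(
  ventral_blubber     = list(fields = "blubber_ventral_mm",
                             fun = function(d) d$blubber_ventral_mm),
  blubber_over_girth  = list(fields = c("blubber_ventral_mm", "girth_cm"),
                             fun = function(d) d$blubber_ventral_mm / d$girth_cm),
  blubber_over_length = list(fields = c("blubber_ventral_mm", "length_cm"),
                             fun = function(d) d$blubber_ventral_mm / d$length_cm),
  girth_over_length   = list(fields = c("girth_cm", "length_cm"),
                             fun = function(d) d$girth_cm / d$length_cm),
  mass_over_length    = list(fields = c("mass_kg", "length_cm"),
                             fun = function(d) d$mass_kg / d$length_cm),
  fulton_K            = list(fields = c("mass_kg", "length_cm"),
                             fun = function(d) d$mass_kg / d$length_cm^3),
  quetelet            = list(fields = c("mass_kg", "length_cm"),
                             fun = function(d) d$mass_kg / d$length_cm^2)
)

#' Compute one of the formula-based condition indices
#'
#' The simple indices are direct ratios: full ventral blubber depth (mm),
#' blubber/girth (mm/cm), blubber/length (mm/cm), girth/length, mass/length
#' (kg/cm), Fulton's K = mass/length^3 (kg/cm^3) and Quetelet's index
#' (BMI) = mass/length^2 (kg/cm^2).
#'
#' @param records One or more morphometric records (data frame rows).
#' @param which Index name; one of the first seven of [index_names()].
#' @return Numeric vector of index values, one per record.
#' @export
compute_simple_index <- function(records, which) {
  def <- SIMPLE_INDEX_DEFS[[which]]
  if (is.null(def))
    cc_stop(paste0("unknown simple index: ", which), "cetacond_bad_index")
  for (f in def$fields) {
    if (is.null(records[[f]]) || anyNA(records[[f]]))
      cc_stop(paste0("index '", which, "' requires field '", f,
                     "' but it is missing"), "cetacond_missing_field")
    if (f %in% c("length_cm", "girth_cm") && any(records[[f]] == 0))
      cc_stop(paste0("zero ", f, " in denominator of '", which, "'"),
              "cetacond_domain_error")
  }
  def$fun(records)
}

#' Log-scale OLS allometry of mass on length
#'
#' Fits `ln M = ln a + b ln L` by ordinary least squares. The residuals of
#' this fit are the residual condition index, and the back-transformed
#' curve `a L^b` predicts the mass used by relative condition.
#'
#' @param records Morphometric records with positive `mass_kg`, `length_cm`.
#' @return An object of class `log_allometry`: list with `a`, `b`,
#'   `residuals`, `fitted_mass` (kg, back-transformed) and the underlying
#'   `lm` fit.
#' @export
fit_log_allometry <- function(records) {
  ok <- !is.na(records$mass_kg) & !is.na(records$length_cm) &
    records$mass_kg > 0 & records$length_cm > 0
  if (sum(ok) < 3)
    cc_stop("need at least 3 records with positive mass and length",
            "cetacond_insufficient_data")
  d <- records[ok, ]
  if (stats::sd(d$length_cm) == 0)
    cc_stop("all lengths identical: log-log fit is singular",
            "cetacond_singular_fit")
  fit <- stats::lm(log(mass_kg) ~ log(length_cm), data = d)
  res <- rep(NA_real_, nrow(records))
  res[ok] <- stats::residuals(fit)
  fitted_mass <- rep(NA_real_, nrow(records))
  fitted_mass[ok] <- exp(stats::fitted(fit))
  structure(list(a = exp(unname(stats::coef(fit)[1])),
                 b = unname(stats::coef(fit)[2]),
                 residuals = res, fitted_mass = fitted_mass,
                 n_used = sum(ok), lm_fit = fit),
            class = "log_allometry")
}

#' Relative condition index Kn
#'
#' `Kn_i = M_i / M*_i`, observed mass over the mass predicted from the
#' length-mass power law `M* = a L^b` fitted on the same records (log-scale
#' OLS by default, so the geometric mean of Kn over the fitting set is 1).
#'
#' @param records Morphometric records.
#' @param fit Optional [fit_log_allometry()] result to reuse.
#' @return Numeric vector of Kn values (dimensionless).
#' @export
relative_condition <- function(records, fit = NULL) {
  fit <- fit %||% fit_log_allometry(records)
  records$mass_kg / fit$fitted_mass
}

#' Residual condition index
#'
#' Residuals (log-kg) of the OLS regression of mass on length after log
#' transformation; mean zero over the fitting set by construction.
#'
#' @inheritParams relative_condition
#' @return Numeric vector of residuals.
#' @export
residual_index <- function(records, fit = NULL) {
  fit <- fit %||% fit_log_allometry(records)
  fit$residuals
}

#' Standardized major axis fit of ln M on ln L
#'
#' The SMA slope is the OLS slope divided by the Pearson correlation of the
#' log-transformed variables, `b_SMA = b_OLS / r`, so `|b_SMA| >= |b_OLS|`.
#'
#' @param records Morphometric records.
#' @return An object of class `sma_fit`: list with `b_ols`, `r`, `b_sma`
#'   and `l0` (arithmetic mean length, cm).
#' @export
sma_fit <- function(records) {
  la <- fit_log_allometry(records)
  d <- records[!is.na(records$mass_kg) & !is.na(records$length_cm), ]
  r <- stats::cor(log(d$mass_kg), log(d$length_cm))
  if (!is.finite(r) || r == 0)
    cc_stop("correlation of ln M and ln L is zero: SMA slope undefined",
            "cetacond_undefined_sma")
  structure(list(b_ols = la$b, r = r, b_sma = la$b / r,
                 l0 = mean(d$length_cm)),
            class = "sma_fit")
}

#' Scaled mass index
#'
#' `M^_i = M_i (L_0 / L_i)^{b_SMA}`: each animal's mass standardized to the
#' reference length `L_0` (arithmetic mean length of the study population)
#' along the SMA scaling line.
#'
#' @param records Morphometric records.
#' @param l0 Optional reference length (cm) overriding the in-sample mean,
#'   for comparability across datasets.
#' @return Numeric vector of scaled masses (kg), with the `sma_fit` object
#'   attached as attribute `"sma"`.
#' @export
scaled_mass_index <- function(records, l0 = NULL) {
  sf <- sma_fit(records)
  l0 <- l0 %||% sf$l0
  out <- records$mass_kg * (l0 / records$length_cm)^sf$b_sma
  attr(out, "sma") <- sf
  out
}

#' Nonlinear mass-length allometry
#'
#' Fits `mass = delta + alpha * length^beta` by nonlinear least squares
#' (Levenberg-Marquardt), with starting values taken deterministically from
#' the log-scale OLS fit (`delta = 0`, `alpha = a`, `beta = b`).
#' Confidence intervals are asymptotic (Wald) by default; a seeded
#' nonparametric bootstrap is available.
#'
#' @param records Morphometric records (>= 10 with positive mass/length).
#' @param ci_level Confidence level for the parameter intervals.
#' @param ci_method `"wald"` (asymptotic) or `"bootstrap"` (percentile).
#' @param B Bootstrap replicates when `ci_method = "bootstrap"`.
#' @param seed Seed for the bootstrap resampling.
#' @return An object of class `allometric_fit`: list with `delta`, `alpha`,
#'   `beta`, `ci` (3 x 2 matrix), `se`, `converged`, `n_used` and the
#'   underlying `nls` object.
#' @export
fit_nonlinear_allometry <- function(records, ci_level = 0.95,
                                    ci_method = c("wald", "bootstrap"),
                                    B = 499, seed = 1) {
  ci_method <- match.arg(ci_method)
  ok <- !is.na(records$mass_kg) & !is.na(records$length_cm) &
    records$mass_kg > 0 & records$length_cm > 0
  if (sum(ok) < 10)
    cc_stop("need at least 10 records for the nonlinear allometry",
            "cetacond_insufficient_data")
  d <- records[ok, ]
  la <- fit_log_allometry(d)
  # fit with lengths scaled by their geometric mean: with raw lengths the
  # Jacobian columns L^beta and alpha L^beta ln L are nearly collinear
  # (ln L varies little over the biological range), which makes the raw
  # parameterization numerically singular near the optimum
  l0 <- exp(mean(log(d$length_cm)))
  d$length_scaled <- d$length_cm / l0
  start <- list(delta = 0, alpha0 = la$a * l0^la$b, beta = la$b)
  fit_scaled <- function(dd, start) tryCatch(
    minpack.lm::nlsLM(mass_kg ~ delta + alpha0 * length_scaled^beta,
                      data = dd, start = start,
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)
  fit <- fit_scaled(d, start)
  # a start sitting exactly on a zero-residual solution trips the
  # singular-gradient guard; deterministic nudges recover it
  if (is.null(fit))
    for (nudge in list(c(1.10, 0.95), c(0.90, 1.05), c(1.25, 0.90))) {
      fit <- fit_scaled(d, list(delta = -0.02 * mean(d$mass_kg),
                                alpha0 = start$alpha0 * nudge[1],
                                beta = start$beta * nudge[2]))
      if (!is.null(fit)) break
    }
  if (is.null(fit))
    return(structure(list(delta = NA_real_, alpha = NA_real_,
                          beta = NA_real_, ci = NULL, se = NULL,
                          converged = FALSE, n_used = nrow(d),
                          nls_fit = NULL),
                     class = "allometric_fit"))
  back <- function(est) c(delta = unname(est["delta"]),
                          alpha = unname(est["alpha0"]) / l0^est[["beta"]],
                          beta = unname(est["beta"]))
  est <- back(stats::coef(fit))
  sm <- summary(fit)$coefficients
  se_scaled <- sm[, "Std. Error"]
  V <- stats::vcov(fit)
  # delta-method SE for alpha = alpha0 / l0^beta
  g <- c(l0^(-est[["beta"]]), -est[["alpha"]] * log(l0))
  se <- c(delta = unname(se_scaled["delta"]),
          alpha = sqrt(drop(t(g) %*% V[c("alpha0", "beta"),
                                       c("alpha0", "beta")] %*% g)),
          beta = unname(se_scaled["beta"]))
  if (ci_method == "wald") {
    tq <- stats::qt(1 - (1 - ci_level) / 2, stats::df.residual(fit))
    ci <- cbind(low = est - tq * se, high = est + tq * se)
  } else {
    set.seed(seed)
    boots <- replicate(B, {
      idx <- sample.int(nrow(d), replace = TRUE)
      f <- fit_scaled(d[idx, ], as.list(stats::coef(fit)))
      if (is.null(f)) rep(NA_real_, 3) else back(stats::coef(f))
    })
    probs <- c((1 - ci_level) / 2, 1 - (1 - ci_level) / 2)
    qs <- apply(boots, 1, stats::quantile, probs = probs, na.rm = TRUE)
    ci <- cbind(low = qs[1, ], high = qs[2, ])
  }
  rownames(ci) <- c("delta", "alpha", "beta")
  structure(list(delta = est[["delta"]], alpha = est[["alpha"]],
                 beta = est[["beta"]], ci = ci, se = se,
                 converged = TRUE, n_used = nrow(d), nls_fit = fit),
            class = "allometric_fit")
}

#' Size-independence diagnostic for a condition index
#'
#' Pearson correlation (with two-sided test) of an index against body
#' length. An index suitable for comparing animals of different sizes
#' should be close to uncorrelated with length; mass/length^k with k near
#' the fitted allometric exponent achieves this, whereas mass/length does
#' not when the exponent exceeds 1.
#'
#' @param index_values Numeric vector of index values.
#' @param lengths Numeric vector of body lengths (same order).
#' @return List with `r` and `p_value`.
#' @export
size_independence <- function(index_values, lengths) {
  ok <- !is.na(index_values) & !is.na(lengths)
  if (sum(ok) < 3)
    cc_stop("need at least 3 paired observations",
            "cetacond_insufficient_data")
  x <- index_values[ok]; y <- lengths[ok]
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    cc_stop("zero variance: correlation undefined",
            "cetacond_undefined_correlation")
  ct <- stats::cor.test(x, y)
  list(r = unname(ct$estimate), p_value = ct$p.value)
}

#' Per-animal table of all ten condition indices
#'
#' Simple indices are computed per record, skipping (with a logged count)
#' records missing the needed fields; the model-based indices are fitted on
#' the records with complete mass and length.
#'
#' @param records Morphometric records.
#' @return Data frame with `id` plus one column per index (see
#'   [index_names()]). Attributes: `"n_excluded"` (named count of records
#'   excluded per index), `"log_allometry"` and `"sma"` (the fits used).
#' @export
condition_indices <- function(records) {
  out <- data.frame(id = records$id, stringsAsFactors = FALSE)
  n_excluded <- integer(0)
  for (ix in names(SIMPLE_INDEX_DEFS)) {
    def <- SIMPLE_INDEX_DEFS[[ix]]
    ok <- Reduce(`&`, lapply(def$fields, function(f) !is.na(records[[f]])))
    vals <- rep(NA_real_, nrow(records))
    if (any(ok)) vals[ok] <- compute_simple_index(records[ok, ], ix)
    out[[ix]] <- vals
    n_excluded[ix] <- sum(!ok)
  }
  la <- fit_log_allometry(records)
  out$relative_condition <- relative_condition(records, la)
  out$residual_index <- residual_index(records, la)
  smi <- scaled_mass_index(records)
  out$scaled_mass <- as.numeric(smi)
  n_excluded["relative_condition"] <- nrow(records) - la$n_used
  n_excluded["residual_index"] <- nrow(records) - la$n_used
  n_excluded["scaled_mass"] <- nrow(records) - la$n_used
  attr(out, "n_excluded") <- n_excluded
  attr(out, "log_allometry") <- la
  attr(out, "sma") <- attr(smi, "sma")
  out
}
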