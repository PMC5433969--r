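# Blubber cortisol chain: competitive ELISA quantification through a
# four-parameter logistic standard curve, correction to tissue
# concentration (ng/g), duplicate/plate CV quality gates, and gamma
# log-link models of concentration over body site, blubber layer and
# individual covariates.

#' Four-parameter logistic response curve
#'
#' `response = d + (a - d) / (1 + (x / c)^b)`. For a competitive assay the
#' curve is descending: `a` is the zero-dose response, `d` the response at
#' infinite concentration, `c` the inflection concentration (ng/ml) and `b`
#' the slope factor.
#'
#' @param params List or `fourpl` object with elements `a`, `d`, `c`, `b`.
#' @param x Concentrations (ng/ml).
#' @return Predicted responses.
#' @export
fourpl_response <- function(params, x) {
  with(params, d + (a - d) / (1 + (x / c)^b))
}

#' Fit a four-parameter logistic standard curve
#'
#' Least-squares fit of the 4PL model to standard-curve points by
#' Levenberg-Marquardt, with deterministic self-derived starting values
#' (asymptotes from the extreme standards, inflection from the standard
#' whose response is nearest the midpoint, slope 1).
#'
#' @param concentration Standard concentrations (ng/ml), including 0.
#' @param response Measured responses (e.g. optical densities).
#' @return Object of class `fourpl`: list with `a`, `d`, `c`, `b`,
#'   `fitted`, `residuals` and the `nls` fit. Warns (class
#'   `cetacond_nonmonotone`) if the standards are not monotone in
#'   concentration.
#' @export
fit_4pl <- function(concentration, response) {
  ok <- !is.na(concentration) & !is.na(response)
  concentration <- concentration[ok]; response <- response[ok]
  if (length(concentration) < 5 || !any(concentration == 0))
    cc_stop("need >= 5 standards spanning the range, including 0",
            "cetacond_insufficient_data")
  ord <- order(concentration)
  if (is.unsorted(response[ord]) && is.unsorted(rev(response[ord])))
    cc_warn("standards are not monotone in concentration; fitting anyway",
            "cetacond_nonmonotone")
  a0 <- response[which.min(concentration)]
  d0 <- response[which.max(concentration)]
  mid <- (a0 + d0) / 2
  pos <- concentration > 0
  c0 <- concentration[pos][which.min(abs(response[pos] - mid))]
  fit <- tryCatch(
    minpack.lm::nlsLM(response ~ d + (a - d) / (1 + (concentration / c)^b),
                      data = data.frame(concentration, response),
                      start = list(a = a0, d = d0, c = c0, b = 1),
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) cc_stop(paste0("4PL fit failed: ",
                                       conditionMessage(e)),
                                "cetacond_fit_failure"))
  est <- as.list(stats::coef(fit))
  structure(list(a = est$a, d = est$d, c = est$c, b = est$b,
                 fitted = stats::fitted(fit),
                 residuals = stats::residuals(fit), nls_fit = fit),
            class = "fourpl")
}

#' Invert a 4PL curve: response to concentration
#'
#' Closed-form inverse `x = c * ((a - y) / (y - d))^(1/b)`. Responses must
#' lie strictly between the asymptotes. Concentrations below the assay
#' sensitivity are flagged (and retained, not imputed).
#'
#' @param params A `fourpl` object (or list with `a`, `d`, `c`, `b`).
#' @param response Responses to invert.
#' @param lod Assay sensitivity (ng/ml) under which values are flagged.
#' @return List with `concentration` (ng/ml) and `below_lod` (logical).
#' @export
invert_4pl <- function(params, response, lod = 2.5) {
  lo <- min(params$a, params$d); hi <- max(params$a, params$d)
  if (any(response <= lo | response >= hi, na.rm = TRUE))
    cc_stop("response outside the open interval between the asymptotes",
            "cetacond_out_of_range")
  x <- with(params, c * ((a - response) / (response - d))^(1 / b))
  list(concentration = x, below_lod = x < lod)
}

#' Convert an assay concentration to tissue concentration
#'
#' `ng/g = ng/ml x resuspension volume (ml) / tissue mass (g) / extraction
#' efficiency`. The default volume corresponds to resuspension of the
#' extract in 500 ul of buffer.
#'
#' @param conc_ngml Assay concentration (ng/ml).
#' @param tissue_mass_g Subsample wet mass (g).
#' @param resuspension_volume_ml Extract resuspension volume (ml).
#' @param efficiency Extraction efficiency in (0, 1].
#' @return Tissue concentration (ng/g).
#' @export
to_tissue_concentration <- function(conc_ngml, tissue_mass_g,
                                    resuspension_volume_ml = 0.5,
                                    efficiency = 1) {
  if (any(tissue_mass_g <= 0))
    cc_stop("tissue mass must be positive", "cetacond_domain_error")
  if (any(efficiency <= 0 | efficiency > 1))
    cc_stop("efficiency must be in (0, 1]", "cetacond_domain_error")
  conc_ngml * resuspension_volume_ml / tissue_mass_g / efficiency
}

#' Intra- and inter-assay coefficients of variation
#'
#' Intra-assay CV: mean over duplicate pairs of `100 * sd / mean` within a
#' plate. Inter-assay CV: mean over control extracts of `100 * sd / mean`
#' of their per-plate mean concentrations across plates. Acceptance gates:
#' intra < 10%, inter < 20%.
#'
#' @param quantified Data frame with one row per replicate well: columns
#'   `plate_id`, `sample_id`, `role` (`"sample"` or `"control"`), and
#'   `concentration` (ng/ml).
#' @param intra_limit,inter_limit Acceptable mean percentage CVs.
#' @return List with `intra_cv`, `inter_cv` (percent, `NA` when not
#'   computable), `intra_pass`, `inter_pass`, `n_pairs`, `n_controls` and
#'   `n_excluded` (pairs with mean 0, dropped with a message).
#' @export
assay_cv <- function(quantified, intra_limit = 10, inter_limit = 20) {
  q <- quantified[quantified$role %in% c("sample", "control"), ]
  key <- interaction(q$plate_id, q$sample_id, drop = TRUE)
  pair_cv <- vapply(split(q$concentration, key), function(v) {
    if (length(v) < 2) return(NA_real_)
    m <- mean(v)
    if (m == 0) return(Inf)
    100 * stats::sd(v) / m
  }, numeric(1))
  n_excluded <- sum(is.infinite(pair_cv))
  if (n_excluded > 0)
    message(n_excluded, " duplicate pair(s) with mean 0 excluded from CV")
  pair_cv <- pair_cv[is.finite(pair_cv)]
  intra <- if (length(pair_cv) > 0) mean(pair_cv) else NA_real_
  ctrl <- q[q$role == "control", ]
  inter <- NA_real_; n_controls <- 0
  if (nrow(ctrl) > 0) {
    per_plate <- stats::aggregate(concentration ~ sample_id + plate_id,
                                  data = ctrl, FUN = mean)
    ctrl_cv <- vapply(split(per_plate$concentration, per_plate$sample_id),
                      function(v) {
                        if (length(v) < 2 || mean(v) == 0) return(NA_real_)
                        100 * stats::sd(v) / mean(v)
                      }, numeric(1))
    ctrl_cv <- ctrl_cv[is.finite(ctrl_cv)]
    n_controls <- length(ctrl_cv)
    if (n_controls > 0) inter <- mean(ctrl_cv)
  }
  list(intra_cv = intra, inter_cv = inter,
       intra_pass = !is.na(intra) && intra < intra_limit,
       inter_pass = is.na(inter) || inter < inter_limit,
       n_pairs = length(pair_cv), n_controls = n_controls,
       n_excluded = n_excluded)
}

#' Quantify one assay plate
#'
#' Fits the 4PL standard curve from the plate's standard wells and inverts
#' every sample/control well response to a concentration, flagging values
#' below the sensitivity.
#'
#' @param plate Data frame with columns `well`, `sample_id`, `role`
#'   (`standard`, `sample` or `control`), `concentration_ngml` (standards
#'   only) and `response`.
#' @param lod Assay sensitivity (ng/ml).
#' @return Data frame of non-standard wells with `concentration` (ng/ml)
#'   and `below_lod` added; the fitted `fourpl` object is attached as
#'   attribute `"curve"`.
#' @export
quantify_plate <- function(plate, lod = 2.5) {
  std <- plate[plate$role == "standard", ]
  if (nrow(std) < 5)
    cc_stop("plate has fewer than 5 standard wells",
            "cetacond_missing_standards")
  curve <- fit_4pl(std$concentration_ngml, std$response)
  smp <- plate[plate$role != "standard", , drop = FALSE]
  inv <- invert_4pl(curve, smp$response, lod = lod)
  smp$concentration <- inv$concentration
  smp$below_lod <- inv$below_lod
  attr(smp, "curve") <- curve
  smp
}

# ---- gamma log-link modelling -----------------------------------------

# shared scaffolding: all-subsets AICc selection with a glmmTMB or glm
# fitter, plus back-transformed marginal means for a focal factor
gamma_selection <- function(data, candidates, random = NULL,
                            criterion = "AICc") {
  fitter <- function(formula, data) {
    if (!is.null(random)) {
      rhs <- paste(deparse(formula[[3]]), "+", random)
      formula <- stats::as.formula(paste("concentration_ngg ~", rhs))
      fit <- suppressWarnings(
        glmmTMB::glmmTMB(formula, data = data,
                         family = Gamma(link = "log")))
      if ((!is.null(fit$fit$convergence) && fit$fit$convergence != 0) ||
          !isTRUE(fit$sdr$pdHess))
        cc_stop("glmmTMB did not converge", "cetacond_fit_failure")
      fit
    } else {
      fit <- suppressWarnings(
        stats::glm(formula, data = data, family = Gamma(link = "log")))
      if (!fit$converged || anyNA(stats::coef(fit)))
        cc_stop("glm did not converge or is rank-deficient",
                "cetacond_fit_failure")
      fit
    }
  }
  all_subsets_select(data, "concentration_ngg", candidates,
                     criterion = criterion, fitter = fitter)
}

marginal_means <- function(fit, focal) {
  em <- emmeans::emmeans(fit, specs = focal, type = "response")
  as.data.frame(em)
}

gamma_fit_result <- function(fit, selection, focal, data, contrasts = NULL) {
  is_mixed <- inherits(fit, "glmmTMB")
  coefs <- if (is_mixed) {
    s <- summary(fit)$coefficients$cond
    s
  } else summary(fit)$coefficients
  re_var <- if (is_mixed) {
    vc <- glmmTMB::VarCorr(fit)$cond
    if (length(vc) > 0) as.numeric(vc[[1]]) else 0
  } else NA_real_
  mm <- tryCatch(marginal_means(fit, focal), error = function(e) NULL)
  structure(list(coefficients = coefs, re_variance = re_var,
                 aicc = aicc(fit), marginal_means = mm,
                 contrasts = contrasts, selection = selection,
                 estimator = if (is_mixed) "glmmTMB ML (Laplace)" else
                   "glm IRLS",
                 fit = fit),
            class = "gamma_fit_result")
}

#' Gamma GLMM of cortisol over body site
#'
#' Models full-depth blubber cortisol (ng/g) with a gamma distribution,
#' log link and a per-individual random intercept, selecting among
#' `{site, quetelet, site:quetelet}` by AICc. Marginal site means are
#' reported from the site-containing model regardless of whether site is
#' retained, so the stratum means are always available.
#'
#' @param samples Data frame of full-depth samples: `individual_id`,
#'   `site`, `concentration_ngg`, and `quetelet` (body condition) if the
#'   condition terms are candidates.
#' @param candidates Candidate fixed-effect terms.
#' @return A `gamma_fit_result` (coefficients on the log scale, random
#'   intercept variance, AICc, back-transformed marginal site means) with
#'   the `selection_table` in `$selection`.
#' @export
fit_site_glmm <- function(samples,
                          candidates = c("site", "quetelet",
                                         "site:quetelet")) {
  if (length(unique(samples$site)) < 2)
    cc_stop("need >= 2 sites", "cetacond_insufficient_data")
  samples$site <- factor(samples$site,
                         levels = c("dorsal", "lateral", "ventral"))
  candidates <- intersect(candidates, available_terms(samples, candidates))
  sel <- gamma_selection(samples, candidates, random = "(1 | individual_id)")
  site_fit <- glmmTMB::glmmTMB(
    concentration_ngg ~ site + (1 | individual_id),
    data = samples, family = Gamma(link = "log"))
  res <- gamma_fit_result(attr(sel, "best_fit"), sel, "site", samples)
  res$marginal_means <- marginal_means(site_fit, "site")
  res
}

#' Gamma GLMM of cortisol over body site and blubber layer
#'
#' As [fit_site_glmm()] with the blubber layer (full, outer, middle,
#' inner) added to the candidate set; reports pairwise layer contrasts on
#' the log scale (reference: outer) alongside the marginal layer means.
#'
#' @param samples Data frame with `individual_id`, `site`, `layer`,
#'   `concentration_ngg` and optionally `quetelet`.
#' @param candidates Candidate fixed-effect terms.
#' @return A `gamma_fit_result`; `$marginal_means` are layer means and
#'   `$contrasts` the pairwise layer contrasts.
#' @export
fit_layer_glmm <- function(samples,
                           candidates = c("site", "layer", "quetelet",
                                          "quetelet:site",
                                          "quetelet:layer")) {
  samples$site <- factor(samples$site,
                         levels = c("dorsal", "lateral", "ventral"))
  samples$layer <- factor(samples$layer,
                          levels = c("outer", "full", "middle", "inner"))
  candidates <- intersect(candidates, available_terms(samples, candidates))
  sel <- gamma_selection(samples, candidates, random = "(1 | individual_id)")
  layer_fit <- glmmTMB::glmmTMB(
    concentration_ngg ~ layer + (1 | individual_id),
    data = samples, family = Gamma(link = "log"))
  em <- emmeans::emmeans(layer_fit, "layer")
  contrasts <- as.data.frame(emmeans::contrast(em, method = "trt.vs.ctrl",
                                               ref = "outer"))
  res <- gamma_fit_result(attr(sel, "best_fit"), sel, "layer", samples,
                          contrasts = contrasts)
  res$marginal_means <- marginal_means(layer_fit, "layer")
  res
}

#' Gamma GLM of outer-dorsal cortisol on individual covariates
#'
#' All-subsets AICc selection of a gamma log-link GLM of outer-layer
#' dorsal cortisol on sex, age class, cause-of-death class and body
#' condition (mass/length^2), mirroring the biopsy-relevant analysis.
#' Reports the equivalence set (delta AICc < 2), back-transformed sex
#' marginal means, and termplot-style partial-effect tables for the terms
#' of the best model.
#'
#' @param samples Data frame with `concentration_ngg`, `sex`, `age_class`,
#'   `cod_class`, `quetelet`.
#' @param candidates Candidate terms.
#' @return A `gamma_fit_result` with `$partial_effects` (list of tables)
#'   and `$selection`.
#' @export
fit_covariate_glm <- function(samples,
                              candidates = c("sex", "age_class",
                                             "cod_class", "quetelet")) {
  samples$sex <- factor(samples$sex, levels = c("female", "male"))
  samples$age_class <- factor(samples$age_class,
                              levels = intersect(
                                c("adult", "calf", "juvenile"),
                                unique(samples$age_class)))
  samples$cod_class <- factor(samples$cod_class,
                              levels = c("acute", "chronic"))
  candidates <- available_terms(samples, candidates)
  if (nrow(samples) < length(candidates) + 2)
    cc_stop("too few samples for the candidate set",
            "cetacond_insufficient_data")
  sel <- gamma_selection(samples, candidates, random = NULL)
  sex_fit <- stats::glm(concentration_ngg ~ sex, data = samples,
                        family = Gamma(link = "log"))
  res <- gamma_fit_result(attr(sel, "best_fit"), sel, "sex", samples)
  res$marginal_means <- marginal_means(sex_fit, "sex")
  best <- attr(sel, "best_fit")
  terms <- attr(sel, "best_terms")
  res$partial_effects <- lapply(stats::setNames(terms, terms), function(tm) {
    if (is.numeric(samples[[tm]])) {
      grid <- stats::quantile(samples[[tm]], c(.1, .25, .5, .75, .9))
      em <- emmeans::emmeans(best, specs = tm, type = "response",
                             at = stats::setNames(list(unname(grid)), tm))
    } else {
      em <- emmeans::emmeans(best, specs = tm, type = "response")
    }
    as.data.frame(em)
  })
  res
}

# keep only candidate terms whose variables vary in the data
available_terms <- function(data, candidates) {
  varies <- function(v) {
    x <- data[[v]]
    !is.null(x) && length(unique(stats::na.omit(x))) >= 2
  }
  candidates[vapply(strsplit(candidates, ":"), function(p)
    all(vapply(p, varies, logical(1))), logical(1))]
}
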