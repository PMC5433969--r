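# Calibrated synthetic-data generator. Emulates the statistical structure
# the analyses assume: age-class-structured lengths with nonlinear
# mass-length allometry, cause-of-death and season effects expressed on the
# mass/length^2 scale, a site/layer/sex/age/condition-structured gamma
# cortisol field with per-individual random intercepts, and competitive
# immunoassay plates with duplicate and plate-level noise. Defaults are
# calibrated so the empirical group means reproduce the published
# harbor-porpoise values.

#' Build a synthetic-data configuration
#'
#' Returns the full parameterization of the generative model with
#' calibrated defaults, validating feasibility and precomputing derived
#' calibration quantities (cause-of-death condition factors, lognormal
#' noise scales, assay noise scales). Any component can be overridden by
#' passing a modified sub-list.
#'
#' @param seed Integer seed; the same seed and config give byte-identical
#'   output.
#' @param n_animals Default number of animals for
#'   [generate_morphometrics()].
#' @param ages Age-class mixture and per-class length distributions (cm).
#' @param allometry Nonlinear mass-length parameters `delta` (kg),
#'   `alpha` (kg cm^-beta) and `beta`.
#' @param condition Cause-of-death structure on mass/length^2 (kg/cm^2):
#'   group means and SDs, and an `enabled` switch (disabled puts every
#'   animal exactly on the allometric curve up to `mass_noise_sd`).
#' @param acute_prop Probability of an acute cause of death per age class.
#' @param season Breeding-season proportion and multiplicative log-scale
#'   effect on condition (0 by default: season is generated but carries no
#'   signal).
#' @param mass_noise_sd Extra lognormal sd on mass, independent of the
#'   condition structure (for allometry-only simulations).
#' @param girth,blubber Morphometric plumbing: girth as a fraction of
#'   length scaled by condition, ventral blubber depth (mm) scaled by
#'   condition, with lognormal noise.
#' @param cortisol Cortisol field: full-depth site means, layer means,
#'   outer-dorsal sex means (ng/g), juvenile log-effect and proportion,
#'   condition log-slope (per kg/cm^2), acute proportion, random-intercept
#'   sd, gamma shape per sampling design (a named vector calibrated so each
#'   sample subset reproduces its published dispersion; a scalar applies to
#'   all designs, `Inf` gives the deterministic limit), optional additive
#'   progesterone cross-reactivity bias for females (ng/g).
#' @param assay 4PL curve parameters, standard concentrations (ng/ml),
#'   sensitivity, intra-/inter-assay CV calibration targets (percent),
#'   standard-well response noise, sample concentration distribution, and
#'   the tissue-mass to extraction-efficiency curve.
#' @return A validated list of class `synth_config` with a `derived`
#'   component holding the calibration quantities.
#' @export
synth_config <- function(
    seed = 1L,
    n_animals = 291L,
    ages = list(proportions = c(calf = 0.10, juvenile = 0.45, adult = 0.45),
                calf = list(mean = 75, sd = 8, min = 55, max = 90),
                juvenile = list(min = 90, max = 135),
                adult = list(mean = 145, sd = 8, min = 135, max = 175)),
    allometry = list(delta = -3.17, alpha = 4e-4, beta = 2.33),
    condition = list(enabled = TRUE,
                     acute_mean = 0.0022, chronic_mean = 0.0018,
                     acute_sd = 0.00035, chronic_sd = 0.00050),
    acute_prop = c(calf = 0.25, juvenile = 0.478, adult = 0.491),
    season = list(breeding_prop = 66 / 291, log_effect = 0),
    mass_noise_sd = 0,
    girth = list(coef = 0.62, cond_exp = 0.5, noise_sd = 0.15),
    blubber = list(ventral_mm = 14, cond_exp = 1.2, noise_sd = 0.35,
                   dorsal_ratio = 0.85, lateral_ratio = 0.90,
                   extra_noise_sd = 0.10),
    cortisol = list(site_means = c(dorsal = 69.09, lateral = 90.48,
                                   ventral = 83.22),
                    layer_means = c(outer = 77.84, middle = 156.28,
                                    inner = 180.02),
                    sex_means = c(female = 111.37, male = 66.77),
                    age_log_effect = 0.35, juvenile_prop = 0.35,
                    condition_log_slope = -400,
                    site_condition_slope = 0,
                    acute_prop = 0.65,
                    re_sd = 0.25,
                    shape = c(site = 4, layer = 1.2, covariate = 6),
                    progesterone_bias = 0),
    assay = list(fourpl = list(a = 2.0, d = 0.1, c = 100, b = 1.2),
                 standards = c(0, 2.5, 10, 25, 50, 100, 200, 400, 800),
                 sensitivity = 2.5,
                 intra_cv_target = 5.65, inter_cv_target = 10.84,
                 standard_noise_sd = 0,
                 n_samples = 10,
                 sample_logmean = log(50), sample_logsd = 0.8,
                 sample_range = c(2.5, 750),
                 efficiency = list(e_max = 0.9, k = 0.03, decline = 2))) {
  cfg <- list(seed = as.integer(seed), n_animals = as.integer(n_animals),
              ages = ages, allometry = allometry, condition = condition,
              acute_prop = acute_prop, season = season,
              mass_noise_sd = mass_noise_sd, girth = girth,
              blubber = blubber, cortisol = cortisol, assay = assay)
  validate_synth_config(cfg)
  cfg$derived <- derive_calibration(cfg)
  structure(cfg, class = "synth_config")
}

validate_synth_config <- function(cfg) {
  chk <- function(cond, msg) if (!isTRUE(cond))
    cc_stop(paste0("invalid config: ", msg), "cetacond_config_error")
  p <- cfg$ages$proportions
  chk(abs(sum(p) - 1) < 1e-8 && all(p >= 0),
      "age proportions must be non-negative and sum to 1")
  chk(all(names(p) == c("calf", "juvenile", "adult")),
      "age proportions must be named calf, juvenile, adult")
  chk(cfg$ages$calf$max <= cfg$ages$juvenile$min ||
        cfg$ages$calf$max == cfg$ages$juvenile$min,
      "length cutoffs must be ordered")
  chk(cfg$ages$juvenile$max <= cfg$ages$adult$min,
      "length cutoffs must be ordered")
  chk(all(cfg$acute_prop >= 0 & cfg$acute_prop <= 1),
      "acute proportions must be in [0, 1]")
  chk(cfg$allometry$alpha > 0 && cfg$allometry$beta > 0,
      "alpha and beta must be positive")
  with(cfg$condition, chk(acute_mean > 0 && chronic_mean > 0 &&
                            acute_sd >= 0 && chronic_sd >= 0,
                          "condition means must be positive"))
  chk(all(cfg$cortisol$site_means > 0) && all(cfg$cortisol$layer_means > 0) &&
        all(cfg$cortisol$sex_means > 0), "cortisol means must be positive")
  chk(all(cfg$cortisol$shape > 0), "gamma shape must be positive")
  chk(cfg$cortisol$re_sd >= 0, "random-intercept sd must be non-negative")
  with(cfg$assay$fourpl, chk(c > 0 && a != d,
                             "4PL needs c > 0 and distinct asymptotes"))
  chk(any(cfg$assay$standards == 0), "standards must include 0")
  # feasibility: predicted mass must be positive over the length support
  grid <- seq(cfg$ages$calf$min, cfg$ages$adult$max, length.out = 500)
  m <- cfg$allometry$delta + cfg$allometry$alpha * grid^cfg$allometry$beta
  chk(all(m > 0), "allometry implies non-positive mass within the length support")
  invisible(cfg)
}

# baseline mass/length^2 implied by the allometric curve
qbase <- function(length_cm, allo) {
  (allo$delta + allo$alpha * length_cm^allo$beta) / length_cm^2
}

# first two moments of qbase over one age class's length distribution
qbase_moments_by_age <- function(cfg) {
  allo <- cfg$allometry
  mom <- function(age) {
    a <- cfg$ages[[age]]
    grid <- seq(a$min, a$max, length.out = 2001)
    w <- if (age == "juvenile") rep(1, length(grid)) else
      stats::dnorm(grid, a$mean, a$sd)
    q <- qbase(grid, allo)
    c(m1 = sum(w * q) / sum(w), m2 = sum(w * q^2) / sum(w))
  }
  vapply(c(calf = "calf", juvenile = "juvenile", adult = "adult"), mom,
         numeric(2))
}

derive_calibration <- function(cfg) {
  qm <- qbase_moments_by_age(cfg)
  qb <- qm["m1", ]
  p_age <- cfg$ages$proportions
  joint_acute <- p_age * cfg$acute_prop
  joint_chronic <- p_age * (1 - cfg$acute_prop)
  p_age_acute <- joint_acute / sum(joint_acute)
  p_age_chronic <- joint_chronic / sum(joint_chronic)
  cond <- cfg$condition
  if (isTRUE(cond$enabled)) {
    factor_acute <- cond$acute_mean / sum(p_age_acute * qb)
    factor_chronic <- cond$chronic_mean / sum(p_age_chronic * qb)
    # the configured group SDs are total within-group spreads of
    # mass/length^2; the lognormal noise only supplies the variance the
    # systematic age/length structure does not already account for
    noise_logsd <- function(p_age_cod, f, target_mean, target_sd) {
      m2_sys <- f^2 * sum(p_age_cod * qm["m2", ])
      var_sys <- m2_sys - target_mean^2
      sqrt(log1p(max(0, target_sd^2 - var_sys) / m2_sys))
    }
    logsd_acute <- noise_logsd(p_age_acute, factor_acute,
                               cond$acute_mean, cond$acute_sd)
    logsd_chronic <- noise_logsd(p_age_chronic, factor_chronic,
                                 cond$chronic_mean, cond$chronic_sd)
  } else {
    factor_acute <- factor_chronic <- 1
    logsd_acute <- logsd_chronic <- 0
  }
  # duplicate noise scale from the intra-assay CV target: the expected
  # sample CV of a lognormal duplicate pair is tau * sqrt(2/pi)
  tau <- (cfg$assay$intra_cv_target / 100) / sqrt(2 / pi)
  plate_sd <- sqrt(max(0, (cfg$assay$inter_cv_target / 100)^2 - tau^2 / 2))
  # cortisol covariate-design mixture moments of quetelet (for exact mean
  # calibration of the sex strata under the centred age/condition terms)
  pa <- cfg$cortisol$acute_prop
  q_mean <- pa * cond$acute_mean + (1 - pa) * cond$chronic_mean
  q_var <- pa * (cond$acute_sd^2 + cond$acute_mean^2) +
    (1 - pa) * (cond$chronic_sd^2 + cond$chronic_mean^2) - q_mean^2
  pj <- cfg$cortisol$juvenile_prop
  a <- cfg$cortisol$age_log_effect
  age_mgf <- log(pj * exp(a * (1 - pj)) + (1 - pj) * exp(-a * pj))
  cond_corr <- cfg$cortisol$condition_log_slope^2 * q_var / 2
  list(qbase_by_age = qb,
       p_age_given_acute = p_age_acute,
       p_age_given_chronic = p_age_chronic,
       cond_factor = c(acute = factor_acute, chronic = factor_chronic),
       cond_logsd = c(acute = logsd_acute, chronic = logsd_chronic),
       duplicate_logsd = tau, plate_logsd = plate_sd,
       q_mixture_mean = q_mean, q_mixture_var = q_var,
       age_mgf_correction = age_mgf,
       condition_correction = cond_corr)
}

#' Tissue-mass to extraction-efficiency curve
#'
#' Efficiency rises with subsample mass to a plateau around 0.15-0.2 g and
#' declines slowly beyond it (an assumption of the generator, flagged as
#' such: the shape is plausible for solvent-limited steroid extraction but
#' is not derived from published measurements).
#'
#' @param tissue_mass_g Subsample mass (g).
#' @param pars List with `e_max`, `k` (half-saturation mass, g) and
#'   `decline` (fractional loss per g above 0.2 g).
#' @return Efficiency in (0, 1].
#' @export
efficiency_curve <- function(tissue_mass_g,
                             pars = list(e_max = 0.9, k = 0.03,
                                         decline = 2)) {
  e <- pars$e_max * tissue_mass_g / (tissue_mass_g + pars$k) *
    pmax(0.5, 1 - pars$decline * pmax(0, tissue_mass_g - 0.2))
  pmin(pmax(e, 1e-6), 1)
}

#' Generate a synthetic morphometric strandings dataset
#'
#' Lengths are drawn per age class (truncated normal for calves and
#' adults, uniform for juveniles); mass follows the nonlinear allometry
#' `delta + alpha L^beta` scaled by a lognormal cause-of-death condition
#' factor calibrated so the group means of mass/length^2 hit the
#' configured targets; girth and blubber thicknesses scale with the
#' realized condition; season labels (and consistent dates) are assigned
#' with the configured breeding proportion. All animals are male, matching
#' the strandings analysis the generator emulates.
#'
#' @param config A [synth_config()].
#' @param n Number of animals (default `config$n_animals`).
#' @param seed Seed override (default `config$seed`).
#' @return A validated morphometric record table (see
#'   [read_morphometrics()] for the schema).
#' @export
generate_morphometrics <- function(config, n = config$n_animals,
                                   seed = config$seed) {
  stopifnot(inherits(config, "synth_config"))
  set.seed(seed)
  if (n == 0) {
    out <- utils::read.csv(text = paste(MORPH_COLUMNS, collapse = ","))
    out$date <- as.Date(character(0))
    return(out)
  }
  ages <- sample(names(config$ages$proportions), n, replace = TRUE,
                 prob = config$ages$proportions)
  len <- numeric(n)
  for (age in unique(ages)) {
    i <- ages == age
    a <- config$ages[[age]]
    len[i] <- if (age == "juvenile") stats::runif(sum(i), a$min, a$max)
    else rtruncnorm(sum(i), a$mean, a$sd, a$min, a$max)
  }
  cod <- ifelse(stats::runif(n) < config$acute_prop[ages], "acute",
                "chronic")
  dv <- config$derived
  f <- dv$cond_factor[cod]
  s <- dv$cond_logsd[cod]
  cond_mult <- exp(stats::rnorm(n, 0, 1) * s - s^2 / 2)
  breeding <- stats::runif(n) < config$season$breeding_prop
  season_mult <- exp(config$season$log_effect * breeding)
  ms <- config$mass_noise_sd
  mass_mult <- if (ms > 0) exp(stats::rnorm(n, 0, ms) - ms^2 / 2) else 1
  base_mass <- config$allometry$delta +
    config$allometry$alpha * len^config$allometry$beta
  mass <- base_mass * f * cond_mult * season_mult * mass_mult
  q <- mass / len^2
  q_ref <- mean(q)
  g <- config$girth
  girth <- g$coef * len * (q / q_ref)^g$cond_exp *
    exp(stats::rnorm(n, 0, g$noise_sd))
  b <- config$blubber
  ventral <- b$ventral_mm * (q / q_ref)^b$cond_exp *
    exp(stats::rnorm(n, 0, b$noise_sd))
  dorsal <- ventral * b$dorsal_ratio * exp(stats::rnorm(n, 0, b$extra_noise_sd))
  lateral <- ventral * b$lateral_ratio * exp(stats::rnorm(n, 0, b$extra_noise_sd))
  cutoffs <- morph_cutoffs(adult_min_cm = config$ages$adult$min,
                           calf_max_cm = config$ages$calf$max)
  year <- sample(2006:2015, n, replace = TRUE)
  month <- integer(n)
  bm <- cutoffs$breeding_months
  month[breeding] <- sample(bm, sum(breeding), replace = TRUE)
  month[!breeding] <- sample(setdiff(1:12, bm), sum(!breeding),
                             replace = TRUE)
  date <- as.Date(sprintf("%d-%02d-%02d", year, month,
                          sample(1:28, n, replace = TRUE)))
  out <- data.frame(id = sprintf("SIM-%04d", seq_len(n)), sex = "male",
                    date = date, cod_class = cod,
                    age_class = assign_age_class(len), season =
                      ifelse(breeding, "breeding", "nonbreeding"),
                    mass_kg = mass, length_cm = len, girth_cm = girth,
                    blubber_dorsal_mm = dorsal,
                    blubber_lateral_mm = lateral,
                    blubber_ventral_mm = ventral,
                    stringsAsFactors = FALSE)
  out$age_class <- assign_age_class(len, cutoffs)
  validate_morphometrics(out, cutoffs)
}

#' Generate a synthetic blubber cortisol dataset
#'
#' Concentrations (ng/g) are gamma-distributed around a log-scale mean
#' built from the configured stratum means plus centred sex, age and
#' condition effects and a per-individual normal random intercept; the
#' centring corrections are exact (normal/Bernoulli moment-generating
#' functions), so the empirical stratum means are calibrated to the
#' configured values.
#'
#' Three sampling designs mirror the published sample subsets:
#' `"site"` (full-depth samples at dorsal/lateral/ventral), `"layer"`
#' (four layers at each of three sites) and `"covariate"` (dorsal outer
#' layer only, balanced sexes, with age class, cause of death and body
#' condition attached).
#'
#' @param config A [synth_config()].
#' @param design Sampling design (see above).
#' @param n_individuals Number of individuals (defaults: 20 site, 6 layer,
#'   20 covariate).
#' @param seed Seed override.
#' @return Data frame with one row per subsample: `individual_id`, `sex`,
#'   `age_class`, `cod_class`, `quetelet`, `site`, `layer`,
#'   `tissue_mass_g`, `efficiency`, `concentration_ngg`.
#' @export
generate_cortisol <- function(config,
                              design = c("site", "layer", "covariate"),
                              n_individuals = NULL, seed = config$seed) {
  stopifnot(inherits(config, "synth_config"))
  design <- match.arg(design)
  n <- n_individuals %||% switch(design, site = 20, layer = 6,
                                 covariate = 20)
  set.seed(seed)
  co <- config$cortisol
  dv <- config$derived
  sex <- sample(rep(c("female", "male"), length.out = n))
  age <- ifelse(stats::runif(n) < co$juvenile_prop, "juvenile", "adult")
  cod <- ifelse(stats::runif(n) < co$acute_prop, "acute", "chronic")
  cnd <- config$condition
  qm <- ifelse(cod == "acute", cnd$acute_mean, cnd$chronic_mean)
  qs <- ifelse(cod == "acute", cnd$acute_sd, cnd$chronic_sd)
  quetelet <- rtruncnorm(n, qm, qs, lower = 1e-4)
  u <- stats::rnorm(n, 0, co$re_sd)
  grid <- switch(design,
    site = expand.grid(ind = seq_len(n),
                       site = c("dorsal", "lateral", "ventral"),
                       layer = "full", stringsAsFactors = FALSE),
    layer = expand.grid(ind = seq_len(n),
                        site = c("dorsal", "lateral", "ventral"),
                        layer = c("full", "outer", "middle", "inner"),
                        stringsAsFactors = FALSE),
    covariate = data.frame(ind = seq_len(n), site = "dorsal",
                           layer = "outer", stringsAsFactors = FALSE))
  grid <- grid[order(grid$ind), , drop = FALSE]
  i <- grid$ind
  site_means <- co$site_means
  site_ratio <- site_means / mean(site_means)
  layer_target <- c(full = unname(mean(site_means)), co$layer_means)
  logmu <- switch(design,
    site = log(site_means[grid$site]) +
      co$site_condition_slope * (quetelet[i] - dv$q_mixture_mean) -
      co$site_condition_slope^2 * dv$q_mixture_var / 2,
    layer = log(site_ratio[grid$site] * layer_target[grid$layer]),
    covariate = log(co$sex_means[sex[i]]) +
      co$age_log_effect * ((age[i] == "juvenile") - co$juvenile_prop) -
      dv$age_mgf_correction +
      co$condition_log_slope * (quetelet[i] - dv$q_mixture_mean) -
      dv$condition_correction)
  logmu <- logmu + u[i] - co$re_sd^2 / 2
  mu <- exp(unname(logmu))
  shape <- if (length(co$shape) > 1) co$shape[[design]] else co$shape
  conc <- if (is.infinite(shape)) mu else
    stats::rgamma(length(mu), shape = shape, scale = mu / shape)
  if (co$progesterone_bias != 0)
    conc <- conc + co$progesterone_bias * (sex[i] == "female")
  tissue_mass <- stats::runif(length(mu), 0.1, 0.2)
  data.frame(individual_id = sprintf("IND-%03d", i), sex = sex[i],
             age_class = age[i], cod_class = cod[i],
             quetelet = quetelet[i], site = grid$site, layer = grid$layer,
             tissue_mass_g = tissue_mass,
             efficiency = efficiency_curve(tissue_mass,
                                           config$assay$efficiency),
             concentration_ngg = conc, stringsAsFactors = FALSE)
}

#' Generate a synthetic assay plate
#'
#' Emits standard wells (exact or noisy responses on the configured 4PL
#' curve), duplicate sample wells and duplicate control wells. Duplicate
#' responses are generated by pushing lognormally perturbed concentrations
#' through the curve, with the perturbation sd calibrated so the mean
#' duplicate CV equals the configured intra-assay target; a lognormal
#' plate-level shift reproduces the inter-assay target for control
#' extracts re-assayed across plates.
#'
#' @param config A [synth_config()].
#' @param true_concentrations Sample concentrations (ng/ml); drawn from
#'   the configured lognormal (clipped to the assay range) when `NULL`.
#' @param control_concentrations Optional named vector of control-extract
#'   concentrations (ng/ml) shared across plates.
#' @param plate_id Plate label.
#' @param seed Seed override.
#' @return Data frame of plate wells: `plate_id`, `well`, `sample_id`,
#'   `role`, `concentration_ngml` (standards only), `response`. True
#'   sample concentrations are attached as attribute
#'   `"true_concentrations"`.
#' @export
generate_assay_plate <- function(config, true_concentrations = NULL,
                                 control_concentrations = NULL,
                                 plate_id = "plate-001",
                                 seed = config$seed) {
  stopifnot(inherits(config, "synth_config"))
  set.seed(seed)
  as_cfg <- config$assay
  dv <- config$derived
  if (is.null(true_concentrations)) {
    x <- stats::rlnorm(as_cfg$n_samples, as_cfg$sample_logmean,
                       as_cfg$sample_logsd)
    true_concentrations <- pmin(pmax(x, as_cfg$sample_range[1]),
                                as_cfg$sample_range[2])
  }
  plate_shift <- exp(stats::rnorm(1, 0, dv$plate_logsd))
  std <- data.frame(sample_id = sprintf("STD-%02d",
                                        seq_along(as_cfg$standards)),
                    role = "standard",
                    concentration_ngml = as_cfg$standards,
                    response = fourpl_response(as_cfg$fourpl,
                                               as_cfg$standards) +
                      stats::rnorm(length(as_cfg$standards), 0,
                                   as_cfg$standard_noise_sd),
                    stringsAsFactors = FALSE)
  dup_rows <- function(conc, ids, role) {
    k <- length(conc)
    obs <- rep(conc, each = 2) * plate_shift *
      exp(stats::rnorm(2 * k, 0, dv$duplicate_logsd))
    data.frame(sample_id = rep(ids, each = 2), role = role,
               concentration_ngml = NA_real_,
               response = fourpl_response(as_cfg$fourpl, obs),
               stringsAsFactors = FALSE)
  }
  smp <- dup_rows(true_concentrations,
                  sprintf("SMP-%02d", seq_along(true_concentrations)),
                  "sample")
  ctl <- if (!is.null(control_concentrations))
    dup_rows(control_concentrations,
             names(control_concentrations) %||%
               sprintf("CTL-%02d", seq_along(control_concentrations)),
             "control")
  out <- rbind(std, smp, ctl)
  out <- cbind(plate_id = plate_id,
               well = sprintf("%s%d", rep(LETTERS[1:8],
                                          length.out = nrow(out)),
                              rep(seq_len(ceiling(nrow(out) / 8)),
                                  each = 8)[seq_len(nrow(out))]),
               out, stringsAsFactors = FALSE)
  attr(out, "true_concentrations") <- true_concentrations
  out
}
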