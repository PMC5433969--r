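# Assay quantification chain and the gamma log-link modelling stage.

fourpl_pars <- list(a = 2.0, d = 0.1, c = 100, b = 1.2)

test_that("4PL fitting recovers noise-free standards and the midpoint
           identity holds", {
  x <- c(0, 2.5, 10, 25, 50, 100, 200, 400, 800)
  y <- fourpl_response(fourpl_pars, x)
  fit <- fit_4pl(x, y)
  expect_equal(fit$a, 2.0, tolerance = 1e-6)
  expect_equal(fit$d, 0.1, tolerance = 1e-6)
  expect_equal(fit$c, 100, tolerance = 1e-4)
  expect_equal(fit$b, 1.2, tolerance = 1e-6)
  expect_equal(fourpl_response(fourpl_pars, 100), (2.0 + 0.1) / 2,
               tolerance = 1e-12)
  expect_error(fit_4pl(c(0, 10, 100), c(2, 1, 0.5)),
               class = "cetacond_insufficient_data")
  expect_warning(fit_4pl(x, y + c(0, 0.5, -0.5, rep(0, 6))),
                 class = "cetacond_nonmonotone")
})

test_that("4PL least squares beats a coarse grid search", {
  set.seed(91)
  x <- c(0, 2.5, 10, 25, 50, 100, 200, 400, 800)
  y <- fourpl_response(fourpl_pars, x) + rnorm(9, 0, 0.02)
  fit <- fit_4pl(x, y)
  sse <- function(p) sum((y - fourpl_response(p, x))^2)
  grid <- expand.grid(a = seq(1.6, 2.4, 0.2), d = seq(0, 0.3, 0.1),
                      c = c(50, 75, 100, 150, 200), b = seq(0.8, 1.6, 0.2))
  grid_sse <- apply(grid, 1, function(g) sse(as.list(g)))
  best <- grid[which.min(grid_sse), ]
  expect_lte(sse(fit[c("a", "d", "c", "b")]), min(grid_sse))
  # same optimum region as the lattice winner
  expect_lt(abs(fit$c - best$c) / best$c, 0.5)
  expect_lt(abs(fit$b - best$b), 0.4)
})

test_that("4PL inversion is the exact inverse of the forward curve", {
  expect_equal(invert_4pl(fourpl_pars, (2.0 + 0.1) / 2)$concentration, 100,
               tolerance = 1e-10)
  for (x in c(2.5, 10, 100, 800)) {
    back <- invert_4pl(fourpl_pars, fourpl_response(fourpl_pars, x))
    expect_equal(back$concentration, x, tolerance = 1e-10 * x)
  }
  low <- invert_4pl(fourpl_pars, fourpl_response(fourpl_pars, 2.0))
  expect_equal(low$concentration, 2.0, tolerance = 1e-8)
  expect_true(low$below_lod)
  expect_false(invert_4pl(fourpl_pars,
                          fourpl_response(fourpl_pars, 50))$below_lod)
  expect_error(invert_4pl(fourpl_pars, 2.5),
               class = "cetacond_out_of_range")
})

test_that("tissue concentration correction is the documented proportionality", {
  expect_equal(to_tissue_concentration(20, tissue_mass_g = 0.2), 50)
  expect_equal(to_tissue_concentration(20, tissue_mass_g = 0.1),
               2 * to_tissue_concentration(20, tissue_mass_g = 0.2))
  expect_equal(to_tissue_concentration(20, 0.2, efficiency = 0.5),
               2 * to_tissue_concentration(20, 0.2, efficiency = 1))
  expect_equal(to_tissue_concentration(20, 0.2,
                                       resuspension_volume_ml = 1),
               2 * to_tissue_concentration(20, 0.2))
  expect_error(to_tissue_concentration(20, 0.2, efficiency = 0),
               class = "cetacond_domain_error")
})

test_that("assay CV summarises duplicate spread and excludes zero-mean
           pairs", {
  q <- data.frame(plate_id = "p1",
                  sample_id = rep(c("s1", "s2"), each = 2),
                  role = "sample",
                  concentration = c(50, 50, 90, 110))
  cv <- assay_cv(q)
  pair2 <- 100 * sd(c(90, 110)) / 100
  expect_equal(cv$intra_cv, mean(c(0, pair2)))
  expect_equal(pair2, 14.142, tolerance = 1e-3)
  expect_true(cv$intra_pass)
  qz <- rbind(q, data.frame(plate_id = "p1", sample_id = "s3",
                            role = "sample", concentration = c(0, 0)))
  expect_message(cvz <- assay_cv(qz), "excluded")
  expect_equal(cvz$n_excluded, 1)
  expect_equal(cvz$intra_cv, cv$intra_cv)
})

test_that("site model drops body location when none was generated", {
  cfg <- default_config(cortisol = modifyList(
    synth_config()$cortisol,
    list(site_means = c(dorsal = 80, lateral = 80, ventral = 80))))
  dropped <- vapply(1:30, function(s) {
    d <- generate_cortisol(cfg, design = "site", seed = s)
    sel <- fit_site_glmm(d)$selection
    !grepl("site", sel$model[1])
  }, logical(1))
  expect_gt(mean(dropped), 0.5)
})

test_that("with no random effect and no covariates the gamma fits collapse
           to the sample mean and the mixed fit matches the glm", {
  cfg <- default_config(cortisol = modifyList(synth_config()$cortisol,
                                              list(re_sd = 0)))
  d <- generate_cortisol(cfg, design = "site", n_individuals = 150,
                         seed = 5)
  g0 <- glm(concentration_ngg ~ 1, data = d, family = Gamma(link = "log"))
  expect_equal(unname(coef(g0)), log(mean(d$concentration_ngg)),
               tolerance = 1e-6)
  gm <- glmmTMB::glmmTMB(concentration_ngg ~ site + (1 | individual_id),
                         data = d, family = Gamma(link = "log"))
  gf <- glm(concentration_ngg ~ site, data = d,
            family = Gamma(link = "log"))
  expect_equal(unname(glmmTMB::fixef(gm)$cond), unname(coef(gf)),
               tolerance = 1e-3)
})

test_that("layer model recovers the stratification pattern", {
  cfg <- default_config()
  d <- generate_cortisol(cfg, design = "layer", n_individuals = 100,
                         seed = 9)
  res <- fit_layer_glmm(d)
  ct <- res$contrasts
  est <- setNames(ct$estimate, ct$contrast)
  pv <- setNames(ct$p.value, ct$contrast)
  expect_gt(est[["inner - outer"]], 0)
  expect_gt(est[["middle - outer"]], 0)
  expect_lt(pv[["inner - outer"]], 0.05)
  expect_lt(pv[["middle - outer"]], 0.05)
  expect_gt(pv[["full - outer"]], 0.05)
  mm <- res$marginal_means
  means <- setNames(mm$response, as.character(mm$layer))
  expect_true(means[["inner"]] > means[["middle"]])
  expect_true(means[["middle"]] > means[["full"]])
  expect_true(means[["full"]] > means[["outer"]])
})

test_that("identical layers are dropped from the best model", {
  co <- synth_config()$cortisol
  co$layer_means <- c(outer = 80, middle = 80, inner = 80)
  co$site_means <- c(dorsal = 80, lateral = 80, ventral = 80)
  cfg <- default_config(cortisol = co)
  d <- generate_cortisol(cfg, design = "layer", n_individuals = 30,
                         seed = 3)
  sel <- fit_layer_glmm(d)$selection
  expect_false(grepl("layer", sel$model[1]))
})

test_that("sex is retained in most small-sample covariate selections and
           condition carries a negative coefficient", {
  cfg <- default_config()
  sex_in <- vapply(1:200, function(s) {
    d <- generate_cortisol(cfg, design = "covariate", seed = s)
    grepl("sex", fit_covariate_glm(d)$selection$model[1])
  }, logical(1))
  expect_gt(mean(sex_in), 0.5)
  d <- generate_cortisol(cfg, design = "covariate", n_individuals = 500,
                         seed = 2)
  f <- glmmTMB::glmmTMB(concentration_ngg ~ sex + age_class + quetelet,
                        data = d, family = Gamma(link = "log"))
  expect_lt(glmmTMB::fixef(f)$cond[["quetelet"]], 0)
})

test_that("a signal-free covariate field selects the intercept-only model
           most often", {
  co <- synth_config()$cortisol
  co$sex_means <- c(female = 90, male = 90)
  co$age_log_effect <- 0
  co$condition_log_slope <- 0
  cfg <- default_config(cortisol = co)
  wins <- vapply(1:50, function(s) {
    d <- generate_cortisol(cfg, design = "covariate", seed = s)
    fit_covariate_glm(d)$selection$model[1]
  }, character(1))
  tab <- sort(table(wins), decreasing = TRUE)
  expect_equal(names(tab)[1], "(intercept)")
})

test_that("gamma GLMM fixed effects recover generating log-scale contrasts
           within two standard errors", {
  cfg <- default_config()
  truth <- log(cfg$cortisol$site_means / cfg$cortisol$site_means["dorsal"])
  hits <- vapply(1:100, function(s) {
    d <- generate_cortisol(cfg, design = "site", n_individuals = 500,
                           seed = s)
    fit <- glmmTMB::glmmTMB(concentration_ngg ~ site + (1 | individual_id),
                            data = d, family = Gamma(link = "log"))
    co <- summary(fit)$coefficients$cond
    all(abs(co["sitelateral", "Estimate"] - truth[["lateral"]]) <=
          2 * co["sitelateral", "Std. Error"],
        abs(co["siteventral", "Estimate"] - truth[["ventral"]]) <=
          2 * co["siteventral", "Std. Error"])
  }, logical(1))
  expect_gte(mean(hits), 0.9)
})
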