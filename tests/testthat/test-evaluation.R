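# Ground-truthing framework: homogeneity test, condition linear models,
# exhaustive selection, effect sizes, verdicts and the ranking procedure.

test_that("levene test is null for identical deviations and calibrated
           under the null", {
  v <- c(-1, 1, -1, 1); g <- c("a", "a", "b", "b")
  res <- levene_test(v, g)
  expect_equal(res$statistic, 0)
  expect_equal(res$p_value, 1)
  expect_error(levene_test(1:3, c("a", "a", "b")),
               class = "cetacond_insufficient_data")
  set.seed(101)
  rej <- replicate(1000, {
    levene_test(rnorm(100), rep(c("a", "b"), each = 50))$p_value < 0.05
  })
  expect_gte(mean(rej), 0.03)
  expect_lte(mean(rej), 0.07)
})

test_that("levene test detects a ninefold variance ratio", {
  set.seed(202)
  rej <- replicate(200, {
    v <- c(rnorm(50, sd = 3), rnorm(50, sd = 1))
    levene_test(v, rep(c("a", "b"), each = 50))$p_value < 0.05
  })
  expect_gte(mean(rej), 0.8)
})

test_that("condition linear model honours OLS identities", {
  cfg <- default_config()
  m <- generate_morphometrics(cfg, n = 80, seed = 31)
  # constant response: no signal, zero adjusted R-squared
  f0 <- fit_condition_lm(rep(1, nrow(m)), m, "cod_class")
  expect_equal(unname(coef(f0$fit)[-1]), 0)
  expect_equal(f0$adj_r2, 0)
  # single binary factor: coefficient is the difference in group means
  q <- m$mass_kg / m$length_cm^2
  f1 <- fit_condition_lm(q, m, "cod_class")
  gm <- tapply(q, m$cod_class, mean)
  expect_equal(unname(coef(f1$fit)["cod_classchronic"]),
               unname(gm["chronic"] - gm["acute"]), tolerance = 1e-10)
  expect_error(fit_condition_lm(q, within(m, season <- "nonbreeding"),
                                "season"),
               class = "cetacond_singular_design")
})

test_that("the chronic condition deficit is recovered at the study scale", {
  cfg <- default_config()
  hits <- vapply(1:100, function(s) {
    m <- generate_morphometrics(cfg, n = 291, seed = s)
    f <- fit_condition_lm(m$mass_kg / m$length_cm^2, m,
                          c("cod_class", "age_class"))
    co <- f$coefficients["cod_classchronic", ]
    co["Estimate"] < 0 && co["Pr(>|t|)"] < 0.05
  }, logical(1))
  expect_gte(mean(hits), 0.95)
})

test_that("subset enumeration respects marginality and order invariance", {
  sets <- enumerate_model_terms(c("a", "b", "c", "a:b"))
  labels <- vapply(sets, paste, character(1), collapse = "+")
  expect_equal(length(sets), 8 + 2)  # 2^3 subsets, interaction on 2
  has_int <- grepl("a:b", labels)
  expect_true(all(grepl("(^|\\+)a($|\\+)", labels[has_int]) &
                    grepl("(^|\\+)b($|\\+)", labels[has_int])))
  cfg <- default_config()
  m <- generate_morphometrics(cfg, n = 120, seed = 41)
  d <- cetacond:::condition_model_frame(m$mass_kg / m$length_cm^2, m)
  s1 <- all_subsets_select(d, "index",
                           c("cod_class", "age_class", "season"))
  s2 <- all_subsets_select(d, "index",
                           c("season", "cod_class", "age_class"))
  expect_equal(s1$model[1], s2$model[1])
  expect_equal(s1$AIC, s2$AIC, tolerance = 1e-10)
  expect_equal(sum(s1$weight), 1, tolerance = 1e-12)
  expect_true(all(diff(s1$weight) <= 1e-12))  # monotone in delta
})

test_that("a null response selects the intercept-only model most often", {
  cfg <- default_config()
  m <- generate_morphometrics(cfg, n = 60, seed = 51)
  d <- cetacond:::condition_model_frame(rnorm(nrow(m)), m)
  wins <- vapply(1:100, function(s) {
    set.seed(s)
    d$index <- rnorm(nrow(d))
    sel <- all_subsets_select(d, "index",
                              c("cod_class", "age_class", "season"))
    sel$model[1] == "(intercept)"
  }, logical(1))
  expect_gt(mean(wins), 0.5)
})

test_that("akaike weights and the equivalence rule reproduce a printed
           four-model selection table", {
  deltas <- c(0, 1.5, 2.5, 2.8)
  w <- akaike_weights(deltas)
  expect_equal(sum(w), 1)
  expect_equal(w[2] / w[1], exp(-0.75), tolerance = 1e-12)
  # the published table rounds these weights to 0.29 and 0.14; rounding
  # each to 2 decimals moves their ratio by at most ~0.026
  expect_lt(abs(w[2] / w[1] - 0.14 / 0.29), 0.026)
  expect_equal(equivalence_set(deltas), c(1L, 2L))
  expect_equal(equivalence_set(c(0, 2.4, 3)), 1L)
})

test_that("partial eta-squared reduces to R-squared and matches hand
           computed sums of squares on a balanced 2x2 design", {
  set.seed(61)
  x <- rnorm(40); y <- 2 * x + rnorm(40)
  f <- lm(y ~ x)
  expect_equal(partial_eta_squared(f, "x"), summary(f)$r.squared,
               tolerance = 1e-12)
  # balanced 2x2 with additive cell means; hand SS from group means
  a <- rep(c(0, 1), each = 20); b <- rep(c(0, 1), times = 20)
  set.seed(62)
  resp <- 1 + 2 * a + 3 * b + rnorm(40, sd = 0.5)
  d <- data.frame(resp, a = factor(a), b = factor(b))
  fit <- lm(resp ~ a + b, data = d)
  n_per <- 20
  ss_a <- n_per * sum((tapply(resp, a, mean) - mean(resp))^2)
  ss_b <- n_per * sum((tapply(resp, b, mean) - mean(resp))^2)
  cell <- tapply(resp, interaction(a, b), mean)
  ss_cells <- 10 * sum((cell - mean(resp))^2)
  ss_err <- sum(resp^2) - 40 * mean(resp)^2 - ss_cells
  ss_err_additive <- ss_err + (ss_cells - ss_a - ss_b)  # interaction -> error
  expect_equal(partial_eta_squared(fit, "a"), ss_a / (ss_a + ss_err_additive),
               tolerance = 1e-10)
  expect_equal(partial_eta_squared(fit, "b"), ss_b / (ss_b + ss_err_additive),
               tolerance = 1e-10)
  # a term with no effect in noise-free data explains nothing
  d0 <- data.frame(resp = 3 * b, a = factor(a), b = factor(b))
  f0 <- lm(resp ~ a + b, data = d0)
  expect_equal(partial_eta_squared(f0, "a"), 0, tolerance = 1e-12)
  expect_error(partial_eta_squared(fit, "c"), class = "cetacond_bad_argument")
})

test_that("ground-truth verdicts follow the hypothesized signs", {
  cfg <- default_config()
  m <- generate_morphometrics(cfg, n = 200, seed = 71)
  q <- m$mass_kg / m$length_cm^2
  f <- fit_condition_lm(q, m, c("cod_class", "age_class"))
  v <- ground_truth_assess(f, c("cod_class", "age_class"))
  expect_equal(v[["cod"]], "+")
  expect_equal(v[["age"]], "+")
  expect_equal(v[["season"]], "n/a")
  # invert the response: adults become lowest, chronic highest
  f2 <- fit_condition_lm(-q, m, c("cod_class", "age_class", "season"))
  v2 <- ground_truth_assess(f2, c("cod_class", "age_class"))
  expect_equal(v2[["cod"]], "-")
  expect_equal(v2[["age"]], "-")
})

test_that("index ranking reproduces the published decision pattern", {
  # the published verdict/fit pattern: mass-based indices retain COD and
  # age with the hypothesized signs; mass/length fits best but is
  # size-dependent; scaling exponent 2.33 selects the squared ratio
  report <- data.frame(
    index = c("ventral_blubber", "blubber_over_girth", "blubber_over_length",
              "girth_over_length", "mass_over_length", "fulton_K",
              "quetelet", "relative_condition", "residual_index",
              "scaled_mass"),
    verdict_cod = "+",
    verdict_age = c("+", "-", "-", "n/a", "+", "-", "+", "+", "+", "n/a"),
    verdict_season = c("+", "+", "+", "-", "n/a", "n/a", "n/a", "n/a",
                       "n/a", "n/a"),
    retained_any = TRUE,
    adj_r2 = c(0.22, 0.09, 0.15, 0.19, 0.72, 0.17, 0.50, 0.25, 0.21, 0.14),
    eta2_cod = c(0.15, 0.14, 0.14, 0.19, 0.17, 0.13, 0.19, 0.17, 0.11,
                 0.14),
    stringsAsFactors = FALSE)
  rk <- rank_indices(report, beta = 2.33, r_mass_length = 0.8)
  expect_equal(rk$recommended, "quetelet")
  # exponent 1 and a size-free mass/length ratio: no override, best fit wins
  rk2 <- rank_indices(report, beta = 1, r_mass_length = 0.05)
  expect_equal(rk2$recommended, "mass_over_length")
  # every index contradicting the age assumption: no recommendation
  report$verdict_age <- "-"
  rk3 <- rank_indices(report, beta = 2.33, r_mass_length = 0.8)
  expect_true(is.na(rk3$recommended))
  expect_true(any(grepl("no recommendation", rk3$trace)))
})

test_that("single-stratum inputs drop the degenerate candidates", {
  cfg <- default_config()
  m <- generate_morphometrics(cfg, n = 150, seed = 81)
  m$cod_class <- "acute"
  ev <- evaluate_indices(m)
  expect_true(all(ev$report$verdict_cod == "n/a"))
  expect_false(any(ev$report$retained_cod))
})
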