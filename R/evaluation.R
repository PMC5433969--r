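# Ground-truthing framework for the condition indices: homogeneity check,
# linear models of index ~ strata, exhaustive information-criterion model
# selection with Akaike weights, partial eta-squared effect sizes,
# directional assumption verdicts, and the ranking procedure that picks the
# recommended index.

#' Levene/Brown-Forsythe test for homogeneity of variance
#'
#' Tests equality of group variances via an ANOVA on absolute deviations
#' from the group center (mean by default; median gives the
#' Brown-Forsythe variant). Delegates to [car::leveneTest()].
#'
#' @param values Numeric response vector.
#' @param groups Group labels (coerced to factor).
#' @param center `"mean"` or `"median"`.
#' @return List with `statistic` (W), `p_value` and `df` (numerator,
#'   denominator).
#' @export
levene_test <- function(values, groups, center = c("mean", "median")) {
  center <- match.arg(center)
  g <- factor(groups)
  if (nlevels(g) < 2)
    cc_stop("need at least 2 groups", "cetacond_insufficient_data")
  if (any(table(g) < 2))
    cc_stop("every group needs at least 2 observations",
            "cetacond_insufficient_data")
  dev <- abs(values - stats::ave(values, g,
                                 FUN = if (center == "mean") mean else
                                   stats::median))
  if (stats::sd(dev) == 0)  # identical spread everywhere: W = 0 exactly
    return(list(statistic = 0, p_value = 1,
                df = c(nlevels(g) - 1, length(values) - nlevels(g))))
  res <- car::leveneTest(values, g,
                         center = if (center == "mean") mean else median)
  list(statistic = res[1, "F value"], p_value = res[1, "Pr(>F)"],
       df = c(res[1, "Df"], res[2, "Df"]))
}

#' Akaike weights from information-criterion values
#'
#' `w_i = exp(-delta_i / 2) / sum_j exp(-delta_j / 2)` where `delta_i` is
#' the criterion difference to the best model.
#'
#' @param criterion Vector of AIC/AICc values, or deltas if already
#'   baselined (the formula is invariant to the baseline).
#' @return Numeric vector of weights summing to 1.
#' @export
akaike_weights <- function(criterion) {
  delta <- criterion - min(criterion)
  w <- exp(-delta / 2)
  w / sum(w)
}

#' Information-criterion equivalence set
#'
#' Models within `threshold` criterion units of the best model are
#' considered of equivalent fit to the data (the conventional threshold is
#' a delta of 2).
#'
#' @param criterion Vector of AIC/AICc values or deltas.
#' @param threshold Delta under which models count as equivalent.
#' @return Integer indices of the equivalent models (always includes the
#'   best one).
#' @export
equivalence_set <- function(criterion, threshold = 2) {
  which(criterion - min(criterion) < threshold)
}

# all subsets of `candidates` respecting marginality: an interaction
# "a:b" enters only together with both main effects
enumerate_model_terms <- function(candidates) {
  mains <- candidates[!grepl(":", candidates)]
  inters <- candidates[grepl(":", candidates)]
  base <- lapply(seq_len(2^length(mains)) - 1, function(mask) {
    mains[bitwAnd(mask, 2^(seq_along(mains) - 1)) > 0]
  })
  out <- base
  for (sub in base) {
    ok_inters <- inters[vapply(strsplit(inters, ":"), function(p)
      all(p %in% sub), logical(1))]
    if (length(ok_inters) > 0)
      for (mask in seq_len(2^length(ok_inters) - 1))
        out <- c(out, list(c(sub,
          ok_inters[bitwAnd(mask, 2^(seq_along(ok_inters) - 1)) > 0])))
  }
  out
}

#' Exhaustive information-criterion model selection
#'
#' Enumerates every marginality-respecting subset of the candidate terms
#' (what MuMIn's `dredge` does for a global model), fits each candidate,
#' and ranks by AIC or AICc with Akaike weights. Models that fail to fit,
#' do not converge, or are rank-deficient are flagged and excluded from the
#' weight normalization.
#'
#' @param data Model frame containing the response and candidate terms.
#' @param response Response column name.
#' @param candidates Character vector of candidate terms; interactions as
#'   `"a:b"`.
#' @param criterion `"AIC"` or `"AICc"`.
#' @param fitter Function `(formula, data) -> fit`. Defaults to
#'   [stats::lm()]. Must error (not silently misfit) on failure.
#' @return An object of class `selection_table`: a data frame with one row
#'   per fitted model (`model` label, `df`, criterion value, `delta`,
#'   `weight`) sorted ascending by criterion, with attributes `best_fit`
#'   (the fitted object), `best_terms`, `fits` (all fitted objects in table
#'   order), `equivalent` (`TRUE` when the two best differ by < 2),
#'   `equivalence_set` (model labels with `delta < 2`) and `failed`
#'   (labels of models excluded).
#' @export
all_subsets_select <- function(data, response, candidates,
                               criterion = c("AIC", "AICc"),
                               fitter = NULL) {
  criterion <- match.arg(criterion)
  if (length(candidates) == 0)
    cc_stop("empty candidate set", "cetacond_bad_candidates")
  fitter <- fitter %||% function(formula, data) {
    fit <- stats::lm(formula, data = data)
    if (anyNA(stats::coef(fit)))
      cc_stop(paste0("rank-deficient design; aliased: ",
                     paste(names(stats::coef(fit))[is.na(stats::coef(fit))],
                           collapse = ", ")), "cetacond_singular_design")
    fit
  }
  term_sets <- enumerate_model_terms(candidates)
  labels <- vapply(term_sets, function(tt)
    if (length(tt) == 0) "(intercept)" else paste(tt, collapse = " + "),
    character(1))
  fits <- vector("list", length(term_sets))
  crit <- df <- rep(NA_real_, length(term_sets))
  for (i in seq_along(term_sets)) {
    rhs <- if (length(term_sets[[i]]) == 0) "1" else
      paste(term_sets[[i]], collapse = " + ")
    fml <- stats::as.formula(paste(response, "~", rhs))
    fit <- tryCatch(fitter(fml, data), error = function(e) NULL)
    if (!is.null(fit)) {
      cv <- tryCatch(
        if (criterion == "AIC") stats::AIC(fit) else aicc(fit),
        error = function(e) NA_real_)
      if (is.finite(cv)) {
        fits[[i]] <- fit
        crit[i] <- cv
        df[i] <- attr(stats::logLik(fit), "df")
      }
    }
  }
  ok <- !is.na(crit)
  if (!any(ok))
    cc_stop("no candidate model could be fitted", "cetacond_fit_failure")
  tab <- data.frame(model = labels[ok], df = df[ok], criterion = crit[ok],
                    stringsAsFactors = FALSE)
  names(tab)[3] <- criterion
  ord <- order(tab[[criterion]])
  tab <- tab[ord, , drop = FALSE]
  rownames(tab) <- NULL
  tab$delta <- tab[[criterion]] - tab[[criterion]][1]
  tab$weight <- akaike_weights(tab[[criterion]])
  keep_sets <- term_sets[ok][ord]
  structure(tab, class = c("selection_table", "data.frame"),
            best_fit = fits[ok][ord][[1]],
            best_terms = keep_sets[[1]],
            term_sets = keep_sets,
            fits = fits[ok][ord],
            equivalent = nrow(tab) > 1 && tab$delta[2] < 2,
            equivalence_set = tab$model[tab$delta < 2],
            failed = labels[!ok],
            criterion = criterion)
}

#' Linear model of a condition index on the stranding strata
#'
#' Ordinary least squares with treatment-coded factors. Reference levels
#' are `acute` (cause of death), `adult` (age class) and `nonbreeding`
#' (season), so each hypothesized condition deficit appears as a negative
#' coefficient.
#'
#' @param index_values Numeric vector of index values, one per record.
#' @param records Morphometric records aligned with `index_values`.
#' @param terms Character vector of model terms among `cod_class`,
#'   `age_class`, `season` and `age_class:season`; empty for the
#'   intercept-only model.
#' @return List of class `condition_lm`: the `lm` fit plus `adj_r2`,
#'   `aic`, `aicc`, the coefficient table, and Type II sums of squares.
#' @export
fit_condition_lm <- function(index_values, records, terms = character(0)) {
  d <- condition_model_frame(index_values, records)
  needed <- unique(unlist(strsplit(terms, ":")))
  for (v in needed)
    if (nlevels(droplevels(d[[v]])) < 2)
      cc_stop(paste0("factor '", v, "' has fewer than 2 observed levels"),
              "cetacond_singular_design")
  rhs <- if (length(terms) == 0) "1" else paste(terms, collapse = " + ")
  fit <- stats::lm(stats::as.formula(paste("index ~", rhs)), data = d)
  if (anyNA(stats::coef(fit)))
    cc_stop(paste0("rank-deficient design; aliased: ",
                   paste(names(stats::coef(fit))[is.na(stats::coef(fit))],
                         collapse = ", ")), "cetacond_singular_design")
  sm <- summary(fit)
  adj_r2 <- if (length(terms) == 0 || stats::sd(d$index) == 0) 0 else
    sm$adj.r.squared
  structure(list(fit = fit,
                 adj_r2 = adj_r2,
                 aic = stats::AIC(fit), aicc = aicc(fit),
                 coefficients = sm$coefficients,
                 ss = if (length(terms) == 0) NULL else
                   tryCatch(car::Anova(fit, type = 2),
                            error = function(e) NULL)),
            class = "condition_lm")
}

# model frame with the documented reference levels
condition_model_frame <- function(index_values, records) {
  d <- data.frame(index = index_values,
                  cod_class = factor(records$cod_class,
                                     levels = c("acute", "chronic")),
                  age_class = factor(records$age_class,
                                     levels = c("adult", "calf", "juvenile")),
                  season = factor(records$season,
                                  levels = c("nonbreeding", "breeding")))
  d[!is.na(d$index), , drop = FALSE]
}

#' Partial eta-squared for a model term
#'
#' `eta_p^2 = SS_term / (SS_term + SS_error)`: the share of variance
#' explained by one predictor net of the others. Sums of squares are
#' Type II by default (via [car::Anova()]); Type I (sequential) and
#' Type III are available.
#'
#' @param fit A fitted `lm` (or a `condition_lm`).
#' @param term Term label as it appears in the ANOVA table.
#' @param type Sums-of-squares type: 1, 2 or 3.
#' @return Partial eta-squared in `[0, 1]`.
#' @export
partial_eta_squared <- function(fit, term, type = 2) {
  if (inherits(fit, "condition_lm")) fit <- fit$fit
  terms_all <- attr(stats::terms(fit), "term.labels")
  if (!(term %in% terms_all))
    cc_stop(paste0("term '", term, "' not in the fitted model"),
            "cetacond_bad_argument")
  resp <- stats::model.response(stats::model.frame(fit))
  if (stats::sd(resp) == 0)
    cc_stop("zero response variance: partial eta-squared undefined",
            "cetacond_domain_error")
  at <- tryCatch(switch(as.character(type),
                        "1" = stats::anova(fit),
                        "2" = car::Anova(fit, type = 2),
                        "3" = car::Anova(fit, type = 3),
                        cc_stop("type must be 1, 2 or 3",
                                "cetacond_bad_argument")),
                 cetacond_error = function(e) stop(e),
                 error = function(e) NULL)
  if (is.null(at)) {
    # saturated (zero-residual) fit: the ANOVA helpers refuse; fall back
    # to marginal sums of squares by refitting without the term
    rss_full <- sum(stats::residuals(fit)^2)
    keep <- setdiff(terms_all, term)
    mf <- stats::model.frame(fit)
    fml <- stats::reformulate(if (length(keep) == 0) "1" else keep,
                              response = as.name(names(mf)[1]))
    reduced <- stats::lm(fml, data = mf)
    ss_term <- sum(stats::residuals(reduced)^2) - rss_full
    tot <- sum((resp - mean(resp))^2)
    if (ss_term < 1e-12 * tot) return(0)
    return(ss_term / (ss_term + rss_full))
  }
  sscol <- grep("Sum Sq", colnames(at), value = TRUE)[1]
  rows <- trimws(rownames(at))
  ss_term <- at[[sscol]][rows == term]
  ss_err <- at[[sscol]][rows == "Residuals"]
  if (ss_term + ss_err == 0)
    cc_stop("zero explained and residual sums of squares",
            "cetacond_domain_error")
  ss_term / (ss_term + ss_err)
}

#' Directional ground-truthing verdicts for a selected model
#'
#' Scores the three a-priori assumptions about a valid condition index:
#' (1) chronic cases are in poorer condition than acute cases, (2) adults
#' are in the best condition of the age classes, (3) condition is lower in
#' the breeding season. A term retained in the best model with the
#' hypothesized direction scores `"+"`, retained with a contrary pattern
#' `"-"`, and dropped `"n/a"`.
#'
#' @param fit The best model (`lm` from [fit_condition_lm()] /
#'   [all_subsets_select()]) with the package's reference levels.
#' @param retained_terms Terms of that model.
#' @return Named character vector with elements `cod`, `age`, `season`.
#' @export
ground_truth_assess <- function(fit, retained_terms) {
  if (inherits(fit, "condition_lm")) fit <- fit$fit
  cf <- stats::coef(fit)
  verdict <- c(cod = "n/a", age = "n/a", season = "n/a")
  if ("cod_class" %in% retained_terms)
    verdict["cod"] <- if (cf[["cod_classchronic"]] < 0) "+" else "-"
  if ("age_class" %in% retained_terms) {
    lev <- grep("^age_class", names(cf), value = TRUE)
    lev <- lev[!grepl(":", lev)]
    verdict["age"] <- if (all(cf[lev] < 0)) "+" else "-"
  }
  if ("season" %in% retained_terms)
    verdict["season"] <- if (cf[["seasonbreeding"]] < 0) "+" else "-"
  verdict
}

#' Rank the condition indices and recommend one
#'
#' The ranking procedure: (i) discard indices whose age-class verdict is
#' `"-"` or whose best model retained none of the tested covariates;
#' (ii) carry adjusted R-squared and the cause-of-death partial eta-squared
#' for the survivors; (iii) apply the size-independence override -- when
#' mass/length correlates with length beyond `r_threshold`, only the
#' surviving mass/length^k family member whose exponent k is nearest the
#' fitted allometric exponent stays in contention; (iv) recommend the surviving
#' index with the highest adjusted R-squared (ties broken by the
#' cause-of-death effect size). Every step is recorded in an audit trace.
#'
#' @param report Data frame with one row per index: columns `index`,
#'   `verdict_cod`, `verdict_age`, `verdict_season`, `retained_any`
#'   (logical), `adj_r2`, `eta2_cod`.
#' @param beta Fitted nonlinear allometric exponent.
#' @param r_mass_length Correlation of mass/length with length (the
#'   size-independence diagnostic for the k = 1 index).
#' @param r_threshold Absolute correlation beyond which the override fires.
#' @return List of class `index_ranking`: `recommended` (index name or
#'   `NA`), `survivors` (data frame) and `trace` (character vector).
#' @export
rank_indices <- function(report, beta, r_mass_length, r_threshold = 0.3) {
  trace <- character(0)
  note <- function(...) trace <<- c(trace, paste0(...))
  keep <- report$verdict_age != "-" & report$retained_any
  note("step 1: discarded for contrary age-class pattern or empty model: ",
       if (any(!keep)) paste(report$index[!keep], collapse = ", ") else
         "none")
  surv <- report[keep, , drop = FALSE]
  if (nrow(surv) == 0) {
    note("no surviving index: no recommendation")
    return(structure(list(recommended = NA_character_, survivors = surv,
                          trace = trace), class = "index_ranking"))
  }
  note("step 2: survivors with adjusted R-squared / COD partial eta-squared: ",
       paste(sprintf("%s (%.3f / %s)", surv$index, surv$adj_r2,
                     ifelse(is.na(surv$eta2_cod), "-",
                            sprintf("%.3f", surv$eta2_cod))),
             collapse = "; "))
  family <- c(mass_over_length = 1, quetelet = 2, fulton_K = 3)
  family <- family[names(family) %in% surv$index]
  if (length(family) > 0 && is.finite(beta) && is.finite(r_mass_length) &&
      abs(r_mass_length) > r_threshold) {
    k_star <- names(family)[which.min(abs(family - beta))]
    drop <- surv$index %in% names(family) & surv$index != k_star
    note("step 3: size-independence override active ",
         sprintf("(|r| = %.2f > %.2f, beta = %.2f -> keep %s): dropped %s",
                 abs(r_mass_length), r_threshold, beta, k_star,
                 if (any(drop)) paste(surv$index[drop], collapse = ", ")
                 else "none"))
    surv <- surv[!drop, , drop = FALSE]
  } else {
    note("step 3: size-independence override inactive")
  }
  if (nrow(surv) == 0) {
    note("no surviving index after override: no recommendation")
    return(structure(list(recommended = NA_character_, survivors = surv,
                          trace = trace), class = "index_ranking"))
  }
  ord <- order(-surv$adj_r2, -ifelse(is.na(surv$eta2_cod), -Inf,
                                     surv$eta2_cod))
  surv <- surv[ord, , drop = FALSE]
  note("step 4: recommended index = ", surv$index[1])
  structure(list(recommended = surv$index[1], survivors = surv,
                 trace = trace), class = "index_ranking")
}

#' Run the full ground-truthing framework over all ten indices
#'
#' Computes the index table, performs exhaustive AIC(c) selection of
#' `index ~ cod_class + age_class + season + age_class:season` for each
#' index, scores the directional assumptions, computes partial eta-squared
#' for retained terms and the adjusted R-squared of the best model, fits
#' the nonlinear allometry for the scaling exponent, evaluates
#' size-independence of each index, and ranks the indices.
#'
#' Strata observed at fewer than two levels are removed from the candidate
#' set (their verdicts become `"n/a"` throughout).
#'
#' @param records Morphometric records.
#' @param criterion `"AIC"` (default for this large-sample stage) or
#'   `"AICc"`.
#' @param r_threshold Override threshold passed to [rank_indices()].
#' @return List of class `index_evaluation`: `report` (one row per index
#'   with retained flags, verdicts, effect sizes, adjusted R-squared and
#'   size-independence r), `selections` (per-index selection tables),
#'   `allometry` (the [fit_nonlinear_allometry()] result), `ranking`, and
#'   `index_table`.
#' @export
evaluate_indices <- function(records, criterion = "AIC",
                             r_threshold = 0.3) {
  idx <- condition_indices(records)
  candidates <- c("cod_class", "age_class", "season", "age_class:season")
  observed <- vapply(c("cod_class", "age_class", "season"), function(v)
    length(unique(stats::na.omit(records[[v]]))) >= 2, logical(1))
  drop_terms <- names(observed)[!observed]
  if (length(drop_terms) > 0)
    candidates <- candidates[!vapply(strsplit(candidates, ":"), function(p)
      any(p %in% drop_terms), logical(1))]
  if (length(candidates) == 0)
    cc_stop("no stratum has 2 observed levels: nothing to evaluate",
            "cetacond_insufficient_data")

  allo <- fit_nonlinear_allometry(records)
  selections <- list()
  rows <- list()
  for (ix in index_names()) {
    vals <- idx[[ix]]
    # rescale to unit variance: partial eta-squared, adjusted R-squared,
    # verdicts and criterion deltas are invariant, and it keeps the
    # sums-of-squares of the smallest-magnitude indices (kg/cm^3) away
    # from floating-point underflow in the ANOVA decomposition
    if (stats::sd(vals, na.rm = TRUE) > 0)
      vals <- vals / stats::sd(vals, na.rm = TRUE)
    si_r <- tryCatch(size_independence(vals, records$length_cm)$r,
                     error = function(e) NA_real_)
    row <- data.frame(index = ix, retained_cod = FALSE, retained_age = FALSE,
                      retained_season = FALSE, retained_any = FALSE,
                      verdict_cod = "n/a", verdict_age = "n/a",
                      verdict_season = "n/a", eta2_cod = NA_real_,
                      eta2_age = NA_real_, eta2_season = NA_real_,
                      adj_r2 = NA_real_, size_independence_r = si_r,
                      stringsAsFactors = FALSE)
    sel <- tryCatch({
      d <- condition_model_frame(vals, records)
      all_subsets_select(d, "index", candidates, criterion = criterion)
    }, error = function(e) NULL)
    if (!is.null(sel)) {
      selections[[ix]] <- sel
      best <- attr(sel, "best_fit")
      terms <- attr(sel, "best_terms")
      verdicts <- ground_truth_assess(best, terms)
      row$retained_cod <- "cod_class" %in% terms
      row$retained_age <- "age_class" %in% terms
      row$retained_season <- "season" %in% terms
      row$retained_any <- length(terms) > 0
      row$verdict_cod <- verdicts[["cod"]]
      row$verdict_age <- verdicts[["age"]]
      row$verdict_season <- verdicts[["season"]]
      row$adj_r2 <- if (length(terms) == 0) 0 else
        summary(best)$adj.r.squared
      eta <- function(tm) if (tm %in% terms)
        partial_eta_squared(best, tm) else NA_real_
      row$eta2_cod <- eta("cod_class")
      row$eta2_age <- eta("age_class")
      row$eta2_season <- eta("season")
    }
    rows[[ix]] <- row
  }
  report <- do.call(rbind, rows)
  rownames(report) <- NULL
  r_ml <- report$size_independence_r[report$index == "mass_over_length"]
  ranking <- rank_indices(report, beta = allo$beta, r_mass_length = r_ml,
                          r_threshold = r_threshold)
  structure(list(report = report, selections = selections,
                 allometry = allo, ranking = ranking, index_table = idx),
            class = "index_evaluation")
}
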