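# The cohort statistics layer: length ANOVA with Tukey contrasts,
# stepwise-AIC logistic survival models with per-scenario confidence
# bands, the mixed-model singular-fit check, multinomial injury models,
# the pump-type comparison, and nonparametric tests on the sensor-derived
# parameters.

#' Significance stars
#'
#' Bins p-values exactly as printed on the figures: ns (> 0.05),
#' * (0.05-0.01), ** (0.01-0.001), *** (0.001-0.0001), **** (< 0.0001).
#'
#' @param p Numeric p-value(s).
#' @return Character vector of star labels.
#' @export
star_bins <- function(p) {
  cut(p, breaks = c(-Inf, 1e-4, 1e-3, 1e-2, 5e-2, Inf),
      labels = c("****", "***", "**", "*", "ns"), right = FALSE) |>
    as.character()
}

#' Fish length ANOVA across scenarios
#'
#' Per species: one-way ANOVA of length on scenario, with Tukey-corrected
#' pairwise comparisons reported only when the omnibus F test is
#' significant at 0.05.
#'
#' @param records Coded fish table with `species`, `scenario`,
#'   `length_mm`.
#' @param alpha Omnibus significance level gating the post hoc
#'   comparisons (default 0.05).
#' @return Named list per species: `p` (omnibus), `anova` (the aov fit)
#'   and `tukey` (data frame of pairwise contrasts, or NULL).
#' @export
anova_length <- function(records, alpha = 0.05) {
  out <- list()
  for (sp in unique(records$species)) {
    d <- records[records$species == sp & !is.na(records$length_mm), , drop = FALSE]
    d$scenario <- factor(d$scenario)
    counts <- table(d$scenario)
    if (length(counts) < 2L || sum(counts >= 2L) < 2L) {
      stop("InsufficientData: need >= 2 scenarios with >= 2 fish for ", sp,
           call. = FALSE)
    }
    fit <- stats::aov(length_mm ~ scenario, data = d)
    p <- summary(fit)[[1L]][["Pr(>F)"]][1L]
    tukey <- NULL
    if (is.finite(p) && p < alpha) {
      tk <- stats::TukeyHSD(fit)$scenario
      tukey <- data.frame(contrast = rownames(tk), tk, row.names = NULL)
    }
    out[[sp]] <- list(p = p, anova = fit, tukey = tukey)
  }
  out
}

# strata (scenarios) in which every fish survived: logistic coefficients
# for them are infinite, so they are set aside before fitting and flagged
all_survived_strata <- function(records) {
  surv <- tapply(records$survival, records$scenario, mean)
  names(surv)[!is.na(surv) & surv >= 1]
}

#' Stepwise-AIC logistic survival model for one species
#'
#' Bernoulli logistic regression of survival (1 = alive) on impeller
#' speed (discrete), fish length (continuous) and their interaction,
#' reduced by both-direction stepwise AIC selection. Strata in which
#' every fish survived are excluded before fitting (their coefficients
#' and standard errors would be infinite) and are reported. Per-scenario
#' predicted survival with 95 percent confidence bands is evaluated at a
#' reference length (default: the species' mean length), via the
#' asymptotic covariance on the logit scale.
#'
#' @param records Coded fish table for one species with `survival`,
#'   `scenario`, `rpm`, `length_mm` columns.
#' @param reference_length_mm Length at which scenario predictions are
#'   made (default: mean observed length).
#' @param full Full-model formula (default
#'   `survival ~ rpm_f * length_mm`).
#' @return Object of class `fit_result`: the selected `model`,
#'   `coefficients` table, `selected_terms`, `aic`, `excluded_strata`,
#'   and `predictions` (scenario, estimate, lo95, hi95).
#' @export
fit_survival_logistic <- function(records, reference_length_mm = NULL,
                                  full = survival ~ rpm_f * length_mm) {
  d <- records[!is.na(records$length_mm), , drop = FALSE]
  excluded <- all_survived_strata(d)
  d <- d[!(d$scenario %in% excluded), , drop = FALSE]
  if (nrow(d) == 0L || length(unique(d$survival)) < 2L) {
    stop("CompleteSeparation: no variation in survival after exclusions",
         call. = FALSE)
  }
  d$rpm_f <- factor(d$rpm)
  if (nlevels(d$rpm_f) < 2L) {
    full <- stats::update(full, . ~ length_mm)
  }
  fit_full <- stats::glm(full, family = stats::binomial(), data = d)
  sel <- stats::step(fit_full, direction = "both", trace = 0,
                     scope = list(lower = ~1))
  if (is.null(reference_length_mm)) {
    reference_length_mm <- mean(d$length_mm)
  }
  preds <- scenario_predictions(sel, d, reference_length_mm)
  fit_result(sel, predictions = preds, excluded_strata = excluded)
}

scenario_predictions <- function(model, d, reference_length_mm) {
  scen <- unique(d[, intersect(c("scenario", "rpm_f"), names(d)), drop = FALSE])
  scen <- scen[!duplicated(scen$scenario), , drop = FALSE]
  nd <- scen
  nd$length_mm <- reference_length_mm
  pr <- stats::predict(model, newdata = nd, type = "link", se.fit = TRUE)
  data.frame(
    scenario = scen$scenario,
    reference_length_mm = reference_length_mm,
    estimate = stats::plogis(pr$fit),
    lo95 = stats::plogis(pr$fit - 1.96 * pr$se.fit),
    hi95 = stats::plogis(pr$fit + 1.96 * pr$se.fit),
    row.names = NULL
  )
}

fit_result <- function(model, predictions = NULL, excluded_strata = character(0),
                       notes = character(0)) {
  sm <- summary(model)
  co <- if (inherits(model, "multinom_fit")) model$coefficients
        else stats::coef(sm)
  structure(
    list(model = model,
         coefficients = co,
         selected_terms = attr(stats::terms(stats::formula(model)),
                               "term.labels"),
         aic = stats::AIC(model),
         predictions = predictions,
         excluded_strata = excluded_strata,
         notes = notes),
    class = "fit_result"
  )
}

#' @export
print.fit_result <- function(x, ...) {
  cat("<fit_result> terms:",
      if (length(x$selected_terms)) paste(x$selected_terms, collapse = " + ")
      else "(intercept only)",
      sprintf(" AIC %.2f\n", x$aic))
  if (length(x$excluded_strata)) {
    cat("excluded all-survived strata:",
        paste(x$excluded_strata, collapse = ", "), "\n")
  }
  if (!is.null(x$predictions)) {
    print(x$predictions, digits = 3)
  }
  if (length(x$notes)) cat(paste("note:", x$notes, collapse = "\n"), "\n")
  invisible(x)
}

#' Should sample be a random effect? The singular-fit check
#'
#' Fish were introduced in samples of roughly 50-100; a sample-level
#' random intercept could absorb batch effects. Samples with fewer than
#' `min_per_sample` fish (default 6) are not representative and are set
#' aside for this check. If the fitted random-intercept model is singular
#' (random-effect variance collapses to zero) the simple logistic model
#' is recommended and all fish are used.
#'
#' @param records Coded fish table with `survival`, `rpm`, `sample_id`.
#' @param min_per_sample Minimum fish per sample for the mixed fit
#'   (default 6).
#' @return List with `decision` (`"simple"` or `"mixed"`), `singular`,
#'   `attempted`, `ranef_sd` and the fitted model (or NULL).
#' @export
mixed_model_check <- function(records, min_per_sample = 6L) {
  keep_ids <- names(which(table(records$sample_id) >= min_per_sample))
  d <- records[records$sample_id %in% keep_ids, , drop = FALSE]
  if (length(unique(d$sample_id)) < 2L) {
    return(list(decision = "simple", singular = NA, attempted = FALSE,
                ranef_sd = NA_real_, model = NULL))
  }
  d$rpm_f <- factor(d$rpm)
  form <- if (nlevels(d$rpm_f) >= 2L) survival ~ rpm_f + (1 | sample_id)
          else survival ~ 1 + (1 | sample_id)
  fit <- suppressMessages(suppressWarnings(
    lme4::glmer(form, data = d, family = stats::binomial())
  ))
  singular <- lme4::isSingular(fit, tol = 1e-4)
  sd_hat <- sqrt(unlist(lme4::VarCorr(fit))[1L])
  list(decision = if (singular) "simple" else "mixed",
       singular = singular, attempted = TRUE,
       ranef_sd = unname(sd_hat), model = fit)
}

#' Multinomial injury model with best-subset AIC selection
#'
#' Baseline-category multinomial model of injury class (or injury code)
#' on the given predictors, with the reference category "no injury"
#' (class 1). Model selection is exact best-subset AIC over all
#' marginality-respecting sub-models of the full formula (the candidate
#' set is small), which can never return a model with higher AIC than
#' the full or the null model. Per-scenario category probabilities with
#' 95 percent bands are obtained by sampling the asymptotic coefficient
#' distribution.
#'
#' @param records Coded fish table.
#' @param response Response column (default `"injury_class"`).
#' @param full Full-model RHS formula (default `~ rpm_f * length_mm`).
#' @param reference_length_mm Length for scenario predictions (default:
#'   mean observed length).
#' @param nsim Coefficient draws for the probability bands (default 500).
#' @return A `fit_result` whose `predictions` holds one row per scenario
#'   x category with `estimate`, `lo95`, `hi95`.
#' @export
fit_injury_multinomial <- function(records, response = "injury_class",
                                   full = ~ rpm_f * length_mm,
                                   reference_length_mm = NULL, nsim = 500L) {
  d <- records[!is.na(records$length_mm) & !is.na(records[[response]]), ,
               drop = FALSE]
  d$rpm_f <- factor(d$rpm)
  y <- factor(d[[response]])
  if (nlevels(y) < 2L) {
    stop("SingleCategory: only one injury category present", call. = FALSE)
  }
  if (nlevels(d$rpm_f) < 2L) {
    full <- stats::update(full, ~ length_mm)
  }
  candidates <- marginality_subsets(full)
  fits <- lapply(candidates, function(f) {
    fml <- stats::update(f, paste(response, "~ ."))
    fit_multinom(fml, d, ref = levels(y)[1L])
  })
  best <- fits[[which.min(vapply(fits, `[[`, numeric(1), "AIC"))]]
  if (is.null(reference_length_mm)) reference_length_mm <- mean(d$length_mm)
  preds <- multinom_scenario_predictions(best, d, reference_length_mm, nsim)
  fit_result(best, predictions = preds)
}

multinom_scenario_predictions <- function(fit, d, reference_length_mm, nsim) {
  if (is.null(d$scenario)) d$scenario <- paste0("rpm_", d$rpm_f)
  scen <- d[!duplicated(d$scenario), intersect(c("scenario", "rpm_f"),
                                               names(d)), drop = FALSE]
  nd <- scen
  nd$length_mm <- reference_length_mm
  P <- predict(fit, nd)
  draws <- NULL
  if (all(is.finite(fit$vcov))) {
    b0 <- as.numeric(t(fit$coefficients))
    L <- tryCatch(chol(fit$vcov), error = function(e) NULL)
    if (!is.null(L)) {
      Z <- matrix(stats::rnorm(nsim * length(b0)), nsim) %*% L
      draws <- array(NA_real_, c(nsim, nrow(nd), length(fit$levels)))
      tmp <- fit
      for (s in seq_len(nsim)) {
        tmp$coefficients[] <- t(matrix(b0 + Z[s, ], ncol = nrow(fit$coefficients)))
        draws[s, , ] <- predict(tmp, nd)
      }
    }
  }
  out <- expand.grid(scenario = scen$scenario, category = fit$levels,
                     KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  out$estimate <- as.numeric(P)
  if (!is.null(draws)) {
    qs <- apply(draws, c(2L, 3L), stats::quantile, probs = c(0.025, 0.975))
    out$lo95 <- as.numeric(qs[1L, , ])
    out$hi95 <- as.numeric(qs[2L, , ])
  } else {
    out$lo95 <- NA_real_; out$hi95 <- NA_real_
  }
  out
}

#' Pump-type survival comparison for roach
#'
#' Survival models over the three scenarios (fish-friendly pump at 468
#' and 550 rpm, conventional pump at 585 rpm), fit both with and without
#' fish length, each reduced by stepwise AIC from the scenario x length
#' (resp. scenario-only) full model. Conventional-vs-fish-friendly
#' contrasts are reported with Wald p-values and log-odds effect sizes.
#' A warning flag is raised when the length distributions differ across
#' scenarios (fish reaching the conventional pump naturally were much
#' smaller, so length-adjusted contrasts deserve caution).
#'
#' @param records Coded fish table (one species) containing all three
#'   scenarios, with a `scenario` column distinguishing them and a
#'   `pump` column (`"FNAFP"` / `"CAFP"`).
#' @param cafp_scenario Label of the conventional-pump scenario
#'   (default `"CAFP_585"`).
#' @return List with `with_length` and `without_length` `fit_result`s,
#'   `contrasts` (data frame), and `length_imbalance_p`.
#' @export
compare_pumps <- function(records, cafp_scenario = "CAFP_585") {
  d <- records[!is.na(records$length_mm), , drop = FALSE]
  d$scenario <- factor(d$scenario)
  if (nlevels(d$scenario) < 3L) {
    stop("MissingScenario: need all three scenarios, got ",
         paste(levels(d$scenario), collapse = ", "), call. = FALSE)
  }
  d$scenario <- stats::relevel(d$scenario, ref = cafp_scenario)
  imb_p <- summary(stats::aov(length_mm ~ scenario, data = d))[[1L]][["Pr(>F)"]][1L]

  fit_wl <- stats::step(
    stats::glm(survival ~ scenario * length_mm, stats::binomial(), d),
    direction = "both", trace = 0,
    scope = list(lower = ~scenario)   # the scenario contrast is the question
  )
  fit_nl <- stats::glm(survival ~ scenario, stats::binomial(), d)

  contrast_rows <- function(fit, label) {
    co <- stats::coef(summary(fit))
    rows <- grep("^scenario", rownames(co))
    data.frame(
      model = label,
      contrast = sub("^scenario", paste0(cafp_scenario, " vs "),
                     rownames(co)[rows]),
      effect_logodds = -co[rows, "Estimate"],   # CAFP minus FNAFP
      se = co[rows, "Std. Error"],
      p = co[rows, "Pr(>|z|)"],
      stars = star_bins(co[rows, "Pr(>|z|)"]),
      row.names = NULL
    )
  }
  list(
    with_length = fit_result(fit_wl,
                             predictions = scenario_predictions(fit_wl, d,
                                                                mean(d$length_mm))),
    without_length = fit_result(fit_nl,
                                predictions = scenario_predictions(fit_nl, d,
                                                                   mean(d$length_mm))),
    contrasts = rbind(contrast_rows(fit_wl, "with_length"),
                      contrast_rows(fit_nl, "without_length")),
    length_imbalance_p = imb_p,
    length_imbalance = is.finite(imb_p) && imb_p < 0.05
  )
}

#' Nonparametric tests on sensor-derived parameters
#'
#' Kruskal-Wallis omnibus test of a per-deployment parameter (nadir, LRP,
#' ROC or strain exposure duration) across scenarios; when significant,
#' pairwise two-sample Wilcoxon rank-sum tests with Bonferroni
#' correction. Deployments are unpaired across scenarios, hence rank-sum
#' rather than signed-rank tests.
#'
#' @param values Numeric parameter values, one per deployment.
#' @param scenario Scenario label per deployment.
#' @param alpha Omnibus gate for the pairwise tests (default 0.05).
#' @return List with `kw_p`, `pairwise` (data frame: pair, p_raw, p_adj
#'   = min(1, m * p_raw), stars; NULL if the omnibus is not significant)
#'   and `n_tests`.
#' @export
nonparametric_bds <- function(values, scenario, alpha = 0.05) {
  scenario <- factor(scenario)
  if (nlevels(scenario) < 2L) {
    stop("InsufficientData: need >= 2 scenarios", call. = FALSE)
  }
  kw <- stats::kruskal.test(values, scenario)
  pairwise <- NULL
  n_tests <- 0L
  if (kw$p.value < alpha) {
    lv <- levels(scenario)
    pairs <- utils::combn(lv, 2L)
    n_tests <- ncol(pairs)
    p_raw <- apply(pairs, 2L, function(pr) {
      suppressWarnings(stats::wilcox.test(values[scenario == pr[1L]],
                                          values[scenario == pr[2L]],
                                          exact = FALSE))$p.value
    })
    p_adj <- pmin(1, n_tests * p_raw)
    pairwise <- data.frame(
      a = pairs[1L, ], b = pairs[2L, ],
      p_raw = p_raw, p_adj = p_adj, stars = star_bins(p_adj)
    )
  }
  list(kw_p = kw$p.value, pairwise = pairwise, n_tests = n_tests)
}
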