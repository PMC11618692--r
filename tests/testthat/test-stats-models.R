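# The statistics layer: ANOVA, stepwise logistic models, the mixed-model
# singular-fit check, CART trees, multinomial models and the
# nonparametric sensor tests.

test_that("length ANOVA: null is flat, strong shifts are detected, Tukey gated", {
  set.seed(21)
  base_sample <- rnorm(30, 168, 10)
  d0 <- data.frame(species = "roach",
                   scenario = rep(c("a", "b", "c"), each = 30),
                   length_mm = rep(base_sample, 3))   # identical group samples
  r0 <- anova_length(d0)$roach
  expect_equal(r0$p, 1)   # F is exactly 0 when group means coincide
  expect_null(r0$tukey)

  d1 <- data.frame(species = "roach",
                   scenario = rep(c("a", "b"), each = 50),
                   length_mm = c(rnorm(50, 168, 10), rnorm(50, 198, 10)))
  r1 <- anova_length(d1)$roach
  expect_lt(r1$p, 0.001)
  expect_equal(nrow(r1$tukey), 1L)

  expect_error(anova_length(data.frame(species = "x", scenario = "a",
                                       length_mm = c(1, 2))),
               "InsufficientData")
})

test_that("ANOVA type-I error sits near 5% under the null", {
  set.seed(99)
  hits <- 0L
  reps <- 400L
  for (i in seq_len(reps)) {
    d <- data.frame(species = "s", scenario = rep(c("a", "b", "c"), each = 15),
                    length_mm = rnorm(45, 168, 20))
    if (anova_length(d)$s$p < 0.05) hits <- hits + 1L
  }
  expect_gt(hits / reps, 0.02)
  expect_lt(hits / reps, 0.09)
})

test_that("stepwise logistic drops null effects and recovers real ones", {
  set.seed(31)
  # both effects null: AIC reaches the null model at roughly the
  # P(chisq1 < 2)^3 ~ 0.60 rate of three successive AIC drop decisions
  dropped <- 0L
  for (i in 1:60) {
    d <- data.frame(
      survival = rbinom(500, 1, 0.7),
      rpm = rep(c(468, 550), each = 250),
      length_mm = rnorm(500, 200, 30),
      scenario = rep(c("FNAFP_468", "FNAFP_550"), each = 250)
    )
    fit <- fit_survival_logistic(d)
    if (length(fit$selected_terms) == 0L) dropped <- dropped + 1L
  }
  expect_gte(dropped / 60, 0.45)

  # a real length effect is retained and estimated with the right sign
  set.seed(32)
  d2 <- data.frame(rpm = rep(c(468, 550), each = 400),
                   length_mm = rnorm(800, 300, 60))
  d2$scenario <- paste0("FNAFP_", d2$rpm)
  d2$survival <- rbinom(800, 1, plogis(1 - 0.02 * (d2$length_mm - 300)))
  fit2 <- fit_survival_logistic(d2)
  expect_true("length_mm" %in% fit2$selected_terms)
  expect_lt(fit2$coefficients["length_mm", "Estimate"], 0)
  expect_true(all(fit2$predictions$lo95 <= fit2$predictions$estimate))
  expect_true(all(fit2$predictions$hi95 >= fit2$predictions$estimate))
})

test_that("all-survived strata are excluded before fitting, and flagged", {
  set.seed(33)
  d <- data.frame(
    rpm = rep(c(468, 468, 550), each = 100),
    length_mm = rnorm(300, 200, 30),
    scenario = rep(c("control_468", "FNAFP_468", "FNAFP_550"), each = 100),
    survival = c(rep(1L, 100), rbinom(200, 1, 0.6))
  )
  fit <- fit_survival_logistic(d)
  expect_equal(fit$excluded_strata, "control_468")
  expect_false("control_468" %in% fit$predictions$scenario)
})

test_that("stepwise AIC never beats the searched models' AIC", {
  set.seed(34)
  d <- data.frame(rpm = rep(c(468, 550), each = 200),
                  length_mm = rnorm(400, 250, 40))
  d$scenario <- paste0("FNAFP_", d$rpm)
  d$survival <- rbinom(400, 1, plogis(0.5 - 0.01 * (d$length_mm - 250)))
  d$rpm_f <- factor(d$rpm)
  fit <- fit_survival_logistic(d)
  full <- glm(survival ~ rpm_f * length_mm, binomial(), d)
  null <- glm(survival ~ 1, binomial(), d)
  expect_lte(fit$aic, AIC(full) + 1e-9)
  expect_lte(fit$aic, AIC(null) + 1e-9)
})

test_that("mixed-model check: singular under no batch effect, mixed under strong one", {
  set.seed(41)
  n_samp <- 12; per <- 40
  base <- data.frame(
    sample_id = rep(seq_len(n_samp), each = per),
    rpm = rep(c(468, 550), each = n_samp / 2 * per),
    length_mm = 200
  )
  d0 <- base
  d0$survival <- rbinom(nrow(d0), 1, 0.6)   # no sample structure
  chk0 <- mixed_model_check(d0)
  expect_true(chk0$attempted)
  expect_equal(chk0$decision, "simple")

  d1 <- base
  u <- rnorm(n_samp, 0, 2)                  # sd 2 on the logit scale
  d1$survival <- rbinom(nrow(d1), 1, plogis(0.4 + u[d1$sample_id]))
  chk1 <- mixed_model_check(d1)
  expect_equal(chk1$decision, "mixed")
  expect_gt(chk1$ranef_sd, 0.5)

  tiny <- d0[d0$sample_id %in% 1:2, ][1:8, ]   # all samples below 6 fish
  tiny$sample_id <- rep(1:4, each = 2)
  chk2 <- mixed_model_check(tiny)
  expect_false(chk2$attempted)
  expect_equal(chk2$decision, "simple")
})

test_that("CART: separable data yields pure leaves, flat data yields no tree", {
  d <- data.frame(
    species = rep(c("eel", "bream"), each = 50),
    survival = rep(c(1L, 0L), each = 50),
    length_mm = rnorm(100, 300, 30)
  )
  tr <- fit_decision_tree(d, "survival", c("species", "length_mm"))
  expect_false(tr$no_tree)
  expect_equal(tr$nodes$split[tr$nodes$id == 1], "species in {bream}")
  leaves <- tr$nodes[tr$nodes$id > 1, ]
  expect_true(all(pmax(leaves$p_0, leaves$p_1) == 1))

  flat <- data.frame(survival = rep(1L, 80), length_mm = rnorm(80))
  tr2 <- fit_decision_tree(flat, "survival", "length_mm")
  expect_true(tr2$no_tree)
  expect_equal(tr2$nodes$label, "Alive")
})

test_that("CART node counts and proportions equal brute-force counting; coverage adds up", {
  set.seed(51)
  d <- data.frame(
    type = rep(c("pump", "control"), c(200, 60)),
    rpm = sample(c(468, 550), 260, TRUE),
    length_mm = c(rnorm(200, 350, 60), rnorm(60, 350, 60))
  )
  p_dead <- ifelse(d$type == "control", 0.02,
                   plogis(-1 + 0.015 * (d$length_mm - 350) +
                            0.8 * (d$rpm == 550)))
  d$survival <- 1L - rbinom(260, 1, p_dead)
  tr <- fit_decision_tree(d, "survival", c("type", "rpm", "length_mm"))
  expect_equal(tr$nodes$split[tr$nodes$id == 1], "type in {control}")

  nodes <- tr$nodes
  for (id in nodes$id) {
    kids <- nodes[nodes$id %in% c(2 * id, 2 * id + 1), ]
    if (nrow(kids) == 2) {
      expect_equal(sum(kids$n), nodes$n[nodes$id == id])
      expect_equal(sum(kids$coverage_pct), nodes$coverage_pct[nodes$id == id])
    }
  }
  # brute-force recount of the root's left child
  root <- tr$frame[[1]]
  left <- if (!is.na(root$split_cut)) d[[root$split_var]] < root$split_cut
          else d[[root$split_var]] %in% root$split_levels
  expect_equal(nodes$n[nodes$id == 2], sum(left))
  expect_equal(nodes$p_0[nodes$id == 2], mean(d$survival[left] == 0))
})

test_that("two-category multinomial agrees with binomial logistic to 1e-6", {
  set.seed(61)
  d <- data.frame(x = rnorm(300), z = rnorm(300))
  d$y <- factor(rbinom(300, 1, plogis(0.3 + 0.8 * d$x - 0.5 * d$z)))
  mfit <- fit_multinom(y ~ x + z, d)
  gfit <- glm(I(y == "1") ~ x + z, binomial(), d)
  expect_equal(unname(mfit$coefficients["1", ]), unname(coef(gfit)),
               tolerance = 1e-6)
  expect_equal(mfit$logLik, as.numeric(logLik(gfit)), tolerance = 1e-8)
})

test_that("multinomial probabilities sum to one and selection drops null predictors", {
  set.seed(62)
  d <- data.frame(rpm = rep(c(468, 550), each = 150),
                  length_mm = rnorm(300, 200, 30))
  d$injury_class <- factor(sample(1:3, 300, TRUE))   # uniform, no structure
  fit <- fit_injury_multinomial(d, nsim = 50)
  probs <- predict(fit$model, data.frame(rpm_f = factor(c(468, 550)),
                                         length_mm = c(150, 250)))
  expect_lt(max(abs(rowSums(probs) - 1)), 1e-9)
  expect_length(fit$selected_terms, 0)
  flat <- predict(fit$model, data.frame(rpm_f = factor(468), length_mm = 200))
  expect_equal(as.numeric(flat), rep(1 / 3, 3), tolerance = 0.12)
})

test_that("multinomial recovers a length-driven severe-injury slope", {
  set.seed(63)
  reps <- 20; hit <- 0
  for (i in seq_len(reps)) {
    len <- rnorm(400, 250, 50)
    eta_severe <- -0.5 + 0.02 * (len - 250)
    p_sev <- exp(eta_severe) / (1 + exp(eta_severe) + 0.8)
    p_sli <- 0.8 / (1 + exp(eta_severe) + 0.8)
    cls <- sapply(seq_along(len), function(j)
      sample(c("3", "2", "1"), 1,
             prob = c(p_sev[j], p_sli[j], 1 - p_sev[j] - p_sli[j])))
    d <- data.frame(rpm = 468, length_mm = len, injury_class = factor(cls))
    fit <- fit_multinom(injury_class ~ length_mm, d, ref = "1")
    if (fit$coefficients["3", "length_mm"] > 0) hit <- hit + 1
  }
  expect_gte(hit / reps, 0.95)
})

test_that("pump comparison flags the conventional pump when it is worse", {
  set.seed(71)
  d <- data.frame(
    scenario = rep(c("FNAFP_468", "FNAFP_550", "CAFP_585"), c(300, 300, 40)),
    length_mm = c(rnorm(600, 170, 25), rnorm(40, 120, 20))
  )
  p <- ifelse(d$scenario == "CAFP_585", 0.15,
              ifelse(d$scenario == "FNAFP_550", 0.62, 0.72))
  d$survival <- rbinom(nrow(d), 1, p)
  cmp <- compare_pumps(d)
  expect_true(cmp$length_imbalance)   # CAFP fish are much smaller
  expect_true(all(cmp$contrasts$p[cmp$contrasts$model == "without_length"] < 0.05))
  # CAFP survival estimate below both fish-friendly scenarios
  pr <- cmp$without_length$predictions
  expect_lt(pr$estimate[pr$scenario == "CAFP_585"],
            min(pr$estimate[pr$scenario != "CAFP_585"]))
  expect_error(compare_pumps(d[d$scenario != "CAFP_585", ]), "MissingScenario")
})

test_that("pump comparison stays quiet under identical survival generators", {
  set.seed(72)
  hits <- 0L; reps <- 40L
  for (i in seq_len(reps)) {
    d <- data.frame(
      scenario = rep(c("FNAFP_468", "FNAFP_550", "CAFP_585"), each = 120),
      length_mm = rnorm(360, 170, 25)
    )
    d$survival <- rbinom(360, 1, 0.6)
    cmp <- compare_pumps(d)
    if (any(cmp$contrasts$p[cmp$contrasts$model == "without_length"] < 0.05)) {
      hits <- hits + 1L
    }
  }
  # two contrasts at alpha = 0.05: null rejection rate should stay near nominal
  expect_lte(hits / reps, 0.2)
})

test_that("Kruskal-Wallis + Bonferroni pipeline: nulls quiet, shifts loud, m*p rule", {
  set.seed(81)
  vals <- c(rnorm(50, 0), rnorm(50, 1))   # 1 SD shift
  scen <- rep(c("a", "b"), each = 50)
  res <- nonparametric_bds(vals, scen)
  expect_lt(res$kw_p, 0.05)
  expect_lt(res$pairwise$p_adj, 0.05)

  vals3 <- c(rnorm(30), rnorm(30, 2), rnorm(30, 4))
  scen3 <- rep(c("a", "b", "c"), each = 30)
  res3 <- nonparametric_bds(vals3, scen3)
  expect_equal(res3$n_tests, 3L)
  expect_equal(res3$pairwise$p_adj, pmin(1, 3 * res3$pairwise$p_raw))
  expect_true(all(res3$pairwise$stars %in% c("ns", "*", "**", "***", "****")))

  same <- rep(c(1, 2, 3, 4, 5), 4)
  res0 <- nonparametric_bds(same, rep(c("a", "b"), each = 10))
  expect_gt(res0$kw_p, 0.9)
  expect_null(res0$pairwise)
  expect_error(nonparametric_bds(1:5, rep("a", 5)), "InsufficientData")
})

test_that("permuting scenario labels destroys the nonparametric significance", {
  set.seed(82)
  vals <- c(rnorm(40, 0), rnorm(40, 1.5))
  scen <- rep(c("a", "b"), each = 40)
  expect_lt(nonparametric_bds(vals, scen)$kw_p, 0.001)
  hits <- 0L; reps <- 200L
  for (i in seq_len(reps)) {
    if (nonparametric_bds(vals, sample(scen))$kw_p < 0.05) hits <- hits + 1L
  }
  expect_lt(hits / reps, 0.1)   # null calibration near alpha
})

test_that("significance stars bin exactly as printed", {
  expect_equal(star_bins(c(0.2, 0.03, 0.005, 5e-4, 5e-5)),
               c("ns", "*", "**", "***", "****"))
  expect_equal(star_bins(0.05), "ns")
  expect_equal(star_bins(0.01), "*")
})
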