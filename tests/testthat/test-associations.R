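test_that("endorsement percentages use completed surveys only", {
  e <- rbind(
    data.frame(participant_id = "a", occasion = 0:18,
               completed = c(rep(1, 16), 0, 0, 0),
               use_tobacco = c(rep(1, 4), rep(0, 12), NA, NA, NA),
               crave_alcohol = c(rep(0, 16), NA, NA, NA)),
    data.frame(participant_id = "b", occasion = 0:18, completed = 1,
               use_tobacco = 0, crave_alcohol = 0),
    data.frame(participant_id = "c", occasion = 0:18,
               completed = c(rep(1, 10), rep(0, 9)),
               use_tobacco = 0, crave_alcohol = c(rep(1, 10), rep(NA, 9)))
  )
  out <- endorsement_percentages(e)
  expect_equal(out$pct_use_tobacco[out$participant_id == "a"], 25)   # 4/16
  expect_equal(out$surveys_completed[out$participant_id == "a"], 16)
  expect_equal(out$pct_use_tobacco[out$participant_id == "b"], 0)    # 0/19
  expect_equal(out$pct_crave_alcohol[out$participant_id == "c"], 100)

  e_zero <- rbind(e, data.frame(participant_id = "d", occasion = 0:18,
                                completed = 0, use_tobacco = NA,
                                crave_alcohol = NA))
  expect_warning(out2 <- endorsement_percentages(e_zero), "zero completed")
  expect_false("d" %in% out2$participant_id)
})

# small scored cohort shared by the regression tests
assoc_fixture <- function(n = 120, seed = 17, preset = "clean") {
  st <- simulate_study(n = n, seed = seed, preset = preset, scales = "time")
  est <- score_scales(st$responses[st$responses$occasion == 0, ],
                      time_selection_bank())
  list(study = st, est = est, outcomes = participant_outcomes(st))
}

test_that("a zero-noise linear outcome is recovered exactly", {
  fx <- assoc_fixture()
  set.seed(1)
  out <- simulate_linear_outcomes(fx$outcomes, fx$est, beta = 4.2,
                                  beta_age = 0.3, beta_sex = 2,
                                  beta_surveys = -0.5, sd = 0)
  fit <- suppressWarnings(  # lm warns about the (intended) perfect fit
    fit_adjusted_models(out, fx$est, scales = "time",
                        outcome_cols = "pct_synthetic")
  )
  expect_equal(fit$estimate, 4.2, tolerance = 1e-8)
  expect_equal(fit$ci_low, 4.2, tolerance = 1e-6)
})

test_that("mean-centering leaves the log-k coefficient and CI unchanged", {
  fx <- assoc_fixture()
  set.seed(2)
  out <- simulate_linear_outcomes(fx$outcomes, fx$est, beta = 3, sd = 8)
  fit <- fit_adjusted_models(out, fx$est, scales = "time",
                             outcome_cols = "pct_synthetic")
  # uncentered reference fit
  e <- as.data.frame(fx$est)
  e <- e[e$phase == "phase2_baseline" & e$occasion == 0 & e$scale == "time", ]
  dat <- merge(out, e[, c("participant_id", "log_k")], by = "participant_id")
  ref <- lm(pct_synthetic ~ log_k + age + factor(sex) + surveys_completed,
            data = dat)
  expect_equal(fit$estimate, unname(coef(ref)["log_k"]), tolerance = 1e-10)
  expect_equal(c(fit$ci_low, fit$ci_high),
               unname(confint(ref, "log_k")[1, ]), tolerance = 1e-10)
})

test_that("coefficients are invariant to participant ordering", {
  fx <- assoc_fixture()
  set.seed(3)
  out <- simulate_linear_outcomes(fx$outcomes, fx$est, beta = 3, sd = 8)
  fit1 <- fit_adjusted_models(out, fx$est, scales = "time",
                              outcome_cols = "pct_synthetic")
  perm <- out[sample(nrow(out)), ]
  fit2 <- fit_adjusted_models(perm, fx$est, scales = "time",
                              outcome_cols = "pct_synthetic")
  expect_equal(fit1$estimate, fit2$estimate)
  expect_equal(fit1$p, fit2$p)
})

test_that("rank-deficient designs fail loudly naming the collinear column", {
  fx <- assoc_fixture(n = 60)
  set.seed(4)
  out <- simulate_linear_outcomes(fx$outcomes, fx$est, beta = 3, sd = 8)
  out$age <- 40  # constant covariate: centered age column is all zero
  expect_error(fit_adjusted_models(out, fx$est, scales = "time",
                                   outcome_cols = "pct_synthetic"),
               "age_c")
})

test_that("the full grid returns one row per scale-outcome pair with sane CIs", {
  st <- simulate_study(n = 97, seed = 19)
  est_cont <- score_scales(
    st$responses[st$responses$occasion == 0, ],
    validate_item_bank(rbind(as.data.frame(time_selection_bank()),
                             as.data.frame(monetary_selection_bank())))
  )
  est_mcq <- score_mcq(st$responses, mcq_bank())
  est_mcq$consistency <- NULL
  est <- rbind(est_cont, est_mcq)
  fit <- fit_adjusted_models(participant_outcomes(st), est)
  expect_equal(nrow(fit), 18)  # 3 scales x 6 outcomes
  expect_true(all(fit$ci_low <= fit$estimate & fit$estimate <= fit$ci_high))
  expect_true(all(fit$p >= 0 & fit$p <= 1))
  # the generative truth puts the strongest use-slope on tobacco
  time_rows <- fit[fit$predictor == "time", ]
  use_tob <- time_rows$estimate[time_rows$outcome == "pct_use_tobacco"]
  expect_gt(use_tob, time_rows$estimate[time_rows$outcome == "pct_use_alcohol"])
  expect_gt(use_tob, time_rows$estimate[time_rows$outcome == "pct_use_cannabis"])
})

test_that("BH adjustment is available but off by default", {
  fx <- assoc_fixture()
  set.seed(5)
  out <- simulate_linear_outcomes(fx$outcomes, fx$est, beta = 0, sd = 8)
  out$pct_other <- out$pct_synthetic + rnorm(nrow(out))
  fit0 <- fit_adjusted_models(out, fx$est, scales = "time",
                              outcome_cols = c("pct_synthetic", "pct_other"))
  expect_equal(fit0$p, fit0$p_adjusted)
  fit1 <- fit_adjusted_models(out, fx$est, scales = "time",
                              outcome_cols = c("pct_synthetic", "pct_other"),
                              p_adjust = "BH")
  expect_equal(fit1$p_adjusted, p.adjust(fit1$p, "BH"))
})

test_that("pre-binned age enters the adjustment as a factor", {
  fx <- assoc_fixture(n = 80)
  set.seed(6)
  out <- simulate_linear_outcomes(fx$outcomes, fx$est, beta = 3, sd = 8)
  out$age <- cut(out$age, c(17, 30, 50, 75))
  fit <- fit_adjusted_models(out, fx$est, scales = "time",
                             outcome_cols = "pct_synthetic")
  expect_true(is.finite(fit$estimate))
  expect_true(fit$ci_low < fit$estimate & fit$estimate < fit$ci_high)
})
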