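# A noiseless, unclamped, unrounded cohort: every item carries the latent
# rate exactly, so item-total r, retest r (rho = 1) and every abbreviation
# r must all equal 1.
noiseless_study <- function(n = 40, seed = 3, rho = 1) {
  simulate_study(
    n = n, seed = seed, mu = log(0.05), sigma = 0.5, rho = rho,
    tau = c(time = 0, monetary = 0),
    time_bank = central_time_bank(), monetary_bank = central_monetary_bank(),
    scales = c("time", "monetary"), n_followups = 0,
    resolution = c(time = 0, monetary = 0)
  )
}

test_that("noiseless unclamped cohorts give item-total r of exactly 1", {
  st <- noiseless_study()
  expect_true(all(st$clamp_counts$n_clamped == 0))
  items <- score_items(st$responses, central_time_bank())
  it <- item_total_correlations(items, scale = "time")
  expect_equal(it$r, rep(1, 4), tolerance = 1e-10)
  expect_true(all(it$informative))
})

test_that("a constant (all-clamped-alike) item is reported as undefined r", {
  st <- noiseless_study()
  items <- score_items(st$responses, central_time_bank())
  items$log_k[items$item_id == "time_V50"] <- -3  # degenerate: no variance
  it <- item_total_correlations(items, scale = "time")
  row <- it[it$item_id == "time_V50", ]
  expect_true(is.na(row$r))
  expect_true(is.na(row$informative))
  expect_match(row$note, "zero variance")
})

test_that("the clamp-prone $99 item ranks last under the default cohort", {
  st <- simulate_study(n = 97, seed = 2, scales = "time", n_followups = 0)
  items <- score_items(st$responses, time_selection_bank())
  it <- item_total_correlations(items, scale = "time")
  v99 <- it$r[it$item_id == "time_V99"]
  others <- it$r[it$item_id != "time_V99"]
  expect_equal(v99, min(it$r))
  expect_true(all(others > v99))
})

test_that("item-excluded totals give smaller correlations than inclusive ones", {
  st <- simulate_study(n = 80, seed = 12, mu = log(0.05), sigma = 0.5,
                       tau = c(time = 0.5, monetary = 0),
                       time_bank = central_time_bank(),
                       scales = "time", n_followups = 0)
  items <- score_items(st$responses, central_time_bank())
  incl <- item_total_correlations(items, scale = "time", include_item = TRUE)
  excl <- item_total_correlations(items, scale = "time", include_item = FALSE)
  expect_true(all(excl$r < incl$r))
})

test_that("test-retest reproduces degenerate and null cases", {
  lk <- rnorm(30, -3, 1)
  est <- rbind(make_estimates(lk, phase = "phase1"),
               make_estimates(lk, phase = "phase2_baseline"))
  rt <- test_retest(est, "time")
  expect_equal(rt$r, 1)
  expect_equal(rt$n, 30)

  # independent phases: r within sampling noise of zero
  st <- simulate_study(n = 97, seed = 8, rho = 0,
                       mu = log(0.05), sigma = 0.5,
                       tau = c(time = 0, monetary = 0),
                       time_bank = central_time_bank(), scales = "time",
                       n_followups = 0)
  est <- score_scales(st$responses, central_time_bank())
  rt <- test_retest(est, "time")
  expect_lt(abs(rt$r), 3 / sqrt(rt$n))

  expect_error(test_retest(make_estimates(c(1, 2)), "time"), "3")
})

test_that("observed retest reliability matches the attenuation prediction", {
  sigma <- 0.5; tau_item <- 0.4; rho <- 0.8; m <- 4
  st <- simulate_study(n = 500, seed = 21, mu = log(0.05), sigma = sigma,
                       rho = rho, tau = c(time = tau_item, monetary = 0),
                       time_bank = central_time_bank(), scales = "time",
                       n_followups = 0)
  est <- score_scales(st$responses, central_time_bank())
  rt <- test_retest(est, "time")
  pred <- predicted_retest_r(rho, sigma, tau_item / sqrt(m))
  z_obs <- atanh(rt$r); z_pred <- atanh(pred)
  expect_lt(abs(z_obs - z_pred), 1.96 / sqrt(rt$n - 3))
})

test_that("convergent validity has unit diagonal and perfect noiseless cross-scale r", {
  st <- noiseless_study(rho = 1)
  bank <- validate_item_bank(rbind(as.data.frame(central_time_bank()),
                                   as.data.frame(central_monetary_bank())))
  est <- score_scales(st$responses, bank)
  cv <- convergent_validity(est)
  expect_equal(unname(diag(cv$r)), rep(1, 4))
  expect_equal(max(abs(cv$r - 1)), 0, tolerance = 1e-10)  # shared latent, no noise
  expect_true(isSymmetric(cv$r))
})

test_that("noisier instruments attenuate their correlation with the MCQ", {
  st <- simulate_study(n = 500, seed = 14, mu = log(0.05), sigma = 0.6,
                       tau = c(time = 0.1, monetary = 1.2),
                       mcq_choice_scale = 0.3,
                       time_bank = central_time_bank(),
                       monetary_bank = central_monetary_bank(),
                       n_followups = 0)
  bank <- validate_item_bank(rbind(as.data.frame(central_time_bank()),
                                   as.data.frame(central_monetary_bank())))
  est_mcq <- score_mcq(st$responses, mcq_bank())
  est_mcq$consistency <- NULL
  est <- rbind(score_scales(st$responses, bank), est_mcq)
  cv <- convergent_validity(est, phases = "phase1")
  r_mcq_time <- cv$r["phase1.mcq", "phase1.time"]
  r_mcq_money <- cv$r["phase1.mcq", "phase1.monetary"]
  expect_gt(r_mcq_time, r_mcq_money)
  expect_true(all(abs(cv$r) <= 1))
})

test_that("abbreviation returns 1 for full subsets and monotone means when noisy", {
  st <- noiseless_study()
  items <- score_items(st$responses, central_time_bank())
  ab <- abbreviation_analysis(items, scale = "time", sizes = c(2, 4),
                              iterations = 20, seed = 5)
  expect_equal(ab$draws$r, rep(1, 40), tolerance = 1e-10)  # all items identical
  # size = full length is permitted only as a self-check
  full <- abbreviation_analysis(items, scale = "time", sizes = 4,
                                iterations = 3, seed = 5)
  expect_equal(full$draws$r, rep(1, 3), tolerance = 1e-12)
  expect_error(abbreviation_analysis(items, scale = "time", sizes = 5),
               "exceeds")

  st2 <- simulate_study(n = 97, seed = 6, scales = "time", n_followups = 0)
  items2 <- score_items(st2$responses, time_selection_bank())
  informative <- item_total_correlations(items2, scale = "time")
  cand <- informative$item_id[informative$informative %in% TRUE]
  ab2 <- abbreviation_analysis(items2, scale = "time",
                               candidate_items = cand, sizes = 1:5,
                               iterations = 100, seed = 6)
  mc_se <- ab2$summary$sd_r / sqrt(ab2$iterations)
  gains <- diff(ab2$summary$mean_r)
  expect_true(all(gains > -2 * mc_se[-1]))  # nondecreasing within MC error
  expect_true(all(ab2$draws$r >= -1 & ab2$draws$r <= 1))
})

test_that("abbreviation resampling is reproducible under its seed", {
  st <- simulate_study(n = 50, seed = 9, scales = "time", n_followups = 0)
  items <- score_items(st$responses, time_selection_bank())
  a <- abbreviation_analysis(items, scale = "time", sizes = 1:3,
                             iterations = 25, seed = 42)
  b <- abbreviation_analysis(items, scale = "time", sizes = 1:3,
                             iterations = 25, seed = 42)
  expect_identical(a$draws, b$draws)
})
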