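test_that("straightlining means every response at the same bound", {
  bank <- time_selection_bank()
  resp <- rbind(
    bank_responses(bank, rep(364, 7), id = "max"),
    bank_responses(bank, rep(1, 7), id = "min"),
    bank_responses(bank, c(rep(1, 6), 2), id = "nearly"),
    bank_responses(bank, c(70, 10, 364, 5, 20, 50, 1), id = "mixed")
  )
  flags <- flag_straightliners(resp, bank)
  get <- function(id) flags$flag[flags$participant_id == id]
  expect_equal(get("max"), "straightline_max")
  expect_equal(get("min"), "straightline_min")
  expect_equal(get("nearly"), "retained")  # "consistently" means all items
  expect_equal(get("mixed"), "retained")
})

test_that("3-SD screening flags a planted contaminant in one pass", {
  set.seed(42)
  log_k <- c(rnorm(96), 5)  # planted contaminant at true z = +5
  est <- make_estimates(log_k)
  stopifnot((log_k[97] - mean(log_k)) / sd(log_k) > 3)  # realized z beyond 3
  out <- flag_sd_outliers(est)
  expect_equal(est$participant_id[out$flag == "sd_outlier"], "p097")
  expect_true(all(abs(out$z_score[out$flag == "retained"]) <= 3))
  expect_equal(out$z_score, (log_k - mean(log_k)) / sd(log_k))
})

test_that("degenerate score sets produce no outliers", {
  expect_warning(out <- flag_sd_outliers(make_estimates(rep(-2, 10))),
                 "zero variance")
  expect_true(all(out$flag == "retained"))
  out <- flag_sd_outliers(make_estimates(c(-1, 0, 1)))
  expect_true(all(out$flag == "retained"))  # max |z| = 1 by construction
  expect_error(flag_sd_outliers(make_estimates(c(0, 1))), "at least 3")
})

test_that("analytic sample is the across-phase intersection of retained ids", {
  d <- data.frame(
    participant_id = c("A", "B", "C", "B", "C", "D"),
    phase = rep(c("phase1", "phase2_baseline"), each = 3),
    scale = "time",
    flag = "retained", stringsAsFactors = FALSE
  )
  expect_equal(build_analytic_sample(d), c("A", "B", "C", "D"))  # no flags anywhere
  d$flag[d$participant_id == "A"] <- "straightline_min"
  d$flag[d$participant_id == "D"] <- "sd_outlier"  # flagged only in phase 2
  expect_equal(build_analytic_sample(d), c("B", "C"))
})

test_that("the contaminated cohort yields exactly its planted exclusions", {
  st <- simulate_study(n = 97, seed = 31, preset = "contaminated")
  qc <- run_qc(st$responses, list(time_selection_bank(), monetary_selection_bank()))
  excluded <- setdiff(st$profiles$participant_id, qc$analytic_sample)
  planted <- st$profiles[st$profiles$behavior != "normal", ]
  expect_equal(sort(excluded), sort(planted$participant_id))
  expect_equal(length(excluded), 8L)
  # flag types match the planted behaviors
  d <- qc$decisions
  for (i in seq_len(nrow(planted))) {
    flags <- unique(d$flag[d$participant_id == planted$participant_id[i] &
                             d$flag != "retained"])
    expected <- if (planted$behavior[i] == "sd_outlier") "sd_outlier" else planted$behavior[i]
    expect_true(expected %in% flags)
  }
})

test_that("re-screening the retained sample finds no contamination-level outliers", {
  st <- simulate_study(n = 97, seed = 5, preset = "contaminated")
  qc1 <- run_qc(st$responses, list(time_selection_bank(), monetary_selection_bank()))
  keep <- st$responses$participant_id %in% qc1$analytic_sample
  qc2 <- run_qc(st$responses[keep, ], list(time_selection_bank(),
                                           monetary_selection_bank()))
  expect_true(all(abs(qc2$decisions$z_score) < 5, na.rm = TRUE))
  expect_false(any(qc2$decisions$flag %in% c("straightline_min",
                                             "straightline_max")))
})

test_that("straightliners are removed before the SD pass", {
  # an extreme straightliner must not inflate the SD used for outlier z-scores
  bank <- time_selection_bank()
  set.seed(9)
  normals <- do.call(rbind, lapply(1:30, function(i) {
    bank_responses(bank, pmin(pmax(round((100 / bank$V - 1) /
                                           exp(rnorm(1, -2.5, 0.4))), 1), 364),
                   id = sprintf("n%02d", i))
  }))
  straight <- bank_responses(bank, rep(364, 7), id = "sl")
  qc <- run_qc(rbind(normals, straight), bank, phases = "phase1")
  d <- qc$decisions
  expect_equal(d$flag[d$participant_id == "sl"], "straightline_max")
  expect_false("sl" %in% d$participant_id[is.finite(d$z_score)])
})

test_that("the per-item SD reading flags a participant with one wild item", {
  set.seed(23)
  n <- 40
  bank <- central_time_bank()
  resp <- do.call(rbind, lapply(seq_len(n), function(i) {
    bank_responses(bank, pmin(pmax(round((100 / bank$V - 1) /
                                           exp(rnorm(4, -3, 0.3))), 1), 364),
                   id = sprintf("p%03d", i))
  }))
  # one participant answers one item wildly out of line with the group
  resp$value[resp$participant_id == "p001" &
               resp$item_id == "time_V50"] <- 364
  items <- score_items(resp, bank)
  out <- flag_sd_outliers(items, level = "item")
  expect_equal(out$participant_id[out$flag == "sd_outlier"], "p001")
  # the reported z is the participant's worst item z
  z50 <- with(items[items$item_id == "time_V50", ],
              (log_k - mean(log_k)) / sd(log_k))
  expect_equal(out$z_score[out$participant_id == "p001"],
               z50[items$participant_id[items$item_id == "time_V50"] == "p001"])
})
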