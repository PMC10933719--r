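# Shared fixtures for the test suite. Everything is generated in code.

# Central time-selection items (V in 30..70): their ideal responses stay
# far from the slider bounds for cohorts with sigma <= 0.6 around the
# default mean, so clamping and its distortions are negligible.
central_time_bank <- function() {
  b <- time_selection_bank()
  b[b$V %in% c(30, 40, 50, 70), , drop = FALSE]
}

central_monetary_bank <- function() {
  b <- monetary_selection_bank()
  b[b$D %in% c(14, 30, 91, 182), , drop = FALSE]
}

# minimal estimates table from a vector of log scores
make_estimates <- function(log_k, phase = "phase1", scale = "time",
                           ids = sprintf("p%03d", seq_along(log_k))) {
  structure(
    data.frame(participant_id = ids, phase = phase, occasion = 0,
               scale = scale, k_geomean = exp(log_k), log_k = log_k,
               n_items = 7L, n_clamped = 0L, stringsAsFactors = FALSE),
    class = c("dd_estimates", "data.frame")
  )
}

# one participant's long-format responses over a bank
bank_responses <- function(bank, values, id = "p1", phase = "phase1",
                           occasion = 0) {
  data.frame(participant_id = id, phase = phase, occasion = occasion,
             item_id = bank$item_id, value = values,
             stringsAsFactors = FALSE)
}

# brute-force MCQ consistency: best count over a dense log-spaced k grid
mcq_grid_consistency <- function(choices, k_indiff, n_grid = 4001) {
  grid <- exp(seq(log(min(k_indiff) / 4), log(max(k_indiff) * 4),
                  length.out = n_grid))
  max(vapply(grid, function(k) {
    sum(as.integer(k < k_indiff) == choices)
  }, numeric(1)))
}
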