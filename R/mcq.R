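#' Indifference rate of a binary MCQ item
#'
#' The discounting rate at which the two options of a "US $V today or US $A
#' in D days" item have equal present value: solving \eqn{V = A/(1 + kD)}
#' gives \eqn{k_{indiff} = (A - V)/(V D)}. A respondent with personal
#' \eqn{k > k_{indiff}} prefers the immediate option, \eqn{k < k_{indiff}}
#' the delayed one.
#'
#' @param bank a `dd_item_bank` with `mcq_binary` rows (or any rows with
#'   V, A, D all present).
#' @return numeric vector of indifference rates per day.
#' @examples
#' indifference_k(mcq_bank())
#' @export
indifference_k <- function(bank) {
  bank <- validate_item_bank(bank)
  if (any(is.na(bank$V) | is.na(bank$D))) {
    stop("indifference rates need V, A and D on every item")
  }
  (bank$A - bank$V) / (bank$V * bank$D)
}

# Candidate rates bracketing each run of sorted indifference rates:
# geometric means of adjacent k_indiff, plus one candidate below the
# smallest (geomean with half of it) and one above the largest (geomean
# with twice it).
mcq_candidates <- function(k_indiff) {
  ks <- sort(k_indiff)
  lo <- sqrt(ks[1] / 2 * ks[1])
  hi <- sqrt(ks[length(ks)] * 2 * ks[length(ks)])
  c(lo, sqrt(ks[-1] * ks[-length(ks)]), hi)
}

# Number of observed binary choices a candidate rate predicts correctly.
# choice coding: 0 = immediate, 1 = delayed.
mcq_consistency <- function(k, k_indiff, choices) {
  predicted_delayed <- as.integer(k < k_indiff)
  sum(predicted_delayed == choices)
}

#' Consistency-based scoring of the binary MCQ
#'
#' Kirby-style scoring: every binary choice is consistent with a half-line of
#' personal rates (immediate choices with \eqn{k} above the item's
#' indifference rate, delayed choices with \eqn{k} below it). The score is
#' the candidate rate that correctly predicts the largest number of observed
#' choices, candidates being the geometric means of adjacent sorted
#' indifference rates plus one bracketing candidate below the smallest and
#' one above the largest. Ties are broken by the geometric mean of all
#' maximizing candidates.
#'
#' @param responses data frame of binary responses (`value` 0 = immediate,
#'   1 = delayed) covering every bank item, with `participant_id`, `phase`,
#'   `occasion`, `item_id` columns.
#' @param bank an `mcq_binary` item bank, see [mcq_bank()].
#' @return data frame of class `dd_estimates` with one row per
#'   (participant, phase, occasion): `k_geomean` (the consistency-maximizing
#'   rate), `log_k`, `n_items`, `consistency` (choices predicted correctly)
#'   and `n_clamped` (always 0, for schema compatibility).
#' @examples
#' bank <- mcq_bank()
#' resp <- data.frame(participant_id = "p1", phase = "phase1", occasion = 0,
#'                    item_id = bank$item_id, value = 1)  # always waits
#' score_mcq(resp, bank)
#' @export
score_mcq <- function(responses, bank) {
  bank <- validate_item_bank(bank)
  bank <- bank[bank$kind == "mcq_binary", , drop = FALSE]
  if (!nrow(bank)) stop("bank contains no mcq_binary items")
  k_indiff <- indifference_k(bank)
  if (anyDuplicated(k_indiff)) stop("MCQ indifference rates must be distinct")
  candidates <- mcq_candidates(k_indiff)

  resp <- responses[responses$item_id %in% bank$item_id, , drop = FALSE]
  if (!all(resp$value %in% c(0, 1))) {
    stop("MCQ responses must be 0 (immediate) or 1 (delayed)")
  }
  key <- interaction(resp$participant_id, resp$phase, resp$occasion, drop = TRUE)
  pieces <- lapply(split(resp, key), function(g) {
    missing_items <- setdiff(bank$item_id, g$item_id)
    if (length(missing_items)) {
      stop("participant ", g$participant_id[1], " (", g$phase[1],
           "): missing MCQ responses for ",
           paste(missing_items, collapse = ", "))
    }
    choices <- g$value[match(bank$item_id, g$item_id)]
    counts <- vapply(candidates, mcq_consistency, integer(1),
                     k_indiff = k_indiff, choices = choices)
    best <- which(counts == max(counts))
    k_hat <- exp(mean(log(candidates[best])))
    data.frame(
      participant_id = g$participant_id[1],
      phase = g$phase[1],
      occasion = g$occasion[1],
      scale = "mcq",
      k_geomean = k_hat,
      log_k = log(k_hat),
      n_items = nrow(bank),
      n_clamped = 0L,
      consistency = max(counts),
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, pieces)
  rownames(out) <- NULL
  class(out) <- c("dd_estimates", "data.frame")
  out
}
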