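#' Hyperbolic discounted value
#'
#' Present value of a delayed reward under hyperbolic decay,
#' \eqn{V = A / (1 + kD)}. With \eqn{k = 0} or \eqn{D = 0} the reward is
#' undiscounted and the value equals \eqn{A}; the value decreases strictly
#' in both \eqn{k} and \eqn{D}.
#'
#' @param A delayed reward (US $), positive.
#' @param k discounting rate per day, nonnegative.
#' @param D delay in days, nonnegative.
#' @return present value in US $ (vectorized).
#' @examples
#' hyperbolic_value(100, 0.1 / 7, 70)  # $50: k of 0.1/week at 10 weeks
#' @export
hyperbolic_value <- function(A, k, D) {
  if (any(A <= 0)) stop("A must be positive")
  if (any(k < 0)) stop("k must be nonnegative")
  if (any(D < 0)) stop("D must be nonnegative")
  A / (1 + k * D)
}

#' Invert the hyperbolic model for k
#'
#' Closed-form recovery of the discounting rate from a single item response.
#' For a time-selection item (V, A fixed) a chosen wait `chosen_D` gives
#' \eqn{k = (A/V - 1)/D}; for a monetary-selection item (A, D fixed) a chosen
#' immediate amount `chosen_V` gives \eqn{k = (A/V - 1)/D}. Both satisfy the
#' round-trip identity `hyperbolic_value(A, k, D) == V` exactly.
#'
#' `invert_k_time()` signals an error for a zero or negative wait: a
#' participant unwilling to wait any time at all carries no finite rate, and
#' the decision of how to treat such responses (clamping to the slider floor)
#' belongs to scoring-time quality control, see [score_items()].
#'
#' @param A delayed reward (US $).
#' @param V immediate reward (US $), `0 < V < A`.
#' @param chosen_D delay response in days, positive.
#' @param D fixed delay in days, positive.
#' @param chosen_V monetary response in US $, `0 < chosen_V < A`.
#' @return discounting rate per day (vectorized).
#' @examples
#' invert_k_time(A = 100, V = 50, chosen_D = 70)    # 1/70 per day
#' invert_k_money(A = 100, D = 364, chosen_V = 40)  # 1.5/364 per day
#' @export
invert_k_time <- function(A, V, chosen_D) {
  if (any(V <= 0) || any(V >= A)) stop("V must satisfy 0 < V < A")
  if (any(chosen_D <= 0)) stop("non-invertible response: chosen_D must be positive")
  (A / V - 1) / chosen_D
}

#' @rdname invert_k_time
#' @export
invert_k_money <- function(A, D, chosen_V) {
  if (any(D <= 0)) stop("D must be positive")
  if (any(chosen_V <= 0)) stop("chosen_V must be positive")
  if (any(chosen_V >= A)) stop("non-invertible response: chosen_V must be below A")
  (A / chosen_V - 1) / D
}

#' Ideal (noise-free) item response implied by a discounting rate
#'
#' The response a perfectly model-consistent respondent with rate `k` would
#' give: the wait \eqn{D^* = (A/V - 1)/k} for time-selection items and the
#' amount \eqn{V^* = A/(1 + kD)} for monetary-selection items, before any
#' slider clamping or rounding.
#'
#' @param bank a `dd_item_bank` of continuous items.
#' @param k discounting rate per day (scalar).
#' @return numeric vector of ideal responses, one per bank row.
#' @export
ideal_response <- function(bank, k) {
  bank <- validate_item_bank(bank)
  if (length(k) != 1 || k <= 0) stop("k must be a positive scalar")
  ifelse(bank$kind == "time_selection",
         (bank$A / bank$V - 1) / k,
         bank$A / (1 + k * bank$D))
}

#' Geometric-mean aggregation of per-item rates
#'
#' The scale score is the geometric mean of the per-item rates,
#' `exp(mean(log(ks)))`; analyses run on its natural log. The geometric mean
#' is permutation-invariant, scale-equivariant and always lies within
#' `range(ks)`.
#'
#' @param ks positive per-item discounting rates.
#' @return a list with `k_geomean`, `log_k` and `n_items`.
#' @examples
#' aggregate_scale(c(0.01, 0.04))$k_geomean  # 0.02
#' @export
aggregate_scale <- function(ks) {
  if (!length(ks)) stop("no item rates to aggregate")
  if (any(!is.finite(ks)) || any(ks <= 0)) {
    stop("all item rates must be positive and finite")
  }
  log_k <- mean(log(ks))
  list(k_geomean = exp(log_k), log_k = log_k, n_items = length(ks))
}

#' Per-item discounting rates from raw responses
#'
#' Joins long-format responses to the item bank and inverts the hyperbolic
#' model row by row. Responses to time-selection items at or below zero are
#' non-invertible; they are clamped to `clamp_floor` days (the deployed
#' slider's minimum positive resolution) and flagged `clamped`, so downstream
#' QC can count them.
#'
#' @param responses data frame with columns `participant_id`, `phase`,
#'   `occasion`, `item_id`, `value` (see [read_responses()]).
#' @param bank a `dd_item_bank` of continuous items.
#' @param clamp_floor floor in days applied to non-positive time responses
#'   (default 1).
#' @return data frame with one row per response: ids, `scale`
#'   (`"time"`/`"monetary"`), `k`, `log_k`, and logical `clamped`.
#' @export
score_items <- function(responses, bank, clamp_floor = 1) {
  bank <- validate_item_bank(bank)
  bank <- bank[bank$kind != "mcq_binary", , drop = FALSE]
  resp <- responses[responses$item_id %in% bank$item_id, , drop = FALSE]
  if (!nrow(resp)) stop("no responses match the bank's item_ids")
  idx <- match(resp$item_id, bank$item_id)
  kind <- bank$kind[idx]
  A <- bank$A[idx]
  value <- as.numeric(resp$value)

  clamped <- kind == "time_selection" & value <= 0
  value[clamped] <- clamp_floor

  k <- numeric(length(value))
  tt <- kind == "time_selection"
  if (any(tt)) k[tt] <- invert_k_time(A[tt], bank$V[idx][tt], value[tt])
  mm <- !tt
  if (any(mm)) k[mm] <- invert_k_money(A[mm], bank$D[idx][mm], value[mm])

  data.frame(
    participant_id = resp$participant_id,
    phase = resp$phase,
    occasion = resp$occasion,
    item_id = resp$item_id,
    scale = ifelse(tt, "time", "monetary"),
    k = k,
    log_k = log(k),
    clamped = clamped,
    stringsAsFactors = FALSE
  )
}

#' Score continuous scales to per-person discounting estimates
#'
#' Computes, for every (participant, phase, occasion, scale) cell, the
#' geometric-mean discounting rate across that scale's items and its natural
#' log — the per-person score all downstream analyses use.
#'
#' @inheritParams score_items
#' @param min_items drop cells with fewer items than this (default 1).
#' @return data frame of class `dd_estimates`: `participant_id`, `phase`,
#'   `occasion`, `scale`, `k_geomean`, `log_k`, `n_items`, `n_clamped`.
#' @export
score_scales <- function(responses, bank, clamp_floor = 1, min_items = 1) {
  items <- score_items(responses, bank, clamp_floor = clamp_floor)
  key <- interaction(items$participant_id, items$phase, items$occasion,
                     items$scale, drop = TRUE)
  pieces <- lapply(split(items, key), function(g) {
    agg <- aggregate_scale(g$k)
    data.frame(
      participant_id = g$participant_id[1],
      phase = g$phase[1],
      occasion = g$occasion[1],
      scale = g$scale[1],
      k_geomean = agg$k_geomean,
      log_k = agg$log_k,
      n_items = agg$n_items,
      n_clamped = sum(g$clamped),
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, pieces)
  out <- out[out$n_items >= min_items, , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("dd_estimates", "data.frame")
  out
}
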