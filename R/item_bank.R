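#' Delay expressed in days
#'
#' Canonical conversion of the verbal delays used by the item banks to days.
#' The calendar year is taken as 364 days (52 weeks exactly, so that "1 year"
#' and the 52-week slider ceiling coincide), a month as 30 days, 6 months as
#' 182 days and 3 months as 91 days.
#'
#' @param x character vector of delay labels, e.g. `"1 year"`, `"6 months"`,
#'   `"2 weeks"`, `"tomorrow"`.
#' @return numeric vector of delays in days.
#' @examples
#' delay_days(c("1 year", "6 months", "tomorrow"))
#' @export
delay_days <- function(x) {
  map <- c(
    "1 year" = 364, "6 months" = 182, "3 months" = 91, "1 month" = 30,
    "2 weeks" = 14, "1 week" = 7, "tomorrow" = 1, "1 day" = 1
  )
  out <- unname(map[x])
  if (anyNA(out)) {
    stop("unknown delay label(s): ", paste(setdiff(x, names(map)), collapse = ", "))
  }
  out
}

#' Construct and validate an item bank
#'
#' An item bank is a data frame with one row per questionnaire item. Three
#' item kinds are supported: `time_selection` (V and A fixed, the respondent
#' slides a delay D), `monetary_selection` (A and D fixed, the respondent
#' slides an immediate amount V) and `mcq_binary` (V, A and D all fixed, the
#' respondent picks immediate vs delayed).
#'
#' @param item_id character item labels (unique).
#' @param kind one of `"time_selection"`, `"monetary_selection"`,
#'   `"mcq_binary"` (recycled).
#' @param A delayed reward, US $.
#' @param V immediate reward, US $ (`NA` for monetary-selection items, where
#'   V is the response).
#' @param D delay in days (`NA` for time-selection items, where D is the
#'   response).
#' @param response_min,response_max slider bounds in the responding dimension
#'   (days for time items, US $ for monetary items; ignored for `mcq_binary`).
#' @return a `data.frame` of class `dd_item_bank`.
#' @seealso [time_selection_bank()], [monetary_selection_bank()], [mcq_bank()]
#' @export
dd_item_bank <- function(item_id, kind, A, V = NA_real_, D = NA_real_,
                         response_min = NA_real_, response_max = NA_real_) {
  bank <- data.frame(
    item_id = as.character(item_id),
    kind = as.character(kind),
    A = as.numeric(A),
    V = as.numeric(V),
    D = as.numeric(D),
    response_min = as.numeric(response_min),
    response_max = as.numeric(response_max),
    stringsAsFactors = FALSE
  )
  validate_item_bank(bank)
}

#' Validate an item-bank data frame
#'
#' Checks the field and invariant contract of an item bank (see
#' [dd_item_bank()]) and returns it classed as `dd_item_bank`. Useful when a
#' bank is assembled by hand or by `rbind()`ing banks of different kinds.
#'
#' @param bank a data frame with the item-bank columns.
#' @return the validated `dd_item_bank`.
#' @export
validate_item_bank <- function(bank) {
  stopifnot(is.data.frame(bank))
  required <- c("item_id", "kind", "A", "V", "D", "response_min", "response_max")
  missing_cols <- setdiff(required, names(bank))
  if (length(missing_cols)) {
    stop("item bank lacks column(s): ", paste(missing_cols, collapse = ", "))
  }
  if (anyDuplicated(bank$item_id)) stop("duplicate item_id in bank")
  ok_kinds <- c("time_selection", "monetary_selection", "mcq_binary")
  if (!all(bank$kind %in% ok_kinds)) {
    stop("unknown item kind(s): ",
         paste(unique(setdiff(bank$kind, ok_kinds)), collapse = ", "))
  }
  if (any(bank$A <= 0)) stop("delayed reward A must be positive")
  needs_v <- bank$kind %in% c("time_selection", "mcq_binary")
  if (any(is.na(bank$V[needs_v]))) stop("V required for time-selection and MCQ items")
  if (any(!is.na(bank$V) & (bank$V <= 0 | bank$V >= bank$A))) {
    stop("immediate reward V must satisfy 0 < V < A")
  }
  needs_d <- bank$kind %in% c("monetary_selection", "mcq_binary")
  if (any(is.na(bank$D[needs_d]))) stop("D required for monetary-selection and MCQ items")
  if (any(!is.na(bank$D) & bank$D <= 0)) stop("delay D must be positive")
  cont <- bank$kind != "mcq_binary"
  if (any(is.na(bank$response_min[cont]) | is.na(bank$response_max[cont]))) {
    stop("continuous items need slider bounds")
  }
  if (any(cont & bank$response_min >= bank$response_max)) {
    stop("response_min must be below response_max")
  }
  class(bank) <- c("dd_item_bank", "data.frame")
  bank
}

#' Default time-selection item bank
#'
#' Seven items of the form "How long would you be willing to wait to get
#' US $100 instead of US $V today?" with V in {50, 70, 10, 80, 40, 30, 99}.
#' The respondent answers with a delay on a 0-52-week slider; the deployed
#' floor is one day, so responses are bounded to `[floor_days, 364]` days.
#'
#' @param floor_days slider minimum in days (default 1; 0 is accepted and
#'   handled at scoring time by clamping, see [score_items()]).
#' @param max_days slider maximum in days (default 364 = 52 weeks).
#' @return a `dd_item_bank`.
#' @export
time_selection_bank <- function(floor_days = 1, max_days = 364) {
  v <- c(50, 70, 10, 80, 40, 30, 99)
  dd_item_bank(
    item_id = sprintf("time_V%02d", v),
    kind = "time_selection",
    A = 100, V = v,
    response_min = floor_days, response_max = max_days
  )
}

#' Default monetary-selection item bank
#'
#' Seven items of the form "How much money would you take today instead of
#' US $100 in <delay>?" with delays of 1 year, 1 month, 6 months, 3 months,
#' 2 weeks, 1 week and tomorrow. The respondent answers with an amount on a
#' US $1-$99 slider.
#'
#' @param min_dollars,max_dollars slider bounds in US $ (defaults 1 and 99).
#' @return a `dd_item_bank`.
#' @export
monetary_selection_bank <- function(min_dollars = 1, max_dollars = 99) {
  delays <- c("1 year", "1 month", "6 months", "3 months",
              "2 weeks", "1 week", "tomorrow")
  dd_item_bank(
    item_id = sprintf("money_D%03d", delay_days(delays)),
    kind = "monetary_selection",
    A = 100, D = delay_days(delays),
    response_min = min_dollars, response_max = max_dollars
  )
}

#' Default 7-item binary Monetary Choice Questionnaire bank
#'
#' "Would you rather receive US $V today or US $100 in <delay>?" variants.
#' The delayed reward is always US $100; immediate amounts reuse the
#' time-selection V grid and delays span 61-364 days, chosen so the implied
#' indifference rates \eqn{k = (A - V)/(V D)} are distinct and spread
#' roughly evenly on the log scale across the range human cohorts occupy
#' (about 3e-5 to 0.15 per day).
#'
#' @return a `dd_item_bank` sorted by increasing indifference rate.
#' @export
mcq_bank <- function() {
  v <- c(99, 80, 70, 50, 40, 30, 10)
  d <- c(364, 364, 243, 182, 91, 61, 61)
  bank <- dd_item_bank(
    item_id = sprintf("mcq%02d", seq_along(v)),
    kind = "mcq_binary",
    A = 100, V = v, D = d
  )
  bank[order((bank$A - bank$V) / (bank$V * bank$D)), , drop = FALSE]
}

#' Read or write an item bank as a YAML config
#'
#' The on-disk dialect is a YAML list with one mapping per item carrying the
#' same fields as [dd_item_bank()]; `~` (null) marks the responding dimension.
#'
#' @param path file path.
#' @param bank a `dd_item_bank`.
#' @return `read_item_bank()` returns a validated `dd_item_bank`;
#'   `write_item_bank()` returns `path` invisibly.
#' @export
read_item_bank <- function(path) {
  raw <- yaml::read_yaml(path)
  if (!length(raw)) stop("empty item bank config: ", path)
  num_or_na <- function(x) if (is.null(x)) NA_real_ else as.numeric(x)
  rows <- lapply(raw, function(it) {
    data.frame(
      item_id = as.character(it$item_id),
      kind = as.character(it$kind),
      A = as.numeric(it$A),
      V = num_or_na(it$V),
      D = num_or_na(it$D),
      response_min = num_or_na(it$response_min),
      response_max = num_or_na(it$response_max),
      stringsAsFactors = FALSE
    )
  })
  validate_item_bank(do.call(rbind, rows))
}

#' @rdname read_item_bank
#' @export
write_item_bank <- function(bank, path) {
  bank <- validate_item_bank(bank)
  items <- lapply(seq_len(nrow(bank)), function(i) {
    row <- as.list(bank[i, , drop = FALSE])
    lapply(row, function(x) if (is.na(x)) NULL else unname(x))
  })
  yaml::write_yaml(items, path)
  invisible(path)
}

#' @export
print.dd_item_bank <- function(x, ...) {
  cat(sprintf("<dd_item_bank> %d items (%s)\n", nrow(x),
              paste(unique(x$kind), collapse = ", ")))
  print.data.frame(x, row.names = FALSE)
  invisible(x)
}
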