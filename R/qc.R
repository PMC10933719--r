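#' Flag straightlining respondents
#'
#' A participant straightlines a continuous scale when *every* response on
#' that scale within a phase sits at the slider minimum (`straightline_min`)
#' or every response sits at the maximum (`straightline_max`). Such patterns
#' carry no information about the discounting rate and are removed before
#' outlier screening.
#'
#' @param responses long-format responses (see [read_responses()]).
#' @param bank continuous item bank the responses belong to.
#' @return data frame: `participant_id`, `phase`, `scale`, `flag`
#'   (one of `straightline_min`, `straightline_max`, `retained`).
#' @export
flag_straightliners <- function(responses, bank) {
  bank <- validate_item_bank(bank)
  bank <- bank[bank$kind != "mcq_binary", , drop = FALSE]
  resp <- responses[responses$item_id %in% bank$item_id, , drop = FALSE]
  if (!nrow(resp)) {
    warning("no responses match the bank; nothing to flag")
    return(data.frame(participant_id = character(), phase = character(),
                      scale = character(), flag = character(),
                      stringsAsFactors = FALSE))
  }
  idx <- match(resp$item_id, bank$item_id)
  resp$scale <- ifelse(bank$kind[idx] == "time_selection", "time", "monetary")
  resp$rmin <- bank$response_min[idx]
  resp$rmax <- bank$response_max[idx]

  key <- interaction(resp$participant_id, resp$phase, resp$scale, drop = TRUE)
  pieces <- lapply(split(resp, key), function(g) {
    flag <- if (all(g$value <= g$rmin)) {
      "straightline_min"
    } else if (all(g$value >= g$rmax)) {
      "straightline_max"
    } else {
      "retained"
    }
    data.frame(participant_id = g$participant_id[1], phase = g$phase[1],
               scale = g$scale[1], flag = flag, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, pieces)
  rownames(out) <- NULL
  out
}

#' Flag 3-SD outliers on the score distribution
#'
#' Standardizes per-person scores within each (phase, scale) group in a
#' single pass and flags |z| above `threshold`. Standardization defaults to
#' the log-scale score (`log_k`), on which the scores are approximately
#' normal; `on = "raw"` standardizes `k_geomean` instead for sensitivity
#' analysis.
#'
#' The SD can be read two ways: per-person (standardize the scale scores;
#' the default) or per-item (standardize each item's rates separately and
#' flag a participant whose response to *any* item exceeds the threshold).
#' `level = "item"` selects the second reading; `estimates` must then be the
#' per-item table from [score_items()].
#'
#' @param estimates a `dd_estimates` data frame (baseline occasions), or the
#'   [score_items()] table when `level = "item"`.
#' @param threshold z cutoff (default 3).
#' @param on `"log"` (default) or `"raw"`.
#' @param level `"person"` (default) or `"item"`, see Details.
#' @return data frame: ids, `scale`, `flag` (`sd_outlier` or `retained`),
#'   `z_score` (for `level = "item"`, the participant's largest-magnitude
#'   item z).
#' @export
flag_sd_outliers <- function(estimates, threshold = 3, on = c("log", "raw"),
                             level = c("person", "item")) {
  on <- match.arg(on)
  level <- match.arg(level)
  if (level == "item") {
    return(flag_sd_outliers_by_item(estimates, threshold, on))
  }
  key <- interaction(estimates$phase, estimates$scale, drop = TRUE)
  pieces <- lapply(split(as.data.frame(estimates), key), function(g) {
    if (nrow(g) < 3) stop("need at least 3 estimates per phase x scale group")
    x <- if (on == "log") g$log_k else g$k_geomean
    s <- sd(x)
    if (s == 0) {
      warning("zero variance in ", g$phase[1], "/", g$scale[1],
              "; no outliers can be flagged")
      z <- rep(0, nrow(g))
    } else {
      z <- (x - mean(x)) / s
    }
    data.frame(
      participant_id = g$participant_id, phase = g$phase, scale = g$scale,
      flag = ifelse(abs(z) > threshold, "sd_outlier", "retained"),
      z_score = z, stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, pieces)
  rownames(out) <- NULL
  out
}

# per-item reading of the SD rule: standardize each item's rates within
# phase x scale x item, then roll the worst |z| up to the participant
flag_sd_outliers_by_item <- function(items, threshold, on) {
  key <- interaction(items$phase, items$scale, items$item_id, drop = TRUE)
  z <- unsplit(lapply(split(seq_len(nrow(items)), key), function(ix) {
    x <- if (on == "log") items$log_k[ix] else items$k[ix]
    if (length(ix) < 3) stop("need at least 3 responses per item group")
    s <- sd(x)
    if (s == 0) rep(0, length(ix)) else (x - mean(x)) / s
  }), key)
  pieces <- lapply(split(data.frame(items, z = z),
                         interaction(items$participant_id, items$phase,
                                     items$scale, drop = TRUE)),
                   function(g) {
    worst <- g$z[which.max(abs(g$z))]
    data.frame(participant_id = g$participant_id[1], phase = g$phase[1],
               scale = g$scale[1],
               flag = if (abs(worst) > threshold) "sd_outlier" else "retained",
               z_score = worst, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, pieces)
  rownames(out) <- NULL
  out
}

#' Run the participant-exclusion pipeline
#'
#' Reproduces the two-stage screening used for EMA discounting studies:
#' straightliner detection first, then one-pass 3-SD outlier detection on the
#' per-person log scores of the remaining participants, per phase and scale.
#'
#' @param responses long-format baseline responses for the phases to screen.
#' @param banks list of continuous item banks (e.g.
#'   `list(time_selection_bank(), monetary_selection_bank())`).
#' @param phases phases to screen (default `c("phase1", "phase2_baseline")`).
#' @param threshold,on passed to [flag_sd_outliers()].
#' @param clamp_floor passed to [score_scales()].
#' @return list of class `dd_qc`: `decisions` (one row per participant x
#'   phase x scale with `flag` and `z_score`), `analytic_sample` (character
#'   vector of retained participant ids) and `summary` (counts per phase,
#'   scale and flag).
#' @export
run_qc <- function(responses, banks, phases = c("phase1", "phase2_baseline"),
                   threshold = 3, on = c("log", "raw"), clamp_floor = 1) {
  on <- match.arg(on)
  if (inherits(banks, "dd_item_bank")) banks <- list(banks)
  base <- responses[responses$phase %in% phases & responses$occasion == 0, ,
                    drop = FALSE]
  decisions <- NULL
  for (bank in banks) {
    straight <- flag_straightliners(base, bank)
    bad <- straight[straight$flag != "retained", , drop = FALSE]
    keep_key <- !interaction(base$participant_id, base$phase) %in%
      interaction(bad$participant_id, bad$phase)
    bank_items <- bank$item_id[bank$kind != "mcq_binary"]
    clean <- base[keep_key & base$item_id %in% bank_items, , drop = FALSE]
    est <- score_scales(clean, bank, clamp_floor = clamp_floor)
    out <- flag_sd_outliers(est, threshold = threshold, on = on)
    bad <- bad[, c("participant_id", "phase", "scale", "flag"), drop = FALSE]
    bad$z_score <- rep(NA_real_, nrow(bad))
    decisions <- rbind(decisions, bad, out)
  }
  rownames(decisions) <- NULL
  res <- list(
    decisions = decisions,
    analytic_sample = build_analytic_sample(decisions, phases = phases),
    summary = qc_flow_summary(decisions)
  )
  class(res) <- "dd_qc"
  res
}

#' Analytic sample: participants retained in every screened phase
#'
#' A participant enters the analytic sample only with valid data in *all*
#' screened phases: anyone carrying a non-`retained` flag in any phase or
#' scale is excluded.
#'
#' @param decisions QC decision table (see [run_qc()]).
#' @param phases phases that must all be clean.
#' @return sorted character vector of retained participant ids.
#' @export
build_analytic_sample <- function(decisions,
                                  phases = c("phase1", "phase2_baseline")) {
  d <- decisions[decisions$phase %in% phases, , drop = FALSE]
  all_ids <- unique(d$participant_id)
  flagged <- unique(d$participant_id[d$flag != "retained"])
  sort(setdiff(all_ids, flagged))
}

#' Flowchart-style exclusion summary
#'
#' @param decisions QC decision table.
#' @return data frame of counts per (phase, scale, flag).
#' @export
qc_flow_summary <- function(decisions) {
  agg <- aggregate(list(n = decisions$participant_id),
                   by = list(phase = decisions$phase, scale = decisions$scale,
                             flag = decisions$flag),
                   FUN = length)
  agg[order(agg$phase, agg$scale, agg$flag), , drop = FALSE]
}

#' @export
print.dd_qc <- function(x, ...) {
  cat("<dd_qc> analytic sample:", length(x$analytic_sample), "participants\n")
  excl <- x$summary[x$summary$flag != "retained", , drop = FALSE]
  if (nrow(excl)) {
    cat("exclusions:\n")
    print(excl, row.names = FALSE)
  } else {
    cat("no exclusions\n")
  }
  invisible(x)
}
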