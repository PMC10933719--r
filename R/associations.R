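#' Per-person endorsement percentages
#'
#' Collapses per-survey binary endorsements to individual-level outcome
#' variables: for each substance, 100 x (endorsing surveys / completed
#' surveys). Only completed surveys enter the denominator; participants with
#' zero completed surveys are dropped with a warning.
#'
#' @param endorsements data frame with one row per (participant, survey):
#'   `participant_id`, `occasion`, logical/0-1 `completed`, and one 0/1
#'   column per endorsement variable (any columns matching `use_` / `crave_`
#'   prefixes, e.g. `use_tobacco`).
#' @return data frame with `participant_id`, `surveys_completed` and one
#'   `pct_*` column (0-100) per endorsement variable.
#' @examples
#' e <- data.frame(participant_id = "p1", occasion = 0:3,
#'                 completed = c(1, 1, 1, 0), use_tobacco = c(1, 0, 0, 0))
#' endorsement_percentages(e)  # 1/3 completed surveys -> 33.3%
#' @export
endorsement_percentages <- function(endorsements) {
  vars <- grep("^(use|crave)_", names(endorsements), value = TRUE)
  if (!length(vars)) stop("no use_*/crave_* endorsement columns found")
  done <- endorsements[as.logical(endorsements$completed), , drop = FALSE]
  rows <- lapply(split(done, done$participant_id), function(g) {
    out <- data.frame(participant_id = g$participant_id[1],
                      surveys_completed = nrow(g), stringsAsFactors = FALSE)
    for (v in vars) out[[paste0("pct_", v)]] <- 100 * mean(g[[v]])
    out
  })
  dropped <- setdiff(unique(endorsements$participant_id),
                     unique(done$participant_id))
  if (length(dropped)) {
    warning(length(dropped), " participant(s) with zero completed surveys dropped")
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Adjusted linear regressions of endorsement percentages on log k
#'
#' Fits one ordinary-least-squares model per (predictor scale, outcome):
#' `pct ~ log_k + age + sex + surveys_completed`, with continuous predictors
#' mean-centered. The reported effect is the adjusted mean difference in
#' percentage points per unit log discounting rate, with its 95% CI and
#' p-value. Centering changes the intercept only; the log-k coefficient and
#' its CI are identical with or without it.
#'
#' @param outcomes per-person outcome table from [endorsement_percentages()]
#'   joined with demographics: must carry `participant_id`,
#'   `surveys_completed`, `sex` (two-level factor or character; the first
#'   level alphabetically is the reference), `age` (continuous years, or a
#'   factor of age bins), and the `pct_*` columns to model.
#' @param estimates a `dd_estimates` data frame supplying the predictors.
#' @param scales predictor scales (default `c("mcq", "time", "monetary")`).
#' @param phase phase of the predictor scores (default `"phase2_baseline"`).
#' @param outcome_cols outcome columns (default: every `pct_*` column).
#' @param p_adjust multiplicity correction across the returned rows
#'   (default `"none"`, matching common single-study reporting; `"BH"`
#'   available).
#' @param participants optional analytic-sample restriction.
#' @return data frame of class `dd_regressions`: `predictor`, `outcome`,
#'   `estimate` (adjusted mean difference), `ci_low`, `ci_high`, `p`, `n`.
#' @export
fit_adjusted_models <- function(outcomes, estimates,
                                scales = c("mcq", "time", "monetary"),
                                phase = "phase2_baseline",
                                outcome_cols = NULL, p_adjust = "none",
                                participants = NULL) {
  if (is.null(outcome_cols)) {
    outcome_cols <- grep("^pct_", names(outcomes), value = TRUE)
  }
  stopifnot(length(outcome_cols) > 0,
            all(c("sex", "age", "surveys_completed") %in% names(outcomes)))
  e <- as.data.frame(estimates)
  e <- e[e$occasion == 0 & e$phase == phase, , drop = FALSE]
  if (!is.null(participants)) {
    e <- e[e$participant_id %in% participants, , drop = FALSE]
    outcomes <- outcomes[outcomes$participant_id %in% participants, , drop = FALSE]
  }
  rows <- list()
  for (sc in scales) {
    pred <- e[e$scale == sc, c("participant_id", "log_k")]
    dat <- merge(pred, outcomes, by = "participant_id")
    dat$sex <- factor(dat$sex)
    if (nlevels(dat$sex) > 2) stop("sex must have at most 2 levels")
    dat$log_k_c <- dat$log_k - mean(dat$log_k)
    # age enters centered when continuous, as a factor when pre-binned
    dat$age_c <- if (is.numeric(dat$age)) dat$age - mean(dat$age) else factor(dat$age)
    dat$surveys_c <- dat$surveys_completed - mean(dat$surveys_completed)
    for (oc in outcome_cols) {
      f <- stats::reformulate(c("log_k_c", "age_c", "sex", "surveys_c"),
                              response = oc)
      mm <- stats::model.matrix(f, dat)
      qr_mm <- qr(mm)
      if (qr_mm$rank < ncol(mm)) {
        stop("rank-deficient design for ", sc, " ~ ", oc, "; collinear: ",
             paste(colnames(mm)[qr_mm$pivot[-seq_len(qr_mm$rank)]],
                   collapse = ", "))
      }
      fit <- lm(f, data = dat)
      ci <- confint(fit, "log_k_c", level = 0.95)
      rows[[paste(sc, oc)]] <- data.frame(
        predictor = sc, outcome = oc,
        estimate = unname(coef(fit)["log_k_c"]),
        ci_low = ci[1], ci_high = ci[2],
        p = summary(fit)$coefficients["log_k_c", "Pr(>|t|)"],
        n = nrow(dat), stringsAsFactors = FALSE
      )
    }
  }
  out <- do.call(rbind, rows)
  out$p_adjusted <- stats::p.adjust(out$p, method = p_adjust)
  rownames(out) <- NULL
  class(out) <- c("dd_regressions", "data.frame")
  out
}

#' @export
print.dd_regressions <- function(x, digits = 2, ...) {
  cat("<dd_regressions> adjusted mean difference in percentage points per unit log k\n")
  cat("(models adjust for age, sex and completed surveys; reference sex level:",
      "first factor level)\n")
  y <- as.data.frame(x)
  y$estimate <- round(y$estimate, digits)
  y$ci_low <- round(y$ci_low, digits)
  y$ci_high <- round(y$ci_high, digits)
  y$p <- signif(y$p, 2)
  y$p_adjusted <- signif(y$p_adjusted, 2)
  print(y, row.names = FALSE)
  invisible(x)
}
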