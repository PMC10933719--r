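#' Synthetic respondent profiles
#'
#' Draws latent discounting traits for a cohort: per-person phase-1 and
#' phase-2 log rates from a bivariate normal with mean `mu`, SD `sigma` and
#' between-phase correlation `rho`, plus a behavioral type. Contaminant
#' types: `straightline_min` / `straightline_max` answer every continuous
#' item at the slider minimum / maximum; `sd_outlier` agents have their
#' latent log rate shifted to `mu - outlier_offset * sigma` (extreme-patient
#' side, where the bounded sliders still leave room for a detectable
#' 3-SD score).
#'
#' @param n cohort size.
#' @param mu,sigma mean and SD of latent log k (per day).
#' @param rho between-phase correlation of latent log k.
#' @param n_straightline_min,n_straightline_max,n_outliers contaminant counts.
#' @param outlier_offset latent shift of outlier agents, in units of `sigma` (default 7, the extreme-patient regime where responses stay interior to the sliders).
#' @return data frame: `participant_id`, `latent_lk_phase1`,
#'   `latent_lk_phase2`, `behavior`.
#' @export
respondent_profiles <- function(n, mu = log(0.08), sigma = 1.0, rho = 0.8,
                                n_straightline_min = 0, n_straightline_max = 0,
                                n_outliers = 0, outlier_offset = 7) {
  stopifnot(n >= n_straightline_min + n_straightline_max + n_outliers,
            sigma > 0, rho >= -1, rho <= 1)
  z1 <- rnorm(n)
  z2 <- rho * z1 + sqrt(1 - rho^2) * rnorm(n)
  behavior <- rep("normal", n)
  contam <- seq_len(n_straightline_min + n_straightline_max + n_outliers)
  # contaminants occupy the tail ids so the clean ids are stable across presets
  slots <- rev(seq_len(n))[contam]
  behavior[slots] <- rep(c("straightline_min", "straightline_max", "sd_outlier"),
                         c(n_straightline_min, n_straightline_max, n_outliers))
  lk1 <- mu + sigma * z1
  lk2 <- mu + sigma * z2
  shift <- behavior == "sd_outlier"
  lk1[shift] <- mu - outlier_offset * sigma + 0.1 * sigma * z1[shift]
  lk2[shift] <- mu - outlier_offset * sigma + 0.1 * sigma * z2[shift]
  data.frame(
    participant_id = sprintf("p%03d", seq_len(n)),
    latent_lk_phase1 = lk1,
    latent_lk_phase2 = lk2,
    behavior = behavior,
    stringsAsFactors = FALSE
  )
}

#' Simulate one survey's continuous item responses
#'
#' For a respondent whose momentary log rate is `log_k`, draws independent
#' item-level noise (SD `tau`), computes the model-implied ideal response —
#' \eqn{D^* = (A/V - 1)/k} for time items, \eqn{V^* = A/(1 + kD)} for
#' monetary items — then clamps to the slider bounds and rounds to the
#' slider resolution (1 day / US $1 by default; `resolution = 0` keeps the
#' continuous value, a check mode used for exact parameter recovery).
#'
#' @param bank continuous item bank.
#' @param log_k latent log rate at this occasion (scalar).
#' @param tau item-level noise SD on the log-k scale.
#' @param resolution rounding grain of the slider (0 = none).
#' @return data frame: `item_id`, `value`, `clamped` (TRUE when the ideal
#'   response fell outside the slider).
#' @export
simulate_responses <- function(bank, log_k, tau = 0, resolution = 1) {
  bank <- validate_item_bank(bank)
  m <- nrow(bank)
  k_item <- exp(log_k + rnorm(m, 0, tau))
  ideal <- ifelse(bank$kind == "time_selection",
                  (bank$A / bank$V - 1) / k_item,
                  bank$A / (1 + k_item * bank$D))
  clamped <- ideal < bank$response_min | ideal > bank$response_max
  value <- pmin(pmax(ideal, bank$response_min), bank$response_max)
  if (resolution > 0) value <- round(value / resolution) * resolution
  data.frame(item_id = bank$item_id, value = value, clamped = clamped,
             stringsAsFactors = FALSE)
}

#' Simulate binary MCQ choices
#'
#' Choice follows a logistic rule on the log-rate distance to each item's
#' indifference rate: `P(immediate) = plogis((log_k - log k_indiff) /
#' choice_scale)`. `choice_scale = 0` gives the deterministic choice
#' (immediate iff `k > k_indiff`).
#'
#' @param bank an `mcq_binary` item bank.
#' @param log_k latent log rate (scalar).
#' @param choice_scale logistic noise scale (log-k units).
#' @return data frame: `item_id`, `value` (0 = immediate, 1 = delayed).
#' @export
simulate_mcq_choices <- function(bank, log_k, choice_scale = 0.5) {
  ki <- indifference_k(bank)
  p_imm <- if (choice_scale > 0) {
    plogis((log_k - log(ki)) / choice_scale)
  } else {
    as.numeric(log_k > log(ki))
  }
  data.frame(item_id = bank$item_id,
             value = 1 - rbinom(length(ki), 1, p_imm),
             stringsAsFactors = FALSE)
}

#' Simulate a complete two-phase EMA discounting study
#'
#' Generates the full long-format dataset the analysis pipeline consumes:
#' phase-1 baseline responses, phase-2 baseline responses, phase-2 momentary
#' follow-up responses with Bernoulli-compliance missingness, per-survey
#' substance-use/craving endorsements logistically linked to the latent
#' trait, and demographics. Defaults emulate the intended study design:
#' 97 participants, 1 baseline + 18 follow-up surveys (3/day for 6 days),
#' ~84% follow-up compliance, a cohort whose ideal time responses span the
#' 1-364-day slider for the central items but clamp at the floor for the
#' nearly-undiscounted $99 item, and low (4-8%) endorsement base rates.
#'
#' @param n cohort size (default 97).
#' @param seed RNG seed fixing the whole study.
#' @param preset `"clean"` (no contamination), `"contaminated"` (2 + 1
#'   straightliners and 5 planted outliers) or `"null"` (clean, with all
#'   endorsement-trait slopes zero).
#' @param mu,sigma,rho latent trait parameters, see [respondent_profiles()].
#' @param tau named item-noise SDs per scale on the log-k scale
#'   (default `c(time = 0.5, monetary = 0.9)`; the monetary instrument is
#'   noisier, mirroring its weaker field performance).
#' @param mcq_choice_scale logistic choice-noise scale for the MCQ.
#' @param time_bank,monetary_bank,mcq_items item banks.
#' @param scales which instruments to administer.
#' @param n_followups number of phase-2 follow-up surveys (default 18).
#' @param compliance per-follow-up completion probability (default 15/18,
#'   giving ~16 of 19 completed surveys including the baseline).
#' @param resolution named slider resolutions (`time` days, `monetary` US $;
#'   0 disables rounding).
#' @param outlier_offset latent shift of planted outliers (units of sigma).
#' @param base_rates named per-survey endorsement base probabilities.
#' @param gamma named slopes of log-odds of endorsement per unit latent
#'   log k (centered at `mu`).
#' @return list of class `dd_study`: `responses` (long format, all scales
#'   and phases), `endorsements` (per participant x phase-2 survey),
#'   `covariates` (`sex`, `age`), `profiles` (generative truth incl.
#'   behavior), `clamp_counts` (per participant x phase x scale count of
#'   generation-side clamped baseline responses) and `settings`.
#' @export
simulate_study <- function(n = 97, seed = NULL,
                           preset = c("clean", "contaminated", "null"),
                           mu = log(0.08), sigma = 1.0, rho = 0.8,
                           tau = c(time = 0.5, monetary = 0.9),
                           mcq_choice_scale = 0.5,
                           time_bank = time_selection_bank(),
                           monetary_bank = monetary_selection_bank(),
                           mcq_items = mcq_bank(),
                           scales = c("time", "monetary", "mcq"),
                           n_followups = 18, compliance = 15 / 18,
                           resolution = c(time = 1, monetary = 1),
                           outlier_offset = 7,
                           base_rates = c(use_alcohol = 0.04, use_cannabis = 0.04,
                                          use_tobacco = 0.06, crave_alcohol = 0.08,
                                          crave_cannabis = 0.08, crave_tobacco = 0.07),
                           gamma = c(use_alcohol = 0.25, use_cannabis = 0,
                                     use_tobacco = 0.7, crave_alcohol = 0.3,
                                     crave_cannabis = 0, crave_tobacco = 0.6)) {
  preset <- match.arg(preset)
  if (!is.null(seed)) set.seed(seed)
  contam <- switch(preset,
                   clean = c(0, 0, 0),
                   null = c(0, 0, 0),
                   contaminated = c(2, 1, 5))
  if (preset == "null") gamma[] <- 0

  profiles <- respondent_profiles(
    n, mu = mu, sigma = sigma, rho = rho,
    n_straightline_min = contam[1], n_straightline_max = contam[2],
    n_outliers = contam[3], outlier_offset = outlier_offset
  )
  covariates <- data.frame(
    participant_id = profiles$participant_id,
    sex = sample(c("female", "male"), n, replace = TRUE, prob = c(0.74, 0.26)),
    age = round(18 + 53 * stats::rbeta(n, 1.5, 2)),
    stringsAsFactors = FALSE
  )

  banks <- list(time = time_bank, monetary = monetary_bank)
  occ_table <- rbind(
    data.frame(phase = "phase1", occasion = 0),
    data.frame(phase = "phase2_baseline", occasion = 0),
    if (n_followups > 0) data.frame(phase = "phase2_followup",
                                    occasion = seq_len(n_followups))
  )

  responses <- vector("list", n)
  clamp_rows <- vector("list", n)
  endorse_rows <- vector("list", n)
  endorse_vars <- names(base_rates)

  for (i in seq_len(n)) {
    pr <- profiles[i, ]
    followup_done <- rbinom(n_followups, 1, compliance) == 1
    per_occ <- vector("list", nrow(occ_table))
    for (o in seq_len(nrow(occ_table))) {
      phase <- occ_table$phase[o]
      occasion <- occ_table$occasion[o]
      if (phase == "phase2_followup" && !followup_done[occasion]) next
      latent <- if (phase == "phase1") pr$latent_lk_phase1 else pr$latent_lk_phase2
      rows <- list()
      for (sc in intersect(scales, names(banks))) {
        bank <- banks[[sc]]
        if (pr$behavior %in% c("straightline_min", "straightline_max")) {
          bound <- if (pr$behavior == "straightline_min") bank$response_min else bank$response_max
          sim <- data.frame(item_id = bank$item_id, value = bound,
                            clamped = FALSE, stringsAsFactors = FALSE)
        } else {
          # planted sd_outlier contaminants respond model-consistently
          # (no item noise): their extreme scores are deterministic, keeping
          # the contamination magnitude well separated from the clean tail
          tau_i <- if (pr$behavior == "sd_outlier") 0 else unname(tau[sc])
          sim <- simulate_responses(bank, latent, tau = tau_i,
                                    resolution = unname(resolution[sc]))
        }
        sim$scale <- sc
        rows[[sc]] <- sim
      }
      if ("mcq" %in% scales && phase %in% c("phase1", "phase2_baseline")) {
        mc <- if (pr$behavior == "straightline_min") {
          data.frame(item_id = mcq_items$item_id, value = 0)  # always immediate
        } else if (pr$behavior == "straightline_max") {
          data.frame(item_id = mcq_items$item_id, value = 1)  # always delayed
        } else {
          simulate_mcq_choices(mcq_items, latent, mcq_choice_scale)
        }
        mc$clamped <- FALSE
        mc$scale <- "mcq"
        rows$mcq <- mc
      }
      occ_df <- do.call(rbind, rows)
      occ_df$participant_id <- pr$participant_id
      occ_df$phase <- phase
      occ_df$occasion <- occasion
      per_occ[[o]] <- occ_df
    }
    resp_i <- do.call(rbind, per_occ)
    responses[[i]] <- resp_i[, c("participant_id", "phase", "occasion",
                                 "item_id", "value", "scale", "clamped")]

    # phase-2 endorsements: baseline survey (occasion 0) is always completed
    completed <- c(TRUE, followup_done)
    p_endorse <- plogis(qlogis(base_rates) +
                          gamma * (pr$latent_lk_phase2 - mu))
    endo <- data.frame(participant_id = pr$participant_id,
                       occasion = 0:n_followups,
                       completed = as.integer(completed))
    for (v in endorse_vars) {
      endo[[v]] <- ifelse(completed, rbinom(n_followups + 1, 1, p_endorse[[v]]), NA)
    }
    endorse_rows[[i]] <- endo
  }

  responses <- do.call(rbind, responses)
  rownames(responses) <- NULL
  baseline <- responses[responses$occasion == 0 & responses$scale != "mcq", ,
                        drop = FALSE]
  clamp_counts <- aggregate(list(n_clamped = baseline$clamped),
                            by = list(participant_id = baseline$participant_id,
                                      phase = baseline$phase,
                                      scale = baseline$scale),
                            FUN = sum)

  study <- list(
    responses = responses[, c("participant_id", "phase", "occasion",
                              "item_id", "value")],
    endorsements = do.call(rbind, endorse_rows),
    covariates = covariates,
    profiles = profiles,
    clamp_counts = clamp_counts,
    settings = list(n = n, seed = seed, preset = preset, mu = mu,
                    sigma = sigma, rho = rho, tau = tau,
                    mcq_choice_scale = mcq_choice_scale,
                    n_followups = n_followups, compliance = compliance,
                    resolution = resolution, outlier_offset = outlier_offset,
                    base_rates = base_rates, gamma = gamma, scales = scales),
    banks = list(time = time_bank, monetary = monetary_bank, mcq = mcq_items)
  )
  rownames(study$endorsements) <- NULL
  class(study) <- "dd_study"
  study
}

#' @export
print.dd_study <- function(x, ...) {
  s <- x$settings
  cat(sprintf("<dd_study> %d participants, preset '%s', %d responses\n",
              s$n, s$preset, nrow(x$responses)))
  cat(sprintf("  latent log k ~ N(%.2f, %.2f^2), between-phase rho = %.2f\n",
              s$mu, s$sigma, s$rho))
  invisible(x)
}

#' Per-person outcome table of a simulated study
#'
#' Convenience join of [endorsement_percentages()] with the study's
#' demographics — the input [fit_adjusted_models()] expects.
#'
#' @param study a `dd_study`.
#' @return data frame with `participant_id`, `surveys_completed`, `pct_*`
#'   columns, `sex`, `age`.
#' @export
participant_outcomes <- function(study) {
  merge(endorsement_percentages(study$endorsements), study$covariates,
        by = "participant_id")
}

#' Synthetic linear outcome with a known regression coefficient
#'
#' Builds a per-person percentage outcome that is exactly linear in the
#' observed (centered) log score plus Gaussian noise — the ground-truth
#' generator for checking coefficient recovery and CI coverage of
#' [fit_adjusted_models()].
#'
#' @param outcomes per-person covariate table (see [participant_outcomes()]).
#' @param estimates a `dd_estimates` data frame supplying the predictor.
#' @param scale,phase predictor score to use.
#' @param beta true coefficient, percentage points per unit log k.
#' @param beta_age,beta_sex,beta_surveys true covariate effects.
#' @param intercept mean outcome level.
#' @param sd residual SD.
#' @return `outcomes` with an added `pct_synthetic` column.
#' @export
simulate_linear_outcomes <- function(outcomes, estimates, scale = "time",
                                     phase = "phase2_baseline", beta = 5,
                                     beta_age = 0, beta_sex = 0,
                                     beta_surveys = 0, intercept = 20,
                                     sd = 10) {
  e <- as.data.frame(estimates)
  e <- e[e$scale == scale & e$phase == phase & e$occasion == 0,
         c("participant_id", "log_k")]
  dat <- merge(outcomes, e, by = "participant_id")
  sex_ind <- as.numeric(factor(dat$sex)) - 1
  dat$pct_synthetic <- intercept +
    beta * (dat$log_k - mean(dat$log_k)) +
    beta_age * (dat$age - mean(dat$age)) +
    beta_sex * sex_ind +
    beta_surveys * (dat$surveys_completed - mean(dat$surveys_completed)) +
    rnorm(nrow(dat), 0, sd)
  dat$log_k <- NULL
  dat
}
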