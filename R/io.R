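#' Read and write long-format response tables
#'
#' The canonical on-disk dialect is comma-delimited UTF-8 with a header:
#' `participant_id, phase, occasion, item_id, value`. Reading validates
#' against an item bank: unknown item ids, non-numeric or out-of-bounds
#' values and duplicate (participant, phase, occasion, item) keys are
#' rejected with the offending row numbers.
#'
#' @param path file path.
#' @param banks item bank (or list of banks) to validate against.
#' @param responses response data frame to write.
#' @return `read_responses()` returns the validated data frame;
#'   `write_responses()` returns `path` invisibly.
#' @export
read_responses <- function(path, banks) {
  if (inherits(banks, "dd_item_bank")) banks <- list(banks)
  bank <- do.call(rbind, lapply(banks, function(b) as.data.frame(validate_item_bank(b))))
  df <- read.csv(path, stringsAsFactors = FALSE)
  required <- c("participant_id", "phase", "occasion", "item_id", "value")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols)) {
    stop("response file lacks column(s): ", paste(missing_cols, collapse = ", "))
  }
  phases <- c("phase1", "phase2_baseline", "phase2_followup")
  bad <- which(!df$phase %in% phases)
  if (length(bad)) stop("unknown phase at row(s): ", paste(head(bad), collapse = ", "))
  bad <- which(!df$item_id %in% bank$item_id)
  if (length(bad)) {
    stop("unknown item_id at row(s): ", paste(head(bad), collapse = ", "))
  }
  if (!is.numeric(df$value)) {
    suppressWarnings(v <- as.numeric(df$value))
    bad <- which(is.na(v) & !is.na(df$value))
    if (length(bad)) stop("non-numeric value at row(s): ", paste(head(bad), collapse = ", "))
    df$value <- v
  }
  idx <- match(df$item_id, bank$item_id)
  cont <- bank$kind[idx] != "mcq_binary"
  bad <- which(cont & (df$value < bank$response_min[idx] |
                         df$value > bank$response_max[idx]))
  if (length(bad)) {
    stop("value outside slider bounds at row(s): ", paste(head(bad), collapse = ", "))
  }
  bad <- which(!cont & !df$value %in% c(0, 1))
  if (length(bad)) {
    stop("binary items need value 0 or 1 at row(s): ", paste(head(bad), collapse = ", "))
  }
  key <- paste(df$participant_id, df$phase, df$occasion, df$item_id)
  if (anyDuplicated(key)) {
    stop("duplicate (participant, phase, occasion, item) at row(s): ",
         paste(head(which(duplicated(key))), collapse = ", "))
  }
  df[required]
}

#' @rdname read_responses
#' @export
write_responses <- function(responses, path) {
  cols <- c("participant_id", "phase", "occasion", "item_id", "value")
  write.csv(responses[cols], path, row.names = FALSE)
  invisible(path)
}

#' Write or read a simulated study as delimited tables
#'
#' Persists a [simulate_study()] result as plain CSV files
#' (`responses.csv`, `endorsements.csv`, `covariates.csv`) in `dir`, the
#' same tables the readers consume.
#'
#' @param study a `dd_study`.
#' @param dir output directory (created if needed).
#' @param banks banks used to validate responses on reading.
#' @return `write_study()` returns `dir` invisibly; `read_study()` returns a
#'   list with `responses`, `endorsements`, `covariates`.
#' @export
write_study <- function(study, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_responses(study$responses, file.path(dir, "responses.csv"))
  write.csv(study$endorsements, file.path(dir, "endorsements.csv"), row.names = FALSE)
  write.csv(study$covariates, file.path(dir, "covariates.csv"), row.names = FALSE)
  invisible(dir)
}

#' @rdname write_study
#' @export
read_study <- function(dir, banks = list(time_selection_bank(),
                                         monetary_selection_bank(),
                                         mcq_bank())) {
  list(
    responses = read_responses(file.path(dir, "responses.csv"), banks),
    endorsements = read.csv(file.path(dir, "endorsements.csv"),
                            stringsAsFactors = FALSE),
    covariates = read.csv(file.path(dir, "covariates.csv"),
                          stringsAsFactors = FALSE)
  )
}

# short stable fingerprint of an R object (for stamping reports)
config_fingerprint <- function(x) {
  bytes <- as.integer(serialize(x, NULL, version = 2))
  h <- 0
  for (b in bytes) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", h)
}

#' Run the full measurement-validation pipeline
#'
#' Executes, in order: quality control (straightliners, then 3-SD outliers,
#' then the valid-in-both-phases analytic sample), scale scoring (time,
#' monetary, MCQ), item-total correlations per scale and phase, test-retest
#' reliability, the convergent-validity correlation matrix, random-subset
#' abbreviation of the time and monetary scales (subsets drawn from the
#' informative items, correlated against the full scale), and the adjusted
#' endorsement regressions. Any stage failure aborts with the stage name.
#'
#' @param responses long-format response table (all phases).
#' @param endorsements per-survey endorsement table (see
#'   [endorsement_percentages()]); `NULL` skips the association stage.
#' @param covariates per-person `sex`/`age` table; `NULL` skips associations.
#' @param time_bank,monetary_bank,mcq_items item banks.
#' @param qc_threshold,qc_on outlier rule settings, see [flag_sd_outliers()].
#' @param cutoff item informativeness cutoff, see [item_total_correlations()].
#' @param abbrev_sizes,abbrev_iterations abbreviation settings.
#' @param seed seed for the abbreviation resampling.
#' @param clamp_floor floor (days) for non-positive time responses.
#' @return object of class `dd_report`: `qc`, `estimates`, `items`,
#'   `item_total` (per scale x phase), `informative_items`, `retest`,
#'   `validity`, `abbreviation`, `regressions`, plus `seed` and
#'   `fingerprint`.
#' @export
run_pipeline <- function(responses, endorsements = NULL, covariates = NULL,
                         time_bank = time_selection_bank(),
                         monetary_bank = monetary_selection_bank(),
                         mcq_items = mcq_bank(),
                         qc_threshold = 3, qc_on = "log", cutoff = 0.5,
                         abbrev_sizes = 1:5, abbrev_iterations = 100,
                         seed = 1, clamp_floor = 1) {
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }
  settings <- list(qc_threshold = qc_threshold, qc_on = qc_on, cutoff = cutoff,
                   abbrev_sizes = abbrev_sizes,
                   abbrev_iterations = abbrev_iterations, seed = seed,
                   clamp_floor = clamp_floor)

  qc <- stage("qc", run_qc(responses, list(time_bank, monetary_bank),
                           threshold = qc_threshold, on = qc_on,
                           clamp_floor = clamp_floor))
  sample_ids <- qc$analytic_sample

  cont_bank <- validate_item_bank(rbind(as.data.frame(time_bank),
                                        as.data.frame(monetary_bank)))
  items <- stage("scoring", score_items(responses, cont_bank,
                                        clamp_floor = clamp_floor))
  estimates <- stage("scoring", {
    est_cont <- score_scales(responses, cont_bank, clamp_floor = clamp_floor)
    mcq_resp <- responses[responses$item_id %in% mcq_items$item_id, , drop = FALSE]
    if (nrow(mcq_resp)) {
      est_mcq <- score_mcq(mcq_resp, mcq_items)
      est_mcq$consistency <- NULL
      rbind(est_cont, est_mcq)
    } else {
      est_cont
    }
  })

  phases <- intersect(c("phase1", "phase2_baseline"), unique(responses$phase))
  item_total <- stage("item_total", {
    grid <- expand.grid(scale = c("time", "monetary"), phase = phases,
                        stringsAsFactors = FALSE)
    res <- lapply(seq_len(nrow(grid)), function(i) {
      item_total_correlations(items, scale = grid$scale[i],
                              phase = grid$phase[i], cutoff = cutoff,
                              participants = sample_ids)
    })
    names(res) <- paste(grid$phase, grid$scale, sep = ".")
    res
  })
  informative <- lapply(c(time = "time", monetary = "monetary"), function(sc) {
    it <- item_total[[paste0(phases[1], ".", sc)]]
    it$item_id[!is.na(it$informative) & it$informative]
  })

  retest <- stage("test_retest", {
    if (length(phases) == 2) {
      lapply(c(time = "time", monetary = "monetary", mcq = "mcq"), function(sc) {
        if (!sc %in% estimates$scale) return(NULL)
        test_retest(estimates, sc, participants = sample_ids)
      })
    }
  })
  validity <- stage("convergent_validity",
                    convergent_validity(estimates, phases = phases,
                                        participants = sample_ids))
  abbreviation <- stage("abbreviation", {
    lapply(c(time = "time", monetary = "monetary"), function(sc) {
      cand <- informative[[sc]]
      if (length(cand) < max(abbrev_sizes)) cand <- NULL  # fall back to all items
      abbreviation_analysis(items, scale = sc, phase = phases[1],
                            candidate_items = cand,
                            sizes = abbrev_sizes,
                            iterations = abbrev_iterations, seed = seed,
                            participants = sample_ids)
    })
  })

  regressions <- NULL
  if (!is.null(endorsements) && !is.null(covariates)) {
    regressions <- stage("associations", {
      outcomes <- merge(endorsement_percentages(endorsements), covariates,
                        by = "participant_id")
      fit_adjusted_models(outcomes, estimates,
                          scales = intersect(c("mcq", "time", "monetary"),
                                             unique(estimates$scale)),
                          participants = sample_ids)
    })
  }

  structure(list(qc = qc, estimates = estimates, items = items,
                 item_total = item_total, informative_items = informative,
                 retest = retest, validity = validity,
                 abbreviation = abbreviation, regressions = regressions,
                 seed = seed, settings = settings,
                 fingerprint = config_fingerprint(settings)),
            class = "dd_report")
}

#' @export
print.dd_report <- function(x, ...) {
  cat("<dd_report> config", x$fingerprint, "seed", x$seed, "\n\n")
  print(x$qc)
  cat("\nInformative items (r >=", x$settings$cutoff, "):\n")
  for (sc in names(x$informative_items)) {
    cat(" ", sc, ":", paste(x$informative_items[[sc]], collapse = ", "), "\n")
  }
  if (!is.null(x$retest)) {
    cat("\nTest-retest (phase1 vs phase2 baseline):\n")
    for (sc in names(x$retest)) {
      rt <- x$retest[[sc]]
      if (!is.null(rt)) {
        cat(sprintf("  %-9s r = %.2f (p = %.2g, n = %d)\n", sc, rt$r, rt$p, rt$n))
      }
    }
  }
  cat("\n")
  print(x$validity)
  for (sc in names(x$abbreviation)) {
    cat("\n")
    print(x$abbreviation[[sc]])
  }
  if (!is.null(x$regressions)) {
    cat("\n")
    print(x$regressions)
  }
  invisible(x)
}

#' Write a pipeline report's tables to disk
#'
#' Emits delimited tables (QC decisions and flow summary, estimates,
#' item-total correlations, validity matrix, abbreviation draws, regression
#' rows) into `dir`, each stamped with the report's config fingerprint and
#' seed in a sidecar `MANIFEST.txt`.
#'
#' @param report a `dd_report`.
#' @param dir output directory.
#' @return `dir`, invisibly.
#' @export
write_report <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  out <- function(df, name) {
    write.csv(df, file.path(dir, name), row.names = FALSE)
  }
  out(report$qc$decisions, "qc_decisions.csv")
  out(report$qc$summary, "qc_summary.csv")
  out(as.data.frame(report$estimates), "estimates.csv")
  it <- do.call(rbind, lapply(names(report$item_total), function(nm) {
    cbind(group = nm, report$item_total[[nm]])
  }))
  out(it, "item_total.csv")
  r <- report$validity$r
  out(cbind(variable = rownames(r), as.data.frame(r)), "validity_r.csv")
  ab <- do.call(rbind, lapply(names(report$abbreviation), function(nm) {
    cbind(scale = nm, report$abbreviation[[nm]]$summary)
  }))
  out(ab, "abbreviation.csv")
  if (!is.null(report$regressions)) {
    out(as.data.frame(report$regressions), "regressions.csv")
  }
  writeLines(c(paste("fingerprint:", report$fingerprint),
               paste("seed:", report$seed),
               paste("analytic_n:", length(report$qc$analytic_sample))),
             file.path(dir, "MANIFEST.txt"))
  invisible(dir)
}
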