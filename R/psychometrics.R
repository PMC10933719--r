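#' Item-total correlations (item informativeness)
#'
#' Pearson correlation between each item's log discounting rate and the full
#' scale's log geometric-mean rate, per phase. An item whose correlation
#' falls below `cutoff` is marked uninformative; in the intended workflow
#' such items are dropped before scale abbreviation. By default the total
#' includes the item itself (the full-scale score); `include_item = FALSE`
#' gives the corrected, item-excluded variant.
#'
#' @param items per-item rates from [score_items()].
#' @param scale `"time"` or `"monetary"`.
#' @param phase phase whose baseline responses to use (default `"phase1"`).
#' @param cutoff informativeness cutoff on r (default 0.5).
#' @param include_item include the item in the total score (default TRUE).
#' @param participants optional id vector restricting to the analytic sample.
#' @return data frame: `item_id`, `r`, `n`, `informative` (NA when r is
#'   undefined), `note`.
#' @export
item_total_correlations <- function(items, scale = c("time", "monetary"),
                                    phase = "phase1", cutoff = 0.5,
                                    include_item = TRUE,
                                    participants = NULL) {
  scale <- match.arg(scale)
  g <- items[items$scale == scale & items$phase == phase & items$occasion == 0, ,
             drop = FALSE]
  if (!is.null(participants)) {
    g <- g[g$participant_id %in% participants, , drop = FALSE]
  }
  if (!nrow(g)) stop("no item-level rates for ", scale, "/", phase)
  wide <- unstack_items(g)
  totals <- rowMeans(wide)
  rows <- lapply(colnames(wide), function(id) {
    x <- wide[, id]
    total <- if (include_item) totals else rowMeans(wide[, colnames(wide) != id, drop = FALSE])
    ok <- complete.cases(x, total)
    n <- sum(ok)
    if (n < 3) stop("fewer than 3 complete pairs for item ", id)
    if (sd(x[ok]) == 0 || sd(total[ok]) == 0) {
      data.frame(item_id = id, r = NA_real_, n = n, informative = NA,
                 note = "zero variance; r undefined", stringsAsFactors = FALSE)
    } else {
      r <- cor(x[ok], total[ok])
      data.frame(item_id = id, r = r, n = n, informative = r >= cutoff,
                 note = "", stringsAsFactors = FALSE)
    }
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# participant x item matrix of log item rates (baseline rows of one
# phase/scale, one occasion)
unstack_items <- function(g) {
  ids <- sort(unique(g$participant_id))
  item_ids <- unique(g$item_id)
  wide <- matrix(NA_real_, length(ids), length(item_ids),
                 dimnames = list(ids, item_ids))
  wide[cbind(match(g$participant_id, ids), match(g$item_id, item_ids))] <- g$log_k
  wide
}

#' Test-retest reliability across phases
#'
#' Pearson correlation of per-person log scores between two measurement
#' occasions (by default phase 1 vs the phase 2 baseline, several months
#' apart). Participants missing either score are dropped listwise.
#'
#' @param estimates a `dd_estimates` data frame.
#' @param scale scale to correlate (`"time"`, `"monetary"` or `"mcq"`).
#' @param phase_x,phase_y the two phases (baseline occasions).
#' @param participants optional analytic-sample restriction.
#' @return list: `r`, `p`, `n`, `conf_int` (Fisher-z 95% CI), `scale`.
#' @export
test_retest <- function(estimates, scale, phase_x = "phase1",
                        phase_y = "phase2_baseline", participants = NULL) {
  pair <- paired_scores(estimates, scale, scale, phase_x, phase_y, participants)
  if (nrow(pair) < 3) stop("fewer than 3 complete pairs")
  ct <- cor.test(pair$x, pair$y, method = "pearson")
  list(r = unname(ct$estimate), p = ct$p.value, n = nrow(pair),
       conf_int = unname(ct$conf.int), scale = scale)
}

paired_scores <- function(estimates, scale_x, scale_y, phase_x, phase_y,
                          participants = NULL) {
  e <- as.data.frame(estimates)
  e <- e[e$occasion == 0, , drop = FALSE]
  if (!is.null(participants)) {
    e <- e[e$participant_id %in% participants, , drop = FALSE]
  }
  a <- e[e$scale == scale_x & e$phase == phase_x, c("participant_id", "log_k")]
  b <- e[e$scale == scale_y & e$phase == phase_y, c("participant_id", "log_k")]
  m <- merge(a, b, by = "participant_id", suffixes = c("_x", "_y"))
  data.frame(participant_id = m$participant_id, x = m$log_k_x, y = m$log_k_y)
}

#' Convergent-validity correlation matrix
#'
#' Full symmetric matrix of pairwise Pearson correlations (with p-values and
#' pairwise n) among the log discounting scores of every (scale, phase)
#' combination present — the layout used to compare a new instrument against
#' the MCQ gold standard within and across phases.
#'
#' @param estimates a `dd_estimates` data frame (baseline occasions used).
#' @param scales scales to include (default all present).
#' @param phases phases to include (default `phase1` and `phase2_baseline`).
#' @param participants optional analytic-sample restriction.
#' @return object of class `dd_validity`: list of matrices `r`, `p`, `n`.
#' @export
convergent_validity <- function(estimates, scales = NULL,
                                phases = c("phase1", "phase2_baseline"),
                                participants = NULL) {
  e <- as.data.frame(estimates)
  e <- e[e$occasion == 0 & e$phase %in% phases, , drop = FALSE]
  if (!is.null(participants)) {
    e <- e[e$participant_id %in% participants, , drop = FALSE]
  }
  if (is.null(scales)) scales <- unique(e$scale)
  vars <- expand.grid(scale = scales, phase = phases, stringsAsFactors = FALSE)
  vars <- vars[order(match(vars$phase, phases)), , drop = FALSE]
  labels <- paste(vars$phase, vars$scale, sep = ".")
  ids <- sort(unique(e$participant_id))
  score <- matrix(NA_real_, length(ids), nrow(vars),
                  dimnames = list(ids, labels))
  for (j in seq_len(nrow(vars))) {
    sub <- e[e$scale == vars$scale[j] & e$phase == vars$phase[j], , drop = FALSE]
    score[match(sub$participant_id, ids), j] <- sub$log_k
  }
  p <- r <- n <- matrix(NA_real_, ncol(score), ncol(score),
                        dimnames = list(labels, labels))
  for (i in seq_len(ncol(score))) {
    for (j in seq_len(i)) {
      ok <- complete.cases(score[, i], score[, j])
      n[i, j] <- n[j, i] <- sum(ok)
      if (i == j) {
        r[i, j] <- 1
        next
      }
      if (sum(ok) >= 3) {
        ct <- cor.test(score[ok, i], score[ok, j])
        r[i, j] <- r[j, i] <- unname(ct$estimate)
        p[i, j] <- p[j, i] <- ct$p.value
      }
    }
  }
  structure(list(r = r, p = p, n = n), class = "dd_validity")
}

#' @export
print.dd_validity <- function(x, digits = 2, ...) {
  cat("<dd_validity> pairwise Pearson correlations of log discounting scores\n")
  print(round(x$r, digits))
  invisible(x)
}

#' Random-subset scale abbreviation
#'
#' How well does a short random subset of items approximate the full scale?
#' For each subset size N, draws `iterations` random N-item subsets (without
#' replacement within a draw, independently across draws) from the candidate
#' items, scores each subset by its log geometric-mean rate and correlates it
#' with the full-scale score. Uninformative items should be removed from
#' `candidate_items` first; `full_items` controls which items define the
#' full-scale denominator (by default every item present, i.e. the original
#' full scale).
#'
#' @param items per-item rates from [score_items()].
#' @param scale,phase which scale/phase (baseline occasion) to analyse.
#' @param candidate_items item ids subsets are drawn from (default: all
#'   items of the scale).
#' @param full_items item ids defining the full-scale score (default: all
#'   items of the scale).
#' @param sizes subset sizes N (default `1:5`). `length(full_items)` itself
#'   is accepted only as a self-check (every r is then 1 when
#'   `candidate_items == full_items`).
#' @param iterations random subsets per size (default 100).
#' @param seed RNG seed governing the whole curve.
#' @param participants optional analytic-sample restriction.
#' @return object of class `dd_abbrev`: `draws` (size, iteration, r),
#'   `summary` (per-size mean, sd and quantiles of r), and the settings.
#' @export
abbreviation_analysis <- function(items, scale = "time", phase = "phase1",
                                  candidate_items = NULL, full_items = NULL,
                                  sizes = 1:5, iterations = 100, seed = 1,
                                  participants = NULL) {
  g <- items[items$scale == scale & items$phase == phase & items$occasion == 0, ,
             drop = FALSE]
  if (!is.null(participants)) {
    g <- g[g$participant_id %in% participants, , drop = FALSE]
  }
  wide <- unstack_items(g)
  if (is.null(full_items)) full_items <- colnames(wide)
  if (is.null(candidate_items)) candidate_items <- colnames(wide)
  stopifnot(all(full_items %in% colnames(wide)),
            all(candidate_items %in% colnames(wide)))
  if (any(sizes > length(candidate_items))) {
    stop("subset size exceeds the number of candidate items")
  }
  total <- rowMeans(wide[, full_items, drop = FALSE])

  set.seed(seed)
  draws <- do.call(rbind, lapply(sizes, function(N) {
    r <- vapply(seq_len(iterations), function(i) {
      pick <- sample(candidate_items, N)
      sub <- rowMeans(wide[, pick, drop = FALSE])
      ok <- complete.cases(sub, total)
      cor(sub[ok], total[ok])
    }, numeric(1))
    data.frame(size = N, iteration = seq_len(iterations), r = r)
  }))
  summ <- do.call(rbind, lapply(split(draws, draws$size), function(d) {
    data.frame(size = d$size[1], mean_r = mean(d$r), sd_r = sd(d$r),
               q05 = quantile(d$r, 0.05), q95 = quantile(d$r, 0.95))
  }))
  rownames(summ) <- NULL
  structure(list(draws = draws, summary = summ, scale = scale, phase = phase,
                 candidate_items = candidate_items, full_items = full_items,
                 iterations = iterations, seed = seed),
            class = "dd_abbrev")
}

#' @export
print.dd_abbrev <- function(x, ...) {
  cat(sprintf("<dd_abbrev> %s/%s: %d-item full scale, subsets from %d items, %d iterations\n",
              x$phase, x$scale, length(x$full_items),
              length(x$candidate_items), x$iterations))
  print(x$summary, row.names = FALSE)
  invisible(x)
}

#' Attenuation-predicted test-retest correlation
#'
#' Classical-test-theory prediction for the observed between-phase
#' correlation of a noisy score: with latent trait SD `sigma`, between-phase
#' latent correlation `rho` and score-level measurement noise SD `tau` on
#' the same (log) scale, the observed correlation is
#' \deqn{r = \rho \sigma^2 / (\sigma^2 + \tau^2).}
#' For a scale averaging m items with independent item noise SD
#' \eqn{\tau_{item}}, use `tau = tau_item / sqrt(m)`.
#'
#' @param rho between-phase correlation of the latent trait.
#' @param sigma latent trait SD (log-k scale).
#' @param tau score-level noise SD (log-k scale).
#' @return predicted Pearson correlation.
#' @export
predicted_retest_r <- function(rho, sigma, tau) {
  rho * sigma^2 / (sigma^2 + tau^2)
}
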