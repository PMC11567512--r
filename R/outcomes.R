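# DALY accounting and policy-comparison analytics.
#
# DALYs = YLL + YLD.  YLL uses a fixed reference life expectancy
# (default 70 years), undiscounted; YLD is disability weight times time
# lived with the condition, attributed pro rata to 365-day calendar years.
# Replicate aggregation uses the normal approximation for 95% confidence
# intervals; percent changes are computed on means against the benchmark
# (No Policy) arm.

#' Years of life lost for one death
#'
#' `max(0, reference - age_at_death)`, undiscounted.
#'
#' @param age_at_death Age in years (>= 0); vectorised.
#' @param reference_life_expectancy Reference life expectancy in years
#'   (default 70).
#' @return Years of life lost.
#' @export
compute_yll <- function(age_at_death, reference_life_expectancy = 70) {
  if (any(age_at_death < 0))
    stop("age_at_death must be >= 0", call. = FALSE)
  pmax(0, reference_life_expectancy - age_at_death)
}

#' Years lived with disability, per cause and calendar year
#'
#' For each episode, `disability_weight * days / 365`, split pro rata
#' across the 365-day calendar years the episode spans. Splitting is
#' conservative: the year cells of a spanning episode sum exactly to the
#' single-cell value of an equivalent non-spanning episode.
#'
#' @param episodes Data frame with columns `cause_id`, `onset_day`,
#'   `end_day` (simulation days; `end_day` exclusive, use the horizon end
#'   for censored episodes).
#' @param causes Named list of `cause_spec` providing disability weights.
#' @param start_year First calendar year (year of day 0); default 1.
#' @return Data frame `cause`, `year`, `yld`, one row per non-empty cell.
#' @export
compute_yld <- function(episodes, causes, start_year = 1L) {
  out <- list()
  weights <- vapply(causes, `[[`, 1, "disability_weight")
  names(weights) <- vapply(causes, `[[`, "", "cause_id")
  for (i in seq_len(nrow(episodes))) {
    cid <- episodes$cause_id[i]
    w <- weights[[cid]]
    a <- episodes$onset_day[i]
    b <- episodes$end_day[i]
    if (is.na(w))
      stop(sprintf("episode cause '%s' not in cause catalogue", cid),
           call. = FALSE)
    if (b <= a || w <= 0) next
    y1 <- a %/% 365; y2 <- (b - 1) %/% 365
    for (y in y1:y2) {
      lo <- max(a, y * 365); hi <- min(b, (y + 1) * 365)
      key <- paste(cid, y)
      out[[key]] <- c(out[[key]], w * (hi - lo) / 365)
    }
  }
  if (!length(out))
    return(data.frame(cause = character(), year = integer(),
                      yld = numeric()))
  keys <- strsplit(names(out), " ")
  data.frame(cause = vapply(keys, `[[`, "", 1),
             year = as.integer(vapply(keys, `[[`, "", 2)) + start_year,
             yld = vapply(out, sum, 1, USE.NAMES = FALSE))
}

#' Construct a per-replicate DALY ledger
#'
#' @param cells Data frame `cause`, `year`, `yll`, `yld` (unscaled,
#'   simulated-population years).
#' @param policy_id,replicate_id Run identifiers.
#' @param scale_factor Multiplier taking simulated totals to the national
#'   population (`national_population / initial_size`).
#' @return `cells` with class `daly_ledger` and identifying attributes.
#' @export
daly_ledger <- function(cells, policy_id, replicate_id, scale_factor = 1) {
  stopifnot(all(c("cause", "year", "yll", "yld") %in% names(cells)))
  if (any(cells$yll < 0) || any(cells$yld < 0))
    stop("yll and yld must be >= 0", call. = FALSE)
  attr(cells, "policy_id") <- policy_id
  attr(cells, "replicate_id") <- replicate_id
  attr(cells, "scale_factor") <- scale_factor
  class(cells) <- c("daly_ledger", "data.frame")
  cells
}

#' Total DALYs of a ledger (scaled)
#'
#' @param ledger A `daly_ledger`.
#' @param scaled Apply the ledger's scale factor (default `TRUE`).
#' @return Total DALYs (YLL + YLD summed over all cells).
#' @export
total_dalys <- function(ledger, scaled = TRUE) {
  s <- if (scaled) attr(ledger, "scale_factor") else 1
  s * sum(ledger$yll + ledger$yld)
}

#' Aggregate per-replicate ledgers into a policy-comparison report
#'
#' Computes, per policy: mean total DALYs with normal-approximation 95%
#' confidence intervals over replicates (`mean +/- 1.96 sd/sqrt(n)`),
#' percent change versus the benchmark policy (computed on means; the
#' benchmark's own change is exactly 0), per-year series, and the
#' per-cause decomposition. With a single replicate the intervals are
#' undefined and flagged via `degenerate_ci`.
#'
#' @param ledgers List of `daly_ledger` objects (all policies, all
#'   replicates; identical year ranges).
#' @param benchmark Benchmark policy id (default `"NP"` when present, else
#'   the first policy).
#' @return List of class `comparison_report`: `totals`, `per_year`,
#'   `per_cause`, `cells`, `benchmark`, `horizon_years`, `degenerate_ci`.
#' @export
aggregate_replicates <- function(ledgers, benchmark = NULL) {
  if (!length(ledgers)) stop("no ledgers to aggregate", call. = FALSE)
  cells <- do.call(rbind, lapply(ledgers, function(l) {
    data.frame(policy = attr(l, "policy_id"),
               replicate = attr(l, "replicate_id"),
               cause = l$cause, year = l$year,
               yll = l$yll * attr(l, "scale_factor"),
               yld = l$yld * attr(l, "scale_factor"))
  }))
  yrs <- lapply(ledgers, function(l) sort(unique(l$year)))
  if (length(unique(vapply(yrs, paste, "", collapse = ","))) != 1L)
    stop("ledgers have mismatched horizons", call. = FALSE)
  if (is.null(benchmark))
    benchmark <- if ("NP" %in% cells$policy) "NP" else cells$policy[1]
  if (!benchmark %in% cells$policy)
    stop(sprintf("benchmark policy '%s' not among ledgers", benchmark),
         call. = FALSE)
  cells$daly <- cells$yll + cells$yld
  # per-replicate totals
  rep_tot <- stats::aggregate(daly ~ policy + replicate, cells, sum)
  agg <- function(x) {
    n <- length(x)
    m <- mean(x)
    se <- if (n > 1) stats::sd(x) / sqrt(n) else NA_real_
    c(mean = m, lo = m - 1.96 * se, hi = m + 1.96 * se, n = n)
  }
  tot <- do.call(rbind, lapply(split(rep_tot$daly, rep_tot$policy), agg))
  totals <- data.frame(policy = rownames(tot), tot, row.names = NULL)
  bmean <- totals$mean[totals$policy == benchmark]
  totals$pct_change <- ifelse(
    totals$policy == benchmark, 0,
    100 * (totals$mean - bmean) / bmean)
  # per-year series (mean and CI over replicates)
  ry <- stats::aggregate(daly ~ policy + replicate + year, cells, sum)
  py <- do.call(rbind, lapply(split(ry, list(ry$policy, ry$year),
                                    drop = TRUE), function(g) {
    a <- agg(g$daly)
    data.frame(policy = g$policy[1], year = g$year[1],
               mean = a[["mean"]], lo = a[["lo"]], hi = a[["hi"]])
  }))
  py <- py[order(py$policy, py$year), , drop = FALSE]
  rownames(py) <- NULL
  # per-cause decomposition of mean totals
  rc <- stats::aggregate(daly ~ policy + replicate + cause, cells, sum)
  pc <- stats::aggregate(daly ~ policy + cause, rc, mean)
  names(pc)[names(pc) == "daly"] <- "mean"
  structure(list(totals = totals, per_year = py, per_cause = pc,
                 cells = cells, benchmark = benchmark,
                 horizon_years = length(yrs[[1]]),
                 degenerate_ci = max(totals$n) < 2),
            class = "comparison_report")
}

#' Recompute a comparison over a shorter event horizon
#'
#' All report quantities are recomputed on cumulative DALYs over the first
#' `horizon_years` calendar years only.
#'
#' @param report A `comparison_report`.
#' @param horizon_years Number of initial years (1 <= h <= simulated
#'   horizon).
#' @return A new `comparison_report` restricted to the horizon.
#' @export
horizon_view <- function(report, horizon_years) {
  if (horizon_years < 1)
    stop("horizon_years must be >= 1", call. = FALSE)
  if (horizon_years > report$horizon_years)
    stop(sprintf("horizon_years (%d) exceeds simulated horizon (%d)",
                 horizon_years, report$horizon_years), call. = FALSE)
  cells <- report$cells
  keep_years <- sort(unique(cells$year))[seq_len(horizon_years)]
  sub <- cells[cells$year %in% keep_years, , drop = FALSE]
  ledgers <- lapply(split(sub, list(sub$policy, sub$replicate), drop = TRUE),
                    function(g)
                      daly_ledger(data.frame(cause = g$cause, year = g$year,
                                             yll = g$yll, yld = g$yld),
                                  policy_id = g$policy[1],
                                  replicate_id = g$replicate[1],
                                  scale_factor = 1))
  aggregate_replicates(unname(ledgers), benchmark = report$benchmark)
}

#' Rank causes by their benchmark-policy DALY contribution
#'
#' Causes are ordered by total DALYs under the benchmark policy,
#' descending; residual causes (ids in `residual`) are not ranked and are
#' appended at the end regardless of size. Ties break stably by cause id.
#'
#' @param report A `comparison_report`.
#' @param residual Character vector of residual cause ids appended last
#'   (default `c("other", ".background")`).
#' @return Character vector of cause ids in display order.
#' @export
rank_causes <- function(report, residual = c("other", ".background")) {
  pc <- report$per_cause
  pc <- pc[pc$policy == report$benchmark, , drop = FALSE]
  is_res <- pc$cause %in% residual
  ranked <- pc[!is_res, , drop = FALSE]
  ranked <- ranked[order(-ranked$mean, ranked$cause), , drop = FALSE]
  c(ranked$cause, sort(pc$cause[is_res]))
}
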