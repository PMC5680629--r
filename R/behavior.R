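# Boldness metrics from raw PIT detection logs, rank-order consistency,
# Lessells-Boag repeatability, and capture summaries.

#' Summarize detection logs into per-fish boldness metrics
#'
#' Feeding-spot reads are collapsed into visits: consecutive reads of the
#' same fish at the same antenna separated by less than `debounce_s` seconds
#' form one visit.  Per day, visits/hr is the visit count divided by 24 (the
#' full day is the observation window); the per-period value is the mean of
#' daily values over every day in the period, so fish with no reads score 0
#' rather than missing.  Shelter reads are merged into presence intervals
#' (gaps under `debounce_s` bridge a stay); each interval contributes its
#' duration plus `debounce_s / 2` (midpoint convention at the interval ends,
#' which also gives isolated single reads a half-window stay), and daily
#' totals are expressed as min/hr.
#'
#' @param log detection log: `data.frame` with `fish_id`, `antenna`
#'   (`close_spot`, `distant_spot`, `shelter`) and `time` (`POSIXct`).
#' @param period length-2 `Date` vector, first and last day (inclusive).
#' @param debounce_s debounce window in seconds (default 60).
#' @param roster character vector of all fish ids that must be summarized.
#' @return A `data.frame`, one row per roster fish: `fish_id`, `bp_close`,
#'   `bp_distant` (mean visits/hr/day) and `sp` (mean min/hr/day).
#' @export
summarize_behavior <- function(log, period, debounce_s = 60, roster) {
  stopifnot(length(period) == 2L, debounce_s > 0, length(roster) > 0)
  period <- as.Date(period)
  if (period[2L] < period[1L]) stop("period end precedes period start")
  n_days <- as.integer(period[2L] - period[1L]) + 1L

  dt <- as.data.table(log)[, .(fish_id, antenna, time)]
  unknown <- setdiff(unique(dt$fish_id), roster)
  if (length(unknown))
    stop("detection log contains fish ids not in roster: ",
         paste(sort(unknown), collapse = ", "))

  t0 <- as.POSIXct(paste(period[1L], "00:00:00"), tz = "UTC")
  t1 <- as.POSIXct(paste(period[2L] + 1L, "00:00:00"), tz = "UTC")
  n_before <- nrow(dt)
  dt <- dt[time >= t0 & time < t1]
  dropped <- n_before - nrow(dt)
  if (dropped > 0)
    message(sprintf("summarize_behavior: ignored %d events outside %s..%s",
                    dropped, period[1L], period[2L]))

  setorderv(dt, c("fish_id", "antenna", "time"))
  dt[, gap := as.numeric(time) - c(-Inf, as.numeric(time)[-.N]),
     by = .(fish_id, antenna)]
  dt[, grp := cumsum(gap >= debounce_s), by = .(fish_id, antenna)]

  feed_dt <- dt[antenna %in% c("close_spot", "distant_spot")]
  if (nrow(feed_dt)) {
    feeding <- feed_dt[, .(start = min(time)), by = .(fish_id, antenna, grp)]
    feeding[, day := as.Date(start, tz = "UTC")]
    fv <- feeding[, .N, by = .(fish_id, antenna, day)]
  } else {
    fv <- data.table(fish_id = character(), antenna = character(),
                     day = as.Date(character()), N = integer())
  }

  shel_dt <- dt[antenna == "shelter"]
  if (nrow(shel_dt)) {
    shelter <- shel_dt[, .(start = min(as.numeric(time)),
                           end = max(as.numeric(time))),
                       by = .(fish_id, grp)]
    shelter[, dur_min := (end - start + debounce_s / 2) / 60]
    shelter[, day := as.Date(as.POSIXct(start, tz = "UTC",
                                        origin = "1970-01-01"), tz = "UTC")]
    sv <- shelter[, .(minutes = sum(dur_min)), by = .(fish_id, day)]
  } else {
    sv <- data.table(fish_id = character(), day = as.Date(character()),
                     minutes = numeric())
  }

  # period mean of daily values over *all* days in the period
  per_fish <- function(tbl, value_col) {
    if (nrow(tbl) == 0L) return(setNames(numeric(0), character(0)))
    agg <- tbl[, .(total = sum(.SD[[1L]])), by = fish_id,
               .SDcols = value_col]
    setNames(agg$total / n_days, agg$fish_id)
  }
  close_rate <- per_fish(fv[antenna == "close_spot", .(fish_id, N)], "N")
  dist_rate <- per_fish(fv[antenna == "distant_spot", .(fish_id, N)], "N")
  sp_rate <- per_fish(sv[, .(fish_id, minutes)], "minutes")

  pick <- function(v, id) ifelse(id %in% names(v), v[id], 0)
  out <- data.frame(
    fish_id = roster,
    bp_close = unname(pick(close_rate, roster)) / 24,
    bp_distant = unname(pick(dist_rate, roster)) / 24,
    sp = unname(pick(sp_rate, roster)) / 24,
    stringsAsFactors = FALSE
  )
  out
}

#' Spearman rank-order consistency between two observation periods
#'
#' Midranks are assigned to ties, rho is the Pearson correlation of the
#' ranks, and the p-value uses the t approximation with `n - 2` degrees of
#' freedom.
#'
#' @param x,y paired per-fish values from the two periods, length >= 3.
#' @return A list of class `consistency_result`: `rho`, `p_value`, `n`.
#' @export
spearman_consistency <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 3L)
  if (sd(x) == 0 || sd(y) == 0)
    stop("Spearman correlation undefined: an input vector is constant")
  rx <- rank(x); ry <- rank(y)
  rho <- cor(rx, ry)
  n <- length(x)
  if (abs(rho) >= 1) {
    p <- 0
  } else {
    tstat <- rho * sqrt((n - 2) / (1 - rho^2))
    p <- 2 * pt(-abs(tstat), df = n - 2)
  }
  structure(list(rho = rho, p_value = p, n = n), class = "consistency_result")
}

#' @export
print.consistency_result <- function(x, ...) {
  cat(sprintf("Spearman rank-order consistency: rho = %.3f, p = %.3g, n = %d\n",
              x$rho, x$p_value, x$n))
  invisible(x)
}

#' Lessells-Boag repeatability (intraclass correlation)
#'
#' One-way ANOVA with individuals as groups: `s2_W = MS_W`,
#' `n0 = (sum(n_i) - sum(n_i^2)/sum(n_i)) / (a - 1)`,
#' `s2_A = (MS_A - MS_W) / n0`, and `r = s2_A / (s2_A + s2_W)`.  The F ratio
#' `MS_A / MS_W` is tested on `(a - 1, N - a)` degrees of freedom.  Negative
#' estimates are reported as computed (flagged, never clamped), which keeps
#' the estimator unbiased near zero.
#'
#' @param measures per-fish repeated measures: a matrix (rows = fish,
#'   columns = periods) or a list of numeric vectors, each of length >= 2;
#'   in the week-on-week design each fish has exactly two period means.
#' @return A list of class `repeatability_result`: `MS_A`, `MS_W`, `n0`,
#'   `s2_A`, `s2_W`, `r`, `F`, `p_value`, `n_groups`, `negative` flag.
#' @export
lessells_boag_repeatability <- function(measures) {
  if (is.matrix(measures) || is.data.frame(measures)) {
    measures <- lapply(seq_len(nrow(measures)),
                       function(i) as.numeric(measures[i, ]))
  }
  a <- length(measures)
  if (a < 2L) stop("need at least 2 individuals")
  ni <- lengths(measures)
  if (any(ni < 2L)) {
    bad <- which(ni < 2L)
    stop("individuals with fewer than 2 measures: ",
         paste(bad, collapse = ", "))
  }
  y <- unlist(measures, use.names = FALSE)
  gmeans <- vapply(measures, mean, numeric(1))
  n_tot <- sum(ni)
  grand <- sum(y) / n_tot
  ss_a <- sum(ni * (gmeans - grand)^2)
  ss_w <- sum((y - rep(gmeans, ni))^2)
  ms_a <- ss_a / (a - 1)
  ms_w <- ss_w / (n_tot - a)
  n0 <- (n_tot - sum(ni^2) / n_tot) / (a - 1)
  s2_a <- (ms_a - ms_w) / n0
  r <- if (s2_a + ms_w == 0) NA_real_ else s2_a / (s2_a + ms_w)
  if (ms_w == 0 && ms_a > 0) r <- 1
  f <- if (ms_w == 0) Inf else ms_a / ms_w
  p <- pf(f, a - 1, n_tot - a, lower.tail = FALSE)
  structure(list(MS_A = ms_a, MS_W = ms_w, n0 = n0, s2_A = s2_a, s2_W = ms_w,
                 r = r, F = f, p_value = p, n_groups = a,
                 negative = isTRUE(r < 0)),
            class = "repeatability_result")
}

#' @export
print.repeatability_result <- function(x, ...) {
  cat(sprintf("Lessells-Boag repeatability: r = %.3f (F = %.3f, p = %.3g, %d individuals)%s\n",
              x$r, x$F, x$p_value, x$n_groups,
              if (x$negative) " [negative estimate]" else ""))
  invisible(x)
}

#' Capture summary over an angling horizon
#'
#' Counts distinct fish first captured within the horizon (recaptures do not
#' count) and expresses effort-corrected catch per unit effort,
#' `CPUE = captured / (horizon * rod_hours_per_day * n_ponds)`.
#'
#' @param captures capture log with columns `fish_id` and `day`.
#' @param horizon days of angling counted.
#' @param population number of fish at risk.
#' @param rod_hours_per_day rod-angling hours per day in one pond
#'   (default 4).
#' @param n_ponds number of replicated ponds fished (default 3).
#' @return A list of class `capture_summary`: `horizon`, `captured`,
#'   `population`, `fraction`, `rod_hours`, `cpue`.
#' @export
capture_summary <- function(captures, horizon, population,
                            rod_hours_per_day = 4, n_ponds = 3) {
  if (population <= 0) stop("population must be positive")
  cap <- as.data.table(captures)
  captured <- if (nrow(cap) == 0L) 0L else
    length(unique(cap[, .(first = min(day)), by = fish_id][first <= horizon,
                                                           fish_id]))
  rod_hours <- horizon * rod_hours_per_day * n_ponds
  structure(list(horizon = horizon, captured = captured,
                 population = population,
                 fraction = captured / population,
                 rod_hours = rod_hours,
                 cpue = captured / rod_hours),
            class = "capture_summary")
}

#' @export
print.capture_summary <- function(x, ...) {
  cat(sprintf("Captures within %d days: %d of %d fish (%.1f%%), CPUE %.3f fish/hr over %g rod-hours\n",
              x$horizon, x$captured, x$population, 100 * x$fraction,
              x$cpue, x$rod_hours))
  invisible(x)
}
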