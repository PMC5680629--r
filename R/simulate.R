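# Individual-based simulator of the pond angling experiment.
# Seed discipline: every simulate_* operation derives its own stream from
# cfg$seed with a fixed offset, so each output is bit-identical under a fixed
# configuration and independent of the caller's RNG state.

.seed_individuals <- 101L
.seed_daily <- 202L
.seed_emit <- 203L
.seed_angling <- 303L
.seed_landmarks <- 404L
.seed_calibrate <- 9781L

#' Simulate the stocked individuals and their traits
#'
#' Draws one fish per row from a multivariate normal over the six analysis
#' traits (`BP`, `TL`, `G`, `SB`, `SH`, `SP`) with the configured means, SDs
#' and correlation matrix, assigns fish to ponds in balanced blocks, draws an
#' individual catchability frailty, and assigns each fish an end-of-experiment
#' fate: `complete`, `predated` (probability `p_predation`) or `tag_lost`
#' (probability `p_tagloss`), mutually exclusive, so the expected fraction of
#' complete records is `1 - p_predation - p_tagloss`.
#'
#' @param cfg a [sim_config()].
#' @return A `data.frame` with one row per fish: `fish_id`, `pond`, latent
#'   z-scores `z_bp` ... `z_sp`, trait values on their original scales
#'   (`bp_true` visits/hr, `tl_mm`, `growth_mm`, `sb_true`, `sh_true`,
#'   `sp_true` min/hr), `catch_frailty`, and the attrition fields `fate`,
#'   `alive`, `tag_retained`.
#' @export
simulate_individuals <- function(cfg) {
  validate_sim_config(cfg)
  n <- cfg$n_ponds * cfg$n_per_pond
  withr::with_seed(cfg$seed + .seed_individuals, {
    L <- chol(cfg$corr)
    z <- matrix(rnorm(n * 6L), n, 6L) %*% L
    colnames(z) <- colnames(cfg$corr)
    u <- runif(n)
    frailty <- rnorm(n)
  })
  traits <- sweep(sweep(z, 2L, cfg$trait_sds, "*"), 2L, cfg$trait_means, "+")
  if (any(traits[, "TL"] <= 0))
    stop("simulated total length <= 0; check trait_means/trait_sds for TL")
  fate <- ifelse(u < cfg$p_predation, "predated",
                 ifelse(u < cfg$p_predation + cfg$p_tagloss, "tag_lost", "complete"))
  out <- data.frame(
    fish_id = sprintf("F%03d", seq_len(n)),
    pond = rep(seq_len(cfg$n_ponds), each = cfg$n_per_pond),
    z_bp = z[, "BP"], z_tl = z[, "TL"], z_g = z[, "G"],
    z_sb = z[, "SB"], z_sh = z[, "SH"], z_sp = z[, "SP"],
    bp_true = pmax(0, traits[, "BP"]),
    tl_mm = traits[, "TL"],
    growth_mm = traits[, "G"],
    sb_true = traits[, "SB"],
    sh_true = traits[, "SH"],
    sp_true = pmin(60, pmax(0, traits[, "SP"])),
    catch_frailty = frailty,
    fate = fate,
    stringsAsFactors = FALSE
  )
  out$alive <- out$fate != "predated"
  out$tag_retained <- out$fate != "tag_lost"
  out
}

# Day-to-day noise SD (log scale) such that the intraclass correlation of
# weekly mean rates equals the target.  The rate model is
#   rate_id = b_i * exp(se * eps_id - se^2/2),  E[rate | fish] = b_i,
# so the between-fish variance B is var(b) and the within variance of a
# weekly mean over nd days is (E[b]/hours + E[b^2] (exp(se^2)-1)) / nd for a
# Poisson count channel, or without the E[b]/hours term for a continuous
# channel (hours = Inf).
.solve_day_noise <- function(target, b_mean, b_var, n_days, hours = 24) {
  stopifnot(target >= 0, target < 1)
  if (b_var == 0) return(0.3)          # ICC is 0 regardless of day noise
  if (target == 0) return(3)           # push ICC toward 0
  poisson_part <- if (is.finite(hours)) b_mean / hours else 0
  need <- b_var * (1 - target) / target * n_days - poisson_part
  if (need < 0)
    stop(sprintf(
      "target repeatability %.2f exceeds the Poisson sampling ceiling %.3f",
      target, b_var / (b_var + poisson_part / n_days)))
  sqrt(log1p(need / (b_mean^2 + b_var)))
}

#' Simulate daily activity totals (event-free level)
#'
#' The generative layer underneath [simulate_detections()]: per fish and day,
#' Poisson counts of feeding-spot visits at the close and distant spot and a
#' continuous shelter-use total.  Expected daily visit rates equal each
#' fish's `bp_true` (distant spot; the close spot shares the individual's
#' boldness with correlation ~0.9), and expected shelter use equals
#' `sp_true`.  Lognormal day-to-day noise is scaled via an analytic variance
#' decomposition so that the intraclass correlation of weekly mean rates
#' equals `target_repeatability` in expectation.
#'
#' @param ind individual table from [simulate_individuals()].
#' @param cfg a [sim_config()].
#' @param target_repeatability expected intraclass correlation of weekly mean
#'   rates, in `[0, 1)`.
#' @param rho_close correlation between the close- and distant-spot
#'   individual visit propensities.
#' @return A `data.table` with columns `fish_id`, `day` (1-based),
#'   `close_visits`, `distant_visits` (counts/day) and `shelter_min`
#'   (minutes/day).
#' @export
simulate_daily_activity <- function(ind, cfg, target_repeatability = 0.65,
                                    rho_close = 0.9) {
  stopifnot(target_repeatability >= 0, target_repeatability < 1)
  n <- nrow(ind)
  nd_week <- (cfg$obs_days + min(7L, cfg$angling_days)) / 2
  days <- cfg$detection_days

  b_bp <- ind$bp_true
  se_bp <- .solve_day_noise(target_repeatability, mean(b_bp), var(b_bp),
                            nd_week, hours = 24)
  b_sp <- ind$sp_true
  se_sp <- .solve_day_noise(target_repeatability, mean(b_sp), var(b_sp),
                            nd_week, hours = Inf)

  withr::with_seed(cfg$seed + .seed_daily, {
    u_close <- rnorm(n)
    b_close <- pmax(0, mean(b_bp) +
                      (rho_close * scale01(b_bp) +
                         sqrt(max(0, 1 - rho_close^2)) * u_close) * sd(b_bp))
    grid <- data.table(
      fish_id = rep(ind$fish_id, each = days),
      day = rep(seq_len(days), times = n),
      b_close = rep(b_close, each = days),
      b_dist = rep(b_bp, each = days),
      b_sp = rep(b_sp, each = days)
    )
    m <- nrow(grid)
    lam_close <- grid$b_close * exp(se_bp * rnorm(m) - se_bp^2 / 2)
    lam_dist <- grid$b_dist * exp(se_bp * rnorm(m) - se_bp^2 / 2)
    sp_rate <- pmin(60, grid$b_sp * exp(se_sp * rnorm(m) - se_sp^2 / 2))
    grid[, `:=`(
      close_visits = rpois(m, 24 * lam_close),
      distant_visits = rpois(m, 24 * lam_dist),
      shelter_min = 24 * sp_rate,
      b_close = NULL, b_dist = NULL, b_sp = NULL
    )]
  })
  grid[]
}

# center/scale a vector to z-scores; constant input maps to zeros
scale01 <- function(x) {
  s <- sd(x)
  if (s == 0) return(rep(0, length(x)))
  (x - mean(x)) / s
}

#' Simulate the raw PIT detection log
#'
#' Expands the daily activity totals of [simulate_daily_activity()] into
#' antenna reads.  Each feeding-spot visit is emitted as a burst of 1-5 reads
#' within 10 s; visit start times are placed on a jittered within-day grid
#' that keeps consecutive visits of the same fish at the same antenna at
#' least 80 s apart, so a downstream debounce window of up to 60 s recovers
#' the visit counts exactly.  Shelter use is emitted as presence intervals
#' (reads every 45 s for the duration of each stay).
#'
#' @inheritParams simulate_daily_activity
#' @return A `data.table` with columns `fish_id`,
#'   `antenna` (`close_spot`, `distant_spot`, `shelter`) and `time`
#'   (`POSIXct`, UTC), sorted by time.
#' @export
simulate_detections <- function(ind, cfg, target_repeatability = 0.65) {
  daily <- simulate_daily_activity(ind, cfg, target_repeatability)
  day0 <- as.POSIXct(paste(cfg$start_date, "00:00:00"), tz = "UTC")

  withr::with_seed(cfg$seed + .seed_emit, {
    visit_reads <- function(counts, antenna) {
      keep <- counts$n > 0L
      v <- counts[keep]
      if (nrow(v) == 0L)
        return(data.table(fish_id = character(), antenna = character(),
                          secs = numeric()))
      v[, n := pmin(n, 960L)]  # spacing floor: at most one visit per 90 s
      visits <- v[rep(seq_len(.N), n)]
      visits[, j := seq_len(.N) - 1L, by = .(fish_id, day)]
      visits[, seg := 86400 / n]
      visits[, start := (day - 1L) * 86400 + j * seg +
               runif(.N) * pmax(0, seg - 80)]
      k <- sample(5L, nrow(visits), replace = TRUE)
      reads <- visits[rep(seq_len(.N), k)]
      reads[, secs := start + runif(.N, 0, 10)]
      data.table(fish_id = reads$fish_id, antenna = antenna,
                 secs = floor(reads$secs))
    }
    close_rd <- visit_reads(daily[, .(fish_id, day, n = close_visits)],
                            "close_spot")
    dist_rd <- visit_reads(daily[, .(fish_id, day, n = distant_visits)],
                           "distant_spot")

    sh <- daily[shelter_min > 0.5,
                .(fish_id, day, total_s = shelter_min * 60)]
    if (nrow(sh) > 0L) {
      sh[, n_stays := 1L + rpois(.N, pmin(6, total_s / 1800))]
      stays <- sh[rep(seq_len(.N), n_stays)]
      stays[, w := rexp(.N)]
      stays[, dur := total_s * w / sum(w), by = .(fish_id, day)]
      stays[, j := seq_len(.N) - 1L, by = .(fish_id, day)]
      stays[, seg := 86400 / n_stays]
      stays[, dur := pmin(dur, seg - 160)]
      stays <- stays[dur > 0]
      stays[, start := (day - 1L) * 86400 + j * seg +
              runif(.N) * pmax(1, seg - dur - 150)]
      k <- floor(stays$dur / 45) + 1L
      reads <- stays[rep(seq_len(.N), k)]
      reads[, off := 45 * (seq_len(.N) - 1L), by = .(fish_id, day, j)]
      shelter_rd <- rbind(
        data.table(fish_id = reads$fish_id, antenna = "shelter",
                   secs = floor(reads$start + reads$off)),
        data.table(fish_id = stays$fish_id, antenna = "shelter",
                   secs = floor(stays$start + stays$dur))
      )
    } else {
      shelter_rd <- data.table(fish_id = character(), antenna = character(),
                               secs = numeric())
    }
  })

  log <- rbindlist(list(close_rd, dist_rd, shelter_rd))
  log[, time := day0 + secs]
  log[, secs := NULL]
  setorderv(log, c("time", "fish_id", "antenna"))
  log[]
}

#' Simulate the experimental angling fishery
#'
#' Every angling session, every fish is landed independently with
#' probability `plogis(capture_intercept + sum(capture_coefs * z) +
#' frailty_sd * catch_frailty)`.  Landed fish are immediately released and
#' remain at risk, so recaptures are logged; downstream fitness coding uses
#' first captures only.  Attrition happens after the experiment, so all fish
#' remain at risk throughout.
#'
#' @param ind individual table from [simulate_individuals()].
#' @param cfg a [sim_config()].
#' @return A `data.table` of landings: `fish_id`, `day` (1-based angling
#'   day), `session` (1-based within day).
#' @export
simulate_angling <- function(ind, cfg) {
  p <- plogis(session_capture_logit(ind, cfg))
  n <- nrow(ind)
  n_sessions <- cfg$angling_days * cfg$sessions_per_day
  withr::with_seed(cfg$seed + .seed_angling, {
    hit <- matrix(runif(n * n_sessions), n, n_sessions) < p
  })
  idx <- which(hit, arr.ind = TRUE)
  out <- data.table(
    fish_id = ind$fish_id[idx[, 1L]],
    day = ((idx[, 2L] - 1L) %/% cfg$sessions_per_day) + 1L,
    session = ((idx[, 2L] - 1L) %% cfg$sessions_per_day) + 1L
  )
  setorderv(out, c("day", "session", "fish_id"))
  out[]
}

session_capture_logit <- function(ind, cfg) {
  z <- as.matrix(ind[, c("z_bp", "z_tl", "z_g", "z_sb", "z_sh", "z_sp")])
  cfg$capture_intercept + drop(z %*% cfg$capture_coefs) +
    cfg$frailty_sd * ind$catch_frailty
}

#' Calibrate the per-session capture intercept to a target capture fraction
#'
#' Finds the intercept for which the expected fraction of fish ever captured
#' within `horizon_days` equals `target_fraction`.  The expectation is a
#' Monte-Carlo average (fixed inner seed) over the trait and frailty
#' distribution of the per-fish closed form
#' `1 - (1 - p_session)^(horizon_days * sessions_per_day)`, and the intercept
#' is found by root bisection, which is valid because the expected fraction
#' is strictly increasing in the intercept.
#'
#' @param cfg a [sim_config()]; its `capture_coefs` and `frailty_sd` are held
#'   fixed.
#' @param horizon_days days of angling over which "ever captured" is counted.
#' @param target_fraction target expected ever-captured fraction, in (0, 1).
#' @param n_mc Monte-Carlo sample size for the trait draw.
#' @return The calibrated intercept (scalar).
#' @export
calibrate_capture_intercept <- function(cfg, horizon_days, target_fraction,
                                        n_mc = 50000L) {
  if (!is.finite(target_fraction) || target_fraction <= 0 || target_fraction >= 1)
    stop(sprintf("target_fraction %.3f is unreachable: must be in (0, 1)",
                 target_fraction))
  withr::with_seed(cfg$seed + .seed_calibrate, {
    L <- chol(cfg$corr)
    z <- matrix(rnorm(n_mc * 6L), n_mc, 6L) %*% L
    f <- rnorm(n_mc)
  })
  lp0 <- drop(z %*% cfg$capture_coefs) + cfg$frailty_sd * f
  n_sessions <- horizon_days * cfg$sessions_per_day
  frac <- function(b0) mean(1 - (1 - plogis(b0 + lp0))^n_sessions)
  lo <- -50; hi <- 20
  if (frac(hi) < target_fraction)
    stop(sprintf("target fraction %.3f not reachable within %d days",
                 target_fraction, horizon_days))
  uniroot(function(b0) frac(b0) - target_fraction, c(lo, hi),
          tol = 1e-6)$root
}

# Orthonormal deformation directions over the 16x2 template, flattened
# (x1, y1, ..., x16, y16): a body-depth direction (SB), a head-elongation
# direction (SH) and a quadratic dorsoventral arching direction (nuisance).
shape_deformation_bases <- function(template) {
  p <- nrow(template)
  flat <- function(m) as.vector(t(m))
  unit <- function(v) v / sqrt(sum(v^2))
  ortho <- function(v, against) {
    for (a in against) v <- v - sum(v * a) * a
    unit(v)
  }
  trunk_idx <- 3:11  # body depth is a trunk property; head landmarks untouched
  depth <- matrix(0, p, 2)
  depth[trunk_idx, 2] <- template[trunk_idx, 2] - mean(template[trunk_idx, 2])
  depth[, 2] <- depth[, 2] - mean(depth[, 2])
  v_sb <- unit(flat(depth))

  head_idx <- c(1L, 2L, 12L, 13L, 15L, 16L)
  headm <- matrix(0, p, 2)
  headm[head_idx, 1] <- template[head_idx, 1] - mean(template[head_idx, 1])
  headm[, 1] <- headm[, 1] - mean(headm[, 1])
  v_sh <- ortho(flat(headm), list(v_sb))

  archm <- matrix(0, p, 2)
  q <- (template[, 1] - mean(template[, 1]))^2
  archm[, 2] <- q - mean(q)
  w_arch <- ortho(flat(archm), list(v_sb, v_sh))

  list(sb = v_sb, sh = v_sh, arch = w_arch)
}

#' Simulate landmark configurations for every fish
#'
#' Each configuration is the template shape deformed along two orthonormal
#' shape directions by the fish's body-shape (`SB`) and head-shape (`SH`)
#' z-scores, bent along a quadratic dorsoventral arching direction by a
#' per-fish standard-normal nuisance score (mimicking inconsistent body
#' posture on the photographs), perturbed by isotropic digitizing noise,
#' scaled by total length, and finally randomly rotated and translated as a
#' photograph would be.
#'
#' @inheritParams simulate_angling
#' @return A `16 x 2 x n` array of image coordinates (units: mm), with fish
#'   ids as the third dimnames; the injected arching scores are attached as
#'   attribute `arch_score`.
#' @export
simulate_landmarks <- function(ind, cfg) {
  template <- cfg$landmark_template
  p <- nrow(template)
  n <- nrow(ind)
  bases <- shape_deformation_bases(template)
  withr::with_seed(cfg$seed + .seed_landmarks, {
    arch <- rnorm(n)
    noise <- array(rnorm(p * 2 * n, 0, cfg$lm_noise_sd), c(p, 2, n))
    theta <- rnorm(n, 0, 0.05)
    shift <- matrix(runif(2 * n, 80, 120), n, 2)
  })
  unflat <- function(v) matrix(v, p, 2, byrow = TRUE)
  out <- array(NA_real_, c(p, 2, n),
               dimnames = list(NULL, c("x", "y"), ind$fish_id))
  for (i in seq_len(n)) {
    shp <- template +
      cfg$sb_mag * ind$z_sb[i] * unflat(bases$sb) +
      cfg$sh_mag * ind$z_sh[i] * unflat(bases$sh) +
      cfg$arch_mag * arch[i] * unflat(bases$arch) +
      noise[, , i]
    rot <- matrix(c(cos(theta[i]), sin(theta[i]),
                    -sin(theta[i]), cos(theta[i])), 2, 2)
    out[, , i] <- sweep(ind$tl_mm[i] * shp %*% rot, 2, shift[i, ], "+")
  }
  attr(out, "arch_score") <- arch
  out
}

#' Simulate the complete pond experiment
#'
#' Convenience wrapper running [simulate_individuals()],
#' [simulate_detections()], [simulate_angling()] and [simulate_landmarks()]
#' under one configuration.
#'
#' @inheritParams simulate_daily_activity
#' @return A list of class `pond_experiment` with elements `individuals`,
#'   `detections`, `captures`, `landmarks` and `config`.
#' @export
simulate_experiment <- function(cfg, target_repeatability = 0.65) {
  ind <- simulate_individuals(cfg)
  structure(list(
    individuals = ind,
    detections = simulate_detections(ind, cfg, target_repeatability),
    captures = simulate_angling(ind, cfg),
    landmarks = simulate_landmarks(ind, cfg),
    config = cfg
  ), class = "pond_experiment")
}

#' @export
print.pond_experiment <- function(x, ...) {
  cat(sprintf("Simulated pond experiment: %d fish, %d detections, %d landings\n",
              nrow(x$individuals), nrow(x$detections), nrow(x$captures)))
  invisible(x)
}

#' Write a simulated experiment to plain-text fixture files
#'
#' Writes `detections.csv` (`fish_id,antenna,timestamp_iso8601`),
#' `captures.csv` (`fish_id,day,session`), `traits.csv`
#' (`fish_id,pond,tl_mm,growth_mm`; growth is empty for fish lost to
#' predation or tag loss, which is how attrition censors records) and
#' `landmarks.tps`.  Output is byte-identical across runs for a fixed
#' configuration.
#'
#' @param bundle a `pond_experiment` from [simulate_experiment()].
#' @param dir output directory (created if missing).
#' @return Invisibly, the vector of file paths written.
#' @export
write_fixture <- function(bundle, dir) {
  stopifnot(inherits(bundle, "pond_experiment"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(dir)) stop("cannot create directory: ", dir)
  det <- data.table(
    fish_id = bundle$detections$fish_id,
    antenna = bundle$detections$antenna,
    timestamp_iso8601 = format(bundle$detections$time, "%Y-%m-%dT%H:%M:%SZ",
                               tz = "UTC")
  )
  ind <- bundle$individuals
  traits <- data.table(
    fish_id = ind$fish_id,
    pond = ind$pond,
    tl_mm = round(ind$tl_mm),
    growth_mm = ifelse(ind$fate == "complete", round(ind$growth_mm, 1), NA_real_)
  )
  paths <- file.path(dir, c("detections.csv", "captures.csv", "traits.csv",
                            "landmarks.tps"))
  fwrite(det, paths[1])
  fwrite(bundle$captures, paths[2])
  fwrite(traits, paths[3])
  write_tps(bundle$landmarks, paths[4])
  invisible(paths)
}

#' Read fixture files written by [write_fixture()]
#'
#' @param dir directory containing the fixture files.
#' @return A list with elements `detections`, `captures`, `traits`,
#'   `landmarks`.
#' @export
read_fixture <- function(dir) {
  det <- fread(file.path(dir, "detections.csv"),
               colClasses = list(character = c("fish_id", "antenna",
                                               "timestamp_iso8601")))
  det[, time := as.POSIXct(timestamp_iso8601, format = "%Y-%m-%dT%H:%M:%SZ",
                           tz = "UTC")]
  det[, timestamp_iso8601 := NULL]
  list(
    detections = det[],
    captures = fread(file.path(dir, "captures.csv"),
                     colClasses = list(character = "fish_id")),
    traits = fread(file.path(dir, "traits.csv"),
                   colClasses = list(character = "fish_id")),
    landmarks = landmark_array(read_tps(file.path(dir, "landmarks.tps")))
  )
}
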