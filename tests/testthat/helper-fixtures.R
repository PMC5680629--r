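# Shared fixture builders: everything is generated in code at test time.

# a reduced experiment configuration for fast tests
small_cfg <- function(seed = 1, ...) {
  sim_config(seed = seed, n_ponds = 2, n_per_pond = 10, obs_days = 3,
             angling_days = 20, detection_days = 5, ...)
}

# raw trait table on the original scales, taken from the simulated truth
# (bypasses telemetry/morphometrics; used to test the selection stage alone)
true_raw_traits <- function(ind, ids = ind$fish_id) {
  i <- match(ids, ind$fish_id)
  data.frame(fish_id = ids, pond = ind$pond[i],
             BP = ind$bp_true[i], TL = ind$tl_mm[i], G = ind$growth_mm[i],
             SB = ind$sb_true[i], SH = ind$sh_true[i], SP = ind$sp_true[i],
             stringsAsFactors = FALSE)
}

# one simulated experiment -> beta_SD estimates for BP and G from a
# BP + TL + G survival fit on the true traits (complete-record fish)
simulate_beta_estimates <- function(seed, horizon) {
  cfg <- sim_config(seed = seed)
  ind <- simulate_individuals(cfg)
  cap <- simulate_angling(ind, cfg)
  complete <- ind$fish_id[ind$fate == "complete"]
  traits <- zstandardize(true_raw_traits(ind, complete))
  cap <- cap[cap$fish_id %in% complete, ]
  fitness <- assign_fitness(cap, horizon, complete)
  fit <- fit_logistic(c("BP", "TL", "G"), traits, fitness, pond_mode = "none")
  janzen_stern(fit)[c("BP", "G")]
}

# weekly mean distant-spot rates from the event-free daily level
weekly_means_from_daily <- function(daily, week1_days, week2_days) {
  dt <- data.table::as.data.table(daily)
  w1 <- dt[day %in% week1_days,
           .(m = mean(distant_visits / 24)), by = fish_id]
  w2 <- dt[day %in% week2_days,
           .(m = mean(distant_visits / 24)), by = fish_id]
  cbind(w1$m, w2$m[match(w1$fish_id, w2$fish_id)])
}

# brute-force likelihood grid search for a 2-parameter logistic model
grid_logistic <- function(x, y, levels = 4, span = 8, grid_n = 81) {
  center <- c(0, 0)
  for (l in seq_len(levels)) {
    a <- seq(center[1] - span, center[1] + span, length.out = grid_n)
    b <- seq(center[2] - span, center[2] + span, length.out = grid_n)
    ll <- outer(a, b, Vectorize(function(ai, bi) {
      p <- plogis(ai + bi * x)
      sum(y * log(p) + (1 - y) * log1p(-p))
    }))
    best <- arrayInd(which.max(ll), dim(ll))
    center <- c(a[best[1]], b[best[2]])
    span <- span / 15
  }
  center
}
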