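test_that("growth residuals are orthogonal to boldness", {
  withr::with_seed(31, {
    bp <- rnorm(60, 4.6, 1.5)
    g <- 7.8 + 1.1 * bp + rnorm(60, sd = 4)
  })
  r <- growth_residuals(g, bp)
  expect_lt(abs(cor(r, bp)), 1e-12)
  expect_lt(abs(mean(r)), 1e-12)
  expect_lt(max(abs(growth_residuals(2 + 3 * bp, bp))), 1e-10)
  # exactly uncorrelated increments: residuals are the centered increments
  g_perp <- unname(resid(lm(withr::with_seed(32, rnorm(60)) ~ bp)))
  expect_equal(growth_residuals(g_perp + 7.8, bp), g_perp)
  expect_error(growth_residuals(g, rep(1, 60)), "constant")
})

test_that("z-standardization stores moments and exact quadratic terms", {
  raw <- data.frame(fish_id = sprintf("f%d", 1:3), pond = 1,
                    BP = c(1, 2, 3), TL = c(190, 199, 208),
                    G = c(-1, 0, 1), SB = c(0.1, 0.3, 0.2),
                    SH = c(-0.2, 0, 0.2), SP = c(4, 6, 8))
  tm <- zstandardize(raw)
  expect_equal(tm$BP, c(-1, 0, 1))
  expect_equal(unname(attr(tm, "mu")["BP"]), 2)
  expect_equal(unname(attr(tm, "sigma")["BP"]), 1)
  for (tr in c("BP", "TL", "G", "SB", "SH", "SP")) {
    expect_lt(abs(mean(tm[[tr]])), 1e-10)
    expect_equal(sd(tm[[tr]]), 1, tolerance = 1e-10)
  }
  expect_identical(tm$G2, tm$G^2)
  expect_identical(tm$BP2, tm$BP^2)

  # the stored mean can be overridden for derived zero-mean traits
  tm2 <- zstandardize(raw, mu = c(G = 7.8))
  expect_equal(unname(attr(tm2, "mu")["G"]), 7.8)
  expect_equal(tm2$G, tm$G)  # z-scores unchanged

  raw$SP <- 5
  expect_error(zstandardize(raw), "SP")
})

test_that("fitness coding uses first captures only and is monotone in horizon", {
  roster <- sprintf("F%02d", 1:5)
  expect_equal(assign_fitness(data.frame(fish_id = character(),
                                         day = integer()), 7, roster)$s,
               rep(1L, 5))

  caps <- data.frame(fish_id = c("F01", "F01", "F02", "F03"),
                     day = c(9, 12, 3, 21))
  f7 <- assign_fitness(caps, 7, roster)
  f20 <- assign_fitness(caps, 20, roster)
  expect_equal(f7$s, c(1L, 0L, 1L, 1L, 1L))   # F01 first captured day 9
  expect_equal(f20$s, c(0L, 0L, 1L, 1L, 1L))
  expect_true(all(f7$s >= f20$s))             # horizon monotonicity
  expect_error(assign_fitness(data.frame(fish_id = "zz", day = 1), 7, roster),
               "zz")

  # 38 distinct first captures on a 94-fish roster: exactly 38 zeros
  roster94 <- sprintf("F%03d", 1:94)
  caps38 <- data.frame(fish_id = rep(roster94[1:38], 2),
                       day = c(rep(1:7, length.out = 38),
                               rep(8, 38)))
  expect_equal(sum(assign_fitness(caps38, 7, roster94)$s == 0), 38)
})

test_that("logistic fits match closed forms and a likelihood grid search", {
  # intercept-only fit: alpha0 = log(odds of survival)
  n1 <- 60; n0 <- 40
  tr <- zstandardize(data.frame(
    fish_id = sprintf("f%d", 1:100), pond = rep(1:2, 50),
    BP = rnorm(100), TL = rnorm(100, 199, 9), G = rnorm(100),
    SB = rnorm(100), SH = rnorm(100), SP = rnorm(100)))
  fitness <- data.frame(fish_id = tr$fish_id, s = rep(c(1L, 0L), c(n1, n0)))
  f0 <- fit_logistic(character(0), tr, fitness, pond_mode = "none")
  expect_equal(f0$coefficients$estimate[1], log(60 / 40), tolerance = 1e-6)
  expect_equal(f0$k, 1)
  expect_equal(f0$wbar, 0.6)

  # one-predictor toy fit against an independent brute-force grid search
  x <- c(-2.1, -1.3, -0.4, 0.2, 0.7, 1.1, 1.9, 2.4)
  y <- c(0, 0, 1, 0, 1, 1, 1, 1)
  toy <- zstandardize(data.frame(
    fish_id = sprintf("t%d", 1:8), pond = 1,
    BP = x, TL = rnorm(8, 199, 9), G = rnorm(8),
    SB = rnorm(8), SH = rnorm(8), SP = rnorm(8)))
  # grid search is on the raw x; refit on the z-scale via the same scaling
  fit <- fit_logistic("BP", toy, data.frame(fish_id = toy$fish_id, s = y),
                      pond_mode = "none")
  oracle <- grid_logistic(toy$BP, y)
  expect_equal(fit$coefficients$estimate, oracle, tolerance = 1e-3)

  # constant predictor: rank-deficiency failure naming the term
  toy2 <- toy; toy2$SH <- 0
  expect_error(fit_logistic(c("BP", "SH"), toy2,
                            data.frame(fish_id = toy$fish_id, s = y),
                            pond_mode = "none"), "SH")

  # complete separation is a failure, not a silent fit
  ysep <- as.integer(x > 0)
  expect_error(fit_logistic("BP", toy,
                            data.frame(fish_id = toy$fish_id, s = ysep),
                            pond_mode = "none"), "separation")
})

test_that("AICc arithmetic and Akaike weights", {
  expect_equal(aicc(-64.5, k = 1, n = 94), 131.0435, tolerance = 1e-6)
  # the small-sample correction term
  expect_equal(aicc(0, k = 9, n = 94) - (2 * 9), 2 * 9 * 10 / 84,
               tolerance = 1e-12)
  # AICc converges to AIC
  expect_lt(aicc(-100, k = 5, n = 1e6) - (200 + 10), 1e-3)
  expect_error(aicc(-10, k = 5, n = 6), "undefined")

  expect_equal(akaike_weights(123.4), 1)
  expect_equal(akaike_weights(c(10, 10)), c(0.5, 0.5))
  w <- akaike_weights(c(130.1, 128.0, 126.3, 131.0))
  expect_equal(sum(w), 1, tolerance = 1e-12)
  # invariance to a constant shift
  expect_equal(akaike_weights(c(130.1, 128.0, 126.3, 131.0) + 57), w)
})

test_that("the candidate model set mirrors the published design", {
  for (h in c(7, 20)) {
    specs <- model_specs(h)
    expect_length(specs, 9)
    expect_equal(unname(lengths(specs) + 1L), 9:1)  # parameter counts 9..1
    expect_equal(specs$M9, character(0))
    expect_equal(specs$M8, "G")
  }
  expect_equal(model_specs(7)$M6, c("BP", "TL", "G"))
  expect_equal(model_specs(20)$M6, c("BP", "SB", "G"))
  expect_equal(model_specs(20)$M7, c("BP", "G"))
})

test_that("model comparison ranks by AICc and flags the final model", {
  cfg <- sim_config(seed = 51)
  ind <- simulate_individuals(cfg)
  cap <- simulate_angling(ind, cfg)
  complete <- ind$fish_id[ind$fate == "complete"]
  traits <- zstandardize(true_raw_traits(ind, complete))
  fitness <- assign_fitness(cap[cap$fish_id %in% complete, ], 7, complete)
  mc <- run_model_set(traits, fitness, 7, pond_mode = "none")
  expect_length(mc$fits, 9)
  expect_equal(mc$table$k, 9:1)
  expect_equal(mc$fits$M9$k, 1)
  expect_equal(sum(mc$table$weight), 1, tolerance = 1e-12)
  expect_equal(min(mc$table$delta), 0)
  expect_true(all(mc$table$delta >= 0))
  # final model is the richest among the delta < 1 set
  best <- mc$table[mc$table$best, ]
  expect_equal(mc$final, best$model[which.max(best$k)])

  # the random-intercept mode runs and reports the same k convention
  mc_r <- run_model_set(traits, fitness, 7, pond_mode = "random")
  expect_equal(mc_r$table$k, 9:1)
  grads <- selection_gradients(mc, traits)
  expect_true(all(c("alpha", "beta_sd", "beta_mu") %in% names(grads)))
  expect_gte(attr(grads, "r2_nagelkerke"), 0)
})

test_that("Janzen-Stern linearization matches a numerical-derivative oracle", {
  # constant-probability case: factor = 0.25 / 0.5
  fake <- list(coefficients = data.frame(term = c("(Intercept)", "BP", "G"),
                                         estimate = c(0, 0.8, -0.4)),
               fitted = rep(0.5, 10), wbar = 0.5)
  expect_equal(janzen_stern(fake), c(BP = 0.4, G = -0.2))
  fake$coefficients$estimate[2:3] <- 0
  expect_equal(unname(janzen_stern(fake)), c(0, 0))

  # fitted toy model: compare against central finite differences of the
  # mean relative fitness with respect to each z-trait
  withr::with_seed(52, {
    raw <- data.frame(fish_id = sprintf("f%d", 1:40), pond = 1,
                      BP = rnorm(40, 4.6, 1.5), TL = rnorm(40, 199, 9),
                      G = rnorm(40, 7.8, 5.4), SB = rnorm(40),
                      SH = rnorm(40), SP = rnorm(40, 6.3, 2.6))
    s <- rbinom(40, 1, plogis(0.3 - 0.8 * scale(raw$BP)))
  })
  tr <- zstandardize(raw)
  fit <- fit_logistic(c("BP", "G"), tr, data.frame(fish_id = tr$fish_id,
                                                   s = as.integer(s)),
                      pond_mode = "none")
  beta <- janzen_stern(fit)
  cf <- setNames(fit$coefficients$estimate, fit$coefficients$term)
  eta <- cf["(Intercept)"] + cf["BP"] * tr$BP + cf["G"] * tr$G
  h <- 1e-4
  for (term in c("BP", "G")) {
    num <- mean((plogis(eta + h * cf[term]) - plogis(eta - h * cf[term])) /
                  (2 * h)) / fit$wbar
    expect_equal(unname(beta[term]), unname(num), tolerance = 1e-4)
  }
})

test_that("mean standardization scales gradients by mu over sigma", {
  expect_equal(mean_standardized_gradients(c(BP = 0.2), c(BP = 3), c(BP = 3)),
               c(BP = 0.2))
  expect_equal(unname(mean_standardized_gradients(c(G = 0), c(G = 7.8),
                                                  c(G = 5.4))), 0)
  expect_equal(unname(mean_standardized_gradients(c(TL = -0.151),
                                                  c(TL = 199), c(TL = 9.2))),
               -0.151 * 199 / 9.2, tolerance = 1e-12)
  # unit invariance: rescaling the raw trait leaves beta_mu unchanged
  expect_equal(mean_standardized_gradients(c(TL = -0.151), c(TL = 398),
                                           c(TL = 18.4)),
               mean_standardized_gradients(c(TL = -0.151), c(TL = 199),
                                           c(TL = 9.2)))
  # quadratic terms have no original-scale mean: NA
  out <- mean_standardized_gradients(c(BP = 0.1, BP2 = 0.2), c(BP = 4.6),
                                     c(BP = 1.5))
  expect_true(is.na(out["BP2"]))
})

test_that("Nagelkerke pseudo R2 follows its closed form", {
  mkfit <- function(ll, n) list(loglik = ll, n = n)
  expect_equal(nagelkerke_r2(mkfit(-60, 94), mkfit(-60, 94)), 0)
  l0 <- -64.5; l1 <- -55.2; n <- 94
  expect_equal(nagelkerke_r2(mkfit(l1, n), mkfit(l0, n)),
               (1 - exp(2 * (l0 - l1) / n)) / (1 - exp(2 * l0 / n)),
               tolerance = 1e-10)
  # near-perfect fit approaches 1
  expect_gt(nagelkerke_r2(mkfit(-1e-9, 50), mkfit(-34, 50)), 0.999)
  expect_error(nagelkerke_r2(mkfit(-70, 94), mkfit(-64.5, 94)), "nested")
})

test_that("estimated gradients are consistent with a mega-replicate", {
  # median of replicate estimates vs one very large simulated fishery
  meds <- apply(vapply(6001:6150, function(s)
    simulate_beta_estimates(s, 7), numeric(2)), 1, median)

  cfg_big <- sim_config(seed = 777, n_ponds = 3, n_per_pond = 20000,
                        p_predation = 0, p_tagloss = 0)
  ind <- simulate_individuals(cfg_big)
  cap <- simulate_angling(ind, cfg_big)
  traits <- zstandardize(true_raw_traits(ind))
  fitness <- assign_fitness(cap, 7, ind$fish_id)
  fit <- fit_logistic(c("BP", "TL", "G"), traits, fitness, pond_mode = "none")
  mega <- janzen_stern(fit)[c("BP", "G")]
  expect_equal(unname(meds), unname(mega), tolerance = 0.25)
})

test_that("group descriptives split captured and uncaptured fish", {
  raw <- true_raw_traits(simulate_individuals(sim_config(seed = 61)))
  fitness <- data.frame(fish_id = raw$fish_id,
                        s = rep(c(0L, 1L), length.out = nrow(raw)))
  d <- trait_descriptives(raw, fitness)
  expect_equal(diag(d$corr), setNames(rep(1, 6), colnames(d$corr)))
  expect_equal(d$groups$n_captured[1], sum(fitness$s == 0))
  cap_bp <- mean(raw$BP[fitness$s == 0])
  expect_equal(d$groups$captured_mean[d$groups$trait == "BP"], cap_bp)
  # identical groups give identical means
  f_all_same <- data.frame(fish_id = rep(raw$fish_id, 2),
                           s = rep(c(0L, 1L), each = nrow(raw)))
  raw2 <- rbind(raw, raw)
  raw2$fish_id <- f_all_same$fish_id <- sprintf("x%d", seq_len(nrow(raw2)))
  d2 <- trait_descriptives(raw2, f_all_same)
  expect_equal(d2$groups$captured_mean, d2$groups$uncaptured_mean)
})
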