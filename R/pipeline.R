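# End-to-end orchestration: simulate (or load) an experiment, summarize
# behavior, run the morphometric chain, fit the survival model sets and
# write a reproducible report.

#' Configuration for a full pipeline run
#'
#' @param seed integer seed; forwarded to the simulator and recorded in the
#'   report.
#' @param simulate named list of [sim_config()] overrides, or `NULL` to read
#'   data from `paths` (a list with `detections`, `captures`, `traits`,
#'   `landmarks` file paths).
#' @param paths input file paths when not simulating (fixture dialect of
#'   [write_fixture()]).
#' @param horizons angling horizons (days) to analyze.
#' @param debounce_s debounce window for [summarize_behavior()].
#' @param target_repeatability simulator target for the intraclass
#'   correlation of the boldness measures.
#' @param pond_mode pond-nesting mode for the survival fits.
#' @param gpa_tol convergence tolerance of the Procrustes superimposition.
#' @param out_dir output directory for the report files, or `NULL` for an
#'   in-memory run.
#' @param write_raw also write the simulated raw data as fixture files.
#' @return A list of class `run_config`.
#' @export
run_config <- function(seed = 1L, simulate = list(), paths = NULL,
                       horizons = c(7L, 20L), debounce_s = 60,
                       target_repeatability = 0.65,
                       pond_mode = "random", gpa_tol = 1e-10,
                       out_dir = NULL, write_raw = FALSE) {
  structure(list(seed = as.integer(seed), simulate = simulate, paths = paths,
                 horizons = as.integer(horizons), debounce_s = debounce_s,
                 target_repeatability = target_repeatability,
                 pond_mode = pond_mode, gpa_tol = gpa_tol,
                 out_dir = out_dir, write_raw = write_raw),
            class = "run_config")
}

#' Read a pipeline configuration from a YAML file
#'
#' Every [run_config()] field is addressable; a `simulate:` block holds
#' [sim_config()] overrides (including nested `trait_means`, `trait_sds`,
#' `capture_coefs`).
#'
#' @param path YAML file path.
#' @param ... overrides applied after reading (e.g. a command-line seed).
#' @return A `run_config`.
#' @export
read_run_config <- function(path, ...) {
  y <- yaml::read_yaml(path)
  dots <- list(...)
  y[names(dots)] <- dots
  known <- names(formals(run_config))
  bad <- setdiff(names(y), known)
  if (length(bad)) stop("unknown config fields: ", paste(bad, collapse = ", "))
  do.call(run_config, y)
}

#' Run the complete analysis pipeline
#'
#' Executes every stage in order: data acquisition (simulation or files),
#' behavioral summaries for the observation week and the first angling week,
#' rank-order consistency and Lessells-Boag repeatability per boldness
#' measure, the morphometric chain (Procrustes superimposition, arching
#' estimation and Burnaby projection, body and head shape PCA, size
#' correction), growth residuals, z-standardization, and, per horizon,
#' fitness coding, the AICc-ranked model set and mean-standardized selection
#' gradients.  When `out_dir` is set, tidy CSV tables, a human-readable
#' `summary.txt` and a `log.txt` (stage timings; not part of the
#' deterministic report) are written; the CSV/report files are byte-identical
#' across runs with the same configuration.
#'
#' @param cfg a [run_config()], a YAML path, or a plain named list of
#'   [run_config()] fields.
#' @return A list of class `anglesel_run` with all stage outputs.
#' @export
run_pipeline <- function(cfg = run_config()) {
  if (is.character(cfg)) cfg <- read_run_config(cfg)
  if (!inherits(cfg, "run_config")) cfg <- do.call(run_config, cfg)
  t_start <- proc.time()[["elapsed"]]
  timings <- numeric(0)
  tick <- function(stage, t0) {
    timings[[stage]] <<- round(proc.time()[["elapsed"]] - t0, 2)
  }

  # --- stage: data -----------------------------------------------------
  t0 <- proc.time()[["elapsed"]]
  if (is.null(cfg$paths)) {
    sim_cfg <- do.call(sim_config, c(list(seed = cfg$seed), cfg$simulate))
    bundle <- simulate_experiment(sim_cfg, cfg$target_repeatability)
    individuals <- bundle$individuals
    detections <- bundle$detections
    captures <- bundle$captures
    landmarks <- bundle$landmarks
    traits_in <- data.frame(fish_id = individuals$fish_id,
                            pond = individuals$pond,
                            tl_mm = individuals$tl_mm,
                            growth_mm = ifelse(individuals$fate == "complete",
                                               individuals$growth_mm, NA_real_),
                            stringsAsFactors = FALSE)
    start_date <- sim_cfg$start_date
    obs_days <- sim_cfg$obs_days
    angling_days <- sim_cfg$angling_days
    if (isTRUE(cfg$write_raw) && !is.null(cfg$out_dir))
      write_fixture(bundle, file.path(cfg$out_dir, "data"))
  } else {
    fx <- list(
      detections = read_fixture_file(cfg$paths$detections),
      captures = fread(cfg$paths$captures,
                       colClasses = list(character = "fish_id")),
      traits = fread(cfg$paths$traits,
                     colClasses = list(character = "fish_id")),
      landmarks = landmark_array(read_tps(cfg$paths$landmarks))
    )
    detections <- fx$detections
    captures <- fx$captures
    traits_in <- as.data.frame(fx$traits)
    landmarks <- fx$landmarks
    individuals <- NULL
    start_date <- as.Date(min(detections$time), tz = "UTC")
    obs_days <- 6L
    angling_days <- max(cfg$horizons)
  }
  if (max(cfg$horizons) > angling_days)
    stop("pipeline: horizon exceeds the angling period (",
         max(cfg$horizons), " > ", angling_days, " days)")
  roster_all <- traits_in$fish_id
  complete <- roster_all[!is.na(traits_in$growth_mm)]
  tick("data", t0)

  # --- stage: behavior -------------------------------------------------
  t0 <- proc.time()[["elapsed"]]
  week1 <- c(start_date, start_date + obs_days - 1L)
  week2 <- c(start_date + obs_days, start_date + obs_days + 6L)
  beh1 <- summarize_behavior(detections, week1, cfg$debounce_s, roster_all)
  beh2 <- summarize_behavior(detections, week2, cfg$debounce_s, roster_all)
  i1 <- match(complete, beh1$fish_id)
  i2 <- match(complete, beh2$fish_id)
  measures <- c(bp_close = "bp_close", bp_distant = "bp_distant", sp = "sp")
  repeatability <- do.call(rbind, lapply(names(measures), function(m) {
    x <- beh1[[m]][i1]; y <- beh2[[m]][i2]
    sp_res <- spearman_consistency(x, y)
    lb <- lessells_boag_repeatability(cbind(x, y))
    data.frame(measure = m, n = length(x),
               spearman_rho = sp_res$rho, spearman_p = sp_res$p_value,
               F = lb$F, F_p = lb$p_value, r = lb$r,
               stringsAsFactors = FALSE)
  }))
  tick("behavior", t0)

  # --- stage: morphometrics -------------------------------------------
  t0 <- proc.time()[["elapsed"]]
  lm_complete <- landmarks[, , match(complete, dimnames(landmarks)[[3L]]),
                           drop = FALSE]
  gpa_body <- generalized_procrustes(lm_complete, tol = cfg$gpa_tol)
  arch_basis <- estimate_arching_basis(gpa_body)
  arch_diag <- arching_diagnostic(gpa_body, arch_basis)
  projected <- burnaby_project(gpa_body$aligned, arch_basis)
  pca_body <- shape_pca(projected)
  gpa_head <- generalized_procrustes(head_subset(lm_complete),
                                     tol = cfg$gpa_tol)
  pca_head <- shape_pca(gpa_head$aligned)
  tl <- traits_in$tl_mm[match(complete, traits_in$fish_id)]
  sb <- size_correct(pca_body$scores[, 1L], tl)
  sh <- size_correct(pca_head$scores[, 1L], tl)
  tick("morpho", t0)

  # --- stage: traits ---------------------------------------------------
  t0 <- proc.time()[["elapsed"]]
  bp <- beh1$bp_distant[i1]
  growth <- traits_in$growth_mm[match(complete, traits_in$fish_id)]
  g_resid <- growth_residuals(growth, bp)
  raw_traits <- data.frame(
    fish_id = complete,
    pond = traits_in$pond[match(complete, traits_in$fish_id)],
    BP = bp, TL = tl, G = g_resid, SB = sb, SH = sh, SP = beh1$sp[i1],
    stringsAsFactors = FALSE
  )
  # G is a residual (mean 0); its mean-standardized gradient uses the raw
  # growth increment's mean as the original-scale trait mean
  traits <- zstandardize(raw_traits, mu = c(G = mean(growth)))
  # the trait correlation matrix reports raw growth (the residual is
  # uncorrelated with BP by construction and would hide the association)
  corr <- cor(cbind(as.matrix(as.data.frame(traits)[c("BP", "TL")]),
                    G = growth,
                    as.matrix(as.data.frame(traits)[c("SB", "SH", "SP")])))
  tick("traits", t0)

  # --- stage: selection ------------------------------------------------
  t0 <- proc.time()[["elapsed"]]
  cap_complete <- as.data.table(captures)[fish_id %in% complete]
  horizons <- sort(cfg$horizons)
  by_horizon <- lapply(horizons, function(h) {
    fitness <- assign_fitness(cap_complete, h, complete)
    comparison <- run_model_set(traits, fitness, h, cfg$pond_mode)
    grads <- selection_gradients(comparison, traits)
    descr <- trait_descriptives(raw_traits, fitness)
    summary <- capture_summary(cap_complete, h, length(complete),
                               n_ponds = length(unique(raw_traits$pond)))
    list(horizon = h, fitness = fitness, comparison = comparison,
         gradients = grads, descriptives = descr, capture_summary = summary)
  })
  names(by_horizon) <- paste0("h", horizons)
  tick("selection", t0)

  run <- structure(list(
    config = cfg,
    individuals = individuals,
    behavior = list(week1 = beh1, week2 = beh2),
    repeatability = repeatability,
    morpho = list(gpa_body = gpa_body, pca_body = pca_body,
                  gpa_head = gpa_head, pca_head = pca_head,
                  arching = arch_diag),
    traits_raw = raw_traits,
    traits = traits,
    correlation = corr,
    horizons = by_horizon,
    n_stocked = length(roster_all),
    n_complete = length(complete),
    timings = timings,
    total_elapsed = round(proc.time()[["elapsed"]] - t_start, 2)
  ), class = "anglesel_run")

  if (!is.null(cfg$out_dir)) write_report(run, cfg$out_dir)
  run
}

# parse a detections CSV in the fixture dialect
read_fixture_file <- function(path) {
  det <- fread(path, colClasses = list(character = c("fish_id", "antenna",
                                                     "timestamp_iso8601")))
  det[, time := as.POSIXct(timestamp_iso8601, format = "%Y-%m-%dT%H:%M:%SZ",
                           tz = "UTC")]
  det[, timestamp_iso8601 := NULL]
  det[]
}

#' Write the report files of a pipeline run
#'
#' Emits tidy CSV tables (repeatability, correlation matrix, per-horizon
#' descriptives, model comparisons and gradients, capture summaries, weekly
#' behavior summaries), a human-readable `summary.txt`, and `log.txt` with
#' stage timings and session info.  All files except `log.txt` are
#' deterministic functions of the run configuration.
#'
#' @param run an `anglesel_run`.
#' @param dir output directory.
#' @return Invisibly, the directory.
#' @export
write_report <- function(run, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  wcsv <- function(x, name) fwrite(signif_df(x), file.path(dir, name))
  wcsv(run$behavior$week1, "behavior_week1.csv")
  wcsv(run$behavior$week2, "behavior_week2.csv")
  wcsv(run$repeatability, "repeatability.csv")
  cm <- as.data.frame(round(run$correlation, 4))
  cm <- cbind(trait = rownames(run$correlation), cm)
  wcsv(cm, "correlation.csv")
  for (h in run$horizons) {
    tag <- sprintf("%dd", h$horizon)
    wcsv(h$comparison$table, sprintf("model_comparison_%s.csv", tag))
    g <- as.data.frame(h$gradients)
    g$r2_nagelkerke <- rep(attr(h$gradients, "r2_nagelkerke"), nrow(g))
    g$model <- rep(attr(h$gradients, "model"), nrow(g))
    wcsv(g, sprintf("gradients_%s.csv", tag))
    wcsv(h$descriptives$groups, sprintf("descriptives_%s.csv", tag))
    cs <- h$capture_summary
    wcsv(data.frame(horizon = cs$horizon, captured = cs$captured,
                    population = cs$population,
                    fraction = round(cs$fraction, 6),
                    rod_hours = cs$rod_hours, cpue = round(cs$cpue, 6)),
         sprintf("capture_summary_%s.csv", tag))
  }
  writeLines(format_summary(run), file.path(dir, "summary.txt"))
  writeLines(c(
    sprintf("anglesel %s; R %s", packageVersion("anglesel"),
            paste(R.version$major, R.version$minor, sep = ".")),
    sprintf("seed: %d", run$config$seed),
    sprintf("stage timings (s): %s",
            paste(sprintf("%s=%.2f", names(run$timings), run$timings),
                  collapse = ", ")),
    sprintf("total elapsed (s): %.2f", run$total_elapsed)
  ), file.path(dir, "log.txt"))
  invisible(dir)
}

signif_df <- function(x) {
  x <- as.data.frame(x)
  num <- vapply(x, is.numeric, logical(1))
  x[num] <- lapply(x[num], function(v) round(v, 6))
  x
}

format_summary <- function(run) {
  out <- c(
    "Angling-induced selection: pipeline summary",
    sprintf("seed: %d", run$config$seed),
    sprintf("stocked fish: %d; complete records: %d (%.1f%%)",
            run$n_stocked, run$n_complete,
            100 * run$n_complete / run$n_stocked),
    "",
    "Repeatability of boldness measures (week 1 vs week 2):",
    sprintf("  %-11s rho=%.3f  F=%.3f  r=%.3f", run$repeatability$measure,
            run$repeatability$spearman_rho, run$repeatability$F,
            run$repeatability$r),
    "",
    sprintf("Arching diagnostic: PC1 explained %.1f%% -> %.1f%% (change %.2f pp)",
            100 * run$morpho$arching$explained_before,
            100 * run$morpho$arching$explained_after,
            run$morpho$arching$change_pp)
  )
  for (h in run$horizons) {
    cs <- h$capture_summary
    g <- h$gradients
    out <- c(out, "",
             sprintf("--- %d-day horizon ---", h$horizon),
             sprintf("captured: %d/%d (%.1f%%), CPUE %.3f fish/hr",
                     cs$captured, cs$population, 100 * cs$fraction, cs$cpue),
             sprintf("final model: %s (Nagelkerke R2 = %.3f)",
                     attr(g, "model"), attr(g, "r2_nagelkerke")),
             sprintf("  %-4s alpha=%8.3f  beta_SD=%8.3f  beta_mu=%s",
                     g$trait, g$alpha, g$beta_sd,
                     ifelse(is.na(g$beta_mu), "     NA",
                            sprintf("%8.3f", g$beta_mu))))
  }
  out
}

#' @export
print.anglesel_run <- function(x, ...) {
  cat(format_summary(x), sep = "\n")
  invisible(x)
}
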