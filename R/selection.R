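# Survival-model machinery: trait standardization, fitness coding, logistic
# fits with pond nesting, AICc and Akaike weights, Janzen-Stern
# linearization and mean-standardized selection gradients.

#' Growth residuals on boldness
#'
#' Angling may select on growth through behavior, so correlated effects of
#' boldness on growth are separated: the growth trait `G` entering the
#' survival models is the residual of an OLS regression of growth increment
#' on the distant-feeding-spot visit rate.
#'
#' @param growth growth increments (mm).
#' @param bp paired distant-spot visit rates (visits/hr), n >= 3.
#' @return The residual vector (trait `G`).
#' @export
growth_residuals <- function(growth, bp) {
  stopifnot(length(growth) == length(bp), length(bp) >= 3L)
  if (sd(bp) == 0) stop("boldness is constant; cannot compute growth residuals")
  unname(resid(lm(growth ~ bp)))
}

#' z-standardize the trait table
#'
#' Standardizes each trait to mean 0 and SD 1 (sample SD, n - 1 denominator),
#' stores the original means and SDs, and appends the quadratic terms `G2`
#' and `BP2` as exact squares of the z-scores.
#'
#' For derived traits whose column mean is zero by construction (the growth
#' residual `G`, the size-corrected shape scores), the stored mean can be
#' overridden with the biologically meaningful original-scale mean (e.g. the
#' raw growth increment's mean), which is what gives the mean-standardized
#' gradient of such a trait a non-degenerate scale; the z-scores themselves
#' always use the column's own mean and SD.
#'
#' @param raw `data.frame` with columns `fish_id`, `pond` and the traits
#'   `BP`, `TL`, `G`, `SB`, `SH`, `SP` on their original scales.
#' @param mu optional named vector overriding stored original means for a
#'   subset of traits.
#' @return An object of class `trait_matrix`: a `data.frame` of z-scores
#'   (plus `G2`, `BP2`) carrying attributes `mu` and `sigma` (named vectors
#'   of the original means and SDs).
#' @export
zstandardize <- function(raw, mu = NULL) {
  traits <- c("BP", "TL", "G", "SB", "SH", "SP")
  missing_tr <- setdiff(traits, names(raw))
  if (length(missing_tr))
    stop("missing trait columns: ", paste(missing_tr, collapse = ", "))
  mu_store <- vapply(raw[traits], mean, numeric(1))
  sigma <- vapply(raw[traits], sd, numeric(1))
  mu_col <- mu_store
  if (!is.null(mu)) {
    bad <- setdiff(names(mu), traits)
    if (length(bad)) stop("mu override for unknown trait(s): ",
                          paste(bad, collapse = ", "))
    mu_store[names(mu)] <- mu
  }
  if (any(sigma == 0))
    stop("zero-variance trait(s): ",
         paste(traits[sigma == 0], collapse = ", "))
  out <- raw[intersect(c("fish_id", "pond"), names(raw))]
  for (tr in traits) out[[tr]] <- (raw[[tr]] - mu_col[tr]) / sigma[tr]
  out$G2 <- out$G^2
  out$BP2 <- out$BP^2
  attr(out, "mu") <- mu_store
  attr(out, "sigma") <- sigma
  class(out) <- c("trait_matrix", "data.frame")
  out
}

#' Code survival-based fitness from the capture log
#'
#' A fish captured in the experimental fishery is considered theoretically
#' dead: fitness `s = 0` if its first capture day is within the horizon,
#' `s = 1` otherwise.  Recaptures are ignored.
#'
#' @param captures capture log with columns `fish_id` and `day`.
#' @param horizon angling horizon in days (7 or 20 in the pond design).
#' @param roster fish ids to code; every captured id must be present.
#' @return A `data.frame` with `fish_id`, `s` (0/1 integer) and `first_day`
#'   (NA if never captured).
#' @export
assign_fitness <- function(captures, horizon, roster) {
  cap <- as.data.table(captures)
  if (nrow(cap)) {
    unknown <- setdiff(unique(cap$fish_id), roster)
    if (length(unknown))
      stop("capture log contains fish ids not in roster: ",
           paste(sort(unknown), collapse = ", "))
    first <- cap[, .(first_day = min(day)), by = fish_id]
  } else {
    first <- data.table(fish_id = character(), first_day = integer())
  }
  fd <- first$first_day[match(roster, first$fish_id)]
  data.frame(fish_id = roster,
             s = as.integer(is.na(fd) | fd > horizon),
             first_day = fd,
             stringsAsFactors = FALSE)
}

#' Fit one logistic survival model
#'
#' Maximum-likelihood logistic regression of survival on z-standardized
#' traits.  Pond nesting is handled by `pond_mode`: `"random"` (default)
#' fits a pond random intercept by Laplace approximation (lme4), `"fixed"`
#' adds pond as a fixed factor, `"none"` ignores pond.  The parameter count
#' `k` used for AICc counts fixed effects including the intercept only (the
#' NULL model has `k = 1`), matching how the candidate models are indexed;
#' the random-effect variance is not penalized.
#'
#' @param terms character vector of predictor terms drawn from
#'   `BP, TL, G, SB, SH, SP, G2, BP2`; `character(0)` is the NULL model.
#' @param traits a [zstandardize()] trait matrix (needs column `pond` for
#'   pond modes other than `"none"`).
#' @param fitness an [assign_fitness()] result aligned with `traits` by
#'   `fish_id`.
#' @param pond_mode `"random"`, `"fixed"` or `"none"`.
#' @return An object of class `survival_fit`: `coefficients` (term,
#'   estimate, se, z, p), `loglik`, `k`, `n`, `fitted` (survival
#'   probabilities), `wbar` (mean observed fitness), `terms`, `pond_mode`,
#'   and the underlying `model` object.
#' @export
fit_logistic <- function(terms, traits, fitness,
                         pond_mode = c("random", "fixed", "none")) {
  pond_mode <- match.arg(pond_mode)
  stopifnot(all(terms %in% c("BP", "TL", "G", "SB", "SH", "SP", "G2", "BP2")))
  dat <- as.data.frame(traits)
  dat$s <- fitness$s[match(dat$fish_id, fitness$fish_id)]
  if (anyNA(dat$s)) stop("fitness missing for some fish in the trait matrix")
  n <- nrow(dat)
  k <- length(terms) + 1L
  if (n <= k + 1L) stop("too few observations for the requested model")

  rhs <- if (length(terms)) paste(terms, collapse = " + ") else "1"
  if (length(terms)) {
    mm <- as.matrix(dat[terms])
    qrr <- qr(cbind(1, mm))
    if (qrr$rank < ncol(mm) + 1L) {
      aliased <- terms[qrr$pivot[seq(qrr$rank + 1L, ncol(mm) + 1L)] - 1L]
      stop("design matrix rank deficient; aliased term(s): ",
           paste(aliased, collapse = ", "))
    }
  }

  sep_msg <- NULL
  fit <- withCallingHandlers(
    {
      if (pond_mode == "random") {
        # a zero pond variance (singular fit) is a legitimate outcome, not
        # a failure; silence lme4's boundary note
        suppressMessages(
          lme4::glmer(as.formula(paste("s ~", rhs, "+ (1 | pond)")),
                      data = dat, family = stats::binomial()))
      } else if (pond_mode == "fixed") {
        stats::glm(as.formula(paste("s ~", rhs, "+ factor(pond)")),
                   data = dat, family = stats::binomial(),
                   control = stats::glm.control(epsilon = 1e-8, maxit = 100))
      } else {
        stats::glm(as.formula(paste("s ~", rhs)),
                   data = dat, family = stats::binomial(),
                   control = stats::glm.control(epsilon = 1e-8, maxit = 100))
      }
    },
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w)))
        sep_msg <<- "complete or quasi-complete separation"
      invokeRestart("muffleWarning")
    }
  )
  if (!is.null(sep_msg))
    stop("logistic fit failed (", sep_msg, ") for model: ", rhs)
  if (inherits(fit, "glm") && !fit$converged)
    stop("IRLS did not converge for model: ", rhs)

  if (inherits(fit, "glmerMod")) {
    cf <- lme4::fixef(fit)
    vc <- as.matrix(stats::vcov(fit))
  } else {
    cf <- coef(fit)
    vc <- stats::vcov(fit)
    keep <- c("(Intercept)", terms)
    cf <- cf[keep]
    vc <- vc[keep, keep, drop = FALSE]
  }
  se <- sqrt(diag(vc))
  zval <- cf / se
  coefs <- data.frame(term = names(cf), estimate = unname(cf),
                      se = unname(se), z = unname(zval),
                      p = unname(2 * pnorm(-abs(zval))),
                      stringsAsFactors = FALSE)
  structure(list(coefficients = coefs,
                 loglik = as.numeric(logLik(fit)),
                 k = k, n = n,
                 fitted = unname(fitted(fit)),
                 wbar = mean(dat$s),
                 terms = terms, pond_mode = pond_mode,
                 model = fit),
            class = "survival_fit")
}

#' @export
print.survival_fit <- function(x, ...) {
  rhs <- if (length(x$terms)) paste(x$terms, collapse = " + ") else "1 (NULL)"
  cat(sprintf("Logistic survival fit: s ~ %s  (pond: %s)\n", rhs, x$pond_mode))
  cat(sprintf("  n = %d, k = %d, logLik = %.3f, AICc = %.3f\n",
              x$n, x$k, x$loglik, aicc(x)))
  print(format(x$coefficients, digits = 3), row.names = FALSE)
  invisible(x)
}

#' Small-sample corrected Akaike information criterion
#'
#' `AICc = -2 logLik + 2k + 2k(k + 1)/(n - k - 1)`.
#'
#' @param fit a [fit_logistic()] result, or a log-likelihood value (then
#'   supply `k` and `n`).
#' @param k,n parameter count and sample size when `fit` is a numeric
#'   log-likelihood.
#' @return The AICc value.
#' @export
aicc <- function(fit, k = NULL, n = NULL) {
  if (inherits(fit, "survival_fit")) {
    ll <- fit$loglik; k <- fit$k; n <- fit$n
  } else {
    ll <- fit
    stopifnot(!is.null(k), !is.null(n))
  }
  if (n - k - 1 <= 0) stop("AICc undefined: n must exceed k + 1")
  -2 * ll + 2 * k + 2 * k * (k + 1) / (n - k - 1)
}

#' Akaike weights from AICc values
#'
#' `delta_i = AICc_i - min(AICc)`;
#' `w_i = exp(-delta_i / 2) / sum(exp(-delta_j / 2))`.  The weights are
#' invariant to adding a constant to every AICc value and sum to one.
#'
#' @param aicc_values numeric vector of finite AICc values.
#' @return A numeric vector of weights (names preserved).
#' @export
akaike_weights <- function(aicc_values) {
  stopifnot(length(aicc_values) >= 1L, all(is.finite(aicc_values)))
  d <- aicc_values - min(aicc_values)
  e <- exp(-d / 2)
  e / sum(e)
}

#' Nagelkerke's pseudo R-squared
#'
#' `R2_CS = 1 - exp(2 (l0 - l1) / n)` rescaled by its maximum,
#' `R2_N = R2_CS / (1 - exp(2 l0 / n))`.
#'
#' @param fit,null_fit [fit_logistic()] results on the same data, the null
#'   (intercept-only) model nested in `fit`.
#' @return The pseudo R-squared in `[0, 1]`.
#' @export
nagelkerke_r2 <- function(fit, null_fit) {
  stopifnot(fit$n == null_fit$n)
  l1 <- fit$loglik; l0 <- null_fit$loglik; n <- fit$n
  if (l1 < l0 - 1e-6)
    stop(sprintf("fitted log-likelihood (%.4f) below null (%.4f); models are not nested",
                 l1, l0))
  r2_cs <- 1 - exp(2 * (l0 - l1) / n)
  r2_max <- 1 - exp(2 * l0 / n)
  min(1, max(0, r2_cs / r2_max))
}

#' Janzen-Stern linearization of logistic coefficients
#'
#' Converts the logistic coefficients into linear selection-gradient
#' equivalents using the average-gradient transformation
#' `beta_j = alpha_j * mean(W_i (1 - W_i)) / Wbar`, with `W_i` the fitted
#' survival probabilities and `Wbar` the mean observed fitness.  Because the
#' predictors are z-standardized, these are the SD-standardized selection
#' gradients.
#'
#' @param fit a [fit_logistic()] result (or any list with elements
#'   `coefficients`, `fitted`, `wbar`).
#' @return Named vector of `beta_SD` gradients, one per non-intercept term.
#' @export
janzen_stern <- function(fit) {
  if (fit$wbar == 0) stop("mean fitness is zero; gradients undefined")
  factor <- mean(fit$fitted * (1 - fit$fitted)) / fit$wbar
  cf <- fit$coefficients
  alpha <- cf$estimate[cf$term != "(Intercept)"]
  setNames(alpha * factor, cf$term[cf$term != "(Intercept)"])
}

#' Mean-standardized selection gradients
#'
#' `beta_mu_j = beta_SD_j * mu_j / sigma_j`, the proportional change in
#' relative fitness caused by doubling the trait value; unit-free and
#' comparable across traits.
#'
#' @param beta_sd named vector of SD-standardized gradients.
#' @param mu,sigma original trait means and SDs (named; matched by the
#'   names of `beta_sd`).
#' @return Named vector of `beta_mu` gradients; terms without a stored
#'   mean/SD (the quadratic terms) are `NA`.
#' @export
mean_standardized_gradients <- function(beta_sd, mu, sigma) {
  out <- setNames(rep(NA_real_, length(beta_sd)), names(beta_sd))
  for (tr in names(beta_sd)) {
    if (tr %in% names(mu)) {
      if (sigma[tr] <= 0) stop("sigma must be positive for trait ", tr)
      out[tr] <- beta_sd[tr] * mu[tr] / sigma[tr]
    }
  }
  out
}

#' Group descriptives and trait correlation matrix
#'
#' Mean and SD of each trait for captured versus uncaptured fish at a given
#' horizon, plus the Pearson correlation matrix of the z-standardized
#' predictors.
#'
#' @param raw raw trait `data.frame` (columns `fish_id` and traits).
#' @param fitness an [assign_fitness()] result.
#' @return A list: `groups` (one row per trait: captured/uncaptured
#'   mean and SD, group sizes) and `corr` (6 x 6 Pearson matrix).
#' @export
trait_descriptives <- function(raw, fitness) {
  traits <- intersect(c("BP", "TL", "G", "SB", "SH", "SP"), names(raw))
  s <- fitness$s[match(raw$fish_id, fitness$fish_id)]
  cap <- raw[s == 0L, traits, drop = FALSE]
  unc <- raw[s == 1L, traits, drop = FALSE]
  groups <- data.frame(
    trait = traits,
    captured_mean = vapply(cap, mean, numeric(1)),
    captured_sd = vapply(cap, sd, numeric(1)),
    uncaptured_mean = vapply(unc, mean, numeric(1)),
    uncaptured_sd = vapply(unc, sd, numeric(1)),
    n_captured = nrow(cap), n_uncaptured = nrow(unc),
    row.names = NULL, stringsAsFactors = FALSE
  )
  z <- scale(as.matrix(raw[traits]))
  list(groups = groups, corr = cor(z))
}
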