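# The nine-model candidate set, AICc ranking, and Table-5-style selection
# gradients from the final model.

#' The nested candidate model set
#'
#' The nine model structures compared for each angling horizon, from the
#' full starting model (all six traits plus quadratic terms for boldness
#' and growth, testing for stabilizing/disruptive selection) down to the
#' intercept-only NULL model.  The reduction path differs slightly between
#' the short (7-day) and long (20-day) horizon sets.
#'
#' @param horizon 7 (short-term) or 20 (long-term).
#' @return A named list of character term vectors (models `M1` ... `M9`).
#' @export
model_specs <- function(horizon) {
  if (horizon <= 7) {
    list(
      M1 = c("BP", "TL", "G", "SB", "SH", "SP", "BP2", "G2"),
      M2 = c("BP", "TL", "SB", "SH", "G", "SP", "G2"),
      M3 = c("BP", "TL", "SB", "SH", "SP", "G"),
      M4 = c("BP", "TL", "SB", "SH", "G"),
      M5 = c("BP", "TL", "SB", "G"),
      M6 = c("BP", "TL", "G"),
      M7 = c("TL", "G"),
      M8 = "G",
      M9 = character(0)
    )
  } else {
    list(
      M1 = c("BP", "TL", "SB", "SH", "G", "SP", "BP2", "G2"),
      M2 = c("BP", "TL", "SB", "SH", "G", "SP", "G2"),
      M3 = c("BP", "TL", "SB", "SH", "G", "SP"),
      M4 = c("BP", "TL", "SB", "SH", "G"),
      M5 = c("BP", "SB", "SH", "G"),
      M6 = c("BP", "SB", "G"),
      M7 = c("BP", "G"),
      M8 = "G",
      M9 = character(0)
    )
  }
}

#' Fit and rank the candidate model set
#'
#' Fits the nine candidate models for the given horizon, ranks them by AICc
#' and computes Akaike weights.  Models within `delta AICc < 1` of the
#' minimum are flagged as best-supported; the "final" model used for
#' selection gradients is the richest (most parameters) among them, with
#' ties broken by fewer parameters and then model order.  Individual fit
#' failures are recorded and the comparison continues over the remaining
#' models.
#'
#' @inheritParams fit_logistic
#' @param horizon 7 or 20; selects the candidate set of [model_specs()].
#' @return An object of class `model_comparison`: `table` (model, terms, k,
#'   loglik, aicc, delta, weight, best flag), `fits` (named list of
#'   [fit_logistic()] results), `final` (model id), `errors` (named list of
#'   failure messages), `horizon`.
#' @export
run_model_set <- function(traits, fitness, horizon,
                          pond_mode = c("random", "fixed", "none")) {
  pond_mode <- match.arg(pond_mode)
  specs <- model_specs(horizon)
  fits <- list()
  errors <- list()
  for (id in names(specs)) {
    res <- tryCatch(fit_logistic(specs[[id]], traits, fitness, pond_mode),
                    error = function(e) e)
    if (inherits(res, "error")) errors[[id]] <- conditionMessage(res)
    else fits[[id]] <- res
  }
  if (!length(fits)) stop("every candidate model failed to fit")
  tab <- data.frame(
    model = names(fits),
    terms = vapply(fits, function(f)
      if (length(f$terms)) paste(f$terms, collapse = " + ") else "NULL",
      character(1)),
    k = vapply(fits, `[[`, integer(1), "k"),
    loglik = vapply(fits, `[[`, numeric(1), "loglik"),
    aicc = vapply(fits, aicc, numeric(1)),
    row.names = NULL, stringsAsFactors = FALSE
  )
  tab$delta <- tab$aicc - min(tab$aicc)
  tab$weight <- akaike_weights(tab$aicc)
  tab$best <- tab$delta < 1
  cand <- tab[tab$best, ]
  final <- cand$model[order(-cand$k, cand$model)][1L]
  structure(list(table = tab, fits = fits, final = final,
                 errors = errors, horizon = horizon),
            class = "model_comparison")
}

#' @export
print.model_comparison <- function(x, ...) {
  cat(sprintf("Candidate survival models, %d-day horizon (final: %s)\n",
              x$horizon, x$final))
  tab <- x$table
  tab$aicc <- round(tab$aicc, 1)
  tab$delta <- round(tab$delta, 2)
  tab$weight <- round(tab$weight, 3)
  print(tab[c("model", "terms", "k", "aicc", "delta", "weight", "best")],
        row.names = FALSE)
  if (length(x$errors))
    cat("Failed fits:", paste(names(x$errors), collapse = ", "), "\n")
  invisible(x)
}

#' Selection gradients from the final model of a comparison
#'
#' Extracts the final (best-supported, richest within delta AICc < 1) model
#' of a [run_model_set()] comparison, linearizes its coefficients with
#' [janzen_stern()], converts them to mean-standardized gradients using the
#' means and SDs stored in the trait matrix, and attaches Nagelkerke's
#' pseudo R-squared against the NULL model.
#'
#' @param comparison a [run_model_set()] result.
#' @param traits the [zstandardize()] trait matrix the models were fit to.
#' @param model optional model id overriding the final-model choice.
#' @return An object of class `selection_gradients`: a `data.frame` with
#'   one row per trait in the model (`trait`, `alpha`, `se`, `p`,
#'   `beta_sd`, `beta_mu`) plus attributes `r2_nagelkerke`, `model`,
#'   `horizon`.
#' @export
selection_gradients <- function(comparison, traits, model = NULL) {
  stopifnot(inherits(comparison, "model_comparison"))
  id <- if (is.null(model)) comparison$final else model
  fit <- comparison$fits[[id]]
  if (is.null(fit)) stop("no fitted model with id ", id)
  null_fit <- comparison$fits[["M9"]]
  r2 <- if (!is.null(null_fit)) nagelkerke_r2(fit, null_fit) else NA_real_
  beta_sd <- janzen_stern(fit)
  beta_mu <- mean_standardized_gradients(beta_sd, attr(traits, "mu"),
                                         attr(traits, "sigma"))
  cf <- fit$coefficients
  cf <- cf[cf$term != "(Intercept)", ]
  out <- data.frame(trait = cf$term, alpha = cf$estimate, se = cf$se,
                    p = cf$p,
                    beta_sd = unname(beta_sd[cf$term]),
                    beta_mu = unname(beta_mu[cf$term]),
                    row.names = NULL, stringsAsFactors = FALSE)
  attr(out, "r2_nagelkerke") <- r2
  attr(out, "model") <- id
  attr(out, "horizon") <- comparison$horizon
  class(out) <- c("selection_gradients", "data.frame")
  out
}

#' @export
print.selection_gradients <- function(x, ...) {
  cat(sprintf("Selection gradients (%d-day horizon, model %s, Nagelkerke R2 = %.2f)\n",
              attr(x, "horizon"), attr(x, "model"), attr(x, "r2_nagelkerke")))
  print(format(as.data.frame(x), digits = 3), row.names = FALSE)
  invisible(x)
}
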