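#' Paired species sensitivities for two chemicals
#'
#' Inner-joins two chemicals' SMAV tables on normalized species name,
#' yielding the (x, y) = (log10 surrogate SMAV, log10 predicted SMAV) pairs
#' an inter-chemical regression is fitted to. Pair models require at least
#' three shared species.
#'
#' @param smavs_surrogate,smavs_predicted SMAV tibbles for the surrogate and
#'   the predicted chemical (see [compute_smavs()]).
#' @param min_common Minimum shared species (default 3).
#' @return Tibble with columns `species`, `surrogate_chemical`,
#'   `predicted_chemical`, `x`, `y` (log10 ug/L).
#' @export
common_species <- function(smavs_surrogate, smavs_predicted, min_common = 3) {
  a <- tibble::as_tibble(smavs_surrogate)
  b <- tibble::as_tibble(smavs_predicted)
  for (tb in list(a, b)) {
    if (!all(c("species", "chemical", "smav") %in% names(tb))) {
      stop("SMAV tables need columns species, chemical, smav", call. = FALSE)
    }
  }
  chem_a <- unique(a$chemical)
  chem_b <- unique(b$chemical)
  if (length(chem_a) != 1 || length(chem_b) != 1) {
    stop("each SMAV table must contain exactly one chemical", call. = FALSE)
  }
  if (chem_a == chem_b) stop("surrogate and predicted chemicals must differ", call. = FALSE)
  a$.key <- normalize_species(a$species)
  b$.key <- normalize_species(b$species)
  joined <- dplyr::inner_join(
    a[, c(".key", "species", "smav")],
    b[, c(".key", "smav")],
    by = ".key", suffix = c("_x", "_y")
  )
  if (nrow(joined) < min_common) {
    stop("insufficient overlap for pair ", chem_a, " -> ", chem_b, ": ",
         nrow(joined), " common species (need >= ", min_common, ")", call. = FALSE)
  }
  tibble::tibble(
    species = joined$species,
    surrogate_chemical = chem_a,
    predicted_chemical = chem_b,
    x = log10(joined$smav_x),
    y = log10(joined$smav_y)
  )
}

#' Fit an inter-chemical toxicity extrapolation model
#'
#' Ordinary least squares of `log10(predicted toxicity)` on
#' `log10(surrogate toxicity)` across shared species:
#' `log10(y) = a * log10(x) + b`. The p-value is the two-sided t-test on the
#' slope, which for simple OLS equals the regression F-test.
#'
#' @param pairs Paired sensitivities from [common_species()].
#' @param loo If TRUE (default), also compute the leave-one-out RMSEP.
#' @return One-row tibble of class `pair_model` with columns
#'   `surrogate_chemical`, `predicted_chemical`, `slope`, `intercept`,
#'   `r_squared`, `p_value`, `n_common`, `rmsep_loo`; the fitting pairs are
#'   attached as attribute `pairs`.
#' @export
fit_pair_model <- function(pairs, loo = TRUE) {
  pairs <- tibble::as_tibble(pairs)
  if (nrow(pairs) < 3) stop("pair model needs at least 3 pairs", call. = FALSE)
  if (stats::var(pairs$x) == 0) {
    stop("singular design: zero variance in surrogate log10 values", call. = FALSE)
  }
  fit <- stats::lm(y ~ x, data = pairs)
  sm <- summary(fit)
  out <- tibble::tibble(
    surrogate_chemical = pairs$surrogate_chemical[1] %||% NA_character_,
    predicted_chemical = pairs$predicted_chemical[1] %||% NA_character_,
    slope = unname(stats::coef(fit)[2]),
    intercept = unname(stats::coef(fit)[1]),
    r_squared = sm$r.squared,
    p_value = sm$coefficients[2, 4],
    n_common = nrow(pairs),
    rmsep_loo = if (loo && nrow(pairs) >= 4) loo_rmsep(pairs) else NA_real_
  )
  attr(out, "pairs") <- pairs
  attr(out, "vcov") <- unname(stats::vcov(fit))
  class(out) <- c("pair_model", class(out))
  out
}

`%||%` <- function(x, y) if (is.null(x)) y else x

#' Keep only statistically significant pair models
#'
#' Removes models whose slope p-value exceeds `alpha`; a p-value exactly at
#' the threshold is kept (only `p > alpha` is removed). Order is preserved.
#'
#' @param models Tibble of pair models (rows from [fit_pair_model()] or
#'   [fit_pair_models()]).
#' @param alpha Significance threshold, default 0.05.
#' @return The retained rows.
#' @export
filter_models <- function(models, alpha = 0.05) {
  models <- tibble::as_tibble(models)
  models[models$p_value <= alpha, , drop = FALSE]
}

#' Leave-one-out root-mean-square error of prediction
#'
#' For each pair in turn, the model is refitted without it and the held-out
#' `y` predicted; RMSEP is the root mean square of those held-out residuals,
#' in log10 concentration units (the model's fitting scale). Refits whose
#' design becomes singular are skipped with a warning.
#'
#' @param pairs Paired sensitivities (needs >= 4 rows so each refit keeps
#'   >= 3).
#' @return RMSEP in log10 ug/L.
#' @export
loo_rmsep <- function(pairs) {
  pairs <- tibble::as_tibble(pairs)
  n <- nrow(pairs)
  if (n < 4) stop("leave-one-out RMSEP needs at least 4 pairs", call. = FALSE)
  sq_err <- rep(NA_real_, n)
  skipped <- 0L
  for (i in seq_len(n)) {
    train <- pairs[-i, , drop = FALSE]
    if (stats::var(train$x) == 0) {
      skipped <- skipped + 1L
      next
    }
    cf <- stats::coef(stats::lm(y ~ x, data = train))
    yhat <- cf[1] + cf[2] * pairs$x[i]
    sq_err[i] <- (pairs$y[i] - yhat)^2
  }
  if (skipped > 0) {
    warning(skipped, " leave-one-out refit(s) skipped (singular design)", call. = FALSE)
  }
  sqrt(mean(sq_err, na.rm = TRUE))
}

#' Predict toxicity of one chemical from another
#'
#' Applies the extrapolation model on the concentration scale:
#' `10^(a * log10(surrogate_value) + b)`.
#'
#' @param model A `pair_model` row (or anything with `slope` and
#'   `intercept` columns).
#' @param surrogate_value Surrogate chemical toxicity value(s) in ug/L (> 0).
#' @return Predicted toxicity in ug/L.
#' @export
predict_toxicity <- function(model, surrogate_value) {
  if (any(!is.finite(surrogate_value) | surrogate_value <= 0)) {
    stop("surrogate value must be positive and finite", call. = FALSE)
  }
  10^(model$slope[1] * log10(surrogate_value) + model$intercept[1])
}

#' Relative prediction error
#'
#' `|predicted - observed| / observed`, the external-validation statistic.
#'
#' @param predicted,observed Concentrations in ug/L; `observed` must be > 0.
#' @return Non-negative proportion.
#' @export
relative_error <- function(predicted, observed) {
  if (any(!is.finite(observed) | observed <= 0)) {
    stop("observed value must be positive and finite", call. = FALSE)
  }
  abs(predicted - observed) / observed
}

#' Are two toxicity values within a k-fold factor?
#'
#' TRUE when `max(p/o, o/p) <= fold`. The conventional acceptability screen
#' is 5-fold, about the inter-laboratory spread of acute toxicity values for
#' a single species and chemical.
#'
#' @param predicted,observed Positive concentrations in ug/L.
#' @param fold Fold-difference threshold, default 5.
#' @return Logical.
#' @export
within_fold <- function(predicted, observed, fold = 5) {
  if (any(predicted <= 0 | observed <= 0)) {
    stop("both values must be positive", call. = FALSE)
  }
  pmax(predicted / observed, observed / predicted) <= fold
}

#' Fit all directed inter-chemical pair models from a long SMAV table
#'
#' For every ordered pair of distinct chemicals with at least `min_common`
#' shared species, fits the surrogate-to-predicted regression. Pairs with
#' insufficient overlap are silently omitted (both directions of an
#' unordered pair are distinct models).
#'
#' @param smavs Long SMAV tibble spanning several chemicals.
#' @param min_common Minimum shared species per pair, default 3.
#' @param loo Compute LOO RMSEP per model (default TRUE).
#' @return Tibble with one row per fitted model.
#' @export
fit_pair_models <- function(smavs, min_common = 3, loo = TRUE) {
  smavs <- tibble::as_tibble(smavs)
  chems <- unique(smavs$chemical)
  rows <- list()
  for (su in chems) {
    for (pr in chems) {
      if (su == pr) next
      pairs <- tryCatch(
        common_species(smavs[smavs$chemical == su, ],
                       smavs[smavs$chemical == pr, ],
                       min_common = min_common),
        error = function(e) NULL
      )
      if (is.null(pairs)) next
      rows[[paste(su, pr, sep = "->")]] <- fit_pair_model(pairs, loo = loo)
    }
  }
  if (length(rows) == 0) {
    stop("no chemical pair has >= ", min_common, " common species", call. = FALSE)
  }
  dplyr::bind_rows(rows)
}

#' Externally validate pair models against observed toxicity values
#'
#' For each model whose surrogate and predicted chemicals both appear in
#' `observed`, predicts the predicted chemical's toxicity from the observed
#' surrogate value and reports the relative error and the k-fold check —
#' the external-verification table of the workflow.
#'
#' @param models Tibble of pair models.
#' @param observed Tibble with columns `chemical` and `value` (ug/L):
#'   measured acute values for one test species.
#' @param fold Fold-difference threshold for acceptability, default 5.
#' @return Tibble with columns `surrogate_chemical`, `surrogate_observed`,
#'   `predicted_chemical`, `observed`, `predicted`, `relative_error`,
#'   `within_fold`.
#' @export
validate_models <- function(models, observed, fold = 5) {
  models <- tibble::as_tibble(models)
  observed <- tibble::as_tibble(observed)
  if (!all(c("chemical", "value") %in% names(observed))) {
    stop("observed table needs columns chemical and value", call. = FALSE)
  }
  obs <- stats::setNames(observed$value, observed$chemical)
  keep <- models$surrogate_chemical %in% names(obs) &
    models$predicted_chemical %in% names(obs)
  models <- models[keep, , drop = FALSE]
  if (nrow(models) == 0) {
    stop("no model has observed values for both chemicals", call. = FALSE)
  }
  pred <- mapply(function(i) {
    predict_toxicity(models[i, ], obs[[models$surrogate_chemical[i]]])
  }, seq_len(nrow(models)))
  obs_y <- obs[models$predicted_chemical]
  tibble::tibble(
    surrogate_chemical = models$surrogate_chemical,
    surrogate_observed = unname(obs[models$surrogate_chemical]),
    predicted_chemical = models$predicted_chemical,
    observed = unname(obs_y),
    predicted = unname(pred),
    relative_error = relative_error(unname(pred), unname(obs_y)),
    within_fold = within_fold(unname(pred), unname(obs_y), fold = fold)
  )
}
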