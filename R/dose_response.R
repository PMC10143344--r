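#' Empirical probit transform
#'
#' Converts an observed mortality proportion to the classical probit scale,
#' `qnorm(p) + 5`. The +5 offset is the traditional shift that keeps probits
#' positive over the usual working range and is the scale on which fitted
#' equations such as `y = 2.9723x - 1.3217` are reported, so that solving
#' `y = 5` gives the LC50.
#'
#' @param p Numeric vector of mortality proportions, strictly between 0 and 1.
#' @return Numeric vector of probit values (`qnorm(p) + 5`).
#' @examples
#' empirical_probit(0.5)    # 5
#' empirical_probit(0.9772) # ~7
#' @export
empirical_probit <- function(p) {
  stopifnot(is.numeric(p))
  bad <- which(!is.finite(p) | p <= 0 | p >= 1)
  if (length(bad) > 0) {
    stop("empirical probit undefined for proportion(s) outside (0, 1) at position(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  stats::qnorm(p) + 5
}

#' Construct a table of dose groups
#'
#' @param concentration Exposure concentrations in ug/L (positive).
#' @param n_exposed Number of organisms exposed per group (positive integer).
#' @param n_dead Number dead per group (0 <= n_dead <= n_exposed).
#' @return A tibble with one row per dose group.
#' @export
dose_groups <- function(concentration, n_exposed, n_dead) {
  groups <- tibble::tibble(
    concentration = as.numeric(concentration),
    n_exposed = as.integer(n_exposed),
    n_dead = as.integer(n_dead)
  )
  validate_dose_groups(groups)
  groups
}

validate_dose_groups <- function(groups) {
  req <- c("concentration", "n_exposed", "n_dead")
  missing_cols <- setdiff(req, names(groups))
  if (length(missing_cols) > 0) {
    stop("dose groups missing column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  if (nrow(groups) == 0) stop("dose group table is empty", call. = FALSE)
  if (any(!is.finite(groups$concentration) | groups$concentration <= 0)) {
    stop("all concentrations must be positive and finite", call. = FALSE)
  }
  if (any(groups$n_exposed < 1)) stop("n_exposed must be >= 1", call. = FALSE)
  if (any(groups$n_dead < 0 | groups$n_dead > groups$n_exposed)) {
    stop("n_dead must satisfy 0 <= n_dead <= n_exposed", call. = FALSE)
  }
  invisible(groups)
}

#' Handle 0% and 100% mortality groups before empirical-probit fitting
#'
#' The empirical probit is undefined at mortality 0 or 1. Policy `"drop"`
#' (classical practice) removes such groups; `"correct"` keeps them with the
#' shrunken proportion `(n_dead + 0.5) / (n_exposed + 1)`.
#'
#' @param groups Dose-group table (see [dose_groups()]).
#' @param policy `"drop"` or `"correct"`.
#' @return Tibble with columns `log10_conc` and `proportion`.
#' @export
adjust_extremes <- function(groups, policy = c("drop", "correct")) {
  policy <- match.arg(policy)
  validate_dose_groups(groups)
  extreme <- groups$n_dead == 0L | groups$n_dead == groups$n_exposed
  if (policy == "drop") {
    kept <- groups[!extreme, , drop = FALSE]
    prop <- kept$n_dead / kept$n_exposed
    out <- tibble::tibble(log10_conc = log10(kept$concentration), proportion = prop)
  } else {
    prop <- ifelse(extreme,
                   (groups$n_dead + 0.5) / (groups$n_exposed + 1),
                   groups$n_dead / groups$n_exposed)
    out <- tibble::tibble(log10_conc = log10(groups$concentration), proportion = prop)
  }
  if (nrow(out) < 2) {
    stop("fewer than 2 usable dose groups after extreme-mortality adjustment (policy \"",
         policy, "\")", call. = FALSE)
  }
  out
}

#' Construct a probit fit from known coefficients
#'
#' Builds a `probit_fit` object directly from a slope and intercept on the
#' probit-plus-5 scale, e.g. from a published fitted equation
#' `y = a * log10(conc) + b`. Such fits support [lc_p()] but not
#' [lc50_ci()] (no covariance information).
#'
#' @param slope Slope `a` in probit units per log10(ug/L).
#' @param intercept Intercept `b` in probit units.
#' @param r_squared Optional coefficient of determination.
#' @param n_groups Optional number of dose groups behind the fit.
#' @return An object of class `probit_fit`.
#' @export
probit_fit <- function(slope, intercept, r_squared = NA_real_, n_groups = NA_integer_) {
  stopifnot(is.numeric(slope), length(slope) == 1,
            is.numeric(intercept), length(intercept) == 1)
  if (is.finite(slope) && slope <= 0) {
    warning("non-positive probit slope: mortality does not increase with dose",
            call. = FALSE)
  }
  structure(
    list(slope = slope, intercept = intercept, r_squared = r_squared,
         n_groups = as.integer(n_groups), method = "coefficients",
         vcov = NULL, groups = NULL),
    class = "probit_fit"
  )
}

#' Fit a probit dose-mortality model
#'
#' Two fitting routes are provided. `"empirical-ols"` (default) regresses the
#' empirical probits `qnorm(p) + 5` of the observed mortality proportions on
#' log10 concentration by ordinary least squares, the classical workflow that
#' yields a fitted line with an R squared. `"mle"` maximises the binomial
#' likelihood under a probit link (iteratively reweighted least squares via
#' [stats::glm()]); its coefficients are reported on the same probit-plus-5
#' scale and R squared is not defined.
#'
#' @param groups Dose-group table (see [dose_groups()]).
#' @param method `"empirical-ols"` or `"mle"`.
#' @param extreme_policy Passed to [adjust_extremes()] (empirical-OLS only;
#'   the binomial likelihood handles extreme groups natively).
#' @return An object of class `probit_fit` with elements `slope`, `intercept`,
#'   `r_squared`, `n_groups`, `method`, `vcov` (2x2, intercept then slope, on
#'   the probit-plus-5 scale) and `groups`.
#' @export
fit_probit <- function(groups,
                       method = c("empirical-ols", "mle"),
                       extreme_policy = c("drop", "correct")) {
  method <- match.arg(method)
  extreme_policy <- match.arg(extreme_policy)
  validate_dose_groups(groups)
  if (length(unique(groups$concentration)) < 2) {
    stop("singular design: all concentrations identical", call. = FALSE)
  }
  prop <- groups$n_dead / groups$n_exposed
  ord <- order(groups$concentration)
  if (all(diff(prop[ord]) < 0)) {
    warning("mortality strictly decreasing with dose; fitted slope will be negative",
            call. = FALSE)
  }

  if (method == "empirical-ols") {
    pts <- adjust_extremes(groups, policy = extreme_policy)
    if (length(unique(pts$log10_conc)) < 2) {
      stop("singular design: fewer than 2 distinct usable concentrations", call. = FALSE)
    }
    probit <- empirical_probit(pts$proportion)
    fit <- stats::lm(probit ~ pts$log10_conc)
    slope <- unname(stats::coef(fit)[2])
    intercept <- unname(stats::coef(fit)[1])
    r2 <- summary(fit)$r.squared
    V <- unname(stats::vcov(fit))
    n_used <- nrow(pts)
  } else {
    x <- log10(groups$concentration)
    fit <- stats::glm(cbind(n_dead, n_exposed - n_dead) ~ x,
                      family = stats::binomial(link = "probit"),
                      data = groups)
    # glm works on qnorm(p); shift intercept so coefficients live on probit + 5
    slope <- unname(stats::coef(fit)[2])
    intercept <- unname(stats::coef(fit)[1]) + 5
    r2 <- NA_real_
    V <- unname(stats::vcov(fit))
    n_used <- nrow(groups)
  }
  if (is.finite(slope) && slope <= 0) {
    warning("non-positive probit slope: mortality does not increase with dose",
            call. = FALSE)
  }
  structure(
    list(slope = slope, intercept = intercept, r_squared = r2,
         n_groups = n_used, method = method, vcov = V, groups = groups),
    class = "probit_fit"
  )
}

#' @export
print.probit_fit <- function(x, ...) {
  cat("Probit dose-mortality fit (", x$method, ")\n", sep = "")
  cat(sprintf("  y = %.4f * log10(conc) + %.4f   (probit + 5 scale)\n",
              x$slope, x$intercept))
  if (!is.na(x$r_squared)) cat(sprintf("  R-squared: %.4f\n", x$r_squared))
  if (!is.na(x$n_groups)) cat("  dose groups used:", x$n_groups, "\n")
  if (is.finite(x$slope) && x$slope > 0) {
    cat(sprintf("  LC50: %.4g ug/L\n", lc_p(x, 0.5)))
  }
  invisible(x)
}

#' Lethal concentration for a given mortality proportion
#'
#' Inverts the fitted probit line: `LC_p = 10^((qnorm(p) + 5 - b) / a)`.
#' At `p = 0.5` this is the LC50, `10^((5 - b) / a)`.
#'
#' @param fit A `probit_fit`.
#' @param p Mortality proportion(s), strictly in (0, 1).
#' @return Concentration(s) in ug/L.
#' @export
lc_p <- function(fit, p = 0.5) {
  stopifnot(inherits(fit, "probit_fit"))
  if (!is.finite(fit$slope) || fit$slope == 0) {
    stop("LC_p undefined: probit slope is zero", call. = FALSE)
  }
  if (any(p <= 0 | p >= 1)) stop("p must lie strictly in (0, 1)", call. = FALSE)
  10^((stats::qnorm(p) + 5 - fit$intercept) / fit$slope)
}

#' Confidence interval for the LC50
#'
#' Default method is the delta method on log10 LC50: the variance of
#' `g = (5 - b)/a` follows from the coefficient covariance by the gradient
#' `(-1/a, -(5 - b)/a^2)` with respect to `(b, a)`, and the interval is
#' exponentiated back to ug/L. Fieller's theorem, which does not rely on the
#' ratio being approximately normal, is available as an option; when the
#' slope is poorly determined Fieller's set can be unbounded, which is
#' reported as an open bound with a warning.
#'
#' @param fit A `probit_fit` produced by [fit_probit()] (needs `vcov`).
#' @param level Confidence level, in (0, 1). Default 0.95.
#' @param method `"delta"` or `"fieller"`.
#' @return Named numeric vector `c(lower, upper)` in ug/L.
#' @export
lc50_ci <- function(fit, level = 0.95, method = c("delta", "fieller")) {
  method <- match.arg(method)
  stopifnot(inherits(fit, "probit_fit"))
  if (is.null(fit$vcov)) {
    stop("confidence interval requires a fit with covariance information ",
         "(use fit_probit(), not probit_fit())", call. = FALSE)
  }
  if (level <= 0 || level >= 1) stop("level must lie in (0, 1)", call. = FALSE)
  a <- fit$slope
  b <- fit$intercept
  V <- fit$vcov  # order: (intercept, slope)
  z <- stats::qnorm(1 - (1 - level) / 2)
  g <- (5 - b) / a

  if (method == "delta") {
    grad <- c(-1 / a, -(5 - b) / a^2)
    var_g <- drop(t(grad) %*% V %*% grad)
    if (!is.finite(var_g) || var_g < 0) {
      warning("degenerate variance for log10 LC50; interval unbounded", call. = FALSE)
      return(c(lower = 0, upper = Inf))
    }
    se <- sqrt(var_g)
    return(c(lower = 10^(g - z * se), upper = 10^(g + z * se)))
  }

  # Fieller: { m : (a*m + b - 5)^2 <= z^2 * (m^2 Vaa + 2 m Vab + Vbb) }
  vbb <- V[1, 1]; vab <- V[1, 2]; vaa <- V[2, 2]
  A <- a^2 - z^2 * vaa
  B <- 2 * (a * (b - 5) - z^2 * vab)
  C <- (b - 5)^2 - z^2 * vbb
  disc <- B^2 - 4 * A * C
  if (A <= 0 || disc < 0) {
    warning("Fieller set unbounded (slope not significantly different from 0); ",
            "returning open interval", call. = FALSE)
    return(c(lower = 0, upper = Inf))
  }
  roots <- sort((-B + c(-1, 1) * sqrt(disc)) / (2 * A))
  c(lower = 10^roots[1], upper = 10^roots[2])
}
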