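#' Rank SMAVs into a species sensitivity distribution table
#'
#' Sorts one chemical's species mean acute values from most to least
#' sensitive (ascending SMAV) and assigns each species the cumulative
#' probability `rank / (n_species + 1)` — the plotting position that places
#' a species ranked 6th of 64 at 6/65 = 9.23%. Ties in SMAV are broken by
#' species name so ranks are deterministic integers.
#'
#' @param smavs SMAV tibble (see [compute_smavs()]); a single chemical, or
#'   pass `chemical` to select one from a long table.
#' @param chemical Optional chemical tag to filter on.
#' @param subset `"all"` or `"native"`; the latter keeps only species whose
#'   `native` flag is TRUE before ranking.
#' @return Tibble of class `ssd_table` with columns `chemical`, `species`,
#'   `smav`, `rank`, `cumulative_probability`, plus attributes `n_species`
#'   and `subset`.
#' @export
rank_and_probability <- function(smavs, chemical = NULL, subset = c("all", "native")) {
  subset <- match.arg(subset)
  smavs <- tibble::as_tibble(smavs)
  req <- c("species", "chemical", "smav")
  missing_cols <- setdiff(req, names(smavs))
  if (length(missing_cols) > 0) {
    stop("SMAV table missing column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  if (!is.null(chemical)) {
    smavs <- smavs[smavs$chemical == chemical, , drop = FALSE]
  }
  if (length(unique(smavs$chemical)) > 1) {
    stop("SMAV table contains multiple chemicals; pass `chemical` to select one",
         call. = FALSE)
  }
  if (subset == "native") {
    if (!"native" %in% names(smavs)) {
      stop("subset = \"native\" requires a `native` column", call. = FALSE)
    }
    smavs <- smavs[!is.na(smavs$native) & smavs$native, , drop = FALSE]
  }
  if (nrow(smavs) == 0) stop("no SMAV entries to rank", call. = FALSE)
  key <- normalize_species(smavs$species)
  if (anyDuplicated(key)) {
    stop("duplicate species in SMAV table: ",
         paste(unique(key[duplicated(key)]), collapse = ", "), call. = FALSE)
  }
  ord <- order(smavs$smav, key)
  smavs <- smavs[ord, , drop = FALSE]
  n <- nrow(smavs)
  out <- tibble::tibble(
    chemical = smavs$chemical,
    species = smavs$species,
    smav = smavs$smav,
    rank = seq_len(n),
    cumulative_probability = seq_len(n) / (n + 1)
  )
  attr(out, "n_species") <- n
  attr(out, "subset") <- subset
  class(out) <- c("ssd_table", class(out))
  out
}

#' Is a species a sensitive test-species candidate?
#'
#' A species is flagged as a candidate test species when its cumulative
#' probability in the SSD falls strictly below the threshold (default 15%).
#'
#' @param probability Cumulative probability / probabilities in (0, 1).
#' @param threshold Strict upper bound; default 0.15.
#' @return Logical vector.
#' @export
is_sensitive_candidate <- function(probability, threshold = 0.15) {
  if (any(probability <= 0 | probability >= 1)) {
    stop("cumulative probability must lie strictly in (0, 1)", call. = FALSE)
  }
  probability < threshold
}

#' Fit a log-normal species sensitivity distribution
#'
#' The conventional SSD parametrisation: species log10 SMAVs are treated as
#' normal with mean `mu` and sample standard deviation `sigma` (n - 1
#' denominator).
#'
#' @param smavs SMAV tibble or a numeric vector of SMAVs in ug/L.
#' @return Object of class `lognormal_ssd`: list with `mu`, `sigma`, `n`.
#' @export
fit_lognormal_ssd <- function(smavs) {
  values <- if (is.numeric(smavs)) smavs else tibble::as_tibble(smavs)$smav
  if (is.null(values) || length(values) < 2) {
    stop("log-normal SSD fit needs at least 2 SMAVs", call. = FALSE)
  }
  if (any(!is.finite(values) | values <= 0)) {
    stop("SMAVs must be positive and finite", call. = FALSE)
  }
  lv <- log10(values)
  sigma <- stats::sd(lv)
  if (sigma == 0) {
    warning("all SMAVs identical: degenerate SSD with sigma = 0", call. = FALSE)
  }
  structure(list(mu = mean(lv), sigma = sigma, n = length(lv)),
            class = "lognormal_ssd")
}

#' @export
print.lognormal_ssd <- function(x, ...) {
  cat("Log-normal SSD: mu =", format(x$mu, digits = 4),
      "sigma =", format(x$sigma, digits = 4),
      "(log10 ug/L), n =", x$n, "\n")
  cat("  HC5 =", format(hc_p(x, 0.05), digits = 4), "ug/L\n")
  invisible(x)
}

#' Hazardous concentration for a fraction p of species
#'
#' The SSD's p-th quantile, `10^(mu + sigma * qnorm(p))`. HC5 (`p = 0.05`)
#' is the concentration expected to leave 95% of species unaffected, the
#' basis of water quality criteria. For an `ssd_table`, the `"empirical"`
#' method instead interpolates log10 SMAV linearly against the rank/(N+1)
#' plotting positions.
#'
#' @param ssd A `lognormal_ssd` (or an `ssd_table` when
#'   `method = "empirical"`).
#' @param p Protected-fraction complement, strictly in (0, 1); default 0.05.
#' @param method `"lognormal"` (default) or `"empirical"`.
#' @return Concentration in ug/L.
#' @export
hc_p <- function(ssd, p = 0.05, method = c("lognormal", "empirical")) {
  method <- match.arg(method)
  if (any(p <= 0 | p >= 1)) stop("p must lie strictly in (0, 1)", call. = FALSE)
  if (method == "lognormal") {
    if (inherits(ssd, "ssd_table")) ssd <- fit_lognormal_ssd(ssd)
    stopifnot(inherits(ssd, "lognormal_ssd"))
    return(10^(ssd$mu + ssd$sigma * stats::qnorm(p)))
  }
  if (!inherits(ssd, "ssd_table")) {
    stop("empirical HC_p needs a ranked ssd_table", call. = FALSE)
  }
  probs <- ssd$cumulative_probability
  lsmav <- log10(ssd$smav)
  # linear interpolation of the plotting positions; flat extrapolation
  # beyond the observed range (rule = 2) keeps small-n tables usable
  10^stats::approx(probs, lsmav, xout = p, rule = 2, ties = "ordered")$y
}
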