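#' Configuration for the synthetic-data generator
#'
#' Bundles and validates everything the generator needs: a mandatory seed,
#' the species-level sensitivity model (per-chemical log10-normal means and
#' standard deviations with a common exchangeable inter-chemical correlation
#' `rho`), and the dose-mortality design (a geometric concentration series
#' and a binomial mortality mechanism under a probit link with a stated true
#' LC50 and slope).
#'
#' Defaults mirror a typical acute heavy-metal study: four metals with
#' species sensitivities centred in the hundreds of ug/L and spanning a few
#' orders of magnitude (sigma 0.8 log10 units), strongly correlated across
#' metals (rho 0.8); five concentrations increasing by a factor of 1.6 from
#' 100 ug/L with ten fish per dose.
#'
#' @param seed Integer seed; all generator randomness flows from it.
#' @param n_species Number of species to simulate.
#' @param chemicals Character vector of chemical tags.
#' @param mu Per-chemical mean of log10 sensitivity (recycled to length of
#'   `chemicals`).
#' @param sigma Per-chemical sd of log10 sensitivity (> 0, recycled).
#' @param rho Common pairwise inter-chemical correlation in \[-1, 1\]; must
#'   keep the exchangeable correlation matrix positive semi-definite
#'   (`rho >= -1/(k-1)` for k chemicals).
#' @param dose_design Concentrations (ug/L) for the dose-mortality design.
#' @param n_per_dose Organisms exposed per concentration.
#' @param true_lc50 True LC50 (ug/L) of the simulated dose-mortality data.
#' @param true_slope True probit slope (probit units per log10 ug/L).
#' @param native_fraction Expected fraction of species flagged native.
#' @return Object of class `synthetic_config` (a validated list).
#' @export
synthetic_config <- function(seed,
                             n_species = 40,
                             chemicals = c("Cu", "Zn", "Pb", "Cd"),
                             mu = c(2.2, 2.5, 2.8, 2.7),
                             sigma = 0.8,
                             rho = 0.8,
                             dose_design = c(100, 160, 250, 400, 630),
                             n_per_dose = 10,
                             true_lc50 = 250,
                             true_slope = 3,
                             native_fraction = 0.3) {
  stopifnot(length(seed) == 1, is.finite(seed))
  k <- length(chemicals)
  if (k < 1 || anyDuplicated(chemicals)) {
    stop("chemicals must be a non-empty set of distinct tags", call. = FALSE)
  }
  mu <- rep_len(as.numeric(mu), k)
  sigma <- rep_len(as.numeric(sigma), k)
  if (any(sigma <= 0)) stop("sigma must be > 0", call. = FALSE)
  if (abs(rho) > 1) stop("rho must lie in [-1, 1]", call. = FALSE)
  if (k > 1 && rho < -1 / (k - 1)) {
    stop("exchangeable correlation matrix not positive semi-definite: ",
         "rho must be >= ", format(-1 / (k - 1), digits = 3), " for ",
         k, " chemicals", call. = FALSE)
  }
  if (n_species < 1) stop("n_species must be >= 1", call. = FALSE)
  if (any(dose_design <= 0)) stop("dose_design concentrations must be > 0", call. = FALSE)
  if (n_per_dose < 1) stop("n_per_dose must be >= 1", call. = FALSE)
  if (true_lc50 <= 0 || true_slope == 0) {
    stop("true_lc50 must be > 0 and true_slope non-zero", call. = FALSE)
  }
  if (native_fraction < 0 || native_fraction > 1) {
    stop("native_fraction must lie in [0, 1]", call. = FALSE)
  }
  structure(
    list(seed = as.integer(seed), n_species = as.integer(n_species),
         chemicals = chemicals, mu = mu, sigma = sigma, rho = rho,
         dose_design = as.numeric(dose_design),
         n_per_dose = as.integer(n_per_dose),
         true_lc50 = as.numeric(true_lc50),
         true_slope = as.numeric(true_slope),
         native_fraction = as.numeric(native_fraction)),
    class = "synthetic_config"
  )
}

#' Generate a long-format species-sensitivity table
#'
#' Draws each species' log10 sensitivities across chemicals from a
#' multivariate normal with means `mu`, standard deviations `sigma` and a
#' common pairwise correlation `rho`, then emits them as conformant acute
#' toxicity records (fish, LC50, 96 h) in ug/L with species names
#' `S0001, S0002, ...` and a Bernoulli(`native_fraction`) native flag.
#' Fully reproducible from the config seed.
#'
#' @param config A [synthetic_config()].
#' @return Tibble with columns `species`, `taxon_group`, `native`,
#'   `chemical`, `endpoint`, `duration_h`, `value`, `source_id`.
#' @export
generate_sensitivity_table <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  set.seed(config$seed)
  k <- length(config$chemicals)
  R <- matrix(config$rho, k, k)
  diag(R) <- 1
  Sigma <- diag(config$sigma, k) %*% R %*% diag(config$sigma, k)
  draws <- MASS::mvrnorm(config$n_species, mu = config$mu, Sigma = Sigma)
  draws <- matrix(draws, ncol = k)  # n_species = 1 returns a vector
  native <- stats::runif(config$n_species) < config$native_fraction
  species <- sprintf("S%04d", seq_len(config$n_species))
  tibble::tibble(
    species = rep(species, each = k),
    taxon_group = "fish",
    native = rep(native, each = k),
    chemical = rep(config$chemicals, times = config$n_species),
    endpoint = "LC50",
    duration_h = 96,
    value = 10^as.vector(t(draws)),
    source_id = "synthetic"
  )
}

#' Generate binomial dose-mortality data under a probit model
#'
#' For each concentration `c` in the design, draws the number dead as
#' `Binomial(n_per_dose, pnorm(true_slope * (log10(c) - log10(true_lc50))))`,
#' the mechanism the probit fitting machinery assumes.
#'
#' @param config A [synthetic_config()].
#' @return Dose-group tibble (columns `concentration`, `n_exposed`,
#'   `n_dead`).
#' @export
generate_dose_response <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  set.seed(config$seed)
  p <- stats::pnorm(config$true_slope *
                      (log10(config$dose_design) - log10(config$true_lc50)))
  tibble::tibble(
    concentration = config$dose_design,
    n_exposed = config$n_per_dose,
    n_dead = stats::rbinom(length(config$dose_design), config$n_per_dose, p)
  )
}

#' Write a complete synthetic fixture bundle to disk
#'
#' Produces the CSV inputs the rest of the pipeline consumes: `records.csv`
#' (screened-format toxicity records), `doses.csv` (dose-mortality table),
#' `observed.csv` (one held-out species' true median sensitivities across
#' chemicals, for external validation) and `manifest.json` recording the
#' config. The held-out observed values are the per-chemical medians
#' `10^mu`, i.e. the sensitivities of a typical species under the generating
#' model.
#'
#' @param config A [synthetic_config()].
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, a named character vector of the four file paths.
#' @export
make_fixture_bundle <- function(config, out_dir) {
  stopifnot(inherits(config, "synthetic_config"))
  if (!dir.exists(out_dir)) {
    ok <- dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok && !dir.exists(out_dir)) {
      stop("cannot create output directory: ", out_dir, call. = FALSE)
    }
  }
  records <- generate_sensitivity_table(config)
  doses <- generate_dose_response(config)
  observed <- tibble::tibble(chemical = config$chemicals, value = 10^config$mu)
  paths <- c(
    records = file.path(out_dir, "records.csv"),
    doses = file.path(out_dir, "doses.csv"),
    observed = file.path(out_dir, "observed.csv"),
    manifest = file.path(out_dir, "manifest.json")
  )
  write_csv_safe(records, paths[["records"]])
  write_csv_safe(doses, paths[["doses"]])
  write_csv_safe(observed, paths[["observed"]])
  manifest <- unclass(config)
  jsonlite::write_json(manifest, paths[["manifest"]], auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(paths)
}
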