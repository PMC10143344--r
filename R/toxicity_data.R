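#' Default acute-endpoint screening rules
#'
#' The rule table encoding which (taxon group, endpoint, duration) records
#' count as usable acute values: 48 h LC50/EC50 for daphnids and midges,
#' 96 h LC50/EC50 for fish, mollusks, shrimp and other aquatic animals.
#' Duration matching is exact by default; `duration_tol_h` widens it.
#'
#' @param duration_tol_h Tolerance (hours) around the required duration.
#' @return A list with elements `rules` (tibble: taxon_group, duration_h),
#'   `endpoints` (accepted endpoint tags) and `duration_tol_h`.
#' @export
screening_rules <- function(duration_tol_h = 0) {
  list(
    rules = tibble::tibble(
      taxon_group = c("daphnid", "midge", "fish", "mollusk", "shrimp", "other"),
      duration_h = c(48, 48, 96, 96, 96, 96)
    ),
    endpoints = c("LC50", "EC50"),
    duration_tol_h = duration_tol_h
  )
}

validate_toxicity_records <- function(records) {
  req <- c("species", "taxon_group", "chemical", "endpoint", "duration_h", "value")
  missing_cols <- setdiff(req, names(records))
  if (length(missing_cols) > 0) {
    stop("toxicity records missing column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  if (any(!is.finite(records$value) | records$value <= 0)) {
    stop("all toxicity values must be positive and finite", call. = FALSE)
  }
  if (any(!is.finite(records$duration_h) | records$duration_h <= 0)) {
    stop("all durations must be positive and finite", call. = FALSE)
  }
  invisible(records)
}

#' Normalize a species name for matching
#'
#' Trims, collapses internal whitespace and case-folds; binomials typed with
#' varying spacing or capitalisation then compare equal. No taxonomic
#' resolution is attempted.
#'
#' @param species Character vector of species names.
#' @return Normalized character vector.
#' @export
normalize_species <- function(species) {
  out <- trimws(tolower(species))
  gsub("\\s+", " ", out)
}

#' Screen toxicity records against the acute-endpoint rule table
#'
#' Partitions the input into records kept for SMAV aggregation and records
#' rejected with a machine-readable reason: `endpoint_not_acute` (endpoint
#' other than LC50/EC50), `wrong_duration` (duration does not match the
#' taxon's required 48 h or 96 h window), or `prescreen_excluded` when an
#' optional logical `prescreened_ok` column carries expert judgments and is
#' FALSE. Judgment-based exclusions (unsuitable dilution water, insensitive
#' life stages, ...) are not machine-checkable and enter only through
#' `prescreened_ok`.
#'
#' @param records Tibble of toxicity records with columns `species`,
#'   `taxon_group`, `chemical`, `endpoint`, `duration_h`, `value`, and
#'   optionally `native`, `source_id`, `prescreened_ok`.
#' @param rules Rule set from [screening_rules()].
#' @return A list with tibbles `kept` and `rejected` (the latter gains a
#'   `reason` column); together they partition the input rows.
#' @export
screen_records <- function(records, rules = screening_rules()) {
  records <- tibble::as_tibble(records)
  validate_toxicity_records(records)
  unknown <- setdiff(unique(records$taxon_group), rules$rules$taxon_group)
  if (length(unknown) > 0) {
    rows <- which(records$taxon_group %in% unknown)
    stop("unknown taxon_group tag(s) ", paste(unique(unknown), collapse = ", "),
         " in row(s): ", paste(rows, collapse = ", "), call. = FALSE)
  }
  required <- rules$rules$duration_h[match(records$taxon_group, rules$rules$taxon_group)]
  reason <- rep(NA_character_, nrow(records))
  bad_endpoint <- !(records$endpoint %in% rules$endpoints)
  reason[bad_endpoint] <- "endpoint_not_acute"
  bad_duration <- !bad_endpoint &
    abs(records$duration_h - required) > rules$duration_tol_h
  reason[bad_duration] <- "wrong_duration"
  if ("prescreened_ok" %in% names(records)) {
    excluded <- is.na(reason) & !is.na(records$prescreened_ok) & !records$prescreened_ok
    reason[excluded] <- "prescreen_excluded"
  }
  kept <- records[is.na(reason), , drop = FALSE]
  rejected <- records[!is.na(reason), , drop = FALSE]
  rejected$reason <- reason[!is.na(reason)]
  list(kept = kept, rejected = rejected)
}

#' Species mean acute values (SMAVs)
#'
#' Aggregates screened records into one geometric-mean acute value per
#' (species, chemical): `smav = 10^mean(log10(value))`. Species names are
#' matched on their normalized form; the first original spelling is kept for
#' display. A `native` flag, when present, is carried through (a species is
#' native if any of its records says so).
#'
#' @param records Tibble of kept records (see [screen_records()]).
#' @return Tibble with columns `species`, `chemical`, `smav`, `n_records`
#'   and `native` (if present in the input), sorted by chemical then species.
#' @export
compute_smavs <- function(records) {
  records <- tibble::as_tibble(records)
  validate_toxicity_records(records)
  records$.species_key <- normalize_species(records$species)
  has_native <- "native" %in% names(records)
  out <- records |>
    dplyr::group_by(.data$chemical, .data$.species_key) |>
    dplyr::summarise(
      species = dplyr::first(.data$species),
      smav = 10^mean(log10(.data$value)),
      n_records = dplyr::n(),
      native = if (has_native) any(.data$native) else NA,
      .groups = "drop"
    ) |>
    dplyr::arrange(.data$chemical, .data$.species_key) |>
    dplyr::select("species", "chemical", "smav", "n_records", "native")
  if (!has_native) out$native <- NULL
  out
}
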