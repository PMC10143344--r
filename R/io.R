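#' @keywords internal
#' @importFrom rlang .data
"_PACKAGE"

write_csv_safe <- function(x, path) {
  tryCatch(
    utils::write.csv(x, path, row.names = FALSE),
    error = function(e) stop("failed to write ", path, ": ", conditionMessage(e),
                             call. = FALSE)
  )
  invisible(path)
}

# column requirements per schema; numeric columns must be positive where noted
.schemas <- list(
  doses = list(
    required = c("concentration", "n_exposed", "n_dead"),
    numeric = c("concentration", "n_exposed", "n_dead"),
    positive = "concentration"
  ),
  records = list(
    required = c("species", "taxon_group", "chemical", "endpoint",
                 "duration_h", "value"),
    numeric = c("duration_h", "value"),
    positive = c("duration_h", "value")
  ),
  smav = list(
    required = c("species", "chemical", "smav"),
    numeric = "smav",
    positive = "smav"
  ),
  observed = list(
    required = c("chemical", "value"),
    numeric = "value",
    positive = "value"
  )
)

#' Read and validate a pipeline CSV table
#'
#' Reads a UTF-8, comma-separated, headered CSV and validates it against one
#' of the pipeline's schemas (`doses`, `records`, `smav`, `observed`).
#' Row-level problems (non-numeric or non-positive values) are collected and
#' reported together with their line numbers rather than one at a time.
#' Aliased unit-bearing headers (`concentration_ugL`, `value_ugL`) are
#' accepted and renamed.
#'
#' @param path Path to the CSV file.
#' @param schema One of `"doses"`, `"records"`, `"smav"`, `"observed"`.
#' @return A validated tibble (possibly with zero rows, with a warning).
#' @export
read_table <- function(path, schema = c("doses", "records", "smav", "observed")) {
  schema <- match.arg(schema)
  if (!file.exists(path)) stop("input file not found: ", path, call. = FALSE)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE, fileEncoding = "UTF-8")
  names(raw)[names(raw) == "concentration_ugL"] <- "concentration"
  names(raw)[names(raw) == "value_ugL"] <- "value"
  names(raw)[names(raw) == "smav_ugL"] <- "smav"
  spec <- .schemas[[schema]]
  missing_cols <- setdiff(spec$required, names(raw))
  if (length(missing_cols) > 0) {
    stop("'", path, "' (schema ", schema, ") missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if (nrow(raw) == 0) {
    warning("'", path, "' contains a header but no rows", call. = FALSE)
    return(tibble::as_tibble(raw))
  }
  problems <- character(0)
  for (col in spec$numeric) {
    val <- suppressWarnings(as.numeric(raw[[col]]))
    bad <- which(is.na(val) & !is.na(raw[[col]]))
    if (length(bad) > 0) {
      problems <- c(problems, paste0("non-numeric ", col, " at line(s) ",
                                     paste(bad + 1, collapse = ", ")))
    }
    raw[[col]] <- val
  }
  for (col in spec$positive) {
    bad <- which(is.finite(raw[[col]]) & raw[[col]] <= 0)
    if (length(bad) > 0) {
      problems <- c(problems, paste0("non-positive ", col, " at line(s) ",
                                     paste(bad + 1, collapse = ", ")))
    }
  }
  if ("native" %in% names(raw)) raw$native <- as.logical(raw$native)
  if ("prescreened_ok" %in% names(raw)) {
    raw$prescreened_ok <- as.logical(raw$prescreened_ok)
  }
  if (length(problems) > 0) {
    stop("validation failed for '", path, "':\n  ",
         paste(problems, collapse = "\n  "), call. = FALSE)
  }
  tibble::as_tibble(raw)
}

#' Run the full screening-to-validation pipeline
#'
#' Executes screen -> SMAV -> SSD ranking -> pair-model fitting and
#' filtering -> external validation, writing every intermediate table as CSV
#' under `out_dir` and logging record counts at each stage to `message()`
#' (stderr). Stages that cannot run (e.g. no observed table) are skipped.
#'
#' @param records Toxicity-record tibble or path to a records CSV.
#' @param observed Optional observed-values tibble (columns `chemical`,
#'   `value`) or CSV path, enabling external validation.
#' @param out_dir Output directory; created if needed.
#' @param subset `"all"` or `"native"` for the SSD ranking stage.
#' @param alpha Significance threshold for model filtering.
#' @param min_common Minimum common species per chemical pair.
#' @param fold Fold-difference threshold for external validation.
#' @param rules Screening rules (see [screening_rules()]).
#' @return Invisibly, a list with the pipeline tables: `kept`, `rejected`,
#'   `smavs`, `ssd_tables` (one per chemical), `models`, `models_retained`,
#'   and `validation` (NULL when no observed data).
#' @export
run_pipeline <- function(records, observed = NULL, out_dir,
                         subset = c("all", "native"),
                         alpha = 0.05, min_common = 3, fold = 5,
                         rules = screening_rules()) {
  subset <- match.arg(subset)
  if (is.character(records)) records <- read_table(records, "records")
  if (is.character(observed)) observed <- read_table(observed, "observed")
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)

  screened <- screen_records(records, rules = rules)
  message("screen: ", nrow(records), " records in, ",
          nrow(screened$kept), " kept, ", nrow(screened$rejected), " rejected")
  stopifnot(nrow(screened$kept) + nrow(screened$rejected) == nrow(records))
  write_csv_safe(screened$kept, file.path(out_dir, "kept.csv"))
  write_csv_safe(screened$rejected, file.path(out_dir, "rejected.csv"))

  smavs <- compute_smavs(screened$kept)
  message("smav: ", nrow(smavs), " species-chemical entries (",
          length(unique(smavs$chemical)), " chemicals)")
  write_csv_safe(smavs, file.path(out_dir, "smav.csv"))

  ssd_tables <- lapply(unique(smavs$chemical), function(ch) {
    tab <- rank_and_probability(smavs, chemical = ch, subset = subset)
    write_csv_safe(tab, file.path(out_dir, paste0("ssd_", ch, ".csv")))
    tab
  })
  names(ssd_tables) <- unique(smavs$chemical)
  message("ssd: ranked ", length(ssd_tables), " chemical(s), subset = ", subset)

  models <- fit_pair_models(smavs, min_common = min_common)
  retained <- filter_models(models, alpha = alpha)
  message("ice-fit: ", nrow(models), " models fitted, ",
          nrow(retained), " retained at alpha = ", alpha)
  write_csv_safe(models, file.path(out_dir, "models.csv"))
  write_csv_safe(retained, file.path(out_dir, "models_retained.csv"))

  validation <- NULL
  if (!is.null(observed) && nrow(retained) > 0) {
    validation <- validate_models(retained, observed, fold = fold)
    message("ice-validate: ", nrow(validation), " predictions, ",
            sum(validation$within_fold), " within ", fold, "-fold")
    write_csv_safe(validation, file.path(out_dir, "validation.csv"))
  }

  invisible(list(kept = screened$kept, rejected = screened$rejected,
                 smavs = smavs, ssd_tables = ssd_tables, models = models,
                 models_retained = retained, validation = validation))
}
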