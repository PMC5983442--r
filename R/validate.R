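# Column schemas for the pipeline's CSV tables. Each check returns a row
# mask of violations for a structured, row-indexed error report.
table_schemas <- function() {
  num_pos <- function(v) !is.na(v) & v > 0
  num_nonneg <- function(v) !is.na(v) & v >= 0
  pct <- function(v) !is.na(v) & v >= 0 & v <= 100
  frac01 <- function(v) !is.na(v) & v > 0 & v <= 1
  list(
    vials = list(
      required = c("sample_id", "sample_kind", "dry_mass", "total_n",
                   "atom_pct_treatment", "atom_pct_control", "vial_volume",
                   "removed_volume", "tracer_volume", "tracer_enrichment",
                   "duration"),
      checks = list(
        sample_kind = function(v) !is.na(v) & v %in% c("soil", "root"),
        dry_mass = num_pos, total_n = num_pos, duration = num_pos,
        atom_pct_treatment = pct, atom_pct_control = pct,
        vial_volume = num_pos, removed_volume = num_nonneg,
        tracer_volume = num_nonneg, tracer_enrichment = frac01
      )
    ),
    minz_assays = list(
      required = c("sample_id", "nitrate_t0", "ammonium_t0", "nitrate_t28",
                   "ammonium_t28", "duration"),
      checks = list(
        nitrate_t0 = num_nonneg, ammonium_t0 = num_nonneg,
        nitrate_t28 = num_nonneg, ammonium_t28 = num_nonneg,
        duration = num_pos
      )
    ),
    plot_years = list(
      required = c("year", "fertilizer_kg_n", "deposition_kg_n",
                   "n_output_kg", "n_output_se"),
      checks = list(
        year = function(v) !is.na(v) & v > 1900,
        fertilizer_kg_n = num_nonneg,
        n_output_kg = num_nonneg, n_output_se = num_nonneg
      )
    )
  )
}

#' Validate a pipeline table against its schema
#'
#' Checks column presence, numeric typing and row-level invariants for the
#' three pipeline table kinds (`"vials"`, `"minz_assays"`, `"plot_years"`).
#' Units are never coerced; a malformed table produces a structured error
#' report rather than a silent fix.
#'
#' @param table A data frame, or a path to a CSV file (lines starting with
#'   `#` are treated as metadata comments).
#' @param schema One of `"vials"`, `"minz_assays"`, `"plot_years"`.
#' @param stop_on_error Raise an error on violations (default `TRUE`);
#'   otherwise return the error report.
#' @return Invisibly, the validated tibble; or, with
#'   `stop_on_error = FALSE`, a tibble of violations (`row`, `column`,
#'   `message`), empty when the table is valid.
#' @export
validate_table <- function(table, schema = c("vials", "minz_assays",
                                             "plot_years"),
                           stop_on_error = TRUE) {
  schema <- match.arg(schema)
  if (is.character(table)) {
    if (!file.exists(table)) stop("file not found: ", table, call. = FALSE)
    table <- utils::read.csv(table, comment.char = "#")
  }
  table <- tibble::as_tibble(table)
  sch <- table_schemas()[[schema]]
  errors <- list()
  missing_cols <- setdiff(sch$required, names(table))
  for (col in missing_cols) {
    errors[[length(errors) + 1]] <- tibble::tibble(
      row = NA_integer_, column = col, message = "required column missing")
  }
  for (col in names(sch$checks)) {
    if (col %in% missing_cols || is.null(table[[col]])) next
    ok <- sch$checks[[col]](table[[col]])
    bad <- which(!ok)
    if (length(bad)) {
      errors[[length(errors) + 1]] <- tibble::tibble(
        row = bad, column = col,
        message = paste0("invariant violated for '", col, "'"))
    }
  }
  report <- if (length(errors)) dplyr::bind_rows(errors) else
    tibble::tibble(row = integer(), column = character(),
                   message = character())
  if (nrow(report) && stop_on_error) {
    stop("table failed '", schema, "' validation (", nrow(report),
         " problem(s)); first: ", report$column[1],
         if (!is.na(report$row[1])) paste0(" row ", report$row[1]) else "",
         " - ", report$message[1], call. = FALSE)
  }
  if (stop_on_error) invisible(table) else report
}

#' Write a pipeline table with provenance comments
#'
#' Writes a CSV with `#`-prefixed metadata header lines (package version,
#' seed and any extra notes), the format [validate_table()] reads back.
#'
#' @param table Data frame to write.
#' @param path Output path.
#' @param seed Optional seed to record.
#' @param notes Optional character vector of extra comment lines.
#' @return Invisibly, `path`.
#' @export
write_pipeline_csv <- function(table, path, seed = NULL, notes = NULL) {
  header <- c(
    paste0("# written by anfbudget ",
           as.character(utils::packageVersion("anfbudget"))),
    if (!is.null(seed)) paste0("# seed: ", seed),
    if (!is.null(notes)) paste0("# ", notes)
  )
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(header, con)
  utils::write.csv(table, con, row.names = FALSE)
  invisible(path)
}

#' Compare scaled fixation against the mass-balance deficit
#'
#' The study's headline comparison: does the annual fixation input implied
#' by scaled incubation rates agree with the plot nitrogen deficit from the
#' mass balance? Juxtaposes the two estimates, their ratio, and whether
#' their +/-1 SE intervals overlap.
#'
#' @param anf Optional one-row tibble from [annual_soil_anf()] (or the sum
#'   of soil and root scalings); `NULL` marks the fixation section absent.
#' @param ledger A [balance_ledger()]; the deficit is the magnitude of its
#'   mean annual balance (or windowed mean when the ledger has one).
#' @return An `anf_report` list with `anf_estimate`, `anf_se`, `deficit`,
#'   `deficit_se`, `ratio`, `se_overlap`, `anf_available`.
#' @export
run_report <- function(anf, ledger) {
  stopifnot(inherits(ledger, "balance_ledger"))
  deficit <- abs(ledger$window_mean %||% ledger$mean_annual)
  deficit_se <- (ledger$window_mean_se %||% ledger$mean_annual_se)
  if (is.null(anf)) {
    out <- list(anf_available = FALSE, anf_estimate = NA_real_,
                anf_se = NA_real_, deficit = deficit,
                deficit_se = deficit_se, ratio = NA_real_,
                se_overlap = NA)
    return(structure(out, class = "anf_report"))
  }
  est <- anf$estimate_kg_n_ha[1]
  se <- anf$se_kg_n_ha[1]
  overlap <- (est - se) <= (deficit + deficit_se) &&
    (deficit - deficit_se) <= (est + se)
  structure(
    list(anf_available = TRUE, anf_estimate = est, anf_se = se,
         deficit = deficit, deficit_se = deficit_se,
         ratio = est / deficit, se_overlap = overlap),
    class = "anf_report"
  )
}

#' @export
print.anf_report <- function(x, ...) {
  cat("Annual N budget comparison (kg N ha-1 yr-1)\n")
  if (x$anf_available) {
    cat(sprintf("  scaled fixation input: %.1f (SE %.1f)\n",
                x$anf_estimate, x$anf_se))
  } else {
    cat("  scaled fixation input: [absent]\n")
  }
  cat(sprintf("  mass-balance deficit:  %.1f (SE %.1f)\n",
              x$deficit, x$deficit_se))
  if (x$anf_available) {
    cat(sprintf("  fixation/deficit ratio: %.2f (+/-1 SE intervals %s)\n",
                x$ratio,
                if (isTRUE(x$se_overlap)) "overlap" else "do not overlap"))
  }
  invisible(x)
}
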