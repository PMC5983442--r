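#' Harvest nitrogen removal from yield and tissue N
#'
#' @param yield_mg_ha Harvested dry biomass (Mg ha-1).
#' @param tissue_n_pct Tissue N content of the harvested biomass (% N).
#' @return N removed in harvest (kg N ha-1): `yield * tissue_n_pct * 10`.
#' @export
#' @examples
#' n_output_from_yield(10.9, 0.52)
n_output_from_yield <- function(yield_mg_ha, tissue_n_pct) {
  stopifnot(all(yield_mg_ha >= 0), all(tissue_n_pct >= 0))
  yield_mg_ha * tissue_n_pct * 10
}

#' Annual plot nitrogen balance
#'
#' Inputs (fertilizer plus atmospheric deposition) minus outputs (harvest N,
#' plus optional leaching and denitrification losses, both defaulting to 0 —
#' omitting them makes a deficit estimate conservative). Negative values are
#' deficits: N leaving the plot beyond known inputs. Fertilizer and
#' deposition are treated as exact, so the balance SE equals the harvest-N
#' SE.
#'
#' @param fertilizer_kg_n Fertilizer input (kg N ha-1 yr-1).
#' @param deposition_kg_n Atmospheric deposition (kg N ha-1 yr-1).
#' @param n_output_kg Harvest N removal (kg N ha-1 yr-1).
#' @param leaching_kg_n,denitrification_kg_n Optional loss terms
#'   (kg N ha-1 yr-1), default 0.
#' @return Balance (kg N ha-1 yr-1), negative = deficit.
#' @export
annual_balance <- function(fertilizer_kg_n, deposition_kg_n, n_output_kg,
                           leaching_kg_n = 0, denitrification_kg_n = 0) {
  if (any(is.na(n_output_kg))) {
    stop("n_output_kg is required for every record", call. = FALSE)
  }
  fertilizer_kg_n + deposition_kg_n - n_output_kg -
    leaching_kg_n - denitrification_kg_n
}

#' Plot-level nitrogen mass-balance ledger
#'
#' Builds the annual and cumulative N balance for a series of plot-years.
#' Cumulative balance is the sum of annual balances; its SE combines annual
#' SEs in quadrature (inputs carry no variance). The mean annual balance is
#' cumulative / n years with SE(cumulative) / n.
#'
#' Records missing `deposition_kg_n` borrow the mean of the observed years
#' and are flagged in the `deposition_borrowed` column.
#'
#' @param records Data frame with one row per year: `year`,
#'   `fertilizer_kg_n`, `deposition_kg_n`, `n_output_kg`, `n_output_se`
#'   (optional loss columns `leaching_kg_n`, `denitrification_kg_n`).
#'   Years must be unique.
#' @param window Optional numeric vector of years over which an additional
#'   windowed mean balance is computed (e.g. `2013:2015`).
#' @return A `balance_ledger` object: a list with `annual` (tibble of
#'   per-year balances and SEs), `cumulative`, `cumulative_se`,
#'   `mean_annual`, `mean_annual_se`, `mean_deposition`, `n_years`, and
#'   `window_mean`/`window_years` when a window was given.
#' @export
#' @examples
#' ledger <- balance_ledger(table1_mi(treatment = 0), window = 2013:2015)
#' ledger
balance_ledger <- function(records, window = NULL) {
  records <- tibble::as_tibble(records)
  needed <- c("year", "fertilizer_kg_n", "deposition_kg_n", "n_output_kg",
              "n_output_se")
  missing_cols <- setdiff(needed, names(records))
  if (length(missing_cols)) {
    stop("records is missing columns: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  if (anyDuplicated(records$year)) {
    stop("duplicate years in records", call. = FALSE)
  }
  borrowed <- is.na(records$deposition_kg_n)
  if (any(borrowed)) {
    if (all(borrowed)) stop("no deposition values to borrow", call. = FALSE)
    records$deposition_kg_n[borrowed] <-
      mean(records$deposition_kg_n[!borrowed])
  }
  leach <- records[["leaching_kg_n"]] %||% 0
  denit <- records[["denitrification_kg_n"]] %||% 0
  annual <- dplyr::mutate(
    records,
    balance_kg_n = annual_balance(.data$fertilizer_kg_n,
                                  .data$deposition_kg_n,
                                  .data$n_output_kg, leach, denit),
    balance_se = .data$n_output_se,
    deposition_borrowed = borrowed
  )
  annual <- dplyr::arrange(annual, .data$year)
  n <- nrow(annual)
  cumulative <- sum(annual$balance_kg_n)
  cumulative_se <- sqrt(sum(annual$balance_se^2))
  out <- structure(
    list(
      annual = annual,
      cumulative = cumulative,
      cumulative_se = cumulative_se,
      mean_annual = cumulative / n,
      mean_annual_se = cumulative_se / n,
      mean_deposition = mean(annual$deposition_kg_n),
      n_years = n
    ),
    class = "balance_ledger"
  )
  if (!is.null(window)) {
    sel <- annual$year %in% window
    if (!any(sel)) stop("window contains no ledger years", call. = FALSE)
    out$window_years <- annual$year[sel]
    out$window_mean <- mean(annual$balance_kg_n[sel])
    out$window_mean_se <- sqrt(sum(annual$balance_se[sel]^2)) / sum(sel)
  }
  out
}

#' @export
print.balance_ledger <- function(x, digits = 1, ...) {
  cat("Nitrogen mass-balance ledger (", x$n_years, " years)\n", sep = "")
  print(dplyr::select(
    x$annual, "year", "fertilizer_kg_n", "deposition_kg_n",
    "n_output_kg", "balance_kg_n", "balance_se"
  ), n = Inf)
  cat(sprintf("Cumulative balance: %.*f (SE %.*f) kg N ha-1\n",
              digits, x$cumulative, digits, x$cumulative_se))
  cat(sprintf("Mean annual balance: %.*f (SE %.*f) kg N ha-1 yr-1\n",
              digits, x$mean_annual, digits, x$mean_annual_se))
  if (!is.null(x$window_mean)) {
    cat(sprintf("Window %s-%s mean: %.*f kg N ha-1 yr-1\n",
                min(x$window_years), max(x$window_years),
                digits, x$window_mean))
  }
  invisible(x)
}

#' Round ledger output for reporting
#'
#' The ledger computes at full precision; this reporting layer rounds the
#' balance columns to a fixed number of decimals (one, matching common
#' field-study tables) for display or export.
#'
#' @param ledger A `balance_ledger`.
#' @param digits Decimal places (default 1).
#' @return Tibble of rounded per-year balances.
#' @export
ledger_report <- function(ledger, digits = 1) {
  stopifnot(inherits(ledger, "balance_ledger"))
  dplyr::mutate(
    ledger$annual,
    balance_kg_n = round(.data$balance_kg_n, digits),
    balance_se = round(.data$balance_se, digits)
  )
}

#' Packaged plot-year fixture: the MI site mass-balance inputs
#'
#' Seven years (2009-2015) of fertilizer, atmospheric deposition, harvest
#' yield and harvest-N columns for the three sampled treatments (0, 56 and
#' 196 kg N ha-1 yr-1) of the Michigan switchgrass fertilization experiment,
#' transcribed from the published study table. Yield and N output are block
#' means with standard errors.
#'
#' @param treatment Optional fertilizer level filter (0, 56 or 196).
#' @return Tibble of plot-year records with columns `year`,
#'   `fertilizer_kg_n`, `deposition_kg_n`, `yield_mg_ha`, `yield_se`,
#'   `n_output_kg`, `n_output_se`, `balance_published`.
#' @export
#' @examples
#' table1_mi(treatment = 0)
table1_mi <- function(treatment = NULL) {
  path <- system.file("extdata", "table1_mi.csv", package = "anfbudget",
                      mustWork = TRUE)
  tab <- tibble::as_tibble(utils::read.csv(path, comment.char = "#"))
  if (!is.null(treatment)) {
    stopifnot(treatment %in% unique(tab$fertilizer_kg_n))
    tab <- tab[tab$fertilizer_kg_n == treatment, ]
  }
  tab
}
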