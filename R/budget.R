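#' Construct a period-mean carbon budget table
#'
#' A budget table holds the four terms of the global carbon budget identity
#' fossil = growth + ocean + land + imbalance, each as a period-mean flux
#' (Pg C/yr) with an independent 1-sigma uncertainty.
#'
#' @param fossil,growth,ocean,land Period-mean fluxes in Pg C/yr. `fossil` is
#'   net fossil fuel and cement emissions, `growth` the atmospheric CO2
#'   accumulation rate, `ocean` the net ocean sink, `land` the net land sink
#'   (positive values are uptake for the sinks).
#' @param fossil_sigma,growth_sigma,ocean_sigma,land_sigma 1-sigma
#'   uncertainties (Pg C/yr), assumed independent.
#' @param period Optional length-2 integer vector of inclusive start/end
#'   years, stored as metadata.
#'
#' @return A tibble with columns `term`, `mean`, `sigma` and a `period`
#'   attribute.
#' @examples
#' gcp_budget_2000_2019()
#' budget_imbalance(weak_sink_budget_2000_2019())
#' @export
budget_table <- function(fossil, growth, ocean, land,
                         fossil_sigma = 0, growth_sigma = 0,
                         ocean_sigma = 0, land_sigma = 0,
                         period = NULL) {
  means <- c(fossil, growth, ocean, land)
  sigmas <- c(fossil_sigma, growth_sigma, ocean_sigma, land_sigma)
  if (any(!is.finite(means))) abort("All budget terms must be finite.")
  if (any(sigmas < 0)) abort("Uncertainties must be >= 0.")
  out <- tibble::tibble(
    term = c("fossil", "growth", "ocean", "land"),
    mean = means,
    sigma = sigmas
  )
  attr(out, "period") <- period
  out
}

#' Consensus and weak-sink budgets for 2000-2019
#'
#' Convenience constructors for the two published period-mean budgets that
#' the package's ledger operations are exercised against: the Global Carbon
#' Project 2023 consensus budget for 2000-2019, and the revised budget in
#' which the land sink is taken from the satellite stock-change estimate
#' with compensating adjustments to the fossil (-6%) and ocean (+8%) terms.
#'
#' @return A budget table (see [budget_table()]).
#' @export
gcp_budget_2000_2019 <- function() {
  budget_table(8.6, 4.6, 2.5, 1.6, 0.4, 0.1, 0.4, 0.6,
               period = c(2000L, 2019L))
}

#' @rdname gcp_budget_2000_2019
#' @export
weak_sink_budget_2000_2019 <- function() {
  budget_table(8.1, 4.6, 2.7, 0.8, 0.9, 0.1, 0.5, 0.7,
               period = c(2000L, 2019L))
}

term_value <- function(budget, term, col = "mean") {
  assert_columns(budget, c("term", col), "budget")
  i <- match(term, budget$term)
  if (is.na(i)) abort(sprintf("Budget table has no `%s` term.", term))
  budget[[col]][i]
}

#' Read and write year-indexed series and budget tables as CSV
#'
#' All tabular interchange uses plain comma-separated text. Annual series
#' (station records, O2 records, flux series) use the header
#' `year,value,sigma`; period budget tables use `term,mean,sigma`.
#'
#' @param path File path.
#' @param x Tibble to write.
#' @return `read_series_csv()` returns a tibble `year,value,sigma`;
#'   `read_budget_csv()` a budget table.
#' @export
read_series_csv <- function(path) {
  out <- readr::read_csv(path, show_col_types = FALSE)
  assert_columns(out, c("year", "value"), "series file")
  if (!"sigma" %in% names(out)) out$sigma <- 0
  out
}

#' @rdname read_series_csv
#' @export
write_series_csv <- function(x, path) {
  assert_columns(x, c("year", "value"), "x")
  readr::write_csv(x, path)
  invisible(path)
}

#' @rdname read_series_csv
#' @export
read_budget_csv <- function(path) {
  out <- readr::read_csv(path, show_col_types = FALSE)
  assert_columns(out, c("term", "mean", "sigma"), "budget file")
  out
}

#' @rdname read_series_csv
#' @export
write_budget_csv <- function(x, path) {
  assert_columns(x, c("term", "mean", "sigma"), "x")
  readr::write_csv(x, path)
  invisible(path)
}
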