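#' Construct a yearly yield series for one geographical unit
#'
#' A `yield_series` holds one unit's annual yield observations together with
#' an internal time index `T` that is 1 at the first year of the series.
#' All model fitting in the package operates on `T`; calendar years are
#' metadata. Missing observations (years with no usable yield value) are
#' kept explicitly as `NA` so that state-space models can skip their
#' measurement update while regression models drop them.
#'
#' @param unit_id Character scalar naming the geographical unit
#'   (country, *departement*, ...).
#' @param years Integer vector of calendar years, strictly increasing.
#'   Gaps are allowed; the internal index still advances by one per
#'   calendar year, so a gap shows up as missing years, not as a
#'   compressed index.
#' @param yields Numeric vector of yields in t/ha, same length as `years`.
#'   Values must be positive and finite where not `NA`.
#'
#' @return An object of class `yield_series` with fields `unit_id`,
#'   `years`, `yields` and `t_index`.
#' @export
#' @examples
#' s <- yield_series("FR", 1961:1970, 2.5 + 0.13 * (0:9))
#' s$t_index
yield_series <- function(unit_id, years, yields) {
  stopifnot(is.character(unit_id), length(unit_id) == 1L, nzchar(unit_id))
  years <- as.integer(years)
  yields <- as.numeric(yields)
  if (length(years) != length(yields))
    stop("`years` and `yields` must have the same length", call. = FALSE)
  if (length(years) == 0L)
    stop("a yield series needs at least one year", call. = FALSE)
  if (any(diff(years) <= 0L))
    stop("`years` must be strictly increasing for unit ", unit_id,
         call. = FALSE)
  bad <- !is.na(yields) & (!is.finite(yields) | yields <= 0)
  if (any(bad))
    stop("non-positive or non-finite yields for unit ", unit_id,
         " in year(s) ", paste(years[bad], collapse = ", "), call. = FALSE)
  # Expand internal gaps so t_index = year - first_year + 1 holds row-wise.
  full_years <- seq(years[1L], years[length(years)])
  full_yields <- rep(NA_real_, length(full_years))
  full_yields[match(years, full_years)] <- yields
  structure(
    list(unit_id = unit_id,
         years = full_years,
         yields = full_yields,
         t_index = seq_along(full_years)),
    class = "yield_series")
}

#' @export
print.yield_series <- function(x, ...) {
  n_obs <- sum(!is.na(x$yields))
  cat(sprintf("<yield_series> unit %s: %d-%d (M = %d, %d observed)\n",
              x$unit_id, x$years[1L], x$years[length(x$years)],
              length(x$years), n_obs))
  invisible(x)
}

#' @export
length.yield_series <- function(x) length(x$years)

#' @export
as.data.frame.yield_series <- function(x, ...) {
  data.frame(unit_id = x$unit_id, year = x$years, t_index = x$t_index,
             yield = x$yields, stringsAsFactors = FALSE)
}

#' Truncate a series at a final calendar year
#'
#' Used by the rolling-origin evaluation protocol: the returned series
#' contains only years `<= last_year`, with the time index still anchored
#' at the original first year.
#'
#' @param series A [yield_series()].
#' @param last_year Last calendar year to keep.
#' @return A `yield_series` (possibly shorter).
#' @export
truncate_series <- function(series, last_year) {
  stopifnot(inherits(series, "yield_series"))
  keep <- series$years <= last_year
  if (!any(keep))
    stop("truncation at ", last_year, " leaves no data for unit ",
         series$unit_id, call. = FALSE)
  # Drop trailing all-NA years so M reflects real data extent.
  idx <- which(keep)
  obs <- which(keep & !is.na(series$yields))
  if (length(obs) == 0L)
    stop("truncation at ", last_year, " leaves no observed yields for unit ",
         series$unit_id, call. = FALSE)
  idx <- idx[idx <= max(obs)]
  structure(
    list(unit_id = series$unit_id,
         years = series$years[idx],
         yields = series$yields[idx],
         t_index = series$t_index[idx]),
    class = "yield_series")
}

n_observed <- function(series) sum(!is.na(series$yields))

#' Construct a panel of yield series
#'
#' @param series A list of [yield_series()] objects with unique unit ids.
#' @param label Dataset name used in result tables.
#' @return An object of class `yield_panel`.
#' @export
yield_panel <- function(series, label = "panel") {
  stopifnot(is.list(series), length(series) > 0L)
  ok <- vapply(series, inherits, logical(1L), what = "yield_series")
  if (!all(ok)) stop("all elements must be yield_series objects", call. = FALSE)
  ids <- vapply(series, function(s) s$unit_id, character(1L))
  if (anyDuplicated(ids))
    stop("duplicate unit ids: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
  names(series) <- ids
  structure(list(series = series, label = label), class = "yield_panel")
}

#' @export
print.yield_panel <- function(x, ...) {
  cat(sprintf("<yield_panel> '%s': %d units\n", x$label, length(x$series)))
  invisible(x)
}

#' @export
length.yield_panel <- function(x) length(x$series)

#' @export
as.data.frame.yield_panel <- function(x, ...) {
  do.call(rbind, c(lapply(x$series, as.data.frame),
                   list(make.row.names = FALSE)))
}
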