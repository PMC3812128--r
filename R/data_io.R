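#' Column-name dialects for yield panel files
#'
#' A dialect maps the three required logical columns (unit, year, yield)
#' onto the column names actually present in a delimited file. Two presets
#' ship with the package: `"faostat"` (columns `Area`, `Year`, `Value`)
#' and `"agreste"` (columns `departement`, `annee`, `rendement`).
#'
#' @param unit,year,yield Column names in the input file.
#' @return A named list usable as the `dialect` argument of
#'   [read_yield_panel()].
#' @export
#' @examples
#' panel_dialect("country", "yr", "t_ha")
panel_dialect <- function(unit = "Area", year = "Year", yield = "Value") {
  stopifnot(is.character(unit), is.character(year), is.character(yield))
  list(unit = unit, year = year, yield = yield)
}

.dialect_presets <- list(
  faostat = list(unit = "Area", year = "Year", yield = "Value"),
  agreste = list(unit = "departement", year = "annee", yield = "rendement")
)

resolve_dialect <- function(dialect) {
  if (is.character(dialect) && length(dialect) == 1L) {
    if (!dialect %in% names(.dialect_presets))
      stop("unknown dialect preset '", dialect, "'; available: ",
           paste(names(.dialect_presets), collapse = ", "), call. = FALSE)
    return(.dialect_presets[[dialect]])
  }
  stopifnot(is.list(dialect), all(c("unit", "year", "yield") %in% names(dialect)))
  dialect
}

#' Read a long-format yield panel from a delimited text file
#'
#' Expects one row per unit x year with a header line. The delimiter is
#' sniffed from the header (comma, semicolon or tab) unless given. Rows
#' whose yield is non-numeric or non-positive are recorded as missing
#' observations; duplicated (unit, year) pairs are an error.
#'
#' @param path Path to a CSV/TSV file (UTF-8, header required).
#' @param dialect A [panel_dialect()], or a preset name (`"faostat"`,
#'   `"agreste"`).
#' @param sep Field delimiter; `NULL` (default) sniffs it from the header.
#' @param scale Multiplicative factor applied to yields, e.g. `1e-4` to
#'   convert FAOSTAT-native hg/ha into t/ha. Default 1 (values already t/ha).
#' @param label Dataset label for the returned panel; defaults to the
#'   file name.
#' @return A [yield_panel()].
#' @export
read_yield_panel <- function(path, dialect = "faostat", sep = NULL,
                             scale = 1, label = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  dialect <- resolve_dialect(dialect)
  header <- readLines(path, n = 1L)
  if (is.null(sep)) {
    counts <- vapply(c(",", ";", "\t"),
                     function(d) lengths(regmatches(header, gregexpr(d, header, fixed = TRUE))),
                     integer(1L))
    sep <- c(",", ";", "\t")[which.max(counts)]
  }
  raw <- read.table(path, header = TRUE, sep = sep, quote = "\"",
                    colClasses = "character", check.names = FALSE,
                    stringsAsFactors = FALSE, encoding = "UTF-8")
  needed <- unlist(dialect[c("unit", "year", "yield")])
  missing_cols <- setdiff(needed, names(raw))
  if (length(missing_cols) > 0L)
    stop("column(s) not found in ", path, ": ",
         paste(missing_cols, collapse = ", "),
         " (check the dialect mapping)", call. = FALSE)
  unit <- trimws(raw[[dialect$unit]])
  year <- suppressWarnings(as.integer(trimws(raw[[dialect$year]])))
  if (anyNA(year))
    stop("non-integer year value(s) in row(s) ",
         paste(which(is.na(year)), collapse = ", "), call. = FALSE)
  dup <- duplicated(paste(unit, year, sep = "\r"))
  if (any(dup)) {
    offending <- paste0("(", unit[dup], ", ", year[dup], ")")
    stop("duplicated unit-year row(s): ",
         paste(unique(offending), collapse = ", "), call. = FALSE)
  }
  yld <- suppressWarnings(as.numeric(trimws(raw[[dialect$yield]]))) * scale
  yld[!is.na(yld) & (!is.finite(yld) | yld <= 0)] <- NA_real_
  series <- lapply(sort(unique(unit)), function(u) {
    sel <- unit == u
    o <- order(year[sel])
    yield_series(u, year[sel][o], yld[sel][o])
  })
  if (is.null(label)) label <- basename(path)
  yield_panel(series, label = label)
}

#' Write a result table as delimited text
#'
#' Writes any of the package's result data frames as CSV with a header
#' row. Floating-point columns are rendered with a fixed number of
#' decimals so tables round-trip through [utils::read.csv()] within
#' rendering precision.
#'
#' @param table A non-empty data frame.
#' @param path Output file path.
#' @param digits Decimals used for numeric columns (default 6).
#' @return Invisibly, the path written.
#' @export
write_result_table <- function(table, path, digits = 6) {
  stopifnot(is.data.frame(table))
  if (nrow(table) == 0L)
    stop("refusing to write an empty table", call. = FALSE)
  out <- table
  for (j in seq_along(out)) {
    if (is.double(out[[j]])) {
      fmt <- formatC(out[[j]], format = "f", digits = digits)
      fmt[is.na(out[[j]])] <- "NA"
      out[[j]] <- fmt
    }
  }
  ok <- tryCatch({
    write.table(out, path, sep = ",", row.names = FALSE, quote = FALSE,
                fileEncoding = "UTF-8")
    TRUE
  }, error = function(e) e, warning = function(w) w)
  if (!isTRUE(ok))
    stop("could not write ", path, ": ", conditionMessage(ok), call. = FALSE)
  invisible(path)
}

#' Write a panel back out in the default FAOSTAT-like dialect
#'
#' @param panel A [yield_panel()].
#' @param path Output file path.
#' @param digits Decimals for the yield column.
#' @return Invisibly, the path written.
#' @export
write_yield_panel <- function(panel, path, digits = 6) {
  stopifnot(inherits(panel, "yield_panel"))
  df <- as.data.frame(panel)
  df <- df[!is.na(df$yield), c("unit_id", "year", "yield")]
  names(df) <- c("Area", "Year", "Value")
  write_result_table(df, path, digits = digits)
}
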