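# Readers and writers for demographic panel CSVs and the monthly NAO
# table, with a column-mapping layer so published files with arbitrary
# headers can be ingested.

#' Default column mapping for demographic CSVs
#'
#' Maps the canonical record fields to file column names.  The default is
#' the identity mapping for the column set this package writes; supply
#' your own named vector (canonical name = file column) for other files,
#' e.g. for the published Soay sheep table.
#'
#' @param ... Overrides as `canonical = "file_column"` pairs.
#' @return Named character vector.
#' @export
demography_mapping <- function(...) {
  map <- c(id = "id", year = "year", m = "m", a_next = "a_next",
           r_next = "r_next", m_next = "m_next", c_next = "c_next",
           newborn = "newborn")
  over <- c(...)
  map[names(over)] <- over
  map
}

#' Read a demographic panel CSV
#'
#' Reads a comma-separated panel of individual-year records, renames
#' columns through `mapping`, coerces types, converts blank cells to
#' missingness flags, optionally log-transforms raw mass columns, and
#' validates the result.  Malformed rows are reported with their line
#' numbers.
#'
#' @param path CSV file with a header row.
#' @param mapping Named character vector from [demography_mapping()];
#'   entries absent from the file are allowed only for optional columns
#'   (`newborn`).
#' @param log_mass If `TRUE`, apply `log()` to the three mass columns
#'   (for files that record raw body mass rather than its natural log).
#' @return A validated records data frame.
#' @export
read_demography_csv <- function(path, mapping = demography_mapping(),
                                log_mass = FALSE) {
  if (!file.exists(path)) stop("no such file: ", path)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("id", "year", "m", "a_next", "r_next", "m_next", "c_next")
  for (canon in need) {
    if (!mapping[[canon]] %in% names(raw)) {
      stop("column '", mapping[[canon]], "' (mapped to ", canon,
           ") not found in ", path)
    }
  }
  out <- data.frame(
    id = raw[[mapping[["id"]]]],
    year = as.integer(raw[[mapping[["year"]]]]),
    m = as.numeric(raw[[mapping[["m"]]]]),
    a_next = suppressWarnings(as.integer(raw[[mapping[["a_next"]]]])),
    r_next = suppressWarnings(as.integer(raw[[mapping[["r_next"]]]])),
    m_next = suppressWarnings(as.numeric(raw[[mapping[["m_next"]]]])),
    c_next = suppressWarnings(as.numeric(raw[[mapping[["c_next"]]]]))
  )
  if (mapping[["newborn"]] %in% names(raw)) {
    out$newborn <- as.logical(raw[[mapping[["newborn"]]]])
    out$newborn[is.na(out$newborn)] <- FALSE
  } else {
    out$newborn <- rep(FALSE, nrow(out))
  }
  if (log_mass) {
    for (cl in c("m", "m_next", "c_next")) out[[cl]] <- log(out[[cl]])
  }
  if (nrow(out)) validate_records(out)
  attr(out, "source") <- path
  out
}

#' Write a demographic panel CSV
#'
#' Canonical comma-separated dialect: header row, one record per line,
#' blank cells for missing values.  Round-trips through
#' [read_demography_csv()].
#'
#' @param records Records data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_demography_csv <- function(records, path) {
  utils::write.csv(records, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Read a monthly NAO table and form winter (DJFM) means
#'
#' Parses a whitespace-separated year-by-month table (first column the
#' calendar year, then 12 monthly values; any further columns are
#' ignored), treating values at or below `na_below` as missing.  The
#' winter index assigned to year `t` averages December of calendar year
#' `t - 1` with January-March of year `t` (the standard winter-NAO
#' convention; the alignment is recorded in the output attributes).
#'
#' @param path File path.
#' @param na_below Sentinel threshold; monthly values `<=` this are
#'   treated as missing (CRU files use -99.99).
#' @return Named numeric vector of DJFM means (names = years), with
#'   attributes `mean`, `sd` (the fitted summary) and `convention`.
#' @export
read_nao_monthly <- function(path, na_below = -90) {
  if (!file.exists(path)) stop("no such file: ", path)
  tab <- utils::read.table(path, header = FALSE, fill = TRUE)
  if (ncol(tab) < 13) stop("expected a year column plus 12 monthly columns")
  years <- as.integer(tab[[1]])
  monthly <- as.matrix(tab[, 2:13])
  monthly[monthly <= na_below] <- NA
  rownames(monthly) <- years
  out <- numeric(0)
  for (y in years[-1]) {
    dec <- monthly[as.character(y - 1), 12]
    jfm <- monthly[as.character(y), 1:3]
    vals <- c(dec, jfm)
    if (anyNA(vals)) {
      mth <- c("Dec", "Jan", "Feb", "Mar")[which(is.na(vals))[1]]
      stop("missing NAO value (", mth, " of winter ", y, ")")
    }
    out[as.character(y)] <- mean(vals)
  }
  attr(out, "mean") <- mean(out)
  attr(out, "sd") <- sd(out)
  attr(out, "convention") <- "DJFM; December taken from the preceding calendar year"
  out
}
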