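#' @keywords internal
"_PACKAGE"

FAERS_TABLES <- c("DEMO", "DRUG", "REAC", "OUTC", "THER", "INDI", "RPSR")

#' Read one FAERS-style dollar-delimited ASCII table
#'
#' FAERS quarterly archives ship each table (DEMO, DRUG, REAC, OUTC, THER,
#' INDI, RPSR) as `$`-delimited text with a single header line. The format has
#' no quoting or escaping, so each line is split literally on `$`.
#'
#' @param file Path to the file, or a character vector of lines (header first).
#' @param table_id One of `"DEMO"`, `"DRUG"`, `"REAC"`, `"OUTC"`, `"THER"`,
#'   `"INDI"`, `"RPSR"`; used in error messages and attached as an attribute.
#' @param quarter Optional quarter label (e.g. `"2021Q1"`) attached as an
#'   attribute.
#' @return A data.frame of character columns (names lower-cased), one row per
#'   data line, with attributes `table_id` and `quarter`.
#'   Unknown columns are preserved verbatim.
#' @details Every table must carry a `primaryid` column; its absence is an
#'   error naming the table. A line whose field count differs from the header
#'   is an error naming the 1-based line number.
#' @examples
#' txt <- c("primaryid$caseid$fda_dt$sex", "1001$100$20200101$F")
#' read_faers_table(txt, "DEMO")
#' @export
read_faers_table <- function(file, table_id, quarter = NA_character_) {
  table_id <- match.arg(toupper(table_id), FAERS_TABLES)
  lines <- if (length(file) == 1L && file.exists(file)) readLines(file, warn = FALSE) else file
  if (length(lines) == 0L) stop("empty ", table_id, " stream: no header line")
  header <- tolower(strsplit(lines[[1L]], "$", fixed = TRUE)[[1L]])
  if (!"primaryid" %in% header) {
    stop("table ", table_id, ": mandatory column 'primaryid' missing from header")
  }
  body <- lines[-1L]
  body <- body[nzchar(body)]
  ncol <- length(header)
  if (length(body) == 0L) {
    out <- as.data.frame(matrix(character(0), 0L, ncol), stringsAsFactors = FALSE)
    names(out) <- header
  } else {
    # strsplit drops trailing empty fields, so count separators directly
    nfield <- vapply(gregexpr("$", body, fixed = TRUE), function(m) {
      if (m[1L] == -1L) 1L else length(m) + 1L
    }, integer(1L))
    if (any(nfield != ncol)) {
      bad <- which(nfield != ncol)[1L]
      stop("table ", table_id, ": malformed line ", bad + 1L,
           " has ", nfield[bad], " fields, expected ", ncol)
    }
    parts <- strsplit(body, "$", fixed = TRUE)
    parts <- lapply(parts, function(p) c(p, rep("", ncol - length(p))))
    m <- matrix(unlist(parts, use.names = FALSE), ncol = ncol, byrow = TRUE)
    out <- as.data.frame(m, stringsAsFactors = FALSE)
    names(out) <- header
  }
  attr(out, "table_id") <- table_id
  attr(out, "quarter") <- quarter
  out
}

#' Write a table in the FAERS dollar-delimited dialect
#'
#' @param x A data.frame; all columns are written as character.
#' @param file Output path.
#' @return `file`, invisibly.
#' @export
write_faers_table <- function(x, file) {
  header <- paste(names(x), collapse = "$")
  if (nrow(x)) {
    cells <- vapply(x, function(col) {
      col <- as.character(col)
      col[is.na(col)] <- ""
      col
    }, character(nrow(x)))
    if (nrow(x) == 1L) cells <- matrix(cells, nrow = 1L)
    body <- apply(cells, 1L, paste, collapse = "$")
  } else {
    body <- character(0)
  }
  writeLines(c(header, body), file)
  invisible(file)
}

#' Parse FAERS numeric date strings
#'
#' FAERS dates are `YYYYMMDD` integers; partially known dates are shipped as
#' `YYYYMM` or `YYYY`. Partial dates are classified `"incomplete"` (they can
#' not support day-resolution arithmetic such as time-to-onset), empty or
#' unparseable values `"missing"`.
#'
#' @param x Character (or numeric) vector of date strings.
#' @return A data.frame with columns `date` (class `Date`, `NA` unless the
#'   status is `"complete"`) and `status` (`"complete"`, `"incomplete"`,
#'   `"missing"`).
#' @export
parse_faers_date <- function(x) {
  x <- trimws(as.character(x))
  x[is.na(x)] <- ""
  status <- rep("missing", length(x))
  status[grepl("^[0-9]{4}$", x) | grepl("^[0-9]{6}$", x)] <- "incomplete"
  full <- grepl("^[0-9]{8}$", x)
  date <- rep(as.Date(NA), length(x))
  if (any(full)) {
    d <- as.Date(x[full], format = "%Y%m%d")
    # e.g. 20200230 survives the regex but is not a real date
    status[full][!is.na(d)] <- "complete"
    status[full][is.na(d)] <- "missing"
    date[full] <- d
  }
  data.frame(date = date, status = status, stringsAsFactors = FALSE)
}

# AGE_COD vocabulary: factor converting the AGE field to years.
AGE_UNIT_FACTORS <- c(YR = 1, DEC = 10, MON = 1 / 12, WK = 1 / 52.18,
                      DY = 1 / 365.25, HR = 1 / 8766)

#' Convert FAERS age values to years
#'
#' @param age Character or numeric age values.
#' @param age_cod Unit codes (`YR`, `DEC`, `MON`, `WK`, `DY`, `HR`); any other
#'   code (or a non-numeric age) yields `NA`.
#' @return Numeric vector of ages in years.
#' @export
age_to_years <- function(age, age_cod) {
  age_num <- suppressWarnings(as.numeric(age))
  fac <- AGE_UNIT_FACTORS[toupper(trimws(as.character(age_cod)))]
  out <- age_num * as.numeric(fac)
  out[!is.finite(out) | out < 0] <- NA_real_
  unname(out)
}

AGE_GROUP_LEVELS <- c("<18", "18-44", "45-64", ">=65", "unknown")

#' Assign age strata
#'
#' Strata follow the conventional FAERS characteristics-table scheme:
#' `<18`, `18-44`, `45-64`, `>=65`, with `unknown` for missing ages.
#'
#' @param age_years Numeric ages in years (NA = unknown).
#' @return Character vector of stratum labels.
#' @export
age_group <- function(age_years) {
  out <- rep("unknown", length(age_years))
  ok <- !is.na(age_years)
  out[ok & age_years < 18] <- "<18"
  out[ok & age_years >= 18 & age_years < 45] <- "18-44"
  out[ok & age_years >= 45 & age_years < 65] <- "45-64"
  out[ok & age_years >= 65] <- ">=65"
  out
}

REPORTER_MAP <- c(MD = "physician", PH = "pharmacist",
                  OT = "other-health-professional", HP = "other-health-professional",
                  CN = "consumer", LW = "consumer")

SERIOUS_OUTCOMES <- c("DE", "LT", "HO", "DS", "CA", "RI")
OUTCOME_CODES <- c(SERIOUS_OUTCOMES, "OT")
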