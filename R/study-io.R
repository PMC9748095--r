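# Typed CSV ingestion and writing for study tables. Dialect: comma
# separated, UTF-8, header required, empty field = missing (the moderator
# is the only column where missingness is tolerated).

STUDY_BINARY_COLS <- c("male", "white", "firstyear", "arm")
STUDY_COUNT_COLS <- c("baseline_drinks", "drinks_4m", "drinks_15m")

# documented case-insensitive aliases for incoming headers
STUDY_ALIASES <- c(sex = "male", race = "white", first_year = "firstyear",
                   intervention = "arm", bmi = "arm",
                   high_school_drinking = "hs_drink",
                   hs_drinking = "hs_drink",
                   baseline = "baseline_drinks")

#' Read a study table from CSV with validation
#'
#' Reads a per-participant CSV (header required; empty fields are missing)
#' and validates the typed contract: binary columns must be 0/1 with no
#' missing values, counts must be nonnegative, and a missing moderator
#' field is preserved as `NA` — it is never coerced to 0, since 0 encodes
#' "did not drink in high school". Header matching is case-insensitive and
#' a few documented aliases are accepted (e.g. `sex` for `male`,
#' `intervention` for `arm`). Unknown columns are kept with a warning.
#'
#' @param path path to a CSV file.
#' @return Data frame with (at least) `id`, `male`, `white`, `firstyear`,
#'   `hs_drink`, `arm`, `baseline_drinks` and one or both of `drinks_4m`,
#'   `drinks_15m`.
#' @seealso [write_study_csv()]
#' @export
read_study_csv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- utils::read.csv(path, na.strings = "", stringsAsFactors = FALSE)
  nm <- tolower(names(raw))
  nm <- ifelse(nm %in% names(STUDY_ALIASES), STUDY_ALIASES[nm], nm)
  names(raw) <- nm
  known <- c("id", "hs_drink", STUDY_BINARY_COLS, STUDY_COUNT_COLS)
  unknown <- setdiff(nm, known)
  if (length(unknown))
    warning("unknown column(s) kept as-is: ", paste(unknown, collapse = ", "))
  need <- c(STUDY_BINARY_COLS, "hs_drink", "baseline_drinks")
  miss <- setdiff(need, nm)
  if (length(miss))
    stop("required column(s) missing: ", paste(miss, collapse = ", "))
  if (!any(c("drinks_4m", "drinks_15m") %in% nm))
    stop("need at least one follow-up outcome column ",
         "(drinks_4m or drinks_15m)")

  for (col in c(STUDY_BINARY_COLS, "hs_drink")) {
    v <- raw[[col]]
    if (!is.numeric(v))
      stop("column '", col, "' is not numeric")
    bad <- !is.na(v) & !(v %in% c(0, 1))
    if (any(bad))
      stop("column '", col, "' must be 0/1; offending value ", v[bad][1],
           " in data row ", which(bad)[1])
    if (col != "hs_drink" && anyNA(v))
      stop("column '", col, "' has a missing value in data row ",
           which(is.na(v))[1])
    raw[[col]] <- as.integer(v)
  }
  for (col in intersect(STUDY_COUNT_COLS, nm)) {
    v <- raw[[col]]
    if (!is.numeric(v)) stop("column '", col, "' is not numeric")
    if (anyNA(v))
      stop("column '", col, "' has a missing value in data row ",
           which(is.na(v))[1])
    if (any(v < 0))
      stop("column '", col, "' has a negative count in data row ",
           which(v < 0)[1])
  }
  if (!"id" %in% nm) raw$id <- seq_len(nrow(raw))
  ord <- intersect(c("id", "male", "white", "firstyear", "hs_drink", "arm",
                     STUDY_COUNT_COLS), nm)
  raw[, c(ord, setdiff(nm, c(ord, "id"))), drop = FALSE]
}

#' Write a study table to CSV
#'
#' One row per participant, header row, missing moderator written as an
#' empty field. `read_study_csv(write_study_csv(x, f))` is the identity on
#' valid tables.
#'
#' @param table a study data frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_study_csv <- function(table, path) {
  utils::write.csv(table, path, row.names = FALSE, na = "", quote = FALSE)
  invisible(path)
}
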