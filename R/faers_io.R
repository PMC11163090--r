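# Mandatory header columns per FAERS ASCII table kind. Anything beyond these
# is carried through untouched ("opaque extras").
.faers_mandatory <- list(
  DEMO    = c("primaryid", "caseid", "caseversion", "event_dt", "fda_dt",
              "sex", "age", "age_cod"),
  DRUG    = c("primaryid", "drug_seq", "role_cod", "drugname"),
  REAC    = c("primaryid", "pt"),
  OUTC    = c("primaryid", "outc_cod"),
  DELETED = "primaryid"
)

.role_codes <- c("PS", "SS", "C", "I")
.outcome_codes <- c("DE", "DS", "HO", "LT", "OT", "RI", "CA")

#' Normalize a free-text drug name or MedDRA preferred term
#'
#' Comparisons of drug names and preferred terms throughout the package are
#' case-insensitive after trimming leading/trailing whitespace and collapsing
#' internal whitespace runs to a single space.
#'
#' @param x character vector.
#' @return upper-cased, whitespace-normalized character vector.
#' @export
#' @examples
#' normalize_term(c("  Pancreatitis ", "VicTOZa  pen"))
normalize_term <- function(x) {
  x <- toupper(trimws(as.character(x)))
  gsub("[[:space:]]+", " ", x)
}

# Validate a FAERS date string: full yyyymmdd must be a real calendar date;
# partial yyyymm / yyyy forms are accepted (FAERS carries them) as long as
# the components are plausible. Returns the string, or NA when invalid.
.validate_faers_date <- function(x) {
  x <- as.character(x)
  out <- rep(NA_character_, length(x))
  x[!is.na(x) & !nzchar(trimws(x))] <- NA
  ok4 <- !is.na(x) & grepl("^[0-9]{4}$", x)
  ok6 <- !is.na(x) & grepl("^[0-9]{6}$", x)
  ok8 <- !is.na(x) & grepl("^[0-9]{8}$", x)
  yr <- function(v) as.integer(substr(v, 1, 4))
  mo <- function(v) as.integer(substr(v, 5, 6))
  good4 <- ok4 & yr(x) >= 1900 & yr(x) <= 2099
  good6 <- ok6 & yr(x) >= 1900 & yr(x) <= 2099 & mo(x) >= 1 & mo(x) <= 12
  good8 <- ok8
  if (any(ok8)) {
    d <- as.Date(x[ok8], format = "%Y%m%d")
    # as.Date() rolls nothing over; impossible days come back NA
    good8[ok8] <- !is.na(d) & yr(x[ok8]) >= 1900 & yr(x[ok8]) <= 2099
  }
  keep <- good4 | good6 | good8
  out[keep] <- x[keep]
  out
}

#' Derive the calendar year from a FAERS date string
#'
#' @param x character vector of (validated) FAERS date strings.
#' @return integer vector of years; NA where the date is missing.
#' @export
faers_date_year <- function(x) {
  y <- rep(NA_integer_, length(x))
  ok <- !is.na(x) & grepl("^[0-9]{4}", x)
  y[ok] <- as.integer(substr(x[ok], 1, 4))
  y
}

#' Read one "$"-delimited FAERS ASCII table
#'
#' Reads a quarterly FAERS ASCII extract file. The first line must be a
#' "$"-delimited header containing every mandatory column for the table kind
#' (extra columns are preserved as-is). Empty fields become `NA`. For DEMO
#' tables, `event_dt`/`fda_dt` values that are not valid calendar dates are
#' set to `NA` with a single summarising warning; the row itself is retained.
#'
#' @param path path to the file.
#' @param table_kind one of `"DEMO"`, `"DRUG"`, `"REAC"`, `"OUTC"`,
#'   `"DELETED"`.
#' @return a `data.frame` with one row per data line; numeric columns
#'   (`caseversion`, `age`, `drug_seq`) are converted, everything else is
#'   character. The table kind is recorded in attribute `"faers_kind"`.
#' @export
read_ascii_table <- function(path, table_kind) {
  table_kind <- match.arg(toupper(table_kind), names(.faers_mandatory))
  if (!file.exists(path)) stop("no such file: ", path)
  con <- file(path, open = "r", encoding = "latin1")
  on.exit(close(con))
  lines <- readLines(con, warn = FALSE)
  if (!length(lines)) stop("empty file (no header line): ", path)
  header <- tolower(trimws(strsplit(lines[[1]], "$", fixed = TRUE)[[1]]))
  miss <- setdiff(.faers_mandatory[[table_kind]], header)
  if (length(miss)) {
    stop(sprintf("%s table '%s' is missing mandatory column(s): %s",
                 table_kind, path, paste(miss, collapse = ", ")))
  }
  body <- lines[-1]
  body <- body[nzchar(trimws(body))]
  ncol <- length(header)
  if (!length(body)) {
    df <- as.data.frame(stats::setNames(rep(list(character(0)), ncol), header),
                        stringsAsFactors = FALSE)
  } else {
    parts <- strsplit(body, "$", fixed = TRUE)
    lens <- lengths(parts)
    if (any(lens > ncol)) {
      warning(sprintf("%d row(s) in %s had more fields than the header; extras dropped",
                      sum(lens > ncol), basename(path)))
    }
    cols <- lapply(seq_len(ncol), function(j) {
      v <- vapply(parts, function(p) if (j <= length(p)) p[[j]] else NA_character_,
                  character(1))
      v[!is.na(v) & !nzchar(trimws(v))] <- NA_character_
      v
    })
    df <- as.data.frame(stats::setNames(cols, header), stringsAsFactors = FALSE)
  }
  for (nm in intersect(c("caseversion", "age", "drug_seq"), names(df))) {
    df[[nm]] <- suppressWarnings(as.numeric(df[[nm]]))
  }
  if (table_kind == "DEMO") {
    for (nm in intersect(c("event_dt", "fda_dt"), names(df))) {
      before <- df[[nm]]
      df[[nm]] <- .validate_faers_date(before)
      bad <- sum(!is.na(before) & is.na(df[[nm]]))
      if (bad > 0) {
        warning(sprintf("%d unparseable %s value(s) in %s set to missing",
                        bad, nm, basename(path)))
      }
    }
  }
  attr(df, "faers_kind") <- table_kind
  df
}

#' Construct a quarterly FAERS bundle
#'
#' @param demo,drug,reac,outc data.frames as returned by
#'   [read_ascii_table()].
#' @param deleted_primaryids character vector of report-version identifiers
#'   listed as invalid for the quarter.
#' @param quarter_label label such as `"2019Q1"`.
#' @return an object of class `quarter_bundle`.
#' @export
quarter_bundle <- function(demo, drug, reac, outc,
                           deleted_primaryids = character(0),
                           quarter_label = "") {
  b <- structure(
    list(demo = demo, drug = drug, reac = reac, outc = outc,
         deleted_primaryids = unique(as.character(deleted_primaryids)),
         quarter_label = quarter_label),
    class = "quarter_bundle")
  b
}

#' @export
print.quarter_bundle <- function(x, ...) {
  cat(sprintf("FAERS quarter bundle %s: %d DEMO, %d DRUG, %d REAC, %d OUTC rows (%d deleted ids)\n",
              x$quarter_label, nrow(x$demo), nrow(x$drug), nrow(x$reac),
              nrow(x$outc), length(x$deleted_primaryids)))
  invisible(x)
}

#' Remove deleted report versions from every table of a bundle
#'
#' Drops every record whose `primaryid` appears in the bundle's deletion
#' list. Idempotent: applying twice equals applying once.
#'
#' @param bundle a [quarter_bundle()].
#' @return the bundle with deleted primaryids removed from all tables.
#' @export
apply_deletions <- function(bundle) {
  stopifnot(inherits(bundle, "quarter_bundle"))
  del <- bundle$deleted_primaryids
  if (length(del)) {
    for (nm in c("demo", "drug", "reac", "outc")) {
      tab <- bundle[[nm]]
      bundle[[nm]] <- tab[!(tab$primaryid %in% del), , drop = FALSE]
      rownames(bundle[[nm]]) <- NULL
    }
  }
  bundle
}

# Locate a quarter's file for one table kind inside a directory.
.find_quarter_file <- function(directory, kind) {
  pat <- sprintf("^%s.*\\.(txt|TXT)$", kind)
  hits <- list.files(directory, pattern = pat, ignore.case = TRUE,
                     full.names = TRUE)
  if (!length(hits)) return(NA_character_)
  sort(hits)[[1]]
}

#' Load one FAERS quarter from a directory
#'
#' Expects the four core tables (DEMO/DRUG/REAC/OUTC) as files whose names
#' start with the table kind (e.g. `DEMO2019Q1.txt`); a `DELETED*` file is
#' optional. Deletions are applied before the bundle is returned.
#'
#' @param directory directory containing the quarter's ASCII files.
#' @param quarter_label label recorded on the bundle (e.g. `"2019Q1"`).
#' @return a [quarter_bundle()] with deletions already applied.
#' @export
load_quarter_bundle <- function(directory, quarter_label = basename(directory)) {
  if (!dir.exists(directory)) stop("no such directory: ", directory)
  paths <- vapply(c("DEMO", "DRUG", "REAC", "OUTC"),
                  function(k) .find_quarter_file(directory, k), character(1))
  absent <- names(paths)[is.na(paths)]
  if (length(absent)) {
    stop(sprintf("quarter '%s' is missing core table(s): %s",
                 quarter_label, paste(absent, collapse = ", ")))
  }
  tabs <- Map(read_ascii_table, paths, names(paths))
  delpath <- .find_quarter_file(directory, "DELETED")
  deleted <- character(0)
  if (!is.na(delpath)) {
    deleted <- read_ascii_table(delpath, "DELETED")$primaryid
    deleted <- deleted[!is.na(deleted)]
  }
  b <- quarter_bundle(tabs[["DEMO"]], tabs[["DRUG"]], tabs[["REAC"]],
                      tabs[["OUTC"]], deleted, quarter_label)
  apply_deletions(b)
}

# Serialize one data.frame back to the "$" dialect. Native FAERS has no
# escape convention, so embedded "$" in a field cannot round-trip; by default
# it is substituted (stripped) with a warning.
.write_ascii_table <- function(df, path, dollar_sub = "") {
  cols <- names(df)
  if (nrow(df) == 0) {
    con <- file(path, open = "w", encoding = "latin1")
    on.exit(close(con))
    writeLines(paste(cols, collapse = "$"), con)
    return(invisible(NULL))
  }
  mat <- vapply(cols, function(nm) {
    v <- df[[nm]]
    if (is.numeric(v)) {
      v <- ifelse(is.na(v), "",
                  ifelse(v == round(v), format(v, scientific = FALSE, trim = TRUE),
                         format(v, scientific = FALSE, trim = TRUE)))
    } else {
      v <- as.character(v)
      v[is.na(v)] <- ""
    }
    has_dollar <- grepl("$", v, fixed = TRUE)
    if (any(has_dollar)) {
      warning(sprintf("%d value(s) in column '%s' contained the field delimiter '$'; substituted",
                      sum(has_dollar), nm))
      v <- gsub("$", dollar_sub, v, fixed = TRUE)
    }
    v
  }, character(nrow(df)))
  if (is.null(dim(mat))) mat <- matrix(mat, nrow = 1)
  lines <- c(paste(cols, collapse = "$"),
             apply(mat, 1, paste, collapse = "$"))
  con <- file(path, open = "w", encoding = "latin1")
  on.exit(close(con))
  writeLines(lines, con)
  invisible(NULL)
}

#' Write a bundle (or single table) back to the FAERS ASCII dialect
#'
#' Writing then re-reading reproduces the typed representation field for
#' field. Embedded `"$"` characters cannot be represented in the native
#' dialect and are substituted (by default removed) with a warning.
#'
#' @param x a [quarter_bundle()] or a data.frame carrying a `"faers_kind"`
#'   attribute.
#' @param path output directory (for a bundle) or file path (for a table).
#' @param dollar_sub replacement for embedded `"$"` characters.
#' @return invisibly, the path(s) written.
#' @export
write_normalized <- function(x, path, dollar_sub = "") {
  if (inherits(x, "quarter_bundle")) {
    if (!dir.exists(path)) dir.create(path, recursive = TRUE)
    lab <- x$quarter_label
    out <- character(0)
    for (nm in c("demo", "drug", "reac", "outc")) {
      fp <- file.path(path, sprintf("%s%s.txt", toupper(nm), lab))
      .write_ascii_table(x[[nm]], fp, dollar_sub)
      out <- c(out, fp)
    }
    fp <- file.path(path, sprintf("DELETED%s.txt", lab))
    .write_ascii_table(
      data.frame(primaryid = x$deleted_primaryids, stringsAsFactors = FALSE),
      fp, dollar_sub)
    out <- c(out, fp)
    return(invisible(out))
  }
  if (is.data.frame(x)) {
    .write_ascii_table(x, path, dollar_sub)
    return(invisible(path))
  }
  stop("write_normalized() expects a quarter_bundle or a data.frame")
}
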