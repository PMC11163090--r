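# Cohort construction: deduplication, study-window filtering, primary-suspect
# drug-class mapping and target-event flagging.

#' Analysis filter configuration
#'
#' Defaults reproduce the study conditions: reports received 2019--2021,
#' target MedDRA preferred term "pancreatitis" (matched exactly, not as a
#' substring, after normalization), two-stage deduplication.
#'
#' @param year_min,year_max inclusive report-year window.
#' @param target_pt target preferred term(s); a vector acts as a term list
#'   (any exact match flags the event).
#' @param dedup_mode `"two_stage"` (latest case version per case, then
#'   collapse identical (caseid, event_dt, pt) rows) or `"literal"`
#'   (drop exact (primaryid, event_dt, pt) duplicates only; sensitivity
#'   mode).
#' @return an object of class `filter_config`.
#' @export
filter_config <- function(year_min = 2019, year_max = 2021,
                          target_pt = "pancreatitis",
                          dedup_mode = c("two_stage", "literal")) {
  stopifnot(year_min <= year_max, length(target_pt) >= 1,
            all(nzchar(target_pt)))
  structure(list(year_min = as.integer(year_min),
                 year_max = as.integer(year_max),
                 target_pt = as.character(target_pt),
                 dedup_mode = match.arg(dedup_mode)),
            class = "filter_config")
}

# Collapse x into a sorted, unique, "|"-joined key per group g.
# Returns a data.frame(group, key). NA values of x are dropped.
.collapse_by <- function(x, g, sep = "|") {
  keep <- !is.na(x) & !is.na(g)
  x <- as.character(x)[keep]
  g <- as.character(g)[keep]
  if (!length(x)) {
    return(data.frame(group = character(0), key = character(0),
                      stringsAsFactors = FALSE))
  }
  o <- order(g, x, method = "radix")
  x <- x[o]; g <- g[o]
  dup <- duplicated(paste(g, x, sep = "\x01"))
  x <- x[!dup]; g <- g[!dup]
  starts <- which(!duplicated(g))
  ends <- c(starts[-1] - 1L, length(g))
  key <- vapply(seq_along(starts),
                function(i) paste(x[starts[i]:ends[i]], collapse = sep),
                character(1))
  data.frame(group = g[starts], key = key, stringsAsFactors = FALSE)
}

.split_key <- function(key, sep = "|") {
  if (is.na(key) || !nzchar(key)) return(character(0))
  strsplit(key, sep, fixed = TRUE)[[1]]
}

# Convert reported age to years. Units: YR(1), MON(/12), WK(/52),
# DY(/365.25), HR(/8766); DEC (decades) also appears in FAERS and is kept.
# Implausible results (> 120 y) and negative ages become missing.
.age_to_years <- function(age, age_cod) {
  unit <- toupper(trimws(ifelse(is.na(age_cod), "", age_cod)))
  div <- rep(NA_real_, length(age))
  div[unit %in% c("", "YR")] <- 1
  div[unit == "DEC"] <- 0.1
  div[unit == "MON"] <- 12
  div[unit == "WK"] <- 52
  div[unit == "DY"] <- 365.25
  div[unit == "HR"] <- 8766
  yrs <- suppressWarnings(as.numeric(age)) / div
  yrs[is.na(age)] <- NA_real_
  yrs[!is.na(yrs) & (yrs < 0 | yrs > 120)] <- NA_real_
  yrs
}

.age_bin_levels <- c("0-18", "19-30", "31-40", "41-50", "51-60", "61-70", ">70")

.age_bin <- function(age_years) {
  cut(age_years, breaks = c(-Inf, 18, 30, 40, 50, 60, 70, Inf),
      labels = .age_bin_levels, right = TRUE)
}

#' Assemble report-level records from quarter bundles
#'
#' Joins DEMO with the per-report sets of reaction preferred terms,
#' primary-suspect drug names and outcome codes, derives the report year
#' (event date preferred, FDA receipt date as fallback) and converts ages
#' to years. One row per `primaryid`.
#'
#' @param bundles a `quarter_bundle` or list of them (deletions applied).
#' @return a data.frame of class `faers_reports`.
#' @export
assemble_reports <- function(bundles) {
  if (inherits(bundles, "quarter_bundle")) bundles <- list(bundles)
  stopifnot(length(bundles) >= 1,
            all(vapply(bundles, inherits, logical(1), "quarter_bundle")))
  pick <- function(tab, cols) {
    for (nm in cols) {
      if (is.null(tab[[nm]])) tab[[nm]] <- rep(NA_character_, nrow(tab))
    }
    tab[cols]
  }
  demo <- do.call(rbind, lapply(bundles, function(b)
    pick(b$demo, c("primaryid", "caseid", "caseversion", "event_dt", "fda_dt",
                   "sex", "age", "age_cod", "occr_country",
                   "reporter_country"))))
  drug <- do.call(rbind, lapply(bundles, function(b)
    pick(b$drug, c("primaryid", "role_cod", "drugname",
                   if (!is.null(b$drug$prod_ai)) "prod_ai"))))
  reac <- do.call(rbind, lapply(bundles, function(b)
    pick(b$reac, c("primaryid", "pt"))))
  outc <- do.call(rbind, lapply(bundles, function(b)
    pick(b$outc, c("primaryid", "outc_cod"))))

  pt_key <- .collapse_by(normalize_term(reac$pt), reac$primaryid)
  ps <- drug[!is.na(drug$role_cod) & toupper(drug$role_cod) == "PS", ,
             drop = FALSE]
  ps_names <- c(ps$drugname, if (!is.null(ps$prod_ai)) ps$prod_ai)
  ps_ids <- c(ps$primaryid, if (!is.null(ps$prod_ai)) ps$primaryid)
  ps_key <- .collapse_by(normalize_term(ps_names), ps_ids)
  oc <- outc
  oc$outc_cod <- toupper(trimws(oc$outc_cod))
  oc$outc_cod[!(oc$outc_cod %in% .outcome_codes)] <- NA
  outc_key <- .collapse_by(oc$outc_cod, oc$primaryid)

  r <- demo
  r$caseid[is.na(r$caseid)] <- r$primaryid[is.na(r$caseid)]
  r$caseversion[is.na(r$caseversion)] <- 1
  r$pt_key <- pt_key$key[match(r$primaryid, pt_key$group)]
  r$ps_key <- ps_key$key[match(r$primaryid, ps_key$group)]
  r$outcome_key <- outc_key$key[match(r$primaryid, outc_key$group)]
  sex <- toupper(trimws(ifelse(is.na(r$sex), "", r$sex)))
  r$sex <- ifelse(sex %in% c("F", "M"), sex, NA_character_)
  r$age_years <- .age_to_years(r$age, r$age_cod)
  yr_ev <- faers_date_year(r$event_dt)
  yr_fda <- faers_date_year(r$fda_dt)
  r$report_year <- ifelse(!is.na(yr_ev), yr_ev, yr_fda)
  r$year_source <- ifelse(!is.na(yr_ev), "event_dt",
                          ifelse(!is.na(yr_fda), "fda_dt", NA_character_))
  r$country <- ifelse(!is.na(r$occr_country), r$occr_country,
                      r$reporter_country)
  rownames(r) <- NULL
  class(r) <- c("faers_reports", "data.frame")
  r
}

#' Deduplicate report versions and duplicate reports
#'
#' Two-stage default: (i) within each `caseid`, only rows carrying the
#' highest `caseversion` are retained; (ii) among retained rows, those
#' identical on (`caseid`, `event_dt`, set of preferred terms) collapse to
#' one (the largest `primaryid` wins, a deterministic tie-break). The
#' `"literal"` mode instead drops only exact (`primaryid`, `event_dt`, pt)
#' duplicates, for sensitivity analyses. Idempotent and invariant to the
#' order in which bundles were supplied.
#'
#' @param x a `faers_reports` data.frame ([assemble_reports()]) or a list of
#'   `quarter_bundle`s.
#' @param mode `"two_stage"` or `"literal"`.
#' @return deduplicated `faers_reports`, one row per case, with an
#'   `"audit"` attribute counting rows removed at each stage.
#' @export
deduplicate_reports <- function(x, mode = c("two_stage", "literal")) {
  mode <- match.arg(mode)
  r <- if (is.data.frame(x)) x else assemble_reports(x)
  n_in <- nrow(r)
  ev <- ifelse(is.na(r$event_dt), "", r$event_dt)
  ptk <- ifelse(is.na(r$pt_key), "", r$pt_key)
  if (mode == "two_stage") {
    vmax <- stats::ave(r$caseversion, r$caseid, FUN = max)
    keep1 <- r$caseversion == vmax
    n_version <- sum(!keep1)
    r <- r[keep1, , drop = FALSE]
    key <- paste(r$caseid, ev[keep1], ptk[keep1], sep = "\x01")
    o <- order(key, r$primaryid, method = "radix",
               decreasing = c(FALSE, TRUE))
    r <- r[o, , drop = FALSE]
    dup <- duplicated(key[o])
    n_dup <- sum(dup)
    r <- r[!dup, , drop = FALSE]
  } else {
    key <- paste(r$primaryid, ev, ptk, sep = "\x01")
    o <- order(key, method = "radix")
    r <- r[o, , drop = FALSE]
    dup <- duplicated(key[o])
    n_version <- 0L
    n_dup <- sum(dup)
    r <- r[!dup, , drop = FALSE]
  }
  r <- r[order(r$caseid, r$primaryid, method = "radix"), , drop = FALSE]
  rownames(r) <- NULL
  attr(r, "audit") <- list(n_input = n_in,
                           n_removed_versions = as.integer(n_version),
                           n_removed_duplicates = as.integer(n_dup))
  class(r) <- c("faers_reports", "data.frame")
  r
}

#' Restrict reports to the study window
#'
#' Keeps reports whose derived report year falls inside the configured
#' window. Reports with no derivable year (both dates missing or invalid)
#' are excluded and tallied separately: the window is an inclusion
#' criterion, so an undatable report cannot satisfy it.
#'
#' @param records a `faers_reports` data.frame with `report_year`.
#' @param config a [filter_config()].
#' @return filtered records with an `"audit"` attribute
#'   (`n_out_of_window`, `n_missing_year`).
#' @export
filter_window <- function(records, config = filter_config()) {
  stopifnot(inherits(config, "filter_config"))
  yr <- records$report_year
  missing_yr <- is.na(yr)
  inside <- !missing_yr & yr >= config$year_min & yr <= config$year_max
  out <- records[inside, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "audit") <- list(
    n_out_of_window = as.integer(sum(!inside & !missing_yr)),
    n_missing_year = as.integer(sum(missing_yr)))
  class(out) <- c("faers_reports", "data.frame")
  out
}

#' Flag the target adverse event in a report's preferred-term set
#'
#' Exact (normalized) matching: `"pancreatitis acute"` does not match the
#' target `"pancreatitis"`. Supplying several terms in `target_pt` turns on
#' term-list matching (any exact hit flags the report).
#'
#' @param pts character vector of a report's preferred terms.
#' @param target_pt target term or term list.
#' @return logical scalar.
#' @export
#' @examples
#' flag_event(c("Pancreatitis", "Nausea"), "pancreatitis")   # TRUE
#' flag_event("Pancreatitis acute", "pancreatitis")          # FALSE
flag_event <- function(pts, target_pt) {
  any(normalize_term(pts) %in% normalize_term(target_pt))
}

# Vectorized event flag over "|"-joined normalized pt keys.
.flag_event_key <- function(pt_key, target_pt) {
  tgt <- normalize_term(target_pt)
  vapply(pt_key, function(k) any(.split_key(k) %in% tgt), logical(1),
         USE.NAMES = FALSE)
}

# Vectorized class mapping over "|"-joined normalized PS-drug keys.
# Returns list(classes_key, generics_key).
.map_classes_key <- function(ps_key, class_map) {
  idx <- which(!is.na(ps_key) & nzchar(ps_key))
  if (!length(idx)) {
    return(list(classes = rep("", length(ps_key)),
                generics = rep("", length(ps_key))))
  }
  parts <- strsplit(ps_key[idx], "|", fixed = TRUE)
  rid <- rep(idx, lengths(parts))
  nm <- unlist(parts, use.names = FALSE)
  m <- match(nm, class_map$synonym_norm)
  classes <- .collapse_by(class_map$class_name[m], rid)
  gen <- ifelse(is.na(m), nm, class_map$drug_norm[m])
  generics <- .collapse_by(gen, rid)
  ck <- rep("", length(ps_key))
  gk <- rep("", length(ps_key))
  ck[as.integer(classes$group)] <- classes$key
  gk[as.integer(generics$group)] <- generics$key
  list(classes = ck, generics = gk)
}

#' Build the analysis cohort
#'
#' Composition of [deduplicate_reports()], [filter_window()],
#' primary-suspect drug-class mapping and target-event flagging, with an
#' audit trail of how many reports each step removed. One row per case.
#'
#' @param bundles `quarter_bundle` list (deletions applied) or an assembled
#'   `faers_reports` data.frame.
#' @param config a [filter_config()].
#' @param class_map a `drug_class_map` ([default_class_map()] by default).
#' @return data.frame of class `faers_cohort` with columns `caseid`,
#'   `primaryid`, `event_flag`, `ps_drugs`, `drug_classes` ("|"-joined
#'   sets), `sex`, `age_years`, `age_bin`, `report_year`, `country`,
#'   `outcome_codes`; attributes `audit`, `target_pt`, `config`.
#' @export
build_cohort <- function(bundles, config = filter_config(),
                         class_map = default_class_map()) {
  stopifnot(inherits(config, "filter_config"))
  if (!inherits(class_map, "drug_class_map")) {
    stop("cohort_builder: class_map must be a drug_class_map (see default_class_map())")
  }
  if (nrow(class_map) == 0) stop("cohort_builder: empty drug-class map")
  dd <- deduplicate_reports(bundles,
                            mode = if (config$dedup_mode == "literal")
                              "literal" else "two_stage")
  a1 <- attr(dd, "audit")
  fw <- filter_window(dd, config)
  a2 <- attr(fw, "audit")
  mapped <- .map_classes_key(fw$ps_key, class_map)
  cohort <- data.frame(
    caseid = fw$caseid,
    primaryid = fw$primaryid,
    event_flag = .flag_event_key(fw$pt_key, config$target_pt),
    ps_drugs = ifelse(is.na(fw$ps_key), "", fw$ps_key),
    ps_generics = mapped$generics,
    drug_classes = mapped$classes,
    sex = fw$sex,
    age_years = fw$age_years,
    age_bin = as.character(.age_bin(fw$age_years)),
    report_year = fw$report_year,
    country = fw$country,
    outcome_codes = ifelse(is.na(fw$outcome_key), "", fw$outcome_key),
    stringsAsFactors = FALSE)
  n_multi <- sum(vapply(cohort$drug_classes,
                        function(k) length(.split_key(k)) > 1, logical(1),
                        USE.NAMES = FALSE))
  audit <- list(n_input = a1$n_input,
                n_removed_versions = a1$n_removed_versions,
                n_removed_duplicates = a1$n_removed_duplicates,
                n_removed_out_of_window = a2$n_out_of_window,
                n_removed_missing_year = a2$n_missing_year,
                n_cohort = nrow(cohort),
                n_event_cases = sum(cohort$event_flag),
                n_multiclass = as.integer(n_multi))
  structure(cohort, audit = audit, target_pt = config$target_pt,
            config = config, class = c("faers_cohort", "data.frame"))
}

#' @export
print.faers_cohort <- function(x, ...) {
  a <- attr(x, "audit")
  cat(sprintf("FAERS analysis cohort: %d cases (%d with the target event)\n",
              nrow(x), sum(x$event_flag)))
  if (!is.null(a)) {
    cat(sprintf("  from %d report versions: -%d superseded versions, -%d duplicates,\n",
                a$n_input, a$n_removed_versions, a$n_removed_duplicates))
    cat(sprintf("  -%d outside the %s window, -%d with no derivable year\n",
                a$n_removed_out_of_window,
                paste(attr(x, "config")$year_min, attr(x, "config")$year_max,
                      sep = "-"),
                a$n_removed_missing_year))
  }
  invisible(x)
}

#' Tabulate the primary-suspect drug by event grid
#'
#' Deduplicates and window-filters the reports, then counts unique cases per
#' (drug, preferred term) pair, with drug names resolved to generics through
#' the class map when one is supplied. A case with several PS drugs or
#' several PTs contributes one count to each pair (the one-row-per-pair
#' disproportionality convention).
#'
#' @param bundles bundles or assembled reports.
#' @param config a [filter_config()].
#' @param class_map optional `drug_class_map` for brand-to-generic
#'   resolution.
#' @return data.frame of class `pair_grid` with columns `drug`, `event`,
#'   `n`, and attribute `n_reports` (cohort size after filtering).
#' @export
pair_count_grid <- function(bundles, config = filter_config(),
                            class_map = NULL) {
  dd <- deduplicate_reports(bundles,
                            mode = if (config$dedup_mode == "literal")
                              "literal" else "two_stage")
  fw <- filter_window(dd, config)
  keep <- !is.na(fw$ps_key) & nzchar(fw$ps_key) &
    !is.na(fw$pt_key) & nzchar(fw$pt_key)
  fw <- fw[keep, , drop = FALSE]
  if (!nrow(fw)) {
    g <- data.frame(drug = character(0), event = character(0),
                    n = integer(0), stringsAsFactors = FALSE)
    return(structure(g, n_reports = 0L, class = c("pair_grid", "data.frame")))
  }
  dparts <- strsplit(fw$ps_key, "|", fixed = TRUE)
  if (!is.null(class_map)) {
    dparts <- lapply(dparts, .resolve_generic, class_map = class_map)
  }
  eparts <- strsplit(fw$pt_key, "|", fixed = TRUE)
  nd <- lengths(dparts); ne <- lengths(eparts)
  rid <- rep(seq_len(nrow(fw)), nd * ne)
  drug <- unlist(Map(function(d, e) rep(d, each = length(e)), dparts, eparts),
                 use.names = FALSE)
  event <- unlist(Map(function(d, e) rep(e, times = length(d)), dparts, eparts),
                  use.names = FALSE)
  key <- paste(rid, drug, event, sep = "\x01")
  keep2 <- !duplicated(key)
  tab <- table(paste(drug[keep2], event[keep2], sep = "\x01"))
  de <- strsplit(names(tab), "\x01", fixed = TRUE)
  g <- data.frame(drug = vapply(de, `[`, character(1), 1),
                  event = vapply(de, `[`, character(1), 2),
                  n = as.integer(tab), stringsAsFactors = FALSE)
  g <- g[order(g$drug, g$event, method = "radix"), , drop = FALSE]
  rownames(g) <- NULL
  structure(g, n_reports = nrow(fw), class = c("pair_grid", "data.frame"))
}
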