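# Drug-class dictionary: maps generic and US brand names onto the three
# antidiabetic classes compared as exposures. User-overridable via
# read_class_map(); each synonym resolves to a generic so that within-class
# (drug-level) comparisons can group brands under their generic.

#' Default antidiabetic drug-class dictionary
#'
#' Ships the three studied classes — GLP-1 receptor agonists, DPP-4
#' inhibitors and SGLT2 inhibitors — with their generic members and common
#' US brand names. Exenatide is marked as the within-class reference drug
#' for the GLP-1 RA class. The dictionary is a convenience default;
#' real analyses should review and extend it via [read_class_map()].
#'
#' @return a `data.frame` of class `drug_class_map` with columns
#'   `class_name`, `drug_name` (generic), `synonym` (name as it may appear
#'   in a report) and `is_reference`.
#' @export
#' @examples
#' head(default_class_map())
default_class_map <- function() {
  glp1 <- list(
    exenatide   = c("exenatide", "byetta", "bydureon", "bydureon bcise"),
    liraglutide = c("liraglutide", "victoza", "saxenda"),
    dulaglutide = c("dulaglutide", "trulicity"),
    semaglutide = c("semaglutide", "ozempic", "rybelsus", "wegovy"),
    albiglutide = c("albiglutide", "tanzeum"),
    lixisenatide = c("lixisenatide", "adlyxin"))
  dpp4 <- list(
    sitagliptin  = c("sitagliptin", "januvia"),
    saxagliptin  = c("saxagliptin", "onglyza"),
    linagliptin  = c("linagliptin", "tradjenta"),
    alogliptin   = c("alogliptin", "nesina"),
    vildagliptin = c("vildagliptin", "galvus"))
  sglt2 <- list(
    empagliflozin = c("empagliflozin", "jardiance"),
    canagliflozin = c("canagliflozin", "invokana"),
    dapagliflozin = c("dapagliflozin", "farxiga"),
    ertugliflozin = c("ertugliflozin", "steglatro"))
  build <- function(class_name, members, reference = NULL) {
    do.call(rbind, lapply(names(members), function(g) {
      data.frame(class_name = class_name, drug_name = g,
                 synonym = members[[g]],
                 is_reference = identical(g, reference),
                 stringsAsFactors = FALSE)
    }))
  }
  m <- rbind(build("GLP-1 RA", glp1, reference = "exenatide"),
             build("DPP-4 inhibitor", dpp4),
             build("SGLT2 inhibitor", sglt2))
  new_class_map(m)
}

#' Construct / validate a drug-class map
#'
#' @param entries data.frame with columns `class_name`, `drug_name`,
#'   `synonym` (optional; defaults to `drug_name`) and `is_reference`
#'   (optional; defaults to `FALSE`).
#' @return a validated `drug_class_map`.
#' @export
new_class_map <- function(entries) {
  stopifnot(is.data.frame(entries),
            all(c("class_name", "drug_name") %in% names(entries)))
  if (is.null(entries$synonym)) entries$synonym <- entries$drug_name
  if (is.null(entries$is_reference)) entries$is_reference <- FALSE
  entries$is_reference <- as.logical(entries$is_reference)
  entries$synonym_norm <- normalize_term(entries$synonym)
  entries$drug_norm <- normalize_term(entries$drug_name)
  # a synonym must resolve to a single class
  cls <- tapply(entries$class_name, entries$synonym_norm,
                function(v) length(unique(v)))
  if (any(cls > 1)) {
    stop("drug name(s) mapped to more than one class: ",
         paste(names(cls)[cls > 1], collapse = ", "))
  }
  # at most one reference drug per class
  refs <- entries[entries$is_reference, c("class_name", "drug_norm")]
  nref <- tapply(refs$drug_norm, refs$class_name,
                 function(v) length(unique(v)))
  if (length(nref) && any(nref > 1)) {
    stop("more than one reference drug in class: ",
         paste(names(nref)[nref > 1], collapse = ", "))
  }
  rownames(entries) <- NULL
  class(entries) <- c("drug_class_map", "data.frame")
  entries
}

#' Read a drug-class dictionary from a delimited file
#'
#' Accepts a tab- or comma-delimited file with a header. Three columns
#' (`class_name`, `drug_name`, `is_reference`) are the minimal form; an
#' optional fourth column `synonym` lets brand names resolve to a generic
#' (when absent, `drug_name` is its own synonym).
#'
#' @param path file path.
#' @return a `drug_class_map`.
#' @export
read_class_map <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  first <- readLines(path, n = 1L)
  sep <- if (grepl("\t", first)) "\t" else ","
  df <- utils::read.table(path, sep = sep, header = TRUE,
                          stringsAsFactors = FALSE, quote = "\"")
  new_class_map(df)
}

#' Map primary-suspect drug names onto drug classes
#'
#' Returns the set of classes whose member names (generic or brand) match
#' any of the supplied drug names after normalization. Matching is exact on
#' the normalized string; role filtering (primary suspect only) is the
#' caller's responsibility and is applied by [build_cohort()].
#'
#' @param drugs character vector of drug names (and/or active ingredients).
#' @param class_map a `drug_class_map`.
#' @return character vector of class names (possibly empty).
#' @export
#' @examples
#' map_drug_classes(c("VICTOZA", "aspirin"), default_class_map())
map_drug_classes <- function(drugs, class_map) {
  stopifnot(inherits(class_map, "drug_class_map"))
  if (nrow(class_map) == 0) stop("empty drug-class map")
  hits <- class_map$synonym_norm %in% normalize_term(drugs)
  sort(unique(class_map$class_name[hits]))
}

# Resolve drug names to generics (drug_name) via the map; names not in the
# map resolve to themselves (normalized).
.resolve_generic <- function(drugs, class_map) {
  norm <- normalize_term(drugs)
  idx <- match(norm, class_map$synonym_norm)
  out <- ifelse(is.na(idx), norm, class_map$drug_norm[idx])
  unique(out)
}

#' Reference drug of a class
#'
#' @param class_map a `drug_class_map`.
#' @param class_name class to look in.
#' @return normalized generic name of the reference drug, or `NA` if none
#'   is marked.
#' @export
reference_drug <- function(class_map, class_name) {
  sel <- class_map$is_reference & class_map$class_name == class_name
  if (!any(sel)) return(NA_character_)
  unique(class_map$drug_norm[sel])[[1]]
}
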