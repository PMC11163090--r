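# End-to-end pipeline: quarters on disk -> cohort -> class-level indices,
# within-class ROR against the reference drug, descriptives, audit log and
# run manifest, all as deterministic delimited text outputs.

.write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "")
  invisible(path)
}

.stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop(sprintf("%s: %s", name, conditionMessage(e)), call. = FALSE)
  })
}

#' Run the full signal-detection pipeline
#'
#' Loads the quarterly bundles under `data_dir` (one subdirectory per
#' quarter, or the files directly in `data_dir`), builds the deduplicated
#' windowed cohort, fits the gamma-mixture prior on the primary-suspect
#' drug-by-event grid, computes all four indices for each drug class and
#' each within-class drug against the class reference drug, applies the
#' signal rule and writes the report tables to `out_dir`.
#'
#' Output files: `audit.tsv`, `cohort.tsv`, `class_signals.tsv`,
#' `within_class_ror.tsv`, `descriptives.tsv`, `prior.txt`,
#' `manifest.txt`. Reruns on the same inputs produce byte-identical files.
#'
#' @param data_dir directory holding the quarterly ASCII files.
#' @param out_dir output directory (created if needed).
#' @param config a [filter_config()].
#' @param class_map a `drug_class_map`.
#' @param criteria a [signal_criteria()].
#' @param exposures class names to evaluate (defaults to every class in
#'   `class_map`); a name not present in the map aborts in the
#'   cohort-building stage.
#' @return invisibly, a list with `cohort`, `grid`, `prior`,
#'   `class_results`, `within_class`, `descriptives`, `paths`.
#' @export
run_pipeline <- function(data_dir, out_dir, config = filter_config(),
                         class_map = default_class_map(),
                         criteria = signal_criteria(),
                         exposures = NULL) {
  bundles <- .stage("faers_io", {
    subs <- list.dirs(data_dir, recursive = FALSE)
    if (!length(subs)) subs <- data_dir
    lapply(sort(subs), load_quarter_bundle)
  })
  cohort <- .stage("cohort_builder", {
    if (is.null(exposures)) {
      exposures <- unique(class_map$class_name)
    } else {
      unknown <- setdiff(normalize_term(exposures),
                         normalize_term(unique(class_map$class_name)))
      if (length(unknown)) {
        stop("unknown class name(s) in config: ",
             paste(unknown, collapse = ", "))
      }
      exposures <- unique(class_map$class_name)[
        normalize_term(unique(class_map$class_name)) %in%
          normalize_term(exposures)]
    }
    build_cohort(bundles, config, class_map)
  })
  grid <- .stage("contingency_stats", {
    pair_count_grid(bundles, config, class_map = class_map)
  })
  prior <- .stage("bayes_signal", fit_gps_prior(expected_counts(grid)))
  class_results <- .stage("signal_triage", {
    rows <- lapply(exposures, function(cl) {
      tab <- build_contingency(cohort, cl, class_map = class_map)
      fr <- ror(tab); fp <- prr(tab)
      e <- (tab$a + tab$b) * (tab$a + tab$c) / max(1, nrow(cohort))
      bm <- if (e > 0) bayes_metrics(tab$a, e, prior, quantiles = TRUE)
        else data.frame(ebgm = NA, eb05 = NA, eb95 = NA, ic = NA,
                        ic025 = NA, ic975 = NA)
      dec <- if (e > 0)
        evaluate_signal(list(ror = fr$ror, ror_lo = fr$ror_lo, prr = fp$prr,
                             ebgm = bm$ebgm, ic = bm$ic),
                        n = tab$a, criteria)
      else list(pass_ror = NA, pass_prr = NA, pass_ebgm = NA,
                pass_ic = NA, is_signal = NA)
      data.frame(class = cl, n = tab$a, a = tab$a, b = tab$b, c = tab$c,
                 d = tab$d, e = round(e, 4),
                 ror = round(fr$ror, 2), ror_lo = round(fr$ror_lo, 2),
                 ror_hi = round(fr$ror_hi, 2),
                 prr = round(fp$prr, 2), prr_lo = round(fp$prr_lo, 2),
                 prr_hi = round(fp$prr_hi, 2),
                 ebgm = round(bm$ebgm, 2), eb05 = round(bm$eb05, 2),
                 eb95 = round(bm$eb95, 2),
                 ic = round(bm$ic, 2), ic025 = round(bm$ic025, 2),
                 ic975 = round(bm$ic975, 2),
                 correction_applied = fr$correction_applied,
                 pass_ror = dec$pass_ror, pass_prr = dec$pass_prr,
                 pass_ebgm = dec$pass_ebgm, pass_ic = dec$pass_ic,
                 is_signal = dec$is_signal, stringsAsFactors = FALSE)
    })
    do.call(rbind, rows)
  })
  within_class <- .stage("signal_triage", {
    rows <- list()
    for (cl in exposures) {
      refd <- reference_drug(class_map, cl)
      if (is.na(refd)) next
      members <- setdiff(unique(class_map$drug_norm[
        class_map$class_name == cl]), refd)
      for (dr in sort(members)) {
        res <- tryCatch(pairwise_ror(cohort, dr, refd), error = function(e) NULL)
        if (is.null(res)) next
        rows[[length(rows) + 1L]] <- data.frame(
          class = cl, drug = dr, reference = refd, n = res$n,
          ror = round(res$ror, 2), ror_lo = round(res$ror_lo, 2),
          ror_hi = round(res$ror_hi, 2),
          correction_applied = res$correction_applied,
          stringsAsFactors = FALSE)
      }
    }
    if (length(rows)) do.call(rbind, rows)
    else data.frame(class = character(0), drug = character(0),
                    reference = character(0), n = integer(0),
                    ror = numeric(0), ror_lo = numeric(0),
                    ror_hi = numeric(0),
                    correction_applied = logical(0))
  })
  descriptives <- .stage("signal_triage", {
    rows <- lapply(exposures, function(cl) {
      s <- summarize_descriptives(cohort, cl)
      long <- rbind(
        data.frame(section = "sex", level = s$by_sex$sex,
                   count = s$by_sex$count, percent = s$by_sex$percent),
        data.frame(section = "sex", level = "missing",
                   count = s$sex_missing, percent = NA_real_),
        data.frame(section = "age_bin", level = s$by_age_bin[[1]],
                   count = s$by_age_bin$count, percent = NA_real_),
        data.frame(section = "year", level = as.character(s$by_year[[1]]),
                   count = s$by_year$count, percent = NA_real_),
        data.frame(section = "country", level = as.character(s$by_country[[1]]),
                   count = s$by_country$count, percent = NA_real_),
        data.frame(section = "outcome", level = s$by_outcome$code,
                   count = s$by_outcome$count, percent = NA_real_),
        data.frame(section = "serious", level = "serious",
                   count = s$serious_count, percent = s$serious_percent))
      cbind(class = cl, long, stringsAsFactors = FALSE)
    })
    do.call(rbind, rows)
  })
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  audit <- attr(cohort, "audit")
  paths <- c(
    audit = .write_tsv(data.frame(step = names(audit),
                                  count = unlist(audit)),
                       file.path(out_dir, "audit.tsv")),
    cohort = .write_tsv(as.data.frame(cohort),
                        file.path(out_dir, "cohort.tsv")),
    class_signals = .write_tsv(class_results,
                               file.path(out_dir, "class_signals.tsv")),
    within_class = .write_tsv(within_class,
                              file.path(out_dir, "within_class_ror.tsv")),
    descriptives = .write_tsv(descriptives,
                              file.path(out_dir, "descriptives.tsv")),
    prior = write_gps_prior(prior, file.path(out_dir, "prior.txt")))
  manifest <- c(
    sprintf("pvsignal_version\t%s",
            as.character(utils::packageVersion("pvsignal"))),
    sprintf("data_dir\t%s", data_dir),
    sprintf("quarters\t%s",
            paste(vapply(bundles, `[[`, character(1), "quarter_label"),
                  collapse = ",")),
    sprintf("year_window\t%d-%d", config$year_min, config$year_max),
    sprintf("target_pt\t%s", paste(config$target_pt, collapse = "|")),
    sprintf("dedup_mode\t%s", config$dedup_mode),
    sprintf("exposures\t%s", paste(exposures, collapse = ",")),
    sprintf("criteria\tror>%g n>=%d; prr>%g n>=%d; ebgm>=%g; ic>%g n>=%d; ror_rule=%s",
            criteria$ror_threshold, criteria$min_n_ror,
            criteria$prr_threshold, criteria$min_n_prr,
            criteria$ebgm_threshold, criteria$ic_threshold,
            criteria$min_n_bayes, criteria$ror_rule))
  writeLines(manifest, file.path(out_dir, "manifest.txt"))
  paths <- c(paths, manifest = file.path(out_dir, "manifest.txt"))
  invisible(list(cohort = cohort, grid = grid, prior = prior,
                 class_results = class_results, within_class = within_class,
                 descriptives = descriptives, paths = paths))
}
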