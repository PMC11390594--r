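#' Read the three-table comparison database
#'
#' The database is exchanged as three UTF-8 CSV tables with "." decimals:
#' `studies` (one row per study: `accession`, `inducers`, `control_types`,
#' `cell_lines`, `timepoints`, `platform`, with multi-valued fields
#' ";"-separated and timepoints encoded `value:unit`), `comparisons` (one
#' row per senescent-vs-control contrast: `comparison_id`,
#' `study_accession`, `inducer`, `control_type`, `cell_line`, `time_value`,
#' `time_unit`, `intervention`, `platform`), and `genestats` (one row per
#' comparison x gene: `comparison_id`, `gene`, `logFC`, `p`).
#'
#' All referential-integrity and vocabulary invariants are validated on
#' load; see [validate_database()] for the rules.
#'
#' @param study_path,comparison_path,genestats_path CSV file paths.
#' @param quiet Suppress the row-count message.
#' @return A list with elements `studies`, `comparisons`, `genestats`
#'   (data frames), of class `"senodb"`.
#' @export
load_database <- function(study_path, comparison_path, genestats_path,
                          quiet = FALSE) {
  rd <- function(p) utils::read.csv(p, stringsAsFactors = FALSE,
                                    colClasses = NA, check.names = TRUE)
  db <- structure(list(studies = rd(study_path),
                       comparisons = rd(comparison_path),
                       genestats = rd(genestats_path)),
                  class = "senodb")
  validate_database(db)
  if (!quiet)
    message(sprintf("loaded %d studies, %d comparisons, %d gene-stat rows",
                    nrow(db$studies), nrow(db$comparisons),
                    nrow(db$genestats)))
  db
}

#' Write a database triple to CSV
#'
#' @param db A `"senodb"` list as returned by [load_database()] or
#'   [generate_database()].
#' @param dir Output directory (created if missing).
#' @return Invisibly, the three file paths written.
#' @export
save_database <- function(db, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- file.path(dir, c("studies.csv", "comparisons.csv",
                            "genestats.csv"))
  utils::write.csv(db$studies, paths[1], row.names = FALSE)
  utils::write.csv(db$comparisons, paths[2], row.names = FALSE)
  utils::write.csv(db$genestats, paths[3], row.names = FALSE)
  invisible(paths)
}

split_multi <- function(x) strsplit(ifelse(is.na(x) | x == "", "", x), ";")

#' Validate a database triple
#'
#' Enforced rules: study accessions nonempty and unique; study inducers
#' within the fourteen-category vocabulary; comparison inducers within the
#' vocabulary or `"none"`; control types, interventions and time units
#' within their vocabularies; every `study_accession` present in the study
#' table; time values nonnegative where the unit is known; gene-stat
#' `p` in (0, 1], finite `logFC`, and at most one row per
#' (comparison, gene) after case-insensitive gene trimming.
#'
#' @param db A `"senodb"` list.
#' @return Invisibly `TRUE`; otherwise stops with an error naming the
#'   offending row.
#' @export
validate_database <- function(db) {
  st <- db$studies; cm <- db$comparisons; gs <- db$genestats
  if (anyNA(st$accession) || any(st$accession == ""))
    stop("study accession missing or empty")
  if (anyDuplicated(st$accession))
    stop("duplicate study accession: ",
         st$accession[duplicated(st$accession)][1])
  for (i in seq_len(nrow(st))) {
    ind <- split_multi(st$inducers)[[i]]
    bad <- setdiff(ind, INDUCER_VOCAB)
    if (length(bad))
      stop(sprintf("study %s: unknown inducer '%s'", st$accession[i],
                   bad[1]))
  }
  if (nrow(cm)) {
    bad <- setdiff(cm$inducer, c(INDUCER_VOCAB, "none"))
    if (length(bad)) {
      row <- which(cm$inducer == bad[1])[1]
      stop(sprintf("comparison %s: unknown inducer '%s'",
                   cm$comparison_id[row], bad[1]))
    }
    bad <- setdiff(cm$control_type, CONTROL_VOCAB)
    if (length(bad)) stop("unknown control type: ", bad[1])
    bad <- setdiff(cm$intervention, INTERVENTION_VOCAB)
    if (length(bad)) stop("unknown intervention: ", bad[1])
    bad <- setdiff(cm$time_unit, TIME_UNIT_VOCAB)
    if (length(bad)) stop("unknown time unit: ", bad[1])
    dangling <- setdiff(cm$study_accession, st$accession)
    if (length(dangling)) {
      row <- which(cm$study_accession == dangling[1])[1]
      stop(sprintf("comparison %s references unknown study %s",
                   cm$comparison_id[row], dangling[1]))
    }
    known <- cm$time_unit != "unknown"
    if (any(known & (is.na(cm$time_value) | cm$time_value < 0))) {
      row <- which(known & (is.na(cm$time_value) | cm$time_value < 0))[1]
      stop(sprintf("comparison %s: negative or missing time value",
                   cm$comparison_id[row]))
    }
    if (anyDuplicated(cm$comparison_id))
      stop("duplicate comparison_id: ",
           cm$comparison_id[duplicated(cm$comparison_id)][1])
  }
  if (nrow(gs)) {
    bad <- which(!is.finite(gs$p) | gs$p <= 0 | gs$p > 1)
    if (length(bad))
      stop(sprintf("gene %s in comparison %s: p = %s outside (0, 1]",
                   gs$gene[bad[1]], gs$comparison_id[bad[1]],
                   format(gs$p[bad[1]])))
    bad <- which(!is.finite(gs$logFC))
    if (length(bad))
      stop(sprintf("gene %s in comparison %s: non-finite logFC",
                   gs$gene[bad[1]], gs$comparison_id[bad[1]]))
    key <- paste(gs$comparison_id, normalize_gene(gs$gene))
    if (anyDuplicated(key))
      stop("duplicate (comparison, gene) row: ", key[duplicated(key)][1])
    dangling <- setdiff(gs$comparison_id, cm$comparison_id)
    if (length(dangling))
      stop("gene stats reference unknown comparison: ", dangling[1])
  }
  invisible(TRUE)
}

#' @keywords internal
normalize_gene <- function(x) toupper(trimws(x))

#' Load the packaged transcription of the printed study table
#'
#' A fixture transcribing the published study inventory (accession,
#' inducers, control types, cell lines, timepoints) for the 119 human
#' fibroblast senescence studies. Platform is `"unknown"` throughout (the
#' printed table does not record it), and entries outside the controlled
#' vocabularies (an unstated senescence type, an apoptosis arm) are dropped
#' from the typed columns during transcription.
#'
#' @return A data frame with one row per study.
#' @export
load_study_fixture <- function() {
  utils::read.csv(system.file("extdata", "senomic_studies.csv",
                              package = "senotemp"),
                  stringsAsFactors = FALSE)
}

#' Assign a temporal bin to comparisons
#'
#' Non-REP comparisons with a day-denominated time `d` fall in the five-bin
#' scheme 0-4, 5-7, 8-11, 12-14, 15+ days; unknown times are `UNBINNED`.
#' REP comparisons fall in `REP0_40` unless a day-denominated time of 41 or
#' more is stated (`REP41plus`); REP times in population doublings or
#' unstated are treated as unknown day-age and binned `REP0_40`.
#'
#' @param inducer Character vector of inducer categories.
#' @param time_value Numeric vector of timepoint values (may be `NA`).
#' @param time_unit Character vector in `c("days", "PD", "unknown")`.
#' @return Character vector of bins (see [TIME_BINS]).
#' @export
assign_time_bin <- function(inducer, time_value, time_unit) {
  n <- max(length(inducer), length(time_value), length(time_unit))
  inducer <- rep_len(inducer, n)
  time_value <- rep_len(as.numeric(time_value), n)
  time_unit <- rep_len(time_unit, n)
  if (any(time_unit != "unknown" & !is.na(time_value) & time_value < 0))
    stop("negative time value")
  known_days <- time_unit == "days" & !is.na(time_value)
  bin <- rep("UNBINNED", n)
  rep_mask <- inducer == "REP"
  bin[rep_mask] <- ifelse(known_days[rep_mask] & time_value[rep_mask] >= 41,
                          "REP41plus", "REP0_40")
  d <- time_value
  nonrep <- !rep_mask & known_days
  bin[nonrep] <- as.character(
    cut(d[nonrep], breaks = c(-Inf, 5, 8, 12, 15, Inf),
        labels = c("D0_4", "D5_7", "D8_11", "D12_14", "D15plus"),
        right = FALSE))
  bin
}

#' Add a `time_bin` column to a comparison table
#'
#' @param comparisons Comparison data frame.
#' @return The same data frame with a `time_bin` column appended.
#' @export
bin_comparisons <- function(comparisons) {
  comparisons$time_bin <- assign_time_bin(comparisons$inducer,
                                          comparisons$time_value,
                                          comparisons$time_unit)
  comparisons
}

#' PRISMA-style record-accounting ledger
#'
#' Derives the screening and inclusion totals of a systematic-review
#' flowchart from its primitive counts and checks the conservation
#' identities `screened = identified_geo + identified_ae -
#' duplicates_removed` and `total_included = included_initial +
#' update_additions`.
#'
#' @param identified_geo,identified_ae Records identified per source.
#' @param duplicates_removed Duplicates removed before screening.
#' @param included_initial Studies included at the initial search.
#' @param update_additions Studies added by update searches.
#' @return A list of class `"prisma_ledger"` with all seven counts.
#' @export
prisma_ledger <- function(identified_geo, identified_ae, duplicates_removed,
                          included_initial, update_additions) {
  counts <- c(identified_geo, identified_ae, duplicates_removed,
              included_initial, update_additions)
  if (any(!is.finite(counts) | counts < 0 | counts != round(counts)))
    stop("ledger counts must be nonnegative integers")
  if (duplicates_removed > identified_geo + identified_ae)
    stop("more duplicates removed than records identified")
  structure(list(
    identified_geo = identified_geo,
    identified_ae = identified_ae,
    duplicates_removed = duplicates_removed,
    screened = identified_geo + identified_ae - duplicates_removed,
    included_initial = included_initial,
    update_additions = update_additions,
    total_included = included_initial + update_additions
  ), class = "prisma_ledger")
}

#' @export
print.prisma_ledger <- function(x, ...) {
  cat(sprintf(paste0("records identified: %d (GEO) + %d (ArrayExpress)\n",
                     "duplicates removed: %d\nscreened: %d\n",
                     "included: %d initial + %d update = %d total\n"),
              x$identified_geo, x$identified_ae, x$duplicates_removed,
              x$screened, x$included_initial, x$update_additions,
              x$total_included))
  invisible(x)
}

#' Filter a comparison table by declarative criteria
#'
#' `criteria` is a named list; recognised names are `inducer`,
#' `exclude_inducer`, `control_type`, `intervention`, `cell_line`,
#' `time_bin` (each a character vector of allowed / excluded values) and
#' `min_day` / `max_day` (inclusive bounds on day-denominated times;
#' comparisons without a day-denominated time fail a day bound). An empty
#' criteria list returns the input unchanged. Row order is preserved.
#'
#' @param comparisons Comparison data frame.
#' @param criteria Named list of criteria.
#' @return The satisfying subset of `comparisons`.
#' @export
filter_comparisons <- function(comparisons, criteria = list()) {
  known <- c("inducer", "exclude_inducer", "control_type", "intervention",
             "cell_line", "time_bin", "min_day", "max_day")
  bad <- setdiff(names(criteria), known)
  if (length(bad)) stop("unknown filter criterion: ", bad[1])
  keep <- rep(TRUE, nrow(comparisons))
  days <- ifelse(comparisons$time_unit == "days", comparisons$time_value,
                 NA_real_)
  for (nm in names(criteria)) {
    v <- criteria[[nm]]
    keep <- keep & switch(nm,
      inducer = comparisons$inducer %in% v,
      exclude_inducer = !(comparisons$inducer %in% v),
      control_type = comparisons$control_type %in% v,
      intervention = comparisons$intervention %in% v,
      cell_line = comparisons$cell_line %in% v,
      time_bin = {
        if (is.null(comparisons$time_bin))
          stop("comparisons are not binned; call bin_comparisons() first")
        comparisons$time_bin %in% v
      },
      min_day = !is.na(days) & days >= v,
      max_day = !is.na(days) & days <= v)
  }
  comparisons[keep, , drop = FALSE]
}
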