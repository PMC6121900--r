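# Summary statistics over classified PTM records. The counting unit for all
# headline statistics is the protein-class pair: one protein exhibiting one
# PTM class counts once, no matter how many sites carry it.

#' Count distinct protein-class pairs
#'
#' The single-count-per-protein-per-class rule: returns the number of
#' distinct (accession, canonical_class) combinations, invariant under
#' duplication and reordering of site records.
#'
#' @param records A `classified_ptms` tibble (see [classify_ptms()]).
#' @return Integer count.
#' @examples
#' recs <- classify_ptms(read_ptm_flatfile(ptmgrav_example("table2_ptm.tsv")))
#' count_protein_class_pairs(recs)
#' @export
count_protein_class_pairs <- function(records) {
  stopifnot(inherits(records, "classified_ptms"))
  nrow(dplyr::distinct(records[c("accession", "canonical_class")]))
}

#' Percentage of protein-class pairs per residue-chemistry group
#'
#' For each of the six groups, the share of protein-class pairs (or,
#' optionally, of raw site records) belonging to that group. Groups absent
#' from the data report 0. Raw percentages sum to exactly 100; the
#' one-decimal `percent` column is a presentation rounding of them.
#'
#' @param records A `classified_ptms` tibble with at least one record.
#' @param denominator `"pairs"` (default; the headline statistic) or
#'   `"sites"` (raw site records, exposed for sensitivity checks).
#' @return A tibble with columns `group`, `n`, `percent_raw`, `percent`,
#'   one row per group in fixed group order.
#' @export
group_percentages <- function(records, denominator = c("pairs", "sites")) {
  stopifnot(inherits(records, "classified_ptms"))
  denominator <- match.arg(denominator)
  if (nrow(records) == 0L) {
    stop("group percentages are undefined for zero records", call. = FALSE)
  }
  units <- if (denominator == "pairs") {
    dplyr::distinct(records[c("accession", "canonical_class", "group")])
  } else {
    records[c("accession", "canonical_class", "group")]
  }
  n <- vapply(PTM_GROUPS, function(g) sum(units$group == g), 0L)
  raw <- 100 * n / nrow(units)
  tibble::tibble(group = PTM_GROUPS, n = unname(n),
                 percent_raw = unname(raw),
                 percent = round(unname(raw), 1))
}

#' Count proteins carrying lysine-N6 modifications
#'
#' Number of distinct proteins with at least one site in the `LYSINE_N6`
#' group. Whether the Gly-Lys isopeptide (ubiquitination, chemically also
#' attached to the lysine N6 amino group) counts toward this statistic is
#' ambiguous, so both modes are exposed.
#'
#' @param records A `classified_ptms` tibble.
#' @param include_isopeptide Also count proteins whose only lysine-side-chain
#'   evidence is a `GLY_LYS_ISOPEPTIDE` site.
#' @return Integer count of accessions.
#' @export
count_n6_proteins <- function(records, include_isopeptide = FALSE) {
  stopifnot(inherits(records, "classified_ptms"))
  groups <- c("LYSINE_N6", if (include_isopeptide) "GLY_LYS_ISOPEPTIDE")
  length(unique(records$accession[records$group %in% groups]))
}

#' Build the full summary report
#'
#' Aggregates the pipeline outputs into one report: selection size, number of
#' modified proteins, distinct classes, protein-class pairs, per-group
#' percentages, lysine-N6 protein counts in both counting modes, and — when
#' the size of the full detected proteome is supplied — the selected fraction
#' of it as a one-decimal percentage.
#'
#' @param selection Optional `selection_result`; its selected-set size
#'   populates `n_proteins_selected` (otherwise the number of distinct
#'   modified proteins is used).
#' @param records A `classified_ptms` tibble (may have zero rows).
#' @param total_detected Optional positive integer, the total number of
#'   proteins detected upstream.
#' @return A list of class `ptm_summary`. `group_percentages` is `NULL` when
#'   there are no records.
#' @examples
#' recs <- classify_ptms(read_ptm_flatfile(ptmgrav_example("table2_ptm.tsv")))
#' build_report(records = recs)
#' @export
build_report <- function(selection = NULL, records, total_detected = NULL) {
  stopifnot(inherits(records, "classified_ptms"))
  if (!is.null(total_detected)) {
    stopifnot(is.numeric(total_detected), length(total_detected) == 1L)
    if (total_detected <= 0) {
      stop("total_detected must be a positive count", call. = FALSE)
    }
  }
  n_with_ptm <- length(unique(records$accession))
  n_selected <- if (!is.null(selection)) {
    length(selection$selected)
  } else {
    n_with_ptm
  }
  report <- list(
    n_proteins_selected = n_selected,
    n_proteins_with_ptm = n_with_ptm,
    n_classes = length(unique(records$canonical_class)),
    n_protein_class_pairs = count_protein_class_pairs(records),
    n_site_records = nrow(records),
    group_percentages = if (nrow(records)) group_percentages(records),
    n_proteins_lysine_n6 = count_n6_proteins(records, FALSE),
    n_proteins_lysine_n6_incl_isopeptide = count_n6_proteins(records, TRUE),
    fraction_of_detected_proteome = if (!is.null(total_detected)) {
      round(100 * n_selected / total_detected, 1)
    } else {
      NA_real_
    }
  )
  structure(report, class = "ptm_summary")
}

#' @export
print.ptm_summary <- function(x, ...) {
  cat("<ptm_summary>\n")
  cat("  proteins selected:        ", x$n_proteins_selected, "\n")
  cat("  proteins with >=1 PTM:    ", x$n_proteins_with_ptm, "\n")
  cat("  distinct PTM classes:     ", x$n_classes, "\n")
  cat("  protein-class pairs:      ", x$n_protein_class_pairs,
      " (from ", x$n_site_records, " site records)\n", sep = "")
  if (!is.null(x$group_percentages)) {
    gp <- x$group_percentages
    for (i in seq_len(nrow(gp))) {
      cat(sprintf("    %-20s %5.1f%% (%d pairs)\n", gp$group[i],
                  gp$percent[i], gp$n[i]))
    }
  }
  cat("  lysine-N6 proteins:       ", x$n_proteins_lysine_n6,
      " (", x$n_proteins_lysine_n6_incl_isopeptide,
      " incl. Gly-Lys isopeptide)\n", sep = "")
  if (!is.na(x$fraction_of_detected_proteome)) {
    cat("  fraction of detected proteome: ",
        x$fraction_of_detected_proteome, "%\n", sep = "")
  }
  invisible(x)
}

#' Write a summary report as JSON
#'
#' Deterministic JSON serialization of a [build_report()] result (fixed field
#' order, full-precision numbers), suitable for byte-identical re-runs.
#'
#' @param report A `ptm_summary`.
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
write_report_json <- function(report, path) {
  stopifnot(inherits(report, "ptm_summary"))
  out <- unclass(report)
  if (!is.null(out$group_percentages)) {
    out$group_percentages <- as.data.frame(out$group_percentages)
  }
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       na = "null", pretty = TRUE)
  invisible(path)
}

#' Per-protein class tallies
#'
#' One row per protein-class pair with the number of underlying site records,
#' exportable as TSV.
#'
#' @param records A `classified_ptms` tibble.
#' @return A tibble `accession`, `canonical_class`, `group`, `n_sites`.
#' @export
protein_class_tally <- function(records) {
  stopifnot(inherits(records, "classified_ptms"))
  dplyr::count(tibble::as_tibble(records),
               .data$accession, .data$canonical_class, .data$group,
               name = "n_sites")
}
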