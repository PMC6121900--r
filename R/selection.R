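#' Differential-accumulation selection criteria
#'
#' Parameters of the candidate-selection rule applied to a two-condition LfQ
#' table. A protein qualifies when it is detected in spheroid cells but not in
#' monolayer control cells (zero baseline), or when its spheroid accumulation
#' is at least `fold_threshold` times the monolayer value. When
#' `require_concordance` is set, a qualifying protein must additionally show
#' up-regulation in a second, independent cell line: spheroid/monolayer ratio
#' strictly greater than `concordance_fold`, or zero-baseline detection there.
#'
#' The concordance default of 1.0 (strict up-regulation) is deliberately the
#' weakest reading consistent with the published secondary-cell-line ratios,
#' some of which fall below the primary 1.8 threshold.
#'
#' @param fold_threshold Minimum spheroid/monolayer LfQ ratio in the primary
#'   cell line (dimensionless; compared with `>=`). Default 1.8.
#' @param require_concordance Require up-regulation in the secondary table?
#' @param concordance_fold Ratio the secondary cell line must strictly exceed.
#' @param zero_baseline_passes Whether detection only under microgravity
#'   (monolayer LfQ exactly 0) qualifies regardless of ratio.
#' @return A list of class `selection_criteria`.
#' @export
selection_criteria <- function(fold_threshold = 1.8,
                               require_concordance = TRUE,
                               concordance_fold = 1.0,
                               zero_baseline_passes = TRUE) {
  stopifnot(is.numeric(fold_threshold), length(fold_threshold) == 1L,
            fold_threshold > 0,
            is.numeric(concordance_fold), length(concordance_fold) == 1L,
            concordance_fold > 0,
            is.logical(require_concordance), is.logical(zero_baseline_passes))
  structure(list(fold_threshold = fold_threshold,
                 require_concordance = require_concordance,
                 concordance_fold = concordance_fold,
                 zero_baseline_passes = zero_baseline_passes),
            class = "selection_criteria")
}

#' Primary selection rule for one protein
#'
#' Vectorized predicate implementing the differential-accumulation rule on the
#' primary cell line: qualify if the protein was undetected in monolayer cells
#' but detected in spheroids, or if the spheroid/monolayer LfQ ratio meets the
#' fold threshold. Proteins undetected in both conditions never qualify.
#'
#' Ratio comparisons use a relative tolerance of one part in 10^9, so a ratio
#' arithmetically equal to the threshold always counts as meeting it and the
#' decision is invariant under rescaling all scores by a positive constant.
#'
#' @param lfq_1g,lfq_ug Non-negative LfQ scores (monolayer 1g, spheroid ug).
#' @param criteria A [selection_criteria()].
#' @return Logical vector.
#' @examples
#' passes_primary_rule(0, 1.11)      # detected only in spheroids
#' passes_primary_rule(5, 5)        # ratio 1.0 < 1.8
#' passes_primary_rule(0.7, 1.32)   # ratio ~1.886
#' @export
passes_primary_rule <- function(lfq_1g, lfq_ug, criteria = selection_criteria()) {
  stopifnot(inherits(criteria, "selection_criteria"),
            all(lfq_1g >= 0), all(lfq_ug >= 0))
  zero_baseline <- lfq_1g == 0 & lfq_ug > 0 & criteria$zero_baseline_passes
  fold <- lfq_1g > 0 &
    lfq_ug / lfq_1g >= criteria$fold_threshold * (1 - RATIO_TOL)
  zero_baseline | fold
}

# Relative tolerance for threshold comparisons on LfQ ratios: large enough to
# absorb last-ulp rounding of the division, far below the data's 2-decimal
# resolution.
RATIO_TOL <- 1e-9

# Concordance predicate on the secondary cell line: strict up-regulation or
# zero-baseline detection. NA scores (protein absent) yield FALSE.
passes_concordance <- function(lfq_1g, lfq_ug, criteria) {
  ok <- (lfq_1g == 0 & lfq_ug > 0 & criteria$zero_baseline_passes) |
    (lfq_1g > 0 &
       lfq_ug / lfq_1g > criteria$concordance_fold * (1 + RATIO_TOL))
  ok & !is.na(ok)
}

#' Select candidate proteins from one or two LfQ tables
#'
#' Applies [passes_primary_rule()] to every protein of the primary table and,
#' when concordance is required, keeps only proteins that also show
#' up-regulation in the secondary table. Tables are joined on gene name, with
#' accession as fallback for genes absent from the secondary table. A protein
#' missing from the secondary table is excluded with the rationale
#' `"no secondary evidence"`, not an error.
#'
#' @param primary A [quant_table()] for the primary cell line.
#' @param secondary Optional `quant_table` for the independent cell line; must
#'   be from a different cell line. Mandatory when
#'   `criteria$require_concordance` is `TRUE`.
#' @param criteria A [selection_criteria()].
#' @return A list of class `selection_result` with elements
#'   \describe{
#'     \item{selected}{accessions of selected proteins, in primary-table order}
#'     \item{rationale}{tibble with one row per evaluated protein: `accession`,
#'       `gene`, `rule` (`"zero-baseline"`, `"fold"` or `"none"`), `fold`
#'       (spheroid/monolayer ratio, `NA` for zero baselines), `concordant`,
#'       `note`, `selected`}
#'     \item{criteria}{the criteria used}
#'   }
#' @examples
#' ftc <- read_quant_table(ptmgrav_example("table1_ftc133.tsv"), "FTC-133")
#' mcf <- read_quant_table(ptmgrav_example("table1_mcf7.tsv"), "MCF-7")
#' res <- select_candidates(ftc, mcf)
#' length(res$selected)
#' @export
select_candidates <- function(primary, secondary = NULL,
                              criteria = selection_criteria()) {
  stopifnot(inherits(primary, "quant_table"),
            inherits(criteria, "selection_criteria"))
  if (criteria$require_concordance && is.null(secondary)) {
    stop("criteria require concordance but no secondary table was given; ",
         "pass one or set require_concordance = FALSE", call. = FALSE)
  }
  if (!is.null(secondary)) {
    stopifnot(inherits(secondary, "quant_table"))
    if (identical(cell_line(primary), cell_line(secondary))) {
      stop("primary and secondary tables are from the same cell line ('",
           cell_line(primary), "'); concordance needs an independent line",
           call. = FALSE)
    }
  }

  rat <- tibble::tibble(
    accession = primary$accession,
    gene = primary$gene,
    zero_baseline = primary$lfq_1g == 0 & primary$lfq_ug > 0 &
      criteria$zero_baseline_passes,
    fold = ifelse(primary$lfq_1g > 0, primary$lfq_ug / primary$lfq_1g,
                  NA_real_),
    primary_pass = passes_primary_rule(primary$lfq_1g, primary$lfq_ug,
                                       criteria)
  )
  rat$rule <- ifelse(rat$zero_baseline, "zero-baseline",
                     ifelse(rat$primary_pass, "fold", "none"))

  if (criteria$require_concordance) {
    idx <- match(primary$gene, secondary$gene)
    fallback <- is.na(idx)
    idx[fallback] <- match(primary$accession[fallback], secondary$accession)
    sec_1g <- secondary$lfq_1g[idx]
    sec_ug <- secondary$lfq_ug[idx]
    rat$concordant <- passes_concordance(sec_1g, sec_ug, criteria)
    rat$note <- ifelse(is.na(idx), "no secondary evidence", "")
    rat$selected <- rat$primary_pass & rat$concordant
  } else {
    rat$concordant <- NA
    rat$note <- ""
    rat$selected <- rat$primary_pass
  }
  rat$zero_baseline <- NULL
  rat$primary_pass <- NULL
  rat <- rat[c("accession", "gene", "rule", "fold", "concordant", "note",
               "selected")]
  structure(list(selected = rat$accession[rat$selected],
                 rationale = rat,
                 criteria = criteria),
            class = "selection_result")
}

#' @export
print.selection_result <- function(x, ...) {
  cat("<selection_result>: ", length(x$selected), " of ",
      nrow(x$rationale), " proteins selected (fold threshold ",
      x$criteria$fold_threshold, ")\n", sep = "")
  invisible(x)
}

#' Export a selection result as TSV
#'
#' Writes the per-protein rationale (accession, gene, rule fired, fold change,
#' concordance flag, selection flag) as tab-separated text.
#'
#' @param result A `selection_result` from [select_candidates()].
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
write_selection <- function(result, path) {
  stopifnot(inherits(result, "selection_result"))
  out <- result$rationale
  out$fold <- ifelse(is.na(out$fold), "", formatC(out$fold, format = "f",
                                                  digits = 4))
  readr::write_tsv(out, path, progress = FALSE)
  invisible(path)
}
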