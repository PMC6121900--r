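# Synthetic two-cell-line LfQ tables and dbPTM-style site records with a
# planted, ledgered ground truth, so that selection, classification, graph
# construction and summarization are all testable without any download.

# Class pools per residue-chemistry group. Every pool class has a unique
# target residue, so generated windows are chemistry-valid by construction.
SYNTH_CLASS_POOLS <- list(
  PHOSPHORYLATION = c("Phosphoserine", "Phosphothreonine", "Phosphotyrosine",
                      "Phosphohistidine"),
  LYSINE_N6 = c("N6-acetyllysine", "N6-methyllysine", "N6,N6-dimethyllysine",
                "N6-succinyllysine", "N6-malonyllysine", "N6-crotonyllysine"),
  OTHER_NITROGEN = c("N-acetylmethionine", "N-acetylserine", "N-acetylalanine",
                     "N-acetylthreonine", "N-acetylvaline",
                     "N-linked (GlcNAc)", "N-myristoyl glycine",
                     "Omega-N-methylarginine"),
  SULFUR = c("S-cysteinyl 3-(oxidosulfanyl)alanine (Cys-Cys)",
             "S-nitrosocysteine", "S-palmitoyl cysteine",
             "S-glutathionyl cysteine", "S-farnesyl cysteine"),
  GLY_LYS_ISOPEPTIDE = c("Glycyl lysine isopeptide (Lys-Gly)",
                         "Glycyl lysine isopeptide (Gly-Lys)"),
  OTHER = c("C-linked (Man)", "4-hydroxyproline", "3-hydroxyproline",
            "5-hydroxylysine", "Pyrrolidone carboxylic acid", "Citrulline")
)

# Default per-group frequencies of protein-class pairs: the observed
# breakdown of the study this pipeline emulates (phosphorylation 48%,
# lysine-N6 18.9%, other nitrogen 12.8%, sulfur 4%, Gly-Lys isopeptide 3.4%,
# remainder 12.9%).
SYNTH_DEFAULT_CLASS_FREQUENCY <- c(PHOSPHORYLATION = 0.48,
                                   LYSINE_N6 = 0.189,
                                   OTHER_NITROGEN = 0.128,
                                   SULFUR = 0.04,
                                   GLY_LYS_ISOPEPTIDE = 0.034,
                                   OTHER = 0.129)

#' Define a synthetic-data scenario
#'
#' All knobs of the generator, with defaults emulating the study conditions:
#' LfQ scores log-normal on the x 10^8 scale spanning roughly 0.2-600, just
#' under half of the planted passers detected only under microgravity (zero
#' baseline), passer fold changes at or above the 1.8 selection threshold,
#' failer fold changes below it, and protein-class pairs distributed over the
#' six residue-chemistry groups at the observed frequencies.
#'
#' @param seed Integer seed; one seed determines the whole scenario.
#' @param n_proteins Number of proteins in each cell line's table.
#' @param n_selected_planted Number of proteins planted to pass selection.
#' @param lfq_log_mean,lfq_log_sd Parameters of the log-normal LfQ score
#'   model (on the log scale).
#' @param zero_baseline_fraction Share of planted passers detected only in
#'   spheroids (monolayer LfQ exactly 0).
#' @param fold_range_passers Interval of spheroid/monolayer ratios for
#'   planted passers; lower bound must be >= `fold_threshold`.
#' @param fold_range_failers Interval for planted failers; upper bound must
#'   be < `fold_threshold`.
#' @param fold_threshold Selection threshold the plants are built around.
#' @param class_frequency Named vector over the six groups, summing to 1.
#' @param class_mode `"quota"` plants the pair-group counts exactly (largest
#'   remainder); `"multinomial"` draws each pair's group independently.
#' @param pairs_per_protein Integer range: protein-class pairs per modified
#'   protein.
#' @param sites_per_pair Integer range: site records per pair (several sites
#'   of one class on one protein exercise the single-count rule).
#' @param sequence_length Integer range of generated protein lengths.
#' @param cell_lines Labels for the primary and secondary tables.
#' @return A list of class `synthetic_scenario`.
#' @export
synthetic_scenario <- function(seed,
                               n_proteins = 400L,
                               n_selected_planted = 40L,
                               lfq_log_mean = 0.5,
                               lfq_log_sd = 1.4,
                               zero_baseline_fraction = 0.46,
                               fold_range_passers = c(1.8, 8),
                               fold_range_failers = c(0.2, 1.7),
                               fold_threshold = 1.8,
                               class_frequency = SYNTH_DEFAULT_CLASS_FREQUENCY,
                               class_mode = c("quota", "multinomial"),
                               pairs_per_protein = c(1L, 6L),
                               sites_per_pair = c(1L, 3L),
                               sequence_length = c(60L, 400L),
                               cell_lines = c("SYN-A", "SYN-B")) {
  class_mode <- match.arg(class_mode)
  stopifnot(length(seed) == 1L, is.finite(seed),
            n_proteins >= 1L, n_selected_planted >= 0L,
            n_selected_planted <= n_proteins,
            n_proteins <= 99999L,
            lfq_log_sd > 0,
            zero_baseline_fraction >= 0, zero_baseline_fraction <= 1,
            fold_range_passers[1] >= fold_threshold,
            fold_range_passers[2] >= fold_range_passers[1],
            fold_range_failers[2] < fold_threshold,
            fold_range_failers[1] > 0,
            pairs_per_protein[1] >= 0L,
            pairs_per_protein[2] >= pairs_per_protein[1],
            sites_per_pair[1] >= 1L,
            sites_per_pair[2] >= sites_per_pair[1],
            sequence_length[1] >= 20L,
            length(cell_lines) == 2L, cell_lines[1] != cell_lines[2])
  if (abs(sum(class_frequency) - 1) > 1e-9) {
    stop("class_frequency must sum to 1", call. = FALSE)
  }
  if (!setequal(names(class_frequency), PTM_GROUPS)) {
    stop("class_frequency must name exactly the six groups", call. = FALSE)
  }
  # an interior 9-mer site needs position in [5, L - 4]
  max_sites <- pairs_per_protein[2] * sites_per_pair[2]
  if (sequence_length[1] - 8L < max_sites) {
    stop("infeasible scenario: shortest sequences cannot host ",
         max_sites, " distinct interior sites", call. = FALSE)
  }
  structure(list(seed = as.integer(seed), n_proteins = as.integer(n_proteins),
                 n_selected_planted = as.integer(n_selected_planted),
                 lfq_log_mean = lfq_log_mean, lfq_log_sd = lfq_log_sd,
                 zero_baseline_fraction = zero_baseline_fraction,
                 fold_range_passers = fold_range_passers,
                 fold_range_failers = fold_range_failers,
                 fold_threshold = fold_threshold,
                 class_frequency = class_frequency[PTM_GROUPS],
                 class_mode = class_mode,
                 pairs_per_protein = as.integer(pairs_per_protein),
                 sites_per_pair = as.integer(sites_per_pair),
                 sequence_length = as.integer(sequence_length),
                 cell_lines = cell_lines),
            class = "synthetic_scenario")
}

# Largest-remainder apportionment of n units over the frequency vector.
quota_counts <- function(freq, n) {
  exact <- freq * n
  base <- floor(exact)
  short <- n - sum(base)
  if (short > 0) {
    extra <- order(exact - base, decreasing = TRUE)[seq_len(short)]
    base[extra] <- base[extra] + 1
  }
  stats::setNames(as.integer(base), names(freq))
}

# Draw one protein's two-condition LfQ pair under a planted role, on the
# rounded 2-decimal scale, re-checking the planted (in)equality after
# rounding so the plant survives serialization precision.
draw_lfq_pair <- function(role, s) {
  if (role == "zero-baseline") {
    ug <- max(round(rlnorm(1, s$lfq_log_mean, s$lfq_log_sd), 2), 0.01)
    return(c(0, ug))
  }
  base <- max(round(rlnorm(1, s$lfq_log_mean, s$lfq_log_sd), 2), 0.01)
  range <- if (role == "fold") s$fold_range_passers else s$fold_range_failers
  ug <- round(base * runif(1, range[1], range[2]), 2)
  if (role == "fold") {
    while (ug / base < s$fold_threshold) ug <- ug + 0.01
  } else {
    while (ug > 0 && ug / base >= s$fold_threshold * (1 - 1e-9)) {
      ug <- ug - 0.01
    }
    ug <- max(ug, 0)
  }
  c(base, ug)
}

# Secondary-table pair for a planted passer: strict up-regulation (or zero
# baseline), again verified on the rounded values.
draw_concordant_pair <- function(s) {
  if (runif(1) < 0.2) {
    return(c(0, max(round(rlnorm(1, s$lfq_log_mean, s$lfq_log_sd), 2), 0.01)))
  }
  base <- max(round(rlnorm(1, s$lfq_log_mean, s$lfq_log_sd), 2), 0.01)
  ug <- round(base * runif(1, 1.2, 4), 2)
  while (ug / base <= 1 + 1e-9) ug <- ug + 0.01
  c(base, ug)
}

#' Generate a synthetic scenario
#'
#' Deterministically expands a [synthetic_scenario()] into two quantitation
#' tables, a PTM record collection, protein sequences, and a ground-truth
#' ledger. Planted passers satisfy the selection rule by construction (on the
#' serialized 2-decimal scale) and planted failers violate it; every site
#' window is cut from the generated sequence by [expected_window()] and
#' centers on the residue its class targets. Per-protein quantities are drawn
#' from substreams keyed by protein index, so enlarging a scenario does not
#' perturb earlier proteins' draws.
#'
#' @param scenario A `synthetic_scenario`.
#' @return A list of class `synthetic_data` with elements `scenario`,
#'   `primary` and `secondary` ([quant_table()]s), `records`
#'   ([ptm_records()]), `sequences` (named character vector) and `ledger`
#'   (class `ground_truth_ledger`: `scenario_id`, `selected_accessions`,
#'   `sites` tibble with true class/group/position per record, and
#'   `expected`, the exact value of every summary-report field).
#' @examples
#' syn <- generate_scenario(synthetic_scenario(seed = 7))
#' length(syn$ledger$selected_accessions)
#' @export
generate_scenario <- function(scenario) {
  stopifnot(inherits(scenario, "synthetic_scenario"))
  s <- scenario
  n <- s$n_proteins
  accession <- sprintf("S%05d", seq_len(n))
  gene <- sprintf("SYNG%04d", seq_len(n))
  protein_name <- sprintf("Synthetic protein %d", seq_len(n))

  set.seed(substream_seed(s$seed, 0L))
  selected_idx <- sort(sample.int(n, s$n_selected_planted))
  is_selected <- seq_len(n) %in% selected_idx
  role <- ifelse(is_selected & runif(n) < s$zero_baseline_fraction,
                 "zero-baseline", ifelse(is_selected, "fold", "failer"))

  lfq <- matrix(0, n, 4)
  seq_len_i <- integer(n)
  sequences <- character(n)
  for (i in seq_len(n)) {
    set.seed(substream_seed(s$seed, i))
    lfq[i, 1:2] <- draw_lfq_pair(role[i], s)
    lfq[i, 3:4] <- if (is_selected[i]) {
      draw_concordant_pair(s)
    } else {
      base <- round(rlnorm(1, s$lfq_log_mean, s$lfq_log_sd), 2)
      c(base, round(base * runif(1, 0.5, 2), 2))
    }
    seq_len_i[i] <- resample(seq(s$sequence_length[1], s$sequence_length[2]), 1)
    sequences[i] <- paste(sample(AMINO_ACIDS, seq_len_i[i], replace = TRUE),
                          collapse = "")
  }
  names(sequences) <- accession

  primary <- quant_table(
    tibble::tibble(gene = gene, protein_name = protein_name,
                   accession = accession, lfq_1g = lfq[, 1],
                   lfq_ug = lfq[, 2]),
    cell_line = s$cell_lines[1],
    provenance = paste0("synthetic seed ", s$seed))
  secondary <- quant_table(
    tibble::tibble(gene = gene, protein_name = protein_name,
                   accession = accession, lfq_1g = lfq[, 3],
                   lfq_ug = lfq[, 4]),
    cell_line = s$cell_lines[2],
    provenance = paste0("synthetic seed ", s$seed))

  # ---- plant protein-class pairs over the selected proteins ----
  set.seed(substream_seed(s$seed, 1000000L))
  n_pairs_i <- if (length(selected_idx)) {
    resample(seq(s$pairs_per_protein[1], s$pairs_per_protein[2]),
           length(selected_idx), replace = TRUE)
  } else {
    integer()
  }
  total_pairs <- sum(n_pairs_i)
  pair_groups <- if (total_pairs == 0L) {
    character()
  } else if (s$class_mode == "quota") {
    counts <- quota_counts(s$class_frequency, total_pairs)
    rep(names(counts), counts)
  } else {
    sample(names(s$class_frequency), total_pairs, replace = TRUE,
           prob = s$class_frequency)
  }

  # deal groups to proteins so that no protein needs more distinct classes
  # of one group than its pool offers: slot-by-slot draws from the remaining
  # group multiset, restricted to groups the protein still has classes for
  # (rare dead ends at the tail are retried with a fresh slot order)
  pool_size <- lengths(SYNTH_CLASS_POOLS)
  deal <- NULL
  if (total_pairs > 0L) {
    owner <- rep(seq_along(selected_idx), n_pairs_i)
    for (try in seq_len(200L)) {
      remaining <- vapply(PTM_GROUPS, function(g) sum(pair_groups == g), 0L)
      used <- matrix(0L, length(selected_idx), length(PTM_GROUPS),
                     dimnames = list(NULL, PTM_GROUPS))
      cand <- character(total_pairs)
      ok <- TRUE
      for (slot in sample.int(total_pairs)) {
        j <- owner[slot]
        eligible <- PTM_GROUPS[remaining > 0L &
                                 used[j, ] < pool_size[PTM_GROUPS]]
        if (!length(eligible)) { ok <- FALSE; break }
        g <- if (length(eligible) == 1L) eligible else
          sample(eligible, 1L, prob = remaining[eligible])
        cand[slot] <- g
        remaining[g] <- remaining[g] - 1L
        used[j, g] <- used[j, g] + 1L
      }
      if (ok) { deal <- cand; break }
    }
    if (is.null(deal)) {
      stop("infeasible scenario: could not allocate planted classes; ",
           "reduce pairs_per_protein or adjust class_frequency",
           call. = FALSE)
    }
  }

  # ---- expand pairs into site records with sequence-consistent windows ----
  site_rows <- list()
  if (total_pairs > 0L) {
    owner <- rep(seq_along(selected_idx), n_pairs_i)
    for (j in seq_along(selected_idx)) {
      i <- selected_idx[j]
      groups_j <- deal[owner == j]
      classes_j <- character(length(groups_j))
      for (g in unique(groups_j)) {
        k <- sum(groups_j == g)
        classes_j[groups_j == g] <- sample(SYNTH_CLASS_POOLS[[g]], k)
      }
      n_sites_j <- resample(seq(s$sites_per_pair[1], s$sites_per_pair[2]),
                          length(classes_j), replace = TRUE)
      positions <- resample(seq(5L, seq_len_i[i] - 4L), sum(n_sites_j))
      seq_i <- strsplit(sequences[i], "")[[1]]
      site_class <- rep(classes_j, n_sites_j)
      site_group <- rep(groups_j, n_sites_j)
      target <- target_residue(site_class)
      seq_i[positions] <- target
      sequences[i] <- paste(seq_i, collapse = "")
      windows <- vapply(positions, function(p) {
        expected_window(sequences[i], p)
      }, "")
      site_rows[[j]] <- tibble::tibble(
        accession = accession[i], class = site_class, group = site_group,
        position = as.integer(positions), window = windows,
        n_sources = sample(1:2, length(positions), replace = TRUE),
        pubmed = 1000000L + sample.int(29000000L, length(positions)))
    }
  }
  sites <- if (length(site_rows)) dplyr::bind_rows(site_rows) else
    tibble::tibble(accession = character(), class = character(),
                   group = character(), position = integer(),
                   window = character(), n_sources = integer(),
                   pubmed = integer())

  records <- ptm_records(
    accession = sites$accession,
    modification = sites$class,
    position = sites$position,
    window = sites$window,
    sources = lapply(sites$n_sources, function(k) PTM_KNOWN_SOURCES[seq_len(k)]),
    pubmed_ids = lapply(sites$pubmed, function(p) as.integer(p)))

  ledger <- build_ledger(s, accession[selected_idx], sites)
  structure(list(scenario = s, primary = primary, secondary = secondary,
                 records = records, sequences = sequences, ledger = ledger),
            class = "synthetic_data")
}

# Ground truth computed from the planted site list with plain base-R tallies,
# independent of the summarize module it later validates.
build_ledger <- function(s, selected_accessions, sites) {
  pairs <- unique(sites[c("accession", "class", "group")])
  n_pairs <- nrow(pairs)
  group_n <- vapply(PTM_GROUPS, function(g) sum(pairs$group == g), 0L)
  raw <- if (n_pairs > 0) 100 * group_n / n_pairs else rep(NA_real_, 6)
  expected <- list(
    n_proteins_selected = length(selected_accessions),
    n_proteins_with_ptm = length(unique(sites$accession)),
    n_classes = length(unique(sites$class)),
    n_protein_class_pairs = n_pairs,
    n_site_records = nrow(sites),
    group_n = stats::setNames(unname(group_n), PTM_GROUPS),
    group_percent_raw = stats::setNames(unname(raw), PTM_GROUPS),
    n_proteins_lysine_n6 =
      length(unique(sites$accession[sites$group == "LYSINE_N6"])),
    n_proteins_lysine_n6_incl_isopeptide =
      length(unique(sites$accession[sites$group %in%
                                      c("LYSINE_N6", "GLY_LYS_ISOPEPTIDE")])),
    fraction_of_detected_proteome =
      round(100 * length(selected_accessions) / s$n_proteins, 1)
  )
  structure(list(scenario_id = paste0("ptmgrav-synthetic-", s$seed),
                 selected_accessions = selected_accessions,
                 sites = sites,
                 expected = expected),
            class = "ground_truth_ledger")
}

#' Check pipeline outputs against a ground-truth ledger
#'
#' Compares a summary report and a selection result field by field against
#' the exact values the generator planted. Any deviation fails, naming the
#' field.
#'
#' @param report A `ptm_summary` from [build_report()].
#' @param selection A `selection_result` from [select_candidates()].
#' @param ledger A `ground_truth_ledger` from [generate_scenario()].
#' @param scenario_id Optional identifier to cross-check against the ledger's
#'   own; a mismatch is a usage error (outputs and ledger from different
#'   scenarios).
#' @return A list of class `ledger_check` with `pass` (logical) and `diffs`
#'   (tibble `field`, `expected`, `actual`, `ok`).
#' @export
ledger_check <- function(report, selection, ledger, scenario_id = NULL) {
  stopifnot(inherits(report, "ptm_summary"),
            inherits(selection, "selection_result"),
            inherits(ledger, "ground_truth_ledger"))
  if (!is.null(scenario_id) && !identical(scenario_id, ledger$scenario_id)) {
    stop("scenario identifier mismatch: outputs are '", scenario_id,
         "' but ledger is '", ledger$scenario_id, "'", call. = FALSE)
  }
  exp <- ledger$expected
  rows <- list()
  cmp <- function(field, expected, actual) {
    rows[[length(rows) + 1L]] <<- tibble::tibble(
      field = field, expected = as.character(expected),
      actual = as.character(actual),
      ok = isTRUE(all.equal(unname(expected), unname(actual),
                            tolerance = 1e-12)))
  }
  cmp("selected_set",
      paste(sort(ledger$selected_accessions), collapse = ","),
      paste(sort(selection$selected), collapse = ","))
  rows[[1]]$ok <- setequal(ledger$selected_accessions, selection$selected)
  for (f in c("n_proteins_selected", "n_proteins_with_ptm", "n_classes",
              "n_protein_class_pairs", "n_site_records",
              "n_proteins_lysine_n6", "n_proteins_lysine_n6_incl_isopeptide",
              "fraction_of_detected_proteome")) {
    cmp(f, exp[[f]], report[[f]])
  }
  gp <- report$group_percentages
  for (g in PTM_GROUPS) {
    cmp(paste0("pairs_", g), exp$group_n[[g]],
        if (is.null(gp)) 0L else gp$n[gp$group == g])
    cmp(paste0("percent_", g), exp$group_percent_raw[[g]],
        if (is.null(gp)) NA_real_ else gp$percent_raw[gp$group == g])
  }
  diffs <- dplyr::bind_rows(rows)
  structure(list(pass = all(diffs$ok), diffs = diffs),
            class = "ledger_check")
}

#' @export
print.ledger_check <- function(x, ...) {
  cat("<ledger_check>: ", if (x$pass) "PASS" else "FAIL", "\n", sep = "")
  bad <- x$diffs[!x$diffs$ok, ]
  if (nrow(bad)) {
    for (i in seq_len(nrow(bad))) {
      cat("  ", bad$field[i], ": expected ", bad$expected[i],
          ", got ", bad$actual[i], "\n", sep = "")
    }
  }
  invisible(x)
}

#' Write a generated scenario to disk
#'
#' Materializes the generator output as the pipeline's input formats: the two
#' LfQ TSV tables, the PTM flat file, the FASTA sequences and the ledger as
#' JSON.
#'
#' @param syn A `synthetic_data` object from [generate_scenario()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, the directory.
#' @export
write_scenario <- function(syn, dir) {
  stopifnot(inherits(syn, "synthetic_data"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_quant_table(syn$primary, file.path(dir, "quant_primary.tsv"))
  write_quant_table(syn$secondary, file.path(dir, "quant_secondary.tsv"))
  write_ptm_flatfile(syn$records, file.path(dir, "ptm_sites.tsv"))
  write_sequences(syn$sequences, file.path(dir, "sequences.fasta"))
  ledger <- syn$ledger
  ledger$sites <- as.data.frame(ledger$sites)
  jsonlite::write_json(unclass(ledger), file.path(dir, "ledger.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}
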