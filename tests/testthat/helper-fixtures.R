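# Shared fixtures and small builders.

ftc_table <- function() {
  read_quant_table(ptmgrav_example("table1_ftc133.tsv"), "FTC-133")
}

mcf_table <- function() {
  read_quant_table(ptmgrav_example("table1_mcf7.tsv"), "MCF-7")
}

table2_records <- function() {
  read_ptm_flatfile(ptmgrav_example("table2_ptm.tsv"))
}

# Quick quantitation table from bare vectors; genes/accessions generated.
make_quant <- function(lfq_1g, lfq_ug, cell_line = "LINE-A") {
  n <- length(lfq_1g)
  quant_table(
    tibble::tibble(gene = sprintf("G%04d", seq_len(n)),
                   protein_name = sprintf("protein %d", seq_len(n)),
                   accession = sprintf("P%05d", seq_len(n)),
                   lfq_1g = lfq_1g, lfq_ug = lfq_ug),
    cell_line = cell_line)
}

# Random two-condition table for property tests.
random_quant <- function(n, cell_line = "LINE-A") {
  lfq_1g <- round(rlnorm(n, 1, 1.5), 2)
  lfq_1g[runif(n) < 0.3] <- 0
  lfq_ug <- round(lfq_1g * runif(n, 0.1, 4) + rlnorm(n, -1, 1) * (lfq_1g == 0),
                  2)
  make_quant(pmax(lfq_1g, 0), pmax(lfq_ug, 0), cell_line)
}

# Classified records with one protein-class pair per requested group,
# repeated per the planted counts; used to plant exact percentages.
plant_pairs <- function(counts) {
  pools <- list(
    PHOSPHORYLATION = "Phosphoserine",
    LYSINE_N6 = "N6-acetyllysine",
    OTHER_NITROGEN = "N-acetylmethionine",
    SULFUR = "S-nitrosocysteine",
    GLY_LYS_ISOPEPTIDE = "Glycyl lysine isopeptide (Lys-Gly)",
    OTHER = "C-linked (Man)")
  groups <- rep(names(counts), counts)
  n <- length(groups)
  classify_ptms(ptm_records(
    accession = sprintf("P%05d", seq_len(n)),
    modification = unlist(pools[groups], use.names = FALSE),
    position = rep(10L, n),
    window = rep("AAAASAAAA", n)))
}
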