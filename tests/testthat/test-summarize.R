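test_that("protein-class pairs apply the single-count-per-protein rule", {
  cls <- classify_ptms(table2_records())
  # PSMA1: 12 site records collapse to 3 classes
  psma1 <- cls[cls$accession == "P25786", ]
  expect_equal(nrow(psma1), 12L)
  expect_equal(count_protein_class_pairs(psma1), 3L)
  # whole fixture, tallied by hand from the printed table
  expect_equal(count_protein_class_pairs(cls), 15L)
  expect_equal(count_protein_class_pairs(cls[1, ]), 1L)
  # duplication and permutation invariance (tibble subsetting keeps the class)
  dup <- cls[rep(seq_len(nrow(cls)), 2), ]
  expect_equal(count_protein_class_pairs(dup), 15L)
  shuf <- cls[sample(nrow(cls)), ]
  expect_equal(count_protein_class_pairs(shuf), 15L)
  expect_equal(group_percentages(shuf), group_percentages(cls))
  expect_equal(group_percentages(dup), group_percentages(cls))
})

test_that("group percentages recover planted pair counts exactly", {
  cls <- plant_pairs(c(PHOSPHORYLATION = 48, LYSINE_N6 = 19,
                       OTHER_NITROGEN = 13, SULFUR = 4,
                       GLY_LYS_ISOPEPTIDE = 3, OTHER = 13))
  gp <- group_percentages(cls)
  expect_equal(gp$percent,
               c(48.0, 19.0, 13.0, 4.0, 3.0, 13.0))
  expect_equal(sum(gp$percent_raw), 100)

  solo <- plant_pairs(c(PHOSPHORYLATION = 0, LYSINE_N6 = 0,
                        OTHER_NITROGEN = 0, SULFUR = 7,
                        GLY_LYS_ISOPEPTIDE = 0, OTHER = 0))
  gp1 <- group_percentages(solo)
  expect_equal(gp1$percent[gp1$group == "SULFUR"], 100)
  expect_equal(sum(gp1$percent), 100)

  empty <- classify_ptms(ptm_records(character(), character(), integer(),
                                     character()))
  expect_error(group_percentages(empty), "zero records")
})

test_that("fixture percentages match the brute-force tally of its pairs", {
  cls <- classify_ptms(table2_records())
  gp <- group_percentages(cls)
  expect_equal(gp$n, c(2L, 1L, 5L, 2L, 2L, 3L))
  expect_equal(gp$percent_raw, 100 * c(2, 1, 5, 2, 2, 3) / 15)
  expect_equal(sum(gp$percent_raw), 100)
  # raw site records as the alternative denominator
  gp_sites <- group_percentages(cls, denominator = "sites")
  expect_equal(sum(gp_sites$n), 46L)
})

test_that("lysine-N6 protein counts expose both counting modes", {
  cls <- classify_ptms(table2_records())
  expect_equal(count_n6_proteins(cls), 1L)                  # only O43592
  expect_equal(count_n6_proteins(cls, TRUE), 2L)            # + P25786
  empty <- classify_ptms(ptm_records(character(), character(), integer(),
                                     character()))
  expect_equal(count_n6_proteins(empty), 0L)
})

test_that("the full report assembles all fields consistently", {
  sel <- select_candidates(ftc_table(), mcf_table())
  cls <- classify_ptms(table2_records())
  rep <- build_report(sel, cls, total_detected = 5989)
  expect_equal(rep$n_proteins_selected, 69L)
  expect_equal(rep$fraction_of_detected_proteome, 1.2)
  expect_equal(rep$n_classes, 12L)
  expect_equal(rep$n_protein_class_pairs, 15L)
  expect_equal(rep$n_site_records, 46L)
  expect_true(rep$n_protein_class_pairs >= rep$n_classes)
  expect_true(rep$n_proteins_lysine_n6 <=
                rep$n_proteins_lysine_n6_incl_isopeptide)
  expect_true(rep$n_proteins_lysine_n6_incl_isopeptide <=
                rep$n_proteins_with_ptm)
  expect_error(build_report(sel, cls, total_detected = 0), "positive")

  empty <- classify_ptms(ptm_records(character(), character(), integer(),
                                     character()))
  rep0 <- build_report(records = empty)
  expect_equal(rep0$n_protein_class_pairs, 0L)
  expect_null(rep0$group_percentages)
  expect_true(is.na(rep0$fraction_of_detected_proteome))
})

test_that("reports on synthetic data equal the planted ledger", {
  syn <- generate_scenario(synthetic_scenario(seed = 9, n_proteins = 150,
                                              n_selected_planted = 35))
  sel <- select_candidates(syn$primary, syn$secondary)
  rep <- build_report(sel, classify_ptms(syn$records),
                      total_detected = syn$scenario$n_proteins)
  chk <- ledger_check(rep, sel, syn$ledger)
  expect_true(chk$pass)
  expect_true(all(chk$diffs$ok))
})

test_that("per-protein tallies count underlying sites", {
  cls <- classify_ptms(table2_records())
  tally <- protein_class_tally(cls)
  expect_equal(sum(tally$n_sites), 46L)
  expect_equal(nrow(tally), 15L)
  expect_equal(tally$n_sites[tally$accession == "P25786" &
                               tally$canonical_class ==
                               "Glycyl lysine isopeptide (Lys-Gly)"], 8L)
})
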