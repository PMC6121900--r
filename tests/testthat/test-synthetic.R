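test_that("generation is deterministic for a fixed seed", {
  s <- synthetic_scenario(seed = 5, n_proteins = 80, n_selected_planted = 20)
  a <- generate_scenario(s)
  b <- generate_scenario(s)
  expect_identical(a, b)
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  write_scenario(a, d1)
  write_scenario(b, d2)
  for (f in list.files(d1)) {
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)), label = f)
  }
  # a different seed changes the data
  expect_false(identical(
    a$primary,
    generate_scenario(synthetic_scenario(seed = 6, n_proteins = 80,
                                         n_selected_planted = 20))$primary))
})

test_that("planted passers and failers behave as built", {
  syn <- generate_scenario(synthetic_scenario(seed = 7, n_proteins = 400,
                                              n_selected_planted = 40))
  planted <- syn$ledger$selected_accessions
  expect_equal(length(planted), 40L)
  prim <- syn$primary
  in_planted <- prim$accession %in% planted
  expect_true(all(passes_primary_rule(prim$lfq_1g[in_planted],
                                      prim$lfq_ug[in_planted])))
  expect_false(any(passes_primary_rule(prim$lfq_1g[!in_planted],
                                       prim$lfq_ug[!in_planted])))
  # survives the 2-decimal serialization round trip
  path <- withr::local_tempfile(fileext = ".tsv")
  write_quant_table(prim, path)
  back <- read_quant_table(path, "SYN-A")
  expect_equal(select_candidates(back, syn$secondary)$selected |> sort(),
               sort(planted))
})

test_that("generated windows validate by construction", {
  syn <- generate_scenario(synthetic_scenario(seed = 2, n_proteins = 50,
                                              n_selected_planted = 25))
  chk <- validate_window(syn$records, syn$sequences)
  expect_true(all(chk$length_ok))
  expect_true(all(chk$chemistry_ok))
  # and the planted class/group labels agree with the taxonomy module
  cls <- classify_ptms(syn$records)
  expect_equal(cls$canonical_class, syn$ledger$sites$class)
  expect_equal(cls$group, syn$ledger$sites$group)
})

test_that("degenerate and infeasible scenarios are rejected up front", {
  expect_error(synthetic_scenario(seed = 1, n_proteins = 5,
                                  n_selected_planted = 10))
  expect_error(synthetic_scenario(seed = 1, sequence_length = c(20L, 30L)),
               "infeasible")
  expect_error(synthetic_scenario(seed = 1,
                                  class_frequency = c(PHOSPHORYLATION = 0.9,
                                                      LYSINE_N6 = 0.2)),
               "sum to 1|six groups")
  expect_error(synthetic_scenario(seed = 1, fold_range_failers = c(0.5, 2)))
  # a single unmodified protein: empty records, zero-pair ledger
  syn <- generate_scenario(synthetic_scenario(
    seed = 1, n_proteins = 1, n_selected_planted = 1,
    pairs_per_protein = c(0L, 0L)))
  expect_equal(nrow(syn$records), 0L)
  expect_equal(syn$ledger$expected$n_protein_class_pairs, 0L)
})

test_that("ledger_check passes untampered runs and names perturbed fields", {
  syn <- generate_scenario(synthetic_scenario(seed = 4, n_proteins = 100,
                                              n_selected_planted = 30))
  sel <- select_candidates(syn$primary, syn$secondary)
  rep <- build_report(sel, classify_ptms(syn$records),
                      total_detected = syn$scenario$n_proteins)
  expect_true(ledger_check(rep, sel, syn$ledger)$pass)

  tampered <- syn$ledger
  tampered$expected$n_classes <- tampered$expected$n_classes + 1L
  res <- ledger_check(rep, sel, tampered)
  expect_false(res$pass)
  expect_equal(res$diffs$field[!res$diffs$ok], "n_classes")

  expect_error(ledger_check(rep, sel, syn$ledger,
                            scenario_id = "something-else"),
               "mismatch")
})

test_that("multinomial class draws converge to the planted frequencies", {
  syn <- generate_scenario(synthetic_scenario(
    seed = 13, n_proteins = 1250, n_selected_planted = 1250,
    pairs_per_protein = c(4L, 4L), sites_per_pair = c(1L, 1L),
    class_mode = "multinomial"))
  pairs <- unique(syn$ledger$sites[c("accession", "class", "group")])
  counts <- table(factor(pairs$group, levels = names(
    ptmgrav:::SYNTH_DEFAULT_CLASS_FREQUENCY)))
  expect_gte(sum(counts), 5000)
  gof <- stats::chisq.test(counts,
                           p = ptmgrav:::SYNTH_DEFAULT_CLASS_FREQUENCY)
  expect_gt(gof$p.value, 0.01)
})
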