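fixture_graph <- function() {
  build_graph(records = classify_ptms(table2_records()))
}

test_that("quantitation attaches to protein nodes per cell line", {
  ftc <- ftc_table()
  sel <- select_candidates(ftc, mcf_table())
  g <- build_graph(selection = sel, quant = list(ftc, mcf_table()))
  hits <- match_bgp(g, paste0('P09601 hasQuant ?q\n',
                              '?q inCellLine "FTC-133"\n',
                              '?q lfqAt1g ?a\n?q lfqAtMicroG ?b'))
  expect_equal(nrow(hits), 1L)
  expect_equal(as.numeric(hits$a), 14.62)
  expect_equal(as.numeric(hits$b), 108.19)
  # no PTM triples were requested
  expect_equal(nrow(match_bgp(g, "?p hasPTM ?m")), 0L)
  # selection rationale is on the node
  expect_equal(match_bgp(g, "P09601 selectedBy ?r")$r, "fold")
})

test_that("records not resolvable to a selected protein are warned and skipped", {
  sel <- select_candidates(ftc_table(), mcf_table())
  cls <- classify_ptms(table2_records())
  expect_warning(g <- build_graph(selection = sel, records = cls), "P17900")
  expect_equal(nrow(match_bgp(g, "P17900 hasPTM ?m")), 0L)
  expect_gt(nrow(match_bgp(g, "P25786 hasPTM ?m")), 0L)
})

test_that("PTM node identity deduplicates repeated site reports", {
  cls <- classify_ptms(ptm_records(
    accession = c("P12345", "P12345"),
    modification = c("Phosphoserine", "Phosphoserine"),
    position = c(14L, 14L),
    window = c("VTVWSPQGR", "VTVWSPQGR"),
    sources = list("UniProt", "HPRD")))
  g <- build_graph(records = cls)
  expect_equal(nrow(match_bgp(g, "?p hasPTM ?m")), 1L)
  # provenance from both reports is retained on the shared node
  expect_equal(nrow(match_bgp(g, "?m hasSource ?s")), 2L)
})

test_that("graph construction is deterministic", {
  expect_identical(fixture_graph(), fixture_graph())
})

test_that("basic graph patterns answer the worked-example queries", {
  g <- fixture_graph()
  ps <- match_bgp(g, '?p hasPTM ?m\n?m hasClass "Phosphoserine"')
  expect_equal(unique(ps$p), "P25786")
  # ground pattern holding in the graph: one empty binding
  ground <- match_bgp(g, 'P25786 hasAccession "P25786"')
  expect_equal(nrow(ground), 1L)
  expect_equal(ncol(ground), 0L)
  # absent class: no bindings
  expect_equal(nrow(match_bgp(g, '?m hasClass "Phosphohistidine"')), 0L)
  # variables may sit in predicate position
  preds <- match_bgp(g, "P25786 ?pr ?o")
  expect_true("hasPTM" %in% preds$pr)
})

test_that("post-hoc filters emulate numeric range restrictions", {
  g <- fixture_graph()
  late <- match_bgp(g, "?p hasPTM ?m\n?m atPosition ?pos",
                    filter = function(b) as.numeric(b$pos) > 600)
  expect_setequal(unique(late$p), c("O43592", "P07996"))
  expect_true(all(as.numeric(late$pos) > 600))
})

test_that("result sets are invariant under clause permutation", {
  g <- fixture_graph()
  clauses <- c('?p hasPTM ?m', '?m hasGroup "GLY_LYS_ISOPEPTIDE"',
               '?m atPosition ?pos')
  perms <- list(c(1, 2, 3), c(3, 2, 1), c(2, 3, 1))
  keys <- lapply(perms, function(pm) {
    binding_key(match_bgp(g, paste(clauses[pm], collapse = "\n")))
  })
  expect_equal(keys[[2]], keys[[1]])
  expect_equal(keys[[3]], keys[[1]])
})

test_that("matching agrees with exhaustive brute-force enumeration", {
  set.seed(17)
  for (i in 1:20) {
    g <- random_graph(sample(20:120, 1))
    pat <- random_pattern(g, sample(1:3, 1))
    expect_equal(binding_key(match_bgp(g, pat)),
                 binding_key(oracle_match(g, pat)))
  }
})

test_that("serialization round-trips exactly in both formats", {
  toy <- rdf_graph(tibble::tibble(
    subject = c("P12345", "P12345", "ptm/P12345/Phosphoserine/14"),
    predicate = c("hasGene", "hasPTM", "hasWindow"),
    object = c("GENE1", "ptm/P12345/Phosphoserine/14", "VTVWSPQGR"),
    object_type = c("string", "iri", "string")))
  nt <- withr::local_tempfile(fileext = ".nt")
  serialize_graph(toy, nt, "ntriples")
  expect_equal(length(readLines(nt)), 3L)
  expect_setequal(binding_key(match_bgp(parse_graph(nt), "?s ?p ?o")),
                  binding_key(match_bgp(toy, "?s ?p ?o")))

  graph_key <- function(g) {
    do.call(paste, c(as.list(tibble::as_tibble(g)), sep = "\r")) |> sort()
  }
  for (g in list(fixture_graph(),
                 build_graph(selection = select_candidates(
                   ftc_table(), mcf_table()),
                   quant = list(ftc_table(), mcf_table())))) {
    for (fmt in c("ntriples", "turtle")) {
      path <- withr::local_tempfile(
        fileext = if (fmt == "ntriples") ".nt" else ".ttl")
      serialize_graph(g, path, fmt)
      expect_equal(graph_key(parse_graph(path)), graph_key(g))
    }
  }

  # empty graph: a prefix-only Turtle document
  path <- withr::local_tempfile(fileext = ".ttl")
  serialize_graph(rdf_graph(), path, "turtle")
  expect_true(all(grepl("^@prefix|^$", readLines(path))))
  expect_equal(nrow(parse_graph(path)), 0L)

  # awkward literals survive: quotes, tabs, newlines, unicode, parentheses
  odd <- rdf_graph(tibble::tibble(
    subject = "ptm/P1/odd class (x)/1",
    predicate = "hasWindow",
    object = "he said \"hi\"\tand\nleft Å",
    object_type = "string"))
  p <- withr::local_tempfile(fileext = ".nt")
  serialize_graph(odd, p, "ntriples")
  expect_equal(parse_graph(p)$object, odd$object)
})

test_that("unknown formats and undeclared predicates are rejected", {
  expect_error(serialize_graph(rdf_graph(), tempfile(), "rdfxml"))
  expect_error(rdf_graph(tibble::tibble(subject = "s", predicate = "madeUp",
                                        object = "o", object_type = "iri")),
               "vocabulary")
  # explicit registration admits extension predicates
  g <- rdf_graph(tibble::tibble(subject = "P12345",
                                predicate = "reactomePathway",
                                object = "R-HSA-917937",
                                object_type = "string"),
                 extensions = "reactomePathway")
  expect_equal(nrow(g), 1L)
})

test_that("synthetic graphs have the closed-form triple count", {
  syn <- generate_scenario(synthetic_scenario(seed = 3, n_proteins = 60,
                                              n_selected_planted = 15))
  sel <- select_candidates(syn$primary, syn$secondary)
  g <- build_graph(selection = sel,
                   quant = list(syn$primary, syn$secondary),
                   records = classify_ptms(syn$records))
  sites <- syn$ledger$sites
  # per protein: accession + gene + selectedBy + 2 x (hasQuant, inCellLine,
  # lfqAt1g, lfqAtMicroG); per site record: hasPTM + class + group +
  # position + window + sources + one pubmed id
  expected <- 15 * (3 + 2 * 4) + sum(5 + sites$n_sources + 1)
  expect_equal(nrow(g), expected)
})
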