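---
title: "Methods: selection, PTM classification and the knowledge graph"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: selection, PTM classification and the knowledge graph}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ptmgrav)
```

`ptmgrav` models the in-silico half of a spheroid-formation proteomics study:
two-condition label-free quantitation (LfQ) under normal gravity versus
simulated microgravity, followed by annotation of the selected proteins with
experimentally verified posttranslational-modification (PTM) sites and
materialization of everything as a queryable triple graph. This vignette
explains the model behind each stage, the tunable parameters and their
defaults, the numerical choices, and what the synthetic-data generator does
and does not emulate.

## The selection rule

For a protein with monolayer score $q_{1g}$ and spheroid score $q_{\mu g}$
(both dimensionless LfQ scores on the published $\times 10^8$ scale, with 0
meaning "not detected"), the primary rule is

$$
\text{pass} \iff (q_{1g} = 0 \wedge q_{\mu g} > 0)
\;\vee\; \left(q_{1g} > 0 \wedge \frac{q_{\mu g}}{q_{1g}} \ge \theta\right),
\qquad \theta = 1.8 .
$$

A protein undetected in both conditions never passes. The threshold
comparison is inclusive ($\ge$): the worked-example table contains a row
whose ratio is ~1.8297, comfortably inside either reading, but $\ge$ is the
safer interpretation of "1.8-fold higher accumulation" and is the default.

**Concordance.** The study design requires candidates to be independently
up-regulated in a second cell line. The published secondary ratios include
values well below 1.8 (e.g. 122.1/83.81 ≈ 1.46), so the secondary filter
cannot reuse $\theta$; the weakest reading consistent with every published
row is *strict up-regulation*: ratio $> 1$, or zero-baseline detection. Both
thresholds are parameters of `selection_criteria()`; proteins missing from
the secondary table are excluded with an explicit "no secondary evidence"
rationale rather than raising an error. Tables are joined on gene symbol
first, accession as fallback, because the two cell lines share gene symbols.

This is a deterministic threshold filter, not a hypothesis test; no
multiple-testing machinery applies. An upstream detection-count filter
("detected in at least four samples") is not reproducible from the published
69-row table and is therefore out of scope here.

**Numerical tolerance.** Ratio comparisons use a relative tolerance of
$10^{-9}$: a ratio arithmetically equal to the threshold always counts as
meeting it. Without this, two-decimal data whose ratio is exactly 1.8 (such
as 0.09/0.05) can change sides under a positive rescaling of all scores,
because floating-point division is not scale-exact in the last ulp. The
tolerance is five orders of magnitude below the resolution of two-decimal
data, so it never changes a decision on real inputs; it only stabilizes
boundary cases.

## PTM site records and the window convention

Sites are read from dbPTM-style tab-separated flat files: UniProt accession,
verbatim modification text, 1-based position, sequence window, and optional
semicolon-joined source databases, PubMed ids, and accessible surface area
(Å²). Two principles govern parsing:

* **Verbatim preservation.** Modification text is never rewritten at parse
  time; normalization is a separate, later step, so provenance is never
  lost. (The packaged fixture faithfully retains a published spelling
  artifact, "N-acetylmelthionine".)
* **Flag, don't drop.** Rows violating hard invariants (non-positive or
  unparsable position, malformed accession, non-amino-acid window) go into
  an attached error report with row numbers. Windows *longer than the
  convention allows* are not a parse error at all — the published
  five-protein table itself contains one 10-mer — they are flagged by
  `validate_window()` and retained.

The window convention, inferred from the published tables (positions 1 and 2
yield 5- and 6-mers, interior sites 9-mers), is a 9-mer centered on the
modified residue and truncated at the termini:

$$
w = s[\max(1, p-4) \,..\, \min(L, p+4)],
$$

whose center sits at index $\min(p, 5)$. `validate_window()` checks window
length (and, when a FASTA sequence is supplied, re-derives the window),
plus residue chemistry: the center residue must match the class's target
residue (S/T/Y for phospho classes, K for lysine-N6 and the Gly–Lys
isopeptide, C for S-attached classes, N for N-linked glycans, W for
C-mannosylation). Classes without a unique target — O-linked glycans attach
to Ser or Thr — return an indeterminate (`NA`) chemistry verdict, which is
deliberately not a failure.

## Class taxonomy

Normalization strips typographic markup and cross-link partner qualifiers of
the form "(interchain with …)" — these describe the partner protein, not the
chemistry — while retaining chemistry qualifiers like "(Lys-Gly)" or
"(GlcNAc)" that distinguish classes: N-, O- and C-linked glycosylation stay
distinct classes. Known spellings are canonicalized case-insensitively;
unknown classes survive trimmed and title-styled, so an extended vocabulary
degrades gracefully rather than erroring. The function is idempotent.

Grouping applies an ordered first-match-wins rule table over six
residue-chemistry groups: `PHOSPHORYLATION`, `LYSINE_N6`,
`GLY_LYS_ISOPEPTIDE`, `SULFUR`, `OTHER_NITROGEN`, and the total fallback
`OTHER`. Two design points:

* The Gly–Lys isopeptide (the ubiquitin-conjugation signature, chemically an
  amide on the lysine ε-amino group) is its **own** group, not folded into
  `LYSINE_N6`, because the study's published percentage breakdown reports
  them separately. The protein-level "modified on lysine N6" statistic, by
  contrast, is genuinely ambiguous about whether ubiquitination counts, so
  `count_n6_proteins()` exposes both counting modes instead of guessing.
* The rule table ships as data (`inst/extdata/taxonomy.yaml`), not code: the
  dbPTM vocabulary exceeds 80 classes and grows, and extending a YAML list
  is safer than patching pattern code. `taxonomy_config()` accepts a user
  file with the same structure.

## Summary statistics

The counting unit for all headline statistics is the **protein-class pair**:
a protein exhibiting a class counts once however many sites carry it. This
makes every pair-based statistic invariant under duplication and reordering
of site records, which the test suite asserts as properties. Group
percentages are computed at full precision (they sum to exactly 100) and
rounded to one decimal only for presentation; a raw-site-count denominator
is available behind a flag for sensitivity checks. The selected fraction of
the detected proteome is $100 \cdot n_{selected} / n_{detected}$, reported
at one decimal (69/5989 → 1.2).

## The knowledge graph

Nodes live in a single artifact namespace (no live SPARQL endpoint is
assumed): protein nodes are bare accessions, per-cell-line quantitation
nodes `quant/<acc>/<line>`, and PTM nodes `ptm/<acc>/<class>/<position>` —
so repeated literature reports of one site deduplicate into one node,
matching experimentally-verified-site semantics. The vocabulary is fixed
(`hasGene`, `hasAccession`, `hasPTM`, `hasClass`, `hasGroup`, `atPosition`,
`hasWindow`, `hasSource`, `hasPubMed`, `lfqAt1g`, `lfqAtMicroG`,
`selectedBy`, `inCellLine`) plus explicitly registered extensions
(`hasQuant` links protein to quantitation node; `hasASA`; user-registered
predicates such as a pathway mapping). Undeclared predicates are rejected at
construction, which catches typos early.

Querying is conjunctive basic-graph-pattern matching: every binding of the
pattern's variables (allowed in any position, including the predicate) such
that all clauses hold simultaneously, deduplicated to set semantics.
Clauses are joined most-selective-first; the heuristic affects only speed —
correctness is defined by, and tested against, an exhaustive brute-force
enumerator, and the result set is invariant under clause permutation.
`OPTIONAL`, aggregation and full SPARQL are out of scope; numeric-range and
string filters are supported as post-hoc predicates on the binding rows,
which covers the query shapes the analysis needs. Serialization targets
N-Triples and a one-statement-per-line prefixed Turtle subset; both are
emitted in sorted order (byte-deterministic) and parse back to the identical
triple set. The parser handles exactly the subset the serializer emits; it
is not a general Turtle reader.

## The synthetic-data generator

`generate_scenario()` emulates the study's statistical shape so that every
stage can be verified against planted ground truth:

* **LfQ scores** are log-normal (`lfq_log_mean = 0.5`, `lfq_log_sd = 1.4` on
  the log scale), spanning roughly 0.2–600 on the $\times 10^8$ scale like
  the published table; this choice is cosmetic and affects no statistic.
  46% of planted passers are zero-baseline detections, the fraction observed
  in the published table (32/69). Passer fold changes are drawn in
  [1.8, 8], failer fold changes in [0.2, 1.7], and every planted
  (in)equality is re-verified *after* rounding to two decimals, so plants
  survive serialization precision.
* **Pairs and classes.** Each planted-selected protein receives 1–6
  protein-class pairs; pair groups follow the configured frequency vector —
  default 0.48 / 0.189 / 0.128 / 0.04 / 0.034 / 0.129 over the six groups,
  the study's observed breakdown. In `quota` mode the counts are planted
  exactly by largest-remainder apportionment; in `multinomial` mode they are
  drawn independently (a chi-square goodness-of-fit property holds at
  $n \ge 5000$). Group quotas are dealt to proteins by capacity-aware
  sequential draws (a protein never needs more distinct classes of a group
  than its class pool offers), with retry on the rare dead end.
* **Sequences and windows.** Sequences are uniform over the 20-letter
  alphabet; each site's center residue is then overwritten with its class's
  target residue and windows are cut with `expected_window()` from the
  final sequence — so generated records pass length and chemistry
  validation by construction.
* **Determinism.** One integer seed drives everything; per-protein
  quantities come from substreams keyed by protein index, so enlarging a
  scenario leaves earlier proteins' draws unchanged. Two runs of one
  scenario are byte-identical on disk.

The **ledger** records the planted selected set, every site with its true
class and group, and the exact expected value of every summary-report field,
computed from the planted site list with plain base-R tallies — independent
of the summarize module it validates. `ledger_check()` compares field by
field and names any deviation.

What the generator does *not* emulate: peptide-level evidence and missing
data patterns of real mass spectrometry, correlated abundances between cell
lines, biased PTM co-occurrence, or accession/spelling artifacts of curated
databases (one such artifact is exercised by the real fixture instead).
Passing ledger recovery therefore demonstrates correctness of the counting
and selection logic, not robustness to real-data noise upstream of LfQ
scores.

## Problem sizes and budgets

The test suite runs the full property checks at sizes chosen to keep a
complete run under a minute of compute while remaining discriminating:
ledger recovery on 20 scenarios of 120 proteins (30 planted passers each),
oracle equivalence of graph matching on 100 random graphs of up to 200
triples, selection monotonicity and scale invariance over 1000 random
15-protein tables, and round trips on both fixtures and generated data.
Ledger equality is exact at any size, so these sizes trade only statistical
breadth, not strictness.

## Known limitations

* The Turtle reader accepts only the dialect the package writes.
* The taxonomy's canonical list covers the fixture classes plus common dbPTM
  classes; unknown classes normalize to themselves and fall into group
  rules by pattern, which is correct for the dominant naming conventions
  (`N6-…`, `S-…`, `N-…`, `Phospho…`) but assigns genuinely novel naming
  schemes to `OTHER`.
* Pathway membership, subcellular localization and interaction networks are
  representable only through user-supplied extension predicates; no
  external database is contacted.
* The upstream 5989-protein discovery table is not redistributable; the
  proteome-fraction statistic therefore takes the total as a user-supplied
  count.
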