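# PTM class taxonomy: normalization of verbatim modification text into
# canonical class names, and mapping of classes into residue-chemistry groups.
# The rule table ships as data (inst/extdata/taxonomy.yaml) so the large and
# growing dbPTM class vocabulary can be extended without code changes.

PTM_GROUPS <- c("PHOSPHORYLATION", "LYSINE_N6", "OTHER_NITROGEN", "SULFUR",
                "GLY_LYS_ISOPEPTIDE", "OTHER")

#' Load a taxonomy rule table
#'
#' Reads the ordered normalization and grouping rules from YAML. The packaged
#' default covers the classes of the worked-example tables plus common dbPTM
#' classes; users may supply their own file with the same structure
#' (`canonical`: list of `{name, target}`; `group_rules`: ordered list of
#' `{pattern, group}`; `isopeptide_counts_as_n6`: logical).
#'
#' @param path Path to a taxonomy YAML file; default is the packaged table.
#' @return A list of class `taxonomy_config` with elements `canonical`
#'   (tibble `name`, `target`), `group_rules` (tibble `pattern`, `group`) and
#'   `isopeptide_counts_as_n6`.
#' @export
taxonomy_config <- function(path = NULL) {
  use_cache <- is.null(path)
  if (use_cache && !is.null(.taxonomy_cache$default)) {
    return(.taxonomy_cache$default)
  }
  path <- path %||% ptmgrav_example("taxonomy.yaml")
  if (!file.exists(path)) stop("no such taxonomy file: ", path, call. = FALSE)
  raw <- yaml::read_yaml(path)
  canonical <- dplyr::bind_rows(lapply(raw$canonical, function(x) {
    tibble::tibble(name = x$name,
                   target = if (is.null(x$target)) NA_character_ else x$target)
  }))
  group_rules <- dplyr::bind_rows(lapply(raw$group_rules, function(x) {
    tibble::tibble(pattern = x$pattern, group = x$group)
  }))
  bad <- setdiff(group_rules$group, PTM_GROUPS)
  if (length(bad)) {
    stop("unknown group(s) in taxonomy file: ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  out <- structure(list(canonical = canonical,
                        group_rules = group_rules,
                        isopeptide_counts_as_n6 =
                          isTRUE(raw$isopeptide_counts_as_n6)),
                   class = "taxonomy_config")
  if (use_cache) .taxonomy_cache$default <- out
  out
}

.taxonomy_cache <- new.env(parent = emptyenv())

#' Normalize a verbatim modification name into a canonical class
#'
#' Normalization strips typographic markup (`*N*-` italics asterisks) and
#' cross-link partner qualifiers of the form `"(interchain with ...)"`, while
#' preserving chemistry qualifiers such as `"(Lys-Gly)"` or `"(GlcNAc)"` that
#' distinguish classes (N- vs O- vs C-linked glycosylation stay distinct).
#' Known classes are matched case-insensitively and returned in their
#' canonical spelling; unknown strings are kept (trimmed, first letter
#' capitalized, remainder lower-cased). The function is idempotent.
#'
#' @param raw Character vector of verbatim modification names.
#' @param cfg A [taxonomy_config()].
#' @return Character vector of canonical class names.
#' @examples
#' normalize_class(
#'   "Glycyl lysine isopeptide (Lys-Gly) (interchain with G-Cter in ubiquitin)")
#' normalize_class("*N*-linked (GlcNAc)")
#' @export
normalize_class <- function(raw, cfg = taxonomy_config()) {
  stopifnot(is.character(raw), all(nzchar(raw)))
  x <- gsub("*", "", raw, fixed = TRUE)
  x <- gsub("\\s*\\(interchain with [^)]*\\)", "", x, ignore.case = TRUE)
  x <- gsub("\\s+", " ", trimws(x))
  hit <- match(tolower(x), tolower(cfg$canonical$name))
  known <- !is.na(hit)
  x[known] <- cfg$canonical$name[hit[known]]
  if (any(!known)) {
    u <- x[!known]
    first_alpha <- regexpr("[A-Za-z]", u)
    u <- tolower(u)
    has <- first_alpha > 0
    substr(u[has], first_alpha[has], first_alpha[has]) <-
      toupper(substr(u[has], first_alpha[has], first_alpha[has]))
    x[!known] <- u
  }
  x
}

#' Assign a canonical PTM class to a residue-chemistry group
#'
#' Applies the ordered group rules (first match wins): phosphorylation
#' classes; lysine-N6 (epsilon amino group) modifications; the Gly-Lys
#' isopeptide ubiquitin signature (its own group, not folded into lysine-N6,
#' mirroring how the headline percentages are broken down); other
#' sulfur-attached classes; other nitrogen-attached classes; and `OTHER` as
#' the total fallback (O-linked, C-linked, hydroxylation, ...).
#'
#' @param canonical_class Character vector of normalized class names.
#' @param cfg A [taxonomy_config()].
#' @return Factor-like character vector over the six groups.
#' @examples
#' assign_group(c("N6-acetyllysine", "Phosphotyrosine", "C-linked (Man)"))
#' @export
assign_group <- function(canonical_class, cfg = taxonomy_config()) {
  stopifnot(is.character(canonical_class))
  out <- rep("OTHER", length(canonical_class))
  undecided <- rep(TRUE, length(canonical_class))
  for (i in seq_len(nrow(cfg$group_rules))) {
    hit <- undecided & grepl(cfg$group_rules$pattern[i], canonical_class,
                             ignore.case = TRUE)
    out[hit] <- cfg$group_rules$group[i]
    undecided <- undecided & !hit
  }
  out
}

#' Target residue of a canonical PTM class
#'
#' The unique amino acid a class modifies, used by [validate_window()] to
#' check that a window centers on a compatible residue: S/T/Y for the phospho
#' classes, K for lysine-N6 classes and the Gly-Lys isopeptide, C for
#' S-attached classes, N for N-linked glycosylation, W for C-mannosylation.
#' `NA` for classes with no unique target (e.g. O-linked glycans on Ser or
#' Thr) and for classes absent from the rule table.
#'
#' @param canonical_class Character vector of normalized class names.
#' @param cfg A [taxonomy_config()].
#' @return Character vector of one-letter residue codes or `NA`.
#' @export
target_residue <- function(canonical_class, cfg = taxonomy_config()) {
  stopifnot(is.character(canonical_class))
  cfg$canonical$target[match(tolower(canonical_class),
                             tolower(cfg$canonical$name))]
}

#' Classify PTM records
#'
#' Adds the taxonomy columns to a record collection: `canonical_class` (from
#' [normalize_class()]), `group` (from [assign_group()]) and `target_residue`.
#' The verbatim `modification` text is retained, so provenance is never lost.
#'
#' @param records A `ptm_records` tibble.
#' @param cfg A [taxonomy_config()].
#' @return The records with the three classification columns appended; class
#'   `classified_ptms` is added.
#' @examples
#' recs <- read_ptm_flatfile(ptmgrav_example("table2_ptm.tsv"))
#' cls <- classify_ptms(recs)
#' table(cls$group)
#' @export
classify_ptms <- function(records, cfg = taxonomy_config()) {
  stopifnot(inherits(records, "ptm_records"))
  out <- tibble::as_tibble(records)
  out$canonical_class <- normalize_class(out$modification, cfg)
  out$group <- assign_group(out$canonical_class, cfg)
  out$target_residue <- target_residue(out$canonical_class, cfg)
  structure(out, class = c("classified_ptms", "ptm_records",
                           class(tibble::tibble())))
}
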