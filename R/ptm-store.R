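# dbPTM-style flat files: one experimentally verified modification site per
# line, keyed by UniProt accession, with a 1-based position and a short
# sequence window around the modified residue.

PTM_KNOWN_SOURCES <- c("UniProt", "PhosphoSitePlus", "SysPTM", "dbSNO",
                       "MeMo", "HPRD", "Phospho.ELM", "dbPTM")

#' Column mapping for dbPTM-style flat files
#'
#' @param accession,modification,position,window,sources,pubmed_ids,asa Column
#'   names in the file header. `sources` and `pubmed_ids` are
#'   semicolon-joined lists; `asa` (accessible surface area, A^2) is optional
#'   and may be empty.
#' @return A named character vector usable as the `dialect` argument of
#'   [read_ptm_flatfile()].
#' @export
ptm_dialect <- function(accession = "accession", modification = "modification",
                        position = "position", window = "window",
                        sources = "sources", pubmed_ids = "pubmed_ids",
                        asa = "asa") {
  c(accession = accession, modification = modification, position = position,
    window = window, sources = sources, pubmed_ids = pubmed_ids, asa = asa)
}

new_ptm_records <- function(df) {
  structure(tibble::as_tibble(df),
            class = c("ptm_records", class(tibble::tibble())))
}

#' Construct a PTM record collection
#'
#' @param accession UniProt accessions.
#' @param modification Verbatim modification class text (normalization is a
#'   separate, later step so provenance is never lost).
#' @param position 1-based residue positions.
#' @param window Sequence windows (uppercase amino-acid letters).
#' @param sources List of character vectors of source-database labels.
#' @param pubmed_ids List of integer vectors of literature identifiers.
#' @param asa Accessible surface area in A^2, `NA` when not recorded.
#' @return A tibble of class `ptm_records`.
#' @export
ptm_records <- function(accession, modification, position, window,
                        sources = NULL, pubmed_ids = NULL, asa = NULL) {
  n <- length(accession)
  sources <- sources %||% rep(list(character()), n)
  pubmed_ids <- pubmed_ids %||% rep(list(integer()), n)
  asa <- asa %||% rep(NA_real_, n)
  df <- tibble::tibble(accession = as.character(accession),
                       modification = as.character(modification),
                       position = as.integer(position),
                       window = as.character(window),
                       sources = as.list(sources),
                       pubmed_ids = as.list(pubmed_ids),
                       asa = as.double(asa))
  errs <- ptm_record_errors(df)
  if (nrow(errs)) {
    stop("invalid PTM record(s): ",
         paste(sprintf("row %d: %s", errs$row, errs$message), collapse = "; "),
         call. = FALSE)
  }
  new_ptm_records(df)
}

# Hard invariants on parsed rows. Over-long windows are NOT an error here:
# they are retained and flagged by validate_window(), because published
# tables themselves contain an anomalous 10-mer.
ptm_record_errors <- function(df) {
  msgs <- list()
  flag <- function(rows, msg) {
    if (length(rows)) msgs[[length(msgs) + 1L]] <<-
        tibble::tibble(row = rows, message = msg)
  }
  flag(which(is.na(df$position) | df$position < 1L),
       "position must be a positive integer")
  flag(which(!is_valid_accession(df$accession)), "malformed accession")
  flag(which(is.na(df$window) | !nzchar(df$window) |
               !grepl("^[ACDEFGHIKLMNPQRSTVWY]+$", df$window)),
       "window must be non-empty uppercase amino-acid letters")
  flag(which(!is.na(df$asa) & df$asa < 0), "negative accessible surface area")
  if (!length(msgs)) {
    return(tibble::tibble(row = integer(), message = character()))
  }
  dplyr::arrange(dplyr::bind_rows(msgs), .data$row)
}

#' Read a dbPTM-style PTM flat file
#'
#' Parses a tab-separated file of experimentally verified modification sites.
#' Modification text is preserved verbatim. Rows violating hard invariants
#' (unparsable or non-positive position, malformed accession, non-amino-acid
#' window) are collected into an error report attached as the `"errors"`
#' attribute and dropped from the returned records, with a warning; they are
#' never silently discarded. Unknown source-database labels are kept verbatim
#' with a warning.
#'
#' @param path Path to the TSV file.
#' @param dialect Column mapping from [ptm_dialect()]. The `sources`,
#'   `pubmed_ids` and `asa` columns are optional in the file.
#' @return A `ptm_records` tibble; `attr(, "errors")` holds a tibble of
#'   rejected rows (`row`, `message`).
#' @examples
#' recs <- read_ptm_flatfile(ptmgrav_example("table2_ptm.tsv"))
#' nrow(recs)
#' @export
read_ptm_flatfile <- function(path, dialect = ptm_dialect()) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  raw <- readr::read_tsv(path, col_types = readr::cols(.default = "c"),
                         progress = FALSE, na = character())
  required <- dialect[c("accession", "modification", "position", "window")]
  missing <- setdiff(unname(required), names(raw))
  if (length(missing)) {
    stop("input file lacks mandatory column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  get_col <- function(field, default) {
    col <- dialect[[field]]
    if (col %in% names(raw)) raw[[col]] else rep(default, nrow(raw))
  }
  split_list <- function(x, convert = identity) {
    lapply(x, function(s) {
      if (is.na(s) || !nzchar(s)) return(convert(character()))
      convert(strsplit(s, ";", fixed = TRUE)[[1]])
    })
  }
  df <- tibble::tibble(
    accession = raw[[dialect[["accession"]]]],
    modification = raw[[dialect[["modification"]]]],
    position = suppressWarnings(as.integer(raw[[dialect[["position"]]]])),
    window = raw[[dialect[["window"]]]],
    sources = split_list(get_col("sources", "")),
    pubmed_ids = split_list(get_col("pubmed_ids", ""),
                            function(x) as.integer(x)),
    asa = suppressWarnings(as.double(ifelse(nzchar(get_col("asa", "")),
                                            get_col("asa", ""), NA_character_)))
  )
  errs <- ptm_record_errors(df)
  if (nrow(errs)) {
    warning(nrow(errs), " row(s) failed validation and were set aside; ",
            "see attr(, 'errors')", call. = FALSE)
    df <- df[-unique(errs$row), ]
  }
  unknown <- setdiff(unique(unlist(df$sources)), PTM_KNOWN_SOURCES)
  if (length(unknown)) {
    warning("unknown source label(s) kept verbatim: ",
            paste(unknown, collapse = ", "), call. = FALSE)
  }
  out <- new_ptm_records(df)
  attr(out, "errors") <- errs
  out
}

#' Write PTM records as a dbPTM-style flat file
#'
#' Inverse of [read_ptm_flatfile()]: semicolon-joins list columns and leaves
#' absent ASA values empty. Reading the written file reproduces the records
#' exactly, and write-read-write is byte-stable.
#'
#' @param records A `ptm_records` tibble.
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
write_ptm_flatfile <- function(records, path) {
  stopifnot(inherits(records, "ptm_records"))
  out <- tibble::tibble(
    accession = records$accession,
    modification = records$modification,
    position = records$position,
    window = records$window,
    sources = vapply(records$sources, paste, "", collapse = ";"),
    pubmed_ids = vapply(records$pubmed_ids, paste, "", collapse = ";"),
    asa = ifelse(is.na(records$asa), "", as.character(records$asa))
  )
  tryCatch(
    readr::write_tsv(out, path, progress = FALSE),
    error = function(e) stop("cannot write PTM flat file to '", path, "': ",
                             conditionMessage(e), call. = FALSE)
  )
  invisible(path)
}

#' Expected sequence window around a modified residue
#'
#' The window convention of the site tables: up to four residues on each side
#' of the modified position (a 9-mer), truncated at the protein termini, so
#' positions 1 and 2 yield 5- and 6-mers.
#'
#' @param sequence Amino-acid sequence (single string).
#' @param position 1-based position of the modified residue; must lie within
#'   the sequence.
#' @return The window substring; its center residue (index
#'   `min(position, 5)`) is `substr(sequence, position, position)`.
#' @examples
#' expected_window("MTDGDYDYLIK", 2)  # "MTDGDY"
#' expected_window("ABCDEFGHI", 5)    # whole 9-mer
#' @export
expected_window <- function(sequence, position) {
  stopifnot(is.character(sequence), length(sequence) == 1L,
            length(position) == 1L)
  len <- nchar(sequence)
  if (is.na(position) || position < 1L || position > len) {
    stop("position ", position, " outside sequence of length ", len,
         call. = FALSE)
  }
  substr(sequence, max(1L, position - 4L), min(len, position + 4L))
}

#' Validate PTM sequence windows against position and residue chemistry
#'
#' Quality gate over site records. For each record it checks that the window
#' obeys the 9-mer convention (`length_ok`), re-deriving the window from the
#' full protein sequence when one is supplied, and that the window's center
#' residue is chemically compatible with the modification class
#' (`chemistry_ok`; `NA` when the class has no single target residue, e.g.
#' O-linked glycans on Ser/Thr). Failures are flags, never errors: anomalous
#' published rows must stay visible.
#'
#' @param records A `ptm_records` tibble.
#' @param sequences Optional named character vector of protein sequences
#'   (names are accessions), e.g. from [read_sequences()].
#' @param cfg A [taxonomy_config()] used to resolve each class's target
#'   residue.
#' @return A tibble with one row per record: `accession`, `modification`,
#'   `position`, `window`, `expected_center_index`, `center_residue`,
#'   `length_ok`, `chemistry_ok`.
#' @examples
#' recs <- read_ptm_flatfile(ptmgrav_example("table2_ptm.tsv"))
#' chk <- validate_window(recs)
#' sum(!chk$length_ok)  # the one anomalous 10-mer
#' @export
validate_window <- function(records, sequences = NULL,
                            cfg = taxonomy_config()) {
  stopifnot(inherits(records, "ptm_records"))
  n <- nrow(records)
  center_idx <- pmin(records$position, 5L)
  center <- substr(records$window, center_idx, center_idx)
  length_ok <- nchar(records$window) <= 9L
  if (!is.null(sequences)) {
    has_seq <- records$accession %in% names(sequences)
    for (i in which(has_seq)) {
      seq_i <- sequences[[records$accession[i]]]
      length_ok[i] <- length_ok[i] &&
        records$position[i] <= nchar(seq_i) &&
        identical(records$window[i],
                  expected_window(seq_i, records$position[i]))
    }
  }
  canonical <- normalize_class(records$modification, cfg)
  target <- target_residue(canonical, cfg)
  chemistry_ok <- ifelse(is.na(target), NA, center == target)
  tibble::tibble(accession = records$accession,
                 modification = records$modification,
                 position = records$position,
                 window = records$window,
                 expected_center_index = center_idx,
                 center_residue = center,
                 length_ok = length_ok,
                 chemistry_ok = chemistry_ok)
}

#' Read protein sequences from a FASTA file
#'
#' Thin wrapper used for optional window re-derivation; sequence names are
#' truncated to the first whitespace-delimited token of the FASTA header.
#'
#' @param path Path to an (uncompressed) amino-acid FASTA file.
#' @return Named character vector of sequences.
#' @export
read_sequences <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  aa <- Biostrings::readAAStringSet(path)
  out <- as.character(aa)
  names(out) <- sub("\\s.*$", "", names(aa))
  out
}

#' Write protein sequences to a FASTA file
#'
#' @param sequences Named character vector of amino-acid sequences.
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
write_sequences <- function(sequences, path) {
  aa <- Biostrings::AAStringSet(sequences)
  Biostrings::writeXStringSet(aa, path)
  invisible(path)
}
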