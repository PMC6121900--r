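#' Column mapping for LfQ table files
#'
#' Describes how the columns of a tab-separated LfQ file map onto the fields
#' of a quantitation table. The defaults follow the worked-example layout:
#' `gene`, `protein_name`, `accession`, `lfq_1g`, `lfq_ug`.
#'
#' @param gene,protein_name,accession,lfq_1g,lfq_ug Column names in the file
#'   header for the respective fields. `lfq_1g` is the LfQ score of monolayer
#'   cells at normal gravity, `lfq_ug` the score of spheroid cells under
#'   simulated microgravity, both on the published x 10^8 scale.
#' @return A named character vector usable as the `dialect` argument of
#'   [read_quant_table()].
#' @export
quant_dialect <- function(gene = "gene", protein_name = "protein_name",
                          accession = "accession", lfq_1g = "lfq_1g",
                          lfq_ug = "lfq_ug") {
  c(gene = gene, protein_name = protein_name, accession = accession,
    lfq_1g = lfq_1g, lfq_ug = lfq_ug)
}

#' Construct and validate a quantitation table
#'
#' A quantitation table holds one row per protein with its identity and the
#' two-condition LfQ scores for a single cell line. Scores of exactly 0 mean
#' "not detected" and are meaningful, never missing.
#'
#' @param records A data frame with columns `gene`, `protein_name`,
#'   `accession`, `lfq_1g`, `lfq_ug`.
#' @param cell_line Label of the cell line the table belongs to (e.g.
#'   `"FTC-133"`).
#' @param provenance Free-text source tag recorded on the table.
#' @return A tibble of class `quant_table` with attributes `cell_line` and
#'   `provenance`.
#' @export
quant_table <- function(records, cell_line, provenance = "unspecified") {
  stopifnot(is.character(cell_line), length(cell_line) == 1L, nzchar(cell_line))
  records <- tibble::as_tibble(records)
  required <- c("gene", "protein_name", "accession", "lfq_1g", "lfq_ug")
  missing <- setdiff(required, names(records))
  if (length(missing)) {
    stop("quant table is missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  records <- records[required]
  records$lfq_1g <- as.double(records$lfq_1g)
  records$lfq_ug <- as.double(records$lfq_ug)
  validate_quant_records(records, cell_line)
  structure(records,
            cell_line = cell_line,
            provenance = provenance,
            class = c("quant_table", class(tibble::tibble())))
}

validate_quant_records <- function(records, cell_line) {
  if (nrow(records) == 0L) return(invisible(records))
  neg <- which(records$lfq_1g < 0 | records$lfq_ug < 0)
  if (length(neg)) {
    stop("negative LfQ score(s) in row(s): ", paste(neg, collapse = ", "),
         call. = FALSE)
  }
  bad_acc <- which(!is_valid_accession(records$accession))
  if (length(bad_acc)) {
    stop("malformed UniProt accession(s) in row(s): ",
         paste(sprintf("%d (%s)", bad_acc, records$accession[bad_acc]),
               collapse = ", "),
         call. = FALSE)
  }
  dup <- records$gene[duplicated(records$gene)]
  if (length(dup)) {
    stop("duplicate (gene, cell_line) entries for cell line ", cell_line,
         ": ", paste(unique(dup), collapse = ", "), call. = FALSE)
  }
  invisible(records)
}

#' Cell line of a quantitation table
#' @param table A `quant_table`.
#' @return The cell-line label.
#' @export
cell_line <- function(table) {
  attr(table, "cell_line")
}

#' Read a two-condition LfQ proteome table
#'
#' Reads a tab-separated file with one header row and one row per protein.
#' Zeros are meaningful ("not detected" in that condition). Malformed numeric
#' cells and duplicate genes are reported with their row numbers.
#'
#' @param path Path to the TSV file.
#' @param cell_line Cell-line label to record on the table.
#' @param dialect Column mapping from [quant_dialect()].
#' @return A [quant_table()].
#' @examples
#' ftc <- read_quant_table(ptmgrav_example("table1_ftc133.tsv"), "FTC-133")
#' nrow(ftc)
#' @export
read_quant_table <- function(path, cell_line, dialect = quant_dialect()) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  raw <- readr::read_tsv(path, col_types = readr::cols(.default = "c"),
                         progress = FALSE, na = character())
  missing <- setdiff(unname(dialect), names(raw))
  if (length(missing)) {
    stop("input file lacks mandatory column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  records <- tibble::tibble(
    gene = raw[[dialect[["gene"]]]],
    protein_name = raw[[dialect[["protein_name"]]]],
    accession = raw[[dialect[["accession"]]]],
    lfq_1g = suppressWarnings(as.double(raw[[dialect[["lfq_1g"]]]])),
    lfq_ug = suppressWarnings(as.double(raw[[dialect[["lfq_ug"]]]]))
  )
  bad <- which(is.na(records$lfq_1g) | is.na(records$lfq_ug))
  if (length(bad)) {
    stop("non-numeric LfQ value(s) in data row(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  quant_table(records, cell_line = cell_line, provenance = path)
}

#' Write a quantitation table
#'
#' Serializes a [quant_table()] as tab-separated text with LfQ scores at two
#' decimal places (the precision of the published tables), such that
#' [read_quant_table()] reproduces the table field for field.
#'
#' @param table A `quant_table`.
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
write_quant_table <- function(table, path) {
  stopifnot(inherits(table, "quant_table"))
  out <- tibble::as_tibble(table)
  out$lfq_1g <- format_fixed(out$lfq_1g, 2)
  out$lfq_ug <- format_fixed(out$lfq_ug, 2)
  tryCatch(
    readr::write_tsv(out, path, progress = FALSE),
    error = function(e) stop("cannot write quant table to '", path, "': ",
                             conditionMessage(e), call. = FALSE)
  )
  invisible(path)
}
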