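# Internal helpers shared across modules.

# UniProt accession shape: 6 or 10 alphanumerics, first a letter.
ACCESSION_PATTERN <- "^[A-Za-z][A-Za-z0-9]{5}([A-Za-z0-9]{4})?$"

AMINO_ACIDS <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

is_valid_accession <- function(x) {
  grepl(ACCESSION_PATTERN, x)
}

#' Path to a packaged example file
#'
#' Convenience accessor for the plain-text fixtures shipped with the package:
#' the worked-example LfQ tables (`table1_ftc133.tsv`, `table1_mcf7.tsv`), the
#' worked-example PTM site table (`table2_ptm.tsv`) and the default taxonomy
#' rule table (`taxonomy.yaml`).
#'
#' @param file File name within `inst/extdata`. With no argument, lists the
#'   available files.
#' @return A file path, or a character vector of file names.
#' @examples
#' ptmgrav_example()
#' ptmgrav_example("table1_ftc133.tsv")
#' @export
ptmgrav_example <- function(file = NULL) {
  if (is.null(file)) {
    return(dir(system.file("extdata", package = "ptmgrav")))
  }
  path <- system.file("extdata", file, package = "ptmgrav")
  if (!nzchar(path)) {
    stop("no packaged example file '", file, "'", call. = FALSE)
  }
  path
}

# Derive a valid 32-bit seed for a keyed substream.
substream_seed <- function(seed, key) {
  as.integer((as.numeric(seed) * 131071 + as.numeric(key)) %% 2147483647)
}

# sample() without the scalar-expansion surprise: always samples from x.
resample <- function(x, size, replace = FALSE, prob = NULL) {
  x[sample.int(length(x), size, replace = replace, prob = prob)]
}

# Format a numeric at fixed decimals without scientific notation.
format_fixed <- function(x, digits = 2) {
  formatC(x, format = "f", digits = digits)
}
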