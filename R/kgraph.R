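# Triple-based knowledge graph over a small fixed vocabulary, with
# basic-graph-pattern (BGP) matching and N-Triples / Turtle serialization.
# Local identifiers live in a single artifact namespace; no live SPARQL
# endpoint is assumed.

KG_BASE_RESOURCE <- "http://ptmgrav.org/resource/"
KG_BASE_VOCAB <- "http://ptmgrav.org/vocab#"
XSD_NS <- "http://www.w3.org/2001/XMLSchema#"

KG_CORE_PREDICATES <- c("hasGene", "hasAccession", "hasPTM", "hasClass",
                        "hasGroup", "atPosition", "hasWindow", "hasSource",
                        "hasPubMed", "lfqAt1g", "lfqAtMicroG", "selectedBy",
                        "inCellLine")
KG_DEFAULT_EXTENSIONS <- c("hasQuant", "hasASA")

#' Construct a knowledge graph from triples
#'
#' A graph is a deduplicated set of (subject, predicate, object) triples.
#' Subjects are local identifiers in the artifact namespace; predicates come
#' from the core vocabulary (`hasGene`, `hasAccession`, `hasPTM`, `hasClass`,
#' `hasGroup`, `atPosition`, `hasWindow`, `hasSource`, `hasPubMed`,
#' `lfqAt1g`, `lfqAtMicroG`, `selectedBy`, `inCellLine`) or from explicitly
#' registered extension predicates; objects are identifiers or typed literals.
#'
#' @param triples A data frame with columns `subject`, `predicate`, `object`
#'   (all character) and `object_type` (one of `"iri"`, `"string"`,
#'   `"integer"`, `"double"`).
#' @param extensions Extra predicate names allowed beyond the core
#'   vocabulary. Defaults to `hasQuant` (protein to per-cell-line
#'   quantitation node) and `hasASA` (accessible surface area literal);
#'   user-supplied mappings (e.g. `reactomePathway`) register here.
#' @return A tibble of class `rdf_graph`.
#' @export
rdf_graph <- function(triples = NULL, extensions = KG_DEFAULT_EXTENSIONS) {
  if (is.null(triples)) {
    triples <- tibble::tibble(subject = character(), predicate = character(),
                              object = character(), object_type = character())
  }
  triples <- tibble::as_tibble(triples)
  required <- c("subject", "predicate", "object", "object_type")
  missing <- setdiff(required, names(triples))
  if (length(missing)) {
    stop("triples lack column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  triples <- triples[required]
  bad_type <- setdiff(unique(triples$object_type),
                      c("iri", "string", "integer", "double"))
  if (length(bad_type)) {
    stop("unknown object_type(s): ", paste(bad_type, collapse = ", "),
         call. = FALSE)
  }
  allowed <- c(KG_CORE_PREDICATES, extensions)
  bad <- setdiff(unique(triples$predicate), allowed)
  if (length(bad)) {
    stop("predicate(s) outside the declared vocabulary: ",
         paste(bad, collapse = ", "),
         "; register them via the 'extensions' argument", call. = FALSE)
  }
  triples <- dplyr::distinct(triples)
  structure(triples, extensions = extensions,
            class = c("rdf_graph", class(tibble::tibble())))
}

kg_triple <- function(subject, predicate, object, object_type) {
  tibble::tibble(subject = subject, predicate = predicate,
                 object = as.character(object), object_type = object_type)
}

#' Build the knowledge graph from pipeline results
#'
#' Materializes one protein node per accession, one quantitation node per
#' (accession, cell line), and one PTM node per (accession, canonical class,
#' position) — so repeated literature reports of one site deduplicate, in line
#' with experimentally-verified-site semantics. Triples are deduplicated and
#' the build is deterministic for identical inputs.
#'
#' When a selection is supplied, records whose accession does not resolve to a
#' selected protein are reported in a warning and skipped (their triples are
#' not emitted).
#'
#' @param selection Optional `selection_result`; restricts the protein
#'   universe to the selected accessions and attaches `selectedBy` rationale.
#' @param quant A `quant_table` or list of them; attaches `lfqAt1g` /
#'   `lfqAtMicroG` per cell line on a quantitation node linked by the
#'   `hasQuant` extension predicate.
#' @param records Optional `classified_ptms` (see [classify_ptms()]).
#' @return An [rdf_graph()].
#' @examples
#' recs <- classify_ptms(read_ptm_flatfile(ptmgrav_example("table2_ptm.tsv")))
#' g <- build_graph(records = recs)
#' nrow(g)
#' @export
build_graph <- function(selection = NULL, quant = list(), records = NULL) {
  if (inherits(quant, "quant_table")) quant <- list(quant)
  stopifnot(all(vapply(quant, inherits, TRUE, "quant_table")))
  if (!is.null(records)) {
    if (!inherits(records, "classified_ptms")) {
      stop("records must be classified first; see classify_ptms()",
           call. = FALSE)
    }
  }

  genes <- character()
  for (qt in quant) genes[qt$accession] <- qt$gene
  if (!is.null(selection)) {
    universe <- selection$selected
    sel_rule <- selection$rationale$rule[match(universe,
                                               selection$rationale$accession)]
    genes[selection$rationale$accession] <- selection$rationale$gene
  } else {
    universe <- unique(c(unlist(lapply(quant, function(q) q$accession)),
                         if (!is.null(records)) records$accession))
    sel_rule <- NULL
  }

  parts <- list()
  add <- function(x) parts[[length(parts) + 1L]] <<- x

  add(kg_triple(universe, "hasAccession", universe, "string"))
  known_gene <- universe %in% names(genes)
  if (any(known_gene)) {
    add(kg_triple(universe[known_gene], "hasGene",
                  unname(genes[universe[known_gene]]), "string"))
  }
  if (!is.null(sel_rule)) {
    add(kg_triple(universe, "selectedBy", sel_rule, "string"))
  }

  for (qt in quant) {
    keep <- qt$accession %in% universe
    if (!any(keep)) next
    acc <- qt$accession[keep]
    qnode <- paste0("quant/", acc, "/", cell_line(qt))
    add(kg_triple(acc, "hasQuant", qnode, "iri"))
    add(kg_triple(qnode, "inCellLine", cell_line(qt), "string"))
    add(kg_triple(qnode, "lfqAt1g", qt$lfq_1g[keep], "double"))
    add(kg_triple(qnode, "lfqAtMicroG", qt$lfq_ug[keep], "double"))
  }

  if (!is.null(records) && nrow(records)) {
    resolvable <- records$accession %in% universe
    if (any(!resolvable)) {
      warning("PTM record(s) with accession(s) not resolvable to a selected ",
              "protein were skipped: ",
              paste(unique(records$accession[!resolvable]), collapse = ", "),
              call. = FALSE)
      records <- records[resolvable, ]
    }
    if (nrow(records)) {
      pnode <- paste0("ptm/", records$accession, "/",
                      records$canonical_class, "/", records$position)
      add(kg_triple(records$accession, "hasPTM", pnode, "iri"))
      add(kg_triple(pnode, "hasClass", records$canonical_class, "string"))
      add(kg_triple(pnode, "hasGroup", records$group, "string"))
      add(kg_triple(pnode, "atPosition", records$position, "integer"))
      add(kg_triple(pnode, "hasWindow", records$window, "string"))
      n_src <- lengths(records$sources)
      if (any(n_src > 0)) {
        add(kg_triple(rep(pnode, n_src), "hasSource",
                      unlist(records$sources), "string"))
      }
      n_pm <- lengths(records$pubmed_ids)
      if (any(n_pm > 0)) {
        add(kg_triple(rep(pnode, n_pm), "hasPubMed",
                      unlist(records$pubmed_ids), "integer"))
      }
      has_asa <- !is.na(records$asa)
      if (any(has_asa)) {
        add(kg_triple(pnode[has_asa], "hasASA", records$asa[has_asa],
                      "double"))
      }
    }
  }

  rdf_graph(dplyr::bind_rows(parts))
}

# ---- basic graph patterns ---------------------------------------------------

#' Parse a basic graph pattern from text
#'
#' Minimal pattern syntax: one clause per line, three whitespace-separated
#' terms. `?name` is a variable (usable in any position, including the
#' predicate), `"..."` a string literal, a bare number an integer or double
#' literal, and any other token a local identifier / predicate name.
#'
#' @param text A single string (clauses separated by newlines) or a character
#'   vector of clause lines. Empty lines and `#` comment lines are ignored.
#' @return A tibble of class `bgp_pattern` with columns `s`, `p`, `o`,
#'   `s_type`, `p_type`, `o_type`.
#' @examples
#' parse_pattern('?p hasPTM ?m
#'                ?m hasClass "Phosphoserine"')
#' @export
parse_pattern <- function(text) {
  lines <- unlist(strsplit(text, "\n", fixed = TRUE))
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (!length(lines)) stop("pattern has no clauses", call. = FALSE)
  clauses <- lapply(lines, function(line) {
    toks <- parse_pattern_terms(line)
    if (length(toks$value) != 3L) {
      stop("malformed pattern clause (need 3 terms): '", line, "'",
           call. = FALSE)
    }
    tibble::tibble(s = toks$value[1], p = toks$value[2], o = toks$value[3],
                   s_type = toks$type[1], p_type = toks$type[2],
                   o_type = toks$type[3])
  })
  pat <- dplyr::bind_rows(clauses)
  if (any(pat$s_type %in% c("string", "integer", "double"))) {
    stop("literals cannot appear in subject position", call. = FALSE)
  }
  structure(pat, class = c("bgp_pattern", class(tibble::tibble())))
}

# Tokenize one clause line, honoring quoted strings.
parse_pattern_terms <- function(line) {
  toks <- regmatches(line, gregexpr('"[^"]*"|\\S+', line))[[1]]
  type <- vapply(toks, function(t) {
    if (startsWith(t, "?")) "var"
    else if (startsWith(t, "\"")) "string"
    else if (grepl("^-?[0-9]+$", t)) "integer"
    else if (grepl("^-?[0-9]*\\.[0-9]+$", t)) "double"
    else "iri"
  }, "", USE.NAMES = FALSE)
  value <- ifelse(type == "string", substr(toks, 2, nchar(toks) - 1L), toks)
  value[type == "var"] <- substring(value[type == "var"], 2L)
  value[type %in% c("integer", "double")] <-
    as.character(as.numeric(value[type %in% c("integer", "double")]))
  list(value = value, type = type)
}

#' Read a graph pattern from a file
#'
#' @param path Path to a pattern file (one clause per line; see
#'   [parse_pattern()]).
#' @return A `bgp_pattern`.
#' @export
read_pattern <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  parse_pattern(paste(readLines(path), collapse = "\n"))
}

# Tagged term keys make matching type-faithful: an IRI "X" and a string
# literal "X" are distinct terms.
tag_term <- function(value, type) {
  code <- c(iri = "R", string = "S", integer = "I", double = "D")[type]
  paste0(code, ":", value)
}

#' Match a basic graph pattern against a graph
#'
#' Returns every binding of the pattern's variables to graph terms such that
#' all clauses hold simultaneously (conjunctive basic-graph-pattern
#' semantics, deduplicated to set semantics). Clause evaluation order does
#' not affect the result; internally clauses are joined most-selective
#' first, a heuristic that only affects speed. Variables may occupy the
#' predicate position.
#'
#' @param graph An [rdf_graph()].
#' @param pattern A `bgp_pattern` (see [parse_pattern()]) or a string parsed
#'   with it.
#' @param filter Optional predicate applied post-hoc to the binding rows
#'   (a function taking the bindings tibble and returning a logical vector),
#'   emulating numeric-range or string-equality query restrictions.
#' @return A tibble with one column per variable and one row per solution.
#'   A ground pattern (no variables) that holds in the graph yields a single
#'   zero-column row; one that does not hold yields zero rows.
#' @examples
#' recs <- classify_ptms(read_ptm_flatfile(ptmgrav_example("table2_ptm.tsv")))
#' g <- build_graph(records = recs)
#' match_bgp(g, '?p hasPTM ?m\n?m hasClass "Phosphoserine"')
#' @export
match_bgp <- function(graph, pattern, filter = NULL) {
  stopifnot(inherits(graph, "rdf_graph"))
  if (is.character(pattern)) pattern <- parse_pattern(pattern)
  stopifnot(inherits(pattern, "bgp_pattern"))

  g <- tibble::as_tibble(graph)
  g$s_key <- tag_term(g$subject, "iri")
  g$p_key <- tag_term(g$predicate, "iri")
  g$o_key <- tag_term(g$object, g$object_type)

  clause_rows <- function(cl) {
    keep <- rep(TRUE, nrow(g))
    if (cl$s_type != "var") keep <- keep & g$s_key == tag_term(cl$s, "iri")
    if (cl$p_type != "var") keep <- keep & g$p_key == tag_term(cl$p, "iri")
    if (cl$o_type != "var") keep <- keep & g$o_key == tag_term(cl$o, cl$o_type)
    m <- g[keep, c("s_key", "p_key", "o_key")]
    # project onto this clause's variables, honoring repeated variables
    vars <- character()
    cols <- character()
    for (pos in c("s", "p", "o")) {
      if (cl[[paste0(pos, "_type")]] == "var") {
        v <- cl[[pos]]
        col <- paste0(pos, "_key")
        if (v %in% vars) {
          m <- m[m[[cols[match(v, vars)]]] == m[[col]], , drop = FALSE]
        } else {
          vars <- c(vars, v)
          cols <- c(cols, col)
        }
      }
    }
    out <- m[cols]
    names(out) <- vars
    dplyr::distinct(out)
  }

  clauses <- lapply(seq_len(nrow(pattern)), function(i) pattern[i, ])
  tables <- lapply(clauses, clause_rows)
  # most-selective-first join order (fewest candidate rows first)
  tables <- tables[order(vapply(tables, nrow, 0L))]

  bindings <- tibble::tibble(.rows = 1L)
  for (tb in tables) {
    shared <- intersect(names(bindings), names(tb))
    bindings <- if (length(shared)) {
      dplyr::inner_join(bindings, tb, by = shared)
    } else if (ncol(tb) == 0L) {
      if (nrow(tb) == 0L) bindings[0, , drop = FALSE] else bindings
    } else {
      dplyr::cross_join(bindings, tb)
    }
    if (nrow(bindings) == 0L) break
  }

  bindings <- dplyr::distinct(bindings)
  # untag: drop the type prefix from term keys for presentation
  for (col in names(bindings)) {
    bindings[[col]] <- substring(bindings[[col]], 3L)
  }
  if (!is.null(filter)) {
    keep <- filter(bindings)
    stopifnot(is.logical(keep), length(keep) == nrow(bindings))
    bindings <- bindings[keep & !is.na(keep), , drop = FALSE]
  }
  bindings
}

# ---- serialization ----------------------------------------------------------

escape_literal <- function(x) {
  x <- gsub("\\", "\\\\", x, fixed = TRUE)
  x <- gsub("\"", "\\\"", x, fixed = TRUE)
  x <- gsub("\n", "\\n", x, fixed = TRUE)
  x <- gsub("\r", "\\r", x, fixed = TRUE)
  gsub("\t", "\\t", x, fixed = TRUE)
}

unescape_literal <- function(x) {
  x <- gsub("\\t", "\t", x, fixed = TRUE)
  x <- gsub("\\r", "\r", x, fixed = TRUE)
  x <- gsub("\\n", "\n", x, fixed = TRUE)
  x <- gsub("\\\"", "\"", x, fixed = TRUE)
  gsub("\\\\", "\\", x, fixed = TRUE)
}

encode_local <- function(id) {
  vapply(id, URLencode, "", reserved = TRUE, USE.NAMES = FALSE)
}

decode_local <- function(x) {
  vapply(x, URLdecode, "", USE.NAMES = FALSE)
}

format_object <- function(object, object_type, style = c("nt", "ttl")) {
  style <- match.arg(style)
  lit <- paste0("\"", escape_literal(object), "\"")
  switch(object_type,
    iri = if (style == "nt") {
      paste0("<", KG_BASE_RESOURCE, encode_local(object), ">")
    } else {
      paste0("kb:", encode_local(object))
    },
    string = lit,
    integer = if (style == "nt") {
      paste0(lit, "^^<", XSD_NS, "integer>")
    } else {
      paste0(lit, "^^xsd:integer")
    },
    double = if (style == "nt") {
      paste0(lit, "^^<", XSD_NS, "double>")
    } else {
      paste0(lit, "^^xsd:double")
    }
  )
}

#' Serialize a knowledge graph to N-Triples or Turtle
#'
#' Writes the graph in a W3C standard text format. Triples are emitted in
#' sorted order so serialization is byte-deterministic; parsing the output
#' with [parse_graph()] reproduces the triple set exactly. The Turtle output
#' uses one prefixed statement per line (namespace prefixes `kb:` for
#' resources, `pv:` for the vocabulary).
#'
#' @param graph An [rdf_graph()].
#' @param path Output file path.
#' @param format `"ntriples"` or `"turtle"`.
#' @return Invisibly, `path`.
#' @export
serialize_graph <- function(graph, path, format = c("ntriples", "turtle")) {
  stopifnot(inherits(graph, "rdf_graph"))
  format <- match.arg(format)
  g <- tibble::as_tibble(graph)
  g <- g[order(g$subject, g$predicate, g$object, g$object_type), ]
  objects <- function(style) {
    vapply(seq_len(nrow(g)), function(i) {
      format_object(g$object[i], g$object_type[i], style)
    }, "")
  }
  if (format == "ntriples") {
    lines <- if (nrow(g) == 0L) character() else {
      paste0("<", KG_BASE_RESOURCE, encode_local(g$subject), "> ",
             "<", KG_BASE_VOCAB, g$predicate, "> ", objects("nt"), " .")
    }
  } else {
    header <- c(paste0("@prefix kb: <", KG_BASE_RESOURCE, "> ."),
                paste0("@prefix pv: <", KG_BASE_VOCAB, "> ."),
                paste0("@prefix xsd: <", XSD_NS, "> ."),
                "")
    body <- if (nrow(g) == 0L) character() else {
      paste0("kb:", encode_local(g$subject), " pv:", g$predicate, " ",
             objects("ttl"), " .")
    }
    lines <- c(header, body)
  }
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

parse_object_token <- function(tok, prefixes) {
  if (startsWith(tok, "<")) {
    iri <- sub("^<(.*)>$", "\\1", tok)
    return(list(object = compact_iri(iri, KG_BASE_RESOURCE),
                object_type = "iri"))
  }
  if (startsWith(tok, "\"")) {
    m <- regmatches(tok, regexec('^"(.*)"(\\^\\^(<[^>]+>|[A-Za-z]+:[A-Za-z]+))?$',
                                 tok))[[1]]
    if (!length(m)) stop("malformed literal: ", tok, call. = FALSE)
    value <- unescape_literal(m[2])
    dt <- m[4]
    if (!nzchar(dt)) return(list(object = value, object_type = "string"))
    dt_iri <- if (startsWith(dt, "<")) {
      sub("^<(.*)>$", "\\1", dt)
    } else {
      pieces <- strsplit(dt, ":", fixed = TRUE)[[1]]
      paste0(prefixes[[pieces[1]]], pieces[2])
    }
    type <- switch(sub(XSD_NS, "", dt_iri, fixed = TRUE),
                   integer = "integer", double = "double",
                   decimal = "double", "string")
    if (type %in% c("integer", "double")) {
      value <- as.character(as.numeric(value))
    }
    return(list(object = value, object_type = type))
  }
  # prefixed name
  pieces <- strsplit(tok, ":", fixed = TRUE)[[1]]
  base <- prefixes[[pieces[1]]]
  if (is.null(base)) stop("unknown prefix: ", pieces[1], call. = FALSE)
  local <- paste(pieces[-1], collapse = ":")
  list(object = compact_iri(paste0(base, local), KG_BASE_RESOURCE),
       object_type = "iri")
}

compact_iri <- function(iri, base) {
  ifelse(startsWith(iri, base), decode_local(sub(base, "", iri, fixed = TRUE)),
         iri)
}

#' Parse a knowledge graph from N-Triples or Turtle
#'
#' Reads the formats emitted by [serialize_graph()]: full-IRI N-Triples, and
#' the one-statement-per-line prefixed Turtle subset. `parse_graph()` after
#' `serialize_graph()` is the identity on the triple set.
#'
#' @param path Input file path.
#' @param format `"ntriples"` or `"turtle"`; guessed from the `.nt` / `.ttl`
#'   extension when omitted.
#' @param extensions Extension predicates to admit (see [rdf_graph()]).
#' @return An [rdf_graph()].
#' @export
parse_graph <- function(path, format = NULL,
                        extensions = KG_DEFAULT_EXTENSIONS) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  format <- format %||% switch(tools::file_ext(path),
                               nt = "ntriples", ttl = "turtle",
                               stop("cannot guess format of '", path,
                                    "'; pass format=", call. = FALSE))
  stopifnot(format %in% c("ntriples", "turtle"))
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  prefixes <- list()
  triples <- list()
  for (line in lines) {
    if (!nzchar(line) || startsWith(line, "#")) next
    if (startsWith(line, "@prefix")) {
      m <- regmatches(line,
                      regexec("^@prefix\\s+([A-Za-z0-9]*):\\s+<([^>]*)>\\s*\\.$",
                              line))[[1]]
      if (!length(m)) stop("malformed @prefix line: ", line, call. = FALSE)
      prefixes[[m[2]]] <- m[3]
      next
    }
    stmt <- sub("\\s*\\.$", "", line)
    toks <- regmatches(stmt,
                       gregexpr('"(\\\\.|[^"\\\\])*"(\\^\\^(<[^>]+>|[A-Za-z]+:[A-Za-z]+))?|<[^>]*>|\\S+',
                                stmt))[[1]]
    if (length(toks) != 3L) {
      stop("malformed statement (need 3 terms): ", line, call. = FALSE)
    }
    resolve_iri <- function(tok) {
      if (startsWith(tok, "<")) return(sub("^<(.*)>$", "\\1", tok))
      pieces <- strsplit(tok, ":", fixed = TRUE)[[1]]
      base <- prefixes[[pieces[1]]]
      if (is.null(base)) stop("unknown prefix: ", pieces[1], call. = FALSE)
      paste0(base, paste(pieces[-1], collapse = ":"))
    }
    subject <- compact_iri(resolve_iri(toks[1]), KG_BASE_RESOURCE)
    predicate <- sub(KG_BASE_VOCAB, "", resolve_iri(toks[2]), fixed = TRUE)
    obj <- parse_object_token(toks[3], prefixes)
    triples[[length(triples) + 1L]] <-
      tibble::tibble(subject = subject, predicate = predicate,
                     object = obj$object, object_type = obj$object_type)
  }
  if (!length(triples)) return(rdf_graph(extensions = extensions))
  rdf_graph(dplyr::bind_rows(triples), extensions = extensions)
}
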