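# Independent brute-force oracles. These deliberately share no code with the
# implementation: plain loops, no join heuristics.

# Row-by-row evaluation of the printed selection rule, sharing only the
# documented one-part-in-1e9 ratio tolerance with the implementation.
oracle_select <- function(primary, secondary = NULL,
                          fold_threshold = 1.8, concordance_fold = 1.0) {
  picked <- character()
  for (i in seq_len(nrow(primary))) {
    a <- primary$lfq_1g[i]
    b <- primary$lfq_ug[i]
    primary_ok <- (a == 0 && b > 0) ||
      (a > 0 && b / a >= fold_threshold * (1 - 1e-9))
    if (!primary_ok) next
    if (!is.null(secondary)) {
      j <- which(secondary$gene == primary$gene[i])
      if (!length(j)) j <- which(secondary$accession == primary$accession[i])
      if (!length(j)) next
      sa <- secondary$lfq_1g[j[1]]
      sb <- secondary$lfq_ug[j[1]]
      if (!((sa == 0 && sb > 0) ||
            (sa > 0 && sb / sa > concordance_fold * (1 + 1e-9)))) {
        next
      }
    }
    picked <- c(picked, primary$accession[i])
  }
  picked
}

oracle_tag <- function(value, type) {
  paste0(c(iri = "R", string = "S", integer = "I", double = "D")[type], ":",
         value)
}

# Exhaustive extension of partial variable assignments, clause by clause in
# the pattern's own order, deduplicated at the end.
oracle_match <- function(graph, pattern) {
  g <- tibble::as_tibble(graph)
  gs <- oracle_tag(g$subject, "iri")
  gp <- oracle_tag(g$predicate, "iri")
  go <- oracle_tag(g$object, g$object_type)
  sols <- list(stats::setNames(character(), character()))
  for (ci in seq_len(nrow(pattern))) {
    cl <- pattern[ci, ]
    keep <- rep(TRUE, nrow(g))
    if (cl$s_type != "var") keep <- keep & gs == oracle_tag(cl$s, "iri")
    if (cl$p_type != "var") keep <- keep & gp == oracle_tag(cl$p, "iri")
    if (cl$o_type != "var") keep <- keep & go == oracle_tag(cl$o, cl$o_type)
    rows <- which(keep)
    new <- list()
    for (sol in sols) {
      for (r in rows) {
        ext <- sol
        ok <- TRUE
        for (pos in c("s", "p", "o")) {
          if (cl[[paste0(pos, "_type")]] == "var") {
            v <- cl[[pos]]
            val <- switch(pos, s = gs[r], p = gp[r], o = go[r])
            if (v %in% names(ext)) {
              if (!identical(unname(ext[v]), val)) { ok <- FALSE; break }
            } else {
              ext[v] <- val
            }
          }
        }
        if (ok) new[[length(new) + 1L]] <- ext
      }
    }
    sols <- unique(new)
    if (!length(sols)) break
  }
  vars <- unique(unlist(lapply(sols, names)))
  if (!length(sols)) {
    out <- tibble::as_tibble(stats::setNames(
      replicate(length(vars), character(), simplify = FALSE), vars))
    return(out)
  }
  if (!length(vars)) return(tibble::tibble(.rows = 1L))
  out <- tibble::as_tibble(stats::setNames(
    lapply(vars, function(v) {
      substring(vapply(sols, function(s) unname(s[v]), ""), 3L)
    }), vars))
  dplyr::distinct(out)
}

# Canonical form for comparing binding sets regardless of row/column order.
binding_key <- function(bindings) {
  if (nrow(bindings) == 0L) return(character(0))
  if (ncol(bindings) == 0L) return(rep("<empty>", nrow(bindings)))
  cols <- sort(names(bindings))
  sort(do.call(paste, c(lapply(cols, function(c) {
    paste0(c, "=", bindings[[c]])
  }), sep = "|")))
}

# Random graph over a small vocabulary with deliberate term reuse so that
# joins actually fire.
random_graph <- function(n_triples) {
  subjects <- sprintf("node%d", 1:8)
  predicates <- c("hasPTM", "hasClass", "hasGroup", "atPosition", "hasGene",
                  "hasSource")
  obj_pool <- list(
    list(o = sprintf("node%d", 1:8), t = "iri"),
    list(o = c("alpha", "beta", "gamma"), t = "string"),
    list(o = as.character(1:4), t = "integer"),
    list(o = c("1.5", "2.25"), t = "double"))
  rows <- lapply(seq_len(n_triples), function(i) {
    pool <- obj_pool[[sample.int(4, 1)]]
    tibble::tibble(subject = sample(subjects, 1),
                   predicate = sample(predicates, 1),
                   object = sample(pool$o, 1),
                   object_type = pool$t)
  })
  rdf_graph(dplyr::bind_rows(rows))
}

# Random pattern derived from the graph's own triples (so matches exist),
# with positions replaced by shared variables at random.
random_pattern <- function(graph, n_clauses) {
  g <- tibble::as_tibble(graph)
  vars <- c("x", "y", "z")
  lines <- vapply(seq_len(n_clauses), function(i) {
    r <- g[sample.int(nrow(g), 1), ]
    s <- if (runif(1) < 0.5) paste0("?", sample(vars, 1)) else r$subject
    p <- if (runif(1) < 0.3) paste0("?", sample(vars, 1)) else r$predicate
    o <- if (runif(1) < 0.5) {
      paste0("?", sample(vars, 1))
    } else {
      switch(r$object_type,
             iri = r$object,
             string = paste0("\"", r$object, "\""),
             r$object)
    }
    paste(s, p, o)
  }, "")
  parse_pattern(paste(lines, collapse = "\n"))
}
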