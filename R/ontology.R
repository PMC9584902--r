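#' Parse a Gene Ontology OBO file
#'
#' Minimal OBO 1.2 stanza parser covering what descendant-closure and
#' enrichment need: term ids, names, `is_a` and (optionally) `part_of`
#' relationships, `alt_id` aliases and `is_obsolete` flags. Obsolete terms
#' are dropped; `alt_id`s are recorded so annotations using them resolve to
#' the canonical id. The edge set must be acyclic and may only reference
#' declared terms.
#'
#' @param path Path to an OBO file (a subset ontology is fine).
#' @param relations Relationship types to keep as child-to-parent edges.
#'   `is_a` is always included; `part_of` is included by default.
#' @return An object of class `ontology_dag`: list with `terms` (tibble
#'   `id`, `name`), `edges` (tibble `child`, `parent`, `relation`),
#'   `alt_ids` (named character vector alias -> canonical) and `roots`.
#' @export
parse_obo <- function(path, relations = c("is_a", "part_of")) {
  if (!file.exists(path)) stop("OBO file not found: ", path, call. = FALSE)
  relations <- union("is_a", relations)
  lines <- readLines(path, warn = FALSE)

  # split into [Term] stanzas
  stanza_start <- which(lines == "[Term]")
  other_start <- which(grepl("^\\[", lines) & lines != "[Term]")
  bounds <- sort(c(stanza_start, other_start, length(lines) + 1L))

  ids <- character(0); names_ <- character(0)
  child <- character(0); parent <- character(0); rel <- character(0)
  alt_alias <- character(0); alt_canon <- character(0)

  for (s in stanza_start) {
    end <- min(bounds[bounds > s]) - 1L
    block <- lines[s:end]
    get <- function(key) {
      hit <- grepl(paste0("^", key, ":"), block)
      trimws(sub(paste0("^", key, ":\\s*"), "", block[hit]))
    }
    if (length(get("is_obsolete")) > 0 && any(get("is_obsolete") == "true")) next
    id <- get("id")
    if (length(id) != 1) next
    nm <- get("name")
    ids <- c(ids, id)
    names_ <- c(names_, if (length(nm) >= 1) nm[1] else NA_character_)

    for (p in get("is_a")) {
      # strip trailing "! name" comments
      p_id <- trimws(sub("\\s*!.*$", "", p))
      child <- c(child, id); parent <- c(parent, p_id); rel <- c(rel, "is_a")
    }
    for (r in get("relationship")) {
      r <- trimws(sub("\\s*!.*$", "", r))
      parts <- strsplit(r, "\\s+")[[1]]
      if (length(parts) >= 2 && parts[1] %in% relations) {
        child <- c(child, id); parent <- c(parent, parts[2])
        rel <- c(rel, parts[1])
      }
    }
    for (a in get("alt_id")) {
      alt_alias <- c(alt_alias, a); alt_canon <- c(alt_canon, id)
    }
  }

  keep <- rel %in% relations
  edges <- tibble::tibble(child = child[keep], parent = parent[keep],
                          relation = rel[keep])
  undeclared <- setdiff(unique(c(edges$child, edges$parent)), ids)
  if (length(undeclared) > 0) {
    stop("edge references undeclared term(s): ",
         paste(undeclared, collapse = ", "), call. = FALSE)
  }

  dag <- structure(list(
    terms = tibble::tibble(id = ids, name = names_),
    edges = edges,
    alt_ids = stats::setNames(alt_canon, alt_alias),
    roots = setdiff(ids, edges$child)
  ), class = "ontology_dag")

  cyc <- find_cycle(dag)
  if (!is.null(cyc)) {
    stop("ontology graph contains a cycle: ", paste(cyc, collapse = " -> "),
         call. = FALSE)
  }
  dag
}

#' @export
print.ontology_dag <- function(x, ...) {
  cat("<ontology_dag>", nrow(x$terms), "terms,", nrow(x$edges), "edges,",
      length(x$roots), "root(s)\n")
  invisible(x)
}

dag_igraph <- function(dag) {
  igraph::graph_from_data_frame(
    dag$edges[, c("child", "parent")],
    directed = TRUE,
    vertices = dag$terms$id)
}

find_cycle <- function(dag) {
  g <- dag_igraph(dag)
  if (igraph::is_dag(g)) return(NULL)
  # report one cycle: take any vertex on a cycle via feedback arc heuristics
  comp <- igraph::components(g, mode = "strong")
  big <- which(comp$csize > 1)[1]
  members <- names(comp$membership)[comp$membership == big]
  members
}

canonical_term <- function(dag, term) {
  ifelse(term %in% dag$terms$id, term,
         unname(dag$alt_ids[term]))
}

#' Descendant closure of an ontology term
#'
#' Returns the term together with every term below it in the DAG, i.e. every
#' term whose child-to-parent chain reaches `root`. A gene annotated to any
#' member of the closure belongs to the root term's gene subset.
#'
#' @param dag An `ontology_dag`.
#' @param root A term id present in the DAG.
#' @return Character vector of term ids (root included), sorted.
#' @export
descendant_closure <- function(dag, root) {
  if (!root %in% dag$terms$id) {
    stop("term not in ontology: ", root, call. = FALSE)
  }
  g <- dag_igraph(dag)
  # edges run child -> parent, so descendants are vertices that reach root
  reach <- igraph::subcomponent(g, root, mode = "in")
  sort(names(reach))
}

ancestor_closure <- function(dag, term) {
  g <- dag_igraph(dag)
  sort(names(igraph::subcomponent(g, term, mode = "out")))
}

#' Read gene-to-GO annotations
#'
#' Supports three dialects: GAF 2.x (columns 2 = gene, 5 = GO id, rows with
#' a NOT qualifier in column 4 skipped, comment lines starting with `!`
#' ignored); InterProScan TSV (gene in column 1, `|`-separated GO ids in the
#' final annotation column); and a plain two-column `gene<TAB>GO` table.
#' Malformed GO ids (not `GO:` + 7 digits) are skipped with a warning and
#' counted in the `n_skipped` attribute. Duplicate gene-term pairs collapse
#' to one.
#'
#' @param path Path to the annotation file.
#' @param format One of `"gaf"`, `"interproscan_tsv"`, `"two_column_tsv"`.
#' @return A tibble `gene_id`, `term` of direct annotations, with attribute
#'   `n_skipped`.
#' @export
read_annotations <- function(path,
                             format = c("gaf", "interproscan_tsv",
                                        "two_column_tsv")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("annotation file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^!", lines) & nzchar(lines)]
  fields <- strsplit(lines, "\t", fixed = TRUE)

  pairs <- switch(format,
    gaf = {
      keep <- vapply(fields, function(f)
        length(f) >= 5 && !grepl("\\bNOT\\b", f[4]), logical(1))
      do.call(rbind, lapply(fields[keep], function(f) c(f[2], f[5])))
    },
    interproscan_tsv = {
      out <- lapply(fields, function(f) {
        gos <- unlist(strsplit(f[length(f)], "|", fixed = TRUE))
        gos <- gos[grepl("^GO:", gos)]
        if (length(gos) == 0) return(NULL)
        cbind(f[1], gos)
      })
      do.call(rbind, out)
    },
    two_column_tsv = {
      do.call(rbind, lapply(fields, function(f) c(f[1], f[2])))
    })

  if (is.null(pairs) || nrow(pairs) == 0) {
    ann <- tibble::tibble(gene_id = character(), term = character())
    attr(ann, "n_skipped") <- 0L
    return(ann)
  }
  term_ok <- grepl("^GO:[0-9]{7}$", pairs[, 2])
  n_skipped <- sum(!term_ok)
  if (n_skipped > 0) {
    warning(n_skipped, " annotation row(s) with malformed GO id skipped",
            call. = FALSE)
  }
  ann <- tibble::tibble(gene_id = pairs[term_ok, 1], term = pairs[term_ok, 2])
  ann <- dplyr::distinct(ann)
  attr(ann, "n_skipped") <- n_skipped
  ann
}

#' Genes annotated within a term's descendant closure
#'
#' Builds the functional gene subset for a root term: genes with at least
#' one direct annotation to the root or any of its descendants. This is how
#' the development-associated (GO:0032502) and metabolism-associated
#' (GO:0008152) subsets are defined.
#'
#' @param annotations Tibble `gene_id`, `term` of direct annotations.
#' @param dag An `ontology_dag`.
#' @param root Root term id.
#' @return Character vector of gene ids (may be empty, with a warning:
#'   sparse functional annotation is common for non-model species).
#' @export
select_gene_subset <- function(annotations, dag, root) {
  closure <- descendant_closure(dag, root)
  terms <- canonical_term(dag, annotations$term)
  genes <- sort(unique(annotations$gene_id[!is.na(terms) & terms %in% closure]))
  if (length(genes) == 0) {
    warning("no genes annotated within the closure of ", root, call. = FALSE)
  }
  genes
}
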