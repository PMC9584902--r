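#' Reference gene set: positively expressed genes
#'
#' The background for over-representation tests is the set of genes with
#' positive estimated expression in the dataset — i.e. FPKM > 0 in at least
#' one sample. Genes never observed expressed cannot be "drawn" by the
#' experiment and would dilute the test.
#'
#' @param expr Expression tibble on the FPKM scale.
#' @return Character vector of gene ids.
#' @export
positive_expression_reference <- function(expr) {
  sc <- expr_scale(expr)
  if (!is.na(sc) && sc != "fpkm") {
    stop("the positive-expression reference is defined on the FPKM scale",
         call. = FALSE)
  }
  m <- as.matrix(expr[, sample_cols(expr), drop = FALSE])
  genes <- expr$gene_id[rowSums(m > 0) > 0]
  if (length(genes) == 0) stop("no gene has positive expression", call. = FALSE)
  genes
}

#' GO term over-representation by Fisher's exact test
#'
#' Tests each GO term for enrichment of a study gene set against a
#' reference (background) set. Direct annotations are first propagated up
#' the ontology: a gene annotated to a term is annotated to all its
#' ancestors, so parent terms aggregate their descendants' genes. For every
#' term with at least one study gene, the one-sided Fisher exact p-value
#' (hypergeometric upper tail) is computed on the 2x2 table of study/rest
#' by term/not, and Benjamini-Hochberg adjustment is applied across the
#' tested terms.
#'
#' @param study Character vector of gene ids; must be a subset of
#'   `reference`.
#' @param reference Background gene ids (see
#'   [positive_expression_reference()]).
#' @param annotations Tibble `gene_id`, `term` of direct annotations.
#' @param dag An `ontology_dag` used for ancestor propagation.
#' @param alpha Adjusted-p threshold for the `significant` flag.
#' @return An object of class `go_enrichment`: a tibble with `term`,
#'   `name`, `study_count`, `study_total`, `pop_count`, `pop_total`, `p`,
#'   `p_adj`, `significant`, sorted by `p`.
#' @export
fisher_enrichment <- function(study, reference, annotations, dag,
                              alpha = 0.05) {
  extra <- setdiff(study, reference)
  if (length(extra) > 0) {
    stop("study genes missing from the reference set: ",
         paste(utils::head(extra, 5), collapse = ", "),
         if (length(extra) > 5) ", ..." else "", call. = FALSE)
  }
  ann <- propagate_annotations(annotations, dag)
  ann <- ann[ann$gene_id %in% reference, ]

  pop_total <- length(reference)
  study_total <- length(study)

  by_term <- split(ann$gene_id, ann$term)
  rows <- purrr::map(names(by_term), function(tm) {
    genes <- unique(by_term[[tm]])
    k <- sum(genes %in% study)
    if (k == 0) return(NULL)
    K <- length(genes)
    # hypergeometric upper tail: P(X >= k)
    p <- stats::phyper(k - 1, K, pop_total - K, study_total,
                       lower.tail = FALSE)
    tibble::tibble(term = tm, study_count = k, study_total = study_total,
                   pop_count = K, pop_total = pop_total, p = p)
  })
  out <- dplyr::bind_rows(rows)
  if (nrow(out) == 0) {
    out <- tibble::tibble(term = character(), name = character(),
                          study_count = integer(), study_total = integer(),
                          pop_count = integer(), pop_total = integer(),
                          p = numeric(), p_adj = numeric(),
                          significant = logical())
    class(out) <- c("go_enrichment", class(out))
    return(out)
  }
  out$p_adj <- stats::p.adjust(out$p, method = "BH")
  out$significant <- out$p_adj <= alpha
  out <- dplyr::left_join(out, dag$terms, by = c(term = "id"))
  out <- dplyr::relocate(out, "name", .after = "term")
  out <- dplyr::arrange(out, .data$p)
  class(out) <- c("go_enrichment", class(out))
  out
}

# gene annotated to a term is annotated to every ancestor of that term
propagate_annotations <- function(annotations, dag) {
  terms <- canonical_term(dag, annotations$term)
  known <- !is.na(terms)
  uniq <- unique(terms[known])
  g <- dag_igraph(dag)
  anc <- stats::setNames(lapply(uniq, function(tm) {
    names(igraph::subcomponent(g, tm, mode = "out"))
  }), uniq)
  expanded <- purrr::map2(annotations$gene_id[known], terms[known],
                          function(g, tm) {
    tibble::tibble(gene_id = g, term = anc[[tm]])
  })
  dplyr::distinct(dplyr::bind_rows(expanded))
}

#' @method tidy go_enrichment
#' @export
tidy.go_enrichment <- function(x, ...) tibble::as_tibble(unclass(x))

#' @method glance go_enrichment
#' @export
glance.go_enrichment <- function(x, ...) {
  tibble::tibble(
    n_terms_tested = nrow(x),
    n_significant = sum(x$significant),
    min_p_adj = if (nrow(x) > 0) min(x$p_adj) else NA_real_
  )
}
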