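# fixture builders and independent oracles shared across tests

tiny_expression <- function() {
  tibble::tibble(
    gene_id = c("g1", "g2", "g3"),
    e1 = c(0, 1, 3),
    l1 = c(1, 2, 4),
    p1 = c(0.5, 1.5, 3.5),
    a1 = c(2, 3, 5)
  )
}

tiny_samples <- function() {
  tibble::tibble(
    sample_id = c("e1", "l1", "p1", "a1"),
    major_stage = c("embryo", "larva", "pupa", "adult"),
    time_order = 1:4,
    sex = "mixed",
    tissue = "whole_body"
  )
}

# expression tibble from a genes x samples matrix + per-sample stages
expr_from_matrix <- function(m, sample_ids = colnames(m),
                             gene_ids = rownames(m)) {
  if (is.null(gene_ids)) gene_ids <- paste0("g", seq_len(nrow(m)))
  if (is.null(sample_ids)) sample_ids <- paste0("s", seq_len(ncol(m)))
  out <- tibble::as_tibble(as.data.frame(m))
  names(out) <- sample_ids
  dplyr::bind_cols(tibble::tibble(gene_id = gene_ids), out)
}

samples_for <- function(sample_ids, stages, sex = "mixed") {
  tibble::tibble(
    sample_id = sample_ids,
    major_stage = stages,
    time_order = seq_along(sample_ids),
    sex = sex,
    tissue = "whole_body"
  )
}

# 5-term toy ontology: A <- B <- C, A <- D, E isolated
toy_obo_lines <- function() {
  c("format-version: 1.2", "",
    "[Term]", "id: GO:0000001", "name: A", "",
    "[Term]", "id: GO:0000002", "name: B", "is_a: GO:0000001 ! A", "",
    "[Term]", "id: GO:0000003", "name: C", "is_a: GO:0000002 ! B", "",
    "[Term]", "id: GO:0000004", "name: D", "is_a: GO:0000001 ! A", "",
    "[Term]", "id: GO:0000005", "name: E", "")
}

write_toy_obo <- function(lines = toy_obo_lines()) {
  path <- withr::local_tempfile(fileext = ".obo",
                                .local_envir = parent.frame())
  writeLines(lines, path)
  path
}

# random DAG over n terms: edges only child -> lower-index parent
random_dag_edges <- function(n, p = 0.15) {
  ids <- sprintf("GO:%07d", seq_len(n))
  child <- character(0); parent <- character(0)
  for (i in 2:n) {
    parents <- which(stats::runif(i - 1) < p)
    if (length(parents) == 0) parents <- sample.int(i - 1, 1)
    child <- c(child, rep(ids[i], length(parents)))
    parent <- c(parent, ids[parents])
  }
  list(ids = ids,
       edges = tibble::tibble(child = child, parent = parent,
                              relation = "is_a"))
}

dag_from_edges <- function(ids, edges) {
  structure(list(
    terms = tibble::tibble(id = ids, name = ids),
    edges = edges,
    alt_ids = stats::setNames(character(0), character(0)),
    roots = setdiff(ids, edges$child)
  ), class = "ontology_dag")
}

# oracle: descendants of root by explicit stack-based DFS over
# parent -> children adjacency, independent of igraph
dfs_descendants <- function(edges, root) {
  children <- split(edges$child, edges$parent)
  seen <- character(0)
  stack <- root
  while (length(stack) > 0) {
    v <- stack[length(stack)]
    stack <- stack[-length(stack)]
    if (v %in% seen) next
    seen <- c(seen, v)
    stack <- c(stack, children[[v]])
  }
  sort(seen)
}

# oracle: Spearman as explicit mid-ranks + textbook Pearson formula
oracle_spearman <- function(x, y) {
  rx <- rank(x); ry <- rank(y)
  num <- sum((rx - mean(rx)) * (ry - mean(ry)))
  den <- sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
  num / den
}

# oracle: hypergeometric upper-tail P(X >= k) by explicit choose() summation
oracle_hyper_tail <- function(k, K, N, n) {
  kk <- k:min(K, n)
  sum(choose(K, kk) * choose(N - K, n - kk)) / choose(N, n)
}
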