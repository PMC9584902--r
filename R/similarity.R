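#' Spearman rank correlation
#'
#' Pearson correlation of mid-ranks, the similarity measure used throughout
#' this package. A constant vector has no rank ordering, so the coefficient
#' is undefined and `NA` is returned rather than a silent zero (a zero would
#' fake dissimilarity).
#'
#' @param x,y Numeric vectors of equal length >= 3; ties allowed.
#' @return The correlation in `[-1, 1]`, or `NA` if either vector is
#'   constant.
#' @export
#' @examples
#' spearman_rho(c(1, 2, 3), c(10, 20, 30))
spearman_rho <- function(x, y) {
  if (length(x) != length(y)) {
    stop("x and y must have equal length (", length(x), " vs ", length(y), ")",
         call. = FALSE)
  }
  if (length(x) < 3) stop("need at least 3 observations", call. = FALSE)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) return(NA_real_)
  stats::cor(x, y, method = "spearman")
}

#' Pairwise Spearman similarity between samples
#'
#' Computes the Spearman correlation over genes for every pair of sample
#' columns, optionally restricted to a gene subset (e.g. the
#' development-associated genes). Expects log-scale expression.
#'
#' @param expr Expression tibble on the log scale.
#' @param subset Optional character vector of gene ids; `NULL` uses all
#'   genes. At least 3 subset genes must be present in the table.
#' @return An object of class `stage_cor`: the labelled correlation matrix
#'   (symmetric, unit diagonal) with the gene count used stored as attribute
#'   `n_genes`.
#' @export
pairwise_similarity <- function(expr, subset = NULL) {
  m <- expr_matrix(expr, subset)
  rho <- stats::cor(m, method = "spearman")
  # guard: constant columns give NA; keep them explicit
  diag(rho) <- 1
  structure(rho, class = c("stage_cor", "matrix"), n_genes = nrow(m))
}

expr_matrix <- function(expr, subset = NULL) {
  if (!is.null(subset)) {
    hit <- expr$gene_id %in% subset
    if (sum(hit) < 3) {
      stop("fewer than 3 subset genes present in the expression table (",
           sum(hit), ")", call. = FALSE)
    }
    expr <- expr[hit, ]
  }
  m <- as.matrix(expr[, sample_cols(expr), drop = FALSE])
  rownames(m) <- expr$gene_id
  if (nrow(m) < 3) stop("need at least 3 genes", call. = FALSE)
  m
}

#' @export
print.stage_cor <- function(x, ...) {
  cat("<stage_cor> Spearman similarity over", attr(x, "n_genes"), "genes\n")
  print(round(unclass(x), 3))
  invisible(x)
}

#' @method tidy stage_cor
#' @export
tidy.stage_cor <- function(x, ...) {
  m <- unclass(x)
  tibble::tibble(
    sample_1 = rep(rownames(m), times = ncol(m)),
    sample_2 = rep(colnames(m), each = nrow(m)),
    rho = as.vector(m)
  )
}

#' Similarity of every sample to the embryonic state
#'
#' The embryonic reference is the per-gene mean log expression over all
#' embryo samples; each sample (embryo samples included) is then correlated
#' against it with Spearman's rho and results are ordered by `time_order`.
#' This is the profile whose pupal bump, relative to the larval trough,
#' signals reversion toward the embryonic transcriptome.
#'
#' @param expr Expression tibble on the log scale.
#' @param samples Sample metadata covering every sample column.
#' @param subset Optional gene subset.
#' @return A tibble `sample_id`, `major_stage`, `time_order`, `rho` ordered
#'   by time.
#' @export
embryo_similarity_profile <- function(expr, samples, subset = NULL) {
  samples <- validate_sample_table(samples)
  m <- expr_matrix(expr, subset)
  ids <- colnames(m)
  meta <- samples[match(ids, samples$sample_id), ]
  if (anyNA(meta$sample_id)) {
    stop("samples absent from metadata: ",
         paste(ids[is.na(meta$sample_id)], collapse = ", "), call. = FALSE)
  }
  emb <- ids[meta$major_stage == "embryo"]
  if (length(emb) == 0) stop("no embryo samples in the dataset", call. = FALSE)
  ref <- rowMeans(m[, emb, drop = FALSE])
  if (stats::sd(ref) == 0) {
    stop("embryonic reference profile is constant; ",
         "Spearman similarity is undefined", call. = FALSE)
  }
  rho <- vapply(ids, function(s) spearman_rho(m[, s], ref), numeric(1))
  out <- tibble::tibble(
    sample_id = ids,
    major_stage = meta$major_stage,
    time_order = meta$time_order,
    rho = unname(rho)
  )
  dplyr::arrange(out, .data$time_order)
}
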