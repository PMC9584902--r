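#' Random-gene-set null for a subset-restricted statistic
#'
#' Assesses whether a functional gene subset carries more of an observed
#' signal than a random set of the same size: `B` gene sets of size
#' `length(subset)` are drawn uniformly without replacement from all genes
#' in the table, the statistic is recomputed on each, and the observed value
#' is placed on that null. The quantile is the fraction of null values at or
#' below the observed value; the p-value is the add-one estimator
#' `(1 + #null >= observed) / (B + 1)`, which never returns zero.
#'
#' @param expr Expression tibble the statistic reads from (the gene universe
#'   is its `gene_id` column).
#' @param subset Character vector of gene ids, length >= 3.
#' @param metric A function taking a character vector of gene ids and
#'   returning a single number. Build one with [metric_pair_rho()] or
#'   [metric_recap_rho()], or supply your own.
#' @param B Number of resampled gene sets.
#' @param seed Integer seed; same seed gives bit-identical draws.
#' @return An object of class `resampling_result` with fields `observed`,
#'   `null_values`, `quantile`, `p_value`, `B`, `seed`.
#' @export
resample_metric <- function(expr, subset, metric, B = 999, seed) {
  if (missing(seed)) stop("seed is required for reproducible resampling",
                          call. = FALSE)
  genes <- expr$gene_id
  subset <- intersect(subset, genes)
  k <- length(subset)
  if (k < 3) stop("subset must contain at least 3 genes from the table",
                  call. = FALSE)
  if (k > length(genes)) stop("subset larger than the gene universe", call. = FALSE)
  if (B < 1) stop("B must be >= 1", call. = FALSE)

  observed <- metric(subset)
  if (!is.finite(observed)) {
    stop("metric is undefined on the observed subset", call. = FALSE)
  }

  null_values <- withr::with_seed(seed, {
    vapply(seq_len(B), function(b) metric(sample(genes, k)), numeric(1))
  })
  if (anyNA(null_values)) {
    stop("metric returned NA on ", sum(is.na(null_values)),
         " resampled gene set(s)", call. = FALSE)
  }

  structure(list(
    observed = observed,
    null_values = null_values,
    quantile = sum(null_values <= observed) / B,
    p_value = (1 + sum(null_values >= observed)) / (B + 1),
    B = B,
    seed = seed
  ), class = "resampling_result")
}

#' Statistic: Spearman similarity of one sample pair on a gene set
#'
#' Returns a metric function for [resample_metric()] measuring the Spearman
#' correlation between two named samples restricted to a gene set.
#'
#' @param expr Log-scale expression tibble.
#' @param sample_1,sample_2 Sample column names.
#' @return A function of a gene-id vector.
#' @export
metric_pair_rho <- function(expr, sample_1, sample_2) {
  for (s in c(sample_1, sample_2)) {
    if (!s %in% sample_cols(expr)) stop("no such sample: ", s, call. = FALSE)
  }
  x_all <- expr[[sample_1]]
  y_all <- expr[[sample_2]]
  ids <- expr$gene_id
  function(gene_ids) {
    i <- match(gene_ids, ids)
    spearman_rho(x_all[i], y_all[i])
  }
}

#' Statistic: cross-transition recapitulation correlation on a gene set
#'
#' Returns a metric function measuring the correlation between the
#' embryo-to-larva and pupa-to-adult log fold changes over a gene set.
#'
#' @param stage_expr Stage-averaged log-scale tibble (see [stage_average()]).
#' @param method `"spearman"` or `"pearson"`.
#' @return A function of a gene-id vector.
#' @export
metric_recap_rho <- function(stage_expr, method = c("spearman", "pearson")) {
  method <- match.arg(method)
  el <- stage_expr$larva - stage_expr$embryo
  pa <- stage_expr$adult - stage_expr$pupa
  ids <- stage_expr$gene_id
  function(gene_ids) {
    i <- match(gene_ids, ids)
    if (method == "spearman") spearman_rho(el[i], pa[i])
    else stats::cor(el[i], pa[i])
  }
}

#' @export
print.resampling_result <- function(x, ...) {
  cat("<resampling_result> observed =", signif(x$observed, 4),
      "| quantile =", signif(x$quantile, 4),
      "| p =", signif(x$p_value, 4),
      "| B =", x$B, "| seed =", x$seed, "\n")
  invisible(x)
}

#' @method tidy resampling_result
#' @export
tidy.resampling_result <- function(x, ...) {
  tibble::tibble(null_value = x$null_values)
}

#' @method glance resampling_result
#' @export
glance.resampling_result <- function(x, ...) {
  tibble::tibble(
    observed = x$observed,
    quantile = x$quantile,
    p_value = x$p_value,
    B = x$B,
    seed = x$seed
  )
}
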