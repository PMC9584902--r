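#' Log fold change across a stage transition
#'
#' Per-gene difference of mean log2 expression between two major stages
#' (`to` minus `from`). Genes whose absolute fold change exceeds the
#' threshold are flagged significant; the conventional cutoff is 1.5 on the
#' log2 scale.
#'
#' @param stage_expr Stage-averaged log-scale tibble with columns `embryo`,
#'   `larva`, `pupa`, `adult` (see [stage_average()]).
#' @param from_stage,to_stage Major-stage names.
#' @param threshold Absolute log2 fold-change cutoff for the `significant`
#'   flag.
#' @return A tibble `gene_id`, `lfc`, `significant` with attributes
#'   `from_stage`, `to_stage`, `threshold`.
#' @export
transition_lfc <- function(stage_expr, from_stage, to_stage, threshold = 1.5) {
  for (st in c(from_stage, to_stage)) {
    if (!st %in% MAJOR_STAGES) {
      stop("unknown stage label: ", st, call. = FALSE)
    }
    if (!st %in% names(stage_expr)) {
      stop("stage column missing from table: ", st, call. = FALSE)
    }
  }
  lfc <- stage_expr[[to_stage]] - stage_expr[[from_stage]]
  out <- tibble::tibble(
    gene_id = stage_expr$gene_id,
    lfc = lfc,
    significant = abs(lfc) > threshold
  )
  attr(out, "from_stage") <- from_stage
  attr(out, "to_stage") <- to_stage
  attr(out, "threshold") <- threshold
  out
}

#' Correlation between two transition fold-change programs
#'
#' The recapitulation statistic: the correlation, over genes, between the
#' embryo-to-larva and pupa-to-adult log fold changes. A positive value
#' means the expression changes at adult eclosion re-run those at larval
#' hatching — the transcriptional signature of metamorphosis replaying the
#' embryonic program.
#'
#' @param lfc_el,lfc_pa Tibbles from [transition_lfc()] over the same gene
#'   universe (typically embryo-to-larva and pupa-to-adult).
#' @param subset Optional gene subset; >= 3 genes must remain.
#' @param method `"spearman"` (default, rank-based like the rest of the
#'   analysis) or `"pearson"`.
#' @return A single correlation coefficient.
#' @export
recapitulation_correlation <- function(lfc_el, lfc_pa, subset = NULL,
                                       method = c("spearman", "pearson")) {
  method <- match.arg(method)
  if (!identical(lfc_el$gene_id, lfc_pa$gene_id)) {
    stop("the two fold-change tables cover different gene sets", call. = FALSE)
  }
  x <- lfc_el$lfc
  y <- lfc_pa$lfc
  if (!is.null(subset)) {
    hit <- lfc_el$gene_id %in% subset
    if (sum(hit) < 3) {
      stop("fewer than 3 subset genes in the fold-change tables", call. = FALSE)
    }
    x <- x[hit]; y <- y[hit]
  }
  if (method == "spearman") spearman_rho(x, y) else stats::cor(x, y)
}

#' Resampling test for subset-driven recapitulation
#'
#' Places the recapitulation correlation of a functional gene subset on the
#' null distribution of random same-size gene sets. High quantiles support
#' the subset carrying more of the cross-transition signal than a random
#' draw.
#'
#' @param expr Log-scale expression tibble.
#' @param samples Sample metadata.
#' @param subset Gene subset to test.
#' @param B Number of resampled sets.
#' @param seed Integer seed.
#' @param method Correlation method passed to the statistic.
#' @return A `resampling_result` (see [resample_metric()]).
#' @export
recapitulation_subset_test <- function(expr, samples, subset, B = 999, seed,
                                       method = c("spearman", "pearson")) {
  method <- match.arg(method)
  stage_expr <- stage_average(expr, samples)
  resample_metric(expr, subset, metric_recap_rho(stage_expr, method),
                  B = B, seed = seed)
}
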