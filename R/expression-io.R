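#' @importFrom rlang .data
#' @importFrom dplyr %>%
NULL

MAJOR_STAGES <- c("embryo", "larva", "pupa", "adult")

#' Read a gene-by-sample expression matrix from TSV
#'
#' Expression tables are tab-separated with genes in rows: the first column
#' (header `gene_id`) holds gene identifiers and every remaining column is a
#' sample, on the FPKM scale. Values are validated to be finite and
#' non-negative, and identifiers to be unique, before anything downstream
#' sees the table.
#'
#' @param path Path to a tab-separated expression file.
#' @return A tibble with a `gene_id` column followed by one numeric column
#'   per sample, carrying attribute `expr_scale = "fpkm"`. Input row and
#'   column order is preserved.
#' @export
#' @examples
#' tf <- tempfile(fileext = ".tsv")
#' writeLines(c("gene_id\ts1\ts2", "g1\t0\t2.5", "g2\t1\t0"), tf)
#' read_expression_matrix(tf)
read_expression_matrix <- function(path) {
  if (!file.exists(path)) {
    stop("expression file not found: ", path, call. = FALSE)
  }
  tbl <- readr::read_tsv(path, col_types = readr::cols(
    .default = readr::col_double(),
    gene_id = readr::col_character()
  ), progress = FALSE)
  if (!identical(names(tbl)[1], "gene_id")) {
    stop("first column of an expression table must be 'gene_id', got '",
         names(tbl)[1], "'", call. = FALSE)
  }
  validate_expression(tbl, scale = "fpkm")
  set_expr_scale(tbl, "fpkm")
}

#' Write an expression table to TSV
#'
#' Inverse of [read_expression_matrix()]: genes in rows, `gene_id` first,
#' tab-separated. Round-trips bit-identically for well-formed tables.
#'
#' @param expr Expression tibble (`gene_id` + sample columns).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_expression_matrix <- function(expr, path) {
  readr::write_tsv(expr, path, progress = FALSE)
  invisible(path)
}

# Hard validation shared by readers and the simulator. Negative values are
# only an error on the fpkm scale; log values may be negative.
validate_expression <- function(expr, scale = c("fpkm", "log")) {
  scale <- match.arg(scale)
  stopifnot(is.data.frame(expr))
  if (names(expr)[1] != "gene_id") {
    stop("expression table must have 'gene_id' as its first column", call. = FALSE)
  }
  dup_g <- unique(expr$gene_id[duplicated(expr$gene_id)])
  if (length(dup_g) > 0) {
    stop("duplicate gene_id: ", paste(dup_g, collapse = ", "), call. = FALSE)
  }
  samp <- sample_cols(expr)
  dup_s <- unique(samp[duplicated(samp)])
  if (length(dup_s) > 0) {
    stop("duplicate sample id: ", paste(dup_s, collapse = ", "), call. = FALSE)
  }
  if (length(samp) == 0) stop("expression table has no sample columns", call. = FALSE)
  for (s in samp) {
    v <- expr[[s]]
    if (!is.numeric(v)) {
      stop("non-numeric values in sample column '", s, "'", call. = FALSE)
    }
    bad <- which(!is.finite(v))
    if (length(bad) > 0) {
      stop("non-finite value at gene '", expr$gene_id[bad[1]],
           "', sample '", s, "'", call. = FALSE)
    }
    if (scale == "fpkm") {
      neg <- which(v < 0)
      if (length(neg) > 0) {
        stop("negative expression value (", v[neg[1]], ") at gene '",
             expr$gene_id[neg[1]], "', sample '", s, "'", call. = FALSE)
      }
    }
  }
  invisible(expr)
}

sample_cols <- function(expr) setdiff(names(expr), "gene_id")

set_expr_scale <- function(expr, scale) {
  attr(expr, "expr_scale") <- scale
  expr
}

#' Scale of an expression table
#'
#' @param expr Expression tibble produced by this package.
#' @return `"fpkm"` or `"log"`; `NA` if the table carries no scale marker.
#' @export
expr_scale <- function(expr) {
  sc <- attr(expr, "expr_scale", exact = TRUE)
  if (is.null(sc)) NA_character_ else sc
}

#' Read a sample metadata table
#'
#' Tab-separated with columns `sample_id`, `major_stage` (one of embryo,
#' larva, pupa, adult), `time_order` (integer rank of the sample within the
#' whole series), `sex` (female, male, mixed, unknown) and `tissue`.
#'
#' @param path Path to the TSV file.
#' @return A validated tibble with those five columns.
#' @export
read_sample_table <- function(path) {
  tbl <- readr::read_tsv(path, col_types = readr::cols(
    sample_id = readr::col_character(),
    major_stage = readr::col_character(),
    time_order = readr::col_integer(),
    sex = readr::col_character(),
    tissue = readr::col_character()
  ), progress = FALSE)
  validate_sample_table(tbl)
}

validate_sample_table <- function(samples) {
  need <- c("sample_id", "major_stage", "time_order", "sex", "tissue")
  miss <- setdiff(need, names(samples))
  if (length(miss) > 0) {
    stop("sample table missing columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  dup <- unique(samples$sample_id[duplicated(samples$sample_id)])
  if (length(dup) > 0) {
    stop("duplicate sample_id in metadata: ", paste(dup, collapse = ", "),
         call. = FALSE)
  }
  bad_stage <- setdiff(unique(samples$major_stage), MAJOR_STAGES)
  if (length(bad_stage) > 0) {
    stop("unknown major_stage value(s): ", paste(bad_stage, collapse = ", "),
         "; must be one of ", paste(MAJOR_STAGES, collapse = ", "), call. = FALSE)
  }
  bad_sex <- setdiff(unique(samples$sex), c("female", "male", "mixed", "unknown"))
  if (length(bad_sex) > 0) {
    stop("unknown sex value(s): ", paste(bad_sex, collapse = ", "), call. = FALSE)
  }
  samples
}

#' Sample-level quality filtering
#'
#' Applies the two sample-exclusion rules used for whole-body developmental
#' time courses. Mature females carry eggs, so adult-female whole-body
#' transcriptomes contain an embryonic signal that inflates their apparent
#' similarity to the embryo; `exclude_females` removes every sample whose
#' recorded sex is `"female"` (samples marked mixed/unknown are kept).
#' `drop_duplicates` removes technical duplicates: within any group of
#' samples whose expression columns are exactly identical, only the first in
#' input order is kept.
#'
#' The analysis needs all four major stages, so filtering that would empty
#' any stage is a hard error rather than a silent degradation.
#'
#' @param expr Expression tibble (any scale).
#' @param samples Sample metadata tibble; must cover every sample column.
#' @param exclude_females Drop samples with `sex == "female"`?
#' @param drop_duplicates Drop exact duplicate expression columns?
#' @return An object of class `qc_result`: a list with `expression` (the
#'   filtered tibble, scale preserved), `samples` (metadata restricted to the
#'   kept samples) and `report` (tibble of removed `sample_id` and `reason`).
#' @export
qc_filter <- function(expr, samples, exclude_females = TRUE,
                      drop_duplicates = TRUE) {
  samples <- validate_sample_table(samples)
  ids <- sample_cols(expr)
  missing_meta <- setdiff(ids, samples$sample_id)
  if (length(missing_meta) > 0) {
    stop("samples absent from metadata: ", paste(missing_meta, collapse = ", "),
         call. = FALSE)
  }
  meta <- samples[match(ids, samples$sample_id), ]

  removed <- tibble::tibble(sample_id = character(), reason = character())
  keep <- rep(TRUE, length(ids))

  if (exclude_females) {
    fem <- meta$sex == "female"
    if (any(fem)) {
      removed <- dplyr::bind_rows(removed, tibble::tibble(
        sample_id = ids[fem], reason = "female"))
      keep <- keep & !fem
    }
  }

  if (drop_duplicates) {
    # exact column equality, checked among currently-kept samples in order
    sig <- vapply(ids, function(s) paste(expr[[s]], collapse = "\r"), character(1))
    seen <- character(0)
    for (i in seq_along(ids)) {
      if (!keep[i]) next
      if (sig[i] %in% seen) {
        removed <- dplyr::bind_rows(removed, tibble::tibble(
          sample_id = ids[i], reason = "duplicate"))
        keep[i] <- FALSE
      } else {
        seen <- c(seen, sig[i])
      }
    }
  }

  kept_ids <- ids[keep]
  lost <- setdiff(MAJOR_STAGES,
                  unique(meta$major_stage[keep]))
  lost <- intersect(lost, unique(meta$major_stage))
  if (length(lost) > 0) {
    stop("qc_filter would remove every sample of stage(s): ",
         paste(lost, collapse = ", "),
         "; the analysis requires all four major stages", call. = FALSE)
  }

  out <- expr[, c("gene_id", kept_ids)]
  out <- set_expr_scale(out, expr_scale(expr))
  structure(list(
    expression = out,
    samples = samples[samples$sample_id %in% kept_ids, ],
    report = removed
  ), class = "qc_result")
}

#' @export
print.qc_result <- function(x, ...) {
  cat("<qc_result> kept", length(sample_cols(x$expression)), "samples,",
      nrow(x$report), "removed\n")
  if (nrow(x$report) > 0) print(x$report)
  invisible(x)
}

#' @method tidy qc_result
#' @export
tidy.qc_result <- function(x, ...) x$report

#' Log-transform an FPKM expression table
#'
#' Replaces every value `v` by `log2(v + pseudocount)`. All similarity and
#' fold-change statistics in this package operate on the log scale; the
#' default pseudocount of 1 maps zero FPKM to zero log expression.
#'
#' @param expr Expression tibble on the FPKM scale.
#' @param pseudocount Positive offset added before the logarithm.
#' @param base Logarithm base (2).
#' @return The transformed tibble with `expr_scale = "log"`.
#' @export
log_transform <- function(expr, pseudocount = 1, base = 2) {
  if (!is.numeric(pseudocount) || length(pseudocount) != 1 || pseudocount <= 0) {
    stop("pseudocount must be a single positive number", call. = FALSE)
  }
  sc <- expr_scale(expr)
  if (!is.na(sc) && sc == "log") {
    stop("expression table is already log-scaled", call. = FALSE)
  }
  validate_expression(expr, "fpkm")
  out <- dplyr::mutate(expr, dplyr::across(
    -"gene_id", ~ log(.x + pseudocount, base = base)))
  set_expr_scale(out, "log")
}

#' Average expression within the four major stages
#'
#' Collapses sample columns to one column per major stage by the arithmetic
#' mean on the table's current scale, columns ordered embryo, larva, pupa,
#' adult. All four stages must be represented.
#'
#' @param expr Expression tibble.
#' @param samples Sample metadata covering every sample column.
#' @return A tibble `gene_id`, `embryo`, `larva`, `pupa`, `adult`; scale
#'   attribute preserved.
#' @export
stage_average <- function(expr, samples) {
  samples <- validate_sample_table(samples)
  ids <- sample_cols(expr)
  missing_meta <- setdiff(ids, samples$sample_id)
  if (length(missing_meta) > 0) {
    stop("samples absent from metadata: ", paste(missing_meta, collapse = ", "),
         call. = FALSE)
  }
  meta <- samples[match(ids, samples$sample_id), ]
  absent <- setdiff(MAJOR_STAGES, unique(meta$major_stage))
  if (length(absent) > 0) {
    stop("no samples for stage(s): ", paste(absent, collapse = ", "),
         call. = FALSE)
  }
  out <- tibble::tibble(gene_id = expr$gene_id)
  for (st in MAJOR_STAGES) {
    cols <- ids[meta$major_stage == st]
    out[[st]] <- rowMeans(as.matrix(expr[, cols, drop = FALSE]))
  }
  set_expr_scale(out, expr_scale(expr))
}
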