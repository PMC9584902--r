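#' The 27 canonical four-stage trajectory templates
#'
#' With four ordered stages (embryo, larva, pupa, adult) there are three
#' stage transitions, and each can go up, stay, or go down: 3^3 = 27
#' possible expression patterns. Each template is written as a three-symbol
#' id over `{+, 0, -}` and expanded to a four-point level vector by
#' cumulative summation starting at 0.
#'
#' @return A tibble of 27 rows: `id`, integer step columns `s1`, `s2`, `s3`
#'   in `{-1, 0, 1}`, `n_steps` (count of non-zero steps) and a `levels`
#'   list-column of 4-point level vectors. Order is deterministic
#'   (lexicographic over `-`, `0`, `+`, first transition slowest).
#' @export
#' @examples
#' trajectory_templates()
trajectory_templates <- function() {
  steps <- c(-1L, 0L, 1L)
  grid <- expand.grid(s3 = steps, s2 = steps, s1 = steps,
                      KEEP.OUT.ATTRS = FALSE)[, c("s1", "s2", "s3")]
  sym <- c(`-1` = "-", `0` = "0", `1` = "+")
  tibble::tibble(
    id = paste0(sym[as.character(grid$s1)],
                sym[as.character(grid$s2)],
                sym[as.character(grid$s3)]),
    s1 = grid$s1, s2 = grid$s2, s3 = grid$s3,
    n_steps = (grid$s1 != 0) + (grid$s2 != 0) + (grid$s3 != 0),
    levels = purrr::pmap(grid, function(s1, s2, s3) cumsum(c(0, s1, s2, s3)))
  )
}

#' Assign genes to trajectory templates by maximal correlation
#'
#' Each gene's four stage values are correlated (Pearson, on the 4-point
#' level vectors) against each of the 26 non-constant templates; the gene is
#' assigned to the template with the highest correlation. The constant
#' template `"000"` has zero variance, so correlation against it is
#' undefined: genes whose stage profile variance falls below `var_tol` are
#' assigned to `"000"` directly (score `NA`). Correlation ties are broken by
#' fewest non-zero steps, then canonical template order.
#'
#' @param stage_expr Stage-averaged log-scale tibble (columns `embryo`,
#'   `larva`, `pupa`, `adult`).
#' @param var_tol Variance below which a profile counts as constant.
#' @return An object of class `trajectory_assignment`: a tibble `gene_id`,
#'   `template`, `score`.
#' @export
assign_trajectories <- function(stage_expr, var_tol = 1e-10) {
  miss <- setdiff(MAJOR_STAGES, names(stage_expr))
  if (length(miss) > 0) {
    stop("stage column(s) missing: ", paste(miss, collapse = ", "),
         "; expected exactly the four major stages", call. = FALSE)
  }
  m <- as.matrix(stage_expr[, MAJOR_STAGES])
  if (ncol(m) != 4) stop("expected exactly 4 stage columns", call. = FALSE)

  tmpl <- trajectory_templates()
  active <- tmpl[tmpl$id != "000", ]
  L <- vapply(active$levels, identity, numeric(4))      # 4 x 26
  Lz <- scale(L)                                        # standardize columns

  vars <- apply(m, 1, stats::var)
  constant <- vars < var_tol

  template <- rep("000", nrow(m))
  score <- rep(NA_real_, nrow(m))

  if (any(!constant)) {
    mv <- m[!constant, , drop = FALSE]
    mz <- t(scale(t(mv)))                               # standardize rows
    S <- (mz %*% Lz) / 3                                # Pearson, n - 1 = 3
    pick <- apply(S, 1, function(row) {
      best <- max(row)
      cand <- which(row >= best - 1e-9)
      cand[order(active$n_steps[cand], cand)][1]
    })
    template[!constant] <- active$id[pick]
    score[!constant] <- S[cbind(seq_len(nrow(S)), pick)]
  }

  out <- tibble::tibble(gene_id = stage_expr$gene_id,
                        template = template, score = score)
  class(out) <- c("trajectory_assignment", class(out))
  out
}

#' @method tidy trajectory_assignment
#' @export
tidy.trajectory_assignment <- function(x, ...) {
  tibble::as_tibble(unclass(x))
}

#' @method glance trajectory_assignment
#' @export
glance.trajectory_assignment <- function(x, ...) {
  tibble::tibble(
    n_genes = nrow(x),
    n_templates_used = dplyr::n_distinct(x$template),
    n_constant = sum(x$template == "000")
  )
}

#' Extract zigzag genes from a trajectory assignment
#'
#' Zigzag genes depart from the embryonic expression level during the larval
#' stage and revert to it at metamorphosis. Under `"strict_alternating"`
#' (default) these are the two fully alternating templates `"+-+"` and
#' `"-+-"`. The looser `"embryo_pupa_return"` criterion accepts any template
#' whose first two steps cancel (larval excursion, pupal return), leaving
#' the pupa-to-adult step free: six templates.
#'
#' @param assignment A `trajectory_assignment`.
#' @param criterion `"strict_alternating"` or `"embryo_pupa_return"`.
#' @return Character vector of gene ids.
#' @export
select_zigzag_genes <- function(assignment,
                                criterion = c("strict_alternating",
                                              "embryo_pupa_return")) {
  criterion <- match.arg(criterion)
  ids <- zigzag_template_ids(criterion)
  assignment$gene_id[assignment$template %in% ids]
}

#' Template ids matching a zigzag criterion
#'
#' @inheritParams select_zigzag_genes
#' @return Character vector of template ids.
#' @export
zigzag_template_ids <- function(criterion = c("strict_alternating",
                                              "embryo_pupa_return")) {
  criterion <- match.arg(criterion)
  tmpl <- trajectory_templates()
  sel <- switch(criterion,
    strict_alternating = tmpl$id %in% c("+-+", "-+-"),
    embryo_pupa_return = tmpl$s1 != 0 & tmpl$s2 == -tmpl$s1
  )
  tmpl$id[sel]
}

#' Hierarchical clustering of dense expression time courses
#'
#' For datasets with more than four time points, genes are clustered
#' agglomeratively with distance `1 - Spearman(profile_i, profile_j)` and
#' the tree cut to exactly `K` clusters. Constant profiles have no rank
#' ordering, hence no defined distance; they are excluded and reported.
#'
#' @param expr Log-scale expression tibble with >= 5 sample columns.
#' @param K Number of clusters.
#' @param linkage `"average"` (default) or `"complete"`.
#' @return An object of class `profile_clusters`: list with `assignment`
#'   (tibble `gene_id`, `cluster`), `means` (cluster-by-sample matrix of
#'   mean profiles), `excluded` (constant gene ids) and the `hclust` tree.
#' @export
cluster_profiles <- function(expr, K, linkage = c("average", "complete")) {
  linkage <- match.arg(linkage)
  m <- expr_matrix(expr)
  if (ncol(m) < 5) {
    stop("hierarchical profile clustering expects more than four time ",
         "points; use assign_trajectories() for four-stage data", call. = FALSE)
  }
  constant <- apply(m, 1, function(v) stats::sd(v) == 0)
  excluded <- rownames(m)[constant]
  m <- m[!constant, , drop = FALSE]
  if (nrow(m) < K) {
    stop("fewer non-constant genes (", nrow(m), ") than clusters (", K, ")",
         call. = FALSE)
  }
  rho <- stats::cor(t(m), method = "spearman")
  d <- stats::as.dist(1 - rho)
  tree <- stats::hclust(d, method = linkage)
  cl <- stats::cutree(tree, k = K)

  means <- do.call(rbind, lapply(sort(unique(cl)), function(k) {
    colMeans(m[cl == k, , drop = FALSE])
  }))
  rownames(means) <- sort(unique(cl))

  structure(list(
    assignment = tibble::tibble(gene_id = rownames(m), cluster = unname(cl)),
    means = means,
    excluded = excluded,
    tree = tree
  ), class = "profile_clusters")
}

#' @export
print.profile_clusters <- function(x, ...) {
  cat("<profile_clusters>", nrow(x$assignment), "genes in",
      nrow(x$means), "clusters;", length(x$excluded), "constant excluded\n")
  invisible(x)
}

#' @method tidy profile_clusters
#' @export
tidy.profile_clusters <- function(x, ...) x$assignment

#' Select clusters with a zigzag-like stage profile
#'
#' Reduces each cluster's mean profile to the four major-stage means,
#' standardizes across stages (z-scores), and selects clusters whose embryo
#' and pupa levels agree (`|z_embryo - z_pupa| < delta`) while the larva
#' departs from the embryo (`|z_larva - z_embryo| > epsilon`) — the
#' embryo-like pupal reversion seen in dense time courses.
#'
#' @param clusters A `profile_clusters` object.
#' @param samples Sample metadata covering the clustered samples.
#' @param delta Maximum embryo-pupa z-distance.
#' @param epsilon Minimum larva-embryo z-distance.
#' @return Integer vector of selected cluster ids.
#' @export
select_zigzag_clusters <- function(clusters, samples, delta = 0.5,
                                   epsilon = 1.0) {
  samples <- validate_sample_table(samples)
  ids <- colnames(clusters$means)
  meta <- samples[match(ids, samples$sample_id), ]
  if (anyNA(meta$sample_id)) {
    stop("clustered samples absent from metadata", call. = FALSE)
  }
  sel <- vapply(seq_len(nrow(clusters$means)), function(k) {
    prof <- clusters$means[k, ]
    stage_means <- vapply(MAJOR_STAGES, function(st) {
      mean(prof[meta$major_stage == st])
    }, numeric(1))
    if (stats::sd(stage_means) == 0) return(FALSE)
    z <- (stage_means - mean(stage_means)) / stats::sd(stage_means)
    abs(z["embryo"] - z["pupa"]) < delta && abs(z["larva"] - z["embryo"]) > epsilon
  }, logical(1))
  as.integer(rownames(clusters$means))[sel]
}
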