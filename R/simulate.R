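GENE_CLASSES <- c("monotone_up", "monotone_down", "zigzag_up", "zigzag_down",
                  "constant", "random")

#' Simulate a developmental transcriptome with planted structure
#'
#' Generates a gene-by-sample FPKM matrix over the four major insect stages
#' (embryo, larva, pupa, adult) with replicates, from known per-gene latent
#' trajectories, so that every downstream statistic can be checked against
#' ground truth.
#'
#' Gene classes plant the structures the analysis looks for, as latent
#' 4-stage log2 levels relative to a per-gene baseline (with `e` the
#' `effect_size`):
#' * `monotone_up` / `monotone_down`: `[0, e/3, 2e/3, e]` and its negation —
#'   gradual development;
#' * `zigzag_up` / `zigzag_down`: `[0, e, 0, e]` and its negation — larval
#'   excursion with pupal reversion to the embryonic level (templates
#'   `"+-+"` / `"-+-"`);
#' * `constant`: flat at a nonzero baseline (expressed, template `"000"`);
#' * `random`: the three transition steps drawn from normals with step sd
#'   `effect_size / 2`; when `shared_program_rho` is nonzero the
#'   embryo-to-larva and pupa-to-adult steps are drawn from a bivariate
#'   normal with that correlation, planting a cross-transition
#'   recapitulation program of known strength.
#'
#' Each replicate observes `baseline + level + N(0, noise_sd)` on the log2
#' scale, back-transformed to FPKM as `2^x - pseudocount` floored at 0
#' (multiplicative log-normal noise on the FPKM scale). With
#' `female_contamination = f > 0`, half of the adult replicates are labelled
#' female and their FPKM becomes a `(1 - f, f)` mixture with the mean
#' embryonic profile — mimicking egg signal in gravid whole-body females.
#'
#' A small synthetic ontology (a development and a metabolism subtree under
#' a common root) is generated alongside, with `annotated_fraction` of the
#' zigzag genes annotated into the development subtree and background genes
#' spread over metabolism/root terms.
#'
#' @param n_genes Number of genes.
#' @param class_fractions Named fractions over the six gene classes, summing
#'   to 1.
#' @param stage_replicates Named integer vector of replicates per stage.
#' @param noise_sd Replicate noise sd, log2 units.
#' @param effect_size Step magnitude, log2 units.
#' @param shared_program_rho Planted correlation between the embryo-to-larva
#'   and pupa-to-adult latent steps of `random`-class genes, in `[-1, 1]`.
#' @param female_contamination Fraction of embryo signal mixed into
#'   adult-female samples; 0 disables the confounder (and labels all samples
#'   `mixed`).
#' @param baseline_range Range of per-gene baseline log2 expression.
#' @param pseudocount Pseudocount consistent with [log_transform()].
#' @param annotated_fraction Fraction of zigzag genes annotated into the
#'   development subtree.
#' @param seed Integer seed; the same seed reproduces the dataset
#'   bit-identically.
#' @return An object of class `dev_simulation`: list with `expression`
#'   (FPKM tibble), `samples` (metadata tibble), `annotations` (tibble
#'   `gene_id`, `term`), `ontology` (an `ontology_dag`) and `truth` (list:
#'   `classes` tibble, `levels` and `steps` matrices, `baseline`, `config`).
#' @export
simulate_dataset <- function(n_genes = 2000,
                             class_fractions = c(monotone_up = 0.15,
                                                 monotone_down = 0.15,
                                                 zigzag_up = 0.10,
                                                 zigzag_down = 0.10,
                                                 constant = 0.20,
                                                 random = 0.30),
                             stage_replicates = c(embryo = 3, larva = 3,
                                                  pupa = 3, adult = 3),
                             noise_sd = 0.2,
                             effect_size = 2,
                             shared_program_rho = 0,
                             female_contamination = 0,
                             baseline_range = c(2, 8),
                             pseudocount = 1,
                             annotated_fraction = 0.8,
                             seed) {
  if (missing(seed)) stop("seed is required", call. = FALSE)
  miss <- setdiff(GENE_CLASSES, names(class_fractions))
  if (length(miss) > 0) {
    stop("class_fractions missing: ", paste(miss, collapse = ", "), call. = FALSE)
  }
  class_fractions <- class_fractions[GENE_CLASSES]
  if (any(class_fractions < 0) || abs(sum(class_fractions) - 1) > 1e-8) {
    stop("class_fractions must be non-negative and sum to 1", call. = FALSE)
  }
  if (abs(shared_program_rho) > 1) {
    stop("shared_program_rho must be in [-1, 1]", call. = FALSE)
  }
  miss_st <- setdiff(MAJOR_STAGES, names(stage_replicates))
  if (length(miss_st) > 0) {
    stop("stage_replicates missing: ", paste(miss_st, collapse = ", "),
         call. = FALSE)
  }
  stage_replicates <- stage_replicates[MAJOR_STAGES]
  if (any(stage_replicates < 1)) stop("need >= 1 replicate per stage", call. = FALSE)

  withr::with_seed(seed, {
    # class sizes: rounded cumulative so counts sum exactly to n_genes
    cum <- round(cumsum(class_fractions) * n_genes)
    counts <- diff(c(0, cum))
    classes <- rep(names(class_fractions), counts)
    gene_id <- sprintf("g%05d", seq_len(n_genes))

    step_sd <- effect_size / 2
    steps <- matrix(0, n_genes, 3,
                    dimnames = list(gene_id, c("d1", "d2", "d3")))
    e <- effect_size
    steps[classes == "monotone_up", ] <- matrix(rep(c(e/3, e/3, e/3),
      each = sum(classes == "monotone_up")), ncol = 3)
    steps[classes == "monotone_down", ] <- matrix(rep(c(-e/3, -e/3, -e/3),
      each = sum(classes == "monotone_down")), ncol = 3)
    steps[classes == "zigzag_up", ] <- matrix(rep(c(e, -e, e),
      each = sum(classes == "zigzag_up")), ncol = 3)
    steps[classes == "zigzag_down", ] <- matrix(rep(c(-e, e, -e),
      each = sum(classes == "zigzag_down")), ncol = 3)
    n_rand <- sum(classes == "random")
    if (n_rand > 0) {
      rho <- shared_program_rho
      z1 <- stats::rnorm(n_rand)
      z2 <- stats::rnorm(n_rand)
      d1 <- step_sd * z1
      d3 <- step_sd * (rho * z1 + sqrt(1 - rho^2) * z2)
      d2 <- stats::rnorm(n_rand, sd = step_sd)
      steps[classes == "random", ] <- cbind(d1, d2, d3)
    }

    levels_ <- cbind(0, t(apply(steps, 1, cumsum)))
    colnames(levels_) <- MAJOR_STAGES
    rownames(levels_) <- gene_id

    baseline <- stats::runif(n_genes, baseline_range[1], baseline_range[2])
    names(baseline) <- gene_id

    # sample layout
    samples <- tibble::tibble(
      sample_id = unlist(lapply(MAJOR_STAGES, function(st) {
        paste0(st, "_", seq_len(stage_replicates[[st]]))
      })),
      major_stage = rep(MAJOR_STAGES, stage_replicates),
      sex = "mixed",
      tissue = "whole_body"
    )
    samples$time_order <- seq_len(nrow(samples))
    if (female_contamination > 0) {
      adults <- which(samples$major_stage == "adult")
      fem <- adults[seq_len(ceiling(length(adults) / 2))]
      samples$sex[adults] <- "male"
      samples$sex[fem] <- "female"
    }
    samples <- samples[, c("sample_id", "major_stage", "time_order",
                           "sex", "tissue")]

    # observations
    fpkm <- matrix(0, n_genes, nrow(samples),
                   dimnames = list(gene_id, samples$sample_id))
    for (j in seq_len(nrow(samples))) {
      st <- samples$major_stage[j]
      x <- baseline + levels_[, st]
      if (noise_sd > 0) x <- x + stats::rnorm(n_genes, sd = noise_sd)
      fpkm[, j] <- pmax(2^x - pseudocount, 0)
    }
    if (female_contamination > 0) {
      emb_mean <- rowMeans(fpkm[, samples$major_stage == "embryo", drop = FALSE])
      fem_cols <- which(samples$sex == "female")
      f <- female_contamination
      for (j in fem_cols) fpkm[, j] <- (1 - f) * fpkm[, j] + f * emb_mean
    }

    ontology <- simulate_ontology()
    annotations <- simulate_annotations(gene_id, classes, annotated_fraction)

    expression <- tibble::as_tibble(cbind(
      tibble::tibble(gene_id = gene_id),
      tibble::as_tibble(fpkm)
    ))
    expression <- set_expr_scale(expression, "fpkm")

    structure(list(
      expression = expression,
      samples = samples,
      annotations = annotations,
      ontology = ontology,
      truth = list(
        classes = tibble::tibble(gene_id = gene_id, class = classes),
        levels = levels_,
        steps = steps,
        baseline = baseline,
        config = list(n_genes = n_genes, class_fractions = class_fractions,
                      stage_replicates = stage_replicates,
                      noise_sd = noise_sd, effect_size = effect_size,
                      shared_program_rho = shared_program_rho,
                      female_contamination = female_contamination,
                      baseline_range = baseline_range,
                      pseudocount = pseudocount,
                      annotated_fraction = annotated_fraction, seed = seed)
      )
    ), class = "dev_simulation")
  })
}

#' @export
print.dev_simulation <- function(x, ...) {
  cfg <- x$truth$config
  cat("<dev_simulation>", cfg$n_genes, "genes x",
      nrow(x$samples), "samples | noise_sd =", cfg$noise_sd,
      "| seed =", cfg$seed, "\n")
  print(table(x$truth$classes$class))
  invisible(x)
}

# fixed miniature GO: a development and a metabolism subtree under one root
SYNTH_GO <- list(
  terms = tibble::tibble(
    id = c("GO:0008150", "GO:0032502", "GO:0048856", "GO:0009790",
           "GO:0008152", "GO:0044237", "GO:0046034"),
    name = c("biological_process", "developmental process",
             "anatomical structure development", "embryo development",
             "metabolic process", "cellular metabolic process",
             "ATP metabolic process")
  ),
  edges = tibble::tibble(
    child = c("GO:0032502", "GO:0048856", "GO:0009790",
              "GO:0008152", "GO:0044237", "GO:0046034"),
    parent = c("GO:0008150", "GO:0032502", "GO:0048856",
               "GO:0008150", "GO:0008152", "GO:0044237"),
    relation = "is_a"
  )
)

#' Miniature synthetic Gene Ontology for simulations
#'
#' Seven terms: a root, a three-term development chain (GO:0032502 and two
#' descendants) and a three-term metabolism chain (GO:0008152 and two
#' descendants). Shape, ids and edge types match what the real ontology
#' parser produces, so closures and enrichment behave identically.
#'
#' @return An `ontology_dag`.
#' @export
simulate_ontology <- function() {
  structure(list(
    terms = SYNTH_GO$terms,
    edges = SYNTH_GO$edges,
    alt_ids = stats::setNames(character(0), character(0)),
    roots = "GO:0008150"
  ), class = "ontology_dag")
}

# zigzag genes go (mostly) into the development subtree; background genes
# spread over metabolism, root, or stay unannotated — deliberately sparse,
# like real non-model-species annotation
simulate_annotations <- function(gene_id, classes, annotated_fraction) {
  dev_terms <- c("GO:0032502", "GO:0048856", "GO:0009790")
  met_terms <- c("GO:0008152", "GO:0044237", "GO:0046034")

  zig <- gene_id[classes %in% c("zigzag_up", "zigzag_down")]
  zig_ann <- zig[stats::runif(length(zig)) < annotated_fraction]
  rows <- list(tibble::tibble(
    gene_id = zig_ann,
    term = sample(dev_terms, length(zig_ann), replace = TRUE)
  ))

  bg <- setdiff(gene_id, zig)
  u <- stats::runif(length(bg))
  met <- bg[u < 0.4]
  rows <- c(rows, list(tibble::tibble(
    gene_id = met, term = sample(met_terms, length(met), replace = TRUE))))
  rootish <- bg[u >= 0.4 & u < 0.5]
  rows <- c(rows, list(tibble::tibble(gene_id = rootish, term = "GO:0008150")))

  dplyr::arrange(dplyr::distinct(dplyr::bind_rows(rows)), .data$gene_id,
                 .data$term)
}

#' Write a simulated dataset to disk in the package's external formats
#'
#' Produces exactly the dialects the readers consume: `expression.tsv`
#' (genes in rows), `samples.tsv`, `annotations.tsv` (two-column gene/GO),
#' `annotations.gaf` (GAF 2.2), `ontology.obo` (OBO 1.2) and
#' `truth_classes.tsv`.
#'
#' @param sim A `dev_simulation`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_simulation <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_expression_matrix(sim$expression, file.path(dir, "expression.tsv"))
  readr::write_tsv(sim$samples, file.path(dir, "samples.tsv"), progress = FALSE)
  readr::write_tsv(sim$annotations, file.path(dir, "annotations.tsv"),
                   col_names = FALSE, progress = FALSE)
  write_gaf(sim$annotations, file.path(dir, "annotations.gaf"))
  write_obo(sim$ontology, file.path(dir, "ontology.obo"))
  readr::write_tsv(sim$truth$classes, file.path(dir, "truth_classes.tsv"),
                   progress = FALSE)
  invisible(dir)
}

write_obo <- function(dag, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("format-version: 1.2", ""), con)
  for (i in seq_len(nrow(dag$terms))) {
    id <- dag$terms$id[i]
    parents <- dag$edges$parent[dag$edges$child == id &
                                  dag$edges$relation == "is_a"]
    part_of <- dag$edges$parent[dag$edges$child == id &
                                  dag$edges$relation == "part_of"]
    writeLines(c(
      "[Term]",
      paste0("id: ", id),
      paste0("name: ", dag$terms$name[i]),
      if (length(parents) > 0) paste0("is_a: ", parents),
      if (length(part_of) > 0) paste0("relationship: part_of ", part_of),
      ""
    ), con)
  }
  invisible(path)
}

write_gaf <- function(annotations, path) {
  lines <- c("!gaf-version: 2.2",
             sprintf("SYN\t%s\t%s\t\t%s\tSYN:ref\tIEA\t\tP\t\t\tgene\ttaxon:0000\t20200101\tSYN\t\t",
                     annotations$gene_id, annotations$gene_id,
                     annotations$term))
  writeLines(lines, path)
  invisible(path)
}
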