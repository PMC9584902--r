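#' Run the full recapitulation analysis end to end
#'
#' Orchestrates the whole pipeline: sample QC, log transform, stage
#' similarity, functional gene subsets, subset resampling, cross-transition
#' recapitulation, trajectory classification with zigzag extraction, and GO
#' enrichment of the zigzag genes. Every stage's table is written to
#' `out_dir` along with a `manifest.tsv` recording inputs, parameters, seed
#' and the files produced; rerunning with the same inputs and seed
#' reproduces every output bit-identically.
#'
#' Inputs may be in-memory objects (as produced by [simulate_dataset()]) or
#' file paths in the package's external formats.
#'
#' @param expression Expression tibble (FPKM) or path to a TSV.
#' @param samples Sample metadata tibble or path.
#' @param ontology An `ontology_dag` or path to an OBO file.
#' @param annotations Annotation tibble (`gene_id`, `term`) or path to a
#'   two-column TSV.
#' @param out_dir Output directory.
#' @param exclude_females,drop_duplicates QC flags (see [qc_filter()]).
#' @param subset_roots Named GO roots defining the functional subsets;
#'   defaults to developmental process and metabolic process.
#' @param B,seed Resampling replicates and seed.
#' @param lcf_threshold Absolute log2 fold-change significance cutoff.
#' @param alpha Adjusted-p threshold for enrichment.
#' @param pseudocount Pseudocount for the log transform.
#' @param zigzag_criterion Passed to [select_zigzag_genes()].
#' @return Invisibly, a named list of all stage results plus the manifest
#'   path.
#' @export
run_pipeline <- function(expression, samples, ontology, annotations,
                         out_dir,
                         exclude_females = TRUE, drop_duplicates = TRUE,
                         subset_roots = c(development = "GO:0032502",
                                          metabolism = "GO:0008152"),
                         B = 999, seed = 1,
                         lcf_threshold = 1.5, alpha = 0.05,
                         pseudocount = 1,
                         zigzag_criterion = "strict_alternating") {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  stage <- function(name, code) {
    tryCatch(code, error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }

  expression <- stage("input", {
    if (is.character(expression)) read_expression_matrix(expression)
    else set_expr_scale(expression, "fpkm")
  })
  samples <- stage("input", {
    if (is.character(samples)) read_sample_table(samples)
    else validate_sample_table(samples)
  })
  ontology <- stage("input", {
    if (is.character(ontology)) parse_obo(ontology) else ontology
  })
  annotations <- stage("input", {
    if (is.character(annotations)) {
      if (!file.exists(annotations)) {
        stop("annotation file not found: ", annotations)
      }
      read_annotations(annotations, "two_column_tsv")
    } else annotations
  })

  results <- list()
  files <- character(0)
  emit <- function(tbl, name) {
    path <- file.path(out_dir, name)
    readr::write_tsv(tbl, path, progress = FALSE)
    files <<- c(files, name)
    path
  }

  # 1. qc
  qc <- stage("qc", qc_filter(expression, samples,
                              exclude_females = exclude_females,
                              drop_duplicates = drop_duplicates))
  emit(qc$report, "qc_report.tsv")
  results$qc <- qc

  # 2. log
  logged <- stage("log", log_transform(qc$expression,
                                       pseudocount = pseudocount))
  results$logged <- logged

  # 3. similarity
  sim_all <- stage("similarity", pairwise_similarity(logged))
  emit(tidy.stage_cor(sim_all), "similarity_all.tsv")
  profile <- stage("similarity",
                   embryo_similarity_profile(logged, qc$samples))
  emit(profile, "embryo_profile.tsv")
  results$similarity <- sim_all
  results$embryo_profile <- profile

  # 4. subsets
  subsets <- stage("subsets", {
    lapply(subset_roots, function(root) {
      suppressWarnings(select_gene_subset(annotations, ontology, root))
    })
  })
  emit(tibble::tibble(
    subset = rep(names(subsets), lengths(subsets)),
    gene_id = unlist(subsets, use.names = FALSE)
  ), "subsets.tsv")
  results$subsets <- subsets

  # 5. resampling (per usable subset)
  results$resampling <- stage("resampling", {
    usable <- subsets[vapply(subsets, function(s)
      sum(s %in% logged$gene_id) >= 3, logical(1))]
    out <- purrr::imap(usable, function(s, nm) {
      recapitulation_subset_test(logged, qc$samples, s, B = B, seed = seed)
    })
    if (length(out) > 0) {
      emit(dplyr::bind_rows(purrr::imap(out, function(r, nm) {
        dplyr::mutate(glance.resampling_result(r), subset = nm,
                      .before = 1)
      })), "resampling.tsv")
    }
    out
  })

  # 6. recapitulation
  recap <- stage("recapitulation", {
    stage_expr <- stage_average(logged, qc$samples)
    lfc_el <- transition_lfc(stage_expr, "embryo", "larva", lcf_threshold)
    lfc_pa <- transition_lfc(stage_expr, "pupa", "adult", lcf_threshold)
    rho <- recapitulation_correlation(lfc_el, lfc_pa)
    emit(tibble::tibble(
      gene_id = lfc_el$gene_id,
      lfc_embryo_larva = lfc_el$lfc,
      significant_embryo_larva = lfc_el$significant,
      lfc_pupa_adult = lfc_pa$lfc,
      significant_pupa_adult = lfc_pa$significant
    ), "transition_lfc.tsv")
    list(stage_expr = stage_expr, lfc_el = lfc_el, lfc_pa = lfc_pa, rho = rho)
  })
  results$recapitulation <- recap

  # 7. trajectories
  traj <- stage("trajectories", {
    assignment <- assign_trajectories(recap$stage_expr)
    zigzag <- select_zigzag_genes(assignment, zigzag_criterion)
    emit(tibble::as_tibble(unclass(assignment)), "trajectories.tsv")
    list(assignment = assignment, zigzag = zigzag)
  })
  results$trajectories <- traj

  # 8. enrichment
  results$enrichment <- stage("enrichment", {
    reference <- positive_expression_reference(qc$expression)
    study <- intersect(traj$zigzag, reference)
    enr <- fisher_enrichment(study, reference, annotations, ontology,
                             alpha = alpha)
    emit(tibble::as_tibble(unclass(enr)), "enrichment.tsv")
    enr
  })

  manifest <- tibble::tibble(
    key = c("stages", "n_genes", "n_samples_in", "n_samples_kept",
            "exclude_females", "drop_duplicates", "subset_roots", "B",
            "seed", "lcf_threshold", "alpha", "pseudocount",
            "zigzag_criterion", "recapitulation_rho", "files"),
    value = c(
      paste(c("qc", "log", "similarity", "subsets", "resampling",
              "recapitulation", "trajectories", "enrichment"),
            collapse = ","),
      nrow(expression),
      length(sample_cols(expression)),
      length(sample_cols(qc$expression)),
      exclude_females, drop_duplicates,
      paste(sprintf("%s=%s", names(subset_roots), subset_roots),
            collapse = ","),
      B, seed, lcf_threshold, alpha, pseudocount, zigzag_criterion,
      format(recap$rho, digits = 10),
      paste(files, collapse = ",")
    )
  )
  manifest_path <- file.path(out_dir, "manifest.tsv")
  readr::write_tsv(manifest, manifest_path, progress = FALSE)
  results$manifest <- manifest_path

  invisible(results)
}
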