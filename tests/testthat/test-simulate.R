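test_that("zero-noise stage means reproduce the latent levels exactly", {
  sim <- simulate_dataset(n_genes = 120, noise_sd = 0, seed = 801)
  st <- stage_average(log_transform(sim$expression), sim$samples)
  latent <- sim$truth$baseline + sim$truth$levels
  # the zero-FPKM floor maps latent values below 0 (log2 scale) to 0
  expected <- log2(pmax(2^latent - 1, 0) + 1)
  for (stg in c("embryo", "larva", "pupa", "adult")) {
    expect_equal(st[[stg]], unname(expected[, stg]), tolerance = 1e-9)
  }
  # and above the floor the recovery is exact
  above <- latent > 0
  expect_true(mean(above) > 0.9)
})

test_that("the same seed reproduces the dataset bit-identically", {
  a <- simulate_dataset(n_genes = 80, seed = 802)
  b <- simulate_dataset(n_genes = 80, seed = 802)
  expect_identical(a$expression, b$expression)
  expect_identical(a$samples, b$samples)
  expect_identical(a$annotations, b$annotations)
  expect_identical(a$truth$steps, b$truth$steps)
  c_ <- simulate_dataset(n_genes = 80, seed = 803)
  expect_false(identical(a$expression, c_$expression))
})

test_that("class counts match the requested fractions within rounding", {
  sim <- simulate_dataset(n_genes = 1000, seed = 804)
  counts <- table(sim$truth$classes$class)
  frac <- sim$truth$config$class_fractions
  for (cl in names(frac)) {
    expect_lte(abs(counts[[cl]] - 1000 * frac[[cl]]), 1)
  }
  expect_equal(sum(counts), 1000)
})

test_that("generated FPKM values are finite and non-negative; validation passes", {
  sim <- simulate_dataset(n_genes = 150, noise_sd = 1.5, seed = 805)
  m <- as.matrix(sim$expression[, -1])
  expect_true(all(is.finite(m)))
  expect_true(all(m >= 0))
  expect_silent(log_transform(sim$expression))
})

test_that("invalid configurations are rejected", {
  expect_error(simulate_dataset(n_genes = 10), "seed")
  expect_error(simulate_dataset(
    n_genes = 10,
    class_fractions = c(monotone_up = 0.5, monotone_down = 0.5,
                        zigzag_up = 0.5, zigzag_down = 0, constant = 0,
                        random = 0), seed = 1), "sum to 1")
  expect_error(simulate_dataset(n_genes = 10, shared_program_rho = 2,
                                seed = 1), "shared_program_rho")
})

test_that("egg contamination makes adult females embryo-like until filtered", {
  sim <- simulate_dataset(n_genes = 500, female_contamination = 0.5,
                          noise_sd = 0.2, seed = 806)
  logged <- log_transform(sim$expression)
  prof <- embryo_similarity_profile(logged, sim$samples)
  merged <- dplyr::left_join(prof, sim$samples[, c("sample_id", "sex")],
                             by = "sample_id")
  fem <- merged$rho[merged$major_stage == "adult" & merged$sex == "female"]
  mal <- merged$rho[merged$major_stage == "adult" & merged$sex == "male"]
  expect_gt(mean(fem), mean(mal))

  qc <- qc_filter(sim$expression, sim$samples)
  expect_false(any(qc$samples$sex == "female"))
  expect_true(all(qc$report$reason == "female"))
})

test_that("annotated zigzag genes land in the development closure", {
  sim <- simulate_dataset(n_genes = 300, seed = 807)
  dev_genes <- select_gene_subset(sim$annotations, sim$ontology, "GO:0032502")
  zig <- sim$truth$classes$gene_id[sim$truth$classes$class %in%
                                     c("zigzag_up", "zigzag_down")]
  expect_true(all(dev_genes %in% zig))
  expect_gt(length(dev_genes), 0.5 * length(zig))
})

test_that("written fixtures round-trip through the package readers", {
  sim <- simulate_dataset(n_genes = 40, seed = 808)
  dir <- withr::local_tempdir()
  write_simulation(sim, dir)

  expr <- read_expression_matrix(file.path(dir, "expression.tsv"))
  expect_equal(as.data.frame(expr), as.data.frame(sim$expression),
               tolerance = 1e-12)
  samples <- read_sample_table(file.path(dir, "samples.tsv"))
  expect_equal(as.data.frame(samples), as.data.frame(sim$samples))

  dag <- parse_obo(file.path(dir, "ontology.obo"))
  expect_setequal(dag$terms$id, sim$ontology$terms$id)
  expect_equal(nrow(dag$edges), nrow(sim$ontology$edges))

  ann_tsv <- read_annotations(file.path(dir, "annotations.tsv"),
                              "two_column_tsv")
  ann_gaf <- read_annotations(file.path(dir, "annotations.gaf"), "gaf")
  expect_setequal(paste(ann_tsv$gene_id, ann_tsv$term),
                  paste(sim$annotations$gene_id, sim$annotations$term))
  expect_setequal(paste(ann_gaf$gene_id, ann_gaf$term),
                  paste(sim$annotations$gene_id, sim$annotations$term))
})
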