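test_that("reading a TSV preserves shape, ids and values, and round-trips", {
  tf <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("gene_id\ts1\ts2\ts3\ts4",
               "g1\t0\t1.5\t2\t3",
               "g2\t4\t0\t0.25\t1",
               "g3\t7\t8\t9\t10"), tf)
  expr <- read_expression_matrix(tf)
  expect_equal(dim(expr), c(3L, 5L))
  expect_identical(expr$gene_id, c("g1", "g2", "g3"))
  expect_identical(names(expr)[-1], paste0("s", 1:4))
  expect_equal(expr$s2, c(1.5, 0, 8))
  expect_identical(expr_scale(expr), "fpkm")

  tf2 <- withr::local_tempfile(fileext = ".tsv")
  write_expression_matrix(expr, tf2)
  expect_identical(readLines(tf2), readLines(tf))
})

test_that("validation names the offending gene, sample or cell", {
  tf <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("gene_id\ts1", "g1\t1", "g1\t2"), tf)
  expect_error(read_expression_matrix(tf), "g1")

  tf2 <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("gene_id\ts1\ts2", "g1\t1\t2", "g2\t-2.0\t1"), tf2)
  expect_error(read_expression_matrix(tf2), "g2.*s1|s1.*g2")
})

test_that("qc_filter removes exact duplicate columns, keeping the first", {
  m <- cbind(e1 = c(1, 2, 3), l1 = c(2, 3, 4),
             p1 = c(5, 6, 7), p2 = c(5, 6, 7), a1 = c(8, 9, 1))
  expr <- expr_from_matrix(m)
  samples <- samples_for(colnames(m),
                         c("embryo", "larva", "pupa", "pupa", "adult"))
  qc <- qc_filter(expr, samples)
  expect_setequal(setdiff(names(qc$expression), "gene_id"),
                  c("e1", "l1", "p1", "a1"))
  expect_equal(qc$report$sample_id, "p2")
  expect_equal(qc$report$reason, "duplicate")
})

test_that("qc_filter female handling: removal, no-op, stage-coverage error", {
  m <- cbind(e1 = c(1, 2, 3), l1 = c(2, 3, 4),
             p1 = c(5, 6, 7), a1 = c(8, 9, 1), a2 = c(3, 1, 2))
  expr <- expr_from_matrix(m)
  samples <- samples_for(colnames(m),
                         c("embryo", "larva", "pupa", "adult", "adult"),
                         sex = c("mixed", "unknown", "male", "female", "male"))
  qc <- qc_filter(expr, samples)
  expect_false("a1" %in% names(qc$expression))
  expect_equal(qc$report$reason, "female")

  # no females: identity
  samples2 <- samples_for(colnames(m),
                          c("embryo", "larva", "pupa", "adult", "adult"))
  qc2 <- qc_filter(expr, samples2)
  expect_equal(qc2$expression[names(expr)], expr, ignore_attr = "expr_scale")
  expect_equal(nrow(qc2$report), 0)

  # the only embryo sample is female -> hard error
  samples3 <- samples_for(colnames(m),
                          c("embryo", "larva", "pupa", "adult", "adult"),
                          sex = c("female", "mixed", "mixed", "mixed", "mixed"))
  expect_error(qc_filter(expr, samples3), "embryo")
})

test_that("qc_filter is idempotent", {
  m <- cbind(e1 = c(1, 2, 3), l1 = c(2, 3, 4), l2 = c(2, 3, 4),
             p1 = c(5, 6, 7), a1 = c(8, 9, 1), a2 = c(0, 1, 2))
  expr <- expr_from_matrix(m)
  samples <- samples_for(colnames(m),
                         c("embryo", "larva", "larva", "pupa", "adult", "adult"),
                         sex = c("mixed", "mixed", "mixed", "male", "female",
                                 "male"))
  once <- qc_filter(expr, samples)
  twice <- qc_filter(once$expression, once$samples)
  expect_identical(twice$expression, once$expression)
  expect_equal(nrow(twice$report), 0)
})

test_that("log_transform maps v to log2(v + pseudocount) and guards inputs", {
  expr <- expr_from_matrix(cbind(s1 = c(0, 1, 3), s2 = c(7, 15, 31)),
                           gene_ids = c("g1", "g2", "g3"))
  out <- log_transform(expr)
  expect_equal(out$s1, c(0, 1, 2))
  expect_equal(out$s2, c(3, 4, 5))
  expect_identical(expr_scale(out), "log")
  expect_error(log_transform(expr, pseudocount = 0), "pseudocount")
  expect_error(log_transform(out), "already log")
})

test_that("stage_average equals a per-stage mean recomputed by explicit loop", {
  withr::local_seed(11)
  m <- matrix(rexp(10 * 12), nrow = 10,
              dimnames = list(paste0("g", 1:10), paste0("s", 1:12)))
  stages <- rep(c("embryo", "larva", "pupa", "adult"), each = 3)
  expr <- expr_from_matrix(m)
  samples <- samples_for(colnames(m), stages)
  avg <- stage_average(expr, samples)
  expect_equal(dim(avg), c(10L, 5L))
  expect_identical(names(avg), c("gene_id", "embryo", "larva", "pupa", "adult"))

  for (st in c("embryo", "larva", "pupa", "adult")) {
    for (g in seq_len(10)) {
      acc <- 0; cnt <- 0
      for (s in colnames(m)) {
        if (stages[match(s, colnames(m))] == st) {
          acc <- acc + m[g, s]; cnt <- cnt + 1
        }
      }
      expect_equal(avg[[st]][g], acc / cnt)
    }
  }
})

test_that("stage_average: single samples reorder, replicates average, missing stage errors", {
  expr <- tiny_expression()
  samples <- tiny_samples()
  avg <- stage_average(expr, samples)
  expect_equal(avg$embryo, expr$e1)
  expect_equal(avg$adult, expr$a1)

  m <- cbind(e1 = c(2, 1), e2 = c(4, 1), l1 = c(0, 0), p1 = c(1, 1),
             a1 = c(2, 2))
  expr2 <- expr_from_matrix(m, gene_ids = c("gA", "gB"))
  samples2 <- samples_for(colnames(m),
                          c("embryo", "embryo", "larva", "pupa", "adult"))
  expect_equal(stage_average(expr2, samples2)$embryo, c(3, 1))

  expect_error(stage_average(expr2, dplyr::mutate(
    samples2, major_stage = dplyr::if_else(major_stage == "pupa", "adult",
                                           major_stage))), "pupa")
})
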