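test_that("read_counts validates files and metadata alignment", {
  dir <- withr::local_tempdir()
  counts <- matrix(c(1L, 2L, 3L, 4L, 5L, 6L, 7L, 8L), nrow = 2,
                   dimnames = list(c("gA", "gB"),
                                   c("s1", "s2", "s3", "s4")))
  meta <- toy_meta(colnames(counts), c("10NO", "10HY", "20NO", "20HY"))
  cp <- file.path(dir, "c.tsv"); mp <- file.path(dir, "m.csv")
  utils::write.table(data.frame(gene_id = rownames(counts), counts),
                     cp, sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.csv(meta, mp, row.names = FALSE)
  cm <- read_counts(cp, mp)
  expect_identical(dim(cm$counts), c(2L, 4L))
  expect_identical(cm$sample_ids, colnames(counts))

  # metadata missing one sample names the offender
  utils::write.csv(meta[-2, ], mp, row.names = FALSE)
  expect_error(read_counts(cp, mp), "s2")

  # negative and fractional counts are rejected
  bad <- counts; bad[1, 1] <- -1L
  utils::write.table(data.frame(gene_id = rownames(bad), bad),
                     cp, sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.csv(meta, mp, row.names = FALSE)
  expect_error(read_counts(cp, mp), "non-negative")

  expect_error(count_matrix(matrix(0.5, 1, 1,
                                   dimnames = list("g", "s")),
                            toy_meta("s", "10NO")), "integer")
  expect_error(count_matrix(counts, transform(meta,
                                              treatment = "15XX")),
               "unknown treatment")
})

test_that("low-count filter removes rows below the total-count threshold", {
  set.seed(1)
  counts <- matrix(rpois(40, 3), nrow = 10,
                   dimnames = list(sprintf("g%02d", 1:10),
                                   sprintf("s%02d", 1:4)))
  counts[2, ] <- c(1L, 1L, 1L, 1L)   # sum 4 < 5 -> removed
  counts[5, ] <- c(0L, 0L, 0L, 2L)
  counts[9, ] <- c(0L, 1L, 1L, 0L)
  counts[1, ] <- c(2L, 1L, 1L, 1L)   # sum 5 -> kept (boundary)
  storage.mode(counts) <- "integer"
  cm <- toy_cm(counts, c("10NO", "10HY", "20NO", "20HY"))
  expected_kept <- rownames(counts)[rowSums(counts) >= 5]
  f <- filter_low_counts(cm, 5)
  expect_identical(f$gene_ids, expected_kept)   # order preserved
  expect_false("g02" %in% f$gene_ids)
  expect_true("g01" %in% f$gene_ids)
  # threshold 0 is the identity
  expect_identical(filter_low_counts(cm, 0)$counts, cm$counts)
})

test_that("size factors follow the median-of-ratios definition", {
  # sample2 doubles sample1 for every gene: geometric mean splits the
  # depth difference, giving factors (1/sqrt(2), sqrt(2))
  counts <- matrix(c(10L, 20L, 30L, 20L, 40L, 60L), nrow = 3)
  cm <- toy_cm(counts, c("10NO", "20NO"))
  sf <- size_factors(cm)
  expect_equal(unname(sf), c(1 / sqrt(2), sqrt(2)), tolerance = 1e-12)
  expect_equal(unname(sf[2] / sf[1]), 2, tolerance = 1e-12)

  # identical samples give unit factors
  counts2 <- matrix(rep(c(5L, 9L, 14L), 4), nrow = 3)
  cm2 <- toy_cm(counts2, c("10NO", "10HY", "20NO", "20HY"))
  expect_equal(unname(size_factors(cm2)), rep(1, 4), tolerance = 1e-12)

  # a gene with a zero in any sample is excluded from the reference
  expect_error(size_factors(toy_cm(matrix(c(0L, 1L, 1L, 0L), 2),
                                   c("10NO", "10HY"))),
               "no gene")
})

test_that("shifted-log VST matches hand-computed values", {
  counts <- matrix(c(3L, 0L, 7L, 3L, 0L, 7L), nrow = 3)
  cm <- toy_cm(counts, c("10NO", "20NO"))
  v <- vst(cm)
  expect_false(v$batch_corrected)
  # identical samples -> unit size factors -> log2(count + 1)
  expect_equal(unname(v$values[, 1]), log2(c(3, 0, 7) + 1),
               tolerance = 1e-12)
  expect_equal(v$values[1, 1], 2, tolerance = 1e-12)
  expect_equal(v$values[2, 1], 0, tolerance = 1e-12)
})

test_that("filter -> vst pipeline is column-permutation equivariant", {
  cfg <- null_sim_config(n_genes = 100, seed = 7)
  cm <- simulate_counts(cfg)$counts
  set.seed(21)
  perm <- sample(ncol(cm$counts))
  cm_p <- count_matrix(cm$counts[, perm], cm$meta[perm, ])
  v <- vst(filter_low_counts(cm))
  v_p <- vst(filter_low_counts(cm_p))
  expect_equal(v_p$values, v$values[, perm], tolerance = 1e-12)
})

test_that("batch correction removes planted additive shifts", {
  # single batch: identity
  v1 <- toy_vst(matrix(rnorm(40), 10), rep(c("10NO", "20NO"), each = 2))
  expect_equal(remove_batch_effect(v1)$values, v1$values)

  # balanced design, additive shift delta on batch b2: exact removal
  set.seed(3)
  base <- matrix(rnorm(80), 10, 8)
  treatment <- rep(c("10NO", "10HY", "20NO", "20HY"), each = 2)
  batch <- rep(c("b1", "b2"), 4)
  delta <- 1.7
  vals <- base + delta * matrix(batch == "b2", 10, 8, byrow = TRUE)
  v <- toy_vst(vals, treatment, batch)
  corr <- remove_batch_effect(v)$values
  # least squares absorbs the whole batch-mean difference in a balanced
  # design, so the corrected batch means coincide exactly
  bdiff <- rowMeans(corr[, batch == "b2"]) - rowMeans(corr[, batch == "b1"])
  expect_lt(max(abs(bdiff)), 1e-10)
  # per-gene grand means preserved
  expect_equal(rowMeans(corr), rowMeans(vals), tolerance = 1e-12,
               ignore_attr = TRUE)

  # unbalanced toy equals the explicit least-squares solution
  treatment2 <- c("10NO", "10NO", "10NO", "20NO", "20NO")
  batch2 <- c("b1", "b1", "b2", "b1", "b2")
  set.seed(4)
  vals2 <- matrix(rnorm(15), 3, 5)
  v2 <- toy_vst(vals2, treatment2, batch2)
  corr2 <- remove_batch_effect(v2)$values
  # oracle: per-gene lm with sum-contrast batch, subtract batch component
  oracle <- t(apply(vals2, 1, function(y) {
    d <- data.frame(y = y, tr = factor(treatment2), b = factor(batch2))
    fit <- lm(y ~ tr + b, data = d,
              contrasts = list(b = "contr.sum"))
    bcomp <- model.matrix(fit)[, "b1", drop = FALSE] %*% coef(fit)["b1"]
    y - as.vector(bcomp)
  }))
  oracle <- oracle - rowMeans(oracle) + rowMeans(vals2)
  expect_equal(corr2, oracle, tolerance = 1e-9,
               ignore_attr = TRUE)

  # confounded design is refused
  v3 <- toy_vst(matrix(rnorm(20), 5, 4),
                c("10NO", "10NO", "20NO", "20NO"),
                c("b1", "b1", "b2", "b2"))
  expect_error(remove_batch_effect(v3), "confounded")
})

test_that("BH adjustment matches the direct step-up formula", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4),
               tolerance = 1e-12)
  expect_equal(bh_adjust(0.33), 0.33)
  expect_error(bh_adjust(c(0.1, 1.2)), "\\[0, 1\\]")

  set.seed(8)
  p <- runif(50)
  # independent oracle: p * m / rank, then running minimum from the top
  m <- length(p)
  o <- order(p, decreasing = TRUE)
  oracle <- pmin(1, cummin(p[o] * m / rank(p)[o]))[order(o)]
  expect_equal(bh_adjust(p), oracle, tolerance = 1e-12)
  expect_true(all(bh_adjust(p) >= p))

  # invariant under permutation (after re-ordering)
  perm <- sample(m)
  expect_equal(bh_adjust(p[perm])[order(perm)], bh_adjust(p),
               tolerance = 1e-12)
})

test_that("DEG calling uses a strict threshold and splits by sign", {
  de <- toy_de(c("a", "b", "c", "d"),
               log2fc = c(-2, 1.5, 3, -1),
               padj = c(0.049, 0.05, 0.001, NA))
  deg <- call_degs(de, 0.05)
  expect_identical(deg$down, "a")      # padj .049 down-gene
  expect_identical(deg$up, "c")        # padj .05 exactly is excluded
  empty <- call_degs(de[0, ], 0.05)
  expect_length(empty$up, 0)
  expect_length(empty$down, 0)
})
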