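test_that("cold-only DEG selection excludes warm-significant genes", {
  cold <- toy_de(c("a", "b", "c", "d", "e"),
                 log2fc = c(1.2, -0.8, 2.0, -1.5, 0.4),
                 padj = c(0.01, 0.03, 0.002, 0.04, 0.60))
  warm <- toy_de(c("a", "b", "c", "d", "e"),
                 log2fc = c(0.5, -0.5, 1.8, -1.2, 0.1),
                 padj = c(0.60, NA, 0.01, 0.20, 0.90))
  sel <- cold_only_degs(cold, warm, 0.05)
  expect_identical(sel$up, "a")            # warm padj .60
  expect_setequal(sel$down, c("b", "d"))   # missing warm padj counts as ns
  expect_identical(sel$overlap$up, "c")    # significant in both
  expect_identical(sel$overlap$total, 1L)

  none <- cold_only_degs(toy_de("a", 1, 0.9), toy_de("a", 1, 0.9))
  expect_length(none$up, 0)
  expect_length(none$down, 0)

  expect_error(cold_only_degs(cold, warm[-1, ]), "same gene universe")
})

test_that("raw fold change follows the directional convention", {
  expect_equal(raw_fold_change(1, "up"), 2)
  expect_equal(raw_fold_change(-2, "down"), 4)
  expect_equal(raw_fold_change(0, "up"), 1)
  expect_equal(raw_fold_change(0, "down"), 1)
  expect_equal(raw_fold_change(c(1, -1), c("up", "down")), c(2, 2))
})

test_that("classification follows the reaction-ratio decision table", {
  genes <- c("fu", "si", "gf", "amb")
  cold <- toy_de(genes, log2fc = c(2, 2, -1, 1),
                 padj = rep(0.01, 4))
  warm <- toy_de(genes, log2fc = c(0.5, 1, -2, 1),
                 padj = rep(0.60, 4))
  # constitutive VST means: 20NO vs 10NO
  vals <- rbind(fu = c(6.0, 6.0, 8.1, 8.1),    # higher at 20NO
                si = c(6.0, 6.0, 5.0, 5.0),    # lower at 20NO
                gf = c(5.0, 5.0, 5.0, 5.0),
                amb = c(4.0, 4.0, 4.0, 4.0))
  v <- toy_vst(vals, c("10NO", "10NO", "20NO", "20NO"))
  fr <- classify_frontloading(cold, warm, v)
  rec <- setNames(fr$category, fr$gene_id)
  expect_identical(unname(rec["fu"]), "frontloaded")
  expect_identical(unname(rec["si"]), "stress_indicator")
  # down-gene, cold -1 warm -2: ratio 2^2/2^1 = 2 > 1
  expect_identical(unname(rec["gf"]), "greater_fc")
  # ratio exactly 1 -> ambiguous
  expect_identical(unname(rec["amb"]), "ambiguous")

  fu_row <- fr[fr$gene_id == "fu", ]
  expect_equal(fu_row$reaction_ratio, 2^0.5 / 2^2, tolerance = 1e-12)
  expect_equal(fu_row$raw_fc_cold, 4)
  gf_row <- fr[fr$gene_id == "gf", ]
  expect_equal(gf_row$reaction_ratio, 2, tolerance = 1e-12)
  # fold magnitudes exceed 1 in the gene's own direction
  expect_true(all(fr$raw_fc_cold >= 1))
})

test_that("categories partition each direction and mirror under negation", {
  set.seed(31)
  n <- 60
  genes <- sprintf("g%02d", 1:n)
  l2c <- c(runif(n / 2, 0.5, 3), runif(n / 2, -3, -0.5))
  l2w <- l2c * runif(n, 0, 1.6)
  cold <- toy_de(genes, l2c, rep(0.01, n))
  warm <- toy_de(genes, l2w, rep(0.50, n))
  vals <- matrix(rnorm(n * 4, 6), n, 4,
                 dimnames = list(genes, paste0("s", 1:4)))
  v <- toy_vst(vals, c("10NO", "10NO", "20NO", "20NO"))
  fr <- classify_frontloading(cold, warm, v)
  s <- summarize_frontloading(fr)
  for (d in c("up", "down")) {
    blk <- s[[d]]
    expect_identical(sum(unlist(blk$counts)), blk$n)
  }
  expect_identical(s$up$n + s$down$n, as.integer(n))

  # direction symmetry: negate all log2FCs -> labels swap, categories map
  fr2 <- classify_frontloading(toy_de(genes, -l2c, rep(0.01, n)),
                               toy_de(genes, -l2w, rep(0.50, n)), v)
  m <- merge(fr, fr2, by = "gene_id")
  expect_true(all(m$direction.x != m$direction.y))
  # frontloaded flips to stress_indicator (constitutive inequality is
  # unchanged while the direction flips); greater_fc/ambiguous persist
  map <- c(frontloaded = "stress_indicator",
           stress_indicator = "frontloaded",
           greater_fc = "greater_fc", ambiguous = "ambiguous")
  expect_identical(unname(map[m$category.x]), m$category.y)
})

test_that("classification only uses the ordering of constitutive means", {
  genes <- c("a", "b")
  cold <- toy_de(genes, c(2, 1.5), c(0.01, 0.01))
  warm <- toy_de(genes, c(0.5, 0.2), c(0.5, 0.5))
  vals <- rbind(a = c(5, 5, 7, 7), b = c(6, 6, 3, 3))
  v <- toy_vst(vals, c("10NO", "10NO", "20NO", "20NO"))
  f1 <- classify_frontloading(cold, warm, v)
  v2 <- v; v2$values <- v$values * 10 + 2   # monotone rescaling
  f2 <- classify_frontloading(cold, warm, v2)
  expect_identical(f1$category, f2$category)
})

test_that("line-of-equality chi-squared matches its closed form", {
  r <- chisq_line_of_equality(317, 0)
  expect_equal(r$statistic, 317)
  expect_lt(r$p, 2.2e-16)
  r2 <- chisq_line_of_equality(690, 23)
  expect_equal(round(r2$statistic, 2), 623.97)
  r3 <- chisq_line_of_equality(10, 10)
  expect_equal(r3$statistic, 0)
  expect_equal(r3$p, 1)
  expect_error(chisq_line_of_equality(0, 0), "at least one")

  # symmetry and closed form (a-b)^2/(a+b); agrees with stats::chisq.test
  set.seed(32)
  for (i in 1:20) {
    a <- rpois(1, 50); b <- rpois(1, 10)
    if (a + b == 0) next
    r <- chisq_line_of_equality(a, b)
    expect_equal(r$statistic, (a - b)^2 / (a + b), tolerance = 1e-12)
    expect_equal(r$statistic, chisq_line_of_equality(b, a)$statistic)
    ref <- suppressWarnings(chisq.test(c(a, b), p = c(0.5, 0.5),
                                       correct = FALSE))
    expect_equal(r$statistic, unname(ref$statistic), tolerance = 1e-12)
    expect_equal(r$p, unname(ref$p.value), tolerance = 1e-12)
  }
})

test_that("summary percentages and DEG reduction match their definitions", {
  # reconstruct a classification with the published category structure:
  # 317 up (313 frontloaded + 4 stress indicators, all reduced-reaction),
  # 713 down (686 frontloaded + 4 stress + 23 greater-fold-change)
  up <- data.frame(
    gene_id = sprintf("u%03d", 1:317), direction = "up",
    reaction_ratio = 0.5,
    category = rep(c("frontloaded", "stress_indicator"), c(313, 4)),
    stringsAsFactors = FALSE)
  down <- data.frame(
    gene_id = sprintf("d%03d", 1:713), direction = "down",
    reaction_ratio = rep(c(0.5, 2), c(690, 23)),
    category = rep(c("frontloaded", "stress_indicator", "greater_fc"),
                   c(686, 4, 23)),
    stringsAsFactors = FALSE)
  s <- summarize_frontloading(rbind(up, down),
                              n_cold_degs = 1033, n_warm_degs = 88)
  expect_equal(s$up$pct$frontloaded, 98.7)
  expect_equal(s$down$pct$frontloaded, 96.2)
  expect_equal(s$reduction_pct, 91.5)
  expect_identical(s$n_total, 1030L)
  expect_equal(s$up$chisq$statistic, 317)
  expect_equal(round(s$down$chisq$statistic, 2), 623.97)

  # empty direction reports undefined percentages
  s2 <- summarize_frontloading(up)
  expect_true(all(is.na(unlist(s2$down$pct))))
})
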