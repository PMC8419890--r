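test_that("intensity filter applies the strict > 2/3 rule and is idempotent", {
  # pooled 30% quantile of 1..15 (type 7) is 5.2
  v <- rbind(c(1, 2, 10),    # below in 2/3 of samples: retained
             c(3, 4, 5),     # below in 3/3: removed
             c(6, 7, 8),     # never below: retained
             c(9, 11, 12),
             c(13, 14, 15))
  em <- make_em(v, scale = "raw_intensity")
  out <- filter_low_intensity(em)
  expect_setequal(gene_ids(out), c("g1", "g3", "g4", "g5"))
  expect_identical(attr(out, "removed_genes"), "g2")
  expect_equal(attr(out, "intensity_threshold"),
               unname(quantile(1:15, 0.3)))
  # second application reuses the recorded threshold: idempotent
  twice <- filter_low_intensity(out)
  expect_identical(twice$values, out$values)
})

test_that("count filter drops genes with summed counts below 100", {
  v <- rbind(c(0, 0), c(50, 50), c(99, 0), c(200, 10))
  em <- make_em(v, scale = "raw_count", platform = "seq")
  out <- filter_low_counts(em)
  expect_setequal(gene_ids(out), c("g2", "g4"))   # sum 100 retained
  expect_setequal(attr(out, "removed_genes"), c("g1", "g3"))
  expect_identical(filter_low_counts(out)$values, out$values)
  expect_error(filter_low_counts(make_em(rbind(c(-1, 5)),
                                         scale = "raw_count",
                                         platform = "seq")),
               "non-negative")
})

test_that("global-median normalization equalizes sample medians", {
  # two samples with medians 5 and 7 -> both medians become 6
  v <- cbind(c(4, 5, 6), c(6, 7, 8))
  em <- make_em(v, scale = "log2")
  out <- log2_global_median_normalize(em)
  expect_equal(unname(apply(out$values, 2, median)), c(6, 6))
  # already-equal medians: unchanged; single sample: unchanged
  expect_equal(log2_global_median_normalize(out)$values, out$values)
  single <- make_em(cbind(c(1, 2, 3)), scale = "log2")
  expect_equal(log2_global_median_normalize(single)$values, single$values)
  # counts get the +1 offset before log2
  cm <- make_em(cbind(c(0, 1, 3)), scale = "raw_count", platform = "seq")
  expect_equal(unname(log2_global_median_normalize(cm)$values[, 1]),
               log2(c(1, 2, 4)))
  expect_error(log2_global_median_normalize(
    make_em(cbind(c(-2, 1, 5)), scale = "raw_intensity")), "positive")
  # property: per-sample medians agree to 1e-9 on random matrices
  set.seed(11)
  r <- make_em(matrix(rnorm(200, 8), 20, 10), scale = "log2")
  meds <- apply(log2_global_median_normalize(r)$values, 2, median)
  expect_lt(diff(range(meds)), 1e-9)
})

test_that("median centering zeroes per-gene medians within platform", {
  em <- make_em(rbind(c(1, 2, 3)), scale = "log2")
  expect_equal(unname(median_center(em)$values[1, ]), c(-1, 0, 1))
  const <- make_em(rbind(c(4, 4, 4)), scale = "log2")
  expect_true(all(median_center(const)$values == 0))
  # two platforms centered independently
  v <- rbind(c(1, 2, 3, 10, 20, 30), c(5, 6, 7, 0, 0, 4))
  em2 <- make_em(v, scale = "log2")
  pl <- rep(c("a", "b"), each = 3)
  out <- median_center(em2, platform = pl)
  for (p in c("a", "b")) {
    med <- apply(out$values[, pl == p, drop = FALSE], 1, median)
    expect_true(all(abs(med) < 1e-9))
  }
})

test_that("merging keeps the sorted common gene set and all samples", {
  a <- make_em(matrix(1, 3, 2), genes = c("A", "B", "C"),
               samples = c("a1", "a2"), scale = "log2")
  b <- make_em(matrix(2, 3, 2), genes = c("B", "C", "D"),
               samples = c("b1", "b2"), scale = "log2", platform = "seq")
  m <- merge_common_genes(a, b)
  expect_identical(gene_ids(m), c("B", "C"))
  expect_identical(sample_ids(m), c("a1", "a2", "b1", "b2"))
  expect_identical(unname(attr(m, "sample_platform")),
                   c("array", "array", "seq", "seq"))
  d <- make_em(matrix(1, 2, 2), genes = c("X", "Y"),
               samples = c("d1", "d2"), scale = "log2")
  expect_error(merge_common_genes(a, d), "no common genes")
  dup <- make_em(matrix(1, 3, 2), genes = c("A", "B", "C"),
                 samples = c("a1", "x"), scale = "log2", platform = "seq")
  expect_error(merge_common_genes(a, dup), "duplicate sample")
})

test_that("quantile normalization maps columns to the shared target", {
  em <- make_em(cbind(c(2, 4, 6), c(1, 5, 9)))
  out <- quantile_normalize(em)
  expect_equal(unname(out$values), cbind(c(1.5, 4.5, 7.5), c(1.5, 4.5, 7.5)))
  # fixed point when all columns already identical
  same <- make_em(cbind(c(1, 3, 2), c(1, 3, 2)))
  expect_equal(quantile_normalize(same)$values, same$values)
  # permuted columns map to the same multiset; sorted columns identical
  set.seed(2)
  x <- matrix(rnorm(50), 10, 5)
  x[, 5] <- x[sample(10), 4]
  q <- quantile_normalize(make_em(x))$values
  sorted <- apply(q, 2, sort)
  for (j in 2:5) expect_identical(sorted[, j], sorted[, 1])
  # agrees with limma on tie-free data
  expect_equal(unname(q), unname(limma::normalizeQuantiles(x)),
               tolerance = 1e-12)
})

test_that("batch correction removes planted shifts and spares group effects", {
  set.seed(31)
  n_genes <- 300; n_per <- 20
  batch <- rep(c("array", "seq"), each = n_per)
  group <- rep(rep(c("young", "neph"), each = n_per / 2), 2)
  shift <- rnorm(n_genes, 0, 1)
  grp_eff <- rnorm(n_genes, 0, 0.8)
  v <- matrix(rnorm(n_genes * 2 * n_per, 6, 0.5), n_genes)
  v[, batch == "seq"] <- v[, batch == "seq"] + shift
  v[, group == "neph"] <- v[, group == "neph"] + grp_eff
  em <- make_em(v)
  out <- batch_correct(em, batch, group = group)
  gap_before <- rowMeans(v[, batch == "seq"]) - rowMeans(v[, batch == "array"])
  gap_after <- rowMeans(out$values[, batch == "seq"]) -
    rowMeans(out$values[, batch == "array"])
  expect_lt(mean(abs(gap_after)) / mean(abs(gap_before)), 0.05)
  ge_before <- rowMeans(v[, group == "neph"]) - rowMeans(v[, group == "young"])
  ge_after <- rowMeans(out$values[, group == "neph"]) -
    rowMeans(out$values[, group == "young"])
  expect_lt(mean(abs(ge_after - ge_before)) / mean(abs(ge_before)), 0.05)
})

test_that("batch correction degenerate cases behave", {
  set.seed(5)
  v <- matrix(rnorm(100, 6), 10)
  em <- make_em(v)
  # single batch: unchanged
  expect_identical(batch_correct(em, rep("a", 10))$values, em$values)
  # two batches that are exact copies: output close to input
  v2 <- cbind(v, v)
  colnames(v2) <- sprintf("s%d", 1:20)
  em2 <- make_em(v2)
  out <- batch_correct(em2, rep(c("a", "b"), each = 10))
  expect_lt(max(abs(out$values - em2$values)) / sd(v2), 0.15)
  expect_error(batch_correct(em, c("a", rep("b", 9))), "at least 2 samples")
  const <- make_em(matrix(rep(c(1, 2), each = 6), 2, 6, byrow = TRUE))
  expect_error(batch_correct(const, rep(c("a", "b"), 3)), "variance")
})

test_that("batch correction matches the reference empirical-Bayes tool", {
  set.seed(77)
  n_genes <- 80
  batch <- rep(c("a", "b"), each = 8)
  v <- matrix(rnorm(n_genes * 16, 7, 1), n_genes)
  v[, batch == "b"] <- v[, batch == "b"] + rnorm(n_genes, 0, 0.8)
  em <- make_em(v)
  ours <- batch_correct(em, batch)$values
  ref <- sva::ComBat(dat = v, batch = batch)
  expect_equal(unname(ours), unname(ref), tolerance = 1e-4)
})

test_that("the full cascade improves paired cross-platform agreement", {
  cfg <- sim_config(n_genes = 250, n_reps = 2, n_paired = 10, seed = 8)
  sim <- generate_expression(cfg)
  merged <- run_preprocess(sim$array, sim$seq, sim$meta, verbose = FALSE)
  paired <- names(which(table(sim$meta$mouse_id) == 2))
  g <- gene_ids(merged)
  # "before": naive merge of log2 data (per-gene grand mean removed, platform
  # offsets left in); "after": the full normalization cascade
  naive <- cbind(log2(sim$array$values[g, , drop = FALSE]),
                 log2(sim$seq$values[g, , drop = FALSE] + 1))
  naive <- naive - rowMeans(naive)
  cor_before <- cor_after <- numeric(0)
  for (m in paired) {
    ids <- sim$meta$sample_id[sim$meta$mouse_id == m]
    aid <- ids[grepl("_array$", ids)]; sid <- ids[grepl("_seq$", ids)]
    cor_before <- c(cor_before,
                    cor(naive[, aid], naive[, sid], method = "spearman"))
    cor_after <- c(cor_after,
                   cor(merged$values[g, aid], merged$values[g, sid],
                       method = "spearman"))
  }
  expect_gt(mean(cor_after), mean(cor_before))
  # stage log recorded
  expect_true(is.data.frame(attr(merged, "stage_log")))
})

test_that("preprocessing errors are explicit", {
  a <- make_em(matrix(5, 2, 2), genes = c("A", "B"), samples = c("a1", "a2"),
               scale = "raw_intensity")
  s <- make_em(matrix(200, 2, 2), genes = c("X", "Y"),
               samples = c("s1", "s2"), scale = "raw_count", platform = "seq")
  meta <- make_meta(c("a1", "a2", "s1", "s2"), group = "young",
                    zt = c(0, 12, 0, 12),
                    platform = c("array", "array", "seq", "seq"))
  expect_error(run_preprocess(a, s, meta, verbose = FALSE), "common genes")
  expect_error(run_preprocess(a, s, meta[1:2, ], verbose = FALSE),
               "absent from metadata")
})
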