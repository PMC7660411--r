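test_that("significance thresholding follows the mean +/- k*sd rule", {
  zeros <- setNames(rep(0, 10), sprintf("g%02d", 1:10))
  expect_warning(res <- significant_genes(zeros, k = 2), "constant")
  expect_length(res$positive_genes, 0)
  expect_length(res$negative_genes, 0)

  # 99 zeros and one spike: population mean 0.009, sd ~0.0896
  P <- setNames(c(rep(0, 99), 0.9), sprintf("g%03d", 1:100))
  res <- significant_genes(P, k = 2)
  expect_equal(res$mean, 0.009)
  expect_equal(res$sd, sqrt(mean((P - 0.009)^2)))
  expect_equal(res$positive_genes, "g100")
  expect_length(res$negative_genes, 0)

  # strict inequality at k = 0: the gene at the mean is excluded
  P2 <- setNames(c(-1, 0, 1), c("g1", "g2", "g3"))
  res2 <- significant_genes(P2, k = 0)
  expect_equal(res2$positive_genes, "g3")
  expect_equal(res2$negative_genes, "g1")
  expect_false("g2" %in% c(res2$positive_genes, res2$negative_genes))
})

test_that("direction naming maps sign to tumor regulation by semantics", {
  P <- setNames(c(0.9, -0.9, 0), c("up1", "dn1", "flat"))
  res <- significant_genes(P, k = 0, semantics = "tumor_to_normal")
  expect_equal(genes_by_direction(res, "tumor_down"), "up1")
  expect_equal(genes_by_direction(res, "tumor_up"), "dn1")
  rev <- significant_genes(P, k = 0, semantics = "normal_to_tumor")
  expect_equal(genes_by_direction(rev, "tumor_up"), "up1")
  expect_equal(genes_by_direction(rev, "tumor_down"), "dn1")
})

test_that("two-sigma flagging on Gaussian noise matches the 4.6% mass", {
  set.seed(51)
  P <- setNames(rnorm(10000), sprintf("g%05d", 1:10000))
  res <- significant_genes(P, k = 2)
  rate <- (length(res$positive_genes) + length(res$negative_genes)) / 10000
  expect_lt(abs(rate - 0.0455), 0.015)
})

test_that("gene lists are sorted by absolute deviation, descending", {
  P <- setNames(c(0.5, 0.9, 0.7, -0.8, -0.6), sprintf("g%d", 1:5))
  res <- significant_genes(P, k = 0)
  expect_equal(res$positive_genes[1], "g2")
  dev <- abs(P[res$positive_genes] - res$mean)
  expect_true(all(diff(dev) <= 0))
})

test_that("rank_gene_extremes orders by signed value with lexicographic ties", {
  P <- setNames(c(0.3, -0.1, 0.5), c("g1", "g2", "g3"))
  expect_equal(rank_gene_extremes(P, 2, "up"), c("g3", "g1"))
  expect_equal(rank_gene_extremes(P, 2, "down"), c("g2", "g1"))
  tied <- setNames(c(0.5, 0.5, 0.1), c("b", "a", "c"))
  expect_equal(rank_gene_extremes(tied, 2, "up"), c("a", "b"))

  set.seed(52)
  for (i in 1:20) {
    P <- setNames(rnorm(30), sprintf("g%02d", 1:30))
    n <- sample(30, 1)
    full_sort <- names(sort(P, decreasing = TRUE))
    expect_setequal(rank_gene_extremes(P, n, "up"), full_sort[seq_len(n)])
  }
})

test_that("overlap ratio is the Jaccard index with counts", {
  expect_equal(overlap_ratio(c("a", "b", "c"), c("b", "c", "d")),
               list(ratio = 0.5, n_shared = 2L, n_union = 4L))
  expect_equal(overlap_ratio(c("a", "b"), c("a", "b"))$ratio, 1.0)
  expect_equal(overlap_ratio(c("a"), c("b")),
               list(ratio = 0, n_shared = 0L, n_union = 2L))
  expect_equal(overlap_ratio(character(), character()),
               list(ratio = 0, n_shared = 0L, n_union = 0L))

  set.seed(53)
  pool <- sprintf("g%03d", 1:200)
  for (i in 1:1000) {
    a <- sample(pool, sample(0:40, 1))
    b <- sample(pool, sample(0:40, 1))
    got <- overlap_ratio(a, b)
    expect_equal(got$n_shared, length(intersect(a, b)))
    expect_equal(got$n_union, length(unique(c(a, b))))
    expect_true(got$ratio >= 0 && got$ratio <= 1)
    expect_equal(got$ratio, overlap_ratio(b, a)$ratio)
  }
})

make_result <- function(P, id) {
  significant_genes(P, k = 1, sample_id = id)
}

test_that("pairwise overlap matrices are symmetric and match the scalar oracle", {
  set.seed(54)
  results <- lapply(1:4, function(i) {
    make_result(setNames(rnorm(100), sprintf("g%03d", 1:100)), paste0("p", i))
  })
  om <- pairwise_overlap_matrix(results, direction = "tumor_up")
  expect_equal(om$ratio, t(om$ratio))
  expect_equal(unname(diag(om$ratio)), rep(1, 4))
  for (i in 1:4) for (j in 1:4) {
    ov <- overlap_ratio(genes_by_direction(results[[i]], "tumor_up"),
                        genes_by_direction(results[[j]], "tumor_up"))
    expect_equal(om$ratio[i, j], ov$ratio)
    expect_equal(om$n_shared[i, j], ov$n_shared)
  }
  # identical results give off-diagonal 1
  om2 <- pairwise_overlap_matrix(list(a = results[[1]], b = results[[1]]),
                                 direction = "tumor_down")
  expect_equal(unname(om2$ratio), matrix(1, 2, 2))

  long <- tidy(om)
  expect_equal(nrow(long), 6L)
  expect_equal(long$ratio[long$patient_a == "p1" & long$patient_b == "p2"],
               om$ratio["p1", "p2"])
})

test_that("DGE table reader accepts DESeq2-style aliases", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("gene\tlog2FoldChange\tpadj",
               "g1\t2.5\t1e-6",
               "g2\t-1.2\t0.5",
               "g3\t0.8\t1e-5"), path)
  tab <- read_dge_table(path)
  expect_equal(tab$gene_id, c("g1", "g2", "g3"))
  expect_equal(tab$log2_fold_change, c(2.5, -1.2, 0.8))
  writeLines(c("gene_id\tlfc\tfdr", "g1\t1\t0.01"), path)
  expect_equal(nrow(read_dge_table(path)), 1L)
  writeLines(c("gene\tstat\tpadj", "g1\t1\t0.01"), path)
  expect_error(read_dge_table(path), "log2 fold change")
})

test_that("DGE overlap percentages follow the set-intersection oracle", {
  dge <- tibble::tibble(
    gene_id = sprintf("g%03d", 1:100),
    log2_fold_change = rep(c(1, -1), 50),
    adjusted_p = c(rep(1e-6, 40), rep(0.5, 60))
  )
  # tumor-up list fully inside the significant positive-lfc set
  res <- make_fixed_result(up = c("g001", "g003"), down = c("g002", "g004"))
  ov <- dge_overlap(res, dge, alpha = 1e-4)
  expect_equal(ov$percentage[ov$direction == "tumor_up"], 100)
  expect_equal(ov$formatted[ov$direction == "tumor_up"], "100.0% (2/2)")

  # 1 of 4 in the set
  res2 <- make_fixed_result(up = c("g001", "g041", "g043", "g045"),
                            down = character())
  ov2 <- dge_overlap(res2, dge, alpha = 1e-4, direction = "tumor_up")
  expect_equal(ov2$percentage, 25)
  expect_equal(ov2$formatted, "25.0% (1/4)")
  expect_warning(ov3 <- dge_overlap(res2, dge, direction = "tumor_down"),
                 "empty")
  expect_equal(ov3$percentage, 0)

  set.seed(55)
  for (i in 1:1000) {
    up <- sample(dge$gene_id, sample(1:20, 1))
    res_i <- make_fixed_result(up = up, down = character())
    got <- suppressWarnings(dge_overlap(res_i, dge, alpha = 1e-4,
                                        direction = "tumor_up"))
    sig_up <- dge$gene_id[dge$adjusted_p < 1e-4 & dge$log2_fold_change > 0]
    expect_equal(got$percentage, 100 * length(intersect(up, sig_up)) / length(up))
  }
})

test_that("perturbation histograms report sd and outlier counts per vector", {
  set.seed(56)
  Pa <- setNames(rnorm(500, sd = 0.02), sprintf("g%03d", 1:500))
  Pb <- setNames(rnorm(500, sd = 0.2), sprintf("g%03d", 1:500))
  ra <- significant_genes(Pa, k = 2, sample_id = "normal")
  rb <- significant_genes(Pb, k = 2, sample_id = "tumor")
  out <- perturbation_histogram(ra, rb)
  expect_s3_class(out$plot, "ggplot")
  expect_equal(out$summary$sd, c(ra$sd, rb$sd))
  expect_equal(out$summary$n_outside_2sd[1],
               sum(abs(Pa - mean(Pa)) > 2 * ra$sd))
  expect_lt(out$summary$sd[1], out$summary$sd[2])

  zero <- suppressWarnings(significant_genes(setNames(rep(0, 500), names(Pa)),
                                             k = 2, sample_id = "z"))
  out0 <- perturbation_histogram(zero, zero)
  expect_equal(out0$summary$sd, c(0, 0))
  expect_equal(out0$summary$n_outside_2sd, c(0L, 0L))
})
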