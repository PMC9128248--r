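# Omics-defined gene-pair relationship tables.

test_that("common-regulator tables count shared regulators per class", {
  tr <- data.frame(
    regulator = c("TF1", "TF1", "TF2", "TF2", "TF3", "miR1", "miR1"),
    class = c("TF", "TF", "TF", "TF", "TF", "miRNA", "miRNA"),
    target = c("A", "B", "A", "B", "C", "A", "B"),
    stringsAsFactors = FALSE)
  tf <- cotr_from_tr(tr, "TF")
  expect_equal(attr(tf, "kind"), "TFCoTR")
  expect_equal(nrow(tf), 1L)
  expect_equal(tf$n_regulators[tf$gene_a == "A" & tf$gene_b == "B"], 2L)
  mir <- cotr_from_tr(tr, "miRNA")
  expect_equal(attr(mir, "kind"), "miRCoTR")
  expect_equal(mir$n_regulators, 1L)
  # pairs with no shared regulator are absent
  expect_false("A|C" %in% pminet:::rel_keys(tf))
})

test_that("direct TR and PPI records canonicalize to unordered pairs", {
  tr <- data.frame(regulator = c("TF1", "B"), class = "TF",
                   target = c("B", "TF1"), stringsAsFactors = FALSE)
  tp <- tr_pairs(tr)
  expect_equal(nrow(tp), 1L)
  expect_equal(pminet:::rel_keys(tp), "B|TF1")
  ppi <- ppi_pairs(data.frame(a = c("P1", "P2", "P3"),
                              b = c("P2", "P1", "P3")))
  expect_equal(pminet:::rel_keys(ppi), "P1|P2")  # dup merged, self dropped
})

test_that("same-chromosome distance uses strand-aware TSS", {
  coords <- data.frame(
    gene = c("A", "B", "C", "D"),
    chrom = c("chr1", "chr1", "chr1", "chr2"),
    start = c(100, 600, 1000, 50),
    end = c(200, 700, 1100, 80),
    strand = c("+", "+", "-", "+"), stringsAsFactors = FALSE)
  tab <- scgd(coords)
  w <- setNames(tab$distance, pminet:::rel_keys(tab))
  expect_equal(w[["A|B"]], 500)        # both + strand: starts 100 vs 600
  expect_equal(w[["A|C"]], 1000)       # C on - strand: TSS is its end
  expect_equal(w[["B|C"]], 500)
  expect_false(any(grepl("D", names(w))))  # different chromosome: absent
  coords$strand[1] <- "?"
  expect_error(scgd(coords), "strand")
})

test_that("CoCNV status follows the sign rules with level products", {
  expect_equal(cocnv_status(2, 1), list(status = "GG", level_product = 2L))
  expect_equal(cocnv_status(-1, 0), list(status = "NC", level_product = 0L))
  expect_equal(cocnv_status(-2, 1)$status, "LG")
  expect_equal(cocnv_status(-2, 1)$level_product, 2L)
  expect_equal(cocnv_status(1, -2)$status, "GL")
  expect_equal(cocnv_status(-1, -2), list(status = "LL",
                                          level_product = 2L))
  expect_error(cocnv_status(3, 0), "-2..2")
})

test_that("CoCNV tables count, normalize and weight by level product", {
  cnv <- matrix(0L, nrow = 2, ncol = 10,
                dimnames = list(c("A", "B"), sprintf("s%02d", 1:10)))
  # GG in 3 samples with products 1, 2, 4; LL in 1 sample
  cnv[, 1] <- c(1L, 1L); cnv[, 2] <- c(1L, 2L); cnv[, 3] <- c(2L, 2L)
  cnv[, 4] <- c(-1L, -1L)
  tabs <- cocnv_table(cnv, data.frame(gene_a = "A", gene_b = "B"))
  gg <- tabs$GG
  expect_equal(gg$n_samples, 3L)
  expect_equal(gg$fraction, 0.3)
  expect_equal(gg$weighted, 7)
  expect_equal(tabs$LL$n_samples, 1L)
  expect_equal(nrow(tabs$GL), 0L)
  # per-pair status counts partition the samples
  st <- cocnv_status(cnv["A", ], cnv["B", ])$status
  expect_equal(sum(table(st)), 10L)
  expect_equal(sum(st == "NC"), 6L)
})

test_that("GL/LG orientation is tied to the canonical gene order", {
  cnv <- matrix(c(1L, -1L), nrow = 2, ncol = 4,
                dimnames = list(c("A", "B"), sprintf("s%d", 1:4)))
  tabs <- cocnv_table(cnv, data.frame(gene_a = "B", gene_b = "A"))
  # canonical order is (A, B): A gained, B lost -> GL
  expect_equal(nrow(tabs$GL), 1L)
  expect_equal(nrow(tabs$LG), 0L)
})

test_that("methylation island counts respect the thresholds", {
  beta <- matrix(c(0.1, 0.2, 0.9,
                   0.5, 0.5, 0.5), nrow = 6, ncol = 2,
                 dimnames = list(sprintf("cpg%d", 1:6), c("s1", "s2")))
  beta[, 2] <- c(0.1, 0.2, 0.9, 0.5, 0.5, 0.5)[c(4, 5, 6, 1, 2, 3)]
  map <- data.frame(cpg = sprintf("cpg%d", 1:6),
                    gene = rep(c("G1", "G2"), each = 3),
                    stringsAsFactors = FALSE)
  counts <- dm_gene_counts(beta, map)
  expect_equal(counts$L["G1", "s1"], 2L)
  expect_equal(counts$H["G1", "s1"], 1L)
  expect_equal(counts$L["G2", "s1"], 0L)   # all betas intermediate
  expect_equal(counts$H["G2", "s1"], 0L)
  map2 <- rbind(map, data.frame(cpg = "cpg99", gene = "G3"))
  expect_warning(dm_gene_counts(beta, map2), "no mapped CpG")
  expect_error(dm_gene_counts(beta, map, low_thr = 0.8, high_thr = 0.7),
               "low_thr")
})

test_that("CoDM profiles are cross products with the algebraic identity", {
  p <- codm_profile(c(L = 2, H = 3), c(L = 1, H = 4))
  expect_equal(p$LL, 2); expect_equal(p$HH, 12)
  expect_equal(p$LH, 8); expect_equal(p$HL, 3)
  expect_equal(codm_profile(c(L = 0, H = 0), c(L = 5, H = 2)),
               data.frame(LL = 0, HH = 0, LH = 0, HL = 0))
  set.seed(1)
  for (rep in 1:20) {
    c1 <- c(L = sample(0:5, 1), H = sample(0:5, 1))
    c2 <- c(L = sample(0:5, 1), H = sample(0:5, 1))
    pr <- codm_profile(c1, c2)
    expect_equal(pr$HH * pr$LL, pr$LH * pr$HL)
  }
})

test_that("CoDM tables normalize weight sums by the cohort size", {
  L <- matrix(c(2L, 1L, 0L, 3L), 2, 2, dimnames = list(c("A", "B"),
                                                       c("s1", "s2")))
  H <- matrix(c(1L, 2L, 2L, 0L), 2, 2, dimnames = list(c("A", "B"),
                                                       c("s1", "s2")))
  tabs <- codm_table(list(L = L, H = H),
                     data.frame(gene_a = "A", gene_b = "B"))
  # LL: s1 = 2*1 = 2, s2 = 0*3 = 0
  expect_equal(tabs$LL$n_samples, 1L)
  expect_equal(tabs$LL$weight_sum, 2)
  expect_equal(tabs$LL$weight_norm, 1)     # sum / 2 samples
  expect_equal(tabs$HH$weight_sum, 1 * 2 + 2 * 0)
  for (v in names(tabs)) {
    t <- tabs[[v]]
    if (nrow(t)) expect_equal(t$weight_norm * 2, t$weight_sum)
  }
})

test_that("relationship tables reject self-pairs and stay canonical", {
  expect_error(pminet:::new_relationship_table(
    data.frame(gene_a = "A", gene_b = "A", w = 1), kind = "PPI"),
    "self-pair")
  tab <- pminet:::new_relationship_table(
    data.frame(gene_a = c("Z", "B"), gene_b = c("A", "C"), w = c(1, 2)),
    kind = "PPI")
  expect_true(all(tab$gene_a <= tab$gene_b))
})
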