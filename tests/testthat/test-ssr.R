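gt4 <- function() genotype_table(paste0("i", 1:4), list(
  L1 = rbind(c("A", "B"), c("A", "B"), c("A", "A"), c("B", "B"))))

test_that("locus diversity matches the hand-worked example", {
  d <- locus_diversity(gt4(), "L1", unbiased = FALSE)
  expect_equal(d$Ao, 2L)
  expect_equal(d$Ho, 0.5)
  expect_equal(d$He, 0.5)
  expect_equal(d$PD, 1 - (0.5^2 + 0.25^2 + 0.25^2))
  # monomorphic locus
  mono <- genotype_table(paste0("i", 1:10),
                         list(L = matrix("A", 10, 2)))
  dm <- locus_diversity(mono, "L")
  expect_equal(c(dm$Ao, dm$Ho, dm$He, dm$PD), c(1, 0, 0, 0))
  # Nei unbiased correction factor 2n/(2n-1)
  du <- locus_diversity(gt4(), "L1", unbiased = TRUE)
  expect_equal(du$He, 0.5 * 8 / 7)
})

test_that("diversity is invariant to allele relabeling and row order", {
  gt <- sim_ssr_genotypes(30, list(L = c(a = .2, b = .3, c = .5)), seed = 4)
  d1 <- locus_diversity(gt, "L")
  relab <- gt
  relab$calls$L[] <- chartr("abc", "zyx", relab$calls$L)
  d2 <- locus_diversity(relab, "L")
  expect_equal(d1, d2)
  shuf <- genotype_table(gt$individuals[30:1],
                         list(L = gt$calls$L[30:1, ]))
  expect_equal(locus_diversity(shuf, "L"), d1)
})

test_that("ssr diversity table appends the Average row", {
  gt <- sim_ssr_genotypes(20, list(A = c(x = .5, y = .5),
                                   B = c(p = .9, q = .1)), seed = 2)
  tab <- ssr_diversity_table(gt)
  expect_equal(tab$Locus, c("A", "B", "Average"))
  expect_equal(tab$Ao[3], mean(tab$Ao[1:2]))
})

test_that("rare-allele filtering is strict at the threshold", {
  # 25 individuals: allele 'r' appears twice in 50 -> freq 0.04 < 0.05
  m <- matrix("A", 25, 2)
  m[1, ] <- c("A", "r"); m[2, ] <- c("B", "r")
  m[3:12, 2] <- "B"
  gt <- genotype_table(paste0("i", 1:25), list(L = m))
  filt <- rare_allele_filter(gt, 0.05)
  left <- unique(as.vector(filt$calls$L))
  expect_false("r" %in% left[!is.na(left)])
  expect_true(all(is.na(filt$calls$L[1:2, ])))      # carriers masked
  expect_false(anyNA(filt$calls$L[3:25, ]))
  # exactly at the threshold: retained
  m2 <- matrix("A", 10, 2)
  m2[1, 2] <- "e"                                   # 1/20 = 0.05
  gt2 <- genotype_table(paste0("i", 1:10), list(L = m2))
  expect_warning(f2 <- rare_allele_filter(gt2, 0.05), NA)
  expect_true("e" %in% as.vector(f2$calls$L))
  # no rare alleles: identity
  gt3 <- gt4()
  expect_equal(rare_allele_filter(gt3, 0.05)$calls, gt3$calls)
})

test_that("filtering that leaves a locus monomorphic warns and flags it", {
  m <- matrix("A", 30, 2)
  m[1, 2] <- "b"
  gt <- genotype_table(paste0("i", 1:30),
                       list(L = m, M = matrix(rep(c("x", "y"), 30),
                                              30, 2, byrow = TRUE)))
  expect_warning(filt <- rare_allele_filter(gt, 0.05), "monomorphic")
  expect_equal(attr(filt, "monomorphic"), "L")
})

test_that("r2 is 1 for perfect coupling and matches the indicator oracle", {
  n <- 16
  m1 <- rbind(matrix("A", n / 2, 2), matrix("a", n / 2, 2))
  m2 <- rbind(matrix("B", n / 2, 2), matrix("b", n / 2, 2))
  gt <- genotype_table(paste0("i", 1:n), list(L1 = m1, L2 = m2))
  ld <- ld_scan(gt, n_perm = 100, seed = 1)
  expect_true(all(abs(ld$allele_pairs$r2 - 1) < 1e-12))
  # random biallelic data: r2 equals squared Pearson cor of dosages
  gt2 <- sim_ssr_genotypes(40, list(L1 = c(A = .6, a = .4),
                                    L2 = c(B = .3, b = .7)), seed = 9)
  ld2 <- ld_scan(gt2, method = "chisq")
  x <- rowSums(gt2$calls$L1 == "A")
  y <- rowSums(gt2$calls$L2 == "B")
  want <- cor(x, y)^2
  got <- ld2$allele_pairs$r2[ld2$allele_pairs$allele1 == "A" &
                             ld2$allele_pairs$allele2 == "B"]
  expect_equal(got, want, tolerance = 1e-12)
})

test_that("permutation p-values are deterministic under a fixed seed", {
  gt <- sim_ssr_genotypes(30, list(L1 = c(A = .5, a = .5),
                                   L2 = c(B = .5, b = .5),
                                   L3 = c(C = .5, c = .5)), seed = 12)
  ld1 <- ld_scan(gt, n_perm = 200, seed = 99)
  ld2 <- ld_scan(gt, n_perm = 200, seed = 99)
  expect_identical(ld1$locus_pairs$p, ld2$locus_pairs$p)
  expect_error(ld_scan(gt, n_perm = 200), "seed")
})

test_that("the P matrix export is square, symmetric, unit-diagonal", {
  gt <- sim_ssr_genotypes(30, list(L1 = c(A = .5, a = .5),
                                   L2 = c(B = .5, b = .5),
                                   L3 = c(C = .4, c = .6)), seed = 5)
  ld <- ld_scan(gt, n_perm = 150, seed = 7)
  f <- withr::local_tempfile(fileext = ".tsv")
  M <- export_p_matrix(ld, f)
  expect_equal(dim(M), c(3L, 3L))
  expect_equal(M, t(M))
  expect_equal(unname(diag(M)), rep(1, 3))
  back <- as.matrix(read.table(f, sep = "\t", header = TRUE, row.names = 1))
  expect_equal(unname(back), unname(round(M, 6)), tolerance = 1e-6)
  expect_true(file.exists(paste0(f, ".pairs")))
})

test_that("genotype tables round-trip through delimited text", {
  gt <- sim_ssr_genotypes(15, list(LocA = c(`101` = .5, `103` = .5),
                                   LocB = c(`7` = .8, `9` = .2)), seed = 3)
  gt$calls$LocA[3, ] <- NA
  gt <- genotype_table(gt$individuals, gt$calls)
  f <- withr::local_tempfile(fileext = ".tsv")
  write_genotypes(gt, f)
  back <- read_genotypes(f)
  expect_equal(back$loci, gt$loci)
  expect_equal(back$calls, gt$calls)
  # half-missing calls are rejected
  bad <- gt$calls
  bad$LocA[1, 1] <- NA
  expect_error(genotype_table(gt$individuals, bad), "half-missing")
})
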