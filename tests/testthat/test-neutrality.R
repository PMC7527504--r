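test_that("Tajima constants and a hand-computed small case check out", {
  cst <- slocuspop:::tajima_constants(4)
  expect_equal(cst$a1, 1 + 1 / 2 + 1 / 3, tolerance = 1e-12)
  expect_equal(slocuspop:::tajima_constants(2)$a1, 1)
  # hand-enumerated: 4 sequences, 2 segregating sites, k-hat = 1
  a <- alignment(paste0("s", 1:4), c("AAT", "AAA", "AAA", "GAA"))
  td <- tajima_D(a)
  expect_equal(td$S, 2L)
  expect_equal(td$k_hat, 1)
  a1 <- cst$a1
  denom <- sqrt(cst$e1 * 2 + cst$e2 * 2 * 1)
  expect_equal(td$D, (1 - 2 / a1) / denom, tolerance = 1e-12)
  # denominator positive whenever S >= 1 and n >= 4 (both variance
  # coefficients vanish identically at n = 3, hence the n >= 4 advice)
  for (n in 4:30) {
    cc <- slocuspop:::tajima_constants(n)
    expect_gt(cc$e1, 0)
    expect_gt(cc$e2, 0)
  }
  c3 <- slocuspop:::tajima_constants(3)
  expect_equal(c3$e1, 0, tolerance = 1e-12)
  expect_equal(c3$e2, 0, tolerance = 1e-12)
})

test_that("Tajima's D is undefined without polymorphism", {
  a <- alignment(paste0("s", 1:4), rep("ACGTACGT", 4))
  expect_true(is.na(tajima_D(a)$D))
})

test_that("partitioned D respects class purity", {
  # every variant synonymous -> D_A undefined, D_S defined
  base <- strrep("GGAACT", 40)
  seqs <- c(base,
            paste0("GGG", substr(base, 4, nchar(base))),
            paste0("GGC", substr(base, 4, nchar(base))),
            base)
  ca <- codon_alignment(alignment(paste0("s", 1:4), seqs))
  part <- tajima_D_partitioned(ca)
  expect_true(is.na(part$nonsyn$D))
  expect_false(is.na(part$syn$D))
  # identical sequences: both undefined
  id <- codon_alignment(alignment(c("a", "b"), rep(base, 2)))
  p0 <- tajima_D_partitioned(id)
  expect_true(is.na(p0$syn$D))
  expect_true(is.na(p0$nonsyn$D))
})

test_that("Fu & Li D* sign tracks singleton excess or deficit", {
  # all mutations singletons (n = 13): strong negative
  m <- matrix("A", 13, 40)
  for (k in 1:10) m[k, k] <- "T"
  a <- slocuspop:::aln_from_matrix(
    `rownames<-`(m, paste0("s", 1:13)), "nucleotide")
  fl <- fu_li(a)
  expect_equal(fl$eta_s, 10L)
  expect_lt(fl$D_star, 0)
  # polymorphism without singletons: positive
  m2 <- matrix("A", 13, 40)
  m2[1:6, 1:8] <- "T"
  b <- slocuspop:::aln_from_matrix(
    `rownames<-`(m2, paste0("s", 1:13)), "nucleotide")
  fl2 <- fu_li(b)
  expect_equal(fl2$eta_s, 0L)
  expect_gt(fl2$D_star, 0)
  # no variation: undefined
  expect_true(is.na(fu_li(alignment(paste0("s", 1:3),
                                    rep("ACGT", 3)))$D_star))
})

test_that("neutrality statistics are invariant to column order", {
  a <- sim_neutral_sample(8, 4, 100, seed = 77)
  m <- aln_matrix(a)
  perm <- sample(ncol(m))
  b <- slocuspop:::aln_from_matrix(m[, perm], "nucleotide")
  expect_equal(tajima_D(a)$D, tajima_D(b)$D, tolerance = 1e-12)
  expect_equal(fu_li(a)$D_star, fu_li(b)$D_star, tolerance = 1e-12)
})

test_that("MK table ratios and Fisher p are computed from the counts", {
  mk <- mk_table(5, 18, 34, 118)
  expect_equal(mk$ratio_fixed, 3.6)
  expect_equal(mk$ratio_poly, 118 / 34)
  expect_equal(mk$p_value,
               stats::fisher.test(matrix(c(5, 18, 34, 118), 2))$p.value)
  expect_true(is.na(mk_table(0, 3, 2, 5)$ratio_fixed))
  expect_error(mk_table(-1, 2, 3, 4), "non-negative")
})

test_that("Fisher exact agrees with hypergeometric enumeration", {
  set.seed(5)
  for (r in 1:40) {
    tab <- matrix(sample(0:12, 4, TRUE), 2)
    if (sum(tab) == 0) next
    got <- stats::fisher.test(tab)$p.value
    want <- oracle_fisher(tab[1, 1], tab[1, 2], tab[2, 1], tab[2, 2])
    expect_equal(got, want, tolerance = 1e-9)
  }
})

test_that("MK classification separates fixed from polymorphic mutations", {
  # codon 1: polymorphic within focal (syn GGA/GGG)
  # codon 2: fixed focal ACT vs outgroup AAT (nonsyn)
  # codon 3: polymorphic AND different from outgroup -> polymorphic only
  focal <- c("GGAACTTTA", "GGGACTTTG", "GGAACTTTA")
  outg <- alignment("anc", "GGAAATCTA", "nucleotide")
  ca <- codon_alignment(alignment(paste0("s", 1:3), focal))
  mk <- mk_test(ca, outg)
  expect_equal(mk$P_S, 2L)   # GGA/GGG and TTA/TTG both synonymous
  expect_equal(mk$P_A, 0L)
  expect_equal(mk$f_A, 1L)   # ACT -> AAT, Thr -> Asn
  expect_equal(mk$f_S, 0L)
  # focal identical to outgroup: all zero
  same <- codon_alignment(alignment(c("a", "b"),
                                    rep("GGAAATCTA", 2)))
  mk0 <- mk_test(same, outg)
  expect_equal(c(mk0$f_S, mk0$f_A, mk0$P_S, mk0$P_A), rep(0L, 4))
  expect_true(is.na(mk0$ratio_fixed))
  # permuting focal sequence order never changes the table
  ca2 <- codon_alignment(alignment(paste0("s", c(2, 3, 1)), focal[c(2, 3, 1)]))
  mk2 <- mk_test(ca2, outg)
  expect_equal(mk[c("f_S", "f_A", "P_S", "P_A")],
               mk2[c("f_S", "f_A", "P_S", "P_A")])
  expect_error(mk_test(ca, NULL), "outgroup")
})

test_that("MK counts never exceed the classified mutation total", {
  s <- sim_codon_sample(8, 12, 150, omega = 0.6, t_div = 0.08, seed = 31)
  mk <- mk_test(s$focal, s$outgroup)
  sp <- site_spectrum(s$focal$aln)
  expect_lte(mk$P_S + mk$P_A, sp$eta)
  # fixed differences live at focal-monomorphic codons, so they are
  # bounded by the Hamming distance of any focal sequence to the outgroup
  expect_lte(mk$f_S + mk$f_A,
             sum(aln_matrix(s$focal$aln)[1, ] != aln_matrix(s$outgroup)[1, ]))
})
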