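test_that("hap/legend round trip preserves the panel", {
  p <- toy_panel()
  prefix <- file.path(withr::local_tempdir(), "toy")
  write_hap_legend(p, prefix)
  q <- load_panel(paste0(prefix, ".hap"), "hap_legend",
                  legend = paste0(prefix, ".legend"))
  expect_identical(unname(q$alleles), unname(p$alleles))
  expect_identical(q$snp_ids, p$snp_ids)
  expect_identical(q$positions, p$positions)
  expect_equal(n_hap(q), 4L)
  expect_equal(n_snp(q), 2L)
  # prefix form
  q2 <- read_hap_legend(prefix)
  expect_identical(q2$alleles, q$alleles)
})

test_that("VCF loader agrees with hap/legend and applies filter rules", {
  set.seed(42)
  p <- random_panel(20L, 4L, seed = 42)          # 20 haplotypes = 10 samples
  dir <- withr::local_tempdir()
  write_hap_legend(p, file.path(dir, "panel"))
  vcf <- write_vcf_fixture(p, file.path(dir, "panel.vcf"))
  ph <- load_panel(file.path(dir, "panel"), "hap_legend")
  pv <- load_panel(vcf, "vcf")
  expect_identical(unname(pv$alleles), unname(ph$alleles))
  expect_identical(pv$snp_ids, ph$snp_ids)

  # tri-allelic record is excluded with a warning
  tri <- vcf_record("1", 9999L, "tri", "A", "G,T",
                    rep("0|0", 10L))
  vcf2 <- write_vcf_fixture(p, file.path(dir, "tri.vcf"), extra_lines = tri)
  expect_warning(p2 <- load_panel(vcf2, "vcf"), "multi-allelic")
  expect_false("tri" %in% p2$snp_ids)
  expect_equal(n_snp(p2), n_snp(pv))

  # unphased genotype is a format error naming the record
  unph <- vcf_record("1", 9998L, "badrec", "A", "G",
                     c("0/1", rep("0|0", 9L)))
  vcf3 <- write_vcf_fixture(p, file.path(dir, "unph.vcf"), extra_lines = unph)
  expect_error(load_panel(vcf3, "vcf"), "badrec")

  # unreadable file
  expect_error(load_panel(file.path(dir, "nope.vcf"), "vcf"), "cannot read")
})

test_that("monomorphic SNPs are dropped at load with a warning", {
  p <- toy_panel()
  p$alleles[, 2] <- 1L   # make s2 monomorphic
  dir <- withr::local_tempdir()
  write_hap_legend(p, file.path(dir, "m"))
  expect_warning(q <- load_panel(file.path(dir, "m"), "hap_legend"),
                 "monomorphic")
  expect_identical(q$snp_ids, "s1")
  # reaching genotype_correlation with a monomorphic SNP is an error
  expect_error(genotype_correlation(p), "s2")
})

test_that("haplotype frequency tables count and smooth correctly", {
  p <- toy_panel()
  ft <- haplotype_freq_table(p, c("s1", "s2"))
  key <- apply(ft$patterns, 1, paste, collapse = "")
  expect_equal(sort(key), c("00", "11"))
  expect_equal(unname(ft$freqs[order(key)]), c(0.5, 0.5))
  expect_equal(sum(ft$freqs), 1, tolerance = 1e-12)

  # single SNP, 3 alt of 10
  p1 <- haplotype_panel(matrix(rep(c(1L, 0L), c(3, 7)), ncol = 1), "x", 1L)
  f1 <- haplotype_freq_table(p1, "x")
  expect_equal(sum(f1$freqs * f1$patterns[, 1]), 0.3)

  # smoothing: all four haplotypes 00 with lambda = 0.5 over 2 SNPs ->
  # (count + lambda) / (H + lambda * 4): 4.5/6 for 00 and 0.5/6 each other
  p00 <- haplotype_panel(matrix(0L, 4, 2), c("s1", "s2"), c(100L, 200L))
  sm <- haplotype_freq_table(p00, c("s1", "s2"), lambda = 0.5)
  expect_equal(nrow(sm$patterns), 4L)
  expect_true(all(sm$freqs > 0))
  expect_equal(sum(sm$freqs), 1, tolerance = 1e-12)
  k <- apply(sm$patterns, 1, paste, collapse = "")
  expect_equal(unname(sm$freqs[k == "00"]), 4.5 / 6)
  expect_equal(unname(sm$freqs[k == "01"]), 0.5 / 6)

  expect_error(haplotype_freq_table(p, "nope"), "unknown SNP")
})

test_that("joint genotype probabilities follow Hardy-Weinberg random union", {
  # single SNP, f = 0.5
  p <- exact_maf_panel(0.5, H = 10L)
  jt <- joint_genotype_probs(haplotype_freq_table(p, "x"))
  expect_equal(jt$probs[match(0:2, jt$geno[, 1])], c(0.25, 0.5, 0.25))

  # perfect LD: {00: .5, 11: .5} -> concordant genotypes only
  jt2 <- joint_genotype_probs(haplotype_freq_table(toy_panel(), c("s1", "s2")))
  expect_equal(sum(jt2$probs), 1, tolerance = 1e-10)
  expect_true(all(jt2$geno[, 1] == jt2$geno[, 2]))
  expect_equal(jt2$probs[match(0:2, jt2$geno[, 1])], c(0.25, 0.5, 0.25))

  # any 3-SNP fixture matches brute-force ordered-pair enumeration
  p3 <- random_panel(30L, 3L, seed = 7)
  ft3 <- haplotype_freq_table(p3, p3$snp_ids)
  jt3 <- joint_genotype_probs(ft3)
  bf <- brute_joint(ft3)
  bkey <- apply(bf$geno, 1, paste, collapse = ",")
  jkey <- apply(jt3$geno, 1, paste, collapse = ",")
  expect_setequal(jkey, bkey)
  expect_equal(jt3$probs, bf$probs[match(jkey, bkey)], tolerance = 1e-12)

  # marginalizing reproduces the single-SNP genotype distribution
  m1 <- marginalize_joint(jt3, p3$snp_ids[2])
  solo <- joint_genotype_probs(haplotype_freq_table(p3, p3$snp_ids[2]))
  expect_equal(m1$probs[match(0:2, m1$geno[, 1])],
               solo$probs[match(0:2, solo$geno[, 1])], tolerance = 1e-12)
})

test_that("genotype correlation equals haplotype correlation and is PSD", {
  # duplicated SNP column -> off-diagonal exactly 1
  a <- random_panel(100L, 1L, seed = 3)$alleles
  p <- haplotype_panel(cbind(a, a), c("d1", "d2"), c(1L, 2L))
  sig <- genotype_correlation(p)
  expect_equal(sig["d1", "d2"], 1)

  # independent SNPs: near zero in a finite fixture
  pi <- random_panel(600L, 2L, seed = 11, mafs = c(0.3, 0.4))
  sigi <- genotype_correlation(pi)
  expect_lt(abs(sigi[1, 2]), 0.1)

  # repair leaves an already-PSD matrix essentially unchanged
  raw <- stats::cor(pi$alleles)
  expect_lt(norm(sigi - raw, "F") / norm(raw, "F"), 1e-6)
  expect_true(min(eigen(sigi, symmetric = TRUE,
                        only.values = TRUE)$values) >= -1e-8)
  expect_equal(unname(diag(sigi)), rep(1, 2))

  # random-union genotypes have the haplotype-level correlation
  ph <- random_panel(40L, 2L, seed = 5)
  hap_r <- stats::cor(ph$alleles)[1, 2]
  set.seed(99)
  i1 <- sample.int(40L, 1e5, replace = TRUE)
  i2 <- sample.int(40L, 1e5, replace = TRUE)
  g <- ph$alleles[i1, ] + ph$alleles[i2, ]
  expect_equal(stats::cor(g)[1, 2], hap_r, tolerance = 0.02)
})
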