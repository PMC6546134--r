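test_that("expected_u reproduces hand enumeration and vanishes under the null", {
  p <- exact_maf_panel(0.5)
  pw <- joint_genotype_probs(haplotype_freq_table(p, "x"))

  m0 <- causal_model("x", log_or = 0, n0 = 1000, n1 = 1000)
  e0 <- solve_enrichment(m0, pw)
  expect_equal(expected_u("x", m0, pw, e0), 0)

  # X = W, MAF 0.5, OR 1.2, 1000v1000:
  # (N-1) N0 N1 / N^2 = 499.75; sum_w (e^{gw}/1.21 - 1) E(G 1{w}) = 1/11
  m <- causal_model("x", or = 1.2, n0 = 1000, n1 = 1000)
  e <- solve_enrichment(m, pw)
  expect_equal(expected_u("x", m, pw, e), 499.75 / 11, tolerance = 1e-12)
})

test_that("expected_u matches the forward-simulation mean of U_X", {
  p <- random_panel(80L, 2L, seed = 31, mafs = c(0.35, 0.2))
  model <- causal_model(p$snp_ids[1], or = 1.4, n0 = 150, n1 = 150)
  pw <- joint_genotype_probs(haplotype_freq_table(p, p$snp_ids[1]))
  enr <- solve_enrichment(model, pw)
  eu <- vapply(p$snp_ids, function(s) {
    j <- if (s == p$snp_ids[1]) pw else
      joint_genotype_probs(haplotype_freq_table(p, c(s, p$snp_ids[1])))
    expected_u(s, model, j, enr)
  }, 0)
  set.seed(77)
  us <- replicate(2500, study_u(sample_study(p, model)))
  for (k in 1:2) {
    se <- stats::sd(us[k, ]) / sqrt(ncol(us))
    expect_lt(abs(mean(us[k, ]) - eu[k]), 3 * se)
  }
})

test_that("variance_moments is exact", {
  # N = 2 example: E(V) = 0.5, E(V^2) = 0.625 for HWE f = 0.5
  d <- list(p0 = c(0.25, 0.5, 0.25), p1 = c(0.25, 0.5, 0.25))
  vm <- variance_moments(d, 1, 1)
  expect_equal(unname(vm), c(0.5, 0.625), tolerance = 1e-12)

  # degenerate distribution: all mass on g = 1
  dd <- list(p0 = c(0, 1, 0), p1 = c(0, 1, 0))
  expect_equal(unname(variance_moments(dd, 3, 3)), c(0, 0))

  # exhaustive enumeration for N <= 6, random case/control distributions
  set.seed(8)
  for (rep in 1:6) {
    p0 <- as.vector(stats::rgamma(3, 1)); p0 <- p0 / sum(p0)
    p1 <- as.vector(stats::rgamma(3, 1)); p1 <- p1 / sum(p1)
    n0 <- sample(1:3, 1); n1 <- sample(1:3, 1)
    if (n0 + n1 < 2) n1 <- n1 + 1L
    got <- variance_moments(list(p0 = p0, p1 = p1), n0, n1)
    want <- enum_variance_moments(p0, p1, n0, n1)
    expect_equal(unname(got), unname(want), tolerance = 1e-12)
  }

  # large N: E(V) approaches the population variance of p0 when p1 = p0
  p0 <- c(0.49, 0.42, 0.09)
  popv <- sum((0:2)^2 * p0) - sum(0:2 * p0)^2
  vmN <- variance_moments(list(p0 = p0, p1 = p0), 5000, 5000)
  expect_equal(vmN[["ev"]], popv, tolerance = 1e-3)

  expect_error(variance_moments(d, 1, 0), ">= 2")
})

test_that("variance_moments matches Monte-Carlo at moderate N", {
  p0 <- c(0.4, 0.45, 0.15); p1 <- c(0.3, 0.5, 0.2)
  n0 <- 40L; n1 <- 25L
  got <- variance_moments(list(p0 = p0, p1 = p1), n0, n1)
  set.seed(12)
  vs <- replicate(20000, {
    g <- c(sample(0:2, n0, TRUE, p0), sample(0:2, n1, TRUE, p1))
    stats::var(g)
  })
  expect_lt(abs(mean(vs) - got[["ev"]]), 3 * stats::sd(vs) / sqrt(2e4))
  expect_lt(abs(mean(vs^2) - got[["ev2"]]), 3 * stats::sd(vs^2) / sqrt(2e4))
})

test_that("inverse-gamma fit round-trips its moments", {
  expect_equal(unname(fit_inverse_gamma(2, 8)), c(3, 4))
  expect_equal(unname(fit_inverse_gamma(0.5, 0.625)), c(8 / 3, 5 / 6))
  set.seed(3)
  for (rep in 1:8) {
    ev <- stats::runif(1, 0.1, 2)
    ev2 <- ev^2 * stats::runif(1, 1.001, 3)
    ab <- fit_inverse_gamma(ev, ev2)
    a <- ab[["alpha"]]; b <- ab[["beta"]]
    expect_equal(b / (a - 1), ev, tolerance = 1e-12)          # mean
    expect_equal(b^2 / ((a - 1) * (a - 2)), ev2, tolerance = 1e-9)
  }
  expect_error(fit_inverse_gamma(1, 1), "degenerate")
  expect_error(fit_inverse_gamma(0, 1), "positive")
})

test_that("expected_inv_sqrt_v matches gamma-function and Monte-Carlo oracles", {
  expect_equal(expected_inv_sqrt_v(1.5, 1), 1 / gamma(1.5), tolerance = 1e-12)
  # beta scale property: value at (a, 4b) is half the value at (a, b)
  expect_equal(expected_inv_sqrt_v(2.3, 4 * 1.7),
               expected_inv_sqrt_v(2.3, 1.7) / 2, tolerance = 1e-12)
  # Monte-Carlo: mean of V^{-1/2} over inverse-gamma draws
  set.seed(21)
  a <- 3.2; b <- 1.4
  v <- 1 / stats::rgamma(1e6, shape = a, rate = b)
  x <- v^-0.5
  expect_lt(abs(mean(x) - expected_inv_sqrt_v(a, b)),
            3 * stats::sd(x) / sqrt(1e6))
})

test_that("expected_z_region: null, single-causal value, antisymmetry", {
  p <- random_panel(100L, 5L, seed = 14)
  mn <- causal_model(p$snp_ids[2], log_or = 0, n0 = 1500, n1 = 1500)
  es0 <- expected_z_region(mn, p)
  expect_equal(es0$ze, rep(0, 5))
  expect_equal(es0$eu, rep(0, 5))
  expect_equal(attr(es0, "vy"), 1500^2 / (3000 * 2999))

  # single causal SNP, MAF 0.5, OR 1.2, 1000v1000 -> ze ~ 2.87
  px <- exact_maf_panel(0.5)
  mx <- causal_model("x", or = 1.2, n0 = 1000, n1 = 1000)
  esx <- expected_z_region(mx, px)
  expect_equal(esx$ze, 2.8739, tolerance = 1e-4)

  # negating all gamma negates ze: exact under an allele-flip symmetric
  # haplotype distribution (flip symmetry maps the +gamma model onto the
  # -gamma model); approximate otherwise
  base <- random_panel(60L, 6L, seed = 17)$alleles
  psym <- haplotype_panel(rbind(base, 1L - base),
                          sprintf("y%d", 1:6), 1:6 * 10L)
  g3 <- c(0.2, -0.1, 0.15)
  mp <- causal_model(psym$snp_ids[1:3], log_or = g3, n0 = 900, n1 = 1100)
  mm <- causal_model(psym$snp_ids[1:3], log_or = -g3, n0 = 900, n1 = 1100)
  expect_equal(expected_z_region(mp, psym)$ze,
               -expected_z_region(mm, psym)$ze, tolerance = 1e-9)
  # general panels: antisymmetric to first order only
  p3 <- random_panel(120L, 6L, seed = 17)
  mp2 <- causal_model(p3$snp_ids[1:3], log_or = g3, n0 = 900, n1 = 1100)
  mm2 <- causal_model(p3$snp_ids[1:3], log_or = -g3, n0 = 900, n1 = 1100)
  zp <- expected_z_region(mp2, p3)$ze; zm <- expected_z_region(mm2, p3)$ze
  expect_equal(zp, -zm, tolerance = 0.1)
})

test_that("ze scales as sqrt(N) under fixed MAF and case fraction", {
  p <- exact_maf_panel(0.3, H = 400L)
  zs <- vapply(c(2000, 8000, 32000), function(n) {
    m <- causal_model("x", or = 1.15, n0 = n / 2, n1 = n / 2)
    expected_z_region(m, p)$ze[1]
  }, 0)
  expect_equal(zs[2] / zs[1], 2, tolerance = 0.02)
  expect_equal(zs[3] / zs[2], 2, tolerance = 0.02)
})

test_that("strong-LD opposing effects attenuate ze (scenario 5 < scenario 4)", {
  s4 <- suppressWarnings(scenario_panel(4, seed = 2, n_snp = 30))
  s5 <- suppressWarnings(scenario_panel(5, seed = 2, n_snp = 30))
  z4 <- expected_z_region(s4$model, s4$panel)
  z5 <- expected_z_region(s5$model, s5$panel)
  m4 <- max(abs(z4$ze[match(s4$causal_ids, z4$snp)]))
  m5 <- max(abs(z5$ze[match(s5$causal_ids, z5$snp)]))
  expect_lt(m5, m4)
})
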