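# Fixtures and independent oracles used across the suite.

# 4-haplotype, 2-SNP panel with haplotypes {00, 00, 11, 11}
toy_panel <- function() {
  haplotype_panel(matrix(c(0L, 0L, 1L, 1L, 0L, 0L, 1L, 1L), ncol = 2),
                  c("s1", "s2"), c(100L, 200L))
}

# panel with a single SNP at exact allele frequency f (H haplotypes)
exact_maf_panel <- function(f = 0.5, H = 600L, id = "x") {
  k <- round(f * H)
  haplotype_panel(matrix(rep(c(1L, 0L), c(k, H - k)), ncol = 1), id, 100L)
}

# two exactly independent SNPs: haplotype counts proportional to product freqs
product_panel <- function(fa = 0.4, fb = 0.3, H = 100L) {
  na <- round(fa * H); nb <- round(fb * H)
  a <- rep(c(1L, 0L), c(na, H - na))
  b <- c(rep(c(1L, 0L), c(round(fb * na), na - round(fb * na))),
         rep(c(1L, 0L), c(nb - round(fb * na), H - na - nb + round(fb * na))))
  haplotype_panel(cbind(a, b), c("a", "b"), c(100L, 200L))
}

# iid random panel (independent SNPs up to sampling noise)
random_panel <- function(H, n, seed, mafs = NULL) {
  set.seed(seed)
  if (is.null(mafs)) mafs <- stats::runif(n, 0.1, 0.5)
  a <- sapply(seq_len(n), function(j) rbinom(H, 1L, mafs[j]))
  # re-draw any monomorphic column
  for (j in seq_len(n)) while (length(unique(a[, j])) == 1L)
    a[, j] <- rbinom(H, 1L, mafs[j])
  haplotype_panel(a, sprintf("r%03d", seq_len(n)), seq_len(n) * 10L)
}

# ORACLE: joint genotype table by explicit enumeration of ordered pairs
brute_joint <- function(freqs) {
  p <- freqs$patterns; f <- freqs$freqs
  env <- new.env()
  for (i in seq_len(nrow(p))) for (j in seq_len(nrow(p))) {
    g <- p[i, ] + p[j, ]
    key <- paste(g, collapse = ",")
    env[[key]] <- (env[[key]] %||0% 0) + f[i] * f[j]
  }
  keys <- ls(env)
  geno <- do.call(rbind, lapply(strsplit(keys, ","), as.integer))
  list(geno = geno, probs = unname(vapply(keys, function(k) env[[k]], 0)),
       subset = freqs$subset)
}
`%||0%` <- function(a, b) if (is.null(a)) b else a

# ORACLE: exact E(V), E(V^2) by exhaustive enumeration over 3^N genotype
# assignments (first n0 individuals ~ p0, rest ~ p1); feasible for N <= 6
enum_variance_moments <- function(p0, p1, n0, n1) {
  N <- n0 + n1
  grid <- as.matrix(expand.grid(rep(list(0:2), N)))
  pr <- apply(grid, 1L, function(g)
    prod(p0[g[seq_len(n0)] + 1L]) * prod(p1[g[n0 + seq_len(n1)] + 1L]))
  v <- apply(grid, 1L, stats::var)
  c(ev = sum(pr * v), ev2 = sum(pr * v^2))
}

# ORACLE: bivariate normal upper-orthant probability by 2-D Simpson rule
# (independent of the package's 1-D quadrature route)
simpson_orthant <- function(ta, tb, rho, lim = 8, nstep = 400L) {
  xs <- seq(ta, lim, length.out = nstep + 1L)
  ys <- seq(tb, lim, length.out = nstep + 1L)
  wx <- c(1, rep(c(4, 2), length.out = nstep - 1L), 1)
  dens <- function(x, y) {
    q <- (x^2 - 2 * rho * x * y + y^2) / (1 - rho^2)
    exp(-q / 2) / (2 * pi * sqrt(1 - rho^2))
  }
  m <- outer(xs, ys, dens)
  hx <- (lim - ta) / nstep; hy <- (lim - tb) / nstep
  as.numeric(wx %*% m %*% wx) * hx * hy / 9
}

# ORACLE: logistic slope by direct likelihood maximization (Nelder-Mead),
# independent of the package's Newton route
brute_logistic_beta <- function(n0g, n1g, g = 0:2) {
  nll <- function(b) {
    eta <- b[1] + b[2] * g
    -sum(n1g * eta - (n0g + n1g) * log1p(exp(eta)))
  }
  stats::optim(c(0, 0), nll, control = list(reltol = 1e-14,
                                            maxit = 5000))$par[2]
}

# score numerator U_X for each SNP of a study
study_u <- function(study) {
  g <- study$genotypes; y <- study$phenotypes
  as.vector(crossprod(
    g - matrix(colMeans(g), length(y), ncol(g), byrow = TRUE), y - mean(y)))
}

# write a minimal phased VCF for a haplotype panel (fixture writer;
# the package only reads VCF)
write_vcf_fixture <- function(panel, path, extra_lines = character()) {
  H <- nrow(panel$alleles)
  stopifnot(H %% 2 == 0)
  ns <- H / 2
  samples <- sprintf("S%02d", seq_len(ns))
  hdr <- c("##fileformat=VCFv4.2",
           "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
           paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                   "INFO", "FORMAT", samples), collapse = "\t"))
  rows <- vapply(seq_len(ncol(panel$alleles)), function(j) {
    gts <- vapply(seq_len(ns), function(s)
      paste0(panel$alleles[2 * s - 1, j], "|", panel$alleles[2 * s, j]), "")
    paste(c(panel$chr[j], panel$positions[j], panel$snp_ids[j],
            panel$a0[j], panel$a1[j], ".", "PASS", ".", "GT", gts),
          collapse = "\t")
  }, "")
  writeLines(c(hdr, rows, extra_lines), path)
  path
}

# extra VCF record lines (tri-allelic / unphased) for filter tests
vcf_record <- function(chr, pos, id, ref, alt, gts) {
  paste(c(chr, pos, id, ref, alt, ".", "PASS", ".", "GT", gts),
        collapse = "\t")
}
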