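#' Construct a haplotype panel
#'
#' A haplotype panel holds a phased binary allele matrix (haplotypes in rows,
#' SNPs in columns; entries count copies of the alternate/`a1` allele) together
#' with SNP metadata.  All frequency, LD and genotype-probability calculations
#' in the package are driven by this object.
#'
#' @param alleles integer/numeric matrix, `H` haplotypes x `n` SNPs, entries
#'   in `{0, 1}`, no missing values.
#' @param snp_ids character vector of unique SNP identifiers (length `n`).
#' @param positions integer base-pair positions (1-based, nondecreasing).
#' @param a0,a1 reference and alternate allele labels per SNP; the allele
#'   matrix counts copies of `a1`.
#' @param chr chromosome label(s), recycled to length `n`.
#' @return An object of class `haplotype_panel`.
#' @export
haplotype_panel <- function(alleles, snp_ids, positions,
                            a0 = rep("A", ncol(alleles)),
                            a1 = rep("G", ncol(alleles)),
                            chr = "1") {
  alleles <- as.matrix(alleles)
  storage.mode(alleles) <- "integer"
  panel <- structure(
    list(alleles = alleles,
         snp_ids = as.character(snp_ids),
         positions = as.integer(positions),
         a0 = as.character(a0), a1 = as.character(a1),
         chr = rep_len(as.character(chr), ncol(alleles))),
    class = "haplotype_panel")
  colnames(panel$alleles) <- panel$snp_ids
  validate_panel(panel)
  panel
}

#' Validate haplotype panel invariants
#'
#' Checks the structural invariants: binary complete allele matrix, at least
#' two haplotypes, unique SNP ids, nondecreasing positions, metadata lengths.
#'
#' @param panel a [haplotype_panel()].
#' @return `panel`, invisibly; errors if an invariant fails.
#' @export
validate_panel <- function(panel) {
  a <- panel$alleles
  if (anyNA(a) || !all(a == 0L | a == 1L))
    stop("panel allele matrix must be binary with no missing values")
  if (nrow(a) < 2L) stop("panel must contain at least 2 haplotypes")
  n <- ncol(a)
  if (anyDuplicated(panel$snp_ids)) stop("snp_ids must be unique")
  if (length(panel$snp_ids) != n || length(panel$positions) != n ||
      length(panel$a0) != n || length(panel$a1) != n)
    stop("metadata length does not match number of SNPs")
  if (n > 1L && any(diff(panel$positions) < 0L))
    stop("positions must be nondecreasing")
  invisible(panel)
}

#' @export
print.haplotype_panel <- function(x, ...) {
  cat(sprintf("haplotype_panel: %d haplotypes x %d SNPs (chr %s, %s..%s bp)\n",
              nrow(x$alleles), ncol(x$alleles), x$chr[1],
              format(min(x$positions)), format(max(x$positions))))
  invisible(x)
}

#' Number of haplotypes / SNPs in a panel
#' @param panel a [haplotype_panel()].
#' @return integer count.
#' @export
n_hap <- function(panel) nrow(panel$alleles)

#' @rdname n_hap
#' @export
n_snp <- function(panel) ncol(panel$alleles)

#' Subset a panel by SNP
#' @param x a [haplotype_panel()].
#' @param snps SNP identifiers or column indices to keep.
#' @param ... ignored.
#' @return a [haplotype_panel()] restricted to `snps`.
#' @export
subset_panel <- function(x, snps, ...) {
  idx <- if (is.character(snps)) match(snps, x$snp_ids) else as.integer(snps)
  if (anyNA(idx)) stop("unknown SNP id: ",
                       paste(snps[is.na(idx)], collapse = ", "))
  haplotype_panel(x$alleles[, idx, drop = FALSE], x$snp_ids[idx],
                  x$positions[idx], x$a0[idx], x$a1[idx], x$chr[idx])
}

drop_monomorphic <- function(panel, warn = TRUE) {
  f <- colMeans(panel$alleles)
  mono <- f == 0 | f == 1
  if (any(mono)) {
    if (warn)
      warning("dropping ", sum(mono), " monomorphic SNP(s): ",
              paste(utils::head(panel$snp_ids[mono], 5L), collapse = ", "),
              if (sum(mono) > 5L) ", ..." else "", call. = FALSE)
    keep <- which(!mono)
    panel <- haplotype_panel(panel$alleles[, keep, drop = FALSE],
                             panel$snp_ids[keep], panel$positions[keep],
                             panel$a0[keep], panel$a1[keep], panel$chr[keep])
  }
  panel
}

#' Load a phased reference panel
#'
#' Reads phased haplotypes from an IMPUTE2-style `.hap`/`.legend` pair or a
#' phased VCF.  Records that are multi-allelic or contain missing alleles are
#' dropped with a warning; monomorphic SNPs are dropped at load time (their
#' trend-test variance is zero, so no Z score is defined for them).
#'
#' @param path for `hap_legend`, the `.hap` file (or a prefix if `legend` is
#'   `NULL`, in which case `<prefix>.hap`/`<prefix>.legend` are used); for
#'   `vcf`, the VCF path.
#' @param format `"hap_legend"` or `"vcf"`.
#' @param legend `.legend` path (only for `hap_legend`).
#' @param chr chromosome label for `.hap/.legend` input (the legend carries
#'   none); ignored for VCF.
#' @param keep_monomorphic keep monomorphic SNPs instead of dropping them.
#' @return a [haplotype_panel()].
#' @export
load_panel <- function(path, format = c("hap_legend", "vcf"), legend = NULL,
                       chr = "1", keep_monomorphic = FALSE) {
  format <- match.arg(format)
  panel <- switch(format,
    hap_legend = read_hap_legend(path, legend, chr = chr),
    vcf = read_panel_vcf(path))
  if (!keep_monomorphic) panel <- drop_monomorphic(panel)
  panel
}

#' Read an IMPUTE2 .hap/.legend pair
#'
#' The `.hap` file is a space-separated 0/1 matrix with one row per SNP and
#' one column per haplotype; `.legend` has a header line `id position a0 a1`.
#' Allele coding counts the `a1` allele.
#'
#' @inheritParams load_panel
#' @param hap path to the `.hap` file, or a prefix when `legend` is `NULL`.
#' @return a [haplotype_panel()].
#' @export
read_hap_legend <- function(hap, legend = NULL, chr = "1") {
  if (is.null(legend)) {
    legend <- paste0(hap, ".legend")
    hap <- paste0(hap, ".hap")
  }
  if (!file.exists(hap)) stop("cannot read .hap file: ", hap)
  if (!file.exists(legend)) stop("cannot read .legend file: ", legend)
  leg <- data.table::fread(legend, header = TRUE, data.table = FALSE)
  need <- c("id", "position", "a0", "a1")
  if (!all(need %in% names(leg)))
    stop(".legend must have header columns: ", paste(need, collapse = " "))
  hp <- data.table::fread(hap, header = FALSE, data.table = FALSE,
                          colClasses = "integer")
  if (nrow(hp) != nrow(leg))
    stop(".hap rows (", nrow(hp), ") do not match .legend rows (",
         nrow(leg), ")")
  m <- t(as.matrix(hp))                       # haplotypes x SNPs
  bad <- apply(m, 2L, function(x) anyNA(x) || any(x != 0L & x != 1L))
  multi <- grepl(",", leg$a1, fixed = TRUE)
  drop <- bad | multi
  if (any(drop))
    warning("dropping ", sum(drop),
            " SNP(s) with missing or multi-allelic records: ",
            paste(utils::head(leg$id[drop], 5L), collapse = ", "),
            call. = FALSE)
  keep <- which(!drop)
  haplotype_panel(m[, keep, drop = FALSE], leg$id[keep], leg$position[keep],
                  leg$a0[keep], leg$a1[keep], chr)
}

#' Read a phased VCF into a haplotype panel
#'
#' Requires every genotype to be phased (`|` separator); an unphased genotype
#' is a format error naming the offending record.  Multi-allelic records and
#' records with missing genotypes are dropped with a warning.
#'
#' @param path path to an (uncompressed or bgzipped) VCF file.
#' @return a [haplotype_panel()].
#' @export
read_panel_vcf <- function(path) {
  if (!file.exists(path)) stop("cannot read VCF: ", path)
  vcf <- VariantAnnotation::readVcf(path)
  gt <- VariantAnnotation::geno(vcf)$GT
  if (is.null(gt)) stop("VCF has no GT field")
  rr <- SummarizedExperiment::rowRanges(vcf)
  ids <- rownames(gt)
  unphased <- matrix(grepl("/", gt, fixed = TRUE), nrow = nrow(gt))
  if (any(unphased)) {
    bad <- which(unphased, arr.ind = TRUE)[1L, ]
    stop("unphased genotype in VCF at record '", ids[bad[1L]],
         "' (sample ", colnames(gt)[bad[2L]], "): all genotypes must be phased")
  }
  nalt <- S4Vectors::elementNROWS(VariantAnnotation::alt(vcf))
  missing_gt <- apply(gt, 1L, function(x) any(grepl(".", x, fixed = TRUE)))
  drop <- nalt != 1L | missing_gt
  if (any(drop))
    warning("dropping ", sum(drop),
            " multi-allelic or incomplete VCF record(s): ",
            paste(utils::head(ids[drop], 5L), collapse = ", "), call. = FALSE)
  keep <- which(!drop)
  if (!length(keep)) stop("no usable biallelic phased records in VCF")
  gt <- gt[keep, , drop = FALSE]
  # one column pair per sample -> H = 2 * n_sample haplotype rows
  split_gt <- strsplit(as.vector(t(gt)), "|", fixed = TRUE)
  if (!all(lengths(split_gt) == 2L))
    stop("VCF genotypes must be diploid 'a|b'")
  al <- matrix(as.integer(unlist(split_gt)), ncol = 2L, byrow = TRUE)
  ns <- ncol(gt); nv <- nrow(gt)
  # rows of `al` enumerate (snp-major over transposed gt): sample varies fastest
  h <- matrix(0L, nrow = 2L * ns, ncol = nv)
  for (s in seq_len(ns)) {
    rows <- (seq_len(nv) - 1L) * ns + s
    h[2L * s - 1L, ] <- al[rows, 1L]
    h[2L * s, ] <- al[rows, 2L]
  }
  haplotype_panel(h, ids[keep],
                  BiocGenerics::start(rr)[keep],
                  as.character(VariantAnnotation::ref(vcf))[keep],
                  as.character(unlist(VariantAnnotation::alt(vcf)[keep])),
                  as.character(GenomeInfoDb::seqnames(rr))[keep])
}

#' Write a panel as an IMPUTE2 .hap/.legend pair
#'
#' @param panel a [haplotype_panel()].
#' @param prefix output prefix; writes `<prefix>.hap` and `<prefix>.legend`.
#' @return the two paths, invisibly.
#' @export
write_hap_legend <- function(panel, prefix) {
  hap <- paste0(prefix, ".hap"); legend <- paste0(prefix, ".legend")
  data.table::fwrite(data.table::as.data.table(t(panel$alleles)), hap,
                     sep = " ", col.names = FALSE)
  data.table::fwrite(data.table::data.table(
    id = panel$snp_ids, position = panel$positions,
    a0 = panel$a0, a1 = panel$a1), legend, sep = " ")
  invisible(c(hap = hap, legend = legend))
}

#' Haplotype frequency table over a SNP subset
#'
#' Tabulates the distinct haplotype patterns over `subset` and their relative
#' frequencies in the panel, with optional Laplace smoothing over all
#' `2^k` patterns: `(count + lambda) / (H + lambda * 2^k)`.
#'
#' @param panel a [haplotype_panel()].
#' @param subset SNP identifiers (order is preserved in the patterns).
#' @param lambda nonnegative pseudo-count; `0` (default) is plain counting.
#' @return a `hap_freq_table`: list with `subset`, `patterns` (matrix, one row
#'   per distinct pattern) and `freqs` summing to 1.
#' @export
haplotype_freq_table <- function(panel, subset, lambda = 0) {
  idx <- match(subset, panel$snp_ids)
  if (!length(idx)) stop("subset must be nonempty")
  if (anyNA(idx)) stop("unknown SNP id: ",
                       paste(subset[is.na(idx)], collapse = ", "))
  k <- length(idx)
  a <- panel$alleles[, idx, drop = FALSE]
  key <- a %*% 2L^(seq_len(k) - 1L)
  if (lambda > 0) {
    if (k > 16L) stop("smoothing requires subset of at most 16 SNPs")
    npat <- 2L^k
    counts <- tabulate(key + 1L, nbins = npat)
    patterns <- as.matrix(expand.grid(rep(list(0:1), k)))[, seq_len(k),
                                                          drop = FALSE]
    dimnames(patterns) <- list(NULL, subset)
    freqs <- (counts + lambda) / (nrow(a) + lambda * npat)
  } else {
    tab <- table(key)
    kept <- as.numeric(names(tab))
    patterns <- t(vapply(kept, function(v) (v %/% 2L^(seq_len(k) - 1L)) %% 2L,
                         numeric(k)))
    patterns <- matrix(as.integer(patterns), ncol = k,
                       dimnames = list(NULL, subset))
    freqs <- as.numeric(tab) / nrow(a)
  }
  structure(list(subset = subset, patterns = patterns, freqs = freqs),
            class = "hap_freq_table")
}

#' Joint genotype probabilities under Hardy-Weinberg random union
#'
#' Turns haplotype-pattern frequencies into a joint genotype table by summing
#' over ordered haplotype pairs `(h1, h2)` with `h1 + h2 = g` (random union of
#' two independently drawn haplotypes).
#'
#' @param freqs a [haplotype_freq_table()].
#' @return a `joint_geno_table`: list with `subset`, `geno` (matrix of
#'   genotype vectors in `{0,1,2}^k`, one row each) and `probs` summing to 1.
#' @export
joint_genotype_probs <- function(freqs) {
  stopifnot(inherits(freqs, "hap_freq_table"))
  p <- freqs$patterns; f <- freqs$freqs
  np <- nrow(p); k <- ncol(p)
  i <- rep(seq_len(np), each = np); j <- rep(seq_len(np), times = np)
  g <- p[i, , drop = FALSE] + p[j, , drop = FALSE]
  pr <- f[i] * f[j]
  key <- as.vector(g %*% 3^(seq_len(k) - 1L))
  agg <- rowsum(pr, group = key)
  kv <- as.numeric(rownames(agg))
  geno <- t(vapply(kv, function(v) (v %/% 3^(seq_len(k) - 1L)) %% 3,
                   numeric(k)))
  geno <- matrix(as.integer(round(geno)), ncol = k,
                 dimnames = list(NULL, freqs$subset))
  structure(list(subset = freqs$subset, geno = geno,
                 probs = as.numeric(agg)),
            class = "joint_geno_table")
}

#' Marginalize a joint genotype table
#'
#' @param joint a [joint_genotype_probs()] table.
#' @param snps SNP identifiers to retain (must be a subset of
#'   `joint$subset`).
#' @return a `joint_geno_table` over `snps`.
#' @export
marginalize_joint <- function(joint, snps) {
  idx <- match(snps, joint$subset)
  if (anyNA(idx)) stop("SNP not in joint table: ",
                       paste(snps[is.na(idx)], collapse = ", "))
  g <- joint$geno[, idx, drop = FALSE]
  k <- ncol(g)
  key <- as.vector(g %*% 3^(seq_len(k) - 1L))
  agg <- rowsum(joint$probs, group = key)
  kv <- as.numeric(rownames(agg))
  geno <- t(vapply(kv, function(v) (v %/% 3^(seq_len(k) - 1L)) %% 3,
                   numeric(k)))
  geno <- matrix(as.integer(round(geno)), ncol = k, dimnames = list(NULL, snps))
  structure(list(subset = snps, geno = geno, probs = as.numeric(agg)),
            class = "joint_geno_table")
}

#' Genotype correlation matrix of a panel
#'
#' Pearson correlation of the haplotype allele indicators, which under random
#' union of gametes equals the correlation between genotypes; this is the LD
#' matrix `Sigma` used for multivariate normal Z-score simulation.  Finite
#' panels can yield numerically indefinite matrices, so eigenvalues are
#' clipped at `clip` and the result rescaled back to unit diagonal.
#'
#' @param panel a [haplotype_panel()]; every SNP must be polymorphic.
#' @param clip eigenvalue floor for the positive semi-definite repair.
#' @return an `n x n` correlation matrix with SNP ids as dimnames.
#' @export
genotype_correlation <- function(panel, clip = 1e-8) {
  f <- colMeans(panel$alleles)
  mono <- f == 0 | f == 1
  if (any(mono))
    stop("monomorphic SNP(s) in panel (undefined correlation): ",
         paste(panel$snp_ids[mono], collapse = ", "))
  sigma <- stats::cor(panel$alleles)
  e <- eigen(sigma, symmetric = TRUE)
  if (min(e$values) < clip) {
    v <- pmax(e$values, clip)
    sigma <- e$vectors %*% (v * t(e$vectors))
    sigma <- stats::cov2cor(sigma)
  }
  sigma <- (sigma + t(sigma)) / 2
  sigma[sigma > 1] <- 1; sigma[sigma < -1] <- -1
  diag(sigma) <- 1
  dimnames(sigma) <- list(panel$snp_ids, panel$snp_ids)
  sigma
}
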