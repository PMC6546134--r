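#' Simulate replicate Z-score vectors
#'
#' Draws `n_rep` independent replicates `Z* ~ MVN(Z_E, Sigma)`, where `Sigma`
#' is the regional genotype (LD) correlation matrix, via a single Cholesky
#' factorization.  Simulated Z scores vary about their expected values with
#' unit variance and the between-SNP correlation of the genotypes.
#'
#' @param ze expected Z-score vector (length `n`).
#' @param sigma `n x n` positive semi-definite correlation matrix
#'   (PSD repair belongs upstream in [genotype_correlation()]).
#' @param n_rep number of replicates.
#' @param seed integer seed.
#' @return `n_rep x n` matrix of Z scores (columns named by SNP if `sigma`
#'   has dimnames).
#' @export
simulate_z <- function(ze, sigma, n_rep, seed) {
  n <- length(ze)
  stopifnot(nrow(sigma) == n, ncol(sigma) == n, n_rep >= 1)
  ev_min <- min(eigen(sigma, symmetric = TRUE, only.values = TRUE)$values)
  if (ev_min < -1e-8)
    stop("sigma is not positive semi-definite (min eigenvalue ", ev_min,
         "); apply PSD repair upstream")
  # pivoted Cholesky handles rank deficiency (perfectly correlated SNPs)
  R <- suppressWarnings(chol(sigma, pivot = TRUE))
  rank <- attr(R, "rank")
  if (rank < n) R[(rank + 1L):n, ] <- 0
  L <- R[, order(attr(R, "pivot")), drop = FALSE]
  set.seed(seed)
  z <- matrix(stats::rnorm(n_rep * n), nrow = n_rep) %*% L
  z <- sweep(z, 2L, ze, "+")
  colnames(z) <- colnames(sigma)
  z
}

#' Simulate replicate standard errors
#'
#' Draws the per-SNP genotype variance `V_X* ~ InverseGamma(alpha, beta)`
#' independently per SNP and replicate, and converts it to a Wald-type
#' standard error through the score-information identity
#' `sigma* = 1 / sqrt((N-1) V_X* V_Y) = 1 / sqrt(V_X* N0 N1 / N)`.
#' SNPs flagged degenerate use the constant `V_X = ev`.
#'
#' @param summary an [expected_z_region()] result (provides `alpha`, `beta`,
#'   `ev`, the degenerate flags and `n0`, `n1`).
#' @param n_rep number of replicates.
#' @param seed integer seed.
#' @return `n_rep x n` matrix of positive standard errors.
#' @export
simulate_se <- function(summary, n_rep, seed) {
  stopifnot(inherits(summary, "expected_summary"), n_rep >= 1)
  n0 <- as.numeric(attr(summary, "n0"))
  n1 <- as.numeric(attr(summary, "n1"))
  n <- n0 + n1
  k <- n0 * n1 / n                      # (N-1) * V_Y
  ns <- nrow(summary)
  set.seed(seed)
  se <- matrix(NA_real_, nrow = n_rep, ncol = ns,
               dimnames = list(NULL, summary$snp))
  for (s in seq_len(ns)) {
    v <- if (summary$degenerate[s]) {
      rep(summary$ev[s], n_rep)
    } else {
      1 / stats::rgamma(n_rep, shape = summary$alpha[s],
                        rate = summary$beta[s])
    }
    se[, s] <- 1 / sqrt(v * k)
  }
  se
}

#' Assemble a simulated summary-statistics object
#'
#' Back-calculates log odds ratios as `gamma* = sigma* Z*` (Wald/score
#' asymptotic equivalence) and two-sided normal p-values `p = 2 Phi(-|Z*|)`.
#'
#' @param z replicate x SNP Z-score matrix from [simulate_z()].
#' @param se replicate x SNP standard-error matrix from [simulate_se()]
#'   (same shape).
#' @param snp_info optional data frame with per-SNP metadata (columns `snp`,
#'   `chr`, `pos`, `a0`, `a1`), e.g. an [expected_z_region()] result.
#' @param seed the master seed used (recorded in the object).
#' @return a `simulated_summary`: list with matrices `z`, `se`, `beta`, `p`,
#'   plus `snp_ids`, `n_rep`, `seed` and `snp_info`.
#' @export
assemble <- function(z, se, snp_info = NULL, seed = NA_integer_) {
  if (!all(dim(z) == dim(se)))
    stop("z and se must have identical dimensions")
  if (any(se <= 0)) stop("standard errors must be positive")
  structure(list(snp_ids = colnames(z), z = z, se = se,
                 beta = se * z, p = 2 * stats::pnorm(-abs(z)),
                 n_rep = nrow(z), seed = seed, snp_info = snp_info),
            class = "simulated_summary")
}

#' @export
print.simulated_summary <- function(x, ...) {
  cat(sprintf("simulated_summary: %d replicates x %d SNPs (seed %s)\n",
              x$n_rep, length(x$snp_ids), format(x$seed)))
  invisible(x)
}

#' Long-format view of a simulated summary
#'
#' @param x a [assemble()] result.
#' @param row.names,optional,... passed for S3 compatibility; unused.
#' @return data frame with one row per replicate x SNP: `replicate`, `snp`,
#'   `chr`, `pos`, `a0`, `a1`, `beta`, `se`, `z`, `p`.
#' @export
as.data.frame.simulated_summary <- function(x, row.names = NULL,
                                            optional = FALSE, ...) {
  ns <- length(x$snp_ids); nr <- x$n_rep
  info <- x$snp_info
  pick <- function(col, default) {
    if (!is.null(info) && col %in% names(info))
      rep(info[[col]], each = nr) else rep(default, ns * nr)
  }
  data.frame(replicate = rep(seq_len(nr), times = ns),
             snp = rep(x$snp_ids, each = nr),
             chr = pick("chr", NA_character_),
             pos = pick("pos", NA_integer_),
             a0 = pick("a0", NA_character_),
             a1 = pick("a1", NA_character_),
             beta = as.vector(x$beta), se = as.vector(x$se),
             z = as.vector(x$z), p = as.vector(x$p),
             stringsAsFactors = FALSE)
}

# Fixed per-component seed streams derived from one master seed; offsets are
# recorded in run metadata. Kept below 2^31 - 1.
derive_seed <- function(seed, stream = c("z", "se", "panel", "oracle")) {
  stream <- match.arg(stream)
  off <- c(z = 101L, se = 202L, panel = 303L, oracle = 404L)[[stream]]
  as.integer((as.numeric(seed) * 7919 + off) %% 2147483647)
}

#' Simulate GWAS summary statistics for a region
#'
#' End-to-end convenience wrapper: expected statistics via
#' [expected_z_region()], LD matrix via [genotype_correlation()], then
#' [simulate_z()], [simulate_se()] and [assemble()].  Per-component seed
#' streams are derived from the single master seed.
#'
#' @param panel a [haplotype_panel()].
#' @param model a [causal_model()].
#' @param n_rep number of replicates.
#' @param seed master integer seed.
#' @param lambda optional haplotype-frequency smoothing.
#' @param expected optionally, a precomputed [expected_z_region()] result
#'   (skips recomputation).
#' @param sigma optionally, a precomputed correlation matrix.
#' @return a `simulated_summary` with the `expected_summary` attached as
#'   `$expected`.
#' @export
simulate_summary <- function(panel, model, n_rep, seed, lambda = 0,
                             expected = NULL, sigma = NULL) {
  if (is.null(expected)) expected <- expected_z_region(model, panel, lambda)
  if (is.null(sigma)) sigma <- genotype_correlation(panel)
  z <- simulate_z(expected$ze, sigma, n_rep, derive_seed(seed, "z"))
  se <- simulate_se(expected, n_rep, derive_seed(seed, "se"))
  out <- assemble(z, se, snp_info = expected, seed = seed)
  out$expected <- expected
  out
}
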