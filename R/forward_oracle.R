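#' Forward-simulate an individual-level case-control study
#'
#' The gold-standard comparator.  Controls are formed by random union of two
#' reference haplotypes.  Cases are drawn by exact rejection sampling from
#' the case-enriched genotype law: a haplotype pair with causal genotype
#' vector `w` is accepted with probability
#' `exp(gamma.w - max_w' gamma.w')`, so accepted genotypes follow
#' `P1(w) propto P0(w) exp(gamma.w)` — the same conditional distribution the
#' direct method targets, without simulating a whole population and
#' discarding samples.
#'
#' @param panel a [haplotype_panel()].
#' @param model a [causal_model()].
#' @param seed integer seed (optional; state is advanced if `NULL`).
#' @param snps SNP identifiers to return genotypes for (default: all panel
#'   SNPs).  Causal genotypes are always computed internally for the
#'   rejection step.
#' @return an `individual_study`: list with `genotypes` (`N x k` matrix,
#'   cases first), `phenotypes` (N1 ones then N0 zeros), `n0`, `n1`,
#'   `snp_ids` and the realized case `acceptance_rate`.
#' @export
sample_study <- function(panel, model, seed = NULL, snps = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (is.null(snps)) snps <- panel$snp_ids
  idx <- match(snps, panel$snp_ids)
  if (anyNA(idx)) stop("unknown SNP id: ",
                       paste(snps[is.na(idx)], collapse = ", "))
  widx <- match(model$snp_ids, panel$snp_ids)
  if (anyNA(widx)) stop("causal SNP(s) not in panel")
  H <- nrow(panel$alleles)
  n0 <- model$n0; n1 <- model$n1
  gamma <- model$gamma
  eta_max <- sum(pmax(0, 2 * gamma))

  # mean acceptance probability under P0; guards against silent underflow
  pacc0 <- {
    hW <- panel$alleles[, widx, drop = FALSE]
    hs <- as.vector(hW %*% gamma)
    mean(exp(outer(hs, hs, "+") - eta_max))
  }
  if (pacc0 < 1e-6)
    stop("case rejection acceptance rate ~", format(pacc0),
         "; reduce |log odds ratios|")

  # controls: random union of two independently drawn haplotypes
  c1 <- sample.int(H, n0, replace = TRUE)
  c2 <- sample.int(H, n0, replace = TRUE)

  # cases: batched rejection
  a1 <- integer(0); a2 <- integer(0); tried <- 0L
  batch <- max(1000L, ceiling(1.2 * n1 / pacc0))
  while (length(a1) < n1) {
    b1 <- sample.int(H, batch, replace = TRUE)
    b2 <- sample.int(H, batch, replace = TRUE)
    eta <- as.vector((panel$alleles[b1, widx, drop = FALSE] +
                      panel$alleles[b2, widx, drop = FALSE]) %*% gamma)
    acc <- stats::runif(batch) < exp(eta - eta_max)
    tried <- tried + batch
    a1 <- c(a1, b1[acc]); a2 <- c(a2, b2[acc])
  }
  n_acc <- length(a1)
  a1 <- a1[seq_len(n1)]; a2 <- a2[seq_len(n1)]

  A <- panel$alleles[, idx, drop = FALSE]
  geno <- rbind(A[a1, , drop = FALSE] + A[a2, , drop = FALSE],
                A[c1, , drop = FALSE] + A[c2, , drop = FALSE])
  colnames(geno) <- snps
  structure(list(genotypes = geno,
                 phenotypes = rep(c(1L, 0L), c(n1, n0)),
                 n0 = n0, n1 = n1, snp_ids = snps,
                 acceptance_rate = n_acc / tried),
            class = "individual_study")
}

#' Cochran-Armitage trend-test Z scores
#'
#' The additive-coding score statistic
#' `Z_X = sum_i (G_iX - mean G_X)(Y_i - mean Y) / sqrt((N-1) V_X V_Y)`
#' with `V_X`, `V_Y` the `(N-1)`-divisor sample variances.  Monomorphic SNPs
#' in the study are flagged `NA`.
#'
#' @param study an [sample_study()] result.
#' @return named numeric vector of Z scores (NA where monomorphic).
#' @export
cochran_armitage_z <- function(study) {
  g <- study$genotypes; y <- study$phenotypes
  n <- length(y)
  if (stats::var(y) == 0) stop("phenotype is constant")
  u <- as.vector(crossprod(g - matrix(colMeans(g), n, ncol(g), byrow = TRUE),
                           y - mean(y)))
  vx <- apply(g, 2L, stats::var)
  vy <- stats::var(y)
  z <- ifelse(vx > 0, u / sqrt((n - 1) * vx * vy), NA_real_)
  names(z) <- study$snp_ids
  z
}

# Newton-Raphson logistic fit on a collapsed 2 x 3 genotype table.
# counts: n_y_g for y in {0,1} at dosages g_values. Returns beta, se, converged.
logistic_fit_counts <- function(n0g, n1g, tol = 1e-8, maxit = 50L,
                                g_values = 0:2) {
  g <- g_values
  tot <- n0g + n1g
  keep <- tot > 0
  # separation screen: cases confined to one side of the genotype range
  if (sum((n0g > 0) & keep) == 0L || sum((n1g > 0) & keep) == 0L)
    return(c(beta = NA_real_, se = NA_real_, converged = 0))
  b <- c(log(sum(n1g) / sum(n0g)), 0)
  conv <- FALSE
  for (it in seq_len(maxit)) {
    eta <- b[1] + b[2] * g
    mu <- stats::plogis(eta)
    w <- tot * mu * (1 - mu)
    score <- c(sum(n1g - tot * mu), sum(g * (n1g - tot * mu)))
    info <- matrix(c(sum(w), sum(g * w), sum(g * w), sum(g^2 * w)), 2L)
    step <- tryCatch(solve(info, score), error = function(e) NULL)
    if (is.null(step) || !all(is.finite(step)))
      return(c(beta = NA_real_, se = NA_real_, converged = 0))
    b <- b + step
    if (sqrt(sum(score^2)) < tol) { conv <- TRUE; break }
    if (abs(b[2]) > 30) break   # diverging: (quasi-)separation
  }
  # saturation makes the gradient vanish under separation; flag it
  if (!conv || abs(b[2]) > 15)
    return(c(beta = NA_real_, se = NA_real_, converged = 0))
  eta <- b[1] + b[2] * g
  mu <- stats::plogis(eta)
  w <- tot * mu * (1 - mu)
  info <- matrix(c(sum(w), sum(g * w), sum(g * w), sum(g^2 * w)), 2L)
  se <- sqrt(solve(info)[2L, 2L])
  c(beta = b[2], se = se, converged = 1)
}

#' Per-SNP logistic Wald fits
#'
#' Single-SNP logistic regression of case status on additive genotype dosage,
#' fitted by Newton-Raphson (iteratively reweighted least squares) on the
#' collapsed genotype x phenotype table to gradient norm `< 1e-8`; the
#' standard error is from the observed information at the MLE (the SNPTEST
#' convention).  Non-converged or separated SNPs are flagged `NA`.
#'
#' @param study an [sample_study()] result.
#' @return data frame with columns `snp`, `beta`, `se`, `converged`.
#' @export
logistic_wald <- function(study) {
  g <- study$genotypes; y <- study$phenotypes
  ns <- ncol(g)
  out <- matrix(NA_real_, ns, 3L,
                dimnames = list(study$snp_ids, c("beta", "se", "converged")))
  for (s in seq_len(ns)) {
    n1g <- vapply(0:2, function(k) sum(y == 1L & g[, s] == k), 0)
    n0g <- vapply(0:2, function(k) sum(y == 0L & g[, s] == k), 0)
    out[s, ] <- logistic_fit_counts(n0g, n1g)
  }
  data.frame(snp = study$snp_ids, beta = out[, "beta"], se = out[, "se"],
             converged = out[, "converged"] == 1, row.names = NULL,
             stringsAsFactors = FALSE)
}

#' Replicate forward-simulation summary statistics
#'
#' Runs [sample_study()] `n_rep` times (optionally restricted to a SNP
#' subset, e.g. the causal variants) and analyses each replicate with the
#' Cochran-Armitage score test and the per-SNP logistic Wald fit.  This is
#' the slow, individual-level path that the direct simulator replaces; its
#' cost scales linearly with `N`.
#'
#' @param panel a [haplotype_panel()].
#' @param model a [causal_model()].
#' @param n_rep number of replicates.
#' @param seed integer seed.
#' @param snps SNP subset to analyse (default: all panel SNPs).
#' @return an `oracle_summary`: list of `n_rep x k` matrices `z`, `beta`,
#'   `se`, plus `snp_ids`, `n_rep`, `seed`.
#' @export
oracle_summary <- function(panel, model, n_rep, seed, snps = NULL) {
  if (is.null(snps)) snps <- panel$snp_ids
  set.seed(seed)
  k <- length(snps)
  z <- beta <- se <- matrix(NA_real_, n_rep, k, dimnames = list(NULL, snps))
  for (r in seq_len(n_rep)) {
    study <- sample_study(panel, model, seed = NULL, snps = snps)
    z[r, ] <- cochran_armitage_z(study)
    lw <- logistic_wald(study)
    beta[r, ] <- lw$beta
    se[r, ] <- lw$se
  }
  structure(list(snp_ids = snps, z = z, beta = beta, se = se,
                 n_rep = n_rep, seed = seed),
            class = "oracle_summary")
}

#' Long-format view of an oracle summary
#' @param x an [oracle_summary()] result.
#' @param row.names,optional,... S3 compatibility; unused.
#' @return data frame with `replicate`, `snp`, `beta`, `se`, `z`, `p`.
#' @export
as.data.frame.oracle_summary <- function(x, row.names = NULL,
                                         optional = FALSE, ...) {
  nr <- x$n_rep; ns <- length(x$snp_ids)
  data.frame(replicate = rep(seq_len(nr), times = ns),
             snp = rep(x$snp_ids, each = nr),
             beta = as.vector(x$beta), se = as.vector(x$se),
             z = as.vector(x$z), p = 2 * stats::pnorm(-abs(as.vector(x$z))),
             stringsAsFactors = FALSE)
}
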