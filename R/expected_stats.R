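#' Expected score-test numerator E(U_X)
#'
#' The Cochran-Armitage numerator is
#' `U_X = sum_i (G_iX - mean(G_X)) (Y_i - mean(Y))`.  Conditioning on the
#' causal genotypes and case-control ascertainment gives
#' `E(U_X) = (N-1) N0 N1 / N^2 * sum_w (factor(w) - 1) *
#'   [2 P0(G_X = 2, G_W = w) + P0(G_X = 1, G_W = w)]`
#' with `factor(w) = (N0/N1) exp(gamma0 + gamma.w) = exp(gamma.w)/C`.  Note
#' `2 P(G_X = 2, w) + P(G_X = 1, w) = E(G_X 1{G_W = w})`, so the sum weights
#' each joint genotype row by its `G_X` dosage.
#'
#' @param snp SNP identifier `X`.
#' @param model a [causal_model()].
#' @param joint a [joint_genotype_probs()] table over `{X} union W`.
#' @param enr the [solve_enrichment()] output.
#' @return the expected numerator (a scalar).
#' @export
expected_u <- function(snp, model, joint, enr) {
  need <- union(snp, model$snp_ids)
  if (!setequal(joint$subset, need))
    stop("joint table must cover {X} union W for X = ", snp)
  ix <- match(snp, joint$subset)
  iw <- match(enr$causal_ids, joint$subset)
  fac <- factor_lookup(enr, joint$geno[, iw, drop = FALSE])
  n0 <- as.numeric(model$n0); n1 <- as.numeric(model$n1); n <- n0 + n1
  (n - 1) * n0 * n1 / n^2 *
    sum((fac - 1) * joint$geno[, ix] * joint$probs)
}

# Sum over individuals of the product of own-moment factors:
# S(e1,...,er) = n0 * prod_j M0[e_j] + n1 * prod_j M1[e_j],
# where Mt[k] = E(G^k) in group t.
moment_S <- function(m0, m1, n0, n1, e) {
  n0 * prod(m0[e]) + n1 * prod(m1[e])
}

#' Exact moments of the sample genotype variance
#'
#' First and second moments of `V_X = sum_i (G_iX - mean(G_X))^2 / (N - 1)`
#' when `N0` genotypes are drawn i.i.d. from the control distribution `p0`
#' and `N1` i.i.d. from the case distribution `p1`.  Computed exactly from
#' power sums `S1 = sum G_i`, `S2 = sum G_i^2` via
#' `(N-1) V = S2 - S1^2 / N`, expanding `E(S2^2)`, `E(S2 S1^2)` and `E(S1^4)`
#' over distinct-index patterns (inclusion-exclusion over the two groups).
#'
#' @param dist a [group_genotype_dist()] result (fields `p0`, `p1`).
#' @param n0,n1 control and case counts, `N = n0 + n1 >= 2`.
#' @return named numeric `c(ev = E(V_X), ev2 = E(V_X^2))`.
#' @export
variance_moments <- function(dist, n0, n1) {
  p0 <- dist$p0; p1 <- dist$p1
  n0 <- as.numeric(n0); n1 <- as.numeric(n1)
  n <- n0 + n1
  if (n < 2) stop("N = n0 + n1 must be >= 2")
  g <- 0:2
  m0 <- vapply(1:4, function(k) sum(g^k * p0), 0)
  m1 <- vapply(1:4, function(k) sum(g^k * p1), 0)
  S <- function(...) moment_S(m0, m1, n0, n1, c(...))

  A1 <- S(1); A2 <- S(2); A3 <- S(3); A4 <- S(4)
  S11 <- S(1, 1); S21 <- S(2, 1); S22 <- S(2, 2); S31 <- S(3, 1)
  S111 <- S(1, 1, 1); S211 <- S(2, 1, 1); S1111 <- S(1, 1, 1, 1)

  ES2 <- A2
  ES1sq <- A2 + A1^2 - S11
  ES2sq <- A4 + A2^2 - S22
  # ordered distinct triples sum_{i,j,k} m2_i m1_j m1_k
  D3 <- A2 * A1^2 - 2 * S21 * A1 - A2 * S11 + 2 * S211
  ES2S1sq <- A4 + 2 * (A3 * A1 - S31) + (A2^2 - S22) + D3
  # ordered distinct quadruples of m1 via power sums p_r = sum_i m1_i^r
  p1s <- A1; p2s <- S11; p3s <- S111; p4s <- S1111
  D4 <- p1s^4 - 6 * p2s * p1s^2 + 3 * p2s^2 + 8 * p3s * p1s - 6 * p4s
  ES1q <- A4 + 4 * (A3 * A1 - S31) + 3 * (A2^2 - S22) + 6 * D3 + D4

  ev <- (ES2 - ES1sq / n) / (n - 1)
  ev2 <- (ES2sq - 2 * ES2S1sq / n + ES1q / n^2) / (n - 1)^2
  c(ev = ev, ev2 = ev2)
}

#' Method-of-moments inverse-gamma fit for V_X
#'
#' The sample genotype variance is modelled as
#' `V_X ~ InverseGamma(alpha, beta)` with parameters matched to its first two
#' moments:
#' `alpha = (2 ev2 - ev^2) / (ev2 - ev^2)`,
#' `beta = ev * ev2 / (ev2 - ev^2)`.
#'
#' @param ev,ev2 first and second moments of `V_X`; requires `ev > 0` and
#'   `ev2 > ev^2`.
#' @return named numeric `c(alpha =, beta =)`.
#' @export
fit_inverse_gamma <- function(ev, ev2) {
  if (!(ev > 0)) stop("ev must be positive")
  d <- ev2 - ev^2
  if (!(d > 0))
    stop("degenerate variance: ev2 <= ev^2 (near-constant V_X)")
  c(alpha = (2 * ev2 - ev^2) / d, beta = ev * ev2 / d)
}

#' E(V^{-1/2}) for an inverse-gamma variance
#'
#' For `V ~ InverseGamma(alpha, beta)`,
#' `E(V^{-1/2}) = beta^{-1/2} Gamma(alpha + 1/2) / Gamma(alpha)`,
#' evaluated on the log scale for stability.
#'
#' @param alpha,beta positive inverse-gamma parameters.
#' @return the `-1/2` moment.
#' @export
expected_inv_sqrt_v <- function(alpha, beta) {
  stopifnot(alpha > 0, beta > 0)
  exp(lgamma(alpha + 0.5) - lgamma(alpha) - 0.5 * log(beta))
}

#' Expected Z scores and variance model for every SNP in a region
#'
#' The deterministic core of the simulator.  For each SNP `X` it computes the
#' expected score numerator `E(U_X)`, the exact first two moments of the
#' genotype sample variance `V_X` under the case-control mixture, the
#' inverse-gamma method-of-moments fit, and the first-order expected Z score
#' `Z_E = E(U_X) * E(V_X^{-1/2}) / sqrt((N-1) V_Y)` with
#' `V_Y = N0 N1 / (N (N-1))` (so the scale factor is `sqrt(N / (N0 N1))`).
#' The enumeration cost is independent of `N0` and `N1`.
#'
#' SNPs whose variance-moment fit is degenerate (`ev2 <= ev^2`, possible for
#' near-monomorphic SNPs in tiny panels) fall back to treating `V_X` as the
#' constant `ev`; they are flagged in the `degenerate` column.
#'
#' @param model a [causal_model()]; its SNPs must be in the panel.
#' @param panel a [haplotype_panel()].
#' @param lambda optional Laplace smoothing for haplotype frequencies.
#' @return an `expected_summary` data frame with one row per SNP (columns
#'   `snp`, `chr`, `pos`, `a0`, `a1`, `eu`, `ev`, `ev2`, `alpha`, `beta`,
#'   `degenerate`, `ze`) and attributes `n0`, `n1`, `vy`, `gamma0` and
#'   `n_ops` (number of enumerated genotype terms).
#' @export
expected_z_region <- function(model, panel, lambda = 0) {
  stopifnot(inherits(model, "causal_model"), inherits(panel, "haplotype_panel"))
  miss <- setdiff(model$snp_ids, panel$snp_ids)
  if (length(miss)) stop("causal SNP(s) not in panel: ",
                         paste(miss, collapse = ", "))
  W <- model$snp_ids
  pw <- joint_genotype_probs(haplotype_freq_table(panel, W, lambda))
  enr <- solve_enrichment(model, pw)
  n0 <- as.numeric(model$n0); n1 <- as.numeric(model$n1); n <- n0 + n1
  vy <- n0 * n1 / (n * (n - 1))
  snps <- panel$snp_ids
  ns <- length(snps)
  eu <- ev <- ev2 <- alpha <- beta <- ze <- numeric(ns)
  degen <- logical(ns)
  n_ops <- 0L
  scale_fac <- sqrt(n / (n0 * n1))     # = 1 / sqrt((N-1) V_Y)
  for (s in seq_len(ns)) {
    x <- snps[s]
    subset <- if (x %in% W) W else c(x, W)
    joint <- joint_genotype_probs(haplotype_freq_table(panel, subset, lambda))
    n_ops <- n_ops + nrow(joint$geno)
    eu[s] <- expected_u(x, model, joint, enr)
    dist <- group_genotype_dist(x, model, joint, enr)
    vm <- variance_moments(dist, n0, n1)
    ev[s] <- vm[["ev"]]; ev2[s] <- vm[["ev2"]]
    if (vm[["ev"]] > 0 && vm[["ev2"]] > vm[["ev"]]^2 * (1 + 1e-12)) {
      ab <- fit_inverse_gamma(vm[["ev"]], vm[["ev2"]])
      alpha[s] <- ab[["alpha"]]; beta[s] <- ab[["beta"]]
      einv <- expected_inv_sqrt_v(ab[["alpha"]], ab[["beta"]])
    } else {
      degen[s] <- TRUE
      alpha[s] <- NA_real_; beta[s] <- NA_real_
      einv <- if (vm[["ev"]] > 0) vm[["ev"]]^-0.5 else 0
    }
    ze[s] <- if (eu[s] == 0) 0 else eu[s] * einv * scale_fac
  }
  out <- data.frame(snp = snps, chr = panel$chr, pos = panel$positions,
                    a0 = panel$a0, a1 = panel$a1,
                    eu = eu, ev = ev, ev2 = ev2,
                    alpha = alpha, beta = beta,
                    degenerate = degen, ze = ze,
                    stringsAsFactors = FALSE)
  structure(out, class = c("expected_summary", "data.frame"),
            n0 = n0, n1 = n1, vy = vy, gamma0 = enr$gamma0, n_ops = n_ops)
}

#' Write an expected summary as tab-delimited text
#'
#' @param summary an [expected_z_region()] result.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_expected_summary <- function(summary, path) {
  data.table::fwrite(summary[, c("snp", "pos", "ze", "alpha", "beta", "eu")],
                     path, sep = "\t")
  invisible(path)
}
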