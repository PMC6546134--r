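#' Feasible correlation range for two binary variables
#'
#' Frechet bounds on the Pearson correlation of two Bernoulli variables with
#' success probabilities `pa`, `pb` (here: alternate-allele frequencies).
#'
#' @param maf_a,maf_b allele frequencies in (0, 1).
#' @return named numeric `c(lower =, upper =)`.
#' @export
feasible_r_range <- function(maf_a, maf_b) {
  pa <- maf_a; pb <- maf_b
  upper <- min(sqrt(pa * (1 - pb) / (pb * (1 - pa))),
               sqrt(pb * (1 - pa) / (pa * (1 - pb))))
  lower <- max(-sqrt(pa * pb / ((1 - pa) * (1 - pb))),
               -sqrt((1 - pa) * (1 - pb) / (pa * pb)))
  c(lower = lower, upper = upper)
}

# P(Z1 > ta, Z2 > tb) for standard bivariate normal with correlation rho,
# by one-dimensional quadrature over the conditional tail.
bvn_orthant <- function(ta, tb, rho) {
  if (abs(rho) > 1 - 1e-12) {
    if (rho > 0) return(stats::pnorm(-max(ta, tb)))
    return(max(0, 1 - stats::pnorm(ta) - stats::pnorm(tb)))
  }
  s <- sqrt(1 - rho^2)
  f <- function(x) stats::dnorm(x) * stats::pnorm((rho * x - tb) / s)
  stats::integrate(f, ta, Inf, rel.tol = 1e-10, abs.tol = 1e-12)$value
}

# Pearson correlation of the thresholded indicators implied by latent rho.
binary_corr_from_rho <- function(rho, maf_a, maf_b) {
  ta <- stats::qnorm(1 - maf_a); tb <- stats::qnorm(1 - maf_b)
  p11 <- bvn_orthant(ta, tb, rho)
  (p11 - maf_a * maf_b) /
    sqrt(maf_a * (1 - maf_a) * maf_b * (1 - maf_b))
}

#' Calibrate a latent Gaussian correlation to a binary target correlation
#'
#' Finds the latent bivariate-normal correlation `rho` such that thresholding
#' at the per-SNP quantiles `qnorm(1 - maf)` yields binary (haplotype-allele)
#' variables with Pearson correlation `target_r`, by bisection against the
#' numerically integrated orthant probability.  The binary correlation is
#' monotone increasing in `rho`.
#'
#' @param target_r target haplotype-allele correlation.
#' @param maf_a,maf_b allele frequencies of the pair.
#' @param tol bisection tolerance on the achieved binary correlation.
#' @return the latent correlation `rho`.
#' @export
calibrate_latent_rho <- function(target_r, maf_a, maf_b, tol = 1e-6) {
  rng <- feasible_r_range(maf_a, maf_b)
  if (target_r < rng[["lower"]] - 1e-9 || target_r > rng[["upper"]] + 1e-9)
    stop(sprintf(
      "target correlation %.4f infeasible for MAFs (%.3f, %.3f): bounds [%.4f, %.4f]",
      target_r, maf_a, maf_b, rng[["lower"]], rng[["upper"]]))
  if (target_r == 0) return(0)
  if (abs(target_r - rng[["upper"]]) < 1e-12 && maf_a == maf_b) return(1)
  lo <- -1 + 1e-9; hi <- 1 - 1e-9
  for (i in 1:200) {
    mid <- (lo + hi) / 2
    r <- binary_corr_from_rho(mid, maf_a, maf_b)
    if (abs(r - target_r) < tol) return(mid)
    if (r < target_r) lo <- mid else hi <- mid
  }
  mid
}

#' Specify a synthetic reference panel
#'
#' @param mafs per-SNP alternate-allele frequencies in (0, 0.5].
#' @param ld either `list(type = "chain", rho = r)` for autoregressive latent
#'   background LD (adjacent-SNP latent correlation `r`, decaying as
#'   `r^distance-in-SNPs`; `rho` may be a scalar or a length `n-1` vector of
#'   adjacent latent correlations), or a data frame with columns `a`, `b`,
#'   `r` giving target haplotype-allele correlations for named SNP pairs
#'   (all other pairs independent).
#' @param n_hap number of haplotypes (>= 100 recommended; smaller panels
#'   trigger a warning).
#' @param seed integer seed.
#' @param snp_ids,positions optional metadata; defaults are generated.
#' @return a `panel_spec`.
#' @export
panel_spec <- function(mafs, ld = list(type = "chain", rho = 0.9),
                       n_hap = 600, seed = 1,
                       snp_ids = NULL, positions = NULL) {
  n <- length(mafs)
  if (any(mafs <= 0 | mafs > 0.5))
    stop("mafs must lie in (0, 0.5]")
  if (n_hap < 2) stop("n_hap must be >= 2")
  if (n_hap < 100) warning("n_hap < 100: frequency estimates will be noisy",
                           call. = FALSE)
  if (is.null(snp_ids)) snp_ids <- sprintf("snp%04d", seq_len(n))
  if (is.null(positions)) positions <- 10000L + 1000L * seq_len(n)
  if (is.data.frame(ld)) {
    ia <- match(ld$a, snp_ids); ib <- match(ld$b, snp_ids)
    if (anyNA(ia) || anyNA(ib)) stop("ld pair names not in snp_ids")
    for (k in seq_len(nrow(ld))) {
      rng <- feasible_r_range(mafs[ia[k]], mafs[ib[k]])
      if (ld$r[k] < rng[["lower"]] - 1e-9 || ld$r[k] > rng[["upper"]] + 1e-9)
        stop(sprintf("ld target r = %.3f infeasible for pair (%s, %s); bounds [%.4f, %.4f]",
                     ld$r[k], ld$a[k], ld$b[k], rng[["lower"]], rng[["upper"]]))
    }
  }
  structure(list(mafs = mafs, ld = ld, n_hap = as.integer(n_hap),
                 seed = as.integer(seed), snp_ids = snp_ids,
                 positions = as.integer(positions)),
            class = "panel_spec")
}

# latent haplotype draws: H x n standard normal with the requested structure
draw_latent <- function(spec) {
  n <- length(spec$mafs); H <- spec$n_hap
  ld <- spec$ld
  if (is.data.frame(ld)) {
    R <- diag(n)
    for (k in seq_len(nrow(ld))) {
      i <- match(ld$a[k], spec$snp_ids); j <- match(ld$b[k], spec$snp_ids)
      rho <- calibrate_latent_rho(ld$r[k], spec$mafs[i], spec$mafs[j])
      R[i, j] <- R[j, i] <- rho
    }
    ev <- eigen(R, symmetric = TRUE, only.values = TRUE)$values
    if (min(ev) < -1e-10) stop("pairwise ld targets yield a non-PSD latent matrix")
    L <- chol(R + diag(1e-10, n))
    matrix(stats::rnorm(H * n), H, n) %*% L
  } else {
    rho <- ld$rho
    if (length(rho) == 1L) rho <- rep(rho, max(n - 1L, 0L))
    if (length(rho) != max(n - 1L, 0L))
      stop("chain rho must be scalar or length n - 1")
    z <- matrix(stats::rnorm(H * n), H, n)
    for (j in seq_len(n - 1L))
      z[, j + 1L] <- rho[j] * z[, j] + sqrt(1 - rho[j]^2) * z[, j + 1L]
    z
  }
}

#' Generate a synthetic reference haplotype panel
#'
#' Haplotype alleles are obtained by thresholding a latent correlated
#' Gaussian vector at the per-SNP quantiles `qnorm(1 - maf)` (Gaussian
#' copula), which controls marginal allele frequencies exactly in
#' expectation while allowing tunable pairwise LD.  Panels containing a
#' monomorphic SNP are redrawn (bounded retries) with a warning.
#'
#' @param spec a [panel_spec()].
#' @param max_retries redraw attempts before giving up on polymorphism.
#' @return a [haplotype_panel()].
#' @export
generate_panel <- function(spec, max_retries = 20L) {
  stopifnot(inherits(spec, "panel_spec"))
  thr <- stats::qnorm(1 - spec$mafs)
  set.seed(spec$seed)
  for (attempt in seq_len(max_retries)) {
    z <- draw_latent(spec)
    a <- matrix(0L, nrow(z), ncol(z))
    a[sweep(z, 2L, thr, ">")] <- 1L
    f <- colMeans(a)
    if (all(f > 0 & f < 1)) {
      if (attempt > 1L)
        warning("panel regenerated ", attempt - 1L,
                " time(s) to avoid monomorphic SNPs", call. = FALSE)
      return(haplotype_panel(a, spec$snp_ids, spec$positions,
                             chr = "1"))
    }
  }
  stop("could not draw a fully polymorphic panel in ", max_retries,
       " attempts; increase n_hap or the MAFs")
}

# Table 1 validation scenarios: causal MAFs, odds ratios and pairwise r.
scenario_table <- function() {
  list(
    `1` = list(mafs = 0.5, or = 1.1, r = NULL,
               label = "single common causal variant, weak effect"),
    `2` = list(mafs = 0.02, or = 1.5, r = NULL,
               label = "single low frequency causal variant, strong effect"),
    `3` = list(mafs = c(0.27, 0.37, 0.26), or = c(1.1, 1.2, 1.3), r = NULL,
               label = "three causal variants, unlinked"),
    `4` = list(mafs = c(0.39, 0.25), or = c(1.2, 1 / 1.2), r = 0.15,
               label = "two causal variants, weakly linked"),
    `5` = list(mafs = c(0.1, 0.15), or = c(1.2, 1 / 1.2), r = 0.8,
               label = "two causal variants, strongly linked"))
}

#' Build a validation-scenario panel and causal model
#'
#' Constructs a synthetic panel emulating a reference cohort (default 600
#' haplotypes, ~1000 SNPs) with autoregressive background LD (latent
#' adjacent-SNP correlation 0.9) and the causal SNPs of one of the five
#' validation scenarios embedded in it: causal MAFs and odds ratios are fixed
#' by the scenario; a linked causal pair is placed at adjacent positions with
#' the latent link calibrated so the realized haplotype-allele correlation
#' matches the scenario target; "unlinked" causal SNPs keep LD with their
#' local background but the latent chain is cut (link set to 0) midway
#' between consecutive causal SNPs, so they are exactly uncorrelated with
#' each other.
#'
#' @param scenario_id integer 1..5.
#' @param n_hap haplotype count (default 600, the reference-cohort scale).
#' @param seed integer seed.
#' @param n_snp total SNP count including causal SNPs (default 1000).
#' @param n0,n1 control and case counts for the returned model.
#' @param r_is_r2 if `TRUE`, interpret the scenario's quoted linkage value as
#'   `r^2` and target `sqrt(r2)` instead (both conventions appear in the
#'   field; default is the direct `r` reading).
#' @param ar_rho background adjacent-SNP latent correlation.
#' @return list with `panel`, `model` (a [causal_model()]), `causal_ids`,
#'   and the scenario `label`.
#' @export
scenario_panel <- function(scenario_id, n_hap = 600, seed = 1, n_snp = 1000,
                           n0 = 2000, n1 = 2000, r_is_r2 = FALSE,
                           ar_rho = 0.9) {
  sc <- scenario_table()[[as.character(scenario_id)]]
  if (is.null(sc)) stop("scenario_id must be 1..5")
  m <- length(sc$mafs)
  if (n_snp < m + 2L) stop("n_snp too small for scenario")
  set.seed(derive_seed(seed, "panel"))
  mafs <- stats::runif(n_snp, 0.05, 0.5)
  # causal placement: evenly spread; linked pairs adjacent
  if (!is.null(sc$r)) {
    mid <- max(2L, n_snp %/% 2L)
    cidx <- c(mid, mid + 1L)
  } else {
    cidx <- round(seq(0.2, 0.8, length.out = m) * n_snp)
    cidx <- pmin(pmax(cidx, 1L), n_snp)
  }
  mafs[cidx] <- sc$mafs
  rho <- rep(ar_rho, n_snp - 1L)
  if (!is.null(sc$r)) {
    target <- if (r_is_r2) sqrt(sc$r) else sc$r
    # Quoted scenario correlations can exceed the Frechet bound for the
    # quoted (rounded) MAFs - e.g. r = 0.8 at MAFs 0.1/0.15 has bound 0.7935.
    # Clamp just inside the bound; the realized LD is as strong as the MAF
    # pair permits.
    rng <- feasible_r_range(sc$mafs[1L], sc$mafs[2L])
    clamped <- min(max(target, 0.999 * rng[["lower"]]),
                   0.999 * rng[["upper"]])
    if (clamped != target)
      warning(sprintf(
        "scenario %s target r = %.3f infeasible for MAFs (%.2f, %.2f); using %.4f (Frechet bound %.4f)",
        scenario_id, target, sc$mafs[1L], sc$mafs[2L], clamped,
        rng[["upper"]]), call. = FALSE)
    rho[cidx[1L]] <- calibrate_latent_rho(clamped, sc$mafs[1L], sc$mafs[2L])
  } else if (m > 1L) {
    # cut the latent chain between consecutive causal SNPs: unlinked by design
    for (k in seq_len(m - 1L))
      rho[(cidx[k] + cidx[k + 1L]) %/% 2L] <- 0
  }
  ids <- sprintf("snp%04d", seq_len(n_snp))
  ids[cidx] <- sprintf("causal%d", seq_len(m))
  spec <- panel_spec(mafs, ld = list(type = "chain", rho = rho),
                     n_hap = n_hap, seed = derive_seed(seed, "panel") + 1L,
                     snp_ids = ids)
  panel <- generate_panel(spec)
  model <- causal_model(ids[cidx], log_or = log(sc$or), n0 = n0, n1 = n1)
  list(panel = panel, model = model, causal_ids = ids[cidx],
       label = sc$label)
}
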