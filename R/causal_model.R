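#' Specify a multi-SNP causal disease model
#'
#' The disease model is a binomial logistic regression of case status on the
#' additive genotype dosages at the causal SNPs `W`, with log odds ratios
#' `gamma` and an intercept `gamma0` fixed by the case-control design
#' (`N1` cases, `N0` controls).
#'
#' @param snp_ids identifiers of the `m` causal SNPs (distinct; must be
#'   present in the panel they are used with).
#' @param log_or log odds ratios `gamma`, one per causal SNP.  Alternatively
#'   supply `or` (odds ratios) and they are converted.
#' @param or odds ratios; ignored if `log_or` is given.
#' @param n0,n1 control and case counts.
#' @return an object of class `causal_model`.
#' @export
causal_model <- function(snp_ids, log_or = NULL, or = NULL, n0, n1) {
  if (is.null(log_or)) {
    if (is.null(or)) stop("supply log_or or or")
    log_or <- log(or)
  }
  snp_ids <- as.character(snp_ids)
  if (length(snp_ids) < 1L) stop("at least one causal SNP is required")
  if (length(snp_ids) > 12L)
    stop("at most 12 causal SNPs supported (3^m genotype enumeration)")
  if (anyDuplicated(snp_ids)) stop("causal snp_ids must be distinct")
  if (length(log_or) != length(snp_ids))
    stop("log_or length must match snp_ids")
  if (!all(is.finite(log_or))) stop("log odds ratios must be finite")
  n0 <- as.integer(n0); n1 <- as.integer(n1)
  if (n0 < 1L || n1 < 1L) stop("n0 and n1 must be >= 1")
  structure(list(snp_ids = snp_ids, gamma = as.numeric(log_or),
                 n0 = n0, n1 = n1),
            class = "causal_model")
}

#' @export
print.causal_model <- function(x, ...) {
  cat(sprintf("causal_model: %d causal SNP(s), N0 = %d controls, N1 = %d cases\n",
              length(x$snp_ids), x$n0, x$n1))
  cat(paste0("  ", x$snp_ids, ": OR = ",
             format(exp(x$gamma), digits = 4), collapse = "\n"), "\n")
  invisible(x)
}

#' Read a causal model from a config file
#'
#' Accepts JSON (`{"snps": [...], "or": [...]}` or an array of
#' `{"snp":, "or":}` records, optionally with `"log_or"`) or tab/space
#' delimited text with columns `snp` and `or` (or `log_or`).
#'
#' @param path config file path.
#' @param n0,n1 control and case counts (may instead be `"n0"`/`"n1"` keys in
#'   the JSON config).
#' @return a [causal_model()].
#' @export
read_causal_model <- function(path, n0 = NULL, n1 = NULL) {
  if (!file.exists(path)) stop("cannot read causal model file: ", path)
  first <- substr(trimws(readChar(path, 4096L)), 1L, 1L)
  if (first %in% c("{", "[")) {
    cfg <- jsonlite::fromJSON(path)
    if (is.data.frame(cfg)) cfg <- list(snps = cfg$snp,
                                        or = cfg$or, log_or = cfg$log_or)
    snps <- cfg$snps %||% cfg$snp
    lo <- cfg$log_or
    if (is.null(lo)) lo <- log(cfg$or)
    n0 <- n0 %||% cfg$n0; n1 <- n1 %||% cfg$n1
  } else {
    tab <- data.table::fread(path, data.table = FALSE)
    snps <- tab$snp
    lo <- if (!is.null(tab$log_or)) tab$log_or else log(tab$or)
  }
  if (is.null(n0) || is.null(n1))
    stop("n0 and n1 must be given (argument or config key)")
  causal_model(snps, log_or = lo, n0 = n0, n1 = n1)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Solve the case-control enrichment model
#'
#' Treating the reference haplotype frequencies as control frequencies, the
#' retrospective design implies a case genotype distribution
#' `P1(w) = P0(w) exp(gamma.w) / C` with normalizer
#' `C = sum_w P0(w) exp(gamma.w)`, and the logistic intercept satisfies
#' `exp(gamma0) = (N1/N0) / C` (so that the sample case fraction is `N1/N`).
#' The per-genotype case enrichment factor is
#' `factor(w) = (N0/N1) exp(gamma0 + gamma.w) = exp(gamma.w)/C`.
#'
#' @param model a [causal_model()].
#' @param pw a [joint_genotype_probs()] table over exactly the causal SNPs.
#' @return an `enrichment_model`: list with `gamma0`, `C`, causal genotype
#'   `patterns`, control probabilities `probs0`, and `factor` per pattern.
#' @export
solve_enrichment <- function(model, pw) {
  stopifnot(inherits(model, "causal_model"), inherits(pw, "joint_geno_table"))
  if (!setequal(pw$subset, model$snp_ids) ||
      length(pw$subset) != length(model$snp_ids))
    stop("pw must cover exactly the causal SNP subset")
  gamma <- model$gamma[match(pw$subset, model$snp_ids)]
  eta <- as.vector(pw$geno %*% gamma)
  if (max(abs(eta)) > 700)
    stop("exp overflow in enrichment model (|gamma . w| too large); ",
         "rescale the odds ratios")
  C <- sum(pw$probs * exp(eta))
  fac <- exp(eta) / C
  enr <- structure(
    list(gamma0 = log(model$n1 / model$n0) - log(C), C = C,
         patterns = pw$geno, probs0 = pw$probs, factor = fac,
         causal_ids = pw$subset, gamma = gamma,
         n0 = model$n0, n1 = model$n1),
    class = "enrichment_model")
  tot <- sum(enr$probs0 * enr$factor)
  if (abs(tot - 1) > 1e-10)
    stop("enrichment normalization failed: sum P0(w) factor(w) = ", tot)
  enr
}

factor_lookup <- function(enr, wmat) {
  k <- length(enr$causal_ids)
  key <- as.vector(enr$patterns %*% 3^(seq_len(k) - 1L))
  qkey <- as.vector(wmat %*% 3^(seq_len(k) - 1L))
  idx <- match(qkey, key)
  if (anyNA(idx)) stop("causal genotype pattern not covered by enrichment model")
  enr$factor[idx]
}

#' Case and control genotype distributions at a SNP
#'
#' Conditioning the joint genotype distribution over `{X} union W` on case
#' status gives, for SNP `X`:
#' `p0(g) = sum_w P0(G_X = g, G_W = w)` (controls: reference frequencies) and
#' `p1(g) = sum_w P0(G_X = g, G_W = w) * factor(w)` (cases).
#'
#' @param snp SNP identifier `X`.
#' @param model a [causal_model()].
#' @param joint a [joint_genotype_probs()] table over `{X} union W`.
#' @param enr the [solve_enrichment()] output for `model`.
#' @return a `cc_geno_dist`: list with `snp_id`, `p0`, `p1` (each a length-3
#'   probability vector over genotypes 0, 1, 2).
#' @export
group_genotype_dist <- function(snp, model, joint, enr) {
  need <- union(snp, model$snp_ids)
  if (!setequal(joint$subset, need))
    stop("joint table must cover {X} union W for X = ", snp)
  ix <- match(snp, joint$subset)
  iw <- match(enr$causal_ids, joint$subset)
  fac <- factor_lookup(enr, joint$geno[, iw, drop = FALSE])
  gx <- joint$geno[, ix]
  p0 <- p1 <- numeric(3L)
  for (g in 0:2) {
    sel <- gx == g
    p0[g + 1L] <- sum(joint$probs[sel])
    p1[g + 1L] <- sum(joint$probs[sel] * fac[sel])
  }
  p0 <- p0 / sum(p0); p1 <- p1 / sum(p1)
  structure(list(snp_id = snp, p0 = p0, p1 = p1), class = "cc_geno_dist")
}
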