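#' Build a run configuration
#'
#' Collects everything one end-to-end run needs: either a scenario id (panel
#' and model generated synthetically) or panel paths plus a causal-model
#' file, replicate counts, the master seed and an optional output prefix.
#'
#' @param scenario integer 1..5, or `NULL` to use file inputs.
#' @param hap,legend,vcf panel input paths (either `hap`+`legend` or `vcf`).
#' @param causals causal-model config path (see [read_causal_model()]), or a
#'   [causal_model()] object.
#' @param n0,n1 control and case counts.
#' @param n_rep number of summary-statistic replicates (>= 1).
#' @param seed master integer seed.
#' @param out output path prefix, or `NULL` for no files.
#' @param oracle run the forward oracle as well.
#' @param oracle_n_rep oracle replicate count.
#' @param n_snp,n_hap scenario-panel dimensions (scenario mode only).
#' @param lambda haplotype-frequency smoothing.
#' @return a `run_config` list.
#' @export
run_config <- function(scenario = NULL, hap = NULL, legend = NULL, vcf = NULL,
                       causals = NULL, n0 = 2000, n1 = 2000,
                       n_rep = 100, seed = 1, out = NULL,
                       oracle = FALSE, oracle_n_rep = 200,
                       n_snp = 1000, n_hap = 600, lambda = 0) {
  if (n_rep < 1) stop("n_rep must be >= 1")
  if (is.null(scenario)) {
    if (is.null(vcf) && (is.null(hap) || is.null(legend)))
      stop("supply scenario, or hap+legend, or vcf")
    for (p in c(hap, legend, vcf, if (is.character(causals)) causals))
      if (!file.exists(p)) stop("input file does not exist: ", p)
    if (is.null(causals)) stop("file input requires a causal model")
  }
  structure(list(scenario = scenario, hap = hap, legend = legend, vcf = vcf,
                 causals = causals, n0 = n0, n1 = n1, n_rep = n_rep,
                 seed = as.integer(seed), out = out, oracle = oracle,
                 oracle_n_rep = oracle_n_rep, n_snp = n_snp, n_hap = n_hap,
                 lambda = lambda),
            class = "run_config")
}

resolve_inputs <- function(config) {
  if (!is.null(config$scenario)) {
    sc <- scenario_panel(config$scenario, n_hap = config$n_hap,
                         seed = config$seed, n_snp = config$n_snp,
                         n0 = config$n0, n1 = config$n1)
    list(panel = sc$panel, model = sc$model, causal_ids = sc$causal_ids)
  } else {
    panel <- if (!is.null(config$vcf)) load_panel(config$vcf, "vcf")
             else load_panel(config$hap, "hap_legend", legend = config$legend)
    model <- if (inherits(config$causals, "causal_model")) config$causals
             else read_causal_model(config$causals, n0 = config$n0,
                                    n1 = config$n1)
    list(panel = panel, model = model, causal_ids = model$snp_ids)
  }
}

write_sidecar <- function(config, path, extra = list()) {
  meta <- c(list(
    package = "sumstatsim",
    version = as.character(utils::packageVersion("sumstatsim")),
    seed = config$seed,
    seed_streams = list(z = derive_seed(config$seed, "z"),
                        se = derive_seed(config$seed, "se"),
                        panel = derive_seed(config$seed, "panel"),
                        oracle = derive_seed(config$seed, "oracle")),
    config = config[!vapply(config, is.null, TRUE) &
                    names(config) != "causals"],
    timestamp_note = "timings recorded, never asserted"),
    extra)
  jsonlite::write_json(meta, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' Run an end-to-end summary-statistic simulation
#'
#' Loads or generates the panel, computes the expected statistics once,
#' simulates `n_rep` replicates and (if `config$out` is set) writes the
#' long-format summary table (`<out>_summary.tsv`: replicate, snp, chr, pos,
#' a0, a1, beta, se, z, p) plus a JSON run-metadata sidecar
#' (`<out>_meta.json`).  The expected-statistics stage runs exactly once
#' regardless of `n_rep`.
#'
#' @param config a [run_config()].
#' @return the `simulated_summary` (with `$expected`, `$timings` and
#'   `$files` attached), invisibly.
#' @export
run_simulation <- function(config) {
  stopifnot(inherits(config, "run_config"))
  t0 <- proc.time()[["elapsed"]]
  inp <- resolve_inputs(config)
  t1 <- proc.time()[["elapsed"]]
  expected <- expected_z_region(inp$model, inp$panel, config$lambda)
  sigma <- genotype_correlation(inp$panel)
  t2 <- proc.time()[["elapsed"]]
  sim <- simulate_summary(inp$panel, inp$model, config$n_rep, config$seed,
                          lambda = config$lambda,
                          expected = expected, sigma = sigma)
  t3 <- proc.time()[["elapsed"]]
  sim$timings <- c(inputs = t1 - t0, expected_stats = t2 - t1,
                   simulate = t3 - t2)
  sim$causal_ids <- inp$causal_ids
  if (!is.null(config$out)) {
    tab <- paste0(config$out, "_summary.tsv")
    data.table::fwrite(as.data.frame(sim), tab, sep = "\t")
    meta <- write_sidecar(config, paste0(config$out, "_meta.json"),
                          list(n_expected_stage_calls = 1L,
                               n_ops = attr(expected, "n_ops"),
                               timings = as.list(sim$timings)))
    sim$files <- c(summary = tab, meta = meta)
  }
  invisible(sim)
}

#' Run the forward oracle under a configuration
#'
#' Emits the same long-format summary-statistic table schema as
#' [run_simulation()], from individual-level forward simulation, for
#' side-by-side comparison.
#'
#' @param config a [run_config()]; `oracle_n_rep` replicates are run.
#' @param snps SNP subset to analyse (default: the causal SNPs, the paper's
#'   own gold-standard design; use `"all"` for every panel SNP).
#' @return the `oracle_summary` (with `$files` if `config$out` is set),
#'   invisibly.
#' @export
run_oracle <- function(config, snps = NULL) {
  stopifnot(inherits(config, "run_config"))
  inp <- resolve_inputs(config)
  if (is.null(snps)) snps <- inp$causal_ids
  else if (identical(snps, "all")) snps <- inp$panel$snp_ids
  orc <- oracle_summary(inp$panel, inp$model, config$oracle_n_rep,
                        derive_seed(config$seed, "oracle"), snps = snps)
  if (!is.null(config$out)) {
    tab <- paste0(config$out, "_oracle.tsv")
    data.table::fwrite(as.data.frame(orc), tab, sep = "\t")
    orc$files <- c(oracle = tab)
  }
  invisible(orc)
}

#' Validate the direct simulator against the forward oracle
#'
#' Runs both paths under one configuration and summarizes, per causal SNP:
#' mean/SD of Z and of the log odds ratio for each method, the combined
#' standard error of the mean difference, and two-sample Kolmogorov-Smirnov
#' statistics; plus the regional per-SNP median and IQR of `-log10 p` from
#' the direct simulator.  Machine-readable tables are written when
#' `config$out` is set; `plot = TRUE` additionally writes a PDF with the
#' regional signal plot and QQ comparison of log odds ratios.
#'
#' @param config a [run_config()] with `oracle = TRUE`.
#' @param plot write a PDF report.
#' @return list with `comparison` (per-causal-SNP data frame), `regional`
#'   (per-SNP data frame), `sim` and `oracle` objects.
#' @export
run_validation <- function(config, plot = FALSE) {
  stopifnot(inherits(config, "run_config"))
  if (!isTRUE(config$oracle)) stop("run_validation requires oracle = TRUE")
  if (config$oracle_n_rep < 100)
    warning("fewer than 100 oracle replicates: comparisons will be noisy",
            call. = FALSE)
  sim <- run_simulation(config)
  orc <- run_oracle(config)
  csnp <- orc$snp_ids
  comparison <- do.call(rbind, lapply(csnp, function(s) {
    zs <- sim$z[, s]; bs <- sim$beta[, s]
    zo <- orc$z[, s]; bo <- orc$beta[, s]
    ok <- is.finite(zo) & is.finite(bo)
    ksz <- suppressWarnings(stats::ks.test(zs, zo[ok]))
    ksb <- suppressWarnings(stats::ks.test(bs, bo[ok]))
    data.frame(snp = s,
               mean_z_sim = mean(zs), sd_z_sim = stats::sd(zs),
               mean_z_oracle = mean(zo[ok]), sd_z_oracle = stats::sd(zo[ok]),
               se_dz = sqrt(stats::var(zs) / length(zs) +
                            stats::var(zo[ok]) / sum(ok)),
               mean_beta_sim = mean(bs), sd_beta_sim = stats::sd(bs),
               mean_beta_oracle = mean(bo[ok]),
               sd_beta_oracle = stats::sd(bo[ok]),
               se_dbeta = sqrt(stats::var(bs) / length(bs) +
                               stats::var(bo[ok]) / sum(ok)),
               ks_stat_z = unname(ksz$statistic), ks_p_z = ksz$p.value,
               ks_stat_beta = unname(ksb$statistic), ks_p_beta = ksb$p.value,
               n_oracle_ok = sum(ok), stringsAsFactors = FALSE)
  }))
  mlp <- -log10(sim$p)
  regional <- data.frame(
    snp = sim$snp_ids,
    pos = sim$snp_info$pos,
    causal = sim$snp_ids %in% csnp,
    median_mlogp = apply(mlp, 2L, stats::median),
    iqr_lo = apply(mlp, 2L, stats::quantile, 0.25),
    iqr_hi = apply(mlp, 2L, stats::quantile, 0.75),
    stringsAsFactors = FALSE)
  out <- list(comparison = comparison, regional = regional,
              sim = sim, oracle = orc)
  if (!is.null(config$out)) {
    data.table::fwrite(comparison, paste0(config$out, "_comparison.tsv"),
                       sep = "\t")
    data.table::fwrite(regional, paste0(config$out, "_regional.tsv"),
                       sep = "\t")
    if (isTRUE(plot)) validation_plot(out, paste0(config$out, "_report.pdf"))
  }
  out
}

validation_plot <- function(val, path) {
  grDevices::pdf(path, width = 8, height = 8)
  on.exit(grDevices::dev.off())
  op <- graphics::par(mfrow = c(2, 1), mar = c(4, 4, 2, 1))
  on.exit(graphics::par(op), add = TRUE)
  reg <- val$regional
  graphics::plot(reg$pos, reg$median_mlogp, pch = 19,
                 col = ifelse(reg$causal, "red", "grey40"),
                 xlab = "position (bp)", ylab = "median -log10(p)",
                 main = "regional signal (median and IQR over replicates)")
  graphics::segments(reg$pos, reg$iqr_lo, reg$pos, reg$iqr_hi,
                     col = "grey70")
  s <- val$comparison$snp[1L]
  qs <- stats::quantile(val$sim$beta[, s], probs = seq(0.01, 0.99, 0.01))
  qo <- stats::quantile(val$oracle$beta[, s], probs = seq(0.01, 0.99, 0.01),
                        na.rm = TRUE)
  graphics::plot(qs, qo, xlab = "simulated log OR quantiles",
                 ylab = "oracle log OR quantiles",
                 main = paste("QQ:", s))
  graphics::abline(0, 1, col = "red")
  invisible(path)
}
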