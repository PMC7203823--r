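#' Configuration for the Bayes B multiple-marker sampler
#'
#' Defaults follow the analysis the package reproduces: prior exclusion
#' probability `pi = 0.999` (so with ~10^5 markers about 100 carry an
#' effect per iteration), a chain of 550,000 with 150,000 burn-in and a
#' thinning lag of 100, prior means of 5.1 and 4.3 for the genomic and
#' residual variances, and prior degrees of freedom 4.2 for the
#' scaled-inverse-chi-square variance priors. Tests and desk-scale runs
#' pass a shorter chain explicitly.
#'
#' @param pi prior probability that a marker has no effect (default 0.999).
#' @param chain_length,burn_in,thin MCMC schedule (defaults 550000, 150000,
#'   100).
#' @param prior_mean_genomic_var prior mean total genomic variance
#'   (default 5.1, phenotype units squared).
#' @param prior_mean_resid_var prior mean residual variance (default 4.3).
#' @param prior_df degrees of freedom of both variance priors (default 4.2).
#' @param seed integer seed.
#' @return list of class `bayesb_config`.
#' @export
bayesb_config <- function(pi = 0.999, chain_length = 550000L,
                          burn_in = 150000L, thin = 100L,
                          prior_mean_genomic_var = 5.1,
                          prior_mean_resid_var = 4.3,
                          prior_df = 4.2, seed = 1L) {
  stopifnot(pi > 0, pi < 1, burn_in < chain_length, thin >= 1L,
            prior_mean_genomic_var > 0, prior_mean_resid_var > 0,
            prior_df > 2)
  structure(list(pi = pi, chain_length = as.integer(chain_length),
                 burn_in = as.integer(burn_in), thin = as.integer(thin),
                 prior_mean_genomic_var = prior_mean_genomic_var,
                 prior_mean_resid_var = prior_mean_resid_var,
                 prior_df = prior_df, seed = as.integer(seed)),
            class = "bayesb_config")
}

#' Bayes B multiple-marker regression
#'
#' Gibbs sampler over `y = 1 mu + sum_j Z_j delta_j beta_j + e` with
#' point-mass-at-zero mixture priors on marker effects. Dosages are
#' centered but not variance-standardized. The marker-variance prior scale
#' is solved from the prior mean genomic variance:
#' `E[sigma2_marker] = Vg / ((1 - pi) * sum_j 2 p_j (1 - p_j))`, so that the
#' expected number of segregating effects times their expected variance
#' contribution matches `Vg`. Per-marker posterior inclusion probabilities
#' are the fraction of saved samples in which the marker is in the model;
#' Bayes factors follow [bayes_factor()].
#'
#' @param pheno phenotype table (`doe_id`, `ve`) or a bare numeric vector
#'   ordered as the genotype rows.
#' @param gs imputed [genotype_set()].
#' @param cfg [bayesb_config()].
#' @param keep_samples keep the per-marker effect samples (needed for
#'   [window_variance()]; default TRUE).
#' @return list of class `bayesb_fit`: `result` (data.table snp, chrom, bp,
#'   p_hat, bf, post_mean_effect), `effect_samples` (m x n_saved matrix),
#'   `mu`, `sigma2e`, `cfg`, `snp_freq`.
#' @export
run_bayesb <- function(pheno, gs, cfg = bayesb_config(), keep_samples = TRUE) {
  stopifnot(inherits(gs, "genotype_set"), inherits(cfg, "bayesb_config"))
  if (is.numeric(pheno)) {
    y <- pheno
    if (length(y) != nrow(gs$dosage)) stop("phenotype length mismatch")
    dos <- gs$dosage
  } else {
    pheno <- data.table::as.data.table(pheno)
    idx <- match(pheno$doe_id, rownames(gs$dosage))
    if (anyNA(idx)) stop("phenotyped does missing from the genotype set")
    dos <- gs$dosage[idx, , drop = FALSE]
    y <- pheno$ve
  }
  if (anyNA(dos)) stop("genotypes must be imputed before Bayes B")
  if (length(y) < 30L) stop("Bayes B requires at least 30 individuals")

  p <- colMeans(dos) / 2
  sum2pq <- sum(2 * p * (1 - p))
  if (sum2pq <= 0) stop("all SNPs monomorphic")
  Z <- sweep(dos, 2L, 2 * p, "-")
  e_sigma2 <- cfg$prior_mean_genomic_var / ((1 - cfg$pi) * sum2pq)
  S2 <- e_sigma2 * (cfg$prior_df - 2) / cfg$prior_df
  S2e <- cfg$prior_mean_resid_var * (cfg$prior_df - 2) / cfg$prior_df

  set.seed(cfg$seed)
  mc <- bayesb_mcmc(Z, y, cfg$pi, cfg$chain_length, cfg$burn_in, cfg$thin,
                    cfg$prior_df, S2, cfg$prior_df, S2e, keep_samples)
  res <- data.table::data.table(snp = gs$map$snp_id, chrom = gs$map$chrom,
                                bp = gs$map$bp, p_hat = mc$p_hat,
                                bf = bayes_factor(mc$p_hat, cfg$pi),
                                post_mean_effect = mc$post_mean_effect)
  structure(list(result = res,
                 effect_samples = if (keep_samples) mc$effect_samples else NULL,
                 mu = mc$mu, sigma2e = mc$sigma2e, n_saved = mc$n_saved,
                 cfg = cfg, snp_freq = p, Z = Z),
            class = "bayesb_fit")
}

#' Bayes factor from a posterior inclusion probability
#'
#' `BF = (p_hat / (1 - p_hat)) / ((1 - pi) / pi)`: the posterior odds of a
#' marker having an effect divided by its prior odds. `p_hat = 1` returns
#' `Inf` (with a warning).
#'
#' @param p_hat posterior inclusion probability in `[0, 1]`.
#' @param pi prior exclusion probability.
#' @return numeric Bayes factor(s).
#' @export
bayes_factor <- function(p_hat, pi) {
  stopifnot(all(p_hat >= 0), all(p_hat <= 1), pi > 0, pi < 1)
  if (any(p_hat == 1)) warning("p_hat = 1: Bayes factor is infinite")
  (p_hat / (1 - p_hat)) / ((1 - pi) / pi)
}

#' Per-window share of the genomic variance
#'
#' Splits the genome into non-overlapping windows (default 1 Mb, anchored
#' at bp 1 of each chromosome) and, for every saved MCMC sample, computes
#' the variance across individuals of the window's genetic value
#' `u_w = sum_{j in w} Z_j delta_j beta_j` relative to the variance of the
#' total genomic value. `pct_genomic_var` is the posterior mean of that
#' ratio times 100 (raw ratios; they need not sum to 100 when windows
#' covary); `pct_normalized` rescales the raw column to sum to 100.
#'
#' @param fit `bayesb_fit` from [run_bayesb()] (run with
#'   `keep_samples = TRUE`).
#' @param gs the [genotype_set()] used in the fit.
#' @param window_bp window size (default 1e6).
#' @return `data.table`: chrom, window_start, window_end, n_snps,
#'   pct_genomic_var, pct_normalized.
#' @export
window_variance <- function(fit, gs, window_bp = 1000000L) {
  stopifnot(inherits(fit, "bayesb_fit"))
  if (is.null(fit$effect_samples) || nrow(fit$effect_samples) == 0L) {
    stop("run_bayesb must be called with keep_samples = TRUE")
  }
  B <- fit$effect_samples
  Z <- fit$Z
  stopifnot(ncol(Z) == nrow(B))
  win <- (gs$map$bp - 1L) %/% as.integer(window_bp)
  key <- paste(gs$map$chrom, win, sep = ":")
  ukey <- unique(key)
  Utot <- Z %*% B
  vtot <- colVarsC(Utot)
  nz <- vtot > 0
  pct <- numeric(length(ukey))
  nsnp <- integer(length(ukey))
  for (i in seq_along(ukey)) {
    jj <- which(key == ukey[i])
    nsnp[i] <- length(jj)
    Bw <- B[jj, , drop = FALSE]
    if (all(Bw == 0)) { pct[i] <- 0; next }
    Uw <- Z[, jj, drop = FALSE] %*% Bw
    vw <- colVarsC(Uw)
    ratio <- ifelse(nz, vw / pmax(vtot, .Machine$double.xmin), 0)
    pct[i] <- 100 * mean(ratio)
  }
  parts <- data.table::tstrsplit(ukey, ":", fixed = TRUE)
  out <- data.table::data.table(chrom = parts[[1]],
                                window_start = as.integer(parts[[2]]) * as.integer(window_bp) + 1L,
                                n_snps = nsnp,
                                pct_genomic_var = pct)
  # fill windows with no SNPs (0%) up to each chromosome's furthest marker
  grid <- data.table::as.data.table(gs$map)[, .(last = max((bp - 1L) %/% as.integer(window_bp))),
                                            by = chrom]
  grid <- grid[, .(window_start = (0:last) * as.integer(window_bp) + 1L), by = chrom]
  out <- merge(grid, out, by = c("chrom", "window_start"), all.x = TRUE)
  out[is.na(n_snps), `:=`(n_snps = 0L, pct_genomic_var = 0)]
  out[, window_end := window_start + as.integer(window_bp) - 1L]
  tot <- sum(out$pct_genomic_var)
  out[, pct_normalized := if (tot > 0) 100 * pct_genomic_var / tot else 0]
  data.table::setcolorder(out, c("chrom", "window_start", "window_end",
                                 "n_snps", "pct_genomic_var", "pct_normalized"))
  data.table::setorder(out, chrom, window_start)
  out[]
}

# column variances without building a full apply chain
colVarsC <- function(M) {
  n <- nrow(M)
  if (n < 2L) return(rep(0, ncol(M)))
  mu <- colMeans(M)
  (colSums(M^2) - n * mu^2) / (n - 1)
}

#' SNPs significant by Bayes factor
#'
#' Strict inequality: a SNP is retained only if `BF > bf_threshold`.
#'
#' @param result `bayesb_fit` or its `result` table.
#' @param bf_threshold Bayes-factor threshold (default 10).
#' @return `data.table` of significant SNPs.
#' @export
bmmr_significant <- function(result, bf_threshold = 10) {
  tab <- if (inherits(result, "bayesb_fit")) result$result else data.table::as.data.table(result)
  tab[bf > bf_threshold]
}
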