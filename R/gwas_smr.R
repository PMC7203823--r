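# Profile REML log-likelihood for y = Xb + g + e with g ~ N(0, sigma2_g G),
# parameterized by the variance ratio lambda = sigma2_g / sigma2_e, on the
# eigenbasis of G. yt = U'y, Xt = U'X, d = eigenvalues of G.
reml_profile <- function(log_lambda, yt, Xt, d) {
  lambda <- exp(log_lambda)
  delta <- lambda * d + 1
  w <- 1 / delta
  XtWX <- crossprod(Xt, Xt * w)
  XtWy <- crossprod(Xt, yt * w)
  beta <- solve(XtWX, XtWy)
  r <- yt - Xt %*% beta
  rss <- sum(w * r^2)
  n <- length(yt); p <- ncol(Xt)
  s2e <- rss / (n - p)
  ll <- -0.5 * ((n - p) * log(s2e) + sum(log(delta)) +
                  determinant(XtWX, logarithm = TRUE)$modulus + (n - p))
  list(ll = as.numeric(ll), s2e = s2e, lambda = lambda)
}

#' REML variance components under a genomic relationship matrix
#'
#' Fits `y = 1 mu + g + e`, `g ~ N(0, sigma2_g G)`, `e ~ N(0, sigma2_e I)`
#' by restricted maximum likelihood. The GRM is eigendecomposed once and
#' the REML log-likelihood is maximized over the variance ratio
#' `sigma2_g / sigma2_e` in one dimension. A ratio at the lower search
#' boundary is reported as `sigma2_g = 0` (`converged = FALSE`). When the
#' GRM is (numerically) the identity the two components are not separately
#' identifiable; the total variance is split evenly and flagged.
#'
#' @param y numeric phenotype vector.
#' @param grm [compute_grm()] result or plain symmetric matrix.
#' @param X fixed-effect design matrix (default intercept only).
#' @return list: `sigma2_g`, `sigma2_e`, `lambda`, `loglik`, `converged`,
#'   `unidentifiable`, and the eigendecomposition (`U`, `d`) for reuse.
#' @export
estimate_variance_components <- function(y, grm, X = NULL) {
  G <- if (inherits(grm, "grm")) grm$G else grm
  n <- length(y)
  stopifnot(is.matrix(G), nrow(G) == n)
  if (is.null(X)) X <- matrix(1, n, 1)
  if (max(abs(G - diag(n))) < 1e-10) {
    vt <- stats::var(y)
    return(list(sigma2_g = vt / 2, sigma2_e = vt / 2, lambda = 1,
                loglik = NA_real_, converged = FALSE, unidentifiable = TRUE,
                U = diag(n), d = rep(1, n)))
  }
  ev <- eigen(G, symmetric = TRUE)
  d <- pmax(ev$values, 0)
  yt <- crossprod(ev$vectors, y)
  Xt <- crossprod(ev$vectors, X)
  lo <- -12; hi <- 12
  opt <- stats::optimize(function(l) reml_profile(l, yt, Xt, d)$ll,
                         c(lo, hi), maximum = TRUE, tol = 1e-8)
  at_lo <- opt$maximum < lo + 0.05
  fit <- reml_profile(opt$maximum, yt, Xt, d)
  s2e <- fit$s2e
  s2g <- fit$lambda * s2e
  if (at_lo) { # boundary: effectively no genomic variance
    s2g <- 0
    s2e <- stats::var(y) * (n - 1) / (n - ncol(X))
  }
  list(sigma2_g = s2g, sigma2_e = s2e, lambda = fit$lambda,
       loglik = fit$ll, converged = !at_lo, unidentifiable = FALSE,
       U = ev$vectors, d = d)
}

# Whitened score test of each column of Z against y given V = s2g G + s2e I.
# Returns beta, se, p per column. U, d: eigen of G; whitening scale
# 1/sqrt(s2g d + s2e). SEs take the plugged-in variance components as known
# (Wald chi-square with 1 df), the convention of mixed-model GWAS software.
whitened_score <- function(y, Z, U, d, s2g, s2e) {
  s <- 1 / sqrt(s2g * d + s2e)
  yt <- s * crossprod(U, y)
  x0 <- s * colSums(U)              # U' 1
  Zt <- s * crossprod(U, Z)
  yr <- yt - x0 * sum(x0 * yt) / sum(x0^2)
  num <- drop(crossprod(Zt, yr))
  b0 <- drop(crossprod(Zt, x0)) / sum(x0^2)
  zz <- colSums(Zt^2) - b0^2 * sum(x0^2)   # ||z residualized on intercept||^2
  beta <- num / zz
  se <- 1 / sqrt(zz)
  chi <- beta^2 * zz
  p <- pchisq(chi, 1L, lower.tail = FALSE)
  data.table::data.table(beta = beta, se = se, p = p)
}

#' Mixed-model association with a leave-one-chromosome-out GRM
#'
#' For each chromosome the GRM is rebuilt without that chromosome's SNPs,
#' variance components are estimated once by REML under the no-SNP null,
#' and every SNP on the chromosome is then tested by generalized least
#' squares of the V_E phenotype on (intercept, dosage) with covariance
#' `sigma2_g G_loco + sigma2_e I` (Wald chi-square p-values). Monomorphic
#' SNPs are reported with `beta = 0`, `p = 1` and flagged.
#'
#' @param pheno phenotype table from [build_doe_phenotypes()] (columns
#'   `doe_id`, `ve`), or any table with those columns.
#' @param gs imputed [genotype_set()]; rownames of the dosage matrix must
#'   match `pheno$doe_id`.
#' @return `data.table`: snp, chrom, bp, beta, se, p, method, flag.
#' @export
mlma_loco <- function(pheno, gs) {
  stopifnot(inherits(gs, "genotype_set"))
  pheno <- data.table::as.data.table(pheno)
  idx <- match(pheno$doe_id, rownames(gs$dosage))
  if (anyNA(idx)) stop("phenotyped does missing from the genotype set")
  dos <- gs$dosage[idx, , drop = FALSE]
  if (anyNA(dos)) stop("genotypes must be imputed before association")
  y <- pheno$ve
  chroms <- unique(gs$map$chrom)
  if (length(chroms) < 2L) {
    stop("LOCO needs at least 2 chromosomes; got ", length(chroms))
  }
  gs_sub <- genotype_set(dos, gs$map, gs$populations[idx])
  out <- vector("list", length(chroms))
  for (i in seq_along(chroms)) {
    cc <- chroms[i]
    grm <- compute_grm(gs_sub, exclude_chrom = cc)
    vc <- estimate_variance_components(y, grm)
    cols <- which(gs$map$chrom == cc)
    Z <- dos[, cols, drop = FALSE]
    p <- colMeans(Z) / 2
    poly <- p > 0 & p < 1
    res <- data.table::data.table(snp = gs$map$snp_id[cols],
                                  chrom = cc, bp = gs$map$bp[cols],
                                  beta = 0, se = NA_real_, p = 1,
                                  flag = ifelse(poly, "", "monomorphic"))
    if (any(poly)) {
      st <- whitened_score(y, Z[, poly, drop = FALSE], vc$U, vc$d,
                           vc$sigma2_g, vc$sigma2_e)
      res[which(poly), `:=`(beta = st$beta, se = st$se, p = st$p)]
    }
    res[, `:=`(sigma2_g = vc$sigma2_g, sigma2_e = vc$sigma2_e)]
    out[[i]] <- res
  }
  res <- data.table::rbindlist(out)
  res[, method := "mlma_loco"]
  data.table::setcolorder(res, c("snp", "chrom", "bp", "beta", "se", "p",
                                 "method", "flag"))
  res[]
}

#' Weighted single-marker regression with principal-component covariates
#'
#' Weighted least squares of the V_E phenotype on (intercept, dosage,
#' PC1..PCk) with per-doe precision weights `w = (n+1)^2 / (2(n-1))`
#' (residual variance proportional to `1/w`). Reported p-values are Wald
#' chi-square. Scaling all weights by a constant leaves beta, SE and p
#' unchanged.
#'
#' @param pheno phenotype table (`doe_id`, `ve`, `weight`).
#' @param gs imputed [genotype_set()] aligned as in [mlma_loco()].
#' @param pcs matrix of principal components from [compute_pcs()] (default
#'   5 columns used).
#' @param weights optional weight vector overriding `pheno$weight`.
#' @return `data.table`: snp, chrom, bp, beta, se, p, method, flag.
#' @export
weighted_smr <- function(pheno, gs, pcs, weights = NULL) {
  stopifnot(inherits(gs, "genotype_set"))
  pheno <- data.table::as.data.table(pheno)
  idx <- match(pheno$doe_id, rownames(gs$dosage))
  if (anyNA(idx)) stop("phenotyped does missing from the genotype set")
  dos <- gs$dosage[idx, , drop = FALSE]
  if (anyNA(dos)) stop("genotypes must be imputed before association")
  w <- if (is.null(weights)) pheno$weight else weights
  if (any(w <= 0)) stop("weights must be positive")
  y <- pheno$ve
  n <- length(y)
  X0 <- cbind(intercept = 1, pcs[idx, , drop = FALSE])
  sw <- sqrt(w)
  ys <- sw * y
  X0s <- sw * X0
  Q <- qr.Q(qr(X0s))
  yr <- ys - Q %*% crossprod(Q, ys)
  p_ <- colMeans(dos) / 2
  poly <- p_ > 0 & p_ < 1
  res <- data.table::data.table(snp = gs$map$snp_id, chrom = gs$map$chrom,
                                bp = gs$map$bp, beta = 0, se = NA_real_, p = 1,
                                flag = ifelse(poly, "", "monomorphic"))
  if (any(poly)) {
    Zs <- sw * dos[, poly, drop = FALSE]
    Zr <- Zs - Q %*% crossprod(Q, Zs)
    zz <- colSums(Zr^2)
    bhat <- drop(crossprod(Zr, yr)) / zz
    # residual variance re-estimated per SNP (df = n - p0 - 1)
    rss <- sum(yr^2) - bhat^2 * zz
    s2 <- rss / (n - ncol(X0) - 1L)
    sehat <- sqrt(s2 / zz)
    pval <- pchisq(bhat^2 / sehat^2, 1L, lower.tail = FALSE)
    data.table::set(res, which(poly), c("beta", "se", "p"),
                    list(bhat, sehat, pval))
  }
  res[, method := "weighted_pc"]
  res[]
}

#' Tier SNPs by single-marker p-value
#'
#' `strict` for `p < threshold`; `near` for `threshold <= p < relaxed`
#' (candidates that are only retained downstream if their Bayes factor also
#' exceeds the multiple-marker threshold); everything else is dropped.
#'
#' @param results association table with columns `snp`, `p`.
#' @param threshold strict significance threshold (default 1e-4).
#' @param relaxed upper bound of the near-significant tier (default 2e-4).
#' @return `data.table` of significant SNPs with a `tier` column.
#' @export
smr_significant <- function(results, threshold = 1e-4, relaxed = 2e-4) {
  results <- data.table::as.data.table(results)
  out <- results[p < relaxed]
  out[, tier := ifelse(p < threshold, "strict", "near")]
  out[]
}
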