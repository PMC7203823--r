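# Build a small phenotype/genotype pair with a polygenic signal so the GRM
# carries real structure.
make_mixed_fixture <- function(n = 60, m = 80, h2 = 0.5, seed = 1) {
  set.seed(seed)
  dos <- rand_dos(n, m, seed = seed, maf = 0.3)
  chrom <- rep(c("1", "2"), each = m / 2)
  gs <- toy_gs(dos, chrom = chrom, bp = rep(seq_len(m / 2) * 1000L, 2L))
  grm <- compute_grm(gs)
  L <- t(chol(grm$G + diag(1e-6, n)))
  g <- sqrt(h2) * (L %*% rnorm(n))
  y <- drop(g) + rnorm(n, sd = sqrt(1 - h2))
  list(gs = gs, grm = grm, y = y)
}

test_that("REML recovers a zero genomic variance under the null", {
  # family-structured genomes (30 families of 10 close relatives): the GRM
  # must carry real structure for the null fit to pin sigma2_g near zero
  fam_dos <- function(n_fam, sibs, m, seed, refresh = 0.05) {
    set.seed(seed)
    founders <- matrix(rbinom(n_fam * m, 2L, 0.4), n_fam, m)
    do.call(rbind, lapply(seq_len(n_fam), function(f) {
      t(vapply(seq_len(sibs), function(s) {
        x <- founders[f, ]
        k <- which(runif(m) < refresh)
        x[k] <- rbinom(length(k), 2L, 0.4)
        x
      }, numeric(m)))
    }))
  }
  hits <- 0L
  for (r in 1:50) {
    dos <- fam_dos(30L, 10L, 200L, seed = 100 + r)
    storage.mode(dos) <- "double"
    grm <- compute_grm(toy_gs(dos))
    set.seed(1000 + r)
    y <- rnorm(nrow(dos))               # pure noise: sigma2_g = 0
    vc <- estimate_variance_components(y, grm)
    if (vc$sigma2_g < 0.05 * (vc$sigma2_g + vc$sigma2_e)) hits <- hits + 1L
  }
  expect_gte(hits, 45L)                 # >= 90% of 50 replicates
})

test_that("REML optimum beats a grid of random variance ratios", {
  fx <- make_mixed_fixture(seed = 2)
  vc <- estimate_variance_components(fx$y, fx$grm)
  expect_true(vc$converged)
  ev <- eigen(fx$grm$G, symmetric = TRUE)
  yt <- crossprod(ev$vectors, fx$y)
  Xt <- crossprod(ev$vectors, matrix(1, length(fx$y), 1))
  ll_at <- function(l) veqtl:::reml_profile(l, yt, Xt, pmax(ev$values, 0))$ll
  set.seed(3)
  for (l in runif(20, -8, 8)) expect_gte(vc$loglik + 1e-6, ll_at(l))
})

test_that("identity GRM is flagged unidentifiable", {
  y <- rnorm(30)
  vc <- estimate_variance_components(y, diag(30))
  expect_true(vc$unidentifiable)
  expect_equal(vc$sigma2_g + vc$sigma2_e, var(y))
})

test_that("GLS with sigma2_g = 0 reproduces OLS estimates", {
  set.seed(4)
  n <- 40
  dos <- rand_dos(n, 20, seed = 5, maf = 0.4)
  y <- rnorm(n)
  # whitened score with identity kernel and unit residual variance
  st <- veqtl:::whitened_score(y, dos, diag(n), rep(1, n), 0, 1)
  for (j in c(1, 7, 15)) {
    ols <- lm(y ~ dos[, j])
    expect_equal(st$beta[j], unname(coef(ols)[2]), tolerance = 1e-10)
  }
})

test_that("mlma_loco beta equals brute-force GLS by explicit covariance inversion", {
  w <- sim_world(seed = 42, n_base = 10, n_high = 10, n_low = 10,
                 n_chrom = 2, snps_per_chrom = 15, causal = NULL,
                 missing_rate = 0)
  res <- mlma_loco(w$pheno, w$gs)
  y <- w$pheno$ve
  dos <- w$gs$dosage[w$pheno$doe_id, ]
  n <- length(y)
  for (cc in c("1", "2")) {
    grm <- compute_grm(genotype_set(dos, w$gs$map, "all"), exclude_chrom = cc)
    vc <- res[chrom == cc][1]
    V <- vc$sigma2_g * grm$G + vc$sigma2_e * diag(n)
    Vi <- solve(V)
    snp <- res[chrom == cc & flag == ""][1]
    X <- cbind(1, dos[, snp$snp])
    beta_gls <- solve(t(X) %*% Vi %*% X, t(X) %*% Vi %*% y)
    se_gls <- sqrt(solve(t(X) %*% Vi %*% X)[2, 2])
    expect_equal(snp$beta, beta_gls[2], tolerance = 1e-8, ignore_attr = TRUE)
    expect_equal(snp$se, se_gls, tolerance = 1e-8)
  }
})

test_that("monomorphic SNPs are reported flagged with p = 1", {
  w <- sim_world(seed = 6, n_base = 15, n_high = 15, n_low = 15,
                 n_chrom = 2, snps_per_chrom = 10, causal = NULL)
  gs <- w$gs
  gs$dosage[, 3] <- 2
  res <- mlma_loco(w$pheno, gs)
  mono <- res[snp == gs$map$snp_id[3]]
  expect_equal(mono$flag, "monomorphic")
  expect_equal(mono$p, 1)
  expect_equal(mono$beta, 0)
})

test_that("null p-values are calibrated and uniform", {
  # linkage-equilibrium panel: KS assumes independent p-values
  w <- null_world(seed = 8, n_base = 100, n_high = 100, n_low = 100,
                  n_chrom = 5, snps_per_chrom = 80, copy_prob = 0,
                  missing_rate = 0)
  res <- mlma_loco(w$pheno, w$gs)
  p <- res[flag == "", p]
  expect_gt(length(p), 300)
  frac <- mean(p < 0.05)
  expect_gt(frac, 0.03); expect_lt(frac, 0.07)
  ks <- suppressWarnings(stats::ks.test(p, "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("weighted_smr matches hand-solved weighted normal equations", {
  # 6 observations, 1 PC column, hand-checkable via solve()
  y <- c(2.0, 1.5, 3.0, 2.5, 4.0, 3.5)
  z <- c(0, 1, 2, 0, 1, 2)
  pc <- matrix(c(0.1, -0.2, 0.3, 0.0, 0.2, -0.1), ncol = 1,
               dimnames = list(NULL, "PC1"))
  w <- c(4.5, 4.0, 4.5, 4.8, 5.0, 4.2)
  dos <- matrix(z, 6, 1, dimnames = list(sprintf("d%d", 1:6), "s01"))
  gs <- genotype_set(dos, data.table::data.table(snp_id = "s01", chrom = "1", bp = 100L))
  rownames(pc) <- rownames(dos)
  ph <- data.table::data.table(doe_id = sprintf("d%d", 1:6), ve = y, weight = w)
  res <- weighted_smr(ph, gs, pc)
  X <- cbind(1, z, pc)
  Wm <- diag(w)
  beta_hand <- solve(t(X) %*% Wm %*% X, t(X) %*% Wm %*% y)
  r <- y - X %*% beta_hand
  s2 <- sum(w * r^2) / (6 - 3)
  se_hand <- sqrt(s2 * solve(t(X) %*% Wm %*% X)[2, 2])
  expect_equal(res$beta, beta_hand[2], tolerance = 1e-10, ignore_attr = TRUE)
  expect_equal(res$se, se_hand, tolerance = 1e-10)

  # scale invariance of WLS: doubling weights changes nothing
  res2 <- weighted_smr(ph, gs, pc, weights = 2 * w)
  expect_equal(res2$beta, res$beta, tolerance = 1e-12)
  expect_equal(res2$se, res$se, tolerance = 1e-12)
  expect_equal(res2$p, res$p, tolerance = 1e-12)
  expect_error(weighted_smr(ph, gs, pc, weights = rep(0, 6)), "positive")
})

test_that("equal weights reproduce the unweighted PC regression ranking", {
  w <- null_world(seed = 10, n_base = 30, n_high = 30, n_low = 30,
                  n_chrom = 2, snps_per_chrom = 25, missing_rate = 0)
  pcs <- compute_pcs(compute_grm(w$gs), k = 5)
  ph <- data.table::copy(w$pheno)[, weight := 1]
  res_w <- weighted_smr(ph, w$gs, pcs)
  # unweighted reference via lm per SNP
  dos <- w$gs$dosage[ph$doe_id, ]
  p_ref <- vapply(seq_len(ncol(dos)), function(j) {
    fit <- summary(lm(ph$ve ~ dos[, j] + pcs[ph$doe_id, ]))
    fit$coefficients[2, 4]
  }, numeric(1))
  expect_equal(order(res_w$p), order(p_ref))
})

test_that("smr_significant tiers follow the strict and near thresholds", {
  res <- data.table::data.table(snp = c("a", "b", "c", "d"),
                                p = c(9e-5, 1.8e-4, 5e-4, 1e-4))
  out <- smr_significant(res)
  expect_equal(out[snp == "a", tier], "strict")
  expect_equal(out[snp == "b", tier], "near")
  expect_equal(out[snp == "d", tier], "near")  # boundary: p == threshold
  expect_false("c" %in% out$snp)
})

test_that("a strong planted vQTL is detected at p < 1e-4", {
  w <- sim_world(seed = 12, n_base = 100, n_high = 100, n_low = 100,
                 n_chrom = 3, snps_per_chrom = 40, missing_rate = 0,
                 causal = data.frame(chrom = "2", bp = 2000001,
                                     effect = log(2), divergence = 0))
  res <- mlma_loco(w$pheno, w$gs)
  causal_id <- w$truth$causal_vqtl_snps
  expect_lt(res[snp == causal_id, p], 1e-4)
})
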