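test_that("simulate_genotypes is deterministic and respects divergence settings", {
  cfg <- sim_config(n_base = 30, n_high = 30, n_low = 30, n_chrom = 2,
                    snps_per_chrom = 50, causal_vqtl = NULL, seed = 99)
  a <- simulate_genotypes(cfg)
  b <- simulate_genotypes(cfg)
  expect_identical(a$genotypes$dosage, b$genotypes$dosage)
  expect_identical(a$truth, b$truth)

  # no divergence anywhere: mean per-line frequency difference ~ 0
  gs <- a$genotypes
  fh <- colMeans(gs$dosage[gs$populations == "high", ], na.rm = TRUE) / 2
  fl <- colMeans(gs$dosage[gs$populations == "low", ], na.rm = TRUE) / 2
  expect_lt(abs(mean(fh - fl)), 0.02)

  # configured divergence is realized at the causal SNP
  cfg2 <- sim_config(n_base = 0, n_high = 400, n_low = 400, n_chrom = 2,
                     snps_per_chrom = 50,
                     causal_vqtl = data.frame(chrom = "1", bp = 2000001,
                                              effect = log(2), divergence = 0.4),
                     missing_rate = 0, seed = 100)
  s2 <- simulate_genotypes(cfg2)
  k <- match(s2$truth$causal_vqtl_snps, s2$genotypes$map$snp_id)
  gh <- mean(s2$genotypes$dosage[s2$genotypes$populations == "high", k]) / 2
  gl <- mean(s2$genotypes$dosage[s2$genotypes$populations == "low", k]) / 2
  expect_equal(gh - gl, 0.4, tolerance = 0.08)
})

test_that("copy probability 1 gives complete LD within a chromosome", {
  cfg <- sim_config(n_base = 60, n_high = 0, n_low = 0, n_chrom = 2,
                    snps_per_chrom = 20, copy_prob = 1, causal_vqtl = NULL,
                    missing_rate = 0, seed = 5)
  gs <- simulate_genotypes(cfg)$genotypes
  for (cc in c("1", "2")) {
    Z <- gs$dosage[, gs$map$chrom == cc, drop = FALSE]
    Z <- Z[, apply(Z, 2, stats::var) > 0, drop = FALSE]
    r2 <- stats::cor(Z)^2   # brute-force r2 on the emitted matrix
    expect_equal(max(abs(r2 - 1)), 0, tolerance = 1e-12)
  }
})

test_that("simulate_litters implements the variance model", {
  # closed form: a doe homozygous alt at a vQTL with v = log(2) has its
  # residual variance multiplied by 4 relative to homozygous ref
  cfg <- sim_config(n_base = 2000, n_high = 0, n_low = 0, n_chrom = 2,
                    snps_per_chrom = 10, parity_range = c(6L, 6L),
                    causal_vqtl = data.frame(chrom = "1", bp = 500001,
                                             effect = log(2), divergence = 0),
                    missing_rate = 0, seed = 21)
  sim <- simulate_genotypes(cfg)
  lt <- simulate_litters(cfg, sim$genotypes)
  tr <- attr(lt, "truth")
  k <- match(sim$truth$causal_vqtl_snps, sim$genotypes$map$snp_id)
  g <- sim$genotypes$dosage[, k]
  expect_equal(unique(tr$true_resvar[g == 0]), exp(cfg$base_log_resvar))
  expect_equal(unique(tr$true_resvar[g == 2]) / unique(tr$true_resvar[g == 0]), 4)
  # realized residual spread follows: empirical var of e for g=2 vs g=0
  v0 <- stats::var(tr$e[tr$doe_index %in% which(g == 0)])
  v2 <- stats::var(tr$e[tr$doe_index %in% which(g == 2)])
  expect_equal(v2 / v0, 4, tolerance = 0.25)

  # parity bounds
  cfg2 <- sim_config(n_base = 200, n_high = 0, n_low = 0, n_chrom = 2,
                     snps_per_chrom = 10, causal_vqtl = NULL, seed = 22)
  lt2 <- simulate_litters(cfg2, simulate_genotypes(cfg2)$genotypes)
  np <- lt2[, .N, by = doe_id]$N
  expect_true(all(np >= 2L & np <= 12L))
  expect_true(all(lt2$tnb >= 0L))
})

test_that("residual variance calibrates to exp(base_log_resvar) under the null", {
  cfg <- sim_config(n_base = 1200, n_high = 0, n_low = 0, n_chrom = 2,
                    snps_per_chrom = 10, causal_vqtl = NULL,
                    base_log_resvar = log(4), seed = 23)
  lt <- simulate_litters(cfg, simulate_genotypes(cfg)$genotypes)
  tr <- attr(lt, "truth")
  within_doe_var <- vapply(split(tr$e, tr$doe_index), stats::var, numeric(1))
  n_par <- lengths(split(tr$e, tr$doe_index))
  expect_gt(length(within_doe_var), 1000)
  expect_equal(mean(within_doe_var[n_par >= 2]), 4, tolerance = 0.05 * 4)
})

test_that("simulate_pooled_vcf realizes designated classes, fates and ANN terms", {
  cfg <- sim_config(seed = 31)
  genes <- simulate_genes(cfg)
  sites <- default_vcf_sites(cfg, genes)
  path <- file.path(withr::local_tempdir(), "pools.vcf")
  out <- simulate_pooled_vcf(sites, path, seed = 31)
  tr <- out$truth
  # absent -> alt depth 0; fixed -> ref depth 0 (construction)
  expect_true(all(tr[low_class == "absent", low_alt_d] == 0L))
  expect_true(all(tr[low_class == "fixed", low_ref_d] == 0L))
  expect_true(all(tr[high_class == "absent", high_alt_d] == 0L))
  expect_true(all(tr[high_class == "segregating", high_alt_d] > 0L &
                    tr[high_class == "segregating", high_ref_d] > 0L))
  # QD-failing site emits QD < 2
  lines <- readLines(path)
  body <- lines[!startsWith(lines, "#")]
  qd <- as.numeric(sub(".*QD=([0-9.]+);.*", "\\1", body))
  expect_true(all(qd[tr$filter_fate == "QD"] < 2))
  expect_true(all(qd[tr$filter_fate != "QD"] >= 2))
  # designated relevant-consequence count matches the ANN terms emitted
  n_rel <- sum(grepl("missense_variant|frameshift_variant|UTR_variant|splice",
                     body))
  rel_classes <- c("missense_variant", "frameshift_variant", "5_prime_UTR_variant",
                   "3_prime_UTR_variant", "splice_region_variant",
                   "splice_donor_variant", "splice_acceptor_variant")
  expect_equal(n_rel, sum(tr$consequence %in% rel_classes))
  # byte-identical under the same seed
  path2 <- file.path(withr::local_tempdir(), "pools2.vcf")
  simulate_pooled_vcf(sites, path2, seed = 31)
  expect_identical(readLines(path), readLines(path2))
  # vocabulary enforcement
  bad <- data.table::copy(sites)[1, consequence := "nonsense_term"]
  expect_error(simulate_pooled_vcf(bad, tempfile()), "unknown consequence")
})

test_that("gene grid is deterministic and non-overlapping", {
  cfg <- sim_config(seed = 7)
  g1 <- simulate_genes(cfg)
  g2 <- simulate_genes(cfg)
  expect_identical(g1, g2)
  by_chr <- split(g1, g1$chrom)
  for (gc in by_chr) {
    o <- order(gc$start)
    expect_true(all(gc$start[o][-1L] > gc$end[o][-nrow(gc)]))
  }
})
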