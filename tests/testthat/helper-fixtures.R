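# shared fixture builders; everything is generated in code at test time
options(veqtl.quiet = TRUE)

# small litter table with explicit factor structure
toy_litters <- function() {
  data.table::data.table(
    doe_id = rep(c("d1", "d2", "d3"), each = 3L),
    parity = rep(1:3, 3L),
    tnb = c(6L, 8L, 10L, 7L, 7L, 7L, 4L, 9L, 8L),
    yearseason = 1L, paritylact = 1L,
    population = "base")
}

# genotype set from an explicit dosage matrix (one chromosome by default)
toy_gs <- function(dos, chrom = NULL, bp = NULL, pops = "all") {
  m <- ncol(dos)
  if (is.null(chrom)) chrom <- rep("1", m)
  if (is.null(bp)) bp <- seq_len(m) * 1000L
  colnames(dos) <- sprintf("s%02d", seq_len(m))
  genotype_set(dos, data.table::data.table(snp_id = colnames(dos),
                                           chrom = chrom, bp = bp), pops)
}

# deterministic random dosage matrix
rand_dos <- function(n, m, seed = 1, maf = 0.5, missing = 0) {
  set.seed(seed)
  d <- matrix(stats::rbinom(n * m, 2L, maf), n, m)
  if (missing > 0) d[matrix(stats::runif(n * m) < missing, n, m)] <- NA_real_
  storage.mode(d) <- "double"
  d
}

# desk-scale simulated world: genotypes + phenotypes aligned, imputed
sim_world <- function(seed = 1, n_base = 40, n_high = 60, n_low = 60,
                      n_chrom = 4, snps_per_chrom = 60,
                      causal = data.frame(chrom = "1", bp = 3000001,
                                          effect = log(2), divergence = 0.3),
                      ...) {
  cfg <- sim_config(n_base = n_base, n_high = n_high, n_low = n_low,
                    n_chrom = n_chrom, snps_per_chrom = snps_per_chrom,
                    causal_vqtl = causal, seed = seed, ...)
  sim <- simulate_genotypes(cfg)
  gs <- impute_missing(sim$genotypes, seed = seed)
  lt <- simulate_litters(cfg, sim$genotypes)
  ph <- build_doe_phenotypes(lt)
  list(cfg = cfg, gs = gs, pheno = ph, truth = sim$truth,
       litter_truth = attr(lt, "truth"), litters = lt)
}

# null world: no variance QTL anywhere
null_world <- function(seed = 1, ...) {
  sim_world(seed = seed, causal = NULL, ...)
}
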