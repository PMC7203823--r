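test_that("group_snps clusters by the 0.5-Mb single-linkage rule", {
  v <- data.table::data.table(snp = c("a", "b", "c"), chrom = "3",
                              bp = c(1000000L, 1300000L, 2500000L))
  b <- group_snps(v)
  expect_equal(nrow(b), 2L)
  expect_equal(sort(b$snps[[1]]), c("a", "b"))
  expect_equal(b$snps[[2]], "c")
  # singleton
  b1 <- group_snps(v[1])
  expect_equal(nrow(b1), 1L)
  # different chromosomes never share a block
  v2 <- data.table::data.table(snp = c("a", "b"), chrom = c("1", "2"),
                               bp = c(100L, 200L))
  expect_equal(nrow(group_snps(v2)), 2L)
})

test_that("expand_blocks pads by 1 Mb with a floor at 1 bp", {
  b <- group_snps(data.table::data.table(snp = "a", chrom = "5", bp = 50400000L))
  e <- expand_blocks(b)
  expect_equal(e$interval_start, 49400000)
  expect_equal(e$interval_end, 51400000)
  b2 <- group_snps(data.table::data.table(snp = "a", chrom = "5", bp = 300000L))
  expect_equal(expand_blocks(b2)$interval_start, 1)
  # two blocks with overlapping padded intervals stay distinct
  v <- data.table::data.table(snp = c("a", "b"), chrom = "1",
                              bp = c(1000000L, 2000000L))
  expect_equal(nrow(expand_blocks(group_snps(v))), 2L)
})

test_that("ld_r2 equals brute-force squared Pearson correlation", {
  dos <- cbind(a = c(0, 1, 2, 0), b = c(0, 1, 2, 2))
  storage.mode(dos) <- "double"
  rownames(dos) <- sprintf("i%d", 1:4)
  gs <- genotype_set(dos, data.table::data.table(snp_id = c("a", "b"),
                                                 chrom = "1", bp = c(100L, 200L)))
  ld <- ld_r2(gs, "1", 1, 1000)
  expect_equal(ld$r2["a", "b"], 0.20661157, tolerance = 1e-6)
  expect_equal(diag(ld$r2), c(a = 1, b = 1))

  # random pairs against a two-pass correlation oracle
  dos2 <- rand_dos(40, 50, seed = 29, maf = 0.4)
  gs2 <- toy_gs(dos2)
  ld2 <- ld_r2(gs2, "1", 1, 1e6)
  two_pass_r2 <- function(x, y) {
    mx <- sum(x) / length(x); my <- sum(y) / length(y)
    num <- sum((x - mx) * (y - my))
    (num / sqrt(sum((x - mx)^2) * sum((y - my)^2)))^2
  }
  set.seed(30)
  for (k in 1:50) {
    ij <- sample(ncol(dos2), 2L)
    expect_equal(ld2$r2[ij[1], ij[2]],
                 two_pass_r2(dos2[, ij[1]], dos2[, ij[2]]), tolerance = 1e-10)
  }
  # duplicated column -> r2 = 1; monomorphic excluded with warning
  dos3 <- cbind(dos2[, 1:3], dos2[, 1], rep(1, 40))  # col 4 dup, col 5 mono
  gs3 <- toy_gs(dos3)
  expect_warning(ld3 <- ld_r2(gs3, "1", 1, 1e6), "monomorphic")
  expect_equal(ncol(ld3$r2), 4L)                     # monomorphic excluded
  expect_equal(unname(ld3$r2[1, 4]), 1)              # duplicated column
})

# hand-built genotype set with a controlled r2 structure:
# 3 significant SNP scenarios across chained/isolated LD
chain_fixture <- function() {
  set.seed(41)
  n <- 200
  a <- rbinom(n, 2, 0.5)
  flip <- function(x, k) { i <- sample(n, k); x[i] <- rbinom(k, 2, 0.5); x }
  b <- flip(a, 25)     # r2(a,b) high
  c_ <- flip(b, 25)    # r2(b,c) high, r2(a,c) lower
  d <- rbinom(n, 2, 0.5)  # independent
  dos <- cbind(a = a, b = b, c = c_, d = d)
  storage.mode(dos) <- "double"
  rownames(dos) <- sprintf("i%03d", 1:n)
  genotype_set(dos, data.table::data.table(snp_id = c("a", "b", "c", "d"),
                                           chrom = "1",
                                           bp = c(100000L, 200000L, 300000L, 400000L)))
}

test_that("define_vqtl_regions follows the connected-component rule", {
  gs <- chain_fixture()
  ld <- ld_r2(gs, "1", 1, 1e6)
  # verify the fixture geometry before using it
  expect_gt(ld$r2["a", "b"], 0.7)
  expect_gt(ld$r2["b", "c"], 0.7)
  expect_lt(ld$r2["a", "c"], 0.7)
  expect_lt(ld$r2["a", "d"], 0.7)

  blocks <- expand_blocks(group_snps(
    data.table::data.table(snp = "a", chrom = "1", bp = 100000L)))
  reg <- define_vqtl_regions(blocks, gs)
  # chain a-b, b-c pulls c in despite r2(a,c) < 0.7; d stays out
  expect_setequal(reg$snps[[1]], c("a", "b", "c"))
  expect_equal(reg$start, 100000L)
  expect_equal(reg$end, 300000L)

  # clique mode only keeps SNPs tied directly to the significant SNP
  reg_cl <- define_vqtl_regions(blocks, gs, mode = "clique")
  expect_setequal(reg_cl$snps[[1]], c("a", "b"))

  # a significant SNP with no strong partner yields a point region
  blocks_d <- expand_blocks(group_snps(
    data.table::data.table(snp = "d", chrom = "1", bp = 400000L)))
  reg_d <- define_vqtl_regions(blocks_d, gs)
  expect_equal(reg_d$start, reg_d$end)
  expect_equal(reg_d$snps[[1]], "d")
  expect_equal(reg_d$anchor_snp, "d")
})

test_that("raising the r2 threshold never enlarges a region", {
  w <- sim_world(seed = 33, n_base = 60, n_high = 60, n_low = 60,
                 n_chrom = 2, snps_per_chrom = 40, copy_prob = 0.95,
                 missing_rate = 0)
  sig <- data.table::data.table(snp = w$truth$causal_vqtl_snps,
                                chrom = "1", bp = 3000001L)
  blocks <- expand_blocks(group_snps(sig))
  widths <- vapply(c(0.5, 0.7, 0.9), function(t) {
    r <- define_vqtl_regions(blocks, w$gs, r2_threshold = t)
    r$end - r$start
  }, numeric(1))
  expect_true(all(diff(widths) <= 0))
})

test_that("a planted LD block is recovered within one marker spacing", {
  # block = SNPs 20..30 on chromosome 1 (copying forced off at the edges
  # via drift SNPs drawn fresh), near-complete LD inside
  hits <- 0L
  for (r in 1:10) {
    cfg <- sim_config(n_base = 150, n_high = 0, n_low = 0, n_chrom = 2,
                      snps_per_chrom = 40, copy_prob = 0.97,
                      causal_vqtl = NULL,
                      drift_snps = data.frame(chrom = "1",
                                              bp = c(1900001L, 3000001L),
                                              divergence = 0),
                      missing_rate = 0, seed = 500 + r)
    gs <- simulate_genotypes(cfg)$genotypes
    # planted block: fresh draws at SNP indices 20 and 31 cut LD there
    sig <- data.table::data.table(snp = "snp_1_25", chrom = "1", bp = 2400001L)
    blocks <- expand_blocks(group_snps(sig))
    reg <- define_vqtl_regions(blocks, gs, r2_threshold = 0.7)
    # true block spans SNPs 20..30 -> bp 1900001..2900001
    ok_start <- abs(reg$start - 1900001) <= cfg$marker_spacing_bp
    ok_end <- abs(reg$end - 2900001) <= cfg$marker_spacing_bp
    if (ok_start && ok_end) hits <- hits + 1L
  }
  expect_gte(hits, 8L)
})

test_that("regions round-trip through TSV", {
  gs <- chain_fixture()
  blocks <- expand_blocks(group_snps(
    data.table::data.table(snp = "a", chrom = "1", bp = 100000L)))
  reg <- define_vqtl_regions(blocks, gs)
  path <- file.path(withr::local_tempdir(), "regions.tsv")
  write_regions(reg, path)
  back <- read_regions(path)
  expect_equal(back$start, reg$start)
  expect_equal(back$snps[[1]], reg$snps[[1]])
})
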