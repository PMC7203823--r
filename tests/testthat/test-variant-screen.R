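# one simulated pooled VCF + gene grid shared across this file
screen_fixture <- local({
  cache <- NULL
  function() {
    if (!is.null(cache)) return(cache)
    cfg <- sim_config(seed = 77)
    genes <- simulate_genes(cfg)
    dir <- tempfile("screen")
    dir.create(dir)
    sites <- default_vcf_sites(cfg, genes)
    vc <- simulate_pooled_vcf(sites, file.path(dir, "pools.vcf"), seed = 77)
    gff <- write_gff3(genes, file.path(dir, "genes.gff3"))
    # the screening region: bounding box of the designed sites
    region <- data.table::data.table(chrom = vc$truth$chrom[1],
                                     start = min(vc$truth$pos) - 1000L,
                                     end = max(vc$truth$pos) + 1000L)
    cache <<- list(cfg = cfg, genes = genes, truth = vc$truth,
                   vcf = file.path(dir, "pools.vcf"), gff = gff,
                   region = region)
    cache
  }
})

test_that("the emitted VCF round-trips through the reader without loss", {
  fx <- screen_fixture()
  v <- read_pooled_vcf(fx$vcf)
  tr <- fx$truth
  expect_equal(nrow(v), nrow(tr))
  expect_equal(v$pos, tr$pos)
  expect_equal(v$ref, tr$ref)
  expect_equal(v$alt, tr$alt)
  expect_equal(v$type, tr$type)
  expect_equal(v$low_ref_d, tr$low_ref_d)
  expect_equal(v$low_alt_d, tr$low_alt_d)
  expect_equal(v$high_ref_d, tr$high_ref_d)
  expect_equal(v$high_alt_d, tr$high_alt_d)
  expect_equal(v$cons_term, tr$consequence)
  expect_equal(ifelse(tr$gene_id == "", "", tr$gene_id),
               ifelse(is.na(v$gene_ann), "", v$gene_ann))
})

test_that("hard_filter applies the SNV and INDEL expressions with strict bounds", {
  mk <- function(type, QD = 20, FS = 5, MQ = 60, MQRankSum = 0, ReadPosRankSum = 0) {
    data.table::data.table(var_id = "v", chrom = "1", pos = 1L, ref = "A",
                           alt = if (type == "SNV") "G" else "AG", type = type,
                           QD = QD, FS = FS, MQ = MQ, MQRankSum = MQRankSum,
                           ReadPosRankSum = ReadPosRankSum)
  }
  expect_false(hard_filter(mk("SNV", QD = 1.5))$filter_pass)
  expect_equal(hard_filter(mk("SNV", QD = 1.5))$filter_reasons, "QD")
  expect_true(hard_filter(mk("INDEL", FS = 100))$filter_pass)   # INDEL bound is 200
  expect_false(hard_filter(mk("INDEL", FS = 250))$filter_pass)
  expect_false(hard_filter(mk("SNV", MQ = 39.9))$filter_pass)
  expect_true(hard_filter(mk("INDEL", MQ = 10))$filter_pass)    # MQ not an INDEL rule
  expect_false(hard_filter(mk("SNV", MQRankSum = -12.6))$filter_pass)
  expect_false(hard_filter(mk("SNV", ReadPosRankSum = -8.5))$filter_pass)
  expect_true(hard_filter(mk("INDEL", ReadPosRankSum = -8.5))$filter_pass)
  expect_false(hard_filter(mk("INDEL", ReadPosRankSum = -21))$filter_pass)
  # exact boundary values all pass (strict inequalities)
  expect_true(hard_filter(mk("SNV", QD = 2, FS = 60, MQ = 40,
                             MQRankSum = -12.5, ReadPosRankSum = -8))$filter_pass)
  # absent statistics never trigger
  expect_true(hard_filter(mk("SNV", QD = NA, FS = NA, MQ = NA,
                             MQRankSum = NA, ReadPosRankSum = NA))$filter_pass)
  bad <- mk("SNV"); bad$type <- "CNV"
  expect_error(hard_filter(bad), "unknown variant type")
})

test_that("select_relevant gates by region and consequence class", {
  fx <- screen_fixture()
  v <- hard_filter(read_pooled_vcf(fx$vcf))
  sel <- select_relevant(v[filter_pass == TRUE], fx$region)
  tr <- fx$truth[pass_filter == TRUE]
  rel_terms <- c("missense_variant", "frameshift_variant", "5_prime_UTR_variant",
                 "3_prime_UTR_variant", "splice_acceptor_variant",
                 "splice_donor_variant", "splice_region_variant")
  expect_setequal(sel$relevant$var_id, tr[consequence %in% rel_terms, var_id])
  # synonymous counted in the table but not relevant
  expect_gte(sel$class_table[class == "synonymous", Total], 1L)
  expect_false(any(sel$relevant$cons_class == "synonymous"))
  # class counts conserve the in-region total
  expect_equal(sum(sel$class_table$Total), nrow(sel$in_region))
  # a missense outside every region is dropped entirely
  far <- data.table::copy(v[cons_class == "missense"][1])[, pos := 999999999L]
  sel2 <- select_relevant(far, fx$region)
  expect_equal(nrow(sel2$relevant), 0L)
  expect_equal(nrow(sel2$in_region), 0L)
})

test_that("classify_segregation reproduces designated classes and patterns", {
  fx <- screen_fixture()
  v <- classify_segregation(read_pooled_vcf(fx$vcf))
  tr <- fx$truth
  expect_equal(v$low_class, tr$low_class)
  expect_equal(v$high_class, tr$high_class)
  # spot-check pattern labels
  one <- classify_segregation(data.table::data.table(
    low_ref_d = 12L, low_alt_d = 0L, high_ref_d = 10L, high_alt_d = 6L))
  expect_equal(one$pattern, "segregating-in-high/absent-in-low")
  two <- classify_segregation(data.table::data.table(
    low_ref_d = 0L, low_alt_d = 20L, high_ref_d = 7L, high_alt_d = 5L))
  expect_equal(two$pattern, "segregating-in-high/fixed-in-low")
  shallow <- classify_segregation(data.table::data.table(
    low_ref_d = 2L, low_alt_d = 1L, high_ref_d = 20L, high_alt_d = 0L))
  expect_equal(shallow$low_class, "no_call")
  # depth-scale invariance above the gate
  base <- data.table::data.table(low_ref_d = 6L, low_alt_d = 3L,
                                 high_ref_d = 0L, high_alt_d = 9L)
  expect_equal(classify_segregation(base)$pattern,
               classify_segregation(base[, lapply(.SD, function(x) x * 7L)])$pattern)
})

test_that("map_to_genes finds candidates by span intersection", {
  fx <- screen_fixture()
  v <- hard_filter(read_pooled_vcf(fx$vcf))
  sel <- select_relevant(v[filter_pass == TRUE], fx$region)
  mg <- map_to_genes(sel$relevant, fx$gff)
  tr <- fx$truth[pass_filter == TRUE]
  rel_terms <- c("missense_variant", "frameshift_variant", "5_prime_UTR_variant",
                 "3_prime_UTR_variant", "splice_acceptor_variant",
                 "splice_donor_variant", "splice_region_variant")
  expected_genes <- sort(unique(tr[consequence %in% rel_terms & gene_id != "", gene_id]))
  expect_setequal(mg$candidates$gene_id, expected_genes)
  # per-gene counts match the design
  for (g in expected_genes) {
    expect_equal(mg$candidates[gene_id == g, n_variants],
                 tr[consequence %in% rel_terms & gene_id == g, .N])
  }
  # boundary inclusion: variant at a gene's first bp counts
  genes <- fx$genes
  v1 <- data.table::data.table(var_id = "x", chrom = genes$chrom[1],
                               pos = genes$start[1], gene_ann = genes$gene_id[1])
  mg2 <- map_to_genes(v1, genes)
  expect_equal(mg2$candidates$gene_id, genes$gene_id[1])
  # unknown annotation gene is flagged
  v2 <- data.table::data.table(var_id = "y", chrom = genes$chrom[1],
                               pos = genes$start[1], gene_ann = "NOT_A_GENE")
  expect_equal(map_to_genes(v2, genes)$variants$gene_flag, "annotation mismatch")
})

test_that("the end-to-end screen reproduces the generator truth exactly", {
  fx <- screen_fixture()
  v <- hard_filter(read_pooled_vcf(fx$vcf))
  tr <- fx$truth
  expect_equal(v$filter_pass, tr$pass_filter)
  sel <- select_relevant(v[filter_pass == TRUE], fx$region)
  cls <- classify_segregation(sel$relevant)
  tcmp <- merge(cls[, .(var_id, low_class, high_class)],
                tr[, .(var_id, low_class, high_class)], by = "var_id")
  expect_equal(tcmp$low_class.x, tcmp$low_class.y)
  expect_equal(tcmp$high_class.x, tcmp$high_class.y)
})
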