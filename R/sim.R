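#' Configuration for the synthetic-data generator
#'
#' The defaults emulate the structure of the rabbit divergent-selection
#' study at desk scale: a base population and two lines divergently
#' selected for high/low environmental variance of litter size, does with
#' 2-12 parities, 47 year-season and 3 parity-lactation levels, and a
#' dense SNP panel with LD along each chromosome.
#'
#' @param n_base,n_high,n_low doe counts per population (defaults 96, 149,
#'   139, the genotyped counts per population in the motivating design).
#' @param parity_range integer pair, min >= 2 (default c(2, 12)).
#' @param n_chrom number of chromosomes (default 10).
#' @param snps_per_chrom SNPs per chromosome (default 200).
#' @param marker_spacing_bp distance between adjacent markers (default 1e5).
#' @param copy_prob probability that a haplotype allele is copied from the
#'   previous marker (first-order LD mosaic); 0 = linkage equilibrium,
#'   1 = complete LD within a chromosome (default 0.9).
#' @param causal_vqtl data.frame with columns `chrom`, `bp`, `effect`
#'   (additive effect of one alt allele on the log residual variance) and
#'   `divergence` (high-line minus low-line allele-frequency difference).
#' @param causal_mean_qtl same layout; `effect` acts on the litter-size mean.
#' @param drift_snps data.frame (`chrom`, `bp`, `divergence`) of neutral
#'   SNPs with line-differentiated frequencies.
#' @param mu_tnb litter-size mean (default 7.5 total born).
#' @param sigma2_doe variance of the permanent (doe) effect on the mean
#'   (default 1).
#' @param base_log_resvar baseline log residual variance of litter size
#'   (default log(4.3)).
#' @param sd_yearseason,sd_paritylact SDs of the systematic-effect levels
#'   (defaults 0.5 and 0.3).
#' @param n_yearseason,n_paritylact numbers of systematic-effect levels
#'   (defaults 47 and 3).
#' @param missing_rate genotype missingness rate (default 0.01).
#' @param freq_range range of base-population allele frequencies
#'   (default c(0.1, 0.9)).
#' @param seed integer seed governing all draws.
#' @return list of class `sim_config`.
#' @export
sim_config <- function(n_base = 96L, n_high = 149L, n_low = 139L,
                       parity_range = c(2L, 12L),
                       n_chrom = 10L, snps_per_chrom = 200L,
                       marker_spacing_bp = 100000L,
                       copy_prob = 0.9,
                       causal_vqtl = data.frame(chrom = "1", bp = 10000001L,
                                                effect = log(2), divergence = 0.3),
                       causal_mean_qtl = NULL,
                       drift_snps = NULL,
                       mu_tnb = 7.5, sigma2_doe = 1,
                       base_log_resvar = log(4.3),
                       sd_yearseason = 0.5, sd_paritylact = 0.3,
                       n_yearseason = 47L, n_paritylact = 3L,
                       missing_rate = 0.01,
                       freq_range = c(0.1, 0.9),
                       seed = 1L) {
  cfg <- list(n_base = n_base, n_high = n_high, n_low = n_low,
              parity_range = as.integer(parity_range),
              n_chrom = as.integer(n_chrom),
              snps_per_chrom = as.integer(snps_per_chrom),
              marker_spacing_bp = as.integer(marker_spacing_bp),
              copy_prob = copy_prob,
              causal_vqtl = if (is.null(causal_vqtl)) NULL else as.data.frame(causal_vqtl),
              causal_mean_qtl = if (is.null(causal_mean_qtl)) NULL else as.data.frame(causal_mean_qtl),
              drift_snps = if (is.null(drift_snps)) NULL else as.data.frame(drift_snps),
              mu_tnb = mu_tnb, sigma2_doe = sigma2_doe,
              base_log_resvar = base_log_resvar,
              sd_yearseason = sd_yearseason, sd_paritylact = sd_paritylact,
              n_yearseason = as.integer(n_yearseason),
              n_paritylact = as.integer(n_paritylact),
              missing_rate = missing_rate,
              freq_range = freq_range,
              seed = as.integer(seed))
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  stopifnot(cfg$parity_range[1] >= 2L, cfg$parity_range[2] >= cfg$parity_range[1],
            cfg$n_chrom >= 1L, cfg$snps_per_chrom >= 1L,
            cfg$n_base + cfg$n_high + cfg$n_low >= 1L,
            cfg$copy_prob >= 0, cfg$copy_prob <= 1,
            cfg$sigma2_doe >= 0, cfg$missing_rate >= 0, cfg$missing_rate < 1,
            cfg$freq_range[1] > 0, cfg$freq_range[2] < 1)
  invisible(cfg)
}

# Map (chrom, bp) pairs onto indices of the simulated marker grid.
sim_snp_index <- function(cfg, tab) {
  if (is.null(tab) || nrow(tab) == 0L) return(integer(0))
  chrom <- as.character(tab$chrom)
  k <- round((tab$bp - 1) / cfg$marker_spacing_bp)
  if (any(k < 0 | k >= cfg$snps_per_chrom)) stop("causal bp outside simulated chromosome")
  ic <- match(chrom, as.character(seq_len(cfg$n_chrom)))
  if (anyNA(ic)) stop("causal chromosome not simulated")
  as.integer((ic - 1L) * cfg$snps_per_chrom + k + 1L)
}

#' Simulate LD-structured genotypes for three populations
#'
#' Haplotypes are first-order mosaics: along a chromosome each allele is
#' copied from the previous marker with probability `copy_prob`, otherwise
#' drawn fresh from the population allele frequency. Causal and drift SNPs
#' are always drawn fresh so their configured line divergence is realized
#' exactly in expectation. With `copy_prob = 1` every polymorphic SNP pair
#' on a chromosome is in complete LD.
#'
#' @param cfg [sim_config()].
#' @return list with `genotypes` (a [genotype_set()]) and `truth` (causal
#'   SNP ids, per-population allele frequencies, seed).
#' @export
simulate_genotypes <- function(cfg) {
  validate_sim_config(cfg)
  set.seed(cfg$seed)
  m <- cfg$n_chrom * cfg$snps_per_chrom
  map <- data.table::data.table(
    snp_id = sprintf("snp_%d_%d", rep(seq_len(cfg$n_chrom), each = cfg$snps_per_chrom),
                     rep(seq_len(cfg$snps_per_chrom), cfg$n_chrom)),
    chrom = as.character(rep(seq_len(cfg$n_chrom), each = cfg$snps_per_chrom)),
    bp = rep((seq_len(cfg$snps_per_chrom) - 1L), cfg$n_chrom) * cfg$marker_spacing_bp + 1L)

  p0 <- runif(m, cfg$freq_range[1], cfg$freq_range[2])
  freq <- cbind(base = p0, high = p0, low = p0)
  idx_v <- sim_snp_index(cfg, cfg$causal_vqtl)
  idx_m <- sim_snp_index(cfg, cfg$causal_mean_qtl)
  idx_d <- sim_snp_index(cfg, cfg$drift_snps)
  div <- c(if (length(idx_v)) cfg$causal_vqtl$divergence,
           if (length(idx_m)) cfg$causal_mean_qtl$divergence,
           if (length(idx_d)) cfg$drift_snps$divergence)
  idx_all <- c(idx_v, idx_m, idx_d)
  if (length(idx_all)) {
    freq[idx_all, "high"] <- pmin(0.99, pmax(0.01, p0[idx_all] + div / 2))
    freq[idx_all, "low"] <- pmin(0.99, pmax(0.01, p0[idx_all] - div / 2))
  }
  fresh <- rep(FALSE, m)
  fresh[idx_all] <- TRUE

  pops <- c(rep("base", cfg$n_base), rep("high", cfg$n_high), rep("low", cfg$n_low))
  n <- length(pops)
  dos <- matrix(0, n, m)
  for (pop in c("base", "high", "low")) {
    rows <- which(pops == pop)
    if (!length(rows)) next
    nh <- 2L * length(rows)
    H <- matrix(0L, nh, m)
    pk <- freq[, pop]
    for (c_i in seq_len(cfg$n_chrom)) {
      cols <- (c_i - 1L) * cfg$snps_per_chrom + seq_len(cfg$snps_per_chrom)
      H[, cols[1L]] <- rbinom(nh, 1L, pk[cols[1L]])
      for (k in cols[-1L]) {
        if (fresh[k]) {
          H[, k] <- rbinom(nh, 1L, pk[k])
        } else {
          copy <- runif(nh) < cfg$copy_prob
          H[, k] <- ifelse(copy, H[, k - 1L], rbinom(nh, 1L, pk[k]))
        }
      }
    }
    dos[rows, ] <- H[seq(1L, nh, 2L), , drop = FALSE] + H[seq(2L, nh, 2L), , drop = FALSE]
  }
  if (cfg$missing_rate > 0) {
    dos[matrix(runif(n * m) < cfg$missing_rate, n, m)] <- NA_real_
  }
  rownames(dos) <- sprintf("doe%04d", seq_len(n))
  colnames(dos) <- map$snp_id
  gs <- genotype_set(dos, map, pops)
  truth <- list(causal_vqtl_snps = map$snp_id[idx_v],
                causal_mean_snps = map$snp_id[idx_m],
                drift_snps = map$snp_id[idx_d],
                freq = data.table::data.table(snp_id = map$snp_id, freq),
                seed = cfg$seed)
  list(genotypes = gs, truth = truth)
}

#' Simulate repeated litter-size records with genetic control of the
#' residual variance
#'
#' For doe j at parity i:
#' `TNB_ij = max(0, round(mu + ys + pl + u_j + e_ij))`, with permanent doe
#' effect `u_j ~ N(0, sigma2_doe)` and residual
#' `e_ij ~ N(0, exp(base_log_resvar + sum_k g_jk v_k))`, where `g_jk` is the
#' doe's dosage at variance-QTL k and `v_k` its effect on the log residual
#' variance. Parity counts are uniform on `parity_range`; the
#' parity-lactation level is `min(parity, n_paritylact)` and year-season
#' levels are assigned cyclically so every level is populated.
#'
#' @param cfg [sim_config()].
#' @param gs [genotype_set()] holding all does (missing causal dosages count
#'   as 0 copies).
#' @return `data.table` litter table (doe_id, parity, tnb, yearseason,
#'   paritylact, population) with attribute `truth`: per-record residual
#'   `e`, per-doe `u` and true log residual variance.
#' @export
simulate_litters <- function(cfg, gs) {
  validate_sim_config(cfg)
  stopifnot(inherits(gs, "genotype_set"))
  set.seed(cfg$seed + 1L)
  n <- nrow(gs$dosage)
  ids <- rownames(gs$dosage)

  log_rv <- rep(cfg$base_log_resvar, n)
  idx_v <- sim_snp_index(cfg, cfg$causal_vqtl)
  if (length(idx_v)) {
    gmat <- gs$dosage[, idx_v, drop = FALSE]
    gmat[is.na(gmat)] <- 0
    log_rv <- log_rv + drop(gmat %*% cfg$causal_vqtl$effect)
  }
  mu_g <- rep(0, n)
  idx_m <- sim_snp_index(cfg, cfg$causal_mean_qtl)
  if (length(idx_m)) {
    gmat <- gs$dosage[, idx_m, drop = FALSE]
    gmat[is.na(gmat)] <- 0
    mu_g <- drop(gmat %*% cfg$causal_mean_qtl$effect)
  }

  ys_eff <- rnorm(cfg$n_yearseason, 0, cfg$sd_yearseason)
  pl_eff <- rnorm(cfg$n_paritylact, 0, cfg$sd_paritylact)
  u <- rnorm(n, 0, sqrt(cfg$sigma2_doe))
  pr <- cfg$parity_range
  n_par <- if (pr[1L] == pr[2L]) rep(pr[1L], n) else
    sample(seq(pr[1L], pr[2L]), n, replace = TRUE)

  rec_doe <- rep(seq_len(n), n_par)
  parity <- unlist(lapply(n_par, seq_len), use.names = FALSE)
  ys <- ((seq_along(rec_doe) - 1L) %% cfg$n_yearseason) + 1L
  pl <- pmin(parity, cfg$n_paritylact)
  e <- rnorm(length(rec_doe), 0, sqrt(exp(log_rv[rec_doe])))
  lin <- cfg$mu_tnb + ys_eff[ys] + pl_eff[pl] + u[rec_doe] + mu_g[rec_doe] + e
  tnb <- pmax(0, round(lin))

  lt <- data.table::data.table(doe_id = ids[rec_doe], parity = parity,
                               tnb = as.integer(tnb),
                               yearseason = ys, paritylact = pl,
                               population = gs$populations[rec_doe])
  attr(lt, "truth") <- list(e = e, u = u, log_resvar = log_rv,
                            true_resvar = exp(log_rv), doe_index = rec_doe)
  lt
}

# --- gene models -----------------------------------------------------------

#' Deterministic gene grid as GFF3
#'
#' Places `genes_per_chrom` genes on each chromosome at regular offsets so
#' that region-gene intersections are predictable: gene g on chromosome c
#' spans `[(g-1)*spacing + offset, (g-1)*spacing + offset + length - 1]`.
#'
#' @param cfg [sim_config()].
#' @param genes_per_chrom genes per chromosome (default 10).
#' @param gene_length_bp gene span length (default 4e5).
#' @param gene_offset_bp offset of the first gene start (default 1e5 + 1).
#' @return `data.table` (gene_id, chrom, start, end, strand).
#' @export
simulate_genes <- function(cfg, genes_per_chrom = 10L, gene_length_bp = 400000L,
                           gene_offset_bp = 100001L) {
  chrom_len <- cfg$snps_per_chrom * cfg$marker_spacing_bp
  spacing <- max(gene_length_bp + 100000L,
                 floor(chrom_len / (genes_per_chrom + 1L)))
  g <- data.table::CJ(chrom = as.character(seq_len(cfg$n_chrom)),
                      idx = seq_len(genes_per_chrom), sorted = FALSE)
  g[, start := (idx - 1L) * spacing + gene_offset_bp]
  g[, end := start + gene_length_bp - 1L]
  g[, gene_id := sprintf("GENE%s_%d", chrom, idx)]
  g[, strand := rep_len(c("+", "-"), .N)]
  g[, idx := NULL]
  data.table::setcolorder(g, c("gene_id", "chrom", "start", "end", "strand"))
  g[]
}

#' Write gene models to a GFF3 file
#' @param genes table from [simulate_genes()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_gff3 <- function(genes, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##gff-version 3", con)
  writeLines(sprintf("%s\tveqtl\tgene\t%d\t%d\t.\t%s\t.\tID=%s;Name=%s;biotype=protein_coding",
                     genes$chrom, genes$start, genes$end, genes$strand,
                     genes$gene_id, genes$gene_id), con)
  invisible(path)
}

# --- pooled VCF ------------------------------------------------------------

ann_vocabulary <- c("missense_variant", "frameshift_variant", "synonymous_variant",
                    "5_prime_UTR_variant", "3_prime_UTR_variant",
                    "splice_acceptor_variant", "splice_donor_variant",
                    "splice_region_variant", "intron_variant",
                    "upstream_gene_variant", "downstream_gene_variant",
                    "intergenic_region")

seg_classes <- c("absent", "fixed", "segregating", "no_call")
filter_fates <- c("PASS", "QD", "FS", "MQ", "MQRankSum", "ReadPosRankSum")

#' Default site design for the pooled-line VCF
#'
#' A deterministic mix of sites inside the four genes nearest the first
#' variance-QTL (so the sites fall inside the vQTL region the pipeline is
#' expected to call): relevant consequences (missense, frameshift, UTR,
#' splice), non-relevant ones (synonymous, intron, up/downstream,
#' intergenic), every hard-filter failure mode, and every line-segregation
#' pattern used by the study (segregating in one line, absent or fixed in
#' the other).
#'
#' @param cfg [sim_config()].
#' @param genes gene table from [simulate_genes()].
#' @return site `data.table` suitable for [simulate_pooled_vcf()].
#' @export
default_vcf_sites <- function(cfg, genes) {
  target_chrom <- "1"; target_bp <- 1
  if (!is.null(cfg$causal_vqtl) && nrow(cfg$causal_vqtl)) {
    target_chrom <- as.character(cfg$causal_vqtl$chrom[1L])
    # causal SNPs are drawn fresh, so in the left-to-right copying model
    # their LD (and hence the called region) extends downstream only
    target_bp <- cfg$causal_vqtl$bp[1L] + 5L * cfg$marker_spacing_bp
  }
  gc <- genes[chrom == target_chrom]
  if (nrow(gc) < 4L) stop("need at least 4 genes on the target chromosome")
  gc <- gc[order(abs((start + end) / 2 - target_bp))][1:4]
  data.table::setorder(gc, start)
  g <- gc$gene_id
  inpos <- function(gid, off) gc[gene_id == gid, start] + off
  s <- data.table::data.table(
    chrom = target_chrom,
    pos = c(inpos(g[1], 100L), inpos(g[1], 200L), inpos(g[1], 300L),
            inpos(g[1], 400L), inpos(g[1], 500L),
            inpos(g[2], 100L), inpos(g[2], 200L), inpos(g[2], 300L),
            inpos(g[2], 400L),
            inpos(g[3], 100L), inpos(g[3], 150L), inpos(g[3], 250L),
            inpos(g[4], 100L), inpos(g[4], 200L),
            gc[gene_id == g[1], end] + 50000L),
    consequence = c("missense_variant", "synonymous_variant", "5_prime_UTR_variant",
                    "intron_variant", "frameshift_variant",
                    "3_prime_UTR_variant", "splice_region_variant", "missense_variant",
                    "upstream_gene_variant",
                    "missense_variant", "missense_variant", "splice_donor_variant",
                    "intron_variant", "downstream_gene_variant",
                    "intergenic_region"),
    gene_id = c(rep(g[1], 5L), rep(g[2], 4L), rep(g[3], 3L),
                rep(g[4], 2L), ""),
    low_class = c("segregating", "segregating", "absent", "segregating", "fixed",
                  "fixed", "absent", "segregating", "segregating",
                  "segregating", "segregating", "absent", "segregating", "absent",
                  "segregating"),
    high_class = c("absent", "fixed", "segregating", "absent", "segregating",
                   "absent", "segregating", "fixed", "absent",
                   "fixed", "absent", "segregating", "absent", "segregating",
                   "absent"),
    filter_fate = c("PASS", "PASS", "PASS", "PASS", "PASS",
                    "PASS", "QD", "FS", "MQ",
                    "MQRankSum", "ReadPosRankSum", "PASS", "PASS", "PASS",
                    "PASS"))
  # alleles: frameshift sites are 1-bp deletions (left-anchored), others SNVs
  s[, ref := ifelse(consequence == "frameshift_variant", "AT", "A")]
  s[, alt := ifelse(consequence == "frameshift_variant", "A", "G")]
  s[]
}

#' Write a pooled-line VCF v4.2 with SnpEff-style annotations
#'
#' Emits one bi-allelic record per site with two pool samples (`low`,
#' `high`). Pool allele depths are drawn from the designated segregation
#' class at a total depth ~ Poisson(`depth`): `absent` puts all reads on
#' the reference allele, `fixed` all on the alternative, `segregating`
#' splits them binomially, and `no_call` emits fewer than `no_call_depth`
#' reads. INFO fields QD, FS, MQ, MQRankSum and ReadPosRankSum are set so
#' that a site designated to fail one hard-filter rule violates exactly
#' that rule (with the SNV/INDEL-specific bound) and all other sites pass.
#'
#' @param sites site table as from [default_vcf_sites()]; required columns
#'   chrom, pos, ref, alt, consequence, gene_id, low_class, high_class,
#'   filter_fate.
#' @param path output VCF path.
#' @param depth mean pool depth (default 27, one pool of 27 males per line).
#' @param seed integer seed.
#' @param no_call_depth total depth emitted for `no_call` sites (default 3).
#' @return list: `path`, and `truth` — the site table augmented with the
#'   emitted depths and the intended downstream classification.
#' @export
simulate_pooled_vcf <- function(sites, path, depth = 27, seed = 1L,
                                no_call_depth = 3L) {
  sites <- data.table::as.data.table(sites)
  bad <- setdiff(sites$consequence, ann_vocabulary)
  if (length(bad)) stop("unknown consequence term(s): ", paste(unique(bad), collapse = ", "))
  stopifnot(all(sites$low_class %in% seg_classes),
            all(sites$high_class %in% seg_classes),
            all(sites$filter_fate %in% filter_fates))
  set.seed(seed)
  data.table::setorder(sites, chrom, pos)
  ns <- nrow(sites)
  is_indel <- nchar(sites$ref) != nchar(sites$alt)

  draw_pool <- function(class) {
    tot <- pmax(10L, rpois(ns, depth))
    alt <- integer(ns)
    alt[class == "fixed"] <- tot[class == "fixed"]
    seg <- class == "segregating"
    if (any(seg)) {
      a <- rbinom(sum(seg), tot[seg], runif(sum(seg), 0.3, 0.7))
      alt[seg] <- pmin(tot[seg] - 1L, pmax(1L, a))
    }
    nc <- class == "no_call"
    if (any(nc)) {
      tot[nc] <- no_call_depth
      alt[nc] <- pmin(no_call_depth, 1L)
    }
    data.table::data.table(ref_d = tot - alt, alt_d = alt)
  }
  low <- draw_pool(sites$low_class)
  high <- draw_pool(sites$high_class)

  qd <- round(runif(ns, 15, 30), 2); fs <- round(runif(ns, 0, 10), 3)
  mq <- round(runif(ns, 50, 60), 2); mqrs <- round(runif(ns, -2, 2), 3)
  rprs <- round(runif(ns, -2, 2), 3)
  fate <- sites$filter_fate
  qd[fate == "QD"] <- 1.2
  fs[fate == "FS" & !is_indel] <- 80
  fs[fate == "FS" & is_indel] <- 250
  mq[fate == "MQ"] <- 30
  mqrs[fate == "MQRankSum"] <- -13.5
  rprs[fate == "ReadPosRankSum" & !is_indel] <- -9.5
  rprs[fate == "ReadPosRankSum" & is_indel] <- -25

  impact <- ifelse(sites$consequence %in% c("frameshift_variant",
                                            "splice_acceptor_variant",
                                            "splice_donor_variant"), "HIGH",
            ifelse(sites$consequence == "missense_variant", "MODERATE",
            ifelse(sites$consequence == "synonymous_variant", "LOW", "MODIFIER")))
  gene <- ifelse(sites$gene_id == "", "", sites$gene_id)
  ann <- sprintf("%s|%s|%s|%s|%s|transcript|%s.1|protein_coding|1/1|n.1A>G||||||",
                 sites$alt, sites$consequence, impact, gene, gene, gene)

  info <- sprintf("QD=%.2f;FS=%.3f;MQ=%.2f;MQRankSum=%.3f;ReadPosRankSum=%.3f;ANN=%s",
                  qd, fs, mq, mqrs, rprs, ann)
  fmt_s <- function(d) sprintf("0/1:%d,%d:%d", d$ref_d, d$alt_d, d$ref_d + d$alt_d)

  hdr <- c("##fileformat=VCFv4.2",
           "##source=veqtl-simulator",
           "##INFO=<ID=QD,Number=1,Type=Float,Description=\"Quality by depth\">",
           "##INFO=<ID=FS,Number=1,Type=Float,Description=\"Fisher strand bias\">",
           "##INFO=<ID=MQ,Number=1,Type=Float,Description=\"RMS mapping quality\">",
           "##INFO=<ID=MQRankSum,Number=1,Type=Float,Description=\"Mapping quality rank sum\">",
           "##INFO=<ID=ReadPosRankSum,Number=1,Type=Float,Description=\"Read position rank sum\">",
           "##INFO=<ID=ANN,Number=.,Type=String,Description=\"Functional annotations: 'Allele | Annotation | Annotation_Impact | Gene_Name | Gene_ID | Feature_Type | Feature_ID | Transcript_BioType | Rank | HGVS.c | HGVS.p | cDNA.pos / cDNA.length | CDS.pos / CDS.length | AA.pos / AA.length | Distance | ERRORS / WARNINGS / INFO'\">",
           "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
           "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Allelic depths\">",
           "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
           paste0("##contig=<ID=", unique(sites$chrom), ">"),
           "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\tlow\thigh")
  body <- sprintf("%s\t%d\t%s\t%s\t%s\t100\t.\t%s\tGT:AD:DP\t%s\t%s",
                  sites$chrom, sites$pos,
                  sprintf("var%03d", seq_len(ns)),
                  sites$ref, sites$alt, info, fmt_s(low), fmt_s(high))
  writeLines(c(hdr, body), path)

  truth <- data.table::copy(sites)
  truth[, `:=`(var_id = sprintf("var%03d", seq_len(ns)),
               type = ifelse(is_indel, "INDEL", "SNV"),
               low_ref_d = low$ref_d, low_alt_d = low$alt_d,
               high_ref_d = high$ref_d, high_alt_d = high$alt_d,
               pass_filter = fate == "PASS")]
  list(path = path, truth = truth)
}

#' Write the generator truth to JSON
#' @param truth list or table of ground-truth values.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_truth_json <- function(truth, path) {
  jsonlite::write_json(truth, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}
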