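#' Construct a genotype set
#'
#' Container for an individuals x SNPs dosage matrix (counts of the
#' alternative allele, 0/1/2 or NA), a SNP map, and individual metadata.
#'
#' @param dosage numeric matrix, individuals in rows (rownames = ids), SNPs
#'   in columns (colnames = snp ids); entries 0, 1, 2 or NA.
#' @param map data.frame with columns `snp_id`, `chrom`, `bp` (1-based);
#'   `bp` may be NA for SNPs of unknown position (removed at QC).
#' @param populations character vector of population labels per individual
#'   (recycled if length 1).
#' @return Object of class `genotype_set`.
#' @export
genotype_set <- function(dosage, map, populations = "all") {
  map <- data.table::as.data.table(map)
  stopifnot(is.matrix(dosage), all(c("snp_id", "chrom", "bp") %in% names(map)))
  if (nrow(dosage) == 0L || ncol(dosage) == 0L) stop("empty genotype set")
  if (ncol(dosage) != nrow(map)) stop("map rows must match dosage columns")
  ok <- dosage %in% c(0, 1, 2) | is.na(dosage)
  if (!all(ok)) stop("dosage entries must be 0, 1, 2 or NA")
  if (is.null(rownames(dosage))) rownames(dosage) <- paste0("ind", seq_len(nrow(dosage)))
  if (is.null(colnames(dosage))) colnames(dosage) <- map$snp_id
  if (!identical(colnames(dosage), as.character(map$snp_id))) {
    stop("dosage colnames must equal map$snp_id in order")
  }
  map$chrom <- as.character(map$chrom)
  ord <- order(map$chrom, map$bp)
  if (is.unsorted(ord)) {
    dosage <- dosage[, ord, drop = FALSE]
    map <- map[ord]
  }
  pops <- rep_len(as.character(populations), nrow(dosage))
  structure(list(dosage = dosage, map = map, populations = pops),
            class = "genotype_set")
}

#' @export
print.genotype_set <- function(x, ...) {
  cat("genotype_set:", nrow(x$dosage), "individuals x", ncol(x$dosage), "SNPs on",
      length(unique(x$map$chrom)), "chromosome(s);",
      format(100 * mean(is.na(x$dosage)), digits = 3), "% missing\n")
  invisible(x)
}

#' Per-SNP alternative allele frequency (observed entries only)
#' @param gs genotype_set
#' @return numeric vector, one entry per SNP.
#' @export
alt_freq <- function(gs) {
  colMeans(gs$dosage, na.rm = TRUE) / 2
}

#' Per-SNP minor allele frequency
#' @param gs genotype_set
#' @return numeric vector in [0, 0.5].
#' @export
snp_maf <- function(gs) {
  p <- alt_freq(gs)
  pmin(p, 1 - p)
}

#' Genotype quality control
#'
#' Removes individuals with a call rate below `min_call_rate`, then SNPs
#' with minor allele frequency below `min_maf`, missing rate above
#' `max_snp_missing`, or an unknown map position; the two steps are
#' alternated until nothing more is removed, so the filter is idempotent.
#' All comparisons are strict, so an individual at exactly the call-rate
#' threshold and a SNP at exactly the MAF or missing-rate threshold are
#' retained. Counts removed per rule are reported and attached as
#' attribute `qc_log`.
#'
#' @param gs genotype_set
#' @param min_call_rate minimum individual call rate kept (default 0.97).
#' @param min_maf minimum SNP minor allele frequency kept (default 0.05).
#' @param max_snp_missing maximum SNP missing rate kept (default 0.05).
#' @return Filtered `genotype_set` with attribute `qc_log` (named counts).
#' @export
qc_filter <- function(gs, min_call_rate = 0.97, min_maf = 0.05,
                      max_snp_missing = 0.05) {
  stopifnot(inherits(gs, "genotype_set"))
  dos <- gs$dosage
  map_bad_pos <- is.na(gs$map$bp) | is.na(gs$map$chrom)
  keep_ind <- rep(TRUE, nrow(dos))
  keep_snp <- rep(TRUE, ncol(dos))
  log <- c(individuals_low_call_rate = 0, snps_low_maf = 0,
           snps_high_missing = 0, snps_unknown_position = 0, snps_removed = 0)
  # Removing SNPs perturbs individual call rates (and vice versa), so the
  # two steps are alternated to a fixed point; this makes the filter
  # idempotent. Individuals are always assessed first.
  repeat {
    sub <- dos[keep_ind, keep_snp, drop = FALSE]
    call_rate <- rowMeans(!is.na(sub))
    drop_ind <- call_rate < min_call_rate
    if (any(drop_ind)) {
      keep_ind[keep_ind][drop_ind] <- FALSE
      log["individuals_low_call_rate"] <- log[["individuals_low_call_rate"]] + sum(drop_ind)
      if (!any(keep_ind)) stop("qc_filter removed all individuals")
      sub <- dos[keep_ind, keep_snp, drop = FALSE]
    }
    miss <- colMeans(is.na(sub))
    p <- colMeans(sub, na.rm = TRUE) / 2
    maf <- pmin(p, 1 - p)
    maf[is.nan(maf)] <- 0   # SNPs with all entries missing
    bad_maf <- maf < min_maf
    bad_miss <- miss > max_snp_missing
    bad_pos <- map_bad_pos[keep_snp]
    drop_snp <- bad_maf | bad_miss | bad_pos
    if (any(drop_snp)) {
      keep_snp[keep_snp][drop_snp] <- FALSE
      log["snps_low_maf"] <- log[["snps_low_maf"]] + sum(bad_maf)
      log["snps_high_missing"] <- log[["snps_high_missing"]] + sum(bad_miss)
      log["snps_unknown_position"] <- log[["snps_unknown_position"]] + sum(bad_pos)
      log["snps_removed"] <- log[["snps_removed"]] + sum(drop_snp)
      if (!any(keep_snp)) stop("qc_filter removed all SNPs")
    }
    if (!any(drop_ind) && !any(drop_snp)) break
  }
  dos <- dos[keep_ind, , drop = FALSE]
  ve_msg("qc_filter: removed ", log[["individuals_low_call_rate"]],
         " individual(s) [call rate < ", min_call_rate, "]; ",
         log[["snps_removed"]], " SNP(s) [",
         log[["snps_low_maf"]], " MAF < ", min_maf, ", ",
         log[["snps_high_missing"]], " missing > ", max_snp_missing, ", ",
         log[["snps_unknown_position"]], " unknown position]")
  out <- genotype_set(dos[, keep_snp, drop = FALSE], gs$map[keep_snp],
                      gs$populations[keep_ind])
  attr(out, "qc_log") <- log
  out
}

#' Impute missing dosages from the observed allele frequency
#'
#' Each missing entry of SNP j is drawn from Binomial(2, p_j), where p_j is
#' the alternative-allele frequency among the SNP's observed entries. This
#' is a deliberately simple stand-in for LD-aware imputation; imputation
#' accuracy is not the object of study.
#'
#' @param gs genotype_set
#' @param seed integer seed; the draw is deterministic given the seed.
#' @return `genotype_set` with no missing entries; observed entries unchanged.
#' @export
impute_missing <- function(gs, seed = 1L) {
  stopifnot(inherits(gs, "genotype_set"))
  dos <- gs$dosage
  nmiss <- colSums(is.na(dos))
  if (any(nmiss == nrow(dos))) {
    stop("cannot impute SNP(s) with all entries missing: ",
         paste(head(colnames(dos)[nmiss == nrow(dos)], 5), collapse = ", "))
  }
  if (sum(nmiss) > 0L) {
    p <- alt_freq(gs)
    withr_seed <- function(expr) {
      old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
      on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
      set.seed(seed)
      expr
    }
    withr_seed({
      for (j in which(nmiss > 0L)) {
        idx <- which(is.na(dos[, j]))
        dos[idx, j] <- stats::rbinom(length(idx), 2L, p[j])
      }
    })
  }
  genotype_set(dos, gs$map, gs$populations)
}

#' VanRaden genomic relationship matrix
#'
#' Each SNP column is centered by twice its allele frequency and scaled by
#' `sqrt(2 p (1 - p))`; the GRM is `W W' / m` over the `m` SNPs used.
#' Monomorphic SNPs carry no information and are skipped. Optionally all
#' SNPs on one chromosome are excluded (leave-one-chromosome-out).
#'
#' @param gs genotype_set with no missing entries (see [impute_missing()]).
#' @param exclude_chrom optional chromosome label whose SNPs are left out.
#' @return list of class `grm`: `G` (n x n), `snps_used`, `excluded_chrom`.
#' @export
compute_grm <- function(gs, exclude_chrom = NULL) {
  stopifnot(inherits(gs, "genotype_set"))
  if (anyNA(gs$dosage)) stop("GRM requires imputed (complete) genotypes")
  keep <- rep(TRUE, ncol(gs$dosage))
  if (!is.null(exclude_chrom)) keep <- !(gs$map$chrom %in% as.character(exclude_chrom))
  p <- colMeans(gs$dosage) / 2
  poly <- p > 0 & p < 1
  keep <- keep & poly
  if (!any(keep)) stop("no SNPs left for the GRM after exclusion")
  Z <- gs$dosage[, keep, drop = FALSE]
  pk <- p[keep]
  W <- sweep(Z, 2L, 2 * pk, "-")
  W <- sweep(W, 2L, sqrt(2 * pk * (1 - pk)), "/")
  G <- tcrossprod(W) / ncol(W)
  dimnames(G) <- list(rownames(gs$dosage), rownames(gs$dosage))
  structure(list(G = G, snps_used = colnames(gs$dosage)[keep],
                 excluded_chrom = exclude_chrom),
            class = "grm")
}

#' Leading principal components of a GRM
#'
#' Top-`k` eigenvectors of the relationship matrix ordered by descending
#' eigenvalue, with each vector's sign fixed so its largest-magnitude entry
#' is positive.
#'
#' @param grm object from [compute_grm()] (or a plain symmetric matrix).
#' @param k number of components (default 5).
#' @return n x k matrix with attribute `eigenvalues`.
#' @export
compute_pcs <- function(grm, k = 5L) {
  G <- if (inherits(grm, "grm")) grm$G else grm
  stopifnot(is.matrix(G), nrow(G) == ncol(G))
  ev <- eigen(G, symmetric = TRUE)
  pos <- sum(ev$values > max(ev$values) * 1e-10)
  if (k > pos) stop("k = ", k, " exceeds numerical rank ", pos)
  V <- ev$vectors[, seq_len(k), drop = FALSE]
  for (j in seq_len(k)) {
    i <- which.max(abs(V[, j]))
    if (V[i, j] < 0) V[, j] <- -V[, j]
  }
  dimnames(V) <- list(rownames(G), paste0("PC", seq_len(k)))
  attr(V, "eigenvalues") <- ev$values[seq_len(k)]
  V
}

#' Write genotypes as PLINK text (.ped/.map)
#'
#' Dosages are expanded to two alleles per SNP with alleles coded A
#' (reference) and B (alternative); missing genotypes are written as `0 0`.
#' The .map has columns chromosome, snp id, genetic distance (0), bp.
#'
#' @param gs genotype_set
#' @param prefix output path prefix; writes `<prefix>.ped` and `<prefix>.map`.
#' @return `prefix`, invisibly.
#' @export
write_plink <- function(gs, prefix) {
  map <- data.table::data.table(chrom = gs$map$chrom, snp = gs$map$snp_id,
                                cm = 0L, bp = gs$map$bp)
  data.table::fwrite(map, paste0(prefix, ".map"), sep = "\t", col.names = FALSE)
  dos <- gs$dosage
  n <- nrow(dos); m <- ncol(dos)
  a1 <- matrix("A", n, m); a2 <- matrix("A", n, m)
  a1[dos >= 1] <- "B"
  a2[dos == 2] <- "B"
  a1[is.na(dos)] <- "0"; a2[is.na(dos)] <- "0"
  geno <- matrix("", n, 2L * m)
  geno[, seq(1L, 2L * m, 2L)] <- a1
  geno[, seq(2L, 2L * m, 2L)] <- a2
  ped <- data.table::data.table(fid = gs$populations, iid = rownames(dos),
                                pat = 0L, mat = 0L, sex = 0L, phe = -9L)
  ped <- cbind(ped, data.table::as.data.table(geno))
  data.table::fwrite(ped, paste0(prefix, ".ped"), sep = " ", col.names = FALSE)
  invisible(prefix)
}

#' Read PLINK text (.ped/.map) genotypes
#'
#' The B allele (and in its absence, the second observed allele) is taken as
#' the alternative allele; `0` denotes a missing allele. Family id is kept
#' as the population label.
#'
#' @param prefix path prefix of the `.ped`/`.map` pair.
#' @return `genotype_set`.
#' @export
read_plink <- function(prefix) {
  map <- data.table::fread(paste0(prefix, ".map"), header = FALSE,
                           col.names = c("chrom", "snp_id", "cm", "bp"))
  ped <- data.table::fread(paste0(prefix, ".ped"), header = FALSE)
  m <- nrow(map)
  if (ncol(ped) != 6L + 2L * m) stop(".ped column count does not match .map")
  ids <- as.character(ped[[2L]])
  pops <- as.character(ped[[1L]])
  A1 <- as.matrix(ped[, seq(7L, 6L + 2L * m, 2L), with = FALSE])
  A2 <- as.matrix(ped[, seq(8L, 6L + 2L * m, 2L), with = FALSE])
  dos <- matrix(NA_real_, nrow(ped), m, dimnames = list(ids, map$snp_id))
  for (j in seq_len(m)) {
    al <- c(A1[, j], A2[, j])
    obs <- setdiff(unique(al), "0")
    alt <- if ("B" %in% obs) "B" else if (length(obs) >= 2L) sort(obs)[2L] else NA_character_
    miss <- A1[, j] == "0" | A2[, j] == "0"
    if (is.na(alt)) { dos[!miss, j] <- 0 } else {
      dos[, j] <- (A1[, j] == alt) + (A2[, j] == alt)
    }
    dos[miss, j] <- NA_real_
  }
  genotype_set(dos, map[, .(snp_id, chrom, bp)], pops)
}
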