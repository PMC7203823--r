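#' Group significant SNPs into positional blocks
#'
#' Single-linkage clustering along the genome: two significant SNPs join
#' the same block when they lie on the same chromosome at most `window_bp`
#' apart (default 0.5 Mb). Positions are 1-based and distances inclusive.
#'
#' @param validated_snps table with columns `snp`, `chrom`, `bp` (the SNPs
#'   that survived both GWAS methods and the additional tests).
#' @param window_bp maximum within-block gap (default 5e5).
#' @return `data.table`: block, chrom, start, end, snps (list column).
#' @export
group_snps <- function(validated_snps, window_bp = 500000L) {
  v <- data.table::as.data.table(validated_snps)
  stopifnot(all(c("snp", "chrom", "bp") %in% names(v)), nrow(v) > 0L)
  data.table::setorder(v, chrom, bp)
  v[, block := cumsum(c(1L, as.integer(chrom[-1L] != chrom[-.N] |
                                         diff(bp) > window_bp)))]
  out <- v[, .(chrom = chrom[1L], start = min(bp), end = max(bp),
               snps = list(snp)), by = block]
  out[]
}

#' Pad blocks into candidate intervals
#'
#' Each block is expanded by `pad_bp` on both sides (default 1 Mb) to form
#' the interval over which LD is examined; the lower bound is floored at 1.
#' Overlapping padded intervals remain distinct — blocks are only merged by
#' the positional rule of [group_snps()], never by padding.
#'
#' @param blocks table from [group_snps()].
#' @param pad_bp padding (default 1e6).
#' @return input table with `interval_start`, `interval_end` columns.
#' @export
expand_blocks <- function(blocks, pad_bp = 1000000L) {
  out <- data.table::as.data.table(blocks)
  out[, interval_start := pmax(1, start - pad_bp)]
  out[, interval_end := end + pad_bp]
  out[]
}

#' Pairwise r-squared within an interval
#'
#' Squared Pearson correlation of unphased dosage vectors (composite LD)
#' for all SNP pairs inside `[start, end]` of one chromosome. Monomorphic
#' SNPs are excluded with a warning.
#'
#' @param gs imputed [genotype_set()].
#' @param chrom chromosome label.
#' @param start,end interval bounds (1-based, inclusive).
#' @return list of class `ld_matrix`: `r2` (symmetric matrix), `map`
#'   (data.table snp_id, chrom, bp of the SNPs kept).
#' @export
ld_r2 <- function(gs, chrom, start, end) {
  stopifnot(inherits(gs, "genotype_set"))
  sel <- which(gs$map$chrom == as.character(chrom) &
                 gs$map$bp >= start & gs$map$bp <= end)
  if (!length(sel)) stop("no SNPs in the interval")
  Z <- gs$dosage[, sel, drop = FALSE]
  if (anyNA(Z)) stop("genotypes must be imputed first")
  v <- apply(Z, 2L, stats::var)
  if (any(v == 0)) {
    warning(sum(v == 0), " monomorphic SNP(s) excluded from the LD matrix")
    sel <- sel[v > 0]
    Z <- Z[, v > 0, drop = FALSE]
  }
  r2 <- stats::cor(Z)^2
  structure(list(r2 = r2, map = gs$map[sel]), class = "ld_matrix")
}

#' Define vQTL regions from LD around significant SNPs
#'
#' Within each padded interval, SNPs are linked when their pairwise
#' `r^2 > r2_threshold` (strict). Under the default connected-component
#' rule the region is the union of the components that contain a
#' significant SNP, spanning from the leftmost to the rightmost member; a
#' significant SNP with no partner above the threshold yields a point
#' region (anchor only). `mode = "clique"` instead requires every member
#' to exceed the threshold with every significant SNP of the block.
#'
#' @param blocks expanded blocks from [expand_blocks()].
#' @param gs imputed [genotype_set()] (LD is computed per interval).
#' @param assoc association table with columns `snp`, `p` used to pick each
#'   region's anchor (most significant member); optional.
#' @param r2_threshold LD threshold (default 0.7, strict inequality).
#' @param mode `"component"` (default) or `"clique"`.
#' @return `data.table` of regions: chrom, start, end, n_snps, anchor_snp,
#'   snps (list column of member SNP ids).
#' @export
define_vqtl_regions <- function(blocks, gs, assoc = NULL, r2_threshold = 0.7,
                                mode = c("component", "clique")) {
  mode <- match.arg(mode)
  blocks <- data.table::as.data.table(blocks)
  stopifnot(all(c("chrom", "interval_start", "interval_end", "snps") %in% names(blocks)))
  out <- vector("list", nrow(blocks))
  for (i in seq_len(nrow(blocks))) {
    ld <- ld_r2(gs, blocks$chrom[i], blocks$interval_start[i], blocks$interval_end[i])
    sig <- intersect(blocks$snps[[i]], ld$map$snp_id)
    sig_i <- match(sig, ld$map$snp_id)
    adj <- ld$r2 > r2_threshold
    diag(adj) <- FALSE
    if (mode == "component") {
      members <- component_members(adj, sig_i)
    } else {
      with_all_sig <- which(apply(adj[, sig_i, drop = FALSE], 1L, all))
      members <- sort(unique(c(sig_i, with_all_sig)))
    }
    mem_map <- ld$map[members]
    anchor <- sig[1L]
    if (!is.null(assoc)) {
      a <- data.table::as.data.table(assoc)
      ps <- a[match(sig, snp), p]
      if (!all(is.na(ps))) anchor <- sig[which.min(ps)]
    }
    out[[i]] <- data.table::data.table(chrom = blocks$chrom[i],
                                       start = min(mem_map$bp),
                                       end = max(mem_map$bp),
                                       n_snps = nrow(mem_map),
                                       anchor_snp = anchor,
                                       snps = list(mem_map$snp_id))
  }
  data.table::rbindlist(out)
}

# breadth-first expansion of the components containing the seed indices
component_members <- function(adj, seeds) {
  seen <- rep(FALSE, nrow(adj))
  queue <- seeds
  seen[seeds] <- TRUE
  while (length(queue)) {
    nb <- which(adj[queue[1L], ])
    queue <- queue[-1L]
    new <- nb[!seen[nb]]
    seen[new] <- TRUE
    queue <- c(queue, new)
  }
  which(seen)
}

#' Write regions to TSV
#' @param regions table from [define_vqtl_regions()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_regions <- function(regions, path) {
  out <- data.table::as.data.table(regions)
  if ("snps" %in% names(out)) {
    out <- data.table::copy(out)
    out[, snps := vapply(snps, paste, character(1), collapse = ",")]
  }
  data.table::fwrite(out, path, sep = "\t")
  invisible(path)
}

#' Read regions from TSV
#' @param path regions TSV path.
#' @return `data.table` with a `snps` list column.
#' @export
read_regions <- function(path) {
  out <- data.table::fread(path, sep = "\t")
  if ("snps" %in% names(out)) {
    out[, snps := strsplit(as.character(snps), ",", fixed = TRUE)]
  }
  out[]
}
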