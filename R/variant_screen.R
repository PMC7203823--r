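# consequence-class machinery -----------------------------------------------

# most-severe-first; severity follows the SnpEff convention
class_levels <- c("frameshift", "missense", "splicing", "utr5", "utr3",
                  "synonymous", "intron", "upstream", "downstream", "intergenic")
relevant_classes <- c("frameshift", "missense", "splicing", "utr5", "utr3")
table2_order <- c("upstream", "utr5", "synonymous", "missense", "frameshift",
                  "splicing", "intron", "utr3", "downstream", "intergenic")

term_to_class <- function(term) {
  cls <- rep(NA_character_, length(term))
  cls[term == "frameshift_variant"] <- "frameshift"
  cls[term == "missense_variant"] <- "missense"
  cls[grepl("^splice_", term)] <- "splicing"
  cls[term == "5_prime_UTR_variant"] <- "utr5"
  cls[term == "3_prime_UTR_variant"] <- "utr3"
  cls[term == "synonymous_variant"] <- "synonymous"
  cls[term == "intron_variant"] <- "intron"
  cls[term == "upstream_gene_variant"] <- "upstream"
  cls[term == "downstream_gene_variant"] <- "downstream"
  cls[term %in% c("intergenic_region", "intergenic_variant")] <- "intergenic"
  cls
}

#' Read a pooled-line VCF with SnpEff annotations
#'
#' Loads a bi-allelic VCF v4.2 with two pool samples named `low` and
#' `high`, the GATK site statistics QD, FS, MQ, MQRankSum and
#' ReadPosRankSum (absent values kept as NA), and SnpEff `ANN` annotations
#' (pipe-delimited; subfields 2 = consequence term, 5 = gene id). Each
#' variant is typed SNV or INDEL by comparing allele lengths, and per-line
#' pooled allele depths are taken from the `AD` genotype field.
#'
#' @param path VCF path.
#' @return `data.table`: var_id, chrom, pos, ref, alt, type, the five site
#'   statistics, `cons_class`/`cons_term`/`gene_ann` (most severe
#'   annotation), `ann` (list column of all parsed annotations), and
#'   low/high ref/alt depths.
#' @export
read_pooled_vcf <- function(path) {
  vcf <- VariantAnnotation::readVcf(path)
  rr <- SummarizedExperiment::rowRanges(vcf)
  alt_l <- VariantAnnotation::alt(vcf)
  if (any(lengths(alt_l) != 1L)) stop("multi-allelic records are not supported")
  ref <- as.character(VariantAnnotation::ref(vcf))
  alt <- as.character(unlist(alt_l))
  info <- VariantAnnotation::info(vcf)
  get_num <- function(field) {
    if (field %in% names(info)) {
      x <- info[[field]]
      if (is.list(x) || methods::is(x, "List")) x <- vapply(x, function(v) if (length(v)) v[1] else NA_real_, numeric(1))
      as.numeric(x)
    } else rep(NA_real_, length(ref))
  }
  ann_raw <- if ("ANN" %in% names(info)) info$ANN else NULL
  parse_ann <- function(strings) {
    if (is.null(strings) || !length(strings)) {
      return(data.table::data.table(term = character(), gene_id = character(),
                                    feature_id = character()))
    }
    parts <- strsplit(strings, "|", fixed = TRUE)
    data.table::data.table(
      term = vapply(parts, function(p) if (length(p) >= 2L) p[2L] else NA_character_, character(1)),
      gene_id = vapply(parts, function(p) if (length(p) >= 5L) p[5L] else NA_character_, character(1)),
      feature_id = vapply(parts, function(p) if (length(p) >= 7L) p[7L] else NA_character_, character(1)))
  }
  ann <- if (is.null(ann_raw)) replicate(length(ref), parse_ann(character()), simplify = FALSE)
         else lapply(seq_along(ref), function(i) parse_ann(as.character(ann_raw[[i]])))

  smp <- colnames(vcf)
  if (!all(c("low", "high") %in% smp)) {
    stop("expected pool samples named 'low' and 'high', got: ",
         paste(smp, collapse = ", "))
  }
  AD <- VariantAnnotation::geno(vcf)$AD
  dep <- function(sample, k) {
    vapply(AD[, sample], function(v) if (length(v) >= k) as.integer(v[k]) else NA_integer_,
           integer(1))
  }
  out <- data.table::data.table(
    var_id = rownames(vcf) %||% sprintf("var%03d", seq_along(ref)),
    chrom = as.character(GenomicRanges::seqnames(rr)),
    pos = GenomicRanges::start(rr),
    ref = ref, alt = alt,
    type = ifelse(nchar(ref) == nchar(alt), "SNV", "INDEL"),
    QD = get_num("QD"), FS = get_num("FS"), MQ = get_num("MQ"),
    MQRankSum = get_num("MQRankSum"), ReadPosRankSum = get_num("ReadPosRankSum"),
    low_ref_d = dep("low", 1L), low_alt_d = dep("low", 2L),
    high_ref_d = dep("high", 1L), high_alt_d = dep("high", 2L))
  # most severe annotation per variant
  sev <- lapply(ann, function(a) {
    cls <- term_to_class(a$term)
    k <- which(!is.na(cls))
    if (!length(k)) return(list(NA_character_, NA_character_, NA_character_))
    best <- k[which.min(match(cls[k], class_levels))]
    list(cls[best], a$term[best], a$gene_id[best])
  })
  out[, cons_class := vapply(sev, `[[`, character(1), 1L)]
  out[, cons_term := vapply(sev, `[[`, character(1), 2L)]
  out[, gene_ann := vapply(sev, `[[`, character(1), 3L)]
  out[, ann := ann]
  out[]
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' GATK-style hard filtering of pooled variants
#'
#' A SNV is rejected when any of `QD < 2`, `FS > 60`, `MQ < 40`,
#' `MQRankSum < -12.5`, `ReadPosRankSum < -8` holds; an INDEL when any of
#' `QD < 2`, `FS > 200`, `ReadPosRankSum < -20` holds. All comparisons are
#' strict, so a site exactly at a boundary passes, and a missing statistic
#' never triggers its rule. Records are labelled rather than deleted
#' (VariantFiltration semantics); per-rule rejection counts are attached as
#' attribute `filter_log`.
#'
#' @param variants table from [read_pooled_vcf()].
#' @return the table with `filter_pass` (logical) and `filter_reasons`
#'   columns; attribute `filter_log` holds the per-rule counts.
#' @export
hard_filter <- function(variants) {
  v <- data.table::as.data.table(variants)
  if (!all(v$type %in% c("SNV", "INDEL"))) {
    stop("unknown variant type(s): ", paste(setdiff(v$type, c("SNV", "INDEL")), collapse = ", "))
  }
  lt <- function(x, thr) !is.na(x) & x < thr
  gt <- function(x, thr) !is.na(x) & x > thr
  snv <- v$type == "SNV"
  fail <- list(
    QD = lt(v$QD, 2),
    FS = (snv & gt(v$FS, 60)) | (!snv & gt(v$FS, 200)),
    MQ = snv & lt(v$MQ, 40),
    MQRankSum = snv & lt(v$MQRankSum, -12.5),
    ReadPosRankSum = (snv & lt(v$ReadPosRankSum, -8)) | (!snv & lt(v$ReadPosRankSum, -20)))
  fm <- do.call(cbind, fail)
  v[, filter_pass := rowSums(fm) == 0L]
  v[, filter_reasons := apply(fm, 1L, function(r) paste(names(fail)[r], collapse = ";"))]
  log <- c(colSums(fm), rejected = sum(!v$filter_pass))
  ve_msg("hard_filter: ", log[["rejected"]], "/", nrow(v), " variant(s) rejected")
  attr(v, "filter_log") <- log
  v[]
}

#' Select relevant variants inside vQTL regions
#'
#' Gates variants to those inside any region, then keeps the ones whose
#' most severe consequence affects the protein (missense, frameshift), a
#' UTR, or splicing. Also builds the consequence-class by region count
#' table for all in-region variants (each variant counted once under its
#' most severe class).
#'
#' @param variants filtered table (typically
#'   `hard_filter(...)[filter_pass == TRUE]`).
#' @param regions table with `chrom`, `start`, `end` (one row per region).
#' @return list: `relevant` (variant subset), `in_region` (all in-region
#'   variants with a `region` column), `class_table` (class x region
#'   counts, rows in the conventional reporting order).
#' @export
select_relevant <- function(variants, regions) {
  v <- data.table::as.data.table(variants)
  rg <- data.table::as.data.table(regions)
  stopifnot(all(c("chrom", "start", "end") %in% names(rg)))
  rg_id <- if ("region" %in% names(rg)) as.character(rg$region) else
    sprintf("%s:%.1f-%.1fMb", rg$chrom, rg$start / 1e6, rg$end / 1e6)
  v[, region := NA_character_]
  for (i in seq_len(nrow(rg))) {
    hit <- v$chrom == rg$chrom[i] & v$pos >= rg$start[i] & v$pos <= rg$end[i]
    v[hit & is.na(region), region := rg_id[i]]
  }
  in_region <- v[!is.na(region)]
  cls <- factor(in_region$cons_class, levels = table2_order)
  tab <- table(class = cls, region = factor(in_region$region, levels = rg_id))
  class_table <- data.table::as.data.table(as.matrix(unclass(tab)), keep.rownames = "class")
  class_table[, Total := rowSums(.SD), .SDcols = rg_id[rg_id %in% names(class_table)]]
  relevant <- in_region[cons_class %in% relevant_classes]
  list(relevant = relevant, in_region = in_region, class_table = class_table)
}

#' Classify pooled-line segregation of variants
#'
#' Per line: `absent` when the alternative-allele depth is 0, `fixed` when
#' the reference depth is 0, `segregating` when both are positive —
#' provided total depth reaches `min_depth`, otherwise `no_call`. The
#' overall pattern concatenates the two line calls with segregating lines
#' listed first (e.g. `segregating-in-high/absent-in-low`).
#'
#' @param variants table with low/high ref/alt depth columns (one or more
#'   rows).
#' @param min_depth minimum total pool depth for a call (default 5).
#' @return the table with `low_class`, `high_class`, `pattern` columns.
#' @export
classify_segregation <- function(variants, min_depth = 5L) {
  v <- data.table::as.data.table(variants)
  call1 <- function(ref_d, alt_d) {
    tot <- ref_d + alt_d
    data.table::fifelse(is.na(tot) | tot < min_depth, "no_call",
      data.table::fifelse(alt_d == 0L, "absent",
        data.table::fifelse(ref_d == 0L, "fixed", "segregating")))
  }
  v[, low_class := call1(low_ref_d, low_alt_d)]
  v[, high_class := call1(high_ref_d, high_alt_d)]
  rank <- c(segregating = 1L, fixed = 2L, absent = 3L, no_call = 4L)
  v[, pattern := {
    a <- paste0(low_class, "-in-low"); b <- paste0(high_class, "-in-high")
    data.table::fifelse(rank[low_class] <= rank[high_class],
                        paste(a, b, sep = "/"), paste(b, a, sep = "/"))
  }]
  v[]
}

#' Read gene models from GFF3
#' @param path GFF3 path.
#' @return `data.table`: gene_id, chrom, start, end, strand.
#' @export
read_gff3_genes <- function(path) {
  g <- rtracklayer::import(path)
  g <- g[g$type == "gene"]
  ids <- if (!is.null(g$ID)) g$ID else g$Name
  data.table::data.table(gene_id = as.character(ids),
                         chrom = as.character(GenomicRanges::seqnames(g)),
                         start = GenomicRanges::start(g),
                         end = GenomicRanges::end(g),
                         strand = as.character(GenomicRanges::strand(g)))
}

#' Candidate genes from relevant variants
#'
#' A gene is a candidate when at least one relevant variant lies within its
#' gene span (1-based inclusive, strand-agnostic). Variants whose SnpEff
#' gene id does not occur in the gene models are flagged
#' `annotation mismatch` but still positioned against the spans.
#'
#' @param relevant relevant-variant table from [select_relevant()].
#' @param genes gene table from [read_gff3_genes()] (or a GFF3 path).
#' @return list: `candidates` (gene_id, chrom, start, end, n_variants,
#'   ordered by position) and `variants` (input with `gene_hit` and
#'   `gene_flag` columns).
#' @export
map_to_genes <- function(relevant, genes) {
  v <- data.table::as.data.table(relevant)
  if (is.character(genes) && length(genes) == 1L) genes <- read_gff3_genes(genes)
  g <- data.table::as.data.table(genes)
  v[, gene_hit := NA_character_]
  for (i in seq_len(nrow(g))) {
    hit <- v$chrom == g$chrom[i] & v$pos >= g$start[i] & v$pos <= g$end[i]
    v[hit & is.na(gene_hit), gene_hit := g$gene_id[i]]
  }
  v[, gene_flag := data.table::fifelse(
    !is.na(gene_ann) & gene_ann != "" & !(gene_ann %in% g$gene_id),
    "annotation mismatch", "")]
  cand <- v[!is.na(gene_hit), .(n_variants = .N), by = .(gene_id = gene_hit)]
  cand <- merge(cand, g, by = "gene_id")
  data.table::setorder(cand, chrom, start)
  data.table::setcolorder(cand, c("gene_id", "chrom", "start", "end"))
  list(candidates = cand[], variants = v[])
}
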