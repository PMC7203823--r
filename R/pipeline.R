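#' Pipeline configuration
#'
#' One configuration object drives the full analysis. In simulate mode the
#' inputs are generated by the synthetic-data module; otherwise paths to a
#' litter TSV, a PLINK text prefix, a pooled-line VCF and a GFF3 must be
#' supplied. Every stage threshold is a named key carrying the analysis
#' default: SMR p < 1e-4 (near tier < 2e-4), Bayes factor > 10, 100,000
#' permutations, EMP1 <= 5e-4, 0.5-Mb grouping, +/- 1-Mb padding,
#' r^2 > 0.7, GATK hard-filter expressions and pooled min depth 5.
#'
#' @param outdir output directory (created if needed).
#' @param simulate generate inputs with the synthetic-data module?
#' @param sim list of overrides passed to [sim_config()] (simulate mode).
#' @param litters,geno_prefix,vcf,gff input paths (non-simulate mode).
#' @param p_threshold,p_relaxed,bf_threshold,n_permutations,emp1_max,
#'   group_window_bp,pad_bp,r2_threshold,min_depth stage thresholds.
#' @param bayesb list of overrides passed to [bayesb_config()].
#' @param seed master seed; stage seeds are derived from it.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(outdir, simulate = TRUE, sim = list(),
                            litters = NULL, geno_prefix = NULL,
                            vcf = NULL, gff = NULL,
                            p_threshold = 1e-4, p_relaxed = 2e-4,
                            bf_threshold = 10, n_permutations = 100000L,
                            emp1_max = 5e-4,
                            group_window_bp = 500000L, pad_bp = 1000000L,
                            r2_threshold = 0.7, min_depth = 5L,
                            bayesb = list(), seed = 1L) {
  stopifnot(p_threshold > 0, p_relaxed >= p_threshold, bf_threshold > 0,
            n_permutations >= 1L, emp1_max > 0, group_window_bp > 0,
            pad_bp >= 0, r2_threshold > 0, r2_threshold < 1, min_depth >= 0)
  structure(list(outdir = outdir, simulate = isTRUE(simulate), sim = sim,
                 litters = litters, geno_prefix = geno_prefix,
                 vcf = vcf, gff = gff,
                 p_threshold = p_threshold, p_relaxed = p_relaxed,
                 bf_threshold = bf_threshold,
                 n_permutations = as.integer(n_permutations),
                 emp1_max = emp1_max,
                 group_window_bp = as.integer(group_window_bp),
                 pad_bp = as.integer(pad_bp), r2_threshold = r2_threshold,
                 min_depth = as.integer(min_depth), bayesb = bayesb,
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Read / write a pipeline configuration as YAML
#' @param path YAML path.
#' @param cfg configuration from [pipeline_config()].
#' @return `pipeline_config` (read) or `path` (write).
#' @export
read_pipeline_config <- function(path) {
  do.call(pipeline_config, yaml::read_yaml(path))
}

#' @rdname read_pipeline_config
#' @export
write_pipeline_config <- function(cfg, path) {
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}

pfile <- function(cfg, name) file.path(cfg$outdir, name)

in_path <- function(cfg, key, stage) {
  if (cfg$simulate) return(pfile(cfg, c(litters = "litters.tsv", geno_prefix = "geno",
                                        vcf = "pools.vcf", gff = "genes.gff3")[[key]]))
  p <- cfg[[key]]
  if (is.null(p)) stop("stage ", stage, ": config key '", key, "' is required in non-simulate mode")
  p
}

run_stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop("pipeline stage '", name, "' failed: ", conditionMessage(e), call. = FALSE)
  })
}

stage_simulate <- function(cfg) {
  if (!cfg$simulate) return(invisible(NULL))
  sc <- do.call(sim_config, modifyList(cfg$sim, list(seed = cfg$seed), keep.null = TRUE))
  sim <- simulate_genotypes(sc)
  lt <- simulate_litters(sc, sim$genotypes)
  genes <- simulate_genes(sc)
  data.table::fwrite(lt, pfile(cfg, "litters.tsv"), sep = "\t")
  write_plink(sim$genotypes, pfile(cfg, "geno"))
  write_gff3(genes, pfile(cfg, "genes.gff3"))
  sites <- default_vcf_sites(sc, genes)
  vc <- simulate_pooled_vcf(sites, pfile(cfg, "pools.vcf"), seed = cfg$seed + 2L)
  write_truth_json(list(genotype = sim$truth,
                        vcf_sites = vc$truth),
                   pfile(cfg, "truth.json"))
  invisible(NULL)
}

stage_phenotype <- function(cfg) {
  lt <- data.table::fread(in_path(cfg, "litters", "phenotype"))
  ph <- build_doe_phenotypes(lt)
  write_phenotypes(ph, pfile(cfg, "phenotypes.tsv"))
}

stage_qc <- function(cfg) {
  gs <- read_plink(sub("\\.ped$", "", in_path(cfg, "geno_prefix", "qc")))
  gs <- qc_filter(gs)
  gs <- impute_missing(gs, seed = cfg$seed + 3L)
  write_plink(gs, pfile(cfg, "geno_qc"))
  grm <- compute_grm(gs)
  pcs <- compute_pcs(grm, k = min(5L, nrow(grm$G) - 1L))
  data.table::fwrite(data.table::data.table(id = rownames(grm$G), round(grm$G, 8)),
                     pfile(cfg, "grm.tsv"), sep = "\t")
  data.table::fwrite(data.table::data.table(id = rownames(gs$dosage), pcs),
                     pfile(cfg, "pcs.tsv"), sep = "\t")
}

align_pheno <- function(cfg, gs) {
  ph <- read_phenotypes(pfile(cfg, "phenotypes.tsv"))
  ph[doe_id %in% rownames(gs$dosage)]
}

stage_smr <- function(cfg) {
  gs <- read_plink(pfile(cfg, "geno_qc"))
  ph <- align_pheno(cfg, gs)
  res <- mlma_loco(ph, gs)
  pcs <- as.matrix(data.table::fread(pfile(cfg, "pcs.tsv"))[, -1L])
  rownames(pcs) <- rownames(gs$dosage)
  resw <- weighted_smr(ph, gs, pcs)
  out <- data.table::rbindlist(list(res, resw), use.names = TRUE, fill = TRUE)
  data.table::fwrite(out, pfile(cfg, "smr_results.tsv"), sep = "\t")
}

stage_bayesb <- function(cfg) {
  gs <- read_plink(pfile(cfg, "geno_qc"))
  ph <- align_pheno(cfg, gs)
  bc <- do.call(bayesb_config, modifyList(cfg$bayesb, list(seed = cfg$seed + 4L),
                                          keep.null = TRUE))
  fit <- run_bayesb(ph, gs, bc)
  data.table::fwrite(fit$result, pfile(cfg, "bmmr_results.tsv"), sep = "\t")
  win <- window_variance(fit, gs)
  data.table::fwrite(win, pfile(cfg, "windows.tsv"), sep = "\t")
}

stage_intersect <- function(cfg) {
  smr <- data.table::fread(pfile(cfg, "smr_results.tsv"))[method == "mlma_loco"]
  bmmr <- data.table::fread(pfile(cfg, "bmmr_results.tsv"))
  tiers <- smr_significant(smr, cfg$p_threshold, cfg$p_relaxed)
  bsig <- bmmr_significant(bmmr, cfg$bf_threshold)
  out <- tiers[snp %in% bsig$snp]
  out <- merge(out, bsig[, .(snp, p_hat, bf)], by = "snp")
  data.table::setorder(out, chrom, bp)
  data.table::fwrite(out, pfile(cfg, "candidate_snps.tsv"), sep = "\t")
}

stage_validate <- function(cfg) {
  cand <- data.table::fread(pfile(cfg, "candidate_snps.tsv"))
  if (nrow(cand) == 0L) {
    data.table::fwrite(data.table::data.table(snp = character()),
                       pfile(cfg, "validation.tsv"), sep = "\t")
    return(invisible(NULL))
  }
  gs <- read_plink(pfile(cfg, "geno_qc"))
  ph <- align_pheno(cfg, gs)
  perm <- permutation_test(ph, gs, cand$snp, N = cfg$n_permutations,
                           seed = cfg$seed + 5L)
  eff <- within_population_gwas(ph, gs, cand$snp)
  dec <- ci_overlap_filter(eff, perm, cfg$emp1_max)
  wide <- data.table::dcast(eff, snp ~ population,
                            value.var = c("beta", "se", "ci_low", "ci_high"))
  out <- Reduce(function(a, b) merge(a, b, by = "snp"),
                list(cand[, .(snp, chrom, bp, tier, p, bf)], dec, wide))
  data.table::fwrite(out, pfile(cfg, "validation.tsv"), sep = "\t")
}

stage_regions <- function(cfg) {
  val <- data.table::fread(pfile(cfg, "validation.tsv"))
  passed <- if (nrow(val)) val[pass == TRUE] else val
  if (nrow(passed) == 0L) {
    write_regions(data.table::data.table(chrom = character(), start = integer(),
                                         end = integer(), n_snps = integer(),
                                         anchor_snp = character(), snps = list()),
                  pfile(cfg, "regions.tsv"))
    return(invisible(NULL))
  }
  gs <- read_plink(pfile(cfg, "geno_qc"))
  blocks <- expand_blocks(group_snps(passed, cfg$group_window_bp), cfg$pad_bp)
  smr <- data.table::fread(pfile(cfg, "smr_results.tsv"))[method == "mlma_loco"]
  reg <- define_vqtl_regions(blocks, gs, assoc = smr,
                             r2_threshold = cfg$r2_threshold)
  write_regions(reg, pfile(cfg, "regions.tsv"))
}

stage_screen <- function(cfg) {
  vcf_path <- in_path(cfg, "vcf", "variant_screen")
  gff_path <- in_path(cfg, "gff", "variant_screen")
  if (!file.exists(vcf_path)) stop("variant_screen: VCF not found: ", vcf_path)
  reg <- read_regions(pfile(cfg, "regions.tsv"))
  variants <- read_pooled_vcf(vcf_path)
  variants <- hard_filter(variants)
  sel <- select_relevant(variants[filter_pass == TRUE], reg)
  rel <- classify_segregation(sel$relevant, cfg$min_depth)
  mg <- map_to_genes(rel, gff_path)
  drop_ann <- function(x) x[, setdiff(names(x), "ann"), with = FALSE]
  data.table::fwrite(drop_ann(mg$variants), pfile(cfg, "relevant_variants.tsv"), sep = "\t")
  data.table::fwrite(mg$candidates, pfile(cfg, "candidate_genes.tsv"), sep = "\t")
  data.table::fwrite(sel$class_table, pfile(cfg, "table2.tsv"), sep = "\t")
}

#' Run the full pipeline
#'
#' Executes simulate (optional) -> phenotype -> qc -> smr -> bayesb ->
#' intersect (SNPs significant by both methods) -> validate -> regions ->
#' screen, writing each stage's outputs to `cfg$outdir` and a
#' `manifest.json` listing every file with its md5 hash. Stages communicate
#' through their files only, so a rerun with an identical configuration is
#' bit-identical. Any stage failure aborts with the stage name and cause.
#'
#' @param cfg [pipeline_config()].
#' @return the manifest as a named list (file -> md5), invisibly.
#' @export
run_all <- function(cfg) {
  stopifnot(inherits(cfg, "pipeline_config"))
  dir.create(cfg$outdir, showWarnings = FALSE, recursive = TRUE)
  run_stage("simulate", stage_simulate(cfg))
  run_stage("phenotype", stage_phenotype(cfg))
  run_stage("qc", stage_qc(cfg))
  run_stage("gwas_smr", stage_smr(cfg))
  run_stage("gwas_bmmr", stage_bayesb(cfg))
  run_stage("intersect", stage_intersect(cfg))
  run_stage("validation", stage_validate(cfg))
  run_stage("regions", stage_regions(cfg))
  run_stage("variant_screen", stage_screen(cfg))
  files <- setdiff(list.files(cfg$outdir), "manifest.json")
  manifest <- as.list(tools::md5sum(file.path(cfg$outdir, files)))
  names(manifest) <- files
  jsonlite::write_json(manifest, pfile(cfg, "manifest.json"), auto_unbox = TRUE)
  invisible(manifest)
}

#' Command-line entry point
#'
#' Subcommands: `simulate`, `phenotype`, `qc`, `gwas-smr`, `gwas-bayesb`,
#' `validate`, `regions`, `screen`, `run-all`. Each reads an optional YAML
#' configuration (keys as in [pipeline_config()]) and an output directory;
#' `simulate` and `run-all` additionally require `--seed`.
#'
#' @param args character vector of command-line arguments (default:
#'   `commandArgs(trailingOnly = TRUE)`).
#' @return exit status, invisibly.
#' @export
veqtl_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  cmds <- c("simulate", "phenotype", "qc", "gwas-smr", "gwas-bayesb",
            "validate", "regions", "screen", "run-all")
  if (!length(args) || !(args[1L] %in% cmds)) {
    message("usage: veqtl <", paste(cmds, collapse = "|"), "> [--config cfg.yaml] [--outdir DIR] [--seed INT]")
    return(invisible(1L))
  }
  cmd <- args[1L]
  parser <- optparse::OptionParser(option_list = list(
    optparse::make_option("--config", type = "character", default = NULL),
    optparse::make_option("--outdir", type = "character", default = "veqtl_out"),
    optparse::make_option("--seed", type = "integer", default = NA_integer_)))
  opt <- optparse::parse_args(parser, args = args[-1L])
  cfg <- if (!is.null(opt$config)) read_pipeline_config(opt$config) else
    pipeline_config(outdir = opt$outdir)
  cfg$outdir <- opt$outdir %||% cfg$outdir
  if (cmd %in% c("simulate", "run-all")) {
    if (is.na(opt$seed)) stop("--seed is mandatory for ", cmd)
  }
  if (!is.na(opt$seed)) cfg$seed <- opt$seed
  dir.create(cfg$outdir, showWarnings = FALSE, recursive = TRUE)
  switch(cmd,
         "simulate" = run_stage("simulate", stage_simulate(cfg)),
         "phenotype" = run_stage("phenotype", stage_phenotype(cfg)),
         "qc" = run_stage("qc", stage_qc(cfg)),
         "gwas-smr" = run_stage("gwas_smr", stage_smr(cfg)),
         "gwas-bayesb" = {
           run_stage("gwas_bmmr", stage_bayesb(cfg))
           run_stage("intersect", stage_intersect(cfg))
         },
         "validate" = run_stage("validation", stage_validate(cfg)),
         "regions" = run_stage("regions", stage_regions(cfg)),
         "screen" = run_stage("variant_screen", stage_screen(cfg)),
         "run-all" = run_all(cfg))
  invisible(0L)
}
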