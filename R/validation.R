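#' Permutation empirical p-values for candidate SNPs
#'
#' The phenotype vector is permuted uniformly at random `N` times; the same
#' permutation is applied to every candidate SNP within a replicate. The
#' association statistic is the mixed-model score statistic of
#' [mlma_loco()], with the variance components frozen at their
#' observed-data (leave-one-chromosome-out) estimates — re-estimating them
#' for each of 10^5 permutations is intractable and leaves the null
#' statistic essentially unchanged. `EMP1 = (b + 1) / N`, where `b` counts
#' permutations whose p-value is at most the observed one, capped at 1; the
#' minimum attainable value is `1 / N`.
#'
#' @param pheno phenotype table (`doe_id`, `ve`).
#' @param gs imputed [genotype_set()].
#' @param candidate_snps character vector of SNP ids to test.
#' @param N number of permutations (default 100000).
#' @param seed integer seed.
#' @param block permutations processed per matrix block (default 2000).
#' @return `data.table`: snp, obs_p, b, N, emp1.
#' @export
permutation_test <- function(pheno, gs, candidate_snps, N = 100000L,
                             seed = 1L, block = 2000L) {
  if (N < 1L) stop("N must be at least 1")
  if (!length(candidate_snps)) stop("candidate SNP list is empty")
  stopifnot(inherits(gs, "genotype_set"))
  pheno <- data.table::as.data.table(pheno)
  idx <- match(pheno$doe_id, rownames(gs$dosage))
  if (anyNA(idx)) stop("phenotyped does missing from the genotype set")
  dos <- gs$dosage[idx, , drop = FALSE]
  if (anyNA(dos)) stop("genotypes must be imputed first")
  y <- pheno$ve
  n <- length(y)
  snp_i <- match(candidate_snps, gs$map$snp_id)
  if (anyNA(snp_i)) stop("unknown candidate SNP(s)")
  gs_sub <- genotype_set(dos, gs$map, gs$populations[idx])

  chroms <- unique(gs$map$chrom[snp_i])
  # Per chromosome: whitening from the frozen observed-data LOCO fit, then
  # the residualized whitened SNP vectors. Observed and permuted statistics
  # share the whitening, so comparing p-values equals comparing statistics.
  Zr_all <- matrix(0, n, length(snp_i))
  M_list <- list()
  chrom_of <- gs$map$chrom[snp_i]
  obs_stat <- numeric(length(snp_i))
  for (cc in chroms) {
    grm <- compute_grm(gs_sub, exclude_chrom = cc)
    vc <- estimate_variance_components(y, grm)
    s <- 1 / sqrt(vc$sigma2_g * vc$d + vc$sigma2_e)
    M <- s * t(vc$U)                      # whitening transform
    x0 <- M %*% rep(1, n)
    P <- diag(n) - tcrossprod(x0) / sum(x0^2)
    jj <- which(chrom_of == cc)
    Zt <- M %*% dos[, snp_i[jj], drop = FALSE]
    Zr <- P %*% Zt
    Zr <- sweep(Zr, 2L, sqrt(colSums(Zr^2)), "/")   # unit norm
    Zr_all[, jj] <- Zr
    M_list[[cc]] <- M
    obs_stat[jj] <- drop(crossprod(Zr, M %*% y))^2
  }

  set.seed(seed)
  b <- numeric(length(snp_i))
  done <- 0L
  while (done < N) {
    nb <- min(block, N - done)
    Yp <- vapply(seq_len(nb), function(i) y[sample.int(n)], numeric(n))
    for (cc in chroms) {
      jj <- which(chrom_of == cc)
      Yt <- M_list[[cc]] %*% Yp
      st <- crossprod(Zr_all[, jj, drop = FALSE], Yt)^2   # |jj| x nb
      b[jj] <- b[jj] + rowSums(st >= obs_stat[jj])
    }
    done <- done + nb
  }
  data.table::data.table(snp = candidate_snps,
                         obs_p = pchisq(obs_stat, 1L, lower.tail = FALSE),
                         b = as.integer(b), N = as.integer(N),
                         emp1 = pmin(1, (b + 1) / N))
}

#' Within-population allele substitution effects
#'
#' For each population (base, high, low, ...) a simple least-squares
#' regression of the V_E phenotype on alt-allele dosage, with a shared
#' alternative-allele orientation across populations. Confidence bounds
#' are `beta +/- 2 SE`. SNPs monomorphic within a population have no
#' estimable effect there and are flagged; populations with fewer than 10
#' individuals are flagged low-power but still reported.
#'
#' @param pheno phenotype table (`doe_id`, `ve`, `population`).
#' @param gs imputed [genotype_set()].
#' @param candidate_snps character vector of SNP ids.
#' @return `data.table`: snp, population, n, beta, se, ci_low, ci_high, flag.
#' @export
within_population_gwas <- function(pheno, gs, candidate_snps) {
  stopifnot(inherits(gs, "genotype_set"))
  pheno <- data.table::as.data.table(pheno)
  idx <- match(pheno$doe_id, rownames(gs$dosage))
  if (anyNA(idx)) stop("phenotyped does missing from the genotype set")
  snp_i <- match(candidate_snps, gs$map$snp_id)
  if (anyNA(snp_i)) stop("unknown candidate SNP(s)")
  out <- list()
  for (pop in unique(pheno$population)) {
    rows <- which(pheno$population == pop)
    y <- pheno$ve[rows]
    flag_pop <- if (length(rows) < 10L) "low_power" else ""
    for (k in seq_along(snp_i)) {
      z <- gs$dosage[idx[rows], snp_i[k]]
      if (anyNA(z)) stop("genotypes must be imputed first")
      if (stats::var(z) == 0) {
        out[[length(out) + 1L]] <- data.table::data.table(
          snp = candidate_snps[k], population = pop, n = length(rows),
          beta = NA_real_, se = NA_real_, ci_low = NA_real_, ci_high = NA_real_,
          flag = trimws(paste(flag_pop, "monomorphic")))
        next
      }
      fit <- stats::lm(y ~ z)
      sm <- summary(fit)$coefficients
      beta <- sm["z", "Estimate"]; se <- sm["z", "Std. Error"]
      out[[length(out) + 1L]] <- data.table::data.table(
        snp = candidate_snps[k], population = pop, n = length(rows),
        beta = beta, se = se, ci_low = beta - 2 * se, ci_high = beta + 2 * se,
        flag = flag_pop)
    }
  }
  data.table::rbindlist(out)
}

#' Combine permutation and cross-population evidence
#'
#' A candidate SNP passes when (i) its confidence intervals overlap for
#' every pair of populations — overlap signifies no evidence of a line
#' difference in the allele effect, and an interval that is undefined
#' because the SNP is monomorphic in a population is treated as overlapping
#' (no evidence of a difference) — and (ii) its permutation `EMP1` is at
#' most `emp1_max`. The exact boundary between a passing and failing EMP1
#' is a configurable choice (default 5e-4).
#'
#' @param effects table from [within_population_gwas()].
#' @param perm table from [permutation_test()].
#' @param emp1_max maximum passing EMP1 (default 5e-4).
#' @return `data.table`: snp, emp1, ci_overlap, pass, reasons.
#' @export
ci_overlap_filter <- function(effects, perm, emp1_max = 5e-4) {
  effects <- data.table::as.data.table(effects)
  perm <- data.table::as.data.table(perm)
  snps <- unique(effects$snp)
  res <- lapply(snps, function(s) {
    ef <- effects[snp == s & !is.na(beta)]
    overlap <- TRUE
    if (nrow(ef) >= 2L) {
      for (a in seq_len(nrow(ef) - 1L)) for (b in (a + 1L):nrow(ef)) {
        if (ef$ci_low[a] > ef$ci_high[b] || ef$ci_low[b] > ef$ci_high[a]) {
          overlap <- FALSE
        }
      }
    }
    e1 <- perm[snp == s, emp1]
    e1 <- if (length(e1)) e1[1] else NA_real_
    perm_ok <- !is.na(e1) && e1 <= emp1_max
    reasons <- c(if (!overlap) "line effect difference",
                 if (!perm_ok) "permutation")
    data.table::data.table(snp = s, emp1 = e1, ci_overlap = overlap,
                           pass = overlap && perm_ok,
                           reasons = paste(reasons, collapse = ";"))
  })
  data.table::rbindlist(res)
}
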