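#' Pre-correct litter size for systematic effects
#'
#' Fits one ordinary fixed-effects linear model of total number born (TNB)
#' on year-season and parity-lactation status, pooled over all populations,
#' and appends the residual. The residual is the quantity from which the
#' per-doe environmental-variance phenotype is computed.
#'
#' Factors use treatment coding with the first level as reference. When a
#' factor has a single observed level it drops out of the model, so with one
#' level of each factor the correction reduces to grand-mean centering.
#'
#' @param litters data.frame/data.table with columns `doe_id`, `parity`,
#'   `tnb` (non-negative integer), `yearseason`, `paritylact`, and optionally
#'   `population`.
#' @return A `data.table` copy of `litters` with a `residual` column.
#' @export
precorrect_tnb <- function(litters) {
  litters <- data.table::as.data.table(litters)
  req <- c("doe_id", "parity", "tnb", "yearseason", "paritylact")
  miss <- setdiff(req, names(litters))
  if (length(miss)) stop("litters is missing columns: ", paste(miss, collapse = ", "))
  if (nrow(litters) == 0L) stop("litters table is empty")
  if (anyNA(litters$tnb) || any(litters$tnb < 0)) stop("tnb must be non-negative and non-missing")
  if (anyDuplicated(litters[, c("doe_id", "parity")])) {
    stop("duplicate (doe_id, parity) rows")
  }

  ys <- factor(litters$yearseason)
  pl <- factor(litters$paritylact)
  terms <- c(if (nlevels(ys) > 1L) "ys", if (nlevels(pl) > 1L) "pl")
  df <- data.frame(tnb = as.numeric(litters$tnb), ys = ys, pl = pl)
  fml <- stats::reformulate(if (length(terms)) terms else "1", response = "tnb")
  fit <- stats::lm(fml, data = df)
  out <- data.table::copy(litters)
  out[, residual := stats::residuals(fit)]
  out[]
}

#' Environmental-variance phenotype for one doe
#'
#' Variance of a doe's pre-corrected litter-size residuals about the doe's
#' own mean, with the sum of squares divided by `n + 1` (the minimum
#' quadratic risk divisor) rather than `n - 1`.
#'
#' @param residuals numeric vector of one doe's pre-corrected residuals,
#'   length `n >= 2`.
#' @return Scalar V_E (>= 0).
#' @export
compute_ve <- function(residuals) {
  residuals <- as.numeric(residuals)
  n <- length(residuals)
  if (n < 2L) stop("compute_ve requires at least 2 parities, got ", n)
  if (anyNA(residuals)) stop("residuals contain NA")
  sum((residuals - mean(residuals))^2) / (n + 1)
}

#' Precision weight for a doe's environmental-variance phenotype
#'
#' `w = (n + 1)^2 / (2 (n - 1))`, where `n` is the doe's number of parities.
#' The weight is the inverse sampling variance of the V_E estimator up to a
#' constant and is minimal at `n = 3`.
#'
#' @param n integer vector of parity counts, all `>= 2`.
#' @return Numeric vector of weights.
#' @export
compute_weight <- function(n) {
  if (any(n < 2L)) stop("weights are undefined for n < 2")
  (n + 1)^2 / (2 * (n - 1))
}

#' Build the per-doe phenotype table
#'
#' Runs [precorrect_tnb()] and collapses records to one row per doe with the
#' parity count `n`, the environmental-variance phenotype `ve`, its weight,
#' the doe's mean residual, and the population label. Does with fewer than
#' two parities cannot contribute a within-doe variance and are dropped with
#' a message reporting the count.
#'
#' @param litters litter table as for [precorrect_tnb()].
#' @return `data.table` with columns `doe_id`, `n`, `ve`, `weight`, `xbar`,
#'   `population`.
#' @export
build_doe_phenotypes <- function(litters) {
  lt <- precorrect_tnb(litters)
  if (!"population" %in% names(lt)) lt[, population := "all"]
  n_doe <- lt[, .N, by = doe_id]
  dropped <- n_doe[N < 2L, .N]
  if (dropped > 0L) {
    ve_msg("build_doe_phenotypes: dropping ", dropped, " doe(s) with a single parity")
  }
  ph <- lt[doe_id %in% n_doe[N >= 2L, doe_id],
           .(n = .N,
             ve = compute_ve(residual),
             xbar = mean(residual),
             population = population[1L]),
           by = doe_id]
  ph[, weight := compute_weight(n)]
  data.table::setcolorder(ph, c("doe_id", "n", "ve", "weight", "xbar", "population"))
  ph[]
}

#' Write / read the phenotype table
#' @param pheno table from [build_doe_phenotypes()].
#' @param path output TSV path.
#' @return `path` (write) or a `data.table` (read).
#' @export
write_phenotypes <- function(pheno, path) {
  data.table::fwrite(pheno, path, sep = "\t")
  invisible(path)
}

#' @rdname write_phenotypes
#' @export
read_phenotypes <- function(path) {
  data.table::fread(path, sep = "\t")
}
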