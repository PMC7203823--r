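# veqtl — mapping environmental-variance QTL for litter size

`veqtl` is an R package for mapping loci that control the **environmental
(residual) variance** of litter size — *vQTL* — in populations divergently
selected for high and low variance, and for screening pooled whole-genome
sequence of those lines for putative functional mutations. The environmental
variance of a repeated trait is increasingly read as a **resilience** proxy
in livestock: does with homogeneous litter sizes cope better with
perturbations such as infections, so the genes behind V_E are of direct
breeding interest.

## Who it is for

Quantitative geneticists who have (i) repeated litter records, (ii) SNP-array
genotypes and (iii) optionally pooled line-level sequence, and who want a
tested, reproducible implementation of the V_E GWAS workflow — or who want to
study the workflow's statistical behaviour on simulated data before
committing to it.

## The model in brief

For a doe with pre-corrected litter-size records $x_1,\dots,x_n$
(OLS correction for year-season and parity-lactation), the phenotype is the
minimum quadratic risk variance estimator and its precision weight:

$$V_E = \frac{1}{n+1}\sum_{i=1}^n (x_i-\bar x)^2, \qquad
  w = \frac{(n+1)^2}{2(n-1)} .$$

Two GWAS models are run on $V_E$:

* **SMR** — single-marker mixed model
  $y = \mathbf 1\mu + z_j\beta_j + g + e$, $g\sim N(0,\sigma^2_g G_{-c})$
  with a leave-one-chromosome-out GRM, REML variance components, Wald
  $\chi^2_1$ tests, threshold $p<10^{-4}$;
* **BMMR** — Bayes B,
  $y = \mathbf 1\mu + \sum_j z_j\delta_j\beta_j + e$ with
  $\delta_j\sim\text{Bern}(1-\pi)$, $\pi = 0.999$, judged by the Bayes
  factor $BF = \frac{\hat p_j/(1-\hat p_j)}{(1-\pi)/\pi} > 10$, plus 1-Mb
  window variance partitioning.

SNPs significant by **both** methods are challenged by a 100,000-fold
permutation test ($EMP1 = (b+1)/N$, floor $1/N$) and by within-population
effect comparisons (CIs $\hat\beta \pm 2\,\mathrm{SE}$ must overlap across
lines). Survivors are grouped (0.5 Mb), padded (±1 Mb) and extended into
vQTL regions through $r^2 > 0.7$ LD components. Pooled-line variants inside
the regions are hard-filtered (GATK-style expressions), reduced to
consequences that touch the protein, UTRs or splicing, classified as
absent / fixed / segregating per line from pooled allele depths, and
intersected with gene models to yield candidate genes.

A first-class synthetic-data module simulates the whole world (litter
records with genetically controlled residual variance, LD-structured
genotypes for three populations, pooled VCF + GFF3 with known truth), so
the entire pipeline is testable end to end. See
`vignettes/veqtl-methods.Rmd` for models, assumptions, parameter defaults
and limitations.

## Worked example

One call simulates a cohort (40 base + 60 high-line + 60 low-line does,
4 chromosomes × 60 SNPs, one planted vQTL doubling the residual variance
per alt allele at chr1:3,000,001) and runs every stage:

```r
library(veqtl)
cfg <- pipeline_config(outdir = "demo", seed = 7,
  sim = list(n_chrom = 4, snps_per_chrom = 60, n_base = 40, n_high = 60,
             n_low = 60,
             causal_vqtl = data.frame(chrom = "1", bp = 3000001,
                                      effect = log(2), divergence = 0.3)),
  n_permutations = 999, emp1_max = 0.01,     # desk-scale permutation budget
  bayesb = list(chain_length = 20000, burn_in = 5000, thin = 10))
run_all(cfg)
```

`demo/candidate_snps.tsv` — the SNP found by *both* GWAS methods is the
planted causal SNP (columns trimmed):

```
snp       chrom  bp       beta   se     p           tier    p_hat  bf
snp_1_31  1      3000001  3.717  0.576  1.12e-10    strict  1      Inf
```

`demo/regions.tsv` — its LD region spans the 11 markers downstream
(the simulator's haplotype-copying runs left to right):

```
chrom  start    end      n_snps  anchor_snp
1      3000001  4000001  11      snp_1_31
```

`demo/table2.tsv` and `demo/candidate_genes.tsv` — of the pooled-line
variants inside the region that survive the hard filters, one splice-donor
variant is "relevant" and lands in a gene, which becomes the candidate:

```
class       1:3.0-4.0Mb  Total        gene_id  chrom  start    end      n_variants
splicing    1            1            GENE1_7  1      3372725  3772724  1
intron      1            1
downstream  1            1
```

Interpretation: the allele-substitution effect on V_E is ~3.7 phenotype
units per alt allele (the planted effect doubles the residual variance per
allele); the SNP passes the permutation floor attainable at N = 999 and the
within-line CI overlap; and the pooled screen narrows the region to one
gene carrying a splicing variant that segregates differently between the
lines. With `n_permutations = 100000` (the default) the same SNP attains
EMP1 = 1e-5.

The same stages are exposed as a CLI:

```sh
Rscript inst/cli/veqtl.R run-all --outdir demo --seed 7 --config cfg.yaml
# or stage by stage: simulate | phenotype | qc | gwas-smr | gwas-bayesb |
#                    validate | regions | screen
```

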