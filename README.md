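# gtaccc

Genomic taxometric analysis of continuous and case-control data: does a
clinical disorder sit on the extreme end of a continuous trait's genetic
liability, or does it carry genetics of its own? `gtaccc` answers this by
binarizing a continuous score at many severity cut points, running a GWAS
per cut, and modelling the resulting genetic correlation structure.

The machinery, end to end:

1. **Severity construction** — cut a 0..k symptom score at every integer;
   map each cut's below-cut prevalence to a latent-normal severity score
   `z = Φ⁻¹(π_below)`, so severity is robust to non-interval scaling.
2. **Association scans** — per-variant OLS of each binarized phenotype on
   dosage (observed scale; liability conversion downstream).
3. **Multivariate LD score regression** — for traits *i, j*, regress
   `z_i z_j` on `√(N_i N_j) ℓ/M` with a free intercept (which absorbs
   sample overlap). All k(k+1)/2 cells share one variant set and one
   partition into 200 contiguous blocks; the joint delete-one-block
   estimates give the sampling covariance **V** of all elements of the
   genetic covariance matrix **S** — correlated estimation errors included.
4. **GLS severity trends** — `β̂ = (X′V⁻¹X)⁻¹X′V⁻¹y`,
   `cov(β̂) = (X′V⁻¹X)⁻¹`, where `y` holds selected genetic correlations
   and `X` an intercept plus severity (optionally quadratic, or severity
   distance for the decay analysis).
5. **Severity-factor SEM** — one/two/three correlated factors with
   overlapping anchor patterns (e.g. low = cuts 1–11, high = cuts 2–12 for
   12 cuts), fitted to (S, V) by diagonally weighted least squares with
   sandwich SEs, residual-based χ², CFI, SRMR and AIC = χ² + 2q.

A bundled simulator plants a two-factor severity-gradient architecture
(genetically correlated `rg_fact` between a low- and a high-severity
factor; items mix them by severity rank; an external disorder loads on the
high factor) so every stage is testable without external data; `rg_fact = 1`
recovers the single liability-threshold model as the null world.

## Worked example

```r
library(gtaccc)

panel  <- simulate_genotypes(6000, 1500, n_blocks = 30, r = 0.9,
                             maf_range = c(0.05, 0.5), seed = 1)
truth  <- truth_record(h2 = 0.5, rg_fact = 0.6, K = 0.15, seed = 2)
cohort <- simulate_disorder(simulate_item_phenotypes(panel, truth, seed = 2),
                            seed = 3)

bz <- binarize_scores(cohort$score, 1:12)
ss <- assoc_scan_multi(panel, bz$bin)
ss$disorder <- assoc_scan(panel, cohort$disorder, trait_id = "disorder",
                          pop_prev = truth$K)

ld     <- compute_ld_scores(panel, window = 60)
struct <- multivariate_ldsc(ss, ld, n_blocks = 200)

severity_trend_test(struct, bz$map, external = "disorder")
```

```
Generalized least squares fit (external mode) 
      term    est      se     z         p
 intercept 0.7699 0.16503 4.665 3.087e-06
  severity 0.1463 0.09979 1.466 1.427e-01
```

The intercept says a mid-severity binarization shares rg ≈ 0.77 with the
disorder; the positive slope (+0.15 rg per severity SD) is the planted
gradient — at this small demo scale it is not yet significant (power
analysis in the methods vignette). The underlying correlation estimates
rise from rg ≈ 0.31 at the lowest cut to above 1 (unconstrained estimates)
at the highest. Comparing factor models on the same run,

```r
f1 <- sem_fit_dwls(build_severity_factor_model(12, 1, "disorder"), struct)
f2 <- sem_fit_dwls(build_severity_factor_model(12, 2, "disorder"), struct)
c(AIC_1factor = f1$AIC, AIC_2factor = f2$AIC)
#> AIC_1factor AIC_2factor 
#>    190.2557    158.1529
```

the two-factor model wins, as the planted architecture demands; over the
acceptance experiment's eight seeds at the full demo scale (20,000
individuals, 5,000 variants) it wins in seven.

The whole chain is also available as one call /
`inst/exec/gtaccc pipeline`:

```r
res <- run_pipeline(default_config(seed = 1))   # writes a run directory
```

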