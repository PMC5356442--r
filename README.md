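# clonotrace

Quantifying clonal diversity in phenotypic plasticity from DNA-barcode
lineage tracing.

Cancer cell populations mix epithelial (E) and mesenchymal (M)
differentiation states, and single cells switch between them. When every
founder cell carries a random genomic DNA barcode, sequencing the barcodes
from FACS-sorted E and M fractions measures, clone by clone, the ratio of
progeny in each state — a clone's *phenotypic plasticity*. `clonotrace`
implements the full computational pipeline around that idea:

- **Synthetic data with known truth** — barcode pools, clonal populations
  with log-normally distributed E:M ratios, sorted sequencing libraries
  (mis-sorting, sequencing errors, Phred qualities), flow-cytometry events,
  CNV-structured single-cell expression matrices, and simulator seed
  tables. The `mda157` preset emulates the study population the package
  models (1372 clones, ~60/40 E:M cell split, mesenchymal-biased clone
  majority).
- **Barcode read processing** — quality filtering (`fewer than 6 bases
  under Q25, none under Q15` for sorted-cell libraries), exact-index
  demultiplexing, and iterative-radius error collapse: barcodes seen at
  least twice are traversed in descending abundance and less-abundant
  neighbours within Hamming distance 1, then 2, 3, 4 are merged into their
  parent.
- **Library design math** — sample-coverage complexity estimation
  (`N̂ = D / (1 − f₁/n)`), Poisson multiplicity of infection
  (`m = −ln(1 − f_infected)`), and birthday-problem barcode-collision
  probabilities computed in log space.
- **Clone quantification** — per-library normalization to the sorted state
  fractions, contamination subtraction using post-sort mis-sort rates σ,
  pseudo-value flooring at 1e−6, replicate averaging, fraction epithelial
  `E/(E+M)`, `log2(E/M)`, growth rates in doublings/week, and the Shannon
  entropy of the binned ratio distribution.
- **The study's statistics** — contamination-aware binomial tests for
  bi-lineage potential (upper tail of `Binom(n = r_e + r_m, p = pC)`),
  χ²(1) tests for cell-state bias, Benjamini–Hochberg FDR control,
  permutation tests for ratio stability, and narrow-sense heritability as
  the Pearson correlation between subclone and parental-pool log-ratios.
- **CNV inference from scRNA-seq** — 101-gene sliding-window expression
  profiles along chromosomes, normal-cell baseline subtraction with a 0.3
  dead zone, Ward clustering of cells into clones, subtype/stemness
  scoring against random-gene-set nulls, and Kruskal–Wallis comparisons
  across clones.
- **Treatment scheduling simulator** — tumours of 500 clones with
  clone-intrinsic equilibrium ratios R and doubling times D (15 time
  points per day), exponential growth, equilibrium-preserving state
  switching (20% of cells per division, split so `P(m→e)/P(e→m) = R`), and
  phenotype-selective kills (10-fold selectivity) arranged into
  monotherapy, sequential, and alternating schedules (30-point treatment +
  20-point rest blocks).

Everything is tibble-in / tibble-out and pipe-friendly; fitted objects
have `tidy()` / `glance()` methods and `autoplot()` / `plot_*()`
visualisations.

## Worked example

```r
library(clonotrace)

truth <- gen_mda157_population(seed = 1, n_clones = 300)
pl <- run_pipeline(truth, sort_sim_config(read_depth = 2e5), seed = 2)
pl
#> <clonotype_pipeline>
#>   291 clones across 12 libraries (seed 2)
#> # A tibble: 1 x 8
#>   n_clones frac_bilineage frac_mono frac_biased frac_mes_biased entropy
#>      <int>          <dbl>     <dbl>       <dbl>           <dbl>   <dbl>
#> 1      291          0.935    0.0653       0.887           0.660    3.44
#> # i 2 more variables: mean_stability_rho <dbl>, frac_stable_015 <dbl>
```

291 of 300 simulated clones survive detection filtering; 93% are called
bi-lineage (progeny in both states beyond what mis-sorting explains), 89%
differ significantly from the population state proportions, 66% are
mesenchymal-biased, and the binned log2(E/M) distribution carries 3.4 bits
of entropy.

Heritability of plasticity through single-cell subcloning:

```r
sub <- gen_subclone_experiment(pl$truth, n_subclones = 28, seed = 3)
heritability(
  dplyr::rename(sub[, c("clone_id", "pooled_log2_em")], log2_em = pooled_log2_em),
  dplyr::rename(sub[, c("clone_id", "subclone_log2_em")], log2_em = subclone_log2_em),
  reps = 1e5, seed = 4
)
#> <heritability> rho = 0.8878 over 28 clone pairs, permutation p = 1e-05
```

Alternating phenotype-selective treatments versus the same doses applied
sequentially:

```r
tab <- gen_empirical_clone_table(truth)
seq33 <- run_schedule(tab, schedule_sequential(3, 3), reps = 100, seed = 5)
alt <- run_schedule(tab, schedule_alternating(3), reps = 100, seed = 5)
seq33$surviving$median / alt$surviving$median
#> [1] 540.8
```

At the default per-time-point kill fraction the alternating design leaves
hundreds-fold fewer cells than the sequential design with the identical
total dose; `autoplot()` on either result shows which plasticities each
schedule enriches.

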