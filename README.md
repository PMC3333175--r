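# dupsplice

Does gene duplication substitute for alternative splicing (AS), or do
the two accumulate together? The answer depends on duplication age:
among *recently* duplicated genes (high protein-identity paralogs) AS is
rarer than among singletons, but once *ancient* duplicates are included
the relationship flips and duplicated genes are the AS-richer set —
except for large gene families, which stay AS-poor at every age.
`dupsplice` is a tidyverse-style R package for running that
age-stratified interrogation on paralog, peptide, Ka/Ks, domain, GO and
EST tables, and for simulating cohorts with planted structure to
validate every stage.

## The method in brief

For each identity criterion *t* in a sweep (default >10, >20, >30, >50,
>70, >90 percent):

* a paralog pair (with directional identities id_a, id_b) **qualifies**
  when `max(id_a, id_b) > t` — higher criteria select younger
  duplications;
* qualified pairs are **clustered by single linkage** (connected
  components; families share at least one gene), splitting the genome
  into families (size ≥ 2) and singletons;
* a gene **has AS** when it has more than one known peptide; per
  criterion each gene is labelled `A_F` (all-AS family), `N_F` (no-AS
  family), `MIXED_F`, `A_S` or `N_S` (AS / no-AS singleton);
* the package reports AS proportions and mean isoform counts per
  criterion × family-size bin (`singleton`, `2–4`, `5–7`, `8+`), a
  duplicate-vs-singleton Pearson chi-squared test (Yates-corrected 2×2)
  per criterion, Ka/Ks, protein-length and domain summaries and GO
  category distributions per group, and average EST hits per transcript
  per group (ESTs filtered at ≥ 100 bp and ≥ 95% alignment-region
  identity, each assigned to its best-matching isoform).

A synthetic-data module (`synth_params()` / `simulate_dataset()`)
generates all input tables with planted family structure, age-dependent
AS probabilities and group-tilted feature models, and
`planted_expectations()` provides the matching closed-form AS
expectations per criterion × size bin.

## Worked example

```r
library(dupsplice)

sim    <- simulate_dataset(synth_params(n_genes = 2000, seed = 7))
genes  <- peptides_to_records(sim$genes, sim$peptides,
                              kaks = sim$kaks, domains = sim$domains)
report <- run_pipeline(genes, sim$pairs, go = sim$go,
                       est_alignments = sim$est,
                       isoform_to_gene = sim$isoform_to_gene)

tidy(report, "overall")
#> # A tibble: 6 × 6
#>   criterion n_duplicate n_singleton as_prop_duplicate as_prop_singleton  p_value
#>       <dbl>       <int>       <int>             <dbl>             <dbl>    <dbl>
#> 1        10        1106         894             0.574             0.509  4.16e-3
#> 2        20         889        1111             0.538             0.551  5.87e-1
#> 3        30         693        1307             0.496             0.571  1.74e-3
#> 4        50         366        1634             0.440             0.569  1.04e-5
#> 5        70         132        1868             0.371             0.557  4.94e-5
#> 6        90          29        1971             0.345             0.548  4.63e-2
```

Read across the rows: at the strictest criterion (>90, young duplicates
only) 34.5% of duplicates have AS versus 54.8% of singletons; relaxing
the criterion admits ever older duplications and the duplicate AS
proportion climbs monotonically until, at >10, duplicates (57.4%)
overtake singletons (50.9%) — the planted sign flip, with the
chi-squared p-value significant on both ends and not at the crossover
(>20). `tidy(report, "proportions")` breaks the same numbers down by
family-size bin (the `8+` bin stays AS-poorest throughout),
`tidy(report, "kaks")`, `"length"`, `"domains"`, `"go_mf"`, `"go_bp"`
and `"est"` expose the group-level summaries, `glance(report)` gives a
one-row run summary, and `plot_as_proportion()`, `plot_kaks()`,
`plot_go()` etc. draw the standard figures. `write_report(report, dir)`
emits deterministic TSVs plus a JSON run summary;
`run_pipeline_files()` is the front door for on-disk TSV/PSL inputs.

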