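# hifbindr

Downstream analysis of isoform-specific DNA binding by the heterodimeric
hypoxia-inducible transcription factor (HIF), for epigenomics researchers
working with ChIP-seq of HIF-1α, HIF-2α and HIF-1β (or any α/β heterodimer
with two competing α-isoforms). The package re-implements, as tested and
reusable functions, the analysis ledger such studies rest on:

- **Site definition** — candidate peaks are filtered quantitatively against
  the empirical 99.99th percentile of counts at random accessible background
  regions (nearest-rank, strict inequality), kept only when both independent
  replicates overlap by ≥ 1 bp, and promoted to *canonical* heterodimer sites
  when the α-subunit consensus also overlaps the β-subunit consensus.
- **Stoichiometry** — per-site ratio *r* = (α1 + α2)/β on CPM-normalized
  signal. Canonical heterodimeric binding predicts a tight unimodal
  distribution of *r* around 1; whether apparent deviations are biology or
  noise is decided by correlating each site's log₂ *r* between replicates.
- **Loading dynamics** — cross-condition comparisons (severity/duration of
  hypoxia) with a tertile corroboration test: sites are ranked by the
  α-subunit loading ratio *q* = signal(A)/signal(B), and a genuine
  progressive/early-loading difference must be mirrored by the β-subunit
  (Wilcoxon rank-sum on *q*(β), upper vs lower α-tertile).
- **Knockout contrasts** — paired Wilcoxon signed-rank tests of the surviving
  isoform's binding in wild-type vs knockout cells, per isoform-specificity
  class (*s* = log₂(α1/α2)), testing for compensatory increases.
- **Genomic distribution** — signed nearest-TSS distance profiles per isoform
  compared by a two-sample chi-squared test, including the accessible-motif
  baseline and stratification by cross-cell conservation.
- **Enrichment** — hypergeometric co-binding tests over a finite accessible
  universe, and pre-ranked weighted GSEA with the ranking score
  π = log₂FC × (−log₁₀ p).

Every stage is exercised end-to-end on a **ground-truthed synthetic
generator** (`sim_config()`, `generate_sites()`, `simulate_coverage()`, ...)
that emulates 1:1 α:β site loading with multiplicative replicate noise,
isoform-dependent TSS-distance placement, graded loading across conditions,
knockouts and cell-type-specific repertoires — so the statistics can be
validated against known truth without any external data. Interval I/O covers
BED3/BED6/narrowPeak, bedGraph (+ mapped-read totals), GTF/TSS-BED, GMT and
TSV, with 0-based half-open coordinates throughout.

## Worked example

```r
library(hifbindr)

cfg <- sim_config(n_sites_per_isoform = 500, replicate_cv = 0.2, seed = 42)
ann <- generate_annotation(cfg)
gs  <- generate_sites(cfg, ann)

# site-by-assay CPM matrix from the generator's sampling model
mat <- local({
  m <- data.frame(site_id = gs$truth$sites$site_id)
  for (a in c("alpha1", "alpha2", "beta")) for (r in 1:2)
    m[[sprintf("%s_r%d", a, r)]] <-
      simulate_site_counts(cfg, gs$truth, a, "hypoxia", r)$cpm
  as_site_signal_matrix(m)
})

ratio_distribution(mat)
#> alpha:beta stoichiometry over 1000 sites
#>   median ratio 0.993, mode at log2 0.034, central-98% fold range 2.77

ratio_reproducibility(mat)$r
#> replicate log2-ratio correlation r = 0.014 (noise dominated: TRUE)

nt  <- nearest_tss(gs$sites, ann)
cls <- gs$truth$sites$class[match(nt$site_id, gs$truth$sites$site_id)]
compare_distance_profiles(
  distance_histogram(nt$distance[cls == "isoform1"]),
  distance_histogram(nt$distance[cls == "isoform2"]))
#> isoform TSS-distance chi-squared = 434.7 (df 4), P = 8.76e-93

ranked <- rank_genes(generate_expression(cfg, gs$truth, ann))
gsea_preranked(ranked, nearest_gene_set(gs$sites, ann),
               n_perm = 1000, seed = 1)
#> GSEA: ES = 0.998, NES = 1.881, nominal P = 0.000999 (1000 permutations, set size 895)
```

Reading left to right: with a true 1:1 α:β loading and 20% replicate noise,
the recovered stoichiometry is unimodal with its median at 0.99; the per-site
ratio does **not** reproduce between replicates (r = 0.01), i.e. deviations
from 1:1 are noise, not biology. Isoform-1 sites are promoter-proximal and
isoform-2 sites promoter-distal (chi-squared P ≈ 10⁻⁹³), and the genes
nearest the bound sites are strongly enriched among upregulated genes
(positive ES at the minimum achievable permutation P).

A thin command-line wrapper with `simulate`, `quantify`, `sites`,
`stoichiometry`, `distances`, `gsea` and `overlap` subcommands is installed
at `inst/scripts/hetdimer-chip`.

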