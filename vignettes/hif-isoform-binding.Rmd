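---
title: "Methods: isoform-specific heterodimer binding analysis"
author: "hifbindr"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: isoform-specific heterodimer binding analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hifbindr)
```

# The scientific setting

Hypoxia-inducible factor (HIF) binds DNA as an α/β heterodimer. The two
α-isoforms, HIF-1α and HIF-2α, recognize the same consensus motif yet bind
largely distinct repertoires of sites: HIF-1 promoter-proximally, HIF-2
promoter-distally. Three questions organise the analyses this package
implements: (i) is binding stoichiometric, i.e. does α-subunit ChIP signal
track β-subunit signal site by site in a 1:1 ratio; (ii) do sites load
proportionally as the stimulus (hypoxia severity or duration) increases, or
do subsets load progressively / saturate early; and (iii) are each site's
isoform preference and the isoform-specific distance-to-promoter bias
conserved across conditions, knockouts and cell types?

All coordinates are 0-based, half-open (BED convention); GTF input is
converted on read. Strand is ignored for peak arithmetic and only determines
the sign of TSS distances. Chromosome names match exactly; there is no alias
table.

# Site definition

Candidate peaks from each replicate are filtered quantitatively: a peak is
kept when its total count (per-base coverage summed over the interval) is
**strictly greater** than the empirical 99.99th percentile of counts at
random, fixed-width, non-overlapping background regions drawn from an
accessible-region universe. The percentile is the nearest-rank value at the
smallest rank strictly exceeding `p/100 * N`; at non-integer `p*N/100` this
equals the usual `ceiling(p/100 * N)` rank, and at exact integers it is one
rank higher, which is the reading consistent with requiring an empirical
tail probability strictly below `1 - p/100` for every kept peak. No
interpolation is used, so thresholds reproduce exactly across platforms.
Counts are raw (not length-normalized); background regions have a fixed
width (default 400 bp) so the comparison is fair. This choice is flagged in
the configuration rather than hidden.

Replicate consensus keeps peaks overlapping the other replicate by at least
`min_overlap` bases (default 1) and merges mutually overlapping peaks by
single linkage. Consensus coordinates are the **union span** of the cluster
— a deliberate design choice so that no replicate-supported base is lost;
the summit is inherited from the strongest member peak. One peak overlapping
two partners therefore yields a single clustered site, the same semantics
the cross-condition superset uses. Canonical heterodimer sites are the
α-consensus sites with β-consensus support (α coordinates retained).
Supersets across conditions and conservation analyses across cell lines use
the same single-linkage clustering with per-input membership flags.

# Signal quantification

Signal at a site is the per-base coverage sum over the interval, normalized
to CPM (`count × 1e6 / total mapped reads`) and RPKM (`CPM × 1e3 / width`).
Both are always computed; downstream stages use CPM by default, since the
figure-level analyses are count-per-million based and length normalization
is irrelevant for fixed-width comparisons. Replicates are averaged
arithmetically **after** normalization. Heatmap matrices bin the ±flank
window around each summit (missing summits fall back deterministically to
the interval midpoint) and zero-pad windows truncated by chromosome ends,
flagging them in metadata.

# Stoichiometry statistics

The per-site ratio `r = (α1 + α2 + pc) / (β + pc)` uses a pseudocount
`pc = 0.1` CPM in both numerator and denominator: it prevents division by
zero at weak sites while shifting strong-site ratios negligibly. All ratio
work is on log₂; histograms are log-scaled because the distribution spans
multiplicative variation. Correlations (α-vs-β signal, replicate ratio
reproducibility, cross-condition ratios) are Pearson on log-transformed
values, matching the linear scatter presentation these analyses use; the
reproducibility statistic flags a run as noise-dominated when the
between-replicate correlation of log₂ `r` falls below 0.2 (configurable).
The 1:1 claim is about the mode/median of the distribution, not a fitted
parameter; no calibration between antibody efficiencies is attempted, and
multimodality is deliberately not modelled.

# Dynamics, tertiles and knockouts

Cross-condition comparisons pair replicate-averaged CPM per site; the
per-site loading ratio is `q = (B + pc)/(A + pc)` and the reported mean fold
change is geometric. The tertile corroboration test ranks sites by `q(α)`
(total α), splits them into tertiles whose sizes differ by at most one
(ties broken by site id; extra members go to the lower then middle tertile)
and compares `q(β)` between the upper and lower tertile with a two-sided
Wilcoxon rank-sum test. The corroboration flag requires both `P < 0.05` and
a positive direction. If every `q(β)` is identical the result is `P = 1`
with the flag off, by contract. The test is invariant to globally rescaling
either condition because it acts on ratios of ratios.

Wilcoxon tests (rank-sum and signed-rank) follow a fixed policy: exact
distribution whenever all group sizes are ≤ 25 and there are no ties, and
the normal approximation with tie and continuity corrections otherwise —
so P values reproduce across platforms. Zero paired differences are dropped
(`P = 1` if all are zero). Both are checked against exhaustive enumeration
oracles in the tests.

Knockout contrasts test, per isoform-specificity class, whether the
surviving isoform's binding increases when the other is ablated: a paired
signed-rank test on log₂ CPM reports the two-sided P, the median paired
difference and a one-sided "increase" P. Classes with fewer than five sites
are skipped with a warning. Specificity classes use
`s = log₂((α1 + pc)/(α2 + pc))` with a symmetric threshold of |s| ≥ 1
(2-fold) — the classification rule is standard but its cut-off is not, so
the threshold is a documented default, configurable, and a threshold of 0
legitimately empties the shared class.

# Distance profiles

Each site's summit is assigned the same-chromosome TSS minimising the
absolute distance (verified against an exhaustive scan); the signed distance
is `(summit − TSS) × strand sign`, negative meaning upstream of the gene.
Equidistant TSSs break deterministically towards the lexicographically
smaller gene id and are flagged; sites on chromosomes absent from the
annotation are excluded and reported. The default histogram uses symmetric
log-magnitude bins (0–1 kb, 1–10 kb, 10–100 kb, > 100 kb per side, plus a
dedicated zero bin); the scheme is configurable but chi-squared comparisons
require identical schemes. The two-sample chi-squared test drops jointly
empty bins, merges tail bins pairwise inwards until at least 80% of bins
have expected counts ≥ 5 (or two bins remain), and uses no continuity
correction.

# Enrichment

Hypergeometric co-binding tests operate on a finite universe of accessible
regions: membership of each universe element in the factor and target sets
is ≥ 1 bp overlap, and the upper-tail probability
`P(X ≥ k)` is computed with the exact hypergeometric distribution, with
fold enrichment `(k/n)/(K/N)`. `k = 0` correctly gives `P = 1` (the upper
tail from zero covers all outcomes).

Pre-ranked GSEA ranks genes by `π = log₂FC × (−log₁₀ p)` (zero p-values are
clipped to 1e-300 and logged; ties break by gene id). The running sum adds
`|π|^w / Σ_hits |π|^w` at set members and subtracts `1/(N − N_set)`
elsewhere; the default weight `w = 1` is the weighted enrichment score of
standard GSEA practice. The enrichment score is the **signed maximum
deviation** from zero (the classic convention; chosen where either signed
reading was possible). Because only a pre-ranked list exists, the null model
permutes gene labels (set membership), not phenotypes. The nominal P uses
the add-one rule `(1 + #direction-matched extremes)/(n_perm + 1)` so it can
never be zero, and NES divides ES by the mean of same-sign null scores
(sign-specific normalization; NA when no null score shares the sign).

# The synthetic generator

`sim_config()` defines the study conditions; its defaults are fixed and are
what the test suite and acceptance script run under:

| parameter | default | meaning |
|---|---|---|
| `genome_length` | 2e7 bp | one synthetic chromosome |
| `n_genes` | 2000 | TSSs, uniform spacing with ±45% jitter |
| `n_sites_per_isoform` | 500 | total sites = 2× (specific + shared) |
| `shared_fraction` | 0.25 | intermediate-mixing sites; the conserved core across cell lines |
| `alpha_beta_ratio` | 1 | true total-α : β loading |
| `ratio_log2_sd` | 0 | site-wise systematic stoichiometry spread |
| `replicate_cv` | 0.2 | log-normal multiplicative replicate noise |
| `depth_per_assay` | 2e6 reads | per-track mapped total |
| `progressive_fraction` / `progressive_slope_sd` | 0 / 0.5 | sites with loading `scale^(1+slope)` |
| `isoform1_proximal_sd` | 500 bp | isoform-1 placement around TSSs |
| `isoform2_min_distance` / `isoform2_distal_range` | 5 kb / 100 kb | isoform-2 placement band |
| `site_mean_reads` / `site_load_sdlog` | 200 / 1 | log-normal base loading (~100-fold site-to-site range) |
| `footprint_half_width` | 150 bp | triangular pileup kernel |
| `min_separation` | 1 kb | between summits |
| `expression_effect` / `expression_sd` | 2 / 0.5 | log₂FC of regulated vs null genes |

Isoform-1-specific sites are placed with a normal offset around a random
TSS; isoform-2-specific sites uniformly at 5–100 kb on either side; shared
sites proximally like isoform-1 sites, reflecting the observation that
conserved sites are the most promoter-proximal. Mixing parameters are drawn
from (0.9, 1), (0, 0.1) and (0.25, 0.75) for the three classes, so with
`shared_fraction = 0` no site has an intermediate mixing value. Expected
counts per site are `base loading × condition multiplier × mix` for the α
assays; the β expectation mirrors **total α** divided by the site's true
α:β ratio, so β redistributes with the surviving isoform under knockout —
the structure the corroboration analyses assume. Replicate noise is
log-normal with mean 1 (`sdlog² = log(1 + CV²)`), applied to the site mean
before Poisson sampling; this reproduces scatter-with-correlation at two
nested noise scales. Coverage tracks spread each site's count over its
footprint with a triangular kernel (multinomial draw) and fill the rest of
the depth with uniform background — the simplest null under which the
99.99th-percentile filter is meaningful. Knockouts are per-assay multipliers
in `condition_scales` (e.g. `list(wt = 1, ko1 = c(alpha1 = 0))`).

One master seed drives everything; per-assay/condition/replicate streams
are derived by stable hashing of the labels, so adding an assay never
perturbs the others and identical configurations produce byte-identical
output files. A single `shared_fraction` parameter controls both the
intermediate-mixing class and the cross-cell conserved core: with
`n_cell_lines > 1` shared sites appear in every cell line while specific
sites are unique to one, which is the minimal configuration producing both
a conserved-ratio shared core and cell-specific repertoires.

The generator's regulated-gene truth is computed by an independent
brute-force nearest-gene scan (not the package's nearest-TSS path), so
recovery checks compare two distinct routes.

What the generator does **not** emulate: fragment-level reads, mappability
or GC bias, diploid genomes, peak-shape diversity, chromatin-state
covariates, or correlated (batch) noise between assays. Passing tests
therefore demonstrate correctness of the statistics under the stated
sampling model, not robustness to every artefact of real ChIP-seq.

# Problem sizes and numerical choices in the test suite

Statistical recovery checks run at sizes chosen to make their expectations
sharp while keeping the suite quick: stoichiometry recovery at 2,000 sites
and 2e6 reads per assay; tertile power and type-I at 100 simulations of 150
sites each (power against `progressive_fraction = 0.5`, type-I at 0);
knockout type-I at 200 simulations, scored on the shared-specificity class,
where the surviving isoform has healthy counts — other-specific sites have
near-zero surviving-isoform signal whose discreteness degrades the
signed-rank approximation; distance separation at 500 sites per isoform over
100 runs with a split-half identical-placement control; conservation
recovery at 1,000 sites across two cell lines through the full
coverage → percentile filter → replicate consensus path (background regions
that overlap true sites are excluded from the null sample, as the background
is meant to represent non-bound accessible chromatin); GSEA at 1,000
permutations. Oracle comparisons (hypergeometric enumeration, exact Wilcoxon,
exhaustive GSEA paths, all-pairs interval scans) run at sizes where full
enumeration is feasible. The stand-in peak caller used by the synthetic
pipeline is a smoothed threshold-run scanner with the summit at the maximum
bin; it exists so the pipeline runs end-to-end and makes no claim to
replicate production peak callers.

# Known limitations

- The percentile filter assumes background counts are exchangeable with
  null candidate counts; background regions overlapping real sites inflate
  the threshold and must be excluded by the caller when the universe is
  broad accessible chromatin.
- CPM-vs-RPKM selection is global (config), not per-analysis; both are
  always computed.
- The tertile test's corroboration flag uses a fixed significance level and
  positive-direction requirement; it is a detection rule, not an effect-size
  estimate.
- GSEA's gene-label permutation null ignores inter-gene correlation, as all
  pre-ranked GSEA does; nominal P values are exact only with respect to that
  null.
- Multiple-testing correction across factor panels is limited to optional
  Benjamini–Hochberg on output tables (`p.adjust`); per-factor tests are
  reported as such.
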