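---
title: "From plot reflectance to stay-green haplotypes: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From plot reflectance to stay-green haplotypes: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`staygreen` implements a complete analysis chain for quantifying the
stay-green trait (delayed leaf senescence) in a cereal diversity panel from
multispectral plot reflectance and tracing it to haplotypes. This vignette
explains the models behind each stage, the tunable parameters and their
defaults, what the synthetic-trial generator does and does not emulate, and
the numerical choices made where the design was genuinely open.

## The phenotype: PSRI in thermal time

Among the supported vegetation indices, the plant senescence reflectance
index, PSRI = Red~668~/Blue~475~ − NIR, is the working stay-green indicator:
it tracks the chlorophyll-to-carotenoid ratio, which changes strongly during
senescence, and it rises as plots senesce. Low PSRI therefore means high
stay-green, and "favourable" alleles throughout the package are alleles
associated with *lower* PSRI. NDVI and NDRE are computed with the 842 nm
near-IR band; for PSRI the near-IR band is camera-specific — 740 nm on the
10-band dual camera, falling back to 842 nm on the 5-band MX, which lacks
the 740 nm band (`cameraModel()`). Moving the near-IR band upward has only a
small effect on the index, which is why the fallback is acceptable.

Plot-level values are medians over the pixels whose centres fall inside the
plot polygon. The pixel-centre rule is deterministic and standard for raster
zonal statistics. Plots with fewer than `minCoveragePx = 50` valid pixels
are flagged and excluded rather than given an unreliable median; the
threshold is a package default (poorly covered plots clearly must go, but no
canonical pixel count exists). Reflectance calibration uses the empirical
line method: per band, a least-squares affine fit DN = gain·ρ + offset over
reference panels, inverted for the scene. Calibrated reflectance is clipped
to [0, 1.5] with a warning — modest overshoot above 1 occurs with bright
canopies and imperfect panels and should not abort an extraction.

Phenology is expressed in growing degree days:
each day contributes (clamp(T~min~) + clamp(T~max~))/2 − 4 °C, with `clamp`
mapping into [4, 25] °C, summed from 1 January to the day before imaging
(flights happen in the morning, before the day's heat). Clamping min and max
*separately* is the more literal reading of "values below the lower or above
the upper limit are set to the thresholds"; clamping the daily mean instead
is available via `gddConfig(clampMean = TRUE)`.

## Trial model: split-plot with repeated measures

The field layout is a split-plot: nitrogen level is the main plot, blocks
are replications, cultivars are sub-plots, and imaging dates are repeated
measurements on each sub-plot:

$$Y_{ijkl} = \mu + N_i + B_j + nb_{ij} + C_k + CN_{ki} + cnb_{kij}
          + T_l + TN_{li} + TC_{lk} + TNC_{lik} + \varepsilon_{ijkl}$$

with main-plot error $nb$, sub-plot error $cnb$ (which induces compound
symmetry across dates) and residual $\varepsilon$. PSRI is transformed to
√(PSRI + 10) before fitting so the response is strictly positive and the
variance more homogeneous.

`fitSplitPlot()` produces three things:

1. **Variance components per date** (cultivar $V_C$, interaction $V_{C×N}$,
   residual $V_R$), by expected mean squares for balanced data. EMS is
   method-of-moments and exactly testable against a hand-computed oracle,
   which is why it is the primary estimator; unbalanced data fall back to
   REML via `lme4`. Negative solutions are truncated at zero and flagged.
   The EMS uses the unrestricted mixed-model convention
   (E[MS~C~] = σ² + b·σ²~C×N~ + n·b·σ²~C~), matching what REML converges to
   on balanced data.
2. **Genotype effects** per date and pooled over chosen dates: centred
   cultivar means of the transformed response (`unshrunken`, default), or
   those means multiplied by the date's reliability (`shrunken`, the
   balanced-design BLUP). Both modes exist because "best linear unbiased
   estimates modelled as random effects" is internally ambiguous
   terminology; unshrunken adjusted means are the default since downstream
   association scans rescale effects anyway and shrinkage would only
   attenuate them uniformly in a balanced trial.
3. **A fixed-effect ANOVA** with each term tested against its correct
   stratum (N against the main-plot error, cultivar and cultivar×N against
   the sub-plot error, time terms against the residual), with a
   Greenhouse–Geisser correction applied to the time-stratum tests.
   The epsilon is computed from the covariance of the sub-plot time series
   after centring within N × date cells; classical stratum degrees of
   freedom are used rather than any approximation-based method, keeping the
   tests exactly reproducible.

Reliability of genotype means,
$V_C / (V_C + V_{C×N}/n + V_R/(r\,n))$, uses $n$ = number of N levels and
$r$ = replications. The replicate count enters as blocks × replicates per
block; the package defaults to one replicate per block, i.e. $r$ = number of
blocks (2 in the default design). Genotype effects for association scans are
pooled over the two central senescence dates, where (in both real and
simulated data) genetic variance and reliability peak; the first, pre-heading
date is kept in the model but dominated by noise, and the last date, with
senescence far advanced, is excluded from the repeated-measures model and the
scans.

The relative senescence rate,
RSR = 100·(PSRI~later~ − PSRI~earlier~)/PSRI~earlier~, is computed on raw
(untransformed) PSRI, matching its definition as a percent change of the
index itself. A negative earlier-date PSRI inverts the sign interpretation;
the value is still returned, with a warning.

## Association scan

Markers are filtered before scanning: monomorphic markers out, minor allele
frequency below 3% out, more than 5% missing calls out. The boundaries are
kept (MAF exactly 3% and missingness exactly 5% are retained) because the
discard rules are stated as "below" and "more than". Missing calls are
replaced by the per-marker mean dose, which preserves allele frequencies.
The first three principal components of the centred dose matrix serve as
structure covariates; kinship matrices are deliberately not used — the
covariate structure is PCs plus, in the multi-locus scan, iterative marker
conditioning.

The single-marker scan is OLS of genotype effects on dose plus covariates;
the multi-locus scan is an explicitly simplified iterative-conditioning
procedure in the spirit of modern multi-locus GWAS models (not a
re-implementation of any published algorithm): scan; admit the most
significant marker past the Bonferroni threshold that is not in LD
(r² > 0.7) with an already-admitted pseudo-QTN; rescan conditioning on all
admitted markers; stop when nothing qualifies or after `maxIter` rounds.
Final p-values come from the last rescan, with each pseudo-QTN itself tested
leave-one-out. Multiple testing is controlled by the Bonferroni threshold
α/m and Benjamini–Hochberg adjusted p-values with a 5% FDR cut-off.

PVE is reported as $100 \cdot 2\,\mathrm{MAF}(1-\mathrm{MAF})\,\beta^2 /
\mathrm{Var}(y)$ — the standard allele-frequency-weighted effect-size
summary. Only the functional dependence on effect and MAF is canonical; this
binomial-variance form is the package's fixed choice. On a fully inbred
panel (doses 0/2) the realised dose variance is twice the binomial term, so
the figure understates the realised variance contribution by up to a factor
of two; since the same convention is used everywhere (including the
generator's analytic values), comparisons within the package are consistent.
Marker effects are on the transformed √(PSRI+10) scale, the scale the model
fits.

## Haplotype calling

Around each focal marker the LD block is grown outward over *physically
adjacent* markers in map order, adding markers while their r² with the focal
marker exceeds 0.7 and stopping at the first failure per direction. This
contiguous-run rule is the most literal reading of "adjacent markers with an
LD greater than 0.7"; a gap-tolerant variant (`maxSkip`) exists for sparse
maps. LD is the squared Pearson correlation of dose vectors (composite LD)
— appropriate when phase is unavailable and the panel is essentially
inbred; whether the 0.7 threshold refers to r² or |r| is not canonical, so
the measure is configurable but defaults to r².

Cultivars are clustered on the block's dose sub-matrix by k-means with a
fixed-seed multi-start. k is chosen as the *largest* k ≤ `kMax` (default 6)
for which every cluster keeps at least 5 members, scanned downward, with
k = 1 as the degenerate fallback — the ≥5-member rule is the stated
constraint, the downward scan is the package's completion of it. Clusters
are named by their modal focal-marker allele: `M` + base for the panel-major
allele, `m` + base for the minor; when several clusters share a letter+base,
the largest keeps the bare code and later ones get a `v` suffix. The code
grammar foresees one variant letter; if more than two clusters share a
combination the package emits `v2`, `v3`, … and flags the call. A cluster is
*favourable* when its mean genotype effect lies below the locus mean and the
difference from the remaining cultivars is Welch-significant at α = 0.05.

Effect tests between haplotypes choose their branch from the data: Levene's
test (α = 0.05) decides variance homogeneity; three or more groups get
ANOVA + Tukey letters (homogeneous) or Kruskal–Wallis + pairwise Wilcoxon
letters with Bonferroni adjustment within the locus (heterogeneous; the
pairwise adjustment is a package choice); two groups get Student or Welch
t-tests. Grouping letters come from a greedy assignment over the pairwise
significance graph. Stacking classes combine the favourable flags of three
configured loci in fixed order into labels U-U-U … F-F-F; combinations
outside the canonical nesting (e.g. F-U-F) are labelled literally. The
carrier fraction is the percentage of the stay-green set — the best 25% of
cultivars by pooled genotype effect, size ⌈0.25·N⌉ with stable-by-id tie
breaking — carrying the favourable variant at every configured locus.
Allele-frequency trends per decade use a Kendall-correlation (Mann-Kendall
type) monotone trend test when at least three decades are present.

## The synthetic-trial generator

The generator exists so every downstream stage can be tested against known
ground truth; its defaults describe one fixed study condition, not a dial.

* **Design**: 221 cultivars, three N levels (low = 81, intermediate = 110,
  high = 220 kg N/ha, the low level being bare mineral soil N), two blocks,
  four imaging dates from late May to early July, 7 × 3 m plots.
* **Trajectories**: PSRI follows a four-parameter logistic in thermal time
  (baseline 0.05, asymptote 1.6, N-specific onset 930/1000/1070 GDD and
  rate 0.013/0.0115/0.010 per GDD, low to high N), so senescence starts
  earlier and runs faster under low N. An optional plateau segment pauses
  the rise after onset, reproducing the mid-season stagnation that real
  stay-green cultivars show — senescence need not be sigmoid. The onsets
  are spread widely enough that the faster low-N curve overtakes the slower
  high-N curve well before imaging starts, so mean PSRI is ordered
  low ≥ intermediate ≥ high at every imaging date in the noiseless limit.
  The trajectory parameters themselves are illustrative: no quantitative
  trajectory values are canonical, so they were chosen once to put the
  index range, timing and N separation in a realistic regime for a
  temperate wheat trial.
* **Genetics**: an essentially inbred panel (doses 0/2) with
  origin-by-decade structure groups whose allele frequencies are perturbed
  on the logit scale. Three planted causal loci mirror the motif the
  pipeline is meant to recover: two favourable-*major*-allele loci acting
  across all N levels and one favourable-*minor*-allele locus acting only
  at the lowest dose, whose frequency ramps upward over decades (emulating
  indirect selection). Each favourable allele copy delays the cultivar's
  senescence onset by the locus effect (32, 18, 30 GDD). The leading
  across-N locus is sized to explain about a quarter of the phenotypic
  variance of pooled genotype effects under the default noise levels —
  `plantedPve()` computes the generator's analytic effect and PVE (delta
  method through the logistic and the √(x+10) transform) for exactly this
  comparison. LD blocks are built by copying the causal column with
  per-cultivar re-draws at a rate set so the expected r² decays linearly
  from 1 at the causal position to 0.7 at the block edge.
* **Reflectance**: band values are constructed so that applying the index
  formulas recovers the simulated index values exactly (blue fixed at 0.08,
  near-IR declining with senescence state, red solved from the PSRI
  identity); `renderBandMedians()` solves the same inverse problem for
  arbitrary attainable targets, and `renderPlotRaster()` writes plot-grid
  rasters with polygons for extraction tests. On disk, rasters are 32-bit
  TIFFs with a plain-text world file and a JSON sidecar (band, CRS tag,
  value scaling); values are rescaled into [0, 1] for storage, which limits
  round-trip fidelity to about 10⁻⁶ — far below any effect of interest but
  the reason extraction tests use a small tolerance against written files.
* **Yields**: grain yield is linear in the negative area under the plot's
  PSRI curve with N-specific noise chosen so the per-plot PSRI–yield
  correlation targets −0.8/−0.7/−0.7 (low/intermediate/high N); these
  target magnitudes are generator settings, not claims about any dataset.
  Straw yield follows from a harvest index around 0.45, and NUE divides
  grain yield by soil-available N per m².
* **Seeding**: one master seed; every component derives its own child seed
  deterministically, so identical seeds give byte-identical outputs.

What the generator does **not** emulate: radiative-transfer realism, weather
reanalysis, camera differences beyond the near-IR band switch, spatial field
trends, heading-date variation, or linkage beyond the planted blocks
(background markers are exchangeable given their structure group). Passing
tests therefore demonstrate that the statistical machinery recovers planted
structure of realistic size and direction — not that any particular field
dataset would yield the same numbers.

## Numerical choices and degenerate inputs

* Variance components: negative EMS solutions truncated at 0 and flagged;
  all-identical observations give all-zero components; designs with a
  single N level *and* a single block are rejected as inestimable.
* Greenhouse–Geisser epsilon is clamped into [1/(t−1), 1]; with two time
  points it is exactly 1; covariance estimation requires more subjects than
  time points.
* k-means uses 25 restarts under a derived seed; cluster labels are
  relabelled by decreasing size so calls are deterministic.
* Modal-allele ties in haplotype naming break towards the major allele and
  are flagged; stay-green-set boundary ties break by cultivar id and are
  flagged.
* The scan marks markers collinear with the covariates (p set missing)
  instead of failing; covariate matrices without rownames are assumed to be
  in phenotype order.
* CRS handling is deliberately minimal: rasters and polygons must carry the
  same CRS tag; mismatches are an error, never an implicit reprojection.
* The pipeline demo sizes (221 cultivars × 1500 markers, four dates) were
  chosen so a full run, including both scans and haplotype calling,
  completes in well under a minute on a single core while leaving every
  planted signal comfortably detectable.

## Known limitations

* The EMS estimator assumes balance; the REML fallback handles moderate
  unbalance but the two differ slightly by construction.
* No standard error is reported for reliability.
* PVE on inbred panels is conservative (see above).
* The multi-locus scan is a transparent approximation to published
  multi-locus GWAS models and will differ from them in marker selection on
  real data, particularly for loci near the significance boundary.
* Haplotype calls depend on the k-selection rule where the true number of
  groups is ambiguous; with noisy blocks and generous `kMax` the clustering
  legitimately sub-splits groups, which fragments codes (the `v` variants).
* The GeoTIFF support is a minimal planar-raster reader/writer (TIFF +
  world file + JSON sidecar); it does not read arbitrary third-party
  GeoTIFF tags.

## Command-line use

The package functions are the primary interface; `runPipeline()` +
`pipelineConfig()`/`readPipelineConfig()` orchestrate the stages
(simulate → extract → gdd → fitmodel → gwas → haplotypes) with per-stage
CSV outputs carrying provenance headers (stage, seed, config fingerprint).
A thin Rscript wrapper, `inst/scripts/staygreen-pipeline.R`, exposes the
same entry point to the shell; individual stages are plain function calls
and are idempotent given unchanged inputs.
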