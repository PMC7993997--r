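---
title: "Models and methods behind riboflux"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind riboflux}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

riboflux is a downstream analysis toolkit for yeast ribosome-profiling
experiments that probe 40S ribosome recycling and initiation competition.
This vignette explains the models it implements, the choices made where the
design was genuinely open, and what its synthetic-data generator does and
does not emulate. Every empirical claim here is one the package's test suite
or `scripts/acceptance.R` recomputes; nothing is quoted from external data.

## Coordinate conventions

All positional analyses run in 0-based, half-open transcript coordinates,
5'→3', with position 0 at the 5' cap. The CDS starts at `utr5_len` and
*includes the stop codon*, so the stop codon's first nucleotide is
`utr5_len + cds_len - 3`. Every module obtains stop positions through the
accessors `stop_codon_first()` / `stop_codon_last()` rather than re-deriving
them — one convention, one encoding, no off-by-one drift. GFF3 (1-based
inclusive) and BED12 (0-based half-open) are converted at the I/O boundary
only; U is canonicalized to T on input. Per-nucleotide tracks are assumed to
be P-site assigned upstream; `psite_from_5p()` offers the conventional yeast
+13 nt offset for 25–34 nt footprints recorded by their 5' ends, overridable
per read length, because published offset tables differ between labs.

## Stop-codon metagene and the queuing peak

`metagene_at_stop()` averages footprint density around stop codons. Each
transcript's window counts are divided by that transcript's mean CDS per-nt
density and transcripts are averaged with equal weight at each offset, so a
handful of very highly expressed genes cannot dominate the profile and the
result is invariant under scaling any library's counts (a pooled raw-count
mode is available behind `pooled = TRUE`). Transcripts shorter than the
window contribute only the offsets they define — masking, never zero
padding, which would bias means downward. Defaults: window (−60, +90) nt
around the stop-codon start and `min_cds_counts = 64`, enough counts that a
single transcript's shot noise does not dent the profile.

`detect_queue_peak()` takes the argmax over a search window upstream of the
stop (default offsets −50..−10, ties resolved to the most upstream offset)
and reports enrichment over a disjoint local CDS background (default
−60..−51). A call of "queued" requires enrichment > 1.5. Only the queue
peak has a detection contract; the stop-codon peak itself varies between
experiments and is left uncalled.

The 3'UTR reinitiation statistic `utr3_orf_ratio()` is
`(3'UTR counts + 1) / (CDS counts + 1)`: one pseudocount added to both raw
sums so the log ratio is always defined. A per-nucleotide density mode is
available; raw counts are the default because the pseudocount then has the
conventional "one read" interpretation.

## Differential translational efficiency

TE inference re-implements the multi-factor negative-binomial design in
which RNA-seq and Ribo-seq libraries enter one model. Per gene:

$$\log \mu_{j} = \log s_j + \beta_0 + \beta_A\,[\text{RPF}] +
\beta_C\,[\text{perturbed}] + \beta_I\,[\text{RPF} \wedge \text{perturbed}]$$

TE is the RPF effect against the RNA baseline, so the interaction
$\beta_I/\ln 2$ is the change in log2 TE between conditions. The stages:

* **Filter** — genes with fewer than 10 total mRNA reads over the four RNA
  samples are removed before anything else.
* **Size factors** — median-of-ratios over genes positive in every library,
  rescaled to geometric mean 1.
* **Dispersions** — per-gene method-of-moments estimates from within-cell
  normalized means and variances, pooled over the four design cells, then
  shrunk toward a robust 1/μ trend. Three details matter for calibration,
  all discovered by measuring the null behaviour of the fitted Wald tests:
  (1) the robust trend fit centers on the *median* of the right-skewed
  moment estimates, so it is recentered on their unbiased mean (a
  through-origin rescale); (2) a non-positive moment estimate carries no
  information beyond shot noise, so such genes take the trend value rather
  than being log-shrunk toward an arbitrary floor; (3) the shrink weight is
  empirical-Bayes, `prior/(prior + sampling)` with the sampling variance of
  a log dispersion at `trigamma(df/2)` and the prior (between-gene) variance
  floored at 0.25². With two replicates per cell the per-gene estimates
  carry ~4 degrees of freedom, so the weight is small and dispersions lean
  on the trend — exactly why the null p-values come out uniform. A fixed
  weight is available via `shrink_weight` for users who want the simpler
  scheme.
* **Fit** — IRLS with the fixed-theta negative-binomial family
  (`stats::glm.fit` + `MASS::negative.binomial`), Wald z on the interaction,
  two-sided normal p, Benjamini–Hochberg FDR over converged genes, and
  classification up/down at FDR < 0.05.

Cox–Reid adjusted dispersion likelihoods, MAP shrinkage with estimated prior
width, and Cook's-distance outlier handling are deliberately *not*
re-implemented; the moment scheme above is transparent and, on data of this
design, calibrated (null KS against U(0,1) passes; ~95% power on a planted
log2 effect of +1 at mean counts ≥ 200 — both recomputed by the acceptance
suite). One limit worth knowing: multiplying one library's counts by a
constant is absorbed *exactly* by the size factors, but a library with
scaled counts genuinely carries different Poisson information, so IRLS
weights and standard errors move slightly — no NB likelihood method is
exactly invariant, and the tests assert statistical rather than bitwise
stability for that case.

`naive_te()` (log2 of pseudocounted mean normalized RPF over RNA, per
condition) is the descriptive statistic used for basal-TE features and CDF
plots; the GLM always works on raw counts.

## uORF calling and relative ribosome occupancy

`enumerate_candidates()` scans 5'UTRs for AUG and the nine single-mismatch
near-cognate starts (GUG, UUG, CUG, AUA, AUU, AUC, ACG, AGG, AAG), extending
in frame to the first stop codon. Candidates must terminate wholly inside
the 5'UTR (uORFs overlapping the main CDS are discarded), span at least 3
codons including the stop, and start at position ≥ 3 so a −1 triplet
exists.

The translation-calling cascade reads the published filters with codon-width
windows: `plus1` sums the start codon's 3 nt and `minus1` the 3 nt upstream
(single-nt windows available by flag; codon windows are robust to P-site
offset error). Filters, all strict inequalities as printed: ratio
`plus1/minus1 > 4` (when `minus1 == 0`, zero upstream signal is the
strongest start evidence, so pass iff `plus1 > 4`), combined counts `> 14`,
zero-frame fraction `> 0.5`. The trained-classifier step is replaced by a
deterministic surrogate built from the same two features it uses: the score
is `sqrt(f0_hat × PME)`, with `f0_hat` the frame fraction rescaled so 1/3
(random) maps to 0, and `PME` the entropy of per-codon counts over
`log(n_codons)`; the same 0.5 probability threshold applies. No trained
weights are shippable, and on synthetic tracks the surrogate's translated
set equals an independently coded straight-line implementation of the
filter cascade (an acceptance check).

RRO is footprints in a uORF over footprints in its main CDS, both on
interior windows that dodge initiation/termination peaks: the CDS window
drops its first 20 codons and the stop codon; the uORF window is its sense
codons minus the first and last, i.e. codons 2..(n−2) of the uORF — the
reading under which a 3-codon uORF has nothing left and is excluded, which
is the stated degenerate case. Positions in the 5'UTR's first or last
triplet are additionally masked (a defensive no-op under the candidate
geometry invariants). Differential RRO excludes uORFs with mean uORF counts
< 2 or mean CDS counts < 32 over the four RPF samples, then reuses the
interaction GLM with region (uORF vs CDS) in the assay slot, so log2 dRRO is
the region × condition interaction. Calling translated uORFs on tracks
pooled over *all* RPF libraries keeps the selection symmetric between
conditions; selecting on one condition's tracks biases the subsequent
contrast, which is visible as a non-uniform null.

## mRNA features

The AUG context score is the geometric mean of relative-adaptiveness weights
at −3, −2, −1 and +4 around the main AUG (A of AUG = +1), computed in log
space. `build_weight_matrix()` reconstructs weights from any reference set
of contexts — per-position base frequencies normalized to the most prevalent
base, with unobserved bases floored at 10⁻³ so the geometric mean never
annihilates. The published reference matrix (from ~270 highly expressed
genes) is not reprinted anywhere we can bundle, so numeric equality with
published scores is not asserted; the analysis scripts instead rebuild
weights from the ~270 best-translated genes of the dataset at hand.

Group-vs-all comparisons use two-sided Kolmogorov–Smirnov and Mann–Whitney U
tests of the group against all mRNAs (group included, matching the CDF-plot
convention). Feature associations use Spearman rank correlations; both are
therefore invariant under monotone transforms. Clustering is
complete-linkage on Euclidean distances (the `hclust` default), with rows
pre-sorted by gene id so distance ties break deterministically and row
permutation cannot change the tree. CDS-length pentiles are equal-size rank
bins with gene-id tie-breaks.

## The competition model

The Discussion-level claim — a limiting 43S PIC pool reprograms relative TE
in favour of strong mRNAs — is made computable with the minimal saturable
form. mRNA $i$ initiates at

$$J_i(P) = J^{max}_i \frac{K_{1,i}\,P}{K_{1,i}\,P + J^{max}_i},$$

the Michaelis-type flux in the free-PIC level $P$: at small $P$ flux is
$K_1 P$ (weak mRNAs lose proportionally), at large $P$ it saturates at the
elongation-limited packing flux $J^{max}$ (strong mRNAs are buffered; the
elasticity identity $d\log J/d\log P = 1 - J/J^{max}$ is verified
numerically in the tests). The free pool closes by conservation,
$P + \sum_i m_i L_i J_i(P) = R_{total}$, solved by bisection — the left side
is continuous and strictly increasing from 0, so bracketing is guaranteed
and no derivative bookkeeping is needed; the residual tolerance is
$10^{-10} R_{total}$ and the scalar case matches the closed-form quadratic
to machine precision. Model TE is flux per mRNA molecule, matching the
density interpretation of profiling TE, and relative TE divides by the
abundance-weighted mean so its abundance-weighted mean is exactly 1 — which
is why a uniform loss of initiation (all $K_1$ equal) changes nothing, and
why with uniform $J^{max}$ the change in log2 relative TE under pool
shrinkage is strictly increasing in $K_1$. Whether 3'UTR-sequestered 40S
subunits should shrink $R_{total}$ or appear as occupancy $L$ is left to the
user; $R_{total}$ is the single exposed lever.

## The synthetic-data generator

The generator is first-class, tested code: it encodes the study conditions
so every stage is testable offline. Defaults: 2000 genes, 2 replicates × 2
conditions × 2 assays; lognormal CDS lengths (median ≈ 1.2 kb); geometric
UTR lengths (medians 60 / 120 nt); abundances log-uniform over
log₁₀ ∈ [0.5, 3]; basal TE lognormal and negatively coupled to CDS length
(rank correlation ≈ −0.5, the short-CDS/high-TE structure of the real
attribute tables); NB dispersion α = 0.01, matching the near-perfect
replicate reproducibility (Pearson r ≈ 0.99) these libraries show; library
size factors log-uniform in [0.5, 2] to exercise normalization; 15% of
genes carry 1–2 planted uORFs (AUG or near-cognate) with frame-0 fraction
0.7 and an elevated start codon; the stop codon is enriched 4-fold in both
conditions; the perturbed condition adds a 4-fold queue peak on the codon
centered 30 nt upstream of the stop (one ribosome footprint) and a 4-fold
elevated 3'UTR rate (0.01 → 0.04 per nt relative to CDS density).

Choices worth flagging:

* RPF totals are drawn NB per gene and then spread multinomially over the
  CDS, so positional CDS sums equal the count-matrix cells *exactly* —
  conservation is an invariant, not an approximation.
* The queue codon's weight is center-heavy (½, 2, ½ × enrichment): a stalled
  80S has one P-site, so the planted peak is sharp at the center nucleotide
  and metagene argmax lands on −30 rather than anywhere within the codon.
* Extra-CDS reads (uORFs, UTR background) follow the *expected* CDS density
  with one independent Gamma(mean 1, var α) multiplier per region and
  library: every region is marginally NB at the study dispersion and regions
  are independent. Tying them to the realized CDS total instead couples
  uORF and CDS noise, which makes the region × condition test conservative —
  measured, and the reason for this design.
* One L'Ecuyer-CMRG stream per library at a fixed index
  (`parallel::nextRNGStream`), so adding replicates or libraries never
  perturbs earlier draws, and a fixed seed reproduces every byte.

What the generator does **not** emulate — and hence what green tests do not
establish about real data: sequence-dependent elongation pausing, codon-level
periodicity within the CDS, batch effects between replicates, coupling of TE
to start-codon context or 5'UTR structure (context-score and UTR-length
correlations are null by construction here), uORF effects on downstream CDS
TE, 3'UTR length biology, or raw-read artifacts upstream of P-site counts
(alignment, rRNA contamination, unique-mapping filters are all out of
scope).

## Problem sizes and numerics

The test and acceptance workloads run at sizes chosen to make the
statistical assertions sharp but cheap: 2000 genes for count-level recovery
and calibration checks, 500–700 transcripts with positional tracks for
cascade/RRO checks, 600 transcripts × 20 seeds for queue-peak recovery, 80
genes for end-to-end pipeline determinism. Numerical tolerances: bisection
residual 10⁻¹⁰·R, context-score oracle agreement 10⁻¹², elasticity check
10⁻⁶ by central differences, GLM convergence at `glm.fit` defaults with 50
iterations and non-converged genes flagged and excluded from the FDR
denominator. The analysis scripts under `analysis/` narrate a 1000-gene
end-to-end run; its bulky intermediate dataset lives under `scratch/` and is
regenerated on demand.

## Known limitations

* The Wald test is slightly liberal in extreme tails for very low counts;
  the LRT is not offered.
* Dispersion trend fitting assumes a 1/μ shape; strongly non-monotone
  mean-dispersion relationships would be tracked only through the per-gene
  component.
* The competition model is deterministic and mean-field: no TASEP-style
  ribosome traffic, no closed-loop/length feedback.
* Spliced transcripts are out of scope: annotation must be single-block in
  transcript space.
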