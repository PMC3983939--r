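---
title: "Quantifying shRNA efficacy with a single-cell ratiometric reporter assay"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying shRNA efficacy with a single-cell ratiometric reporter assay}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ratiokd)
```

## The assay and its model

RNA interference screens need a fast readout of how well each candidate
short hairpin RNA (shRNA) silences its 19-nt target. The assay this
package quantifies answers that with two fluorescent-protein plasmids
co-transfected into cultured cells: a green reference (EGFP, on the same
plasmid that expresses the shRNA) and a red reporter carrying the 19-nt
target proxy in its 3'-UTR. If the shRNA recognises the target, the red
reporter is degraded while the green reference is not. Because the two
cassettes share promoter and polyadenylation signals, red output is
proportional to green output in every cell over decades of expression
level, so the per-cell ratio

$$ R/G = \frac{\text{mean red} - \text{red background}}
             {\text{mean green} - \text{green background}} $$

is a per-cell measure of remaining target that cancels the huge
cell-to-cell variation of transient transfection.

The knockdown index compares the test arm (candidate shRNA + cognate
reporter) with a control arm (empty vector + same reporter):

$$ \mathrm{KD} = 100 \cdot \frac{m_\mathrm{test}}{m_\mathrm{control}}
   \cdot \delta \quad [\%] $$

where $m$ is the **median** R/G over transfected cells. 0% means no
remaining target (strongest knockdown); 100% means none. The median is
essential: under active RNAi the R/G distribution is strongly skewed by
a minority of RNAi-insensitive cells with unusually bright red, which
drag the mean but barely move the median. These outliers are reported
(share of ratios above median + 3 IQR) but never removed.

Hairpin insertion can lower the EGFP output of the shRNA plasmid, which
rescales every test-arm ratio. The correction coefficient $\delta$ is
measured with a scrambled-target reporter, for which genuine knockdown is
impossible: we define

$$ \delta = \frac{m_\mathrm{scramble,control}}{m_\mathrm{scramble,test}}, $$

the unique scalar that makes the scrambled experiment's own KD read
exactly 100%. `compute_kd_index()` keeps this self-normalisation exact by
evaluating the corrected index in product form, avoiding intermediate
rounding. When the shRNA, the green reference and the red reporter are on
three separate plasmids the green reference is identical in both arms,
so `mode = "three_plasmid"` fixes $\delta = 1$.

Uncertainty is quantified with a percentile bootstrap (default 2000
replicates, seeded): cells are resampled within each arm — and within
both scramble arms when $\delta$ is estimated — and the KD recomputed.
The per-experiment CI complements `aggregate_kd()`, which summarises
independent experiment repeats as mean ± SD, the form used for bar-graph
reporting across 2–3 repeats.

## Image analysis

Nuclei are the measurement compartment: expressed fluorophores fill the
cell, but the DNA stain defines crisp, well-separated regions.

1. **Threshold** (`compute_dna_threshold`). Manual mode reproduces any
   externally chosen value. Quantile mode operationalises the protocol
   rule — choose the threshold so that ~95% of stained material lies
   above it — by first separating foreground with a global two-class
   Otsu criterion, then returning the intensity below the
   `(1 - retain_quantile)` fraction of foreground pixels. The returned
   value sits halfway between adjacent observed intensities so that at
   least the requested fraction lies *strictly* above it, matching the
   strict `>` rule used for region growth.
2. **Regions** (`segment_nuclei`). ROIs are the 8-connected components
   of pixels strictly above the threshold. 8-connectivity is the
   standard blob-detection choice and absorbs diagonal speckle. Labels
   are consecutive integers in raster order of each component's first
   pixel, so outputs are reproducible across runs and implementations.
3. **Filter** (`filter_nuclei`). ROIs are kept when area lies in a
   closed interval (default 1.1–2.7 µm², the printed protocol range for
   Rat2 nuclei) and eccentricity is at most 0.95. The printed range is
   unusually small for mammalian nuclei — it is treated as a
   configurable default consistent with the synthetic scenes' optical
   calibration, not as a biological assertion. There is no watershed
   splitting: the assay's cell line is chosen for well-separated,
   homogeneous nuclei, and merged (oversized) clumps fall to the area
   ceiling.
4. **Background** (`estimate_background`). A per-channel scalar: the
   mean of per-nucleus mean intensities over an untransfected sample,
   measured in the same nuclear compartment as the signal. The SD of
   those per-nucleus means is kept for gating.
5. **Measurement and gating** (`measure_cells`, `gate_transfectants`).
   Per-ROI channel means minus background, clamped at zero (intensities
   are physical). Transfectants are cells with background-subtracted
   green strictly above a gate: either a preset value or
   `k_sd` (default 3) untransfected-green SDs above zero. Gated-out
   cells have undefined R/G and are excluded, never zero-filled.

Numerical conventions: intensities are processed as floating point
regardless of stored bit depth; pixel coordinates are row-major; equal
thresholds exclude (strict inequalities) while the area interval is
closed; degenerate inputs (constant images, zero-variance linearity
input, empty arms) raise errors rather than returning silent NAs.

## The synthetic-data generator

`generate_scene()` and `generate_experiment()` emulate exactly the
structure the method relies on, with per-cell ground truth:

* per-cell expression $E \sim \mathrm{LogNormal}(\mu = 5, \sigma = 1)$
  (arbitrary units), spanning the decade-wide range over which the
  green–red coupling must stay linear;
* noise-free green $= a E f$ and red $= b E (1 - k)$ in transfected
  cells (gains $a = b = 1$), zero otherwise — so control scatter lies
  exactly on the line red $= (b/a) \cdot$ green;
* a fraction (default 2%) of transfected cells is RNAi-insensitive
  ($k$ treated as 0), reproducing the bright-red outlier tail with the
  simplest mechanism; while that fraction is below one half it leaves
  the noise-free median untouched, so the generator-predicted corrected
  KD is $100(1-k)$ (`predicted_kd()`);
* the GFP bias $f$ (test condition only) models the reduced EGFP output
  of hairpin-bearing plasmids; $\delta$ should recover $f$;
* nuclei are non-overlapping rotated ellipses, areas uniform in
  1.3–2.5 µm² at 0.1 µm/pixel, eccentricity up to 0.7; the DNA stain is
  centre-bright with a ~40% falloff to the rim, so an intensity
  threshold erodes dim rims instead of deleting whole dim nuclei;
* noise: optional Poisson shot noise on signal, Gaussian read noise
  (SD 5), constant offset (100) per channel, rounding to integer camera
  counts and 16-bit clipping. With all noise off, images are exact and
  every downstream identity holds to machine precision;
* default field: 512×512 px, 150 cells, 50% transfection — a realistic
  transient-transfection efficiency; validation experiments in the
  tests and the acceptance script use 600×600 px fields of 250 cells,
  four per arm, giving ≈500 transfected cells per arm, the scale at
  which the protocol collects >300 cells per sample.

The generator does **not** simulate optics (PSF blur, chromatic shift),
cytoplasm, illumination gradients, bleed-through, or touching nuclei.
Passing its tests therefore demonstrates the correctness of the
measurement and statistics pipeline under the assay's own assumptions —
not robustness to every real-microscope artefact, which is why manual
threshold and preset-gate modes exist for real data.

Probabilities the spec leaves open (outlier fraction 2%, GFP bias
magnitude, expression dispersion) are free parameters with defaults
chosen once for realism; they are printed into every manifest so a run
is self-describing. All randomness flows from a single seed through
per-field substreams; identical parameters and seed give bit-identical
images, tables and result JSON.

## Oligonucleotide design

`design_shrna_oligos()` emits the four-oligo hairpin insert
(sense–loop–antisense–TTTT terminator, loop `GCTTCCTGTCAC` from human
miR23); `design_reporter_oligos()` the two 23-nt reporter-insert oligos;
`control_shrna_oligos()` the verbatim negative-control pair (whose
`TTCAAGAGA` loop differs by design). The printed templates describe the
antisense arm as the target's "complementary sequence"; it is realised
as the **reverse** complement, the only reading under which the strands
anneal and the transcript folds into a stem-loop. `validate_hairpin()`
audits duplex complementarity, hairpin structure, terminator presence
and the directional (anti-tandem) overhang logic: the internal junction
overhangs and the terminator-side extension must be non-palindromic and
mutually incompatible, while the 5' `GATC` extension is
self-complementary by construction (it mates a BglII-cut vector end) and
is reported, not failed — directionality at that end is enforced by the
vector. Sequences are DNA-only; no thermodynamic scoring or efficacy
prediction is attempted.

## Worked example

```{r example, eval = FALSE}
params <- scene_params(image_shape = c(600L, 600L), n_cells = 250L,
                       knockdown_efficiency = 0.95,
                       outlier_fraction = 0.02)
ex <- generate_experiment(params, n_fields_test = 4, n_fields_control = 4,
                          seed = 101)
res <- kd_from_experiment(ex$test, ex$control, ex$untransfected,
                          n_boot = 500, seed = 101)
res
predicted_kd(params)$kd_corrected_percent  # 5: the planted remaining target
plot(res)                                  # paired R/G histograms
```

## Known limitations

* The automatic threshold assumes a bimodal DNA-intensity histogram; a
  field dominated by debris or empty of cells raises an error instead
  of guessing.
* δ is estimated per scramble pairing; whether one δ may be reused
  across targets sharing a vector is left to the user.
* KD values above 100% (possible by sampling noise) are reported as-is.
* The bootstrap quantifies within-experiment sampling error only;
  between-experiment variation needs `aggregate_kd()` over independent
  repeats.
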