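---
title: "Quantifying tau-RNA complex coacervation with coacervr"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying tau-RNA complex coacervation with coacervr}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(coacervr)
library(dplyr)
```

## The system

The microtubule-associated protein tau is an intrinsically disordered
polycation that, mixed with RNA (a polyanion), demixes into micrometre-sized
liquid droplets — a complex coacervate. Three quantitative workflows
characterise this system, and a fourth characterises which RNAs tau binds in
cells:

1. **Charge balance**: sequence-based net-charge calculation locates the
   mixing ratio at which protein positive charge matches RNA negative
   charge, where coacervation is maximal.
2. **Binding**: gel-shift titrations fit to the Hill equation, stoichiometric
   saturation curves, and isothermal titration calorimetry (ITC) fit to a
   one-set-of-sites ("independent") binding model.
3. **Droplet quantification**: bright-field images segmented into dark
   droplets, shape-filtered, and summarised as percent coverage.
4. **iCLIP analytics**: post-alignment read filtering, cross-link site
   calling, genomic category enrichment, and anticodon-anchored tRNA
   positional profiles.

`coacervr` implements each workflow as pipeable functions over data frames,
plus seeded generators that synthesise inputs with known ground truth so
every stage is testable end to end.

## Charge balance

The net charge of a protein at pH $p$ is a Henderson–Hasselbalch sum over
ionisable groups with pKa $k_i$ and sign $s_i$:

$$Z(p) = \sum_{i \in \text{bases}} \frac{1}{1 + 10^{\,p - k_i}}
       - \sum_{i \in \text{acids}} \frac{1}{1 + 10^{\,k_i - p}},$$

including both chain termini. The default table (`pka_table()`) is a fixed
model-compound set: R 12.5, K 10.8, H 6.5, D 3.9, E 4.1, C 8.5, Y 10.1,
N-terminus 8.6, C-terminus 3.6. Published tables differ by tenths of a unit;
the table is an argument everywhere, and the default is frozen so results
are reproducible bit for bit.

RNA is modelled as a uniform polyanion: one negative charge per nucleotide
at a mean residue mass of 330 Da (both overridable per species via
`rna_spec()`), so a mass concentration $c$ µg/ml carries $1000\,c/330$ µM
of negative charge. A mixture's **charge ratio** is protein charge
concentration (molarity × $Z$) over RNA charge concentration; the
coacervation optimum sits near 1:1.

```{r charge}
dtau <- tau_protein("dtau187")
net_protein_charge(dtau, pH = 7)
charge_ratio_from_mass_ratio(7, dtau)
```

Three tau constructs are bundled as sequence fixtures keyed to the canonical
441-residue isoform: full-length 4R2N (1–441), K18 (244–372) and the
C-terminal fragment dtau187 (255–441, expressed with an N-terminal His6
tag).

**The His-tag choice.** Whether a charge calculation for the dtau187
construct should include the expression tag is genuinely open: the tag is
present on the expressed protein, but reported charge ratios for these
mixtures (1.2:1 at a 7:1 mass ratio; 1.2–1.3 at the maximal-coverage
compositions) are reproduced by this model only for the tag-free 255–441
polypeptide (1.27 and 1.29 here), while the tagged form predicts ~8% higher
(1.37 and 1.47) because six histidines add ~1.4 charges at pH 7 for ~1 kDa
of mass. We therefore default `tau_protein("dtau187")` to the tag-free
core and treat the tag as opt-in (`his_tag = TRUE`); the vignette states
this as a modelling decision, not an inference about how the original
calculation was done. A useful internal consistency check: the model puts
4R2N at +4.8 at pH 7 but +11.7 at pH 6, essentially equal to dtau187's
+10.8 — matching the observation that full-length tau only coacervates
robustly once its net charge is raised to the fragment's level.

`charge_balance_map()` scans a composition grid, scores each point by
$|\log(\text{charge ratio})|$ and flags the composition closest to 1:1
(ties broken toward lower total mass). Cysteines can be masked
(`mask_cys = TRUE`) for spin-labelled constructs whose thiol is conjugated.

## Hill analysis of gel-shift titrations

With trace RNA and protein in excess, the fraction of RNA bound at protein
concentration $x$ follows the Hill equation

$$y = \frac{1}{1 + (K_d/x)^n},$$

with $y = 1/2$ exactly at $x = K_d$ and cooperativity for $n > 1$.
`fit_hill()` uses bounded Levenberg–Marquardt least squares
($K_d \in (1, 10^5)$ nM, $n \in (0.2, 8)$), initialised at the
concentration whose fraction bound is nearest 0.5 with $n = 1$. The
optimiser choice is ours; the equation is the model. Standard errors come
from the Jacobian at the optimum, with a seeded residual bootstrap as an
alternative (`bootstrap = TRUE`) since the provenance of reported
uncertainties of this kind is rarely stated. Flat or all-bound/all-free
curves are refused or flagged `converged = FALSE` rather than silently
fitted; estimates pinned to a box edge are likewise flagged.

```{r hill}
curve <- sim_binding_curve(kd = 460, n = 2.8, noise_sd = 0.03, seed = 1)
glance(fit_hill(curve))
```

The stoichiometric experiments (constant RNA well above $K_d$, varying
protein) are summarised by **saturation curves**: with $m$ proteins per RNA
and molar ratio $r$, the tight-binding limit gives a bound fraction
$\min(1, m/r)$. These curves bracket data rather than fit it, which is why
the infinitely-tight limit is the default; a finite-affinity variant (the
per-site mass-balance quadratic) is available via `kd_nM` for sensitivity
checks.

## ITC: the independent binding model

The titration protocol (300 µM titrant in 5 µl injections into 1 ml of
30 µM macromolecule, 25 injections by default) is dilution-corrected with
the perfusion-cell displacement model: each injection multiplies cell
contents by $(1 - \Delta V/V_0)$ and delivers titrant at the syringe
concentration. The instrument's internal convention is not observable from
integrated heats alone; the displacement model is the standard choice and
is documented here as such.

For one set of $n$ identical independent sites, occupancy $\Theta_i$ after
injection $i$ solves

$$\Theta^2 - \Theta\left(1 + \frac{X_i}{nM_i} + \frac{K_d}{nM_i}\right)
  + \frac{X_i}{nM_i} = 0,$$

taking the root in $[0,1]$. Cumulative heat is
$Q_i = n \Theta_i M_i \Delta H V_0$ and the per-injection heat adds a
trapezoidal displacement term
$\delta Q_i = Q_i - Q_{i-1} + \frac{\Delta V_i}{V_0}\frac{Q_i+Q_{i-1}}{2}$.
The implementation is cross-checked in the test suite against a brute-force
equilibrium solver (numerical root of the mass balance) to $10^{-8}$
relative.

$n$ is oriented as titrant (RNA) per macromolecule (tau), matching the
molar-ratio axis of these titrations, so a protein-dimer-per-RNA
stoichiometry appears as $n \approx 0.5$. $\Delta H$ is in kcal/mol of
titrant. Because no enthalpy value is reported for this system, synthetic
truth uses $\Delta H = -2$ kcal/mol as a documented, arbitrary choice —
small enough that per-injection heats sit in the few-µcal range typical of
a low-enthalpy binder, and it is excluded from quantitative recovery
claims. Cooperative and two-site fits are deliberately not offered
(`itc_model_notes()`): at low enthalpy their extra constants are
unidentifiable, with parameter errors beyond 100%.

```{r itc}
tg <- sim_itc_thermogram(kd_nM = 735, dh_kcal = -2, n = 0.52,
                         noise_prop = 0.02, noise_ucal = 0.1, seed = 1)
glance(fit_itc(tg))
```

## Droplet coverage from bright-field images

Droplets settle onto the cover slide darker than the background, so the
pipeline is: threshold at the **mean intensity of a buffer blank image**,
classify pixels strictly below threshold as droplet, label connected
components (8-connectivity by default, so anti-aliased rims do not
fragment; 4-connectivity available), and measure each region. Eccentricity
is that of the equivalent ellipse from central second moments; equivalent
diameter is $2\sqrt{A/\pi}$ in µm (the µm calibration is mandatory, since
the filters are physical). Regions with eccentricity above 0.9 or
equivalent diameter below 1 µm are filtered out as false readings; percent
coverage is 100 × kept droplet pixels / image pixels. Border-touching
regions are kept but flagged; holes are not filled; no illumination
flattening is applied (the acquisition relies on Köhler alignment).

Two numerical points deserve note. First, the plain buffer-mean threshold
is exactly the published procedure, and on noise-free synthetic images the
pipeline reproduces ground-truth coverage pixel for pixel. On noisy images
a mean threshold necessarily classifies ~half the background pixels as
dark; the 1 µm diameter filter removes that speckle in real images with
strong contrast, but for quantitative work on low-contrast images the
`offset_sd` option thresholds at mean $- k\sigma$ (we use $k = 3$ in the
noisy-image tests, where it keeps coverage within 0.2 points of truth at
noise of 2% of contrast). Second, the mask is invariant under any strictly
increasing affine intensity map applied to image and threshold together,
so 12-bit data stored in 16-bit containers quantify identically.

```{r droplets}
ell <- data.frame(cx = c(120, 350), cy = c(150, 300), a = c(30, 20),
                  b = c(28, 20), angle = 0, depth = 600)
img <- sim_droplet_image(500, 500, pixel_size_um = 0.5, ellipses = ell,
                         background_sd = 12, seed = 61)
buf <- sim_droplet_image(500, 500, pixel_size_um = 0.5,
                         background_sd = 12, seed = 62)
quantify_droplets(img, buffer_image = buf, offset_sd = 3)
attr(img, "truth_coverage")
```

## iCLIP analytics

Coordinates are 0-based half-open (BED-compatible) throughout.
`preprocess_reads()` collapses PCR duplicates (identical chromosome, start,
strand and random barcode — ties resolved by name so the result is
order-independent), then drops reads shorter than 18 bp or scoring below
10. Reads without a random barcode are routed to an `unbarcoded` attribute
rather than silently discarded.

Cross-link sites follow truncation logic: reverse transcription stops at
the cross-linked nucleotide, so the site is the base immediately 5′ of the
read start (+ strand: `start - 1`; − strand: `end`); the
`"read_start"` convention is available since the underlying definition
("the termination site of sequencing") admits either reading.

`enrichment_table()` assigns each site to exactly one of eight categories
under the precedence tRNA > rRNA > miRNA > snRNA > lincRNA > exon >
intron > intergenic — a documented choice (small RNA classes would
otherwise be swallowed by host-gene exons/introns) that guarantees read
percentages sum to 100. Genome percentages partition nucleotides with the
same precedence; fold enrichment is read% / genome%. Assignment is by the
single cross-link nucleotide, consistent with truncation logic
(`by_site = FALSE` switches to read midpoint). `cluster_reads()` merges
same-strand reads overlapping by ≥1 nt transitively and retains clusters
with at least 5 reads — the retention rule is normative, the single-linkage
merge is our definition since no clustering parameters are published.

tRNA cross-links are profiled anticodon-relative: the anticodon's first
nucleotide is position 1 (anticodon = 1–3), positions 5′ of it run 0, −1,
−2, …. The bundled cloverleaf model labels every position of a 76-nt gene
(acceptor stem 1–7/66–76, D-arm 8–25, anticodon stem 26–31/39–43,
anticodon loop 32–38 with the anticodon at 34–36, variable loop 44–47,
T-arm 48–65); it is a deliberately simplified consensus, adequate for
positional profiling, not for tRNA biology. `abundance_compare()`
contrasts per-gene CLIP fractions against a background small-RNA pool with
log2 ratios and a 0.5-read pseudocount for genes absent from one pool.

```{r clip}
sim <- sim_clip_dataset(n_reads = 20000, dup_rate = 0.1, seed = 7)
pre <- preprocess_reads(sim$reads)
enrichment_table(pre, sim$annotation)
```

## What the generators emulate — and what they do not

Every generator is a pure function of its seed and ships a machine-readable
truth record (`sim_truth()`).

* `sim_binding_curve()`: Hill fractions on 12 log-spaced concentrations
  from 20 nM to 2 µM (the direct-titration design, trace RNA at 26 nM)
  plus additive Gaussian noise (σ = 0.03 default), clipped to [0, 1].
  Real densitometry noise is heteroscedastic and band quantification can
  be biased near saturation; neither is modelled.
* `sim_itc_thermogram()`: model heats plus 2% proportional and 0.1 µcal
  additive Gaussian noise; an optional constant blank channel emulates
  titrant-into-buffer dilution heat. Real first-injection artefacts are
  not generated (use `drop_first` against real data), and baseline
  integration error is folded into the additive term.
* `sim_droplet_image()`: Gaussian background minus a constant depth inside
  rasterised ellipses, on a 12-bit scale. Real images add shading,
  defocus halos, overlapping and fusing droplets; passing the pixel-exact
  tests therefore validates the measurement code, not robustness to
  optical artefacts.
* `sim_clip_dataset()`: a 100 kb toy genome with the eight categories laid
  out contiguously; reads drawn multinomially with probability ∝ genome
  fraction × enrichment weight (the realised expected fold is the weight
  divided by $\sum_c g_c e_c$, and the truth record stores these
  normalised folds). Within tRNA genes, cross-link positions follow
  element weights (anticodon loop 0.70, T-loop 0.15, D-loop 0.10, rest
  0.05) that encode the qualitative anticodon ≫ T-loop > D-loop ordering
  — the quantitative split is a stand-in, not a published value. PCR
  duplicates and sub-threshold decoys are injected at configurable rates.
  Multi-mapping, strand mixtures and splicing are not simulated.

## Problem sizes and tolerances

The recovery experiments in the test suite and acceptance script use 200
simulated titrations (Hill) and 100 simulated thermograms (ITC) per truth
set — enough for the ensemble medians to stabilise within a few percent
while keeping the whole suite around a minute on one core. Noiseless
round trips are asserted to 10⁻⁵–10⁻⁶ relative; the ITC forward model is
cross-checked against an independent numerical equilibrium solver at
10⁻⁸. Degenerate inputs (flat titrations, zero thermograms, blank images,
zero-RNA mixtures) error or flag explicitly; nothing silently returns a
number it cannot support.

## Known limitations

* No salt- or temperature-dependent charge screening: NaCl and temperature
  are metadata. The charge model is a counting model, not
  Poisson–Boltzmann, and it predicts the coacervation optimum only through
  the 1:1 balance point, not droplet yield.
* The Hill and saturation analyses do not model the multi-band
  protein-multimer ladder; that narrative is qualitative.
* Droplet segmentation performs no watershed splitting of merged droplets
  and no fusion/tracking analysis.
* The CLIP module starts from aligned records: trimming, alignment and
  tRNA gene prediction are upstream tools' territory, and uniquely
  assigned inputs are assumed.
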