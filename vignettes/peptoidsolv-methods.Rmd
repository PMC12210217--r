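---
title: "Methods: solvent-resolved analysis of peptoid self-assembly simulations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: solvent-resolved analysis of peptoid self-assembly simulations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

`peptoidsolv` analyses molecular-simulation output for amphiphilic diblock
polypeptoids — a hydrophobic, crystalline-forming poly(N-decylglycine)
block (Ndc) joined to an amorphous oligo-ether block (Nte) — assembling
into stacks, nanofibers and nanosheets out of THF/water mixtures. This
vignette explains each model and procedure, the defaults and why they were
chosen, what the synthetic-data generator emulates, and where the numerical
edges are.

## Solvent composition and the virtual unit

Experimental recipes quote THF content as "~50 wt%", "4 M", or "5 vol%".
All analyses in this package reduce these to the THF/water molar ratio
$r$ (0 for pure water, $\infty$ for pure THF) with fixed constants:
molar masses 72.11 and 18.015 g/mol, liquid densities 0.889 and
0.997 g/mL at 25 °C, held in `solvent_constants`. Two deliberate
conventions:

- **"N molar" means moles of THF per litre of water**, implemented as
  $r = c/55.5$. The alternative (per litre of solution) gives
  $r \approx 0.107$ for 4 M, which is inconsistent with the ~0.072 a
  per-litre-of-water reading produces; 55.5 mol/L is the standard round
  value for the molarity of water itself.
- **Volume fractions assume ideal mixing**; THF/water mixes with a small
  excess volume that this package ignores (a sub-percent effect on $r$
  at the compositions of interest).

For mixed solvents the assembly-energy bookkeeping (below) counts solvent
in **virtual units**: one THF molecule plus $1/r$ water molecules. Water
counts per unit are kept fractional — rounding would bias the reference
energy. Pure water degenerates to one water per unit, pure THF to one THF.

## Assembly energy

For $N$ peptoids in $M$ virtual solvent units with total potential energy
$E$, the per-molecule assembly energy is

$$e(A\,\mathrm{in}\,S) = \frac{E - M\,e(S)}{N},$$

where $e(S)$ is the per-unit energy of an equilibrated solvent-only box.
Lower is more stable; profiled over structure classes (isolated →
stacks → nanofibers → nanosheet) the class-to-class drops measure the
thermodynamic driving force toward two-dimensional growth
(`assembly_profile()` reports `delta_from_previous` per solvent).

Two exact invariances are useful for validation and are tested: adding a
constant per virtual unit to both $E$ (as $Mc$) and $e(S)$ (as $c$) leaves
the statistic unchanged, and scaling $N$ together with the
solvent-referenced excess leaves it unchanged. The statistic is undefined
relative to vacuum, so $M = 0$ is rejected rather than special-cased.
Energies are expected as upstream time-averages; when a per-frame series
is available `block_standard_error()` attaches a 5-block standard error
(five blocks is the common compromise between bias and variance for
~10–100 ns series).

## Conformational metrics and the landscape pipeline

Backbone conformations are ordered heavy-atom coordinate matrices.
`rmsd()` superimposes with the Kabsch algorithm restricted to **proper
rotations** (determinant +1): allowing reflections would silently cancel
chirality differences, which is exactly what a conformational comparison
must not do. `radius_of_gyration()` is mass-weighted;
`end_to_end()` measures backbone extension (the coiled C-shape sits near
5–9 Å at these chain lengths, the maximally extended Ndc backbone near
26 Å).

### Featurization

`featurize()` maps a conformation to the distances from every atom to the
first three atoms (the anchors). The representation is exactly invariant
under rigid motions. The first three rows (anchor–anchor distances) are
included even though they are partially redundant: they make the feature
self-contained, so a mean feature vector can be inverted without outside
information. Anchors that are nearly collinear (within 1e-6 Å of a common
line) make the inversion ill-conditioned; featurization proceeds with a
warning rather than failing, since embedding does not need the inversion.

### Reconstruction

`reconstruct()` inverts the feature by trilateration: anchor 1 at the
origin, anchor 2 on +x, anchor 3 in the xy-plane (y > 0), every later atom
placed from its three anchor distances. Distances to three coplanar
anchors cannot encode the sign of z, so each atom's mirror ambiguity is
resolved by bond-length continuity — choose the sign that brings the bond
to the preceding atom closest to the 1.5 Å backbone bond, falling back to
z ≥ 0 on ties. Consequences, all tested:

- noise-free planar chains are recovered exactly (RMSD < 1e-9 Å);
- noise-free chiral chains (helices with 1.5 Å bonds) are recovered up to
  a possible **global** mirror (RMSD ≤ 1e-6 Å after allowing it);
- averaged features from a cluster are usually slightly infeasible
  (negative trilateration discriminant); discriminants below -1e-6 are
  clamped to the anchor plane and the affected atom indices recorded in
  the `clamped` attribute. A z-magnitude below 1e-5 Å is treated as the
  numerical residue of a planar atom and snapped to zero, which is what
  keeps the planar roundtrip exact.

### Embedding and clustering

`embed_conformations()` runs UMAP with 15 neighbours and minimal distance
0.0 — the hyperparameters used for this system's landscape analyses — and
a recorded seed (default 42). `cluster_embedding()` runs HDBSCAN with
minimal cluster size 10, minimal core neighbourhood 3 and a 0.2 merge
threshold; points in low-density regions are labelled noise (-1). Both
steps execute in a Python subprocess (`umap-learn`, `scikit-learn`) via a
bundled backend script, because no R implementation of either algorithm is
available in the package's dependency set; one process serves several
seeds (`landscape_replicates()`) to amortise start-up. UMAP layouts are
not comparable across library versions or training sets, so all claims
(cluster identity, overlap of provenance groups) are made within a single
embedding — never by comparing coordinates across runs.

`summarize_clusters()` reports, per cluster, the population fraction with
**all** samples (noise included) in the denominator — so small
populations mean "fraction of everything sampled", not "fraction of the
clustered subset" — plus the mean feature, its reconstruction and that
reconstruction's end-to-end distance.

`rmsd_histogram()` uses left-closed right-open bins of 0.5 Å by default
(fine enough to separate coiled from extended families, coarse enough not
to fragment at a few hundred samples) and normalises to unit integral per
solvent condition.

## Preferential solvation

"Distance from the peptoid surface" is the minimum-image distance to the
nearest selected solute heavy atom — deliberately the same convention as
the umbrella-sampling collective variable, not a fitted molecular
surface, so the two analyses share a geometry. Only orthorhombic boxes
are supported; triclinic input is rejected loudly.

`solvation_profile()` accumulates THF and water centre-of-mass counts in
1 Å shells (default) out to a 20 Å bulk cutoff; molecules beyond the
cutoff define the bulk ratio and per-shell enhancement. Counts are
conserved (shells + bulk = totals, tested), and a THF-free system yields
zero ratios with the enhancement flagged undefined rather than silently
infinite.

The first shells of a steep enhancement are systematically flattened by
binning (a 1 Å bin averages the decay over its width) and are also the
shells with the fewest molecules. `surface_enhancement()` therefore
estimates the surface (d = 0) factor parametrically: the uniform water
counts serve as a per-shell volume reference, and the THF counts are fit
with a Poisson likelihood to $r_0\,n_\mathrm{water}(d)\,[1 + A e^{-d/\lambda}]$,
reporting $1 + A$. On generator output with a planted factor of 3.5 and
3 Å decay (200 frames) this recovers the factor to within a few percent,
where the raw first-bin reading is biased low by ~10%.

`density_map()` deposits molecular masses on a grid; the requested voxel
edge is rounded down so an integer number of voxels tiles the box, making
per-frame mass conservation exact (tested to 1e-6 relative).
`isolevel_mask()` thresholds at 0.5/0.3/0.2/0.1 g/cm³ by default — the
contour levels conventionally used to display THF domains around a
nanosheet — and the masks are nested by construction.

## Umbrella sampling and WHAM

The adsorption collective variable is the minimal distance from a tagged
THF to the nearest Ndc atom, smoothed with
$s = \beta/\ln\sum_i \exp(\beta/s_i)$ at $\beta = 100$. Note the form:
the inverted variant $\beta/\log\sum_i \exp(\beta s_i)$ that sometimes
appears in print diverges with distance and fails to reduce to $s_1$ for
a single term; the convention implemented here has the correct one-term
limit and approaches the hard minimum monotonically from below as
$\beta \to \infty$ (both tested).

`build_windows()` produces centres on a half-open interval; the standard
desorption schedule 0.35–4.4 nm at 0.05 nm yields 81 windows
(0.35 … 4.35 nm).

`wham()` solves the standard self-consistent equations with harmonic
biases $w_k(\xi) = \tfrac{1}{2}K_k(\xi - c_k)^2$:

$$p(\xi_b) = \frac{\sum_k n_k(b)}{\sum_k N_k e^{(f_k - w_k(\xi_b))/k_BT}},
\qquad f_k = -k_BT \ln \sum_b p(\xi_b)\, e^{-w_k(\xi_b)/k_BT},$$

iterated Jacobi-style (all $f_k$ updated simultaneously, no acceleration)
with log-sum-exp throughout, until $\max_k |\Delta f_k| < 10^{-8}\,k_BT$.
$k_B = 0.0083144621$ kJ/mol/K. Choices worth knowing:

- **Binning**: default 0.05 nm (the window spacing; finer bins gain no
  information at these sample sizes). The grid is snapped to multiples of
  the bin width; replicates that must share a grid should pass an explicit
  `range`.
- **Anchor**: the PMF zero is the minimum over the first 1 nm of the
  covered range — the adsorbed state — because the physically meaningful
  number is the cost of leaving it. `desorption_cost()` is the mean over
  the last 0.5 nm (the bulk plateau) minus that minimum, with a slope test
  (1 $k_BT$/nm over the plateau region) warning when no plateau exists.
  Both are invariant to the anchoring gauge.
- **Degenerate inputs**: empty windows are dropped with a warning;
  adjacent windows whose sampled ranges do not overlap trigger a gap
  report (the PMF is then disconnected); empty bins are `NA`, never 0.
- In the single-window, zero-bias limit WHAM reduces *exactly* to the
  histogram estimator, which is tested as an oracle.

`pmf_uncertainty()` re-anchors each replicate before aggregating, so a
pure offset between replicates contributes zero variance.

## The synthetic-data generator

The generator provides every input with known ground truth; its defaults
are the study conditions under which the package's guarantees are stated.

- **Backbones** (`make_backbone()`): circular arcs subtending 300°
  (coiled C-shape) and 150° (semi-open), and a planar zig-zag with 1.5 Å
  bonds (extended), optionally scaled to an exact target end-to-end
  distance (26 Å is the maximally extended Ndc reference) and perturbed
  with isotropic Gaussian noise. These are geometric idealisations, not
  force-field minima: they exercise featurization, embedding, clustering
  and reconstruction with exactly known answers, but they do not model
  torsional statistics, side chains, or *cis/trans* isomerism — passing
  the landscape tests shows the pipeline recovers planted structure, not
  that real REST2 ensembles cluster this cleanly.
- **Conformation sets**: three families at 100 samples each with 0.3 Å
  positional noise — enough spread that embedded families are clouds, not
  points, while remaining separable; the planted labels support adjusted
  Rand index scoring (≥ 0.9 across five seeds is the tested guarantee).
- **Agglomerates** (`make_agglomerate()`): chains stacked (z) or laid
  side-by-side (sheet); the spacing multiplier orders compactness for
  radius-of-gyration checks, and the sheet doubles as a large-surface
  solute.
- **Solvated frames** (`make_solvated_frame()`): water uniform, THF by
  rejection against $1 + (f-1)e^{-d/\lambda}$, point centres with THF/water
  masses, default 60³ Å box, and a liquid-density cap (0.034 centres/Å³)
  on the total count. The solvation study conditions are a 10-chain sheet
  solute with 495 THF / 6800 water per frame (bulk ratio 0.0728 ≈ the 4 M
  composition) over 200 frames: a single-chain solute leaves too little
  near-surface volume for per-shell statistics at liquid density, and the
  nanosheet is the physically relevant solute for surface enrichment
  anyway. What the generator does **not** model: solvent structure
  (RDF oscillations), excluded volume around the solute, and molecular
  orientation — so recovered enhancements validate the estimator, not a
  force field.
- **Umbrella windows** (`sample_umbrella()`): Metropolis sampling of
  $e^{-(U + w_k)/k_BT}$ per window, step size adapted during a 10% burn-in
  toward 30–50% acceptance, burn-in discarded, and one sample recorded
  every 5 updates (the same role as an MD engine's output interval;
  recording every update would store heavily autocorrelated values and
  make histogram noise look smaller than it is). Acceptance rates are
  recorded per window and a zero-acceptance chain is an error. The
  double-well potential is $U = 16\,\Delta G\,[x(1-x)]^2$ with
  $x = (\xi - a)/L$, whose barrier is exactly $\Delta G$ — the prefactor
  matters; the superficially similar $4\,\Delta G\,[x^2 - x]^2$ plants a
  barrier of $\Delta G/4$. Test conditions: 10 windows across the well at
  $K = 200$ kJ/mol/nm² (window width ~0.11 nm, giving healthy overlap at
  0.1 nm spacing), 5000 samples per window; the 5 kJ/mol barrier is
  recovered within 0.5 kJ/mol across seeds and a flat potential within
  0.2 $k_BT$.
- **Energy tables** (`make_energy_table()`): totals built as
  $N\varepsilon + M e_S$ exactly, so the assembly-energy statistic must
  return $\varepsilon$ to machine precision for every $(N, M)$ — and does.

All generators restore the caller's RNG state and are bit-reproducible
given a seed.

## Problem sizes

The validation suite runs at the sizes quoted above (300-conformation
landscapes, 200-frame solvation sets, 10 × 5000-sample umbrella runs,
three to five seeds per stochastic check), which keeps the full suite to a
few minutes on a single core while leaving each stochastic estimate's
sampling error several times smaller than the tolerance it is checked
against.

## Known limitations

- The landscape backend requires a Python with `umap-learn` and
  `scikit-learn`; without it, featurization, reconstruction and all
  non-embedding analyses still work.
- UMAP coordinates are reproducible only for a fixed seed and library
  version; persist cluster *summaries*, not embedded coordinates.
- Reconstruction loses global chirality by construction (three coplanar
  anchors); it is reported up to a mirror, flagged in the docs rather
  than hidden.
- WHAM error bars come from replicates (`pmf_uncertainty()`), not from
  autocorrelation analysis within a single run; serially correlated input
  will make single-run histograms look better than they are.
- Solvation analyses treat solvent molecules as point centres; per-atom
  binning of real trajectories is available (`selection`/species mapping
  in the readers) but the generator does not emulate internal geometry.
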