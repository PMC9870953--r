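---
title: "Methods: haplotype diversity, statistical parsimony, and glacial cover hindcasts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: haplotype diversity, statistical parsimony, and glacial cover hindcasts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(kelpRefugia)
```

`kelpRefugia` couples a COI-barcode population-genetics workflow to a
temperature-driven hindcast of kelp cover. This vignette is the package's
account of the science behind each stage: the models, the defaults and why
they were chosen, the numerical details, and what the synthetic data can and
cannot tell you about real datasets.

## 1. From reads to an analysable alignment

The unit of data is an `AlignedSeqSet`: equal-length DNA sequences (IUPAC
symbols plus `-`) with unique sample ids. The package deliberately does
*not* align — barcoding studies align externally (MUSCLE, MAFFT) and the
statistics below are only defined on an alignment. Sequences are uppercased
and `U` is mapped to `T` on read.

**Primer trimming.** COI barcodes are amplified with degenerate primers
(the built-in pair is Gaz F2 `CCAACCAYAAAGATATWGGTAC` / Gaz R2
`GGATGACCAAARAACCAAAA`). `trimPrimers()` scans the first and last
(primer length + 10) columns for the forward primer and the reverse
complement of the reverse primer, matching degeneracy sets (Y ≡ C/T, and so
on; a gap matches nothing). The window padding and the default tolerance of
one mismatch are standard barcode practice; neither is critical, since a
primer either flanks the amplicon or it does not. Trimming removes whole
columns (the modal matched offset across records), so the result is still
an alignment; per-record outcomes go to a trim log. Columns are 1-based in
all logs and reports.

**Translation QC.** A protein-coding barcode should translate without
internal stop codons. `translationQc()` counts internal stops in the three
forward frames and keeps the best frame per sequence (or a user-fixed
frame); codons containing gaps or ambiguities are skipped, and a stop in
the frame's final codon counts as terminal. The genetic code is a
parameter defaulting to the standard table (`"1"`); mitochondrial barcodes
are often screened with an organellar code instead, so `"5"` (invertebrate
mitochondrial) or any other Biostrings table id can be supplied. Algal COI
has no stop-codon differences that matter for this screen under either
choice.

## 2. Haplotypes and diversity

**Site filter.** `completeDeletion()` removes every column containing a gap
or ambiguity in *any* sequence — the default site handling of
sequence-polymorphism software — applied once to the full dataset so every
population is scored on the same columns. The retained-column count
`L_used` is carried through and reported next to π, because π is only
interpretable relative to it.

**Collapsing.** Haplotypes are exact sequence matches over retained columns
(no fuzzy matching is needed: ambiguity codes cannot survive the filter).
Ids are assigned by descending total count with ties broken by first
occurrence, which makes outputs reproducible and record-order-independent
up to relabelling among equal-count haplotypes.

**The diversity panel.** Per population and pooled:
`N`; `H`; `S` (columns with ≥2 observed bases among that population's
haplotypes); `K = Σ n_i n_j d_ij / C(N, 2)`; `π = K / L_used`; and the
unbiased `Hd = N (1 − Σ p_i²) / (N − 1)`. The unbiased estimator is used
because it is what the field's reference software prints; it has the
elegant property of equalling the fraction of unordered sequence pairs that
differ, which the tests exploit as a brute-force oracle. `Hd` is undefined
(reported `NA`) for single-sequence populations. Statistics are computed in
full precision; `formatDiversityReport()` renders Hd and K to 3 decimals
and π to 3 significant figures, the conventional table style.

## 3. Statistical-parsimony networks

Haplotype networks join sequences through single-substitution edges;
the statistical-parsimony family only joins haplotypes while multiple hits
at a site are improbable. The quantity at the method's core is the
probability that `j` observed differences between two sequences of
`L_used` sites involve no superimposed substitutions. The package's
transcription of that calculation, exposed as `parsimonyProbability()` for
audit, is:

- per-site substitution counts are independent Poisson with mean λ;
- a site hit `k` times shows a difference with the Jukes–Cantor
  visibility `¾(1 − (−⅓)^k)` (so `q(λ) = ¾(1 − e^{−4λ/3})` overall);
- λ is estimated from the pair itself by inverting `q = j/L_used`;
- conditioning on the observed differences,
  `P(parsimony | j) = (λe^{−λ}/q)^j · (e^{−λ}/(1−q))^{L−j}`.

`P(0) = 1`, `P` is strictly decreasing in `j`, the implied 95% connection
limit grows with alignment length (8 steps at 658 bp), and pairs beyond the
Jukes–Cantor saturation horizon (`q ≥ ¾`) get probability zero. For very
short alignments even one step can fall below 95%; the limit is then
honestly 0 rather than clamped to 1, and no network can be built.

**Construction.** `buildNetwork()` is agglomerative: candidate pairs sorted
by ascending distance (ties: larger combined count first — the classic
"connect frequent haplotypes first" heuristic — then lexicographic ids),
linked only when within the limit and in different components. A link of
length `j` inserts `j − 1` inferred intermediates (`mv*`), so every edge is
one substitution. Links that would close a loop are skipped: the output is
a forest, which is exact for homoplasy-free data and a deliberate
simplification otherwise — reticulation/loop resolution is out of scope,
and tree-like barcoding datasets (like the kelp data this package targets)
do not exercise it. One consequence worth knowing: in a forest, two
sampled haplotypes connected through a third can sit farther apart along
the graph than the pairwise limit; this cannot occur when the maximum
pairwise distance is within the limit, as here.

## 4. The glacial cover hindcast

The hindcast chain is deliberately modular: SST → cover (response curve),
bathymetry + sea level → habitat mask, then latitudinal averaging and a
shift summary.

**Response curve.** The empirical cover–SST relationship for this kelp is
not published as an equation, so the curve is pluggable. The default is the
symmetric quadratic bump `peak · max(0, 1 − ((T − 23)/3)²)`: peak cover at
the 23 °C optimum isotherm, zero at and beyond the 26 °C thermal threshold,
mirrored below. Defaults `tOpt = 23`, `tMax = 26` (°C) are the species'
published optimum and threshold; `peakCover = 60%` is a realistic dense
cover for the region's reefs, and only sets the plot scale — every shift
statistic is invariant to it. Custom curves (fitted or tabulated) are
validated at construction for the peak/threshold/range conditions.

**Depth masking.** A cell is habitat when
`depthBand[1] ≤ bathymetry − seaLevelOffset ≤ depthBand[2]` and its
latitude is in the analysis window (defaults: 0–80 m, 18–38° S). With the
LGM's ~120 m lower sea level this selects shelf 120–200 m deep today. The
offset is a parameter (the literature range is ~65–125 m) so sensitivity
runs are one-liners. Cover maps are computed across the full grid; the
mask applies to the profile, mirroring how such maps are usually presented
(full-shelf colour, masked averages). No cross-shelf rocky-reef
availability is modelled — a stated limitation of the original analysis
preserved here.

**Profiles and shifts.** `latitudinalProfile()` takes unweighted means of
masked cells in 0.5° bins (the analysis states plain latitudinal averaging;
no area weighting). Empty bins are flagged, never zero-filled — zero cover
and no habitat are different facts. `rangeShift()` compares a feature of
two profiles — `peak` (ties averaged), cover-weighted `centroid`, or the
equatorward `threshold` crossing (default half the profile maximum) — and
returns `|lat_A| − |lat_B|`, so positive is equatorward in either
hemisphere.

## 5. Synthetic data: what it does and does not emulate

**Alignment fixture.** `makePaperFixture()` deterministically encodes the
published haplotype structure of the south-west Pacific kelp dataset: 119
sequences × 658 bp, four regional populations (63/26/12/18), six haplotypes
with totals 74/35/7/1/1/1, the rare Queensland haplotype three
substitutions from the central one, all other haplotypes one substitution
from their parent. Substitution columns are evenly spaced (not random) and
chosen to keep frame 0 stop-free, so the fixture is stable across releases
and passes translation QC by construction. One count is not printed
anywhere and is derived arithmetically: the SA/Vic/Tas share of the central
haplotype must be 74 − 25 − 3 − 18 = 28, which implies Hd = 0.502 for that
population and 0.528 overall — the fixture manifest records this
derivation. Whether the second Queensland singleton attaches to the common
haplotype or to the local 7-copy haplotype is not determinable from the
published material; both give the same per-population segregating-site
counts, and `h11Parent` selects between them (default: the local parent,
the biogeographically parsimonious reading).

The fixture reproduces exactly the published cells that are arithmetically
consistent with the published haplotype counts (NSW Hd/K, QLD Hd and S,
SA/Vic/Tas S, the zero-diversity island row, pooled N and H). Three printed
cells (SA/Vic/Tas Hd 0.486, pooled Hd 0.543, QLD K 1.515) and the π column
are not derivable from any count set consistent with the printed totals;
the package reproduces what its inputs imply and reports `L_used` so π is
auditable.

**Grids.** `gridSpec()`/`simulateGrids()` build a latitudinally graded SST
field (`base + gradient·(lat − refLat) − cooling + noise`; defaults: 14 °C
at 38° S, 0.8 °C per degree — the realistic along-shelf gradient for
eastern Australia — Gaussian noise sd 0.25 °C, seed-fixed) over a monotone
0–250 m cross-shelf depth ramp. These support exact analytic expectations:
with 4 °C uniform cooling the optimum isotherm, and hence the cover peak,
moves `4/0.8 = 5°` equatorward. They do not emulate coastline geometry,
eddies, cross-shelf SST structure, or reconstruction error in paleo-SST
fields — so passing tests demonstrate the machinery (masking, averaging,
shift detection), not the realism of any particular hindcast. The
published "3 to 10 degrees" equatorward shift depends on external SST
products and an unpublished fitted response curve; the package reproduces
its direction and mechanism, not its magnitude.

## 6. Numerical and design details

- **Determinism.** Every generator takes a seed and restores the caller's
  RNG state; identical config + seed give byte-identical TSV/JSON
  artifacts (the NEXUS writer's timestamp comment is stripped for this
  reason). Problem sizes in the tests — 100 random alignments up to 50 × 200
  for the oracle equivalences, 50 random parameter-recovery specs, 41 × 9
  hindcast grids — keep the full suite around ten seconds while exercising
  every code path at sizes where brute-force oracles are exact.
- **Degenerate inputs.** All-gap columns → error from the site filter;
  single-haplotype populations → zero K/S/Hd; single-sequence populations
  → `NA` Hd; flat profiles → explicit error from shift metrics; empty
  habitat masks → warning, not silent zeros.
- **Tie-breaks** are all deterministic and documented: first-seen width for
  ragged-FASTA reporting, modal-then-earliest primer offset, count-then-
  first-seen haplotype ids, frequency-then-lexicographic network linking,
  averaged tied profile peaks.
- **Orchestration.** `runGenetics()`/`runHindcast()` take a config list or
  YAML file, reject unknown keys before any computation, and write a run
  manifest with md5 hashes of every artifact. They are plain R functions:
  this package is a library to be scripted, not a shell tool.

## 7. A complete run

```{r, eval = FALSE}
out <- runGenetics(list(fixture = TRUE, seed = 1, primers = TRUE,
                        outDir = tempfile()))
formatDiversityReport(out$report)
out$network

hind <- runHindcast(list(grid = list(noiseSd = 0), outDir = tempfile()))
hind$shift$peak_shift_deg
```
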