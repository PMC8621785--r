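---
title: "Detecting complex lasso motifs: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting complex lasso motifs: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lassotopo)
```

## The motif

A *complex lasso* arises when a protein backbone segment is closed into a
covalent loop by a side-chain-mediated bond — most often a disulfide between
two cysteines, but also amide, ester, thioester or C–C bridges — and one or
both terminal tails of the chain thread through that loop. The motif
generalizes two classical structure families: lasso peptides (miniproteins
such as Microcin J25, whose amide-closed ring is threaded by its own
C-terminal tail) and cysteine knots. Whether a tail "threads" the loop is
made precise by spanning a surface on the loop and counting oriented
crossings of the tail through that surface.

`lassotopo` implements this pipeline end to end: structure reading and gap
modelling, bridge detection, covalent-loop extraction, surface spanning and
area minimization, oriented crossing detection and reduction, the lasso
nomenclature and fingerprint, per-residue stabilization scoring, bridge
conservation classification, and survey aggregation, plus a deterministic
generator of chains with prescribed lasso types used as the package's own
test oracle.

## Pipeline model and assumptions

1. **Gap modelling.** Missing residues (jumps in author numbering) are
   modelled as straight intervals: *g* virtual residues placed equidistantly
   between the flanking CA atoms. No other repair is attempted. Loops
   containing a modelled gap of more than `max_loop_gap` residues (default
   2), and loops with any gap within 3 residues of a piercing segment, are
   classified as topological *artifacts* rather than certain assignments.
2. **Bridges.** Disulfides are detected geometrically as CYS SG–SG pairs
   within `max_ss_dist` (default 2.5 Å; a covalent S–S bond is ~2.05 Å, the
   margin absorbs poorly refined models). Non-disulfide bridges are accepted
   only from explicit file records (SSBOND/LINK, `struct_conn`), because
   distance-plausible candidates in deposited files are frequently
   artificial; chemistry is inferred from the element pair (N–C →
   amide/amine, C–O → ester/ether, C–S → thioester/thioether, C–C). A
   `permissive` flag enables distance-based detection at ≤ 1.8 Å for curated
   inputs.
3. **Surface.** The loop CA polygon (closed by the bridge edge) is spanned
   by a triangle fan from its centroid, refined once by midpoint subdivision
   when any edge exceeds `max_edge` (default: the mean boundary edge
   length), and shrunk by per-vertex area-gradient descent with backtracking
   — boundary vertices immobile, deterministic index-order updates, area
   non-increasing by construction. Iteration stops at a relative area change
   below `rel_tol` (1e-4) or `max_iter` (200) sweeps. This is not an exact
   Plateau solver: piercing counting needs the surface's topology, not its
   exact geometry, and the approximate minimal surface is sufficient and
   reproducible.
4. **Crossings.** Every tail CA–CA segment is tested against every triangle
   with signed-volume orientation predicates. The crossing sign is `+` iff
   the chain direction of increasing residue index agrees with the local
   triangle normal; triangles are wound by the right-hand rule around the
   loop traversed N→C. This convention is internally consistent but could be
   globally mirrored relative to other software — `flip_signs` mirrors every
   reported sign, and all sign statistics are convention-relative.
5. **Reduction.** Adjacent opposite-sign crossings within `cancel_eps`
   (2 Å) on segments within `cancel_sep` (1 residue) are cancelled pairwise
   as surface wobble; crossings with fewer than `min_tail_depth` (3)
   residues of tail beyond them are dropped as too shallow. Both thresholds
   are explicit, configurable stand-ins: the survey literature states that
   shallow piercings are disregarded without printing a cutoff.
6. **Nomenclature.** Single-tail alternating piercings give `L` types
   (`L-1C`: one negative piercing by the C-tail); at least two consecutive
   same-side crossings give supercoiling `LS` types (`LS2--N`); both tails
   piercing give `LL`/`LLS` types with the N part written first
   (`LL+4,-2` reads N = +4, C = −2). The sign shown in `L`/`LL` labels is
   that of the loop-proximal (rank-1) piercing. Major types strip signs and
   tail letters. The per-chain *fingerprint* concatenates major types of all
   pierced loops in sequential order, suppresses `L0` and compresses
   consecutive repeats with a multiplicity prefix (`2L1`).

## Tunable parameters

| parameter | default | units | role |
|---|---|---|---|
| `max_ss_dist` | 2.5 | Å | geometric SG–SG disulfide threshold |
| `max_loop_gap` | 2 | residues | largest in-loop gap still "certain" |
| `min_tail_depth` | 3 | residues | shallowness cutoff for piercings |
| `cancel_eps` | 2.0 | Å | wobble cancellation radius |
| `cancel_sep` | 1 | residues | wobble cancellation segment separation |
| `rel_tol` | 1e-4 | – | surface convergence tolerance |
| `max_iter` | 200 | sweeps | surface iteration cap |
| `max_edge` | mean boundary edge | Å | refinement trigger |
| `window` | 5 | residues | stability profile smoothing (odd) |

All values are logged into every result record (`result$config`), so a
stored result is reproducible without external context.

## Numerical choices

* **Degeneracies.** A segment endpoint exactly on a triangle plane is
  tie-broken to the positive side, so a touch-and-cross counts once and a
  touch-and-return not at all; tie-broken contacts must pass strictly
  through the triangle interior (corner grazes are not crossings). A
  segment lying fully in a triangle's plane triggers a deterministic
  symbolic perturbation of the segment — never random jitter — so results
  are machine-reproducible. Crossings shared by adjacent triangles (common
  edges) are deduplicated by parametric position.
* **Plateaus.** Profile extrema use strict neighbor comparisons; a plateau
  strictly better than both flanks reports its midpoint. Chain ends are
  never extrema.
* **NMR ensembles.** The B-factor analogue for multi-model structures is
  the per-residue mean square deviation of CA positions about the ensemble
  mean, after least-squares (Kabsch) superposition of every model onto
  model 1. Fitting removes trivial rigid drift between models; without it
  the profile would measure global motion, not local flexibility.
* **Fingerprint grammar.** The compressed fingerprint string is ambiguous
  unless per-loop piercing counts are limited to one digit: `L1L2L12L2`
  must read L1 · L2 · L1 · 2×L2 (five loops), not L1 · L2 · L12 · L2.
  Since no deposited structure approaches ten piercings of a single loop,
  the grammar fixes counts at a single digit; run-length multiplicities
  (the digits before an `L`) may have several digits.

## Design choices that were genuinely open

* **Label sign for alternating types.** `L`/`LL` labels carry a single
  sign; the package uses the rank-1 (loop-proximal) piercing's sign, the
  reading most consistent with how bridge-proximal piercing statistics are
  framed. Supercoiled parts spell out their full sign string.
* **Loop self-threading.** A loop's own span can cross its surface; such
  crossings are reported separately (`self_crossings`) and never enter the
  lasso type, which attributes piercings to tails only.
* **Evolution-flower neighborhoods.** `flower_neighbors()` applies a
  terminal-piercing (append/remove one sign) or terminal-slipknot (append
  an opposite-sign pair) move to every minor realization of a major type.
  Because a slipknot move appends an opposite-sign pair, a fully one-sided
  supercoil (e.g. signs `---`) can never arise from it — the reason triply
  same-side-pierced types are absent from slipknot-reachable neighborhoods.
  The function can return neighborhoods at minor resolution, since major
  labels cannot express the same/mixed-sign distinction.
* **Conservation boundaries.** "More than 80%" and "less than 30%" are
  implemented with strict inequalities, so a (0.80, 0.80) bridge is medium,
  not highly, conserved. Gapped alignment rows count as non-cysteine and
  stay in the denominator.

## The synthetic generator: what it emulates and what it does not

`make_lasso_fixture()` realizes any minor label as a deterministic chain:
a regular planar polygon loop (default 12 residues at 3.8 Å CA spacing)
whose minimal surface is exactly flat, tails routed through the polygon
interior at crossing points separated by more than `cancel_eps` (so genuine
crossings can never be cancelled as wobble), consecutive same-sign
crossings routed around the loop exterior, and every tail extended well
beyond its last crossing. `sample_ideal_chain()` draws closed equilateral
random polygons with freely jointed tails — no excluded volume, no
interactions, exactly unit bonds — via mean-removal/renormalization to
closure at 1e-9; this sampler is simple and adequate for property tests but
is not claimed to be the exact uniform measure on closed polygons.

These fixtures exercise the full geometric pipeline, but they are idealized:
real loops are non-planar, surfaces curve, crossings crowd together, and
coordinates carry experimental noise. Passing the fixture round-trip
therefore demonstrates the correctness of the geometry, reduction and
nomenclature machinery — not the robustness of any particular threshold
choice on noisy crystal structures, which is why every threshold is exposed
and logged.

## Problem sizes used by the test suite

The suite round-trips all 49 canonical minor labels with up to three
piercings, checks 200 random planar-loop/zig-zag-tail instances against an
independent point-in-polygon oracle, and estimates piercing probability on
ideal chains with 120 samples per condition (loop 10, tails 5 vs 50) — a
deliberate desk-scale Monte Carlo that verifies the qualitative trend
(longer tails pierce more often) rather than a fitted probability curve.
PDB-wide census numbers require a full PDB snapshot and are out of scope;
three single-accession benchmarks (5yj7, 1cq3, 3a55) validate the pipeline
on real deposited structures when network access permits their download.

## Known limitations

* The minimized surface is approximate; for pathologically folded loops a
  sharper minimum could in principle change a marginal crossing. All
  piercing semantics are defined on the final mesh, deterministically.
* Non-disulfide bridge chemistry is inferred from atom element pairs, not
  from connectivity dictionaries; exotic linkages fall back to `other`.
* Bridges piercing loops (the cysteine-knot bridge-through-loop geometry)
  are out of scope: only main-chain tails pierce.
* The fingerprint does not characterize chain topology unequivocally — two
  linked loops and two independent loops can share `2L1`; no link invariant
  is computed.
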