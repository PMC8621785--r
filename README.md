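# lassotopo

Detection, classification and annotation of **complex lasso motifs** in
protein (or generic polymer) 3D structures.

A complex lasso forms when a backbone segment is closed into a covalent
loop by a side-chain bridge — a disulfide, or an amide, ester, thioester or
C–C bond — and one or both terminal tails thread through that loop. The
motif unifies lasso peptides (miniproteins such as Microcin J25) and
cysteine knots, and correlates with function: threaded antimicrobial
proteins act as molecular plugs, and the loop/tail arrangement can behave
as a redox-controlled switch.

Threading is decided geometrically. For a covalent loop closed by a bridge
between residues *i* and *j*, the loop's CA polygon is spanned by a
triangulated surface of approximately minimal area (boundary fixed to the
loop), and every tail segment is tested for oriented crossings through that
surface with signed-volume predicates. Crossings are signed `+`/`−` by the
right-hand rule around the loop traversed N→C, cleaned of surface wobble
(adjacent opposite-sign pairs within 2 Å) and of shallow passes (fewer than
3 tail residues beyond the crossing), and the surviving signed sequences
become the lasso type:

* `L n` — one tail, *n* alternating-side piercings (`L-1C`, `L+3C`);
* `LS n` — supercoiling: one tail, at least two consecutive same-side
  crossings (`LS2--N`);
* `LL i,j` / `LLS i,j` — both tails pierce (`LL+1,+2`, `LLS2--,+2`);
* `L0` — an unpierced loop.

Major types strip signs and tail letters; the per-chain **lasso
fingerprint** concatenates the major types of all pierced loops in
sequential order, suppressing `L0` and compressing consecutive repeats
(`2L1`, `LS32L1LS2`).

The package also scores the stabilization of piercing residues (distance
to local maxima of bulky-residue concentration and to local minima of the
B-factor or NMR ensemble deviation), classifies bridge conservation from
precomputed multiple sequence alignments (high / medium / poor at the
strict >80% / <30% boundaries), aggregates survey statistics, and contains
a deterministic generator of chains with any prescribed lasso type, which
doubles as the package's test oracle.

## Worked example

```r
library(lassotopo)

# build a chain whose loop is pierced once by the N-tail (+) and twice by
# the C-tail (- then +), write it as a CA-only PDB, and detect from file
fx <- make_lasso_fixture("LL+1,-2")
write_ca_pdb(fx$chain, "fixture.pdb", fx$bridges)
res <- detect_file("fixture.pdb")
print(res[[1]])
#> Lasso detection for chain 'A' (66 residues)
#>   bridges: 1   covalent loops: 1   fingerprint: "LL1,2"
#>   loop 24-35 (disulfide): LL+1,-2 [LL], 3 piercing(s), status certain

res[[1]]$loops[[1]]$piercings[, c("tail", "seg_from", "seg_to", "sign", "depth", "rank")]
#>   tail seg_from seg_to sign depth rank
#> 1    N       16     15    1    15    1
#> 2    C       45     46   -1    21    1
#> 3    C       50     51    1    16    2

res[[1]]$loops[[1]]$bridge_distance
#> [1] 8
```

The loop spans residues 24–35 and is closed by a disulfide-style bridge.
The N-tail pierces once in the `+` direction at segment 16→15 with 15
residues of tail beyond the crossing; the C-tail pierces twice (`−` then
`+`). The minor label `LL+1,-2` records both tails with their rank-1 signs;
the fingerprint keeps only the major type `LL1,2`. The bridge-to-nearest-
piercing sequential distance is 8 residues.

Survey aggregation over several chains:

```r
results <- lapply(c("L-1C", "L-1C", "L+1N", "LS2--C"), function(l) {
  x <- make_lasso_fixture(l)
  detect_chain(x$chain, bridges = x$bridges)
})
lasso_survey(results)
#> Lasso survey over 4 chain(s), 4 pierced loop(s)
#>   major types:  L1:3  LS2:1
#>   C-tail fraction (non-LL): 75.0%
#>   negative-nearest fraction (non-LL): 75.0%
```

## Command line

```sh
Rscript inst/cli/lasso.R detect structure.pdb --json out.json
Rscript inst/cli/lasso.R fingerprint structure.cif --format cif
Rscript inst/cli/lasso.R conserve family.aln --cols 12,47
Rscript inst/cli/lasso.R simulate --label LS2--C --out fixture.pdb
```

(After installation the script lives at
`system.file("cli/lasso.R", package = "lassotopo")`.)

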