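# apfp3d — stereoselective 3D atom-pair fingerprints for virtual screening

`apfp3d` is an R toolkit for ligand-based virtual screening (LBVS) with
scalar atom-pair fingerprints computed from 3D molecular structures.  It is
aimed at cheminformaticians who need compact shape and pharmacophore
descriptors that (unlike topological fingerprints) distinguish conformers
and diastereomers, together with a fast city-block-distance
nearest-neighbour search and the evaluation metrics used in enrichment
studies.

## The descriptors

For every heavy-atom pair *AB* at through-space distance *d<sub>AB</sub>*
(Å), a gaussian with unit peak amplitude and standard deviation
0.18·*d<sub>AB</sub>* is evaluated at 16 sampling distances

> 1.45, 1.71, 2.02, …, 17.36 Å  (d<sub>n+1</sub> = 1.18·d<sub>n</sub>)

Per-bit sums over all pairs are normalized by HAC<sup>1.5</sup> (HAC =
heavy atom count), scaled by 100 and rounded — the 16-bit **3DAPfp**.
Restricting the pairs to pharmacophore categories (hydrophobic Hyb,
H-bond acceptor HBA, donor HBD, planar sp2, plus the HBA–HBD cross pair)
gives the 80-bit **3DXfp**.  Replacing gaussian sampling by a hard 0.5 Å
binning of *d<sub>AB</sub>* over 0–20 Å, normalized by HAC, gives
**R3DAPfp** (40 bits) and **R3DXfp** (200 bits).  The topological parents
**APfp** (20 bits) and **Xfp** (55 bits) count pairs by shortest-path bond
distance, and the comparison shape descriptors **PMIfp** (normalized
principal moments of inertia), **USR** and **USRCAT** are included.

Databases are searched by city-block distance
CBD(a,b) = Σ|aᵢ − bᵢ| using a bit-sum hash index: entries are sorted by
their total bit value, and because |Σa − Σb| ≤ CBD(a,b) a k-NN scan can
expand outward from the query's sum and stop early.

## Worked example

```r
library(apfp3d)

# the canonical single-pair fixture: two atoms 8.51 A apart
pair <- make_pair(8.51)
fp_3dapfp(pair)
#> <fingerprint 3DAPfp> pair_8.51
#>  [1]  0  0  0  0  0  0  0  1  5 14 30 34 14  1  0  0
which(as.numeric(fp_r3dapfp(pair)) != 0)
#> [1] 18          # the 8.5-9.0 A regular bin

# folded vs extended: same topology, very different 3D shape
helix <- make_chain(24, geometry = "helix", radius = 3, pitch = 0.3)
rod   <- make_chain(24)
cbd(fp_apfp(helix),   fp_apfp(rod))     #> 0    (2D cannot tell them apart)
cbd(fp_3dapfp(helix), fp_3dapfp(rod))   #> 632  (3D separates them)

# indexed nearest-neighbour search
db  <- lapply(1:100, function(i) random_molecule(8, seed = i,
                                                 id = sprintf("mol%03d", i)))
idx <- build_index(lapply(db, fp_3dapfp))
as.data.frame(knn(idx, fp_3dapfp(db[[1]]), 5))
#>   rank mol_id cbd
#> 1    1 mol001   0
#> 2    2 mol077  41
#> 3    3 mol065  45
#> 4    4 mol079  47
#> 5    5 mol038  49

# shape triangle corners: rod (0,1) and disc (0.5,0.5)
npmi(rod)             #> 0.0 1.0
npmi(make_ring(12))   #> 0.5 0.5
```

The first gaussian fingerprint shows the single 8.51 Å pair smeared over
grid points 8–14 with its maximum at the 8.96 Å sampling point; the
regular-binned variant places one increment in bin R18.  The helix/rod
comparison illustrates why through-space fingerprints retrieve different
analogs for folded molecules than topological ones.

## Command line

```sh
inst/scripts/apfp3d fixtures --kind chain --n 20 --geometry helix --out toy.sdf
inst/scripts/apfp3d fp --scheme 3DXfp --in toy.sdf --out toy.fps
inst/scripts/apfp3d search --index db.fps --query-sdf query.sdf \
    --scheme 3DXfp --k 1000 --out hits.tsv
```

Subcommands: `prepare` (largest fragment + HAC ≤ 50 filter), `categories`,
`fp`, `search`, `bench recover|overlap`, `fixtures`.  Exit codes: 0 ok,
1 runtime error, 2 usage error.

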