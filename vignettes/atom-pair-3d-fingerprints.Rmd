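---
title: "3D atom-pair fingerprints: model, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{3D atom-pair fingerprints: model, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(apfp3d)
```

## Why through-space atom pairs

Topological atom-pair fingerprints count heavy-atom pairs by their
shortest-path bond distance.  They encode molecular shape surprisingly well,
but they are blind to everything the 2D graph does not determine:
conformation, diastereomerism, folding.  Replacing the bond count with the
euclidean through-space distance yields fingerprints that separate
diastereomers and folded/extended conformers while retaining the scalar,
fixed-length form that makes city-block-distance searches over very large
databases cheap.

Two binning principles are implemented:

* **Gaussian/exponential sampling** (`fp_3dapfp`, 16 bits).  Each pair
  contributes a gaussian centred at its distance $d_{AB}$ with
  $\sigma = 0.18\,d_{AB}$, evaluated at 16 sampling distances in geometric
  progression, $d_1 = 1.45$ Å and $d_{n+1} = 1.18\,d_n$ (so $d_{16} =
  17.36$ Å).  Bit $n$ is $\mathrm{round}\!\left(100\sum_{AB}
  e^{-(s_n - d_{AB})^2 / (2(0.18 d_{AB})^2)} / \mathrm{HAC}^{1.5}\right)$.
  The proportional width makes shape perception fuzzier at long range,
  which is what allows 16 bits to cover 1–20 Å.
* **Regular binning** (`fp_r3dapfp`, 40 bits).  Each pair increments the
  half-open 0.5 Å bin $[0.5(k{-}1), 0.5k)$ containing its distance; counts
  are normalized by HAC and expressed in percent.  Pairs at 20 Å or beyond
  are dropped (with a logged count) — relevant only for molecules far
  larger than the HAC ≤ 50 screening regime.

Category-extended versions (`fp_3dxfp`, 80 bits; `fp_r3dxfp`, 200 bits)
compute the parent scheme within five atom-pair categories in fixed block
order: Hyb–Hyb, HBA–HBA, HBD–HBD, sp2–sp2, HBA–HBD.  The topological
parents `fp_apfp` (20 bits, 1–20 bonds) and `fp_xfp` (55 bits) and the
shape descriptors `fp_pmifp`, `fp_usr`, `fp_usrcat` complete the family.

## Parameters that matter

| Parameter | Default | Meaning |
|---|---|---|
| `d1`, `ratio`, `n` | 1.45 Å, 1.18, 16 | geometric sampling grid |
| `width_fraction` | 0.18 | gaussian $\sigma$ as fraction of $d_{AB}$ |
| bin width, range | 0.5 Å, [0, 20) Å | regular binning |
| normalization | HAC$^{1.5}$ (gaussian), HAC (regular) | size damping |
| `max_hac` | 50 | database preparation cut |
| HAC window | ±2 | size-constrained recovery subsets |

The defaults are the published operating point of the method; the grid and
width were reported as optimal in the original enrichment studies and are
exposed as arguments only so that tests can probe the formula.

## Design choices where the description was open

* **"Width" = standard deviation.**  The gaussian's "width of
  $0.18\,d_{AB}$" is interpreted as $\sigma$, with unit peak amplitude.
  Amplitude choice cancels into the percent scale; a FWHM reading would
  narrow every gaussian by a factor 2.35 and is not recoverable from the
  published numbers at this precision.
* **Rounding** is half-away-from-zero (`floor(x + 0.5)` on non-negative
  values), avoiding platform-dependent banker's rounding.
* **Half-open bins.**  A distance exactly on a 0.5 Å boundary belongs to
  the upper bin: 8.50 Å and 8.51 Å both fall in bin R18 (8.5–9 Å).
  Coincident atoms ($d = 0$) fall in bin R1 for regular schemes and
  contribute nothing to gaussian schemes (degenerate gaussian suppressed).
* **Category normalization.**  Same-category blocks replace HAC by the
  category atom count (to the same power as the parent scheme); the
  HBA–HBD cross block normalizes to the acceptor count.  A category with
  fewer than two atoms (or a cross block missing either side) yields an
  all-zero block.  An unordered pair in which one atom accepts and the
  other donates counts once in the cross block, also when an atom carries
  both flags.
* **Xfp layout.**  The 55-bit length is realized as 5 blocks × 11
  topological distances (1–11 bonds), the unique block-uniform
  factorization over five categories.
* **USR third moment** is excess kurtosis (0 for zero-variance
  distributions), matching the descriptor table this family was evaluated
  against, although the original USR publication uses skewness.  The
  divergence is intentional and documented rather than silently fixed.
* **PMIfp** divides each principal moment of the heavy-atom point set
  (standard atomic masses) by the summed heavy-atom mass.  For a molecule
  of uniform composition this cancels mass entirely; the normalized pair
  (I1/I3, I2/I3) is what the shape triangle plots.
* **Far tail.**  With $\sigma \propto d_{AB}$ the gaussian of a very
  distant pair never underflows to zero at the grid (a 1000 Å pair still
  leaves $\sim 10^{-7}$ at 17.36 Å); no truncation threshold is applied,
  so the formula is exact and free of hidden parameters.

## Atom typing

The pharmacophore categories follow standard conventions: HBA = N or O not
positively charged, excluding N donating its lone pair into a π system
(amide/aniline-type and aromatic N–H); HBD = N or O bearing at least one
hydrogen (explicit hydrogens are recorded before being stripped at parse
time, implicit ones inferred from default valences and formal charges);
Hyb = C, S or halogen with no N/O neighbour; sp2 = aromatic atoms plus
atoms in double bonds.  Aromaticity is perceived by a pragmatic ring rule
(smallest ring through each ring bond; a 5–7-ring is aromatic when every
member is π-bonded within the ring or is an N/O/S heteroatom contributing
a lone pair) rather than Hückel electron counting.  These rules are an
acknowledged approximation: published screening services inherit their
exact typing from proprietary toolkits, so bit-level identity with them is
not claimed, and all results in this package are internally consistent
with this module's own typing.

## The search index

`build_index` sorts fingerprints by total bit value.  For any two vectors
$|\sum a - \sum b| \le \mathrm{CBD}(a, b)$, so `knn` and `range_query`
expand outward from the query's position in sum order and terminate once
the sum gap exceeds the current k-th best (or the range radius).  Results
are therefore exactly those of an exhaustive scan — the tests assert
equality against a brute-force oracle on hundreds of random fingerprints —
with ties at the cut broken by ascending molecule id for reproducibility
across platforms and insertion orders.

## What the synthetic generators emulate — and what they do not

All tests run on toy molecules built in code: exact two-atom pairs, linear
and helical chains, rings, regular polyhedra, and seeded random point
chains.  These exercise every formula exactly (distances are known in
closed form) and reproduce the structural regimes that matter — folded
versus extended chains, diastereomeric embeddings of one graph, rod/disc/
sphere shapes.  They are chemically naive: geometries ignore valence
angles and van der Waals contacts, and random chains are not
energy-minimized conformers.  Passing tests therefore certify the
correctness of the descriptors, search and metrics, not screening
performance on real databases, which additionally depends on conformer
quality and ionization handling.  Database preparation reproduces the
published filters (largest fragment, HAC ≤ 50) but deliberately omits
pH 7.4 ionization adjustment, for which no public algorithm is specified;
formal charges are taken from the input file.

Problem sizes used by the test suite — 500-entry indexes, ≤6-atom oracle
fixtures, $10^4$ random vector pairs for the metric properties, $10^3$
shuffles for the null-AUC check — were chosen as the smallest sets that
make the deterministic oracles exhaustive and the stochastic checks stable
to the asserted tolerances.

## Known limitations

* Mirror images are indistinguishable by construction: all schemes consume
  pair distances or unsigned moments, which reflections preserve.
  Enantioselective searching requires an overlay method, out of scope.
* One conformer per record; conformer ensembles are not aggregated.
* SDF charges are carried through the V2000 charge code (±3) and `M CHG`
  lines on read, but only the charge-code range on write.
* MOL2 and SMILES input rely on OpenBabel via ChemmineOB; records that
  OpenBabel cannot parse are skipped with a warning.
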