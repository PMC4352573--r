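#' Fingerprint schemes and their lengths
#'
#' Nine scalar fingerprint schemes are supported.  The gaussian-sampled 3D
#' atom-pair fingerprints (`3DAPfp`, 16 bits; `3DXfp`, 80 bits) and their
#' regularly binned variants (`R3DAPfp`, 40 bits; `R3DXfp`, 200 bits) encode
#' through-space distances; `APfp` (20 bits) and `Xfp` (55 bits) are the
#' topological parents; `PMIfp` (3), `USR` (12) and `USRCAT` (60) are shape
#' descriptors used for comparison.
#'
#' @format A named integer vector mapping scheme name to vector length.
#' @export
SCHEME_LENGTHS <- c(`3DAPfp` = 16L, `3DXfp` = 80L, `R3DAPfp` = 40L,
                    `R3DXfp` = 200L, APfp = 20L, Xfp = 55L,
                    PMIfp = 3L, USR = 12L, USRCAT = 60L)

# category block order shared by every category-extended scheme
CATEGORY_BLOCKS <- c("HybHyb", "HBAHBA", "HBDHBD", "sp2sp2", "HBAHBD")

#' Construct a fingerprint object
#'
#' @param values numeric vector of the scheme's fixed length; non-negative.
#' @param scheme one of `names(SCHEME_LENGTHS)`.
#' @param mol_id identifier of the fingerprinted molecule.
#' @return A numeric vector of class `fingerprint` with attributes `scheme`
#'   and `mol_id`.
#' @export
fingerprint <- function(values, scheme, mol_id = "") {
  scheme <- match.arg(scheme, names(SCHEME_LENGTHS))
  values <- as.numeric(values)
  if (length(values) != SCHEME_LENGTHS[[scheme]])
    stop(sprintf("%s fingerprints have length %d, got %d",
                 scheme, SCHEME_LENGTHS[[scheme]], length(values)),
         call. = FALSE)
  if (scheme %in% c("3DAPfp", "3DXfp", "R3DAPfp", "R3DXfp", "APfp", "Xfp") &&
      any(values < 0))
    stop("fingerprint values must be non-negative", call. = FALSE)
  structure(values, scheme = scheme, mol_id = as.character(mol_id),
            class = "fingerprint")
}

#' @export
print.fingerprint <- function(x, ...) {
  cat(sprintf("<fingerprint %s> %s\n", attr(x, "scheme"), attr(x, "mol_id")))
  print(as.numeric(x))
  invisible(x)
}

fp_scheme <- function(fp) attr(fp, "scheme")
fp_id <- function(fp) attr(fp, "mol_id")

# "rounded to the integer value" with ties going away from zero, so the
# result does not depend on the platform's banker's rounding
round_half_up <- function(x) floor(x + 0.5)

#' The geometric distance sampling grid
#'
#' Sixteen sampling distances starting at 1.45 Angstrom, each 1.18 times the
#' previous (1.45, 1.71, 2.02, ..., 17.36 A), together with the relative
#' gaussian width 0.18.  These are the sampling points at which every atom
#' pair's gaussian is evaluated for the 16-bit gaussian-sampled fingerprint.
#'
#' @param d1 first sampling distance in Angstrom.
#' @param ratio multiplier between consecutive sampling distances.
#' @param n number of sampling points.
#' @param width_fraction gaussian sigma as a fraction of the pair distance.
#' @return A list with elements `distances` (length-`n` numeric) and
#'   `width_fraction`.
#' @export
sampling_grid <- function(d1 = 1.45, ratio = 1.18, n = 16,
                          width_fraction = 0.18) {
  list(distances = d1 * ratio^(0:(n - 1)), width_fraction = width_fraction)
}

#' Gaussian sampling of one atom-pair distance
#'
#' Evaluates, at every grid distance s, the gaussian centred at the pair
#' distance with standard deviation `width_fraction * d_ab` and unit peak
#' amplitude: `exp(-(s - d_ab)^2 / (2 * (width_fraction * d_ab)^2))`.
#' A coincident pair (`d_ab = 0`) has a degenerate gaussian and contributes
#' the zero vector.
#'
#' @param d_ab atom-pair distance in Angstrom.
#' @param grid a [sampling_grid()].
#' @return Numeric vector, one value per grid distance.
#' @export
gaussian_sample <- function(d_ab, grid = sampling_grid()) {
  if (d_ab <= 0) return(numeric(length(grid$distances)))
  sigma <- grid$width_fraction * d_ab
  exp(-(grid$distances - d_ab)^2 / (2 * sigma^2))
}

#' Through-space heavy-atom pair distances
#'
#' @param mol a [molecule3d] with `has_3d = TRUE`.
#' @return A data.frame with columns `i`, `j` (i < j) and `d` (Angstrom),
#'   one row per unordered heavy-atom pair.  Coincident atoms trigger a
#'   warning but the pair is kept with `d = 0`.
#' @export
pair_distances_3d <- function(mol) {
  stopifnot(mol$has_3d, hac(mol) >= 1)
  n <- hac(mol)
  if (n < 2)
    return(data.frame(i = integer(0), j = integer(0), d = numeric(0)))
  idx <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  dm <- as.matrix(stats::dist(mol$coords))
  d <- dm[idx]
  if (any(d == 0))
    warning(sprintf("%d coincident atom pair(s) in %s", sum(d == 0), mol$id),
            call. = FALSE)
  data.frame(i = idx[, "row"], j = idx[, "col"], d = d)
}

#' Topological heavy-atom pair distances
#'
#' Shortest-path bond counts between all heavy-atom pairs, computed on the
#' bond graph.  Requires a connected molecule; apply [largest_fragment()]
#' first for complexed records.
#'
#' @param mol a connected [molecule3d].
#' @return A data.frame with columns `i`, `j` (i < j) and `t` (bonds).
#' @export
pair_distances_topological <- function(mol) {
  n <- hac(mol)
  if (n < 2)
    return(data.frame(i = integer(0), j = integer(0), t = integer(0)))
  g <- mol_graph(mol)
  if (igraph::components(g)$no > 1)
    stop("molecule is disconnected; apply largest_fragment() first",
         call. = FALSE)
  dm <- igraph::distances(g)
  idx <- which(upper.tri(dm), arr.ind = TRUE)
  data.frame(i = idx[, "row"], j = idx[, "col"], t = as.integer(dm[idx]))
}

# shared accumulation of the gaussian-sampled scheme over a set of pairs,
# normalized by norm_count^1.5
gaussian_accumulate <- function(d, norm_count, grid = sampling_grid()) {
  acc <- numeric(length(grid$distances))
  for (dd in d) acc <- acc + gaussian_sample(dd, grid)
  if (norm_count > 0)
    round_half_up(100 * acc / norm_count^1.5)
  else
    numeric(length(grid$distances))
}

# shared accumulation of the regular-binned scheme: 0.5 A half-open bins
# [0, 20) A, counts normalized by norm_count; d >= 20 dropped with a message
regular_accumulate <- function(d, norm_count, mol_id = "",
                               bin_width = 0.5, d_max = 20) {
  n_bins <- as.integer(d_max / bin_width)
  dropped <- sum(d >= d_max)
  if (dropped > 0)
    message(sprintf("%s: %d atom pair(s) beyond %g A dropped from regular bins",
                    mol_id, dropped, d_max))
  d <- d[d < d_max]
  counts <- tabulate(floor(d / bin_width) + 1L, nbins = n_bins)
  if (norm_count > 0)
    round_half_up(100 * counts / norm_count)
  else
    numeric(n_bins)
}

#' 16-bit gaussian-sampled 3D atom-pair fingerprint
#'
#' For every heavy-atom pair a unit-amplitude gaussian centred at the pair
#' distance (sigma = 18% of the distance) is evaluated at the 16 grid
#' distances; per-bit sums are divided by HAC^1.5, multiplied by 100 and
#' rounded to integers.  The HAC^1.5 normalization reduces sensitivity to
#' molecular size.
#'
#' @param mol a [molecule3d] with 3D coordinates.
#' @param grid sampling grid, by default [sampling_grid()].
#' @return A 16-value [fingerprint] of scheme `3DAPfp`.
#' @export
fp_3dapfp <- function(mol, grid = sampling_grid()) {
  pd <- pair_distances_3d(mol)
  fingerprint(gaussian_accumulate(pd$d, hac(mol), grid), "3DAPfp", mol$id)
}

# pair subsets for the five category blocks; cross pairs count once per
# unordered pair when one atom accepts and the other donates
category_pair_sets <- function(pd, cats) {
  same <- function(flag) pd[flag[pd$i] & flag[pd$j], , drop = FALSE]
  cross <- pd[(cats$hba[pd$i] & cats$hbd[pd$j]) |
              (cats$hba[pd$j] & cats$hbd[pd$i]), , drop = FALSE]
  list(HybHyb = same(cats$hyb), HBAHBA = same(cats$hba),
       HBDHBD = same(cats$hbd), sp2sp2 = same(cats$sp2), HBAHBD = cross)
}

# per-block normalization counts: the category atom count for same-category
# blocks, the acceptor count for the HBA-HBD cross block; a same-category
# block needs >= 2 atoms to hold a pair
category_norm_counts <- function(cats) {
  counts <- c(HybHyb = sum(cats$hyb), HBAHBA = sum(cats$hba),
              HBDHBD = sum(cats$hbd), sp2sp2 = sum(cats$sp2),
              HBAHBD = sum(cats$hba))
  pairable <- c(counts[1:4] >= 2, sum(cats$hba) > 0 && sum(cats$hbd) > 0)
  counts[!pairable] <- 0
  counts
}

#' 80-bit category-extended gaussian 3D fingerprint
#'
#' The gaussian-sampled fingerprint computed within each of five atom-pair
#' categories and concatenated in the fixed block order Hyb-Hyb, HBA-HBA,
#' HBD-HBD, sp2-sp2, HBA-HBD.  Same-category blocks are normalized by the
#' category atom count to the power 1.5; the acceptor-donor cross block is
#' normalized to the acceptor count.  A block whose category cannot form a
#' pair is all-zero.
#'
#' @param mol a [molecule3d] with 3D coordinates.
#' @param cats categories from [assign_categories()]; computed when omitted.
#' @param grid sampling grid.
#' @return An 80-value [fingerprint] of scheme `3DXfp`.
#' @export
fp_3dxfp <- function(mol, cats = assign_categories(mol), grid = sampling_grid()) {
  pd <- pair_distances_3d(mol)
  sets <- category_pair_sets(pd, cats)
  norms <- category_norm_counts(cats)
  blocks <- lapply(CATEGORY_BLOCKS, function(bl)
    gaussian_accumulate(sets[[bl]]$d, norms[[bl]], grid))
  fingerprint(unlist(blocks), "3DXfp", mol$id)
}

#' 40-bit regularly binned 3D atom-pair fingerprint
#'
#' Every heavy-atom pair increments the 0.5 Angstrom bin containing its
#' through-space distance; bins cover `[0, 20)` A half-open, so bin k spans
#' `[0.5 (k-1), 0.5 k)`.  Counts are divided by HAC, multiplied by 100 and
#' rounded.  Pairs at 20 A or more are dropped with a message.
#'
#' @param mol a [molecule3d] with 3D coordinates.
#' @return A 40-value [fingerprint] of scheme `R3DAPfp`.
#' @export
fp_r3dapfp <- function(mol) {
  pd <- pair_distances_3d(mol)
  fingerprint(regular_accumulate(pd$d, hac(mol), mol$id), "R3DAPfp", mol$id)
}

#' 200-bit category-extended regularly binned 3D fingerprint
#'
#' Five 40-bit regular-binned blocks in the order Hyb-Hyb, HBA-HBA, HBD-HBD,
#' sp2-sp2, HBA-HBD; same-category blocks are normalized by the category
#' atom count, the cross block by the acceptor count.
#'
#' @inheritParams fp_3dxfp
#' @return A 200-value [fingerprint] of scheme `R3DXfp`.
#' @export
fp_r3dxfp <- function(mol, cats = assign_categories(mol)) {
  pd <- pair_distances_3d(mol)
  sets <- category_pair_sets(pd, cats)
  norms <- category_norm_counts(cats)
  blocks <- lapply(CATEGORY_BLOCKS, function(bl)
    regular_accumulate(sets[[bl]]$d, norms[[bl]], mol$id))
  fingerprint(unlist(blocks), "R3DXfp", mol$id)
}

#' 20-bit topological atom-pair fingerprint
#'
#' Bit t counts the heavy-atom pairs at topological distance t bonds
#' (shortest path), t = 1..20, normalized to HAC, times 100, rounded.
#' Pairs farther than 20 bonds apart do not contribute.
#'
#' @param mol a connected [molecule3d].
#' @return A 20-value [fingerprint] of scheme `APfp`.
#' @export
fp_apfp <- function(mol) {
  pd <- pair_distances_topological(mol)
  counts <- tabulate(pd$t[pd$t >= 1 & pd$t <= 20], nbins = 20)
  fingerprint(round_half_up(100 * counts / hac(mol)), "APfp", mol$id)
}

#' 55-bit category-extended topological fingerprint
#'
#' Five 11-bit blocks (topological distances 1-11 bonds) in the order
#' Hyb-Hyb, HBA-HBA, HBD-HBD, sp2-sp2, HBA-HBD, each normalized by its
#' category count (acceptor count for the cross block).
#'
#' @param mol a connected [molecule3d].
#' @param cats categories from [assign_categories()].
#' @return A 55-value [fingerprint] of scheme `Xfp`.
#' @export
fp_xfp <- function(mol, cats = assign_categories(mol)) {
  pd <- pair_distances_topological(mol)
  sets <- category_pair_sets(pd, cats)
  norms <- category_norm_counts(cats)
  blocks <- lapply(CATEGORY_BLOCKS, function(bl) {
    t <- sets[[bl]]$t
    counts <- tabulate(t[t >= 1 & t <= 11], nbins = 11)
    if (norms[[bl]] > 0) round_half_up(100 * counts / norms[[bl]]) else numeric(11)
  })
  fingerprint(unlist(blocks), "Xfp", mol$id)
}

# principal moments of inertia of the heavy-atom point set with atomic masses
principal_moments <- function(mol) {
  m <- atomic_mass(mol$elements)
  x <- sweep(mol$coords, 2, colSums(mol$coords * m) / sum(m))
  xx <- x[, 1]; yy <- x[, 2]; zz <- x[, 3]
  tensor <- matrix(c(
    sum(m * (yy^2 + zz^2)), -sum(m * xx * yy),      -sum(m * xx * zz),
    -sum(m * xx * yy),      sum(m * (xx^2 + zz^2)), -sum(m * yy * zz),
    -sum(m * xx * zz),      -sum(m * yy * zz),      sum(m * (xx^2 + yy^2))),
    nrow = 3)
  ev <- eigen(tensor, symmetric = TRUE)$values
  sort(pmax(ev, 0))  # I1 <= I2 <= I3; clip tiny negative round-off
}

#' Principal-moments-of-inertia fingerprint and normalized moments
#'
#' `fp_pmifp` returns the three principal moments of inertia of the
#' heavy-atom point set (atomic masses), each divided by the summed
#' heavy-atom mass.  `npmi` returns the normalized pair
#' (I1/I3, I2/I3) locating the molecule in the rod-disc-sphere shape
#' triangle: rod (0, 1), disc (0.5, 0.5), sphere (1, 1).
#'
#' @param mol a [molecule3d] with 3D coordinates and at least 3 atoms.
#' @return `fp_pmifp`: a 3-value [fingerprint] of scheme `PMIfp`;
#'   `npmi`: numeric vector `c(i1_i3, i2_i3)`.
#' @export
fp_pmifp <- function(mol) {
  stopifnot(mol$has_3d, hac(mol) >= 3)
  I <- principal_moments(mol)
  fingerprint(I / sum(atomic_mass(mol$elements)), "PMIfp", mol$id)
}

#' @rdname fp_pmifp
#' @export
npmi <- function(mol) {
  stopifnot(mol$has_3d, hac(mol) >= 3)
  I <- principal_moments(mol)
  if (I[3] <= 0) return(c(i1_i3 = 1, i2_i3 = 1))  # all atoms coincident
  c(i1_i3 = I[1] / I[3], i2_i3 = I[2] / I[3])
}

# mean, population standard deviation, excess kurtosis of a distance set;
# kurtosis is 0 for a degenerate (zero-variance) distribution
usr_moments <- function(d) {
  mu <- mean(d)
  m2 <- mean((d - mu)^2)
  if (m2 <= 0) return(c(mu, 0, 0))
  m4 <- mean((d - mu)^4)
  c(mu, sqrt(m2), m4 / m2^2 - 3)
}

usr_reference_points <- function(coords) {
  ctd <- colMeans(coords)
  d_ctd <- sqrt(rowSums(sweep(coords, 2, ctd)^2))
  cst <- coords[which.min(d_ctd), ]
  fct <- coords[which.max(d_ctd), ]
  d_fct <- sqrt(rowSums(sweep(coords, 2, fct)^2))
  ftf <- coords[which.max(d_fct), ]
  list(ctd = ctd, cst = cst, fct = fct, ftf = ftf)
}

usr_block <- function(coords, refs) {
  if (is.null(coords) || nrow(coords) == 0) return(numeric(12))
  unlist(lapply(refs, function(p)
    usr_moments(sqrt(rowSums(sweep(coords, 2, p)^2)))), use.names = FALSE)
}

#' Ultrafast shape recognition descriptor
#'
#' Twelve reals: for each of four reference points (centroid, atom closest
#' to the centroid, atom farthest from the centroid, atom farthest from the
#' previous) the distribution of distances to all heavy atoms is summarized
#' by mean, standard deviation and excess kurtosis.  Kurtosis (rather than
#' the skewness of the original descriptor) is used as third moment; it is
#' defined as 0 for degenerate distributions.
#'
#' @param mol a [molecule3d] with 3D coordinates and at least 2 atoms.
#' @return A 12-value [fingerprint] of scheme `USR`.
#' @export
fp_usr <- function(mol) {
  stopifnot(mol$has_3d, hac(mol) >= 2)
  refs <- usr_reference_points(mol$coords)
  fingerprint(usr_block(mol$coords, refs), "USR", mol$id)
}

#' Category-extended ultrafast shape recognition descriptor
#'
#' The 12 USR moments computed on five atom subsets -- all atoms,
#' hydrophobic, aromatic, acceptor, donor -- always using the reference
#' points of the full molecule.  Empty subsets yield zero blocks; 60 reals.
#'
#' @param mol a [molecule3d] with 3D coordinates and at least 2 atoms.
#' @param cats categories from [assign_categories()].
#' @return A 60-value [fingerprint] of scheme `USRCAT`.
#' @export
fp_usrcat <- function(mol, cats = assign_categories(mol)) {
  stopifnot(mol$has_3d, hac(mol) >= 2)
  refs <- usr_reference_points(mol$coords)
  subsets <- list(rep(TRUE, hac(mol)), cats$hyb, cats$aromatic,
                  cats$hba, cats$hbd)
  vals <- unlist(lapply(subsets, function(keep)
    usr_block(mol$coords[keep, , drop = FALSE], refs)))
  fingerprint(vals, "USRCAT", mol$id)
}

#' Compute a fingerprint by scheme name
#'
#' Dispatch helper used by the fingerprint file writer and the command-line
#' interface.
#'
#' @param mol a [molecule3d].
#' @param scheme one of `names(SCHEME_LENGTHS)`.
#' @return A [fingerprint].
#' @export
compute_fingerprint <- function(mol, scheme) {
  scheme <- match.arg(scheme, names(SCHEME_LENGTHS))
  switch(scheme,
         `3DAPfp` = fp_3dapfp(mol),
         `3DXfp` = fp_3dxfp(mol),
         `R3DAPfp` = fp_r3dapfp(mol),
         `R3DXfp` = fp_r3dxfp(mol),
         APfp = fp_apfp(mol),
         Xfp = fp_xfp(mol),
         PMIfp = fp_pmifp(mol),
         USR = fp_usr(mol),
         USRCAT = fp_usrcat(mol))
}
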