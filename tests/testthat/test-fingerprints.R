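all_3d_schemes <- c("3DAPfp", "3DXfp", "R3DAPfp", "R3DXfp", "PMIfp", "USR", "USRCAT")

test_that("sampling grid reproduces the geometric distance series", {
  g <- sampling_grid()
  expect_length(g$distances, 16)
  expect_equal(round(g$distances, 2),
               c(1.45, 1.71, 2.02, 2.38, 2.81, 3.32, 3.91, 4.62, 5.45, 6.43,
                 7.59, 8.96, 10.57, 12.47, 14.71, 17.36))
  expect_equal(g$distances[16] / g$distances[1], 1.18^15)
  expect_true(all(diff(g$distances) > 0))
  expect_equal(g$width_fraction, 0.18)
})

test_that("gaussian sampling follows the stated formula", {
  g <- sampling_grid()
  expect_equal(gaussian_sample(1.45, g)[1], 1.0)  # sampling point at the centre
  expect_equal(gaussian_sample(8.51, g),
               exp(-(g$distances - 8.51)^2 / (2 * (0.18 * 8.51)^2)))
  # far tail: at d = 1000 A the closest grid point sits > 5 sigma away
  expect_true(all(gaussian_sample(1000, g) < 1e-6))
  expect_equal(gaussian_sample(0, g), rep(0, 16))
})

test_that("3D pair distances enumerate all unordered heavy-atom pairs", {
  pd <- pair_distances_3d(make_pair(8.51))
  expect_equal(nrow(pd), 1)
  expect_equal(pd$d, 8.51)

  lone <- molecule3d("x", "C", rbind(c(0, 0, 0)))
  expect_equal(nrow(pair_distances_3d(lone)), 0)

  tri <- make_ring(3, radius = 2 / sqrt(3))  # equilateral, side 2
  pd <- pair_distances_3d(tri)
  expect_equal(pd$d, rep(2, 3))

  chain <- make_chain(8)
  expect_equal(nrow(pair_distances_3d(chain)), 8 * 7 / 2)

  co <- molecule3d("co", c("C", "C"), rbind(c(1, 1, 1), c(1, 1, 1)),
                   cbind(1L, 2L, 1L))
  expect_warning(pd <- pair_distances_3d(co), "coincident")
  expect_equal(pd$d, 0)
})

test_that("topological distances are shortest-path bond counts", {
  butane <- make_chain(4)
  expect_equal(sort(pair_distances_topological(butane)$t), c(1, 1, 1, 2, 2, 3))

  benzene <- make_ring(6)
  pd <- pair_distances_topological(benzene)
  for (atom in 1:6) {
    dists <- sort(c(pd$t[pd$i == atom], pd$t[pd$j == atom]))
    expect_equal(dists, c(1, 1, 2, 2, 3))
  }

  two_parts <- molecule3d("2p", c("C", "C", "C"),
                          rbind(c(0, 0, 0), c(1.5, 0, 0), c(9, 0, 0)),
                          cbind(1L, 2L, 1L))
  expect_error(pair_distances_topological(two_parts), "largest_fragment")
})

test_that("gaussian 3D fingerprint matches the literal formula", {
  lone <- molecule3d("x", "C", rbind(c(0, 0, 0)))
  expect_equal(as.numeric(fp_3dapfp(lone)), rep(0, 16))

  pairmol <- make_pair(8.51)
  g <- exp(-(sampling_grid()$distances - 8.51)^2 / (2 * (0.18 * 8.51)^2))
  expect_equal(as.numeric(fp_3dapfp(pairmol)), floor(100 * g / 2^1.5 + 0.5))

  helix <- make_chain(12, geometry = "helix")
  expect_equal(as.numeric(fp_3dapfp(helix)), oracle_3dapfp(helix))
})

test_that("regular-binned fingerprint uses half-open 0.5 A bins over [0,20)", {
  expect_equal(which(as.numeric(fp_r3dapfp(make_pair(8.51))) > 0), 18L)
  expect_equal(which(as.numeric(fp_r3dapfp(make_pair(8.50))) > 0), 18L)
  expect_equal(as.numeric(fp_r3dapfp(make_pair(8.51)))[18], 50)  # 100 * 1 / 2

  far <- make_pair(25)
  expect_message(fpv <- fp_r3dapfp(far), "dropped")
  expect_equal(as.numeric(fpv), rep(0, 40))

  edge <- make_pair(19.99)
  expect_equal(which(as.numeric(fp_r3dapfp(edge)) > 0), 40L)

  co <- molecule3d("co", c("C", "C"), rbind(c(0, 0, 0), c(0, 0, 0)),
                   cbind(1L, 2L, 1L))
  suppressWarnings(expect_equal(which(as.numeric(fp_r3dapfp(co)) > 0), 1L))
})

test_that("topological fingerprint counts pairs per bond distance", {
  butane <- make_chain(4)
  expect_equal(as.numeric(fp_apfp(butane)),
               c(75, 50, 25, rep(0, 17)))  # round(100 * {3,2,1} / 4)

  lone <- molecule3d("x", "C", rbind(c(0, 0, 0)))
  expect_equal(as.numeric(fp_apfp(lone)), rep(0, 20))

  # a pair 21 bonds apart contributes nothing
  long <- make_chain(22)
  expect_equal(as.numeric(fp_apfp(long)), oracle_apfp(long))
  expect_equal(sum(oracle_topo_dist(long) == 21) / 2, 1)
})

test_that("category-extended schemes follow the fixed block layout", {
  # plain alkane chain: only the Hyb-Hyb block can fire
  alkane <- make_chain(6)
  cats <- assign_categories(alkane)
  expect_true(all(cats$hyb) && !any(cats$hba | cats$hbd | cats$sp2))

  x3d <- as.numeric(fp_3dxfp(alkane, cats))
  expect_equal(x3d[17:80], rep(0, 64))
  expect_equal(x3d[1:16], as.numeric(fp_3dapfp(alkane)))  # category = all atoms

  rx <- as.numeric(fp_r3dxfp(alkane, cats))
  expect_equal(rx[41:200], rep(0, 160))
  expect_equal(rx[1:40], as.numeric(fp_r3dapfp(alkane)))

  xfp <- as.numeric(fp_xfp(alkane, cats))
  expect_equal(xfp[12:55], rep(0, 44))
  apfp_counts <- tabulate(pair_distances_topological(alkane)$t, 11)
  expect_equal(xfp[1:11], floor(100 * apfp_counts / 6 + 0.5))
})

test_that("the acceptor-donor cross block is normalized to the acceptor count", {
  # one pure acceptor (O-) and one pure donor (N+ with hydrogens) at 8.51 A
  mol <- molecule3d("ad", c("O", "N"), rbind(c(0, 0, 0), c(8.51, 0, 0)),
                    cbind(1L, 2L, 1L), c(-1L, 1L))
  cats <- assign_categories(mol)
  expect_equal(which(cats$hba), 1L)
  expect_equal(which(cats$hbd), 2L)

  x3d <- as.numeric(fp_3dxfp(mol, cats))
  g <- exp(-(sampling_grid()$distances - 8.51)^2 / (2 * (0.18 * 8.51)^2))
  expect_equal(x3d[1:64], rep(0, 64))              # same-category blocks empty
  expect_equal(x3d[65:80], floor(100 * g / 1^1.5 + 0.5))

  rx <- as.numeric(fp_r3dxfp(mol, cats))
  expect_equal(rx[1:160], rep(0, 160))
  expect_equal(which(rx[161:200] > 0), 18L)
  expect_equal(rx[160 + 18], 100)                  # 1 pair / 1 acceptor * 100
})

test_that("atom-pair schemes equal literal-formula oracles on small fixtures", {
  set.seed(99)
  mols <- c(
    list(make_pair(3.3, c("C", "N")),
         make_chain(5),
         make_chain(6, geometry = "helix", radius = 2, pitch = 0.4),
         make_ring(6, element = c("N", rep("C", 5)), bond_orders = c(2, 1)),
         make_ring(5, element = c("O", "C", "C", "N", "C"),
                   bond_orders = c(1L, 2L, 1L, 1L, 2L))),
    lapply(1:6, function(s) random_molecule(sample(2:6, 1) + (s %% 2),
                                            box = 6, seed = s)))
  for (mol in mols) {
    cats <- assign_categories(mol)
    expect_equal(as.numeric(fp_3dapfp(mol)), oracle_3dapfp(mol), info = mol$id)
    expect_equal(suppressMessages(as.numeric(fp_r3dapfp(mol))),
                 oracle_r3dapfp(mol), info = mol$id)
    expect_equal(as.numeric(fp_apfp(mol)), oracle_apfp(mol), info = mol$id)
    expect_equal(as.numeric(fp_3dxfp(mol, cats)), oracle_3dxfp(mol, cats),
                 info = mol$id)
    expect_equal(suppressMessages(as.numeric(fp_r3dxfp(mol, cats))),
                 oracle_r3dxfp(mol, cats), info = mol$id)
    expect_equal(as.numeric(fp_xfp(mol, cats)), oracle_xfp(mol, cats),
                 info = mol$id)
  }
})

test_that("normalized principal moments hit the rod, disc and sphere corners", {
  rod <- make_chain(9)
  expect_equal(unname(npmi(rod)), c(0, 1), tolerance = 1e-9)

  disc <- make_ring(12)
  expect_equal(unname(npmi(disc)), c(0.5, 0.5), tolerance = 1e-9)

  octa <- molecule3d("octa", rep("C", 6),
                     rbind(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0),
                           c(0, -1, 0), c(0, 0, 1), c(0, 0, -1)),
                     cbind(1:5, c(2:5, 6L), 1L))
  expect_equal(unname(npmi(octa)), c(1, 1), tolerance = 1e-9)

  pmi <- as.numeric(fp_pmifp(rod))
  expect_length(pmi, 3)
  expect_true(all(diff(pmi) >= 0))     # sorted I1 <= I2 <= I3
  expect_equal(pmi[1], 0)              # rod: zero moment about its own axis
  # moments are normalized by the summed heavy-atom mass
  I <- pmi * sum(9 * 14.007)
  d2 <- (rod$coords[, 1] - mean(rod$coords[, 1]))^2
  expect_equal(I[3], sum(14.007 * d2))
})

test_that("USR moments match a direct computation", {
  tetra <- molecule3d("tetra", rep("C", 4),
                      rbind(c(1, 1, 1), c(1, -1, -1), c(-1, 1, -1),
                            c(-1, -1, 1)) * 1.2,
                      cbind(1:3, 2:4, 1L))
  u <- as.numeric(fp_usr(tetra))
  expect_length(u, 12)
  ctd <- colMeans(tetra$coords)
  d_ctd <- sqrt(rowSums(sweep(tetra$coords, 2, ctd)^2))
  expect_equal(u[1], mean(d_ctd))
  expect_equal(u[2], sqrt(mean((d_ctd - mean(d_ctd))^2)))
  if (requireNamespace("e1071", quietly = TRUE) && stats::sd(d_ctd) > 0)
    expect_equal(u[3], e1071::kurtosis(d_ctd, type = 1))

  # regular tetrahedron: every atom equidistant from the centroid
  expect_equal(u[2], 0, tolerance = 1e-12)
  expect_equal(u[3], 0)  # degenerate distribution: kurtosis defined as 0

  # general 4-point cloud against brute-force moments at every reference
  cloud <- random_molecule(4, seed = 11)
  u <- as.numeric(fp_usr(cloud))
  refs <- list()
  ctd <- colMeans(cloud$coords)
  dc <- sqrt(rowSums(sweep(cloud$coords, 2, ctd)^2))
  refs$cst <- cloud$coords[which.min(dc), ]
  refs$fct <- cloud$coords[which.max(dc), ]
  df <- sqrt(rowSums(sweep(cloud$coords, 2, refs$fct)^2))
  refs$ftf <- cloud$coords[which.max(df), ]
  mom <- function(d) {
    m2 <- mean((d - mean(d))^2)
    c(mean(d), sqrt(m2), mean((d - mean(d))^4) / m2^2 - 3)
  }
  expected <- c(mom(dc),
                mom(sqrt(rowSums(sweep(cloud$coords, 2, refs$cst)^2))),
                mom(df),
                mom(sqrt(rowSums(sweep(cloud$coords, 2, refs$ftf)^2))))
  expect_equal(u, expected)
})

test_that("USRCAT blocks follow the all/Hyb/aromatic/HBA/HBD layout", {
  alkane <- make_chain(6)
  uc <- as.numeric(fp_usrcat(alkane))
  expect_length(uc, 60)
  expect_equal(uc[1:12], as.numeric(fp_usr(alkane)))
  expect_equal(uc[13:24], as.numeric(fp_usr(alkane)))  # all atoms hydrophobic
  expect_equal(uc[25:60], rep(0, 36))                  # no aromatic/HBA/HBD

  benzene <- make_ring(6, bond_orders = c(2, 1))
  uc <- as.numeric(fp_usrcat(benzene))
  expect_equal(uc[25:36], uc[1:12])  # aromatic subset is the whole molecule
})

test_that("every scheme is invariant under rigid motion, mirroring, renumbering", {
  mol <- random_molecule(9, seed = 5)
  cats <- assign_categories(mol)
  variants <- list(
    transform_molecule(mol, "rotate", axis = "z", angle = pi / 6),
    transform_molecule(transform_molecule(mol, "rotate", axis = "x",
                                          angle = 1.0),
                       "translate", v = c(5, 5, 5)),
    transform_molecule(mol, "mirror", plane = "xz"))
  for (scheme in names(SCHEME_LENGTHS)) {
    base <- as.numeric(compute_fingerprint(mol, scheme))
    for (v in variants)
      expect_equal(as.numeric(compute_fingerprint(v, scheme)), base,
                   info = scheme)
  }
  set.seed(7)
  for (rep in 1:3) {
    perm <- sample(hac(mol))
    pm <- permute_molecule(mol, perm)
    for (scheme in c("3DAPfp", "R3DAPfp", "APfp", "3DXfp", "R3DXfp", "Xfp",
                     "PMIfp", "USR"))
      expect_equal(as.numeric(compute_fingerprint(pm, scheme)),
                   as.numeric(compute_fingerprint(mol, scheme)), info = scheme)
  }
})

test_that("diastereomeric embeddings agree in 2D and differ in 3D", {
  pair <- make_diastereomer_pair()
  d_trans <- sort(pair_distances_3d(pair$trans)$d)
  d_cis <- sort(pair_distances_3d(pair$cis)$d)
  expect_false(isTRUE(all.equal(d_trans, d_cis)))

  expect_equal(as.numeric(fp_apfp(pair$trans)), as.numeric(fp_apfp(pair$cis)))
  expect_equal(as.numeric(fp_xfp(pair$trans)), as.numeric(fp_xfp(pair$cis)))
  expect_false(identical(as.numeric(fp_3dapfp(pair$trans)),
                         as.numeric(fp_3dapfp(pair$cis))))
})

test_that("fingerprint constructor enforces scheme lengths", {
  expect_equal(unname(SCHEME_LENGTHS),
               c(16L, 80L, 40L, 200L, 20L, 55L, 3L, 12L, 60L))
  expect_error(fingerprint(rep(0, 15), "3DAPfp"), "length 16")
  expect_error(fingerprint(c(-1, rep(0, 15)), "3DAPfp"), "non-negative")
  for (scheme in names(SCHEME_LENGTHS))
    expect_length(fingerprint(rep(0, SCHEME_LENGTHS[[scheme]]), scheme),
                  SCHEME_LENGTHS[[scheme]])
})

test_that("fingerprint files round-trip through the TSV format", {
  mols <- lapply(1:4, function(s) random_molecule(6, seed = s))
  for (scheme in c("R3DAPfp", "USR")) {
    fps <- lapply(mols, compute_fingerprint, scheme = scheme)
    path <- withr::local_tempfile(fileext = ".fps")
    write_fps(fps, path)
    back <- read_fps(path)
    expect_equal(lapply(back, as.numeric), lapply(fps, as.numeric),
                 tolerance = 1e-5)
    expect_equal(vapply(back, function(f) attr(f, "mol_id"), character(1)),
                 vapply(fps, function(f) attr(f, "mol_id"), character(1)))
  }
})
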