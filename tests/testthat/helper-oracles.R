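# Independent brute-force oracles: literal transcriptions of the fingerprint
# formulas, kept free of the package's accumulation code paths.

oracle_grid <- c(1.45, 1.45 * 1.18^(1:15))

oracle_round <- function(x) floor(x + 0.5)

oracle_gauss <- function(d_ab, s) {
  if (d_ab <= 0) return(rep(0, length(s)))
  exp(-(s - d_ab)^2 / (2 * (0.18 * d_ab)^2))
}

oracle_pairs_3d <- function(mol) {
  n <- length(mol$elements)
  out <- NULL
  if (n >= 2) {
    for (i in 1:(n - 1)) for (j in (i + 1):n) {
      d <- sqrt(sum((mol$coords[i, ] - mol$coords[j, ])^2))
      out <- rbind(out, c(i, j, d))
    }
  }
  out
}

# hand-written breadth-first search, independent of igraph
oracle_topo_dist <- function(mol) {
  n <- length(mol$elements)
  adj <- rep(list(integer(0)), n)
  b <- mol$bonds
  for (k in seq_len(nrow(b))) {
    adj[[b[k, 1]]] <- c(adj[[b[k, 1]]], b[k, 2])
    adj[[b[k, 2]]] <- c(adj[[b[k, 2]]], b[k, 1])
  }
  dm <- matrix(Inf, n, n)
  for (s in seq_len(n)) {
    dist <- rep(Inf, n); dist[s] <- 0
    queue <- s
    while (length(queue) > 0) {
      v <- queue[1]; queue <- queue[-1]
      for (w in adj[[v]]) if (dist[w] > dist[v] + 1) {
        dist[w] <- dist[v] + 1
        queue <- c(queue, w)
      }
    }
    dm[s, ] <- dist
  }
  dm
}

oracle_3dapfp <- function(mol) {
  acc <- rep(0, 16)
  pr <- oracle_pairs_3d(mol)
  for (k in seq_len(NROW(pr))) acc <- acc + oracle_gauss(pr[k, 3], oracle_grid)
  oracle_round(100 * acc / length(mol$elements)^1.5)
}

oracle_r3dapfp <- function(mol) {
  acc <- rep(0, 40)
  pr <- oracle_pairs_3d(mol)
  for (k in seq_len(NROW(pr))) {
    d <- pr[k, 3]
    if (d < 20) {
      bin <- floor(d / 0.5) + 1
      acc[bin] <- acc[bin] + 1
    }
  }
  oracle_round(100 * acc / length(mol$elements))
}

oracle_apfp <- function(mol) {
  acc <- rep(0, 20)
  dm <- oracle_topo_dist(mol)
  n <- length(mol$elements)
  if (n >= 2) for (i in 1:(n - 1)) for (j in (i + 1):n) {
    t <- dm[i, j]
    if (t >= 1 && t <= 20) acc[t] <- acc[t] + 1
  }
  oracle_round(100 * acc / n)
}

# category blocks in the fixed order HybHyb, HBAHBA, HBDHBD, sp2sp2, HBAHBD;
# `per_pair` maps a pair distance to a bit-contribution vector, `power` is
# the exponent of the normalization count
oracle_blocks <- function(mol, cats, per_pair, n_bits, power) {
  pr <- oracle_pairs_3d(mol)
  block_for <- function(members_i, members_j, norm, cross = FALSE) {
    acc <- rep(0, n_bits)
    npairs <- 0
    for (k in seq_len(NROW(pr))) {
      i <- pr[k, 1]; j <- pr[k, 2]
      keep <- if (cross) (members_i[i] && members_j[j]) || (members_i[j] && members_j[i])
              else members_i[i] && members_i[j]
      if (keep) { acc <- acc + per_pair(i, j); npairs <- npairs + 1 }
    }
    if (norm > 0) oracle_round(100 * acc / norm^power) else rep(0, n_bits)
  }
  c(block_for(cats$hyb, NULL, if (sum(cats$hyb) >= 2) sum(cats$hyb) else 0),
    block_for(cats$hba, NULL, if (sum(cats$hba) >= 2) sum(cats$hba) else 0),
    block_for(cats$hbd, NULL, if (sum(cats$hbd) >= 2) sum(cats$hbd) else 0),
    block_for(cats$sp2, NULL, if (sum(cats$sp2) >= 2) sum(cats$sp2) else 0),
    block_for(cats$hba, cats$hbd,
              if (sum(cats$hba) > 0 && sum(cats$hbd) > 0) sum(cats$hba) else 0,
              cross = TRUE))
}

oracle_3dxfp <- function(mol, cats) {
  pr <- oracle_pairs_3d(mol)
  dist_of <- function(i, j) {
    for (k in seq_len(NROW(pr)))
      if (pr[k, 1] == i && pr[k, 2] == j) return(pr[k, 3])
  }
  oracle_blocks(mol, cats,
                function(i, j) oracle_gauss(dist_of(i, j), oracle_grid),
                16, 1.5)
}

oracle_r3dxfp <- function(mol, cats) {
  pr <- oracle_pairs_3d(mol)
  dist_of <- function(i, j) {
    for (k in seq_len(NROW(pr)))
      if (pr[k, 1] == i && pr[k, 2] == j) return(pr[k, 3])
  }
  oracle_blocks(mol, cats, function(i, j) {
    d <- dist_of(i, j)
    v <- rep(0, 40)
    if (d < 20) v[floor(d / 0.5) + 1] <- 1
    v
  }, 40, 1)
}

oracle_xfp <- function(mol, cats) {
  dm <- oracle_topo_dist(mol)
  oracle_blocks(mol, cats, function(i, j) {
    v <- rep(0, 11)
    t <- dm[i, j]
    if (t >= 1 && t <= 11) v[t] <- 1
    v
  }, 11, 1)
}

oracle_knn <- function(fps, query, k) {
  d <- vapply(fps, function(f) sum(abs(as.numeric(f) - as.numeric(query))),
              numeric(1))
  ids <- vapply(fps, function(f) attr(f, "mol_id"), character(1))
  ord <- order(d, ids)[seq_len(min(k, length(fps)))]
  list(ids = ids[ord], d = d[ord])
}

oracle_range <- function(fps, query, max_cbd) {
  d <- vapply(fps, function(f) sum(abs(as.numeric(f) - as.numeric(query))),
              numeric(1))
  ids <- vapply(fps, function(f) attr(f, "mol_id"), character(1))
  keep <- d <= max_cbd
  ord <- order(d[keep], ids[keep])
  list(ids = ids[keep][ord], d = d[keep][ord])
}

# reorder atoms by a permutation, remapping bonds accordingly
permute_molecule <- function(mol, perm) {
  inv <- order(perm)
  b <- mol$bonds
  if (nrow(b) > 0) {
    b[, 1] <- inv[b[, 1]]
    b[, 2] <- inv[b[, 2]]
  }
  molecule3d(mol$id, mol$elements[perm], mol$coords[perm, , drop = FALSE],
             b, mol$formal_charges[perm], has_3d = mol$has_3d,
             hcount = mol$hcount[perm])
}

# random fingerprints over a scheme, for index tests
random_fps <- function(n, scheme = "3DAPfp", seed = 0, max_val = 60) {
  len <- SCHEME_LENGTHS[[scheme]]
  set.seed(seed)
  lapply(seq_len(n), function(i)
    fingerprint(sample(0:max_val, len, replace = TRUE), scheme,
                sprintf("fp%04d", i)))
}

# small V2000 SDF text for I/O tests (3 atoms, 2 bonds, one charged oxygen)
sdf_record_text <- function(name = "rec", charge_line = TRUE) {
  c(name, "  apfp3d-test", "",
    "  3  2  0  0  0  0            999 V2000",
    "    0.0000    0.0000    0.0000 C   0  0  0  0  0  0  0  0  0  0  0  0",
    "    1.5000    0.0000    0.0000 C   0  0  0  0  0  0  0  0  0  0  0  0",
    "    2.1000    1.3000    0.2000 O   0  0  0  0  0  0  0  0  0  0  0  0",
    "  1  2  1  0  0  0  0",
    "  2  3  2  0  0  0  0",
    if (charge_line) "M  CHG  1   3  -1",
    "M  END", "$$$$")
}
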