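#' Assign pharmacophore atom categories
#'
#' Flags every heavy atom of a molecule with the four categories used by the
#' category-extended fingerprints:
#'
#' * `hyb` (hydrophobic): carbon, sulfur or halogen with no nitrogen or
#'   oxygen neighbour.
#' * `hba` (H-bond acceptor): nitrogen or oxygen that is not positively
#'   charged, excluding N whose lone pair is donated into a pi system
#'   (amide/aniline-type N and aromatic N bearing a hydrogen).
#' * `hbd` (H-bond donor): nitrogen or oxygen bearing at least one hydrogen,
#'   explicit or implicit.
#' * `sp2` (planar/unsaturated): aromatic atoms and atoms in a double bond.
#'
#' An atom may carry several flags (a hydroxyl oxygen is both acceptor and
#' donor).  The flags depend only on the bond graph, elements and formal
#' charges, never on coordinates, and are invariant under atom reordering.
#' The `aromatic` flag is returned as well because the USRCAT descriptor
#' uses an aromatic atom subset.
#'
#' @param mol a [molecule3d] with valid bonds.
#' @return An object of class `atom_categories`: a list of logical vectors
#'   `hyb`, `hba`, `hbd`, `sp2`, `aromatic`, each of length `hac(mol)`.
#' @examples
#' benzene <- make_ring(6, element = "C", bond_orders = c(2, 1))
#' assign_categories(benzene)
#' @export
assign_categories <- function(mol) {
  n <- hac(mol)
  el <- mol$elements
  chg <- mol$formal_charges
  b <- mol$bonds
  res <- tryCatch({
    nbr <- neighbour_lists(mol)
    n_h <- total_hydrogens(mol)
    arom <- perceive_aromatic(mol)
    in_double <- logical(n)
    if (nrow(b) > 0) {
      dbl <- b[, 3] == 2L
      in_double[b[dbl, 1]] <- TRUE
      in_double[b[dbl, 2]] <- TRUE
      ar_bond <- b[, 3] == 4L
      arom[b[ar_bond, 1]] <- TRUE
      arom[b[ar_bond, 2]] <- TRUE
    }
    sp2 <- arom | in_double
    next_to_polar <- vapply(nbr, function(v) any(el[v] %in% c("N", "O")),
                            logical(1))
    hyb <- el %in% c("C", "S", "F", "Cl", "Br", "I") & !next_to_polar

    # any N or O with a hydrogen donates; quaternary N has no H and drops out
    hbd <- el %in% c("N", "O") & n_h > 0

    hba <- el %in% c("N", "O") & chg <= 0
    # N donating its lone pair into a pi system is not an acceptor:
    # aromatic N-H (pyrrole type), and singly-bonded N next to a pi system
    # (amide, aniline) -- unless the N itself holds a double bond (pyridine,
    # imine) in which case the lone pair stays in the sigma plane.
    for (i in which(hba & el == "N")) {
      if (arom[i] && n_h[i] > 0) { hba[i] <- FALSE; next }
      if (!in_double[i] && !arom[i]) {
        pi_neighbour <- any(arom[nbr[[i]]] | in_double[nbr[[i]]])
        if (pi_neighbour) hba[i] <- FALSE
      }
    }
    structure(list(hyb = hyb, hba = hba, hbd = hbd, sp2 = sp2,
                   aromatic = arom),
              class = "atom_categories")
  }, error = function(e) {
    stop(sprintf("category perception failed for molecule '%s': %s",
                 mol$id, conditionMessage(e)), call. = FALSE)
  })
  res
}

#' @export
print.atom_categories <- function(x, ...) {
  cat(sprintf("<atom_categories> %d atoms: %d Hyb, %d HBA, %d HBD, %d sp2\n",
              length(x$hyb), sum(x$hyb), sum(x$hba), sum(x$hbd), sum(x$sp2)))
  invisible(x)
}

neighbour_lists <- function(mol) {
  n <- hac(mol)
  nbr <- rep(list(integer(0)), n)
  b <- mol$bonds
  for (k in seq_len(nrow(b))) {
    nbr[[b[k, 1]]] <- c(nbr[[b[k, 1]]], b[k, 2])
    nbr[[b[k, 2]]] <- c(nbr[[b[k, 2]]], b[k, 1])
  }
  nbr
}

# usual valences used to infer implicit hydrogen counts
default_valence <- function(element, charge) {
  base <- c(C = 4, N = 3, O = 2, S = 2, P = 3, B = 3,
            F = 1, Cl = 1, Br = 1, I = 1, Si = 4, Se = 2)
  v <- base[element]
  v[is.na(v)] <- 0
  # protonation raises N valence, deprotonation lowers O/N valence
  v <- v + ifelse(element %in% c("N", "O", "P", "S"), charge, 0)
  pmax(unname(v), 0)
}

# explicit hydrogens recorded at parse time plus implicit hydrogens filling
# the default valence after the heavy-atom bond order sum
total_hydrogens <- function(mol) {
  n <- hac(mol)
  order_sum <- numeric(n)
  b <- mol$bonds
  for (k in seq_len(nrow(b))) {
    o <- if (b[k, 3] == 4L) 1.5 else b[k, 3]
    order_sum[b[k, 1]] <- order_sum[b[k, 1]] + o
    order_sum[b[k, 2]] <- order_sum[b[k, 2]] + o
  }
  val <- default_valence(mol$elements, mol$formal_charges)
  implicit <- pmax(0, floor(val - order_sum - mol$hcount + 1e-9))
  as.integer(mol$hcount + implicit)
}

# Pragmatic aromaticity: for every bond that lies on a cycle, take the
# smallest ring through it; a ring of size 5-7 is aromatic when each of its
# atoms either shares a double/aromatic bond with another ring member or is
# an N, O or S contributing a lone pair.  This is a ring-level approximation,
# not Hueckel electron counting.
perceive_aromatic <- function(mol) {
  n <- hac(mol)
  arom <- logical(n)
  b <- mol$bonds
  if (nrow(b) == 0) return(arom)
  g <- mol_graph(mol)
  rings <- smallest_rings(g, b)
  for (ring in rings) {
    if (length(ring) < 5 || length(ring) > 7) next
    ok <- vapply(ring, function(i) {
      inb <- b[, 1] == i | b[, 2] == i
      partner <- ifelse(b[inb, 1] == i, b[inb, 2], b[inb, 1])
      pi_in_ring <- any(b[inb, 3] %in% c(2L, 4L) & partner %in% ring)
      pi_in_ring || mol$elements[i] %in% c("N", "O", "S")
    }, logical(1))
    if (all(ok)) arom[ring] <- TRUE
  }
  arom
}

# smallest ring through each cycle edge: drop the edge, shortest path between
# its endpoints
smallest_rings <- function(g, bonds) {
  rings <- list()
  for (k in seq_len(nrow(bonds))) {
    i <- bonds[k, 1]; j <- bonds[k, 2]
    eid <- igraph::get_edge_ids(g, c(i, j))
    g2 <- igraph::delete_edges(g, eid)
    sp <- suppressWarnings(igraph::shortest_paths(g2, from = i, to = j)$vpath[[1]])
    if (length(sp) >= 3) rings[[length(rings) + 1]] <- as.integer(sp)
  }
  unique(lapply(rings, function(r) sort(r)))
}

#' Per-atom category table
#'
#' Convenience tabulation of [assign_categories()] for one or more molecules,
#' matching the `apfp3d categories` command-line output.
#'
#' @param mols a [molecule3d] or list of them.
#' @return A data.frame with columns mol_id, atom_idx, element, hyb, hba,
#'   hbd, sp2.
#' @export
category_table <- function(mols) {
  if (inherits(mols, "molecule3d")) mols <- list(mols)
  do.call(rbind, lapply(mols, function(mol) {
    cats <- assign_categories(mol)
    data.frame(mol_id = mol$id, atom_idx = seq_len(hac(mol)),
               element = mol$elements, hyb = cats$hyb, hba = cats$hba,
               hbd = cats$hbd, sp2 = cats$sp2, stringsAsFactors = FALSE)
  }))
}
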