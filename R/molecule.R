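#' Construct a heavy-atom molecule with optional 3D coordinates
#'
#' `molecule3d` is the unit every fingerprint consumes: an identifier, heavy
#' atom element symbols, cartesian coordinates in Angstrom, a bond list and
#' per-atom formal charges.  Hydrogens are never stored; parsers drop them and
#' record the number of explicit hydrogens each heavy atom carried in
#' `hcount`, so that H-bond donor perception still sees them.
#'
#' @param id character identifier.
#' @param elements character vector of element symbols, one per heavy atom.
#' @param coords numeric matrix with one row per atom and columns x, y, z
#'   (Angstrom).  May be all-zero when `has_3d` is `FALSE`.
#' @param bonds integer matrix with columns `from`, `to`, `order`
#'   (order 1, 2, 3 or 4 = aromatic); zero-row matrix for no bonds.
#' @param formal_charges integer vector of formal charges, one per atom.
#' @param has_3d logical; `TRUE` when `coords` are meaningful 3D positions.
#' @param hcount integer vector of explicit hydrogens attached to each heavy
#'   atom (defaults to zero).
#'
#' @return An object of class `molecule3d`.
#' @examples
#' m <- molecule3d("pair", c("C", "C"),
#'                 rbind(c(0, 0, 0), c(8.51, 0, 0)),
#'                 cbind(1L, 2L, 1L), c(0L, 0L), TRUE)
#' hac(m)
#' @export
molecule3d <- function(id, elements, coords, bonds = empty_bonds(),
                       formal_charges = integer(length(elements)),
                       has_3d = TRUE, hcount = integer(length(elements))) {
  coords <- matrix(as.numeric(coords), ncol = 3,
                   dimnames = list(NULL, c("x", "y", "z")))
  bonds <- matrix(as.integer(bonds), ncol = 3,
                  dimnames = list(NULL, c("from", "to", "order")))
  mol <- structure(
    list(id = as.character(id)[1],
         elements = as.character(elements),
         coords = coords,
         bonds = bonds,
         formal_charges = as.integer(formal_charges),
         has_3d = isTRUE(has_3d),
         hcount = as.integer(hcount)),
    class = "molecule3d")
  validate_molecule3d(mol)
  mol
}

empty_bonds <- function() {
  matrix(integer(0), ncol = 3, dimnames = list(NULL, c("from", "to", "order")))
}

validate_molecule3d <- function(mol) {
  n <- length(mol$elements)
  stopifnot(nrow(mol$coords) == n,
            length(mol$formal_charges) == n,
            length(mol$hcount) == n)
  if (any(mol$elements %in% c("H", "D", "T")))
    stop("molecule3d stores heavy atoms only; drop hydrogens first", call. = FALSE)
  if (nrow(mol$bonds) > 0) {
    b <- mol$bonds
    if (any(b[, 1] < 1L | b[, 1] > n | b[, 2] < 1L | b[, 2] > n))
      stop("bond references an invalid atom index", call. = FALSE)
    if (any(b[, 1] == b[, 2]))
      stop("self-bonds are not allowed", call. = FALSE)
  }
  if (mol$has_3d && any(!is.finite(mol$coords)))
    stop("non-finite coordinates in a 3D molecule", call. = FALSE)
  invisible(mol)
}

#' Heavy atom count
#'
#' @param mol a [molecule3d].
#' @return integer, the number of non-hydrogen atoms.
#' @export
hac <- function(mol) length(mol$elements)

#' @export
print.molecule3d <- function(x, ...) {
  cat(sprintf("<molecule3d> %s: %d heavy atoms, %d bonds, %s\n",
              x$id, hac(x), nrow(x$bonds),
              if (x$has_3d) "3D" else "2D/no coordinates"))
  invisible(x)
}

#' @export
format.molecule3d <- function(x, ...) {
  sprintf("%s (HAC=%d)", x$id, hac(x))
}

# Standard atomic weights for the elements that occur in drug-like molecules;
# used for the mass-weighted principal moments of inertia.
ATOMIC_MASSES <- c(
  H = 1.008, B = 10.811, C = 12.011, N = 14.007, O = 15.999, F = 18.998,
  Si = 28.086, P = 30.974, S = 32.065, Cl = 35.453, Se = 78.971,
  Br = 79.904, I = 126.904
)

atomic_mass <- function(element) {
  m <- ATOMIC_MASSES[element]
  # rare elements fall back to a carbon-like mass rather than failing
  m[is.na(m)] <- 12.011
  unname(m)
}

# bond graph as an igraph object over all heavy atoms (isolated atoms kept)
mol_graph <- function(mol) {
  igraph::make_graph(edges = as.vector(t(mol$bonds[, 1:2, drop = FALSE])),
                     n = hac(mol), directed = FALSE)
}
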