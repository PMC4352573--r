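#' Two-atom toy molecule at an exact distance
#'
#' The minimal fixture for distance-binning checks: two bonded atoms at
#' (0,0,0) and (d,0,0).
#'
#' @param d inter-atomic distance in Angstrom, `>= 0`.
#' @param elements two element symbols.
#' @param id identifier.
#' @return A [molecule3d].
#' @examples
#' make_pair(8.51)  # lands in regular bin 18 (8.5-9 A)
#' @export
make_pair <- function(d, elements = c("C", "C"), id = sprintf("pair_%g", d)) {
  stopifnot(d >= 0, length(elements) == 2)
  molecule3d(id, elements, rbind(c(0, 0, 0), c(d, 0, 0)),
             cbind(1L, 2L, 1L))
}

#' Chain toy molecule, extended or helical
#'
#' `n` atoms bonded consecutively.  The linear geometry places atoms on the
#' x axis at `bond_length` spacing, so through-space distance is exactly
#' proportional to topological distance.  The helix geometry winds the chain
#' around a cylinder; with a pitch much smaller than the radius, atoms far
#' apart along the chain come close in space -- the folded-molecule regime
#' in which 3D and topological fingerprints disagree most.
#'
#' @param n number of atoms, `>= 2`.
#' @param bond_length consecutive-atom distance in Angstrom.
#' @param geometry `"linear"` or `"helix"`.
#' @param radius helix radius (Angstrom).
#' @param pitch helix rise per full turn (Angstrom).
#' @param element element symbol for all atoms.
#' @param id identifier.
#' @return A [molecule3d].
#' @export
make_chain <- function(n, bond_length = 1.5, geometry = c("linear", "helix"),
                       radius = 3, pitch = 0.5, element = "C",
                       id = paste0(geometry[1], "_chain_", n)) {
  geometry <- match.arg(geometry)
  stopifnot(n >= 2, bond_length > 0)
  coords <- if (geometry == "linear") {
    cbind(bond_length * (seq_len(n) - 1), 0, 0)
  } else {
    # angular step chosen so consecutive atoms sit one bond length apart:
    # chord^2 + rise^2 = b^2 with chord = 2 r sin(theta/2), rise = pitch*theta/(2 pi)
    f <- function(theta) {
      (2 * radius * sin(theta / 2))^2 + (pitch * theta / (2 * pi))^2 -
        bond_length^2
    }
    upper <- 2 * asin(min(1, bond_length / (2 * radius))) + 1
    theta <- stats::uniroot(f, c(1e-9, upper), tol = 1e-12)$root
    k <- seq_len(n) - 1
    cbind(radius * cos(k * theta), radius * sin(k * theta),
          pitch * k * theta / (2 * pi))
  }
  bonds <- if (n >= 2) cbind(seq_len(n - 1), seq_len(n - 1) + 1L, 1L)
           else empty_bonds()
  molecule3d(id, rep(element, n), coords, bonds)
}

#' Rigid motions and reflections of a molecule
#'
#' Applies a rotation about a coordinate axis, a translation, or a mirror
#' reflection through a coordinate plane.  The bond graph is untouched.
#' Rotations and translations are proper rigid motions; a mirror image has
#' identical pair distances but opposite chirality, which none of the
#' fingerprints can perceive.
#'
#' @param mol a [molecule3d] with 3D coordinates.
#' @param op one of `"rotate"`, `"translate"`, `"mirror"`.
#' @param axis rotation axis `"x"`, `"y"` or `"z"`.
#' @param angle rotation angle in radians.
#' @param v length-3 translation vector.
#' @param plane mirror plane `"xy"`, `"xz"` or `"yz"`.
#' @return The transformed [molecule3d].
#' @export
transform_molecule <- function(mol, op = c("rotate", "translate", "mirror"),
                               axis = "z", angle = 0, v = c(0, 0, 0),
                               plane = "xy") {
  stopifnot(mol$has_3d)
  op <- match.arg(op)
  x <- mol$coords
  x <- switch(op,
    rotate = {
      cs <- cos(angle); sn <- sin(angle)
      R <- switch(axis,
        x = matrix(c(1, 0, 0, 0, cs, sn, 0, -sn, cs), 3),
        y = matrix(c(cs, 0, -sn, 0, 1, 0, sn, 0, cs), 3),
        z = matrix(c(cs, sn, 0, -sn, cs, 0, 0, 0, 1), 3),
        stop("axis must be x, y or z"))
      x %*% t(R)
    },
    translate = sweep(x, 2, -as.numeric(v)),
    mirror = {
      flip <- switch(plane, xy = 3, xz = 2, yz = 1,
                     stop("plane must be xy, xz or yz"))
      x[, flip] <- -x[, flip]
      x
    })
  out <- mol
  out$coords <- matrix(as.numeric(x), ncol = 3,
                       dimnames = list(NULL, c("x", "y", "z")))
  out
}

#' Enumerate stereoisomer configurations
#'
#' All `2^(n_centers + n_double_bonds)` configuration strings over R/S for
#' tetrahedral centers and E/Z for double bonds.  Five stereocenters give
#' the 32 diastereomeric hexopyranoses; four double bonds give the 16 E/Z
#' isomers of eicosatetraenoic acid.
#'
#' @param n_centers number of tetrahedral stereocenters.
#' @param n_double_bonds number of configurable double bonds.
#' @return A list with `count` and `configurations` (character vector; the
#'   empty configuration is `""` for a molecule with no stereo elements).
#' @export
enumerate_stereo <- function(n_centers, n_double_bonds = 0) {
  stopifnot(n_centers >= 0, n_double_bonds >= 0)
  grids <- c(rep(list(c("R", "S")), n_centers),
             rep(list(c("E", "Z")), n_double_bonds))
  configs <- if (length(grids) == 0) "" else
    do.call(paste0, expand.grid(grids, stringsAsFactors = FALSE))
  list(count = length(configs), configurations = configs)
}

#' Random chained toy molecule
#'
#' `n` atoms placed uniformly in a cube of side `box`, bonded consecutively.
#' Deterministic for a fixed seed; the caller's random-number state is left
#' untouched.
#'
#' @param n number of atoms, `>= 1`.
#' @param box cube side length in Angstrom.
#' @param seed integer seed.
#' @param element element symbol.
#' @param id identifier.
#' @return A [molecule3d].
#' @export
random_molecule <- function(n, box = 10, seed = 0, element = "C",
                            id = sprintf("rand_%d_%d", n, seed)) {
  stopifnot(n >= 1)
  coords <- with_local_seed(seed, matrix(stats::runif(3 * n, 0, box), ncol = 3))
  bonds <- if (n >= 2) cbind(seq_len(n - 1), seq_len(n - 1) + 1L, 1L)
           else empty_bonds()
  molecule3d(id, rep(element, n), coords, bonds)
}

# evaluate expr under a fixed seed and restore the caller's RNG state
with_local_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (had) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  expr
}

#' Ring toy molecule
#'
#' `n` atoms on a planar regular polygon, bonded in a cycle.  With
#' alternating bond orders (e.g. `c(2, 1)`) a six-ring is a Kekule benzene.
#'
#' @param n ring size, `>= 3`.
#' @param radius circumradius in Angstrom.
#' @param element element symbol, recycled over the ring.
#' @param bond_orders bond order pattern, recycled around the cycle.
#' @param id identifier.
#' @return A [molecule3d].
#' @export
make_ring <- function(n, radius = 1.4, element = "C", bond_orders = 1L,
                      id = sprintf("ring_%d", n)) {
  stopifnot(n >= 3)
  k <- seq_len(n) - 1
  coords <- cbind(radius * cos(2 * pi * k / n), radius * sin(2 * pi * k / n), 0)
  from <- seq_len(n)
  to <- c(seq_len(n)[-1], 1L)
  orders <- rep_len(as.integer(bond_orders), n)
  molecule3d(id, rep_len(element, n), coords, cbind(from, to, orders))
}

#' Diastereomer-like pair of 3D embeddings sharing one bond graph
#'
#' Two embeddings of a four-atom chain differing only in the dihedral angle
#' (cis vs trans).  Topological distances are identical, so all 2D
#' fingerprints agree, while the 1-4 through-space distance differs, so the
#' 3D fingerprints separate the two -- the defining behaviour of
#' diastereomers under 3D versus 2D perception.
#'
#' @param bond_length bond length in Angstrom.
#' @return A list of two [molecule3d] objects `trans` and `cis`.
#' @export
make_diastereomer_pair <- function(bond_length = 1.5) {
  theta <- 109.5 * pi / 180
  p1 <- c(0, 0, 0)
  p2 <- c(bond_length, 0, 0)
  p3 <- p2 + bond_length * c(-cos(theta), sin(theta), 0)
  p4 <- function(phi) place_atom(p1, p2, p3, bond_length, theta, phi)
  bonds <- cbind(1:3, 2:4, 1L)
  list(
    trans = molecule3d("dia_trans", rep("C", 4), rbind(p1, p2, p3, p4(pi)), bonds),
    cis = molecule3d("dia_cis", rep("C", 4), rbind(p1, p2, p3, p4(0)), bonds))
}

# internal-coordinate atom placement: new atom at distance b from p3, bond
# angle theta at p3, torsion phi about the p2-p3 axis
place_atom <- function(p1, p2, p3, b, theta, phi) {
  cross <- function(u, v) c(u[2] * v[3] - u[3] * v[2],
                            u[3] * v[1] - u[1] * v[3],
                            u[1] * v[2] - u[2] * v[1])
  unit <- function(v) v / sqrt(sum(v^2))
  bc <- unit(p3 - p2)
  n <- unit(cross(p2 - p1, bc))
  m <- cross(n, bc)
  p3 + b * (-cos(theta) * bc + sin(theta) * (cos(phi) * m + sin(phi) * n))
}
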