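#' A labeled ranking for enrichment evaluation
#'
#' Couples a best-first ranked list of molecule ids with the subset regarded
#' as active.  Optional similarity scores (same order as `ids`, higher =
#' better) allow tie-aware AUC computation.
#'
#' @param ids character vector, best-first ranking; no duplicates.
#' @param actives character vector of active ids; must be a subset of `ids`.
#' @param scores optional numeric vector aligned with `ids`.
#' @return An object of class `labeled_ranking`.
#' @export
labeled_ranking <- function(ids, actives, scores = NULL) {
  stopifnot(!anyDuplicated(ids), all(actives %in% ids))
  if (!is.null(scores)) stopifnot(length(scores) == length(ids))
  structure(list(ids = ids, actives = unique(actives), scores = scores),
            class = "labeled_ranking")
}

#' Rank-based ROC AUC
#'
#' The probability that a randomly chosen active outranks a randomly chosen
#' inactive (Mann-Whitney statistic).  Ties in the similarity scores
#' contribute 1/2.  Invariant under strictly monotone transformation of the
#' scores.
#'
#' @param r a [labeled_ranking()] with at least one active and one inactive.
#' @return Real in `[0, 1]`.
#' @export
roc_auc <- function(r) {
  is_active <- r$ids %in% r$actives
  n_a <- sum(is_active)
  n_i <- sum(!is_active)
  if (n_a == 0 || n_i == 0)
    stop("AUC needs at least one active and one inactive", call. = FALSE)
  # rank 1 = best; with scores, equal scores share an average rank
  rk <- if (is.null(r$scores)) seq_along(r$ids)
        else rank(-r$scores, ties.method = "average")
  sum_ra <- sum(rk[is_active])
  (n_a * n_i + n_a * (n_a + 1) / 2 - sum_ra) / (n_a * n_i)
}

#' Enrichment factor at a coverage fraction
#'
#' The fraction of actives recovered in the top `ceiling(fraction * N)` of
#' the ranking, divided by the fraction.  A random ranking gives 1 in
#' expectation; the maximum is `1 / fraction`.
#'
#' @param r a [labeled_ranking()].
#' @param fraction coverage in `(0, 1]`, e.g. 0.05 for EF5%.
#' @return Non-negative real, at most `1 / fraction`.
#' @export
enrichment_factor <- function(r, fraction) {
  stopifnot(fraction > 0, fraction <= 1)
  n_a <- length(r$actives)
  if (n_a == 0) stop("enrichment factor needs at least one active", call. = FALSE)
  top <- r$ids[seq_len(ceiling(fraction * length(r$ids)))]
  (sum(top %in% r$actives) / n_a) / fraction
}

#' Shape-triangle occupancy histogram
#'
#' Bins the normalized principal moments (I1/I3, I2/I3) of a molecule set
#' into a `pixels x pixels` grid over the rod-disc-sphere triangle with
#' vertices (0, 1) rod, (0.5, 0.5) disc and (1, 1) sphere.  The x axis
#' spans I1/I3 in `[0, 1]`, the y axis I2/I3 in `[0.5, 1]`.  A molecule
#' whose moments fall outside the triangle beyond `tol` triggers a warning
#' but is still counted in its pixel.
#'
#' @param mols list of [molecule3d] with 3D coordinates and HAC >= 3.
#' @param pixels grid resolution per axis.
#' @param tol tolerance for the triangle-membership warning.
#' @return An integer matrix (`pixels` rows = y bins from 0.5 up, columns =
#'   x bins) with attribute `npmi` holding the per-molecule coordinates.
#' @export
shape_triangle <- function(mols, pixels = 50, tol = 1e-6) {
  h <- matrix(0L, nrow = pixels, ncol = pixels)
  pts <- matrix(numeric(0), ncol = 2)
  for (mol in mols) {
    p <- npmi(mol)
    pts <- rbind(pts, p)
    if (p[1] + p[2] < 1 - tol || p[2] > 1 + tol || p[1] > p[2] + tol)
      warning(sprintf("%s: nPMI (%.3f, %.3f) outside the shape triangle",
                      mol$id, p[1], p[2]), call. = FALSE)
    ix <- min(pixels, max(1L, ceiling(p[1] * pixels)))
    iy <- min(pixels, max(1L, ceiling((p[2] - 0.5) / 0.5 * pixels)))
    if (p[1] <= 0) ix <- 1L
    if (p[2] <= 0.5) iy <- 1L
    h[iy, ix] <- h[iy, ix] + 1L
  }
  attr(h, "npmi") <- pts
  h
}

#' Three-way overlap partition of nearest-neighbour hit lists
#'
#' Partitions the union of three hit-id sets into the seven regions of a
#' Venn diagram: unique to each search, each pairwise-only intersection,
#' and the triple intersection.  Used to quantify how different the analog
#' sets retrieved for two diastereomers and for the 2D parent fingerprint
#' are.
#'
#' @param a,b,c `ranked_hits` objects or character id vectors over one
#'   database.
#' @return An object of class `overlap_partition`: a list with the seven
#'   counts (`only_a`, `only_b`, `only_c`, `ab`, `ac`, `bc`, `abc`), the
#'   union size `total`, and `shared_fraction` (pairwise shared ids divided
#'   by the respective list length).
#' @export
nn_overlap <- function(a, b, c) {
  ids <- lapply(list(a, b, c), function(x)
    unique(if (inherits(x, "ranked_hits")) x$ids else as.character(x)))
  in_a <- ids[[1]]; in_b <- ids[[2]]; in_c <- ids[[3]]
  u <- unique(c(in_a, in_b, in_c))
  m <- cbind(u %in% in_a, u %in% in_b, u %in% in_c)
  key <- m[, 1] + 2 * m[, 2] + 4 * m[, 3]
  cnt <- function(k) sum(key == k)
  part <- list(only_a = cnt(1), only_b = cnt(2), only_c = cnt(4),
               ab = cnt(3), ac = cnt(5), bc = cnt(6), abc = cnt(7),
               total = length(u),
               shared_fraction = c(
                 ab = length(intersect(in_a, in_b)) / max(1, length(in_a)),
                 ac = length(intersect(in_a, in_c)) / max(1, length(in_a)),
                 bc = length(intersect(in_b, in_c)) / max(1, length(in_b))))
  structure(part, class = "overlap_partition")
}

#' @export
print.overlap_partition <- function(x, ...) {
  cat(sprintf(
    "<overlap_partition> union %d: only A %d, only B %d, only C %d, AB %d, AC %d, BC %d, ABC %d\n",
    x$total, x$only_a, x$only_b, x$only_c, x$ab, x$ac, x$bc, x$abc))
  invisible(x)
}

#' Size-constrained database subset
#'
#' Ids of database entries whose heavy atom count lies within `window` of
#' the query's, the subset from which analogs are retrieved in
#' size-constrained recovery experiments (HAC +/- 2 by default).
#'
#' @param ids character vector of database ids.
#' @param hacs integer vector of heavy atom counts aligned with `ids`.
#' @param query_hac the query's heavy atom count.
#' @param window half-width of the HAC window (default 2).
#' @return Character vector of retained ids.
#' @export
size_constrained_actives <- function(ids, hacs, query_hac, window = 2) {
  stopifnot(length(ids) == length(hacs))
  ids[abs(hacs - query_hac) <= window]
}

#' Cross-scheme recovery experiment
#'
#' Self-contained re-enactment of a shape-analog recovery study: for one
#' query, the `n_active` nearest neighbours under a reference scheme define
#' the actives, and the ranking of the size-constrained database under an
#' evaluation scheme is scored by ROC AUC.  Using different schemes for
#' defining and recovering actives keeps the experiment meaningful without
#' an external reference scorer.
#'
#' @param mols list of [molecule3d] (the database; must include the query).
#' @param query_id id of the query molecule.
#' @param ref_scheme scheme defining the actives.
#' @param eval_scheme scheme being evaluated.
#' @param n_active number of reference neighbours labelled active.
#' @param hac_window HAC window for the candidate subset.
#' @return A list with the AUC, the active ids and the evaluated ranking.
#' @export
recovery_auc <- function(mols, query_id, ref_scheme, eval_scheme,
                         n_active = 100, hac_window = 2) {
  ids <- vapply(mols, function(m) m$id, character(1))
  stopifnot(query_id %in% ids)
  query <- mols[[match(query_id, ids)]]
  hacs <- vapply(mols, hac, integer(1))
  keep_ids <- size_constrained_actives(ids, hacs, hac(query), hac_window)
  keep_ids <- setdiff(keep_ids, query_id)
  pool <- mols[match(keep_ids, ids)]
  rank_by <- function(scheme) {
    fps <- lapply(pool, compute_fingerprint, scheme = scheme)
    qfp <- compute_fingerprint(query, scheme)
    d <- vapply(fps, cbd, numeric(1), b = qfp)
    ord <- order(d, keep_ids)
    list(ids = keep_ids[ord], d = d[ord])
  }
  ref <- rank_by(ref_scheme)
  actives <- ref$ids[seq_len(min(n_active, length(ref$ids)))]
  ev <- rank_by(eval_scheme)
  r <- labeled_ranking(ev$ids, actives, scores = -ev$d)
  list(auc = roc_auc(r), actives = actives, ranking = r)
}
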