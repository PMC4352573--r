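#' City-block distance between two fingerprints
#'
#' The L1 distance `sum(|a_i - b_i|)` is the similarity measure used for all
#' scalar fingerprint searches; smaller means more similar.
#'
#' @param a,b [fingerprint] objects of the same scheme (or plain numeric
#'   vectors of equal length).
#' @return Non-negative number.
#' @export
cbd <- function(a, b) {
  check_same_scheme(a, b)
  sum(abs(as.numeric(a) - as.numeric(b)))
}

#' Tanimoto coefficient for scalar (count) fingerprints
#'
#' `sum(min(a_i, b_i)) / sum(max(a_i, b_i))`, the continuous Tanimoto
#' generalization for non-negative value vectors; defined as 1 when both
#' vectors are all-zero.
#'
#' @inheritParams cbd
#' @return Real in `[0, 1]`.
#' @export
tanimoto_scalar <- function(a, b) {
  check_same_scheme(a, b)
  a <- as.numeric(a); b <- as.numeric(b)
  denom <- sum(pmax(a, b))
  if (denom == 0) return(1)
  sum(pmin(a, b)) / denom
}

check_same_scheme <- function(a, b) {
  sa <- attr(a, "scheme"); sb <- attr(b, "scheme")
  if (!is.null(sa) && !is.null(sb) && sa != sb)
    stop(sprintf("scheme mismatch: %s vs %s", sa, sb), call. = FALSE)
  if (length(a) != length(b))
    stop("fingerprint lengths differ", call. = FALSE)
  invisible(TRUE)
}

#' Build a bit-sum hash index over a fingerprint database
#'
#' Entries are stored sorted by their total bit-value sum.  Because
#' `|sum(a) - sum(b)| <= cbd(a, b)`, a nearest-neighbour search can expand
#' outward from the query's position in sum order and stop as soon as the
#' sum difference exceeds the current k-th best distance -- the hash
#' principle that makes city-block searches over millions of fingerprints
#' fast.
#'
#' @param fps list of [fingerprint] objects, all of one scheme, with unique
#'   `mol_id`s.
#' @return An object of class `sum_index` with fields `vectors` (matrix, one
#'   row per entry, sum-sorted), `ids`, `sums` and `scheme`.
#' @export
build_index <- function(fps) {
  stopifnot(length(fps) >= 1)
  schemes <- unique(vapply(fps, fp_scheme, character(1)))
  if (length(schemes) != 1)
    stop("all fingerprints in an index must share one scheme", call. = FALSE)
  ids <- vapply(fps, fp_id, character(1))
  if (anyDuplicated(ids))
    stop("duplicate mol_ids in index: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
  mat <- do.call(rbind, lapply(fps, as.numeric))
  sums <- rowSums(mat)
  ord <- order(sums, ids)
  structure(list(vectors = mat[ord, , drop = FALSE], ids = ids[ord],
                 sums = sums[ord], scheme = schemes),
            class = "sum_index")
}

#' @export
print.sum_index <- function(x, ...) {
  cat(sprintf("<sum_index %s> %d entries, bit sums %g..%g\n",
              x$scheme, length(x$ids), min(x$sums), max(x$sums)))
  invisible(x)
}

#' @export
length.sum_index <- function(x) length(x$ids)

ranked_hits <- function(ids, distances, query_id, scheme) {
  structure(list(ids = ids, distances = distances,
                 query_id = query_id, scheme = scheme),
            class = "ranked_hits")
}

#' @export
print.ranked_hits <- function(x, ...) {
  cat(sprintf("<ranked_hits> %d hits for query %s (%s)\n",
              length(x$ids), x$query_id, x$scheme))
  if (length(x$ids) > 0)
    print(utils::head(data.frame(rank = seq_along(x$ids), mol_id = x$ids,
                                 cbd = x$distances), 10))
  invisible(x)
}

#' @export
as.data.frame.ranked_hits <- function(x, ...) {
  data.frame(rank = seq_along(x$ids), mol_id = x$ids, cbd = x$distances,
             stringsAsFactors = FALSE)
}

#' k-nearest-neighbour search in a sum index
#'
#' Returns the `k` database entries with smallest city-block distance to the
#' query.  The scan expands outward from the query's position in sum order
#' and terminates when the sum-difference lower bound exceeds the current
#' k-th best distance, so distant entries are never touched.  Ties at the
#' cut are broken by ascending `mol_id` for reproducibility.
#'
#' @param index a [build_index()] result.
#' @param query a [fingerprint] of the index's scheme.
#' @param k number of neighbours; capped at the index size.
#' @return A `ranked_hits` object (fields `ids`, `distances`, sorted by
#'   distance then `mol_id`).
#' @export
knn <- function(index, query, k) {
  check_index_query(index, query)
  stopifnot(k >= 1)
  n <- length(index$ids)
  k <- min(k, n)
  q <- as.numeric(query)
  qsum <- sum(q)
  pos <- integer(0); d <- numeric(0)
  lr <- init_pointers(index, qsum)
  left <- lr[1]; right <- lr[2]
  kth_best <- Inf
  repeat {
    gap_left <- if (left >= 1L) qsum - index$sums[left] else Inf
    gap_right <- if (right <= n) index$sums[right] - qsum else Inf
    gap <- min(gap_left, gap_right)
    if (is.infinite(gap) || gap > kth_best) break
    if (gap_left <= gap_right) { p <- left; left <- left - 1L }
    else { p <- right; right <- right + 1L }
    pos <- c(pos, p)
    d <- c(d, sum(abs(index$vectors[p, ] - q)))
    if (length(pos) >= k) kth_best <- sort(d, partial = k)[k]
  }
  sel <- order(d, index$ids[pos])[seq_len(min(k, length(pos)))]
  ranked_hits(index$ids[pos][sel], d[sel], fp_id(query), index$scheme)
}

#' Range query in a sum index
#'
#' All entries with city-block distance at most `max_cbd` from the query,
#' sorted by distance (ties by `mol_id`), pruned by the sum bound.
#'
#' @inheritParams knn
#' @param max_cbd inclusive distance threshold, `>= 0`.
#' @return A `ranked_hits` object.
#' @export
range_query <- function(index, query, max_cbd) {
  check_index_query(index, query)
  stopifnot(max_cbd >= 0)
  n <- length(index$ids)
  q <- as.numeric(query)
  qsum <- sum(q)
  pos <- integer(0); d <- numeric(0)
  lr <- init_pointers(index, qsum)
  left <- lr[1]; right <- lr[2]
  repeat {
    gap_left <- if (left >= 1L) qsum - index$sums[left] else Inf
    gap_right <- if (right <= n) index$sums[right] - qsum else Inf
    gap <- min(gap_left, gap_right)
    if (is.infinite(gap) || gap > max_cbd) break
    if (gap_left <= gap_right) { p <- left; left <- left - 1L }
    else { p <- right; right <- right + 1L }
    dd <- sum(abs(index$vectors[p, ] - q))
    if (dd <= max_cbd) { pos <- c(pos, p); d <- c(d, dd) }
  }
  sel <- order(d, index$ids[pos])
  ranked_hits(index$ids[pos][sel], d[sel], fp_id(query), index$scheme)
}

init_pointers <- function(index, qsum) {
  right <- findInterval(qsum, index$sums, left.open = TRUE) + 1L
  c(right - 1L, right)
}

check_index_query <- function(index, query) {
  stopifnot(inherits(index, "sum_index"))
  qs <- attr(query, "scheme")
  if (!is.null(qs) && qs != index$scheme)
    stop(sprintf("scheme mismatch: index holds %s, query is %s",
                 index$scheme, qs), call. = FALSE)
  if (length(query) != ncol(index$vectors))
    stop("query length does not match the index", call. = FALSE)
  invisible(TRUE)
}
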