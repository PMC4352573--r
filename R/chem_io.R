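#' Read molecular structures from SDF, MOL2 or SMILES files
#'
#' Parses each record into a heavy-atom [molecule3d].  Explicit hydrogens are
#' dropped at parse time (their count per heavy atom is kept for donor
#' perception).  SDF and MOL2 records are treated as 3D; SMILES records have
#' `has_3d = FALSE`.  Unparsable records are skipped with a warning and the
#' skip count is reported; a file with zero parsable records is an error.
#'
#' Formal charges are taken from the V2000 atom-block charge code and from
#' `M  CHG` property lines (the latter override the former, as the format
#' prescribes).  MOL2 input is converted to SDF with OpenBabel before parsing.
#'
#' @param path path to the input file.
#' @param format one of `"sdf"`, `"mol2"`, `"smiles"`.  SMILES files hold one
#'   record per line, optionally followed by whitespace and an identifier.
#' @return A list of [molecule3d] objects, in record order.
#' @seealso [write_sdf()], [largest_fragment()], [filter_by_hac()]
#' @export
read_structures <- function(path, format = c("sdf", "mol2", "smiles")) {
  format <- match.arg(format)
  if (!file.exists(path))
    stop("cannot read input file: ", path, call. = FALSE)
  mols <- switch(format,
    sdf = read_sdf_records(readLines(path, warn = FALSE), basename(path)),
    mol2 = {
      sdf_text <- ChemmineOB::convertFormat(
        "MOL2", "SDF", paste(readLines(path, warn = FALSE), collapse = "\n"))
      read_sdf_records(strsplit(sdf_text, "\n", fixed = TRUE)[[1]],
                       basename(path), has_3d = TRUE)
    },
    smiles = read_smiles_lines(readLines(path, warn = FALSE)))
  if (length(mols) == 0)
    stop("no parsable records in ", path, call. = FALSE)
  mols
}

# Parse V2000 SDF records held as a character vector of lines.  ChemmineR does
# the parsing; raw record lines are scanned for the M CHG property lines that
# ChemmineR discards.  Zero-bond records (which ChemmineR rejects) fall back
# to a fixed-width read of the atom block.
read_sdf_records <- function(lines, source_name, has_3d = TRUE) {
  records <- split_sdf_lines(lines)
  n_total <- length(records)
  out <- vector("list", n_total)
  n_skip <- 0L
  for (r in seq_len(n_total)) {
    rec <- records[[r]]
    mol <- tryCatch(
      parse_sdf_record(rec, fallback_id = sprintf("%s:%d", source_name, r),
                       has_3d = has_3d),
      error = function(e) NULL)
    if (is.null(mol)) n_skip <- n_skip + 1L
    out[[r]] <- mol
  }
  if (n_skip > 0)
    warning(sprintf("skipped %d unparsable record(s) in %s", n_skip, source_name),
            call. = FALSE)
  out[!vapply(out, is.null, logical(1))]
}

# split a file's lines into records at the $$$$ delimiters
split_sdf_lines <- function(lines) {
  ends <- grepl("^\\$\\$\\$\\$", lines)
  grp <- c(0, cumsum(ends))[seq_along(lines)]
  recs <- split(lines, grp)
  recs <- lapply(recs, function(r) r[!grepl("^\\$\\$\\$\\$", r)])
  unname(recs[vapply(recs, function(r) any(nzchar(trimws(r))), logical(1))])
}

parse_sdf_record <- function(rec, fallback_id, has_3d = TRUE) {
  if (length(rec) < 5) stop("truncated record")
  counts <- rec[4]
  n_atoms <- suppressWarnings(as.integer(substr(counts, 1, 3)))
  n_bonds <- suppressWarnings(as.integer(substr(counts, 4, 6)))
  if (is.na(n_atoms) || n_atoms < 1 || is.na(n_bonds)) stop("bad counts line")
  if (n_bonds >= 1) {
    sdfset <- suppressWarnings(ChemmineR::read.SDFset(methods::as(rec, "SDFstr")))
    if (!ChemmineR::validSDF(sdfset)[1]) stop("invalid record")
    return(sdf_to_molecule3d(sdfset[[1]], rec, fallback_id, has_3d))
  }
  # zero-bond record: fixed-width V2000 atom block
  at <- rec[5:(4 + n_atoms)]
  coords <- cbind(as.numeric(substr(at, 1, 10)),
                  as.numeric(substr(at, 11, 20)),
                  as.numeric(substr(at, 21, 30)))
  if (any(is.na(coords))) stop("bad atom block")
  elements <- trimws(substr(at, 31, 34))
  codes <- suppressWarnings(as.integer(substr(at, 37, 39)))
  codes[is.na(codes)] <- 0L
  charges <- resolve_charges(charge_from_code(codes), rec, n_atoms)
  id <- trimws(rec[1])
  if (!nzchar(id)) id <- fallback_id
  strip_hydrogens(id, elements, coords, empty_bonds(), charges, has_3d)
}

# M CHG property lines override atom-block charge codes for the whole record
resolve_charges <- function(charges, raw_lines, n) {
  chg_lines <- grep("^M  CHG", raw_lines, value = TRUE)
  if (length(chg_lines) == 0) return(charges)
  charges <- integer(n)
  for (ln in chg_lines) {
    f <- as.integer(strsplit(trimws(substring(ln, 7)), "\\s+")[[1]])
    k <- f[1]
    idx <- f[seq(2, by = 2, length.out = k)]
    val <- f[seq(3, by = 2, length.out = k)]
    ok <- idx >= 1 & idx <= n
    charges[idx[ok]] <- val[ok]
  }
  charges
}

# charge code field of the V2000 atom block: 1..7 -> +3..-3 (4 = radical, 0)
CHARGE_CODE <- c(`1` = 3L, `2` = 2L, `3` = 1L, `4` = 0L,
                 `5` = -1L, `6` = -2L, `7` = -3L)

charge_from_code <- function(code) {
  ch <- CHARGE_CODE[as.character(code)]
  ch[is.na(ch)] <- 0L
  unname(ch)
}

sdf_to_molecule3d <- function(sdf, raw_lines, fallback_id, has_3d = TRUE) {
  ab <- ChemmineR::atomblock(sdf)
  bb <- ChemmineR::bondblock(sdf)
  n <- nrow(ab)
  if (n < 1) stop("record with no atoms")
  elements <- sub("_.*$", "", rownames(ab))
  coords <- unname(ab[, 1:3, drop = FALSE])
  codes <- if ("C6" %in% colnames(ab)) ab[, "C6"] else rep(0, n)
  charges <- resolve_charges(charge_from_code(codes), raw_lines, n)
  bonds <- if (is.null(bb) || nrow(bb) == 0) empty_bonds() else
    unname(as.matrix(bb[, 1:3, drop = FALSE]))
  id <- trimws(ChemmineR::header(sdf)[["Molecule_Name"]])
  if (is.na(id) || !nzchar(id)) id <- fallback_id
  strip_hydrogens(id, elements, coords, bonds, charges, has_3d)
}

# remove H atoms, reindex bonds, and remember explicit H per heavy atom
strip_hydrogens <- function(id, elements, coords, bonds, charges, has_3d) {
  heavy <- !(elements %in% c("H", "D", "T"))
  if (!any(heavy)) stop("record contains no heavy atoms")
  new_idx <- cumsum(heavy)
  hcount <- integer(sum(heavy))
  keep_bond <- logical(nrow(bonds))
  if (nrow(bonds) > 0) {
    for (b in seq_len(nrow(bonds))) {
      i <- bonds[b, 1]; j <- bonds[b, 2]
      if (heavy[i] && heavy[j]) {
        keep_bond[b] <- TRUE
      } else if (heavy[i] && !heavy[j]) {
        hcount[new_idx[i]] <- hcount[new_idx[i]] + 1L
      } else if (!heavy[i] && heavy[j]) {
        hcount[new_idx[j]] <- hcount[new_idx[j]] + 1L
      }
    }
  }
  bonds <- bonds[keep_bond, , drop = FALSE]
  if (nrow(bonds) > 0) {
    bonds[, 1] <- new_idx[bonds[, 1]]
    bonds[, 2] <- new_idx[bonds[, 2]]
  }
  molecule3d(id, elements[heavy], coords[heavy, , drop = FALSE],
             if (nrow(bonds) > 0) bonds else empty_bonds(),
             charges[heavy], has_3d = has_3d, hcount = hcount)
}

read_smiles_lines <- function(lines) {
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  out <- vector("list", length(lines))
  n_skip <- 0L
  for (r in seq_along(lines)) {
    f <- strsplit(lines[r], "\\s+")[[1]]
    smi <- f[1]
    id <- if (length(f) > 1) f[2] else sprintf("smiles:%d", r)
    mol <- tryCatch({
      sdfset <- suppressWarnings(ChemmineR::smiles2sdf(smi))
      m <- parse_sdf_record(ChemmineR::sdf2str(sdfset[[1]]),
                            fallback_id = id, has_3d = FALSE)
      m$id <- id
      m
    }, error = function(e) NULL)
    if (is.null(mol)) n_skip <- n_skip + 1L
    out[[r]] <- mol
  }
  if (n_skip > 0)
    warning(sprintf("skipped %d unparsable SMILES record(s)", n_skip),
            call. = FALSE)
  out[!vapply(out, is.null, logical(1))]
}

#' Write molecules to an SDF (V2000) file
#'
#' Formal charges are written through the atom-block charge code, which
#' represents charges between -3 and +3; values outside that range are
#' clamped with a warning.
#'
#' @param mols a [molecule3d] or list of them.
#' @param path output file path.
#' @return Invisibly, `path`.
#' @export
write_sdf <- function(mols, path) {
  if (inherits(mols, "molecule3d")) mols <- list(mols)
  code_of <- c(`3` = 1, `2` = 2, `1` = 3, `0` = 0, `-1` = 5, `-2` = 6, `-3` = 7)
  records <- lapply(mols, function(mol) {
    n <- hac(mol)
    ch <- mol$formal_charges
    if (any(abs(ch) > 3)) {
      warning("formal charge outside [-3, 3] clamped on SDF write", call. = FALSE)
      ch <- pmax(pmin(ch, 3L), -3L)
    }
    if (n == 1) {
      # ChemmineR's writer mis-formats one-row atom blocks; emit the
      # single fixed-width atom line directly
      return(c(mol$id, "  apfp3d", "",
               "  1  0  0  0  0  0            999 V2000",
               sprintf("%10.4f%10.4f%10.4f %-3s 0%3d  0  0  0  0  0  0  0  0  0  0",
                       mol$coords[1, 1], mol$coords[1, 2], mol$coords[1, 3],
                       mol$elements[1], code_of[as.character(ch[1])]),
               "M  END", "$$$$"))
    }
    ab <- cbind(mol$coords,
                matrix(0, n, 12, dimnames = list(NULL, paste0("C", 5:16))))
    ab[, "C6"] <- code_of[as.character(ch)]
    rownames(ab) <- paste(mol$elements, seq_len(n), sep = "_")
    colnames(ab)[1:3] <- c("C1", "C2", "C3")
    bb <- if (nrow(mol$bonds) > 0) {
      b <- cbind(mol$bonds, matrix(0L, nrow(mol$bonds), 4))
      rownames(b) <- seq_len(nrow(b))
      colnames(b) <- paste0("C", 1:7)
      b
    } else {
      matrix(0L, 0, 7, dimnames = list(NULL, paste0("C", 1:7)))
    }
    sdf <- methods::new("SDF",
        header = c(Molecule_Name = mol$id, Source = "apfp3d", Comment = "",
                   Counts_Line = sprintf("%3d%3d  0  0  0  0            999 V2000",
                                         n, nrow(mol$bonds))),
        atomblock = ab, bondblock = bb, datablock = character(0))
    unlist(ChemmineR::sdf2str(sdf))
  })
  writeLines(unlist(records), path)
  invisible(path)
}

#' Keep only the largest connected fragment of a molecule
#'
#' Complexed records (salts, co-crystallised counter ions) are reduced to the
#' connected component with the most heavy atoms.  Ties are broken by first
#' occurrence in atom order, so the result is deterministic.  Idempotent.
#'
#' @param mol a [molecule3d].
#' @return A [molecule3d] holding only the selected component, coordinates
#'   preserved.
#' @export
largest_fragment <- function(mol) {
  stopifnot(hac(mol) >= 1)
  comp <- igraph::components(mol_graph(mol))
  if (comp$no == 1) return(mol)
  sizes <- comp$csize
  best <- which(sizes == max(sizes))
  # first occurrence in atom order among maximal components
  first_atom <- vapply(best, function(k) min(which(comp$membership == k)), integer(1))
  keep_comp <- best[which.min(first_atom)]
  keep <- comp$membership == keep_comp
  new_idx <- cumsum(keep)
  bonds <- mol$bonds[keep[mol$bonds[, 1]] & keep[mol$bonds[, 2]], , drop = FALSE]
  if (nrow(bonds) > 0) {
    bonds[, 1] <- new_idx[bonds[, 1]]
    bonds[, 2] <- new_idx[bonds[, 2]]
  }
  molecule3d(mol$id, mol$elements[keep], mol$coords[keep, , drop = FALSE],
             if (nrow(bonds) > 0) bonds else empty_bonds(),
             mol$formal_charges[keep], has_3d = mol$has_3d,
             hcount = mol$hcount[keep])
}

#' Filter molecules by heavy atom count
#'
#' @param mols list of [molecule3d].
#' @param max_hac keep molecules with at most this many heavy atoms
#'   (default 50, the usual cut for drug-like screening databases).
#' @return The retained molecules, input order preserved.
#' @export
filter_by_hac <- function(mols, max_hac = 50) {
  stopifnot(max_hac >= 1)
  mols[vapply(mols, hac, integer(1)) <= max_hac]
}
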