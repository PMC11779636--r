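#' Coarse-grained conformer objects
#'
#' A `conformer` stores one coarse-grained structure: one bead per residue
#' (for RNA typically the phosphorus atom), with 1-based residue numbers taken
#' verbatim from the source file and optional crystallographic B factors.
#' A `conformer_ensemble` is an ordered collection of conformers sharing an
#' identical residue numbering, the object every downstream analysis consumes.
#'
#' @param id Character label for the structure.
#' @param residue_numbers Strictly increasing integer vector of residue numbers.
#' @param coords Numeric N x 3 matrix of bead coordinates in Angstrom, one row
#'   per residue number.
#' @param bfactors Optional numeric vector of length N with per-residue B
#'   factors (Angstrom^2-scaled).
#' @return `conformer()` returns a `conformer` object.
#' @examples
#' cf <- conformer("toy", 1:3, matrix(c(0, 0, 0, 10, 0, 0, 20, 0, 0),
#'   ncol = 3, byrow = TRUE
#' ))
#' n_residues(cf)
#' @export
conformer <- function(id, residue_numbers, coords, bfactors = NULL) {
  residue_numbers <- as.integer(residue_numbers)
  coords <- as.matrix(coords)
  storage.mode(coords) <- "double"
  if (ncol(coords) != 3L) stop("`coords` must have three columns (x, y, z)")
  n <- length(residue_numbers)
  if (n < 1L) stop("a conformer needs at least 1 residue")
  if (nrow(coords) != n) {
    stop("`coords` must have exactly one row per residue number")
  }
  if (any(diff(residue_numbers) <= 0L)) {
    stop("`residue_numbers` must be strictly increasing")
  }
  if (!all(is.finite(coords))) stop("non-finite coordinates")
  if (!is.null(bfactors)) {
    bfactors <- as.numeric(bfactors)
    if (length(bfactors) != n) stop("`bfactors` length must match residues")
    if (!all(is.finite(bfactors))) stop("non-finite B factors")
  }
  structure(
    list(
      id = as.character(id), residue_numbers = residue_numbers,
      coords = coords, bfactors = bfactors
    ),
    class = "conformer"
  )
}

#' @rdname conformer
#' @param x A `conformer`.
#' @export
n_residues <- function(x) length(x$residue_numbers)

#' @export
print.conformer <- function(x, ...) {
  cat(
    "<conformer> ", x$id, ": ", n_residues(x), " residues",
    if (!is.null(x$bfactors)) ", with B factors" else "", "\n",
    sep = ""
  )
  invisible(x)
}

#' @rdname conformer
#' @param members List of `conformer` objects sharing identical residue
#'   numbers.
#' @param reference_index Index of the member used as superposition reference
#'   where one is needed.
#' @return `conformer_ensemble()` returns a `conformer_ensemble` object.
#' @export
conformer_ensemble <- function(members, reference_index = 1L) {
  if (length(members) < 2L) stop("an ensemble needs at least 2 members")
  if (!all(vapply(members, inherits, logical(1), "conformer"))) {
    stop("all members must be `conformer` objects")
  }
  ref_res <- members[[1L]]$residue_numbers
  for (m in members[-1L]) {
    if (!identical(m$residue_numbers, ref_res)) {
      stop("member '", m$id, "' has a residue set inconsistent with '",
        members[[1L]]$id, "'",
        call. = FALSE
      )
    }
  }
  reference_index <- as.integer(reference_index)
  if (reference_index < 1L || reference_index > length(members)) {
    stop("`reference_index` out of range")
  }
  ids <- vapply(members, `[[`, character(1), "id")
  names(members) <- ids
  structure(
    list(members = members, reference_index = reference_index),
    class = "conformer_ensemble"
  )
}

#' @export
print.conformer_ensemble <- function(x, ...) {
  cat("<conformer_ensemble> ", length(x$members), " conformers x ",
    n_residues(x$members[[1L]]), " residues\n",
    sep = ""
  )
  invisible(x)
}

#' @rdname conformer
#' @export
ensemble_ids <- function(x) {
  unname(vapply(x$members, `[[`, character(1), "id"))
}

#' Stack ensemble coordinates into an M x 3N matrix
#'
#' Row m holds member m's coordinates as (x1, y1, z1, x2, y2, z2, ...), the
#' layout used for ensemble PCA and fluctuation statistics. Columns follow the
#' positional (0-based internal) residue order of the shared residue numbering.
#'
#' @param ensemble A `conformer_ensemble`.
#' @return Numeric matrix with one row per member, `3 * N` columns.
#' @export
ensemble_xyz <- function(ensemble) {
  stopifnot(inherits(ensemble, "conformer_ensemble"))
  t(vapply(
    ensemble$members, function(m) as.numeric(t(m$coords)),
    numeric(3L * n_residues(ensemble$members[[1L]]))
  ))
}

#' Read a coarse-grained conformer from a PDB file
#'
#' Selects one named atom per residue (default the RNA backbone phosphorus)
#' from the ATOM records and returns the beads in ascending residue order,
#' capturing the B-factor column when present. Only the first alternate
#' location is kept; insertion codes are rejected because coarse-grained
#' models do not use them.
#'
#' @param path Path to a PDB-format file.
#' @param atom_name Atom name to select, one occurrence per residue
#'   (default `"P"`; use `"C4'"` or `"CA"` for other bead conventions).
#' @param id Label for the conformer; defaults to the file base name.
#' @return A [conformer].
#' @export
read_conformer <- function(path, atom_name = "P", id = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  pdb <- bio3d::read.pdb(path, verbose = FALSE)
  at <- pdb$atom[pdb$atom$type %in% c("ATOM", "HETATM"), , drop = FALSE]
  at <- at[trimws(at$elety) == atom_name, , drop = FALSE]
  if (nrow(at) == 0L) {
    stop("no matching atoms named '", atom_name, "' in ", path)
  }
  ins <- at$insert
  if (!is.null(ins) && any(!is.na(ins) & nzchar(trimws(ins)))) {
    stop("insertion codes are not supported (", path, ")")
  }
  # keep the first altloc per residue, then require uniqueness
  alt <- at$alt
  if (!is.null(alt) && any(!is.na(alt) & nzchar(trimws(alt)))) {
    keep_alt <- sort(unique(trimws(alt[!is.na(alt)])))
    keep_alt <- keep_alt[nzchar(keep_alt)][1L]
    at <- at[is.na(alt) | trimws(alt) %in% c("", keep_alt), , drop = FALSE]
  }
  if (anyDuplicated(at$resno)) {
    dup <- at$resno[duplicated(at$resno)][1L]
    stop("atom '", atom_name, "' duplicated for residue ", dup, " in ", path)
  }
  ord <- order(at$resno)
  at <- at[ord, , drop = FALSE]
  bf <- at$b
  if (all(is.na(bf))) bf <- NULL
  conformer(
    id = if (is.null(id)) sub("\\.[^.]*$", "", basename(path)) else id,
    residue_numbers = at$resno,
    coords = cbind(at$x, at$y, at$z),
    bfactors = bf
  )
}

#' Write conformers as minimal PDB ATOM records
#'
#' Emits wwPDB v3.3 ATOM records with occupancy 1.00 and the stored B factor
#' (0.00 when absent). An ensemble is written as a multi-model PDB with
#' MODEL/ENDMDL blocks, the format used for principal-component trajectories.
#'
#' @param x A [conformer] or [conformer_ensemble].
#' @param path Output file path.
#' @param atom_name Atom name to write (default `"P"`).
#' @return Invisibly, `path`.
#' @export
write_conformer <- function(x, path, atom_name = "P") {
  if (inherits(x, "conformer")) {
    members <- list(x)
  } else if (inherits(x, "conformer_ensemble")) {
    members <- x$members
  } else {
    stop("`x` must be a conformer or conformer_ensemble")
  }
  multi <- length(members) > 1L
  con <- file(path, "w")
  on.exit(close(con))
  for (m in seq_along(members)) {
    cf <- members[[m]]
    if (multi) writeLines(sprintf("MODEL     %4d", m), con)
    bf <- if (is.null(cf$bfactors)) rep(0, n_residues(cf)) else cf$bfactors
    # atom names shorter than 4 characters start in column 14 (wwPDB v3.3)
    nm <- if (nchar(atom_name) < 4L) paste0(" ", atom_name) else atom_name
    lines <- sprintf(
      "ATOM  %5d %-4s %3s %s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f",
      seq_len(n_residues(cf)),
      nm,
      "  N", "A", cf$residue_numbers,
      cf$coords[, 1], cf$coords[, 2], cf$coords[, 3],
      1, bf
    )
    writeLines(lines, con)
    if (multi) writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  invisible(path)
}

#' Load a directory of conformers into an ensemble
#'
#' Reads every matching file (sorted by filename) with [read_conformer] and
#' enforces residue-number consistency across members.
#'
#' @param dir_path Directory containing at least two structure files.
#' @param atom_name Atom name to select per residue.
#' @param pattern Filename regular expression (default PDB extensions).
#' @return A [conformer_ensemble], members ordered by filename.
#' @export
load_ensemble <- function(dir_path, atom_name = "P",
                          pattern = "\\.(pdb|ent)$") {
  if (!dir.exists(dir_path)) stop("directory not found: ", dir_path)
  files <- sort(list.files(dir_path, pattern = pattern, full.names = TRUE))
  if (length(files) < 2L) {
    stop("need at least 2 structure files in ", dir_path)
  }
  members <- lapply(files, read_conformer, atom_name = atom_name)
  conformer_ensemble(members)
}

# Kabsch rotation: returns the proper rotation R minimising |P R - Q| for
# centred point sets P (mobile) and Q (reference); reflections are corrected
# by forcing det(R) = +1.
kabsch_rotation <- function(p_centred, q_centred) {
  s <- svd(crossprod(p_centred, q_centred)) # H = P'Q = U D V'
  d <- sign(det(tcrossprod(s$v, s$u)))
  if (d == 0) d <- 1
  s$u %*% diag(c(1, 1, d)) %*% t(s$v) # P %*% R approximates Q
}

#' Superpose one conformer onto another (Kabsch)
#'
#' Finds the rigid rotation + translation of `mobile` minimising the r.m.s.d.
#' to `reference` over a residue subset, applies it to all residues, and
#' returns the transformed conformer together with the minimised r.m.s.d.
#' (computed over the subset). The rotation is constrained to be proper
#' (determinant +1), so mirror images are never produced.
#'
#' @param mobile,reference [conformer] objects on the same residue numbering
#'   (at least over `subset`).
#' @param subset Residue numbers to superpose on; default all shared residues.
#' @return List with elements `conformer` (the transformed mobile) and `rmsd`
#'   (Angstrom, over `subset`).
#' @export
kabsch_superpose <- function(mobile, reference, subset = NULL) {
  stopifnot(inherits(mobile, "conformer"), inherits(reference, "conformer"))
  if (is.null(subset)) {
    subset <- intersect(mobile$residue_numbers, reference$residue_numbers)
  }
  if (length(subset) == 0L) stop("empty superposition subset")
  im <- match(subset, mobile$residue_numbers)
  ir <- match(subset, reference$residue_numbers)
  if (anyNA(im) || anyNA(ir)) {
    stop("subset contains residues absent from mobile or reference")
  }
  p <- mobile$coords[im, , drop = FALSE]
  q <- reference$coords[ir, , drop = FALSE]
  if (nrow(p) < 3L) stop("superposition needs at least 3 residues")
  cp <- colMeans(p)
  cq <- colMeans(q)
  pc <- sweep(p, 2, cp)
  qc <- sweep(q, 2, cq)
  sv <- svd(pc)$d
  if (sv[2] < max(sv[1], 1) * 1e-9) {
    stop("superposition subset is (near-)collinear; rotation underdetermined")
  }
  rot <- kabsch_rotation(pc, qc)
  new_coords <- sweep(sweep(mobile$coords, 2, cp) %*% rot, 2, cq, `+`)
  moved <- pc %*% rot
  rmsd <- sqrt(mean(rowSums((moved - qc)^2)))
  out <- mobile
  out$coords <- new_coords
  list(conformer = out, rmsd = rmsd)
}

#' Pairwise r.m.s.d. matrix of an ensemble
#'
#' Entry (i, j) is the minimised superposed r.m.s.d. between members i and j
#' over `subset`; the matrix is symmetric with a zero diagonal. Row/column
#' names are member ids.
#'
#' @param ensemble A [conformer_ensemble].
#' @param subset Residue numbers used for superposition and r.m.s.d.; default
#'   all residues.
#' @return M x M numeric matrix (Angstrom).
#' @export
pairwise_rmsd_matrix <- function(ensemble, subset = NULL) {
  stopifnot(inherits(ensemble, "conformer_ensemble"))
  m <- length(ensemble$members)
  out <- matrix(0, m, m, dimnames = list(
    ensemble_ids(ensemble),
    ensemble_ids(ensemble)
  ))
  for (i in seq_len(m - 1L)) {
    for (j in seq((i + 1L), m)) {
      r <- kabsch_superpose(
        ensemble$members[[j]], ensemble$members[[i]],
        subset
      )$rmsd
      out[i, j] <- r
      out[j, i] <- r
    }
  }
  out
}
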