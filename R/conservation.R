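IUPAC_RNA <- c(
  "A", "C", "G", "U", "R", "Y", "S", "W", "K", "M",
  "B", "D", "H", "V", "N", "-"
)

#' Multiple sequence alignments
#'
#' An `msa` is a character matrix of aligned RNA sequences (rows = sequences,
#' columns = alignment positions) over the alphabet A, C, G, U, gap (`-`) and
#' IUPAC ambiguity codes. Rows are case-folded to upper case and T is mapped
#' to U on construction.
#'
#' @param rows Character matrix, or a character vector of equal-length aligned
#'   strings (named by sequence id).
#' @return An object of class `msa`.
#' @export
msa <- function(rows) {
  if (is.character(rows) && is.null(dim(rows))) {
    lens <- nchar(rows)
    if (length(unique(lens)) != 1L) stop("ragged alignment: unequal row lengths")
    ids <- names(rows)
    rows <- do.call(rbind, strsplit(rows, ""))
    rownames(rows) <- ids
  }
  if (!is.matrix(rows) || !is.character(rows)) {
    stop("`rows` must be a character matrix or vector of aligned strings")
  }
  if (nrow(rows) < 2L) stop("an alignment needs at least 2 sequences")
  rows[] <- toupper(rows)
  rows[rows == "T"] <- "U"
  rows[rows == "."] <- "-"
  bad <- setdiff(unique(as.vector(rows)), IUPAC_RNA)
  if (length(bad)) {
    stop("unknown alignment characters: ", paste(bad, collapse = " "))
  }
  if (is.null(rownames(rows))) {
    rownames(rows) <- sprintf("seq%03d", seq_len(nrow(rows)))
  }
  structure(rows, class = c("msa", "matrix", "array"))
}

#' @export
print.msa <- function(x, ...) {
  cat("<msa> ", nrow(x), " sequences x ", ncol(x), " columns\n", sep = "")
  invisible(x)
}

#' Read a multiple alignment (Stockholm or aligned FASTA)
#'
#' Stockholm files are parsed with Biostrings (Rfam dialect; `#=GC` and other
#' annotation lines are tolerated and ignored); FASTA via Biostrings with a
#' row-length consistency check. Sequences are upper-cased and T mapped to U.
#'
#' @param path File path.
#' @param format `"auto"` (by extension/first line), `"stockholm"` or
#'   `"fasta"`.
#' @return An [msa].
#' @export
read_alignment <- function(path, format = c("auto", "stockholm", "fasta")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "auto") {
    first <- readLines(path, n = 1L)
    format <- if (startsWith(first, "# STOCKHOLM")) "stockholm" else "fasta"
  }
  if (format == "stockholm") {
    # RNA first; fall back to DNA for T-containing alignments (folded to U)
    aln <- tryCatch(
      Biostrings::readRNAMultipleAlignment(path, format = "stockholm"),
      error = function(e) {
        Biostrings::readDNAMultipleAlignment(path, format = "stockholm")
      }
    )
    aln <- Biostrings::unmasked(aln)
  } else {
    aln <- Biostrings::readBStringSet(path, format = "fasta")
  }
  strs <- as.character(aln)
  if (length(unique(nchar(strs))) != 1L) {
    stop("ragged alignment: unequal row lengths")
  }
  msa(stats::setNames(strs, names(aln)))
}

#' @rdname read_alignment
#' @param x An [msa].
#' @export
write_alignment <- function(x, path, format = c("stockholm", "fasta")) {
  format <- match.arg(format)
  strs <- apply(unclass(x), 1, paste0, collapse = "")
  if (format == "fasta") {
    Biostrings::writeXStringSet(
      Biostrings::BStringSet(strs),
      filepath = path
    )
  } else {
    ids <- formatC(names(strs), width = max(nchar(names(strs))), flag = "-")
    writeLines(
      c("# STOCKHOLM 1.0", "", paste(ids, strs), "//"),
      path
    )
  }
  invisible(path)
}

#' Map alignment columns to reference residue numbers
#'
#' Non-gap columns of the reference row are numbered consecutively from 1 (the
#' residue numbering used to project alignment scores onto a structure); gap
#' columns are unmapped.
#'
#' @param x An [msa].
#' @param reference_id Row name of the reference sequence.
#' @return Tibble with columns `column` and `residue_number`.
#' @export
map_columns_to_reference <- function(x, reference_id) {
  stopifnot(inherits(x, "msa"))
  if (!reference_id %in% rownames(x)) {
    stop("reference id '", reference_id, "' not in alignment")
  }
  ref <- unclass(x)[reference_id, ]
  cols <- which(ref != "-")
  if (length(cols) == 0L) stop("reference sequence is all gaps")
  tibble::tibble(column = cols, residue_number = seq_along(cols))
}

column_entropy_score <- function(col) {
  bases <- col[col %in% c("A", "C", "G", "U")]
  occupancy <- sum(col != "-") / length(col)
  if (length(bases) == 0L) {
    return(c(score = 0, occupancy = occupancy))
  }
  p <- table(factor(bases, levels = c("A", "C", "G", "U"))) / length(bases)
  p <- p[p > 0]
  h <- -sum(p * log2(p))
  c(score = (1 - h / 2) * occupancy, occupancy = occupancy)
}

#' Per-residue sequence conservation score (SCS)
#'
#' Information-based column conservation: 1 - H(column)/log2(4) over
#' \{A, C, G, U\} with gaps excluded from the entropy but penalising the score
#' through occupancy weighting (score x non-gap fraction), then min-max
#' rescaled to \[0, 1\] across the mapped residues. Zero-occupancy columns
#' score 0 and are flagged. Higher means more conserved.
#'
#' @param x An [msa].
#' @param mapping Column-to-residue mapping from
#'   [map_columns_to_reference()]; defaults to all columns numbered 1..L.
#' @return Tibble with `residue_number`, `column`, `occupancy`, `score_raw`
#'   (pre-rescale), `scs` and `zero_occupancy`.
#' @export
sequence_conservation_score <- function(x, mapping = NULL) {
  stopifnot(inherits(x, "msa"))
  m <- unclass(x)
  if (is.null(mapping)) {
    mapping <- tibble::tibble(
      column = seq_len(ncol(m)),
      residue_number = seq_len(ncol(m))
    )
  }
  stats_mat <- vapply(
    mapping$column, function(j) column_entropy_score(m[, j]),
    numeric(2)
  )
  raw <- stats_mat["score", ]
  rng <- range(raw)
  scs <- if (diff(rng) == 0) rep(1, length(raw)) else (raw - rng[1]) / diff(rng)
  tibble::tibble(
    residue_number = mapping$residue_number,
    column = mapping$column,
    occupancy = stats_mat["occupancy", ],
    score_raw = raw,
    scs = scs,
    zero_occupancy = stats_mat["occupancy", ] == 0
  )
}

#' Per-residue 3D conformation conservation score (3DCS)
#'
#' 1 minus the min-max normalised per-residue r.m.s.f.: the most mobile
#' residue scores 0, the most rigid scores 1. Invariant to affine rescaling
#' of the r.m.s.f. A constant r.m.s.f. vector is degenerate; all scores are
#' then defined as 1 (with a warning).
#'
#' @param rmsf Nonempty numeric vector of per-residue r.m.s.f. (Angstrom).
#' @return Numeric vector of 3DCS values in \[0, 1\].
#' @export
conformation_conservation_score <- function(rmsf) {
  if (length(rmsf) == 0L) stop("empty r.m.s.f. vector")
  rng <- range(rmsf)
  if (diff(rng) == 0) {
    warning("constant r.m.s.f.: degenerate 3DCS, all scores set to 1")
    return(rep(1, length(rmsf)))
  }
  1 - (rmsf - rng[1]) / diff(rng)
}

#' Assemble a per-residue conservation table
#'
#' Joins SCS, r.m.s.f. and 3DCS on residue number; residues without alignment
#' coverage are dropped. Core membership (from an invariant-core analysis)
#' is recorded in the `core` column.
#'
#' @param scs Tibble from [sequence_conservation_score()].
#' @param rmsf Numeric vector of r.m.s.f. named or ordered by residue number.
#' @param residue_numbers Residue numbers corresponding to `rmsf` (default
#'   `seq_along(rmsf)`).
#' @param core_residues Optional residue numbers in the invariant core.
#' @return Tibble with `residue_number`, `scs`, `rmsf`, `threeDCS`, `core`.
#' @export
conservation_table <- function(scs, rmsf,
                               residue_numbers = seq_along(rmsf),
                               core_residues = NULL) {
  rt <- tibble::tibble(
    residue_number = residue_numbers, rmsf = as.numeric(rmsf)
  )
  tab <- dplyr::inner_join(
    scs[, c("residue_number", "scs")], rt,
    by = "residue_number"
  )
  tab$threeDCS <- conformation_conservation_score(tab$rmsf)
  tab$core <- tab$residue_number %in% (core_residues %||% integer())
  tab
}

#' Correlate sequence and conformational conservation; flag outlier residues
#'
#' Computes the Pearson correlation between SCS and 3DCS, flags
#' anticorrelated residues (SCS above the upper `flag_quantile` while 3DCS
#' below the lower quantile, and vice versa), and recomputes the correlation
#' excluding them. Because squaring the scores has been proposed as an
#' alternative scale, the correlation of the squared scores is reported
#' alongside the raw one.
#'
#' @param table Tibble with columns `scs` and `threeDCS` (e.g. from
#'   [conservation_table()]).
#' @param exclusion Optional residue numbers excluded from all computations.
#' @param flag_quantile Tail quantile defining "high"/"low" (default 0.25,
#'   i.e. quartiles).
#' @return Object of class `conservation_correlation`: `r_all`,
#'   `r_excluding_flagged`, `r_all_squared`, `table` (input plus a `flag`
#'   column in \{correlated, high-SCS/low-3DCS, low-SCS/high-3DCS\}), and the
#'   flagged residue sets.
#' @export
correlate_and_flag <- function(table, exclusion = NULL, flag_quantile = 0.25) {
  tab <- table
  if (!is.null(exclusion)) {
    tab <- tab[!tab$residue_number %in% exclusion, , drop = FALSE]
  }
  if (nrow(tab) < 3L) stop("need at least 3 residues")
  if (stats::sd(tab$scs) == 0 || stats::sd(tab$threeDCS) == 0) {
    stop("degenerate variance: constant score vector")
  }
  hi_scs <- tab$scs >= stats::quantile(tab$scs, 1 - flag_quantile)
  lo_scs <- tab$scs <= stats::quantile(tab$scs, flag_quantile)
  hi_3d <- tab$threeDCS >= stats::quantile(tab$threeDCS, 1 - flag_quantile)
  lo_3d <- tab$threeDCS <= stats::quantile(tab$threeDCS, flag_quantile)
  flag <- rep("correlated", nrow(tab))
  flag[hi_scs & lo_3d] <- "high-SCS/low-3DCS"
  flag[lo_scs & hi_3d] <- "low-SCS/high-3DCS"
  tab$flag <- flag
  keep <- flag == "correlated"
  r_all <- stats::cor(tab$scs, tab$threeDCS)
  r_excl <- if (sum(keep) >= 3L) {
    stats::cor(tab$scs[keep], tab$threeDCS[keep])
  } else {
    NA_real_
  }
  structure(
    list(
      r_all = r_all,
      r_excluding_flagged = r_excl,
      r_all_squared = stats::cor(tab$scs^2, tab$threeDCS^2),
      flagged_high_scs_low_3dcs =
        tab$residue_number[flag == "high-SCS/low-3DCS"],
      flagged_low_scs_high_3dcs =
        tab$residue_number[flag == "low-SCS/high-3DCS"],
      table = tab, flag_quantile = flag_quantile
    ),
    class = "conservation_correlation"
  )
}

#' @export
print.conservation_correlation <- function(x, ...) {
  cat("<conservation_correlation> r = ", signif(x$r_all, 3),
    "; excluding ", length(x$flagged_high_scs_low_3dcs) +
      length(x$flagged_low_scs_high_3dcs),
    " anticorrelated residues: r = ", signif(x$r_excluding_flagged, 3), "\n",
    sep = ""
  )
  invisible(x)
}
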