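#' Construct a protein record
#'
#' A protein record holds a one-letter amino-acid sequence of length `L`
#' together with one representative 3D coordinate per residue: the C-beta
#' atom position, or C-alpha for glycine.  Residues without an observed
#' representative atom carry `NA` coordinates and are excluded from both
#' contact labels and evaluation denominators.
#'
#' @param id Target identifier (single string).
#' @param sequence One-letter amino-acid string of length `L`.
#' @param coords `L x 3` numeric matrix of coordinates in Angstrom; rows may
#'   be all-`NA` for residues with missing density.
#' @return An object of class `protein_record` with fields `id`, `sequence`
#'   (character vector of length `L`), `coords`, and `L`.
#' @export
protein_record <- function(id, sequence, coords = NULL) {
  stopifnot(is.character(id), length(id) == 1L, nzchar(id))
  stopifnot(is.character(sequence), length(sequence) == 1L)
  seq_chars <- strsplit(toupper(sequence), "")[[1]]
  L <- length(seq_chars)
  if (L < 1L) stop("empty sequence for record '", id, "'")
  if (is.null(coords)) {
    coords <- matrix(NA_real_, nrow = L, ncol = 3L)
  }
  coords <- as.matrix(coords)
  if (!is.numeric(coords) || ncol(coords) != 3L || nrow(coords) != L) {
    stop("coords must be an L x 3 numeric matrix (L = ", L, ") for record '",
         id, "'")
  }
  if (!all(is.finite(coords) | is.na(coords))) {
    stop("non-finite coordinates in record '", id, "'")
  }
  # a residue either has a full 3-vector or none of it
  if (any(rowSums(is.na(coords)) %in% 1:2)) {
    stop("residues with partially missing coordinates in record '", id, "'")
  }
  dimnames(coords) <- list(NULL, c("x", "y", "z"))
  structure(list(id = id, sequence = seq_chars, coords = coords, L = L),
            class = "protein_record")
}

#' @export
print.protein_record <- function(x, ...) {
  cat(sprintf("<protein_record> %s  L=%d  (%d residues with coordinates)\n",
              x$id, x$L, sum(stats::complete.cases(x$coords))))
  invisible(x)
}

#' Compute the residue-residue contact map of a structure
#'
#' Two residues are in contact when the Euclidean distance between their
#' representative atoms (C-beta; C-alpha for glycine) is strictly less than
#' the threshold, 8 Angstrom by default (the CASP definition).  Pairs where
#' either residue lacks coordinates have undefined distance and `NA` contact
#' status; the diagonal is never a contact.
#'
#' @param record A [protein_record()].
#' @param threshold Contact distance threshold in Angstrom (default 8.0).
#' @return Object of class `contact_map`: list with `distances` (`L x L`
#'   symmetric, `NA` where undefined), `contacts` (`L x L` logical, `NA`
#'   where undefined), `threshold`, and `L`.
#' @export
contact_map <- function(record, threshold = 8.0) {
  stopifnot(inherits(record, "protein_record"))
  if (!is.numeric(threshold) || length(threshold) != 1L || threshold <= 0) {
    stop("threshold must be a positive number")
  }
  has_xyz <- stats::complete.cases(record$coords)
  if (!any(has_xyz)) {
    stop("record '", record$id, "' has no residue coordinates at all")
  }
  D <- as.matrix(stats::dist(record$coords))  # NA rows propagate to NA dist
  dimnames(D) <- NULL
  diag(D) <- 0
  contacts <- D < threshold
  diag(contacts) <- FALSE
  structure(list(distances = D, contacts = contacts,
                 threshold = threshold, L = record$L),
            class = "contact_map")
}

#' @export
print.contact_map <- function(x, ...) {
  n_def <- sum(!is.na(x$contacts[upper.tri(x$contacts)]))
  n_con <- sum(x$contacts[upper.tri(x$contacts)], na.rm = TRUE)
  cat(sprintf("<contact_map> L=%d  threshold=%g A  %d/%d defined pairs in contact\n",
              x$L, x$threshold, n_con, n_def))
  invisible(x)
}

RANGE_CLASSES <- c("short", "medium", "long")

#' Classify residue pairs by sequence separation
#'
#' Contacts are stratified by the separation `|i - j|` along the chain:
#' short range 6-11, medium range 12-23, long range >= 24.  Pairs closer
#' than 6 residues usually share a secondary-structure element and are
#' excluded from contact prediction.
#'
#' @param i,j 1-based residue indices (vectorized; `i != j` elementwise).
#' @return Character vector over `"excluded"`, `"short"`, `"medium"`,
#'   `"long"`.
#' @export
classify_separation <- function(i, j) {
  i <- as.integer(i); j <- as.integer(j)
  if (length(i) != length(j)) stop("i and j must have equal length")
  if (any(i < 1L) || any(j < 1L)) stop("indices are 1-based; got value < 1")
  if (any(i == j)) stop("i == j: a residue has no separation from itself")
  sep <- abs(i - j)
  out <- rep("excluded", length(sep))
  out[sep >= 6L & sep <= 11L] <- "short"
  out[sep >= 12L & sep <= 23L] <- "medium"
  out[sep >= 24L] <- "long"
  out
}

range_separation_bounds <- function(range_class) {
  switch(match.arg(range_class, c(RANGE_CLASSES, "excluded", "all")),
         short = c(6L, 11L),
         medium = c(12L, 23L),
         long = c(24L, .Machine$integer.max),
         excluded = c(1L, 5L),
         all = c(6L, .Machine$integer.max))
}

#' Enumerate residue pairs of one separation class
#'
#' @param L Sequence length (>= 2).
#' @param range_class One of `"short"`, `"medium"`, `"long"`, `"excluded"`,
#'   or `"all"` (any separation >= 6).
#' @return Integer matrix with columns `i`, `j`; `i < j`, rows in
#'   deterministic row-major order (by `i`, then `j`).
#' @export
enumerate_pairs <- function(L, range_class) {
  L <- as.integer(L)
  if (is.na(L) || L < 2L) stop("L must be an integer >= 2")
  b <- range_separation_bounds(range_class)
  lo <- b[1]; hi <- min(b[2], L - 1L)
  if (hi < lo) {
    return(matrix(integer(0), ncol = 2L, dimnames = list(NULL, c("i", "j"))))
  }
  i <- unlist(lapply(seq_len(L - lo), function(ii) {
    rep.int(ii, length(seq.int(ii + lo, min(L, ii + hi))))
  }))
  j <- unlist(lapply(seq_len(L - lo), function(ii) seq.int(ii + lo, min(L, ii + hi))))
  cbind(i = as.integer(i), j = as.integer(j))
}

THREE_TO_ONE <- c(
  ALA = "A", ARG = "R", ASN = "N", ASP = "D", CYS = "C", GLN = "Q",
  GLU = "E", GLY = "G", HIS = "H", ILE = "I", LEU = "L", LYS = "K",
  MET = "M", PHE = "F", PRO = "P", SER = "S", THR = "T", TRP = "W",
  TYR = "Y", VAL = "V")

#' Read one chain of a PDB file into a protein record
#'
#' Minimal ATOM-record reader: keeps one representative coordinate per
#' residue, preferring CB and falling back to CA (always CA for glycine);
#' alternate locations other than blank or 'A' are ignored; unknown residue
#' types become 'X'.  Residues are taken in order of appearance.
#'
#' @param path PDB-format file.
#' @param chain Chain identifier to read; default the first chain seen.
#' @param id Record id; defaults to the file name.
#' @return A [protein_record()].
#' @export
read_pdb_record <- function(path, chain = NULL, id = NULL) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[startsWith(lines, "ATOM  ")]
  if (length(lines) == 0L) stop("no ATOM records in ", path)
  fld <- function(l, a, b) trimws(substr(l, a, b))
  atom <- fld(lines, 13, 16)
  altloc <- substr(lines, 17, 17)
  resname <- fld(lines, 18, 20)
  ch <- substr(lines, 22, 22)
  resseq <- fld(lines, 23, 27)  # includes insertion code column
  keep <- altloc %in% c(" ", "A")
  lines <- lines[keep]; atom <- atom[keep]; resname <- resname[keep]
  ch <- ch[keep]; resseq <- resseq[keep]
  if (is.null(chain)) chain <- ch[1]
  sel <- ch == chain
  if (!any(sel)) stop("chain '", chain, "' not found in ", path)
  lines <- lines[sel]; atom <- atom[sel]; resname <- resname[sel]
  resseq <- resseq[sel]
  rid <- factor(resseq, levels = unique(resseq))
  xyz <- cbind(as.numeric(substr(lines, 31, 38)),
               as.numeric(substr(lines, 39, 46)),
               as.numeric(substr(lines, 47, 54)))
  L <- nlevels(rid)
  coords <- matrix(NA_real_, L, 3L)
  seq_chars <- character(L)
  for (k in seq_len(L)) {
    rows <- which(as.integer(rid) == k)
    rn <- resname[rows[1]]
    seq_chars[k] <- if (rn %in% names(THREE_TO_ONE)) THREE_TO_ONE[[rn]] else "X"
    want <- if (identical(rn, "GLY")) "CA" else "CB"
    hit <- rows[atom[rows] == want]
    if (length(hit) == 0L) hit <- rows[atom[rows] == "CA"]
    if (length(hit) > 0L) coords[k, ] <- xyz[hit[1], ]
  }
  if (is.null(id)) id <- sub("\\.(pdb|ent)$", "", basename(path))
  protein_record(id, paste(seq_chars, collapse = ""), coords)
}

#' Write a protein record as minimal PDB ATOM records
#'
#' Inverse of [read_pdb_record()] for fixture round-trips: one CB atom per
#' residue (CA for glycine); residues without coordinates are skipped.
#'
#' @param record A [protein_record()].
#' @param path Output file.
#' @export
write_pdb_record <- function(record, path) {
  stopifnot(inherits(record, "protein_record"))
  one_to_three <- stats::setNames(names(THREE_TO_ONE), unname(THREE_TO_ONE))
  con <- file(path, "w"); on.exit(close(con))
  serial <- 0L
  for (k in seq_len(record$L)) {
    if (anyNA(record$coords[k, ])) next
    serial <- serial + 1L
    aa <- record$sequence[k]
    rn <- if (aa %in% names(one_to_three)) one_to_three[[aa]] else "UNK"
    an <- if (identical(rn, "GLY")) "CA" else "CB"
    writeLines(sprintf(
      "ATOM  %5d  %-3s %3s A%4d    %8.3f%8.3f%8.3f  1.00  0.00",
      serial, an, rn, k,
      record$coords[k, 1], record$coords[k, 2], record$coords[k, 3]), con)
  }
  writeLines("END", con)
  invisible(path)
}
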