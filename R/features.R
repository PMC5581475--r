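# Per-residue feature table (F = 32 columns) and windowed pair vectors.
# Column layout, fixed: 20 PSSM log-odds, info-per-position, relative
# weight, SS one-hot (H, E, C), SA (0 buried / 1 exposed), 5 Atchley
# factors, relative position p/L.

# Published five-factor solution summarizing amino-acid physicochemistry:
# f1 polarity/accessibility, f2 secondary-structure propensity,
# f3 size/volume, f4 codon composition, f5 electrostatic charge.
ATCHLEY_TABLE <- matrix(c(
  -0.591, -1.302, -0.733,  1.570, -0.146,  # A
  -1.343,  0.465, -0.862, -1.020, -0.255,  # C
   1.050,  0.302, -3.656, -0.259, -3.242,  # D
   1.357, -1.453,  1.477,  0.113, -0.837,  # E
  -1.006, -0.590,  1.891, -0.397,  0.412,  # F
  -0.384,  1.652,  1.330,  1.045,  2.064,  # G
   0.336, -0.417, -1.673, -1.474, -0.078,  # H
  -1.239, -0.547,  2.131,  0.393,  0.816,  # I
   1.831, -0.561,  0.533, -0.277,  1.648,  # K
  -1.019, -0.987, -1.505,  1.266, -0.912,  # L
  -0.663, -1.524,  2.219, -1.005,  1.212,  # M
   0.945,  0.828,  1.299, -0.169,  0.933,  # N
   0.189,  2.081, -1.628,  0.421, -1.392,  # P
   0.931, -0.179, -3.005, -0.503, -1.853,  # Q
   1.538, -0.055,  1.502,  0.440,  2.897,  # R
  -0.228,  1.399, -4.760,  0.670, -2.647,  # S
  -0.032,  0.326,  2.213,  0.908,  1.313,  # T
  -1.337, -0.279, -0.544,  1.242, -1.262,  # V
  -0.595,  0.009,  0.672, -2.128, -0.184,  # W
   0.260,  0.830,  3.097, -0.838,  1.512), # Y
  nrow = 20, ncol = 5, byrow = TRUE,
  dimnames = list(c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                    "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y"),
                  paste0("f", 1:5)))

#' Atchley factors of an amino acid
#'
#' Returns the published five numeric factors characterizing an amino acid
#' (polarity/accessibility, secondary-structure propensity, size/volume,
#' codon composition, charge).  Non-standard residues (X, B, Z, gaps) map to
#' the zero vector; lowercase input is normalized.
#'
#' @param aa Character vector of 1-letter codes.
#' @return `length(aa) x 5` numeric matrix.
#' @export
atchley_factors <- function(aa) {
  aa <- toupper(as.character(aa))
  if (any(nchar(aa) != 1L) || any(!grepl("^[A-Z]$", aa))) {
    stop("amino-acid codes must be single letters")
  }
  out <- matrix(0, length(aa), 5L, dimnames = list(NULL, colnames(ATCHLEY_TABLE)))
  hit <- aa %in% rownames(ATCHLEY_TABLE)
  out[hit, ] <- ATCHLEY_TABLE[aa[hit], , drop = FALSE]
  out
}

#' Relative sequence position
#'
#' `rPosition = p / L` for a 1-based residue index `p` in a chain of length
#' `L`; always in `(0, 1]`.
#'
#' @param p 1-based index (vectorized).
#' @param L Sequence length.
#' @return Numeric vector `p / L`.
#' @export
relative_position <- function(p, L) {
  p <- as.integer(p); L <- as.integer(L)
  if (any(p < 1L) || any(p > L)) stop("position index outside [1, L]")
  p / L
}

FEATURE_NAMES <- c(paste0("pssm_", PSSM_ALPHABET), "info_per_pos", "rel_weight",
                   "ss_H", "ss_E", "ss_C", "sa_exposed",
                   paste0("atchley_", 1:5), "rel_position")

#' Assemble the per-residue feature table
#'
#' Binds the five per-residue feature types into a fixed-order `L x 32`
#' matrix: PSSM log-odds (20) plus its two trailing profile columns,
#' 3-state secondary-structure one-hot, binary solvent accessibility,
#' five Atchley factors, and the relative position `p/L`.
#'
#' @param record A [protein_record()].
#' @param pssm A `pssm_profile` from [read_pssm()] with `L` rows.
#' @param ss Length-`L` string over `{H, E, C}`.
#' @param sa Length-`L` string over `{b, e}`.
#' @return `L x 32` numeric matrix with column names `FEATURE_NAMES`.
#' @export
build_feature_table <- function(record, pssm, ss, sa) {
  stopifnot(inherits(record, "protein_record"))
  L <- record$L
  if (nrow(pssm$scores) != L) {
    stop("PSSM has ", nrow(pssm$scores), " rows but record length is ", L)
  }
  if (nchar(ss) != L) stop("secondary-structure string length != L")
  if (nchar(sa) != L) stop("solvent-accessibility string length != L")
  ss_chars <- strsplit(ss, "")[[1]]
  sa_chars <- strsplit(sa, "")[[1]]
  if (!all(ss_chars %in% c("H", "E", "C"))) stop("SS alphabet must be {H,E,C}")
  if (!all(sa_chars %in% c("b", "e"))) stop("SA alphabet must be {b,e}")
  tab <- cbind(
    pssm$scores,
    pssm$info_per_pos,
    pssm$rel_weight,
    as.numeric(ss_chars == "H"),
    as.numeric(ss_chars == "E"),
    as.numeric(ss_chars == "C"),
    as.numeric(sa_chars == "e"),
    atchley_factors(record$sequence),
    relative_position(seq_len(L), L))
  colnames(tab) <- FEATURE_NAMES
  tab
}

#' Windowed feature vector for one residue pair
#'
#' Concatenates the rows of a 9-residue window centered at residue `i`
#' followed by the window centered at `j` (an 18-residue window instance in
#' total).  Window positions outside the chain contribute zero rows, so the
#' vector length is always `2 * window * F`.
#'
#' @param table Feature table from [build_feature_table()].
#' @param i,j 1-based residue indices, `i < j`.
#' @param window Odd window size (default 9).
#' @return Numeric vector of length `2 * window * ncol(table)`.
#' @export
build_pair_vector <- function(table, i, j, window = 9L) {
  v <- build_pair_matrix(table, cbind(i = i, j = j), window)
  v[1L, ]
}

#' Windowed feature vectors for many residue pairs
#'
#' Vectorized form of [build_pair_vector()]: one row per pair.
#'
#' @param table Feature table (`L x F`).
#' @param pairs Integer matrix with columns `i`, `j` (`i < j`).
#' @param window Odd window size.
#' @return `nrow(pairs) x (2 * window * F)` matrix.
#' @export
build_pair_matrix <- function(table, pairs, window = 9L) {
  window <- as.integer(window)
  if (window < 1L || window %% 2L == 0L) stop("window must be a positive odd integer")
  pairs <- matrix(as.integer(pairs), ncol = 2L)
  L <- nrow(table); F <- ncol(table)
  if (any(pairs < 1L) || any(pairs > L)) stop("pair index outside [1, L]")
  if (any(pairs[, 1] >= pairs[, 2])) stop("pairs must satisfy i < j")
  half <- (window - 1L) %/% 2L
  # pad the table with zero rows so window lookups never go off-chain
  padded <- rbind(matrix(0, half, F), table, matrix(0, half, F))
  offs <- seq.int(0L, window - 1L)  # into padded: residue p -> rows p..p+window-1
  win_rows <- function(p) rep(p, each = window) + offs
  rows <- cbind(matrix(win_rows(pairs[, 1]), ncol = window, byrow = TRUE),
                matrix(win_rows(pairs[, 2]), ncol = window, byrow = TRUE))
  n <- nrow(pairs)
  out <- matrix(0, n, 2L * window * F)
  for (w in seq_len(2L * window)) {
    block <- padded[rows[, w], , drop = FALSE]
    out[, ((w - 1L) * F + 1L):(w * F)] <- block
  }
  out
}
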