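# Readers/writers for the stage-1 input files and CASP RR prediction lists.
# All residue indices in files are 1-based.

#' Read a PSI-BLAST ASCII PSSM profile
#'
#' Parses the layout written by `psiblast -out_ascii_pssm`: header lines,
#' then one row per residue carrying the position index, the residue letter,
#' 20 log-odds integers, 20 weighted-percentage integers, and two trailing
#' floats (information per position and the relative weight of gapless real
#' matches to pseudo-counts).  Only the log-odds block and the two trailing
#' columns are retained; both are passed through unscaled.
#'
#' @param path Profile file.
#' @return Object of class `pssm_profile`: list with `scores` (`L x 20`
#'   log-odds matrix, columns named by residue), `info_per_pos`,
#'   `rel_weight`, and `sequence` (character vector).
#' @export
read_pssm <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (length(lines) == 0L) stop("empty PSSM file: ", path)
  rows <- list(); seqs <- character(); info <- numeric(); relw <- numeric()
  for (ln in seq_along(lines)) {
    tok <- strsplit(trimws(lines[[ln]]), "\\s+")[[1]]
    if (length(tok) == 0L || is.na(suppressWarnings(as.integer(tok[1])))) next
    if (length(tok) == 1L) next  # stray numeric footer (Lambda/K lines differ)
    if (length(tok) != 44L) {
      stop("PSSM parse error at line ", ln, ": expected 44 columns, got ",
           length(tok))
    }
    vals <- suppressWarnings(as.numeric(tok[3:44]))
    if (anyNA(vals)) stop("PSSM parse error at line ", ln, ": non-numeric cell")
    rows[[length(rows) + 1L]] <- vals[1:20]
    seqs <- c(seqs, tok[2])
    info <- c(info, vals[41])
    relw <- c(relw, vals[42])
  }
  if (length(rows) == 0L) stop("no PSSM rows found in ", path)
  scores <- do.call(rbind, rows)
  colnames(scores) <- PSSM_ALPHABET
  structure(list(scores = scores, info_per_pos = info, rel_weight = relw,
                 sequence = seqs),
            class = "pssm_profile")
}

#' Write a PSSM profile in PSI-BLAST ASCII layout
#'
#' Emits the same 44-column row layout that [read_pssm()] consumes (the
#' second 20-column percentage block is filled with zeros), so fixture
#' profiles round-trip exactly.
#'
#' @param profile A `pssm_profile`.
#' @param path Output file.
#' @export
write_pssm <- function(profile, path) {
  stopifnot(inherits(profile, "pssm_profile"))
  L <- nrow(profile$scores)
  con <- file(path, "w"); on.exit(close(con))
  writeLines(c("",
               "Last position-specific scoring matrix computed",
               paste(c("   ", PSSM_ALPHABET, PSSM_ALPHABET), collapse = "  ")),
             con)
  for (p in seq_len(L)) {
    writeLines(paste(
      c(sprintf("%5d %s", p, profile$sequence[p]),
        sprintf("%3d", as.integer(profile$scores[p, ])),
        sprintf("%3d", integer(20)),
        sprintf("%6.2f", profile$info_per_pos[p]),
        sprintf("%6.2f", profile$rel_weight[p])),
      collapse = " "), con)
  }
  writeLines("", con)
  invisible(path)
}

#' Min-max normalize a correlated-mutations score matrix to [0, 1]
#'
#' Raw correlated-mutations scores are not naturally bounded; per-protein
#' min-max scaling makes the 0-1 contact-probability contract hold.  A
#' constant matrix maps to 0.5 everywhere.  The diagonal is forced to 0.
#'
#' @param m Symmetric numeric matrix.
#' @return Matrix with off-diagonal values in `[0, 1]`.
#' @export
normalize_cm <- function(m) {
  off <- m[upper.tri(m)]
  rng <- range(off, na.rm = TRUE)
  if (diff(rng) == 0) {
    m[] <- 0.5
  } else {
    m <- (m - rng[1]) / (rng[2] - rng[1])
    m[m < 0] <- 0; m[m > 1] <- 1
  }
  diag(m) <- 0
  m
}

#' Read a correlated-mutations score matrix
#'
#' Three dialects cover the common tool outputs: `triplet` (lines
#' `i j score`, 1-based, as emitted by PSICOV/GREMLIN-style rankers),
#' `matrix` (`L` rows of `L` whitespace-separated floats, CCMpred-style),
#' and `rr` (CASP RR lines `i j d_low d_high prob`).  Unlisted pairs default
#' to 0; self-pairs are ignored.  An asymmetric full matrix is symmetrized
#' by averaging with a warning.
#'
#' @param path Score file.
#' @param dialect One of `"triplet"`, `"matrix"`, `"rr"`.
#' @param L Declared sequence length; indices outside `[1, L]` are an error.
#' @param method_tag Label stored with the matrix (e.g. tool name).
#' @param normalize Min-max normalize to `[0, 1]` at load (default `TRUE`).
#' @return Object of class `cm_scores`: list with `scores` (`L x L`
#'   symmetric) and `method_tag`.
#' @export
read_cm_scores <- function(path, dialect = c("triplet", "matrix", "rr"), L,
                           method_tag = dialect, normalize = TRUE) {
  dialect <- match.arg(dialect)
  L <- as.integer(L)
  stopifnot(L >= 1L)
  m <- matrix(0, L, L)
  if (dialect == "matrix") {
    vals <- utils::read.table(path, header = FALSE)
    if (nrow(vals) != L || ncol(vals) != L) {
      stop("matrix dialect: file implies ", nrow(vals), " x ", ncol(vals),
           " but declared L = ", L)
    }
    m <- as.matrix(vals)
    dimnames(m) <- NULL
    if (max(abs(m - t(m))) > 1e-8) {
      warning("asymmetric score matrix symmetrized by averaging")
      m <- (m + t(m)) / 2
    }
  } else {
    lines <- readLines(path, warn = FALSE)
    lines <- lines[nzchar(trimws(lines))]
    lines <- lines[grepl("^\\s*[0-9]", lines)]  # skip RR/extra headers
    if (length(lines) > 0L) {
      tok <- strsplit(trimws(lines), "\\s+")
      nfld <- if (dialect == "triplet") 3L else 5L
      bad <- vapply(tok, length, 1L) != nfld
      if (any(bad)) {
        stop(dialect, " dialect: malformed line ", which(bad)[1])
      }
      rec <- matrix(suppressWarnings(as.numeric(unlist(tok))),
                    ncol = nfld, byrow = TRUE)
      if (anyNA(rec)) stop(dialect, " dialect: non-numeric field")
      i <- as.integer(rec[, 1]); j <- as.integer(rec[, 2])
      s <- rec[, nfld]
      if (any(i < 1L | i > L | j < 1L | j > L)) {
        stop("pair index outside [1, ", L, "] in ", path)
      }
      keep <- i != j
      i <- i[keep]; j <- j[keep]; s <- s[keep]
      key <- paste(pmin(i, j), pmax(i, j))
      if (anyDuplicated(key)) {
        agg <- tapply(s, key, function(v) diff(range(v)))
        if (any(agg > 1e-9)) {
          stop("duplicate pair with conflicting scores in ", path, ": pair ",
               names(agg)[which(agg > 1e-9)[1]])
        }
      }
      m[cbind(i, j)] <- s
      m[cbind(j, i)] <- s
    }
  }
  if (normalize) m <- normalize_cm(m) else diag(m) <- 0
  structure(list(scores = m, method_tag = method_tag), class = "cm_scores")
}

#' Read a predicted secondary-structure or solvent-accessibility string
#'
#' Minimal per-residue string formats: secondary structure is one line over
#' the 3-state alphabet `{H, E, C}`; solvent accessibility is one line over
#' `{b, e}` (buried/exposed at the usual 25% relative-accessibility cutoff).
#'
#' @param path File whose first non-empty line is the string.
#' @param L Declared length; mismatch is an error.
#' @return Character scalar of length-`L` states.
#' @name read_residue_strings
#' @export
read_ss <- function(path, L) {
  s <- read_state_string(path, L, c("H", "E", "C"), "secondary structure")
  s
}

#' @rdname read_residue_strings
#' @export
read_sa <- function(path, L) {
  read_state_string(path, L, c("b", "e"), "solvent accessibility")
}

read_state_string <- function(path, L, alphabet, what) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) stop("empty ", what, " file: ", path)
  s <- trimws(lines[[1]])
  if (nchar(s) != L) {
    stop(what, " string length ", nchar(s), " conflicts with declared L = ", L)
  }
  if (!all(strsplit(s, "")[[1]] %in% alphabet)) {
    stop(what, " string contains characters outside {",
         paste(alphabet, collapse = ","), "}")
  }
  s
}

#' Build a ranked contact prediction list
#'
#' @param target Target identifier.
#' @param i,j 1-based residue indices with `i < j`.
#' @param score Finite prediction scores.
#' @param range_class Optional separation class label for the list.
#' @return Object of class `prediction_list`: data frame `(i, j, score)`
#'   sorted by descending score, ties broken by `(i, j)` ascending; with
#'   attributes `target` and `range_class`.
#' @export
prediction_list <- function(target, i, j, score, range_class = "all") {
  i <- as.integer(i); j <- as.integer(j); score <- as.numeric(score)
  stopifnot(length(i) == length(j), length(j) == length(score))
  if (any(i >= j)) stop("prediction pairs must satisfy i < j")
  if (length(score) && !all(is.finite(score))) stop("non-finite scores")
  if (anyDuplicated(paste(i, j))) stop("duplicate pairs in prediction list")
  ord <- order(-score, i, j)
  structure(data.frame(i = i[ord], j = j[ord], score = score[ord]),
            target = target, range_class = range_class,
            class = c("prediction_list", "data.frame"))
}

#' Write / read contact predictions in CASP RR style
#'
#' Lines are `i j 0 8 score` (the distance bounds mirror the 8 Angstrom
#' contact definition), preceded by a minimal `PFRMAT RR` header and
#' terminated by `END`.  Scores must already lie in `[0, 1]`; out-of-range
#' scores are an error, never silently clipped.  `read_rr` inverts
#' `write_rr` exactly.
#'
#' @param predictions A [prediction_list()] with scores in `[0, 1]`.
#' @param path File path.
#' @param target Target id used when reading (default: from `TARGET` line).
#' @return `read_rr` returns a [prediction_list()].
#' @export
write_rr <- function(predictions, path) {
  stopifnot(inherits(predictions, "prediction_list"))
  s <- predictions$score
  if (length(s) && (min(s) < 0 || max(s) > 1)) {
    stop("RR scores must lie in [0, 1]; rescale before writing")
  }
  con <- file(path, "w"); on.exit(close(con))
  writeLines(c("PFRMAT RR",
               paste("TARGET", attr(predictions, "target")),
               "MODEL 1"), con)
  if (nrow(predictions)) {
    writeLines(sprintf("%d %d 0 8 %.6f",
                       predictions$i, predictions$j, s), con)
  }
  writeLines("END", con)
  invisible(path)
}

#' @rdname write_rr
#' @export
read_rr <- function(path, target = NULL) {
  lines <- readLines(path, warn = FALSE)
  if (is.null(target)) {
    t_line <- grep("^TARGET\\s", lines, value = TRUE)
    target <- if (length(t_line)) sub("^TARGET\\s+", "", t_line[1]) else "unknown"
  }
  dat <- lines[grepl("^\\s*[0-9]", lines)]
  if (length(dat) == 0L) {
    return(prediction_list(target, integer(0), integer(0), numeric(0)))
  }
  rec <- matrix(as.numeric(unlist(strsplit(trimws(dat), "\\s+"))),
                ncol = 5L, byrow = TRUE)
  prediction_list(target, rec[, 1], rec[, 2], rec[, 5])
}
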