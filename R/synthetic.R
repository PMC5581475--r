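# Deterministic synthetic-fixture generator: toy folded structures from a
# compact self-avoiding walk, correlated-mutations score matrices with
# tunable correlation to the true contact map, and sequence-feature files
# with tunable contact-informative signal.  Everything any other module
# consumes can be produced here, so the full pipeline is testable offline.

AA20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
          "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

#' Generate a toy folded structure
#'
#' A self-avoiding random walk with fixed virtual-bond step (3.8 Angstrom,
#' the C-alpha spacing) and a hard exclusion radius, confined to a sphere of
#' radius `compactness * L^(1/3)` so the chain folds back on itself and
#' produces contacts at all separations.  Native contacts are extremely
#' sparse (around 2-3% of considered pairs), and the walk parameters are
#' frozen to land in a configurable density band; seeds whose walk misses
#' the band are retried with deterministic offsets.
#'
#' @param L Chain length (>= 10).
#' @param seed Integer seed; same `(L, seed)` gives identical coordinates.
#' @param step Virtual bond length in Angstrom (default 3.8).
#' @param exclusion Minimum distance between non-adjacent residues (default 4).
#' @param compactness Confinement radius scale (default 4.4, i.e. radius
#'   `4.4 * L^(1/3)` Angstrom).
#' @param density_band Acceptable contact density over considered pairs
#'   (separation >= 6), default `c(0.01, 0.05)`.
#' @param threshold Contact threshold passed to [contact_map()].
#' @param max_attempts Seed offsets to try before giving up.
#' @return List with `record` (a [protein_record()]) and `cmap` (its
#'   [contact_map()]).
#' @export
generate_structure <- function(L, seed = 1L, step = 3.8, exclusion = 4.0,
                               compactness = 4.4, center_bias = 0.1,
                               density_band = c(0.01, 0.05),
                               threshold = 8.0, max_attempts = 40L) {
  L <- as.integer(L)
  if (L < 10L) stop("L must be >= 10")
  radius <- compactness * L^(1 / 3)
  considered <- nrow(enumerate_pairs(L, "all"))
  for (attempt in seq_len(max_attempts)) {
    res <- with_seed(seed + (attempt - 1L) * 1000L, {
      saw_walk(L, step, exclusion, radius, center_bias)
    })
    if (is.null(res)) next
    seq_str <- with_seed(seed + (attempt - 1L) * 1000L + 7L,
                         paste(sample(AA20, L, replace = TRUE), collapse = ""))
    rec <- protein_record(sprintf("synth_L%d_s%d", L, seed), seq_str, res)
    cm <- contact_map(rec, threshold)
    dens <- sum(cm$contacts[enumerate_pairs(L, "all")]) / considered
    if (dens >= density_band[1] && dens <= density_band[2]) {
      return(list(record = rec, cmap = cm, density = dens,
                  attempts = attempt))
    }
  }
  stop("could not reach contact density in [", density_band[1], ", ",
       density_band[2], "] after ", max_attempts,
       " attempts; adjust compactness or the band")
}

# one confined self-avoiding walk; NULL if it dead-ends
saw_walk <- function(L, step, exclusion, radius, center_bias) {
  coords <- matrix(NA_real_, L, 3L)
  coords[1L, ] <- stats::runif(3, -radius / 4, radius / 4)
  for (k in 2:L) {
    placed <- FALSE
    for (try in 1:60) {
      dir <- stats::rnorm(3)
      # soft bias toward the sphere center keeps the chain compact
      dir <- dir - center_bias * coords[k - 1L, ] / radius
      dir <- dir / sqrt(sum(dir^2))
      cand <- coords[k - 1L, ] + step * dir
      if (sqrt(sum(cand^2)) > radius) next
      if (k > 2L) {
        prev <- coords[1:(k - 2L), , drop = FALSE]
        d2 <- (prev[, 1] - cand[1])^2 + (prev[, 2] - cand[2])^2 +
          (prev[, 3] - cand[3])^2
        if (min(d2) < exclusion^2) next
      }
      coords[k, ] <- cand
      placed <- TRUE
      break
    }
    if (!placed) return(NULL)
  }
  coords
}

#' Generate a synthetic correlated-mutations score matrix
#'
#' `score = rho * contact_indicator + (1 - rho) * uniform_noise`, then
#' symmetrized and min-max normalized: `rho = 1` is a perfect oracle,
#' `rho = 0` pure noise.  Signal can be restricted to chosen separation
#' classes to emulate method complementarity (correlated-mutations tools
#' are strongest at long range).
#'
#' @param cmap A [contact_map()].
#' @param rho Signal strength in `[0, 1]`.
#' @param seed Integer seed.
#' @param method_tag Label for the matrix.
#' @param signal_range Optional character vector of separation classes that
#'   carry signal; contacts outside them are treated as noise-only.
#' @return A `cm_scores` object.
#' @export
generate_cm_scores <- function(cmap, rho, seed = 1L, method_tag = "synthetic",
                               signal_range = NULL) {
  stopifnot(inherits(cmap, "contact_map"), rho >= 0, rho <= 1)
  L <- cmap$L
  ind <- cmap$contacts
  ind[is.na(ind)] <- FALSE
  mode(ind) <- "numeric"
  if (!is.null(signal_range)) {
    ij <- which(upper.tri(ind), arr.ind = TRUE)
    cls <- classify_separation(ij[, 1], ij[, 2])
    off <- ij[!(cls %in% signal_range), , drop = FALSE]
    ind[off] <- 0
    ind[off[, c(2, 1), drop = FALSE]] <- 0
  }
  noise <- with_seed(seed, matrix(stats::runif(L * L), L, L))
  noise[lower.tri(noise)] <- t(noise)[lower.tri(noise)]
  m <- rho * ind + (1 - rho) * noise
  diag(m) <- 0
  structure(list(scores = normalize_cm(m), method_tag = method_tag),
            class = "cm_scores")
}

#' Generate synthetic per-residue feature inputs
#'
#' Emulates the stage-1 feature files: a PSSM profile with residue-type
#' conditioned log-odds plus the two trailing profile columns, and SS/SA
#' strings from persistent 2-state hidden processes.  With probability
#' `informativeness` each considered contact plants a correlated
#' perturbation in its two residues: a shared log-odds bump in the profile
#' column indexed by the pair's separation (mod 20) at both endpoints, plus
#' a generic information-content lift there.  `informativeness = 0` leaves
#' pure noise.
#'
#' @param record A [protein_record()].
#' @param cmap The matching [contact_map()].
#' @param informativeness Planting probability in `[0, 1]`.
#' @param seed Integer seed.
#' @param amp Log-odds bump amplitude (default 10).
#' @param signal_range Optional separation classes whose contacts are
#'   planted; others stay noise (machine-learning sequence features are
#'   strongest at short range, the complement of correlated mutations).
#' @return List with `pssm` (a `pssm_profile`), `ss`, `sa`.
#' @export
generate_features <- function(record, cmap, informativeness = 1, seed = 1L,
                              amp = 10, signal_range = NULL) {
  stopifnot(informativeness >= 0, informativeness <= 1)
  L <- record$L
  with_seed(seed, {
    scores <- matrix(round(stats::rnorm(L * 20, -1, 1.5)), L, 20)
    colnames(scores) <- PSSM_ALPHABET
    own <- match(record$sequence, PSSM_ALPHABET)
    ok <- !is.na(own)
    scores[cbind(which(ok), own[ok])] <- scores[cbind(which(ok), own[ok])] + 3
    info <- round(stats::runif(L, 0.3, 1.5), 2)
    relw <- round(stats::runif(L, 0.2, 0.8), 2)
    ss <- markov_string(L, c("H", "E", "C"), 0.85)
    sa <- markov_string(L, c("b", "e"), 0.80)
    pairs <- enumerate_pairs(L, "all")
    is_con <- cmap$contacts[pairs]
    con <- pairs[!is.na(is_con) & is_con, , drop = FALSE]
    if (!is.null(signal_range) && nrow(con) > 0L) {
      cls <- classify_separation(con[, 1], con[, 2])
      con <- con[cls %in% signal_range, , drop = FALSE]
    }
    if (nrow(con) > 0L && informativeness > 0) {
      planted <- stats::runif(nrow(con)) < informativeness
      for (r in which(planted)) {
        i <- con[r, 1]; j <- con[r, 2]
        col <- 1L + (j - i) %% 20L
        scores[c(i, j), col] <- scores[c(i, j), col] + amp
        info[c(i, j)] <- info[c(i, j)] + 0.5
      }
    }
    pssm <- structure(list(scores = scores, info_per_pos = info,
                           rel_weight = relw, sequence = record$sequence),
                      class = "pssm_profile")
    list(pssm = pssm, ss = ss, sa = sa)
  })
}

markov_string <- function(L, states, persistence) {
  s <- integer(L)
  s[1] <- sample.int(length(states), 1L)
  for (k in 2:L) {
    s[k] <- if (stats::runif(1) < persistence) s[k - 1L] else
      sample.int(length(states), 1L)
  }
  paste(states[s], collapse = "")
}

#' Generate a complete synthetic target
#'
#' One call produces everything the two-stage pipeline needs for a target:
#' structure and contact map, `k` correlated-mutations matrices with the
#' requested signal strengths, feature files, and the assembled per-residue
#' feature table.
#'
#' @param L Chain length.
#' @param seed Integer seed (all sub-generators derive from it).
#' @param rho Named numeric vector of CM signal strengths, one matrix per
#'   entry (default `c(psicov = 0.6, ccmpred = 0.6, gremlin = 0.6)`).
#' @param informativeness Feature-signal strength for [generate_features()].
#' @param cm_signal_range Passed to [generate_cm_scores()] as
#'   `signal_range` (applies to every matrix).
#' @param feature_signal_range Passed to [generate_features()] as
#'   `signal_range`.
#' @param ... Further arguments to [generate_structure()].
#' @return A target list: `record`, `cmap`, `cm`, `pssm`, `ss`, `sa`,
#'   `feature_table`, `params`.
#' @export
generate_target <- function(L = 100L, seed = 1L,
                            rho = c(psicov = 0.6, ccmpred = 0.6, gremlin = 0.6),
                            informativeness = 0.8, cm_signal_range = NULL,
                            feature_signal_range = NULL, ...) {
  st <- generate_structure(L, seed = seed, ...)
  cm <- lapply(seq_along(rho), function(k) {
    generate_cm_scores(st$cmap, rho[[k]], seed = seed * 97L + k,
                       method_tag = names(rho)[k],
                       signal_range = cm_signal_range)
  })
  names(cm) <- names(rho)
  feats <- generate_features(st$record, st$cmap,
                             informativeness = informativeness,
                             seed = seed * 131L + 5L,
                             signal_range = feature_signal_range)
  tab <- build_feature_table(st$record, feats$pssm, feats$ss, feats$sa)
  list(record = st$record, cmap = st$cmap, cm = cm,
       pssm = feats$pssm, ss = feats$ss, sa = feats$sa,
       feature_table = tab,
       params = list(L = L, seed = seed, rho = rho,
                     informativeness = informativeness,
                     density = st$density))
}

#' Write a synthetic target's fixture files to disk
#'
#' Emits the on-disk forms every reader consumes: a PDB coordinate file, a
#' PSI-BLAST-layout PSSM, SS and SA strings, and one triplet score file per
#' correlated-mutations matrix.
#'
#' @param target A list from [generate_target()].
#' @param dir Output directory (created if needed).
#' @return Named character vector of the written paths.
#' @export
write_fixture_target <- function(target, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  id <- target$record$id
  paths <- c(pdb = file.path(dir, paste0(id, ".pdb")),
             pssm = file.path(dir, paste0(id, ".pssm")),
             ss = file.path(dir, paste0(id, ".ss")),
             sa = file.path(dir, paste0(id, ".sa")))
  write_pdb_record(target$record, paths[["pdb"]])
  write_pssm(target$pssm, paths[["pssm"]])
  writeLines(target$ss, paths[["ss"]])
  writeLines(target$sa, paths[["sa"]])
  for (nm in names(target$cm)) {
    p <- file.path(dir, paste0(id, ".", nm, ".cm"))
    m <- target$cm[[nm]]$scores
    ij <- which(upper.tri(m) & m != 0, arr.ind = TRUE)
    writeLines(sprintf("%d %d %.6f", ij[, 1], ij[, 2], m[ij]), p)
    paths[[nm]] <- p
  }
  paths
}
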