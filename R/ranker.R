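# Stage 2: per-protein pairwise ranking SVM fusing the stage-1 scores.
# Each target protein is a query group; its residue pairs are the documents.
# The feature vector Phi(t, d) holds the k normalized correlated-mutations
# scores plus the RF ensemble score of pair d; relevance is derived from the
# true inter-residue distance (smaller distance = higher relevance).  The
# model is a linear scoring function w . Phi trained on within-group
# difference vectors under the soft-margin objective
# 0.5*||w||^2 + C * sum(hinge).

DEFAULT_RELEVANCE_BINS <- c(8, 12, 16, 20)

#' Build ranking examples for one query group
#'
#' Distances are binned into ordinal relevance levels (default edges 8, 12,
#' 16, 20 Angstrom: the closest bin, below the contact threshold, gets the
#' highest relevance).  Binning preserves "smaller distance, higher rank"
#' while keeping the pairwise-constraint count tractable.  At most
#' `pair_cap` pairs per group are kept, sampled deterministically per seed.
#'
#' @param qid Query-group identifier (target id + range class).
#' @param phi `n x k` matrix of stage-1 features, all in `[0, 1]`.
#' @param distances Length-`n` true distances in Angstrom (`NA` rows are
#'   dropped).
#' @param pairs Optional `n x 2` matrix of residue indices carried along.
#' @param bins Increasing relevance-bin edges in Angstrom.
#' @param pair_cap Maximum examples kept per group (default 2000).
#' @param seed Seed for the cap subsample.
#' @return Object of class `rank_group`: list with `qid`, `phi`,
#'   `relevance` (integer, larger = closer), `pairs`.
#' @export
build_rank_examples <- function(qid, phi, distances, pairs = NULL,
                                bins = DEFAULT_RELEVANCE_BINS,
                                pair_cap = 2000L, seed = 1L) {
  phi <- as.matrix(phi)
  if (nrow(phi) != length(distances)) stop("phi rows and distances differ")
  if (is.unsorted(bins, strictly = TRUE)) stop("bins must be strictly increasing")
  keep <- which(!is.na(distances))
  if (length(keep) == 0L) {
    warning("query group '", qid, "' has no pairs with defined distance")
  }
  if (length(keep) > pair_cap) {
    keep <- sort(with_seed(seed, sample(keep, pair_cap, replace = FALSE)))
  }
  phi <- phi[keep, , drop = FALSE]
  if (any(!is.finite(phi))) stop("non-finite stage-1 features in group '", qid, "'")
  d <- distances[keep]
  lev <- findInterval(d, bins, left.open = FALSE)  # 0 = closest bin
  relevance <- as.integer(length(bins) + 1L - lev)  # larger = closer
  structure(list(qid = qid, phi = phi, relevance = relevance,
                 pairs = if (is.null(pairs)) NULL else pairs[keep, , drop = FALSE]),
            class = "rank_group")
}

#' Within-group difference vectors
#'
#' For every ordered pair of examples in one query group whose relevance
#' levels differ strictly, emits `phi(more relevant) - phi(less relevant)`.
#' Constraints never cross query groups.  The row count is the sum over
#' relevance-level pairs of `n_a * n_b`.
#'
#' @param group A `rank_group` (or list of them, concatenated).
#' @param diff_cap Optional maximum number of difference vectors per group
#'   (training-size bound; default unlimited).  When the cap binds, the
#'   budget is split evenly over the relevance-level pairs before sampling
#'   with `seed`: contacts are a few percent of pairs, so proportional
#'   sampling would drown the contact-versus-rest constraints under
#'   far-versus-farther ones.
#' @param seed Seed for the cap subsample.
#' @return Matrix of difference vectors (possibly 0 rows).
#' @export
pairwise_differences <- function(group, diff_cap = Inf, seed = 1L) {
  if (!inherits(group, "rank_group")) {
    stopifnot(is.list(group), all(vapply(group, inherits, TRUE, "rank_group")))
    out <- lapply(group, pairwise_differences, diff_cap = diff_cap, seed = seed)
    return(do.call(rbind, out))
  }
  rel <- group$relevance
  levels_present <- sort(unique(rel), decreasing = TRUE)
  hi_idx <- list(); lo_idx <- list()
  for (a in seq_along(levels_present)) {
    for (b in seq_along(levels_present)) {
      if (b <= a) next
      ia <- which(rel == levels_present[a])
      ib <- which(rel == levels_present[b])
      hi_idx[[length(hi_idx) + 1L]] <- rep(ia, times = length(ib))
      lo_idx[[length(lo_idx) + 1L]] <- rep(ib, each = length(ia))
    }
  }
  if (length(hi_idx) == 0L) {
    return(matrix(numeric(0), ncol = ncol(group$phi)))
  }
  sizes <- lengths(hi_idx)
  if (is.finite(diff_cap) && sum(sizes) > diff_cap) {
    share <- even_shares(sizes, diff_cap)
    sel <- with_seed(seed, lapply(seq_along(sizes), function(k) {
      if (share[k] >= sizes[k]) seq_len(sizes[k])
      else sample(sizes[k], share[k], replace = FALSE)
    }))
    hi <- unlist(lapply(seq_along(sel), function(k) hi_idx[[k]][sel[[k]]]))
    lo <- unlist(lapply(seq_along(sel), function(k) lo_idx[[k]][sel[[k]]]))
  } else {
    hi <- unlist(hi_idx); lo <- unlist(lo_idx)
  }
  group$phi[hi, , drop = FALSE] - group$phi[lo, , drop = FALSE]
}

# water-fill a budget over strata as evenly as their sizes allow
even_shares <- function(sizes, budget) {
  share <- integer(length(sizes))
  left <- as.integer(budget)
  idx <- order(sizes)
  n_left <- length(sizes)
  for (s in idx) {
    share[s] <- min(sizes[s], left %/% n_left)
    left <- left - share[s]
    n_left <- n_left - 1L
  }
  if (left > 0L) {
    for (s in rev(idx)) {
      add <- min(left, sizes[s] - share[s])
      share[s] <- share[s] + add
      left <- left - add
      if (left == 0L) break
    }
  }
  share
}

#' Hinge-loss ranking objective
#'
#' `0.5 * ||w||^2 + C * sum_i max(0, 1 - w . delta_i)` over difference
#' vectors; the slack variables of the constrained form are exactly the
#' hinge terms.
#'
#' @param w Weight vector.
#' @param differences Matrix of difference vectors.
#' @param C Soft-margin trade-off.
#' @return Objective value.
#' @export
rank_svm_objective <- function(w, differences, C) {
  margins <- 1 - as.numeric(differences %*% w)
  0.5 * sum(w^2) + C * sum(pmax(0, margins))
}

#' Train the linear ranking SVM
#'
#' Minimizes `0.5*||w||^2 + C*sum(hinge)` over the difference vectors by
#' dual coordinate descent (linear kernel only).  Convergence is declared
#' when the largest projected dual gradient falls below `tol`; failure to
#' converge within `max_iter` sweeps is an error carrying the final
#' violation and objective.
#'
#' @param differences Matrix of within-group difference vectors.
#' @param C Soft-margin trade-off (> 0).
#' @param tol Projected-gradient tolerance (default 1e-8).  The stopping
#'   test uses `tol * max(1, C)`: dual gradients scale with C, so an
#'   absolute threshold would demand disproportionate precision at large C.
#' @param max_iter Maximum coordinate-descent sweeps (default 20000).
#' @param feature_names Optional feature names stored for later checks.
#' @return Object of class `rank_model`: `w`, `C`, `iterations`,
#'   `objective`, `feature_names`.
#' @export
train_rank_svm <- function(differences, C = 1, tol = 1e-8, max_iter = 20000L,
                           feature_names = colnames(differences)) {
  differences <- as.matrix(differences)
  if (nrow(differences) < 1L) stop("need at least one difference vector")
  if (!is.numeric(C) || C <= 0) stop("C must be > 0")
  fit <- cpp_rank_svm(differences, C, tol * max(1, C), as.integer(max_iter))
  if (!fit$converged) {
    stop(sprintf(paste0("ranking SVM did not converge in %d sweeps ",
                        "(max violation %.3e, objective %.6f)"),
                 max_iter, fit$max_violation, fit$objective))
  }
  structure(list(w = as.numeric(fit$w), C = C, iterations = fit$iterations,
                 objective = fit$objective, feature_names = feature_names),
            class = "rank_model")
}

#' @export
print.rank_model <- function(x, ...) {
  cat(sprintf("<rank_model> %d features, C=%g, objective=%.6g (%d sweeps)\n",
              length(x$w), x$C, x$objective, x$iterations))
  if (!is.null(x$feature_names)) {
    cat("  w:", paste(sprintf("%s=%.3f", x$feature_names, x$w), collapse = ", "),
        "\n")
  }
  invisible(x)
}

#' Score feature vectors with a trained ranking model
#'
#' The linear form `w . phi`; larger means more likely in contact.
#'
#' @param model A `rank_model`.
#' @param phi Feature matrix (or single vector).
#' @return Numeric scores.
#' @export
rank_score <- function(model, phi) {
  stopifnot(inherits(model, "rank_model"))
  if (is.null(dim(phi))) phi <- matrix(phi, nrow = 1L)
  phi <- as.matrix(phi)
  if (ncol(phi) != length(model$w)) {
    stop("feature-dimension mismatch: model has ", length(model$w),
         " weights, phi has ", ncol(phi), " columns")
  }
  as.numeric(phi %*% model$w)
}

#' Choose C by grouped cross-validation
#'
#' Splits query groups (never individual pairs) into folds, trains on each
#' training split over a logarithmic C grid, and scores held-out groups by
#' the fraction of correctly ordered difference vectors.  Ties prefer the
#' smaller C.
#'
#' @param groups List of `rank_group`s.
#' @param C_grid Candidate values (default `10^(-2:2)`).
#' @param nfolds Number of folds (default 5, capped at the group count).
#' @param diff_cap Per-group difference cap passed through.
#' @param seed Seed for fold assignment.
#' @return List with `C` (chosen), `accuracy` (per grid point), `folds`.
#' @export
cv_select_C <- function(groups, C_grid = 10^(-2:2), nfolds = 5L,
                        diff_cap = 20000L, seed = 1L) {
  stopifnot(length(groups) >= 2L)
  nfolds <- min(nfolds, length(groups))
  fold <- with_seed(seed, sample(rep_len(seq_len(nfolds), length(groups))))
  diffs <- lapply(seq_along(groups), function(g) {
    pairwise_differences(groups[[g]], diff_cap = diff_cap, seed = seed + g)
  })
  acc <- sapply(C_grid, function(C) {
    fold_acc <- vapply(seq_len(nfolds), function(f) {
      tr <- do.call(rbind, diffs[fold != f])
      te <- do.call(rbind, diffs[fold == f])
      if (is.null(tr) || nrow(tr) == 0L || is.null(te) || nrow(te) == 0L) {
        return(NA_real_)
      }
      m <- train_rank_svm(tr, C = C, tol = 1e-3, max_iter = 30000L)
      mean(te %*% m$w > 0)
    }, numeric(1))
    mean(fold_acc, na.rm = TRUE)
  })
  list(C = C_grid[which.max(acc)], accuracy = stats::setNames(acc, C_grid),
       folds = fold)
}

#' Assemble stage-1 fusion features for a target
#'
#' Builds `Phi(t, d)` for every residue pair of one separation class:
#' the k per-protein min-max-normalized correlated-mutations scores and the
#' RF ensemble probability, each in `[0, 1]`.
#'
#' @param target List with components `record` (a [protein_record()]),
#'   `cm` (named list of `cm_scores` or plain `L x L` matrices), and either
#'   `feature_table` or (`pssm`, `ss`, `sa`).
#' @param rf_model An `rf_ensemble` for this separation class (or `NULL` to
#'   omit the RF column).
#' @param range_class `"short"`, `"medium"`, or `"long"`.
#' @param window Window size used at RF training time.
#' @param cm_names Required correlated-mutations inputs, in column order;
#'   default the names of `target$cm`.
#' @param allow_missing If `TRUE`, a missing CM input contributes a zero
#'   column with a warning instead of an error.
#' @return List with `pairs` (`n x 2`), `phi` (`n x k+1`), `qid`.
#' @export
stage1_features <- function(target, rf_model, range_class, window = 9L,
                            cm_names = NULL, allow_missing = FALSE) {
  record <- target$record
  L <- record$L
  pairs <- enumerate_pairs(L, range_class)
  if (is.null(cm_names)) cm_names <- names(target$cm)
  cols <- list()
  for (nm in cm_names) {
    cm <- target$cm[[nm]]
    if (is.null(cm)) {
      if (!allow_missing) {
        stop("missing correlated-mutations input '", nm, "' for target '",
             record$id, "'")
      }
      warning("missing CM input '", nm, "': feature column set to 0")
      cols[[nm]] <- numeric(nrow(pairs))
    } else {
      m <- if (inherits(cm, "cm_scores")) cm$scores else cm
      cols[[nm]] <- m[pairs]
    }
  }
  if (!is.null(rf_model)) {
    tab <- target$feature_table
    if (is.null(tab)) {
      tab <- build_feature_table(record, target$pssm, target$ss, target$sa)
    }
    X <- build_pair_matrix(tab, pairs, window = window)
    cols[["rf"]] <- rf_score(rf_model, X)
  }
  phi <- do.call(cbind, cols)
  colnames(phi) <- names(cols)
  list(pairs = pairs, phi = phi, qid = paste(record$id, range_class, sep = "/"))
}

#' Predict contacts for one target with the fused two-stage model
#'
#' Computes the stage-1 features, applies the ranking model, and returns the
#' residue pairs of the requested separation class sorted by descending
#' fused score.  For RR output the per-protein scores are min-max mapped to
#' `[0, 1]` (a constant score vector maps to 0.5).
#'
#' @inheritParams stage1_features
#' @param rank_model A `rank_model` whose features match the stage-1 layout.
#' @param normalize Map scores to `[0, 1]` per protein (default `TRUE`).
#' @return A [prediction_list()].
#' @export
predict_contacts <- function(target, rf_model, rank_model, range_class,
                             window = 9L, cm_names = NULL,
                             allow_missing = FALSE, normalize = TRUE) {
  s1 <- stage1_features(target, rf_model, range_class, window = window,
                        cm_names = cm_names, allow_missing = allow_missing)
  if (!is.null(rank_model$feature_names) && !is.null(colnames(s1$phi)) &&
      !identical(colnames(s1$phi), rank_model$feature_names)) {
    stop("stage-1 feature layout (", paste(colnames(s1$phi), collapse = ","),
         ") does not match rank model (",
         paste(rank_model$feature_names, collapse = ","), ")")
  }
  sc <- rank_score(rank_model, s1$phi)
  if (normalize) {
    rng <- range(sc)
    sc <- if (diff(rng) == 0) rep(0.5, length(sc)) else (sc - rng[1]) / diff(rng)
  }
  prediction_list(target$record$id, s1$pairs[, 1], s1$pairs[, 2], sc,
                  range_class = range_class)
}
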