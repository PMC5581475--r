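# Stage 1: under-sampled random-forest ensemble contact scorer.
# Contacts are ~2-3% of considered pairs in native structures, so the
# non-contact class is under-sampled to a fixed 4:1 ratio; three forests
# per separation class are trained on repeated under-samples and their
# probabilities averaged to counteract the information loss.

#' Evaluate an expression under a temporary RNG seed
#'
#' Restores the caller's RNG state afterwards, so seeded sampling inside the
#' package never perturbs user code.
#'
#' @param seed Integer seed.
#' @param code Expression to evaluate.
#' @return Value of `code`.
#' @export
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, globalenv())
    else suppressWarnings(rm(".Random.seed", envir = globalenv()))
  })
  set.seed(as.integer(seed))
  force(code)
}

#' Under-sample non-contacts to a fixed ratio against contacts
#'
#' Keeps every contact and draws `min(ratio * n_contact, n_noncontact)`
#' non-contacts uniformly without replacement; deterministic per seed.
#'
#' @param labels Logical/0-1 vector (`TRUE` = contact).
#' @param ratio Non-contact : contact ratio (default 4).
#' @param seed Integer seed for the draw.
#' @param exclude Optional indices that may not be drawn (used to keep
#'   ensemble members' negative sets disjoint).
#' @return Sorted integer indices into `labels` of the retained samples.
#' @export
undersample <- function(labels, ratio = 4L, seed = 1L, exclude = integer(0)) {
  labels <- as.logical(labels)
  if (anyNA(labels)) stop("labels must not contain NA")
  ratio <- as.integer(ratio)
  if (ratio < 1L) stop("ratio must be >= 1")
  pos <- which(labels)
  if (length(pos) == 0L) stop("no contacts in the pool: nothing to balance against")
  neg <- setdiff(which(!labels), exclude)
  n_draw <- min(ratio * length(pos), length(neg))
  drawn <- if (n_draw == length(neg)) neg else {
    with_seed(seed, sample(neg, n_draw, replace = FALSE))
  }
  sort(c(pos, drawn))
}

#' Train an ensemble of under-sampled random forests
#'
#' For one separation class: the training pool is put in a canonical order
#' (by the supplied keys, so results do not depend on input file order),
#' under-sampled `n_members` times at the given ratio — negative draws are
#' disjoint across members when availability permits, the positives are
#' shared — and one random forest is grown per subset.
#'
#' @param X Numeric feature matrix (rows = pair instances).
#' @param y Logical/0-1 contact labels.
#' @param range_class Separation class label stored with the model.
#' @param n_members Number of under-samples / forests (default 3).
#' @param ratio Non-contact:contact under-sampling ratio (default 4).
#' @param n_trees Trees per forest (default 500).
#' @param mtry Features tried per split (default `2 * floor(sqrt(ncol(X)))`:
#'   windowed profile features carry few informative columns, and a wider
#'   draw finds them with far fewer trees).
#' @param min_node Minimum node size before a split is attempted (default 5).
#' @param max_depth Maximum tree depth, 0 = unlimited.
#' @param seed Base seed; member `m` uses `seed + m`.
#' @param keys Optional data frame (e.g. target, i, j) defining the
#'   canonical pool order; default keeps the given order.
#' @return Object of class `rf_ensemble`.
#' @export
train_rf_ensemble <- function(X, y, range_class = "all", n_members = 3L,
                              ratio = 4L, n_trees = 500L, mtry = NULL,
                              min_node = 5L, max_depth = 0L, seed = 1L,
                              keys = NULL) {
  X <- as.matrix(X)
  y <- as.logical(y)
  if (nrow(X) != length(y)) stop("X and y sizes differ")
  if (all(y) || !any(y)) stop("training pool must contain both classes")
  if (!is.null(keys)) {
    ord <- do.call(order, as.list(as.data.frame(keys)))
    X <- X[ord, , drop = FALSE]
    y <- y[ord]
  }
  if (is.null(mtry)) mtry <- min(ncol(X), max(1L, 2L * floor(sqrt(ncol(X)))))
  members <- vector("list", n_members)
  subset_sizes <- integer(n_members)
  used_neg <- integer(0)
  for (m in seq_len(n_members)) {
    idx <- undersample(y, ratio = ratio, seed = seed + m, exclude = used_neg)
    used_neg <- c(used_neg, setdiff(idx, which(y)))
    subset_sizes[m] <- length(idx)
    members[[m]] <- cpp_grow_forest(X[idx, , drop = FALSE], as.integer(y[idx]),
                                    as.integer(n_trees), as.integer(mtry),
                                    as.integer(min_node), as.integer(max_depth),
                                    as.numeric(seed) * 1000 + m)
  }
  structure(list(members = members, range_class = range_class,
                 n_features = ncol(X), feature_names = colnames(X),
                 meta = list(n_members = n_members, ratio = ratio,
                             n_trees = n_trees, mtry = mtry,
                             min_node = min_node, max_depth = max_depth,
                             seed = seed, subset_sizes = subset_sizes)),
            class = "rf_ensemble")
}

#' @export
print.rf_ensemble <- function(x, ...) {
  cat(sprintf("<rf_ensemble> %s: %d members x %d trees, %d features\n",
              x$range_class, x$meta$n_members, x$meta$n_trees, x$n_features))
  invisible(x)
}

#' Ensemble contact probability
#'
#' Arithmetic mean of the member forests' class probabilities; always in
#' `[0, 1]`.
#'
#' @param model An `rf_ensemble`.
#' @param X Feature matrix with `model$n_features` columns (a single vector
#'   is treated as one row).
#' @return Numeric vector of per-row scores.
#' @export
rf_score <- function(model, X) {
  stopifnot(inherits(model, "rf_ensemble"))
  if (is.null(dim(X))) X <- matrix(X, nrow = 1L)
  X <- as.matrix(X)
  if (ncol(X) != model$n_features) {
    stop("feature-dimension mismatch: model expects ", model$n_features,
         " features, got ", ncol(X))
  }
  preds <- vapply(model$members, function(f) cpp_predict_forest(f, X),
                  numeric(nrow(X)))
  if (is.null(dim(preds))) preds <- matrix(preds, nrow = nrow(X))
  rowMeans(preds)
}
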