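# CASP-style assessment: precision of the Top 5, L/10 and L/5 highest-scored
# pairs, stratified by separation class, macro-averaged over targets.

#' Number of scored pairs for a list-length metric
#'
#' `top5` is the constant 5; `L10` and `L5` are `floor(L/10)` and
#' `floor(L/5)` (rounding mode configurable), clamped to at least 1.
#'
#' @param L Target (domain) sequence length.
#' @param metric One of `"top5"`, `"L10"`, `"L5"`.
#' @param rounding `"floor"` (default), `"ceiling"`, or `"round"`.
#' @return Positive integer k.
#' @export
k_from_L <- function(L, metric = c("top5", "L10", "L5"),
                     rounding = c("floor", "ceiling", "round")) {
  metric <- match.arg(metric)
  rounding <- match.arg(rounding)
  L <- as.integer(L)
  if (L < 1L) stop("L must be >= 1")
  if (metric == "top5") return(5L)
  div <- if (metric == "L10") 10 else 5
  f <- switch(rounding, floor = floor, ceiling = ceiling, round = round)
  max(1L, as.integer(f(L / div)))
}

#' Precision of the top-k predicted pairs
#'
#' `precision = 100 * TP / (TP + FP)` over the `k` highest-scored predicted
#' pairs of one separation class (ties already resolved by the prediction
#' list's deterministic order).  If fewer than `k` predictions exist the
#' denominator is the number taken.  Pairs with undefined contact status are
#' skipped with a warning; if no scored pair has a defined label the cell is
#' undefined (`NA`).
#'
#' @param predictions A [prediction_list()].
#' @param cmap A [contact_map()] providing the true labels.
#' @param range_class Separation class the predictions must belong to; pairs
#'   outside it are dropped before taking the top k.
#' @param k Number of top pairs to score.
#' @return Precision in percent, or `NA` if undefined.
#' @export
precision_at_k <- function(predictions, cmap, range_class, k) {
  stopifnot(inherits(predictions, "prediction_list"), inherits(cmap, "contact_map"))
  if (k < 1L) stop("k must be >= 1")
  if (nrow(predictions) == 0L) return(NA_real_)
  cls <- classify_separation(predictions$i, predictions$j)
  pl <- predictions[cls == range_class, , drop = FALSE]
  if (nrow(pl) == 0L) return(NA_real_)
  top <- utils::head(pl, k)
  lab <- cmap$contacts[cbind(top$i, top$j)]
  if (anyNA(lab)) {
    warning("top-", k, " list contains pairs with undefined contact status; ",
            "they are excluded from the denominator")
    lab <- lab[!is.na(lab)]
  }
  if (length(lab) == 0L) return(NA_real_)
  100 * sum(lab) / length(lab)
}

EVAL_METRICS <- c("top5", "L10", "L5")

#' Evaluate one target across ranges and metrics
#'
#' @param pred_by_range Named list of [prediction_list()]s, one per range
#'   class present.
#' @param cmap The target's [contact_map()].
#' @param L Domain length used for L/10 and L/5 (default `cmap$L`).
#' @param rounding Rounding mode for [k_from_L()].
#' @return Data frame with columns `range`, `metric`, `k`, `precision`.
#' @export
evaluate_target <- function(pred_by_range, cmap, L = cmap$L,
                            rounding = "floor") {
  rows <- list()
  for (rc in names(pred_by_range)) {
    for (m in EVAL_METRICS) {
      k <- k_from_L(L, m, rounding)
      rows[[length(rows) + 1L]] <- data.frame(
        range = rc, metric = m, k = k,
        precision = precision_at_k(pred_by_range[[rc]], cmap, rc, k))
    }
  }
  do.call(rbind, rows)
}

#' Aggregate per-target evaluations into a report
#'
#' Macro-averages: the aggregate value of each (range, metric) cell is the
#' arithmetic mean of the per-target precisions (undefined cells excluded);
#' pairs are never pooled across targets.  Only targets with domain length
#' > `min_length` (default 50, the usual assessment cutoff) enter.
#'
#' @param per_target Named list of data frames from [evaluate_target()].
#' @param lengths Named integer vector of domain lengths, same names.
#' @param min_length Minimum domain length for inclusion (default 50).
#' @return Object of class `evaluation_report`: list with `per_target`
#'   (long data frame with a `target` column) and `aggregate`.
#' @export
evaluation_report <- function(per_target, lengths, min_length = 50L) {
  stopifnot(length(per_target) > 0L, all(names(per_target) %in% names(lengths)))
  keep <- names(per_target)[lengths[names(per_target)] > min_length]
  if (length(keep) == 0L) stop("no targets with length > ", min_length)
  long <- do.call(rbind, lapply(keep, function(t) {
    cbind(target = t, per_target[[t]])
  }))
  agg <- stats::aggregate(precision ~ range + metric, data = long,
                          FUN = mean, na.rm = TRUE, na.action = NULL)
  structure(list(per_target = long, aggregate = agg, n_targets = length(keep)),
            class = "evaluation_report")
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat(sprintf("<evaluation_report> %d targets (macro-averaged precision, %%)\n",
              x$n_targets))
  wide <- stats::reshape(x$aggregate, idvar = "range", timevar = "metric",
                         direction = "wide")
  names(wide) <- sub("^precision\\.", "", names(wide))
  print(wide, row.names = FALSE, digits = 4)
  invisible(x)
}

#' Paired Student's t-test on per-target precisions
#'
#' Two-sided paired t-test on matched per-target precision vectors (the L/5
#' metric by convention).  If every per-target difference is zero the
#' comparison carries no evidence and `p = 1` is returned; zero variance
#' with a non-zero mean difference degenerates to `p = 0` with a warning.
#'
#' @param precisions_a,precisions_b Per-target precision vectors, matched by
#'   position (or by names when both are named).
#' @return List with `t`, `df`, `p_value`, `mean_difference`.
#' @export
paired_t_test <- function(precisions_a, precisions_b) {
  if (!is.null(names(precisions_a)) && !is.null(names(precisions_b))) {
    common <- intersect(names(precisions_a), names(precisions_b))
    if (length(common) == 0L) stop("no overlapping targets")
    precisions_a <- precisions_a[common]
    precisions_b <- precisions_b[common]
  }
  if (length(precisions_a) != length(precisions_b)) {
    stop("precision vectors must cover the same targets")
  }
  ok <- !is.na(precisions_a) & !is.na(precisions_b)
  d <- precisions_a[ok] - precisions_b[ok]
  n <- length(d)
  if (n < 2L) stop("need at least 2 paired targets")
  if (stats::sd(d) == 0) {
    if (all(d == 0)) {
      return(list(t = 0, df = n - 1L, p_value = 1, mean_difference = 0))
    }
    warning("zero variance with non-zero mean difference: degenerate t-test")
    return(list(t = sign(mean(d)) * Inf, df = n - 1L, p_value = 0,
                mean_difference = mean(d)))
  }
  tt <- stats::t.test(precisions_a[ok], precisions_b[ok], paired = TRUE)
  list(t = unname(tt$statistic), df = unname(tt$parameter),
       p_value = tt$p.value, mean_difference = mean(d))
}

#' Per-target scatter comparison of two methods
#'
#' The data behind an x = y scatter plot: one (x, y) point per shared
#' target, plus counts above, below and on the diagonal.
#'
#' @param precisions_a,precisions_b Named per-target precision vectors
#'   (method A on x, method B on y).
#' @return List with `points` (data frame `target`, `x`, `y`) and `counts`
#'   (`above`, `below`, `on`): above means B beats A.
#' @export
scatter_report <- function(precisions_a, precisions_b) {
  common <- intersect(names(precisions_a), names(precisions_b))
  if (length(common) == 0L) stop("methods share no targets")
  x <- unname(precisions_a[common]); y <- unname(precisions_b[common])
  list(points = data.frame(target = common, x = x, y = y),
       counts = c(above = sum(y > x, na.rm = TRUE),
                  below = sum(y < x, na.rm = TRUE),
                  on = sum(y == x, na.rm = TRUE)))
}
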