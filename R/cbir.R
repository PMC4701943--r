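#' Min-max normalize feature columns
#'
#' Per feature, over its non-missing values: `(f - min) / (max - min)`.
#' A constant feature maps to all zeros (declared convention); missing
#' values stay missing. This is the normalization stage applied before any
#' query score, and is what keeps every score in `[0, 1]`.
#'
#' @param table a spine feature table.
#' @param features character vector of feature columns; defaults to all of
#'   [feature_names()].
#' @return The table with the selected columns rescaled.
#' @export
normalize_features <- function(table, features = feature_names(table)) {
  miss <- setdiff(features, names(table))
  if (length(miss)) {
    abort(sprintf("unknown feature(s): %s", paste(miss, collapse = ", ")))
  }
  for (f in features) {
    v <- table[[f]]
    if (all(is.na(v))) abort(sprintf("feature '%s' is entirely missing.", f))
    rng <- range(v, na.rm = TRUE)
    table[[f]] <- if (rng[1] == rng[2]) {
      ifelse(is.na(v), NA_real_, 0)
    } else {
      (v - rng[1]) / (rng[2] - rng[1])
    }
  }
  table
}

.check_weights <- function(weights, table) {
  if (length(weights) == 0 || is.null(names(weights)) ||
      any(!nzchar(names(weights)))) {
    abort("`weights` must be a named numeric vector, one entry per selected feature.")
  }
  if (any(!is.finite(weights)) || any(abs(weights) > 1)) {
    abort("weights must lie in [-1, 1].")
  }
  if (all(weights == 0)) abort("at least one weight must be nonzero.")
  miss <- setdiff(names(weights), feature_names(table))
  if (length(miss)) {
    abort(sprintf("weight(s) name unknown feature(s): %s",
                  paste(miss, collapse = ", ")))
  }
  weights[weights != 0]
}

.new_scores <- function(ids, raw, score, mode, weights, query_ids,
                        unscored) {
  ord <- order(-score, ids)
  out <- tibble(id = ids, raw = raw, score = score)[ord, ]
  out$rank <- seq_len(nrow(out))
  structure(out,
            class = c("spine_scores", class(out)),
            mode = mode, weights = weights, query_ids = query_ids,
            unscored = unscored)
}

#' Cell-distribution query: rank spines by their own feature values
#'
#' The raw score of a spine is the weighted sum of its min-max normalized
#' selected features; the reported score is its rank percentile,
#' `(rank - 1) / (N - 1)` with average ranks on ties (defined as 1 when a
#' single spine is scored), so with one positive-weight feature the spine
#' with the largest value scores exactly 1. Raw weighted values are kept in
#' the `raw` column for transparency. Spines missing any selected feature
#' are left unscored.
#'
#' @param table a spine feature table.
#' @param weights named numeric vector, feature name -> weight in
#'   `[-1, 1]`; positive weights seek large values, negative small.
#' @return A `spine_scores` tibble (`id`, `raw`, `score`, `rank`, in rank
#'   order) carrying the query as attributes. Unscored ids are available
#'   via [unscored_ids()].
#' @examples
#' tab <- generate_feature_dataset(n_spines = 50, seed = 1, peaks = FALSE)
#' cell_distribution_query(tab, c(Volume = 1))
#' @export
cell_distribution_query <- function(table, weights) {
  weights <- .check_weights(weights, table)
  feats <- names(weights)
  norm <- normalize_features(table, feats)
  fmat <- as.matrix(norm[feats])
  complete <- stats::complete.cases(fmat)
  if (!any(complete)) abort("no spine has all selected features present.")
  raw <- as.numeric(fmat[complete, , drop = FALSE] %*% weights)
  n <- length(raw)
  score <- if (n == 1) 1 else (rank(raw, ties.method = "average") - 1) / (n - 1)
  .new_scores(table$id[complete], raw, score,
              mode = "cell_distribution", weights = weights, query_ids = NULL,
              unscored = table$id[!complete])
}

#' Signature of a query set
#'
#' Per-feature mean of the min-max normalized values over the query
#' spines; for a singleton query this is that spine's normalized feature
#' vector. Invariant under permutation of `query_ids`.
#'
#' @inheritParams cell_distribution_query
#' @param query_ids ids of the query spines (at least one).
#' @param features feature columns to include.
#' @return Named numeric vector in `[0, 1]`.
#' @export
spine_signature <- function(table, query_ids,
                            features = feature_names(table)) {
  missing_ids <- setdiff(query_ids, table$id)
  if (length(query_ids) == 0 || length(missing_ids)) {
    abort(sprintf("query id(s) absent from the table: %s",
                  paste(utils::head(missing_ids, 5), collapse = ", ")))
  }
  norm <- normalize_features(table, features)
  q <- as.matrix(norm[match(unique(query_ids), table$id), features,
                      drop = FALSE])
  if (anyNA(q)) {
    abort("a query spine is missing one of the selected features.")
  }
  colMeans(q)
}

#' Spine-comparison query: rank spines by similarity to a query set
#'
#' Per selected feature, similarity to the query signature is
#' `1 - |fhat - c|` in normalized feature space. Positive weights reward
#' similarity, negative weights reward dissimilarity (the contribution
#' flips to `|fhat - c|`), and contributions are averaged with weights
#' `|w| / sum(|w|)`, so every score lands in `[0, 1]` and a singleton query
#' spine scores exactly 1 against itself under all-positive weights.
#'
#' @inheritParams cell_distribution_query
#' @inheritParams spine_signature
#' @return A `spine_scores` tibble; see [cell_distribution_query()].
#' @examples
#' tab <- generate_feature_dataset(n_spines = 50, seed = 1, peaks = FALSE)
#' spine_comparison_query(tab, c(Volume = 1, Length = -0.5), tab$id[1])
#' @export
spine_comparison_query <- function(table, weights, query_ids) {
  weights <- .check_weights(weights, table)
  feats <- names(weights)
  sig <- spine_signature(table, query_ids, feats)
  norm <- normalize_features(table, feats)
  fmat <- as.matrix(norm[feats])
  complete <- stats::complete.cases(fmat)
  if (!any(complete)) abort("no spine has all selected features present.")
  fm <- fmat[complete, , drop = FALSE]
  sim <- 1 - abs(sweep(fm, 2, sig))
  contrib <- sweep(sim, 2, weights > 0, function(s, pos) ifelse(pos, s, 1 - s))
  score <- as.numeric(contrib %*% abs(weights)) / sum(abs(weights))
  .new_scores(table$id[complete], score, score,
              mode = "spine_comparison", weights = weights,
              query_ids = query_ids, unscored = table$id[!complete])
}

#' Run a query described by a query spec
#'
#' Dispatcher over the two query modes, convenient for config- or
#' CLI-driven use.
#'
#' @inheritParams cell_distribution_query
#' @param mode `"cell_distribution"` or `"spine_comparison"`.
#' @param query_ids required for `spine_comparison`.
#' @return A `spine_scores` object.
#' @export
spine_query <- function(table, mode = c("cell_distribution", "spine_comparison"),
                        weights, query_ids = NULL) {
  mode <- match.arg(mode)
  if (mode == "cell_distribution") {
    cell_distribution_query(table, weights)
  } else {
    if (is.null(query_ids) || length(query_ids) == 0) {
      abort("spine_comparison needs at least one query id.")
    }
    spine_comparison_query(table, weights, query_ids)
  }
}

#' Histogram of similarity scores over the unit interval
#'
#' Equal-width bins, left-closed with a right-closed last bin; counts sum
#' to the number of scored spines.
#'
#' @param scores a `spine_scores` object or numeric vector in `[0, 1]`.
#' @param n_bins number of bins.
#' @return Tibble with `bin`, `lo`, `hi`, `count`.
#' @export
score_histogram <- function(scores, n_bins = 50) {
  s <- if (inherits(scores, "spine_scores")) scores$score else scores
  if (length(s) < 1) abort("at least one score is required.")
  idx <- pmin(floor(s * n_bins) + 1L, n_bins)
  counts <- tabulate(idx, nbins = n_bins)
  tibble(bin = seq_len(n_bins),
         lo = (seq_len(n_bins) - 1) / n_bins,
         hi = seq_len(n_bins) / n_bins,
         count = counts)
}

#' Filter spine ids by score range
#'
#' The double-slider filter: keeps scored spines with
#' `lo <= score <= hi`; `complement = TRUE` returns exactly the other
#' scored spines, so range and complement always partition the scored set.
#'
#' @param scores a `spine_scores` object.
#' @param lo,hi score bounds, `0 <= lo <= hi <= 1`.
#' @param complement return the complementary set instead.
#' @return Character vector of spine ids.
#' @export
range_filter <- function(scores, lo = 0, hi = 1, complement = FALSE) {
  stopifnot(inherits(scores, "spine_scores"))
  if (!(is.finite(lo) && is.finite(hi) && lo >= 0 && lo <= hi && hi <= 1)) {
    abort("need 0 <= lo <= hi <= 1.")
  }
  inside <- scores$score >= lo & scores$score <= hi
  if (complement) scores$id[!inside] else scores$id[inside]
}

#' Rescale scores to stretch a sub-range of the colormap
#'
#' Dynamic-range reduction for display: linear remap of `[lo, hi]` onto
#' `[0, 1]`, clipping values outside. Operating on a `spine_scores` object
#' adds a `display_score` column and leaves the scores themselves intact.
#'
#' @param scores a `spine_scores` object or numeric vector.
#' @param lo,hi new extremes, `lo < hi`.
#' @return Same shape as the input.
#' @export
rescale_range <- function(scores, lo, hi) {
  if (!(is.finite(lo) && is.finite(hi) && lo < hi)) {
    abort("need lo < hi.")
  }
  if (inherits(scores, "spine_scores")) {
    scores$display_score <- pmin(pmax((scores$score - lo) / (hi - lo), 0), 1)
    scores
  } else {
    pmin(pmax((scores - lo) / (hi - lo), 0), 1)
  }
}

#' Ids a query could not score
#'
#' @param scores a `spine_scores` object.
#' @return Character vector (spines missing a selected feature).
#' @export
unscored_ids <- function(scores) {
  attr(scores, "unscored") %||% character()
}

#' @importFrom rlang %||%
NULL

#' @export
print.spine_scores <- function(x, ...) {
  cat(sprintf("<spine_scores: %s query, %d scored, %d unscored>\n",
              attr(x, "mode"), nrow(x), length(unscored_ids(x))))
  NextMethod()
}

#' @method tidy spine_scores
#' @export
tidy.spine_scores <- function(x, ...) {
  out <- x
  class(out) <- setdiff(class(out), "spine_scores")
  attr(out, "mode") <- attr(out, "weights") <- NULL
  attr(out, "query_ids") <- attr(out, "unscored") <- NULL
  out
}

#' @method glance spine_scores
#' @export
glance.spine_scores <- function(x, ...) {
  tibble(mode = attr(x, "mode"),
         n_scored = nrow(x),
         n_unscored = length(unscored_ids(x)),
         n_features = length(attr(x, "weights")),
         min_score = min(x$score), max_score = max(x$score))
}

#' @method autoplot spine_scores
#' @export
autoplot.spine_scores <- function(object, n_bins = 50, ...) {
  h <- score_histogram(object, n_bins)
  ggplot2::ggplot(h, ggplot2::aes(x = (.data$lo + .data$hi) / 2,
                                  y = .data$count)) +
    ggplot2::geom_col(width = 1 / n_bins, fill = "steelblue") +
    ggplot2::labs(x = "similarity score", y = "spines") +
    ggplot2::xlim(-0.01, 1.01) +
    ggplot2::theme_minimal()
}

#' JSON provenance report for a query
#'
#' Bundles the query parameters, score histogram and optional filter
#' result into a JSON file, so a saved scores CSV carries its provenance.
#'
#' @param scores a `spine_scores` object.
#' @param path output JSON path.
#' @param n_bins histogram bins.
#' @param filter optional list with `lo`, `hi`, `complement` applied via
#'   [range_filter()] and echoed with the resulting ids.
#' @return `path`, invisibly.
#' @export
write_query_report <- function(scores, path, n_bins = 50, filter = NULL) {
  rep <- list(mode = attr(scores, "mode"),
              weights = as.list(attr(scores, "weights")),
              query_ids = attr(scores, "query_ids"),
              n_scored = nrow(scores),
              unscored_ids = unscored_ids(scores),
              histogram = score_histogram(scores, n_bins)$count)
  if (!is.null(filter)) {
    ids <- range_filter(scores, filter$lo, filter$hi,
                        isTRUE(filter$complement))
    rep$filter <- list(lo = filter$lo, hi = filter$hi,
                       complement = isTRUE(filter$complement),
                       ids = ids)
  }
  jsonlite::write_json(rep, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
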