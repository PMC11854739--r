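#' Per-feature importance scores
#'
#' The importance of feature i is the accumulated weight
#' `|w_i| = sum_p W[i, p]` — the row sum of the non-negative weight matrix
#' (equal to the row l1 norm since `W >= 0`).
#'
#' @param W d x r non-negative weight matrix.
#' @return length-d non-negative numeric vector.
#' @export
feature_scores <- function(W) {
  W <- as.matrix(W)
  if (any(W < 0)) stop("W must be non-negative", call. = FALSE)
  rowSums(W)
}

#' Rank features by descending score
#'
#' Ties are broken by ascending feature index, so the ranking is a
#' deterministic permutation of `1..d`.
#'
#' @param scores length-d finite numeric vector.
#' @return integer permutation of `1..d` (1-based feature indices).
#' @export
rank_features <- function(scores) {
  if (anyNA(scores) || any(!is.finite(scores))) {
    stop("scores must be finite", call. = FALSE)
  }
  order(-scores, seq_along(scores))
}

#' Top-k selected features
#'
#' @param ranking permutation from [rank_features()].
#' @param k number of features, `1 <= k <= d`.
#' @return first k entries of the ranking.
#' @export
top_k <- function(ranking, k) {
  if (k < 1L || k > length(ranking)) stop("k out of range", call. = FALSE)
  ranking[seq_len(k)]
}

#' Write a feature ranking as TSV
#'
#' Columns: `rank`, `feature_index` (0-based, matching the on-disk column
#' order), `feature_name`, `score`.  Byte-stable for identical inputs.
#'
#' @param fit a `drfs_fit` object (or a list with `scores`, `ranking`,
#'   `feature_names`).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_ranking <- function(fit, path) {
  rk <- fit$ranking
  df <- data.frame(rank = seq_along(rk),
                   feature_index = rk - 1L,
                   feature_name = fit$feature_names[rk],
                   score = sprintf("%.12g", fit$scores[rk]))
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a ranking TSV written by [write_ranking()]
#' @param path input path.
#' @return data frame with rank, feature_index, feature_name, score.
#' @export
read_ranking <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE)
  df$score <- as.numeric(df$score)
  df
}
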