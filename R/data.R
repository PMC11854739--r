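#' Construct a labeled sample-by-feature data matrix
#'
#' The basic container for the package: an n x d numeric matrix of samples
#' (rows) by features (columns) plus one class label per sample.  Arbitrary
#' label values (e.g. 5, 9, 5) are remapped to contiguous ids `1..r` by
#' first appearance, so the one-hot indicator columns are reproducible.
#'
#' @param values numeric n x d matrix (samples in rows).
#' @param labels length-n vector of class labels; remapped to `1..r` by
#'   first appearance.
#' @param feature_names optional length-d character vector; synthesized as
#'   `f0001..` when absent.
#' @return an object of class `drfs_data` with elements `values` (matrix),
#'   `labels` (integer `1..r`), `label_levels` (original values in
#'   first-appearance order), `feature_names`, and counts `n`, `d`, `r`.
#' @export
drfs_data <- function(values, labels, feature_names = NULL) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (nrow(values) < 2L || ncol(values) < 2L) {
    stop("need at least 2 samples and 2 features", call. = FALSE)
  }
  if (length(labels) != nrow(values)) {
    stop("length(labels) must equal nrow(values)", call. = FALSE)
  }
  if (anyNA(values) || any(!is.finite(values))) {
    stop("data matrix contains NaN/Inf or missing values", call. = FALSE)
  }
  levels <- unique(labels)
  y <- match(labels, levels)
  if (is.null(feature_names)) {
    feature_names <- sprintf("f%04d", seq_len(ncol(values)))
  }
  if (length(feature_names) != ncol(values)) {
    stop("feature_names length must equal number of features", call. = FALSE)
  }
  colnames(values) <- feature_names
  structure(
    list(values = values, labels = as.integer(y),
         label_levels = levels, feature_names = as.character(feature_names),
         n = nrow(values), d = ncol(values), r = length(levels)),
    class = "drfs_data")
}

#' @export
print.drfs_data <- function(x, ...) {
  cat(sprintf("drfs_data: %d samples x %d features, %d classes\n",
              x$n, x$d, x$r))
  cat("class counts:", paste(tabulate(x$labels, x$r), collapse = " "), "\n")
  invisible(x)
}

#' Read a labeled dataset from delimited text or a MAT container
#'
#' The delimited dialect is samples x features plus one label column
#' (default name `"label"`); the delimiter is sniffed among comma and tab
#' and a header row is detected by a non-numeric first row.  The MAT dialect
#' is the scikit-feature convention: a MATLAB container with variables `X`
#' (n x d) and `Y` (n x 1); it is read through the `scipy.io` bridge (a
#' `python` interpreter with scipy must be on the PATH).
#'
#' @param path file path.
#' @param format `"delimited"` or `"mat"`.
#' @param label_column column name or index holding the labels (delimited
#'   format only).
#' @return a [drfs_data()] object; labels are remapped to `1..r` by first
#'   appearance.
#' @export
read_dataset <- function(path, format = c("delimited", "mat"),
                         label_column = "label") {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (format == "mat") return(read_mat_dataset(path))

  first <- readLines(path, n = 1L)
  delim <- if (lengths(regmatches(first, gregexpr("\t", first))) > 0) "\t" else ","
  cells <- strsplit(first, delim, fixed = TRUE)[[1L]]
  has_header <- anyNA(suppressWarnings(as.numeric(cells)))
  df <- utils::read.table(path, sep = delim, header = has_header,
                          stringsAsFactors = FALSE, check.names = FALSE)
  if (is.character(label_column)) {
    if (!has_header || !(label_column %in% names(df))) {
      if (has_header) stop("label column '", label_column, "' not found",
                           call. = FALSE)
      # headerless files: fall back to the last column
      label_column <- ncol(df)
    } else {
      label_column <- match(label_column, names(df))
    }
  }
  if (label_column < 1L || label_column > ncol(df)) {
    stop("label column index out of range", call. = FALSE)
  }
  labels <- df[[label_column]]
  vals <- df[, -label_column, drop = FALSE]
  if (!all(vapply(vals, is.numeric, logical(1)))) {
    stop("non-numeric cell in data columns", call. = FALSE)
  }
  x <- drfs_data(as.matrix(vals), labels,
                 feature_names = if (has_header) names(df)[-label_column])
  message(sprintf("read %s: n=%d d=%d r=%d", basename(path), x$n, x$d, x$r))
  x
}

read_mat_dataset <- function(path) {
  py <- Sys.which("python")
  if (!nzchar(py)) stop("MAT format needs a 'python' interpreter with scipy",
                        call. = FALSE)
  tmpx <- tempfile(fileext = ".csv"); tmpy <- tempfile(fileext = ".csv")
  on.exit(unlink(c(tmpx, tmpy)), add = TRUE)
  code <- paste(
    "import sys, numpy, scipy.io",
    "m = scipy.io.loadmat(sys.argv[1])",
    "assert 'X' in m and 'Y' in m, 'variables X and Y required'",
    "numpy.savetxt(sys.argv[2], numpy.asarray(m['X'], dtype=float), delimiter=',')",
    "numpy.savetxt(sys.argv[3], numpy.asarray(m['Y'], dtype=float).ravel(), delimiter=',')",
    sep = "\n")
  status <- system2(py, c("-c", shQuote(code), shQuote(path),
                          shQuote(tmpx), shQuote(tmpy)),
                    stdout = FALSE, stderr = "")
  if (status != 0L) stop("failed to parse MAT container: ", path, call. = FALSE)
  vals <- as.matrix(utils::read.table(tmpx, sep = ","))
  labels <- utils::read.table(tmpy, sep = ",")[[1L]]
  dimnames(vals) <- NULL
  x <- drfs_data(vals, labels)
  message(sprintf("read %s: n=%d d=%d r=%d", basename(path), x$n, x$d, x$r))
  x
}

#' Write a dataset as delimited text
#'
#' Inverse of [read_dataset()] for the delimited dialect: features in named
#' columns plus a `label` column holding the original label values.
#'
#' @param x a [drfs_data()] object.
#' @param path output path.
#' @param sep field separator.
#' @return `path`, invisibly.
#' @export
write_dataset <- function(x, path, sep = ",") {
  stopifnot(inherits(x, "drfs_data"))
  df <- as.data.frame(x$values)
  names(df) <- x$feature_names
  df$label <- x$label_levels[x$labels]
  utils::write.table(df, path, sep = sep, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' One-hot label indicator matrix
#'
#' Builds the n x r binary matrix Y with `Y[i, c] == 1` iff sample i has
#' class c; column sums are the per-class counts.
#'
#' @param labels integer class ids in `1..r`.
#' @param r number of classes.
#' @return an n x r 0/1 matrix.
#' @export
one_hot <- function(labels, r = max(labels)) {
  labels <- as.integer(labels)
  if (any(labels < 1L) || any(labels > r)) {
    stop("class id out of range 1..r", call. = FALSE)
  }
  Y <- matrix(0, nrow = length(labels), ncol = r)
  Y[cbind(seq_along(labels), labels)] <- 1
  Y
}

#' Per-feature standardization
#'
#' `zscore` centers and scales each feature to unit sample variance;
#' `minmax` rescales to `[0, 1]`.  Constant features map to all-zeros under
#' both modes (variance / range guard).  RBF feature distances are
#' scale-sensitive, so `zscore` is the pipeline default.
#'
#' @param x a [drfs_data()] object.
#' @param mode `"zscore"`, `"minmax"` or `"none"`.
#' @return a [drfs_data()] object with transformed values.
#' @export
standardize <- function(x, mode = c("zscore", "minmax", "none")) {
  stopifnot(inherits(x, "drfs_data"))
  mode <- match.arg(mode)
  v <- x$values
  if (mode == "zscore") {
    mu <- colMeans(v)
    sdv <- apply(v, 2L, stats::sd)
    sdv[sdv == 0] <- Inf   # constant feature -> zeros
    v <- sweep(sweep(v, 2L, mu), 2L, sdv, "/")
  } else if (mode == "minmax") {
    lo <- apply(v, 2L, min)
    rng <- apply(v, 2L, max) - lo
    rng[rng == 0] <- Inf
    v <- sweep(sweep(v, 2L, lo), 2L, rng, "/")
  }
  out <- x
  out$values <- v
  colnames(out$values) <- x$feature_names
  out$standardize_mode <- mode
  out
}

#' Partition samples by class
#'
#' Splits the rows of the data matrix into per-class matrices
#' `X^(1)..X^(r)`, preserving within-class sample order.
#'
#' @param x a [drfs_data()] object.
#' @return a list of r numeric matrices; element l has `n^(l)` rows.
#' @export
split_by_class <- function(x) {
  stopifnot(inherits(x, "drfs_data"))
  lapply(seq_len(x$r), function(l) {
    x$values[x$labels == l, , drop = FALSE]
  })
}
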