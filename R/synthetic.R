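#' Specification of a synthetic labeled dataset
#'
#' Describes a stated world with three kinds of features: *informative*
#' features whose class means differ and which co-vary in class-assigned
#' equicorrelated blocks (the correlation is present only in the block's
#' assigned class — the class-specific association the local regularizer
#' is built to exploit); *redundant* features that are near-duplicates of
#' informative ones (the global-redundancy signal); and pure-noise
#' features.  Total dimension is
#' `d = d_informative + n_redundant + d_noise`.
#'
#' @param r number of classes (>= 2).
#' @param n_per_class samples per class.
#' @param d_informative number of informative features.
#' @param block_size features per class-assigned correlated block; blocks
#'   are assigned to classes round-robin.
#' @param within_block_corr target within-block correlation in (0, 1),
#'   realized only in the block's assigned class.
#' @param n_redundant number of near-duplicate copies of informative
#'   features (sources cycle through the informative set).
#' @param dup_noise_sd standard deviation of the duplicate perturbation.
#' @param d_noise number of i.i.d. standard-normal noise features.
#' @param class_shift mean separation Delta: informative feature j has mean
#'   `class_shift` in its preferred class (features cycle through classes)
#'   and 0 elsewhere.
#' @param noise_sd within-class standard deviation of informative features.
#' @param seed RNG seed.
#' @return a `synthetic_spec` list.
#' @export
synthetic_spec <- function(r = 3L, n_per_class = 50L, d_informative = 10L,
                           block_size = 5L, within_block_corr = 0.8,
                           n_redundant = 5L, dup_noise_sd = 0.05,
                           d_noise = 85L, class_shift = 1.5, noise_sd = 1,
                           seed = 0L) {
  stopifnot(r >= 2L, n_per_class >= 1L, d_informative >= 1L,
            block_size >= 1L, block_size <= d_informative,
            within_block_corr > 0, within_block_corr < 1,
            n_redundant >= 0L, d_noise >= 0L, dup_noise_sd >= 0,
            noise_sd > 0)
  structure(list(r = as.integer(r), n_per_class = as.integer(n_per_class),
                 d_informative = as.integer(d_informative),
                 block_size = as.integer(block_size),
                 within_block_corr = within_block_corr,
                 n_redundant = as.integer(n_redundant),
                 dup_noise_sd = dup_noise_sd, d_noise = as.integer(d_noise),
                 class_shift = class_shift, noise_sd = noise_sd,
                 seed = as.integer(seed)),
            class = "synthetic_spec")
}

#' Generate a synthetic dataset with known ground truth
#'
#' Columns are laid out informative, then redundant, then noise; only the
#' sample rows are shuffled.  Within a class-assigned block the features
#' share a latent factor giving equicorrelation `within_block_corr`; in all
#' other classes the same features are independent, so the block structure
#' is class-specific by construction.  Duplicates are
#' `source + N(0, dup_noise_sd^2)` and therefore mutual nearest neighbours
#' of their sources in the global feature graph.
#'
#' @param spec a [synthetic_spec()].
#' @return list with `data` (a [drfs_data()]), `informative` (indices),
#'   `redundant` (indices), `noise` (indices), `ground_truth`
#'   (informative + redundant, the planted-signal set), `redundancy_map`
#'   (data frame duplicate -> source), `block_of` (block id per
#'   informative feature), and `class_of_block` / `pref_class` (class ids
#'   as carried by `data$labels`, i.e. after first-appearance remapping).
#' @export
generate_synthetic <- function(spec = synthetic_spec()) {
  stopifnot(inherits(spec, "synthetic_spec"))
  r <- spec$r
  n <- r * spec$n_per_class
  di <- spec$d_informative
  d <- di + spec$n_redundant + spec$d_noise
  rho <- spec$within_block_corr

  block_of <- ((seq_len(di) - 1L) %/% spec$block_size) + 1L
  n_blocks <- max(block_of)
  block_class <- ((seq_len(n_blocks) - 1L) %% r) + 1L
  pref_class <- ((seq_len(di) - 1L) %% r) + 1L

  with_seed(spec$seed, {
    labels <- rep(seq_len(r), each = spec$n_per_class)
    Xi <- matrix(0, n, di)
    for (l in seq_len(r)) {
      rows <- which(labels == l)
      nl <- length(rows)
      for (b in seq_len(n_blocks)) {
        cols <- which(block_of == b)
        E <- matrix(stats::rnorm(nl * length(cols)), nl, length(cols))
        if (block_class[b] == l) {
          shared <- stats::rnorm(nl)
          E <- sqrt(rho) * shared + sqrt(1 - rho) * E
        }
        Xi[rows, cols] <- spec$noise_sd * E
      }
      Xi[rows, ] <- Xi[rows, ] +
        matrix(rep(spec$class_shift * (pref_class == l), each = nl), nl, di)
    }
    src <- if (spec$n_redundant > 0L) {
      ((seq_len(spec$n_redundant) - 1L) %% di) + 1L
    } else integer(0)
    Xr <- if (spec$n_redundant > 0L) {
      Xi[, src, drop = FALSE] +
        matrix(stats::rnorm(n * spec$n_redundant, sd = spec$dup_noise_sd),
               n, spec$n_redundant)
    } else matrix(0, n, 0L)
    Xn <- if (spec$d_noise > 0L) {
      matrix(stats::rnorm(n * spec$d_noise), n, spec$d_noise)
    } else matrix(0, n, 0L)
    X <- cbind(Xi, Xr, Xn)
    perm <- sample.int(n)
    X <- X[perm, , drop = FALSE]
    labels <- labels[perm]

    fn <- c(sprintf("inf%02d", seq_len(di)),
            if (spec$n_redundant > 0L) sprintf("dup%02d", seq_len(spec$n_redundant)),
            if (spec$d_noise > 0L) sprintf("noise%03d", seq_len(spec$d_noise)))
    informative <- seq_len(di)
    redundant <- if (spec$n_redundant > 0L) di + seq_len(spec$n_redundant) else integer(0)
    noise_idx <- if (spec$d_noise > 0L) di + spec$n_redundant + seq_len(spec$d_noise) else integer(0)
    x <- drfs_data(X, labels, feature_names = fn)
    # row shuffling + first-appearance remapping permute the class ids, so
    # class-indexed metadata is translated to the ids carried by `data`
    remap <- function(cl) match(cl, x$label_levels)
    list(data = x,
         informative = informative, redundant = redundant, noise = noise_idx,
         ground_truth = c(informative, redundant),
         redundancy_map = data.frame(duplicate = redundant, source = src),
         block_of = block_of, class_of_block = remap(block_class),
         pref_class = remap(pref_class), spec = spec)
  })
}

#' The fixed reference fixture
#'
#' The acceptance-scale instance: 3 classes x 50 samples, 10 informative
#' features in two blocks of 5 (correlation 0.8, mean shift 1.5), 5
#' near-duplicates (sd 0.05), 85 noise features; n = 150, d = 100.
#'
#' @param seed RNG seed (default 0).
#' @return as [generate_synthetic()].
#' @export
reference_instance <- function(seed = 0L) {
  generate_synthetic(synthetic_spec(seed = seed))
}
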