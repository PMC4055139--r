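#' Intensity statistics of a masked region
#'
#' Computes the mean and the population standard deviation (divisor `n`, not
#' `n - 1`) of the image intensities under the foreground of a binary mask.
#' These per-slice statistics are the atoms of the a priori feature set that
#' guides propagation.
#'
#' @param image Numeric matrix, one grayscale slice.
#' @param mask Binary matrix (nonzero = foreground) of the same shape.
#' @return An object of class `region_stats`: a list with elements `mean`,
#'   `sd` (population) and `n_pixels`.
#' @examples
#' img <- matrix(c(90, 110, 0, 0), 2, 2)
#' msk <- matrix(c(1, 1, 0, 0), 2, 2)
#' compute_region_stats(img, msk)  # mean 100, sd 10
#' @export
compute_region_stats <- function(image, mask) {
  .check_same_shape(image, mask)
  px <- image[mask != 0]
  n <- length(px)
  if (n < 1L) stop("mask has no foreground pixels: degenerate sample",
                   call. = FALSE)
  m <- mean(px)
  s <- sqrt(sum((px - m)^2) / n)
  structure(list(mean = m, sd = s, n_pixels = n), class = "region_stats")
}

#' @export
print.region_stats <- function(x, ...) {
  cat(sprintf("region_stats: mean %.4f, sd %.4f, n %d\n",
              x$mean, x$sd, x$n_pixels))
  invisible(x)
}

#' Construct or grow the a priori feature set
#'
#' The feature set F = {(u_i, sigma_i)} holds one `region_stats` entry per
#' previously segmented slice, seed sample first, in segmentation order. It
#' is the committee that votes on the probability density of each pixel.
#'
#' `fs_append()` adds the statistics of a newly segmented slice. With a
#' finite `window`, only the most recent `window` entries are retained
#' (a sliding window over the slice history); the default keeps everything.
#'
#' @param ... One or more `region_stats` objects (or lists with `mean`, `sd`,
#'   `n_pixels`), oldest first.
#' @return A `feature_set`: a data frame with columns `mean`, `sd`,
#'   `n_pixels`, one row per entry.
#' @examples
#' fs <- feature_set(list(mean = 100, sd = 5, n_pixels = 200))
#' fs <- fs_append(fs, list(mean = 102, sd = 6, n_pixels = 210))
#' nrow(fs)
#' @export
feature_set <- function(...) {
  entries <- list(...)
  if (length(entries) == 0L) stop("feature_set needs at least one entry",
                                  call. = FALSE)
  df <- do.call(rbind, lapply(entries, function(e) {
    data.frame(mean = e$mean, sd = e$sd, n_pixels = as.integer(e$n_pixels))
  }))
  rownames(df) <- NULL
  class(df) <- c("feature_set", "data.frame")
  df
}

#' @param features An existing `feature_set`.
#' @param stats A `region_stats` entry to append.
#' @param window Maximum number of entries to retain (`Inf` = unlimited).
#' @rdname feature_set
#' @export
fs_append <- function(features, stats, window = Inf) {
  stopifnot(inherits(features, "feature_set"))
  row <- data.frame(mean = stats$mean, sd = stats$sd,
                    n_pixels = as.integer(stats$n_pixels))
  df <- rbind(as.data.frame(features), row)
  if (is.finite(window) && nrow(df) > window) {
    df <- df[(nrow(df) - window + 1L):nrow(df), , drop = FALSE]
  }
  rownames(df) <- NULL
  class(df) <- c("feature_set", "data.frame")
  df
}

#' Write / read a feature set as plain text
#'
#' One `mean sd n_pixels` row per entry, whitespace separated, with a header
#' line. Allows a propagation run to be restarted from disk.
#'
#' @param features A `feature_set`.
#' @param path File path.
#' @return `read_feature_set()` returns a `feature_set`.
#' @export
write_feature_set <- function(features, path) {
  stopifnot(inherits(features, "feature_set"))
  write.table(as.data.frame(features), path, row.names = FALSE,
              quote = FALSE)
  invisible(path)
}

#' @rdname write_feature_set
#' @export
read_feature_set <- function(path) {
  df <- read.table(path, header = TRUE)
  stopifnot(all(c("mean", "sd", "n_pixels") %in% names(df)))
  df <- df[, c("mean", "sd", "n_pixels")]
  df$n_pixels <- as.integer(df$n_pixels)
  class(df) <- c("feature_set", "data.frame")
  df
}

# Vectorized two-branch density for one (mean, sd) committee member.
# Inside the closed 2-sigma interval: exp(-(x - mu)^2 / (2 sigma^2)).
# Outside: the linear penalty -|x - mu| / (2 sigma).
# sigma = 0 is the degenerate constant-intensity sample: density 1 at an
# exact intensity match, penalty -|x - mu| otherwise (the sigma -> 0 limit
# of interval membership, with the scale-free penalty reduced to the raw
# deviation).
.density_vec <- function(x, mu, sigma) {
  d <- numeric(length(x))
  dev <- abs(x - mu)
  if (sigma > 0) {
    inside <- dev <= 2 * sigma
    d[inside] <- exp(-(x[inside] - mu)^2 / (2 * sigma^2))
    d[!inside] <- -dev[!inside] / (2 * sigma)
  } else {
    inside <- dev == 0
    d[inside] <- 1
    d[!inside] <- -dev[!inside]
  }
  d
}

.inside_vec <- function(x, mu, sigma) {
  if (sigma > 0) abs(x - mu) <= 2 * sigma else x == mu
}

#' Two-branch intensity probability density
#'
#' For a pixel intensity `x` and one committee member with statistics
#' (mean, sd), returns `exp(-(x - mean)^2 / (2 sd^2))` when `x` lies in the
#' closed interval `[mean - 2 sd, mean + 2 sd]`, and the signed penalty
#' `-(|x - mean|) / (2 sd)` otherwise. The exponential branch lies in
#' `[exp(-2), 1]`; the penalty branch is non-positive and unbounded below,
#' so dissimilar intensities actively repel the contour rather than merely
#' failing to attract it.
#'
#' @param x Numeric vector of intensities.
#' @param stats A `region_stats` (or any list with `mean` and `sd`).
#' @return Numeric vector of densities, same length as `x`.
#' @examples
#' s <- list(mean = 100, sd = 10)
#' intensity_density(c(100, 120, 130), s)  # 1, exp(-2), -1.5
#' @export
intensity_density <- function(x, stats) {
  .density_vec(x, stats$mean, stats$sd)
}

#' Committee vote on interval membership
#'
#' Each feature-set entry casts an affirmative vote when `x` lies in its
#' closed 2-sigma interval, a negative vote otherwise. The two counts always
#' sum to the number of entries.
#'
#' @param x A single intensity value.
#' @param features A `feature_set`.
#' @return Named integer vector `c(affirmative = , negative = )`.
#' @export
density_votes <- function(x, features) {
  stopifnot(inherits(features, "feature_set"), nrow(features) >= 1L,
            length(x) == 1L)
  aff <- 0L
  for (i in seq_len(nrow(features))) {
    if (.inside_vec(x, features$mean[i], features$sd[i])) aff <- aff + 1L
  }
  c(affirmative = aff, negative = nrow(features) - aff)
}

# Shared evaluator: resolved density (and affirmative counts) for a vector
# of intensities against the whole feature set, without materialising the
# n_pixels x n_features density matrix.
.resolve_vec <- function(x, features) {
  k <- nrow(features)
  aff <- integer(length(x))
  dmax <- rep(-Inf, length(x))
  dmin <- rep(Inf, length(x))
  for (i in seq_len(k)) {
    mu <- features$mean[i]; sigma <- features$sd[i]
    d <- .density_vec(x, mu, sigma)
    aff <- aff + as.integer(.inside_vec(x, mu, sigma))
    dmax <- pmax(dmax, d)
    dmin <- pmin(dmin, d)
  }
  majority <- aff > (k - aff)
  list(value = ifelse(majority, dmax, dmin), affirmative = aff)
}

#' Voting-resolved probability density
#'
#' Evaluates the two-branch density of `x` under every feature-set entry,
#' then resolves the set by majority vote: if strictly more entries place
#' `x` inside their 2-sigma interval than outside, the maximum density is
#' returned; on a tie or a minority, the minimum. The vote makes the map
#' robust to singular entries: one drifted slice cannot veto an intensity
#' the rest of the history endorses, and vice versa.
#'
#' @param x Numeric vector of intensities.
#' @param features A `feature_set`.
#' @return Numeric vector of resolved densities.
#' @examples
#' fs <- feature_set(list(mean = 100, sd = 10, n_pixels = 1),
#'                   list(mean = 100, sd = 10, n_pixels = 1),
#'                   list(mean = 200, sd = 10, n_pixels = 1))
#' resolve_density(100, fs)  # votes 2:1 -> max -> 1
#' @export
resolve_density <- function(x, features) {
  stopifnot(inherits(features, "feature_set"), nrow(features) >= 1L)
  .resolve_vec(x, features)$value
}

#' Probability density map over a search region
#'
#' Applies [resolve_density()] to every pixel inside the search mask.
#' Pixels outside the search region carry the sentinel value 0, so the
#' balloon term of the level-set evolution vanishes there and the contour
#' is neither pushed nor pulled outside the region where the object is
#' sought.
#'
#' @param image Numeric matrix, one (denoised) slice.
#' @param search_mask Binary matrix delimiting the search region.
#' @param features A `feature_set`.
#' @return Numeric matrix of resolved densities, 0 outside the search
#'   region, with the search mask attached as attribute `domain`.
#' @export
probability_map <- function(image, search_mask, features) {
  .check_same_shape(image, search_mask, "image", "search_mask")
  idx <- which(search_mask != 0)
  if (length(idx) == 0L) stop("search mask is empty", call. = FALSE)
  pm <- matrix(0, nrow(image), ncol(image))
  pm[idx] <- .resolve_vec(image[idx], features)$value
  attr(pm, "domain") <- .as_binary(search_mask)
  pm
}
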