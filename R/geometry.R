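# Mask-derived geometry: the search region (dilation), the initial contour
# region (erosion), and the binary-step level-set initialization.

.brush1 <- function() EBImage::makeBrush(3L, shape = "diamond")

#' Dilate a binary mask
#'
#' Grows the mask outward by `n` pixels along its shape to form the search
#' region for the next slice: the object is sought only inside this region.
#' A radius-1 disk structuring element is applied iteratively `n` times,
#' which approximates an isotropic Euclidean offset of the contour.
#'
#' @param mask Binary matrix (nonzero = foreground).
#' @param n Non-negative integer, dilation extent in pixels. `n = 0` is the
#'   identity.
#' @return Binary 0/1 matrix, a superset of the input foreground.
#' @export
dilate_mask <- function(mask, n) {
  stopifnot(n >= 0, n == round(n))
  m <- .as_binary(mask)
  if (sum(m) == 0) stop("cannot dilate an empty mask: propagation lost",
                        call. = FALSE)
  if (n == 0) return(m)
  b <- .brush1()
  for (i in seq_len(n)) m <- EBImage::dilate(m, b)
  .as_binary(m)
}

#' Erode a binary mask
#'
#' Shrinks the mask inward by `k` pixels along its shape to form the initial
#' contour region: starting strictly inside the object keeps the initial
#' zero level set in object territory even under moderate inter-slice
#' motion. If eroding by `k` would empty the mask, `k` is reduced one step
#' at a time until the result is non-empty (a single-pixel mask is returned
#' unchanged); the `k` actually applied is attached as attribute
#' `k_applied` so callers can log the fallback.
#'
#' @param mask Binary matrix (nonzero = foreground).
#' @param k Non-negative integer, erosion extent in pixels.
#' @return Binary 0/1 matrix, a subset of the input foreground.
#' @export
erode_mask <- function(mask, k) {
  stopifnot(k >= 0, k == round(k))
  m <- .as_binary(mask)
  if (sum(m) == 0) stop("cannot erode an empty mask", call. = FALSE)
  if (k == 0) { attr(m, "k_applied") <- 0L; return(m) }
  b <- .brush1()
  cur <- m
  applied <- 0L
  for (i in seq_len(k)) {
    nxt <- .as_binary(EBImage::erode(cur, b))
    if (sum(nxt) == 0) break
    cur <- nxt
    applied <- applied + 1L
  }
  attr(cur, "k_applied") <- applied
  cur
}

#' Binary-step level-set initialization
#'
#' Builds the initial level-set field as a binary step: `-c` inside the
#' initial contour region, `+c` outside (interior is negative throughout
#' the package). The distance-regularization term of the evolution
#' reshapes this step into a signed-distance-like profile near the zero
#' set within a few iterations, so no signed-distance initialization (or
#' any later reinitialization) is needed.
#'
#' @param region Binary matrix, the initial contour region.
#' @param c Positive step height; default 2.
#' @return Numeric matrix taking exactly the two values `-c` and `+c`.
#' @export
init_lsf <- function(region, c = 2) {
  stopifnot(c > 0)
  m <- .as_binary(region)
  if (sum(m) == 0) stop("initial contour region is empty", call. = FALSE)
  matrix(ifelse(m != 0, -c, c), nrow(m), ncol(m))
}
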