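# Internal finite-difference helpers. All derivatives are central differences
# with replicate (Neumann) boundary handling, implemented by clamped index
# shifts so no explicit padding is allocated.

.shift <- function(m, dr, dc) {
  nr <- nrow(m); nc <- ncol(m)
  ri <- pmin(pmax(seq_len(nr) + dr, 1L), nr)
  ci <- pmin(pmax(seq_len(nc) + dc, 1L), nc)
  m[ri, ci, drop = FALSE]
}

# d/dcol (horizontal) and d/drow (vertical); at the borders the clamped shift
# degrades to a one-sided difference over half the spacing, matching replicate
# padding.
.dx <- function(m) (.shift(m, 0L, 1L) - .shift(m, 0L, -1L)) / 2
.dy <- function(m) (.shift(m, 1L, 0L) - .shift(m, -1L, 0L)) / 2

.div <- function(fx, fy) .dx(fx) + .dy(fy)

.laplacian <- function(m) {
  .shift(m, 1L, 0L) + .shift(m, -1L, 0L) +
    .shift(m, 0L, 1L) + .shift(m, 0L, -1L) - 4 * m
}

.check_same_shape <- function(a, b, what_a = "image", what_b = "mask") {
  if (!identical(dim(a), dim(b))) {
    stop(sprintf("%s (%s) and %s (%s) must share one grid shape",
                 what_a, paste(dim(a), collapse = "x"),
                 what_b, paste(dim(b), collapse = "x")), call. = FALSE)
  }
  invisible(TRUE)
}

.as_binary <- function(mask) {
  m <- matrix(as.numeric(mask != 0), nrow(mask), ncol(mask))
  m
}

# Coerce a volume (list of matrices, or H x W x Z array) to a list of slices.
.as_slices <- function(volume) {
  if (is.list(volume)) {
    slices <- volume
  } else if (is.array(volume) && length(dim(volume)) == 3L) {
    slices <- lapply(seq_len(dim(volume)[3L]), function(z) volume[, , z])
  } else if (is.matrix(volume)) {
    slices <- list(volume)
  } else {
    stop("volume must be a list of matrices or a 3-D array", call. = FALSE)
  }
  shp <- dim(slices[[1L]])
  for (s in slices) {
    if (!identical(dim(s), shp)) stop("all slices must share one grid shape",
                                      call. = FALSE)
  }
  slices
}

# Restore the global RNG state on exit so generators are side-effect free.
.with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}
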