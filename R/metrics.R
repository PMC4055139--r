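# Segmentation accuracy measures: false positive error, false negative
# error, and the similarity index (Dice coefficient). All three are
# returned as fractions; multiply by 100 for percentages.

.count_sets <- function(pred, truth) {
  .check_same_shape(pred, truth, "pred", "truth")
  o <- pred != 0
  g <- truth != 0
  list(n_o = sum(o), n_g = sum(g), n_og = sum(o & g), n_ob = sum(o & !g))
}

#' False positive error
#'
#' `FPE = |O intersect B| / |G|`: extracted pixels outside the gold
#' standard `G`, relative to the size of `G` (`B` is the complement of
#' `G`). Unbounded above — an extraction twice the size of `G` lying
#' entirely outside it scores 2.
#'
#' @param pred Binary matrix, the extracted object `O`.
#' @param truth Binary matrix, the gold standard `G` (non-empty).
#' @return A fraction `>= 0`.
#' @export
fpe <- function(pred, truth) {
  cs <- .count_sets(pred, truth)
  if (cs$n_g == 0) stop("gold standard is empty: FPE undefined", call. = FALSE)
  cs$n_ob / cs$n_g
}

#' False negative error
#'
#' `FNE = (|G| - |O intersect G|) / |G|`: the fraction of the gold
#' standard missed by the extraction.
#'
#' @inheritParams fpe
#' @return A fraction in `[0, 1]`.
#' @export
fne <- function(pred, truth) {
  cs <- .count_sets(pred, truth)
  if (cs$n_g == 0) stop("gold standard is empty: FNE undefined", call. = FALSE)
  (cs$n_g - cs$n_og) / cs$n_g
}

#' Similarity index (Dice coefficient)
#'
#' `SI = 2 |O intersect G| / (|O| + |G|)`, symmetric in its arguments,
#' 1 iff the two masks are identical, 0 iff disjoint.
#'
#' @inheritParams fpe
#' @return A fraction in `[0, 1]`.
#' @export
si <- function(pred, truth) {
  cs <- .count_sets(pred, truth)
  if (cs$n_o + cs$n_g == 0) stop("both masks empty: SI undefined",
                                 call. = FALSE)
  2 * cs$n_og / (cs$n_o + cs$n_g)
}

#' Batch evaluation of aligned mask sequences
#'
#' Per-slice FPE/FNE/SI plus their unweighted means across slices.
#'
#' @param pred_masks,truth_masks Equal-length lists of binary matrices,
#'   aligned slice by slice.
#' @return An object of class `priorseg_report`: list with `per_slice`
#'   (data frame: slice, fpe, fne, si and the underlying pixel counts) and
#'   `mean_fpe`, `mean_fne`, `mean_si`.
#' @export
batch_report <- function(pred_masks, truth_masks) {
  if (length(pred_masks) != length(truth_masks)) {
    stop("pred and truth sequences differ in length", call. = FALSE)
  }
  rows <- lapply(seq_along(pred_masks), function(z) {
    cs <- .count_sets(pred_masks[[z]], truth_masks[[z]])
    data.frame(slice = z,
               fpe = cs$n_ob / cs$n_g,
               fne = (cs$n_g - cs$n_og) / cs$n_g,
               si = 2 * cs$n_og / (cs$n_o + cs$n_g),
               n_pred = cs$n_o, n_truth = cs$n_g,
               n_intersect = cs$n_og)
  })
  per_slice <- do.call(rbind, rows)
  structure(list(per_slice = per_slice,
                 mean_fpe = mean(per_slice$fpe),
                 mean_fne = mean(per_slice$fne),
                 mean_si = mean(per_slice$si)),
            class = "priorseg_report")
}

#' @export
print.priorseg_report <- function(x, ...) {
  cat(sprintf("priorseg_report over %d slice(s)\n", nrow(x$per_slice)))
  cat(sprintf("  mean FPE %.4f  mean FNE %.4f  mean SI %.4f\n",
              x$mean_fpe, x$mean_fne, x$mean_si))
  invisible(x)
}

#' Write an evaluation report to disk
#'
#' @param report A `priorseg_report`.
#' @param path Output path.
#' @param format `"json"` (default; per-slice records plus the means) or
#'   `"csv"` (per-slice table only).
#' @export
write_report <- function(report, path, format = c("json", "csv")) {
  stopifnot(inherits(report, "priorseg_report"))
  format <- match.arg(format)
  if (format == "json") {
    jsonlite::write_json(
      list(per_slice = report$per_slice,
           mean_fpe = report$mean_fpe,
           mean_fne = report$mean_fne,
           mean_si = report$mean_si),
      path, auto_unbox = TRUE, digits = NA)
  } else {
    write.csv(report$per_slice, path, row.names = FALSE)
  }
  invisible(path)
}
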