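# Streamline sets: tractography fiber paths with per-streamline mean FA.

#' Construct a streamline set
#'
#' @param points list of numeric matrices, one per streamline, each with
#'   3 columns (x, y, z) of continuous voxel coordinates (0-based, so a point
#'   inside voxel `(i, j, k)` of the label array has coordinates in
#'   `[i-1, i) x [j-1, j) x [k-1, k)`), and at least 2 rows.
#' @param fa numeric vector of per-streamline mean fractional anisotropy
#'   values, in `[0, 1]`, same length as `points`.
#' @return An object of class `streamline_set`.
#' @export
streamline_set <- function(points, fa) {
  if (length(points) != length(fa))
    stop("`points` and `fa` must have the same length")
  if (length(points)) {
    ok <- vapply(points, function(p) is.matrix(p) && ncol(p) == 3 &&
                   nrow(p) >= 2 && all(is.finite(p)), logical(1))
    if (!all(ok)) stop("each streamline needs a finite n x 3 matrix, n >= 2")
    if (any(!is.finite(fa)) || any(fa < 0) || any(fa > 1))
      stop("`fa` values must lie in [0, 1]")
  }
  structure(list(points = points, fa = as.numeric(fa)),
            class = "streamline_set")
}

#' @export
print.streamline_set <- function(x, ...) {
  cat(sprintf("<streamline_set> %d streamlines", length(x$fa)))
  if (length(x$fa))
    cat(sprintf(", mean FA %.3f (range %.3f-%.3f)",
                mean(x$fa), min(x$fa), max(x$fa)))
  cat("\n")
  invisible(x)
}

#' @export
length.streamline_set <- function(x) length(x$fa)
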