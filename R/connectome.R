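# Connectomes: symmetric weighted graphs over parcellation nodes, in three
# variants: binary (edge presence), fa_weighted (mean FA per connection) and
# fa_normalized (FA weights rescaled to unit total network strength).

CONNECTOME_VARIANTS <- c("binary", "fa_weighted", "fa_normalized")

#' Construct a connectome
#'
#' @param weights symmetric non-negative numeric matrix with zero diagonal.
#' @param nodes node labels (character or integer); defaults to the matrix
#'   dimnames or `1:n`.
#' @param variant one of `"binary"`, `"fa_weighted"`, `"fa_normalized"`.
#' @param counts optional matrix of per-edge streamline counts (construction
#'   provenance).
#' @return An object of class `connectome`: a list with elements `weights`
#'   (dimnames set to `nodes`), `nodes`, `variant` and `counts`.
#' @details Invariants enforced: exact symmetry, zero diagonal, non-negative
#'   weights; `binary` weights must be 0/1; `fa_normalized` total strength
#'   (sum over undirected edges, each counted once) must equal 1 within
#'   `1e-8`.
#' @export
connectome <- function(weights, nodes = NULL,
                       variant = c("fa_weighted", "binary", "fa_normalized"),
                       counts = NULL) {
  variant <- match.arg(variant)
  if (!is.matrix(weights) || nrow(weights) != ncol(weights))
    stop("`weights` must be a square matrix")
  n <- nrow(weights)
  if (n < 1) stop("connectome needs at least one node")
  if (any(!is.finite(weights))) stop("weights must be finite")
  if (any(weights < 0)) stop("weights must be non-negative")
  if (!isTRUE(all.equal(weights, t(weights), tolerance = 0,
                        check.attributes = FALSE)))
    stop("`weights` must be exactly symmetric")
  if (any(diag(weights) != 0)) stop("diagonal must be zero (no self-loops)")
  if (variant == "binary" && !all(weights %in% c(0, 1)))
    stop("binary connectome weights must be 0 or 1")
  if (variant == "fa_normalized") {
    s <- sum(weights[upper.tri(weights)])
    # edgeless networks are tolerated as a degenerate case so that an empty
    # subject still has a representable variant triplet
    if (s != 0 && abs(s - 1) > 1e-8)
      stop(sprintf("fa_normalized total strength is %.10f, expected 1", s))
  }
  if (is.null(nodes)) nodes <- rownames(weights)
  if (is.null(nodes)) nodes <- as.character(seq_len(n))
  nodes <- as.character(nodes)
  if (length(nodes) != n) stop("`nodes` length must match matrix size")
  if (anyDuplicated(nodes)) stop("node labels must be unique")
  dimnames(weights) <- list(nodes, nodes)
  if (!is.null(counts)) dimnames(counts) <- list(nodes, nodes)
  structure(list(weights = weights, nodes = nodes, variant = variant,
                 counts = counts),
            class = "connectome")
}

#' @export
print.connectome <- function(x, ...) {
  m <- sum(x$weights[upper.tri(x$weights)] > 0)
  cat(sprintf("<connectome> %s, %d nodes, %d edges (density %.3f)\n",
              x$variant, length(x$nodes), m,
              if (length(x$nodes) > 1)
                m / choose(length(x$nodes), 2) else 0))
  invisible(x)
}

#' @export
plot.connectome <- function(x, main = NULL, ...) {
  n <- length(x$nodes)
  graphics::image(seq_len(n), seq_len(n), t(x$weights[n:1, , drop = FALSE]),
                  axes = FALSE, xlab = "node", ylab = "node",
                  main = if (is.null(main)) paste0(x$variant, " connectome")
                         else main, ...)
  invisible(x)
}

# offsets within a Euclidean search radius, ordered by distance then by
# lexicographic position so ties are resolved deterministically
.search_offsets <- function(radius) {
  r <- floor(radius)
  g <- expand.grid(dx = -r:r, dy = -r:r, dz = -r:r)
  g$dist <- sqrt(g$dx^2 + g$dy^2 + g$dz^2)
  g <- g[g$dist <= radius + 1e-12 & g$dist > 0, ]
  g[order(g$dist, g$dx, g$dy, g$dz), ]
}

.assign_voxel_label <- function(vox, pm, offsets) {
  d <- dim(pm$labels)
  lab <- pm$labels[vox[1], vox[2], vox[3]]
  if (lab > 0) return(lab)
  best_lab <- 0L; best_dist <- Inf
  for (i in seq_len(nrow(offsets))) {
    if (offsets$dist[i] > best_dist) break
    v <- vox + c(offsets$dx[i], offsets$dy[i], offsets$dz[i])
    if (any(v < 1) || any(v > d)) next
    l <- pm$labels[v[1], v[2], v[3]]
    if (l > 0) {
      # among voxels at the minimal distance keep the lowest label
      if (offsets$dist[i] < best_dist || l < best_lab) {
        best_lab <- l; best_dist <- offsets$dist[i]
      }
    }
  }
  best_lab
}

#' Assign a streamline's endpoints to parcellation regions
#'
#' Each endpoint gets the label of its containing voxel; endpoints landing in
#' background are assigned the nearest labeled voxel within `radius` voxels
#' (Euclidean, lowest label on ties), reflecting that tractography terminates
#' near the WM-GM interface where the voxel itself may be unlabeled.
#'
#' @param points n x 3 matrix of streamline points (0-based voxel
#'   coordinates); only the first and last rows are used.
#' @param pm a `parcel_map`.
#' @param radius background search radius in voxels (default 2).
#' @return Integer vector `c(region_i, region_j)` with `region_i < region_j`,
#'   or `integer(0)` ("none") when either endpoint is outside the grid or
#'   unassignable, or when both endpoints fall in the same region
#'   (self-loop); a `"reason"` attribute (`"outside"`, `"unassigned"`,
#'   `"self_loop"`) says why.
#' @export
endpoints_to_regions <- function(points, pm, radius = 2) {
  stopifnot(inherits(pm, "parcel_map"))
  if (inherits(points, "streamline_set"))
    stop("pass a single streamline's point matrix, not a streamline_set")
  d <- dim(pm$labels)
  offsets <- .search_offsets(radius)
  labs <- integer(2)
  for (k in 1:2) {
    p <- points[if (k == 1) 1 else nrow(points), ]
    vox <- floor(p) + 1L
    if (any(vox < 1) || any(vox > d))
      return(structure(integer(0), reason = "outside"))
    labs[k] <- .assign_voxel_label(vox, pm, offsets)
    if (labs[k] == 0L)
      return(structure(integer(0), reason = "unassigned"))
  }
  if (labs[1] == labs[2])
    return(structure(integer(0), reason = "self_loop"))
  sort(labs)
}

#' Build binary and FA-weighted connectomes from streamlines
#'
#' A pair of regions is connected if at least one streamline has its
#' endpoints assigned to both regions (self-loops excluded). The binary
#' connectome records presence; the FA-weighted connectome records, per
#' connection, the arithmetic mean of the per-streamline mean-FA values over
#' all streamlines linking the pair.
#'
#' @param streamlines a `streamline_set`.
#' @param pm a `parcel_map` (typically after [merge_cerebellar_labels()]).
#' @param radius endpoint background search radius, see
#'   [endpoints_to_regions()].
#' @return List with elements `binary` and `fa_weighted` (both `connectome`
#'   objects carrying per-edge streamline counts) and `discarded`, a named
#'   count of rejected streamlines by reason.
#' @export
build_connectomes <- function(streamlines, pm, radius = 2) {
  stopifnot(inherits(streamlines, "streamline_set"), inherits(pm, "parcel_map"))
  labs <- node_labels(pm)
  if (length(labs) < 2) stop("parcel map must define at least 2 regions")
  n <- length(labs)
  idx <- setNames(seq_len(n), labs)
  counts <- matrix(0L, n, n)
  fasum <- matrix(0, n, n)
  discarded <- c(outside = 0L, unassigned = 0L, self_loop = 0L)
  for (s in seq_along(streamlines$fa)) {
    ep <- endpoints_to_regions(streamlines$points[[s]], pm, radius = radius)
    if (length(ep) == 0) {
      r <- attr(ep, "reason")
      discarded[r] <- discarded[r] + 1L
      next
    }
    i <- idx[[as.character(ep[1])]]; j <- idx[[as.character(ep[2])]]
    counts[i, j] <- counts[i, j] + 1L; counts[j, i] <- counts[i, j]
    fasum[i, j] <- fasum[i, j] + streamlines$fa[s]; fasum[j, i] <- fasum[i, j]
  }
  if (sum(counts) == 0L)
    warning("no streamline was accepted; connectomes are empty")
  faw <- ifelse(counts > 0, fasum / pmax(counts, 1L), 0)
  bin <- (counts > 0) * 1
  list(binary = connectome(bin, nodes = labs, variant = "binary",
                           counts = counts),
       fa_weighted = connectome(faw, nodes = labs, variant = "fa_weighted",
                                counts = counts),
       discarded = discarded)
}

#' Normalize a connectome to unit total network strength
#'
#' Divides every weight by the total FA weight of all connections in the
#' network (sum over undirected edges, each counted once), so the resulting
#' connectome has total network strength exactly 1. This isolates the
#' topology and relative weight distribution from overall network strength.
#'
#' @param conn an `fa_weighted` (or any weighted) `connectome` with at least
#'   one non-zero edge.
#' @return A `connectome` with `variant = "fa_normalized"`.
#' @export
normalize_total_strength <- function(conn) {
  stopifnot(inherits(conn, "connectome"))
  s <- sum(conn$weights[upper.tri(conn$weights)])
  if (s <= 0) stop("cannot normalize an all-zero connectome")
  connectome(conn$weights / s, nodes = conn$nodes,
             variant = "fa_normalized", counts = conn$counts)
}

#' Total network strength
#'
#' Sum of connection weights over undirected edges, each counted once.
#' @param conn a `connectome`.
#' @return A number; exactly 1 for `fa_normalized` connectomes.
#' @export
total_strength <- function(conn) {
  stopifnot(inherits(conn, "connectome"))
  sum(conn$weights[upper.tri(conn$weights)])
}

#' Edges above a display threshold
#'
#' Returns the connections whose weight is strictly greater than `tau`
#' (the high-FA display rule uses `tau = 0.3`), sorted by descending weight.
#'
#' @param conn a `connectome`.
#' @param tau non-negative threshold; strict inequality.
#' @return data frame with columns `node_i`, `node_j`, `weight`.
#' @export
threshold_edges <- function(conn, tau = 0.3) {
  stopifnot(inherits(conn, "connectome"), tau >= 0)
  W <- conn$weights
  ut <- which(upper.tri(W) & W > tau, arr.ind = TRUE)
  out <- data.frame(node_i = conn$nodes[ut[, 1]],
                    node_j = conn$nodes[ut[, 2]],
                    weight = W[ut],
                    stringsAsFactors = FALSE)
  out[order(-out$weight), , drop = FALSE]
}

#' Group-average connectome
#'
#' Entrywise arithmetic mean over subjects; a connection absent in a subject
#' contributes 0 to the average of that entry.
#'
#' @param conns list of `connectome`s with identical node sets and variant.
#' @return A `connectome`. Averaging binary connectomes yields edge
#'   proportions, which are tagged `fa_weighted` (a general weighted matrix);
#'   other variants keep their tag (an average of unit-strength networks
#'   still has unit strength).
#' @export
group_average_connectome <- function(conns) {
  if (length(conns) < 1) stop("need at least one connectome")
  stopifnot(all(vapply(conns, inherits, logical(1), "connectome")))
  nodes <- conns[[1]]$nodes
  variant <- conns[[1]]$variant
  for (cc in conns) {
    if (!identical(cc$nodes, nodes)) stop("node sets differ across subjects")
    if (!identical(cc$variant, variant)) stop("variants differ across subjects")
  }
  avg <- Reduce(`+`, lapply(conns, `[[`, "weights")) / length(conns)
  out_variant <- variant
  if (variant == "binary" && !all(avg %in% c(0, 1)))
    out_variant <- "fa_weighted"
  connectome(avg, nodes = nodes, variant = out_variant)
}
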