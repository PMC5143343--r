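# Graph metrics: basic (degree, strength), integration (global efficiency)
# and segregation (local efficiency, clustering coefficient) measures,
# following the Rubinov & Sporns conventions. Weighted path length uses the
# inverse-weight mapping (step length = 1/weight); weighted clustering uses
# the Onnela geometric-mean triangle intensity with max-weight rescaling.

# step-length matrix for shortest paths: 1 (binary) or 1/w (weighted),
# Inf where no direct connection
.length_matrix <- function(conn) {
  W <- conn$weights
  if (conn$variant == "binary") {
    L <- ifelse(W > 0, 1, Inf)
  } else {
    L <- ifelse(W > 0, 1 / W, Inf)
  }
  diag(L) <- 0
  L
}

#' Average network degree
#'
#' Mean over nodes of the number of distinct neighbors (non-zero pattern;
#' identical for all variants built from the same streamline set).
#' @param conn a `connectome`.
#' @return A number in `[0, n-1]`.
#' @export
average_degree <- function(conn) {
  stopifnot(inherits(conn, "connectome"))
  mean(rowSums(conn$weights > 0))
}

#' Average network strength
#'
#' Mean over nodes of the summed weights of their connections.
#' @param conn a weighted `connectome`.
#' @return A number.
#' @export
average_strength <- function(conn) {
  stopifnot(inherits(conn, "connectome"))
  mean(rowSums(conn$weights))
}

#' Global efficiency
#'
#' Mean over ordered node pairs of the inverse shortest-path distance, with
#' disconnected pairs contributing 0. Binary distance is the hop count;
#' weighted distance minimizes the sum of step lengths `1/weight`.
#' An integration measure: high values mean short paths between regions.
#' @param conn a `connectome`.
#' @return A number; in `[0, 1]` for binary connectomes.
#' @export
global_efficiency <- function(conn) {
  stopifnot(inherits(conn, "connectome"))
  pairwise_efficiency(.length_matrix(conn))
}

#' Local efficiency
#'
#' Mean over nodes of the global efficiency of the subgraph induced by each
#' node's neighbors (the node itself excluded); nodes with fewer than two
#' neighbors contribute 0. A segregation measure. Neighbor subgraphs retain
#' their original weights.
#' @param conn a `connectome`.
#' @return A number; in `[0, 1]` for binary connectomes.
#' @export
local_efficiency <- function(conn) {
  stopifnot(inherits(conn, "connectome"))
  if (nrow(conn$weights) == 0) return(0)
  local_efficiency_cpp(.length_matrix(conn))
}

#' Average clustering coefficient
#'
#' Binary: per node, the fraction of neighbor pairs that are themselves
#' connected, `2 t_i / (k_i (k_i - 1))` with `t_i` the triangle count.
#' Weighted: the Onnela geometric-mean triangle intensity on weights rescaled
#' by the network-wide maximum weight. Nodes with degree < 2 contribute 0;
#' the value is averaged over all nodes. With 0/1 weights the weighted form
#' reduces exactly to the binary one.
#' @param conn a `connectome`.
#' @return A number in `[0, 1]`.
#' @export
average_clustering <- function(conn) {
  stopifnot(inherits(conn, "connectome"))
  W <- conn$weights
  n <- nrow(W)
  if (n == 0) return(0)
  k <- rowSums(W > 0)
  if (all(k < 2)) return(0)
  if (conn$variant == "binary") {
    A <- (W > 0) * 1
    tri <- diag(A %*% A %*% A) / 2
    ci <- ifelse(k >= 2, 2 * tri / (k * (k - 1)), 0)
  } else {
    mx <- max(W)
    if (mx == 0) return(0)
    Wc <- (W / mx)^(1 / 3)
    intensity <- diag(Wc %*% Wc %*% Wc) / 2   # geometric-mean triangle sum
    ci <- ifelse(k >= 2, 2 * intensity / (k * (k - 1)), 0)
  }
  mean(ci)
}

METRIC_COLUMNS <- c("bin_degree", "bin_global_eff", "bin_local_eff",
                    "bin_clustering",
                    "faw_strength", "faw_global_eff", "faw_local_eff",
                    "faw_clustering",
                    "fan_global_eff", "fan_local_eff", "fan_clustering")

#' Compute the full per-subject metric table
#'
#' Applies the five metric families to a subject's three connectome variants,
#' yielding the 11 standard values: binary average degree, global/local
#' efficiency and clustering; FA-weighted average strength, global/local
#' efficiency and clustering; FA-normalized global/local efficiency and
#' clustering.
#'
#' @param variants named list with `connectome`s `binary`, `fa_weighted` and
#'   `fa_normalized` over the same node set.
#' @param subject_id optional id attached to the output row.
#' @return A one-row data frame with the 11 metric columns (prefixed `bin_`,
#'   `faw_`, `fan_`) and, when given, `subject_id`.
#' @export
compute_metric_table <- function(variants, subject_id = NULL) {
  need <- c("binary", "fa_weighted", "fa_normalized")
  if (!all(need %in% names(variants)))
    stop("`variants` must contain connectomes ",
         paste(setdiff(need, names(variants)), collapse = ", "))
  for (v in need) {
    stopifnot(inherits(variants[[v]], "connectome"))
    if (!identical(variants[[v]]$nodes, variants$binary$nodes))
      stop("variants must share one node set")
  }
  row <- data.frame(
    bin_degree     = average_degree(variants$binary),
    bin_global_eff = global_efficiency(variants$binary),
    bin_local_eff  = local_efficiency(variants$binary),
    bin_clustering = average_clustering(variants$binary),
    faw_strength   = average_strength(variants$fa_weighted),
    faw_global_eff = global_efficiency(variants$fa_weighted),
    faw_local_eff  = local_efficiency(variants$fa_weighted),
    faw_clustering = average_clustering(variants$fa_weighted),
    fan_global_eff = global_efficiency(variants$fa_normalized),
    fan_local_eff  = local_efficiency(variants$fa_normalized),
    fan_clustering = average_clustering(variants$fa_normalized))
  if (!is.null(subject_id))
    row <- cbind(data.frame(subject_id = subject_id,
                            stringsAsFactors = FALSE), row)
  row
}

#' Metric table for a whole cohort
#'
#' @param cohort a `connectome_cohort` from [simulate_cohort()], or a list of
#'   subjects each carrying `id` and a `connectomes` list of the three
#'   variants.
#' @return data frame, one row per subject (column `subject_id` first).
#' @export
cohort_metric_table <- function(cohort) {
  subjects <- if (inherits(cohort, "connectome_cohort")) cohort$subjects
              else cohort
  do.call(rbind, lapply(subjects, function(s)
    compute_metric_table(s$connectomes, subject_id = s$id)))
}
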