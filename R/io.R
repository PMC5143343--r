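# Text interchange: tab-separated values throughout (period decimal
# separator, UTF-8, Unix newlines). Connectomes are square matrices with a
# header row of node labels; parcellations and streamlines have documented
# long-format tables; GraphML export is available for visualization tools.

.write_tsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = TRUE, fileEncoding = "UTF-8", eol = "\n")
}

#' Write a connectome to a delimited text file
#'
#' Tab-separated square matrix with a header row of node labels; weights are
#' written with full double precision so that a write/read round trip is an
#' identity to 1e-12 (in practice, exact).
#'
#' @param conn a `connectome`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_connectome <- function(conn, path) {
  stopifnot(inherits(conn, "connectome"))
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(paste(conn$nodes, collapse = "\t"), con, sep = "\n")
  apply(conn$weights, 1, function(row)
    writeLines(paste(sprintf("%.17g", row), collapse = "\t"), con,
               sep = "\n"))
  invisible(path)
}

#' Read a connectome from a delimited text file
#'
#' Expects the format written by [write_connectome()]: a header row of node
#' labels followed by a square numeric matrix. The matrix must be symmetric
#' within 1e-9 (it is then symmetrized exactly); larger asymmetry, NaN
#' entries or a header/shape mismatch are errors reporting the offending
#' row/column.
#'
#' @param path input file path.
#' @param variant `"auto"` (default: `binary` if all weights are 0/1,
#'   `fa_normalized` if the total strength is 1 within 1e-6, otherwise
#'   `fa_weighted`) or an explicit variant tag.
#' @return A `connectome`.
#' @export
read_connectome <- function(path,
                            variant = c("auto", "binary", "fa_weighted",
                                        "fa_normalized")) {
  variant <- match.arg(variant)
  lines <- readLines(path, encoding = "UTF-8")
  if (length(lines) < 2) stop("file has no matrix rows: ", path)
  nodes <- strsplit(lines[1], "\t", fixed = TRUE)[[1]]
  n <- length(nodes)
  if (length(lines) - 1 != n)
    stop(sprintf("header has %d labels but file has %d matrix rows",
                 n, length(lines) - 1))
  W <- matrix(0, n, n)
  for (i in seq_len(n)) {
    vals <- suppressWarnings(
      as.numeric(strsplit(lines[i + 1], "\t", fixed = TRUE)[[1]]))
    if (length(vals) != n)
      stop(sprintf("row %d has %d entries, expected %d (non-square matrix)",
                   i, length(vals), n))
    if (any(is.na(vals)))
      stop(sprintf("row %d, column %d: unparseable or NaN entry",
                   i, which(is.na(vals))[1]))
    W[i, ] <- vals
  }
  asym <- max(abs(W - t(W)))
  if (asym > 1e-9) {
    ij <- which(abs(W - t(W)) == asym, arr.ind = TRUE)[1, ]
    stop(sprintf("matrix asymmetric beyond tolerance at (%d, %d): |diff| = %g",
                 ij[1], ij[2], asym))
  }
  W <- (W + t(W)) / 2
  if (variant == "auto") {
    variant <- if (all(W %in% c(0, 1))) "binary"
               else if (abs(sum(W[upper.tri(W)]) - 1) < 1e-6) "fa_normalized"
               else "fa_weighted"
  }
  connectome(W, nodes = nodes, variant = variant)
}

#' Read a subject metadata table
#'
#' TSV with required columns `subject_id`, `group` (values `control` /
#' `IUGR`), `gender`, `ga_weeks`, `maternal_edu`, `age_scan`, `age_test`;
#' extra columns are kept verbatim.
#'
#' @param path input TSV path.
#' @return data frame of typed subject records.
#' @export
read_metadata <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE, fileEncoding = "UTF-8")
  need <- c("subject_id", "group", "gender", "ga_weeks", "maternal_edu",
            "age_scan", "age_test")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("metadata is missing column(s): ", paste(miss, collapse = ", "))
  bad <- which(!df$group %in% c("control", "IUGR"))
  if (length(bad))
    stop(sprintf("row %d: group value '%s' is not 'control' or 'IUGR'",
                 bad[1], df$group[bad[1]]))
  for (col in c("gender", "ga_weeks", "maternal_edu", "age_scan",
                "age_test")) {
    v <- suppressWarnings(as.numeric(df[[col]]))
    if (any(is.na(v) & !is.na(df[[col]])))
      stop(sprintf("row %d, column %s: unparseable number",
                   which(is.na(v) & !is.na(df[[col]]))[1], col))
    df[[col]] <- v
  }
  df
}

#' Read a neuropsychological score table
#'
#' TSV with a `subject_id` column; every other column is taken as a numeric
#' score (unknown instruments accepted verbatim).
#'
#' @param path input TSV path.
#' @return data frame with `subject_id` and numeric score columns.
#' @export
read_scores <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE, fileEncoding = "UTF-8",
                   na.strings = c("NA", ""))
  if (!"subject_id" %in% names(df))
    stop("score table is missing column: subject_id")
  for (col in setdiff(names(df), "subject_id")) {
    v <- suppressWarnings(as.numeric(df[[col]]))
    if (any(is.na(v) & !is.na(df[[col]])))
      stop(sprintf("row %d, column %s: unparseable number",
                   which(is.na(v) & !is.na(df[[col]]))[1], col))
    df[[col]] <- v
  }
  df
}

#' Write / read a parcellation as a voxel table
#'
#' Long-format TSV with columns `x`, `y`, `z` (1-based voxel indices), and
#' `label`; grid dimensions are recorded on a `#dims` comment line.
#'
#' @param pm a `parcel_map`.
#' @param path file path.
#' @return `write_parcellation_table()`: `path`, invisibly;
#'   `read_parcellation_table()`: a `parcel_map`.
#' @export
write_parcellation_table <- function(pm, path) {
  stopifnot(inherits(pm, "parcel_map"))
  d <- dim(pm$labels)
  idx <- which(pm$labels > 0, arr.ind = TRUE)
  df <- data.frame(x = idx[, 1], y = idx[, 2], z = idx[, 3],
                   label = pm$labels[idx])
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(sprintf("#dims\t%d\t%d\t%d", d[1], d[2], d[3]), con, sep = "\n")
  writeLines(paste(names(df), collapse = "\t"), con, sep = "\n")
  apply(df, 1, function(r) writeLines(paste(r, collapse = "\t"), con,
                                      sep = "\n"))
  invisible(path)
}

#' @rdname write_parcellation_table
#' @export
read_parcellation_table <- function(path) {
  first <- readLines(path, n = 1)
  if (!startsWith(first, "#dims"))
    stop("missing '#dims' header line in ", path)
  d <- as.integer(strsplit(first, "\t", fixed = TRUE)[[1]][2:4])
  df <- read.delim(path, skip = 1, stringsAsFactors = FALSE)
  arr <- array(0L, dim = d)
  arr[cbind(df$x, df$y, df$z)] <- as.integer(df$label)
  parcel_map(arr)
}

#' Write / read streamlines as a point table
#'
#' Long-format TSV, one point per row: columns `streamline` (integer id),
#' `x`, `y`, `z` (0-based continuous voxel coordinates) and `fa` (the
#' streamline's mean FA, repeated on each of its rows).
#'
#' @param sl a `streamline_set`.
#' @param path file path.
#' @return `write_streamlines()`: `path`, invisibly; `read_streamlines()`:
#'   a `streamline_set`.
#' @export
write_streamlines <- function(sl, path) {
  stopifnot(inherits(sl, "streamline_set"))
  rows <- lapply(seq_along(sl$fa), function(i) {
    p <- sl$points[[i]]
    data.frame(streamline = i, x = p[, 1], y = p[, 2], z = p[, 3],
               fa = sl$fa[i])
  })
  df <- if (length(rows)) do.call(rbind, rows)
        else data.frame(streamline = integer(0), x = numeric(0),
                        y = numeric(0), z = numeric(0), fa = numeric(0))
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(paste(names(df), collapse = "\t"), con, sep = "\n")
  if (nrow(df))
    writeLines(sprintf("%d\t%.17g\t%.17g\t%.17g\t%.17g", df$streamline,
                       df$x, df$y, df$z, df$fa), con, sep = "\n")
  invisible(path)
}

#' @rdname write_streamlines
#' @export
read_streamlines <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("streamline", "x", "y", "z", "fa")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("streamline table missing column(s): ", paste(miss, collapse = ", "))
  ids <- unique(df$streamline)
  pts <- lapply(ids, function(i) {
    as.matrix(df[df$streamline == i, c("x", "y", "z")])
  })
  fa <- vapply(ids, function(i) df$fa[df$streamline == i][1], numeric(1))
  streamline_set(pts, fa)
}

#' Export thresholded connections as GraphML
#'
#' Writes the edges with weight strictly above `tau` (see
#' [threshold_edges()]) as an undirected GraphML graph for visualization.
#'
#' @param conn a `connectome`.
#' @param path output path.
#' @param tau display threshold (default 0.3, the high-FA convention).
#' @return `path`, invisibly.
#' @export
export_graphml <- function(conn, path, tau = 0.3) {
  stopifnot(inherits(conn, "connectome"))
  edges <- threshold_edges(conn, tau)
  g <- igraph::graph_from_data_frame(
    edges, directed = FALSE,
    vertices = data.frame(name = conn$nodes, stringsAsFactors = FALSE))
  igraph::write_graph(g, path, format = "graphml")
  invisible(path)
}

#' Write a simulated cohort to a directory
#'
#' Writes `metadata.tsv` (one row per subject), `scores.tsv` when scores are
#' given, and one connectome file per subject and variant under
#' `connectomes/` (`<subject_id>_<variant>.tsv`).
#'
#' @param cohort a `connectome_cohort`.
#' @param dir output directory (created if needed).
#' @param scores optional score table to include.
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir, scores = NULL) {
  stopifnot(inherits(cohort, "connectome_cohort"))
  dir.create(file.path(dir, "connectomes"), recursive = TRUE,
             showWarnings = FALSE)
  .write_tsv(cohort_metadata(cohort), file.path(dir, "metadata.tsv"))
  if (!is.null(scores)) .write_tsv(scores, file.path(dir, "scores.tsv"))
  for (s in cohort$subjects) {
    for (v in names(s$connectomes)) {
      write_connectome(s$connectomes[[v]],
                       file.path(dir, "connectomes",
                                 sprintf("%s_%s.tsv", s$id, v)))
    }
  }
  invisible(dir)
}

#' Read a cohort design from a YAML configuration file
#'
#' The file holds the scalar fields of [cohort_design()] plus a `cells` list
#' (one mapping per design cell) and an optional `score_models` list.
#'
#' @param path YAML file path.
#' @return A [cohort_design()].
#' @export
read_cohort_design <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg$cells)) stop("design config must define `cells`")
  cells <- do.call(rbind, lapply(cfg$cells, function(cell) {
    # YAML 1.1 reads a bare `n` key as boolean FALSE; map it back
    names(cell)[names(cell) %in% c("FALSE", "FALSE.")] <- "n"
    as.data.frame(cell)
  }))
  args <- list(cells = cells)
  for (f in c("n_nodes", "seed", "weight_sd_within", "gender_p",
              "edu_probs"))
    if (!is.null(cfg[[f]])) args[[f]] <- cfg[[f]]
  if (!is.null(cfg$score_models)) args$score_models <- cfg$score_models
  do.call(cohort_design, args)
}
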