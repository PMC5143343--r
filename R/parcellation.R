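# Parcellations: integer-labeled 3-D voxel grids defining network nodes.

#' Construct a parcellation map
#'
#' A `parcel_map` wraps a 3-D integer label volume together with a label
#' table mapping each non-zero label to a region name. Label 0 is background
#' (unlabeled tissue); network nodes are the distinct non-zero labels.
#'
#' @param labels 3-D integer array of voxel labels (0 = background).
#' @param label_table data frame with columns `label` and `name`; defaults to
#'   generic region names for the labels present.
#' @param merged logical, whether the cerebellar merge has been applied.
#' @return An object of class `parcel_map`.
#' @seealso [make_toy_parcellation()], [merge_cerebellar_labels()]
#' @export
parcel_map <- function(labels, label_table = NULL, merged = FALSE) {
  if (length(dim(labels)) != 3L)
    stop("`labels` must be a 3-D array")
  if (any(labels < 0) || any(labels != round(labels)))
    stop("labels must be non-negative integers")
  present <- sort(unique(as.integer(labels[labels > 0])))
  if (is.null(label_table)) {
    label_table <- data.frame(label = present,
                              name = sprintf("region_%03d", present),
                              stringsAsFactors = FALSE)
  }
  stopifnot(all(c("label", "name") %in% names(label_table)))
  structure(list(labels = labels,
                 label_table = label_table[label_table$label %in% present, ,
                                           drop = FALSE],
                 merged = isTRUE(merged)),
            class = "parcel_map")
}

#' @export
print.parcel_map <- function(x, ...) {
  d <- dim(x$labels)
  cat(sprintf("<parcel_map> %d x %d x %d voxels, %d regions%s\n",
              d[1], d[2], d[3], nrow(x$label_table),
              if (x$merged) " (cerebellum merged)" else ""))
  invisible(x)
}

#' Node labels of a parcellation
#' @param pm a `parcel_map`.
#' @return Integer vector of distinct non-zero labels, sorted.
#' @export
node_labels <- function(pm) {
  stopifnot(inherits(pm, "parcel_map"))
  sort(unique(as.integer(pm$labels[pm$labels > 0])))
}

# ---------------------------------------------------------------------------
# AAL-style label inventory: 90 cortical regions (45 left/right pairs,
# standard AAL-90 names) plus a 16-parcel cerebellar block. The exact
# 16-parcel cerebellar subdivision used with infant atlases is not published
# as a label list, so the cerebellar names below are a synthetic default
# (6 left, 6 right, 4 vermis); pass your own split to
# merge_cerebellar_labels() if your atlas differs.

.aal_cortical_stems <- c(
  "Precentral", "Frontal_Sup", "Frontal_Sup_Orb", "Frontal_Mid",
  "Frontal_Mid_Orb", "Frontal_Inf_Oper", "Frontal_Inf_Tri", "Frontal_Inf_Orb",
  "Rolandic_Oper", "Supp_Motor_Area", "Olfactory", "Frontal_Sup_Medial",
  "Frontal_Med_Orb", "Rectus", "Insula", "Cingulum_Ant", "Cingulum_Mid",
  "Cingulum_Post", "Hippocampus", "ParaHippocampal", "Amygdala", "Calcarine",
  "Cuneus", "Lingual", "Occipital_Sup", "Occipital_Mid", "Occipital_Inf",
  "Fusiform", "Postcentral", "Parietal_Sup", "Parietal_Inf", "SupraMarginal",
  "Angular", "Precuneus", "Paracentral_Lobule", "Caudate", "Putamen",
  "Pallidum", "Thalamus", "Heschl", "Temporal_Sup", "Temporal_Pole_Sup",
  "Temporal_Mid", "Temporal_Pole_Mid", "Temporal_Inf")

.aal_cerebellar_stems <- c("Cerebelum_Crus1", "Cerebelum_Crus2",
                           "Cerebelum_Ant", "Cerebelum_Post",
                           "Cerebelum_Sup", "Cerebelum_Inf")

#' Full AAL-style label inventory (90 cortical + 16 cerebellar parcels)
#'
#' Returns the default 106-parcel inventory used as input to the cerebellar
#' merge: labels 1-90 are the standard AAL-90 cortical/subcortical regions
#' (odd = left, even = right), labels 91-106 a 16-parcel cerebellar block.
#'
#' @return data frame with columns `label`, `name`, `class`
#'   (`"cortical"`/`"cerebellar"`) and `laterality` (`"L"`, `"R"`, `"V"`).
#' @export
aal_label_table <- function() {
  cort <- data.frame(
    label = 1:90,
    name = as.vector(t(outer(.aal_cortical_stems, c("_L", "_R"), paste0))),
    class = "cortical",
    laterality = rep(c("L", "R"), 45),
    stringsAsFactors = FALSE)
  cer <- data.frame(
    label = 91:106,
    name = c(paste0(.aal_cerebellar_stems, "_L"),
             paste0(.aal_cerebellar_stems, "_R"),
             c("Vermis_1_2", "Vermis_3_5", "Vermis_6_7", "Vermis_8_10")),
    class = "cerebellar",
    laterality = c(rep("L", 6), rep("R", 6), rep("V", 4)),
    stringsAsFactors = FALSE)
  rbind(cort, cer)
}

#' Default cerebellar label split by laterality
#'
#' @return Named list with integer label vectors `left`, `right`, `vermis`.
#' @export
aal_cerebellar_labels <- function() {
  tab <- aal_label_table()
  cer <- tab[tab$class == "cerebellar", ]
  list(left = cer$label[cer$laterality == "L"],
       right = cer$label[cer$laterality == "R"],
       vermis = cer$label[cer$laterality == "V"])
}

#' Merge cerebellar parcels into three super-regions
#'
#' Collapses the 16 cerebellar parcels into right cerebellum, left cerebellum
#' and vermis, leaving all other labels untouched. Starting from the full
#' AAL inventory (90 cortical + 16 cerebellar parcels) this yields the
#' 93 network nodes used throughout the analysis. Each merged group is
#' relabeled to the smallest label it contains, so label identity is stable.
#'
#' @param pm a `parcel_map`.
#' @param cerebellar named list with integer vectors `left`, `right`,
#'   `vermis`; defaults to [aal_cerebellar_labels()].
#' @param strict if `TRUE`, missing cerebellar labels are an error; default
#'   is a warning and an unchanged map.
#' @return A `parcel_map` with `merged = TRUE` (or the input, unchanged, when
#'   no cerebellar label is present and `strict = FALSE`).
#' @export
merge_cerebellar_labels <- function(pm, cerebellar = aal_cerebellar_labels(),
                                    strict = FALSE) {
  stopifnot(inherits(pm, "parcel_map"))
  stopifnot(all(c("left", "right", "vermis") %in% names(cerebellar)))
  expected <- sort(unlist(cerebellar, use.names = FALSE))
  present <- node_labels(pm)
  found <- intersect(expected, present)
  if (length(found) == 0L) {
    msg <- "no expected cerebellar labels present; map returned unchanged"
    if (strict) stop(msg)
    warning(msg)
    return(pm)
  }
  if (length(found) < length(expected)) {
    msg <- sprintf("only %d of %d expected cerebellar labels present",
                   length(found), length(expected))
    if (strict) stop(msg)
    warning(msg)
  }
  super_names <- c(left = "Cerebellum_L", right = "Cerebellum_R",
                   vermis = "Vermis")
  lab <- pm$labels
  tab <- pm$label_table
  for (side in c("left", "right", "vermis")) {
    grp <- intersect(cerebellar[[side]], present)
    if (length(grp) == 0L) next
    target <- min(grp)
    lab[lab %in% grp] <- target
    tab <- tab[!(tab$label %in% setdiff(grp, target)), , drop = FALSE]
    tab$name[tab$label == target] <- super_names[[side]]
  }
  parcel_map(lab, label_table = tab, merged = TRUE)
}
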