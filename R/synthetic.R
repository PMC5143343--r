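# Synthetic data: toy parcellations and streamline sets, single random
# connectomes, and full two-group multi-age cohorts with covariates and
# neurobehavioral scores. Everything is deterministic given its seed.
#
# Cohort generative model (the simplest model whose induced metrics are
# tunable): edge presence is Bernoulli with a per-subject connection density
# chosen so the group mean degree hits its target, and edge weights are
# truncated normal on [0, 1] with the location solved so the truncated mean
# hits the target FA weight. Degree and strength are therefore controlled
# directly; efficiencies and clustering emerge from density and weights,
# which preserves the qualitative group ordering (lower degree/weights in
# the restricted-growth group => lower binary/FA-weighted efficiencies and
# higher normalized efficiencies) without pinning their absolute values.

# --- truncated normal ------------------------------------------------------

# inverse-CDF sampler; sd = 0 degenerates to the point mass at `mean`
rtrunc_norm <- function(n, mean, sd, lo = 0, hi = 1) {
  if (sd <= 0) return(rep(pmin(pmax(mean, lo), hi), n))
  plo <- pnorm(lo, mean, sd)
  phi <- pnorm(hi, mean, sd)
  qnorm(runif(n, plo, phi), mean, sd)
}

.truncnorm_mean <- function(mu, sd, lo = 0, hi = 1) {
  a <- (lo - mu) / sd; b <- (hi - mu) / sd
  z <- pnorm(b) - pnorm(a)
  if (z < 1e-12) return(pmin(pmax(mu, lo), hi))
  mu + sd * (dnorm(a) - dnorm(b)) / z
}

# location mu such that the [lo, hi]-truncated N(mu, sd) has mean `target`
solve_truncnorm_mu <- function(target, sd, lo = 0, hi = 1) {
  if (sd <= 0) return(target)
  if (target <= lo || target >= hi)
    stop("target truncated mean must lie strictly inside [lo, hi]")
  f <- function(mu) .truncnorm_mean(mu, sd, lo, hi) - target
  stats::uniroot(f, lower = lo - 10 * sd, upper = hi + 10 * sd,
                 tol = 1e-12)$root
}

# --- toy parcellations and streamlines -------------------------------------

#' Generate a toy parcellation
#'
#' Voronoi-style partition of a voxel grid: `n_regions` seed voxels are
#' drawn, every voxel is assigned its nearest seed (lowest label on ties),
#' and a fraction of the voxels farthest from any seed is relabeled as
#' background (seed voxels are never dropped, so every label keeps at least
#' one voxel).
#'
#' @param grid_dims integer vector of length 3 (voxels per axis).
#' @param n_regions number of regions, at least 2.
#' @param seed integer seed; fully determines the map.
#' @param background_frac fraction of voxels relabeled to background 0.
#' @return A [parcel_map()].
#' @export
make_toy_parcellation <- function(grid_dims, n_regions, seed = 1,
                                  background_frac = 0.1) {
  grid_dims <- as.integer(grid_dims)
  if (length(grid_dims) != 3 || any(grid_dims < 1))
    stop("`grid_dims` must be 3 positive integers")
  if (n_regions < 2) stop("`n_regions` must be at least 2")
  nvox <- prod(grid_dims)
  if (nvox < n_regions)
    stop(sprintf("grid with %d voxels cannot host %d regions",
                 nvox, n_regions))
  set.seed(seed)
  coords <- as.matrix(expand.grid(x = seq_len(grid_dims[1]),
                                  y = seq_len(grid_dims[2]),
                                  z = seq_len(grid_dims[3])))
  centers <- sample.int(nvox, n_regions)
  d2 <- matrix(0, nvox, n_regions)
  for (r in seq_len(n_regions)) {
    d2[, r] <- colSums((t(coords) - coords[centers[r], ])^2)
  }
  lab <- max.col(-d2, ties.method = "first")
  mind <- d2[cbind(seq_len(nvox), lab)]
  if (background_frac > 0) {
    n_bg <- floor(background_frac * nvox)
    cand <- setdiff(order(mind, decreasing = TRUE), centers)
    lab[cand[seq_len(min(n_bg, length(cand)))]] <- 0L
  }
  parcel_map(array(as.integer(lab), dim = grid_dims))
}

#' Toy parcellation carrying the full AAL-style inventory
#'
#' Convenience wrapper producing a toy voxel map whose 106 labels are the
#' full inventory of [aal_label_table()] (90 cortical + 16 cerebellar
#' parcels), ready for [merge_cerebellar_labels()].
#'
#' @param grid_dims grid size, default `c(12, 12, 6)`.
#' @param seed integer seed.
#' @return A [parcel_map()] with 106 regions and AAL names.
#' @export
make_aal_toy_parcellation <- function(grid_dims = c(12, 12, 6), seed = 1) {
  tab <- aal_label_table()
  pm <- make_toy_parcellation(grid_dims, n_regions = nrow(tab), seed = seed,
                              background_frac = 0)
  parcel_map(pm$labels, label_table = tab)
}

#' Generate toy streamlines over a parcellation
#'
#' Streamlines are straight segments (plus small jitter) between two random
#' labeled voxels, with a per-streamline mean-FA value drawn uniformly from
#' `fa_range`. Generated FA values are floored at `fa_floor` (the
#' tractography stop threshold: streamlines with lower anisotropy would not
#' have been reconstructed).
#'
#' @param pm a `parcel_map` with at least one labeled voxel.
#' @param n_streamlines number of streamlines (0 gives an empty set).
#' @param fa_range length-2 numeric in `[0, 1]`.
#' @param seed integer seed.
#' @param fa_floor lower bound applied to generated FA values (default 0.1);
#'   ignored when the requested range lies entirely above it.
#' @param n_points points per streamline (>= 2).
#' @return A [streamline_set()].
#' @export
make_toy_streamlines <- function(pm, n_streamlines, fa_range = c(0.1, 0.9),
                                 seed = 1, fa_floor = 0.1, n_points = 5) {
  stopifnot(inherits(pm, "parcel_map"))
  if (length(fa_range) != 2 || any(fa_range < 0) || any(fa_range > 1) ||
      fa_range[1] > fa_range[2])
    stop("`fa_range` must be an ordered pair within [0, 1]")
  if (n_points < 2) stop("`n_points` must be at least 2")
  labeled <- which(pm$labels > 0)
  if (length(labeled) == 0) stop("parcel map has no labeled voxels")
  if (n_streamlines == 0) return(streamline_set(list(), numeric(0)))
  set.seed(seed)
  d <- dim(pm$labels)
  lo <- min(max(fa_range[1], fa_floor), fa_range[2])
  pts <- vector("list", n_streamlines)
  for (s in seq_len(n_streamlines)) {
    vox <- sample(labeled, 2, replace = length(labeled) == 1)
    ends <- t(vapply(vox, function(v) arrayInd(v, d)[1, ], numeric(3)))
    a <- ends[1, ] - 0.5   # 0-based voxel-center coordinates
    b <- ends[2, ] - 0.5
    tseq <- seq(0, 1, length.out = n_points)
    path <- outer(1 - tseq, a) + outer(tseq, b)
    mid <- seq_len(n_points)[-c(1, n_points)]
    if (length(mid))
      path[mid, ] <- path[mid, ] + matrix(rnorm(3 * length(mid), 0, 0.15),
                                          ncol = 3)
    # keep jittered interior points inside the grid
    path <- pmin(pmax(path, 0), rep(d - 1e-9, each = n_points))
    pts[[s]] <- path
  }
  fa <- runif(n_streamlines, lo, fa_range[2])
  streamline_set(pts, fa)
}

#' Simulate a single random connectome
#'
#' Erdos-Renyi edge presence at the requested density with truncated-normal
#' FA-like weights on `[0, 1]` whose truncated mean equals `weight_mean`.
#'
#' @param n_nodes number of nodes (>= 2).
#' @param density edge probability in `(0, 1]`.
#' @param weight_mean target mean edge weight, strictly inside `(0, 1)`.
#' @param weight_sd weight spread before truncation.
#' @param seed integer seed.
#' @return An `fa_weighted` [connectome()].
#' @export
simulate_connectome <- function(n_nodes, density = 0.5, weight_mean = 0.3,
                                weight_sd = 0.05, seed = 1) {
  if (n_nodes < 2) stop("`n_nodes` must be at least 2")
  if (density <= 0 || density > 1) stop("`density` must be in (0, 1]")
  set.seed(seed)
  mu <- solve_truncnorm_mu(weight_mean, weight_sd)
  W <- matrix(0, n_nodes, n_nodes)
  ut <- upper.tri(W)
  m <- sum(ut)
  present <- runif(m) < density
  w <- numeric(m)
  w[present] <- rtrunc_norm(sum(present), mu, weight_sd)
  W[ut] <- w
  W <- W + t(W)
  connectome(W, variant = "fa_weighted")
}

# binary/FA-weighted/FA-normalized triplet from one weighted matrix
.connectome_triplet <- function(faw) {
  list(binary = connectome((faw$weights > 0) * 1, nodes = faw$nodes,
                           variant = "binary"),
       fa_weighted = faw,
       fa_normalized = normalize_total_strength(faw))
}

# --- cohort design ---------------------------------------------------------

# Per-cell calibration: group sizes, gestational age and ages at scan/test,
# target mean degree and FA-weight parameters, emulating a two-group preterm
# cohort (control vs. IUGR) evaluated at 1, 6 and 10 years. At 1 year the
# published strength statistic is an average nodal strength, so the edge
# weight is its ratio to the degree; at 6/10 years it is already an average
# edge weight and is used as-is.
.default_cells <- function() {
  cells <- rbind(
    data.frame(age = 1, group = c("control", "IUGR"), n = c(7, 8),
               ga_mean = c(32.2, 30.9), ga_sd = c(1.7, 1.7),
               age_scan_mean = c(1.1, 1.0), age_scan_sd = c(0.2, 0.1),
               age_test_mean = c(1.7, 1.7), age_test_sd = c(0.3, 0.4),
               degree_mean = c(60.24, 56.87), degree_sd = c(1.26, 2.57),
               weight_mean = c(19.05 / 60.24, 17.61 / 56.87),
               weight_sd = c(0.93 / 60.24, 1.68 / 56.87)),
    data.frame(age = 6, group = c("control", "IUGR"), n = c(8, 10),
               ga_mean = c(32.4, 32.6), ga_sd = c(2.3, 1.5),
               age_scan_mean = c(6.8, 6.9), age_scan_sd = c(0.6, 0.7),
               age_test_mean = c(6.3, 6.2), age_test_sd = c(0.7, 0.5),
               degree_mean = c(55.13, 53.65), degree_sd = c(3.72, 2.96),
               weight_mean = c(0.210, 0.198), weight_sd = c(0.010, 0.011)),
    data.frame(age = 10, group = c("control", "IUGR"), n = c(8, 8),
               ga_mean = c(32.5, 32.7), ga_sd = c(1.8, 1.5),
               age_scan_mean = c(10.0, 10.2), age_scan_sd = c(1.0, 1.0),
               age_test_mean = c(9.8, 10.0), age_test_sd = c(1.0, 0.9),
               degree_mean = c(53.14, 48.88), degree_sd = c(1.735, 6.522),
               weight_mean = c(0.204, 0.187), weight_sd = c(0.011, 0.019)))
  cells
}

# Default score models: each links one score to one network metric with a
# target age-residualized partial correlation, on the instrument's scale
# (developmental quotients: mean 100, SD 15; BRIEF indices as T-scores;
# SDQ hyperactivity/inattention 0-10; CPM raw score).
.default_score_models <- function() {
  list(
    list(age = 1, name = "bsid_cognitive", metric = "faw_strength",
         rho = 0.6359, mean = 100, sd = 15),
    list(age = 1, name = "bsid_motor", metric = "faw_global_eff",
         rho = 0.6842, mean = 100, sd = 15),
    list(age = 1, name = "bsid_socio_emotional", metric = "faw_strength",
         rho = 0.9001, mean = 100, sd = 15),
    list(age = 6, name = "brief_bri", metric = "bin_local_eff",
         rho = -0.6182, mean = 50, sd = 10),
    list(age = 10, name = "sdq_hyperactivity", metric = "faw_global_eff",
         rho = -0.9239, mean = 4, sd = 2),
    list(age = 10, name = "brief_bri", metric = "fan_global_eff",
         rho = 0.6015, mean = 50, sd = 10),
    list(age = 10, name = "cpm_raw", metric = "faw_strength",
         rho = 0.6344, mean = 30, sd = 5))
}

#' Specify a synthetic cohort design
#'
#' @param cells data frame with one row per (age, group) cell and columns
#'   `age`, `group` (`"control"`/`"IUGR"`), `n`, `ga_mean`, `ga_sd`,
#'   `age_scan_mean`, `age_scan_sd`, `age_test_mean`, `age_test_sd`,
#'   `degree_mean`, `degree_sd`, `weight_mean`, `weight_sd`.
#' @param n_nodes connectome size (default 93 nodes).
#' @param seed integer seed; fully determines the generated cohort.
#' @param score_models list of score specifications (see
#'   [simulate_scores()]); each is a list with `age`, `name`, `metric`,
#'   `rho`, `mean`, `sd`.
#' @param weight_sd_within within-subject spread of edge weights.
#' @param gender_p probability of gender code 1.
#' @param edu_probs proportions of the three ordinal maternal-education
#'   levels.
#' @param metric_targets optional reference table of target metric means/SDs
#'   (columns `metric`, `age`, `group`, `mean`, `sd`) used for validation
#'   and calibration checks.
#' @return An object of class `cohort_design`.
#' @export
cohort_design <- function(cells, n_nodes = 93, seed = 1,
                          score_models = list(), weight_sd_within = 0.05,
                          gender_p = 0.5, edu_probs = c(0.3, 0.4, 0.3),
                          metric_targets = NULL) {
  need <- c("age", "group", "n", "ga_mean", "ga_sd", "age_scan_mean",
            "age_scan_sd", "age_test_mean", "age_test_sd", "degree_mean",
            "degree_sd", "weight_mean", "weight_sd")
  if (!all(need %in% names(cells)))
    stop("`cells` is missing columns: ",
         paste(setdiff(need, names(cells)), collapse = ", "))
  if (any(cells$n < 1)) stop("group sizes must be at least 1")
  sds <- c(cells$ga_sd, cells$age_scan_sd, cells$age_test_sd,
           cells$degree_sd, cells$weight_sd, weight_sd_within)
  if (any(sds < 0)) stop("standard deviations must be non-negative")
  if (!all(cells$group %in% c("control", "IUGR")))
    stop("`group` must be 'control' or 'IUGR'")
  if (n_nodes < 2) stop("`n_nodes` must be at least 2")
  if (any(cells$degree_mean <= 0 | cells$degree_mean > n_nodes - 1))
    stop("target mean degree must lie in (0, n_nodes - 1]: unreachable design")
  if (any(cells$weight_mean <= 0 | cells$weight_mean >= 1))
    stop("target mean FA weight must lie strictly inside (0, 1)")
  for (m in score_models) {
    stopifnot(all(c("age", "name", "metric", "rho", "mean", "sd") %in%
                    names(m)))
    if (abs(m$rho) > 1)
      stop("target partial correlation must lie in [-1, 1]")
  }
  if (!is.null(metric_targets)) {
    bounded <- metric_targets$metric %in%
      c("bin_global_eff", "bin_local_eff", "bin_clustering")
    if (any(metric_targets$mean[bounded] > 1) || any(metric_targets$mean < 0))
      stop("binary efficiency/clustering targets must lie in [0, 1]: ",
           "unreachable design")
    if (any(metric_targets$sd < 0)) stop("target SDs must be non-negative")
  }
  if (abs(sum(edu_probs) - 1) > 1e-8 || any(edu_probs < 0))
    stop("`edu_probs` must be non-negative and sum to 1")
  structure(list(cells = cells, n_nodes = n_nodes, seed = as.integer(seed),
                 score_models = score_models,
                 weight_sd_within = weight_sd_within,
                 gender_p = gender_p, edu_probs = edu_probs,
                 metric_targets = metric_targets),
            class = "cohort_design")
}

#' Default cohort design calibrated to the study conditions
#'
#' Two groups (control, IUGR) at ages 1, 6 and 10 years, 93-node
#' connectomes, with gestational ages, ages at scan/test, group sizes and
#' degree/FA-weight targets taken from the published cohort tables, and
#' score models inducing the reported metric-score partial correlations.
#'
#' @param ages subset of `c(1, 6, 10)` to include.
#' @param n_per_group optional common group size overriding the published
#'   sample sizes (useful for power/calibration studies).
#' @param n_nodes connectome size.
#' @param seed integer seed.
#' @return A [cohort_design()].
#' @export
default_cohort_design <- function(ages = c(1, 6, 10), n_per_group = NULL,
                                  n_nodes = 93, seed = 1) {
  cells <- .default_cells()
  cells <- cells[cells$age %in% ages, , drop = FALSE]
  if (nrow(cells) == 0) stop("`ages` must intersect c(1, 6, 10)")
  if (!is.null(n_per_group)) cells$n <- n_per_group
  models <- Filter(function(m) m$age %in% ages, .default_score_models())
  cohort_design(cells, n_nodes = n_nodes, seed = seed, score_models = models)
}

#' @export
print.cohort_design <- function(x, ...) {
  cat(sprintf("<cohort_design> %d cells, %d subjects, %d-node connectomes, seed %d\n",
              nrow(x$cells), sum(x$cells$n), x$n_nodes, x$seed))
  print(x$cells[, c("age", "group", "n", "degree_mean", "weight_mean")],
        row.names = FALSE)
  invisible(x)
}

# --- cohort simulation -----------------------------------------------------

# per-subject density draw: the between-subject SD of the latent mean degree
# is chosen so that, combined with the Bernoulli sampling noise of the edge
# count, the observed degree SD matches its target
.subject_densities <- function(n, n_nodes, degree_mean, degree_sd) {
  npairs <- choose(n_nodes, 2)
  p <- degree_mean / (n_nodes - 1)
  var_bin <- (2 / n_nodes)^2 * npairs * p * (1 - p)
  between_sd <- sqrt(max(0, degree_sd^2 - var_bin)) / (n_nodes - 1)
  pi <- rnorm(n, p, between_sd)
  pmin(pmax(pi, 1 / (n_nodes - 1)), 1)
}

.simulate_subject_connectomes <- function(p, w_target, w_sd_within, n_nodes) {
  W <- matrix(0, n_nodes, n_nodes)
  ut <- upper.tri(W)
  m <- sum(ut)
  present <- runif(m) < p
  w <- numeric(m)
  if (any(present)) {
    mu <- solve_truncnorm_mu(w_target, w_sd_within)
    w[present] <- rtrunc_norm(sum(present), mu, w_sd_within)
  }
  W[ut] <- w
  W <- W + t(W)
  .connectome_triplet(connectome(W, variant = "fa_weighted"))
}

#' Simulate a full two-group multi-age cohort
#'
#' Generates, per design cell, subjects with covariates (gestational age,
#' gender, maternal education, ages at scan and test) and the three
#' connectome variants, using the Bernoulli-density / truncated-normal
#' weight model described in the package vignette. The group mean degree and
#' strength track the cell targets; efficiency and clustering group
#' orderings follow from the density and weight orderings.
#'
#' @param design a [cohort_design()].
#' @return An object of class `connectome_cohort`: list with `subjects`
#'   (each carrying `id`, `group`, `age_cohort`, covariates and a
#'   `connectomes` triplet) and `design`.
#' @export
simulate_cohort <- function(design) {
  stopifnot(inherits(design, "cohort_design"))
  set.seed(design$seed)
  n_nodes <- design$n_nodes
  subjects <- list()
  for (ci in seq_len(nrow(design$cells))) {
    cell <- design$cells[ci, ]
    dens <- .subject_densities(cell$n, n_nodes, cell$degree_mean,
                               cell$degree_sd)
    w_means <- pmin(pmax(rnorm(cell$n, cell$weight_mean, cell$weight_sd),
                         0.02), 0.98)
    for (s in seq_len(cell$n)) {
      id <- sprintf("a%02d_%s_%02d", cell$age,
                    if (cell$group == "IUGR") "iugr" else "ctrl", s)
      subjects[[length(subjects) + 1L]] <- list(
        id = id,
        group = cell$group,
        age_cohort = cell$age,
        gender = as.integer(runif(1) < design$gender_p),
        ga_weeks = max(rnorm(1, cell$ga_mean, cell$ga_sd), 24),
        maternal_edu = sample.int(3, 1, prob = design$edu_probs),
        age_scan = max(rnorm(1, cell$age_scan_mean, cell$age_scan_sd), 0.1),
        age_test = max(rnorm(1, cell$age_test_mean, cell$age_test_sd), 0.1),
        connectomes = .simulate_subject_connectomes(
          dens[s], w_means[s], design$weight_sd_within, n_nodes))
    }
  }
  structure(list(subjects = subjects, design = design),
            class = "connectome_cohort")
}

#' @export
print.connectome_cohort <- function(x, ...) {
  md <- cohort_metadata(x)
  cat(sprintf("<connectome_cohort> %d subjects, %d-node connectomes\n",
              nrow(md), x$design$n_nodes))
  print(table(age = md$age_cohort, group = md$group))
  invisible(x)
}

#' Cohort metadata table
#'
#' @param cohort a `connectome_cohort`.
#' @return data frame with one row per subject: `subject_id`, `group`,
#'   `age_cohort`, `gender`, `ga_weeks`, `maternal_edu`, `age_scan`,
#'   `age_test`.
#' @export
cohort_metadata <- function(cohort) {
  stopifnot(inherits(cohort, "connectome_cohort"))
  do.call(rbind, lapply(cohort$subjects, function(s)
    data.frame(subject_id = s$id, group = s$group, age_cohort = s$age_cohort,
               gender = s$gender, ga_weeks = s$ga_weeks,
               maternal_edu = s$maternal_edu, age_scan = s$age_scan,
               age_test = s$age_test, stringsAsFactors = FALSE)))
}

#' Simulate neurobehavioral scores linked to network metrics
#'
#' For each score model, the score is built as a linear function of the
#' linked metric's confounder-adjusted residual plus an age-at-test trend
#' and Gaussian noise whose variance is solved from the target partial
#' correlation, then rescaled to the instrument's mean and SD. For large
#' cohorts, the age-residualized partial correlation between the score and
#' its metric (confounders: gender, gestational age, maternal education,
#' group) recovers the target. Affine rescaling leaves the partial
#' correlation untouched, so the calibration is analytically exact in
#' population terms.
#'
#' @param cohort a `connectome_cohort`.
#' @param metric_table metric table from [cohort_metric_table()].
#' @param models list of score models (default: the design's); each a list
#'   with `age`, `name`, `metric`, `rho` (target partial correlation),
#'   `mean`, `sd`.
#' @param seed integer seed (default: design seed + 1).
#' @return data frame with `subject_id` and one column per score (NA for
#'   subjects outside a score's age cell).
#' @export
simulate_scores <- function(cohort, metric_table, models = NULL,
                            seed = NULL) {
  stopifnot(inherits(cohort, "connectome_cohort"))
  if (is.null(models)) models <- cohort$design$score_models
  if (is.null(seed)) seed <- cohort$design$seed + 1L
  set.seed(seed)
  md <- cohort_metadata(cohort)
  dat <- merge(md, metric_table, by = "subject_id", sort = FALSE)
  out <- data.frame(subject_id = md$subject_id, stringsAsFactors = FALSE)
  for (m in models) {
    if (abs(m$rho) > 1) stop("target partial correlation out of [-1, 1]")
    if (!m$metric %in% names(dat))
      stop(sprintf("metric '%s' not present for every subject", m$metric))
    sel <- dat$age_cohort == m$age
    n <- sum(sel)
    score <- rep(NA_real_, nrow(out))
    if (n >= 3) {
      d <- dat[sel, ]
      X <- cbind(1, d$age_scan, d$gender, d$ga_weeks, d$maternal_edu,
                 as.integer(d$group == "IUGR"))
      r <- if (n > ncol(X)) resid(lm.fit(X, d[[m$metric]]))
           else d[[m$metric]] - mean(d[[m$metric]])
      sr <- sd(r)
      if (m$rho == 0 || sr == 0) {
        core <- rnorm(n)
      } else {
        sd_eps <- sr * sqrt(1 - m$rho^2) / abs(m$rho)
        core <- sign(m$rho) * r + rnorm(n, 0, sd_eps)
      }
      sa <- sd(d$age_test)
      if (sa > 0 && sd(core) > 0)
        core <- core + 0.5 * sd(core) / sa * (d$age_test - mean(d$age_test))
      z <- if (sd(core) > 0) (core - mean(core)) / sd(core)
           else rep(0, n)
      score[match(d$subject_id, out$subject_id)] <- m$mean + m$sd * z
    }
    out[[m$name]] <- score
  }
  out
}
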