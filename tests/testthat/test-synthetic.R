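# Synthetic-data generators: determinism, sampling checks, calibration of
# the cohort model, and score generation with injected partial correlations.

small_cells <- function(n = 10, degree_ctrl = 8, degree_iugr = 8,
                        w_ctrl = 0.3, w_iugr = 0.3) {
  data.frame(age = 1, group = c("control", "IUGR"), n = n,
             ga_mean = c(32, 31), ga_sd = 1.5,
             age_scan_mean = 1.1, age_scan_sd = 0.2,
             age_test_mean = 1.7, age_test_sd = 0.3,
             degree_mean = c(degree_ctrl, degree_iugr), degree_sd = 1.2,
             weight_mean = c(w_ctrl, w_iugr), weight_sd = 0.02)
}

test_that("toy streamline generation obeys its contracts", {
  pm <- make_toy_parcellation(c(6, 6, 2), 4, seed = 1)
  expect_length(make_toy_streamlines(pm, 0, seed = 1), 0)
  # degenerate FA range pins every value
  sl <- make_toy_streamlines(pm, 20, c(0.5, 0.5), seed = 2)
  expect_true(all(sl$fa == 0.5))
  sl <- make_toy_streamlines(pm, 100, c(0.1, 0.9), seed = 3)
  expect_length(sl, 100)
  expect_true(all(sl$fa >= 0.1 & sl$fa <= 0.9))
  expect_true(all(vapply(sl$points, nrow, integer(1)) >= 2))
  d <- dim(pm$labels)
  inside <- vapply(sl$points, function(p)
    all(p >= 0) && all(t(p) <= d), logical(1))
  expect_true(all(inside))
  # generated FA never drops below the tractography stop threshold
  sl_low <- make_toy_streamlines(pm, 50, c(0.0, 0.6), seed = 4)
  expect_true(all(sl_low$fa >= 0.1))
  # determinism
  expect_identical(make_toy_streamlines(pm, 10, seed = 5)$points,
                   make_toy_streamlines(pm, 10, seed = 5)$points)
  empty <- parcel_map(array(0L, c(2, 2, 1)))
  expect_error(make_toy_streamlines(empty, 5), "no labeled voxels")
})

test_that("simulated connectomes hit density and weight targets", {
  # density 1 on 5 nodes: the complete graph with 10 undirected edges
  full <- simulate_connectome(5, density = 1, weight_mean = 0.4,
                              weight_sd = 0.05, seed = 1)
  expect_equal(sum(full$weights[upper.tri(full$weights)] > 0), 10)
  # seed repetition is bit-identical
  expect_identical(simulate_connectome(20, 0.4, 0.3, 0.05, seed = 9)$weights,
                   simulate_connectome(20, 0.4, 0.3, 0.05, seed = 9)$weights)
  # mean realized edge weight within 3 SE of target
  conn <- simulate_connectome(93, 0.65, 0.21, 0.01, seed = 11)
  w <- conn$weights[upper.tri(conn$weights)]
  w <- w[w > 0]
  expect_lt(abs(mean(w) - 0.21), 3 * 0.01 / sqrt(length(w)))
  expect_true(all(w >= 0 & w <= 1))
  expect_error(simulate_connectome(1, 0.5), "at least 2")
  expect_error(simulate_connectome(10, 0), "density")
})

test_that("cohort generation is seed-deterministic and validates designs", {
  d <- cohort_design(small_cells(4), n_nodes = 16, seed = 3)
  c1 <- simulate_cohort(d)
  c2 <- simulate_cohort(d)
  expect_identical(cohort_metadata(c1), cohort_metadata(c2))
  expect_identical(c1$subjects[[5]]$connectomes$fa_weighted$weights,
                   c2$subjects[[5]]$connectomes$fa_weighted$weights)
  expect_equal(length(c1$subjects), 8)
  # unreachable targets are design errors
  expect_error(cohort_design(small_cells(4, degree_ctrl = 20), n_nodes = 16),
               "unreachable")
  expect_error(cohort_design(small_cells(4), n_nodes = 16,
                             score_models = list(list(age = 1, name = "s",
                                                      metric = "bin_degree",
                                                      rho = 1.2, mean = 0,
                                                      sd = 1))),
               "\\[-1, 1\\]")
  bad <- small_cells(4); bad$degree_sd <- -1
  expect_error(cohort_design(bad, n_nodes = 16), "non-negative")
  tgt <- data.frame(metric = "bin_global_eff", age = 1, group = "control",
                    mean = 1.2, sd = 0.1)
  expect_error(cohort_design(small_cells(4), n_nodes = 16,
                             metric_targets = tgt), "unreachable")
})

test_that("generated group means calibrate to the degree/strength targets", {
  d <- default_cohort_design(ages = 1, n_per_group = 50, seed = 42)
  ch <- simulate_cohort(d)
  md <- cohort_metadata(ch)
  deg <- vapply(ch$subjects, function(s)
    average_degree(s$connectomes$binary), numeric(1))
  str <- vapply(ch$subjects, function(s)
    average_strength(s$connectomes$fa_weighted), numeric(1))
  for (g in c("control", "IUGR")) {
    cell <- d$cells[d$cells$group == g, ]
    sel <- md$group == g
    expect_lt(abs(mean(deg[sel]) - cell$degree_mean), 1.0)
    # calibration bound: generated mean within half a generated SD
    expect_lt(abs(mean(deg[sel]) - cell$degree_mean), 0.5 * sd(deg[sel]))
    target_strength <- cell$degree_mean * cell$weight_mean
    expect_lt(abs(mean(str[sel]) - target_strength), 0.5 * sd(str[sel]))
  }
  # covariates follow the design distributions (loose sampling checks)
  expect_lt(abs(mean(md$ga_weeks[md$group == "control"]) - 32.2),
            3 * 1.7 / sqrt(50))
  expect_true(all(md$maternal_edu %in% 1:3))
  expect_true(all(md$gender %in% 0:1))
})

test_that("null designs keep the downstream group test at its nominal level", {
  d0 <- cohort_design(small_cells(10), n_nodes = 16, seed = 1)
  rejections <- 0L
  n_rep <- 500
  tstats <- numeric(n_rep)
  for (r in seq_len(n_rep)) {
    d0$seed <- r
    ch <- simulate_cohort(d0)
    md <- cohort_metadata(ch)
    deg <- vapply(ch$subjects, function(s)
      average_degree(s$connectomes$binary), numeric(1))
    X <- build_design_matrix(md, "metric")
    cmp <- glm_group_compare(deg, X)
    tstats[r] <- cmp$t
    if (cmp$p < 0.05) rejections <- rejections + 1L
  }
  rate <- rejections / n_rep
  expect_gte(rate, 0.02)
  expect_lte(rate, 0.08)
  # equal-target design: group differences center on zero
  expect_lt(abs(mean(tstats)), 0.15)
})

test_that("score generation recovers injected partial correlations", {
  d <- cohort_design(small_cells(250), n_nodes = 16, seed = 7,
                     weight_sd_within = 0.05)
  ch <- simulate_cohort(d)
  md <- cohort_metadata(ch)
  mt <- data.frame(subject_id = md$subject_id,
                   faw_strength = vapply(ch$subjects, function(s)
                     average_strength(s$connectomes$fa_weighted), numeric(1)))
  models <- list(
    list(age = 1, name = "null_score", metric = "faw_strength", rho = 0,
         mean = 100, sd = 15),
    list(age = 1, name = "linked_score", metric = "faw_strength", rho = 0.9,
         mean = 100, sd = 15))
  sc <- simulate_scores(ch, mt, models = models, seed = 99)
  conf <- cbind(gender = md$gender, ga = md$ga_weeks,
                edu = md$maternal_edu, group = as.numeric(md$group == "IUGR"))
  mres <- residualize_by_age(mt$faw_strength, md$age_scan)
  # null link: empirical partial rho within +/- 0.1 at n = 500
  p0 <- partial_correlation(mres,
                            residualize_by_age(sc$null_score, md$age_test),
                            conf)
  expect_lt(abs(p0$rho), 0.1)
  # strong link emulating the strongest reported metric-score association
  p9 <- partial_correlation(mres,
                            residualize_by_age(sc$linked_score, md$age_test),
                            conf)
  expect_gt(p9$rho, 0.85)
  expect_lt(p9$rho, 0.95)
  # instrument scale: mean within 3 SE of 100 (here exact by construction)
  expect_lt(abs(mean(sc$linked_score) - 100), 3 * 15 / sqrt(500))
  expect_equal(sd(sc$linked_score), 15, tolerance = 1e-8)
  # a score referencing a missing metric is an input error
  expect_error(simulate_scores(ch, mt, models = list(
    list(age = 1, name = "x", metric = "bin_degree", rho = 0.5,
         mean = 0, sd = 1))), "not present")
})
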