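# Connectome construction: endpoint assignment, edge accumulation,
# normalization, thresholding, group averaging.

# 3-region toy map on a 5x5x1 grid with an explicit background corridor
toy_map <- function() {
  lab <- array(0L, dim = c(5, 5, 1))
  lab[1:2, , 1] <- 1L
  lab[4:5, 1:2, 1] <- 2L
  lab[4:5, 4:5, 1] <- 3L
  parcel_map(lab)
}

straight_line <- function(a, b, n = 4) {
  tseq <- seq(0, 1, length.out = n)
  outer(1 - tseq, a) + outer(tseq, b)
}

test_that("endpoints map to containing-voxel labels, excluding self-loops", {
  pm <- toy_map()
  # centers of voxels (1,1,1) [label 1] and (5,1,1) [label 2]
  expect_equal(endpoints_to_regions(straight_line(c(0.5, 0.5, 0.5),
                                                  c(4.5, 0.5, 0.5)), pm),
               c(1, 2))
  same <- endpoints_to_regions(straight_line(c(0.5, 0.5, 0.5),
                                             c(1.5, 3.5, 0.5)), pm)
  expect_length(same, 0)
  expect_equal(attr(same, "reason"), "self_loop")
  out <- endpoints_to_regions(straight_line(c(0.5, 0.5, 0.5),
                                            c(9.5, 0.5, 0.5)), pm)
  expect_length(out, 0)
  expect_equal(attr(out, "reason"), "outside")
})

test_that("background endpoints take the nearest label within the radius", {
  pm <- toy_map()
  # voxel (3,1,1) is background; its labeled neighbors at distance 1 are
  # (2,1,1) -> 1 and (4,1,1) -> 2; exhaustive scan of the toy grid confirms
  # the nearest-label rule resolves the distance-1 tie to the lowest label 1.
  dists <- expand.grid(x = 1:5, y = 1:5, z = 1)
  dists$lab <- apply(dists, 1, function(v) pm$labels[v[1], v[2], v[3]])
  labeled <- dists[dists$lab > 0, ]
  d2 <- (labeled$x - 3)^2 + (labeled$y - 1)^2
  nearest <- labeled$lab[d2 == min(d2)]
  expect_equal(sort(unique(nearest)), c(1, 2))   # genuine tie
  ep <- endpoints_to_regions(straight_line(c(2.5, 0.5, 0.5),
                                           c(4.5, 4.5, 0.5)), pm)
  expect_equal(ep[1], min(nearest))
  # with a zero radius the same endpoint is unassignable
  un <- endpoints_to_regions(straight_line(c(2.5, 0.5, 0.5),
                                           c(4.5, 4.5, 0.5)), pm, radius = 0)
  expect_equal(attr(un, "reason"), "unassigned")
})

test_that("two streamlines between a pair give binary 1 and mean FA weight", {
  pm <- toy_map()
  p <- straight_line(c(0.5, 0.5, 0.5), c(4.5, 0.5, 0.5))
  sl <- streamline_set(list(p, p[nrow(p):1, ]), fa = c(0.2, 0.4))
  built <- build_connectomes(sl, pm)
  expect_equal(built$binary$weights["1", "2"], 1)
  expect_equal(built$fa_weighted$weights["1", "2"], 0.3)
  expect_equal(built$fa_weighted$weights["1", "3"], 0)
  expect_equal(built$binary$weights["1", "3"], 0)
  expect_equal(built$fa_weighted$counts["1", "2"], 2)
})

test_that("construction matches a brute-force per-pair accumulation oracle", {
  pm <- make_toy_parcellation(c(6, 6, 3), 5, seed = 9)
  sl <- make_toy_streamlines(pm, 50, c(0.15, 0.85), seed = 10)
  built <- build_connectomes(sl, pm)
  labs <- node_labels(pm)
  n <- length(labs)
  cnt <- matrix(0, n, n, dimnames = list(labs, labs))
  fas <- cnt
  for (s in 1:50) {
    ep <- endpoints_to_regions(sl$points[[s]], pm)
    if (length(ep) == 0) next
    i <- as.character(ep[1]); j <- as.character(ep[2])
    cnt[i, j] <- cnt[i, j] + 1; cnt[j, i] <- cnt[i, j]
    fas[i, j] <- fas[i, j] + sl$fa[s]; fas[j, i] <- fas[i, j]
  }
  expect_equal(unname(built$binary$weights), unname((cnt > 0) * 1))
  expect_equal(unname(built$fa_weighted$weights),
               unname(ifelse(cnt > 0, fas / pmax(cnt, 1), 0)))
  # binary(i,j) = 1 <=> fa_weighted(i,j) > 0 for a shared streamline set
  expect_identical(built$binary$weights > 0, built$fa_weighted$weights > 0)
})

test_that("zero accepted streamlines yields a valid empty connectome", {
  pm <- toy_map()
  p <- straight_line(c(0.5, 0.5, 0.5), c(1.5, 3.5, 0.5))  # self-loop only
  expect_warning(built <- build_connectomes(streamline_set(list(p), 0.5), pm),
                 "empty")
  expect_true(all(built$binary$weights == 0))
  expect_equal(built$discarded[["self_loop"]], 1L)
})

test_that("construction is permutation-equivariant under region relabeling", {
  pm <- make_toy_parcellation(c(6, 6, 2), 4, seed = 21, background_frac = 0)
  sl <- make_toy_streamlines(pm, 40, c(0.2, 0.8), seed = 22)
  built <- build_connectomes(sl, pm)
  # relabel regions 1..4 -> 11,13,10,12 (order-scrambling permutation)
  perm <- c(11L, 13L, 10L, 12L)
  lab2 <- pm$labels
  lab2[pm$labels > 0] <- perm[pm$labels[pm$labels > 0]]
  built2 <- build_connectomes(sl, parcel_map(lab2), radius = 2)
  for (v in c("binary", "fa_weighted")) {
    W1 <- built[[v]]$weights
    W2 <- built2[[v]]$weights
    for (i in 1:4) for (j in 1:4)
      expect_identical(W2[as.character(perm[i]), as.character(perm[j])],
                       unname(W1[as.character(i), as.character(j)]))
  }
})

test_that("normalization gives unit total strength and preserves ratios", {
  W <- matrix(0, 4, 4)
  W[1, 2] <- W[2, 1] <- 0.2
  W[1, 3] <- W[3, 1] <- 0.3
  W[2, 4] <- W[4, 2] <- 0.5
  fan <- normalize_total_strength(connectome(W))
  expect_equal(fan$variant, "fa_normalized")
  expect_equal(total_strength(fan), 1, tolerance = 1e-12)
  # S = 1.0 here, so the weights are unchanged exactly
  expect_identical(unname(fan$weights), W)
  # single-edge network: the edge becomes exactly 1
  W1 <- matrix(0, 3, 3); W1[1, 2] <- W1[2, 1] <- 0.37
  expect_equal(normalize_total_strength(connectome(W1))$weights[1, 2], 1)
  # scale invariance: normalize(c W) == normalize(W)
  conn <- rand_connectome(12, 0.5, seed = 4)
  f1 <- normalize_total_strength(conn)
  f2 <- normalize_total_strength(connectome(conn$weights * 7.3))
  expect_equal(f1$weights, f2$weights, tolerance = 1e-12)
  expect_error(normalize_total_strength(connectome(matrix(0, 3, 3))),
               "all-zero")
})

test_that("edge thresholding is strict and matches a brute-force scan", {
  W <- matrix(0, 4, 4)
  W[1, 2] <- W[2, 1] <- 0.31
  W[1, 3] <- W[3, 1] <- 0.30
  W[2, 4] <- W[4, 2] <- 0.29
  ed <- threshold_edges(connectome(W), 0.3)
  expect_equal(nrow(ed), 1)
  expect_equal(ed$weight, 0.31)
  conn <- rand_connectome(20, 0.5, seed = 8)
  ed <- threshold_edges(conn, 0.25)
  brute <- sum(conn$weights[upper.tri(conn$weights)] > 0.25)
  expect_equal(nrow(ed), brute)
  expect_false(is.unsorted(rev(ed$weight)))
  all_edges <- threshold_edges(conn, 0)
  expect_equal(nrow(all_edges),
               sum(conn$weights[upper.tri(conn$weights)] > 0))
})

test_that("group averaging is the entrywise mean with absent edges as zero", {
  conn <- rand_connectome(10, 0.4, seed = 5)
  same <- group_average_connectome(list(conn, conn, conn))
  expect_equal(same$weights, conn$weights)
  # edge present in one of two subjects at 0.4 averages to 0.2
  Wa <- matrix(0, 3, 3); Wa[1, 2] <- Wa[2, 1] <- 0.4
  Wb <- matrix(0, 3, 3)
  avg <- group_average_connectome(list(connectome(Wa), connectome(Wb)))
  expect_equal(avg$weights[1, 2], 0.2)
  # 5 random subjects against the entrywise mean oracle
  conns <- lapply(1:5, function(s) rand_connectome(8, 0.5, seed = s))
  avg <- group_average_connectome(conns)
  manual <- Reduce(`+`, lapply(conns, `[[`, "weights")) / 5
  expect_equal(avg$weights, manual)
  expect_error(group_average_connectome(list(conn, rand_connectome(9))),
               "node sets")
})

test_that("every constructor output is symmetric with a zero diagonal", {
  pm <- make_toy_parcellation(c(6, 6, 2), 5, seed = 2)
  sl <- make_toy_streamlines(pm, 60, seed = 3)
  built <- build_connectomes(sl, pm)
  for (conn in list(built$binary, built$fa_weighted,
                    normalize_total_strength(built$fa_weighted))) {
    expect_identical(conn$weights, t(conn$weights))
    expect_true(all(diag(conn$weights) == 0))
  }
})
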