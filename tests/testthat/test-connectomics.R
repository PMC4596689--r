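# Connectome construction: subject correlation matrices, Fisher-z group
# averaging, seed-connectivity t-maps, ACP effective distances and graph
# geodesics, with exhaustive path oracles.

test_that("subject correlation matrix behaves and matches the oracle", {
  set.seed(1)
  ts <- matrix(rnorm(50 * 4), 50, 4)
  ts[, 2] <- ts[, 1]
  ts[, 3] <- -ts[, 1]
  R <- subject_correlation_matrix(ts)
  expect_equal(R[1, 2], 1)
  expect_equal(R[1, 3], -1)
  expect_true(isSymmetric(R))
  expect_equal(R[1, 4], oracle_pearson(ts[, 1], ts[, 4]), tolerance = 1e-12)
  ts_bad <- ts; ts_bad[, 2] <- 7
  colnames(ts_bad) <- paste0("region", 1:4)
  expect_error(subject_correlation_matrix(ts_bad), "region2")
  expect_error(subject_correlation_matrix(ts[1:2, ]), "3 time points")
})

test_that("Fisher group averaging has its exact fixed points", {
  m <- diag(4)
  m[upper.tri(m)] <- c(0.5, -0.3, 0.8, 0.1, -0.6, 0.25)
  m <- m + t(m) - diag(diag(m))
  # N identical matrices reproduce the input exactly
  expect_identical(fisher_group_average(list(m, m, m))$R_group, m)
  # N = 1 is the identity operation
  expect_identical(fisher_group_average(list(m))$R_group, m)
  # +0.5 / -0.5 cancel exactly (odd symmetry of atanh)
  m1 <- diag(2); m1[1, 2] <- m1[2, 1] <- 0.5
  m2 <- diag(2); m2[1, 2] <- m2[2, 1] <- -0.5
  expect_identical(fisher_group_average(list(m1, m2))$R_group[1, 2], 0)
  # r = 0 everywhere stays 0
  z <- diag(3)
  expect_true(all(fisher_group_average(list(z, z))$R_group == diag(3)))
  # averaging commutes with subject reordering
  set.seed(2)
  mats <- replicate(5, {
    ts <- matrix(rnorm(60 * 3), 60, 3); cor(ts)
  }, simplify = FALSE)
  expect_equal(fisher_group_average(mats)$R_group,
               fisher_group_average(rev(mats))$R_group, tolerance = 1e-15)
  # the defining identity: inverse-Fisher of the mean Fisher z
  Z <- Reduce(`+`, lapply(mats, function(x) atanh(x * !diag(3)))) / 5
  expect_equal(fisher_group_average(mats)$R_group[1, 2], tanh(Z[1, 2]),
               tolerance = 1e-15)
  # perfect correlations are rejected unless clamping is requested
  mb <- diag(2); mb[1, 2] <- mb[2, 1] <- 1
  expect_error(fisher_group_average(list(mb)), "infinite")
  expect_lt(fisher_group_average(list(mb), clamp = TRUE)$R_group[1, 2], 1)
})

test_that("seed-connectivity t-map detects coupling and is calibrated", {
  set.seed(3)
  T_len <- 300; n_vox <- 500; n_sub <- 20
  subs <- lapply(1:n_sub, function(s) matrix(rnorm(T_len * n_vox), T_len, n_vox))
  sm <- seed_connectivity_map(subs, seed_voxels = 1:5, alpha = 0.05)
  frac <- mean(sm$significant[-(1:5)])
  expect_lt(abs(frac - 0.05), 0.02)

  # planted seed-coupled voxels at r ~ 0.6
  subs2 <- lapply(1:n_sub, function(s) {
    ts <- matrix(rnorm(T_len * 50), T_len, 50)
    seed_sig <- rowMeans(ts[, 1:3])
    for (v in 40:45)
      ts[, v] <- 0.75 * scale(seed_sig) + sqrt(1 - 0.75^2) * rnorm(T_len)
    ts
  })
  sm2 <- seed_connectivity_map(subs2, seed_voxels = 1:3)
  cut <- qt(1 - 0.001 / 2, df = sm2$df)
  expect_true(all(sm2$t[40:45] > cut))

  # voxels equal to the seed series give the maximal statistic
  subs3 <- lapply(1:4, function(s) {
    x <- rnorm(100); cbind(x, x, x)
  })
  sm3 <- seed_connectivity_map(subs3, seed_voxels = 1)
  expect_true(all(sm3$t == Inf))
  expect_error(seed_connectivity_map(subs3[1], 1), "2 subjects")
  expect_error(seed_connectivity_map(subs3, integer(0)), "empty")
})

test_that("ACP effective distances follow the hand-computed and exhaustive oracles", {
  # chain of perfect connections: -log 1 = 0 edge lengths everywhere
  acp <- matrix(0, 4, 4)
  for (i in 1:3) acp[i, i + 1] <- acp[i + 1, i] <- 1
  sc <- acp_effective_distance(acp)
  expect_true(all(sc$effective_distance == 0))

  # two-path comparison: via the middle node beats the direct edge
  a3 <- matrix(0, 3, 3)
  a3[1, 2] <- a3[2, 1] <- 0.5; a3[2, 3] <- a3[3, 2] <- 0.5
  a3[1, 3] <- a3[3, 1] <- 0.1
  d <- acp_effective_distance(a3)$effective_distance
  expect_equal(d[1, 3], -log(0.25), tolerance = 1e-12)

  # random graphs up to 10 nodes: exact match with exhaustive enumeration
  for (s in 1:6) {
    n <- sample(4:10, 1)
    acp_r <- random_acp(n, density = 0.4, seed = s)
    sc_r <- acp_effective_distance(acp_r)
    w <- matrix(Inf, n, n)
    w[acp_r > 0] <- -log(acp_r[acp_r > 0])
    expect_equal(sc_r$effective_distance, oracle_shortest_paths(w),
                 tolerance = 1e-12)
    # -log shortest path == -log of max-product path reliability
    mp <- oracle_max_product(acp_r)
    expect_equal(sc_r$effective_distance, -log(mp), tolerance = 1e-10)
  }

  # disconnected pairs are Inf
  iso <- matrix(0, 3, 3); iso[1, 2] <- iso[2, 1] <- 0.5
  expect_equal(acp_effective_distance(iso)$effective_distance[1, 3], Inf)

  # validation
  bad <- matrix(0.5, 2, 2)
  expect_error(acp_effective_distance(bad), "diagonal")
  asym <- matrix(c(0, 0.2, 0.5, 0), 2, 2)
  expect_error(acp_effective_distance(asym), "symmetric")
  expect_error(acp_effective_distance(matrix(c(0, 2, 2, 0), 2, 2)), "0, 1")

  # alternative transforms
  expect_equal(acp_effective_distance(a3, "one_minus")$effective_distance[1, 2],
               0.5)
  expect_equal(acp_effective_distance(a3, "reciprocal")$effective_distance[1, 3],
               4)   # 1/0.5 + 1/0.5 beats 1/0.1
})

test_that("raising an ACP entry never increases any effective distance", {
  for (s in 1:10) {
    acp <- random_acp(8, density = 0.4, seed = 100 + s)
    d0 <- acp_effective_distance(acp)$effective_distance
    set.seed(s)
    pick <- which(upper.tri(acp) & acp > 0)
    ij <- arrayInd(sample(pick, 1), dim(acp))
    acp2 <- acp
    acp2[ij[1], ij[2]] <- acp2[ij[2], ij[1]] <- min(1, acp[ij[1], ij[2]] + 0.3)
    d1 <- acp_effective_distance(acp2)$effective_distance
    expect_true(all(d1 <= d0 + 1e-12))
  }
})

test_that("graph geodesics count hops and match the matrix-power oracle", {
  path3 <- matrix(0, 3, 3)
  path3[1, 2] <- path3[2, 1] <- 1; path3[2, 3] <- path3[3, 2] <- 1
  expect_equal(graph_geodesic(path3)[1, 3], 2)
  cg <- matrix(1, 4, 4) - diag(4)
  D <- graph_geodesic(cg)
  expect_true(all(D[upper.tri(D)] == 1))
  for (s in 1:5) {
    adj <- (random_acp(7, density = 0.3, seed = 200 + s) > 0) * 1
    expect_equal(graph_geodesic(adj), oracle_hops(adj))
  }
})

test_that("centroid Euclidean distances use mm spacing", {
  tab <- data.frame(region = 1:2, name = c("a", "b"),
                    x = c(0, 5), y = c(0, 0), z = c(0, 0))
  D <- euclidean_centroid_distances(tab)
  expect_equal(D[1, 2], 5)
  expect_true(all(diag(D) == 0))
  p <- make_parcellation(c(12, 12, 12), 6, seed = 3, spacing = c(2, 2, 2))
  Dp <- euclidean_centroid_distances(p)
  for (i in 1:5) for (j in (i + 1):6) {
    ci <- unlist(p$table[i, c("x", "y", "z")])
    cj <- unlist(p$table[j, c("x", "y", "z")])
    expect_equal(Dp[i, j], sqrt(sum((ci - cj)^2)), tolerance = 1e-12)
  }
  expect_error(euclidean_centroid_distances(tab[1, , drop = FALSE]),
               "2 regions")
})
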