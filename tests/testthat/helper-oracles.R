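# Independent brute-force oracles used to cross-check the implementation.
# These are deliberately coded from first principles (loops, textbook
# formulas, exhaustive enumeration) and share no code with the package.

# per-voxel 3x3 Jacobian oracle: builds the full matrix at each voxel from
# separately coded finite differences and calls base det()
oracle_jacobian <- function(u, spacing, boundary = "one_sided") {
  dims <- dim(u)[1:3]
  out <- array(NA_real_, dims)
  deriv <- function(comp, idx, axis) {
    n <- dims[axis]
    i <- idx[axis]
    at <- function(j) { idx[axis] <- j; u[idx[1], idx[2], idx[3], comp] }
    if (i > 1 && i < n) {
      (at(i + 1) - at(i - 1)) / (2 * spacing[axis])
    } else if (boundary == "one_sided") {
      if (i == 1) (at(2) - at(1)) / spacing[axis]
      else (at(n) - at(n - 1)) / spacing[axis]
    } else { # replicate padding, central difference
      lo <- max(1, i - 1); hi <- min(n, i + 1)
      (at(hi) - at(lo)) / (2 * spacing[axis])
    }
  }
  for (i in seq_len(dims[1])) for (j in seq_len(dims[2]))
    for (k in seq_len(dims[3])) {
      J <- matrix(0, 3, 3)
      for (ci in 1:3) for (cj in 1:3)
        J[ci, cj] <- deriv(ci, c(i, j, k), cj)
      out[i, j, k] <- det(diag(3) + J) - 1
    }
  out
}

# textbook pooled-variance two-sample t
oracle_pooled_t <- function(x, y) {
  nx <- length(x); ny <- length(y)
  sp2 <- ((nx - 1) * var(x) + (ny - 1) * var(y)) / (nx + ny - 2)
  (mean(x) - mean(y)) / sqrt(sp2 * (1 / nx + 1 / ny))
}

# Pearson r from the covariance formula
oracle_pearson <- function(x, y) {
  mx <- mean(x); my <- mean(y)
  sum((x - mx) * (y - my)) /
    sqrt(sum((x - mx)^2) * sum((y - my)^2))
}

# partial correlation from the closed-form three-variable formula
oracle_partial_r <- function(x, y, z) {
  rxy <- oracle_pearson(x, y)
  rxz <- oracle_pearson(x, z)
  ryz <- oracle_pearson(y, z)
  (rxy - rxz * ryz) / sqrt((1 - rxz^2) * (1 - ryz^2))
}

# OLS via the normal equations
oracle_ols <- function(X, y) {
  solve(t(X) %*% X, t(X) %*% y)
}

# ANCOVA group t: normal equations + classical standard error
oracle_ancova_t <- function(y, group01, age) {
  X <- cbind(1, group01, age)
  b <- oracle_ols(X, y)
  res <- y - X %*% b
  s2 <- sum(res^2) / (length(y) - 3)
  covb <- s2 * solve(t(X) %*% X)
  b[2] / sqrt(covb[2, 2])
}

# exhaustive shortest-path oracle: enumerates every simple path between
# each node pair (feasible for <= 10 nodes)
oracle_shortest_paths <- function(wmat) {
  n <- nrow(wmat)
  has_edge <- is.finite(wmat) & !is.na(wmat)
  best <- matrix(Inf, n, n); diag(best) <- 0
  walk <- function(node, target, visited, len) {
    if (node == target) {
      if (len < best[start, target]) best[start, target] <<- len
      return(invisible())
    }
    for (nxt in seq_len(n)) {
      if (!visited[nxt] && has_edge[node, nxt]) {
        walk(nxt, target, `[<-`(visited, nxt, TRUE), len + wmat[node, nxt])
      }
    }
  }
  for (start in seq_len(n)) for (target in seq_len(n)) {
    if (start != target) {
      v <- rep(FALSE, n); v[start] <- TRUE
      walk(start, target, v, 0)
    }
  }
  best
}

# max-product path reliability (brute force over simple paths)
oracle_max_product <- function(acp) {
  n <- nrow(acp)
  best <- matrix(0, n, n); diag(best) <- 1
  walk <- function(node, target, visited, prob) {
    if (node == target) {
      if (prob > best[start, target]) best[start, target] <<- prob
      return(invisible())
    }
    for (nxt in seq_len(n)) {
      if (!visited[nxt] && acp[node, nxt] > 0) {
        walk(nxt, target, `[<-`(visited, nxt, TRUE), prob * acp[node, nxt])
      }
    }
  }
  for (start in seq_len(n)) for (target in seq_len(n)) {
    if (start != target) {
      v <- rep(FALSE, n); v[start] <- TRUE
      walk(start, target, v, 1)
    }
  }
  best
}

# hop-count oracle via boolean matrix powers
oracle_hops <- function(adj) {
  A <- (adj != 0) * 1; diag(A) <- 0
  n <- nrow(A)
  D <- matrix(Inf, n, n); diag(D) <- 0
  P <- diag(n)
  for (h in seq_len(n)) {
    P <- (P %*% A > 0) * 1          # reachable by a walk of exactly h edges
    newly <- (P > 0) & !is.finite(D)
    D[newly] <- h
  }
  D
}

# random symmetric ACP matrix for graph tests
random_acp <- function(n, density = 0.5, seed = 1) {
  set.seed(seed)
  a <- matrix(0, n, n)
  ut <- upper.tri(a)
  vals <- runif(sum(ut), 0.05, 1) * (runif(sum(ut)) < density)
  a[ut] <- vals
  a + t(a)
}

# small displacement-field builder from component functions of voxel coords
build_field <- function(grid_shape, fns, spacing = c(1, 1, 1)) {
  u <- array(0, c(grid_shape, 3))
  coords <- lapply(1:3, function(a)
    (slice.index(array(0, grid_shape), a) - 1) * spacing[a])
  for (i in 1:3) u[, , , i] <- fns[[i]](coords[[1]], coords[[2]], coords[[3]])
  displacement_field(u, spacing = spacing)
}

interior <- function(vol, margin = 1) {
  d <- dim(vol)
  vol[(1 + margin):(d[1] - margin),
      (1 + margin):(d[2] - margin),
      (1 + margin):(d[3] - margin)]
}
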