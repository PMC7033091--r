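test_that("exactly block-diagonal generators give indicator memberships", {
  for (sizes in list(c(4, 4), c(3, 4, 5))) {
    q <- length(sizes)
    L <- build_generator(block_diag_tau(sizes))
    sd <- suppressWarnings(spectral_decomposition(L, q))
    # one vanishing eigenvalue per block
    expect_true(all(abs(sd$values) < 1e-10))
    # rows constant within each block
    blk <- rep(seq_along(sizes), sizes)
    for (b in seq_along(sizes)) {
      rows <- sd$E[blk == b, , drop = FALSE]
      expect_lt(max(abs(sweep(rows, 2, rows[1, ]))), 1e-10)
    }
    reps <- select_representatives(sd)
    expect_setequal(blk[reps], seq_along(sizes))
    mem <- compute_memberships(sd, reps)
    expect_lt(max(abs(mem$W * (1 - mem$W))), 1e-10)  # entries in {0, 1}
    expect_equal(mem$theta, 0, tolerance = 1e-10)
  }
})

test_that("spectral decomposition returns true eigenpairs, deterministically signed", {
  L <- build_generator(random_tau(10, 5))
  sd <- spectral_decomposition(L, 4)
  for (k in 1:4) {
    expect_lt(max(abs(L$L %*% sd$E[, k] - sd$values[k] * sd$E[, k])), 1e-10)
    expect_equal(sum(sd$E[, k]^2), 1, tolerance = 1e-12)
    expect_gt(sd$E[which.max(abs(sd$E[, k])), k], 0)
  }
  expect_true(all(diff(sd$values) <= 1e-12))
  expect_lt(abs(sd$values[1]), 1e-10 * max(abs(sd$values)))
  expect_error(spectral_decomposition(L, 1), "q must")
})

test_that("q = 2 representatives are the brute-force maximum-distance pair", {
  for (seed in 1:5) {
    L <- build_generator(random_tau(12, seed + 100))
    sd <- spectral_decomposition(L, 2)
    reps <- select_representatives(sd)
    d <- as.matrix(dist(sd$E))
    best <- which(d == max(d), arr.ind = TRUE)[1, ]
    expect_setequal(reps, unname(best))
  }
})

test_that("q = 3 representatives maximise the simplex volume over planted blocks", {
  sys <- generate_block_tau(n = 21, blocks = 3, ratio = 100, noise = 0.2,
                            seed = 4)
  L <- build_generator(sys$tau)
  sd <- spectral_decomposition(L, 3)
  reps <- select_representatives(sd)
  # brute force: triple maximising |det| of edge vectors
  n <- nrow(sd$E)
  vol <- function(i, j, k) {
    abs(det(rbind(sd$E[j, ] - sd$E[i, ], sd$E[k, ] - sd$E[i, ])[, 2:3]))
  }
  best <- c(1, 2, 3); bv <- -1
  for (i in 1:(n - 2)) for (j in (i + 1):(n - 1)) for (k in (j + 1):n) {
    v <- vol(i, j, k)
    if (v > bv) { bv <- v; best <- c(i, j, k) }
  }
  # greedy and brute force land in the same planted blocks
  expect_setequal(unname(sys$clusters[reps]), 1:3)
  expect_setequal(unname(sys$clusters[best]), unname(sys$clusters[reps]))
})

test_that("memberships invert the vertex expansion and sum to one", {
  sys <- generate_block_tau(n = 30, blocks = 2, ratio = 1000, noise = 0.3,
                            seed = 8)
  L <- build_generator(sys$tau)
  sd <- spectral_decomposition(L, 2)
  reps <- select_representatives(sd)
  mem <- compute_memberships(sd, reps)
  expect_lt(max(abs(rowSums(mem$W) - 1)), 1e-8)
  # representative rows are one-hot
  expect_equal(unname(mem$W[reps, ]), diag(2), tolerance = 1e-8)
  # independent route: least-squares solve of the same expansion
  W_ls <- t(qr.solve(t(sd$E[reps, ]), t(sd$E)))
  expect_lt(max(abs(mem$W - W_ls)), 1e-6)
  # weak coupling: memberships near the indicator values
  expect_true(all(abs(mem$W - round(mem$W)) < 0.05))
  expect_gte(mem$theta, -0.05)
})

test_that("theta is the minimum membership and degrades with over-clustering", {
  expect_equal(theta(matrix(c(1, 0, 0, 1), 2, 2)), 0)
  expect_equal(theta(matrix(c(1.3, -0.3, 0, 1), 2, 2)), -0.3)
  sys <- generate_block_tau(n = 40, blocks = 2, ratio = 100, noise = 0.3,
                            seed = 2)
  L <- build_generator(sys$tau)
  th <- vapply(2:4, function(q) {
    sd <- spectral_decomposition(L, q)
    compute_memberships(sd, select_representatives(sd))$theta
  }, numeric(1))
  expect_gte(th[1], -1e-10)   # true split: theta = 0 up to fp
  expect_lt(th[2], th[1])     # extra clusters push memberships negative
  expect_lt(th[3], 0)
})

test_that("scan_cluster_number recovers planted block counts and flags no split", {
  sys2 <- generate_block_tau(n = 40, blocks = 2, ratio = 100, noise = 0.3,
                             seed = 13)
  expect_identical(scan_cluster_number(build_generator(sys2$tau), 5)$recommended, 2L)
  sys3 <- generate_block_tau(n = 40, blocks = 3, ratio = 100, noise = 0.3,
                             seed = 13)
  expect_identical(scan_cluster_number(build_generator(sys3$tau), 5)$recommended, 3L)
  # structureless network: all exchange times equal
  tm <- matrix(1, 12, 12); diag(tm) <- NA
  L_flat <- build_generator(tau_matrix(tm, labels = paste0("A", 1:12)))
  scan <- suppressWarnings(scan_cluster_number(L_flat, 4))
  expect_true(is.na(scan$recommended))
})

test_that("assignment thresholds behave as documented and are cutoff-robust", {
  W <- structure(list(labels = c("r1", "r2"),
                      W = rbind(c(0.95, 0.05), c(0.6, 0.4)),
                      representatives = 1L, theta = 0.05),
                 class = "membership_matrix")
  asg <- assign_clusters(W, cutoff = 0.7)
  expect_identical(asg$cluster, c(1L, NA_integer_))
  expect_error(assign_clusters(W, cutoff = 0.4), "cutoff")

  sys <- generate_block_tau(n = 40, blocks = 2, ratio = 1000, noise = 0.3,
                            seed = 5)
  L <- build_generator(sys$tau)
  sd <- spectral_decomposition(L, 2)
  mem <- compute_memberships(sd, select_representatives(sd))
  a7 <- assign_clusters(mem, 0.7)$cluster
  expect_identical(a7, assign_clusters(mem, 0.8)$cluster)
  expect_identical(a7, assign_clusters(mem, 0.9)$cluster)
})

test_that("relabeling residues permutes membership rows identically", {
  sys <- generate_block_tau(n = 20, blocks = 2, ratio = 100, noise = 0.3,
                            seed = 17)
  tau <- sys$tau
  perm <- sample(seq_along(tau$labels))
  tau_p <- tau_matrix(tau$times[perm, perm], labels = tau$labels[perm])
  mem_of <- function(tau) {
    sd <- spectral_decomposition(build_generator(tau), 2)
    compute_memberships(sd, select_representatives(sd))
  }
  W1 <- mem_of(tau)$W
  W2 <- mem_of(tau_p)$W
  expect_equal(unname(W2), unname(W1[perm, ]), tolerance = 1e-10)
})
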