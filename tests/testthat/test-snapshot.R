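# Snapshot-selection pipeline: neighbor-distance features, PCA projection,
# PAM clustering with validation consensus, GRASP selection, allocation.

mk_traj2 <- function(frames, topo, radius = 20) {
  arr <- array(0, c(nrow(frames[[1]]), 3, length(frames)))
  for (k in seq_along(frames)) arr[, , k] <- frames[[k]]
  structure(list(positions = arr, radius = rep(radius, length(frames)),
                 time = 10 * seq_along(frames), topology = topo),
            class = "npbc_trajectory")
}

test_that("features are sorted first/second neighbor distances", {
  # solute site X (frozen mol 1) + three solvent 'O' atoms at known distances
  topo <- topology(mass = c(10, 18, 18, 18), charge = rep(0, 4),
                   sigma = rep(0, 4), epsilon = rep(0, 4), mol = 1:4,
                   name = c("X", "O", "O", "O"), frozen = 1L)
  f1 <- rbind(c(0, 0, 0), c(2, 0, 0), c(0, 3.5, 0), c(0, 0, 5))
  fm <- build_features(mk_traj2(list(f1), topo), sites = "X",
                       solvent_atoms = "O")
  expect_equal(as.numeric(fm$features[1, ]), c(2, 3.5))
  # permuting solvent atoms leaves features unchanged
  f2 <- f1[c(1, 4, 2, 3), ]
  fm2 <- build_features(mk_traj2(list(f2), topo), sites = "X",
                        solvent_atoms = "O")
  expect_equal(fm2$features, fm$features)
  # brute-force all-distances sort agrees on random frames
  set.seed(3)
  frames <- lapply(1:5, function(i)
    rbind(c(0, 0, 0), matrix(rnorm(9, sd = 4), 3, 3)))
  fm3 <- build_features(mk_traj2(frames, topo), sites = "X",
                        solvent_atoms = "O")
  for (k in 1:5) {
    d <- sort(sqrt(rowSums(sweep(frames[[k]][-1, ], 2,
                                 frames[[k]][1, ])^2)))
    expect_equal(as.numeric(fm3$features[k, ]), d[1:2])
  }
  expect_error(build_features(mk_traj2(list(f1), topo), sites = "X",
                              solvent_atoms = "H"),
               "fewer than 2")
})

test_that("PCA projection retains the minimal dimension above the threshold", {
  set.seed(4)
  # exact 2-D plane embedded in 5-D
  b1 <- rnorm(5); b2 <- rnorm(5)
  x <- outer(rnorm(100), b1) + outer(rnorm(100), b2)
  pr <- project_features(x)
  expect_equal(pr$d, 2L)
  expect_equal(sum(pr$ratios[1:2]), 1, tolerance = 1e-10)
  # one dominant direction
  y <- cbind(rnorm(200, sd = 30), rnorm(200, sd = 1), rnorm(200, sd = 1))
  expect_equal(project_features(y)$d, 1L)
  # isotropic 4-D: all four needed
  z <- matrix(rnorm(4000), 1000, 4)
  expect_equal(project_features(z)$d, 4L)
  expect_error(project_features(matrix(1, 50, 3)), "zero-variance")
})

test_that("PAM recovers planted blobs and matches exhaustive search", {
  set.seed(5)
  x <- rbind(matrix(rnorm(160, sd = 0.4), 80, 2),
             sweep(matrix(rnorm(160, sd = 0.4), 80, 2), 2, c(8, 8), "+"))
  cm <- pam_cluster(x, 2)
  truth <- rep(1:2, each = 80)
  agree <- max(mean(cm$labels == truth), mean(cm$labels == 3 - truth))
  expect_gte(agree, 0.99)
  # k = n: singletons with zero cost
  xs <- matrix(rnorm(12), 6, 2)
  cn <- pam_cluster(xs, 6)
  expect_equal(cn$medoids, 1:6)
  expect_equal(cn$cost, 0)
  # 4 points in 2 pairs: enumeration over all medoid pairs
  p4 <- rbind(c(0, 0), c(0.5, 0), c(10, 0), c(10.4, 0))
  c4 <- pam_cluster(p4, 2)
  D <- as.matrix(dist(p4))
  best <- Inf
  for (i in 1:3) for (j in (i + 1):4) {
    cost <- sum(pmin(D[, i], D[, j]))
    best <- min(best, cost)
  }
  expect_equal(c4$cost, best, tolerance = 1e-12)
  expect_true(all(c4$labels[1:2] == c4$labels[1]))
  expect_true(all(c4$labels[3:4] == c4$labels[3]))
})

test_that("PAM cost matches the reference implementation on random data", {
  set.seed(6)
  x <- matrix(rnorm(120), 60, 2)
  for (k in c(2, 4)) {
    ours <- pam_cluster(x, k)
    ref <- cluster::pam(x, k)
    # both are local optima of the same objective; ours must not be worse
    refcost <- sum(apply(as.matrix(dist(x))[, ref$id.med, drop = FALSE],
                         1, min))
    expect_lte(ours$cost, refcost + 1e-9)
  }
})

test_that("cluster-count consensus picks the planted k for separated blobs", {
  set.seed(7)
  mk_blobs <- function(k, n_per, sep, sd = 1) {
    cen <- rbind(c(0, 0, 0), c(sep, 0, 0), c(0, sep, 0), c(sep, sep, 0),
                 c(0, 0, sep))[seq_len(k), , drop = FALSE] * 2
    do.call(rbind, lapply(1:k, function(i)
      sweep(matrix(rnorm(n_per * 3, sd = sd), n_per, 3), 2, cen[i, ], "+")))
  }
  x3 <- mk_blobs(3, 50, 6)
  s3 <- select_k(x3, 2:8)
  expect_equal(s3$k, 3)
  expect_true(s3$consensus)
  x2 <- mk_blobs(2, 60, 8)
  s2 <- select_k(x2, 2:8)
  expect_equal(s2$k, 2)
  expect_true(all(s2$votes[c("silhouette", "dunn", "psf")] == 2))
  # a single Gaussian has no preferred k: low silhouettes across the board
  x1 <- matrix(rnorm(450), 150, 3)
  s1 <- select_k(x1, 2:8)
  expect_lt(max(s1$scores$silhouette), 0.35)
})

test_that("planted-k recovery holds in at least 95% of seeds", {
  hits <- 0
  n_seeds <- 12
  for (s in seq_len(n_seeds)) {
    set.seed(100 + s)
    k <- 2 + (s %% 3)
    cen <- matrix(0, k, 2)
    for (i in seq_len(k)) cen[i, ] <- 6 * c(i %% 2, i %/% 2) * 1.8
    x <- do.call(rbind, lapply(seq_len(k), function(i)
      sweep(matrix(rnorm(80, sd = 1), 40, 2), 2, cen[i, ], "+")))
    got <- select_k(x, 2:7)$k
    hits <- hits + (got == k)
  }
  expect_gte(hits / n_seeds, 0.95)
})

test_that("GRASP finds brute-force optima on small instances", {
  set.seed(8)
  # 5 points, budget 2, alpha 0: exhaustive optimal weighted pair
  x5 <- matrix(rnorm(10, sd = 3), 5, 2)
  g <- grasp_select(x5, 2, grasp_config(alpha = 0, restarts = 5))
  D <- as.matrix(dist(x5)); w <- g$weights
  best <- -Inf; bestpair <- NULL
  for (i in 1:4) for (j in (i + 1):5) {
    v <- w[i] * w[j] * D[i, j]
    if (v > best) { best <- v; bestpair <- c(i, j) }
  }
  expect_equal(sort(g$selected), bestpair)
  expect_equal(g$objective, best, tolerance = 1e-12)
  # budget = n returns everything
  gall <- grasp_select(x5, 5, grasp_config(restarts = 1))
  expect_equal(gall$selected, 1:5)
  expect_equal(grasp_select(x5, 0)$selected, integer(0))
  # colinear equally spaced points, uniform weights: matches enumeration
  xc <- cbind(0:6, 0)
  gc_ <- grasp_select(xc, 3, grasp_config(alpha = 0.1, restarts = 20),
                      weights = rep(1, 7))
  Dc <- as.matrix(dist(xc))
  best3 <- -Inf
  for (i in 1:5) for (j in (i + 1):6) for (k in (j + 1):7) {
    v <- Dc[i, j] + Dc[i, k] + Dc[j, k]
    best3 <- max(best3, v)
  }
  expect_equal(gc_$objective, best3, tolerance = 1e-12)
  expect_true(all(c(1, 7) %in% gc_$selected))
})

test_that("GRASP with restarts attains the optimum on >= 95% of instances
           and never loses to pure greedy", {
  ok <- 0; n_inst <- 20
  for (s in seq_len(n_inst)) {
    set.seed(200 + s)
    n <- sample(8:14, 1)
    x <- matrix(rnorm(2 * n, sd = 2), n, 2)
    D <- as.matrix(dist(x))
    cfg <- grasp_config(alpha = 0.1, restarts = 100)
    g <- grasp_select(x, 3, cfg)
    w <- g$weights
    # exhaustive optimum
    best <- -Inf
    cmb <- combn(n, 3)
    for (c_ in seq_len(ncol(cmb))) {
      id <- cmb[, c_]
      v <- w[id[1]] * w[id[2]] * D[id[1], id[2]] +
        w[id[1]] * w[id[3]] * D[id[1], id[3]] +
        w[id[2]] * w[id[3]] * D[id[2], id[3]]
      best <- max(best, v)
    }
    ok <- ok + (abs(g$objective - best) < 1e-9)
    # objective never below the alpha = 0 greedy construction
    set.seed(300 + s)
    g0 <- grasp_select(x, 3, grasp_config(alpha = 0, restarts = 1))
    expect_gte(g$objective + 1e-12, g0$objective)
  }
  expect_gte(ok / n_inst, 0.95)
})

test_that("largest-remainder allocation reproduces the reference splits", {
  expect_equal(largest_remainder(c(707, 548), 64), c(36L, 28L))
  expect_equal(largest_remainder(c(173, 425, 343), 51), c(9L, 23L, 19L))
  expect_equal(largest_remainder(c(432, 463), 25), c(12L, 13L))
  expect_equal(sum(largest_remainder(c(3, 3, 3), 7)), 7L)
})

test_that("allocate_and_select honors budgets and always keeps medoids", {
  set.seed(9)
  x <- rbind(matrix(rnorm(120, sd = 0.6), 60, 2),
             sweep(matrix(rnorm(80, sd = 0.6), 40, 2), 2, c(7, 0), "+"))
  cm <- pam_cluster(x, 2)
  sel <- allocate_and_select(x, cm, 10, grasp_config(restarts = 10))
  expect_equal(sum(sel$budgets), 10)
  expect_equal(sel$budgets, largest_remainder(tabulate(cm$labels, 2), 10))
  expect_true(all(cm$medoids %in% sel$selected))
  expect_equal(length(sel$selected), 10)
  # one cluster takes the whole budget
  cm1 <- pam_cluster(x[1:60, ], 1)
  s1 <- allocate_and_select(x[1:60, ], cm1, 5, grasp_config(restarts = 5))
  expect_equal(length(s1$selected), 5)
})

test_that("the pipeline is deterministic under a fixed seed", {
  synth <- synth_feature_trajectory(rbind(c(0, 0, 0), c(6, 6, 0)),
                                    sds = 1, weights = c(0.48, 0.52),
                                    n_frames = 120, seed = 42)
  run_once <- function() {
    set.seed(77)
    pr <- project_features(synth$features, 0.9)
    cm <- pam_cluster(pr$points, 2)
    allocate_and_select(pr$points, cm, 8, grasp_config(restarts = 20))
  }
  a <- run_once(); b <- run_once()
  expect_identical(a$selected, b$selected)
  expect_identical(a$objectives, b$objectives)
})
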