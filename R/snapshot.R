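# Trajectory-mining pipeline: neighbor-distance feature spaces, variance-
# thresholded PCA projection, partitioning-around-medoids clustering with a
# four-criterion consensus on the cluster count, and GRASP selection of
# representative frames with density weighting and proportional per-cluster
# budgets.

#' Neighbor-distance feature matrix
#'
#' For every (solute site, solvent atom type) pair, the first and second
#' smallest site-atom distances per frame: 3 sites x 2 atom types x 2 ranks
#' gives the canonical 12 features.
#'
#' @param traj An `npbc_trajectory`.
#' @param sites Atom names (or indices) of the solute sites, e.g.
#'   `c("N", "LP1", "LP2")`.
#' @param solvent_atoms Two solvent atom names, e.g. `c("O", "H")`.
#' @param frame_stride Use every `frame_stride`-th stored frame (the stored
#'   stride times this should reach the decorrelation stride, 10 ps in the
#'   reference protocol).
#' @return A `FeatureMatrix`: list with `features` (n_frames x n_features),
#'   `frame_index`, `time`.
#' @export
build_features <- function(traj, sites, solvent_atoms, frame_stride = 1L) {
  at <- traj$topology$atoms
  site_idx <- if (is.character(sites)) {
    vapply(sites, function(s) {
      w <- which(at$name == s)
      if (!length(w)) stop(sprintf("no site named '%s'", s))
      w[1]
    }, 0L)
  } else as.integer(sites)
  solv <- lapply(solvent_atoms, function(s) {
    w <- which(at$name == s & !(at$mol %in% traj$topology$frozen))
    if (length(w) < 2L)
      stop(sprintf("fewer than 2 solvent atoms of type '%s'", s))
    w
  })
  frames <- seq(frame_stride, dim(traj$positions)[3], by = frame_stride)
  feat <- matrix(0, length(frames), length(site_idx) * length(solv) * 2L)
  nm <- character(ncol(feat))
  col <- 1L
  for (si in seq_along(site_idx)) {
    for (ai in seq_along(solv)) {
      nm[col] <- paste0(sites[si], "-", solvent_atoms[ai], "-1")
      nm[col + 1L] <- paste0(sites[si], "-", solvent_atoms[ai], "-2")
      col <- col + 2L
    }
  }
  for (f in seq_along(frames)) {
    x <- traj$positions[, , frames[f]]
    col <- 1L
    for (si in site_idx) {
      p <- x[si, ]
      for (ai in seq_along(solv)) {
        d <- sqrt(colSums((t(x[solv[[ai]], , drop = FALSE]) - p)^2))
        two <- sort(d, partial = 2)[1:2]
        feat[f, col] <- min(two)
        feat[f, col + 1L] <- max(two[1:2])
        col <- col + 2L
      }
    }
  }
  colnames(feat) <- nm
  structure(list(features = feat, frame_index = frames,
                 time = traj$time[frames]),
            class = "FeatureMatrix")
}

#' Variance-thresholded PCA projection
#'
#' Centered (not scaled -- all features share units) principal component
#' analysis retaining the smallest dimension whose cumulative explained
#' variance ratio exceeds `threshold`.
#'
#' @param features Numeric matrix (or a `FeatureMatrix`).
#' @param threshold Cumulative variance ratio to exceed (default 0.9).
#' @return A `Projection`: list with `points` (projected coordinates),
#'   `ratios` (explained-variance ratios), `d` (retained dimension) and
#'   `rotation`.
#' @export
project_features <- function(features, threshold = 0.9) {
  x <- if (inherits(features, "FeatureMatrix")) features$features else features
  vtot <- sum(apply(x, 2, stats::var))
  if (!is.finite(vtot) || vtot <= 0) stop("zero-variance feature matrix")
  pc <- prcomp(x, center = TRUE, scale. = FALSE)
  ratios <- pc$sdev^2 / sum(pc$sdev^2)
  d <- which(cumsum(ratios) > threshold)[1]
  structure(list(points = pc$x[, seq_len(d), drop = FALSE], ratios = ratios,
                 d = d, rotation = pc$rotation[, seq_len(d), drop = FALSE]),
            class = "Projection")
}

# ---------------------------------------------------------------------------
# Partitioning around medoids (BUILD + SWAP), deterministic tie-breaking by
# lowest index.
# ---------------------------------------------------------------------------

#' PAM clustering
#'
#' Classic partitioning around medoids on Euclidean distances: greedy BUILD
#' initialization followed by best-improvement SWAP passes until no swap
#' lowers the total dissimilarity.  Deterministic (ties resolved toward the
#' lowest index).
#'
#' @param points n x d matrix.
#' @param k Number of clusters, `2 <= k < n` (`k = n` returns singletons).
#' @return A `ClusterModel`: `k`, `medoids` (row indices), `labels`, `cost`.
#' @export
pam_cluster <- function(points, k) {
  x <- as.matrix(points)
  n <- nrow(x)
  stopifnot(k >= 1, k <= n)
  if (k == n) {
    return(structure(list(k = k, medoids = seq_len(n), labels = seq_len(n),
                          cost = 0), class = "ClusterModel"))
  }
  D <- as.matrix(stats::dist(x))
  med <- integer(0)
  # BUILD
  med <- which.min(colSums(D))
  while (length(med) < k) {
    dn <- apply(D[, med, drop = FALSE], 1, min)
    gain <- vapply(seq_len(n), function(h) {
      if (h %in% med) return(-Inf)
      sum(pmax(dn - D[, h], 0))
    }, 0)
    med <- c(med, which.max(gain))
  }
  cost_of <- function(med) sum(apply(D[, med, drop = FALSE], 1, min))
  cost <- cost_of(med)
  repeat {
    dmat <- D[, med, drop = FALSE]
    improved <- FALSE
    best_delta <- -1e-12
    best_swap <- NULL
    nonmed <- setdiff(seq_len(n), med)
    ord1 <- apply(dmat, 1, which.min)
    dn <- dmat[cbind(seq_len(n), ord1)]
    ds <- if (length(med) > 1L) {
      apply(dmat, 1, function(r) sort(r, partial = 2)[2])
    } else rep(Inf, n)
    for (j in seq_along(med)) {
      is_j <- ord1 == j
      for (h in nonmed) {
        dh <- D[, h]
        newd <- ifelse(is_j, pmin(ds, dh), pmin(dn, dh))
        delta <- sum(newd) - cost
        if (delta < best_delta) {
          best_delta <- delta
          best_swap <- c(j, h)
        }
      }
    }
    if (is.null(best_swap)) break
    med[best_swap[1]] <- best_swap[2]
    cost <- cost + best_delta
    improved <- TRUE
  }
  med <- sort(med)
  labels <- apply(D[, med, drop = FALSE], 1, which.min)
  structure(list(k = k, medoids = med, labels = labels,
                 cost = cost_of(med)), class = "ClusterModel")
}

# internal validation scores on a clustering
cluster_scores <- function(points, labels, medoids = NULL) {
  x <- as.matrix(points)
  n <- nrow(x)
  k <- length(unique(labels))
  D <- as.matrix(stats::dist(x))
  # silhouette
  si <- vapply(seq_len(n), function(i) {
    own <- labels == labels[i]
    if (sum(own) <= 1L) return(0)
    a <- sum(D[i, own]) / (sum(own) - 1L)
    b <- min(vapply(setdiff(unique(labels), labels[i]),
                    function(cl) mean(D[i, labels == cl]), 0))
    (b - a) / max(a, b)
  }, 0)
  # Dunn: min inter-cluster separation / max intra-cluster diameter
  diam <- max(vapply(unique(labels), function(cl) {
    idx <- which(labels == cl)
    if (length(idx) < 2L) 0 else max(D[idx, idx])
  }, 0))
  sep <- Inf
  ul <- sort(unique(labels))
  for (a in seq_along(ul)) for (b in seq_along(ul)) {
    if (b <= a) next
    sep <- min(sep, min(D[labels == ul[a], labels == ul[b]]))
  }
  dunn <- if (diam > 0) sep / diam else Inf
  # Calinski-Harabasz (pSF) and WSS on centroids
  gmean <- colMeans(x)
  wss <- 0; bss <- 0
  for (cl in ul) {
    idx <- which(labels == cl)
    cen <- colMeans(x[idx, , drop = FALSE])
    wss <- wss + sum(sweep(x[idx, , drop = FALSE], 2L, cen)^2)
    bss <- bss + length(idx) * sum((cen - gmean)^2)
  }
  ch <- if (k > 1 && wss > 0) (bss / (k - 1)) / (wss / (n - k)) else NA_real_
  list(silhouette = mean(si), dunn = dunn, psf = ch, wss = wss)
}

#' Cluster-count selection by four-criterion consensus
#'
#' Runs [pam_cluster()] for each k in `k_range` and scores every clustering
#' by Silhouette (max), Dunn index (max), Calinski-Harabasz / pSF (max) and
#' the WSS elbow (maximal discrete second difference).  The returned k is the
#' one chosen by at least three criteria; if no k reaches three votes, the k
#' with most votes (ties toward smaller k) is returned with
#' `consensus = FALSE`.
#'
#' @param points n x d matrix (n > max(k_range)).
#' @param k_range Candidate cluster counts (default 2:20).
#' @return List with `k`, `consensus` flag, `votes` and the per-k `scores`
#'   data frame.
#' @export
select_k <- function(points, k_range = 2:20) {
  n <- nrow(as.matrix(points))
  k_range <- k_range[k_range < n]
  stopifnot(length(k_range) >= 2L)
  rows <- lapply(k_range, function(k) {
    cm <- pam_cluster(points, k)
    sc <- cluster_scores(points, cm$labels)
    data.frame(k = k, silhouette = sc$silhouette, dunn = sc$dunn,
               psf = sc$psf, wss = sc$wss)
  })
  scores <- do.call(rbind, rows)
  picks <- c(silhouette = scores$k[which.max(scores$silhouette)],
             dunn = scores$k[which.max(scores$dunn)],
             psf = scores$k[which.max(scores$psf)],
             wss_elbow = {
               w <- scores$wss
               if (length(w) >= 3L) {
                 d2 <- w[-c(length(w) - 1L, length(w))] -
                   2 * w[-c(1L, length(w))] + w[-c(1L, 2L)]
                 scores$k[which.max(d2) + 1L]
               } else scores$k[1]
             })
  votes <- table(picks)
  topv <- max(votes)
  kbest <- min(as.integer(names(votes)[votes == topv]))
  list(k = kbest, consensus = topv >= 3L, votes = picks, scores = scores)
}

# ---------------------------------------------------------------------------
# GRASP selection of representative frames
# ---------------------------------------------------------------------------

#' GRASP configuration
#'
#' @param alpha Greediness of the restricted candidate list, in `[0, 1]`
#'   (0 = pure greedy; default 0.1).
#' @param neighborhood Fraction of the data set scanned per member in the
#'   local-search phase (default 0.05).
#' @param restarts Multistart repetitions (default 100).
#' @param literal_rcl Use the least-dissimilar candidate band
#'   `[DS_min, DS_min + alpha (DS_max - DS_min)]` instead of the top band
#'   (see the methods vignette for why the top band is the default).
#' @return A `GRASPConfig` list.
#' @export
grasp_config <- function(alpha = 0.1, neighborhood = 0.05, restarts = 100L,
                         literal_rcl = FALSE) {
  stopifnot(alpha >= 0, alpha <= 1, neighborhood > 0, restarts >= 1)
  structure(list(alpha = alpha, neighborhood = neighborhood,
                 restarts = as.integer(restarts), literal_rcl = literal_rcl),
            class = "GRASPConfig")
}

# k-nearest-neighbor inverse-density weights, tempered by a square root and
# normalized to mean 1
density_weights <- function(D, k = 10L) {
  n <- nrow(D)
  k <- min(k, n - 1L)
  if (k < 1L) return(rep(1, n))
  rk <- apply(D, 1, function(r) sort(r, partial = k + 1L)[k + 1L])
  dens <- k / pmax(rk, 1e-12)  # kNN radius proxy: monotone in local density
  w <- 1 / sqrt(dens)
  w / mean(w)
}

grasp_objective <- function(D, w, sel) {
  if (length(sel) < 2L) return(0)
  s <- 0
  for (i in seq_along(sel)) for (j in seq_along(sel)) {
    if (j <= i) next
    s <- s + w[sel[i]] * w[sel[j]] * D[sel[i], sel[j]]
  }
  s
}

#' GRASP selection of maximally diverse points
#'
#' Maximizes the density-weighted total dissimilarity
#' `DS(F) = sum_{i<j in F} w_i w_j d(i, j)` over subsets of size `budget`.
#' Construction adds a random member of the restricted candidate list (the
#' top-`alpha` band of incremental dissimilarity by default); local search
#' swaps every member against its nearest neighbors (up to the neighborhood
#' fraction of the data set); the best of `restarts` repetitions is returned.
#'
#' @param points n x d matrix (one cluster's projected frames).
#' @param budget Number of points to select (`0` gives an empty selection).
#' @param config A [grasp_config()].
#' @param include Indices always contained in the selection (e.g. the cluster
#'   medoid).
#' @param weights Optional density weights; computed from a 10-NN inverse
#'   density by default.
#' @return List with `selected` (row indices), `objective` and `weights`.
#' @export
grasp_select <- function(points, budget, config = grasp_config(),
                         include = integer(0), weights = NULL) {
  x <- as.matrix(points)
  n <- nrow(x)
  budget <- min(budget, n)
  if (budget == 0L)
    return(list(selected = integer(0), objective = 0, weights = NULL))
  D <- as.matrix(stats::dist(x))
  w <- unname(if (is.null(weights)) density_weights(D) else weights)
  if (budget == n)
    return(list(selected = seq_len(n), objective = grasp_objective(D, w, seq_len(n)),
                weights = w))
  WD <- (w %o% w) * D
  # neighborhood fraction of the data set, floored so that small clusters
  # still get a meaningful local search
  nn_cap <- min(n - 1L, max(5L, ceiling(config$neighborhood * n)))
  nn_order <- apply(D, 1, order)   # column i: indices sorted by distance to i
  best_sel <- NULL; best_obj <- -Inf
  for (rs in seq_len(config$restarts)) {
    sel <- unique(as.integer(include))
    # construction: greedy-randomized additions from the RCL
    while (length(sel) < budget) {
      cand <- setdiff(seq_len(n), sel)
      inc <- if (length(sel)) {
        colSums(WD[sel, cand, drop = FALSE])
      } else {
        # first element: total weighted dissimilarity to all points
        colSums(WD[, cand, drop = FALSE])
      }
      dmin <- min(inc); dmax <- max(inc)
      band <- if (config$literal_rcl) {
        inc <= dmin + config$alpha * (dmax - dmin)
      } else {
        inc >= dmax - config$alpha * (dmax - dmin)
      }
      rcl <- cand[band]
      pick <- if (length(rcl) == 1L) rcl else rcl[sample.int(length(rcl), 1L)]
      sel <- c(sel, pick)
    }
    # local search: first-improvement swaps against nearest neighbors
    repeat {
      improved <- FALSE
      obj <- grasp_objective(D, w, sel)
      for (si in seq_along(sel)) {
        if (sel[si] %in% include) next
        neigh <- nn_order[-1, sel[si]][seq_len(nn_cap)]
        for (h in neigh) {
          if (h %in% sel) next
          trial <- sel; trial[si] <- h
          to <- grasp_objective(D, w, trial)
          if (to > obj + 1e-12) {
            sel <- trial; obj <- to; improved <- TRUE
            break
          }
        }
        if (improved) break
      }
      if (!improved) break
    }
    obj <- grasp_objective(D, w, sel)
    if (obj > best_obj) { best_obj <- obj; best_sel <- sort(sel) }
  }
  list(selected = best_sel, objective = best_obj, weights = w)
}

#' Largest-remainder proportional allocation
#'
#' Allocates `total` units over groups proportionally to `sizes`, assigning
#' floors first and distributing the remainder by largest fractional part
#' (ties toward the larger group, then the lower index).
#'
#' @param sizes Group sizes.
#' @param total Units to allocate.
#' @return Integer allocation summing to `total`.
#' @export
largest_remainder <- function(sizes, total) {
  quota <- total * sizes / sum(sizes)
  base <- floor(quota)
  rem <- total - sum(base)
  if (rem > 0) {
    frac <- quota - base
    ord <- order(-frac, -sizes, seq_along(sizes))
    base[ord[seq_len(rem)]] <- base[ord[seq_len(rem)]] + 1
  }
  as.integer(base)
}

#' Proportional per-cluster GRASP selection
#'
#' Splits a total frame budget over the clusters of a [pam_cluster()] model
#' by largest-remainder proportional allocation, runs [grasp_select()] inside
#' each cluster (the medoid is always included), and returns the combined
#' selection.
#'
#' @param points The projected coordinates the model was built on.
#' @param model A `ClusterModel`.
#' @param total_frames Total number of frames to select.
#' @param config A [grasp_config()].
#' @return A `SelectionResult`: `selected` (indices into `points`), `cluster`
#'   per selected frame, `budgets`, `medoids`, `objectives`.
#' @export
allocate_and_select <- function(points, model, total_frames,
                                config = grasp_config()) {
  sizes <- tabulate(model$labels, model$k)
  budgets <- largest_remainder(sizes, total_frames)
  sel <- integer(0); selcl <- integer(0); objs <- numeric(model$k)
  for (cl in seq_len(model$k)) {
    idx <- which(model$labels == cl)
    med_local <- match(model$medoids[cl], idx)
    gs <- grasp_select(points[idx, , drop = FALSE], budgets[cl], config,
                       include = med_local)
    sel <- c(sel, idx[gs$selected])
    selcl <- c(selcl, rep(cl, length(gs$selected)))
    objs[cl] <- gs$objective
  }
  structure(list(selected = sel, cluster = selcl, budgets = budgets,
                 medoids = model$medoids, objectives = objs),
            class = "SelectionResult")
}
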