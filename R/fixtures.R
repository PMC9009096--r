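# Deterministic generators of test systems: rigid water spheres at a target
# density (jittered lattice placement + rigid-body steepest descent), a toy
# rigid nitroxide-fragment solute with lone-pair virtual sites, and synthetic
# Gaussian-mixture feature-space trajectories with ground-truth labels.

water_geometry <- function(model) {
  wm <- water_model(model)
  th <- wm$theta_deg * pi / 180
  # O at origin, H's in the xz plane, bisector along +z
  h1 <- wm$r_OH * c(sin(th / 2), 0, cos(th / 2))
  h2 <- wm$r_OH * c(-sin(th / 2), 0, cos(th / 2))
  rbind(O = c(0, 0, 0), H1 = h1, H2 = h2)
}

water_topology <- function(model, n_molecules, frozen = integer(0)) {
  wm <- water_model(model)
  n <- n_molecules
  topology(mass = rep(c(wm$mass_O, wm$mass_H, wm$mass_H), n),
           charge = rep(c(wm$q_O, wm$q_H, wm$q_H), n),
           sigma = rep(c(wm$sigma_O, 0, 0), n),
           epsilon = rep(c(wm$eps_O, 0, 0), n),
           mol = rep(seq_len(n), each = 3L),
           name = rep(c("O", "H", "H"), n),
           frozen = frozen)
}

#' Specification of a water-sphere test system
#'
#' @param model `"SPC"` or `"TIP3P-FB"`.
#' @param radius Cavity radius (A), >= 6.
#' @param density Target mass density (g/cm^3); 0.997 is water at 298.15 K.
#' @param seed Integer seed; the builder is a pure function of (spec, seed).
#' @return A `BuildSpec` list.
#' @export
build_spec <- function(model = "SPC", radius = 8.5, density = 0.997,
                       seed = 1L) {
  stopifnot(radius >= 6, density > 0)
  structure(list(model = model, radius = radius, density = density,
                 seed = as.integer(seed)), class = "BuildSpec")
}

#' Number of water molecules at a target density
#'
#' `N = round(rho * V / m_molecule)` for the spherical volume `V = 4/3 pi R^3`.
#'
#' @param radius Cavity radius (A).
#' @param density Mass density (g/cm^3).
#' @param molar_mass Molecular mass (g/mol).
#' @return Integer molecule count.
#' @export
n_molecules_at_density <- function(radius, density = 0.997,
                                   molar_mass = 18.0154) {
  v <- 4 / 3 * pi * radius^3                    # A^3
  nd <- density / molar_mass * 0.602214076      # molecules / A^3
  as.integer(round(nd * v))
}

#' Build a rigid water sphere at the experimental density
#'
#' Places `N = round(rho V / m)` rigid water molecules on a jittered cubic
#' lattice clipped to the sphere with random orientations, then relaxes the
#' configuration by rigid-body steepest descent to remove close contacts.
#' Deterministic under the seed of the build specification.
#'
#' @param spec A [build_spec()].
#' @param relax_steps Steepest-descent iterations.
#' @return An `npbc_system`.
#' @export
build_water_sphere <- function(spec, relax_steps = 150L) {
  stopifnot(inherits(spec, "BuildSpec"))
  set.seed(spec$seed)
  wm <- water_model(spec$model)
  mmol <- wm$mass_O + 2 * wm$mass_H
  n <- n_molecules_at_density(spec$radius, spec$density, mmol)
  # lattice constant chosen so the clipped lattice (kept away from the wall
  # by a small margin) holds N sites; relaxation then spreads the molecules
  margin <- 0.8
  a <- (4 / 3 * pi * (spec$radius - margin)^3 / (1.12 * n))^(1 / 3)
  lattice_sites <- function(a) {
    # cubic lattice clipped to the sphere, offset so no site sits at 0,0,0
    k <- ceiling(spec$radius / a) + 1L
    g <- expand.grid(x = -k:k, y = -k:k, z = -k:k)
    sites <- sweep(as.matrix(g) * a, 2L, rep(a / 2, 3), "+")
    sites[order(rowSums(sites^2)), , drop = FALSE]
  }
  sites <- lattice_sites(a)
  keep <- which(sqrt(rowSums(sites^2)) < spec$radius - margin)
  while (length(keep) < n && a > 1.2) {
    # discrete clipping can be lumpy for small systems: tighten the lattice
    a <- a * 0.95
    sites <- lattice_sites(a)
    keep <- which(sqrt(rowSums(sites^2)) < spec$radius - margin)
  }
  if (length(keep) < n)
    stop(sprintf(paste0("cannot place %d molecules at density %.3f g/cm^3 ",
                        "inside R = %.2f A"), n, spec$density, spec$radius))
  sites <- sites[keep[seq_len(n)], , drop = FALSE]
  sites <- sites + matrix(runif(3 * n, -0.1, 0.1), n, 3)
  geom <- water_geometry(spec$model)
  pos <- matrix(0, 3L * n, 3L)
  for (m in seq_len(n)) {
    q <- rnorm(4); q <- q / sqrt(sum(q^2))
    Rm <- quat_to_mat(q)
    block <- geom %*% t(Rm)
    comg <- colSums(block * c(wm$mass_O, wm$mass_H, wm$mass_H)) / mmol
    pos[(3 * m - 2):(3 * m), ] <- sweep(block, 2L, comg - sites[m, ])
  }
  topo <- water_topology(spec$model, n)
  sys <- make_rigid_system(topo, pos, spec$radius)
  sys <- relax_rigid(sys, steps = relax_steps)
  # overlap-free placement check: relaxation must have opened all contacts
  D <- as.matrix(stats::dist(sys$positions))
  D[outer(topo$atoms$mol, topo$atoms$mol, "==")] <- Inf
  if (min(D) < 1.2)
    stop(sprintf(paste0("cannot place %d molecules at density %.3f g/cm^3 ",
                        "inside R = %.2f A: overlap-free placement failed"),
                 n, spec$density, spec$radius))
  sys
}

#' Rigid-body steepest-descent relaxation
#'
#' Quenches close contacts by translating and rotating whole molecules along
#' their net forces and torques, with displacement- and angle-clamped steps.
#'
#' @param sys An `npbc_system`.
#' @param steps Iterations.
#' @param max_disp Displacement clamp per step (A).
#' @param max_rot Rotation clamp per step (rad).
#' @return The relaxed system.
#' @export
relax_rigid <- function(sys, steps = 150L, max_disp = 0.15, max_rot = 0.15) {
  for (it in seq_len(steps)) {
    pf <- pair_energy_forces(sys$positions, sys$topology)
    ft <- .body_force_torque(sys, pf$forces)
    for (m in seq_len(nrow(sys$com))) {
      if (!sys$free[m]) next
      f <- ft$force[m, ]
      fn <- sqrt(sum(f^2))
      if (fn > 0) {
        step <- min(0.002 * fn, max_disp)
        newcom <- sys$com[m, ] + step * f / fn
        if (sum(newcom^2) < (sys$radius - 0.5)^2) sys$com[m, ] <- newcom
      }
      tq <- ft$torque[m, ]
      tn <- sqrt(sum(tq^2))
      if (tn > 0 && any(sys$inertia[m, ] > 0)) {
        ang <- min(0.002 * tn, max_rot)
        ax <- tq / tn
        dq <- c(cos(ang / 2), sin(ang / 2) * ax)
        qn <- quat_mul(dq, sys$quat[m, ])
        sys$quat[m, ] <- qn / sqrt(sum(qn^2))
      }
    }
    sys <- rebuild_positions(sys)
  }
  sys
}

#' Toy rigid nitroxide-fragment solute
#'
#' A rigid 4-atom mimic of a nitroxide moiety (two carbon-like anchors, N, O)
#' with two lone-pair virtual sites placed symmetrically out of the C-N-C
#' plane near the oxygen.  Charges give an N-O dipole; the solute is meant to
#' exercise the solute-insertion and feature-space machinery, not to model
#' any real radical.
#'
#' @return List with `topology` (single frozen molecule) and `positions`.
#' @export
toy_solute <- function() {
  # C1, C2, N, O, LP1, LP2
  pos <- rbind(c(-1.25, 0.95, 0), c(-1.25, -0.95, 0), c(-0.70, 0, 0),
               c(0.58, 0, 0), c(0, 0, 0), c(0, 0, 0))
  topo <- topology(
    mass = c(12.011, 12.011, 14.007, 15.999, 0, 0),
    charge = c(0.05, 0.05, 0.12, -0.42, 0.10, 0.10),
    sigma = c(3.4, 3.4, 3.25, 2.96, 0, 0),
    epsilon = c(0.36, 0.36, 0.71, 0.88, 0, 0),
    mol = rep(1L, 6L), name = c("C1", "C2", "N", "O", "LP1", "LP2"),
    virtual_sites = list(
      list(site = 5L, parents = c(4L, 3L, 1L), a = -0.18, b = 0, c = 0.25),
      list(site = 6L, parents = c(4L, 3L, 1L), a = -0.18, b = 0, c = -0.25)),
    frozen = 1L)
  pos <- project_virtual_sites(pos, topo)
  list(topology = topo, positions = pos)
}

#' Insert a solute at the cavity center
#'
#' Centers the solute at the origin and removes every solvent molecule having
#' any atom within the van der Waals contact distance
#' `0.5 * (sigma_solvent + sigma_solute)` of any solute atom (sites without
#' LJ, e.g. hydrogens and virtual sites, have zero contact radius).  The
#' operation is idempotent; a zero-radius point solute removes nothing.
#'
#' @param sys A solvent `npbc_system`.
#' @param solute A list with `topology` and `positions` (e.g. [toy_solute()]).
#' @return The combined `npbc_system` with the solute as the last (frozen)
#'   molecule.
#' @export
insert_solute <- function(sys, solute) {
  st <- solute$topology
  sp <- solute$positions
  ext <- max(sqrt(rowSums(sp^2)))
  if (ext >= sys$radius)
    stop("solute does not fit inside the cavity")
  sp <- sweep(sp, 2L, colMeans(sp[st$atoms$mass > 0, , drop = FALSE]))
  topo <- sys$topology
  keep_mol <- rep(TRUE, nrow(sys$com))
  for (m in seq_len(nrow(sys$com))) {
    idx <- which(topo$atoms$mol == m)
    for (i in idx) {
      d <- sqrt(colSums((t(sp) - sys$positions[i, ])^2))
      cut <- 0.5 * (topo$atoms$sigma[i] + st$atoms$sigma)
      if (any(d < cut)) { keep_mol[m] <- FALSE; break }
    }
  }
  kept <- which(keep_mol)
  atom_keep <- topo$atoms$mol %in% kept
  old <- topo$atoms[atom_keep, , drop = FALSE]
  old$mol <- match(old$mol, kept)
  nsolv <- length(kept)
  vs <- lapply(st$virtual_sites, function(v) {
    v$site <- v$site + nrow(old); v$parents <- v$parents + nrow(old); v
  })
  newtopo <- topology(c(old$mass, st$atoms$mass),
                      c(old$charge, st$atoms$charge),
                      c(old$sigma, st$atoms$sigma),
                      c(old$epsilon, st$atoms$epsilon),
                      c(old$mol, rep(nsolv + 1L, nrow(st$atoms))),
                      name = c(old$name, st$atoms$name),
                      virtual_sites = vs,
                      frozen = nsolv + 1L)
  newpos <- rbind(sys$positions[atom_keep, , drop = FALSE], sp)
  out <- make_rigid_system(newtopo, newpos, sys$radius, sys$time)
  out$removed <- sum(!keep_mol)
  out
}

#' Synthetic Gaussian-mixture feature trajectory
#'
#' Samples a labelled feature matrix from a mixture of Gaussians -- a stand-in
#' for MD feature spaces in clustering and selection tests.
#'
#' @param means k x d matrix of component means.
#' @param sds k x d matrix (or scalar) of per-dimension standard deviations.
#' @param weights Mixture weights (sum to 1).
#' @param n_frames Number of samples.
#' @param seed Integer seed.
#' @return List with `features` (n x d), `labels` (1..k) and `stride_ps`.
#' @export
synth_feature_trajectory <- function(means, sds = 1, weights = NULL,
                                     n_frames = 500L, seed = 1L) {
  means <- as.matrix(means)
  k <- nrow(means); d <- ncol(means)
  if (is.null(weights)) weights <- rep(1 / k, k)
  stopifnot(abs(sum(weights) - 1) < 1e-8)
  if (length(sds) == 1L) sds <- matrix(sds, k, d)
  set.seed(seed)
  lab <- sample.int(k, n_frames, replace = TRUE, prob = weights)
  x <- means[lab, , drop = FALSE] +
    matrix(rnorm(n_frames * d), n_frames, d) * sds[lab, , drop = FALSE]
  colnames(x) <- paste0("f", seq_len(d))
  list(features = x, labels = lab, stride_ps = 10)
}
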