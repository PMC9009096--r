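# Structural observables on finite-sphere (NPBC) trajectories.  The radial
# distribution function restricts central atoms to an inner selection sphere
# so that neighbor shells never cross the boundary, and normalizes by the
# ideal-gas count at the global number density of the finite droplet.

.traj_nframes <- function(traj) dim(traj$positions)[3]

.atom_sel <- function(traj, name) {
  idx <- which(traj$topology$atoms$name == name)
  if (!length(idx)) stop(sprintf("no atoms named '%s' in the topology", name))
  idx
}

#' Radial distribution function with finite-sphere normalization
#'
#' Histograms distances from central atoms (those within `r_sel` of the
#' cavity center) to all partner atoms up to `r_max`, and normalizes per
#' frame by the ideal-gas shell count at the droplet's global number density
#' `rho = N_partner / V(R)` and by the number of central atoms.  Requires
#' `r_sel + r_max <= R` so neighbor shells stay inside the boundary.
#'
#' @param traj An `npbc_trajectory`.
#' @param pair Character pair of atom names, e.g. `c("O", "O")`.
#' @param r_sel Central-atom selection radius (A).
#' @param r_max Neighbor cutoff (A).
#' @param bin_width Histogram bin (A), default 0.05.
#' @return An `RDFResult` with `r` (bin centers), `g`, `r_sel`, `r_max`,
#'   `n_frames`.
#' @export
rdf_npbc <- function(traj, pair = c("O", "O"), r_sel, r_max,
                     bin_width = 0.05) {
  Rmin <- min(traj$radius)
  if (r_sel + r_max > Rmin)
    stop(sprintf(paste0("r_sel + r_max = %.2f A exceeds the cavity radius ",
                        "%.2f A: neighbor shells would cross the boundary"),
                 r_sel + r_max, Rmin))
  ci <- .atom_sel(traj, pair[1])
  pi_ <- .atom_sel(traj, pair[2])
  mol <- traj$topology$atoms$mol
  nb <- ceiling(r_max / bin_width)
  counts <- numeric(nb)
  denom <- numeric(nb)
  edges <- (0:nb) * bin_width
  vshell <- 4 / 3 * pi * (edges[-1]^3 - edges[-(nb + 1)]^3)
  nf <- .traj_nframes(traj)
  for (k in seq_len(nf)) {
    x <- traj$positions[, , k]
    cx <- x[ci, , drop = FALSE]
    centers <- ci[rowSums(cx^2) <= r_sel^2]
    if (!length(centers)) next
    px <- x[pi_, , drop = FALSE]
    rho <- length(pi_) / (4 / 3 * pi * traj$radius[k]^3)
    for (i in centers) {
      d2 <- (px[, 1] - x[i, 1])^2 + (px[, 2] - x[i, 2])^2 +
        (px[, 3] - x[i, 3])^2
      ok <- mol[pi_] != mol[i] & d2 <= r_max^2
      if (any(ok)) {
        b <- pmin(floor(sqrt(d2[ok]) / bin_width) + 1L, nb)
        tb <- tabulate(b, nb)
        counts <- counts + tb
      }
    }
    denom <- denom + length(centers) * rho * vshell
  }
  structure(list(r = edges[-(nb + 1)] + bin_width / 2,
                 g = ifelse(denom > 0, counts / denom, 0),
                 r_sel = r_sel, r_max = r_max, bin_width = bin_width,
                 n_frames = nf),
            class = "RDFResult")
}

#' First-peak position and half width at half maximum of a g(r)
#'
#' The first-peak position is refined parabolically through the maximal bin
#' and its neighbors.  The baseline is the minimum of g to the left of the
#' peak (0 when the peak rises from the origin); the HWHM is the distance
#' from the peak to where g first falls to half the peak height above that
#' baseline, located by linear interpolation between bins.  By default the
#' crossing is sought on the falling (outer) flank; `side = "left"` measures
#' the rising flank instead.
#'
#' @param rdf An `RDFResult` (or any list with `r` and `g`).
#' @param side Flank on which the half-height crossing is measured.
#' @return List with `position` and `hwhm` (A), plus `height` and `baseline`.
#' @export
hwhm_first_peak <- function(rdf, side = c("right", "left")) {
  side <- match.arg(side)
  g <- rdf$g; r <- rdf$r
  ipk <- which.max(g)
  if (ipk <= 1L || ipk >= length(g) || g[ipk] <= 0)
    stop("no resolvable first peak in g(r)")
  base <- if (ipk > 1L) min(g[1:(ipk - 1L)]) else 0
  if (g[ipk] - base <= .Machine$double.eps * 10 ||
      (max(g) - min(g)) < 1e-3 * max(g))
    stop("no resolvable first peak in g(r): profile is flat")
  # parabolic refinement of the peak position
  y1 <- g[ipk - 1L]; y2 <- g[ipk]; y3 <- g[ipk + 1L]
  dd <- (y1 - 2 * y2 + y3)
  off <- if (dd != 0) 0.5 * (y1 - y3) / dd else 0
  pos <- r[ipk] + off * rdf$bin_width
  half <- base + 0.5 * (g[ipk] - base)
  if (side == "left") {
    i <- ipk
    while (i > 1L && g[i - 1L] > half) i <- i - 1L
    if (i == 1L) stop("no resolvable first peak in g(r): no half crossing")
    frac <- (half - g[i - 1L]) / (g[i] - g[i - 1L])
    rcross <- r[i - 1L] + frac * (r[i] - r[i - 1L])
    hw <- pos - rcross
  } else {
    i <- ipk
    while (i < length(g) && g[i + 1L] > half) i <- i + 1L
    if (i == length(g))
      stop("no resolvable first peak in g(r): no half crossing")
    frac <- (g[i] - half) / (g[i] - g[i + 1L])
    rcross <- r[i] + frac * (r[i + 1L] - r[i])
    hw <- rcross - pos
  }
  list(position = pos, hwhm = hw, height = g[ipk], baseline = base)
}

#' Mean density in constant-volume concentric shells
#'
#' Splits the sphere into `n_shells` equal-volume shells
#' (`r_i = R (i/n)^(1/3)`), assigns each molecule by its centre of mass, and
#' reports the mass density per shell averaged over frames with its standard
#' deviation across frames.
#'
#' @param traj An `npbc_trajectory`.
#' @param n_shells Number of shells (>= 2).
#' @return Data frame with `r_inner`, `r_outer`, `mean_density`, `sd_density`
#'   (g/cm^3).
#' @export
shell_density <- function(traj, n_shells = 5L) {
  stopifnot(n_shells >= 2L)
  topo <- traj$topology
  mol <- topo$atoms$mol
  nmol <- max(mol)
  mass <- vapply(seq_len(nmol),
                 function(m) sum(topo$atoms$mass[mol == m]), 0)
  mm <- topo$atoms$mass
  nf <- .traj_nframes(traj)
  dens <- matrix(0, nf, n_shells)
  for (k in seq_len(nf)) {
    R <- traj$radius[k]
    edges <- R * (seq_len(n_shells) / n_shells)^(1 / 3)
    vol <- 4 / 3 * pi * R^3 / n_shells        # equal volumes, A^3
    x <- traj$positions[, , k]
    com2 <- vapply(seq_len(nmol), function(m) {
      idx <- mol == m
      sum((colSums(x[idx, , drop = FALSE] * mm[idx]) / mass[m])^2)
    }, 0)
    sh <- findInterval(sqrt(com2), edges) + 1L
    for (s in seq_len(n_shells)) {
      msum <- sum(mass[sh == s])
      dens[k, s] <- msum / vol / 0.602214076   # amu/A^3 -> g/cm^3
    }
  }
  edges <- traj$radius[1] * (0:n_shells / n_shells)^(1 / 3)
  data.frame(r_inner = edges[-(n_shells + 1)], r_outer = edges[-1],
             mean_density = colMeans(dens),
             sd_density = apply(dens, 2, sd))
}

#' Parameters of the continuous hydrogen-bond strength function
#'
#' @param r0 Distance midpoint of the H...acceptor switch (A).
#' @param a Distance steepness (1/A).
#' @param theta0 Donor-H-acceptor angle midpoint (degrees).
#' @param b Angle steepness (1/degree).
#' @param donor,hydrogen,acceptor Atom names of donor heavy atoms, their
#'   hydrogens and acceptor atoms.
#' @return An `HBondParams` list.
#' @export
hbond_params <- function(r0 = 2.5, a = 10, theta0 = 140, b = 0.1,
                         donor = "O", hydrogen = "H", acceptor = "O") {
  stopifnot(a > 0, b > 0)
  structure(list(r0 = r0, a = a, theta0 = theta0, b = b, donor = donor,
                 hydrogen = hydrogen, acceptor = acceptor),
            class = "HBondParams")
}

#' Continuous hydrogen-bond strength of one frame
#'
#' For every donor-H / acceptor pair (different molecules) the pair strength
#' is the product of two logistic switches,
#' `S_r(r) = 1/(1 + exp(a (r - r0)))` on the H...acceptor distance and
#' `S_theta(theta) = 1/(1 + exp(-b (theta - theta0)))` on the
#' donor-H-acceptor angle, each in `[0, 1]`.
#'
#' @param positions n x 3 coordinates of one frame (A).
#' @param topo A [topology()].
#' @param params An [hbond_params()].
#' @return List with `total` and a data frame `pairs`
#'   (donor H index, acceptor index, r, theta, strength).
#' @export
f_hb <- function(positions, topo, params = hbond_params()) {
  at <- topo$atoms
  hyd <- which(at$name == params$hydrogen)
  acc <- which(at$name == params$acceptor)
  # donor heavy atom for each H: same-molecule atom with the donor name
  res <- list()
  tot <- 0
  for (h in hyd) {
    dheavy <- which(at$name == params$donor & at$mol == at$mol[h])
    if (!length(dheavy)) next
    d <- dheavy[1]
    aok <- acc[at$mol[acc] != at$mol[h]]
    if (!length(aok)) next
    rha <- sqrt(colSums((t(positions[aok, , drop = FALSE]) -
                           positions[h, ])^2))
    near <- which(rha < 2 * params$r0)
    if (!length(near)) next
    v1 <- positions[d, ] - positions[h, ]
    for (jj in near) {
      aidx <- aok[jj]
      v2 <- positions[aidx, ] - positions[h, ]
      cosang <- sum(v1 * v2) / sqrt(sum(v1^2) * sum(v2^2))
      theta <- acos(min(max(cosang, -1), 1)) * 180 / pi
      s <- 1 / (1 + exp(params$a * (rha[jj] - params$r0))) *
        1 / (1 + exp(-params$b * (theta - params$theta0)))
      tot <- tot + s
      res[[length(res) + 1L]] <- c(h, aidx, rha[jj], theta, s)
    }
  }
  pairs <- if (length(res)) {
    df <- as.data.frame(do.call(rbind, res))
    names(df) <- c("hydrogen", "acceptor", "r", "theta", "strength")
    df
  } else {
    data.frame(hydrogen = integer(), acceptor = integer(), r = numeric(),
               theta = numeric(), strength = numeric())
  }
  list(total = tot, pairs = pairs)
}
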