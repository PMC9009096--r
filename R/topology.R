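# Topology container: per-atom masses, charges, Lennard-Jones parameters and
# molecule membership, plus rigid-body membership, virtual sites (massless
# charge carriers placed from parent atoms) and holonomic constraints.
# Intramolecular pairs are always excluded from nonbonded interactions.

#' System topology
#'
#' @param mass Per-atom masses (amu); virtual sites have mass 0.
#' @param charge Per-atom charges (e).
#' @param sigma,epsilon Lennard-Jones parameters (A, kJ/mol); 0 disables LJ
#'   on a site.  Lorentz-Berthelot combination is used between sites.
#' @param mol Integer molecule id per atom (1-based, consecutive).
#' @param name Optional atom names (element symbols by default).
#' @param virtual_sites List of virtual-site rules, each
#'   `list(site, parents = c(i, j, k), a, b, c)`: the site is placed at
#'   `r_i + a*(r_j - r_i) + b*(r_k - r_i) + c*(r_j - r_i) x (r_k - r_i)`
#'   (an out-of-plane construction; `c != 0` lifts the site off the parent
#'   plane).  Virtual sites must be massless and carry no LJ.
#' @param constraints Matrix with columns `(i, j, dist)` of holonomic bond
#'   constraints (A), used by the RATTLE integrator path.
#' @param frozen Integer vector of molecule ids kept immobile (e.g. a solute).
#' @return A `Topology` object.
#' @export
topology <- function(mass, charge, sigma, epsilon, mol, name = NULL,
                     virtual_sites = list(), constraints = NULL,
                     frozen = integer(0)) {
  n <- length(mass)
  stopifnot(length(charge) == n, length(sigma) == n, length(epsilon) == n,
            length(mol) == n, all(mol >= 1L), all(is.finite(mass)))
  if (is.null(name)) name <- rep("X", n)
  for (vs in virtual_sites) {
    stopifnot(length(vs$parents) == 3L)
    if (mass[vs$site] != 0)
      stop(sprintf("virtual site %d must be massless", vs$site))
    if (epsilon[vs$site] != 0)
      stop(sprintf("virtual site %d must carry charge only (no LJ)", vs$site))
  }
  if (!is.null(constraints)) {
    constraints <- matrix(as.numeric(constraints), ncol = 3L)
    if (any(constraints[, 3] <= 0)) stop("constraint distances must be > 0")
  }
  structure(list(n_atoms = n,
                 atoms = data.frame(name = name, mass = mass, charge = charge,
                                    sigma = sigma, epsilon = epsilon,
                                    mol = as.integer(mol),
                                    stringsAsFactors = FALSE),
                 virtual_sites = virtual_sites,
                 constraints = constraints,
                 frozen = as.integer(frozen)),
            class = "Topology")
}

#' @export
print.Topology <- function(x, ...) {
  cat(sprintf("Topology: %d atoms, %d molecules, %d virtual sites, %d constraints\n",
              x$n_atoms, length(unique(x$atoms$mol)), length(x$virtual_sites),
              if (is.null(x$constraints)) 0L else nrow(x$constraints)))
  invisible(x)
}

#' Place virtual sites from their parent atoms
#'
#' Applies each virtual-site construction rule to the current positions.
#' The construction is deterministic and idempotent (sites do not serve as
#' parents).
#'
#' @param positions n x 3 matrix (A).
#' @param topo A [topology()].
#' @return Updated positions with virtual sites placed.
#' @export
project_virtual_sites <- function(positions, topo) {
  for (vs in topo$virtual_sites) {
    p <- vs$parents
    ri <- positions[p[1], ]; rj <- positions[p[2], ]; rk <- positions[p[3], ]
    u <- rj - ri; v <- rk - ri
    cr <- c(u[2] * v[3] - u[3] * v[2],
            u[3] * v[1] - u[1] * v[3],
            u[1] * v[2] - u[2] * v[1])
    if (vs$c != 0 && sqrt(sum(cr^2)) < 1e-8 * sqrt(sum(u^2)) * sqrt(sum(v^2)))
      stop(sprintf("degenerate (collinear) parents for virtual site %d",
                   vs$site))
    positions[vs$site, ] <- ri + vs$a * u + vs$b * v + vs$c * cr
  }
  positions
}

#' Transfer virtual-site forces to parent atoms
#'
#' Redistributes the force acting on each virtual site onto its parents by
#' the chain rule of the construction, so that the gradient with respect to
#' parent coordinates (with sites re-projected) is exact.  Site forces are
#' zeroed afterwards; total force is conserved.
#'
#' @param positions n x 3 positions with sites placed.
#' @param forces n x 3 forces including site forces.
#' @param topo A [topology()].
#' @return Updated force matrix.
#' @export
vsite_spread_forces <- function(positions, forces, topo) {
  for (vs in topo$virtual_sites) {
    p <- vs$parents
    fs <- forces[vs$site, ]
    ri <- positions[p[1], ]; rj <- positions[p[2], ]; rk <- positions[p[3], ]
    u <- rj - ri; v <- rk - ri
    cross <- function(a, b) c(a[2] * b[3] - a[3] * b[2],
                              a[3] * b[1] - a[1] * b[3],
                              a[1] * b[2] - a[2] * b[1])
    forces[p[1], ] <- forces[p[1], ] + (1 - vs$a - vs$b) * fs +
      vs$c * (cross(u, fs) - cross(v, fs))
    forces[p[2], ] <- forces[p[2], ] + vs$a * fs + vs$c * cross(v, fs)
    forces[p[3], ] <- forces[p[3], ] + vs$b * fs - vs$c * cross(u, fs)
    forces[vs$site, ] <- 0
  }
  forces
}

# ---------------------------------------------------------------------------
# Plain-text topology and coordinate formats
# ---------------------------------------------------------------------------

#' Write / read a topology as a sectioned text file
#'
#' The format has `[atoms]` (name mass charge sigma epsilon mol),
#' `[virtual_sites]` (site pi pj pk a b c), `[constraints]` (i j dist) and
#' `[frozen]` (molecule ids) sections.
#'
#' @param topo A [topology()].
#' @param file Path.
#' @return `read_topology` returns a [topology()].
#' @export
write_topology <- function(topo, file) {
  con <- file(file, "w"); on.exit(close(con))
  writeLines("[atoms]", con)
  a <- topo$atoms
  writeLines(sprintf("%s %.6f %.12g %.8g %.8g %d", a$name, a$mass, a$charge,
                     a$sigma, a$epsilon, a$mol), con)
  if (length(topo$virtual_sites)) {
    writeLines("[virtual_sites]", con)
    for (vs in topo$virtual_sites)
      writeLines(sprintf("%d %d %d %d %.10g %.10g %.10g", vs$site,
                         vs$parents[1], vs$parents[2], vs$parents[3],
                         vs$a, vs$b, vs$c), con)
  }
  if (!is.null(topo$constraints)) {
    writeLines("[constraints]", con)
    writeLines(sprintf("%d %d %.10g", topo$constraints[, 1],
                       topo$constraints[, 2], topo$constraints[, 3]), con)
  }
  if (length(topo$frozen)) {
    writeLines("[frozen]", con)
    writeLines(paste(topo$frozen, collapse = " "), con)
  }
  invisible(file)
}

#' @rdname write_topology
#' @export
read_topology <- function(file) {
  lines <- trimws(readLines(file))
  lines <- lines[nzchar(lines)]
  sec <- cumsum(grepl("^\\[", lines))
  headers <- lines[grepl("^\\[", lines)]
  out <- list(virtual_sites = list(), constraints = NULL, frozen = integer(0))
  for (s in seq_along(headers)) {
    body <- lines[sec == s & !grepl("^\\[", lines)]
    key <- gsub("\\[|\\]", "", headers[s])
    if (key == "atoms") {
      tok <- do.call(rbind, strsplit(body, "\\s+"))
      out$atoms <- data.frame(name = tok[, 1],
                              mass = as.numeric(tok[, 2]),
                              charge = as.numeric(tok[, 3]),
                              sigma = as.numeric(tok[, 4]),
                              epsilon = as.numeric(tok[, 5]),
                              mol = as.integer(tok[, 6]),
                              stringsAsFactors = FALSE)
    } else if (key == "virtual_sites") {
      for (ln in body) {
        v <- as.numeric(strsplit(ln, "\\s+")[[1]])
        out$virtual_sites <- c(out$virtual_sites,
                               list(list(site = as.integer(v[1]),
                                         parents = as.integer(v[2:4]),
                                         a = v[5], b = v[6], c = v[7])))
      }
    } else if (key == "constraints") {
      out$constraints <- do.call(rbind, lapply(strsplit(body, "\\s+"),
                                               as.numeric))
    } else if (key == "frozen") {
      out$frozen <- as.integer(strsplit(body, "\\s+")[[1]])
    }
  }
  a <- out$atoms
  topology(a$mass, a$charge, a$sigma, a$epsilon, a$mol, name = a$name,
           virtual_sites = out$virtual_sites, constraints = out$constraints,
           frozen = out$frozen)
}

#' Read and write XYZ coordinate files
#'
#' Standard XYZ (element + Angstrom coordinates).  The comment line holds
#' `key=value` metadata (e.g. `time=... radius=...`); [write_xyz()] accepts a
#' named list for it.
#'
#' @param file Path.
#' @param positions n x 3 matrix.
#' @param elements Character vector of element symbols.
#' @param meta Named list written to the comment line.
#' @param append Append a frame instead of overwriting (trajectories).
#' @return `read_xyz` returns `list(elements, positions, meta)` for the first
#'   frame; `read_xyz_trajectory` returns a list of such frames.
#' @export
write_xyz <- function(positions, elements, file, meta = list(),
                      append = FALSE) {
  con <- file(file, if (append) "a" else "w"); on.exit(close(con))
  writeLines(as.character(nrow(positions)), con)
  writeLines(paste(sprintf("%s=%.8g", names(meta), as.numeric(meta)),
                   collapse = " "), con)
  writeLines(sprintf("%-3s %14.8f %14.8f %14.8f", elements, positions[, 1],
                     positions[, 2], positions[, 3]), con)
  invisible(file)
}

#' @rdname write_xyz
#' @export
read_xyz <- function(file) {
  read_xyz_trajectory(file)[[1]]
}

#' @rdname write_xyz
#' @export
read_xyz_trajectory <- function(file) {
  lines <- readLines(file)
  frames <- list()
  i <- 1L
  while (i <= length(lines) && nzchar(trimws(lines[i]))) {
    n <- as.integer(trimws(lines[i]))
    meta <- list()
    cm <- trimws(lines[i + 1L])
    if (nzchar(cm)) {
      kv <- strsplit(strsplit(cm, "\\s+")[[1]], "=")
      kv <- kv[vapply(kv, length, 1L) == 2L]
      meta <- setNames(lapply(kv, function(p) as.numeric(p[2])),
                       vapply(kv, `[`, "", 1L))
    }
    tok <- do.call(rbind, strsplit(trimws(lines[i + 1L + seq_len(n)]), "\\s+"))
    frames[[length(frames) + 1L]] <-
      list(elements = tok[, 1],
           positions = matrix(as.numeric(tok[, 2:4]), ncol = 3L),
           meta = meta)
    i <- i + 2L + n
  }
  frames
}
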