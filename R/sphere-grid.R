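# Real spherical harmonics and Lebedev-Laikov quadrature grids on the unit
# sphere.  Basis functions use the real orthonormal convention and the flat
# index map j = l*(l+1) + m + 1 (1-based), so the monopole is element 1.

#' Real spherical-harmonic basis descriptor
#'
#' @param l_max Maximum angular momentum (integer >= 0).
#' @return A `HarmonicBasis` object with `l_max`, the number of basis
#'   functions `(l_max+1)^2` and the convention tag.
#' @examples
#' harmonic_basis(10)$n_basis
#' @export
harmonic_basis <- function(l_max) {
  l_max <- as.integer(l_max)
  stopifnot(length(l_max) == 1L, l_max >= 0L)
  structure(list(l_max = l_max, n_basis = (l_max + 1L)^2,
                 convention = "real-orthonormal"),
            class = "HarmonicBasis")
}

#' Flat (l, m) index of the harmonic basis
#'
#' @param l Angular momentum.
#' @param m Order, `-l <= m <= l`.
#' @return 1-based position `l*(l+1) + m + 1` in the coefficient vectors.
#' @export
sh_index <- function(l, m) {
  stopifnot(all(abs(m) <= l))
  l * (l + 1L) + m + 1L
}

#' Evaluate real orthonormal spherical harmonics
#'
#' Evaluates all `Y_lm` up to `basis$l_max` at one or more unit vectors, in
#' the flat `(l, m)` ordering of [sh_index()].  The convention is real
#' orthonormal: the Gram matrix over the sphere is the identity, and
#' `Y_00 = 1/sqrt(4*pi)`.
#'
#' @param basis A [harmonic_basis()].
#' @param direction A unit 3-vector, or a matrix with one unit vector per row.
#' @return A vector of `(l_max+1)^2` values (or a matrix with one row per
#'   input direction).
#' @examples
#' eval_real_sph_harm(harmonic_basis(1), c(0, 0, 1))
#' @export
eval_real_sph_harm <- function(basis, direction) {
  stopifnot(inherits(basis, "HarmonicBasis"))
  d <- if (is.matrix(direction)) direction else matrix(direction, nrow = 1L)
  stopifnot(ncol(d) == 3L)
  nrm <- sqrt(rowSums(d^2))
  bad <- which(abs(nrm - 1) > 1e-9)
  if (length(bad))
    stop(sprintf("direction %d is not a unit vector (norm = %.12g)",
                 bad[1], nrm[bad[1]]))
  out <- cpp_sph_harm(basis$l_max, d)
  if (!is.matrix(direction)) drop(out) else out
}

#' Supported Lebedev-Laikov grid sizes
#' @return Integer vector of supported node counts.
#' @export
lebedev_sizes <- function() as.integer(names(.lebedev_raw))

#' Build a Lebedev-Laikov quadrature grid on the unit sphere
#'
#' Returns the node table of the Lebedev-Laikov rule with the requested
#' number of points.  Weights are normalized to sum to 1, so an integral over
#' the sphere is `4*pi * sum(w * f(s))`.  A rule of algebraic precision `p`
#' integrates spherical harmonics exactly up to degree `p`.
#'
#' @param requested_points One of [lebedev_sizes()].
#' @return A `LebedevGrid` with fields `order` (node count), `precision`,
#'   `points` (n x 3 unit vectors) and `weights`.
#' @examples
#' g <- build_lebedev_grid(6)
#' sum(g$weights)
#' @export
build_lebedev_grid <- function(requested_points) {
  key <- as.character(as.integer(requested_points))
  if (!key %in% names(.lebedev_raw))
    stop(sprintf("unsupported Lebedev grid size %s; supported sizes: %s",
                 key, paste(names(.lebedev_raw), collapse = ", ")))
  raw <- .lebedev_raw[[key]]
  structure(list(order = as.integer(key), precision = raw$precision,
                 points = raw$xyz, weights = raw$w),
            class = "LebedevGrid")
}
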