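#' Unit cell with an associated real-space sampling grid
#'
#' Defines the periodic box on which densities live: cell dimensions, a
#' regular grid (fractional coordinates, voxel `(0,0,0)` at the origin,
#' 0-based indexing) and the resolution limit `d_min` of the associated
#' reflection data. The grid must sample the cell finely enough for the
#' requested resolution (spacing at most `d_min / 2` along every axis), so
#' that all reflections within the resolution sphere sit strictly inside the
#' Nyquist box of the discrete Fourier transform.
#'
#' @param cell_lengths numeric(3), cell edges a, b, c in Angstrom.
#' @param cell_angles numeric(3), cell angles alpha, beta, gamma in degrees.
#' @param shape integer(3), number of grid divisions along each axis
#'   (even values only).
#' @param d_min resolution limit in Angstrom.
#' @return An object of class `unit_cell_grid` with the direct and reciprocal
#'   metric tensors and cell volume precomputed.
#' @export
unit_cell_grid <- function(cell_lengths, cell_angles = c(90, 90, 90), shape,
                           d_min) {
  cell_lengths <- as.numeric(cell_lengths)
  cell_angles <- as.numeric(cell_angles)
  shape <- as.integer(shape)
  if (length(cell_lengths) == 1L) cell_lengths <- rep(cell_lengths, 3L)
  if (length(shape) == 1L) shape <- rep(shape, 3L)
  stopifnot(length(cell_lengths) == 3L, length(cell_angles) == 3L,
            length(shape) == 3L, length(d_min) == 1L)
  if (any(!is.finite(cell_lengths)) || any(cell_lengths <= 0))
    stop("cell lengths must be positive and finite")
  if (any(cell_angles <= 0) || any(cell_angles >= 180))
    stop("cell angles must lie in (0, 180) degrees")
  if (any(shape < 2L)) stop("grid shape entries must be >= 2")
  if (any(shape %% 2L != 0L)) stop("grid dimensions must be even")
  if (!is.finite(d_min) || d_min <= 0) stop("d_min must be positive")

  ca <- cos(cell_angles * pi / 180)
  G <- diag(cell_lengths^2)
  G[1, 2] <- G[2, 1] <- cell_lengths[1] * cell_lengths[2] * ca[3]
  G[1, 3] <- G[3, 1] <- cell_lengths[1] * cell_lengths[3] * ca[2]
  G[2, 3] <- G[3, 2] <- cell_lengths[2] * cell_lengths[3] * ca[1]
  vol <- sqrt(det(G))
  Gstar <- solve(G)

  spacing <- cell_lengths / shape
  if (any(spacing > d_min / 2 + 1e-9))
    stop("grid too coarse for d_min: spacing must be <= d_min/2 on every axis")

  structure(
    list(lengths = cell_lengths, angles = cell_angles, shape = shape,
         d_min = d_min, metric = G, metric_star = Gstar, volume = vol),
    class = "unit_cell_grid")
}

#' @export
print.unit_cell_grid <- function(x, ...) {
  cat(sprintf("Unit cell %.2f %.2f %.2f A, %g %g %g deg; grid %d x %d x %d; d_min %.2f A\n",
              x$lengths[1], x$lengths[2], x$lengths[3],
              x$angles[1], x$angles[2], x$angles[3],
              x$shape[1], x$shape[2], x$shape[3], x$d_min))
  invisible(x)
}

#' Resolution of reflections
#'
#' d-spacing in Angstrom of Miller index triples for a given cell, from the
#' reciprocal metric tensor (valid for any triclinic cell).
#'
#' @param cell a [unit_cell_grid()].
#' @param hkl integer matrix with columns h, k, l (a single triple may be
#'   given as a vector).
#' @return numeric vector of d-spacings.
#' @export
d_spacing <- function(cell, hkl) {
  hkl <- rbind_hkl(hkl)
  inv_d2 <- rowSums((hkl %*% cell$metric_star) * hkl)
  1 / sqrt(inv_d2)
}

rbind_hkl <- function(hkl) {
  if (is.null(dim(hkl))) hkl <- matrix(hkl, ncol = 3L)
  storage.mode(hkl) <- "integer"
  hkl
}

# Friedel-unique hemisphere convention: keep (h,k,l) when h > 0, or h == 0 and
# k > 0, or h == k == 0 and l > 0.  (0,0,0) is never a reflection.
hemisphere_canonical <- function(hkl) {
  hkl <- rbind_hkl(hkl)
  h <- hkl[, 1]; k <- hkl[, 2]; l <- hkl[, 3]
  h > 0 | (h == 0 & k > 0) | (h == 0 & k == 0 & l > 0)
}

#' Enumerate the Friedel-unique reflection indices of a grid
#'
#' All Miller indices in the canonical hemisphere with `d >= d_min`, sorted
#' lexicographically by (h, k, l).  Indices are guaranteed to lie strictly
#' inside the Nyquist box of the grid (|index| <= shape/2 - 1), which the
#' Shannon condition on the grid ensures.
#'
#' @param cell a [unit_cell_grid()].
#' @return integer matrix with columns `h`, `k`, `l`.
#' @export
reflection_indices <- function(cell) {
  hmax <- pmin(cell$shape %/% 2L - 1L,
               ceiling(cell$lengths / cell$d_min))
  grid <- expand.grid(l = -hmax[3]:hmax[3], k = -hmax[2]:hmax[2],
                      h = -hmax[1]:hmax[1])
  hkl <- cbind(h = grid$h, k = grid$k, l = grid$l)
  hkl <- hkl[hemisphere_canonical(hkl), , drop = FALSE]
  keep <- d_spacing(cell, hkl) >= cell$d_min - 1e-9
  hkl <- hkl[keep, , drop = FALSE]
  hkl[order(hkl[, 1], hkl[, 2], hkl[, 3]), , drop = FALSE]
}

#' Indexed Fourier data for a crystal
#'
#' A `reflection_set` stores one member of each Friedel pair (the canonical
#' hemisphere), sorted lexicographically by (h, k, l) so that replicate runs
#' align term by term.  Each reflection carries a measured amplitude
#' (`NA` when unmeasured), an optional reference phase used for scoring, a
#' centric flag, a statistical degeneracy factor epsilon, its d-spacing and a
#' measured/unmeasured status.
#'
#' @param hkl integer matrix with columns h, k, l (Friedel-unique; (0,0,0)
#'   excluded).
#' @param cell a [unit_cell_grid()] or `NULL` for geometry-free sets (used by
#'   purely statistical experiments).
#' @param f_measured numeric amplitudes, `NA` allowed for unmeasured terms.
#' @param phase_ref reference phases in radians, or `NA`.
#' @param centric logical centric flags.
#' @param epsilon positive degeneracy factors (1 in P1).
#' @param is_measured logical; defaults to `!is.na(f_measured)`.
#' @param f000 the F(000) term, carried separately from the reflection list.
#' @return An object of class `reflection_set`: a data frame with columns
#'   `h,k,l,f_measured,phase_ref,centric,epsilon,d,is_measured` plus `cell`
#'   and `f000` attributes.
#' @export
reflection_set <- function(hkl, cell = NULL, f_measured = NA_real_,
                           phase_ref = NA_real_, centric = FALSE,
                           epsilon = 1, is_measured = NULL, f000 = 0) {
  hkl <- rbind_hkl(hkl)
  n <- nrow(hkl)
  if (n < 1L) stop("empty reflection list")
  if (any(hkl[, 1] == 0 & hkl[, 2] == 0 & hkl[, 3] == 0))
    stop("(0,0,0) is not a reflection; F(000) is carried separately")
  if (!all(hemisphere_canonical(hkl)))
    stop("reflections must be Friedel-unique (canonical hemisphere only)")
  key <- paste(hkl[, 1], hkl[, 2], hkl[, 3])
  if (anyDuplicated(key))
    stop("duplicate hkl: ", key[duplicated(key)][1])

  f_measured <- rep_len(as.numeric(f_measured), n)
  if (any(f_measured < 0, na.rm = TRUE)) stop("negative measured amplitude")
  phase_ref <- rep_len(as.numeric(phase_ref), n)
  if (any(is.finite(phase_ref)))
    phase_ref <- ifelse(is.na(phase_ref), NA_real_, wrap_angle(phase_ref))
  centric <- rep_len(as.logical(centric), n)
  epsilon <- rep_len(as.numeric(epsilon), n)
  if (any(!is.finite(epsilon)) || any(epsilon <= 0))
    stop("epsilon factors must be positive")
  if (is.null(is_measured)) is_measured <- !is.na(f_measured)
  is_measured <- rep_len(as.logical(is_measured), n)

  d <- if (is.null(cell)) rep(NA_real_, n) else d_spacing(cell, hkl)
  if (!is.null(cell) && any(d < cell$d_min - 1e-9))
    stop("reflections beyond the d_min resolution limit of the cell")

  df <- data.frame(h = hkl[, 1], k = hkl[, 2], l = hkl[, 3],
                   f_measured = f_measured, phase_ref = phase_ref,
                   centric = centric, epsilon = epsilon, d = d,
                   is_measured = is_measured)
  df <- df[order(df$h, df$k, df$l), , drop = FALSE]
  rownames(df) <- NULL
  structure(df, cell = cell, f000 = as.numeric(f000),
            class = c("reflection_set", "data.frame"))
}

#' @export
print.reflection_set <- function(x, ...) {
  cell <- attr(x, "cell")
  cat(sprintf("Reflection set: %d Friedel-unique reflections (%d measured, %d centric)\n",
              nrow(x), sum(x$is_measured), sum(x$centric)))
  if (!is.null(cell))
    cat(sprintf("  resolution %.2f - %.2f A; F(000) = %.4g\n",
                max(x$d), min(x$d), attr(x, "f000")))
  invisible(x)
}

#' Real-space density map on a cell grid
#'
#' @param values numeric array matching the grid shape of `cell` (a vector is
#'   reshaped).
#' @param cell a [unit_cell_grid()].
#' @return An object of class `density_map` (a 3D array with a `cell`
#'   attribute).
#' @export
density_map <- function(values, cell) {
  stopifnot(inherits(cell, "unit_cell_grid"))
  if (is.null(dim(values))) {
    if (length(values) == 1L) values <- rep(values, prod(cell$shape))
    dim(values) <- cell$shape
  }
  if (!all(dim(values) == cell$shape)) stop("map shape does not match grid")
  if (any(!is.finite(values))) stop("non-finite map values")
  structure(values, cell = cell, class = "density_map")
}

#' @export
print.density_map <- function(x, ...) {
  cell <- attr(x, "cell")
  cat(sprintf("Density map %d x %d x %d; mean %.4g, sd %.4g\n",
              dim(x)[1], dim(x)[2], dim(x)[3], mean(x), stats::sd(x)))
  invisible(x)
}

map_cell <- function(map) {
  cell <- attr(map, "cell")
  if (is.null(cell)) stop("map carries no cell")
  cell
}

# 1-based linear indices into the FFT array for Miller index triples.
grid_linear_index <- function(hkl, shape) {
  hm <- hkl[, 1] %% shape[1]
  km <- hkl[, 2] %% shape[2]
  lm <- hkl[, 3] %% shape[3]
  1 + hm + shape[1] * (km + shape[2] * lm)
}

#' Fourier analysis: density to structure factors
#'
#' Computes the complex structure factors F(h) = sum_x rho(x) exp(+2 pi i h.x)
#' (unnormalized discrete Fourier transform, fractional coordinates x) at the
#' stored reflections.  Because the map is real, Friedel mates are implied:
#' F(-h) = conj(F(h)).  On this scale F(000) equals the sum of the map, i.e.
#' the mean density times the number of grid points.
#'
#' @param map a [density_map()].
#' @param refl a [reflection_set()] sharing the map's cell.
#' @return complex vector aligned with the rows of `refl`.
#' @export
density_to_structure_factors <- function(map, refl) {
  cell <- map_cell(map)
  check_same_cell(cell, attr(refl, "cell"))
  if (any(!is.finite(map))) stop("non-finite map values")
  Farr <- stats::fft(unclass(map), inverse = TRUE)  # e^{+2 pi i h.x}
  idx <- grid_linear_index(as.matrix(refl[, c("h", "k", "l")]), cell$shape)
  Farr[idx]
}

#' Fourier synthesis: structure factors to density
#'
#' Inverse of [density_to_structure_factors()]: places each coefficient and
#' its Friedel mate on the reciprocal grid (all unlisted coefficients are
#' explicitly zero), sets F(000), and returns the real map
#' rho(x) = (1/N) sum_h F(h) exp(-2 pi i h.x).
#'
#' @param coeffs complex vector aligned with `refl` (must be complete;
#'   unmeasured terms must be passed as explicit zeros, not dropped).
#' @param refl a [reflection_set()].
#' @param cell grid to synthesize on; defaults to the cell of `refl`.
#' @param f000 value of the F(000) term; defaults to the set's `f000`
#'   attribute.
#' @return a [density_map()].
#' @export
structure_factors_to_density <- function(coeffs, refl, cell = NULL,
                                         f000 = NULL) {
  if (is.null(cell)) cell <- attr(refl, "cell")
  if (is.null(cell)) stop("no cell available for synthesis")
  if (length(coeffs) != nrow(refl))
    stop("need exactly one coefficient per stored reflection ",
         "(zero-fill missing terms explicitly)")
  if (any(is.na(coeffs))) stop("NA coefficients; zero-fill explicitly")
  if (is.null(f000)) f000 <- attr(refl, "f000")
  hkl <- as.matrix(refl[, c("h", "k", "l")])
  A <- array(0i, cell$shape)
  A[grid_linear_index(hkl, cell$shape)] <- coeffs
  A[grid_linear_index(-hkl, cell$shape)] <- Conj(coeffs)
  A[1] <- f000
  rho <- stats::fft(A) / prod(cell$shape)  # e^{-2 pi i h.x} / N
  density_map(Re(rho), cell)
}

check_same_cell <- function(a, b) {
  if (is.null(a) || is.null(b)) stop("both objects must carry a cell")
  if (!isTRUE(all.equal(a$lengths, b$lengths)) ||
      !isTRUE(all.equal(a$angles, b$angles)) ||
      !all(a$shape == b$shape))
    stop("cell/grid mismatch")
  invisible(TRUE)
}

#' Assign statistical degeneracy factors
#'
#' In P1 with Friedel symmetry every reciprocal-lattice point has degeneracy
#' epsilon = 1; imported data from higher-symmetry space groups may supply
#' their own epsilon column, which is passed through unchanged.
#'
#' @param refl a [reflection_set()].
#' @param epsilon optional user-supplied factors (positive), recycled.
#' @return the reflection set with its `epsilon` column set.
#' @export
assign_epsilon <- function(refl, epsilon = NULL) {
  if (is.null(epsilon)) epsilon <- 1
  epsilon <- rep_len(as.numeric(epsilon), nrow(refl))
  if (any(!is.finite(epsilon)) || any(epsilon <= 0))
    stop("epsilon factors must be positive")
  refl$epsilon <- epsilon
  refl
}

#' Equal-count resolution shells
#'
#' Partitions the reflections into `n_shells` concentric shells of
#' approximately equal reflection count in 1/d^3 (i.e. equal reciprocal-space
#' volume per reflection).  A reflection falling exactly on a shell boundary
#' is assigned to the lower-resolution shell (smaller 1/d).
#'
#' @param refl a [reflection_set()] with known d-spacings.
#' @param n_shells number of shells (>= 1).
#' @return list with `shell` (1-based integer per reflection) and `limits`
#'   (data frame of shell d-spacing ranges in Angstrom).
#' @export
resolution_shells <- function(refl, n_shells) {
  n_shells <- as.integer(n_shells)
  if (n_shells < 1L) stop("n_shells must be >= 1")
  if (nrow(refl) < n_shells) stop("fewer reflections than shells")
  if (any(!is.finite(refl$d))) stop("reflections carry no d-spacings")
  s3 <- 1 / refl$d^3
  if (n_shells == 1L) {
    shell <- rep(1L, nrow(refl))
  } else {
    br <- stats::quantile(s3, probs = seq_len(n_shells - 1L) / n_shells,
                          names = FALSE, type = 7)
    # strictly-greater comparison: a term exactly on a boundary stays in the
    # lower-resolution (smaller 1/d) shell
    shell <- 1L + rowSums(outer(s3, br, `>`))
  }
  limits <- data.frame(
    shell = seq_len(n_shells),
    d_max = tapply(refl$d, shell, max)[as.character(seq_len(n_shells))],
    d_min = tapply(refl$d, shell, min)[as.character(seq_len(n_shells))])
  rownames(limits) <- NULL
  list(shell = as.integer(shell), limits = limits)
}
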