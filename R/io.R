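#' Write a reflection set as whitespace-delimited text
#'
#' Columns: `h k l F phi centric eps measured`, one reflection per line,
#' preceded by a `#`-comment header.  Phases are written in radians with 10
#' significant digits so a write/read round trip reproduces the set exactly
#' on the chosen decimal representation.  Unmeasured amplitudes and missing
#' phases are written as `NA`.
#'
#' @param refl a [reflection_set()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_reflections <- function(refl, path) {
  con <- file(path, "w")
  on.exit(close(con))
  cell <- attr(refl, "cell")
  writeLines("# h k l F phi centric eps measured", con)
  if (!is.null(cell))
    writeLines(sprintf("# cell %.6g %.6g %.6g %.6g %.6g %.6g shape %d %d %d d_min %.6g f000 %.10g",
                       cell$lengths[1], cell$lengths[2], cell$lengths[3],
                       cell$angles[1], cell$angles[2], cell$angles[3],
                       cell$shape[1], cell$shape[2], cell$shape[3],
                       cell$d_min, attr(refl, "f000")), con)
  fmt <- function(x) ifelse(is.na(x), "NA", sprintf("%.10g", x))
  writeLines(sprintf("%d %d %d %s %s %d %s %d",
                     refl$h, refl$k, refl$l, fmt(refl$f_measured),
                     fmt(refl$phase_ref), as.integer(refl$centric),
                     fmt(refl$epsilon), as.integer(refl$is_measured)), con)
  invisible(path)
}

#' Read a reflection set from whitespace-delimited text
#'
#' Accepts files with columns `h k l F [phi] [centric] [eps] [measured]`
#' (missing trailing columns default to no phase, acentric, epsilon 1,
#' measured).  A cell comment line written by [write_reflections()] restores
#' the grid.  Malformed lines and duplicate indices are reported with their
#' line numbers.
#'
#' @param path input file path.
#' @param cell optional [unit_cell_grid()] overriding any cell stored in the
#'   file.
#' @return a [reflection_set()].
#' @export
read_reflections <- function(path, cell = NULL) {
  lines <- readLines(path)
  f000 <- 0
  cellline <- grep("^# cell ", lines, value = TRUE)
  if (length(cellline) == 1L) {
    toks <- strsplit(trimws(sub("^# cell", "", cellline)), "\\s+")[[1]]
    v <- suppressWarnings(as.numeric(toks))
    v <- v[is.finite(v)]
    if (length(v) == 11) {
      if (is.null(cell))
        cell <- unit_cell_grid(v[1:3], v[4:6], as.integer(v[7:9]), v[10])
      f000 <- v[11]
    }
  }
  keep <- !grepl("^\\s*(#|$)", lines)
  lineno <- which(keep)
  toks <- strsplit(trimws(lines[keep]), "\\s+")
  nf <- lengths(toks)
  if (any(nf < 4))
    stop("malformed reflection line ", lineno[which(nf < 4)[1]],
         ": need at least h k l F")
  get_col <- function(i, default = "NA") {
    vapply(toks, function(t) if (length(t) >= i) t[i] else default,
           character(1))
  }
  num <- function(x, what, allow_na = FALSE) {
    out <- suppressWarnings(as.numeric(x))
    bad <- is.na(out) & !(allow_na & x == "NA")
    if (any(bad))
      stop("malformed ", what, " on line ", lineno[which(bad)[1]])
    out
  }
  h <- num(get_col(1), "h"); k <- num(get_col(2), "k"); l <- num(get_col(3), "l")
  fm <- num(get_col(4), "F", allow_na = TRUE)
  phi <- num(get_col(5), "phi", allow_na = TRUE)
  cen <- num(get_col(6, "0"), "centric flag")
  eps <- num(get_col(7, "1"), "epsilon", allow_na = TRUE)
  msd <- num(get_col(8), "measured flag", allow_na = TRUE)
  key <- paste(h, k, l)
  if (anyDuplicated(key))
    stop("duplicate hkl (", key[duplicated(key)][1], ") on line ",
         lineno[which(duplicated(key))[1]])
  eps[is.na(eps)] <- 1
  reflection_set(cbind(h, k, l), cell = cell, f_measured = fm,
                 phase_ref = phi, centric = cen != 0, epsilon = eps,
                 is_measured = if (all(is.na(msd))) NULL else msd != 0,
                 f000 = f000)
}

#' Write a density map in CCP4/MRC format (mode 2)
#'
#' Standard 1024-byte CCP4/MRC header (mode 2, 32-bit float data, axis order
#' X fastest) followed by the voxel values in little-endian float32.  A
#' round-trip read reproduces the voxels to single precision.
#'
#' @param map a [density_map()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_map <- function(map, path) {
  cell <- map_cell(map)
  con <- file(path, "wb")
  on.exit(close(con))
  shape <- cell$shape
  wi <- function(x) writeBin(as.integer(x), con, size = 4L,
                             endian = "little")
  wf <- function(x) writeBin(as.numeric(x), con, size = 4L,
                             endian = "little")
  wi(shape)                 # NC NR NS
  wi(2L)                    # MODE 2 = float32
  wi(c(0L, 0L, 0L))         # NCSTART NRSTART NSSTART
  wi(shape)                 # MX MY MZ
  wf(cell$lengths)          # CELLA
  wf(cell$angles)           # CELLB
  wi(c(1L, 2L, 3L))         # MAPC MAPR MAPS
  wf(c(min(map), max(map), mean(map)))  # DMIN DMAX DMEAN
  wi(1L)                    # ISPG (P1)
  wi(0L)                    # NSYMBT
  wi(integer(25))           # EXTRA
  wf(c(0, 0, 0))            # ORIGIN
  writeChar("MAP ", con, nchars = 4L, eos = NULL)
  writeBin(as.raw(c(0x44, 0x44, 0x00, 0x00)), con)  # little-endian stamp
  wf(stats::sd(as.vector(map)))  # RMS
  wi(0L)                    # NLABL
  writeBin(raw(800), con)   # label block
  wf(as.vector(unclass(map)))
  invisible(path)
}

#' Read a CCP4/MRC density map
#'
#' Reads mode-2 maps, honoring the axis-order permutation declared in the
#' MAPC/MAPR/MAPS header words (the returned array is always ordered x, y,
#' z).
#'
#' @param path input file path.
#' @param d_min resolution limit to attach to the reconstructed
#'   [unit_cell_grid()] (the header does not store one); defaults to twice
#'   the coarsest grid spacing.
#' @return a [density_map()].
#' @export
read_map <- function(path, d_min = NULL) {
  con <- file(path, "rb")
  on.exit(close(con))
  ri <- function(n) readBin(con, "integer", n, size = 4L, endian = "little")
  rf <- function(n) readBin(con, "numeric", n, size = 4L, endian = "little")
  nc <- ri(3L)
  mode <- ri(1L)
  if (mode != 2L) stop("only mode-2 (float32) maps supported")
  ri(3L)                       # start offsets (ignored)
  m <- ri(3L)                  # sampling MX MY MZ
  cella <- rf(3L)
  cellb <- rf(3L)
  axes <- ri(3L)               # MAPC MAPR MAPS
  seek(con, 1024L)
  vals <- rf(prod(nc))
  arr <- array(vals, nc)       # dims ordered (column, row, section)
  # permute so that dimension i of the output is crystal axis i
  perm <- order(axes)          # output axis -> file dimension
  arr <- aperm(arr, perm)
  if (is.null(d_min)) d_min <- 2 * max(cella / m)
  cell <- unit_cell_grid(cella, cellb, m, d_min)
  density_map(arr, cell)
}

#' Replicated return-to-solution experiment
#'
#' Reproduces the replicated-corruption experiment design: for each
#' combination of algorithm, beta and error-function circular variance,
#' generates `n_replicates` corrupted phase sets from the reference data,
#' runs the algorithm for a fixed number of iterations, and records the
#' real-space correlation with the reference per iteration.  Returns a tidy
#' long-format table with one row per (algorithm, beta, V, replicate,
#' iteration), deterministic given `seed`.
#'
#' @param refl a [reflection_set()] with reference phases (the known
#'   solution).
#' @param prior the [density_prior()].
#' @param algorithms character vector of algorithm names.
#' @param betas numeric vector of beta values (recycled per algorithm; use
#'   `NA` for ER).
#' @param variances circular variances of the phase-error distributions.
#' @param n_replicates replicates per cell of the design.
#' @param n_iterations fixed run length.
#' @param seed master seed; replicate r at variance V uses an offset
#'   substream so the table is reproducible row by row.
#' @param envelope0 optional starting envelope shared by all runs.
#' @param window_radius envelope window radius in Angstrom.
#' @return data frame with columns `algorithm, beta, v, replicate,
#'   iteration, correlation`; the attribute `final` holds the final-iteration
#'   summaries per design cell.
#' @export
experiment_return_to_solution <- function(refl, prior, algorithms, betas,
                                          variances, n_replicates = 30,
                                          n_iterations = 100, seed = 1L,
                                          envelope0 = NULL,
                                          window_radius = 4) {
  stopifnot(length(algorithms) == length(betas))
  rows <- list()
  for (ai in seq_along(algorithms)) {
    alg <- algorithms[ai]
    beta <- if (is.na(betas[ai])) NULL else betas[ai]
    for (v in variances) {
      for (rep_i in seq_len(n_replicates)) {
        sub_seed <- (seed * 1009 + ai * 797003 +
                       round(1000 * v) * 7919 + rep_i) %% 2147483629
        spec <- error_spec(v, seed = sub_seed)
        corrupted <- corrupt_phases(refl, spec)
        cfg <- ipa_config(alg, beta = beta, n_iterations = n_iterations,
                          seed = sub_seed)
        rec <- ipa_run(refl, prior, cfg,
                       start_phases = corrupted$phase_ref,
                       envelope0 = envelope0,
                       window_radius = window_radius)
        rows[[length(rows) + 1L]] <- data.frame(
          algorithm = alg, beta = if (is.null(beta)) NA_real_ else beta,
          v = v, replicate = rep_i,
          iteration = seq_len(n_iterations),
          correlation = rec$correlation)
      }
    }
  }
  out <- do.call(rbind, rows)
  fin <- out[out$iteration == n_iterations, ]
  attr(out, "final") <- stats::aggregate(
    correlation ~ algorithm + beta + v, data = fin,
    FUN = function(x) c(mean = mean(x), sd = stats::sd(x)))
  out
}

#' Self-weighted mean trajectory
#'
#' Mean correlation trajectory over replicates in which each replicate is
#' weighted, at every iteration, by its own correlation value (so converged
#' replicates dominate the displayed average).
#'
#' @param tbl long-format table from [experiment_return_to_solution()],
#'   restricted to one design cell.
#' @return data frame with `iteration` and `correlation`.
#' @export
self_weighted_mean_trajectory <- function(tbl) {
  sp <- split(tbl$correlation, tbl$iteration)
  data.frame(iteration = as.integer(names(sp)),
             correlation = vapply(sp, function(x) {
               w <- pmax(x, 0)
               if (sum(w) == 0) mean(x) else sum(w * x) / sum(w)
             }, numeric(1)))
}
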