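#' Uniform or custom binning of a 1-D order parameter
#'
#' Defines the discretization of a real-valued order parameter (for example a
#' collective dihedral coordinate, or a cavity photon number) into `n_bins`
#' integer state labels. Binning is half-open: value `x` falls in bin `i` when
#' `edges[i+1] <= x < edges[i+2]` (0-based labels). Values below `lo` clamp to
#' bin 0, values at or above `hi` clamp to bin `n_bins - 1`.
#'
#' @param n_bins number of states (>= 2).
#' @param lo,hi lower and upper edge of the binned range (`lo < hi`).
#' @param edges optional full vector of `n_bins + 1` strictly increasing edges;
#'   defaults to a uniform grid on `[lo, hi]`.
#' @return An object of class `binning_spec`.
#' @examples
#' spec <- binning_spec(32, -15, 15)
#' bin_midpoints(spec)[1:4]
#' @export
binning_spec <- function(n_bins, lo, hi, edges = NULL) {
  n_bins <- as.integer(n_bins)
  if (is.na(n_bins) || n_bins < 2L) stop("n_bins must be an integer >= 2")
  if (!is.finite(lo) || !is.finite(hi) || lo >= hi) stop("need finite lo < hi")
  if (is.null(edges)) {
    edges <- seq(lo, hi, length.out = n_bins + 1L)
  } else {
    if (length(edges) != n_bins + 1L) stop("edges must have length n_bins + 1")
    if (any(diff(edges) <= 0)) stop("edges must be strictly increasing")
    if (abs(edges[1] - lo) > 1e-12 || abs(edges[n_bins + 1L] - hi) > 1e-12)
      stop("edges must span [lo, hi]")
  }
  structure(list(n_bins = n_bins, lo = lo, hi = hi, edges = as.numeric(edges)),
            class = "binning_spec")
}

#' Bin midpoints of a binning specification
#' @param spec a [binning_spec()].
#' @return numeric vector of length `n_bins`.
#' @export
bin_midpoints <- function(spec) {
  stopifnot(inherits(spec, "binning_spec"))
  (spec$edges[-1] + spec$edges[-length(spec$edges)]) / 2
}

#' Discrete 1-D trajectory of integer state labels
#'
#' @param states integer vector of 0-based labels.
#' @param dt time step between consecutive samples (metadata; arbitrary units).
#' @param binning optional [binning_spec()] recording how real values map to
#'   the labels (required by [undiscretize()]).
#' @return An object of class `discrete_trajectory`.
#' @export
discrete_trajectory <- function(states, dt = 1, binning = NULL) {
  states <- as.integer(states)
  if (length(states) < 1L) stop("a trajectory needs at least 1 sample")
  if (anyNA(states)) stop("states contain NA")
  if (any(states < 0L)) stop("state labels must be >= 0")
  if (!is.null(binning)) {
    stopifnot(inherits(binning, "binning_spec"))
    if (any(states >= binning$n_bins))
      stop("state label out of range of the binning (>= n_bins)")
  }
  if (!is.finite(dt) || dt <= 0) stop("dt must be a positive real")
  structure(list(states = states, dt = dt, binning = binning),
            class = "discrete_trajectory")
}

#' @export
print.discrete_trajectory <- function(x, ...) {
  cat(sprintf("<discrete_trajectory> length %d, dt = %g, %s\n",
              length(x$states), x$dt,
              if (is.null(x$binning)) "no binning"
              else sprintf("%d bins on [%g, %g]",
                           x$binning$n_bins, x$binning$lo, x$binning$hi)))
  invisible(x)
}

#' @export
length.discrete_trajectory <- function(x) length(x$states)

#' Ensemble of equal-length discrete trajectories
#'
#' Internally stored as an `n_paths x length` integer matrix of state labels,
#' the set of labelled paths over which Maximum Caliber reweighting operates.
#'
#' @param trajectories list of [discrete_trajectory()] objects (equal length,
#'   equal dt), or an integer matrix of labels, one row per path.
#' @param weights optional nonnegative per-path weights (sum > 0); `NULL`
#'   means unweighted.
#' @param dt,binning used when `trajectories` is a matrix.
#' @return An object of class `path_ensemble`.
#' @export
path_ensemble <- function(trajectories, weights = NULL, dt = 1, binning = NULL) {
  if (is.matrix(trajectories)) {
    states <- matrix(as.integer(trajectories), nrow = nrow(trajectories))
  } else {
    stopifnot(is.list(trajectories), length(trajectories) >= 1L)
    lens <- vapply(trajectories, function(t) length(t$states), integer(1))
    if (length(unique(lens)) != 1L)
      stop("all trajectories in an ensemble must have equal length")
    dts <- vapply(trajectories, function(t) t$dt, numeric(1))
    dt <- dts[1]
    bn <- Filter(Negate(is.null), lapply(trajectories, function(t) t$binning))
    if (is.null(binning) && length(bn)) binning <- bn[[1]]
    states <- do.call(rbind, lapply(trajectories, function(t) t$states))
  }
  if (ncol(states) < 2L) stop("paths need at least 2 samples")
  if (anyNA(states) || any(states < 0L)) stop("invalid state labels")
  if (!is.null(binning) && any(states >= binning$n_bins))
    stop("state label out of range of the binning")
  if (!is.null(weights)) {
    weights <- as.numeric(weights)
    if (length(weights) != nrow(states)) stop("one weight per trajectory required")
    if (any(!is.finite(weights)) || any(weights < 0)) stop("weights must be finite and >= 0")
    if (sum(weights) <= 0) stop("weights must have positive sum")
  }
  structure(list(states = states, weights = weights, dt = dt, binning = binning),
            class = "path_ensemble")
}

#' @export
print.path_ensemble <- function(x, ...) {
  cat(sprintf("<path_ensemble> %d paths x %d samples, dt = %g%s%s\n",
              nrow(x$states), ncol(x$states), x$dt,
              if (is.null(x$binning)) "" else sprintf(", %d bins", x$binning$n_bins),
              if (is.null(x$weights)) "" else ", weighted"))
  invisible(x)
}

#' Number of paths in an ensemble
#' @param ensemble a [path_ensemble()].
#' @export
n_paths <- function(ensemble) nrow(ensemble$states)

#' Extract one member trajectory from an ensemble
#' @param ensemble a [path_ensemble()].
#' @param i path index (1-based).
#' @export
ensemble_member <- function(ensemble, i) {
  discrete_trajectory(ensemble$states[i, ], dt = ensemble$dt,
                      binning = ensemble$binning)
}

#' Discretize a real-valued series into integer state labels
#'
#' Maps each value to the half-open bin `[edge_i, edge_{i+1})` containing it;
#' values below `lo` clamp to bin 0 and values at or above `hi` clamp to the
#' top bin. The number of clamped values is reported in attribute
#' `clamped` (`c(low = ..., high = ...)`).
#'
#' @param series numeric vector (finite values).
#' @param spec a [binning_spec()].
#' @param dt time step metadata for the resulting trajectory.
#' @return A [discrete_trajectory()] with the binning attached.
#' @examples
#' discretize(c(-0.9, 0.1, 0.9), binning_spec(2, -1, 1))$states
#' @export
discretize <- function(series, spec, dt = 1) {
  stopifnot(inherits(spec, "binning_spec"))
  if (length(series) == 0L) stop("series is empty")
  bad <- which(!is.finite(series))
  if (length(bad))
    stop(sprintf("non-finite value in series at index %d", bad[1]))
  # findInterval with left-closed intervals; rightmost.closed not wanted
  idx <- findInterval(series, spec$edges, left.open = FALSE)
  low <- sum(idx < 1L); high <- sum(idx > spec$n_bins)
  idx <- pmin(pmax(idx, 1L), spec$n_bins)
  out <- discrete_trajectory(idx - 1L, dt = dt, binning = spec)
  attr(out, "clamped") <- c(low = low, high = high)
  out
}

#' Map state labels back to real values at bin midpoints
#' @param traj a [discrete_trajectory()] carrying a binning.
#' @return numeric vector of bin-midpoint values.
#' @export
undiscretize <- function(traj) {
  stopifnot(inherits(traj, "discrete_trajectory"))
  if (is.null(traj$binning))
    stop("trajectory has no binning_spec; cannot undiscretize")
  bin_midpoints(traj$binning)[traj$states + 1L]
}

.meta_header <- function(dt, binning) {
  h <- sprintf("# dt=%.17g", dt)
  if (!is.null(binning))
    h <- c(h, sprintf("# n_bins=%d", binning$n_bins),
           sprintf("# lo=%.17g", binning$lo),
           sprintf("# hi=%.17g", binning$hi))
  h
}

.parse_meta <- function(lines) {
  meta <- list()
  for (l in lines) {
    kv <- sub("^#\\s*", "", l)
    parts <- strsplit(kv, "=", fixed = TRUE)[[1]]
    if (length(parts) == 2L) meta[[trimws(parts[1])]] <- trimws(parts[2])
  }
  meta
}

#' Write a trajectory (or real series) to a plain-text file
#'
#' One value per line (csv/tsv/plain are equivalent for a single column), with
#' `# key=value` comment headers recording `dt` and any binning metadata.
#'
#' @param traj a [discrete_trajectory()] or numeric vector.
#' @param path output file.
#' @param dt time step metadata when `traj` is a bare numeric vector.
#' @export
write_trajectory <- function(traj, path, dt = 1) {
  if (inherits(traj, "discrete_trajectory")) {
    lines <- c(.meta_header(traj$dt, traj$binning), format(traj$states))
  } else {
    lines <- c(.meta_header(dt, NULL), sprintf("%.17g", as.numeric(traj)))
  }
  writeLines(lines, path)
  invisible(path)
}

#' Read a trajectory from a plain-text/CSV file
#'
#' Accepts one numeric token per line (comma- or tab-separated single columns
#' also work); `#`-prefixed header comments carry `dt` and binning metadata.
#' Integer-valued files are returned as [discrete_trajectory()]; otherwise the
#' raw numeric series is returned.
#'
#' @param path input file.
#' @return A [discrete_trajectory()] or a numeric vector (with attribute `dt`).
#' @export
read_trajectory <- function(path) {
  lines <- readLines(path)
  is_meta <- grepl("^\\s*#", lines)
  meta <- .parse_meta(lines[is_meta])
  body <- trimws(lines[!is_meta])
  body <- body[nzchar(body)]
  if (!length(body)) stop("no data lines in ", path)
  toks <- strsplit(body, "[,\t]")
  nf <- lengths(toks)
  if (any(nf != nf[1]))
    stop(sprintf("ragged row at line %d of %s",
                 which(!is_meta)[which(nf != nf[1])[1]], path))
  if (nf[1] != 1L) stop("expected a single column in ", path)
  vals <- suppressWarnings(as.numeric(vapply(toks, `[[`, "", 1L)))
  if (anyNA(vals)) {
    bad <- which(is.na(vals))[1]
    stop(sprintf("non-numeric token at data line %d of %s", bad, path))
  }
  dt <- if (!is.null(meta$dt)) as.numeric(meta$dt) else 1
  binning <- NULL
  if (!is.null(meta$n_bins))
    binning <- binning_spec(as.integer(meta$n_bins),
                            as.numeric(meta$lo), as.numeric(meta$hi))
  if (all(vals == round(vals)) && all(vals >= 0)) {
    discrete_trajectory(vals, dt = dt, binning = binning)
  } else {
    structure(vals, dt = dt)
  }
}

#' Write an ensemble as a single wide CSV (one column per path)
#' @param ensemble a [path_ensemble()].
#' @param path output file.
#' @export
write_ensemble <- function(ensemble, path) {
  stopifnot(inherits(ensemble, "path_ensemble"))
  con <- file(path, "w"); on.exit(close(con))
  writeLines(.meta_header(ensemble$dt, ensemble$binning), con)
  utils::write.table(t(ensemble$states), con, sep = ",",
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a wide-CSV ensemble written by [write_ensemble()]
#' @param path input file.
#' @export
read_ensemble <- function(path) {
  lines <- readLines(path)
  is_meta <- grepl("^\\s*#", lines)
  meta <- .parse_meta(lines[is_meta])
  m <- as.matrix(utils::read.csv(text = lines[!is_meta], header = FALSE))
  binning <- NULL
  if (!is.null(meta$n_bins))
    binning <- binning_spec(as.integer(meta$n_bins),
                            as.numeric(meta$lo), as.numeric(meta$hi))
  path_ensemble(t(m), dt = if (!is.null(meta$dt)) as.numeric(meta$dt) else 1,
                binning = binning)
}
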