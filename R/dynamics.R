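#' @title Flexibility and active-site dynamics
#' @description Per-residue RMSF about an iteratively refined time-average
#'   reference, atom-pair distance series, active-geometry fractions with
#'   block-bootstrap confidence intervals, histograms, and aggregation of
#'   replicate runs by the standard deviation of per-trajectory means.
#' @name memdyn-dynamics
NULL

#' Per-frame scalar metric series
#'
#' @param values numeric vector, one value per analyzed frame.
#' @param units unit string.
#' @param label replicate/trajectory label.
#' @param provenance free-form description of the selection or atom pair.
#' @return object of class `MetricSeries`.
#' @export
metric_series <- function(values, units = "", label = "", provenance = "") {
  structure(list(values = as.numeric(values), units = units, label = label,
                 provenance = provenance), class = "MetricSeries")
}

#' @export
print.MetricSeries <- function(x, ...) {
  cat(sprintf("MetricSeries [%s] '%s': %d frames, mean %.4g %s\n",
              x$provenance, x$label, length(x$values), mean(x$values), x$units))
  invisible(x)
}

#' Per-residue metric profile (one replicate)
#'
#' @param labels residue labels ("chain/resid/resname").
#' @param values numeric vector aligned with `labels`.
#' @param units unit string.
#' @param label replicate label.
#' @return object of class `ResidueProfile`.
#' @export
residue_profile <- function(labels, values, units = "", label = "") {
  if (length(labels) != length(values)) stop("labels/values length mismatch")
  structure(list(labels = labels, values = as.numeric(values), units = units,
                 label = label), class = "ResidueProfile")
}

#' Frame indices of a trailing analysis window
#'
#' The study convention of analyzing the final stretch of each run
#' (e.g. the last 200 ns of 600 ns) generalizes here to a trailing
#' fraction of frames; an explicit frame range is also accepted.
#'
#' @param traj a `Trajectory`.
#' @param window trailing fraction in (0, 1] (default 1/3), or an integer
#'   vector of frame indices.
#' @return integer frame indices.
#' @export
analysis_window <- function(traj, window = 1/3) {
  nf <- n_frames(traj)
  if (length(window) == 1 && window > 0 && window <= 1) {
    start <- nf - max(1L, floor(window * nf)) + 1L
    return(seq.int(start, nf))
  }
  idx <- as.integer(window)
  if (any(idx < 1 | idx > nf)) stop("window indices outside trajectory")
  idx
}

#' Backbone RMSF profile about the time-average structure
#'
#' Frames of the analysis window are superposed (backbone fit) onto their
#' own time-average structure, computed by iterative refinement: fit to an
#' initial reference, average, re-fit to the average, re-average, until
#' the mean structure moves less than `tol` (or `max_iter` passes). The
#' RMSF of a residue is the root of the mean squared deviation of its
#' reported atoms from their average positions, over window frames.
#'
#' @param traj a `Trajectory`.
#' @param fit_sel `Selection` used for superposition (typically backbone).
#' @param report_sel `Selection` of atoms whose residues are profiled
#'   (defaults to `fit_sel`).
#' @param window trailing fraction or frame indices, see [analysis_window()].
#' @param max_iter mean-structure refinement passes (default 2).
#' @param tol convergence tolerance on the mean structure, Angstrom RMSD.
#' @return a `ResidueProfile` in Angstrom, one value per reported residue.
#' @export
rmsf_profile <- function(traj, fit_sel, report_sel = fit_sel, window = 1/3,
                         max_iter = 2L, tol = 1e-3) {
  if (!length(fit_sel$indices)) stop("empty fit selection")
  widx <- analysis_window(traj, window)
  if (length(widx) < 10) stop("analysis window shorter than 10 frames")
  fidx <- fit_sel$indices
  ridx <- report_sel$indices
  nf <- length(widx)
  # stack fit and report coordinates: frames x atoms x 3 as list of matrices
  fit_xyz <- lapply(widx, function(k) traj$frames[[k]]$xyz[fidx, , drop = FALSE])
  rep_xyz <- lapply(widx, function(k) traj$frames[[k]]$xyz[ridx, , drop = FALSE])
  ref <- fit_xyz[[1]]
  for (pass in seq_len(max_iter)) {
    acc_fit <- matrix(0, length(fidx), 3)
    acc_rep <- matrix(0, length(ridx), 3)
    for (k in seq_len(nf)) {
      sp <- kabsch_superpose(fit_xyz[[k]], ref)
      fit_xyz[[k]] <- apply_superposition(sp, fit_xyz[[k]])
      rep_xyz[[k]] <- apply_superposition(sp, rep_xyz[[k]])
      acc_fit <- acc_fit + fit_xyz[[k]]
      acc_rep <- acc_rep + rep_xyz[[k]]
    }
    newref <- acc_fit / nf
    shift <- rmsd_raw(newref, ref)
    ref <- newref
    if (shift < tol) break
  }
  mean_rep <- Reduce(`+`, rep_xyz) / nf
  # mean squared deviation per reported atom
  msd <- Reduce(`+`, lapply(rep_xyz, function(m) rowSums((m - mean_rep)^2))) / nf
  rrow <- findInterval(ridx, traj$topology$residues$first)
  per_res <- tapply(msd, rrow, mean)
  labs <- residue_labels(traj$topology)[as.integer(names(per_res))]
  residue_profile(labs, sqrt(as.numeric(per_res)), units = "Angstrom",
                  label = traj$label)
}

#' Specification of a monitored atom-pair distance
#'
#' The canonical use is the active-site gamma-carbon pair of the two
#' catalytic aspartates (D162:CG and D220:CG), with geometries below
#' 7 Angstrom taken as proteolysis-compatible.
#'
#' @param a,b selection expressions each resolving to exactly one atom,
#'   e.g. `"chain A and resid 162 and name CG"`.
#' @param threshold active-geometry threshold in Angstrom (default 7).
#' @return object of class `DistanceSpec`.
#' @export
distance_spec <- function(a, b, threshold = 7.0) {
  if (threshold <= 0) stop("threshold must be > 0")
  structure(list(a = a, b = b, threshold = threshold), class = "DistanceSpec")
}

#' Per-frame minimum-image distance series for an atom pair
#'
#' @param traj a `Trajectory`.
#' @param spec a [distance_spec()].
#' @return a `MetricSeries` in Angstrom.
#' @export
distance_series <- function(traj, spec) {
  ia <- .resolve_single_atom(traj$topology, spec$a)
  ib <- .resolve_single_atom(traj$topology, spec$b)
  vals <- vapply(traj$frames, function(f) {
    minimum_image_distance(f$xyz[ia, ], f$xyz[ib, ], f$box)
  }, 0)
  metric_series(vals, units = "Angstrom", label = traj$label,
                provenance = paste(spec$a, "<->", spec$b))
}

.resolve_single_atom <- function(top, expr) {
  sel <- suppressWarnings(resolve_selection(top, expr))
  if (length(sel$indices) != 1) {
    stop(sprintf("'%s' resolves to %d atoms (need exactly 1)", expr,
                 length(sel$indices)))
  }
  sel$indices
}

#' Fraction of frames strictly below a threshold, with block bootstrap CI
#'
#' Reports the fraction of frames with values strictly below `threshold`
#' (ties count as above). The confidence interval comes from a circular
#' block bootstrap so that frame autocorrelation is respected.
#'
#' @param series a `MetricSeries` (or numeric vector).
#' @param threshold threshold in the series' units.
#' @param block_length bootstrap block length in frames (default 50).
#' @param n_boot number of bootstrap resamples (default 1000).
#' @param conf confidence level (default 0.95).
#' @param seed RNG seed for the bootstrap (default 1).
#' @return list with `fraction`, `ci` (length 2), `n` frames.
#' @export
fraction_below <- function(series, threshold, block_length = 50L,
                           n_boot = 1000L, conf = 0.95, seed = 1L) {
  x <- if (inherits(series, "MetricSeries")) series$values else as.numeric(series)
  n <- length(x)
  if (!n) stop("empty series")
  frac <- mean(x < threshold)
  if (n_boot < 1) return(list(fraction = frac, ci = c(NA_real_, NA_real_), n = n))
  bl <- max(1L, min(as.integer(block_length), n))
  nblk <- ceiling(n / bl)
  boot <- withr_seed(seed, {
    vapply(seq_len(n_boot), function(b) {
      starts <- sample.int(n, nblk, replace = TRUE)
      idx <- (rep(starts, each = bl) + rep(seq_len(bl) - 1L, nblk) - 1L) %% n + 1L
      mean(x[idx[seq_len(n)]] < threshold)
    }, 0)
  })
  alpha <- (1 - conf) / 2
  list(fraction = frac,
       ci = as.numeric(stats::quantile(boot, c(alpha, 1 - alpha), names = FALSE)),
       n = n)
}

# evaluate expr under a local RNG seed without disturbing the caller's stream
withr_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Probability-normalized histogram of a metric series
#'
#' Densities satisfy sum(density * bin_width) = 1.
#'
#' @param series a `MetricSeries` or numeric vector.
#' @param bin_width bin width in the series' units.
#' @return data.frame with `mid`, `count`, `density`.
#' @export
metric_histogram <- function(series, bin_width) {
  if (bin_width <= 0) stop("bin_width must be > 0")
  x <- if (inherits(series, "MetricSeries")) series$values else as.numeric(series)
  lo <- floor(min(x) / bin_width) * bin_width
  breaks <- seq(lo, max(x) + bin_width, by = bin_width)
  h <- graphics::hist(x, breaks = breaks, plot = FALSE, right = FALSE)
  data.frame(mid = h$mids, count = h$counts,
             density = h$counts / (length(x) * bin_width))
}

#' Aggregate replicate profiles or scalars: mean and SD of the mean
#'
#' The replicate-uncertainty convention used throughout: the reported
#' error is the sample standard deviation of the n per-trajectory means
#' (NOT the pooled-frame standard error).
#'
#' @param replicates list of `ResidueProfile`s with identical labels, or a
#'   numeric vector/list of per-replicate scalar summaries.
#' @return for profiles, a data.frame with `label`, `mean`, `sd_of_mean`;
#'   for scalars, a list with `mean` and `sd_of_mean`.
#' @export
aggregate_replicates <- function(replicates) {
  if (is.numeric(replicates)) replicates <- as.list(replicates)
  if (length(replicates) < 2) stop("need at least 2 replicates")
  if (inherits(replicates[[1]], "ResidueProfile")) {
    labs <- replicates[[1]]$labels
    for (r in replicates[-1]) {
      if (!identical(r$labels, labs)) stop("replicate residue labels mismatch")
    }
    M <- do.call(cbind, lapply(replicates, function(r) r$values))
    return(data.frame(label = labs, mean = rowMeans(M),
                      sd_of_mean = apply(M, 1, stats::sd),
                      stringsAsFactors = FALSE))
  }
  v <- vapply(replicates, as.numeric, 0)
  list(mean = mean(v), sd_of_mean = stats::sd(v))
}
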