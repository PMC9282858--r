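#' @title Periodic-aware geometry kernels
#' @description Minimum-image distances under orthorhombic periodic
#'   boundaries, a cell-list neighbor search, Kabsch least-squares
#'   superposition and RMSD series.
#' @name memdyn-geometry
NULL

#' Minimum-image distance between two points
#'
#' Without a box this is the Euclidean distance; with an orthorhombic box
#' it is the distance to the nearest periodic image.
#'
#' @param a,b numeric length-3 coordinates (Angstrom).
#' @param box optional length-3 orthorhombic edges.
#' @return distance in Angstrom.
#' @export
minimum_image_distance <- function(a, b, box = NULL) {
  d <- as.numeric(b) - as.numeric(a)
  if (!is.null(box)) {
    box <- as.numeric(box)
    if (any(box <= 0)) stop("box edges must be positive")
    d <- d - box * round(d / box)
  }
  sqrt(sum(d * d))
}

# full min-image distance matrix (n_a x n_b); brute-force kernel used by
# the cell list within candidate sets and by the test oracles
.mi_distmat <- function(A, B, box = NULL) {
  out <- matrix(0, nrow(A), nrow(B))
  for (j in 1:3) {
    d <- outer(A[, j], B[, j], "-")
    if (!is.null(box)) d <- d - box[j] * round(d / box[j])
    out <- out + d * d
  }
  sqrt(out)
}

#' Neighbor query parameters
#'
#' @param cutoff neighbor cutoff in Angstrom (the water-accessibility
#'   default elsewhere is 5).
#' @param use_pbc apply minimum-image convention when a box is available.
#' @return object of class `NeighborQuery`.
#' @export
neighbor_query <- function(cutoff, use_pbc = TRUE) {
  if (!is.numeric(cutoff) || cutoff <= 0) stop("cutoff must be > 0")
  structure(list(cutoff = cutoff, use_pbc = use_pbc), class = "NeighborQuery")
}

#' Which probes lie within a cutoff of any center
#'
#' Cell-list implementation: probes are binned into a grid with cell edge
#' at least the cutoff (periodic wrap when a box is present) and only the
#' 27 neighboring cells of each center's cell are scanned. The result is
#' exact: identical to an all-pairs scan.
#'
#' @param centers,probes coordinate matrices (N x 3).
#' @param query a [neighbor_query()].
#' @param box optional orthorhombic box edges; used when `query$use_pbc`.
#' @return logical vector over probe rows.
#' @export
neighbors_within <- function(centers, probes, query, box = NULL) {
  centers <- rbind(centers)
  probes <- rbind(probes)
  if (!nrow(centers)) {
    warning("empty center set in neighbor search")
    return(rep(FALSE, nrow(probes)))
  }
  cutoff <- query$cutoff
  usebox <- if (query$use_pbc) box else NULL
  if (is.null(usebox)) {
    lo <- pmin(apply(centers, 2, min), apply(probes, 2, min)) - cutoff
    hi <- pmax(apply(centers, 2, max), apply(probes, 2, max)) + cutoff
    span <- hi - lo
    ncell <- pmax(1L, as.integer(floor(span / cutoff)))
    edge <- span / ncell
    cellof <- function(M) {
      ix <- pmin(ncell[1] - 1L, pmax(0L, floor((M[, 1] - lo[1]) / edge[1])))
      iy <- pmin(ncell[2] - 1L, pmax(0L, floor((M[, 2] - lo[2]) / edge[2])))
      iz <- pmin(ncell[3] - 1L, pmax(0L, floor((M[, 3] - lo[3]) / edge[3])))
      cbind(ix, iy, iz)
    }
    wrap <- FALSE
  } else {
    ncell <- pmax(1L, as.integer(floor(usebox / cutoff)))
    edge <- usebox / ncell
    cellof <- function(M) {
      W <- M
      for (j in 1:3) W[, j] <- W[, j] - usebox[j] * floor(W[, j] / usebox[j])
      ix <- pmin(ncell[1] - 1L, floor(W[, 1] / edge[1]))
      iy <- pmin(ncell[2] - 1L, floor(W[, 2] / edge[2]))
      iz <- pmin(ncell[3] - 1L, floor(W[, 3] / edge[3]))
      cbind(ix, iy, iz)
    }
    wrap <- TRUE
  }
  pc <- cellof(probes)
  pid <- pc[, 1] + ncell[1] * (pc[, 2] + ncell[2] * pc[, 3])
  probe_map <- split(seq_len(nrow(probes)), pid)
  cc <- cellof(centers)
  hit <- rep(FALSE, nrow(probes))
  offs <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  ckey <- cc[, 1] + ncell[1] * (cc[, 2] + ncell[2] * cc[, 3])
  for (key in unique(ckey)) {
    cen_rows <- which(ckey == key)
    base <- c(key %% ncell[1],
              (key %/% ncell[1]) %% ncell[2],
              key %/% (ncell[1] * ncell[2]))
    nb <- sweep(offs, 2, base, "+")
    if (wrap) {
      for (j in 1:3) nb[, j] <- nb[, j] %% ncell[j]
    } else {
      ok <- nb[, 1] >= 0 & nb[, 1] < ncell[1] &
            nb[, 2] >= 0 & nb[, 2] < ncell[2] &
            nb[, 3] >= 0 & nb[, 3] < ncell[3]
      nb <- nb[ok, , drop = FALSE]
    }
    keys <- unique(nb[, 1] + ncell[1] * (nb[, 2] + ncell[2] * nb[, 3]))
    cand <- unlist(probe_map[as.character(keys)], use.names = FALSE)
    cand <- cand[!hit[cand]]
    if (!length(cand)) next
    dm <- .mi_distmat(centers[cen_rows, , drop = FALSE],
                      probes[cand, , drop = FALSE], usebox)
    hit[cand[colSums(dm <= cutoff) > 0]] <- TRUE
  }
  hit
}

#' Count probes within a cutoff of any center
#'
#' Each probe is counted at most once even when close to several centers.
#'
#' @inheritParams neighbors_within
#' @return integer count.
#' @export
neighbor_count <- function(centers, probes, query, box = NULL) {
  sum(neighbors_within(centers, probes, query, box))
}

#' Kabsch least-squares superposition
#'
#' Finds the proper rotation and translation minimizing the (weighted)
#' RMSD between `mobile` and `reference`. Reflections are suppressed by
#' the usual determinant correction of the SVD solution, so the returned
#' rotation always has determinant +1.
#'
#' @param mobile,reference M x 3 coordinate matrices, M >= 3.
#' @param weights optional non-negative per-point weights (default uniform).
#' @return object of class `SuperpositionResult` with fields `rotation`
#'   (3 x 3, applies to column vectors), `translation` (length 3) and
#'   `rmsd` (Angstrom). The fitted mobile coordinates are
#'   `mobile %*% t(rotation) + translation` (row-wise).
#' @export
kabsch_superpose <- function(mobile, reference, weights = NULL) {
  mobile <- as.matrix(mobile); reference <- as.matrix(reference)
  if (nrow(mobile) != nrow(reference) || ncol(mobile) != 3) {
    stop("mobile and reference must be matching M x 3 matrices")
  }
  if (nrow(mobile) < 3) stop("superposition needs at least 3 points")
  m <- nrow(mobile)
  w <- if (is.null(weights)) rep(1, m) else as.numeric(weights)
  if (length(w) != m || any(w < 0) || sum(w) == 0) stop("bad weights")
  w <- w / sum(w)
  cm <- colSums(mobile * w)
  cr <- colSums(reference * w)
  P <- sweep(mobile, 2, cm)
  Q <- sweep(reference, 2, cr)
  H <- t(P * w) %*% Q
  sv <- svd(H)
  if (sv$d[2] < 1e-12 * max(sv$d[1], 1e-300)) {
    stop("degenerate (collinear) reference: superposition undefined")
  }
  d <- sign(det(sv$v %*% t(sv$u)))
  if (d == 0) d <- 1
  R <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  fitted <- P %*% t(R)
  rmsd <- sqrt(sum(w * rowSums((fitted - Q)^2)))
  structure(list(rotation = R, translation = as.numeric(cr - R %*% cm),
                 rmsd = rmsd), class = "SuperpositionResult")
}

#' Apply a superposition result to coordinates
#' @param sp a `SuperpositionResult`.
#' @param xyz N x 3 matrix.
#' @return transformed N x 3 matrix.
#' @export
apply_superposition <- function(sp, xyz) {
  sweep(as.matrix(xyz) %*% t(sp$rotation), 2, sp$translation, "+")
}

#' RMSD between two coordinate sets (no fitting)
#' @param a,b N x 3 matrices.
#' @keywords internal
rmsd_raw <- function(a, b) sqrt(mean(rowSums((a - b)^2)))

#' Per-frame RMSD series after superposition
#'
#' Each frame's selected atoms are superposed onto the reference
#' coordinates and the post-fit RMSD is reported, as in trajectory
#' stability plots (values of about or below 4 Angstrom indicating a
#' structure near its start).
#'
#' @param traj a `Trajectory`.
#' @param sel `Selection` used both for fitting and for the RMSD.
#' @param reference a `Frame` (e.g. the start structure); defaults to the
#'   first trajectory frame.
#' @return a `MetricSeries` (see [metric_series()]) in Angstrom.
#' @export
rmsd_series <- function(traj, sel, reference = NULL) {
  if (!length(sel$indices)) stop("empty selection")
  ref <- if (is.null(reference)) traj$frames[[1]] else reference
  refc <- ref$xyz[sel$indices, , drop = FALSE]
  vals <- vapply(traj$frames, function(f) {
    kabsch_superpose(f$xyz[sel$indices, , drop = FALSE], refc)$rmsd
  }, 0)
  metric_series(vals, units = "Angstrom", label = traj$label,
                provenance = sel$name)
}
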