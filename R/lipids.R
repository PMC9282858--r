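#' @title Amphiphile ordering and membrane geometry
#' @description Lipid tail order parameter S_CH relative to a reference
#'   axis, leaflet assignment from headgroup z positions, and per-leaflet
#'   area per lipid by periodic two-dimensional Voronoi tessellation.
#' @name memdyn-lipids
NULL

#' Tail atom definition for order-parameter profiles
#'
#' @param carbons ordered character vector of tail carbon atom names
#'   (e.g. `c("C1", ..., "C8")`).
#' @param hydrogens optional named list mapping each carbon name to its
#'   hydrogen atom names; when missing for a carbon, hydrogens are
#'   reconstructed tetrahedrally from the flanking carbons (terminal
#'   carbons are then skipped with a warning).
#' @param axis reference axis: `"box_z"`, `"protein_principal_axis"`, or
#'   a numeric length-3 vector. The study convention: the bilayer normal
#'   (box z) for membranes, the protein principal axis for micelles
#'   (these coincide once the protein is aligned to the membrane normal).
#' @return object of class `TailDefinition`.
#' @export
tail_definition <- function(carbons, hydrogens = NULL, axis = "box_z") {
  if (!length(carbons)) stop("need at least one tail carbon")
  if (is.numeric(axis)) {
    if (length(axis) != 3 || sum(axis^2) == 0) stop("bad explicit axis")
    axis <- axis / sqrt(sum(axis^2))
  } else if (!axis %in% c("box_z", "protein_principal_axis")) {
    stop("axis must be box_z, protein_principal_axis, or a 3-vector")
  }
  structure(list(carbons = carbons, hydrogens = hydrogens, axis = axis),
            class = "TailDefinition")
}

.reference_axis <- function(tails, top, frm) {
  if (is.numeric(tails$axis)) return(tails$axis)
  if (identical(tails$axis, "box_z")) return(c(0, 0, 1))
  prot <- which(top$atoms$role %in% c("protein", "substrate"))
  if (!length(prot)) stop("no protein atoms for principal-axis reference")
  x <- frm$xyz[prot, , drop = FALSE]
  x <- sweep(x, 2, colMeans(x))
  ev <- eigen(crossprod(x) / nrow(x), symmetric = TRUE)
  ax <- ev$vectors[, 1]
  ax / sqrt(sum(ax^2))
}

# second Legendre polynomial of cos(theta)
.p2 <- function(c2) (3 * c2 - 1) / 2

#' Lipid tail order parameter profile S_CH
#'
#' For each tail carbon position k, S_CH(k) = mean over all lipids,
#' frames and C-H vectors of (3 cos^2 theta - 1)/2, where theta is the
#' angle between the C-H vector and the reference axis. S_CH is 1 for
#' C-H parallel to the axis, -0.5 for perpendicular, 0 for isotropic.
#' The signed value is the physical convention; `abs_SCH` is also
#' reported.
#'
#' @param traj a `Trajectory` containing lipid-role residues.
#' @param tails a [tail_definition()].
#' @param lipid_sel optional `Selection` restricting which lipids enter;
#'   default all residues with role `lipid`.
#' @return object of class `OrderProfile`: data.frame with `carbon`,
#'   `SCH`, `abs_SCH`, `n_vectors`.
#' @export
order_parameter_profile <- function(traj, tails, lipid_sel = NULL) {
  top <- traj$topology
  res <- top$residues
  lip_rows <- which(top$atoms$role[res$first] == "lipid")
  if (!is.null(lipid_sel)) {
    lip_rows <- intersect(lip_rows, selection_residues(top, lipid_sel))
  }
  if (!length(lip_rows)) stop("no lipid residues in trajectory")
  a <- top$atoms
  nk <- length(tails$carbons)
  sums <- numeric(nk); cnts <- integer(nk)
  warned <- FALSE
  for (f in traj$frames) {
    ax <- .reference_axis(tails, top, f)
    for (lr in lip_rows) {
      rng <- res$first[lr]:res$last[lr]
      nm <- a$name[rng]
      cidx <- match(tails$carbons, nm)
      for (k in seq_len(nk)) {
        if (is.na(cidx[k])) next
        cpos <- f$xyz[rng[cidx[k]], ]
        hnames <- if (!is.null(tails$hydrogens)) tails$hydrogens[[tails$carbons[k]]] else NULL
        if (is.null(hnames)) {
          # try the C<k>HA/C<k>HB naming the synthetic generator uses
          hnames <- nm[startsWith(nm, paste0("H", sub("^C", "", tails$carbons[k])))]
        }
        hidx <- match(hnames, nm)
        hidx <- hidx[!is.na(hidx)]
        if (length(hidx)) {
          hv <- f$xyz[rng[hidx], , drop = FALSE]
          for (r in seq_len(nrow(hv))) {
            v <- hv[r, ] - cpos
            c2 <- (sum(v * ax))^2 / sum(v^2)
            sums[k] <- sums[k] + .p2(c2); cnts[k] <- cnts[k] + 1L
          }
        } else {
          # tetrahedral reconstruction from flanking carbons
          if (k == 1 || k == nk || is.na(cidx[k - 1]) || is.na(cidx[k + 1])) {
            if (!warned) {
              warning("terminal/incomplete carbon positions without ",
                      "hydrogens skipped")
              warned <- TRUE
            }
            next
          }
          hpair <- .tetrahedral_h(f$xyz[rng[cidx[k - 1]], ], cpos,
                                  f$xyz[rng[cidx[k + 1]], ])
          for (r in 1:2) {
            v <- hpair[[r]] - cpos
            c2 <- (sum(v * ax))^2 / sum(v^2)
            sums[k] <- sums[k] + .p2(c2); cnts[k] <- cnts[k] + 1L
          }
        }
      }
    }
  }
  keep <- cnts > 0
  out <- data.frame(carbon = tails$carbons[keep], SCH = sums[keep] / cnts[keep],
                    abs_SCH = abs(sums[keep] / cnts[keep]),
                    n_vectors = cnts[keep], stringsAsFactors = FALSE)
  class(out) <- c("OrderProfile", "data.frame")
  out
}

# two tetrahedral hydrogens on a CH2 carbon given the flanking carbons;
# a collinear C-C-C arrangement leaves the azimuth undefined, in which
# case a deterministic perpendicular is chosen
.tetrahedral_h <- function(c_prev, c_k, c_next) {
  v1 <- c_prev - c_k; v1 <- v1 / sqrt(sum(v1^2))
  v2 <- c_next - c_k; v2 <- v2 / sqrt(sum(v2^2))
  s <- v1 + v2
  perp <- c(v1[2] * v2[3] - v1[3] * v2[2], v1[3] * v2[1] - v1[1] * v2[3],
            v1[1] * v2[2] - v1[2] * v2[1])
  pn <- sqrt(sum(perp^2))
  half <- (109.47 / 2) * pi / 180
  if (pn < 1e-8 || sqrt(sum(s^2)) < 1e-8) {
    a <- if (abs(v2[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
    e1 <- a - sum(a * v2) * v2; e1 <- e1 / sqrt(sum(e1^2))
    e2 <- c(v2[2] * e1[3] - v2[3] * e1[2], v2[3] * e1[1] - v2[1] * e1[3],
            v2[1] * e1[2] - v2[2] * e1[1])
    return(list(c_k + 1.09 * (cos(half) * e1 + sin(half) * e2),
                c_k + 1.09 * (cos(half) * e1 - sin(half) * e2)))
  }
  bis <- -s / sqrt(sum(s^2))
  perp <- perp / pn
  list(c_k + 1.09 * (cos(half) * bis + sin(half) * perp),
       c_k + 1.09 * (cos(half) * bis - sin(half) * perp))
}

#' Assign bilayer lipids to leaflets
#'
#' The midplane is the mean headgroup z; lipids are assigned by the sign
#' of (headgroup z - midplane), with lipids within 2 Angstrom of the
#' midplane flagged unassigned. A headgroup z distribution that is not
#' clearly bimodal (either leaflet empty, more than 20 percent
#' unassigned, or the spread of |z - midplane| large relative to its
#' mean) raises a "not a bilayer" error - micelles have no leaflets.
#'
#' @param frm a `Frame`.
#' @param top the `Topology`.
#' @param headgroups `Selection` with exactly one headgroup atom per
#'   lipid (e.g. the phosphorus).
#' @param margin unassigned band half-width about the midplane (Angstrom).
#' @return object of class `LeafletPartition`: list with `leaflet`
#'   (factor upper/lower/unassigned per lipid), `midplane`, and the
#'   headgroup atom indices.
#' @export
assign_leaflets <- function(frm, top, headgroups, margin = 2.0) {
  idx <- headgroups$indices
  if (length(idx) < 2) stop("need at least 2 headgroup atoms")
  z <- frm$xyz[idx, 3]
  mid <- mean(z)
  d <- z - mid
  leaflet <- ifelse(abs(d) <= margin, "unassigned",
                    ifelse(d > 0, "upper", "lower"))
  nu <- sum(leaflet == "upper"); nl <- sum(leaflet == "lower")
  if (nu == 0 || nl == 0 || mean(leaflet == "unassigned") > 0.2) {
    stop("not a bilayer: headgroup z distribution is not bimodal")
  }
  # bimodality proxy: in a bilayer, |z - midplane| clusters tightly at the
  # leaflet distance; a micelle or monolayer spreads it out
  ad <- abs(d)
  if (stats::sd(ad) / mean(ad) > 0.3) {
    stop("not a bilayer: headgroup z distribution is not bimodal")
  }
  structure(list(leaflet = leaflet, midplane = mid, indices = idx),
            class = "LeafletPartition")
}

#' Area per lipid, per leaflet
#'
#' `box_ratio`: lateral box area divided by the leaflet's lipid count.
#' `voronoi`: periodic 2-D Voronoi tessellation of the headgroup
#' positions projected on the xy-plane (each generator point is tiled
#' into the 8 neighboring images); per-lipid cell areas are returned and
#' sum exactly to the lateral box area.
#'
#' @param frm a `Frame` with a box (the lateral area must be defined).
#' @param partition a [assign_leaflets()] result.
#' @param method `"voronoi"` (default) or `"box_ratio"`.
#' @return list with `mean` (Angstrom^2, over both leaflets), `per_leaflet`
#'   (named vector), and for voronoi `per_lipid` (list of per-leaflet
#'   area vectors).
#' @export
area_per_lipid <- function(frm, partition, method = c("voronoi", "box_ratio")) {
  method <- match.arg(method)
  if (is.null(frm$box)) stop("area per lipid needs a periodic box")
  bx <- frm$box[1]; by <- frm$box[2]
  out <- list(per_leaflet = c(upper = NA_real_, lower = NA_real_),
              per_lipid = list())
  for (lf in c("upper", "lower")) {
    idx <- partition$indices[partition$leaflet == lf]
    nL <- length(idx)
    if (method == "box_ratio") {
      out$per_leaflet[lf] <- bx * by / nL
    } else {
      if (nL < 3) stop("voronoi needs at least 3 lipids per leaflet")
      pts <- frm$xyz[idx, 1:2, drop = FALSE]
      pts[, 1] <- pts[, 1] %% bx
      pts[, 2] <- pts[, 2] %% by
      areas <- .periodic_voronoi_areas(pts, bx, by)
      out$per_lipid[[lf]] <- areas
      out$per_leaflet[lf] <- mean(areas)
    }
  }
  out$mean <- mean(out$per_leaflet)
  out
}

# cell areas of the periodic 2-D Voronoi diagram of pts in a bx x by box.
# Each cell is an intersection of half-planes. The bisectors against the
# point's own periodic images reduce exactly to the rectangle
# p +/- (bx/2, by/2), which is the starting polygon; the other points'
# nine images are then applied nearest-first, stopping once the next
# generator is too far to cut the current cell (half its distance exceeds
# the cell's maximal vertex radius), which keeps the result exact.
.periodic_voronoi_areas <- function(pts, bx, by) {
  n <- nrow(pts)
  shifts <- as.matrix(expand.grid(x = c(-bx, 0, bx), y = c(-by, 0, by)))
  others <- vector("list", n)
  areas <- numeric(n)
  gx <- as.vector(outer(pts[, 1], shifts[, 1], "+"))
  gy <- as.vector(outer(pts[, 2], shifts[, 2], "+"))
  src <- rep(seq_len(n), times = nrow(shifts))
  for (i in seq_len(n)) {
    p <- pts[i, ]
    keep <- src != i
    qx <- gx[keep]; qy <- gy[keep]
    d2 <- (qx - p[1])^2 + (qy - p[2])^2
    ord <- order(d2)
    poly <- cbind(p[1] + c(-bx, bx, bx, -bx) / 2,
                  p[2] + c(-by, -by, by, by) / 2)
    maxr2 <- max((poly[, 1] - p[1])^2 + (poly[, 2] - p[2])^2)
    for (g in ord) {
      if (d2[g] > 4 * maxr2) break
      poly <- .clip_halfplane(poly, p, c(qx[g], qy[g]))
      if (nrow(poly) < 3) break
      maxr2 <- max((poly[, 1] - p[1])^2 + (poly[, 2] - p[2])^2)
    }
    areas[i] <- .shoelace(poly)
  }
  areas
}

# clip convex polygon to the half-plane of points closer to p than to q
.clip_halfplane <- function(poly, p, q) {
  nrm <- q - p
  off <- sum(nrm * (p + q)) / 2
  val <- poly %*% nrm - off  # <= 0 inside
  n <- nrow(poly)
  out <- matrix(0, 0, 2)
  for (k in seq_len(n)) {
    k2 <- if (k == n) 1L else k + 1L
    a_in <- val[k] <= 0; b_in <- val[k2] <= 0
    if (a_in) out <- rbind(out, poly[k, ])
    if (xor(a_in, b_in)) {
      t <- val[k] / (val[k] - val[k2])
      out <- rbind(out, poly[k, ] + t * (poly[k2, ] - poly[k, ]))
    }
  }
  out
}

.shoelace <- function(poly) {
  if (nrow(poly) < 3) return(0)
  x <- poly[, 1]; y <- poly[, 2]
  abs(sum(x * c(y[-1], y[1]) - c(x[-1], x[1]) * y)) / 2
}
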