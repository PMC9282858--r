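#' @title Ideal backbone construction
#' @description Poly-alanine backbones built from standard bond lengths and
#'   angles by natural-extension-of-reference-frame (NeRF) placement, used
#'   as ground-truth fixtures for secondary-structure and hydrogen-bond
#'   analysis and as the reference structures of the synthetic generator.
#' @name memdyn-build
NULL

# standard backbone geometry (Angstrom / degrees)
.bb <- list(n_ca = 1.458, ca_c = 1.525, c_n = 1.329, c_o = 1.231,
            ang_c_n_ca = 121.7, ang_n_ca_c = 111.2, ang_ca_c_n = 116.2,
            ang_ca_c_o = 120.5)

# place atom D bonded to C with |CD| = r, angle(B,C,D) = theta and
# dihedral(A,B,C,D) = chi (degrees)
.place_atom <- function(A, B, C, r, theta, chi) {
  th <- theta * pi / 180
  ph <- chi * pi / 180
  bc <- C - B; bc <- bc / sqrt(sum(bc^2))
  ab <- B - A; ab <- ab / sqrt(sum(ab^2))
  n <- c(ab[2] * bc[3] - ab[3] * bc[2],
         ab[3] * bc[1] - ab[1] * bc[3],
         ab[1] * bc[2] - ab[2] * bc[1])
  n <- n / sqrt(sum(n^2))
  m <- c(n[2] * bc[3] - n[3] * bc[2],
         n[3] * bc[1] - n[1] * bc[3],
         n[1] * bc[2] - n[2] * bc[1])
  C + r * (-cos(th) * bc + sin(th) * (cos(ph) * m - sin(ph) * n))
}

#' Dihedral angle of four points (degrees, IUPAC sign convention)
#' @param a,b,c,d length-3 coordinates.
#' @export
dihedral <- function(a, b, c, d) {
  b1 <- b - a; b2 <- c - b; b3 <- d - c
  n1 <- c(b1[2] * b2[3] - b1[3] * b2[2], b1[3] * b2[1] - b1[1] * b2[3],
          b1[1] * b2[2] - b1[2] * b2[1])
  n2 <- c(b2[2] * b3[3] - b2[3] * b3[2], b2[3] * b3[1] - b2[1] * b3[3],
          b2[1] * b3[2] - b2[2] * b3[1])
  m1 <- c(n1[2] * b2[3] - n1[3] * b2[2], n1[3] * b2[1] - n1[1] * b2[3],
          n1[1] * b2[2] - n1[2] * b2[1]) / sqrt(sum(b2^2))
  atan2(sum(m1 * n2), sum(n1 * n2)) * 180 / pi
}

#' Build a poly-alanine backbone from phi/psi dihedrals
#'
#' Atoms per residue: N, CA, C, O (in this order); standard bond lengths
#' and angles, omega fixed at 180 degrees. Coordinates start at the
#' origin with the first N-CA bond along x.
#'
#' @param n number of residues (>= 2).
#' @param phi,psi backbone dihedrals in degrees; scalars are recycled.
#'   `phi[1]` and `psi[n]` only affect terminal atom placement.
#' @param chain chain identifier for the topology.
#' @param resid_start first author residue number.
#' @return list(topology, frame) — a 4-atom-per-residue backbone.
#' @export
build_peptide <- function(n, phi = -57, psi = -47, chain = "A",
                          resid_start = 1L) {
  if (n < 2) stop("need at least 2 residues")
  phi <- rep_len(phi, n); psi <- rep_len(psi, n)
  N <- matrix(0, n, 3); CA <- matrix(0, n, 3); C <- matrix(0, n, 3)
  O <- matrix(0, n, 3)
  N[1, ] <- c(0, 0, 0)
  CA[1, ] <- c(.bb$n_ca, 0, 0)
  # first C placed in the xy-plane at the N-CA-C angle
  ang <- .bb$ang_n_ca_c * pi / 180
  C[1, ] <- CA[1, ] + .bb$ca_c * c(-cos(ang), sin(ang), 0)
  for (i in seq_len(n - 1)) {
    N[i + 1, ] <- .place_atom(N[i, ], CA[i, ], C[i, ], .bb$c_n,
                              .bb$ang_ca_c_n, psi[i])
    CA[i + 1, ] <- .place_atom(CA[i, ], C[i, ], N[i + 1, ], .bb$n_ca,
                               .bb$ang_c_n_ca, 180)
    C[i + 1, ] <- .place_atom(C[i, ], N[i + 1, ], CA[i + 1, ], .bb$ca_c,
                              .bb$ang_n_ca_c, phi[i + 1])
  }
  for (i in seq_len(n)) {
    O[i, ] <- .place_atom(N[i, ], CA[i, ], C[i, ], .bb$c_o,
                          .bb$ang_ca_c_o, psi[i] + 180)
  }
  xyz <- matrix(0, 4 * n, 3)
  xyz[seq(1, 4 * n, 4), ] <- N
  xyz[seq(2, 4 * n, 4), ] <- CA
  xyz[seq(3, 4 * n, 4), ] <- C
  xyz[seq(4, 4 * n, 4), ] <- O
  atoms <- data.frame(serial = seq_len(4 * n),
                      name = rep(c("N", "CA", "C", "O"), n),
                      element = rep(c("N", "C", "C", "O"), n),
                      resid = rep(seq.int(resid_start, length.out = n), each = 4),
                      resname = "ALA", chain = chain, stringsAsFactors = FALSE)
  list(topology = topology(atoms), frame = frame(xyz))
}

#' Ideal alpha-helix fixture
#'
#' Poly-alanine with phi = -57, psi = -47 degrees; the helical rise of
#' about 1.5 Angstrom per residue and ~3.6 residues per turn emerge from
#' the dihedrals.
#'
#' @param n number of residues (>= 4).
#' @inheritParams build_peptide
#' @return list(topology, frame).
#' @export
build_ideal_helix <- function(n, chain = "A", resid_start = 1L) {
  if (n < 4) stop("helix needs at least 4 residues")
  build_peptide(n, phi = -57, psi = -47, chain = chain,
                resid_start = resid_start)
}

#' Ideal extended strand fixture
#' @param n number of residues.
#' @inheritParams build_peptide
#' @export
build_ideal_strand <- function(n, chain = "A", resid_start = 1L) {
  build_peptide(n, phi = -139, psi = 135, chain = chain,
                resid_start = resid_start)
}

#' Idealized two-strand antiparallel beta-sheet fixture
#'
#' Two extended poly-alanine strands; the second strand is the first one
#' rotated by 180 degrees about the strand axis' perpendicular and placed
#' by a deterministic grid search over the rigid offset that maximizes the
#' number of Kabsch-Sander inter-strand hydrogen bonds. The resulting
#' ladder is the ground truth for hydrogen-bond counting tests.
#'
#' @param n_res residues per strand (default 6).
#' @return list(topology, frame) with chains "A" and "B".
#' @export
build_beta_sheet <- function(n_res = 6L) {
  s1 <- build_peptide(n_res, phi = -139, psi = 135, chain = "A")
  ax <- stats::prcomp(s1$frame$xyz)$rotation[, 1]
  # align strand A axis to x for a clean search space
  R0 <- .rotation_onto(ax, c(1, 0, 0))
  A <- s1$frame$xyz %*% t(R0)
  A <- sweep(A, 2, colMeans(A))
  # the antiparallel partner is a 180-degree rotation of strand A about an
  # axis perpendicular to the strand direction (about y or about z,
  # whichever matches the pleat), shifted by the inter-strand offset
  flips <- list(diag(c(-1, 1, -1)), diag(c(-1, -1, 1)))
  # score placements by the strict geometric bond count (tie-broken by
  # the Kabsch-Sander count) so that both criteria agree on the fixture
  score <- function(fl, off) {
    B <- sweep(A %*% t(fl), 2, off, "+")
    cnt <- .count_sheet_bonds(A, B, n_res)
    cnt["geometric"] * 1000L + cnt["kabsch_sander"]
  }
  best <- list(n = -1L)
  for (fi in seq_along(flips)) {
    for (dx in seq(-4, 4, by = 0.5)) {
      for (dy in seq(-5.5, 5.5, by = 0.5)) {
        for (dz in seq(-2, 2, by = 0.5)) {
          if (abs(dy) < 3 && abs(dz) < 3) next  # overlapping placements
          nb <- score(flips[[fi]], c(dx, dy, dz))
          if (nb > best$n) best <- list(n = nb, fi = fi, off = c(dx, dy, dz))
        }
      }
    }
  }
  # refine around the coarse optimum
  for (dx in best$off[1] + seq(-0.4, 0.4, by = 0.1)) {
    for (dy in best$off[2] + seq(-0.4, 0.4, by = 0.1)) {
      for (dz in best$off[3] + seq(-0.4, 0.4, by = 0.1)) {
        nb <- score(flips[[best$fi]], c(dx, dy, dz))
        if (nb > best$n) best <- list(n = nb, fi = best$fi, off = c(dx, dy, dz))
      }
    }
  }
  B <- sweep(A %*% t(flips[[best$fi]]), 2, best$off, "+")
  a1 <- s1$topology$atoms
  a2 <- a1
  a2$chain <- "B"
  a2$serial <- a2$serial + nrow(a1)
  top <- topology(rbind(a1, a2))
  list(topology = top, frame = frame(rbind(A, B)))
}

# minimal rotation taking unit vector u onto unit vector v
.rotation_onto <- function(u, v) {
  u <- u / sqrt(sum(u^2)); v <- v / sqrt(sum(v^2))
  c_ <- sum(u * v)
  if (c_ > 1 - 1e-12) return(diag(3))
  if (c_ < -1 + 1e-12) {
    # pick any perpendicular axis
    p <- if (abs(u[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
    ax <- p - sum(p * u) * u; ax <- ax / sqrt(sum(ax^2))
    K <- .skew(ax)
    return(diag(3) + 2 * K %*% K)
  }
  ax <- c(u[2] * v[3] - u[3] * v[2], u[3] * v[1] - u[1] * v[3],
          u[1] * v[2] - u[2] * v[1])
  s <- sqrt(sum(ax^2))
  K <- .skew(ax / s)
  diag(3) + s * K + (1 - c_) * K %*% K
}

.skew <- function(a) {
  matrix(c(0, a[3], -a[2], -a[3], 0, a[1], a[2], -a[1], 0), 3, 3)
}

# inter-strand bond counts (geometric and Kabsch-Sander) for the sheet
# placement search; strands are 4-atom-per-residue build_peptide backbones
.count_sheet_bonds <- function(A, B, n_res) {
  bbA <- .strand_bb(A, n_res); bbB <- .strand_bb(B, n_res)
  ks <- 0L; geo <- 0L
  pair <- function(N, H, C, O) {
    if (is.null(H)) return(c(0L, 0L))
    k <- ks_energy(N, H, C, O) < -0.5
    r_no <- sqrt(sum((O - N)^2))
    g <- FALSE
    if (r_no <= 3.5) {
      v1 <- N - H; v2 <- O - H
      cosang <- sum(v1 * v2) / sqrt(sum(v1^2) * sum(v2^2))
      g <- acos(pmin(1, pmax(-1, cosang))) * 180 / pi >= 135
    }
    c(as.integer(g), as.integer(k))
  }
  for (i in seq_len(n_res)) {
    for (j in seq_len(n_res)) {
      a <- pair(bbA$N[i, ], bbA$H[[i]], bbB$C[j, ], bbB$O[j, ])
      b <- pair(bbB$N[j, ], bbB$H[[j]], bbA$C[i, ], bbA$O[i, ])
      geo <- geo + a[1] + b[1]; ks <- ks + a[2] + b[2]
    }
  }
  c(geometric = geo, kabsch_sander = ks)
}

.strand_bb <- function(xyz, n_res) {
  N <- xyz[seq(1, 4 * n_res, 4), , drop = FALSE]
  CA <- xyz[seq(2, 4 * n_res, 4), , drop = FALSE]
  C <- xyz[seq(3, 4 * n_res, 4), , drop = FALSE]
  O <- xyz[seq(4, 4 * n_res, 4), , drop = FALSE]
  H <- vector("list", n_res)
  for (i in 2:n_res) H[[i]] <- amide_h_position(C[i - 1, ], N[i, ], CA[i, ])
  list(N = N, CA = CA, C = C, O = O, H = H)
}
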