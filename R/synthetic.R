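#' @title Synthetic trajectory generator
#' @description Deterministic pseudo-physical generator emulating the
#'   statistical structure of membrane-protein simulations in two
#'   environments: a "bilayer" mode (low flexible-region mobility, stable
#'   helix, ordered amphiphile tails, high active-geometry occupancy) and
#'   a "micelle" mode (elevated flexible-region fluctuations, scheduled
#'   helix-coil transitions, disordered tails, lower occupancy). Every
#'   parameter a downstream metric estimates is emitted as a ground-truth
#'   sidecar. This is analysis-validation machinery, not molecular
#'   dynamics: no force field, no energetics, no physical realism beyond
#'   the statistical features the metrics read out.
#' @name memdyn-synthetic
NULL

#' Synthetic system specification
#'
#' Defaults emulate the deposited study systems at desk scale: a
#' ~290-residue enzyme chain (A) with a designated high-mobility region
#' (the short helix at residues 171-177 standing in for TMD6a), an
#' 83-residue substrate chain (B), catalytic pseudo-atoms on residues 162
#' and 220 whose separation follows a two-state Markov process with an
#' active mode near 6.8 Angstrom, a diffusing water bath, and an
#' amphiphile system (128 lipids; the bilayer lateral box is sized for an
#' area per lipid of ~68 Angstrom^2). Micelle mode triples the flexible
#' region's fluctuation amplitude, schedules a helix-coil-helix
#' transition, lowers the tail order concentration and lowers the
#' active-geometry occupancy (0.63 vs 0.76).
#'
#' @param mode `"bilayer"` or `"micelle"`.
#' @param seed integer; fully determines all output (replicate r uses
#'   seed + r).
#' @param n_protein_residues,n_substrate_residues chain lengths.
#' @param flexible_region inclusive residue range of the high-mobility
#'   helix on chain A.
#' @param sigma_base stationary per-coordinate fluctuation amplitude
#'   (Angstrom) of the per-residue AR(1) displacement process.
#' @param flexible_sigma_factor amplitude multiplier inside
#'   `flexible_region` (default 1 in bilayer, 3 in micelle mode).
#' @param ar1_rho frame-to-frame AR(1) correlation of displacements.
#' @param helix_schedule data.frame(from, to, state) of frame ranges with
#'   state "helix" or "coil" for the flexible region; default all-helix
#'   (bilayer) or helix/coil/helix thirds (micelle).
#' @param ramp_frames frames over which dihedrals interpolate at schedule
#'   switches.
#' @param n_waters water molecule count.
#' @param box protein-system orthorhombic box (Angstrom).
#' @param n_lipids amphiphile count (bilayer: split into two leaflets).
#' @param kappa von Mises-Fisher concentration of tail directors
#'   (default 20 bilayer, 0.5 micelle).
#' @param n_tail_carbons tail carbons per lipid.
#' @param lipid_box amphiphile-system box; the bilayer default
#'   66 x 66 x 100 gives 64 lipids per leaflet an area per lipid of
#'   ~68 Angstrom^2.
#' @param catalytic_resids the two chain-A residues carrying CG
#'   pseudo-atoms.
#' @param active_mu two-state distance means (Angstrom).
#' @param active_noise_sd within-state distance jitter (kept at 5 sigma
#'   from the 7 Angstrom threshold so below-threshold occupancy equals
#'   the state-1 stationary probability).
#' @param p_active stationary probability of the short-distance state
#'   (default 0.76 bilayer, 0.63 micelle).
#' @param switch_rate Markov switching rate parameter (per-frame escape
#'   probabilities `switch_rate * (1 - p_active)` and
#'   `switch_rate * p_active`).
#' @param n_frames frames per replicate.
#' @param n_replicates replicate trajectories.
#' @return object of class `SyntheticSpec`.
#' @export
synthetic_spec <- function(mode = c("bilayer", "micelle"), seed = 42L,
                           n_protein_residues = 290L,
                           n_substrate_residues = 83L,
                           flexible_region = c(171L, 177L),
                           sigma_base = 0.3,
                           flexible_sigma_factor = NULL,
                           ar1_rho = 0.9,
                           helix_schedule = NULL,
                           ramp_frames = 5L,
                           n_waters = 300L,
                           box = c(80, 80, 100),
                           n_lipids = 128L,
                           kappa = NULL,
                           n_tail_carbons = 8L,
                           lipid_box = NULL,
                           catalytic_resids = c(162L, 220L),
                           active_mu = c(6.8, 8.5),
                           active_noise_sd = 0.04,
                           p_active = NULL,
                           switch_rate = 0.5,
                           n_frames = 300L,
                           n_replicates = 3L) {
  mode <- match.arg(mode)
  if (is.null(flexible_sigma_factor)) {
    flexible_sigma_factor <- if (mode == "micelle") 3 else 1
  }
  if (is.null(kappa)) kappa <- if (mode == "micelle") 0.5 else 20
  if (is.null(p_active)) p_active <- if (mode == "micelle") 0.63 else 0.76
  if (is.null(lipid_box)) {
    lipid_box <- if (mode == "bilayer") c(66, 66, 100) else c(80, 80, 80)
  }
  if (is.null(helix_schedule)) {
    helix_schedule <- if (mode == "micelle") {
      t1 <- floor(n_frames / 3); t2 <- floor(2 * n_frames / 3)
      data.frame(from = c(1L, t1 + 1L, t2 + 1L), to = c(t1, t2, n_frames),
                 state = c("helix", "coil", "helix"), stringsAsFactors = FALSE)
    } else {
      data.frame(from = 1L, to = n_frames, state = "helix",
                 stringsAsFactors = FALSE)
    }
  }
  stopifnot(sigma_base > 0, p_active >= 0, p_active <= 1,
            ar1_rho >= 0, ar1_rho < 1, n_frames >= 10,
            flexible_region[1] >= 1,
            flexible_region[2] <= n_protein_residues,
            all(catalytic_resids <= n_protein_residues))
  spec <- list(mode = mode, seed = as.integer(seed),
               n_protein_residues = as.integer(n_protein_residues),
               n_substrate_residues = as.integer(n_substrate_residues),
               flexible_region = as.integer(flexible_region),
               sigma_base = sigma_base,
               flexible_sigma_factor = flexible_sigma_factor,
               ar1_rho = ar1_rho, helix_schedule = helix_schedule,
               ramp_frames = as.integer(ramp_frames),
               n_waters = as.integer(n_waters), box = box,
               n_lipids = as.integer(n_lipids), kappa = kappa,
               n_tail_carbons = as.integer(n_tail_carbons),
               lipid_box = lipid_box,
               catalytic_resids = as.integer(catalytic_resids),
               active_mu = active_mu, active_noise_sd = active_noise_sd,
               p_active = p_active, switch_rate = switch_rate,
               n_frames = as.integer(n_frames),
               n_replicates = as.integer(n_replicates))
  class(spec) <- "SyntheticSpec"
  spec
}

#' Per-residue fluctuation amplitude profile of a spec (chain A then B)
#' @param spec a `SyntheticSpec`.
#' @return named numeric vector, one sigma per residue.
#' @export
sigma_profile <- function(spec) {
  sig <- rep(spec$sigma_base, spec$n_protein_residues + spec$n_substrate_residues)
  fr <- spec$flexible_region
  sig[fr[1]:fr[2]] <- spec$sigma_base * spec$flexible_sigma_factor
  names(sig) <- c(paste0("A/", seq_len(spec$n_protein_residues)),
                  paste0("B/", seq_len(spec$n_substrate_residues)))
  sig
}

# ---- reference structure -------------------------------------------------

# segment layout: chains built as helical segments of seg_len residues
# arranged on circles (a crude transmembrane-bundle geometry that keeps a
# ~300-residue chain inside the box)
.segment_layout <- function(n_res, seg_len) {
  starts <- seq(1L, n_res, by = seg_len)
  data.frame(start = starts, end = pmin(starts + seg_len - 1L, n_res))
}

# build + place one segment; returns 4*len x 3 coordinates. lambda
# interpolates region dihedrals from helix (0) to extended (1).
.build_segment <- function(len, resid0, region = NULL, lambda = 0,
                           anchor_rot, anchor_pos) {
  phi <- rep(-57, len); psi <- rep(-47, len)
  if (!is.null(region) && lambda > 0) {
    loc <- intersect(seq_len(len), region - resid0 + 1L)
    phi[loc] <- -57 + lambda * (-139 - -57)
    psi[loc] <- -47 + lambda * (135 - -47)
  }
  pep <- build_peptide(len, phi = phi, psi = psi)
  x <- pep$frame$xyz %*% t(anchor_rot)
  sweep(x, 2, anchor_pos - x[1, ], "+")
}

# rotation aligning a segment's principal axis to +/- z, computed once
# from the pure-helix build so that all schedule variants share it
.segment_anchor <- function(len, up) {
  pep <- build_peptide(len, phi = -57, psi = -47)
  x <- pep$frame$xyz
  xc <- sweep(x, 2, colMeans(x))
  ax <- eigen(crossprod(xc) / nrow(xc), symmetric = TRUE)$vectors[, 1]
  # orient the axis along the chain direction, then flip for "down" segments
  if (sum((x[nrow(x), ] - x[1, ]) * ax) < 0) ax <- -ax
  .rotation_onto(ax, c(0, 0, if (up) 1 else -1))
}

# static reference coordinates + atom table for protein & substrate;
# returns list(atoms, xyz, seg_info) where seg_info locates the flexible
# segment for per-frame rebuilds
.reference_structure <- function(spec) {
  segsA <- .segment_layout(spec$n_protein_residues, 30L)
  segsB <- .segment_layout(spec$n_substrate_residues, 28L)
  nsegA <- nrow(segsA); nsegB <- nrow(segsB)
  atoms <- list(); coords <- list(); seg_info <- NULL
  k <- 0L
  place <- function(chain, segs, radius, ang0) {
    for (s in seq_len(nrow(segs))) {
      k <<- k + 1L
      len <- segs$end[s] - segs$start[s] + 1L
      up <- s %% 2L == 1L
      rot <- .segment_anchor(len, up)
      ang <- ang0 + 2 * pi * (s - 1) / nrow(segs)
      pos <- c(radius * cos(ang), radius * sin(ang),
               if (up) -22 else 22)
      region <- if (chain == "A" &&
                    spec$flexible_region[1] >= segs$start[s] &&
                    spec$flexible_region[1] <= segs$end[s]) {
        spec$flexible_region[1]:spec$flexible_region[2]
      } else NULL
      x <- .build_segment(len, segs$start[s], region, 0, rot, pos)
      atoms[[k]] <<- data.frame(
        serial = NA_integer_, name = rep(c("N", "CA", "C", "O"), len),
        element = rep(c("N", "C", "C", "O"), len),
        resid = rep(segs$start[s]:segs$end[s], each = 4),
        resname = "ALA", chain = chain, stringsAsFactors = FALSE)
      coords[[k]] <<- x
      if (!is.null(region)) {
        seg_info <<- list(block = k, len = len, resid0 = segs$start[s],
                          region = region, rot = rot, pos = pos)
      }
    }
  }
  place("A", segsA, 16, 0)
  place("B", segsB, 28, pi / nsegB)
  at <- do.call(rbind, atoms)
  xyz <- do.call(rbind, coords)
  # center the bundle in the box
  shift <- spec$box / 2 - colMeans(xyz)
  xyz <- sweep(xyz, 2, shift, "+")
  list(atoms = at, xyz = xyz, seg_info = seg_info, shift = shift,
       block_rows = cumsum(c(0, vapply(coords, nrow, 0L))))
}

# insert CG pseudo-atoms after the O of the two catalytic residues
.add_catalytic_cg <- function(atoms, xyz, resids) {
  for (rr in resids) {
    at_o <- which(atoms$chain == "A" & atoms$resid == rr & atoms$name == "O")
    at_ca <- which(atoms$chain == "A" & atoms$resid == rr & atoms$name == "CA")
    row <- atoms[at_o, ]; row$name <- "CG"; row$element <- "C"
    row$resname <- "ASP"
    atoms <- rbind(atoms[1:at_o, ], row,
                   atoms[(at_o + 1):nrow(atoms), , drop = FALSE])
    cg <- xyz[at_ca, ] + c(1.0, 1.0, 0.5)
    xyz <- rbind(xyz[1:at_o, , drop = FALSE], cg,
                 xyz[(at_o + 1):nrow(xyz), , drop = FALSE])
  }
  atoms$resname[atoms$chain == "A" & atoms$resid %in% resids] <- "ASP"
  list(atoms = atoms, xyz = xyz)
}

# per-frame interpolation factor (0 helix, 1 coil) from the schedule
.schedule_lambda <- function(schedule, n_frames, ramp) {
  lam <- numeric(n_frames)
  for (s in seq_len(nrow(schedule))) {
    lam[schedule$from[s]:schedule$to[s]] <-
      if (schedule$state[s] == "coil") 1 else 0
  }
  if (ramp > 1) {
    lam <- stats::filter(c(rep(lam[1], ramp), lam), rep(1 / ramp, ramp),
                         sides = 1)
    lam <- as.numeric(lam)[-seq_len(ramp)]
  }
  lam
}

# uniform random rotation matrix from a random quaternion
.random_rotation <- function() {
  q <- stats::rnorm(4); q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y + w * z), 2 * (x * z - w * y),
           2 * (x * y - w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z + w * x),
           2 * (x * z + w * y), 2 * (y * z - w * x), 1 - 2 * (x^2 + y^2)),
         3, 3)
}

#' Generate replicate protein+substrate+water trajectories
#'
#' Reference structure: helical segments arranged as a bundle. Per frame:
#' the flexible region follows the helix schedule (dihedral
#' interpolation), every residue carries a temporally correlated AR(1)
#' rigid displacement with the spec's per-residue sigma, catalytic CG
#' pseudo-atoms follow the two-state distance process, waters take
#' diffusive steps inside the box, and a global random rigid-body motion
#' is applied to the whole frame (so downstream superposition is actually
#' exercised). Fully deterministic given the spec seed; replicate r uses
#' seed + r.
#'
#' @param spec a [synthetic_spec()].
#' @return list of `Trajectory` (length `n_replicates`), with the
#'   ground-truth sidecar as attribute `ground_truth`.
#' @export
generate_protein_trajectory <- function(spec) {
  ref <- .reference_structure(spec)
  aug <- .add_catalytic_cg(ref$atoms, ref$xyz, spec$catalytic_resids)
  atoms <- aug$atoms; base_xyz <- aug$xyz
  # water atom block
  nw <- spec$n_waters
  if (nw > 0) {
    watoms <- data.frame(
      serial = NA_integer_, name = rep(c("O", "H1", "H2"), nw),
      element = rep(c("O", "H", "H"), nw),
      resid = rep(seq_len(nw), each = 3), resname = "HOH", chain = "W",
      stringsAsFactors = FALSE)
    atoms <- rbind(atoms, watoms)
  }
  atoms$serial <- seq_len(nrow(atoms))
  top <- topology(atoms, substrate_chains = "B")
  n_prot_atoms <- nrow(base_xyz)
  # residue row (chain A then B order) per protein/substrate atom
  sig <- sigma_profile(spec)
  akey <- paste0(atoms$chain[seq_len(n_prot_atoms)], "/",
                 atoms$resid[seq_len(n_prot_atoms)])
  sig_atom_row <- match(akey, names(sig))
  icg1 <- which(atoms$chain == "A" & atoms$resid == spec$catalytic_resids[1] &
                atoms$name == "CG")
  icg2 <- which(atoms$chain == "A" & atoms$resid == spec$catalytic_resids[2] &
                atoms$name == "CG")
  ica1 <- which(atoms$chain == "A" & atoms$resid == spec$catalytic_resids[1] &
                atoms$name == "CA")
  ica2 <- which(atoms$chain == "A" & atoms$resid == spec$catalytic_resids[2] &
                atoms$name == "CA")
  u_cat <- base_xyz[ica2, ] - base_xyz[ica1, ]
  u_cat <- u_cat / sqrt(sum(u_cat^2))
  cg_off <- base_xyz[icg1, ] - base_xyz[ica1, ]
  lam <- round(.schedule_lambda(spec$helix_schedule, spec$n_frames,
                                spec$ramp_frames), 6)
  lam_grid <- sort(unique(lam))
  # precompute flexible-segment variants on the lambda grid
  si <- ref$seg_info
  variants <- NULL
  if (!is.null(si)) {
    variants <- lapply(lam_grid, function(l) {
      x <- .build_segment(si$len, si$resid0, si$region, l, si$rot, si$pos)
      sweep(x, 2, ref$shift, "+")
    })
  }
  # CG insertion shifts row indices; locate each reference-structure row
  # in the augmented atom table by atom identity
  ref_ids <- paste(ref$atoms$chain, ref$atoms$resid, ref$atoms$name,
                   ave(seq_len(nrow(ref$atoms)),
                       paste(ref$atoms$chain, ref$atoms$resid, ref$atoms$name),
                       FUN = seq_along))
  aug_ids <- paste(atoms$chain[seq_len(n_prot_atoms)],
                   atoms$resid[seq_len(n_prot_atoms)],
                   atoms$name[seq_len(n_prot_atoms)],
                   ave(seq_len(n_prot_atoms),
                       paste(atoms$chain[seq_len(n_prot_atoms)],
                             atoms$resid[seq_len(n_prot_atoms)],
                             atoms$name[seq_len(n_prot_atoms)]),
                       FUN = seq_along))
  ref_to_aug <- match(ref_ids, aug_ids)
  n_res_total <- length(sig)
  sig_res <- as.numeric(sig)
  replicates <- vector("list", spec$n_replicates)
  for (r in seq_len(spec$n_replicates)) {
    replicates[[r]] <- withr_seed(spec$seed + r, {
      # water walk state
      wpos <- matrix(stats::runif(3 * nw), nw, 3) %*% diag(spec$box)
      # AR(1) displacement state, initialized from its stationary law
      disp <- matrix(stats::rnorm(3 * n_res_total), n_res_total, 3) * sig_res
      d_cat <- simulate_active_distance(spec$n_frames, spec$p_active,
                                        spec$active_mu, spec$active_noise_sd,
                                        spec$switch_rate)
      frames <- vector("list", spec$n_frames)
      n_total <- n_prot_atoms + 3L * nw
      for (t in seq_len(spec$n_frames)) {
        xyz <- matrix(0, n_total, 3)
        xyz[seq_len(n_prot_atoms), ] <- base_xyz
        if (!is.null(variants)) {
          v <- variants[[match(lam[t], lam_grid)]]
          rows <- (ref$block_rows[si$block] + 1L):ref$block_rows[si$block + 1L]
          xyz[ref_to_aug[rows], ] <- v
        }
        disp <- spec$ar1_rho * disp + sqrt(1 - spec$ar1_rho^2) *
          (matrix(stats::rnorm(3 * n_res_total), n_res_total, 3) * sig_res)
        xyz[seq_len(n_prot_atoms), ] <- xyz[seq_len(n_prot_atoms), ] +
          disp[sig_atom_row, , drop = FALSE]
        # catalytic distance process
        xyz[icg1, ] <- xyz[ica1, ] + cg_off
        xyz[icg2, ] <- xyz[icg1, ] + d_cat[t] * u_cat
        # waters: diffusive step, wrapped
        if (nw > 0) {
          wpos <- wpos + matrix(stats::rnorm(3 * nw, 0, 0.3), nw, 3)
          for (j in 1:3) wpos[, j] <- wpos[, j] %% spec$box[j]
          wxyz <- matrix(0, 3 * nw, 3)
          wxyz[seq(1, 3 * nw, 3), ] <- wpos
          wxyz[seq(2, 3 * nw, 3), ] <- sweep(wpos, 2, c(0.96, 0, 0), "+")
          wxyz[seq(3, 3 * nw, 3), ] <- sweep(wpos, 2, c(-0.24, 0.93, 0), "+")
          xyz[(n_prot_atoms + 1):nrow(xyz), ] <- wxyz
        }
        # global rigid-body motion about the box center
        R <- .random_rotation()
        tau <- stats::rnorm(3, 0, 2)
        ctr <- spec$box / 2
        xyz <- sweep(sweep(xyz, 2, ctr) %*% t(R), 2, ctr + tau, "+")
        frames[[t]] <- frame(xyz, box = spec$box, time = t)
      }
      trajectory(top, frames, label = sprintf("%s_rep%d", spec$mode, r))
    })
  }
  attr(replicates, "ground_truth") <- synthetic_ground_truth(spec)
  replicates
}

#' Ground-truth sidecar for a spec
#'
#' Everything a downstream metric estimates: the per-residue sigma
#' profile, the active-state occupancy, the helix schedule, the director
#' concentration and its implied S_CH (by direct Monte Carlo over the
#' von Mises-Fisher director distribution), and leaflet labels.
#'
#' @param spec a `SyntheticSpec`.
#' @param n_mc Monte Carlo draws for the expected order parameter.
#' @return list; serialize with [jsonlite::write_json()].
#' @export
synthetic_ground_truth <- function(spec, n_mc = 20000L) {
  exp_sch <- withr_seed(spec$seed + 9000L, {
    if (spec$mode == "bilayer") {
      # CH vectors are perpendicular to the director with uniform azimuth,
      # so E[P2(CH.z) | director] = -P2(director.z) / 2
      dirs <- .rvmf(n_mc, c(0, 0, 1), spec$kappa)
      mean(-0.5 * .p2(dirs[, 3]^2))
    } else {
      heads <- .rvmf(2000, c(0, 0, 1), 0)
      s <- vapply(seq_len(2000), function(i) {
        d <- .rvmf(1, -heads[i, ], spec$kappa)
        -0.5 * .p2(d[3]^2)
      }, 0)
      mean(s)
    }
  })
  list(mode = spec$mode, seed = spec$seed,
       sigma = as.list(sigma_profile(spec)),
       flexible_region = spec$flexible_region,
       helix_schedule = spec$helix_schedule,
       p_active = spec$p_active, active_mu = spec$active_mu,
       kappa = spec$kappa, expected_SCH = exp_sch,
       n_frames = spec$n_frames, n_replicates = spec$n_replicates)
}

#' Simulate the two-state catalytic distance process
#'
#' A two-state Markov chain (active state with mean `mu[1]`, inactive
#' with mean `mu[2]`, i.i.d. Gaussian within-state jitter `noise_sd`)
#' with per-frame escape probabilities `switch_rate * (1 - p_active)`
#' from the active and `switch_rate * p_active` from the inactive state,
#' giving stationary active occupancy `p_active`. With the default
#' 5-sigma separation of both means from the 7 Angstrom threshold, the
#' below-threshold occupancy equals `p_active`.
#'
#' @param n_frames series length.
#' @param p_active stationary probability of the short-distance state.
#' @param mu state means (Angstrom).
#' @param noise_sd within-state jitter (Angstrom).
#' @param switch_rate Markov switching rate parameter.
#' @param seed RNG seed (the caller's RNG state is untouched); `NULL`
#'   draws from the current stream.
#' @return numeric distance series (Angstrom).
#' @export
simulate_active_distance <- function(n_frames, p_active, mu = c(6.8, 8.5),
                                     noise_sd = 0.04, switch_rate = 0.5,
                                     seed = NULL) {
  gen <- function() {
    a12 <- switch_rate * (1 - p_active)  # escape from active
    a21 <- switch_rate * p_active        # escape from inactive
    state <- integer(0)
    s <- if (stats::runif(1) < p_active) 1L else 2L
    total <- 0L
    while (total < n_frames) {
      esc <- if (s == 1L) a12 else a21
      dwell <- if (esc <= 0) n_frames else stats::rgeom(1, esc) + 1L
      dwell <- min(dwell, n_frames - total)
      state <- c(state, rep(s, dwell))
      total <- total + dwell
      s <- 3L - s
    }
    mu[state] + stats::rnorm(n_frames, 0, noise_sd)
  }
  if (is.null(seed)) gen() else withr_seed(seed, gen())
}

# von Mises-Fisher sampler on the unit sphere (Wood 1994); kappa = 0 is
# the uniform distribution
.rvmf <- function(n, mu, kappa) {
  mu <- mu / sqrt(sum(mu^2))
  if (kappa < 1e-8) {
    w <- stats::runif(n, -1, 1)
  } else {
    u <- stats::runif(n)
    w <- 1 + log(u + (1 - u) * exp(-2 * kappa)) / kappa
  }
  v <- stats::runif(n, 0, 2 * pi)
  s <- sqrt(pmax(0, 1 - w^2))
  local <- cbind(s * cos(v), s * sin(v), w)
  R <- .rotation_onto(c(0, 0, 1), mu)
  local %*% t(R)
}

#' Generate an amphiphile (lipid/detergent) trajectory
#'
#' Bilayer mode: two leaflets on a jittered lattice, tail directors drawn
#' per lipid per frame from a von Mises-Fisher distribution about the
#' inward normal with concentration `kappa`. Micelle mode: headgroups on
#' a sphere, directors about the inward radial with low `kappa`. Tails
#' are all-trans chains along the director; each carbon carries two
#' hydrogens exactly perpendicular to the director (so the implied S_CH
#' is -0.5 times the director's P2 average, which the sidecar tabulates
#' by Monte Carlo). Deterministic given the spec seed.
#'
#' @param spec a [synthetic_spec()].
#' @param replicate replicate number (affects the seed as seed + 100 + r).
#' @return a `Trajectory` of lipid residues (chain L), with ground-truth
#'   leaflet labels as attribute `leaflets` (bilayer mode).
#' @export
generate_amphiphile_system <- function(spec, replicate = 1L) {
  nl <- spec$n_lipids
  nc <- spec$n_tail_carbons
  bx <- spec$lipid_box
  atoms_per <- 1L + 3L * nc  # P + (C, HA, HB) per carbon
  nm <- c("P", as.vector(rbind(paste0("C", seq_len(nc)),
                               paste0("H", seq_len(nc), "A"),
                               paste0("H", seq_len(nc), "B"))))
  el <- c("P", rep(c("C", "H", "H"), nc))
  atoms <- data.frame(serial = seq_len(nl * atoms_per),
                      name = rep(nm, nl), element = rep(el, nl),
                      resid = rep(seq_len(nl), each = atoms_per),
                      resname = "LIP", chain = "L", stringsAsFactors = FALSE)
  top <- topology(atoms)
  withr_seed(spec$seed + 100L + replicate, {
    if (spec$mode == "bilayer") {
      per <- nl %/% 2L
      m <- ceiling(sqrt(per))
      g <- expand.grid(i = seq_len(m) - 1, j = seq_len(m) - 1)[seq_len(per), ]
      lat <- cbind((g$i + 0.5) * bx[1] / m, (g$j + 0.5) * bx[2] / m)
      heads <- rbind(
        cbind(lat + matrix(stats::rnorm(2 * per, 0, 0.8), per, 2),
              bx[3] / 2 + 17 + stats::rnorm(per, 0, 0.5)),
        cbind(lat + matrix(stats::rnorm(2 * per, 0, 0.8), per, 2),
              bx[3] / 2 - 17 + stats::rnorm(per, 0, 0.5)))
      inward <- rbind(matrix(rep(c(0, 0, -1), each = per), per, 3),
                      matrix(rep(c(0, 0, 1), each = per), per, 3))
      leaflets <- rep(c("upper", "lower"), each = per)
    } else {
      # Fibonacci sphere of headgroups
      i <- seq_len(nl) - 0.5
      phi_g <- pi * (3 - sqrt(5)) * i
      zc <- 1 - 2 * i / nl
      rc <- sqrt(pmax(0, 1 - zc^2))
      heads <- cbind(rc * cos(phi_g), rc * sin(phi_g), zc) * 25
      heads <- sweep(heads, 2, bx / 2, "+")
      ctr <- matrix(rep(bx / 2, each = nl), nl, 3)
      inward <- (ctr - heads) / sqrt(rowSums((ctr - heads)^2))
      leaflets <- rep("unassigned", nl)
    }
    frames <- vector("list", spec$n_frames)
    half <- (109.47 / 2) * pi / 180
    for (t in seq_len(spec$n_frames)) {
      xyz <- matrix(0, nl * atoms_per, 3)
      for (l in seq_len(nl)) {
        dir <- as.numeric(.rvmf(1, inward[l, ], spec$kappa))
        # orthonormal frame perpendicular to the director
        a <- if (abs(dir[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
        e1 <- a - sum(a * dir) * dir; e1 <- e1 / sqrt(sum(e1^2))
        e2 <- c(dir[2] * e1[3] - dir[3] * e1[2],
                dir[3] * e1[1] - dir[1] * e1[3],
                dir[1] * e1[2] - dir[2] * e1[1])
        ph <- stats::runif(1, 0, 2 * pi)
        h1 <- cos(ph) * e1 + sin(ph) * e2
        h2 <- cos(ph + 2 * half) * e1 + sin(ph + 2 * half) * e2
        base <- (l - 1L) * atoms_per
        p <- heads[l, ]
        xyz[base + 1L, ] <- p
        for (k in seq_len(nc)) {
          cpos <- p + 1.25 * k * dir
          xyz[base + 1L + 3L * (k - 1L) + 1L, ] <- cpos
          xyz[base + 1L + 3L * (k - 1L) + 2L, ] <- cpos + 1.09 * h1
          xyz[base + 1L + 3L * (k - 1L) + 3L, ] <- cpos + 1.09 * h2
        }
      }
      frames[[t]] <- frame(xyz, box = bx, time = t)
    }
    traj <- trajectory(top, frames,
                       label = sprintf("%s_lipids_rep%d", spec$mode, replicate))
    attr(traj, "leaflets") <- leaflets
    traj
  })
}
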