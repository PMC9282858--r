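#' @title Hydrogen bonds and secondary structure
#' @description Amide-hydrogen reconstruction, the Kabsch-Sander
#'   electrostatic hydrogen-bond energy, geometric and energetic bond
#'   criteria, inter-strand bond counting (the hybrid beta-sheet readout),
#'   a reduced three-state DSSP-style assignment (H/E/C) and helicity
#'   series with transition detection.
#' @name memdyn-hbonds
NULL

#' Standard amide hydrogen position
#'
#' H is placed 1.01 Angstrom from N along the outward bisector of the
#' C(prev)-N-CA angle (the DSSP convention, coplanar with those atoms).
#'
#' @param c_prev,n,ca coordinates of the preceding carbonyl C, the amide N
#'   and the CA.
#' @return length-3 H coordinate.
#' @export
amide_h_position <- function(c_prev, n, ca) {
  u1 <- n - c_prev; u1 <- u1 / sqrt(sum(u1^2))
  u2 <- n - ca; u2 <- u2 / sqrt(sum(u2^2))
  b <- u1 + u2
  n + 1.01 * b / sqrt(sum(b^2))
}

#' Reconstruct backbone amide hydrogens
#'
#' Adds an atom named `H` after the `N` of every protein/substrate residue
#' that has a preceding residue (resid - 1, same chain) with a carbonyl C,
#' is not a proline, and has N and CA present. Chain N-termini and
#' prolines receive no hydrogen. Residues with missing backbone atoms are
#' skipped with a warning.
#'
#' @param top a `Topology`.
#' @param frm a `Frame` on `top`.
#' @return list(topology, frame) with the H atoms inserted.
#' @export
reconstruct_amide_hydrogens <- function(top, frm) {
  res <- top$residues
  a <- top$atoms
  newrows <- list(); newxyz <- list(); after <- integer(0)
  skipped <- 0L
  for (i in seq_len(nrow(res))) {
    if (!(a$role[res$first[i]] %in% c("protein", "substrate"))) next
    if (res$resname[i] == "PRO") next
    prev <- which(res$chain == res$chain[i] & res$resid == res$resid[i] - 1L)
    if (!length(prev)) next
    rng <- res$first[i]:res$last[i]
    iN <- rng[a$name[rng] == "N"][1]
    iCA <- rng[a$name[rng] == "CA"][1]
    prng <- res$first[prev]:res$last[prev]
    iC <- prng[a$name[prng] == "C"][1]
    if (anyNA(c(iN, iCA, iC))) { skipped <- skipped + 1L; next }
    if (any(a$name[rng] == "H")) next  # real hydrogen already present
    h <- amide_h_position(frm$xyz[iC, ], frm$xyz[iN, ], frm$xyz[iCA, ])
    k <- length(newrows) + 1L
    newrows[[k]] <- data.frame(serial = NA_integer_, name = "H", element = "H",
                               resid = res$resid[i], resname = res$resname[i],
                               chain = res$chain[i], role = a$role[res$first[i]],
                               stringsAsFactors = FALSE)
    newxyz[[k]] <- h
    after <- c(after, iN)
  }
  if (skipped) warning(skipped, " residue(s) skipped: missing backbone atoms")
  if (!length(after)) return(list(topology = top, frame = frm))
  ord <- order(after)
  after <- after[ord]; newrows <- newrows[ord]; newxyz <- newxyz[ord]
  n <- nrow(a)
  pieces <- list(); xyzp <- list()
  prevcut <- 0L
  for (k in seq_along(after)) {
    pieces[[2 * k - 1]] <- a[(prevcut + 1L):after[k], , drop = FALSE]
    xyzp[[2 * k - 1]] <- frm$xyz[(prevcut + 1L):after[k], , drop = FALSE]
    pieces[[2 * k]] <- newrows[[k]]
    xyzp[[2 * k]] <- matrix(newxyz[[k]], 1, 3)
    prevcut <- after[k]
  }
  if (prevcut < n) {
    pieces[[length(pieces) + 1]] <- a[(prevcut + 1L):n, , drop = FALSE]
    xyzp[[length(xyzp) + 1]] <- frm$xyz[(prevcut + 1L):n, , drop = FALSE]
  }
  newa <- do.call(rbind, pieces)
  newa$serial <- seq_len(nrow(newa))
  list(topology = topology(newa),
       frame = frame(do.call(rbind, xyzp), box = frm$box, time = frm$time))
}

#' Kabsch-Sander hydrogen-bond energy
#'
#' The DSSP electrostatic model:
#' E = q1 q2 (1/r_ON + 1/r_CH - 1/r_OH - 1/r_CN) * 332 kcal/mol, with
#' q1 = 0.42 e (carbonyl) and q2 = 0.20 e (amide). A bond is accepted
#' when E < -0.5 kcal/mol. Any interatomic distance below 0.5 Angstrom is
#' treated as a clash and returns +Inf (bond rejected).
#'
#' @param n,h donor backbone N and amide H coordinates.
#' @param c,o acceptor backbone C and O coordinates.
#' @return energy in kcal/mol.
#' @export
ks_energy <- function(n, h, c, o) {
  r_on <- sqrt(sum((o - n)^2)); r_ch <- sqrt(sum((c - h)^2))
  r_oh <- sqrt(sum((o - h)^2)); r_cn <- sqrt(sum((c - n)^2))
  if (min(r_on, r_ch, r_oh, r_cn) < 0.5) return(Inf)
  0.42 * 0.20 * 332 * (1 / r_on + 1 / r_ch - 1 / r_oh - 1 / r_cn)
}

.ks_cutoff <- -0.5

# per-residue backbone coordinate table for a set of residue rows;
# H is the real atom when present, else reconstructed; NULL where
# undefined (proline, chain start, missing atoms)
.backbone_table <- function(top, frm, res_rows) {
  res <- top$residues; a <- top$atoms
  n <- length(res_rows)
  get1 <- function(rng, nm) {
    i <- rng[a$name[rng] == nm][1]
    if (is.na(i)) NULL else frm$xyz[i, ]
  }
  out <- list(N = vector("list", n), CA = vector("list", n),
              C = vector("list", n), O = vector("list", n),
              H = vector("list", n),
              chain = res$chain[res_rows], resid = res$resid[res_rows],
              resname = res$resname[res_rows])
  for (k in seq_len(n)) {
    i <- res_rows[k]
    rng <- res$first[i]:res$last[i]
    put <- function(field, v) if (!is.null(v)) out[[field]][[k]] <<- v
    put("N", get1(rng, "N")); put("CA", get1(rng, "CA"))
    put("C", get1(rng, "C")); put("O", get1(rng, "O"))
    h <- get1(rng, "H")
    if (is.null(h)) h <- get1(rng, "HN")
    put("H", h)
  }
  # reconstruct missing amide H from the previous residue's carbonyl
  for (k in seq_len(n)) {
    if (!is.null(out$H[[k]]) || out$resname[k] == "PRO") next
    prev <- which(out$chain == out$chain[k] & out$resid == out$resid[k] - 1L)
    if (length(prev) != 1) next
    if (is.null(out$C[[prev]]) || is.null(out$N[[k]]) || is.null(out$CA[[k]])) next
    out$H[[k]] <- amide_h_position(out$C[[prev]], out$N[[k]], out$CA[[k]])
  }
  out
}

# TRUE when NH of residue d donates to CO of residue a
.hbond_pair <- function(bb, d, a, criterion = c("geometric", "kabsch_sander"),
                        dist_cut = 3.5, angle_cut = 135) {
  criterion <- match.arg(criterion)
  N <- bb$N[[d]]; H <- bb$H[[d]]; C <- bb$C[[a]]; O <- bb$O[[a]]
  if (is.null(N) || is.null(H) || is.null(C) || is.null(O)) return(FALSE)
  if (criterion == "kabsch_sander") return(ks_energy(N, H, C, O) < .ks_cutoff)
  r_no <- sqrt(sum((O - N)^2))
  if (r_no > dist_cut) return(FALSE)
  v1 <- N - H; v2 <- O - H
  cosang <- sum(v1 * v2) / sqrt(sum(v1^2) * sum(v2^2))
  ang <- acos(pmin(1, pmax(-1, cosang))) * 180 / pi
  ang >= angle_cut
}

#' Per-frame inter-selection hydrogen-bond count
#'
#' Counts accepted backbone hydrogen bonds between two residue groups
#' (e.g. the enzyme beta2-strand and the substrate beta3-strand of the
#' hybrid beta-sheet), in both donor directions by default. The geometric
#' criterion is donor-acceptor N...O distance <= 3.5 Angstrom and
#' N-H...O angle >= 135 degrees; the alternative is the Kabsch-Sander
#' energy with the -0.5 kcal/mol cutoff.
#'
#' @param traj a `Trajectory`.
#' @param sel_a,sel_b `Selection`s covering the two strands.
#' @param criterion `"geometric"` (default) or `"kabsch_sander"`.
#' @param direction `"both"` (default), `"a_to_b"` (A donates) or
#'   `"b_to_a"`.
#' @return a `MetricSeries` of integer counts; its mean is the
#'   per-trajectory summary aggregated across replicates elsewhere.
#' @export
hbond_count_series <- function(traj, sel_a, sel_b,
                               criterion = c("geometric", "kabsch_sander"),
                               direction = c("both", "a_to_b", "b_to_a")) {
  criterion <- match.arg(criterion)
  direction <- match.arg(direction)
  if (!length(sel_a$indices) || !length(sel_b$indices)) {
    stop("empty strand selection")
  }
  ra <- selection_residues(traj$topology, sel_a)
  rb <- selection_residues(traj$topology, sel_b)
  rows <- sort(unique(c(ra, rb)))
  ia <- match(ra, rows); ib <- match(rb, rows)
  vals <- vapply(seq_len(n_frames(traj)), function(k) {
    bb <- .backbone_table(traj$topology, traj$frames[[k]], rows)
    cnt <- 0L
    for (d in ia) for (acc in ib) {
      if (direction != "b_to_a" && .hbond_pair(bb, d, acc, criterion)) {
        cnt <- cnt + 1L
      }
    }
    for (d in ib) for (acc in ia) {
      if (direction != "a_to_b" && .hbond_pair(bb, d, acc, criterion)) {
        cnt <- cnt + 1L
      }
    }
    as.numeric(cnt)
  }, 0)
  metric_series(vals, units = "bonds", label = traj$label,
                provenance = paste(sel_a$name, "|", sel_b$name, criterion,
                                   direction))
}

#' DSSP-style three-state secondary-structure assignment
#'
#' A reduced DSSP: backbone hydrogen bonds are accepted by Kabsch-Sander
#' energy (< -0.5 kcal/mol, hydrogens reconstructed when absent); residue
#' i..i+3 are labeled `H` when two consecutive i -> i+4 turns start at
#' i-1 and i (strict alpha-helix only; 3-10 and pi turns count as coil);
#' `E` comes from parallel/antiparallel bridge patterns between
#' non-adjacent residues; everything else is `C`. Helix takes precedence
#' over strand. Consecutive residues with CA-CA above 4.5 Angstrom are
#' treated as a chain break.
#'
#' @param traj a `Trajectory`.
#' @param sel `Selection`; the assignment covers its residues plus
#'   `context` flanking residues on each side (the hydrogen-bond network
#'   is computed over that whole set, so i,i+4 turns at the region edges
#'   are seen).
#' @param context flanking residues included in the network (default 4).
#' @return object of class `SSAssignment`: a frames x residues character
#'   matrix (`codes`) plus residue metadata.
#' @export
assign_secondary_structure <- function(traj, sel, context = 4L) {
  top <- traj$topology
  rows <- selection_residues(top, sel)
  if (context > 0) {
    ext <- unique(unlist(lapply(rows, function(r) {
      (r - context):(r + context)
    })))
    ext <- ext[ext >= 1 & ext <= nrow(top$residues)]
    # keep only extensions on the same chain as some selected residue
    ext <- ext[top$residues$chain[ext] %in% unique(top$residues$chain[rows])]
    rows <- sort(unique(c(rows, ext)))
  }
  rows <- rows[top$atoms$role[top$residues$first[rows]] %in%
                 c("protein", "substrate")]
  if (!length(rows)) stop("selection touches no protein/substrate residues")
  nf <- n_frames(traj)
  codes <- matrix("C", nf, length(rows))
  for (k in seq_len(nf)) {
    bb <- .backbone_table(top, traj$frames[[k]], rows)
    codes[k, ] <- .dssp_lite(bb)
  }
  structure(list(codes = codes,
                 chain = top$residues$chain[rows],
                 resid = top$residues$resid[rows],
                 labels = residue_labels(top)[rows]),
            class = "SSAssignment")
}

# one-frame 3-state assignment from a backbone table
.dssp_lite <- function(bb) {
  n <- length(bb$N)
  if (n < 2) return(rep("C", n))
  # bonded[i]: residue i follows i-1 covalently (same chain, consecutive
  # resid, CA-CA <= 4.5)
  bonded <- rep(FALSE, n)
  for (i in 2:n) {
    bonded[i] <- bb$chain[i] == bb$chain[i - 1] &&
      bb$resid[i] == bb$resid[i - 1] + 1L &&
      !is.null(bb$CA[[i]]) && !is.null(bb$CA[[i - 1]]) &&
      sqrt(sum((bb$CA[[i]] - bb$CA[[i - 1]])^2)) <= 4.5
  }
  seg <- cumsum(!bonded)  # segment id per residue
  hb <- matrix(FALSE, n, n)  # hb[d, a]: NH of d donates to CO of a
  for (d in seq_len(n)) {
    if (is.null(bb$N[[d]]) || is.null(bb$H[[d]])) next
    for (a in seq_len(n)) {
      if (seg[d] == seg[a] && abs(bb$resid[d] - bb$resid[a]) < 2) next
      if (d == a) next
      if (is.null(bb$C[[a]]) || is.null(bb$O[[a]])) next
      hb[d, a] <- ks_energy(bb$N[[d]], bb$H[[d]], bb$C[[a]], bb$O[[a]]) < .ks_cutoff
    }
  }
  cons <- function(i, j) {
    # i..j are consecutive residues of one segment
    j >= 1 && j <= n && i >= 1 && i <= n && seg[i] == seg[j] &&
      bb$resid[j] - bb$resid[i] == j - i
  }
  turn4 <- rep(FALSE, n)
  for (i in seq_len(n)) {
    if (cons(i, i + 4) && hb[i + 4, i]) turn4[i] <- TRUE
  }
  code <- rep("C", n)
  is_h <- rep(FALSE, n)
  for (i in 2:n) {
    if (turn4[i - 1] && turn4[i] && cons(i - 1, i + 4)) {
      is_h[i:(i + 3)] <- TRUE
    }
  }
  # bridges (strand pairing) between residues >= 3 apart or on different
  # segments
  is_e <- rep(FALSE, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (j <= i) next
      if (seg[i] == seg[j] && abs(bb$resid[i] - bb$resid[j]) < 3) next
      anti <- (hb[i, j] && hb[j, i]) ||
        (cons(i - 1, i) && cons(i, i + 1) && cons(j - 1, j) && cons(j, j + 1) &&
         hb[j + 1, i - 1] && hb[i + 1, j - 1])
      para <- (cons(j - 1, j) && cons(j, j + 1) && hb[i, j - 1] && hb[j + 1, i]) ||
        (cons(i - 1, i) && cons(i, i + 1) && hb[j, i - 1] && hb[i + 1, j])
      if (anti || para) { is_e[i] <- TRUE; is_e[j] <- TRUE }
    }
  }
  code[is_e] <- "E"
  code[is_h] <- "H"
  code
}

#' Per-frame helicity of a residue region, with transition detection
#'
#' Helicity is the fraction of region residues labeled `H`. Transitions
#' are crossings of `threshold` that persist for at least `min_dwell`
#' frames on both sides.
#'
#' @param assignment an `SSAssignment`.
#' @param region `Selection` (its residues must lie within the
#'   assignment), or a character vector of residue labels.
#' @param top the `Topology` the assignment came from (needed when
#'   `region` is a `Selection`).
#' @param threshold helicity threshold for transition events (default 0.5).
#' @param min_dwell minimum frames a state must persist (default 5).
#' @return list with `series` (a `MetricSeries` in [0,1]) and
#'   `transitions` (data.frame of frame and direction).
#' @export
helicity_series <- function(assignment, region, top = NULL, threshold = 0.5,
                            min_dwell = 5L) {
  if (inherits(region, "Selection")) {
    if (is.null(top)) stop("need topology to resolve a Selection region")
    labs <- residue_labels(top)[selection_residues(top, region)]
  } else labs <- region
  cols <- match(labs, assignment$labels)
  if (anyNA(cols)) stop("region residues not in assignment: ",
                        paste(labs[is.na(cols)], collapse = ", "))
  hel <- rowMeans(assignment$codes[, cols, drop = FALSE] == "H")
  state <- hel >= threshold
  # collapse runs shorter than min_dwell into their predecessor
  r <- rle(state)
  if (length(r$lengths) > 1) {
    keep <- r$lengths >= min_dwell
    keep[1] <- TRUE
    vals <- r$values; lens <- r$lengths
    i <- 2
    while (i <= length(lens)) {
      if (lens[i] < min_dwell) {
        lens[i - 1] <- lens[i - 1] + lens[i]
        vals <- vals[-i]; lens <- lens[-i]
        if (i <= length(vals) && i > 1 && vals[i] == vals[i - 1]) {
          lens[i - 1] <- lens[i - 1] + lens[i]
          vals <- vals[-i]; lens <- lens[-i]
        }
      } else i <- i + 1
    }
    r <- list(values = vals, lengths = lens)
  }
  trans <- data.frame(frame = integer(0), direction = character(0),
                      stringsAsFactors = FALSE)
  if (length(r$lengths) > 1) {
    at <- cumsum(r$lengths)
    for (k in seq_len(length(r$lengths) - 1)) {
      trans <- rbind(trans, data.frame(
        frame = at[k] + 1L,
        direction = if (r$values[k + 1]) "coil_to_helix" else "helix_to_coil",
        stringsAsFactors = FALSE))
    }
  }
  list(series = metric_series(hel, units = "fraction",
                              provenance = "helicity"),
       transitions = trans)
}

#' Write per-frame secondary-structure strings
#'
#' One row per frame, one character per residue.
#' @param assignment an `SSAssignment`.
#' @param path output path.
#' @export
write_ss_block <- function(assignment, path) {
  writeLines(apply(assignment$codes, 1, paste, collapse = ""), path)
  invisible(path)
}
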