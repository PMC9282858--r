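# Independent oracles and shared fixtures for the test suite.

# brute-force minimum-image distance by enumerating all 27 periodic images
brute_min_image <- function(a, b, box) {
  best <- Inf
  for (i in -2:2) for (j in -2:2) for (k in -2:2) {
    d <- b + c(i, j, k) * box - a
    best <- min(best, sqrt(sum(d * d)))
  }
  best
}

# O(N^2) neighbor scan: which probes lie within cutoff of any center
brute_neighbors <- function(centers, probes, cutoff, box = NULL) {
  dm <- matrix(0, nrow(centers), nrow(probes))
  for (j in 1:3) {
    d <- outer(centers[, j], probes[, j], "-")
    if (!is.null(box)) d <- d - box[j] * round(d / box[j])
    dm <- dm + d * d
  }
  colSums(sqrt(dm) <= cutoff) > 0
}

# minimal RMSD over proper rotations found WITHOUT Kabsch: many random
# quaternion starts, each refined by Nelder-Mead over the quaternion
quaternion_rmsd_oracle <- function(mobile, reference, n_starts = 40) {
  P <- sweep(mobile, 2, colMeans(mobile))
  Q <- sweep(reference, 2, colMeans(reference))
  rot <- function(q) {
    q <- q / sqrt(sum(q^2))
    w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
    matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y + w * z), 2 * (x * z - w * y),
             2 * (x * y - w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z + w * x),
             2 * (x * z + w * y), 2 * (y * z - w * x), 1 - 2 * (x^2 + y^2)),
           3, 3)
  }
  obj <- function(q) sqrt(mean(rowSums((P %*% t(rot(q)) - Q)^2)))
  best <- Inf
  for (s in seq_len(n_starts)) {
    q0 <- stats::rnorm(4)
    r <- stats::optim(q0, obj, method = "Nelder-Mead",
                      control = list(maxit = 2000, reltol = 1e-14))
    best <- min(best, r$value)
  }
  best
}

# reference DSSP (mdtraj's internal implementation) on a topology+frame,
# as a simplified H/E/C string
mdtraj_dssp <- function(top, frm) {
  pdb <- tempfile(fileext = ".pdb")
  on.exit(unlink(pdb))
  write_pdb(top, frm, pdb)
  code <- sprintf(
    "import mdtraj as md; t = md.load('%s'); print(''.join(md.compute_dssp(t, simplified=True)[0]))",
    pdb)
  out <- system2("python", c("-c", shQuote(code)), stdout = TRUE)
  strsplit(tail(out, 1), "")[[1]]
}

# the beta-sheet fixture search is deterministic but not instant; build once
sheet_fixture <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- build_beta_sheet(6)
    cache
  }
})

# a small fast synthetic spec for unit tests; any field can be overridden
tiny_spec <- function(mode = "bilayer", ...) {
  args <- list(mode = mode, seed = 101, n_protein_residues = 60,
               n_substrate_residues = 28, flexible_region = c(31, 37),
               catalytic_resids = c(10, 40), n_waters = 40, n_lipids = 32,
               n_frames = 60, n_replicates = 2)
  dots <- list(...)
  args[names(dots)] <- dots
  do.call(synthetic_spec, args)
}

# one-carbon "lipids" with explicit CH vectors for exact S_CH checks
ch_system <- function(ch_vectors) {
  n <- nrow(ch_vectors)
  at <- data.frame(serial = NA,
                   name = rep(c("P", "C1", "H1A"), n),
                   element = rep(c("P", "C", "H"), n),
                   resid = rep(seq_len(n), each = 3), resname = "LIP",
                   chain = "L", stringsAsFactors = FALSE)
  at$serial <- seq_len(nrow(at))
  top <- topology(at)
  xyz <- matrix(0, 3 * n, 3)
  for (l in seq_len(n)) {
    base <- 10 * l
    xyz[3 * l - 2, ] <- c(base, 0, 0)
    xyz[3 * l - 1, ] <- c(base, 0, 5)
    xyz[3 * l, ] <- c(base, 0, 5) + ch_vectors[l, ]
  }
  trajectory(top, list(frame(xyz)))
}

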