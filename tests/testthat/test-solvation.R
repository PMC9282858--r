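water_system <- function(n_waters, seed, box = c(24, 24, 24)) {
  set.seed(seed)
  pep <- build_ideal_helix(10)
  at <- pep$topology$atoms
  at$role <- NULL
  w <- data.frame(serial = NA, name = rep(c("O", "H1", "H2"), n_waters),
                  element = rep(c("O", "H", "H"), n_waters),
                  resid = rep(seq_len(n_waters), each = 3), resname = "HOH",
                  chain = "W", stringsAsFactors = FALSE)
  at <- rbind(at, w)
  at$serial <- seq_len(nrow(at))
  top <- topology(at)
  wo <- matrix(runif(3 * n_waters, 0, box[1]), n_waters, 3)
  wxyz <- matrix(0, 3 * n_waters, 3)
  wxyz[seq(1, 3 * n_waters, 3), ] <- wo
  wxyz[seq(2, 3 * n_waters, 3), ] <- sweep(wo, 2, c(0.96, 0, 0), "+")
  wxyz[seq(3, 3 * n_waters, 3), ] <- sweep(wo, 2, c(-0.24, 0.93, 0), "+")
  pxyz <- sweep(pep$frame$xyz, 2, box / 2 - colMeans(pep$frame$xyz), "+")
  list(top = top, frm = frame(rbind(pxyz, wxyz), box = box))
}

brute_water_counts <- function(top, frm, res_rows, cutoff = 5) {
  a <- top$atoms
  wat <- which(a$role == "water")
  wmol <- findInterval(wat, top$residues$first)
  vapply(res_rows, function(rr) {
    rng <- top$residues$first[rr]:top$residues$last[rr]
    dm <- matrix(0, length(rng), length(wat))
    for (j in 1:3) {
      d <- outer(frm$xyz[rng, j], frm$xyz[wat, j], "-")
      d <- d - frm$box[j] * round(d / frm$box[j])
      dm <- dm + d * d
    }
    length(unique(wmol[colSums(sqrt(dm) <= cutoff) > 0]))
  }, 0)
}

test_that("a single water is counted by molecule at the 5 A boundary", {
  sys <- water_system(1, seed = 1)
  # place the water oxygen 4.9 A from the first residue's N along x
  iN <- which(sys$top$atoms$name == "N" & sys$top$atoms$resid == 1)[1]
  wo <- which(sys$top$atoms$chain == "W")
  xyz <- sys$frm$xyz
  xyz[wo[1], ] <- xyz[iN, ] + c(4.9, 0, 0)
  xyz[wo[2], ] <- xyz[wo[1], ] + c(0.96, 0, 0)
  xyz[wo[3], ] <- xyz[wo[1], ] + c(-0.24, 0.93, 0)
  tr <- trajectory(sys$top, list(frame(xyz, box = sys$frm$box)))
  sel <- resolve_selection(sys$top, "chain A and resid 1")
  expect_equal(water_accessibility(tr, sel)$mean_waters, 1)
  # all atoms beyond 5 A: zero (and still one molecule, not three atoms,
  # when closer)
  xyz[wo, ] <- sweep(xyz[wo, ], 2, c(7, 7, 7), "+")
  tr2 <- trajectory(sys$top, list(frame(xyz, box = sys$frm$box)))
  expect_equal(water_accessibility(tr2, sel)$mean_waters, 0)
})

test_that("profile equals the O(N^2) brute-force oracle exactly", {
  for (s in 1:6) {
    sys <- water_system(150, seed = 100 + s)
    tr <- trajectory(sys$top, list(sys$frm))
    sel <- resolve_selection(sys$top, "chain A")
    prof <- water_accessibility(tr, sel)
    want <- brute_water_counts(sys$top, sys$frm, seq_len(10))
    expect_identical(prof$mean_waters, as.numeric(want))
  }
})

test_that("counts are monotone in cutoff and invariant under wrap+rigid shift", {
  sys <- water_system(120, seed = 7)
  tr <- trajectory(sys$top, list(sys$frm))
  sel <- resolve_selection(sys$top, "chain A")
  m <- vapply(c(2, 3.5, 5, 6.5, 8), function(cf) {
    sum(water_accessibility(tr, sel, cutoff = cf)$mean_waters)
  }, 0)
  expect_true(all(diff(m) >= 0))
  # translate everything and wrap into the box: identical counts
  xyz <- sweep(sys$frm$xyz, 2, c(11, -5, 30), "+")
  xyz <- xyz %% matrix(sys$frm$box, nrow(xyz), 3, byrow = TRUE)
  tr2 <- trajectory(sys$top, list(frame(xyz, box = sys$frm$box)))
  expect_identical(water_accessibility(tr2, sel)$mean_waters,
                   water_accessibility(tr, sel)$mean_waters)
})

test_that("waterless systems warn and return zeros", {
  h <- build_ideal_helix(5)
  tr <- trajectory(h$topology, list(h$frame))
  sel <- resolve_selection(h$topology, "chain A")
  expect_warning(prof <- water_accessibility(tr, sel), "no waters")
  expect_equal(prof$mean_waters, rep(0, 5))
})
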