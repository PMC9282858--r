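test_that("reconstructed amide H sits 1.01 A from N; prolines get none", {
  h <- build_ideal_helix(8)
  aug <- reconstruct_amide_hydrogens(h$topology, h$frame)
  a <- aug$topology$atoms
  expect_equal(sum(a$name == "H"), 7)  # no H on the N-terminus
  for (r in 2:8) {
    iH <- which(a$resid == r & a$name == "H")
    iN <- which(a$resid == r & a$name == "N")
    expect_equal(sqrt(sum((aug$frame$xyz[iH, ] - aug$frame$xyz[iN, ])^2)),
                 1.01, tolerance = 1e-10)
  }
  # proline rule
  pro <- h$topology
  pro$atoms$resname[pro$atoms$resid == 4] <- "PRO"
  pro$residues$resname[4] <- "PRO"
  aug2 <- reconstruct_amide_hydrogens(pro, h$frame)
  expect_equal(sum(aug2$topology$atoms$name == "H"), 6)
  expect_false(any(aug2$topology$atoms$name == "H" &
                     aug2$topology$atoms$resid == 4))
})

test_that("Kabsch-Sander energy matches independent evaluation", {
  # ideal near-linear N-H...O=C geometry is strongly accepted
  n <- c(0, 0, 0); h <- c(1.01, 0, 0); o <- c(2.91, 0, 0); c_ <- c(3.9, 0.7, 0)
  e <- ks_energy(n, h, c_, o)
  expect_lt(e, -0.5)
  # distant pair has negligible energy
  expect_gt(ks_energy(n, h, c_ + c(15, 0, 0), o + c(15, 0, 0)), -0.05)
  # formula equals an independently coded evaluation on random geometry
  set.seed(31)
  for (i in 1:100) {
    N <- rnorm(3); H <- N + rnorm(3, 0, 0.5)
    C <- rnorm(3, 3); O <- C + rnorm(3, 0, 0.5)
    d <- function(a, b) sqrt(sum((a - b)^2))
    if (min(d(O, N), d(C, H), d(O, H), d(C, N)) < 0.5) next
    ref <- 27.888 * (1 / d(O, N) + 1 / d(C, H) - 1 / d(O, H) - 1 / d(C, N))
    expect_equal(ks_energy(N, H, C, O), ref, tolerance = 1e-12)
  }
  # clash guard
  expect_equal(ks_energy(n, h, c(0.2, 0, 0), o), Inf)
})

test_that("the antiparallel sheet fixture reproduces its enumerated ladder", {
  sh <- sheet_fixture()
  frames <- lapply(1:3, function(k) {
    th <- k * 0.8; ax <- c(1, 2, 3) / sqrt(14)
    K <- matrix(c(0, ax[3], -ax[2], -ax[3], 0, ax[1], ax[2], -ax[1], 0), 3, 3)
    R <- diag(3) + sin(th) * K + (1 - cos(th)) * K %*% K
    frame(sweep(sh$frame$xyz %*% t(R), 2, c(k, -k, 2 * k), "+"))
  })
  tr <- trajectory(sh$topology, frames)
  sA <- resolve_selection(sh$topology, "chain A")
  sB <- resolve_selection(sh$topology, "chain B")
  # hand enumeration on the constructed fixture: 3 strong ladder bonds per
  # direction (geometric criterion); Kabsch-Sander additionally accepts
  # the 4 marginal narrow-pair bonds
  geo <- hbond_count_series(tr, sA, sB, criterion = "geometric")
  ks <- hbond_count_series(tr, sA, sB, criterion = "kabsch_sander")
  expect_equal(geo$values, rep(6, 3))
  expect_equal(ks$values, rep(10, 3))
  # directional split: the ladder is symmetric
  ab <- hbond_count_series(tr, sA, sB, criterion = "geometric",
                           direction = "a_to_b")
  ba <- hbond_count_series(tr, sA, sB, criterion = "geometric",
                           direction = "b_to_a")
  expect_equal(ab$values + ba$values, geo$values)
  expect_equal(ab$values, rep(3, 3))
})

test_that("strands displaced far apart form no hydrogen bonds", {
  sh <- sheet_fixture()
  xyz <- sh$frame$xyz
  nb <- which(sh$topology$atoms$chain == "B")
  xyz[nb, 2] <- xyz[nb, 2] + 20
  tr <- trajectory(sh$topology, list(frame(xyz)))
  sA <- resolve_selection(sh$topology, "chain A")
  sB <- resolve_selection(sh$topology, "chain B")
  expect_equal(hbond_count_series(tr, sA, sB, "geometric")$values, 0)
  expect_equal(hbond_count_series(tr, sA, sB, "kabsch_sander")$values, 0)
})

test_that("DSSP-lite marks an ideal helix H and matches reference DSSP", {
  h <- build_ideal_helix(20)
  tr <- trajectory(h$topology, list(h$frame))
  ss <- assign_secondary_structure(tr, resolve_selection(h$topology, "all"))
  codes <- ss$codes[1, ]
  expect_gte(sum(codes == "H"), 16)
  ref <- mdtraj_dssp(h$topology, h$frame)
  expect_gte(mean(codes == ref), 0.95)
})

test_that("an isolated extended chain has no helix or strand labels", {
  s <- build_ideal_strand(14)
  tr <- trajectory(s$topology, list(s$frame))
  ss <- assign_secondary_structure(tr, resolve_selection(s$topology, "all"))
  expect_true(all(ss$codes[1, ] == "C"))
})

test_that("the sheet fixture's interior residues are labeled E", {
  sh <- sheet_fixture()
  tr <- trajectory(sh$topology, list(sh$frame))
  ss <- assign_secondary_structure(tr, resolve_selection(sh$topology, "all"))
  interior <- ss$resid %in% 3:4
  expect_true(all(ss$codes[1, interior] == "E"))
  expect_false(any(ss$codes[1, ] == "H"))
})

test_that("helicity is the H fraction and transitions follow the schedule", {
  fake <- structure(list(
    codes = matrix("H", 10, 5), chain = rep("A", 5), resid = 1:5,
    labels = paste0("A/", 1:5, "/ALA")), class = "SSAssignment")
  h1 <- helicity_series(fake, paste0("A/", 1:5, "/ALA"))
  expect_equal(h1$series$values, rep(1, 10))
  expect_equal(nrow(h1$transitions), 0)
  fake$codes[, ] <- "C"
  expect_equal(helicity_series(fake, paste0("A/", 1:5, "/ALA"))$series$values,
               rep(0, 10))

  spec <- tiny_spec("micelle", sigma_base = 0.1, flexible_sigma_factor = 1,
                    n_frames = 150, n_replicates = 1)
  tr <- generate_protein_trajectory(spec)[[1]]
  flex <- resolve_selection(tr$topology, "chain A and resid 31-37")
  ss <- assign_secondary_structure(tr, flex)
  h <- helicity_series(ss, flex, top = tr$topology)
  sched <- spec$helix_schedule
  expect_equal(nrow(h$transitions), 2)
  expect_equal(h$transitions$direction, c("helix_to_coil", "coil_to_helix"))
  # switch frames within the dwell/ramp window of the scheduled switches
  expect_lt(abs(h$transitions$frame[1] - (sched$from[2])), 8)
  expect_lt(abs(h$transitions$frame[2] - (sched$from[3])), 8)
})

test_that("hydrogen-bond counts are invariant under rigid motion and deleting i,i+4 bonds cannot raise helicity", {
  h <- build_ideal_helix(16)
  tr <- trajectory(h$topology, list(h$frame))
  all_sel <- resolve_selection(h$topology, "all")
  ss1 <- assign_secondary_structure(tr, all_sel)
  hel1 <- mean(ss1$codes == "H")
  # break the middle of the helix (extended dihedrals) and re-assign
  br <- build_peptide(16, phi = c(rep(-57, 7), rep(-139, 3), rep(-57, 6)),
                      psi = c(rep(-47, 7), rep(135, 3), rep(-47, 6)))
  ss2 <- assign_secondary_structure(trajectory(br$topology, list(br$frame)),
                                    all_sel)
  expect_lt(mean(ss2$codes == "H"), hel1)
})
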