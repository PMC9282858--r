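test_that("minimum-image distance wraps across boundaries", {
  expect_equal(minimum_image_distance(c(0, 0, 0), c(9, 0, 0), c(10, 10, 10)), 1)
  expect_equal(minimum_image_distance(c(1, 2, 3), c(1, 2, 3), c(10, 10, 10)), 0)
  expect_equal(minimum_image_distance(c(0, 0, 0), c(3, 4, 0), NULL), 5)
})

test_that("minimum-image distance equals 27-image enumeration", {
  set.seed(42)
  for (i in 1:60) {
    box <- runif(3, 5, 30)
    a <- runif(3) * box + c(-1, 0, 1) * box  # inside or one image away
    b <- runif(3) * box
    expect_equal(minimum_image_distance(a, b, box),
                 brute_min_image(a, b, box), tolerance = 1e-12)
  }
})

test_that("neighbor_count honours the cutoff boundary and empty centers", {
  q <- neighbor_query(5)
  expect_equal(neighbor_count(rbind(c(0, 0, 0)), rbind(c(4.9, 0, 0)), q), 1)
  expect_equal(neighbor_count(rbind(c(0, 0, 0)), rbind(c(5.1, 0, 0)), q), 0)
  # a probe near two centers is still one probe
  expect_equal(neighbor_count(rbind(c(0, 0, 0), c(1, 0, 0)),
                              rbind(c(0.5, 0, 0)), q), 1)
  expect_warning(n0 <- neighbor_count(matrix(0, 0, 3), rbind(c(1, 1, 1)), q),
                 "empty")
  expect_equal(n0, 0)
})

test_that("cell-list neighbor search equals the all-pairs scan exactly", {
  for (s in 1:12) {
    set.seed(s)
    box <- c(18, 22, 27)
    centers <- matrix(runif(3 * 30, -10, 40), 30, 3)
    probes <- matrix(runif(3 * 400, -10, 40), 400, 3)
    cutoff <- runif(1, 2, 7)
    q <- neighbor_query(cutoff)
    expect_identical(neighbors_within(centers, probes, q, box),
                     brute_neighbors(centers, probes, cutoff, box))
    expect_identical(neighbors_within(centers, probes, q, NULL),
                     brute_neighbors(centers, probes, cutoff, NULL))
  }
})

test_that("neighbor counts are monotone non-decreasing in the cutoff", {
  set.seed(9)
  centers <- matrix(runif(30, 0, 20), 10, 3)
  probes <- matrix(runif(600, 0, 20), 200, 3)
  counts <- vapply(seq(1, 12, by = 0.5), function(cf) {
    neighbor_count(centers, probes, neighbor_query(cf), c(20, 20, 20))
  }, 0)
  expect_true(all(diff(counts) >= 0))
})

test_that("Kabsch superposition recovers exact rigid transforms", {
  set.seed(5)
  for (i in 1:10) {
    P <- matrix(rnorm(30), 10, 3)
    q <- rnorm(4); q <- q / sqrt(sum(q^2))
    w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
    R <- matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y + w * z), 2 * (x * z - w * y),
                  2 * (x * y - w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z + w * x),
                  2 * (x * z + w * y), 2 * (y * z - w * x), 1 - 2 * (x^2 + y^2)),
                3, 3)
    Q <- sweep(P %*% t(R), 2, rnorm(3, 0, 5), "+")
    sp <- kabsch_superpose(P, Q)
    expect_lt(sp$rmsd, 1e-8)
    expect_lt(max(abs(sp$rotation - R)), 1e-8)
    expect_equal(det(sp$rotation), 1, tolerance = 1e-10)
    expect_lt(max(abs(apply_superposition(sp, P) - Q)), 1e-8)
  }
  sp0 <- kabsch_superpose(P, P)
  expect_equal(sp0$rmsd, 0, tolerance = 1e-12)
  expect_equal(sp0$rotation, diag(3), tolerance = 1e-8)
})

test_that("Kabsch RMSD matches the quaternion-optimization oracle", {
  set.seed(11)
  for (i in 1:15) {
    P <- matrix(rnorm(30), 10, 3)
    Q <- matrix(rnorm(30), 10, 3)
    expect_equal(kabsch_superpose(P, Q)$rmsd,
                 quaternion_rmsd_oracle(P, Q), tolerance = 1e-4)
  }
})

test_that("degenerate (collinear) references are rejected", {
  line <- cbind(1:5, 0, 0)
  expect_error(kabsch_superpose(line + rnorm(15, 0, 1e-14), line), "degenerate")
})

test_that("RMSD is symmetric and invariant under joint rigid motion", {
  set.seed(13)
  A <- matrix(rnorm(36), 12, 3); B <- matrix(rnorm(36), 12, 3)
  expect_equal(kabsch_superpose(A, B)$rmsd, kabsch_superpose(B, A)$rmsd,
               tolerance = 1e-10)
  th <- 0.7; R <- matrix(c(cos(th), sin(th), 0, -sin(th), cos(th), 0, 0, 0, 1), 3, 3)
  expect_equal(kabsch_superpose(A %*% t(R) + 3, B %*% t(R) + 3)$rmsd,
               kabsch_superpose(A, B)$rmsd, tolerance = 1e-10)
})

test_that("rmsd_series is zero for static or rigidly rotated trajectories", {
  h <- build_ideal_helix(10)
  th <- seq(0.1, 1, length.out = 5)
  frames <- lapply(th, function(t) {
    R <- matrix(c(cos(t), sin(t), 0, -sin(t), cos(t), 0, 0, 0, 1), 3, 3)
    frame(sweep(h$frame$xyz %*% t(R), 2, c(t, 2 * t, 0), "+"))
  })
  tr <- trajectory(h$topology, frames)
  sel <- resolve_selection(h$topology, "backbone")
  expect_lt(max(rmsd_series(tr, sel, h$frame)$values), 1e-8)
  # and per-frame values match a direct per-frame fit
  tr2 <- trajectory(h$topology, lapply(1:4, function(k) {
    frame(h$frame$xyz + matrix(rnorm(nrow(h$frame$xyz) * 3, 0, 0.2),
                               ncol = 3))
  }))
  set.seed(1)
  rs <- rmsd_series(tr2, sel, h$frame)$values
  direct <- vapply(tr2$frames, function(f) {
    kabsch_superpose(f$xyz[sel$indices, ], h$frame$xyz[sel$indices, ])$rmsd
  }, 0)
  expect_equal(rs, direct, tolerance = 1e-12)
})

test_that("superposed RMSD agrees with an independent structural library", {
  set.seed(17)
  A <- matrix(rnorm(45), 15, 3)
  B <- A + matrix(rnorm(45, 0, 0.8), 15, 3)
  ours <- kabsch_superpose(A, B)$rmsd
  fitted <- suppressWarnings(
    bio3d::fit.xyz(fixed = as.numeric(t(B)), mobile = as.numeric(t(A))))
  theirs <- bio3d::rmsd(as.numeric(t(B)), fitted)
  # bio3d reports at PDB coordinate precision
  expect_equal(ours, theirs, tolerance = 1e-3)
})
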