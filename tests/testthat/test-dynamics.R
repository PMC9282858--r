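test_that("RMSF of a static trajectory is zero everywhere", {
  h <- build_ideal_helix(15)
  tr <- trajectory(h$topology, replicate(12, h$frame, simplify = FALSE))
  sel <- resolve_selection(h$topology, "backbone")
  prof <- rmsf_profile(tr, sel, window = 1.0)
  expect_equal(prof$values, rep(0, 15), tolerance = 1e-10)
})

test_that("RMSF is invariant under per-frame global rigid motion", {
  set.seed(21)
  h <- build_ideal_helix(15)
  n <- nrow(h$frame$xyz)
  jitters <- lapply(1:40, function(k) matrix(rnorm(3 * n, 0, 0.4), n, 3))
  plain <- lapply(jitters, function(j) frame(h$frame$xyz + j))
  moved <- lapply(jitters, function(j) {
    th <- runif(1, 0, 2 * pi); ax <- rnorm(3); ax <- ax / sqrt(sum(ax^2))
    K <- matrix(c(0, ax[3], -ax[2], -ax[3], 0, ax[1], ax[2], -ax[1], 0), 3, 3)
    R <- diag(3) + sin(th) * K + (1 - cos(th)) * K %*% K
    frame(sweep((h$frame$xyz + j) %*% t(R), 2, rnorm(3, 0, 8), "+"))
  })
  sel <- resolve_selection(h$topology, "backbone")
  p1 <- rmsf_profile(trajectory(h$topology, plain), sel, window = 1.0)
  p2 <- rmsf_profile(trajectory(h$topology, moved), sel, window = 1.0)
  expect_equal(p1$values, p2$values, tolerance = 1e-6)
})

test_that("isotropic jitter gives RMSF near sigma*sqrt(3)", {
  set.seed(22)
  h <- build_ideal_helix(20)
  n <- nrow(h$frame$xyz)
  sigma <- 0.5
  frames <- lapply(1:800, function(k) {
    frame(h$frame$xyz + matrix(rnorm(3 * n, 0, sigma), n, 3))
  })
  sel <- resolve_selection(h$topology, "backbone")
  prof <- rmsf_profile(trajectory(h$topology, frames), sel, window = 1.0)
  expect_equal(mean(prof$values), sigma * sqrt(3), tolerance = 0.05)
})

test_that("an amplified region is localized in the RMSF profile", {
  spec <- tiny_spec(flexible_sigma_factor = 3, n_frames = 400,
                    n_replicates = 1, n_waters = 0)
  tr <- generate_protein_trajectory(spec)[[1]]
  sel <- resolve_selection(tr$topology, "chain A and backbone")
  prof <- rmsf_profile(tr, sel, window = 1.0)
  resid <- as.integer(sub("^A/([0-9]+)/.*", "\\1", prof$labels))
  inside <- resid >= 31 & resid <= 37
  expect_gt(min(prof$values[inside]), max(prof$values[!inside]))
})

test_that("windows shorter than 10 frames are rejected", {
  h <- build_ideal_helix(6)
  tr <- trajectory(h$topology, replicate(12, h$frame, simplify = FALSE))
  sel <- resolve_selection(h$topology, "backbone")
  expect_error(rmsf_profile(tr, sel, window = 1:5), "10 frames")
})

test_that("distance series report minimum-image atom-pair distances", {
  sp <- tiny_spec(n_frames = 30, n_replicates = 1)
  tr <- generate_protein_trajectory(sp)[[1]]
  ds <- distance_series(tr, distance_spec("chain A and resid 10 and name CG",
                                          "chain A and resid 40 and name CG"))
  direct <- vapply(tr$frames, function(f) {
    ia <- which(tr$topology$atoms$chain == "A" &
                tr$topology$atoms$resid == 10 & tr$topology$atoms$name == "CG")
    ib <- which(tr$topology$atoms$chain == "A" &
                tr$topology$atoms$resid == 40 & tr$topology$atoms$name == "CG")
    brute_min_image(f$xyz[ia, ], f$xyz[ib, ], f$box)
  }, 0)
  expect_equal(ds$values, direct, tolerance = 1e-10)
  expect_error(distance_series(tr, distance_spec("chain A and name CG",
                                                 "chain A and resid 40 and name CG")),
               "exactly 1")
})

test_that("PBC wrap is respected for pairs straddling the boundary", {
  at <- data.frame(serial = 1:2, name = "CG", element = "C", resid = 1:2,
                   resname = "ASP", chain = "A", stringsAsFactors = FALSE)
  top <- topology(at)
  f <- frame(rbind(c(0.5, 5, 5), c(9.5, 5, 5)), box = c(10, 10, 10))
  tr <- trajectory(top, list(f))
  ds <- distance_series(tr, distance_spec("resid 1 and name CG",
                                          "resid 2 and name CG"))
  expect_equal(ds$values, 1.0)
})

test_that("fraction_below uses a strict threshold and complements to 1", {
  expect_equal(fraction_below(rep(6.8, 50), 7.0)$fraction, 1.0)
  expect_equal(fraction_below(rep(7.5, 50), 7.0)$fraction, 0.0)
  expect_equal(fraction_below(rep(7.0, 50), 7.0)$fraction, 0.0)  # tie above
  set.seed(3)
  x <- rnorm(500, 7, 0.5)
  fb <- fraction_below(x, 7.0)
  above <- mean(x >= 7.0)
  expect_equal(fb$fraction + above, 1.0)
  expect_true(fb$ci[1] <= fb$fraction && fb$fraction <= fb$ci[2])
})

test_that("block-bootstrap CI covers the truth for the Markov process", {
  hits <- 0L
  for (s in 1:10) {
    d <- simulate_active_distance(3000, 0.7, seed = s)
    fb <- fraction_below(d, 7.0, seed = s)
    if (fb$ci[1] <= 0.7 && 0.7 <= fb$ci[2]) hits <- hits + 1L
  }
  expect_gte(hits, 8)
})

test_that("histograms are probability-normalized", {
  expect_equal(metric_histogram(rep(3.14, 100), 0.25)$density, 4)
  set.seed(4)
  u <- runif(20000)
  hst <- metric_histogram(u, 0.1)
  expect_equal(sum(hst$density * 0.1), 1.0, tolerance = 1e-12)
  expect_equal(hst$density[hst$mid > 0 & hst$mid < 1], rep(1, 10),
               tolerance = 0.05)
  x <- rnorm(500, 7, 1)
  h2 <- metric_histogram(x, 0.2)
  expect_equal(sum(h2$density * 0.2), 1.0, tolerance = 1e-12)
})

test_that("replicate aggregation is the SD of per-replicate means", {
  expect_equal(aggregate_replicates(c(1, 1, 1)),
               list(mean = 1, sd_of_mean = 0))
  expect_equal(aggregate_replicates(c(1, 2, 3)),
               list(mean = 2, sd_of_mean = 1))
  set.seed(6)
  for (i in 1:5) {
    v <- rnorm(4, 10, 2)
    agg <- aggregate_replicates(as.list(v))
    expect_equal(agg$mean, mean(v))
    expect_equal(agg$sd_of_mean, sd(v))
  }
  p1 <- residue_profile(c("A/1/ALA", "A/2/ALA"), c(1, 4))
  p2 <- residue_profile(c("A/1/ALA", "A/2/ALA"), c(3, 8))
  agg <- aggregate_replicates(list(p1, p2))
  expect_equal(agg$mean, c(2, 6))
  expect_equal(agg$sd_of_mean, c(sd(c(1, 3)), sd(c(4, 8))))
  p3 <- residue_profile(c("A/9/ALA", "A/2/ALA"), c(0, 0))
  expect_error(aggregate_replicates(list(p1, p3)), "mismatch")
})
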