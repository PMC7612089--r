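# A simple planar-ish dead-reckoned track builder for correction tests.
dr_track <- function(headings, speeds, start = c(0, 0), t0 = 0) {
  tv <- travel_vectors(t0 + seq_along(headings) - 1, headings, speeds)
  integrate_track(start, tv)
}

test_that("VPs are matched to the nearest sample within half a step", {
  tr <- dr_track(rep(0, 100), rep(1, 100))
  vp <- geo_track(c(0, 50, 100), tr$lat[c(1, 51, 101)], tr$lon[c(1, 51, 101)],
                  kind = "verified")
  m <- time_match(tr, vp)
  expect_equal(m$sample, c(1, 51, 101))
  # 0.4 dt from a sample still matches the nearest sample
  vp <- geo_track(50.4, tr$lat[51], tr$lon[51], kind = "verified")
  expect_equal(time_match(tr, vp)$sample, 51)
  # a VP during a logger gap is skipped and counted
  vp <- geo_track(c(50, 200.7), c(0, 0), c(0, 0), kind = "verified")
  m <- time_match(tr, vp)
  expect_equal(nrow(m), 1)
  expect_equal(attr(m, "skipped"), 1)
  expect_error(time_match(tr, geo_track(999.7, 0, 0, kind = "verified")), "no VP")
})

test_that("thinning keeps the first fix, the spacing rule, and the final fix", {
  vp <- geo_track(0:3600, rep(0, 3601), seq(0, 0.36, by = 1e-4), kind = "verified")
  th <- thin_vps(vp, 3600)
  expect_equal(nrow(th), 2)
  expect_equal(th$t, c(0, 3600))
  expect_equal(nrow(thin_vps(vp, 1)), 3601)     # interval <= spacing keeps all
  expect_equal(nrow(thin_vps(vp, 600)), 7)
  # a dropout longer than the interval: the next available fix is kept
  tt <- c(0:10, 7200 + 0:10)
  vp <- geo_track(tt, rep(0, 22), seq_along(tt) * 1e-4, kind = "verified")
  th <- thin_vps(vp, 3600)
  expect_true(7200 %in% th$t)
  expect_equal(th$t[1], 0)
})

test_that("segment factors are the beeline ratio and bearing difference", {
  f <- segment_factors(c(0, 0), c(0.01, 0.01), c(0, 0), c(0.01, 0.01))
  expect_equal(f$dcf, 1, tolerance = 1e-12)
  expect_equal(f$hcf, 0, tolerance = 1e-12)
  expect_false(f$degenerate)
  # DR 100 m north, VP 300 m east: dcf 3, hcf +90
  dr_end <- forward_step(0, 0, 0, 100)
  vp_end <- forward_step(0, 0, 90, 300)
  f <- segment_factors(c(0, 0), c(dr_end$lat, dr_end$lon),
                       c(0, 0), c(vp_end$lat, vp_end$lon))
  expect_equal(f$dcf, 3, tolerance = 1e-9)
  expect_equal(f$hcf, 90, tolerance = 1e-9)
  f <- segment_factors(c(0, 0), c(0, 0), c(0, 0), c(0.01, 0))
  expect_true(f$degenerate)
  expect_true(is.na(f$dcf))
})

test_that("a track already through the VPs is left unchanged", {
  set.seed(31)
  tr <- dr_track(cumsum(rnorm(300, sd = 5)) %% 360, runif(300, 0.5, 1.5))
  vp <- geo_track(tr$t[c(1, 101, 201, 301)], tr$lat[c(1, 101, 201, 301)],
                  tr$lon[c(1, 101, 201, 301)], kind = "verified")
  out <- correct_track(tr, vp)
  expect_equal(out$track$lat, tr$lat, tolerance = 1e-12)
  expect_equal(out$track$lon, tr$lon, tolerance = 1e-12)
  expect_equal(out$report$segments$dcf, rep(1, 3), tolerance = 1e-9)
  expect_equal(out$report$segments$hcf, rep(0, 3), tolerance = 1e-9)
  ne <- net_error(out$track, vp)
  expect_lt(max(ne$error_m), 1e-6)
})

test_that("corrected anchors land on their VPs within the residual tolerance", {
  set.seed(32)
  n <- 1800
  tr <- dr_track(cumsum(rnorm(n, sd = 3)) %% 360, runif(n, 0.5, 2), start = c(-40, 10))
  # pretend truth differs: rotate and scale the VPs relative to the track
  anchors <- seq(1, n + 1, by = 300)
  vp <- geo_track(tr$t[anchors],
                  tr$lat[anchors] + seq_along(anchors) * 2e-4,
                  tr$lon[anchors] - seq_along(anchors) * 1.5e-4,
                  kind = "verified")
  out <- correct_track(tr, vp)
  m <- time_match(out$track, vp)
  gap <- haversine(vp$lat, vp$lon, out$track$lat[m$sample], out$track$lon[m$sample])
  bee <- out$report$segments$vp_beeline_m
  expect_true(all(gap[-1] <= pmax(0.01, 1e-4 * bee)))
  expect_lt(gap[1], 1e-6)
})

test_that("an injected heading bias is recovered as the negated hcf", {
  cfg <- sim_preset("land_walker", seed = 7, duration_s = 3600)
  truth <- simulate_truth(cfg)
  vps <- simulate_vps(truth)
  start <- c(truth$track$lat[1], truth$track$lon[1], 0)
  tv <- travel_vectors_from_truth(truth, heading_bias = 15)
  dr <- integrate_track(start, tv)
  out <- correct_track(dr, thin_vps(vps, 600))
  hcf <- out$report$segments$hcf
  expect_true(all(abs(hcf + 15) <= 1))
  # anchors coincide with the VPs
  expect_lt(max(out$report$segments$residual_m), 0.01)
})

test_that("a speed scale error k is recovered as dcf = 1/k", {
  cfg <- sim_preset("land_walker", seed = 8, duration_s = 3600)
  truth <- simulate_truth(cfg)
  vps <- simulate_vps(truth)
  start <- c(truth$track$lat[1], truth$track$lon[1], 0)
  for (k in c(0.5, 2)) {
    tv <- travel_vectors_from_truth(truth, speed_scale = k)
    dr <- integrate_track(start, tv)
    out <- correct_track(dr, thin_vps(vps, 600))
    dcf <- out$report$segments$dcf
    expect_true(all(abs(dcf * k - 1) <= 0.01))
  }
})

test_that("stationary clusters stay point-coincident through correction", {
  headings <- rep(45, 400)
  speeds <- c(rep(1, 150), rep(0, 100), rep(1, 150))
  tr <- dr_track(headings, speeds)
  # VPs displaced so a real correction happens
  anchors <- c(1, 401)
  vp <- geo_track(tr$t[anchors], tr$lat[anchors] * 1.3 + 0.001,
                  tr$lon[anchors] * 0.8, kind = "verified")
  out <- correct_track(tr, vp)
  idx <- 151:251   # positions during the zero-speed block
  expect_equal(diff(out$track$lat[idx]), rep(0, 100))
  expect_equal(diff(out$track$lon[idx]), rep(0, 100))
  f <- out$report$segments
  expect_false(f$degenerate[1])
  expect_gt(abs(f$hcf[1]), 1e-6)   # a non-trivial rotation was applied
})

test_that("correction is idempotent", {
  set.seed(33)
  tr <- dr_track(cumsum(rnorm(600, sd = 4)) %% 360, runif(600, 0.5, 2))
  anchors <- seq(1, 601, by = 100)
  vp <- geo_track(tr$t[anchors], tr$lat[anchors] + 1e-3, tr$lon[anchors] - 2e-3,
                  kind = "verified")
  once <- correct_track(tr, vp)
  twice <- correct_track(once$track, vp)
  expect_equal(twice$report$segments$dcf, rep(1, 6), tolerance = 1e-6)
  expect_equal(twice$report$segments$hcf, rep(0, 6), tolerance = 1e-6)
})

test_that("within-segment turn angles are preserved by the correction", {
  set.seed(34)
  tr <- dr_track(cumsum(rnorm(300, sd = 10)) %% 360, runif(300, 0.5, 2))
  anchors <- c(1, 301)
  vp <- geo_track(tr$t[anchors], tr$lat[anchors] + 2e-3, tr$lon[anchors] + 1e-3,
                  kind = "verified")
  out <- correct_track(tr, vp)
  turn <- function(g) {
    b <- initial_bearing(g$lat[-nrow(g)], g$lon[-nrow(g)], g$lat[-1], g$lon[-1])
    wrap_angle(diff(b))
  }
  expect_equal(turn(out$track), turn(tr), tolerance = 0.1)
})

test_that("degenerate segments snap their endpoint to the VP", {
  tr <- dr_track(rep(0, 200), c(rep(1, 100), rep(0, 100)))
  # second half has no displacement; put the end VP elsewhere
  anchors <- c(1, 101, 201)
  endp <- forward_step(tr$lat[201], tr$lon[201], 90, 50)
  vp <- geo_track(tr$t[anchors],
                  c(tr$lat[1], tr$lat[101], endp$lat),
                  c(tr$lon[1], tr$lon[101], endp$lon), kind = "verified")
  out <- correct_track(tr, vp)
  s <- out$report$segments
  expect_true(s$degenerate[2])
  expect_equal(s$residual_m[2], 50, tolerance = 0.01)
  expect_lt(haversine(out$track$lat[201], out$track$lon[201], endp$lat, endp$lon), 1e-6)
  # the stationary cluster itself was not spread out
  expect_equal(diff(out$track$lat[101:200]), rep(0, 99))
})
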