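test_that("sprout seeds respect the excluded margins and the profile", {
  x <- seq(0, 100, 0.5)
  rho <- sprout_init_density(x)
  expect_true(all(rho[x <= 14 | x >= 86] == 0))
  expect_true(all(rho[x > 14 & x < 86] > 0))
  # 10^4 seeded draws match the truncated normal by chi-square
  lat <- make_lattice(50, 50, 50)
  set.seed(12)
  ang <- angio_state(lat)
  xs <- integer(0)
  for (i in 1:1250) {
    ang2 <- init_sprouts(angio_state(lat), lat, n = 8)
    xs <- c(xs, ang2$tips$x)
  }
  # no seed ever lands in the margins (sites 8..42 on a 50-column axis)
  expect_true(all(xs >= 8 & xs <= 42))
  # chi-square against the exact discretized truncated normal: site k
  # collects the normal mass of its rounding preimage (2k - 1, 2k + 1]
  sites <- 8:42
  pk <- pnorm(pmin(2 * sites + 1, 86), 50, 12) -
    pnorm(pmax(2 * sites - 1, 14), 50, 12)
  pk <- pk / sum(pk)
  obs <- table(factor(xs, levels = sites))
  keep <- pk * length(xs) >= 5
  o <- as.numeric(obs[keep]); q <- pk[keep]
  if (any(!keep)) { o <- c(o, sum(obs[!keep])); q <- c(q, sum(pk[!keep])) }
  p <- suppressWarnings(chisq.test(o, p = q / sum(q))$p.value)
  expect_gt(p, 0.01)
})

test_that("the onset flag latches one-way at the critical diameter", {
  lat <- make_lattice(20, 20, 20)
  ang <- angio_state(lat)
  ang <- maybe_start_angiogenesis(ang, diameter_mm = 1)
  expect_false(ang$onset)
  ang <- maybe_start_angiogenesis(ang, diameter_mm = 2.1)
  expect_true(ang$onset)
  ang <- maybe_start_angiogenesis(ang, diameter_mm = 0.5)
  expect_true(ang$onset) # regression does not reverse it
})

test_that("tips random-walk without a gradient and climb a strong one", {
  lat <- make_lattice(30, 30, 30)
  # uniform VEGF: zero mean displacement over many seeded steps
  set.seed(20)
  vegf <- array(1, lat$dims)
  disp <- replicate(400, {
    ang <- angio_state(lat)
    # start in the domain interior so walls cannot bias the walk
    ang$tips <- data.frame(id = 1L, x = 15L, y = 15L, z = 15L, age_h = 0,
                           active = TRUE, steps = 0L)
    ang$vessel_id[15, 15, 15] <- 1L
    y0 <- ang$tips$y
    for (k in 1:6)
      ang <- tip_step(ang, vegf, lat, p_move = 1, lambda = 50,
                      noise_sd = 0.05)$angio
    ang$tips$y - y0
  })
  expect_lt(abs(mean(disp)) / 6, 0.12) # near-zero drift per step
  # strong linear gradient with vanishing noise: strictly monotone approach
  grad <- array(0, lat$dims)
  for (y in 1:30) grad[, y, ] <- y / 30
  ang <- angio_state(lat)
  ang <- init_sprouts(ang, lat, n = 1)
  ys <- ang$tips$y
  for (k in 1:15) {
    ang <- tip_step(ang, grad, lat, p_move = 1, lambda = 100,
                    noise_sd = 1e-9)$angio
    ys <- c(ys, ang$tips$y)
  }
  expect_true(all(diff(ys) > 0))
})

test_that("branching is gated by the 18-h age and monotone in TAF", {
  lat <- make_lattice(20, 20, 20)
  vegf <- array(5, lat$dims)
  set.seed(3)
  ang <- init_sprouts(angio_state(lat), lat, n = 4)
  ang$tips$age_h <- 10
  ang2 <- branch_sprouts(ang, vegf, lat, c_taf = 100)
  expect_equal(nrow(ang2$tips), 4L) # under-age tips never branch
  ang$tips$age_h <- 18
  ang3 <- branch_sprouts(ang, vegf, lat, c_taf = 100)
  expect_gt(nrow(ang3$tips), 4L)
  expect_true(all(ang3$tips$age_h[ang3$tips$id %in% ang$tips$id] == 0))
  # zero TAF with zero basal floor: never branches
  ang4 <- branch_sprouts(ang, array(0, lat$dims), lat, c_taf = 100,
                         basal = 0)
  expect_equal(nrow(ang4$tips), 4L)
})

test_that("anastomosis closes loops but never with a sprout's own trail", {
  lat <- make_lattice(12, 12, 12)
  ang <- angio_state(lat)
  # construct two sprouts; put tip 2 onto sprout 1's trail
  ang$tips <- data.frame(id = c(1L, 2L), x = c(5L, 5L), y = c(5L, 5L),
                         z = c(5L, 6L), age_h = 0, active = TRUE,
                         steps = 0L)
  ang$vessel_id[5, 5, 5] <- 1L
  ang$vessel_id[5, 5, 6] <- 2L
  moved <- anastomose(ang, lat)
  expect_true(all(moved$tips$active)) # separate trails: both stay active
  ang$tips$x[2] <- 5L; ang$tips$y[2] <- 5L; ang$tips$z[2] <- 5L
  merged <- anastomose(ang, lat)
  expect_false(merged$tips$active[2])
  expect_true(merged$tips$active[1]) # standing on its own trail is fine
  # a tip cannot revisit its own path: with a single open neighbor being
  # its own trail, the move is blocked and the tip stalls
  ang2 <- angio_state(lat)
  ang2$tips <- data.frame(id = 1L, x = 2L, y = 2L, z = 2L, age_h = 0,
                          active = TRUE, steps = 0L)
  region <- lat$region
  lat2 <- lat
  lat2$region[] <- hmsm:::REGION_VOID
  lat2$region[2, 2, 2] <- hmsm:::REGION_TUMOR
  lat2$region[3, 2, 2] <- hmsm:::REGION_TUMOR
  ang2$vessel_id[3, 2, 2] <- 1L # own trail on the only open neighbor
  set.seed(1)
  out <- tip_step(ang2, array(1, lat$dims), lat2, p_move = 1)
  expect_equal(out$angio$tips$x, 2L)
  expect_gt(out$angio$tips$age_h, 0)
})

test_that("the vessel network export has the documented schema", {
  lat <- make_lattice(20, 20, 20)
  set.seed(5)
  ang <- init_sprouts(angio_state(lat), lat, n = 3)
  ang <- tip_step(ang, array(1, lat$dims), lat, p_move = 1)$angio
  f <- tempfile(fileext = ".csv")
  write_vessels_csv(ang, f)
  df <- utils::read.csv(f)
  expect_equal(names(df), c("sprout_id", "step", "x", "y", "z", "active"))
  expect_true(all(df$sprout_id %in% 1:3))
})
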