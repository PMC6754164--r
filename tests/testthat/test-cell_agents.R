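mini_world <- function(n = 7) {
  occ <- array(0L, c(n, n, n))
  region <- array(hmsm:::REGION_TUMOR, c(n, n, n))
  list(occ = occ, region = region)
}

test_that("placement proposals honour exclusion and the dispersal weights", {
  w <- mini_world()
  center <- hmsm:::lin_idx(4, 4, 4, dim(w$occ))
  # fully occupied neighborhood: no proposal
  occ <- w$occ
  k <- 0L
  for (dx in -1:1) for (dy in -1:1) for (dz in -1:1) {
    k <- k + 1L
    occ[4 + dx, 4 + dy, 4 + dz] <- k
  }
  type <- rep(hmsm:::TYPE_PC, k)
  expect_null(propose_placement(center, 1L, occ, w$region, type))
  # exactly one empty candidate: that site is proposed, acceptance = M
  occ2 <- occ
  occ2[5, 4, 4] <- 0L
  pr <- propose_placement(center, 1L, occ2, w$region, type)
  expect_equal(pr$site, hmsm:::lin_idx(5, 4, 4, dim(occ2)))
  expect_lte(pr$accept, 1)
  # |d| = 1 is proposed more often than |d| = 2 at equal occupancy; the
  # empirical frequency matches the exact normalized weights
  occ3 <- w$occ
  occ3[center] <- 1L
  type3 <- hmsm:::TYPE_PC
  region3 <- w$region
  # block everything except two candidates at distance 1 and 2 along +x
  region3[] <- hmsm:::REGION_VOID
  region3[4, 4, 4] <- hmsm:::REGION_TUMOR
  region3[5, 4, 4] <- hmsm:::REGION_TUMOR
  region3[6, 4, 4] <- hmsm:::REGION_TUMOR
  set.seed(11)
  picks <- replicate(1e4, propose_placement(center, 2L, occ3, region3,
                                            type3)$site)
  near <- hmsm:::lin_idx(5, 4, 4, dim(occ3))
  pr1 <- propose_placement(center, 2L, occ3, region3, type3)
  wgt <- pr1$weights[match(near, pr1$sites)]
  phat <- mean(picks == near)
  expect_gt(phat, 0.5) # nearer candidate wins more often
  expect_lt(abs(phat - wgt), 3 * sqrt(wgt * (1 - wgt) / 1e4))
})

test_that("tumor-cell probabilities respond to androgen and ligands", {
  cfg <- hmsm_config()
  sig <- list(params = as_ode_params(cfg$signaling$params),
              basal = cfg$signaling$basal)
  pre <- pc_step_probs(0, 0, 1.0, FALSE, FALSE, cfg$pc, sig)
  cast <- pc_step_probs(0, 0, 0.2, FALSE, FALSE, cfg$pc, sig)
  # androgen-dependent cells at castrate androgen die faster than baseline
  expect_gt(cast$p_die, pre$p_die)
  expect_lt(cast$p_div, pre$p_div)
  # resistant cells restore androgen-receptor signaling autonomously
  res <- pc_step_probs(0, 0, 0.2, TRUE, FALSE, cfg$pc, sig)
  expect_lt(res$p_die, cast$p_die)
  # WNT5A dose monotonicity flows through the signaling module
  lo <- pc_step_probs(0, 0, 0.2, FALSE, FALSE, cfg$pc, sig)
  hi <- pc_step_probs(1, 0, 0.2, FALSE, FALSE, cfg$pc, sig)
  expect_gte(hi$p_div, lo$p_div)
  # a perivascular cell proliferates faster
  vasc <- pc_step_probs(0, 0, 1, FALSE, TRUE, cfg$pc, sig)
  expect_gt(vasc$p_div, pre$p_div)
})

test_that("fate decisions demote space-less divisions", {
  set.seed(3)
  acts <- replicate(2000, pc_decide(p_div = 1, p_die = 0, p_mig = 0.5,
                                    has_space = FALSE))
  expect_true(all(acts %in% c("migrate", "quiesce")))
  expect_true(all(replicate(50, pc_decide(0, 1, 0)) == "die"))
  expect_true(all(replicate(50, pc_decide(1, 0, 0, TRUE)) == "divide"))
})

test_that("resistance switching ramps from zero and hits the 2-week window", {
  expect_equal(pc_resistance_switch_prob(-5), 0)
  expect_equal(pc_resistance_switch_prob(0), 0)
  p1 <- pc_resistance_switch_prob(100)
  p2 <- pc_resistance_switch_prob(336)
  p3 <- pc_resistance_switch_prob(1000)
  expect_true(p1 < p2)
  expect_equal(p2, p3) # capped after the ramp
  # Monte-Carlo cohort under castrate conditions: androgen-dependent cells
  # die at the castrate rate while resistant cells are rescued by autonomous
  # DHT synthesis; the median time for a 200-cell cohort to become >50%
  # resistant lies in the 11-17 day window (the model's 2-week
  # androgen-receptor reactivation)
  cfg <- hmsm_config()$pc
  h0 <- hill_activation(1, cfg$h_ad)
  d_ad <- cfg$p_die0 +
    cfg$p_die_castrate * (1 - hill_activation(0.2, cfg$h_ad) / h0)
  d_res <- cfg$p_die0 +
    cfg$p_die_castrate * (1 - hill_activation(cfg$a_auto, cfg$h_ad) / h0)
  set.seed(99)
  t50 <- replicate(50, {
    res <- rep(FALSE, 200); alive <- rep(TRUE, 200); t <- 0
    repeat {
      t <- t + 2
      p <- pc_resistance_switch_prob(t, cfg$switch_rate, cfg$switch_ramp_h)
      sw <- !res & alive & runif(200) < p
      res[sw] <- TRUE
      idx <- which(alive)
      d <- ifelse(res[idx], d_res, d_ad)
      alive[idx[runif(length(idx)) < d]] <- FALSE
      if (!any(alive)) { t <- NA; break } # rare extinct cohort
      if (mean(res[alive]) > 0.5) break
    }
    t / 24
  })
  expect_gte(median(t50, na.rm = TRUE), 11)
  expect_lte(median(t50, na.rm = TRUE), 17)
})

test_that("macrophage, CTL and Treg rate laws honour their blockades", {
  cfg <- hmsm_config()
  # CSF1 = 0: basal recruitment only; full CSF1R blockade removes the
  # CSF1-driven term exactly; doubling CSF1 never decreases the rate
  expect_equal(tam_division_prob(0, cfg$tam), cfg$tam$p_div_basal)
  cs <- seq(0, 5, 0.5)
  expect_true(all(diff(tam_division_prob(cs, cfg$tam)) >= 0))
  expect_equal(tam_division_prob(cs, cfg$tam, plx_efficacy = 1),
               rep(cfg$tam$p_div_basal, length(cs)))
  # suppressed CTLs cannot kill; IL10 reduces killing monotonically
  expect_equal(ctl_kill_prob(2, cfg$ctl, suppressed = TRUE), 0)
  il <- seq(0, 5, 0.5)
  expect_true(all(diff(ctl_kill_prob(il, cfg$ctl)) <= 0))
  # anti-IL-2 at full efficacy zeroes the IL-2 term of Treg division
  base <- treg_division_prob(0, 0, cfg$treg)
  with_il2 <- treg_division_prob(0, 10, cfg$treg)
  expect_gt(with_il2, base)
  expect_equal(treg_division_prob(0, 10, cfg$treg, anti_il2_efficacy = 1),
               base)
  tr <- seq(0, 5, 0.5)
  expect_true(all(diff(treg_division_prob(tr, 0, cfg$treg)) >= 0))
})

test_that("the compiled sweep preserves exclusion and kills on contact", {
  # CTL adjacent to one PC with certain kill probability: the PC dies
  w <- mini_world(5)
  a <- agents_new()
  pc_site <- hmsm:::lin_idx(3, 3, 3, dim(w$occ))
  ctl_site <- hmsm:::lin_idx(4, 3, 3, dim(w$occ))
  i1 <- agents_append(a, hmsm:::TYPE_PC, pc_site)
  i2 <- agents_append(a, hmsm:::TYPE_CTL, ctl_site, effector = TRUE)
  occ <- w$occ; occ[pc_site] <- i1; occ[ctl_site] <- i2
  set.seed(1)
  res <- cpp_agents_step(occ, w$region, a$type, a$site,
                         as.integer(a$alive), as.integer(a$effector),
                         as.integer(a$suppressed), c(i2, i1),
                         p_die = c(0, 0), p_div = c(0, 0), p_mig = c(0, 0),
                         p_kill = c(0, 1), chemo_type = c(0L, 1L),
                         chemo_w = c(0, 0), grad_a = numeric(125),
                         grad_gamma_a = c(0, 0), grad_b = numeric(125),
                         grad_gamma_b = c(0, 0), grad_sel = c(0L, 0L),
                         5L, 5L, 5L, 0L, 0, matrix(1, 4, 4))
  expect_equal(res$alive, c(0L, 1L))
  expect_equal(res$pc_deaths, 1L)
  # exclusion after heavy churn: one id per site, ids consistent
  set.seed(42)
  w <- mini_world(9)
  a <- agents_new()
  sites <- sample(which(w$region == hmsm:::REGION_TUMOR), 60)
  idx <- agents_append(a, hmsm:::TYPE_PC, sites)
  occ <- w$occ; occ[sites] <- idx
  for (step in 1:30) {
    n <- length(a$type)
    ord <- which(a$alive)
    ord <- ord[sample.int(length(ord))]
    res <- cpp_agents_step(occ, w$region, a$type, a$site,
                           as.integer(a$alive), as.integer(a$effector),
                           as.integer(a$suppressed), ord,
                           p_die = rep(0.05, n), p_div = rep(0.3, n),
                           p_mig = rep(0.5, n), p_kill = numeric(n),
                           chemo_type = integer(n), chemo_w = numeric(n),
                           grad_a = numeric(729), grad_gamma_a = numeric(n),
                           grad_b = numeric(729), grad_gamma_b = numeric(n),
                           grad_sel = integer(n),
                           9L, 9L, 9L, 0L, 0, matrix(1, 4, 4))
    occ[] <- res$occ
    a$site <- res$site
    a$alive <- as.logical(res$alive)
    if (length(res$child_parent))
      agents_append(a, a$type[res$child_parent], res$child_site)
    placed <- which(a$alive & a$site > 0)
    expect_true(all(occ[a$site[placed]] == placed))
    expect_equal(sort(occ[occ != 0L]), sort(placed))
  }
})
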