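# a small, fast configuration for engine-level unit tests
small_cfg <- function(extra = list()) {
  base <- list(lattice = list(nx = 30, ny = 30, nz = 30,
                              ln_dim = c(14, 14, 14)),
               init = list(seed_radius_sites = 7),
               timeline = list(castration_week = 1, horizon_weeks = 2,
                               drug_start_week = 1))
  hmsm_config(hmsm:::merge_config(base, extra))
}

test_that("configuration is complete, mergeable and round-trips as YAML", {
  cfg <- hmsm_config()
  expect_s3_class(cfg, "hmsm_config")
  expect_equal(cfg_get(cfg, "pc.p_div_ad"), cfg$pc$p_div_ad)
  cfg2 <- cfg_set(cfg, "tam.p_die", 0.99)
  expect_equal(cfg2$tam$p_die, 0.99)
  expect_error(cfg_get(cfg, "no.such.entry"), "unknown")
  expect_error(hmsm_config(list(regimen = list(plx = 2))), "efficacies")
  expect_error(hmsm_config(list(timeline = list(drug_start_week = 1))),
               "before castration")
  # every scanned key parameter exists and is numeric
  for (p in key_parameters()) expect_true(is.numeric(cfg_get(cfg, p)))
  expect_length(key_parameters(), 34)
  f <- tempfile(fileext = ".yaml")
  write_config_yaml(cfg, f)
  back <- read_config_yaml(f)
  expect_equal(back$pc, cfg$pc)
  expect_equal(back$fields, cfg$fields)
})

test_that("treatments activate at the drug start and map onto their knobs", {
  cfg <- hmsm_config(list(regimen = list(anti_wnt5a = 0.5, plx = 1,
                                         anti_il2 = 0.3, egfr = 0.7)))
  off <- apply_treatment(cfg$regimen, cfg$timeline, t_h = 100)
  expect_true(all(unlist(off) == 0))
  on <- apply_treatment(cfg$regimen, cfg$timeline, t_h = 4 * 168)
  expect_equal(on, list(anti_wnt5a = 0.5, plx = 1, anti_il2 = 0.3,
                        egfr = 0.7))
})

test_that("a zero-length horizon returns only the seeded census", {
  cfg <- hmsm_config(list(timeline = list(horizon_weeks = 0,
                                          castration_week = 0,
                                          drug_start_week = 0)))
  r <- run_hmsm(cfg, 1)
  df <- as.data.frame(r)
  expect_equal(nrow(df), 1L)
  expect_equal(df$pc_total, 200)
  expect_equal(df$tam, 100)
  expect_equal(df$ctl_tumor, 2)
  expect_equal(df$treg_tumor, 2)
})

test_that("identical config and seed reproduce the recorder bit-for-bit", {
  cfg <- small_cfg()
  r1 <- run_hmsm(cfg, 123)
  r2 <- run_hmsm(cfg, 123)
  expect_identical(unclass(r1)[, ], unclass(r2)[, ])
  r3 <- run_hmsm(cfg, 124)
  expect_false(identical(unclass(r1)[, ], unclass(r3)[, ]))
  expect_length(unique(replicate_seeds(1, 10)), 10)
})

test_that("fold change follows its definition, both references, both SDs", {
  mk <- function(vals, tc = 0) {
    m <- cbind(t_h = seq(0, by = 2, length.out = length(vals)), q = vals)
    structure(m, class = "hmsm_recorder", castration_h = tc)
  }
  # constant quantity: 1.0 +- 0.0
  recs <- list(mk(rep(4, 10)), mk(rep(4, 10)))
  f <- fold_change(recs, "q", t_h = 10, reference = "t0")
  expect_equal(f$mean, 1); expect_equal(f$sd, 0)
  # ratios 2 and 4: mean 3, sample SD (n-1) = sqrt(2)
  recs <- list(mk(c(1, 2)), mk(c(1, 4)))
  f <- fold_change(recs, "q", t_h = 2, reference = "t0")
  expect_equal(f$mean, 3)
  expect_equal(f$sd, sqrt(2))
  # arm-vs-arm with identical arms: exactly 1 +- 0
  f2 <- fold_change(recs, "q", t_h = 2, ref_arm = recs)
  expect_equal(f2$mean, 1); expect_equal(f2$sd, 0)
  # zero references are excluded and counted
  recs <- list(mk(c(0, 2)), mk(c(1, 4)))
  f3 <- fold_change(recs, "q", t_h = 2, reference = "t0")
  expect_equal(f3$n_excluded, 1L)
  expect_equal(f3$values, 4)
})

test_that("a zero-delta sensitivity scan returns exactly zero everywhere", {
  cfg <- small_cfg()
  sc <- sensitivity_scan(cfg, params = c("pc.p_div_ad", "tam.p_die"),
                         delta = 0, n_rep = 1, base_seed = 1,
                         t_eval_h = 2 * 168,
                         baseline = list(run_hmsm(cfg, replicate_seeds(1, 1))))
  expect_equal(sc$pct_change, c(0, 0))
})

test_that("a dead knob produces no change under the same seeds", {
  cfg <- small_cfg()
  base <- list(run_hmsm(cfg, replicate_seeds(7, 1)))
  # a drug efficacy with no drug scheduled is a dead knob: scaling it by
  # 1.05 leaves the zero efficacy at zero, so the run is unchanged
  sc <- sensitivity_scan(cfg, params = "regimen.plx", delta = 0.05,
                         n_rep = 1, base_seed = 7, t_eval_h = 2 * 168,
                         baseline = base)
  expect_equal(sc$pct_change, 0)
})

test_that("census export matches the documented schema", {
  cfg <- small_cfg(list(timeline = list(horizon_weeks = 1,
                                        castration_week = 1,
                                        drug_start_week = 1)))
  r <- run_hmsm(cfg, 2)
  f <- tempfile(fileext = ".csv")
  write_census_csv(r, f)
  df <- utils::read.csv(f)
  expect_equal(names(df), c("t_h", "pc_total", "pc_resistant", "tam",
                            "ctl_tumor", "ctl_ln", "treg_tumor", "treg_ln",
                            "ec"))
  expect_true(all(df[, -1] >= 0))
})
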