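test_that("hill activation has the closed-form values and guards its domain", {
  expect_equal(hill_activation(0, 0.5), 0)
  for (H in c(0.1, 1, 7)) expect_equal(hill_activation(H, H), 0.5)
  expect_equal(hill_activation(1, 0.5), 2 / 3)
  expect_true(all(diff(hill_activation(seq(0, 10, 0.1), 1)) > 0))
  expect_error(hill_activation(-1, 1), "non-negative")
  expect_error(hill_activation(1, 0), "half-saturation")
})

test_that("the cascade derivative matches hand-computed cases", {
  p <- ode_params(k1 = 1, k2 = 1, k3 = 1, k4 = 1, k5 = 1, k6 = 1,
                  H1 = 1, H2 = 1, H3 = 1, H4 = 1, H5 = 1, H6 = 1,
                  d1 = 1, d2 = 1, d3 = 1, d4 = 1, d5 = 1)
  # zero state, zero ligands: the origin is a fixed point
  d0 <- signaling_rhs(signaling_state(), p, ligand_input(0, 0))
  expect_equal(unname(d0), rep(0, 5))
  # unit parameters, maximal ligands, zero state: only the ligand-facing
  # stages move, each at k * 1/(1+1)
  d1 <- signaling_rhs(signaling_state(), p, ligand_input(1, 1))
  expect_equal(unname(d1), c(0.5, 0.5, 0, 0, 0))
  # full blockade of both branches: AR sees pure decay whatever ERK/AKT do
  s <- signaling_state(erk = 2, skp2 = 1, akt = 3, ar = 0.7, prol = 0.1)
  db <- signaling_rhs(s, p, ligand_input(1, 1), inhibition_state(1, 1))
  expect_equal(db[["ar"]], -1 * 0.7)
})

test_that("integration stays non-negative and hits the analytic steady state", {
  # zero input from zero state stays identically zero
  tr0 <- integrate_signaling(default_signaling_params(), ligand_input(0, 0),
                             times = seq(0, 200, 10))
  expect_true(all(abs(as.matrix(tr0[, -1])) < 1e-12))
  # single-branch closed form: ERK* = (k1/d1) hill(W, H1)
  p <- ode_params(k1 = 0.1, k2 = 0.1, k3 = 0.1, k4 = 0.1, k5 = 0.1,
                  k6 = 0.1, H1 = 1, H2 = 1, H3 = 1, H4 = 1, H5 = 1, H6 = 1,
                  d1 = 0.05, d2 = 0.05, d3 = 0.05, d4 = 0.05, d5 = 0.05)
  tr <- integrate_signaling(p, ligand_input(wnt5a = 1),
                            times = seq(0, 1000, 50))
  expect_equal(tr$erk[nrow(tr)], 1.0, tolerance = 1e-5)
  # random positive parameters: endpoint within 1e-4 of the cascade
  # steady-state composition, and the whole trajectory non-negative
  set.seed(7)
  for (i in 1:5) {
    pr <- as_ode_params(stats::setNames(
      c(runif(6, 0.05, 0.5), runif(6, 0.2, 2), runif(5, 0.05, 0.3)),
      param_names_ode <- c(paste0("k", 1:6), paste0("H", 1:6),
                           paste0("d", 1:5))))
    lig <- ligand_input(wnt5a = 1, egf = 0)
    tr <- integrate_signaling(pr, lig, times = seq(0, 2000, 100))
    expect_true(all(as.matrix(tr[, -1]) > -1e-12))
    ss <- signaling_steady_state(pr, lig)
    expect_equal(unname(unlist(tr[nrow(tr), -1])), unname(unclass(ss)),
                 tolerance = 1e-4)
  }
})

test_that("the calibrated system stabilizes within a simulated hour", {
  p <- default_signaling_params()
  lig <- ligand_input(wnt5a = 1, egf = 1)
  tr <- integrate_signaling(p, lig, times = seq(0, 60, 5))
  ss <- signaling_steady_state(p, lig)
  end <- unlist(tr[nrow(tr), -1])
  expect_true(all(abs(end - unclass(ss)) <= 0.05 * pmax(unclass(ss), 1e-6)))
})

test_that("proliferation fold change is 1 at zero dose and under blockade,
          and monotone in each ligand", {
  p <- default_signaling_params()
  expect_equal(proliferation_fold_change(p, ligand_input(0, 0)), 1.0)
  expect_equal(
    proliferation_fold_change(p, ligand_input(1, 1), inhibition_state(1, 1)),
    1.0, tolerance = 1e-8)
  doses <- seq(0, 1, 0.25)
  fw <- vapply(doses, function(w)
    proliferation_fold_change(p, ligand_input(wnt5a = w)), numeric(1))
  fe <- vapply(doses, function(e)
    proliferation_fold_change(p, ligand_input(egf = e)), numeric(1))
  expect_true(all(diff(fw) >= 0))
  expect_true(all(diff(fe) >= 0))
  # fast quasi-steady-state path agrees with the 72-h integration closely
  expect_equal(prolif_fold_ss(0.5, 0.25, p),
               proliferation_fold_change(p, ligand_input(0.5, 0.25)),
               tolerance = 0.02)
})

test_that("parameter serialization round-trips and trajectories export", {
  p <- default_signaling_params()
  f <- tempfile(fileext = ".yaml")
  write_params_yaml(p, f)
  expect_equal(unclass(read_params_yaml(f)), unclass(p))
  tr <- integrate_signaling(p, ligand_input(1, 0), times = c(0, 30, 60))
  csv <- tempfile(fileext = ".csv")
  write_trajectory_csv(tr, csv)
  expect_equal(names(utils::read.csv(csv)),
               c("t_min", "erk", "skp2", "akt", "ar", "prol"))
})

test_that("single-parameter perturbations move the 72-h output boundedly", {
  p <- default_signaling_params()
  base <- proliferation_fold_change(p, ligand_input(1, 0))
  nm <- c(paste0("k", 1:6), paste0("H", 1:6), paste0("d", 1:5))
  for (delta in c(0.95, 1.05)) {
    changes <- vapply(nm, function(k) {
      q <- unclass(p); q[k] <- q[k] * delta
      abs(proliferation_fold_change(as_ode_params(q), ligand_input(1, 0)) -
            base) / base
    }, numeric(1))
    expect_true(all(changes < 0.25))
  }
})
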