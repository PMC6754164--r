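#' Simulation configuration
#'
#' Builds the complete, materialized configuration for a hybrid multi-scale
#' run: lattice geometry, event timeline, treatment regimen, and every rate
#' the modules consume. All defaults are the package's calibrated study
#' conditions; any entry can be overridden through a nested list, e.g.
#' `hmsm_config(list(regimen = list(plx = 1)))`. There are no hidden
#' defaults at run time: the returned object contains every parameter.
#'
#' @param overrides Nested named list of overrides.
#' @return A list of class `"hmsm_config"`.
#' @export
hmsm_config <- function(overrides = list()) {
  cfg <- list(
    lattice = list(nx = 50, ny = 50, nz = 50, ln_dim = c(24, 24, 24),
                   spacing_um = 80),
    timeline = list(castration_week = 4, horizon_weeks = 9,
                    drug_start_week = 4, record_every_h = 2),
    init = list(n_pc = 200, n_tam = 100, n_ctl = 2, n_treg = 2,
                seed_radius_sites = 12),
    regimen = list(castration = TRUE, anti_wnt5a = 0, plx = 0, anti_il2 = 0,
                   egfr = 0),
    signaling = list(params = as.list(unclass(default_signaling_params())),
                     basal = 0.01, k_w_dose = 2, k_e_dose = 4.2),
    pc = list(p_div_ad = 0.0145, p_div_ai = 1.9e-5, p_die0 = 0.004,
              p_die_castrate = 0.035, h_ad = 0.3, a_auto = 0.9,
              vasc_bonus = 0.2, vasc_radius = 5, p_mig = 0.05,
              switch_rate = 0.005, switch_ramp_h = 336),
    tam = list(p_div_basal = 0.002, p_div_csf1 = 0.054, h_csf1 = 0.82,
               k_crowd = 36, p_die = 0.03, p_mig = 0.3, chemo_w = 0.5,
               rec_rate = 1, rec_h = 2000),
    ctl = list(p_kill = 0.15, s_il10 = 0.9, h_il10 = 0.5, p_die = 0.01,
               p_mig = 0.5, chemo_w = 1, grad_gamma = 3),
    treg = list(p_div_basal = 0.004, p_div_trail = 0.036, h_trail = 0.15,
                p_div_il2 = 0.008, h_il2 = 1, p_die = 0.028, p_mig = 0.5,
                chemo_w = 1, supp_radius = 2, p_kill_ctl = 0.012,
                k_crowd = 10, grad_gamma = 3),
    ln = list(act_ctl_max = 0.15, act_h_stim = 60, act_rate_treg = 0.07,
              gen_range = c(7, 10), gen_range_treg = c(5, 7),
              stim_threshold_h = 20, div_period_h = 8,
              div_period_treg_h = 12, p_mem = 0.01, p_mem_treg = 0.02,
              p_die_ln = 0.04,
              p_div_treg_il2 = 0.025, h_il2_ln = 400, il2_per_ctl = 0.01,
              il2_ln_decay = 0.05, inf_frac_ctl = 5e-4,
              inf_frac_treg = 1.3e-3, inf_cap = 5),
    dc = list(uptake = 0.1, max_new = 30),
    androgen = list(tau_h = 48, blood_frac = 0.10, tissue_frac = 0.20,
                    dht_rate = 0.01, dht_halfsat = 2000, dht_plateau = 0.95),
    angio = list(threshold_mm = 2, n_sprouts = 8, p_move = 0.1, lambda = 50,
                 noise_sd = 0.05, consume = 0.02, branch_age_h = 18,
                 c_taf = 0.5, basal_branch = 0, profile_mean = 50,
                 profile_sd = 12),
    antigen = list(decay = 0.05),
    fields = list(
      wnt5a = list(D = 0.08, decay = 0.03, sec_treg = 1.0),
      egf   = list(D = 0.08, decay = 0.05, sec_tam = 0.2),
      csf1  = list(D = 0.08, decay = 0.03, sec_pc = 0.4, stress_amp = 2.2,
                   cons_tam = 0.05),
      vegf  = list(D = 0.08, decay = 0.01, sec_pc = 0.002, sec_tam = 0.02,
                   stress_amp = 1.7),
      il10  = list(D = 0.08, decay = 0.03, sec_tam = 0.05, stress_amp = 8.8),
      il2   = list(D = 0.08, decay = 0.01, sec_ctl = 0.2),
      trail = list(D = 0.08, decay = 0.005, sec_pc = 0.2, wnt5a_amp = 4,
                   resist_amp = 5)),
    wtype = matrix(1, 4, 4),
    replicates = 20
  )
  cfg <- merge_config(cfg, overrides)
  validate_config(cfg)
  class(cfg) <- "hmsm_config"
  cfg
}

merge_config <- function(base, over) {
  for (nm in names(over)) {
    if (is.list(base[[nm]]) && is.list(over[[nm]]))
      base[[nm]] <- merge_config(base[[nm]], over[[nm]])
    else base[[nm]] <- over[[nm]]
  }
  base
}

validate_config <- function(cfg) {
  eff <- unlist(cfg$regimen[c("anti_wnt5a", "plx", "anti_il2", "egfr")])
  if (any(eff < 0 | eff > 1)) stop("treatment efficacies must lie in [0, 1]")
  if (cfg$timeline$castration_week > cfg$timeline$horizon_weeks &&
      cfg$timeline$horizon_weeks > 0 && cfg$regimen$castration)
    warning("castration scheduled after the horizon; it will never fire")
  if (cfg$timeline$drug_start_week < cfg$timeline$castration_week)
    stop("drugs cannot start before castration")
  invisible(TRUE)
}

#' Read or modify a configuration entry by dotted path
#' @param cfg An [hmsm_config()].
#' @param path Dotted path, e.g. `"pc.p_div_ad"`.
#' @param value Replacement value (for `cfg_set`).
#' @return The entry (`cfg_get`) or the updated config (`cfg_set`).
#' @export
cfg_get <- function(cfg, path) {
  for (k in strsplit(path, ".", fixed = TRUE)[[1]]) {
    if (is.null(cfg[[k]])) stop("unknown config entry: ", path)
    cfg <- cfg[[k]]
  }
  cfg
}

#' @rdname cfg_get
#' @export
cfg_set <- function(cfg, path, value) {
  keys <- strsplit(path, ".", fixed = TRUE)[[1]]
  ref <- "cfg"
  for (k in keys) {
    if (is.null(eval(parse(text = ref))[[k]]))
      stop("unknown config entry: ", path)
    ref <- sprintf("%s[[\"%s\"]]", ref, k)
  }
  eval(parse(text = sprintf("%s <- value", ref)))
  cfg
}

#' The designated key parameters of the calibrated model
#'
#' The 34 rates and thresholds scanned by [sensitivity_scan()]: tumor-cell
#' proliferation/death/resistance, macrophage and T-cell kinetics,
#' lymph-node program rates, androgen dynamics and the castration-responsive
#' secretion gains.
#'
#' @return Character vector of 34 dotted config paths.
#' @export
key_parameters <- function() {
  c("pc.p_div_ad", "pc.p_div_ai", "pc.p_die0", "pc.p_die_castrate",
    "pc.h_ad", "pc.a_auto", "pc.vasc_bonus", "pc.p_mig", "pc.switch_rate",
    "pc.switch_ramp_h",
    "tam.p_div_basal", "tam.p_div_csf1", "tam.h_csf1", "tam.p_die",
    "ctl.p_kill", "ctl.s_il10", "ctl.h_il10", "ctl.p_die",
    "treg.p_div_basal", "treg.p_div_trail", "treg.p_div_il2", "treg.p_die",
    "ln.act_ctl_max", "ln.act_rate_treg", "ln.p_mem", "ln.p_die_ln",
    "ln.p_div_treg_il2", "ln.inf_frac_ctl",
    "dc.uptake",
    "androgen.tau_h", "androgen.dht_rate", "androgen.dht_plateau",
    "fields.csf1.stress_amp", "fields.il10.stress_amp")
}

#' Active treatment efficacies at a given time
#'
#' Maps the regimen onto the module-level knobs: anti-WNT5A scales the
#' effective WNT5A ligand, PLX (CSF1R inhibition) scales the CSF1-driven
#' macrophage term, anti-IL-2 scales IL-2-driven regulatory-T-cell division,
#' and the EGFR inhibitor sets the `D2` blockade of the signaling system.
#' All drugs start at `drug_start_week` (never before castration); the
#' castration event itself is routed through [apply_castration()] by the
#' engine.
#'
#' @param regimen The `regimen` block of an [hmsm_config()].
#' @param timeline The `timeline` block.
#' @param t_h Simulation time (hours).
#' @return Named list of active efficacies.
#' @export
apply_treatment <- function(regimen, timeline, t_h) {
  on <- t_h >= timeline$drug_start_week * 168
  list(anti_wnt5a = if (on) regimen$anti_wnt5a else 0,
       plx = if (on) regimen$plx else 0,
       anti_il2 = if (on) regimen$anti_il2 else 0,
       egfr = if (on) regimen$egfr else 0)
}

REC_COLS <- c("t_h", "pc_total", "pc_resistant", "tam", "ctl_tumor", "ctl_ln",
              "treg_tumor", "treg_ln", "ec", "dc_presenting", "antigen",
              "androgen_blood", "androgen_tissue", "csf1_total", "vegf_total",
              "il10_total", "wnt5a_total", "egf_total", "il2_total",
              "trail_total", "il2_ln", "tam_il10_out", "tam_vegf_out",
              "radius_mm", "linked", "n_inf_ctl", "n_inf_treg",
              "csf1_tam_mean", "w_dose_mean", "e_dose_mean",
              "trail_treg_mean", "il2_treg_mean")

#' Run one replicate of the hybrid multi-scale simulation
#'
#' Executes the event timeline on a 2-hour decision clock: cytokine
#' secretion, diffusion and decay; androgen withdrawal and CRPC-driven
#' resynthesis; resistance switching; the lymph-node dendritic-cell/T-cell
#' cycle and infiltration; the tumor-compartment agent sweep in a seeded
#' random order; angiogenesis after onset; and a census record every step.
#' The run is fully deterministic given `(config, seed)`.
#'
#' @param config An [hmsm_config()].
#' @param seed Integer RNG seed for this replicate.
#' @return A recorder: matrix of per-step records (class
#'   `"hmsm_recorder"`) with the config, seed and castration time attached
#'   as attributes.
#' @export
run_hmsm <- function(config, seed = 1L) {
  set.seed(seed)
  cfg <- config
  lat <- make_lattice(cfg$lattice$nx, cfg$lattice$ny, cfg$lattice$nz,
                      cfg$lattice$ln_dim, cfg$lattice$spacing_um)
  dims <- lat$dims
  region <- lat$region
  occ <- array(0L, dims)
  a <- agents_new()

  seed_agents(a, occ, lat, cfg)

  fields <- sapply(names(cfg$fields), function(s) new_field(lat),
                   simplify = FALSE)
  field_active <- stats::setNames(logical(length(fields)), names(fields))
  field_totals <- stats::setNames(numeric(length(fields)), names(fields))
  fstep <- lapply(cfg$fields, function(fc) {
    dtd <- 2 * cfg$timeline$record_every_h # diffusion applied every 2nd step
    nsub <- max(1L, ceiling(6 * fc$D * dtd))
    list(alpha = fc$D * dtd / nsub, nsub = nsub,
         decay_factor = exp(-fc$decay * cfg$timeline$record_every_h))
  })
  androgen <- androgen_state()
  angio <- angio_state(lat)
  sprouts_placed <- FALSE
  vasc <- array(FALSE, dims)
  dcs <- dc_pool_new(); antigen <- 0; il2_ln <- 0
  castration_h <- cfg$timeline$castration_week * 168
  horizon_h <- cfg$timeline$horizon_weeks * 168
  dt <- cfg$timeline$record_every_h
  n_steps <- floor(horizon_h / dt)
  rec <- matrix(0, nrow = n_steps + 1, ncol = length(REC_COLS),
                dimnames = list(NULL, REC_COLS))
  h_ad <- cfg$pc$h_ad
  h0 <- hill_activation(1, h_ad)
  n_sites <- prod(dims)
  ro <- expand.grid(dx = -2:2, dy = -2:2, dz = -2:2)
  rec_offsets <- with(ro, dx + dims[1] * (dy + dims[2] * dz))
  rec_offsets <- rec_offsets[rec_offsets != 0]
  sig_params <- as_ode_params(cfg$signaling$params)

  record <- function(i, t_h, extra) {
    pc <- a$alive & a$type == TYPE_PC
    rec[i, ] <<- c(t_h,
      sum(pc), sum(pc & a$resistant),
      agents_count(a, TYPE_TAM),
      agents_count(a, TYPE_CTL, COMP_TUMOR),
      agents_count(a, TYPE_CTL, COMP_LN),
      agents_count(a, TYPE_TREG, COMP_TUMOR),
      agents_count(a, TYPE_TREG, COMP_LN),
      length(angio$path_id),
      sum(dcs$state == "presenting"),
      antigen, androgen$blood, androgen$tissue,
      field_totals["csf1"], field_totals["vegf"], field_totals["il10"],
      field_totals["wnt5a"], field_totals["egf"], field_totals["il2"],
      field_totals["trail"], il2_ln,
      extra["il10_out"], extra["vegf_out"],
      extra["radius_mm"], as.numeric(angio$linked),
      extra["n_inf_ctl"], extra["n_inf_treg"],
      {ts <- a$site[a$alive & a$type == TYPE_TAM]
       if (length(ts)) mean(fields$csf1[ts]) else 0},
      {ps <- a$site[a$alive & a$type == TYPE_PC]
       if (length(ps)) mean(ligand_dose(fields$wnt5a[ps],
                                        cfg$signaling$k_w_dose)) else 0},
      {ps <- a$site[a$alive & a$type == TYPE_PC]
       if (length(ps)) mean(ligand_dose(fields$egf[ps],
                                        cfg$signaling$k_e_dose)) else 0},
      {gs <- a$site[a$alive & a$type == TYPE_TREG & a$compartment ==
                      COMP_TUMOR]
       if (length(gs)) mean(fields$trail[gs]) else 0},
      {gs <- a$site[a$alive & a$type == TYPE_TREG & a$compartment ==
                      COMP_TUMOR]
       if (length(gs)) mean(fields$il2[gs]) else 0})
  }
  # pre-equilibrate the cytokine fields under the seeded census (no stress)
  warm_src <- list(
    csf1 = list(sites = a$site[a$alive & a$type == TYPE_PC],
                rate = cfg$fields$csf1$sec_pc),
    trail = list(sites = a$site[a$alive & a$type == TYPE_PC],
                 rate = cfg$fields$trail$sec_pc),
    vegf = list(sites = a$site[a$alive & a$type %in% c(TYPE_PC, TYPE_TAM)],
                rate = c(rep(cfg$fields$vegf$sec_pc,
                             sum(a$alive & a$type == TYPE_PC)),
                         rep(cfg$fields$vegf$sec_tam,
                             sum(a$alive & a$type == TYPE_TAM)))),
    il10 = list(sites = a$site[a$alive & a$type == TYPE_TAM],
                rate = cfg$fields$il10$sec_tam),
    egf = list(sites = a$site[a$alive & a$type == TYPE_TAM],
               rate = cfg$fields$egf$sec_tam))
  for (w in seq_len(36)) {
    for (s in names(warm_src)) {
      ws <- warm_src[[s]]
      fs <- cpp_field_step(fields[[s]], ws$sites,
                           rep_len(ws$rate * 2 * dt, length(ws$sites)),
                           integer(0), numeric(0),
                           dims[1], dims[2], dims[3], fstep[[s]]$alpha,
                           fstep[[s]]$nsub, fstep[[s]]$decay_factor)
      fields[[s]] <- fs$field
      field_totals[s] <- fs$total
      field_active[s] <- TRUE
    }
  }
  r0 <- tumor_radius_mm(a, lat)
  record(1, 0, c(il10_out = 0, vegf_out = 0, radius_mm = r0,
                 n_inf_ctl = 0, n_inf_treg = 0))

  for (step in seq_len(n_steps)) {
    t_h <- step * dt
    tx <- apply_treatment(cfg$regimen, cfg$timeline, t_h)

    if (cfg$regimen$castration && !androgen$castrated && t_h >= castration_h)
      androgen <- apply_castration(androgen, t_h)
    n_res <- sum(a$alive & a$type == TYPE_PC & a$resistant)
    androgen <- androgen_step(androgen, dt, n_res,
                              cfg$androgen$tau_h, cfg$androgen$blood_frac,
                              cfg$androgen$tissue_frac, cfg$androgen$dht_rate,
                              cfg$androgen$dht_halfsat,
                              cfg$androgen$dht_plateau)
    stress <- max(0, 1 - hill_activation(androgen$tissue, h_ad) / h0)

    # one-way androgen-independence switching
    if (androgen$castrated) {
      adpc <- which(a$alive & a$type == TYPE_PC & !a$resistant)
      if (length(adpc)) {
        psw <- pc_resistance_switch_prob(t_h - androgen$t_castration,
                                         cfg$pc$switch_rate,
                                         cfg$pc$switch_ramp_h)
        a$resistant[adpc[stats::runif(length(adpc)) < psw]] <- TRUE
      }
    }

    # --- secretion ---------------------------------------------------------
    pc_sites <- a$site[a$alive & a$type == TYPE_PC]
    tam_sites <- a$site[a$alive & a$type == TYPE_TAM]
    treg_sites <- a$site[a$alive & a$type == TYPE_TREG &
                           a$compartment == COMP_TUMOR]
    ctl_eff_sites <- a$site[a$alive & a$type == TYPE_CTL &
                              a$compartment == COMP_TUMOR & a$effector]
    fcfg <- cfg$fields
    w_at_pc <- fields$wnt5a[pc_sites]
    w_dose_pc <- ligand_dose(w_at_pc, cfg$signaling$k_w_dose, tx$anti_wnt5a)
    tam_vegf_rate <- fcfg$vegf$sec_tam * (1 + fcfg$vegf$stress_amp * stress)
    tam_il10_rate <- fcfg$il10$sec_tam * (1 + fcfg$il10$stress_amp * stress)
    none <- integer(0)
    sec <- list(
      csf1 = list(sites = pc_sites,
                  amt = fcfg$csf1$sec_pc * (1 + fcfg$csf1$stress_amp * stress),
                  cons = tam_sites, cons_amt = fcfg$csf1$cons_tam),
      trail = list(sites = pc_sites,
                   amt = fcfg$trail$sec_pc *
                     (1 + fcfg$trail$wnt5a_amp * w_dose_pc) *
                     (1 + fcfg$trail$resist_amp *
                        a$resistant[a$alive & a$type == TYPE_PC])),
      vegf = list(sites = c(pc_sites, tam_sites),
                  amt = c(rep(fcfg$vegf$sec_pc, length(pc_sites)),
                          rep(tam_vegf_rate, length(tam_sites)))),
      il10 = list(sites = tam_sites, amt = tam_il10_rate),
      egf = list(sites = tam_sites, amt = fcfg$egf$sec_tam),
      wnt5a = list(sites = treg_sites, amt = fcfg$wnt5a$sec_treg),
      il2 = list(sites = ctl_eff_sites, amt = fcfg$il2$sec_ctl))
    for (s in names(fields)) {
      sc <- sec[[s]]
      if (!field_active[s] && !length(sc$sites)) next
      field_active[s] <- TRUE
      fs <- cpp_field_step(fields[[s]], sc$sites,
                           if (length(sc$sites)) rep_len(sc$amt * dt,
                                                         length(sc$sites))
                           else numeric(0),
                           if (is.null(sc$cons)) none else sc$cons,
                           if (is.null(sc$cons)) numeric(0)
                           else rep_len(sc$cons_amt * dt, length(sc$cons)),
                           dims[1], dims[2], dims[3], fstep[[s]]$alpha,
                           if (step %% 2 == 0) fstep[[s]]$nsub else 0L,
                           fstep[[s]]$decay_factor)
      fields[[s]] <- fs$field
      field_totals[s] <- fs$total
    }
    il10_out <- length(tam_sites) * tam_il10_rate * dt
    vegf_out <- length(tam_sites) * tam_vegf_rate * dt
    n_ctl_ln_eff <- sum(a$alive & a$type == TYPE_CTL &
                          a$compartment == COMP_LN & a$effector)
    il2_ln <- il2_ln * exp(-cfg$ln$il2_ln_decay * dt) +
      cfg$ln$il2_per_ctl * n_ctl_ln_eff * dt

    # --- lymph node --------------------------------------------------------
    dcr <- dc_cycle(dcs, antigen, t_h, cfg$dc$uptake, cfg$dc$max_new)
    dcs <- dcr$dcs; antigen <- dcr$antigen
    occ <- t_activate_expand(a, occ, lat, dcr$n_stimulating, t_h, cfg$ln,
                             il2_ln, tx$anti_il2)
    eff_ln <- a$alive & a$compartment == COMP_LN & a$effector
    inf <- infiltrate(a, occ, lat,
                      frac_rate(min(cfg$ln$inf_cap,
                                    cfg$ln$inf_frac_ctl *
                                      sum(eff_ln & a$type == TYPE_CTL))),
                      frac_rate(min(cfg$ln$inf_cap,
                                    cfg$ln$inf_frac_treg *
                                      sum(eff_ln & a$type == TYPE_TREG))))
    occ <- inf$occ

    # --- macrophage recruitment (CSF1-driven monocyte influx) -------------
    n_rec <- stats::rpois(1, cfg$tam$rec_rate * (1 - tx$plx) *
                            hill_activation(field_totals["csf1"],
                                            cfg$tam$rec_h))
    if (n_rec > 0 && length(pc_sites)) {
      anchors <- pc_sites[sample.int(length(pc_sites), n_rec, replace = TRUE)]
      for (s_a in anchors) {
        cand <- s_a + rec_offsets
        cand <- cand[cand >= 1 & cand <= n_sites]
        cand <- cand[occ[cand] == 0L & region[cand] == REGION_TUMOR]
        if (length(cand)) {
          tgt <- cand[sample.int(length(cand), 1)]
          idx <- agents_append(a, TYPE_TAM, tgt)
          occ[tgt] <- idx
        }
      }
    }

    # --- tumor-compartment agent sweep ------------------------------------
    tum <- which(a$alive & a$compartment == COMP_TUMOR & a$site > 0)
    n <- length(a$type)
    p_die <- p_div <- p_mig <- p_kill <- chemo_w <- numeric(n)
    grad_gamma <- numeric(n)
    grad_sel <- chemo_type <- integer(n)
    a$suppressed[] <- FALSE
    if (length(tum)) {
      ty <- a$type[tum]
      st <- a$site[tum]
      is_pc <- ty == TYPE_PC
      if (any(is_pc)) {
        i <- tum[is_pc]
        w_dose <- ligand_dose(fields$wnt5a[a$site[i]], cfg$signaling$k_w_dose,
                              tx$anti_wnt5a)
        e_dose <- ligand_dose(fields$egf[a$site[i]], cfg$signaling$k_e_dose, 0)
        pp <- pc_step_probs(w_dose, e_dose, androgen$tissue, a$resistant[i],
                            angio$linked & vasc[a$site[i]], cfg$pc,
                            list(params = sig_params,
                                 basal = cfg$signaling$basal),
                            d1_block = 0, d2_block = tx$egfr)
        p_div[i] <- pp$p_div; p_die[i] <- pp$p_die; p_mig[i] <- cfg$pc$p_mig
      }
      is_tam <- ty == TYPE_TAM
      if (any(is_tam)) {
        i <- tum[is_tam]
        crowd <- cpp_count_type_near(occ, a$type, a$site[i], 2, TYPE_TAM,
                                     dims[1], dims[2], dims[3]) - 1L
        p_div[i] <- tam_division_prob(fields$csf1[a$site[i]], cfg$tam,
                                      tx$plx) *
          pmax(0, 1 - crowd / cfg$tam$k_crowd)
        p_die[i] <- cfg$tam$p_die; p_mig[i] <- cfg$tam$p_mig
        chemo_type[i] <- TYPE_PC; chemo_w[i] <- cfg$tam$chemo_w
      }
      is_ctl <- ty == TYPE_CTL
      if (any(is_ctl)) {
        i <- tum[is_ctl]
        near_treg <- cpp_count_type_near(occ, a$type, a$site[i],
                                         cfg$treg$supp_radius, TYPE_TREG,
                                         dims[1], dims[2], dims[3])
        a$suppressed[i] <- near_treg > 0
        p_kill[i] <- ctl_kill_prob(fields$il10[a$site[i]], cfg$ctl,
                                   a$suppressed[i])
        p_die[i] <- cfg$ctl$p_die; p_mig[i] <- cfg$ctl$p_mig
        chemo_type[i] <- TYPE_PC; chemo_w[i] <- cfg$ctl$chemo_w
        grad_sel[i] <- 1L; grad_gamma[i] <- cfg$ctl$grad_gamma
      }
      is_treg <- ty == TYPE_TREG
      if (any(is_treg)) {
        i <- tum[is_treg]
        tcrowd <- cpp_count_type_near(occ, a$type, a$site[i], 2, TYPE_TREG,
                                      dims[1], dims[2], dims[3]) - 1L
        p_div[i] <- treg_division_prob(fields$trail[a$site[i]],
                                       fields$il2[a$site[i]], cfg$treg,
                                       tx$anti_il2) *
          pmax(0, 1 - tcrowd / cfg$treg$k_crowd)
        p_die[i] <- cfg$treg$p_die; p_mig[i] <- cfg$treg$p_mig
        chemo_type[i] <- TYPE_CTL; chemo_w[i] <- cfg$treg$chemo_w
        grad_sel[i] <- 2L; grad_gamma[i] <- cfg$treg$grad_gamma
      }
      ord <- tum[sample.int(length(tum))]
      res <- cpp_agents_step(occ, region, a$type, a$site,
                             as.integer(a$alive), as.integer(a$effector),
                             as.integer(a$suppressed), ord,
                             p_die, p_div, p_mig, p_kill,
                             chemo_type, chemo_w,
                             fields$trail, grad_gamma,
                             fields$il2, grad_gamma, grad_sel,
                             dims[1], dims[2], dims[3],
                             cfg$treg$supp_radius, cfg$treg$p_kill_ctl,
                             cfg$wtype)
      occ[] <- res$occ
      a$site <- res$site
      a$alive <- as.logical(res$alive)
      a$suppressed <- as.logical(res$suppressed)
      if (length(res$child_parent)) {
        par <- res$child_parent
        agents_append(a, type = a$type[par], site = res$child_site,
                      compartment = COMP_TUMOR,
                      resistant = a$resistant[par],
                      effector = a$effector[par],
                      gen = a$gen[par], gen_target = a$gen_target[par])
      }
      antigen <- antigen * exp(-cfg$antigen$decay * dt) + res$pc_deaths
    }

    # --- angiogenesis ------------------------------------------------------
    radius_mm <- tumor_radius_mm(a, lat)
    angio <- maybe_start_angiogenesis(angio, 2 * radius_mm,
                                      cfg$angio$threshold_mm)
    if (angio$onset) {
      if (!sprouts_placed) {
        angio <- init_sprouts(angio, lat, cfg$angio$n_sprouts,
                              cfg$angio$profile_mean, cfg$angio$profile_sd)
        sprouts_placed <- TRUE
        vasc <- cpp_dilate_mask(vasc, path_sites(angio, dims),
                                cfg$pc$vasc_radius,
                                dims[1], dims[2], dims[3])
        dim(vasc) <- dims
      }
      n_before <- length(angio$path_id)
      ts <- tip_step(angio, fields$vegf, lat, dt, cfg$angio$p_move,
                     cfg$angio$lambda, cfg$angio$noise_sd, cfg$angio$consume)
      angio <- ts$angio; fields$vegf <- ts$vegf
      angio <- branch_sprouts(angio, fields$vegf, lat, cfg$angio$branch_age_h,
                              cfg$angio$c_taf, cfg$angio$basal_branch)
      if (length(angio$path_id) > n_before) {
        new_sites <- path_sites(angio, dims,
                                rows = (n_before + 1):length(angio$path_id))
        vasc <- cpp_dilate_mask(vasc, new_sites, cfg$pc$vasc_radius,
                                dims[1], dims[2], dims[3])
        dim(vasc) <- dims
        if (!angio$linked &&
            any(cpp_count_type_near(occ, a$type, new_sites, 2, TYPE_PC,
                                    dims[1], dims[2], dims[3]) > 0))
          angio$linked <- TRUE
      }
    }

    record(step + 1, t_h,
           c(il10_out = il10_out, vegf_out = vegf_out, radius_mm = radius_mm,
             n_inf_ctl = inf$n_ctl, n_inf_treg = inf$n_treg))

    if (step %% 12 == 0 && sum(!a$alive) > 2000) occ <- agents_compact(a, occ)
  }

  structure(rec, class = "hmsm_recorder", config = cfg, seed = seed,
            castration_h = if (cfg$regimen$castration)
              min(castration_h, horizon_h) else NA_real_)
}

# map a cytokine concentration to a bounded [0, 1) ligand dose; neutralizing
# antibody reduces the effective concentration by (1 - efficacy)
ligand_dose <- function(conc, half_sat, neutralization = 0) {
  c_eff <- (1 - neutralization) * conc
  c_eff / (half_sat + c_eff)
}

# fractional per-step rates: floor + Bernoulli remainder
frac_rate <- function(rate) {
  floor(rate) + (stats::runif(1) < rate - floor(rate))
}

path_sites <- function(angio, dims, rows = seq_along(angio$path_id)) {
  angio$path_x[rows] + dims[1] * ((angio$path_y[rows] - 1) +
                                    dims[2] * (angio$path_z[rows] - 1))
}

tumor_radius_mm <- function(a, lat) {
  pc <- a$alive & a$type == TYPE_PC & a$site > 0
  if (!any(pc)) return(0)
  d <- lat$dims
  s0 <- a$site[pc] - 1L
  x <- s0 %% d[1]; y <- (s0 %/% d[1]) %% d[2]; z <- s0 %/% (d[1] * d[2])
  ctr <- lat$center - 1
  r <- sqrt((x - ctr[1])^2 + (y - ctr[2])^2 + (z - ctr[3])^2)
  stats::quantile(r, 0.95, names = FALSE) * lat$spacing_um / 1000
}

seed_agents <- function(a, occ, lat, cfg) {
  dims <- lat$dims
  ctr <- lat$center
  rmax <- cfg$init$seed_radius_sites
  # candidate tumor sites within the seeding ball
  off <- expand.grid(x = -rmax:rmax, y = -rmax:rmax, z = -rmax:rmax)
  off <- off[sqrt(off$x^2 + off$y^2 + off$z^2) <= rmax, ]
  x <- ctr[1] + off$x; y <- ctr[2] + off$y; z <- ctr[3] + off$z
  ok <- x >= 1 & x <= dims[1] & y >= 2 & y <= dims[2] & z >= 1 & z <= dims[3]
  ball <- lin_idx(x[ok], y[ok], z[ok], dims)
  ball <- ball[lat$region[ball] == REGION_TUMOR]
  take <- function(sites, n) sites[sample.int(length(sites), n)]
  pc_sites <- take(ball, cfg$init$n_pc)
  idx <- agents_append(a, TYPE_PC, pc_sites)
  occ[pc_sites] <- idx
  # tumor-infiltrating macrophages intersperse with the seeded tumor cells
  tam_sites <- take(ball[occ[ball] == 0L], cfg$init$n_tam)
  idx <- agents_append(a, TYPE_TAM, tam_sites)
  occ[tam_sites] <- idx
  freeb <- ball[occ[ball] == 0L]
  tc <- take(freeb, cfg$init$n_ctl + cfg$init$n_treg)
  if (cfg$init$n_ctl > 0) {
    idx <- agents_append(a, TYPE_CTL, tc[seq_len(cfg$init$n_ctl)],
                         effector = TRUE)
    occ[tc[seq_len(cfg$init$n_ctl)]] <- idx
  }
  if (cfg$init$n_treg > 0) {
    s <- tc[cfg$init$n_ctl + seq_len(cfg$init$n_treg)]
    idx <- agents_append(a, TYPE_TREG, s, effector = TRUE)
    occ[s] <- idx
  }
  # write back occupancy by reference through the caller's frame
  assign("occ", occ, envir = parent.frame())
  invisible(NULL)
}

#' Run independent replicates
#'
#' Derives one seed per replicate from the master seed (kept below 2^31) and
#' runs each replicate independently.
#'
#' @param config An [hmsm_config()].
#' @param n Number of replicates (defaults to `config$replicates`).
#' @param base_seed Master seed.
#' @return List of recorders (class `"hmsm_recorder_set"`).
#' @export
run_replicates <- function(config, n = config$replicates, base_seed = 1L) {
  seeds <- replicate_seeds(base_seed, n)
  out <- lapply(seeds, function(s) run_hmsm(config, s))
  class(out) <- "hmsm_recorder_set"
  out
}

#' @rdname run_replicates
#' @param i Replicate indices.
#' @export
replicate_seeds <- function(base_seed, i) {
  if (length(i) == 1 && i >= 1 && i == round(i)) i <- seq_len(i)
  as.integer((as.numeric(base_seed) + 104729 * i) %% 2147483647)
}

#' Fold change of a recorded quantity over replicates
#'
#' Per replicate, the ratio of the quantity at `t_h` to its reference value;
#' the reference is the pre-castration census (the record at the castration
#' step) by default, the initial census (`"t0"`), or a paired reference arm
#' (`ref_arm`, same seeds), in which case the ratio is taken between arms at
#' `t_h`. Replicates with a zero reference are excluded and counted. The
#' spread is the sample standard deviation (n - 1).
#'
#' @param recorders A list of recorders ([run_replicates()] output).
#' @param quantity Recorder column name (e.g. `"tam"`, `"pc_total"`).
#' @param t_h Evaluation time (hours).
#' @param reference `"pre_castration"` (default), `"t0"`, or a time in
#'   hours.
#' @param ref_arm Optional paired reference arm (list of recorders).
#' @return List with `mean`, `sd`, per-replicate `values`, and
#'   `n_excluded`.
#' @export
fold_change <- function(recorders, quantity, t_h,
                        reference = "pre_castration", ref_arm = NULL) {
  val_at <- function(r, t) {
    i <- which.min(abs(r[, "t_h"] - t))
    r[i, quantity]
  }
  num <- vapply(recorders, val_at, numeric(1), t = t_h)
  if (!is.null(ref_arm)) {
    stopifnot(length(ref_arm) == length(recorders))
    den <- vapply(ref_arm, val_at, numeric(1), t = t_h)
  } else if (identical(reference, "t0")) {
    den <- vapply(recorders, val_at, numeric(1), t = 0)
  } else if (identical(reference, "pre_castration")) {
    den <- vapply(recorders, function(r) {
      tc <- attr(r, "castration_h")
      val_at(r, if (is.na(tc)) 0 else tc)
    }, numeric(1))
  } else {
    den <- vapply(recorders, val_at, numeric(1), t = as.numeric(reference))
  }
  ok <- den > 0
  ratios <- num[ok] / den[ok]
  list(mean = mean(ratios),
       sd = if (length(ratios) > 1) stats::sd(ratios) else 0,
       values = ratios, n_excluded = sum(!ok))
}

#' One-at-a-time parameter sensitivity scan
#'
#' For each named parameter, reruns the simulation with that parameter
#' scaled by `1 + delta` under the same replicate seeds as the baseline, and
#' reports the percent change of the mean output. The default output is the
#' model's standard endpoint: the mean tumor-cell fold change at five weeks
#' post-castration relative to the pre-castration census. With `delta = 0`
#' every change is exactly zero.
#'
#' @param config An [hmsm_config()].
#' @param params Character vector of dotted config paths (defaults to the
#'   34 [key_parameters()]).
#' @param delta Relative perturbation (default +5%).
#' @param n_rep Replicates per arm.
#' @param base_seed Master seed (shared across arms).
#' @param t_eval_h Evaluation time; defaults to 5 weeks post-castration.
#' @param quantity Recorder column.
#' @param baseline Optional precomputed baseline recorders (same config,
#'   seeds `replicate_seeds(base_seed, n_rep)`).
#' @return Data frame with `parameter` and `pct_change`, ordered as given.
#' @export
sensitivity_scan <- function(config, params = key_parameters(), delta = 0.05,
                             n_rep = 2, base_seed = 1L, t_eval_h = NULL,
                             quantity = "pc_total", baseline = NULL) {
  if (is.null(t_eval_h))
    t_eval_h <- (config$timeline$castration_week + 5) * 168
  if (is.null(baseline))
    baseline <- run_replicates(config, n_rep, base_seed)
  base_val <- fold_change(baseline, quantity, t_eval_h)$mean
  pct <- vapply(params, function(p) {
    if (delta == 0) return(0)
    cfg2 <- cfg_set(config, p, cfg_get(config, p) * (1 + delta))
    recs <- run_replicates(cfg2, n_rep, base_seed)
    100 * (fold_change(recs, quantity, t_eval_h)$mean - base_val) / base_val
  }, numeric(1))
  data.frame(parameter = params, pct_change = unname(pct),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Coerce a recorder to a data frame
#' @param x An `"hmsm_recorder"`.
#' @param ... Unused.
#' @return Data frame of the per-step census.
#' @export
as.data.frame.hmsm_recorder <- function(x, ...) {
  as.data.frame(unclass(x)[, , drop = FALSE])
}

#' Export the agent census time series as CSV
#'
#' Schema: `t_h,pc_total,pc_resistant,tam,ctl_tumor,ctl_ln,treg_tumor,
#' treg_ln,ec`.
#' @param recorder An `"hmsm_recorder"`.
#' @param path Output file path.
#' @export
write_census_csv <- function(recorder, path) {
  cols <- c("t_h", "pc_total", "pc_resistant", "tam", "ctl_tumor", "ctl_ln",
            "treg_tumor", "treg_ln", "ec")
  utils::write.csv(as.data.frame(recorder)[, cols], path,
                   row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write / read a simulation configuration as YAML
#' @param cfg An [hmsm_config()].
#' @param path File path.
#' @export
write_config_yaml <- function(cfg, path) {
  out <- unclass(cfg)
  out$wtype <- as.numeric(cfg$wtype)
  yaml::write_yaml(out, path)
  invisible(path)
}

#' @rdname write_config_yaml
#' @export
read_config_yaml <- function(path) {
  raw <- yaml::read_yaml(path)
  if (!is.null(raw$wtype)) raw$wtype <- matrix(unlist(raw$wtype), 4, 4)
  hmsm_config(raw)
}
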