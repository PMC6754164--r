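#' Create an empty dendritic-cell pool
#'
#' DCs are tracked as a clock table rather than lattice agents: antigen
#' uptake spawns a migrating DC, presentation begins 12 h after arrival in
#' the lymph node, T-cell stimulation becomes possible 12 h after
#' presentation starts, and presenting DCs die 48 h into presentation.
#'
#' @return A list with vectors `t_spawn`, `t_present`, `state`.
#' @export
dc_pool_new <- function() {
  list(t_spawn = numeric(0), t_present = numeric(0), state = character(0))
}

#' Advance the dendritic-cell antigen cycle
#'
#' Dying tumor cells release antigen (a counter). Each unit of antigen can
#' be engulfed by a dendritic cell with probability `uptake` per step; new
#' DCs migrate to the lymph node, mature 12 h after arrival, present for up
#' to 48 h and then die. With zero antigen no DC is ever activated, so no
#' T-cell response can start.
#'
#' @param dcs DC pool from [dc_pool_new()].
#' @param antigen Current antigen counter (`>= 0`).
#' @param t_h Simulation time (hours).
#' @param uptake Per-antigen uptake probability this step.
#' @param max_new Cap on new DCs per step.
#' @param mature_h Arrival-to-presentation latency (default 12 h).
#' @param stim_delay_h Presentation-to-first-stimulation latency (12 h).
#' @param present_life_h Presenting-state lifetime (48 h).
#' @return List with the updated `dcs`, remaining `antigen`, and
#'   `n_stimulating` (presenting DCs past the stimulation latency).
#' @export
dc_cycle <- function(dcs, antigen, t_h, uptake = 0.02, max_new = 20,
                     mature_h = 12, stim_delay_h = 12, present_life_h = 48) {
  stopifnot(antigen >= 0)
  n_new <- 0L
  if (antigen > 0) {
    n_new <- min(stats::rbinom(1, floor(antigen), uptake), max_new)
    antigen <- antigen - n_new
  }
  if (n_new > 0) {
    dcs$t_spawn <- c(dcs$t_spawn, rep(t_h, n_new))
    dcs$t_present <- c(dcs$t_present, rep(t_h + mature_h, n_new))
    dcs$state <- c(dcs$state, rep("migrating", n_new))
  }
  if (length(dcs$state)) {
    dcs$state[dcs$state == "migrating" & t_h >= dcs$t_present] <- "presenting"
    dcs$state[dcs$state == "presenting" &
                t_h >= dcs$t_present + present_life_h] <- "dead"
    keep <- dcs$state != "dead"
    dcs <- lapply(dcs, `[`, keep)
  }
  n_stim <- sum(dcs$state == "presenting" &
                  t_h >= dcs$t_present + stim_delay_h)
  list(dcs = dcs, antigen = antigen, n_stimulating = n_stim)
}

#' Activate naive T cells and run programmed clonal expansion
#'
#' While stimulating DCs are present, naive CTLs are activated at a rate
#' proportional to the number of stimulating DCs, and naive regulatory T
#' cells at a low DC-gated basal rate (their amplification after castration
#' is cytokine-driven, not antigen-load-driven). Each activated clone
#' samples a generation target uniformly from `gen_range`; after 20 h of
#' antigenic stimulation it divides once per `div_period_h` until the target
#' generation, then acquires effector function. Effector cells in the lymph
#' node keep a low memory proliferation rate. Divisions require free
#' lymph-node sites (the node is treated as well mixed).
#'
#' @param a Agent population ([agents_new()]).
#' @param occ Occupancy array.
#' @param lattice A [make_lattice()] result.
#' @param n_stimulating Stimulating DC count from [dc_cycle()].
#' @param t_h Simulation time (hours).
#' @param cfg The `ln` block of [hmsm_config()] (rates, latencies, memory
#'   and death rates).
#' @param il2_ln Lymph-node IL-2 level (drives Treg division there).
#' @param anti_il2 IL-2 neutralization efficacy.
#' @return Updated occupancy (agents are modified in place).
#' @export
t_activate_expand <- function(a, occ, lattice, n_stimulating, t_h, cfg,
                              il2_ln = 0, anti_il2 = 0) {
  free_ln <- function() {
    s <- lattice$ln_sites
    s[occ[s] == 0L]
  }
  # activation of naive cells (naive pool is not size-limited; DC-limited,
  # saturating in the number of stimulating DCs)
  if (n_stimulating > 0) {
    n_ctl <- stats::rpois(1, cfg$act_ctl_max *
                            hill_activation(n_stimulating, cfg$act_h_stim))
    n_treg <- stats::rpois(1, cfg$act_rate_treg)
    for (spec in list(c(TYPE_CTL, n_ctl), c(TYPE_TREG, n_treg))) {
      if (spec[2] <= 0) next
      fs <- free_ln()
      n <- min(spec[2], length(fs))
      if (n <= 0) next
      sites <- fs[sample.int(length(fs), n)]
      gr <- if (spec[1] == TYPE_TREG && !is.null(cfg$gen_range_treg))
        cfg$gen_range_treg else cfg$gen_range
      gt <- sample(gr[1]:gr[2], n, replace = TRUE)
      idx <- agents_append(a, type = spec[1], site = sites,
                           compartment = COMP_LN, gen = 0L, gen_target = gt,
                           stim_start = t_h,
                           next_div = t_h + cfg$stim_threshold_h)
      occ[sites] <- idx
    }
  }
  # programmed expansion: no division before 19-24 h of stimulation
  # (threshold 20 h), then doubling each division period up to the target
  per <- ifelse(a$type == TYPE_TREG, cfg$div_period_treg_h, cfg$div_period_h)
  expanding <- which(a$alive & a$compartment == COMP_LN & !a$effector &
                       !is.na(a$next_div) & t_h >= a$next_div &
                       a$gen < a$gen_target)
  if (length(expanding)) {
    fs <- free_ln()
    if (length(expanding) > length(fs))
      expanding <- expanding[seq_len(length(fs))] # space-limited; retry later
    if (length(expanding)) {
      sites <- fs[sample.int(length(fs), length(expanding))]
      a$gen[expanding] <- a$gen[expanding] + 1L
      a$next_div[expanding] <- t_h + per[expanding]
      idx <- agents_append(a, type = a$type[expanding], site = sites,
                           compartment = COMP_LN,
                           gen = a$gen[expanding],
                           gen_target = a$gen_target[expanding],
                           stim_start = a$stim_start[expanding],
                           next_div = t_h + per[expanding])
      occ[sites] <- idx
    }
  }
  done <- a$alive & a$compartment == COMP_LN & !a$effector &
    a$gen_target > 0 & a$gen >= a$gen_target
  a$effector[done] <- TRUE
  # memory maintenance and IL-2-driven lymph-node Treg proliferation
  eff <- which(a$alive & a$compartment == COMP_LN & a$effector)
  if (length(eff)) {
    p_mem_treg <- if (is.null(cfg$p_mem_treg)) cfg$p_mem else cfg$p_mem_treg
    p_mem <- ifelse(a$type[eff] == TYPE_TREG,
                    pmin(1, p_mem_treg + (1 - anti_il2) * cfg$p_div_treg_il2 *
                           hill_activation(il2_ln, cfg$h_il2_ln)),
                    cfg$p_mem)
    div <- eff[stats::runif(length(eff)) < p_mem]
    if (length(div)) {
      fs <- free_ln()
      if (length(div) > length(fs)) div <- div[seq_len(length(fs))]
      if (length(div)) {
        sites <- fs[sample.int(length(fs), length(div))]
        idx <- agents_append(a, type = a$type[div], site = sites,
                             compartment = COMP_LN, gen = a$gen[div],
                             gen_target = a$gen_target[div], effector = TRUE)
        occ[sites] <- idx
      }
    }
    dies <- eff[stats::runif(length(eff)) < cfg$p_die_ln]
    if (length(dies)) {
      occ[a$site[dies]] <- 0L
      a$alive[dies] <- FALSE
      a$site[dies] <- 0L
    }
  }
  occ
}

#' Infiltrate effector T cells from the lymph node into the tumor
#'
#' Each step a rate-limited, uniformly sampled subset of lymph-node effector
#' cells relocates through the lymphatic vessel to empty tumor-side entry
#' sites; their coordinates are updated immediately and their compartment
#' flips. Cells that find no empty entry site remain queued in the node and
#' are retried next step.
#'
#' @param a Agent population.
#' @param occ Occupancy array.
#' @param lattice A [make_lattice()] result.
#' @param rate_ctl,rate_treg Maximum cells of each type moved per step.
#' @return List with updated `occ` and the counts `n_ctl`, `n_treg` moved.
#' @export
infiltrate <- function(a, occ, lattice, rate_ctl = 2, rate_treg = 1) {
  entry <- lattice$entry_sites
  moved <- c(0L, 0L)
  for (k in 1:2) {
    ty <- if (k == 1) TYPE_CTL else TYPE_TREG
    rate <- if (k == 1) rate_ctl else rate_treg
    if (rate <= 0) next
    pool <- which(a$alive & a$compartment == COMP_LN & a$effector &
                    a$type == ty)
    if (!length(pool)) next
    sel <- if (length(pool) > rate)
      pool[sample.int(length(pool), rate)] else pool
    for (i in sel) {
      freee <- entry[occ[entry] == 0L]
      if (!length(freee)) break # queued; retried next step
      tgt <- freee[sample.int(length(freee), 1)]
      occ[a$site[i]] <- 0L
      occ[tgt] <- i
      a$site[i] <- tgt
      a$compartment[i] <- COMP_TUMOR
      moved[k] <- moved[k] + 1L
    }
  }
  list(occ = occ, n_ctl = moved[1], n_treg = moved[2])
}
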