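# Agent type codes (shared with the C++ kernel)
TYPE_PC <- 1L
TYPE_TAM <- 2L
TYPE_CTL <- 3L
TYPE_TREG <- 4L

COMP_TUMOR <- 0L
COMP_LN <- 1L

#' Create an empty agent population
#'
#' Agents are stored as parallel vectors (structure-of-arrays): lattice site
#' (1-based linear index, 0 = removed), type, compartment, and the
#' type-specific state used by tumor cells (resistance) and T cells
#' (activation program, generation counters, effector/suppression flags).
#'
#' @return An environment holding the agent vectors.
#' @export
agents_new <- function() {
  a <- new.env(parent = emptyenv())
  a$type <- integer(0); a$site <- integer(0); a$alive <- logical(0)
  a$compartment <- integer(0)
  a$resistant <- logical(0)
  a$effector <- logical(0); a$suppressed <- logical(0)
  a$gen <- integer(0); a$gen_target <- integer(0)
  a$stim_start <- numeric(0); a$next_div <- numeric(0)
  a
}

#' Append agents to a population
#'
#' @param a An [agents_new()] environment.
#' @param type,site,compartment Vectors (recycled to the longest).
#' @param resistant,effector,gen,gen_target,stim_start,next_div Optional
#'   state; sensible defaults otherwise.
#' @return Invisibly, the indices of the appended agents.
#' @export
agents_append <- function(a, type, site, compartment = COMP_TUMOR,
                          resistant = FALSE, effector = FALSE,
                          gen = 0L, gen_target = 0L,
                          stim_start = NA_real_, next_div = NA_real_) {
  n <- max(length(type), length(site))
  idx <- length(a$type) + seq_len(n)
  a$type <- c(a$type, rep_len(as.integer(type), n))
  a$site <- c(a$site, rep_len(as.integer(site), n))
  a$alive <- c(a$alive, rep_len(TRUE, n))
  a$compartment <- c(a$compartment, rep_len(as.integer(compartment), n))
  a$resistant <- c(a$resistant, rep_len(resistant, n))
  a$effector <- c(a$effector, rep_len(effector, n))
  a$suppressed <- c(a$suppressed, rep_len(FALSE, n))
  a$gen <- c(a$gen, rep_len(as.integer(gen), n))
  a$gen_target <- c(a$gen_target, rep_len(as.integer(gen_target), n))
  a$stim_start <- c(a$stim_start, rep_len(stim_start, n))
  a$next_div <- c(a$next_div, rep_len(next_div, n))
  invisible(idx)
}

# Drop dead agents and rewrite occupancy ids accordingly.
agents_compact <- function(a, occ) {
  keep <- a$alive
  if (all(keep)) return(occ)
  for (f in c("type", "site", "alive", "compartment", "resistant", "effector",
              "suppressed", "gen", "gen_target", "stim_start", "next_div"))
    assign(f, get(f, envir = a)[keep], envir = a)
  occ[] <- 0L
  placed <- which(a$site > 0)
  occ[a$site[placed]] <- placed
  occ
}

agents_count <- function(a, type, compartment = NULL) {
  sel <- a$alive & a$type == type
  if (!is.null(compartment)) sel <- sel & a$compartment == compartment
  sum(sel)
}

#' Propose a move or division placement for one agent
#'
#' Reference implementation of the spatial dispersal rule: enumerate the
#' empty sites within Chebyshev distance `R` of the agent (R = 2 for
#' migration, R = 1 for proliferation placement), score each candidate by
#' \deqn{M = w_{dist}(1/|d|) \cdot w_{occ}(1/(1+\#occupied)) \cdot w_{type}}
#' optionally boosted toward candidates whose neighborhoods hold more agents
#' of a chemotactic target type, and sample one candidate with probability
#' proportional to its score. The returned `accept` value (the candidate's
#' score clamped to `[0, 1]`) is the probability with which the engine
#' accepts the move; with a single candidate the agent relocates with
#' probability `M` and stays otherwise.
#'
#' @param site Agent's current site (1-based linear index).
#' @param R Search radius in sites (1 or 2).
#' @param occ Integer occupancy array (0 = empty, else agent id).
#' @param region Region label array; candidates must share the agent's
#'   region.
#' @param type Agent type vector (for neighbor-type weighting).
#' @param self_type This agent's type code.
#' @param wtype 4x4 occupant-type weight matrix (default all 1).
#' @param chemo_type Target type code for chemotactic bias (0 = none).
#' @param chemo_w Chemotactic weight per neighboring target agent.
#' @param grad_field Optional chemoattractant field; candidates are
#'   additionally weighted by `(field + 1e-12)^grad_gamma`, giving
#'   scale-free long-range gradient climbing. The acceptance probability
#'   keeps the dispersal-rule weights only.
#' @param grad_gamma Gradient-climbing gain (0 = off).
#' @return `NULL` if no empty candidate exists, else a list with the chosen
#'   `site`, its `accept` probability, and the full candidate table
#'   (`sites`, `weights`).
#' @export
propose_placement <- function(site, R, occ, region, type,
                              self_type = TYPE_PC,
                              wtype = matrix(1, 4, 4),
                              chemo_type = 0L, chemo_w = 0,
                              grad_field = NULL, grad_gamma = 0) {
  stopifnot(R %in% c(1L, 2L))
  d <- dim(occ)
  s0 <- site - 1L
  z0 <- s0 %/% (d[1] * d[2]); y0 <- (s0 %/% d[1]) %% d[2]; x0 <- s0 %% d[1]
  offs <- expand.grid(dx = -R:R, dy = -R:R, dz = -R:R)
  offs <- offs[!(offs$dx == 0 & offs$dy == 0 & offs$dz == 0), ]
  x <- x0 + offs$dx; y <- y0 + offs$dy; z <- z0 + offs$dz
  ok <- x >= 0 & x < d[1] & y >= 0 & y < d[2] & z >= 0 & z < d[3]
  offs <- offs[ok, ]; x <- x[ok]; y <- y[ok]; z <- z[ok]
  cand <- 1L + x + d[1] * (y + d[2] * z)
  ok <- occ[cand] == 0L & region[cand] == region[site]
  offs <- offs[ok, ]; cand <- cand[ok]
  if (!length(cand)) return(NULL)
  w <- vapply(seq_along(cand), function(i) {
    cd <- max(abs(offs$dx[i]), abs(offs$dy[i]), abs(offs$dz[i]))
    nb <- neighbor_ids(cand[i], occ)
    nocc <- length(nb)
    tw <- if (nocc) prod(wtype[self_type, type[nb]]) else 1
    ntarget <- if (chemo_type > 0) sum(type[nb] == chemo_type) else 0
    (1 / cd) * (1 / (1 + nocc)) * tw * (1 + chemo_w * ntarget)
  }, numeric(1))
  wsel <- w
  if (!is.null(grad_field) && grad_gamma > 0)
    wsel <- w * (grad_field[cand] + 1e-12)^grad_gamma
  if (sum(wsel) <= 0) return(NULL)
  pick <- sample.int(length(cand), 1, prob = wsel)
  list(site = cand[pick], accept = min(1, w[pick]),
       sites = cand, weights = wsel / sum(wsel))
}

# ids of agents on the 26-neighborhood of a site
neighbor_ids <- function(site, occ) {
  d <- dim(occ)
  s0 <- site - 1L
  z0 <- s0 %/% (d[1] * d[2]); y0 <- (s0 %/% d[1]) %% d[2]; x0 <- s0 %% d[1]
  offs <- expand.grid(dx = -1:1, dy = -1:1, dz = -1:1)
  offs <- offs[!(offs$dx == 0 & offs$dy == 0 & offs$dz == 0), ]
  x <- x0 + offs$dx; y <- y0 + offs$dy; z <- z0 + offs$dz
  ok <- x >= 0 & x < d[1] & y >= 0 & y < d[2] & z >= 0 & z < d[3]
  ids <- occ[1L + x[ok] + d[1] * (y[ok] + d[2] * z[ok])]
  ids[ids != 0L]
}

#' Tumor-cell step probabilities
#'
#' The per-2h proliferation probability combines the androgen-dependent
#' pathway (a Hill function of tissue androgen) and the androgen-independent
#' pathway (the WNT5A/EGF signaling fold change), clamped to `[0, 1]`:
#' \deqn{p = clamp(p_{AD} \cdot hill(A, H_{AD}) + p_{AI} \cdot fold(W, E))}
#' Resistant cells sense `max(A, a_auto)`: intracellular DHT synthesis
#' restores androgen-receptor signaling regardless of the castrate tissue
#' level. The death probability rises as androgen-receptor signaling falls
#' below its pre-treatment level. Cells within the perivascular bonus mask
#' proliferate faster by `vasc_bonus`.
#'
#' @param wnt5a_dose,egf_dose Normalized local ligand doses in `[0, 1]`.
#' @param androgen_tissue Tissue androgen (fraction of pre-treatment).
#' @param resistant Logical vector: androgen-independent cells.
#' @param vascular Logical vector: within the perivascular bonus region.
#' @param cfg The `pc` block of [hmsm_config()].
#' @param signaling The `signaling` block (ODE parameters + basal offset).
#' @param d1_block,d2_block Pathway blockade fractions (anti-WNT5A acts
#'   upstream on the dose; the EGFR inhibitor sets `d2_block`).
#' @return List with vectors `p_div` and `p_die`.
#' @export
pc_step_probs <- function(wnt5a_dose, egf_dose, androgen_tissue, resistant,
                          vascular, cfg, signaling,
                          d1_block = 0, d2_block = 0) {
  a_eff <- ifelse(resistant, pmax(androgen_tissue, cfg$a_auto), androgen_tissue)
  h <- hill_activation(a_eff, cfg$h_ad)
  h0 <- hill_activation(1, cfg$h_ad)
  fold <- prolif_fold_ss(wnt5a_dose, egf_dose, signaling$params,
                         d1_block, d2_block, signaling$basal)
  p_div <- pmin(1, pmax(0, cfg$p_div_ad * h + cfg$p_div_ai * fold)) *
    ifelse(vascular, 1 + cfg$vasc_bonus, 1)
  p_die <- cfg$p_die0 + cfg$p_die_castrate * pmax(0, (h0 - h) / h0)
  list(p_div = pmin(1, p_div), p_die = pmin(1, p_die))
}

#' Single tumor-cell fate decision
#'
#' Rolls the dice against the computed probability thresholds and returns
#' one action. Division requires an empty adjacent (R = 1) site; without
#' space the cell is demoted to the migrate/quiesce path.
#'
#' @param p_div,p_die,p_mig Step probabilities.
#' @param has_space Is there an empty R = 1 neighbor site?
#' @return One of `"die"`, `"divide"`, `"migrate"`, `"quiesce"`,
#'   `"persist"`.
#' @export
pc_decide <- function(p_div, p_die, p_mig, has_space = TRUE) {
  if (stats::runif(1) < p_die) return("die")
  if (stats::runif(1) < p_div) {
    if (has_space) return("divide")
    return(if (stats::runif(1) < p_mig) "migrate" else "quiesce")
  }
  if (stats::runif(1) < p_mig) return("migrate")
  "persist"
}

#' Per-step probability of switching to androgen independence
#'
#' Zero before castration; afterwards the probability ramps linearly with
#' time since castration up to a cap, calibrated so the resistant fraction
#' of a surviving cohort becomes dominant around two weeks after castration.
#' The switch is one-way.
#'
#' @param t_since_castration_h Hours since castration (may be a vector).
#' @param rate Plateau per-step switch probability.
#' @param ramp_h Ramp duration (hours).
#' @return Switch probabilities.
#' @export
pc_resistance_switch_prob <- function(t_since_castration_h, rate = 0.005,
                                      ramp_h = 336) {
  ifelse(t_since_castration_h <= 0, 0,
         rate * pmin(1, t_since_castration_h / ramp_h))
}

#' Macrophage recruitment/division probability
#'
#' Basal turnover plus a CSF1-driven Hill term; CSF1R blockade (PLX) scales
#' the CSF1-driven term by `1 - efficacy`, leaving basal recruitment
#' untouched.
#'
#' @param csf1_local Local CSF1 concentration (vectorized).
#' @param cfg The `tam` block of [hmsm_config()].
#' @param plx_efficacy CSF1R-inhibitor efficacy in `[0, 1]`.
#' @return Per-step division probabilities.
#' @export
tam_division_prob <- function(csf1_local, cfg, plx_efficacy = 0) {
  pmin(1, cfg$p_div_basal +
         (1 - plx_efficacy) * cfg$p_div_csf1 *
           hill_activation(csf1_local, cfg$h_csf1))
}

#' CTL per-contact kill probability
#'
#' Tumor-resident effector CTLs lyse adjacent tumor cells; the
#' immunosuppressive cytokine IL10 reduces killing through a Hill term, and
#' a regulatory-T-cell suppression contact blocks it entirely for the step.
#'
#' @param il10_local Local IL10 concentration (vectorized).
#' @param cfg The `ctl` block of [hmsm_config()].
#' @param suppressed Logical vector of suppression flags.
#' @return Kill probabilities.
#' @export
ctl_kill_prob <- function(il10_local, cfg, suppressed = FALSE) {
  p <- cfg$p_kill * (1 - cfg$s_il10 * hill_activation(il10_local, cfg$h_il10))
  ifelse(suppressed, 0, pmax(0, p))
}

#' Regulatory-T-cell division probability in the tumor
#'
#' Basal rate plus TRAIL- and IL-2-driven Hill terms; IL-2 neutralization
#' scales the IL-2 term by `1 - efficacy`.
#'
#' @param trail_local,il2_local Local concentrations (vectorized).
#' @param cfg The `treg` block of [hmsm_config()].
#' @param anti_il2_efficacy IL-2 neutralization efficacy in `[0, 1]`.
#' @return Per-step division probabilities.
#' @export
treg_division_prob <- function(trail_local, il2_local, cfg,
                               anti_il2_efficacy = 0) {
  pmin(1, cfg$p_div_basal +
         cfg$p_div_trail * hill_activation(trail_local, cfg$h_trail) +
         (1 - anti_il2_efficacy) * cfg$p_div_il2 *
           hill_activation(il2_local, cfg$h_il2))
}
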