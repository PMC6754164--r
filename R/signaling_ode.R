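#' Hill activation function
#'
#' Saturating activation \eqn{x / (H + x)} used throughout the model for
#' ligand-receptor and downstream signal transduction. Strictly increasing in
#' `x`, equal to 1/2 at `x = H`, and approaching 1 as `x` grows.
#'
#' @param x Non-negative activity or concentration level (vectorized).
#' @param H Half-saturation constant, strictly positive.
#' @return Activation fraction in `[0, 1)`.
#' @examples
#' hill_activation(0, 0.5)   # 0
#' hill_activation(1, 1)     # 0.5
#' @export
hill_activation <- function(x, H) {
  if (any(H <= 0)) stop("hill_activation: half-saturation H must be > 0")
  if (any(x < 0)) stop("hill_activation: x must be non-negative")
  x / (H + x)
}

#' Rate constants of the androgen-independent signaling ODE system
#'
#' The intracellular cascade WNT5A -> ERK -> AR and EGF -> Skp2 -> AKT -> AR
#' -> proliferation is parameterized by maximal rates `k1..k6` (1/min),
#' half-saturation constants `H1..H6` (dimensionless activity units) and
#' first-order decay rates `d1..d5` (1/min). All must be strictly positive.
#' Six distinct half-saturation constants are used, one per Hill term
#' (`H6` gates proliferation on AR).
#'
#' @param k1,k2,k3,k4,k5,k6 Maximal activation rates (1/min).
#' @param H1,H2,H3,H4,H5,H6 Half-saturation constants.
#' @param d1,d2,d3,d4,d5 Decay rates (1/min).
#' @return A named numeric vector of class `"ode_params"`.
#' @export
ode_params <- function(k1, k2, k3, k4, k5, k6,
                       H1, H2, H3, H4, H5, H6,
                       d1, d2, d3, d4, d5) {
  p <- c(k1 = k1, k2 = k2, k3 = k3, k4 = k4, k5 = k5, k6 = k6,
         H1 = H1, H2 = H2, H3 = H3, H4 = H4, H5 = H5, H6 = H6,
         d1 = d1, d2 = d2, d3 = d3, d4 = d4, d5 = d5)
  if (any(!is.finite(p)) || any(p <= 0))
    stop("ode_params: all rate constants must be finite and > 0")
  class(p) <- "ode_params"
  p
}

param_names_ode <- function() {
  c(paste0("k", 1:6), paste0("H", 1:6), paste0("d", 1:5))
}

as_ode_params <- function(x) {
  x <- unlist(x)[param_names_ode()]
  if (any(is.na(x))) stop("parameter vector must contain k1..k6, H1..H6, d1..d5")
  do.call(ode_params, as.list(x))
}

#' Calibrated default signaling parameters
#'
#' The parameter set shipped with the package. Decay rates of 0.2/min give
#' single-stage time constants of 5 min, so the five-stage cascade settles to
#' within 5% of its steady state inside a simulated hour under constant
#' stimulation; gains are chosen so normalized activities stay of order one.
#'
#' @return An [ode_params()] vector.
#' @export
default_signaling_params <- function() {
  ode_params(k1 = 0.4, k2 = 0.4, k3 = 0.4, k4 = 0.2, k5 = 0.2, k6 = 0.4,
             H1 = 0.3, H2 = 0.3, H3 = 1.0, H4 = 1.0, H5 = 1.0, H6 = 0.5,
             d1 = 0.2, d2 = 0.2, d3 = 0.2, d4 = 0.2, d5 = 0.2)
}

#' Ligand input for the signaling system
#'
#' Doses are dimensionless in `[0, 1]`; 1 is the maximal experimental dose
#' (250 ng/mL WNT5A, 50 ng/mL EGF).
#'
#' @param wnt5a,egf Doses in `[0, 1]`.
#' @return Named numeric vector of class `"ligand_input"`.
#' @export
ligand_input <- function(wnt5a = 0, egf = 0) {
  if (wnt5a < 0 || wnt5a > 1 || egf < 0 || egf > 1)
    stop("ligand doses must lie in [0, 1]")
  structure(c(wnt5a = wnt5a, egf = egf), class = "ligand_input")
}

#' Pathway inhibition state
#'
#' `d1_block` scales down the WNT5A/ERK branch into AR, `d2_block` the
#' EGF/AKT branch (e.g. an EGFR inhibitor); 0 = no drug, 1 = complete
#' blockade. Both are held constant over an integration.
#'
#' @param d1_block,d2_block Blockade fractions in `[0, 1]`.
#' @return Named numeric vector of class `"inhibition_state"`.
#' @export
inhibition_state <- function(d1_block = 0, d2_block = 0) {
  if (d1_block < 0 || d1_block > 1 || d2_block < 0 || d2_block > 1)
    stop("inhibition fractions must lie in [0, 1]")
  structure(c(d1_block = d1_block, d2_block = d2_block),
            class = "inhibition_state")
}

#' Signaling state vector
#'
#' Non-negative activity levels of ERK, Skp2, AKT, AR and the proliferation
#' readout.
#'
#' @param erk,skp2,akt,ar,prol Activity levels, all `>= 0`.
#' @return Named numeric vector of class `"signaling_state"`.
#' @export
signaling_state <- function(erk = 0, skp2 = 0, akt = 0, ar = 0, prol = 0) {
  s <- c(erk = erk, skp2 = skp2, akt = akt, ar = ar, prol = prol)
  if (any(s < 0)) stop("signaling state components must be non-negative")
  class(s) <- "signaling_state"
  s
}

#' Right-hand side of the signaling ODE system
#'
#' Implements the cascade
#' \deqn{dERK/dt = k_1 W/(H_1+W) - d_1 ERK}
#' \deqn{dSkp2/dt = k_2 E/(H_2+E) - d_2 Skp2}
#' \deqn{dAKT/dt = k_3 Skp2/(H_3+Skp2) - d_3 AKT}
#' \deqn{dAR/dt = (1-D_1) k_4 ERK/(H_4+ERK) + (1-D_2) k_5 AKT/(H_5+AKT) - d_4 AR}
#' \deqn{dProl/dt = k_6 AR/(H_6+AR) - d_5 Prol}
#'
#' @param state A [signaling_state()] (or named numeric with the same names).
#' @param params An [ode_params()] vector.
#' @param ligands A [ligand_input()].
#' @param inhib An [inhibition_state()].
#' @return Named numeric vector of derivatives (1/min).
#' @export
signaling_rhs <- function(state, params, ligands, inhib = inhibition_state()) {
  p <- params; s <- state
  c(erk  = p[["k1"]] * hill_activation(ligands[["wnt5a"]], p[["H1"]]) -
           p[["d1"]] * s[["erk"]],
    skp2 = p[["k2"]] * hill_activation(ligands[["egf"]], p[["H2"]]) -
           p[["d2"]] * s[["skp2"]],
    akt  = p[["k3"]] * hill_activation(s[["skp2"]], p[["H3"]]) -
           p[["d3"]] * s[["akt"]],
    ar   = (1 - inhib[["d1_block"]]) * p[["k4"]] *
             hill_activation(s[["erk"]], p[["H4"]]) +
           (1 - inhib[["d2_block"]]) * p[["k5"]] *
             hill_activation(s[["akt"]], p[["H5"]]) -
           p[["d4"]] * s[["ar"]],
    prol = p[["k6"]] * hill_activation(s[["ar"]], p[["H6"]]) -
           p[["d5"]] * s[["prol"]])
}

#' Integrate the signaling system over time
#'
#' Solves the initial-value problem with a stiff-capable integrator
#' ([deSolve::lsoda]) on a user-supplied time grid.
#'
#' @param params An [ode_params()] vector.
#' @param ligands A [ligand_input()] (held constant).
#' @param inhib An [inhibition_state()].
#' @param times Strictly increasing time grid starting at 0.
#' @param init Initial [signaling_state()]; defaults to all-zero (quiescent
#'   cell at stimulation onset).
#' @param rtol,atol Integrator tolerances.
#' @param time_unit `"min"` (default) or `"h"`; hours are converted to
#'   minutes internally.
#' @return A data frame with columns `t_min, erk, skp2, akt, ar, prol`.
#' @export
integrate_signaling <- function(params, ligands, inhib = inhibition_state(),
                                times = seq(0, 420, by = 2),
                                init = signaling_state(),
                                rtol = 1e-8, atol = 1e-10,
                                time_unit = c("min", "h")) {
  time_unit <- match.arg(time_unit)
  if (time_unit == "h") times <- times * 60
  if (length(times) < 2 || times[1] != 0 || any(diff(times) <= 0))
    stop("times must be strictly increasing and start at 0")
  deriv <- function(t, y, parms) {
    # the solver may probe marginally negative states; clamp for the Hill
    # terms so non-negativity of the system is preserved numerically
    list(unname(signaling_rhs(pmax(y, 0), params, ligands, inhib)))
  }
  out <- deSolve::lsoda(y = unclass(init), times = times, func = deriv,
                        parms = NULL, rtol = rtol, atol = atol)
  if (attr(out, "istate")[1] < 0)
    stop(sprintf(
      "signaling integration failed (istate = %d) for params [%s]",
      attr(out, "istate")[1], paste(signif(unclass(params), 3), collapse = ", ")))
  df <- as.data.frame(out)
  names(df) <- c("t_min", "erk", "skp2", "akt", "ar", "prol")
  class(df) <- c("signaling_traj", class(df))
  df
}

#' Closed-form steady state under constant stimulation
#'
#' Composes the per-stage fixed points of the cascade:
#' `ERK* = (k1/d1) hill(W, H1)` and so on down to the proliferation readout.
#'
#' @inheritParams integrate_signaling
#' @return A [signaling_state()] vector.
#' @export
signaling_steady_state <- function(params, ligands,
                                   inhib = inhibition_state()) {
  p <- params
  erk <- p[["k1"]] / p[["d1"]] * hill_activation(ligands[["wnt5a"]], p[["H1"]])
  skp2 <- p[["k2"]] / p[["d2"]] * hill_activation(ligands[["egf"]], p[["H2"]])
  akt <- p[["k3"]] / p[["d3"]] * hill_activation(skp2, p[["H3"]])
  ar <- ((1 - inhib[["d1_block"]]) * p[["k4"]] * hill_activation(erk, p[["H4"]]) +
         (1 - inhib[["d2_block"]]) * p[["k5"]] * hill_activation(akt, p[["H5"]])) /
        p[["d4"]]
  prol <- p[["k6"]] / p[["d5"]] * hill_activation(ar, p[["H6"]])
  signaling_state(erk = erk, skp2 = skp2, akt = akt, ar = ar, prol = prol)
}

#' Proliferation fold change relative to no stimulation
#'
#' Integrates the system under the given ligands and under a paired zero-dose
#' baseline with identical parameters and initial state, and returns the
#' ratio of the proliferation readout at the horizon. Because an unstimulated
#' quiescent cell has a zero readout, a fixed basal proliferation offset
#' (default 0.01) is added to numerator and denominator; the fold change is
#' exactly 1 at zero dose or under complete blockade of both branches.
#'
#' @inheritParams integrate_signaling
#' @param horizon_min Evaluation horizon in minutes (default 72 h).
#' @param basal Basal proliferation offset added to both arms, `> 0`.
#' @return Scalar fold change `>= 0`.
#' @export
proliferation_fold_change <- function(params, ligands,
                                      inhib = inhibition_state(),
                                      horizon_min = 72 * 60,
                                      init = signaling_state(),
                                      basal = 0.01, rtol = 1e-8, atol = 1e-10) {
  if (basal < 0) stop("basal offset must be >= 0")
  times <- c(0, horizon_min)
  stim <- integrate_signaling(params, ligands, inhib, times, init, rtol, atol)
  base <- integrate_signaling(params, ligand_input(0, 0), inhib, times, init,
                              rtol, atol)
  num <- stim$prol[nrow(stim)] + basal
  den <- base$prol[nrow(base)] + basal
  if (den < 1e-12)
    stop("degenerate zero baseline: increase the basal proliferation offset")
  num / den
}

#' Fast quasi-steady-state proliferation fold change
#'
#' Vectorized closed-form version of [proliferation_fold_change()] used by
#' the agent layer: the cascade settles well within one 2-hour decision step,
#' so each tumor cell's proliferation readout is taken at the steady state
#' implied by its current local ligand doses.
#'
#' @param wnt5a,egf Ligand doses in `[0, 1]` (vectorized, equal length or
#'   scalar).
#' @param params An [ode_params()] vector.
#' @param d1_block,d2_block Branch blockade fractions.
#' @param basal Basal proliferation offset (see
#'   [proliferation_fold_change()]).
#' @return Numeric vector of fold changes `>= 1` when doses are
#'   non-negative.
#' @export
prolif_fold_ss <- function(wnt5a, egf, params = default_signaling_params(),
                           d1_block = 0, d2_block = 0, basal = 0.01) {
  p <- params
  erk <- p[["k1"]] / p[["d1"]] * hill_activation(wnt5a, p[["H1"]])
  skp2 <- p[["k2"]] / p[["d2"]] * hill_activation(egf, p[["H2"]])
  akt <- p[["k3"]] / p[["d3"]] * hill_activation(skp2, p[["H3"]])
  ar <- ((1 - d1_block) * p[["k4"]] * hill_activation(erk, p[["H4"]]) +
         (1 - d2_block) * p[["k5"]] * hill_activation(akt, p[["H5"]])) / p[["d4"]]
  prol <- p[["k6"]] / p[["d5"]] * hill_activation(ar, p[["H6"]])
  (prol + basal) / basal
}

#' Write a fitted or default parameter set as flat YAML
#' @param params An [ode_params()] vector.
#' @param path Output file path.
#' @export
write_params_yaml <- function(params, path) {
  yaml::write_yaml(as.list(unclass(params)), path)
  invisible(path)
}

#' Read a parameter set written by [write_params_yaml()]
#' @param path Input file path.
#' @return An [ode_params()] vector.
#' @export
read_params_yaml <- function(path) {
  as_ode_params(yaml::read_yaml(path))
}

#' Export a signaling trajectory as CSV
#'
#' Header is `t_min,erk,skp2,akt,ar,prol`.
#' @param traj Result of [integrate_signaling()].
#' @param path Output file path.
#' @export
write_trajectory_csv <- function(traj, path) {
  utils::write.csv(traj[, c("t_min", "erk", "skp2", "akt", "ar", "prol")],
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
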