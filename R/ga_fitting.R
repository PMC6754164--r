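#' Protein time-course observation set
#'
#' Validates a table of observed, `[0, 1]`-normalized protein activities used
#' to fit the signaling parameters. Observations come from single-ligand
#' stimulation experiments (WNT5A-only or EGF-only), sampled on the design
#' grid {0, 30, 60, 420} minutes; Skp2 is informative only at 30 and 60 min
#' (its expression does not separate from control later), so Skp2 rows are
#' restricted to those two times.
#'
#' @param df Data frame with columns `protein` (one of `ERK`, `Skp2`, `AKT`,
#'   `AR`), `t_min`, `condition` (`"wnt5a"` or `"egf"`), `dose` in `[0, 1]`,
#'   and non-negative `value`.
#' @param times Allowed time grid (minutes).
#' @return The validated data frame, classed `"observation_set"`.
#' @export
observation_set <- function(df, times = c(0, 30, 60, 420)) {
  need <- c("protein", "t_min", "condition", "dose", "value")
  if (!all(need %in% names(df)))
    stop("observations need columns: ", paste(need, collapse = ", "))
  if (nrow(df) == 0) stop("empty observation set")
  if (!all(df$protein %in% c("ERK", "Skp2", "AKT", "AR")))
    stop("protein must be one of ERK, Skp2, AKT, AR")
  if (!all(df$t_min %in% times))
    stop("observation times must lie on the design grid {",
         paste(times, collapse = ", "), "} min")
  if (!all(df$t_min[df$protein == "Skp2"] %in% c(30, 60)))
    stop("Skp2 observations are restricted to 30 and 60 min")
  if (!all(df$condition %in% c("wnt5a", "egf")))
    stop("condition must be 'wnt5a' or 'egf'")
  if (any(df$value < 0)) stop("observed values must be non-negative")
  if (any(df$dose < 0 | df$dose > 1)) stop("doses must lie in [0, 1]")
  structure(df, class = c("observation_set", class(df)))
}

#' Genetic-algorithm configuration
#'
#' Settings for the real-coded GA used to estimate the signaling parameters.
#' Defaults: tournament selection (size 3), blend (BLX-alpha) crossover,
#' Gaussian mutation, one elite carried over unchanged. Bounds default to
#' `k, d` in `[1e-4, 1]` (1/min) and `H` in `[1e-3, 10]` on the normalized
#' activity scale.
#'
#' @param pop_size Population size (>= 2).
#' @param generations Number of generations.
#' @param p_crossover,p_mutation Per-pair crossover and per-gene mutation
#'   probabilities.
#' @param bounds Named list with `lower` and `upper` numeric vectors over
#'   the 17 parameters (k1..k6, H1..H6, d1..d5).
#' @param tournament_k Tournament size.
#' @param blend_alpha BLX-alpha crossover expansion factor.
#' @param mut_sd_frac Mutation SD as a fraction of each parameter's range.
#' @param elitism Number of elites preserved each generation.
#' @param seed Integer RNG seed; same seed, same result.
#' @return A list of class `"ga_config"`.
#' @export
ga_config <- function(pop_size = 80, generations = 60, p_crossover = 0.9,
                      p_mutation = 0.15, bounds = default_ga_bounds(),
                      tournament_k = 3, blend_alpha = 0.3, mut_sd_frac = 0.1,
                      elitism = 1, seed = 1L) {
  if (pop_size < 2) stop("population size must be at least 2")
  if (any(bounds$lower <= 0) || any(bounds$upper <= bounds$lower))
    stop("bounds must be positive with upper > lower")
  structure(list(pop_size = as.integer(pop_size),
                 generations = as.integer(generations),
                 p_crossover = p_crossover, p_mutation = p_mutation,
                 bounds = bounds, tournament_k = as.integer(tournament_k),
                 blend_alpha = blend_alpha, mut_sd_frac = mut_sd_frac,
                 elitism = as.integer(elitism), seed = as.integer(seed)),
            class = "ga_config")
}

#' @rdname ga_config
#' @export
default_ga_bounds <- function() {
  nm <- param_names_ode()
  lower <- ifelse(grepl("^H", nm), 1e-3, 1e-4)
  upper <- ifelse(grepl("^H", nm), 10, 1)
  list(lower = stats::setNames(lower, nm), upper = stats::setNames(upper, nm))
}

# Model predictions at the observation design points: one integration per
# (condition, dose) group over its pooled time grid.
predict_observations <- function(params, obs) {
  key <- paste(obs$condition, obs$dose)
  pred <- numeric(nrow(obs))
  for (g in unique(key)) {
    rows <- which(key == g)
    cond <- obs$condition[rows[1]]
    dose <- obs$dose[rows[1]]
    lig <- if (cond == "wnt5a") ligand_input(wnt5a = dose) else
      ligand_input(egf = dose)
    tt <- sort(unique(c(0, obs$t_min[rows])))
    traj <- integrate_signaling(params, lig, times = tt)
    col <- c(ERK = "erk", Skp2 = "skp2", AKT = "akt", AR = "ar")
    pred[rows] <- mapply(function(pr, t) {
      traj[[col[[pr]]]][match(t, traj$t_min)]
    }, obs$protein[rows], obs$t_min[rows])
  }
  pred
}

#' L1 fitting objective
#'
#' Sum of absolute residuals between observed protein activities and the ODE
#' model's predictions at the observed (protein, time, condition) design
#' points. Zero iff the model reproduces every observation exactly. An
#' integration failure yields `+Inf` with a warning, so the GA discards the
#' candidate.
#'
#' @param params An [ode_params()] vector (or coercible named vector).
#' @param obs An [observation_set()].
#' @return Non-negative scalar.
#' @export
l1_objective <- function(params, obs) {
  params <- as_ode_params(params)
  pred <- tryCatch(predict_observations(params, obs), error = function(e) {
    warning("objective: integration failed, returning Inf: ",
            conditionMessage(e))
    NULL
  })
  if (is.null(pred)) return(Inf)
  sum(abs(obs$value - pred))
}

#' Fit signaling parameters with a genetic algorithm
#'
#' Real-coded GA minimizing [l1_objective()]. The recorded best fitness is
#' non-increasing across generations (elitism), and the run is fully
#' deterministic given `cfg$seed`.
#'
#' @param obs An [observation_set()].
#' @param cfg A [ga_config()].
#' @return List with `params` (best [ode_params()]), `fitness` (its
#'   objective value) and `trace` (best fitness per generation).
#' @export
fit_signaling_ga <- function(obs, cfg = ga_config()) {
  obs <- observation_set(as.data.frame(obs))
  lo <- cfg$bounds$lower; hi <- cfg$bounds$upper
  np <- length(lo)
  set.seed(cfg$seed)
  pop <- matrix(stats::runif(cfg$pop_size * np, rep(lo, each = cfg$pop_size),
                             rep(hi, each = cfg$pop_size)),
                nrow = cfg$pop_size, dimnames = list(NULL, names(lo)))
  evaluate <- function(P) apply(P, 1, function(g) l1_objective(g, obs))
  fit <- evaluate(pop)
  trace <- numeric(cfg$generations)
  for (gen in seq_len(cfg$generations)) {
    ord <- order(fit)
    elite <- pop[ord[seq_len(cfg$elitism)], , drop = FALSE]
    tournament <- function() {
      cand <- sample.int(cfg$pop_size, cfg$tournament_k, replace = TRUE)
      pop[cand[which.min(fit[cand])], ]
    }
    kids <- matrix(NA_real_, cfg$pop_size, np, dimnames = list(NULL, names(lo)))
    i <- 1L
    while (i <= cfg$pop_size) {
      p1 <- tournament(); p2 <- tournament()
      if (stats::runif(1) < cfg$p_crossover) {
        # BLX-alpha: children drawn uniformly from the expanded parent span
        cmin <- pmin(p1, p2); cmax <- pmax(p1, p2)
        span <- cmax - cmin
        l <- cmin - cfg$blend_alpha * span; u <- cmax + cfg$blend_alpha * span
        c1 <- stats::runif(np, l, u); c2 <- stats::runif(np, l, u)
      } else {
        c1 <- p1; c2 <- p2
      }
      for (child in list(c1, c2)) {
        if (i > cfg$pop_size) break
        mut <- stats::runif(np) < cfg$p_mutation
        child[mut] <- child[mut] +
          stats::rnorm(sum(mut), 0, cfg$mut_sd_frac * (hi - lo)[mut])
        kids[i, ] <- pmin(pmax(child, lo), hi)
        i <- i + 1L
      }
    }
    kids[seq_len(cfg$elitism), ] <- elite
    pop <- kids
    fit <- evaluate(pop)
    trace[gen] <- min(fit)
  }
  best <- which.min(fit)
  list(params = as_ode_params(pop[best, ]),
       fitness = fit[best], trace = trace)
}

#' Generate synthetic protein time-course observations
#'
#' Stand-in fixture for Western-blot time courses: simulates the signaling
#' system from a known parameter set under each stimulation condition,
#' samples it on the design grid (Skp2 only at 30/60 min) and adds Gaussian
#' noise clipped at zero. Useful for parameter-recovery experiments and as
#' the package's synthetic observation source.
#'
#' @param true_params An [ode_params()] vector.
#' @param conditions Data frame with columns `condition`
#'   (`"wnt5a"`/`"egf"`) and `dose`; defaults to both ligands at maximal
#'   dose.
#' @param times Design time grid (minutes).
#' @param noise_sd Additive Gaussian noise SD (`>= 0`).
#' @param seed Integer RNG seed.
#' @return An [observation_set()].
#' @export
generate_synthetic_observations <- function(true_params,
                                            conditions = data.frame(
                                              condition = c("wnt5a", "egf"),
                                              dose = 1),
                                            times = c(0, 30, 60, 420),
                                            noise_sd = 0, seed = 1L) {
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  grid <- do.call(rbind, lapply(seq_len(nrow(conditions)), function(i) {
    expand.grid(protein = c("ERK", "Skp2", "AKT", "AR"), t_min = times,
                condition = conditions$condition[i], dose = conditions$dose[i],
                stringsAsFactors = FALSE)
  }))
  grid <- grid[!(grid$protein == "Skp2" & !(grid$t_min %in% c(30, 60))), ]
  rownames(grid) <- NULL
  grid$value <- predict_observations(as_ode_params(true_params), grid)
  set.seed(seed)
  grid$value <- pmax(0, grid$value + stats::rnorm(nrow(grid), 0, noise_sd))
  observation_set(grid, times = times)
}

#' Write an observation table as CSV
#'
#' Schema: `protein,t_min,condition,dose,value`.
#' @param obs An [observation_set()].
#' @param path Output file path.
#' @export
write_observations_csv <- function(obs, path) {
  utils::write.csv(as.data.frame(obs)[, c("protein", "t_min", "condition",
                                          "dose", "value")],
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read an observation table written by [write_observations_csv()]
#' @param path Input file path.
#' @return An [observation_set()].
#' @export
read_observations_csv <- function(path) {
  observation_set(utils::read.csv(path, stringsAsFactors = FALSE))
}
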