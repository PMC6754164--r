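#' Sprout initiation density along the parent vessel
#'
#' Per-column density of initial sprout positions on the normalized axis
#' `x in [0, 100]`: exactly zero on the margins `[0, 14]` and `[86, 100]`,
#' and a (truncated) normal profile in between (defaults mean 50, sd 12).
#'
#' @param x Normalized axis positions in `[0, 100]` (vectorized).
#' @param mean,sd Normal-profile parameters.
#' @return Unnormalized density values.
#' @export
sprout_init_density <- function(x, mean = 50, sd = 12) {
  ifelse(x <= 14 | x >= 86, 0, stats::dnorm(x, mean, sd))
}

#' Angiogenesis state
#'
#' Holds the sprout tip table, the per-sprout site paths, the vessel-id
#' array used for anastomosis checks, and the one-way onset/linkage flags.
#'
#' @param lattice A [make_lattice()] result.
#' @return A list of class `"angio_state"`.
#' @export
angio_state <- function(lattice) {
  structure(list(
    onset = FALSE, linked = FALSE,
    tips = data.frame(id = integer(0), x = integer(0), y = integer(0),
                      z = integer(0), age_h = numeric(0), active = logical(0),
                      steps = integer(0)),
    path_id = integer(0), path_step = integer(0), path_x = integer(0),
    path_y = integer(0), path_z = integer(0),
    vessel_id = array(0L, dim = lattice$dims),
    next_id = 1L), class = "angio_state")
}

#' Check and latch the avascular-to-vascular transition
#'
#' Angiogenesis starts once the tumor's effective diameter exceeds the
#' critical threshold (~2 mm); the flag is one-way, so later regression
#' below the threshold does not reverse it.
#'
#' @param angio An [angio_state()].
#' @param diameter_mm Current effective tumor diameter.
#' @param threshold_mm Critical diameter (default 2 mm).
#' @return Updated state.
#' @export
maybe_start_angiogenesis <- function(angio, diameter_mm, threshold_mm = 2) {
  if (!angio$onset && diameter_mm >= threshold_mm) angio$onset <- TRUE
  angio
}

#' Initialize sprouts along the parent vessel
#'
#' Samples sprout x positions from the [sprout_init_density()] profile
#' (rescaled to the tumor cube's x extent), z positions uniformly, and
#' seeds each tip one site above the parent-vessel plane.
#'
#' @param angio An [angio_state()].
#' @param lattice A [make_lattice()] result.
#' @param n Number of sprouts.
#' @param mean,sd Density profile parameters (normalized axis units).
#' @return Updated state.
#' @export
init_sprouts <- function(angio, lattice, n = 8, mean = 50, sd = 12) {
  nx <- lattice$tumor_dims[1]; nz <- lattice$tumor_dims[3]
  xs <- integer(0)
  while (length(xs) < n) { # rejection sampling from the truncated profile
    cand <- stats::rnorm(4 * n, mean, sd)
    cand <- cand[cand > 14 & cand < 86]
    xs <- c(xs, cand)
  }
  lo <- as.integer(floor(0.14 * nx)) + 1L  # first site outside the margin
  hi <- as.integer(ceiling(0.86 * nx)) - 1L
  xs <- pmax(lo, pmin(hi, as.integer(round(xs[seq_len(n)] / 100 * nx))))
  zs <- sample.int(nz, n, replace = TRUE)
  ids <- angio$next_id + seq_len(n) - 1L
  angio$next_id <- angio$next_id + n
  tips <- data.frame(id = ids, x = xs, y = 2L, z = zs, age_h = 0,
                     active = TRUE, steps = 0L)
  angio$tips <- rbind(angio$tips, tips)
  angio$path_id <- c(angio$path_id, ids)
  angio$path_step <- c(angio$path_step, rep(0L, n))
  angio$path_x <- c(angio$path_x, xs)
  angio$path_y <- c(angio$path_y, rep(2L, n))
  angio$path_z <- c(angio$path_z, zs)
  angio$vessel_id[cbind(xs, 2L, zs)] <- ids
  angio
}

# linear index helper for (x, y, z) triples
lin_idx <- function(x, y, z, dims) x + dims[1] * ((y - 1) + dims[2] * (z - 1))

#' Advance all active sprout tips one step
#'
#' Each active tip attempts a move with probability `p_move`; candidate
#' sites are the 26 lattice neighbors inside the tumor space, excluding the
#' tip's own path (a tip may not revisit its own trail). The chosen site
#' maximizes the stochastic score `lambda * (VEGF(candidate) - VEGF(tip)) +
#' noise`; with `lambda = 0` the walk is unbiased, and with vanishing noise
#' a linear gradient is climbed deterministically. Stepping onto another
#' sprout's trail closes a loop (anastomosis) and inactivates the tip.
#' Moving tips lay down trail sites; the tip consumes VEGF locally; tip age
#' accrues even when boxed in.
#'
#' @param angio An [angio_state()].
#' @param vegf VEGF (tumor-angiogenic-factor) field.
#' @param lattice A [make_lattice()] result.
#' @param dt_h Step (hours).
#' @param p_move Per-step move-attempt probability.
#' @param lambda Chemotactic gain on the VEGF gradient.
#' @param noise_sd Score noise SD.
#' @param consume VEGF amount consumed at the tip per step.
#' @return List with updated `angio` and `vegf`.
#' @export
tip_step <- function(angio, vegf, lattice, dt_h = 2, p_move = 0.35,
                     lambda = 50, noise_sd = 0.05, consume = 0.05) {
  dims <- lattice$dims
  offs <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  offs <- offs[rowSums(abs(offs)) > 0, ]
  for (i in which(angio$tips$active)) {
    angio$tips$age_h[i] <- angio$tips$age_h[i] + dt_h
    if (stats::runif(1) >= p_move) next
    tp <- angio$tips[i, ]
    cx <- tp$x + offs[, 1]; cy <- tp$y + offs[, 2]; cz <- tp$z + offs[, 3]
    ok <- cx >= 1 & cx <= dims[1] & cy >= 1 & cy <= dims[2] &
      cz >= 1 & cz <= dims[3]
    if (!any(ok)) next
    cand <- lin_idx(cx[ok], cy[ok], cz[ok], dims)
    in_tumor <- lattice$region[cand] == REGION_TUMOR
    own <- angio$vessel_id[cand] == tp$id
    cand <- cand[in_tumor & !own]
    if (!length(cand)) next # boxed in: stall, age keeps accruing
    here <- lin_idx(tp$x, tp$y, tp$z, dims)
    score <- lambda * (vegf[cand] - vegf[here]) +
      stats::rnorm(length(cand), 0, noise_sd)
    tgt <- cand[which.max(score)]
    other <- angio$vessel_id[tgt]
    s0 <- tgt - 1L
    zx <- s0 %/% (dims[1] * dims[2])
    yx <- (s0 %/% dims[1]) %% dims[2]
    xx <- s0 %% dims[1]
    angio$tips$x[i] <- xx + 1L; angio$tips$y[i] <- yx + 1L
    angio$tips$z[i] <- zx + 1L
    angio$tips$steps[i] <- tp$steps + 1L
    angio$path_id <- c(angio$path_id, tp$id)
    angio$path_step <- c(angio$path_step, tp$steps + 1L)
    angio$path_x <- c(angio$path_x, xx + 1L)
    angio$path_y <- c(angio$path_y, yx + 1L)
    angio$path_z <- c(angio$path_z, zx + 1L)
    if (other != 0L && other != tp$id) {
      angio$tips$active[i] <- FALSE # loop closed with another sprout
    } else {
      angio$vessel_id[tgt] <- tp$id
    }
    vegf[tgt] <- max(0, vegf[tgt] - consume)
  }
  list(angio = angio, vegf = vegf)
}

#' Branch eligible sprout tips
#'
#' New sprouts form only from existing tips that have not branched for at
#' least the branching age (18 h). The branching probability increases with
#' the local tumor-angiogenic-factor concentration,
#' `p = min(1, basal + c * TAF)`, reflecting that the endothelial-cell
#' density needed to support a new branch is inversely proportional to TAF.
#' Branching resets the tip age of both the parent and the new tip.
#'
#' @param angio An [angio_state()].
#' @param vegf VEGF field.
#' @param lattice A [make_lattice()] result.
#' @param branch_age_h Minimum tip age (default 18 h).
#' @param c_taf Branching gain per unit TAF.
#' @param basal Basal branching probability (default 0).
#' @return Updated state.
#' @export
branch_sprouts <- function(angio, vegf, lattice, branch_age_h = 18,
                           c_taf = 2, basal = 0) {
  dims <- lattice$dims
  for (i in which(angio$tips$active & angio$tips$age_h >= branch_age_h)) {
    tp <- angio$tips[i, ]
    taf <- vegf[lin_idx(tp$x, tp$y, tp$z, dims)]
    if (stats::runif(1) < min(1, basal + c_taf * taf)) {
      nid <- angio$next_id
      angio$next_id <- nid + 1L
      angio$tips <- rbind(angio$tips, data.frame(
        id = nid, x = tp$x, y = tp$y, z = tp$z, age_h = 0, active = TRUE,
        steps = 0L))
      angio$path_id <- c(angio$path_id, nid)
      angio$path_step <- c(angio$path_step, 0L)
      angio$path_x <- c(angio$path_x, tp$x)
      angio$path_y <- c(angio$path_y, tp$y)
      angio$path_z <- c(angio$path_z, tp$z)
      angio$tips$age_h[i] <- 0
    }
  }
  angio
}

#' Resolve anastomosis for tips standing on another sprout's trail
#'
#' A tip whose site belongs to a different sprout's path becomes inactive
#' (the loop is closed). Normally handled during [tip_step()]; exposed for
#' direct use on constructed networks.
#'
#' @param angio An [angio_state()].
#' @param lattice A [make_lattice()] result.
#' @return Updated state.
#' @export
anastomose <- function(angio, lattice) {
  dims <- lattice$dims
  for (i in which(angio$tips$active)) {
    tp <- angio$tips[i, ]
    v <- angio$vessel_id[lin_idx(tp$x, tp$y, tp$z, dims)]
    if (v != 0L && v != tp$id) angio$tips$active[i] <- FALSE
  }
  angio
}

#' Export the vessel network as CSV
#'
#' Schema: `sprout_id,step,x,y,z,active`.
#' @param angio An [angio_state()].
#' @param path Output file path.
#' @export
write_vessels_csv <- function(angio, path) {
  df <- data.frame(sprout_id = angio$path_id, step = angio$path_step,
                   x = angio$path_x, y = angio$path_y, z = angio$path_z,
                   active = angio$path_id %in%
                     angio$tips$id[angio$tips$active])
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
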