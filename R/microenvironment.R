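# Region codes used on the lattice
REGION_TUMOR <- 0L
REGION_LN <- 1L
REGION_LYMPH_VESSEL <- 2L
REGION_PARENT_VESSEL <- 3L
REGION_VOID <- 9L

#' Build the simulation lattice
#'
#' The domain is two connected boxes: a tumor cube and a lymph-node box,
#' joined by a short lymphatic-vessel conduit on the +x face of the tumor
#' cube. The y = 1 plane of the tumor cube is the parent blood vessel from
#' which angiogenic sprouts grow. At most one cell agent occupies a site;
#' agents may live only in the tumor space or the lymph node.
#'
#' @param nx,ny,nz Tumor-cube dimensions in sites.
#' @param ln_dim Lymph-node box dimensions (length-3 integer).
#' @param spacing_um Site spacing in micrometres.
#' @return A list with the full domain dims, the `region` label array,
#'   precomputed site-index sets (lymph node, infiltration entry sites,
#'   parent-vessel face) and the spacing.
#' @export
make_lattice <- function(nx = 50, ny = 50, nz = 50, ln_dim = c(20, 20, 20),
                         spacing_um = 80) {
  NX <- nx + 1L + ln_dim[1]; NY <- max(ny, ln_dim[2]); NZ <- max(nz, ln_dim[3])
  region <- array(REGION_VOID, dim = c(NX, NY, NZ))
  region[1:nx, 1:ny, 1:nz] <- REGION_TUMOR
  region[1:nx, 1, 1:nz] <- REGION_PARENT_VESSEL
  cy <- max(2L, round(ny / 2)); cz <- max(1L, round(nz / 2))
  vy <- pmax(2L, pmin(NY, cy + (-1:1))); vz <- pmax(1L, pmin(NZ, cz + (-1:1)))
  region[nx + 1L, vy, vz] <- REGION_LYMPH_VESSEL
  region[(nx + 2L):(nx + 1L + ln_dim[1]), 1:ln_dim[2], 1:ln_dim[3]] <- REGION_LN
  entry <- which(slice.index(region, 1) == nx &
                 slice.index(region, 2) %in% vy &
                 slice.index(region, 3) %in% vz &
                 region == REGION_TUMOR)
  list(dims = c(NX, NY, NZ), tumor_dims = c(nx, ny, nz), ln_dim = ln_dim,
       region = region,
       ln_sites = which(region == REGION_LN),
       entry_sites = entry,
       parent_vessel_sites = which(region == REGION_PARENT_VESSEL),
       center = c(round(nx / 2), cy, cz),
       spacing_um = spacing_um)
}

#' Create an empty cytokine concentration field
#' @param lattice A [make_lattice()] result.
#' @return A zero 3D array over the full domain.
#' @export
new_field <- function(lattice) array(0, dim = lattice$dims)

#' Diffuse and decay a cytokine field
#'
#' Explicit 7-point finite-difference diffusion with zero-flux boundaries,
#' followed by exact exponential decay. The explicit scheme requires
#' `D dt / h^2 <= 1/6`; larger steps are split into the minimal number of
#' stable substeps automatically, never integrated unstably.
#'
#' @param field 3D concentration array.
#' @param D Diffusion coefficient (sites^2 per hour).
#' @param decay First-order decay rate (1/h).
#' @param dt_h Time step (hours).
#' @return The updated field (non-negative everywhere).
#' @export
diffuse_decay <- function(field, D, decay, dt_h) {
  d <- dim(field)
  if (length(d) != 3) stop("field must be a 3D array")
  if (D < 0 || decay < 0 || dt_h <= 0) stop("D, decay must be >= 0, dt > 0")
  out <- field
  if (D > 0) {
    nsub <- max(1L, ceiling(6 * D * dt_h))
    alpha <- D * dt_h / nsub
    out <- cpp_diffuse_decay(as.numeric(field), d[1], d[2], d[3],
                             alpha, nsub, exp(-decay * dt_h))
    dim(out) <- d
  } else if (decay > 0) {
    out <- out * exp(-decay * dt_h)
  }
  out
}

#' Apply per-site secretion and consumption to a field
#'
#' Adds `rate * dt` at each secreting site and removes `consume * dt` at
#' each consuming site, clipping at zero so concentrations never go
#' negative.
#'
#' @param field 3D concentration array.
#' @param sites Linear site indices of secreting agents (may repeat).
#' @param rate Secretion rates (per hour), recycled along `sites`.
#' @param dt_h Time step (hours).
#' @param consume_sites,consume_rate Optional consuming sites and rates.
#' @return The updated field.
#' @export
secrete_consume <- function(field, sites, rate, dt_h,
                            consume_sites = integer(0), consume_rate = 0) {
  if (length(sites)) {
    add <- rep_len(rate, length(sites)) * dt_h
    if (anyDuplicated(sites)) {
      agg <- rowsum(add, sites)
      sites <- as.integer(rownames(agg)); add <- agg[, 1]
    }
    field[sites] <- field[sites] + add
  }
  if (length(consume_sites)) {
    rem <- rep_len(consume_rate, length(consume_sites)) * dt_h
    if (anyDuplicated(consume_sites)) {
      agg <- rowsum(rem, consume_sites)
      consume_sites <- as.integer(rownames(agg)); rem <- agg[, 1]
    }
    field[consume_sites] <- pmax(0, field[consume_sites] - rem)
  }
  field
}

#' Two-compartment androgen level
#'
#' Blood and tumor-tissue androgen as fractions of their pre-treatment
#' values. After castration the compartments relax exponentially to 10%
#' (blood) and 20% (tissue) of baseline; castration-resistant tumor cells
#' synthesize DHT intratumorally and pull the tissue level back up toward a
#' configurable plateau.
#'
#' @param blood,tissue Initial levels (fraction of pre-treatment).
#' @return A list of class `"androgen_state"`.
#' @export
androgen_state <- function(blood = 1, tissue = 1) {
  structure(list(blood = blood, tissue = tissue,
                 baseline_blood = blood, baseline_tissue = tissue,
                 castrated = FALSE, t_castration = NA_real_),
            class = "androgen_state")
}

#' Castrate: start androgen withdrawal
#'
#' Sets the castration flag at time `t_h`; levels then relax continuously
#' (no instantaneous jump) toward the castrate set points under
#' [androgen_step()]. Castrating twice is a warning no-op.
#'
#' @param androgen An [androgen_state()].
#' @param t_h Simulation time (hours).
#' @return Updated state.
#' @export
apply_castration <- function(androgen, t_h) {
  if (androgen$castrated) {
    warning("already castrated; ignoring")
    return(androgen)
  }
  androgen$castrated <- TRUE
  androgen$t_castration <- t_h
  androgen
}

#' Advance the androgen compartments by one step
#'
#' Exponential relaxation toward the castrate set points (time constant
#' `tau_h`, default 48 h), plus the resistant-cell DHT synthesis term from
#' [update_crpc_androgen()] when `resistant_pc_count > 0`.
#'
#' @param androgen An [androgen_state()].
#' @param dt_h Step (hours).
#' @param resistant_pc_count Number of androgen-independent tumor cells.
#' @param tau_h Relaxation time constant (hours); 0 gives a hard step.
#' @param blood_frac,tissue_frac Castrate set points as fractions of
#'   baseline (defaults 0.10 and 0.20).
#' @param dht_rate Per-hour DHT synthesis gain at saturating resistant
#'   numbers.
#' @param dht_halfsat Resistant-cell count at half-maximal synthesis.
#' @param dht_plateau Tissue androgen plateau under full CRPC re-synthesis.
#' @return Updated state.
#' @export
androgen_step <- function(androgen, dt_h, resistant_pc_count = 0,
                          tau_h = 48, blood_frac = 0.10, tissue_frac = 0.20,
                          dht_rate = 0.02, dht_halfsat = 400,
                          dht_plateau = 0.95) {
  if (!androgen$castrated) return(androgen)
  tb <- blood_frac * androgen$baseline_blood
  tt <- tissue_frac * androgen$baseline_tissue
  f <- if (tau_h > 0) 1 - exp(-dt_h / tau_h) else 1
  androgen$blood <- androgen$blood + (tb - androgen$blood) * f
  androgen$tissue <- androgen$tissue + (tt - androgen$tissue) * f
  if (resistant_pc_count > 0)
    androgen <- update_crpc_androgen(androgen, resistant_pc_count, dt_h,
                                     dht_rate, dht_halfsat, dht_plateau)
  androgen
}

#' CRPC-driven intratumoral androgen synthesis
#'
#' Resistant tumor cells synthesize DHT; the tissue level rises
#' monotonically toward `dht_plateau` at a rate saturating in the resistant
#' count. Requires castration to be active.
#'
#' @inheritParams androgen_step
#' @return Updated state.
#' @export
update_crpc_androgen <- function(androgen, resistant_pc_count, dt_h,
                                 dht_rate = 0.02, dht_halfsat = 400,
                                 dht_plateau = 0.95) {
  if (!androgen$castrated) stop("CRPC androgen synthesis requires castration")
  if (resistant_pc_count <= 0) return(androgen)
  gain <- dht_rate * resistant_pc_count / (dht_halfsat + resistant_pc_count)
  androgen$tissue <- androgen$tissue +
    gain * max(0, dht_plateau - androgen$tissue) * dt_h
  androgen
}

#' Export an axis-normal 2D slice of a field as CSV
#'
#' Follows the slice convention of reporting e.g. the Y = 40 or Y = 50
#' plane of the tumor cube.
#'
#' @param field 3D concentration array.
#' @param y Slice index along the y axis.
#' @param path Output file path.
#' @export
write_field_slice_csv <- function(field, y, path) {
  utils::write.csv(field[, y, ], path, row.names = FALSE)
  invisible(path)
}

#' Export a field snapshot with a JSON sidecar
#'
#' Writes the flattened field values plus a JSON descriptor (dims, spacing,
#' species, time) so snapshots can be reassembled elsewhere.
#'
#' @param field 3D array.
#' @param species Species name.
#' @param t_h Simulation time (hours).
#' @param spacing_um Site spacing.
#' @param path Base path; writes `<path>.txt` and `<path>.json`.
#' @export
write_field_snapshot <- function(field, species, t_h, spacing_um, path) {
  writeLines(format(as.numeric(field), digits = 8), paste0(path, ".txt"))
  jsonlite::write_json(list(dims = dim(field), spacing_um = spacing_um,
                            species = species, t_h = t_h),
                       paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}
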