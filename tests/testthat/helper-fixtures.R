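# Shared in-code fixtures: a small synthetic world and species set used
# across test files. Everything is generated at test time; nothing binary.

tiny_world <- function(nx = 24, ny = 24, years = 1981:2000, warming = 0.04,
                       noise_sd = 0.2, seed = 42) {
  dem <- make_dem(nx, ny, cell_size = 100,
                  relief = list(base_elev = 400, amplitude = 3000,
                                n_ridges = 3), seed = seed)
  climate <- make_climate_series(dem, years, warming_rate = warming,
                                 noise_sd = noise_sd, seed = seed + 1)
  list(dem = dem, years = years, climate = climate,
       insolation = make_insolation(dem))
}

mid_species <- function(name = "spA", elev = 1500, breadth = 1.5,
                        records_per_year = 15) {
  # thermal optimum matching the programmed lapse profile at `elev`
  species_spec(name, thermal_optimum = 14 - 0.0065 * elev,
               thermal_breadth = breadth, prec_optimum = 1100,
               prec_breadth = 2000, records_per_year = records_per_year)
}

# flat and inclined analytic DEMs for insolation / downscaling checks
flat_dem <- function(n = 20, value = 1000)
  oro_grid(matrix(value, n, n), cell_size = 100)

# an inclined plane; `facing` is the downslope (exposure) direction: a
# south-facing plane rises towards the north (row index grows northwards)
ramp_dem <- function(n = 20, slope_per_cell = 10,
                     facing = c("south", "north")) {
  facing <- match.arg(facing)
  rows <- seq_len(n) * slope_per_cell
  if (facing == "north") rows <- rev(rows)
  oro_grid(matrix(rows, n, n, byrow = FALSE) + 500, cell_size = 100)
}

# independent penalized-objective oracle for the maxent fit: multi-start
# Nelder-Mead on the identical objective
maxent_oracle_objective <- function(Fp, Fb, beta_j, n_starts = 5, seed = 1) {
  obj <- function(l) -(mean(Fp %*% l) - {
    s <- Fb %*% l; m <- max(s); m + log(sum(exp(s - m)))
  } - sum(beta_j * abs(l)))
  p <- ncol(Fp)
  set.seed(seed)
  best <- Inf
  for (k in seq_len(n_starts)) {
    start <- if (k == 1) rep(0, p) else stats::rnorm(p, 0, 2)
    o <- stats::optim(start, obj, method = "Nelder-Mead",
                      control = list(maxit = 5000, reltol = 1e-12))
    o <- stats::optim(o$par, obj, method = "Nelder-Mead",
                      control = list(maxit = 5000, reltol = 1e-12))
    best <- min(best, o$value)
  }
  -best
}
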