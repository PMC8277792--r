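# Synthetic mountain landscapes, warming climates and virtual species.
#
# The generator emulates the statistical structure the downstream analysis
# assumes: a high-relief DEM, monthly climate following an elevational lapse
# rate plus an interannual warming trend, insolation controlled by slope and
# aspect, and species whose occurrences track their climatic niche uphill at
# the isotherm velocity warming_rate / lapse_rate.

# run expr under a fixed RNG seed, restoring the caller's RNG state
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

#' Generate a synthetic mountain DEM
#'
#' Relief is a sum of randomly oriented cosine ridges plus a smoothed
#' Gaussian random field, optionally superimposed on a south-to-north linear
#' ramp, rescaled so elevations span exactly
#' `[base_elev, base_elev + amplitude]`. Deterministic for a fixed seed.
#'
#' The optional ramp matters for calibration experiments: a ridge-dominated
#' landscape has a lumpy hypsometry (area per elevation band), and the
#' elevation distribution of a climate-tracking species is then distorted by
#' the available area ("mountain-top squeeze"), so the expected uphill
#' velocity `warming_rate / lapse_rate` is only realized exactly on terrain
#' whose hypsometry is approximately uniform. `ramp_weight = 1` with small
#' `ridge_amp` / `noise_amp` produces such terrain.
#'
#' @param nx,ny grid dimensions (>= 16 each).
#' @param cell_size cell edge length in m.
#' @param relief list with `base_elev` (m), `amplitude` (m, > 0), `n_ridges`
#'   (number of cosine ridge components) and optionally `ramp_weight`
#'   (weight of the linear gradient, default 0), `ridge_amp` (ridge
#'   amplitude multiplier, default 1) and `noise_amp` (random-field
#'   amplitude, default 0.6).
#' @param seed integer RNG seed.
#' @return an [oro_grid] DEM.
#' @export
make_dem <- function(nx, ny, cell_size = 100,
                     relief = list(base_elev = 400, amplitude = 3400,
                                   n_ridges = 4),
                     seed = 1) {
  if (nx < 16 || ny < 16) stop("nx and ny must be >= 16", call. = FALSE)
  if (!is.finite(relief$amplitude) || relief$amplitude <= 0)
    stop("relief amplitude must be > 0", call. = FALSE)
  ramp_weight <- if (is.null(relief$ramp_weight)) 0 else relief$ramp_weight
  ridge_amp <- if (is.null(relief$ridge_amp)) 1 else relief$ridge_amp
  noise_amp <- if (is.null(relief$noise_amp)) 0.6 else relief$noise_amp
  with_seed(seed, {
    xs <- (seq_len(nx) - 0.5) / nx
    ys <- (seq_len(ny) - 0.5) / ny
    X <- matrix(xs, ny, nx, byrow = TRUE)
    Y <- matrix(ys, ny, nx)
    z <- ramp_weight * Y
    n_ridges <- max(1L, as.integer(relief$n_ridges))
    for (k in seq_len(n_ridges)) {
      theta <- stats::runif(1, 0, pi)
      freq  <- stats::runif(1, 0.5, 2.5) * pi
      phase <- stats::runif(1, 0, 2 * pi)
      amp   <- stats::runif(1, 0.5, 1) * ridge_amp
      z <- z + amp * cos(freq * (cos(theta) * X + sin(theta) * Y) * 2 + phase)
    }
    # smoothed Gaussian-field noise: white noise blurred by repeated
    # 3x3 box smoothing
    noise <- matrix(stats::rnorm(nx * ny), ny, nx)
    for (i in 1:4) noise <- box_smooth3(noise)
    z <- z + noise_amp * noise / stats::sd(noise)
    z <- (z - min(z)) / (max(z) - min(z))
    oro_grid(relief$base_elev + relief$amplitude * z, cell_size = cell_size)
  })
}

#' Relief parameters for a calibration landscape
#'
#' A ramp-dominated relief with mild ridges and noise, whose hypsometry is
#' close to uniform; used by recovery experiments where the closed-form
#' isotherm velocity is the expected uphill rate.
#'
#' @param base_elev,amplitude elevation range in m.
#' @return a relief list for [make_dem()].
#' @export
ramp_relief <- function(base_elev = 400, amplitude = 3400) {
  # hypsometric density scales with the local terrain gradient, i.e. with
  # ridge amplitude x spatial frequency; keeping that product a fraction of
  # a percent of the ramp gradient keeps the area-per-elevation-band nearly
  # uniform, which is what makes warming_rate / lapse_rate the exact
  # expected drift
  list(base_elev = base_elev, amplitude = amplitude, n_ridges = 3,
       ramp_weight = 1, ridge_amp = 0.003, noise_amp = 0.003)
}

box_smooth3 <- function(m) {
  ny <- nrow(m); nx <- ncol(m)
  p <- m[c(1, seq_len(ny), ny), c(1, seq_len(nx), nx)]
  r <- seq_len(ny) + 1L; c <- seq_len(nx) + 1L
  (p[r - 1, c - 1] + p[r - 1, c] + p[r - 1, c + 1] +
   p[r,     c - 1] + p[r,     c] + p[r,     c + 1] +
   p[r + 1, c - 1] + p[r + 1, c] + p[r + 1, c + 1]) / 9
}

#' Generate a monthly climate series over a DEM
#'
#' For year `y`, month `m` and a cell of elevation `E`, monthly mean
#' temperature is
#' `sea_level_temp + warming_rate * (y - years[1]) - lapse_rate * E +
#'  seasonal_amp * cos(2 * pi * (m - 7) / 12) + noise`,
#' with `tmin = tmean - diurnal_delta` and `tmax = tmean + diurnal_delta`.
#' Noise is a spatially constant draw per (year, month): it emulates
#' interannual weather variability, the component that matters for
#' trend-recovery analyses. Monthly precipitation follows a seasonal cycle
#' plus noise, with an optional linear elevation (orographic) gradient,
#' truncated at zero. The gradient defaults to 0 — the study design assumes
#' precipitation is at most weakly correlated with elevation; a strong
#' orographic gradient anchors part of the environmental space to static
#' terrain and attenuates the apparent uphill shift of modelled
#' distributions (see the methods vignette).
#'
#' @param dem an [oro_grid] DEM.
#' @param years integer vector of calendar years (ascending).
#' @param lapse_rate temperature lapse in degC per m (> 0; default 0.0065).
#' @param warming_rate linear warming trend in degC per year.
#' @param seasonal_amp amplitude of the seasonal temperature cycle (degC).
#' @param noise_sd s.d. of the per-(year, month) temperature noise (degC).
#' @param prec_base mean monthly precipitation at sea level (mm).
#' @param prec_elev_grad linear orographic gradient of precipitation per m
#'   of elevation (fraction of `prec_base`; default 0).
#' @param sea_level_temp annual mean temperature at elevation 0 in the first
#'   year (degC).
#' @param diurnal_delta half-width between tmin/tmax and tmean (degC).
#' @param seed integer RNG seed.
#' @return list of per-year climates, each a list with `year` and `tmin`,
#'   `tmean`, `tmax`, `prec`: 12-element lists of matrices matching the DEM.
#' @export
make_climate_series <- function(dem, years, lapse_rate = 0.0065,
                                warming_rate = 0.04, seasonal_amp = 9,
                                noise_sd = 0.3, prec_base = 90,
                                prec_elev_grad = 0,
                                sea_level_temp = 14, diurnal_delta = 5,
                                seed = 1) {
  if (!is.finite(lapse_rate) || lapse_rate <= 0)
    stop("lapse_rate must be > 0", call. = FALSE)
  if (length(years) < 1) stop("need at least one year", call. = FALSE)
  years <- as.integer(years)
  E <- dem$values
  with_seed(seed, {
    lapply(years, function(y) {
      tmean <- tmin <- tmax <- prec <- vector("list", 12L)
      for (m in 1:12) {
        season <- seasonal_amp * cos(2 * pi * (m - 7) / 12)
        eps <- stats::rnorm(1, 0, noise_sd)
        tm <- sea_level_temp + warming_rate * (y - years[1]) -
          lapse_rate * E + season + eps
        tmean[[m]] <- tm
        tmin[[m]] <- tm - diurnal_delta
        tmax[[m]] <- tm + diurnal_delta
        p <- prec_base * (1 - 0.3 * cos(2 * pi * (m - 7) / 12)) *
          (1 + prec_elev_grad * E) + stats::rnorm(1, 0, noise_sd * 5)
        prec[[m]] <- pmax(p, 0)
      }
      list(year = y, tmin = tmin, tmean = tmean, tmax = tmax, prec = prec)
    })
  })
}

# annual mean temperature and annual cumulative precipitation grids
annual_climate <- function(mc) {
  tmean <- Reduce(`+`, mc$tmean) / 12
  prec <- Reduce(`+`, mc$prec)
  list(tmean = tmean, prec = prec)
}

#' Monthly insolation proxy from terrain
#'
#' Hillshade-based proxy for monthly insolation: illumination of each cell by
#' a sun at the given elevation angle and a fixed southern azimuth (180
#' degrees, northern hemisphere), computed from Horn slope and aspect and
#' rescaled to a nominal 0-1000 (W m-2 h like) range. Flat terrain yields a
#' spatially constant layer whose value increases with sun elevation;
#' south-facing slopes score higher than north-facing ones.
#'
#' @param dem an [oro_grid] DEM.
#' @param months integer vector of months to compute (default 1:12).
#' @param sun_elevations per-month solar elevation angles in degrees; the
#'   default is the mid-latitude (47 degrees N) noon height by month.
#' @return named list of matrices (`ins_01` ... `ins_12`), one per month.
#' @export
make_insolation <- function(dem, months = 1:12,
                            sun_elevations = 43 + 23.5 *
                              cos(2 * pi * (months - 6.5) / 12)) {
  if (length(sun_elevations) != length(months))
    stop("sun_elevations must match months in length", call. = FALSE)
  sa <- slope_aspect(dem)
  azimuth <- pi  # due south
  out <- vector("list", length(months))
  names(out) <- sprintf("ins_%02d", months)
  for (k in seq_along(months)) {
    zenith <- pi / 2 - sun_elevations[k] * pi / 180
    hs <- cos(zenith) * cos(sa$slope) +
      sin(zenith) * sin(sa$slope) * cos(azimuth - sa$aspect)
    out[[k]] <- pmax(hs, 0) * 1000
  }
  out
}

#' Define a virtual species
#'
#' @param name species identifier.
#' @param thermal_optimum optimum annual mean temperature (degC).
#' @param thermal_breadth Gaussian niche s.d. on temperature (degC, > 0).
#' @param prec_optimum,prec_breadth optimum and s.d. on annual cumulative
#'   precipitation (mm).
#' @param detectability probability in (0, 1] scaling the expected number of
#'   records actually observed.
#' @param records_per_year expected number of records per year before
#'   detectability.
#' @param traits list with `euryocy` ("generalist"/"specialist"),
#'   `dispersal` ("sedentary"/"intermediate"/"mobile") and `endangerment`
#'   ("threatened"/"least_concern").
#' @return an object of class `species_spec`.
#' @export
species_spec <- function(name, thermal_optimum, thermal_breadth = 1.5,
                         prec_optimum = 1200, prec_breadth = 600,
                         detectability = 1, records_per_year = 10,
                         traits = list(euryocy = "generalist",
                                       dispersal = "intermediate",
                                       endangerment = "least_concern")) {
  stopifnot(thermal_breadth > 0, prec_breadth > 0,
            detectability > 0, detectability <= 1)
  traits$euryocy <- match.arg(traits$euryocy, c("generalist", "specialist"))
  traits$dispersal <- match.arg(traits$dispersal,
                                c("sedentary", "intermediate", "mobile"))
  traits$endangerment <- match.arg(traits$endangerment,
                                   c("threatened", "least_concern"))
  structure(list(name = name, thermal_optimum = thermal_optimum,
                 thermal_breadth = thermal_breadth,
                 prec_optimum = prec_optimum, prec_breadth = prec_breadth,
                 detectability = detectability,
                 records_per_year = records_per_year, traits = traits),
            class = "species_spec")
}

# Gaussian suitability of one species over annual climate grids
species_suitability <- function(sp, ann) {
  exp(-((ann$tmean - sp$thermal_optimum)^2) / (2 * sp$thermal_breadth^2)) *
    exp(-((ann$prec - sp$prec_optimum)^2) / (2 * sp$prec_breadth^2))
}

#' Sample virtual occurrence records
#'
#' For each species and year, the number of records is Poisson with mean
#' `records_per_year * detectability`; record cells are drawn (with
#' replacement) with probability proportional to the Gaussian climatic
#' suitability in that year's annual mean temperature and annual cumulative
#' precipitation. Coordinates are exact cell centres; elevation is read from
#' the DEM; the date is a uniform random day within the flight season.
#'
#' @param species list of [species_spec] objects.
#' @param climate list of per-year climates from [make_climate_series()].
#' @param dem an [oro_grid] DEM.
#' @param seed integer RNG seed.
#' @param season integer day-of-year window for record dates (default
#'   June-August).
#' @return data frame with columns `species`, `date` (ISO day), `x`, `y`,
#'   `elevation`, `year`.
#' @export
sample_records <- function(species, climate, dem, seed = 1,
                           season = c(152L, 243L)) {
  if (length(species) < 1) stop("need at least one species", call. = FALSE)
  if (length(climate) < 2) stop("need at least two years", call. = FALSE)
  if (inherits(species, "species_spec")) species <- list(species)
  xs <- grid_x(dem); ys <- grid_y(dem)
  nyx <- dim(dem$values)
  ann_by_year <- lapply(climate, annual_climate)
  with_seed(seed, {
    out <- list()
    for (sp in species) {
      for (k in seq_along(climate)) {
        yr <- climate[[k]]$year
        suit <- species_suitability(sp, ann_by_year[[k]]) * sp$detectability
        n <- stats::rpois(1, sp$records_per_year * sp$detectability)
        if (n == 0) next
        tot <- sum(suit)
        if (!is.finite(tot) || tot <= .Machine$double.eps) {
          warning(sprintf("species %s, year %d: no suitable area, 0 records",
                          sp$name, yr), call. = FALSE)
          next
        }
        idx <- sample.int(length(suit), n, replace = TRUE, prob = as.vector(suit))
        rc <- arrayInd(idx, nyx)
        doy <- sample(seq(season[1], season[2]), n, replace = TRUE)
        out[[length(out) + 1L]] <- data.frame(
          species = sp$name,
          date = as.Date(doy - 1L, origin = as.Date(sprintf("%d-01-01", yr))),
          x = xs[rc[, 2]], y = ys[rc[, 1]],
          elevation = dem$values[rc],
          year = yr,
          stringsAsFactors = FALSE)
      }
    }
    if (length(out) == 0)
      return(data.frame(species = character(), date = as.Date(character()),
                        x = numeric(), y = numeric(), elevation = numeric(),
                        year = integer()))
    res <- do.call(rbind, out)
    rownames(res) <- NULL
    res
  })
}

#' Write / read occurrence tables
#'
#' CSV with header `species,date,x,y,elevation` (year is re-derived from the
#' date on read).
#'
#' @param records occurrence data frame from [sample_records()].
#' @param path CSV file path.
#' @return `path` invisibly; for the reader, the occurrence data frame.
#' @export
write_occurrences <- function(records, path) {
  utils::write.csv(records[, c("species", "date", "x", "y", "elevation")],
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_occurrences
#' @export
read_occurrences <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  df$date <- as.Date(df$date)
  df$year <- as.integer(format(df$date, "%Y"))
  df
}
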