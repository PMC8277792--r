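# Record-based and model-based altitudinal statistics: extreme-record years,
# weighted medians, annual distribution summaries (range, variance-mean
# ratio, skewness) and their regression slopes against study year.

#' Variance-mean ratio of an elevation vector
#'
#' `VMR = sigma^2(h) / mu(h)` with the sample (n - 1) variance; the weighted
#' variant treats weights as frequencies normalized to the number of
#' observations, so equal weights reduce exactly to the unweighted case.
#'
#' @param h numeric vector of elevations (m).
#' @param w optional non-negative weights.
#' @return the ratio in m; `NA` for fewer than 2 observations.
#' @export
vmr <- function(h, w = NULL) {
  n <- length(h)
  if (n < 2) return(NA_real_)
  if (is.null(w)) return(stats::var(h) / mean(h))
  w <- n * w / sum(w)
  mu <- sum(w * h) / n
  s2 <- sum(w * (h - mu)^2) / (n - 1)
  s2 / mu
}

#' Adjusted Fisher-Pearson skewness
#'
#' `G1 = g1 * sqrt(n (n - 1)) / (n - 2)` with `g1 = m3 / m2^(3/2)`; the
#' weighted variant uses frequency weights normalized to the observation
#' count.
#'
#' @inheritParams vmr
#' @return unitless skewness; `NA` for fewer than 3 observations or zero
#'   variance.
#' @export
skewness_g1 <- function(h, w = NULL) {
  n <- length(h)
  if (n < 3) return(NA_real_)
  if (is.null(w)) w <- rep(1, n)
  w <- n * w / sum(w)
  mu <- sum(w * h) / n
  m2 <- sum(w * (h - mu)^2) / n
  m3 <- sum(w * (h - mu)^3) / n
  if (m2 <= 0) return(NA_real_)
  (m3 / m2^1.5) * sqrt(n * (n - 1)) / (n - 2)
}

#' Weighted quantile (cumulative rule)
#'
#' Smallest value `x` whose cumulative normalized weight reaches `p`; with
#' equal weights the 0.5 case is the lower ordinary median.
#'
#' @param x numeric values.
#' @param w non-negative weights, not all zero.
#' @param p probability in `[0, 1]`.
#' @export
weighted_quantile <- function(x, w = rep(1, length(x)), p = 0.5) {
  if (all(w == 0)) stop("all weights zero", call. = FALSE)
  o <- order(x)
  cw <- cumsum(w[o]) / sum(w)
  x[o][which(cw >= p - 1e-12)[1]]
}

#' Probability-weighted elevation of a surface
#'
#' The weighted median (cumulative rule) and weighted mean of the DEM
#' elevations of all surviving (non-nodata) cells of a probability surface,
#' weights being the cell probabilities.
#'
#' @param surface an [oro_grid] probability surface.
#' @param dem the matching [oro_grid] DEM.
#' @return list with `median` and `mean` elevations (m), and `n_cells`.
#' @export
weighted_median_elevation <- function(surface, dem) {
  ok <- is.finite(surface$values) & is.finite(dem$values)
  w <- surface$values[ok]
  e <- dem$values[ok]
  if (!length(e) || all(w == 0))
    return(list(median = NA_real_, mean = NA_real_, n_cells = 0L))
  list(median = weighted_quantile(e, w, 0.5),
       mean = sum(w * e) / sum(w),
       n_cells = sum(ok))
}

#' Annual altitudinal distribution summary
#'
#' Median and mean altitude, range size (`max - min`; for the weighted case
#' the weighted 5-95% span, see Details), variance-mean ratio, adjusted
#' skewness and the number of distinct-elevation sites (elevations rounded
#' to 1 m).
#'
#' Weighted range size uses the weighted 95% minus 5% quantile span rather
#' than the raw extremes: model surfaces often retain single marginal cells
#' whose raw extremes would be unstable.
#'
#' @param h numeric vector of elevations for one species-year.
#' @param w optional weights (model cell probabilities).
#' @param year calendar year carried through to the output.
#' @return one-row data frame: `year, median_alt, mean_alt, range_size, vmr,
#'   skewness, n_sites`.
#' @export
annual_stats <- function(h, w = NULL, year = NA_integer_) {
  stopifnot(length(h) >= 1)
  if (!is.null(w)) {
    stopifnot(length(w) == length(h), all(w >= 0))
    if (all(w == 0)) stop("all weights zero", call. = FALSE)
  }
  n <- length(h)
  if (is.null(w)) {
    med <- stats::median(h); mn <- mean(h)
    rng <- max(h) - min(h)
  } else {
    med <- weighted_quantile(h, w, 0.5)
    mn <- sum(w * h) / sum(w)
    rng <- if (n < 2) 0 else
      weighted_quantile(h, w, 0.95) - weighted_quantile(h, w, 0.05)
  }
  data.frame(year = year, median_alt = med, mean_alt = mn,
             range_size = rng, vmr = vmr(h, w),
             skewness = skewness_g1(h, w),
             n_sites = length(unique(round(h))))
}

#' Ordinary least-squares trend
#'
#' Slope of `values ~ years` with `r^2` and the two-sided parametric p value;
#' the standard error of the slope is reported for recovery checks.
#'
#' @param years numeric predictor (calendar years).
#' @param values numeric response.
#' @return list `slope, intercept, r2, p, se, n`; slope is `NA` when the
#'   predictor has no variance or fewer than 3 points support inference.
#' @export
ols_slope <- function(years, values) {
  ok <- is.finite(years) & is.finite(values)
  years <- years[ok]; values <- values[ok]
  n <- length(years)
  if (n < 2 || stats::sd(years) == 0)
    return(list(slope = NA_real_, intercept = NA_real_, r2 = NA_real_,
                p = NA_real_, se = NA_real_, n = n))
  fit <- stats::lm(values ~ years)
  sm <- suppressWarnings(summary(fit))  # "perfect fit" is a legal input
  co <- sm$coefficients
  list(slope = unname(co["years", "Estimate"]),
       intercept = unname(co["(Intercept)", "Estimate"]),
       r2 = sm$r.squared,
       p = if (nrow(co) > 1 && n > 2) unname(co["years", "Pr(>|t|)"])
           else NA_real_,
       se = unname(co["years", "Std. Error"]),
       n = n)
}

#' Years of the extreme altitude records
#'
#' The calendar years of the single lowest- and single highest-elevation
#' occurrence; ties are broken by the earliest year.
#'
#' @param series data frame with columns `year` and `elevation` (one row per
#'   record, or per annual summary for model-based series).
#' @return list `t_min_year, t_max_year`.
#' @export
extreme_record_years <- function(series) {
  stopifnot(nrow(series) >= 1)
  o <- order(series$elevation, series$year)
  list(t_min_year = series$year[o[1]],
       t_max_year = series$year[rev(order(series$elevation,
                                          -series$year))[1]])
}

# per-year annual_stats over a series data frame (elevation + optional weight)
annual_stats_by_year <- function(series) {
  weighted <- "weight" %in% names(series) && !all(is.na(series$weight))
  out <- lapply(split(series, series$year), function(sy) {
    annual_stats(sy$elevation,
                 w = if (weighted) sy$weight else NULL,
                 year = sy$year[1])
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res[order(res$year), , drop = FALSE]
}

#' Skewness trend with site and year filters
#'
#' Annual skewness is computed only for years in which the species occurred
#' at `min_sites` or more sites of different altitude (distinct elevations
#' after rounding to 1 m); the regression against year is fitted only when at
#' least `min_years` qualifying years remain, otherwise the slope is missing.
#'
#' @param series per-record (or per-cell, weighted) data frame with `year`,
#'   `elevation` and optionally `weight`.
#' @param min_sites minimum number of distinct-elevation sites per year
#'   (default 5).
#' @param min_years minimum number of qualifying years (default 5).
#' @return list as [ols_slope()] plus `n_years` (qualifying years).
#' @export
z_skew_filtered <- function(series, min_sites = 5, min_years = 5) {
  ann <- annual_stats_by_year(series)
  ann <- ann[ann$n_sites >= min_sites & is.finite(ann$skewness), ,
             drop = FALSE]
  if (nrow(ann) < min_years)
    return(list(slope = NA_real_, intercept = NA_real_, r2 = NA_real_,
                p = NA_real_, se = NA_real_, n = nrow(ann),
                n_years = nrow(ann)))
  res <- ols_slope(ann$year, ann$skewness)
  res$n_years <- nrow(ann)
  res
}

#' Per-species shift slopes
#'
#' Computes the full slope set for one species series: `z_alt` (altitude of
#' every record against its year for record series; annual weighted medians
#' against year for model series), `z_range` (annual range size against
#' year), `z_vmr` (annual variance-mean ratio against year), `z_skew` (with
#' the site/year filters), the years of the extreme records, and the overall
#' median altitude, VMR and skewness pooled over all years.
#'
#' @param series data frame with `year`, `elevation`, optional `weight`
#'   (model-based) for a single species.
#' @param source `"records"` or `"sdm"`; model-based series regress annual
#'   weighted medians for `z_alt` and use weighted annual statistics.
#' @param min_sites,min_years filters for `z_skew` (defaults 5 and 5).
#' @return one-row data frame (a `SlopeSet` row).
#' @export
shift_slopes <- function(series, source = c("records", "sdm"),
                         min_sites = 5, min_years = 5) {
  source <- match.arg(source)
  ann <- annual_stats_by_year(series)
  weighted <- source == "sdm"
  if (weighted) {
    z_alt <- ols_slope(ann$year, ann$median_alt)
    ext <- extreme_record_years(
      data.frame(year = ann$year, elevation = ann$median_alt))
  } else {
    z_alt <- ols_slope(series$year, series$elevation)
    ext <- extreme_record_years(series)
  }
  ann_rng <- ann[is.finite(ann$range_size), , drop = FALSE]
  z_range <- ols_slope(ann_rng$year, ann_rng$range_size)
  ann_vmr <- ann[is.finite(ann$vmr), , drop = FALSE]
  z_vmr <- ols_slope(ann_vmr$year, ann_vmr$vmr)
  z_skew <- z_skew_filtered(series, min_sites, min_years)
  w <- if (weighted) series$weight else NULL
  data.frame(
    source = source,
    z_alt = z_alt$slope, z_alt_se = z_alt$se, z_alt_p = z_alt$p,
    z_range = z_range$slope, z_vmr = z_vmr$slope, z_skew = z_skew$slope,
    t_min_year = ext$t_min_year, t_max_year = ext$t_max_year,
    median_alt = if (weighted) weighted_quantile(series$elevation, w, 0.5)
                 else stats::median(series$elevation),
    overall_vmr = vmr(series$elevation, w),
    overall_skew = skewness_g1(series$elevation, w),
    n_years = nrow(ann))
}

#' Model surfaces as a weighted altitudinal series
#'
#' Converts a per-year list of rescaled probability surfaces into the paired
#' (elevation, weight) series used by the shift statistics.
#'
#' @param surfaces named list (by year) of [oro_grid] surfaces.
#' @param dem matching [oro_grid] DEM.
#' @return data frame `year, elevation, weight` over surviving cells.
#' @export
surface_series <- function(surfaces, dem) {
  out <- lapply(names(surfaces), function(yr) {
    s <- surfaces[[yr]]
    ok <- is.finite(s$values) & is.finite(dem$values) & s$values > 0
    if (!any(ok)) return(NULL)
    data.frame(year = as.integer(yr), elevation = dem$values[ok],
               weight = s$values[ok])
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Decadal median altitudinal anomalies
#'
#' For each species and calendar decade, the median altitude within the
#' decade minus the species' median over the whole study period; the
#' per-decade value is the median of these anomalies over species (species
#' without data in a decade are omitted from that decade), and a linear
#' trend is fitted against the decade midpoints.
#'
#' @param series data frame with `species`, `year`, `elevation`, optional
#'   `weight` covering all species.
#' @return list with `per_decade` (decade, midpoint, median anomaly,
#'   n species) and `trend` (an [ols_slope()] fit on the decade midpoints).
#' @export
decadal_median_shift <- function(series) {
  weighted <- "weight" %in% names(series) && !all(is.na(series$weight))
  dec <- (series$year %/% 10) * 10
  overall <- vapply(split(series, series$species), function(ss) {
    if (weighted) weighted_quantile(ss$elevation, ss$weight, 0.5)
    else stats::median(ss$elevation)
  }, 0)
  key <- interaction(series$species, dec, drop = TRUE)
  anom <- vapply(split(seq_len(nrow(series)), key), function(ix) {
    med <- if (weighted)
      weighted_quantile(series$elevation[ix], series$weight[ix], 0.5)
    else stats::median(series$elevation[ix])
    med - overall[[as.character(series$species[ix[1]])]]
  }, 0)
  dec_of <- vapply(split(dec, key), `[`, 0, 1)
  per_decade <- do.call(rbind, lapply(split(anom, dec_of), function(a)
    data.frame(anomaly = stats::median(a), n_species = length(a))))
  per_decade$decade <- as.integer(rownames(per_decade))
  per_decade$midpoint <- per_decade$decade + 5
  rownames(per_decade) <- NULL
  per_decade <- per_decade[order(per_decade$decade),
                           c("decade", "midpoint", "anomaly", "n_species")]
  list(per_decade = per_decade,
       trend = ols_slope(per_decade$midpoint, per_decade$anomaly))
}

#' Expected occupancy density by altitude
#'
#' Sums, per altitude bin, the rescaled occurrence probabilities of the
#' bin's cells (nodata cells contribute 0) across species: the density
#' profile of predicted potential distribution along the altitudinal
#' gradient. A uniform surface yields a profile proportional to the DEM's
#' cell counts per bin.
#'
#' @param surfaces list over species of [oro_grid] surfaces (one year).
#' @param dem matching [oro_grid] DEM.
#' @param breaks altitude bin breaks in m (default 250 m bins spanning the
#'   DEM).
#' @return data frame `bin_low, bin_high, richness`.
#' @export
richness_profile <- function(surfaces, dem,
                             breaks = seq(floor(min(dem$values) / 250) * 250,
                                          ceiling(max(dem$values) / 250) * 250,
                                          by = 250)) {
  bin <- cut(as.vector(dem$values), breaks, include.lowest = TRUE,
             labels = FALSE)
  nb <- length(breaks) - 1L
  rich <- numeric(nb)
  for (s in surfaces) {
    v <- as.vector(s$values)
    v[!is.finite(v)] <- 0
    sums <- vapply(seq_len(nb), function(b) sum(v[bin == b]), 0)
    rich <- rich + sums
  }
  data.frame(bin_low = breaks[-length(breaks)], bin_high = breaks[-1],
             richness = rich)
}
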