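# Annual environmental layers: bioclimatic variables, temperature
# downscaling, PCA spaces and species-with-data (SWD) tables.

#' Default retained bioclimatic variables
#'
#' bio1-bio7 and bio10-bio17. The wettest/warmest-quarter hybrid variables
#' (bio8, bio9, bio18, bio19) are excluded by default as artifact-prone.
#' @export
default_bioclim_vars <- function() {
  c(sprintf("bio%02d", c(1:7, 10:17)))
}

# month windows of the four-quantity monthly stacks as 3-d arrays
month_array <- function(lst) {
  if (length(lst) != 12L) stop("12 monthly layers required", call. = FALSE)
  array(unlist(lst), dim = c(dim(lst[[1]]), 12L))
}

#' Compute annual bioclimatic variables
#'
#' Standard bioclim definitions from one year of monthly climate: annual mean
#' temperature (bio1), diurnal range (bio2), isothermality (bio3),
#' temperature seasonality as 100 x s.d. of monthly means (bio4), extremes
#' (bio5-bio7), quarter temperatures (bio8-bio11), annual precipitation
#' (bio12), precipitation extremes (bio13, bio14), precipitation seasonality
#' as 100 x s.d./(mean + 1) (bio15), and quarter precipitation (bio16-bio19).
#' Quarters are rolling 3-month windows with December-January wraparound.
#'
#' @param mc one year of monthly climate (an element of the list returned by
#'   [make_climate_series()]): `year` plus 12-month lists `tmin`, `tmean`,
#'   `tmax`, `prec`.
#' @param variable_set character vector of layer names to retain (default
#'   [default_bioclim_vars()]).
#' @return list with `year` and `layers`, a named list of matrices.
#' @export
compute_bioclim <- function(mc, variable_set = default_bioclim_vars()) {
  for (q in c("tmin", "tmean", "tmax", "prec"))
    if (length(mc[[q]]) != 12L)
      stop(sprintf("monthly quantity '%s' must have 12 layers", q),
           call. = FALSE)
  tmin <- month_array(mc$tmin); tmean <- month_array(mc$tmean)
  tmax <- month_array(mc$tmax); prec <- month_array(mc$prec)
  d <- dim(tmean)[1:2]

  m_mean <- function(a) rowMeans(a, dims = 2)
  m_sd <- function(a) {                          # sample s.d. across months
    mm <- rowMeans(a, dims = 2)
    sqrt(pmax(rowSums(a^2, dims = 2) - 12 * mm^2, 0) / 11)
  }
  # rolling 3-month windows with wraparound: window m = months m, m+1, m+2
  win <- lapply(1:12, function(m) ((m - 1):(m + 1)) %% 12 + 1)
  qt <- vapply(win, function(w) rowMeans(tmean[, , w], dims = 2),
               matrix(0, d[1], d[2]))           # quarter mean temp
  qp <- vapply(win, function(w) rowSums(prec[, , w], dims = 2),
               matrix(0, d[1], d[2]))           # quarter prec sum
  amax <- function(a) Reduce(pmax, lapply(seq_len(dim(a)[3]),
                                          function(m) a[, , m]))
  amin <- function(a) Reduce(pmin, lapply(seq_len(dim(a)[3]),
                                          function(m) a[, , m]))
  wmax <- function(a, idx) {                    # value of a at argmax of idx
    sel <- apply(idx, 1:2, which.max)
    matrix(a[cbind(rep(seq_len(d[1]), d[2]), rep(seq_len(d[2]),
           each = d[1]), as.vector(sel))], d[1], d[2])
  }
  wmin <- function(a, idx) {
    sel <- apply(idx, 1:2, which.min)
    matrix(a[cbind(rep(seq_len(d[1]), d[2]), rep(seq_len(d[2]),
           each = d[1]), as.vector(sel))], d[1], d[2])
  }

  L <- list()
  L$bio01 <- m_mean(tmean)
  L$bio02 <- m_mean(tmax - tmin)
  L$bio05 <- amax(tmax)
  L$bio06 <- amin(tmin)
  L$bio07 <- L$bio05 - L$bio06
  L$bio03 <- 100 * L$bio02 / L$bio07
  L$bio03[!is.finite(L$bio03)] <- 0
  L$bio04 <- 100 * m_sd(tmean)
  L$bio10 <- amax(qt)       # mean temp of warmest quarter
  L$bio11 <- amin(qt)       # mean temp of coldest quarter
  L$bio12 <- rowSums(prec, dims = 2)
  L$bio13 <- amax(prec)
  L$bio14 <- amin(prec)
  L$bio15 <- 100 * m_sd(prec) / (m_mean(prec) + 1)
  L$bio16 <- amax(qp)
  L$bio17 <- amin(qp)
  # the hybrid wettest/driest x warmest/coldest quarter layers are costlier
  # (cell-wise argmax) and excluded from the default set; compute on demand
  if (any(c("bio08", "bio09", "bio18", "bio19") %in% variable_set)) {
    L$bio08 <- wmax(qt, qp)  # mean temp of wettest quarter
    L$bio09 <- wmin(qt, qp)  # mean temp of driest quarter
    L$bio18 <- wmax(qp, qt)  # prec of warmest quarter
    L$bio19 <- wmin(qp, qt)  # prec of coldest quarter
  }

  missing_vars <- setdiff(variable_set, names(L))
  if (length(missing_vars))
    stop("unknown bioclim variables: ", paste(missing_vars, collapse = ", "),
         call. = FALSE)
  list(year = mc$year, layers = L[variable_set])
}

#' Downscale temperature by geographically weighted regression
#'
#' For every fine-grid cell, a weighted least-squares regression
#' `temperature ~ 1 + elevation` is fitted over the coarse cells with
#' Gaussian distance weights `exp(-d^2 / (2 * bandwidth^2))` centred on the
#' fine cell, and evaluated at the fine cell's elevation. Cells with fewer
#' than 3 positive-weight coarse neighbours become nodata; a locally singular
#' design (all neighbour elevations equal) falls back to the weighted mean.
#'
#' @param coarse_temp,coarse_dem [oro_grid]s sharing one geometry.
#' @param fine_dem [oro_grid] giving the target geometry and elevations.
#' @param bandwidth Gaussian kernel bandwidth in map units (default 3 x the
#'   coarse cell size).
#' @return an [oro_grid] of downscaled temperature on the fine geometry.
#' @export
gwr_downscale <- function(coarse_temp, coarse_dem, fine_dem,
                          bandwidth = 3 * coarse_temp$cell_size) {
  if (!identical(dim(coarse_temp$values), dim(coarse_dem$values)))
    stop("coarse grids must share geometry", call. = FALSE)
  if (bandwidth <= 0) stop("bandwidth must be > 0", call. = FALSE)
  cx <- grid_x(coarse_temp); cy <- grid_y(coarse_temp)
  cc <- expand.grid(x = cx, y = cy)       # x fastest within each y
  ce <- as.vector(t(coarse_dem$values))   # same ordering as expand.grid
  ct <- as.vector(t(coarse_temp$values))
  ok <- is.finite(ce) & is.finite(ct)
  cc <- cc[ok, ]; ce <- ce[ok]; ct <- ct[ok]

  fx <- grid_x(fine_dem); fy <- grid_y(fine_dem)
  nyf <- length(fy); nxf <- length(fx)
  out <- matrix(NA_real_, nyf, nxf)
  n_singular <- 0L
  dx2 <- outer(cc$x, fx, function(a, b) (a - b)^2)
  for (i in seq_len(nyf)) {
    dy2 <- (cc$y - fy[i])^2
    W <- exp(-(dx2 + dy2) / (2 * bandwidth^2))   # n_coarse x nxf
    npos <- colSums(W > 0)
    S0 <- colSums(W)
    S1 <- colSums(W * ce)
    S2 <- colSums(W * ce^2)
    Sy <- colSums(W * ct)
    Sxy <- colSums(W * ce * ct)
    den <- S0 * S2 - S1^2
    mean_e <- S1 / S0
    scale2 <- pmax(S2 / S0 - mean_e^2, 0)
    singular <- scale2 < 1e-10 * pmax(mean_e^2, 1)
    slope <- ifelse(singular, 0, (S0 * Sxy - S1 * Sy) / den)
    intercept <- (Sy - slope * S1) / S0
    pred <- intercept + slope * fine_dem$values[i, ]
    pred[npos < 3] <- NA_real_
    n_singular <- n_singular + sum(singular & npos >= 3)
    out[i, ] <- pred
  }
  if (n_singular > 0)
    message(sprintf(
      "gwr_downscale: %d cells with locally constant elevation used the weighted mean",
      n_singular))
  oro_grid(out, cell_size = fine_dem$cell_size, origin = fine_dem$origin,
           nodata = fine_dem$nodata)
}

#' Downscale a grid by bilinear interpolation
#'
#' Standard bilinear interpolation between coarse cell centres, evaluated at
#' fine cell centres; fine cells outside the hull of coarse centres are
#' clamped to the edge. Used for variables (precipitation) whose correlation
#' with elevation is weak.
#'
#' @param coarse an [oro_grid].
#' @param fine_geometry an [oro_grid] providing the target geometry (its
#'   values are ignored).
#' @return an [oro_grid] on the fine geometry.
#' @export
bilinear_downscale <- function(coarse, fine_geometry) {
  cx <- grid_x(coarse); cy <- grid_y(coarse)
  fx <- grid_x(fine_geometry); fy <- grid_y(fine_geometry)
  fxc <- pmin(pmax(fx, cx[1]), cx[length(cx)])
  fyc <- pmin(pmax(fy, cy[1]), cy[length(cy)])
  jx <- pmin(pmax(findInterval(fxc, cx), 1L), length(cx) - 1L)
  iy <- pmin(pmax(findInterval(fyc, cy), 1L), length(cy) - 1L)
  tx <- (fxc - cx[jx]) / (cx[jx + 1L] - cx[jx])
  ty <- (fyc - cy[iy]) / (cy[iy + 1L] - cy[iy])
  v <- coarse$values
  out <- matrix(NA_real_, length(fy), length(fx))
  for (i in seq_along(fy)) {
    r0 <- iy[i]; w <- ty[i]
    row0 <- v[r0, jx] * (1 - tx) + v[r0, jx + 1L] * tx
    row1 <- v[r0 + 1L, jx] * (1 - tx) + v[r0 + 1L, jx + 1L] * tx
    out[i, ] <- row0 * (1 - w) + row1 * w
  }
  oro_grid(out, cell_size = fine_geometry$cell_size,
           origin = fine_geometry$origin, nodata = fine_geometry$nodata)
}

#' Fit a PCA environmental space
#'
#' Variables are z-scored, decomposed by PCA, and components with eigenvalue
#' > 1 (Kaiser rule) are retained. Zero-variance variables are dropped with a
#' warning.
#'
#' @param X numeric matrix or data frame, observations x variables.
#' @return an object of class `pca_space`: `means`, `sds`, `loadings`
#'   (orthonormal columns), `eigenvalues` (non-increasing), `n_retained`.
#' @export
fit_env_pca <- function(X) {
  X <- as.matrix(X)
  if (ncol(X) < 2) stop("need at least 2 variables", call. = FALSE)
  if (nrow(X) < ncol(X) + 1)
    stop("need at least variables + 1 observations", call. = FALSE)
  sds <- apply(X, 2, stats::sd)
  keep <- sds > 0
  if (!all(keep)) {
    warning("dropping zero-variance variables: ",
            paste(colnames(X)[!keep], collapse = ", "), call. = FALSE)
    X <- X[, keep, drop = FALSE]
    if (ncol(X) < 2) stop("fewer than 2 informative variables", call. = FALSE)
  }
  pc <- stats::prcomp(X, center = TRUE, scale. = TRUE)
  ev <- pc$sdev^2
  structure(list(
    means = pc$center, sds = pc$scale, loadings = pc$rotation,
    eigenvalues = ev, n_retained = max(1L, sum(ev > 1)),
    variables = colnames(X)), class = "pca_space")
}

#' Project data onto a fitted PCA space
#'
#' @param space a `pca_space` from [fit_env_pca()].
#' @param X matrix or data frame with (at least) the training variables.
#' @param n_comp number of components to return (default the retained count).
#' @return score matrix, observations x `n_comp`.
#' @export
project_pca <- function(space, X, n_comp = space$n_retained) {
  X <- as.matrix(X[, space$variables, drop = FALSE])
  Z <- sweep(sweep(X, 2, space$means), 2, space$sds, "/")
  (Z %*% space$loadings)[, seq_len(n_comp), drop = FALSE]
}

# raw environmental values (bioclim of the point's own year + monthly
# insolation) at point locations; points outside the grid or on nodata
# cells are dropped and counted in attr(result, "n_dropped")
extract_env <- function(points, bioclim_by_year, insolation, grid) {
  yrs <- vapply(bioclim_by_year, `[[`, 0, "year")
  bio_names <- names(bioclim_by_year[[1]]$layers)
  rc <- cell_at(grid, points$x, points$y)
  year_idx <- match(points$year, yrs)
  if (anyNA(year_idx))
    stop("record years without climate layers: ",
         paste(unique(points$year[is.na(year_idx)]), collapse = ", "),
         call. = FALSE)
  ok <- !is.na(rc[, 1])
  env <- matrix(NA_real_, nrow(points), length(bio_names) + length(insolation))
  colnames(env) <- c(bio_names, names(insolation))
  for (k in which(ok)) {
    lay <- bioclim_by_year[[year_idx[k]]]$layers
    env[k, seq_along(bio_names)] <-
      vapply(lay, function(m) m[rc[k, 1], rc[k, 2]], 0)
    env[k, length(bio_names) + seq_along(insolation)] <-
      vapply(insolation, function(m) m[rc[k, 1], rc[k, 2]], 0)
  }
  ok <- ok & stats::complete.cases(env)
  out <- data.frame(points[ok, , drop = FALSE],
                    env[ok, , drop = FALSE], check.names = FALSE)
  attr(out, "n_dropped") <- sum(!ok)
  out
}

#' Assemble a species-with-data (SWD) table
#'
#' Extracts, for each record, the bioclimatic conditions of the record's own
#' year of discovery plus the (static) monthly insolation of its cell,
#' projects them onto the fitted climate and topography PCA spaces, and
#' returns one SWD row per surviving record. Records outside the grid are
#' dropped; their count is reported in `attr(, "n_dropped")`.
#'
#' @param records data frame with `species`, `x`, `y`, `year` (the label
#'   column may also be the literal string `"background"`).
#' @param bioclim_by_year list of [compute_bioclim()] results, one per year.
#' @param insolation monthly insolation list from [make_insolation()].
#' @param climate_pca,topo_pca `pca_space` objects for the bioclim and
#'   insolation variables.
#' @param grid the working [oro_grid] geometry.
#' @return data frame `species, x, y, year, pc1..pcK, topo1..topoM`.
#' @export
extract_swd <- function(records, bioclim_by_year, insolation,
                        climate_pca, topo_pca, grid) {
  env <- extract_env(records[, c("species", "x", "y", "year")],
                     bioclim_by_year, insolation, grid)
  cl <- project_pca(climate_pca, env)
  tp <- project_pca(topo_pca, env)
  colnames(cl) <- paste0("pc", seq_len(ncol(cl)))
  colnames(tp) <- paste0("topo", seq_len(ncol(tp)))
  out <- data.frame(env[, c("species", "x", "y", "year")], cl, tp,
                    check.names = FALSE)
  attr(out, "n_dropped") <- attr(env, "n_dropped")
  out
}

#' Sample random background points
#'
#' Uniform random cells, without replacement within each year, labelled with
#' the literal species string `"background"`. Environmental values are
#' year-matched downstream exactly as for presences.
#'
#' @param years integer vector of years.
#' @param n_per_year background points per year.
#' @param grid the working [oro_grid]; cells that are nodata are excluded.
#' @param seed integer RNG seed.
#' @return data frame `species, x, y, year`.
#' @export
sample_background <- function(years, n_per_year, grid, seed = 1) {
  xs <- grid_x(grid); ys <- grid_y(grid)
  valid <- which(is.finite(grid$values))
  if (length(valid) < n_per_year)
    stop("fewer valid cells than n_per_year", call. = FALSE)
  nyx <- dim(grid$values)
  with_seed(seed, {
    out <- lapply(years, function(yr) {
      idx <- sample(valid, n_per_year, replace = FALSE)
      rc <- arrayInd(idx, nyx)
      data.frame(species = "background", x = xs[rc[, 2]], y = ys[rc[, 1]],
                 year = as.integer(yr), stringsAsFactors = FALSE)
    })
    res <- do.call(rbind, out)
    rownames(res) <- NULL
    res
  })
}

#' Write / read SWD tables
#'
#' CSV with header `species,x,y,year,pc1,...,topo1,...`; the background label
#' is the literal string `background`.
#'
#' @param swd SWD data frame from [extract_swd()].
#' @param path CSV file path.
#' @export
write_swd <- function(swd, path) {
  utils::write.csv(swd, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_swd
#' @export
read_swd <- function(path) utils::read.csv(path, stringsAsFactors = FALSE)
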