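# independent direct-arithmetic oracle for the bioclim layers of a single
# 12-value series (one cell)
bioclim_oracle <- function(tmin, tmean, tmax, prec) {
  wins <- lapply(1:12, function(m) ((m - 1):(m + 1)) %% 12 + 1)
  qt <- vapply(wins, function(w) mean(tmean[w]), 0)
  qp <- vapply(wins, function(w) sum(prec[w]), 0)
  b5 <- max(tmax); b6 <- min(tmin)
  list(bio01 = mean(tmean), bio02 = mean(tmax - tmin), bio04 = 100 * sd(tmean),
       bio05 = b5, bio06 = b6, bio07 = b5 - b6,
       bio10 = max(qt), bio11 = min(qt),
       bio12 = sum(prec), bio13 = max(prec), bio14 = min(prec),
       bio15 = 100 * sd(prec) / (mean(prec) + 1),
       bio16 = max(qp), bio17 = min(qp))
}

one_cell_climate <- function(tmin, tmean, tmax, prec) {
  m <- function(x) matrix(x, 2, 2)
  list(year = 2000L, tmin = lapply(tmin, m), tmean = lapply(tmean, m),
       tmax = lapply(tmax, m), prec = lapply(prec, m))
}

test_that("bioclim handles constant and printed series exactly", {
  mc <- one_cell_climate(rep(8, 12), rep(10, 12), rep(12, 12), rep(50, 12))
  bc <- compute_bioclim(mc)
  expect_equal(bc$layers$bio01[1, 1], 10)
  expect_equal(bc$layers$bio04[1, 1], 0)
  expect_equal(bc$layers$bio12[1, 1], 600)
  tmean <- c(-5, -3, 0, 4, 9, 13, 15, 14, 10, 5, 0, -4)
  mc2 <- one_cell_climate(tmean - 4, tmean, tmean + 4, rep(80, 12))
  bc2 <- compute_bioclim(mc2)
  expect_equal(bc2$layers$bio01[1, 1], 4.8333333333, tolerance = 1e-9)
  expect_equal(bc2$layers$bio04[1, 1], 727.1780241371, tolerance = 1e-9)
  mc$tmean <- mc$tmean[1:11]
  expect_error(compute_bioclim(mc), "12")
})

test_that("bioclim matches the direct-arithmetic oracle on random series", {
  set.seed(301)
  for (i in 1:200) {
    tmean <- rnorm(12, 5, 8)
    delta <- runif(12, 0.5, 6)
    prec <- runif(12, 0, 250)
    mc <- one_cell_climate(tmean - delta, tmean, tmean + delta, prec)
    got <- compute_bioclim(mc)
    want <- bioclim_oracle(tmean - delta, tmean, tmean + delta, prec)
    for (nm in names(want))
      expect_equal(got$layers[[nm]][1, 1], want[[nm]], tolerance = 1e-9,
                   label = nm)
  }
})

test_that("GWR downscaling recovers an exact linear lapse everywhere", {
  set.seed(17)
  cdem <- oro_grid(matrix(runif(100, 400, 3400), 10, 10), cell_size = 1000)
  ctemp <- oro_grid(20 - 0.0065 * cdem$values, cell_size = 1000)
  fdem <- oro_grid(matrix(runif(1600, 400, 3400), 40, 40), cell_size = 250)
  fine <- gwr_downscale(ctemp, cdem, fdem, bandwidth = 2500)
  expect_lt(max(abs(fine$values - (20 - 0.0065 * fdem$values))), 1e-6)
  # spatially constant temperature stays constant
  cflat <- oro_grid(matrix(12, 10, 10), cell_size = 1000)
  fine2 <- gwr_downscale(cflat, cdem, fdem, bandwidth = 2500)
  expect_lt(max(abs(fine2$values - 12)), 1e-9)
})

test_that("GWR matches a per-cell weighted-least-squares oracle", {
  set.seed(18)
  cdem <- oro_grid(matrix(runif(64, 400, 3400), 8, 8), cell_size = 500)
  ctemp <- oro_grid(matrix(rnorm(64, 8, 3), 8, 8), cell_size = 500)
  fdem <- oro_grid(matrix(runif(36, 400, 3400), 6, 6), cell_size = 400,
                   origin = c(300, 300))
  bw <- 900
  fine <- gwr_downscale(ctemp, cdem, fdem, bandwidth = bw)
  cx <- rep(seq(250, by = 500, length.out = 8), each = 1)
  cc <- expand.grid(x = seq(250, by = 500, length.out = 8),
                    y = seq(250, by = 500, length.out = 8))
  ce <- as.vector(t(cdem$values)); ct <- as.vector(t(ctemp$values))
  for (i in c(1, 3, 6)) for (j in c(2, 5)) {
    fx <- 300 + (j - 0.5) * 400; fy <- 300 + (i - 0.5) * 400
    w <- exp(-((cc$x - fx)^2 + (cc$y - fy)^2) / (2 * bw^2))
    X <- cbind(1, ce)
    beta <- solve(t(X) %*% (w * X), t(X) %*% (w * ct))
    want <- beta[1] + beta[2] * fdem$values[i, j]
    expect_equal(fine$values[i, j], want, tolerance = 1e-8)
  }
})

test_that("GWR tends to the global regression as bandwidth grows", {
  set.seed(19)
  cdem <- oro_grid(matrix(runif(100, 400, 3400), 10, 10), cell_size = 100)
  ctemp <- oro_grid(matrix(rnorm(100, 8, 3), 10, 10), cell_size = 100)
  fine <- gwr_downscale(ctemp, cdem, cdem, bandwidth = 1e9)
  glob <- lm(as.vector(t(ctemp$values)) ~ as.vector(t(cdem$values)))
  want <- coef(glob)[1] + coef(glob)[2] * cdem$values
  expect_lt(max(abs(fine$values - want)), 1e-6)
})

test_that("bilinear downscaling is exact for constants, nodes and midpoints", {
  co <- oro_grid(matrix(7, 4, 4), cell_size = 100)
  fg <- oro_grid(matrix(0, 8, 8), cell_size = 50)
  expect_true(all(bilinear_downscale(co, fg)$values == 7))
  # the midpoint of four corner centres (0, 0, 10, 10) interpolates to 5:
  # a 2x2 fine grid whose shared corner sits at the coarse-centre midpoint
  co2 <- oro_grid(matrix(c(0, 0, 10, 10), 2, 2), cell_size = 100)
  fg2 <- oro_grid(matrix(0, 2, 2), cell_size = 100, origin = c(-50, -50))
  got <- bilinear_downscale(co2, fg2)
  expect_equal(got$values[2, 2], 5)  # fine centre (100, 100) = midpoint
  # a fine centre coincident with a coarse centre preserves the value
  co3 <- oro_grid(matrix(1:16, 4, 4), cell_size = 100)
  fg3 <- oro_grid(matrix(0, 2, 2), cell_size = 100, origin = c(100, 100))
  got3 <- bilinear_downscale(co3, fg3)
  expect_equal(got3$values[1, 1], co3$values[2, 2])
})

test_that("PCA space retains Kaiser components and conserves variance", {
  set.seed(20)
  Z <- matrix(rnorm(1000), 250, 4)
  X <- cbind(a = Z[, 1], b = Z[, 1] + 0.1 * Z[, 2], c = Z[, 3],
             d = Z[, 4])
  ps <- fit_env_pca(X)
  expect_equal(sum(ps$eigenvalues), 4, tolerance = 1e-8)
  expect_true(all(diff(ps$eigenvalues) <= 1e-12))
  expect_equal(ps$n_retained, sum(ps$eigenvalues > 1))
  # loadings orthonormal
  G <- t(ps$loadings) %*% ps$loadings
  expect_lt(max(abs(G - diag(ncol(X)))), 1e-8)
  # eigen-decomposition oracle on the correlation matrix
  want <- sort(eigen(cor(X))$values, decreasing = TRUE)
  expect_equal(unname(ps$eigenvalues), want, tolerance = 1e-8)
  # single-axis data: PC1 explains everything
  Y <- cbind(p = Z[, 1], q = 2 * Z[, 1], r = -Z[, 1])
  suppressWarnings(ps1 <- fit_env_pca(Y))
  expect_equal(ps1$eigenvalues[1] / sum(ps1$eigenvalues), 1,
               tolerance = 1e-8)
  # zero-variance variable dropped with a warning
  expect_warning(fit_env_pca(cbind(X, const = 1)), "zero-variance")
})

test_that("PCA projection reproduces training scores and inverts", {
  set.seed(21)
  X <- matrix(rnorm(300), 100, 3, dimnames = list(NULL, c("u", "v", "w")))
  ps <- fit_env_pca(X)
  sc <- project_pca(ps, X, n_comp = 3)
  # mean row maps to the origin
  expect_lt(max(abs(project_pca(ps, t(as.matrix(colMeans(X)))))), 1e-10)
  # round-trip through the full loadings reconstructs z-scored X
  expect_lt(max(abs(sc %*% t(ps$loadings) - scale(X))), 1e-8)
})

test_that("SWD extraction is year-matched and drops off-grid records", {
  w <- tiny_world(years = 1999:2000, warming = 2, noise_sd = 0)
  bioclim <- lapply(w$climate, compute_bioclim)
  rec <- data.frame(species = "s", x = c(250, 250, -1000),
                    y = c(250, 250, 250), year = c(1999L, 2000L, 1999L))
  env <- oroshift:::extract_env(rec, bioclim, w$insolation, w$dem)
  expect_equal(attr(env, "n_dropped"), 1)
  # strong programmed warming: the two years differ by 2 degC in bio01
  expect_equal(env$bio01[2] - env$bio01[1], 2, tolerance = 1e-9)
})

test_that("background sampling is uniform over the DEM", {
  w <- tiny_world(nx = 40, ny = 40)
  bg <- sample_background(2001:2003, 500, w$dem, seed = 5)
  expect_equal(nrow(bg), 1500)
  expect_true(all(bg$species == "background"))
  # no duplicate cells within a year
  for (yr in 2001:2003) {
    byr <- bg[bg$year == yr, ]
    expect_equal(anyDuplicated(paste(byr$x, byr$y)), 0)
  }
  # elevations follow the DEM distribution
  bg10k <- sample_background(2001, 1500, w$dem, seed = 6)
  ks <- suppressWarnings(
    ks.test(grid_extract(w$dem, bg10k$x, bg10k$y), as.vector(w$dem$values)))
  expect_lt(unname(ks$statistic), 0.05)
})
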