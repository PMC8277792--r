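random_instance <- function(n_axes = 2, n_pres = 20, n_bg = 40,
                            classes = c("linear", "quadratic", "product")) {
  bg <- matrix(runif(n_bg * n_axes), n_bg, n_axes,
               dimnames = list(NULL, paste0("pc", seq_len(n_axes))))
  pres <- matrix(rbeta(n_pres * n_axes, 3, 1.5), n_pres, n_axes,
                 dimnames = list(NULL, paste0("pc", seq_len(n_axes))))
  fm <- build_features(bg, classes = classes)
  list(pres = pres, bg = bg, fm = fm)
}

test_that("feature expansion counts, scales and prunes correctly", {
  bg <- matrix(runif(60), 20, 3, dimnames = list(NULL, c("pc1", "pc2",
                                                         "topo1")))
  fm <- build_features(bg)
  expect_length(fm$features, 9)  # 3 linear + 3 quadratic + 3 products
  Fb <- feature_values(fm, bg)
  expect_equal(unname(apply(Fb, 2, min)), rep(0, 9))
  expect_equal(unname(apply(Fb, 2, max)), rep(1, 9))
  bg_const <- cbind(bg, pc3 = 1)
  expect_warning(fm2 <- build_features(bg_const), "constant")
  expect_lt(length(fm2$features), 4 + 4 + 6)
})

test_that("no-signal problems yield a uniform model", {
  set.seed(31)
  env <- matrix(runif(50), 50, 1, dimnames = list(NULL, "pc1"))
  pres <- env[1:20, , drop = FALSE]
  # presences == background subset, and observed == expected means when
  # presences are drawn from the background distribution: lambda stays small
  fm <- build_features(env, classes = "linear")
  fit <- fit_maxent(env, env, fm = fm, beta = 1)
  raw <- predict_raw(fit, env)
  expect_equal(sum(raw), 1, tolerance = 1e-6)
  expect_equal(max(raw) / min(raw), 1, tolerance = 0.3)
})

test_that("raw scores normalize over background; cloglog transforms sanely", {
  set.seed(32)
  inst <- random_instance()
  fit <- fit_maxent(inst$pres, inst$bg, fm = inst$fm)
  expect_equal(sum(predict_raw(fit, inst$bg)), 1, tolerance = 1e-6)
  expect_gte(fit$entropy_H, 0)
  expect_lte(fit$entropy_H, log(nrow(inst$bg)) + 1e-9)
  # uniform model: H = log n, raw = 1/n -> cloglog = 1 - exp(-1)
  unif <- fit
  unif$lambdas <- rep(0, length(fit$lambdas))
  unif$log_Z <- log(nrow(inst$bg))
  unif$entropy_H <- log(nrow(inst$bg))
  expect_equal(predict_cloglog(unif, inst$bg),
               rep(1 - exp(-1), nrow(inst$bg)), tolerance = 1e-12)
  # cloglog strictly increasing in raw
  o <- order(predict_raw(fit, inst$bg))
  expect_true(all(diff(predict_cloglog(fit, inst$bg)[o]) >= 0))
})

test_that("fitted objective matches a generic convex-optimizer oracle", {
  set.seed(33)
  for (k in 1:20) {
    n_axes <- sample(1:2, 1)
    classes <- if (n_axes == 1) c("linear", "quadratic")
               else sample(c("linear", "quadratic", "product"),
                           sample(2:3, 1))
    inst <- random_instance(n_axes = n_axes, n_pres = sample(10:25, 1),
                            n_bg = sample(20:50, 1), classes = classes)
    beta <- sample(c(0.1, 0.5, 1), 1)
    fit <- fit_maxent(inst$pres, inst$bg, fm = inst$fm, beta = beta)
    Fp <- feature_values(inst$fm, inst$pres)
    Fb <- feature_values(inst$fm, inst$bg)
    s_j <- pmax(apply(Fp, 2, sd), 1e-4)
    beta_j <- beta * s_j / sqrt(nrow(Fp))
    want <- maxent_oracle_objective(Fp, Fb, beta_j, seed = k)
    expect_gte(fit$objective, want - 1e-3)
    expect_lte(fit$objective, want + 1e-3)
  }
})

test_that("the spec toy instance reaches the 1-D oracle optimum", {
  bg <- matrix(rep(c(0, 1 / 3, 2 / 3, 1), 3), ncol = 1,
               dimnames = list(NULL, "pc1"))
  pres <- matrix(rep(1, 5), ncol = 1, dimnames = list(NULL, "pc1"))
  fm <- build_features(bg, classes = "linear")
  expect_warning(fit <- fit_maxent(pres, bg, fm = fm, beta = 0.05),
                 "identical")
  Fp <- feature_values(fm, pres); Fb <- feature_values(fm, bg)
  beta_j <- 0.05 * pmax(apply(Fp, 2, sd), 1e-4) / sqrt(5)
  obj <- function(l) mean(Fp %*% l) - log(sum(exp(Fb %*% l))) -
    sum(beta_j * abs(l))
  want <- -optimize(function(l) -obj(l), c(-100, 100))$objective
  expect_equal(fit$objective, want, tolerance = 1e-3)
})

test_that("penalized optimum is non-increasing in beta", {
  set.seed(34)
  inst <- random_instance()
  objs <- vapply(c(0.01, 0.1, 1, 10), function(b)
    fit_maxent(inst$pres, inst$bg, fm = inst$fm, beta = b)$objective, 0)
  expect_true(all(diff(objs) <= 1e-8))
})

test_that("AUC equals the Mann-Whitney statistic with half ties", {
  expect_equal(auc(c(0.9, 0.8), c(0.1, 0.2)), 1)
  expect_equal(auc(rep(0.5, 4), rep(0.5, 7)), 0.5)
  expect_equal(auc(c(0.8, 0.3), c(0.5, 0.1)), 0.75)
  set.seed(35)
  for (i in 1:100) {
    p <- round(runif(sample(3:20, 1)), 2)  # rounding forces ties
    b <- round(runif(sample(3:20, 1)), 2)
    w <- wilcox.test(p, b, exact = FALSE, correct = FALSE)
    expect_equal(auc(p, b), unname(w$statistic) / (length(p) * length(b)),
                 tolerance = 1e-12)
  }
})

test_that("omission threshold follows the sorted-index rule", {
  expect_equal(omission_threshold(seq(0.1, 1, by = 0.1), 0.1), 0.2)
  expect_equal(omission_threshold(c(0.7, 0.2, 0.9), 0), 0.2)
  expect_equal(omission_threshold(0.4, 0.1), 0.4)
  # exactly the scores strictly below the threshold are omitted
  s <- seq(0.1, 1, by = 0.1)
  thr <- omission_threshold(s, 0.1)
  expect_equal(sum(s < thr), 1)
})

test_that("bootstrap evaluation is reproducible and separates a clear niche", {
  set.seed(36)
  bg <- matrix(runif(400), 200, 2, dimnames = list(NULL, c("pc1", "pc2")))
  pres <- matrix(rnorm(60, 0.8, 0.05), 30, 2,
                 dimnames = list(NULL, c("pc1", "pc2")))
  fm <- build_features(bg)
  ev <- bootstrap_evaluate(pres, bg, fm = fm, n_rep = 5, seed = 9)
  ev2 <- bootstrap_evaluate(pres, bg, fm = fm, n_rep = 5, seed = 9)
  expect_identical(ev, ev2)
  expect_true(all(ev$auc_test >= 0 & ev$auc_test <= 1))
  expect_gt(mean(ev$auc_test), 0.9)
  expect_equal(ev$omission_threshold_mean, mean(ev$thresholds))
})

test_that("projection rescaling and masking follow the stated rules", {
  g <- oro_grid(matrix(c(0.1, 0.4, 0.8, 0.2), 2, 2), 10)
  r <- rescale_projection(g, 0.4)
  expect_equal(r$values[1, 1], NA_real_)
  expect_equal(r$values[2, 1], 0)    # value 0.4 -> (0.4-0.4)/(0.8-0.4)
  expect_equal(r$values[1, 2], 1)    # the maximum maps to 1
  expect_true(all(r$values >= 0 & r$values <= 1, na.rm = TRUE))
  # all below threshold -> all nodata
  expect_true(all(is.na(rescale_projection(g, 0.9)$values)))
  # p_max == threshold -> surviving cells become 1
  g2 <- oro_grid(matrix(c(0.4, 0.4, 0.1, 0.1), 2, 2), 10)
  expect_equal(sort(as.vector(rescale_projection(g2, 0.4)$values),
                    na.last = TRUE), c(1, 1, NA, NA))
  # masking
  ones <- matrix(1, 2, 2)
  expect_equal(mask_landcover(r, ones)$values, r$values)
  expect_true(all(is.na(mask_landcover(r, matrix(0, 2, 2))$values)))
  checker <- matrix(c(1, 0, 0, 1), 2, 2)
  gm <- mask_landcover(oro_grid(matrix(0.5, 2, 2), 10), checker)
  expect_equal(sum(is.finite(gm$values)), 2)
})

test_that("annual projections track a warming-driven uphill shift", {
  w <- tiny_world(nx = 30, ny = 30, years = 1981:2000, warming = 0.1,
                  noise_sd = 0)
  sp <- mid_species(elev = 1800, breadth = 1, records_per_year = 25)
  rec <- sample_records(list(sp), w$climate, w$dem, seed = 12)
  bioclim <- lapply(w$climate, compute_bioclim)
  # the noise-free synthetic world has some constant bioclim layers
  pcas <- suppressWarnings(oroshift:::fit_pca_spaces(rec, bioclim, w))
  stacks <- env_axis_stacks(bioclim, w$insolation, pcas$climate, pcas$topo,
                            w$dem)
  swd <- extract_swd(rec, bioclim, w$insolation, pcas$climate, pcas$topo,
                     w$dem)
  bg <- sample_background(w$years, 40, w$dem, seed = 13)
  bswd <- extract_swd(bg, bioclim, w$insolation, pcas$climate, pcas$topo,
                      w$dem)
  fm <- build_features(bswd)
  fit <- fit_maxent(swd, bswd, fm = fm)
  surf <- annual_projection(fit, stacks, 0.2, w$dem)
  expect_length(surf, length(w$years))
  expect_true(all(vapply(surf, function(s)
    all(s$values >= 0 & s$values <= 1, na.rm = TRUE), TRUE)))
  first <- weighted_median_elevation(surf[[1]], w$dem)$median
  last <- weighted_median_elevation(surf[[length(surf)]], w$dem)$median
  expect_gt(last, first)  # cold-adapted species projected uphill
})

test_that("maxent models survive a JSON round-trip", {
  set.seed(37)
  inst <- random_instance()
  fit <- fit_maxent(inst$pres, inst$bg, fm = inst$fm)
  path <- withr::local_tempfile(fileext = ".json")
  write_maxent_json(fit, path)
  fit2 <- read_maxent_json(path)
  expect_equal(predict_cloglog(fit2, inst$bg), predict_cloglog(fit, inst$bg),
               tolerance = 1e-12)
})
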