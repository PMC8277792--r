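# Maximum-entropy presence-background distribution model, implemented from
# scratch: linear/quadratic/product features scaled on background, an
# L1-penalized log-likelihood fitted by proximal gradient ascent, cloglog
# output, bootstrap AUC evaluation, omission-threshold rescaling and
# land-cover masking.

# pull the numeric environmental axis columns out of an SWD table
swd_env_matrix <- function(x) {
  if (is.matrix(x)) return(x)
  keep <- grepl("^(pc|topo)[0-9]+$", names(x))
  if (!any(keep)) {
    keep <- vapply(x, is.numeric, TRUE) &
      !names(x) %in% c("x", "y", "year", "elevation")
  }
  as.matrix(x[, keep, drop = FALSE])
}

#' Build a Maxent feature map
#'
#' Expands `d` environmental axes into `d` linear, `d` quadratic and
#' `d(d-1)/2` pairwise-product features, each scaled to `[0, 1]` using its
#' minimum and maximum over the background sample. Features constant over the
#' background are dropped with a warning.
#'
#' @param env background environmental values: a numeric matrix or an SWD
#'   data frame (axis columns `pc*` / `topo*`).
#' @param classes feature classes to include, subset of
#'   `c("linear", "quadratic", "product")`.
#' @return an object of class `feature_map`.
#' @export
build_features <- function(env,
                           classes = c("linear", "quadratic", "product")) {
  X <- swd_env_matrix(env)
  d <- ncol(X)
  axes <- colnames(X)
  if (is.null(axes)) axes <- paste0("v", seq_len(d))
  classes <- match.arg(classes, several.ok = TRUE)
  feats <- list()
  if ("linear" %in% classes)
    for (a in seq_len(d))
      feats[[length(feats) + 1L]] <- list(kind = "linear", a1 = a, a2 = NA)
  if ("quadratic" %in% classes)
    for (a in seq_len(d))
      feats[[length(feats) + 1L]] <- list(kind = "quadratic", a1 = a, a2 = NA)
  if ("product" %in% classes && d >= 2)
    for (a in seq_len(d - 1)) for (b in (a + 1):d)
      feats[[length(feats) + 1L]] <- list(kind = "product", a1 = a, a2 = b)
  fm <- structure(list(axes = axes, features = feats,
                       fmin = NULL, fmax = NULL), class = "feature_map")
  Fraw <- raw_features(fm, X)
  fmin <- apply(Fraw, 2, min)
  fmax <- apply(Fraw, 2, max)
  constant <- fmax - fmin <= 0
  if (any(constant)) {
    warning(sprintf("dropping %d constant feature(s) over background",
                    sum(constant)), call. = FALSE)
    fm$features <- fm$features[!constant]
    fmin <- fmin[!constant]; fmax <- fmax[!constant]
  }
  fm$fmin <- fmin
  fm$fmax <- fmax
  fm
}

#' @export
print.feature_map <- function(x, ...) {
  kinds <- vapply(x$features, `[[`, "", "kind")
  cat(sprintf("<feature_map> %d axes -> %d features (%s)\n",
              length(x$axes), length(kinds),
              paste(sprintf("%s: %d", names(table(kinds)), table(kinds)),
                    collapse = ", ")))
  invisible(x)
}

# unscaled feature values, n x n_features
raw_features <- function(fm, X) {
  n <- nrow(X)
  out <- matrix(0, n, length(fm$features))
  for (j in seq_along(fm$features)) {
    f <- fm$features[[j]]
    out[, j] <- switch(f$kind,
      linear = X[, f$a1],
      quadratic = X[, f$a1]^2,
      product = X[, f$a1] * X[, f$a2])
  }
  out
}

#' Evaluate scaled features
#'
#' @param fm a `feature_map` from [build_features()].
#' @param env matrix or SWD data frame of environmental axis values.
#' @return matrix of feature values scaled by the background min/max (values
#'   outside the background range extrapolate beyond `[0, 1]`).
#' @export
feature_values <- function(fm, env) {
  X <- swd_env_matrix(env)
  if (ncol(X) != length(fm$axes))
    stop("env axes do not match feature map", call. = FALSE)
  Fraw <- raw_features(fm, X)
  sweep(sweep(Fraw, 2, fm$fmin), 2, fm$fmax - fm$fmin, "/")
}

# penalized objective: mean presence score - log sum exp over background
# - sum beta_j |lambda_j|
maxent_objective <- function(lambda, Fp, Fb, beta_j) {
  s <- as.vector(Fb %*% lambda)
  mean(as.vector(Fp %*% lambda)) - log_sum_exp(s) - sum(beta_j * abs(lambda))
}

log_sum_exp <- function(x) {
  m <- max(x)
  m + log(sum(exp(x - m)))
}

#' Fit a maximum-entropy presence-background model
#'
#' Maximizes the L1-penalized presence log-likelihood
#' `mean_presence(lambda . f) - log sum_background exp(lambda . f)
#'  - sum_j beta_j |lambda_j|`
#' with `beta_j = beta * s_j / sqrt(m)` (`s_j` the presence standard
#' deviation of feature `j`, floored; `m` the presence count) by full-batch
#' proximal gradient ascent with soft-thresholding and an adaptive step. The
#' fitted Gibbs density `raw(x) = exp(lambda . f(x)) / Z` sums to 1 over the
#' training background.
#'
#' @param presence,background SWD tables (or env matrices) of presence and
#'   background points.
#' @param fm a `feature_map`; defaults to linear + quadratic + product
#'   features built on `background`.
#' @param beta regularization multiplier (default 1).
#' @param tol convergence tolerance on the objective (default 1e-7).
#' @param max_iter iteration cap (default 5000).
#' @param sd_floor lower bound on the presence s.d. entering the penalty.
#' @return an object of class `maxent_model` with elements `feature_map`,
#'   `lambdas`, `log_Z`, `entropy_H` (nats, over the training background),
#'   `beta`, `converged`, `n_iter`, `objective`.
#' @export
fit_maxent <- function(presence, background, fm = build_features(background),
                       beta = 1, tol = 1e-7, max_iter = 5000,
                       sd_floor = 1e-4) {
  Fp <- feature_values(fm, presence)
  Fb <- feature_values(fm, background)
  m <- nrow(Fp)
  if (m < 5) stop("need at least 5 presence points", call. = FALSE)
  if (nrow(Fb) < 10) stop("need at least 10 background points", call. = FALSE)
  p <- ncol(Fp)
  if (p > 0 && m > 1 && nrow(unique(Fp)) == 1L)
    warning(paste("all presences identical in feature space;",
                  "the fit is determined by the penalty alone"),
            call. = FALSE)
  s_j <- pmax(apply(Fp, 2, stats::sd), sd_floor)
  beta_j <- beta * s_j / sqrt(m)
  lambda <- rep(0, p)
  fbar <- colMeans(Fp)

  obj <- maxent_objective(lambda, Fp, Fb, beta_j)
  step <- 1
  converged <- FALSE
  iter <- 0L
  # ascent is monotone; stop when the objective gain over a whole window of
  # iterations drops below tol (a single tiny step can stall transiently
  # while the backtracked step size recovers)
  window <- 20L
  obj_hist <- rep(-Inf, window)
  if (p > 0) {
    while (iter < max_iter) {
      iter <- iter + 1L
      s <- as.vector(Fb %*% lambda)
      w <- exp(s - log_sum_exp(s))           # raw density over background
      grad <- fbar - as.vector(crossprod(Fb, w))
      repeat {
        cand <- lambda + step * grad
        cand <- sign(cand) * pmax(abs(cand) - step * beta_j, 0)  # prox L1
        obj_new <- maxent_objective(cand, Fp, Fb, beta_j)
        if (obj_new >= obj - 1e-15 || step < 1e-12) break
        step <- step / 2
      }
      lambda <- cand
      obj <- obj_new
      step <- min(step * 1.1, 1e3)
      lag <- obj_hist[(iter - 1L) %% window + 1L]
      obj_hist[(iter - 1L) %% window + 1L] <- obj
      if (iter >= window && obj - lag < tol) { converged <- TRUE; break }
    }
  } else converged <- TRUE

  s <- as.vector(Fb %*% lambda)
  log_Z <- log_sum_exp(s)
  w <- exp(s - log_Z)
  entropy_H <- -sum(ifelse(w > 0, w * log(w), 0))
  structure(list(feature_map = fm, lambdas = lambda, log_Z = log_Z,
                 entropy_H = entropy_H, beta = beta, converged = converged,
                 n_iter = iter, objective = obj),
            class = "maxent_model")
}

#' @export
print.maxent_model <- function(x, ...) {
  cat(sprintf(
    "<maxent_model> %d features, H = %.3f nats, %sconverged in %d iterations\n",
    length(x$lambdas), x$entropy_H, if (x$converged) "" else "NOT ",
    x$n_iter))
  invisible(x)
}

#' Raw (Gibbs) density prediction
#'
#' `exp(lambda . f(x)) / Z` with the normalizer fixed at its training
#' background value, so raw scores over the training background sum to 1.
#'
#' @param model a `maxent_model`.
#' @param env matrix or SWD data frame of environmental axis values.
#' @return numeric vector of raw scores.
#' @export
predict_raw <- function(model, env) {
  Fx <- feature_values(model$feature_map, env)
  exp(as.vector(Fx %*% model$lambdas) - model$log_Z)
}

#' cloglog occurrence prediction
#'
#' `1 - exp(-exp(H) * raw(x))`, `H` the entropy of the fitted distribution
#' over the training background; a uniform model (`H = log n`) scores
#' `1 - exp(-1)` everywhere. Monotone in the raw density.
#'
#' @inheritParams predict_raw
#' @return numeric vector of scores in `[0, 1]`.
#' @export
predict_cloglog <- function(model, env) {
  1 - exp(-exp(model$entropy_H) * predict_raw(model, env))
}

#' Rank-based AUC
#'
#' Area under the ROC curve computed as the normalized Mann-Whitney U
#' statistic; tied scores count one half.
#'
#' @param pres_scores,bg_scores numeric score vectors for presences and
#'   background.
#' @return AUC in `[0, 1]`.
#' @export
auc <- function(pres_scores, bg_scores) {
  n1 <- length(pres_scores); n2 <- length(bg_scores)
  if (n1 == 0 || n2 == 0) stop("empty score vector", call. = FALSE)
  r <- rank(c(pres_scores, bg_scores))
  (sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2) / (n1 * n2)
}

#' Training omission threshold
#'
#' The cutoff below which a fraction `rate` of training presences is omitted:
#' with scores sorted ascending, the score at 0-based index
#' `floor(rate * n)`; exactly the scores strictly below it are omitted.
#'
#' @param training_scores presence scores on the training split.
#' @param rate omission rate (default 0.10).
#' @return the threshold score.
#' @export
omission_threshold <- function(training_scores, rate = 0.10) {
  s <- sort(training_scores)
  s[min(floor(rate * length(s)) + 1L, length(s))]
}

#' Bootstrap model evaluation
#'
#' Repeatedly splits the presences into training and test fractions, refits
#' the model on the training split, and scores training and test presences
#' against the pooled background with rank-based AUC; also records each
#' replicate's training omission threshold (cloglog units) and reports its
#' mean.
#'
#' @inheritParams fit_maxent
#' @param n_rep number of bootstrap replicates (default 100).
#' @param train_frac training fraction of presences (default 0.8).
#' @param omission_rate training omission rate (default 0.10).
#' @param seed integer RNG seed.
#' @return an object of class `eval_result`: `auc_training`, `auc_test`
#'   (per-replicate vectors), `thresholds`, `omission_threshold_mean`.
#' @export
bootstrap_evaluate <- function(presence, background,
                               fm = build_features(background), beta = 1,
                               n_rep = 100, train_frac = 0.8,
                               omission_rate = 0.10, seed = 1, ...) {
  Xp <- swd_env_matrix(presence)
  m <- nrow(Xp)
  n_train <- max(5L, min(m - 1L, round(train_frac * m)))
  with_seed(seed, {
    auc_tr <- auc_te <- thr <- numeric(n_rep)
    for (r in seq_len(n_rep)) {
      idx <- sample.int(m, n_train)
      fit <- fit_maxent(Xp[idx, , drop = FALSE], background, fm = fm,
                        beta = beta, ...)
      sc_tr <- predict_cloglog(fit, Xp[idx, , drop = FALSE])
      sc_te <- predict_cloglog(fit, Xp[-idx, , drop = FALSE])
      sc_bg <- predict_cloglog(fit, background)
      auc_tr[r] <- auc(sc_tr, sc_bg)
      auc_te[r] <- auc(sc_te, sc_bg)
      thr[r] <- omission_threshold(sc_tr, omission_rate)
    }
    structure(list(auc_training = auc_tr, auc_test = auc_te,
                   thresholds = thr, omission_threshold_mean = mean(thr)),
              class = "eval_result")
  })
}

#' @export
print.eval_result <- function(x, ...) {
  cat(sprintf(
    "<eval_result> %d replicates; AUC training %.3f-%.3f, test %.3f-%.3f, mean 10%% omission threshold %.3f\n",
    length(x$auc_training), min(x$auc_training), max(x$auc_training),
    min(x$auc_test), max(x$auc_test), x$omission_threshold_mean))
  invisible(x)
}

#' Omission-threshold rescaling of a projection
#'
#' Cells below the threshold become nodata; surviving cells are rescaled to
#' `(p - threshold) / (p_max - threshold)` so the output spans `[0, 1]`. If
#' the surface maximum equals the threshold, all surviving cells map to 1.
#'
#' @param surface an [oro_grid] of cloglog scores.
#' @param threshold cutoff in cloglog units.
#' @return an [oro_grid] with `attr(, "threshold_applied")` set.
#' @export
rescale_projection <- function(surface, threshold) {
  v <- surface$values
  v[v < threshold] <- NA_real_
  pmax_v <- suppressWarnings(max(v, na.rm = TRUE))
  if (is.finite(pmax_v)) {
    if (pmax_v > threshold) v <- (v - threshold) / (pmax_v - threshold)
    else v[!is.na(v)] <- 1
  }
  out <- oro_grid(v, cell_size = surface$cell_size, origin = surface$origin,
                  nodata = surface$nodata)
  attr(out, "threshold_applied") <- threshold
  out
}

#' Land-cover masking
#'
#' @param surface an [oro_grid] probability surface.
#' @param mask an [oro_grid] or matrix of 0/1 suitability; cells with 0 (or
#'   nodata) become nodata, cells with 1 pass unchanged.
#' @return the masked [oro_grid].
#' @export
mask_landcover <- function(surface, mask) {
  mv <- if (inherits(mask, "oro_grid")) mask$values else mask
  if (!identical(dim(mv), dim(surface$values)))
    stop("mask geometry mismatch", call. = FALSE)
  v <- surface$values
  v[is.na(mv) | mv == 0] <- NA_real_
  out <- oro_grid(v, cell_size = surface$cell_size, origin = surface$origin,
                  nodata = surface$nodata)
  attr(out, "threshold_applied") <- attr(surface, "threshold_applied")
  out
}

#' Per-year environmental axis stacks
#'
#' Projects each year's bioclim layers (plus the static monthly insolation)
#' onto the fitted climate and topography PCA spaces cell by cell, producing
#' per-year grids of the model's input axes.
#'
#' @inheritParams extract_swd
#' @return list of per-year stacks: `year` plus `axes`, a named list of
#'   matrices (`pc1..pcK`, `topo1..topoM`).
#' @export
env_axis_stacks <- function(bioclim_by_year, insolation, climate_pca,
                            topo_pca, grid) {
  d <- dim(grid$values)
  ins_mat <- vapply(insolation, as.vector, numeric(prod(d)))
  tp_scores <- NULL
  lapply(bioclim_by_year, function(bc) {
    bio_mat <- vapply(bc$layers, as.vector, numeric(prod(d)))
    env <- cbind(bio_mat, ins_mat)
    cl <- project_pca(climate_pca, env)
    tp <- project_pca(topo_pca, env)
    axes <- c(
      stats::setNames(lapply(seq_len(ncol(cl)),
        function(j) matrix(cl[, j], d[1], d[2])),
        paste0("pc", seq_len(ncol(cl)))),
      stats::setNames(lapply(seq_len(ncol(tp)),
        function(j) matrix(tp[, j], d[1], d[2])),
        paste0("topo", seq_len(ncol(tp)))))
    list(year = bc$year, axes = axes)
  })
}

#' Annual cloglog projections
#'
#' Predicts the cloglog surface for each year's environmental axis stack,
#' applies the omission-threshold rescaling, and (optionally) the land-cover
#' mask.
#'
#' @param model a `maxent_model`.
#' @param stacks per-year axis stacks from [env_axis_stacks()].
#' @param threshold cloglog omission threshold (e.g.
#'   `eval$omission_threshold_mean`).
#' @param grid the working [oro_grid] geometry.
#' @param mask optional 0/1 land-cover mask.
#' @return named list (by year) of rescaled [oro_grid] surfaces.
#' @export
annual_projection <- function(model, stacks, threshold, grid, mask = NULL) {
  out <- lapply(stacks, function(st) {
    env <- vapply(st$axes, as.vector, numeric(prod(dim(grid$values))))
    keep <- match(model$feature_map$axes, colnames(env))
    if (anyNA(keep)) stop("stack axes do not match model", call. = FALSE)
    sc <- predict_cloglog(model, env[, keep, drop = FALSE])
    surf <- oro_grid(matrix(sc, nrow(grid$values), ncol(grid$values)),
                     cell_size = grid$cell_size, origin = grid$origin,
                     nodata = grid$nodata)
    surf <- rescale_projection(surf, threshold)
    if (!is.null(mask)) surf <- mask_landcover(surf, mask)
    surf
  })
  names(out) <- vapply(stacks, function(st) as.character(st$year), "")
  out
}

#' Serialize / restore a Maxent model as JSON
#'
#' @param model a `maxent_model`.
#' @param path JSON file path.
#' @export
write_maxent_json <- function(model, path) {
  fm <- model$feature_map
  obj <- list(
    axes = fm$axes,
    features = lapply(fm$features, function(f)
      list(kind = f$kind, a1 = f$a1, a2 = f$a2)),
    fmin = fm$fmin, fmax = fm$fmax,
    lambdas = model$lambdas, log_Z = model$log_Z,
    entropy_H = model$entropy_H, beta = model$beta,
    converged = model$converged, n_iter = model$n_iter,
    objective = model$objective)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_maxent_json
#' @export
read_maxent_json <- function(path) {
  o <- jsonlite::read_json(path, simplifyVector = TRUE)
  feats <- lapply(seq_len(nrow(o$features)), function(i)
    list(kind = o$features$kind[i],
         a1 = o$features$a1[i], a2 = o$features$a2[i]))
  fm <- structure(list(axes = o$axes, features = feats,
                       fmin = o$fmin, fmax = o$fmax), class = "feature_map")
  structure(list(feature_map = fm, lambdas = o$lambdas, log_Z = o$log_Z,
                 entropy_H = o$entropy_H, beta = o$beta,
                 converged = o$converged, n_iter = o$n_iter,
                 objective = o$objective),
            class = "maxent_model")
}
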