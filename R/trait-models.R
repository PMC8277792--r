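# Trait-based general linear models: shift statistics as responses,
# categorical ecological traits as predictors, median altitude as covariate,
# Type II sums of squares (single-term deletions) and partial eta-squared
# effect sizes.

#' Fit a trait general linear model
#'
#' Linear model of a per-species shift statistic on the categorical traits
#' dispersal ability (3 levels, reference `sedentary`), specialisation
#' (euryocy, reference `specialist`) and endangerment (reference
#' `threatened`), with median altitude as continuous covariate. Effects are
#' assessed by Type II sums of squares; partial eta-squared is
#' `SS_effect / (SS_effect + SS_error)`. Predictors constant across species
#' are dropped with a warning.
#'
#' @param response numeric per-species response (e.g. `z_alt`).
#' @param traits data frame with columns `euryocy`, `dispersal`,
#'   `endangerment` (one row per species, aligned with `response`).
#' @param covariate numeric per-species covariate, by default missing; pass
#'   the per-species median altitude to reproduce the standard layout.
#' @return an object of class `trait_glm`: `table` (per-predictor df,
#'   partial eta-squared, F, p), `r2`, `model` (the underlying `lm`).
#' @export
fit_trait_glm <- function(response, traits, covariate = NULL) {
  n <- length(response)
  if (n < 10) stop("need at least 10 species", call. = FALSE)
  df <- data.frame(
    response = response,
    dispersal = factor(traits$dispersal,
                       levels = c("sedentary", "intermediate", "mobile")),
    euryocy = factor(traits$euryocy,
                     levels = c("specialist", "generalist")),
    endangerment = factor(traits$endangerment,
                          levels = c("threatened", "least_concern")))
  if (!is.null(covariate)) df$altitude <- covariate
  preds <- setdiff(names(df), "response")
  keep <- vapply(preds, function(p) length(unique(df[[p]])) > 1, TRUE)
  if (!all(keep)) {
    warning("dropping constant predictor(s): ",
            paste(preds[!keep], collapse = ", "), call. = FALSE)
    preds <- preds[keep]
  }
  lev_ok <- vapply(preds, function(p) {
    if (!is.factor(df[[p]])) return(TRUE)
    all(table(droplevels(df[[p]])) >= 2)
  }, TRUE)
  if (!all(lev_ok))
    warning("trait level(s) represented fewer than 2 times: ",
            paste(preds[!lev_ok], collapse = ", "), call. = FALSE)
  for (p in preds) if (is.factor(df[[p]])) df[[p]] <- droplevels(df[[p]])
  fml <- stats::reformulate(preds, response = "response")
  fit <- stats::lm(fml, data = df)
  # Type II SS for a main-effects model: RSS(model without the predictor)
  # minus RSS(full), i.e. single-term deletions; robust to a perfect fit
  ss_err <- sum(stats::resid(fit)^2)
  df_err <- stats::df.residual(fit)
  # sums of squares below floating-point noise relative to the response's
  # total SS are treated as exact zeros
  eps <- 1e-12 * max(sum((df$response - mean(df$response))^2), 1e-300)
  if (ss_err < eps) ss_err <- 0
  tab <- do.call(rbind, lapply(preds, function(pr) {
    others <- setdiff(preds, pr)
    red <- stats::lm(stats::reformulate(if (length(others)) others else "1",
                                        "response"), data = df)
    ss <- max(sum(stats::resid(red)^2) - ss_err, 0)
    if (ss < eps) ss <- 0
    dfp <- stats::df.residual(red) - df_err
    Fv <- if (ss_err > 0) (ss / dfp) / (ss_err / df_err)
          else if (ss > 0) Inf else NA_real_
    data.frame(
      predictor = pr, df = dfp,
      partial_eta2 = if (ss + ss_err > 0) ss / (ss + ss_err) else 0,
      F = Fv,
      p = if (!is.na(Fv) && is.finite(Fv))
            stats::pf(Fv, dfp, df_err, lower.tail = FALSE) else NA_real_)
  }))
  rownames(tab) <- NULL
  r2 <- suppressWarnings(summary(fit)$r.squared)  # exact fits are legal
  structure(list(table = tab, r2 = r2, model = fit), class = "trait_glm")
}

#' @export
print.trait_glm <- function(x, ...) {
  cat("<trait_glm> Type II effects, r2 =", round(x$r2, 3), "\n")
  print(transform(x$table, partial_eta2 = round(partial_eta2, 3),
                  F = round(F, 2), p = round(p, 4)))
  invisible(x)
}

#' Pairwise OLS relation between per-species statistics
#'
#' Simple least-squares regression of one per-species quantity on another
#' (e.g. `z_alt` on climatic niche volume), with `r^2` and two-sided
#' parametric p. A constant predictor yields a flagged undefined slope.
#'
#' @param x,y numeric per-species vectors.
#' @return list `slope, intercept, r2, p, se, n` (see [ols_slope()]).
#' @export
ols_relation <- function(x, y) ols_slope(x, y)
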