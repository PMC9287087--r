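#' Estimated marginal means and pairwise contrasts
#'
#' Model-based factor-level means with 95% intervals and multiplicity-
#' adjusted all-pairwise contrasts, for the package's GLS ([fit_gls_car1()])
#' and proportion-GLM ([fit_proportion_glm()]) fits.
#'
#' A level's estimate is the linear predictor at that level, averaged with
#' equal weights over the levels of every other factor in the model (so for
#' the colonizer model `value ~ period + treatment`, the period means average
#' over the two treatments).  Intervals use `estimate +/- t(df, 0.975) * SE`
#' on the link scale, back-transformed through the inverse logit for the
#' proportion models; `df` is the residual degrees of freedom.  Pairwise
#' contrasts are computed on the link scale; p-values use the studentized
#' range ("Tukey") adjustment by default, with `"bonferroni"` and `"none"`
#' available.
#'
#' @param fit a `car1_fit` or `prop_glm` object.
#' @param spec name of the factor whose levels are summarized; default the
#'   first factor in the model.
#' @param adjust multiplicity adjustment for the pairwise contrasts.
#' @param level confidence level (default 0.95).
#' @param at optional named list fixing other factors at given levels instead
#'   of averaging over them, e.g. `at = list(treatment = "exclosure")`.
#' @return object of class `marginal_summary`: list with data.frames `means`
#'   (`level`, `estimate`, `se`, `df`, `lower`, `upper`, response scale) and
#'   `contrasts` (`contrast`, `estimate`, `se`, `df`, `t`, `p_value`, link
#'   scale), plus `spec`, `adjust`, `level`, `link`.
#' @export
marginal_means <- function(fit, spec = NULL,
                           adjust = c("tukey", "none", "bonferroni"),
                           level = 0.95, at = NULL) {
  adjust <- match.arg(adjust)
  if (!inherits(fit, c("car1_fit", "prop_glm"))) {
    stop("marginal_means supports car1_fit and prop_glm objects")
  }
  link <- if (inherits(fit, "prop_glm")) "logit" else "identity"
  xlev <- fit$xlevels
  if (length(xlev) == 0) stop("model has no factor predictors")
  if (is.null(spec)) spec <- names(xlev)[1]
  if (!spec %in% names(xlev)) stop(sprintf("'%s' is not a factor in the model", spec))
  if (length(xlev[[spec]]) < 1) stop("factor has no levels")

  # reference grid: all factor-level combinations, equal weights
  grid <- expand.grid(xlev, KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  if (!is.null(at)) {
    for (f in names(at)) {
      if (!f %in% names(xlev)) stop(sprintf("'at' factor '%s' not in model", f))
      grid <- grid[grid[[f]] %in% at[[f]], , drop = FALSE]
    }
  }
  for (f in names(xlev)) grid[[f]] <- factor(grid[[f]], levels = xlev[[f]])
  Terms <- stats::delete.response(fit$terms)
  M <- stats::model.matrix(Terms, grid, contrasts.arg = fit$contrasts)

  levels_f <- xlev[[spec]]
  L <- t(vapply(levels_f, function(lv) {
    colMeans(M[grid[[spec]] == lv, , drop = FALSE])
  }, numeric(ncol(M))))

  beta <- fit$coefficients
  V <- fit$vcov
  est <- as.numeric(L %*% beta)
  se <- sqrt(rowSums((L %*% V) * L))

  # degrees of freedom: for the GLS fits use the effective sample size
  # (1' R^-1 1 summed over correlation groups) rather than the nominal n - p,
  # so that plug-in phi-hat intervals keep close-to-nominal coverage; under
  # per-group variances each level carries its own group's df and contrasts
  # are combined Welch-style (the Games-Howell construction).
  k <- length(levels_f)
  if (inherits(fit, "car1_fit")) {
    df_eff <- if (is.null(fit$df_effective)) fit$df_residual else fit$df_effective
    per_level <- fit$var_by_group && identical(spec, fit$group) &&
      all(levels_f %in% names(fit$n_eff))
    df <- if (per_level) pmax(fit$n_eff[levels_f] - 1, 2) else rep(df_eff, k)
  } else {
    per_level <- FALSE
    df <- rep(fit$df_residual, k)
  }
  df <- unname(df)
  crit <- stats::qt(1 - (1 - level) / 2, df)
  lo <- est - crit * se
  hi <- est + crit * se
  inv <- if (link == "logit") stats::plogis else identity
  means <- data.frame(level = levels_f, estimate = inv(est), se = se, df = df,
                      lower = inv(lo), upper = inv(hi),
                      stringsAsFactors = FALSE)

  contrasts <- NULL
  if (k >= 2) {
    pairs <- utils::combn(k, 2)
    Lc <- L[pairs[1, ], , drop = FALSE] - L[pairs[2, ], , drop = FALSE]
    cest <- as.numeric(Lc %*% beta)
    cse <- sqrt(rowSums((Lc %*% V) * Lc))
    tt <- cest / cse
    cdf <- if (per_level) {
      v1 <- se[pairs[1, ]]^2; v2 <- se[pairs[2, ]]^2
      (v1 + v2)^2 / (v1^2 / df[pairs[1, ]] + v2^2 / df[pairs[2, ]])
    } else {
      df[pairs[1, ]]
    }
    p <- switch(adjust,
      tukey = stats::ptukey(sqrt(2) * abs(tt), nmeans = k, df = cdf,
                            lower.tail = FALSE),
      bonferroni = pmin(1, ncol(pairs) * 2 * stats::pt(abs(tt), cdf,
                                                       lower.tail = FALSE)),
      none = 2 * stats::pt(abs(tt), cdf, lower.tail = FALSE)
    )
    contrasts <- data.frame(
      contrast = paste(levels_f[pairs[1, ]], "-", levels_f[pairs[2, ]]),
      estimate = cest, se = cse, df = cdf, t = tt, p_value = p,
      stringsAsFactors = FALSE
    )
  }
  structure(list(means = means, contrasts = contrasts, spec = spec,
                 adjust = adjust, level = level, link = link),
            class = "marginal_summary")
}

#' @export
print.marginal_summary <- function(x, ...) {
  cat(sprintf("Estimated marginal means for '%s' (%d%% intervals, link = %s)\n",
              x$spec, round(100 * x$level), x$link))
  print(transform(x$means, estimate = round(estimate, 4),
                  lower = round(lower, 4), upper = round(upper, 4),
                  se = round(se, 4)), row.names = FALSE)
  if (!is.null(x$contrasts)) {
    cat(sprintf("Pairwise contrasts (link scale, %s adjustment):\n", x$adjust))
    print(transform(x$contrasts, estimate = round(estimate, 4),
                    se = round(se, 4), t = round(t, 3),
                    p_value = signif(p_value, 3)), row.names = FALSE)
  }
  invisible(x)
}

#' Export a marginal summary as tidy tables
#' @param x a `marginal_summary`; @param path_means,path_contrasts CSV paths.
#' @export
write_marginal_summary <- function(x, path_means, path_contrasts = NULL) {
  utils::write.csv(x$means, path_means, row.names = FALSE, quote = FALSE)
  if (!is.null(path_contrasts) && !is.null(x$contrasts)) {
    utils::write.csv(x$contrasts, path_contrasts, row.names = FALSE, quote = FALSE)
  }
  invisible(x)
}
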