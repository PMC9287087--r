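#' Quasi-binomial GLM for continuous proportions
#'
#' Proportional energy use is bounded in `[0, 1]` and is modelled on the
#' logit scale with binomial-form quasi-likelihood: IRLS with unit prior
#' weights (via [stats::glm()] with `family = quasibinomial("logit")`) and
#' dispersion estimated by Pearson chi-squared over residual degrees of
#' freedom.  Responses exactly 0 or 1 are handled by the working-response
#' formulation, so no continuity correction is applied to the data.
#'
#' Factor cells whose fitted mean is driven to the 0/1 boundary (all-zero or
#' all-one cells) are reported through the `boundary` flag; their logit-scale
#' coefficients are unbounded and their intervals should not be interpreted.
#'
#' @param formula model formula, e.g. `value ~ period_label` or
#'   `value ~ period_label + treatment`.
#' @param data data.frame; the response must lie in `[0, 1]`.
#' @return object of class `prop_glm`: the underlying `glm` object plus
#'   `dispersion` (Pearson), `boundary`, and the pieces used by
#'   [marginal_means()].
#' @export
fit_proportion_glm <- function(formula, data) {
  mf <- stats::model.frame(formula, data = data, na.action = stats::na.fail)
  y <- stats::model.response(mf)
  if (any(y < 0 | y > 1)) stop("responses must lie in [0, 1]")
  fit <- stats::glm(formula, family = stats::quasibinomial("logit"),
                    data = data)
  pear <- stats::residuals(fit, type = "pearson")
  dispersion <- sum(pear^2) / fit$df.residual
  mu <- stats::fitted(fit)
  boundary <- any(mu < 1e-8 | mu > 1 - 1e-8)
  structure(list(
    glm = fit,
    coefficients = stats::coef(fit),
    vcov = summary(fit)$cov.unscaled * dispersion,
    dispersion = dispersion,
    boundary = boundary,
    n = length(y),
    p = length(stats::coef(fit)),
    df_residual = fit$df.residual,
    fitted = mu,
    terms = fit$terms,
    xlevels = fit$xlevels,
    contrasts = fit$contrasts,
    model = stats::model.frame(fit),
    call = match.call()
  ), class = "prop_glm")
}

#' @export
print.prop_glm <- function(x, ...) {
  cat("Quasi-binomial proportion model (logit link)\n")
  cat(sprintf("  n = %d, dispersion = %.4g%s\n", x$n, x$dispersion,
              if (x$boundary) ", BOUNDARY cell(s)" else ""))
  cat("Coefficients (logit scale):\n")
  print(round(x$coefficients, 5))
  invisible(x)
}

#' @export
coef.prop_glm <- function(object, ...) object$coefficients

#' @export
vcov.prop_glm <- function(object, ...) object$vcov
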