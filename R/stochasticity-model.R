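#' Stochasticity-versus-community-size mixed model
#'
#' Linear mixed-effects model of the stochastic assembly fraction on
#' community size with a random intercept per compartment, the test behind
#' the drift signature: if stochastic compositional variance is driven by
#' ecological drift it must shrink as communities grow, so the fixed-effect
#' slope should be negative. Variance explained is reported in the Nakagawa
#' form: marginal `R2 = varF / (varF + varR + varE)` (fixed effects only)
#' and conditional `R2 = (varF + varR) / (varF + varR + varE)` (fixed plus
#' random), with `varF` the variance of the fixed-effect predictions,
#' `varR` the random-intercept variance and `varE` the residual variance.
#'
#' @param fraction stochastic fraction per group (response, in `[0, 1]`).
#' @param size community size per group (predictor; pass log-transformed
#'   values if the size gradient spans decades).
#' @param compartment grouping factor for the random intercept.
#' @return list with `slope`, `p` (Satterthwaite t-test on the slope),
#'   `marginalR2`, `conditionalR2` and the fitted model as `model`. With a
#'   single compartment the model degenerates to ordinary least squares
#'   (with a warning) and conditional equals marginal R2.
#' @export
mixedStochasticityModel <- function(fraction, size, compartment) {
  df <- data.frame(y = fraction, x = size,
                   compartment = as.factor(compartment))
  if (nrow(df) < 3L) stop("need >= 3 observations")
  if (nlevels(droplevels(df$compartment)) < 2L) {
    warning("single compartment: fitting ordinary least squares")
    fit <- stats::lm(y ~ x, df)
    sm <- summary(fit)
    return(list(slope = stats::coef(fit)[["x"]],
                p = sm$coefficients["x", "Pr(>|t|)"],
                marginalR2 = sm$r.squared, conditionalR2 = sm$r.squared,
                model = fit))
  }
  fit <- lmerTest::lmer(y ~ x + (1 | compartment), data = df, REML = TRUE)
  co <- stats::coef(summary(fit))
  varF <- stats::var(stats::model.matrix(fit) %*% lme4::fixef(fit))[1L]
  vc <- lme4::VarCorr(fit)
  varR <- sum(vapply(vc, function(v) v[1L, 1L], numeric(1)))
  varE <- attr(vc, "sc")^2
  tot <- varF + varR + varE
  list(slope = co["x", "Estimate"], p = co["x", "Pr(>|t|)"],
       marginalR2 = varF / tot, conditionalR2 = (varF + varR) / tot,
       model = fit)
}
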