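#' Fit a gamma log-link generalized linear model
#'
#' The association model for strictly positive, right-skewed activity
#' outcomes: the log of the expected outcome is linear in the covariates and
#' `exp(beta)` is the multiplicative change in the expected outcome per unit
#' covariate. Fitting is iteratively reweighted least squares
#' ([stats::glm()], relative tolerance 1e-8, at most 100 iterations);
#' dispersion is the Pearson chi-square estimate, and inference is Wald:
#' `z = beta / SE`, two-sided normal p-values, 95% CI `beta +/- 1.96 SE`
#' (so the CI excludes 0 exactly when p < 0.05).
#'
#' Gamma likelihoods cannot absorb exact zeros (a resident with 0 walking
#' minutes). `zero_policy = "shift"` (default) adds half the metric's
#' resolution (`zero_shift`, default 0.5) to zero outcomes only;
#' `"drop"` removes them. The number of affected observations is recorded.
#'
#' @param data Data frame holding outcome and covariates.
#' @param formula Model formula, outcome on the left.
#' @param zero_policy `"shift"` or `"drop"`.
#' @param zero_shift Amount added to zero outcomes under `"shift"`.
#' @return Object of class `"gamma_glm"`: the underlying `glm` fit plus
#'   `dispersion`, `n`, `zero_report`. Use [generics::tidy()] /
#'   [generics::glance()] to extract results.
#' @export
#' @examples
#' d <- data.frame(y = rgamma(100, 2, 0.5), x = rnorm(100))
#' fit <- fit_gamma_glm(d, y ~ x)
#' tidy(fit)
fit_gamma_glm <- function(data, formula, zero_policy = c("shift", "drop"),
                          zero_shift = 0.5) {
  zero_policy <- match.arg(zero_policy)
  mf <- stats::model.frame(formula, data = data, na.action = stats::na.omit)
  y <- stats::model.response(mf)
  if (any(y < 0)) stop("outcome must be non-negative", call. = FALSE)
  n_zero <- sum(y == 0)
  if (n_zero > 0) {
    if (zero_policy == "shift") {
      y[y == 0] <- zero_shift
      mf[[1]] <- y
    } else {
      mf <- mf[y > 0, , drop = FALSE]
      y <- y[y > 0]
    }
  }
  X <- stats::model.matrix(formula, mf)
  if (nrow(X) <= ncol(X)) {
    stop("more parameters than observations", call. = FALSE)
  }
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    dropped <- colnames(X)[qrX$pivot[(qrX$rank + 1):ncol(X)]]
    stop(sprintf("design matrix is rank deficient; collinear column(s): %s",
                 paste(dropped, collapse = ", ")), call. = FALSE)
  }
  fit <- stats::glm(formula, data = mf, family = stats::Gamma(link = "log"),
                    control = stats::glm.control(epsilon = 1e-8, maxit = 100))
  if (!fit$converged) {
    stop(sprintf("IRLS did not converge in %d iterations (deviance %.6g)",
                 fit$iter, fit$deviance), call. = FALSE)
  }
  pearson <- sum(stats::residuals(fit, type = "pearson")^2)
  dispersion <- pearson / stats::df.residual(fit)
  structure(
    list(
      fit = fit,
      dispersion = dispersion,
      n = length(y),
      zero_report = list(policy = zero_policy, n_zero = n_zero,
                         shift = if (zero_policy == "shift") zero_shift else NA_real_)
    ),
    class = "gamma_glm"
  )
}

#' @export
print.gamma_glm <- function(x, ...) {
  cat(sprintf("Gamma GLM (log link), n = %d, dispersion = %.4g\n", x$n, x$dispersion))
  print(tidy(x), ...)
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a gamma GLM fit
#'
#' @param x A `gamma_glm` object.
#' @param conf.level Confidence level for the Wald interval.
#' @param ... Unused.
#' @return Tibble: `term`, `estimate` (log scale), `std.error`, `statistic`,
#'   `p.value`, `conf.low`, `conf.high`, `pct_change`
#'   (`100 * (exp(estimate) - 1)`).
#' @method tidy gamma_glm
#' @export
tidy.gamma_glm <- function(x, conf.level = 0.95, ...) {
  beta <- stats::coef(x$fit)
  se <- sqrt(diag(stats::summary.glm(x$fit, dispersion = x$dispersion)$cov.scaled))
  z <- beta / se
  crit <- stats::qnorm(1 - (1 - conf.level) / 2)
  tibble::tibble(
    term = names(beta),
    estimate = unname(beta),
    std.error = unname(se),
    statistic = unname(z),
    p.value = unname(2 * stats::pnorm(-abs(z))),
    conf.low = unname(beta - crit * se),
    conf.high = unname(beta + crit * se),
    pct_change = unname(interpret_coefficient(beta))
  )
}

#' Glance at a gamma GLM fit
#'
#' @param x A `gamma_glm` object.
#' @param ... Unused.
#' @return One-row tibble: `n`, `df.residual`, `dispersion`, `deviance`,
#'   `n_zero_outcomes`, `zero_policy`, `iterations`.
#' @method glance gamma_glm
#' @export
glance.gamma_glm <- function(x, ...) {
  tibble::tibble(
    n = x$n,
    df.residual = stats::df.residual(x$fit),
    dispersion = x$dispersion,
    deviance = x$fit$deviance,
    n_zero_outcomes = x$zero_report$n_zero,
    zero_policy = x$zero_report$policy,
    iterations = x$fit$iter
  )
}

#' Percent-change reading of a log-link coefficient
#'
#' `100 * (exp(beta) - 1)`: the percent change in the expected outcome per
#' one-unit increase in the covariate. For example, a coefficient of 0.35
#' corresponds to a 42% rise, 0.25 to a 28% rise, and -0.02 to a 2% decrease.
#'
#' @param beta Log-scale coefficient(s).
#' @param digits Optional rounding.
#' @return Numeric vector of percent changes.
#' @export
#' @examples
#' interpret_coefficient(c(0.35, 0.25, -0.02), digits = 0)
interpret_coefficient <- function(beta, digits = NULL) {
  stopifnot(all(is.finite(beta)))
  out <- 100 * (exp(beta) - 1)
  if (!is.null(digits)) out <- round(out, digits)
  out
}

assoc_outcomes <- function() {
  c("minutes_walking", "minutes_standing", "minutes_sitting", "minutes_lying",
    "transitions_daily")
}

assoc_predictors <- function() {
  c("nps_agitation", "nps_psychosis", "nps_affective", "nps_apathy",
    "sppb_total", "severity_code")
}

#' Fit the five activity-outcome association models
#'
#' For each of the five activity metrics (daily walking, standing, sitting
#' and lying minutes, and daily sedentary-to-active transitions) fits one
#' gamma log-link model with the six clinical predictors — the four NPI
#' subsyndromes, the SPPB total and the severity group as a single ordinal
#' 1-4 term — jointly. Each model keeps participants with complete
#' covariates. The coefficient table is the exposure-on-clinical direction
#' (activity predicted from clinical status); because the design is
#' cross-sectional the percent-change column can be read in either direction
#' as an association, never causally.
#'
#' @param summaries Per-participant activity summaries from
#'   [summarize_cohort()].
#' @param clinical Scored clinical table from [score_clinical()] (needs the
#'   `nps_*`, `sppb_total` and `severity_code` columns).
#' @inheritParams fit_gamma_glm
#' @return Tibble of class `"assoc_suite"` with exactly 30 predictor rows
#'   (5 outcomes x 6 predictors): `outcome`, `term`, `estimate`,
#'   `std.error`, `p.value`, `conf.low`, `conf.high`, `pct_change`, `n`.
#'   Full `gamma_glm` fits (including intercepts) are in attribute `"fits"`;
#'   zero-handling counts in attribute `"zero_report"`.
#' @export
run_association_suite <- function(summaries, clinical,
                                  zero_policy = c("shift", "drop"),
                                  zero_shift = 0.5) {
  zero_policy <- match.arg(zero_policy)
  orphans_s <- setdiff(summaries$participant_id, clinical$participant_id)
  orphans_c <- setdiff(clinical$participant_id, summaries$participant_id)
  if (length(orphans_s) > 0 || length(orphans_c) > 0) {
    stop(sprintf(
      "summaries and clinical tables do not join 1:1; orphan id(s): %s",
      paste(c(orphans_s, orphans_c), collapse = ", ")), call. = FALSE)
  }
  preds <- assoc_predictors()
  missing <- setdiff(preds, names(clinical))
  if (length(missing) > 0) {
    stop(sprintf("clinical table is missing predictor column(s): %s (run score_clinical())",
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  joined <- dplyr::inner_join(summaries, clinical, by = "participant_id")
  fml <- function(outcome) {
    stats::as.formula(paste(outcome, "~", paste(preds, collapse = " + ")))
  }
  fits <- purrr::map(stats::setNames(assoc_outcomes(), assoc_outcomes()),
                     function(o) fit_gamma_glm(joined, fml(o),
                                               zero_policy = zero_policy,
                                               zero_shift = zero_shift))
  tab <- purrr::imap_dfr(fits, function(f, o) {
    tidy(f) |>
      dplyr::filter(.data$term != "(Intercept)") |>
      dplyr::mutate(outcome = o, n = f$n, .before = 1)
  })
  zero <- purrr::imap_dfr(fits, function(f, o) {
    tibble::tibble(outcome = o, n_zero = f$zero_report$n_zero,
                   policy = f$zero_report$policy)
  })
  attr(tab, "fits") <- fits
  attr(tab, "zero_report") <- zero
  class(tab) <- c("assoc_suite", class(tab))
  tab
}

#' @method tidy assoc_suite
#' @export
tidy.assoc_suite <- function(x, ...) {
  out <- x
  attr(out, "fits") <- NULL
  attr(out, "zero_report") <- NULL
  class(out) <- setdiff(class(out), "assoc_suite")
  out
}

#' @method glance assoc_suite
#' @export
glance.assoc_suite <- function(x, ...) {
  purrr::imap_dfr(attr(x, "fits"), function(f, o) {
    dplyr::mutate(glance(f), outcome = o, .before = 1)
  })
}

#' Write the association table to CSV
#'
#' @param suite Output of [run_association_suite()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_association_csv <- function(suite, path) {
  readr::write_csv(tidy(suite), path, progress = FALSE)
  invisible(path)
}
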