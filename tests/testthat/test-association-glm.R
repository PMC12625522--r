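test_that("intercept-only gamma/log fit returns log of the sample mean", {
  set.seed(701)
  y <- rgamma(200, shape = 2, rate = 0.1)
  fit <- fit_gamma_glm(data.frame(y = y), y ~ 1)
  expect_equal(unname(coef(fit$fit)), log(mean(y)), tolerance = 1e-8)
})

test_that("simulated gamma coefficients are recovered within 3 SE", {
  set.seed(702)
  n <- 2000
  x <- rnorm(n)
  mu <- exp(0.5 + 0.3 * x)
  y <- rgamma(n, shape = 2, rate = 2 / mu)
  fit <- fit_gamma_glm(data.frame(y = y, x = x), y ~ x)
  tab <- tidy(fit)
  expect_lt(abs(tab$estimate[1] - 0.5) / tab$std.error[1], 3)
  expect_lt(abs(tab$estimate[2] - 0.3) / tab$std.error[2], 3)
})

test_that("centering a covariate shifts only the intercept", {
  set.seed(703)
  d <- data.frame(x = runif(150, 2, 6))
  d$y <- rgamma(150, shape = 3, rate = 3 / exp(1 + 0.2 * d$x))
  f1 <- fit_gamma_glm(d, y ~ x)
  d2 <- transform(d, x = x - mean(x))
  f2 <- fit_gamma_glm(d2, y ~ x)
  b1 <- coef(f1$fit); b2 <- coef(f2$fit)
  expect_equal(unname(b1["x"]), unname(b2["x"]), tolerance = 1e-7)
  expect_equal(unname(b2["(Intercept)"]),
               unname(b1["(Intercept)"] + b1["x"] * mean(d$x)), tolerance = 1e-7)
  expect_equal(unname(fitted(f1$fit)), unname(fitted(f2$fit)), tolerance = 1e-7)
})

test_that("exp(coefficient) is the multiplicative change per unit covariate", {
  set.seed(704)
  d <- data.frame(x = rnorm(300))
  d$y <- rgamma(300, shape = 2, rate = 2 / exp(0.8 + 0.25 * d$x))
  fit <- fit_gamma_glm(d, y ~ x)
  mu0 <- predict(fit$fit, newdata = data.frame(x = 1), type = "response")
  mu1 <- predict(fit$fit, newdata = data.frame(x = 2), type = "response")
  expect_equal(unname(mu1 / mu0), unname(exp(coef(fit$fit)["x"])), tolerance = 1e-9)
})

test_that("Wald CI excludes zero exactly when p < 0.05", {
  set.seed(705)
  for (rep in 1:20) {
    d <- data.frame(x = rnorm(60))
    d$y <- rgamma(60, shape = 2, rate = 2 / exp(0.5 + 0.1 * d$x))
    tab <- tidy(fit_gamma_glm(d, y ~ x))
    excl <- tab$conf.low > 0 | tab$conf.high < 0
    expect_equal(excl, tab$p.value < 0.05)
  }
})

test_that("refitting on permuted rows reproduces coefficients", {
  set.seed(706)
  d <- data.frame(x = rnorm(120), z = rnorm(120))
  d$y <- rgamma(120, shape = 2, rate = 2 / exp(0.3 + 0.2 * d$x - 0.1 * d$z))
  f1 <- fit_gamma_glm(d, y ~ x + z)
  f2 <- fit_gamma_glm(d[sample(120), ], y ~ x + z)
  expect_equal(coef(f1$fit), coef(f2$fit), tolerance = 1e-10)
})

test_that("degenerate designs and zero outcomes are handled explicitly", {
  d <- data.frame(x = rnorm(50))
  d$x2 <- 2 * d$x
  d$y <- rgamma(50, 2, 1)
  expect_error(fit_gamma_glm(d, y ~ x + x2), "collinear.*x2")

  dz <- data.frame(y = c(0, 0, rgamma(48, 2, 1)), x = rnorm(50))
  fs <- fit_gamma_glm(dz, y ~ x)
  expect_equal(fs$zero_report$n_zero, 2)
  expect_equal(fs$n, 50)
  fd <- fit_gamma_glm(dz, y ~ x, zero_policy = "drop")
  expect_equal(fd$n, 48)
  expect_error(fit_gamma_glm(data.frame(y = c(-1, rgamma(9, 2, 1)), x = rnorm(10)),
                             y ~ x), "non-negative")
})

test_that("log-link coefficients translate to percent changes", {
  expect_equal(interpret_coefficient(c(0.35, 0.25, -0.02), digits = 0),
               c(42, 28, -2))
  expect_equal(interpret_coefficient(0), 0)
  expect_equal(interpret_coefficient(log(2)), 100)
  expect_error(interpret_coefficient(Inf))
})

suite_fixture <- function(n = 120, seed = 711, sppb_coef = 0) {
  summ <- make_summaries(n, seed = seed)
  clin <- simulate_clinical_outcomes(summ, sppb_coef = sppb_coef, seed = seed + 1)
  list(summaries = summ, clinical = score_clinical(clin))
}

test_that("the association suite has the 5 x 6 outcome-by-predictor shape", {
  fx <- suite_fixture()
  suite <- run_association_suite(fx$summaries, fx$clinical)
  expect_equal(nrow(suite), 30)
  expect_equal(dplyr::n_distinct(suite$outcome), 5)
  expect_equal(dplyr::n_distinct(suite$term), 6)
  expect_false("(Intercept)" %in% suite$term)
  expect_named(attr(suite, "fits"), unique(suite$outcome))
  expect_equal(suite$pct_change, 100 * (exp(suite$estimate) - 1))

  g <- glance(suite)
  expect_equal(nrow(g), 5)
  expect_true(all(g$n == 120))
})

test_that("mismatched participant ids are rejected with the orphan list", {
  fx <- suite_fixture(n = 30)
  clin <- fx$clinical[-1, ]
  expect_error(run_association_suite(fx$summaries, clin),
               fx$summaries$participant_id[1])
})

test_that("an implanted SPPB association is recovered in sign and rough size", {
  set.seed(712)
  summ <- make_summaries(500)
  hits <- 0
  ests <- numeric(25)
  for (r in 1:25) {
    clin <- score_clinical(suppressMessages(
      simulate_clinical_outcomes(summ, sppb_coef = 0.3, outcome = "minutes_walking")))
    fit <- fit_gamma_glm(dplyr::inner_join(summ, clin, by = "participant_id"),
                         minutes_walking ~ nps_agitation + nps_psychosis +
                           nps_affective + nps_apathy + sppb_total + severity_code)
    est <- tidy(fit)$estimate[tidy(fit)$term == "sppb_total"]
    ests[r] <- est
    if (est > 0) hits <- hits + 1
  }
  expect_gte(hits / 25, 0.95)
  # magnitude approximately recovered (rounding/clipping of SPPB attenuates)
  expect_gt(mean(ests), 0.15)
  expect_lt(mean(ests), 0.45)
})
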