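test_that("truncated negative log-likelihood matches hand evaluation and the Gaussian limit", {
  X1 <- matrix(1, 1, 1)
  # y = 1, mu = 0, sigma = 1, tau = 0: -log[phi(1) / (1 - Phi(0))]
  expect_equal(
    tobit_negloglik(c(0, 0), y = 1, X = X1, bound = 0, variant = "truncated"),
    -log(dnorm(1) / 0.5)
  )
  # bound -> -Inf recovers the ordinary Gaussian negative log-likelihood
  set.seed(2)
  n <- 25
  X <- cbind(1, rnorm(n))
  y <- drop(X %*% c(1, 0.5)) + rnorm(n)
  par <- c(0.8, 0.4, log(1.3))
  gauss <- -sum(dnorm((y - drop(X %*% par[1:2])) / 1.3, log = TRUE) - log(1.3))
  expect_equal(
    tobit_negloglik(par, y, X, bound = -1e6, variant = "truncated"),
    gauss, tolerance = 1e-10
  )
  expect_equal(
    tobit_negloglik(par, y, X, bound = -1e6, variant = "censored"),
    gauss, tolerance = 1e-10
  )
  expect_error(tobit_negloglik(par, y = c(0, 1), X = matrix(1, 2, 1),
                               bound = 0, variant = "truncated"),
               "y > bound")
})

test_that("the profile in sigma is unimodal for fixed coefficients", {
  set.seed(8)
  y <- abs(rnorm(500, 1, 1))
  X <- matrix(1, 500, 1)
  grid <- seq(0.1, 10, length.out = 200)
  nll <- vapply(grid, function(s) {
    tobit_negloglik(c(1, log(s)), y, X, bound = 0, variant = "truncated")
  }, 1.0)
  d <- diff(nll)
  # strictly decreasing then strictly increasing: one sign change
  expect_equal(sum(diff(sign(d)) != 0), 1L)
})

test_that("the censored fit collapses to OLS when the bound is far below the data", {
  set.seed(4)
  n <- 120
  X <- cbind(1, rnorm(n), rbinom(n, 1, 0.5))
  colnames(X) <- c("(Intercept)", "x1", "x2")
  y <- drop(X %*% c(5, 1, -0.5)) + rnorm(n)
  fit <- fit_tobit(y, X, bound = min(y) - 50, variant = "censored")
  ols <- lm.fit(X, y)
  expect_equal(unname(fit$beta), unname(ols$coefficients), tolerance = 1e-6)
  sig_mle <- sqrt(mean(ols$residuals^2))
  expect_equal(fit$sigma, sig_mle, tolerance = 1e-6)
  # no observation at the bound: censored log-likelihood equals Gaussian
  par <- c(fit$beta, log(fit$sigma))
  gauss <- -sum(dnorm((y - drop(X %*% fit$beta)) / fit$sigma, log = TRUE) -
                  log(fit$sigma))
  expect_equal(-fit$loglik, gauss, tolerance = 1e-10)
})

test_that("the truncated fit recovers truncated-normal parameters", {
  set.seed(9)
  n <- 2000
  # draw from normal(1, 1) truncated at 0 by inverse CDF
  u <- runif(n, pnorm(0, 1, 1), 1)
  y <- qnorm(u, 1, 1)
  X <- matrix(1, n, 1, dimnames = list(NULL, "(Intercept)"))
  fit <- fit_tobit(y, X, bound = 0, variant = "truncated")
  td <- tidy(fit)
  expect_true(fit$converged)
  expect_lt(abs(td$estimate[1] - 1), 3 * td$std.error[1])
  expect_lt(abs(td$estimate[2] - 1), 3 * td$std.error[2])
})

test_that("the optimizer lands on the dense-grid optimum (intercept-only)", {
  set.seed(10)
  y <- abs(rnorm(50, 0.8, 0.9))
  X <- matrix(1, 50, 1)
  fit <- fit_tobit(y, X, bound = 0, variant = "truncated")
  mus <- seq(-1, 2, by = 0.01)
  sigs <- seq(0.3, 2.5, by = 0.01)
  nll <- outer(mus, sigs, Vectorize(function(m, s) {
    tobit_negloglik(c(m, log(s)), y, X, bound = 0, variant = "truncated")
  }))
  best <- which(nll == min(nll), arr.ind = TRUE)
  expect_lt(abs(fit$beta[[1]] - mus[best[1]]), 0.011)
  expect_lt(abs(fit$sigma - sigs[best[2]]), 0.011)
})

test_that("the censored fit agrees with an independent left-censored Gaussian fitter", {
  skip_if_not_installed("survival")
  set.seed(12)
  n <- 400
  x <- rnorm(n)
  ystar <- 0.4 + 0.8 * x + rnorm(n, 0, 1.2)
  y <- pmax(ystar, 0)
  X <- cbind(`(Intercept)` = 1, x = x)
  fit <- fit_tobit(y, X, bound = 0, variant = "censored")
  sv <- survival::survreg(
    survival::Surv(y, y > 0, type = "left") ~ x, dist = "gaussian"
  )
  expect_equal(unname(fit$beta), unname(coef(sv)), tolerance = 1e-4)
  expect_equal(fit$sigma, sv$scale, tolerance = 1e-4)
  expect_equal(fit$loglik, sv$loglik[2], tolerance = 1e-6)
})

test_that("convergent fits have tiny gradients and the likelihood is extensive", {
  set.seed(14)
  n <- 150
  g <- sample(0:2, n, TRUE, c(.25, .5, .25))
  X <- model.matrix(~ factor(g))
  y <- abs(rnorm(n, 1, 1 + 0.3 * g))
  for (variant in c("truncated", "censored")) {
    fit <- fit_tobit(y, X, bound = 0, variant = variant)
    expect_true(fit$converged)
    expect_lt(fit$gradient_norm, 1e-5)
    par <- c(fit$beta, log(fit$sigma))
    # appending an exact copy doubles the log-likelihood at the same point
    ll1 <- -tobit_negloglik(par, y, X, bound = 0, variant = variant)
    ll2 <- -tobit_negloglik(par, c(y, y), rbind(X, X), bound = 0,
                            variant = variant)
    expect_equal(ll2, 2 * ll1, tolerance = 1e-10)
  }
})

test_that("Wald machinery: z-ratio identity, null fit, and error cases", {
  set.seed(15)
  n <- 200
  x <- rbinom(n, 1, 0.5)
  X <- cbind(`(Intercept)` = 1, x = x)
  y <- abs(rnorm(n, 1 + 0.5 * x))
  fit <- fit_tobit(y, X, bound = 0, variant = "truncated")
  td <- tidy(fit)
  w <- wald_contrast(fit, c(0, 1), label = "slope")
  expect_equal(w$statistic, td$statistic[2]^2, tolerance = 1e-10)
  expect_equal(w$estimate, td$estimate[2])
  expect_equal(w$df, 1)

  fit0 <- fake_locus_fit(0, 0, 0)
  fit0$beta[] <- 0
  w0 <- wald_contrast(fit0, diag(3), label = "identity")
  expect_equal(w0$statistic, 0)
  expect_equal(w0$p.value, 1)

  expect_error(wald_contrast(fit, c(0, 0)), "all-zero")
  expect_error(wald_contrast(fit, rbind(c(0, 1), c(0, 2))), "dependent")
})

test_that("joint Wald P-values are uniform under a correctly specified null", {
  set.seed(16)
  ps <- replicate(1000, {
    n <- 300
    g <- sample(0:2, n, TRUE, c(.25, .5, .25))
    X <- model.matrix(~ factor(g))
    y <- qnorm(runif(n, pnorm(0, 1, 1), 1), 1, 1)
    fit <- fit_tobit(y, X, bound = 0, variant = "truncated")
    wald_contrast(fit, cbind(0, diag(2)), label = "joint")$p.value
  })
  expect_gt(stats::ks.test(ps, "punif")$p.value, 0.01)
})
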