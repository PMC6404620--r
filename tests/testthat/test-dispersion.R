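test_that("MLH counts heterozygous calls over typed markers only", {
  g <- tibble::tibble(
    individual = c("a", "b", "c", "d"),
    m1 = c(1L, 0L, 1L, NA),
    m2 = c(1L, 2L, NA, NA),
    m3 = c(1L, 0L, 0L, NA)
  )
  expect_warning(res <- compute_mlh(g), "zero typed")
  expect_equal(res$mlh[1], 1.0)   # all het
  expect_equal(res$mlh[2], 0.0)   # none het
  expect_equal(res$mlh[3], 0.5)   # 1 het of 2 typed, missing excluded
  expect_true(is.na(res$mlh[4]))
})

test_that("intercept-only covariate model reproduces the mean and residuals", {
  co <- toy_cohort()
  co$phenotypes$ualb <- c(1, 2, 3)
  spec <- covariate_spec("ualb", include_ucrea = FALSE)
  fit <- fit_covariate_model(co, spec)
  expect_equal(unname(coef(fit$lm)), 2)
  expect_equal(unname(residuals(fit$lm)), c(-1, 0, 1))
})

test_that("covariate-model coefficients solve the normal equations", {
  set.seed(21)
  n <- 20
  X <- cbind(1, rnorm(n), runif(n))
  beta <- c(0.5, -1.2, 2)
  y <- drop(X %*% beta) + rnorm(n)
  co <- f2_cohort(
    genotypes = tibble::tibble(individual = sprintf("i%02d", 1:n),
                               m1 = rep(1L, n), m2 = rep(0L, n)),
    phenotypes = tibble::tibble(individual = sprintf("i%02d", 1:n),
                                ualb = pmax(y, 0) + 1, ucrea = abs(X[, 2]) * 10,
                                weight = X[, 3] * 10 + 30),
    map = toy_map(), strains = c("P1", "P2")
  )
  spec <- covariate_spec("ualb", include_ucrea = TRUE)
  fit <- fit_covariate_model(co, spec)
  # brute-force normal equations oracle
  Xo <- cbind(1, co$phenotypes$ucrea)
  bo <- solve(t(Xo) %*% Xo) %*% t(Xo) %*% co$phenotypes$ualb
  expect_equal(unname(coef(fit$lm)), drop(bo), tolerance = 1e-8)
})

test_that("a covariate orthogonal to the locus factor leaves locus coefficients unchanged", {
  set.seed(33)
  n <- 60
  g <- rep(0:2, each = n / 3)
  dat <- data.frame(
    locus = factor(c("hom_p1", "het", "hom_p2")[g + 1],
                   levels = c("hom_p2", "het", "hom_p1"))
  )
  y <- rnorm(n, mean = g)
  # build a covariate orthogonal to the locus design columns
  D <- model.matrix(~ locus, dat)
  zraw <- rnorm(n)
  z <- residuals(lm(zraw ~ D - 1))
  f1 <- lm(y ~ locus, dat)
  f2 <- lm(y ~ locus + z, dat)
  expect_equal(coef(f2)[names(coef(f1))], coef(f1), tolerance = 1e-10)
})

test_that("externally Studentized residuals match the leave-one-out refit oracle", {
  set.seed(5)
  for (rep in 1:20) {
    n <- sample(12:25, 1)
    X <- cbind(1, rnorm(n))
    y <- drop(X %*% c(1, 0.5)) + rnorm(n)
    ids <- sprintf("i%02d", 1:n)
    co <- f2_cohort(
      genotypes = tibble::tibble(individual = ids, m1 = rep(1L, n),
                                 m2 = rep(0L, n)),
      phenotypes = tibble::tibble(individual = ids, ualb = abs(y),
                                  ucrea = abs(X[, 2]) + 1),
      map = toy_map(), strains = c("P1", "P2")
    )
    spec <- covariate_spec("ualb", include_ucrea = TRUE)
    fit <- fit_covariate_model(co, spec)
    res <- studentize_external(fit)
    # oracle: scale recomputed after deleting each observation in turn
    Xo <- cbind(1, co$phenotypes$ucrea)
    yo <- co$phenotypes$ualb
    e <- residuals(lm(yo ~ Xo - 1))
    h <- diag(Xo %*% solve(t(Xo) %*% Xo) %*% t(Xo))
    m <- ncol(Xo)
    t_oracle <- vapply(1:n, function(i) {
      fi <- lm(yo[-i] ~ Xo[-i, ] - 1)
      s_i <- sqrt(sum(residuals(fi)^2) / (n - 1 - m))
      e[i] / (s_i * sqrt(1 - h[i]))
    }, 1.0)
    expect_equal(res$t, t_oracle, tolerance = 1e-8)
    expect_equal(res$pd, abs(t_oracle))
  }
})

test_that("residual orthogonality holds and the middle point of a symmetric fit has zero dispersion", {
  co <- toy_cohort()
  co$phenotypes$ualb <- c(0, 1, 2)
  spec <- covariate_spec("ualb", include_ucrea = FALSE)
  fit <- fit_covariate_model(co, spec)
  res <- studentize_external(fit)
  expect_equal(res$t[2], 0)
  expect_equal(res$pd[2], 0)
  expect_lt(abs(sum(res$residual)), 1e-10)

  set.seed(13)
  n <- 40
  ids <- sprintf("i%02d", 1:n)
  co2 <- f2_cohort(
    genotypes = tibble::tibble(individual = ids,
                               m1 = sample(0:2, n, TRUE),
                               m2 = sample(0:2, n, TRUE)),
    phenotypes = tibble::tibble(individual = ids, ualb = abs(rnorm(n)),
                                ucrea = runif(n, 50, 100)),
    map = toy_map(), strains = c("P1", "P2")
  )
  spec2 <- covariate_spec("ualb", locus = "m1", include_ucrea = TRUE)
  fit2 <- fit_covariate_model(co2, spec2)
  res2 <- studentize_external(fit2)
  Xm <- model.matrix(fit2$lm)
  for (j in seq_len(ncol(Xm))) {
    expect_lt(abs(sum(res2$residual * Xm[, j])) /
                max(1, sum(abs(res2$residual))), 1e-8)
  }
})

test_that("dispersion is invariant to positive affine transformation of the trait", {
  set.seed(17)
  n <- 30
  ids <- sprintf("i%02d", 1:n)
  base <- abs(rnorm(n)) + 0.1
  make <- function(y) {
    f2_cohort(
      genotypes = tibble::tibble(individual = ids,
                                 m1 = sample(0:2, n, TRUE),
                                 m2 = rep(1L, n)),
      phenotypes = tibble::tibble(individual = ids, ualb = y,
                                  ucrea = runif(n, 50, 100)),
      map = toy_map(), strains = c("P1", "P2")
    )
  }
  set.seed(17)
  co1 <- make(base)
  set.seed(17)
  co2 <- make(10 * base + 7)
  spec <- covariate_spec("ualb", include_ucrea = TRUE)
  r1 <- studentize_external(fit_covariate_model(co1, spec))
  r2 <- studentize_external(fit_covariate_model(co2, spec))
  expect_equal(r1$t, r2$t, tolerance = 1e-10)
})

test_that("covariate selection includes MLH when it drives dispersion and respects the creatinine rule", {
  map <- fast_map()
  # strong negative MLH effect on dispersion (generator default is -2)
  co <- simulate_cohort(map = map,
                        config = sim_config(n = 300, mlh_sigma_slope = -4),
                        seed = 31)
  spec <- select_covariates(co, "ualb")
  expect_true(spec$include_mlh)
  expect_true(spec$include_ucrea)
  probe <- attr(spec, "mlh_probe")
  expect_lt(probe$estimate, 0)

  spec_cr <- select_covariates(co, "ucrea")
  expect_false(spec_cr$include_ucrea)
  expect_error(covariate_spec("ucrea", include_ucrea = TRUE), "permitted")
})

test_that("the MLH probe fires at roughly its nominal rate under no MLH effect", {
  map <- fast_map()
  set.seed(61)
  hits <- replicate(400, {
    co <- simulate_cohort(
      map = map,
      config = sim_config(n = 300, mlh_sigma_slope = 0, mlh_ualb_slope = 0),
      seed = sample.int(2^31 - 2, 1)
    )
    select_covariates(co, "ualb")$include_mlh
  })
  # nominal 0.1; 99% binomial band for 400 replicates
  band <- qbinom(c(0.005, 0.995), 400, 0.1) / 400
  expect_gte(mean(hits), band[1])
  expect_lte(mean(hits), band[2])
})
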