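#' Negative log-likelihood of a left-bounded Gaussian regression
#'
#' Two variants of the zero-bounded ("Tobit") Gaussian model for a response
#' with a lower bound `tau`:
#' \describe{
#'   \item{truncated}{all observations lie strictly above the bound and the
#'     Gaussian density is renormalized there:
#'     `ll_i = log phi(z_i) - log sigma - log(1 - Phi(a_i))` with
#'     `z_i = (y_i - x_i'b)/sigma` and `a_i = (tau - x_i'b)/sigma`.}
#'   \item{censored}{observations at or below the bound contribute the mass
#'     `log Phi(a_i)`; uncensored ones the usual Gaussian log-density.}
#' }
#' The scale enters as `log(sigma)` (last element of `par`) so optimization is
#' unconstrained. Log-CDF asymptotics (`pnorm(..., log.p = TRUE)`) guard the
#' tails; a non-finite value is returned as a large finite penalty so
#' quasi-Newton steps can recover.
#'
#' @param par Numeric vector `c(beta, log_sigma)`.
#' @param y Response vector.
#' @param X Design matrix (rows match `y`).
#' @param bound Lower bound `tau` (default 0).
#' @param variant `"truncated"` or `"censored"`.
#' @return Scalar negative log-likelihood.
#' @export
tobit_negloglik <- function(par, y, X, bound = 0,
                            variant = c("truncated", "censored")) {
  variant <- match.arg(variant)
  if (variant == "truncated" && any(y <= bound)) {
    abort("truncated variant requires all y > bound")
  }
  tobit_nll_impl(par, y, X, bound, truncated = variant == "truncated")
}

tobit_nll_impl <- function(par, y, X, bound, truncated) {
  p <- ncol(X)
  sigma <- exp(par[p + 1L])
  mu <- drop(X %*% par[seq_len(p)])
  z <- (y - mu) / sigma
  a <- (bound - mu) / sigma
  if (truncated) {
    ll <- dnorm(z, log = TRUE) - log(sigma) -
      pnorm(a, lower.tail = FALSE, log.p = TRUE)
  } else {
    cens <- y <= bound
    ll <- numeric(length(y))
    ll[!cens] <- dnorm(z[!cens], log = TRUE) - log(sigma)
    ll[cens] <- pnorm(a[cens], log.p = TRUE)
  }
  val <- -sum(ll)
  if (!is.finite(val)) val <- .Machine$double.xmax / 2
  val
}

# Analytic gradient of tobit_negloglik in (beta, log sigma).
tobit_gradient <- function(par, y, X, bound = 0,
                           variant = c("truncated", "censored")) {
  variant <- match.arg(variant)
  tobit_grad_impl(par, y, X, bound, truncated = variant == "truncated")
}

tobit_grad_impl <- function(par, y, X, bound, truncated) {
  p <- ncol(X)
  sigma <- exp(par[p + 1L])
  mu <- drop(X %*% par[seq_len(p)])
  z <- (y - mu) / sigma
  a <- (bound - mu) / sigma
  if (truncated) {
    # hazard of the upper tail: phi(a) / (1 - Phi(a))
    lam <- exp(dnorm(a, log = TRUE) -
                 pnorm(a, lower.tail = FALSE, log.p = TRUE))
    dmu <- (z - lam) / sigma
    dls <- z^2 - 1 - a * lam
  } else {
    cens <- y <= bound
    # inverse Mills ratio for censored terms: phi(a) / Phi(a)
    mills <- exp(dnorm(a, log = TRUE) - pnorm(a, log.p = TRUE))
    dmu <- ifelse(cens, -mills / sigma, z / sigma)
    dls <- ifelse(cens, -a * mills, z^2 - 1)
  }
  g <- c(drop(crossprod(X, dmu)), sum(dls))
  -g
}

# Observed information via central differences of the analytic gradient,
# step 1e-5 * (1 + |theta|) per coordinate; symmetrized.
tobit_obs_info <- function(par, y, X, bound, truncated) {
  k <- length(par)
  H <- matrix(0, k, k)
  for (j in seq_len(k)) {
    h <- 1e-5 * (1 + abs(par[j]))
    up <- dn <- par
    up[j] <- par[j] + h
    dn[j] <- par[j] - h
    H[, j] <- (tobit_grad_impl(up, y, X, bound, truncated) -
                 tobit_grad_impl(dn, y, X, bound, truncated)) / (2 * h)
  }
  (H + t(H)) / 2
}

#' Fit a left-bounded Gaussian (Tobit) regression by maximum likelihood
#'
#' BFGS quasi-Newton optimization of [tobit_negloglik()] from OLS start
#' values, followed by Newton polishing steps until the gradient norm falls
#' below 1e-6 (the convergence criterion). Standard errors come from the
#' inverse of the numerically differentiated observed information at the
#' optimum; the scale is optimized as `log sigma` and reported (with its
#' variance, via the delta method) on the natural scale.
#'
#' @param y Response vector (phenotypic dispersion in the scan).
#' @param X Design matrix with named columns; must be full rank.
#' @param bound Lower bound `tau` (default 0).
#' @param variant `"truncated"` (density renormalized above the bound; the
#'   scan default) or `"censored"` (probability mass at the bound).
#' @param start Optional start values `c(beta, log_sigma)`.
#' @return An object of class `tobit_fit`: list with `beta` (named), `sigma`,
#'   `vcov` ((p+1) x (p+1), last row/col = sigma on the natural scale),
#'   `loglik`, `converged`, `n`, `iterations`, `gradient_norm`, `fitted`,
#'   `variant`, `bound`.
#' @export
fit_tobit <- function(y, X, bound = 0,
                      variant = c("truncated", "censored"), start = NULL) {
  variant <- match.arg(variant)
  X <- as.matrix(X)
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  p <- ncol(X)
  n <- length(y)
  if (n < p + 2L) abort("need at least ncol(X) + 2 observations")
  qrX <- qr(X)
  if (qrX$rank < p) abort("rank-deficient design matrix",
                          class = "dispscan_degenerate")
  if (is.null(start)) {
    b0 <- qr.coef(qrX, y)
    r0 <- y - drop(X %*% b0)
    s0 <- sqrt(mean(r0^2))
    if (!is.finite(s0) || s0 <= 0) s0 <- sd(y) %||% 1
    start <- c(b0, log(s0))
  }
  truncated <- variant == "truncated"
  if (truncated && any(y <= bound)) {
    abort("truncated variant requires all y > bound")
  }
  opt <- optim(start, tobit_nll_impl, gr = tobit_grad_impl,
               y = y, X = X, bound = bound, truncated = truncated,
               method = "BFGS",
               control = list(maxit = 500, reltol = 1e-8))
  par <- opt$par
  iterations <- opt$counts[["function"]]
  # Newton polish: drive the gradient norm below the 1e-6 convergence cut.
  for (it in seq_len(25L)) {
    g <- tobit_grad_impl(par, y, X, bound, truncated)
    if (sqrt(sum(g^2)) < 1e-8) break
    H <- tobit_obs_info(par, y, X, bound, truncated)
    step <- tryCatch(solve(H, g), error = function(e) NULL)
    if (is.null(step)) break
    f_old <- tobit_nll_impl(par, y, X, bound, truncated)
    damp <- 1
    repeat {
      cand <- par - damp * step
      f_new <- tobit_nll_impl(cand, y, X, bound, truncated)
      if (is.finite(f_new) && f_new <= f_old + 1e-12) break
      damp <- damp / 2
      if (damp < 1e-6) {
        cand <- par
        break
      }
    }
    if (identical(cand, par)) break
    par <- cand
    iterations <- iterations + 1L
  }
  g <- tobit_grad_impl(par, y, X, bound, truncated)
  gnorm <- sqrt(sum(g^2))
  converged <- is.finite(gnorm) && gnorm < 1e-6
  if (!converged) {
    warn(paste0("tobit fit did not reach gradient norm < 1e-6 (",
                formatC(gnorm, format = "e", digits = 2), ")"))
  }
  H <- tobit_obs_info(par, y, X, bound, truncated)
  Vint <- tryCatch(solve(H), error = function(e) {
    warn("observed information singular; vcov from pseudoinverse")
    ev <- eigen(H, symmetric = TRUE)
    pos <- ev$values > max(ev$values) * 1e-12
    ev$vectors[, pos, drop = FALSE] %*%
      diag(1 / ev$values[pos], sum(pos)) %*%
      t(ev$vectors[, pos, drop = FALSE])
  })
  sigma <- unname(exp(par[p + 1L]))
  J <- diag(c(rep(1, p), sigma))
  V <- J %*% Vint %*% J
  dimnames(V) <- list(c(colnames(X), "sigma"), c(colnames(X), "sigma"))
  beta <- setNames(par[seq_len(p)], colnames(X))
  structure(
    list(
      beta = beta, sigma = sigma, vcov = V,
      loglik = -tobit_nll_impl(par, y, X, bound, truncated),
      converged = converged, n = n, iterations = unname(iterations),
      gradient_norm = gnorm,
      fitted = drop(X %*% beta),
      y = y, variant = variant, bound = bound
    ),
    class = "tobit_fit"
  )
}

#' @export
print.tobit_fit <- function(x, ...) {
  cat("<tobit_fit> variant:", x$variant, " bound:", x$bound,
      " n:", x$n, " logLik:", formatC(x$loglik, digits = 6), "\n")
  print(tidy(x), n = Inf)
  invisible(x)
}

#' Tidy a Tobit fit
#'
#' @param x A `tobit_fit`.
#' @param ... Unused.
#' @return Tibble with `term`, `estimate`, `std.error`, `statistic`,
#'   `p.value` (normal-theory z tests), including the scale `sigma`.
#' @method tidy tobit_fit
#' @export
tidy.tobit_fit <- function(x, ...) {
  est <- c(x$beta, sigma = x$sigma)
  se <- sqrt(pmax(diag(x$vcov), 0))
  z <- est / se
  tibble(
    term = names(est),
    estimate = unname(est),
    std.error = unname(se),
    statistic = unname(z),
    p.value = 2 * pnorm(abs(unname(z)), lower.tail = FALSE)
  )
}

#' Glance at a Tobit fit
#'
#' @param x A `tobit_fit`.
#' @param ... Unused.
#' @return One-row tibble with `logLik`, `sigma`, `n`, `converged`,
#'   `iterations`, `variant`, `bound`.
#' @method glance tobit_fit
#' @export
glance.tobit_fit <- function(x, ...) {
  tibble(logLik = x$loglik, sigma = x$sigma, n = x$n,
         converged = x$converged, iterations = x$iterations,
         variant = x$variant, bound = x$bound)
}

#' Wald test of linear contrasts on Tobit coefficients
#'
#' Computes `W = (C b)' (C V C')^-1 (C b)` and refers it to a chi-square with
#' `nrow(C)` degrees of freedom. A single-row contrast additionally reports
#' its signed estimate and standard error.
#'
#' @param fit A `tobit_fit`.
#' @param C Contrast matrix (rows = contrasts) over the regression
#'   coefficients, `ncol(C) = length(fit$beta)`. A vector is treated as one
#'   row.
#' @param label Optional contrast label for reporting.
#' @return Tibble with `contrast`, `estimate`, `std.error` (NA for joint
#'   contrasts), `statistic`, `df`, `p.value`.
#' @export
wald_contrast <- function(fit, C, label = NULL) {
  stopifnot(inherits(fit, "tobit_fit"))
  if (is.null(dim(C))) C <- matrix(C, nrow = 1)
  p <- length(fit$beta)
  if (ncol(C) != p) abort("contrast has wrong number of columns")
  if (any(rowSums(abs(C)) == 0)) abort("all-zero contrast row")
  if (qr(C)$rank < nrow(C)) abort("contrast rows are linearly dependent")
  Vb <- fit$vcov[seq_len(p), seq_len(p), drop = FALSE]
  est <- drop(C %*% fit$beta)
  M <- C %*% Vb %*% t(C)
  Mi <- tryCatch(solve(M), error = function(e) NULL)
  if (is.null(Mi) || !is.finite(rcond(M)) || rcond(M) < 1e-14) {
    abort(paste0("singular contrast covariance for: ",
                 label %||% paste(apply(C, 1, paste, collapse = " "),
                                  collapse = "; ")))
  }
  stat <- drop(t(est) %*% Mi %*% est)
  df <- nrow(C)
  tibble::new_tibble(list(
    contrast = label %||% if (df == 1L) paste(C[1, ], collapse = " ") else "joint",
    estimate = if (df == 1L) est else NA_real_,
    std.error = if (df == 1L) sqrt(M[1, 1]) else NA_real_,
    statistic = stat,
    df = df,
    p.value = pchisq(stat, df = df, lower.tail = FALSE)
  ), nrow = 1L)
}
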