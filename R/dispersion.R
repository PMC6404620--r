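#' Multilocus heterozygosity per individual
#'
#' MLH = n_het / n_typed, counting only non-missing genotypes in the
#' denominator. Used as a proxy for genome-wide inbreeding; individuals with
#' no typed markers get `NA` with a warning.
#'
#' @param x An `f2_cohort` or a genotype tibble (`individual` + 0/1/2 marker
#'   columns).
#' @return Tibble with columns `individual`, `n_typed`, `n_het`, `mlh`.
#' @export
compute_mlh <- function(x) {
  g <- if (inherits(x, "f2_cohort")) x$genotypes else as_tibble(x)
  mk <- setdiff(names(g), "individual")
  gm <- as.matrix(g[mk])
  n_typed <- rowSums(!is.na(gm))
  n_het <- rowSums(gm == 1L, na.rm = TRUE)
  mlh <- ifelse(n_typed > 0L, n_het / n_typed, NA_real_)
  if (any(n_typed == 0L)) {
    warn(paste0(sum(n_typed == 0L),
                " individual(s) with zero typed markers: MLH set to NA"))
  }
  tibble(individual = g$individual, n_typed = n_typed,
         n_het = as.integer(n_het), mlh = mlh)
}

#' Covariate model specification
#'
#' Describes the stage-1 linear model for one trait: optional per-marker locus
#' term (a 3-level genotype factor), optional multilocus heterozygosity, and a
#' creatinine regression term that is only permitted for albumin (creatinine
#' is the throughput covariate for albuminuria, not for itself).
#'
#' @param trait One of `"ualb"`, `"ucrea"`, `"bun"`.
#' @param locus Optional marker ID for the locus term.
#' @param include_mlh Include MLH as a covariate?
#' @param include_ucrea Include urinary creatinine as a covariate? Only
#'   allowed when `trait = "ualb"`.
#' @return An object of class `covariate_spec`.
#' @export
covariate_spec <- function(trait = c("ualb", "ucrea", "bun"), locus = NULL,
                           include_mlh = FALSE,
                           include_ucrea = (trait[1] == "ualb")) {
  trait <- match.arg(trait)
  if (include_ucrea && trait != "ualb") {
    abort("include_ucrea is only permitted when trait = 'ualb'")
  }
  structure(
    list(trait = trait, locus = locus, include_mlh = include_mlh,
         include_ucrea = include_ucrea),
    class = "covariate_spec"
  )
}

# Assemble the casewise-complete model frame for a covariate spec.
# Genotype classes are labelled hom_p1/het/hom_p2 with the P2 homozygote as
# the reference (first) factor level.
covariate_frame <- function(cohort, spec, mlh = NULL) {
  ids <- cohort$phenotypes$individual
  cols <- list(individual = ids, y = cohort$phenotypes[[spec$trait]])
  if (spec$include_ucrea) cols$ucrea <- cohort$phenotypes$ucrea
  if (spec$include_mlh) {
    if (is.null(mlh)) mlh <- compute_mlh(cohort)
    cols$mlh <- mlh$mlh[match(ids, mlh$individual)]
  }
  if (!is.null(spec$locus)) {
    gcol <- cohort$genotypes[[spec$locus]]
    if (is.null(gcol)) abort(paste0("marker not in genotypes: ", spec$locus))
    g <- gcol[match(ids, cohort$genotypes$individual)]
    cols$locus <- factor(c("hom_p1", "het", "hom_p2")[g + 1L],
                         levels = c("hom_p2", "het", "hom_p1"))
  }
  dat <- tibble::new_tibble(cols, nrow = length(ids))
  dat[complete.cases(dat), , drop = FALSE]
}

#' Fit the stage-1 covariate model
#'
#' Ordinary least squares on casewise-complete data for
#' `y = mu + locus + b_MLH * MLH + b_UCrea * UCrea + e`, with whichever terms
#' the spec includes. The locus term enters as a 3-level genotype factor with
#' the P2 homozygote as reference level.
#'
#' @param cohort An `f2_cohort`.
#' @param spec A [covariate_spec()].
#' @param mlh Optional precomputed [compute_mlh()] table (avoids recomputation
#'   in per-marker loops).
#' @return An object of class `covariate_fit` wrapping the `lm` fit, the data
#'   used, and the spec.
#' @export
fit_covariate_model <- function(cohort, spec, mlh = NULL) {
  stopifnot(inherits(spec, "covariate_spec"))
  dat <- covariate_frame(cohort, spec, mlh = mlh)
  rhs <- c(
    if (!is.null(spec$locus)) "locus",
    if (spec$include_mlh) "mlh",
    if (spec$include_ucrea) "ucrea"
  )
  fml <- stats::reformulate(if (length(rhs)) rhs else "1", response = "y")
  ncol_model <- 1L +
    (if (!is.null(spec$locus)) length(unique(as.integer(dat$locus))) - 1L else 0L) +
    spec$include_mlh + spec$include_ucrea
  if (nrow(dat) < ncol_model + 2L) {
    abort("too few complete cases for the covariate model",
          class = "dispscan_too_few")
  }
  if (!is.null(spec$locus)) {
    dat$locus <- droplevels(dat$locus)
    if (nlevels(dat$locus) < 2L) {
      abort(paste0("degenerate fit: locus ", spec$locus,
                   " has fewer than 2 observed genotype classes"),
            class = "dispscan_degenerate")
    }
  }
  fit <- lm(fml, data = dat)
  if (fit$rank < length(coef(fit)) || anyNA(coef(fit))) {
    abort("degenerate fit: rank-deficient design",
          class = "dispscan_degenerate")
  }
  structure(
    list(lm = fit, data = dat, spec = spec, n = nrow(dat),
         df_residual = fit$df.residual),
    class = "covariate_fit"
  )
}

#' @export
print.covariate_fit <- function(x, ...) {
  cat("<covariate_fit> trait:", x$spec$trait,
      if (!is.null(x$spec$locus)) paste0("locus: ", x$spec$locus),
      "n:", x$n, "\n")
  print(coef(x$lm))
  invisible(x)
}

#' Externally Studentized residuals and phenotypic dispersion
#'
#' Divides each ordinary residual by its standard error computed with that
#' observation deleted: `t_i = e_i / (sigma_(i) * sqrt(1 - h_ii))`, where
#' `h_ii` is the leverage and `sigma_(i)^2 = sum_{j != i} e_j^2 / (n - m - 1)`
#' is the deleted scale. Phenotypic dispersion is `pd_i = |t_i|`.
#' Observations with leverage numerically at 1 carry no residual information
#' and are dropped with a warning.
#'
#' @param fit A `covariate_fit` from [fit_covariate_model()].
#' @return A tibble (class `dispersion_result`) with columns `individual`,
#'   `residual`, `leverage`, `sigma_loo`, `t`, `pd`; attributes `n`, `df`
#'   (residual degrees of freedom of the leave-one-out scale, n - m - 1) and
#'   `m` (model columns).
#' @export
studentize_external <- function(fit) {
  stopifnot(inherits(fit, "covariate_fit"))
  lmfit <- fit$lm
  n <- fit$n
  m <- lmfit$rank
  if (n - m - 1L < 1L) abort("need n - m - 1 >= 1 to studentize externally")
  h <- hatvalues(lmfit)
  infl <- lm.influence(lmfit, do.coef = FALSE)
  e <- residuals(lmfit)
  keep <- h < 1 - 1e-10
  if (any(!keep)) {
    warn(paste0(sum(!keep), " observation(s) with leverage ~1 dropped"))
  }
  sigma_loo <- infl$sigma
  t <- e / (sigma_loo * sqrt(1 - h))
  out <- tibble::new_tibble(list(
    individual = fit$data$individual,
    residual = unname(e),
    leverage = unname(h),
    sigma_loo = unname(sigma_loo),
    t = unname(t),
    pd = abs(unname(t))
  ), nrow = fit$n)[keep, , drop = FALSE]
  structure(out, n = n, df = n - m - 1L, m = m,
            class = c("dispersion_result", class(out)))
}

#' Choose stage-1 covariates for a trait
#'
#' Fits the locus-free covariate model, computes phenotypic dispersion from
#' it, and probes the association of MLH with PD by ordinary regression. MLH
#' is included as a covariate when its two-sided P-value is below
#' `probe_p` (default 0.1); creatinine is included exactly when the trait is
#' albumin.
#'
#' @param cohort An `f2_cohort`.
#' @param trait Trait label.
#' @param probe_p Inclusion threshold for the MLH-PD probe.
#' @param mlh Optional precomputed MLH table.
#' @return A [covariate_spec()] (locus-free) with `include_mlh` set; the
#'   probe regression summary is attached as attribute `"mlh_probe"`.
#' @export
select_covariates <- function(cohort, trait, probe_p = 0.1, mlh = NULL) {
  if (is.null(mlh)) mlh <- compute_mlh(cohort)
  base <- covariate_spec(trait = trait)
  fit0 <- fit_covariate_model(cohort, base, mlh = mlh)
  disp <- studentize_external(fit0)
  probe_dat <- left_join(disp[c("individual", "pd")],
                         mlh[c("individual", "mlh")], by = "individual")
  probe_dat <- probe_dat[complete.cases(probe_dat), ]
  pr <- lm(pd ~ mlh, data = probe_dat)
  cs <- summary(pr)$coefficients
  probe <- tibble(
    term = "mlh",
    estimate = cs["mlh", "Estimate"],
    std.error = cs["mlh", "Std. Error"],
    p.value = cs["mlh", "Pr(>|t|)"],
    n = nrow(probe_dat)
  )
  out <- covariate_spec(trait = trait,
                        include_mlh = probe$p.value < probe_p,
                        include_ucrea = (trait == "ualb"))
  attr(out, "mlh_probe") <- probe
  out
}
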