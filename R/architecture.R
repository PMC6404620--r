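# Locate the locus coefficients in a tobit_fit whose design was built as
# model.matrix(~ locus [+ mlh]) with factor levels (hom_p2, het, hom_p1).
locus_coef_idx <- function(fit) {
  nm <- names(fit$beta)
  i_cc <- match("locushom_p1", nm)
  i_het <- match("locushet", nm)
  if (is.na(i_cc) || is.na(i_het)) {
    abort("fit has no full locus factor (need coefficients locushom_p1 and locushet)")
  }
  list(cc = i_cc, het = i_het, p = length(nm))
}

# Contrast row over beta for weights (w_cc, w_ca, w_aa) on genotype means.
# With the P2 homozygote as reference, w . mu = sum(w) * intercept +
# w_cc * b_cc + w_ca * b_het; the intercept weight is sum(w) (zero for true
# contrasts).
mean_weights_to_beta <- function(fit, w) {
  idx <- locus_coef_idx(fit)
  C <- numeric(idx$p)
  nm <- names(fit$beta)
  i_int <- match("(Intercept)", nm)
  if (!is.na(i_int)) C[i_int] <- sum(w)
  C[idx$cc] <- C[idx$cc] + w[1]
  C[idx$het] <- C[idx$het] + w[2]
  C
}

#' Fitted genotype-class means from a Tobit fit
#'
#' Linear combinations of the fitted coefficients giving the modelled mean
#' for each genotype class (covariates at zero), with standard errors from
#' the coefficient covariance. Classes are CC = P1 homozygote, CA =
#' heterozygote, AA = P2 homozygote (the reference level).
#'
#' @param fit A `tobit_fit` containing a full 3-level locus factor.
#' @param strains Length-2 character vector naming the P1 and P2 strains.
#' @return Tibble with `class` (`hom_p1`, `het`, `hom_p2`), `strain`,
#'   `estimate`, `std.error`.
#' @export
genotype_means <- function(fit, strains = c("P1", "P2")) {
  idx <- locus_coef_idx(fit)
  nm <- names(fit$beta)
  i_int <- match("(Intercept)", nm)
  A <- matrix(0, 3, idx$p)
  if (!is.na(i_int)) A[, i_int] <- 1
  A[1, idx$cc] <- 1
  A[2, idx$het] <- 1
  Vb <- fit$vcov[seq_len(idx$p), seq_len(idx$p), drop = FALSE]
  est <- drop(A %*% fit$beta)
  se <- sqrt(pmax(diag(A %*% Vb %*% t(A)), 0))
  tibble::new_tibble(list(
    class = c("hom_p1", "het", "hom_p2"),
    strain = c(strains[1], paste(strains, collapse = "x"), strains[2]),
    estimate = est,
    std.error = se
  ), nrow = 3L)
}

#' Griffing's potence ratio
#'
#' `h_P = (2 mu_CA - (mu_CC + mu_AA)) / (mu_CC - mu_AA) = Q / L`: the ratio of
#' the dominance deviation of the heterozygote from the midparent to half the
#' homozygote difference. 0 indicates additivity, +/-1 complete dominance,
#' `|h_P| > 1` over-/underdominance. When the homozygote means coincide
#' (within `tol`) the ratio is undefined and flagged rather than returned as
#' a silent NaN.
#'
#' @param mu_cc,mu_ca,mu_aa Genotype-class means (P1 homozygote, heterozygote,
#'   P2 homozygote).
#' @param tol Tolerance for `mu_CC = mu_AA`.
#' @return List with `h_p` (NA when undefined) and `defined` (logical).
#' @export
potence_ratio <- function(mu_cc, mu_ca, mu_aa, tol = 1e-12) {
  stopifnot(is.finite(mu_cc), is.finite(mu_ca), is.finite(mu_aa))
  L <- mu_cc - mu_aa
  if (abs(L) <= tol) {
    return(list(h_p = NA_real_, defined = FALSE))
  }
  list(h_p = (2 * mu_ca - (mu_cc + mu_aa)) / L, defined = TRUE)
}

#' Additivity contrasts
#'
#' Reports both the homozygote linear contrast `(+1, 0, -1)` (CC vs AA; this
#' is the contrast feeding the "A" architecture label) and the
#' heterozygote-vs-midparent contrast `(-0.5, +1, -0.5)`, each with estimate,
#' standard error and Wald P-value.
#'
#' @param fit A `tobit_fit` with a full locus factor.
#' @return Tibble with rows `linear` and `midparent`.
#' @export
test_additivity <- function(fit) {
  bind_rows(
    wald_contrast(fit, mean_weights_to_beta(fit, c(1, 0, -1)), label = "linear"),
    wald_contrast(fit, mean_weights_to_beta(fit, c(-0.5, 1, -0.5)),
                  label = "midparent")
  )
}

#' Dominance contrasts
#'
#' The four single-degree-of-freedom dominance vectors over the genotype
#' means `(CC, CA, AA)`, applied sequentially:
#' `(+0.5, +0.5, -1.0)` and `(-1.0, +0.5, +0.5)` test positive dominance
#' (heterozygote grouped with the high class), `(+1.0, -0.5, -0.5)` and
#' `(-0.5, -0.5, +1.0)` test negative dominance (one homozygote isolated
#' high, dispersion behaving recessively). Sign conventions are preserved so
#' a significant positive estimate identifies which homozygote is the
#' isolated high-dispersion class.
#'
#' @param fit A `tobit_fit` with a full locus factor.
#' @return Tibble with columns `contrast`, `family` (`"D+"`/`"D-"`),
#'   `isolated` (the homozygote class the vector isolates), `high_class`
#'   (the homozygote that is high-dispersion when the estimate is positive),
#'   `estimate`, `std.error`, `statistic`, `df`, `p.value`.
#' @export
test_dominance <- function(fit) {
  # `isolated` is the homozygote the vector singles out; `high_class` is the
  # homozygote that is high-dispersion when the estimate is positive (for D+
  # the heterozygote moves with the non-isolated, high homozygote).
  vecs <- list(
    pos_dom_aa_isolated = list(w = c(0.5, 0.5, -1.0), family = "D+",
                               isolated = "hom_p2", high_class = "hom_p1"),
    pos_dom_cc_isolated = list(w = c(-1.0, 0.5, 0.5), family = "D+",
                               isolated = "hom_p1", high_class = "hom_p2"),
    neg_dom_cc_isolated = list(w = c(1.0, -0.5, -0.5), family = "D-",
                               isolated = "hom_p1", high_class = "hom_p1"),
    neg_dom_aa_isolated = list(w = c(-0.5, -0.5, 1.0), family = "D-",
                               isolated = "hom_p2", high_class = "hom_p2")
  )
  rows <- purrr::imap(vecs, function(v, nm) {
    res <- wald_contrast(fit, mean_weights_to_beta(fit, v$w), label = nm)
    tibble::new_tibble(list(
      contrast = nm, family = v$family, isolated = v$isolated,
      high_class = v$high_class, estimate = res$estimate,
      std.error = res$std.error, statistic = res$statistic, df = res$df,
      p.value = res$p.value
    ), nrow = 1L)
  })
  bind_rows(rows)
}

#' Classify the genetic architecture of a dispersion locus
#'
#' Assigns architecture labels from the contrast tests at a nominal
#' per-contrast threshold `alpha_label`:
#' \itemize{
#'   \item `A` when the homozygote linear contrast is significant;
#'   \item `D-` when a negative-dominance vector is significant in the
#'     isolating direction (its isolated homozygote high): high dispersion
#'     behaves recessively, the heterozygote resembling the low homozygote;
#'   \item `D+` when a positive-dominance vector is significant with the
#'     heterozygote grouped with the high class;
#'   \item `OD`/`UD` when the heterozygote is significantly above/below both
#'     homozygotes.
#' }
#' Multiple labels are permitted (partial dominance is typically `{D-, A}`).
#' Contradictory simultaneous families (`D+` with `D-`, or `OD` with `UD`)
#' are all reported and the call flagged ambiguous rather than suppressed.
#' The high-dispersion allele is reported by strain name from the fitted
#' genotype means; it is `NA` when the heterozygote is the top class.
#'
#' @param fit A `tobit_fit` with a full locus factor.
#' @param strains Length-2 character vector (P1, P2 strain names).
#' @param alpha_label Nominal labelling threshold per contrast (default 0.05).
#' @return An object of class `architecture_call`: list with `labels` (tibble
#'   `form`, `p_arch`, `high_allele`), `means`, `potence`, `potence_defined`,
#'   `high_pd_class`, `high_pd_allele`, `ambiguous`, and the underlying
#'   contrast tables.
#' @export
classify_architecture <- function(fit, strains = c("P1", "P2"),
                                  alpha_label = 0.05) {
  means <- genotype_means(fit, strains)
  add <- test_additivity(fit)
  dom <- test_dominance(fit)
  het_vs <- bind_rows(
    wald_contrast(fit, mean_weights_to_beta(fit, c(-1, 1, 0)),
                  label = "het_vs_cc"),
    wald_contrast(fit, mean_weights_to_beta(fit, c(0, 1, -1)),
                  label = "het_vs_aa")
  )
  strain_of <- function(class) {
    means$strain[match(class, means$class)]
  }
  labels <- list()
  lin <- add[add$contrast == "linear", ]
  if (lin$p.value < alpha_label) {
    high <- if (lin$estimate > 0) "hom_p1" else "hom_p2"
    labels <- c(labels, list(tibble::new_tibble(list(
      form = "A", p_arch = lin$p.value, high_allele = strain_of(high)
    ), nrow = 1L)))
  }
  mu_of <- function(class) means$estimate[match(class, means$class)]
  mu_het <- mu_of("het")
  for (fam in c("D+", "D-")) {
    hits <- dom[dom$family == fam & dom$p.value < alpha_label &
                  dom$estimate > 0, ]
    if (nrow(hits)) {
      # direction gate: the heterozygote must actually side with the class
      # the vector claims it does (with the high homozygote for D+, with the
      # low one for D-); a heterozygote beyond both homozygotes is an
      # over-/underdominance pattern, not a dominance family
      ok <- vapply(seq_len(nrow(hits)), function(i) {
        hi <- mu_of(hits$high_class[i])
        lo <- mu_of(setdiff(c("hom_p1", "hom_p2"), hits$high_class[i]))
        if (fam == "D+") abs(mu_het - hi) < abs(mu_het - lo)
        else abs(mu_het - lo) < abs(mu_het - hi)
      }, TRUE)
      hits <- hits[ok, , drop = FALSE]
    }
    if (nrow(hits)) {
      hit <- hits[which.min(hits$p.value), ]
      labels <- c(labels, list(tibble::new_tibble(list(
        form = fam, p_arch = hit$p.value,
        high_allele = strain_of(hit$high_class)
      ), nrow = 1L)))
    }
  }
  het_up <- all(het_vs$estimate > 0) && all(het_vs$p.value < alpha_label)
  het_dn <- all(het_vs$estimate < 0) && all(het_vs$p.value < alpha_label)
  if (het_up) {
    labels <- c(labels, list(tibble::new_tibble(list(
      form = "OD", p_arch = max(het_vs$p.value),
      high_allele = NA_character_), nrow = 1L)))
  }
  if (het_dn) {
    labels <- c(labels, list(tibble::new_tibble(list(
      form = "UD", p_arch = max(het_vs$p.value),
      high_allele = NA_character_), nrow = 1L)))
  }
  labels <- if (length(labels)) bind_rows(labels) else {
    tibble(form = character(), p_arch = numeric(), high_allele = character())
  }
  forms <- labels$form
  ambiguous <- ("D+" %in% forms && "D-" %in% forms) ||
    ("OD" %in% forms && "UD" %in% forms)
  high_class <- means$class[which.max(means$estimate)]
  pot <- potence_ratio(means$estimate[1], means$estimate[2], means$estimate[3])
  structure(
    list(
      labels = labels,
      means = means,
      potence = pot$h_p,
      potence_defined = pot$defined,
      high_pd_class = high_class,
      high_pd_allele = if (high_class == "het") NA_character_
                       else strain_of(high_class),
      ambiguous = ambiguous,
      alpha_label = alpha_label,
      contrasts = list(additivity = add, dominance = dom,
                       heterozygote = het_vs)
    ),
    class = "architecture_call"
  )
}

#' @export
print.architecture_call <- function(x, ...) {
  cat("<architecture_call>\n")
  if (nrow(x$labels)) {
    for (i in seq_len(nrow(x$labels))) {
      cat("  ", x$labels$form[i],
          if (!is.na(x$labels$high_allele[i]))
            paste0(" (", x$labels$high_allele[i], ")"),
          "  P_arch = ", format.pval(x$labels$p_arch[i], digits = 3),
          "\n", sep = "")
    }
  } else {
    cat("  no architecture label at alpha =", x$alpha_label, "\n")
  }
  cat("  potence h_P:",
      if (x$potence_defined) formatC(x$potence, digits = 3) else "undefined",
      " high-PD class:", x$high_pd_class,
      if (x$ambiguous) " [ambiguous]", "\n")
  invisible(x)
}

#' Tidy an architecture call
#'
#' @param x An `architecture_call`.
#' @param ... Unused.
#' @return The label tibble (`form`, `p_arch`, `high_allele`) with the
#'   potence ratio and ambiguity flag appended as columns.
#' @method tidy architecture_call
#' @export
tidy.architecture_call <- function(x, ...) {
  lb <- x$labels
  if (!nrow(lb)) {
    lb <- tibble(form = NA_character_, p_arch = NA_real_,
                 high_allele = NA_character_)
  }
  lb$potence <- x$potence
  lb$ambiguous <- x$ambiguous
  lb
}
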