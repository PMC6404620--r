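# Approximate genetic lengths (cM) of the 19 mouse autosomes, used for the
# default synthetic map.
mouse_autosome_cm <- c(98, 103, 82, 84, 92, 79, 89, 76, 75, 77,
                       88, 64, 67, 66, 59, 57, 61, 59, 57)

#' Synthetic marker map for an F2 intercross
#'
#' Evenly spaced markers along each chromosome (default: 19 autosomes with
#' approximate mouse genetic lengths, 17 cM spacing, giving ~100 markers).
#' Synthetic base-pair positions are an affine function of the cM position
#' (`bp = cM * 2e6`) since only relative positions matter downstream. An
#' X chromosome (hemizygous in the all-male cohorts emulated here) can be
#' appended.
#'
#' @param chr_lengths_cm Named or unnamed numeric vector of chromosome
#'   lengths in cM.
#' @param spacing_cm Inter-marker spacing in cM (default 17).
#' @param include_x Append an X chromosome (default FALSE)?
#' @param x_length_cm Length of the X, if included.
#' @return Tibble with `marker`, `chr`, `pos_cm`, `pos_bp`.
#' @export
sim_map <- function(chr_lengths_cm = mouse_autosome_cm, spacing_cm = 17,
                    include_x = FALSE, x_length_cm = 75) {
  chrs <- as.character(seq_along(chr_lengths_cm))
  if (include_x) {
    chr_lengths_cm <- c(chr_lengths_cm, x_length_cm)
    chrs <- c(chrs, "X")
  }
  purrr::map2(chrs, chr_lengths_cm, function(ch, len) {
    pos <- seq(0, len, by = spacing_cm)
    tibble(
      marker = sprintf("%s-%09.0f-S",
                       ifelse(ch == "X", "20", sprintf("%02d", as.integer(ch))),
                       pos * 2e6),
      chr = ch, pos_cm = pos, pos_bp = pos * 2e6
    )
  }) |> bind_rows()
}

#' Define a variance-QTL effect
#'
#' Attaches a per-genotype residual-SD pattern (and optionally a mean shift)
#' to one marker. Architecture presets map onto SD multipliers for
#' `(CC, CA, AA)` = (P1 homozygote, heterozygote, P2 homozygote):
#' `D-` with the high allele in P2 gives `(1, 1, ratio)` (high dispersion
#' recessive), `D+` gives `(1, ratio, ratio)`, `additive`
#' `(1, sqrt(ratio), ratio)`, `OD` `(1, ratio, 1)`, `UD` `(ratio, 1, ratio)`,
#' `null` `(1, 1, 1)`.
#'
#' @param marker Marker ID the effect acts at.
#' @param architecture Preset name.
#' @param sigma_ratio High/low residual-SD ratio (> 0; default 2).
#' @param high_allele `"P2"` (default) or `"P1"`: which homozygote carries
#'   high dispersion (ignored for `OD`/`UD`/`null`).
#' @param mean_shift Numeric length-3 mean-QTL component for `(CC, CA, AA)`.
#' @return A one-row tibble with a `sigma` list-column.
#' @export
vqtl_effect <- function(marker,
                        architecture = c("D-", "null", "additive", "D+",
                                         "OD", "UD"),
                        sigma_ratio = 2, high_allele = c("P2", "P1"),
                        mean_shift = c(0, 0, 0)) {
  architecture <- match.arg(architecture)
  high_allele <- match.arg(high_allele)
  stopifnot(sigma_ratio > 0, length(mean_shift) == 3L)
  r <- sigma_ratio
  sig <- switch(architecture,
    "null" = c(1, 1, 1),
    "additive" = c(1, sqrt(r), r),
    "D-" = c(1, 1, r),
    "D+" = c(1, r, r),
    "OD" = c(1, r, 1),
    "UD" = c(r, 1, r)
  )
  if (high_allele == "P1" && architecture %in% c("additive", "D-", "D+")) {
    sig <- rev(sig)
  }
  tibble(marker = marker, architecture = architecture,
         sigma_ratio = sigma_ratio, high_allele = high_allele,
         sigma = list(sig), mean_shift = list(mean_shift))
}

#' Simulation configuration for phenotypes
#'
#' Defaults emulate a male F2 renal cohort: urinary creatinine around
#' 76 mg/dl (SD 20), urinary albumin averaging about 0.72 mg/dl with a
#' positive creatinine slope (0.013 mg/dl per mg/dl) and a negative
#' multilocus-heterozygosity slope (-4.87 mg/dl per unit MLH), blood urea
#' nitrogen around 20 mg/dl, and a detection floor at zero on all
#' concentrations. Dispersion structure: each vQTL multiplies the albumin
#' residual SD by its per-genotype factor, and MLH acts on the log residual
#' SD with slope `mlh_sigma_slope` (negative: more heterozygous individuals
#' are better buffered).
#'
#' @param n Number of individuals (default 383).
#' @param ualb_mean Target mean albumin, mg/dl.
#' @param ualb_base_sd Baseline albumin residual SD, mg/dl.
#' @param ucrea_mean,ucrea_sd Creatinine mean and SD, mg/dl.
#' @param bun_mean,bun_sd BUN mean and SD, mg/dl.
#' @param weight_mean,weight_sd Body weight mean and SD, g.
#' @param ucrea_slope Albumin-on-creatinine regression slope.
#' @param mlh_ualb_slope Albumin-on-MLH regression slope.
#' @param mlh_sigma_slope Log residual-SD slope on centred MLH.
#' @param floor_at_zero Apply the detection floor at 0 to concentrations?
#' @param missing Named numeric vector of per-trait missingness rates in
#'   `[0, 1]` (names among `ualb`, `ucrea`, `bun`, `weight`; rate 1 drops
#'   the trait entirely).
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(n = 383, ualb_mean = 0.72, ualb_base_sd = 0.5,
                       ucrea_mean = 76, ucrea_sd = 20,
                       bun_mean = 20.4, bun_sd = 3,
                       weight_mean = 30, weight_sd = 3,
                       ucrea_slope = 0.013, mlh_ualb_slope = -4.87,
                       mlh_sigma_slope = -2,
                       floor_at_zero = TRUE,
                       missing = c(ualb = 0, ucrea = 0, bun = 1,
                                   weight = 0)) {
  stopifnot(n >= 10, all(missing >= 0), all(missing <= 1))
  structure(
    list(n = n, ualb_mean = ualb_mean, ualb_base_sd = ualb_base_sd,
         ucrea_mean = ucrea_mean, ucrea_sd = ucrea_sd,
         bun_mean = bun_mean, bun_sd = bun_sd,
         weight_mean = weight_mean, weight_sd = weight_sd,
         ucrea_slope = ucrea_slope, mlh_ualb_slope = mlh_ualb_slope,
         mlh_sigma_slope = mlh_sigma_slope,
         floor_at_zero = floor_at_zero, missing = missing),
    class = "sim_config"
  )
}

# One set of n gametes along one chromosome: Markov chain over markers with
# Haldane recombination fraction r = (1 - exp(-2d)) / 2, d in Morgans.
sim_gametes <- function(pos_cm, n) {
  k <- length(pos_cm)
  g <- matrix(0L, n, k)
  g[, 1] <- rbinom(n, 1L, 0.5)
  if (k > 1L) {
    for (j in 2:k) {
      d <- (pos_cm[j] - pos_cm[j - 1]) / 100
      r <- (1 - exp(-2 * d)) / 2
      rec <- rbinom(n, 1L, r)
      g[, j] <- ifelse(rec == 1L, 1L - g[, j - 1], g[, j - 1])
    }
  }
  g
}

#' Simulate F2 genotypes
#'
#' Each individual is the union of two independent gametes; each gamete is a
#' Markov chain along each chromosome with inter-marker recombination
#' fraction given by the Haldane map function `r = (1 - exp(-2d)) / 2`
#' (`d` in Morgans); chromosomes are independent (no interference). Markers
#' on a chromosome named `"X"` are hemizygous (all-male cohort): a single
#' maternal gamete determines the genotype, coded as the corresponding
#' homozygote.
#'
#' @param map Tibble from [sim_map()] (columns `marker`, `chr`, `pos_cm`).
#' @param n Number of individuals.
#' @param seed Optional integer seed.
#' @return Genotype tibble (`individual` + one 0/1/2 column per marker)
#'   suitable for [f2_cohort()].
#' @export
simulate_f2_genotypes <- function(map, n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  ids <- sprintf("ind%04d", seq_len(n))
  out <- tibble(individual = ids)
  for (ch in unique(map$chr)) {
    sub <- map[map$chr == ch, ]
    sub <- sub[order(sub$pos_cm), ]
    if (ch == "X") {
      g <- 2L * sim_gametes(sub$pos_cm, n)
    } else {
      g <- sim_gametes(sub$pos_cm, n) + sim_gametes(sub$pos_cm, n)
    }
    colnames(g) <- sub$marker
    out <- bind_cols(out, as_tibble(g))
  }
  out
}

#' Simulate phenotypes with genotype-dependent residual variance
#'
#' Creatinine (and BUN, weight) are drawn first; albumin is
#' `intercept + ucrea_slope * UCrea + mlh_ualb_slope * MLH + sum(mean shifts)
#' + e`, where `sd(e)` is the baseline SD times the product of each vQTL's
#' per-genotype SD factor for the individual's genotypes times
#' `exp(mlh_sigma_slope * (MLH - 0.5))`. The intercept is chosen so the
#' expected albumin mean matches `config$ualb_mean`. The optional detection
#' floor truncates concentrations at 0; per-trait missingness is applied
#' last.
#'
#' @param genotypes Genotype tibble from [simulate_f2_genotypes()].
#' @param effects Tibble of [vqtl_effect()] rows (or NULL for no vQTL).
#' @param config A [sim_config()].
#' @param seed Optional integer seed.
#' @return Phenotype tibble (`individual`, `ualb`, `ucrea`, `bun`, `weight`).
#' @export
simulate_phenotypes <- function(genotypes, effects = NULL,
                                config = sim_config(), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  n <- nrow(genotypes)
  mlh <- compute_mlh(genotypes)$mlh
  ucrea <- rnorm(n, config$ucrea_mean, config$ucrea_sd)
  bun <- rnorm(n, config$bun_mean, config$bun_sd)
  weight <- rnorm(n, config$weight_mean, config$weight_sd)
  sd_mult <- rep(1, n)
  shift <- rep(0, n)
  if (!is.null(effects) && nrow(effects)) {
    for (i in seq_len(nrow(effects))) {
      mk <- effects$marker[i]
      g <- genotypes[[mk]]
      if (is.null(g)) abort(paste0("effect marker not in genotypes: ", mk))
      # genotype 0 = CC (P1 hom), 1 = CA, 2 = AA (P2 hom)
      sd_mult <- sd_mult * effects$sigma[[i]][g + 1L]
      shift <- shift + effects$mean_shift[[i]][g + 1L]
    }
  }
  sd_i <- config$ualb_base_sd * sd_mult *
    exp(config$mlh_sigma_slope * (mlh - 0.5))
  intercept <- config$ualb_mean - config$ucrea_slope * config$ucrea_mean -
    config$mlh_ualb_slope * 0.5
  ualb <- intercept + config$ucrea_slope * ucrea +
    config$mlh_ualb_slope * mlh + shift + rnorm(n, 0, sd_i)
  if (config$floor_at_zero) {
    ualb <- pmax(ualb, 0)
    ucrea <- pmax(ucrea, 0)
    bun <- pmax(bun, 0)
  }
  drop_at <- function(x, rate) {
    if (rate >= 1) return(rep(NA_real_, n))
    x[runif(n) < rate] <- NA_real_
    x
  }
  tibble(
    individual = genotypes$individual,
    ualb = drop_at(ualb, config$missing[["ualb"]]),
    ucrea = drop_at(ucrea, config$missing[["ucrea"]]),
    bun = drop_at(bun, config$missing[["bun"]]),
    weight = drop_at(weight, config$missing[["weight"]])
  )
}

#' Simulate a complete F2 cohort
#'
#' Convenience wrapper: genotypes, phenotypes and map bundled as a validated
#' [f2_cohort()]. With the same seed the result is identical byte for byte.
#'
#' @param map Marker map (default [sim_map()]).
#' @param effects Tibble of [vqtl_effect()] rows, or NULL.
#' @param config A [sim_config()].
#' @param seed Optional integer seed (drives genotypes and phenotypes).
#' @param strains Parental strain names.
#' @param name Cohort label.
#' @return An `f2_cohort`.
#' @export
simulate_cohort <- function(map = sim_map(), effects = NULL,
                            config = sim_config(), seed = NULL,
                            strains = c("C57BL/6J", "A/J"),
                            name = "simulated") {
  if (!is.null(seed)) set.seed(seed)
  geno <- simulate_f2_genotypes(map, config$n)
  pheno <- simulate_phenotypes(geno, effects = effects, config = config)
  f2_cohort(genotypes = geno, phenotypes = pheno, map = map,
            strains = strains, name = name)
}

#' Estimate the genotype residual-SD ratio at a marker
#'
#' Within each genotype class at `marker`, fits a zero-bounded *censored*
#' Gaussian regression of albumin on creatinine and MLH by maximum
#' likelihood and returns the per-class scale estimates. The censored
#' likelihood keeps the estimator consistent under the generator's detection
#' floor. The ratio reported is the largest class SD over the smallest.
#'
#' @param cohort An `f2_cohort`.
#' @param marker Marker ID.
#' @return Tibble with `class`, `n`, `sigma`, plus attribute `"ratio"`.
#' @export
estimate_sigma_ratio <- function(cohort, marker) {
  g <- cohort$genotypes[[marker]]
  if (is.null(g)) abort(paste0("marker not in genotypes: ", marker))
  mlh <- compute_mlh(cohort)
  dat <- tibble(
    individual = cohort$genotypes$individual,
    g = g
  ) |>
    left_join(cohort$phenotypes[c("individual", "ualb", "ucrea")],
              by = "individual") |>
    left_join(mlh[c("individual", "mlh")], by = "individual")
  dat <- dat[complete.cases(dat), ]
  res <- purrr::map(0:2, function(cls) {
    sub <- dat[dat$g == cls, ]
    if (nrow(sub) < 10L) return(NULL)
    X <- cbind(`(Intercept)` = 1, ucrea = sub$ucrea, mlh = sub$mlh)
    fit <- fit_tobit(sub$ualb, X, bound = 0, variant = "censored")
    tibble(class = c("hom_p1", "het", "hom_p2")[cls + 1L],
           n = nrow(sub), sigma = fit$sigma)
  }) |> bind_rows()
  structure(res, ratio = max(res$sigma) / min(res$sigma))
}

#' Simulation-based operating characteristics of the scan
#'
#' Runs replicated scans over a grid of scenarios and reports, per scenario:
#' the empirical rejection rate of the per-marker joint test at the nominal
#' 0.05 level and at the FDR (with floor), the proportion of replicates
#' whose minimum-P marker is the causal marker or an immediate map
#' neighbour, and the distribution of architecture labels at the causal
#' marker. A separate large-sample component estimates the per-genotype
#' residual-SD ratio via [estimate_sigma_ratio()].
#'
#' @param scenarios Tibble with columns `name`, `architecture`,
#'   `sigma_ratio`, `n` (see [vqtl_effect()] presets; `architecture =
#'   "null"` means no vQTL).
#' @param replicates Replicates per scenario.
#' @param seed Integer seed.
#' @param map Marker map (default [sim_map()]); the causal marker is taken
#'   near the middle of chromosome 1.
#' @param config_scan A [scan_config()].
#' @param sigma_n Sample size for the SD-ratio component (0 to skip).
#' @return List of class `recovery_report` with elements `scenarios` (one
#'   row per scenario: `rate_nominal`, `rate_fdr`, `localized`,
#'   `modal_call`, `call_table`) and `sigma` (tibble with the estimated and
#'   true SD ratio), plus the inputs.
#' @export
recovery_suite <- function(scenarios = NULL, replicates = 50, seed = 1,
                           map = sim_map(),
                           config_scan = scan_config(),
                           sigma_n = 10000) {
  if (is.null(scenarios)) {
    scenarios <- tibble(
      name = c("null", "dminus_r2"),
      architecture = c("null", "D-"),
      sigma_ratio = c(1, 2),
      n = c(300, 400)
    )
  }
  chr1 <- map[map$chr == "1", ]
  causal <- chr1$marker[ceiling(nrow(chr1) / 2)]
  neighbours <- chr1$marker[
    abs(match(causal, chr1$marker) - seq_len(nrow(chr1))) <= 1L
  ]
  set.seed(seed)
  out <- purrr::pmap(scenarios, function(name, architecture, sigma_ratio, n) {
    eff <- if (architecture == "null") NULL else {
      vqtl_effect(causal, architecture = architecture,
                  sigma_ratio = sigma_ratio)
    }
    cfg <- sim_config(n = n)
    calls <- character(0)
    nominal <- fdr_rej <- localized <- logical(0)
    rates <- numeric(0)
    for (r in seq_len(replicates)) {
      co <- simulate_cohort(map = map, effects = eff, config = cfg,
                            seed = sample.int(2^31 - 2, 1))
      sc <- suppressWarnings(scan_trait(co, "ualb", config_scan))
      tab <- sc$table
      rates <- c(rates, mean(tab$p_joint < 0.05))
      fdr_rej <- c(fdr_rej, any(tab$reject, na.rm = TRUE))
      if (!is.null(eff)) {
        top <- tab$marker[which.min(tab$p_joint)]
        localized <- c(localized, top %in% neighbours)
        fr <- tab$forms[[match(causal, tab$marker)]]
        calls <- c(calls, if (!is.null(fr) && nrow(fr)) {
          paste(sort(unique(fr$form)), collapse = "+")
        } else "none")
        nominal <- c(nominal, tab$p_joint[match(causal, tab$marker)] < 0.05)
      }
    }
    tibble(
      name = name, architecture = architecture, sigma_ratio = sigma_ratio,
      n = n, replicates = replicates,
      rate_nominal = mean(rates),
      rate_fdr = mean(fdr_rej),
      power_causal = if (length(nominal)) mean(nominal) else NA_real_,
      localized = if (length(localized)) mean(localized) else NA_real_,
      modal_call = if (length(calls)) {
        names(sort(table(calls), decreasing = TRUE))[1]
      } else NA_character_,
      call_table = list(if (length(calls)) table(calls) else NULL)
    )
  }) |> bind_rows()

  sigma_tbl <- NULL
  if (sigma_n > 0) {
    vq <- scenarios[scenarios$architecture != "null", ]
    if (nrow(vq)) {
      ratio_true <- vq$sigma_ratio[1]
      eff <- vqtl_effect(causal, architecture = vq$architecture[1],
                         sigma_ratio = ratio_true)
      co <- simulate_cohort(map = map, effects = eff,
                            config = sim_config(n = sigma_n),
                            seed = sample.int(2^31 - 2, 1))
      est <- estimate_sigma_ratio(co, causal)
      # for homozygote-high architectures compare the two homozygote classes
      # (the heterozygote's scale also carries the MLH dispersion covariate)
      s_of <- function(cls) est$sigma[match(cls, est$class)]
      ratio_est <- if (vq$architecture[1] %in% c("D-", "D+", "additive")) {
        if (eff$high_allele == "P2") s_of("hom_p2") / s_of("hom_p1")
        else s_of("hom_p1") / s_of("hom_p2")
      } else attr(est, "ratio")
      sigma_tbl <- tibble(marker = causal, n = sigma_n,
                          ratio_true = ratio_true,
                          ratio_est = ratio_est)
    }
  }
  structure(
    list(scenarios = out, sigma = sigma_tbl, causal_marker = causal,
         replicates = replicates, seed = seed),
    class = "recovery_report"
  )
}

#' @export
print.recovery_report <- function(x, ...) {
  cat("<recovery_report> causal marker:", x$causal_marker,
      " replicates:", x$replicates, "\n")
  print(x$scenarios |> select(-"call_table"))
  if (!is.null(x$sigma)) print(x$sigma)
  invisible(x)
}
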