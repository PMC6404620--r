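#' Scan configuration
#'
#' All tunable thresholds and modelling switches for a dispersion scan, in
#' one validated object that is serialized into every output header.
#'
#' @param alpha_fdr FDR level for Benjamini-Hochberg (default 0.05).
#' @param floor Nominal hard floor for FDR rejection (default 0.01).
#' @param alpha_label Per-contrast architecture labelling threshold
#'   (default 0.05).
#' @param mlh_probe_p MLH covariate inclusion threshold (default 0.1).
#' @param tobit_variant `"truncated"` (scan default, matching the
#'   renormalized-density likelihood) or `"censored"`.
#' @param residualization `"per_marker"` (dispersion recomputed from the
#'   covariate model containing each marker's locus term) or `"global"`
#'   (one locus-free dispersion vector per trait, for sensitivity analysis).
#' @param min_class_n Minimum individuals per observed genotype class
#'   (default 5); markers below it are skipped.
#' @param window_mb Consensus-locus grouping window in megabases (default 10).
#' @param require_same_allele Require matching high-dispersion allele for
#'   consensus grouping (default TRUE)?
#' @param r2_method `"fitted_cor"` (squared Pearson correlation of fitted vs
#'   observed dispersion) or `"mckelvey_zavoina"` (latent-scale).
#' @param seed Optional integer recorded in outputs (the scan itself is
#'   deterministic).
#' @return An object of class `scan_config`.
#' @export
scan_config <- function(alpha_fdr = 0.05, floor = 0.01, alpha_label = 0.05,
                        mlh_probe_p = 0.1,
                        tobit_variant = c("truncated", "censored"),
                        residualization = c("per_marker", "global"),
                        min_class_n = 5L, window_mb = 10,
                        require_same_allele = TRUE,
                        r2_method = c("fitted_cor", "mckelvey_zavoina"),
                        seed = NULL) {
  tobit_variant <- match.arg(tobit_variant)
  residualization <- match.arg(residualization)
  r2_method <- match.arg(r2_method)
  for (nm in c("alpha_fdr", "floor", "alpha_label", "mlh_probe_p")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1L || is.na(v) || v <= 0 || v > 1) {
      abort(paste0("config field `", nm, "` must be a probability in (0, 1]"),
            class = "dispscan_config_error")
    }
  }
  if (!is.numeric(min_class_n) || min_class_n < 1) {
    abort("min_class_n must be >= 1", class = "dispscan_config_error")
  }
  if (!is.numeric(window_mb) || window_mb <= 0) {
    abort("window_mb must be > 0", class = "dispscan_config_error")
  }
  structure(
    list(alpha_fdr = alpha_fdr, floor = floor, alpha_label = alpha_label,
         mlh_probe_p = mlh_probe_p, tobit_variant = tobit_variant,
         residualization = residualization,
         min_class_n = as.integer(min_class_n), window_mb = window_mb,
         require_same_allele = require_same_allele, r2_method = r2_method,
         seed = seed),
    class = "scan_config"
  )
}

#' @export
print.scan_config <- function(x, ...) {
  cat("<scan_config>\n")
  for (nm in names(x)) {
    cat("  ", nm, ": ", paste(x[[nm]] %||% "NULL", collapse = ", "),
        "\n", sep = "")
  }
  invisible(x)
}

config_hash <- function(config) {
  rlang::hash(config[sort(names(config))])
}

#' Proportion of dispersion explained by a marker
#'
#' Default: squared Pearson correlation between the genotype-class fitted
#' dispersion and the observed dispersion. The latent-scale
#' (McKelvey-Zavoina-style) alternative `var(fitted) / (var(fitted) +
#' sigma^2)` is available for sensitivity analysis.
#'
#' @param fit A `tobit_fit` from the scanned marker.
#' @param pd Observed dispersion vector (defaults to the fitted response).
#' @param method `"fitted_cor"` or `"mckelvey_zavoina"`.
#' @return Proportion in `[0, 1]`; 0 with a warning when the dispersion (or
#'   the fitted values) carry no variance.
#' @export
variance_explained <- function(fit, pd = fit$y,
                               method = c("fitted_cor", "mckelvey_zavoina")) {
  method <- match.arg(method)
  if (method == "mckelvey_zavoina") {
    vf <- var(fit$fitted)
    return(vf / (vf + fit$sigma^2))
  }
  if (!is.finite(sd(pd)) || sd(pd) == 0) {
    warn("dispersion has zero variance; r2 set to 0")
    return(0)
  }
  if (sd(fit$fitted) == 0) {
    warn("fitted values are constant; r2 set to 0")
    return(0)
  }
  cor(fit$fitted, pd)^2
}

# One marker's analysis: residualize, studentize, Tobit, contrasts.
scan_one_marker <- function(cohort, trait, marker, spec0, mlh_tbl, config,
                            global_pd = NULL) {
  if (config$residualization == "per_marker") {
    spec_m <- covariate_spec(trait = trait, locus = marker,
                             include_mlh = spec0$include_mlh,
                             include_ucrea = spec0$include_ucrea)
    cfit <- fit_covariate_model(cohort, spec_m, mlh = mlh_tbl)
    disp <- studentize_external(cfit)
    idx <- match(disp$individual, cfit$data$individual)
    dat <- tibble::new_tibble(list(
      individual = disp$individual, pd = disp$pd,
      locus = cfit$data$locus[idx]
    ), nrow = nrow(disp))
  } else {
    g <- cohort$genotypes[[marker]]
    dat <- tibble(
      individual = cohort$genotypes$individual,
      locus = factor(c("hom_p1", "het", "hom_p2")[g + 1L],
                     levels = c("hom_p2", "het", "hom_p1"))
    )
    dat <- dplyr::inner_join(global_pd, dat, by = "individual")
    dat <- dat[!is.na(dat$locus), , drop = FALSE]
  }
  use_mlh <- isTRUE(spec0$include_mlh)
  if (use_mlh) {
    dat$mlh <- mlh_tbl$mlh[match(dat$individual, mlh_tbl$individual)]
    dat <- dat[!is.na(dat$mlh), , drop = FALSE]
  }
  if (config$tobit_variant == "truncated" && any(dat$pd <= 0)) {
    # exact zeros cannot enter a renormalized-density likelihood
    dat <- dat[dat$pd > 0, , drop = FALSE]
  }
  dat$locus <- droplevels(dat$locus)
  counts <- table(dat$locus)
  if (length(counts) < 2L) {
    return(list(skip = "monomorphic"))
  }
  if (any(counts < config$min_class_n)) {
    return(list(skip = paste0("genotype class below min_class_n (",
                              paste(counts, collapse = "/"), ")")))
  }
  X <- if (use_mlh) model.matrix(~ locus + mlh, data = dat)
       else model.matrix(~ locus, data = dat)
  fit <- fit_tobit(dat$pd, X, bound = 0, variant = config$tobit_variant)
  loc_idx <- grep("^locus", colnames(X))
  Cj <- matrix(0, length(loc_idx), length(fit$beta))
  Cj[cbind(seq_along(loc_idx), loc_idx)] <- 1
  joint <- wald_contrast(fit, Cj, label = "joint")
  r2 <- variance_explained(fit, dat$pd, method = config$r2_method)

  full3 <- nlevels(dat$locus) == 3L
  if (full3) {
    arch <- classify_architecture(fit, strains = cohort$strains,
                                  alpha_label = config$alpha_label)
    forms <- arch$labels
    high_allele <- arch$high_pd_allele
    potence <- arch$potence
    ambiguous <- arch$ambiguous
  } else {
    # two observed classes (e.g. hemizygous X): 1-df joint test only
    arch <- NULL
    forms <- tibble(form = character(), p_arch = numeric(),
                    high_allele = character())
    cls <- levels(dat$locus)
    mu <- c(fit$beta[1], fit$beta[1] + fit$beta[loc_idx])
    hi <- cls[which.max(mu)]
    high_allele <- switch(hi, hom_p1 = cohort$strains[1],
                          hom_p2 = cohort$strains[2], NA_character_)
    potence <- NA_real_
    ambiguous <- FALSE
  }
  list(
    row = tibble::new_tibble(list(
      marker = marker,
      n_used = fit$n,
      df_joint = joint$df,
      stat_joint = joint$statistic,
      p_joint = joint$p.value,
      r2 = r2,
      converged = fit$converged,
      forms = list(forms),
      high_pd_allele = high_allele,
      potence = potence,
      ambiguous = ambiguous
    ), nrow = 1L),
    fit = fit,
    architecture = arch
  )
}

#' Run a per-marker dispersion scan for one trait
#'
#' For each marker: fit the stage-1 covariate model (with the marker's locus
#' term under the default per-marker residualization), compute the absolute
#' externally Studentized residuals (phenotypic dispersion), regress
#' dispersion on genotype with a zero-bounded Tobit model (plus MLH when
#' selected), test the joint Wald contrast of the genotype coefficients
#' against the reference homozygote, compute the variance explained and the
#' architecture contrasts; finally apply Benjamini-Hochberg FDR with the
#' hard floor across all tested markers.
#'
#' @param cohort An `f2_cohort`.
#' @param trait `"ualb"`, `"ucrea"` or `"bun"`.
#' @param config A [scan_config()].
#' @return An object of class `pd_scan`: list with `table` (one row per
#'   tested marker, joined with the map and FDR columns; architecture label
#'   rows nested in the `forms` list-column), `skipped` (marker, reason),
#'   `mlh_probe`, `trait`, `cohort`, `strains`, `config`.
#' @export
scan_trait <- function(cohort, trait, config = scan_config()) {
  stopifnot(inherits(cohort, "f2_cohort"), inherits(config, "scan_config"))
  if (!trait %in% cohort$traits_available ||
      all(is.na(cohort$phenotypes[[trait]]))) {
    abort(paste0("trait not available in cohort: ", trait))
  }
  mlh_tbl <- compute_mlh(cohort)
  spec0 <- select_covariates(cohort, trait, probe_p = config$mlh_probe_p,
                             mlh = mlh_tbl)
  global_pd <- NULL
  if (config$residualization == "global") {
    cfit0 <- fit_covariate_model(cohort, spec0, mlh = mlh_tbl)
    d0 <- studentize_external(cfit0)
    global_pd <- tibble(individual = d0$individual, pd = d0$pd)
  }
  markers <- intersect(cohort$map$marker,
                       setdiff(names(cohort$genotypes), "individual"))
  rows <- list()
  skipped <- list()
  n_nonconv <- 0L
  for (mk in markers) {
    res <- tryCatch(
      scan_one_marker(cohort, trait, mk, spec0, mlh_tbl, config,
                      global_pd = global_pd),
      dispscan_degenerate = function(e) {
        msg <- conditionMessage(e)
        if (grepl("fewer than 2 observed genotype classes", msg)) {
          msg <- "monomorphic"
        }
        list(skip = msg)
      },
      dispscan_too_few = function(e) list(skip = conditionMessage(e)),
      error = function(e) list(skip = paste0("fit error: ",
                                             conditionMessage(e)))
    )
    if (!is.null(res$skip)) {
      skipped[[mk]] <- tibble(marker = mk, reason = res$skip)
    } else {
      if (!res$row$converged) n_nonconv <- n_nonconv + 1L
      rows[[mk]] <- res$row
    }
  }
  tab <- bind_rows(rows)
  skipped <- if (length(skipped)) bind_rows(skipped) else {
    tibble(marker = character(), reason = character())
  }
  if (nrow(tab)) {
    fdr <- bh_with_floor(tab$p_joint, alpha_fdr = config$alpha_fdr,
                         floor = config$floor)
    tab$fdr_rank <- fdr$rank
    tab$bh_threshold <- fdr$bh_threshold
    tab$bh_pass <- fdr$bh_pass
    tab$floor_pass <- fdr$floor_pass
    tab$reject <- fdr$reject
    tab <- left_join(cohort$map, tab, by = "marker") |>
      filter(!is.na(.data$p_joint)) |>
      mutate(mb = .data$pos_bp / 1e6)
  } else {
    tab <- tibble()
  }
  if (n_nonconv > 0L) {
    warn(paste0(n_nonconv, " marker fit(s) flagged non-convergent"))
  }
  structure(
    list(table = tab, skipped = skipped,
         mlh_probe = attr(spec0, "mlh_probe"),
         include_mlh = spec0$include_mlh,
         trait = trait, cohort = cohort$name, strains = cohort$strains,
         config = config),
    class = "pd_scan"
  )
}

#' @export
print.pd_scan <- function(x, ...) {
  cat("<pd_scan> trait:", x$trait, " cohort:", x$cohort, "\n")
  cat("  markers tested:", nrow(x$table), " skipped:", nrow(x$skipped),
      " FDR rejections:", sum(x$table$reject, na.rm = TRUE), "\n")
  cat("  MLH covariate included:", x$include_mlh, "\n")
  if (nrow(x$table)) {
    top <- x$table |> arrange(.data$p_joint) |> head(5) |>
      select("marker", "chr", "mb", "p_joint", "r2", "reject")
    print(top)
  }
  invisible(x)
}

trait_label <- function(trait) {
  c(ualb = "UAlb", ucrea = "UCrea", bun = "BUN")[[trait]]
}

chr_order <- function(chr) {
  n <- suppressWarnings(as.numeric(chr))
  ifelse(is.na(n), 1000 + as.integer(factor(chr)), n)
}

# Normalize a pd_scan or a read_scan_table() tibble to marker-level rows
# for consensus grouping.
consensus_input <- function(x, i) {
  if (inherits(x, "pd_scan")) {
    tibble(
      marker = x$table$marker, chr = as.character(x$table$chr),
      mb = x$table$mb, reject = x$table$reject,
      allele = x$table$high_pd_allele,
      cohort = x$cohort %||% paste0("scan", i), trait = x$trait
    )
  } else {
    tb <- as_tibble(x)
    tb <- tb[!duplicated(tb$Marker), ]
    tibble(
      marker = tb$Marker, chr = as.character(tb$Chr), mb = as.numeric(tb$MB),
      reject = as.logical(tb$FDR_pass),
      allele = ifelse(tb$HighPDAllele %in% c(".", "", "NA"), NA_character_,
                      tb$HighPDAllele),
      cohort = attr(x, "cohort") %||% paste0("scan", i),
      trait = attr(x, "trait") %||% "ualb"
    )
  }
}

#' Group FDR-significant markers into cross-cohort consensus loci
#'
#' Markers rejected at the FDR (with the hard floor) in different cohorts,
#' lying on the same chromosome within `window_mb` of each other
#' (single-linkage chaining) and -- optionally -- sharing the same
#' high-dispersion allele, are grouped into one named consensus locus
#' (`PDUAlb1`, `PDUAlb2`, ... ordered by chromosome then position). Clusters
#' spanning two cohorts with *opposite* high-dispersion alleles are reported
#' as contrast pairs, not consensus loci; single-cohort clusters are
#' singletons.
#'
#' @param scans List of at least two `pd_scan` objects (or tibbles from
#'   [read_scan_table()]) for the same trait on a shared map build.
#' @param window_mb Grouping window in megabases (default 10).
#' @param require_same_allele Require a shared high-dispersion allele for
#'   consensus status (default TRUE)?
#' @return Tibble with one row per cluster: `locus` (name or `NA`), `type`
#'   (`consensus`/`contrast_pair`/`singleton`), `chr`, `mb_min`, `mb_max`,
#'   `n_markers`, `cohorts`, `high_pd_allele`, `markers` (list-column).
#'   Marker-to-locus assignments are attached as attribute `"assignments"`.
#' @export
consensus_loci <- function(scans, window_mb = 10, require_same_allele = TRUE) {
  stopifnot(is.list(scans), length(scans) >= 2L)
  parts <- purrr::imap(scans, consensus_input)
  trait <- unique(map_chr(parts, ~ unique(.x$trait)))
  if (length(trait) != 1L) {
    abort("scans are for different traits")
  }
  all_mk <- bind_rows(parts)
  chk <- all_mk |>
    group_by(.data$marker) |>
    summarise(n_chr = dplyr::n_distinct(.data$chr),
              mb_spread = diff(range(.data$mb)), .groups = "drop")
  if (any(chk$n_chr > 1L) || any(chk$mb_spread > 1e-6)) {
    abort("scans appear to use different map builds (shared markers disagree on position)")
  }
  sig <- all_mk |> filter(.data$reject %in% TRUE)
  if (!nrow(sig)) {
    out <- tibble(locus = character(), type = character(), chr = character(),
                  mb_min = numeric(), mb_max = numeric(),
                  n_markers = integer(), cohorts = character(),
                  high_pd_allele = character(), markers = list())
    attr(out, "assignments") <- tibble(marker = character(),
                                       cohort = character(),
                                       locus = character())
    return(out)
  }
  sig <- sig |> arrange(chr_order(.data$chr), .data$mb)
  sig$cluster <- NA_integer_
  cl <- 0L
  last_chr <- NULL
  last_mb <- -Inf
  for (i in seq_len(nrow(sig))) {
    if (is.null(last_chr) || sig$chr[i] != last_chr ||
        sig$mb[i] - last_mb > window_mb) {
      cl <- cl + 1L
    }
    sig$cluster[i] <- cl
    last_chr <- sig$chr[i]
    last_mb <- sig$mb[i]
  }
  clusters <- sig |>
    group_by(.data$cluster) |>
    summarise(
      chr = .data$chr[1],
      mb_min = min(.data$mb), mb_max = max(.data$mb),
      n_markers = dplyr::n(),
      n_cohorts = dplyr::n_distinct(.data$cohort),
      cohorts = paste(sort(unique(.data$cohort)), collapse = ","),
      alleles = list(unique(.data$allele[!is.na(.data$allele)])),
      markers = list(.data$marker),
      .groups = "drop"
    ) |>
    mutate(
      n_alleles = purrr::map_int(.data$alleles, length),
      type = dplyr::case_when(
        n_cohorts >= 2 & !require_same_allele ~ "consensus",
        n_cohorts >= 2 & n_alleles >= 2 ~ "contrast_pair",
        n_cohorts >= 2 ~ "consensus",
        TRUE ~ "singleton"
      ),
      high_pd_allele = purrr::map_chr(
        .data$alleles, ~ if (length(.x) == 1L) .x else NA_character_
      )
    ) |>
    arrange(chr_order(.data$chr), .data$mb_min)
  is_cons <- clusters$type == "consensus"
  clusters$locus <- NA_character_
  clusters$locus[is_cons] <- paste0("PD", trait_label(trait),
                                    seq_len(sum(is_cons)))
  out <- clusters |>
    select("locus", "type", "chr", "mb_min", "mb_max", "n_markers",
           "cohorts", "high_pd_allele", "markers")
  assignments <- sig |>
    left_join(clusters |> select("cluster", "locus"), by = "cluster") |>
    filter(!is.na(.data$locus)) |>
    select("marker", "cohort", "locus")
  attr(out, "assignments") <- assignments
  out
}
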