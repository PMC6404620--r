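#' Construct an F2 cohort object
#'
#' Bundles a genotype table, phenotype table and marker map for one F2
#' mapping population, with the two parental strain names attached so results
#' (e.g. the high-dispersion allele) can be reported by strain.
#'
#' Genotypes are stored as integers: `0` = homozygote for the first parental
#' strain (P1), `1` = heterozygote, `2` = homozygote for the second strain
#' (P2), `NA` = missing.
#'
#' @param genotypes Tibble with an `individual` column followed by one integer
#'   column per marker (values 0/1/2/NA).
#' @param phenotypes Tibble with columns `individual` and any of `ualb`,
#'   `ucrea`, `bun` (mg/dl) and `weight` (g); missing traits may be absent.
#' @param map Tibble with columns `marker`, `chr`, `pos_bp`, `pos_cm`.
#' @param strains Character vector of length 2: P1 and P2 strain names.
#' @param name Cohort label used in reports.
#' @return An object of class `f2_cohort`.
#' @export
f2_cohort <- function(genotypes, phenotypes, map, strains, name = "cohort") {
  stopifnot(is.character(strains), length(strains) == 2L)
  traits <- intersect(c("ualb", "ucrea", "bun", "weight"), names(phenotypes))
  for (tr in setdiff(c("ualb", "ucrea", "bun", "weight"), traits)) {
    phenotypes[[tr]] <- NA_real_
  }
  x <- structure(
    list(
      name = name,
      genotypes = as_tibble(genotypes),
      phenotypes = as_tibble(phenotypes),
      map = as_tibble(map),
      strains = strains,
      traits_available = traits
    ),
    class = "f2_cohort"
  )
  validate_cohort(x)
}

#' Validate an F2 cohort
#'
#' Enforces the cohort invariants: unique individual and marker IDs, genotype
#' markers present in the map, map positions strictly increasing within each
#' chromosome, consistent individual sets between tables, and non-negative
#' phenotype values.
#'
#' @param x An `f2_cohort`.
#' @return `x`, invisibly unchanged, or an error describing the violation.
#' @export
validate_cohort <- function(x) {
  stopifnot(inherits(x, "f2_cohort"))
  g <- x$genotypes
  p <- x$phenotypes
  m <- x$map
  if (!"individual" %in% names(g) || !"individual" %in% names(p)) {
    abort("genotype and phenotype tables need an `individual` column")
  }
  dup_g <- g$individual[duplicated(g$individual)]
  dup_p <- p$individual[duplicated(p$individual)]
  if (length(dup_g) || length(dup_p)) {
    abort(paste0(
      "duplicated individual IDs: ",
      paste(unique(c(dup_g, dup_p)), collapse = ", ")
    ), class = "dispscan_duplicate_id")
  }
  if (anyDuplicated(m$marker)) {
    abort(paste0(
      "duplicated marker IDs in map: ",
      paste(unique(m$marker[duplicated(m$marker)]), collapse = ", ")
    ), class = "dispscan_duplicate_id")
  }
  only_g <- setdiff(g$individual, p$individual)
  only_p <- setdiff(p$individual, g$individual)
  if (length(only_g) || length(only_p)) {
    abort(paste0(
      "individual IDs disagree between genotypes and phenotypes; ",
      "genotype-only: [", paste(only_g, collapse = ", "),
      "], phenotype-only: [", paste(only_p, collapse = ", "), "]"
    ), class = "dispscan_id_mismatch")
  }
  mk <- setdiff(names(g), "individual")
  missing_map <- setdiff(mk, m$marker)
  if (length(missing_map)) {
    abort(paste0(
      "genotype markers absent from map: ",
      paste(missing_map, collapse = ", ")
    ), class = "dispscan_map_mismatch")
  }
  if (any(m$pos_bp < 0, na.rm = TRUE)) abort("map pos_bp must be >= 0")
  bad_chr <- m |>
    dplyr::group_by(.data$chr) |>
    dplyr::arrange(.data$pos_bp, .by_group = TRUE) |>
    dplyr::summarise(ok = !anyDuplicated(.data$pos_bp), .groups = "drop")
  if (any(!bad_chr$ok)) {
    abort(paste0(
      "map positions not strictly increasing on chromosome(s): ",
      paste(bad_chr$chr[!bad_chr$ok], collapse = ", ")
    ))
  }
  gm <- as.matrix(g[mk])
  if (!all(gm %in% c(0L, 1L, 2L, NA))) {
    abort("genotype cells must be 0, 1, 2 or NA")
  }
  for (tr in c("ualb", "ucrea", "bun", "weight")) {
    if (any(p[[tr]] < 0, na.rm = TRUE)) {
      abort(paste0("negative values in phenotype `", tr, "`"))
    }
  }
  invisible(x)
}

#' @export
print.f2_cohort <- function(x, ...) {
  cat("<f2_cohort> ", x$name, "\n", sep = "")
  cat("  individuals: ", nrow(x$genotypes),
      ", markers: ", ncol(x$genotypes) - 1L,
      " on ", length(unique(x$map$chr)), " chromosome(s)\n", sep = "")
  cat("  strains: ", x$strains[1], " (P1) x ", x$strains[2], " (P2)\n", sep = "")
  cat("  traits available: ", paste(x$traits_available, collapse = ", "),
      "\n", sep = "")
  invisible(x)
}

default_geno_codes <- function() {
  list(hom_p1 = "A", het = "H", hom_p2 = "B", missing = c("-", "NA", ""))
}

#' Read an F2 cohort from delimited text files
#'
#' Reads genotype, phenotype and map CSV files and assembles a validated
#' [f2_cohort()]. Genotype code mapping is configuration, not inference: pass
#' a `codes` dictionary (or a YAML sidecar via `config`) declaring which
#' strings mean P1-homozygote, heterozygote, P2-homozygote and missing.
#' Genotype codes not covered by the dictionary become missing with a warning
#' giving the count.
#'
#' @param geno_path CSV of individuals x markers; first column is the
#'   individual ID, remaining columns hold genotype codes.
#' @param pheno_path CSV with an individual ID column and any of
#'   `ualb`, `ucrea`, `bun`, `weight` (case-insensitive). Absent columns mark
#'   the trait unavailable; they are not an error.
#' @param map_path CSV with columns `marker`, `chr`, `pos_bp` (or `bp`),
#'   `pos_cm` (or `cm`).
#' @param strains Length-2 character vector of parental strain names (P1, P2).
#' @param codes Genotype code dictionary; see [default_geno_codes] in source.
#' @param config Optional path to a YAML sidecar with `strains`, `codes`
#'   and/or `name` entries, overriding the corresponding arguments.
#' @param name Cohort label.
#' @return An `f2_cohort`.
#' @export
read_cohort <- function(geno_path, pheno_path, map_path,
                        strains = c("P1", "P2"),
                        codes = default_geno_codes(),
                        config = NULL,
                        name = "cohort") {
  if (!is.null(config)) {
    cfg <- yaml::read_yaml(config)
    if (!is.null(cfg$strains)) strains <- as.character(cfg$strains)
    if (!is.null(cfg$codes)) codes <- modifyList(codes, cfg$codes)
    if (!is.null(cfg$name)) name <- cfg$name
  }
  graw <- readr::read_csv(geno_path, col_types = readr::cols(
    .default = readr::col_character()
  ), progress = FALSE)
  names(graw)[1] <- "individual"
  mk <- setdiff(names(graw), "individual")
  lut <- c(
    setNames(rep(0L, length(codes$hom_p1)), as.character(codes$hom_p1)),
    setNames(rep(1L, length(codes$het)), as.character(codes$het)),
    setNames(rep(2L, length(codes$hom_p2)), as.character(codes$hom_p2))
  )
  n_unmapped <- 0L
  geno <- graw
  for (j in mk) {
    v <- graw[[j]]
    out <- unname(lut[v])
    declared_missing <- v %in% as.character(codes$missing) | is.na(v)
    n_unmapped <- n_unmapped + sum(is.na(out) & !declared_missing)
    geno[[j]] <- out
  }
  if (n_unmapped > 0L) {
    warn(paste0(n_unmapped, " genotype cell(s) with unmappable codes set to missing"))
  }

  praw <- readr::read_csv(pheno_path, col_types = readr::cols(), progress = FALSE)
  names(praw)[1] <- "individual"
  names(praw) <- tolower(names(praw))
  praw$individual <- as.character(praw$individual)
  geno$individual <- as.character(geno$individual)

  mraw <- readr::read_csv(map_path, col_types = readr::cols(), progress = FALSE)
  names(mraw) <- tolower(names(mraw))
  nm <- names(mraw)
  pick <- function(...) {
    cand <- c(...)
    hit <- cand[cand %in% nm]
    if (!length(hit)) abort(paste0("map file lacks a column among: ",
                                   paste(cand, collapse = ", ")))
    hit[1]
  }
  map <- tibble(
    marker = as.character(mraw[[pick("marker", "marker_id", "snp")]]),
    chr = as.character(mraw[[pick("chr", "chromosome")]]),
    pos_bp = as.numeric(mraw[[pick("pos_bp", "bp", "position_bp")]]),
    pos_cm = as.numeric(mraw[[pick("pos_cm", "cm", "position_cm")]])
  )

  f2_cohort(genotypes = geno, phenotypes = praw, map = map,
            strains = strains, name = name)
}

#' Write an F2 cohort to delimited text files
#'
#' Writes `<prefix>_geno.csv`, `<prefix>_pheno.csv`, `<prefix>_map.csv` and a
#' YAML sidecar `<prefix>_cohort.yaml` declaring the genotype code dictionary
#' and strain names, so that [read_cohort()] round-trips losslessly.
#'
#' @param cohort An `f2_cohort`.
#' @param prefix Output path prefix.
#' @param codes Genotype code dictionary used for encoding.
#' @return Named character vector of the four file paths, invisibly.
#' @export
write_cohort <- function(cohort, prefix, codes = default_geno_codes()) {
  stopifnot(inherits(cohort, "f2_cohort"))
  mk <- setdiff(names(cohort$genotypes), "individual")
  out <- cohort$genotypes
  enc <- c(codes$hom_p1[1], codes$het[1], codes$hom_p2[1])
  for (j in mk) {
    v <- enc[cohort$genotypes[[j]] + 1L]
    v[is.na(v)] <- codes$missing[1]
    out[[j]] <- v
  }
  paths <- c(
    geno = paste0(prefix, "_geno.csv"),
    pheno = paste0(prefix, "_pheno.csv"),
    map = paste0(prefix, "_map.csv"),
    config = paste0(prefix, "_cohort.yaml")
  )
  readr::write_csv(out, paths["geno"], progress = FALSE)
  readr::write_csv(
    cohort$phenotypes[c("individual",
                        intersect(c("ualb", "ucrea", "bun", "weight"),
                                  cohort$traits_available))],
    paths["pheno"], progress = FALSE
  )
  readr::write_csv(cohort$map, paths["map"], progress = FALSE)
  yaml::write_yaml(
    list(name = cohort$name, strains = cohort$strains,
         codes = lapply(codes, as.character)),
    paths["config"]
  )
  invisible(paths)
}
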