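# Shared fixture builders; everything is generated in code at test time.

toy_map <- function() {
  tibble::tibble(
    marker = c("m1", "m2"),
    chr = c("1", "1"),
    pos_bp = c(1e6, 5e6),
    pos_cm = c(0.5, 2.5)
  )
}

toy_cohort <- function() {
  f2_cohort(
    genotypes = tibble::tibble(
      individual = c("i1", "i2", "i3"),
      m1 = c(0L, 1L, 2L),
      m2 = c(1L, 1L, 0L)
    ),
    phenotypes = tibble::tibble(
      individual = c("i1", "i2", "i3"),
      ualb = c(0.5, 1.2, 0.8),
      ucrea = c(70, 80, 75)
    ),
    map = toy_map(),
    strains = c("C57BL/6J", "A/J"),
    name = "toy"
  )
}

write_toy_files <- function(dir, geno_codes = c("A", "H", "B")) {
  geno <- data.frame(
    individual = c("i1", "i2", "i3"),
    m1 = geno_codes[c(1, 2, 3)],
    m2 = geno_codes[c(2, 2, 1)]
  )
  pheno <- data.frame(
    individual = c("i1", "i2", "i3"),
    ualb = c(0.5, 1.2, 0.8),
    ucrea = c(70, 80, 75)
  )
  map <- data.frame(
    marker = c("m1", "m2"), chr = c("1", "1"),
    pos_bp = c(1e6, 5e6), pos_cm = c(0.5, 2.5)
  )
  paths <- list(
    geno = file.path(dir, "geno.csv"),
    pheno = file.path(dir, "pheno.csv"),
    map = file.path(dir, "map.csv")
  )
  write.csv(geno, paths$geno, row.names = FALSE)
  write.csv(pheno, paths$pheno, row.names = FALSE)
  write.csv(map, paths$map, row.names = FALSE)
  paths
}

# Small fast map for simulation-heavy tests: 3 chromosomes, 12 markers.
fast_map <- function() {
  sim_map(chr_lengths_cm = c(60, 60, 60), spacing_cm = 20)
}

# A tobit_fit-shaped object with prescribed genotype means and (co)variance,
# for contrast arithmetic tests that need exact means.
fake_locus_fit <- function(mu_cc, mu_ca, mu_aa, se = 1e-4) {
  beta <- c(`(Intercept)` = mu_aa, locushet = mu_ca - mu_aa,
            locushom_p1 = mu_cc - mu_aa)
  V <- diag(se^2, 4)
  dimnames(V) <- list(c(names(beta), "sigma"), c(names(beta), "sigma"))
  structure(
    list(beta = beta, sigma = 1, vcov = V, loglik = 0, converged = TRUE,
         n = 100L, iterations = 0L, gradient_norm = 0,
         fitted = numeric(0), y = numeric(0),
         variant = "truncated", bound = 0),
    class = "tobit_fit"
  )
}
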