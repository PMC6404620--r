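test_that("a strong dispersion locus is found, labelled, and the scan is deterministic", {
  map <- fast_map()
  causal <- map$marker[2]
  eff <- vqtl_effect(causal, "D-", sigma_ratio = 3)
  co <- simulate_cohort(map = map, effects = eff,
                        config = sim_config(n = 300), seed = 41)
  sc1 <- suppressWarnings(scan_trait(co, "ualb"))
  sc2 <- suppressWarnings(scan_trait(co, "ualb"))
  expect_identical(sc1$table, sc2$table)
  expect_equal(sc1$table$marker[which.min(sc1$table$p_joint)], causal)
  forms <- sc1$table$forms[[match(causal, sc1$table$marker)]]
  expect_true("D-" %in% forms$form)
  expect_equal(sc1$table$high_pd_allele[match(causal, sc1$table$marker)],
               "A/J")
  expect_true(all(sc1$table$df_joint == 2))
  expect_true(all(sc1$table$converged))
})

test_that("monomorphic markers are skipped and excluded from the FDR family", {
  map <- fast_map()
  co <- simulate_cohort(map = map, config = sim_config(n = 120), seed = 43)
  mono <- map$marker[5]
  co$genotypes[[mono]] <- rep(1L, nrow(co$genotypes))
  sc <- suppressWarnings(scan_trait(co, "ualb"))
  expect_true(mono %in% sc$skipped$marker)
  expect_match(sc$skipped$reason[sc$skipped$marker == mono], "monomorphic")
  expect_false(mono %in% sc$table$marker)
  # FDR thresholds use m = number of *tested* markers
  m_tested <- nrow(sc$table)
  expect_equal(sort(unique(sc$table$bh_threshold)),
               sort(unique(sc$table$fdr_rank)) * 0.05 / m_tested)
})

test_that("removing a non-significant marker changes only the FDR columns", {
  map <- fast_map()
  eff <- vqtl_effect(map$marker[2], "D-", sigma_ratio = 3)
  co <- simulate_cohort(map = map, effects = eff,
                        config = sim_config(n = 250), seed = 44)
  sc_full <- suppressWarnings(scan_trait(co, "ualb"))
  drop_mk <- sc_full$table$marker[which.max(sc_full$table$p_joint)]
  co2 <- co
  co2$map <- co2$map[co2$map$marker != drop_mk, ]
  co2$genotypes[[drop_mk]] <- NULL
  co2$genotypes[[paste0(drop_mk, "_shadow")]] <- co$genotypes[[drop_mk]]
  co2$map <- rbind(co2$map, tibble::tibble(
    marker = paste0(drop_mk, "_shadow"), chr = "19", pos_bp = 1e6,
    pos_cm = 0.5
  ))
  # keep the marker's genotypes in the cohort (as an untested shadow column
  # outside the scan) so MLH is unchanged; then drop the shadow row too
  co2$map <- co2$map[co2$map$marker != paste0(drop_mk, "_shadow"), ]
  sc_red <- suppressWarnings(scan_trait(co2, "ualb"))
  shared <- intersect(sc_full$table$marker, sc_red$table$marker)
  i1 <- match(shared, sc_full$table$marker)
  i2 <- match(shared, sc_red$table$marker)
  for (col in c("p_joint", "stat_joint", "r2", "n_used", "high_pd_allele",
                "potence")) {
    expect_equal(sc_red$table[[col]][i2], sc_full$table[[col]][i1])
  }
  expect_equal(sc_red$table$forms[i2], sc_full$table$forms[i1])
})

test_that("two-class markers get a 1-df joint test and no architecture call", {
  map <- sim_map(chr_lengths_cm = c(60, 60), spacing_cm = 20,
                 include_x = TRUE, x_length_cm = 40)
  co <- simulate_cohort(map = map, config = sim_config(n = 200), seed = 45)
  x_markers <- map$marker[map$chr == "X"]
  expect_true(all(as.matrix(co$genotypes[x_markers]) %in% c(0L, 2L)))
  sc <- suppressWarnings(scan_trait(co, "ualb"))
  xt <- sc$table[sc$table$chr == "X", ]
  expect_true(nrow(xt) > 0)
  expect_true(all(xt$df_joint == 1))
  expect_true(all(vapply(xt$forms, nrow, 1L) == 0L))
  at <- sc$table[sc$table$chr != "X", ]
  expect_true(all(at$df_joint == 2))
})

test_that("variance explained behaves at the edges and matches OLS R2 without censoring", {
  fit <- fake_locus_fit(1, 2, 3)
  fit$fitted <- c(1, 2, 3, 4)
  fit$y <- c(1, 2, 3, 4)
  expect_equal(variance_explained(fit), 1)
  fit$fitted <- rep(2, 4)
  expect_warning(r0 <- variance_explained(fit), "constant")
  expect_equal(r0, 0)
  fit$fitted <- c(1, 2, 3, 4)
  fit$y <- rep(1, 4)
  expect_warning(rz <- variance_explained(fit), "zero variance")
  expect_equal(rz, 0)

  set.seed(47)
  n <- 300
  g <- sample(0:2, n, TRUE, c(.25, .5, .25))
  X <- model.matrix(~ factor(g))
  y <- 5 + 0.8 * g + rnorm(n)
  tf <- fit_tobit(y, X, bound = min(y) - 10, variant = "censored")
  r2_tobit <- variance_explained(tf, y)
  r2_ols <- summary(lm(y ~ factor(g)))$r.squared
  expect_equal(r2_tobit, r2_ols, tolerance = 1e-6)
})

test_that("consensus grouping follows the window and allele rules", {
  mk_scan <- function(cohort_name, marker, chr, mb, allele, p = 0.001) {
    structure(
      list(table = tibble::tibble(
        marker = marker, chr = chr, mb = mb, pos_bp = mb * 1e6,
        pos_cm = mb / 2, p_joint = p, r2 = 0.05,
        reject = TRUE, high_pd_allele = allele,
        forms = replicate(length(marker), tibble::tibble(
          form = "D-", p_arch = 0.001, high_allele = allele[1]
        ), simplify = FALSE)
      ), skipped = tibble::tibble(), trait = "ualb",
      cohort = cohort_name, strains = c("C57BL/6J", "A/J"),
      config = scan_config()),
      class = "pd_scan"
    )
  }
  # peaks at 22.6 and 35.7 MB: same chromosome, same allele -> one locus
  a <- mk_scan("cohA", "01-023061064-M", "1", 22.6, "A/J")
  b <- mk_scan("cohB", "01-036208806-N", "1", 35.7, "A/J")
  cons <- consensus_loci(list(a, b), window_mb = 15)
  expect_equal(nrow(cons), 1L)
  expect_equal(cons$type, "consensus")
  expect_equal(cons$locus, "PDUAlb1")
  expect_equal(cons$high_pd_allele, "A/J")

  # 50 MB apart: no grouping at the default 10 MB window
  c2 <- mk_scan("cohB", "far", "1", 72.6, "A/J")
  cons2 <- consensus_loci(list(a, c2))
  expect_true(all(cons2$type == "singleton"))
  expect_true(all(is.na(cons2$locus)))

  # same position, opposite high-dispersion alleles: contrast pair
  d <- mk_scan("cohB", "flip", "1", 23.0, "C57BL/6J")
  cons3 <- consensus_loci(list(a, d))
  expect_equal(cons3$type, "contrast_pair")
  expect_true(is.na(cons3$locus))
  # without the allele requirement the same cluster becomes a consensus locus
  cons4 <- consensus_loci(list(a, d), require_same_allele = FALSE)
  expect_equal(cons4$type, "consensus")

  # conflicting map builds are an error
  a2 <- mk_scan("cohB", "01-023061064-M", "2", 22.6, "A/J")
  expect_error(consensus_loci(list(a, a2)), "map builds")
})

test_that("consensus naming orders loci by chromosome then position", {
  mk <- function(cohort_name, marker, chr, mb) {
    structure(
      list(table = tibble::tibble(
        marker = marker, chr = chr, mb = mb, pos_bp = mb * 1e6,
        pos_cm = mb / 2, p_joint = 1e-4, r2 = 0.1, reject = TRUE,
        high_pd_allele = "A/J",
        forms = replicate(length(marker),
                          tibble::tibble(form = "D-", p_arch = 1e-3,
                                         high_allele = "A/J"),
                          simplify = FALSE)
      ), skipped = tibble::tibble(), trait = "ualb", cohort = cohort_name,
      strains = c("C57BL/6J", "A/J"), config = scan_config()),
      class = "pd_scan"
    )
  }
  a <- mk("A", c("c8a", "c1a"), c("8", "1"), c(40, 10))
  b <- mk("B", c("c8b", "c1b"), c("8", "1"), c(42, 12))
  cons <- consensus_loci(list(a, b))
  expect_equal(cons$locus, c("PDUAlb1", "PDUAlb2"))
  expect_equal(cons$chr, c("1", "8"))
  asg <- attr(cons, "assignments")
  expect_equal(sort(asg$marker[asg$locus == "PDUAlb2"]), c("c8a", "c8b"))
})
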