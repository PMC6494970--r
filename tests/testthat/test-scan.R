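test_that("with no polygenic variance the scan matches a fixed-effects OLS oracle", {
  # balanced design, sigma2_g = 0: the mixed model collapses to OLS and the
  # LRT p-values must match likelihoods computed independently via lm().
  map <- simulate_genetic_map(1, 8, 80, seed = 51)
  geno <- simulate_ril_genotypes(map, 60, seed = 52)
  comps <- trial_components(mu = 20, sigma2_g = 0, sigma2_gy = 0,
                            sigma2_ge = 0, sigma2_bloc = 0, sigma2_E = 5,
                            year_effects = c(`2013` = 0, `2014` = 1),
                            scenario_effects = c(I = 0, NI = -3))
  des <- trial_design(years = c(2013L, 2014L), blocs_per_year = 1L,
                      check_lines = NULL)
  tr <- simulate_trial_phenotypes(geno, NULL, des, comps, seed = 53)
  sc <- scan_markers(tr$phenotypes, geno, map, "trait")

  ph <- tr$phenotypes
  for (i in seq_len(nrow(map))) {
    x <- ifelse(geno$calls[ph$line, map$marker[i]] == "A", 1, -1)
    d <- data.frame(y = ph$trait, yr = factor(ph$year),
                    sc = factor(ph$scenario), x = x)
    d$xi <- d$x * (d$sc == "NI")
    full <- lm(y ~ yr * sc + x + xi, data = d)
    p_main <- pchisq(2 * (logLik(full) - logLik(lm(y ~ yr * sc + xi,
                                                   data = d))),
                     1, lower.tail = FALSE)
    p_int <- pchisq(2 * (logLik(full) - logLik(lm(y ~ yr * sc + x,
                                                  data = d))),
                    1, lower.tail = FALSE)
    expect_equal(signif(sc$p_const[i], 2), signif(as.numeric(p_main), 2))
    expect_equal(signif(sc$p_resp[i], 2), signif(as.numeric(p_int), 2))
  }
})

test_that("a purely responsive QTL is detected by the interaction term only", {
  map <- simulate_genetic_map(2, 15, 100, seed = 61)
  geno <- simulate_ril_genotypes(map, 150, seed = 62)
  qt <- qtl_effects("c01_m008", additive_effect = 0, interaction_effect = 3)
  comps <- trial_components(mu = 0, sigma2_g = 10, sigma2_gy = 1,
                            sigma2_ge = 1, sigma2_bloc = 0, sigma2_E = 6,
                            year_effects = c(`2013` = 0, `2014` = 1),
                            scenario_effects = c(I = 0, NI = -4))
  st <- small_trial(n_lines = 150, seed = 63, qtls = qt, components = comps)
  # regenerate with this test's own map/genotypes for anchor control
  tr <- simulate_trial_phenotypes(geno, qt, trial_design(
    years = c(2013L, 2014L), blocs_per_year = 4L), comps, seed = 64)
  sc <- scan_markers(tr$phenotypes, geno, map, "trait")
  at <- which(sc$marker == "c01_m008")
  expect_lt(sc$p_resp[at], 5e-5)
  expect_lt(sc$p_resp[at], sc$p_const[at])
})

test_that("markers with a single allele class are flagged untestable, not errors", {
  map <- simulate_genetic_map(1, 5, 60, seed = 71)
  geno <- simulate_ril_genotypes(map, 40, seed = 72)
  calls <- geno$calls
  calls[, 3] <- "A"  # monomorphic
  geno2 <- ril_genotypes(calls)
  st <- small_trial(n_lines = 40, seed = 73)
  tr <- simulate_trial_phenotypes(geno2, NULL, trial_design(
    years = 2013L, blocs_per_year = 3L), trial_components(), seed = 74)
  sc <- scan_markers(tr$phenotypes, geno2, map, "trait")
  expect_true(sc$untestable[3])
  expect_equal(sc$p_const[3], 1)
  expect_equal(sc$p_resp[3], 1)
  expect_false(any(sc$untestable[-3]))
})

test_that("scan p-values are invariant to marker order and allele relabeling", {
  map <- simulate_genetic_map(1, 6, 70, seed = 81)
  geno <- simulate_ril_genotypes(map, 50, seed = 82)
  tr <- simulate_trial_phenotypes(geno, NULL, trial_design(
    years = c(2013L, 2014L), blocs_per_year = 2L),
    trial_components(), seed = 83)
  sc <- scan_markers(tr$phenotypes, geno, map, "trait")

  perm <- c(4, 1, 6, 2, 5, 3)
  geno_p <- ril_genotypes(geno$calls[, perm])
  sc_p <- scan_markers(tr$phenotypes, geno_p, map, "trait")
  expect_equal(sc_p$marker, sc$marker)  # output stays in map order
  expect_equal(sc_p$p_const, sc$p_const, tolerance = 1e-8)

  flipped <- ifelse(geno$calls == "A", "B", "A")
  geno_f <- ril_genotypes(flipped)
  sc_f <- scan_markers(tr$phenotypes, geno_f, map, "trait")
  expect_equal(sc_f$p_const, sc$p_const, tolerance = 1e-6)
  expect_equal(sc_f$p_resp, sc$p_resp, tolerance = 1e-6)
  # class means swap roles under relabeling
  expect_equal(sc_f$mean_A_I, sc$mean_B_I)
})

test_that("lines with missing calls are dropped per marker only", {
  map <- simulate_genetic_map(1, 4, 40, seed = 91)
  geno <- simulate_ril_genotypes(map, 30, seed = 92)
  calls <- geno$calls
  calls[1:5, 2] <- NA
  geno2 <- ril_genotypes(calls)
  tr <- simulate_trial_phenotypes(geno, NULL, trial_design(
    years = 2013L, blocs_per_year = 2L), trial_components(), seed = 93)
  sc <- scan_markers(tr$phenotypes, geno2, map, "trait")
  expect_equal(sc$n_lines, c(30L, 25L, 30L, 30L))
})
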