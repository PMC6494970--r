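test_that("without bloc variance the bloc BLUPs are negligible", {
  comps <- trial_components(mu = 100, sigma2_g = 20, sigma2_gy = 2,
                            sigma2_ge = 2, sigma2_bloc = 0, sigma2_E = 8)
  st <- small_trial(n_lines = 60, components = comps, seed = 5)
  bc <- correct_bloc_effects(st$trial$phenotypes, "trait")
  expect_lt(max(abs(bc$blups$blup)), 0.05 * sqrt(8))
  expect_equal(bc$corrected$trait, st$trial$phenotypes$trait,
               tolerance = 0.02)
})

test_that("bloc BLUPs recover injected bloc effects and shrink toward zero", {
  st <- small_trial(n_lines = 60, seed = 8,
                    design = trial_design(
                      years = c(2013L, 2014L, 2015L),
                      blocs_per_year = c(`2013` = 8L, `2014` = 8L,
                                         `2015` = 8L)))
  ph <- st$trial$phenotypes
  truth <- st$trial$truth$bloc_effects
  bc <- correct_bloc_effects(ph, "trait")
  expect_gte(nrow(bc$blups), 20)
  m <- merge(bc$blups, truth, by = c("year", "scenario", "bloc"))
  expect_gt(cor(m$blup, m$effect), 0.9)
  # shrinkage: predicted effects are smaller than raw bloc-mean deviations
  key <- paste(ph$year, ph$scenario, ph$bloc)
  raw_dev <- tapply(ph$trait, key, mean) - mean(ph$trait)
  expect_lt(var(bc$blups$blup), var(raw_dev))
  # corrected bloc means vary less than raw bloc means
  corr_dev <- tapply(bc$corrected$trait, key, mean)
  expect_lt(var(corr_dev), var(tapply(ph$trait, key, mean)))
  # keys and dimensions unchanged
  expect_equal(dim(bc$corrected), dim(ph))
  expect_identical(bc$corrected$line, ph$line)
})

test_that("bloc correction is refused with a single bloc and is idempotent in expectation", {
  des1 <- trial_design(years = 2013L, blocs_per_year = 1L,
                       scenarios = "I")
  map <- simulate_genetic_map(1, 4, 50, seed = 1)
  g <- simulate_ril_genotypes(map, 30, seed = 1)
  tr <- simulate_trial_phenotypes(g, NULL, des1, trial_components(),
                                  seed = 12)
  expect_error(correct_bloc_effects(tr$phenotypes, "trait"),
               "at least 2 blocs")

  st2 <- small_trial(n_lines = 50, seed = 13)
  bc1 <- correct_bloc_effects(st2$trial$phenotypes, "trait")
  bc2 <- suppressWarnings(correct_bloc_effects(bc1$corrected, "trait"))
  expect_lt(sd(bc2$blups$blup), 0.2 * sd(bc1$blups$blup) + 1e-6)
})

test_that("variance components recover generating values on a mid-size trial", {
  comps <- trial_components(mu = 10, sigma2_g = 4, sigma2_gy = 3,
                            sigma2_ge = 2, sigma2_bloc = 0, sigma2_E = 6,
                            year_effects = c(`2013` = 0, `2014` = 1),
                            scenario_effects = c(I = 0, NI = -2))
  st <- small_trial(n_lines = 150, components = comps, seed = 17)
  vc <- estimate_components(st$trial$phenotypes, "trait")
  expect_lt(abs(vc$sigma2_g - 4) / 4, 0.35)
  expect_lt(abs(vc$sigma2_gy - 3) / 3, 0.35)
  expect_lt(abs(vc$sigma2_ge - 2) / 2, 0.45)
  expect_lt(abs(vc$sigma2_E - 6) / 6, 0.15)
  expect_equal(vc$k, 2L)
  expect_equal(vc$j, 2L)
  expect_equal(vc$obs_per_line, 14)
})

test_that("REML estimates are location invariant and zero for constant data", {
  st <- small_trial(n_lines = 40, seed = 19)
  ph <- st$trial$phenotypes
  vc1 <- estimate_components(ph, "trait")
  ph2 <- ph
  ph2$trait <- ph2$trait + 1000
  vc2 <- estimate_components(ph2, "trait")
  expect_equal(vc1$sigma2_g, vc2$sigma2_g, tolerance = 1e-3)
  expect_equal(vc1$sigma2_E, vc2$sigma2_E, tolerance = 1e-3)

  ph3 <- ph
  ph3$trait <- 7
  vc3 <- estimate_components(ph3, "trait")
  expect_equal(vc3$sigma2_g + vc3$sigma2_gy + vc3$sigma2_ge + vc3$sigma2_E,
               0)
})

test_that("permuting line labels moves genetic variance into the residual", {
  comps <- trial_components(mu = 0, sigma2_g = 30, sigma2_gy = 1,
                            sigma2_ge = 1, sigma2_bloc = 0, sigma2_E = 5)
  st <- small_trial(n_lines = 80, components = comps, seed = 23)
  ph <- st$trial$phenotypes[!st$trial$phenotypes$is_check, ]
  vc <- estimate_components(ph, "trait")
  set.seed(1)
  ph2 <- ph
  ph2$line <- sample(ph2$line)
  vc2 <- estimate_components(ph2, "trait")
  expect_lt(vc2$sigma2_g, 0.1 * vc$sigma2_g)
  expect_gt(vc2$sigma2_E, vc$sigma2_E)
})

test_that("with one year and one scenario REML reduces to one-way ANOVA moments", {
  des <- trial_design(years = 2013L, blocs_per_year = 4L,
                      scenarios = "I", check_lines = NULL)
  comps <- trial_components(mu = 5, sigma2_g = 6, sigma2_gy = 0,
                            sigma2_ge = 0, sigma2_bloc = 0, sigma2_E = 3,
                            year_effects = NULL, scenario_effects = NULL)
  map <- simulate_genetic_map(1, 5, 50, seed = 2)
  g <- simulate_ril_genotypes(map, 40, seed = 3)
  tr <- simulate_trial_phenotypes(g, NULL, des, comps, seed = 4)
  ph <- tr$phenotypes
  vc <- estimate_components(ph, "trait")
  # balanced one-way method of moments: sigma_E = MSW, sigma_g = (MSB-MSW)/r
  fit <- aov(trait ~ factor(line), data = ph)
  ms <- summary(fit)[[1]][["Mean Sq"]]
  r <- 4
  expect_equal(vc$sigma2_E, ms[2], tolerance = 1e-4)
  expect_equal(vc$sigma2_g, max((ms[1] - ms[2]) / r, 0), tolerance = 1e-4)
})

test_that("degenerate designs raise identifiability errors", {
  des <- trial_design(years = 2013L, blocs_per_year = 1L,
                      scenarios = c("I", "NI"), check_lines = NULL)
  map <- simulate_genetic_map(1, 4, 50, seed = 1)
  g <- simulate_ril_genotypes(map, 20, seed = 1)
  tr <- simulate_trial_phenotypes(g, NULL, des, trial_components(), seed = 2)
  expect_error(estimate_components(tr$phenotypes, "trait"), "degenerate")
})

test_that("heritability follows its closed form and limits", {
  vc <- variance_components(4, 3, 2, 6, k = 2, j = 3, obs_per_line = 46)
  expect_equal(broad_sense_heritability(vc), 4 / (4 + 1 + 1 + 6 / 46),
               tolerance = 1e-12)
  expect_equal(round(broad_sense_heritability(vc), 4), 0.6525)

  vc1 <- variance_components(5, 0, 0, 0, k = 2, j = 3, obs_per_line = 10)
  expect_equal(broad_sense_heritability(vc1), 1)

  h <- sapply(c(2, 5, 20, 100), function(obs)
    broad_sense_heritability(
      variance_components(4, 3, 2, 6, k = 2, j = 3, obs_per_line = obs)))
  expect_false(is.unsorted(h))

  expect_error(broad_sense_heritability(
    variance_components(0, 0, 0, 0, k = 2, j = 3, obs_per_line = 10)),
    "undefined")
})

test_that("the sequential r-squared decomposition sums to 100 and tracks the design", {
  st <- small_trial(n_lines = 60, seed = 29)
  tab <- anova_r2_table(st$trial$phenotypes, "trait")
  expect_equal(sum(tab$r2_percent), 100, tolerance = 0.1)

  # scenario-dominated data
  comps <- trial_components(mu = 0, sigma2_g = 0.01, sigma2_gy = 0.01,
                            sigma2_ge = 0.01, sigma2_bloc = 0,
                            sigma2_E = 0.05, year_effects = NULL,
                            scenario_effects = c(I = 0, NI = -10))
  st2 <- small_trial(n_lines = 60, components = comps, seed = 31)
  tab2 <- anova_r2_table(st2$trial$phenotypes, "trait")
  expect_gt(tab2$r2_percent[tab2$term == "scenario"], 90)
  expect_true(all(tab2$r2_percent[!tab2$term %in%
                                    c("scenario", "residual")] < 5))

  # genetics-dominated data
  comps3 <- trial_components(mu = 0, sigma2_g = 50, sigma2_gy = 1,
                             sigma2_ge = 1, sigma2_bloc = 0, sigma2_E = 4,
                             year_effects = c(`2013` = 0, `2014` = 0.5),
                             scenario_effects = c(I = 0, NI = -1))
  st3 <- small_trial(n_lines = 60, components = comps3, seed = 37)
  tab3 <- anova_r2_table(st3$trial$phenotypes, "trait")
  expect_equal(tab3$term[which.max(tab3$r2_percent)], "genetic")

  ph <- st$trial$phenotypes
  ph$trait <- 1
  expect_error(anova_r2_table(ph, "trait"), "zero total variance")
})

test_that("the r-squared decomposition equals a direct plot-level sequential ANOVA", {
  st <- small_trial(n_lines = 12, seed = 41)
  ph <- st$trial$phenotypes[!st$trial$phenotypes$is_check, ]
  tab <- anova_r2_table(ph, "trait")
  fit <- lm(trait ~ factor(line) + factor(year) + factor(scenario) +
              factor(line):factor(year) + factor(line):factor(scenario) +
              factor(year):factor(scenario), data = ph)
  an <- anova(fit)
  ss <- an[["Sum Sq"]]
  r2 <- 100 * ss / sum(ss)
  expect_equal(tab$r2_percent[tab$term == "genetic"], r2[1],
               tolerance = 1e-6)
  expect_equal(tab$r2_percent[tab$term == "year"], r2[2], tolerance = 1e-6)
  expect_equal(tab$r2_percent[tab$term == "residual"], r2[7],
               tolerance = 1e-6)
})
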