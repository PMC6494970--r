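# Shared fixture builders. Everything is generated in code under fixed
# seeds; no data files.

# A compact two-chromosome trial: fast enough for unit tests while keeping
# the full design structure (two scenarios, >= 2 years, blocs, checks).
small_trial <- function(n_lines = 80, seed = 42, qtls = NULL,
                        components = trial_components(
                          mu = 100, sigma2_g = 20, sigma2_gy = 4,
                          sigma2_ge = 3, sigma2_bloc = 6, sigma2_E = 8,
                          year_effects = c(`2013` = 0, `2014` = 2),
                          scenario_effects = c(I = 0, NI = -10)),
                        design = trial_design(
                          years = c(2013L, 2014L),
                          blocs_per_year = c(`2013` = 4L, `2014` = 3L))) {
  map <- simulate_genetic_map(2, 25, 120, seed = seed)
  geno <- simulate_ril_genotypes(map, n_lines, seed = seed + 1L)
  trial <- simulate_trial_phenotypes(geno, qtls, design, components,
                                     seed = seed + 2L)
  list(map = map, geno = geno, trial = trial, design = design,
       components = components)
}

# Noise-free components: only fixed effects (and whatever variances the
# caller re-enables) so algebraic identities hold exactly.
silent_components <- function(...) {
  trial_components(mu = 50, sigma2_g = 0, sigma2_gy = 0, sigma2_ge = 0,
                   sigma2_bloc = 0, sigma2_E = 0,
                   year_effects = c(`2013` = 1, `2014` = -1),
                   scenario_effects = c(I = 0, NI = -5), ...)
}

# Brute-force least-squares ls-means oracle: solves the normal equations of
# the dummy-coded fixed model directly and averages predictions over the
# full factor grid. Independent of lm()/emmeans.
lsmeans_oracle <- function(df, trait, terms = c("line", "year")) {
  fac <- lapply(df[terms], factor)
  X <- matrix(1, nrow(df), 1)
  for (f in fac) X <- cbind(X, outer(f, levels(f)[-1], `==`) * 1)
  y <- df[[trait]]
  beta <- qr.solve(crossprod(X) + diag(1e-10, ncol(X)), crossprod(X, y))
  grid <- expand.grid(lapply(fac, levels), stringsAsFactors = FALSE)
  names(grid) <- terms
  Xg <- matrix(1, nrow(grid), 1)
  for (i in seq_along(terms))
    Xg <- cbind(Xg, outer(factor(grid[[terms[i]]],
                                 levels = levels(fac[[i]])),
                          levels(fac[[i]])[-1], `==`) * 1)
  pred <- drop(Xg %*% beta)
  tapply(pred, grid$line, mean)
}
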