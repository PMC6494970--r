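mini_map <- function(pos = c(0, 10, 20, 30, 40, 50), chrom = "chr01") {
  m <- data.frame(marker = sprintf("m%02d", seq_along(pos)), chrom = chrom,
                  pos_cM = pos, stringsAsFactors = FALSE)
  class(m) <- c("genetic_map", "data.frame")
  m
}

mini_scan <- function(p, map, presp = rep(1, nrow(map))) {
  data.frame(trait = "t", marker = map$marker, chrom = map$chrom,
             pos_cM = map$pos_cM, p_const = p, p_resp = presp,
             n_lines = 100L, untestable = FALSE, stringsAsFactors = FALSE)
}

test_that("adjacent significant runs become QTLs with run-based intervals", {
  map <- mini_map()
  sc <- mini_scan(c(0.1, 1e-6, 1e-7, 1e-6, 0.2, 1e-6), map)
  q <- declare_qtls(sc, map, alpha = 5e-5, kind = "constitutive")
  expect_equal(nrow(q), 2L)
  expect_equal(q$peak_pos_cM, c(20, 50))
  expect_equal(q$ci_start_cM, c(10, 50))
  expect_equal(q$ci_end_cM, c(30, 50))
  expect_equal(q$p_peak, c(1e-7, 1e-6))
  expect_equal(q$n_markers, c(3L, 1L))
})

test_that("the significance threshold is strict and defaults to 5e-5", {
  map <- mini_map()
  sc <- mini_scan(c(5e-5, 1, 1, 1, 1, 1), map)
  expect_equal(nrow(declare_qtls(sc, map, kind = "constitutive")), 0L)
  sc2 <- mini_scan(c(4.999e-5, 1, 1, 1, 1, 1), map)
  expect_equal(nrow(declare_qtls(sc2, map, kind = "constitutive")), 1L)
  expect_error(declare_qtls(sc, map, alpha = 0, kind = "constitutive"),
               "alpha")
})

test_that("peak ties break toward the run midpoint then the lowest position", {
  map <- mini_map()
  sc <- mini_scan(c(1e-6, 1e-6, 1e-6, 1e-6, 1e-6, 0.5), map)
  q <- declare_qtls(sc, map, kind = "constitutive")
  # run spans 0-40, midpoint 20 -> m03 at 20 cM
  expect_equal(q$peak_marker, "m03")
  sc2 <- mini_scan(c(1e-6, 1e-6, 0.5, 1, 1, 1), map)
  q2 <- declare_qtls(sc2, map, kind = "constitutive")
  # midpoint 5, both at distance 5 -> lowest position wins
  expect_equal(q2$peak_marker, "m01")
})

test_that("runs never span chromosomes and kinds are scanned separately", {
  map <- mini_map(pos = c(0, 10, 0, 10), chrom = rep(c("c1", "c2"), each = 2))
  sc <- mini_scan(c(1e-6, 1e-6, 1e-6, 1e-6), map,
                  presp = c(1, 1, 1e-6, 1))
  q <- declare_qtls(sc, map, kind = "constitutive")
  expect_equal(nrow(q), 2L)
  expect_equal(q$chrom, c("c1", "c2"))
  qr <- declare_qtls(sc, map, kind = "responsive")
  expect_equal(nrow(qr), 1L)
  expect_equal(qr$peak_marker, "m03")
  expect_equal(nrow(declare_qtls(mini_scan(rep(0.5, 4), map), map,
                                 kind = "constitutive")), 0L)
})

make_lsm <- function(lines, values) {
  structure(data.frame(line = lines, lsmean = values,
                       stringsAsFactors = FALSE),
            class = c("ls_means", "data.frame"))
}

test_that("QTL r-squared equals the OLS difference-of-R2 oracle", {
  set.seed(10)
  n <- 20
  lines <- sprintf("L%02d", 1:n)
  x <- rep(c("A", "B"), each = n / 2)
  calls <- matrix(x, n, 1, dimnames = list(lines, "mk"))
  geno <- ril_genotypes(calls)
  xi <- ifelse(x == "A", 1, -1)
  yI <- 2 + 0.8 * xi + rnorm(n, sd = 0.6)
  yNI <- 1 + 0.8 * xi + 0.5 * xi + rnorm(n, sd = 0.6)
  lsI <- make_lsm(lines, yI)
  lsNI <- make_lsm(lines, yNI)
  qtl <- data.frame(peak_marker = "mk", kind = "constitutive")

  # independent OLS oracle via lm() R-squared differences
  d <- data.frame(y = c(yI, yNI), s = rep(c(0, 1), each = n),
                  x = rep(xi, 2))
  r2 <- function(f) summary(lm(f, data = d))$r.squared
  oracle_const <- 100 * (r2(y ~ s + x + s:x) - r2(y ~ s + s:x))
  oracle_resp <- 100 * (r2(y ~ s + x + s:x) - r2(y ~ s + x))
  expect_equal(qtl_r2(lsI, lsNI, geno, qtl), oracle_const,
               tolerance = 1e-8)
  qtl$kind <- "responsive"
  expect_equal(qtl_r2(lsI, lsNI, geno, qtl), oracle_resp, tolerance = 1e-8)

  # squared semipartial correlation of the dropped column
  mfull <- lm(y ~ s + x + s:x, data = d)
  mres <- lm(x ~ s + s:x, data = d)
  semi <- cor(resid(mres), d$y)^2
  qtl$kind <- "constitutive"
  expect_equal(qtl_r2(lsI, lsNI, geno, qtl) / 100, unname(semi),
               tolerance = 1e-8)
})

test_that("null markers explain essentially nothing on a 250-line panel", {
  set.seed(4)
  n <- 250
  lines <- sprintf("L%03d", 1:n)
  calls <- matrix(sample(c("A", "B"), n, TRUE), n, 1,
                  dimnames = list(lines, "mk"))
  geno <- ril_genotypes(calls)
  lsI <- make_lsm(lines, rnorm(n))
  lsNI <- make_lsm(lines, rnorm(n))
  for (k in c("constitutive", "responsive")) {
    r2 <- qtl_r2(lsI, lsNI, geno,
                 data.frame(peak_marker = "mk", kind = k))
    expect_lt(r2, 1)
    expect_gte(r2, 0)
  }
})

test_that("an allele pattern identical in both scenarios is purely constitutive", {
  n <- 40
  lines <- sprintf("L%02d", 1:n)
  x <- rep(c("A", "B"), n / 2)
  geno <- ril_genotypes(matrix(x, n, 1, dimnames = list(lines, "mk")))
  y <- ifelse(x == "A", 3, 1)  # value fixed by allele, same in both scenarios
  lsI <- make_lsm(lines, y)
  lsNI <- make_lsm(lines, y)
  rc <- qtl_r2(lsI, lsNI, geno,
               data.frame(peak_marker = "mk", kind = "constitutive"))
  rr <- qtl_r2(lsI, lsNI, geno,
               data.frame(peak_marker = "mk", kind = "responsive"))
  # the interaction column alone can absorb the NI half of the pattern, so
  # the constitutive share is 100 minus that interaction share (here 50)
  expect_equal(rc, 50, tolerance = 1e-8)
  expect_lt(rr, 1e-8)
  # and the full model is perfect: both shares bounded by 100
  expect_lte(rc + rr, 100 + 1e-8)
})

test_that("normalized effects follow the stated arithmetic and sign convention", {
  n <- 10
  lines <- sprintf("L%02d", 1:n)
  x <- rep(c("A", "B"), each = n / 2)
  geno <- ril_genotypes(matrix(x, n, 1, dimnames = list(lines, "mk")))
  # class means differ by 2 (7 vs 5), range max - min = 10
  y <- c(10, 6, 6, 6, 7, 0, 6, 6, 6, 7)
  lsa <- make_lsm(lines, y)
  qtl <- data.frame(peak_marker = "mk", kind = "constitutive")
  eff <- qtl_effect(geno, qtl, lsmeans_all = lsa)
  expect_equal(eff$normalized_effect, 0.2 / 1, tolerance = 1e-12)
  expect_equal(eff$favorable_parent, "A")

  # equal class means -> zero effect
  lsb <- make_lsm(lines, rep(c(2, 2), each = n / 2))
  expect_error(qtl_effect(geno, qtl, lsmeans_all = lsb), "zero range")
  lsc <- make_lsm(lines, c(1, 2, 3, 4, 5, 1, 2, 3, 4, 5))
  expect_equal(qtl_effect(geno, qtl,
                          lsmeans_all = lsc)$normalized_effect, 0)

  # relabeling alleles flips the sign
  flipped <- ril_genotypes(matrix(ifelse(x == "A", "B", "A"), n, 1,
                                  dimnames = list(lines, "mk")))
  eff2 <- qtl_effect(flipped, qtl, lsmeans_all = lsa)
  expect_equal(eff2$normalized_effect, -eff$normalized_effect)
  expect_equal(eff2$favorable_parent, "B")
})

test_that("responsive effects recover a planted interaction at low noise", {
  qt <- qtl_effects("c01_m010", additive_effect = 0, interaction_effect = 2)
  comps <- trial_components(mu = 30, sigma2_g = 2, sigma2_gy = 0.05,
                            sigma2_ge = 0.05, sigma2_bloc = 0.2,
                            sigma2_E = 0.3,
                            year_effects = c(`2013` = 0, `2014` = 1),
                            scenario_effects = c(I = 0, NI = -4))
  st <- small_trial(n_lines = 120, seed = 55, qtls = qt,
                    components = comps)
  bc <- correct_bloc_effects(st$trial$phenotypes, "trait")
  lsI <- lsmeans(bc$corrected, "trait", "I")
  lsNI <- lsmeans(bc$corrected, "trait", "NI")
  qtl <- data.frame(peak_marker = "c01_m010", kind = "responsive")
  eff <- qtl_effect(st$geno, qtl, lsmeans_I = lsI, lsmeans_NI = lsNI)
  # responses split by allele differ by 2 * 2 over an allele-driven range
  # of about 4: a strong positive normalized effect
  expect_gt(eff$normalized_effect, 0.4)
  resp <- lsNI$lsmean[match(lsI$line, lsNI$line)] - lsI$lsmean
  truth_eff <- 2 * 2 / (max(resp) - min(resp))
  expect_lt(abs(eff$normalized_effect - truth_eff) / truth_eff, 0.3)
})

test_that("cluster detection chains overlapping intervals per kind and chromosome", {
  qtls <- data.frame(
    trait = c("t1", "t2", "t3", "t4", "t5"),
    kind = "constitutive",
    chrom = "chr01",
    peak_marker = sprintf("m%d", 1:5),
    peak_pos_cM = c(20, 30, 45, 70, 90),
    ci_start_cM = c(10, 25, 38, 65, 85),
    ci_end_cM = c(30, 40, 50, 75, 95),
    p_peak = 1e-8, n_markers = 2L, r2_percent = NA_real_,
    normalized_effect = NA_real_, favorable_parent = NA_character_,
    stringsAsFactors = FALSE)
  cl <- cluster_qtls(qtls)
  # [10,30],[25,40],[38,50] chain into one cluster; [65,75] and [85,95] stay out
  expect_equal(nrow(cl$clusters), 1L)
  expect_equal(cl$clusters$n_qtls, 3L)
  expect_equal(cl$clusters$span_start_cM, 10)
  expect_equal(cl$clusters$span_end_cM, 50)
  expect_equal(sum(is.na(cl$members$cluster_id)), 2L)

  # touching endpoints count as overlap; same-trait pairs are not clusters
  q2 <- qtls[1:2, ]
  q2$ci_start_cM <- c(10, 20)
  q2$ci_end_cM <- c(20, 30)
  expect_equal(nrow(cluster_qtls(q2)$clusters), 1L)
  q2$trait <- "t1"
  expect_equal(nrow(cluster_qtls(q2)$clusters), 0L)

  # disjoint intervals and different chromosomes never cluster
  q3 <- qtls[1:2, ]
  q3$ci_start_cM <- c(10, 21)
  q3$ci_end_cM <- c(20, 30)
  expect_equal(nrow(cluster_qtls(q3)$clusters), 0L)
  q4 <- qtls[1:2, ]
  q4$chrom <- c("chr01", "chr02")
  expect_equal(nrow(cluster_qtls(q4)$clusters), 0L)

  # different kinds are clustered separately
  q5 <- qtls[1:2, ]
  q5$kind <- c("constitutive", "responsive")
  expect_equal(nrow(cluster_qtls(q5)$clusters), 0L)
})
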