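#' Describe a multi-year two-scenario augmented-bloc trial
#'
#' The default design emulates the field trial the package targets: three
#' years (15 blocs per scenario in the first year, 8 in the two following
#' years), two irrigation scenarios (`I` irrigated, `NI` non-irrigated), each
#' RIL planted once per bloc, and both parental lines replicated once in
#' every bloc as checks.
#'
#' @param years Integer vector of trial years.
#' @param blocs_per_year Named (by year) or recycled integer vector: number
#'   of blocs per (year, scenario).
#' @param scenarios Character vector of irrigation scenarios; the scan needs
#'   exactly `c("I", "NI")`.
#' @param check_lines Named character vector mapping check line ids to their
#'   fixed parental allele (`"A"` or `"B"`); checks are replicated once per
#'   bloc. Use `NULL` for a check-free design.
#' @param ril_blocs_per_year Optional named/recycled integer vector: number
#'   of blocs (out of `blocs_per_year`) in which each RIL appears per
#'   (year, scenario). Defaults to all blocs. When smaller, each RIL is
#'   assigned an independent random subset of blocs (field losses are not
#'   modeled beyond this).
#' @return A `trial_design` list.
#' @export
trial_design <- function(years = c(2013L, 2014L, 2015L),
                         blocs_per_year = c(`2013` = 15L, `2014` = 8L, `2015` = 8L),
                         scenarios = c("I", "NI"),
                         check_lines = c(F271 = "A", Cm484 = "B"),
                         ril_blocs_per_year = NULL) {
  if (length(years) < 1L) stop("need at least one year")
  if (!all(scenarios %in% c("I", "NI")) || anyDuplicated(scenarios))
    stop("`scenarios` must be a subset of c(\"I\", \"NI\") without duplicates")
  blocs <- normalize_per_year(blocs_per_year, years, "blocs_per_year")
  if (any(blocs < 1L)) stop("bloc counts must be positive")
  if (!is.null(check_lines)) {
    if (is.null(names(check_lines)) || !all(check_lines %in% c("A", "B")))
      stop("`check_lines` must be a named vector of parental alleles (A/B)")
  }
  if (!is.null(ril_blocs_per_year)) {
    ril_blocs_per_year <- normalize_per_year(ril_blocs_per_year, years,
                                             "ril_blocs_per_year")
    if (any(ril_blocs_per_year < 1L) || any(ril_blocs_per_year > blocs))
      stop("`ril_blocs_per_year` must be between 1 and the bloc count")
  }
  structure(list(years = as.integer(years), scenarios = scenarios,
                 blocs_per_year = blocs, check_lines = check_lines,
                 ril_blocs_per_year = ril_blocs_per_year),
            class = "trial_design")
}

normalize_per_year <- function(x, years, what) {
  if (is.null(names(x))) {
    x <- rep_len(as.integer(x), length(years))
    names(x) <- as.character(years)
  } else {
    miss <- setdiff(as.character(years), names(x))
    if (length(miss))
      stop("`", what, "` lacks entries for year(s): ",
           paste(miss, collapse = ", "))
    x <- as.integer(x[as.character(years)])
    names(x) <- as.character(years)
  }
  x
}

#' Generating components of the trial phenotypes
#'
#' Variances (squared trait units) and fixed shifts (trait units) used by
#' [simulate_trial_phenotypes()]. The defaults are sized like a plant-height
#' trait in the emulated trial: a strong genotypic component, a sizeable
#' water-deficit depression, moderate year effects, and small bloc and
#' interaction components.
#'
#' @param mu Intercept.
#' @param sigma2_g,sigma2_gy,sigma2_ge,sigma2_bloc,sigma2_E Variances of the
#'   line, line-by-year, line-by-scenario, bloc and residual components
#'   (all >= 0).
#' @param year_effects Named (by year) fixed year shifts; recycled if
#'   unnamed. Missing years default to 0.
#' @param scenario_effects Named fixed scenario shifts, e.g.
#'   `c(I = 0, NI = -22)`.
#' @param year_x_scenario Named fixed interaction shifts with names
#'   `"<year>:<scenario>"`; absent cells default to 0.
#' @return A `trial_components` list.
#' @export
trial_components <- function(mu = 138,
                             sigma2_g = 150, sigma2_gy = 20, sigma2_ge = 15,
                             sigma2_bloc = 10, sigma2_E = 40,
                             year_effects = c(`2013` = 0, `2014` = 3, `2015` = -3),
                             scenario_effects = c(I = 0, NI = -22),
                             year_x_scenario = NULL) {
  vars <- c(sigma2_g = sigma2_g, sigma2_gy = sigma2_gy, sigma2_ge = sigma2_ge,
            sigma2_bloc = sigma2_bloc, sigma2_E = sigma2_E)
  if (any(is.na(vars)) || any(vars < 0))
    stop("variance components must be non-negative")
  structure(list(mu = mu, sigma2_g = sigma2_g, sigma2_gy = sigma2_gy,
                 sigma2_ge = sigma2_ge, sigma2_bloc = sigma2_bloc,
                 sigma2_E = sigma2_E, year_effects = year_effects,
                 scenario_effects = scenario_effects,
                 year_x_scenario = year_x_scenario),
            class = "trial_components")
}

#' Planted QTL effects
#'
#' Ground-truth allele effects injected by the generator so that downstream
#' scans can be validated. `additive_effect` is the constitutive half
#' difference between homozygote classes (value added for the `A` allele and
#' subtracted for `B` in every scenario); `interaction_effect` is the
#' additional scenario-dependent allele effect applied in the `NI` scenario
#' only, i.e. a purely responsive component.
#'
#' @param anchor_marker Marker ids (must exist in the genotypes).
#' @param additive_effect,interaction_effect Numeric effects in trait units.
#' @return A `qtl_effects` data frame.
#' @export
qtl_effects <- function(anchor_marker, additive_effect = 0,
                        interaction_effect = 0) {
  out <- data.frame(anchor_marker = as.character(anchor_marker),
                    additive_effect = as.numeric(additive_effect),
                    interaction_effect = as.numeric(interaction_effect),
                    stringsAsFactors = FALSE)
  if (any(!is.finite(out$additive_effect)) ||
      any(!is.finite(out$interaction_effect)))
    stop("QTL effects must be finite")
  class(out) <- c("qtl_effects", "data.frame")
  out
}

fixed_cell_effect <- function(components, year, scenario) {
  ye <- components$year_effects
  se <- components$scenario_effects
  yse <- components$year_x_scenario
  y <- if (!is.null(ye) && as.character(year) %in% names(ye))
    ye[[as.character(year)]] else 0
  s <- if (!is.null(se) && scenario %in% names(se)) se[[scenario]] else 0
  key <- paste0(year, ":", scenario)
  ys <- if (!is.null(yse) && key %in% names(yse)) yse[[key]] else 0
  y + s + ys
}

#' Simulate plot-level trial phenotypes
#'
#' Generates one plot record per (line, year, scenario, bloc) according to
#' the design. Each value is
#' mu + year + scenario + year x scenario + bloc draw + line draw +
#' line x year draw + line x scenario draw + planted QTL terms + residual,
#' with all random draws independent zero-mean Gaussians at the stated
#' variances. The QTL term for a line with allele x (+1 for `A`, -1 for `B`)
#' at an anchor marker is `x * additive_effect`, plus `x * interaction_effect`
#' when the scenario is `NI`. Check lines receive no random genetic draws
#' (their genetic value is the fixed parental QTL sum), mirroring their
#' fixed-check role in the bloc-correction model.
#'
#' The generating truth (per-line draws, bloc effects, per-plot components)
#' is returned alongside the table for recovery tests.
#'
#' @param genotypes A `ril_geno`. QTL anchors must be non-missing; plant
#'   QTLs before [inject_missing()].
#' @param qtls A `qtl_effects` table or `NULL`.
#' @param design A `trial_design`.
#' @param components A `trial_components`.
#' @param seed Integer seed.
#' @param trait Name of the generated trait column.
#' @return A `ril_trial` list: `phenotypes` (data frame `line`, `year`,
#'   `scenario`, `bloc`, `is_check`, trait), and `truth` (components, QTLs,
#'   per-line effects `g`, `gy`, `ge`, `bloc_effects`, per-plot component
#'   columns).
#' @export
simulate_trial_phenotypes <- function(genotypes, qtls = NULL,
                                      design = trial_design(),
                                      components = trial_components(),
                                      seed = 1L, trait = "trait") {
  stopifnot(inherits(genotypes, "ril_geno"),
            inherits(design, "trial_design"),
            inherits(components, "trial_components"))
  lines <- genotypes$line_ids
  n <- length(lines)

  # planted QTL values per line (and per parent check), split by component
  qtl_add <- stats::setNames(numeric(n), lines)
  qtl_int <- stats::setNames(numeric(n), lines)
  if (!is.null(qtls) && nrow(qtls) > 0L) {
    miss <- setdiff(qtls$anchor_marker, genotypes$marker_ids)
    if (length(miss))
      stop("QTL anchor marker(s) absent from genotypes: ",
           paste(miss, collapse = ", "))
    for (q in seq_len(nrow(qtls))) {
      x <- allele_code(genotypes$calls[, qtls$anchor_marker[q]])
      if (anyNA(x))
        stop("missing genotype calls at QTL anchor ", qtls$anchor_marker[q],
             "; plant QTLs before injecting missingness")
      qtl_add <- qtl_add + x * qtls$additive_effect[q]
      qtl_int <- qtl_int + x * qtls$interaction_effect[q]
    }
  }
  checks <- design$check_lines
  chk_add <- chk_int <- numeric(0)
  if (!is.null(checks) && length(checks)) {
    xc <- ifelse(checks == "A", 1, -1)
    tot_add <- if (is.null(qtls)) 0 else sum(qtls$additive_effect)
    tot_int <- if (is.null(qtls)) 0 else sum(qtls$interaction_effect)
    chk_add <- stats::setNames(xc * tot_add, names(checks))
    chk_int <- stats::setNames(xc * tot_int, names(checks))
  }

  set.seed(as.integer(seed))
  years <- design$years
  scens <- design$scenarios
  g <- stats::setNames(stats::rnorm(n, 0, sqrt(components$sigma2_g)), lines)
  gy <- matrix(stats::rnorm(n * length(years), 0, sqrt(components$sigma2_gy)),
               n, length(years), dimnames = list(lines, as.character(years)))
  ge <- matrix(stats::rnorm(n * length(scens), 0, sqrt(components$sigma2_ge)),
               n, length(scens), dimnames = list(lines, scens))

  bloc_eff <- do.call(rbind, lapply(years, function(yy) {
    nb <- design$blocs_per_year[[as.character(yy)]]
    do.call(rbind, lapply(scens, function(ss) {
      data.frame(year = yy, scenario = ss, bloc = seq_len(nb),
                 effect = stats::rnorm(nb, 0, sqrt(components$sigma2_bloc)))
    }))
  }))

  # RIL bloc memberships (all blocs unless the design subsamples them)
  recs <- vector("list", length(years) * length(scens))
  ri <- 0L
  for (yy in years) {
    nb <- design$blocs_per_year[[as.character(yy)]]
    nr <- if (is.null(design$ril_blocs_per_year)) nb
          else design$ril_blocs_per_year[[as.character(yy)]]
    for (ss in scens) {
      if (nr == nb) {
        ril_rows <- data.frame(line = rep(lines, each = nb),
                               bloc = rep(seq_len(nb), n),
                               is_check = FALSE)
      } else {
        picks <- lapply(seq_len(n), function(i) sort(sample.int(nb, nr)))
        ril_rows <- data.frame(line = rep(lines, each = nr),
                               bloc = unlist(picks), is_check = FALSE)
      }
      chk_rows <- if (length(chk_add))
        data.frame(line = rep(names(chk_add), each = nb),
                   bloc = rep(seq_len(nb), length(chk_add)), is_check = TRUE)
      else NULL
      rows <- rbind(ril_rows, chk_rows)
      rows$year <- yy
      rows$scenario <- ss
      ri <- ri + 1L
      recs[[ri]] <- rows
    }
  }
  ph <- do.call(rbind, recs)
  ph <- ph[, c("line", "year", "scenario", "bloc", "is_check")]
  rownames(ph) <- NULL

  is_chk <- ph$is_check
  gv <- ifelse(is_chk, 0, g[ph$line])
  gyv <- ifelse(is_chk, 0,
                gy[cbind(match(ph$line, lines),
                         match(as.character(ph$year), colnames(gy)))])
  gev <- ifelse(is_chk, 0,
                ge[cbind(match(ph$line, lines), match(ph$scenario, scens))])
  gv[is.na(gv)] <- 0; gyv[is.na(gyv)] <- 0; gev[is.na(gev)] <- 0
  addv <- ifelse(is_chk, chk_add[ph$line], qtl_add[ph$line])
  intv <- ifelse(is_chk, chk_int[ph$line], qtl_int[ph$line])
  qtlv <- addv + ifelse(ph$scenario == "NI", intv, 0)
  bkey <- paste(ph$year, ph$scenario, ph$bloc)
  bv <- bloc_eff$effect[match(bkey, paste(bloc_eff$year, bloc_eff$scenario,
                                          bloc_eff$bloc))]
  fixedv <- mapply(fixed_cell_effect, ph$year, ph$scenario,
                   MoreArgs = list(components = components))
  resid <- stats::rnorm(nrow(ph), 0, sqrt(components$sigma2_E))

  ph[[trait]] <- components$mu + fixedv + bv + gv + gyv + gev + qtlv + resid

  truth <- list(components = components, qtls = qtls, design = design,
                g = g, gy = gy, ge = ge, bloc_effects = bloc_eff,
                plot_components = data.frame(fixed = fixedv, bloc = bv,
                                             genetic = gv, gxy = gyv,
                                             gxe = gev, qtl = qtlv,
                                             residual = resid))
  structure(list(phenotypes = ph, truth = truth, trait = trait),
            class = "ril_trial")
}

#' @method print ril_trial
#' @export
print.ril_trial <- function(x, ...) {
  ph <- x$phenotypes
  cat("Simulated trial:", nrow(ph), "plots;",
      length(unique(ph$line[!ph$is_check])), "RILs;",
      length(unique(ph$year)), "year(s) x",
      length(unique(ph$scenario)), "scenario(s); trait:", x$trait, "\n")
  invisible(x)
}
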