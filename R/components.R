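#' Estimate variance components from corrected phenotypes
#'
#' REML decomposition of bloc-corrected RIL phenotypes into line,
#' line x year, line x scenario and residual variances, with year, scenario
#' and their interaction fixed. Interaction terms whose factor has a single
#' level are dropped. Check rows are excluded. Negative estimates cannot
#' occur (REML is bounded at zero).
#'
#' @param corrected Bloc-corrected phenotype table (or raw table for designs
#'   without bloc structure).
#' @param trait Trait column name.
#' @return A `variance_components` list: `sigma2_g`, `sigma2_gy`,
#'   `sigma2_ge`, `sigma2_E`, plus design counts `k` (scenarios), `j`
#'   (years), `obs_per_line`, `n_lines`, and `diagnostics`.
#' @export
estimate_components <- function(corrected, trait) {
  check_phenotype_table(corrected, trait)
  df <- corrected[!corrected$is_check & !is.na(corrected[[trait]]), ,
                  drop = FALSE]
  if (length(unique(df$line)) < 2L)
    stop("need at least 2 RILs to estimate a genetic variance")
  df$.y <- df[[trait]]
  df$.line <- factor(df$line)
  df$.year <- factor(df$year)
  df$.scenario <- factor(df$scenario)
  j <- nlevels(df$.year)
  k <- nlevels(df$.scenario)
  if (j < 2L && k < 2L) {
    reps <- table(df$.line)
    if (max(reps) < 2L)
      stop("degenerate design: single year, single scenario and no ",
           "replication; genetic and residual variances are confounded")
  }
  cell <- paste(df$line, df$year, df$scenario)
  if (max(table(cell)) == 1L && j < 2L) {
    # single obs per cell and no year axis: ge and E confounded
    if (k >= 2L)
      stop("degenerate design: one observation per (line, scenario) cell ",
           "with a single year; line-by-scenario and residual variances ",
           "are not separable")
  }
  if (max(table(cell)) == 1L && k < 2L && j >= 2L)
    stop("degenerate design: one observation per (line, year) cell with a ",
         "single scenario; line-by-year and residual variances are not ",
         "separable")

  if (stats::var(df$.y) == 0) {
    out <- variance_components(0, 0, 0, 0, k = k, j = j,
                               obs_per_line = nrow(df) / nlevels(df$.line),
                               n_lines = nlevels(df$.line))
    return(out)
  }

  fixed <- c(if (j > 1L) ".year", if (k > 1L) ".scenario",
             if (j > 1L && k > 1L) ".year:.scenario")
  rand <- c("(1 | .line)",
            if (j > 1L) "(1 | .line:.year)",
            if (k > 1L) "(1 | .line:.scenario)")
  form <- stats::as.formula(paste(".y ~", paste(c(fixed, "1", rand),
                                                collapse = " + ")))
  diagnostics <- character(0)
  fit <- withCallingHandlers(
    lme4::lmer(form, data = df, REML = TRUE,
               control = lme4::lmerControl(calc.derivs = FALSE,
                                           check.nobs.vs.nlev = "ignore",
                                           check.nobs.vs.nRE = "ignore")),
    warning = function(w) {
      diagnostics <<- c(diagnostics, conditionMessage(w))
      invokeRestart("muffleWarning")
    },
    message = function(m) {
      diagnostics <<- c(diagnostics, conditionMessage(m))
      invokeRestart("muffleMessage")
    }
  )
  vc <- as.data.frame(lme4::VarCorr(fit))
  get <- function(g) {
    v <- vc$vcov[vc$grp == g]
    if (length(v)) v[1L] else 0
  }
  variance_components(sigma2_g = get(".line"),
                      sigma2_gy = get(".line:.year"),
                      sigma2_ge = get(".line:.scenario"),
                      sigma2_E = get("Residual"),
                      k = k, j = j,
                      obs_per_line = nrow(df) / nlevels(df$.line),
                      n_lines = nlevels(df$.line),
                      diagnostics = diagnostics)
}

#' Construct a variance-components object
#'
#' @param sigma2_g,sigma2_gy,sigma2_ge,sigma2_E Non-negative variances:
#'   line, line x year, line x scenario, residual.
#' @param k,j Number of irrigation scenarios and of years.
#' @param obs_per_line Average number of observations per line.
#' @param n_lines Number of lines (optional, for reporting).
#' @param diagnostics Optional character vector of fit messages.
#' @return A `variance_components` list.
#' @export
variance_components <- function(sigma2_g, sigma2_gy, sigma2_ge, sigma2_E,
                                k, j, obs_per_line, n_lines = NA_integer_,
                                diagnostics = character(0)) {
  vars <- c(sigma2_g, sigma2_gy, sigma2_ge, sigma2_E)
  if (any(is.na(vars)) || any(vars < 0))
    stop("variances must be non-negative")
  if (k < 1L || j < 1L || obs_per_line <= 0)
    stop("design counts must be positive")
  structure(list(sigma2_g = sigma2_g, sigma2_gy = sigma2_gy,
                 sigma2_ge = sigma2_ge, sigma2_E = sigma2_E,
                 k = k, j = j, obs_per_line = obs_per_line,
                 n_lines = n_lines, diagnostics = diagnostics),
            class = "variance_components")
}

#' @method print variance_components
#' @export
print.variance_components <- function(x, ...) {
  cat(sprintf(
    "Variance components: g=%.4g, gxy=%.4g, gxe=%.4g, E=%.4g (k=%d, j=%d, obs/i=%.2f)\n",
    x$sigma2_g, x$sigma2_gy, x$sigma2_ge, x$sigma2_E, x$k, x$j,
    x$obs_per_line))
  invisible(x)
}

#' Broad-sense heritability of line means
#'
#' h2 = sigma2_g / (sigma2_g + sigma2_ge / k + sigma2_gy / j +
#' sigma2_E / (obs/i)), the fraction of variance among RIL means across the
#' whole design attributable to genetic differences, given `k` scenarios,
#' `j` years and `obs/i` observations per line.
#'
#' @param vc A `variance_components` object.
#' @return Heritability in `[0, 1]`.
#' @examples
#' vc <- variance_components(4, 3, 2, 6, k = 2, j = 3, obs_per_line = 46)
#' broad_sense_heritability(vc)  # 4 / (4 + 1 + 1 + 6/46)
#' @export
broad_sense_heritability <- function(vc) {
  stopifnot(inherits(vc, "variance_components"))
  denom <- vc$sigma2_g + vc$sigma2_ge / vc$k + vc$sigma2_gy / vc$j +
    vc$sigma2_E / vc$obs_per_line
  if (denom <= 0)
    stop("heritability undefined: all variance components are zero")
  vc$sigma2_g / denom
}

#' Sequential ANOVA r-squared decomposition
#'
#' Percentage of the total sum of squares attributed to each term of the
#' variance model when all terms are entered as fixed effects, in the
#' sequential (type-I) order line, year, scenario, line x year,
#' line x scenario, year x scenario, plus the residual. Computed exactly via
#' a count-weighted regression on (line, year, scenario) cell means — every
#' model term is a function of the cell — with the within-cell sum of
#' squares folded into the residual. Entries sum to 100.
#'
#' @param corrected Bloc-corrected phenotype table (RIL rows are used).
#' @param trait Trait column name.
#' @return Data frame with columns `term` and `r2_percent`.
#' @export
anova_r2_table <- function(corrected, trait) {
  check_phenotype_table(corrected, trait)
  df <- corrected[!corrected$is_check & !is.na(corrected[[trait]]), ,
                  drop = FALSE]
  y <- df[[trait]]
  if (length(y) < 2L || stats::var(y) == 0)
    stop("zero total variance: the r-squared decomposition is undefined")
  df$.line <- factor(df$line)
  df$.year <- factor(df$year)
  df$.scenario <- factor(df$scenario)
  cell <- interaction(df$.line, df$.year, df$.scenario, drop = TRUE)
  agg <- data.frame(
    m = as.vector(tapply(y, cell, mean)),
    n = as.vector(table(cell))
  )
  first <- match(levels(cell), as.character(cell))
  agg$.line <- df$.line[first]
  agg$.year <- df$.year[first]
  agg$.scenario <- df$.scenario[first]
  within_ss <- sum((y - agg$m[match(as.character(cell), levels(cell))])^2)

  terms <- c(".line",
             if (nlevels(df$.year) > 1L) ".year",
             if (nlevels(df$.scenario) > 1L) ".scenario",
             if (nlevels(df$.year) > 1L) ".line:.year",
             if (nlevels(df$.scenario) > 1L) ".line:.scenario",
             if (nlevels(df$.year) > 1L && nlevels(df$.scenario) > 1L)
               ".year:.scenario")
  form <- stats::as.formula(paste("m ~", paste(terms, collapse = " + ")))
  fit <- stats::lm(form, data = agg, weights = agg$n)
  an <- stats::anova(fit)
  ss <- an[["Sum Sq"]]
  labels <- rownames(an)
  resid_ss <- ss[labels == "Residuals"] + within_ss
  term_ss <- ss[labels != "Residuals"]
  term_labels <- labels[labels != "Residuals"]
  pretty <- c(.line = "genetic", .year = "year", .scenario = "scenario",
              `.line:.year` = "genetic_x_year",
              `.line:.scenario` = "genetic_x_scenario",
              `.year:.scenario` = "year_x_scenario")
  total <- sum(term_ss) + resid_ss
  out <- data.frame(term = c(unname(pretty[term_labels]), "residual"),
                    r2_percent = 100 * c(term_ss, resid_ss) / total,
                    stringsAsFactors = FALSE)
  # report in the conventional table order
  ord <- c("genetic", "scenario", "genetic_x_scenario", "year",
           "genetic_x_year", "year_x_scenario", "residual")
  out <- out[order(match(out$term, ord)), , drop = FALSE]
  rownames(out) <- NULL
  out
}
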