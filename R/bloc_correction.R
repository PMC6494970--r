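#' Correct plot phenotypes by subtracting bloc BLUPs
#'
#' Fits the plot-level mixed model with fixed check effects and fixed year,
#' scenario and year x scenario terms; random RIL genetic effects (entering
#' only for non-check rows), random line x year and line x scenario
#' interactions, and random bloc effects nested in (year, scenario). The
#' best linear unbiased predictions (BLUPs) of the bloc effects are then
#' subtracted from every plot value, removing the field-bloc environmental
#' component while leaving all keys and the row count untouched.
#'
#' Terms involving a single-level factor (one year, one scenario, or no
#' checks) are dropped automatically. Fitting is REML via \pkg{lme4}.
#'
#' @param table Plot-level phenotype data frame with columns `line`, `year`,
#'   `scenario`, `bloc`, `is_check` and the trait.
#' @param trait Name of the trait column to correct.
#' @return A `bloc_correction` list: `blups` (data frame `year`, `scenario`,
#'   `bloc`, `blup`), `corrected` (the input table with the trait replaced by
#'   its corrected value), `varcomp` (named variances from the fit) and
#'   `diagnostics` (convergence messages, if any).
#' @export
correct_bloc_effects <- function(table, trait) {
  check_phenotype_table(table, trait)
  df <- table[!is.na(table[[trait]]), , drop = FALSE]
  df$bloc_id <- factor(paste(df$year, df$scenario, df$bloc, sep = ":"))
  if (nlevels(df$bloc_id) < 2L)
    stop("bloc correction needs at least 2 blocs; found ",
         nlevels(df$bloc_id))
  df$.y <- df[[trait]]
  df$.line <- factor(df$line)
  df$.year <- factor(df$year)
  df$.scenario <- factor(df$scenario)
  df$.ril <- as.numeric(!df$is_check)
  df$.check <- factor(ifelse(df$is_check, as.character(df$line), ".ril"))
  df$.check <- stats::relevel(df$.check, ref = ".ril")

  fixed <- c(if (nlevels(df$.check) > 1L) ".check",
             if (nlevels(df$.year) > 1L) ".year",
             if (nlevels(df$.scenario) > 1L) ".scenario",
             if (nlevels(df$.year) > 1L && nlevels(df$.scenario) > 1L)
               ".year:.scenario")
  rand <- c("(0 + .ril | .line)",
            if (nlevels(df$.year) > 1L) "(0 + .ril | .line:.year)",
            if (nlevels(df$.scenario) > 1L) "(0 + .ril | .line:.scenario)",
            "(1 | bloc_id)")
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
  if (length(diagnostics))
    warning("bloc-correction fit raised diagnostics: ",
            paste(unique(diagnostics), collapse = "; "))

  re <- lme4::ranef(fit)$bloc_id
  blup <- stats::setNames(re[["(Intercept)"]], rownames(re))
  parts <- do.call(rbind, strsplit(names(blup), ":", fixed = TRUE))
  blups <- data.frame(year = utils::type.convert(parts[, 1L], as.is = TRUE),
                      scenario = parts[, 2L],
                      bloc = utils::type.convert(parts[, 3L], as.is = TRUE),
                      blup = unname(blup), stringsAsFactors = FALSE)

  corrected <- table
  key <- paste(table$year, table$scenario, table$bloc, sep = ":")
  adj <- blup[key]
  adj[is.na(adj)] <- 0  # blocs with no usable data keep raw values
  corrected[[trait]] <- table[[trait]] - adj

  vc <- as.data.frame(lme4::VarCorr(fit))
  varcomp <- stats::setNames(vc$vcov, vc$grp)
  structure(list(blups = blups, corrected = corrected, varcomp = varcomp,
                 trait = trait, diagnostics = diagnostics),
            class = "bloc_correction")
}

#' @method print bloc_correction
#' @export
print.bloc_correction <- function(x, ...) {
  cat("Bloc correction for trait", shQuote(x$trait), "-",
      nrow(x$blups), "bloc BLUPs, SD",
      sprintf("%.4g", stats::sd(x$blups$blup)), "\n")
  invisible(x)
}

check_phenotype_table <- function(table, trait = NULL) {
  need <- c("line", "year", "scenario", "bloc", "is_check")
  miss <- setdiff(need, names(table))
  if (length(miss))
    stop("phenotype table is missing column(s): ",
         paste(miss, collapse = ", "))
  bad <- setdiff(unique(table$scenario), c("I", "NI"))
  if (length(bad))
    stop("unknown scenario code(s): ", paste(shQuote(bad), collapse = ", "))
  if (!is.null(trait)) {
    if (!trait %in% names(table))
      stop("trait column ", shQuote(trait), " not found")
    if (!is.numeric(table[[trait]]))
      stop("trait column ", shQuote(trait), " is not numeric")
    if (any(is.infinite(table[[trait]])))
      stop("trait column ", shQuote(trait), " contains non-finite values")
  }
  invisible(table)
}
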