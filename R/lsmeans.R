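#' Least-square means of RILs
#'
#' Model-adjusted per-line means on bloc-corrected data (checks excluded).
#' With `scope = "all"` the model is a fixed-effects linear model with line,
#' year, scenario and year x scenario terms, and the ls-mean averages the
#' predictions over the full year x scenario grid. With `scope = "I"` or
#' `"NI"` the data are first subset to that scenario and the model contains
#' line and year only. On a fully balanced design the ls-mean equals the
#' per-line arithmetic mean.
#'
#' Terms with a single level are dropped. Lines with no usable observation
#' in the (sub)dataset receive no ls-mean; their ids are reported in the
#' `dropped` attribute.
#'
#' @param corrected Bloc-corrected phenotype table.
#' @param trait Trait column name.
#' @param scope `"all"`, `"I"` or `"NI"`.
#' @return An `ls_means` data frame with columns `line` and `lsmean`,
#'   attributes `scope` and `dropped`.
#' @export
lsmeans <- function(corrected, trait, scope = c("all", "I", "NI")) {
  scope <- match.arg(scope)
  check_phenotype_table(corrected, trait)
  df <- corrected[!corrected$is_check, , drop = FALSE]
  if (scope == "all") {
    if (length(unique(df$scenario)) < 2L)
      stop("scope 'all' requires both irrigation scenarios in the data")
  } else {
    df <- df[df$scenario == scope, , drop = FALSE]
  }
  all_lines <- unique(df$line)
  df <- df[!is.na(df[[trait]]), , drop = FALSE]
  if (nrow(df) == 0L) stop("no usable observations for trait ", shQuote(trait))
  dropped <- setdiff(all_lines, unique(df$line))

  df$.y <- df[[trait]]
  df$.line <- factor(df$line)
  df$.year <- factor(df$year)
  df$.scenario <- factor(df$scenario)
  terms <- c(".line", if (nlevels(df$.year) > 1L) ".year")
  if (scope == "all") {
    terms <- c(terms, if (nlevels(df$.scenario) > 1L) ".scenario",
               if (nlevels(df$.year) > 1L && nlevels(df$.scenario) > 1L)
                 ".year:.scenario")
  }
  form <- stats::as.formula(paste(".y ~", paste(terms, collapse = " + ")))
  fit <- stats::lm(form, data = df)
  em <- emmeans::emmeans(fit, ".line")
  es <- summary(em)
  out <- data.frame(line = as.character(es$.line), lsmean = es$emmean,
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  structure(out, scope = scope, dropped = dropped,
            class = c("ls_means", "data.frame"))
}
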