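#' Percent response to the non-irrigated scenario
#'
#' The magnitude of the change from the irrigated (I) to the non-irrigated
#' (NI) mean, as a percentage of the irrigated mean:
#' 100 * |mean_NI - mean_I| / mean_I. With `signed = TRUE` the sign of the
#' change is kept (negative for a reduction under NI). Scale-invariant:
#' multiplying both means by the same positive constant leaves it unchanged.
#'
#' @param mean_I,mean_NI Trait means under the two scenarios (vectorized);
#'   `mean_I` must be non-zero.
#' @param signed Keep the direction of the response (default `FALSE`).
#' @param digits Optional rounding of the returned percentage (reports in
#'   the field conventionally use one decimal).
#' @return Percent response(s).
#' @examples
#' percent_response(3.83, 2.43, digits = 1)  # 36.6
#' @export
percent_response <- function(mean_I, mean_NI, signed = FALSE, digits = NULL) {
  if (any(is.na(mean_I)) || any(is.na(mean_NI)))
    stop("means must be non-missing")
  if (any(mean_I == 0))
    stop("percent response is undefined when the irrigated mean is 0")
  out <- 100 * (mean_NI - mean_I) / mean_I
  if (!signed) out <- abs(out)
  if (!is.null(digits)) out <- round(out, digits)
  out
}

#' Per-scenario Pearson correlation matrix of traits
#'
#' Pairwise-complete Pearson correlations between trait columns. Traits with
#' zero variance get `NA` rows/columns and are reported in the `degenerate`
#' attribute. The diagonal is exactly 1 for non-degenerate traits.
#'
#' @param data Data frame of per-line values (e.g. ls-means in one
#'   scenario).
#' @param traits Character vector of trait column names (>= 2).
#' @return Symmetric correlation matrix with a `degenerate` attribute.
#' @export
correlation_matrix <- function(data, traits) {
  miss <- setdiff(traits, names(data))
  if (length(miss))
    stop("trait column(s) not found: ", paste(miss, collapse = ", "))
  x <- as.matrix(data[, traits, drop = FALSE])
  if (nrow(x) < 3L)
    stop("need at least 3 lines to compute correlations")
  sds <- apply(x, 2L, stats::sd, na.rm = TRUE)
  degenerate <- traits[is.na(sds) | sds == 0]
  cm <- suppressWarnings(stats::cor(x, use = "pairwise.complete.obs"))
  if (length(degenerate)) {
    cm[degenerate, ] <- NA_real_
    cm[, degenerate] <- NA_real_
  }
  dg <- diag(cm)
  dg[!(traits %in% degenerate)] <- 1
  diag(cm) <- dg
  attr(cm, "degenerate") <- degenerate
  cm
}

#' Principal component analysis of trait data
#'
#' PCA of centered, unit-variance-scaled trait columns (eigen-decomposition
#' of the correlation matrix), the usual first step for reducing a battery
#' of correlated cell-wall traits. Rows with any missing trait are dropped.
#' The percent variance of component h is 100 * eigenvalue_h / n_traits, so
#' the full set sums to 100. Component signs follow a fixed convention: the
#' largest-magnitude loading of each component is positive.
#'
#' @param data Data frame of observations (plot-level corrected values or
#'   per-line summaries).
#' @param traits Character vector of trait columns (>= 2).
#' @param group Optional name of a grouping column (e.g. `scenario`) carried
#'   into the scores for plotting/inspection.
#' @return A `trait_pca` list: `loadings` (traits x components), `scores`
#'   (rows x components), `percent_variance`, and optionally `groups`.
#' @export
pca_traits <- function(data, traits, group = NULL) {
  miss <- setdiff(traits, names(data))
  if (length(miss))
    stop("trait column(s) not found: ", paste(miss, collapse = ", "))
  if (length(traits) < 2L) stop("PCA needs at least 2 traits")
  keep <- stats::complete.cases(data[, traits, drop = FALSE])
  x <- as.matrix(data[keep, traits, drop = FALSE])
  if (nrow(x) <= length(traits))
    stop("PCA needs more complete observations than traits (",
         nrow(x), " vs ", length(traits), ")")
  sds <- apply(x, 2L, stats::sd)
  if (any(sds == 0))
    stop("constant trait column(s): ",
         paste(traits[sds == 0], collapse = ", "))
  pr <- stats::prcomp(x, center = TRUE, scale. = TRUE)
  load <- pr$rotation
  scores <- pr$x
  for (h in seq_len(ncol(load))) {
    if (load[which.max(abs(load[, h])), h] < 0) {
      load[, h] <- -load[, h]
      scores[, h] <- -scores[, h]
    }
  }
  out <- list(loadings = load, scores = scores,
              percent_variance = 100 * pr$sdev^2 / length(traits),
              n_used = nrow(x))
  if (!is.null(group)) out$groups <- data[[group]][keep]
  class(out) <- "trait_pca"
  out
}

#' @method print trait_pca
#' @export
print.trait_pca <- function(x, ...) {
  pv <- x$percent_variance
  cat("Trait PCA:", nrow(x$loadings), "traits,", x$n_used, "observations\n")
  cat("  % variance:", paste(sprintf("%.2f", pv[seq_len(min(3, length(pv)))]),
                             collapse = ", "),
      if (length(pv) > 3) "...\n" else "\n")
  invisible(x)
}

#' Van Soest derived fiber fractions
#'
#' Cellulose and hemicellulose contents, as percent of the neutral detergent
#' fiber (NDF), from the sequential Van Soest fractions:
#' CL.NDF = 100 * (ADF - ADL) / NDF and HC.NDF = 100 * (NDF - ADF) / NDF,
#' where ADF is acid detergent fiber and ADL acid detergent lignin.
#'
#' @param NDF,ADF,ADL Fiber fractions in percent of dry matter (vectorized);
#'   biochemistry requires NDF >= ADF >= ADL >= 0 and NDF > 0.
#' @return Data frame with columns `CL.NDF` and `HC.NDF` (percent of NDF).
#' @examples
#' vansoest_derived(50, 30, 5)  # CL.NDF 50, HC.NDF 40
#' @export
vansoest_derived <- function(NDF, ADF, ADL) {
  n <- max(length(NDF), length(ADF), length(ADL))
  NDF <- rep_len(NDF, n); ADF <- rep_len(ADF, n); ADL <- rep_len(ADL, n)
  if (any(is.na(c(NDF, ADF, ADL))))
    stop("fiber fractions must be non-missing")
  if (any(NDF <= 0)) stop("NDF must be > 0")
  bad <- which(!(NDF >= ADF & ADF >= ADL & ADL >= 0))
  if (length(bad))
    stop("impossible fiber ordering (need NDF >= ADF >= ADL >= 0) at ",
         "position(s): ", paste(bad, collapse = ", "))
  data.frame(CL.NDF = 100 * (ADF - ADL) / NDF,
             HC.NDF = 100 * (NDF - ADF) / NDF)
}
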