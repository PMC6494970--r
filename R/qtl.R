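#' Declare QTLs from a marker scan
#'
#' Per chromosome, maximal runs of map-adjacent markers whose p-value for
#' the chosen kind is strictly below `alpha` form one QTL each; a single
#' non-significant marker terminates a run. The confidence interval spans
#' the positions of the run's first and last markers; the peak is the run's
#' minimum p-value, ties resolved toward the marker closest to the run's
#' positional midpoint, then toward the lowest position.
#'
#' The default threshold reads the conventional "p-value inferior to
#' 0.005 percent" rule literally: alpha = 5e-5, strict inequality (a
#' p-value exactly equal to alpha is not significant). Note 0.005 percent
#' is 5e-5, not 0.005.
#'
#' @param results A `marker_scan` (from [scan_markers()]).
#' @param map The `genetic_map` the scan was run on.
#' @param alpha Significance threshold in (0, 1); default `5e-5`.
#' @param kind `"constitutive"` (uses `p_const`) or `"responsive"`
#'   (`p_resp`).
#' @return A `qtl_table` data frame: `trait`, `kind`, `chrom`,
#'   `peak_marker`, `peak_pos_cM`, `ci_start_cM`, `ci_end_cM`, `p_peak`,
#'   `n_markers`, plus `r2_percent`, `normalized_effect` and
#'   `favorable_parent` columns initialized to `NA` (filled by [qtl_r2()] /
#'   [qtl_effect()]), ordered by (trait, chrom, ci_start_cM).
#' @export
declare_qtls <- function(results, map, alpha = 5e-5,
                         kind = c("constitutive", "responsive")) {
  kind <- match.arg(kind)
  if (length(alpha) != 1L || is.na(alpha) || alpha <= 0 || alpha >= 1)
    stop("`alpha` must be in (0, 1)")
  pcol <- if (kind == "constitutive") "p_const" else "p_resp"
  res <- results[order(match(results$marker, map$marker)), , drop = FALSE]
  empty <- data.frame(trait = character(0), kind = character(0),
                      chrom = character(0), peak_marker = character(0),
                      peak_pos_cM = numeric(0), ci_start_cM = numeric(0),
                      ci_end_cM = numeric(0), p_peak = numeric(0),
                      n_markers = integer(0), r2_percent = numeric(0),
                      normalized_effect = numeric(0),
                      favorable_parent = character(0),
                      stringsAsFactors = FALSE)
  out <- empty
  for (cc in unique(res$chrom)) {
    sub <- res[res$chrom == cc, , drop = FALSE]
    sig <- !is.na(sub[[pcol]]) & sub[[pcol]] < alpha
    if (!any(sig)) next
    r <- rle(sig)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    for (b in which(r$values)) {
      idx <- starts[b]:ends[b]
      run <- sub[idx, , drop = FALSE]
      pmin_ <- min(run[[pcol]])
      tied <- which(run[[pcol]] == pmin_)
      mid <- (run$pos_cM[1L] + run$pos_cM[nrow(run)]) / 2
      tied <- tied[order(abs(run$pos_cM[tied] - mid), run$pos_cM[tied])]
      peak <- tied[1L]
      out <- rbind(out, data.frame(
        trait = run$trait[1L], kind = kind, chrom = cc,
        peak_marker = run$marker[peak], peak_pos_cM = run$pos_cM[peak],
        ci_start_cM = run$pos_cM[1L], ci_end_cM = run$pos_cM[nrow(run)],
        p_peak = pmin_, n_markers = nrow(run), r2_percent = NA_real_,
        normalized_effect = NA_real_, favorable_parent = NA_character_,
        stringsAsFactors = FALSE))
    }
  }
  out <- out[order(out$trait, out$chrom, out$ci_start_cM), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("qtl_table", "data.frame")
  out
}

qtl_model_matrices <- function(lsmeans_I, lsmeans_NI, genotypes, marker) {
  if (!marker %in% genotypes$marker_ids)
    stop("peak marker ", shQuote(marker), " absent from genotypes")
  lines <- intersect(lsmeans_I$line, lsmeans_NI$line)
  x <- allele_code(genotypes$calls[, marker])[match(lines,
                                                   genotypes$line_ids)]
  keep <- !is.na(x)
  lines <- lines[keep]; x <- x[keep]
  if (length(lines) < 4L)
    stop("too few genotyped lines with ls-means at marker ", shQuote(marker))
  yI <- lsmeans_I$lsmean[match(lines, lsmeans_I$line)]
  yNI <- lsmeans_NI$lsmean[match(lines, lsmeans_NI$line)]
  list(lines = lines, x = x, yI = yI, yNI = yNI)
}

#' Percent variance explained by a QTL
#'
#' Stacks the per-scenario ls-means of the genotyped lines and fits the
#' fixed-effects single-marker model with scenario, marker and
#' marker x scenario terms at the QTL's peak marker. The QTL's r-squared is
#' the drop in the model R-squared when its defining term is removed:
#' the marker main effect for a constitutive QTL, the marker x scenario
#' interaction for a responsive QTL. Equals the squared semipartial
#' correlation of the removed column.
#'
#' @param lsmeans_I,lsmeans_NI Per-scenario `ls_means` (scope `"I"`/`"NI"`).
#' @param genotypes A `ril_geno`.
#' @param qtl One-row subset of a `qtl_table` (or a list with
#'   `peak_marker` and `kind`).
#' @return r-squared as a percentage.
#' @export
qtl_r2 <- function(lsmeans_I, lsmeans_NI, genotypes, qtl) {
  mm <- qtl_model_matrices(lsmeans_I, lsmeans_NI, genotypes,
                           qtl$peak_marker[1L])
  n <- length(mm$lines)
  y <- c(mm$yI, mm$yNI)
  sni <- rep(c(0, 1), each = n)
  x <- rep(mm$x, 2L)
  X_full <- cbind(1, sni, x, x * sni)
  if (qr(X_full)$rank < ncol(X_full))
    stop("single-marker model is collinear at marker ",
         shQuote(qtl$peak_marker[1L]),
         " (an allele class may be empty in one scenario)")
  r2 <- function(X) {
    fit <- stats::lm.fit(X, y)
    1 - sum(fit$residuals^2) / sum((y - mean(y))^2)
  }
  full <- r2(X_full)
  red <- if (qtl$kind[1L] == "constitutive")
    r2(X_full[, -3L, drop = FALSE]) else r2(X_full[, -4L, drop = FALSE])
  100 * (full - red)
}

#' Normalized allele effect of a QTL
#'
#' For a constitutive QTL: the difference between the two parental
#' allele-class means of the joint ls-means, divided by the range
#' (max - min) of the joint ls-means over the RIL progeny. For a responsive
#' QTL: the per-line scenario response is ls-mean(NI) - ls-mean(I); the
#' effect is the allele-class difference of mean responses divided by the
#' range of per-line responses. Positive values mean the `A` (F271-type)
#' allele increases the trait (or its response); the magnitude is at most 1
#' by construction. The favorable parent is the allele class with the
#' higher mean.
#'
#' @param genotypes A `ril_geno`.
#' @param qtl One-row `qtl_table` subset (uses `peak_marker` and `kind`).
#' @param lsmeans_all Joint-scope `ls_means` (required for constitutive
#'   QTLs).
#' @param lsmeans_I,lsmeans_NI Per-scenario `ls_means` (required for
#'   responsive QTLs).
#' @return A list: `normalized_effect` (signed, dimensionless) and
#'   `favorable_parent` (`"A"` or `"B"` class label).
#' @export
qtl_effect <- function(genotypes, qtl, lsmeans_all = NULL,
                       lsmeans_I = NULL, lsmeans_NI = NULL) {
  kind <- qtl$kind[1L]
  marker <- qtl$peak_marker[1L]
  if (kind == "constitutive") {
    if (is.null(lsmeans_all))
      stop("constitutive effects need joint-scope ls-means (`lsmeans_all`)")
    x <- allele_code(genotypes$calls[, marker])[match(lsmeans_all$line,
                                                      genotypes$line_ids)]
    y <- lsmeans_all$lsmean
  } else {
    if (is.null(lsmeans_I) || is.null(lsmeans_NI))
      stop("responsive effects need per-scenario ls-means")
    mm <- qtl_model_matrices(lsmeans_I, lsmeans_NI, genotypes, marker)
    x <- mm$x
    y <- mm$yNI - mm$yI
  }
  keep <- !is.na(x) & !is.na(y)
  x <- x[keep]; y <- y[keep]
  if (!any(x == 1) || !any(x == -1))
    stop("an allele class is empty at marker ", shQuote(marker))
  rng <- max(y) - min(y)
  if (rng == 0)
    stop("zero range: the normalized effect is undefined")
  eff <- (mean(y[x == 1]) - mean(y[x == -1])) / rng
  list(normalized_effect = eff,
       favorable_parent = if (eff >= 0) "A" else "B")
}

#' Annotate declared QTLs with r-squared and normalized effects
#'
#' Convenience wrapper filling the `r2_percent`, `normalized_effect` and
#' `favorable_parent` columns of a `qtl_table` using [qtl_r2()] and
#' [qtl_effect()].
#'
#' @param qtls A `qtl_table`.
#' @param genotypes A `ril_geno`.
#' @param lsmeans_all,lsmeans_I,lsmeans_NI `ls_means` at the scopes needed
#'   by the QTL kinds present.
#' @return The annotated `qtl_table`.
#' @export
annotate_qtls <- function(qtls, genotypes, lsmeans_all = NULL,
                          lsmeans_I = NULL, lsmeans_NI = NULL) {
  if (!nrow(qtls)) return(qtls)
  for (i in seq_len(nrow(qtls))) {
    q <- qtls[i, , drop = FALSE]
    qtls$r2_percent[i] <- qtl_r2(lsmeans_I, lsmeans_NI, genotypes, q)
    eff <- qtl_effect(genotypes, q, lsmeans_all = lsmeans_all,
                      lsmeans_I = lsmeans_I, lsmeans_NI = lsmeans_NI)
    qtls$normalized_effect[i] <- eff$normalized_effect
    qtls$favorable_parent[i] <- eff$favorable_parent
  }
  qtls
}

#' Cluster co-localizing QTLs across traits
#'
#' Single-linkage grouping of same-kind QTLs on the same chromosome whose
#' confidence intervals overlap (closed intervals; touching endpoints count
#' as overlap). Groups with at least two members from at least two distinct
#' traits are reported as clusters; all other QTLs are singletons.
#'
#' @param qtls A `qtl_table` (may mix kinds; each kind is clustered
#'   separately unless `kind` is given).
#' @param kind Optional `"constitutive"` or `"responsive"` filter.
#' @return A list: `clusters` (data frame `cluster_id`, `kind`, `chrom`,
#'   `n_qtls`, `n_traits`, `traits`, `span_start_cM`, `span_end_cM`) and
#'   `members` (the input rows with a `cluster_id` column, `NA` for
#'   singletons).
#' @export
cluster_qtls <- function(qtls, kind = NULL) {
  if (!is.null(kind)) qtls <- qtls[qtls$kind == kind, , drop = FALSE]
  members <- qtls
  members$cluster_id <- rep(NA_character_, nrow(qtls))
  clusters <- data.frame(cluster_id = character(0), kind = character(0),
                         chrom = character(0), n_qtls = integer(0),
                         n_traits = integer(0), traits = character(0),
                         span_start_cM = numeric(0), span_end_cM = numeric(0),
                         stringsAsFactors = FALSE)
  if (!nrow(qtls)) return(list(clusters = clusters, members = members))
  cid <- 0L
  for (kk in unique(qtls$kind)) {
    for (cc in unique(qtls$chrom[qtls$kind == kk])) {
      idx <- which(qtls$kind == kk & qtls$chrom == cc)
      idx <- idx[order(qtls$ci_start_cM[idx], qtls$ci_end_cM[idx])]
      group <- list()
      cur <- idx[1L]
      cur_end <- qtls$ci_end_cM[idx[1L]]
      for (i in idx[-1L]) {
        if (qtls$ci_start_cM[i] <= cur_end) {
          cur <- c(cur, i)
          cur_end <- max(cur_end, qtls$ci_end_cM[i])
        } else {
          group[[length(group) + 1L]] <- cur
          cur <- i
          cur_end <- qtls$ci_end_cM[i]
        }
      }
      group[[length(group) + 1L]] <- cur
      for (g in group) {
        traits <- unique(qtls$trait[g])
        if (length(g) >= 2L && length(traits) >= 2L) {
          cid <- cid + 1L
          id <- sprintf("%d-%s", cid, substr(kk, 1L, 5L))
          members$cluster_id[g] <- id
          clusters <- rbind(clusters, data.frame(
            cluster_id = id, kind = kk, chrom = cc, n_qtls = length(g),
            n_traits = length(traits),
            traits = paste(sort(traits), collapse = ","),
            span_start_cM = min(qtls$ci_start_cM[g]),
            span_end_cM = max(qtls$ci_end_cM[g]),
            stringsAsFactors = FALSE))
        }
      }
    }
  }
  list(clusters = clusters, members = members)
}
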