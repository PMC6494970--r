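#' Per-marker mixed-model scan for constitutive and responsive effects
#'
#' For each marker, fits the single-marker mixed model on bloc-corrected
#' phenotypes: fixed year, scenario and year x scenario effects, a fixed
#' marker main effect (allele coded +1 for `A`/F271-type, -1 for
#' `B`/Cm484-type), a fixed marker x scenario interaction (the allele effect
#' added in the non-irrigated scenario), and a random residual polygenic
#' line effect. Two p-values are produced per marker by likelihood-ratio
#' tests between nested maximum-likelihood fits (1-df chi-square):
#' `p_const` for the marker main effect (constitutive signal, tested with
#' the interaction retained) and `p_resp` for the marker x scenario
#' interaction (responsive signal).
#'
#' Observations are first averaged to (line, year, scenario) cell means:
#' the scan model contains no bloc term, so within-cell replicates carry no
#' marker information beyond their mean. Lines missing the genotype at a
#' marker are dropped for that marker only. A marker with fewer than two
#' allele classes after dropping is flagged untestable with p-values of 1.
#'
#' @param corrected Bloc-corrected phenotype table (checks are excluded).
#' @param genotypes A `ril_geno` covering the phenotyped lines.
#' @param map A `genetic_map` covering the genotyped markers.
#' @param trait Trait column name.
#' @return A `marker_scan` data frame: `trait`, `marker`, `chrom`, `pos_cM`,
#'   `p_const`, `p_resp`, `n_lines`, `untestable`, and allele-class means
#'   per scenario (`mean_A_I`, `mean_A_NI`, `mean_B_I`, `mean_B_NI`).
#' @export
scan_markers <- function(corrected, genotypes, map, trait) {
  check_phenotype_table(corrected, trait)
  stopifnot(inherits(genotypes, "ril_geno"))
  validate_genetic_map(map)
  markers <- intersect(map$marker, genotypes$marker_ids)
  if (!length(markers))
    stop("no genotyped marker is present on the map")

  df <- corrected[!corrected$is_check & !is.na(corrected[[trait]]), ,
                  drop = FALSE]
  df <- df[df$line %in% genotypes$line_ids, , drop = FALSE]
  if (!nrow(df))
    stop("no phenotyped line matches the genotype matrix")
  if (length(unique(df$scenario)) < 2L)
    stop("the scan needs both irrigation scenarios")

  # (line, year, scenario) cell means
  key <- paste(df$line, df$year, df$scenario, sep = "\r")
  m <- tapply(df[[trait]], key, mean)
  parts <- do.call(rbind, strsplit(names(m), "\r", fixed = TRUE))
  agg <- data.frame(line = parts[, 1L], year = parts[, 2L],
                    scenario = parts[, 3L], y = as.vector(m),
                    stringsAsFactors = FALSE)

  rot <- make_line_rotation(agg$line)
  agg_o <- agg[rot$order, , drop = FALSE]
  yearf <- factor(agg_o$year)
  scenf <- factor(agg_o$scenario, levels = c("I", "NI"))
  Xb <- if (nlevels(yearf) > 1L)
    stats::model.matrix(~ yearf * scenf) else stats::model.matrix(~ scenf)
  Xb_r <- rot$rotate(Xb)
  y_r <- drop(rot$rotate(matrix(agg_o$y, ncol = 1L)))
  one_r <- drop(rot$rotate(matrix(1, nrow(agg_o), 1L)))
  sni_r <- drop(rot$rotate(matrix(as.numeric(agg_o$scenario == "NI"),
                                  ncol = 1L)))
  d <- rot$d
  lines_used <- unique(rot$line)
  row_line <- match(rot$line, lines_used)

  # per (line, scenario) means of cell means, for allele-class summaries
  ls_I <- tapply(agg$y[agg$scenario == "I"], agg$line[agg$scenario == "I"],
                 mean)[lines_used]
  ls_NI <- tapply(agg$y[agg$scenario == "NI"], agg$line[agg$scenario == "NI"],
                  mean)[lines_used]

  geno <- genotypes$calls[lines_used, markers, drop = FALSE]
  mi <- match(markers, map$marker)
  n_mark <- length(markers)
  p_const <- p_resp <- rep(NA_real_, n_mark)
  nl <- integer(n_mark)
  untestable <- logical(n_mark)
  cls <- matrix(NA_real_, n_mark, 4L,
                dimnames = list(NULL, c("mean_A_I", "mean_A_NI",
                                        "mean_B_I", "mean_B_NI")))

  for (im in seq_len(n_mark)) {
    xl <- allele_code(geno[, im])
    ok_line <- !is.na(xl)
    classes <- unique(xl[ok_line])
    nl[im] <- sum(ok_line)
    if (length(classes) < 2L) {
      p_const[im] <- p_resp[im] <- 1
      untestable[im] <- TRUE
      next
    }
    a <- xl == 1; b <- xl == -1
    cls[im, ] <- c(mean(ls_I[a], na.rm = TRUE), mean(ls_NI[a], na.rm = TRUE),
                   mean(ls_I[b], na.rm = TRUE), mean(ls_NI[b], na.rm = TRUE))

    xv <- xl[row_line]
    keep <- !is.na(xv)
    main <- xv[keep] * one_r[keep]
    inter <- xv[keep] * sni_r[keep]
    Xf <- cbind(Xb_r[keep, , drop = FALSE], main, inter)
    yk <- y_r[keep]
    dk <- d[keep]
    pb <- ncol(Xb_r)
    dev_full <- fit_rotated(Xf, yk, dk, REML = FALSE)$deviance
    dev_nomain <- fit_rotated(Xf[, -(pb + 1L), drop = FALSE], yk, dk,
                              REML = FALSE)$deviance
    dev_noint <- fit_rotated(Xf[, -(pb + 2L), drop = FALSE], yk, dk,
                             REML = FALSE)$deviance
    p_const[im] <- stats::pchisq(max(dev_nomain - dev_full, 0), df = 1L,
                                 lower.tail = FALSE)
    p_resp[im] <- stats::pchisq(max(dev_noint - dev_full, 0), df = 1L,
                                lower.tail = FALSE)
  }

  out <- data.frame(trait = trait, marker = markers, chrom = map$chrom[mi],
                    pos_cM = map$pos_cM[mi], p_const = p_const,
                    p_resp = p_resp, n_lines = nl, untestable = untestable,
                    stringsAsFactors = FALSE)
  out <- cbind(out, as.data.frame(cls))
  # map order for downstream run-based declaration
  out <- out[order(match(out$marker, map$marker)), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("marker_scan", "data.frame")
  out
}
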