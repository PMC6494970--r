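#' Construct a RIL genotype object
#'
#' Thin container for a lines x markers matrix of parental-origin calls.
#' Calls are `"A"` (first-parent allele, e.g. F271), `"B"` (second-parent
#' allele, e.g. Cm484) or `NA` (missing). Lines are fully homozygous: no
#' heterozygous code exists in this representation.
#'
#' @param calls Character matrix, rows = lines, columns = markers, values in
#'   `{"A", "B", NA}`. Row and column names are used as line / marker ids if
#'   `line_ids` / `marker_ids` are not given.
#' @param line_ids,marker_ids Optional id vectors overriding dimnames.
#' @return A `ril_geno` object (list with `calls`, `line_ids`, `marker_ids`).
#' @export
ril_genotypes <- function(calls, line_ids = rownames(calls),
                          marker_ids = colnames(calls)) {
  calls <- as.matrix(calls)
  if (is.null(line_ids) || is.null(marker_ids))
    stop("line and marker ids are required (dimnames or explicit arguments)")
  if (length(line_ids) != nrow(calls) || length(marker_ids) != ncol(calls))
    stop("id lengths do not match the call matrix dimensions")
  if (anyDuplicated(line_ids)) stop("duplicated line id(s)")
  if (anyDuplicated(marker_ids)) stop("duplicated marker id(s)")
  bad <- setdiff(unique(as.vector(calls)), c("A", "B", NA))
  if (length(bad))
    stop("invalid genotype code(s): ", paste(bad, collapse = ", "),
         " (expected A, B or NA)")
  dimnames(calls) <- list(line_ids, marker_ids)
  structure(list(calls = calls, line_ids = as.character(line_ids),
                 marker_ids = as.character(marker_ids)),
            class = "ril_geno")
}

#' @method print ril_geno
#' @export
print.ril_geno <- function(x, ...) {
  cat("RIL genotypes:", length(x$line_ids), "lines x",
      length(x$marker_ids), "markers;",
      sprintf("%.1f%% missing\n", 100 * mean(is.na(x$calls))))
  invisible(x)
}

#' @method dim ril_geno
#' @export
dim.ril_geno <- function(x) dim(x$calls)

#' Simulate selfing-RIL genotypes along a genetic map
#'
#' Each line is an independent mosaic of the two parental genomes. The first
#' marker of every chromosome is `A` or `B` with probability 1/2; between
#' adjacent markers separated by d cM the genotype switches with the
#' selfing-RIL recombination probability R = 2r/(1+2r), where
#' r = (1 - exp(-2d/100))/2 is the Haldane single-meiosis fraction (Markov
#' chain along the chromosome, no interference). Chromosomes are independent,
#' and the expected allele frequency is 1/2 at every marker.
#'
#' @param map A `genetic_map`.
#' @param n_lines Number of RILs to simulate (>= 1).
#' @param seed Integer seed.
#' @param line_prefix Prefix for generated line ids.
#' @return A `ril_geno` with no missing calls.
#' @export
simulate_ril_genotypes <- function(map, n_lines, seed = 1L,
                                   line_prefix = "RIL") {
  validate_genetic_map(map)
  if (nrow(map) == 0L) stop("the genetic map is empty")
  if (length(n_lines) != 1L || is.na(n_lines) || n_lines < 1)
    stop("`n_lines` must be a single count >= 1")
  n_lines <- as.integer(n_lines)

  set.seed(as.integer(seed))
  chroms <- unique(map$chrom)
  blocks <- vector("list", length(chroms))
  for (ci in seq_along(chroms)) {
    pos <- map$pos_cM[map$chrom == chroms[ci]]
    m <- length(pos)
    # state: TRUE = "A"; start each chromosome at random parent
    g <- matrix(NA, n_lines, m)
    g[, 1L] <- stats::runif(n_lines) < 0.5
    if (m > 1L) {
      pr <- ril_switch_prob(diff(pos))
      for (k in 2L:m) {
        flip <- stats::runif(n_lines) < pr[k - 1L]
        g[, k] <- xor(g[, k - 1L], flip)
      }
    }
    blocks[[ci]] <- g
  }
  calls <- ifelse(do.call(cbind, blocks), "A", "B")
  dimnames(calls) <- list(sprintf("%s%04d", line_prefix, seq_len(n_lines)),
                          map$marker)
  ril_genotypes(calls)
}

#' Inject missing genotype calls
#'
#' Sets each call to `NA` independently with probability `rate`, emulating
#' the missingness of genotyping-by-sequencing data ahead of marker
#' filtering.
#'
#' @param genotypes A `ril_geno`.
#' @param rate Per-call missing probability in `[0, 1)`.
#' @param seed Integer seed (the mask is reproducible).
#' @return A `ril_geno` with the masked calls.
#' @export
inject_missing <- function(genotypes, rate, seed = 1L) {
  stopifnot(inherits(genotypes, "ril_geno"))
  if (length(rate) != 1L || is.na(rate) || rate < 0 || rate >= 1)
    stop("`rate` must be a single proportion in [0, 1)")
  if (rate == 0) return(genotypes)
  set.seed(as.integer(seed))
  calls <- genotypes$calls
  mask <- matrix(stats::runif(length(calls)) < rate, nrow(calls), ncol(calls))
  calls[mask] <- NA_character_
  ril_genotypes(calls)
}

#' Filter markers on parental polymorphism and missingness
#'
#' Retains markers that are polymorphic between the two parental lines and
#' have a missing-call fraction at most `max_missing` among the RILs
#' (boundary kept at equality). Marker order is preserved.
#'
#' @param genotypes A `ril_geno` of RIL calls.
#' @param parents Optional 2 x markers character matrix (or `ril_geno`) of
#'   parental calls; a marker is polymorphic when both parental calls are
#'   non-missing and differ. When `NULL`, calls are assumed pre-coded by
#'   parental origin and a marker is polymorphic when both `A` and `B` occur
#'   among the RILs.
#' @param max_missing Maximum tolerated missing fraction (default 0.15).
#' @return A `ril_geno` restricted to the retained markers, with attribute
#'   `n_dropped`.
#' @export
filter_markers <- function(genotypes, parents = NULL, max_missing = 0.15) {
  stopifnot(inherits(genotypes, "ril_geno"))
  if (max_missing < 0 || max_missing >= 1)
    stop("`max_missing` must be in [0, 1)")
  calls <- genotypes$calls
  miss <- colMeans(is.na(calls))
  if (is.null(parents)) {
    poly <- apply(calls, 2L, function(v) {
      u <- unique(v[!is.na(v)]); length(u) == 2L
    })
  } else {
    pc <- if (inherits(parents, "ril_geno")) parents$calls else as.matrix(parents)
    if (nrow(pc) != 2L)
      stop("`parents` must contain exactly two genotype rows")
    pc <- pc[, genotypes$marker_ids, drop = FALSE]
    poly <- !is.na(pc[1L, ]) & !is.na(pc[2L, ]) & pc[1L, ] != pc[2L, ]
  }
  keep <- poly & miss <= max_missing
  if (!any(keep))
    stop("all markers were filtered out (polymorphism / missingness)")
  out <- ril_genotypes(calls[, keep, drop = FALSE])
  attr(out, "n_dropped") <- sum(!keep)
  out
}

#' Numeric allele coding at a marker
#'
#' Internal coding used throughout the scan: `A` (F271-type) -> +1,
#' `B` (Cm484-type) -> -1, missing -> `NA`.
#' @noRd
allele_code <- function(calls) {
  x <- rep(NA_real_, length(calls))
  x[calls == "A"] <- 1
  x[calls == "B"] <- -1
  x
}
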