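#' Simulate a genetic map
#'
#' Generates an ordered marker map on `n_chrom` chromosomes. Marker positions
#' are drawn uniformly on each chromosome and sorted; the first and last
#' markers of every chromosome are pinned at 0 and `chrom_length_cM`, so the
#' realized map length equals `n_chrom * chrom_length_cM` exactly. The
#' defaults emulate a dense biparental maize framework map: 10 chromosomes of
#' 235.5 cM each (2,355 cM total) carrying 1,000 markers.
#'
#' @param n_chrom Number of chromosomes (>= 1).
#' @param markers_per_chrom Markers per chromosome (>= 1; >= 2 to pin both
#'   chromosome ends).
#' @param chrom_length_cM Chromosome length in centimorgans (> 0). Either a
#'   single value recycled to all chromosomes or a vector of length `n_chrom`.
#' @param seed Integer seed; the same seed always yields the same map.
#' @return A `genetic_map`: a data frame with columns `marker`, `chrom`,
#'   `pos_cM`, ordered by chromosome then position, with an attribute
#'   `chrom_lengths` (named numeric vector).
#' @examples
#' map <- simulate_genetic_map(2, 10, 150, seed = 1)
#' @export
simulate_genetic_map <- function(n_chrom = 10, markers_per_chrom = 100,
                                 chrom_length_cM = 235.5, seed = 1L) {
  if (length(n_chrom) != 1L || is.na(n_chrom) || n_chrom < 1)
    stop("`n_chrom` must be a single count >= 1")
  if (length(markers_per_chrom) != 1L || is.na(markers_per_chrom) ||
      markers_per_chrom < 1)
    stop("`markers_per_chrom` must be a single count >= 1")
  if (any(is.na(chrom_length_cM)) || any(chrom_length_cM <= 0))
    stop("`chrom_length_cM` must be > 0")
  n_chrom <- as.integer(n_chrom)
  m <- as.integer(markers_per_chrom)
  lens <- rep_len(as.numeric(chrom_length_cM), n_chrom)

  set.seed(as.integer(seed))
  pieces <- lapply(seq_len(n_chrom), function(cc) {
    L <- lens[cc]
    if (m == 1L) {
      pos <- 0
    } else {
      pos <- c(0, sort(stats::runif(m - 2L, 0, L)), L)
    }
    data.frame(
      marker = sprintf("c%02d_m%03d", cc, seq_len(m)),
      chrom = sprintf("chr%02d", cc),
      pos_cM = pos,
      stringsAsFactors = FALSE
    )
  })
  map <- do.call(rbind, pieces)
  rownames(map) <- NULL
  names(lens) <- sprintf("chr%02d", seq_len(n_chrom))
  attr(map, "chrom_lengths") <- lens
  class(map) <- c("genetic_map", "data.frame")
  validate_genetic_map(map)
  map
}

#' Validate a genetic map
#'
#' Checks the `genetic_map` invariants: required columns, unique marker ids,
#' non-negative positions non-decreasing within chromosome, and positions not
#' exceeding the chromosome length (when lengths are attached).
#'
#' @param map A `genetic_map` or plain data frame with `marker`, `chrom`,
#'   `pos_cM` columns.
#' @return The map, invisibly; errors describe the offending marker.
#' @export
validate_genetic_map <- function(map) {
  need <- c("marker", "chrom", "pos_cM")
  miss <- setdiff(need, names(map))
  if (length(miss))
    stop("genetic map is missing column(s): ", paste(miss, collapse = ", "))
  if (anyDuplicated(map$marker))
    stop("duplicated marker id(s): ",
         paste(unique(map$marker[duplicated(map$marker)]), collapse = ", "))
  if (any(is.na(map$pos_cM)) || any(map$pos_cM < 0))
    stop("marker positions must be non-negative and non-missing")
  for (cc in unique(map$chrom)) {
    p <- map$pos_cM[map$chrom == cc]
    if (is.unsorted(p))
      stop("marker positions not sorted on chromosome ", cc)
  }
  lens <- attr(map, "chrom_lengths")
  if (!is.null(lens)) {
    for (cc in intersect(unique(map$chrom), names(lens))) {
      bad <- map$marker[map$chrom == cc & map$pos_cM > lens[[cc]] + 1e-9]
      if (length(bad))
        stop("marker(s) beyond chromosome length on ", cc, ": ",
             paste(bad, collapse = ", "))
    }
  }
  invisible(map)
}

#' Haldane map function and selfing-RIL recombination
#'
#' `haldane_r()` converts a map distance in cM to a single-meiosis
#' recombination fraction under the Haldane (no-interference) model,
#' r = (1 - exp(-2 d/100)) / 2. `ril_switch_prob()` converts the same distance
#' to the expected genotype-switch probability between adjacent markers in a
#' selfing-derived RIL, R = 2 r / (1 + 2 r).
#'
#' @param d_cM Map distance in centimorgans (>= 0), vectorized.
#' @return Probabilities in `[0, 0.5)` for `haldane_r`; `[0, 2/3)` for
#'   `ril_switch_prob`.
#' @examples
#' ril_switch_prob(10)  # ~0.1533
#' @export
haldane_r <- function(d_cM) {
  if (any(d_cM < 0, na.rm = TRUE)) stop("map distances must be >= 0")
  (1 - exp(-2 * d_cM / 100)) / 2
}

#' @rdname haldane_r
#' @export
ril_switch_prob <- function(d_cM) {
  r <- haldane_r(d_cM)
  2 * r / (1 + 2 * r)
}
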