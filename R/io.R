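# Tabular readers/writers. All files are UTF-8 TSV with '#'-prefixed
# comment headers, "NA" for missing values and a decimal point.

provenance_header <- function(provenance = NULL) {
  ver <- as.character(utils::packageVersion("rilqtl"))
  lines <- paste0("# rilqtl ", ver)
  if (!is.null(provenance))
    lines <- c(lines, paste0("# ", names(provenance), ": ",
                             unname(unlist(provenance))))
  lines
}

write_tsv_commented <- function(df, path, provenance = NULL) {
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(provenance_header(provenance), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "NA")
  invisible(path)
}

read_tsv_commented <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  utils::read.table(path, sep = "\t", header = TRUE, comment.char = "#",
                    na.strings = "NA", stringsAsFactors = FALSE,
                    check.names = FALSE)
}

#' Read and write the tabular interchange formats
#'
#' The on-disk dialect is TSV with `#`-prefixed provenance comments and
#' `NA` for missing values. Maps use columns `marker`, `chrom`, `pos_cM`;
#' genotype files have one row per line (first column `line`) and one
#' column per marker with calls in `{A, B, NA}`; phenotype files have
#' columns `line`, `year`, `scenario`, `bloc`, `is_check` followed by one
#' column per trait. Scenario codes are whitespace-normalized on read with
#' a warning; anything other than `I`/`NI` after normalization is an error
#' naming the offending rows.
#'
#' @param map,genotypes,table Objects to write.
#' @param path File path.
#' @param provenance Optional named list written into the comment header
#'   (e.g. seed, config hash).
#' @return Readers return the validated object; writers return the path
#'   invisibly.
#' @name trial_io
NULL

#' @rdname trial_io
#' @export
write_map <- function(map, path, provenance = NULL) {
  validate_genetic_map(map)
  write_tsv_commented(as.data.frame(map)[, c("marker", "chrom", "pos_cM")],
                      path, provenance)
}

#' @rdname trial_io
#' @export
read_map <- function(path) {
  df <- read_tsv_commented(path)
  need <- c("marker", "chrom", "pos_cM")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("map file ", path, " is missing column(s): ",
         paste(miss, collapse = ", "))
  df <- df[, need]
  df$marker <- as.character(df$marker)
  df$chrom <- as.character(df$chrom)
  class(df) <- c("genetic_map", "data.frame")
  validate_genetic_map(df)
  df
}

#' @rdname trial_io
#' @export
write_genotypes <- function(genotypes, path, provenance = NULL) {
  stopifnot(inherits(genotypes, "ril_geno"))
  df <- data.frame(line = genotypes$line_ids, genotypes$calls,
                   check.names = FALSE, stringsAsFactors = FALSE)
  write_tsv_commented(df, path, provenance)
}

#' @rdname trial_io
#' @param map Optional `genetic_map`; when given, genotype markers are
#'   cross-checked against it and unknown markers raise an error naming
#'   them.
#' @export
read_genotypes <- function(path, map = NULL) {
  df <- read_tsv_commented(path)
  if (names(df)[1L] != "line")
    stop("genotype file ", path, " must start with a `line` column")
  calls <- as.matrix(df[, -1L, drop = FALSE])
  rownames(calls) <- as.character(df$line)
  g <- ril_genotypes(calls)
  if (!is.null(map)) {
    unknown <- setdiff(g$marker_ids, map$marker)
    if (length(unknown))
      stop("genotype marker(s) absent from the map: ",
           paste(unknown, collapse = ", "))
  }
  g
}

#' @rdname trial_io
#' @export
write_phenotypes <- function(table, path, provenance = NULL) {
  check_phenotype_table(table)
  write_tsv_commented(table, path, provenance)
}

#' @rdname trial_io
#' @export
read_phenotypes <- function(path) {
  df <- read_tsv_commented(path)
  need <- c("line", "year", "scenario", "bloc", "is_check")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("phenotype file ", path, " is missing column(s): ",
         paste(miss, collapse = ", "))
  raw <- as.character(df$scenario)
  norm <- trimws(raw)
  if (!identical(norm, raw))
    warning("scenario codes were whitespace-normalized in ", path)
  bad <- which(!norm %in% c("I", "NI"))
  if (length(bad))
    stop("unknown scenario code(s) in ", path, " at row(s) ",
         paste(utils::head(bad, 5L), collapse = ", "), ": ",
         paste(unique(norm[bad]), collapse = ", "))
  df$scenario <- norm
  df$line <- as.character(df$line)
  df$is_check <- as.logical(df$is_check)
  traits <- setdiff(names(df), need)
  for (tr in traits) {
    if (!is.numeric(df[[tr]]))
      stop("trait column ", shQuote(tr), " in ", path, " is not numeric")
    if (any(is.infinite(df[[tr]])))
      stop("trait column ", shQuote(tr), " in ", path,
           " has non-finite values")
  }
  df
}

#' Read a full dataset (map, genotypes, phenotypes) with cross-checks
#'
#' @param map_path,genotype_path,phenotype_path File paths.
#' @return A list `map`, `genotypes`, `phenotypes`; genotype markers are
#'   verified against the map and phenotyped non-check lines are checked
#'   for genotype coverage (uncovered lines are reported in a warning, not
#'   an error, since checks and field-only lines are legitimate).
#' @export
read_tables <- function(map_path, genotype_path, phenotype_path) {
  map <- read_map(map_path)
  genotypes <- read_genotypes(genotype_path, map = map)
  phenotypes <- read_phenotypes(phenotype_path)
  uncov <- setdiff(unique(phenotypes$line[!phenotypes$is_check]),
                   genotypes$line_ids)
  if (length(uncov))
    warning(length(uncov), " phenotyped RIL(s) lack genotypes, e.g. ",
            paste(utils::head(uncov, 3L), collapse = ", "))
  list(map = map, genotypes = genotypes, phenotypes = phenotypes)
}
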