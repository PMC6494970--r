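#' Build a validated pipeline configuration
#'
#' A run configuration either points at input files (`map`, `genotypes`,
#' `phenotypes` paths) or describes a simulation (`sim`). The same seed and
#' configuration always produce byte-identical outputs; per-stage seeds are
#' derived from the master seed (map: seed+1, genotypes: seed+2,
#' missingness: seed+3, phenotypes: seed+4, 5, ... per trait).
#'
#' @param out_dir Output directory (created if needed).
#' @param seed Master integer seed.
#' @param alpha Scan significance threshold in (0, 1); default `5e-5`.
#' @param max_missing Marker missing-fraction filter threshold.
#' @param map,genotypes,phenotypes Input file paths (analysis mode).
#' @param sim Simulation description (simulation mode): a list with
#'   `n_lines`, `n_chrom`, `markers_per_chrom`, `chrom_length_cM`,
#'   `missing_rate`, optional `design` arguments (`years`,
#'   `blocs_per_year`), and `traits` — a named list, one entry per trait,
#'   each with `components` (arguments to [trial_components()]) and `qtls`
#'   (a list of `anchor_marker` / `additive_effect` /
#'   `interaction_effect` entries).
#' @return A `run_config` list.
#' @export
run_config <- function(out_dir, seed = 1L, alpha = 5e-5, max_missing = 0.15,
                       map = NULL, genotypes = NULL, phenotypes = NULL,
                       sim = NULL) {
  if (missing(out_dir) || !nzchar(out_dir)) stop("`out_dir` is required")
  if (length(alpha) != 1L || is.na(alpha) || alpha <= 0 || alpha >= 1)
    stop("`alpha` must be in (0, 1)")
  if (max_missing < 0 || max_missing >= 1)
    stop("`max_missing` must be in [0, 1)")
  file_mode <- !is.null(map) || !is.null(genotypes) || !is.null(phenotypes)
  if (file_mode && (is.null(map) || is.null(genotypes) ||
                    is.null(phenotypes)))
    stop("analysis mode needs all three of map, genotypes, phenotypes")
  if (file_mode && !is.null(sim))
    stop("give either input paths or a `sim` block, not both")
  if (!file_mode && is.null(sim)) sim <- list()
  if (!file_mode) {
    defaults <- list(n_lines = 261L, n_chrom = 10L, markers_per_chrom = 100L,
                     chrom_length_cM = 235.5, missing_rate = 0.05,
                     design = list(), traits = NULL)
    sim <- utils::modifyList(defaults, sim)
    if (is.null(sim$traits)) {
      m1 <- sprintf("c01_m%03d", max(1L, sim$markers_per_chrom %/% 4L))
      m2 <- sprintf("c%02d_m%03d", min(3L, sim$n_chrom),
                    max(1L, sim$markers_per_chrom %/% 2L))
      m3 <- sprintf("c%02d_m%03d", min(5L, sim$n_chrom),
                    max(1L, sim$markers_per_chrom %/% 2L))
      sim$traits <- list(
        height = list(components = list(),
                      qtls = list(list(anchor_marker = m1,
                                       additive_effect = 6),
                                  list(anchor_marker = m3,
                                       interaction_effect = 4))),
        digestibility = list(
          components = list(mu = 37, sigma2_g = 2.5, sigma2_gy = 0.4,
                            sigma2_ge = 0.3, sigma2_bloc = 0.2,
                            sigma2_E = 1.2,
                            year_effects = c(`2013` = 0, `2014` = 0.4,
                                             `2015` = -0.4),
                            scenario_effects = c(I = 0, NI = 7.9)),
          qtls = list(list(anchor_marker = m2, additive_effect = -0.8),
                      list(anchor_marker = m3, interaction_effect = 0.6))))
    }
  }
  structure(list(out_dir = out_dir, seed = as.integer(seed), alpha = alpha,
                 max_missing = max_missing,
                 paths = if (file_mode)
                   list(map = map, genotypes = genotypes,
                        phenotypes = phenotypes) else NULL,
                 sim = if (!file_mode) sim else NULL),
            class = "run_config")
}

#' Load a pipeline configuration from YAML or JSON
#'
#' @param path Configuration file (`.yaml`/`.yml` or `.json`) whose keys
#'   match the arguments of [run_config()].
#' @return A validated `run_config`.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  cfg <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE))
    yaml::read_yaml(path)
  else jsonlite::fromJSON(path, simplifyVector = TRUE,
                          simplifyDataFrame = FALSE)
  do.call(run_config, cfg)
}

coerce_qtls <- function(qtls) {
  if (is.null(qtls) || !length(qtls)) return(NULL)
  rows <- lapply(qtls, function(q)
    qtl_effects(q$anchor_marker,
                if (is.null(q$additive_effect)) 0 else q$additive_effect,
                if (is.null(q$interaction_effect)) 0
                else q$interaction_effect))
  do.call(rbind, rows)
}

stage <- function(name, expr) {
  message("[rilqtl] stage: ", name)
  tryCatch(force(expr),
           error = function(e)
             stop("pipeline stage ", shQuote(name), " failed: ",
                  conditionMessage(e), call. = FALSE))
}

#' Run the full analysis pipeline
#'
#' Sequences the whole workflow: obtain inputs (simulate or read), bloc-BLUP
#' correction per trait, variance components / heritability / ANOVA
#' r-squared, ls-means (joint and per scenario), percent response,
#' per-scenario trait correlations and PCA (when at least two traits),
#' marker filtering, the constitutive/responsive genome scan, QTL
#' declaration with r-squared and normalized-effect annotation, cross-trait
#' clustering, and a report bundle written to `config$out_dir`. Fully
#' deterministic for a given configuration and seed; input files are never
#' modified.
#'
#' @param config A `run_config` (or path accepted by [read_config()]).
#' @return Invisibly, a list with the in-memory results (`map`,
#'   `genotypes`, `phenotypes`, per-trait `corrected`, `stats`, `scan`,
#'   `qtls`, `clusters`, output `files`).
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_config(config)
  stopifnot(inherits(config, "run_config"))
  out_dir <- config$out_dir
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  seed <- config$seed

  cfg_json <- jsonlite::toJSON(unclass(config), auto_unbox = TRUE,
                               digits = NA, null = "null")
  tf <- file.path(out_dir, "config.json")
  writeLines(cfg_json, tf)
  # hash the scientific configuration only, so equal analyses written to
  # different directories stay byte-identical
  hashable <- unclass(config)
  hashable$out_dir <- NULL
  hf <- tempfile()
  writeLines(jsonlite::toJSON(hashable, auto_unbox = TRUE, digits = NA,
                              null = "null"), hf)
  cfg_md5 <- unname(tools::md5sum(hf))
  unlink(hf)
  prov <- list(seed = seed, config_md5 = cfg_md5)
  files <- c(config = tf)

  truth <- NULL
  if (!is.null(config$sim)) {
    sim <- config$sim
    inputs <- stage("simulate", {
      map <- simulate_genetic_map(sim$n_chrom, sim$markers_per_chrom,
                                  sim$chrom_length_cM, seed = seed + 1L)
      geno <- simulate_ril_genotypes(map, sim$n_lines, seed = seed + 2L)
      design <- do.call(trial_design, sim$design)
      ph <- NULL
      truth_rows <- list()
      tseed <- seed + 4L
      for (tn in names(sim$traits)) {
        spec <- sim$traits[[tn]]
        comps <- do.call(trial_components, spec$components)
        trial <- simulate_trial_phenotypes(geno, coerce_qtls(spec$qtls),
                                           design, comps, seed = tseed,
                                           trait = tn)
        tseed <- tseed + 1L
        if (is.null(ph)) ph <- trial$phenotypes
        else ph[[tn]] <- trial$phenotypes[[tn]]
        truth_rows[[tn]] <- trial$truth
      }
      geno_obs <- if (sim$missing_rate > 0)
        inject_missing(geno, sim$missing_rate, seed = seed + 3L) else geno
      list(map = map, genotypes = geno_obs, phenotypes = ph,
           truth = truth_rows)
    })
    truth <- inputs$truth
    stage("write inputs", {
      files["map"] <- write_map(inputs$map,
                                 file.path(out_dir, "map.tsv"), prov)
      files["genotypes"] <- write_genotypes(
        inputs$genotypes, file.path(out_dir, "genotypes.tsv"), prov)
      files["phenotypes"] <- write_phenotypes(
        inputs$phenotypes, file.path(out_dir, "phenotypes.tsv"), prov)
      tq <- do.call(rbind, lapply(names(truth), function(tn) {
        q <- truth[[tn]]$qtls
        if (is.null(q) || !nrow(q)) return(NULL)
        cbind(trait = tn, as.data.frame(q))
      }))
      if (!is.null(tq))
        files["truth_qtls"] <- write_tsv_commented(
          tq, file.path(out_dir, "truth_qtls.tsv"), prov)
    })
  } else {
    inputs <- stage("read inputs",
                    read_tables(config$paths$map, config$paths$genotypes,
                                config$paths$phenotypes))
  }
  map <- inputs$map
  phenotypes <- inputs$phenotypes
  traits <- setdiff(names(phenotypes),
                    c("line", "year", "scenario", "bloc", "is_check"))
  if (!length(traits)) stop("no trait column in the phenotype table")

  corrected <- phenotypes
  blups <- list()
  stage("bloc correction", {
    for (tn in traits) {
      bc <- correct_bloc_effects(phenotypes, tn)
      corrected[[tn]] <- bc$corrected[[tn]]
      blups[[tn]] <- bc$blups
    }
    files["corrected"] <- write_phenotypes(
      corrected, file.path(out_dir, "phenotypes_corrected.tsv"), prov)
  })

  stats_rows <- list()
  lsm <- list()
  stage("variance components and ls-means", {
    for (tn in traits) {
      vc <- estimate_components(corrected, tn)
      h2 <- broad_sense_heritability(vc)
      r2tab <- anova_r2_table(corrected, tn)
      stats_rows[[tn]] <- rbind(
        data.frame(trait = tn,
                   quantity = c("sigma2_g", "sigma2_gy", "sigma2_ge",
                                "sigma2_E", "h2", "obs_per_line"),
                   value = c(vc$sigma2_g, vc$sigma2_gy, vc$sigma2_ge,
                             vc$sigma2_E, h2, vc$obs_per_line)),
        data.frame(trait = tn, quantity = paste0("r2_", r2tab$term),
                   value = r2tab$r2_percent))
      lsm[[tn]] <- list(all = lsmeans(corrected, tn, "all"),
                        I = lsmeans(corrected, tn, "I"),
                        NI = lsmeans(corrected, tn, "NI"))
    }
    stats <- do.call(rbind, stats_rows)
    rownames(stats) <- NULL
    files["stats"] <- write_tsv_commented(
      stats, file.path(out_dir, "stats.tsv"), prov)
    jsonlite::write_json(
      split(stats[, c("quantity", "value")], stats$trait),
      file.path(out_dir, "stats.json"), dataframe = "rows",
      auto_unbox = TRUE, digits = NA)
    files["stats_json"] <- file.path(out_dir, "stats.json")
  })

  stage("trait descriptives", {
    resp <- do.call(rbind, lapply(traits, function(tn) {
      mi <- mean(lsm[[tn]]$I$lsmean)
      mni <- mean(lsm[[tn]]$NI$lsmean)
      data.frame(trait = tn, group = "RIL_population", mean_I = mi,
                 mean_NI = mni,
                 percent_response = percent_response(mi, mni, digits = 1L))
    }))
    files["response"] <- write_tsv_commented(
      resp, file.path(out_dir, "response.tsv"), prov)
    if (length(traits) >= 2L) {
      for (sc in c("I", "NI")) {
        wide <- Reduce(function(a, b) merge(a, b, by = "line"),
                       lapply(traits, function(tn) {
                         x <- lsm[[tn]][[sc]]
                         stats::setNames(as.data.frame(x)[, c("line",
                                                              "lsmean")],
                                         c("line", tn))
                       }))
        cm <- correlation_matrix(wide, traits)
        files[paste0("correlations_", sc)] <- write_tsv_commented(
          data.frame(trait = rownames(cm), as.data.frame(cm),
                     check.names = FALSE),
          file.path(out_dir, paste0("correlations_", sc, ".tsv")), prov)
      }
      pca <- pca_traits(corrected[!corrected$is_check, , drop = FALSE],
                        traits, group = "scenario")
      files["pca_loadings"] <- write_tsv_commented(
        data.frame(trait = rownames(pca$loadings),
                   as.data.frame(pca$loadings), check.names = FALSE),
        file.path(out_dir, "pca_loadings.tsv"), prov)
      jsonlite::write_json(
        list(percent_variance = pca$percent_variance, n_used = pca$n_used),
        file.path(out_dir, "pca_summary.json"), auto_unbox = TRUE,
        digits = NA)
      files["pca_summary"] <- file.path(out_dir, "pca_summary.json")
    }
  })

  genotypes <- stage("marker filtering",
                     filter_markers(inputs$genotypes,
                                    max_missing = config$max_missing))

  scans <- list()
  qtls <- list()
  stage("genome scan", {
    for (tn in traits) {
      sc <- scan_markers(corrected, genotypes, map, tn)
      scans[[tn]] <- sc
      qc <- declare_qtls(sc, map, alpha = config$alpha, "constitutive")
      qr <- declare_qtls(sc, map, alpha = config$alpha, "responsive")
      qq <- rbind(qc, qr)
      qtls[[tn]] <- annotate_qtls(qq, genotypes,
                                  lsmeans_all = lsm[[tn]]$all,
                                  lsmeans_I = lsm[[tn]]$I,
                                  lsmeans_NI = lsm[[tn]]$NI)
    }
    scan_all <- do.call(rbind, scans)
    rownames(scan_all) <- NULL
    files["scan"] <- write_tsv_commented(
      scan_all[, c("trait", "marker", "chrom", "pos_cM", "p_const",
                   "p_resp")],
      file.path(out_dir, "scan.tsv"), prov)
    qtl_all <- do.call(rbind, qtls)
    rownames(qtl_all) <- NULL
    files["qtls"] <- write_tsv_commented(
      qtl_all, file.path(out_dir, "qtls.tsv"), prov)
  })

  clusters <- stage("clustering", {
    qtl_all <- do.call(rbind, qtls)
    cl <- cluster_qtls(qtl_all)
    jsonlite::write_json(cl, file.path(out_dir, "clusters.json"),
                         dataframe = "rows", auto_unbox = TRUE, digits = NA,
                         na = "null")
    files["clusters"] <- file.path(out_dir, "clusters.json")
    cl
  })

  stage("report", {
    qtl_all <- do.call(rbind, qtls)
    lines <- c(provenance_header(prov),
               "",
               sprintf("Traits analysed: %s", paste(traits, collapse = ", ")),
               sprintf("Lines: %d RILs; markers kept: %d of %d",
                       length(unique(
                         phenotypes$line[!phenotypes$is_check])),
                       length(genotypes$marker_ids), nrow(map)),
               sprintf("Scan threshold alpha = %g", config$alpha),
               "",
               sprintf("QTLs declared: %d constitutive, %d responsive",
                       sum(qtl_all$kind == "constitutive"),
                       sum(qtl_all$kind == "responsive")),
               sprintf("Clusters (>=2 traits): %d", nrow(clusters$clusters)))
    writeLines(lines, file.path(out_dir, "summary.txt"))
    files["summary"] <- file.path(out_dir, "summary.txt")
    jsonlite::write_json(
      list(package = "rilqtl",
           version = as.character(utils::packageVersion("rilqtl")),
           seed = seed, config_md5 = cfg_md5),
      file.path(out_dir, "provenance.json"), auto_unbox = TRUE)
    files["provenance"] <- file.path(out_dir, "provenance.json")
  })

  invisible(list(map = map, genotypes = genotypes, phenotypes = phenotypes,
                 corrected = corrected, blups = blups, lsmeans = lsm,
                 scans = scans, qtls = do.call(rbind, qtls),
                 clusters = clusters, truth = truth, files = files))
}
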