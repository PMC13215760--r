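#' Build a pipeline configuration
#'
#' Collects the paths, thresholds and sizes controlling a full analysis
#' run. Defaults mirror the package-wide conventions: PCPS axes retained
#' above 5% variance, 55% species-affiliation threshold, 90%
#' explained-variation floor for the number of phyloregions, 5%
#' contribution flag, 999 randomizations.
#'
#' @param tree Path to a Newick tree, or a `phylo` object.
#' @param occurrence Path to an occurrence CSV, or an `occurrence_grid`.
#' @param external_maps Named list of region-map CSV paths or named label
#'   vectors to include in the congruence comparisons.
#' @param out_dir Output directory for the report bundle.
#' @param k_range Candidate k for evoregions.
#' @param k_max,min_explained Phyloregion k selection.
#' @param pcps_variance,affiliation,contribution Thresholds.
#' @param n_maps Stochastic maps per scheme.
#' @param n_rand Randomizations per congruence direction.
#' @param seed Global seed, fanned out to per-stage seeds.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(tree, occurrence, external_maps = list(),
                            out_dir = "evoregio_run",
                            k_range = 2:10, k_max = 20,
                            min_explained = 0.90, pcps_variance = 0.05,
                            affiliation = 0.55, contribution = 0.05,
                            n_maps = 1000, n_rand = 999, seed = 1L) {
  thr <- c(pcps_variance, affiliation, min_explained, contribution)
  if (any(thr <= 0 | thr >= 1)) {
    stop("thresholds must lie in (0, 1)", call. = FALSE)
  }
  structure(list(tree = tree, occurrence = occurrence,
                 external_maps = external_maps, out_dir = out_dir,
                 k_range = k_range, k_max = k_max,
                 min_explained = min_explained,
                 pcps_variance = pcps_variance,
                 affiliation = affiliation, contribution = contribution,
                 n_maps = n_maps, n_rand = n_rand, seed = seed),
            class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' @param path YAML file with fields matching [pipeline_config()]
#'   arguments.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  if (!is.null(y$k_range) && length(y$k_range) == 2) {
    y$k_range <- seq(y$k_range[[1]], y$k_range[[2]])
  }
  do.call(pipeline_config, y)
}

#' Run the full regionalization analysis
#'
#' Executes, in order: tree/table alignment, evoregion delineation,
#' phyloregion delineation, species affiliation under both schemes,
#' equal-rates Mk fitting and stochastic character maps of regional
#' affiliation under both schemes, phylogenetic correspondence analysis
#' with species contributions under both schemes, and all pairwise
#' V-measure congruence tests among the two delineations and any external
#' maps. Every stage's tables are written as CSV into `out_dir`, plus a
#' JSON run manifest listing the configuration, package version, seed,
#' wall-clock time, and an md5 digest of every output file. A stage
#' failure aborts with the stage name; outputs written so far remain on
#' disk.
#'
#' @param config A `pipeline_config` (or path to a YAML file).
#' @return Invisibly, a list with all stage results and the manifest.
#' @export
run_full_pipeline <- function(config) {
  if (is.character(config)) config <- read_pipeline_config(config)
  stopifnot(inherits(config, "pipeline_config"))
  t0 <- Sys.time()
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  seeds <- derive_seeds(config$seed, 9L)
  stages <- character(0)
  run_stage <- function(name, expr) {
    message("[evoregio] stage: ", name)
    res <- tryCatch(expr, error = function(e) {
      stop("stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
    stages <<- c(stages, name)
    res
  }

  tree <- if (inherits(config$tree, "phylo")) config$tree else
    read_newick(config$tree)
  occ <- if (inherits(config$occurrence, "occurrence_grid"))
    config$occurrence else read_occurrence_csv(config$occurrence)

  al <- run_stage("align", align_tree_and_table(force_ultrametric(tree), occ))

  evo <- run_stage("evoregions", {
    e <- evoregion(al$tree, al$occ, k_range = config$k_range,
                   seed = seeds[1], retain_threshold = config$pcps_variance)
    write_region_map(e$regionalization,
                     file.path(config$out_dir, "evoregions.csv"))
    utils::write.csv(e$diagnostics,
                     file.path(config$out_dir, "evoregion_k_curve.csv"),
                     row.names = FALSE)
    utils::write.csv(data.frame(cell_id = rownames(e$pcps$scores),
                                e$pcps$scores),
                     file.path(config$out_dir, "pcps_scores.csv"),
                     row.names = FALSE)
    e
  })

  phy <- run_stage("phyloregions", {
    p <- phyloregion_delineate(al$tree, al$occ, k_max = config$k_max,
                               min_explained = config$min_explained)
    write_region_map(p$regionalization,
                     file.path(config$out_dir, "phyloregions.csv"))
    utils::write.csv(p$curve,
                     file.path(config$out_dir, "phyloregion_k_curve.csv"),
                     row.names = FALSE)
    p
  })

  schemes <- list(evoregion = evo$regionalization,
                  phyloregion = phy$regionalization)

  affil <- run_stage("affiliation", {
    lapply(names(schemes), function(nm) {
      a <- species_affiliation(al$occ, schemes[[nm]],
                               threshold = config$affiliation)
      utils::write.csv(data.frame(species = rownames(a$fractions),
                                  a$fractions, state = unname(a$state)),
                       file.path(config$out_dir,
                                 paste0("affiliation_", nm, ".csv")),
                       row.names = FALSE)
      a
    }) |> stats::setNames(names(schemes))
  })

  anc <- run_stage("ancestral", {
    lapply(seq_along(schemes), function(i) {
      nm <- names(schemes)[i]
      fit <- fit_mk(al$tree, affil[[nm]]$state)
      sm <- stochastic_maps(fit, n_maps = config$n_maps,
                            seed = seeds[1 + i])
      utils::write.csv(data.frame(node = rownames(sm$node_freq),
                                  sm$node_freq),
                       file.path(config$out_dir,
                                 paste0("ancestral_", nm, ".csv")),
                       row.names = FALSE)
      list(fit = fit, maps = sm)
    }) |> stats::setNames(names(schemes))
  })

  ca <- run_stage("evoca", {
    lapply(names(schemes), function(nm) {
      res <- evoca(al$occ, al$tree, schemes[[nm]])
      contr <- species_contributions(res, threshold = config$contribution)
      utils::write.csv(contr,
                       file.path(config$out_dir,
                                 paste0("contributions_", nm, ".csv")),
                       row.names = FALSE)
      utils::write.csv(data.frame(region = rownames(res$site_scores),
                                  res$site_scores),
                       file.path(config$out_dir,
                                 paste0("evoca_sites_", nm, ".csv")),
                       row.names = FALSE)
      list(evoca = res, contributions = contr)
    }) |> stats::setNames(names(schemes))
  })

  all_maps <- schemes
  for (nm in names(config$external_maps)) {
    m <- config$external_maps[[nm]]
    a <- if (is.character(m) && length(m) == 1 && file.exists(m)) {
      read_region_map(m)
    } else {
      as_assignment(m)
    }
    shared <- intersect(names(a), al$occ$coords$cell_id)
    all_maps[[nm]] <- regionalization(
      a[shared], method = "external",
      coords = al$occ$coords[al$occ$coords$cell_id %in% shared, ])
  }

  cong <- run_stage("congruence", {
    pairs <- utils::combn(names(all_maps), 2, simplify = FALSE)
    rows <- lapply(seq_along(pairs), function(i) {
      pr <- pairs[[i]]
      ct <- congruence_test(all_maps[[pr[1]]], all_maps[[pr[2]]],
                            n_rand = config$n_rand,
                            seed = seeds[8] + i)
      data.frame(map_a = pr[1], map_b = pr[2], V = ct$V,
                 homogeneity = ct$homogeneity,
                 completeness = ct$completeness,
                 p_A_vs_randB = ct$p_A_vs_randB,
                 p_B_vs_randA = ct$p_B_vs_randA,
                 SES = ct$SES, n_rand = ct$n_randomizations,
                 significant = ct$significant)
    })
    tab <- do.call(rbind, rows)
    utils::write.csv(tab, file.path(config$out_dir, "congruence.csv"),
                     row.names = FALSE)
    tab
  })

  manifest <- run_stage("manifest", {
    files <- list.files(config$out_dir, pattern = "\\.csv$",
                        full.names = TRUE)
    man <- list(
      package = "evoregio",
      version = as.character(utils::packageVersion("evoregio")),
      seed = config$seed,
      stages = stages,
      wall_clock_sec = as.numeric(difftime(Sys.time(), t0, units = "secs")),
      config = config[setdiff(names(config),
                              c("tree", "occurrence", "external_maps"))],
      outputs = lapply(files, function(f) {
        list(file = basename(f), md5 = unname(tools::md5sum(f)))
      }))
    jsonlite::write_json(man, file.path(config$out_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE)
    man
  })

  invisible(list(alignment = al, evoregion = evo, phyloregion = phy,
                 affiliation = affil, ancestral = anc, evoca = ca,
                 congruence = cong, manifest = manifest))
}
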