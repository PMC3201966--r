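# Pipeline orchestration: one structured config in, a directory of CSV
# reports out, with full determinism from a single master seed.

#' Validate a pipeline configuration
#'
#' A configuration is a named list (or a YAML file parsed into one) with:
#' exactly one of `webs` (named list of adjacency CSV paths) or `synthetic`
#' (named list of [generateWeb()] argument lists); optionally `parasites`
#' (path to a parasite table CSV) or `synthetic_parasites` (argument list
#' for [generateParasites()]); `seed` (master seed, required);
#' `replicates` (null-model ensemble size), `g_range` and `restarts`
#' (group-model scan), `n_trees` (forest size).
#'
#' @param config named list or path to a YAML file.
#' @return the validated config with defaults filled in.
#' @export
readPipelineConfig <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  if (!is.list(config)) stop("config must be a named list or a YAML path")
  hasWebs <- !is.null(config$webs)
  hasSyn <- !is.null(config$synthetic)
  if (hasWebs == hasSyn)
    stop("config must set exactly one of 'webs' (file mode) or ",
         "'synthetic' (simulation mode)")
  if (is.null(config$seed))
    stop("config field 'seed' (master seed) is required")
  if (hasWebs) {
    missing <- !vapply(config$webs, file.exists, logical(1))
    if (any(missing))
      stop("web input file(s) not found: ",
           paste(unlist(config$webs[missing]), collapse = ", "))
    if (!is.null(config$parasites) && !file.exists(config$parasites))
      stop("parasite table not found: ", config$parasites)
  }
  defaults <- list(replicates = 1000L, g_range = NULL, restarts = 5L,
                   n_trees = 1000L, transpose = FALSE)
  for (nm in names(defaults))
    if (is.null(config[[nm]])) config[[nm]] <- defaults[[nm]]
  config
}

.writeReport <- function(df, outDir, name) {
  path <- file.path(outDir, name)
  utils::write.csv(df, path, row.names = FALSE, quote = TRUE)
  path
}

#' Run the full analysis pipeline
#'
#' Loads (or generates) the webs and parasite records, then runs every stage
#' -- web statistics, degree-distribution fits, nestedness with Ce nulls,
#' centrality and coreness, group-model scan, parasite viability/incidence,
#' and the richness models -- writing seven CSV reports plus a YAML manifest
#' (stage status, seeds, input checksums) to `outDir`.  All stochastic
#' stages draw their seeds from the master seed through named substreams, so
#' two runs with the same config are byte-identical.  If a stage fails, the
#' reports already written are kept and the manifest records the failure.
#'
#' @param config see [readPipelineConfig()].
#' @param outDir output directory (created if needed).
#' @return invisibly, a list with the in-memory stage results and the
#'   manifest.
#' @export
runPipeline <- function(config, outDir) {
  config <- readPipelineConfig(config)
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  master <- as.integer(config$seed)
  manifest <- list(seed = master, mode = if (is.null(config$webs))
    "synthetic" else "files", stages = list())
  results <- list()
  finishManifest <- function()
    yaml::write_yaml(manifest, file.path(outDir, "manifest.yaml"))
  on.exit(finishManifest())

  stage <- function(name, fun) {
    res <- tryCatch(fun(), error = function(e) {
      manifest$stages[[name]] <<- list(status = "failed",
                                       error = conditionMessage(e))
      finishManifest()
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
    manifest$stages[[name]] <<- list(status = "ok")
    res
  }

  # -- inputs ---------------------------------------------------------------
  webs <- stage("load_webs", function() {
    if (!is.null(config$webs)) {
      manifest$inputs <<- lapply(config$webs, function(p)
        list(path = p, md5 = unname(tools::md5sum(p))))
      lapply(config$webs, readAdjacency, transpose = config$transpose)
    } else {
      syn <- config$synthetic
      stats::setNames(lapply(names(syn), function(wn)
        do.call(generateWeb,
                c(syn[[wn]][setdiff(names(syn[[wn]]), "seed")],
                  list(seed = .substreamSeed(master,
                                             paste0("generate_web.", wn)))))),
        names(syn))
    }
  })
  records <- stage("load_parasites", function() {
    if (!is.null(config$parasites)) readParasiteTable(config$parasites)
    else if (!is.null(config$synthetic_parasites) ||
             is.null(config$webs)) {
      args <- config$synthetic_parasites
      do.call(generateParasites,
              c(list(web = webs[[1L]],
                     seed = .substreamSeed(master, "generate_parasites")),
                args))
    } else NULL
  })

  # -- web-level stages -----------------------------------------------------
  results$metrics <- stage("metrics", function() {
    tab <- do.call(rbind, lapply(names(webs), function(wn)
      cbind(web = wn, basicMetrics(webs[[wn]]))))
    .writeReport(tab, outDir, "web_metrics.csv")
    tab
  })
  results$degreeFits <- stage("degree_fits", function() {
    tab <- do.call(rbind, lapply(names(webs), function(wn) {
      f <- fitDegreeModels(cumulativeDegreeDistribution(webs[[wn]]))
      cbind(web = wn, f)
    }))
    .writeReport(tab, outDir, "degree_fits.csv")
    tab
  })
  results$nestedness <- stage("nestedness", function() {
    tab <- do.call(rbind, lapply(names(webs), function(wn)
      nestednessTable(nestednessAnalysis(
        webs[[wn]], replicates = config$replicates,
        seed = .substreamSeed(master, paste0("nestedness.", wn)),
        label = wn))))
    .writeReport(tab, outDir, "nestedness.csv")
    tab
  })
  results$centrality <- stage("centrality", function() {
    tab <- do.call(rbind, lapply(names(webs), function(wn) {
      cs <- centralitySuite(webs[[wn]])
      cs$coreness <- unname(corenessMinres(webs[[wn]])@coreness[cs$label])
      cbind(web = wn, cs)
    }))
    .writeReport(tab, outDir, "centrality.csv")
    tab
  })
  results$groups <- stage("groups", function() {
    parts <- lapply(names(webs), function(wn) {
      web <- webs[[wn]]
      if (!is.null(config$g_range)) {
        sc <- scanGroupSizes(web, config$g_range,
                             restarts = config$restarts,
                             seed = .substreamSeed(master,
                                                   paste0("groups.", wn)))
        sc$best
      } else if (is(web, "SyntheticFoodWeb")) {
        groupLoglikAic(web, plantedGroups(web))
      } else {
        annealPartition(web, g = max(2L, round(sqrt(nSpecies(web)))),
                        restarts = config$restarts,
                        seed = .substreamSeed(master,
                                              paste0("groups.", wn)))
      }
    })
    names(parts) <- names(webs)
    tab <- do.call(rbind, lapply(names(parts), function(wn)
      data.frame(web = wn, label = names(parts[[wn]]@partition),
                 group = unname(parts[[wn]]@partition),
                 g = parts[[wn]]@g, aic = parts[[wn]]@aic)))
    .writeReport(tab, outDir, "groups.csv")
    parts
  })
  results$incidence <- stage("incidence", function() {
    if (is.null(records)) return(NULL)
    tab <- do.call(rbind, lapply(names(webs), function(wn) {
      viable <- filterViableParasites(webs[[wn]], records,
                                      warnUnknown = FALSE)
      cbind(web = wn, hostRichness(webs[[wn]], viable))
    }))
    .writeReport(tab, outDir, "incidence.csv")
    tab
  })
  results$models <- stage("models", function() {
    if (is.null(records)) return(NULL)
    partitions <- lapply(results$groups, slot, "partition")
    rows <- buildPredictorTable(webs, partitions = partitions,
                                records = records)
    tf <- fitRegressionTree(rows,
                            seed = .substreamSeed(master, "tree"))
    ff <- fitRandomForest(rows, nTrees = config$n_trees,
                          seed = .substreamSeed(master, "forest"))
    rep <- importanceReport(treeFits = list(all = tf),
                            forestFits = list(all = ff))
    .writeReport(rep$report, outDir, "model_report.csv")
    list(tree = tf, forest = ff, report = rep, rows = rows)
  })
  manifest$package <- as.character(utils::packageVersion("trophicnets"))
  results$manifest <- manifest
  invisible(results)
}
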