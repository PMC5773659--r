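configError <- function(...) {
  stop(structure(class = c("litprop_config_error", "error", "condition"),
                 list(message = paste0(...), call = NULL)))
}

readGeneList <- function(path) {
  if (!file.exists(path)) configError("gene list not found: ", path)
  x <- trimws(readLines(path, warn = FALSE))
  x[nzchar(x)]
}

cfgGet <- function(config, name, default = NULL) {
  if (!is.null(config[[name]])) config[[name]] else default
}

cfgPath <- function(config, name) {
  p <- config[[name]]
  if (is.null(p)) configError("config is missing required path: ", name)
  if (!file.exists(p)) configError(name, " path does not exist: ", p)
  p
}

loadInputs <- function(config) {
  corpus <- readCorpus(cfgPath(config, "corpus"))
  dict <- readGeneDictionary(cfgPath(config, "dictionary"))
  list(corpus = corpus, dict = dict)
}

rankingInputs <- function(config) {
  inp <- loadInputs(config)
  knowns <- readGeneList(cfgPath(config, "known"))
  candidates <- if (!is.null(config$candidates))
    setdiff(readGeneList(cfgPath(config, "candidates")), knowns)
  else setdiff(dictionaryGenes(inp$dict), knowns)
  cutoff <- parseDate(cfgGet(config, "cutoff",
                             format(max(documents(inp$corpus)$date))))
  annotated <- annotateCorpus(sliceByDate(inp$corpus, cutoff), inp$dict,
                              policy = cfgGet(config, "policy", "strict"))
  eligK <- eligibleEntities(annotated, knowns, cutoff)
  if (length(eligK) < length(knowns))
    configError("known gene(s) without an eligible mention: ",
                paste(setdiff(knowns, eligK), collapse = ", "))
  eligC <- eligibleEntities(annotated, candidates, cutoff)
  profiles <- buildProfiles(annotated, c(knowns, eligC),
                            weighting = cfgGet(config, "weighting", "tfidf"))
  list(sim = similarityMatrix(profiles), knowns = knowns, candidates = eligC,
       corpus = inp$corpus, dict = inp$dict, cutoff = cutoff)
}

diffusionArgs <- function(config) {
  list(alpha = cfgGet(config, "alpha", 0.7),
       tol = cfgGet(config, "tol", 1e-9),
       maxIter = as.integer(cfgGet(config, "max_iter", 1000L)))
}

writeManifest <- function(config, command, outDir) {
  canonical <- jsonlite::toJSON(config[order(names(config))], auto_unbox = TRUE)
  tmp <- tempfile()
  writeLines(canonical, tmp)
  manifest <- list(command = command, config = config,
                   config_hash = unname(tools::md5sum(tmp)),
                   seed = cfgGet(config, "seed", NA),
                   package_version = as.character(utils::packageVersion("litprop")))
  unlink(tmp)
  jsonlite::write_json(manifest, file.path(outDir, "run_manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
}

#' Run the pipeline end to end
#'
#' Orchestrates the package's stages behind a single reproducible entry
#' point. `config` is a YAML file path or an equivalent named list; all
#' outputs are written under `config$out_dir` together with a
#' `run_manifest.json` recording the configuration, its hash and the seed,
#' so identical config plus seed reproduces identical outputs. Progress is
#' logged to standard error; results go only to files.
#'
#' Commands: `simulate` (synthetic corpus + dictionary + ground truth),
#' `annotate` (mention table as JSON), `rank` (candidate ranking TSV),
#' `loo` (leave-one-out report JSON), `retro` (retrospective report JSON).
#'
#' Config keys: paths `corpus`, `dictionary`, `known`, `candidates`
#' (optional), `later` (retro); `out_dir`; `cutoff`; diffusion `alpha`,
#' `tol`, `max_iter`; `weighting`; `policy`; `thresholds` (loo); `seed`
#' and `simulate:` sub-keys mirroring [syntheticParams()] arguments
#' (simulate).
#'
#' @param config YAML path or named list.
#' @param command one of "simulate", "annotate", "rank", "loo", "retro".
#' @return invisibly, a named list of the paths written.
#' @export
runPipeline <- function(config,
                        command = c("simulate", "annotate", "rank", "loo", "retro")) {
  command <- match.arg(command)
  if (is.character(config)) {
    if (!file.exists(config)) configError("config file not found: ", config)
    config <- yaml::read_yaml(config)
  }
  if (!is.list(config)) configError("config must be a YAML file or a list")
  outDir <- cfgGet(config, "out_dir")
  if (is.null(outDir)) configError("config is missing out_dir")
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  t0 <- proc.time()[["elapsed"]]

  paths <- switch(command,
    simulate = {
      sp <- config$simulate
      if (!is.null(config$seed)) sp$seed <- config$seed
      params <- tryCatch(do.call(syntheticParams, if (is.null(sp)) list() else sp),
                         error = function(e) configError("simulate: ",
                                                         conditionMessage(e)))
      out <- simulateCorpus(params)
      message("simulate: ", length(out$corpus), " documents, ",
              length(out$dictionary), " genes")
      corpusPath <- file.path(outDir, "corpus.jsonl")
      dictPath <- file.path(outDir, "dictionary.tsv")
      truthPath <- file.path(outDir, "ground_truth.json")
      writeCorpus(out$corpus, corpusPath)
      writeGeneDictionary(out$dictionary, dictPath)
      truth <- out$truth
      truth$discovery_date <- as.list(stats::setNames(
        format(truth$discovery_date), names(truth$discovery_date)))
      jsonlite::write_json(truth, truthPath, auto_unbox = TRUE, digits = NA)
      list(corpus = corpusPath, dictionary = dictPath, ground_truth = truthPath)
    },
    annotate = {
      inp <- loadInputs(config)
      annotated <- annotateCorpus(inp$corpus, inp$dict,
                                  policy = cfgGet(config, "policy", "strict"))
      message("annotate: ", nrow(mentions(annotated)), " mentions in ",
              length(inp$corpus), " documents")
      outPath <- file.path(outDir, "mentions.json")
      jsonlite::write_json(mentions(annotated), outPath, digits = NA)
      list(mentions = outPath)
    },
    rank = {
      ri <- rankingInputs(config)
      da <- diffusionArgs(config)
      ranked <- rankBySeeds(ri$sim, ri$knowns, ri$candidates,
                            alpha = da$alpha, tol = da$tol, maxIter = da$maxIter)
      message("rank: ", length(ri$knowns), " seeds, ",
              nrow(rankedCandidates(ranked)), " candidates ranked")
      outPath <- file.path(outDir, "ranked.tsv")
      writeRankedList(ranked, outPath)
      list(ranked = outPath)
    },
    loo = {
      ri <- rankingInputs(config)
      da <- diffusionArgs(config)
      thresholds <- as.integer(cfgGet(config, "thresholds", integer()))
      rep <- looReport(ri$sim, ri$knowns, ri$candidates, alpha = da$alpha,
                       tol = da$tol, maxIter = da$maxIter,
                       thresholds = thresholds)
      message("loo: AUC ", format(rep@auc, digits = 4),
              ", Wilcoxon p ", format(rep@wilcoxonP, digits = 3))
      outPath <- file.path(outDir, "report.json")
      jsonlite::write_json(c(list(loo_ranks = looRanks(rep)), reportStats(rep)),
                           outPath, auto_unbox = TRUE, digits = NA)
      list(report = outPath)
    },
    retro = {
      inp <- loadInputs(config)
      knowns <- readGeneList(cfgPath(config, "known"))
      later <- readGeneList(cfgPath(config, "later"))
      da <- diffusionArgs(config)
      cutoff <- cfgGet(config, "cutoff")
      if (is.null(cutoff)) configError("retro requires a cutoff date")
      rep <- retrospectiveRun(inp$corpus, inp$dict, cutoff, knowns, later,
                              weighting = cfgGet(config, "weighting", "tfidf"),
                              policy = cfgGet(config, "policy", "strict"),
                              alpha = da$alpha, tol = da$tol,
                              maxIter = da$maxIter)
      message("retro: ", rep$n_candidates, " candidates at cutoff ",
              format(rep$cutoff))
      outPath <- file.path(outDir, "retro.json")
      jsonlite::write_json(
        list(cutoff = format(rep$cutoff), n_candidates = rep$n_candidates,
             later_ranks = as.list(rep$later_ranks),
             later_percentiles = as.list(rep$later_percentiles),
             ineligible = rep$ineligible,
             ranking = rankedCandidates(rep$ranked)),
        outPath, auto_unbox = TRUE, digits = NA)
      list(retro = outPath)
    })

  writeManifest(config, command, outDir)
  message(command, " finished in ",
          round(proc.time()[["elapsed"]] - t0, 2), " s")
  invisible(c(paths, list(manifest = file.path(outDir, "run_manifest.json"))))
}
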