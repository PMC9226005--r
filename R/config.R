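## Unified run configuration (YAML) and the end-to-end orchestration:
## simulate -> pipeline -> classify -> enrich -> build dataset -> train ->
## evaluate -> interpret, with a machine-readable run manifest.

.block_constructors <- function() {
    list(simulate = SimulationConfig, pipeline = PipelineConfig,
         negative = NegativeConfig, model = ModelConfig)
}

.check_keys <- function(given, known, where) {
    unknown <- setdiff(given, known)
    if (!length(unknown)) return(invisible())
    key <- unknown[1]
    sugg <- agrep(key, known, max.distance = 0.3, value = TRUE)
    stop("unknown configuration key '", key, "' in ", where,
         if (length(sugg)) paste0("; did you mean '", sugg[1], "'?") else
             paste0("; known keys: ", paste(known, collapse = ", ")))
}

#' Load a run configuration from YAML
#'
#' The file may contain `simulate:`, `pipeline:`, `negative:` and
#' `model:` blocks (keys as in the corresponding constructor arguments)
#' plus the global keys `seed`, `log_level` and `outdir`.  Missing keys
#' take the package defaults; unknown keys are rejected with a
#' suggestion.  An empty or absent file yields all defaults.
#'
#' @param path YAML file, or `NULL` for pure defaults
#' @param seed overrides the global seed (and is threaded into every
#'   block that does not set its own)
#' @return list with the four config objects (`simulate`, `pipeline`,
#'   `negative`, `model`) and globals `seed`, `log_level`, `outdir`
#' @export
loadRunConfig <- function(path = NULL, seed = NULL) {
    raw <- list()
    if (!is.null(path)) {
        if (!file.exists(path)) stop("config file not found: ", path)
        raw <- yaml::read_yaml(path)
        if (is.null(raw)) raw <- list()
    }
    ctors <- .block_constructors()
    .check_keys(names(raw), c(names(ctors), "seed", "log_level", "outdir"),
                "the top level")
    global_seed <- seed %||% raw$seed %||% 1L
    if (!is.numeric(global_seed) || global_seed != as.integer(global_seed))
        stop("validation error: 'seed' must be an integer")
    out <- list(seed = as.integer(global_seed),
                log_level = raw$log_level %||% "info",
                outdir = raw$outdir %||% "results")
    for (block in names(ctors)) {
        ctor <- ctors[[block]]
        args <- raw[[block]] %||% list()
        .check_keys(names(args), names(formals(ctor)),
                    paste0("block '", block, "'"))
        if (!is.null(formals(ctor)$seed) && is.null(args$seed))
            args$seed <- out$seed
        out[[block]] <- tryCatch(do.call(ctor, args), error = function(e)
            stop("validation error in block '", block, "': ",
                 conditionMessage(e)))
    }
    out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run the full study end to end
#'
#' Simulates a dataset, runs the chimera pipeline, classifies isomiRs,
#' tests type enrichment, builds labelled pairs, splits 80/20, trains
#' the classifier, evaluates it on the held-out pairs and runs both
#' interpretation procedures.  All intermediate tables are written to
#' `outdir` under stable names together with a machine-readable
#' `manifest.json` (package version, seeds, and counts at every filter
#' stage); rerunning with the same seed reproduces the manifest counts.
#'
#' @param run_config list from [loadRunConfig()]
#' @param outdir output directory (defaults to the config's)
#' @param epochs training epochs (defaults to the model config's; the
#'   historical default of 500 is far more than the synthetic study
#'   needs)
#' @param interpret_pairs how many held-out pairs feed the perturbation
#'   scan
#' @return (invisibly) list with every intermediate object and the
#'   manifest
#' @export
runEndToEnd <- function(run_config = loadRunConfig(), outdir = NULL,
                        epochs = NULL, interpret_pairs = 50L) {
    outdir <- outdir %||% run_config$outdir
    dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
    stage <- function(name, expr) {
        tryCatch(expr, error = function(e)
            stop("stage '", name, "' failed: ", conditionMessage(e),
                 " (inputs under ", outdir, ")"))
    }
    sim <- stage("simulate",
                 simulateInteractionDataset(run_config$simulate,
                                            outdir = file.path(outdir,
                                                               "simulated")))
    pipe <- stage("pipeline",
                  runChimeraPipeline(sim$reads, sim$hits_mirna,
                                     sim$hits_transcript,
                                     sim$references$mirnas,
                                     run_config$pipeline))
    interactions <- pipe$interactions
    write.table(interactions, file.path(outdir, "interactions.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    iso_rows <- interactions[interactions$isomir_seq != "=", , drop = FALSE]
    isomir_calls <- stage("classify-isomirs", {
        if (!nrow(iso_rows)) data.frame(mirna_id = character(0),
                                        isomir_seq = character(0),
                                        offset_5p = integer(0),
                                        offset_3p = integer(0),
                                        mismatch_positions = character(0),
                                        types = character(0),
                                        support = integer(0)) else {
            anc <- lapply(seq_len(nrow(iso_rows)), function(i)
                anchorAlign(iso_rows$isomir_seq[i],
                            sim$references$mirnas[[iso_rows$mirna_id[i]]]))
            types <- vapply(seq_len(nrow(iso_rows)), function(i)
                paste(classifyIsomir(iso_rows$isomir_seq[i],
                                     sim$references$mirnas[[
                                         iso_rows$mirna_id[i]]]),
                      collapse = ";"), character(1))
            data.frame(mirna_id = iso_rows$mirna_id,
                       isomir_seq = iso_rows$isomir_seq,
                       offset_5p = vapply(anc, `[[`, 0L, "offset_5p"),
                       offset_3p = vapply(anc, `[[`, 0L, "offset_3p"),
                       mismatch_positions = vapply(anc, function(a)
                           paste(a$internal_mismatch_positions,
                                 collapse = ";"), character(1)),
                       types = types,
                       support = iso_rows$read_support,
                       stringsAsFactors = FALSE)
        }
    })
    write.table(isomir_calls, file.path(outdir, "isomir_calls.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    enrichment <- stage("enrich-types", {
        counts <- isomirTypeCounts(isomir_calls)
        if (nrow(counts)) typeEnrichment(counts) else counts
    })
    write.table(enrichment, file.path(outdir, "enrichment.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    pairs <- stage("build-dataset",
                   buildTrainingPairs(interactions,
                                      sim$references$transcripts,
                                      sim$references$utr,
                                      run_config$negative,
                                      seed = run_config$seed))
    write.table(pairs, file.path(outdir, "pairs.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    split <- stage("split", splitPairs(pairs, 0.8, "by_pair",
                                       seed = run_config$seed))
    net <- stage("train", {
        m <- buildModel(run_config$model)
        trainModel(m, split$train, epochs = epochs)
    })
    saveModel(net, file.path(outdir, "model.json"))
    pred <- stage("predict", predictPairs(net, split$test))
    write.table(cbind(split$test[, c("small_rna_seq", "site_seq", "label")],
                      pred),
                file.path(outdir, "predictions.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    metrics <- stage("evaluate", {
        if (length(unique(split$test$label)) == 2L)
            metricReport(split$test$label, pred$probability,
                         run_config$model@decision_threshold)
        else NULL
    })
    if (!is.null(metrics))
        jsonlite::write_json(metrics, file.path(outdir, "metrics.json"),
                             auto_unbox = TRUE, digits = NA)
    interp <- stage("interpret", {
        motifs <- suppressWarnings(extractKernelMotifs(net))
        sub <- head(split$test, interpret_pairs)
        scan <- if (nrow(sub) >= 2L) perturbationScan(net, sub) else NULL
        list(motifs = motifs, scan = scan)
    })
    if (!is.null(interp$scan)) {
        prof <- rbind(cbind(branch = "mirna", interp$scan$mirna),
                      cbind(branch = "site", interp$scan$site))
        write.table(prof, file.path(outdir, "profiles.tsv"), sep = "\t",
                    quote = FALSE, row.names = FALSE)
    }
    manifest <- list(
        package = "isomiRTarget",
        package_version = as.character(utils::packageVersion("isomiRTarget")),
        seed = run_config$seed,
        counts = c(as.list(pipe$stats),
                   list(pairs_pos = sum(pairs$label == 1),
                        pairs_neg = sum(pairs$label == 0),
                        train = nrow(split$train),
                        test = nrow(split$test))))
    jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    invisible(list(sim = sim, interactions = interactions,
                   isomir_calls = isomir_calls, enrichment = enrichment,
                   pairs = pairs, split = split, model = net,
                   predictions = pred, metrics = metrics,
                   interpret = interp, manifest = manifest))
}
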