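# End-to-end workflow: simulate (or load) -> Dollo -> enrichment ->
# birth-death fit -> shifts -> giant-branch analyses, with TSV outputs and
# a run manifest.  Every threshold default mirrors the analysis defaults
# used throughout the package.

#' Pipeline run configuration
#'
#' @param outDir output directory (created if absent).
#' @param seed integer seed used for every stochastic stage.
#' @param sim a [simConfig()] configuration to generate inputs, or
#'   \code{NULL} to read them from files.
#' @param nTips,treeDepth tree size/depth used when simulating.
#' @param treePath,countsPath paths to a Newick tree and a count table
#'   (orthofinder dialect), required when \code{sim} is NULL.
#' @param giantLabels character node labels of the giant branch set (used
#'   for both simulated and loaded trees); \code{NULL} picks the
#'   \code{k} longest tip branches when simulating.
#' @param sisterLabels optional node labels of the sister control set.
#' @param alpha shift/enrichment significance threshold (default 0.05).
#' @param maxCopies,minSpecies birth-death input filter (defaults 100, 2).
#' @param sMax kernel truncation (default 100).
#' @param k giant-set size for permutation draws (default 6).
#' @param nPerm permutation count (default 100).
#' @param nBoot bootstrap replicate count for the rate LRT (default 500;
#'   set 0 to skip the bootstrap stage).
#' @param proteinFrac,taxonFrac representative-annotation thresholds
#'   (defaults 0.75/0.75).
#' @param stages character vector of stages to run (default all).
#' @return a validated list of class \code{"RunConfig"}.
#' @export
runConfig <- function(outDir, seed, sim = NULL, nTips = 16L,
                      treeDepth = 450, treePath = NULL, countsPath = NULL,
                      giantLabels = NULL, sisterLabels = NULL,
                      alpha = 0.05, maxCopies = 100L, minSpecies = 2L,
                      sMax = 100L, k = 6L, nPerm = 100L, nBoot = 500L,
                      proteinFrac = 0.75, taxonFrac = 0.75,
                      stages = c("simulate", "dollo", "enrich", "bdfit",
                                 "shifts", "giants")) {
    if (missing(seed)) stop("seed is mandatory")
    if (is.null(sim) && (is.null(treePath) || is.null(countsPath)))
        stop("either a simulation config or tree/counts paths are required")
    if (!is.null(treePath) && !file.exists(treePath))
        stop("tree path does not exist: ", treePath)
    if (!is.null(countsPath) && !file.exists(countsPath))
        stop("counts path does not exist: ", countsPath)
    structure(list(outDir = outDir, seed = as.integer(seed), sim = sim,
                   nTips = as.integer(nTips), treeDepth = treeDepth,
                   treePath = treePath, countsPath = countsPath,
                   giantLabels = giantLabels, sisterLabels = sisterLabels,
                   alpha = alpha, maxCopies = as.integer(maxCopies),
                   minSpecies = as.integer(minSpecies),
                   sMax = as.integer(sMax), k = as.integer(k),
                   nPerm = as.integer(nPerm), nBoot = as.integer(nBoot),
                   proteinFrac = proteinFrac, taxonFrac = taxonFrac,
                   stages = stages),
              class = "RunConfig")
}

.stage <- function(name, manifest, outDir, config, expr) {
    t0 <- proc.time()[["elapsed"]]
    res <- tryCatch(expr, error = function(e)
        stop("stage '", name, "' failed: ", conditionMessage(e),
             call. = FALSE))
    for (f in res$files)
        manifest$rows[[length(manifest$rows) + 1L]] <- data.frame(
            stage = name, output = f,
            elapsed = round(proc.time()[["elapsed"]] - t0, 3))
    res$value
}

#' Run the full analysis pipeline
#'
#' Executes the configured stages in order (simulate or load inputs,
#' Dollo reconstruction and node accounting, term enrichment of novel
#' families, birth-death rate fitting with an optional bootstrap LRT,
#' branch shift tests and rates, and the giant-branch cancer analyses),
#' writing each result as a TSV under \code{outDir} and returning a run
#' manifest.  Any stage error aborts with the stage name.  Reruns with
#' the same configuration and seed are byte-identical.
#'
#' @param config a [runConfig()] configuration.
#' @return invisibly, a list with the manifest data.frame and the main
#'   in-memory results.
#' @export
runPipeline <- function(config) {
    stopifnot(inherits(config, "RunConfig"))
    dir.create(config$outDir, showWarnings = FALSE, recursive = TRUE)
    manifest <- new.env()
    manifest$rows <- list()
    out <- function(f) file.path(config$outDir, f)
    results <- list()
    doSim <- !is.null(config$sim) && "simulate" %in% config$stages

    # --- inputs -----------------------------------------------------------
    if (doSim) {
        tree <- simulateTimeTree(config$nTips, config$seed,
                                 config$treeDepth)
    } else {
        tree <- readNewick(config$treePath)
    }
    giant <- if (!is.null(config$giantLabels))
        branchSet(tree, config$giantLabels, "giant")
    else {
        tid <- tipIds(tree)
        branchSet(tree, tid[order(tree@brlen[tid],
                                  decreasing = TRUE)][seq_len(config$k)],
                  "giant")
    }
    sister <- if (!is.null(config$sisterLabels))
        branchSet(tree, config$sisterLabels, "sister") else NULL

    if (doSim) {
        sim <- config$sim
        sim$giantBranches <- setBranches(giant)
        simc <- .stage("simulate", manifest, config$outDir, config, {
            writeNewick(tree, out("tree.nwk"))
            cs <- simulateCounts(tree, sim)
            labs <- simulateLabels(cs$counts, cs$truth, sim)
            m <- famCounts(cs$counts)
            writeResultTsv(data.frame(Orthogroup = rownames(m), m,
                                      check.names = FALSE),
                           out("gene_counts.tsv"), config)
            writeResultTsv(data.frame(family = rownames(m),
                                      shifted = cs$truth$shifted,
                                      cancer = rownames(m) %in%
                                          setFamilies(labs$cancer)),
                           out("truth.tsv"), config)
            list(value = list(counts = cs$counts, truth = cs$truth,
                              labels = labs),
                 files = c("tree.nwk", "gene_counts.tsv", "truth.tsv"))
        })
        counts <- simc$counts
        cancer <- simc$labels$cancer
        ann <- simc$labels$annotations
        results$truth <- simc$truth
    } else {
        counts <- readGeneCounts(config$countsPath)
        checkSpeciesMatch(counts, tree)
        cancer <- NULL
        ann <- NULL
    }
    results$tree <- tree
    results$giant <- giant

    # --- Dollo ------------------------------------------------------------
    if ("dollo" %in% config$stages) {
        rec <- .stage("dollo", manifest, config$outDir, config, {
            rec <- dolloReconstruct(counts, tree)
            ns <- nodeSummaries(rec)
            writeResultTsv(data.frame(
                family = names(rec@origin), origin = rec@origin,
                nLosses = lengths(rec@losses),
                lossBranches = vapply(rec@losses, paste, "",
                                      collapse = ",")),
                out("dollo_families.tsv"), config)
            writeResultTsv(ns, out("dollo_nodes.tsv"), config)
            list(value = rec,
                 files = c("dollo_families.tsv", "dollo_nodes.tsv"))
        })
        results$dollo <- rec
    }

    # --- enrichment -------------------------------------------------------
    if ("enrich" %in% config$stages && !is.null(ann) &&
        !is.null(results$dollo)) {
        results$enrichment <- .stage("enrich", manifest, config$outDir,
                                     config, {
            famAnn <- assignFamilyAnnotations(ann, config$proteinFrac,
                                              config$taxonFrac)
            novelRoot <- names(results$dollo@origin)[
                results$dollo@origin == rootNode(tree)]
            uni <- familyIds(counts)
            enr <- termEnrichment(novelRoot, uni, famAnn, config$alpha)
            writeResultTsv(enr, out("enrichment_root_novel.tsv"), config)
            list(value = enr, files = "enrichment_root_novel.tsv")
        })
    }

    # --- birth-death fit --------------------------------------------------
    if ("bdfit" %in% config$stages && !is.null(results$dollo)) {
        bd <- .stage("bdfit", manifest, config$outDir, config, {
            filt <- filterForBD(counts, results$dollo, rootNode(tree),
                                config$maxCopies, config$minSpecies)
            classes2 <- rep("background", length(branchIds(tree)))
            names(classes2) <- as.character(branchIds(tree))
            classes2[as.character(setBranches(giant))] <- "giant"
            fit1 <- fitLambda(filt, tree, sMax = config$sMax,
                              conditionMinSpecies = config$minSpecies,
                              seed = config$seed)
            fit2 <- fitLambda(filt, tree, classes = classes2,
                              sMax = config$sMax,
                              conditionMinSpecies = config$minSpecies,
                              seed = config$seed)
            lrt <- NULL
            if (config$nBoot > 0)
                lrt <- lrtBootstrap(filt, tree, NULL, classes2,
                                    nReps = config$nBoot,
                                    seed = config$seed,
                                    sMax = config$sMax,
                                    conditionMinSpecies =
                                        config$minSpecies)
            fitTab <- data.frame(
                model = c("one-rate", rep("two-rate",
                                          length(fittedLambda(fit2)))),
                class = c("all", names(fittedLambda(fit2))),
                lambda = c(fittedLambda(fit1), fittedLambda(fit2)),
                logLik = c(fit1@logLik, rep(fit2@logLik,
                                            length(fittedLambda(fit2)))))
            if (!is.null(lrt)) {
                fitTab$lrt2dlnL <- lrt$observed
                fitTab$lrtP <- lrt$p
            }
            writeResultTsv(fitTab, out("bd_fit.tsv"), config)
            list(value = list(filtered = filt, oneRate = fit1,
                              twoRate = fit2, lrt = lrt),
                 files = "bd_fit.tsv")
        })
        results$bd <- bd
    }

    # --- shifts -----------------------------------------------------------
    if ("shifts" %in% config$stages && !is.null(results$bd)) {
        sh <- .stage("shifts", manifest, config$outDir, config, {
            anc <- ancestralStates(results$bd$filtered, tree,
                                   results$bd$twoRate@model)
            shifts <- branchShiftPvalues(anc, tree,
                                         results$bd$twoRate@model,
                                         config$alpha)
            rates <- branchRates(anc, tree)
            long <- data.frame(
                family = rep(rownames(shifts@p), ncol(shifts@p)),
                branch = rep(as.integer(colnames(shifts@p)),
                             each = nrow(shifts@p)),
                p = as.vector(shifts@p))
            long$rate <- rates$rate[match(paste(long$family, long$branch),
                                          paste(rates$family,
                                                rates$branch))]
            writeResultTsv(long, out("branch_shifts.tsv"), config)
            list(value = list(anc = anc, shifts = shifts, rates = rates),
                 files = "branch_shifts.tsv")
        })
        results$shifts <- sh
    }

    # --- giants -----------------------------------------------------------
    if ("giants" %in% config$stages && !is.null(results$shifts) &&
        !is.null(cancer)) {
        results$giants <- .stage("giants", manifest, config$outDir,
                                 config, {
            shifts <- results$shifts$shifts
            ss <- shiftedSets(shifts, giant)
            orAll <- branchSetEnrichment(shifts, giant, cancer,
                                         "all_families")
            orShift <- branchSetEnrichment(shifts, giant, cancer,
                                           "all_shifted")
            sis <- if (!is.null(sister))
                sisterControl(shifts, sister, cancer, "all_shifted")
            perm <- permutationNull(shifts, giant, cancer, tree,
                                    k = config$k, nPerm = config$nPerm,
                                    seed = config$seed)
            ratesShifted <- results$shifts$rates[
                results$shifts$rates$family %in% ss$allShifted, ]
            im <- tryCatch(interactionModel(ratesShifted, giant, cancer),
                           error = function(e) NULL)
            rr <- tryCatch(rateRatio(ratesShifted, giant, cancer),
                           error = function(e) NULL)
            enrTab <- data.frame(
                test = c("giant_vs_all", "giant_vs_shifted",
                         if (!is.null(sis)) "sister_vs_shifted",
                         "permutation"),
                oddsRatio = c(orAll$oddsRatio, orShift$oddsRatio,
                              if (!is.null(sis)) sis$oddsRatio,
                              perm$observedOR),
                p = c(orAll$p, orShift$p, if (!is.null(sis)) sis$p,
                      perm$p))
            writeResultTsv(enrTab, out("giant_enrichment.tsv"), config)
            writeResultTsv(data.frame(permutation = seq_along(perm$nullOR),
                                      nullOR = perm$nullOR),
                           out("permutation_null.tsv"), config)
            if (!is.null(im))
                writeResultTsv(im$coefficients,
                               out("interaction_model.tsv"), config)
            if (!is.null(rr))
                writeResultTsv(cbind(stratum = rownames(rr), rr),
                               out("rate_ratios.tsv"), config)
            list(value = list(shiftSets = ss, orAll = orAll,
                              orShifted = orShift, sister = sis,
                              permutation = perm, interaction = im,
                              rateRatios = rr),
                 files = c("giant_enrichment.tsv", "permutation_null.tsv",
                           if (!is.null(im)) "interaction_model.tsv",
                           if (!is.null(rr)) "rate_ratios.tsv"))
        })
    }

    mdf <- do.call(rbind, manifest$rows)
    mdf$seed <- config$seed
    writeResultTsv(mdf, out("manifest.tsv"), config)
    results$manifest <- mdf
    invisible(results)
}
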