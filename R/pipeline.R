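#' Pipeline configuration
#'
#' Bundles the three published constants of the prioritization
#' procedure — the Fold screen threshold (2.5), the Influence-Factor
#' band half-width (1) and the per-group selection size (3) — with the
#' table delimiter.
#'
#' @param foldThreshold positive Fold screen cutoff (default 2.5).
#' @param ifThreshold positive IF band half-width (default 1).
#' @param topK genes selected per group (default 3).
#' @param delimiter field separator for table output (default tab).
#' @return a validated `PipelineConfig` (list).
#' @export
pipelineConfig <- function(foldThreshold = 2.5, ifThreshold = 1.0,
                           topK = 3L, delimiter = "\t") {
    stopifnot(foldThreshold > 0, ifThreshold > 0, topK >= 1)
    structure(list(foldThreshold = foldThreshold,
                   ifThreshold = ifThreshold,
                   topK = as.integer(topK),
                   delimiter = delimiter),
              class = "PipelineConfig")
}

.logStage <- function(quiet, ...) {
    if (!quiet) message(...)
}

#' Run the full prioritization pipeline
#'
#' Deterministic composition of score -> screen -> classify -> select
#' and, when qPCR data are supplied, ddCt -> re-rank: per-gene log2
#' fold changes in both subsets, composite Fold/IF/Distance scores, the
#' absolute-Fold screen, six-group IF classification, per-group top-k
#' Distance selection, and qPCR-based recalculation of the Distance
#' that names the final target gene. Gene counts at every stage are
#' logged via `message()`.
#'
#' @param exp an [MDSCExperiment-class].
#' @param qpcr optional qPCR input: either a Ct table with a `subset`
#'   column (as from [readQpcr()]), or a precomputed delta table with
#'   columns `gene_id`, `delta_mo`, `delta_gr`.
#' @param config a [pipelineConfig()].
#' @param quiet suppress stage logging.
#' @return a [SelectionResult-class]; empty but valid (with a warning)
#'   when no gene passes the screen.
#' @examples
#' sim <- generateExperiment(sixGroupScenario(perGroup = 3, seed = 1))
#' res <- runPipeline(sim$experiment, quiet = TRUE)
#' nrow(selectedGenes(res))
#' @export
runPipeline <- function(exp, qpcr = NULL, config = pipelineConfig(),
                        quiet = FALSE) {
    stopifnot(is(exp, "MDSCExperiment"),
              inherits(config, "PipelineConfig"))
    scores <- scoreGenes(exp)
    .logStage(quiet, "input genes: ", nrow(scores))
    screened <- screenByFold(scores, config$foldThreshold)
    .logStage(quiet, "screened (|Fold| > ", config$foldThreshold,
              "): ", nrow(screened))
    if (nrow(screened) == 0L) {
        warning("no gene passes the Fold screen; empty selection")
        return(selectTopK(.emptyScores(), k = config$topK))
    }
    screened <- assignGroups(screened, config$ifThreshold)
    counts <- table(factor(screened$group, levels = GROUP_LEVELS))
    .logStage(quiet, "group sizes: ",
              paste(sprintf("%s=%d", names(counts), as.integer(counts)),
                    collapse = " "))
    result <- selectTopK(screened, k = config$topK)
    .logStage(quiet, "selected: ", nrow(selectedGenes(result)))
    if (!is.null(qpcr)) {
        deltas <- if (all(c("delta_mo", "delta_gr") %in%
                          colnames(qpcr))) {
            qpcr
        } else {
            qpcrDeltas(qpcrDdct(qpcr))
        }
        result <- rerankWithQpcr(result, deltas)
        .logStage(quiet, "final target after qPCR re-ranking: ",
                  finalTarget(result))
    }
    result
}

#' Plot coordinates of the (Fold, IF) plane
#'
#' Emits each gene's position in the two-dimensional prioritization
#' plot plus its band key, as a table; rendering is left to the caller
#' (e.g. `plot(fold, influence_factor)`).
#'
#' @param scores score data.frame from [computeScores()] /
#'   [scoreGenes()]; the `group` column is used when assigned,
#'   otherwise the band is derived from Fold sign and the IF band
#'   (`"unassigned"` when `fold == 0`).
#' @param ifThreshold IF band half-width used for unassigned rows.
#' @return data.frame with columns `gene_id`, `fold`,
#'   `influence_factor`, `band`.
#' @export
plotCoordinates <- function(scores, ifThreshold = 1.0) {
    stopifnot(is.data.frame(scores))
    band <- scores$group
    todo <- is.na(band)
    if (any(todo)) {
        nz <- todo & scores$fold != 0
        if (any(nz))
            band[nz] <- assignGroups(scores[nz, , drop = FALSE],
                                     ifThreshold)$group
        band[todo & scores$fold == 0] <- "unassigned"
    }
    data.frame(gene_id = scores$gene_id,
               fold = scores$fold,
               influence_factor = scores$influence_factor,
               band = band,
               stringsAsFactors = FALSE)
}
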