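#' Per-subset log2 fold change (treated vs control)
#'
#' For every gene, the mean log2 expression over the subset's treated
#' replicates minus the mean over its control replicates. Because the
#' input is on the log2 scale this equals the log2 of the geometric-mean
#' intensity ratio.
#'
#' @param exp an [MDSCExperiment-class].
#' @param subset `"Mo"` or `"Gr"`.
#' @return named numeric vector of log2 fold changes, one per gene.
#' @examples
#' sim <- generateExperiment(sixGroupScenario(perGroup = 1, seed = 1))
#' head(subsetLog2FC(sim$experiment, "Mo"))
#' @export
subsetLog2FC <- function(exp, subset = c("Mo", "Gr")) {
    stopifnot(is(exp, "MDSCExperiment"))
    subset <- match.arg(subset)
    cd <- colData(exp)
    treated <- cd$subset == subset & cd$condition == "treated"
    control <- cd$subset == subset & cd$condition == "control"
    if (!any(treated) || !any(control))
        stop("subset ", subset, " lacks treated or control samples")
    x <- assay(exp)
    rowMeans(x[, treated, drop = FALSE]) -
        rowMeans(x[, control, drop = FALSE])
}

#' Composite Fold, Influence Factor and Distance scores
#'
#' Given per-gene log2 fold changes in the Mo-MDSC and Gr-MDSC subsets,
#' computes the composite statistics that define the prioritization
#' plane:
#' \deqn{F = \Delta_{Mo} + \Delta_{Gr}}
#' \deqn{IF = F \times (\Delta_{Mo} - \Delta_{Gr})}
#' \deqn{D = \sqrt{F^2 + IF^2}}
#' `F` (Fold) is the summed response in log2 units; `IF` (Influence
#' Factor) is positive when the response is stronger in Mo-MDSCs and
#' negative when stronger in Gr-MDSCs, for up- and down-regulated genes
#' alike; `D` (Distance) is the distance from the origin of the
#' (Fold, IF) plot and is the ranking score.
#'
#' @param deltaMo,deltaGr numeric vectors of per-gene log2 fold changes
#'   (recycled against each other must be equal length).
#' @param geneIds optional character vector of gene identifiers;
#'   defaults to `names(deltaMo)`, or `gene_1 ...` if unnamed.
#' @return data.frame with columns `gene_id`, `delta_mo`, `delta_gr`,
#'   `fold`, `influence_factor`, `distance`, `group` (initialized to
#'   `NA`; see [assignGroups()]).
#' @examples
#' computeScores(c(a = 2.0, b = 1), c(a = 0.5, b = 1))
#' @export
computeScores <- function(deltaMo, deltaGr, geneIds = NULL) {
    if (length(deltaMo) != length(deltaGr))
        stop("deltaMo and deltaGr must have equal length")
    if (any(!is.finite(deltaMo)) || any(!is.finite(deltaGr)))
        stop("non-finite log2 fold change")
    if (is.null(geneIds)) {
        geneIds <- names(deltaMo)
        if (is.null(geneIds))
            geneIds <- if (length(deltaMo) > 0L)
                paste0("gene_", seq_along(deltaMo)) else character()
    }
    if (length(geneIds) != length(deltaMo))
        stop("geneIds length mismatch")
    fold <- deltaMo + deltaGr
    infl <- fold * (deltaMo - deltaGr)
    data.frame(gene_id = as.character(geneIds),
               delta_mo = unname(deltaMo),
               delta_gr = unname(deltaGr),
               fold = unname(fold),
               influence_factor = unname(infl),
               distance = unname(sqrt(fold^2 + infl^2)),
               group = rep(NA_character_, length(fold)),
               stringsAsFactors = FALSE)
}

#' Score every gene of an experiment
#'
#' Convenience composition of [subsetLog2FC()] for both subsets and
#' [computeScores()].
#'
#' @param exp an [MDSCExperiment-class].
#' @return score data.frame, one row per gene (see [computeScores()]).
#' @export
scoreGenes <- function(exp) {
    computeScores(subsetLog2FC(exp, "Mo"), subsetLog2FC(exp, "Gr"),
                  geneIds = geneIds(exp))
}
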