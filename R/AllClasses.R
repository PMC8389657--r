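#' @import methods
#' @importFrom SummarizedExperiment SummarizedExperiment assay colData
#' @importFrom S4Vectors DataFrame metadata metadata<-
NULL

## Six-group labels in Table-1 output order: the central band first
## (Up, Down), then Gr-dominant, then Mo-dominant.
GROUP_LEVELS <- c("Up", "Down", "Gr-Up", "Gr-Down", "Mo-Up", "Mo-Down")

SUBSET_LEVELS <- c("Mo", "Gr")
CONDITION_LEVELS <- c("control", "treated")

SCORE_COLUMNS <- c("gene_id", "delta_mo", "delta_gr", "fold",
                   "influence_factor", "distance", "group")

#' Container for a two-subset, two-condition expression experiment
#'
#' `MDSCExperiment` extends
#' [SummarizedExperiment][SummarizedExperiment::SummarizedExperiment-class]
#' and holds normalized log2 expression values (genes x samples) together
#' with the sample design: each sample is annotated with its MDSC
#' `subset` (`"Mo"` or `"Gr"`), its treatment `condition` (`"control"`
#' or `"treated"`), and a `replicate` index. Validity requires a
#' non-empty design cell for every subset/condition combination, unique
#' replicate indices within a cell, unique non-empty gene identifiers,
#' and no missing expression values.
#'
#' @seealso [MDSCExperiment()] for construction from a matrix and a
#'   design table, [readExpression()] for construction from files.
#' @aliases MDSCExperiment-class
#' @exportClass MDSCExperiment
setClass("MDSCExperiment", contains = "SummarizedExperiment")

setValidity("MDSCExperiment", function(object) {
    msg <- character()
    cd <- colData(object)
    needed <- c("subset", "condition", "replicate")
    missing_cols <- setdiff(needed, colnames(cd))
    if (length(missing_cols) > 0L)
        return(paste("design is missing column(s):",
                     paste(missing_cols, collapse = ", ")))
    if (!all(cd$subset %in% SUBSET_LEVELS))
        msg <- c(msg, sprintf("unknown subset token(s): %s",
            paste(unique(setdiff(cd$subset, SUBSET_LEVELS)), collapse = ", ")))
    if (!all(cd$condition %in% CONDITION_LEVELS))
        msg <- c(msg, sprintf("unknown condition token(s): %s",
            paste(unique(setdiff(cd$condition, CONDITION_LEVELS)),
                  collapse = ", ")))
    rep_idx <- cd$replicate
    if (!is.numeric(rep_idx) || any(!is.finite(rep_idx)) ||
        any(rep_idx < 1) || any(rep_idx != round(rep_idx)))
        msg <- c(msg, "replicate indices must be positive integers")
    if (length(msg) == 0L) {
        for (s in SUBSET_LEVELS) {
            for (co in CONDITION_LEVELS) {
                in_cell <- cd$subset == s & cd$condition == co
                if (!any(in_cell))
                    msg <- c(msg,
                        sprintf("empty design cell %s/%s", s, co))
                else if (anyDuplicated(rep_idx[in_cell]))
                    msg <- c(msg,
                        sprintf("duplicate replicate index in cell %s/%s",
                                s, co))
            }
        }
    }
    ids <- rownames(object)
    if (nrow(object) > 0L && (is.null(ids) || any(!nzchar(ids))))
        msg <- c(msg, "gene ids must be non-empty strings")
    else if (!is.null(ids) && anyDuplicated(ids))
        msg <- c(msg, sprintf("duplicate gene id: %s",
                              ids[duplicated(ids)][1L]))
    x <- assay(object)
    if (!is.numeric(x))
        msg <- c(msg, "expression values must be numeric")
    else if (anyNA(x) || any(!is.finite(x)))
        msg <- c(msg, "expression matrix contains missing or non-finite values")
    if (length(msg) == 0L) TRUE else msg
})

#' Result of screening, six-group classification and top-k selection
#'
#' Produced by [selectTopK()] and refined by [rerankWithQpcr()] /
#' [runPipeline()]. Slots:
#' \describe{
#'   \item{`screened`}{data.frame of gene scores passing the Fold screen
#'     (columns as written by [writeScores()]).}
#'   \item{`groups`}{named list, one element per group label in Table-1
#'     order (`Up`, `Down`, `Gr-Up`, `Gr-Down`, `Mo-Up`, `Mo-Down`),
#'     each a data.frame of the group's genes sorted by decreasing
#'     Distance (ties broken by gene id).}
#'   \item{`selected`}{data.frame of the per-group top-k genes, in group
#'     order, with `rank_in_group`.}
#'   \item{`finalRanking`}{data.frame of selected genes re-ranked by
#'     qPCR-recalculated Distance (`distance_qpcr`); genes without qPCR
#'     coverage follow the covered ones with `qpcr_covered = FALSE`.
#'     Zero rows until [rerankWithQpcr()] has run.}
#'   \item{`finalTarget`}{gene id with the largest recalculated
#'     Distance, or `NA_character_` before re-ranking.}
#' }
#'
#' @aliases SelectionResult-class
#' @exportClass SelectionResult
setClass("SelectionResult",
    representation(screened = "data.frame",
                   groups = "list",
                   selected = "data.frame",
                   finalRanking = "data.frame",
                   finalTarget = "character"))

setValidity("SelectionResult", function(object) {
    msg <- character()
    if (!identical(names(object@groups), GROUP_LEVELS))
        msg <- c(msg, "groups must be named by the six group labels")
    if (length(object@finalTarget) != 1L)
        msg <- c(msg, "finalTarget must be a single gene id or NA")
    sel <- object@selected
    if (nrow(sel) > 0L && anyDuplicated(sel$gene_id))
        msg <- c(msg, "a selected gene appears in more than one group")
    if (length(msg) == 0L) TRUE else msg
})
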