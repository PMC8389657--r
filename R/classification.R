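#' Screen genes by absolute Fold
#'
#' Retains genes with `|fold| > threshold` (strict inequality), keeping
#' input order. The screen is on the absolute value so that
#' down-regulated genes survive into the Down-side groups.
#'
#' @param scores score data.frame from [computeScores()].
#' @param threshold positive Fold cutoff; default 2.5.
#' @return the retained rows of `scores`.
#' @export
screenByFold <- function(scores, threshold = 2.5) {
    stopifnot(is.data.frame(scores), threshold > 0)
    scores[abs(scores$fold) > threshold, , drop = FALSE]
}

#' Assign the six Influence-Factor groups
#'
#' Each screened gene gets exactly one label from the sign of its Fold
#' and the position of its Influence Factor relative to the ±`ifThreshold`
#' band: `IF > t` is Mo-dominant (`Mo-Up` / `Mo-Down`), `IF < -t` is
#' Gr-dominant (`Gr-Up` / `Gr-Down`), and `|IF| <= t` (boundary
#' included) falls in the central band (`Up` / `Down`). The Up/Down half
#' is decided by the sign of Fold.
#'
#' @param scores score data.frame; every row must have `fold != 0`
#'   (guaranteed after [screenByFold()]).
#' @param ifThreshold positive half-width of the central IF band;
#'   default 1.
#' @return `scores` with the `group` column filled.
#' @export
assignGroups <- function(scores, ifThreshold = 1.0) {
    stopifnot(is.data.frame(scores), ifThreshold > 0)
    if (nrow(scores) == 0L)
        return(scores)
    if (any(scores$fold == 0))
        stop("cannot assign a group when fold is 0; screen first")
    up <- scores$fold > 0
    lab <- ifelse(scores$influence_factor > ifThreshold,
                  ifelse(up, "Mo-Up", "Mo-Down"),
           ifelse(scores$influence_factor < -ifThreshold,
                  ifelse(up, "Gr-Up", "Gr-Down"),
                  ifelse(up, "Up", "Down")))
    scores$group <- lab
    scores
}

## deterministic within-group order: Distance descending, gene id
## ascending on ties — makes selection invariant to input order
.orderGroup <- function(df) {
    df[order(-df$distance, df$gene_id), , drop = FALSE]
}

.emptyScores <- function() {
    data.frame(gene_id = character(), delta_mo = numeric(),
               delta_gr = numeric(), fold = numeric(),
               influence_factor = numeric(), distance = numeric(),
               group = character(), stringsAsFactors = FALSE)
}

.emptyRanking <- function() {
    data.frame(gene_id = character(), group = character(),
               rank_in_group = integer(), distance = numeric(),
               distance_qpcr = numeric(), qpcr_covered = logical(),
               is_final_target = logical(), stringsAsFactors = FALSE)
}

#' Select the top-k genes per group by Distance
#'
#' Within each of the six groups, genes are ordered by decreasing
#' Distance (ties broken by gene id ascending) and the top
#' `min(k, group size)` are taken. The selection is reported in fixed
#' group order `Up, Down, Gr-Up, Gr-Down, Mo-Up, Mo-Down`.
#'
#' @param screened score data.frame with `group` assigned (see
#'   [assignGroups()]).
#' @param k genes to keep per group; default 3.
#' @return a [SelectionResult-class] with `screened`, `groups` and
#'   `selected` populated; the qPCR slots stay empty until
#'   [rerankWithQpcr()].
#' @export
selectTopK <- function(screened, k = 3L) {
    stopifnot(is.data.frame(screened))
    if (k < 1)
        stop("k must be >= 1")
    if (nrow(screened) > 0L && anyNA(screened$group))
        stop("every screened gene needs a group; run assignGroups()")
    groups <- lapply(GROUP_LEVELS, function(g)
        .orderGroup(screened[!is.na(screened$group) &
                             screened$group == g, , drop = FALSE]))
    names(groups) <- GROUP_LEVELS
    sel_list <- lapply(groups, function(df)
        utils::head(df, n = min(k, nrow(df))))
    selected <- do.call(rbind, c(sel_list, list(make.row.names = FALSE)))
    if (nrow(selected) > 0L) {
        selected$rank_in_group <- unlist(lapply(sel_list, function(df)
            seq_len(nrow(df))), use.names = FALSE)
    } else {
        selected <- .emptyScores()
        selected$rank_in_group <- integer()
    }
    new("SelectionResult",
        screened = screened,
        groups = groups,
        selected = selected,
        finalRanking = .emptyRanking(),
        finalTarget = NA_character_)
}

#' Re-rank the selection with qPCR-derived fold changes
#'
#' Recomputes Fold, Influence Factor and Distance from per-subset qPCR
#' log2 fold changes (typically `log2_fold` values from [qpcrDdct()],
#' combined per gene by [qpcrDeltas()]) for the selected genes covered
#' by the qPCR table. Covered genes are ranked by the recalculated
#' Distance, descending, ties broken by gene id; genes without coverage
#' are appended, flagged, and can never become the final target.
#'
#' @param selection a [SelectionResult-class] from [selectTopK()].
#' @param qpcrScores data.frame with columns `gene_id`, `delta_mo`,
#'   `delta_gr` holding qPCR log2 fold changes per subset.
#' @return `selection` with `finalRanking` and `finalTarget` filled.
#' @export
rerankWithQpcr <- function(selection, qpcrScores) {
    stopifnot(is(selection, "SelectionResult"),
              is.data.frame(qpcrScores))
    needed <- c("gene_id", "delta_mo", "delta_gr")
    if (!all(needed %in% colnames(qpcrScores)))
        stop("qpcrScores needs columns gene_id, delta_mo, delta_gr")
    sel <- selection@selected
    hit <- match(sel$gene_id, qpcrScores$gene_id)
    if (nrow(sel) == 0L || all(is.na(hit)))
        stop("no selected gene is covered by the qPCR table")
    covered <- !is.na(hit)
    qsc <- computeScores(qpcrScores$delta_mo[hit[covered]],
                         qpcrScores$delta_gr[hit[covered]],
                         geneIds = sel$gene_id[covered])
    ranking <- data.frame(gene_id = sel$gene_id,
                          group = sel$group,
                          rank_in_group = sel$rank_in_group,
                          distance = sel$distance,
                          distance_qpcr = NA_real_,
                          qpcr_covered = covered,
                          is_final_target = FALSE,
                          stringsAsFactors = FALSE)
    ranking$distance_qpcr[covered] <- qsc$distance
    cov <- ranking[covered, , drop = FALSE]
    cov <- cov[order(-cov$distance_qpcr, cov$gene_id), , drop = FALSE]
    unc <- ranking[!covered, , drop = FALSE]
    unc <- unc[order(-unc$distance, unc$gene_id), , drop = FALSE]
    ranking <- rbind(cov, unc)
    rownames(ranking) <- NULL
    ranking$is_final_target <- seq_len(nrow(ranking)) == 1L
    selection@finalRanking <- ranking
    selection@finalTarget <- ranking$gene_id[1L]
    validObject(selection)
    selection
}

#' @describeIn selectTopK Screened gene scores.
#' @param x a `SelectionResult`.
#' @export
screenedGenes <- function(x) {
    stopifnot(is(x, "SelectionResult"))
    x@screened
}

#' @describeIn selectTopK Per-group ordered member tables.
#' @export
groupMembers <- function(x) {
    stopifnot(is(x, "SelectionResult"))
    x@groups
}

#' @describeIn selectTopK The per-group top-k selection table.
#' @export
selectedGenes <- function(x) {
    stopifnot(is(x, "SelectionResult"))
    x@selected
}

#' @describeIn selectTopK qPCR re-ranked table (empty before
#'   [rerankWithQpcr()]).
#' @export
finalRanking <- function(x) {
    stopifnot(is(x, "SelectionResult"))
    x@finalRanking
}

#' @describeIn selectTopK Final target gene id (`NA` before
#'   re-ranking).
#' @export
finalTarget <- function(x) {
    stopifnot(is(x, "SelectionResult"))
    x@finalTarget
}

setMethod("show", "SelectionResult", function(object) {
    cat("SelectionResult:", nrow(object@screened), "screened,",
        nrow(object@selected), "selected\n")
    sizes <- vapply(object@groups, nrow, integer(1))
    cat("  group sizes:",
        paste(sprintf("%s=%d", names(sizes), sizes), collapse = " "),
        "\n")
    if (!is.na(object@finalTarget))
        cat("  final target (qPCR re-ranked):", object@finalTarget, "\n")
    invisible(object)
})
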