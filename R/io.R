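## Table IO. Tab is the canonical delimiter; comma is accepted via the
## `delimiter` argument. Numeric values round-trip to 12 significant
## digits (written at 15).

.readTable <- function(path, delimiter = "\t") {
    if (!file.exists(path))
        stop("file not found: ", path)
    utils::read.delim(path, sep = delimiter, header = TRUE,
                      stringsAsFactors = FALSE, check.names = FALSE)
}

.writeTable <- function(df, path, delimiter = "\t") {
    num <- vapply(df, is.numeric, logical(1))
    df[num] <- lapply(df[num], function(x) sprintf("%.15g", x))
    ok <- tryCatch({
        utils::write.table(df, path, sep = delimiter, quote = FALSE,
                           row.names = FALSE, na = "")
        TRUE
    }, error = function(e) e)
    if (!isTRUE(ok))
        stop("cannot write ", path, ": ", conditionMessage(ok))
    invisible(NULL)
}

#' Read an expression matrix and its sample design
#'
#' The matrix file is delimited text with gene ids in the first column
#' (`gene_id`) and one column per sample; the design file maps every
#' sample id to `subset` (`Mo`/`Gr`), `condition` (`control`/`treated`)
#' and `replicate`. Column order of the matrix and row order of the
#' design are irrelevant: samples are joined on id. Missing values are
#' fatal unless `dropMissing = TRUE`, in which case genes with any
#' missing value are dropped with a message reporting the count (the
#' underlying assays provide no imputation rule, so none is applied).
#'
#' @param matrixPath,designPath paths to the two delimited files.
#' @param delimiter field separator, default tab.
#' @param dropMissing drop genes containing missing values instead of
#'   raising an error.
#' @return a validated [MDSCExperiment-class].
#' @export
readExpression <- function(matrixPath, designPath, delimiter = "\t",
                           dropMissing = FALSE) {
    mat_df <- .readTable(matrixPath, delimiter)
    if (ncol(mat_df) < 2L)
        stop("expression matrix needs a gene id column and >= 1 sample")
    ids <- as.character(mat_df[[1L]])
    if (anyDuplicated(ids))
        stop("duplicate gene id: ", ids[duplicated(ids)][1L])
    values <- as.matrix(mat_df[, -1L, drop = FALSE])
    suppressWarnings(storage.mode(values) <- "double")
    bad_cell <- is.na(values) & !is.na(as.matrix(mat_df[, -1L]))
    if (any(bad_cell))
        stop("non-numeric expression value for gene ",
             ids[which(rowSums(bad_cell) > 0)[1L]])
    rownames(values) <- ids
    if (anyNA(values)) {
        if (!dropMissing)
            stop("expression matrix contains missing values ",
                 "(use dropMissing = TRUE to drop affected genes)")
        drop <- rowSums(is.na(values)) > 0
        message("dropping ", sum(drop), " gene(s) with missing values")
        values <- values[!drop, , drop = FALSE]
    }
    design <- .readTable(designPath, delimiter)
    MDSCExperiment(values, design)
}

#' Write / read a gene score table
#'
#' Seven columns (`gene_id`, `delta_mo`, `delta_gr`, `fold`,
#' `influence_factor`, `distance`, `group`); these are also the plot
#' coordinates of the (Fold, IF) plane. Round-trips are lossless to 12
#' significant digits.
#'
#' @param scores score data.frame (see [computeScores()]).
#' @param path output/input path.
#' @param delimiter field separator, default tab.
#' @export
writeScores <- function(scores, path, delimiter = "\t") {
    stopifnot(is.data.frame(scores))
    missing_cols <- setdiff(SCORE_COLUMNS, colnames(scores))
    if (length(missing_cols) > 0L)
        stop("score table is missing column(s): ",
             paste(missing_cols, collapse = ", "))
    .writeTable(scores[, SCORE_COLUMNS, drop = FALSE], path, delimiter)
}

#' @rdname writeScores
#' @export
readScores <- function(path, delimiter = "\t") {
    df <- .readTable(path, delimiter)
    missing_cols <- setdiff(SCORE_COLUMNS, colnames(df))
    if (length(missing_cols) > 0L)
        stop("score table is missing column(s): ",
             paste(missing_cols, collapse = ", "))
    df$gene_id <- as.character(df$gene_id)
    df$group <- as.character(df$group)
    df$group[!is.na(df$group) & df$group == ""] <- NA_character_
    for (cc in setdiff(SCORE_COLUMNS, c("gene_id", "group")))
        df[[cc]] <- as.numeric(df[[cc]])
    df
}

#' Read a qPCR Ct table
#'
#' One row per gene (or per gene and subset when a `subset` column is
#' present) with the four replicate-averaged Ct values:
#' `ct_target_treated`, `ct_ref_treated`, `ct_target_control`,
#' `ct_ref_control`. Genes must be unique (within subset when given)
#' and Ct values finite and positive.
#'
#' @param path input path.
#' @param delimiter field separator, default tab.
#' @return validated data.frame of Ct records.
#' @export
readQpcr <- function(path, delimiter = "\t") {
    df <- .readTable(path, delimiter)
    ct_cols <- c("ct_target_treated", "ct_ref_treated",
                 "ct_target_control", "ct_ref_control")
    needed <- c("gene_id", ct_cols)
    missing_cols <- setdiff(needed, colnames(df))
    if (length(missing_cols) > 0L)
        stop("qPCR table is missing column(s): ",
             paste(missing_cols, collapse = ", "))
    df$gene_id <- as.character(df$gene_id)
    key <- if ("subset" %in% colnames(df))
        paste(df$gene_id, df$subset) else df$gene_id
    if (anyDuplicated(key))
        stop("duplicate gene id in qPCR table: ",
             df$gene_id[duplicated(key)][1L])
    for (cc in ct_cols) {
        x <- suppressWarnings(as.numeric(df[[cc]]))
        if (anyNA(x) || any(!is.finite(x)))
            stop("non-numeric or missing Ct value in column ", cc)
        if (any(x <= 0))
            stop("non-positive Ct value in column ", cc)
        df[[cc]] <- x
    }
    df
}

#' Write a selection table
#'
#' Emits the final ranking (or, before qPCR re-ranking, the selection)
#' as delimited text with columns `gene_id`, `group`, `rank_in_group`,
#' `distance`, `distance_qpcr` (empty when uncovered) and
#' `is_final_target`.
#'
#' @param selection a [SelectionResult-class].
#' @param path output path.
#' @param delimiter field separator, default tab.
#' @export
writeSelection <- function(selection, path, delimiter = "\t") {
    stopifnot(is(selection, "SelectionResult"))
    fr <- finalRanking(selection)
    if (nrow(fr) == 0L) {
        sel <- selectedGenes(selection)
        fr <- data.frame(gene_id = sel$gene_id,
                         group = sel$group,
                         rank_in_group = sel$rank_in_group,
                         distance = sel$distance,
                         distance_qpcr = rep(NA_real_, nrow(sel)),
                         is_final_target = rep(FALSE, nrow(sel)),
                         stringsAsFactors = FALSE)
    } else {
        fr <- fr[, c("gene_id", "group", "rank_in_group", "distance",
                     "distance_qpcr", "is_final_target"), drop = FALSE]
    }
    .writeTable(fr, path, delimiter)
}
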