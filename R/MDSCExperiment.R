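#' Construct an MDSCExperiment from a matrix and a design table
#'
#' @param values numeric matrix of normalized log2 expression, genes in
#'   rows (rownames are gene ids), samples in columns (colnames are
#'   sample ids).
#' @param design data.frame with columns `sample_id`, `subset`
#'   (`"Mo"`/`"Gr"`), `condition` (`"control"`/`"treated"`) and
#'   `replicate` (positive integer), one row per sample. Row order is
#'   irrelevant; samples are joined on `sample_id`.
#'
#' @return a validated [MDSCExperiment-class] object whose columns are
#'   ordered as in `values`.
#' @examples
#' design <- expand.grid(subset = c("Mo", "Gr"),
#'                       condition = c("control", "treated"),
#'                       replicate = 1:3, stringsAsFactors = FALSE)
#' design$sample_id <- with(design, paste(subset, condition, replicate, sep = "_"))
#' m <- matrix(7, nrow = 2, ncol = 12,
#'             dimnames = list(c("g1", "g2"), design$sample_id))
#' exp <- MDSCExperiment(m, design)
#' @export
MDSCExperiment <- function(values, design) {
    values <- as.matrix(values)
    if (is.null(colnames(values)))
        stop("expression matrix must have sample ids as column names")
    if (!is.data.frame(design))
        design <- as.data.frame(design)
    needed <- c("sample_id", "subset", "condition", "replicate")
    missing_cols <- setdiff(needed, colnames(design))
    if (length(missing_cols) > 0L)
        stop("design is missing column(s): ",
             paste(missing_cols, collapse = ", "))
    if (anyDuplicated(design$sample_id))
        stop("duplicate sample id in design: ",
             design$sample_id[duplicated(design$sample_id)][1L])
    not_in_design <- setdiff(colnames(values), design$sample_id)
    if (length(not_in_design) > 0L)
        stop("sample not in design: ",
             paste(not_in_design, collapse = ", "))
    not_in_matrix <- setdiff(design$sample_id, colnames(values))
    if (length(not_in_matrix) > 0L)
        stop("design sample absent from matrix: ",
             paste(not_in_matrix, collapse = ", "))
    design <- design[match(colnames(values), design$sample_id), ,
                     drop = FALSE]
    cd <- DataFrame(subset = as.character(design$subset),
                    condition = as.character(design$condition),
                    replicate = as.integer(design$replicate),
                    row.names = design$sample_id)
    se <- SummarizedExperiment(assays = list(log2exprs = values),
                               colData = cd)
    new("MDSCExperiment", se)
}

#' @describeIn MDSCExperiment Sample design as a data.frame
#'   (`sample_id`, `subset`, `condition`, `replicate`).
#' @param x an `MDSCExperiment`.
#' @export
sampleDesign <- function(x) {
    stopifnot(is(x, "MDSCExperiment"))
    cd <- colData(x)
    data.frame(sample_id = rownames(cd),
               subset = cd$subset,
               condition = cd$condition,
               replicate = cd$replicate,
               row.names = NULL,
               stringsAsFactors = FALSE)
}

#' @describeIn MDSCExperiment Normalized log2 expression matrix.
#' @export
log2Exprs <- function(x) {
    stopifnot(is(x, "MDSCExperiment"))
    assay(x, "log2exprs")
}

#' @describeIn MDSCExperiment Gene identifiers.
#' @export
geneIds <- function(x) {
    stopifnot(is(x, "MDSCExperiment"))
    rownames(x)
}

setMethod("show", "MDSCExperiment", function(object) {
    cd <- colData(object)
    cat("MDSCExperiment:", nrow(object), "genes x", ncol(object),
        "samples\n")
    tab <- table(subset = cd$subset, condition = cd$condition)
    cat("  samples per design cell:\n")
    for (s in SUBSET_LEVELS)
        for (co in CONDITION_LEVELS)
            cat(sprintf("    %s/%-8s %d\n", s, co, tab[s, co]))
    invisible(object)
})
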