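#' Relative expression by the delta-delta-Ct method
#'
#' Classic qPCR relative quantification with amplification efficiency
#' fixed at 2 and normalization to a reference gene (GAPDH in the
#' assays this models). Per record:
#' \deqn{\Delta Ct_{t} = Ct^{target}_{treated} - Ct^{ref}_{treated}}
#' \deqn{\Delta Ct_{c} = Ct^{target}_{control} - Ct^{ref}_{control}}
#' \deqn{\Delta\Delta Ct = \Delta Ct_{t} - \Delta Ct_{c}, \quad
#'       \mathrm{fold} = 2^{-\Delta\Delta Ct}}
#' Replicate Ct values are expected to be arithmetically averaged
#' before entry.
#'
#' @param qpcr data.frame of Ct quadruples as returned by [readQpcr()]:
#'   columns `gene_id`, optionally `subset`, `ct_target_treated`,
#'   `ct_ref_treated`, `ct_target_control`, `ct_ref_control`.
#' @return data.frame with `gene_id` (and `subset` if present), `ddct`,
#'   `fold_linear` (= 2^-ddct) and `log2_fold` (= -ddct).
#' @examples
#' qpcrDdct(data.frame(gene_id = "Mfge8",
#'                     ct_target_treated = 20, ct_ref_treated = 15,
#'                     ct_target_control = 22, ct_ref_control = 15))
#' @export
qpcrDdct <- function(qpcr) {
    stopifnot(is.data.frame(qpcr))
    ct_cols <- c("ct_target_treated", "ct_ref_treated",
                 "ct_target_control", "ct_ref_control")
    if (!all(ct_cols %in% colnames(qpcr)))
        stop("qPCR table needs columns ",
             paste(ct_cols, collapse = ", "))
    for (cc in ct_cols)
        if (!is.numeric(qpcr[[cc]]) || any(!is.finite(qpcr[[cc]])))
            stop("non-finite Ct value in column ", cc)
    ddct <- (qpcr$ct_target_treated - qpcr$ct_ref_treated) -
            (qpcr$ct_target_control - qpcr$ct_ref_control)
    out <- data.frame(gene_id = qpcr$gene_id,
                      stringsAsFactors = FALSE)
    if ("subset" %in% colnames(qpcr))
        out$subset <- qpcr$subset
    out$ddct <- ddct
    out$fold_linear <- 2^(-ddct)
    out$log2_fold <- -ddct
    out
}

#' Per-gene subset log2 fold changes from qPCR relative expression
#'
#' Pivots a per-subset [qpcrDdct()] result into the
#' `(gene_id, delta_mo, delta_gr)` table that [rerankWithQpcr()]
#' consumes. Every gene must be measured in both subsets.
#'
#' @param relExpr data.frame from [qpcrDdct()] with a `subset` column
#'   (`"Mo"`/`"Gr"`) and `log2_fold`.
#' @return data.frame with columns `gene_id`, `delta_mo`, `delta_gr`.
#' @export
qpcrDeltas <- function(relExpr) {
    stopifnot(is.data.frame(relExpr))
    if (!all(c("subset", "log2_fold") %in% colnames(relExpr)))
        stop("need per-subset qPCR results (columns subset, log2_fold)")
    if (!all(relExpr$subset %in% SUBSET_LEVELS))
        stop("unknown subset token in qPCR table")
    mo <- relExpr[relExpr$subset == "Mo", , drop = FALSE]
    gr <- relExpr[relExpr$subset == "Gr", , drop = FALSE]
    genes <- sort(unique(relExpr$gene_id))
    i_mo <- match(genes, mo$gene_id)
    i_gr <- match(genes, gr$gene_id)
    if (anyNA(i_mo) || anyNA(i_gr))
        stop("gene(s) missing a subset measurement: ",
             paste(genes[is.na(i_mo) | is.na(i_gr)], collapse = ", "))
    data.frame(gene_id = genes,
               delta_mo = mo$log2_fold[i_mo],
               delta_gr = gr$log2_fold[i_gr],
               stringsAsFactors = FALSE)
}
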