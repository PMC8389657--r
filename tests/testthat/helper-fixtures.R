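## programmatic fixtures: a full 2x2x3 design and a tiny matrix

fullDesign <- function(nReplicates = 3L) {
    d <- expand.grid(replicate = seq_len(nReplicates),
                     condition = c("control", "treated"),
                     subset = c("Mo", "Gr"),
                     stringsAsFactors = FALSE)
    d$sample_id <- with(d, paste(subset, condition, replicate, sep = "_"))
    d[, c("sample_id", "subset", "condition", "replicate")]
}

## constant-replicate matrix: each gene has fixed values per design cell
## cellValues: named list gene_id -> c(Mo_control, Mo_treated,
##                                     Gr_control, Gr_treated)
cellMatrix <- function(cellValues, nReplicates = 3L) {
    design <- fullDesign(nReplicates)
    m <- t(vapply(cellValues, function(v) {
        key <- paste(design$subset, design$condition, sep = "_")
        unname(c(Mo_control = v[1], Mo_treated = v[2],
                 Gr_control = v[3], Gr_treated = v[4])[key])
    }, numeric(nrow(design))))
    dimnames(m) <- list(names(cellValues), design$sample_id)
    m
}

writeTsv <- function(df, path) {
    write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
    path
}

writeMatrixTsv <- function(m, path) {
    writeTsv(data.frame(gene_id = rownames(m), m, check.names = FALSE),
             path)
}

randomScores <- function(n, seed = 42L) {
    set.seed(seed)
    sc <- computeScores(runif(n, -4, 4), runif(n, -4, 4),
                        geneIds = sprintf("r%03d", seq_len(n)))
    sc$group <- sample(c("Up", "Down", "Gr-Up", "Gr-Down",
                         "Mo-Up", "Mo-Down"), n, replace = TRUE)
    sc
}
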