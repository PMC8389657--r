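#' Configuration for a synthetic two-subset experiment
#'
#' Describes a simulated version of the study design: 2 MDSC subsets x
#' 2 conditions x `nReplicates` independent experiments. Per gene and
#' subset, control replicates are drawn from
#' `Normal(baseline_g, noiseSd)` and treated replicates from
#' `Normal(baseline_g + delta, noiseSd)`, with per-gene baselines
#' `baseline_g ~ Normal(baselineMean, baselineSd)` and `delta` taken
#' from the planted effects (0 for unplanted genes). All values are
#' log2 intensities; noise is Gaussian and homoscedastic across genes.
#'
#' @param nGenes number of genes (ids `g0001`, `g0002`, ...).
#' @param nReplicates independent experiments per design cell
#'   (default 3, the modeled study design).
#' @param noiseSd replicate noise SD in log2 units (default 0.2).
#' @param baselineMean,baselineSd per-gene baseline distribution in
#'   log2 units (defaults 7 and 1.5).
#' @param planted data.frame with columns `gene_id`, `true_delta_mo`,
#'   `true_delta_gr`; ids must be among the generated gene ids and
#'   unique. `NULL` means no planted effects.
#' @param seed integer driving all randomness.
#' @return a validated `SyntheticConfig` (list).
#' @export
syntheticConfig <- function(nGenes, nReplicates = 3L, noiseSd = 0.2,
                            baselineMean = 7.0, baselineSd = 1.5,
                            planted = NULL, seed = 1L) {
    stopifnot(nGenes >= 1, nReplicates >= 1, noiseSd >= 0,
              baselineSd >= 0, is.numeric(seed), length(seed) == 1L)
    gene_ids <- sprintf("g%04d", seq_len(nGenes))
    if (!is.null(planted)) {
        stopifnot(is.data.frame(planted),
                  all(c("gene_id", "true_delta_mo", "true_delta_gr")
                      %in% colnames(planted)))
        if (anyDuplicated(planted$gene_id))
            stop("duplicate planted gene id: ",
                 planted$gene_id[duplicated(planted$gene_id)][1L])
        if (!all(planted$gene_id %in% gene_ids))
            stop("planted gene id(s) outside the generated genes")
        if (any(!is.finite(planted$true_delta_mo)) ||
            any(!is.finite(planted$true_delta_gr)))
            stop("planted effects must be finite")
    }
    structure(list(nGenes = as.integer(nGenes),
                   geneIds = gene_ids,
                   nReplicates = as.integer(nReplicates),
                   noiseSd = noiseSd,
                   baselineMean = baselineMean,
                   baselineSd = baselineSd,
                   planted = planted,
                   seed = as.integer(seed)),
              class = "SyntheticConfig")
}

## true scores and (screened) groups implied by the planted effects
.syntheticTruth <- function(cfg, foldThreshold = 2.5,
                            ifThreshold = 1.0) {
    planted <- cfg$planted
    if (is.null(planted) || nrow(planted) == 0L)
        return(.emptyScores())
    truth <- computeScores(planted$true_delta_mo,
                           planted$true_delta_gr,
                           geneIds = planted$gene_id)
    pass <- abs(truth$fold) > foldThreshold
    if (any(pass))
        truth$group[pass] <-
            assignGroups(truth[pass, , drop = FALSE],
                         ifThreshold)$group
    truth
}

#' Generate a synthetic experiment with known ground truth
#'
#' @param cfg a [syntheticConfig()].
#' @return list with elements `experiment` (an
#'   [MDSCExperiment-class]) and `truth` (a score data.frame of the
#'   planted genes: true deltas, Fold, Influence Factor, Distance, and
#'   the group each gene would receive after a noise-free |Fold| > 2.5
#'   screen, `NA` for genes below it). Bit-identical for equal seeds.
#' @examples
#' cfg <- sixGroupScenario(perGroup = 2, seed = 7)
#' sim <- generateExperiment(cfg)
#' sim$experiment
#' head(sim$truth)
#' @export
generateExperiment <- function(cfg) {
    stopifnot(inherits(cfg, "SyntheticConfig"))
    old_seed <- if (exists(".Random.seed", globalenv()))
        get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old_seed))
        assign(".Random.seed", old_seed, globalenv()))
    set.seed(cfg$seed)

    n <- cfg$nGenes
    delta <- matrix(0, nrow = n, ncol = 2,
                    dimnames = list(cfg$geneIds, SUBSET_LEVELS))
    if (!is.null(cfg$planted)) {
        i <- match(cfg$planted$gene_id, cfg$geneIds)
        delta[i, "Mo"] <- cfg$planted$true_delta_mo
        delta[i, "Gr"] <- cfg$planted$true_delta_gr
    }
    design <- expand.grid(replicate = seq_len(cfg$nReplicates),
                          condition = CONDITION_LEVELS,
                          subset = SUBSET_LEVELS,
                          stringsAsFactors = FALSE)
    design <- design[, c("subset", "condition", "replicate")]
    design$sample_id <- with(design,
        paste(subset, condition, replicate, sep = "_"))

    baseline <- stats::rnorm(n, cfg$baselineMean, cfg$baselineSd)
    mu <- matrix(baseline, nrow = n, ncol = nrow(design))
    treated <- design$condition == "treated"
    mu[, treated] <- mu[, treated] +
        delta[, design$subset[treated], drop = FALSE]
    values <- mu + matrix(stats::rnorm(n * nrow(design),
                                       sd = cfg$noiseSd),
                          nrow = n)
    dimnames(values) <- list(cfg$geneIds, design$sample_id)
    list(experiment = MDSCExperiment(values, design),
         truth = .syntheticTruth(cfg))
}

#' Scenario populating all six classification groups
#'
#' Builds a [syntheticConfig()] that plants `perGroup` genes in each of
#' the six groups, plus unaffected background genes. Composite Fold
#' values are drawn uniformly with magnitude in [3, 6] (comfortably
#' past the 2.5 screen). Influence Factors are drawn uniformly with
#' magnitude in [1.2, 2.2] for the Mo-/Gr-dominant groups — strictly
#' beyond the ±1 band, with a margin, but small relative to Fold so
#' that all six groups have comparable Distance distributions — and in
#' [0, 0.5] inside the central band for Up/Down. At zero noise every
#' planted gene therefore survives the screen and lands in its intended
#' group, and under replicate noise a gene whose estimated IF crosses
#' the band boundary still competes on an equal Distance footing in the
#' neighbouring group, which keeps group-wise top-Distance recovery
#' high. Per-subset deltas are recovered from (F, IF) by
#' `delta_mo = (F + IF/F)/2`, `delta_gr = (F - IF/F)/2`.
#'
#' @param perGroup planted genes per group (default 5).
#' @param seed integer seed driving both the effect draws and,
#'   downstream, the replicate noise.
#' @param nBackground unaffected genes added on top (default 40).
#' @param nReplicates,noiseSd passed to [syntheticConfig()].
#' @return a `SyntheticConfig` with `6 * perGroup` planted genes.
#' @export
sixGroupScenario <- function(perGroup = 5L, seed = 1L,
                             nBackground = 40L, nReplicates = 3L,
                             noiseSd = 0.2) {
    stopifnot(perGroup >= 1, nBackground >= 0)
    old_seed <- if (exists(".Random.seed", globalenv()))
        get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old_seed))
        assign(".Random.seed", old_seed, globalenv()))
    ## decoupled stream so the same seed can drive the noise draws
    set.seed(bitwXor(as.integer(seed), 76543L))

    n_planted <- 6L * perGroup
    fold_sign <- c("Up" = 1, "Down" = -1, "Gr-Up" = 1, "Gr-Down" = -1,
                   "Mo-Up" = 1, "Mo-Down" = -1)
    if_kind <- c("Up" = "central", "Down" = "central",
                 "Gr-Up" = "gr", "Gr-Down" = "gr",
                 "Mo-Up" = "mo", "Mo-Down" = "mo")
    groups <- rep(GROUP_LEVELS, each = perGroup)
    fold <- fold_sign[groups] * stats::runif(n_planted, 3, 6)
    infl <- vapply(seq_len(n_planted), function(i) {
        switch(if_kind[groups[i]],
               central = stats::runif(1, -0.5, 0.5),
               mo = stats::runif(1, 1.2, 2.2),
               gr = stats::runif(1, -2.2, -1.2))
    }, numeric(1))
    diff_mo_gr <- infl / fold
    planted <- data.frame(
        gene_id = sprintf("g%04d", seq_len(n_planted)),
        true_delta_mo = (fold + diff_mo_gr) / 2,
        true_delta_gr = (fold - diff_mo_gr) / 2,
        stringsAsFactors = FALSE)
    syntheticConfig(nGenes = n_planted + nBackground,
                    nReplicates = nReplicates, noiseSd = noiseSd,
                    planted = planted, seed = seed)
}

#' Write a synthetic experiment to disk
#'
#' Emits the expression matrix, the design table and the planted-truth
#' score table as delimited text (the `simulate` step of the pipeline).
#'
#' @param sim list from [generateExperiment()].
#' @param matrixPath,designPath,truthPath output paths.
#' @param delimiter field separator, default tab.
#' @export
writeSyntheticExperiment <- function(sim, matrixPath, designPath,
                                     truthPath, delimiter = "\t") {
    exp <- sim$experiment
    mat_df <- data.frame(gene_id = geneIds(exp),
                         as.data.frame(log2Exprs(exp)),
                         check.names = FALSE,
                         stringsAsFactors = FALSE)
    .writeTable(mat_df, matrixPath, delimiter)
    .writeTable(sampleDesign(exp), designPath, delimiter)
    writeScores(sim$truth, truthPath, delimiter)
    invisible(NULL)
}
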