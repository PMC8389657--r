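test_that("Fold screen is strict, absolute and monotone in threshold", {
    sc <- computeScores(c(1.25, 1.3, -1.3, 0), c(1.25, 1.3, -1.3, 0),
                        geneIds = c("eq", "up", "down", "null"))
    ## folds are 2.5, 2.6, -2.6, 0
    kept <- screenByFold(sc, 2.5)
    expect_equal(kept$gene_id, c("up", "down"))  # 2.5 itself excluded
    expect_equal(nrow(screenByFold(sc, 0.5)), 3L)
    ## raising the threshold never adds a gene
    set.seed(21)
    rnd <- computeScores(runif(300, -4, 4), runif(300, -4, 4))
    thr <- seq(0.5, 6, by = 0.5)
    sizes <- vapply(thr, function(t) nrow(screenByFold(rnd, t)),
                    integer(1))
    expect_true(all(diff(sizes) <= 0))
    for (t in thr) {
        kept <- screenByFold(rnd, t)
        expect_true(all(abs(kept$fold) > t))
    }
})

test_that("group assignment follows the IF band rules, boundary to center", {
    sc <- data.frame(gene_id = letters[1:6],
                     delta_mo = 0, delta_gr = 0,
                     fold = c(2.5, -3.0, 2.5, 2.6, 3.0, -2.7),
                     influence_factor = c(3.75, 3.0, -3.75, 0, 1.0, -1.0),
                     distance = 1, group = NA_character_)
    got <- assignGroups(sc)$group
    expect_equal(got, c("Mo-Up",   # F>0, IF>1
                        "Mo-Down", # F<0, IF>1 (down, Mo-dominant)
                        "Gr-Up",   # F>0, IF<-1
                        "Up",      # IF = 0
                        "Up",      # IF = +1 boundary -> central band
                        "Down"))   # IF = -1 boundary -> central band
    zero <- sc; zero$fold[1] <- 0
    expect_error(assignGroups(zero), "fold is 0")
})

test_that("every screened gene gets exactly one of six labels", {
    ## exhaustive sign(F) x IF-band enumeration
    grid <- expand.grid(fold = c(-3, 3),
                        influence_factor = c(-2.5, -1, -0.3, 0, 0.3, 1, 2.5))
    grid$gene_id <- sprintf("e%02d", seq_len(nrow(grid)))
    grid$delta_mo <- 0; grid$delta_gr <- 0; grid$distance <- 1
    grid$group <- NA_character_
    lab <- assignGroups(grid)$group
    expect_false(anyNA(lab))
    expect_true(all(lab %in% c("Up", "Down", "Gr-Up", "Gr-Down",
                               "Mo-Up", "Mo-Down")))
    expect_setequal(unique(lab), c("Up", "Down", "Gr-Up", "Gr-Down",
                                   "Mo-Up", "Mo-Down"))
    ## the same holds for any positive threshold
    for (t in c(0.25, 1, 4))
        expect_false(anyNA(assignGroups(grid, t)$group))
})

test_that("swapping Mo and Gr exchanges Mo-/Gr- groups and fixes Up/Down", {
    set.seed(31)
    a <- runif(400, -4, 4); b <- runif(400, -4, 4)
    fwd <- assignGroups(screenByFold(computeScores(a, b)))
    rev <- assignGroups(screenByFold(computeScores(b, a)))
    expect_equal(rev$gene_id, fwd$gene_id)
    map <- c("Up" = "Up", "Down" = "Down",
             "Mo-Up" = "Gr-Up", "Gr-Up" = "Mo-Up",
             "Mo-Down" = "Gr-Down", "Gr-Down" = "Mo-Down")
    expect_equal(rev$group, unname(map[fwd$group]))
})

test_that("top-k selection takes min(k, size) per group in fixed order", {
    sc <- assignGroups(screenByFold(randomScores(120, seed = 8)))
    res <- selectTopK(sc, k = 3)
    sel <- selectedGenes(res)
    sizes <- vapply(groupMembers(res), nrow, integer(1))
    expect_equal(nrow(sel), sum(pmin(3, sizes)))
    expect_equal(unique(sel$group),
                 c("Up", "Down", "Gr-Up", "Gr-Down", "Mo-Up",
                   "Mo-Down")[sizes > 0])
    expect_false(anyDuplicated(sel$gene_id) > 0)
    ## within groups: distance non-increasing, ranks 1..k
    for (g in unique(sel$group)) {
        gs <- sel[sel$group == g, ]
        expect_true(all(diff(gs$distance) <= 0))
        expect_equal(gs$rank_in_group, seq_len(nrow(gs)))
        expect_equal(gs$distance,
                     sort(sc$distance[sc$group == g],
                          decreasing = TRUE)[seq_len(nrow(gs))])
    }
    ## an emptied group just contributes nothing
    res15 <- selectTopK(sc[sc$group != "Gr-Up", ], k = 3)
    expect_equal(nrow(selectedGenes(res15)),
                 sum(pmin(3, sizes[names(sizes) != "Gr-Up"])))
    expect_error(selectTopK(sc, k = 0), "k must be")
    expect_error(selectTopK(randomScores(5)[-7] |>
        transform(group = NA_character_)), "needs a group")
})

test_that("ties at the k-th rank break by gene id, making order irrelevant", {
    sc <- data.frame(gene_id = c("zz", "aa", "mm", "bb"),
                     delta_mo = 1, delta_gr = 1,
                     fold = 3, influence_factor = 0,
                     distance = c(5, 5, 9, 2), group = "Up")
    res <- selectTopK(sc, k = 2)
    expect_equal(selectedGenes(res)$gene_id, c("mm", "aa"))
    ## invariance under input permutation (all 24 orders)
    perms <- list(1:4, 4:1, c(2, 4, 1, 3), c(3, 1, 4, 2), c(2, 1, 3, 4))
    for (p in perms)
        expect_equal(selectedGenes(selectTopK(sc[p, ], k = 2))$gene_id,
                     c("mm", "aa"))
})

test_that("qPCR re-ranking orders by recalculated distance and names a target", {
    sc <- data.frame(gene_id = c("gA", "gB", "gC"),
                     delta_mo = c(2, 1.5, 1.6), delta_gr = c(1, 1.5, 1.6),
                     fold = c(3, 3, 3.2), influence_factor = c(3, 0, 0),
                     distance = c(sqrt(18), 3, 3.2),
                     group = c("Mo-Up", "Up", "Up"))
    res <- selectTopK(sc, k = 3)
    ## qPCR deltas (2, 0.5) -> D ~ 4.507 beats (1, 1) -> D = 2
    deltas <- data.frame(gene_id = c("gB", "gA"),
                         delta_mo = c(2, 1), delta_gr = c(0.5, 1))
    out <- rerankWithQpcr(res, deltas)
    fr <- finalRanking(out)
    expect_equal(finalTarget(out), "gB")
    expect_equal(fr$gene_id, c("gB", "gA", "gC"))
    expect_equal(fr$distance_qpcr[1], sqrt(2.5^2 + 3.75^2))
    expect_equal(fr$qpcr_covered, c(TRUE, TRUE, FALSE))
    expect_equal(fr$is_final_target, c(TRUE, FALSE, FALSE))
    ## uncovered genes can never become the target
    one <- rerankWithQpcr(res, deltas[2, ])
    expect_equal(finalTarget(one), "gA")
    ## idempotence: qPCR deltas equal to array deltas keep array order
    same <- rerankWithQpcr(res, sc[, c("gene_id", "delta_mo", "delta_gr")])
    expect_equal(finalRanking(same)$gene_id,
                 selectedGenes(res)$gene_id[
                     order(-selectedGenes(res)$distance,
                           selectedGenes(res)$gene_id)])
    expect_error(rerankWithQpcr(res,
        data.frame(gene_id = "nope", delta_mo = 1, delta_gr = 1)),
        "no selected gene")
})
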