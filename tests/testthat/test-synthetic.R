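test_that("generator is deterministic and validates its config", {
    cfg <- sixGroupScenario(perGroup = 2, seed = 77)
    a <- generateExperiment(cfg)
    b <- generateExperiment(cfg)
    expect_identical(log2Exprs(a$experiment), log2Exprs(b$experiment))
    expect_identical(a$truth, b$truth)
    c <- generateExperiment(sixGroupScenario(perGroup = 2, seed = 78))
    expect_false(identical(log2Exprs(a$experiment),
                           log2Exprs(c$experiment)))
    expect_error(syntheticConfig(10, planted = data.frame(
        gene_id = c("g0001", "g0001"), true_delta_mo = 1,
        true_delta_gr = 1)), "duplicate planted")
    expect_error(syntheticConfig(10, planted = data.frame(
        gene_id = "g9999", true_delta_mo = 1, true_delta_gr = 1)),
        "outside the generated genes")
})

test_that("zero-noise experiments reproduce the planted truth exactly", {
    cfg <- syntheticConfig(nGenes = 5, noiseSd = 0,
        planted = data.frame(gene_id = c("g0001", "g0002", "g0003"),
                             true_delta_mo = c(2.0, -1.2, 2.0),
                             true_delta_gr = c(0.5, -1.2, 1.0)),
        seed = 3)
    sim <- generateExperiment(cfg)
    sc <- scoreGenes(sim$experiment)
    expect_equal(sc$delta_mo[1:3], c(2.0, -1.2, 2.0), tolerance = 1e-12)
    expect_equal(sc$delta_gr[1:3], c(0.5, -1.2, 1.0), tolerance = 1e-12)
    expect_equal(sc$fold[1], 2.5, tolerance = 1e-12)
    expect_equal(sc$influence_factor[1], 3.75, tolerance = 1e-12)
    expect_equal(sc$distance[1], sqrt(2.5^2 + 3.75^2), tolerance = 1e-12)
    expect_equal(sc$fold[4:5], rep(0, 2), tolerance = 1e-12)
    ## truth carries the same closed forms; the screen is strict, so
    ## g0001 (|F| = 2.5 exactly) and g0002 (2.4) stay unassigned while
    ## g0003 (F = 3, IF = 3) is Mo-dominant
    expect_equal(sim$truth$distance,
                 c(sqrt(2.5^2 + 3.75^2), 2.4, sqrt(18)),
                 tolerance = 1e-12)
    expect_equal(sim$truth$group, c(NA, NA, "Mo-Up"))
})

test_that("six-group scenario plants the intended geometry", {
    cfg <- sixGroupScenario(perGroup = 5, seed = 10)
    expect_equal(nrow(cfg$planted), 30L)
    truth <- generateExperiment(cfg)$truth
    expect_equal(as.vector(table(factor(truth$group,
        levels = c("Up", "Down", "Gr-Up", "Gr-Down", "Mo-Up",
                   "Mo-Down")))), rep(5L, 6))
    expect_true(all(abs(truth$fold) > 2.5))
    ## per_group = 1 gives 6 selected; per_group = 3 at zero noise
    ## recovers exactly the 18 planted genes
    one <- generateExperiment(sixGroupScenario(perGroup = 1, seed = 4,
                                               noiseSd = 0))
    res1 <- runPipeline(one$experiment, quiet = TRUE)
    expect_equal(nrow(selectedGenes(res1)), 6L)
    three <- generateExperiment(sixGroupScenario(perGroup = 3, seed = 4,
                                                 noiseSd = 0))
    res3 <- runPipeline(three$experiment, quiet = TRUE)
    sel <- selectedGenes(res3)
    expect_equal(nrow(sel), 18L)
    expect_setequal(sel$gene_id, three$truth$gene_id)
    m <- match(sel$gene_id, three$truth$gene_id)
    expect_equal(sel$group, three$truth$group[m])
})

test_that("replicate noise propagates into delta estimates as sqrt(2/n)*sd", {
    ## SE of a difference of two 3-replicate means: 0.2 * sqrt(2/3)
    cfg0 <- syntheticConfig(nGenes = 1, noiseSd = 0.2,
        planted = data.frame(gene_id = "g0001", true_delta_mo = 2.0,
                             true_delta_gr = 0), seed = 1)
    est <- vapply(seq_len(1000), function(s) {
        cfg <- cfg0; cfg$seed <- s
        unname(subsetLog2FC(generateExperiment(cfg)$experiment, "Mo"))
    }, numeric(1))
    expect_equal(sd(est), 0.2 * sqrt(2 / 3), tolerance = 0.08)
    ## unbiasedness of the estimated delta
    expect_equal(mean(est) - 2.0, 0, tolerance = 0.01)
})

test_that("synthetic experiments round-trip through the table writers", {
    sim <- generateExperiment(sixGroupScenario(perGroup = 2, seed = 5))
    mp <- tempfile(fileext = ".tsv"); dp <- tempfile(fileext = ".tsv")
    tp <- tempfile(fileext = ".tsv")
    writeSyntheticExperiment(sim, mp, dp, tp)
    back <- readExpression(mp, dp)
    expect_equal(log2Exprs(back), log2Exprs(sim$experiment),
                 tolerance = 1e-12)
    expect_equal(sampleDesign(back), sampleDesign(sim$experiment))
    expect_equal(readScores(tp), sim$truth, tolerance = 1e-12)
})
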