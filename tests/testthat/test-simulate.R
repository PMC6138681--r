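test_that("identical configurations produce byte-identical fixtures", {
    eff <- plantedEffects(c("mirA", "geneA"), c("miRNA", "gene"),
                          c(2, -1), "fully_reverted", c(500, 1))
    cfg <- simulationConfig(seed = 42, n_genes = 12, n_mirnas = 30,
                            effects = eff)
    expect_identical(assay(simulateCqExperiment(cfg), "cq"),
                     assay(simulateCqExperiment(cfg), "cq"))
    expect_identical(assay(simulateMirnaCounts(cfg), "counts"),
                     assay(simulateMirnaCounts(cfg), "counts"))
    # a different seed changes the draw
    cfg2 <- simulationConfig(seed = 43, n_genes = 12, n_mirnas = 30,
                             effects = eff)
    expect_false(identical(assay(simulateMirnaCounts(cfg), "counts"),
                           assay(simulateMirnaCounts(cfg2), "counts")))
})

test_that("noise-free Cq simulation encodes effects as cycle shifts", {
    eff <- plantedEffects(c("g_null", "g_up2"), "gene", c(0, 2),
                          "not_modulated", 1)
    cfg <- simulationConfig(seed = 3, n_genes = 2, effects = eff,
                            cq_noise_sd = 0)
    cq <- assay(simulateCqExperiment(cfg), "cq")
    grp <- sampleGroups(simulateCqExperiment(cfg))
    # null effect: identical Cq in all groups
    expect_equal(unname(diff(range(cq["g_null", ]))), 0)
    # +2 log2 up-regulation: IR crosses threshold exactly 2 cycles earlier
    expect_equal(unique(cq["g_up2", grp == "Sham"]) -
                     unique(cq["g_up2", grp == "IR"]), 2)
})

test_that("invalid simulation configurations are rejected", {
    expect_error(simulationConfig(n_per_group = 1), "n_per_group")
    expect_error(simulationConfig(n_genes = 0), "positive")
    expect_error(simulationConfig(dispersion = 0), "dispersion")
    expect_error(simulationConfig(library_size_range = c(10, 5)),
                 "library_size_range")
    expect_error(simulationConfig(prediction_fp_rate = 1.5), "\\[0, 1\\]")
    expect_error(plantedEffects("x", "gene", 1, "mostly_reverted", 1),
                 "t3_class")
})

test_that("counts approach the Poisson limit as dispersion vanishes", {
    eff <- plantedEffects(sprintf("m%04d", 1:1200), "miRNA", 0,
                          "not_modulated", 500)
    cfg <- simulationConfig(seed = 9, n_mirnas = 1200, dispersion = 1e-6,
                            library_size_range = c(1e6, 1e6),
                            effects = eff)
    k <- assay(simulateMirnaCounts(cfg, groups = c("Sham", "IR")), "counts")
    # 1200 features x 10 samples of iid NB(mu = 500, alpha ~ 0)
    expect_gt(length(k), 1e4 - 1)
    expect_equal(var(as.vector(k)) / mean(k), 1, tolerance = 0.05)
})

test_that("planted fold changes are recovered by group means", {
    eff <- plantedEffects(c(sprintf("up%02d", 1:25),
                            sprintf("nul%02d", 1:25)),
                          "miRNA", rep(c(2, 0), each = 25),
                          "not_modulated", 1000)
    cfg <- simulationConfig(seed = 11, n_mirnas = 50, effects = eff)
    mce <- simulateMirnaCounts(cfg, groups = c("Sham", "IR"))
    k <- assay(mce, "counts")
    lib <- S4Vectors::metadata(mce)$library_sizes
    z <- sweep(k, 2, lib / 1e6, "/")
    grp <- as.character(sampleGroups(mce))
    ratio <- rowMeans(z[, grp == "IR"]) / rowMeans(z[, grp == "Sham"])
    # calibration band for a planted 4-fold effect
    expect_gt(mean(ratio[1:25]), 3.5)
    expect_lt(mean(ratio[1:25]), 4.6)
    # null features are unbiased on average
    expect_equal(mean(ratio[26:50]), 1, tolerance = 0.1)
    # under near-Poisson noise every null feature stays within 1.2-fold
    cfgp <- simulationConfig(seed = 11, n_mirnas = 50, effects = eff,
                             dispersion = 0.005)
    mcep <- simulateMirnaCounts(cfgp, groups = c("Sham", "IR"))
    kp <- assay(mcep, "counts")
    zp <- sweep(kp, 2, S4Vectors::metadata(mcep)$library_sizes / 1e6, "/")
    gp <- as.character(sampleGroups(mcep))
    rp <- rowMeans(zp[, gp == "IR"]) / rowMeans(zp[, gp == "Sham"])
    expect_true(all(rp[26:50] > 1 / 1.2 & rp[26:50] < 1.2))
})

test_that("target predictions contain truth and calibrated decoys", {
    genes <- sprintf("g%03d", 1:100)
    targets <- lapply(1:10, function(i) genes[((i - 1) * 5 + 1):(i * 5)])
    eff <- plantedEffects(c(sprintf("mir%02d", 1:10), genes),
                          c(rep("miRNA", 10), rep("gene", 100)),
                          1, "fully_reverted", 100,
                          targets = c(targets, rep(list(character()), 100)))
    p0 <- simulateTargetPredictions(eff, fp_rate = 0, seed = 5)
    expect_setequal(paste(p0$mirna, p0$gene),
                    unlist(lapply(1:10, function(i)
                        paste(sprintf("mir%02d", i), targets[[i]]))))
    expect_true(all(p0$provenance == "true"))
    p1 <- simulateTargetPredictions(eff, fp_rate = 1, seed = 5)
    expect_equal(nrow(unique(p1[, c("mirna", "gene")])), 10 * 100)
    # decoy count within 3 sigma of the binomial expectation
    p01 <- simulateTargetPredictions(eff, fp_rate = 0.1, seed = 5)
    n_decoy <- sum(p01$provenance == "decoy")
    expn <- 0.1 * (1000 - 50)
    expect_lt(abs(n_decoy - expn), 3 * sqrt(expn * 0.9))
})

test_that("annotation fixture plants a strongly enriched term", {
    genes <- sprintf("g%03d", 1:100)
    eff <- plantedEffects(genes, "gene",
                          c(rep(2, 10), rep(0, 90)), "fully_reverted", 1)
    ann <- simulateAnnotations(eff, n_terms = 5, term_size = 10, seed = 2)
    expect_length(ann, 5)
    expect_true(all(genes[1:10] %in% ann$term_enriched))
    res <- overrepresentationTest(genes[1:10], ann, universe = genes)
    expect_lt(res$p[res$term == "term_enriched"], 1e-6)
})

test_that("interaction-edge fixture plants a top-degree hub", {
    nodes <- sprintf("v%02d", 1:20)
    ed <- simulateInteractionEdges(nodes, hubs = "v01", n_hub_edges = 8,
                                   density = 0.1, seed = 4)
    g <- buildInteractionGraph(ed, min_score = 0.7)
    hr <- hubRanking(g)
    expect_equal(hr$node[1], "v01")
    expect_gte(hr$degree[1], 8)
    # jitter disabled -> configured scores reproduced exactly
    ed0 <- simulateInteractionEdges(nodes, hubs = "v01", density = 0.2,
                                    hub_score = 0.9,
                                    background_score = 0.5,
                                    jitter = FALSE, seed = 4)
    expect_setequal(unique(ed0$combined_score), c(0.9, 0.5))
})

test_that("every emitted feature appears exactly once in the truth table", {
    eff <- plantedEffects(c("mirA", "geneA"), c("miRNA", "gene"),
                          2, "fully_reverted", c(500, 1))
    cfg <- simulationConfig(seed = 6, n_genes = 15, n_mirnas = 40,
                            effects = eff)
    ce <- simulateCqExperiment(cfg)
    mce <- simulateMirnaCounts(cfg)
    truth_g <- S4Vectors::metadata(ce)$truth
    truth_m <- S4Vectors::metadata(mce)$truth
    targets <- setdiff(rownames(ce), referenceAssays(ce))
    expect_setequal(truth_g$feature_id, targets)
    expect_false(anyDuplicated(truth_g$feature_id) > 0)
    expect_setequal(truth_m$feature_id, rownames(mce))
    expect_false(anyDuplicated(truth_m$feature_id) > 0)
})

test_that("benchmark effect tables match their declared designs", {
    rev <- reversalBenchmarkEffects()
    expect_equal(sum(rev$t3_class == "fully_reverted"), 11)
    expect_equal(sum(rev$t3_class == "not_modulated"), 5)
    expect_true(all(abs(rev$ir_log2fc) >= 2))
    expect_true(all(rev$base_abundance >= 500))
    de <- dysregulationBenchmarkEffects()
    expect_equal(sum(de$ir_log2fc < 0), 42)
    expect_equal(sum(de$ir_log2fc > 0), 60)
    expect_true(all(abs(de$ir_log2fc) >= 2))
    # designs are frozen: two calls agree
    expect_identical(de, dysregulationBenchmarkEffects())
})
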