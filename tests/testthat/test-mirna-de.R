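test_that("size factors follow the median-of-ratios definition", {
    expect_equal(estimateSizeFactors(cbind(c(10, 20, 30), c(20, 40, 60))),
                 c(1 / sqrt(2), sqrt(2)))
    m <- matrix(rpois(40, 50), ncol = 4)
    expect_equal(estimateSizeFactors(cbind(m[, 1], m[, 1])), c(1, 1))
    # doubling one sample's counts doubles its factor relative to others
    sf1 <- estimateSizeFactors(m)
    m2 <- m; m2[, 2] <- m2[, 2] * 2
    sf2 <- estimateSizeFactors(m2)
    expect_equal(sf2[2] / sf2[1], 2 * sf1[2] / sf1[1], tolerance = 1e-12)
    # after normalization, each sample's median ratio to the feature
    # geometric means is 1
    set.seed(4)
    k <- matrix(rnbinom(600, mu = 200, size = 5), ncol = 6)
    sf <- estimateSizeFactors(k)
    kp <- k[rowSums(k > 0) == 6, ]
    lr <- log(kp) - rowMeans(log(kp))     # log ratios to geometric means
    med <- apply(sweep(lr, 2, log(sf), "-"), 2, median)
    expect_equal(unname(med), rep(0, 6), tolerance = 1e-12)
})

test_that("size factors agree with the reference implementation", {
    set.seed(5)
    k <- matrix(rnbinom(1000, mu = 150, size = 4), ncol = 10)
    ref <- DESeq2::estimateSizeFactorsForMatrix(k)
    expect_equal(unname(estimateSizeFactors(k)), unname(ref),
                 tolerance = 1e-10)
})

test_that("rpm normalization scales counts by library size", {
    expect_equal(normalizeRpm(matrix(100), 1e6)[1, 1], 100)
    expect_equal(normalizeRpm(matrix(50), 5e5)[1, 1], 100)
    k <- rbind(a = c(0, 0), b = c(5, 5))
    expect_equal(normalizeRpm(k, c(1e6, 1e6))["a", ], c(0, 0))
    expect_error(normalizeRpm(matrix(1), 0), "positive")
})

test_that("dispersion estimation recovers the method-of-moments value", {
    d <- estimateDispersions(matrix(c(5, 15), 1), c(1, 1), c("A", "A"))
    expect_equal(d$dispersion_raw, 0.4)   # (50 - 10) / 100
    # zero-variance replicates clamp to the floor
    d0 <- estimateDispersions(matrix(c(7, 7, 7), 1), c(1, 1, 1),
                              c("A", "A", "A"))
    expect_equal(d0$dispersion_raw, 1e-8)
    expect_error(estimateDispersions(matrix(1:2, 1), c(1, 1), c("A", "B")),
                 "replicated")
})

test_that("dispersion is recovered from simulated data at alpha = 0.2", {
    set.seed(6)
    k <- matrix(rnbinom(500 * 10, mu = 400, size = 5), ncol = 10)
    d <- estimateDispersions(k, rep(1, 10), rep(c("A", "B"), each = 5))
    expect_gt(median(d$dispersion), 0.1)
    expect_lt(median(d$dispersion), 0.4)
})

test_that("the exact NB test degenerates correctly", {
    expect_equal(nbExactTest(7, 7, rep(1, 5), rep(1, 5), 0.2), 1)
    expect_equal(nbExactTest(0, 0, rep(1, 5), rep(1, 5), 0.2), 1)
    expect_equal(nbExactTest(0, 10, rep(1, 5), rep(1, 5), 0), 2 / 1024)
    expect_error(nbExactTest(-1, 3, 1, 1, 0.1), "non-negative")
})

test_that("at zero dispersion the NB test equals the conditional binomial",
{
    for (case in list(c(0, 10), c(2, 8), c(3, 17), c(25, 25), c(1, 40))) {
        a <- case[1]; K <- sum(case)
        expect_equal(nbExactTest(a, K - a, rep(1, 5), rep(1, 5), 0),
                     condBinomOracle(a, K), info = paste(case, collapse = ","))
    }
})

test_that("NB-test type-I error is near nominal under the null", {
    set.seed(7)
    n_sim <- 2000
    rej <- logical(n_sim)
    for (i in seq_len(n_sim)) {
        k <- rnbinom(10, mu = 100, size = 5)
        rej[i] <- nbExactTest(sum(k[1:5]), sum(k[6:10]), rep(1, 5),
                              rep(1, 5), 0.2) < 0.05
    }
    expect_lte(mean(rej), 0.07)
})

test_that("BH adjustment equals the brute-force step-up definition", {
    expect_equal(adjustBH(c(0.001, 0.01, 0.02, 0.9)),
                 c(0.004, 0.02, 1 / 37.5, 0.9))
    expect_equal(adjustBH(rep(0.03, 5)), rep(0.03, 5))
    expect_equal(adjustBH(0.2), 0.2)
    expect_error(adjustBH(c(0.5, 1.2)), "\\[0, 1\\]")
    set.seed(8)
    for (i in 1:20) {
        p <- runif(sample(1:40, 1))
        expect_equal(adjustBH(p), bhOracle(p))
    }
})

test_that("DE filters implement the three criteria plus force-include", {
    res <- data.frame(feature_id = c("a", "b", "c", "d", "e"),
                      baseMean = 1, rpm_mean = c(150, 150, 50, 150, 20),
                      log2FC = c(log2(2.5), log2(1.8), 2, 2, -0.1),
                      dispersion = 0.1,
                      p = 0.001, p_adj = c(0.01, 0.01, 0.01, 0.2, 0.9))
    de <- callDE(res)
    expect_equal(de$de, c(TRUE, FALSE, FALSE, FALSE, FALSE))
    expect_equal(de$direction[1], "up")
    forced <- callDE(res, force_include = "e")
    expect_true(forced$de[5])
    expect_true(forced$forced[5])
    expect_false(forced$passes_filters[5])
    expect_error(callDE(res, fold_min = 0), "positive")
})

test_that("p_adj never falls below p and filters match the flag", {
    eff <- dysregulationBenchmarkEffects()
    cfg <- simulationConfig(seed = 2, n_mirnas = 300,
                            effects = eff[1:40, ])
    mce <- simulateMirnaCounts(cfg, groups = c("Sham", "IR"))
    de <- callDE(mirnaDE(mce, c("IR", "Sham")))
    ok <- !is.na(de$p_adj)
    expect_true(all(de$p_adj[ok] >= de$p[ok]))
    expect_equal(de$passes_filters,
                 ok & abs(de$log2FC) >= 1 & de$rpm_mean > 100 &
                     de$p_adj < 0.05)
})

test_that("the DE stage attains high sensitivity and controlled FDR on
           planted effects", {
    eff <- dysregulationBenchmarkEffects()
    cfg <- simulationConfig(seed = 12, n_mirnas = 600, effects = eff)
    mce <- simulateMirnaCounts(cfg, groups = c("Sham", "IR"))
    de <- callDE(mirnaDE(mce, c("IR", "Sham")))
    called <- de$feature_id[de$de]
    tp <- length(intersect(called, eff$feature_id))
    expect_gte(tp / nrow(eff), 0.9)
    expect_lte((length(called) - tp) / max(length(called), 1), 0.1)
})
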