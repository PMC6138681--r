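mkCq <- function(values, group, ref = paste0("r", 1:3)) {
    CqExperiment(values, group, ref)
}

test_that("delta-Cq subtracts the per-sample reference mean", {
    cq <- matrix(c(20, 21, 19, 24,
                   21, 22, 20, 21), ncol = 2,
                 dimnames = list(c("r1", "r2", "r3", "g"), c("s1", "s2")))
    d <- deltaCq(mkCq(cq, c("Sham", "Sham")))
    expect_equal(d["g", "s1"], 4)       # 24 - mean(20, 21, 19)
    expect_equal(d["g", "s2"], 0)       # target equals reference mean
    # single reference assay degenerates to a pairwise difference
    cq1 <- matrix(c(20, 24), ncol = 1, dimnames = list(c("r1", "g"), "s1"))
    expect_equal(deltaCq(CqExperiment(cq1, "Sham", "r1"))["g", "s1"], 4)
    # a sample with every reference missing is an error naming it
    cq_na <- cq; cq_na[1:3, 2] <- NA
    expect_error(deltaCq(mkCq(cq_na, c("Sham", "Sham"))), "s2")
})

test_that("delta-delta-Cq quantities are calibrated to the control group", {
    d <- matrix(c(5, 5, 4, 6), nrow = 1,
                dimnames = list("g", paste0("s", 1:4)))
    fc <- relativeQuantity(d, c("Sham", "Sham", "IR", "IR"), "Sham")
    q <- quantityMatrix(fc)
    expect_equal(q["g", "s3"], 2)       # ddCq = 4 - 5 = -1 -> 2^1
    expect_equal(q["g", "s1"], 1)       # calibrator sample at its mean
    expect_equal(q["g", "s3"] * q["g", "s4"], 1)  # +1/-1 multiplicativity
    expect_error(relativeQuantity(d, rep("IR", 4), "Sham"), "calibrator")
})

test_that("calibrator normalization and Cq scale invariance hold", {
    set.seed(1)
    cq <- matrix(rnorm(9 * 12, 24, 2), nrow = 9,
                 dimnames = list(c(paste0("r", 1:3), paste0("g", 1:6)),
                                 paste0("s", 1:12)))
    grp <- rep(c("Sham", "IR", "IRT3"), each = 4)
    fc <- relativeQuantity(deltaCq(mkCq(cq, grp)), grp, "Sham")
    q <- quantityMatrix(fc)
    # geometric mean of calibrator quantities is 1
    expect_equal(exp(rowMeans(log(q[, grp == "Sham"]))),
                 setNames(rep(1, 6), paste0("g", 1:6)))
    # adding a constant to all Cq of one sample leaves quantities unchanged
    cq2 <- cq; cq2[, "s5"] <- cq2[, "s5"] + 3.7
    q2 <- quantityMatrix(relativeQuantity(deltaCq(mkCq(cq2, grp)), grp,
                                          "Sham"))
    expect_equal(q2, q)
})

test_that("fold-change summaries use linear-interpolation quartiles", {
    q <- rbind(g1 = c(1, 2, 3, 4, 5), g2 = c(2, 2, 2, 2, 2))
    colnames(q) <- paste0("s", 1:5)
    fc <- new("FoldChangeTable", quantity = q,
              group = factor(rep("IR", 5)), calibrator = "IR")
    s <- summarizeFoldChanges(fc)
    expect_equal(s$median_IR, c(3, 2))
    expect_equal(s$iqr_IR, c(2, 0))
    # a group with < 2 samples warns and reports a missing IQR
    fc1 <- new("FoldChangeTable", quantity = q[, 1, drop = FALSE],
               group = factor("IR"), calibrator = "IR")
    expect_warning(s1 <- summarizeFoldChanges(fc1), "IQR")
    expect_true(all(is.na(s1$iqr_IR)))
})

test_that("exact Mann-Whitney matches enumeration on frozen cases", {
    expect_equal(mannWhitneyExact(1:5, 6:10), 2 / 252)
    expect_equal(mannWhitneyExact(1:5, 1:5), 1)
    # the minimal two-sided exact p at n = m = 5 clears the 0.017 level
    expect_lt(mannWhitneyExact(1:5, 6:10), 0.017)
    expect_error(mannWhitneyExact(numeric(0), 1:3), "non-empty")
})

test_that("exact Mann-Whitney agrees with the brute-force oracle", {
    set.seed(20)
    for (n in 2:6) for (m in 2:(min(6, 12 - n))) {
        x <- sample(1:6, n, replace = TRUE)   # ties likely
        y <- sample(1:6, m, replace = TRUE)
        expect_equal(mannWhitneyExact(x, y), mwOracle(x, y),
                     info = sprintf("n=%d m=%d", n, m))
        x2 <- rnorm(n); y2 <- rnorm(m)        # continuous, no ties
        expect_equal(mannWhitneyExact(x2, y2), mwOracle(x2, y2))
    }
})

test_that("large-sample Mann-Whitney matches the corrected normal
           approximation", {
    set.seed(21)
    x <- rnorm(12); y <- rnorm(10, 1)
    ref <- suppressWarnings(stats::wilcox.test(x, y, exact = FALSE,
                                               correct = FALSE))$p.value
    expect_equal(mannWhitneyExact(x, y), ref, tolerance = 1e-10)
})

test_that("Kruskal-Wallis statistic and gatekeeping behave as specified", {
    expect_equal(kruskalWallis(list(1:5, 6:10, 11:15))$statistic, 12.5)
    same <- kruskalWallis(list(c(1, 2, 3), c(1, 2, 3), c(1, 2, 3)))
    expect_equal(same$statistic, 0)
    expect_equal(same$p.value, 1)
    expect_error(kruskalWallis(list(1:5)), ">= 2")
    # two-group H is the squared standardized rank-sum statistic
    set.seed(3)
    x <- rnorm(6); y <- rnorm(7)
    H <- kruskalWallis(list(x, y))$statistic
    N <- 13; r <- rank(c(x, y))
    z2 <- (sum(r[1:6]) - 6 * (N + 1) / 2)^2 / (6 * 7 * (N + 1) / 12)
    expect_equal(H, z2)
})

test_that("panel classification flags a strong planted reversal", {
    eff <- plantedEffects(c("g_rev", "g_null"), "gene", c(2, 0),
                          c("fully_reverted", "not_modulated"), 1)
    cfg <- simulationConfig(seed = 8, n_genes = 2, effects = eff,
                            cq_noise_sd = 0.01)
    ce <- simulateCqExperiment(cfg)
    fc <- relativeQuantity(deltaCq(ce), sampleGroups(ce), "Sham")
    pan <- classifyPanel(fc)
    rec <- pan[pan$feature_id == "g_rev", ]
    expect_true(rec$flag_star)
    expect_true(rec$flag_hash)
    expect_equal(rec$direction_ir, "up")
    nul <- pan[pan$feature_id == "g_null", ]
    expect_false(nul$flag_star)
    expect_false(nul$flag_hash)
})

test_that("the exact test is conservative at the panel alpha level", {
    # empirical type-I error of the IR-vs-Sham flag at alpha = 0.017
    set.seed(30)
    rej <- replicate(2000, mannWhitneyExact(rnorm(5), rnorm(5)) < 0.017)
    expect_lte(mean(rej), 0.025)
})

test_that("the Bonferroni per-comparison level reproduces the panel
           threshold", {
    expect_equal(bonferroniAlpha(0.05, 3), 0.017)
})
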