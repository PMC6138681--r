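mkCalls <- function(ids, dirs, forced = FALSE) {
    data.frame(feature_id = ids, direction_t3shift = dirs,
               forced = forced, stringsAsFactors = FALSE)
}

test_that("only predicted, anti-modulated couples are retained", {
    mir <- mkCalls(c("miR-1", "miR-2"), c("up", "up"))
    gene <- mkCalls(c("Tp53", "Myc"), c("down", "up"))
    pred <- data.frame(mirna = c("miR-1", "miR-2"),
                       gene = c("Tp53", "Myc"))
    cc <- crossAntimodulated(mir, gene, pred)
    # miR-1 up / Tp53 down with an edge -> retained
    expect_equal(nrow(cc), 1)
    expect_equal(cc$mirna, "miR-1")
    expect_equal(cc$gene, "Tp53")
    # miR-2 up / Myc up -> excluded despite the edge;
    # miR-1 / Myc anti-modulated but no edge -> excluded
    expect_false("Myc" %in% cc$gene)
    expect_setequal(uncoveredGenes(cc), "Myc")
})

test_that("identifier matching is case-insensitive and unknown ids are
           skipped, not fatal", {
    mir <- mkCalls("MIR-9", "up")
    gene <- mkCalls("tp53", "down")
    pred <- data.frame(mirna = c("mir-9", "mir-unknown"),
                       gene = c("TP53", "Nosuchgene"))
    expect_message(cc <- crossAntimodulated(mir, gene, pred), "skipped")
    expect_equal(nrow(cc), 1)
})

test_that("circuit output is contained in predictions and reverted sets,
           and recrossing is idempotent", {
    set.seed(16)
    mirs <- sprintf("miR-%02d", 1:8)
    genes <- sprintf("Gene%02d", 1:15)
    mir <- mkCalls(mirs, sample(c("up", "down"), 8, TRUE))
    gene <- mkCalls(genes, sample(c("up", "down"), 15, TRUE))
    pred <- expand.grid(mirna = mirs, gene = genes,
                        stringsAsFactors = FALSE)
    pred <- pred[runif(nrow(pred)) < 0.3, ]
    cc <- crossAntimodulated(mir, gene, pred)
    key <- function(d, a, b) paste(tolower(d[[a]]), tolower(d[[b]]))
    expect_true(all(key(cc, "mirna", "gene") %in%
                        key(pred, "mirna", "gene")))
    expect_true(all(cc$mirna %in% mirs) && all(cc$gene %in% genes))
    expect_true(all(cc$mirna_direction != cc$gene_direction))
    cc2 <- crossAntimodulated(mir, gene,
                              cc[, c("mirna", "gene")])
    expect_equal(cc2[, c("mirna", "gene")], cc[, c("mirna", "gene")])
    # anti-symmetry: flipping miRNA directions retains the complementary
    # predicted pairs
    mir_fl <- mir
    mir_fl$direction_t3shift <- ifelse(mir$direction_t3shift == "up",
                                       "down", "up")
    cc_fl <- crossAntimodulated(mir_fl, gene, pred)
    all_pred <- unique(key(pred, "mirna", "gene"))
    both <- c(key(cc, "mirna", "gene"), key(cc_fl, "mirna", "gene"))
    expect_setequal(both, all_pred)
    expect_false(any(duplicated(both)))
})

test_that("family-map entries inherit the members' direction and forced
           miRNAs are flagged", {
    mir <- mkCalls(c("miR-30a", "miR-30c"), c("up", "up"), forced = TRUE)
    gene <- mkCalls("Col1a2", "down")
    pred <- data.frame(mirna = "30-fam", gene = "Col1a2")
    fam <- data.frame(family = "30-fam", member = c("miR-30a", "miR-30c"))
    cc <- crossAntimodulated(mir, gene, pred, family_map = fam)
    expect_equal(nrow(cc), 1)
    expect_equal(cc$mirna, "30-fam")
    expect_true(cc$forced_mirna)
    # disagreeing member directions invalidate the family entry
    mir2 <- mkCalls(c("miR-30a", "miR-30c"), c("up", "down"))
    expect_warning(cc2 <- crossAntimodulated(mir2, gene, pred,
                                             family_map = fam),
                   "disagree")
    expect_equal(nrow(cc2), 0)
})

test_that("multiplicity, cooperativity and overlap match brute-force set
           arithmetic", {
    set.seed(17)
    mirs <- sprintf("m%02d", 1:6)
    genes <- sprintf("g%02d", 1:10)
    mir <- mkCalls(mirs, "up")
    gene <- mkCalls(genes, "down")
    pred <- expand.grid(mirna = mirs, gene = genes,
                        stringsAsFactors = FALSE)
    pred <- pred[runif(nrow(pred)) < 0.4, ]
    # ensure one miRNA has no retained target
    pred <- pred[pred$mirna != "m06", ]
    cc <- crossAntimodulated(mir, gene, pred)
    st <- circuitStats(cc)
    tg <- lapply(mirs, function(m) sort(unique(cc$gene[cc$mirna == m])))
    names(tg) <- mirs
    for (m in mirs)
        expect_equal(st$cooperativity$n_targets[
            st$cooperativity$mirna == m], length(tg[[m]]))
    expect_true("m06" %in% st$cooperativity$mirna)
    for (g in unique(cc$gene))
        expect_equal(st$multiplicity$n_mirnas[st$multiplicity$gene == g],
                     sum(cc$gene == g))
    for (i in mirs) for (j in mirs)
        expect_equal(st$overlap[i, j],
                     length(intersect(tg[[i]], tg[[j]])))
    expect_equal(st$coverage,
                 length(unique(cc$gene)) /
                     (length(unique(cc$gene)) + length(uncoveredGenes(cc))))
    expect_warning(st0 <- circuitStats(cc[0, ]), "empty")
    expect_equal(nrow(st0$multiplicity), 0)
})
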