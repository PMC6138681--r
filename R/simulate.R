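#' Configuration for the synthetic-data generator
#'
#' Bundles every tunable of the fixture generator: the three-arm design
#' (Sham surgery, ischemia-reperfusion, ischemia-reperfusion plus T3
#' replacement), replicate number, negative-binomial dispersion, sequencing
#' depth range, the table of planted effects, and the parameters of the
#' derived fixtures (target predictions, annotation terms, interaction
#' edges). The same configuration (including `seed`) always produces
#' byte-identical fixtures.
#'
#' @param seed integer RNG seed.
#' @param groups ordered group labels; the first is the control/calibrator.
#' @param n_per_group biological replicates per group (>= 2).
#' @param n_genes number of target assays in the simulated qPCR panel.
#' @param n_mirnas number of miRNA features in the simulated count matrix.
#' @param n_reference_assays number of housekeeping assays (default 3, as in
#'   a Tbp/Gapdh/Hprt normalization scheme).
#' @param dispersion shared negative-binomial dispersion alpha
#'   (variance = mu + alpha * mu^2); must be > 0.
#' @param library_size_range low/high bounds for per-sample library sizes
#'   (reads); factors are drawn log-uniformly within the range.
#' @param effects a planted-effect table from [plantedEffects()], or NULL.
#' @param prediction_fp_rate probability that a non-target miRNA-gene pair
#'   appears as a decoy prediction edge.
#' @param n_terms number of annotation terms to generate (>= 1).
#' @param edge_density background edge probability for the interaction-edge
#'   fixture.
#' @param cq_noise_sd Gaussian noise on the Cq cycle scale (default 0.15
#'   cycles, a typical instrument repeatability).
#' @param null_abundance_meanlog,null_abundance_sdlog log-normal parameters
#'   of the baseline abundance (in reads per million) of unplanted miRNA
#'   features; the long-tailed default (median 20 rpm, sdlog 1.5) mimics the
#'   skewed abundance distribution of real small-RNA libraries.
#' @return A validated list of class `SimulationConfig`.
#' @examples
#' cfg <- simulationConfig(seed = 1, n_mirnas = 50)
#' @export
simulationConfig <- function(seed = 1L,
                             groups = c("Sham", "IR", "IRT3"),
                             n_per_group = 5L,
                             n_genes = 90L,
                             n_mirnas = 300L,
                             n_reference_assays = 3L,
                             dispersion = 0.2,
                             library_size_range = c(8e5, 1.2e6),
                             effects = NULL,
                             prediction_fp_rate = 0.05,
                             n_terms = 8L,
                             edge_density = 0.1,
                             cq_noise_sd = 0.15,
                             null_abundance_meanlog = log(20),
                             null_abundance_sdlog = 1.5) {
    if (length(groups) < 2L || anyDuplicated(groups))
        stop("'groups' must be >= 2 distinct labels")
    if (!is.numeric(n_per_group) || n_per_group < 2)
        stop("'n_per_group' must be >= 2")
    if (!is.numeric(n_genes) || n_genes < 1 || !is.numeric(n_mirnas) ||
        n_mirnas < 1)
        stop("'n_genes' and 'n_mirnas' must be positive")
    if (!is.numeric(dispersion) || dispersion <= 0)
        stop("'dispersion' must be > 0")
    if (length(library_size_range) != 2L ||
        any(library_size_range <= 0) ||
        library_size_range[1] > library_size_range[2])
        stop("'library_size_range' must be a positive (low, high) pair")
    stopIfNot01(prediction_fp_rate, "prediction_fp_rate")
    stopIfNot01(edge_density, "edge_density")
    if (!is.numeric(n_terms) || n_terms < 1)
        stop("'n_terms' must be >= 1")
    if (!is.null(effects)) effects <- validatePlantedEffects(effects)
    structure(list(
        seed = as.integer(seed), groups = as.character(groups),
        n_per_group = as.integer(n_per_group),
        n_genes = as.integer(n_genes), n_mirnas = as.integer(n_mirnas),
        n_reference_assays = as.integer(n_reference_assays),
        dispersion = dispersion,
        library_size_range = as.numeric(library_size_range),
        effects = effects,
        prediction_fp_rate = prediction_fp_rate,
        n_terms = as.integer(n_terms), edge_density = edge_density,
        cq_noise_sd = cq_noise_sd,
        null_abundance_meanlog = null_abundance_meanlog,
        null_abundance_sdlog = null_abundance_sdlog),
        class = "SimulationConfig")
}

#' @export
print.SimulationConfig <- function(x, ...) {
    cat("SimulationConfig: ", paste(x$groups, collapse = "/"),
        " x ", x$n_per_group, " replicates, seed ", x$seed, "\n",
        "  dispersion ", x$dispersion, ", ",
        if (is.null(x$effects)) 0L else nrow(x$effects),
        " planted effects\n", sep = "")
    invisible(x)
}

.T3_CLASSES <- c("fully_reverted", "partially_reverted", "not_modulated",
                 "aggravated")

#' Build a planted-effect table
#'
#' One row per feature carrying a planted ischemia-reperfusion (IR) effect.
#' The treatment-arm (IRT3) mean is determined deterministically by
#' `t3_class`: `fully_reverted` resets it to the Sham mean,
#' `partially_reverted` to the log-scale midpoint between Sham and IR,
#' `not_modulated` leaves it at the IR mean, and `aggravated` extends the IR
#' effect by 50\% on the log scale.
#'
#' @param feature_id character identifiers.
#' @param feature_kind `"gene"` or `"miRNA"` per feature.
#' @param ir_log2fc planted log2 fold change of IR versus Sham.
#' @param t3_class one of `fully_reverted`, `partially_reverted`,
#'   `not_modulated`, `aggravated`.
#' @param base_abundance positive baseline abundance (rpm for miRNA counts;
#'   relative quantity for panel genes).
#' @param targets for miRNA features, a list of character vectors of target
#'   gene identifiers (empty for genes).
#' @return data.frame with one row per planted feature (class
#'   `PlantedEffects`).
#' @export
plantedEffects <- function(feature_id, feature_kind, ir_log2fc, t3_class,
                           base_abundance, targets = NULL) {
    n <- length(feature_id)
    if (is.null(targets)) targets <- rep(list(character()), n)
    df <- data.frame(feature_id = as.character(feature_id),
                     feature_kind = rep_len(feature_kind, n),
                     ir_log2fc = rep_len(ir_log2fc, n),
                     t3_class = rep_len(t3_class, n),
                     base_abundance = rep_len(base_abundance, n),
                     stringsAsFactors = FALSE)
    df$targets <- targets
    validatePlantedEffects(df)
}

validatePlantedEffects <- function(df) {
    req <- c("feature_id", "feature_kind", "ir_log2fc", "t3_class",
             "base_abundance")
    miss <- setdiff(req, names(df))
    if (length(miss))
        stop("planted-effect table lacks columns: ",
             paste(miss, collapse = ", "))
    if (anyDuplicated(df$feature_id))
        stop("duplicate feature_id in planted-effect table")
    if (!all(df$feature_kind %in% c("gene", "miRNA")))
        stop("feature_kind must be 'gene' or 'miRNA'")
    if (!all(df$t3_class %in% .T3_CLASSES))
        stop("t3_class must be one of: ", paste(.T3_CLASSES, collapse = ", "))
    if (any(df$base_abundance <= 0))
        stop("base_abundance must be positive")
    if (is.null(df$targets)) df$targets <- rep(list(character()), nrow(df))
    class(df) <- c("PlantedEffects", "data.frame")
    df
}

# IRT3 log2 offset from the Sham mean implied by the planted class
t3ClassOffset <- function(ir_log2fc, t3_class) {
    mult <- c(fully_reverted = 0, partially_reverted = 0.5,
              not_modulated = 1, aggravated = 1.5)[t3_class]
    unname(mult) * ir_log2fc
}

# per-group log2 offsets (relative to Sham) for a planted feature set
.groupOffsets <- function(ir_log2fc, t3_class, groups) {
    off <- matrix(0, nrow = length(ir_log2fc), ncol = length(groups),
                  dimnames = list(NULL, groups))
    if ("IR" %in% groups) off[, "IR"] <- ir_log2fc
    if ("IRT3" %in% groups)
        off[, "IRT3"] <- t3ClassOffset(ir_log2fc, t3_class)
    off
}

.sampleLayout <- function(config) {
    group <- rep(config$groups, each = config$n_per_group)
    data.frame(sample_id = paste0(group, "_", seq_len(config$n_per_group)),
               group = group, stringsAsFactors = FALSE)
}

#' Simulate a qPCR Cq panel with planted effects
#'
#' Housekeeping assays receive a group-independent mean Cq; each target
#' assay's Cq is `base - log2(relative quantity) + noise`, so a planted
#' up-regulation of `ir_log2fc` cycles the IR group exactly `ir_log2fc`
#' cycles *lower* than Sham (more template, earlier crossing). The planted
#' truth is stored in `metadata(x)$truth` and is never consulted by any
#' analysis stage.
#'
#' @param config a [simulationConfig()] object.
#' @return A [CqExperiment-class]; `metadata` holds the truth table.
#' @examples
#' eff <- plantedEffects("GeneA", "gene", 2, "fully_reverted", 1)
#' cfg <- simulationConfig(seed = 7, n_genes = 10, effects = eff)
#' ce <- simulateCqExperiment(cfg)
#' @export
simulateCqExperiment <- function(config) {
    stopifnot(inherits(config, "SimulationConfig"))
    withSeed(config$seed + 101L, {
        layout <- .sampleLayout(config)
        n_samp <- nrow(layout)
        eff <- config$effects
        eff <- if (is.null(eff)) NULL else eff[eff$feature_kind == "gene", ]
        n_planted <- if (is.null(eff)) 0L else nrow(eff)
        if (config$n_genes < n_planted)
            stop("n_genes smaller than the number of planted gene effects")
        null_ids <- sprintf("gene_null_%03d", seq_len(config$n_genes - n_planted))
        gene_ids <- c(if (n_planted) eff$feature_id, null_ids)
        lfc <- c(if (n_planted) eff$ir_log2fc, rep(0, length(null_ids)))
        t3c <- c(if (n_planted) eff$t3_class,
                 rep("not_modulated", length(null_ids)))
        off <- .groupOffsets(lfc, t3c, config$groups)

        ref_ids <- paste0("ref_", seq_len(config$n_reference_assays))
        base_ref <- stats::runif(length(ref_ids), 18, 24)
        base_tgt <- stats::runif(length(gene_ids), 22, 30)

        cq <- matrix(NA_real_, nrow = length(ref_ids) + length(gene_ids),
                     ncol = n_samp,
                     dimnames = list(c(ref_ids, gene_ids), layout$sample_id))
        for (j in seq_len(n_samp)) {
            g <- layout$group[j]
            noise_r <- stats::rnorm(length(ref_ids), 0, config$cq_noise_sd)
            noise_t <- stats::rnorm(length(gene_ids), 0, config$cq_noise_sd)
            gcol <- if (g %in% colnames(off)) off[, g] else rep(0, nrow(off))
            cq[ref_ids, j] <- base_ref + noise_r
            cq[gene_ids, j] <- base_tgt - gcol + noise_t
        }
        ce <- CqExperiment(cq, group = layout$group,
                           reference_assays = ref_ids)
        metadata(ce)$truth <- data.frame(
            feature_id = gene_ids, feature_kind = "gene",
            ir_log2fc = lfc, t3_class = t3c, stringsAsFactors = FALSE)
        ce
    })
}

#' Simulate a small-RNA count matrix with planted effects
#'
#' Counts are drawn from a negative binomial with
#' `mean = group abundance (rpm) * library size / 1e6` and shared dispersion
#' `config$dispersion` (variance = mu + alpha mu^2). Library sizes are drawn
#' log-uniformly within `library_size_range`. Unplanted features are null
#' (no group effect) with log-normal baseline abundances. The planted truth
#' is stored in `metadata(x)$truth` and is never consulted by any analysis
#' stage.
#'
#' @param config a [simulationConfig()] object.
#' @param groups optional subset of `config$groups` to simulate (e.g. a
#'   two-arm Sham/IR design).
#' @return A [MirnaCountExperiment-class]; `metadata` holds the truth table
#'   and the drawn library sizes.
#' @export
simulateMirnaCounts <- function(config, groups = config$groups) {
    stopifnot(inherits(config, "SimulationConfig"))
    if (config$dispersion <= 0) stop("'dispersion' must be > 0")
    withSeed(config$seed + 202L, {
        group <- rep(groups, each = config$n_per_group)
        sample_id <- paste0(group, "_", seq_len(config$n_per_group))
        n_samp <- length(sample_id)

        eff <- config$effects
        eff <- if (is.null(eff)) NULL else eff[eff$feature_kind == "miRNA", ]
        n_planted <- if (is.null(eff)) 0L else nrow(eff)
        if (config$n_mirnas < n_planted)
            stop("n_mirnas smaller than the number of planted miRNA effects")
        n_null <- config$n_mirnas - n_planted
        null_ids <- sprintf("mir_null_%04d", seq_len(n_null))
        ids <- c(if (n_planted) eff$feature_id, null_ids)
        base <- c(if (n_planted) eff$base_abundance,
                  stats::rlnorm(n_null, config$null_abundance_meanlog,
                                config$null_abundance_sdlog))
        lfc <- c(if (n_planted) eff$ir_log2fc, rep(0, n_null))
        t3c <- c(if (n_planted) eff$t3_class, rep("not_modulated", n_null))
        off <- .groupOffsets(lfc, t3c, groups)

        lsr <- config$library_size_range
        lib <- round(exp(stats::runif(n_samp, log(lsr[1]), log(lsr[2]))))

        counts <- matrix(0L, nrow = length(ids), ncol = n_samp,
                         dimnames = list(ids, sample_id))
        size <- 1 / config$dispersion
        for (j in seq_len(n_samp)) {
            g <- group[j]
            gcol <- if (g %in% colnames(off)) off[, g] else rep(0, nrow(off))
            mu <- base * 2^gcol * lib[j] / 1e6
            counts[, j] <- stats::rnbinom(length(ids), mu = mu, size = size)
        }
        mce <- MirnaCountExperiment(counts, group = group)
        metadata(mce)$truth <- data.frame(
            feature_id = ids, feature_kind = "miRNA", ir_log2fc = lfc,
            t3_class = t3c, base_abundance = base, stringsAsFactors = FALSE)
        metadata(mce)$library_sizes <- stats::setNames(lib, sample_id)
        mce
    })
}

#' Simulate a miRNA-to-gene target-prediction table
#'
#' Every planted (miRNA, target) edge is emitted; decoy edges are added among
#' the remaining miRNA x gene pairs with probability `fp_rate`. The
#' `provenance` column (`"true"`/`"decoy"`) exists for testing only and must
#' not be consulted by analysis stages.
#'
#' @param effects a [plantedEffects()] table containing at least one miRNA
#'   with declared targets.
#' @param fp_rate decoy probability in [0, 1].
#' @param genes gene universe; defaults to all gene features plus all
#'   declared targets in `effects`.
#' @param seed RNG seed.
#' @return data.frame with columns `mirna`, `gene`, `source`, `score`,
#'   `provenance`.
#' @export
simulateTargetPredictions <- function(effects, fp_rate = 0.05, genes = NULL,
                                      seed = 1L) {
    effects <- validatePlantedEffects(effects)
    stopIfNot01(fp_rate, "fp_rate")
    mir <- effects[effects$feature_kind == "miRNA", ]
    if (nrow(mir) == 0L || all(lengths(mir$targets) == 0L))
        stop("'effects' must contain at least one miRNA with targets")
    if (is.null(genes))
        genes <- unique(c(effects$feature_id[effects$feature_kind == "gene"],
                          unlist(mir$targets)))
    withSeed(seed + 303L, {
        true_edges <- do.call(rbind, lapply(seq_len(nrow(mir)), function(i) {
            tg <- mir$targets[[i]]
            if (length(tg) == 0L) return(NULL)
            data.frame(mirna = mir$feature_id[i], gene = tg,
                       stringsAsFactors = FALSE)
        }))
        all_pairs <- expand.grid(mirna = mir$feature_id, gene = genes,
                                 KEEP.OUT.ATTRS = FALSE,
                                 stringsAsFactors = FALSE)
        key <- function(d) paste(canonId(d$mirna), canonId(d$gene), sep = "\r")
        is_true <- key(all_pairs) %in% key(true_edges)
        decoys <- all_pairs[!is_true & stats::runif(nrow(all_pairs)) < fp_rate, ]
        out <- rbind(
            data.frame(true_edges, provenance = "true",
                       stringsAsFactors = FALSE),
            if (nrow(decoys))
                data.frame(decoys, provenance = "decoy",
                           stringsAsFactors = FALSE))
        out$source <- "sim"
        out$score <- 1
        rownames(out) <- NULL
        out[, c("mirna", "gene", "source", "score", "provenance")]
    })
}

#' Simulate annotation terms with one deliberately enriched term
#'
#' Terms are random gene sets over the universe, except the first
#' (`"term_enriched"`), which is loaded with planted differentially
#' expressed genes so that downstream over-representation analysis has a
#' recoverable signal.
#'
#' @param effects a [plantedEffects()] table (the DE genes are those with
#'   `ir_log2fc != 0`).
#' @param universe gene universe; defaults to all gene features in `effects`.
#' @param n_terms number of terms (>= 1).
#' @param term_size nominal genes per term.
#' @param seed RNG seed.
#' @return named list of character vectors with attribute `universe`.
#' @export
simulateAnnotations <- function(effects, universe = NULL, n_terms = 8L,
                                term_size = 10L, seed = 1L) {
    effects <- validatePlantedEffects(effects)
    if (n_terms < 1) stop("'n_terms' must be >= 1")
    genes <- effects[effects$feature_kind == "gene", ]
    if (is.null(universe)) universe <- genes$feature_id
    de <- intersect(genes$feature_id[genes$ir_log2fc != 0], universe)
    withSeed(seed + 404L, {
        terms <- vector("list", n_terms)
        names(terms) <- c("term_enriched",
                          sprintf("term_%02d", seq_len(n_terms))[-1])
        terms[[1L]] <- utils::head(de, max(term_size, length(de)))
        if (length(terms[[1L]]) < term_size)
            terms[[1L]] <- unique(c(terms[[1L]],
                sample(setdiff(universe, terms[[1L]]),
                       min(term_size - length(terms[[1L]]),
                           length(setdiff(universe, terms[[1L]]))))))
        for (i in seq_len(n_terms)[-1])
            terms[[i]] <- sort(sample(universe,
                                      min(term_size, length(universe))))
        attr(terms, "universe") <- universe
        terms
    })
}

#' Simulate a scored interaction-edge table with planted hubs
#'
#' Background edges appear between node pairs with probability `density`;
#' each planted hub receives `n_hub_edges` additional high-score edges, so
#' after thresholding at 0.7 the hub attains maximum degree by construction.
#' With `jitter = FALSE` the configured scores are emitted exactly.
#'
#' @param nodes character vector of node identifiers.
#' @param hubs nodes to plant as high-degree hubs (default: the first node).
#' @param n_hub_edges high-score edges per hub.
#' @param density background edge probability in [0, 1].
#' @param hub_score score of hub edges (jittered upward to at most 0.99).
#' @param background_score score of background edges before jitter.
#' @param jitter add uniform jitter to scores (disable for exactness tests).
#' @param seed RNG seed.
#' @return data.frame with columns `node_a`, `node_b`, `combined_score`.
#' @export
simulateInteractionEdges <- function(nodes, hubs = nodes[1L],
                                     n_hub_edges = 8L, density = 0.1,
                                     hub_score = 0.9,
                                     background_score = 0.5,
                                     jitter = TRUE, seed = 1L) {
    stopIfNot01(density, "density")
    stopifnot(length(nodes) >= 2L)
    withSeed(seed + 505L, {
        pairs <- utils::combn(sort(nodes), 2L)
        keep <- stats::runif(ncol(pairs)) < density
        bg <- data.frame(node_a = pairs[1L, keep], node_b = pairs[2L, keep],
                         combined_score = if (jitter)
                             stats::runif(sum(keep), 0.2, 0.95)
                         else rep(background_score, sum(keep)),
                         stringsAsFactors = FALSE)
        hub_edges <- do.call(rbind, lapply(hubs, function(h) {
            partners <- setdiff(nodes, h)
            partners <- utils::head(sample(partners), n_hub_edges)
            data.frame(node_a = h, node_b = partners,
                       combined_score = if (jitter)
                           pmin(hub_score + stats::runif(length(partners),
                                                         0, 0.09), 0.99)
                       else rep(hub_score, length(partners)),
                       stringsAsFactors = FALSE)
        }))
        out <- rbind(hub_edges, bg)
        # hub edges take precedence over duplicated background pairs
        k <- apply(cbind(pmin(out$node_a, out$node_b),
                         pmax(out$node_a, out$node_b)), 1L, paste,
                   collapse = "\r")
        out <- out[!duplicated(k), ]
        rownames(out) <- NULL
        out
    })
}

#' Write a complete fixture bundle to disk
#'
#' Emits the Cq table, count matrix, sample sheet, prediction table,
#' annotation (GMT) file, interaction-edge table, the planted-truth table
#' (kept in a separate file so pipeline stages cannot read it by accident)
#' and a JSON manifest recording the configuration and seed.
#'
#' @param config a [simulationConfig()] object.
#' @param dir output directory (created if needed).
#' @return invisibly, the named vector of written file paths.
#' @export
writeFixtureBundle <- function(config, dir) {
    stopifnot(inherits(config, "SimulationConfig"))
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    ce <- simulateCqExperiment(config)
    mce <- simulateMirnaCounts(config)
    eff <- config$effects
    paths <- c(cq = file.path(dir, "cq.tsv"),
               counts = file.path(dir, "counts.tsv"),
               samples = file.path(dir, "samples.tsv"),
               predictions = file.path(dir, "predictions.tsv"),
               annotations = file.path(dir, "annotations.gmt"),
               edges = file.path(dir, "edges.tsv"),
               truth = file.path(dir, "truth.tsv"),
               manifest = file.path(dir, "manifest.json"))
    writeCqTable(ce, paths[["cq"]])
    writeCountTable(mce, paths[["counts"]])
    utils::write.table(
        data.frame(sample = colnames(mce), group = sampleGroups(mce)),
        paths[["samples"]], sep = "\t", quote = FALSE, row.names = FALSE)
    has_targets <- !is.null(eff) &&
        any(eff$feature_kind == "miRNA" & lengths(eff$targets) > 0)
    if (has_targets) {
        pred <- simulateTargetPredictions(eff, config$prediction_fp_rate,
                                          seed = config$seed)
        utils::write.table(pred[, c("mirna", "gene", "source", "score")],
                           paths[["predictions"]], sep = "\t", quote = FALSE,
                           row.names = FALSE)
    }
    if (!is.null(eff) && any(eff$feature_kind == "gene")) {
        ann <- simulateAnnotations(eff, n_terms = config$n_terms,
                                   seed = config$seed)
        writeGmt(ann, paths[["annotations"]])
        edges <- simulateInteractionEdges(
            eff$feature_id[eff$feature_kind == "gene"],
            density = config$edge_density, seed = config$seed)
        utils::write.table(edges, paths[["edges"]], sep = "\t", quote = FALSE,
                           row.names = FALSE)
    }
    truth <- rbind(metadata(ce)$truth,
                   metadata(mce)$truth[, names(metadata(ce)$truth)])
    utils::write.table(truth, paths[["truth"]], sep = "\t", quote = FALSE,
                       row.names = FALSE)
    cfg <- config
    cfg$effects <- if (is.null(eff)) NULL else
        eff[, c("feature_id", "feature_kind", "ir_log2fc", "t3_class",
                "base_abundance")]
    jsonlite::write_json(list(config = unclass(cfg),
                              files = as.list(basename(paths))),
                         paths[["manifest"]], auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
    invisible(paths)
}

#' Benchmark planted-effect tables emulating the study design
#'
#' Two ready-made effect tables reproducing the dysregulation patterns the
#' pipeline is designed to recover. `reversalBenchmarkEffects()` plants 11
#' miRNAs with a strong IR effect (alternating down/up) that T3 fully
#' reverts, plus 5 equally strong persistent (not-modulated) decoys.
#' `dysregulationBenchmarkEffects()` plants 102 strongly IR-dysregulated
#' miRNAs (42 down, 60 up). Effect magnitudes are drawn once from
#' `|log2FC|` in [2.2, 3.2] (at least 4-fold) and baseline abundances
#' log-uniformly in [500, 5000] rpm, under a fixed internal seed, so the
#' planted design itself is constant; only the counts drawn around it vary
#' with the simulation seed.
#'
#' @return a [plantedEffects()] table.
#' @export
reversalBenchmarkEffects <- function() {
    withSeed(7L, {
        n_rev <- 11L; n_dec <- 5L; n <- n_rev + n_dec
        lfc <- stats::runif(n, 2.2, 3.2) *
            c(rep_len(c(-1, 1), n_rev), rep(1, n_dec))
        plantedEffects(
            c(sprintf("mir_rev_%02d", seq_len(n_rev)),
              sprintf("mir_dec_%02d", seq_len(n_dec))),
            "miRNA", lfc,
            c(rep("fully_reverted", n_rev), rep("not_modulated", n_dec)),
            base_abundance = exp(stats::runif(n, log(500), log(5000))))
    })
}

#' @rdname reversalBenchmarkEffects
#' @export
dysregulationBenchmarkEffects <- function() {
    withSeed(8L, {
        lfc <- c(stats::runif(42, -3.2, -2.2), stats::runif(60, 2.2, 3.2))
        plantedEffects(sprintf("mir_de_%03d", 1:102), "miRNA", lfc,
                       "fully_reverted",
                       base_abundance = exp(stats::runif(102, log(500),
                                                         log(5000))))
    })
}
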