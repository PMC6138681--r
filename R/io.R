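#' Read a Cq table from TSV
#'
#' Expected layout: one row per sample with a `sample` column, a `group`
#' column and one numeric column per assay.
#'
#' @param path TSV file (comma-separated accepted as fallback).
#' @param reference_assays housekeeping assay names (columns of the file).
#' @return A [CqExperiment-class].
#' @export
readCqTable <- function(path, reference_assays) {
    df <- .readTable(path)
    .requireColumns(df, c("sample", "group"), path)
    if (anyDuplicated(df$sample))
        stop("duplicate sample id in ", path, ": ",
             df$sample[duplicated(df$sample)][1L])
    assays <- setdiff(names(df), c("sample", "group"))
    if (length(assays) == 0L) stop("no assay columns in ", path)
    m <- t(as.matrix(.numericColumns(df, assays, path)))
    colnames(m) <- df$sample
    CqExperiment(m, group = df$group, reference_assays = reference_assays)
}

#' Write a CqExperiment to TSV (samples in rows)
#' @param x a [CqExperiment-class].
#' @param path output path.
#' @export
writeCqTable <- function(x, path) {
    stopifnot(is(x, "CqExperiment"))
    df <- data.frame(sample = colnames(x),
                     group = as.character(sampleGroups(x)),
                     t(assay(x, "cq")), check.names = FALSE)
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
}

#' Read a count matrix and sample sheet from TSV
#'
#' @param path count TSV: a `feature` column plus one integer column per
#'   sample.
#' @param sample_sheet TSV with columns `sample`, `group`, or a data.frame.
#' @return A [MirnaCountExperiment-class].
#' @export
readCountTable <- function(path, sample_sheet) {
    df <- .readTable(path)
    .requireColumns(df, "feature", path)
    if (anyDuplicated(df$feature))
        stop("duplicate feature id in ", path, ": ",
             df$feature[duplicated(df$feature)][1L])
    samples <- setdiff(names(df), "feature")
    m <- as.matrix(.numericColumns(df, samples, path))
    bad <- which(m < 0 | m != round(m), arr.ind = TRUE)
    if (nrow(bad))
        stop("non-count value in ", path, " at feature '",
             df$feature[bad[1L, 1L]], "', sample '",
             samples[bad[1L, 2L]], "'")
    rownames(m) <- df$feature
    if (is.character(sample_sheet)) sample_sheet <- .readTable(sample_sheet)
    .requireColumns(sample_sheet, c("sample", "group"), "sample sheet")
    idx <- match(colnames(m), sample_sheet$sample)
    if (any(is.na(idx)))
        stop("sample(s) missing from sample sheet: ",
             paste(colnames(m)[is.na(idx)], collapse = ", "))
    MirnaCountExperiment(m, group = sample_sheet$group[idx])
}

#' Write a MirnaCountExperiment to TSV (features in rows)
#' @param x a [MirnaCountExperiment-class].
#' @param path output path.
#' @export
writeCountTable <- function(x, path) {
    stopifnot(is(x, "MirnaCountExperiment"))
    df <- data.frame(feature = rownames(x), assay(x, "counts"),
                     check.names = FALSE)
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
}

#' Read a miRNA target-prediction table
#' @param path TSV with columns `mirna`, `gene`, optional `source`, `score`.
#' @return validated data.frame.
#' @export
readPredictionTable <- function(path) {
    df <- .readTable(path)
    .requireColumns(df, c("mirna", "gene"), path)
    df
}

#' Read a scored interaction edge table
#' @param path TSV with columns `node_a`, `node_b`, `combined_score`.
#' @return validated data.frame (scores checked to lie in [0, 1]).
#' @export
readEdgeTable <- function(path) {
    df <- .readTable(path)
    .requireColumns(df, c("node_a", "node_b", "combined_score"), path)
    .numericColumns(df, "combined_score", path)
    stopIfNot01(df$combined_score, "combined_score")
    df
}

.readTable <- function(path) {
    if (!file.exists(path)) stop("file not found: ", path)
    first <- readLines(path, n = 1L)
    sep <- if (grepl("\t", first)) "\t" else ","
    df <- utils::read.table(path, header = TRUE, sep = sep,
                            stringsAsFactors = FALSE, check.names = FALSE,
                            quote = "\"", comment.char = "")
    if (nrow(df) == 0L) stop("no data rows in ", path)
    df
}

.requireColumns <- function(df, cols, where) {
    miss <- setdiff(cols, names(df))
    if (length(miss))
        stop("missing column(s) in ", where, ": ",
             paste(miss, collapse = ", "))
    invisible(df)
}

.numericColumns <- function(df, cols, where) {
    for (cl in cols) {
        v <- df[[cl]]
        if (is.character(v)) v <- suppressWarnings(as.numeric(v))
        if (any(is.na(v) & !is.na(df[[cl]])))
            stop("non-numeric value in column '", cl, "' of ", where)
        df[[cl]] <- v
    }
    df[cols]
}

#' Bundled three-group qPCR panel summaries
#'
#' Median fold changes (relative to Sham), interquartile ranges and
#' significance flags for the mitochondria panel (MPA) and fibrosis panel
#' (FPA) of a rat cardiac ischemia-reperfusion study with and without T3
#' replacement, transcribed from the published summary tables
#' (`flag_star`: p < 0.017 vs Sham; `flag_hash`: p < 0.01 vs IR;
#' `flag_irt3_vs_sham`: the IRT3-column asterisk). One fibrosis-panel row
#' was not recoverable from the source text, so the FPA table carries 49
#' of its 50 printed rows; see [panelPrintedCounts()] for the printed
#' per-panel tallies.
#'
#' @param panel `"MPA"`, `"FPA"` or `"both"`.
#' @return data.frame with columns `feature_id`, `panel`,
#'   `function_group`, per-group medians/IQRs and the three flags.
#' @export
panelSummary <- function(panel = c("both", "MPA", "FPA")) {
    panel <- match.arg(panel)
    read1 <- function(p) {
        f <- system.file("extdata", paste0("panel_", tolower(p), ".tsv"),
                         package = "mircuits", mustWork = TRUE)
        df <- .readTable(f)
        for (fl in c("flag_star", "flag_hash", "flag_irt3_vs_sham"))
            df[[fl]] <- as.logical(df[[fl]])
        df
    }
    if (panel == "both") rbind(read1("MPA"), read1("FPA"))
    else read1(panel)
}

#' Printed per-panel feature tallies of the bundled panel summaries
#'
#' The headline counts printed alongside the bundled panel tables: number
#' of evaluable panel genes, IR-dysregulated genes per panel (with the
#' printed up/down split) and the number of those significantly modulated
#' back by T3 replacement.
#'
#' @return data.frame with one row per panel and columns `panel`,
#'   `n_up`, `n_down`, `n_dysregulated`, `n_t3_modulated`, plus the
#'   attribute `n_evaluable` (total evaluable genes across panels).
#' @export
panelPrintedCounts <- function() {
    out <- data.frame(panel = c("MPA", "FPA"),
                      n_up = c(18L, 50L), n_down = c(19L, 0L),
                      n_dysregulated = c(37L, 50L),
                      n_t3_modulated = c(32L, 36L),
                      stringsAsFactors = FALSE)
    attr(out, "n_evaluable") <- 150L
    out
}

#' Configuration of the end-to-end pipeline
#'
#' @param input_dir directory with the input tables (the layout written by
#'   [writeFixtureBundle()]: `cq.tsv`, `counts.tsv`, `samples.tsv`,
#'   `predictions.tsv`, `annotations.gmt`, `edges.tsv`).
#' @param out_dir output directory for stage artifacts.
#' @param reference_assays housekeeping assay names of the Cq table.
#' @param calibrator calibrator group (default `"Sham"`).
#' @param groups named mapping of roles `sham`, `ir`, `irt3`.
#' @param alpha_star,alpha_hash,family_alpha panel-test thresholds.
#' @param fold_min,rpm_min,fdr_max count-DE filters.
#' @param min_score interaction-score threshold.
#' @param enrich_alpha enrichment significance level on raw p (set
#'   `enrich_adjusted = TRUE` to filter on BH-adjusted p instead).
#' @param enrich_adjusted filter enrichment on adjusted p.
#' @param force_include miRNA ids force-included in the DE set.
#' @param seed integer seed recorded in the manifest.
#' @return validated list of class `PipelineConfig`.
#' @export
pipelineConfig <- function(input_dir, out_dir,
                           reference_assays = paste0("ref_", 1:3),
                           calibrator = "Sham",
                           groups = c(sham = "Sham", ir = "IR",
                                      irt3 = "IRT3"),
                           alpha_star = 0.017, alpha_hash = 0.01,
                           family_alpha = 0.05,
                           fold_min = 2, rpm_min = 100, fdr_max = 0.05,
                           min_score = 0.7, enrich_alpha = 0.05,
                           enrich_adjusted = FALSE,
                           force_include = NULL, seed = 1L) {
    for (v in c(alpha_star, alpha_hash, family_alpha, fdr_max,
                enrich_alpha))
        if (v <= 0 || v > 1) stop("alpha/FDR thresholds must be in (0, 1]")
    if (fold_min <= 0 || rpm_min <= 0) stop("thresholds must be positive")
    stopIfNot01(min_score, "min_score")
    structure(list(input_dir = input_dir, out_dir = out_dir,
                   reference_assays = reference_assays,
                   calibrator = calibrator, groups = groups,
                   alpha_star = alpha_star, alpha_hash = alpha_hash,
                   family_alpha = family_alpha, fold_min = fold_min,
                   rpm_min = rpm_min, fdr_max = fdr_max,
                   min_score = min_score, enrich_alpha = enrich_alpha,
                   enrich_adjusted = enrich_adjusted,
                   force_include = force_include, seed = as.integer(seed)),
              class = "PipelineConfig")
}

#' Run the full integrative pipeline
#'
#' Executes the stages in dependency order -- panel quantification and
#' flagging, count-based DE with reversal classification, gene-panel
#' reversal, anti-modulated circuit crossing, over-representation analysis
#' and interaction-network assembly -- writing one TSV per artifact plus a
#' JSON manifest (config snapshot, input/output checksums, package
#' version, seed). Identical config and inputs produce identical outputs.
#' Any stage failure aborts with the stage name; artifacts of completed
#' stages are preserved.
#'
#' @param config a [pipelineConfig()] object.
#' @return invisibly, the manifest as a list.
#' @export
runPipeline <- function(config) {
    stopifnot(inherits(config, "PipelineConfig"))
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    inp <- function(f) file.path(config$input_dir, f)
    outp <- function(f) file.path(config$out_dir, f)
    written <- character()
    emit <- function(df, f) {
        utils::write.table(df, outp(f), sep = "\t", quote = FALSE,
                           row.names = FALSE)
        written <<- c(written, outp(f))
    }
    stage <- function(name, expr)
        tryCatch(expr, error = function(e)
            stop("stage '", name, "' failed: ", conditionMessage(e),
                 call. = FALSE))

    panel <- stage("qpcr", {
        ce <- readCqTable(inp("cq.tsv"), config$reference_assays)
        fc <- relativeQuantity(deltaCq(ce), sampleGroups(ce),
                               config$calibrator)
        pn <- classifyPanel(fc, groups = config$groups,
                            alpha_star = config$alpha_star,
                            alpha_hash = config$alpha_hash,
                            family_alpha = config$family_alpha)
        emit(pn, "panel_summary.tsv")
        pn
    })
    mres <- stage("mirna-de", {
        mce <- readCountTable(inp("counts.tsv"), inp("samples.tsv"))
        r <- mirnaReversal(mce, groups = config$groups,
                           fold_min = config$fold_min,
                           rpm_min = config$rpm_min,
                           fdr_max = config$fdr_max,
                           force_include = config$force_include)
        emit(r$de_ir, "mirna_de_ir_vs_sham.tsv")
        emit(r$calls, "mirna_reversal.tsv")
        r
    })
    gene_calls <- stage("reversal", {
        calls <- panelReversal(panel, groups = config$groups)
        emit(calls, "gene_reversal.tsv")
        calls
    })
    circuits <- stage("integrate", {
        pred <- readPredictionTable(inp("predictions.tsv"))
        mc <- mres$calls[mres$calls$t3de | (mres$calls$forced %in% TRUE), ]
        # forced miRNAs take their shift direction from the point estimate
        mc$direction_t3shift[mc$forced %in% TRUE] <-
            ifelse(mc$effect_t3[mc$forced %in% TRUE] > 0, "up", "down")
        gc <- gene_calls[gene_calls$t3de, ]
        cc <- crossAntimodulated(mc, gc, pred)
        emit(cc, "circuits.tsv")
        emit(data.frame(gene = uncoveredGenes(cc)), "uncovered_genes.tsv")
        cc
    })
    stage("enrich", {
        ann <- readGmt(inp("annotations.gmt"))
        truth_free_universe <- unique(panel$feature_id)
        query <- gene_calls$feature_id[gene_calls$t3de]
        enr <- overrepresentationTest(query, ann, truth_free_universe)
        enr$significant <- if (config$enrich_adjusted)
            enr$p_adj < config$enrich_alpha else enr$p < config$enrich_alpha
        emit(enr, "enrichment.tsv")
    })
    stage("network", {
        edges <- readEdgeTable(inp("edges.tsv"))
        targets <- unique(circuits$gene)
        if (length(targets) == 0L) stop("no circuit targets for the network")
        ig <- buildInteractionGraph(edges, nodes = targets,
                                    min_score = config$min_score)
        if (igraph::vcount(asIgraph(ig)) > 0L) {
            ed <- igraph::as_data_frame(asIgraph(ig), what = "edges")
            names(ed) <- c("node_a", "node_b", "combined_score")
            emit(ed, "network_edges.tsv")
            comp <- graphComponents(ig)
            emit(data.frame(
                component = rep(seq_along(comp), lengths(comp)),
                node = unlist(comp)), "network_components.tsv")
            emit(hubRanking(ig), "network_centrality.tsv")
        } else emit(data.frame(node_a = character(), node_b = character(),
                               combined_score = numeric()),
                    "network_edges.tsv")
    })

    inputs <- list.files(config$input_dir, full.names = TRUE)
    manifest <- list(
        package_version = as.character(utils::packageVersion("mircuits")),
        seed = config$seed,
        config = unclass(config),
        inputs = as.list(tools::md5sum(inputs)),
        outputs = as.list(tools::md5sum(sort(written))))
    jsonlite::write_json(manifest, outp("manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    invisible(manifest)
}
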