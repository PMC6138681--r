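.REVERSAL_LEVELS <- c("fully_reverted", "partially_reverted",
                      "not_modulated", "aggravated", "de_novo", "unchanged")

#' Classify three-group expression trajectories into reversal categories
#'
#' Implements the treatment-reversal ("T3DE") logic shared by the gene-panel
#' and miRNA branches of the pipeline. A feature is *T3DE* when it is
#' dysregulated by ischemia-reperfusion (IR vs Sham significant), the
#' treatment shift (IRT3 vs IR) is significant, and that shift opposes the
#' IR effect. T3DE features are `fully_reverted` when IRT3 no longer differs
#' from Sham and `partially_reverted` when it still does in the IR
#' direction. IR-dysregulated features without a significant treatment
#' shift are `not_modulated`; a significant shift in the *same* direction
#' as the IR effect is `aggravated`; an effect appearing only under
#' treatment (IR vs Sham not significant but IRT3 vs Sham significant) is
#' `de_novo`; everything else is `unchanged`. The significance booleans are
#' inherited from the producing stage (panel flags at their alpha levels,
#' count-DE calls at their FDR) rather than re-tested here.
#'
#' @param stats data.frame with one row per feature and columns:
#'   `feature_id`; logical `ir_significant`, `t3_significant`,
#'   `irt3_vs_sham_significant`; numeric `effect_ir` (signed IR-vs-Sham
#'   effect, e.g. log2 fold change or median difference), `effect_t3`
#'   (IRT3 vs IR) and `effect_irt3_vs_sham`. Optional logical `forced`
#'   (carried through).
#' @return `stats` with added columns `direction_ir`, `direction_t3shift`
#'   (`"up"`/`"down"`/`"none"`), `t3de` (logical) and `category` (factor
#'   over fully_reverted, partially_reverted, not_modulated, aggravated,
#'   de_novo, unchanged).
#' @export
classifyReversal <- function(stats) {
    req <- c("feature_id", "ir_significant", "t3_significant",
             "irt3_vs_sham_significant", "effect_ir", "effect_t3",
             "effect_irt3_vs_sham")
    miss <- setdiff(req, names(stats))
    if (length(miss))
        stop("missing per-feature statistics: ", paste(miss, collapse = ", "))

    sgn <- function(x) ifelse(x > 0, 1L, ifelse(x < 0, -1L, 0L))
    ir_sig <- stats$ir_significant
    t3_sig <- stats$t3_significant
    is_sig <- stats$irt3_vs_sham_significant
    s_ir <- sgn(stats$effect_ir)
    s_t3 <- sgn(stats$effect_t3)
    s_is <- sgn(stats$effect_irt3_vs_sham)

    opposite <- ir_sig & t3_sig & s_t3 == -s_ir & s_ir != 0L
    same <- ir_sig & t3_sig & s_t3 == s_ir & s_ir != 0L
    t3de <- opposite

    category <- rep("unchanged", nrow(stats))
    category[!ir_sig & is_sig] <- "de_novo"
    category[ir_sig & !t3_sig] <- "not_modulated"
    category[same] <- "aggravated"
    # residual IRT3-vs-Sham significance in the IR direction means the
    # rescue is incomplete; anything else (including over-correction past
    # the Sham level) counts as full reversion
    category[t3de & is_sig & s_is == s_ir] <- "partially_reverted"
    category[t3de & !(is_sig & s_is == s_ir)] <- "fully_reverted"

    stats$direction_ir <- ifelse(ir_sig & s_ir != 0L,
                                 ifelse(s_ir > 0, "up", "down"), "none")
    stats$direction_t3shift <- ifelse(t3_sig & s_t3 != 0L,
                                      ifelse(s_t3 > 0, "up", "down"), "none")
    stats$t3de <- t3de
    stats$category <- factor(category, levels = .REVERSAL_LEVELS)
    stats
}

#' Reversal classification for a three-group count dataset
#'
#' Convenience wrapper running the full count branch: DE on the
#' test-vs-control contrast with the fold/abundance/FDR filters
#' (IR-dysregulation call), then the treatment contrasts IRT3 vs IR and
#' IRT3 vs Sham (each its own BH family, significance at `fdr_max` with no
#' abundance or fold filter), feeding [classifyReversal()]. Size factors
#' and dispersions are shared across contrasts (pooled estimation over all
#' three groups).
#'
#' @param x a [MirnaCountExperiment-class] containing the three groups.
#' @param groups named character vector mapping roles `sham`, `ir`, `irt3`
#'   to group labels.
#' @param fold_min,rpm_min,fdr_max the DE filters (see [callDE()]).
#' @param force_include features added to the IR-DE set regardless of the
#'   filters.
#' @return list with elements `calls` (the [classifyReversal()] table),
#'   `de_ir` (the filtered IR-vs-Sham table) and the raw contrast tables
#'   `de_t3`, `de_irt3_vs_sham`.
#' @export
mirnaReversal <- function(x,
                          groups = c(sham = "Sham", ir = "IR",
                                     irt3 = "IRT3"),
                          fold_min = 2, rpm_min = 100, fdr_max = 0.05,
                          force_include = NULL) {
    stopifnot(is(x, "MirnaCountExperiment"))
    grp <- as.character(sampleGroups(x))
    missing_g <- setdiff(groups, grp)
    if (length(missing_g))
        stop("group(s) absent from data: ", paste(missing_g, collapse = ", "))
    counts <- assay(x, "counts")
    sf <- estimateSizeFactors(counts)
    disp <- estimateDispersions(counts, sf, grp)

    de_ir <- callDE(mirnaDE(x, c(groups[["ir"]], groups[["sham"]]),
                            size_factors = sf, dispersions = disp),
                    fold_min, rpm_min, fdr_max, force_include)
    de_t3 <- mirnaDE(x, c(groups[["irt3"]], groups[["ir"]]),
                     size_factors = sf, dispersions = disp)
    de_is <- mirnaDE(x, c(groups[["irt3"]], groups[["sham"]]),
                     size_factors = sf, dispersions = disp)

    stats <- data.frame(
        feature_id = de_ir$feature_id,
        ir_significant = de_ir$de,
        t3_significant = !is.na(de_t3$p_adj) & de_t3$p_adj < fdr_max,
        irt3_vs_sham_significant = !is.na(de_is$p_adj) &
            de_is$p_adj < fdr_max,
        effect_ir = de_ir$log2FC,
        effect_t3 = de_t3$log2FC,
        effect_irt3_vs_sham = de_is$log2FC,
        forced = de_ir$forced,
        stringsAsFactors = FALSE)
    list(calls = classifyReversal(stats), de_ir = de_ir, de_t3 = de_t3,
         de_irt3_vs_sham = de_is)
}

#' Reversal classification from a flagged panel summary
#'
#' Maps the reporting convention of a three-group qPCR panel table --
#' asterisk (vs Sham at the star level), hash (vs IR) and the IRT3-vs-Sham
#' flag, with group medians -- onto [classifyReversal()]. Accepts the
#' output of [classifyPanel()] or any table with the same flag columns
#' (e.g. a transcribed published panel summary).
#'
#' @param panel data.frame with columns `feature_id`, `median_Sham`,
#'   `median_IR`, `median_IRT3`, `flag_star`, `flag_hash`,
#'   `flag_irt3_vs_sham` (group label suffixes configurable via `groups`).
#' @param groups named mapping of roles to the median column suffixes.
#' @return the [classifyReversal()] call table.
#' @export
panelReversal <- function(panel,
                          groups = c(sham = "Sham", ir = "IR",
                                     irt3 = "IRT3")) {
    med <- function(role) panel[[paste0("median_", groups[[role]])]]
    stats <- data.frame(
        feature_id = panel$feature_id,
        ir_significant = panel$flag_star,
        t3_significant = panel$flag_hash,
        irt3_vs_sham_significant = panel$flag_irt3_vs_sham,
        effect_ir = med("ir") - med("sham"),
        effect_t3 = med("irt3") - med("ir"),
        effect_irt3_vs_sham = med("irt3") - med("sham"),
        stringsAsFactors = FALSE)
    classifyReversal(stats)
}

#' Rescue percentage of a panel
#'
#' The percentage of IR-dysregulated features whose expression the
#' treatment significantly modulates back, as reported for focused panels
#' (e.g. 32 of 37 mitochondria-panel genes: 86\%).
#'
#' @param n_modulated number of treatment-modulated (T3DE) features.
#' @param n_dysregulated number of IR-dysregulated features.
#' @param digits rounding of the reported percentage (default 0).
#' @return the rescue percentage.
#' @export
rescuePercent <- function(n_modulated, n_dysregulated, digits = 0) {
    if (n_dysregulated <= 0) stop("'n_dysregulated' must be positive")
    round(100 * n_modulated / n_dysregulated, digits)
}
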