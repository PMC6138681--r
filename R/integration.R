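#' Cross treatment-reverted miRNAs against reverted genes, keeping
#' anti-modulated couples
#'
#' Emits one row per (miRNA, gene) pair that (a) appears in the
#' target-prediction table with at least `min_sources` supporting sources
#' and (b) joins a treatment-shifted miRNA to a treatment-shifted gene with
#' *opposite* shift directions -- the anti-modulated couples through which a
#' miRNA can plausibly drive its target's reversion. Identifiers are
#' case-normalized before matching; prediction rows naming unknown features
#' are skipped (never fatal). miRNA family entries in the prediction table
#' (e.g. a single row standing for a whole seed family) are supported
#' through `family_map`.
#'
#' @param mirna_calls data.frame with columns `feature_id` and
#'   `direction_t3shift` (`"up"`/`"down"`), typically the T3DE subset of a
#'   [classifyReversal()] table; an optional logical `forced` column marks
#'   force-included miRNAs whose direction comes from the sign of the point
#'   estimate.
#' @param gene_calls same structure for genes (plus optional `panel` and
#'   `function_group` columns, carried through).
#' @param predictions data.frame with columns `mirna`, `gene` and
#'   optionally `source`.
#' @param family_map optional data.frame with columns `family`, `member`
#'   mapping family labels to mature miRNA identifiers; a family inherits
#'   the direction of its treatment-shifted members when they agree.
#' @param min_sources minimum number of distinct prediction sources per
#'   pair (default 1).
#' @return data.frame (the circuit table) with columns `mirna`,
#'   `mirna_direction`, `gene`, `gene_direction`, `n_sources`,
#'   `forced_mirna` plus any carried gene annotation; attributes
#'   `uncovered_genes` (reverted genes with no qualifying miRNA) and
#'   `mirnas` (the miRNA universe used).
#' @export
crossAntimodulated <- function(mirna_calls, gene_calls, predictions,
                               family_map = NULL, min_sources = 1L) {
    if (nrow(mirna_calls) == 0L || nrow(gene_calls) == 0L)
        stop("both input sets must be non-empty")
    if (!all(c("mirna", "gene") %in% names(predictions)))
        stop("'predictions' needs columns 'mirna' and 'gene'")

    mir <- data.frame(id = canonId(mirna_calls$feature_id),
                      label = as.character(mirna_calls$feature_id),
                      dir = as.character(mirna_calls$direction_t3shift),
                      forced = if (!is.null(mirna_calls$forced))
                          mirna_calls$forced else FALSE,
                      stringsAsFactors = FALSE)
    mir <- mir[mir$dir %in% c("up", "down"), ]

    # a family label acts as an alias for its treatment-shifted members
    if (!is.null(family_map)) {
        fam <- split(canonId(family_map$member), canonId(family_map$family))
        for (f in names(fam)) {
            hit <- mir[mir$id %in% fam[[f]], ]
            if (nrow(hit) == 0L) next
            dirs <- unique(hit$dir)
            if (length(dirs) != 1L) {
                warning("family '", f, "' members disagree in direction; ",
                        "family entry skipped")
                next
            }
            mir <- rbind(mir, data.frame(id = f, label = f, dir = dirs,
                                         forced = all(hit$forced),
                                         stringsAsFactors = FALSE))
        }
    }
    mir <- mir[!duplicated(mir$id), ]

    gene <- data.frame(id = canonId(gene_calls$feature_id),
                       label = as.character(gene_calls$feature_id),
                       dir = as.character(gene_calls$direction_t3shift),
                       stringsAsFactors = FALSE)
    if (!is.null(gene_calls$panel)) gene$panel <- gene_calls$panel
    if (!is.null(gene_calls$function_group))
        gene$function_group <- gene_calls$function_group
    gene <- gene[gene$dir %in% c("up", "down"), ]
    gene <- gene[!duplicated(gene$id), ]

    pr <- data.frame(mirna = canonId(predictions$mirna),
                     gene = canonId(predictions$gene),
                     source = if (!is.null(predictions$source))
                         as.character(predictions$source) else "unknown",
                     stringsAsFactors = FALSE)
    known <- pr$mirna %in% mir$id & pr$gene %in% gene$id
    if (any(!known))
        message(sum(!known), " prediction row(s) with identifiers outside ",
                "the reverted sets were skipped")
    pr <- pr[known, ]
    key <- paste(pr$mirna, pr$gene, sep = "\r")
    n_src <- tapply(pr$source, key, function(s) length(unique(s)))
    pairs <- unique(pr[, c("mirna", "gene")])
    pairs$n_sources <- as.integer(n_src[paste(pairs$mirna, pairs$gene,
                                              sep = "\r")])
    pairs <- pairs[pairs$n_sources >= min_sources, ]

    mi <- match(pairs$mirna, mir$id)
    gi <- match(pairs$gene, gene$id)
    anti <- mir$dir[mi] != gene$dir[gi]
    out <- data.frame(mirna = mir$label[mi][anti],
                      mirna_direction = mir$dir[mi][anti],
                      gene = gene$label[gi][anti],
                      gene_direction = gene$dir[gi][anti],
                      n_sources = pairs$n_sources[anti],
                      forced_mirna = mir$forced[mi][anti],
                      stringsAsFactors = FALSE)
    if (!is.null(gene$panel)) out$panel <- gene$panel[gi][anti]
    if (!is.null(gene$function_group))
        out$function_group <- gene$function_group[gi][anti]
    out <- out[order(out$gene, out$mirna), ]
    rownames(out) <- NULL
    attr(out, "uncovered_genes") <- setdiff(gene$label,
                                            unique(out$gene))
    attr(out, "mirnas") <- mir$label
    out
}

#' Reverted genes left without a qualifying miRNA
#'
#' @param circuits a circuit table from [crossAntimodulated()].
#' @return character vector of uncovered gene labels.
#' @export
uncoveredGenes <- function(circuits) attr(circuits, "uncovered_genes")

#' Multiplicity and cooperativity summaries of a circuit table
#'
#' *Multiplicity* counts the miRNAs converging on each gene (how many
#' regulators a target integrates); *cooperativity* counts the retained
#' targets of each miRNA (zero-target miRNAs from the crossing universe are
#' kept in the summary). The overlap matrix gives, for every miRNA pair,
#' the number of shared targets; coverage is the fraction of reverted genes
#' with at least one predicted recognition element.
#'
#' @param circuits a circuit table from [crossAntimodulated()].
#' @return list with `multiplicity` (data.frame gene/n_mirnas),
#'   `cooperativity` (data.frame mirna/n_targets), `overlap` (symmetric
#'   integer matrix) and `coverage` (numeric fraction).
#' @export
circuitStats <- function(circuits) {
    mirnas <- attr(circuits, "mirnas")
    uncovered <- attr(circuits, "uncovered_genes")
    if (nrow(circuits) == 0L) {
        warning("empty circuit table; summaries are empty")
        return(list(multiplicity = data.frame(gene = character(),
                                              n_mirnas = integer()),
                    cooperativity = data.frame(mirna = character(),
                                               n_targets = integer()),
                    overlap = matrix(0L, 0, 0), coverage = NA_real_))
    }
    mult <- as.data.frame(table(gene = circuits$gene),
                          stringsAsFactors = FALSE)
    names(mult)[2L] <- "n_mirnas"

    if (is.null(mirnas)) mirnas <- unique(circuits$mirna)
    tg <- lapply(stats::setNames(mirnas, mirnas),
                 function(m) unique(circuits$gene[circuits$mirna == m]))
    coop <- data.frame(mirna = mirnas, n_targets = lengths(tg),
                       row.names = NULL, stringsAsFactors = FALSE)

    overlap <- outer(seq_along(tg), seq_along(tg),
                     Vectorize(function(i, j)
                         length(intersect(tg[[i]], tg[[j]]))))
    dimnames(overlap) <- list(mirnas, mirnas)

    n_genes <- length(unique(circuits$gene)) + length(uncovered)
    list(multiplicity = mult[order(-mult$n_mirnas, mult$gene), ],
         cooperativity = coop[order(-coop$n_targets, coop$mirna), ],
         overlap = overlap,
         coverage = length(unique(circuits$gene)) / n_genes)
}
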