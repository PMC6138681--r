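#' Assemble a score-thresholded interaction network
#'
#' Canonicalizes an undirected scored edge table (self-loops removed,
#' (a, b) identified with (b, a), duplicate pairs collapsed to their
#' maximum score), optionally restricts it to the induced subgraph on a
#' node subset, drops edges below `min_score`, and removes nodes left with
#' degree zero -- the convention of interaction databases where
#' disconnected nodes are omitted from the display.
#'
#' @param edges data.frame with columns `node_a`, `node_b`,
#'   `combined_score` (scores in [0, 1]).
#' @param nodes optional node subset: a character vector, or a data.frame
#'   with columns `node` and `panel` (panel labels become a vertex
#'   attribute). Must be non-empty when supplied.
#' @param min_score minimum retained interaction score (default 0.7).
#' @return An [InteractionGraph-class]; dropped isolated nodes are listed
#'   in [droppedNodes()]. A threshold excluding every edge yields an empty
#'   graph with a warning.
#' @export
buildInteractionGraph <- function(edges, nodes = NULL, min_score = 0.7) {
    stopIfNot01(min_score, "min_score")
    req <- c("node_a", "node_b", "combined_score")
    if (!all(req %in% names(edges)))
        stop("'edges' needs columns: ", paste(req, collapse = ", "))
    stopIfNot01(edges$combined_score, "combined_score")

    panel <- NULL
    if (!is.null(nodes)) {
        if (is.data.frame(nodes)) {
            panel <- stats::setNames(as.character(nodes$panel),
                                     canonId(nodes$node))
            nodes <- nodes$node
        }
        if (length(nodes) == 0L) stop("'nodes' subset is empty")
        nodes <- unique(canonId(nodes))
    }

    a <- canonId(edges$node_a); b <- canonId(edges$node_b)
    lo <- pmin(a, b); hi <- pmax(a, b)
    keep <- lo != hi
    e <- data.frame(a = lo[keep], b = hi[keep],
                    score = edges$combined_score[keep],
                    stringsAsFactors = FALSE)
    if (!is.null(nodes)) e <- e[e$a %in% nodes & e$b %in% nodes, ]
    if (nrow(e)) {
        key <- paste(e$a, e$b, sep = "\r")
        smax <- tapply(e$score, key, max)
        e <- unique(e[, c("a", "b")])
        e$score <- as.numeric(smax[paste(e$a, e$b, sep = "\r")])
    }
    e <- e[e$score >= min_score, ]
    universe <- if (is.null(nodes)) unique(c(lo, hi)) else nodes
    if (nrow(e) == 0L) {
        warning("no edge reaches min_score = ", min_score,
                "; the graph is empty")
        g <- igraph::make_empty_graph(0, directed = FALSE)
        return(new("InteractionGraph", graph = g,
                   dropped = sort(universe), minScore = min_score))
    }
    g <- igraph::graph_from_data_frame(e, directed = FALSE)
    igraph::E(g)$score <- e$score
    dropped <- sort(setdiff(universe, igraph::V(g)$name))
    if (!is.null(panel))
        igraph::V(g)$panel <- unname(panel[igraph::V(g)$name])
    new("InteractionGraph", graph = g, dropped = dropped,
        minScore = min_score)
}

#' Connected components of an interaction graph
#'
#' @param x an [InteractionGraph-class] (or igraph).
#' @return list of character vectors of node names, largest component
#'   first (ties broken by first node name); empty graph gives an empty
#'   list.
#' @export
graphComponents <- function(x) {
    g <- if (is(x, "InteractionGraph")) asIgraph(x) else x
    if (igraph::vcount(g) == 0L) return(list())
    comp <- igraph::components(g)
    parts <- split(igraph::V(g)$name, comp$membership)
    parts <- lapply(parts, sort)
    ord <- order(-lengths(parts),
                 vapply(parts, `[`, "", 1L))
    unname(parts[ord])
}

#' Degree/betweenness hub ranking with bridge annotation
#'
#' Ranks nodes by degree (betweenness as tiebreak, then lexicographic id;
#' betweenness is computed on the unweighted topology -- scores express
#' evidence strength, not distance). A node is annotated as a *bridge*
#' when its removal increases the number of connected components, i.e. it
#' is an articulation point linking otherwise separate sub-networks.
#'
#' @param x an [InteractionGraph-class] (or igraph); must be non-empty.
#' @return data.frame with columns `node`, `degree`, `betweenness`,
#'   `bridge`, `rank`.
#' @export
hubRanking <- function(x) {
    g <- if (is(x, "InteractionGraph")) asIgraph(x) else x
    if (igraph::vcount(g) == 0L) stop("graph is empty")
    deg <- igraph::degree(g)
    btw <- igraph::betweenness(g, weights = NA, directed = FALSE)
    art <- igraph::articulation_points(g)
    bridge <- igraph::V(g)$name %in% igraph::V(g)$name[art]
    out <- data.frame(node = igraph::V(g)$name, degree = as.integer(deg),
                      betweenness = as.numeric(btw), bridge = bridge,
                      stringsAsFactors = FALSE)
    out <- out[order(-out$degree, -out$betweenness, out$node), ]
    out$rank <- seq_len(nrow(out))
    rownames(out) <- NULL
    out
}
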