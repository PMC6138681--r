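# Independent brute-force oracles used to validate the implementations.
# These deliberately share no code with the package.

# exact two-sided Mann-Whitney p by enumeration over value assignments
mwOracle <- function(x, y) {
    n <- length(x); m <- length(y)
    vals <- c(x, y)
    r <- rank(vals)
    u_of <- function(idx) sum(r[idx]) - n * (n + 1) / 2
    u_obs <- u_of(seq_len(n))
    center <- n * m / 2
    combos <- utils::combn(n + m, n)
    devs <- apply(combos, 2L, function(idx) abs(u_of(idx) - center))
    mean(devs >= abs(u_obs - center) - 1e-9)
}

# literal step-up Benjamini-Hochberg definition
bhOracle <- function(p) {
    m <- length(p)
    o <- order(p)
    adj <- numeric(m)
    prev <- 1
    for (i in m:1) {
        prev <- min(prev, p[o[i]] * m / i)
        adj[o[i]] <- prev
    }
    pmin(adj, 1)
}

# conditional binomial two-sided p (NB exact test at dispersion 0 with
# equal size factors and balanced groups)
condBinomOracle <- function(a, K) {
    probs <- stats::dbinom(0:K, K, 0.5)
    sum(probs[probs <= probs[a + 1] * (1 + 1e-7)])
}

# connected components by flood fill on an edge list (character nodes)
floodFillComponents <- function(nodes, edges_a, edges_b) {
    comp <- stats::setNames(rep(NA_integer_, length(nodes)), nodes)
    cid <- 0L
    for (start in nodes) {
        if (!is.na(comp[start])) next
        cid <- cid + 1L
        queue <- start
        while (length(queue)) {
            v <- queue[1L]; queue <- queue[-1L]
            if (!is.na(comp[v])) next
            comp[v] <- cid
            nb <- c(edges_b[edges_a == v], edges_a[edges_b == v])
            queue <- c(queue, nb[is.na(comp[nb])])
        }
    }
    comp
}

# articulation points by node-removal component recount
articulationOracle <- function(nodes, edges_a, edges_b) {
    ncomp <- function(nd, ea, eb)
        length(unique(floodFillComponents(nd, ea, eb)))
    base <- ncomp(nodes, edges_a, edges_b)
    vapply(nodes, function(v) {
        keep <- edges_a != v & edges_b != v
        nd <- setdiff(nodes, v)
        if (length(nd) == 0L) return(FALSE)
        ncomp(nd, edges_a[keep], edges_b[keep]) > base
    }, logical(1))
}

# random undirected simple graph as an edge data.frame
randomGraphEdges <- function(n_nodes, p_edge, score = 1) {
    nodes <- sprintf("n%02d", seq_len(n_nodes))
    pairs <- utils::combn(nodes, 2L)
    keep <- stats::runif(ncol(pairs)) < p_edge
    data.frame(node_a = pairs[1L, keep], node_b = pairs[2L, keep],
               combined_score = rep_len(score, sum(keep)),
               stringsAsFactors = FALSE)
}
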