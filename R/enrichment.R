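#' Hypergeometric over-representation test of a query set against
#' annotation terms
#'
#' For each term, with `N` the universe size, `K` the term size within the
#' universe, `n` the query size and `k` the overlap, the one-sided p-value
#' is the hypergeometric upper tail `P(X >= k)` (identical to Fisher's
#' one-sided exact test on the corresponding 2x2 table). `mode = "ease"`
#' computes the tail at `k - 1` instead -- the conservative variant
#' popularized by annotation servers -- so a single-gene overlap is never
#' significant. Both raw and BH-adjusted p-values are reported; results
#' are sorted by raw p.
#'
#' @param query character vector of feature identifiers (must be a subset
#'   of `universe`).
#' @param annotations named list of character vectors (term members), or a
#'   GMT-style list from [readGmt()].
#' @param universe character vector, the sampling frame.
#' @param mode `"fisher"` (default) or `"ease"`.
#' @return data.frame with columns `term`, `k`, `K`, `n`, `N`, `p`,
#'   `p_adj`, `members` (semicolon-joined overlap).
#' @examples
#' overrepresentationTest(letters[1:5],
#'                        list(t1 = letters[1:5], t2 = letters[6:10]),
#'                        universe = letters[1:20])
#' @export
overrepresentationTest <- function(query, annotations, universe,
                                   mode = c("fisher", "ease")) {
    mode <- match.arg(mode)
    query <- unique(canonId(query))
    universe <- unique(canonId(universe))
    stray <- setdiff(query, universe)
    if (length(stray))
        stop("query identifiers outside the universe: ",
             paste(utils::head(stray, 10L), collapse = ", "))
    if (is.null(names(annotations)))
        stop("'annotations' must be a named list of terms")
    n <- length(query); N <- length(universe)
    rows <- lapply(names(annotations), function(tm) {
        members <- intersect(unique(canonId(annotations[[tm]])), universe)
        K <- length(members)
        hit <- intersect(query, members)
        k <- length(hit)
        keff <- if (mode == "ease") max(k - 1L, 0L) else k
        p <- if (keff == 0L) 1 else
            stats::phyper(keff - 1L, K, N - K, n, lower.tail = FALSE)
        data.frame(term = tm, k = k, K = K, n = n, N = N, p = min(p, 1),
                   members = paste(sort(hit), collapse = ";"),
                   stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, rows)
    out$p_adj <- adjustBH(out$p)
    out <- out[order(out$p, out$term),
               c("term", "k", "K", "n", "N", "p", "p_adj", "members")]
    rownames(out) <- NULL
    out
}

#' Pathway enrichment of a miRNA set with the incidence map
#'
#' Runs [overrepresentationTest()] of a miRNA query against a
#' pathway-membership table and additionally returns the bipartite
#' miRNA-pathway incidence list used to draw enrichment maps (which miRNA
#' connects to which pathway of interest).
#'
#' @param query character vector of miRNA identifiers (empty query returns
#'   empty results with a warning).
#' @param membership named list: pathway -> member miRNAs (non-empty).
#' @param universe miRNA universe.
#' @param mode passed to [overrepresentationTest()].
#' @return list with `enrichment` (the test table) and `incidence`
#'   (data.frame `mirna`, `pathway`).
#' @export
mirnaPathwayEnrichment <- function(query, membership, universe,
                                   mode = "fisher") {
    if (length(membership) == 0L)
        stop("'membership' table is empty")
    if (length(query) == 0L) {
        warning("empty miRNA query; no enrichment computed")
        return(list(enrichment = data.frame(), incidence = data.frame()))
    }
    enr <- overrepresentationTest(query, membership, universe, mode = mode)
    qc <- canonId(query)
    inc <- do.call(rbind, lapply(names(membership), function(pw) {
        hit <- qc[qc %in% canonId(membership[[pw]])]
        if (length(hit) == 0L) return(NULL)
        data.frame(mirna = hit, pathway = pw, stringsAsFactors = FALSE)
    }))
    if (is.null(inc))
        inc <- data.frame(mirna = character(), pathway = character())
    list(enrichment = enr, incidence = inc)
}

#' Read a GMT-like annotation file
#'
#' Tab-separated lines `term <tab> description <tab> member1 <tab> ...`.
#'
#' @param path file path.
#' @return named list of character vectors; term descriptions in
#'   `attr(x, "description")`.
#' @export
readGmt <- function(path) {
    lines <- readLines(path)
    lines <- lines[nzchar(trimws(lines))]
    if (length(lines) == 0L) stop("empty annotation file: ", path)
    parts <- strsplit(lines, "\t", fixed = TRUE)
    bad <- lengths(parts) < 3L
    if (any(bad))
        stop("malformed GMT line(s): ", paste(which(bad), collapse = ", "))
    terms <- lapply(parts, function(p) unique(p[-(1:2)]))
    names(terms) <- vapply(parts, `[`, "", 1L)
    attr(terms, "description") <- vapply(parts, `[`, "", 2L)
    terms
}

#' Write a GMT-like annotation file
#'
#' @param annotations named list of character vectors.
#' @param path output path.
#' @param descriptions optional term descriptions (defaults to the names).
#' @export
writeGmt <- function(annotations, path, descriptions = names(annotations)) {
    lines <- vapply(seq_along(annotations), function(i)
        paste(c(names(annotations)[i], descriptions[i],
                annotations[[i]]), collapse = "\t"), "")
    writeLines(lines, path)
}
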