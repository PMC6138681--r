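#' Median-of-ratios size factors
#'
#' For each sample j, the size factor is the median over features of
#' `count[i, j] / geometric mean of count[i, ]`, restricted to features with
#' strictly positive counts in every sample. If no feature is positive
#' everywhere the function falls back, with a warning, to the ratio of
#' library sizes to their geometric mean.
#'
#' @param counts count matrix (features x samples) or a
#'   [MirnaCountExperiment-class].
#' @return positive numeric vector, one size factor per sample.
#' @examples
#' estimateSizeFactors(cbind(s1 = c(10, 20, 30), s2 = c(20, 40, 60)))
#' @export
estimateSizeFactors <- function(counts) {
    if (is(counts, "MirnaCountExperiment")) counts <- assay(counts, "counts")
    counts <- as.matrix(counts)
    allpos <- rowSums(counts > 0) == ncol(counts)
    if (!any(allpos)) {
        warning("no feature with positive counts in every sample; ",
                "falling back to library-size ratios")
        ls <- colSums(counts)
        return(ls / exp(mean(log(ls))))
    }
    k <- counts[allpos, , drop = FALSE]
    loggeo <- rowMeans(log(k))
    apply(k, 2L, function(col) exp(stats::median(log(col) - loggeo)))
}

#' Reads-per-million normalization
#'
#' `rpm[i, j] = count[i, j] * 1e6 / library_size[j]`. Library sizes default
#' to column sums.
#'
#' @param counts count matrix or [MirnaCountExperiment-class].
#' @param library_sizes per-sample totals (reads); must be positive.
#' @return rpm matrix of the same dimensions.
#' @export
normalizeRpm <- function(counts, library_sizes = NULL) {
    if (is(counts, "MirnaCountExperiment")) counts <- assay(counts, "counts")
    counts <- as.matrix(counts)
    if (is.null(library_sizes)) library_sizes <- colSums(counts)
    if (any(library_sizes <= 0)) stop("library sizes must be positive")
    sweep(counts, 2L, library_sizes / 1e6, "/")
}

#' Pooled dispersion estimation with a fitted mean-dispersion trend
#'
#' On the common scale (counts divided by size factors), each feature's raw
#' dispersion is a pooled method-of-moments estimate: within every condition
#' with replicates, `alpha_g = (variance_g - mean_g) / mean_g^2` relates the
#' within-group residual variance to that group's own mean, and the
#' per-group estimates are pooled as a degrees-of-freedom-weighted average,
#' clamped below at `min_disp`. (Relating each group's variance to its own
#' mean keeps the estimate unbiased for strongly differential features,
#' whose between-group spread would otherwise masquerade as dispersion.)
#' A mean-dispersion trend is then fitted -- lowess of the raw estimates on
#' log mean when at least `min_features_loess` features are available,
#' otherwise a parametric `a0 + a1/mu` fit -- and the final dispersion is
#' the maximum of the per-feature estimate and the trend value
#' (conservative sharing).
#'
#' @param counts count matrix or [MirnaCountExperiment-class].
#' @param size_factors from [estimateSizeFactors()] (computed if NULL).
#' @param groups group label per sample (taken from the container if NULL).
#' @param min_disp dispersion floor (default 1e-8).
#' @param min_features_loess minimum features for the lowess trend
#'   (default 50).
#' @param share use the max-of-fit-and-estimate sharing rule (default TRUE;
#'   FALSE returns the raw per-feature estimates).
#' @return data.frame with columns `mean`, `dispersion_raw`,
#'   `dispersion_trend`, `dispersion` (one row per feature).
#' @export
estimateDispersions <- function(counts, size_factors = NULL, groups = NULL,
                                min_disp = 1e-8,
                                min_features_loess = 50L, share = TRUE) {
    if (is(counts, "MirnaCountExperiment")) {
        if (is.null(groups)) groups <- sampleGroups(counts)
        counts <- assay(counts, "counts")
    }
    counts <- as.matrix(counts)
    if (is.null(groups)) stop("'groups' is required")
    groups <- factor(groups)
    if (is.null(size_factors)) size_factors <- estimateSizeFactors(counts)
    repl <- names(table(groups))[table(groups) >= 2L]
    if (length(repl) == 0L)
        stop("dispersion is not estimable without a replicated group")
    z <- sweep(counts, 2L, size_factors, "/")
    use <- groups %in% repl
    zr <- z[, use, drop = FALSE]
    gr <- droplevels(groups[use])

    mu <- rowMeans(zr)
    asum <- rep(0, nrow(zr)); wsum <- rep(0, nrow(zr))
    for (g in levels(gr)) {
        cols <- zr[, gr == g, drop = FALSE]
        ng <- ncol(cols)
        mu_g <- rowMeans(cols)
        v_g <- rowSums((cols - mu_g)^2) / (ng - 1L)
        ok_g <- mu_g > 0
        a_g <- ifelse(ok_g, (v_g - mu_g) / mu_g^2, 0)
        asum <- asum + ifelse(ok_g, (ng - 1L) * a_g, 0)
        wsum <- wsum + ifelse(ok_g, ng - 1L, 0)
    }
    raw <- ifelse(wsum > 0, pmax(asum / wsum, min_disp), NA_real_)

    ok <- is.finite(raw) & mu > 0
    trend <- rep(NA_real_, length(raw))
    if (sum(ok) >= min_features_loess) {
        lo <- stats::lowess(log(mu[ok]), raw[ok], f = 0.5)
        fit <- stats::approx(lo$x, lo$y, xout = log(mu[ok]), rule = 2,
                             ties = "ordered")$y
        trend[ok] <- pmax(fit, min_disp)
    } else if (sum(ok) >= 2L) {
        cf <- try(stats::coef(stats::lm(raw[ok] ~ I(1 / mu[ok]))),
                  silent = TRUE)
        if (!inherits(cf, "try-error") && all(is.finite(cf)))
            trend[ok] <- pmax(cf[1] + cf[2] / mu[ok], min_disp)
        else trend[ok] <- stats::median(raw[ok])
    } else trend[ok] <- raw[ok]

    final <- if (share) pmax(raw, trend, na.rm = FALSE) else raw
    data.frame(mean = mu, dispersion_raw = raw, dispersion_trend = trend,
               dispersion = final,
               row.names = rownames(counts) %||% NULL)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Exact conditional negative-binomial test for a two-group comparison
#'
#' Conditions on the total count K = sumA + sumB of a feature: under the
#' null of equal concentration, each group's sum is negative-binomial with
#' mean `q0 * S_g` (q0 = K divided by the total of all size factors, S_g the
#' group's size-factor total) and variance
#' `mu_g + dispersion * q0^2 * sum of squared size factors in g`. The
#' two-sided p-value sums, over all splits (a, K - a), the probabilities not
#' exceeding that of the observed split, normalized by the total over all
#' splits. At dispersion 0 this degenerates to the conditional
#' Poisson/binomial test. For K above `exact_limit` a Gaussian
#' approximation to the conditional distribution is used.
#'
#' @param sumA,sumB observed group sum counts (non-negative).
#' @param sfA,sfB size factors of the samples in each group.
#' @param dispersion shared dispersion alpha (>= 0).
#' @param exact_limit largest K for full enumeration (default 1e5).
#' @return two-sided p-value in (0, 1].
#' @examples
#' nbExactTest(0, 10, rep(1, 5), rep(1, 5), dispersion = 0)  # 2/1024
#' @export
nbExactTest <- function(sumA, sumB, sfA, sfB, dispersion,
                        exact_limit = 1e5) {
    if (sumA < 0 || sumB < 0) stop("counts must be non-negative")
    if (dispersion < 0) stop("dispersion must be >= 0")
    K <- sumA + sumB
    if (K == 0) return(1)
    SA <- sum(sfA); SB <- sum(sfB)
    q0 <- K / (SA + SB)
    muA <- q0 * SA; muB <- q0 * SB
    varA <- muA + dispersion * q0^2 * sum(sfA^2)
    varB <- muB + dispersion * q0^2 * sum(sfB^2)

    ldens <- function(k, mu, v) {
        if (v > mu * (1 + 1e-12)) {
            size <- mu^2 / (v - mu)
            stats::dnbinom(k, mu = mu, size = size, log = TRUE)
        } else stats::dpois(k, mu, log = TRUE)
    }
    if (K <= exact_limit) {
        a <- 0:K
        lp <- ldens(a, muA, varA) + ldens(K - a, muB, varB)
        lp <- lp - max(lp)
        pr <- exp(lp)
        obs <- pr[sumA + 1L]
        p <- sum(pr[pr <= obs * (1 + 1e-7)]) / sum(pr)
    } else {
        # Gaussian approximation to A | A + B = K
        v <- varA * varB / (varA + varB)
        z <- (abs(sumA - muA) - 0.5) / sqrt(v)
        p <- 2 * stats::pnorm(-max(z, 0))
    }
    min(max(p, .Machine$double.xmin), 1)
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate adjustment (via [stats::p.adjust()]), with
#' input validation: all p-values must lie in [0, 1].
#'
#' @param p numeric vector of p-values.
#' @return adjusted p-values, monotone in rank and capped at 1.
#' @export
adjustBH <- function(p) {
    if (any(is.na(p)) || any(p < 0 | p > 1))
        stop("p-values must lie in [0, 1]")
    stats::p.adjust(p, method = "BH")
}

#' Negative-binomial differential expression for one contrast
#'
#' Runs the full count-based DE stage for `contrast = c(test, reference)`:
#' median-of-ratios normalization, pooled dispersion estimation with trend
#' sharing (across *all* groups in the container, the pooling-mode
#' assumption), the exact conditional NB test per feature, and BH
#' adjustment. The log2 fold change is computed from normalized group means
#' with a pseudo-count of 0.5 added to both means when either is zero; the
#' mean rpm is taken over the samples of the contrast.
#'
#' @param x a [MirnaCountExperiment-class].
#' @param contrast character pair `c(test_group, reference_group)`, e.g.
#'   `c("IR", "Sham")`.
#' @param size_factors,dispersions optional precomputed values.
#' @param library_sizes per-sample read totals for rpm (defaults to the
#'   generator-recorded sizes if present, else column sums).
#' @return data.frame with columns `feature_id`, `baseMean`, `rpm_mean`,
#'   `log2FC`, `dispersion`, `p`, `p_adj`.
#' @export
mirnaDE <- function(x, contrast = c("IR", "Sham"), size_factors = NULL,
                    dispersions = NULL, library_sizes = NULL) {
    stopifnot(is(x, "MirnaCountExperiment"), length(contrast) == 2L)
    grp <- as.character(sampleGroups(x))
    if (!all(contrast %in% grp))
        stop("contrast group(s) absent from data: ",
             paste(setdiff(contrast, grp), collapse = ", "))
    counts <- assay(x, "counts")
    if (is.null(size_factors)) size_factors <- estimateSizeFactors(counts)
    if (is.null(dispersions))
        dispersions <- estimateDispersions(counts, size_factors, grp)
    if (is.null(library_sizes))
        library_sizes <- metadata(x)$library_sizes %||% colSums(counts)

    selA <- grp == contrast[1L]; selB <- grp == contrast[2L]
    sfA <- size_factors[selA]; sfB <- size_factors[selB]
    z <- sweep(counts, 2L, size_factors, "/")
    meanA <- rowMeans(z[, selA, drop = FALSE])
    meanB <- rowMeans(z[, selB, drop = FALSE])
    pseudo <- ifelse(meanA == 0 | meanB == 0, 0.5, 0)
    log2fc <- log2((meanA + pseudo) / (meanB + pseudo))

    rpm <- normalizeRpm(counts, library_sizes)
    rpm_mean <- rowMeans(rpm[, selA | selB, drop = FALSE])
    sumA <- rowSums(counts[, selA, drop = FALSE])
    sumB <- rowSums(counts[, selB, drop = FALSE])

    p <- vapply(seq_len(nrow(counts)), function(i) {
        if (sumA[i] + sumB[i] == 0) return(NA_real_)
        nbExactTest(sumA[i], sumB[i], sfA, sfB,
                    dispersion = dispersions$dispersion[i])
    }, numeric(1))
    p_adj <- rep(NA_real_, length(p))
    tested <- !is.na(p)
    p_adj[tested] <- adjustBH(p[tested])

    data.frame(feature_id = rownames(counts),
               baseMean = rowMeans(z[, selA | selB, drop = FALSE]),
               rpm_mean = rpm_mean, log2FC = log2fc,
               dispersion = dispersions$dispersion,
               p = p, p_adj = p_adj,
               row.names = NULL, stringsAsFactors = FALSE)
}

#' Apply the differential-expression filters
#'
#' A feature is called differentially expressed when it satisfies all three
#' criteria: (I) at least `fold_min`-fold up- or down-regulation, (II) mean
#' rpm above `rpm_min`, and (III) BH-adjusted p below `fdr_max`. Features in
#' `force_include` are added to the DE set regardless, flagged
#' `forced = TRUE` (the mechanism for biologically mandated inclusions such
#' as a miRNA family with a consistent but non-significant trend).
#'
#' @param res result table from [mirnaDE()].
#' @param fold_min minimum fold change (default 2; linear scale).
#' @param rpm_min minimum mean rpm (default 100; strict inequality).
#' @param fdr_max maximum adjusted p (default 0.05; strict inequality).
#' @param force_include character vector of feature ids to include
#'   regardless of the filters.
#' @return `res` with added columns `passes_filters`, `forced`, `de`
#'   (passes or forced) and `direction` (`"up"`/`"down"`/`"none"`).
#' @export
callDE <- function(res, fold_min = 2, rpm_min = 100, fdr_max = 0.05,
                   force_include = NULL) {
    if (fold_min <= 0 || rpm_min <= 0 || fdr_max <= 0)
        stop("thresholds must be positive")
    pass <- !is.na(res$p_adj) &
        abs(res$log2FC) >= log2(fold_min) &
        res$rpm_mean > rpm_min &
        res$p_adj < fdr_max
    forced <- canonId(res$feature_id) %in% canonId(force_include)
    res$passes_filters <- pass
    res$forced <- forced & !pass
    res$de <- pass | forced
    res$direction <- ifelse(!res$de, "none",
                            ifelse(res$log2FC > 0, "up", "down"))
    res
}
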