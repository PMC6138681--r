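#' Housekeeping normalization of a Cq table (delta-Cq)
#'
#' Subtracts, within each sample, the arithmetic mean of the reference-assay
#' Cq values from every target assay's Cq. Averaging on the cycle (log2)
#' scale is equivalent to normalizing linear quantities by the geometric
#' mean of the housekeeping genes. Missing reference Cq values are dropped
#' sample-wise; a sample with no usable reference value is an error.
#'
#' @param x a [CqExperiment-class].
#' @return numeric matrix of delta-Cq values, target assays x samples.
#' @examples
#' cq <- matrix(c(20, 21, 19, 24), ncol = 1,
#'              dimnames = list(c("r1", "r2", "r3", "g"), "s1"))
#' ce <- CqExperiment(cq, "Sham", c("r1", "r2", "r3"))
#' deltaCq(ce)  # g: 24 - mean(20,21,19) = 4
#' @export
deltaCq <- function(x) {
    stopifnot(is(x, "CqExperiment"))
    cq <- assay(x, "cq")
    ref <- rowData(x)$reference
    refcq <- cq[ref, , drop = FALSE]
    ref_mean <- colMeans(refcq, na.rm = TRUE)
    bad <- !is.finite(ref_mean)
    if (any(bad))
        stop("no usable reference Cq in sample(s): ",
             paste(colnames(cq)[bad], collapse = ", "))
    sweep(cq[!ref, , drop = FALSE], 2L, ref_mean, "-")
}

#' Relative quantities by the delta-delta-Cq method
#'
#' For each target assay, the delta-delta-Cq of a sample is its delta-Cq
#' minus the mean delta-Cq over the calibrator-group samples, and the
#' relative quantity is `2^(-ddCq)` (amplification efficiency fixed at 2).
#' The calibrator-group mean delta-delta-Cq is zero by construction, so the
#' geometric mean of calibrator quantities equals 1.
#'
#' @param dcq delta-Cq matrix from [deltaCq()] (targets x samples).
#' @param group group label per sample.
#' @param calibrator the calibrator group (default `"Sham"`).
#' @return A [FoldChangeTable-class].
#' @export
relativeQuantity <- function(dcq, group, calibrator = "Sham") {
    group <- factor(group)
    if (length(group) != ncol(dcq))
        stop("'group' must have one label per sample")
    cal <- which(group == calibrator)
    if (length(cal) == 0L)
        stop("calibrator group '", calibrator, "' has no samples")
    cal_mean <- rowMeans(dcq[, cal, drop = FALSE], na.rm = TRUE)
    ddcq <- sweep(dcq, 1L, cal_mean, "-")
    new("FoldChangeTable", quantity = 2^(-ddcq), group = group,
        calibrator = as.character(calibrator))
}

#' Per-group median and IQR of fold changes
#'
#' Summarizes a [FoldChangeTable-class] the way qPCR panel tables are
#' reported: median fold change relative to the calibrator, with the
#' interquartile range (Q3 - Q1, linear-interpolation quantiles) per group.
#' Groups with fewer than 2 samples get an `NA` IQR with a warning.
#'
#' @param fc a [FoldChangeTable-class].
#' @return data.frame with one row per feature and columns
#'   `median_<group>` / `iqr_<group>` for every group.
#' @export
summarizeFoldChanges <- function(fc) {
    stopifnot(is(fc, "FoldChangeTable"))
    q <- quantityMatrix(fc)
    grp <- sampleGroups(fc)
    out <- data.frame(feature_id = rownames(q), stringsAsFactors = FALSE)
    for (g in levels(grp)) {
        cols <- q[, grp == g, drop = FALSE]
        if (ncol(cols) < 2L)
            warning("group '", g, "' has < 2 samples; IQR reported missing")
        out[[paste0("median_", g)]] <-
            apply(cols, 1L, stats::median, na.rm = TRUE)
        out[[paste0("iqr_", g)]] <- apply(cols, 1L, iqrLinear)
    }
    rownames(out) <- NULL
    out
}

#' Exact two-sided Mann-Whitney test
#'
#' For small samples (n + m <= `exact_limit`) the permutation distribution
#' of the rank-sum statistic is enumerated exhaustively over all
#' C(n + m, n) group assignments, using midranks for ties; the two-sided
#' p-value is the probability of a statistic at least as far from its null
#' mean n*m/2 as the observed one. Larger samples fall back to the normal
#' approximation with the usual tie correction.
#'
#' @param x,y numeric sample vectors (non-empty).
#' @param exact_limit maximum n + m for exhaustive enumeration (default 16).
#' @return two-sided p-value in (0, 1].
#' @examples
#' mannWhitneyExact(1:5, 6:10)  # 2/252
#' @export
mannWhitneyExact <- function(x, y, exact_limit = 16L) {
    x <- x[!is.na(x)]; y <- y[!is.na(y)]
    n <- length(x); m <- length(y)
    if (n == 0L || m == 0L) stop("both samples must be non-empty")
    r <- rank(c(x, y))            # midranks
    u_obs <- sum(r[seq_len(n)]) - n * (n + 1) / 2
    center <- n * m / 2
    if (n + m <= exact_limit) {
        idx <- utils::combn(n + m, n)
        u_all <- colSums(matrix(r[idx], nrow = n)) - n * (n + 1) / 2
        dev <- abs(u_all - center)
        p <- mean(dev >= abs(u_obs - center) - 1e-9)
    } else {
        N <- n + m
        ties <- table(r)
        sigma2 <- n * m / 12 *
            ((N + 1) - sum(ties^3 - ties) / (N * (N - 1)))
        if (sigma2 <= 0) return(1)
        z <- (u_obs - center) / sqrt(sigma2)
        p <- 2 * stats::pnorm(-abs(z))
    }
    min(max(p, .Machine$double.xmin), 1)
}

#' Kruskal-Wallis rank-sum test across groups
#'
#' Thin wrapper over [stats::kruskal.test()] (H statistic with tie
#' correction; p from the chi-square approximation with k - 1 df), with the
#' argument and error contract of this pipeline.
#'
#' @param groups list of >= 2 non-empty numeric vectors.
#' @return list with elements `statistic` (H), `p.value`, `df`.
#' @examples
#' kruskalWallis(list(1:5, 6:10, 11:15))  # H = 12.5
#' @export
kruskalWallis <- function(groups) {
    if (!is.list(groups) || length(groups) < 2L)
        stop("'groups' must be a list of >= 2 samples")
    if (any(lengths(groups) == 0L))
        stop("all groups must be non-empty")
    kt <- stats::kruskal.test(groups)
    list(statistic = unname(kt$statistic), p.value = kt$p.value,
         df = unname(kt$parameter))
}

#' Three-group significance flagging of a qPCR panel
#'
#' Reproduces the reporting convention of focused qPCR array tables: for
#' each feature a Kruskal-Wallis test across the three groups acts as a
#' gatekeeper (pairwise tests count only when its p-value is below
#' `family_alpha`), then exact Mann-Whitney tests flag IR vs Sham
#' (`flag_star`, the table asterisk, at `alpha_star`) and IRT3 vs IR
#' (`flag_hash`, the table hash, at `alpha_hash`). An IRT3-vs-Sham test is
#' also reported, which downstream reversal classification uses to separate
#' full from partial reversion. Directions come from group medians and are
#' `"none"` when the corresponding flag is not set.
#'
#' @param fc a [FoldChangeTable-class] with all three groups present.
#' @param groups named character vector mapping the roles `sham`, `ir`,
#'   `irt3` to group labels.
#' @param alpha_star per-comparison threshold for IR vs Sham (default 0.017,
#'   a Bonferroni-style adjustment of 0.05 over three comparisons).
#' @param alpha_hash threshold for IRT3 vs IR (default 0.01).
#' @param family_alpha Kruskal-Wallis gate level (default 0.05).
#' @param gate apply the gatekeeping rule (set `FALSE` for pure pairwise
#'   testing).
#' @return data.frame with one row per feature: group medians/IQRs, `p_kw`,
#'   `p_vs_sham`, `p_vs_ir`, `p_irt3_vs_sham`, flags `flag_star`,
#'   `flag_hash`, `flag_irt3_vs_sham`, and `direction_ir`, `direction_t3`.
#' @export
classifyPanel <- function(fc,
                          groups = c(sham = "Sham", ir = "IR", irt3 = "IRT3"),
                          alpha_star = 0.017, alpha_hash = 0.01,
                          family_alpha = 0.05, gate = TRUE) {
    stopifnot(is(fc, "FoldChangeTable"))
    grp <- sampleGroups(fc)
    missing_g <- setdiff(groups, levels(grp))
    if (length(missing_g))
        stop("group(s) not present in data: ",
             paste(missing_g, collapse = ", "))
    q <- quantityMatrix(fc)
    sham <- q[, grp == groups[["sham"]], drop = FALSE]
    ir <- q[, grp == groups[["ir"]], drop = FALSE]
    irt3 <- q[, grp == groups[["irt3"]], drop = FALSE]

    res <- summarizeFoldChanges(fc)
    n <- nrow(q)
    p_kw <- p_star <- p_hash <- p_is <- rep(NA_real_, n)
    for (i in seq_len(n)) {
        xs <- sham[i, !is.na(sham[i, ])]
        xi <- ir[i, !is.na(ir[i, ])]
        xt <- irt3[i, !is.na(irt3[i, ])]
        p_kw[i] <- kruskalWallis(list(xs, xi, xt))$p.value
        p_star[i] <- mannWhitneyExact(xi, xs)
        p_hash[i] <- mannWhitneyExact(xt, xi)
        p_is[i] <- mannWhitneyExact(xt, xs)
    }
    pass_gate <- if (gate) p_kw < family_alpha else rep(TRUE, n)
    flag_star <- pass_gate & p_star < alpha_star
    flag_hash <- pass_gate & p_hash < alpha_hash
    flag_is <- pass_gate & p_is < alpha_star

    med_sham <- res[[paste0("median_", groups[["sham"]])]]
    med_ir <- res[[paste0("median_", groups[["ir"]])]]
    med_irt3 <- res[[paste0("median_", groups[["irt3"]])]]
    dir_ir <- ifelse(!flag_star, "none",
                     ifelse(med_ir > med_sham, "up", "down"))
    dir_t3 <- ifelse(!flag_hash, "none",
                     ifelse(med_irt3 > med_ir, "up", "down"))

    cbind(res,
          data.frame(p_kw = p_kw, p_vs_sham = p_star, p_vs_ir = p_hash,
                     p_irt3_vs_sham = p_is, flag_star = flag_star,
                     flag_hash = flag_hash, flag_irt3_vs_sham = flag_is,
                     direction_ir = dir_ir, direction_t3 = dir_t3,
                     stringsAsFactors = FALSE))
}

#' Bonferroni-adjusted per-comparison alpha
#'
#' The per-comparison level for `k` pairwise tests at family level `alpha`,
#' rounded to three decimals as conventionally reported (0.05 over three
#' comparisons gives 0.017).
#'
#' @param alpha family-wise level.
#' @param k number of comparisons.
#' @param digits rounding for the reported threshold (default 3).
#' @return the per-comparison threshold.
#' @export
bonferroniAlpha <- function(alpha = 0.05, k = 3L, digits = 3L) {
    round(alpha / k, digits)
}
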