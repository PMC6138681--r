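# internal helpers

# Evaluate expr under a local RNG state seeded with `seed`; the caller's
# .Random.seed is restored afterwards so simulation calls never perturb the
# session RNG stream.
withSeed <- function(seed, expr) {
    had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    if (had) old <- get(".Random.seed", envir = globalenv())
    on.exit({
        if (had) assign(".Random.seed", old, envir = globalenv())
        else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
            rm(".Random.seed", envir = globalenv())
    })
    set.seed(seed)
    expr
}

# case-normalized feature identifiers (gene symbols and miRNA names mix case
# across sources)
canonId <- function(x) tolower(trimws(as.character(x)))

stopIfNot01 <- function(x, what) {
    if (!is.numeric(x) || any(is.na(x)) || any(x < 0 | x > 1))
        stop("'", what, "' must lie in [0, 1]", call. = FALSE)
    invisible(x)
}

# linear-interpolation quartiles (type 7), IQR = Q3 - Q1
iqrLinear <- function(x) {
    x <- x[!is.na(x)]
    if (length(x) < 2) return(NA_real_)
    unname(diff(stats::quantile(x, c(0.25, 0.75), type = 7)))
}
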