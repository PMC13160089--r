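#' @include AllClasses.R
NULL

# Evaluate `expr` under a temporary RNG state seeded with `seed`, restoring
# the caller's RNG state afterwards.
.withSeed <- function(seed, expr) {
    if (!is.null(seed)) {
        had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
        if (had) old <- get(".Random.seed", envir = globalenv())
        on.exit({
            if (had) assign(".Random.seed", old, envir = globalenv())
            else if (exists(".Random.seed", envir = globalenv(),
                            inherits = FALSE))
                rm(".Random.seed", envir = globalenv())
        })
        set.seed(as.integer(seed))
    }
    force(expr)
}

# Deterministic child-seed derivation (Lehmer step plus stream offset),
# kept strictly below 2^31 so it is a valid R integer seed.
.childSeed <- function(seed, stream = 0L) {
    s <- (as.numeric(seed) %% 2147483647) * 48271 + as.numeric(stream) * 7919
    as.integer(s %% 2147483647)
}

.assertNumber <- function(x, name, lower = -Inf, upper = Inf,
                          strictLower = FALSE, strictUpper = FALSE) {
    if (!is.numeric(x) || length(x) != 1L || is.na(x))
        stop(sprintf("'%s' must be a single non-missing number", name),
             call. = FALSE)
    if (x < lower || (strictLower && x == lower))
        stop(sprintf("'%s' must be %s %g", name,
                     if (strictLower) ">" else ">=", lower), call. = FALSE)
    if (x > upper || (strictUpper && x == upper))
        stop(sprintf("'%s' must be %s %g", name,
                     if (strictUpper) "<" else "<=", upper), call. = FALSE)
    invisible(x)
}

.assertFraction <- function(x, name, allowOne = TRUE) {
    .assertNumber(x, name, 0, 1, strictUpper = !allowOne)
}
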