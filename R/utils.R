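`%||%` <- function(a, b) if (is.null(a)) b else a

# Evaluate expr under a local RNG stream; the caller's RNG state is restored.
withSeed <- function(seed, expr) {
    if (!is.null(seed)) {
        had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
        if (had) old <- get(".Random.seed", envir = globalenv())
        on.exit({
            if (had) assign(".Random.seed", old, envir = globalenv())
            else if (exists(".Random.seed", envir = globalenv(),
                            inherits = FALSE))
                rm(".Random.seed", envir = globalenv())
        })
        set.seed(seed)
    }
    expr
}

# Derive independent per-component seeds from one global seed, keeping the
# result inside the 32-bit integer range.
fanOutSeed <- function(seed, component) {
    if (is.null(seed)) return(NULL)
    offs <- sum(utf8ToInt(component) * seq_along(utf8ToInt(component)))
    as.integer((as.numeric(seed) * 7919 + offs) %% .Machine$integer.max)
}
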