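## RNG scoping: simulator and sampler entry points take an explicit seed and
## must not disturb the caller's RNG stream.
.seededRNG <- function(seed) {
    stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
    had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
    set.seed(as.integer(seed))
    list(restore = function() {
        if (had) assign(".Random.seed", old, envir = globalenv())
        else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
            rm(".Random.seed", envir = globalenv())
    })
}

## derive a reproducible sub-seed for an independent simulator stage,
## kept below 2^31 - 1
.subSeed <- function(seed, offset) {
    (as.numeric(seed) * 1000 + offset) %% 2147483647
}
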