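# internal helpers

# run code under a temporary RNG seed, restoring global state afterwards
withSeed <- function(seed, code) {
    if (!is.null(seed)) {
        old <- if (exists(".Random.seed", envir = globalenv()))
            get(".Random.seed", envir = globalenv()) else NULL
        on.exit({
            if (is.null(old)) {
                if (exists(".Random.seed", envir = globalenv()))
                    rm(".Random.seed", envir = globalenv())
            } else assign(".Random.seed", old, envir = globalenv())
        })
        set.seed(seed)
    }
    force(code)
}

# deterministic content hash of a character scalar (via tools::md5sum)
contentHash <- function(txt) {
    f <- tempfile()
    on.exit(unlink(f))
    writeLines(txt, f)
    unname(tools::md5sum(f))
}

stopIfNot <- function(cond, ...) if (!cond) stop(..., call. = FALSE)
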