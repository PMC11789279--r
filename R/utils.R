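# Run expr with a local RNG stream: the global .Random.seed is saved and
# restored, so generators never leak state between calls.
withLocalSeed <- function(seed, expr) {
    if (!is.null(seed)) {
        has_old <- exists(".Random.seed", envir = globalenv(),
                          inherits = FALSE)
        if (has_old)
            old <- get(".Random.seed", envir = globalenv(), inherits = FALSE)
        on.exit({
            if (has_old)
                assign(".Random.seed", old, envir = globalenv())
            else if (exists(".Random.seed", envir = globalenv(),
                            inherits = FALSE))
                rm(".Random.seed", envir = globalenv())
        })
        set.seed(seed)
    }
    expr
}

stopIfNot <- function(cond, msg, class = "spinecyto_parameter_error") {
    if (!cond)
        stop(errorCondition(msg, class = c(class, "error", "condition")))
    invisible(TRUE)
}
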