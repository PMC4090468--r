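# internal helpers

# run expr with a given RNG seed, restoring the caller's RNG state afterwards
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

stop_validation <- function(...) {
  stop(errorCondition(paste0(...), class = c("seizpred_validation", "error")))
}

stop_config <- function(...) {
  stop(errorCondition(paste0(...), class = c("seizpred_config", "error")))
}

stop_monotonic <- function(...) {
  stop(errorCondition(paste0(...), class = c("seizpred_monotonic", "error")))
}

is_scalar_num <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)
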