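`%||%` <- function(a, b) if (is.null(a)) b else a

# user-facing errors that the CLI maps to exit status 1
stop_user <- function(...) {
  stop(structure(class = c("qpcrUserError", "error", "condition"),
                 list(message = paste0(...), call = sys.call(-1))))
}

# deterministic per-replicate seed in [0, 2^31 - 2]; 2^31 - 1 is prime, so for
# a fixed base seed the map i -> seed is injective over any practical n_reps
derive_seed <- function(seed, i) {
  x <- (as.double(seed) %% 2147483647) * 48271 + as.double(i) * 1664525 + 1013904223
  as.integer(x %% 2147483647)
}
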