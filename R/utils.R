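`%||%` <- function(x, y) if (is.null(x)) y else x

#' @keywords internal
rmse <- function(obs, pred) sqrt(mean((obs - pred)^2))

# Deterministic substream seed derived from a user seed and a small offset.
# Kept strictly below 2^31 - 1 so it is always a valid R integer seed.
substream_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) * 7919 + as.numeric(offset) * 104729) %% 2147483629)
}

stop_format <- function(...) {
  stop(structure(class = c("priorselect_format_error", "error", "condition"),
                 list(message = sprintf(...), call = NULL)))
}

is_binary01 <- function(x) all(x %in% c(0, 1))
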