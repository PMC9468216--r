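#' @importFrom rlang abort warn inform %||% .data
#' @importFrom stats pchisq plogis qnorm runif setNames uniroot
#' @importFrom utils head
NULL

# Deterministic sub-seed for a named random stream, so that partial re-runs
# of a pipeline reuse identical draws. Kept below 2^31 - 1.
sub_seed <- function(seed, stream) {
  stopifnot(length(seed) == 1L, is.finite(seed))
  chars <- utf8ToInt(stream)
  h <- sum(chars * seq_along(chars)) %% 65536
  as.integer((abs(as.numeric(seed)) * 48271 + h * 7919 + 1) %% 2147483629)
}

stop_contract <- function(msg, class = "mmdbn_contract_error") {
  abort(msg, class = c(class, "mmdbn_error"))
}

# round-half-up at `digits`, matching the reporting style of survey tables
# (base round() is round-half-even)
round_half_up <- function(x, digits = 1) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

is_whole <- function(x) {
  is.numeric(x) & is.finite(x) & abs(x - round(x)) < 1e-8
}
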