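# Condition classes shared across the package.
#
# Three error families map onto the CLI exit codes:
#   fpca_value_error      -- invalid argument values (exit 2)
#   fpca_structural_error -- malformed panel structure (exit 2)
#   fpca_estimation_error -- a model fit failed (exit 3)

stop_value <- function(msg, ...) {
  stop(errorCondition(sprintf(msg, ...),
                      class = c("fpca_value_error", "fpca_error")))
}

stop_structural <- function(msg, ...) {
  stop(errorCondition(sprintf(msg, ...),
                      class = c("fpca_structural_error", "fpca_error")))
}

stop_estimation <- function(msg, ...) {
  stop(errorCondition(sprintf(msg, ...),
                      class = c("fpca_estimation_error", "fpca_error")))
}

# Run an expression with a temporary RNG seed, restoring the caller's RNG
# state afterwards so package functions never disturb the user's stream.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(as.integer(seed))
  expr
}

# Derive a child seed from a base seed and stream indices, kept inside the
# 32-bit signed integer range required by set.seed().
derive_seed <- function(seed, ...) {
  idx <- c(...)
  s <- as.double(seed)
  for (i in idx) s <- (s * 69069 + 1234567 + as.double(i)) %% 2147483647
  as.integer(s)
}
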