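# Structured error conditions. Every user-facing failure mode carries a
# subclass of "filmcal_error" so callers (and the CLI) can branch on the
# kind of failure rather than on message text.

filmcal_abort <- function(message, class, ...) {
  cond <- structure(
    class = c(class, "filmcal_error", "error", "condition"),
    list(message = message, call = sys.call(-1), ...)
  )
  stop(cond)
}

abort_domain <- function(msg) filmcal_abort(msg, "filmcal_domain_error")
abort_below_background <- function(msg) filmcal_abort(msg, "filmcal_below_background_error")
abort_saturation <- function(msg) filmcal_abort(msg, "filmcal_saturation_error")
abort_infeasible <- function(msg) filmcal_abort(msg, "filmcal_infeasible_error")
abort_unidentifiable <- function(msg) filmcal_abort(msg, "filmcal_unidentifiable_error")
abort_lookup <- function(msg) filmcal_abort(msg, "filmcal_lookup_error")
abort_config <- function(msg) filmcal_abort(msg, "filmcal_config_error")
abort_parse <- function(msg) filmcal_abort(msg, "filmcal_parse_error")
abort_usage <- function(msg) filmcal_abort(msg, "filmcal_usage_error")

# Evaluate `code` under a fixed RNG seed without disturbing the caller's
# RNG stream. A NULL seed leaves the global stream untouched.
with_seed <- function(seed, code) {
  if (is.null(seed)) {
    return(force(code))
  }
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    set.seed(NULL)
  }
  old <- get(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(seed)
  force(code)
}
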