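#' @keywords internal
stop_invalid <- function(...) {
  stop(errorCondition(paste0(...), class = c("quietmr_invalid", "error")))
}

#' @keywords internal
stop_infeasible <- function(...) {
  stop(errorCondition(paste0(...),
                      class = c("quietmr_infeasible", "error")))
}

check_scalar <- function(x, name, finite = TRUE) {
  if (!is.numeric(x) || length(x) != 1L || (finite && !is.finite(x)))
    stop_invalid(name, " must be a single finite number")
  invisible(x)
}

# Rolling polynomial hash over a serialized object; returns a hex string.
# Used to stamp reports with a configuration fingerprint without extra
# dependencies (not cryptographic).
config_hash <- function(x) {
  raw <- serialize(x, connection = NULL, version = 2)
  # drop serialization header (R version bytes) so the hash is stable
  raw <- raw[-seq_len(14)]
  h <- 0
  for (b in as.integer(raw))
    h <- (h * 131 + b) %% 2147483629
  sprintf("%08x", as.integer(h))
}

# Centered n-point index offsets: -floor(n/2) .. ceiling(n/2)-1, DC at
# floor(n/2)+1 (1-based).
centered_offsets <- function(n) seq_len(n) - (n %/% 2L) - 1L

nrmse <- function(x, ref) {
  sqrt(sum(Mod(x - ref)^2) / sum(Mod(ref)^2))
}
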