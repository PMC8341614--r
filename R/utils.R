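#' Derive a reproducible child seed from a master seed and a label
#'
#' Stage and restart seeds are a stable hash of the master seed and a text
#' label, so adding stages (or restarts) never perturbs the random streams of
#' earlier ones. The result always lies in `[1, 2^31 - 2]`.
#'
#' @param seed integer master seed.
#' @param label character scalar naming the consumer of the child stream.
#' @return an integer seed.
#' @export
derive_seed <- function(seed, label) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(label))
  m <- 2147483647 # 2^31 - 1, prime
  s <- abs(as.numeric(seed)) %% m
  for (ch in utf8ToInt(paste(label, collapse = "/"))) {
    s <- (s * 31 + ch) %% m
  }
  as.integer(s %% (m - 2) + 1)
}

# all permutations of 1..n as a list (n is small: cluster counts)
permutations <- function(n) {
  if (n == 1L) return(list(1L))
  out <- list()
  for (p in permutations(n - 1L)) {
    for (pos in seq_len(n)) {
      out[[length(out) + 1L]] <- append(p, n, after = pos - 1L)
    }
  }
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_bt <- function(...) stop(..., call. = FALSE)
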