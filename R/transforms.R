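#' Response transformations used before mixed-model fits
#'
#' Integrated z-scores can be negative, so the log and square-root
#' transforms are applied after a minimal order-preserving shift:
#' `log(x - min(x) + 1)` and `sqrt(x - min(x))`. The rank transform uses
#' ascending ranks with ties receiving the average rank.
#'
#' @param values numeric vector.
#' @param kind one of `"none"`, `"log-shift"`, `"sqrt-shift"`, `"rank"`.
#' @return transformed numeric vector of the same length.
#' @export
transform_dimension <- function(values,
                                kind = c("none", "log-shift", "sqrt-shift",
                                         "rank")) {
  kind <- match.arg(kind)
  if (length(values) == 0L) stop_bt("empty input to transform_dimension")
  if (anyNA(values) || any(!is.finite(values))) {
    stop_bt("values must be finite")
  }
  switch(kind,
    "none" = values,
    "log-shift" = log(values - min(values) + 1),
    "sqrt-shift" = sqrt(values - min(values)),
    "rank" = rank(values, ties.method = "average"))
}
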