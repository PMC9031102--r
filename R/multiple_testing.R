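#' Benjamini-Hochberg FDR adjustment of one p-value family
#'
#' Step-up adjustment q_(i) = min_{j >= i} (m * p_(j) / j), capped at 1,
#' returned in input order. One family per tested effect across all isoforms.
#' Missing p-values propagate as NA and do not count towards the family size
#' m. The step-up arithmetic is delegated to \code{stats::p.adjust(method =
#' "BH")}; this wrapper owns validation and NA bookkeeping.
#'
#' @param p numeric p-values in [0, 1], NA allowed.
#' @return q-values, same length and order as \code{p}.
#' @export
bh_adjust <- function(p) {
  if (length(p) == 0L) stop("empty p-value family")
  ok <- !is.na(p)
  if (any(p[ok] < 0 | p[ok] > 1))
    stop("p-values must lie in [0, 1]")
  q <- rep(NA_real_, length(p))
  q[ok] <- stats::p.adjust(p[ok], method = "BH")
  q
}
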