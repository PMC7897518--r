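#' Circular genome intervals
#'
#' The human mitochondrial genome is circular, so genomic intervals may wrap
#' across the origin (e.g. the control region, rCRS 16024-576). A circular
#' interval is stored as 1-based inclusive `start` and `end` on a circle of
#' length `L`; when `start > end` the interval wraps through position `L`
#' and back to 1.
#'
#' @param start,end 1-based inclusive endpoints, each within `1..L`.
#' @param L genome length (default 16569, the rCRS).
#' @return An object of class `circular_interval`.
#' @examples
#' circular_interval(16024, 576)   # the mtDNA control region, wraps the origin
#' circular_interval(3485, 3553)   # a 69 bp coding-region amplicon
#' @export
circular_interval <- function(start, end, L = 16569L) {
  start <- as.integer(start); end <- as.integer(end); L <- as.integer(L)
  stopifnot(length(start) == 1, length(end) == 1, L >= 1)
  if (is.na(start) || is.na(end) || start < 1 || start > L || end < 1 || end > L)
    stop("interval endpoints must lie in 1..", L)
  structure(list(start = start, end = end, L = L), class = "circular_interval")
}

#' @export
print.circular_interval <- function(x, ...) {
  cat(sprintf("<circular interval %d-%d on circle of %d bp (%d bp)>\n",
              x$start, x$end, x$L, circular_length(x)))
  invisible(x)
}

#' Inclusive length of a circular interval
#'
#' Counts positions 1-based inclusively; a wrapping interval contributes
#' `(L - start + 1) + end` positions.
#'
#' @param iv a [circular_interval()].
#' @return Integer number of positions covered.
#' @examples
#' circular_length(circular_interval(3485, 3553))  # 69
#' circular_length(circular_interval(16024, 576))  # 1122
#' @export
circular_length <- function(iv) {
  stopifnot(inherits(iv, "circular_interval"))
  if (iv$start <= iv$end) iv$end - iv$start + 1L
  else (iv$L - iv$start + 1L) + iv$end
}

#' Enumerate the positions of a circular interval in circular order
#'
#' @param iv a [circular_interval()].
#' @return Integer vector of positions, starting at `iv$start`.
#' @export
circular_positions <- function(iv) {
  stopifnot(inherits(iv, "circular_interval"))
  if (iv$start <= iv$end) seq.int(iv$start, iv$end)
  else c(seq.int(iv$start, iv$L), seq.int(1L, iv$end))
}

#' Test whether positions fall inside circular intervals
#'
#' @param pos integer vector of 1-based positions.
#' @param range a `circular_interval` or list of them.
#' @return Logical vector, `TRUE` where the position is covered by any
#'   interval of `range`.
#' @export
in_covered_range <- function(pos, range) {
  ivs <- as_interval_list(range)
  out <- rep(FALSE, length(pos))
  for (iv in ivs) {
    hit <- if (iv$start <= iv$end) pos >= iv$start & pos <= iv$end
           else pos >= iv$start | pos <= iv$end
    out <- out | hit
  }
  out
}

# Normalise range arguments: single interval -> list of intervals.
as_interval_list <- function(range) {
  if (inherits(range, "circular_interval")) return(list(range))
  if (is.list(range) && all(vapply(range, inherits, TRUE, "circular_interval")))
    return(range)
  stop("range must be a circular_interval or a list of them")
}

range_identical <- function(a, b) {
  a <- as_interval_list(a); b <- as_interval_list(b)
  identical(lapply(a, unclass), lapply(b, unclass))
}

#' The mtDNA control region as a circular interval
#'
#' rCRS positions 16024-576 across the replication origin; the region
#' conventionally sequenced in forensic mtDNA work.
#'
#' @param L genome length (default 16569).
#' @return A [circular_interval()].
#' @export
control_region <- function(L = 16569L) circular_interval(16024L, 576L, L)

#' The full mitochondrial genome as an interval
#'
#' @param L genome length (default 16569).
#' @return A [circular_interval()].
#' @export
full_genome <- function(L = 16569L) circular_interval(1L, L, L)
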