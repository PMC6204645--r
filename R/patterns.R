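#' Compress an alignment into site patterns
#'
#' Groups identical alignment columns into distinct site patterns with
#' multiplicities, the standard speedup for likelihood computation. Pattern
#' order is the order of first occurrence, so compression is deterministic.
#'
#' @param aln a character matrix over `A`, `C`, `G`, `T`, `N`, `-` with
#'   taxa in rows and rownames set.
#' @return an object of class `pattern_table`: a list with `states`
#'   (patterns x taxa integer matrix, 0..3 = A,C,G,T, 4 = missing),
#'   `counts`, `n` (total sites), `taxa`, and `const_state` (-1 for a
#'   variable pattern, otherwise the shared state, 4 if all missing).
#' @examples
#' aln <- rbind(s1 = c("A", "A", "C"), s2 = c("A", "A", "G"))
#' compress_patterns(aln)$counts  # 2 1
#' @export
compress_patterns <- function(aln) {
  stopifnot(is.matrix(aln))
  if (nrow(aln) < 2L) stop("alignment must contain at least two sequences")
  if (ncol(aln) < 1L) stop("alignment must contain at least one site")
  if (is.null(rownames(aln))) stop("alignment must have taxon rownames")

  code <- match(aln, c("A", "C", "G", "T"))
  code[is.na(code)] <- 5L
  im <- matrix(code - 1L, nrow(aln), ncol(aln))

  keys <- do.call(paste, c(lapply(seq_len(nrow(im)), function(i) im[i, ]),
                           sep = "."))
  first <- !duplicated(keys)
  idx <- match(keys, keys[first])
  counts <- tabulate(idx, nbins = sum(first))
  states <- t(im[, first, drop = FALSE])

  const_state <- apply(states, 1L, function(v) {
    nm <- v[v < 4L]
    if (length(nm) == 0L) 4L
    else if (all(nm == nm[1L])) nm[1L]
    else -1L
  })

  structure(
    list(states = states, counts = counts, n = ncol(aln),
         taxa = rownames(aln), const_state = as.integer(const_state)),
    class = "pattern_table"
  )
}

#' @export
print.pattern_table <- function(x, ...) {
  cat(sprintf("pattern_table: %d sites, %d distinct patterns, %d taxa\n",
              x$n, length(x$counts), length(x$taxa)))
  cat(sprintf("constant-site fraction: %.4g\n", constant_fraction(x)))
  invisible(x)
}

#' Fraction of constant sites
#'
#' A site is constant when all its non-missing states agree (all-missing
#' sites count as constant). This fraction is the upper end of the grid of
#' `p_inv` starting values used by [fit_ig()], and an upper bound for any
#' estimate of the invariable proportion.
#'
#' @param patterns a [compress_patterns()] table.
#' @return the count-weighted fraction of constant sites.
#' @export
constant_fraction <- function(patterns) {
  stopifnot(inherits(patterns, "pattern_table"))
  sum(patterns$counts[patterns$const_state >= 0L]) / patterns$n
}
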