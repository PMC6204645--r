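## Internal: postorder tree + pattern columns aligned to tip order.
prepare_engine_input <- function(tree, patterns) {
  stopifnot(inherits(tree, "phylo"), inherits(patterns, "pattern_table"))
  if (is.null(tree$edge.length)) stop("tree must carry branch lengths")
  if (any(tree$edge.length < 0)) stop("branch lengths must be nonnegative")
  ord <- match(tree$tip.label, patterns$taxa)
  if (anyNA(ord) || length(tree$tip.label) != length(patterns$taxa))
    stop("tree tips and alignment taxa do not match")
  tr <- reorder(tree, "postorder")
  list(tree = tr,
       states = patterns$states[, ord, drop = FALSE])
}

## Internal: log-likelihood of the invariable category per pattern:
## log(1/4) for a constant pattern (shared non-missing state), 0 for an
## all-missing pattern, -Inf otherwise.
invariable_logliks <- function(patterns) {
  ifelse(patterns$const_state == 4L, 0,
         ifelse(patterns$const_state >= 0L, log(0.25), -Inf))
}

## Internal: same on the plain (not log) scale, as the C++ engine expects.
invariable_liks <- function(patterns) {
  ifelse(patterns$const_state == 4L, 1,
         ifelse(patterns$const_state >= 0L, 0.25, 0))
}

#' Per-pattern, per-category likelihoods
#'
#' Computes the matrix `L[i, j] = P(D_i | r_j)` (on the log scale) for every
#' site pattern `i` and mixture category `j = 0..k`. Categories `j >= 1` use
#' the pruning algorithm with every branch scaled by the category rate;
#' category 0 (rate zero) has likelihood 1/4 for a constant pattern, 1 for
#' an all-missing pattern and 0 otherwise. Missing states (N, gap)
#' contribute a partial likelihood of 1 for every nucleotide.
#'
#' @param tree an [ape::phylo] tree with branch lengths.
#' @param mixture a [rate_mixture()].
#' @param patterns a [compress_patterns()] table.
#' @param kappa K2P transition/transversion rate ratio.
#' @return an object of class `pattern_likelihoods`: list with `loglik`
#'   (patterns x (k+1) matrix, invariable category in column 1, `-Inf`
#'   allowed) and `weights` (the mixture weights used).
#' @export
pattern_category_likelihoods <- function(tree, mixture, patterns, kappa = 4) {
  inp <- prepare_engine_input(tree, patterns)
  lv <- ig_cat_loglik_cpp(inp$tree$edge, inp$tree$edge.length, inp$states,
                          mixture$rates[-1L], kappa)
  ll <- cbind(invariable_logliks(patterns), lv)
  colnames(ll) <- paste0("cat", 0:mixture$k)
  structure(list(loglik = ll, weights = mixture$weights),
            class = "pattern_likelihoods")
}

## Internal: per-pattern mixture log-likelihood log(sum_j w_j L_ij) from a
## pattern_likelihoods object, by log-sum-exp.
pattern_mixture_loglik <- function(pat_liks) {
  a <- sweep(pat_liks$loglik, 2L, log(pat_liks$weights), "+")
  m <- do.call(pmax, as.data.frame(a))
  bad <- !is.finite(m)
  if (any(bad))
    stop("pattern ", which(bad)[1L],
         " has zero likelihood under every mixture category")
  m + log(rowSums(exp(a - m)))
}

#' Mixture log-likelihood of an alignment on a tree
#'
#' `sum_i count_i * log(sum_j w_j P(D_i | r_j))` over the compressed site
#' patterns, with per-pattern scaling against underflow.
#'
#' @inheritParams pattern_category_likelihoods
#' @return the log-likelihood (a single number).
#' @export
log_likelihood <- function(tree, mixture, patterns, kappa = 4) {
  pl <- pattern_category_likelihoods(tree, mixture, patterns, kappa)
  sum(patterns$counts * pattern_mixture_loglik(pl))
}

#' Log-likelihood at a fully specified parameter point
#'
#' Plain evaluation without any optimization, for comparing fitted
#' estimates against the generating ("true") parameters and for likelihood
#' surface scans.
#'
#' @param tree tree with branch lengths at which to evaluate.
#' @param alpha Gamma shape parameter.
#' @param p_inv invariable proportion.
#' @param patterns a [compress_patterns()] table (or an alignment matrix,
#'   which is compressed on the fly).
#' @param kappa K2P transition/transversion rate ratio.
#' @param k number of Gamma categories.
#' @return the log-likelihood.
#' @export
loglik_at <- function(tree, alpha, p_inv, patterns, kappa = 4, k = 4) {
  if (is.matrix(patterns)) patterns <- compress_patterns(patterns)
  log_likelihood(tree, rate_mixture(alpha, p_inv, k), patterns, kappa)
}
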