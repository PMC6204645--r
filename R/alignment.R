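#' Simulate an alignment along a tree under K2P + I + discrete Gamma
#'
#' Seq-Gen-style simulation: each site independently draws a rate category
#' from the mixture weights, the root state is drawn from the uniform
#' stationary distribution, and states are propagated along every branch by
#' sampling from the K2P transition matrix evaluated at branch length times
#' the site's category rate (pre-order, node-by-node). Sites in category 0
#' are invariable and identical across all taxa. The whole alignment is
#' driven by one random stream, so a single integer seed makes it
#' reproducible.
#'
#' @param tree an [ape::phylo] tree with branch lengths.
#' @param mixture a [rate_mixture()].
#' @param n_sites number of sites (>= 0).
#' @param kappa K2P transition/transversion rate ratio (default 4,
#'   i.e. an expected-counts ratio of 2).
#' @param seed optional integer seed; `NULL` uses the current RNG state.
#' @return a character matrix (taxa in rows, rownames are tip labels) over
#'   `A`, `C`, `G`, `T` with attributes `site_category` (the true per-site
#'   category, 0 = invariable) and `params` (the generating parameters).
#' @examples
#' tr <- make_balanced_tree(6, 0.1, 0.2)
#' aln <- simulate_alignment(tr, rate_mixture(0.5, 0.2), 1000, seed = 1)
#' dim(aln)
#' @export
simulate_alignment <- function(tree, mixture, n_sites, kappa = 4, seed = NULL) {
  stopifnot(inherits(tree, "phylo"), inherits(mixture, "rate_mixture"))
  if (is.null(tree$edge.length) || any(tree$edge.length < 0))
    stop("tree must carry nonnegative branch lengths")
  if (!is.numeric(n_sites) || length(n_sites) != 1L || n_sites < 0 ||
      n_sites != round(n_sites))
    stop("'n_sites' must be a single nonnegative integer")
  if (!is.numeric(kappa) || kappa <= 0) stop("'kappa' must be positive")
  n_sites <- as.integer(n_sites)
  if (!is.null(seed)) set.seed(seed)

  tr <- reorder(tree, "postorder")
  ntip <- length(tr$tip.label)
  nnode <- ntip + tr$Nnode
  root <- tr$edge[nrow(tr$edge), 1L]

  cat_idx <- sample.int(length(mixture$weights), n_sites, replace = TRUE,
                        prob = mixture$weights) - 1L
  site_rate <- mixture$rates[cat_idx + 1L]

  states <- matrix(NA_integer_, nnode, n_sites)
  states[root, ] <- sample.int(4L, n_sites, replace = TRUE) - 1L
  for (e in rev(seq_len(nrow(tr$edge)))) {  # pre-order: parents before children
    par <- tr$edge[e, 1L]
    chi <- tr$edge[e, 2L]
    states[chi, ] <- evolve_states(states[par, ],
                                   tr$edge.length[e] * site_rate, kappa)
  }

  seqs <- matrix(c("A", "C", "G", "T")[states[seq_len(ntip), , drop = FALSE] + 1L],
                 ntip, n_sites)
  rownames(seqs) <- tr$tip.label
  attr(seqs, "site_category") <- cat_idx
  attr(seqs, "params") <- list(alpha = mixture$alpha, p_inv = mixture$p_inv,
                               k = mixture$k, kappa = kappa,
                               tree_length = tree_length(tree),
                               n_sites = n_sites, seed = seed)
  seqs
}

## Vectorized single-branch evolution: per site, keep the parent state with
## probability P_same(d), move to the transition partner with P_ti(d), else
## to one of the two transversion partners with equal probability. State
## codes 0..3 = A,C,G,T; XOR with 2 gives the transition partner, XOR with
## 1 or 3 the transversion partners.
evolve_states <- function(parent, d, kappa) {
  beta <- 1 / (kappa + 2)
  e1 <- exp(-4 * beta * d)
  e2 <- exp(-2 * (kappa + 1) * beta * d)
  p_same <- 0.25 + 0.25 * e1 + 0.5 * e2
  p_ti   <- 0.25 + 0.25 * e1 - 0.5 * e2
  n <- length(parent)
  u <- runif(n)
  w <- runif(n)
  child <- parent
  ti <- u >= p_same & u < p_same + p_ti
  tv <- u >= p_same + p_ti
  child[ti] <- bitwXor(parent[ti], 2L)
  if (any(tv))
    child[tv] <- bitwXor(parent[tv], ifelse(w[tv] < 0.5, 1L, 3L))
  child
}

#' Read / write alignments in FASTA or relaxed PHYLIP
#'
#' File I/O goes through `ape`; sequences are stored as an uppercase
#' character matrix with taxa in rows. On reading, characters outside
#' `A`, `C`, `G`, `T`, `-` are mapped to `N` with a warning; both `N` and
#' `-` are treated as missing data by the likelihood functions.
#'
#' @param path file path.
#' @param format `"fasta"` or `"phylip"` (sequential).
#' @param aln a character matrix with rownames (as returned by
#'   [simulate_alignment()] or [read_alignment()]).
#' @return `read_alignment`: the alignment matrix; `write_alignment`:
#'   `path`, invisibly.
#' @export
read_alignment <- function(path, format = c("fasta", "phylip")) {
  format <- match.arg(format)
  if (format == "fasta") {
    # seqinr preserves arbitrary residue letters, so unknowns can be
    # reported rather than silently dropped
    x <- seqinr::read.fasta(path, seqtype = "DNA", forceDNAtolower = FALSE)
    if (length(unique(lengths(x))) > 1L)
      stop("ragged alignment: sequences differ in length")
    m <- do.call(rbind, lapply(x, as.character))
    rownames(m) <- names(x)
  } else {
    x <- ape::read.dna(path, format = "sequential")
    m <- as.character(x)
  }
  m <- toupper(m)
  bad <- !(m %in% c("A", "C", "G", "T", "N", "-"))
  if (any(bad)) {
    warning(sum(bad), " unrecognized character(s) mapped to N")
    m[bad] <- "N"
  }
  m
}

#' @rdname read_alignment
#' @export
write_alignment <- function(aln, path, format = c("fasta", "phylip")) {
  format <- match.arg(format)
  stopifnot(is.matrix(aln), !is.null(rownames(aln)))
  x <- ape::as.DNAbin(aln)
  if (format == "fasta") {
    ape::write.dna(x, path, format = "fasta", colsep = "", colw = 80)
  } else {
    ape::write.dna(x, path, format = "sequential", colsep = "", nbcol = -1)
  }
  invisible(path)
}
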