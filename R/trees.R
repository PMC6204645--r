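#' Construct a balanced unrooted tree with uniform branch lengths
#'
#' Builds the maximally balanced unrooted binary tree on `n_taxa` leaves:
#' the central node splits the taxa into three groups of as even size as
#' possible and each group is a balanced rooted subtree (even splits at
#' every level). For `n_taxa = 6` this is the three-cherry shape
#' `((t1,t2),(t3,t4),(t5,t6))`. All branch lengths are set to
#' `branch_length`, in expected substitutions per site. If `long_internal`
#' is given, the internal branch adjacent to the first cherry is set to
#' that value instead; on the 6-taxon tree this creates three distinct
#' leaf-to-leaf distances, the condition under which the invariable-sites
#' plus continuous-Gamma model is identifiable.
#'
#' @param n_taxa number of leaves (at least 3).
#' @param branch_length branch length assigned to every branch (> 0).
#' @param long_internal optional length for the internal branch adjacent to
#'   the first cherry; `NULL` leaves all branches at `branch_length`.
#' @param labels taxon labels; default `t1 ... tn`.
#' @return an [ape::phylo] tree with `2 * n_taxa - 3` branches.
#' @examples
#' tr <- make_balanced_tree(6, 0.1, long_internal = 0.2)
#' tree_length(tr)  # 1.0
#' @export
make_balanced_tree <- function(n_taxa, branch_length = 0.1, long_internal = NULL,
                               labels = NULL) {
  if (!is.numeric(n_taxa) || length(n_taxa) != 1L || n_taxa != round(n_taxa))
    stop("'n_taxa' must be a single integer")
  n_taxa <- as.integer(n_taxa)
  if (n_taxa < 3L) stop("'n_taxa' must be at least 3")
  if (!is.numeric(branch_length) || branch_length <= 0)
    stop("'branch_length' must be positive")
  if (is.null(labels)) labels <- paste0("t", seq_len(n_taxa))
  if (length(labels) != n_taxa || anyDuplicated(labels))
    stop("'labels' must be ", n_taxa, " unique taxon names")

  build <- function(lab) {
    n <- length(lab)
    if (n == 1L) return(lab)
    h <- ceiling(n / 2)
    paste0("(", build(lab[seq_len(h)]), ",", build(lab[(h + 1L):n]), ")")
  }
  sizes <- rep(n_taxa %/% 3L, 3L) +
    c(rep(1L, n_taxa %% 3L), rep(0L, 3L - n_taxa %% 3L))
  grp <- split(seq_len(n_taxa), rep.int(1:3, sizes))
  nwk <- paste0("(",
                paste(vapply(grp, function(i) build(labels[i]), character(1)),
                      collapse = ","),
                ");")
  tr <- ape::read.tree(text = nwk)
  tr$edge.length <- rep(branch_length, nrow(tr$edge))
  if (!is.null(long_internal)) {
    if (!is.numeric(long_internal) || long_internal <= 0)
      stop("'long_internal' must be positive")
    tr$edge.length[first_cherry_stem(tr)] <- long_internal
  }
  tr
}

## Index of the internal edge whose child node is the parent of the first
## cherry (the cherry containing tip 1). Errors when no such edge exists
## (e.g. a 3-taxon star).
first_cherry_stem <- function(tr) {
  ntip <- length(tr$tip.label)
  par <- tr$edge[, 1L]
  chi <- tr$edge[, 2L]
  p1 <- par[chi == 1L]
  sib <- chi[par == p1 & chi != 1L]
  if (!any(sib <= ntip))
    stop("tip 1 is not part of a cherry; cannot place the long internal branch")
  e <- which(chi == p1)
  if (length(e) == 0L)
    stop("tree has no internal branch adjacent to the first cherry")
  e[1L]
}

#' Total tree length
#'
#' Sum of all branch lengths, in expected substitutions per site.
#'
#' @param tree an [ape::phylo] tree.
#' @return the tree length; 0 when the tree carries no branch lengths.
#' @export
tree_length <- function(tree) {
  stopifnot(inherits(tree, "phylo"))
  if (is.null(tree$edge.length)) return(0)
  sum(tree$edge.length)
}

#' Parse a Newick string
#'
#' Thin wrapper around [ape::read.tree()] with stricter handling of branch
#' lengths: by default a branch without a length is an error, because a
#' silently defaulted length hides data problems; `missing_lengths = "zero"`
#' maps missing lengths to 0 instead.
#'
#' @param text a Newick string (must end with `;`).
#' @param missing_lengths `"error"` (default) or `"zero"`.
#' @return an [ape::phylo] tree.
#' @export
parse_newick <- function(text, missing_lengths = c("error", "zero")) {
  missing_lengths <- match.arg(missing_lengths)
  stopifnot(is.character(text), length(text) == 1L)
  check_newick_syntax(text)
  tr <- tryCatch(
    ape::read.tree(text = text),
    error = function(e) stop("Newick parse error: ", conditionMessage(e), call. = FALSE),
    warning = function(w) stop("Newick parse error: ", conditionMessage(w), call. = FALSE)
  )
  if (is.null(tr) || !inherits(tr, "phylo"))
    stop("Newick parse error: string could not be read as a tree")
  nb <- nrow(tr$edge)
  if (is.null(tr$edge.length)) tr$edge.length <- rep(NA_real_, nb)
  miss <- !is.finite(tr$edge.length)
  if (any(miss)) {
    if (missing_lengths == "error")
      stop("Newick parse error: ", sum(miss), " branch(es) without a length")
    tr$edge.length[miss] <- 0
  }
  if (any(tr$edge.length < 0))
    stop("Newick parse error: negative branch length")
  if (anyDuplicated(tr$tip.label))
    stop("Newick parse error: duplicate taxon labels")
  tr
}

## Pre-check bracket balance so parse errors can report a position.
check_newick_syntax <- function(text) {
  ch <- strsplit(text, "", fixed = TRUE)[[1L]]
  depth <- cumsum((ch == "(") - (ch == ")"))
  bad <- which(depth < 0L)
  if (length(bad))
    stop(sprintf("Newick parse error: unbalanced ')' at position %d", bad[1L]))
  semi <- which(ch == ";")
  if (length(semi) == 0L)
    stop("Newick parse error: missing terminal ';'")
  if (depth[semi[1L]] != 0L)
    stop(sprintf("Newick parse error: %d unclosed '(' at position %d",
                 depth[semi[1L]], semi[1L]))
  invisible(TRUE)
}

#' Serialize a tree to Newick
#'
#' Branch lengths are always written, with `digits` significant digits
#' (default 10), so that [parse_newick()] round-trips losslessly for
#' practical purposes.
#'
#' @param tree an [ape::phylo] tree with branch lengths.
#' @param digits significant digits for branch lengths.
#' @return a Newick string.
#' @export
write_newick <- function(tree, digits = 10) {
  stopifnot(inherits(tree, "phylo"))
  if (is.null(tree$edge.length))
    stop("tree has no branch lengths; refuse to write Newick without them")
  ape::write.tree(tree, digits = digits)
}
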