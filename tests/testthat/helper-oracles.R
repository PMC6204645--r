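# Independent oracles and small fixture builders used across the suite.

# Brute-force likelihood of one site pattern: enumerate the states of all
# internal nodes (and of missing tips) and sum products of transition
# probabilities. Deliberately independent of the pruning engine -- it only
# uses the closed-form K2P matrix.
brute_pattern_lik <- function(tree, states, taxa, rate, kappa) {
  tr <- reorder(tree, "postorder")
  ntip <- length(tr$tip.label)
  nnode <- ntip + tr$Nnode
  root <- tr$edge[nrow(tr$edge), 1]
  st <- states[match(tr$tip.label, taxa)]
  P <- lapply(seq_len(nrow(tr$edge)), function(e)
    k2p_transition_matrix(tr$edge.length[e] * rate, kappa))
  free <- c(setdiff((ntip + 1):nnode, integer(0)), which(st == 4L))
  fixed <- setdiff(seq_len(ntip), which(st == 4L))
  grid <- as.matrix(expand.grid(rep(list(1:4), length(free))))
  tot <- 0
  for (g in seq_len(nrow(grid))) {
    asn <- integer(nnode)
    asn[fixed] <- st[fixed] + 1L
    asn[free] <- grid[g, ]
    pr <- 0.25
    for (e in seq_len(nrow(tr$edge)))
      pr <- pr * P[[e]][asn[tr$edge[e, 1]], asn[tr$edge[e, 2]]]
    tot <- tot + pr
  }
  tot
}

# Brute-force mixture log-likelihood of a whole alignment.
brute_loglik <- function(tree, aln, mixture, kappa) {
  pat <- compress_patterns(aln)
  ll <- 0
  for (i in seq_along(pat$counts)) {
    site <- sum(vapply(seq_along(mixture$rates), function(j)
      mixture$weights[j] *
        brute_pattern_lik(tree, pat$states[i, ], pat$taxa,
                          mixture$rates[j], kappa),
      numeric(1)))
    ll <- ll + pat$counts[i] * log(site)
  }
  ll
}

# Random unrooted tree with branch lengths, via ape.
rand_tree <- function(n, min_bl = 0.02, max_bl = 0.8) {
  tr <- ape::unroot(ape::rtree(n))
  tr$edge.length <- runif(nrow(tr$edge), min_bl, max_bl)
  tr
}

# Random alignment matrix, optionally with missing data.
rand_aln <- function(taxa, n_sites, p_missing = 0) {
  ch <- sample(c("A", "C", "G", "T"), length(taxa) * n_sites, replace = TRUE)
  if (p_missing > 0) {
    miss <- runif(length(ch)) < p_missing
    ch[miss] <- "N"
  }
  matrix(ch, length(taxa), n_sites, dimnames = list(taxa, NULL))
}
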