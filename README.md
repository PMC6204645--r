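# igfit — accurate ML estimation of the invariable-sites + discrete-Gamma model

Phylogenetic analyses routinely model among-site rate heterogeneity with
the I+Γ model: a proportion *p*<sub>inv</sub> of sites is invariable
(rate 0), the rest draw rates from a discretized Gamma(α) distribution
with *k* equal-weight categories. Because a small α and a large
*p*<sub>inv</sub> explain similar signal, the log-likelihood surface in
(α, *p*<sub>inv</sub>) is frequently **bimodal**, and the generic
hill-climbing routines inside popular phylogenetic programs can converge
to the wrong peak — yielding badly biased shape, invariable-proportion
and even tree-length estimates although the data are long enough to
identify the truth.

`igfit` implements, for a fixed tree topology under the Kimura
two-parameter (K2P) substitution model, an estimation heuristic that is
robust to this surface. Per outer iteration:

1. Newton–Raphson optimization of all branch lengths (safeguarded,
   analytic derivatives);
2. quasi-Newton optimization of the ts/tv parameter κ;
3. E-step: posterior probability that each site is invariable,
   *P*(r₀|Dᵢ) = w₀·P(Dᵢ|r₀) / Σⱼ wⱼ·P(Dᵢ|rⱼ);
4. M-step: *p*<sub>inv</sub> ← (1/n) Σᵢ P(r₀|Dᵢ);
5. Brent search for α;

iterated until the log-likelihood gain drops below ε, and the whole
procedure repeated from ten starting values of *p*<sub>inv</sub> evenly
spaced between 0 and the observed constant-site fraction (α always
started at 1.0), returning the best-scoring start.

The package also ships a Seq-Gen-style simulator (K2P + I + discrete Γ,
seed-reproducible), a pattern-compressed pruning likelihood engine
(Rcpp), an accuracy-study harness over a (tree size × α ×
*p*<sub>inv</sub>) grid, likelihood-surface scans, and a command-line
interface.

## Worked example

```r
library(igfit)

tr  <- make_balanced_tree(6, 0.1, long_internal = 0.2)   # tree length 1.0
aln <- simulate_alignment(tr, rate_mixture(0.5, 0.3), 10000, kappa = 4, seed = 42)
fit <- fit_ig(tr, aln)
fit
#> I+G maximum-likelihood fit (fixed topology)
#>   alpha  = 0.5172
#>   p_inv  = 0.2984
#>   kappa  = 3.7844 (ts/tv = 1.8922)
#>   tree length = 0.9823
#>   log-likelihood = -39071.2975 (best of 10 starts, start p_inv = 0.5055)
#>   sites = 10000 (1193 patterns); outer iterations: 6 9 7 7 10 13 19 5 8 19
```

The data were simulated with α = 0.5, *p*<sub>inv</sub> = 0.3, κ = 4 and
tree length 1.0; the fit recovers all four within sampling error, and its
log-likelihood (−39071.30) exceeds the value at the generating parameters
(−39075.44), as it must when the optimizer has found the dominant peak.
`loglik_at()` evaluates any (tree, α, *p*<sub>inv</sub>, κ) point for
such comparisons, and `surface_scan()` maps the (α, *p*<sub>inv</sub>)
surface with its local maxima.

Larger experiments run through `run_grid()` / `scaled_profile()`, or from
the shell:

```sh
Rscript inst/exec/igfit.R simulate --preset paper6 --alpha 0.5 --pinv 0 \
    --sites 100000 --seed 1 --out sim.fasta
Rscript inst/exec/igfit.R fit --aln sim.fasta --preset paper6 --out fit.json
```

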