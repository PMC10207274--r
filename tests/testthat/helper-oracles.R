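# Independent brute-force oracles. These deliberately avoid the package's
# log-sum-exp code paths: populations are computed by direct (unshifted)
# exponentiation, midpoints by dense-grid interpolation, and macroscopic pKa
# values by locating equal-population crossings of adjacent macrostates.

oracle_populations <- function(system, pH) {
  w <- 10^(system$d * pH - system$g)
  w / sum(w)
}

oracle_asp <- function(system, site, pH) {
  p <- oracle_populations(system, pH)
  sum(p[system$occ[, site] == 1L])
}

oracle_nbar <- function(system, pH) {
  p <- oracle_populations(system, pH)
  sum((nrow(system$sites) - system$d) * p)
}

# dense-grid scan + linear interpolation of the ASP = 0.5 midpoint
oracle_pk50 <- function(system, site, window = c(-5, 20), step = 0.001) {
  grid <- seq(window[[1]], window[[2]], by = step)
  f <- vapply(grid, function(p) oracle_asp(system, site, p), numeric(1)) - 0.5
  k <- which(f[-1] * f[-length(f)] < 0)
  grid[k] + step * f[k] / (f[k] - f[k + 1])
}

# macro pKa as the pH where macrostates j-1 and j protons removed are
# equally populated (uniroot on the log population ratio)
oracle_macro_pka <- function(system, j, interval = c(-30, 30)) {
  ratio <- function(pH) {
    p <- oracle_populations(system, pH)
    log10(sum(p[system$d == j - 1L])) - log10(sum(p[system$d == j]))
  }
  stats::uniroot(ratio, interval, tol = 1e-12)$root
}

# edge list in a shuffled order (spanning the hypercube regardless of order)
shuffle_edges <- function(edges, seed) {
  withr::with_seed(seed, edges[sample.int(nrow(edges)), ])
}

expect_no_condition_value <- function(x) x # readability alias
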