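#' Build a microstate system from a pairwise interaction model
#'
#' A minimal (Ising-like) generative model for consistent microstate
#' systems: each site has an intrinsic micro-pKa (its pKa in the fully
#' protonated molecule) and pairs of sites interact through a symmetric
#' coupling matrix. For the set `D` of deprotonated sites,
#' `g(D) = sum of intrinsic_pka over D + sum of c[i, j] over pairs in D`,
#' so the micro-pKa of site `i` in a molecule whose deprotonated set is
#' `D` is `intrinsic_pka[i] + sum of c[i, j] over j in D` — the context
#' dependence of microconstants on the protonation state of the other
#' groups. `c >= 0` is anticooperative (repulsive): removing one proton
#' makes removing the next harder, the ordinary behavior of charged groups
#' in a polyprotic acid. The model is cycle-consistent by construction.
#'
#' @param intrinsic_pka numeric vector of per-site intrinsic micro-pKa
#'   values (log10 units).
#' @param coupling symmetric numeric matrix with zero diagonal (log10
#'   units); default no interaction.
#' @param sites,name passed to [microstate_system()].
#' @return A [microstate_system()].
#' @examples
#' from_pairwise(c(5, 5), matrix(c(0, 2, 2, 0), 2)) # edge pKas 5, 5, 7, 7
#' @export
from_pairwise <- function(intrinsic_pka, coupling = NULL, sites = NULL, name = "pairwise") {
  n <- length(intrinsic_pka)
  check_n_sites(n)
  if (any(!is.finite(intrinsic_pka))) abort_schema("intrinsic pKa values must be finite")
  if (is.null(coupling)) coupling <- matrix(0, n, n)
  coupling <- as.matrix(coupling)
  if (!all(dim(coupling) == n)) abort_schema("coupling must be an n x n matrix")
  if (any(abs(coupling - t(coupling)) > 0) || any(diag(coupling) != 0)) {
    abort_schema("coupling must be symmetric with zero diagonal")
  }
  occ <- enumerate_occ(n)
  z <- 1 - occ # deprotonated indicator
  g <- as.vector(z %*% intrinsic_pka) + rowSums((z %*% coupling) * z) / 2
  microstate_system(stats::setNames(g, occ_to_string(occ)), sites = sites, name = name)
}

#' Fully symmetric multiprotic system
#'
#' All sites equivalent: equal intrinsic pKa and equal pairwise coupling,
#' as in a molecule whose ionizable groups are chemically identical, where
#' assigning distinct pKa values to individual groups is meaningless. All
#' sites share one pK50 and one titration profile; with `c = 0` the
#' macroscopic pKa values carry the exact statistical factors
#' `pk + log10(j / (n - j + 1))`.
#'
#' @param n_sites number of equivalent sites.
#' @param pk common intrinsic micro-pKa.
#' @param c common pairwise coupling (default 0).
#' @param name system name.
#' @return A [microstate_system()].
#' @examples
#' symmetric_system(6, pk = 2, c = 0.7) # mellitic-acid-like hexaprotic acid
#' @export
symmetric_system <- function(n_sites, pk, c = 0, name = "symmetric") {
  n <- check_n_sites(n_sites)
  coupling <- matrix(c, n, n)
  diag(coupling) <- 0
  from_pairwise(rep(pk, n), coupling, name = name)
}

#' Random pairwise microstate system
#'
#' Reproducible random systems for property testing: intrinsic pKa values
#' drawn uniformly from `pka_range` and pairwise couplings uniformly from
#' `coupling_range` (the default `[0, 3]` keeps the system
#' anticooperative). The seed is a mandatory argument and is applied in a
#' local RNG scope, never via global state.
#'
#' @param n_sites number of sites.
#' @param seed integer seed (mandatory).
#' @param pka_range range for intrinsic pKa values, default `c(1, 12)`.
#' @param coupling_range range for pairwise couplings, default `c(0, 3)`.
#' @param name system name.
#' @return A [microstate_system()].
#' @export
random_system <- function(n_sites, seed, pka_range = c(1, 12),
                          coupling_range = c(0, 3), name = NULL) {
  n <- check_n_sites(n_sites)
  if (missing(seed)) abort_schema("seed is mandatory for random_system")
  if (any(!is.finite(c(pka_range, coupling_range)))) abort_schema("ranges must be finite")
  withr::with_seed(seed, {
    pka <- stats::runif(n, pka_range[[1L]], pka_range[[2L]])
    coupling <- matrix(0, n, n)
    if (n > 1L) {
      vals <- stats::runif(n * (n - 1) / 2, coupling_range[[1L]], coupling_range[[2L]])
      coupling[upper.tri(coupling)] <- vals
      coupling <- coupling + t(coupling)
    }
    from_pairwise(pka, coupling,
                  name = name %||% sprintf("random-%d-site (seed %d)", n, seed))
  })
}

#' Monoprotic acid
#'
#' The two-state system of a monoprotic acid HA with dissociation constant
#' `Ka = 10^-pk`: the reduction case in which ASP collapses to the
#' familiar fraction protonated `1 / (1 + 10^(pH - pKa))` and pASPA and
#' pK50 both equal the pKa.
#'
#' @param pk the pKa (log10 units).
#' @param label site label.
#' @param kind `"acid"` or `"base"` (display only).
#' @param name system name.
#' @return A [microstate_system()].
#' @examples
#' asp(monoprotic(4), 1, 5) # 1/11
#' @export
monoprotic <- function(pk, label = "s1", kind = "acid", name = "monoprotic") {
  if (!is.finite(pk)) abort_schema("pk must be finite")
  microstate_system(
    c("1" = 0, "0" = pk),
    sites = tibble::tibble(label = label, kind = kind),
    name = name
  )
}
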