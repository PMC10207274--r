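#' Per-microstate log10 statistical weights
#'
#' Relative to the fully protonated reference, a microstate that has lost
#' `d` protons and sits `g` log10 units up the deprotonation ladder has
#' statistical weight `10^(d * pH - g)`: every removed proton contributes a
#' factor `[H+]^-1 = 10^pH` and the free energy a factor `10^-g`. All
#' population quantities are ratios of these weights, so no molar
#' concentration scale is ever needed.
#'
#' @param system a [microstate_system()].
#' @param pH numeric vector of pH values.
#' @return A numeric matrix of log10 weights, one row per microstate
#'   (canonical order, rownames = bitstrings), one column per pH.
#' @export
log_weights <- function(system, pH) {
  if (any(!is.finite(pH))) abort_schema("pH must be finite")
  w <- outer(system$d, pH) - system$g
  rownames(w) <- occ_to_string(system$occ)
  w
}

# populations as a (states x pH) matrix via shifted base-10 softmax
pop_matrix <- function(system, pH) {
  w <- log_weights(system, pH)
  m <- apply(w, 2, max)
  u <- 10^sweep(w, 2, m)
  sweep(u, 2, colSums(u), "/")
}

#' pH-dependent microstate populations
#'
#' Normalized Boltzmann fractions of every microstate, computed with a
#' shifted base-10 softmax of [log_weights()] so the result is finite and
#' normalized even for extreme pH or energies.
#'
#' @inheritParams log_weights
#' @return A tibble with columns `pH`, `state`, `d`, `n_protons` and
#'   `fraction`; fractions sum to 1 within each pH.
#' @examples
#' populations(monoprotic(4), pH = c(4, 5))
#' @export
populations <- function(system, pH) {
  p <- pop_matrix(system, pH)
  n <- n_sites(system)
  d_rep <- rep(system$d, times = length(pH))
  pH_rep <- rep(pH, each = nrow(p))
  state_rep <- rep(rownames(p), times = length(pH))
  tibble::tibble(
    pH = pH_rep,
    state = state_rep,
    d = d_rep,
    n_protons = n - d_rep,
    fraction = as.vector(p)
  )
}

#' pH-dependent macrostate (proton-count) populations
#'
#' Microstate populations summed within each protonation macrostate, i.e.
#' over microstates sharing a bound-proton count.
#'
#' @inheritParams log_weights
#' @return A tibble with columns `pH`, `n_protons`, `d` and `fraction`.
#' @export
macrostate_populations <- function(system, pH) {
  populations(system, pH) |>
    dplyr::group_by(.data$pH, .data$n_protons, .data$d) |>
    dplyr::summarise(fraction = sum(.data$fraction), .groups = "drop") |>
    dplyr::arrange(.data$pH, .data$d)
}

#' Apparent (macroscopic) pKa values
#'
#' The observed macroconstants of an `n`-protic compound are functions of
#' the microconstants: with `S_j = log10 sum over d = j of 10^-g` the log10
#' binding-polynomial coefficient of the `j`-proton-removed macrostate
#' (`S_0 = 0`), the apparent pKa of the `j`-th dissociation is
#' `S_(j-1) - S_j`. Values are reported in dissociation order, never
#' sorted; a warning is emitted when they are non-monotonic, which can
#' happen under strong cooperativity.
#'
#' @param system a [microstate_system()].
#' @return A tibble with one row per dissociation step: `step` (1 = loss
#'   of the first proton from the fully protonated form) and `pka_macro`.
#'   The log10 macrostate sums are attached as attribute `"S"` (length
#'   `n + 1`, starting at `S_0 = 0`).
#' @examples
#' macro_pkas(from_pairwise(c(5, 5))) # statistical factors: 5 -/+ log10(2)
#' @export
macro_pkas <- function(system) {
  n <- n_sites(system)
  S <- vapply(0:n, function(j) lse10(-system$g[system$d == j]), numeric(1))
  pka <- S[-length(S)] - S[-1L]
  if (n > 1L && any(diff(pka) < 0)) {
    warning("macroscopic pKa values are non-monotonic in dissociation order",
            call. = FALSE)
  }
  out <- tibble::tibble(step = seq_len(n), pka_macro = pka)
  attr(out, "S") <- S
  out
}

#' Average number of bound protons (Bjerrum function)
#'
#' The statistical average of the number of bound ionizable protons at
#' each pH; identically equal to the sum of the per-site averaged site
#' protonations ([asp()]).
#'
#' @inheritParams log_weights
#' @return Numeric vector, one value per pH, in `[0, n]`.
#' @export
nbar <- function(system, pH) {
  p <- pop_matrix(system, pH)
  as.vector((n_sites(system) - system$d) %*% p)
}

#' Relative microstate contributions within each macrostate
#'
#' The relative contribution (probability) of a microstate to its parent
#' macrostate. Within a proton-count class every weight shares the factor
#' `10^(d * pH)`, so these fractions are pH-independent.
#'
#' @param system a [microstate_system()].
#' @return A tibble with columns `state`, `d`, `n_protons` and `fraction`;
#'   fractions sum to 1 within each `d`.
#' @export
microstate_dominance <- function(system) {
  tidy(system) |>
    dplyr::group_by(.data$d) |>
    dplyr::mutate(fraction = {
      s <- lse10(-.data$g)
      10^(-.data$g - s)
    }) |>
    dplyr::ungroup() |>
    dplyr::select("state", "d", "n_protons", "fraction")
}

#' Per-site dissociation branching probabilities of a microstate
#'
#' Given a microstate with at least one bound proton, the probability that
#' the next proton lost comes off each particular protonated site. With
#' micro-pKa `k_i` for the edge at site `i`, the branching probability is
#' `10^-k_i / sum_j 10^-k_j` — the equilibrium population ratio of the
#' product microstates, not a kinetic rate.
#'
#' @param system a [microstate_system()].
#' @param state a microstate, as occupancy bitstring or 0/1 vector.
#' @return A tibble with one row per protonated site: `site`, `label`,
#'   `to_state`, `pka_micro` and `probability` (sums to 1).
#' @examples
#' branching_probabilities(from_pairwise(c(3, 4)), "11")
#' @export
branching_probabilities <- function(system, state) {
  if (!is.character(state)) state <- occ_to_string(as.integer(state))
  occ <- system$occ[match(state, occ_to_string(system$occ)), ]
  if (anyNA(occ)) abort_schema(sprintf("unknown microstate '%s'", state))
  prot <- which(occ == 1L)
  if (length(prot) == 0L) {
    abort_schema("fully deprotonated microstate has no proton to dissociate")
  }
  to <- vapply(prot, function(i) {
    o <- occ
    o[i] <- 0L
    occ_to_string(o)
  }, character(1))
  k <- unname(system$g[to] - system$g[[state]])
  logp <- -k - lse10(-k)
  tibble::tibble(
    site = prot,
    label = system$sites$label[prot],
    to_state = to,
    pka_micro = k,
    probability = 10^logp
  )
}
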