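# log10 of (sum of weights with site protonated, sum with site deprotonated)
# returned as a 2 x length(pH) matrix; all arithmetic stays in log10 domain
site_log_sums <- function(system, site, pH) {
  w <- log_weights(system, pH)
  prot <- system$occ[, site] == 1L
  rbind(
    lse10_cols(w[prot, , drop = FALSE]),
    lse10_cols(w[!prot, , drop = FALSE])
  )
}

#' Averaged site protonation (ASP)
#'
#' The probability that one specific ionizable group carries its proton at
#' a given pH — the group's site titration curve, i.e. the summed
#' population of all microstates in which the site is protonated. Lies in
#' `[0, 1]` since every site here holds at most one dissociable proton.
#'
#' @param system a [microstate_system()].
#' @param site a site, by label or 1-based position.
#' @param pH numeric vector of pH values.
#' @return Numeric vector of fractions protonated, one per pH.
#' @examples
#' asp(monoprotic(4), 1, pH = c(4, 5)) # 0.5, 1/11
#' @export
asp <- function(system, site, pH) {
  i <- resolve_site(system, site)
  L <- site_log_sums(system, i, pH)
  1 / (1 + 10^(L[2L, ] - L[1L, ]))
}

#' Averaged single-proton acidity (ASPA) and its negative log10 (pASPA)
#'
#' The equilibrium-constant-like ratio obtained from the formal
#' dissociation reaction in which the population of all microstates with
#' group G protonated loses one proton to yield the population with G
#' deprotonated:
#' `ASPA = [H+] * (sum of G-deprotonated microstates) / (sum of
#' G-protonated microstates)`. Because numerator and denominator mix
#' different charge states, ASPA is a function of pH, not a constant; it
#' reduces to the ordinary Ka for a monoprotic acid. ASP and ASPA of the
#' same group obey `ASP = [H+] / ([H+] + ASPA)` identically.
#'
#' `paspa()` evaluates `pH + log10(sum protonated) - log10(sum
#' deprotonated)` entirely in the log10 domain, so it stays finite even
#' where ASP saturates at 0 or 1 in floating point; `aspa()` is simply
#' `10^-pASPA` and may underflow to 0 (or overflow) for extreme arguments.
#'
#' @inheritParams asp
#' @return Numeric vector, one value per pH: the acidity on the
#'   equilibrium-constant scale (`aspa`) or in log10 units (`paspa`).
#' @examples
#' paspa(monoprotic(4), 1, pH = c(0, 7, 14)) # constant 4
#' @export
paspa <- function(system, site, pH) {
  i <- resolve_site(system, site)
  L <- site_log_sums(system, i, pH)
  out <- pH + L[1L, ] - L[2L, ]
  if (any(!is.finite(out))) {
    warning("pASPA is infinite where one side of the site equilibrium has underflowed",
            call. = FALSE)
  }
  out
}

#' @rdname paspa
#' @export
aspa <- function(system, site, pH) 10^(-paspa(system, site, pH))

#' Site titration profiles over a pH grid
#'
#' Vectorized [asp()] and [paspa()] for a set of sites over an ascending
#' pH grid, in long (tidy) form ready for plotting.
#'
#' @param system a [microstate_system()].
#' @param pH ascending numeric grid (default 0 to 14 in steps of 0.1).
#' @param sites sites to profile (labels or 1-based positions); default all.
#' @return A tibble of class `titration_profile` with columns `pH`,
#'   `site`, `label`, `asp` and `paspa`, plus the molecular Bjerrum
#'   function as attribute `"nbar"`.
#' @seealso [autoplot.titration_profile()], [write_profiles()]
#' @export
site_profile <- function(system, pH = seq(0, 14, by = 0.1), sites = NULL) {
  if (length(pH) == 0L) abort_size("pH grid must be non-empty")
  if (is.unsorted(pH, strictly = TRUE)) abort_schema("pH grid must be strictly ascending")
  idx <- resolve_sites(system, sites)
  out <- dplyr::bind_rows(lapply(idx, function(i) {
    L <- site_log_sums(system, i, pH)
    tibble::tibble(
      pH = pH,
      site = i,
      label = system$sites$label[[i]],
      asp = 1 / (1 + 10^(L[2L, ] - L[1L, ])),
      paspa = pH + L[1L, ] - L[2L, ]
    )
  }))
  attr(out, "nbar") <- nbar(system, pH)
  class(out) <- c("titration_profile", class(out))
  out
}

#' Analytic low- and high-pH acidity asymptotes of a site
#'
#' At low pH almost all molecules are fully protonated, so a group's
#' averaged acidity converges to its microconstant in the fully protonated
#' macrostate: `paspa_low = g(all-ones with the site deprotonated)`. At
#' high pH the protonated-site population is dominated by the microstate
#' in which only that site still holds its proton, so the acidity
#' converges to the one-proton microconstant:
#' `paspa_high = g(all-zeros) - g(only the site protonated)`.
#'
#' @param system a [microstate_system()].
#' @param sites sites (labels or 1-based positions); default all.
#' @return A tibble with columns `site`, `label`, `paspa_low`, `paspa_high`.
#' @examples
#' asymptotes(from_pairwise(c(5, 5), matrix(c(0, 2, 2, 0), 2))) # 5 and 7
#' @export
asymptotes <- function(system, sites = NULL) {
  idx <- resolve_sites(system, sites)
  n <- n_sites(system)
  key <- occ_to_string(system$occ)
  ones <- rep(1L, n)
  zeros <- rep(0L, n)
  dplyr::bind_rows(lapply(idx, function(i) {
    lo_state <- ones; lo_state[i] <- 0L
    hi_state <- zeros; hi_state[i] <- 1L
    tibble::tibble(
      site = i,
      label = system$sites$label[[i]],
      paspa_low = unname(system$g[[occ_to_string(lo_state)]]),
      paspa_high = unname(system$g[[occ_to_string(zeros)]] - system$g[[occ_to_string(hi_state)]])
    )
  }))
}

# vectorized bisection on asp(site) - 0.5 over pre-bracketed intervals
refine_crossings <- function(system, site, lo, hi, tol = 1e-9) {
  f <- function(x) asp(system, site, x) - 0.5
  flo <- f(lo)
  for (iter in seq_len(80L)) {
    mid <- (lo + hi) / 2
    if (all(hi - lo <= tol)) break
    fmid <- f(mid)
    same <- sign(fmid) == sign(flo) | fmid == 0
    lo <- ifelse(same, mid, lo)
    flo <- ifelse(same, fmid, flo)
    hi <- ifelse(same, hi, mid)
  }
  (lo + hi) / 2
}

#' Single-proton midpoint (pK50) of each ionizable group
#'
#' The pH at which a group's averaged site protonation equals 50% — a
#' pH-independent, per-group acidity constant that reduces to the ordinary
#' pKa for monoprotic compounds, and that equals the pH at which the
#' group's pASPA profile crosses the identity line. Found by scanning
#' `ASP - 0.5` on a coarse grid, bracketing every sign change and refining
#' each bracket by bisection.
#'
#' The midpoint is well defined only when ASP crosses 0.5 exactly once in
#' the scan window; with several crossings all are reported, `pk50` is set
#' to `NA` and (in strict mode) an error is raised rather than picking one
#' silently.
#'
#' @param system a [microstate_system()].
#' @param sites sites to analyze (labels or 1-based positions); default all.
#' @param window pH scan window, default `c(-5, 20)`.
#' @param step coarse scan step, default 0.05.
#' @param report_pH pH values at which to report ASP snapshots (columns
#'   `asp_pH<value>`); default 7.4.
#' @param tol bisection convergence tolerance on pH.
#' @param strict error on ambiguous (multi-crossing) midpoints.
#' @return A tibble of class `site_report`, one row per site: `site`,
#'   `label`, `pk50`, `n_crossings`, `crossings` (list column),
#'   `paspa_low`, `paspa_high` and one ASP column per `report_pH`.
#' @examples
#' pk50(monoprotic(4))
#' @export
pk50 <- function(system, sites = NULL, window = c(-5, 20), step = 0.05,
                 report_pH = 7.4, tol = 1e-9, strict = FALSE) {
  idx <- resolve_sites(system, sites)
  grid <- seq(window[[1L]], window[[2L]], by = step)
  out <- dplyr::bind_rows(lapply(idx, function(i) {
    f <- asp(system, i, grid) - 0.5
    hit <- which(f == 0)
    flips <- which(f[-1L] * f[-length(f)] < 0)
    crossings <- sort(c(grid[hit], refine_crossings(system, i, grid[flips], grid[flips + 1L], tol)))
    if (length(crossings) == 0L) {
      abort_window(sprintf(
        "ASP of site '%s' does not cross 0.5 in pH window [%g, %g]; widen the window",
        system$sites$label[[i]], window[[1L]], window[[2L]]
      ))
    }
    if (length(crossings) > 1L && strict) {
      abort_consistency(sprintf(
        "site '%s' has %d ASP = 0.5 crossings; midpoint is ambiguous",
        system$sites$label[[i]], length(crossings)
      ))
    }
    row <- tibble::tibble(
      site = i,
      label = system$sites$label[[i]],
      pk50 = if (length(crossings) == 1L) crossings[[1L]] else NA_real_,
      n_crossings = length(crossings),
      crossings = list(crossings)
    )
    row <- dplyr::bind_cols(row, asymptotes(system, i)[, c("paspa_low", "paspa_high")])
    for (p in report_pH) row[[paste0("asp_pH", format(p))]] <- asp(system, i, p)
    row
  }))
  class(out) <- c("site_report", class(out))
  out
}

#' Molecular Bjerrum (average bound proton) profile
#'
#' The fraction-of-bound-protons profile over a pH grid. The molecular
#' profile is exactly the sum of the individual per-site titration curves,
#' and this identity (against [asp()]) is asserted on every call.
#'
#' @param system a [microstate_system()].
#' @param pH ascending numeric grid.
#' @return A tibble with columns `pH` and `nbar`.
#' @export
bjerrum <- function(system, pH = seq(0, 14, by = 0.1)) {
  if (is.unsorted(pH, strictly = TRUE)) abort_schema("pH grid must be strictly ascending")
  nb <- nbar(system, pH)
  asp_mat <- vapply(seq_len(n_sites(system)),
                    function(i) asp(system, i, pH), numeric(length(pH)))
  asp_sum <- rowSums(matrix(asp_mat, nrow = length(pH)))
  stopifnot(max(abs(nb - asp_sum)) <= 1e-10)
  tibble::tibble(pH = pH, nbar = nb)
}
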