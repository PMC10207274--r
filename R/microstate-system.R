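#' Construct a microstate system
#'
#' A microstate system is the complete description of the protonation
#' hypercube of an `n`-site molecule: all `2^n` protonation microstates,
#' each a binary occupancy vector (1 = site protonated), together with a
#' relative free energy `g` in log10 units. `g` is defined as the sum of
#' micro-pKa values along any deprotonation path from the fully protonated
#' reference microstate, so `g = 0` for the all-ones state and every
#' one-proton edge has micro-pKa `g(to) - g(from)`. Microstate populations
#' depend only on differences of `g` (gauge invariance), so energies
#' supplied in a different gauge are shifted to the all-ones reference with
#' a warning.
#'
#' @param energies named numeric vector of relative free energies, one per
#'   microstate, named by occupancy bitstring (site 1 leftmost, `"1"` =
#'   protonated). Must contain all `2^n` bitstrings for some `n`.
#' @param sites optional site metadata: a data frame with columns `label`
#'   and optionally `kind` (`"acid"` or `"base"`, display only) and
#'   `charge_protonated` (integer formal charge of the protonated form;
#'   defaults to 0 for acids, +1 for bases). Defaults to labels
#'   `s1 ... sn`.
#' @param name free-text system name.
#'
#' @return An object of class `microstate_system`: a list with elements
#'   `name`, `sites` (tibble), `occ` (integer occupancy matrix, one row per
#'   microstate in canonical order), `d` (protons removed per microstate)
#'   and `g` (relative free energies, all-ones state at 0).
#'
#' Microstates are kept in canonical order: by `d` (protons removed)
#' ascending, then by bitstring, so the fully protonated state is first and
#' the fully deprotonated state last.
#'
#' @seealso [monoprotic()], [from_pairwise()], [read_system()]
#' @examples
#' sys <- microstate_system(c("1" = 0, "0" = 4))
#' sys
#' @export
microstate_system <- function(energies, sites = NULL, name = "system") {
  if (is.null(names(energies)) || anyNA(names(energies))) {
    abort_schema("energies must be a named vector keyed by occupancy bitstring")
  }
  n <- unique(nchar(names(energies)))
  if (length(n) != 1L) abort_schema("all occupancy bitstrings must have the same length")
  check_n_sites(n)
  canon <- enumerate_occ(n)
  key <- occ_to_string(canon)
  missing <- setdiff(key, names(energies))
  if (length(missing) > 0L) {
    abort_schema(sprintf(
      "incomplete microstate set: %d of %d states missing (first: %s)",
      length(missing), 2^n, missing[[1L]]
    ))
  }
  if (length(energies) != 2^n) abort_schema("duplicate or extraneous microstate keys")
  g <- as.numeric(energies[key])
  if (any(!is.finite(g))) abort_schema("all free energies must be finite")
  if (g[[1L]] != 0) {
    warning(sprintf(
      "fully protonated reference has g = %g; shifting all energies to g(all-ones) = 0",
      g[[1L]]
    ), call. = FALSE)
    g <- g - g[[1L]]
  }
  sites <- canonical_sites(sites, n)
  structure(
    list(
      name = name,
      sites = sites,
      occ = canon,
      d = n - as.integer(rowSums(canon)),
      g = stats::setNames(g, key)
    ),
    class = "microstate_system"
  )
}

canonical_sites <- function(sites, n) {
  if (is.null(sites)) {
    sites <- tibble::tibble(label = paste0("s", seq_len(n)), kind = "acid")
  }
  sites <- tibble::as_tibble(sites)
  if (nrow(sites) != n) abort_schema(sprintf("expected %d sites, got %d", n, nrow(sites)))
  label <- sites[["label"]] %||% paste0("s", seq_len(n))
  if (anyDuplicated(label)) abort_schema("site labels must be unique")
  kind <- sites[["kind"]] %||% rep("acid", n)
  if (!all(kind %in% c("acid", "base"))) abort_schema("site kind must be 'acid' or 'base'")
  charge <- sites[["charge_protonated"]] %||% ifelse(kind == "base", 1L, 0L)
  tibble::tibble(
    site = seq_len(n),
    label = as.character(label),
    kind = kind,
    charge_protonated = as.integer(charge)
  )
}

check_n_sites <- function(n, max_sites = 20L) {
  if (length(n) != 1L || is.na(n) || n < 1L || n != round(n)) {
    abort_size("n_sites must be a single positive integer")
  }
  if (n > max_sites) {
    abort_size(sprintf("n_sites = %d exceeds the explicit-enumeration cap of %d", n, max_sites))
  }
  invisible(as.integer(n))
}

n_sites <- function(system) nrow(system$sites)

#' @export
print.microstate_system <- function(x, ...) {
  n <- n_sites(x)
  cat(sprintf(
    "<microstate_system> %s: %d sites, %d microstates, %d one-proton edges\n",
    x$name, n, 2^n, n * 2^(n - 1)
  ))
  cat("sites: ", paste0(x$sites$label, collapse = ", "), "\n", sep = "")
  mp <- macro_pkas(x)
  cat("macro pKa:", paste0(sprintf("%.3f", mp$pka_macro), collapse = ", "), "\n")
  invisible(x)
}

# resolve a site given as label or 1-based position to its position
resolve_site <- function(system, site) {
  if (length(site) != 1L) abort_schema("site must be a single label or index")
  if (is.character(site)) {
    i <- match(site, system$sites$label)
    if (is.na(i)) abort_schema(sprintf("unknown site label '%s'", site))
    return(i)
  }
  i <- as.integer(site)
  if (is.na(i) || i < 1L || i > n_sites(system)) {
    abort_schema(sprintf("site index %s out of range 1..%d", site, n_sites(system)))
  }
  i
}

resolve_sites <- function(system, sites) {
  if (is.null(sites)) seq_len(n_sites(system)) else vapply(sites, resolve_site, 1L, system = system)
}

#' Tidy a microstate system into its microstate table
#'
#' @param x a `microstate_system`.
#' @param ... unused.
#' @return A tibble with one row per microstate: `state` (bitstring), `d`
#'   (protons removed), `n_protons`, `g` (relative free energy, log10
#'   units) and `charge` (formal charge from the site bookkeeping).
#' @export
tidy.microstate_system <- function(x, ...) {
  charge <- as.integer(x$occ %*% x$sites$charge_protonated +
    (1 - x$occ) %*% (x$sites$charge_protonated - 1L))
  tibble::tibble(
    state = occ_to_string(x$occ),
    d = x$d,
    n_protons = n_sites(x) - x$d,
    g = unname(x$g),
    charge = charge
  )
}

#' One-row summary of a microstate system
#'
#' @param x a `microstate_system`.
#' @param ... unused.
#' @return A tibble with the site/microstate/edge counts and the span of
#'   the relative free energies.
#' @export
glance.microstate_system <- function(x, ...) {
  n <- n_sites(x)
  tibble::tibble(
    name = x$name,
    n_sites = n,
    n_microstates = 2^n,
    n_edges = n * 2^(n - 1),
    g_max = max(x$g)
  )
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance
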