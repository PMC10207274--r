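# canonical occupancy matrix: rows ordered by d ascending, then bitstring
enumerate_occ <- function(n_sites) {
  n <- check_n_sites(n_sites)
  occ <- as.matrix(rev(expand.grid(rep(list(c(0L, 1L)), n))))
  dimnames(occ) <- NULL
  key <- occ_to_string(occ)
  occ[order(n - rowSums(occ), key), , drop = FALSE]
}

#' Enumerate the protonation microstates of an n-site molecule
#'
#' A molecule with `n` ionizable sites, each carrying at most one
#' dissociable proton, has `2^n` protonation microstates, one per binary
#' occupancy vector (1 = protonated).
#'
#' @param n_sites number of ionizable sites (1 to 20).
#' @return A tibble with one row per microstate in canonical order
#'   (`d` ascending, then bitstring): `state` (bitstring, site 1
#'   leftmost), `d` (protons removed relative to the fully protonated
#'   state) and `occupancy` (list column of 0/1 vectors).
#' @examples
#' enumerate_microstates(3) # 8 microstates
#' @export
enumerate_microstates <- function(n_sites) {
  occ <- enumerate_occ(n_sites)
  tibble::tibble(
    state = occ_to_string(occ),
    d = ncol(occ) - as.integer(rowSums(occ)),
    occupancy = lapply(seq_len(nrow(occ)), function(i) occ[i, ])
  )
}

#' Enumerate the one-proton edges of the protonation hypercube
#'
#' Microstates differing by a single proton are joined by a reversible
#' one-proton equilibrium, each characterized by an ionization
#' microconstant. The hypercube of an `n`-site molecule has
#' `n * 2^(n-1)` such edges.
#'
#' @inheritParams enumerate_microstates
#' @return A tibble with columns `from_state` (protonated side),
#'   `to_state` (deprotonated side, one bit flipped 1 to 0) and `site`
#'   (1-based position of the dissociating site), ordered by `from_state`
#'   in canonical order then by site.
#' @examples
#' hypercube_edges(3) # 12 edges
#' @export
hypercube_edges <- function(n_sites) {
  occ <- enumerate_occ(n_sites)
  n <- ncol(occ)
  key <- occ_to_string(occ)
  from <- integer(0)
  site <- integer(0)
  for (i in seq_len(n)) {
    rows <- which(occ[, i] == 1L)
    from <- c(from, rows)
    site <- c(site, rep(i, length(rows)))
  }
  to_occ <- occ[from, , drop = FALSE]
  to_occ[cbind(seq_along(from), site)] <- 0L
  out <- tibble::tibble(
    from_state = key[from],
    to_state = occ_to_string(to_occ),
    site = site
  )
  dplyr::arrange(out, match(.data$from_state, key), .data$site)
}

#' Recover microstate free energies from a micro-pKa edge list
#'
#' Assigns each microstate a relative free energy `g` (log10 units) by
#' breadth-first accumulation of micro-pKa values from the fully
#' protonated reference, then checks every supplied edge against the
#' thermodynamic-cycle closure requirement
#' `pka == g(to) - g(from)` within `tolerance`.
#'
#' @param edges a data frame with columns `from_state`, `to_state`
#'   (occupancy bitstrings differing by one bit flipped 1 to 0), `pka`
#'   (micro-pKa, log10 units) and optionally `site`.
#' @param tolerance maximum absolute cycle residual (log10 units) for the
#'   edge set to count as consistent.
#' @param sites,name passed to [microstate_system()].
#' @param strict if `TRUE`, an inconsistent or incomplete edge set is an
#'   error; otherwise the report carries the diagnosis.
#' @return A list with elements `system` (the [microstate_system()], or
#'   `NULL` when the edge graph does not span all microstates) and
#'   `report` (a consistency report).
#' @examples
#' edges <- tibble::tibble(
#'   from_state = c("11", "11", "10", "01"),
#'   to_state = c("01", "10", "00", "00"),
#'   pka = c(3, 4, 4, 5)
#' )
#' edges_to_energies(edges)$system
#' @export
edges_to_energies <- function(edges, tolerance = 1e-6, sites = NULL, name = "system",
                              strict = FALSE) {
  edges <- tibble::as_tibble(edges)
  for (col in c("from_state", "to_state", "pka")) {
    if (is.null(edges[[col]])) abort_schema(sprintf("edge list lacks column '%s'", col))
  }
  n <- unique(nchar(c(edges$from_state, edges$to_state)))
  if (length(n) != 1L) abort_schema("edge bitstrings must share one site count")
  check_n_sites(n)
  occ_from <- strings_to_occ_matrix(edges$from_state, n)
  occ_to <- strings_to_occ_matrix(edges$to_state, n)
  flip <- occ_from - occ_to
  if (any(rowSums(abs(flip)) != 1L) || any(flip < 0L)) {
    abort_schema("every edge must flip exactly one bit from 1 (protonated) to 0")
  }

  canon <- enumerate_occ(n)
  key <- occ_to_string(canon)
  idx <- stats::setNames(seq_along(key), key)
  from_i <- idx[edges$from_state]
  to_i <- idx[edges$to_state]

  # undirected BFS from the all-ones reference (canonical row 1)
  g <- rep(NA_real_, length(key))
  g[[1L]] <- 0
  queue <- 1L
  nbr_head <- split(seq_len(nrow(edges) * 2L),
                    factor(c(from_i, to_i), levels = seq_along(key)))
  other <- c(to_i, from_i)
  step <- c(edges$pka, -edges$pka)
  while (length(queue) > 0L) {
    v <- queue[[1L]]
    queue <- queue[-1L]
    for (e in nbr_head[[v]]) {
      w <- other[[e]]
      if (is.na(g[[w]])) {
        g[[w]] <- g[[v]] + step[[e]]
        queue <- c(queue, w)
      }
    }
  }

  n_expected <- n * 2^(n - 1L)
  edge_key <- paste(edges$from_state, edges$to_state)
  all_edges <- hypercube_edges(n)
  missing_edges <- all_edges[!paste(all_edges$from_state, all_edges$to_state) %in% edge_key, ]

  if (anyNA(g)) {
    report <- consistency_report(
      status = "incomplete", max_cycle_residual = NA_real_,
      n_edges_given = nrow(edges), n_edges_expected = n_expected,
      missing_edges = missing_edges,
      message = sprintf("edge graph does not span all %d microstates", 2^n)
    )
    if (strict) abort_consistency(report$message)
    return(list(system = NULL, report = report))
  }

  residual <- abs(edges$pka - (g[to_i] - g[from_i]))
  max_res <- if (nrow(edges) > 0L) max(residual) else 0
  status <- if (max_res <= tolerance) "consistent" else "inconsistent"
  report <- consistency_report(
    status = status, max_cycle_residual = max_res,
    n_edges_given = nrow(edges), n_edges_expected = n_expected,
    missing_edges = missing_edges,
    message = if (status == "inconsistent") {
      sprintf("max cycle residual %.6g exceeds tolerance %.3g", max_res, tolerance)
    } else {
      "ok"
    }
  )
  if (strict && status != "consistent") abort_consistency(report$message)
  system <- microstate_system(stats::setNames(g, key), sites = sites, name = name)
  list(system = system, report = report)
}

#' Recover every ionization microconstant from a microstate system
#'
#' Each one-proton edge of the hypercube carries the micro-pKa
#' `g(to) - g(from)`; this round-trips with [edges_to_energies()] to
#' machine precision.
#'
#' @param system a [microstate_system()].
#' @return The [hypercube_edges()] tibble with columns `site_label` and
#'   `pka` added.
#' @examples
#' energies_to_edges(monoprotic(4))
#' @export
energies_to_edges <- function(system) {
  edges <- hypercube_edges(n_sites(system))
  edges$site_label <- system$sites$label[edges$site]
  edges$pka <- unname(system$g[edges$to_state] - system$g[edges$from_state])
  edges
}

consistency_report <- function(status, max_cycle_residual, n_edges_given,
                               n_edges_expected, missing_edges, message = "ok") {
  structure(
    list(
      status = status,
      max_cycle_residual = max_cycle_residual,
      n_edges_given = n_edges_given,
      n_edges_expected = n_edges_expected,
      missing_edges = missing_edges,
      message = message
    ),
    class = "consistency_report"
  )
}

#' @export
print.consistency_report <- function(x, ...) {
  cat(sprintf(
    "<consistency_report> status: %s (%d/%d edges, max cycle residual %s)\n",
    x$status, x$n_edges_given, x$n_edges_expected,
    ifelse(is.na(x$max_cycle_residual), "NA", sprintf("%.3g", x$max_cycle_residual))
  ))
  if (x$message != "ok") cat(" ", x$message, "\n")
  invisible(x)
}

#' Validate the structure of a microstate system
#'
#' Checks completeness (`2^n` distinct microstates), reference
#' normalization (`g = 0` for the fully protonated state) and finiteness.
#' Construction through [microstate_system()] enforces these, so the check
#' is idempotent on any system built by this package; it exists to vet
#' objects assembled by hand or read from disk.
#'
#' @param system a [microstate_system()].
#' @param tolerance maximum tolerated deviation of the reference energy
#'   from zero (log10 units).
#' @param strict if `TRUE`, problems are errors instead of a report.
#' @return A consistency report.
#' @export
validate_system <- function(system, tolerance = 1e-6, strict = FALSE) {
  problems <- character(0)
  n <- n_sites(system)
  key <- occ_to_string(system$occ)
  if (nrow(system$occ) != 2^n || anyDuplicated(key)) {
    problems <- c(problems, sprintf("expected %d distinct microstates, got %d", 2^n, nrow(system$occ)))
  }
  if (any(!is.finite(system$g))) problems <- c(problems, "non-finite free energies")
  ref <- which(system$d == 0L)
  if (length(ref) == 1L && abs(system$g[[ref]]) > tolerance) {
    problems <- c(problems, sprintf("reference g(all-ones) = %g, expected 0", system$g[[ref]]))
  }
  status <- if (length(problems) == 0L) "consistent" else "inconsistent"
  if (nrow(system$occ) != 2^n) status <- "incomplete"
  report <- consistency_report(
    status = status, max_cycle_residual = 0,
    n_edges_given = n * 2^(n - 1L), n_edges_expected = n * 2^(n - 1L),
    missing_edges = hypercube_edges(n)[0, ],
    message = if (length(problems) == 0L) "ok" else paste(problems, collapse = "; ")
  )
  if (strict && status != "consistent") abort_consistency(report$message)
  report
}
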