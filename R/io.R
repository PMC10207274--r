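#' Read a microstate system from disk
#'
#' Two on-disk forms are supported. A JSON system file contains `"name"`,
#' optional `"sites"` (objects with `"label"`, `"kind"`,
#' `"charge_protonated"`) and exactly one of:
#' \describe{
#'   \item{`"energies"`}{object mapping occupancy bitstrings to relative
#'     free energies `g` (log10 units);}
#'   \item{`"edges"`}{array of objects with `"from_state"`, `"to_state"`,
#'     `"pka"` and optionally `"site_index"` (0-based);}
#'   \item{`"model"`}{object with `"intrinsic_pka"` (array) and optional
#'     `"coupling"` (square matrix) for the pairwise generator.}
#' }
#' A `.csv` path is read as an edge list with columns
#' `from_state,to_state,site_index,pka` (bitstring states, 0-based site
#' index).
#'
#' @param path path to a `.json` system file or `.csv` edge list.
#' @param tolerance cycle-closure tolerance for edge input (log10 units).
#' @param strict if `TRUE`, inconsistent or incomplete edge sets are
#'   errors; otherwise the consistency report is attached to the
#'   returned system as attribute `"report"`.
#' @return A [microstate_system()].
#' @examples
#' path <- system.file("extdata", "synthetic_triprotic_ampholyte.json",
#'                     package = "micropka")
#' read_system(path)
#' @export
read_system <- function(path, tolerance = 1e-6, strict = FALSE) {
  if (!file.exists(path)) abort_schema(sprintf("no such file: %s", path))
  if (grepl("\\.csv$", path, ignore.case = TRUE)) {
    edges <- read_edges_csv(path)
    out <- edges_to_energies(edges, tolerance = tolerance, strict = strict,
                             name = sub("\\.csv$", "", basename(path), ignore.case = TRUE))
    if (is.null(out$system)) abort_consistency(out$report$message)
    return(structure(out$system, report = out$report))
  }
  doc <- tryCatch(jsonlite::fromJSON(path, simplifyVector = TRUE),
                   error = function(e) abort_schema(paste("cannot parse JSON:", conditionMessage(e))))
  forms <- intersect(c("energies", "edges", "model"), names(doc))
  if (length(forms) != 1L) {
    abort_schema(sprintf(
      "system file must contain exactly one of 'energies', 'edges', 'model' (found %d)",
      length(forms)
    ))
  }
  name <- doc$name %||% sub("\\.json$", "", basename(path), ignore.case = TRUE)
  sites <- if (!is.null(doc$sites)) tibble::as_tibble(doc$sites)
  system <- switch(forms,
    energies = {
      g <- unlist(doc$energies)
      microstate_system(g, sites = sites, name = name)
    },
    edges = {
      edges <- tibble::as_tibble(doc$edges)
      out <- edges_to_energies(edges, tolerance = tolerance, sites = sites,
                               name = name, strict = strict)
      if (is.null(out$system)) abort_consistency(out$report$message)
      structure(out$system, report = out$report)
    },
    model = {
      if (is.null(doc$model$intrinsic_pka)) {
        abort_schema("model form requires 'intrinsic_pka'")
      }
      coupling <- doc$model$coupling
      if (!is.null(coupling)) coupling <- as.matrix(coupling)
      from_pairwise(as.numeric(doc$model$intrinsic_pka), coupling,
                    sites = sites, name = name)
    }
  )
  report <- validate_system(system, strict = strict)
  if (is.null(attr(system, "report"))) attr(system, "report") <- report
  system
}

read_edges_csv <- function(path) {
  edges <- readr::read_csv(path, show_col_types = FALSE,
                           col_types = readr::cols(
                             from_state = readr::col_character(),
                             to_state = readr::col_character(),
                             .default = readr::col_double()
                           ))
  for (col in c("from_state", "to_state", "pka")) {
    if (is.null(edges[[col]])) abort_schema(sprintf("edge CSV lacks column '%s'", col))
  }
  if (!is.null(edges$site_index)) edges$site <- as.integer(edges$site_index) + 1L
  edges
}

#' Write a microstate system to JSON (energies form)
#'
#' @param system a [microstate_system()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_system <- function(system, path) {
  doc <- list(
    name = system$name,
    sites = lapply(seq_len(n_sites(system)), function(i) {
      s <- system$sites[i, ]
      list(label = s$label, kind = s$kind, charge_protonated = s$charge_protonated)
    }),
    energies = as.list(system$g)
  )
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Write an edge list to CSV
#'
#' Columns `from_state,to_state,site_index,pka` with 0-based
#' `site_index`, the transposable external form of the hypercube.
#'
#' @param edges an edge tibble from [energies_to_edges()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_edges_csv <- function(edges, path) {
  out <- tibble::tibble(
    from_state = edges$from_state,
    to_state = edges$to_state,
    site_index = edges$site - 1L,
    pka = edges$pka
  )
  lines <- c(
    "from_state,to_state,site_index,pka",
    sprintf("%s,%s,%d,%s", out$from_state, out$to_state, out$site_index, fmt12(out$pka))
  )
  writeLines(lines, path)
  invisible(path)
}

# 12 significant digits, locale-independent
fmt12 <- function(x) sprintf("%.12g", x)

#' Write titration profiles to CSV or JSON
#'
#' Serializes a [site_profile()] in wide form: one row per pH with columns
#' `pH`, `asp_<label>...`, `paspa_<label>...`, `nbar`. Numbers carry 12
#' significant digits and the byte output is deterministic for fixed
#' input.
#'
#' @param profiles a `titration_profile` from [site_profile()].
#' @param path output path.
#' @param format `"csv"` or `"json"`.
#' @return `path`, invisibly.
#' @export
write_profiles <- function(profiles, path, format = c("csv", "json")) {
  format <- match.arg(format)
  wide <- profile_wide(profiles)
  if (format == "json") {
    jsonlite::write_json(wide, path, auto_unbox = TRUE, digits = NA)
    return(invisible(path))
  }
  body <- as.data.frame(lapply(wide, function(col) if (is.numeric(col)) fmt12(col) else col))
  lines <- c(
    paste(names(wide), collapse = ","),
    do.call(paste, c(body, sep = ","))
  )
  writeLines(lines, path)
  invisible(path)
}

profile_wide <- function(profiles) {
  nb <- attr(profiles, "nbar")
  wide <- tibble::as_tibble(profiles) |>
    dplyr::select("pH", "label", "asp", "paspa") |>
    tidyr::pivot_wider(names_from = "label", values_from = c("asp", "paspa"))
  if (!is.null(nb)) wide$nbar <- nb
  wide
}

#' Read titration profiles written by [write_profiles()]
#'
#' @param path CSV path.
#' @return A wide tibble (`pH`, `asp_*`, `paspa_*`, `nbar`).
#' @export
read_profiles <- function(path) {
  readr::read_csv(path, show_col_types = FALSE)
}
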