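# internal numeric helpers -------------------------------------------------

# log10(sum(10^x)) with shift; x may contain -Inf
lse10 <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log10(sum(10^(x - m)))
}

# column-wise lse10 for a matrix (states x pH)
lse10_cols <- function(x) {
  m <- apply(x, 2, max)
  m + log10(colSums(10^sweep(x, 2, m)))
}

occ_to_string <- function(occ) {
  if (is.matrix(occ)) apply(occ, 1, paste0, collapse = "") else paste0(occ, collapse = "")
}

string_to_occ <- function(s) {
  out <- lapply(strsplit(s, "", fixed = TRUE), function(ch) {
    v <- match(ch, c("0", "1")) - 1L
    if (anyNA(v)) abort_schema(sprintf("invalid occupancy bitstring %s", paste0(ch, collapse = "")))
    v
  })
  if (length(out) == 1L) out[[1]] else out
}

strings_to_occ_matrix <- function(s, n) {
  rows <- string_to_occ(s)
  if (!is.list(rows)) rows <- list(rows)
  matrix(unlist(rows), ncol = n, byrow = TRUE)
}

# condition helpers: distinct classes so the CLI can map them to exit codes
abort_schema <- function(msg) rlang::abort(msg, class = "micropka_schema_error")
abort_consistency <- function(msg) rlang::abort(msg, class = "micropka_consistency_error")
abort_window <- function(msg) rlang::abort(msg, class = "micropka_window_error")
abort_size <- function(msg) rlang::abort(msg, class = "micropka_size_error")
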