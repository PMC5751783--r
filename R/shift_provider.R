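#' Chemical-shift providers
#'
#' The 3D-SDAR method is agnostic to where its \eqn{^{13}}C and
#' \eqn{^{15}}N shifts come from; in practice they are predicted by an
#' external NMR predictor and supplied as a table. Two providers are
#' available:
#'
#' * `shift_provider_table(x)` — shifts from a CSV table with header
#'   `id,atom_index,element,shift_ppm` (atom_index 1-based, matching the
#'   MOL atom block), or an equivalent `data.frame`.
#' * `shift_provider_naive()` — a deterministic rule-based fallback
#'   assigning published-typical class-center shifts from the local atom
#'   environment. It exists so synthetic fixtures and tests need no
#'   external predictor; it makes no claim of spectroscopic accuracy.
#'
#' Sign convention: carbon shifts are positive-dominant, nitrogen shifts
#' negative. A provider emitting positive \eqn{^{15}}N shifts must be
#' converted upstream.
#'
#' @param x Path to a shift CSV or a `data.frame` with the same columns.
#' @return An object of class `sdar_shift_provider`.
#' @name shift_providers
NULL

#' @rdname shift_providers
#' @export
shift_provider_table <- function(x) {
  if (is.character(x)) {
    if (!file.exists(x)) {
      sdar_error(sprintf("shift table not found: %s", x), "sdar_io_error")
    }
    x <- read.table(x, sep = ",", header = TRUE, stringsAsFactors = FALSE,
                    strip.white = TRUE)
  }
  req <- c("id", "atom_index", "element", "shift_ppm")
  if (!all(req %in% names(x))) {
    sdar_error(sprintf("shift table must have columns %s",
                       paste(req, collapse = ",")), "sdar_validation_error")
  }
  x$id <- as.character(x$id)
  structure(list(kind = "table", table = x), class = "sdar_shift_provider")
}

#' @rdname shift_providers
#' @export
shift_provider_naive <- function() {
  structure(list(kind = "naive_rules", version = 1L),
            class = "sdar_shift_provider")
}

#' Rule-based fallback shift for a single atom environment
#'
#' Deterministic class-center lookup by element, aromaticity and the number
#' of heteroatom (non-C, non-H) neighbors. Values are typical-range class
#' centers inside the default carbon (-4..204 PPM) and nitrogen
#' (-356..-11 PPM) windows.
#'
#' @param element "C" or "N".
#' @param aromatic Logical: is the atom part of an aromatic ring?
#' @param n_hetero_neighbors Nonnegative count of bonded heteroatoms.
#' @return Shift in PPM.
#' @export
naive_rule_shift <- function(element, aromatic, n_hetero_neighbors = 0) {
  if (!element %in% c("C", "N")) {
    sdar_error(sprintf("naive_rule_shift: element '%s' outside {C,N}", element),
               "sdar_domain_error")
  }
  h <- min(n_hetero_neighbors, 2L)
  if (element == "C") {
    if (aromatic) c(128, 145, 152)[h + 1L] else c(30, 58, 95)[h + 1L]
  } else {
    if (aromatic) -70 else c(-330, -290, -250)[h + 1L]
  }
}

#' Assign chemical shifts to the C and N atoms of a molecule
#'
#' Returns one shift per carbon and nitrogen atom; atoms of other elements
#' get `NA`. For table providers every C/N atom must be present in the
#' table; a missing atom raises an incomplete-assignment error listing the
#' missing indices. Shifts outside the sanity windows (C: -50..250 PPM,
#' N: -500..100 PPM) trigger a warning but pass through.
#'
#' @param mol An `sdar_mol`.
#' @param provider An `sdar_shift_provider`.
#' @return Numeric vector of length `nrow(mol$atoms)` (PPM; `NA` for
#'   non-C/N atoms), with the molecule id as attribute `id`.
#' @export
assign_shifts <- function(mol, provider) {
  stopifnot(inherits(provider, "sdar_shift_provider"))
  el <- mol$atoms$element
  idx_cn <- which(el %in% c("C", "N"))
  shifts <- rep(NA_real_, length(el))
  if (length(idx_cn) == 0) {
    return(structure(shifts, id = mol$id))
  }
  if (provider$kind == "table") {
    tab <- provider$table[provider$table$id == mol$id, , drop = FALSE]
    hit <- match(idx_cn, tab$atom_index)
    if (anyNA(hit)) {
      sdar_error(sprintf("molecule '%s': shift table missing atoms %s",
                         mol$id,
                         paste(idx_cn[is.na(hit)], collapse = ", ")),
                 "sdar_incomplete_shift_error")
    }
    shifts[idx_cn] <- tab$shift_ppm[hit]
  } else {
    aro <- aromatic_atom_flags(mol)
    nh <- hetero_neighbor_counts(mol)
    shifts[idx_cn] <- vapply(idx_cn, function(i) {
      naive_rule_shift(el[i], aro[i], nh[i])
    }, numeric(1))
  }
  bad_c <- idx_cn[el[idx_cn] == "C" &
                  (shifts[idx_cn] < -50 | shifts[idx_cn] > 250)]
  bad_n <- idx_cn[el[idx_cn] == "N" &
                  (shifts[idx_cn] < -500 | shifts[idx_cn] > 100)]
  if (length(bad_c) || length(bad_n)) {
    warning(sprintf("molecule '%s': %d shift(s) outside the sanity window (passed through)",
                    mol$id, length(bad_c) + length(bad_n)))
  }
  structure(shifts, id = mol$id)
}

aromatic_atom_flags <- function(mol) {
  flags <- rep(FALSE, nrow(mol$atoms))
  for (r in perceive_aromatic_rings(mol)) flags[r$atoms] <- TRUE
  flags
}

hetero_neighbor_counts <- function(mol) {
  el <- mol$atoms$element
  counts <- integer(length(el))
  b <- mol$bonds
  for (k in seq_len(nrow(b))) {
    if (!el[b$b[k]] %in% c("C", "H")) counts[b$a[k]] <- counts[b$a[k]] + 1L
    if (!el[b$a[k]] %in% c("C", "H")) counts[b$b[k]] <- counts[b$b[k]] + 1L
  }
  counts
}

#' Read shift assignments embedded as SDF properties
#'
#' Molecules read from an annotated SDF may carry their shifts in a
#' `SDAR_SHIFTS` data field of semicolon-separated `index:shift` pairs.
#'
#' @param mol An `sdar_mol` read by [read_structures()].
#' @return A shift vector as from [assign_shifts()], or `NULL` when the
#'   record carries no `SDAR_SHIFTS` field.
#' @export
shifts_from_properties <- function(mol) {
  props <- attr(mol, "properties")
  if (is.null(props) || !"SDAR_SHIFTS" %in% names(props)) return(NULL)
  pairs <- strsplit(strsplit(props[["SDAR_SHIFTS"]], ";", fixed = TRUE)[[1]],
                    ":", fixed = TRUE)
  shifts <- rep(NA_real_, nrow(mol$atoms))
  for (p in pairs) {
    shifts[as.integer(p[1])] <- as.numeric(p[2])
  }
  structure(shifts, id = mol$id)
}

#' Serialize a shift vector to the SDF property encoding
#'
#' @param shifts Shift vector from [assign_shifts()].
#' @return Single string of `index:shift` pairs joined by semicolons.
#' @export
shifts_to_property <- function(shifts) {
  i <- which(!is.na(shifts))
  paste(sprintf("%d:%.6f", i, shifts[i]), collapse = ";")
}
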