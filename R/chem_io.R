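#' Construct a molecule record
#'
#' The basic structural container used throughout the package: an ordered
#' atom table with 3D coordinates plus a bond table. Atom order is
#' significant — atom indices (1-based, matching the MOL V2000 atom block)
#' are the join key for chemical-shift tables.
#'
#' @param id Character scalar, compound identifier.
#' @param atoms `data.frame` with columns `element` (symbol), `x`, `y`, `z`
#'   (Angstrom).
#' @param bonds `data.frame` with columns `a`, `b` (atom indices), `order`
#'   (integer bond order) and `aromatic` (logical flag). May have zero rows.
#' @return An object of class `sdar_mol`.
#' @export
molecule_record <- function(id, atoms, bonds = NULL) {
  if (is.null(bonds)) {
    bonds <- data.frame(a = integer(), b = integer(), order = integer(),
                        aromatic = logical())
  }
  atoms <- as.data.frame(atoms)
  bonds <- as.data.frame(bonds)
  stopifnot(all(c("element", "x", "y", "z") %in% names(atoms)),
            all(c("a", "b", "order") %in% names(bonds)))
  if (is.null(bonds$aromatic)) bonds$aromatic <- bonds$order == 4L
  n <- nrow(atoms)
  coords <- as.matrix(atoms[, c("x", "y", "z")])
  if (!all(is.finite(coords))) {
    sdar_error(sprintf("molecule '%s': non-finite coordinates", id),
               "sdar_degenerate_error")
  }
  if (nrow(bonds) > 0 &&
      (any(bonds$a < 1) || any(bonds$b < 1) ||
       any(bonds$a > n) || any(bonds$b > n))) {
    sdar_error(sprintf("molecule '%s': bond atom index out of range", id),
               "sdar_validation_error")
  }
  structure(list(id = as.character(id), atoms = atoms, bonds = bonds),
            class = "sdar_mol")
}

#' @export
print.sdar_mol <- function(x, ...) {
  cat(sprintf("<sdar_mol> %s: %d atoms (%s), %d bonds\n", x$id,
              nrow(x$atoms),
              paste(names(sort(-table(x$atoms$element))), collapse = ","),
              nrow(x$bonds)))
  invisible(x)
}

mol_coords <- function(mol) as.matrix(mol$atoms[, c("x", "y", "z")])

#' Read molecular structures from a MOL or SDF file
#'
#' Reads a single MOL V2000 file or a multi-record SDF. Atom order is
#' preserved exactly as in the file. Records flagged "2D" in the program
#' line whose z coordinates are all zero are rejected, since fingerprinting
#' requires 3D geometry.
#'
#' @param path Path to a `.mol` or `.sdf` file (V2000).
#' @return A list of [molecule_record()] objects, named by the record title
#'   (falling back to `mol_<i>` for blank titles).
#' @export
read_structures <- function(path) {
  if (!file.exists(path)) {
    sdar_error(sprintf("structure file not found: %s", path), "sdar_io_error")
  }
  if (!any(nzchar(trimws(readLines(path, warn = FALSE))))) {
    return(list())  # zero-record SDF
  }
  # (suppressed warning: ChemmineR flags legitimate zero-bond records)
  set <- tryCatch(suppressWarnings(ChemmineR::read.SDFset(path)),
                  error = function(e) {
                    sdar_error(sprintf("cannot parse '%s' as MOL/SDF: %s",
                                       path, conditionMessage(e)),
                               "sdar_io_error")
                  })
  n_rec <- length(set)
  if (n_rec == 0) return(list())
  out <- vector("list", n_rec)
  ids <- character(n_rec)
  for (i in seq_len(n_rec)) {
    sdf <- set[[i]]
    hd <- ChemmineR::header(sdf)
    id <- trimws(hd[["Molecule_Name"]])
    if (!nzchar(id)) id <- sprintf("mol_%d", i)
    ab <- ChemmineR::atomblock(sdf)
    bb <- ChemmineR::bondblock(sdf)
    elements <- sub("_\\d+$", "", rownames(ab))
    atoms <- data.frame(element = elements,
                        x = ab[, 1], y = ab[, 2], z = ab[, 3],
                        row.names = NULL)
    # zero-bond records can leave a malformed stub bond block behind
    if (is.matrix(bb) && nrow(bb) > 0 && ncol(bb) >= 3) {
      bonds <- data.frame(a = as.integer(bb[, 1]), b = as.integer(bb[, 2]),
                          order = as.integer(bb[, 3]))
      bonds <- bonds[bonds$a >= 1 & bonds$b >= 1, , drop = FALSE]
    } else {
      bonds <- data.frame(a = integer(), b = integer(), order = integer())
    }
    bonds$aromatic <- bonds$order == 4L
    flagged_2d <- grepl("2D", hd[["Source"]], fixed = TRUE)
    if (flagged_2d && all(atoms$z == 0)) {
      sdar_error(sprintf("record '%s' is flagged 2D with all-zero z; 3D coordinates required", id),
                 "sdar_degenerate_error")
    }
    props <- ChemmineR::datablock(sdf)
    mol <- molecule_record(id, atoms, bonds)
    if (length(props)) attr(mol, "properties") <- props
    out[[i]] <- mol
    ids[i] <- id
  }
  names(out) <- ids
  out
}

#' Write molecule records to an SDF file
#'
#' Inverse of [read_structures()]; optional per-record properties are
#' emitted as SDF data fields (used by the toxicophore module to annotate
#' matched atoms).
#'
#' @param mols List of `sdar_mol` objects.
#' @param path Output path.
#' @param properties Optional list (parallel to `mols`) of named character
#'   vectors written as SDF data fields.
#' @return `path`, invisibly.
#' @export
write_structures <- function(mols, path, properties = NULL) {
  if (!is.null(properties)) stopifnot(length(properties) == length(mols))
  blocks <- lapply(seq_along(mols), function(i) {
    mol <- mols[[i]]
    n <- nrow(mol$atoms)
    nb <- nrow(mol$bonds)
    lines <- c(
      mol$id,
      "  sdar3d          3D",
      "",
      sprintf("%3d%3d  0  0  0  0  0  0  0  0999 V2000", n, nb),
      sprintf("%10.4f%10.4f%10.4f %-3s0  0  0  0  0  0  0  0  0  0  0  0",
              mol$atoms$x, mol$atoms$y, mol$atoms$z, mol$atoms$element))
    if (nb > 0) {
      order_out <- ifelse(mol$bonds$aromatic & mol$bonds$order != 4L,
                          4L, mol$bonds$order)
      lines <- c(lines, sprintf("%3d%3d%3d  0",
                                mol$bonds$a, mol$bonds$b, order_out))
    }
    lines <- c(lines, "M  END")
    props <- properties[[i]]
    for (nm in names(props)) {
      lines <- c(lines, sprintf("> <%s>", nm), props[[nm]], "")
    }
    c(lines, "$$$$")
  })
  writeLines(unlist(blocks), path)
  invisible(path)
}

#' Read a compound label manifest
#'
#' The manifest assigns each compound its TdP activity (1 = torsadogenic,
#' 0 = non-torsadogenic) and its dataset role (`model` compounds are used
#' for training/internal validation; `external` compounds form the blind
#' test set). An optional `report_count` column carries the number of
#' post-marketing adverse-event reports behind an external label.
#'
#' @param path Delimited text file (comma or tab, autodetected) with header
#'   `id,activity,role[,report_count]`.
#' @return A validated `data.frame` with class `sdar_manifest`.
#' @export
read_manifest <- function(path) {
  if (!file.exists(path)) {
    sdar_error(sprintf("manifest not found: %s", path), "sdar_io_error")
  }
  first <- readLines(path, n = 1L)
  sep <- if (grepl("\t", first)) "\t" else ","
  df <- read.table(path, sep = sep, header = TRUE,
                   stringsAsFactors = FALSE, strip.white = TRUE)
  req <- c("id", "activity", "role")
  if (!all(req %in% names(df))) {
    sdar_error(sprintf("manifest must have columns %s; found: %s",
                       paste(req, collapse = ","),
                       paste(names(df), collapse = ",")),
               "sdar_validation_error")
  }
  df$id <- as.character(df$id)
  if (anyDuplicated(df$id)) {
    sdar_error(sprintf("duplicate manifest ids: %s",
                       paste(unique(df$id[duplicated(df$id)]), collapse = ", ")),
               "sdar_validation_error")
  }
  if (!all(df$activity %in% c(0L, 1L))) {
    sdar_error("manifest activity values must be 0 or 1",
               "sdar_validation_error")
  }
  if (!all(df$role %in% c("model", "external"))) {
    sdar_error(sprintf("unknown role token(s): %s",
                       paste(setdiff(unique(df$role), c("model", "external")),
                             collapse = ", ")),
               "sdar_validation_error")
  }
  df$activity <- as.integer(df$activity)
  if (!is.null(df$report_count) &&
      any(!is.na(df$report_count) & df$report_count < 0)) {
    sdar_error("report_count must be nonnegative", "sdar_validation_error")
  }
  class(df) <- c("sdar_manifest", "data.frame")
  df
}

#' Interatomic distance matrix
#'
#' Symmetric matrix of Euclidean distances (Angstrom) between all atoms of
#' a molecule, computed from its 3D coordinates.
#'
#' @param mol An `sdar_mol`.
#' @return An n x n numeric matrix with zero diagonal.
#' @export
distance_matrix <- function(mol) {
  xyz <- mol_coords(mol)
  if (nrow(xyz) == 0 || !all(is.finite(xyz))) {
    sdar_error(sprintf("molecule '%s': missing or non-finite coordinates",
                       mol$id), "sdar_degenerate_error")
  }
  dm <- as.matrix(stats::dist(xyz))
  dimnames(dm) <- NULL
  diag(dm) <- 0
  dm
}

#' Perceive aromatic rings
#'
#' Finds rings whose bonds are all aromatic. A bond is aromatic when the
#' input file flagged it so (MOL bond type 4); for Kekulé-form inputs with
#' no aromatic flags, even-sized rings whose bond orders alternate strictly
#' between single and double are treated as aromatic. Each ring is reported
#' with its member atom indices and its centroid (the arithmetic mean of
#' the member coordinates), used by the toxicophore module to express
#' feature distances relative to ring centers.
#'
#' @param mol An `sdar_mol`.
#' @return A list of rings, each `list(atoms = <indices>, centroid = <xyz>)`;
#'   empty list for acyclic molecules.
#' @export
perceive_aromatic_rings <- function(mol) {
  bonds <- mol$bonds
  if (nrow(bonds) == 0) return(list())
  rings <- find_rings(bonds, nrow(mol$atoms))
  has_flags <- any(bonds$aromatic)
  keep <- Filter(function(r) ring_is_aromatic(r, bonds, has_flags), rings)
  xyz <- mol_coords(mol)
  lapply(keep, function(r) {
    list(atoms = r, centroid = colMeans(xyz[r, , drop = FALSE]))
  })
}

# smallest ring through each edge, via shortest path in the graph with that
# edge removed; deduplicated by sorted member set
find_rings <- function(bonds, n_atoms) {
  g <- igraph::graph_from_edgelist(cbind(bonds$a, bonds$b), directed = FALSE)
  if (igraph::vcount(g) < n_atoms) {
    g <- igraph::add_vertices(g, n_atoms - igraph::vcount(g))
  }
  rings <- list()
  seen <- character()
  for (e in seq_len(nrow(bonds))) {
    g2 <- igraph::delete_edges(g, e)
    sp <- suppressWarnings(
      igraph::shortest_paths(g2, from = bonds$a[e], to = bonds$b[e]))
    pth <- as.integer(sp$vpath[[1]])
    if (length(pth) >= 3) {
      key <- paste(sort(pth), collapse = "-")
      if (!key %in% seen) {
        seen <- c(seen, key)
        rings[[length(rings) + 1L]] <- pth  # cycle order preserved
      }
    }
  }
  rings
}

ring_bond_rows <- function(ring, bonds) {
  k <- length(ring)
  pairs <- cbind(ring, ring[c(2:k, 1)])
  vapply(seq_len(k), function(i) {
    hit <- which((bonds$a == pairs[i, 1] & bonds$b == pairs[i, 2]) |
                 (bonds$a == pairs[i, 2] & bonds$b == pairs[i, 1]))
    if (length(hit)) hit[1] else NA_integer_
  }, integer(1))
}

ring_is_aromatic <- function(ring, bonds, has_flags) {
  rows <- ring_bond_rows(ring, bonds)
  if (anyNA(rows)) return(FALSE)
  if (has_flags) return(all(bonds$aromatic[rows]))
  # Kekulé fallback: even ring, orders strictly alternating 1/2
  ord <- bonds$order[rows]
  if (length(ord) %% 2 != 0 || !all(ord %in% c(1L, 2L))) return(FALSE)
  all(ord != ord[c(2:length(ord), 1)])
}

#' Apply a rigid motion to a molecule
#'
#' Utility used mainly in invariance testing: rotates the coordinates by a
#' 3x3 orthonormal matrix and translates them. Fingerprints and distance
#' matrices are invariant under this operation.
#'
#' @param mol An `sdar_mol`.
#' @param rotation 3x3 rotation matrix (default identity).
#' @param translation Length-3 numeric offset (default zero).
#' @return The transformed `sdar_mol`.
#' @export
transform_molecule <- function(mol, rotation = diag(3), translation = c(0, 0, 0)) {
  xyz <- mol_coords(mol) %*% t(rotation)
  xyz <- sweep(xyz, 2, translation, "+")
  mol$atoms$x <- xyz[, 1]
  mol$atoms$y <- xyz[, 2]
  mol$atoms$z <- xyz[, 3]
  mol
}

# uniform random rotation matrix (QR of Gaussian, sign-fixed)
random_rotation <- function() {
  qr_ <- qr(matrix(rnorm(9), 3, 3))
  q <- qr.Q(qr_)
  if (det(q) < 0) q[, 1] <- -q[, 1]
  q
}
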