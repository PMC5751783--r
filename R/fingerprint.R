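#' Compute the 3D-SDAR fingerprint of one molecule
#'
#' Iterates over all unordered pairs of carbon/nitrogen atoms, combines the
#' two chemical shifts with the interatomic distance into a
#' (shift, shift, distance) triplet, and increments the corresponding bin.
#' Pairs with any coordinate outside its window are skipped and counted.
#' Hydrogens and all other elements never participate. The fingerprint
#' depends only on elements, shifts and interatomic distances, so it is
#' invariant under rigid motion of the coordinates and under permutation of
#' atom order.
#'
#' @param mol An `sdar_mol`.
#' @param shifts Shift vector from [assign_shifts()].
#' @param dm Optional precomputed [distance_matrix()]; computed on demand.
#' @param cfg A [binning_config()].
#' @return An object of class `sdar_fp`: list with `id`, `bins` (named
#'   integer vector, names are bin ids, sorted), `n_pairs` (eligible
#'   unordered C/N pairs) and `n_skipped` (pairs with an out-of-window
#'   coordinate).
#' @export
compute_fingerprint <- function(mol, shifts, dm = NULL, cfg = binning_config()) {
  el <- mol$atoms$element
  idx <- which(el %in% c("C", "N"))
  if (any(is.na(shifts[idx]))) {
    sdar_error(sprintf("molecule '%s': missing shifts for atoms %s",
                       mol$id, paste(idx[is.na(shifts[idx])], collapse = ", ")),
               "sdar_incomplete_shift_error")
  }
  empty <- structure(
    list(id = mol$id, bins = setNames(integer(0), character(0)),
         n_pairs = 0L, n_skipped = 0L),
    class = "sdar_fp")
  if (length(idx) < 2) return(empty)
  if (is.null(dm)) dm <- distance_matrix(mol)
  pr <- utils::combn(idx, 2)
  a <- pr[1, ]; b <- pr[2, ]
  ea <- el[a]; eb <- el[b]
  sa <- shifts[a]; sb <- shifts[b]
  # canonical axis order: CN puts carbon on axis 1; CC/NN the smaller shift
  swap <- (ea == "N" & eb == "C") | (ea == eb & sa > sb)
  s1 <- ifelse(swap, sb, sa); s2 <- ifelse(swap, sa, sb)
  e1 <- ifelse(swap, eb, ea); e2 <- ifelse(swap, ea, eb)
  class <- paste0(e1, e2)
  d <- dm[cbind(a, b)]
  i1 <- ifelse(e1 == "C",
               bin_axis_index(s1, cfg$c_window, cfg$w_c),
               bin_axis_index(s1, cfg$n_window, cfg$w_n))
  i2 <- ifelse(e2 == "C",
               bin_axis_index(s2, cfg$c_window, cfg$w_c),
               bin_axis_index(s2, cfg$n_window, cfg$w_n))
  k <- bin_axis_index(d, cfg$d_window, cfg$w_d)
  ok <- !(is.na(i1) | is.na(i2) | is.na(k))
  ids <- integer(sum(ok))
  if (any(ok)) {
    ids <- vapply(which(ok), function(j) {
      encode_bin(class[j], i1[j], i2[j], k[j], cfg)
    }, integer(1))
  }
  tab <- table(ids)
  bins <- if (length(tab) == 0) setNames(integer(0), character(0))
          else setNames(as.integer(tab), names(tab))
  bins <- bins[order(as.integer(names(bins)))]
  if (cfg$occupancy == "binary") bins <- setNames(pmin(bins, 1L), names(bins))
  structure(list(id = mol$id, bins = bins,
                 n_pairs = ncol(pr), n_skipped = as.integer(sum(!ok))),
            class = "sdar_fp")
}

#' @export
print.sdar_fp <- function(x, ...) {
  cat(sprintf("<sdar_fp> %s: %d occupied bins, %d pairs (%d skipped)\n",
              x$id, length(x$bins), x$n_pairs, x$n_skipped))
  invisible(x)
}

#' Assemble the compound-by-bin feature matrix
#'
#' Retains the bins that are nonzero in at least one modeling compound,
#' then scales each retained column (default: z-score) using statistics
#' from the modeling compounds only. External compounds are transformed
#' with those frozen statistics; their values may fall outside the
#' training range, and any bins absent from the retained set are dropped
#' (logged as `dropped_external_bins`). All-constant columns scale to zero.
#'
#' @param fps List of [compute_fingerprint()] results.
#' @param modeling_ids Ids of the compounds that define the retained-bin
#'   set and the scaling statistics.
#' @param cfg The [binning_config()] used to compute the fingerprints.
#' @return An object of class `sdar_features`: `ids`, `bin_ids` (retained,
#'   ascending), `counts` (raw occupancy matrix), `X` (scaled matrix),
#'   `center`/`scale` per column, `scaling`, `modeling_ids`, `cfg`.
#' @export
build_feature_matrix <- function(fps, modeling_ids, cfg = binning_config()) {
  stopifnot(length(fps) > 0)
  ids <- vapply(fps, function(f) f$id, character(1))
  if (anyDuplicated(ids)) {
    sdar_error("duplicate compound ids in fingerprint list",
               "sdar_validation_error")
  }
  if (!all(modeling_ids %in% ids)) {
    sdar_error("modeling_ids contains ids with no fingerprint",
               "sdar_validation_error")
  }
  is_model <- ids %in% modeling_ids
  retained <- sort(unique(unlist(lapply(fps[is_model], function(f) {
    as.integer(names(f$bins)[f$bins > 0])
  }))))
  if (length(retained) == 0) {
    sdar_error("no retained bins: every modeling fingerprint is empty",
               "sdar_degenerate_error")
  }
  counts <- matrix(0, nrow = length(fps), ncol = length(retained),
                   dimnames = list(ids, as.character(retained)))
  dropped <- 0L
  for (i in seq_along(fps)) {
    b <- fps[[i]]$bins
    pos <- match(as.integer(names(b)), retained)
    keep <- !is.na(pos)
    if (!is_model[i]) dropped <- dropped + sum(!keep)
    counts[i, pos[keep]] <- as.numeric(b[keep])
  }
  sc <- compute_scaling(counts[is_model, , drop = FALSE], cfg$scaling)
  X <- apply_scaling(counts, sc)
  structure(list(ids = ids, bin_ids = retained, counts = counts, X = X,
                 center = sc$center, scale = sc$scale, scaling = cfg$scaling,
                 modeling_ids = intersect(ids, modeling_ids), cfg = cfg,
                 dropped_external_bins = dropped),
            class = "sdar_features")
}

compute_scaling <- function(M, scaling) {
  if (scaling == "zscore") {
    center <- colMeans(M)
    scale <- apply(M, 2, stats::sd)
  } else if (scaling == "minmax") {
    center <- apply(M, 2, min)
    scale <- apply(M, 2, max) - center
  } else {
    center <- rep(0, ncol(M))
    scale <- rep(1, ncol(M))
  }
  list(center = center, scale = scale, mode = scaling)
}

apply_scaling <- function(M, sc) {
  X <- sweep(M, 2, sc$center, "-")
  s <- ifelse(sc$scale > 0, sc$scale, Inf)  # constant columns -> 0
  sweep(X, 2, s, "/")
}

#' Transform new fingerprints with a frozen feature space
#'
#' Projects fingerprints of unseen compounds onto the retained-bin columns
#' of an existing [build_feature_matrix()] result, applying its frozen
#' scaling. Bins outside the retained set are dropped.
#'
#' @param features An `sdar_features` object.
#' @param fps List of `sdar_fp` for the new compounds.
#' @return Scaled matrix with one row per new compound.
#' @export
scale_new_fingerprints <- function(features, fps) {
  ids <- vapply(fps, function(f) f$id, character(1))
  M <- matrix(0, nrow = length(fps), ncol = length(features$bin_ids),
              dimnames = list(ids, as.character(features$bin_ids)))
  for (i in seq_along(fps)) {
    b <- fps[[i]]$bins
    pos <- match(as.integer(names(b)), features$bin_ids)
    keep <- !is.na(pos)
    M[i, pos[keep]] <- as.numeric(b[keep])
  }
  apply_scaling(M, list(center = features$center, scale = features$scale,
                        mode = features$scaling))
}

#' Export / import fingerprints as sparse triplet CSV
#'
#' The CSV holds `id,bin_id,occupancy` rows; a JSON sidecar
#' (`<path>.json`) serializes the [binning_config()] so bin ids remain
#' decodable.
#'
#' @param fps List of `sdar_fp`.
#' @param path CSV output path.
#' @param cfg The binning configuration to record in the sidecar.
#' @return `path`, invisibly.
#' @export
write_fingerprints <- function(fps, path, cfg = binning_config()) {
  rows <- do.call(rbind, lapply(fps, function(f) {
    if (length(f$bins) == 0) return(NULL)
    data.frame(id = f$id, bin_id = as.integer(names(f$bins)),
               occupancy = as.integer(f$bins))
  }))
  if (is.null(rows)) {
    rows <- data.frame(id = character(), bin_id = integer(),
                       occupancy = integer())
  }
  write.csv(rows, path, row.names = FALSE, quote = FALSE)
  jsonlite::write_json(binning_to_list(cfg), paste0(path, ".json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_fingerprints
#' @export
read_fingerprints <- function(path) {
  df <- read.table(path, sep = ",", header = TRUE, stringsAsFactors = FALSE)
  cfg <- binning_from_list(jsonlite::read_json(paste0(path, ".json"),
                                               simplifyVector = TRUE))
  fps <- lapply(split(df, df$id), function(d) {
    o <- order(d$bin_id)
    structure(list(id = d$id[1],
                   bins = setNames(as.integer(d$occupancy[o]),
                                   as.character(d$bin_id[o])),
                   n_pairs = NA_integer_, n_skipped = NA_integer_),
              class = "sdar_fp")
  })
  list(fps = unname(fps), cfg = cfg)
}

binning_to_list <- function(cfg) {
  cfg[c("c_window", "n_window", "w_c", "cn_ratio", "d_window", "w_d",
        "occupancy", "scaling")]
}

binning_from_list <- function(x) {
  binning_config(c_window = unlist(x$c_window), n_window = unlist(x$n_window),
                 w_c = x$w_c, cn_ratio = x$cn_ratio,
                 d_window = unlist(x$d_window), w_d = x$w_d,
                 occupancy = x$occupancy, scaling = x$scaling)
}
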