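#' Back-project significant bins onto active compounds as toxicophores
#'
#' Decodes each significant bin into its (pair class, shift window, shift
#' window, distance range) description and enumerates, in every active
#' compound, the atom pairs whose (shift, shift, distance) triplet falls
#' inside that box. When a matched atom belongs to a perceived aromatic
#' ring, the reported anchor is the ring centroid and the reported
#' distance is recomputed to that centroid (so features read like
#' "benzene ring and a nitrogen atom linked at 7-8 A"); non-ring atoms
#' keep atom-anchored distances. Features are sorted by aggregate
#' sensitivity (descending) and then support — the number of distinct
#' active compounds containing at least one match.
#'
#' @param bin_ids Integer ids of the significant bins, or an
#'   `sdar_sensitivity` object (its significant set is used, in rank
#'   order).
#' @param actives List of `list(mol = <sdar_mol>, shifts = <shift vector>)`
#'   for the TdP-positive compounds only.
#' @param cfg The [binning_config()] the fingerprints were computed with.
#' @param sensitivity Optional named vector of aggregate sensitivities
#'   (by bin id) used for sorting when `bin_ids` is a plain vector.
#' @return A list of `sdar_toxicophore` features, each with `bin_id`,
#'   `decode`, `sensitivity`, `support` and `instances` (data.frame: id,
#'   atom/anchor indices, whether each anchor is a ring centroid, the raw
#'   atom-atom distance and the anchor distance).
#' @export
map_bins_to_atoms <- function(bin_ids, actives, cfg = binning_config(),
                              sensitivity = NULL) {
  if (inherits(bin_ids, "sdar_sensitivity")) {
    tab <- bin_ids$table[bin_ids$table$significant, ]
    sensitivity <- setNames(tab$mean_ratio, tab$bin_id)
    bin_ids <- tab$bin_id
  }
  if (length(actives) == 0) {
    warning("no active compounds: toxicophore list is empty")
    return(list())
  }
  prepped <- lapply(actives, function(a) {
    list(mol = a$mol, shifts = a$shifts, dm = distance_matrix(a$mol),
         rings = perceive_aromatic_rings(a$mol))
  })
  features <- lapply(bin_ids, function(bid) {
    dec <- decode_bin(bid, cfg)
    inst <- do.call(rbind, lapply(prepped, function(p) {
      match_bin_in_molecule(dec, p, cfg)
    }))
    if (is.null(inst)) {
      inst <- data.frame(id = character(), anchor_a = integer(),
                         ring_a = logical(), anchor_b = integer(),
                         ring_b = logical(), atom_a = integer(),
                         atom_b = integer(), atom_distance = numeric(),
                         anchor_distance = numeric())
    }
    structure(list(bin_id = bid, decode = dec,
                   sensitivity = unname(if (!is.null(sensitivity))
                     sensitivity[as.character(bid)] else NA_real_),
                   support = length(unique(inst$id)),
                   instances = inst),
              class = "sdar_toxicophore")
  })
  ord <- order(-vapply(features, function(f) f$sensitivity %||% NA_real_,
                       numeric(1)),
               -vapply(features, function(f) f$support, numeric(1)),
               na.last = TRUE)
  features[ord]
}

# all atom pairs of one molecule matching a decoded bin box
match_bin_in_molecule <- function(dec, p, cfg) {
  mol <- p$mol
  el <- mol$atoms$element
  shifts <- p$shifts
  e1 <- substr(dec$class, 1, 1)
  e2 <- substr(dec$class, 2, 2)
  in_axis <- function(s, interval, window) {
    # same closure rule as binning: right-open except at the window edge
    s >= interval[1] & (s < interval[2] | (interval[2] == window[2] & s == interval[2]))
  }
  win1 <- axis_for(cfg, e1)$window
  win2 <- axis_for(cfg, e2)$window
  cand1 <- which(el == e1 & !is.na(shifts) &
                 in_axis(shifts, dec$axis1_interval, win1))
  cand2 <- which(el == e2 & !is.na(shifts) &
                 in_axis(shifts, dec$axis2_interval, win2))
  if (length(cand1) == 0 || length(cand2) == 0) return(NULL)
  grid <- expand.grid(a = cand1, b = cand2)
  grid <- grid[grid$a != grid$b, , drop = FALSE]
  if (dec$class %in% c("CC", "NN")) {
    # canonical axis order: smaller shift on axis 1; dedupe unordered pairs
    grid <- grid[shifts[grid$a] <= shifts[grid$b], , drop = FALSE]
    key <- paste(pmin(grid$a, grid$b), pmax(grid$a, grid$b))
    grid <- grid[!duplicated(key), , drop = FALSE]
    if (!identical(dec$axis1_interval, dec$axis2_interval)) {
      # off-diagonal box: axis-1 atom must sit in interval 1, axis-2 in 2
      grid <- grid[in_axis(shifts[grid$a], dec$axis1_interval, win1) &
                   in_axis(shifts[grid$b], dec$axis2_interval, win2), ,
                   drop = FALSE]
    }
  }
  if (nrow(grid) == 0) return(NULL)
  d <- p$dm[cbind(grid$a, grid$b)]
  ok <- d >= dec$d_interval[1] &
    (d < dec$d_interval[2] |
     (dec$d_interval[2] == cfg$d_window[2] & d == dec$d_interval[2]))
  grid <- grid[ok, , drop = FALSE]
  if (nrow(grid) == 0) return(NULL)
  d <- d[ok]
  xyz <- mol_coords(mol)
  anchor <- function(i) {
    for (r in seq_along(p$rings)) {
      if (i %in% p$rings[[r]]$atoms) {
        return(list(ring = r, pos = p$rings[[r]]$centroid))
      }
    }
    list(ring = NA_integer_, pos = xyz[i, ])
  }
  rows <- lapply(seq_len(nrow(grid)), function(j) {
    aa <- anchor(grid$a[j]); ab <- anchor(grid$b[j])
    data.frame(id = mol$id,
               anchor_a = if (is.na(aa$ring)) grid$a[j] else aa$ring,
               ring_a = !is.na(aa$ring),
               anchor_b = if (is.na(ab$ring)) grid$b[j] else ab$ring,
               ring_b = !is.na(ab$ring),
               atom_a = grid$a[j], atom_b = grid$b[j],
               atom_distance = d[j],
               anchor_distance = sqrt(sum((aa$pos - ab$pos)^2)))
  })
  do.call(rbind, rows)
}

#' @export
print.sdar_toxicophore <- function(x, ...) {
  d <- x$decode
  cat(sprintf(
    "<sdar_toxicophore> bin %d [%s]: shifts %g..%g / %g..%g PPM, distance %.1f-%.1f A; support %d compound(s)%s\n",
    x$bin_id, d$class, d$axis1_interval[1], d$axis1_interval[2],
    d$axis2_interval[1], d$axis2_interval[2],
    d$d_interval[1], d$d_interval[2], x$support,
    if (is.na(x$sensitivity)) "" else
      sprintf(", sensitivity %.3f", x$sensitivity)))
  invisible(x)
}

#' Write a toxicophore report
#'
#' Emits the feature list as JSON (full precision) and, optionally, an
#' annotated SDF in which each active compound carries an
#' `SDAR_FEATURES` property listing `feature_bin:atomA,atomB` matches.
#' Displayed distances in the JSON summary are rounded to 0.1 A; the
#' instance tables keep full precision.
#'
#' @param features List from [map_bins_to_atoms()].
#' @param path Output path for the JSON report.
#' @param actives Optional actives list (as for [map_bins_to_atoms()]);
#'   when given, `<path>.sdf` is written with match annotations.
#' @return `path`, invisibly.
#' @export
write_toxicophore_report <- function(features, path, actives = NULL) {
  js <- lapply(features, function(f) {
    list(bin_id = f$bin_id, class = f$decode$class,
         axis1_interval_ppm = f$decode$axis1_interval,
         axis2_interval_ppm = f$decode$axis2_interval,
         distance_interval_angstrom = f$decode$d_interval,
         display_distance = sprintf("%.1f-%.1f A",
                                    round(f$decode$d_interval[1], 1),
                                    round(f$decode$d_interval[2], 1)),
         sensitivity = f$sensitivity, support = f$support,
         instances = f$instances)
  })
  jsonlite::write_json(js, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows")
  if (!is.null(actives) && length(actives) > 0) {
    props <- lapply(actives, function(a) {
      hits <- character()
      for (f in features) {
        inst <- f$instances[f$instances$id == a$mol$id, , drop = FALSE]
        if (nrow(inst) > 0) {
          hits <- c(hits, sprintf("%d:%s", f$bin_id,
                                  paste(inst$atom_a, inst$atom_b, sep = ",",
                                        collapse = ";")))
        }
      }
      c(SDAR_FEATURES = paste(hits, collapse = "|"))
    })
    write_structures(lapply(actives, `[[`, "mol"), paste0(path, ".sdf"),
                     properties = props)
  }
  invisible(path)
}
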