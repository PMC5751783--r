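# fixtures built in code: toy molecules, MOL/SDF text, tiny feature sets

methane_mol_text <- function() {
  c("methane", "  test  3D", "",
    "  5  4  0  0  0  0  0  0  0  0999 V2000",
    "    0.0000    0.0000    0.0000 C   0  0  0  0  0  0  0  0  0  0  0  0",
    "    0.6300    0.6300    0.6300 H   0  0  0  0  0  0  0  0  0  0  0  0",
    "   -0.6300   -0.6300    0.6300 H   0  0  0  0  0  0  0  0  0  0  0  0",
    "   -0.6300    0.6300   -0.6300 H   0  0  0  0  0  0  0  0  0  0  0  0",
    "    0.6300   -0.6300   -0.6300 H   0  0  0  0  0  0  0  0  0  0  0  0",
    "  1  2  1  0", "  1  3  1  0", "  1  4  1  0", "  1  5  1  0",
    "M  END")
}

write_methane_mol <- function(path = tempfile(fileext = ".mol")) {
  writeLines(methane_mol_text(), path)
  path
}

# regular hexagon of aromatic carbons in the xy-plane, circumradius r
hexagon_ring_mol <- function(id = "hexring", r = 1.39, extra = NULL) {
  th <- seq(0, 2 * pi, length.out = 7)[1:6]
  atoms <- data.frame(element = rep("C", 6),
                      x = r * cos(th), y = r * sin(th), z = 0)
  bonds <- data.frame(a = 1:6, b = c(2:6, 1L), order = 4L, aromatic = TRUE)
  if (!is.null(extra)) atoms <- rbind(atoms, extra)
  molecule_record(id, atoms, bonds)
}

# benzene in Kekule form (alternating single/double bonds, no aromatic flag)
benzene_kekule_mol <- function() {
  th <- seq(0, 2 * pi, length.out = 7)[1:6]
  atoms <- data.frame(element = rep("C", 6),
                      x = 1.39 * cos(th), y = 1.39 * sin(th), z = 0)
  bonds <- data.frame(a = 1:6, b = c(2:6, 1L),
                      order = rep(c(1L, 2L), 3), aromatic = FALSE)
  molecule_record("benzene", atoms, bonds)
}

ethane_mol <- function() {
  molecule_record("ethane",
                  data.frame(element = c("C", "C"),
                             x = c(0, 1.54), y = 0, z = 0),
                  data.frame(a = 1L, b = 2L, order = 1L, aromatic = FALSE))
}

# random C/N cloud with shifts inside the default windows
random_small_molecule <- function(id, n_atoms) {
  repeat {
    xyz <- matrix(runif(n_atoms * 3, -4, 4), ncol = 3)
    if (n_atoms == 1 || min(dist(xyz)) > 0.8) break
  }
  el <- sample(c("C", "N", "H"), n_atoms, replace = TRUE,
               prob = c(0.6, 0.25, 0.15))
  shifts <- rep(NA_real_, n_atoms)
  shifts[el == "C"] <- runif(sum(el == "C"), -4, 204)
  shifts[el == "N"] <- runif(sum(el == "N"), -356, -11)
  mol <- molecule_record(id, data.frame(element = el, x = xyz[, 1],
                                        y = xyz[, 2], z = xyz[, 3]))
  list(mol = mol, shifts = structure(shifts, id = id))
}

# independent oracle: naive triple loop over all unordered C/N pairs
oracle_fingerprint <- function(mol, shifts, cfg) {
  el <- mol$atoms$element
  xyz <- as.matrix(mol$atoms[, c("x", "y", "z")])
  idx <- which(el %in% c("C", "N"))
  bins <- integer(0)
  skipped <- 0L
  n_pairs <- 0L
  if (length(idx) >= 2) {
    for (ii in seq_len(length(idx) - 1)) {
      for (jj in seq(ii + 1, length(idx))) {
        i <- idx[ii]; j <- idx[jj]
        n_pairs <- n_pairs + 1L
        d <- sqrt(sum((xyz[i, ] - xyz[j, ])^2))
        # canonical order
        if (el[i] == el[j]) {
          s1 <- min(shifts[i], shifts[j]); s2 <- max(shifts[i], shifts[j])
          e1 <- el[i]; e2 <- el[j]
        } else if (el[i] == "C") {
          s1 <- shifts[i]; s2 <- shifts[j]; e1 <- "C"; e2 <- "N"
        } else {
          s1 <- shifts[j]; s2 <- shifts[i]; e1 <- "C"; e2 <- "N"
        }
        w1 <- if (e1 == "C") cfg$c_window else cfg$n_window
        w2 <- if (e2 == "C") cfg$c_window else cfg$n_window
        b1 <- if (e1 == "C") cfg$w_c else cfg$w_n
        b2 <- if (e2 == "C") cfg$w_c else cfg$w_n
        i1 <- bin_axis_index(s1, w1, b1)
        i2 <- bin_axis_index(s2, w2, b2)
        k <- bin_axis_index(d, cfg$d_window, cfg$w_d)
        if (is.na(i1) || is.na(i2) || is.na(k)) {
          skipped <- skipped + 1L
        } else {
          bins <- c(bins, encode_bin(paste0(e1, e2), i1, i2, k, cfg))
        }
      }
    }
  }
  tab <- table(bins)
  occ <- if (length(tab) == 0) setNames(integer(0), character(0))
         else setNames(as.integer(tab), names(tab))
  occ <- occ[order(as.integer(names(occ)))]
  list(bins = occ, n_pairs = n_pairs, skipped = skipped)
}

# tiny linearly separable feature set: 4 compounds, 2 features
separable_toy <- function() {
  X <- rbind(c(1, 0), c(0.8, 0.1), c(0, 1), c(0.1, 0.9))
  rownames(X) <- paste0("cpd", 1:4)
  y <- setNames(c(1L, 1L, 0L, 0L), rownames(X))
  list(X = X, y = y)
}

# small trained ensemble shared by several test files (cheap: 8 members)
small_recovery <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cache <<- recovery_harness(synthetic_spec(n_compounds = 24),
                                 n_members = 8, seed = 11)
    }
    cache
  }
})
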