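test_that("default binning reproduces the element window arithmetic", {
  cfg <- binning_config()
  expect_identical(diff(cfg$c_window), 208)
  expect_identical(mean(cfg$c_window), 100)
  expect_identical(diff(cfg$n_window), 345)
  expect_identical(mean(cfg$n_window), -183.5)
  expect_identical(cfg$w_n, 2.5 * cfg$w_c)
  expect_identical(cfg$n_bins_c, 26L)   # 208 / 8
  expect_identical(cfg$n_bins_n, 18L)   # ceil(345 / 20), last bin truncated
})

test_that("bin_axis_index follows floor arithmetic with closed upper edge", {
  cfg <- binning_config()
  # lower edge maps to the first bin
  expect_identical(bin_axis_index(-4, cfg$c_window, cfg$w_c), 1L)
  # floor((100 - (-4)) / 8) = 13 zero-based -> 14th bin
  expect_identical(bin_axis_index(100, cfg$c_window, cfg$w_c), 14L)
  # upper window edge belongs to the last bin
  expect_identical(bin_axis_index(204, cfg$c_window, cfg$w_c), 26L)
  # below the nitrogen window -> out of window
  expect_true(is.na(bin_axis_index(-360, cfg$n_window, cfg$w_n)))
  expect_error(bin_axis_index(NaN, cfg$c_window, cfg$w_c),
               class = "sdar_domain_error")
})

test_that("bin id codec encodes and decodes every class block", {
  cfg <- binning_config()
  for (cl in c("CC", "CN", "NN")) {
    dims <- switch(cl, CC = c(cfg$n_bins_c, cfg$n_bins_c),
                   CN = c(cfg$n_bins_c, cfg$n_bins_n),
                   NN = c(cfg$n_bins_n, cfg$n_bins_n))
    set.seed(17)
    for (r in 1:25) {
      i1 <- sample(dims[1], 1); i2 <- sample(dims[2], 1)
      k <- sample(cfg$n_bins_d, 1)
      dec <- decode_bin(encode_bin(cl, i1, i2, k, cfg), cfg)
      expect_identical(dec$class, cl)
      expect_identical(c(dec$i1, dec$i2, dec$k), c(i1, i2, k))
    }
  }
  # decoded intervals cover the encoded value
  dec <- decode_bin(encode_bin("CN", 16, 2, 7, cfg), cfg)
  expect_identical(dec$axis1_interval, c(116, 124))
  expect_identical(dec$axis2_interval, c(-336, -316))
  expect_identical(dec$d_interval, c(7, 8))
})

test_that("single-carbon molecule has an empty fingerprint", {
  mol <- molecule_record("c1", data.frame(element = "C", x = 0, y = 0, z = 0))
  fp <- compute_fingerprint(mol, structure(30, id = "c1"))
  expect_length(fp$bins, 0)
  expect_identical(fp$n_pairs, 0L)
})

test_that("3-atom toy matches brute-force enumeration: one CC and two CN bins", {
  # 2 C (20, 130 PPM), 1 N (-300 PPM); distances 2, 5, 6 A
  # place atoms: C1 (0,0,0), C2 (2,0,0); N such that |N-C1|=5, |N-C2|=6
  # x from 25-x^2 = 36-(x-2)^2 -> x = -7/4; y = sqrt(25 - 49/16)
  y <- sqrt(25 - (7 / 4)^2)
  mol <- molecule_record("toy3", data.frame(
    element = c("C", "C", "N"),
    x = c(0, 2, -7 / 4), y = c(0, 0, y), z = 0))
  shifts <- structure(c(20, 130, -300), id = "toy3")
  dm <- distance_matrix(mol)
  expect_equal(dm[1, 3], 5)
  expect_equal(dm[2, 3], 6)
  cfg <- binning_config()
  fp <- compute_fingerprint(mol, shifts, cfg = cfg)
  expect_length(fp$bins, 3)
  expect_true(all(fp$bins == 1L))
  oracle <- oracle_fingerprint(mol, shifts, cfg)
  expect_identical(fp$bins, oracle$bins)
  # decode: one CC bin, two CN bins
  classes <- vapply(as.integer(names(fp$bins)),
                    function(b) decode_bin(b, cfg)$class, character(1))
  expect_identical(sort(classes), c("CC", "CN", "CN"))
})

test_that("fingerprint equals the all-pairs oracle on 100 random molecules", {
  set.seed(99)
  cfg <- binning_config()
  for (r in 1:100) {
    x <- random_small_molecule(sprintf("r%d", r), sample(2:8, 1))
    fp <- compute_fingerprint(x$mol, x$shifts, cfg = cfg)
    oracle <- oracle_fingerprint(x$mol, x$shifts, cfg)
    expect_identical(fp$bins, oracle$bins)
    expect_identical(fp$n_skipped, oracle$skipped)
    # count conservation
    expect_identical(sum(fp$bins) + fp$n_skipped, oracle$n_pairs)
  }
})

test_that("fingerprint is bitwise invariant under rigid motion and atom permutation", {
  set.seed(123)
  for (r in 1:20) {
    x <- random_small_molecule(sprintf("inv%d", r), sample(3:8, 1))
    fp <- compute_fingerprint(x$mol, x$shifts)
    rot <- sdar3d:::random_rotation()
    mol2 <- transform_molecule(x$mol, rot, rnorm(3, sd = 20))
    expect_identical(compute_fingerprint(mol2, x$shifts)$bins, fp$bins)
    # permute atom order
    perm <- sample(nrow(x$mol$atoms))
    mol3 <- molecule_record(x$mol$id, x$mol$atoms[perm, ])
    sh3 <- structure(as.numeric(x$shifts)[perm], id = x$mol$id)
    expect_identical(compute_fingerprint(mol3, sh3)$bins, fp$bins)
  }
})

test_that("missing shifts for eligible atoms raise an incomplete error", {
  mol <- molecule_record("m", data.frame(element = c("C", "C"),
                                         x = c(0, 2), y = 0, z = 0))
  expect_error(compute_fingerprint(mol, structure(c(20, NA), id = "m")),
               class = "sdar_incomplete_shift_error")
})

test_that("feature matrix retains modeling-set bins and z-scores columns", {
  mk_fp <- function(id, bins) {
    structure(list(id = id, bins = bins, n_pairs = sum(bins),
                   n_skipped = 0L), class = "sdar_fp")
  }
  fps <- list(mk_fp("A", setNames(2L, "7")),
              mk_fp("B", setNames(integer(0), character(0))),
              mk_fp("X", setNames(c(1L, 3L), c("7", "9"))))
  fm <- build_feature_matrix(fps, c("A", "B"), binning_config())
  expect_identical(fm$bin_ids, 7L)         # bin 9 absent from modeling set
  expect_identical(fm$dropped_external_bins, 1L)
  # hand z-score of the 2-vector (2, 0): mean 1, sd sqrt(2)
  expect_equal(unname(fm$X[c("A", "B"), 1]),
               c(1 / sqrt(2), -1 / sqrt(2)))
  expect_equal(mean(fm$X[c("A", "B"), 1]), 0, tolerance = 1e-8)
  expect_equal(sd(fm$X[c("A", "B"), 1]), 1, tolerance = 1e-8)
  # external compound transformed with frozen statistics
  expect_equal(unname(fm$X["X", 1]), (1 - 1) / sqrt(2))
})

test_that("all-constant columns scale to zero", {
  mk_fp <- function(id) {
    structure(list(id = id, bins = setNames(3L, "5"), n_pairs = 3L,
                   n_skipped = 0L), class = "sdar_fp")
  }
  fm <- build_feature_matrix(list(mk_fp("A"), mk_fp("B")), c("A", "B"),
                             binning_config())
  expect_true(all(fm$X == 0))
})

test_that("empty modeling fingerprints give a degenerate-input error", {
  fp <- structure(list(id = "A", bins = setNames(integer(0), character(0)),
                       n_pairs = 0L, n_skipped = 0L), class = "sdar_fp")
  expect_error(build_feature_matrix(list(fp), "A", binning_config()),
               class = "sdar_degenerate_error")
})

test_that("scaled column means vanish over modeling compounds for real data", {
  set.seed(31)
  xs <- lapply(1:6, function(i) random_small_molecule(sprintf("s%d", i), 8))
  fps <- lapply(xs, function(x) compute_fingerprint(x$mol, x$shifts))
  ids <- vapply(fps, function(f) f$id, character(1))
  fm <- build_feature_matrix(fps, ids, binning_config())
  mu <- colMeans(fm$X)
  expect_true(all(abs(mu) < 1e-8))
  sds <- apply(fm$X, 2, sd)
  expect_true(all(abs(sds[sds > 0] - 1) < 1e-8))
})

test_that("fingerprints round-trip through the sparse CSV + sidecar", {
  set.seed(8)
  xs <- lapply(1:3, function(i) random_small_molecule(sprintf("io%d", i), 6))
  fps <- lapply(xs, function(x) compute_fingerprint(x$mol, x$shifts))
  path <- tempfile(fileext = ".csv")
  write_fingerprints(fps, path)
  back <- read_fingerprints(path)
  expect_equal(back$cfg$w_c, 8)
  ids_in <- vapply(fps, function(f) f$id, character(1))
  for (f in back$fps) {
    expect_identical(f$bins, fps[[match(f$id, ids_in)]]$bins)
  }
})

test_that("minmax and none scaling modes behave as documented", {
  mk_fp <- function(id, v) {
    structure(list(id = id, bins = setNames(v, "3"), n_pairs = v,
                   n_skipped = 0L), class = "sdar_fp")
  }
  fps <- list(mk_fp("A", 4L), mk_fp("B", 0L))
  fm_mm <- build_feature_matrix(fps, c("A", "B"),
                                binning_config(scaling = "minmax"))
  expect_equal(unname(fm_mm$X[, 1]), c(1, 0))
  fm_no <- build_feature_matrix(fps, c("A", "B"),
                                binning_config(scaling = "none"))
  expect_equal(unname(fm_no$X[, 1]), c(4, 0))
})
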