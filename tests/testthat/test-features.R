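test_that("singular values match the eigendecomposition oracle", {
  expect_equal(svd_singular_values(diag(2)), c(1, 1))
  expect_equal(svd_singular_values(diag(c(3, 4))), c(4, 3))

  set.seed(10)
  for (i in 1:100) {
    m <- sample(2:6, 1); n <- sample(2:6, 1)
    X <- matrix(rnorm(m * n), m, n)
    oracle <- sqrt(sort(pmax(eigen(crossprod(X), symmetric = TRUE,
                                   only.values = TRUE)$values, 0),
                        decreasing = TRUE))[seq_len(min(m, n))]
    expect_equal(svd_singular_values(X), oracle, tolerance = 1e-8)
  }
  expect_error(svd_singular_values(matrix(c(1, NA), 1)), "finite")
})

test_that("the segment singular value is the Euclidean norm", {
  expect_equal(segment_svd_feature(c(3, 4)), 5)
  expect_equal(segment_svd_feature(rep(0, 10)), 0)
  set.seed(11)
  x <- rnorm(500)
  expect_equal(segment_svd_feature(x), sqrt(sum(x^2)), tolerance = 1e-10)
  expect_error(segment_svd_feature(numeric(0)), "empty")

  # reshape variant: leading singular value of the folded matrix
  r <- floor(sqrt(500))
  m <- matrix(x[1:(r * floor(500 / r))], nrow = r, byrow = TRUE)
  expect_equal(segment_svd_feature(x, shape = "reshape"),
               svd_singular_values(m)[1])
})

test_that("time-domain descriptors match hand arithmetic", {
  x <- c(1, -1, 2, -2)
  f <- td_features(x)
  expect_equal(unname(f["MAV"]), 1.5)
  expect_equal(unname(f["ZC"]), 3)
  expect_equal(unname(f["WL"]), 9)
  expect_equal(unname(f["RMS"]), sqrt(2.5))
  expect_equal(unname(f["VAR"]), 10 / 3)
  expect_equal(unname(f["STD"]), sqrt(10 / 3))
  expect_equal(unname(f["SE"]), sqrt(10 / 3) / 2)
  expect_equal(unname(f["SNR"]), 1.5 / sqrt(10 / 3))

  const <- td_features(rep(2, 10))
  expect_equal(unname(const[c("ZC", "WL", "VAR", "SNR")]), c(0, 0, 0, 0))
  expect_error(td_features(1), "short")
})

test_that("LS4/LS9 descriptors match hand arithmetic", {
  x <- c(0, 1, 0, 1)
  f9 <- ls_features(x, "LS9", wamp_threshold = 0.5)
  expect_named(f9, c("LS", "MAV", "ZC", "SSC", "WL", "RMS", "IAV",
                     "DASDV", "VAR"))
  f4 <- ls_features(x, "LS4", wamp_threshold = 0.5)
  expect_equal(unname(f4["WAMP"]), 3)
  expect_equal(unname(f4["MFL"]), log10(sqrt(3)))
  expect_equal(unname(f4["MSR"]), 0.5)

  expect_equal(unname(f9["IAV"]), 2)
  expect_equal(unname(f9["SSC"]), 2)
  expect_equal(unname(f9["DASDV"]), 1)
  expect_length(f4, 4)
  expect_length(f9, 9)

  z <- ls_features(rep(0, 10), "LS4")
  expect_equal(unname(z[c("MSR", "WAMP", "LS")]), c(0, 0, 0))
  expect_equal(unname(ls_features(rep(0, 10), "LS9")["IAV"]), 0)

  # L-scale oracle: mean absolute pairwise difference / 2
  set.seed(12)
  y <- rnorm(40)
  pairs <- combn(40, 2)
  expect_equal(unname(ls_features(y, "LS4")["LS"]),
               mean(abs(y[pairs[1, ]] - y[pairs[2, ]])) / 2,
               tolerance = 1e-10)
})

test_that("feature-matrix dimensionality is channels x modes", {
  rec <- short_recording()
  f12 <- extract_vmd_svd(rec, K = 12)
  expect_equal(ncol(f12$values), 36)
  f2 <- extract_vmd_svd(rec, K = 2)
  expect_equal(ncol(f2$values), 6)
  expect_equal(nrow(f2$values), nrow(f12$values))
  expect_equal(ncol(extract_td(rec, "TD8")$values), 24)
  expect_equal(ncol(extract_td(rec, "LS4")$values), 12)
  expect_equal(ncol(extract_td(rec, "LS9")$values), 27)
})

test_that("a stationary tone gives near-constant segment features", {
  t <- (0:9999) / 2000
  rec <- emg_recording(matrix(cos(2 * pi * 50 * t), nrow = 1), 2000)
  f <- extract_vmd_svd(rec, K = 1)
  interior <- f$values[2:(nrow(f$values) - 1), 1]
  expect_lt(diff(range(interior)) / mean(interior), 0.01)
})

test_that("EMD features zero-fill missing modes and stay deterministic", {
  rec <- short_recording()
  f <- extract_emd_svd(rec, n_imfs = 8)
  expect_equal(ncol(f$values), 24)
  expect_identical(f, extract_emd_svd(rec, n_imfs = 8))

  mono <- emg_recording(matrix(rep(seq(0, 1, length.out = 1000), 2),
                               nrow = 2, byrow = TRUE), 2000)
  fm <- extract_emd_svd(mono, n_imfs = 3, window_ms = 100)
  expect_true(all(fm$values == 0))
})

test_that("combining feature sets concatenates columns and keeps labels", {
  rec <- short_recording()
  td <- extract_td(rec, "TD8")
  vs <- extract_vmd_svd(rec, K = 2)
  both <- combine_features(td, vs)
  expect_equal(ncol(both$values), 24 + 6)
  expect_identical(both$row_labels, td$row_labels)
  expect_equal(both$feature_set_id, "TD8+VMD_SVD")
  expect_identical(combine_features(td), td)

  bad <- vs
  bad$values <- bad$values[-1, , drop = FALSE]
  bad$row_labels <- bad$row_labels[-1]
  expect_error(combine_features(td, bad), "mismatch")
})

test_that("features scale equivariantly with the signal", {
  set.seed(13)
  x <- rnorm(500)
  c0 <- 3.7
  expect_equal(segment_svd_feature(c0 * x), c0 * segment_svd_feature(x))
  f1 <- td_features(x); f2 <- td_features(c0 * x)
  for (nm in c("MAV", "WL", "RMS", "STD", "SE"))
    expect_equal(unname(f2[nm]), c0 * unname(f1[nm]))
  expect_equal(unname(f2["ZC"]), unname(f1["ZC"]))
  expect_equal(unname(ls_features(c0 * x, "LS9")["IAV"]),
               c0 * unname(ls_features(x, "LS9")["IAV"]))
})

test_that("feature matrices round-trip through CSV", {
  rec <- short_recording()
  fm <- extract_td(rec, "TD8")
  path <- withr::local_tempfile(fileext = ".csv")
  write_feature_matrix(fm, path)
  back <- utils::read.csv(path, check.names = FALSE)
  expect_equal(as.matrix(back[, -ncol(back)]), fm$values,
               ignore_attr = TRUE, tolerance = 1e-12)
  expect_equal(back$label, fm$row_labels)
})
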