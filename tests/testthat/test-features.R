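test_that("correlation matches the Pearson oracle and its invariances", {
  A <- matrix(c(0, 2, 1, 3), 2, 2)
  B <- matrix(c(0, 4, 2, 6), 2, 2)   # positive affine transform of A
  Bn <- matrix(c(3, 1, 2, 0), 2, 2)  # negative affine transform of A
  expect_equal(compute_correlation(A, A), 1.0)
  expect_equal(compute_correlation(A, B), 1.0)
  expect_equal(compute_correlation(A, Bn), -1.0)

  for (s in 1:100) {
    a <- rand_frame(12, 9, seed = 1000 + s)
    b <- rand_frame(12, 9, seed = 2000 + s)
    r <- compute_correlation(a, b)
    expect_equal(r, pearson_oracle(a, b), tolerance = 1e-9)
    expect_true(r >= -1 && r <= 1)
    expect_identical(r, compute_correlation(b, a))
    # invariance under positive affine intensity transforms of either argument
    expect_equal(compute_correlation(a * 0.43 + 17, b), r, tolerance = 1e-9)
    expect_equal(compute_correlation(a, b * 0.85 + 3), r, tolerance = 1e-9)
  }
})

test_that("degenerate (zero-variance) frames raise a degenerate-input error", {
  flat <- matrix(5, 4, 4)
  b <- rand_frame(4, 4, seed = 1)
  expect_error(compute_correlation(flat, b), class = "sonoqc_degenerate_error")
  expect_error(compute_correlation(b, flat), class = "sonoqc_degenerate_error")
  expect_error(compute_correlation(b, rand_frame(5, 4, seed = 2)),
               class = "sonoqc_shape_error")
})

test_that("contact gate boundary is inclusive", {
  expect_identical(contact_gate(0.70, 0.70), 1L)
  expect_identical(contact_gate(0.69, 0.70), 0L)
  expect_identical(contact_gate(1.0, 0.70), 1L)
  expect_identical(contact_gate(-1.0, 0.70), 0L)
})

test_that("compression feature equals the row-scan extent", {
  f <- matrix(0, 10, 6)
  f[3, 2] <- 50; f[8, 5] <- 200   # bright rows 2 and 7, 0-based
  res <- compute_compression(f, t_comp = 20)
  expect_equal(res$compression, (7 - 2) / 10)
  expect_false(res$no_signal)

  full <- matrix(255, 12, 5)
  expect_equal(compute_compression(full, 20)$compression, (12 - 1) / 12)

  dark <- matrix(0, 8, 8)
  res0 <- compute_compression(dark, 20)
  expect_equal(res0$compression, 0)
  expect_true(res0$no_signal)
})

test_that("adding supra-threshold pixels outside [L, U] never decreases f_c", {
  for (s in 1:25) {
    f <- rand_frame(16, 12, seed = 3000 + s)
    f[f >= 20] <- 0
    # seed two bright rows, then perturb a random outside row
    rows <- local_seed(s, sort(sample(3:14, 2)))
    f[rows, 4] <- 100
    base <- compute_compression(f, 20)$compression
    out_row <- local_seed(s + 1, sample(c(seq_len(rows[1] - 1),
                                          seq(rows[2] + 1, 16)), 1))
    f2 <- f; f2[out_row, 7] <- 100
    expect_gte(compute_compression(f2, 20)$compression, base)
  }
})

test_that("wiener filter is bit-identical to the per-pixel oracle", {
  for (s in 1:5) {
    img <- rand_frame(24, 20, seed = 4000 + s)
    for (w in list(c(3L, 3L), c(5L, 5L), c(7L, 7L))) {
      got <- wiener_filter(img, w)
      want <- wiener_oracle(img, w[1], w[2])
      expect_identical(got$filtered, want$filtered)
      expect_identical(got$stats$mu, want$mu)
      expect_identical(got$stats$sigma2, want$sigma2)
      expect_identical(got$stats$nu2, want$nu2)
    }
  }
})

test_that("wiener filter is the identity on constant frames", {
  for (level in c(0, 1, 100, 255)) {
    f <- matrix(level, 9, 9)
    res <- wiener_filter(f, c(5L, 5L))
    expect_equal(res$filtered, f)
    expect_equal(res$stats$nu2, 0)
  }
})

test_that("wiener filter reduces the variance of additive noise", {
  base <- matrix(100, 32, 32)
  for (s in 1:20) {
    noisy <- local_seed(5000 + s,
      pmin(pmax(round(base + rnorm(1024, sd = 10)), 0), 255))
    flt <- wiener_filter(noisy, c(5L, 5L))$filtered
    expect_lte(var(as.vector(flt)), var(as.vector(noisy)))
  }
})

test_that("wiener window validation", {
  f <- rand_frame(8, 8, seed = 1)
  expect_error(wiener_filter(f, c(9L, 9L)), class = "sonoqc_config_error")
  expect_error(wiener_filter(f, c(4L, 4L)), class = "sonoqc_config_error")
})

test_that("noise feature matches the two-pass residual oracle", {
  for (level in c(0, 37, 255))
    expect_identical(compute_noise_feature(matrix(level, 10, 10)), 0)
  for (s in 1:5) {
    img <- rand_frame(20, 20, seed = 6000 + s)
    expect_equal(compute_noise_feature(img, c(5L, 5L)),
                 noise_feature_oracle(img, 5, 5), tolerance = 1e-12)
  }
})

test_that("noisier frames yield larger noise features on average", {
  base <- matrix(rep(seq(20, 220, length.out = 24), 24), 24, 24)
  fn <- function(sd, s) {
    f <- local_seed(7000 + s, pmin(pmax(round(base + rnorm(576, sd = sd)), 0), 255))
    compute_noise_feature(f)
  }
  lo <- mean(vapply(1:20, function(s) fn(5, s), numeric(1)))
  hi <- mean(vapply(1:20, function(s) fn(15, s + 100), numeric(1)))
  expect_gt(hi, lo)
})

test_that("feature extraction is deterministic and honors the degenerate policy", {
  ph <- small_phantom()
  ref <- ph$reference
  fv1 <- extract_features(render_contact(ph, 6, seed = 9), ref)
  fv2 <- extract_features(render_contact(ph, 6, seed = 9), ref)
  expect_identical(fv1, fv2)

  # reference vs itself: gate fires
  fvr <- extract_features(ref, ref)
  expect_identical(fvr$contact, 1L)
  expect_equal(fvr$correlation_raw, 1.0)

  # all-zero frame vs reference: degenerate => gate fires, no_signal set
  fz <- extract_features(matrix(0, nrow(ref), ncol(ref)), ref)
  expect_identical(fz$contact, 1L)
  expect_true(is.na(fz$correlation_raw))
  expect_true(fz$no_signal)
})

test_that("feature table covers every frame with the documented columns", {
  ph <- small_phantom()
  frames <- list(a = render_contact(ph, 5, seed = 1),
                 b = render_no_contact(ph, seed = 2))
  tab <- extract_features_table(frames, ph$reference)
  expect_identical(tab$frame_id, c("a", "b"))
  expect_identical(names(tab), c("frame_id", "correlation_raw", "contact",
                                 "compression", "noise", "no_signal"))
  expect_identical(tab$contact, c(0L, 1L))
})
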