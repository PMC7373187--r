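test_that("constant per-row offsets vanish under order-0 flattening", {
  h <- matrix(rep(seq(-2, 2, length.out = 64), 64), 64, 64)
  out <- flatten_scanlines(height_map(h, 2), order = 0)
  expect_lt(max(abs(out$heights)), 1e-10)
})

test_that("flattening removes known polynomial backgrounds exactly", {
  # molecule-free map: per-row quadratic backgrounds, sequential 0,1,2 pass
  set.seed(1)
  n <- 128
  xn <- seq(-1, 1, length.out = n)
  h <- t(vapply(seq_len(n), function(r) {
    cf <- rnorm(3, 0, 0.3)
    cf[1] + cf[2] * xn + cf[3] * xn^2
  }, numeric(n)))
  m <- height_map(h, 2)
  out <- flatten_image(m)
  expect_lt(max(abs(out$heights)), 1e-8)
  # idempotence on the already-flat result
  out2 <- flatten_image(out)
  expect_lt(sqrt(mean((out2$heights - out$heights)^2)), 1e-9)
})

test_that("masked fitting recovers injected ramps despite molecules", {
  # rendered chain + per-row linear ramps with known coefficients
  sc <- make_scene(list(straight_chain(c(60, 130), 0.7, 100)), NULL, 500)
  base <- render_height_map(sc, render_params(pixel_size_nm = 2,
                                              noise_sigma = 0.08,
                                              background_coeff_scale = 0,
                                              seed = 2))
  n <- nrow(base$heights)
  xn <- seq(-1, 1, length.out = n)
  set.seed(3)
  cf <- cbind(rnorm(n, 0, 0.5), rnorm(n, 0, 0.5))
  ramp <- cf[, 1] + cf[, 2] %o% xn
  m <- height_map(base$heights + ramp, 2)
  out <- flatten_scanlines(flatten_scanlines(m, 0), 1)
  removed <- m$heights - out$heights
  # recovered per-row slope and offset within 2% of injected (RMS, relative
  # to the injected coefficient scale)
  rec <- t(apply(removed, 1, function(y) coef(lm(y ~ xn))))
  expect_lt(sqrt(mean((rec[, 2] - cf[, 2])^2)) / 0.5, 0.02)
  # background-pixel residual noise not inflated
  bg <- base$heights < 0.05
  expect_lt(sqrt(mean(out$heights[bg]^2)), 1.1 * 0.08)
})

test_that("output minus input is a per-scanline polynomial of the order", {
  stack <- default_stack(1)
  m <- stack$map
  for (ord in 0:2) {
    out <- flatten_scanlines(m, ord)
    diffm <- m$heights - out$heights
    xn <- seq(-1, 1, length.out = ncol(diffm))
    X <- cbind(1, poly(xn, degree = max(ord, 1), raw = TRUE))[, 1:(ord + 1),
                                                             drop = FALSE]
    resid <- diffm - t(X %*% solve(crossprod(X), crossprod(X, t(diffm))))
    expect_lt(max(abs(resid)), 1e-8)
  }
})

test_that("junction heights are preserved through flattening", {
  # diagonal crossing: neither molecule lies along a single scanline
  sc <- crossing_scene(at = c(249, 249), protein_bound = TRUE,
                       diagonal = TRUE)
  p0 <- render_params(pixel_size_nm = 2, noise_sigma = 0,
                      background_coeff_scale = 0.3, seed = 6)
  hm <- render_height_map(sc, p0)
  flat <- flatten_image(hm)
  res <- analyze_image(flat, comps = label_components(flat, 0.3))
  expect_equal(nrow(res$junctions), 1)
  expect_equal(res$junctions$height_diff_nm, 1.36, tolerance = 0.02)
})

test_that("narrow scanlines fall back to order zero with a warning", {
  m <- height_map(matrix(rnorm(8), 4, 2), 1)
  expect_warning(flatten_scanlines(m, 2), "order-0")
})

test_that("flattening parameters are validated", {
  m <- height_map(matrix(0, 4, 4), 1)
  expect_error(flatten_scanlines(m, 3), "order")
  expect_error(flatten_scanlines(m, 1, n_iter = 0))
  expect_error(flatten_scanlines(m, 1, mask_k = 0))
})
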