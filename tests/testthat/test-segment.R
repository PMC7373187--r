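test_that("background statistics: degenerate, pure-noise and sparse cases", {
  z <- height_map(matrix(0, 32, 32), 1)
  s <- estimate_background_stats(z)
  expect_equal(s$median_nm, 0)
  expect_equal(s$robust_sigma_nm, 0)
  expect_true(s$degenerate)

  set.seed(4)
  noise <- matrix(rnorm(512^2, 0, 0.08), 512, 512)
  sn <- estimate_background_stats(height_map(noise, 2))
  expect_equal(sn$robust_sigma_nm, 0.08, tolerance = 0.005 / 0.08)

  # sparse molecules (< 5% area) barely move the median: render the same
  # noise realization with and without molecules
  p <- render_params(noise_sigma = 0.08, background_coeff_scale = 0, seed = 8)
  sc <- place_molecules(5, 1000, seed = 2,
                        bridging = bridging_config(0, 0, 0))
  with_mol <- render_height_map(sc, p)
  no_mol <- render_height_map(make_scene(list(), field_size_nm = 1000), p)
  expect_lt(mean(with_mol$heights > 0.3), 0.05)
  expect_lt(abs(estimate_background_stats(with_mol)$median_nm -
                estimate_background_stats(no_mol)$median_nm), 0.01)
})

test_that("automatic threshold is median + k robust sigmas", {
  set.seed(5)
  m <- height_map(matrix(rnorm(256^2, 0.2, 0.08), 256, 256), 2)
  s <- estimate_background_stats(m)
  expect_equal(choose_threshold(m, 3), s$median_nm + 3 * s$robust_sigma_nm)
  expect_error(choose_threshold(m, 0), "> 0")
})

test_that("component labelling is 8-connected with an area filter", {
  # empty mask
  m <- height_map(matrix(0, 64, 64), 2)
  expect_equal(nrow(label_components(m, 0.5, 1)$components), 0)
  # two disjoint straight chains -> 2 components
  sc <- make_scene(list(straight_chain(c(60, 100), 0, 80, 2, 1),
                        straight_chain(c(60, 300), 0, 80, 2, 2)), NULL, 500)
  hm <- render_height_map(sc, render_params(pixel_size_nm = 2,
                                            noise_sigma = 0,
                                            background_coeff_scale = 0))
  expect_equal(nrow(label_components(hm, 0.3, 30)$components), 2)
  # crossing chains merge into 1 component
  hx <- render_height_map(crossing_scene(), render_params(
    pixel_size_nm = 2, noise_sigma = 0, background_coeff_scale = 0))
  expect_equal(nrow(label_components(hx, 0.3, 30)$components), 1)
  # a diagonal single-pixel line stays one component (8-connectivity)
  d <- matrix(0, 20, 20); diag(d) <- 1
  cs <- label_components(height_map(d, 1), 0.5, 5)
  expect_equal(nrow(cs$components), 1)
})

test_that("capture is monotone non-increasing along a threshold sweep", {
  stack <- default_stack(1)
  fracs <- vapply(seq(0.1, 0.9, by = 0.1), function(thr) {
    capture_fraction(stack$scene,
                     label_components(stack$flat, thr, 30))$fraction
  }, numeric(1))
  expect_true(all(diff(fracs) <= 1e-12))
  # k -> very large gives an empty mask and zero capture
  cs <- label_components(stack$flat, choose_threshold(stack$flat, 1e6), 30)
  expect_equal(nrow(cs$components), 0)
  expect_equal(capture_fraction(stack$scene, cs)$fraction, 0)
})

test_that("zero-noise maps threshold at zero and capture everything", {
  sc <- make_scene(list(straight_chain(c(60, 130), 0.4, 100)), NULL, 500)
  hm <- render_height_map(sc, render_params(pixel_size_nm = 2,
                                            noise_sigma = 0,
                                            background_coeff_scale = 0))
  expect_equal(choose_threshold(hm, 3), 0)
  cap <- capture_fraction(sc, label_components(hm, choose_threshold(hm, 3), 30))
  expect_equal(cap$fraction, 1)
})

test_that("smoothing preserves ridge structure while damping noise", {
  stack <- default_stack(1)
  sm <- smooth_height_map(stack$flat, 1)
  expect_equal(dim(sm$heights), dim(stack$flat$heights))
  # noise suppressed on background
  expect_lt(stats::mad(sm$heights), stats::mad(stack$flat$heights))
})
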