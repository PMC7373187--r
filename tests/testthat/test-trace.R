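bar_mask <- function(nr, nc, rows, cols) {
  m <- matrix(FALSE, nr, nc)
  m[rows, cols] <- TRUE
  m
}

test_that("thinning preserves simple shapes and their topology", {
  # a straight 3-px-wide bar thins to a line with 2 endpoints, no branches
  m <- bar_mask(20, 120, 9:11, 11:110)
  g <- skeletonize_component(m, 1)
  expect_equal(sum(g$nodes$kind == "endpoint"), 2)
  expect_equal(sum(g$nodes$kind == "branch"), 0)
  expect_equal(nrow(g$edges), 1)
  # an X of two crossing bars: 4 endpoints, one merged degree-4 junction
  x <- bar_mask(60, 60, 29:31, 6:55) | t(bar_mask(60, 60, 29:31, 6:55))
  gx <- skeletonize_component(x, 1)
  expect_equal(sum(gx$nodes$kind == "endpoint"), 4)
  jx <- detect_junctions(gx)
  expect_equal(nrow(jx), 1)
  expect_gte(jx$degree, 4)
  expect_equal(jx$row, 30, tolerance = 2)
  # a T: 3 endpoints, one degree-3 junction
  tt <- bar_mask(60, 60, 29:31, 6:55) | bar_mask(60, 60, 31:55, 29:31)
  gt <- skeletonize_component(tt, 1)
  expect_equal(sum(gt$nodes$kind == "endpoint"), 3)
  jt <- detect_junctions(gt)
  expect_equal(nrow(jt), 1)
  expect_gte(jt$degree, 3)
})

test_that("a ring component becomes a flagged closed loop", {
  m <- matrix(FALSE, 40, 40)
  th <- seq(0, 2 * pi, length.out = 400)
  for (i in seq_along(th)) {
    m[round(20 + 12 * sin(th[i])), round(20 + 12 * cos(th[i]))] <- TRUE
    m[round(20 + 13 * sin(th[i])), round(20 + 13 * cos(th[i]))] <- TRUE
  }
  g <- skeletonize_component(m, 1)
  expect_true(any(g$edges$closed_loop))
  expect_equal(sum(g$nodes$kind == "endpoint"), 0)
})

test_that("contour length uses the 1 / sqrt(2) step metric on clean paths", {
  # horizontal 1-px path of 100 pixels at 2 nm/px: 99 steps * 2 nm
  m <- bar_mask(10, 110, 5, 6:105)
  g <- skeletonize_component(m, 1)
  expect_equal(contour_length_nm(g, 2), 198, tolerance = 1e-9)
  # 45-degree diagonal path of 100 pixels: 99 * sqrt(2) * 2 nm
  d <- matrix(FALSE, 120, 120)
  d[cbind(6:105, 6:105)] <- TRUE
  gd <- skeletonize_component(d, 1)
  expect_equal(contour_length_nm(gd, 2), 99 * sqrt(2) * 2, tolerance = 1e-9)
})

test_that("traced lengths of rendered molecules recover the true contour", {
  # noise-free 1-kbp worm-like chains; thinning/pixelation bias stays small
  lens <- c()
  for (sd in 1:60) {
    sc <- place_molecules(1, 1000, seed = sd,
                          bridging = bridging_config(0, 0, 0))
    if (sc$chains[[1]]$clipped || nrow(sc$junctions)) next
    hm <- render_height_map(sc, render_params(noise_sigma = 0,
                                              background_coeff_scale = 0))
    res <- analyze_image(hm, comps = label_components(hm, 0.2, 30))
    m <- res$molecules[!res$molecules$clipped & res$molecules$n_junctions == 0, ]
    lens <- c(lens, m$contour_length_nm)
    if (length(lens) >= 25) break
  }
  expect_gte(length(lens), 20)
  expect_equal(mean(lens), 340, tolerance = 0.15)
})

test_that("skeletons of rendered chains track the true polyline", {
  sc <- place_molecules(1, 1000, seed = 3,
                        bridging = bridging_config(0, 0, 0))
  hm <- render_height_map(sc, render_params(noise_sigma = 0,
                                            background_coeff_scale = 0))
  comps <- label_components(hm, 0.2, 30)
  g <- skeletonize_component(comps$label_grid == 1, 1)
  px <- hm$pixel_size_nm
  v <- sc$chains[[1]]$vertices
  # every skeleton pixel lies within 2 px of the polyline
  d_to_chain <- vapply(seq_len(nrow(g$pixels)), function(i) {
    p <- c(g$pixels[i, 2], g$pixels[i, 1]) * px - px / 2
    min(sqrt((v[, 1] - p[1])^2 + (v[, 2] - p[2])^2))
  }, numeric(1))
  expect_lt(max(d_to_chain) / px, 2)
})

test_that("junction classification follows the endpoint/length rules", {
  fake_graph <- function(n_end, length_px, loop = FALSE, n_branch = 1) {
    nodes <- data.frame(
      id = seq_len(n_end + n_branch),
      row = 1, col = 1,
      kind = c(rep("endpoint", n_end), rep("branch", n_branch)),
      degree = 1L)
    edges <- data.frame(from = 1, to = 1, length_px = length_px,
                        n_px = round(length_px), closed_loop = loop)
    structure(list(nodes = nodes, edges = edges,
                   pixels = cbind(row = 1, col = 1), component_id = 1L,
                   r_merge = 4, total_length_px = length_px),
              class = "skeleton_graph")
  }
  L0 <- 340
  expect_equal(unname(classify_junction(fake_graph(2, 0.95 * L0), L0,
                                        pixel_size_nm = 1)[1]), "intra")
  expect_equal(unname(classify_junction(fake_graph(4, 2.05 * L0), L0,
                                        pixel_size_nm = 1)[1]), "inter")
  expect_equal(unname(classify_junction(fake_graph(2, 3.2 * L0), L0,
                                        pixel_size_nm = 1)[1]), "ambiguous")
  expect_equal(unname(classify_junction(fake_graph(0, L0, loop = TRUE), L0,
                                        pixel_size_nm = 1)[1]), "intra")
})

test_that("noise-free junction height differences match the injected values", {
  p0 <- render_params(pixel_size_nm = 2, noise_sigma = 0,
                      background_coeff_scale = 0)
  for (pb in c(FALSE, TRUE)) {
    hm <- render_height_map(crossing_scene(protein_bound = pb), p0)
    res <- analyze_image(hm, comps = label_components(hm, 0.3, 30))
    expect_equal(nrow(res$junctions), 1)
    expect_equal(res$junctions$height_diff_nm, 0.86 + 0.5 * pb,
                 tolerance = 0.02)
  }
})

test_that("noisy height-difference ensembles recover the injected excess", {
  hd <- collect_height_diffs(1, n_target = 30)
  expect_gte(length(hd), 30)
  sem <- sd(hd) / sqrt(length(hd))
  expect_lt(abs(mean(hd) - 1.36), 2 * sem)
})

test_that("junction counts are invariant under rotation and flattening", {
  stack <- default_stack(2)
  n0 <- nrow(stack$res$junctions)
  rot <- height_map(t(stack$flat$heights)[ncol(stack$flat$heights):1, ],
                    stack$flat$pixel_size_nm)
  # thinning sub-iterations are direction-ordered, so a 90-degree rotation
  # may shift one borderline region in or out
  expect_lte(abs(nrow(analyze_image(rot)$junctions) - n0), 1)
  # flattening an already-flat image does not change the count
  reflat <- flatten_image(stack$flat)
  expect_equal(nrow(analyze_image(reflat)$junctions), n0)
})

test_that("junctions are skipped when a component has no free DNA", {
  sc <- crossing_scene(at = c(49, 49), field_size_nm = 100, n_seg = 20)
  hm <- render_height_map(sc, render_params(pixel_size_nm = 2,
                                            noise_sigma = 0,
                                            background_coeff_scale = 0))
  comps <- label_components(hm, 0.3, 10)
  g <- skeletonize_component(comps$label_grid == 1, 1)
  j <- detect_junction_regions(hm, g)
  expect_warning(
    out <- junction_height_difference(hm, j[1, ], g, excl_r = 30,
                                      exclude = j),
    "insufficient free DNA")
  expect_true(is.na(out))
})
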