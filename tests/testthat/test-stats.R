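mol_df <- function(n, n_junc = integer(n), class = "intra",
                   est = rep(1L, n)) {
  data.frame(component_id = seq_len(n), n_px = rep(100, n),
             n_endpoints = rep(2, n), contour_length_nm = rep(340, n),
             n_junctions = n_junc, class = rep_len(class, n),
             est_n_molecules = est, clipped = rep(FALSE, n))
}

junc_df <- function(component_id, jtype = "intra", hd = 1) {
  n <- length(component_id)
  data.frame(component_id = component_id, row = rep(1, n), col = rep(1, n),
             x_nm = rep(1, n), y_nm = rep(1, n), degree = rep(4L, n),
             jtype = rep_len(jtype, n), height_diff_nm = rep_len(hd, n))
}

test_that("sample summaries compute counts, percentages and mean +/- SEM", {
  s0 <- summarize_sample(mol_df(10), junc_df(integer(0)), "dna", "high")
  expect_equal(s0$pct_molecules_with_junction, 0)
  expect_true(is.na(s0$mean_height_diff))

  s <- summarize_sample(mol_df(4, n_junc = rep(1L, 4)),
                        junc_df(1:4, hd = c(1, 2, 3, 4)), "gapr", "high")
  expect_equal(s$mean_height_diff, 2.5)
  expect_equal(s$sem_height_diff, 0.6455, tolerance = 1e-4)
  expect_equal(s$sem_height_diff, sqrt(5 / 3) / 2, tolerance = 1e-12)

  s2 <- summarize_sample(mol_df(151, n_junc = c(rep(1L, 17), rep(0L, 134))),
                         junc_df(1:17), "dna", "high")
  expect_equal(s2$pct_molecules_with_junction, 100 * 17 / 151,
               tolerance = 1e-12)
  expect_equal(round(s2$pct_molecules_with_junction, 2), 11.26)

  expect_error(summarize_sample(mol_df(0), junc_df(integer(0))), "zero")
})

test_that("summaries merge exactly (pooled, not averaged)", {
  set.seed(7)
  hd <- rnorm(20, 1.2, 0.3)
  whole <- summarize_sample(mol_df(30, n_junc = c(rep(1L, 20), rep(0L, 10))),
                            junc_df(1:20, hd = hd), "gapr", "high")
  half1 <- summarize_sample(mol_df(30, c(rep(1L, 8), rep(0L, 22)))[1:15, ],
                            junc_df(1:8, hd = hd[1:8]), "gapr", "high")
  half2 <- summarize_sample(mol_df(30, c(rep(0L, 15), rep(1L, 12), rep(0L, 3)))[16:30, ],
                            junc_df(16:27, hd = hd[9:20]), "gapr", "high")
  merged <- merge_summaries(half1, half2)
  expect_equal(merged$n_molecules, whole$n_molecules)
  expect_equal(merged$n_junctions, whole$n_junctions)
  expect_equal(merged$mean_height_diff, whole$mean_height_diff,
               tolerance = 1e-12)
  expect_equal(merged$sem_height_diff, whole$sem_height_diff,
               tolerance = 1e-12)
})

test_that("the pooled t statistic matches the closed form and stats::t.test", {
  r <- unpaired_t_test(c(1, 2, 3), c(2, 3, 4))
  expect_equal(r$t, -1.2247, tolerance = 1e-4)
  expect_equal(r$df, 4)
  expect_equal(r$p, 0.2878, tolerance = 1e-3)

  set.seed(11)
  for (i in 1:10) {
    a <- rnorm(sample(3:12, 1)); b <- rnorm(sample(3:12, 1), 0.5)
    r <- unpaired_t_test(a, b)
    ref <- stats::t.test(a, b, var.equal = TRUE)
    expect_equal(r$t, unname(ref$statistic), tolerance = 1e-12)
    expect_equal(r$df, unname(ref$parameter))
    expect_equal(r$p, ref$p.value, tolerance = 1e-12)
  }
})

test_that("degenerate t-test inputs follow the documented contract", {
  same <- unpaired_t_test(c(2, 2, 2), c(2, 2, 2))
  expect_equal(same$t, 0)
  expect_equal(same$p, 1)
  expect_true(same$degenerate)
  apart <- unpaired_t_test(c(1, 1, 1), c(2, 2, 2))
  expect_equal(apart$p, 0)
  expect_true(is.infinite(apart$t))
  expect_true(apart$degenerate)
  expect_error(unpaired_t_test(1, c(1, 2)), "at least 2")
})

test_that("the t-test p value agrees with an exact permutation oracle", {
  # all C(8,4) = 70 relabellings enumerated; moderate-p regime where the
  # Student approximation is close to the exact permutation distribution
  a <- c(0.3, 1.1, 0.8, 1.6)
  b <- c(1.2, 1.9, 1.4, 2.3)
  r <- unpaired_t_test(a, b)
  pool <- c(a, b)
  combs <- utils::combn(8, 4)
  t_of <- function(ia) {
    x <- pool[ia]; y <- pool[-ia]
    sp2 <- (var(x) * 3 + var(y) * 3) / 6
    (mean(x) - mean(y)) / sqrt(sp2 * (1 / 4 + 1 / 4))
  }
  tall <- apply(combs, 2, t_of)
  p_perm <- mean(abs(tall) >= abs(r$t) - 1e-12)
  expect_lt(abs(r$p - p_perm), 0.06)
})

test_that("density fold changes reproduce the reference arithmetic", {
  mk <- function(pct_inter, pct_intra) {
    s <- summarize_sample(mol_df(10), junc_df(integer(0)), "gapr", "low")
    s$pct_inter <- pct_inter; s$pct_intra <- pct_intra
    s
  }
  fc <- density_fold_change(mk(0.4, 30), mk(10, 20))
  expect_equal(fc$fold_inter, 25)
  expect_equal(fc$fold_intra, 1.5)
  expect_false(fc$flagged)
  same <- density_fold_change(mk(5, 5), mk(5, 5))
  expect_equal(same$fold_inter, 1)
  expect_equal(same$fold_intra, 1)
  zero <- density_fold_change(mk(0, 10), mk(5, 10))
  expect_true(is.infinite(zero$fold_inter))
  expect_true(zero$flagged)
})
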