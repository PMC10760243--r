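test_that("cohort generation is deterministic in the seed and counts labels", {
  sp <- cohort_spec(c(AD = 3, MCI = 2, CN = 3), grid_dims = c(12, 12, 12),
                    seed = 5)
  a <- generate_cohort(sp)
  b <- generate_cohort(sp)
  expect_identical(a$subjects, b$subjects)
  expect_identical(table(a$table$label),
                   table(factor(rep(c("AD", "CN", "MCI"), c(3, 3, 2)))))
  d <- generate_cohort(cohort_spec(c(AD = 3, MCI = 2, CN = 3),
                                   grid_dims = c(12, 12, 12), seed = 6))
  expect_false(identical(a$subjects[[1]]$smri$values,
                         d$subjects[[1]]$smri$values))

  co2 <- generate_cohort(cohort_spec(c(AD = 10, MCI = 0, CN = 10),
                                     grid_dims = c(10, 10, 10)))
  expect_identical(nrow(co2$table), 20L)
  expect_identical(sort(unique(co2$table$label)), c("AD", "CN"))
})

test_that("generated volumes are finite and share the cohort grid", {
  co <- generate_cohort(cohort_spec(c(AD = 2, MCI = 1, CN = 2),
                                    grid_dims = c(10, 12, 14)))
  for (s in co$subjects) {
    expect_true(all(is.finite(s$smri$values)))
    expect_true(all(is.finite(s$icn_stack$values)))
    expect_true(grid_equal(s$smri$grid, co$spec$grid))
    expect_true(grid_equal(s$icn_stack$grid, co$spec$grid))
    expect_identical(s$icn_stack$K, co$spec$k_components)
  }
  expect_error(cohort_spec(c(AD = 2, MCI = 0, CN = 2),
                           grid_dims = c(6, 6, 6)), "grid too small")
})

test_that("with zero effects the designated blobs carry no class signal", {
  # Monte-Carlo calibration of the null generator: a two-sample t-test on the
  # designated-blob gray-matter mean should be non-significant at alpha 0.01
  # in >= 95% of repeated generations
  reps <- 20
  pvals <- vapply(seq_len(reps), function(r) {
    co <- generate_cohort(cohort_spec(c(AD = 20, MCI = 0, CN = 20),
                                      grid_dims = c(12, 12, 12),
                                      gm_effect = 0, icn_effect = 0,
                                      seed = 100 + r))
    bl <- neurofuse:::blob_on_grid(c(12, 12, 12),
                                   co$templates$atrophy[[1]]$center,
                                   rep(co$templates$atrophy[[1]]$sigma, 3), 1)
    sel <- bl > 0.5
    bm <- vapply(co$subjects, function(s) mean(s$smri$values[sel]), 0)
    lab <- co$table$label
    stats::t.test(bm[lab == "AD"], bm[lab == "CN"])$p.value
  }, 0)
  expect_gte(mean(pvals > 0.01), 0.95)
})

test_that("strong effects separate classes on the fused interaction channel", {
  co <- generate_cohort(cohort_spec(c(AD = 50, MCI = 0, CN = 50),
                                    grid_dims = c(24, 24, 24),
                                    gm_effect = 0.4, icn_effect = 1.0,
                                    seed = 9))
  inp <- build_inputs(co, "fused", "abs_min_icn")
  t1 <- co$templates$atrophy[[1]]; t2 <- co$templates$atrophy[[2]]
  sel <- neurofuse:::blob_on_grid(c(24, 24, 24), t1$center,
                                  rep(t1$sigma, 3), 1) > 0.5 |
    neurofuse:::blob_on_grid(c(24, 24, 24), t2$center,
                             rep(t2$sigma, 3), 1) > 0.5
  bm <- vapply(inp, function(i) mean(i$channels[[2]]$values[sel]), 0)
  lab <- co$table$label
  thr <- mean(tapply(bm, lab, mean))
  acc <- mean((bm > thr) == (lab == "CN"))
  expect_gte(acc, 0.95)
})

test_that("the class-shifted component is recoverable from the argmax diagnostic", {
  co <- generate_cohort(cohort_spec(c(AD = 5, MCI = 0, CN = 5),
                                    grid_dims = c(24, 24, 24),
                                    gm_effect = 0.4, icn_effect = 1.0,
                                    seed = 13))
  t1 <- co$templates$atrophy[[1]]
  sel <- neurofuse:::blob_on_grid(c(24, 24, 24), t1$center,
                                  rep(t1$sigma, 3), 1) > 0.6
  hit <- vapply(co$subjects, function(s) {
    am <- attr(project_max(s$icn_stack, return_argmax = TRUE), "argmax")
    mean(am[sel] == co$templates$designated[1])
  }, 0)
  expect_gte(mean(hit), 0.9)
})

test_that("synthetic time series scale linearly and reproduce from the seed", {
  co <- generate_cohort(cohort_spec(c(AD = 1, MCI = 0, CN = 1),
                                    grid_dims = c(8, 8, 8)))
  s <- co$subjects[[1]]
  ts1 <- generate_timeseries(s, T = 64, tr_seconds = 2, amp_scale = 1,
                             noise_sd = 0)
  ts2 <- generate_timeseries(s, T = 64, tr_seconds = 2, amp_scale = 2,
                             noise_sd = 0)
  a1 <- compute_alff(ts1)$values
  a2 <- compute_alff(ts2)$values
  nz <- a1 > 1e-6
  expect_true(any(nz))
  expect_equal(a2[nz], 2 * a1[nz], tolerance = 1e-9)
  expect_identical(generate_timeseries(s, T = 64, tr_seconds = 2)$values,
                   generate_timeseries(s, T = 64, tr_seconds = 2)$values)
  expect_error(generate_timeseries(s, T = 32, tr_seconds = 0.05), "infeasible")
})

test_that("zero-amplitude series give fALFF near the in-band bin fraction", {
  co <- generate_cohort(cohort_spec(c(AD = 1, MCI = 0, CN = 1),
                                    grid_dims = c(10, 10, 10)))
  T <- 96; tr <- 2
  ts <- generate_timeseries(co$subjects[[1]], T = T, tr_seconds = tr,
                            amp_scale = 0, noise_sd = 1)
  f <- compute_falff(ts)$values
  freqs <- (1:(T %/% 2)) / (T * tr)
  frac <- mean(freqs >= 0.01 & freqs <= 0.08)
  expect_lt(abs(mean(f) - frac) / frac, 0.15)
})

test_that("cohorts round-trip through NIfTI + CSV on disk", {
  co <- generate_cohort(cohort_spec(c(AD = 2, MCI = 0, CN = 1),
                                    grid_dims = c(8, 8, 8)))
  dir <- withr::local_tempdir()
  tab_path <- write_cohort(co, dir)
  tab <- load_subject_table(tab_path)
  expect_identical(nrow(tab), 3L)
  expect_identical(unname(attr(tab, "n_total")), 3L)
  s1 <- read_volume(tab$smri_path[1])
  expect_equal(s1$values, co$subjects[[tab$subject_id[1]]]$smri$values,
               tolerance = 1e-7)
  st <- read_volume(tab$icn_stack_path[1])
  expect_identical(st$K, co$spec$k_components)
  expect_error(suppressWarnings(load_subject_table(tempfile())),
               "cannot open")
})
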