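test_that("phase identification labels the low-marker crossing as raft", {
  g <- generate_gpmv_linescan(3, noise_sd = 0, seed = 2)
  ph <- identify_phases(g)
  expect_equal(ph$raft, g$truth$raft_position)
  expect_equal(ph$nonraft, g$truth$nonraft_position)
  expect_lt(ph$raft_marker, ph$nonraft_marker)
})

test_that("profiles without two prominent peaks are rejected and countable", {
  flat <- list(positions = 1:32, construct_channel = rep(10, 32),
               marker_channel = rep(5, 32))
  expect_error(identify_phases(flat), class = "rush_vesicle_rejected")
  one_peak <- generate_gpmv_linescan(0, background = 10, amplitude = 100,
                                     noise_sd = 0, seed = 1)
  one_peak$marker_channel <- rep(10, length(one_peak$positions))
  expect_error(identify_phases(one_peak), class = "rush_vesicle_rejected")
  expect_error(identify_phases(list(positions = 1:8, construct_channel = 1:8,
                                    marker_channel = 1:8)), ">= 16")
})

test_that("phase assignment is accurate at realistic noise and marker contrast", {
  correct <- 0L
  for (i in 1:200) {
    g <- generate_gpmv_linescan(1.8, background = 50, amplitude = 50,
                                noise_sd = 5, marker_contrast = 4, seed = 1000 + i)
    ph <- tryCatch(identify_phases(g), rush_vesicle_rejected = function(e) NULL)
    # assignment is correct when the raft label lands on the raft crossing
    # (peak positions may jitter by a point or two under noise)
    if (!is.null(ph) &&
        abs(ph$raft - g$truth$raft_position) <
          abs(ph$raft - g$truth$nonraft_position)) correct <- correct + 1L
  }
  expect_gte(correct, 190L)
})

test_that("partition coefficient is the background-subtracted peak ratio", {
  g <- generate_gpmv_linescan(3, background = 50, amplitude = 50,
                              noise_sd = 0, seed = 3)
  expect_equal(compute_kp(g, background = 50), 3, tolerance = 1e-6)
  expect_equal(compute_kp(g), 3, tolerance = 0.02)  # estimated background
  g1 <- generate_gpmv_linescan(1, noise_sd = 0, seed = 3)
  expect_equal(compute_kp(g1, background = 50), 1, tolerance = 1e-6)
})

test_that("partition coefficient is invariant to joint affine intensity rescaling", {
  g <- generate_gpmv_linescan(1.8, noise_sd = 0, seed = 4)
  kp0 <- compute_kp(g, background = 50)
  g2 <- g
  g2$construct_channel <- 3.7 * g$construct_channel + 12
  g2$marker_channel <- 3.7 * g$marker_channel + 12
  expect_equal(compute_kp(g2, background = 3.7 * 50 + 12), kp0, tolerance = 1e-9)
})

test_that("raft-depleted constructs round-trip through the quantification", {
  kps <- vapply(1:100, function(i) {
    g <- generate_gpmv_linescan(0.4, background = 50, amplitude = 50,
                                noise_sd = 5, seed = 4000 + i)
    tryCatch(compute_kp(g), rush_vesicle_rejected = function(e) NA_real_)
  }, numeric(1))
  expect_lt(abs(mean(kps, na.rm = TRUE) / 0.4 - 1), 0.05)
})

test_that("partition summaries use experiments, not vesicles, as replicates", {
  m <- summarize_kp(c(2.0, 2.0, 2.2), experiment = c("e1", "e1", "e2"))
  expect_equal(m$grand_mean, 2.1)
  expect_equal(m$n_experiments, 2L)
  # pooled vesicles would give a different (wrong) grand mean
  unequal <- summarize_kp(c(rep(2, 10), 3), experiment = c(rep("e1", 10), "e2"))
  expect_equal(unequal$grand_mean, 2.5)
})

test_that("group comparison is a Welch test on experiment means", {
  a <- summarize_kp(rep(c(1.7, 1.8, 1.9), each = 5),
                    experiment = rep(1:3, each = 5))
  cmp_same <- compare_kp_groups(a, a)
  expect_equal(cmp_same$statistic, 0)
  expect_equal(cmp_same$p_value, 1)
  b <- summarize_kp(rep(c(0.35, 0.4, 0.45), each = 5),
                    experiment = rep(1:3, each = 5))
  cmp <- compare_kp_groups(a, b)
  expect_lt(cmp$p_value, 0.01)
  single <- summarize_kp(c(1, 1.1), experiment = c("e1", "e1"))
  expect_error(compare_kp_groups(a, single), ">= 2")
})

test_that("raft-affinity contrast is detected reliably at experiment scale", {
  reject <- 0L
  n_rep <- 100L
  for (i in seq_len(n_rep)) {
    measure_group <- function(kp_true, offset) {
      kp <- numeric(0); expt <- character(0)
      for (e in 1:3) {
        v <- vapply(1:15, function(j) {
          g <- generate_gpmv_linescan(kp_true, noise_sd = 5,
                                      seed = offset + e * 100 + j)
          tryCatch(compute_kp(g), rush_vesicle_rejected = function(err) NA_real_)
        }, numeric(1))
        v <- v[is.finite(v)]
        kp <- c(kp, v); expt <- c(expt, rep(paste0("e", e), length(v)))
      }
      summarize_kp(kp, expt)
    }
    ga <- measure_group(1.8, 10000 + i * 1000)
    gb <- measure_group(0.4, 20000 + i * 1000)
    if (compare_kp_groups(ga, gb)$p_value < 0.01) reject <- reject + 1L
  }
  expect_gte(reject, round(0.95 * n_rep))
})

test_that("Pearson colocalization behaves on exact and masked inputs", {
  a <- matrix(stats::rnorm(400, 50, 10), 20, 20)
  expect_equal(pearson_coloc(a, a), 1)
  expect_equal(pearson_coloc(a, -a + 100), -1)
  # invariant to per-channel positive affine transforms
  b <- matrix(stats::rnorm(400, 50, 10), 20, 20)
  expect_equal(pearson_coloc(a, b), pearson_coloc(2 * a + 5, 0.3 * b + 50))
  expect_error(pearson_coloc(a, matrix(1, 20, 20)), "zero variance")
  # the mask really restricts the computation
  pair <- generate_coloc_pair(0.9, dim = c(40, 40), seed = 6)
  r_in <- pearson_coloc(pair$image_a, pair$image_b, pair$mask)
  r_all <- pearson_coloc(pair$image_a, pair$image_b)
  expect_equal(r_in, 0.9, tolerance = 0.05)
  expect_false(isTRUE(all.equal(r_in, r_all)))
})

test_that("organelle fraction measures in-mask share of background-subtracted signal", {
  img <- matrix(0, 10, 10)
  mask <- matrix(FALSE, 10, 10); mask[3:5, 3:5] <- TRUE
  img[mask] <- 7
  expect_equal(organelle_fraction(img, mask), 1)
  uniform <- matrix(5, 20, 20)
  quarter <- matrix(FALSE, 20, 20); quarter[1:10, 1:10] <- TRUE
  expect_equal(organelle_fraction(uniform, quarter), 0.25)
  # monotone in mask coverage
  bigger <- quarter; bigger[1:10, 11:15] <- TRUE
  expect_gt(organelle_fraction(uniform, bigger),
            organelle_fraction(uniform, quarter))
  expect_error(organelle_fraction(matrix(0, 5, 5), matrix(TRUE, 5, 5)),
               "zero total")
})

test_that("rendered Golgi images round-trip the generating fraction", {
  p <- default_truth_params()
  ct <- default_construct_table()
  times <- c(0, 0.5, 1, 2, 4)
  fr <- model_fractions(p, ct[["LAT-allL"]], "Golgi", times)
  for (i in seq_along(times)) {
    scene <- render_golgi_image(fr$golgi_fraction[i], noise_sd = 2,
                                seed = 50 + i)
    measured <- organelle_fraction(scene$image, scene$golgi_mask,
                                   background = scene$background,
                                   cell_mask = scene$cell_mask)
    expect_lt(abs(measured - fr$golgi_fraction[i]), 0.03)
  }
})
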