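test_that("the default design reproduces the reference bag/scan bookkeeping", {
  d <- default_design()
  bags <- d$bags
  expect_equal(nrow(bags), 135)
  expect_equal(nrow(bags) * d$scans_per_bag, 810)
  counts <- table(bags$cultivar)
  expect_equal(as.vector(counts[c("Alto", "Bronsyn", "Maxsyn", "Trojan")]),
               c(36, 32, 10, 57))
  # per-cultivar scan records
  expect_equal(sum(bags$cultivar == "Trojan") * 6, 342)
  expect_equal(sum(bags$cultivar == "Maxsyn") * 6, 60)
  # endophyte-free bags per cultivar: 6/5/1/4
  we <- table(bags$cultivar[bags$endophyte_strain == "WE"])
  expect_equal(as.vector(we[c("Alto", "Bronsyn", "Maxsyn", "Trojan")]),
               c(6, 5, 1, 4))
  # E+ scans before any outlier handling: 714 of 810
  expect_equal(sum(bags$endophyte_status == "E+") * 6, 714)
  expect_equal(anyDuplicated(bags$bag_id), 0)
  # strain/status invariant
  expect_true(all((bags$endophyte_strain == "WE") ==
                    (bags$endophyte_status == "E-")))
})

test_that("noiseless generation is deterministic within and across bags", {
  d <- toy_design(n_bags_per_class = 3, scans_per_bag = 3)
  p0 <- spectral_effect_params(bag_sd = 0, within_bag_sd = 0,
                               scatter_slope_sd = 0, scatter_offset_sd = 0,
                               tilt_sd = 0, noise_sd = 0)
  s <- generate_spectra(d, p0, shuffle = FALSE)
  md <- s$metadata
  # scans of one bag identical
  b1 <- s$absorbance[md$bag_id == md$bag_id[1], ]
  expect_equal(max(apply(b1, 2, function(col) diff(range(col)))), 0)
  # two bags with the same (cultivar, status) identical
  same <- unique(md$bag_id[md$cultivar == "Alto" & md$endophyte_status == "E+"])
  expect_gte(length(same), 2)
  r1 <- s$absorbance[md$bag_id == same[1], 1:50][1, ]
  r2 <- s$absorbance[md$bag_id == same[2], 1:50][1, ]
  expect_equal(r1, r2)
  # E+ and E- bags of a cultivar differ once the endophyte band effect is
  # nonzero (the default effect scales with noise_sd, zero here)
  p1 <- spectral_effect_params(bag_sd = 0, within_bag_sd = 0,
                               scatter_slope_sd = 0, scatter_offset_sd = 0,
                               tilt_sd = 0, noise_sd = 0,
                               endophyte_effect = c(0, 0.01, 0, 0, 0, 0))
  s1 <- generate_spectra(d, p1, shuffle = FALSE)
  md1 <- s1$metadata
  ep_row <- which(md1$cultivar == "Alto" & md1$endophyte_status == "E+")[1]
  we_row <- which(md1$cultivar == "Alto" & md1$endophyte_status == "E-")[1]
  expect_gt(max(abs(s1$absorbance[ep_row, ] - s1$absorbance[we_row, ])), 0.001)
})

test_that("generation is reproducible from the seed and varies across seeds", {
  d <- toy_design(n_bags_per_class = 2)
  s1 <- generate_spectra(d, spectral_effect_params(seed = 5))
  s2 <- generate_spectra(d, spectral_effect_params(seed = 5))
  expect_identical(s1$absorbance, s2$absorbance)
  expect_identical(s1$metadata, s2$metadata)
  s3 <- generate_spectra(d, spectral_effect_params(seed = 6))
  expect_gt(max(abs(s1$absorbance - s3$absorbance)), 0)
})

test_that("band centers outside the grid are rejected", {
  d <- toy_design()
  bad <- spectral_effect_params(band_centers = c(12000, 6824, 5736,
                                                 5176, 4776, 4304))
  expect_error(generate_spectra(d, bad), "outside the grid")
})

test_that("endophyte class contrast peaks at the designated band after pre-processing", {
  bags <- data.frame(
    bag_id = sprintf("Trojan_%02d", 1:12), cultivar = "Trojan",
    endophyte_strain = rep(c("AR1", "WE"), each = 6),
    endophyte_status = rep(c("E+", "E-"), each = 6),
    stringsAsFactors = FALSE)
  d <- sim_design(bags, grid = small_grid())
  params <- spectral_effect_params(seed = 60)
  s <- generate_spectra(d, params)
  fitted <- fit_pipeline(endophyte_chain(), s$absorbance)
  Xp <- fitted$cal_transformed
  ep <- s$metadata$endophyte_status == "E+"
  diffm <- abs(colMeans(Xp[ep, ]) - colMeans(Xp[!ep, ]))
  interior <- 8:(ncol(Xp) - 7)  # skip shrink-window derivative edges
  w_at_max <- s$grid$points[interior][which.max(diffm[interior])]
  center <- params$band_centers[which(params$endophyte_effect != 0)]
  width <- params$band_widths[which(params$endophyte_effect != 0)]
  expect_lt(abs(w_at_max - center), 3 * width)
})

test_that("outlier injection corrupts exactly the designated scans", {
  s <- generate_spectra(default_design(), spectral_effect_params(seed = 3))
  so <- inject_outliers(s, seed = 3)
  inj <- which(so$metadata$outlier_injected)
  expect_length(inj, 3)
  md <- so$metadata[inj, ]
  expect_true(all(md$cultivar == "Alto"))
  expect_equal(sum(md$endophyte_strain == "WE"), 2)
  expect_equal(sum(md$endophyte_strain == "NEA2"), 1)
  changed <- which(rowSums(so$absorbance != s$absorbance) > 0)
  expect_equal(sort(changed), sort(inj))
  # each corrupted scan has a 5-point spike of the stated magnitude
  delta <- so$absorbance[inj[1], ] - s$absorbance[inj[1], ]
  expect_equal(sum(delta != 0), 5)
  expect_true(all(abs(delta[delta != 0] - 0.06) < 1e-12))
  # zero magnitude is the identity
  s0 <- inject_outliers(s, magnitude = 0)
  expect_equal(s0$absorbance, s$absorbance)
})

test_that("corrupted scans dominate the Q-residual ordering", {
  s <- generate_spectra(default_design(), spectral_effect_params(seed = 4))
  so <- inject_outliers(trim_spectra(s, 9000, 3952), seed = 4)
  inj <- which(so$metadata$outlier_injected)
  rep <- screen_outliers(so)
  expect_true(all(rank(-rep$q_residuals)[inj] <= 3))
  expect_true(all(rep$q_residuals >= 0))
})

test_that("the benchmark suite is reproducible and sized as documented", {
  su1 <- benchmark_suite(seed = 2)
  su2 <- benchmark_suite(seed = 2)
  expect_identical(su1$spectra$absorbance, su2$spectra$absorbance)
  expect_equal(nrow(su1$spectra$absorbance), 600)  # 100 bags x 6 scans
  expect_equal(length(unique(su1$truth$bag_id)), 100)
  expect_equal(su1$thresholds$scan_accuracy, 0.90)
  expect_equal(su1$thresholds$bag_accuracy, 0.98)
})

test_that("within-bag spread shrinks with the scan-level dispersions", {
  d <- toy_design(n_bags_per_class = 2)
  p_small <- spectral_effect_params(within_bag_sd = 1e-5,
                                    scatter_slope_sd = 1e-5,
                                    scatter_offset_sd = 1e-5,
                                    tilt_sd = 1e-5, noise_sd = 1e-5, seed = 8)
  p_big <- spectral_effect_params(seed = 8)
  sd_within <- function(s) {
    md <- s$metadata
    mean(sapply(unique(md$bag_id), function(b)
      mean(apply(s$absorbance[md$bag_id == b, ], 2, sd))))
  }
  expect_lt(sd_within(generate_spectra(d, p_small)) * 100,
            sd_within(generate_spectra(d, p_big)))
})
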