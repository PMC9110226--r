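test_that("baseline subtraction behaves on vectors and matrices", {
  expect_equal(baseline_subtract(rep(5, 6), 2), rep(0, 6))
  expect_equal(baseline_subtract(c(3, 4, 5), 1), c(0, 1, 2))
  m <- rbind(c(1, 1, 3), c(2, 2, 6))
  expect_equal(baseline_subtract(m, 2), rbind(c(0, 0, 2), c(0, 0, 4)))
  expect_error(baseline_subtract(1:3, 3), "n_baseline")
})

test_that("time-to-peak follows its definition with earliest-tie break", {
  enh <- c(0, 1, 3, 2, 1, 0, 0, 5, 1)
  expect_equal(compute_ttp(enh, 2.25), 7 * 2.25) # peak at frame 8 (0-based 7)
  expect_equal(compute_ttp(c(0, 1, 2, 3), 2), 6) # monotone: last frame time
  expect_equal(compute_ttp(c(0, 4, 4, 1), 1), 1) # tie: earliest frame
})

test_that("a pixel sharing the AIF curve has CBV = 100 and quiet pixels are invalid", {
  nt <- 12L; dt <- 2
  t <- (seq_len(nt) - 1) * dt
  k <- tissue_kinetics(100, 50, 3, 2, 1.5)
  curve <- gamma_variate(t, k)
  frames <- array(90, dim = c(4, 4, nt)) # flat non-enhancing tissue
  aif <- matrix(FALSE, 4, 4); aif[1, 1] <- TRUE
  for (f in seq_len(nt)) {
    frames[1, 1, f] <- curve[f]       # the AIF pixel
    frames[2, 2, f] <- curve[f] + 7   # same enhancement, shifted baseline
  }
  maps <- compute_maps(dynamic_image(frames, dt), aif, n_baseline = 2)
  expect_equal(maps$cbv[1, 1], 100, tolerance = 1e-9)
  expect_equal(maps$cbv[2, 2], 100, tolerance = 1e-9)
  expect_equal(maps$mtt[1, 1], maps$cbv[1, 1] / maps$cbf[1, 1])
  # all-baseline pixel: no volume, no flow, invalid transit time
  expect_equal(maps$cbv[3, 3], 0)
  expect_equal(maps$cbf[3, 3], 0)
  expect_true(is.na(maps$mtt[3, 3]))
})

test_that("noiseless phantom maps recover TTP and the CBF rank order", {
  gt <- build_phantom(phantom_spec(48L))
  dt <- attr(gt$frames, "frame_interval_s")
  maps <- compute_maps(gt$frames, class_mask(gt, "artery"))
  kin <- gt$kinetics
  for (cl in c("normal", "penumbra", "core", "artery")) {
    sel <- class_mask(gt, cl)
    analytic <- kin[[cl]]$delay_s + kin[[cl]]$alpha * kin[[cl]]$beta
    expect_lt(abs(mean(maps$ttp[sel]) - analytic), dt)
  }
  cbf_mean <- vapply(c("core", "penumbra", "normal"),
                     function(cl) mean(maps$cbf[class_mask(gt, cl)]),
                     numeric(1))
  expect_true(all(diff(cbf_mean) > 0))
})

test_that("maps are invariant to a common positive scaling of the frames", {
  gt <- build_phantom(phantom_spec(32L, frame_count = 10L))
  aif <- class_mask(gt, "artery")
  m1 <- compute_maps(gt$frames, aif)
  m2 <- compute_maps(dynamic_image(unclass(gt$frames) * 3.7,
                                   attr(gt$frames, "frame_interval_s")), aif)
  for (m in names(m1)) expect_equal(m2[[m]], m1[[m]], tolerance = 1e-9)
})

test_that("central-volume identity holds wherever MTT is valid", {
  gt <- build_phantom(phantom_spec(32L, frame_count = 10L))
  maps <- compute_maps(gt$frames, class_mask(gt, "artery"))
  ok <- !is.na(maps$mtt)
  expect_true(any(ok))
  expect_lt(max(abs(maps$mtt[ok] - maps$cbv[ok] / maps$cbf[ok])), 1e-6)
  expect_true(all(maps$cbv >= 0) && all(maps$cbf >= 0))
  scan_end <- (dim(gt$frames)[3] - 1) * attr(gt$frames, "frame_interval_s")
  expect_true(all(maps$ttp >= 0 & maps$ttp <= scan_end))
})

test_that("region report normalizes to the normal class and skips empty classes", {
  gt <- build_phantom(phantom_spec(48L))
  maps <- compute_maps(gt$frames, class_mask(gt, "artery"))
  rep <- region_report(maps, gt$label_map)
  norm <- rep[rep$tissue_class == "normal", ]
  expect_equal(unlist(norm[paste0("rel_", c("cbv", "cbf", "mtt", "ttp"))]),
               c(rel_cbv = 1, rel_cbf = 1, rel_mtt = 1, rel_ttp = 1))
  expect_lt(rep$rel_cbf[rep$tissue_class == "penumbra"], 1)
  # a phantom without a core class yields no core row
  spec2 <- phantom_spec(32L, list(
    ellipse_region(c(0.5, 0.5), c(0.4, 0.4), 0, "normal"),
    ellipse_region(c(0.5, 0.74), c(0.05, 0.05), 0, "artery")))
  gt2 <- build_phantom(spec2)
  rep2 <- region_report(compute_maps(gt2$frames, class_mask(gt2, "artery")),
                        gt2$label_map)
  expect_false("core" %in% rep2$tissue_class)
})

test_that("degenerate AIF inputs error out", {
  gt <- build_phantom(phantom_spec(32L, frame_count = 5L))
  empty <- matrix(FALSE, 32, 32)
  expect_error(compute_maps(gt$frames, empty), "nonempty")
  bg <- class_mask(gt, "background") # zero enhancement everywhere
  expect_error(compute_maps(gt$frames, bg), "positive peak")
})
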