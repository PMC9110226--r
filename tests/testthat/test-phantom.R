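test_that("gamma-variate curve honors baseline, normalized peak, and the closed form", {
  k <- tissue_kinetics(baseline_hu = 40, amplitude = 30, delay_s = 3,
                       alpha = 2, beta = 1.5)
  # pre-arrival values are exactly the baseline
  expect_identical(gamma_variate(c(0, 1.5, 3), k), c(40, 40, 40))
  # peak of exactly baseline + amplitude at delay + alpha*beta
  expect_equal(gamma_variate(3 + 2 * 1.5, k), 70)
  # independent hand evaluation at t = 4.5: tau/tp = 0.5,
  # value = 40 + 30 * 0.25 * exp(1)
  expect_equal(gamma_variate(4.5, k), 40 + 7.5 * exp(1), tolerance = 1e-12)
  expect_error(gamma_variate(-0.1, k), "t must be")
})

test_that("kinetics constructor enforces parameter ranges", {
  expect_error(tissue_kinetics(40, -1, 0, 2, 1), "amplitude")
  expect_error(tissue_kinetics(40, 1, -1, 2, 1), "delay")
  expect_error(tissue_kinetics(40, 1, 0, 0, 1), "alpha")
})

test_that("a single-region phantom samples the class curve at the frame times", {
  spec <- small_spec(grid = 32L, frames = 3L, dt = 2.0)
  kin <- list(background = tissue_kinetics(0, 0, 0, 2, 1),
              normal = tissue_kinetics(1040, 30, 1, 2, 1.5))
  gt <- build_phantom(spec, kin)
  inside <- class_mask(gt, "normal")
  expected <- gamma_variate(c(0, 2, 4), kin$normal)
  for (f in 1:3) {
    vals <- gt$frames[, , f][inside]
    expect_true(all(vals == expected[f]))
    expect_true(all(gt$frames[, , f][!inside] == 0))
  }
})

test_that("overlapping regions follow painter's order", {
  spec <- phantom_spec(32L, list(
    ellipse_region(c(0.5, 0.5), c(0.4, 0.4), 0, "normal"),
    ellipse_region(c(0.5, 0.5), c(0.15, 0.15), 0, "penumbra")
  ), frame_count = 3L)
  gt <- build_phantom(spec, default_kinetics())
  classes <- attr(gt$label_map, "classes")
  center_class <- classes[gt$label_map[16, 16]]
  expect_identical(center_class, "penumbra")
  expect_true(any(classes[gt$label_map] == "normal"))
})

test_that("phantom generation is deterministic and missing kinetics error out", {
  spec <- phantom_spec(32L, frame_count = 5L)
  a <- build_phantom(spec)
  b <- build_phantom(spec)
  expect_identical(a, b)
  expect_error(build_phantom(spec, list(background = tissue_kinetics(0, 0, 0, 2, 1))),
               "missing kinetics")
})

test_that("ground-truth maps are pure within each class and analytic", {
  gt <- build_phantom(phantom_spec(48L, frame_count = 10L))
  lab <- gt$label_map
  for (m in names(gt$true_maps)) {
    v <- gt$true_maps[[m]]
    for (cl in unique(as.vector(lab))) {
      vals <- v[lab == cl]
      vals <- vals[is.finite(vals)]
      if (length(vals) > 1) expect_equal(var(vals), 0)
    }
  }
  # TTP truth is delay + alpha * beta per class
  kin <- default_kinetics()
  for (cl in c("normal", "penumbra", "core", "artery")) {
    k <- kin[[cl]]
    expect_equal(unique(gt$true_maps$ttp[class_mask(gt, cl)]),
                 k$delay_s + k$alpha * k$beta)
  }
})

test_that("default kinetics suppress the infarct core below penumbra below normal", {
  kin <- default_kinetics()
  expect_lt(kin$core$amplitude, kin$penumbra$amplitude)
  expect_lt(kin$penumbra$amplitude, kin$normal$amplitude)
  gt <- build_phantom(phantom_spec(64L, frame_count = 10L))
  cbf <- gt$true_maps$cbf
  expect_lt(mean(cbf[class_mask(gt, "core")]),
            mean(cbf[class_mask(gt, "penumbra")]))
  expect_lt(mean(cbf[class_mask(gt, "penumbra")]),
            mean(cbf[class_mask(gt, "normal")]))
})

test_that("spec invariants are validated", {
  expect_error(phantom_spec(8L), "grid_size")
  expect_error(phantom_spec(32L, frame_count = 2L), "frame_count")
  expect_error(phantom_spec(32L, frame_interval_s = 0), "frame_interval_s")
  expect_error(ellipse_region(c(0.9, 0.5), c(0.2, 0.2), 0, "normal"),
               "within the grid")
})
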