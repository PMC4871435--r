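# the synthetic assemblage generator: determinism, geometry, factor effects

test_that("noise-free outlines are deterministic and honour the planar limit", {
  p <- shape_params(ventral_bow = 0)
  o1 <- generate_outline(p, 96L, noise_sd = 0, seed = 1L)
  o2 <- generate_outline(p, 96L, noise_sd = 0, seed = 999L)
  expect_identical(o1$contour, o2$contour)
  expect_identical(o1$anchors, o2$anchors)
  expect_lt(max(abs(o1$contour[, "z"])), 1e-12)        # ventral_bow = 0: flat
  pz <- shape_params(ventral_bow = 0.1)
  oz <- generate_outline(pz, 96L, noise_sd = 0)
  expect_gt(max(abs(oz$contour[, "z"])), 1)            # bowed out of plane
})

test_that("generated outlines satisfy the raw-outline invariants", {
  a <- small_assemblage(n = 8L, seed = 19L)
  for (o in a$outlines) {
    expect_s3_class(o, "outline")
    expect_identical(nrow(o$anchors), 3L)
    expect_identical(nrow(o$contour), 96L)
    expect_identical(unname(o$anchors[1L, ]), unname(o$contour[1L, ]))
    expect_true(all(is.finite(o$contour)))
    # anchors sit at the corners: L1 at the top, L2 right of L3 (clockwise)
    expect_gt(o$anchors[1L, "y"], o$anchors[2L, "y"])
    expect_gt(o$anchors[2L, "x"], o$anchors[3L, "x"])
  }
  for (f in names(lithomorph:::factor_vocabulary))
    expect_true(all(a$factors[[f]] %in% lithomorph:::factor_vocabulary[[f]]))
  expect_true(all(a$sizes$volume_mm3 > 0))
})

test_that("doubling the scale doubles centroid size exactly (noise free)", {
  p1 <- shape_params(scale = 30)
  p2 <- shape_params(scale = 60)
  o1 <- generate_outline(p1, 96L, noise_sd = 0)
  o2 <- generate_outline(p2, 96L, noise_sd = 0)
  expect_equal(centroid_size(full_config(o2)), 2 * centroid_size(full_config(o1)),
               tolerance = 1e-12)
  expect_equal(attr(o2, "area_mm2"), 4 * attr(o1, "area_mm2"), tolerance = 1e-12)
})

test_that("assemblages are reproducible from the seed, byte for byte", {
  cfg <- assemblage_config(6L, seed = 77L, n_points = 64L)
  a1 <- generate_assemblage(cfg)
  a2 <- generate_assemblage(cfg)
  f1 <- withr::local_tempfile(fileext = ".csv")
  f2 <- withr::local_tempfile(fileext = ".csv")
  write_outline_table(a1$outlines, f1)
  write_outline_table(a2$outlines, f2)
  expect_identical(unname(tools::md5sum(f1)), unname(tools::md5sum(f2)))
  expect_identical(a1$factors, a2$factors)
  expect_identical(a1$sizes, a2$sizes)
  # a different seed gives different outlines
  a3 <- generate_assemblage(assemblage_config(6L, seed = 78L, n_points = 64L))
  expect_gt(max(abs(a3$outlines[[1L]]$contour - a1$outlines[[1L]]$contour)), 1e-3)
})

test_that("factor bookkeeping and infeasible shifts are validated", {
  cfg <- assemblage_config(37L, seed = 5L, n_points = 48L)
  a <- generate_assemblage(cfg)
  expect_identical(sum(table(a$factors$action)), 37L)
  expect_identical(nrow(a$sizes), 37L)
  expect_error(
    assemblage_config(10L, seed = 1L,
                      factors = list(action = list(
                        probs = c(T = 0.5, L = 0.5),
                        shifts = list(T = c(tip_angle = 500))))),
    "infeasible class shift.*tip_angle")
  expect_error(assemblage_config(10L), "'seed' is mandatory")
  expect_error(shape_params(corner_radius = 0.5), "corner_radius")
  expect_error(shape_params(elongation = -1), "elongation")
})

test_that("generate -> write -> read -> analyze closes the loop", {
  a <- small_assemblage(n = 8L, seed = 23L, n_points = 196L)
  dir <- withr::local_tempdir()
  write_outline_table(a$outlines, file.path(dir, "outlines.csv"))
  write_factor_table(a$factors, file.path(dir, "factors.csv"))
  write_size_table(a$sizes, file.path(dir, "sizes.csv"))
  cfg <- pipeline_config(outlines = file.path(dir, "outlines.csv"),
                         factors = file.path(dir, "factors.csv"),
                         sizes = file.path(dir, "sizes.csv"),
                         n_points = 96L)
  b <- run_pipeline(cfg, quiet = TRUE)
  expect_s3_class(b, "pipeline_bundle")
  expect_identical(nrow(b$scores), 8L)
})

test_that("a dominant elongation axis is recovered as PC1", {
  hits <- 0L
  for (seed in 1:5) {
    cfg <- assemblage_config(
      20L, seed = seed, n_points = 96L, noise_sd = 0.1, null_effects = TRUE,
      param_sds = list(elongation = 0.45, asymmetry = 0.01, ventral_bow = 0.005,
                       tip_angle = 1.5, corner_radius = 0.005,
                       base_convexity = 0.01, scale = 6))
    a <- generate_assemblage(cfg)
    sc <- lithomorph:::shape_scores(a$outlines, n_points = 96L)
    r <- abs(stats::cor(sc$space$scores[, 1L], a$params$elongation))
    if (r > 0.9) hits <- hits + 1L
  }
  expect_gte(hits, 4L)
})

test_that("class shifts of two pooled SDs are detected with high power", {
  cfg <- assemblage_config(
    37L, seed = 500L,
    factors = list(action = list(probs = c(T = 1 / 3, L = 1 / 3, P = 1 / 3),
                                 shifts = list(T = c(tip_angle = -18),
                                               P = c(tip_angle = +18)))))
  rate <- manova_calibration(cfg, reps = 100L, k = 9L)
  expect_gt(as.numeric(rate), 0.8)
})

test_that("the calibration harness is seeded and honours alpha", {
  cfg <- assemblage_config(12L, seed = 3L, n_points = 64L, null_effects = TRUE)
  r1 <- manova_calibration(cfg, reps = 100L, alpha = 0.05, k = 3L)
  r2 <- manova_calibration(cfg, reps = 100L, alpha = 0.05, k = 3L)
  expect_identical(attr(r1, "p_values"), attr(r2, "p_values"))
  expect_identical(as.numeric(manova_calibration(cfg, reps = 100L, alpha = 0,
                                                 k = 3L)), 0)
  expect_error(manova_calibration(cfg, reps = 10L), "at least 100")
})
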