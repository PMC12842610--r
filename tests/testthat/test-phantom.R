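# synthetic_meibography: grading rules, rendering invariants, domain shift

test_that("grade_from_dropout implements the 33%/66% thresholds", {
  expect_identical(grade_from_dropout(c(0, 0.2, 0.5, 0.7)), c(0L, 1L, 2L, 3L))
  # grade 0 iff rho is exactly zero
  expect_identical(grade_from_dropout(1e-9), 1L)
  # boundary values round up to the more severe grade
  expect_identical(grade_from_dropout(0.33), 2L)
  expect_identical(grade_from_dropout(0.66), 3L)
  expect_identical(grade_from_dropout(1), 3L)
  expect_error(grade_from_dropout(-0.1), "\\[0, 1\\]")
  expect_error(grade_from_dropout(1.5), "\\[0, 1\\]")
  expect_error(grade_from_dropout(NA_real_), "\\[0, 1\\]")
})

test_that("render_phantom is deterministic and respects value ranges", {
  spec <- phantom_spec(rho = 0.4, unit_id = "u1", rng_seed = 7L)
  a <- render_phantom(spec)
  b <- render_phantom(spec)
  expect_identical(a$image, b$image)
  expect_identical(a$mask, b$mask)
  expect_true(all(a$image >= 0 & a$image <= 1))
  expect_true(all(a$mask %in% c(0, 1)))
  expect_identical(a$grade, 2L)
  # a different render seed changes the image but not the mask geometry
  c2 <- render_phantom(phantom_spec(rho = 0.4, unit_id = "u1", rng_seed = 8L))
  expect_false(identical(a$image, c2$image))
  expect_identical(a$mask, c2$mask)
})

test_that("dropout erases the requested gland fraction", {
  base <- render_phantom(phantom_spec(rho = 0, unit_id = "uA"))
  n_total <- sum(base$mask)
  expect_gt(n_total, 0)
  for (rho in c(0.1, 0.33, 0.5, 0.8, 1)) {
    s <- render_phantom(phantom_spec(rho = rho, unit_id = "uA"))
    achieved <- 1 - sum(s$mask) / n_total
    expect_lt(abs(achieved - rho), 0.02)
    expect_identical(s$grade, grade_from_dropout(rho))
  }
  # rho = 1 erases every gland pixel
  s1 <- render_phantom(phantom_spec(rho = 1, unit_id = "uA"))
  expect_identical(sum(s1$mask), 0)
})

test_that("images of one unit share geometry; different units differ", {
  m1 <- render_phantom(phantom_spec(rho = 0, unit_id = "uX", rng_seed = 1L))$mask
  m2 <- render_phantom(phantom_spec(rho = 0, unit_id = "uX", rng_seed = 2L))$mask
  m3 <- render_phantom(phantom_spec(rho = 0, unit_id = "uY", rng_seed = 1L))$mask
  expect_identical(m1, m2)
  expect_false(identical(m1, m3))
})

test_that("phantom_spec validates its arguments", {
  expect_error(phantom_spec(image_size = c(16L, 16L)), "32")
  expect_error(phantom_spec(rho = 2), "\\[0, 1\\]")
  expect_error(phantom_spec(unit_id = ""), "non-empty")
  expect_error(phantom_spec(domain_id = "other"), "source")
  expect_error(phantom_spec(artifact_spec = list(sparkle = 1)), "unknown")
  # unsatisfiable geometry: stripe wider than the stripe period
  expect_error(render_phantom(phantom_spec(n_glands = 30L,
                                           stripe_width_px = 10L)),
               "unsatisfiable")
})

test_that("identity domain shift is bit-exact; real shifts move intensities", {
  img <- render_phantom(phantom_spec(rho = 0.3, unit_id = "uS"))$image
  expect_identical(apply_domain_shift(img, domain_shift_spec()), img)
  shifted <- apply_domain_shift(img, domain_shift_spec(
    brightness_offset = 0.15, contrast_gain = 1.5, gamma = 0.65,
    blur_sigma_px = 1, noise_model = "speckle", noise_scale = 0.08,
    resolution_scale = 0.5), rng_seed = 3L)
  expect_identical(dim(shifted), dim(img))
  expect_true(all(shifted >= 0 & shifted <= 1))
  expect_gt(mean(abs(shifted - img)), 0.01)
  # deterministic given the seed
  shifted2 <- apply_domain_shift(img, domain_shift_spec(
    brightness_offset = 0.15, contrast_gain = 1.5, gamma = 0.65,
    blur_sigma_px = 1, noise_model = "speckle", noise_scale = 0.08,
    resolution_scale = 0.5), rng_seed = 3L)
  expect_identical(shifted, shifted2)
  expect_error(domain_shift_spec(gamma = 0), "positive")
  expect_error(domain_shift_spec(blur_sigma_px = -1), "non-negative")
})

test_that("artifacts stay in range and are reproducible", {
  img <- render_phantom(phantom_spec(rho = 0.2, unit_id = "uA2"))$image
  art <- inject_artifacts(img, list(specular = 0.5, swab = 0.4,
                                    eyelash = 0.6), rng_seed = 5L)
  expect_identical(dim(art), dim(img))
  expect_true(all(art >= 0 & art <= 1))
  expect_false(identical(art, img))
  expect_identical(art, inject_artifacts(img, list(specular = 0.5, swab = 0.4,
                                                   eyelash = 0.6),
                                         rng_seed = 5L))
})
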