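# Synthetic carcass generator: rasterization oracle, scaling laws, the
# noisy linear weight model, and dataset-level determinism.

test_that("rasterized masks equal the per-pixel membership oracle exactly", {
  sp <- carcass_spec(s = 1, sigma_pos = 0, sigma_tex = 0,
                     canvas = c(120, 100), torso_a = 22, torso_b = 15,
                     head_r = 8, leg_len = 25, leg_w = 7, px_per_cm = 4)
  for (seed in c(7, 11)) {
    car <- generate_carcass(sp, seed = seed, replicates = 1)
    for (view in c("ventral", "dorsal", "lateral")) {
      m <- car[[view]]$replicates[[1]]$mask
      mask <- matrix(as.integer(m), nrow(m), ncol(m))
      oracle <- carcass_membership_oracle(car[[view]]$shapes, 120, 100)
      expect_identical(mask, oracle)
    }
  }
})

test_that("foreground area scales with the square of the global scale", {
  mk <- function(s) carcass_spec(s = s, sigma_pos = 0, sigma_tex = 0,
                                 canvas = c(300, 240), torso_a = 30,
                                 torso_b = 20, head_r = 10, leg_len = 34,
                                 leg_w = 9)
  c1 <- generate_carcass(mk(1), seed = 7, replicates = 1)
  c2 <- generate_carcass(mk(2), seed = 7, replicates = 1)
  a1 <- sum(unclass(c1$ventral$replicates[[1]]$mask) > 0)
  a2 <- sum(unclass(c2$ventral$replicates[[1]]$mask) > 0)
  expect_lt(abs(a2 / a1 - 4), 0.08)
  # analytic areas scale exactly
  expect_equal(c2$ventral$areas_cm2, 4 * c1$ventral$areas_cm2,
               tolerance = 1e-12)
})

test_that("replicates are pixel-identical when jitter and noise are zero", {
  sp <- carcass_spec(sigma_pos = 0, sigma_tex = 0, canvas = c(160, 128),
                     torso_a = 22, torso_b = 15, head_r = 8, leg_len = 25,
                     leg_w = 7)
  car <- generate_carcass(sp, seed = 3, replicates = 3)
  reps <- car$ventral$replicates
  expect_identical(reps[[1]]$image, reps[[2]]$image)
  expect_identical(reps[[2]]$image, reps[[3]]$image)
  expect_identical(unclass(reps[[1]]$mask), unclass(reps[[3]]$mask))
})

test_that("masks use exactly the background/torso/head/leg class set", {
  sp <- carcass_spec(canvas = c(160, 128), torso_a = 22, torso_b = 15,
                     head_r = 8, leg_len = 25, leg_w = 7)
  car <- generate_carcass(sp, seed = 5, replicates = 1)
  m <- car$lateral$replicates[[1]]$mask
  expect_setequal(unique(as.vector(m)), 0:3)
  img <- car$lateral$replicates[[1]]$image
  expect_gt(mean(img[unclass(m) > 0]), mean(img[unclass(m) == 0]))
})

test_that("oversized geometry is rejected naming the offending dimension", {
  sp <- carcass_spec(canvas = c(64, 64))  # default geometry needs ~320 px
  expect_error(generate_carcass(sp, seed = 1), "canvas")
  expect_error(carcass_spec(torso_a = -1), "torso_a")
  expect_error(carcass_spec(views = character(0)))
})

test_that("weight model is the stated noisy linear form", {
  a <- c(torso = 60, head = 15, leg = 25)
  w0 <- assign_weights(a, weight_model(beta0 = 0,
                                       betas = c(torso = 1, head = 1,
                                                 leg = 1), sigma_w = 0))
  expect_equal(w0$weight_total_g, 100)
  w1 <- assign_weights(a, weight_model(beta0 = 50,
                                       betas = c(torso = 0, head = 0,
                                                 leg = 0), sigma_w = 0))
  expect_equal(w1$weight_total_g, 50)
  # part weights sum to the deterministic total when noiseless
  wm <- weight_model(sigma_w = 0)
  wp <- assign_weights(a, wm)
  expect_equal(wp$weight_carcass_g + wp$weight_head_g + wp$weight_leg_g,
               wp$weight_total_g, tolerance = 1e-10)
  expect_error(assign_weights(c(torso = -1, head = 1, leg = 1), wm),
               "negative area")
})

test_that("weight noise is centred: Monte-Carlo mean deviation is small", {
  a <- c(torso = 60, head = 15, leg = 25)
  wm <- weight_model(sigma_w = 20)
  det <- assign_weights(a, weight_model(sigma_w = 0))$weight_total_g
  devs <- vapply(1:1000, function(i)
    assign_weights(a, wm, seed = i)$weight_total_g - det, numeric(1))
  expect_lt(abs(mean(devs)), 4 * 20 / sqrt(1000))
})

test_that("dataset has n x views x replicates records and unique ids", {
  ds <- generate_dataset(301, seed = 1)
  expect_equal(nrow(ds$manifest), 2709)
  expect_equal(length(unique(ds$manifest$carcass_id)), 301)
  expect_equal(nrow(ds$weights), 301)
  expect_true(all(ds$manifest$px_per_cm > 0))
  ds1 <- generate_dataset(1, seed = 1)
  expect_equal(nrow(ds1$manifest), 9)
  expect_error(generate_dataset(0), "n_carcasses")
})

test_that("identical seeds give byte-identical manifests and weights", {
  a <- generate_dataset(25, seed = 42)
  b <- generate_dataset(25, seed = 42)
  expect_identical(a$manifest, b$manifest)
  expect_identical(a$weights, b$weights)
  expect_identical(a$areas, b$areas)
  c2 <- generate_dataset(25, seed = 43)
  expect_false(identical(a$weights, c2$weights))
})

test_that("least squares on noiseless data recovers the weight model", {
  ds <- generate_dataset(150, seed = 9, wmodel = weight_model(sigma_w = 0))
  ag <- stats::aggregate(area_cm2 ~ carcass_id + part, ds$areas, mean)
  wide <- stats::reshape(ag, idvar = "carcass_id", timevar = "part",
                         direction = "wide")
  wide <- wide[match(ds$weights$carcass_id, wide$carcass_id), ]
  fit <- stats::lm(ds$weights$weight_total_g ~ wide$area_cm2.torso +
                     wide$area_cm2.head + wide$area_cm2.leg)
  expect_equal(unname(coef(fit)), c(150, 9, 3, 3), tolerance = 1e-6)
})
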