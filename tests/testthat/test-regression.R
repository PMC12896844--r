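# Feature assembly, the five regression families, bootstrap intervals and
# residual outlier flags.

small_dataset <- function(n = 60, seed = 1, sigma_w = NULL) {
  wm <- if (is.null(sigma_w)) weight_model() else
    weight_model(sigma_w = sigma_w)
  generate_dataset(n, seed = seed, wmodel = wm)
}

test_that("replicate areas average into one feature per view", {
  areas <- data.frame(
    carcass_id = "C1",
    view = rep(c("ventral", "lateral", "dorsal"), each = 3),
    replicate = rep(1:3, 3),
    part = "torso",
    area_cm2 = c(10, 12, 14, 20, 22, 24, 30, 32, 34))
  weights <- data.frame(carcass_id = "C1", weight_total_g = 500,
                        weight_carcass_g = 400, weight_head_g = 50,
                        weight_leg_g = 50)
  tab <- assemble_features(areas, weights, "Mod2")
  expect_equal(tab$area_ventral, 12)
  expect_equal(tab$area_lateral, 22)
  expect_equal(tab$area_dorsal, 32)
  expect_equal(tab$target, 400)
})

test_that("feature tables have one row and three features per carcass", {
  ds <- small_dataset(30, seed = 3)
  for (mod in c("Mod1", "Mod2", "Mod3", "Mod4")) {
    tab <- assemble_features(ds$areas, ds$weights, mod)
    expect_equal(nrow(tab), 30)
    expect_equal(sum(grepl("^area_", names(tab))), 3)
  }
  expect_error(assemble_features(ds$areas, ds$weights, "Mod9"),
               "unknown mod")
  # Mod1 target is the total, Mod3 the head weight
  t1 <- assemble_features(ds$areas, ds$weights, "Mod1")
  t3 <- assemble_features(ds$areas, ds$weights, "Mod3")
  expect_equal(t1$target,
               ds$weights$weight_total_g[match(t1$carcass_id,
                                               ds$weights$carcass_id)])
  expect_equal(t3$target,
               ds$weights$weight_head_g[match(t3$carcass_id,
                                              ds$weights$carcass_id)])
})

test_that("carcasses missing a view are dropped with a warning", {
  ds <- small_dataset(12, seed = 4)
  areas <- ds$areas[!(ds$areas$carcass_id == "C0001" &
                        ds$areas$view == "lateral"), ]
  expect_warning(tab <- assemble_features(areas, ds$weights, "Mod1"),
                 "missing views")
  expect_equal(nrow(tab), 11)
  expect_false("C0001" %in% tab$carcass_id)
})

test_that("linearly realizable models recover noiseless data", {
  ds <- small_dataset(120, seed = 5, sigma_w = 0)
  tab <- assemble_features(ds$areas, ds$weights, "Mod1")
  split <- build_split(tab$carcass_id, seed = 5)
  sd_y <- stats::sd(tab$target)
  for (model in c("bayes", "mlp")) {
    res <- fit_and_evaluate(tab, model, split, seed = 5, bootstrap_B = 0)
    expect_gte(res$r2, 0.999)
    expect_lte(res$rmse, 0.05 * sd_y)
  }
  expect_error(fit_and_evaluate(tab, "gbm", split), "svr_rbf")
})

test_that("all five families fit noisy data with positive skill", {
  ds <- small_dataset(120, seed = 6)
  tab <- assemble_features(ds$areas, ds$weights, "Mod2")
  split <- build_split(tab$carcass_id, seed = 6)
  for (model in c("mlp", "svr_rbf", "bayes", "lgbm", "catboost")) {
    res <- fit_and_evaluate(tab, model, split, seed = 6, bootstrap_B = 0)
    expect_gt(res$r2, 0.5)
    expect_lte(res$r2, 1)
    expect_gte(res$rmse, 0)
  }
})

test_that("a train-mean predictor scores near-zero R2", {
  ds <- small_dataset(150, seed = 7)
  tab <- assemble_features(ds$areas, ds$weights, "Mod1")
  split <- build_split(tab$carcass_id, seed = 7)
  te <- tab[split$subset[match(tab$carcass_id,
                               split$carcass_id)] == "test", ]
  tr <- tab[split$subset[match(tab$carcass_id,
                               split$carcass_id)] == "train", ]
  pred <- rep(mean(tr$target), nrow(te))
  r2 <- 1 - sum((te$target - pred)^2) /
    sum((te$target - mean(te$target))^2)
  expect_lt(abs(r2), 0.35)
})

test_that("test rows never correspond to training carcasses", {
  ds <- small_dataset(60, seed = 8)
  tab <- assemble_features(ds$areas, ds$weights, "Mod1")
  split <- build_split(tab$carcass_id, seed = 8)
  expect_length(intersect(split_ids(split, "train"),
                          split_ids(split, "test")), 0)
  res <- fit_and_evaluate(tab, "bayes", split, seed = 8, bootstrap_B = 50)
  expect_equal(res$n_test, length(split_ids(split, "test")))
})

test_that("test R2 declines as generator noise grows", {
  r2_at <- vapply(c(10, 60, 200, 600), function(sw) {
    # extreme noise levels occasionally clamp a weight at zero
    ds <- suppressWarnings(small_dataset(150, seed = 9, sigma_w = sw))
    tab <- assemble_features(ds$areas, ds$weights, "Mod1")
    split <- build_split(tab$carcass_id, seed = 9)
    fit_and_evaluate(tab, "bayes", split, seed = 9, bootstrap_B = 0)$r2
  }, numeric(1))
  expect_true(all(diff(r2_at) < 0))
})

test_that("bootstrap intervals are ordered, deterministic and collapse for
          perfect predictions", {
  set.seed(10)
  y <- rnorm(40, 100, 10)
  pred <- y + rnorm(40, 0, 3)
  ci <- bootstrap_ci(y, pred, B = 200, seed = 4)
  expect_lte(ci$ci_r2[1], ci$ci_r2[2])
  expect_lte(ci$ci_rmse[1], ci$ci_rmse[2])
  expect_identical(ci, bootstrap_ci(y, pred, B = 200, seed = 4))
  perfect <- bootstrap_ci(y, y, B = 100, seed = 1)
  expect_equal(perfect$ci_r2, c(1, 1))
  expect_equal(perfect$ci_rmse, c(0, 0))
  expect_error(bootstrap_ci(y[1:4], pred[1:4]), "at least 5")
})

test_that("residual outlier flags follow the 2-sigma rule", {
  # all residuals equal: sigma 0, nothing flagged
  ro <- residual_outliers(c(5, 5, 5), c(4, 4, 4))
  expect_equal(ro$sigma, 0)
  expect_false(any(ro$flags))
  # one gross outlier among near-zero residuals is the only flag
  y <- c(rep(0, 20), 50)
  ro2 <- residual_outliers(y, rep(0, 21))
  expect_equal(which(ro2$flags), 21L)
  expect_error(residual_outliers(1, 1), "length >= 2")
})
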