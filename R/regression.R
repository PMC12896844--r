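# Area -> weight regression: Mod1-Mod4 feature assembly, five regression
# families, R^2/RMSE on the held-out test split, percentile bootstrap
# confidence intervals, and +/-2 sigma residual outlier flags.
#
# Backends: MLP -> nnet (skip connections, linear output); RBF-SVR ->
# e1071::svm; Bayesian regression -> in-package evidence-maximization
# Bayesian ridge; the two gradient-boosting families -> xgboost with
# leaf-wise (histogram) and depth-wise growth respectively.

REGRESSION_MODELS <- c("mlp", "svr_rbf", "bayes", "lgbm", "catboost")

MOD_DEFS <- list(
  Mod1 = list(parts = c("torso", "head", "leg"), target = "weight_total_g",
              label = "overall"),
  Mod2 = list(parts = "torso", target = "weight_carcass_g",
              label = "carcass"),
  Mod3 = list(parts = "head", target = "weight_head_g", label = "head"),
  Mod4 = list(parts = "leg", target = "weight_leg_g", label = "leg")
)

#' Assemble a Mod feature table
#'
#' Builds one row per carcass with three features — the part-group area
#' (cm^2) in each of the ventral, lateral and dorsal views, averaged over
#' replicates — and the mod-appropriate target weight (Mod1 overall, Mod2
#' carcass, Mod3 head, Mod4 leg). Carcasses missing a view are dropped
#' with a warning.
#'
#' @param areas data.frame with columns `carcass_id`, `view`, `part`,
#'   `area_cm2` and optionally `replicate` (e.g. from [measure_areas()] or
#'   a [generate_dataset()] `areas` table).
#' @param weights data.frame with `carcass_id` and the weight columns of
#'   [assign_weights()].
#' @param mod One of `"Mod1"` .. `"Mod4"`.
#' @return Object of class `feature_table`: data.frame with `carcass_id`,
#'   `area_ventral`, `area_lateral`, `area_dorsal`, `target`.
#' @export
assemble_features <- function(areas, weights, mod = "Mod1") {
  if (!mod %in% names(MOD_DEFS))
    stop("unknown mod '", mod, "'; supported: ",
         paste(names(MOD_DEFS), collapse = ", "))
  def <- MOD_DEFS[[mod]]
  sub <- areas[areas$part %in% def$parts, , drop = FALSE]
  # mean over replicates, then sum over the part group per view
  agg <- stats::aggregate(area_cm2 ~ carcass_id + view + part, data = sub,
                          FUN = mean)
  agg <- stats::aggregate(area_cm2 ~ carcass_id + view, data = agg,
                          FUN = sum)
  views <- c("ventral", "lateral", "dorsal")
  wide <- stats::reshape(agg, idvar = "carcass_id", timevar = "view",
                         direction = "wide")
  need <- paste0("area_cm2.", views)
  missing_view <- !need %in% names(wide)
  if (any(missing_view))
    stop("areas table has no rows for view(s): ",
         paste(views[missing_view], collapse = ", "))
  keep <- stats::complete.cases(wide[, need])
  if (any(!keep))
    warning("dropped ", sum(!keep), " carcass(es) with missing views: ",
            paste(utils::head(wide$carcass_id[!keep], 5), collapse = ", "))
  wide <- wide[keep, , drop = FALSE]
  out <- data.frame(carcass_id = wide$carcass_id,
                    area_ventral = wide[["area_cm2.ventral"]],
                    area_lateral = wide[["area_cm2.lateral"]],
                    area_dorsal = wide[["area_cm2.dorsal"]],
                    stringsAsFactors = FALSE)
  wsub <- weights[match(out$carcass_id, weights$carcass_id), , drop = FALSE]
  out$target <- wsub[[def$target]]
  out <- out[!is.na(out$target), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "mod") <- mod
  class(out) <- c("feature_table", "data.frame")
  out
}

# Evidence-maximization Bayesian ridge regression (Gaussian prior on the
# coefficients, Gamma-flat hyperpriors): iterates closed-form updates of
# the noise and weight precisions and returns the posterior mean predictor.
bayes_ridge_fit <- function(X, y, max_iter = 300, tol = 1e-10) {
  X <- as.matrix(X)
  n <- nrow(X)
  xm <- colMeans(X); xs <- apply(X, 2, stats::sd)
  xs[xs == 0] <- 1
  Xs <- sweep(sweep(X, 2, xm, "-"), 2, xs, "/")
  ym <- mean(y)
  yc <- y - ym
  # SVD form keeps the updates stable for ill-conditioned designs
  sv <- svd(Xs)
  d2 <- sv$d^2
  uty <- as.vector(crossprod(sv$u, yc))
  alpha <- 1e-6
  beta <- 1 / max(stats::var(yc), 1e-12)
  w <- NULL
  for (it in seq_len(max_iter)) {
    shrink <- sv$d / (alpha / beta + d2)
    w_new <- as.vector(sv$v %*% (shrink * uty))
    gamma_eff <- sum(d2 / (alpha / beta + d2))
    alpha <- gamma_eff / max(sum(w_new^2), 1e-12)
    resid <- yc - Xs %*% w_new
    beta <- max(n - gamma_eff, 1e-6) / max(sum(resid^2), 1e-12)
    done <- !is.null(w) && max(abs(w_new - w)) < tol * max(1, max(abs(w)))
    w <- w_new
    if (done) break
  }
  list(w = w, xm = xm, xs = xs, ym = ym)
}

bayes_ridge_predict <- function(fit, X) {
  Xs <- sweep(sweep(as.matrix(X), 2, fit$xm, "-"), 2, fit$xs, "/")
  as.vector(Xs %*% fit$w) + fit$ym
}

# Fit one model family on (X, y), choosing hyperparameters on the
# validation split by RMSE. Returns a predict(X) closure.
.fit_regressor <- function(name, Xtr, ytr, Xval, yval, seed) {
  rmse <- function(a, b) sqrt(mean((a - b)^2))
  scale_fit <- function(X) {
    m <- colMeans(X); s <- apply(X, 2, stats::sd); s[s == 0] <- 1
    list(m = m, s = s)
  }
  apply_scale <- function(X, sc) sweep(sweep(X, 2, sc$m, "-"), 2, sc$s, "/")
  have_val <- !is.null(Xval) && nrow(Xval) >= 1L
  pick_best <- function(fits) {
    if (!have_val || length(fits) == 1L) return(fits[[1]])
    errs <- vapply(fits, function(f) rmse(f$predict(Xval), yval), numeric(1))
    fits[[which.min(errs)]]
  }
  switch(name,
    mlp = {
      sc <- scale_fit(Xtr)
      ym <- mean(ytr); ys <- stats::sd(ytr); if (ys == 0) ys <- 1
      grid <- expand.grid(size = c(4, 8), decay = c(1e-4, 1e-2))
      fits <- lapply(seq_len(nrow(grid)), function(i) {
        set.seed(seed + i)
        fit <- nnet::nnet(apply_scale(Xtr, sc), (ytr - ym) / ys,
                          size = grid$size[i], decay = grid$decay[i],
                          linout = TRUE, skip = TRUE, maxit = 2000,
                          trace = FALSE)
        list(predict = function(X)
          as.vector(stats::predict(fit, apply_scale(X, sc))) * ys + ym)
      })
      pick_best(fits)
    },
    svr_rbf = {
      grid <- expand.grid(cost = c(1, 10, 100), gamma = c(0.1, 0.5, 2))
      sc <- scale_fit(Xtr)
      fits <- lapply(seq_len(nrow(grid)), function(i) {
        fit <- e1071::svm(apply_scale(Xtr, sc), ytr, type = "eps-regression",
                          kernel = "radial", cost = grid$cost[i],
                          gamma = grid$gamma[i], epsilon = 0.01,
                          scale = FALSE)
        list(predict = function(X)
          as.vector(stats::predict(fit, apply_scale(X, sc))))
      })
      pick_best(fits)
    },
    bayes = {
      fit <- bayes_ridge_fit(Xtr, ytr)
      list(predict = function(X) bayes_ridge_predict(fit, X))
    },
    lgbm = {
      grid <- expand.grid(nrounds = c(200, 500), eta = c(0.05, 0.1))
      fits <- lapply(seq_len(nrow(grid)), function(i) {
        fit <- xgboost::xgboost(
          Xtr, ytr, nrounds = grid$nrounds[i],
          learning_rate = grid$eta[i], tree_method = "hist",
          grow_policy = "lossguide", max_depth = 0, max_leaves = 31,
          min_child_weight = 2, nthreads = 1, seed = seed, verbosity = 0)
        list(predict = function(X) as.vector(stats::predict(fit, X)))
      })
      pick_best(fits)
    },
    catboost = {
      grid <- expand.grid(nrounds = c(300, 600), max_depth = c(4, 6))
      fits <- lapply(seq_len(nrow(grid)), function(i) {
        fit <- xgboost::xgboost(
          Xtr, ytr, nrounds = grid$nrounds[i], learning_rate = 0.05,
          tree_method = "hist", grow_policy = "depthwise",
          max_depth = grid$max_depth[i], min_child_weight = 2,
          nthreads = 1, seed = seed, verbosity = 0)
        list(predict = function(X) as.vector(stats::predict(fit, X)))
      })
      pick_best(fits)
    },
    stop("unknown model '", name, "'; supported: ",
         paste(REGRESSION_MODELS, collapse = ", "))
  )
}

#' Fit and evaluate a weight regressor
#'
#' Fits the requested model family on the training carcasses, selects
#' hyperparameters on the validation carcasses, and reports test-split
#' R^2 = 1 - SSres/SStot and RMSE, with optional percentile bootstrap
#' confidence intervals.
#'
#' @param table A [assemble_features()] table.
#' @param model One of `"mlp"`, `"svr_rbf"`, `"bayes"`, `"lgbm"`,
#'   `"catboost"`.
#' @param split A [build_split()] manifest over the table's carcass ids.
#' @param seed Integer seed.
#' @param bootstrap_B Bootstrap resamples for CIs (0 disables).
#' @return Object of class `regression_result`: a list with `model`,
#'   `mod`, `r2`, `rmse`, `ci_r2`, `ci_rmse`, `n_test`, `y_true`,
#'   `y_pred`, `outliers`.
#' @export
fit_and_evaluate <- function(table, model, split, seed = 1L,
                             bootstrap_B = 1000) {
  if (!model %in% REGRESSION_MODELS)
    stop("unknown model '", model, "'; supported: ",
         paste(REGRESSION_MODELS, collapse = ", "))
  feat_cols <- c("area_ventral", "area_lateral", "area_dorsal")
  subset_of <- split$subset[match(table$carcass_id, split$carcass_id)]
  if (anyNA(subset_of))
    stop("split manifest is missing carcass ids present in the table")
  tr <- table[subset_of == "train", , drop = FALSE]
  va <- table[subset_of == "val", , drop = FALSE]
  te <- table[subset_of == "test", , drop = FALSE]
  if (nrow(tr) == 0L || nrow(te) == 0L)
    stop("train and test splits must be non-empty")
  Xtr <- as.matrix(tr[, feat_cols]); ytr <- tr$target
  Xva <- if (nrow(va)) as.matrix(va[, feat_cols]) else NULL
  Xte <- as.matrix(te[, feat_cols])
  reg <- .fit_regressor(model, Xtr, ytr, Xva, va$target, seed)
  pred <- reg$predict(Xte)
  y <- te$target
  ss_res <- sum((y - pred)^2)
  ss_tot <- sum((y - mean(y))^2)
  r2 <- if (ss_tot == 0) NA_real_ else 1 - ss_res / ss_tot
  rmse <- sqrt(mean((y - pred)^2))
  ci <- if (bootstrap_B > 0 && length(y) >= 5) {
    bootstrap_ci(y, pred, B = bootstrap_B, seed = seed)
  } else {
    list(ci_r2 = c(NA_real_, NA_real_), ci_rmse = c(NA_real_, NA_real_))
  }
  out <- list(model = model, mod = attr(table, "mod") %||% NA_character_,
              r2 = r2, rmse = rmse, ci_r2 = ci$ci_r2,
              ci_rmse = ci$ci_rmse, n_test = length(y), y_true = y,
              y_pred = pred,
              outliers = if (length(y) >= 2) residual_outliers(y, pred)
                         else NULL)
  class(out) <- "regression_result"
  out
}

#' @export
print.regression_result <- function(x, ...) {
  cat(sprintf("%s on %s: R2 = %.4f, RMSE = %.2f g (n_test = %d)\n",
              x$model, x$mod, x$r2, x$rmse, x$n_test))
  if (!anyNA(x$ci_r2))
    cat(sprintf("  95%% CI  R2 [%.4f, %.4f]  RMSE [%.2f, %.2f]\n",
                x$ci_r2[1], x$ci_r2[2], x$ci_rmse[1], x$ci_rmse[2]))
  invisible(x)
}

#' Percentile bootstrap confidence intervals for R^2 and RMSE
#'
#' Resamples (truth, prediction) pairs with replacement `B` times and
#' takes the percentile interval of the resampled statistics.
#'
#' @param y_true,y_pred Paired observations (length >= 5).
#' @param B Number of resamples.
#' @param level Confidence level.
#' @param seed Integer seed.
#' @return List with `ci_r2` and `ci_rmse`, each `c(lo, hi)`.
#' @export
bootstrap_ci <- function(y_true, y_pred, B = 1000, level = 0.95,
                         seed = 1L) {
  n <- length(y_true)
  if (n < 5) stop("bootstrap CI requires at least 5 paired observations")
  stopifnot(length(y_pred) == n)
  set.seed(seed)
  r2s <- numeric(B); rmses <- numeric(B)
  for (b in seq_len(B)) {
    idx <- sample.int(n, n, replace = TRUE)
    yt <- y_true[idx]; yp <- y_pred[idx]
    ss_res <- sum((yt - yp)^2)
    ss_tot <- sum((yt - mean(yt))^2)
    r2s[b] <- if (ss_tot == 0) { if (ss_res == 0) 1 else -Inf }
              else 1 - ss_res / ss_tot
    rmses[b] <- sqrt(mean((yt - yp)^2))
  }
  probs <- c((1 - level) / 2, 1 - (1 - level) / 2)
  list(ci_r2 = unname(stats::quantile(r2s, probs, type = 7)),
       ci_rmse = unname(stats::quantile(rmses, probs, type = 7)))
}

#' Flag residual outliers beyond two residual standard deviations
#'
#' Residuals are `actual - predicted`; sigma is their sample standard
#' deviation (n - 1 denominator). Points with `|residual| > 2 sigma` are
#' flagged; with sigma = 0 nothing is flagged.
#'
#' @param y_true,y_pred Paired observations (length >= 2).
#' @return List with `residuals`, `sigma`, `flags` (logical) and `rate`.
#' @export
residual_outliers <- function(y_true, y_pred) {
  if (length(y_true) < 2) stop("residual outliers require length >= 2")
  stopifnot(length(y_pred) == length(y_true))
  r <- y_true - y_pred
  sigma <- stats::sd(r)
  flags <- if (sigma == 0) rep(FALSE, length(r)) else abs(r) > 2 * sigma
  list(residuals = r, sigma = sigma, flags = flags, rate = mean(flags))
}
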