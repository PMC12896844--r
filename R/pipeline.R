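# End-to-end orchestration: synth -> split -> train -> eval -> segment ->
# refine -> measure -> regress -> report. Every stage is a pure function of
# (inputs, config, seed); outputs are written under cfg$out_dir with a
# manifest recording the config digest, seed and package version.

#' Desk-scale pipeline configuration
#'
#' @param out_dir Output directory.
#' @param seed Integer seed propagated to every stage.
#' @param n_carcasses Number of synthetic carcasses.
#' @param replicates Images per view.
#' @param canvas Image canvas (desk-scale default 64 x 64).
#' @param net Named list of [net_config()] overrides.
#' @param train Named list of [train_config()] overrides.
#' @param se_radius Structuring-element radius for mask refinement (the
#'   production default of 5 px at 640 px inputs is scaled with the
#'   canvas).
#' @param mods Mods to regress.
#' @param models Regression families to fit.
#' @param weights_csv Optional external weights table (columns of
#'   [assign_weights()]); must exist if given.
#' @param bootstrap_B Bootstrap resamples for regression CIs.
#' @return Named list of class `run_config`.
#' @export
run_config <- function(out_dir, seed = 1L, n_carcasses = 12,
                       replicates = 1, canvas = c(64, 64),
                       net = list(depth = 3, base_width = 8),
                       train = list(epochs = 4, batch_size = 4,
                                    lr = 0.003),
                       se_radius = NULL, mods = c("Mod1", "Mod2"),
                       models = c("bayes", "catboost"),
                       weights_csv = NULL, bootstrap_B = 200) {
  if (is.null(se_radius))
    se_radius <- max(1L, round(5 * min(canvas) / 640))
  structure(list(out_dir = out_dir, seed = seed,
                 n_carcasses = n_carcasses, replicates = replicates,
                 canvas = canvas, net = net, train = train,
                 se_radius = se_radius, mods = mods, models = models,
                 weights_csv = weights_csv, bootstrap_B = bootstrap_B),
            class = "run_config")
}

# Small polynomial digest of a serialized object, for provenance stamps.
config_digest <- function(x) {
  bytes <- as.integer(serialize(x, NULL, version = 2))
  h <- 0
  for (b in bytes) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", h)
}

# Desk-scale geometry leaves headroom for the generator's scale and
# part-shape jitter at its upper clamp.
.desk_spec <- function(canvas, px_per_cm = 2) {
  k <- min(canvas) / 64
  carcass_spec(torso_a = 11 * k, torso_b = 7.2 * k, head_r = 3.8 * k,
               leg_len = 12.8 * k, leg_w = 3.6 * k, sigma_pos = 0.4 * k,
               sigma_tex = 8, px_per_cm = px_per_cm * k, canvas = canvas)
}

.load_samples <- function(manifest, rows) {
  lapply(rows, function(i) list(
    image = read_view_image(manifest$image[i]),
    mask = read_mask(manifest$mask[i])))
}

#' Run the full pipeline
#'
#' Generates a synthetic dataset, builds the carcass-wise split, trains
#' the segmentation network, evaluates it on the held-out test carcasses,
#' segments every image, refines the predicted masks morphologically,
#' measures calibrated areas, fits the weight regressions, and writes a
#' report bundle under `cfg$out_dir`. Reruns with identical config and
#' seed produce identical artifacts.
#'
#' @param cfg A [run_config()].
#' @param verbose Log per-stage progress to stderr.
#' @return The report list (also written as `report.json`), invisibly.
#' @export
run_pipeline <- function(cfg, verbose = FALSE) {
  stage <- "init"
  say <- function(...) if (verbose) message("[", stage, "] ", ...)
  result <- tryCatch({
    if (!is.null(cfg$weights_csv) && !file.exists(cfg$weights_csv))
      stop("weights CSV not found: ", cfg$weights_csv)
    dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)

    stage <- "synth"
    say("generating ", cfg$n_carcasses, " carcasses")
    ds <- generate_dataset(cfg$n_carcasses, replicates = cfg$replicates,
                           seed = cfg$seed,
                           dir = file.path(cfg$out_dir, "images"),
                           write_images = TRUE,
                           spec_defaults = .desk_spec(cfg$canvas))
    # manifest on disk holds paths relative to out_dir so identical runs
    # in different directories stay byte-identical
    man_rel <- ds$manifest
    man_rel$image <- file.path("images", basename(man_rel$image))
    man_rel$mask <- file.path("images", basename(man_rel$mask))
    utils::write.csv(man_rel, file.path(cfg$out_dir, "manifest.csv"),
                     row.names = FALSE)
    weights <- if (!is.null(cfg$weights_csv)) {
      utils::read.csv(cfg$weights_csv, stringsAsFactors = FALSE)
    } else {
      ds$weights
    }
    utils::write.csv(weights, file.path(cfg$out_dir, "weights.csv"),
                     row.names = FALSE)

    stage <- "split"
    split <- build_split(unique(ds$manifest$carcass_id), seed = cfg$seed)
    utils::write.csv(split, file.path(cfg$out_dir, "split.csv"),
                     row.names = FALSE)

    stage <- "train"
    net_args <- utils::modifyList(
      list(n_classes = 4, input_size = min(cfg$canvas)), cfg$net)
    model <- build_model(do.call(net_config, net_args), seed = cfg$seed)
    train_args <- utils::modifyList(
      list(input_size = min(cfg$canvas), seed = cfg$seed), cfg$train)
    tcfg <- do.call(train_config, train_args)
    rows_of <- function(subset) which(ds$manifest$carcass_id %in%
                                        split_ids(split, subset))
    train_samples <- .load_samples(ds$manifest, rows_of("train"))
    val_samples <- .load_samples(ds$manifest, rows_of("val"))
    say(length(train_samples), " training images")
    history <- train_model(model, train_samples,
                           if (length(val_samples)) val_samples else NULL,
                           tcfg)
    utils::write.csv(as.data.frame(history),
                     file.path(cfg$out_dir, "history.csv"),
                     row.names = FALSE)
    save_checkpoint(model, file.path(cfg$out_dir, "checkpoint.rds"),
                    meta = list(epochs = tcfg$epochs))

    stage <- "eval"
    test_samples <- .load_samples(ds$manifest, rows_of("test"))
    ev <- evaluate_model(model, test_samples)
    seg_df <- data.frame(metric = c("miou", "mean_dice", "mean_f1"),
                         value = c(ev$miou, ev$mean_dice, ev$mean_f1))
    utils::write.csv(seg_df, file.path(cfg$out_dir, "seg_metrics.csv"),
                     row.names = FALSE)

    stage <- "segment"
    pred_dir <- file.path(cfg$out_dir, "pred_masks")
    dir.create(pred_dir, showWarnings = FALSE)
    se <- structuring_element("disc", cfg$se_radius)
    areas_rows <- vector("list", nrow(ds$manifest))
    stage <- "measure"
    for (i in seq_len(nrow(ds$manifest))) {
      img <- read_view_image(ds$manifest$image[i])
      pred <- predict_mask(model, img)
      pred <- refine_mask(pred, se)
      mp <- file.path(pred_dir, basename(ds$manifest$mask[i]))
      write_mask(pred, mp)
      areas_rows[[i]] <- measure_areas(pred, ds$manifest$px_per_cm[i],
                                       carcass_id = ds$manifest$carcass_id[i],
                                       view = ds$manifest$view[i],
                                       replicate = ds$manifest$replicate[i])
    }
    areas <- do.call(rbind, areas_rows)
    utils::write.csv(areas, file.path(cfg$out_dir, "areas.csv"),
                     row.names = FALSE)

    stage <- "regress"
    reg_rows <- list()
    for (mod in cfg$mods) for (mdl in cfg$models) {
      tab <- assemble_features(areas, weights, mod)
      res <- fit_and_evaluate(tab, mdl, split, seed = cfg$seed,
                              bootstrap_B = cfg$bootstrap_B)
      reg_rows[[paste(mod, mdl)]] <- data.frame(
        mod = mod, model = mdl, r2 = res$r2, rmse = res$rmse,
        ci_r2_lo = res$ci_r2[1], ci_r2_hi = res$ci_r2[2],
        ci_rmse_lo = res$ci_rmse[1], ci_rmse_hi = res$ci_rmse[2],
        n_test = res$n_test)
    }
    reg_df <- do.call(rbind, reg_rows)
    rownames(reg_df) <- NULL
    utils::write.csv(reg_df, file.path(cfg$out_dir, "regression.csv"),
                     row.names = FALSE)

    stage <- "report"
    report <- list(
      config_digest = config_digest(unclass(cfg)),
      seed = cfg$seed,
      version = as.character(utils::packageVersion("ccwpipe")),
      segmentation = as.list(stats::setNames(seg_df$value, seg_df$metric)),
      regression = reg_df,
      n_images = nrow(ds$manifest))
    jsonlite::write_json(report, file.path(cfg$out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    report
  }, error = function(e) {
    stop("pipeline failed at stage '", stage, "': ", conditionMessage(e),
         call. = FALSE)
  })
  invisible(result)
}

#' Read a pipeline configuration from YAML
#'
#' Keys mirror the arguments of [run_config()]; unknown keys are
#' rejected.
#'
#' @param path YAML file path.
#' @param overrides Named list of values overriding the file.
#' @return A [run_config()].
#' @export
read_run_config <- function(path, overrides = list()) {
  raw <- yaml::read_yaml(path)
  known <- names(formals(run_config))
  bad <- setdiff(names(raw), known)
  if (length(bad))
    stop("unknown config keys: ", paste(bad, collapse = ", "))
  args <- utils::modifyList(raw, overrides)
  do.call(run_config, args)
}
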