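# Procedural synthetic carcass generator.
#
# Each carcass is a union of analytic primitives on a dark canvas: a torso
# ellipse, a head disc and two leg capsules, laid out as a suspended carcass
# (hung by the shanks, head down). Parts are placed tangent but disjoint, so
# every per-part area has a closed form and rasterized masks can be checked
# against a per-pixel membership oracle. A pixel belongs to a part iff its
# center lies strictly inside the analytic shape; overlap (possible only
# after morphological processing) is resolved by the priority
# torso < leg < head.

#' Synthetic carcass specification
#'
#' Geometry is given in pixels at scale `s = 1`; linear dimensions scale
#' with `s`, areas with `s^2`. The calibration `px_per_cm` converts pixel
#' counts to cm^2 and is carried through the manifest.
#'
#' @param carcass_id Identifier string.
#' @param s Dimensionless global scale, > 0.
#' @param torso_a,torso_b Torso ellipse semi-axes (px): horizontal,
#'   vertical.
#' @param head_r Head disc radius (px).
#' @param leg_len,leg_w Leg capsule segment length and capsule width (px).
#' @param views Subset of ventral/dorsal/lateral.
#' @param sigma_pos Replicate re-hanging jitter (px, standard deviation of
#'   a global translation).
#' @param sigma_tex Texture noise (intensity units).
#' @param px_per_cm Calibration (px per cm), > 0.
#' @param canvas `c(H, W)` canvas in pixels.
#' @return Object of class `carcass_spec`.
#' @export
carcass_spec <- function(carcass_id = "C001", s = 1, torso_a = 70,
                         torso_b = 45, head_r = 24, leg_len = 80,
                         leg_w = 22,
                         views = c("ventral", "dorsal", "lateral"),
                         sigma_pos = 1.5, sigma_tex = 8, px_per_cm = 10,
                         canvas = c(320, 256)) {
  geom <- c(s = s, torso_a = torso_a, torso_b = torso_b, head_r = head_r,
            leg_len = leg_len, leg_w = leg_w, px_per_cm = px_per_cm)
  for (nm in names(geom)) {
    if (!is.finite(geom[[nm]]) || geom[[nm]] <= 0)
      stop("carcass geometry must be strictly positive: ", nm, " = ",
           geom[[nm]])
  }
  views <- match.arg(views, c("ventral", "dorsal", "lateral"),
                     several.ok = TRUE)
  if (length(views) < 1L) stop("views must be non-empty")
  stopifnot(sigma_pos >= 0, sigma_tex >= 0, length(canvas) == 2L)
  structure(list(carcass_id = carcass_id, s = s, torso_a = torso_a,
                 torso_b = torso_b, head_r = head_r, leg_len = leg_len,
                 leg_w = leg_w, views = views, sigma_pos = sigma_pos,
                 sigma_tex = sigma_tex, px_per_cm = px_per_cm,
                 canvas = as.integer(canvas)),
            class = "carcass_spec")
}

# Per-view shape layout. Returns the analytic shapes (in px, unjittered)
# and closed-form per-part areas in cm^2.
view_geometry <- function(spec, view) {
  s <- spec$s
  a <- spec$torso_a * s
  b <- spec$torso_b * s
  r <- spec$head_r * s
  L <- spec$leg_len * s
  w <- spec$leg_w * s
  mult <- switch(view,
    ventral = list(ax = 1, by = 1, head_dx = 0, leg_off = 0.45,
                   leg_angle = 12),
    dorsal = list(ax = 1, by = 0.95, head_dx = 0, leg_off = 0.42,
                  leg_angle = 10),
    lateral = list(ax = 0.78, by = 1.12, head_dx = 0.35, leg_off = 0.25,
                   leg_angle = 5))
  av <- a * mult$ax
  bv <- b * mult$by
  H <- spec$canvas[1]; W <- spec$canvas[2]
  leg_vert <- L * cospi(mult$leg_angle / 180)
  leg_horiz <- L * sinpi(mult$leg_angle / 180)
  # vertical layout: legs (top), torso, head (bottom), centered on canvas
  total_h <- (L * 1 + w) + 2 * bv + 2 * r  # upper bound on extent
  cy <- (H - total_h) / 2 + w / 2 + leg_vert + bv
  cx <- W / 2
  # keep the two capsules disjoint even under part-shape jitter so leg
  # area stays a closed form (2 disjoint capsules)
  off <- max(mult$leg_off * av, 0.55 * w)
  if (2 * off < w)
    stop("leg capsules overlap: leg_w = ", w, " exceeds separation ",
         2 * off, " in ", view, " view")
  legs <- lapply(c(-1, 1), function(sgn) {
    x0 <- cx + sgn * off
    y0 <- cy - bv - w / 2
    list(x0 = x0, y0 = y0, x1 = x0 + sgn * leg_horiz, y1 = y0 - leg_vert,
         w = w)
  })
  head <- list(x = cx + mult$head_dx * av, y = cy + bv + r, r = r)
  shapes <- list(torso = list(cx = cx, cy = cy, a = av, b = bv),
                 head = head, legs = legs)
  ppc2 <- spec$px_per_cm^2
  areas <- c(torso = pi * av * bv / ppc2,
             head = pi * r^2 / ppc2,
             leg = 2 * (L * w + pi * (w / 2)^2) / ppc2)
  extent <- list(
    top = legs[[1]]$y1 - w / 2,
    bottom = head$y + r,
    left = min(cx - av, legs[[1]]$x1 - w / 2),
    right = max(cx + av, legs[[2]]$x1 + w / 2, head$x + r)
  )
  list(shapes = shapes, areas_cm2 = areas, extent = extent)
}

.check_fit <- function(spec, geo, view) {
  H <- spec$canvas[1]; W <- spec$canvas[2]
  margin <- 4 * spec$sigma_pos + 1
  ex <- geo$extent
  if (ex$top < margin || ex$bottom > H - margin)
    stop("geometry does not fit the canvas vertically in ", view,
         " view (leg_len/torso_b/head_r too large for canvas height ", H,
         ")")
  if (ex$left < margin || ex$right > W - margin)
    stop("geometry does not fit the canvas horizontally in ", view,
         " view (torso_a/leg_w too large for canvas width ", W, ")")
}

# Membership of pixel centers in the analytic shapes, given a global
# translation (dx, dy). px, py are vectors of pixel-center coordinates.
shape_membership <- function(shapes, px, py, dx = 0, dy = 0) {
  to <- shapes$torso
  torso <- ((px - to$cx - dx) / to$a)^2 + ((py - to$cy - dy) / to$b)^2 < 1
  hd <- shapes$head
  head <- (px - hd$x - dx)^2 + (py - hd$y - dy)^2 < hd$r^2
  leg <- rep(FALSE, length(px))
  for (lg in shapes$legs) {
    vx <- lg$x1 - lg$x0; vy <- lg$y1 - lg$y0
    len2 <- vx^2 + vy^2
    tt <- pmin(1, pmax(0, ((px - lg$x0 - dx) * vx + (py - lg$y0 - dy) * vy) /
                         len2))
    d2 <- (px - lg$x0 - dx - tt * vx)^2 + (py - lg$y0 - dy - tt * vy)^2
    leg <- leg | (d2 < (lg$w / 2)^2)
  }
  list(torso = torso, head = head, leg = leg)
}

# Rasterize one view into a label matrix under the priority
# torso < leg < head (later paints win).
rasterize_view <- function(spec, shapes, dx = 0, dy = 0) {
  H <- spec$canvas[1]; W <- spec$canvas[2]
  px <- rep(seq_len(W) - 0.5, each = H)
  py <- rep(seq_len(H) - 0.5, times = W)
  mem <- shape_membership(shapes, px, py, dx, dy)
  lab <- matrix(0L, H, W)
  lab[matrix(mem$torso, H, W)] <- 1L
  lab[matrix(mem$leg, H, W)] <- 3L
  lab[matrix(mem$head, H, W)] <- 2L
  lab
}

# Small deterministic per-carcass seed derivation (kept below 2^31).
derive_seed <- function(seed, k) {
  (as.numeric(seed) * 7919 + as.numeric(k) * 104729) %% 2147483646 + 1
}

#' Generate one synthetic carcass (images, masks, analytic areas)
#'
#' For each requested view, renders `replicates` images (dark background,
#' brighter foreground, optional texture noise) and ground-truth label
#' masks. Each replicate re-hangs the carcass with a random global
#' translation of standard deviation `sigma_pos`. With `sigma_pos = 0` and
#' `sigma_tex = 0` the replicates of a view are pixel-identical.
#'
#' @param spec A [carcass_spec()].
#' @param seed Integer seed.
#' @param replicates Images per view.
#' @param bg_mean,fg_mean Background and foreground mean intensities.
#' @return List with one element per view: `replicates` (list of
#'   `list(image, mask)`), `areas_cm2` (closed-form per-part areas) and
#'   `shapes`.
#' @export
generate_carcass <- function(spec, seed = 1L, replicates = 3,
                             bg_mean = 20, fg_mean = 180) {
  stopifnot(inherits(spec, "carcass_spec"))
  H <- spec$canvas[1]; W <- spec$canvas[2]
  set.seed(derive_seed(seed, 0))
  out <- list()
  for (view in spec$views) {
    geo <- view_geometry(spec, view)
    .check_fit(spec, geo, view)
    reps <- vector("list", replicates)
    for (rep_i in seq_len(replicates)) {
      shift <- if (spec$sigma_pos > 0) {
        stats::rnorm(2, 0, spec$sigma_pos)
      } else {
        c(0, 0)
      }
      mask <- rasterize_view(spec, geo$shapes, shift[1], shift[2])
      img <- matrix(bg_mean, H, W)
      img[mask > 0L] <- fg_mean
      if (spec$sigma_tex > 0)
        img <- img + matrix(stats::rnorm(H * W, 0, spec$sigma_tex), H, W)
      img <- pmin(pmax(round(img), 0), 255)
      reps[[rep_i]] <- list(image = array(rep(img, 3), c(H, W, 3L)),
                            mask = label_mask(mask))
    }
    out[[view]] <- list(replicates = reps, areas_cm2 = geo$areas_cm2,
                        shapes = geo$shapes)
  }
  attr(out, "spec") <- spec
  out
}

#' Allometric weight model
#'
#' Weights are a noisy linear function of mean-over-view part areas:
#' `total = beta0 + sum_p beta_p * A_p + N(0, sigma_w)`. Part weights are
#' generated analogously, with fixed weight shares scaling the intercept
#' and the noise, so every part sees a comparable signal-variance fraction.
#'
#' @param beta0 Intercept (g).
#' @param betas Named per-part slopes (g per cm^2) for torso, head, leg.
#' @param sigma_w Total-weight noise standard deviation (g), >= 0. The
#'   default is calibrated so the default dataset generator yields a
#'   signal-variance fraction of about 0.9 in total weight.
#' @param shares Named part shares of intercept and noise (sum to 1).
#' @return Object of class `weight_model`.
#' @export
weight_model <- function(beta0 = 150,
                         betas = c(torso = 9, head = 3, leg = 3),
                         sigma_w = 61,
                         shares = c(torso = 0.82, head = 0.05, leg = 0.13)) {
  if (sigma_w < 0) stop("sigma_w must be >= 0")
  stopifnot(setequal(names(betas), c("torso", "head", "leg")),
            abs(sum(shares) - 1) < 1e-8)
  structure(list(beta0 = beta0, betas = betas, sigma_w = sigma_w,
                 shares = shares),
            class = "weight_model")
}

#' Assign weights to a carcass from its true areas
#'
#' @param areas_cm2 Either a part x view numeric matrix (rows named torso /
#'   head / leg) or a named per-part vector of mean areas in cm^2. All
#'   areas must be non-negative.
#' @param model A [weight_model()].
#' @param seed Integer seed (noise draw).
#' @param carcass_id Identifier copied into the record.
#' @return A one-row data.frame (class `carcass_record`) with columns
#'   `carcass_id`, `weight_total_g`, `weight_carcass_g`, `weight_head_g`,
#'   `weight_leg_g` and `clamped`.
#' @export
assign_weights <- function(areas_cm2, model = weight_model(), seed = 1L,
                           carcass_id = "C001") {
  if (is.matrix(areas_cm2)) areas_cm2 <- rowMeans(areas_cm2)
  parts <- c("torso", "head", "leg")
  stopifnot(all(parts %in% names(areas_cm2)))
  a <- areas_cm2[parts]
  if (any(a < 0)) stop("negative area: ", paste(parts[a < 0], collapse = ", "))
  set.seed(derive_seed(seed, 1))
  sh <- model$shares[parts]
  det_part <- model$beta0 * sh + model$betas[parts] * a
  noise_part <- if (model$sigma_w > 0) {
    stats::rnorm(3, 0, model$sigma_w * sh)
  } else {
    numeric(3)
  }
  det_total <- model$beta0 + sum(model$betas[parts] * a)
  noise_total <- if (model$sigma_w > 0) stats::rnorm(1, 0, model$sigma_w) else 0
  w <- c(total = det_total + noise_total, det_part + noise_part)
  clamped <- w < 0
  if (any(clamped))
    warning("clamped negative weights to 0 for: ",
            paste(names(w)[clamped], collapse = ", "))
  w <- pmax(w, 0)
  out <- data.frame(carcass_id = carcass_id,
                    weight_total_g = w[["total"]],
                    weight_carcass_g = w[["torso"]],
                    weight_head_g = w[["head"]],
                    weight_leg_g = w[["leg"]],
                    clamped = any(clamped),
                    stringsAsFactors = FALSE)
  class(out) <- c("carcass_record", "data.frame")
  out
}

#' Generate a synthetic carcass dataset
#'
#' Draws per-carcass global scales and per-part shape multipliers, lays out
#' every view, records closed-form per-part areas and noisy linear weights,
#' and (optionally) renders images and ground-truth masks to disk. The
#' manifest has one row per (carcass, view, replicate).
#'
#' @param n_carcasses Number of carcasses, >= 1.
#' @param views Views to generate.
#' @param replicates Images per view.
#' @param seed Integer seed; identical seeds give byte-identical outputs.
#' @param dir Output directory for images/masks (required when
#'   `write_images = TRUE`).
#' @param write_images Render and write PNG images and masks.
#' @param spec_defaults A [carcass_spec()] providing base geometry, canvas,
#'   jitter and calibration.
#' @param s_mean,s_sd Mean and sd of the per-carcass global scale
#'   (truncated to `[0.75, 1.3]`).
#' @param part_jitter_sd Log-normal sd of per-part shape multipliers
#'   (breaks exact collinearity between part areas, as real birds vary in
#'   proportions).
#' @param wmodel A [weight_model()].
#' @return List of class `carcass_dataset` with elements `manifest`,
#'   `weights`, `areas` (closed-form, one row per carcass x view x part),
#'   `specs` and `px_per_cm`.
#' @export
generate_dataset <- function(n_carcasses, views = c("ventral", "dorsal",
                                                    "lateral"),
                             replicates = 3, seed = 1L, dir = NULL,
                             write_images = FALSE,
                             spec_defaults = carcass_spec(),
                             s_mean = 1, s_sd = 0.08,
                             part_jitter_sd = 0.05,
                             wmodel = weight_model()) {
  if (n_carcasses < 1) stop("n_carcasses must be >= 1")
  if (write_images && is.null(dir))
    stop("dir is required when write_images = TRUE")
  if (!is.null(dir)) dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  set.seed(derive_seed(seed, 2))
  ids <- sprintf("C%04d", seq_len(n_carcasses))
  s_draw <- pmin(pmax(stats::rnorm(n_carcasses, s_mean, s_sd), 0.75), 1.3)
  part_mult <- matrix(exp(stats::rnorm(3 * n_carcasses, 0, part_jitter_sd)),
                      n_carcasses, 3,
                      dimnames = list(NULL, c("torso", "head", "leg")))
  specs <- vector("list", n_carcasses)
  areas_rows <- vector("list", n_carcasses)
  weights <- vector("list", n_carcasses)
  manifest_rows <- vector("list", n_carcasses)
  for (i in seq_len(n_carcasses)) {
    sp <- spec_defaults
    sp$carcass_id <- ids[i]
    sp$s <- s_draw[i]
    sp$torso_a <- sp$torso_a * part_mult[i, "torso"]
    sp$torso_b <- sp$torso_b * part_mult[i, "torso"]
    sp$head_r <- sp$head_r * part_mult[i, "head"]
    sp$leg_len <- sp$leg_len * part_mult[i, "leg"]
    sp$leg_w <- sp$leg_w * part_mult[i, "leg"]
    sp$views <- views
    specs[[i]] <- sp
    geo <- lapply(views, function(v) view_geometry(sp, v))
    names(geo) <- views
    areas_mat <- vapply(geo, function(g) g$areas_cm2,
                        c(torso = 0, head = 0, leg = 0))
    areas_rows[[i]] <- data.frame(
      carcass_id = ids[i],
      view = rep(views, each = 3),
      part = rep(c("torso", "head", "leg"), times = length(views)),
      area_cm2 = as.vector(areas_mat),
      stringsAsFactors = FALSE)
    weights[[i]] <- assign_weights(areas_mat, wmodel,
                                   seed = derive_seed(seed, 100 + i),
                                   carcass_id = ids[i])
    mrow <- expand.grid(replicate = seq_len(replicates), view = views,
                        stringsAsFactors = FALSE)
    manifest_rows[[i]] <- data.frame(
      carcass_id = ids[i], view = mrow$view, replicate = mrow$replicate,
      image = NA_character_, mask = NA_character_,
      px_per_cm = sp$px_per_cm, stringsAsFactors = FALSE)
  }
  manifest <- do.call(rbind, manifest_rows)
  if (write_images) {
    for (i in seq_len(n_carcasses)) {
      car <- generate_carcass(specs[[i]], seed = derive_seed(seed, 200 + i),
                              replicates = replicates)
      for (v in views) for (r in seq_len(replicates)) {
        stub <- sprintf("%s_%s_r%d", ids[i], v, r)
        ip <- file.path(dir, paste0(stub, ".png"))
        mp <- file.path(dir, paste0(stub, "_mask.png"))
        write_view_image(car[[v]]$replicates[[r]]$image, ip)
        write_mask(car[[v]]$replicates[[r]]$mask, mp)
        sel <- manifest$carcass_id == ids[i] & manifest$view == v &
          manifest$replicate == r
        manifest$image[sel] <- ip
        manifest$mask[sel] <- mp
      }
    }
  }
  structure(list(manifest = manifest,
                 weights = do.call(rbind, weights),
                 areas = do.call(rbind, areas_rows),
                 specs = specs,
                 px_per_cm = spec_defaults$px_per_cm,
                 seed = seed),
            class = "carcass_dataset")
}
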