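# Label masks, Labelme polygon annotations, carcass-wise splits, and
# single-channel PNG mask serialization.

#' Default part label set
#'
#' @return Named integer vector mapping part names to mask labels.
#' @export
default_class_map <- function() {
  c(background = 0L, torso = 1L, head = 2L, leg = 3L)
}

#' Label mask constructor
#'
#' A per-pixel part-label matrix with its class map. Every label occurring
#' in the matrix must be present in the class map.
#'
#' @param labels Integer matrix `H x W`.
#' @param class_map Named integer vector (label values must be unique).
#' @return Object of class `label_mask` (an integer matrix with a
#'   `class_map` attribute).
#' @export
label_mask <- function(labels, class_map = default_class_map()) {
  labels <- matrix(as.integer(labels), nrow(labels), ncol(labels))
  if (anyDuplicated(class_map))
    stop("palette collision: two labels share one value in class_map")
  bad <- setdiff(unique(as.vector(labels)), class_map)
  if (length(bad))
    stop("mask contains labels absent from class_map: ",
         paste(bad, collapse = ", "))
  structure(labels, class_map = class_map, class = c("label_mask", "matrix"))
}

#' @export
print.label_mask <- function(x, ...) {
  cm <- attr(x, "class_map")
  tab <- table(factor(as.vector(x), levels = cm, labels = names(cm)))
  cat(sprintf("<label_mask %d x %d>\n", nrow(x), ncol(x)))
  print(tab)
  invisible(x)
}

# Even-odd (crossing-number) point-in-polygon test, vectorized over points.
# Pixel centers on polygon edges count as outside (strict interior).
point_in_polygon <- function(px, py, xs, ys) {
  n <- length(xs)
  inside <- rep(FALSE, length(px))
  j <- n
  for (i in seq_len(n)) {
    crosses <- ((ys[i] > py) != (ys[j] > py)) &
      (px < (xs[j] - xs[i]) * (py - ys[i]) / (ys[j] - ys[i]) + xs[i])
    inside <- xor(inside, crosses)
    j <- i
  }
  inside
}

#' Read a Labelme polygon annotation into a label mask
#'
#' Rasterizes `shapes[].points` polygons in file order onto the given
#' canvas; later polygons overwrite earlier ones. A pixel belongs to a
#' polygon iff its center lies strictly inside (even-odd rule). Pixel `(r,
#' c)` has its center at `(x, y) = (c - 0.5, r - 0.5)` in Labelme image
#' coordinates.
#'
#' @param json_text Labelme JSON document as a string (or path to a file).
#' @param class_map Named integer vector mapping shape labels to mask labels.
#' @param canvas `c(H, W)` canvas size in pixels.
#' @return A [label_mask()].
#' @export
read_labelme <- function(json_text, class_map = default_class_map(),
                         canvas) {
  if (length(json_text) == 1L && file.exists(json_text))
    json_text <- paste(readLines(json_text, warn = FALSE), collapse = "\n")
  doc <- tryCatch(jsonlite::fromJSON(json_text, simplifyVector = FALSE),
                  error = function(e) stop("malformed Labelme JSON: ",
                                           conditionMessage(e)))
  H <- canvas[1]; W <- canvas[2]
  labels <- matrix(0L, H, W)
  cx <- rep(seq_len(W) - 0.5, each = H)
  cy <- rep(seq_len(H) - 0.5, times = W)
  for (shape in doc$shapes) {
    lab <- shape$label
    if (!lab %in% names(class_map))
      stop("unknown label '", lab, "'; known labels: ",
           paste(names(class_map), collapse = ", "))
    pts <- do.call(rbind, lapply(shape$points, unlist))
    inside <- point_in_polygon(cx, cy, pts[, 1], pts[, 2])
    labels[matrix(inside, H, W)] <- class_map[[lab]]
  }
  label_mask(labels, class_map)
}

#' Carcass-wise train/validation/test split
#'
#' Assigns every carcass id to exactly one subset, so all images of a
#' carcass land in the same subset. With ratios `(8, 1, 1)`,
#' `floor(n * 1/10)` ids go to validation and test each and the remainder
#' to training (301 ids give 241/30/30). Shuffling is seed-deterministic.
#'
#' @param carcass_ids Character vector of unique ids.
#' @param ratios Positive weights for train/val/test.
#' @param seed Integer seed.
#' @return Object of class `split_manifest`: a data.frame with columns
#'   `carcass_id` and `subset`.
#' @export
build_split <- function(carcass_ids, ratios = c(8, 1, 1), seed = 1L) {
  if (anyDuplicated(carcass_ids))
    stop("duplicate carcass ids: ",
         paste(unique(carcass_ids[duplicated(carcass_ids)]), collapse = ", "))
  stopifnot(length(ratios) == 3L, all(ratios > 0))
  n <- length(carcass_ids)
  total <- sum(ratios)
  n_val <- floor(n * ratios[2] / total)
  n_test <- floor(n * ratios[3] / total)
  n_train <- n - n_val - n_test
  set.seed(seed)
  shuffled <- sample(carcass_ids)
  subset <- rep(c("train", "val", "test"), c(n_train, n_val, n_test))
  out <- data.frame(carcass_id = shuffled, subset = subset,
                    stringsAsFactors = FALSE)
  out <- out[order(match(out$carcass_id, carcass_ids)), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("split_manifest", "data.frame")
  out
}

#' Query a split manifest
#'
#' @param split A `split_manifest`.
#' @param subset One of `"train"`, `"val"`, `"test"`.
#' @return Character vector of carcass ids in that subset.
#' @export
split_ids <- function(split, subset) {
  split$carcass_id[split$subset == subset]
}

#' Write / read a label mask as single-channel PNG
#'
#' Masks are stored as 8-bit grayscale PNGs whose pixel value is the label
#' index, so a write-then-read roundtrip is label-identical.
#'
#' @param mask A [label_mask()].
#' @param path PNG file path.
#' @param class_map Class map used to validate on read.
#' @return `write_mask` returns `path` invisibly; `read_mask` returns a
#'   [label_mask()].
#' @export
write_mask <- function(mask, path) {
  cm <- attr(mask, "class_map")
  if (is.null(cm)) stop("mask has no class_map; use label_mask()")
  if (anyDuplicated(cm))
    stop("palette collision: two labels share one value in class_map")
  bad <- setdiff(unique(as.vector(mask)), cm)
  if (length(bad))
    stop("write refused: mask contains labels absent from class_map: ",
         paste(bad, collapse = ", "))
  png::writePNG(matrix(as.vector(mask) / 255, nrow(mask), ncol(mask)), path)
  invisible(path)
}

#' @rdname write_mask
#' @export
read_mask <- function(path, class_map = default_class_map()) {
  m <- png::readPNG(path)
  if (length(dim(m)) == 3L) m <- m[, , 1]
  label_mask(matrix(as.integer(round(m * 255)), nrow(m), ncol(m)), class_map)
}

#' Write / read a view image as PNG
#'
#' @param image `H x W x 3` array with intensities in 0..255.
#' @param path PNG file path.
#' @return `write_view_image` returns `path` invisibly; `read_view_image`
#'   returns the integer intensity array.
#' @export
write_view_image <- function(image, path) {
  png::writePNG(image / 255, path)
  invisible(path)
}

#' @rdname write_view_image
#' @export
read_view_image <- function(path) {
  m <- png::readPNG(path)
  if (length(dim(m)) == 2L) m <- array(rep(m, 3), c(dim(m), 3L))
  array(as.integer(round(m[, , 1:3] * 255)), dim = c(dim(m)[1:2], 3L))
}
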