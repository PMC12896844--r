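# Morphological refinement of predicted masks and calibrated area
# extraction. Each foreground class is binarized, closed (fills holes) then
# opened (removes speckles) with the structuring element, and the classes
# are recomposed under the fixed priority torso < leg < head. Binary
# morphology is delegated to EBImage; masks are zero-padded by twice the
# radius beforehand so the image border behaves as background.

#' Structuring element
#'
#' @param shape `"disc"` or `"box"`.
#' @param radius Radius in pixels, >= 1; the element spans
#'   `2 * radius + 1` pixels.
#' @return Object of class `structuring_element` (a 0/1 matrix with
#'   attributes).
#' @export
structuring_element <- function(shape = c("disc", "box"), radius = 5) {
  shape <- match.arg(shape)
  if (radius < 1) stop("structuring element radius must be >= 1")
  kern <- EBImage::makeBrush(2L * as.integer(radius) + 1L, shape = shape)
  structure(kern, shape = shape, radius = as.integer(radius),
            class = c("structuring_element", class(kern)))
}

.pad_morph <- function(bin, kern, op) {
  r <- attr(kern, "radius")
  p <- 2L * r
  H <- nrow(bin); W <- ncol(bin)
  mp <- matrix(0L, H + 2L * p, W + 2L * p)
  mp[p + seq_len(H), p + seq_len(W)] <- bin
  out <- op(mp, unclass(kern))
  matrix(as.integer(out[p + seq_len(H), p + seq_len(W)] > 0), H, W)
}

#' Morphological closing / opening of a binary mask
#'
#' @param bin 0/1 integer matrix.
#' @param se A [structuring_element()].
#' @return 0/1 integer matrix of the same shape.
#' @export
binary_closing <- function(bin, se) .pad_morph(bin, se, EBImage::closing)

#' @rdname binary_closing
#' @export
binary_opening <- function(bin, se) .pad_morph(bin, se, EBImage::opening)

#' Refine a label mask morphologically
#'
#' Applies closing (dilation then erosion, filling holes) followed by
#' opening (erosion then dilation, removing speckles) to each foreground
#' class independently, then recomposes the classes under the priority
#' torso < leg < head (later classes claim contested pixels). Background
#' is the complement of all refined classes.
#'
#' @param mask A [label_mask()].
#' @param se A [structuring_element()].
#' @param priority Part names in increasing priority order.
#' @return A refined [label_mask()].
#' @export
refine_mask <- function(mask, se = structuring_element("disc", 5),
                        priority = c("torso", "leg", "head")) {
  if (2L * attr(se, "radius") + 1L > min(dim(mask)))
    stop("structuring element radius ", attr(se, "radius"),
         " is larger than the image")
  cm <- attr(mask, "class_map")
  out <- matrix(0L, nrow(mask), ncol(mask))
  for (part in priority) {
    if (!part %in% names(cm)) next
    lab <- cm[[part]]
    bin <- matrix(as.integer(unclass(mask) == lab), nrow(mask), ncol(mask))
    if (!any(bin == 1L)) next
    refined <- binary_opening(binary_closing(bin, se), se)
    out[refined == 1L] <- lab
  }
  label_mask(out, cm)
}

#' Measure calibrated per-part areas
#'
#' Counts pixels per foreground part and converts them to cm^2 with the
#' calibration `area = pixels / px_per_cm^2`.
#'
#' @param mask A [label_mask()].
#' @param px_per_cm Calibration, > 0.
#' @param carcass_id,view,replicate Metadata copied into the result.
#' @return Object of class `part_areas`: a data.frame with columns
#'   `carcass_id`, `view`, `replicate`, `part`, `pixels`, `area_cm2` and
#'   `empty` (flag for zero-area parts).
#' @export
measure_areas <- function(mask, px_per_cm, carcass_id = NA_character_,
                          view = NA_character_, replicate = NA_integer_) {
  if (!is.numeric(px_per_cm) || px_per_cm <= 0)
    stop("px_per_cm must be > 0")
  cm <- attr(mask, "class_map")
  parts <- setdiff(names(cm), "background")
  pixels <- vapply(parts, function(p) sum(unclass(mask) == cm[[p]]),
                   numeric(1))
  out <- data.frame(carcass_id = carcass_id, view = view,
                    replicate = replicate, part = parts,
                    pixels = as.numeric(pixels),
                    area_cm2 = as.numeric(pixels) / px_per_cm^2,
                    empty = pixels == 0,
                    stringsAsFactors = FALSE, row.names = NULL)
  class(out) <- c("part_areas", "data.frame")
  out
}
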