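#' Augmentation grid specification
#'
#' The geometric augmentation grid applied identically to image and mask:
#' right-angle rotations plus graded one-sided crops (resized back to the
#' working resolution), optionally a left-right flip and a fixed (25, 25)
#' pixel shift. The default grid — 3 rotations + 4 sides x 3 crop settings —
#' yields exactly 15 augmented pairs per input; enabling flip and shift
#' raises that to 17.
#'
#' @param rotations angles in degrees, multiples of 90.
#' @param crop_sides subset of `c("right", "left", "top", "bottom")`.
#' @param crop_settings retain-fractions in `(0, 1]`; a crop "from" a side
#'   removes pixels at that side, keeping a window anchored at the opposite
#'   side.
#' @param include_flip include a left-right flip.
#' @param include_shift include a `(25, 25)` pixel shift.
#' @param shift_by `(rows, cols)` translation for the shift op.
#' @return An object of class `augmentation_spec`.
#' @export
augmentation_spec <- function(rotations = c(90, 180, 270),
                              crop_sides = c("right", "left", "top", "bottom"),
                              crop_settings = c(0.45, 0.60, 0.90),
                              include_flip = FALSE,
                              include_shift = FALSE,
                              shift_by = c(25, 25)) {
  if (length(rotations) && any(rotations %% 90 != 0))
    stop("rotation angles must be multiples of 90 degrees")
  if (length(crop_settings) && any(crop_settings <= 0 | crop_settings > 1))
    stop("crop_settings (retain fractions) must lie in (0, 1]")
  if (!all(crop_sides %in% c("right", "left", "top", "bottom")))
    stop("crop_sides must be among right/left/top/bottom")
  structure(list(rotations = rotations, crop_sides = crop_sides,
                 crop_settings = crop_settings, include_flip = include_flip,
                 include_shift = include_shift, shift_by = shift_by),
            class = "augmentation_spec")
}

rot90_ccw <- function(m) t(m)[ncol(m):1, , drop = FALSE]

apply_planes <- function(pair, f, id_suffix) {
  img <- pair$image
  planes <- lapply(seq_len(dim(img)[3L]), function(ch) f(img[, , ch]))
  out <- array(0, c(dim(planes[[1L]]), dim(img)[3L]))
  for (ch in seq_along(planes)) out[, , ch] <- planes[[ch]]
  image_pair(out, f(pair$mask), id = paste0(pair$id, id_suffix))
}

#' Rotate a pair by a right angle
#'
#' Lossless rotation (pixel permutation, counter-clockwise) applied to image
#' and mask alike; the mask stays binary and its foreground count is
#' invariant.
#'
#' @param pair an [image_pair()].
#' @param angle 90, 180 or 270 (degrees, counter-clockwise).
#' @return The rotated [image_pair()].
#' @export
rotate_pair <- function(pair, angle) {
  if (!angle %in% c(90, 180, 270)) stop("angle must be one of 90, 180, 270")
  f <- switch(as.character(angle),
    "90" = rot90_ccw,
    "180" = function(m) m[nrow(m):1, ncol(m):1, drop = FALSE],
    "270" = function(m) rot90_ccw(rot90_ccw(rot90_ccw(m))))
  apply_planes(pair, f, sprintf("_rot%d", angle))
}

#' Crop from one side, then resize back
#'
#' "Crop from right" removes columns at the right, keeping a window of
#' `floor(retain_fraction * width)` columns anchored at the left (and
#' symmetrically for the other sides). The window is resized back to the
#' original dimensions: image bilinearly, mask by nearest neighbour with
#' re-thresholding, so labels remain exactly binary.
#'
#' @param pair an [image_pair()].
#' @param side `"right"`, `"left"`, `"top"` or `"bottom"`.
#' @param retain_fraction fraction of the image to keep, in `(0, 1]`.
#' @return The cropped-and-resized [image_pair()].
#' @export
crop_side <- function(pair, side, retain_fraction) {
  if (retain_fraction <= 0 || retain_fraction > 1)
    stop("retain_fraction must lie in (0, 1]")
  H <- nrow(pair$mask); W <- ncol(pair$mask)
  h <- floor(retain_fraction * H); w <- floor(retain_fraction * W)
  if ((side %in% c("left", "right") && w < 1) ||
      (side %in% c("top", "bottom") && h < 1))
    stop("crop would remove the entire image")
  idx <- switch(side,
    right = list(rows = 1:H, cols = 1:w),
    left = list(rows = 1:H, cols = (W - w + 1L):W),
    top = list(rows = (H - h + 1L):H, cols = 1:W),
    bottom = list(rows = 1:h, cols = 1:W),
    stop("side must be one of right/left/top/bottom"))
  img <- pair$image[idx$rows, idx$cols, , drop = FALSE]
  msk <- pair$mask[idx$rows, idx$cols, drop = FALSE]
  if (retain_fraction < 1) {
    img <- resize_image(img, c(H, W))
    msk <- resize_mask(msk, c(H, W))
  }
  image_pair(img, msk,
             id = sprintf("%s_crop_%s_%02.0f", pair$id, side,
                          100 * retain_fraction))
}

#' Flip left-right
#'
#' @param pair an [image_pair()].
#' @return The mirrored [image_pair()]; applying it twice is the identity.
#' @export
flip_lr <- function(pair) {
  apply_planes(pair, function(m) m[, ncol(m):1, drop = FALSE], "_flip")
}

#' Translate a pair
#'
#' Shifts both channels down/right by `shift` pixels. Vacated image pixels
#' are filled by edge replication, vacated mask pixels with background (0).
#' If the shift pushes all lesion pixels outside the frame a warning is
#' raised and the (empty) mask returned as-is.
#'
#' @param pair an [image_pair()].
#' @param shift integer `(rows, cols)` translation.
#' @return The shifted [image_pair()].
#' @export
shift_pair <- function(pair, shift = c(25, 25)) {
  dr <- as.integer(shift[1L]); dc <- as.integer(shift[2L])
  H <- nrow(pair$mask); W <- ncol(pair$mask)
  src_r <- pmin(pmax(1:H - dr, 1L), H)
  src_c <- pmin(pmax(1:W - dc, 1L), W)
  img <- pair$image[src_r, src_c, , drop = FALSE]
  msk <- matrix(0, H, W)
  in_r <- which(1:H - dr >= 1L & 1:H - dr <= H)
  in_c <- which(1:W - dc >= 1L & 1:W - dc <= W)
  if (length(in_r) && length(in_c))
    msk[in_r, in_c] <- pair$mask[in_r - dr, in_c - dc, drop = FALSE]
  if (sum(pair$mask) > 0 && sum(msk) == 0)
    warning("shift pushed all mask foreground outside the frame")
  image_pair(img, msk, id = sprintf("%s_shift_%d_%d", pair$id, dr, dc))
}

#' Expand one pair into its augmentation grid
#'
#' Deterministic output order: rotations, then crops (by side, then
#' setting), then flip, then shift. The default spec emits exactly 15 pairs.
#'
#' @param pair an [image_pair()].
#' @param spec an [augmentation_spec()].
#' @return List of augmented [image_pair()] objects.
#' @export
augment_pair <- function(pair, spec = augmentation_spec()) {
  stopifnot(inherits(pair, "image_pair"), inherits(spec, "augmentation_spec"))
  out <- list()
  for (ang in spec$rotations) out <- c(out, list(rotate_pair(pair, ang)))
  for (side in spec$crop_sides)
    for (f in spec$crop_settings)
      out <- c(out, list(crop_side(pair, side, f)))
  if (spec$include_flip) out <- c(out, list(flip_lr(pair)))
  if (spec$include_shift) out <- c(out, list(shift_pair(pair, spec$shift_by)))
  out
}
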