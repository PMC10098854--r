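#' Image/mask pair
#'
#' The atom flowing through the whole pipeline: an RGB dermoscopic image in
#' `[0, 1]` (array `H x W x 3`) and its aligned binary lesion mask
#' (`H x W`, values exactly 0/1 with 1 = lesion foreground).
#'
#' @param image numeric array `H x W x 3` with values in `[0, 1]`.
#' @param mask numeric matrix `H x W` with values in `{0, 1}`.
#' @param id opaque sample identifier (character scalar).
#' @return An object of class `image_pair`.
#' @export
image_pair <- function(image, mask, id = "sample") {
  if (length(dim(image)) == 2L) {
    image <- array(rep(image, 3L), c(dim(image), 3L))
  }
  stopifnot(length(dim(image)) == 3L, dim(image)[3L] == 3L)
  if (!is.matrix(mask)) stop("mask must be a matrix")
  if (!all(dim(image)[1:2] == dim(mask)))
    stop("image and mask must have identical height and width")
  if (min(image) < -1e-6 || max(image) > 1 + 1e-6)
    stop("image values must lie in [0, 1]")
  vals <- unique(as.vector(mask))
  if (!all(vals %in% c(0, 1)))
    stop("mask values must be exactly 0 or 1")
  structure(list(image = image, mask = mask, id = as.character(id)),
            class = "image_pair")
}

#' @export
print.image_pair <- function(x, ...) {
  cat(sprintf("<image_pair '%s'> %dx%d, lesion fraction %.3f\n",
              x$id, nrow(x$mask), ncol(x$mask), mean(x$mask)))
  invisible(x)
}

## EBImage stores images as (x = width, y = height); package arrays are
## (row = height, col = width). Converted at the boundary, nowhere else.
ebi_from_array <- function(a) {
  if (length(dim(a)) == 3L) {
    EBImage::Image(aperm(a, c(2L, 1L, 3L)), colormode = "Color")
  } else {
    EBImage::Image(t(a), colormode = "Grayscale")
  }
}

array_from_ebi <- function(img) {
  a <- EBImage::imageData(img)
  if (length(dim(a)) == 3L) aperm(a, c(2L, 1L, 3L)) else t(a)
}

read_image_array <- function(path) {
  if (!file.exists(path)) stop("cannot read image: ", path)
  img <- tryCatch(EBImage::readImage(path),
                  error = function(e) stop("cannot decode image ", path, ": ",
                                           conditionMessage(e)))
  a <- array_from_ebi(img)
  # drop an alpha channel if present
  if (length(dim(a)) == 3L && dim(a)[3L] == 4L) a <- a[, , 1:3, drop = FALSE]
  pmin(pmax(a, 0), 1)
}

# BT.601 luminance collapse for RGB-encoded masks
luminance <- function(a) {
  if (length(dim(a)) == 3L) {
    0.299 * a[, , 1L] + 0.587 * a[, , 2L] + 0.114 * a[, , 3L]
  } else {
    a
  }
}

# threshold with the documented tie rule: values equal to the threshold are
# foreground
binarize_mask <- function(m, threshold = 0.5) {
  (m >= threshold) * 1
}

resize_image <- function(a, size) {
  out <- EBImage::resize(ebi_from_array(a), w = size[2L], h = size[1L],
                         filter = "bilinear")
  pmin(pmax(array_from_ebi(out), 0), 1)
}

resize_mask <- function(m, size) {
  out <- EBImage::resize(ebi_from_array(m), w = size[2L], h = size[1L],
                         filter = "none")
  binarize_mask(array_from_ebi(out))
}

#' Load an image/mask pair from disk
#'
#' Reads a dermoscopic image (PNG or JPEG) and its ground-truth mask, resizes
#' both to the working resolution (image bilinearly, mask by nearest neighbour
#' followed by re-thresholding so labels stay binary), and validates the pair.
#' RGB-encoded masks are collapsed by luminance before thresholding; values
#' equal to the threshold map to foreground.
#'
#' @param image_path,mask_path file paths.
#' @param target_size integer vector `c(height, width)`; default `c(256, 256)`.
#' @param threshold mask binarization threshold in `[0, 1]`.
#' @param id sample identifier; defaults to the image file stem.
#' @return An [image_pair()].
#' @export
load_pair <- function(image_path, mask_path, target_size = c(256L, 256L),
                      threshold = 0.5, id = NULL) {
  if (is.null(id)) id <- sub("\\.[^.]*$", "", basename(image_path))
  img <- read_image_array(image_path)
  if (length(dim(img)) == 2L) img <- array(rep(img, 3L), c(dim(img), 3L))
  msk <- binarize_mask(luminance(read_image_array(mask_path)), threshold)
  if (!all(dim(img)[1:2] == target_size)) img <- resize_image(img, target_size)
  if (!all(dim(msk) == target_size)) msk <- resize_mask(msk, target_size)
  image_pair(img, msk, id = id)
}

#' Write an image/mask pair as PNG files
#'
#' @param pair an [image_pair()].
#' @param image_path,mask_path output PNG paths.
#' @return `pair`, invisibly.
#' @export
write_pair <- function(pair, image_path, mask_path) {
  EBImage::writeImage(ebi_from_array(pair$image), image_path)
  EBImage::writeImage(ebi_from_array(pair$mask), mask_path)
  invisible(pair)
}

#' Map image values between display and model ranges
#'
#' The generator works on `[-1, 1]` (tanh output); images load as `[0, 1]`.
#' `to_model_range` applies `2 v - 1`, `from_model_range` inverts it.
#'
#' @param x numeric array in the stated input range (validated to 1e-6).
#' @return Array of the same shape in the mapped range.
#' @export
to_model_range <- function(x) {
  if (min(x) < -1e-6 || max(x) > 1 + 1e-6)
    stop("to_model_range expects values in [0, 1]")
  2 * x - 1
}

#' @rdname to_model_range
#' @export
from_model_range <- function(x) {
  if (min(x) < -1 - 1e-6 || max(x) > 1 + 1e-6)
    stop("from_model_range expects values in [-1, 1]")
  (x + 1) / 2
}

#' Scan a dataset directory into a manifest
#'
#' Expects `images/` and `masks/` subdirectories with matching file stems.
#' Files present on one side only are reported by warning (never silently
#' dropped) and excluded from the entries.
#'
#' @param root dataset directory.
#' @param split tag recorded on the manifest (e.g. "train" or "test").
#' @return A `dataset_manifest`: list with `root`, `split` and an `entries`
#'   data frame (`id`, `image`, `mask`).
#' @export
dataset_manifest <- function(root, split = "train") {
  img_dir <- file.path(root, "images")
  msk_dir <- file.path(root, "masks")
  if (!dir.exists(img_dir) || !dir.exists(msk_dir))
    stop("dataset root must contain images/ and masks/ directories: ", root)
  imgs <- list.files(img_dir, pattern = "\\.(png|jpg|jpeg)$", ignore.case = TRUE)
  msks <- list.files(msk_dir, pattern = "\\.(png|jpg|jpeg)$", ignore.case = TRUE)
  istem <- sub("\\.[^.]*$", "", imgs)
  mstem <- sub("\\.[^.]*$", "", msks)
  orphans <- c(setdiff(istem, mstem), setdiff(mstem, istem))
  if (length(orphans) > 0)
    warning("unpaired files excluded from manifest: ",
            paste(orphans, collapse = ", "))
  keep <- intersect(istem, mstem)
  entries <- data.frame(
    id = keep,
    image = file.path(img_dir, imgs[match(keep, istem)]),
    mask = file.path(msk_dir, msks[match(keep, mstem)]),
    stringsAsFactors = FALSE)
  entries <- entries[order(entries$id), , drop = FALSE]
  rownames(entries) <- NULL
  structure(list(root = root, split = split, entries = entries),
            class = "dataset_manifest")
}

#' @export
print.dataset_manifest <- function(x, ...) {
  cat(sprintf("<dataset_manifest> %s (%s): %d pairs\n",
              x$root, x$split, nrow(x$entries)))
  invisible(x)
}

#' Load every pair listed in a manifest
#'
#' @param manifest a [dataset_manifest()].
#' @inheritParams load_pair
#' @return List of [image_pair()] objects.
#' @export
load_manifest_pairs <- function(manifest, target_size = c(256L, 256L)) {
  stopifnot(inherits(manifest, "dataset_manifest"))
  lapply(seq_len(nrow(manifest$entries)), function(i) {
    e <- manifest$entries[i, ]
    load_pair(e$image, e$mask, target_size = target_size, id = e$id)
  })
}

#' Save / load model checkpoints
#'
#' A checkpoint directory holds the serialized generator and discriminator
#' weights plus a JSON sidecar recording both architecture specs, the training
#' seed and step. A saved-then-loaded generator reproduces forward passes
#' bit-exactly (dropout disabled).
#'
#' @param models list with elements `G` (from [build_generator()]) and `D`
#'   (from [build_discriminator()]).
#' @param path checkpoint directory (created if needed).
#' @param meta optional named list merged into the sidecar (e.g. seed, step).
#' @return `save_checkpoint`: `path`, invisibly. `load_checkpoint`: a list
#'   with `G`, `D` and `meta`.
#' @export
save_checkpoint <- function(models, path, meta = list()) {
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  saveRDS(list(G = models$G$params, D = models$D$params),
          file.path(path, "weights.rds"))
  sidecar <- c(list(generator_spec = unclass(models$G$spec),
                    discriminator_spec = unclass(models$D$spec)), meta)
  jsonlite::write_json(sidecar, file.path(path, "spec.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  wfile <- file.path(path, "weights.rds")
  sfile <- file.path(path, "spec.json")
  if (!file.exists(wfile) || !file.exists(sfile))
    stop("not a checkpoint directory (missing weights.rds or spec.json): ", path)
  w <- tryCatch(readRDS(wfile),
                error = function(e) stop("corrupt checkpoint ", wfile, ": ",
                                         conditionMessage(e)))
  side <- jsonlite::read_json(sfile, simplifyVector = TRUE)
  gs <- do.call(generator_spec, side$generator_spec)
  ds <- do.call(discriminator_spec, side$discriminator_spec)
  G <- structure(list(spec = gs, params = w$G), class = "cgan_generator")
  D <- structure(list(spec = ds, params = w$D), class = "cgan_discriminator")
  meta <- side[setdiff(names(side), c("generator_spec", "discriminator_spec"))]
  list(G = G, D = D, meta = meta)
}
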