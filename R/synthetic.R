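#' Parameters of one synthetic dermoscopy scene
#'
#' Describes a skin-toned background carrying a single darker, irregularly
#' shaped lesion blob, optionally contaminated by dark curvilinear hair
#' strokes and bright circular air bubbles — the artifact classes that make
#' real dermoscopic images hard to threshold. The ground-truth mask is the
#' rendering predicate itself, so mask/lesion correspondence is exact.
#'
#' The lesion boundary is an ellipse whose radius is modulated by a low-order
#' random harmonic series (orders 3-8), giving seed-reproducible irregular
#' blobs. `contrast` scales the lesion-skin colour difference: 0 hides the
#' lesion entirely (mask unchanged), 1 paints the full lesion colour.
#'
#' @param image_size side length in pixels.
#' @param lesion_center `(row, col)`; default image centre.
#' @param lesion_axes ellipse semi-axes `(a, b)` in pixels (each >= 2);
#'   `a` spans columns (horizontal), `b` rows (vertical).
#' @param boundary_irregularity amplitude in `[0, 1]` of the radial
#'   perturbation.
#' @param lesion_color,skin_color RGB triples in `[0, 1]`.
#' @param contrast scalar in `[0, 1]` scaling the lesion-skin difference.
#' @param n_hairs,hair_width count and stroke width (px) of hair strokes.
#' @param n_bubbles count of air bubbles.
#' @param noise_sd additive Gaussian pixel noise standard deviation.
#' @param seed integer; identical params (including seed) render bit-identical
#'   scenes.
#' @return An object of class `scene_params`.
#' @export
scene_params <- function(image_size = 256L,
                         lesion_center = NULL,
                         lesion_axes = c(0.25, 0.2) * image_size,
                         boundary_irregularity = 0.15,
                         lesion_color = c(0.35, 0.21, 0.16),
                         skin_color = c(0.87, 0.67, 0.57),
                         contrast = 0.8,
                         n_hairs = 0L, hair_width = 2L,
                         n_bubbles = 0L,
                         noise_sd = 0.02,
                         seed = 1L) {
  if (is.null(lesion_center)) lesion_center <- c(image_size, image_size) / 2
  if (any(lesion_axes < 2))
    stop("degenerate lesion axes: both semi-axes must be >= 2 px")
  if (boundary_irregularity < 0 || boundary_irregularity > 1)
    stop("boundary_irregularity must be in [0, 1]")
  if (contrast < 0 || contrast > 1) stop("contrast must be in [0, 1]")
  reach <- max(lesion_axes) * (1 + boundary_irregularity)
  if (lesion_center[1L] - reach < 1 || lesion_center[1L] + reach > image_size ||
      lesion_center[2L] - reach < 1 || lesion_center[2L] + reach > image_size)
    stop("lesion ellipse (with irregularity margin) must fit inside the image")
  structure(list(image_size = as.integer(image_size),
                 lesion_center = as.numeric(lesion_center),
                 lesion_axes = as.numeric(lesion_axes),
                 boundary_irregularity = boundary_irregularity,
                 lesion_color = lesion_color, skin_color = skin_color,
                 contrast = contrast,
                 n_hairs = as.integer(n_hairs),
                 hair_width = as.integer(hair_width),
                 n_bubbles = as.integer(n_bubbles),
                 noise_sd = noise_sd, seed = as.integer(seed)),
            class = "scene_params")
}

# stamp a value onto image channels at given pixel centres with a disk of
# radius r; returns the stamped logical mask
stamp_disk <- function(size, rows, cols, r) {
  hit <- matrix(FALSE, size, size)
  off <- expand.grid(dr = -ceiling(r):ceiling(r), dc = -ceiling(r):ceiling(r))
  off <- off[off$dr^2 + off$dc^2 <= r^2, , drop = FALSE]
  for (k in seq_len(nrow(off))) {
    rr <- round(rows) + off$dr[k]
    cc <- round(cols) + off$dc[k]
    ok <- rr >= 1 & rr <= size & cc >= 1 & cc <= size
    hit[cbind(rr[ok], cc[ok])] <- TRUE
  }
  hit
}

#' Render a synthetic dermoscopy scene
#'
#' Hair strokes (random cubic Bezier curves of dark brown) and bubbles
#' (bright circles with a darker rim) are drawn on the image only — the mask
#' records exactly the perturbed-ellipse lesion interior. Each scene
#' component draws from its own seed substream so that, e.g., a re-render
#' with `n_hairs = 0` leaves lesion, bubbles and noise untouched.
#'
#' @param params a [scene_params()].
#' @param keep_artifacts if `TRUE`, attach logical matrices `hair_mask` and
#'   `bubble_mask` as attributes of the returned pair (used by tests and the
#'   artifact-removal diagnostics).
#' @return An [image_pair()].
#' @export
render_scene <- function(params, keep_artifacts = FALSE) {
  stopifnot(inherits(params, "scene_params"))
  S <- params$image_size
  cr <- params$lesion_center[1L]; cc <- params$lesion_center[2L]
  a <- params$lesion_axes[1L]; b <- params$lesion_axes[2L]

  # lesion interior via perturbed ellipse radius
  set.seed(params$seed)
  H <- 3:8
  amp <- stats::rnorm(length(H))
  phs <- stats::runif(length(H), 0, 2 * pi)
  irr <- params$boundary_irregularity
  if (sum(abs(amp)) > 0) amp <- amp * irr / sum(abs(amp)) else amp <- amp * 0

  rows <- matrix(seq_len(S), S, S)
  cols <- matrix(seq_len(S), S, S, byrow = TRUE)
  dy <- rows - cr; dx <- cols - cc
  theta <- atan2(dy, dx)
  rho <- sqrt(dy * dy + dx * dx)
  r_ell <- a * b / sqrt((b * cos(theta))^2 + (a * sin(theta))^2)
  pert <- Reduce(`+`, lapply(seq_along(H), function(i)
    amp[i] * cos(H[i] * theta + phs[i])))
  mask <- (rho <= r_ell * (1 + pert)) * 1

  img <- array(0, c(S, S, 3L))
  for (ch in 1:3) {
    img[, , ch] <- params$skin_color[ch] +
      mask * params$contrast * (params$lesion_color[ch] - params$skin_color[ch])
  }

  # hair strokes: cubic Bezier curves stamped with a disk of radius width/2
  hair_hit <- matrix(FALSE, S, S)
  set.seed(params$seed + 1L)
  if (params$n_hairs > 0) {
    hair_col <- c(0.16, 0.11, 0.08)
    for (h in seq_len(params$n_hairs)) {
      P <- matrix(stats::runif(8, -0.1 * S, 1.1 * S), 4L, 2L)
      t <- seq(0, 1, length.out = 4L * S)
      bz <- function(j) (1 - t)^3 * P[1L, j] + 3 * (1 - t)^2 * t * P[2L, j] +
        3 * (1 - t) * t^2 * P[3L, j] + t^3 * P[4L, j]
      hit <- stamp_disk(S, bz(1L), bz(2L), params$hair_width / 2)
      hair_hit <- hair_hit | hit
      for (ch in 1:3) {
        plane <- img[, , ch]
        plane[hit] <- hair_col[ch]
        img[, , ch] <- plane
      }
    }
  }

  # air bubbles: bright fill, darker rim; image only
  bubble_hit <- matrix(FALSE, S, S)
  set.seed(params$seed + 2L)
  if (params$n_bubbles > 0) {
    for (k in seq_len(params$n_bubbles)) {
      bc <- stats::runif(2, 0.1 * S, 0.9 * S)
      br <- stats::runif(1, 2, 6)
      d <- sqrt((rows - bc[1L])^2 + (cols - bc[2L])^2)
      fill <- d <= max(br - 1.2, 0.8)
      rim <- d <= br & !fill
      bubble_hit <- bubble_hit | fill | rim
      for (ch in 1:3) {
        plane <- img[, , ch]
        plane[fill] <- plane[fill] + 0.3 * (1 - plane[fill])
        plane[rim] <- plane[rim] * 0.55
        img[, , ch] <- plane
      }
    }
  }

  set.seed(params$seed + 3L)
  if (params$noise_sd > 0) {
    img <- img + array(stats::rnorm(length(img), 0, params$noise_sd), dim(img))
  }
  img <- pmin(pmax(img, 0), 1)

  pair <- image_pair(img, mask, id = sprintf("scene_%d", params$seed))
  if (keep_artifacts) {
    attr(pair, "hair_mask") <- hair_hit
    attr(pair, "bubble_mask") <- bubble_hit
  }
  pair
}

#' Draw random scene parameters
#'
#' All randomness flows from `rng_seed`. `difficulty` controls the regime:
#' easy scenes have contrast in `[0.5, 0.9]`, mild boundary irregularity and
#' few artifacts; hard scenes have contrast in `[0.1, 0.3]`, stronger
#' irregularity and many hairs/bubbles.
#'
#' @param rng_seed integer seed.
#' @param image_size side length in pixels.
#' @param difficulty `"easy"` or `"hard"`.
#' @return A [scene_params()].
#' @export
sample_scene_params <- function(rng_seed, image_size = 256L,
                                difficulty = c("easy", "hard")) {
  difficulty <- match.arg(difficulty)
  set.seed(rng_seed)
  S <- image_size
  skin_palette <- rbind(c(0.93, 0.79, 0.69), c(0.87, 0.67, 0.57),
                        c(0.80, 0.58, 0.45), c(0.68, 0.47, 0.34),
                        c(0.55, 0.36, 0.25))
  lesion_palette <- rbind(c(0.35, 0.21, 0.16), c(0.28, 0.16, 0.12),
                          c(0.42, 0.25, 0.15), c(0.22, 0.13, 0.11))
  skin <- skin_palette[sample.int(nrow(skin_palette), 1L), ]
  lesion <- lesion_palette[sample.int(nrow(lesion_palette), 1L), ]
  if (difficulty == "easy") {
    contrast <- stats::runif(1, 0.5, 0.9)
    irr <- stats::runif(1, 0.02, 0.15)
    n_hairs <- sample(0:3, 1L)
    n_bubbles <- sample(0:2, 1L)
    noise_sd <- stats::runif(1, 0.01, 0.03)
  } else {
    contrast <- stats::runif(1, 0.1, 0.3)
    irr <- stats::runif(1, 0.15, 0.35)
    n_hairs <- sample(5:12, 1L)
    n_bubbles <- sample(2:6, 1L)
    noise_sd <- stats::runif(1, 0.03, 0.06)
  }
  center <- S / 2 + stats::runif(2, -0.08, 0.08) * S
  # bound axes so the perturbed ellipse always fits
  margin <- min(center - 1, S - center) / (1 + irr + 0.02)
  axes <- pmin(stats::runif(2, 0.15, 0.30) * S, margin)
  scene_params(image_size = S, lesion_center = center, lesion_axes = axes,
               boundary_irregularity = irr, lesion_color = lesion,
               skin_color = skin, contrast = contrast, n_hairs = n_hairs,
               hair_width = sample(1:3, 1L), n_bubbles = n_bubbles,
               noise_sd = noise_sd,
               seed = sample.int(.Machine$integer.max - 4L, 1L))
}

#' Generate a synthetic dataset on disk
#'
#' Writes `n` image/mask PNG pairs under `out_dir/images` and
#' `out_dir/masks` and returns the manifest. Regeneration with the same seed
#' reproduces the arrays exactly.
#'
#' @param n number of scenes.
#' @param image_size side length in pixels.
#' @param difficulty `"easy"` or `"hard"` (see [sample_scene_params()]).
#' @param seed integer master seed; scene `i` uses `seed + i`.
#' @param out_dir output directory.
#' @return A [dataset_manifest()].
#' @export
generate_dataset <- function(n, image_size = 256L, difficulty = "easy",
                             seed = 1L, out_dir) {
  dir.create(file.path(out_dir, "images"), recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(out_dir, "masks"), recursive = TRUE, showWarnings = FALSE)
  for (i in seq_len(n)) {
    p <- sample_scene_params(seed + i, image_size, difficulty)
    pair <- render_scene(p)
    stem <- sprintf("scene_%04d", i)
    write_pair(pair, file.path(out_dir, "images", paste0(stem, ".png")),
               file.path(out_dir, "masks", paste0(stem, ".png")))
  }
  dataset_manifest(out_dir, split = difficulty)
}

#' Generate synthetic pairs in memory
#'
#' Convenience used by training/tests: renders `n` scenes without touching
#' disk.
#'
#' @inheritParams generate_dataset
#' @return List of [image_pair()] objects.
#' @export
generate_pairs <- function(n, image_size = 64L, difficulty = "easy",
                           seed = 1L) {
  lapply(seq_len(n), function(i)
    render_scene(sample_scene_params(seed + i, image_size, difficulty)))
}
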