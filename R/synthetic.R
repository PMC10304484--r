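#' Specification of a synthetic image-classification dataset
#'
#' Describes a procedurally generated dataset with a controllable
#' long-tail profile, intra-class appearance diversity and inter-class
#' visual similarity. Classes are partitioned into "similarity groups":
#' classes in the same group share a background hue band and texture
#' orientation, so they look alike to a feature extractor, while each
#' class keeps its own foreground shape, foreground hue offset and
#' texture frequency, so classes remain separable. Per-image jitter
#' (hue, position, scale, rotation, pixel noise) provides intra-class
#' diversity. This emulates the inter-class similarity / intra-class
#' diversity structure of food photographs at desk scale; it does not
#' emulate natural-image statistics.
#'
#' @param n_classes number of classes.
#' @param profile a `class_size_profile` with `n_classes` sizes; class
#'   `i` receives `profile$sizes[i]` training images (class 1 largest).
#' @param image_size `c(width, height)` in pixels, at least 16 x 16.
#' @param test_per_class balanced test images per class.
#' @param similarity_groups integer vector (length `n_classes`) giving
#'   each class's group; default assigns classes round-robin to
#'   `n_groups` groups, so head and tail classes mix within groups.
#' @param n_groups number of groups for the default assignment
#'   (default: about one group per three classes, at least 2).
#' @param jitter list of appearance-noise parameters: `hue` (hue spread,
#'   fraction of the hue circle), `pos` (centre spread, fraction of image
#'   width), `scale` (relative size spread), `noise` (pixel noise sd),
#'   `outlier` (fraction of images rendered as atypical outliers —
#'   random hue, extreme placement, heavy noise — emulating the junk and
#'   near-mislabelled shots that web-scraped image classes contain).
#' @param seed integer seed; the generated dataset is a pure function of
#'   the spec including this seed.
#' @return list of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n_classes, profile, image_size = c(32, 32),
                           test_per_class = 10, similarity_groups = NULL,
                           n_groups = NULL,
                           jitter = list(hue = 0.06, pos = 0.25,
                                         scale = 0.35, noise = 0.08,
                                         outlier = 0.08),
                           seed = 1L) {
  stopifnot(length(profile$sizes) == n_classes)
  if (any(image_size < 16)) stop("image_size must be at least 16 x 16", call. = FALSE)
  if (is.null(similarity_groups)) {
    if (is.null(n_groups)) n_groups <- max(2L, round(n_classes / 3))
    similarity_groups <- ((seq_len(n_classes) - 1L) %% n_groups) + 1L
  }
  stopifnot(length(similarity_groups) == n_classes)
  def <- list(hue = 0.06, pos = 0.25, scale = 0.35, noise = 0.08,
              outlier = 0.08)
  jitter <- utils::modifyList(def, jitter)
  structure(list(n_classes = n_classes, profile = profile,
                 image_size = as.integer(image_size),
                 test_per_class = as.integer(test_per_class),
                 similarity_groups = as.integer(similarity_groups),
                 jitter = jitter, seed = as.integer(seed)),
            class = "synthetic_spec")
}

#' The packaged synthetic long-tailed benchmark conditions
#'
#' Ten classes with a geometric profile from 400 down to 4 training
#' images (imbalance ratio 100, 994 training images), 30 balanced test
#' images per class, 32 x 32 px, three similarity groups assigned
#' round-robin so every group contains one head class and two or three
#' tail classes.
#'
#' @param seed dataset seed.
#' @return a `synthetic_spec`.
#' @export
synthetic_benchmark_spec <- function(seed = 1L) {
  synthetic_spec(
    n_classes = 10,
    profile = make_rank_profile(10, 400, 4),
    image_size = c(32, 32),
    test_per_class = 30,
    n_groups = 3,
    seed = seed)
}

hsv_vec <- function(h, s, v) {
  as.vector(grDevices::col2rgb(grDevices::hsv(h %% 1, s, v))) / 255
}

# render one image as an H x W x 3 array; consumes the current RNG stream
render_synthetic_image <- function(class_id, spec, allow_outlier = TRUE) {
  w <- spec$image_size[1]; h <- spec$image_size[2]
  g <- spec$similarity_groups[class_id]
  n_groups <- max(spec$similarity_groups)
  # class's index within its group controls the class-specific attributes
  members <- which(spec$similarity_groups == g)
  wi <- match(class_id, members)
  jt <- spec$jitter

  hue_g <- (g - 0.5) / n_groups
  theta <- (g - 1) * pi / n_groups            # group grating orientation
  freq <- 3 + 2 * wi                          # class texture frequency (cycles)
  sides <- 2 + wi                             # class polygon: 3, 4, 5, ...
  noise_sd <- jt$noise

  out_p <- if (is.null(jt$outlier) || !allow_outlier) 0 else jt$outlier
  if (stats::runif(1) < out_p) {
    # atypical shot: arbitrary hues, extreme placement and size, heavy
    # noise — carries almost no usable class signal
    bg <- hsv_vec(stats::runif(1), 0.30, 0.80)
    fg <- hsv_vec(stats::runif(1), 0.85, 0.90)
    cx <- 0.5 + stats::runif(1, -2.5 * jt$pos, 2.5 * jt$pos)
    cy <- 0.5 + stats::runif(1, -2.5 * jt$pos, 2.5 * jt$pos)
    rad <- 0.28 * (1 + stats::runif(1, -1, 2 * jt$scale + 1))
    noise_sd <- 3 * jt$noise
  } else {
    bg <- hsv_vec(hue_g + stats::runif(1, -jt$hue, jt$hue), 0.30, 0.80)
    fg <- hsv_vec(hue_g + 0.08 * wi + stats::runif(1, -jt$hue, jt$hue), 0.85, 0.90)
    cx <- 0.5 + stats::runif(1, -jt$pos, jt$pos)
    cy <- 0.5 + stats::runif(1, -jt$pos, jt$pos)
    rad <- 0.28 * (1 + stats::runif(1, -jt$scale, jt$scale))
  }
  rot <- stats::runif(1, 0, 2 * pi)
  phase <- stats::runif(1, 0, 2 * pi)

  x <- matrix(rep((seq_len(w) - 0.5) / w, each = h), nrow = h)
  y <- matrix(rep((seq_len(h) - 0.5) / h, times = w), nrow = h)

  # sinusoidal grating along the group orientation, class-specific frequency
  grat <- 0.06 * sin(2 * pi * freq * (x * cos(theta) + y * sin(theta)) + phase)

  # regular polygon membership via the apothem inequality
  dx <- x - cx; dy <- y - cy
  r <- sqrt(dx^2 + dy^2)
  ang <- (atan2(dy, dx) - rot) %% (2 * pi / sides)
  inside <- r * cos(ang - pi / sides) <= rad * cos(pi / sides)

  img <- array(0, dim = c(h, w, 3))
  for (ch in 1:3) {
    plane <- matrix(bg[ch], nrow = h, ncol = w)
    plane[inside] <- fg[ch]
    img[, , ch] <- plane + grat
  }
  img <- img + stats::rnorm(length(img), 0, noise_sd)
  img[img < 0] <- 0; img[img > 1] <- 1
  img
}

#' Generate a synthetic image dataset on disk
#'
#' Renders every training and test image of a [synthetic_spec()] as an
#' 8-bit RGB PNG under `output_root/images/` and writes
#' `output_root/manifest.csv` plus the spec itself as
#' `output_root/spec.yaml`. Identical specs (including the seed) produce
#' byte-identical images and manifests. Training counts follow the
#' spec's profile exactly; the test split is balanced with
#' `test_per_class` images per class.
#'
#' @param spec a `synthetic_spec`.
#' @param output_root writable output directory (created if needed).
#' @return the `dataset_manifest`, invisibly carrying the root in
#'   attribute `"root"`.
#' @export
generate_dataset <- function(spec, output_root) {
  dir.create(output_root, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(output_root)) stop("cannot create output root: ", output_root, call. = FALSE)
  set.seed(spec$seed)
  rows <- list()
  for (cid in seq_len(spec$n_classes)) {
    cdir <- file.path("images", sprintf("class_%02d", cid))
    dir.create(file.path(output_root, cdir), recursive = TRUE, showWarnings = FALSE)
    n_train <- spec$profile$sizes[cid]
    for (i in seq_len(n_train + spec$test_per_class)) {
      split <- if (i <= n_train) "train" else "test"
      fname <- file.path(cdir, sprintf("%s_%04d.png", split, i))
      # outliers are a training-set phenomenon; the balanced test split
      # stays clean so accuracies measure typical-image recognition
      img <- render_synthetic_image(cid, spec, allow_outlier = split == "train")
      png::writePNG(img, file.path(output_root, fname))
      rows[[length(rows) + 1L]] <- list(image_path = fname, class_id = cid, split = split)
    }
  }
  df <- do.call(rbind, lapply(rows, as.data.frame))
  manifest <- dataset_manifest(df$image_path, df$class_id,
                               class_name = sprintf("synthetic_%02d", df$class_id),
                               split = df$split)
  write_manifest(manifest, file.path(output_root, "manifest.csv"))
  yaml::write_yaml(list(n_classes = spec$n_classes,
                        sizes = spec$profile$sizes,
                        image_size = spec$image_size,
                        test_per_class = spec$test_per_class,
                        similarity_groups = spec$similarity_groups,
                        jitter = spec$jitter, seed = spec$seed),
                   file.path(output_root, "spec.yaml"))
  attr(manifest, "root") <- output_root
  manifest
}
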