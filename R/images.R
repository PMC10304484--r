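#' Load manifest images into memory
#'
#' Reads every PNG referenced by a manifest into a dense pixel matrix
#' (one row per sample, values in `[0, 1]`, channels stacked
#' column-major). All downstream math — training, feature extraction,
#' CutMix composition — operates on this store; pixel files are read
#' once.
#'
#' @param manifest a `dataset_manifest`.
#' @param root directory the manifest's `image_path`s are relative to.
#' @return an `image_store`: list with `pixels` (`n x (H*W*3)` matrix,
#'   rownames = sample ids), `sample_ids`, `width`, `height`.
#' @export
load_images <- function(manifest, root) {
  paths <- file.path(root, manifest$image_path)
  missing <- !file.exists(paths)
  if (any(missing)) {
    stop("missing image file(s): ", paste(utils::head(paths[missing], 3), collapse = ", "),
         call. = FALSE)
  }
  first <- png::readPNG(paths[1])
  h <- dim(first)[1]; w <- dim(first)[2]
  px <- matrix(0, nrow = length(paths), ncol = h * w * 3)
  for (i in seq_along(paths)) {
    a <- png::readPNG(paths[i])
    if (dim(a)[3] > 3) a <- a[, , 1:3]
    px[i, ] <- as.vector(a)
  }
  rownames(px) <- manifest$sample_id
  structure(list(pixels = px, sample_ids = manifest$sample_id,
                 width = w, height = h),
            class = "image_store")
}

# build an image_store directly from a pixel matrix (in-memory fixtures)
image_store <- function(pixels, sample_ids, width, height) {
  rownames(pixels) <- sample_ids
  structure(list(pixels = pixels, sample_ids = sample_ids,
                 width = width, height = height),
            class = "image_store")
}

# one sample as an H x W x 3 array
image_of <- function(store, sample_id) {
  v <- store$pixels[as.character(sample_id), ]
  array(v, dim = c(store$height, store$width, 3))
}

# rows of the pixel matrix for a set of sample ids
pixel_rows <- function(store, sample_ids) {
  store$pixels[as.character(sample_ids), , drop = FALSE]
}

# flatten an H x W x 3 array to a store row
flatten_image <- function(img) as.vector(img)

#' Feature matrices
#'
#' Container aligning per-sample feature vectors (rows) with manifest
#' sample ids; produced by [extract_features()].
#'
#' @param vectors numeric matrix, one row per sample.
#' @param sample_ids aligned sample ids.
#' @param normalized logical: rows unit-normalized?
#' @return list of class `feature_matrix`.
#' @export
feature_matrix <- function(vectors, sample_ids, normalized = FALSE) {
  stopifnot(nrow(vectors) == length(sample_ids))
  rownames(vectors) <- sample_ids
  structure(list(vectors = vectors, sample_ids = sample_ids,
                 normalized = normalized),
            class = "feature_matrix")
}

feature_of <- function(fm, sample_id) fm$vectors[as.character(sample_id), ]

feature_rows <- function(fm, sample_ids) {
  fm$vectors[as.character(sample_ids), , drop = FALSE]
}
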