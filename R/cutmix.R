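#' Sample a rectangular CutMix mask
#'
#' Draws a mixing ratio \eqn{s} uniformly from `s_range` (redrawing until
#' the cut rectangle is at least 1 px in both dimensions), then places a
#' \eqn{\lfloor sW \rfloor \times \lfloor sH \rfloor} rectangle uniformly
#' at random inside the image. The binary mask grid is 1 inside the
#' rectangle — the region where the tail image is kept — and 0 outside,
#' where the donor image provides the surrounding context.
#'
#' Uses the current RNG stream; seed at the caller for reproducibility.
#'
#' @param width,height image dimensions in pixels (>= 2 each).
#' @param s_range numeric `(low, high)` with `0 <= low < high <= 1`.
#' @return object of class `mix_mask`: list with `width`, `height`, `s`,
#'   `rect = c(x0, y0, w, h)` (1-based column/row offsets) and `grid`
#'   (`height x width` 0/1 matrix).
#' @examples
#' set.seed(1)
#' m <- sample_mask(32, 32)
#' sum(m$grid) == m$rect[3] * m$rect[4]
#' @export
sample_mask <- function(width, height, s_range = c(0, 1)) {
  if (width < 2 || height < 2) stop("image must be at least 2x2", call. = FALSE)
  if (length(s_range) != 2 || s_range[1] < 0 || s_range[2] > 1 ||
      s_range[1] >= s_range[2]) {
    stop("s_range must satisfy 0 <= low < high <= 1", call. = FALSE)
  }
  repeat {
    s <- stats::runif(1, s_range[1], s_range[2])
    w <- floor(s * width)
    h <- floor(s * height)
    if (w >= 1 && h >= 1) break
  }
  x0 <- sample.int(width - w + 1L, 1L)
  y0 <- sample.int(height - h + 1L, 1L)
  grid <- matrix(0L, nrow = height, ncol = width)
  grid[y0:(y0 + h - 1L), x0:(x0 + w - 1L)] <- 1L
  structure(list(width = width, height = height, s = s,
                 rect = c(x0 = x0, y0 = y0, w = w, h = h), grid = grid),
            class = "mix_mask")
}

# complement a mask in place: the sampled rectangle becomes the donor
# region and the rest of the image keeps the running composite
mask_complement <- function(mask) {
  mask$grid <- 1L - mask$grid
  mask
}

# build a mix_mask from an explicit rectangle (tests, forced limits)
manual_mask <- function(width, height, x0, y0, w, h, s = NA_real_) {
  stopifnot(x0 >= 1, y0 >= 1, x0 + w - 1 <= width, y0 + h - 1 <= height, w >= 0, h >= 0)
  grid <- matrix(0L, nrow = height, ncol = width)
  if (w >= 1 && h >= 1) grid[y0:(y0 + h - 1), x0:(x0 + w - 1)] <- 1L
  structure(list(width = width, height = height, s = s,
                 rect = c(x0 = x0, y0 = y0, w = w, h = h), grid = grid),
            class = "mix_mask")
}

#' Top-k most visually similar head-class donors
#'
#' Ranks the candidate donor images of a head batch by cosine similarity
#' between their feature vectors and the tail image's feature vector, and
#' returns the ids of the `k` most similar, descending. Ties are broken
#' by sample id so the ranking is deterministic.
#'
#' @param tail_feature numeric feature vector of the tail image (non-zero).
#' @param head_features matrix, one row per candidate donor (non-zero rows).
#' @param head_ids sample ids aligned with the rows of `head_features`.
#' @param k number of donors to return (`k <= nrow(head_features)`).
#' @return integer vector of `k` donor sample ids, most similar first.
#' @export
topk_similar_heads <- function(tail_feature, head_features, head_ids, k = 1L) {
  if (!is.matrix(head_features)) head_features <- rbind(head_features)
  if (k > nrow(head_features)) {
    stop("k exceeds the number of candidate donors", call. = FALSE)
  }
  nt <- sqrt(sum(tail_feature^2))
  nh <- sqrt(rowSums(head_features^2))
  if (nt == 0 || any(nh == 0)) stop("zero feature vector in cosine similarity", call. = FALSE)
  cs <- as.vector(head_features %*% tail_feature) / (nh * nt)
  head_ids[order(-cs, head_ids)][seq_len(k)]
}

#' Compose a multi-image CutMix sample
#'
#' Sequentially mixes the tail image with `k` donor images. Starting from
#' the tail image, step \eqn{i} keeps the current composite inside the
#' mask rectangle (mask value 1) and replaces everything outside with
#' donor \eqn{i}: `running = (1 - M_i) * donor_i + M_i * running`. With
#' `k = 1` this is exactly single-donor CutMix; as `k` grows, donor
#' context progressively occupies the image and the surviving tail area
#' shrinks. A per-pixel ownership map is updated identically, recording
#' which source image owns each pixel of the final composite.
#'
#' @param tail_image `H x W x 3` array, values in `[0, 1]`.
#' @param donors list of donor arrays with the same dimensions.
#' @param masks list of `mix_mask` objects, one per donor, same order.
#' @return list with `image` (`H x W x 3` array, values in `[0, 1]`) and
#'   `owner` (`H x W` integer matrix: 0 = tail image, `i` = i-th donor).
#' @export
compose_cutmix <- function(tail_image, donors, masks) {
  if (!is.list(donors)) donors <- list(donors)
  if (inherits(masks, "mix_mask")) masks <- list(masks)
  if (length(donors) != length(masks)) {
    stop("need exactly one mask per donor", call. = FALSE)
  }
  dm <- dim(tail_image)
  running <- tail_image
  owner <- matrix(0L, nrow = dm[1], ncol = dm[2])
  for (i in seq_along(donors)) {
    d <- donors[[i]]
    if (!identical(dim(d), dm)) stop("donor ", i, " has mismatched dimensions", call. = FALSE)
    g <- masks[[i]]$grid
    if (!identical(dim(g), dm[1:2])) stop("mask ", i, " has mismatched dimensions", call. = FALSE)
    keep <- array(g, dim = dm)  # broadcast over channels
    running <- (1 - keep) * d + keep * running
    owner[g == 0L] <- i
  }
  list(image = running, owner = owner)
}

#' Label vector for an augmented sample
#'
#' Converts the pixel-ownership map of a composite into a per-class
#' weight vector. Policy `"area-mix"` (the CutMix convention) weights
#' each class by the fraction of pixels it owns; `"tail-only"` puts all
#' weight on the tail class regardless of ownership.
#'
#' @param owner `H x W` integer ownership map from [compose_cutmix()].
#' @param tail_class class id of the tail image (owner value 0).
#' @param donor_classes class ids of the donors (owner values `1..k`).
#' @param class_ids all class ids, defining the order of the returned
#'   weight vector.
#' @param policy `"area-mix"` (default) or `"tail-only"`.
#' @return named numeric vector over `class_ids`, summing to 1.
#' @export
make_label <- function(owner, tail_class, donor_classes, class_ids,
                       policy = c("area-mix", "tail-only")) {
  policy <- match.arg(policy)
  w <- stats::setNames(numeric(length(class_ids)), class_ids)
  if (policy == "tail-only") {
    w[as.character(tail_class)] <- 1
    return(w)
  }
  src_class <- c(tail_class, donor_classes)  # owner value v -> src_class[v + 1]
  frac <- tabulate(owner + 1L, nbins = length(src_class)) / length(owner)
  for (v in seq_along(src_class)) {
    key <- as.character(src_class[v])
    w[key] <- w[key] + frac[v]
  }
  stopifnot(abs(sum(w) - 1) < 1e-9)
  w
}

#' Generate CutMix oversampling recipes for the tail classes
#'
#' Brings every tail class up to `m_target` effective training samples by
#' generating `m_target - n_t` augmented composites per class. For each
#' composite, a fresh head batch \eqn{B_r} is drawn uniformly from the
#' removed-head donor pool \eqn{D_r}, the `k` donors most visually
#' similar to the tail image (cosine similarity in feature space) are
#' retrieved, and the composite is built by [compose_cutmix()] with a
#' fresh mask per donor. With `selection = "random"` the donors are drawn
#' uniformly from \eqn{B_r} instead — the context-rich oversampling
#' baseline — leaving every other step unchanged.
#'
#' `direction` sets which side of the cut the donor occupies. The
#' default `"donor-patch"` pastes the sampled
#' \eqn{\lfloor sW\rfloor \times \lfloor sH\rfloor} rectangle of head
#' context into the tail image, so at `k = 1` the original tail image
#' remains the majority of the composite and donor context progressively
#' occupies it as `k` grows. `"tail-patch"` is the transpose reading —
#' the tail survives only inside the rectangle, the donor supplies the
#' surrounding canvas.
#'
#' @param manifest a `dataset_manifest`.
#' @param tail_ids class ids of the tail classes.
#' @param donor_pool integer sample ids forming the donor pool
#'   (typically the removed head samples \eqn{D_r}).
#' @param features a `feature_matrix` covering tail and donor samples.
#' @param images an `image_store` from [load_images()].
#' @param m_target integer per-class target count (`floor(m)`).
#' @param k donors per composite (default 1).
#' @param br_size size of each head batch \eqn{B_r} (default 32; capped
#'   at the pool size).
#' @param s_range mixing-ratio range passed to [sample_mask()].
#' @param selection `"topk"` (visual-aware, default) or `"random"`.
#' @param direction `"donor-patch"` (default) or `"tail-patch"`; see
#'   Details.
#' @param label_policy passed to [make_label()].
#' @param seed integer seed; the full recipe list is reproducible from it.
#' @return list of recipes, each a list with `tail_id`, `tail_class`,
#'   `donor_ids`, `donor_classes`, `s` and `rect` per step, `label`
#'   (named weight vector) and `image` (`H x W x 3` array).
#' @export
oversample_tail <- function(manifest, tail_ids, donor_pool, features, images,
                            m_target, k = 1L, br_size = 32L,
                            s_range = c(0, 1),
                            selection = c("topk", "random"),
                            direction = c("donor-patch", "tail-patch"),
                            label_policy = "area-mix", seed = 1L) {
  selection <- match.arg(selection)
  direction <- match.arg(direction)
  if (length(donor_pool) == 0) {
    stop("empty donor pool: no removed head samples to mix from", call. = FALSE)
  }
  set.seed(seed)
  tr <- manifest[manifest$split == "train", ]
  class_ids <- sort(unique(tr$class_id))
  donor_class <- stats::setNames(tr$class_id, tr$sample_id)
  recipes <- list()
  for (cid in tail_ids) {
    own <- tr$sample_id[tr$class_id == cid]
    n_rec <- m_target - length(own)
    if (n_rec <= 0) next
    # cycle through the class's originals so every image is augmented
    tail_seq <- rep_len(sample(own), n_rec)
    for (j in seq_len(n_rec)) {
      tid <- tail_seq[j]
      br <- if (length(donor_pool) <= br_size) donor_pool else
        sample(donor_pool, br_size)
      donors <- if (selection == "topk") {
        topk_similar_heads(feature_of(features, tid),
                           feature_rows(features, br), br, k = min(k, length(br)))
      } else {
        sample(br, min(k, length(br)))
      }
      masks <- lapply(seq_along(donors), function(i) {
        m <- sample_mask(images$width, images$height, s_range)
        if (direction == "donor-patch") mask_complement(m) else m
      })
      comp <- compose_cutmix(image_of(images, tid),
                             lapply(donors, function(d) image_of(images, d)),
                             masks)
      lab <- make_label(comp$owner, cid, unname(donor_class[as.character(donors)]),
                        class_ids, policy = label_policy)
      recipes[[length(recipes) + 1L]] <- list(
        tail_id = tid, tail_class = cid,
        donor_ids = donors,
        donor_classes = unname(donor_class[as.character(donors)]),
        s = vapply(masks, function(m) m$s, numeric(1)),
        rect = lapply(masks, function(m) m$rect),
        tail_fraction = mean(comp$owner == 0L),
        label = lab, image = comp$image)
    }
  }
  recipes
}

#' Write a recipe log as JSON lines
#'
#' One JSON object per recipe (tail id, donor ids, rectangles, mixing
#' ratios, label weights); pixel data are omitted.
#'
#' @param recipes list from [oversample_tail()].
#' @param path output file.
#' @export
write_recipe_log <- function(recipes, path) {
  lines <- vapply(recipes, function(r) {
    jsonlite::toJSON(list(
      tail_id = r$tail_id, tail_class = r$tail_class,
      donor_ids = r$donor_ids, donor_classes = r$donor_classes,
      s = round(r$s, 6), rect = r$rect,
      tail_fraction = r$tail_fraction,
      label = as.list(r$label)), auto_unbox = TRUE)
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}
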