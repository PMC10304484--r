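#' Dataset manifests
#'
#' A dataset manifest is a tibble with one row per image and columns
#' `sample_id` (stable integer id), `image_path` (relative to a declared
#' image root), `class_id`, `class_name` and `split` (`"train"` or
#' `"test"`). All builders in this package consume and produce manifests;
#' pixel data stay on disk until [load_images()] is called.
#'
#' @param image_path,class_id,class_name,split vectors of equal length.
#' @return a tibble of class `dataset_manifest`.
#' @export
dataset_manifest <- function(image_path, class_id, class_name = NULL, split = "train") {
  n <- length(image_path)
  if (is.null(class_name)) class_name <- paste0("class_", class_id)
  m <- tibble::tibble(
    sample_id = seq_len(n),
    image_path = as.character(image_path),
    class_id = as.integer(class_id),
    class_name = as.character(class_name),
    split = rep_len(as.character(split), n)
  )
  validate_manifest(m)
}

validate_manifest <- function(m) {
  stopifnot(all(c("image_path", "class_id", "class_name", "split") %in% names(m)))
  if (!"sample_id" %in% names(m)) m$sample_id <- seq_len(nrow(m))
  if (!all(m$split %in% c("train", "test"))) {
    stop("split must be 'train' or 'test'", call. = FALSE)
  }
  for (sp in unique(m$split)) {
    if (anyDuplicated(m$image_path[m$split == sp])) {
      stop("duplicate image_path within split '", sp, "'", call. = FALSE)
    }
  }
  if (!inherits(m, "dataset_manifest")) class(m) <- c("dataset_manifest", class(m))
  m
}

#' Read / write a dataset manifest CSV
#'
#' The on-disk format is a UTF-8 CSV with header
#' `image_path,class_id,class_name,split`; paths are relative to an image
#' root chosen by the caller. Stable `sample_id`s are assigned in file
#' order on read.
#'
#' @param path CSV file path.
#' @return `read_manifest()` returns a `dataset_manifest` tibble.
#' @export
read_manifest <- function(path) {
  m <- utils::read.csv(path, stringsAsFactors = FALSE,
                       colClasses = c(image_path = "character",
                                      class_id = "integer",
                                      class_name = "character",
                                      split = "character"))
  validate_manifest(tibble::as_tibble(m))
}

#' @rdname read_manifest
#' @param manifest a `dataset_manifest`.
#' @export
write_manifest <- function(manifest, path) {
  utils::write.csv(
    manifest[, c("image_path", "class_id", "class_name", "split")],
    path, row.names = FALSE, quote = TRUE, fileEncoding = "UTF-8")
  invisible(path)
}

train_counts <- function(manifest) {
  tr <- manifest[manifest$split == "train", ]
  tab <- table(tr$class_id)
  stats::setNames(as.integer(tab), names(tab))
}

#' Subsample a manifest into a long-tailed training set
#'
#' Reduces the training split of `source` to the per-class target counts
#' given by a sampling plan, a class-size profile, or a named count
#' vector. Selection within each class is uniform without replacement and
#' seeded, so identical seeds reproduce the selection exactly. The test
#' split passes through unchanged (long-tailed benchmarks keep a balanced
#' test set).
#'
#' When `targets` is a `class_size_profile`, its sizes are assigned to
#' classes by rank of their source training count (largest class gets the
#' largest size; ties broken by class id).
#'
#' @param source a `dataset_manifest`.
#' @param targets a `sampling_plan`, a `class_size_profile`, or a named
#'   integer vector of per-class target counts (names = class ids).
#' @param seed integer seed for the within-class selection.
#' @return a `dataset_manifest` whose training split has exactly the
#'   target counts; `sample_id`s are retained from `source`.
#' @export
subsample_manifest <- function(source, targets, seed = 1L) {
  source <- validate_manifest(source)
  cnt <- train_counts(source)
  if (inherits(targets, "class_size_profile")) {
    if (length(targets$sizes) != length(cnt)) {
      stop("profile has ", length(targets$sizes), " sizes but manifest has ",
           length(cnt), " classes", call. = FALSE)
    }
    ord <- order(-cnt, as.integer(names(cnt)))
    tgt <- integer(length(cnt))
    tgt[ord] <- targets$sizes
    names(tgt) <- names(cnt)
  } else if (inherits(targets, "sampling_plan")) {
    id_of <- unique(source[source$split == "train", c("class_id", "class_name")])
    idx <- match(id_of$class_name, targets$class_name)
    if (anyNA(idx)) {
      stop("sampling plan is missing class(es): ",
           paste(id_of$class_name[is.na(idx)], collapse = ", "), call. = FALSE)
    }
    tgt <- stats::setNames(targets$s_i[idx], id_of$class_id)
  } else {
    if (is.null(names(targets))) stop("targets vector must be named by class id", call. = FALSE)
    tgt <- targets[names(cnt)]
    if (anyNA(tgt)) stop("targets missing for some classes", call. = FALSE)
  }
  over <- tgt > cnt[names(tgt)]
  if (any(over)) {
    stop("target count exceeds source count for class(es): ",
         paste(names(tgt)[over], collapse = ", "), call. = FALSE)
  }
  set.seed(seed)
  keep <- logical(nrow(source))
  keep[source$split == "test"] <- TRUE
  for (cid in names(tgt)) {
    rows <- which(source$split == "train" & source$class_id == as.integer(cid))
    keep[sample(rows, tgt[[cid]])] <- TRUE
  }
  out <- source[keep, ]
  class(out) <- class(source)
  out
}

#' Summary statistics of a training manifest
#'
#' Computes the totals that characterise a long-tailed training set: the
#' per-class counts, the imbalance ratio (maximum over minimum per-class
#' count) and the mean class size \eqn{m = D / n} where \eqn{D} is the
#' total number of training images and \eqn{n} the number of classes.
#' `m` is real-valued; resampling targets use `floor(m)`.
#'
#' @param manifest a `dataset_manifest` with a non-empty training split.
#' @return a list of class `dataset_stats` with `total`, `n_classes`,
#'   `per_class` (named counts), `imbalance_ratio`, `mean_m`.
#' @export
dataset_stats <- function(manifest) {
  manifest <- validate_manifest(manifest)
  cnt <- train_counts(manifest)
  if (length(cnt) == 0) stop("manifest has an empty training split", call. = FALSE)
  structure(
    list(total = sum(cnt), n_classes = length(cnt), per_class = cnt,
         imbalance_ratio = imbalance_ratio(as.numeric(cnt)),
         mean_m = sum(cnt) / length(cnt)),
    class = "dataset_stats"
  )
}

#' @export
print.dataset_stats <- function(x, ...) {
  cat(sprintf("<dataset_stats> %d train images, %d classes\n", x$total, x$n_classes))
  cat(sprintf("  imbalance ratio %.4g, mean class size m = %.2f\n",
              x$imbalance_ratio, x$mean_m))
  invisible(x)
}

#' Partition classes into head and tail at the mean class size
#'
#' Head classes are those with strictly more than \eqn{m = D/n} training
#' samples; classes with at most \eqn{m} samples (including exactly
#' \eqn{m}) are tail. The two sets are disjoint and cover all classes.
#'
#' @param stats a `dataset_stats` (computed from the same manifest).
#' @return list with integer vectors `head` and `tail` of class ids.
#' @export
split_head_tail <- function(stats) {
  stopifnot(inherits(stats, "dataset_stats"))
  ids <- as.integer(names(stats$per_class))
  is_head <- stats$per_class > stats$mean_m
  list(head = ids[is_head], tail = ids[!is_head])
}
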