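#' Herding selection of representative class samples
#'
#' Ranks the samples of one class by how well they represent the class
#' in feature space and returns the ids of the first `n_select`.
#'
#' Method `"nearest-mean"` (default) ranks samples by ascending
#' Euclidean distance to the class mean feature vector. Method
#' `"greedy-herding"` is the classic exemplar-herding procedure: picks
#' are made one at a time, each chosen to minimise the Euclidean
#' distance between the running mean of the picks and the class mean.
#' Both break ties by sample id, so the ranking is deterministic and
#' invariant to input order.
#'
#' @param features a `feature_matrix` restricted to one class (or a
#'   plain matrix with one row per sample).
#' @param sample_ids ids aligned with the feature rows (taken from the
#'   `feature_matrix` if omitted).
#' @param n_select how many samples to keep (`1 <= n_select <= class size`).
#' @param method `"nearest-mean"` or `"greedy-herding"`.
#' @return integer vector of `n_select` sample ids in selection order.
#' @export
herding_select <- function(features, n_select, sample_ids = NULL,
                           method = c("nearest-mean", "greedy-herding")) {
  method <- match.arg(method)
  if (inherits(features, "feature_matrix")) {
    if (is.null(sample_ids)) sample_ids <- features$sample_ids
    X <- features$vectors
  } else {
    X <- features
    if (is.null(sample_ids)) sample_ids <- seq_len(nrow(X))
  }
  n <- nrow(X)
  if (n_select < 1 || n_select > n) {
    stop("n_select must be between 1 and the class size (", n, ")", call. = FALSE)
  }
  mu <- colMeans(X)
  if (method == "nearest-mean") {
    d <- sqrt(rowSums(sweep(X, 2, mu)^2))
    return(sample_ids[order(d, sample_ids)][seq_len(n_select)])
  }
  # greedy herding: argmin over remaining x of || mu - (S + x)/(t) ||
  picked <- integer(0)
  remaining <- seq_len(n)
  S <- numeric(ncol(X))
  for (t in seq_len(n_select)) {
    cand <- sweep(X[remaining, , drop = FALSE], 2, S, "+") / t
    d <- sqrt(rowSums(sweep(cand, 2, mu)^2))
    best <- remaining[order(d, sample_ids[remaining])][1]
    picked <- c(picked, best)
    S <- S + X[best, ]
    remaining <- setdiff(remaining, best)
  }
  sample_ids[picked]
}

#' Undersample head classes by herding
#'
#' Partitions every head class into the herding-selected set
#' \eqn{D_s} (exactly `m_target` samples, the most representative ones)
#' and the removed set \eqn{D_r} (everything else). \eqn{D_s} is what
#' phase II trains on for head classes; \eqn{D_r} becomes the donor pool
#' for tail-class CutMix augmentation.
#'
#' @param manifest a `dataset_manifest`.
#' @param features a `feature_matrix` covering the head-class training
#'   samples.
#' @param head_ids class ids of the head classes (each with more than
#'   `m_target` training samples).
#' @param m_target integer per-class target (`floor(m)`).
#' @param method passed to [herding_select()].
#' @return a tibble of class `head_partition` with columns `class_id`,
#'   `sample_id`, `status` (`"selected"` or `"removed"`).
#' @export
undersample_heads <- function(manifest, features, head_ids, m_target,
                              method = "nearest-mean") {
  tr <- manifest[manifest$split == "train", ]
  out <- list()
  for (cid in head_ids) {
    ids <- tr$sample_id[tr$class_id == cid]
    if (length(ids) <= m_target) {
      stop("class ", cid, " has ", length(ids),
           " samples, not more than the target ", m_target,
           "; it is not a head class", call. = FALSE)
    }
    sel <- herding_select(feature_rows(features, ids), m_target,
                          sample_ids = ids, method = method)
    out[[length(out) + 1L]] <- tibble::tibble(
      class_id = cid,
      sample_id = ids,
      status = ifelse(ids %in% sel, "selected", "removed"))
  }
  part <- if (length(out)) do.call(rbind, out) else
    tibble::tibble(class_id = integer(), sample_id = integer(), status = character())
  class(part) <- c("head_partition", class(part))
  part
}

#' Read / write a head partition CSV
#'
#' On-disk format: `class_id,sample_id,status` with
#' `status` in `selected`/`removed`.
#'
#' @param partition a `head_partition`.
#' @param path CSV file path.
#' @export
write_partition <- function(partition, path) {
  utils::write.csv(as.data.frame(partition), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_partition
#' @export
read_partition <- function(path) {
  p <- tibble::as_tibble(utils::read.csv(path, stringsAsFactors = FALSE))
  stopifnot(all(p$status %in% c("selected", "removed")))
  class(p) <- c("head_partition", class(p))
  p
}

partition_ids <- function(partition, status) {
  partition$sample_id[partition$status == status]
}
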