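#' Construct a long-tailed class-size profile
#'
#' Builds the ordered vector of per-class training-set sizes that defines a
#' long-tailed benchmark. The default `"geometric"` shape is deterministic
#' and log-linear in class rank: the size at rank \eqn{i} (0-based) is
#' \eqn{round(n_{max} \rho^i)} with \eqn{\rho = (n_{min}/n_{max})^{1/(C-1)}},
#' which pins both endpoints exactly and yields imbalance ratio
#' \eqn{n_{max}/n_{min}}. The `"pareto-sample"` shape draws class sizes from
#' a Pareto law with power `alpha`, sorts them descending and rescales
#' affinely onto the `[n_min, n_max]` endpoints; `"file"` takes the sizes
#' verbatim from `sizes`.
#'
#' The packaged defaults (101 classes, 750 down to 5) reproduce the
#' aggregates of the Food101-LT benchmark: imbalance ratio 150 and a
#' training set of over 11,000 images.
#'
#' @param n_classes number of classes (>= 2).
#' @param n_max largest per-class training count (rank 0).
#' @param n_min smallest per-class training count (last rank); must be
#'   strictly less than `n_max` and at least 1.
#' @param shape one of `"geometric"`, `"pareto-sample"`, `"file"`.
#' @param alpha power parameter of the Pareto law (used by
#'   `"pareto-sample"`; default 6).
#' @param seed integer seed for the stochastic `"pareto-sample"` shape.
#' @param sizes integer vector of per-class sizes, rank order (only for
#'   `shape = "file"`).
#' @return an object of class `class_size_profile`: a list with `sizes`
#'   (non-increasing integer vector), `alpha`, `n_max`, `n_min`, `shape`.
#' @examples
#' prof <- make_rank_profile(101, 750, 5)
#' imbalance_ratio(prof)   # 150
#' sum(prof$sizes)         # > 11000
#' @export
make_rank_profile <- function(n_classes, n_max = 750, n_min = 5,
                              shape = c("geometric", "pareto-sample", "file"),
                              alpha = 6, seed = NULL, sizes = NULL) {
  shape <- match.arg(shape)
  if (n_classes < 2) stop("n_classes must be at least 2", call. = FALSE)
  if (shape != "file") {
    if (n_min < 1) stop("n_min must be at least 1", call. = FALSE)
    if (n_min >= n_max) {
      stop("invalid profile: n_min (", n_min, ") must be strictly less than n_max (",
           n_max, ")", call. = FALSE)
    }
  }
  s <- switch(shape,
    geometric = {
      rho <- (n_min / n_max)^(1 / (n_classes - 1))
      round(n_max * rho^(seq_len(n_classes) - 1))
    },
    `pareto-sample` = {
      if (!is.null(seed)) set.seed(seed)
      if (alpha <= 0) stop("alpha must be positive", call. = FALSE)
      # standard Pareto(alpha) draws, sorted heavy-end first
      x <- sort(stats::runif(n_classes)^(-1 / alpha), decreasing = TRUE)
      # affine map so the extremes land exactly on n_max / n_min
      x <- (x - min(x)) / (max(x) - min(x))
      round(n_min + x * (n_max - n_min))
    },
    file = {
      if (is.null(sizes)) stop("shape 'file' requires `sizes`", call. = FALSE)
      if (length(sizes) != n_classes)
        stop("`sizes` must have length n_classes", call. = FALSE)
      if (is.unsorted(rev(sizes))) stop("`sizes` must be non-increasing", call. = FALSE)
      as.integer(round(sizes))
    }
  )
  s <- as.integer(s)
  if (shape == "file") {
    n_max <- s[1]
    n_min <- s[length(s)]
  }
  stopifnot(s[1] == n_max, s[n_classes] == n_min, !is.unsorted(rev(s)))
  structure(
    list(sizes = s, alpha = alpha, n_max = as.integer(n_max),
         n_min = as.integer(n_min), shape = shape),
    class = "class_size_profile"
  )
}

#' Imbalance ratio of a profile or per-class count vector
#'
#' The imbalance ratio of a long-tailed dataset is the largest per-class
#' training count divided by the smallest.
#'
#' @param x a `class_size_profile` or a numeric vector of per-class counts.
#' @return a single number, `max(counts) / min(counts)`.
#' @export
imbalance_ratio <- function(x) {
  counts <- if (inherits(x, "class_size_profile")) x$sizes else x
  if (any(counts <= 0)) stop("counts must be positive", call. = FALSE)
  max(counts) / min(counts)
}

#' @export
print.class_size_profile <- function(x, ...) {
  cat(sprintf("<class_size_profile> %d classes, shape=%s\n",
              length(x$sizes), x$shape))
  cat(sprintf("  sizes %d .. %d  (imbalance ratio %.4g, total %d)\n",
              x$n_max, x$n_min, imbalance_ratio(x), sum(x$sizes)))
  invisible(x)
}

#' Read a class-size profile from a plain-text file
#'
#' One integer per line, rank order (largest class first).
#'
#' @param path file path.
#' @return a `class_size_profile`.
#' @export
read_profile <- function(path) {
  s <- as.integer(readLines(path))
  make_rank_profile(length(s), shape = "file", sizes = s)
}

#' Write a class-size profile to a plain-text file
#'
#' @param profile a `class_size_profile`.
#' @param path file path; one integer per line, rank order.
#' @export
write_profile <- function(profile, path) {
  writeLines(as.character(profile$sizes), path)
  invisible(path)
}
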