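#' Load the packaged food consumption-frequency table
#'
#' The table lists 74 common U.S. food types, each matched to an 8-digit
#' FNDDS food code and to its consumption frequency: how often the food
#' was reported eaten per day in NHANES 2009--2016 among 17,796 healthy
#' U.S. adults aged 20--65. These frequencies drive the construction of a
#' realistically long-tailed benchmark: class sizes are scaled by
#' frequency so that the most frequently consumed foods become the head
#' classes.
#'
#' @param path path to a TSV with columns
#'   `index, food_type, food_code, consumption_frequency`; defaults to the
#'   packaged table.
#' @return a tibble with those four columns and attribute `f_max`
#'   (the maximum consumption frequency), of class `frequency_table`.
#' @examples
#' ft <- load_frequency_table()
#' nrow(ft)            # 74
#' attr(ft, "f_max")   # 8275
#' @export
load_frequency_table <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "vfn_frequency_table.tsv", package = "tailmix")
  }
  tab <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                           colClasses = c("integer", "character", "character", "integer"))
  expected <- c("index", "food_type", "food_code", "consumption_frequency")
  if (!identical(names(tab), expected)) {
    stop("frequency table must have columns ", paste(expected, collapse = ", "),
         call. = FALSE)
  }
  if (any(tab$consumption_frequency <= 0)) {
    stop("all consumption frequencies must be strictly positive", call. = FALSE)
  }
  if (anyDuplicated(tab$food_code)) {
    stop("food codes must be unique", call. = FALSE)
  }
  tab <- tibble::as_tibble(tab)
  attr(tab, "f_max") <- max(tab$consumption_frequency)
  class(tab) <- c("frequency_table", class(tab))
  tab
}

# round half away from zero (base round() is half-to-even)
round_half_away <- function(x) sign(x) * floor(abs(x) + 0.5)

#' Frequency-scaled sampling plan for a long-tailed benchmark
#'
#' For each class \eqn{i} with \eqn{n_i} source images matched to a food
#' type with consumption frequency \eqn{f_i}, the number of training
#' images to keep is \eqn{s_i = n_i f_i / f_{max}}, rounded half away from
#' zero and floored at 1 so every class retains at least one image. The
#' class matched to the most frequent food keeps all of its images.
#'
#' @param table a `frequency_table` from [load_frequency_table()].
#' @param source_counts named integer vector: per-class source image
#'   counts, names are class names.
#' @param matching named character vector mapping class name to the
#'   `food_type` of its table row; defaults to the identity (class names
#'   are food types).
#' @return a tibble of class `sampling_plan` with columns `class_name`,
#'   `food_type`, `n_i`, `f_i`, `s_i`.
#' @examples
#' ft <- load_frequency_table()
#' frequency_plan(ft, c(Cookies = 100, `Yeast breads` = 120))
#' @export
frequency_plan <- function(table, source_counts, matching = NULL) {
  if (is.null(names(source_counts))) {
    stop("source_counts must be a named vector (class names)", call. = FALSE)
  }
  if (any(source_counts < 1)) stop("source counts must be positive", call. = FALSE)
  cls <- names(source_counts)
  food <- if (is.null(matching)) cls else unname(matching[cls])
  idx <- match(food, table$food_type)
  if (anyNA(idx)) {
    stop("no frequency-table row for class(es): ",
         paste(cls[is.na(idx)], collapse = ", "), call. = FALSE)
  }
  f_max <- attr(table, "f_max")
  if (is.null(f_max)) f_max <- max(table$consumption_frequency)
  f_i <- table$consumption_frequency[idx]
  n_i <- as.integer(source_counts)
  s_i <- pmax(1L, as.integer(round_half_away(n_i * f_i / f_max)))
  plan <- tibble::tibble(class_name = cls, food_type = food,
                         n_i = n_i, f_i = f_i, s_i = s_i)
  stopifnot(all(plan$s_i >= 1L), all(plan$s_i <= plan$n_i))
  class(plan) <- c("sampling_plan", class(plan))
  plan
}
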