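#' Evaluate a model on a test manifest
#'
#' Computes top-1 accuracy overall and separately for head and tail
#' classes. Head and tail accuracies are macro averages (the mean of the
#' per-class accuracies within each group); on a class-balanced test
#' split the overall accuracy equals the mean of all per-class
#' accuracies, so macro and micro coincide.
#'
#' @param model a `tailmix_net`.
#' @param manifest a `dataset_manifest` whose test split covers every
#'   class in the head/tail split.
#' @param images an `image_store` covering the test split.
#' @param head_tail list with `head` and `tail` class-id vectors, from
#'   [split_head_tail()].
#' @param metadata optional named list recorded in the report (dataset,
#'   method, seed, ...).
#' @return an `eval_report`: list with `overall`, `head`, `tail` (top-1
#'   accuracies in percent), `per_class`, `n_head`, `n_tail`, `metadata`.
#' @export
evaluate_model <- function(model, manifest, images, head_tail,
                           metadata = list()) {
  te <- manifest[manifest$split == "test", ]
  if (nrow(te) == 0) stop("manifest has an empty test split", call. = FALSE)
  known <- c(head_tail$head, head_tail$tail)
  if (!all(te$class_id %in% known)) {
    stop("test split contains class(es) absent from the head/tail split",
         call. = FALSE)
  }
  pred <- net_predict(model, pixel_rows(images, te$sample_id))
  eval_core(pred, te$class_id, head_tail, metadata)
}

# accuracy bookkeeping shared by evaluate_model and tests
eval_core <- function(pred, truth, head_tail, metadata = list()) {
  correct <- pred == truth
  cls <- sort(unique(truth))
  per_class <- vapply(cls, function(cid)
    100 * mean(correct[truth == cid]), numeric(1))
  names(per_class) <- cls
  macro <- function(ids) {
    ids <- intersect(ids, as.integer(names(per_class)))
    if (length(ids) == 0) NA_real_ else mean(per_class[as.character(ids)])
  }
  structure(list(
    overall = 100 * mean(correct),
    head = macro(head_tail$head),
    tail = macro(head_tail$tail),
    per_class = per_class,
    n_head = length(head_tail$head), n_tail = length(head_tail$tail),
    metadata = metadata),
    class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("<eval_report> overall %.1f%% | head %.1f%% (%d) | tail %.1f%% (%d)\n",
              x$overall, x$head, x$n_head, x$tail, x$n_tail))
  invisible(x)
}

#' Tabulate evaluation reports
#'
#' Renders a list of named reports as a Head/Tail/Overall table, in
#' markdown (best value per column bolded) or TSV.
#'
#' @param reports named list of `eval_report`s (names are method labels).
#' @param format `"markdown"` or `"tsv"`.
#' @return a character string (the table).
#' @export
report_table <- function(reports, format = c("markdown", "tsv")) {
  format <- match.arg(format)
  stopifnot(length(reports) > 0)
  if (is.null(names(reports))) names(reports) <- paste0("method_", seq_along(reports))
  df <- data.frame(
    Method = names(reports),
    Head = vapply(reports, function(r) r$head, numeric(1)),
    Tail = vapply(reports, function(r) r$tail, numeric(1)),
    Overall = vapply(reports, function(r) r$overall, numeric(1)))
  if (format == "tsv") {
    con <- textConnection("out", "w", local = TRUE)
    utils::write.table(df, con, sep = "\t", row.names = FALSE, quote = FALSE)
    close(con)
    return(paste(out, collapse = "\n"))
  }
  fmt <- function(v, col) {
    s <- sprintf("%.1f", v)
    s[v == max(v)] <- paste0("**", s[v == max(v)], "**")
    s
  }
  lines <- c("| Method | Head | Tail | Overall |",
             "|---|---|---|---|",
             sprintf("| %s | %s | %s | %s |", df$Method,
                     fmt(df$Head), fmt(df$Tail), fmt(df$Overall)))
  paste(lines, collapse = "\n")
}

#' Write an evaluation report as JSON
#'
#' @param report an `eval_report`.
#' @param path output file.
#' @export
write_eval_report <- function(report, path) {
  jsonlite::write_json(
    list(overall = report$overall, head = report$head, tail = report$tail,
         per_class = as.list(report$per_class),
         n_head = report$n_head, n_tail = report$n_tail,
         metadata = report$metadata),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
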