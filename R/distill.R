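#' Temperature-softened class distribution
#'
#' Divides the logits by the temperature `T` and applies a numerically
#' stable softmax: component \eqn{i} is
#' \eqn{\exp(z_i/T) / \sum_j \exp(z_j/T)}. A temperature below 1 sharpens
#' the distribution (efficient knowledge transfer); a temperature above 1
#' flattens it towards uniform (exposes "dark" inter-class structure).
#'
#' @param logits finite numeric vector, or a matrix with one row per
#'   sample.
#' @param temperature positive scalar `T`.
#' @return probabilities of the same shape as `logits`; each vector/row
#'   is strictly positive and sums to 1.
#' @examples
#' softened_distribution(c(2, 0), 1)    # c(0.8808, 0.1192)
#' softened_distribution(c(2, 0), 0.5)  # sharper: c(0.9820, 0.0180)
#' @export
softened_distribution <- function(logits, temperature = 0.5) {
  if (!all(is.finite(logits))) stop("logits must be finite", call. = FALSE)
  if (!is.numeric(temperature) || length(temperature) != 1 || temperature <= 0) {
    stop("temperature must be a positive scalar", call. = FALSE)
  }
  if (is.matrix(logits)) {
    z <- logits / temperature
    z <- z - apply(z, 1, max)
    e <- exp(z)
    e / rowSums(e)
  } else {
    z <- logits / temperature
    e <- exp(z - max(z))
    e / sum(e)
  }
}

# row-wise log-softmax of logits/T, numerically stable
log_softened <- function(logits, temperature) {
  z <- if (is.matrix(logits)) logits / temperature else matrix(logits / temperature, nrow = 1)
  mx <- apply(z, 1, max)
  z <- z - mx
  z - log(rowSums(exp(z)))
}

#' Knowledge-distillation loss
#'
#' Cross-entropy of the student's temperature-softened distribution under
#' the teacher's temperature-softened distribution,
#' \eqn{-\sum_i p^T_{teacher}(i) \log p^T_{student}(i)} (natural log).
#' By Gibbs' inequality this is at least the entropy of the softened
#' teacher, with equality exactly when the two softened distributions
#' coincide; minimising it drives the phase-II student to reproduce the
#' frozen phase-I teacher's outputs on the retained head-class samples.
#'
#' @param teacher_logits,student_logits finite numeric vectors of equal
#'   length (one logit per class), or matrices with one row per sample.
#' @param temperature positive scalar `T` (default 0.5).
#' @return a non-negative scalar (or one value per row for matrix input).
#' @examples
#' kd_loss(c(0, 0, 0, 0), c(0, 0, 0, 0), 1)  # log(4)
#' @export
kd_loss <- function(teacher_logits, student_logits, temperature = 0.5) {
  if (length(teacher_logits) != length(student_logits)) {
    stop("teacher and student logits must have the same length", call. = FALSE)
  }
  if (is.matrix(teacher_logits) != is.matrix(student_logits)) {
    stop("teacher and student logits must have the same shape", call. = FALSE)
  }
  p_t <- softened_distribution(teacher_logits, temperature)
  ls <- log_softened(student_logits, temperature)
  if (is.matrix(teacher_logits)) {
    -rowSums(p_t * ls)
  } else {
    -sum(p_t * as.vector(ls))
  }
}

#' Distillation configuration
#'
#' @param temperature softmax temperature `T` (> 0; default 0.5).
#' @param weight loss weight of the KD term in the phase-II objective
#'   (>= 0; default 1).
#' @param scope which samples the KD term applies to:
#'   `"selected-head-only"` (default; the herding-selected head samples)
#'   or `"all-samples"`.
#' @param t_squared multiply the KD term by `T^2` (common gradient-scale
#'   convention; off by default).
#' @return list of class `distill_config`.
#' @export
distill_config <- function(temperature = 0.5, weight = 1,
                           scope = c("selected-head-only", "all-samples"),
                           t_squared = FALSE) {
  scope <- match.arg(scope)
  stopifnot(temperature > 0, weight >= 0)
  structure(list(temperature = temperature, weight = weight,
                 scope = scope, t_squared = t_squared),
            class = "distill_config")
}
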