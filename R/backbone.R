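#' Compact convolutional classification backbone
#'
#' A small convolutional network sized for desk-scale fixtures: one 3x3
#' convolution with stride 2 (He-initialised), ReLU, 3x3 average
#' pooling with stride 3, a dense ReLU hidden layer (the penultimate
#' representation used for herding and visual retrieval), and a linear
#' output layer with one logit per class. Inputs are flattened `[0,1]`
#' pixel vectors, centred at 0.5 internally. The convolution + pooling
#' front end makes the features tolerant to the position jitter and
#' patch translation that CutMix composition introduces, which a dense
#' network on raw pixels is not. Implemented as im2col matrix algebra,
#' so training runs in seconds on the synthetic benchmarks.
#'
#' @param width,height input image size in pixels (>= 16 each).
#' @param n_classes number of output classes.
#' @param n_filters convolution filters (default 12).
#' @param n_hidden dense hidden width (default 64).
#' @param seed integer seed for the He-scaled Gaussian initialisation.
#' @return list of class `tailmix_net` holding the weights and the
#'   precomputed layer geometry; `class_ids` is filled by the trainers.
#' @export
net_init <- function(width, height, n_classes, n_filters = 12L,
                     n_hidden = 64L, seed = 1L) {
  stopifnot(width >= 16, height >= 16)
  set.seed(seed)
  oh <- (height - 3L) %/% 2L + 1L   # conv output rows, stride 2
  ow <- (width - 3L) %/% 2L + 1L
  ph <- oh %/% 3L                   # pool output rows, stride 3
  pw <- ow %/% 3L
  # im2col index: for conv position (i, j), the 27 input offsets
  pos <- expand.grid(i = seq_len(oh), j = seq_len(ow))
  off <- expand.grid(di = 0:2, dj = 0:2, ch = 0:2)
  idx <- matrix(0L, nrow = nrow(pos), ncol = nrow(off))
  for (o in seq_len(nrow(off))) {
    r <- (pos$i - 1L) * 2L + off$di[o] + 1L
    cc <- (pos$j - 1L) * 2L + off$dj[o] + 1L
    idx[, o] <- r + (cc - 1L) * height + off$ch[o] * (height * width)
  }
  # pool cell (0-based) of each conv position; positions beyond the last
  # full 3x3 cell are dropped
  ci <- (pos$i - 1L) %/% 3L
  cj <- (pos$j - 1L) %/% 3L
  keep <- ci < ph & cj < pw
  cell <- ifelse(keep, ci + cj * ph, NA_integer_)
  structure(list(
    Wc = matrix(stats::rnorm(27 * n_filters, 0, sqrt(2 / 27)), 27, n_filters),
    bc = numeric(n_filters),
    W1 = matrix(stats::rnorm(ph * pw * n_filters * n_hidden, 0,
                             sqrt(2 / (ph * pw * n_filters))),
                ph * pw * n_filters, n_hidden),
    b1 = numeric(n_hidden),
    W2 = matrix(stats::rnorm(n_hidden * n_classes, 0, sqrt(2 / n_hidden)),
                n_hidden, n_classes),
    b2 = numeric(n_classes),
    width = width, height = height, n_filters = n_filters,
    n_hidden = n_hidden, n_classes = n_classes,
    n_pos = nrow(pos), n_cells = ph * pw, idx = idx, cell = cell,
    pool_n = 9, class_ids = seq_len(n_classes)),
    class = "tailmix_net")
}

# forward pass; returns intermediates needed for backprop
net_forward <- function(model, X) {
  B <- nrow(X)
  P <- model$n_pos
  # im2col: rows ordered batch-fastest, then position
  A <- matrix(array(X[, as.vector(model$idx)] - 0.5,
                    dim = c(B, P, 27)), B * P, 27)
  Zc <- sweep(A %*% model$Wc, 2, model$bc, "+")
  act_c <- Zc > 0
  Zc[!act_c] <- 0
  # average pooling via rowsum over (batch, cell) groups
  keep <- !is.na(model$cell)
  rows_keep <- rep(keep, each = B)
  grp <- rep(model$cell[keep], each = B) * B + rep.int(seq_len(B), sum(keep))
  pooled <- rowsum(Zc[rows_keep, , drop = FALSE], grp) / model$pool_n
  H1 <- matrix(pooled, B, model$n_cells * model$n_filters)
  Z1 <- sweep(H1 %*% model$W1, 2, model$b1, "+")
  act_1 <- Z1 > 0
  Z1[!act_1] <- 0
  Z <- sweep(Z1 %*% model$W2, 2, model$b2, "+")
  list(A = A, act_c = act_c, H1 = H1, act_1 = act_1, H2 = Z1, Z = Z,
       B = B, rows_keep = rows_keep)
}

# penultimate (dense hidden) representation
net_hidden <- function(model, X) net_forward(model, X)$H2

#' Class logits of a backbone
#'
#' @param model a `tailmix_net`.
#' @param X pixel matrix (one row per image, values in `[0, 1]`).
#' @return `n x n_classes` logit matrix (inference mode; deterministic).
#' @export
net_logits <- function(model, X) net_forward(model, X)$Z

#' @rdname net_logits
#' @return `net_predict()` returns the predicted class id per row.
#' @export
net_predict <- function(model, X) {
  model$class_ids[max.col(net_logits(model, X), ties.method = "first")]
}

#' Extract penultimate-layer features
#'
#' Runs the backbone's lower layers over the given samples and returns
#' one feature vector per manifest record, order-aligned with the sample
#' ids. With `normalize = TRUE` (default) each vector is scaled to unit
#' Euclidean norm, which stabilises the class means used by herding and
#' is required by the cosine retrieval of the CutMix donor search; rows
#' that are exactly zero (a fully inactive ReLU layer) are replaced by a
#' uniform unit vector.
#'
#' @param model a `tailmix_net` trained in phase I.
#' @param images an `image_store`.
#' @param sample_ids which samples to featurise (default: all in the store).
#' @param normalize unit-normalize rows (default TRUE).
#' @return a `feature_matrix`.
#' @export
extract_features <- function(model, images, sample_ids = images$sample_ids,
                             normalize = TRUE) {
  X <- pixel_rows(images, sample_ids)
  H <- net_hidden(model, X)
  if (normalize) {
    nrm <- sqrt(rowSums(H^2))
    zero <- nrm < 1e-12
    if (any(zero)) {
      H[zero, ] <- 1 / sqrt(ncol(H))
      nrm[zero] <- 1
    }
    H <- H / nrm
  }
  feature_matrix(H, sample_ids, normalized = normalize)
}

# combined phase-II batch objective: per-sample soft-target cross-entropy
# plus lambda * KD (teacher vs student at temperature T) on the rows
# flagged by kd_mask, averaged over the batch — i.e. the KD sum over the
# batch's D_s members divided by the batch size. Returns the scalar loss.
batch_loss <- function(logits, targets, kd_mask = NULL, teacher_logits = NULL,
                       kd = NULL) {
  ls <- log_softened(logits, 1)
  ce <- -mean(rowSums(targets * ls))
  if (is.null(kd) || is.null(kd_mask) || !any(kd_mask) || kd$weight == 0) return(ce)
  kl <- kd_loss(teacher_logits[kd_mask, , drop = FALSE],
                logits[kd_mask, , drop = FALSE], kd$temperature)
  scale <- if (isTRUE(kd$t_squared)) kd$temperature^2 else 1
  ce + kd$weight * scale * sum(kl) / nrow(logits)
}

# cosine-decay learning rate over `epochs` epochs
cosine_lr <- function(lr0, epoch, epochs) {
  0.5 * lr0 * (1 + cos(pi * (epoch - 1) / epochs))
}

# SGD-with-momentum engine. `provider(epoch)` returns the epoch's data:
# list(X, Y, kd_mask = NULL, teacher_logits = NULL). Cross-entropy uses
# soft targets (rows of Y sum to 1); KD gradient flows only to the
# student. The cosine schedule spans `schedule_total` epochs starting at
# `schedule_offset` (so a phase-II run continues phase I's decay rather
# than restarting it). Returns list(model, log).
train_sgd <- function(model, provider, epochs, lr0 = 0.1, momentum = 0.9,
                      batch_size = 64L, seed = 1L, kd = NULL,
                      schedule_offset = 0L, schedule_total = NULL) {
  if (is.null(schedule_total)) schedule_total <- schedule_offset + epochs
  set.seed(seed)
  wn <- c("Wc", "bc", "W1", "b1", "W2", "b2")
  vel <- lapply(model[wn], function(w) w * 0)
  log <- data.frame(epoch = integer(), lr = numeric(), loss = numeric(),
                    accuracy = numeric())
  for (epoch in seq_len(epochs)) {
    dat <- provider(epoch)
    n <- nrow(dat$X)
    lr <- cosine_lr(lr0, schedule_offset + epoch, schedule_total)
    ord <- sample.int(n)
    tot_loss <- 0; tot_correct <- 0
    for (start in seq(1, n, by = batch_size)) {
      idx <- ord[start:min(start + batch_size - 1L, n)]
      Xb <- dat$X[idx, , drop = FALSE]
      Yb <- dat$Y[idx, , drop = FALSE]
      fw <- net_forward(model, Xb)
      P <- softened_distribution(fw$Z, 1)
      b <- length(idx)
      use_kd <- !is.null(kd) && !is.null(dat$kd_mask) && !is.null(dat$teacher_logits)
      loss <- batch_loss(fw$Z, Yb,
                         kd_mask = if (use_kd) dat$kd_mask[idx] else NULL,
                         teacher_logits = if (use_kd) dat$teacher_logits[idx, , drop = FALSE] else NULL,
                         kd = if (use_kd) kd else NULL)
      dZ <- (P - Yb) / b
      if (use_kd && kd$weight > 0 && any(dat$kd_mask[idx])) {
        km <- dat$kd_mask[idx]
        Tt <- kd$temperature
        Ps <- softened_distribution(fw$Z[km, , drop = FALSE], Tt)
        Pt <- softened_distribution(dat$teacher_logits[idx, , drop = FALSE][km, , drop = FALSE], Tt)
        scale <- if (isTRUE(kd$t_squared)) Tt^2 else 1
        dZ[km, ] <- dZ[km, ] + kd$weight * scale * (Ps - Pt) / (Tt * b)
      }
      g <- net_backward(model, fw, dZ)
      for (w in wn) {
        vel[[w]] <- momentum * vel[[w]] - lr * g[[w]]
        model[[w]] <- model[[w]] + vel[[w]]
      }
      tot_loss <- tot_loss + loss * b
      hard <- max.col(Yb, ties.method = "first")
      tot_correct <- tot_correct + sum(max.col(P, ties.method = "first") == hard)
    }
    log <- rbind(log, data.frame(epoch = epoch, lr = lr,
                                 loss = tot_loss / n,
                                 accuracy = tot_correct / n))
  }
  list(model = model, log = log)
}

# gradients of all weights given the forward intermediates and dL/dZ
net_backward <- function(model, fw, dZ) {
  B <- fw$B
  dW2 <- crossprod(fw$H2, dZ)
  db2 <- colSums(dZ)
  dH2 <- dZ %*% t(model$W2)
  dH2[!fw$act_1] <- 0
  dW1 <- crossprod(fw$H1, dH2)
  db1 <- colSums(dH2)
  dH1 <- dH2 %*% t(model$W1)
  # un-pool: spread each cell gradient to its 9 conv positions, / pool_n
  dPool <- array(dH1, dim = c(B, model$n_cells, model$n_filters))
  dZc <- matrix(0, nrow = B * model$n_pos, ncol = model$n_filters)
  cell_idx <- model$cell + 1L           # NA outside full pool cells
  keep <- !is.na(cell_idx)
  # rows ordered batch-fastest within position
  sel <- rep(keep, each = B)
  pos_cells <- rep(cell_idx[keep], each = B)
  batch_rep <- rep.int(seq_len(B), sum(keep))
  for (f in seq_len(model$n_filters)) {
    dZc[sel, f] <- dPool[cbind(batch_rep, pos_cells, f)] / model$pool_n
  }
  dZc[!fw$act_c] <- 0
  dWc <- crossprod(fw$A, dZc)
  dbc <- colSums(dZc)
  list(Wc = dWc, bc = dbc, W1 = dW1, b1 = db1, W2 = dW2, b2 = db2)
}

# one-hot (or pass-through soft) target matrix over the model's classes
one_hot <- function(class_id, class_ids) {
  Y <- matrix(0, nrow = length(class_id), ncol = length(class_ids))
  Y[cbind(seq_along(class_id), match(class_id, class_ids))] <- 1
  Y
}
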