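#' Training configuration for the two-phase framework
#'
#' Defaults follow the framework's reference settings: SGD with momentum
#' 0.9, initial learning rate 0.1 with cosine decay, 50 epochs of
#' phase-I standard training on all data and 100 epochs of phase-II
#' training on the balanced set, distillation temperature 0.5, and
#' single-donor (`k = 1`) visual-aware CutMix. The test suite and the
#' packaged benchmark scale the epoch counts down.
#'
#' @param epochs_phase1,epochs_phase2 epoch counts for the two phases.
#' @param lr initial learning rate of the cosine schedule.
#' @param momentum SGD momentum.
#' @param batch_size mini-batch size.
#' @param n_filters convolution filters of the compact backbone.
#' @param n_hidden dense hidden width of the compact backbone.
#' @param kd a [distill_config()].
#' @param cutmix list: `k` (donors per composite), `s_range`
#'   (mixing-ratio range), `selection` (`"topk"`/`"random"`), `direction`
#'   (`"donor-patch"`/`"tail-patch"`, see [oversample_tail()]),
#'   `label_policy` (`"area-mix"`/`"tail-only"`), `br_size` (head batch
#'   size), `on_the_fly` (regenerate recipes every epoch).
#' @param herding_method passed to [undersample_heads()].
#' @param warm_start initialise the phase-II student from the phase-I
#'   weights (default) or from a fresh seed.
#' @param seed master seed; all stage seeds derive from it.
#' @return list of class `train_config`.
#' @export
train_config <- function(epochs_phase1 = 50L, epochs_phase2 = 100L,
                         lr = 0.1, momentum = 0.9, batch_size = 64L,
                         n_filters = 12L, n_hidden = 64L, kd = distill_config(),
                         cutmix = list(), herding_method = "greedy-herding",
                         warm_start = TRUE, seed = 1L) {
  stopifnot(epochs_phase1 >= 1, epochs_phase2 >= 1, lr > 0)
  cm_def <- list(k = 1L, s_range = c(0, 1), selection = "topk",
                 direction = "donor-patch", label_policy = "area-mix",
                 br_size = 32L, on_the_fly = TRUE)
  structure(list(epochs_phase1 = epochs_phase1, epochs_phase2 = epochs_phase2,
                 lr = lr, momentum = momentum, batch_size = batch_size,
                 n_filters = n_filters, n_hidden = n_hidden, kd = kd,
                 cutmix = utils::modifyList(cm_def, cutmix),
                 herding_method = herding_method,
                 warm_start = warm_start, seed = as.integer(seed)),
            class = "train_config")
}

train_xy <- function(manifest, images, class_ids) {
  tr <- manifest[manifest$split == "train", ]
  list(X = pixel_rows(images, tr$sample_id),
       Y = one_hot(tr$class_id, class_ids),
       sample_ids = tr$sample_id, class_id = tr$class_id)
}

#' Phase I: standard training on all data
#'
#' Trains the compact backbone with plain cross-entropy on every
#' training sample. The resulting model is the feature extractor, the
#' frozen distillation teacher, and (by default) the initialisation of
#' the phase-II student.
#'
#' @param manifest a `dataset_manifest` with a non-empty training split.
#' @param images an `image_store` covering the manifest.
#' @param config a [train_config()].
#' @return list with `model` (a `tailmix_net`) and `log` (per-epoch
#'   loss/accuracy data frame).
#' @export
train_phase1 <- function(manifest, images, config = train_config()) {
  tr <- manifest[manifest$split == "train", ]
  if (nrow(tr) == 0) stop("manifest has an empty training split", call. = FALSE)
  class_ids <- sort(unique(manifest$class_id))
  dat <- train_xy(manifest, images, class_ids)
  model <- net_init(images$width, images$height, length(class_ids),
                    n_filters = config$n_filters, n_hidden = config$n_hidden,
                    seed = config$seed)
  model$class_ids <- class_ids
  # one cosine schedule spans both phases; phase I covers its first leg
  fit <- train_sgd(model, function(epoch) dat, config$epochs_phase1,
                   lr0 = config$lr, momentum = config$momentum,
                   batch_size = config$batch_size, seed = config$seed + 1L,
                   schedule_total = config$epochs_phase1 + config$epochs_phase2)
  fit
}

#' Build the balanced phase-II training plan
#'
#' Computes the head/tail split at the mean class size \eqn{m = D/n},
#' extracts penultimate features with the phase-I model, herds every
#' head class down to `floor(m)` selected samples, and generates CutMix
#' recipes that raise every tail class to `floor(m)` effective samples
#' using the removed head samples as donor pool. The resulting plan
#' makes every class's effective count exactly `floor(m)`.
#'
#' @param manifest a `dataset_manifest`.
#' @param model the phase-I backbone.
#' @param images an `image_store`.
#' @param config a [train_config()].
#' @return list of class `balanced_plan`: `m_target`, `head`, `tail`,
#'   `partition` (a `head_partition`), `recipes`, `features`, `stats`.
#' @export
build_balanced_set <- function(manifest, model, images, config = train_config()) {
  stats <- dataset_stats(manifest)
  ht <- split_head_tail(stats)
  m_target <- floor(stats$mean_m)
  tr_ids <- manifest$sample_id[manifest$split == "train"]
  features <- extract_features(model, images, tr_ids)
  partition <- undersample_heads(manifest, features, ht$head, m_target,
                                 method = config$herding_method)
  donor_pool <- partition_ids(partition, "removed")
  need <- any(stats$per_class[as.character(ht$tail)] < m_target)
  recipes <- if (need && length(donor_pool) > 0) {
    oversample_tail(manifest, ht$tail, donor_pool, features, images,
                    m_target, k = config$cutmix$k,
                    br_size = config$cutmix$br_size,
                    s_range = config$cutmix$s_range,
                    selection = config$cutmix$selection,
                    direction = config$cutmix$direction,
                    label_policy = config$cutmix$label_policy,
                    seed = config$seed + 2L)
  } else list()
  structure(list(m_target = m_target, head = ht$head, tail = ht$tail,
                 partition = partition, recipes = recipes,
                 features = features, stats = stats),
            class = "balanced_plan")
}

#' Save / load a balanced plan (without pixel data)
#'
#' Serialises the plan's structure — target count, head/tail split, the
#' head partition and the recipe metadata (tail ids, donors, rectangles,
#' mixing ratios, labels) — as JSON. Composite pixel data are not
#' stored; they are deterministic given the recipe metadata and images.
#'
#' @param plan a `balanced_plan`.
#' @param path JSON file path.
#' @export
save_plan <- function(plan, path) {
  obj <- list(
    m_target = plan$m_target, head = plan$head, tail = plan$tail,
    partition = as.data.frame(plan$partition),
    recipes = lapply(plan$recipes, function(r)
      r[c("tail_id", "tail_class", "donor_ids", "donor_classes", "s",
          "rect", "tail_fraction", "label")]))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname save_plan
#' @export
load_plan <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE,
                             simplifyDataFrame = FALSE)
  part <- tibble::as_tibble(do.call(
    rbind.data.frame, c(obj$partition, stringsAsFactors = FALSE)))
  if (nrow(part)) part$sample_id <- as.integer(part$sample_id)
  class(part) <- c("head_partition", class(part))
  recipes <- lapply(obj$recipes, function(r) {
    r$tail_id <- as.integer(r$tail_id)
    r$tail_class <- as.integer(r$tail_class)
    r$donor_ids <- as.integer(r$donor_ids)
    r$donor_classes <- as.integer(r$donor_classes)
    r$label <- unlist(r$label)
    r$rect <- lapply(r$rect, unlist)
    r
  })
  structure(list(m_target = obj$m_target, head = obj$head, tail = obj$tail,
                 partition = part, recipes = recipes),
            class = "balanced_plan")
}

# assemble one epoch of phase-II training data from a plan
phase2_epoch_data <- function(manifest, images, plan, teacher, kd_scope,
                              class_ids, recipes) {
  tr <- manifest[manifest$split == "train", ]
  ds_ids <- partition_ids(plan$partition, "selected")
  tail_rows <- tr[tr$class_id %in% plan$tail, ]
  X_head <- pixel_rows(images, ds_ids)
  Y_head <- one_hot(plan$partition$class_id[plan$partition$status == "selected"],
                    class_ids)
  X_tail <- pixel_rows(images, tail_rows$sample_id)
  Y_tail <- one_hot(tail_rows$class_id, class_ids)
  if (length(recipes)) {
    X_mix <- do.call(rbind, lapply(recipes, function(r) flatten_image(r$image)))
    Y_mix <- do.call(rbind, lapply(recipes, function(r)
      r$label[as.character(class_ids)]))
  } else {
    X_mix <- NULL; Y_mix <- NULL
  }
  X <- rbind(X_head, X_tail, X_mix)
  Y <- rbind(Y_head, Y_tail, Y_mix)
  kd_mask <- c(rep(TRUE, nrow(X_head)),
               rep(kd_scope == "all-samples", nrow(X) - nrow(X_head)))
  list(X = X, Y = Y, kd_mask = kd_mask,
       teacher_logits = net_logits(teacher, X))
}

#' Phase II: balanced training with knowledge retention
#'
#' Trains the phase-II student on the balanced set — herding-selected
#' head samples, original tail samples and CutMix composites — with
#' soft-target cross-entropy plus the temperature-scaled distillation
#' loss against the frozen phase-I teacher on the samples in the KD
#' scope (the selected head set \eqn{D_s} by default). When the config's
#' `cutmix$on_the_fly` is set (default), recipes are regenerated with a
#' fresh seeded stream every epoch.
#'
#' @param model_f1 the trained phase-I model (teacher; never updated).
#' @param plan a `balanced_plan` built from the same model.
#' @param manifest,images the training data.
#' @param config a [train_config()].
#' @return list with `model` (the student) and `log`.
#' @export
train_phase2 <- function(model_f1, plan, manifest, images,
                         config = train_config()) {
  class_ids <- model_f1$class_ids
  if (length(class_ids) != length(sort(unique(manifest$class_id))) ||
      !all(sort(unique(manifest$class_id)) %in% class_ids)) {
    stop("plan/model class mismatch with manifest", call. = FALSE)
  }
  student <- if (config$warm_start) model_f1 else {
    m <- net_init(images$width, images$height, length(class_ids),
                  n_filters = config$n_filters, n_hidden = config$n_hidden,
                  seed = config$seed + 10L)
    m$class_ids <- class_ids
    m
  }
  donor_pool <- partition_ids(plan$partition, "removed")
  counts <- plan$stats$per_class
  fresh <- config$cutmix$on_the_fly && length(plan$recipes) > 0
  provider <- function(epoch) {
    recipes <- if (fresh && epoch > 1) {
      oversample_tail(manifest, plan$tail, donor_pool, plan$features, images,
                      plan$m_target, k = config$cutmix$k,
                      br_size = config$cutmix$br_size,
                      s_range = config$cutmix$s_range,
                      selection = config$cutmix$selection,
                      direction = config$cutmix$direction,
                      label_policy = config$cutmix$label_policy,
                      seed = config$seed + 100L + epoch)
    } else plan$recipes
    phase2_epoch_data(manifest, images, plan, model_f1, config$kd$scope,
                      class_ids, recipes)
  }
  train_sgd(student, provider, config$epochs_phase2,
            lr0 = config$lr, momentum = config$momentum,
            batch_size = config$batch_size, seed = config$seed + 3L,
            kd = config$kd,
            schedule_offset = if (config$warm_start) config$epochs_phase1 else 0L,
            schedule_total = if (config$warm_start)
              config$epochs_phase1 + config$epochs_phase2 else NULL)
}

#' Run the full two-phase method
#'
#' Phase I (standard training on all data), balanced-plan construction,
#' and phase II (balanced set + distillation + visual-aware CutMix).
#'
#' @inheritParams train_phase1
#' @return list with `model` (the phase-II student), `model_phase1`,
#'   `plan`, `log_phase1`, `log_phase2`.
#' @export
two_phase_train <- function(manifest, images, config = train_config()) {
  p1 <- train_phase1(manifest, images, config)
  plan <- build_balanced_set(manifest, p1$model, images, config)
  p2 <- train_phase2(p1$model, plan, manifest, images, config)
  list(model = p2$model, model_phase1 = p1$model, plan = plan,
       log_phase1 = p1$log, log_phase2 = p2$log)
}

#' Reference resampling baselines
#'
#' Trains the comparison strategies. The single-phase methods —
#' `baseline-ce`, `ros`, `rus` — are trained from scratch on their
#' (re)sampled data for the full epoch budget
#' (`epochs_phase1 + epochs_phase2`, matching the total budget of the
#' two-phase method), as is conventional for these baselines. The
#' framework ablations — `hus`, `cutmix-random` — run inside the
#' two-phase protocol, since they require the phase-I feature extractor:
#' \describe{
#'   \item{`baseline-ce`}{plain cross-entropy training on all data.}
#'   \item{`ros`}{random oversampling — tail classes duplicated uniformly
#'     at random up to `floor(m)`.}
#'   \item{`rus`}{random undersampling — head classes cut uniformly at
#'     random to `floor(m)`.}
#'   \item{`hus`}{herding undersampling — identical to `rus` (from
#'     scratch, full budget) except that the head subsets are the
#'     herding-selected representative samples, chosen in the phase-I
#'     model's feature space; no distillation, no CutMix. Swapping only
#'     the selection rule isolates it.}
#'   \item{`cutmix-random`}{the full pipeline with donor selection policy
#'     `"random"` instead of visual top-k (context-rich oversampling
#'     baseline); everything else unchanged.}
#' }
#'
#' @inheritParams train_phase1
#' @param strategy one of `"baseline-ce"`, `"ros"`, `"rus"`, `"hus"`,
#'   `"cutmix-random"`.
#' @param phase1 optional precomputed [train_phase1()] result, shared
#'   across the two-phase strategies; ignored by the single-phase ones.
#' @return list with `model`, `log`, and `model_phase1` (NULL for the
#'   single-phase strategies).
#' @export
run_baseline <- function(manifest, images, config = train_config(),
                         strategy = c("baseline-ce", "ros", "rus", "hus",
                                      "cutmix-random"),
                         phase1 = NULL) {
  strategy <- match.arg(strategy)
  class_ids <- sort(unique(manifest$class_id))
  stats <- dataset_stats(manifest)
  ht <- split_head_tail(stats)
  m_target <- floor(stats$mean_m)
  tr <- manifest[manifest$split == "train", ]

  if (strategy == "cutmix-random") {
    if (is.null(phase1)) phase1 <- train_phase1(manifest, images, config)
    model <- phase1$model
    cfg <- config
    cfg$cutmix$selection <- "random"
    plan <- build_balanced_set(manifest, model, images, cfg)
    fit <- train_phase2(model, plan, manifest, images, cfg)
    return(list(model = fit$model, log = fit$log, model_phase1 = model))
  }

  ids <- switch(strategy,
    `baseline-ce` = tr$sample_id,
    hus = {
      if (is.null(phase1)) phase1 <- train_phase1(manifest, images, config)
      features <- extract_features(phase1$model, images, tr$sample_id)
      part <- undersample_heads(manifest, features, ht$head, m_target,
                                method = config$herding_method)
      c(tr$sample_id[tr$class_id %in% ht$tail],
        partition_ids(part, "selected"))
    },
    ros = {
      set.seed(config$seed + 4L)
      keep <- tr$sample_id[tr$class_id %in% ht$head]
      for (cid in ht$tail) {
        own <- tr$sample_id[tr$class_id == cid]
        extra <- m_target - length(own)
        dup <- if (extra > 0) sample(own, extra, replace = TRUE) else integer(0)
        keep <- c(keep, own, dup)
      }
      keep
    },
    rus = {
      set.seed(config$seed + 5L)
      keep <- tr$sample_id[tr$class_id %in% ht$tail]
      for (cid in ht$head) {
        own <- tr$sample_id[tr$class_id == cid]
        keep <- c(keep, sample(own, m_target))
      }
      keep
    })
  cls <- tr$class_id[match(ids, tr$sample_id)]
  model <- net_init(images$width, images$height, length(class_ids),
                    n_filters = config$n_filters, n_hidden = config$n_hidden,
                    seed = config$seed)
  model$class_ids <- class_ids
  dat <- list(X = pixel_rows(images, ids), Y = one_hot(cls, class_ids))
  fit <- train_sgd(model, function(epoch) dat,
                   config$epochs_phase1 + config$epochs_phase2,
                   lr0 = config$lr, momentum = config$momentum,
                   batch_size = config$batch_size, seed = config$seed + 6L)
  list(model = fit$model, log = fit$log,
       model_phase1 = if (is.null(phase1)) NULL else phase1$model)
}
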