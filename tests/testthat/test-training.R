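test_that("training config carries the reference defaults", {
  cfg <- train_config()
  expect_equal(cfg$epochs_phase1, 50L)
  expect_equal(cfg$epochs_phase2, 100L)
  expect_equal(cfg$lr, 0.1)
  expect_equal(cfg$momentum, 0.9)
  expect_equal(cfg$kd$temperature, 0.5)
  expect_equal(cfg$cutmix$k, 1L)
  expect_equal(cfg$cutmix$s_range, c(0, 1))
  expect_error(train_config(epochs_phase1 = 0))
})

test_that("initial loss sits near the uniform-prediction cross-entropy", {
  # with He-initialised small weights the network is near-uniform, so the
  # cross-entropy on balanced one-hot targets starts close to ln(n_classes)
  set.seed(10)
  model <- net_init(32, 32, 4, seed = 3)
  X <- matrix(stats::runif(40 * 3072), 40)
  Y <- one_hot(rep(1:4, each = 10), 1:4)
  loss <- batch_loss(net_logits(model, X), Y)
  expect_lt(abs(loss - log(4)), 0.2)
})

test_that("the phase-II objective equals hand-computed CE plus weighted KD", {
  Z <- rbind(c(1.2, -0.3, 0.1), c(0.2, 0.4, -0.5))
  Y <- rbind(c(1, 0, 0), c(0.3, 0.5, 0.2))
  Tch <- rbind(c(0.8, 0.1, -0.2), c(0.1, 0.9, -0.3))
  kd <- distill_config(temperature = 0.5, weight = 0.7)
  # hand formula: mean soft-target CE + weight * sum(KD over flagged)/batch
  ce_hand <- mean(sapply(1:2, function(i) -sum(Y[i, ] * log(softened_distribution(Z[i, ], 1)))))
  kd_hand <- kd_loss(Tch[1, ], Z[1, ], 0.5)
  expect_equal(batch_loss(Z, Y, kd_mask = c(TRUE, FALSE),
                          teacher_logits = Tch, kd = kd),
               ce_hand + 0.7 * kd_hand / 2)
  # weight zero reduces to the plain cross-entropy
  kd0 <- distill_config(weight = 0)
  expect_equal(batch_loss(Z, Y, c(TRUE, FALSE), Tch, kd0), ce_hand)
  # t_squared rescales the KD term by T^2
  kdt <- distill_config(temperature = 0.5, weight = 0.7, t_squared = TRUE)
  expect_equal(batch_loss(Z, Y, c(TRUE, FALSE), Tch, kdt),
               ce_hand + 0.7 * 0.25 * kd_hand / 2)
})

test_that("the balanced plan reaches floor(m) effective samples for every class", {
  fx <- make_fixture(c(40, 20, 8, 4), test_per_class = 3, seed = 37)
  cfg <- train_config(epochs_phase1 = 3, epochs_phase2 = 2, seed = 7)
  p1 <- train_phase1(fx$manifest, fx$images, cfg)
  plan <- build_balanced_set(fx$manifest, p1$model, fx$images, cfg)
  expect_equal(plan$m_target, 18L)   # floor(72 / 4)
  expect_equal(plan$head, c(1L, 2L))  # counts 40 and 20 both exceed m
  expect_equal(plan$tail, c(3L, 4L))
  # head effective count: selected only, m_target per head class
  expect_equal(sum(plan$partition$status == "selected"), 36L)
  # tails: originals + recipes reach the target
  for (cid in plan$tail) {
    n_orig <- sum(fx$manifest$split == "train" & fx$manifest$class_id == cid)
    n_rec <- sum(sapply(plan$recipes, `[[`, "tail_class") == cid)
    expect_equal(n_orig + n_rec, 18L)
  }
  # the assembled phase-II epoch has one row per effective sample
  dat <- tailmix:::phase2_epoch_data(fx$manifest, fx$images, plan, p1$model,
                                     "selected-head-only", p1$model$class_ids,
                                     plan$recipes)
  expect_equal(nrow(dat$X), 4 * 18L)
  expect_equal(sum(dat$kd_mask), 36L)   # KD only on the selected head rows
  expect_true(all(abs(rowSums(dat$Y) - 1) < 1e-9))
  unlink(fx$root, recursive = TRUE)
})

test_that("an already-balanced manifest needs no undersampling or recipes", {
  fx <- make_fixture(c(10, 10, 10), test_per_class = 2, seed = 41)
  cfg <- train_config(epochs_phase1 = 2, epochs_phase2 = 2, seed = 3)
  p1 <- train_phase1(fx$manifest, fx$images, cfg)
  plan <- build_balanced_set(fx$manifest, p1$model, fx$images, cfg)
  expect_length(plan$head, 0)
  expect_equal(nrow(plan$partition), 0L)
  expect_length(plan$recipes, 0)
  unlink(fx$root, recursive = TRUE)
})

test_that("balanced plans round-trip through JSON", {
  fx <- make_fixture(c(30, 10, 4), test_per_class = 2, seed = 43)
  cfg <- train_config(epochs_phase1 = 2, epochs_phase2 = 2, seed = 9)
  p1 <- train_phase1(fx$manifest, fx$images, cfg)
  plan <- build_balanced_set(fx$manifest, p1$model, fx$images, cfg)
  f <- tempfile(fileext = ".json")
  save_plan(plan, f)
  back <- load_plan(f)
  expect_equal(back$m_target, plan$m_target)
  expect_equal(back$head, plan$head)
  expect_equal(back$tail, plan$tail)
  expect_equal(back$partition$sample_id, plan$partition$sample_id)
  expect_equal(back$partition$status, plan$partition$status)
  expect_equal(length(back$recipes), length(plan$recipes))
  expect_equal(sapply(back$recipes, `[[`, "tail_id"),
               sapply(plan$recipes, `[[`, "tail_id"))
  expect_equal(back$recipes[[1]]$s, plan$recipes[[1]]$s)
  # recipe log lines parse back to the same donors
  lg <- tempfile(fileext = ".jsonl")
  write_recipe_log(plan$recipes, lg)
  lines <- readLines(lg)
  expect_length(lines, length(plan$recipes))
  first <- jsonlite::fromJSON(lines[1])
  expect_equal(first$donor_ids, plan$recipes[[1]]$donor_ids)
  unlink(fx$root, recursive = TRUE)
})

test_that("identical seeds reproduce training exactly", {
  fx <- make_fixture(c(12, 6), test_per_class = 2, seed = 47)
  cfg <- train_config(epochs_phase1 = 3, epochs_phase2 = 2, batch_size = 16,
                      seed = 12)
  a <- train_phase1(fx$manifest, fx$images, cfg)
  b <- train_phase1(fx$manifest, fx$images, cfg)
  expect_identical(a$log$loss, b$log$loss)
  expect_identical(a$model$W2, b$model$W2)
  unlink(fx$root, recursive = TRUE)
})

test_that("the full two-phase pipeline runs end to end on a small fixture", {
  fx <- make_fixture(c(30, 24, 8, 4, 3, 2), test_per_class = 4, n_groups = 3,
                     seed = 53)
  cfg <- train_config(epochs_phase1 = 4, epochs_phase2 = 6, seed = 15)
  out <- two_phase_train(fx$manifest, fx$images, cfg)
  expect_s3_class(out$model, "tailmix_net")
  expect_equal(nrow(out$log_phase2), 6L)
  ht <- split_head_tail(dataset_stats(fx$manifest))
  rep <- evaluate_model(out$model, fx$manifest, fx$images, ht,
                        metadata = list(method = "ours"))
  expect_true(rep$overall >= 0 && rep$overall <= 100)
  expect_equal(rep$metadata$method, "ours")
  unlink(fx$root, recursive = TRUE)
})

test_that("baseline strategies run and degenerate cases reduce sensibly", {
  fx <- make_fixture(c(20, 8, 4), test_per_class = 3, seed = 59)
  cfg <- train_config(epochs_phase1 = 2, epochs_phase2 = 3, seed = 21)
  ht <- split_head_tail(dataset_stats(fx$manifest))
  p1 <- train_phase1(fx$manifest, fx$images, cfg)
  for (s in c("baseline-ce", "ros", "rus", "hus", "cutmix-random")) {
    b <- run_baseline(fx$manifest, fx$images, cfg, s, phase1 = p1)
    rep <- evaluate_model(b$model, fx$manifest, fx$images, ht)
    expect_true(is.finite(rep$overall))
  }
  expect_error(run_baseline(fx$manifest, fx$images, cfg, "focal"))
  unlink(fx$root, recursive = TRUE)
})

test_that("random oversampling on balanced data equals plain training", {
  fx <- make_fixture(c(8, 8, 8), test_per_class = 2, seed = 61)
  cfg <- train_config(epochs_phase1 = 2, epochs_phase2 = 2, batch_size = 8,
                      seed = 33)
  a <- run_baseline(fx$manifest, fx$images, cfg, "baseline-ce")
  b <- run_baseline(fx$manifest, fx$images, cfg, "ros")
  expect_identical(a$log$loss, b$log$loss)
  unlink(fx$root, recursive = TRUE)
})
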