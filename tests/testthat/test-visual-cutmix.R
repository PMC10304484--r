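test_that("sampled masks have the prescribed rectangle geometry", {
  set.seed(1)
  m <- sample_mask(32, 32, s_range = c(0.5, 0.5001))
  expect_equal(unname(m$rect[c("w", "h")]), c(16, 16))
  expect_equal(sum(m$grid), 256)
  for (i in 1:100) {
    mk <- sample_mask(17, 23)
    r <- mk$rect
    expect_equal(sum(mk$grid), r[["w"]] * r[["h"]])
    expect_gte(r[["w"]], 1); expect_gte(r[["h"]], 1)
    expect_lte(r[["x0"]] + r[["w"]] - 1, 17)
    expect_lte(r[["y0"]] + r[["h"]] - 1, 23)
    expect_true(mk$s >= 0 && mk$s <= 1)
  }
  expect_error(sample_mask(1, 10), "at least 2x2")
  expect_error(sample_mask(10, 10, s_range = c(0.5, 0.2)))
})

test_that("top-k donor retrieval ranks by cosine similarity with id tie-breaks", {
  # identical vector ranks first with similarity 1
  M <- rbind(c(1, 0), c(0.6, 0.8), c(0, 1))
  expect_equal(topk_similar_heads(c(1, 0), M, c(11L, 12L, 13L), 1), 11L)
  # all orthogonal: ties broken by ascending id
  M2 <- rbind(c(0, 1), c(0, 2), c(0, 5))
  expect_equal(topk_similar_heads(c(1, 0), M2, c(30L, 10L, 20L), 3),
               c(10L, 20L, 30L))
  expect_error(topk_similar_heads(c(0, 0), M, 1:3, 1), "zero")
  expect_error(topk_similar_heads(c(1, 0), M, 1:3, 4), "exceeds")
})

test_that("top-k retrieval matches a brute-force oracle on random instances", {
  for (seed in 1:100) {
    set.seed(seed)
    n <- sample(5:20, 1)
    d <- sample(2:8, 1)
    M <- matrix(stats::rnorm(n * d), n)
    v <- stats::rnorm(d)
    ids <- sample.int(1000, n)
    k <- sample(1:5, 1)
    expect_equal(topk_similar_heads(v, M, ids, k), oracle_topk_cosine(v, M, ids, k))
  }
})

test_that("composition limits reproduce the single-mask equation", {
  tail_img <- array(stats::runif(4 * 4 * 3), c(4, 4, 3))
  donor <- array(stats::runif(4 * 4 * 3), c(4, 4, 3))
  all_ones <- tailmix:::manual_mask(4, 4, 1, 1, 4, 4)
  out <- compose_cutmix(tail_img, list(donor), list(all_ones))
  expect_equal(out$image, tail_img)
  expect_true(all(out$owner == 0L))
  all_zero <- tailmix:::manual_mask(4, 4, 1, 1, 0, 0)
  out0 <- compose_cutmix(tail_img, list(donor), list(all_zero))
  expect_equal(out0$image, donor)
  expect_true(all(out0$owner == 1L))
})

test_that("a hand-built k=2 composite matches pixel-by-pixel", {
  # constant-color 4x4 images: tail = 0.1, donors = 0.5 and 0.9
  const_img <- function(v) array(v, c(4, 4, 3))
  tail_img <- const_img(0.1)
  d1 <- const_img(0.5)
  d2 <- const_img(0.9)
  # step 1 keeps rows 1:2 x cols 1:2 of the tail, rest becomes donor 1;
  # step 2 keeps rows 2:4 x cols 2:4 of that result, rest becomes donor 2
  m1 <- tailmix:::manual_mask(4, 4, 1, 1, 2, 2)
  m2 <- tailmix:::manual_mask(4, 4, 2, 2, 3, 3)
  out <- compose_cutmix(tail_img, list(d1, d2), list(m1, m2))
  expected <- matrix(0.9, 4, 4)
  expected[2:4, 2:4] <- 0.5   # donor 1 surviving inside rect 2
  expected[2, 2] <- 0.1       # tail surviving in rect1 intersect rect2
  expect_equal(out$image[, , 1], expected)
  expect_equal(out$image[, , 2], expected)
  exp_owner <- matrix(2L, 4, 4)
  exp_owner[2:4, 2:4] <- 1L
  exp_owner[2, 2] <- 0L
  expect_equal(out$owner, exp_owner)
  # labels from the same ownership map, by hand: 1/16 tail, 8/16 d1, 7/16 d2
  lab <- make_label(out$owner, tail_class = 7, donor_classes = c(3, 5),
                    class_ids = c(3, 5, 7))
  expect_equal(unname(lab), c(8, 7, 1) / 16)
  expect_error(compose_cutmix(tail_img, list(array(0, c(3, 3, 3))), list(m1)),
               "mismatch")
})

test_that("labels follow the area-mix and tail-only policies", {
  owner <- matrix(0L, 4, 4)
  lab <- make_label(owner, 2, integer(0), 1:3)
  expect_equal(unname(lab), c(0, 1, 0))
  expect_equal(unname(make_label(owner, 2, integer(0), 1:3, "tail-only")),
               c(0, 1, 0))
  owner[1, ] <- 1L   # 25% donor
  lab2 <- make_label(owner, 2, 1L, 1:3)
  expect_equal(unname(lab2), c(0.25, 0.75, 0))
  expect_equal(unname(make_label(owner, 2, 1L, 1:3, "tail-only")), c(0, 1, 0))
  # donors sharing a class pool their area
  owner2 <- matrix(0L, 4, 4); owner2[1, ] <- 1L; owner2[2, ] <- 2L
  lab3 <- make_label(owner2, 2, c(1L, 1L), 1:2)
  expect_equal(unname(lab3), c(0.5, 0.5))
})

test_that("tail oversampling generates the right number of seeded recipes", {
  fx <- make_fixture(c(12, 12, 5, 2), test_per_class = 2, seed = 21)
  st <- dataset_stats(fx$manifest)
  ht <- split_head_tail(st)   # m = 7.75: heads {1,2}, tails {3,4}
  model <- net_init(32, 32, 4, seed = 1)
  feats <- extract_features(model, fx$images)
  part <- undersample_heads(fx$manifest, feats, ht$head, 7)
  pool <- tailmix:::partition_ids(part, "removed")
  rec <- oversample_tail(fx$manifest, ht$tail, pool, feats, fx$images,
                         m_target = 7, seed = 42)
  # tails at (5, 2) need (2, 5) recipes
  expect_equal(sum(sapply(rec, `[[`, "tail_class") == 3), 2L)
  expect_equal(sum(sapply(rec, `[[`, "tail_class") == 4), 5L)
  for (r in rec) {
    expect_true(all(r$donor_ids %in% pool))
    expect_equal(sum(r$label), 1)
    expect_true(r$tail_fraction >= 0 && r$tail_fraction <= 1)
    expect_true(all(r$image >= 0 & r$image <= 1))
  }
  # a tail class already at target gets no recipes
  rec5 <- oversample_tail(fx$manifest, ht$tail, pool, feats, fx$images,
                          m_target = 5, seed = 42)
  expect_false(any(sapply(rec5, `[[`, "tail_class") == 3))
  # bit-identical under the same seed
  rec_b <- oversample_tail(fx$manifest, ht$tail, pool, feats, fx$images,
                           m_target = 7, seed = 42)
  expect_identical(lapply(rec, `[[`, "donor_ids"), lapply(rec_b, `[[`, "donor_ids"))
  expect_identical(lapply(rec, `[[`, "s"), lapply(rec_b, `[[`, "s"))
  expect_error(oversample_tail(fx$manifest, ht$tail, integer(0), feats,
                               fx$images, 7), "empty donor pool")
  unlink(fx$root, recursive = TRUE)
})

test_that("mixing direction controls which side the donor occupies", {
  fx <- make_fixture(c(10, 3), test_per_class = 2, seed = 31)
  model <- net_init(32, 32, 2, seed = 1)
  feats <- extract_features(model, fx$images)
  tr <- fx$manifest[fx$manifest$split == "train", ]
  pool <- tr$sample_id[tr$class_id == 1][1:5]
  rec_dp <- oversample_tail(fx$manifest, 2L, pool, feats, fx$images, 6,
                            direction = "donor-patch", seed = 9)
  rec_tp <- oversample_tail(fx$manifest, 2L, pool, feats, fx$images, 6,
                            direction = "tail-patch", seed = 9)
  # same seeds draw the same s, so the two directions complement:
  # donor-patch keeps 1 - floor(sW)floor(sH)/(WH), tail-patch keeps the rect
  for (i in seq_along(rec_dp)) {
    expect_equal(rec_dp[[i]]$s, rec_tp[[i]]$s)
    expect_equal(rec_dp[[i]]$tail_fraction + rec_tp[[i]]$tail_fraction, 1)
  }
  # donor-patch composites keep the tail image as the majority on average
  expect_gt(mean(sapply(rec_dp, `[[`, "tail_fraction")), 0.5)
  unlink(fx$root, recursive = TRUE)
})

test_that("visual selection retrieves donors aligned with the tail feature", {
  # synthetic features: donors 1-5 near the tail vector, 6-10 orthogonal
  set.seed(5)
  V <- rbind(matrix(rep(c(1, 0, 0, 0), 5), ncol = 4, byrow = TRUE) +
               matrix(stats::rnorm(20, 0, 0.05), 5),
             matrix(rep(c(0, 0, 1, 0), 5), ncol = 4, byrow = TRUE) +
               matrix(stats::rnorm(20, 0, 0.05), 5))
  ids <- 1:10
  got <- topk_similar_heads(c(1, 0, 0, 0), V, ids, 5)
  expect_setequal(got, 1:5)
})
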