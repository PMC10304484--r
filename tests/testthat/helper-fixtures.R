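# small seeded image fixtures generated on the fly; every helper returns
# manifest + loaded pixels so tests never touch the network or ship data

make_fixture <- function(sizes, test_per_class = 8, n_groups = 2,
                         seed = 7, jitter = list()) {
  n <- length(sizes)
  prof <- make_rank_profile(n, shape = "file", sizes = sort(sizes, decreasing = TRUE))
  spec <- synthetic_spec(n, prof, image_size = c(32, 32),
                         test_per_class = test_per_class,
                         n_groups = n_groups, jitter = jitter, seed = seed)
  root <- tempfile("fix")
  manifest <- generate_dataset(spec, root)
  list(spec = spec, root = root, manifest = manifest,
       images = load_images(manifest, root))
}

# an in-memory manifest with no image files (builder-level tests)
toy_manifest <- function(train_counts, test_per_class = 0) {
  rows <- do.call(rbind, lapply(seq_along(train_counts), function(cid) {
    n_tr <- train_counts[cid]
    data.frame(
      image_path = c(sprintf("c%d/tr%03d.png", cid, seq_len(n_tr)),
                     if (test_per_class > 0)
                       sprintf("c%d/te%03d.png", cid, seq_len(test_per_class))),
      class_id = cid,
      split = c(rep("train", n_tr), rep("test", test_per_class)))
  }))
  dataset_manifest(rows$image_path, rows$class_id, split = rows$split)
}

# brute-force oracles, kept independent of the package implementations
oracle_nearest_mean <- function(X, ids, n_select) {
  mu <- colMeans(X)
  d <- apply(X, 1, function(x) sqrt(sum((x - mu)^2)))
  ids[order(d, ids)][seq_len(n_select)]
}

oracle_greedy_herding <- function(X, ids, n_select) {
  mu <- colMeans(X)
  picked <- integer(0)
  left <- seq_len(nrow(X))
  S <- numeric(ncol(X))
  for (t in seq_len(n_select)) {
    d <- sapply(left, function(i) sqrt(sum((mu - (S + X[i, ]) / t)^2)))
    best <- left[order(d, ids[left])][1]
    picked <- c(picked, best)
    S <- S + X[best, ]
    left <- setdiff(left, best)
  }
  ids[picked]
}

oracle_topk_cosine <- function(v, M, ids, k) {
  cs <- apply(M, 1, function(r) sum(r * v) / sqrt(sum(r^2) * sum(v^2)))
  ids[order(-cs, ids)][seq_len(k)]
}
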