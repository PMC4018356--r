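# toy training set with a hand-computable feature table:
# prior 0.5 (4 inhibitors / 4 non), K = 2
toy_fsets <- list(
  fs_of("a1", c("F:good", "F:both")), fs_of("a2", c("F:good", "F:both")),
  fs_of("a3", c("F:good")),           fs_of("a4", c("F:both")),
  fs_of("n1", c("F:bad", "F:both")),  fs_of("n2", c("F:bad", "F:both")),
  fs_of("n3", c("F:both")),           fs_of("n4", c("F:good"))
)
toy_labels <- rep(c("inhibitor", "non_inhibitor"), each = 4)

test_that("Laplacian-corrected weights match direct arithmetic", {
  model <- nb_fit(toy_fsets, toy_labels)
  expect_equal(model$prior, 0.5)
  expect_equal(model$laplace_K, 2)
  # F:good: A=3, N=4 -> P_corr = (3+1)/(4+2) = 0.6667, w = ln(4/3)
  i <- match("F:good", model$keys)
  expect_equal(model$A_F[i], 3L); expect_equal(model$N_F[i], 4L)
  expect_equal(model$weights[i], log(4 / 3), tolerance = 1e-12)
  expect_equal(model$weights[i], 0.2877, tolerance = 1e-4)
  # F:both: A=3, N=6 -> (3+1)/(6+2) = 0.5 = prior, w = 0
  j <- match("F:both", model$keys)
  expect_equal(model$weights[j], 0, tolerance = 1e-12)

  # the high-count case: A=N=98 at prior 0.5 -> w = ln(1.98)
  big <- c(lapply(1:98, function(i) fs_of(paste0("x", i), "F:hit")),
           list(fs_of("y1", "F:miss"), fs_of("y2", "F:miss")))
  big_labels <- c(rep("inhibitor", 98), rep("non_inhibitor", 2))
  bm <- nb_fit(big, big_labels)
  k <- match("F:hit", bm$keys)
  pa <- 0.98
  expect_equal(bm$weights[k],
               log(((98 + 1) / (98 + 1 / pa)) / pa), tolerance = 1e-12)

  expect_error(nb_fit(toy_fsets[1:2], c("inhibitor", "inhibitor")),
               "both classes")
})

test_that("scoring is additive and unseen features are neutral", {
  model <- nb_fit(toy_fsets, toy_labels)
  expect_equal(nb_score(model, fs_of("z", character(0)))$score, 0)
  expect_equal(nb_score(model, fs_of("z", c("F:novel1", "F:novel2")))$score, 0)
  s1 <- nb_score(model, fs_of("z", "F:good"))$score
  expect_equal(s1, log(4 / 3), tolerance = 1e-12)
  s2 <- nb_score(model, fs_of("z", c("F:good", "F:bad")))$score
  i <- match("F:bad", model$keys)
  expect_equal(s2, s1 + model$weights[i], tolerance = 1e-12)
})

test_that("score zones follow the configured uncertain-zone bounds", {
  model <- nb_fit(toy_fsets, toy_labels)
  mk <- function(score) {
    m <- model; m$keys <- "F:z"; m$N_F <- 5L; m$A_F <- 3L; m$weights <- score
    nb_score(m, fs_of("z", "F:z"))$zone
  }
  expect_equal(mk(0.5), "reliable_inhibitor")
  expect_equal(mk(0), "reliable_inhibitor")
  expect_equal(mk(-5), "uncertain")
  expect_equal(mk(-20), "uncertain")
  expect_equal(mk(-25), "reliable_noninhibitor")
})

test_that("prediction uses a strict score threshold, monotone in threshold", {
  model <- nb_fit(toy_fsets, toy_labels)
  expect_equal(nb_predict(model, fs_of("z", "F:good")), "inhibitor")
  expect_equal(nb_predict(model, fs_of("z", character(0))), "non_inhibitor")
  # lowering the threshold never flips inhibitor -> non_inhibitor
  for (fs in toy_fsets) {
    p0 <- nb_predict(model, fs, threshold = 0)
    pm <- nb_predict(model, fs, threshold = -20)
    expect_false(p0 == "inhibitor" && pm == "non_inhibitor")
  }
})

test_that("rank_fragments orders by weight with counts reported", {
  model <- nb_fit(toy_fsets, toy_labels)
  rk <- rank_fragments(model, 2)
  expect_equal(nrow(rk$favorable), 2L)
  expect_equal(rk$favorable$key[1], "F:good")
  expect_equal(rk$unfavorable$key[1], "F:bad")
  expect_true(all(c("weight", "A_F", "N_F") %in% names(rk$favorable)))
  expect_warning(rk_all <- rank_fragments(model, 99), "exceeds")
  expect_equal(nrow(rk_all$favorable), length(model$keys))

  # a feature in 10/10 actives and no non-actives ranks first
  pure <- c(lapply(1:10, function(i) fs_of(paste0("p", i), c("F:star", "F:pad"))),
            lapply(1:10, function(i) fs_of(paste0("q", i), "F:pad")))
  pm <- nb_fit(pure, rep(c("inhibitor", "non_inhibitor"), each = 10))
  expect_equal(rank_fragments(pm, 1)$favorable$key, "F:star")
  expect_equal(fragment_rank(pm, "F:star"), 1L)
})

test_that("singleton pruning is available behind a flag", {
  fsets <- c(toy_fsets, list(fs_of("s", "F:once")))
  labels <- c(toy_labels, "inhibitor")
  m_all <- nb_fit(fsets, labels)
  m_pruned <- nb_fit(fsets, labels, prune_singletons = TRUE)
  expect_true("F:once" %in% m_all$keys)
  expect_false("F:once" %in% m_pruned$keys)
})

test_that("count tallies match a brute-force recount", {
  set.seed(21)
  pool <- sprintf("F:%02d", 1:15)
  fsets <- lapply(1:40, function(i)
    fs_of(paste0("c", i), sample(pool, sample(1:6, 1))))
  labels <- sample(c("inhibitor", "non_inhibitor"), 40, replace = TRUE,
                   prob = c(0.7, 0.3))
  if (length(unique(labels)) == 1L) labels[1] <- "non_inhibitor"
  model <- nb_fit(fsets, labels)
  for (k in model$keys) {
    has <- vapply(fsets, function(f) k %in% names(f), FALSE)
    expect_equal(model$N_F[match(k, model$keys)], sum(has))
    expect_equal(model$A_F[match(k, model$keys)],
                 sum(has & labels == "inhibitor"))
  }
})

test_that("LOO fast path equals explicit refits", {
  set.seed(22)
  pool <- sprintf("F:%02d", 1:12)
  fsets <- lapply(1:25, function(i)
    fs_of(paste0("c", i), sample(pool, sample(1:5, 1))))
  labels <- c(rep("inhibitor", 17), rep("non_inhibitor", 8))
  fast <- loo_bayes_scores(fsets, labels)
  for (i in seq_along(fsets)) {
    ref <- nb_fit(fsets[-i], labels[-i])
    expect_equal(fast[i], nb_score(ref, fsets[[i]])$score, tolerance = 1e-9)
  }
  # compound whose features are unique to it scores 0 under LOO
  fsets2 <- c(fsets, list(fs_of("u", c("F:unique1", "F:unique2"))))
  labels2 <- c(labels, "inhibitor")
  fast2 <- loo_bayes_scores(fsets2, labels2)
  expect_equal(fast2[26], 0)
})

test_that("model persistence is score-identical", {
  model <- nb_fit(toy_fsets, toy_labels)
  path <- withr::local_tempfile(fileext = ".json")
  nb_save(model, path, config = list(method = "acf", level = 3))
  back <- nb_load(path)
  expect_identical(back$keys, model$keys)
  for (fs in toy_fsets) {
    expect_identical(nb_score(back, fs)$score, nb_score(model, fs)$score)
  }
  expect_equal(attr(back, "config")$level, 3)
})

test_that("descriptor binning is equal-frequency, frozen and order-stable", {
  set.seed(23)
  x <- matrix(c(1:100, rnorm(100)), ncol = 2,
              dimnames = list(sprintf("c%03d", 1:100), c("A", "B")))
  bins <- bin_descriptors(x, 10)
  fs <- apply_bins(x, bins)
  binsA <- table(vapply(fs, function(f)
    grep("^BIN:A:", names(f), value = TRUE), ""))
  expect_true(all(binsA == 10))   # bins of size 10

  # shuffling training order leaves edges unchanged (sort-based oracle)
  xs <- x[sample(100), , drop = FALSE]
  expect_equal(bin_descriptors(xs, 10)$edges, bins$edges)

  # out-of-range values clamp to the boundary bins
  xt <- matrix(c(-50, 1e6, 0, 0), ncol = 2,
               dimnames = list(c("lo", "hi"), c("A", "B")))
  fst <- apply_bins(xt, bins)
  expect_true("BIN:A:1" %in% names(fst$lo))
  expect_true("BIN:A:10" %in% names(fst$hi))

  # constant column: single bin, weight 0 by construction
  xc <- matrix(rep(5, 20), ncol = 1, dimnames = list(NULL, "K"))
  bc <- bin_descriptors(xc, 10)
  expect_length(bc$edges$K, 0)
  fsc <- apply_bins(matrix(5, 1, 1, dimnames = list("z", "K")), bc)
  expect_equal(names(fsc$z), "BIN:K:1")
})
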