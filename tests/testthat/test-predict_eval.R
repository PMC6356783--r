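# Fixed 2-gene / 3-label evaluation fixture, hand-evaluated.
metrics_fixture <- function() {
  list(scores = rbind(c(0.6, 0.3, 0.1),
                      c(0.2, 0.5, 0.3)),
       truth = rbind(c(1L, 0L, 1L),
                     c(1L, 1L, 0L)))
}

test_that("prediction rows are normalized and uniform inputs give uniform scores", {
  # uniform theta and uniform alpha: complete symmetry across labels
  theta <- matrix(1 / 4, 3, 4)
  model <- structure(list(theta_hat = theta,
                          beta_hat = init_feature_weights(3, 0, alpha0 = 1),
                          lambda = rep(200 / 4, 4),
                          vocabulary = dmrllda:::new_vocabulary(
                            paste0("w", 1:4), integer(0)),
                          label_names = paste0("t", 1:3),
                          transform = NULL,
                          config = list(clip = 30), inference = "cvb0"),
                     class = "dmr_llda")
  corp <- make_corpus(list(c(1L, 2L, 3L), c(4L, 4L)), W = 4,
                      Lambda = rbind(c(1L, 1L, 1L), c(1L, 1L, 1L)))
  p <- predict(model, corp, method = "cvb0")
  expect_equal(rowSums(p$scores), c(g001 = 1, g002 = 1))
  expect_equal(unname(p$scores[1, ]), rep(1 / 3, 3), tolerance = 1e-9)

  # candidate mask restricts and renormalizes
  p2 <- predict(model, corp, method = "cvb0",
                candidate_mask = rbind(c(1L, 1L, 0L), c(0L, 1L, 1L)))
  expect_equal(unname(p2$scores[1, 3]), 0)
  expect_equal(rowSums(p2$scores), c(g001 = 1, g002 = 1))
})

test_that("documents from one well-separated topic are assigned to it", {
  set.seed(71)
  T_ <- 4; W <- 16
  theta <- matrix(0.01 / (W - 4), T_, W)
  for (t in 1:T_) theta[t, (t - 1) * 4 + 1:4] <- 0.99 / 4
  beta <- init_feature_weights(T_, 0, alpha0 = 1)
  hits <- 0
  n_rep <- 100
  for (r in 1:n_rep) {
    l <- sample.int(T_, 1)
    toks <- sample.int(W, 30, replace = TRUE, prob = theta[l, ])
    corp <- make_corpus(list(toks), W = W, Lambda = rbind(rep(1L, T_)))
    model <- structure(list(theta_hat = theta, beta_hat = beta,
                            lambda = rep(200 / W, W),
                            vocabulary = corp$vocabulary,
                            label_names = paste0("t", 1:T_),
                            transform = NULL, config = list(clip = 30),
                            inference = "cvb0"),
                       class = "dmr_llda")
    p <- predict(model, corp, method = "cvb0")
    if (which.max(p$scores[1, ]) == l) hits <- hits + 1
  }
  expect_gte(hits / n_rep, 0.95)
})

test_that("a feature with large positive weight raises its label's score", {
  T_ <- 3; W <- 6
  theta <- matrix(1 / W, T_, W)
  tr <- list(center = c(0), scale = c(1))
  bmat <- rbind(c(2, 0), c(0, 0), c(0, 0))   # feature 1 boosts label 1
  model <- structure(list(theta_hat = theta,
                          beta_hat = feature_weights(bmat),
                          lambda = rep(200 / W, W),
                          vocabulary = dmrllda:::new_vocabulary(
                            paste0("w", 1:W), integer(0)),
                          label_names = paste0("t", 1:T_),
                          transform = tr, config = list(clip = 30),
                          inference = "cvb0"),
                     class = "dmr_llda")
  toks <- list(c(1L, 2L, 3L))
  mk <- function(y) make_corpus(toks, W = W,
                                Lambda = rbind(rep(1L, T_)),
                                features = matrix(y, 1, 1))
  p_lo <- predict(model, mk(0.5), method = "cvb0")
  p_hi <- predict(model, mk(1.0), method = "cvb0")   # doubled feature
  expect_gt(p_hi$scores[1, 1], p_lo$scores[1, 1])
})

test_that("cgs and cvb0 fold-in agree on easy inputs", {
  set.seed(72)
  sim <- sim_scenario(seed = 73, n_docs = 30, doc_length = 60,
                      n_topics = 3, n_words = 12)
  m <- train_cgs(sim$corpus, cgs_config(iterations = 200, burn_in = 100,
                                        thin = 20, seed = 74))
  p_g <- predict(m, sim$corpus, method = "cgs", iterations = 600,
                 burn_in = 300, seed = 75)
  p_v <- predict(m, sim$corpus, method = "cvb0")
  # same ranking of the top label for most genes
  agree <- mean(apply(p_g$scores, 1, which.max) ==
                apply(p_v$scores, 1, which.max))
  expect_gte(agree, 0.8)
})

test_that("binarization policies behave at their boundaries", {
  # perfect one-hot scores -> exact one-label predictions
  s <- rbind(c(1, 0, 0), c(0, 0, 1))
  expect_equal(unname(binarize(s, "uniform")), rbind(c(1L, 0L, 0L),
                                                     c(0L, 0L, 1L)),
               ignore_attr = TRUE)
  # all-uniform scores: every label on (inclusive boundary)
  u <- matrix(1 / 3, 2, 3)
  expect_true(all(binarize(u, "uniform") == 1L))

  # tuned threshold equals the exhaustive-scan optimum on a worked example
  sc <- rbind(c(0.9, 0.4, 0.1, 0.05),
              c(0.8, 0.6, 0.3, 0.2),
              c(0.7, 0.2, 0.15, 0.1),
              c(0.5, 0.45, 0.35, 0.3))
  tr <- rbind(c(1L, 1L, 0L, 0L),
              c(1L, 0L, 0L, 0L),
              c(1L, 1L, 0L, 0L),
              c(1L, 0L, 1L, 0L))
  b <- binarize(sc, "tuned", truth = tr)
  cand <- sort(unique(as.vector(sc)))
  f1s <- vapply(cand, function(th)
    dmrllda:::micro_f1((sc >= th) * 1L, tr), numeric(1))
  expect_equal(dmrllda:::micro_f1(b, tr), max(f1s))
  expect_error(binarize(sc, "tuned"), "truth")
})

test_that("the hand-evaluated fixture reproduces all eight metrics exactly", {
  fx <- metrics_fixture()
  m <- compute_metrics(fx$scores, binarize(fx$scores, "uniform"), fx$truth)
  expect_equal(m$average_precision, 5 / 6)
  expect_equal(m$one_error, 0)
  expect_equal(m$hamming_loss, 1 / 3)
  expect_equal(m$micro_f1, 2 / 3)
  expect_equal(m$macro_f1, 5 / 9)
  expect_equal(m$aupr_macro, 5 / 6)
  expect_equal(m$aupr_weighted, 7 / 8)
  expect_equal(m$aupr_pooled, 49 / 60)
})

test_that("metric edge cases: perfection, equal curves, empty truths", {
  s <- rbind(c(0.8, 0.1, 0.1), c(0.1, 0.8, 0.1))
  tp <- rbind(c(1L, 0L, 0L), c(0L, 1L, 0L))
  m <- compute_metrics(s, binarize(s, "uniform"), tp)
  expect_equal(m$hamming_loss, 0)
  expect_equal(m$average_precision, 1)
  expect_equal(m$one_error, 0)
  expect_equal(m$micro_f1, 1)
  # label 3 has no positives: excluded from the macro areas
  expect_equal(m$aupr_macro, 1)
  expect_equal(m$aupr_pooled, 1)

  # identical per-label PR curves -> macro equals weighted
  s2 <- rbind(c(0.9, 0.9), c(0.2, 0.2), c(0.6, 0.6))
  t2 <- rbind(c(1L, 1L), c(0L, 0L), c(1L, 1L))
  m2 <- compute_metrics(s2, binarize(s2, "uniform"), t2)
  expect_equal(m2$aupr_macro, m2$aupr_weighted)

  # a gene with empty truth is excluded from ranking metrics, with count
  t3 <- rbind(c(1L, 0L), c(0L, 0L))
  m3 <- compute_metrics(s2[1:2, ], binarize(s2[1:2, ], "uniform"), t3)
  expect_identical(m3$n_excluded_genes, 1L)
  expect_equal(m3$average_precision, 1)

  # everything stays inside [0, 1]
  for (nm in c("hamming_loss", "average_precision", "one_error",
               "micro_f1", "macro_f1", "aupr_macro", "aupr_pooled",
               "aupr_weighted")) {
    expect_gte(m2[[nm]], 0); expect_lte(m2[[nm]], 1)
  }
})

test_that("pooled area is label-permutation invariant; macro survives monotone transforms", {
  set.seed(81)
  s <- matrix(runif(30), 10, 3)
  t_ <- matrix(rbinom(30, 1, 0.4), 10, 3)
  t_[rowSums(t_) == 0, 1] <- 1L
  m <- compute_metrics(s, binarize(s, "uniform"), t_)
  perm <- c(3, 1, 2)
  mp <- compute_metrics(s[, perm], binarize(s[, perm], "uniform"),
                        t_[, perm])
  expect_equal(m$aupr_pooled, mp$aupr_pooled)

  ms <- compute_metrics(s^3, binarize(s^3, "uniform"), t_)
  expect_equal(m$aupr_macro, ms$aupr_macro)
})

test_that("cross-validation partitions cleanly and reproduces with the seed", {
  sim <- sim_scenario(seed = 91, n_docs = 25, doc_length = 15)
  trainer <- function(cc) train_cgs(cc, cgs_config(iterations = 40,
                                                   burn_in = 20, thin = 10,
                                                   beta_start = 10,
                                                   beta_interval = 10,
                                                   seed = 92))
  cv1 <- cross_validate(sim$corpus, trainer, folds = 5, rounds = 2,
                        seed = 93, predict_args = list(iterations = 60,
                                                       burn_in = 30,
                                                       thin = 10))
  # per round, the test folds partition the gene set
  for (r in 1:2) {
    expect_setequal(unique(cv1$fold_assignments[[r]]), 1:5)
    expect_length(cv1$fold_assignments[[r]], 25)
  }
  expect_length(cv1$per_fold, 10)

  cv2 <- cross_validate(sim$corpus, trainer, folds = 5, rounds = 2,
                        seed = 93, predict_args = list(iterations = 60,
                                                       burn_in = 30,
                                                       thin = 10))
  expect_identical(cv1$fold_assignments, cv2$fold_assignments)
  expect_equal(cv1$mean, cv2$mean)

  expect_error(cross_validate(subset_corpus(sim$corpus, 1:3), trainer,
                              folds = 5), "fewer genes")
})

test_that("cross-validation supports the compress-train-recover label path", {
  sim <- sim_scenario(seed = 95, n_docs = 30, doc_length = 15)
  trainer <- function(cc) train_cgs(cc, cgs_config(iterations = 40,
                                                   burn_in = 20, thin = 10,
                                                   seed = 96))
  cv <- cross_validate(sim$corpus, trainer, folds = 3, rounds = 1,
                       seed = 97, bmd_max_rank = 5,
                       predict_args = list(iterations = 40, burn_in = 20,
                                           thin = 10))
  expect_length(cv$per_fold, 3)
  expect_true(all(vapply(cv$per_fold, function(m)
    m$average_precision >= 0 && m$average_precision <= 1, logical(1))))
})
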