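lambda_of <- function(corpus) 200 / length(corpus$vocabulary$words)

tiny_instance <- function(seed = 21) {
  # D = 2, T = 3, W = 4, Nd <= 3 (the oracle-enumeration scale)
  Lambda <- rbind(c(1L, 1L, 0L), c(0L, 1L, 1L))
  feats <- matrix(c(0.5, -0.8), 2, 1)
  corp <- make_corpus(list(c(1L, 3L, 2L), c(4L, 1L)), W = 4,
                      Lambda = Lambda, features = feats)
  beta <- feature_weights(rbind(c(0.4, -0.2), c(0.0, 0.3), c(-0.5, 0.1)))
  yh <- augment_features(feats)
  alpha <- compute_alpha(yh, beta)
  set.seed(seed)
  state <- init_state(corp, alpha)
  list(corpus = corp, state = state, alpha = alpha)
}

test_that("initialization draws from the label support and builds consistent counts", {
  ti <- tiny_instance()
  expect_true(dmrllda:::audit_state(ti$state))

  # single-label gene: all tokens forced onto that label
  corp1 <- make_corpus(list(c(1L, 2L, 2L)), W = 3,
                       Lambda = rbind(c(0L, 1L)))
  set.seed(1)
  st1 <- init_state(corp1, matrix(1, 1, 2))
  expect_true(all(st1$assignments[[1]] == 2L))

  # determinism under a fixed seed
  set.seed(33); a <- init_state(ti$corpus, ti$alpha)
  set.seed(33); b <- init_state(ti$corpus, ti$alpha)
  expect_identical(a$assignments, b$assignments)

  # no active labels is an error
  corp0 <- make_corpus(list(1L), W = 2, Lambda = rbind(c(0L, 0L)))
  expect_error(init_state(corp0, matrix(1, 1, 2)), "active label")
})

test_that("the full conditional equals the brute-force ratio of collapsed joints", {
  ti <- tiny_instance()
  lam <- lambda_of(ti$corpus)
  for (d in 1:2) {
    for (n in seq_along(ti$corpus$documents[[d]]$tokens)) {
      p_impl <- topic_conditional(ti$state, d, n, lam)
      p_oracle <- oracle_conditional(ti$state, ti$corpus, d, n, lam)
      expect_equal(p_impl, p_oracle, tolerance = 1e-10)
    }
  }

  # symmetry: two active topics with identical residual counts and equal
  # alpha (single token, so removal leaves empty tables)
  st <- list(assignments = list(1L), Ndt = rbind(c(1L, 0L)),
             Ntw = rbind(c(1L, 0L), c(0L, 0L)), Nt = c(1L, 0L),
             alpha = rbind(c(2, 2)), Lambda = rbind(c(1L, 1L)),
             aL = rbind(c(2, 2)), tokens = list(1L))
  expect_equal(topic_conditional(st, 1, 1, 1), c(0.5, 0.5))

  # single active label: degenerate one-hot conditional
  corp1 <- make_corpus(list(c(1L, 2L)), W = 2, Lambda = rbind(c(0L, 1L)))
  set.seed(2)
  st1 <- init_state(corp1, matrix(1, 1, 2))
  expect_equal(topic_conditional(st1, 1, 1, 1), c(0, 1))
})

test_that("sweeps preserve invariants and fix single-label corpora", {
  ti <- tiny_instance()
  lam <- lambda_of(ti$corpus)
  st <- gibbs_sweep(ti$state, lam, 25)
  expect_true(dmrllda:::audit_state(st))

  # all-single-label corpus: assignments can never move
  corp <- make_corpus(list(c(1L, 2L), c(2L, 3L)), W = 3,
                      Lambda = rbind(c(1L, 0L), c(0L, 1L)))
  set.seed(3)
  st2 <- init_state(corp, matrix(0.5, 2, 2))
  before <- lapply(st2$assignments, identity)
  st2 <- gibbs_sweep(st2, 1, 10)
  expect_identical(st2$assignments, before)
})

test_that("long-run sweep frequencies match the enumerated collapsed posterior", {
  # 2-token chain: exact posterior by enumerating all topic configurations
  Lambda <- rbind(c(1L, 1L))
  corp <- make_corpus(list(c(1L, 2L)), W = 3, Lambda = Lambda)
  alpha <- rbind(c(0.8, 1.6))
  lam <- 0.7
  tokens <- list(c(1L, 2L))

  configs <- expand.grid(t1 = 1:2, t2 = 1:2)
  logp <- apply(configs, 1, function(cf)
    collapsed_log_joint(list(as.integer(cf)), tokens, alpha, Lambda,
                        lam, 3))
  post <- exp(logp - max(logp)); post <- post / sum(post)
  marg1 <- c(sum(post[configs$t1 == 1]), sum(post[configs$t1 == 2]))

  set.seed(17)
  st <- init_state(corp, alpha)
  nsweep <- 20000
  tally <- c(0, 0)
  for (s in seq_len(nsweep)) {
    st <- gibbs_sweep(st, lam, 1)
    tally[st$assignments[[1]][1]] <- tally[st$assignments[[1]][1]] + 1
  }
  freq <- tally / nsweep
  se <- sqrt(marg1[1] * (1 - marg1[1]) / nsweep)
  expect_lt(abs(freq[1] - marg1[1]), 3 * se * 3)  # allow chain autocorrelation
})

test_that("point estimates follow the smoothed expected counts", {
  # prior-only: theta is lambda-proportional (uniform for symmetric lambda)
  st <- list(aL = rbind(c(1, 1)), Lambda = rbind(c(1L, 1L)),
             Ntw = matrix(0L, 2, 2), Nt = c(0L, 0L))
  rec <- list(list(Ndt = rbind(c(0, 0)), Ntw = matrix(0, 2, 2)))
  est <- estimate_parameters(st, rec, lambda = 1)
  expect_equal(est$theta_hat, matrix(0.5, 2, 2), ignore_attr = TRUE)

  # W = 2, lambda = 1, E[Ntw] = (3, 1) -> theta = (4/6, 2/6)
  rec2 <- list(list(Ndt = rbind(c(2, 2)), Ntw = rbind(c(3, 1), c(0, 0))))
  est2 <- estimate_parameters(st, rec2, lambda = 1)
  expect_equal(est2$theta_hat[1, ], c(4 / 6, 2 / 6))

  # pi rows normalize over the active labels
  stm <- list(aL = rbind(c(0.5, 0, 1)), Lambda = rbind(c(1L, 0L, 1L)),
              Ntw = matrix(0L, 3, 2), Nt = integer(3))
  rec3 <- list(list(Ndt = rbind(c(4, 0, 2)), Ntw = matrix(0, 3, 2)))
  est3 <- estimate_parameters(stm, rec3, lambda = 1)
  expect_equal(sum(est3$pi_hat[1, ]), 1)
  expect_equal(est3$pi_hat[1, 2], 0)

  expect_error(estimate_parameters(st, list(), 1), "record")
})

test_that("training records the scheduled number of states and recovers structure", {
  sim <- sim_scenario(seed = 31, n_docs = 60, doc_length = 40,
                      n_topics = 4, n_words = 20)
  cfg <- cgs_config(iterations = 300, burn_in = 150, thin = 25,
                    beta_start = 50, beta_interval = 25, seed = 32)
  m <- train_cgs(sim$corpus, cfg)
  expect_identical(m$n_records, as.integer((300 - 150) / 25))
  expect_equal(rowSums(m$theta_hat), rep(1, 4), tolerance = 1e-12)
  expect_equal(unname(rowSums(m$pi_train)), rep(1, 60), tolerance = 1e-12)

  # label-anchored recovery beats a uniform baseline by a wide margin
  l1 <- mean(rowSums(abs(m$theta_hat - sim$truth$theta_true)))
  perm <- sim$truth$theta_true[c(2, 3, 4, 1), ]
  l1_perm <- mean(rowSums(abs(m$theta_hat - perm)))
  expect_lt(l1, l1_perm)   # topics align with labels, not arbitrarily

  # feature-frozen run reduces to label-masked LLDA: flat alpha throughout
  cfg0 <- cgs_config(iterations = 60, burn_in = 30, thin = 10,
                     update_features = FALSE, seed = 32)
  m0 <- train_cgs(sim$corpus, cfg0)
  expect_equal(unique(as.vector(m0$beta_hat$matrix[, 1:2])), 0)
  expect_equal(unique(as.vector(m0$beta_hat$matrix[, 3])), log(50 / 4))
})

test_that("training is deterministic under a fixed seed", {
  sim <- sim_scenario(seed = 41, n_docs = 20, doc_length = 15)
  cfg <- cgs_config(iterations = 60, burn_in = 30, thin = 10, seed = 5)
  m1 <- train_cgs(sim$corpus, cfg)
  m2 <- train_cgs(sim$corpus, cfg)
  expect_identical(m1$theta_hat, m2$theta_hat)
  expect_identical(m1$beta_hat$matrix, m2$beta_hat$matrix)
})
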