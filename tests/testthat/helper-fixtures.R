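# Shared fixtures and independent oracles.  Oracles are deliberately
# written as direct transcriptions of the collapsed joint probability /
# brute-force enumerations, independent of the package's incremental
# implementations.

# Hand-assembled corpus from explicit token id lists.
make_corpus <- function(token_ids, W, Lambda, features = NULL) {
  D <- length(token_ids)
  gene_ids <- sprintf("g%03d", seq_len(D))
  documents <- lapply(seq_len(D), function(d) {
    w <- as.integer(token_ids[[d]])
    cnt <- table(w)
    list(gene_id = gene_ids[d], tokens = w,
         counts = setNames(as.integer(cnt), names(cnt)))
  })
  vocab <- dmrllda:::new_vocabulary(sprintf("w%03d", seq_len(W)), integer(0))
  rownames(Lambda) <- gene_ids
  feats <- NULL
  if (!is.null(features)) feats <- feature_table(features, gene_ids)
  structure(list(documents = documents, vocabulary = vocab,
                 labels = label_matrix(Lambda),
                 features = feats,
                 report = list(dropped_genes = character(0), oov_tokens = 0L)),
            class = "dmr_corpus")
}

# Log of the collapsed joint p(T, W | ...) up to a constant, computed from
# a full assignment configuration by summing the Dirichlet-multinomial
# evidence terms directly (the beta prior term is constant in the topic
# assignments and omitted).
collapsed_log_joint <- function(assignments, tokens, aL, Lambda, lambda, W) {
  D <- nrow(aL); T_ <- ncol(aL)
  lambda <- rep_len(lambda, W)
  Ndt <- matrix(0, D, T_)
  Ntw <- matrix(0, T_, W)
  for (d in seq_len(D)) {
    for (n in seq_along(tokens[[d]])) {
      t <- assignments[[d]][n]; w <- tokens[[d]][n]
      Ndt[d, t] <- Ndt[d, t] + 1
      Ntw[t, w] <- Ntw[t, w] + 1
    }
  }
  Nt <- rowSums(Ntw)
  ll <- 0
  for (d in seq_len(D)) {
    A <- sum(aL[d, ])
    Nd <- length(tokens[[d]])
    ll <- ll + lgamma(A) - lgamma(A + Nd)
    for (t in seq_len(T_)) {
      if (Lambda[d, t] == 1) {
        ll <- ll + lgamma(aL[d, t] + Ndt[d, t]) - lgamma(aL[d, t])
      } else if (Ndt[d, t] > 0) {
        return(-Inf)   # assignment outside the label support
      }
    }
  }
  for (t in seq_len(T_)) {
    ll <- ll + lgamma(sum(lambda)) - lgamma(sum(lambda) + Nt[t])
    for (w in seq_len(W)) {
      ll <- ll + lgamma(lambda[w] + Ntw[t, w]) - lgamma(lambda[w])
    }
  }
  ll
}

# Brute-force conditional for token (d, n): ratio of collapsed joints over
# the removed token's topic with everything else held fixed.
oracle_conditional <- function(state, corpus, d, n, lambda) {
  T_ <- ncol(state$Lambda)
  W <- length(corpus$vocabulary$words)
  tokens <- lapply(corpus$documents, `[[`, "tokens")
  logp <- rep(-Inf, T_)
  for (t in seq_len(T_)) {
    z <- lapply(state$assignments, identity)
    z[[d]][n] <- t
    logp[t] <- collapsed_log_joint(z, tokens, state$aL, state$Lambda,
                                   lambda, W)
  }
  p <- exp(logp - max(logp))
  p / sum(p)
}

# Exhaustive minimum Boolean rank of a small binary matrix: search all
# basis subsets drawn from the distinct nonzero rows' closure under the
# candidate space of all binary vectors contained in some row.
exhaustive_bmd_rank <- function(Y) {
  D <- nrow(Y); L <- ncol(Y)
  stopifnot(L <= 6, D <= 8)
  # candidate basis rows: any nonzero binary vector contained in >= 1 row
  cand <- list()
  for (bits in 1:(2^L - 1)) {
    v <- as.integer(intToBits(bits)[1:L])
    if (any(apply(Y, 1, function(r) all(v <= r)))) cand[[length(cand) + 1]] <- v
  }
  covers <- function(basis) {
    for (d in seq_len(D)) {
      usable <- Filter(function(v) all(v <= Y[d, ]), basis)
      u <- if (length(usable)) as.integer(Reduce(`|`, usable)) else rep(0L, L)
      if (!all(u == Y[d, ])) return(FALSE)
    }
    TRUE
  }
  for (r in 0:length(cand)) {
    if (r == 0) {
      if (all(Y == 0)) return(0L)
      next
    }
    idx <- utils::combn(length(cand), r)
    for (j in seq_len(ncol(idx))) {
      if (covers(cand[idx[, j]])) return(r)
    }
  }
  stop("no factorization found")
}
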