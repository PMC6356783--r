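#' Collapsed variational Bayes configuration
#'
#' Defaults follow the standard schedule: up to 1000 global passes; each
#' gene's local loop runs until the mean absolute change in its expected
#' topic counts per token falls below `1e-5` or 100 local iterations.  The
#' global loop additionally stops early once the same change measure,
#' averaged over genes, falls below `global_tol`.
#'
#' @param global_iters Maximum global passes (default 1000).
#' @param local_iters Maximum local iterations per gene (default 100).
#' @param local_tol Local convergence threshold on `(1/Nd) sum_t
#'   |delta gamma_dt|` (default 1e-5).
#' @param global_tol Global early-stopping threshold on the gene-averaged
#'   local change (default 1e-4).
#' @param beta_interval Global passes between feature-weight updates
#'   (default 1: every pass).
#' @inheritParams cgs_config
#' @return A config list of class `cvb_config`.
#' @export
cvb_config <- function(global_iters = 1000L, local_iters = 100L,
                       local_tol = 1e-5, global_tol = 1e-4,
                       beta_interval = 1L, update_features = TRUE,
                       alpha0 = NULL, lambda = NULL, mu = 0, sigma2 = 1,
                       clip = 30, seed = 1L) {
  stopifnot(global_iters >= 1, local_iters >= 1, local_tol > 0)
  structure(list(global_iters = as.integer(global_iters),
                 local_iters = as.integer(local_iters),
                 local_tol = local_tol, global_tol = global_tol,
                 beta_interval = as.integer(beta_interval),
                 update_features = isTRUE(update_features),
                 alpha0 = alpha0, lambda = lambda, mu = mu, sigma2 = sigma2,
                 clip = clip, seed = as.integer(seed)),
            class = "cvb_config")
}

## Word-type view of a corpus (internal): per doc the distinct word ids and
## their multiplicities Ndw.
doc_word_types <- function(corpus) {
  lapply(corpus$documents, function(doc) {
    wid <- as.integer(names(doc$counts))
    list(wids = wid, ndw = as.numeric(doc$counts))
  })
}

#' One zero-order local update for a gene
#'
#' A single pass of the CVB0 responsibility update for one gene:
#' `eta[w, t] ~ (adt + gamma_t) * word_factor[w, t]` normalized over the
#' active labels, where `gamma_t = sum_w (Ndw - 1) eta[w, t]` is computed
#' from the incoming responsibilities (the `(Ndw - 1)` weight is the
#' word-type self-exclusion) and `word_factor[w, t] = (lambda_w + mu_tw) /
#' (sum_w lambda_w + mu_t)` carries the global expected-count statistics.
#'
#' @param eta Wd x T responsibility matrix for the gene's word types.
#' @param ndw Word-type multiplicities (length Wd).
#' @param adt Label-masked prior row `alpha_dt * Lambda_dt` (length T).
#' @param word_factor Wd x T matrix of global word factors.
#' @return List with updated `eta` and the new `gamma`.
#' @export
cvb0_local_update <- function(eta, ndw, adt, word_factor) {
  gamma <- colSums((ndw - 1) * eta)
  raw <- sweep(word_factor, 2, (adt + gamma) * (adt > 0), "*")
  tot <- rowSums(raw)
  if (any(tot <= 0)) stop("zero normalization mass in CVB0 update")
  eta_new <- raw / tot
  list(eta = eta_new, gamma = colSums((ndw - 1) * eta_new))
}

#' One variance-corrected local update for a gene
#'
#' The CVB counterpart of [cvb0_local_update()]: each expected log count is
#' evaluated by the second-order expansion `log(a + m) - v / (2 (a + m)^2)`
#' with mean `m` and variance `v` of the excluded count, so the update
#' multiplies the zero-order factors by `exp` correction terms.  The
#' per-gene mean/variance (`gamma`, `s2`) are recomputed from the incoming
#' responsibilities; the topic-word corrections enter through
#' `word_factor`, which the caller builds with its own variance terms.
#'
#' @inheritParams cvb0_local_update
#' @param word_factor Wd x T matrix of corrected global word factors.
#' @return List with updated `eta`, `gamma` and the variance accumulator
#'   `s2` (per topic).
#' @export
cvb_local_update <- function(eta, ndw, adt, word_factor) {
  w1 <- ndw - 1
  gamma <- colSums(w1 * eta)
  s2 <- colSums(w1 * eta * (1 - eta))
  active <- adt > 0
  doc_fac <- numeric(length(adt))
  m <- adt[active] + gamma[active]
  doc_fac[active] <- exp(log(m) - s2[active] / (2 * m^2))
  raw <- sweep(word_factor, 2, doc_fac, "*")
  tot <- rowSums(raw)
  if (any(tot <= 0)) stop("zero normalization mass in CVB update")
  eta_new <- raw / tot
  list(eta = eta_new, gamma = colSums(w1 * eta_new),
       s2 = colSums(w1 * eta_new * (1 - eta_new)))
}

## Corrected global word factor matrix (T x W) for CVB (internal):
## exp(E[log(lambda_w + Ntw)]) / exp(E[log(sum lambda + Nt)]).
cvb_word_factor <- function(mu_tw, var_tw, mu_t, var_t, lambda) {
  lam_sum <- sum(lambda)
  num <- sweep(mu_tw, 2, lambda, "+")
  log_num <- log(num) - var_tw / (2 * num^2)
  den <- lam_sum + mu_t
  log_den <- log(den) - var_t / (2 * den^2)
  exp(log_num - log_den)
}

#' Train DMR-LLDA by collapsed variational Bayes
#'
#' Implements the global/local variational loops for the word-type
#' collapsed parameterization.  Each global pass refreshes the
#' feature-conditioned prior, runs every gene's local fixed-point loop to
#' its stopping rule, recomputes the global expected-count statistics
#' (`mu_tw`, `mu_t`, plus variance accumulators for the `cvb` variant) and
#' optimizes the feature weights.  `variant = "cvb0"` uses only expected
#' counts (zero-order); `variant = "cvb"` adds the second-order variance
#' corrections to every expected log count.
#'
#' @param corpus A `dmr_corpus`.
#' @param config A [cvb_config()].
#' @param variant `"cvb0"` (default) or `"cvb"`.
#' @return A fitted `dmr_llda` (fields as in [train_cgs()], plus
#'   `converged` and `global_iterations` metadata; `inference` records the
#'   variant).
#' @export
train_variational <- function(corpus, config = cvb_config(),
                              variant = c("cvb0", "cvb")) {
  stopifnot(inherits(corpus, "dmr_corpus"))
  variant <- match.arg(variant)
  set.seed(config$seed)
  Lambda <- corpus$labels$matrix
  if (any(rowSums(Lambda) == 0)) stop("every training gene needs at least one active label")
  D <- nrow(Lambda); T_ <- ncol(Lambda)
  W <- length(corpus$vocabulary$words)
  lambda <- rep_len(if (is.null(config$lambda)) 200 / W else config$lambda, W)
  lam_sum <- sum(lambda)
  alpha0 <- if (is.null(config$alpha0)) 50 / T_ else config$alpha0

  yh <- corpus_y_hat(corpus)
  beta <- init_feature_weights(T_, ncol(yh$y_hat) - 1L, alpha0 = alpha0,
                               mu = config$mu, sigma2 = config$sigma2)
  wt <- doc_word_types(corpus)
  Nd <- doc_lengths(corpus)

  # global init: mu_tw = lambda_w + s * lambda_w / 10, s random in (0, 1)
  s <- matrix(runif(T_ * W), T_, W)
  mu_tw <- sweep(1 + s / 10, 2, lambda, "*")
  mu_t <- rowSums(mu_tw)
  var_tw <- matrix(0, T_, W)
  var_t <- numeric(T_)

  eta <- lapply(wt, function(x)
    matrix(0, length(x$wids), T_))
  gamma <- matrix(0, D, T_)
  converged <- FALSE
  iter_done <- 0L

  for (r in seq_len(config$global_iters)) {
    alpha <- compute_alpha(yh$y_hat, beta, clip = config$clip)
    aL <- alpha * Lambda
    wf_global <- if (variant == "cvb0") {
      sweep(mu_tw, 2, lambda, "+") / (lam_sum + mu_t)
    } else {
      cvb_word_factor(mu_tw, var_tw, mu_t, var_t, lambda)
    }
    gamma_old <- gamma
    for (d in seq_len(D)) {
      wids <- wt[[d]]$wids; ndw <- wt[[d]]$ndw
      Bd <- t(wf_global[, wids, drop = FALSE])
      if (variant == "cvb0") {
        loc <- cvb0_local_cpp(ndw, Bd, aL[d, ], config$local_tol,
                              config$local_iters, Nd[d])
        eta[[d]] <- loc$eta
        gamma[d, ] <- loc$gamma
      } else {
        n_active <- sum(aL[d, ] > 0)
        e <- matrix(rep((aL[d, ] > 0) / n_active, each = length(wids)),
                    length(wids), T_)
        g_prev <- colSums((ndw - 1) * e)
        for (li in seq_len(config$local_iters)) {
          upd <- cvb_local_update(e, ndw, aL[d, ], Bd)
          e <- upd$eta
          if (sum(abs(upd$gamma - g_prev)) / Nd[d] < config$local_tol) {
            g_prev <- upd$gamma
            break
          }
          g_prev <- upd$gamma
        }
        eta[[d]] <- e
        gamma[d, ] <- g_prev
      }
    }

    # global refresh of expected-count statistics (word-type exclusion
    # weights (Ndw - 1); variances only for the cvb variant)
    mu_tw[] <- 0; var_tw[] <- 0
    for (d in seq_len(D)) {
      wids <- wt[[d]]$wids; w1 <- wt[[d]]$ndw - 1
      mu_tw[, wids] <- mu_tw[, wids] + t(w1 * eta[[d]])
      if (variant == "cvb") {
        var_tw[, wids] <- var_tw[, wids] + t(w1 * eta[[d]] * (1 - eta[[d]]))
      }
    }
    mu_t <- rowSums(mu_tw)
    var_t <- rowSums(var_tw)

    if (config$update_features && r %% config$beta_interval == 0L) {
      Ndt_full <- expected_doc_counts(eta, wt, D, T_)
      beta <- update_beta(beta, Ndt_full, Lambda, yh$y_hat, Nd = Nd,
                          max_iter = 25L, clip = config$clip)
    }

    change <- mean(rowSums(abs(gamma - gamma_old)) / Nd)
    iter_done <- r
    if (r > 1L && change < config$global_tol) { converged <- TRUE; break }
  }
  if (!converged) {
    warning("variational inference hit global_iters without meeting global_tol")
  }

  alpha <- compute_alpha(yh$y_hat, beta, clip = config$clip)
  aL <- alpha * Lambda
  Ndt_full <- expected_doc_counts(eta, wt, D, T_)
  Ntw_full <- matrix(0, T_, W)
  for (d in seq_len(D)) {
    Ntw_full[, wt[[d]]$wids] <- Ntw_full[, wt[[d]]$wids] +
      t(wt[[d]]$ndw * eta[[d]])
  }
  num_pi <- aL + Ndt_full * Lambda
  pi_hat <- num_pi / rowSums(num_pi)
  num_th <- sweep(Ntw_full, 2, lambda, "+")
  theta_hat <- num_th / rowSums(num_th)

  structure(list(theta_hat = theta_hat, pi_train = pi_hat,
                 beta_hat = beta, lambda = lambda,
                 vocabulary = corpus$vocabulary,
                 label_names = corpus$labels$label_names,
                 transform = yh$transform, config = config,
                 inference = variant, converged = converged,
                 global_iterations = iter_done,
                 state = list(mu_tw = mu_tw, mu_t = mu_t,
                              var_tw = var_tw, var_t = var_t)),
            class = "dmr_llda")
}

## Full expected doc-topic counts sum_w Ndw * eta (internal).
expected_doc_counts <- function(eta, wt, D, T_) {
  out <- matrix(0, D, T_)
  for (d in seq_len(D)) out[d, ] <- colSums(wt[[d]]$ndw * eta[[d]])
  out
}
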