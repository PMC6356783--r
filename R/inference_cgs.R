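#' Collapsed Gibbs sampling configuration
#'
#' Defaults follow the model's standard training schedule: a single Markov
#' chain of at most 2000 sweeps, 1000 of them burn-in, recording the state
#' every 50 sweeps thereafter (20 records).  Feature-weight optimization is
#' interleaved every `beta_interval` sweeps once `beta_start` sweeps have
#' passed.
#'
#' @param iterations Total Gibbs sweeps (default 2000).
#' @param burn_in Burn-in sweeps (default 1000).
#' @param thin Record interval after burn-in (default 50).
#' @param beta_interval Sweeps between feature-weight updates (default 20).
#' @param beta_start First sweep at which the weights may be updated
#'   (default 100).
#' @param update_features Optimize the feature weights during training;
#'   `FALSE` freezes the prior at its flat initial value, which reduces the
#'   model to plain label-masked LLDA (default `TRUE`).
#' @param alpha0 Initial flat concentration (default `50 / T`, resolved at
#'   fit time).
#' @param lambda Topic-word Dirichlet parameter (default `200 / W`,
#'   resolved at fit time).
#' @param mu,sigma2 Gaussian prior on the feature weights.
#' @param clip Log-scale clip bound for the prior (see [compute_alpha()]).
#' @param seed Integer seed for the chain.
#' @return A config list of class `cgs_config`.
#' @export
cgs_config <- function(iterations = 2000L, burn_in = 1000L, thin = 50L,
                       beta_interval = 20L, beta_start = 100L,
                       update_features = TRUE, alpha0 = NULL, lambda = NULL,
                       mu = 0, sigma2 = 1, clip = 30, seed = 1L) {
  stopifnot(iterations >= 1, burn_in >= 0, burn_in < iterations, thin >= 1)
  structure(list(iterations = as.integer(iterations),
                 burn_in = as.integer(burn_in), thin = as.integer(thin),
                 beta_interval = as.integer(beta_interval),
                 beta_start = as.integer(beta_start),
                 update_features = isTRUE(update_features),
                 alpha0 = alpha0, lambda = lambda, mu = mu, sigma2 = sigma2,
                 clip = clip, seed = as.integer(seed)),
            class = "cgs_config")
}

## Augmented feature matrix for a corpus (internal). Feature-free corpora
## get just the default column of ones.
corpus_y_hat <- function(corpus, transform = NULL, fit = is.null(transform)) {
  D <- length(corpus$documents)
  if (is.null(corpus$features) || ncol(corpus$features$values) == 0L) {
    return(list(y_hat = matrix(1, D, 1L), transform = NULL))
  }
  std <- standardize_features(corpus$features, fit = fit, transform = transform)
  list(y_hat = augment_features(std$values), transform = std$transform)
}

#' Initialize a Gibbs sampler state
#'
#' Every token's topic is drawn uniformly from its gene's active labels
#' (so a single-label gene has all tokens forced to that label), and the
#' count tables are built to match.  Uses R's RNG: call `set.seed()` first
#' for reproducibility.
#'
#' @param corpus A `dmr_corpus`; every gene needs at least one label.
#' @param alpha D x T prior matrix from [compute_alpha()].
#' @return A `cgs_state`: `assignments`, `Ndt`, `Ntw`, `Nt`, `alpha`,
#'   `Lambda`, `aL` (the masked prior used by the sweeps).
#' @export
init_state <- function(corpus, alpha) {
  Lambda <- corpus$labels$matrix
  if (any(rowSums(Lambda) == 0)) stop("every training gene needs at least one active label")
  D <- nrow(Lambda); T_ <- ncol(Lambda)
  W <- length(corpus$vocabulary$words)
  Ndt <- matrix(0L, D, T_)
  Ntw <- matrix(0L, T_, W)
  Nt <- integer(T_)
  assignments <- vector("list", D)
  for (d in seq_len(D)) {
    active <- which(Lambda[d, ] == 1L)
    toks <- corpus$documents[[d]]$tokens
    z <- active[sample.int(length(active), length(toks), replace = TRUE)]
    assignments[[d]] <- as.integer(z)
    for (t in active) Ndt[d, t] <- sum(z == t)
    for (n in seq_along(toks)) Ntw[z[n], toks[n]] <- Ntw[z[n], toks[n]] + 1L
  }
  Nt <- as.integer(rowSums(Ntw))
  structure(list(assignments = assignments, Ndt = Ndt, Ntw = Ntw, Nt = Nt,
                 alpha = alpha, Lambda = Lambda, aL = alpha * Lambda,
                 tokens = lapply(corpus$documents, `[[`, "tokens")),
            class = "cgs_state")
}

#' Full-conditional topic distribution for one token
#'
#' The collapsed predictive distribution used by the Gibbs sweep:
#' `p(t) ~ (alpha_dt + Ndt^(-dn)) Lambda_dt * (lambda_w + Ntw^(-dn)) /
#' (sum_w lambda_w + Nt^(-dn))`, with the token itself removed from all
#' counts, normalized over the gene's active labels.  This R implementation
#' exists for inspection and testing; the training loop uses the equivalent
#' compiled sweep.
#'
#' @param state A `cgs_state`.
#' @param d Document index.
#' @param n Token index within document `d`.
#' @param lambda Topic-word Dirichlet parameter (scalar or length-W).
#' @return Length-T probability vector.
#' @export
topic_conditional <- function(state, d, n, lambda) {
  W <- ncol(state$Ntw)
  lambda <- rep_len(lambda, W)
  w <- state$tokens[[d]][n]
  told <- state$assignments[[d]][n]
  Ndt <- state$Ndt[d, ]; Ndt[told] <- Ndt[told] - 1L
  Ntw <- state$Ntw[, w]; Ntw[told] <- Ntw[told] - 1L
  Nt <- state$Nt; Nt[told] <- Nt[told] - 1L
  p <- (state$aL[d, ] + Ndt * state$Lambda[d, ]) * state$Lambda[d, ] *
    (lambda[w] + Ntw) / (sum(lambda) + Nt)
  if (sum(p) <= 0) stop("zero normalization mass at (", d, ", ", n, ")")
  unname(p / sum(p))
}

#' Run Gibbs sweeps
#'
#' Resamples every token once per sweep from its full conditional,
#' updating the count tables incrementally (compiled inner loop; R's RNG).
#'
#' @param state A `cgs_state`.
#' @param lambda Topic-word Dirichlet parameter (scalar or length-W).
#' @param nsweeps Number of full sweeps (default 1).
#' @return The updated state.
#' @export
gibbs_sweep <- function(state, lambda, nsweeps = 1L) {
  W <- ncol(state$Ntw)
  lambda <- rep_len(as.numeric(lambda), W)
  cgs_sweeps_cpp(state$tokens, state$assignments, state$Ndt, state$Ntw,
                 state$Nt, state$aL, lambda, as.integer(nsweeps))
  state
}

## Audit the count-table invariants of a sampler state (internal; used by
## tests).  Returns TRUE or stops with the violated invariant.
audit_state <- function(state) {
  Nd <- vapply(state$tokens, length, integer(1))
  stopifnot(all(rowSums(state$Ndt) == Nd),
            all(rowSums(state$Ntw) == state$Nt),
            all(state$Ndt[state$Lambda == 0L] == 0L),
            all(state$Ndt >= 0L), all(state$Ntw >= 0L))
  recount <- matrix(0L, nrow(state$Ndt), ncol(state$Ndt))
  for (d in seq_along(state$tokens)) {
    for (t in state$assignments[[d]]) recount[d, t] <- recount[d, t] + 1L
  }
  stopifnot(all(recount == state$Ndt))
  TRUE
}

#' Posterior point estimates from recorded states
#'
#' Smoothed relative frequencies using expectations over the recorded
#' states: `pi_hat[d, t] = (alpha_dt Lambda_dt + E[Ndt]) / sum_t (...)`
#' and `theta_hat[t, w] = (lambda_w + E[Ntw]) / sum_w (...)`.
#'
#' @param state The final `cgs_state` (supplies `alpha` and the mask).
#' @param recorded_states List of records, each with elements `Ndt` and
#'   `Ntw` (as produced by [train_cgs()]).
#' @param lambda Topic-word Dirichlet parameter.
#' @return List with `pi_hat` (D x T, rows sum to 1) and `theta_hat`
#'   (T x W, rows sum to 1).
#' @export
estimate_parameters <- function(state, recorded_states, lambda) {
  if (length(recorded_states) == 0L) stop("no recorded states to average")
  W <- ncol(state$Ntw)
  lambda <- rep_len(lambda, W)
  Ndt_bar <- Reduce(`+`, lapply(recorded_states, `[[`, "Ndt")) /
    length(recorded_states)
  Ntw_bar <- Reduce(`+`, lapply(recorded_states, `[[`, "Ntw")) /
    length(recorded_states)
  num_pi <- state$aL + Ndt_bar * state$Lambda
  pi_hat <- num_pi / rowSums(num_pi)
  num_th <- sweep(Ntw_bar, 2, lambda, "+")
  theta_hat <- num_th / rowSums(num_th)
  list(pi_hat = pi_hat, theta_hat = theta_hat)
}

#' Train DMR-LLDA by collapsed Gibbs sampling
#'
#' Runs the Markov chain with the schedule in `config`, interleaving
#' feature-weight optimization (and the prior refresh it implies) every
#' `beta_interval` sweeps, then forms posterior point estimates by
#' averaging the recorded post-burn-in states.
#'
#' @param corpus A `dmr_corpus` with labels (and, optionally, features).
#' @param config A [cgs_config()].
#' @return A fitted `dmr_llda` model: `theta_hat` (T x W), `pi_train`
#'   (D x T), `beta_hat` (a `dmr_beta`), `lambda`, `vocabulary`,
#'   `label_names`, `transform`, `config`, `inference = "cgs"`.
#' @export
train_cgs <- function(corpus, config = cgs_config()) {
  stopifnot(inherits(corpus, "dmr_corpus"))
  set.seed(config$seed)
  Lambda <- corpus$labels$matrix
  T_ <- ncol(Lambda)
  W <- length(corpus$vocabulary$words)
  lambda <- rep_len(if (is.null(config$lambda)) 200 / W else config$lambda, W)
  alpha0 <- if (is.null(config$alpha0)) 50 / T_ else config$alpha0

  yh <- corpus_y_hat(corpus)
  beta <- init_feature_weights(T_, ncol(yh$y_hat) - 1L, alpha0 = alpha0,
                               mu = config$mu, sigma2 = config$sigma2)
  alpha <- compute_alpha(yh$y_hat, beta, clip = config$clip)
  state <- init_state(corpus, alpha)
  Nd <- doc_lengths(corpus)

  records <- list()
  if (config$burn_in + config$thin > config$iterations) {
    stop("schedule records no states: need burn_in + thin <= iterations")
  }
  record_at <- seq(config$burn_in + config$thin, config$iterations,
                   by = config$thin)
  for (sweep in seq_len(config$iterations)) {
    state <- gibbs_sweep(state, lambda, 1L)
    if (config$update_features && sweep >= config$beta_start &&
        sweep %% config$beta_interval == 0L) {
      beta <- update_beta(beta, state$Ndt, Lambda, yh$y_hat, Nd = Nd,
                          max_iter = 25L, clip = config$clip)
      state$alpha <- compute_alpha(yh$y_hat, beta, clip = config$clip)
      state$aL <- state$alpha * Lambda
    }
    if (sweep %in% record_at) {
      records[[length(records) + 1L]] <- list(Ndt = state$Ndt, Ntw = state$Ntw)
    }
  }
  est <- estimate_parameters(state, records, lambda)
  structure(list(theta_hat = est$theta_hat, pi_train = est$pi_hat,
                 beta_hat = beta, lambda = lambda,
                 vocabulary = corpus$vocabulary,
                 label_names = corpus$labels$label_names,
                 transform = yh$transform, config = config,
                 inference = "cgs", n_records = length(records)),
            class = "dmr_llda")
}

#' @export
print.dmr_llda <- function(x, ...) {
  cat("<dmr_llda> ", nrow(x$theta_hat), " topics x ", ncol(x$theta_hat),
      " words, inference: ", x$inference, "\n", sep = "")
  invisible(x)
}
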