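#' Predict label distributions for test genes (fold-in)
#'
#' Scores every label for each test gene with the trained global
#' parameters held fixed: the gene's Dirichlet prior comes from its own
#' features through the trained weights (scaled with the training
#' standardization transform), the label support defaults to all labels
#' (an unannotated gene may carry any function) unless a candidate mask is
#' supplied, and the gene's topic distribution is inferred either by
#' fold-in Gibbs sampling (`method = "cgs"`: 1000 sweeps, 500 burn-in,
#' record every 50) or by the zero-order variational local loop
#' (`method = "cvb0"`).
#'
#' @param object A fitted `dmr_llda`.
#' @param corpus Test `dmr_corpus` sharing the training vocabulary.
#' @param method `"cgs"` or `"cvb0"` (defaults to the training flavour).
#' @param candidate_mask Optional D x L binary matrix restricting each
#'   gene's admissible labels.
#' @param iterations,burn_in,thin Fold-in Gibbs schedule.
#' @param local_iters,local_tol Variational fold-in stopping rule.
#' @param seed Seed for the fold-in chain.
#' @param ... Unused.
#' @return A `dmr_prediction`: `scores` (D x L, rows summing to 1),
#'   `method`, `config`.
#' @export
predict.dmr_llda <- function(object, corpus,
                             method = if (object$inference == "cgs") "cgs" else "cvb0",
                             candidate_mask = NULL,
                             iterations = 1000L, burn_in = 500L, thin = 50L,
                             local_iters = 100L, local_tol = 1e-5,
                             seed = 1L, ...) {
  stopifnot(inherits(corpus, "dmr_corpus"))
  method <- match.arg(method, c("cgs", "cvb0"))
  T_ <- nrow(object$theta_hat)
  D <- length(corpus$documents)

  if (is.null(object$transform)) {
    y_hat <- matrix(1, D, 1L)
  } else {
    if (is.null(corpus$features) ||
        ncol(corpus$features$values) != length(object$transform$center)) {
      stop("test features do not match the training feature dimension")
    }
    std <- standardize_features(corpus$features, fit = FALSE,
                                transform = object$transform)
    y_hat <- augment_features(std$values)
  }
  if (ncol(y_hat) != ncol(object$beta_hat$matrix)) {
    stop("test features do not match the training feature dimension")
  }
  alpha <- compute_alpha(y_hat, object$beta_hat,
                         clip = object$config$clip %||% 30)
  mask <- if (is.null(candidate_mask)) matrix(1L, D, T_) else {
    m <- as.matrix(candidate_mask)
    if (!all(dim(m) == c(D, T_))) stop("candidate mask shape mismatch")
    storage.mode(m) <- "integer"
    m
  }
  if (any(rowSums(mask) == 0)) stop("candidate mask leaves a gene with no labels")
  aL <- alpha * mask

  scores <- if (method == "cgs") {
    foldin_cgs(corpus, aL, mask, object$theta_hat, iterations, burn_in,
               thin, seed)
  } else {
    foldin_cvb0(corpus, aL, object$theta_hat, local_iters, local_tol)
  }
  colnames(scores) <- object$label_names
  rownames(scores) <- vapply(corpus$documents, `[[`, character(1), "gene_id")
  structure(list(scores = scores, method = method,
                 config = list(iterations = iterations, burn_in = burn_in,
                               thin = thin, local_iters = local_iters,
                               local_tol = local_tol, seed = seed)),
            class = "dmr_prediction")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

foldin_cgs <- function(corpus, aL, mask, theta, iterations, burn_in, thin,
                       seed) {
  set.seed(seed)
  D <- nrow(aL); T_ <- ncol(aL)
  tokens <- lapply(corpus$documents, `[[`, "tokens")
  Ndt <- matrix(0L, D, T_)
  z <- vector("list", D)
  for (d in seq_len(D)) {
    active <- which(mask[d, ] == 1L)
    zd <- active[sample.int(length(active), length(tokens[[d]]),
                            replace = TRUE)]
    z[[d]] <- as.integer(zd)
    for (t in active) Ndt[d, t] <- sum(zd == t)
  }
  if (burn_in > 0) cgs_foldin_cpp(tokens, z, Ndt, aL, theta, as.integer(burn_in))
  record_at <- seq(burn_in + thin, iterations, by = thin)
  acc <- matrix(0, D, T_)
  prev <- burn_in
  for (r in record_at) {
    cgs_foldin_cpp(tokens, z, Ndt, aL, theta, as.integer(r - prev))
    acc <- acc + Ndt
    prev <- r
  }
  Ndt_bar <- acc / length(record_at)
  num <- aL + Ndt_bar * mask
  num / rowSums(num)
}

foldin_cvb0 <- function(corpus, aL, theta, local_iters, local_tol) {
  wt <- doc_word_types(corpus)
  D <- nrow(aL); T_ <- ncol(aL)
  out <- matrix(0, D, T_)
  for (d in seq_len(D)) {
    wids <- wt[[d]]$wids; ndw <- wt[[d]]$ndw
    Bd <- t(theta[, wids, drop = FALSE])
    Nd <- sum(ndw)
    loc <- cvb0_local_cpp(ndw, Bd, aL[d, ], local_tol, local_iters, Nd)
    Ndt_full <- colSums(ndw * loc$eta)
    num <- aL[d, ] + Ndt_full
    out[d, ] <- num / sum(num)
  }
  out
}

#' Binarize prediction scores
#'
#' Turns per-gene label scores into hard label assignments.  Policy
#' `"uniform"` switches a label on when its score reaches the uniform
#' level `1 / L` (inclusive, so perfectly flat scores switch every label
#' on).  Policy `"tuned"` uses one global threshold; if `threshold` is not
#' given it is chosen by an exhaustive scan over the observed scores to
#' maximize micro-F1 against `truth` (typically training-fold predictions).
#'
#' @param scores D x L score matrix (or a `dmr_prediction`).
#' @param policy `"uniform"` or `"tuned"`.
#' @param threshold Optional fixed threshold for `"tuned"`.
#' @param truth A `dmr_labels` or binary matrix, required to tune.
#' @return Binary D x L matrix with attribute `threshold`.
#' @export
binarize <- function(scores, policy = c("uniform", "tuned"),
                     threshold = NULL, truth = NULL) {
  if (inherits(scores, "dmr_prediction")) scores <- scores$scores
  policy <- match.arg(policy)
  if (policy == "uniform") {
    thr <- 1 / ncol(scores)
  } else {
    if (is.null(threshold)) {
      if (is.null(truth)) stop("tuning a threshold requires truth labels")
      truth_m <- if (inherits(truth, "dmr_labels")) truth$matrix else as.matrix(truth)
      cand <- sort(unique(as.vector(scores)))
      f1 <- vapply(cand, function(th) {
        pred <- (scores >= th) * 1L
        micro_f1(pred, truth_m)
      }, numeric(1))
      thr <- cand[which.max(f1)]
    } else {
      thr <- threshold
    }
  }
  out <- (scores >= thr) * 1L
  attr(out, "threshold") <- thr
  out
}

micro_f1 <- function(pred, truth) {
  tp <- sum(pred == 1L & truth == 1L)
  fp <- sum(pred == 1L & truth == 0L)
  fn <- sum(pred == 0L & truth == 1L)
  if (2 * tp + fp + fn == 0) return(0)
  2 * tp / (2 * tp + fp + fn)
}

macro_f1 <- function(pred, truth) {
  f1s <- vapply(seq_len(ncol(truth)), function(l) {
    tp <- sum(pred[, l] == 1L & truth[, l] == 1L)
    fp <- sum(pred[, l] == 1L & truth[, l] == 0L)
    fn <- sum(pred[, l] == 0L & truth[, l] == 1L)
    if (2 * tp + fp + fn == 0) return(NA_real_)
    2 * tp / (2 * tp + fp + fn)
  }, numeric(1))
  mean(f1s, na.rm = TRUE)
}

## Area under the precision-recall curve, step-wise (non-interpolated)
## estimator: sum over descending-score cuts of (R_i - R_{i-1}) * P_i.
## Ties in score are broken by stable index order.
pr_auc <- function(scores, truth) {
  n_pos <- sum(truth == 1)
  if (n_pos == 0) return(NA_real_)
  ord <- order(-scores, seq_along(scores))
  hit <- truth[ord] == 1
  tp <- cumsum(hit)
  prec <- tp / seq_along(tp)
  rec <- tp / n_pos
  sum(diff(c(0, rec)) * prec)
}

#' Multi-label evaluation metrics
#'
#' Computes the full metric suite from ranking scores and a binarization:
#' Hamming loss (mean per-cell mismatch), average precision (mean over
#' genes of the mean precision at the rank of each true label), one-error
#' (fraction of genes whose top-scored label is not true), micro- and
#' macro-averaged F1 from `binary_pred`, and three areas under
#' precision-recall curves — macro (`aupr_macro`: unweighted mean of
#' per-label areas), pooled (`aupr_pooled`: one curve over all gene-label
#' pairs) and frequency-weighted (`aupr_weighted`: per-label areas weighted
#' by label prevalence).  Genes with no true label are excluded from the
#' ranking metrics with a count; labels with no positive gene are excluded
#' from the macro areas.
#'
#' @param scores D x L score matrix (or `dmr_prediction`).
#' @param binary_pred D x L binary matrix from [binarize()] (computed with
#'   the uniform policy if omitted).
#' @param truth A `dmr_labels` or binary D x L matrix.
#' @return A `dmr_metrics` list with the eight metrics, `n_excluded_genes`
#'   and the binarization `threshold`.
#' @export
compute_metrics <- function(scores, binary_pred = NULL, truth) {
  if (inherits(scores, "dmr_prediction")) scores <- scores$scores
  truth_m <- if (inherits(truth, "dmr_labels")) truth$matrix else as.matrix(truth)
  stopifnot(all(dim(scores) == dim(truth_m)))
  if (is.null(binary_pred)) binary_pred <- binarize(scores, "uniform")
  D <- nrow(truth_m); L <- ncol(truth_m)

  hl <- mean(binary_pred != truth_m)

  has_truth <- rowSums(truth_m) > 0
  ap_g <- one_err_g <- rep(NA_real_, D)
  for (d in which(has_truth)) {
    ord <- order(-scores[d, ], seq_len(L))
    rank_of <- match(seq_len(L), ord)
    true_l <- which(truth_m[d, ] == 1)
    prec_at <- vapply(true_l, function(l) {
      r <- rank_of[l]
      sum(rank_of[true_l] <= r) / r
    }, numeric(1))
    ap_g[d] <- mean(prec_at)
    one_err_g[d] <- as.numeric(truth_m[d, ord[1]] != 1)
  }
  ap <- mean(ap_g, na.rm = TRUE)
  one_error <- mean(one_err_g, na.rm = TRUE)

  per_label_auc <- vapply(seq_len(L), function(l)
    pr_auc(scores[, l], truth_m[, l]), numeric(1))
  label_freq <- colSums(truth_m)
  ok <- !is.na(per_label_auc)
  aupr_macro <- mean(per_label_auc[ok])
  aupr_weighted <- sum(per_label_auc[ok] * label_freq[ok]) / sum(label_freq[ok])
  aupr_pooled <- pr_auc(as.vector(scores), as.vector(truth_m))

  structure(list(
    hamming_loss = hl,
    average_precision = ap,
    one_error = one_error,
    micro_f1 = micro_f1(binary_pred, truth_m),
    macro_f1 = macro_f1(binary_pred, truth_m),
    aupr_macro = aupr_macro,
    aupr_pooled = aupr_pooled,
    aupr_weighted = aupr_weighted,
    n_excluded_genes = sum(!has_truth),
    threshold = attr(binary_pred, "threshold")
  ), class = "dmr_metrics")
}

#' @export
print.dmr_metrics <- function(x, ...) {
  nm <- c("hamming_loss", "average_precision", "one_error", "micro_f1",
          "macro_f1", "aupr_macro", "aupr_pooled", "aupr_weighted")
  vals <- unlist(x[nm])
  cat("<dmr_metrics>\n")
  for (i in seq_along(nm)) cat(sprintf("  %-18s %.4f\n", nm[i], vals[i]))
  invisible(x)
}
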