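#' Subset a corpus by document index
#'
#' Keeps the vocabulary and label catalog; rows of the label and feature
#' matrices stay aligned with the retained documents.
#'
#' @param corpus A `dmr_corpus`.
#' @param idx Integer vector of document indices.
#' @return A `dmr_corpus` with `length(idx)` documents.
#' @export
subset_corpus <- function(corpus, idx) {
  stopifnot(inherits(corpus, "dmr_corpus"))
  out <- corpus
  out$documents <- corpus$documents[idx]
  out$labels$matrix <- corpus$labels$matrix[idx, , drop = FALSE]
  if (!is.null(corpus$features)) {
    out$features$values <- corpus$features$values[idx, , drop = FALSE]
    out$features$transform <- NULL
  }
  out
}

#' Repeated k-fold cross-validation
#'
#' Random (stratification-free) partitions into `folds` folds, repeated
#' over `rounds` independent rounds.  Each fold trains on the remaining
#' genes, predicts the held-out genes over the full label space, and
#' evaluates the metric suite.  Optionally the label space is compressed
#' with Boolean matrix decomposition before training and predictions are
#' recovered through the basis matrix before scoring.
#'
#' @param corpus A `dmr_corpus`.
#' @param trainer Function `corpus -> dmr_llda` (e.g. a closure over
#'   [train_cgs()] with a chosen config).
#' @param folds Number of folds (default 5).
#' @param rounds Number of independent repetition rounds (default 5).
#' @param seed Seed governing all partitions and fold-in chains.
#' @param predict_method `"cgs"` or `"cvb0"`.
#' @param predict_args Extra arguments passed to [predict.dmr_llda()].
#' @param bmd_max_rank If non-`NULL`, compress the training label space by
#'   [bmd_decompose()] with this maximum rank and recover predictions via
#'   [bmd_recover()].
#' @return A `dmr_cv` list: `per_fold` (one `dmr_metrics` per round/fold),
#'   `mean` (metric means across all folds), `folds`, `rounds`, `seed`.
#' @export
cross_validate <- function(corpus, trainer, folds = 5L, rounds = 5L,
                           seed = 1L, predict_method = "cgs",
                           predict_args = list(), bmd_max_rank = NULL) {
  stopifnot(inherits(corpus, "dmr_corpus"))
  D <- length(corpus$documents)
  if (D < folds) stop("fewer genes (", D, ") than folds (", folds, ")")
  per_fold <- list()
  assignments <- list()
  for (r in seq_len(rounds)) {
    set.seed(seed + 1000L * (r - 1L))
    fold_of <- sample(rep_len(seq_len(folds), D))
    assignments[[r]] <- fold_of
    for (k in seq_len(folds)) {
      test_idx <- which(fold_of == k)
      train_idx <- which(fold_of != k)
      train_c <- subset_corpus(corpus, train_idx)
      test_c <- subset_corpus(corpus, test_idx)

      bmd <- NULL
      if (!is.null(bmd_max_rank)) {
        bmd <- bmd_decompose(train_c$labels, max_rank = bmd_max_rank)
        train_c$labels <- label_matrix(bmd$C, paste0("c", seq_len(bmd$rank)))
        # an approximate factorization can leave a gene with no compressed
        # label; such genes cannot be trained on and are dropped
        covered <- rowSums(bmd$C) > 0
        if (!all(covered)) train_c <- subset_corpus(train_c, which(covered))
      }
      model <- trainer(train_c)
      pred <- do.call(predict, c(list(model, test_c,
                                      method = predict_method,
                                      seed = seed + 7L * r + k),
                                 predict_args))
      scores <- pred$scores
      if (!is.null(bmd)) scores <- bmd_recover(scores, bmd)
      m <- compute_metrics(scores, binarize(scores, "uniform"),
                           test_c$labels$matrix[, , drop = FALSE])
      m$round <- r; m$fold <- k
      per_fold[[length(per_fold) + 1L]] <- m
    }
  }
  nm <- c("hamming_loss", "average_precision", "one_error", "micro_f1",
          "macro_f1", "aupr_macro", "aupr_pooled", "aupr_weighted")
  means <- vapply(nm, function(s)
    mean(vapply(per_fold, function(m) m[[s]], numeric(1))), numeric(1))
  structure(list(per_fold = per_fold, mean = as.list(means),
                 fold_assignments = assignments,
                 folds = folds, rounds = rounds, seed = seed),
            class = "dmr_cv")
}

#' @export
print.dmr_cv <- function(x, ...) {
  cat("<dmr_cv> ", x$rounds, " rounds x ", x$folds, " folds\n", sep = "")
  for (nm in names(x$mean)) cat(sprintf("  mean %-18s %.4f\n", nm, x$mean[[nm]]))
  invisible(x)
}
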