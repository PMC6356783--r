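#' Read protein sequences from a FASTA file
#'
#' Thin wrapper around [Biostrings::readAAStringSet()] that returns plain
#' uppercase character strings keyed by the first whitespace-delimited token
#' of each header, preserving order of appearance.
#'
#' @param path Path to a FASTA file.
#' @return Named character vector of sequences (possibly empty, with a
#'   warning, for an empty file).
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  nonblank <- which(nzchar(trimws(lines)))
  if (length(nonblank) == 0L) {
    warning("empty FASTA file: ", path)
    return(setNames(character(0), character(0)))
  }
  first <- nonblank[1L]
  if (!startsWith(trimws(lines[first]), ">")) {
    stop("malformed FASTA header at line ", first, " of ", path,
         ": expected '>' but found: ", substr(lines[first], 1, 40))
  }
  set <- Biostrings::readAAStringSet(path)
  ids <- vapply(strsplit(names(set), "[[:space:]]+"), `[[`, character(1), 1L)
  if (anyDuplicated(ids)) {
    stop("duplicate sequence ids in ", path, ": ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  setNames(toupper(as.character(set)), ids)
}

#' Tokenize a protein sequence into amino-acid-block words
#'
#' Slides fixed-length windows over the sequence, one pass per block length
#' in `k_set`.  Windows start at positions `1, 1 + stride, 1 + 2 * stride,
#' ...` and only full-length windows are emitted.  Windows containing any
#' character outside the 20-letter amino-acid alphabet (e.g. `X`, `B`, `Z`,
#' `U`, `*`) are skipped and counted rather than raising an error.
#'
#' With `stride = 1` the tokens are overlapping k-mers; `stride = k` gives a
#' disjoint partition of the sequence into consecutive blocks.
#'
#' @param seq A single character string (uppercased amino acids).
#' @param k_set Integer vector of block lengths (each >= 1).
#' @param stride Window step (>= 1). Default 1 (overlapping windows).
#' @return Character vector of tokens with attribute `n_skipped`, the number
#'   of windows dropped because of non-standard characters.
#' @export
tokenize_sequence <- function(seq, k_set = 2L, stride = 1L) {
  stopifnot(is.character(seq), length(seq) == 1L)
  k_set <- sort(unique(as.integer(k_set)))
  if (length(k_set) == 0L || any(k_set < 1L)) stop("k_set must contain integers >= 1")
  stride <- as.integer(stride)
  if (is.na(stride) || stride < 1L) stop("stride must be >= 1")

  chars <- strsplit(seq, "", fixed = TRUE)[[1]]
  n <- length(chars)
  ok <- chars %in% AA_ALPHABET
  tokens <- character(0)
  n_skipped <- 0L
  for (k in k_set) {
    if (n < k) next
    starts <- seq.int(1L, n - k + 1L, by = stride)
    # a window is valid iff every residue inside it is a standard amino acid
    valid <- vapply(starts, function(s) all(ok[s:(s + k - 1L)]), logical(1))
    n_skipped <- n_skipped + sum(!valid)
    if (any(valid)) {
      tokens <- c(tokens, vapply(starts[valid], function(s)
        paste(chars[s:(s + k - 1L)], collapse = ""), character(1)))
    }
  }
  attr(tokens, "n_skipped") <- n_skipped
  tokens
}

#' Enumerate the candidate word space for a set of block lengths
#'
#' All amino-acid blocks of the given lengths over the 20-letter alphabet,
#' in lexicographic order; for example lengths `2` give 400 words and
#' lengths `c(2, 3)` give 8400.
#'
#' @param k_set Integer vector of block lengths.
#' @return Character vector of all `sum(20^k)` candidate words.
#' @export
all_kmers <- function(k_set) {
  k_set <- sort(unique(as.integer(k_set)))
  ab <- sort(AA_ALPHABET)
  unlist(lapply(k_set, function(k) {
    grids <- rev(rep(list(ab), k))
    do.call(paste0, rev(expand.grid(grids, stringsAsFactors = FALSE)))
  }), use.names = FALSE)
}

#' Build a vocabulary from tokenized documents
#'
#' Collects every observed word, optionally dropping words whose document
#' frequency exceeds `max_doc_freq` (a fraction of documents), and assigns
#' dense integer ids in lexicographic order so that the vocabulary is a
#' deterministic function of its inputs.
#'
#' @param token_lists List of character vectors, one per document, as
#'   produced by [tokenize_sequence()].
#' @param k_set Block lengths the tokens were built with (recorded on the
#'   vocabulary and validated against the observed word lengths).
#' @param max_doc_freq Optional maximum document frequency as a fraction in
#'   `[0, 1]`; `NULL` (default) disables high-frequency filtering.
#' @return A `dmr_vocabulary`: list with `words`, `index` (named integer
#'   vector word -> id), `k_set`, `alphabet`.
#' @export
build_vocabulary <- function(token_lists, k_set = 2L, max_doc_freq = NULL) {
  stopifnot(is.list(token_lists))
  k_set <- sort(unique(as.integer(k_set)))
  words <- sort(unique(unlist(token_lists, use.names = FALSE)))
  if (length(words) > 0 && !all(nchar(words) %in% k_set)) {
    stop("observed word lengths are inconsistent with k_set")
  }
  if (!is.null(max_doc_freq)) {
    if (max_doc_freq < 0 || max_doc_freq > 1) stop("max_doc_freq must be in [0, 1]")
    ndoc <- length(token_lists)
    df <- table(unlist(lapply(token_lists, unique), use.names = FALSE))
    keep <- names(df)[as.vector(df) / max(ndoc, 1L) <= max_doc_freq]
    words <- sort(intersect(words, keep))
  }
  new_vocabulary(words, k_set)
}

new_vocabulary <- function(words, k_set) {
  structure(list(
    words = words,
    index = setNames(seq_along(words), words),
    k_set = as.integer(k_set),
    alphabet = AA_ALPHABET
  ), class = "dmr_vocabulary")
}

#' @export
print.dmr_vocabulary <- function(x, ...) {
  cat("<dmr_vocabulary> ", length(x$words), " words, block lengths {",
      paste(x$k_set, collapse = ","), "}\n", sep = "")
  invisible(x)
}

#' Read a gene feature table
#'
#' Reads a delimited text file with a header row whose first column is the
#' gene id and whose remaining columns are numeric gene features (e.g.
#' molecular weight, isoelectric point, hydrophilicity).
#'
#' @param path Path to a TSV/CSV file.
#' @param sep Field separator (default tab).
#' @return A `dmr_features` object (see [feature_table()]).
#' @export
read_features <- function(path, sep = "\t") {
  df <- read.delim(path, sep = sep, header = TRUE, check.names = FALSE,
                   stringsAsFactors = FALSE)
  if (ncol(df) < 1L) stop("feature file has no columns: ", path)
  ids <- as.character(df[[1]])
  mat <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(mat) <- "double"
  feature_table(mat, gene_ids = ids)
}

#' Construct a gene feature table
#'
#' @param values Numeric matrix, one row per gene, one column per feature.
#' @param gene_ids Character vector of row ids.
#' @param feature_names Optional column names (default taken from `values`).
#' @return A `dmr_features` object: the matrix plus an (initially unfitted)
#'   standardization transform.
#' @export
feature_table <- function(values, gene_ids, feature_names = colnames(values)) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (is.null(feature_names)) feature_names <- paste0("f", seq_len(ncol(values)))
  if (length(gene_ids) != nrow(values)) stop("gene_ids length must match rows")
  if (anyNA(values)) stop("feature table contains missing values")
  dimnames(values) <- list(as.character(gene_ids), feature_names)
  structure(list(values = values, transform = NULL), class = "dmr_features")
}

#' Standardize gene features (z-score)
#'
#' Centers and scales each feature column.  With `fit = TRUE` the per-column
#' mean and standard deviation are estimated from `table` and stored as its
#' transform; with `fit = FALSE` a previously fitted transform (from
#' `transform` or already attached to `table`) is applied unchanged — this
#' is the prediction path, where test genes must be scaled exactly as the
#' training genes were.  Constant columns get a standard deviation of 1 so
#' they map to all zeros instead of dividing by zero.
#'
#' @param table A `dmr_features` object.
#' @param fit Estimate a new transform (`TRUE`) or apply a stored one.
#' @param transform Optional transform to apply when `fit = FALSE`.
#' @return A `dmr_features` with standardized `values` and the transform
#'   recorded in `$transform` (fields `center`, `scale`).
#' @export
standardize_features <- function(table, fit = TRUE, transform = NULL) {
  stopifnot(inherits(table, "dmr_features"))
  x <- table$values
  if (fit) {
    center <- colMeans(x)
    scale <- apply(x, 2, sd)
    scale[!is.finite(scale) | scale == 0] <- 1
    tr <- list(center = center, scale = scale)
  } else {
    tr <- if (!is.null(transform)) transform else table$transform
    if (is.null(tr)) stop("no fitted transform to apply (call with fit = TRUE first)")
    if (length(tr$center) != ncol(x)) stop("transform dimension mismatch")
  }
  z <- sweep(sweep(x, 2, tr$center, "-"), 2, tr$scale, "/")
  structure(list(values = z, transform = tr), class = "dmr_features")
}

#' Invert a feature standardization
#'
#' @param table A standardized `dmr_features` with a fitted transform.
#' @return A `dmr_features` on the original scale (transform cleared).
#' @export
unstandardize_features <- function(table) {
  stopifnot(inherits(table, "dmr_features"))
  tr <- table$transform
  if (is.null(tr)) stop("feature table carries no transform")
  x <- sweep(sweep(table$values, 2, tr$scale, "*"), 2, tr$center, "+")
  structure(list(values = x, transform = NULL), class = "dmr_features")
}

#' Assemble a model-ready corpus
#'
#' Aligns sequences, labels and features on their shared gene-id universe
#' (genes missing any component are dropped and reported), tokenizes each
#' sequence, maps tokens to vocabulary ids (out-of-vocabulary tokens are
#' dropped and counted) and packages everything as a `dmr_corpus` whose
#' document list, label matrix and feature matrix are row-aligned.
#'
#' @param sequences Named character vector from [read_fasta()].
#' @param vocabulary A `dmr_vocabulary`.
#' @param label_matrix A `dmr_labels` object (see [label_matrix()]).
#' @param feature_table A `dmr_features` object, or `NULL` for the
#'   feature-free model.
#' @param k_set,stride Tokenizer settings (see [tokenize_sequence()]).
#' @return A `dmr_corpus`: `documents` (list of `gene_id`, `tokens` integer
#'   word ids, `counts` named by word id), `vocabulary`, `labels`,
#'   `features`, plus a `report` of dropped genes/tokens.
#' @export
build_corpus <- function(sequences, vocabulary, label_matrix,
                         feature_table = NULL, k_set = vocabulary$k_set,
                         stride = 1L) {
  stopifnot(inherits(vocabulary, "dmr_vocabulary"),
            inherits(label_matrix, "dmr_labels"))
  ids <- intersect(names(sequences), rownames(label_matrix$matrix))
  if (!is.null(feature_table)) ids <- intersect(ids, rownames(feature_table$values))
  dropped <- setdiff(unique(c(names(sequences), rownames(label_matrix$matrix),
                              if (!is.null(feature_table)) rownames(feature_table$values))),
                     ids)
  if (length(ids) == 0L) stop("no gene ids shared by sequences, labels and features")
  ids <- ids[order(match(ids, names(sequences)))]  # keep FASTA order

  oov <- 0L
  documents <- lapply(ids, function(g) {
    toks <- tokenize_sequence(sequences[[g]], k_set = k_set, stride = stride)
    wid <- vocabulary$index[toks]
    keep <- !is.na(wid)
    oov <<- oov + sum(!keep)
    wid <- unname(wid[keep])
    cnt <- table(wid)
    list(gene_id = g, tokens = as.integer(wid),
         counts = setNames(as.integer(cnt), names(cnt)))
  })

  labels <- label_matrix
  labels$matrix <- labels$matrix[ids, , drop = FALSE]
  features <- feature_table
  if (!is.null(features)) {
    features$values <- features$values[ids, , drop = FALSE]
  }
  structure(list(
    documents = documents,
    vocabulary = vocabulary,
    labels = labels,
    features = features,
    report = list(dropped_genes = dropped, oov_tokens = oov)
  ), class = "dmr_corpus")
}

#' @export
print.dmr_corpus <- function(x, ...) {
  cat("<dmr_corpus> ", length(x$documents), " genes, W = ",
      length(x$vocabulary$words), ", L = ", ncol(x$labels$matrix), ", F = ",
      if (is.null(x$features)) 0L else ncol(x$features$values), "\n", sep = "")
  invisible(x)
}

## Dense D x W count matrix view of a corpus (internal).
corpus_counts <- function(corpus) {
  W <- length(corpus$vocabulary$words)
  D <- length(corpus$documents)
  m <- matrix(0L, D, W)
  for (d in seq_len(D)) {
    cnt <- corpus$documents[[d]]$counts
    m[d, as.integer(names(cnt))] <- cnt
  }
  rownames(m) <- vapply(corpus$documents, `[[`, character(1), "gene_id")
  colnames(m) <- corpus$vocabulary$words
  m
}

## Per-document token totals Nd (internal).
doc_lengths <- function(corpus) {
  vapply(corpus$documents, function(d) length(d$tokens), integer(1))
}
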