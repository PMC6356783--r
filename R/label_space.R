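#' Construct a binary gene-label matrix
#'
#' @param matrix Binary matrix, genes in rows, labels in columns.
#' @param label_names Column ids (e.g. GO terms); default from `matrix`.
#' @return A `dmr_labels` object.
#' @export
label_matrix <- function(matrix, label_names = colnames(matrix)) {
  m <- as.matrix(matrix)
  storage.mode(m) <- "integer"
  if (length(m) > 0 && !all(m %in% c(0L, 1L))) stop("label matrix must be binary")
  if (is.null(label_names)) label_names <- paste0("L", seq_len(ncol(m)))
  if (ncol(m) > 0) colnames(m) <- label_names
  structure(list(matrix = m, label_names = as.character(label_names)),
            class = "dmr_labels")
}

#' @export
print.dmr_labels <- function(x, ...) {
  cat("<dmr_labels> ", nrow(x$matrix), " genes x ", ncol(x$matrix),
      " labels, ", sum(x$matrix), " annotations\n", sep = "")
  invisible(x)
}

#' Load gene-label annotations from a two-column file
#'
#' Each line pairs a gene id with a label id (e.g. a GO term).  Duplicate
#' pairs collapse to a single annotation; pairs whose gene id is not in
#' `gene_universe` (when given) are dropped with a reported count.  Labels
#' are sorted lexicographically so the column order is deterministic.
#'
#' @param path Path to a delimited file with two columns (no header).
#' @param gene_universe Optional character vector restricting (and ordering)
#'   the rows; genes with no annotation get an all-zero row.
#' @param sep Field separator (default tab).
#' @return A `dmr_labels` with attribute `n_dropped` (unknown-gene pairs).
#' @export
load_annotations <- function(path, gene_universe = NULL, sep = "\t") {
  if (!file.exists(path)) stop("annotation file not found: ", path)
  df <- if (length(readLines(path, n = 1L, warn = FALSE)) == 0L) {
    data.frame(V1 = character(0), V2 = character(0))
  } else {
    read.delim(path, sep = sep, header = FALSE, stringsAsFactors = FALSE)
  }
  if (nrow(df) > 0 && ncol(df) < 2L) stop("annotation file must have two columns: ", path)
  genes <- as.character(df[[1]])
  labs <- if (nrow(df) > 0) as.character(df[[2]]) else character(0)
  n_dropped <- 0L
  if (!is.null(gene_universe)) {
    keep <- genes %in% gene_universe
    n_dropped <- sum(!keep)
    genes <- genes[keep]; labs <- labs[keep]
  }
  rows <- if (is.null(gene_universe)) sort(unique(genes)) else as.character(gene_universe)
  cols <- sort(unique(labs))
  m <- matrix(0L, length(rows), length(cols), dimnames = list(rows, cols))
  if (length(genes) > 0) m[cbind(match(genes, rows), match(labs, cols))] <- 1L
  out <- label_matrix(m, cols)
  attr(out, "n_dropped") <- n_dropped
  out
}

## Boolean product of binary matrices: (C %bool% B)[d,l] = OR_k C[d,k] & B[k,l]
bool_product <- function(C, B) {
  (C %*% B > 0) * 1L
}

#' Boolean matrix decomposition of a label matrix
#'
#' Factorizes a binary matrix `Y` as the Boolean product `C o B` of a gene
#' by compressed-label matrix `C` and a basis matrix `B`, for label-space
#' dimension reduction.  The construction is a greedy exact cover over the
#' distinct nonzero row patterns of `Y`: each distinct pattern starts as a
#' basis row, and a basis row is discarded when it equals the Boolean OR of
#' the remaining basis rows contained in it (checked from the heaviest row
#' down, ties broken by row order, so the result is deterministic).  When
#' the resulting rank exceeds `max_rank` the heaviest-used patterns are
#' kept and the factorization is approximate; the number of mismatched
#' cells is reported as `residual`.
#'
#' @param Y A `dmr_labels` or binary matrix.
#' @param max_rank Maximum number of compressed labels (default `ncol(Y)`).
#' @return A `dmr_bmd`: list `C` (D x rank), `B` (rank x L), `rank`,
#'   `residual` (0 for an exact factorization).
#' @export
bmd_decompose <- function(Y, max_rank = NULL) {
  if (inherits(Y, "dmr_labels")) Y <- Y$matrix
  Y <- as.matrix(Y); storage.mode(Y) <- "integer"
  if (length(Y) > 0 && !all(Y %in% c(0L, 1L))) stop("Y must be binary")
  if (is.null(max_rank)) max_rank <- ncol(Y)
  if (max_rank < 1L) stop("max_rank must be >= 1")
  D <- nrow(Y); L <- ncol(Y)

  pat_key <- apply(Y, 1, paste, collapse = "")
  nonzero <- rowSums(Y) > 0
  keys <- unique(pat_key[nonzero])
  basis <- t(vapply(keys, function(k) Y[match(k, pat_key), ], integer(L)))
  rownames(basis) <- NULL
  n_use <- as.vector(table(factor(pat_key[nonzero], levels = keys)))

  # Greedy pruning: drop a pattern reproducible as the OR of the other
  # retained patterns it contains.  Heaviest rows are tried first so that
  # broad patterns are expressed through narrow ones.
  keep <- rep(TRUE, nrow(basis))
  ord <- order(-rowSums(basis), seq_len(nrow(basis)))
  for (i in ord) {
    others <- which(keep)
    others <- others[others != i]
    if (length(others) == 0L) next
    contained <- others[vapply(others, function(j)
      all(basis[j, ] <= basis[i, ]), logical(1))]
    if (length(contained) == 0L) next
    cover <- if (length(contained) == 1L) basis[contained, ]
             else as.integer(colSums(basis[contained, , drop = FALSE]) > 0)
    if (all(cover == basis[i, ])) keep[i] <- FALSE
  }
  basis <- basis[keep, , drop = FALSE]
  n_use <- n_use[keep]

  if (nrow(basis) > max_rank) {
    ord2 <- order(-n_use, seq_len(nrow(basis)))
    basis <- basis[sort(ord2[seq_len(max_rank)]), , drop = FALSE]
  }
  rank <- nrow(basis)

  # C: cover each gene's row by every basis row contained in it.
  C <- matrix(0L, D, rank)
  for (d in seq_len(D)) {
    if (rank > 0) {
      C[d, ] <- as.integer(vapply(seq_len(rank), function(j)
        all(basis[j, ] <= Y[d, ]), logical(1)))
    }
  }
  recon <- if (rank > 0) bool_product(C, basis) else matrix(0L, D, L)
  structure(list(C = C, B = basis, rank = rank,
                 residual = sum(recon != Y)),
            class = "dmr_bmd")
}

#' @export
print.dmr_bmd <- function(x, ...) {
  cat("<dmr_bmd> rank ", x$rank, ", residual ", x$residual, "\n", sep = "")
  invisible(x)
}

#' Recover full-label predictions from a compressed label space
#'
#' Binary input is expanded by the Boolean product `C_pred o B`.  Real
#' valued scores are expanded by max-product — the score of label `l` is
#' `max over l'` of `C_pred[d, l'] * B[l', l]` — so that score rankings
#' survive the recovery.
#'
#' @param C_pred D x rank binary matrix or real score matrix.
#' @param B Basis matrix from [bmd_decompose()] (or a `dmr_bmd`).
#' @return D x L matrix of the same flavour (binary or scores).
#' @export
bmd_recover <- function(C_pred, B) {
  if (inherits(B, "dmr_bmd")) B <- B$B
  C_pred <- as.matrix(C_pred)
  if (ncol(C_pred) != nrow(B)) {
    stop("column count of C_pred (", ncol(C_pred),
         ") must equal the factorization rank (", nrow(B), ")")
  }
  binary <- all(C_pred %in% c(0, 1))
  if (binary) return(bool_product(C_pred, B))
  out <- matrix(0, nrow(C_pred), ncol(B))
  for (l in seq_len(ncol(B))) {
    idx <- which(B[, l] > 0)
    if (length(idx) > 0) {
      out[, l] <- apply(C_pred[, idx, drop = FALSE], 1, max)
    }
  }
  colnames(out) <- colnames(B)
  out
}
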