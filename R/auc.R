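#' Area under the ROC curve for one covariate
#'
#' Computes the AUC for predicting the binary class `z` from covariate `x`
#' via the Mann-Whitney rank identity: with midranks `r`,
#' `AUC = (sum of positive-class ranks - n1 (n1 + 1) / 2) / (n1 n0)`.
#' Ties between a positive and a negative value count 1/2, so the result
#' equals the trapezoidal area under the empirical ROC curve and the
#' probability that a random positive exceeds a random negative.
#'
#' @param x numeric covariate values (e.g. one gene's expression).
#' @param z binary labels, see [as_binary_labels()].
#' @return AUC in [0, 1].
#' @examples
#' gene_auc(c(1, 2, 3, 4), c(0, 0, 1, 1))  # 1: perfect separation
#' gene_auc(c(1, 3, 2, 4), c(0, 0, 1, 1))  # 0.75
#' @export
gene_auc <- function(x, z) {
  z <- as_binary_labels(z)
  if (length(x) != length(z)) stop("x and z must have the same length")
  if (!all(is.finite(x))) stop("x must be finite")
  .check_two_classes(z)
  n1 <- sum(z == 1L)
  n0 <- sum(z == 0L)
  r <- rank(x, ties.method = "average")
  (sum(r[z == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

# Vectorized per-row AUC for a genes x samples matrix; same rank identity.
.auc_matrix <- function(m, z) {
  n1 <- sum(z == 1L)
  n0 <- sum(z == 0L)
  pos <- z == 1L
  rk <- t(apply(m, 1L, rank, ties.method = "average"))
  if (nrow(m) == 1L) rk <- matrix(rk, nrow = 1L)
  aucs <- (rowSums(rk[, pos, drop = FALSE]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  names(aucs) <- rownames(m)
  aucs
}

#' Orient an AUC value to the [0.5, 1] performance scale
#'
#' A covariate negatively associated with the class (AUC < 0.5) becomes
#' informative after negation, which maps AUC to 1 - AUC. The oriented AUC
#' `max(AUC, 1 - AUC)` is therefore the covariate's performance, and the sign
#' records whether negation was needed. An AUC of exactly 0.5 keeps sign +1.
#'
#' @param auc AUC value(s) in [0, 1].
#' @return list with `oriented_auc` and `sign` (-1 or +1), vectorized.
#' @export
orient_auc <- function(auc) {
  if (any(auc < 0 | auc > 1)) stop("auc must lie in [0, 1]")
  sign <- ifelse(auc < 0.5, -1, 1)
  list(oriented_auc = pmax(auc, 1 - auc), sign = sign)
}

#' Rank all genes by oriented AUC
#'
#' Computes each gene's AUC against the phenotype, orients it, and sorts by
#' oriented AUC descending. Ties in oriented AUC are broken by gene id
#' (C-locale lexicographic), so the ranking does not depend on input row
#' order.
#'
#' @param m expression matrix, genes x samples, unique gene ids.
#' @param z binary labels aligned to the columns of `m`.
#' @return data.frame with columns `gene_id`, `auc`, `oriented_auc`, `sign`,
#'   `rank`, ordered by rank.
#' @export
rank_genes <- function(m, z) {
  if (is.null(rownames(m)) || anyDuplicated(rownames(m))) {
    stop("gene ids must be unique; run merge_duplicate_genes() first")
  }
  z <- as_binary_labels(z, colnames(m))
  .check_two_classes(z)
  aucs <- .auc_matrix(m, z)
  o <- orient_auc(aucs)
  ord <- order(-o$oriented_auc, rownames(m), method = "radix")
  data.frame(gene_id = rownames(m)[ord],
             auc = unname(aucs[ord]),
             oriented_auc = unname(o$oriented_auc[ord]),
             sign = unname(o$sign[ord]),
             rank = seq_len(nrow(m)),
             stringsAsFactors = FALSE)
}

#' Take the top genes of an AUC ranking
#'
#' @param ranking a ranking from [rank_genes()].
#' @param xgenes signature size, between 1 and the number of ranked genes.
#' @return the first `xgenes` rows of the ranking, order preserved.
#' @export
top_signature <- function(ranking, xgenes) {
  if (length(xgenes) != 1L || is.na(xgenes) || xgenes < 1L ||
      xgenes > nrow(ranking)) {
    stop("xgenes must be a single value between 1 and ", nrow(ranking))
  }
  ranking[seq_len(xgenes), , drop = FALSE]
}

#' Export a gene ranking as TSV
#' @param ranking a ranking from [rank_genes()].
#' @param path output path.
#' @param header_lines optional `#` comment lines.
#' @export
write_ranking <- function(ranking, path, header_lines = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (length(header_lines)) writeLines(paste0("# ", header_lines), con)
  utils::write.table(ranking, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
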