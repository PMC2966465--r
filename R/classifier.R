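#' Average sign-corrected gene expression into a metagene
#'
#' The metagene value of a sample is the arithmetic mean of the signature
#' genes' expression after multiplying genes negatively associated with the
#' phenotype (sign -1) by -1.
#'
#' @param m expression matrix containing at least the signature genes.
#' @param genes character vector of signature gene ids.
#' @param signs numeric vector of -1/+1, one per gene.
#' @return named numeric vector, one metagene value per sample.
#' @export
build_metagene <- function(m, genes, signs) {
  if (length(genes) != length(signs) || length(genes) == 0L) {
    stop("genes and signs must be non-empty and of equal length")
  }
  if (!all(signs %in% c(-1, 1))) stop("signs must be -1 or +1")
  missing <- setdiff(genes, rownames(m))
  if (length(missing)) {
    stop("gene(s) absent from the expression matrix: ",
         paste(missing, collapse = ", "))
  }
  colMeans(m[genes, , drop = FALSE] * signs)
}

#' Fit the metagene decision threshold on training data
#'
#' Scans every achievable split of the samples ordered by metagene value and
#' picks the threshold with the highest training accuracy (plain fraction of
#' correct assignments), placing the threshold at the midpoint of the two
#' border samples. Samples strictly above the threshold are predicted class 1.
#'
#' Ties in accuracy are resolved deterministically: highest sensitivity
#' first, then the largest threshold. When the best split leaves all samples
#' on one side, the threshold is set just beyond the extreme value (offset by
#' half the smallest positive gap between metagene values, or 1 if all values
#' are equal) so it stays finite.
#'
#' @param metagene per-sample metagene values.
#' @param z binary labels.
#' @return list with `threshold`, `accuracy` (training, unbalanced),
#'   `sensitivity` and `specificity` at the chosen threshold.
#' @export
fit_threshold <- function(metagene, z) {
  z <- as_binary_labels(z, names(metagene))
  if (length(metagene) != length(z)) {
    stop("metagene and labels must have the same length")
  }
  .check_two_classes(z)
  u <- sort(unique(metagene))
  gaps <- diff(u)
  delta <- if (length(gaps) && any(gaps > 0)) min(gaps[gaps > 0]) / 2 else 1
  cand <- c(u[1L] - delta,
            if (length(u) > 1L) (u[-length(u)] + u[-1L]) / 2,
            u[length(u)] + delta)
  pred <- outer(metagene, cand, ">")           # n x n_candidates
  correct <- pred == (z == 1L)
  acc <- colMeans(correct)
  sens <- colMeans(pred[z == 1L, , drop = FALSE])
  spec <- colMeans(!pred[z == 0L, , drop = FALSE])
  best <- which(acc == max(acc))
  best <- best[sens[best] == max(sens[best])]
  best <- best[which.max(cand[best])]
  list(threshold = cand[best],
       accuracy = acc[best],
       sensitivity = sens[best],
       specificity = spec[best])
}

#' Train the univariate gene-expression-average classifier
#'
#' Ranks all genes by oriented AUC, keeps the top `xgenes`, builds the
#' sign-corrected metagene on the training samples and fits the decision
#' threshold that maximizes training accuracy.
#'
#' @param m training expression matrix, genes x samples, unique gene ids.
#' @param z binary labels aligned to the columns of `m`.
#' @param xgenes number of genes in the signature (default 200).
#' @return object of class `metagene_model` with elements `genes` (ordered by
#'   rank), `signs`, `threshold` and `trained_on` (sample counts and training
#'   accuracy).
#' @seealso [predict.metagene_model()], [write_model()]
#' @export
train_metagene <- function(m, z, xgenes = 200L) {
  z <- as_binary_labels(z, colnames(m))
  counts <- .check_two_classes(z)
  sig <- top_signature(rank_genes(m, z), xgenes)
  mg <- build_metagene(m, sig$gene_id, sig$sign)
  fit <- fit_threshold(mg, z)
  structure(list(genes = sig$gene_id,
                 signs = sig$sign,
                 threshold = fit$threshold,
                 trained_on = list(n_samples = length(z),
                                   n_pos = unname(counts["n1"]),
                                   n_neg = unname(counts["n0"]),
                                   training_accuracy = fit$accuracy)),
            class = "metagene_model")
}

#' Classify samples with a trained metagene model
#'
#' Computes each sample's metagene value from the model's genes and signs and
#' calls class 1 when it exceeds the model threshold (exact equality is
#' class 0). In `"strict"` mode (default) every model gene must be present in
#' the new data; `"intersect"` mode drops absent genes with a warning and
#' re-averages over the remaining ones, for transfer across platforms with
#' partial gene overlap.
#'
#' @param object a `metagene_model`.
#' @param newdata expression matrix, genes x samples.
#' @param mode `"strict"` or `"intersect"`.
#' @param ... unused.
#' @return data.frame with columns `sample_id`, `metagene`, `class`.
#' @export
predict.metagene_model <- function(object, newdata,
                                   mode = c("strict", "intersect"), ...) {
  mode <- match.arg(mode)
  present <- object$genes %in% rownames(newdata)
  genes <- object$genes
  signs <- object$signs
  if (!all(present)) {
    if (mode == "strict") {
      stop("gene(s) absent from new data: ",
           paste(genes[!present], collapse = ", "),
           " (use mode = \"intersect\" to drop them)")
    }
    if (!any(present)) stop("no model gene present in the new data")
    warning(sum(!present), " model gene(s) absent from new data; ",
            "re-averaging over the ", sum(present), " present")
    genes <- genes[present]
    signs <- signs[present]
  }
  mg <- build_metagene(newdata, genes, signs)
  data.frame(sample_id = colnames(newdata),
             metagene = unname(mg),
             class = as.integer(mg > object$threshold),
             stringsAsFactors = FALSE)
}

#' @export
print.metagene_model <- function(x, ...) {
  cat("Metagene classifier\n")
  cat("  signature genes :", length(x$genes), "\n")
  cat("  sign -1 genes   :", sum(x$signs == -1), "\n")
  cat("  threshold       :", format(x$threshold), "\n")
  cat(sprintf("  trained on      : %d samples (%d pos / %d neg), accuracy %.3f\n",
              x$trained_on$n_samples, x$trained_on$n_pos, x$trained_on$n_neg,
              x$trained_on$training_accuracy))
  invisible(x)
}
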