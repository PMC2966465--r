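#' Confusion counts for binary predictions
#'
#' @param truth true 0/1 labels.
#' @param pred predicted 0/1 labels.
#' @return object of class `confusion_counts`: list with `tp`, `fp`, `tn`,
#'   `fn`.
#' @export
confusion_counts <- function(truth, pred) {
  truth <- as_binary_labels(truth)
  pred <- as_binary_labels(pred)
  if (length(truth) != length(pred)) {
    stop("truth and pred must have the same length")
  }
  structure(list(tp = sum(truth == 1L & pred == 1L),
                 fp = sum(truth == 0L & pred == 1L),
                 tn = sum(truth == 0L & pred == 0L),
                 fn = sum(truth == 1L & pred == 0L)),
            class = "confusion_counts")
}

#' Balanced accuracy
#'
#' `(sensitivity + specificity) / 2` with sensitivity `tp / (tp + fn)` and
#' specificity `tn / (tn + fp)`. Independent of class prevalence, unlike the
#' plain accuracy used to fit the threshold.
#'
#' @param x a `confusion_counts` object, or a vector of true labels (then
#'   `pred` must be given).
#' @param pred predicted labels when `x` is the truth vector.
#' @return balanced accuracy in [0, 1].
#' @export
balanced_accuracy <- function(x, pred = NULL) {
  cc <- if (inherits(x, "confusion_counts")) x else confusion_counts(x, pred)
  if (cc$tp + cc$fn == 0L) stop("no positive samples in truth")
  if (cc$tn + cc$fp == 0L) stop("no negative samples in truth")
  sens <- cc$tp / (cc$tp + cc$fn)
  spec <- cc$tn / (cc$tn + cc$fp)
  (sens + spec) / 2
}

# Validate a vector of signature sizes against the gene count.
.check_sizes <- function(xgenes, n_genes) {
  xgenes <- as.integer(xgenes)
  if (length(xgenes) == 0L) stop("signature size grid is empty")
  if (anyNA(xgenes) || any(xgenes < 1L) || any(xgenes > n_genes)) {
    stop("signature sizes must lie between 1 and ", n_genes)
  }
  xgenes
}

#' Leave-one-out cross-validation with in-fold feature selection
#'
#' For each held-out sample, the gene ranking, signature signs and decision
#' threshold are all re-derived on the remaining n - 1 samples only; the
#' held-out sample is then classified. Held-out predictions are pooled into
#' one global confusion table per signature size, from which the balanced
#' accuracy is computed. Nothing from a held-out sample ever enters its own
#' fold's feature selection or threshold fit.
#'
#' @param m expression matrix, genes x samples, unique gene ids.
#' @param z binary labels; each class needs at least 2 members so every fold
#'   retains both classes.
#' @param xgenes vector of signature sizes to evaluate.
#' @return object of class `cv_report`: list with `summary` (data.frame of
#'   `xgenes`, `tp`, `fp`, `tn`, `fn`, `sensitivity`, `specificity`,
#'   `balanced_accuracy`), `predictions` (samples x sizes matrix of held-out
#'   calls) and `truth`.
#' @export
loocv <- function(m, z, xgenes = 200L) {
  if (is.null(rownames(m)) || anyDuplicated(rownames(m))) {
    stop("gene ids must be unique; run merge_duplicate_genes() first")
  }
  z <- as_binary_labels(z, colnames(m))
  n <- length(z)
  if (n < 3L) stop("LOOCV needs at least 3 samples")
  .check_two_classes(z, min_per_class = 2L)
  xgenes <- .check_sizes(xgenes, nrow(m))
  K <- max(xgenes)
  preds <- matrix(NA_integer_, n, length(xgenes),
                  dimnames = list(colnames(m), as.character(xgenes)))
  for (i in seq_len(n)) {
    ztr <- z[-i]
    rk <- rank_genes(m[, -i, drop = FALSE], ztr)
    top <- rk[seq_len(K), ]
    s <- m[top$gene_id, , drop = FALSE] * top$sign
    cs_tr <- apply(s[, -i, drop = FALSE], 2L, cumsum)
    if (K == 1L) cs_tr <- matrix(cs_tr, nrow = 1L)
    cs_ho <- cumsum(s[, i])
    for (j in seq_along(xgenes)) {
      k <- xgenes[j]
      fit <- fit_threshold(cs_tr[k, ] / k, ztr)
      preds[i, j] <- as.integer(cs_ho[k] / k > fit$threshold)
    }
  }
  summ <- do.call(rbind, lapply(seq_along(xgenes), function(j) {
    cc <- confusion_counts(z, preds[, j])
    data.frame(xgenes = xgenes[j], tp = cc$tp, fp = cc$fp, tn = cc$tn,
               fn = cc$fn,
               sensitivity = cc$tp / (cc$tp + cc$fn),
               specificity = cc$tn / (cc$tn + cc$fp),
               balanced_accuracy = balanced_accuracy(cc))
  }))
  structure(list(summary = summ, predictions = preds, truth = z),
            class = "cv_report")
}

#' @export
print.cv_report <- function(x, ...) {
  cat("LOOCV report (", nrow(x$predictions), " samples, pooled confusion)\n",
      sep = "")
  print(x$summary, row.names = FALSE)
  invisible(x)
}

#' Balanced accuracy across a grid of signature sizes
#'
#' Runs [loocv()] over an increasing grid of signature sizes (the classic
#' sweep is 5 to 500 in steps of 5) to trace the accuracy-versus-size curve.
#'
#' @param m expression matrix.
#' @param z binary labels.
#' @param sizes vector of signature sizes, e.g. `seq(5, 500, by = 5)`.
#' @return a `cv_report` whose summary has one row per size.
#' @export
signature_sweep <- function(m, z, sizes = seq(5L, 500L, by = 5L)) {
  loocv(m, z, xgenes = sizes)
}

#' Step-to-step changes of an accuracy-versus-size curve
#'
#' `delta_i = acc_{i+1} - acc_i`; small deltas at large sizes indicate the
#' signature has become robust to its exact composition.
#'
#' @param curve numeric vector of balanced accuracies (ordered by size), or a
#'   `cv_report`.
#' @return numeric vector of length `length(curve) - 1`.
#' @export
accuracy_deltas <- function(curve) {
  if (inherits(curve, "cv_report")) curve <- curve$summary$balanced_accuracy
  if (length(curve) < 2L) stop("need at least 2 points to form deltas")
  diff(curve)
}

#' Gene-transfer validation of a signature on independent data
#'
#' Only the gene identities are carried over from training: within each
#' leave-one-out fold of the validation cohort, the per-gene AUC orientation
#' (signs) and the metagene threshold are re-derived on that fold's n - 1
#' samples, then the held-out sample is classified. This mimics moving a
#' signature to a platform where the training AUCs and threshold are not
#' transferable. Signature genes absent from the validation data are dropped
#' with a warning and recorded.
#'
#' @param genes character vector of signature gene ids (training order).
#' @param m_val validation expression matrix.
#' @param z_val validation labels; each class needs >= 2 members.
#' @return object of class `validation_report`: list with `genes_requested`,
#'   `genes_used`, `dropped`, `thresholds` (per fold), `predictions`,
#'   `confusion` and `balanced_accuracy`.
#' @export
external_validate <- function(genes, m_val, z_val) {
  if (is.null(rownames(m_val)) || anyDuplicated(rownames(m_val))) {
    stop("gene ids must be unique; run merge_duplicate_genes() first")
  }
  z <- as_binary_labels(z_val, colnames(m_val))
  used <- genes[genes %in% rownames(m_val)]
  dropped <- setdiff(genes, used)
  if (length(used) == 0L) stop("no signature gene present in validation data")
  if (length(dropped)) {
    warning(length(dropped), " signature gene(s) absent from validation data; ",
            "proceeding on the ", length(used), " present")
  }
  n <- length(z)
  if (n < 3L) stop("validation LOOCV needs at least 3 samples")
  .check_two_classes(z, min_per_class = 2L)
  sub <- m_val[used, , drop = FALSE]
  preds <- integer(n)
  thresholds <- numeric(n)
  for (i in seq_len(n)) {
    ztr <- z[-i]
    aucs <- .auc_matrix(sub[, -i, drop = FALSE], ztr)
    signs <- orient_auc(aucs)$sign
    mg_tr <- colMeans(sub[, -i, drop = FALSE] * signs)
    fit <- fit_threshold(mg_tr, ztr)
    thresholds[i] <- fit$threshold
    preds[i] <- as.integer(mean(sub[, i] * signs) > fit$threshold)
  }
  cc <- confusion_counts(z, preds)
  structure(list(genes_requested = genes,
                 genes_used = used,
                 dropped = dropped,
                 thresholds = thresholds,
                 predictions = stats::setNames(preds, colnames(m_val)),
                 confusion = cc,
                 balanced_accuracy = balanced_accuracy(cc)),
            class = "validation_report")
}

#' @export
print.validation_report <- function(x, ...) {
  cat("Gene-transfer validation\n")
  cat("  signature genes :", length(x$genes_requested),
      "(", length(x$genes_used), "found in validation data )\n")
  cat(sprintf("  balanced accuracy: %.3f (tp %d, fp %d, tn %d, fn %d)\n",
              x$balanced_accuracy, x$confusion$tp, x$confusion$fp,
              x$confusion$tn, x$confusion$fn))
  invisible(x)
}
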