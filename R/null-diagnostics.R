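#' Randomize an expression matrix gene-wise
#'
#' Replaces every gene's values with independent Gaussian draws matching that
#' gene's observed mean and standard deviation (or, with
#' `per_gene = FALSE`, the whole matrix's mean and SD). This destroys any
#' association with the phenotype while preserving the per-gene marginal
#' scale, giving the null reference against which observed AUC values are
#' judged. A zero-SD gene becomes a constant row at its mean.
#'
#' @param m expression matrix without missing values.
#' @param seed optional integer; when given, `set.seed(seed)` is called so
#'   the randomization is reproducible.
#' @param per_gene use each gene's own mean/SD (default) or global moments.
#' @return matrix of the same shape and dimnames.
#' @export
randomize_dataset <- function(m, seed = NULL, per_gene = TRUE) {
  if (anyNA(m)) stop("impute missing values before randomization")
  if (!is.null(seed)) set.seed(seed)
  n <- ncol(m)
  if (per_gene) {
    mu <- rowMeans(m)
    sdv <- apply(m, 1L, stats::sd)
    out <- matrix(stats::rnorm(length(m), mean = rep(mu, times = n),
                               sd = rep(sdv, times = n)),
                  nrow = nrow(m), ncol = n)
  } else {
    out <- matrix(stats::rnorm(length(m), mean = mean(m), sd = stats::sd(as.vector(m))),
                  nrow = nrow(m), ncol = n)
  }
  dimnames(out) <- dimnames(m)
  out
}

#' Empirical null interval of per-gene AUC values
#'
#' Computes per-gene AUCs on (randomized) data and returns the central
#' interval containing `coverage` of them — the envelope outside which an
#' observed AUC is considered informative. With 10,000 null genes and a
#' balanced 56-sample design the 99% interval is approximately [0.30, 0.70].
#'
#' @param m expression matrix, typically from [randomize_dataset()].
#' @param z binary labels.
#' @param coverage central probability mass of the interval (default 0.99).
#' @return object of class `null_auc`: list with `coverage`, `lower`,
#'   `upper`, `n_genes` and the per-gene `aucs`.
#' @export
null_auc_interval <- function(m, z, coverage = 0.99) {
  if (coverage <= 0 || coverage > 1) stop("coverage must lie in (0, 1]")
  z <- as_binary_labels(z, colnames(m))
  .check_two_classes(z)
  if (nrow(m) < 100L) {
    warning("fewer than 100 genes; interval quantiles will be unstable")
  }
  aucs <- .auc_matrix(m, z)
  alpha <- 1 - coverage
  q <- unname(stats::quantile(aucs, c(alpha / 2, 1 - alpha / 2)))
  structure(list(coverage = coverage, lower = q[1L], upper = q[2L],
                 n_genes = nrow(m), aucs = aucs),
            class = "null_auc")
}

#' @export
print.null_auc <- function(x, ...) {
  cat(sprintf("Null AUC interval: [%.3f, %.3f] at %.0f%% coverage (%d genes)\n",
              x$lower, x$upper, 100 * x$coverage, x$n_genes))
  invisible(x)
}

#' Fraction of genes outside a null AUC envelope
#'
#' By construction `1 - coverage` of null genes fall outside the envelope;
#' the excess beyond that false-discovery share estimates the fraction of
#' genuinely informative genes, and hence bounds the useful signature size.
#'
#' @param aucs per-gene AUC values.
#' @param nd a `null_auc` envelope.
#' @return list with `fraction_outside` and `excess`
#'   (`max(0, fraction_outside - (1 - coverage))`).
#' @export
informative_fraction <- function(aucs, nd) {
  if (length(aucs) == 0L) stop("aucs is empty")
  stopifnot(inherits(nd, "null_auc"))
  fo <- mean(aucs < nd$lower | aucs > nd$upper)
  list(fraction_outside = fo,
       excess = max(0, fo - (1 - nd$coverage)))
}

#' Concordance of per-gene AUC values between two datasets
#'
#' For genes shared by two cohorts (same set, same order), reports the
#' Pearson correlation of their AUC vectors and classifies each gene by its
#' position relative to each cohort's null envelope: `concordant_high`
#' (above the upper bound in both), `concordant_low` (below the lower bound
#' in both), `discordant` (outside in both but in opposite directions, or
#' outside in exactly one), `uninformative` (inside both envelopes).
#'
#' @param aucs_a,aucs_b per-gene AUCs on the shared genes, same order.
#' @param nd_a,nd_b `null_auc` envelopes for the two datasets.
#' @return list with `pearson_r` and `category` (factor per gene).
#' @export
auc_concordance <- function(aucs_a, aucs_b, nd_a, nd_b) {
  if (length(aucs_a) != length(aucs_b)) {
    stop("AUC vectors must cover the same genes in the same order")
  }
  if (length(aucs_a) < 3L) stop("need at least 3 shared genes")
  stopifnot(inherits(nd_a, "null_auc"), inherits(nd_b, "null_auc"))
  high_a <- aucs_a > nd_a$upper; low_a <- aucs_a < nd_a$lower
  high_b <- aucs_b > nd_b$upper; low_b <- aucs_b < nd_b$lower
  out_a <- high_a | low_a
  out_b <- high_b | low_b
  category <- rep("uninformative", length(aucs_a))
  category[out_a | out_b] <- "discordant"
  category[high_a & high_b] <- "concordant_high"
  category[low_a & low_b] <- "concordant_low"
  list(pearson_r = stats::cor(aucs_a, aucs_b),
       category = factor(category, levels = c("concordant_high",
                                              "concordant_low",
                                              "discordant",
                                              "uninformative")))
}

#' Normality and variance profile per gene
#'
#' For each gene, the Shapiro-Wilk normality p-value (reported as -log10 p)
#' and the sample standard deviation, optionally grouped by supplied gene
#' categories (e.g. the concordance classes) for side-by-side comparison.
#' Shapiro-Wilk is applied to at most 5000 values per gene (an evenly spaced
#' subsample beyond that); constant genes have no defined p-value and are
#' reported as `NA`.
#'
#' @param m expression matrix with >= 3 samples.
#' @param gene_groups optional vector of group labels, one per gene.
#' @return data.frame with `gene_id`, `group`, `shapiro_neglog10_p`, `sd`.
#' @export
normality_variance_profile <- function(m, gene_groups = NULL) {
  if (ncol(m) < 3L) stop("Shapiro-Wilk needs at least 3 samples per gene")
  if (!is.null(gene_groups) && length(gene_groups) != nrow(m)) {
    stop("gene_groups must have one entry per gene")
  }
  idx <- if (ncol(m) > 5000L) {
    unique(round(seq(1L, ncol(m), length.out = 5000L)))
  } else {
    seq_len(ncol(m))
  }
  neglog <- apply(m, 1L, function(x) {
    x <- x[idx]
    if (stats::sd(x) == 0) return(NA_real_)
    -log10(stats::shapiro.test(x)$p.value)
  })
  data.frame(gene_id = if (is.null(rownames(m))) seq_len(nrow(m)) else rownames(m),
             group = if (is.null(gene_groups)) NA_character_ else as.character(gene_groups),
             shapiro_neglog10_p = unname(neglog),
             sd = unname(apply(m, 1L, stats::sd)),
             stringsAsFactors = FALSE)
}
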