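#' Specification of a synthetic two-class expression dataset
#'
#' Defines the generative model used throughout the package's tests and
#' examples: log-scale expression is Gaussian per gene; a subset of
#' "informative" genes has its class-1 mean shifted by
#' `effect_size * within_class_sd`, a fraction of them in the downward
#' direction; an optional shared latent factor induces equicorrelation
#' within the informative block (mimicking co-regulated genes, which is what
#' makes metagene averaging pay off).
#'
#' Defaults describe a cohort-sized two-class study: 2000 genes, 30 samples
#' per class, 50 informative genes with a 1.5-SD shift, half of them
#' down-regulated, unit within-class SD, no correlation.
#'
#' @param n_genes total number of genes.
#' @param n_pos,n_neg samples in class 1 / class 0.
#' @param n_informative number of genes with a planted class shift.
#' @param effect_size class-1 mean shift in units of `within_class_sd`.
#' @param within_class_sd per-gene within-class standard deviation.
#' @param gene_correlation equicorrelation in [0, 1) within the informative
#'   block, induced by one latent factor per sample.
#' @param flip_fraction fraction of informative genes shifted downward in
#'   class 1.
#' @param seed RNG seed; the generator is deterministic given these settings.
#' @return object of class `synth_spec`.
#' @export
synth_spec <- function(n_genes = 2000L, n_pos = 30L, n_neg = 30L,
                       n_informative = 50L, effect_size = 1.5,
                       within_class_sd = 1, gene_correlation = 0,
                       flip_fraction = 0.5, seed = 1L) {
  if (n_informative > n_genes) stop("n_informative must be <= n_genes")
  if (any(c(n_genes, n_pos, n_neg, n_informative) < 0)) {
    stop("counts must be non-negative")
  }
  if (gene_correlation < 0 || gene_correlation >= 1) {
    stop("gene_correlation must lie in [0, 1)")
  }
  if (within_class_sd <= 0) stop("within_class_sd must be positive")
  if (flip_fraction < 0 || flip_fraction > 1) {
    stop("flip_fraction must lie in [0, 1]")
  }
  structure(list(n_genes = as.integer(n_genes), n_pos = as.integer(n_pos),
                 n_neg = as.integer(n_neg),
                 n_informative = as.integer(n_informative),
                 effect_size = effect_size,
                 within_class_sd = within_class_sd,
                 gene_correlation = gene_correlation,
                 flip_fraction = flip_fraction, seed = as.integer(seed)),
            class = "synth_spec")
}

# Draw one matrix from the generative model; assumes the RNG state is set and
# the informative gene indices / directions are fixed.
.draw_matrix <- function(spec, info_idx, directions, z) {
  n <- length(z)
  sdv <- spec$within_class_sd
  rho <- spec$gene_correlation
  m <- matrix(stats::rnorm(spec$n_genes * n, sd = sdv), spec$n_genes, n)
  if (length(info_idx) && rho > 0) {
    f <- stats::rnorm(n)   # latent factor shared by the informative block
    load <- directions * sqrt(rho)
    m[info_idx, ] <- sqrt(1 - rho) * m[info_idx, , drop = FALSE] +
      sdv * outer(load, f)
  }
  if (length(info_idx)) {
    shift <- directions * spec$effect_size * sdv
    m[info_idx, z == 1L] <- m[info_idx, z == 1L, drop = FALSE] + shift
  }
  dimnames(m) <- list(sprintf("g%04d", seq_len(spec$n_genes)), names(z))
  m
}

.synth_labels <- function(spec) {
  z <- rep(c(0L, 1L), c(spec$n_neg, spec$n_pos))
  names(z) <- sprintf("s%03d", seq_along(z))
  z
}

.plant_truth <- function(spec) {
  info_idx <- sort(sample.int(spec$n_genes, spec$n_informative))
  directions <- rep(1, spec$n_informative)
  n_flip <- round(spec$flip_fraction * spec$n_informative)
  if (n_flip > 0L) directions[sample.int(spec$n_informative, n_flip)] <- -1
  list(idx = info_idx, directions = directions)
}

#' Generate a two-class expression dataset with planted signal
#'
#' @param spec a [synth_spec()].
#' @return list with `expr` (genes x samples matrix), `labels` (named 0/1
#'   vector) and `truth` (data.frame of informative `gene_id` and
#'   `direction` +1/-1, the planted ground truth).
#' @export
simulate_two_class <- function(spec) {
  stopifnot(inherits(spec, "synth_spec"))
  set.seed(spec$seed)
  z <- .synth_labels(spec)
  truth <- .plant_truth(spec)
  m <- .draw_matrix(spec, truth$idx, truth$directions, z)
  list(expr = m, labels = z,
       truth = data.frame(gene_id = rownames(m)[truth$idx],
                          direction = truth$directions,
                          stringsAsFactors = FALSE))
}

#' Generate a training/validation dataset pair from one generative model
#'
#' Both datasets share the informative genes and directions; the validation
#' dataset additionally receives an independent per-gene offset drawn from
#' `N(0, batch_shift^2)`, emulating the systematic per-gene shifts seen when
#' a signature moves to a different platform or cohort.
#'
#' @param spec a [synth_spec()].
#' @param batch_shift SD of the per-gene offset added to the validation data.
#' @return list with `train`, `validation` (each as in
#'   [simulate_two_class()]) and the shared `truth`.
#' @export
simulate_train_validation <- function(spec, batch_shift = 0) {
  stopifnot(inherits(spec, "synth_spec"))
  if (batch_shift < 0) stop("batch_shift must be non-negative")
  set.seed(spec$seed)
  z <- .synth_labels(spec)
  truth <- .plant_truth(spec)
  m_tr <- .draw_matrix(spec, truth$idx, truth$directions, z)
  m_val <- .draw_matrix(spec, truth$idx, truth$directions, z)
  if (batch_shift > 0) {
    m_val <- m_val + stats::rnorm(spec$n_genes, sd = batch_shift)
  }
  colnames(m_val) <- sub("^s", "v", colnames(m_val))
  z_val <- stats::setNames(z, colnames(m_val))
  truth_df <- data.frame(gene_id = rownames(m_tr)[truth$idx],
                         direction = truth$directions,
                         stringsAsFactors = FALSE)
  list(train = list(expr = m_tr, labels = z, truth = truth_df),
       validation = list(expr = m_val, labels = z_val, truth = truth_df),
       truth = truth_df)
}
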