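# Independent oracles and tiny fixtures shared across tests.

# AUC by explicit (positive, negative) pair counting, ties worth 1/2.
brute_auc <- function(x, z) {
  pos <- x[z == 1]
  neg <- x[z == 0]
  total <- 0
  for (p in pos) {
    for (q in neg) total <- total + (p > q) + 0.5 * (p == q)
  }
  total / (length(pos) * length(neg))
}

# Best achievable training accuracy of the rule "predict 1 iff v > t",
# found by direct evaluation at every achievable cut (just below the
# minimum, and at each observed value).
brute_best_accuracy <- function(v, z) {
  cand <- c(min(v) - 1, unique(v))
  max(vapply(cand, function(t) mean((v > t) == (z == 1)), numeric(1)))
}

# Deliberately leaky LOOCV: feature selection on ALL samples (held-out one
# included), only the threshold is refit per fold. Used as the positive
# control that the honest loocv() guards against selection bias.
leaky_loocv_ba <- function(m, z, xgenes) {
  sig <- top_signature(rank_genes(m, z), xgenes)
  n <- ncol(m)
  preds <- integer(n)
  for (i in seq_len(n)) {
    mg_tr <- build_metagene(m[, -i, drop = FALSE], sig$gene_id, sig$sign)
    fit <- fit_threshold(mg_tr, z[-i])
    mg_i <- build_metagene(m[, i, drop = FALSE], sig$gene_id, sig$sign)
    preds[i] <- as.integer(mg_i > fit$threshold)
  }
  balanced_accuracy(confusion_counts(z, preds))
}

# 4-sample toy with two perfectly anti-correlated genes: the metagene is
# [-1.5, -0.5, 0.5, 1.5] with threshold 0 separating z = [0,0,1,1].
toy4 <- function() {
  m <- rbind(g1 = c(1, 2, 3, 4), g2 = c(4, 3, 2, 1))
  colnames(m) <- paste0("s", 1:4)
  list(m = m, z = c(s1 = 0, s2 = 0, s3 = 1, s4 = 1))
}

# random two-class instance for property loops; may contain ties
random_instance <- function(n_max = 30, ties = TRUE) {
  n <- sample(4:n_max, 1)
  z <- integer(n)
  # force both classes present
  z[sample(n, sample(seq_len(n - 1), 1))] <- 1L
  x <- if (ties && runif(1) < 0.5) sample(1:5, n, replace = TRUE) else rnorm(n)
  list(x = as.numeric(x), z = z)
}
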