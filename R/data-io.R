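#' Read a gene-expression matrix from delimited text
#'
#' Expects genes as rows and samples as columns: the first column holds gene
#' identifiers and the header row holds sample identifiers. Empty cells and
#' the literal "NA" are parsed as missing values. Lines starting with `#` are
#' treated as comments (outputs of the command-line tools embed their run
#' configuration this way).
#'
#' Duplicate gene identifiers are preserved on read — collapsing them is the
#' job of [merge_duplicate_genes()]. Duplicate sample identifiers are an
#' error.
#'
#' @param path path to the file.
#' @param dialect `"tsv"` (default) or `"csv"`.
#' @return numeric matrix (genes x samples) with gene ids as rownames and
#'   sample ids as colnames; may contain `NA` before imputation.
#' @seealso [merge_duplicate_genes()], [knn_impute()], [write_expression()]
#' @export
read_expression <- function(path, dialect = c("tsv", "csv")) {
  dialect <- match.arg(dialect)
  sep <- if (dialect == "tsv") "\t" else ","
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.table(path, header = TRUE, sep = sep, quote = "",
                          comment.char = "#", colClasses = "character",
                          check.names = FALSE, na.strings = c("", "NA"),
                          stringsAsFactors = FALSE)
  if (ncol(df) < 2L) stop("expected a gene id column plus at least one sample")
  sample_ids <- colnames(df)[-1L]
  if (anyDuplicated(sample_ids)) {
    stop("duplicate sample id(s) in header: ",
         paste(unique(sample_ids[duplicated(sample_ids)]), collapse = ", "))
  }
  gene_ids <- df[[1L]]
  vals <- as.matrix(df[, -1L, drop = FALSE])
  num <- suppressWarnings(array(as.numeric(vals), dim = dim(vals)))
  bad <- which(is.na(num) & !is.na(vals), arr.ind = TRUE)
  if (nrow(bad) > 0L) {
    stop(sprintf("non-numeric value '%s' at gene '%s', sample '%s'",
                 vals[bad[1L, 1L], bad[1L, 2L]],
                 gene_ids[bad[1L, 1L]], sample_ids[bad[1L, 2L]]))
  }
  dimnames(num) <- list(gene_ids, sample_ids)
  num
}

#' Write a gene-expression matrix as tab-delimited text
#'
#' @param m numeric matrix, genes x samples, with dimnames.
#' @param path output path.
#' @param header_lines optional character vector written as leading `#`
#'   comment lines (used by the CLI to embed the run configuration).
#' @export
write_expression <- function(m, path, header_lines = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (length(header_lines)) {
    writeLines(paste0("# ", header_lines), con)
  }
  writeLines(paste(c("gene_id", colnames(m)), collapse = "\t"), con)
  utils::write.table(m, con, sep = "\t", quote = FALSE,
                     col.names = FALSE, row.names = TRUE)
  invisible(path)
}

#' Read binary phenotype labels from a two-column file
#'
#' The file has two tab-separated columns, sample id and label, where the
#' label is 0 or 1. A header line is detected (second field not 0/1) and
#' skipped. Single-class files are accepted at read time; training and
#' evaluation functions reject them.
#'
#' @param path path to the labels file.
#' @return named integer vector of 0/1 labels in file order.
#' @export
read_labels <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.table(path, header = FALSE, sep = "\t", quote = "",
                          comment.char = "#", colClasses = "character",
                          stringsAsFactors = FALSE)
  if (ncol(df) != 2L) stop("labels file must have exactly two columns")
  if (nrow(df) > 0L && !df[1L, 2L] %in% c("0", "1")) {
    df <- df[-1L, , drop = FALSE]   # header row
  }
  if (anyDuplicated(df[[1L]])) {
    stop("duplicate sample id(s) in labels file: ",
         paste(unique(df[[1L]][duplicated(df[[1L]])]), collapse = ", "))
  }
  z <- df[[2L]]
  names(z) <- df[[1L]]
  as_binary_labels(z)
}

#' Write labels as a two-column TSV
#' @param z named integer vector of 0/1 labels.
#' @param path output path.
#' @param header_lines optional `#` comment lines.
#' @export
write_labels <- function(z, path, header_lines = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (length(header_lines)) writeLines(paste0("# ", header_lines), con)
  writeLines("sample_id\tlabel", con)
  writeLines(paste(names(z), z, sep = "\t"), con)
  invisible(path)
}

#' Collapse duplicated gene identifiers by the element-wise median
#'
#' Rows sharing a gene identifier are merged into one row holding, per
#' sample, the median of the duplicated values. Unique rows pass through
#' unchanged. The first occurrence's position determines the merged row's
#' position, so the operation is idempotent and order-preserving.
#'
#' @param m expression matrix with gene ids as rownames.
#' @return matrix with one row per unique gene id.
#' @export
merge_duplicate_genes <- function(m) {
  ids <- rownames(m)
  if (is.null(ids)) stop("expression matrix must have gene ids as rownames")
  if (!anyDuplicated(ids)) return(m)
  keep <- unique(ids)
  out <- matrix(NA_real_, length(keep), ncol(m),
                dimnames = list(keep, colnames(m)))
  dup_ids <- unique(ids[duplicated(ids)])
  single <- setdiff(keep, dup_ids)
  out[single, ] <- m[match(single, ids), ]
  for (g in dup_ids) {
    out[g, ] <- apply(m[ids == g, , drop = FALSE], 2L, stats::median)
  }
  out
}

#' Impute missing values by k-nearest-neighbour averaging
#'
#' Genes missing more than `max_missing_frac` of their samples are dropped
#' first. Each remaining missing cell is filled with the mean, over the `k`
#' genes nearest to the target gene, of those genes' observed values at that
#' sample. Gene-gene distance is the mean squared difference over mutually
#' observed samples, so genes with different missingness patterns remain
#' comparable. Observed cells are never altered.
#'
#' @param m expression matrix, possibly containing `NA`.
#' @param k number of neighbour genes to average (default 10).
#' @param max_missing_frac genes with a larger missing fraction are removed
#'   (default 0.20).
#' @return matrix without missing values (possibly with fewer rows).
#' @export
knn_impute <- function(m, k = 10L, max_missing_frac = 0.20) {
  if (k < 1L) stop("k must be >= 1")
  miss_frac <- rowMeans(is.na(m))
  m <- m[miss_frac <= max_missing_frac, , drop = FALSE]
  if (!anyNA(m)) return(m)
  obs <- !is.na(m)
  target_rows <- which(rowSums(!obs) > 0L)
  for (g in target_rows) {
    for (s in which(!obs[g, ])) {
      cand <- which(obs[, s])
      cand <- cand[cand != g]
      if (length(cand) == 0L) {
        stop("no gene with an observed value at sample '", colnames(m)[s],
             "' to impute gene '", rownames(m)[g], "'")
      }
      shared <- obs[cand, , drop = FALSE] & rep(obs[g, ], each = length(cand))
      n_shared <- rowSums(shared)
      cand <- cand[n_shared > 0L]
      if (length(cand) == 0L) {
        stop("no candidate neighbour shares an observed sample with gene '",
             rownames(m)[g], "'")
      }
      diffs <- sweep(m[cand, , drop = FALSE], 2L, m[g, ], "-")^2
      d <- rowMeans(diffs, na.rm = TRUE)
      if (length(cand) < k) {
        warning("only ", length(cand), " neighbour(s) available for gene '",
                rownames(m)[g], "' at sample '", colnames(m)[s],
                "'; using all of them")
        nn <- cand
      } else {
        nn <- cand[order(d, cand)[seq_len(k)]]
      }
      m[g, s] <- mean(m[nn, s])
    }
  }
  m
}

#' Centre every gene at mean zero
#'
#' Subtracts each gene's mean expression across samples, the standard
#' per-dataset centring applied before cross-dataset gene transfer.
#'
#' @param m expression matrix without missing values.
#' @return matrix whose rows all have mean 0.
#' @export
mean_center <- function(m) {
  if (anyNA(m)) stop("impute missing values before centring")
  m - rowMeans(m)
}

#' Quantile-normalize samples to a common distribution
#'
#' Every column is mapped onto the element-wise mean of the per-column sorted
#' vectors; ties within a column receive the mean of the reference values at
#' their tied ranks. Delegates to [limma::normalizeQuantiles()].
#'
#' @param m expression matrix without missing values, >= 2 samples.
#' @return matrix with identically distributed columns.
#' @export
quantile_normalize <- function(m) {
  if (anyNA(m)) stop("impute missing values before quantile normalization")
  if (ncol(m) < 2L) stop("quantile normalization needs at least 2 samples")
  out <- limma::normalizeQuantiles(m, ties = TRUE)
  dimnames(out) <- dimnames(m)
  out
}

.MODEL_FORMAT_VERSION <- "1.0"

#' Serialize a trained metagene classifier to JSON
#'
#' @param model a `metagene_model` from [train_metagene()].
#' @param path output path.
#' @seealso [read_model()]
#' @export
write_model <- function(model, path) {
  stopifnot(inherits(model, "metagene_model"))
  obj <- list(
    format_version = .MODEL_FORMAT_VERSION,
    xgenes = length(model$genes),
    genes = model$genes,
    signs = model$signs,
    threshold = model$threshold,
    trained_on = model$trained_on
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a serialized metagene classifier
#'
#' Validates the format version, the sign vector (every entry -1 or +1), the
#' threshold, and internal consistency before returning the model.
#'
#' @param path path to a model JSON written by [write_model()].
#' @return a `metagene_model`.
#' @export
read_model <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(obj$format_version) || obj$format_version != .MODEL_FORMAT_VERSION) {
    stop("unsupported model format version: ",
         if (is.null(obj$format_version)) "<missing>" else obj$format_version)
  }
  if (is.null(obj$threshold) || !is.finite(obj$threshold)) {
    stop("model is missing a finite threshold")
  }
  if (length(obj$genes) == 0L || length(obj$genes) != length(obj$signs)) {
    stop("model genes and signs must be non-empty and of equal length")
  }
  if (!all(obj$signs %in% c(-1, 1))) {
    stop("model signs must all be -1 or +1")
  }
  structure(list(genes = as.character(obj$genes),
                 signs = as.numeric(obj$signs),
                 threshold = as.numeric(obj$threshold),
                 trained_on = obj$trained_on),
            class = "metagene_model")
}
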