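#' Coerce and validate binary phenotype labels
#'
#' Accepts a numeric, integer, character or factor vector of 0/1 labels and
#' returns a plain integer vector in \{0, 1\}. If `sample_ids` is supplied and
#' the labels are named, the labels are reordered to match; unnamed labels must
#' already be in matrix column order.
#'
#' @param z labels coded 0/1 (numeric, character, or a factor with levels
#'   "0"/"1"), optionally named by sample id.
#' @param sample_ids optional character vector of sample identifiers (usually
#'   `colnames()` of an expression matrix) to align against.
#' @return integer vector of 0/1, named when names were available.
#' @export
as_binary_labels <- function(z, sample_ids = NULL) {
  nm <- names(z)
  if (is.factor(z)) z <- as.character(z)
  if (is.character(z)) {
    bad <- !z %in% c("0", "1")
    if (any(bad)) {
      stop("labels must be 0 or 1; offending value(s): ",
           paste(unique(z[bad]), collapse = ", "))
    }
    z <- as.integer(z)
  }
  z <- as.numeric(z)
  if (anyNA(z) || any(z != 0 & z != 1)) {
    stop("labels must be 0 or 1")
  }
  z <- as.integer(z)
  names(z) <- nm
  if (!is.null(sample_ids)) {
    if (!is.null(nm)) {
      if (!setequal(nm, sample_ids) || anyDuplicated(nm)) {
        stop("label sample ids do not match the expression matrix columns")
      }
      z <- z[sample_ids]
    } else if (length(z) != length(sample_ids)) {
      stop("found ", length(z), " labels for ", length(sample_ids), " samples")
    } else {
      names(z) <- sample_ids
    }
  }
  z
}

# Both classes must be present (and optionally have >= min_per_class members)
# for any training or evaluation step.
.check_two_classes <- function(z, min_per_class = 1L) {
  n1 <- sum(z == 1L)
  n0 <- sum(z == 0L)
  if (n1 < min_per_class || n0 < min_per_class) {
    stop("both classes must have at least ", min_per_class,
         " sample(s); got ", n0, " in class 0 and ", n1, " in class 1")
  }
  invisible(c(n0 = n0, n1 = n1))
}
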