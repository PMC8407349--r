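# Internal helpers: seed plumbing, validation, TSV io conventions.

# Derive a reproducible child seed for an independent random layer.
# Layers get disjoint streams from one user-facing seed; arithmetic kept in
# doubles below 2^31 so set.seed() never overflows.
child_seed <- function(seed, layer) {
  offsets <- c(
    genes = 1, amplicon_bacteria = 2, amplicon_fungi = 3,
    metagenome = 4, mrna = 5, qpcr = 6
  )
  if (!layer %in% names(offsets)) {
    stop("unknown random layer: ", layer)
  }
  (abs(as.double(seed)) * 48271 + offsets[[layer]] * 65537) %% 2147483629
}

# Evaluate `expr` under `seed`, restoring the caller's RNG state afterwards.
with_local_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(expr)
}

assert_scalar_number <- function(x, name, min = -Inf, strict = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x)) {
    stop(name, " must be a single non-missing number")
  }
  if (strict && x <= min) stop(name, " must be > ", min)
  if (!strict && x < min) stop(name, " must be >= ", min)
  invisible(x)
}

# A count matrix: nonnegative integral values, unique feature/sample names.
validate_counts <- function(counts, what = "counts") {
  if (!is.matrix(counts) || !is.numeric(counts)) {
    stop(what, " must be a numeric matrix")
  }
  if (is.null(rownames(counts)) || is.null(colnames(counts))) {
    stop(what, " must carry feature rownames and sample colnames")
  }
  if (anyDuplicated(rownames(counts))) stop(what, ": duplicate feature ids")
  if (anyDuplicated(colnames(counts))) stop(what, ": duplicate sample ids")
  if (anyNA(counts)) stop(what, ": missing values not allowed")
  if (any(counts < 0)) stop(what, ": negative counts not allowed")
  if (any(abs(counts - round(counts)) > 1e-8)) {
    stop(what, ": counts must be integral")
  }
  invisible(counts)
}

#' Read and write feature-by-sample TSV tables
#'
#' Tables are written features-as-rows, samples-as-columns, with a header row
#' of sample identifiers and the feature identifier in the first column
#' (named `feature_id`). `read_count_matrix()` additionally validates that
#' the values are nonnegative integers.
#'
#' @param path File path.
#' @param x Numeric matrix with feature rownames and sample colnames.
#' @param digits Significant digits used when writing non-integer values;
#'   `NA` writes full precision.
#' @return `read_feature_matrix()` and `read_count_matrix()` return a numeric
#'   matrix with feature rownames and sample colnames; the writers return the
#'   path, invisibly.
#' @export
read_feature_matrix <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 2L) stop("feature table needs a feature_id column plus samples: ", path)
  m <- as.matrix(df[, -1L, drop = FALSE])
  if (!is.numeric(m)) stop("non-numeric values in feature table: ", path)
  rownames(m) <- as.character(df[[1L]])
  m
}

#' @rdname read_feature_matrix
#' @export
read_count_matrix <- function(path) {
  m <- read_feature_matrix(path)
  validate_counts(m, paste0("counts (", basename(path), ")"))
  m
}

#' @rdname read_feature_matrix
#' @export
write_feature_matrix <- function(x, path, digits = 6) {
  stopifnot(is.matrix(x))
  vals <- x
  if (!is.na(digits) && is.double(vals)) vals <- signif(vals, digits)
  df <- data.frame(feature_id = rownames(x), vals,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

write_tsv_table <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
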