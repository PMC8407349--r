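#' Abundance profiles
#'
#' An abundance profile is a feature-by-sample numeric matrix tagged with the
#' unit it carries (`"relative"`, `"marker_copies_per_ml"` or
#' `"genomes_per_ml"`) and the domain it covers (`"bacteria"`, `"fungi"` or
#' `"all"`). Relative profiles have columns that sum to one; samples whose
#' input column was all zero are carried through as all-zero columns and
#' recorded in the `empty_samples` attribute rather than dropped, so failed
#' libraries stay visible in a time course.
#'
#' @param values Numeric feature-by-sample matrix.
#' @param kind One of `"relative"`, `"marker_copies_per_ml"`,
#'   `"genomes_per_ml"`.
#' @param scope One of `"bacteria"`, `"fungi"`, `"all"`.
#' @param empty_samples Character vector of sample ids whose column is
#'   all-zero by construction.
#' @return A matrix of class `"abund_profile"` with attributes `kind`,
#'   `scope` and `empty_samples`.
#' @export
abund_profile <- function(values, kind, scope = "all",
                          empty_samples = character()) {
  kind <- match.arg(kind, c("relative", "marker_copies_per_ml", "genomes_per_ml"))
  scope <- match.arg(scope, c("all", "bacteria", "fungi"))
  stopifnot(is.matrix(values), is.numeric(values))
  if (anyNA(values) || any(values < 0)) {
    stop("abundance values must be nonnegative and non-missing")
  }
  if (kind == "relative") {
    cs <- colSums(values)
    nonempty <- !colnames(values) %in% empty_samples
    if (any(abs(cs[nonempty] - 1) > 1e-9)) {
      stop("relative abundance columns must sum to 1")
    }
  }
  structure(values,
    kind = kind, scope = scope, empty_samples = empty_samples,
    class = c("abund_profile", "matrix", "array")
  )
}

#' @export
print.abund_profile <- function(x, ...) {
  cat(sprintf(
    "<abund_profile> %d features x %d samples  [kind: %s, scope: %s]\n",
    nrow(x), ncol(x), attr(x, "kind"), attr(x, "scope")
  ))
  es <- attr(x, "empty_samples")
  if (length(es)) cat("  empty samples:", paste(es, collapse = ", "), "\n")
  print(unclass_profile(x)[seq_len(min(6L, nrow(x))),
                           seq_len(min(6L, ncol(x))), drop = FALSE], ...)
  invisible(x)
}

unclass_profile <- function(x) {
  attributes(x) <- attributes(x)[c("dim", "dimnames")]
  x
}

profile_kind <- function(x) attr(x, "kind")
profile_scope <- function(x) attr(x, "scope")

#' Expression matrices
#'
#' A gene-by-sample matrix of RPKM values (reads per kilobase of coding
#' sequence per million mapped reads). The object records whether spike-in
#' scale factors have been applied (`normalized`), the factors themselves,
#' and the reference sample they were computed against, so downstream steps
#' can refuse to normalize twice or to aggregate un-normalized values.
#'
#' @param values Numeric gene-by-sample matrix of RPKM values.
#' @param normalized Logical flag: have cross-sample scale factors been
#'   applied?
#' @param scale_factors Named per-sample positive factors (required when
#'   `normalized`).
#' @param reference_sample Sample id the factors are relative to.
#' @return A matrix of class `"expr_matrix"`.
#' @export
expr_matrix <- function(values, normalized = FALSE, scale_factors = NULL,
                        reference_sample = NULL) {
  stopifnot(is.matrix(values), is.numeric(values))
  if (anyNA(values) || any(values < 0)) {
    stop("RPKM values must be nonnegative and non-missing")
  }
  if (normalized) {
    if (is.null(scale_factors)) stop("normalized expression requires scale factors")
    if (any(scale_factors <= 0)) stop("scale factors must be positive")
    if (!setequal(names(scale_factors), colnames(values))) {
      stop("scale factors must be named by sample")
    }
  }
  structure(values,
    normalized = normalized,
    scale_factors = scale_factors,
    reference_sample = reference_sample,
    class = c("expr_matrix", "matrix", "array")
  )
}

#' @export
print.expr_matrix <- function(x, ...) {
  cat(sprintf(
    "<expr_matrix> %d genes x %d samples  [%s]\n",
    nrow(x), ncol(x),
    if (isTRUE(attr(x, "normalized"))) {
      paste0("spike-normalized, ref = ", attr(x, "reference_sample"))
    } else "raw RPKM"
  ))
  print(unclass_profile(x)[seq_len(min(6L, nrow(x))),
                           seq_len(min(6L, ncol(x))), drop = FALSE], ...)
  invisible(x)
}

is_normalized <- function(x) isTRUE(attr(x, "normalized"))
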