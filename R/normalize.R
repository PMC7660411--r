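#' Log2-transform an expression matrix
#'
#' Applies `log2(v + 1)` elementwise. The +1 pseudocount is the standard
#' convention for FPKM-like matrices, where exact zeros are common.
#'
#' @param x a [gem()] in `"raw"` state with non-negative values.
#' @return a `gem` in `"log2"` state.
#' @export
log2_transform <- function(x) {
  stopifnot(inherits(x, "gem"))
  if (x$norm_state != "raw") {
    stop(sprintf("log2_transform expects a 'raw' gem, got '%s'", x$norm_state),
         call. = FALSE)
  }
  if (any(x$values < 0)) stop("negative expression values", call. = FALSE)
  x$values <- log2(x$values + 1)
  x$norm_state <- "log2"
  x
}

#' Quantile-normalize an expression matrix
#'
#' Forces every sample to share the same value distribution: the reference
#' distribution is the across-sample mean of each sample's sorted values,
#' and each value is replaced by the reference value at its within-sample
#' rank. Tied values receive the mean of the reference values at the ranks
#' the tie group occupies.
#'
#' A single-gene matrix is returned unchanged (rank-1 everywhere is
#' degenerate), as is a single-sample matrix (its own distribution is the
#' reference).
#'
#' @param x a [gem()] in `"log2"` state.
#' @return a `gem` in `"quantile"` state.
#' @export
quantile_normalize <- function(x) {
  stopifnot(inherits(x, "gem"))
  if (!x$norm_state %in% c("log2", "quantile")) {
    stop(sprintf("quantile_normalize expects a 'log2' gem, got '%s'", x$norm_state),
         call. = FALSE)
  }
  v <- x$values
  if (ncol(v) > 1 && nrow(v) > 1) {
    sorted <- apply(v, 1, sort)            # genes x samples, each column sorted
    ref <- rowMeans(sorted)                # reference distribution, ascending
    x$values <- t(apply(v, 1, map_to_reference, ref = ref))
    dimnames(x$values) <- dimnames(v)
  }
  x$norm_state <- "quantile"
  x
}

# Substitute each value by the reference value at its rank, averaging the
# reference over the ranks occupied by a tie group.
map_to_reference <- function(row, ref) {
  o <- order(row)
  sorted <- row[o]
  grp <- cumsum(c(TRUE, sorted[-1] != sorted[-length(sorted)]))
  mapped <- stats::ave(ref, grp)
  out <- numeric(length(row))
  out[o] <- mapped
  out
}

#' Restrict a GEM to a gene set
#'
#' Keeps the genes of `genes` that are present in `x`, in the gene set's
#' order. Genes absent from the matrix are dropped with a warning reporting
#' how many were missing.
#'
#' @param x a [gem()] object.
#' @param genes a character vector of gene ids, or a one-row slice of the
#'   tibble returned by [read_gmt()].
#' @param set_name optional set name used in messages.
#' @return a `gem` restricted to the intersection.
#' @export
subset_genes <- function(x, genes, set_name = NULL) {
  stopifnot(inherits(x, "gem"))
  if (is.data.frame(genes)) {
    if (nrow(genes) != 1) stop("pass a single gene set (one row)", call. = FALSE)
    set_name <- set_name %||% genes$set[[1]]
    genes <- genes$genes[[1]]
  }
  genes <- as.character(genes)
  present <- genes[genes %in% gene_ids(x)]
  n_missing <- length(genes) - length(present)
  if (length(present) == 0) {
    stop(sprintf("gene set%s shares no genes with the matrix",
                 if (is.null(set_name)) "" else sprintf(" '%s'", set_name)),
         call. = FALSE)
  }
  if (n_missing > 0) {
    warning(sprintf("%d of %d gene(s) in the set are absent from the matrix and were dropped",
                    n_missing, length(genes)), call. = FALSE)
  }
  x$values <- x$values[, present, drop = FALSE]
  x
}

#' Per-gene min-max scaling to [0, 1]
#'
#' Fits a per-gene (per-feature) min-max scaler on `x` and applies it:
#' `v' = (v - min_g) / (max_g - min_g)`. Constant genes map to 0 rather than
#' being dropped, so gene indexing stays aligned with gene sets. The fitted
#' scaler can be applied to later samples with [minmax_apply()] and inverted
#' with [minmax_inverse()].
#'
#' @param x a [gem()] in `"quantile"` or `"log2"` state.
#' @return a list with elements `gem` (in `"minmax"` state) and `scaler`
#'   (class `minmax_scaler`: per-gene `min` and `max` vectors).
#' @export
minmax_fit_transform <- function(x) {
  stopifnot(inherits(x, "gem"))
  if (!x$norm_state %in% c("quantile", "log2")) {
    stop(sprintf("minmax_fit_transform expects a 'quantile' or 'log2' gem, got '%s'",
                 x$norm_state), call. = FALSE)
  }
  mins <- apply(x$values, 2, min)
  maxs <- apply(x$values, 2, max)
  scaler <- structure(list(min = mins, max = maxs, gene_ids = gene_ids(x)),
                      class = "minmax_scaler")
  list(gem = minmax_apply(scaler, x), scaler = scaler)
}

#' Apply / invert a fitted min-max scaler
#'
#' `minmax_apply()` scales new data with a previously fitted scaler, clipping
#' to [0, 1] (values outside the fitted range can occur for samples appended
#' after fitting). `minmax_inverse()` maps `"minmax"`-state values back to
#' the fitted scale; constant genes recover their fitted minimum.
#'
#' @param scaler a `minmax_scaler` from [minmax_fit_transform()].
#' @param x a [gem()] with the scaler's genes.
#' @return a `gem` in `"minmax"` (apply) or `"quantile"` (inverse) state.
#' @export
minmax_apply <- function(scaler, x) {
  stopifnot(inherits(scaler, "minmax_scaler"), inherits(x, "gem"))
  if (!identical(scaler$gene_ids, gene_ids(x))) {
    stop("scaler was fitted on a different gene list/order", call. = FALSE)
  }
  rng <- scaler$max - scaler$min
  rng[rng == 0] <- 1  # constant genes: numerator is 0 anyway -> 0
  v <- sweep(sweep(x$values, 2, scaler$min, "-"), 2, rng, "/")
  x$values <- pmin(pmax(v, 0), 1)
  x$norm_state <- "minmax"
  x
}

#' @rdname minmax_apply
#' @export
minmax_inverse <- function(scaler, x) {
  stopifnot(inherits(scaler, "minmax_scaler"), inherits(x, "gem"))
  if (x$norm_state != "minmax") {
    stop("minmax_inverse expects a 'minmax' gem", call. = FALSE)
  }
  if (!identical(scaler$gene_ids, gene_ids(x))) {
    stop("scaler was fitted on a different gene list/order", call. = FALSE)
  }
  rng <- scaler$max - scaler$min
  x$values <- sweep(sweep(x$values, 2, rng, "*"), 2, scaler$min, "+")
  x$norm_state <- "quantile"
  x
}

#' Full normalization chain for a raw GEM
#'
#' Convenience wrapper running log2 transform, quantile normalization,
#' optional gene-set subsetting, and per-gene min-max scaling — the standard
#' preparation before training. Patient or test samples to analyse alongside
#' a reference cohort should be appended to the matrix *before* calling this,
#' so that all samples are normalized jointly.
#'
#' @param x a [gem()] in `"raw"` state.
#' @param genes optional gene set (see [subset_genes()]).
#' @return a list with `gem` (in `"minmax"` state) and `scaler`.
#' @export
normalize_gem <- function(x, genes = NULL) {
  x <- quantile_normalize(log2_transform(x))
  if (!is.null(genes)) x <- subset_genes(x, genes)
  minmax_fit_transform(x)
}
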