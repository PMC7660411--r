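#' Gene expression matrix (GEM) container
#'
#' A `gem` wraps a numeric matrix of expression values oriented samples x
#' genes, together with the per-sample class labels and a record of which
#' normalization state the values are in (`"raw"`, `"log2"`, `"quantile"`
#' or `"minmax"`). All modelling functions in gempert consume and produce
#' this container; [as_tibble.gem()] converts to a long tibble for
#' tidyverse-style exploration.
#'
#' @param values numeric matrix, samples as rows and genes as columns, with
#'   row and column names (sample and gene identifiers).
#' @param labels optional per-sample class labels: either an unnamed vector
#'   ordered like the rows of `values`, or a vector/tibble keyed by sample id
#'   (see [set_labels()]).
#' @param norm_state normalization state of `values`; one of `"raw"`,
#'   `"log2"`, `"quantile"`, `"minmax"`.
#' @return An object of class `gem`.
#' @examples
#' m <- matrix(runif(6), 2, 3, dimnames = list(c("s1", "s2"), c("g1", "g2", "g3")))
#' g <- gem(m, labels = c("tumor", "normal"), norm_state = "minmax")
#' g
#' @export
gem <- function(values, labels = NULL, norm_state = "raw") {
  if (!is.matrix(values) || !is.numeric(values)) {
    stop("`values` must be a numeric matrix (samples x genes)", call. = FALSE)
  }
  if (is.null(rownames(values)) || is.null(colnames(values))) {
    stop("`values` must carry sample ids as rownames and gene ids as colnames",
         call. = FALSE)
  }
  norm_state <- match.arg(norm_state, c("raw", "log2", "quantile", "minmax"))
  x <- structure(
    list(values = values, labels = NULL, norm_state = norm_state),
    class = "gem"
  )
  if (!is.null(labels)) x <- set_labels(x, labels)
  validate_gem(x)
}

validate_gem <- function(x) {
  v <- x$values
  if (anyNA(v) || any(!is.finite(v))) {
    stop("expression values contain missing or non-finite entries", call. = FALSE)
  }
  dup_check(rownames(v), "sample id")
  dup_check(colnames(v), "gene id")
  if (x$norm_state %in% c("raw", "log2") && any(v < 0)) {
    stop(sprintf("negative values are not allowed in '%s' state", x$norm_state),
         call. = FALSE)
  }
  if (x$norm_state == "minmax" && (any(v < 0) || any(v > 1))) {
    stop("values in 'minmax' state must lie in [0, 1]", call. = FALSE)
  }
  if (!is.null(x$labels) && length(x$labels) != nrow(v)) {
    stop("labels length must equal the number of samples", call. = FALSE)
  }
  x
}

dup_check <- function(ids, what) {
  d <- unique(ids[duplicated(ids)])
  if (length(d) > 0) {
    stop(sprintf("duplicate %ss: %s", what, paste(d, collapse = ", ")),
         call. = FALSE)
  }
  invisible(ids)
}

#' @export
print.gem <- function(x, ...) {
  cat(sprintf("<gem> %d samples x %d genes [%s]\n",
              nrow(x$values), ncol(x$values), x$norm_state))
  if (!is.null(x$labels)) {
    tab <- table(x$labels)
    cat("labels:", paste(sprintf("%s (%d)", names(tab), tab), collapse = ", "), "\n")
  }
  invisible(x)
}

#' @export
dim.gem <- function(x) dim(x$values)

#' Accessors for `gem` objects
#'
#' @param x a [gem()] object.
#' @return `gene_ids()` and `sample_ids()` return character vectors;
#'   `gem_values()` the underlying samples x genes matrix; `gem_labels()` the
#'   per-sample label vector (or `NULL`).
#' @export
gene_ids <- function(x) colnames(x$values)

#' @rdname gene_ids
#' @export
sample_ids <- function(x) rownames(x$values)

#' @rdname gene_ids
#' @export
gem_values <- function(x) x$values

#' @rdname gene_ids
#' @export
gem_labels <- function(x) x$labels

#' Attach per-sample class labels to a GEM
#'
#' @param x a [gem()] object.
#' @param labels either an unnamed vector ordered like `sample_ids(x)`, a
#'   named vector keyed by sample id, or a two-column tibble/data.frame
#'   (`sample_id`, `label`) such as returned by [read_labels()].
#' @return `x` with labels attached.
#' @export
set_labels <- function(x, labels) {
  if (is.data.frame(labels)) {
    labels <- stats::setNames(as.character(labels[[2]]), labels[[1]])
  }
  if (!is.null(names(labels))) {
    missing <- setdiff(sample_ids(x), names(labels))
    if (length(missing) > 0) {
      stop(sprintf("no label for sample(s): %s",
                   paste(utils::head(missing, 5), collapse = ", ")), call. = FALSE)
    }
    labels <- unname(labels[sample_ids(x)])
  }
  if (length(labels) != nrow(x$values)) {
    stop("labels length must equal the number of samples", call. = FALSE)
  }
  x$labels <- as.character(labels)
  x
}

#' Subset a GEM by sample ids
#'
#' @param x a [gem()] object.
#' @param ids sample identifiers to keep (order preserved).
#' @return a `gem` with the selected samples.
#' @export
subset_samples <- function(x, ids) {
  missing <- setdiff(ids, sample_ids(x))
  if (length(missing) > 0) {
    stop(sprintf("unknown sample id(s): %s", paste(missing, collapse = ", ")),
         call. = FALSE)
  }
  keep <- match(ids, sample_ids(x))
  out <- x
  out$values <- x$values[keep, , drop = FALSE]
  if (!is.null(x$labels)) out$labels <- x$labels[keep]
  out
}

#' @importFrom tibble as_tibble
#' @export
tibble::as_tibble

#' Convert a GEM to a long tibble
#'
#' @param x a [gem()] object.
#' @param ... unused.
#' @return a tibble with columns `sample_id`, `label` (if present), `gene_id`,
#'   `value`.
#' @export
as_tibble.gem <- function(x, ...) {
  out <- tibble::tibble(
    sample_id = rep(sample_ids(x), times = ncol(x$values)),
    gene_id   = rep(gene_ids(x), each = nrow(x$values)),
    value     = as.vector(x$values)
  )
  if (!is.null(x$labels)) {
    out <- dplyr::mutate(out,
      label = rep(x$labels, times = ncol(x$values)), .after = "sample_id")
  }
  out
}

# ---- file formats -----------------------------------------------------------

#' Read a tab-delimited gene expression matrix
#'
#' Reads the plain-text GEM dialect used by merged GTEx/TCGA FPKM releases:
#' one header row of ids, one leading id column, tab-delimited numeric cells.
#' Files may store genes as rows (the usual convention) or samples as rows;
#' either way the returned object is oriented samples x genes.
#'
#' @param path file path.
#' @param orientation `"genes_as_rows"` (default) or `"samples_as_rows"`:
#'   which entity the file's rows represent.
#' @return a [gem()] in `"raw"` normalization state.
#' @export
read_gem <- function(path, orientation = c("genes_as_rows", "samples_as_rows")) {
  orientation <- match.arg(orientation)
  lines <- readLines(path)
  if (length(lines) < 2) stop("GEM file must have a header row and at least one data row",
                              call. = FALSE)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  header <- fields[[1]]
  # header may or may not carry a placeholder over the id column
  n_data_cols <- length(fields[[2]]) - 1L
  col_ids <- if (length(header) == n_data_cols) header else header[-1]
  if (length(col_ids) != n_data_cols) {
    stop(sprintf("header has %d ids but data rows have %d value columns",
                 length(col_ids), n_data_cols), call. = FALSE)
  }
  body <- fields[-1]
  widths <- lengths(body)
  if (any(widths != n_data_cols + 1L)) {
    bad <- which(widths != n_data_cols + 1L)[1]
    stop(sprintf("ragged row at line %d: expected %d fields, found %d",
                 bad + 1L, n_data_cols + 1L, widths[bad]), call. = FALSE)
  }
  row_ids <- vapply(body, `[[`, character(1), 1L)
  vals <- suppressWarnings(
    vapply(body, function(f) as.numeric(f[-1]), numeric(n_data_cols))
  )
  vals <- matrix(vals, nrow = n_data_cols)  # columns = file rows
  if (anyNA(vals)) {
    idx <- which(is.na(vals), arr.ind = TRUE)[1, ]
    stop(sprintf("non-numeric value at file row '%s', column '%s'",
                 row_ids[idx[2]], col_ids[idx[1]]), call. = FALSE)
  }
  m <- t(vals)  # file rows as matrix rows
  dimnames(m) <- list(row_ids, col_ids)
  dup_check(row_ids, "row id")
  dup_check(col_ids, "column id")
  if (orientation == "genes_as_rows") m <- t(m)
  gem(m, norm_state = "raw")
}

#' Write a GEM as tab-delimited text
#'
#' Values are written with 17 significant digits so that
#' `read_gem(write_gem(x))` round-trips bit-for-bit.
#'
#' @param x a [gem()] object.
#' @param path output file path.
#' @param orientation file row entity, as in [read_gem()].
#' @return `path`, invisibly.
#' @export
write_gem <- function(x, path, orientation = c("genes_as_rows", "samples_as_rows")) {
  orientation <- match.arg(orientation)
  m <- gem_values(x)
  if (orientation == "genes_as_rows") m <- t(m)
  header <- paste(c("id", colnames(m)), collapse = "\t")
  body <- vapply(seq_len(nrow(m)), function(i) {
    paste(c(rownames(m)[i], sprintf("%.17g", m[i, ])), collapse = "\t")
  }, character(1))
  writeLines(c(header, body), path)
  invisible(path)
}

#' Read a two-column sample label table
#'
#' Tab-delimited `sample_id<TAB>label` rows; a header row (detected by a
#' first field of `sample`, `sample_id` or `id`, case-insensitive) is
#' skipped. A sample listed twice with conflicting labels is an error;
#' exact duplicate rows are collapsed.
#'
#' @param path file path.
#' @return a tibble with columns `sample_id` and `label` (empty if the file
#'   is empty).
#' @export
read_labels <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  empty <- tibble::tibble(sample_id = character(), label = character())
  if (length(lines) == 0) return(empty)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  if (any(lengths(fields) < 2)) {
    bad <- which(lengths(fields) < 2)[1]
    stop(sprintf("line %d does not have two tab-separated fields", bad),
         call. = FALSE)
  }
  ids <- vapply(fields, `[[`, character(1), 1L)
  labs <- vapply(fields, `[[`, character(1), 2L)
  if (tolower(ids[1]) %in% c("sample", "sample_id", "id", "sampleid")) {
    ids <- ids[-1]; labs <- labs[-1]
  }
  if (length(ids) == 0) return(empty)
  tab <- tibble::tibble(sample_id = ids, label = labs)
  tab <- dplyr::distinct(tab)
  conflict <- unique(tab$sample_id[duplicated(tab$sample_id)])
  if (length(conflict) > 0) {
    stop(sprintf("conflicting labels for sample(s): %s",
                 paste(conflict, collapse = ", ")), call. = FALSE)
  }
  tab
}

#' Write a sample label table
#'
#' @param x a [gem()] with labels, or a tibble with `sample_id` and `label`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_labels <- function(x, path) {
  if (inherits(x, "gem")) {
    if (is.null(gem_labels(x))) stop("gem has no labels", call. = FALSE)
    x <- tibble::tibble(sample_id = sample_ids(x), label = gem_labels(x))
  }
  writeLines(paste(x$sample_id, x$label, sep = "\t"), path)
  invisible(path)
}

#' Read gene sets from a GMT file
#'
#' Standard MSigDB-style GMT: one set per line, tab-delimited
#' `name<TAB>description<TAB>gene1<TAB>gene2...`. The description column is
#' discarded; gene order is preserved; duplicate genes within a set are
#' dropped with a warning.
#'
#' @param path file path.
#' @return a tibble with one row per set: `set` (name), `n_genes`, and
#'   `genes` (list-column of character vectors).
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  short <- which(lengths(fields) < 3)
  if (length(short) > 0) {
    stop(sprintf("GMT line %d has fewer than 3 fields", short[1]), call. = FALSE)
  }
  sets <- purrr::map(fields, function(f) {
    genes <- f[-(1:2)]
    if (anyDuplicated(genes)) {
      warning(sprintf("gene set '%s': duplicate gene(s) %s removed", f[1],
                      paste(unique(genes[duplicated(genes)]), collapse = ", ")),
              call. = FALSE)
      genes <- genes[!duplicated(genes)]
    }
    list(set = f[1], genes = genes)
  })
  tibble::tibble(
    set = purrr::map_chr(sets, "set"),
    n_genes = purrr::map_int(sets, ~ length(.x$genes)),
    genes = purrr::map(sets, "genes")
  )
}
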