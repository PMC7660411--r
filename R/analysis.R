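#' Per-sample significant gene lists from a perturbation vector
#'
#' The single-sample surrogate for differential expression: over the genes
#' of one sample's perturbation vector, compute the mean and (population)
#' standard deviation, and flag genes lying strictly outside
#' `mean +/- k * sd`. Under the tumor-to-normal convention a *positive*
#' perturbation raises a gene toward the normal state, so it marks a gene
#' that is *lower* in the tumor ("tumor-downregulated"); a negative
#' perturbation marks a "tumor-upregulated" gene. The `semantics` argument
#' controls that naming; the raw sign is always reported as well.
#'
#' @param P named numeric perturbation vector (names are gene ids), or a
#'   one-row `gempert_perturbations` tibble.
#' @param k threshold multiplier in standard deviations (default 2).
#' @param semantics `"tumor_to_normal"` (default; the perturbation was
#'   aimed at a normal target) or `"normal_to_tumor"`.
#' @param sample_id optional sample identifier for reporting.
#' @return an object of class `significance_result`: fields `sample_id`,
#'   `mean`, `sd`, `k`, `semantics`, `genes` (tibble of all genes with
#'   columns `gene_id`, `P`, `deviation`, `sign`, `label`), and the
#'   convenience vectors `positive_genes` / `negative_genes` (sorted by
#'   `|P - mean|` descending).
#' @export
significant_genes <- function(P, k = 2,
                              semantics = c("tumor_to_normal", "normal_to_tumor"),
                              sample_id = NULL) {
  semantics <- match.arg(semantics)
  if (is.data.frame(P)) {
    stopifnot(nrow(P) == 1)
    sample_id <- sample_id %||% P$sample_id[[1]]
    P <- P$P[[1]]
  }
  stopifnot(is.numeric(P), k >= 0)
  if (length(P) < 2) stop("need at least two genes", call. = FALSE)
  if (is.null(names(P))) names(P) <- sprintf("gene_%04d", seq_along(P))
  mu <- mean(P)
  sdev <- sqrt(mean((P - mu)^2))
  if (sdev == 0 && k > 0) {
    warning("constant perturbation vector: no genes can be flagged", call. = FALSE)
  }
  up_label <- if (semantics == "tumor_to_normal") "tumor-downregulated" else "tumor-upregulated"
  down_label <- if (semantics == "tumor_to_normal") "tumor-upregulated" else "tumor-downregulated"
  genes <- tibble::tibble(
    gene_id = names(P),
    P = as.numeric(P),
    deviation = as.numeric(P - mu),
    sign = dplyr::case_when(
      .data$P > mu + k * sdev ~ "positive",
      .data$P < mu - k * sdev ~ "negative",
      TRUE ~ "none"
    )
  )
  genes$label <- dplyr::case_when(
    genes$sign == "positive" ~ up_label,
    genes$sign == "negative" ~ down_label,
    TRUE ~ NA_character_
  )
  pick <- function(s) {
    g <- genes[genes$sign == s, ]
    g$gene_id[order(-abs(g$deviation), g$gene_id)]
  }
  structure(list(
    sample_id = sample_id, mean = mu, sd = sdev, k = k, semantics = semantics,
    genes = genes,
    positive_genes = pick("positive"), negative_genes = pick("negative")
  ), class = "significance_result")
}

#' @export
print.significance_result <- function(x, ...) {
  cat(sprintf("<significance_result> %s: %d genes, mean %.4g, sd %.4g, k = %g\n",
              x$sample_id %||% "(unnamed)", nrow(x$genes), x$mean, x$sd, x$k))
  cat(sprintf("  positive (%s): %d genes\n  negative (%s): %d genes\n",
              if (x$semantics == "tumor_to_normal") "tumor-downregulated" else "tumor-upregulated",
              length(x$positive_genes),
              if (x$semantics == "tumor_to_normal") "tumor-upregulated" else "tumor-downregulated",
              length(x$negative_genes)))
  invisible(x)
}

#' Gene lists of a significance result, by direction label
#'
#' @param x a `significance_result`.
#' @param direction `"tumor_up"` or `"tumor_down"`.
#' @return character vector of gene ids.
#' @export
genes_by_direction <- function(x, direction = c("tumor_up", "tumor_down")) {
  direction <- match.arg(direction)
  want <- if (direction == "tumor_up") "tumor-upregulated" else "tumor-downregulated"
  if (x$semantics == "tumor_to_normal") {
    if (want == "tumor-upregulated") x$negative_genes else x$positive_genes
  } else {
    if (want == "tumor-upregulated") x$positive_genes else x$negative_genes
  }
}

#' Most extreme perturbed genes
#'
#' Top `n_top` genes by signed perturbation: descending for `"up"`,
#' ascending for `"down"`. Ties are broken by gene id so output is
#' deterministic.
#'
#' @param P named numeric perturbation vector.
#' @param n_top number of genes to return (<= gene count).
#' @param direction `"up"` or `"down"`.
#' @return ordered character vector of gene ids.
#' @export
rank_gene_extremes <- function(P, n_top, direction = c("up", "down")) {
  direction <- match.arg(direction)
  stopifnot(is.numeric(P), n_top <= length(P))
  if (is.null(names(P))) names(P) <- sprintf("gene_%04d", seq_along(P))
  o <- if (direction == "up") order(-P, names(P)) else order(P, names(P))
  names(P)[o][seq_len(n_top)]
}

#' Overlap ratio between two gene lists
#'
#' Shared genes divided by the union of genes found in either list (the
#' Jaccard index). Two empty lists give ratio 0 with `n_union = 0`.
#'
#' @param a,b character vectors of gene ids (duplicates ignored).
#' @return a list with `ratio`, `n_shared`, `n_union`.
#' @export
overlap_ratio <- function(a, b) {
  a <- unique(a); b <- unique(b)
  n_shared <- length(intersect(a, b))
  n_union <- length(union(a, b))
  list(ratio = if (n_union == 0) 0 else n_shared / n_union,
       n_shared = n_shared, n_union = n_union)
}

#' Pairwise overlap matrix across patients
#'
#' For each pair of significance results, the overlap ratio of their gene
#' lists in the chosen direction. The diagonal is 1 (0 for an empty list).
#'
#' @param results list of `significance_result` objects (>= 2), ideally
#'   named by patient/sample.
#' @param direction `"tumor_up"` or `"tumor_down"` (see
#'   [genes_by_direction()]).
#' @return an object of class `overlap_matrix`: list with symmetric
#'   matrices `ratio`, `n_shared`, `n_union`, and `direction`.
#' @export
pairwise_overlap_matrix <- function(results, direction = c("tumor_up", "tumor_down")) {
  direction <- match.arg(direction)
  stopifnot(length(results) >= 2)
  ids <- names(results) %||% purrr::map_chr(results, function(r) {
    r$sample_id %||% ""
  })
  if (any(!nzchar(ids))) ids <- paste0("patient_", seq_along(results))
  lists <- purrr::map(results, genes_by_direction, direction = direction)
  n <- length(lists)
  ratio <- shared <- uni <- matrix(0, n, n, dimnames = list(ids, ids))
  for (i in seq_len(n)) {
    for (j in i:n) {
      ov <- overlap_ratio(lists[[i]], lists[[j]])
      ratio[i, j] <- ratio[j, i] <- ov$ratio
      shared[i, j] <- shared[j, i] <- ov$n_shared
      uni[i, j] <- uni[j, i] <- ov$n_union
    }
  }
  structure(list(ratio = ratio, n_shared = shared, n_union = uni,
                 direction = direction),
            class = "overlap_matrix")
}

#' Write an overlap matrix as TSV (and optionally a heatmap PNG)
#'
#' @param x an `overlap_matrix`.
#' @param path output path prefix; writes `<path>.tsv` and `<path>.png`.
#' @param write_png also write the heatmap image.
#' @return `path`, invisibly.
#' @export
write_overlap_matrix <- function(x, path, write_png = TRUE) {
  df <- data.frame(patient = rownames(x$ratio), x$ratio, check.names = FALSE)
  utils::write.table(df, paste0(path, ".tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE)
  if (write_png) {
    grDevices::png(paste0(path, ".png"), width = 700, height = 600, res = 120)
    print(autoplot(x))
    grDevices::dev.off()
  }
  invisible(path)
}

#' Read an external differential-expression result table
#'
#' Accepts any tab-delimited table with a gene id column, a log2 fold
#' change, and an adjusted p value. DESeq2-style column names are accepted
#' as aliases (`gene`/`gene_id`, `log2FoldChange`/`log2_fold_change`/`lfc`,
#' `padj`/`adjusted_p`/`p_adj`).
#'
#' @param path file path.
#' @return a tibble with columns `gene_id`, `log2_fold_change`, `adjusted_p`.
#' @export
read_dge_table <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  find_col <- function(aliases, what) {
    hit <- which(tolower(names(df)) %in% aliases)
    if (length(hit) == 0) {
      stop(sprintf("no %s column found (looked for: %s)", what,
                   paste(aliases, collapse = ", ")), call. = FALSE)
    }
    df[[hit[1]]]
  }
  out <- tibble::tibble(
    gene_id = as.character(find_col(c("gene", "gene_id", "geneid", "id"), "gene id")),
    log2_fold_change = as.numeric(find_col(
      c("log2foldchange", "log2_fold_change", "lfc", "log2fc"), "log2 fold change")),
    adjusted_p = as.numeric(find_col(c("padj", "adjusted_p", "p_adj", "qvalue", "fdr"),
                                     "adjusted p"))
  )
  dup_check(out$gene_id, "gene id")
  if (any(out$adjusted_p < 0 | out$adjusted_p > 1, na.rm = TRUE)) {
    stop("adjusted p values must lie in [0, 1]", call. = FALSE)
  }
  out
}

#' Overlap between per-sample gene lists and a cohort DGE table
#'
#' Splits the DGE table's significant genes (`adjusted_p < alpha`) by the
#' sign of their log2 fold change, then intersects the sample's
#' tumor-upregulated list with the positive-fold-change set and the
#' tumor-downregulated list with the negative set. The fold-change
#' convention is tumor relative to normal (positive = higher in tumor).
#'
#' @param result a `significance_result` from [significant_genes()].
#' @param dge a tibble from [read_dge_table()] (or with the same columns).
#' @param alpha adjusted-p cutoff in (0, 1]; default 1e-4.
#' @param direction `"tumor_up"`, `"tumor_down"`, or `"both"` (default).
#' @return a tibble with one row per direction: `direction`, `percentage`,
#'   `n_shared`, `n_list`, `formatted` (as `"x% (n/m)"`).
#' @export
dge_overlap <- function(result, dge, alpha = 1e-4,
                        direction = c("both", "tumor_up", "tumor_down")) {
  direction <- match.arg(direction)
  stopifnot(inherits(result, "significance_result"), alpha > 0, alpha <= 1)
  sig <- dge[!is.na(dge$adjusted_p) & dge$adjusted_p < alpha, ]
  dge_sets <- list(
    tumor_up = sig$gene_id[sig$log2_fold_change > 0],
    tumor_down = sig$gene_id[sig$log2_fold_change < 0]
  )
  dirs <- if (direction == "both") c("tumor_up", "tumor_down") else direction
  rows <- lapply(dirs, function(d) {
    lst <- genes_by_direction(result, d)
    if (length(lst) == 0) {
      warning(sprintf("empty %s gene list: overlap percentage reported as 0", d),
              call. = FALSE)
      pct <- 0; n_shared <- 0L
    } else {
      n_shared <- length(intersect(lst, dge_sets[[d]]))
      pct <- 100 * n_shared / length(lst)
    }
    tibble::tibble(direction = d, percentage = pct,
                   n_shared = as.integer(n_shared), n_list = length(lst),
                   formatted = sprintf("%.1f%% (%d/%d)", pct, n_shared, length(lst)))
  })
  dplyr::bind_rows(rows)
}

#' Compare two perturbation distributions
#'
#' Builds the overlaid histogram of two perturbation vectors (for example a
#' tumor sample and a normal sample perturbed toward the same normal
#' target) and the summary statistics behind the null-contrast check: each
#' vector's standard deviation and its count of genes deviating more than
#' `2 * sd` from the mean. A normal-to-normal perturbation is expected to
#' show a visibly narrower distribution than tumor-to-normal.
#'
#' @param result_a,result_b `significance_result` objects on the same gene
#'   universe.
#' @param path optional output prefix; writes `<path>.png` and
#'   `<path>.json` (the summary).
#' @return a list with `plot` (ggplot) and `summary` (tibble with columns
#'   `sample_id`, `sd`, `n_outside_2sd`).
#' @export
perturbation_histogram <- function(result_a, result_b, path = NULL) {
  stopifnot(inherits(result_a, "significance_result"),
            inherits(result_b, "significance_result"))
  if (nrow(result_a$genes) != nrow(result_b$genes)) {
    stop("results cover different gene universes", call. = FALSE)
  }
  summarize_one <- function(r, fallback) {
    tibble::tibble(
      sample_id = r$sample_id %||% fallback,
      sd = r$sd,
      n_outside_2sd = sum(abs(r$genes$deviation) > 2 * r$sd)
    )
  }
  summary <- dplyr::bind_rows(summarize_one(result_a, "a"),
                              summarize_one(result_b, "b"))
  long <- dplyr::bind_rows(
    dplyr::mutate(result_a$genes, sample = summary$sample_id[1]),
    dplyr::mutate(result_b$genes, sample = summary$sample_id[2])
  )
  plot <- ggplot2::ggplot(long, ggplot2::aes(x = .data$P, fill = .data$sample)) +
    ggplot2::geom_histogram(alpha = 0.55, position = "identity", bins = 60) +
    ggplot2::labs(x = "perturbation", y = "genes", fill = NULL) +
    ggplot2::theme_minimal()
  if (!is.null(path)) {
    grDevices::png(paste0(path, ".png"), width = 800, height = 500, res = 120)
    print(plot)
    grDevices::dev.off()
    jsonlite::write_json(summary, paste0(path, ".json"), auto_unbox = TRUE,
                         digits = NA)
  }
  list(plot = plot, summary = summary)
}
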