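#' Perturb samples toward a target class
#'
#' Applies a trained generator to each sample, forms the adversarial sample
#' `x_adv = clip(x + P, 0, 1)`, and validates it against the frozen
#' classifier: a perturbed sample is *valid* if the classifier assigns it to
#' the target class. `P` is stored pre-clipping, so `x_adv - x` can differ
#' from `P` at the [0, 1] boundary.
#'
#' @param G a `gempert_generator` from [train_generator()].
#' @param f the frozen `gempert_target` classifier.
#' @param x a labeled [gem()] (all samples are perturbed), a sample vector,
#'   or a samples x genes matrix.
#' @param target_label target class; defaults to the class `G` was trained
#'   toward.
#' @param source_labels optional source labels when `x` is not a labeled gem.
#' @return a `gempert_perturbations` tibble with one row per sample:
#'   `sample_id`, `source_label`, `target_label`, `predicted_label`,
#'   `valid`, and list-columns `x`, `P`, `x_adv` (named per-gene vectors).
#' @export
perturb_gem <- function(G, f, x, target_label = NULL, source_labels = NULL) {
  stopifnot(inherits(G, "gempert_generator"), inherits(f, "gempert_target"))
  target_label <- target_label %||% G$target_label
  if (inherits(x, "gem")) {
    if (!identical(gene_ids(x), G$gene_ids)) {
      stop("gene order differs between data and generator", call. = FALSE)
    }
    source_labels <- source_labels %||% gem_labels(x)
    xm <- gem_values(x)
  } else {
    xm <- as_row_matrix(x)
    if (ncol(xm) != length(G$gene_ids)) {
      stop(sprintf("sample has %d genes, generator expects %d",
                   ncol(xm), length(G$gene_ids)), call. = FALSE)
    }
    colnames(xm) <- G$gene_ids
    if (is.null(rownames(xm))) {
      rownames(xm) <- sprintf("sample_%d", seq_len(nrow(xm)))
    }
  }
  if (any(xm < 0 | xm > 1)) {
    stop("samples must be min-max normalized to [0, 1]", call. = FALSE)
  }
  P <- apply_generator(G, xm)
  x_adv <- pmin(pmax(xm + P, 0), 1)
  predicted <- predict(f, x_adv)
  out <- tibble::tibble(
    sample_id = rownames(xm),
    source_label = if (is.null(source_labels)) NA_character_ else source_labels,
    target_label = target_label,
    predicted_label = predicted,
    valid = predicted == target_label,
    x = lapply(seq_len(nrow(xm)), function(i) xm[i, ]),
    P = lapply(seq_len(nrow(xm)), function(i) P[i, ]),
    x_adv = lapply(seq_len(nrow(x_adv)), function(i) x_adv[i, ])
  )
  class(out) <- c("gempert_perturbations", class(out))
  attr(out, "gene_ids") <- G$gene_ids
  out
}

#' @rdname perturb_gem
#' @param x_vec a single sample vector in [0, 1].
#' @param source_label source class label of the sample.
#' @export
perturb_sample <- function(G, f, x_vec, source_label = NA_character_,
                           target_label = NULL) {
  perturb_gem(G, f, x_vec, target_label = target_label,
              source_labels = source_label)
}

#' Attack success rate
#'
#' Fraction of perturbed samples that the frozen classifier assigns to the
#' target class, as a percentage. This is the headline measure of the
#' generator's ability to "trick" the classifier.
#'
#' @param records a `gempert_perturbations` tibble from [perturb_gem()].
#' @return percentage in [0, 100].
#' @export
attack_success_rate <- function(records) {
  if (!is.data.frame(records) || nrow(records) == 0) {
    stop("need a non-empty set of perturbation records", call. = FALSE)
  }
  if (length(unique(records$target_label)) > 1) {
    stop("records mix different target classes", call. = FALSE)
  }
  100 * mean(records$valid)
}

#' Naive difference between two samples
#'
#' Elementwise `x_a - x_b`: the baseline "n = 1 vs n = 1" comparison (for
#' example patient tumor minus patient normal) against which learned
#' perturbations can be judged.
#'
#' @param x_a,x_b numeric vectors of equal length.
#' @return their elementwise difference.
#' @export
naive_difference <- function(x_a, x_b) {
  if (length(x_a) != length(x_b)) {
    stop("vectors must have equal length", call. = FALSE)
  }
  x_a - x_b
}

#' Export a perturbation heatmap panel
#'
#' Writes the four-row panel summarizing one perturbed sample — original
#' `x`, perturbation `P`, adversarial `x_adv`, and the target-class mean
#' `mu_t` — as a TSV of the underlying numbers and (optionally) a PNG
#' heatmap. `x`, `x_adv` and `mu_t` share a [0, 1] color scale; `P` is drawn
#' on a [-1, 1] diverging scale. If the frozen classifier is supplied, the
#' record's validity flag is re-checked before export.
#'
#' @param record a one-row `gempert_perturbations` tibble.
#' @param mu_t target-class mean expression vector (e.g. `stats$mu` from
#'   [class_stats()]).
#' @param path output path prefix; writes `<path>.tsv` and `<path>.png`.
#' @param f optional `gempert_target` used to re-validate the record.
#' @param write_png write the PNG heatmap (default TRUE).
#' @return invisibly, the panel matrix (rows `x`, `P`, `x_adv`, `mu_t`).
#' @export
export_heatmap_panel <- function(record, mu_t, path, f = NULL,
                                 write_png = TRUE) {
  stopifnot(is.data.frame(record), nrow(record) == 1)
  x <- record$x[[1]]; P <- record$P[[1]]; x_adv <- record$x_adv[[1]]
  if (length(mu_t) != length(x)) {
    stop("mu_t length does not match the record's gene count", call. = FALSE)
  }
  if (!is.null(f)) {
    pred <- predict(f, x_adv)
    if ((pred == record$target_label) != record$valid) {
      stop("record validity flag is stale: classifier disagrees", call. = FALSE)
    }
  }
  panel <- rbind(x = x, P = P, x_adv = x_adv, mu_t = as.numeric(mu_t))
  colnames(panel) <- names(x)
  df <- data.frame(row = rownames(panel), panel, check.names = FALSE)
  utils::write.table(df, paste0(path, ".tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE)
  if (write_png) {
    long <- tidyr::pivot_longer(tibble::as_tibble(df), -"row",
                                names_to = "gene", values_to = "value")
    long$gene <- factor(long$gene, levels = colnames(panel))
    long$row <- factor(long$row, levels = rev(rownames(panel)))
    p1 <- ggplot2::ggplot(
      dplyr::filter(long, .data$row != "P"),
      ggplot2::aes(x = .data$gene, y = .data$row, fill = .data$value)) +
      ggplot2::geom_tile() +
      ggplot2::scale_fill_viridis_c(limits = c(0, 1), name = "expression") +
      ggplot2::labs(x = NULL, y = NULL) +
      ggplot2::theme_minimal() +
      ggplot2::theme(axis.text.x = ggplot2::element_blank())
    p2 <- ggplot2::ggplot(
      dplyr::filter(long, .data$row == "P"),
      ggplot2::aes(x = .data$gene, y = .data$row, fill = .data$value)) +
      ggplot2::geom_tile() +
      ggplot2::scale_fill_gradient2(limits = c(-1, 1), low = "blue",
                                    mid = "white", high = "red", name = "P") +
      ggplot2::labs(x = NULL, y = NULL) +
      ggplot2::theme_minimal() +
      ggplot2::theme(axis.text.x = ggplot2::element_blank())
    grDevices::png(paste0(path, ".png"), width = 1200, height = 500, res = 120)
    print(p1 + ggplot2::theme(plot.margin = ggplot2::margin(2, 2, 2, 2)))
    grDevices::dev.off()
    grDevices::png(paste0(path, "_P.png"), width = 1200, height = 250, res = 120)
    print(p2)
    grDevices::dev.off()
  }
  invisible(panel)
}
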