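#' Tidy and glance methods
#'
#' broom-style summaries: `tidy()` returns the per-epoch training history
#' (classifier) or per-epoch loss log (generator), the per-gene table
#' (significance result), or the long pair table (overlap matrix);
#' `glance()` returns a one-row model summary.
#'
#' @param x a fitted gempert object.
#' @param ... unused.
#' @return a tibble.
#' @name tidiers
NULL

#' @rdname tidiers
#' @export
tidy.gempert_target <- function(x, ...) x$history

#' @rdname tidiers
#' @export
glance.gempert_target <- function(x, ...) {
  tibble::tibble(
    n_classes = length(x$classes),
    n_genes = length(x$gene_ids),
    epochs = x$config$target_epochs,
    holdout_n = length(x$holdout_ids),
    holdout_accuracy = x$holdout_accuracy
  )
}

#' @rdname tidiers
#' @export
tidy.gempert_generator <- function(x, ...) x$loss_log

#' @rdname tidiers
#' @export
glance.gempert_generator <- function(x, ...) {
  final <- x$loss_log[nrow(x$loss_log), ]
  tibble::tibble(
    target_label = x$target_label,
    n_genes = length(x$gene_ids),
    epochs = x$config$gan_epochs,
    L_total = final$L_total,
    L_D = final$L_D,
    train_attack_success = final$train_attack_success
  )
}

#' @rdname tidiers
#' @export
tidy.significance_result <- function(x, ...) x$genes

#' @rdname tidiers
#' @export
glance.significance_result <- function(x, ...) {
  tibble::tibble(
    sample_id = x$sample_id %||% NA_character_,
    mean = x$mean, sd = x$sd, k = x$k, semantics = x$semantics,
    n_genes = nrow(x$genes),
    n_positive = length(x$positive_genes),
    n_negative = length(x$negative_genes)
  )
}

#' @rdname tidiers
#' @export
tidy.overlap_matrix <- function(x, ...) {
  ids <- rownames(x$ratio)
  idx <- which(upper.tri(x$ratio, diag = FALSE), arr.ind = TRUE)
  tibble::tibble(
    patient_a = ids[idx[, 1]], patient_b = ids[idx[, 2]],
    ratio = x$ratio[idx], n_shared = as.integer(x$n_shared[idx]),
    n_union = as.integer(x$n_union[idx]), direction = x$direction
  )
}

#' @export
print.gempert_target <- function(x, ...) {
  cat(sprintf("<gempert_target> %d classes, %d genes; holdout accuracy %.1f%% (n = %d)\n",
              length(x$classes), length(x$gene_ids),
              100 * x$holdout_accuracy, length(x$holdout_ids)))
  invisible(x)
}

#' @export
print.gempert_generator <- function(x, ...) {
  g <- glance(x)
  cat(sprintf("<gempert_generator> target '%s', %d genes, %d epochs; final L = %.3f, train attack %.1f%%\n",
              g$target_label, g$n_genes, g$epochs, g$L_total,
              100 * g$train_attack_success))
  invisible(x)
}

# ---- autoplot methods -------------------------------------------------------

#' Plot methods for gempert results
#'
#' `autoplot.gempert_generator()` draws per-epoch loss curves;
#' `autoplot.significance_result()` the perturbation histogram with the
#' `mean +/- k*sd` thresholds; `autoplot.overlap_matrix()` the pairwise
#' overlap heatmap; `autoplot.gempert_perturbations()` the per-sample
#' heatmap panel of `x`, `P`, `x_adv`.
#'
#' @param object the result object.
#' @param ... unused.
#' @return a ggplot.
#' @name gempert-autoplot
NULL

#' @rdname gempert-autoplot
#' @export
autoplot.gempert_generator <- function(object, ...) {
  long <- tidyr::pivot_longer(object$loss_log,
                              dplyr::all_of(c("L_gan", "L_adv", "L_norm", "L_td", "L_D")),
                              names_to = "term", values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$epoch, y = .data$value,
                                     color = .data$term)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "epoch", y = "loss") +
    ggplot2::theme_minimal()
}

#' @rdname gempert-autoplot
#' @export
autoplot.significance_result <- function(object, ...) {
  thr <- c(object$mean - object$k * object$sd, object$mean + object$k * object$sd)
  ggplot2::ggplot(object$genes, ggplot2::aes(x = .data$P)) +
    ggplot2::geom_histogram(bins = 60, fill = "grey40") +
    ggplot2::geom_vline(xintercept = thr, linetype = "dashed", color = "red") +
    ggplot2::labs(x = "perturbation", y = "genes") +
    ggplot2::theme_minimal()
}

#' @rdname gempert-autoplot
#' @export
autoplot.overlap_matrix <- function(object, ...) {
  long <- tibble::tibble(
    a = rep(rownames(object$ratio), times = ncol(object$ratio)),
    b = rep(colnames(object$ratio), each = nrow(object$ratio)),
    ratio = as.vector(object$ratio)
  )
  ggplot2::ggplot(long, ggplot2::aes(x = .data$a, y = .data$b, fill = .data$ratio)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = sprintf("%.2f", .data$ratio)),
                       size = 3, color = "white") +
    ggplot2::scale_fill_viridis_c(limits = c(0, 1)) +
    ggplot2::labs(x = NULL, y = NULL,
                  fill = sprintf("overlap (%s)", object$direction)) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' @rdname gempert-autoplot
#' @export
autoplot.gempert_perturbations <- function(object, ...) {
  gene_levels <- attr(object, "gene_ids")
  long <- dplyr::bind_rows(lapply(seq_len(nrow(object)), function(i) {
    tibble::tibble(
      sample_id = object$sample_id[[i]],
      gene = rep(gene_levels, 3),
      row = rep(c("x", "P", "x_adv"), each = length(gene_levels)),
      value = c(object$x[[i]], object$P[[i]], object$x_adv[[i]])
    )
  }))
  long$gene <- factor(long$gene, levels = gene_levels)
  long$row <- factor(long$row, levels = c("x", "P", "x_adv"))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$gene, y = .data$row,
                                     fill = .data$value)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(low = "blue", mid = "white", high = "red",
                                  limits = c(-1, 1)) +
    ggplot2::facet_wrap(~sample_id, ncol = 1) +
    ggplot2::labs(x = NULL, y = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_blank())
}
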