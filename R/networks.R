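#' Network architecture configurations
#'
#' The three networks follow fixed dense-layer plans: the generator is an
#' hourglass (encoder 512/256/128, three width-128 residual blocks, decoder
#' 256/512, tanh output of gene dimension); the discriminator stacks dense
#' layers 512/256/128 with batch normalization and leaky-ReLU (alpha 0.2)
#' before a single linear unit; the classifier ("target model") stacks ReLU
#' dense layers 1024/512/128 before a one-logit-per-class head.
#'
#' @param n_genes input/output dimension (number of genes).
#' @param n_classes number of classes (target model).
#' @param encoder_widths,decoder_widths,widths hidden-layer widths.
#' @param n_residual_blocks number of width-preserving residual blocks.
#' @return a config list of the corresponding class.
#' @name network_configs
NULL

#' @rdname network_configs
#' @export
generator_config <- function(n_genes, encoder_widths = c(512L, 256L, 128L),
                             n_residual_blocks = 3L,
                             decoder_widths = c(256L, 512L)) {
  stopifnot(n_genes >= 1, all(encoder_widths > 0), all(decoder_widths > 0),
            n_residual_blocks >= 0)
  structure(list(n_genes = as.integer(n_genes),
                 encoder_widths = as.integer(encoder_widths),
                 n_residual_blocks = as.integer(n_residual_blocks),
                 decoder_widths = as.integer(decoder_widths)),
            class = "generator_config")
}

#' @rdname network_configs
#' @export
discriminator_config <- function(n_genes, widths = c(512L, 256L, 128L)) {
  stopifnot(n_genes >= 1, all(widths > 0))
  structure(list(n_genes = as.integer(n_genes), widths = as.integer(widths)),
            class = "discriminator_config")
}

#' @rdname network_configs
#' @export
target_model_config <- function(n_genes, n_classes,
                                widths = c(1024L, 512L, 128L)) {
  stopifnot(n_genes >= 1, n_classes >= 2, all(widths > 0))
  structure(list(n_genes = as.integer(n_genes), n_classes = as.integer(n_classes),
                 widths = as.integer(widths)),
            class = "target_model_config")
}

#' Loss-term weights for the generator objective
#'
#' The generator objective is the weighted sum of four terms: the
#' least-squares GAN term, the classifier margin ("adversarial") term, the
#' L2 penalty on the perturbation, and the L1 target-distribution term. All
#' weights default to 1, giving the plain sum; `kappa` is the confidence
#' margin of the adversarial term (default 0).
#'
#' @param w_gan,w_adv,w_norm,w_td non-negative term weights.
#' @param kappa confidence margin (>= 0 is typical; 0 by default).
#' @param td_reduction reduction used for the target-distribution term
#'   during training: `"sum"` (default) is the raw L1 distance, whose
#'   per-gene gradient is scale-matched to the L2 magnitude term; with
#'   `"gene_mean"` the term is divided by gene count, making it
#'   independent of gene-set size but much weaker than the other terms at
#'   realistic gene counts.
#' @return an object of class `loss_weights`.
#' @export
loss_weights <- function(w_gan = 1, w_adv = 1, w_norm = 1, w_td = 1, kappa = 0,
                         td_reduction = c("sum", "gene_mean")) {
  stopifnot(w_gan >= 0, w_adv >= 0, w_norm >= 0, w_td >= 0)
  structure(list(w_gan = w_gan, w_adv = w_adv, w_norm = w_norm, w_td = w_td,
                 kappa = kappa, td_reduction = match.arg(td_reduction)),
            class = "loss_weights")
}

# ---- loss terms -------------------------------------------------------------

#' Least-squares GAN losses
#'
#' Uses the canonical least-squares objective (real target 1, fake target 0,
#' generator target 1): `L_D = mean((D_real - 1)^2)/2 + mean(D_fake^2)/2`
#' and `L_G = mean((D_fake - 1)^2)/2`.
#'
#' @param d_real discriminator outputs on real target-class samples.
#' @param d_fake discriminator outputs on adversarial samples.
#' @return a list with scalars `L_D` and `L_G_gan`.
#' @examples
#' gan_losses(1, 0) # perfect discriminator: L_D = 0, L_G_gan = 0.5
#' @export
gan_losses <- function(d_real, d_fake) {
  d_real <- as.numeric(d_real); d_fake <- as.numeric(d_fake)
  if (length(d_real) == 0 || length(d_fake) == 0) {
    stop("empty minibatch", call. = FALSE)
  }
  if (any(!is.finite(d_real)) || any(!is.finite(d_fake))) {
    stop("non-finite discriminator outputs", call. = FALSE)
  }
  list(L_D = 0.5 * mean((d_real - 1)^2) + 0.5 * mean(d_fake^2),
       L_G_gan = 0.5 * mean((d_fake - 1)^2))
}

#' Classifier margin ("adversarial") loss
#'
#' Margin loss on pre-softmax logits: per sample,
#' `max(max_{i != t} z_i - z_t, kappa)`. It is zero (at `kappa = 0`) exactly
#' when the target class already attains the largest logit; minimizing it
#' pushes the classifier's decision toward the target class. For a minibatch
#' (matrix of logits, samples as rows) the mean of per-sample values is
#' returned.
#'
#' @param logits numeric vector (one sample) or matrix (samples x classes)
#'   of pre-softmax class scores.
#' @param target target class index (1-based).
#' @param kappa confidence margin (default 0).
#' @return scalar loss.
#' @examples
#' adversarial_loss(c(5, 1, 2), target = 1) # 0: target dominates
#' adversarial_loss(c(1, 5, 2), target = 1) # 4
#' @export
adversarial_loss <- function(logits, target, kappa = 0) {
  z <- as_row_matrix(logits)
  if (ncol(z) < 2) stop("need at least two classes", call. = FALSE)
  if (target < 1 || target > ncol(z)) stop("invalid target index", call. = FALSE)
  others <- apply(z[, -target, drop = FALSE], 1, max)
  mean(pmax(others - z[, target], kappa))
}

#' L2 perturbation magnitude loss
#'
#' Euclidean norm of the perturbation vector; for a minibatch (matrix,
#' samples as rows), the mean of per-sample norms.
#'
#' @param P perturbation vector or samples x genes matrix.
#' @return scalar loss.
#' @examples
#' norm_loss(c(3, 4)) # 5
#' @export
norm_loss <- function(P) {
  P <- as_row_matrix(P)
  mean(sqrt(rowSums(P * P)))
}

#' L1 target-distribution loss
#'
#' L1 distance between an adversarial sample and a random draw `r_t` from
#' the target-class distribution, averaged over genes (so the term's scale
#' does not grow with gene-set size; set `reduction = "sum"` for the raw L1
#' sum). For minibatches, the mean over samples, each paired with its own
#' row of `r_t`.
#'
#' @param x_adv adversarial sample vector or matrix (samples x genes).
#' @param r_t target vector(s), same shape.
#' @param reduction `"gene_mean"` (default) or `"sum"`.
#' @return scalar loss.
#' @export
target_distribution_loss <- function(x_adv, r_t, reduction = c("gene_mean", "sum")) {
  reduction <- match.arg(reduction)
  x_adv <- as_row_matrix(x_adv); r_t <- as_row_matrix(r_t)
  if (!all(dim(x_adv) == dim(r_t))) {
    stop("x_adv and r_t must have the same dimensions", call. = FALSE)
  }
  per_sample <- rowSums(abs(x_adv - r_t))
  if (reduction == "gene_mean") per_sample <- per_sample / ncol(x_adv)
  mean(per_sample)
}

#' Total generator loss
#'
#' Weighted sum of the four generator loss terms; with default weights this
#' is their plain sum.
#'
#' @param parts list (or `loss_breakdown`) with `L_gan`, `L_adv`, `L_norm`,
#'   `L_td`.
#' @param weights a [loss_weights()].
#' @return scalar total loss.
#' @export
total_generator_loss <- function(parts, weights = loss_weights()) {
  stopifnot(inherits(weights, "loss_weights"))
  with(parts, weights$w_gan * L_gan + weights$w_adv * L_adv +
         weights$w_norm * L_norm + weights$w_td * L_td)
}

loss_breakdown <- function(L_gan, L_adv, L_norm, L_td, weights = loss_weights()) {
  parts <- list(L_gan = L_gan, L_adv = L_adv, L_norm = L_norm, L_td = L_td)
  parts$L_total <- total_generator_loss(parts, weights)
  parts
}

# ---- target-class statistics ------------------------------------------------

#' Per-class mean and diagonal covariance
#'
#' Computes the per-gene mean `mu` and per-gene population variance
#' (`sigma_diag`, the diagonal of the class covariance) over the samples of
#' one class. These parametrize the Gaussian from which target anchor
#' vectors `r_t` are drawn for the target-distribution loss. The covariance
#' is kept diagonal: with far more genes than samples a full covariance is
#' singular, while diagonal sampling is well defined at any dimension.
#'
#' @param x a labeled [gem()].
#' @param label class label.
#' @return an object of class `class_stats` with fields `label`, `mu`,
#'   `sigma_diag`, `n`.
#' @export
class_stats <- function(x, label) {
  stopifnot(inherits(x, "gem"))
  if (is.null(gem_labels(x))) stop("gem has no labels", call. = FALSE)
  keep <- gem_labels(x) == label
  if (sum(keep) < 2) {
    stop(sprintf("need >= 2 samples labeled '%s' (found %d)", label, sum(keep)),
         call. = FALSE)
  }
  v <- gem_values(x)[keep, , drop = FALSE]
  mu <- colMeans(v)
  sigma_diag <- colMeans(v * v) - mu * mu
  sigma_diag <- pmax(sigma_diag, 0)
  structure(list(label = label, mu = mu, sigma_diag = sigma_diag,
                 n = sum(keep)),
            class = "class_stats")
}

#' Draw target anchor vectors from class statistics
#'
#' Draws `r_t ~ N(mu_t, diag(sigma_t))` independently per gene. Values are
#' not clipped to [0, 1]: the loss uses the draw as written.
#'
#' @param stats a [class_stats()].
#' @param n number of draws.
#' @param seed optional seed for a reproducible draw.
#' @return an `n` x genes matrix.
#' @export
sample_target_vector <- function(stats, n = 1, seed = NULL) {
  stopifnot(inherits(stats, "class_stats"))
  draw <- function() {
    g <- length(stats$mu)
    m <- matrix(rnorm(n * g), n, g)
    m <- sweep(m, 2, sqrt(stats$sigma_diag), "*")
    m <- sweep(m, 2, stats$mu, "+")
    colnames(m) <- names(stats$mu)
    m
  }
  if (is.null(seed)) draw() else withr_seed(seed, draw())
}

#' Apply a trained generator to samples
#'
#' Runs the generator in inference mode (frozen batch-norm statistics) on
#' one sample vector or a samples x genes matrix in [0, 1]. The output is
#' the perturbation `P` in [-1, 1] (tanh-bounded), not yet added to the
#' input.
#'
#' @param G a trained generator (from [train_generator()]).
#' @param x sample vector or matrix, values in [0, 1], genes in the
#'   generator's gene order.
#' @return perturbation of the same shape as `x`.
#' @export
apply_generator <- function(G, x) {
  net <- if (inherits(G, "gempert_generator")) G$net else G
  vec_in <- !is.matrix(x)
  xm <- as_row_matrix(x)
  if (ncol(xm) != net$n_in) {
    stop(sprintf("sample has %d genes, generator expects %d", ncol(xm), net$n_in),
         call. = FALSE)
  }
  P <- net_fwd(net, xm, training = FALSE)$out
  colnames(P) <- colnames(xm)
  if (vec_in) P <- stats::setNames(as.numeric(P), colnames(xm))
  P
}
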