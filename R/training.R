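#' Training hyperparameters
#'
#' Defaults are the standard recipe for this architecture: Adam with
#' learning rates 0.0002 (generator), 0.0001 (discriminator) and 0.001
#' (classifier); the classifier trains for 30 epochs with minibatches of 32
#' on a stratified 90/10 split, the GAN for 150 epochs with minibatches of
#' 128 on a stratified 80/20 split.
#'
#' @param lr_generator,lr_discriminator,lr_target Adam learning rates.
#' @param target_epochs,target_batch classifier training schedule.
#' @param gan_epochs,gan_batch GAN training schedule.
#' @param target_holdout_fraction,gan_holdout_fraction held-out fractions
#'   per class, in (0, 1).
#' @param seed master seed for splits, initialization and shuffling.
#' @param target_class label of the class perturbations are aimed at
#'   (may also be given directly to [train_generator()]).
#' @return an object of class `training_config`.
#' @export
training_config <- function(lr_generator = 2e-4, lr_discriminator = 1e-4,
                            lr_target = 1e-3,
                            target_epochs = 30L, target_batch = 32L,
                            gan_epochs = 150L, gan_batch = 128L,
                            target_holdout_fraction = 0.10,
                            gan_holdout_fraction = 0.20,
                            seed = 42L, target_class = NULL) {
  stopifnot(lr_generator > 0, lr_discriminator > 0, lr_target > 0,
            target_epochs >= 1, target_batch >= 1, gan_epochs >= 1,
            gan_batch >= 1,
            target_holdout_fraction > 0, target_holdout_fraction < 1,
            gan_holdout_fraction > 0, gan_holdout_fraction < 1)
  structure(list(
    lr_generator = lr_generator, lr_discriminator = lr_discriminator,
    lr_target = lr_target,
    target_epochs = as.integer(target_epochs),
    target_batch = as.integer(target_batch),
    gan_epochs = as.integer(gan_epochs), gan_batch = as.integer(gan_batch),
    target_holdout_fraction = target_holdout_fraction,
    gan_holdout_fraction = gan_holdout_fraction,
    seed = as.integer(seed), target_class = target_class
  ), class = "training_config")
}

#' Stratified train/holdout split
#'
#' Splits the samples of each class at random so that approximately
#' `holdout_fraction` of every class is held out. Each class appears in both
#' partitions whenever it has at least two samples; a single-sample class
#' goes entirely to training with a warning.
#'
#' @param x a labeled [gem()].
#' @param holdout_fraction fraction of each class to hold out, in (0, 1).
#' @param seed integer seed.
#' @return a list with `gem` elements `train` and `test`.
#' @export
split_stratified <- function(x, holdout_fraction, seed = 42L) {
  stopifnot(inherits(x, "gem"), holdout_fraction > 0, holdout_fraction < 1)
  if (is.null(gem_labels(x))) stop("gem has no labels", call. = FALSE)
  ids <- sample_ids(x)
  labs <- gem_labels(x)
  test_ids <- withr_seed(seed, {
    unlist(lapply(unique(labs), function(cl) {
      members <- ids[labs == cl]
      n <- length(members)
      if (n < 2) {
        warning(sprintf("class '%s' has a single sample; kept in training", cl),
                call. = FALSE)
        return(character())
      }
      n_test <- min(max(round(n * holdout_fraction), 1L), n - 1L)
      sample(members, n_test)
    }), use.names = FALSE)
  })
  train_ids <- setdiff(ids, test_ids)
  list(train = subset_samples(x, train_ids),
       test = subset_samples(x, test_ids))
}

# Shuffled minibatch index sets for one epoch.
epoch_batches <- function(n, batch_size) {
  idx <- sample.int(n)
  split(idx, ceiling(seq_along(idx) / batch_size))
}

one_hot <- function(labels, levels) {
  m <- matrix(0, length(labels), length(levels))
  m[cbind(seq_along(labels), match(labels, levels))] <- 1
  m
}

#' Train the expression classifier ("target model")
#'
#' Fits the multi-class dense classifier with softmax cross-entropy and
#' Adam on a stratified split of `x` (fraction
#' `config$target_holdout_fraction` held out), and reports held-out
#' accuracy. The fitted model is the frozen oracle the generator is later
#' trained to fool.
#'
#' @param x a labeled [gem()] in `"minmax"` state.
#' @param config a [training_config()].
#' @return an object of class `gempert_target` with elements `net`,
#'   `classes`, `gene_ids`, `holdout_accuracy`, `history` (per-epoch tibble),
#'   `holdout_ids`, `config`.
#' @export
train_target_model <- function(x, config = training_config()) {
  stopifnot(inherits(x, "gem"), inherits(config, "training_config"))
  if (is.null(gem_labels(x))) stop("gem has no labels", call. = FALSE)
  classes <- sort(unique(gem_labels(x)))
  if (length(classes) < 2) stop("need at least two classes", call. = FALSE)

  parts <- split_stratified(x, config$target_holdout_fraction, seed = config$seed)
  xtr <- gem_values(parts$train)
  ytr <- one_hot(gem_labels(parts$train), classes)
  net <- withr_seed(config$seed, make_target_net(ncol(xtr), length(classes)))
  opt <- adam_init(net_params(net))

  history <- vector("list", config$target_epochs)
  for (epoch in seq_len(config$target_epochs)) {
    batches <- withr_seed(config$seed + epoch, epoch_batches(nrow(xtr), config$target_batch))
    ep_loss <- 0; ep_correct <- 0
    for (b in batches) {
      xb <- xtr[b, , drop = FALSE]
      yb <- ytr[b, , drop = FALSE]
      fw <- net_fwd(net, xb, training = TRUE, keep_cache = TRUE)
      net <- fw$net
      p <- softmax_rows(fw$out)
      loss <- -mean(rowSums(yb * log(pmax(p, 1e-12))))
      if (!is.finite(loss)) {
        stop(sprintf("non-finite classifier loss at epoch %d", epoch), call. = FALSE)
      }
      dlogits <- (p - yb) / nrow(xb)
      grads <- net_bwd(net, fw$caches, dlogits)$grads
      upd <- adam_step(net_params(net), grads, opt, config$lr_target)
      net <- net_set_params(net, upd$params)
      opt <- upd$state
      ep_loss <- ep_loss + loss * nrow(xb)
      ep_correct <- ep_correct + sum(max.col(p) == max.col(yb))
    }
    history[[epoch]] <- tibble::tibble(
      epoch = epoch, loss = ep_loss / nrow(xtr), train_accuracy = ep_correct / nrow(xtr))
  }

  model <- structure(list(
    net = net, classes = classes, gene_ids = gene_ids(x),
    history = dplyr::bind_rows(history), holdout_ids = sample_ids(parts$test),
    config = config
  ), class = "gempert_target")
  model$holdout_accuracy <-
    mean(predict(model, parts$test) == gem_labels(parts$test))
  model
}

#' Predict classes, probabilities or logits from a trained classifier
#'
#' @param object a `gempert_target` from [train_target_model()].
#' @param newdata a [gem()], sample vector or samples x genes matrix with
#'   the model's genes in order.
#' @param type `"class"` (default), `"prob"` or `"logit"`.
#' @param ... unused.
#' @return a character vector of class labels, or a samples x classes matrix.
#' @export
predict.gempert_target <- function(object, newdata,
                                   type = c("class", "prob", "logit"), ...) {
  type <- match.arg(type)
  xm <- if (inherits(newdata, "gem")) gem_values(newdata) else as_row_matrix(newdata)
  if (ncol(xm) != length(object$gene_ids)) {
    stop(sprintf("input has %d genes, model expects %d",
                 ncol(xm), length(object$gene_ids)), call. = FALSE)
  }
  logits <- net_fwd(object$net, xm, training = FALSE)$out
  colnames(logits) <- object$classes
  switch(type,
    logit = logits,
    prob = softmax_rows(logits),
    class = object$classes[max.col(logits, ties.method = "first")]
  )
}

#' Train the perturbation generator against a frozen classifier
#'
#' Trains the generator/discriminator pair on a stratified split of `x`
#' (fraction `config$gan_holdout_fraction` held out), with the classifier
#' `target` frozen throughout. Each minibatch takes one discriminator step
#' (least-squares loss on real target-class samples vs clipped adversarial
#' samples) followed by one generator step minimizing the weighted sum of
#' the GAN, classifier-margin, L2-magnitude and L1 target-distribution
#' terms. Target anchor vectors `r_t` are drawn per sample per minibatch
#' from the target class's diagonal Gaussian fitted on the training
#' partition.
#'
#' @param x a labeled [gem()] in `"minmax"` state (the same data the
#'   classifier was trained on).
#' @param target a frozen `gempert_target`.
#' @param config a [training_config()]; `target_class` must be set here or
#'   via `target_class`.
#' @param weights a [loss_weights()].
#' @param target_class target class label (overrides `config$target_class`).
#' @return an object of class `gempert_generator` with elements `net`
#'   (generator), `d_net` (discriminator), `target_label`, `gene_ids`,
#'   `stats` (target-class [class_stats()]), `loss_log` (per-epoch tibble),
#'   `holdout_ids`, `config`, `weights`.
#' @export
train_generator <- function(x, target, config = training_config(),
                            weights = loss_weights(), target_class = NULL) {
  stopifnot(inherits(x, "gem"), inherits(target, "gempert_target"),
            inherits(config, "training_config"), inherits(weights, "loss_weights"))
  target_class <- target_class %||% config$target_class
  if (is.null(target_class)) stop("target_class must be given", call. = FALSE)
  if (!target_class %in% gem_labels(x)) {
    stop(sprintf("target class '%s' not present in labels", target_class),
         call. = FALSE)
  }
  if (!identical(gene_ids(x), target$gene_ids)) {
    stop("gene order differs between data and classifier", call. = FALSE)
  }
  t_idx <- match(target_class, target$classes)
  n_genes <- ncol(gem_values(x))

  parts <- split_stratified(x, config$gan_holdout_fraction,
                            seed = config$seed + 1L)
  xtr <- gem_values(parts$train)
  stats <- class_stats(parts$train, target_class)
  real_pool <- xtr[gem_labels(parts$train) == target_class, , drop = FALSE]

  gnet <- withr_seed(config$seed + 2L, make_generator_net(n_genes))
  dnet <- withr_seed(config$seed + 3L, make_discriminator_net(n_genes))
  g_opt <- adam_init(net_params(gnet))
  d_opt <- adam_init(net_params(dnet))
  sd_t <- sqrt(stats$sigma_diag)

  loss_log <- vector("list", config$gan_epochs)
  for (epoch in seq_len(config$gan_epochs)) {
    set_epoch <- config$seed + 1000L + epoch
    ep <- withr_seed(set_epoch, {
      batches <- epoch_batches(nrow(xtr), config$gan_batch)
      acc <- c(L_gan = 0, L_adv = 0, L_norm = 0, L_td = 0, L_D = 0,
               n = 0, n_valid = 0)
      for (b in batches) {
        xb <- xtr[b, , drop = FALSE]
        nb <- nrow(xb)

        ## ---- discriminator step ----
        P <- net_fwd(gnet, xb, training = TRUE)$out
        x_adv <- pmin(pmax(xb + P, 0), 1)
        real <- real_pool[sample.int(nrow(real_pool), nb, replace = TRUE), ,
                          drop = FALSE]
        fr <- net_fwd(dnet, real, training = TRUE, keep_cache = TRUE)
        dnet <- fr$net
        ff <- net_fwd(dnet, x_adv, training = TRUE, keep_cache = TRUE)
        dnet <- ff$net
        ld <- gan_losses(fr$out, ff$out)$L_D
        g_real <- net_bwd(dnet, fr$caches, (fr$out - 1) / nb)$grads
        g_fake <- net_bwd(dnet, ff$caches, ff$out / nb)$grads
        d_grads <- param_map(`+`, g_real, g_fake)
        upd <- adam_step(net_params(dnet), d_grads, d_opt, config$lr_discriminator)
        dnet <- net_set_params(dnet, upd$params)
        d_opt <- upd$state

        ## ---- generator step ----
        fg <- net_fwd(gnet, xb, training = TRUE, keep_cache = TRUE)
        gnet <- fg$net
        P <- fg$out
        pre_clip <- xb + P
        x_adv <- pmin(pmax(pre_clip, 0), 1)
        clip_mask <- (pre_clip > 0) & (pre_clip < 1)

        fd <- net_fwd(dnet, x_adv, training = TRUE, keep_cache = TRUE)
        dnet <- fd$net
        l_gan <- 0.5 * mean((fd$out - 1)^2)
        dx_gan <- net_bwd(dnet, fd$caches, (fd$out - 1) / nb)$dx

        fl <- net_fwd(target$net, x_adv, training = FALSE, keep_cache = TRUE)
        logits <- fl$out
        others <- apply(logits[, -t_idx, drop = FALSE], 1, which.max)
        other_idx <- seq_len(ncol(logits))[-t_idx][others]
        margin <- logits[cbind(seq_len(nb), other_idx)] - logits[, t_idx]
        l_adv <- mean(pmax(margin, weights$kappa))
        dlogits <- matrix(0, nb, ncol(logits))
        active <- margin > weights$kappa
        dlogits[cbind(which(active), other_idx[active])] <- 1 / nb
        dlogits[cbind(which(active), rep(t_idx, sum(active)))] <- -1 / nb
        dx_adv_f <- net_bwd(target$net, fl$caches, dlogits)$dx

        norms <- sqrt(rowSums(P * P))
        l_norm <- mean(norms)
        dP_norm <- P / pmax(norms, 1e-12) / nb
        dP_norm[norms == 0, ] <- 0

        r_t <- sweep(matrix(rnorm(nb * n_genes), nb, n_genes), 2, sd_t, "*")
        r_t <- sweep(r_t, 2, stats$mu, "+")
        diff <- x_adv - r_t
        td_scale <- if (weights$td_reduction == "gene_mean") n_genes else 1
        l_td <- mean(rowSums(abs(diff))) / td_scale
        dx_td <- sign(diff) / (nb * td_scale)

        dx_adv <- weights$w_gan * dx_gan + weights$w_adv * dx_adv_f +
          weights$w_td * dx_td
        dP <- dx_adv * clip_mask + weights$w_norm * dP_norm
        g_grads <- net_bwd(gnet, fg$caches, dP)$grads
        upd <- adam_step(net_params(gnet), g_grads, g_opt, config$lr_generator)
        gnet <- net_set_params(gnet, upd$params)
        g_opt <- upd$state

        total <- weights$w_gan * l_gan + weights$w_adv * l_adv +
          weights$w_norm * l_norm + weights$w_td * l_td
        if (!is.finite(total) || !is.finite(ld)) {
          stop(sprintf("non-finite GAN loss at epoch %d", epoch), call. = FALSE)
        }
        acc <- acc + c(l_gan * nb, l_adv * nb, l_norm * nb, l_td * nb,
                       ld * nb, nb,
                       sum(max.col(logits, ties.method = "first") == t_idx))
      }
      acc
    })
    n <- ep[["n"]]
    loss_log[[epoch]] <- tibble::tibble(
      epoch = epoch,
      L_gan = ep[["L_gan"]] / n, L_adv = ep[["L_adv"]] / n,
      L_norm = ep[["L_norm"]] / n, L_td = ep[["L_td"]] / n,
      L_total = (weights$w_gan * ep[["L_gan"]] + weights$w_adv * ep[["L_adv"]] +
                 weights$w_norm * ep[["L_norm"]] + weights$w_td * ep[["L_td"]]) / n,
      L_D = ep[["L_D"]] / n,
      train_attack_success = ep[["n_valid"]] / n
    )
  }

  structure(list(
    net = gnet, d_net = dnet, target_label = target_class,
    gene_ids = gene_ids(x), stats = stats,
    loss_log = dplyr::bind_rows(loss_log),
    holdout_ids = sample_ids(parts$test),
    config = config, weights = weights
  ), class = "gempert_generator")
}
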