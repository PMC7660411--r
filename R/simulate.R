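#' Specification for a synthetic multi-class expression matrix
#'
#' Describes the desk-scale stand-in for a multi-tissue expression cohort:
#' each class gets a per-gene mean drawn uniformly on
#' `[class_mean_low, class_mean_high]`, and each sample is its class mean
#' plus i.i.d. Gaussian noise, clipped to [0, 1]. Independent per-gene class
#' means yield strongly separated classes at moderate noise, mimicking the
#' dominant tissue signal of large expression compendia.
#'
#' @param n_classes number of classes (>= 2).
#' @param n_genes number of genes.
#' @param samples_per_class samples per class (>= 2).
#' @param class_mean_low,class_mean_high bounds for the per-class per-gene
#'   mean, within [0, 1].
#' @param noise_sd standard deviation of the additive Gaussian noise, on the
#'   [0, 1] expression scale.
#' @param seed integer seed making the simulation reproducible.
#' @return an object of class `simulation_spec`.
#' @export
simulation_spec <- function(n_classes = 10, n_genes = 200, samples_per_class = 50,
                            class_mean_low = 0, class_mean_high = 1,
                            noise_sd = 0.05, seed = 42) {
  stopifnot(n_classes >= 2, samples_per_class >= 2, n_genes >= 1,
            class_mean_low >= 0, class_mean_high <= 1,
            class_mean_low < class_mean_high, noise_sd >= 0)
  structure(
    list(n_classes = as.integer(n_classes), n_genes = as.integer(n_genes),
         samples_per_class = as.integer(samples_per_class),
         class_mean_low = class_mean_low, class_mean_high = class_mean_high,
         noise_sd = noise_sd, seed = as.integer(seed)),
    class = "simulation_spec"
  )
}

#' Simulate a multi-class expression matrix
#'
#' @param spec a [simulation_spec()].
#' @return a [gem()] in `"minmax"` state with labels `"class_0"`,
#'   `"class_1"`, ... and an attribute `"class_means"` (classes x genes
#'   matrix of the drawn means) for downstream checks.
#' @examples
#' g <- simulate_gem(simulation_spec(n_classes = 3, n_genes = 20,
#'                                   samples_per_class = 5, seed = 1))
#' table(gem_labels(g))
#' @export
simulate_gem <- function(spec) {
  stopifnot(inherits(spec, "simulation_spec"))
  withr_seed(spec$seed, {
    means <- matrix(
      runif(spec$n_classes * spec$n_genes, spec$class_mean_low, spec$class_mean_high),
      nrow = spec$n_classes
    )
    n <- spec$n_classes * spec$samples_per_class
    labels <- rep(paste0("class_", seq_len(spec$n_classes) - 1L),
                  each = spec$samples_per_class)
    v <- means[rep(seq_len(spec$n_classes), each = spec$samples_per_class), ,
               drop = FALSE]
    v <- v + matrix(rnorm(n * spec$n_genes, sd = spec$noise_sd), nrow = n)
    v <- pmin(pmax(v, 0), 1)
    dimnames(v) <- list(sprintf("sample_%04d", seq_len(n)),
                        sprintf("gene_%04d", seq_len(spec$n_genes)))
    rownames(means) <- paste0("class_", seq_len(spec$n_classes) - 1L)
    colnames(means) <- colnames(v)
    out <- gem(v, labels = labels, norm_state = "minmax")
    attr(out, "class_means") <- means
    out
  })
}

#' Ground truth for a planted tumor/normal contrast
#'
#' @param up_genes gene ids raised in the tumor class (tumor-upregulated).
#' @param down_genes gene ids lowered in the tumor class; disjoint from
#'   `up_genes`.
#' @param delta effect magnitude on the [0, 1] scale, in (0, 1].
#' @return an object of class `planted_truth`.
#' @export
planted_truth <- function(up_genes, down_genes, delta = 0.4) {
  up_genes <- as.character(up_genes); down_genes <- as.character(down_genes)
  if (length(intersect(up_genes, down_genes)) > 0) {
    stop("up_genes and down_genes must be disjoint", call. = FALSE)
  }
  stopifnot(delta > 0, delta <= 1)
  structure(list(up_genes = up_genes, down_genes = down_genes, delta = delta),
            class = "planted_truth")
}

#' Simulate a paired tumor/normal cohort with planted differential genes
#'
#' Two classes, `"normal"` and `"tumor"`, share a per-gene mean vector except
#' on the planted genes: the tumor mean is shifted by `+delta` on `up_genes`
#' and `-delta` on `down_genes` (clipped to [0, 1]). Class means for
#' non-planted genes are identical in expectation, so any perturbation an
#' analysis recovers on them is a false positive. To keep the planted effect
#' at full strength, normal means for planted genes are drawn in
#' `[0.05, 1 - delta - 0.05]` (up genes) or `[delta + 0.05, 0.95]`
#' (down genes) so the shift is never clipped away.
#'
#' @param base a [simulation_spec()]; `n_classes` is ignored (always 2) and
#'   `samples_per_class`, `n_genes`, `noise_sd`, `seed` are honoured.
#' @param truth a [planted_truth()] whose gene ids must be among the
#'   simulated gene ids (`gene_0001`, ...).
#' @return a list with `gem` (labels `"normal"`/`"tumor"`, `"minmax"` state)
#'   and `truth` (the `planted_truth`, echoed back).
#' @export
simulate_paired_tumor <- function(base, truth) {
  stopifnot(inherits(base, "simulation_spec"), inherits(truth, "planted_truth"))
  ids <- sprintf("gene_%04d", seq_len(base$n_genes))
  unknown <- setdiff(c(truth$up_genes, truth$down_genes), ids)
  if (length(unknown) > 0) {
    stop(sprintf("planted gene(s) not among simulated genes: %s",
                 paste(unknown, collapse = ", ")), call. = FALSE)
  }
  delta <- truth$delta
  withr_seed(base$seed, {
    normal_mean <- runif(base$n_genes, base$class_mean_low, base$class_mean_high)
    names(normal_mean) <- ids
    pad <- 0.05
    up <- match(truth$up_genes, ids)
    down <- match(truth$down_genes, ids)
    lo_up <- pmin(pad, 1 - delta); hi_up <- max(1 - delta - pad, pad)
    if (length(up) > 0) normal_mean[up] <- runif(length(up), lo_up, hi_up)
    if (length(down) > 0) normal_mean[down] <- runif(length(down),
                                                     min(delta + pad, 1 - pad),
                                                     1 - pad)
    tumor_mean <- normal_mean
    tumor_mean[up] <- pmin(tumor_mean[up] + delta, 1)
    tumor_mean[down] <- pmax(tumor_mean[down] - delta, 0)

    n <- 2L * base$samples_per_class
    means <- rbind(normal = normal_mean, tumor = tumor_mean)
    labels <- rep(c("normal", "tumor"), each = base$samples_per_class)
    v <- means[rep(1:2, each = base$samples_per_class), , drop = FALSE]
    v <- v + matrix(rnorm(n * base$n_genes, sd = base$noise_sd), nrow = n)
    v <- pmin(pmax(v, 0), 1)
    dimnames(v) <- list(sprintf("sample_%04d", seq_len(n)), ids)
    out <- gem(v, labels = labels, norm_state = "minmax")
    attr(out, "class_means") <- means
    list(gem = out, truth = truth)
  })
}

# Run code with a temporarily-seeded RNG, restoring the caller's RNG state.
withr_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  code
}
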