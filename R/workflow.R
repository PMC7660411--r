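#' Derive a reproducible per-stage seed from a master seed
#'
#' One master seed fans out to independent per-stage seeds (a small
#' polynomial hash of the stage name folded into the master seed), so
#' individual stages can be rerun independently yet reproducibly.
#'
#' @param seed master integer seed.
#' @param stage stage name.
#' @return an integer seed in `[0, 2^31 - 1)`.
#' @export
derive_seed <- function(seed, stage) {
  h <- 0
  for (ch in utf8ToInt(stage)) h <- (h * 131 + ch) %% 1013904223
  as.integer((as.numeric(seed) * 2654435761 + h) %% 2147483647)
}

#' Run the full perturbation workflow
#'
#' Ties the stages together: `simulate` writes a synthetic GEM + labels;
#' `train-target` fits the classifier; `train-gan` fits the generator
#' against the frozen classifier; `perturb` perturbs the GAN-stage holdout
#' samples toward the target class; `analyze` thresholds each perturbation
#' vector into significant gene lists. Artifacts and a manifest JSON
#' (inputs, seeds, config hash, key metrics) are written under `out_dir`;
#' rerunning with the same config and seed reproduces the manifest metrics.
#'
#' @param steps subset of `c("simulate", "train-target", "train-gan",
#'   "perturb", "analyze")`, in dependency order.
#' @param out_dir output directory (created if absent); also where earlier
#'   steps' artifacts are looked up when resuming.
#' @param gem_path,labels_path input GEM and label files (ignored when
#'   `simulate` is among the steps); the GEM must already be normalized to
#'   [0, 1] or `normalize` must be TRUE.
#' @param normalize run the log2/quantile/min-max chain on the input GEM.
#' @param geneset optional gene set (character vector or one-row
#'   [read_gmt()] slice) to subset to before scaling.
#' @param spec a [simulation_spec()] for the `simulate` step.
#' @param truth optional [planted_truth()]: simulate the paired
#'   tumor/normal design instead of the multi-class one.
#' @param config a [training_config()]; its `seed` is overridden by `seed`.
#' @param weights a [loss_weights()].
#' @param target_class target class label (defaults to `"class_0"` for
#'   multi-class simulations and `"normal"` for paired ones).
#' @param k threshold multiplier for the `analyze` step.
#' @param semantics direction naming for the `analyze` step (see
#'   [significant_genes()]).
#' @param dge_path optional external DGE table for the `analyze` step.
#' @param seed master seed.
#' @param verbose print per-stage progress.
#' @return the manifest, invisibly (a named list, also written to
#'   `out_dir/manifest.json`).
#' @export
run_workflow <- function(steps = c("simulate", "train-target", "train-gan",
                                   "perturb", "analyze"),
                         out_dir,
                         gem_path = NULL, labels_path = NULL, normalize = FALSE,
                         geneset = NULL,
                         spec = simulation_spec(), truth = NULL,
                         config = training_config(), weights = loss_weights(),
                         target_class = NULL, k = 2,
                         semantics = "tumor_to_normal",
                         dge_path = NULL,
                         seed = 42L, verbose = FALSE) {
  all_steps <- c("simulate", "train-target", "train-gan", "perturb", "analyze")
  steps <- match.arg(steps, all_steps, several.ok = TRUE)
  steps <- all_steps[all_steps %in% steps]
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  say <- function(...) if (verbose) message(sprintf(...))
  manifest_path <- file.path(out_dir, "manifest.json")
  manifest <- if (file.exists(manifest_path)) {
    jsonlite::read_json(manifest_path)
  } else list()
  manifest$master_seed <- seed
  need <- function(file, step, maker) {
    if (!file.exists(file)) {
      stop(sprintf("missing artifact '%s': run the '%s' step first",
                   basename(file), step), call. = FALSE)
    }
  }

  gem_file <- file.path(out_dir, "gem.txt")
  labels_file <- file.path(out_dir, "labels.txt")
  target_file <- file.path(out_dir, "target_model.rds")
  gan_file <- file.path(out_dir, "generator.rds")

  if ("simulate" %in% steps) {
    s_seed <- derive_seed(seed, "simulate")
    spec$seed <- s_seed
    if (is.null(truth)) {
      g <- simulate_gem(spec)
    } else {
      g <- simulate_paired_tumor(spec, truth)$gem
      jsonlite::write_json(unclass(truth), file.path(out_dir, "truth.json"),
                           auto_unbox = TRUE, digits = NA)
    }
    write_gem(g, gem_file)
    write_labels(g, labels_file)
    manifest$simulate <- list(seed = s_seed, n_samples = nrow(gem_values(g)),
                              n_genes = ncol(gem_values(g)),
                              config_hash = rlang::hash(spec))
    say("simulate: %d samples x %d genes", nrow(gem_values(g)), ncol(gem_values(g)))
  }

  load_gem <- function() {
    if (!is.null(gem_path) && !"simulate" %in% steps) {
      g <- read_gem(gem_path)
      if (!is.null(labels_path)) g <- set_labels(g, read_labels(labels_path))
      if (normalize) {
        g <- normalize_gem(g, genes = geneset)$gem
      } else {
        g$norm_state <- "minmax"
        g <- validate_gem(g)
      }
      g
    } else {
      need(gem_file, "simulate")
      g <- read_gem(gem_file)
      g <- set_labels(g, read_labels(labels_file))
      g$norm_state <- "minmax"
      validate_gem(g)
    }
  }

  default_target <- function(g) {
    target_class %||% config$target_class %||%
      (if ("normal" %in% gem_labels(g)) "normal" else "class_0")
  }

  if ("train-target" %in% steps) {
    g <- load_gem()
    cfg <- config
    cfg$seed <- derive_seed(seed, "train-target")
    model <- train_target_model(g, cfg)
    saveRDS(model, target_file)
    manifest$train_target <- list(
      seed = cfg$seed, holdout_accuracy = model$holdout_accuracy,
      n_classes = length(model$classes), config_hash = rlang::hash(cfg))
    say("train-target: holdout accuracy %.1f%%", 100 * model$holdout_accuracy)
  }

  if ("train-gan" %in% steps) {
    g <- load_gem()
    need(target_file, "train-target")
    model <- readRDS(target_file)
    cfg <- config
    cfg$seed <- derive_seed(seed, "train-gan")
    tc <- default_target(g)
    gen <- train_generator(g, model, cfg, weights, target_class = tc)
    saveRDS(gen, gan_file)
    fin <- gen$loss_log[nrow(gen$loss_log), ]
    manifest$train_gan <- list(
      seed = cfg$seed, target_class = tc,
      final_loss = fin$L_total,
      train_attack_success = fin$train_attack_success,
      config_hash = rlang::hash(list(cfg, weights)))
    say("train-gan: target '%s', final loss %.3f", tc, fin$L_total)
  }

  if ("perturb" %in% steps) {
    g <- load_gem()
    need(gan_file, "train-gan")
    need(target_file, "train-target")
    gen <- readRDS(gan_file)
    model <- readRDS(target_file)
    holdout <- subset_samples(g, intersect(gen$holdout_ids, sample_ids(g)))
    records <- perturb_gem(gen, model, holdout)
    rate <- attack_success_rate(records)
    per_sample <- dplyr::bind_rows(lapply(seq_len(nrow(records)), function(i) {
      tibble::tibble(gene_id = names(records$x[[i]]),
                     sample_id = records$sample_id[[i]],
                     x = records$x[[i]], P = records$P[[i]],
                     x_adv = records$x_adv[[i]])
    }))
    utils::write.table(per_sample, file.path(out_dir, "perturbations.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    saveRDS(records, file.path(out_dir, "perturbations.rds"))
    manifest$perturb <- list(
      n_samples = nrow(records), attack_success = rate,
      n_valid = sum(records$valid))
    say("perturb: attack success %.1f%% on %d holdout samples", rate,
        nrow(records))
  }

  if ("analyze" %in% steps) {
    rec_file <- file.path(out_dir, "perturbations.rds")
    need(rec_file, "perturb")
    records <- readRDS(rec_file)
    results <- lapply(seq_len(nrow(records)), function(i) {
      significant_genes(records[i, ], k = k, semantics = semantics)
    })
    names(results) <- records$sample_id
    sig_tab <- dplyr::bind_rows(lapply(results, function(r) {
      dplyr::mutate(dplyr::filter(r$genes, .data$sign != "none"),
                    sample_id = r$sample_id, .before = 1)
    }))
    utils::write.table(sig_tab, file.path(out_dir, "significant_genes.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    counts <- purrr::map(results, function(r) {
      list(positive = length(r$positive_genes),
           negative = length(r$negative_genes))
    })
    manifest$analyze <- list(k = k, semantics = semantics,
                             significant_counts = counts)
    if (length(results) >= 2) {
      for (d in c("tumor_up", "tumor_down")) {
        om <- pairwise_overlap_matrix(results, direction = d)
        write_overlap_matrix(om, file.path(out_dir, paste0("overlap_", d)),
                             write_png = FALSE)
      }
    }
    if (!is.null(dge_path)) {
      dge <- read_dge_table(dge_path)
      ov <- dplyr::bind_rows(lapply(names(results), function(id) {
        dplyr::mutate(dge_overlap(results[[id]], dge), sample_id = id,
                      .before = 1)
      }))
      jsonlite::write_json(ov, file.path(out_dir, "dge_overlap.json"),
                           auto_unbox = TRUE, digits = NA)
      manifest$analyze$dge_overlap <- ov$formatted
    }
    say("analyze: %d samples thresholded at k = %g", length(results), k)
  }

  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(manifest)
}
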