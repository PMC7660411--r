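# Shared fixtures, built in code.

# Tiny labeled gem with known values.
tiny_gem <- function() {
  m <- matrix(c(0.1, 0.2, 0.3,
                0.9, 0.8, 0.7,
                0.2, 0.1, 0.4,
                0.8, 0.9, 0.6), nrow = 4, byrow = TRUE,
              dimnames = list(paste0("s", 1:4), paste0("g", 1:3)))
  gem(m, labels = c("a", "b", "a", "b"), norm_state = "minmax")
}

# A generator object whose output is a constant perturbation, for testing
# the perturbation bookkeeping independently of training. Built by zeroing
# the final layer and setting its bias to atanh(P).
constant_generator <- function(P, target_label = "b") {
  n <- length(P)
  net <- gempert:::make_generator_net(n)
  last <- length(net$layers)
  net$layers[[last]]$par$W[] <- 0
  net$layers[[last]]$par$b <- atanh(P)
  structure(list(net = net, target_label = target_label,
                 gene_ids = names(P) %||% sprintf("g%d", seq_len(n)),
                 stats = NULL, loss_log = NULL, holdout_ids = character(),
                 config = NULL, weights = loss_weights()),
            class = "gempert_generator")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# A significance_result with prescribed tumor-up/tumor-down lists, built by
# planting P = -1 (tumor-up under tumor_to_normal semantics) / +1 on a flat
# background; k = 1 flags exactly the planted genes.
make_fixed_result <- function(up, down, n = 100, id = "fixed") {
  P <- setNames(rep(0, n), sprintf("g%03d", seq_len(n)))
  P[up] <- -1
  P[down] <- 1
  significant_genes(P, k = 1, semantics = "tumor_to_normal", sample_id = id)
}

# Small trained model pair shared across test files (trained once per run).
.fixture_cache <- new.env(parent = emptyenv())

small_trained <- function() {
  if (!is.null(.fixture_cache$small)) return(.fixture_cache$small)
  g <- simulate_gem(simulation_spec(n_classes = 3, n_genes = 40,
                                    samples_per_class = 20, seed = 909))
  cfg <- training_config(target_epochs = 10, target_batch = 16,
                         gan_epochs = 30, gan_batch = 32, seed = 17)
  f <- train_target_model(g, cfg)
  gen <- train_generator(g, f, cfg, target_class = "class_0")
  .fixture_cache$small <- list(gem = g, config = cfg, target = f, generator = gen)
  .fixture_cache$small
}
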