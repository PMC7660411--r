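test_that("stratified split honours per-class fractions and partitions", {
  g <- simulate_gem(simulation_spec(n_classes = 3, n_genes = 10,
                                    samples_per_class = 10, seed = 4))
  parts <- split_stratified(g, 0.10, seed = 2)
  for (cl in unique(gem_labels(g))) {
    expect_equal(sum(gem_labels(parts$train) == cl), 9L)
    expect_equal(sum(gem_labels(parts$test) == cl), 1L)
  }
  expect_setequal(c(sample_ids(parts$train), sample_ids(parts$test)),
                  sample_ids(g))
  expect_length(intersect(sample_ids(parts$train), sample_ids(parts$test)), 0)

  # fraction 0.5 on 2-sample classes -> 1/1
  g2 <- simulate_gem(simulation_spec(n_classes = 2, n_genes = 5,
                                     samples_per_class = 2, seed = 6))
  parts2 <- split_stratified(g2, 0.5, seed = 1)
  expect_equal(as.vector(table(gem_labels(parts2$train))), c(1L, 1L))
  expect_equal(as.vector(table(gem_labels(parts2$test))), c(1L, 1L))

  # reproducible
  expect_identical(split_stratified(g, 0.2, seed = 7)$test$values,
                   split_stratified(g, 0.2, seed = 7)$test$values)
})

test_that("a single-sample class stays in training with a warning", {
  m <- matrix(runif(4 * 3), 4, 3,
              dimnames = list(paste0("s", 1:4), paste0("g", 1:3)))
  g <- gem(m, labels = c("a", "a", "a", "lonely"), norm_state = "minmax")
  expect_warning(parts <- split_stratified(g, 0.3, seed = 1), "lonely")
  expect_true("s4" %in% sample_ids(parts$train))
})

test_that("classifier training validates inputs and is seed-reproducible", {
  g <- small_trained()$gem
  cfg <- training_config(target_epochs = 3, target_batch = 16, seed = 5)
  single <- g
  single$labels <- rep("only", nrow(gem_values(g)))
  expect_error(train_target_model(single, cfg), "two classes")

  m1 <- train_target_model(g, cfg)
  m2 <- train_target_model(g, cfg)
  expect_identical(gempert:::net_params(m1$net), gempert:::net_params(m2$net))
  expect_identical(m1$holdout_accuracy, m2$holdout_accuracy)
})

test_that("classifier learns well-separated classes (vs multinomial oracle)", {
  skip_if_not_installed("nnet")
  fx <- small_trained()
  expect_gte(fx$target$holdout_accuracy, 0.95)
  # independent oracle: multinomial logistic regression on the same split
  parts <- split_stratified(fx$gem, fx$config$target_holdout_fraction,
                            seed = fx$config$seed)
  df <- data.frame(y = factor(gem_labels(parts$train)), gem_values(parts$train))
  fit <- nnet::multinom(y ~ ., df, trace = FALSE, MaxNWts = 5000)
  pred <- predict(fit, data.frame(gem_values(parts$test)))
  expect_gte(mean(pred == gem_labels(parts$test)), 0.95)
})

test_that("the frozen classifier is bitwise unchanged by GAN training", {
  fx <- small_trained()
  before <- serialize(gempert:::net_params(fx$target$net), NULL)
  cfg <- training_config(target_epochs = 2, gan_epochs = 2, gan_batch = 16,
                         seed = 33)
  invisible(train_generator(fx$gem, fx$target, cfg, target_class = "class_1"))
  after <- serialize(gempert:::net_params(fx$target$net), NULL)
  expect_identical(before, after)
})

test_that("GAN training logs one row per epoch satisfying the breakdown invariant", {
  fx <- small_trained()
  log <- fx$generator$loss_log
  expect_equal(nrow(log), fx$config$gan_epochs)
  expect_equal(log$L_total,
               log$L_gan + log$L_adv + log$L_norm + log$L_td,
               tolerance = 1e-6)
  expect_true(all(log$L_adv >= 0))
  expect_true(all(log$L_norm >= 0))
  expect_true(all(log$L_td >= 0))
})

test_that("GAN training requires the target class and matching genes", {
  fx <- small_trained()
  cfg <- training_config(gan_epochs = 1, seed = 1)
  expect_error(train_generator(fx$gem, fx$target, cfg, target_class = "nope"),
               "not present")
  shuffled <- fx$gem
  shuffled$values <- shuffled$values[, rev(gene_ids(fx$gem))]
  expect_error(train_generator(shuffled, fx$target, cfg, target_class = "class_0"),
               "gene order")
})

test_that("a norm-only objective shrinks the perturbation magnitude", {
  g <- simulate_gem(simulation_spec(n_classes = 2, n_genes = 20,
                                    samples_per_class = 10, seed = 19))
  cfg <- training_config(target_epochs = 2, gan_epochs = 15, gan_batch = 16,
                         seed = 20)
  f <- train_target_model(g, cfg)
  gen <- train_generator(g, f, cfg, loss_weights(0, 0, 1, 0),
                         target_class = "class_0")
  expect_lt(gen$loss_log$L_norm[nrow(gen$loss_log)], gen$loss_log$L_norm[1])
})

test_that("GAN training is reproducible from (data, config, seed)", {
  g <- simulate_gem(simulation_spec(n_classes = 2, n_genes = 15,
                                    samples_per_class = 8, seed = 21))
  cfg <- training_config(target_epochs = 2, gan_epochs = 3, gan_batch = 8,
                         seed = 22)
  f <- train_target_model(g, cfg)
  g1 <- train_generator(g, f, cfg, target_class = "class_0")
  g2 <- train_generator(g, f, cfg, target_class = "class_0")
  expect_identical(gempert:::net_params(g1$net), gempert:::net_params(g2$net))
  expect_identical(g1$loss_log, g2$loss_log)
})

test_that("perturbation concentrates on class-separating genes", {
  # the first 8 genes carry the class signal; the rest are shared noise
  set.seed(23)
  n <- 40
  base <- runif(32, 0.3, 0.7)
  m <- matrix(0, 2 * n, 40)
  sig_a <- runif(8, 0.05, 0.25); sig_b <- runif(8, 0.75, 0.95)
  for (i in seq_len(n)) {
    m[i, ] <- c(sig_a, base) + rnorm(40, sd = 0.04)
    m[n + i, ] <- c(sig_b, base) + rnorm(40, sd = 0.04)
  }
  m <- pmin(pmax(m, 0), 1)
  dimnames(m) <- list(sprintf("s%03d", seq_len(2 * n)), sprintf("g%02d", 1:40))
  g <- gem(m, labels = rep(c("a", "b"), each = n), norm_state = "minmax")
  cfg <- training_config(target_epochs = 10, target_batch = 16,
                         gan_epochs = 60, gan_batch = 32, seed = 24)
  f <- train_target_model(g, cfg)
  gen <- train_generator(g, f, cfg, target_class = "b")
  rec <- perturb_gem(gen, f, subset_samples(g, gen$holdout_ids))
  P <- do.call(rbind, rec$P[rec$source_label == "a"])
  expect_gt(median(abs(P[, 1:8])), median(abs(P[, 9:40])))
})
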