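test_that("least-squares GAN losses match their closed forms", {
  expect_equal(gan_losses(1, 0), list(L_D = 0, L_G_gan = 0.5))
  expect_equal(gan_losses(0, 1), list(L_D = 1.0, L_G_gan = 0))
  expect_error(gan_losses(numeric(), 1), "empty")

  set.seed(11)
  for (i in 1:20) {
    dr <- rnorm(7); df <- rnorm(5)
    got <- gan_losses(dr, df)
    # independent elementwise recomputation
    expect_equal(got$L_D, sum((dr - 1)^2) / (2 * 7) + sum(df^2) / (2 * 5))
    expect_equal(got$L_G_gan, sum((df - 1)^2) / (2 * 5))
  }
})

test_that("margin loss is zero iff the target logit dominates", {
  expect_equal(adversarial_loss(c(5, 1, 2), target = 1), 0)
  expect_equal(adversarial_loss(c(1, 5, 2), target = 1), 4)
  expect_error(adversarial_loss(matrix(1, 2, 1), target = 1), "two classes")

  set.seed(12)
  for (i in 1:200) {
    z <- rnorm(sample(2:6, 1))
    t <- sample(length(z), 1)
    kappa <- sample(c(0, 0.3), 1)
    brute <- max(max(z[-t]) - z[t], kappa)
    expect_equal(adversarial_loss(z, t, kappa), brute)
    if (kappa == 0) {
      expect_equal(adversarial_loss(z, t) == 0, which.max(z) == t || max(z[-t]) <= z[t])
    }
  }
  # minibatch reduction is the mean of per-sample values
  z <- rbind(c(5, 1, 2), c(1, 5, 2))
  expect_equal(adversarial_loss(z, 1), mean(c(0, 4)))
})

test_that("perturbation magnitude loss is the Euclidean norm", {
  expect_equal(norm_loss(c(0, 0, 0)), 0)
  expect_equal(norm_loss(c(3, 4)), 5)
  set.seed(13)
  P <- matrix(rnorm(12), 3, 4)
  expect_equal(norm_loss(P), mean(apply(P, 1, function(r) sqrt(sum(r^2)))))
})

test_that("target-distribution loss is per-gene mean L1 (sum optional)", {
  expect_equal(target_distribution_loss(c(1, 2), c(1, 2)), 0)
  expect_equal(target_distribution_loss(c(0, 1), c(1, 0)), 1.0)
  expect_equal(target_distribution_loss(c(0, 1), c(1, 0), reduction = "sum"), 2)
  expect_error(target_distribution_loss(1:3, 1:2), "dimensions")
  set.seed(14)
  x <- matrix(rnorm(20), 4, 5); r <- matrix(rnorm(20), 4, 5)
  expect_equal(target_distribution_loss(x, r),
               mean(rowSums(abs(x - r)) / 5))
})

test_that("total generator loss is the weighted sum of the four terms", {
  parts <- list(L_gan = 1, L_adv = 1, L_norm = 1, L_td = 1)
  expect_equal(total_generator_loss(parts), 4)
  expect_equal(total_generator_loss(list(L_gan = 1, L_adv = 2, L_norm = 3, L_td = 4),
                                    loss_weights(0, 0, 0, 1)), 4)
  set.seed(15)
  for (i in 1:20) {
    p <- as.list(setNames(rnorm(4), c("L_gan", "L_adv", "L_norm", "L_td")))
    w <- runif(4)
    expect_equal(total_generator_loss(p, loss_weights(w[1], w[2], w[3], w[4])),
                 sum(unlist(p) * w))
  }
})

test_that("class statistics use the population variance convention", {
  m <- matrix(c(0, 1,
                1, 0), 2, 2, byrow = TRUE,
              dimnames = list(c("s1", "s2"), c("g1", "g2")))
  g <- gem(m, labels = c("t", "t"), norm_state = "minmax")
  st <- class_stats(g, "t")
  expect_equal(unname(st$mu), c(0.5, 0.5))
  expect_equal(unname(st$sigma_diag), c(0.25, 0.25))

  same_m <- m * 0 + 0.3
  same <- gem(same_m, labels = c("t", "t"), norm_state = "minmax")
  st2 <- class_stats(same, "t")
  expect_equal(unname(st2$mu), c(0.3, 0.3))
  expect_equal(unname(st2$sigma_diag), c(0, 0))

  set.seed(16)
  v <- matrix(runif(50), 10, 5,
              dimnames = list(sprintf("s%d", 1:10), sprintf("g%d", 1:5)))
  g3 <- gem(v, labels = rep("t", 10), norm_state = "minmax")
  st3 <- class_stats(g3, "t")
  expect_equal(st3$mu, colMeans(v))
  expect_equal(st3$sigma_diag, apply(v, 2, function(x) mean((x - mean(x))^2)))

  expect_error(class_stats(g3, "missing"), "2 samples")
})

test_that("target vector sampling is seeded and matches its Gaussian", {
  st <- structure(list(label = "t", mu = c(a = 0.2, b = 0.8),
                       sigma_diag = c(a = 0, b = 0), n = 5),
                  class = "class_stats")
  expect_equal(sample_target_vector(st)[1, ], c(a = 0.2, b = 0.8))

  st$sigma_diag <- c(a = 0.01, b = 0.04)
  d1 <- sample_target_vector(st, n = 3, seed = 9)
  d2 <- sample_target_vector(st, n = 3, seed = 9)
  expect_identical(d1, d2)

  draws <- sample_target_vector(st, n = 10000, seed = 10)
  tol <- 4 * sqrt(st$sigma_diag) / sqrt(10000)
  expect_true(all(abs(colMeans(draws) - st$mu) < tol))
})

test_that("generator output is tanh-bounded, deterministic, and zero for zero weights", {
  set.seed(17)
  gen <- constant_generator(rep(0, 6))
  x <- runif(6)
  expect_equal(unname(apply_generator(gen, x)), rep(0, 6))

  net <- gempert:::make_generator_net(8)
  xs <- matrix(runif(50 * 8), 50, 8)
  P <- gempert:::net_fwd(net, xs, training = FALSE)$out
  expect_true(max(abs(P)) <= 1)
  P2 <- gempert:::net_fwd(net, xs, training = FALSE)$out
  expect_identical(P, P2)
  expect_error(apply_generator(structure(list(net = net, gene_ids = letters[1:8]),
                                         class = "gempert_generator"),
                               runif(5)), "expects 8")
})

test_that("backpropagation matches finite-difference gradients", {
  set.seed(18)
  net <- gempert:::new_net(list(
    gempert:::new_dense(4, 6, act = "relu", bn = TRUE),
    gempert:::new_residual(6),
    gempert:::new_dense(6, 5, act = "lrelu", bn = TRUE),
    gempert:::new_dense(5, 3, act = "tanh", bn = FALSE)
  ), 4, 3)
  x <- matrix(runif(5 * 4), 5, 4)
  tgt <- matrix(rnorm(5 * 3), 5, 3)
  loss_of <- function(n) {
    o <- gempert:::net_fwd(n, x, training = TRUE)$out
    0.5 * sum((o - tgt)^2)
  }
  fw <- gempert:::net_fwd(net, x, training = TRUE, keep_cache = TRUE)
  analytic <- gempert:::net_bwd(fw$net, fw$caches, fw$out - tgt)$grads
  params <- gempert:::net_params(net)

  flat_paths <- list(list(1, "W"), list(1, "gamma"), list(1, "beta"),
                     list(2, "l1", "W"), list(2, "l2", "gamma"),
                     list(3, "W"), list(3, "b"), list(4, "W"), list(4, "b"))
  eps <- 1e-5
  for (path in flat_paths) {
    leaf <- purrr::reduce(path, function(acc, k) acc[[k]], .init = analytic)
    p_leaf <- purrr::reduce(path, function(acc, k) acc[[k]], .init = params)
    for (ii in sample(length(p_leaf), min(3, length(p_leaf)))) {
      poke <- function(delta) {
        p2 <- params
        expr <- p_leaf
        expr[ii] <- expr[ii] + delta
        p2 <- purrr::modify_in(p2, path, function(old) expr)
        loss_of(gempert:::net_set_params(net, p2))
      }
      numeric_grad <- (poke(eps) - poke(-eps)) / (2 * eps)
      expect_equal(leaf[ii], numeric_grad, tolerance = 1e-5)
    }
  }
})

test_that("loss breakdown satisfies its weighted-sum invariant", {
  w <- loss_weights(0.5, 2, 1, 0.25)
  parts <- gempert:::loss_breakdown(0.3, 1.2, 0.7, 2.0, w)
  expect_equal(parts$L_total,
               0.5 * 0.3 + 2 * 1.2 + 1 * 0.7 + 0.25 * 2.0, tolerance = 1e-6)
  expect_gte(parts$L_adv, 0)
})

test_that("network configs validate their architecture parameters", {
  expect_error(generator_config(0), "n_genes")
  expect_error(target_model_config(10, 1), "n_classes")
  expect_error(discriminator_config(10, widths = c(-1, 2)))
  cfg <- generator_config(50)
  expect_equal(cfg$encoder_widths, c(512L, 256L, 128L))
  expect_equal(cfg$decoder_widths, c(256L, 512L))
  expect_equal(cfg$n_residual_blocks, 3L)
})
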