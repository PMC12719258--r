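test_that("encode/decode round-trips and repair enforces the belief-sum constraint", {
  rb <- random_rulebase(3, n_classes = 3)
  p <- encode_params(rb)
  expect_equal(length(p), 6 + 2 + 18)
  rb2 <- decode_params(p, rb)
  expect_equal(encode_params(rb2), p, tolerance = 1e-12)
  # an over-complete belief row is rescaled proportionally
  p_bad <- p
  p_bad[6 + 2 + c(1, 7, 13)] <- c(0.9, 0.8, 0.7)  # rule 1 beliefs sum 2.4
  rb3 <- decode_params(p_bad, rb)
  expect_equal(sum(rb3$beta[1, ]), 1, tolerance = 1e-12)
  expect_equal(unname(rb3$beta[1, ] / rb3$beta[1, 1]),
               c(0.9, 0.8, 0.7) / 0.9, tolerance = 1e-12)
  # out-of-box components are clipped
  rb4 <- decode_params(pmin(p + 5, 5), rb)
  expect_true(all(encode_params(rb4) <= 1))
})

test_that("fitness blends accuracy and the distributional error as specified", {
  # a perfectly separating one-hot rule base scores 1 for any alpha
  fr <- brb_frame(list(x = c(0, 1)))
  rb <- brb_rulebase(fr, c("lo", "hi"), beta = rbind(c(1, 0), c(0, 1)))
  data <- data.frame(x = c(0, 0, 1, 1))
  labels <- c("lo", "lo", "hi", "hi")
  for (a in c(0, 0.3, 0.7, 1)) {
    expect_equal(brb_fitness(encode_params(rb), rb, data, labels, alpha = a), 1)
  }
  # alpha = 1 reduces to plain accuracy; alpha blends with the recomputed MAE
  set.seed(88)
  rb2 <- random_rulebase(21)
  data2 <- data.frame(u = stats::runif(50), v = stats::runif(50))
  labels2 <- sample(c("c1", "c2"), 50, replace = TRUE)
  p2 <- stats::runif(length(encode_params(rb2)))
  out <- infer_batch(decode_params(p2, rb2), data2)
  acc <- mean(colnames(out$masses)[apply(out$masses, 1, which.max)] == labels2)
  onehot <- cbind(labels2 == "c1", labels2 == "c2") * 1
  nmae <- mean(abs(out$masses - onehot))  # N/2 = 1 for two classes
  expect_equal(brb_fitness(p2, rb2, data2, labels2, alpha = 1), acc)
  expect_equal(brb_fitness(p2, rb2, data2, labels2, alpha = 0.7),
               0.7 * acc + 0.3 * (1 - nmae), tolerance = 1e-12)
  expect_error(brb_fitness(p2, rb2, data2[0, ], character(0)), "empty")
})

test_that("the DE-PSO cascade solves a 20-dim convex benchmark to < 1e-3", {
  sphere <- function(x) -sum((x - 0.5)^2)  # maximum 0 at 0.5
  cfg <- optimizer_config(NP = 50, F = 0.6, CR = 0.9)
  de <- de_stage(sphere, n_par = 20, config = cfg, generations = 100, seed = 4)
  expect_false(is.unsorted(de$history$best_fitness))
  ps <- pso_stage(sphere, cfg, generations = 100, seed = 5,
                  init_population = de$population, init_fitness = de$fitness)
  expect_gt(ps$best_fit, -1e-3)
  expect_gte(ps$best_fit, de$best_fit)
})

test_that("DE with F=0, CR=0 still never worsens the best", {
  set.seed(5)
  noisy <- function(x) sum(x)
  cfg <- optimizer_config(NP = 8, F = 1e-9, CR = 0, G = 20)
  res <- de_stage(noisy, n_par = 5, config = cfg, seed = 9)
  expect_false(is.unsorted(res$history$best_fitness))
})

test_that("DE and PSO are deterministic given the seed", {
  sphere <- function(x) -sum((x - 0.5)^2)
  cfg <- optimizer_config(NP = 10, G = 15)
  a <- de_stage(sphere, 6, cfg, seed = 42)
  b <- de_stage(sphere, 6, cfg, seed = 42)
  expect_identical(a$history, b$history)
  expect_identical(a$best_par, b$best_par)
  pa <- pso_stage(sphere, cfg, seed = 43, init_population = a$population,
                  init_fitness = a$fitness)
  pb <- pso_stage(sphere, cfg, seed = 43, init_population = b$population,
                  init_fitness = b$fitness)
  expect_identical(pa$history, pb$history)
  expect_identical(pa$best_par, pb$best_par)
})

test_that("PSO refines the DE handoff and a converged swarm is stationary", {
  sphere <- function(x) -sum((x - 0.5)^2)
  cfg <- optimizer_config(NP = 20, G = 30)
  de <- de_stage(sphere, 8, cfg, seed = 11)
  ps <- pso_stage(sphere, cfg, seed = 12, init_population = de$population,
                  init_fitness = de$fitness)
  expect_gte(ps$best_fit, de$best_fit)
  expect_false(is.unsorted(ps$history$best_fitness))
  # all particles at the same point with zero velocity: output = input best
  x0 <- matrix(0.5, 6, 4)
  st <- pso_stage(sphere, optimizer_config(NP = 6, G = 10), seed = 1,
                  init_population = x0)
  expect_equal(st$best_par, rep(0.5, 4))
  expect_equal(st$best_fit, 0)
})

test_that("cascaded training is reproducible and honors the validation pick", {
  gen <- recovery_rulebase()
  sim <- generate_from_rulebase(gen, 150, seed = 2)
  cfg <- optimizer_config(NP = 12, G = 20, seed = 6)
  rb0 <- brb_rulebase(gen$frame, gen$class_labels)
  f1 <- train_rulebase(rb0, sim$records[1:100, ], sim$labels[1:100],
                       sim$records[101:150, ], sim$labels[101:150], cfg)
  f2 <- train_rulebase(rb0, sim$records[1:100, ], sim$labels[1:100],
                       sim$records[101:150, ], sim$labels[101:150], cfg)
  expect_identical(encode_params(f1), encode_params(f2))
  expect_false(is.unsorted(attr(f1, "history")$best_fitness))
  expect_false(is.na(attr(f1, "val_fitness")))
})

test_that("training initialized at the generating parameters cannot lose fitness", {
  gen <- recovery_rulebase()
  sim <- generate_from_rulebase(gen, 120, seed = 14)
  cfg <- optimizer_config(NP = 10, G = 10, seed = 3)
  start_fit <- brb_fitness(encode_params(gen), gen, sim$records, sim$labels,
                           cfg$alpha)
  # seed the DE population with the generating parameters
  res <- de_stage(function(p) brb_fitness(p, gen, sim$records, sim$labels, cfg$alpha),
                  length(encode_params(gen)), cfg, seed = 3,
                  init = encode_params(gen))
  expect_gte(res$best_fit, start_fit)
})
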