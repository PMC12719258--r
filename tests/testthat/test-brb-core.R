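test_that("input transformation interpolates, hits references exactly and clamps", {
  refs <- c(1.50, 1.75, 2.00)
  expect_equal(transform_input(1.625, refs), c(0.5, 0.5, 0))
  expect_equal(transform_input(1.75, refs), c(0, 1, 0))
  expect_equal(transform_input(2.30, refs), c(0, 0, 1))
  expect_equal(transform_input(1.10, refs), c(1, 0, 0))
  expect_error(transform_input(1.6, c(1.5)), "reference")
  expect_error(transform_input(NaN, refs), "finite")
})

test_that("matching degrees always sum to 1 with at most two adjacent nonzeros", {
  set.seed(101)
  for (i in 1:200) {
    refs <- sort(stats::runif(sample(2:6, 1), -5, 5))
    while (any(diff(refs) < 1e-3)) refs <- sort(stats::runif(4, -5, 5))
    v <- stats::runif(1, -7, 7)
    m <- transform_input(v, refs)
    expect_equal(sum(m), 1, tolerance = 1e-12)
    expect_true(all(m >= 0))
    nz <- which(m > 0)
    expect_lte(length(nz), 2)
    if (length(nz) == 2) expect_equal(diff(nz), 1)
  }
})

test_that("activation weights follow the weighted product form", {
  # symmetric two-rule case
  rb <- brb_rulebase(brb_frame(list(x = c(0, 1))), c("a", "b"))
  expect_equal(activation_weights(rb, list(c(0.5, 0.5))), c(0.5, 0.5))
  # zero rule weight kills the rule
  rb0 <- brb_rulebase(brb_frame(list(x = c(0, 1))), c("a", "b"), theta = c(1, 0))
  expect_equal(activation_weights(rb0, list(c(0.3, 0.7)))[2], 0)
  # uniform theta and delta: activation equals the normalized matching product
  rb2 <- random_rulebase(5)
  rb2$theta <- rep(1, 6)
  rb2$delta <- c(1, 1)
  m <- list(c(0.2, 0.8, 0), c(0.4, 0.6))
  w <- activation_weights(rb2, m)
  raw <- m[[1]][rb2$antecedents[, 1]] * m[[2]][rb2$antecedents[, 2]]
  expect_equal(w, raw / sum(raw), tolerance = 1e-12)
})

test_that("activation matches a brute-force per-rule product oracle on random draws", {
  set.seed(77)
  for (rep in 1:1000) {
    rb <- random_rulebase(rep)
    m1 <- transform_input(stats::runif(1), rb$frame$reference_values$u)
    m2 <- transform_input(stats::runif(1), rb$frame$reference_values$v)
    w <- activation_weights(rb, list(m1, m2))
    dbar <- rb$delta / max(rb$delta)
    raw <- vapply(seq_len(6), function(k) {
      rb$theta[k] * m1[rb$antecedents[k, 1]]^dbar[1] * m2[rb$antecedents[k, 2]]^dbar[2]
    }, numeric(1))
    expect_equal(w, raw / sum(raw), tolerance = 1e-12)
    expect_equal(sum(w), 1, tolerance = 1e-12)
  }
})

test_that("single activated rule reproduces its beliefs; residual reflects incompleteness", {
  rb <- brb_rulebase(brb_frame(list(x = c(0, 1))), c("a", "b"),
                     beta = rbind(c(0.2, 0.8), c(0.3, 0.4)))
  d <- er_combine(rb, c(1, 0))
  expect_equal(unname(d$masses), c(0.2, 0.8))
  expect_equal(d$residual, 0)
  d2 <- er_combine(rb, c(0, 1))
  expect_equal(unname(d2$masses), c(0.3, 0.4))
  expect_equal(d2$residual, 0.3)
})

test_that("analytic ER equals the recursive pairwise oracle on random instances", {
  set.seed(20260919)
  worst <- 0
  for (i in 1:1000) {
    K <- sample(2:5, 1)
    N <- sample(2:4, 1)
    w <- stats::runif(K)
    w <- w / sum(w)
    beta <- matrix(stats::runif(K * N), K, N)
    beta <- beta / (rowSums(beta) * stats::runif(K, 1, 2))
    a <- dbrbc:::er_combine_masses(matrix(w, 1), beta)
    o <- oracle_er(w, beta)
    worst <- max(worst, abs(a$masses[1, ] - o$masses), abs(a$residual - o$residual))
  }
  expect_lt(worst, 1e-10)
})

test_that("ER combination is order-invariant under rule permutation", {
  set.seed(7)
  for (i in 1:50) {
    K <- sample(3:5, 1)
    N <- 3
    w <- stats::runif(K)
    w <- w / sum(w)
    beta <- matrix(stats::runif(K * N), K, N)
    beta <- beta / (rowSums(beta) * 1.3)
    p <- sample(K)
    a <- dbrbc:::er_combine_masses(matrix(w, 1), beta)
    b <- dbrbc:::er_combine_masses(matrix(w[p], 1), beta[p, , drop = FALSE])
    expect_equal(a$masses, b$masses, tolerance = 1e-12)
    expect_equal(a$residual, b$residual, tolerance = 1e-12)
  }
})

test_that("complete rule beliefs yield zero residual and masses summing to 1", {
  set.seed(13)
  for (i in 1:50) {
    K <- sample(2:5, 1)
    N <- sample(2:4, 1)
    w <- stats::runif(K)
    w <- w / sum(w)
    beta <- matrix(stats::runif(K * N), K, N)
    beta <- beta / rowSums(beta)  # complete
    a <- dbrbc:::er_combine_masses(matrix(w, 1), beta)
    expect_equal(a$residual[1], 0, tolerance = 1e-12)
    expect_equal(sum(a$masses[1, ]), 1, tolerance = 1e-12)
  }
})

test_that("forward inference composes the three stages (end-to-end oracle)", {
  set.seed(31)
  for (i in 1:40) {
    rb <- random_rulebase(1000 + i, n_classes = 3)
    rec <- list(u = stats::runif(1, -0.2, 1.2), v = stats::runif(1))
    d <- infer(rb, rec)
    o <- oracle_infer(rb, rec)
    expect_equal(unname(d$masses), unname(o$masses), tolerance = 1e-10)
    expect_equal(d$residual, unname(o$residual), tolerance = 1e-10)
  }
})

test_that("a record at a rule's antecedent point returns that rule's beliefs", {
  rb <- random_rulebase(9)
  k <- 4
  rec <- list(u = rb$frame$reference_values$u[rb$antecedents[k, 1]],
              v = rb$frame$reference_values$v[rb$antecedents[k, 2]])
  d <- infer(rb, rec)
  expect_equal(unname(d$masses), unname(rb$beta[k, ]), tolerance = 1e-9)
})

test_that("uniform rule bases infer uniform masses; missing attributes are named", {
  rb <- brb_rulebase(brb_frame(list(x = c(0, 1), y = c(0, 2))), c("a", "b"))
  d <- infer(rb, list(x = 0.31, y = 1.7))
  expect_equal(unname(d$masses), c(0.5, 0.5), tolerance = 1e-12)
  expect_error(infer(rb, list(x = 0.3)), "y")
})

test_that("decision takes the maximal mass with lowest-index tie break", {
  expect_equal(decide(c(a = 0.1, b = 0.9)), "b")
  expect_equal(decide(c(a = 0.5, b = 0.5)), "a")
  expect_equal(decide(c(0.2, 0.3, 0.5), labels = c("x", "y", "z")), "z")
})

test_that("rule counts multiply reference values over attributes", {
  expect_equal(rule_count(6, 3), 729)
  expect_equal(rule_count(2, 3), 9)
  expect_equal(rule_count(1, 2), 2)
  expect_equal(rule_count(refs_per_attribute = c(3, 4, 2)), 24)
  rb <- brb_rulebase(brb_frame(list(x = c(0, 0.5, 1), y = c(0, 1))), c("a", "b"))
  expect_equal(nrow(rb$antecedents), 6)
  expect_equal(nrow(unique(rb$antecedents)), 6)  # each combination once
})

test_that("rule-base JSON serialization round-trips losslessly", {
  rb <- random_rulebase(55, n_classes = 3)
  path <- withr::local_tempfile(fileext = ".json")
  write_rulebase(rb, path)
  rb2 <- read_rulebase(path)
  expect_equal(rb2$theta, rb$theta)
  expect_equal(rb2$delta, rb$delta)
  expect_equal(unname(rb2$beta), unname(rb$beta))
  expect_equal(rb2$frame$reference_values, rb$frame$reference_values)
  expect_equal(rb2$class_labels, rb$class_labels)
  rec <- list(u = 0.4, v = 0.6)
  expect_equal(infer(rb2, rec)$masses, infer(rb, rec)$masses)
})

test_that("frame and rule-base constructors validate their invariants", {
  expect_error(brb_frame(list(x = c(1, 1))), "increasing")
  expect_error(brb_frame(list(x = 1)), "at least 2")
  fr <- brb_frame(list(x = c(0, 1)))
  expect_error(brb_rulebase(fr, c("a", "b"), beta = rbind(c(0.9, 0.9), c(0, 0))),
               "sum to <= 1")
  expect_error(brb_rulebase(fr, c("a", "b"), delta = 0), "delta")
  expect_error(brb_rulebase(fr, "one"), "unique labels")
})
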