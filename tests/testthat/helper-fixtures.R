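# Shared fixtures and independent oracles for the test suite.

# Independent recursive (two-at-a-time) Dempster-style ER combination.
# Tracks the class masses and the two unassigned-mass components separately;
# serves as the oracle for the analytic closed form.
oracle_er <- function(weights, beta) {
  mn <- weights[1] * beta[1, ]
  mbar <- 1 - weights[1]
  mtil <- weights[1] * (1 - sum(beta[1, ]))
  for (k in seq_along(weights)[-1]) {
    m2 <- weights[k] * beta[k, ]
    mbar2 <- 1 - weights[k]
    mtil2 <- weights[k] * (1 - sum(beta[k, ]))
    mD <- mbar + mtil
    mD2 <- mbar2 + mtil2
    K <- 1 / (1 - (sum(mn) * sum(m2) - sum(mn * m2)))
    mn_new <- K * (mn * m2 + mn * mD2 + mD * m2)
    mbar_new <- K * mbar * mbar2
    mtil_new <- K * (mtil * mtil2 + mtil * mbar2 + mbar * mtil2)
    mn <- mn_new
    mbar <- mbar_new
    mtil <- mtil_new
  }
  list(masses = mn / (1 - mbar), residual = mtil / (1 - mbar))
}

# Straight-line reimplementation of the forward inference composition for
# one record (independent of the package's vectorized path).
oracle_infer <- function(rulebase, record) {
  frame <- rulebase$frame
  matching <- lapply(frame$attribute_names, function(a) {
    refs <- frame$reference_values[[a]]
    v <- min(max(record[[a]], refs[1]), refs[length(refs)])
    out <- numeric(length(refs))
    for (j in seq_len(length(refs) - 1)) {
      if (v >= refs[j] && v <= refs[j + 1]) {
        t <- (v - refs[j]) / (refs[j + 1] - refs[j])
        out[j] <- out[j] + (1 - t)
        out[j + 1] <- out[j + 1] + t
        break
      }
    }
    out
  })
  dbar <- rulebase$delta / max(rulebase$delta)
  L <- nrow(rulebase$antecedents)
  w <- numeric(L)
  for (k in seq_len(L)) {
    prod_a <- 1
    for (i in seq_along(matching)) {
      prod_a <- prod_a * matching[[i]][rulebase$antecedents[k, i]]^dbar[i]
    }
    w[k] <- rulebase$theta[k] * prod_a
  }
  w <- w / sum(w)
  oracle_er(w, rulebase$beta)
}

# random small rule base on 2 attributes (used across property tests)
random_rulebase <- function(seed, n_classes = 2) {
  set.seed(seed)
  fr <- brb_frame(list(u = sort(c(0, stats::runif(1, 0.3, 0.7), 1)),
                       v = c(0, 1)))
  L <- 3 * 2
  beta <- matrix(stats::runif(L * n_classes), L, n_classes)
  beta <- beta / (rowSums(beta) * stats::runif(L, 1, 1.6))
  brb_rulebase(fr, paste0("c", seq_len(n_classes)),
               theta = stats::runif(L, 0.2, 1),
               delta = stats::runif(2, 0.3, 1),
               beta = beta)
}

# session-cached trained hierarchy on the standard synthetic cohort; shared
# by the hierarchy, RCA and acceptance tests to keep the suite fast
.fixtures <- new.env(parent = emptyenv())

fixture_cohort <- function() {
  if (is.null(.fixtures$cohort)) .fixtures$cohort <- generate_cohort(30, seed = 42)
  .fixtures$cohort
}

fixture_trained <- function() {
  if (!is.null(.fixtures$trained)) return(.fixtures$trained)
  ds <- fixture_cohort()
  sp <- stratified_split(ds$fine_labels, seed = 7)
  tr <- ds$records[sp$train, ]
  model <- build_hierarchy(tr, ds$scheme,
                           fine_labels = ds$fine_labels[sp$train])
  model <- train_hierarchy(model, tr, ds$fine_labels[sp$train],
                           ds$records[sp$validation, ],
                           ds$fine_labels[sp$validation],
                           optimizer_config(G = 60, seed = 3))
  .fixtures$trained <- list(model = model, ds = ds, split = sp)
  .fixtures$trained
}
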