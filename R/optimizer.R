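#' Optimizer configuration for cascaded DE-PSO training
#'
#' Defaults follow the model's standard settings: population NP = 50, DE
#' scaling factor F = 0.6, crossover rate CR = 0.9, PSO inertia w = 0.7,
#' learning factors c1 = c2 = 1.5, a total budget of G = 200 generations and
#' fitness weight alpha = 0.7. `de_fraction` splits the total budget between
#' the DE stage (global exploration) and the PSO stage (local refinement);
#' default 0.5, i.e. 100 + 100 generations.
#'
#' @param NP Population size (>= 4).
#' @param F DE scaling factor in (0, 2].
#' @param CR DE crossover rate in \[0, 1\].
#' @param w PSO inertia weight.
#' @param c1,c2 PSO cognitive / social learning factors.
#' @param G Total generation budget (>= 1), shared by both stages.
#' @param alpha Fitness weight blending accuracy with the distributional
#'   error term, in \[0, 1\].
#' @param de_fraction Fraction of G given to the DE stage, in \[0, 1\].
#' @param vmax PSO per-dimension velocity clamp.
#' @param seed Integer RNG seed.
#' @return Object of class `optimizer_config`.
#' @export
optimizer_config <- function(NP = 50, F = 0.6, CR = 0.9, w = 0.7,
                             c1 = 1.5, c2 = 1.5, G = 200, alpha = 0.7,
                             de_fraction = 0.5, vmax = 0.2, seed = 1L) {
  stopifnot(NP >= 4, F > 0, F <= 2, CR >= 0, CR <= 1, G >= 1,
            alpha >= 0, alpha <= 1, de_fraction >= 0, de_fraction <= 1)
  structure(list(NP = as.integer(NP), F = F, CR = CR, w = w, c1 = c1, c2 = c2,
                 G = as.integer(G), alpha = alpha, de_fraction = de_fraction,
                 vmax = vmax, seed = as.integer(seed)),
            class = "optimizer_config")
}

# --- parameter vector encoding -------------------------------------------

# layout: theta (L), delta (T), beta (L*N, column-major)
param_length <- function(rulebase) {
  L <- nrow(rulebase$beta)
  L + ncol(rulebase$antecedents) + L * ncol(rulebase$beta)
}

#' Encode a rule base's free parameters as a flat unit-box vector
#'
#' Order: rule weights theta (L), attribute weights delta (T), belief
#' degrees beta (L x N, column-major). All entries lie in \[0, 1\].
#'
#' @param rulebase A [brb_rulebase()].
#' @return Numeric vector of length L + T + L*N.
#' @export
encode_params <- function(rulebase) {
  c(rulebase$theta, rulebase$delta, as.vector(rulebase$beta))
}

#' Decode (with repair) a flat parameter vector into a rule base
#'
#' Components are clipped to \[0, 1\]; rule and attribute weights are
#' floored at a small positive value (1e-6), so every decoded candidate
#' defines a usable inference; any rule whose beliefs
#' sum to more than 1 is rescaled proportionally so the belief-sum
#' constraint holds. `encode_params()` after decoding reproduces the
#' repaired vector exactly.
#'
#' @param params Flat parameter vector (see [encode_params()]).
#' @param rulebase Template [brb_rulebase()] supplying structure.
#' @return A `brb_rulebase` with the decoded parameters.
#' @export
decode_params <- function(params, rulebase) {
  L <- nrow(rulebase$beta)
  T_k <- ncol(rulebase$antecedents)
  N <- ncol(rulebase$beta)
  if (length(params) != L + T_k + L * N) {
    stop("parameter vector has the wrong length", call. = FALSE)
  }
  params <- pmin(pmax(params, 0), 1)
  # rule weights are floored at a small positive value so every decoded
  # candidate yields a well-defined activation (a search vector may zero
  # out all rules matched by some record otherwise)
  theta <- pmax(params[seq_len(L)], 1e-6)
  delta <- pmax(params[L + seq_len(T_k)], 1e-6)
  beta <- matrix(params[L + T_k + seq_len(L * N)], L, N)
  bs <- rowSums(beta)
  over <- bs > 1
  if (any(over)) beta[over, ] <- beta[over, , drop = FALSE] / bs[over]
  colnames(beta) <- rulebase$class_labels
  out <- rulebase
  out$theta <- theta
  out$delta <- delta
  out$beta <- beta
  out
}

# --- fitness --------------------------------------------------------------

#' Training fitness of a parameter vector
#'
#' Blended objective: `alpha * accuracy + (1 - alpha) * (1 - nMAE)`, where
#' nMAE is the mean absolute deviation between the combined output masses
#' and the one-hot encoding of the true labels, scaled by N/2 so it lies in
#' \[0, 1\]. A perfect classifier with one-hot outputs scores 1 for any
#' alpha; with alpha = 1 the fitness is plain accuracy.
#'
#' @param params Flat parameter vector ([encode_params()] layout); decoded
#'   with repair before evaluation.
#' @param rulebase Template [brb_rulebase()].
#' @param data Data frame of training records (frame attributes as columns).
#' @param labels True class labels (character, in the rule base's label set).
#' @param alpha Fitness weight in \[0, 1\]. Default 0.7.
#' @return Scalar fitness in \[0, 1\] (higher is better).
#' @export
brb_fitness <- function(params, rulebase, data, labels, alpha = 0.7) {
  if (nrow(as.data.frame(data)) == 0) stop("empty training set", call. = FALSE)
  rb <- decode_params(params, rulebase)
  fitness_of_rulebase(rb, data, labels, alpha)
}

fitness_of_rulebase <- function(rb, data, labels, alpha) {
  out <- infer_batch(rb, data)
  pred <- decide_batch(out$masses)
  acc <- mean(pred == labels)
  N <- ncol(out$masses)
  onehot <- matrix(0, nrow(out$masses), N)
  onehot[cbind(seq_along(labels), match(labels, colnames(out$masses)))] <- 1
  nmae <- (N / 2) * mean(abs(out$masses - onehot))
  alpha * acc + (1 - alpha) * (1 - nmae)
}

# --- DE stage -------------------------------------------------------------

#' Differential-evolution stage (DE/rand/1/bin, maximizing)
#'
#' Classic DE over the unit box: mutation `v = a + F (b - c)` with distinct
#' donors, binomial crossover with rate CR plus one guaranteed index,
#' clipping to \[0, 1\], and greedy one-to-one selection. Best-so-far fitness
#' is non-decreasing by construction.
#'
#' @param objective Function of a parameter vector returning a scalar
#'   fitness (maximized). Any decoding/repair happens inside `objective`.
#' @param n_par Problem dimension.
#' @param config An [optimizer_config()]; uses NP, F, CR.
#' @param generations Number of DE generations to run.
#' @param seed Integer RNG seed (deterministic trajectories).
#' @param init Optional matrix (rows = vectors) seeding the first rows of
#'   the population; remaining members are uniform random in \[0, 1\].
#' @return List: `best_par`, `best_fit`, `population`, `fitness`, `history`
#'   (data frame: generation, stage, best_fitness, mean_fitness), and
#'   `incumbents` (list of best-so-far vectors as they improved).
#' @export
de_stage <- function(objective, n_par, config = optimizer_config(),
                     generations = NULL, seed = config$seed, init = NULL) {
  if (is.null(generations)) generations <- config$G
  NP <- config$NP
  set.seed(seed)
  pop <- matrix(stats::runif(NP * n_par), NP, n_par)
  if (!is.null(init)) {
    init <- matrix(init, ncol = n_par)
    k <- min(nrow(init), NP)
    pop[seq_len(k), ] <- pmin(pmax(init[seq_len(k), , drop = FALSE], 0), 1)
  }
  fit <- apply(pop, 1L, objective)
  best_i <- which.max(fit)
  best_par <- pop[best_i, ]
  best_fit <- fit[best_i]
  incumbents <- list(best_par)
  history <- data.frame(generation = 0L, stage = "de",
                        best_fitness = best_fit, mean_fitness = mean(fit))
  for (g in seq_len(generations)) {
    for (i in seq_len(NP)) {
      donors <- sample(setdiff(seq_len(NP), i), 3L)
      v <- pop[donors[1L], ] + config$F * (pop[donors[2L], ] - pop[donors[3L], ])
      v <- pmin(pmax(v, 0), 1)
      cross <- stats::runif(n_par) < config$CR
      cross[sample.int(n_par, 1L)] <- TRUE
      trial <- ifelse(cross, v, pop[i, ])
      f_trial <- objective(trial)
      if (f_trial >= fit[i]) {
        pop[i, ] <- trial
        fit[i] <- f_trial
        if (f_trial > best_fit) {
          best_fit <- f_trial
          best_par <- trial
          incumbents[[length(incumbents) + 1L]] <- trial
        }
      }
    }
    history <- rbind(history,
                     data.frame(generation = g, stage = "de",
                                best_fitness = best_fit, mean_fitness = mean(fit)))
  }
  list(best_par = best_par, best_fit = best_fit, population = pop,
       fitness = fit, history = history, incumbents = incumbents)
}

# --- PSO stage ------------------------------------------------------------

#' Particle-swarm stage (cascaded from DE)
#'
#' Standard inertial PSO: `v <- w v + c1 r1 (pbest - x) + c2 r2 (gbest - x)`
#' with per-dimension velocity clamp and position clipping to \[0, 1\].
#' The swarm is seeded from the final DE population, so the returned best is
#' never worse than the DE-stage best (gbest is monotone).
#'
#' @inheritParams de_stage
#' @param init_population Matrix of initial particle positions (typically
#'   the DE stage's final population).
#' @param init_fitness Optional fitness of `init_population` rows (skips
#'   re-evaluation).
#' @return As [de_stage()] (history rows carry stage `"pso"`).
#' @export
pso_stage <- function(objective, config = optimizer_config(),
                      generations = NULL, seed = config$seed,
                      init_population, init_fitness = NULL) {
  if (is.null(generations)) generations <- config$G
  x <- as.matrix(init_population)
  NP <- nrow(x)
  n_par <- ncol(x)
  set.seed(seed)
  fit <- if (is.null(init_fitness)) apply(x, 1L, objective) else init_fitness
  v <- matrix(0, NP, n_par)
  pbest <- x
  pfit <- fit
  g_i <- which.max(pfit)
  gbest <- pbest[g_i, ]
  gfit <- pfit[g_i]
  incumbents <- list(gbest)
  history <- data.frame(generation = 0L, stage = "pso",
                        best_fitness = gfit, mean_fitness = mean(fit))
  for (g in seq_len(generations)) {
    r1 <- matrix(stats::runif(NP * n_par), NP, n_par)
    r2 <- matrix(stats::runif(NP * n_par), NP, n_par)
    v <- config$w * v + config$c1 * r1 * (pbest - x) +
      config$c2 * r2 * (matrix(gbest, NP, n_par, byrow = TRUE) - x)
    v <- pmin(pmax(v, -config$vmax), config$vmax)
    x <- pmin(pmax(x + v, 0), 1)
    fit <- apply(x, 1L, objective)
    improved <- fit > pfit
    pbest[improved, ] <- x[improved, , drop = FALSE]
    pfit[improved] <- fit[improved]
    if (max(pfit) > gfit) {
      g_i <- which.max(pfit)
      gbest <- pbest[g_i, ]
      gfit <- pfit[g_i]
      incumbents[[length(incumbents) + 1L]] <- gbest
    }
    history <- rbind(history,
                     data.frame(generation = g, stage = "pso",
                                best_fitness = gfit, mean_fitness = mean(fit)))
  }
  list(best_par = gbest, best_fit = gfit, population = x, fitness = fit,
       history = history, incumbents = incumbents)
}

# --- cascade --------------------------------------------------------------

# data-seeded initial member: theta = 1, delta = 1, beta from the
# activation-weighted class frequencies of the training records
seeded_member <- function(rulebase, data, labels) {
  ml <- matching_list(rulebase, data)
  W <- activation_matrix(rulebase, ml)
  N <- length(rulebase$class_labels)
  L <- nrow(rulebase$beta)
  beta <- matrix(0, L, N)
  for (n in seq_len(N)) {
    sel <- labels == rulebase$class_labels[n]
    if (any(sel)) beta[, n] <- colSums(W[sel, , drop = FALSE])
  }
  tot <- rowSums(beta)
  beta[tot > 0, ] <- beta[tot > 0, , drop = FALSE] / tot[tot > 0]
  beta[tot == 0, ] <- 1 / N
  c(rep(1, L), rep(1, ncol(rulebase$antecedents)), as.vector(beta))
}

#' Train a rule base with the cascaded DE-PSO strategy
#'
#' Runs the DE stage for `ceiling(de_fraction * G)` generations, hands the
#' final population to the PSO stage for the remaining generations, and
#' returns the rule base decoded from the parameter vector with the best
#' validation fitness among the best-so-far incumbents encountered (training
#' fitness when no validation set is given). The DE population is seeded
#' with one data-informed member (unit weights, activation-weighted class
#' frequency beliefs); the rest start uniform random.
#'
#' @param rulebase Template [brb_rulebase()] (structure and frame).
#' @param train_data,train_labels Training records and labels.
#' @param val_data,val_labels Optional validation records and labels
#'   (disjoint from training).
#' @param config An [optimizer_config()].
#' @return Trained `brb_rulebase` with attributes `history` (both stages),
#'   `train_fitness` and `val_fitness`.
#' @export
train_rulebase <- function(rulebase, train_data, train_labels,
                           val_data = NULL, val_labels = NULL,
                           config = optimizer_config()) {
  train_data <- as.data.frame(train_data)
  if (nrow(train_data) == 0) stop("empty training set", call. = FALSE)
  objective <- function(p) brb_fitness(p, rulebase, train_data, train_labels,
                                       config$alpha)
  n_par <- param_length(rulebase)
  g_de <- ceiling(config$de_fraction * config$G)
  g_pso <- config$G - g_de
  de <- de_stage(objective, n_par, config, generations = g_de,
                 seed = config$seed,
                 init = seeded_member(rulebase, train_data, train_labels))
  incumbents <- de$incumbents
  history <- de$history
  best_par <- de$best_par
  best_train <- de$best_fit
  if (g_pso > 0) {
    ps <- pso_stage(objective, config, generations = g_pso,
                    seed = config$seed + 1L,
                    init_population = de$population, init_fitness = de$fitness)
    incumbents <- c(incumbents, ps$incumbents)
    history <- rbind(history, ps$history)
    best_par <- ps$best_par
    best_train <- ps$best_fit
  }
  if (!is.null(val_data) && nrow(as.data.frame(val_data)) > 0) {
    val_fit <- vapply(incumbents, function(p) {
      brb_fitness(p, rulebase, as.data.frame(val_data), val_labels, config$alpha)
    }, numeric(1))
    best_par <- incumbents[[which.max(val_fit)]]
    best_val <- max(val_fit)
  } else {
    best_val <- NA_real_
  }
  out <- decode_params(best_par, rulebase)
  attr(out, "history") <- history
  attr(out, "train_fitness") <- best_train
  attr(out, "val_fitness") <- best_val
  out
}

#' Train every module of a dual-layer model
#'
#' The coarse rule base is trained on coarse labels; each submodule is
#' trained only on records whose ground-truth coarse label matches it
#' (teacher routing at training time; inference uses predicted routes).
#' Module seeds are derived deterministically from `config$seed`.
#'
#' @param model An untrained [dbrb_model()] (e.g. [build_hierarchy()]).
#' @param train_data,train_fine_labels Training records and fine labels.
#' @param val_data,val_fine_labels Optional validation records/labels.
#' @param config An [optimizer_config()].
#' @return The model with trained modules; per-module histories are kept as
#'   attributes on each rule base.
#' @export
train_hierarchy <- function(model, train_data, train_fine_labels,
                            val_data = NULL, val_fine_labels = NULL,
                            config = optimizer_config()) {
  stopifnot(inherits(model, "dbrb_model"))
  scheme <- model$scheme
  train_data <- as.data.frame(train_data)
  coarse_tr <- coarsen(train_fine_labels, scheme)
  has_val <- !is.null(val_data) && nrow(as.data.frame(val_data)) > 0
  coarse_val <- if (has_val) coarsen(val_fine_labels, scheme)
  cfg_m <- function(offset) {
    cfg <- config
    cfg$seed <- config$seed + offset
    cfg
  }
  model$coarse <- train_rulebase(
    model$coarse, train_data, coarse_tr,
    if (has_val) val_data, if (has_val) coarse_val, cfg_m(0L))
  for (gi in seq_along(scheme$coarse_labels)) {
    g <- scheme$coarse_labels[gi]
    sel <- coarse_tr == g
    if (!any(sel)) stop(sprintf("no training records for coarse group '%s'", g),
                        call. = FALSE)
    vsel <- if (has_val) coarse_val == g
    model$submodules[[g]] <- train_rulebase(
      model$submodules[[g]],
      train_data[sel, , drop = FALSE], train_fine_labels[sel],
      if (has_val && any(vsel)) val_data[vsel, , drop = FALSE],
      if (has_val && any(vsel)) val_fine_labels[vsel],
      cfg_m(100L * gi))
  }
  model
}
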