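# Reinforcement-learning conformer generator: a PPO-trained policy over
# discrete torsion moves that proposes low-energy, diverse conformers.
# One policy serves all protonation states of a given size: the state
# vector is sin/cos of all torsions plus a charge-location one-hot, and
# episodes sample charge classes during training.

# ---- small feed-forward nets with manual backprop -----------------------

.mlp_init <- function(sizes, seed) {
  .with_seed(seed, {
    layers <- list()
    for (k in seq_len(length(sizes) - 1)) {
      fan_in <- sizes[k]
      layers[[k]] <- list(
        W = matrix(stats::rnorm(fan_in * sizes[k + 1], sd = sqrt(1 / fan_in)),
                   fan_in, sizes[k + 1]),
        b = numeric(sizes[k + 1]))
    }
    layers
  })
}

# X: B x d. tanh hidden layers, linear output. Returns output + cache.
.mlp_forward <- function(net, X) {
  acts <- list(X)
  n <- length(net)
  for (k in seq_len(n)) {
    Z <- acts[[k]] %*% net[[k]]$W
    Z <- sweep(Z, 2, net[[k]]$b, "+")
    acts[[k + 1]] <- if (k < n) tanh(Z) else Z
  }
  list(out = acts[[n + 1]], acts = acts)
}

# dOut: B x out gradient of scalar loss wrt output. Returns per-layer grads.
.mlp_backward <- function(net, cache, dOut) {
  n <- length(net)
  grads <- vector("list", n)
  delta <- dOut
  for (k in rev(seq_len(n))) {
    A_prev <- cache$acts[[k]]
    grads[[k]] <- list(W = t(A_prev) %*% delta, b = colSums(delta))
    if (k > 1) {
      dA <- delta %*% t(net[[k]]$W)
      delta <- dA * (1 - cache$acts[[k]]^2)   # tanh'
    }
  }
  grads
}

.adam_init <- function(net) {
  lapply(net, function(l) list(mW = l$W * 0, vW = l$W * 0,
                               mb = l$b * 0, vb = l$b * 0, t = 0))
}

.adam_step <- function(net, grads, opt, lr, beta1 = 0.9, beta2 = 0.999,
                       eps = 1e-8) {
  for (k in seq_along(net)) {
    o <- opt[[k]]; g <- grads[[k]]
    o$t <- o$t + 1
    o$mW <- beta1 * o$mW + (1 - beta1) * g$W
    o$vW <- beta2 * o$vW + (1 - beta2) * g$W^2
    o$mb <- beta1 * o$mb + (1 - beta1) * g$b
    o$vb <- beta2 * o$vb + (1 - beta2) * g$b^2
    c1 <- 1 - beta1^o$t; c2 <- 1 - beta2^o$t
    net[[k]]$W <- net[[k]]$W - lr * (o$mW / c1) / (sqrt(o$vW / c2) + eps)
    net[[k]]$b <- net[[k]]$b - lr * (o$mb / c1) / (sqrt(o$vb / c2) + eps)
    opt[[k]] <- o
  }
  list(net = net, opt = opt)
}

.softmax <- function(z) {
  z <- z - max(z)
  e <- exp(z)
  e / sum(e)
}

# ---- configuration and training state -----------------------------------

#' Generator configuration
#'
#' @param angle_set discrete rotation increments (degrees); default
#'   `c(-120, -60, -30, 30, 60, 120, 180)`
#' @param horizon episode length; NULL means 3 x torsion count
#' @param w_energy,w_novelty reward weights
#' @param clip_ratio PPO clip ratio epsilon, in (0, 1)
#' @param lr learning rate
#' @param batch_size episodes per iteration
#' @param epochs PPO epochs per batch
#' @param hidden hidden-layer sizes of the policy/value nets
#' @param max_iterations training budget
#' @param plateau_window,plateau_tol advantage-plateau stopping rule
#' @param archive_cap novelty-archive capacity during training
#' @param seed master seed
#' @return object of class `generator_config`
#' @export
generator_config <- function(angle_set = c(-120, -60, -30, 30, 60, 120, 180),
                             horizon = NULL, w_energy = 1, w_novelty = 1,
                             clip_ratio = 0.2, lr = 3e-3, batch_size = 32,
                             epochs = 4, hidden = c(32, 32),
                             max_iterations = 200, plateau_window = 10,
                             plateau_tol = 0.01, archive_cap = 256,
                             seed = 1L) {
  stopifnot(clip_ratio > 0, clip_ratio < 1, plateau_window >= 2)
  structure(as.list(environment()), class = "generator_config")
}

#' Environment for the torsion-policy generator
#'
#' @param n_torsions number of rotatable torsions
#' @param energy function(theta) -> kcal/mol on a torsion vector (degrees)
#' @param n_classes number of charge-location classes the policy serves
#' @param periods optional symmetry periods for TFD novelty
#' @return object of class `generator_env`
#' @export
generator_env <- function(n_torsions, energy, n_classes = 1, periods = NULL) {
  if (is.null(periods)) periods <- rep(360, n_torsions)
  structure(list(n_torsions = n_torsions, energy = energy,
                 n_classes = n_classes, periods = periods),
            class = "generator_env")
}

#' Environment wrapping a topology and a torsion-space backend
#' @param topo a `topology`
#' @param backend a torsion-space `energy_backend`
#' @param n_classes charge classes served
#' @return a `generator_env`
#' @export
env_from_topology <- function(topo, backend, n_classes = 1) {
  ref <- conformation(topo)
  generator_env(length(topo$torsions),
                energy = function(theta) backend$energy(set_torsions(ref, theta)),
                n_classes = n_classes,
                periods = topo$torsion_periods)
}

.state_vec <- function(theta, class_id, n_classes) {
  th <- theta * pi / 180
  onehot <- numeric(n_classes)
  onehot[class_id] <- 1
  c(sin(th), cos(th), onehot)
}

#' Initialize a PPO training state
#' @param env a `generator_env`
#' @param config a [generator_config()]
#' @return object of class `training_state`
#' @export
training_state <- function(env, config = generator_config()) {
  d <- 2 * env$n_torsions + env$n_classes
  n_actions <- env$n_torsions * length(config$angle_set)
  policy <- .mlp_init(c(d, config$hidden, n_actions), seed = config$seed)
  value <- .mlp_init(c(d, config$hidden, 1), seed = config$seed + 1000L)
  structure(list(policy = policy, value = value,
                 opt_policy = .adam_init(policy), opt_value = .adam_init(value),
                 advantage_trace = numeric(0), iteration = 0L,
                 env = env, config = config, archive = list(),
                 trained = FALSE, seed = config$seed),
            class = "training_state")
}

# ---- reward -------------------------------------------------------------

#' Reward of a conformer: low energy plus novelty
#'
#' reward = -w_E * E + w_N * novelty, where novelty is the minimum TFD to
#' the archive of previously kept fingerprints (1.0 for an empty archive).
#'
#' @param theta torsion vector (degrees) or a `conformation`
#' @param archive list of `torsion_fingerprint`
#' @param env a `generator_env` (supplies the energy function and periods)
#' @param w_energy,w_novelty weights
#' @return finite scalar reward
#' @export
reward_conformer <- function(theta, archive, env, w_energy = 1,
                             w_novelty = 1) {
  if (inherits(theta, "conformation")) theta <- get_torsions(theta)
  E <- env$energy(theta)
  if (!is.finite(E)) stop("energy evaluation failed (non-finite)")
  fp <- torsion_fingerprint(theta, periods = env$periods)
  novelty <- if (!length(archive)) 1.0
             else min(vapply(archive, function(a) tfd(fp, a), numeric(1)))
  r <- -w_energy * E + w_novelty * novelty
  if (!is.finite(r)) stop("non-finite reward")
  r
}

# ---- episodes -----------------------------------------------------------

.run_episode <- function(state, class_id, greedy = FALSE) {
  env <- state$env; cfg <- state$config
  horizon <- cfg$horizon %||% (3L * env$n_torsions)
  n_ang <- length(cfg$angle_set)
  theta <- stats::runif(env$n_torsions, -180, 180)
  S <- matrix(0, horizon, 2 * env$n_torsions + env$n_classes)
  actions <- integer(horizon); logp <- numeric(horizon)
  for (t in seq_len(horizon)) {
    s <- .state_vec(theta, class_id, env$n_classes)
    S[t, ] <- s
    pr <- .softmax(as.vector(.mlp_forward(state$policy,
                                          matrix(s, 1))$out))
    a <- if (greedy) which.max(pr)
         else sample.int(length(pr), 1, prob = pr)
    actions[t] <- a
    logp[t] <- log(pr[a] + 1e-12)
    ti <- (a - 1) %/% n_ang + 1
    inc <- cfg$angle_set[(a - 1) %% n_ang + 1]
    theta[ti] <- wrap_angle(theta[ti] + inc)
  }
  ret <- tryCatch(
    reward_conformer(theta, state$archive, env,
                     w_energy = cfg$w_energy, w_novelty = cfg$w_novelty),
    error = function(e) {
      message("episode aborted: ", conditionMessage(e))
      NA_real_
    })
  list(states = S, actions = actions, logp_old = logp, return_ = ret,
       theta = theta, class_id = class_id)
}

# ---- PPO update ---------------------------------------------------------

#' Clipped-surrogate PPO objective (per sample)
#' @param r probability ratio pi_new / pi_old
#' @param A advantage
#' @param eps clip ratio
#' @return min(r A, clip(r, 1 - eps, 1 + eps) A)
#' @export
ppo_objective <- function(r, A, eps = 0.2) {
  pmin(r * A, pmax(pmin(r, 1 + eps), 1 - eps) * A)
}

#' One PPO update from a batch of episodes
#'
#' Computes advantages (episode return minus value baseline, normalized per
#' batch unless degenerate), runs `epochs` passes of clipped-surrogate
#' policy gradient plus value regression, and appends the batch mean (raw)
#' advantage to the training trace. A non-finite gradient skips the update
#' with a message.
#'
#' @param batch list of episodes from the internal rollout
#' @param state a `training_state`
#' @param config a `generator_config` (defaults to the state's)
#' @return the updated `training_state`
#' @export
ppo_update <- function(batch, state, config = state$config) {
  batch <- Filter(function(ep) is.finite(ep$return_), batch)
  if (!length(batch)) stop("empty batch")
  S <- do.call(rbind, lapply(batch, `[[`, "states"))
  actions <- unlist(lapply(batch, `[[`, "actions"))
  logp_old <- unlist(lapply(batch, `[[`, "logp_old"))
  returns <- unlist(lapply(batch, function(ep)
    rep(ep$return_, nrow(ep$states))))

  Vout <- .mlp_forward(state$value, S)
  V <- as.vector(Vout$out)
  adv_raw <- returns - V
  mean_adv <- mean(vapply(batch, function(ep)
    ep$return_ - as.vector(.mlp_forward(state$value,
                                        ep$states[1, , drop = FALSE])$out),
    numeric(1)))
  sd_adv <- stats::sd(adv_raw)
  A <- if (is.finite(sd_adv) && sd_adv > 1e-12)
    (adv_raw - mean(adv_raw)) / sd_adv else adv_raw

  B <- nrow(S)
  eps <- config$clip_ratio
  for (ep_i in seq_len(config$epochs)) {
    # policy
    fw <- .mlp_forward(state$policy, S)
    logits <- fw$out
    P <- t(apply(logits, 1, .softmax))
    logp <- log(P[cbind(seq_len(B), actions)] + 1e-12)
    ratio <- exp(logp - logp_old)
    unclipped <- (A >= 0 & ratio <= 1 + eps) | (A < 0 & ratio >= 1 - eps)
    coef <- ifelse(unclipped, ratio * A, 0)
    dLogits <- -P * coef / B                 # maximize -> minimize negative
    dLogits[cbind(seq_len(B), actions)] <-
      dLogits[cbind(seq_len(B), actions)] + coef / B
    dLogits <- -dLogits                      # gradient of loss (=-objective)
    gp <- .mlp_backward(state$policy, fw, dLogits)
    # value
    fv <- .mlp_forward(state$value, S)
    dV <- matrix(2 * (as.vector(fv$out) - returns) / B, ncol = 1)
    gv <- .mlp_backward(state$value, fv, dV)
    finite <- all(vapply(c(gp, gv), function(g)
      all(is.finite(g$W)) && all(is.finite(g$b)), logical(1)))
    if (!finite) {
      message("non-finite gradient; update skipped")
      break
    }
    up <- .adam_step(state$policy, gp, state$opt_policy, config$lr)
    state$policy <- up$net; state$opt_policy <- up$opt
    uv <- .adam_step(state$value, gv, state$opt_value, config$lr)
    state$value <- uv$net; state$opt_value <- uv$opt
  }
  state$advantage_trace <- c(state$advantage_trace, mean_adv)
  state$iteration <- state$iteration + 1L
  state
}

#' Advantage-plateau stopping rule
#'
#' TRUE iff the trailing `window` of the advantage trace varies, relative
#' to its mean magnitude, by less than `tolerance`.
#'
#' @param state a `training_state` (or numeric trace)
#' @param window trailing window length (>= 2)
#' @param tolerance relative-variation tolerance
#' @return logical
#' @export
plateau_reached <- function(state, window = 10, tolerance = 0.01) {
  trace <- if (is.numeric(state)) state else state$advantage_trace
  if (length(trace) < window) return(FALSE)
  w <- utils::tail(trace, window)
  spread <- max(w) - min(w)
  scale <- max(abs(mean(w)), 1e-8)
  spread / scale < tolerance
}

#' Train the generator policy to advantage plateau
#'
#' Iterates rollout batches and PPO updates until the advantage plateau or
#' the iteration budget; episodes sample charge classes uniformly so one
#' policy serves all protonation states of the size.
#'
#' @param env a `generator_env`
#' @param config a [generator_config()]
#' @param verbose print progress every 10 iterations
#' @return a trained `training_state`
#' @export
train_generator <- function(env, config = generator_config(),
                            verbose = FALSE) {
  state <- training_state(env, config)
  .with_seed(config$seed, {
    for (it in seq_len(config$max_iterations)) {
      batch <- lapply(seq_len(config$batch_size), function(k)
        .run_episode(state, class_id = sample.int(env$n_classes, 1)))
      state <- ppo_update(batch, state, config)
      # archive terminal fingerprints for the novelty term
      for (ep in batch) {
        if (!is.finite(ep$return_)) next
        state$archive[[length(state$archive) + 1]] <-
          torsion_fingerprint(ep$theta, periods = env$periods)
      }
      if (length(state$archive) > config$archive_cap)
        state$archive <- utils::tail(state$archive, config$archive_cap)
      if (verbose && it %% 10 == 0)
        message(sprintf("iter %d  mean advantage %.4f", it,
                        utils::tail(state$advantage_trace, 1)))
      if (it > config$plateau_window &&
          plateau_reached(state, config$plateau_window, config$plateau_tol))
        break
    }
  })
  state$trained <- TRUE
  state
}

#' Save a training state as a portable, versioned JSON checkpoint
#'
#' The environment's energy function is not serialized; reattach it on load.
#'
#' @param state a `training_state`
#' @param path output file
#' @export
save_training_state <- function(state, path) {
  ser_net <- function(net) lapply(net, function(l)
    list(dim = dim(l$W), W = as.vector(l$W), b = l$b))
  obj <- list(format = "oligoconf-checkpoint", version = 1L,
              policy = ser_net(state$policy), value = ser_net(state$value),
              advantage_trace = state$advantage_trace,
              iteration = state$iteration, trained = state$trained,
              seed = state$seed,
              n_torsions = state$env$n_torsions,
              n_classes = state$env$n_classes,
              config = state$config[setdiff(names(state$config), "")])
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Load a training state checkpoint saved by [save_training_state()]
#'
#' @param path checkpoint file
#' @param env a `generator_env` matching the checkpoint's torsion count
#' @return a `training_state`
#' @export
load_training_state <- function(path, env) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE,
                             simplifyDataFrame = FALSE)
  if (!identical(obj$format, "oligoconf-checkpoint"))
    stop("not an oligoconf checkpoint: ", path)
  if (obj$n_torsions != env$n_torsions)
    stop("checkpoint serves ", obj$n_torsions, " torsions, env has ",
         env$n_torsions)
  cfg_in <- obj$config[names(obj$config) %in%
                         names(formals(generator_config))]
  cfg_in <- Filter(function(x) length(x) > 0, cfg_in)  # JSON null -> {}
  cfg <- do.call(generator_config, cfg_in)
  state <- training_state(env, cfg)
  de_net <- function(net) lapply(net, function(l)
    list(W = matrix(as.numeric(l$W), l$dim[1], l$dim[2]),
         b = as.numeric(l$b)))
  state$policy <- de_net(obj$policy)
  state$value <- de_net(obj$value)
  state$advantage_trace <- as.numeric(obj$advantage_trace)
  state$iteration <- as.integer(obj$iteration)
  state$trained <- isTRUE(obj$trained)
  state
}

#' Generate conformers with a (possibly untrained) policy
#'
#' Rolls out the policy for `count` episodes; an untrained state falls back
#' to uniform-random torsions. When a topology is supplied, every candidate
#' is checked against the minimum-interatomic-distance invariant and
#' resampled until valid, so exactly `count` valid conformations return.
#'
#' @param topo a `topology` (NULL for bare torsion vectors)
#' @param state a `training_state`
#' @param count number of conformations
#' @param seed RNG seed
#' @param class_id charge-location class used in the state encoding
#' @return list of `conformation` (or torsion vectors when `topo` is NULL)
#' @export
generate <- function(topo, state, count, seed = 1L, class_id = 1L) {
  if (count == 0) return(list())
  env <- state$env
  out <- vector("list", count)
  ref <- if (!is.null(topo)) conformation(topo) else NULL
  .with_seed(seed, {
    k <- 1L; attempts <- 0L
    while (k <= count) {
      attempts <- attempts + 1L
      if (attempts > 50L * count)
        stop("could not generate enough valid conformations")
      theta <- if (isTRUE(state$trained))
        .run_episode(state, class_id = class_id)$theta
      else stats::runif(env$n_torsions, -180, 180)
      if (!is.null(ref)) {
        n_topo <- length(topo$torsions)
        if (n_topo > env$n_torsions)
          stop("topology has more torsions (", n_topo,
               ") than the policy serves (", env$n_torsions, ")")
        conf <- set_torsions(ref, theta[seq_len(n_topo)])
        if (!is_valid_conformation(conf)) next
        conf$provenance <- sprintf("generate:seed=%d;iter=%d;k=%d",
                                   seed, state$iteration, k)
        out[[k]] <- conf
      } else {
        out[[k]] <- theta
      }
      k <- k + 1L
    }
  })
  out
}
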