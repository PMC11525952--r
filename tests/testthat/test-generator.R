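# PPO conformer generator: reward, clipped updates, plateau rule, rollout.

test_that("reward combines energy and novelty as specified", {
  lw <- toy_double_well(2)
  env <- generator_env(2, lw$fn)

  # empty archive, zero-energy point -> w_N * 1.0
  theta_g <- lw$theta_g
  expect_equal(lw$fn(theta_g), 0)
  expect_equal(reward_conformer(theta_g, list(), env, w_energy = 1,
                                w_novelty = 2.5), 2.5)

  # identical to an archived conformer -> novelty term 0
  fp <- torsion_fingerprint(theta_g, periods = env$periods)
  expect_equal(reward_conformer(theta_g, list(fp), env, w_energy = 1,
                                w_novelty = 2.5), 0)

  # with w_N = 0, reward ranking equals brute-force energy ranking
  gs <- grid_search(lw, step = 10)
  idx <- seq(1, nrow(gs$grid), by = 37)
  r <- vapply(idx, function(i)
    reward_conformer(gs$grid[i, ], list(), env, w_energy = 1,
                     w_novelty = 0), numeric(1))
  expect_equal(order(r, decreasing = TRUE), order(gs$energies[idx]))
})

test_that("ppo_objective implements the clipped surrogate", {
  expect_equal(ppo_objective(2, 1, eps = 0.2), 1.2)
  expect_equal(ppo_objective(0.5, 1, eps = 0.2), 0.5)
  expect_equal(ppo_objective(0.5, -1, eps = 0.2), -0.8)
  expect_equal(ppo_objective(1.0, 0, eps = 0.2), 0)
})

test_that("ppo_update: zero advantages leave parameters unchanged", {
  env <- generator_env(2, toy_double_well(2)$fn)
  cfg <- generator_config(seed = 3, batch_size = 4)
  st <- training_state(env, cfg)
  # zero the value net so V = 0 everywhere, and build episodes with return 0
  nl <- length(st$value)
  st$value[[nl]]$W[] <- 0
  st$value[[nl]]$b[] <- 0
  horizon <- 6L
  d <- 2 * env$n_torsions + env$n_classes
  ep <- list(states = matrix(0.3, horizon, d),
             actions = rep(1L, horizon),
             logp_old = rep(log(0.5), horizon),
             return_ = 0, theta = c(0, 0), class_id = 1L)
  st2 <- ppo_update(list(ep, ep), st, cfg)
  expect_equal(st2$policy, st$policy)
  expect_equal(st2$value, st$value)
  expect_equal(st2$advantage_trace, 0)
  expect_equal(st2$iteration, 1L)
})

test_that("ppo_update is deterministic for a fixed batch", {
  env <- generator_env(2, toy_double_well(2)$fn)
  cfg <- generator_config(seed = 3)
  st <- training_state(env, cfg)
  d <- 2 * env$n_torsions + env$n_classes
  withr::with_seed(12, {
    ep <- list(states = matrix(rnorm(6 * d), 6, d),
               actions = sample.int(14, 6, replace = TRUE),
               logp_old = log(runif(6, 0.1, 0.9)),
               return_ = 1.7, theta = c(0, 0), class_id = 1L)
  })
  a <- ppo_update(list(ep), st, cfg)
  b <- ppo_update(list(ep), st, cfg)
  expect_identical(a$policy, b$policy)
  expect_identical(a$value, b$value)
})

test_that("plateau_reached follows the windowed relative-variation rule", {
  expect_true(plateau_reached(rep(2.5, 12), window = 10, tolerance = 0.01))
  expect_false(plateau_reached(seq(1, 30), window = 10, tolerance = 0.01))
  expect_true(plateau_reached(c(1, 2, 3, 3.0001, 3.0002), window = 3,
                              tolerance = 1e-3))
  expect_false(plateau_reached(c(1, 2), window = 10, tolerance = 0.01))
})

test_that("generate honors count, determinism, validity, charge classes", {
  lw <- toy_double_well(2)
  env <- generator_env(2, lw$fn, n_classes = 2)
  cfg <- generator_config(seed = 5)
  st <- training_state(env, cfg)   # untrained: uniform fallback
  topo <- toy_chain_topology(2)

  expect_equal(generate(topo, st, 0), list())

  g1 <- generate(topo, st, 10, seed = 4)
  g2 <- generate(topo, st, 10, seed = 4)
  expect_length(g1, 10L)
  expect_equal(lapply(g1, get_torsions), lapply(g2, get_torsions))
  expect_true(all(vapply(g1, is_valid_conformation, logical(1))))

  # one policy serves any charge class without retraining
  ga <- generate(topo, st, 3, seed = 4, class_id = 1L)
  gb <- generate(topo, st, 3, seed = 4, class_id = 2L)
  expect_length(ga, 3L)
  expect_length(gb, 3L)
})

test_that("training-state checkpoints round-trip through JSON", {
  lw <- toy_double_well(2)
  env <- generator_env(2, lw$fn)
  cfg <- generator_config(seed = 8, batch_size = 8, max_iterations = 3,
                          plateau_window = 50)
  st <- train_generator(env, cfg)
  path <- withr::local_tempfile(fileext = ".json")
  save_training_state(st, path)
  st2 <- load_training_state(path, env)
  expect_equal(st2$policy, st$policy, tolerance = 1e-12)
  expect_equal(st2$advantage_trace, st$advantage_trace)
  expect_true(st2$trained)
  # identical rollouts after reload
  topo <- toy_chain_topology(2)
  expect_equal(lapply(generate(topo, st2, 5, seed = 3), get_torsions),
               lapply(generate(topo, st, 5, seed = 3), get_torsions))
  expect_error(load_training_state(path, generator_env(3, lw$fn)),
               "torsions")
})

test_that("a briefly trained policy lowers the mean generated energy", {
  lw <- toy_double_well(2)
  env <- generator_env(2, lw$fn)
  cfg <- generator_config(seed = 11, batch_size = 16, max_iterations = 25,
                          plateau_window = 40)   # fixed budget, no early stop
  st <- train_generator(env, cfg)
  expect_true(st$trained)
  expect_equal(length(st$advantage_trace), st$iteration)

  topo <- toy_chain_topology(2)
  gen <- generate(topo, st, 200, seed = 2)
  unif <- generate(topo, training_state(env, cfg), 200, seed = 2)
  e_gen <- mean(vapply(gen, function(cf) lw$fn(get_torsions(cf)), numeric(1)))
  e_unif <- mean(vapply(unif, function(cf) lw$fn(get_torsions(cf)),
                        numeric(1)))
  expect_lte(e_gen, e_unif)
})
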