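test_that("encode returns a 64-dim posterior, deterministically", {
  model <- helper_model()
  g <- helper_graphs()[[1]]
  p1 <- vgae_encode(g, model)
  p2 <- vgae_encode(g, model)
  expect_length(p1$mu, 64)
  expect_length(p1$logvar, 64)
  expect_true(all(is.finite(c(p1$mu, p1$logvar))))
  expect_identical(p1, p2)

  # a graph violating the symmetry invariant is rejected
  bad <- g
  bad$edge_features[1, 2, 1] <- 1
  bad$edge_features[2, 1, 1] <- 0
  expect_error(vgae_encode(bad, model), class = "molgrow_config_error")
})

test_that("posterior sampling follows the reparameterization", {
  post <- structure(list(mu = c(1.5, -2, 0.25), logvar = c(-40, -40, -40)),
                    class = "latent_posterior")
  # variance ~ 0 collapses the draw onto mu
  expect_equal(sample_posterior(post, seed = 1), post$mu, tolerance = 1e-6)

  post2 <- structure(list(mu = rep(2, 4), logvar = rep(log(0.25), 4)),
                     class = "latent_posterior")
  expect_identical(sample_posterior(post2, seed = 9),
                   sample_posterior(post2, seed = 9))
  # Monte Carlo: sample mean within 4 standard errors of mu
  draws <- withr::with_seed(11, {
    replicate(10000, sample_posterior(post2))
  })
  se <- 0.5 / sqrt(10000)
  expect_true(all(abs(rowMeans(draws) - 2) < 4 * se))
})

test_that("prior sampling is standard normal with identity covariance", {
  model <- helper_model()
  z1 <- sample_prior(model, seed = 3)
  expect_length(z1, 64)
  expect_identical(z1, sample_prior(model, seed = 3))
  draws <- withr::with_seed(5, {
    matrix(stats::rnorm(10000 * 64), 10000, 64)
  })
  # empirical diagonal of the covariance within 3 standard errors of 1
  v <- apply(draws, 2, stats::var)
  se_var <- sqrt(2 / 10000)
  expect_true(all(abs(v - 1) < 3 * se_var))
})

test_that("decode yields a valid symmetric probability map", {
  model <- helper_model()
  for (seed in 1:5) {
    z <- sample_prior(model, seed = seed)
    fm <- vgae_decode(z, model)
    expect_true(all(fm$edge_prob >= 0 & fm$edge_prob <= 1))
    expect_equal(fm$edge_prob, t(fm$edge_prob))
    expect_true(all(diag(fm$edge_prob) == 0))
    el <- seq_along(model$config$allowed_elements)
    expect_equal(unname(rowSums(fm$node_map[, el])),
                 rep(1, model$config$max_atoms), tolerance = 1e-8)
  }
  z <- sample_prior(model, seed = 1)
  expect_identical(vgae_decode(z, model), vgae_decode(z, model))
  expect_error(vgae_decode(z[1:10], model), class = "molgrow_config_error")
})

test_that("elbo pieces match their closed forms", {
  model <- helper_model()
  g <- helper_graphs()[[1]]
  dec <- vgae_decode(sample_prior(model, seed = 2), model)

  post0 <- structure(list(mu = rep(0, 64), logvar = rep(0, 64)),
                     class = "latent_posterior")
  expect_equal(elbo_loss(g, dec, post0)[["kl"]], 0)

  post1 <- structure(list(mu = c(1, rep(0, 63)), logvar = rep(0, 64)),
                     class = "latent_posterior")
  expect_equal(elbo_loss(g, dec, post1)[["kl"]], 0.5)

  # kl non-negative for random posteriors (closed-form property)
  withr::with_seed(8, {
    for (k in 1:25) {
      p <- structure(list(mu = stats::rnorm(64), logvar = stats::rnorm(64)),
                     class = "latent_posterior")
      expect_gte(elbo_loss(g, dec, p)[["kl"]], 0)
    }
  })

  # perfect edge/node reconstruction drives the reconstruction term to 0
  gt <- molgrow:::graph_tensors(g, model$config)
  perfect <- dec
  perfect$edge_prob <- gt$Tadj
  perfect$node_map <- g$node_features
  expect_equal(elbo_loss(g, perfect, post0)[["reconstruction"]], 0,
               tolerance = 1e-6)
  expect_equal(elbo_loss(g, perfect, post0)[["total"]], 0, tolerance = 1e-6)
})

test_that("training reduces the loss on a small set, reproducibly", {
  cfg <- helper_feature_config()
  graphs <- lapply(helper_smiles(20), smiles_to_graph, config = cfg)
  h <- list(epochs = 25, batch_size = 10, val_frac = 0)
  m1 <- vgae_train(graphs, cfg, hyper = h, seed = 13)
  expect_lt(utils::tail(m1$history$train, 1), m1$history$train[1])
  # monotone trend over epoch windows (not per step)
  first_third <- mean(m1$history$train[1:8])
  last_third <- mean(utils::tail(m1$history$train, 8))
  expect_lt(last_third, first_third)

  m2 <- vgae_train(graphs, cfg, hyper = h, seed = 13)
  expect_identical(m1$history, m2$history)

  expect_error(vgae_train(list(), cfg), class = "molgrow_config_error")

  # defaults carry the documented training setup
  d <- default_vgae_hyper()
  expect_equal(d$learning_rate, 0.001)
  expect_equal(d$batch_size, 64L)
  expect_equal(d$latent_dim, 64L)
})

test_that("decoded prior samples always feed candidate extraction", {
  model <- helper_model()
  st <- build_state(model$config)
  st <- molgrow:::state_add_atom(st, 1L, "C", anchor = 0L)
  for (seed in 1:10) {
    fm <- vgae_decode(sample_prior(model, seed = seed), model)
    expect_no_error(candidate_edges(fm, st, threshold = 0.10))
  }
})

test_that("checkpoints round-trip and validate their configuration", {
  model <- helper_model()
  path <- withr::local_tempfile(fileext = ".rds")
  save_model(model, path)
  loaded <- load_model(path)
  expect_identical(loaded$params, model$params)
  expect_identical(loaded$config$max_atoms, model$config$max_atoms)
  expect_no_error(load_model(path, config = helper_feature_config()))
  expect_error(load_model(path, config = feature_config(max_atoms = 9)),
               class = "molgrow_config_error")
  expect_error(load_model("missing.rds"), class = "molgrow_io_error")
})
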