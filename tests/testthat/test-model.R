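# Tiny deterministic model: 1 pathway x 2 genes, 1 batch, parameters set
# by hand so forward passes can be traced on paper.
toy_model <- function(W_d = matrix(c(1, 2), 1), O = matrix(0, 1, 2),
                      mode = "l2") {
  A <- structure(list(A = matrix(1, 1, 2,
                                 dimnames = list("PW1", c("G1", "G2"))),
                      pathways = "PW1", genes = c("G1", "G2")),
                 class = "pathway_matrix")
  X <- count_matrix(matrix(1, 2, 2, dimnames = list(NULL, c("G1", "G2"))),
                    batch = c("b1", "b1"))
  cfg <- train_config(knowledge_mode = mode, epochs = 0, seed = 1)
  m <- fit_pathvae(X, A, cfg)
  m$params$W_d <- W_d
  m$params$b_d <- c(0, 0)
  m$params$O <- O
  m
}

test_that("reparameterization is the location-scale transform of the posterior", {
  mu <- matrix(c(1, -2), 1)
  lv <- matrix(c(0, log(4)), 1)
  expect_equal(reparameterize(mu, lv, matrix(0, 1, 2)), mu)
  expect_equal(reparameterize(mu, lv, matrix(1, 1, 2)), mu + c(1, 2))
  # law of large numbers: sample mean of z approaches mu
  withr::local_seed(8)
  n <- 1e5
  z <- reparameterize(matrix(0.7, n, 1), matrix(log(2), n, 1),
                      matrix(rnorm(n), n, 1))
  expect_lt(abs(mean(z) - 0.7), 4 * sqrt(2) / sqrt(n))
})

test_that("closed-form KL matches hand values and is nonnegative", {
  expect_equal(kl_divergence(matrix(0, 3, 4), matrix(0, 3, 4)), 0)
  expect_equal(kl_divergence(matrix(1, 1, 1), matrix(0, 1, 1)), 0.5)
  withr::local_seed(9)
  for (i in 1:10) {
    mu <- matrix(rnorm(6), 2)
    lv <- matrix(rnorm(6), 2)
    expect_gte(kl_divergence(mu, lv), 0)
  }
})

test_that("closed-form KL agrees with a Monte-Carlo estimate of E_q[log q - log p]", {
  withr::local_seed(10)
  n_draws <- 1e5
  for (trial in 1:5) {
    d <- sample(1:3, 1)
    mu <- matrix(rnorm(d, sd = 1.5), 1)
    lv <- matrix(rnorm(d, sd = 0.7), 1)
    sig <- exp(0.5 * lv)
    draws <- matrix(rnorm(n_draws * d), n_draws, d)
    z <- sweep(sweep(draws, 2, sig, "*"), 2, mu, "+")
    log_q <- rowSums(dnorm(z, mean = rep(mu, each = n_draws),
                           sd = rep(sig, each = n_draws), log = TRUE))
    log_p <- rowSums(dnorm(z, log = TRUE))
    diffs <- log_q - log_p
    se <- sd(diffs) / sqrt(n_draws)
    expect_lt(abs(mean(diffs) - kl_divergence(mu, lv)), 3 * se)
  }
})

test_that("reconstruction loss is the per-cell summed squared error", {
  x <- matrix(c(0, 0), 1)
  expect_equal(reconstruction_loss(x, x), 0)
  expect_equal(reconstruction_loss(x, matrix(c(1, 1), 1)), 2)
  withr::local_seed(11)
  a <- matrix(rnorm(20), 4); b <- matrix(rnorm(20), 4)
  expect_equal(reconstruction_loss(a, a + 3 * (b - a)),
               9 * reconstruction_loss(a, b))
})

test_that("knowledge penalties match their closed forms", {
  A <- matrix(0, 2, 5); A[1, 1:4] <- 1; A[2, 3:5] <- 1  # 7 ones
  expect_equal(knowledge_penalty(A, A, "l2"), 0)
  expect_equal(knowledge_penalty(A * 0, A, "l1"), 7)
  expect_equal(knowledge_penalty(matrix(1, 2, 5), A, "literal_hadamard_l1"), 7)
  expect_equal(knowledge_penalty(matrix(1, 2, 5), A, "literal_hadamard_l2"),
               sqrt(7))
  w <- A + 0.5
  expect_equal(knowledge_penalty(w, A, "l2"), sqrt(10 * 0.25))
  expect_equal(knowledge_penalty(w, A, "mask_decoder"), 0)
  expect_error(knowledge_penalty(matrix(0, 3, 5), A, "l1"), "shape")
})

test_that("total loss equals the sum of its reported components", {
  withr::local_seed(12)
  x <- matrix(rnorm(12), 3); xh <- matrix(rnorm(12), 3)
  mu <- matrix(rnorm(6), 3); lv <- matrix(rnorm(6), 3)
  A <- matrix(rbinom(8, 1, 0.5), 2, 4)
  w <- matrix(rnorm(8), 2, 4)
  cfg <- train_config(lambda_k = 2.5, beta_kl = 0.7)
  tl <- total_loss(x, xh, mu, lv, w, A, cfg)
  expect_equal(tl$total,
               tl$reconstruction + 0.7 * tl$kl + 2.5 * tl$knowledge)
  # doubling lambda doubles the knowledge contribution
  cfg2 <- train_config(lambda_k = 5, beta_kl = 0.7)
  tl2 <- total_loss(x, xh, mu, lv, w, A, cfg2)
  expect_equal(tl2$total - tl$total, 2.5 * tl$knowledge)
  cfg0 <- train_config(lambda_k = 0, beta_kl = 0)
  expect_equal(total_loss(x, xh, mu, lv, w, A, cfg0)$total,
               reconstruction_loss(x, xh))
})

test_that("decoding is the stated linear map", {
  m <- toy_model()
  # z = [[3]], w = [[1, 2]], zero biases -> [[3, 6]]
  expect_equal(unname(decode_cells(m, matrix(3, 1, 1), "b1")),
               matrix(c(3, 6), 1))
  # z = 0 -> batch offset row
  m2 <- toy_model(O = matrix(c(5, -1), 1))
  expect_equal(unname(decode_cells(m2, matrix(0, 1, 1), "b1")),
               matrix(c(5, -1), 1))
})

test_that("analytic gradients match finite differences in every knowledge mode", {
  modes <- c("l2", "l1", "mask_decoder", "mask_both", "none",
             "literal_hadamard_l1", "literal_hadamard_l2")
  withr::local_seed(13)
  G <- 5; P <- 2; B <- 2; n <- 3
  A <- matrix(rbinom(P * G, 1, 0.5), P, G)
  A[rowSums(A) == 0, 1] <- 1
  x <- matrix(rnorm(n * G), n, G)
  bo <- cbind(c(1, 1, 0), c(0, 0, 1))
  eps <- matrix(rnorm(n * P), n, P)
  for (mode in modes) {
    cfg <- train_config(knowledge_mode = mode, lambda_k = 0.8,
                        beta_kl = 0.6, hidden_width = 4, seed = 1)
    params <- pathvae:::init_params(G, P, B, cfg)
    # keep away from the non-differentiable points of l1/relu
    params <- lapply(params, function(p) p + 0.05 * sign(p + 0.01))
    if (mode == "mask_both") attr(params, "mask_t") <- t(A)
    lg <- pathvae:::loss_and_grads(params, x, bo, eps, A, cfg)
    h <- 1e-6
    for (nm in names(lg$grads)) {
      pick <- sample(length(params[[nm]]), min(4, length(params[[nm]])))
      for (j in pick) {
        pp <- params[[nm]]
        params_hi <- params; params_lo <- params
        params_hi[[nm]][j] <- pp[j] + h
        params_lo[[nm]][j] <- pp[j] - h
        if (mode == "mask_both") {
          attr(params_hi, "mask_t") <- t(A); attr(params_lo, "mask_t") <- t(A)
        }
        fd <- (pathvae:::loss_and_grads(params_hi, x, bo, eps, A, cfg)$loss$total -
               pathvae:::loss_and_grads(params_lo, x, bo, eps, A, cfg)$loss$total) /
              (2 * h)
        expect_equal(lg$grads[[nm]][j], fd, tolerance = 1e-4,
                     label = sprintf("grad %s[%d] mode %s", nm, j, mode))
      }
    }
  }
})

test_that("encoding is deterministic, shape-correct, and validates inputs", {
  fx <- default_fixture()
  m <- trained_model("l2")
  enc <- encode_cells(m, fx$Xp)
  expect_identical(dim(enc$mu), c(nrow(fx$Xp$values), 10L))
  expect_identical(dim(enc$log_var), dim(enc$mu))
  enc2 <- encode_cells(m, fx$Xp)
  expect_identical(enc$mu, enc2$mu)

  xg <- pathvae:::dense_values(fx$Xp)
  expect_error(encode_cells(m, xg[, rev(seq_len(ncol(xg)))],
                            batch = fx$Xp$batch),
               "gene order|gene columns")
  expect_error(encode_cells(m, xg[1:2, ], batch = c("weird", "weird")),
               "unseen batch")
  enc3 <- encode_cells(m, xg[1:2, ], batch = c("weird", "weird"),
                       allow_unseen = TRUE)
  expect_identical(dim(enc3$mu), c(2L, 10L))
})

test_that("mask_decoder keeps off-pathway effective weights at exactly zero", {
  fx <- default_fixture()
  cfg <- train_config(knowledge_mode = "mask_decoder", epochs = 5,
                      minibatch_size = 64, seed = 3)
  m <- fit_pathvae(fx$Xp, fx$A, cfg)
  w <- decoder_weights(m)
  expect_true(all(w[fx$A$A == 0] == 0))
  expect_true(any(w[fx$A$A == 1] != 0))
})

test_that("fit records a finite loss history and reduces the objective", {
  fx <- default_fixture()
  m0 <- fit_pathvae(fx$Xp, fx$A, train_config(epochs = 0, seed = 1))
  expect_identical(nrow(m0$history), 0L)

  m <- trained_model("l2")
  h <- m$history
  expect_identical(nrow(h), 150L)
  expect_true(all(is.finite(as.matrix(h))))
  expect_lt(tail(h$total, 1), h$total[1])
  expect_equal(h$total,
               h$reconstruction + m$config$beta_kl * h$kl +
                 m$config$lambda_k * h$knowledge)
  # determinism: same config and seed reproduce the history exactly
  m2 <- fit_pathvae(fx$Xp, fx$A, fixture_train_config("l2"))
  expect_identical(m2$history, h)

  Xbad <- fx$Xp
  colnames(Xbad$values) <- rev(colnames(Xbad$values))
  expect_error(fit_pathvae(Xbad, fx$A, train_config(epochs = 1)),
               "gene order")
})

test_that("transform returns pathway-named posterior means", {
  fx <- default_fixture()
  m <- trained_model("l2")
  emb <- transform_cells(m, fx$Xp)
  expect_identical(dim(emb), c(nrow(fx$Xp$values), 10L))
  expect_identical(colnames(emb), fx$A$pathways)
  expect_identical(rownames(emb), cell_ids(fx$Xp))
  # two identical cells from the same batch embed identically
  x2 <- pathvae:::dense_values(fx$Xp)[c(1, 1), ]
  e2 <- transform_cells(m, x2, batch = rep(fx$Xp$batch[1], 2))
  expect_identical(e2[1, ], e2[2, ])
})

test_that("a reloaded checkpoint reproduces the embedding bit-exactly", {
  fx <- default_fixture()
  m <- trained_model("l2")
  f <- withr::local_tempfile(fileext = ".rds")
  save_model(m, f)
  m2 <- load_model(f)
  expect_identical(transform_cells(m2, fx$Xp), transform_cells(m, fx$Xp))

  # embedding table round-trip
  tsv <- withr::local_tempfile(fileext = ".tsv")
  emb <- transform_cells(m, fx$Xp)
  write_embedding(emb, tsv)
  expect_equal(read_embedding(tsv), emb, tolerance = 1e-12)
})
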