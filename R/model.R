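#' Training configuration for the pathway-regularized VAE
#'
#' @param knowledge_mode How the pathway-gene prior enters training.
#'   `"l1"`/`"l2"` penalize the elementwise distance between the decoder
#'   weight matrix and the binary adjacency (the default, `"l2"`);
#'   `"mask_decoder"` enforces the prior structurally by zeroing
#'   off-pathway decoder weights; `"mask_both"` additionally replaces the
#'   encoder by a single linear layer masked by the transposed adjacency;
#'   `"none"` trains an unconstrained conditional VAE;
#'   `"literal_hadamard_l1"`/`"literal_hadamard_l2"` penalize the norm of
#'   the Hadamard product of weights and adjacency (shrinking in-pathway
#'   weights toward 0 rather than 1).
#' @param lambda_k Weight of the knowledge penalty (>= 0).  The default
#'   50 makes the distance penalty's gradient comparable to the
#'   reconstruction gradient at typical data scales, so the prior actually
#'   binds and latent dimensions align with pathways; with a much smaller
#'   weight the penalty is inert and the latent axes are an arbitrary
#'   rotation.
#' @param beta_kl Weight of the KL term (>= 0).
#' @param learning_rate Adam learning rate.
#' @param epochs Number of passes over the data.
#' @param minibatch_size Cells per gradient step.
#' @param hidden_width Width of the encoder hidden layer (ignored under
#'   `mask_both`).
#' @param seed Integer seed controlling initialization, shuffling and
#'   reparameterization noise.
#' @param logvar_clamp Length-2 numeric; log-variance is clamped to this
#'   range for numerical stability.
#' @return A `train_config` list.
#' @export
train_config <- function(knowledge_mode = c("l2", "l1", "mask_decoder",
                                            "mask_both", "none",
                                            "literal_hadamard_l1",
                                            "literal_hadamard_l2"),
                         lambda_k = 50, beta_kl = 1.0,
                         learning_rate = 1e-3, epochs = 20,
                         minibatch_size = 128, hidden_width = 256,
                         seed = 1, logvar_clamp = c(-10, 10)) {
  knowledge_mode <- match.arg(knowledge_mode)
  stopifnot(lambda_k >= 0, beta_kl >= 0, minibatch_size >= 1,
            epochs >= 0, learning_rate > 0, hidden_width >= 1,
            length(logvar_clamp) == 2, logvar_clamp[1] < logvar_clamp[2])
  structure(list(knowledge_mode = knowledge_mode, lambda_k = lambda_k,
                 beta_kl = beta_kl, learning_rate = learning_rate,
                 epochs = as.integer(epochs),
                 minibatch_size = as.integer(minibatch_size),
                 hidden_width = as.integer(hidden_width),
                 seed = as.integer(seed), logvar_clamp = logvar_clamp),
            class = "train_config")
}

#' Reparameterization trick
#'
#' Draws latent samples `z = mu + exp(log_var / 2) * noise`.
#'
#' @param mu,log_var Posterior mean and log-variance matrices (cells x P).
#' @param noise Standard-normal draws of the same shape.
#' @return Matrix of latent samples.
#' @export
reparameterize <- function(mu, log_var, noise) {
  stopifnot(all(dim(mu) == dim(log_var)), all(dim(mu) == dim(noise)))
  mu + exp(0.5 * log_var) * noise
}

#' Closed-form KL divergence to the standard-normal prior
#'
#' `KL(N(mu, sigma^2) || N(0, 1))` summed over latent dimensions and
#' averaged over cells: `0.5 * mean_i sum_p (mu^2 + sigma^2 - log sigma^2 - 1)`.
#'
#' @param mu,log_var Posterior mean and log-variance matrices.
#' @return Nonnegative scalar.
#' @export
kl_divergence <- function(mu, log_var) {
  stopifnot(all(dim(mu) == dim(log_var)))
  0.5 * mean(rowSums(mu^2 + exp(log_var) - log_var - 1))
}

#' Gaussian reconstruction loss
#'
#' Mean over cells of the summed squared error over genes (unit-variance
#' Gaussian likelihood up to constants).
#'
#' @param x Observed matrix (cells x genes).
#' @param x_hat Reconstruction of the same shape.
#' @return Nonnegative scalar.
#' @export
reconstruction_loss <- function(x, x_hat) {
  stopifnot(all(dim(x) == dim(x_hat)))
  mean(rowSums((x - x_hat)^2))
}

#' Knowledge penalty on the decoder weights
#'
#' Measures how far the decoder weight matrix is from the binary
#' pathway-gene adjacency.  Distance modes: `"l1"` is `sum(|w - A|)`,
#' `"l2"` is `sqrt(sum((w - A)^2))` — both are zero exactly when the
#' decoder reproduces the prior.  The literal Hadamard modes penalize
#' `||w * A||` (elementwise product) instead, shrinking in-pathway weights
#' toward zero.  Mask modes and `"none"` return 0: under masking the
#' constraint is structural, not a loss term.
#'
#' @param w Decoder weight matrix, P x G.
#' @param A Binary adjacency of the same shape (a `pathway_matrix` or bare
#'   matrix).
#' @param mode One of the `knowledge_mode` values of [train_config()].
#' @return Nonnegative scalar.
#' @export
knowledge_penalty <- function(w, A, mode = "l2") {
  if (inherits(A, "pathway_matrix")) A <- A$A
  if (!all(dim(w) == dim(A)))
    stop("decoder weight shape ", paste(dim(w), collapse = "x"),
         " does not match adjacency shape ", paste(dim(A), collapse = "x"))
  switch(mode,
    l1 = sum(abs(w - A)),
    l2 = sqrt(sum((w - A)^2)),
    literal_hadamard_l1 = sum(abs(w * A)),
    literal_hadamard_l2 = sqrt(sum((w * A)^2)),
    mask_decoder = 0,
    mask_both = 0,
    none = 0,
    stop("unknown knowledge mode: ", mode)
  )
}

# Gradient of the knowledge penalty with respect to w.
knowledge_penalty_grad <- function(w, A, mode) {
  switch(mode,
    l1 = sign(w - A),
    l2 = { s <- sqrt(sum((w - A)^2)); if (s == 0) w * 0 else (w - A) / s },
    literal_hadamard_l1 = sign(w) * A,
    literal_hadamard_l2 = { s <- sqrt(sum((w * A)^2))
                            if (s == 0) w * 0 else (w * A) / s },
    w * 0
  )
}

#' Total training objective
#'
#' `total = reconstruction + beta_kl * KL + lambda_k * knowledge`; the
#' components are reported separately so the bookkeeping can be audited.
#'
#' @param x,x_hat Observed and reconstructed matrices.
#' @param mu,log_var Encoder outputs.
#' @param w Decoder weight matrix.
#' @param A Pathway-gene adjacency.
#' @param config A [train_config()].
#' @return List with `total`, `reconstruction`, `kl`, `knowledge`.
#' @export
total_loss <- function(x, x_hat, mu, log_var, w, A, config) {
  rec <- reconstruction_loss(x, x_hat)
  kl <- kl_divergence(mu, log_var)
  kn <- knowledge_penalty(w, A, config$knowledge_mode)
  list(total = rec + config$beta_kl * kl + config$lambda_k * kn,
       reconstruction = rec, kl = kl, knowledge = kn)
}

# ---- parameter initialization -------------------------------------------

init_params <- function(G, P, B, config) {
  rn <- function(n1, n2, sd) matrix(stats::rnorm(n1 * n2, sd = sd), n1, n2)
  p <- list()
  if (config$knowledge_mode == "mask_both") {
    p$W_mu_g <- rn(G, P, 1 / sqrt(G))
    p$W_lv_g <- rn(G, P, 1 / sqrt(G))
    p$W_mu_b <- rn(B, P, 0.01)
    p$W_lv_b <- rn(B, P, 0.01)
    p$b_mu <- rep(0, P)
    p$b_lv <- rep(0, P)
  } else {
    H <- config$hidden_width
    p$W1 <- rn(G + B, H, 1 / sqrt(G + B))
    p$b1 <- rep(0, H)
    p$W_mu <- rn(H, P, 1 / sqrt(H))
    p$b_mu <- rep(0, P)
    p$W_lv <- rn(H, P, 1 / sqrt(H))
    p$b_lv <- rep(0, P)
  }
  p$W_d <- rn(P, G, 0.01)
  p$b_d <- rep(0, G)
  p$O <- matrix(0, B, G)
  p
}

# One-hot batch indicator matrix (cells x B) for known batch levels.
batch_onehot <- function(batch, levels_ref, allow_unseen = FALSE) {
  batch <- as.character(batch)
  unseen <- !(batch %in% levels_ref)
  if (any(unseen) && !allow_unseen)
    stop("unseen batch categor(ies): ",
         paste(unique(batch[unseen]), collapse = ", "),
         "; set allow_unseen = TRUE for an all-zero indicator")
  bo <- matrix(0, length(batch), length(levels_ref),
               dimnames = list(NULL, levels_ref))
  idx <- match(batch, levels_ref)
  hit <- which(!is.na(idx))
  bo[cbind(hit, idx[hit])] <- 1
  bo
}

# Forward pass of the encoder given raw parameter list.  Returns mu,
# log_var (clamped), plus intermediates needed for backprop.
encoder_forward <- function(params, x, bo, config) {
  cl <- config$logvar_clamp
  if (config$knowledge_mode == "mask_both") {
    Mt <- attr(params, "mask_t")
    mu <- x %*% (params$W_mu_g * Mt) + bo %*% params$W_mu_b +
      rep(params$b_mu, each = nrow(x))
    lv_raw <- x %*% (params$W_lv_g * Mt) + bo %*% params$W_lv_b +
      rep(params$b_lv, each = nrow(x))
    h <- NULL
  } else {
    inp <- cbind(x, bo)
    h <- pmax(inp %*% params$W1 + rep(params$b1, each = nrow(x)), 0)
    mu <- h %*% params$W_mu + rep(params$b_mu, each = nrow(x))
    lv_raw <- h %*% params$W_lv + rep(params$b_lv, each = nrow(x))
  }
  lv <- pmin(pmax(lv_raw, cl[1]), cl[2])
  list(mu = mu, log_var = lv, clamped = (lv_raw < cl[1]) | (lv_raw > cl[2]),
       h = h)
}

decoder_forward <- function(params, z, bo, A, config) {
  W_eff <- effective_decoder_weights(params$W_d, A, config$knowledge_mode)
  z %*% W_eff + rep(params$b_d, each = nrow(z)) + bo %*% params$O
}

effective_decoder_weights <- function(W_d, A, mode) {
  if (mode %in% c("mask_decoder", "mask_both")) W_d * A else W_d
}

# Loss and analytic gradients for one minibatch; the workhorse of fit()
# and of the finite-difference gradient tests.
loss_and_grads <- function(params, x, bo, eps, A, config) {
  n <- nrow(x)
  enc <- encoder_forward(params, x, bo, config)
  z <- reparameterize(enc$mu, enc$log_var, eps)
  x_hat <- decoder_forward(params, z, bo, A, config)
  loss <- total_loss(x, x_hat, enc$mu, enc$log_var, params$W_d, A, config)

  g <- list()
  dxh <- 2 * (x_hat - x) / n
  W_eff <- effective_decoder_weights(params$W_d, A, config$knowledge_mode)
  gWd <- crossprod(z, dxh)
  if (config$knowledge_mode %in% c("mask_decoder", "mask_both")) gWd <- gWd * A
  g$W_d <- gWd + config$lambda_k *
    knowledge_penalty_grad(params$W_d, A, config$knowledge_mode)
  g$b_d <- colSums(dxh)
  g$O <- crossprod(bo, dxh)

  dz <- dxh %*% t(W_eff)
  dmu <- dz + config$beta_kl * enc$mu / n
  sig <- exp(0.5 * enc$log_var)
  dlv <- dz * eps * 0.5 * sig +
    config$beta_kl * 0.5 * (exp(enc$log_var) - 1) / n
  dlv[enc$clamped] <- 0

  if (config$knowledge_mode == "mask_both") {
    Mt <- attr(params, "mask_t")
    g$W_mu_g <- crossprod(x, dmu) * Mt
    g$W_lv_g <- crossprod(x, dlv) * Mt
    g$W_mu_b <- crossprod(bo, dmu)
    g$W_lv_b <- crossprod(bo, dlv)
    g$b_mu <- colSums(dmu)
    g$b_lv <- colSums(dlv)
  } else {
    g$W_mu <- crossprod(enc$h, dmu)
    g$b_mu <- colSums(dmu)
    g$W_lv <- crossprod(enc$h, dlv)
    g$b_lv <- colSums(dlv)
    dh <- dmu %*% t(params$W_mu) + dlv %*% t(params$W_lv)
    dh[enc$h <= 0] <- 0
    inp <- cbind(x, bo)
    g$W1 <- crossprod(inp, dh)
    g$b1 <- colSums(dh)
  }
  list(loss = loss, grads = g)
}

adam_init <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0),
       t = 0L)
}

adam_step <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in names(grads)) {
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * grads[[nm]]
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * grads[[nm]]^2
    params[[nm]] <- params[[nm]] -
      lr * (state$m[[nm]] / bc1) / (sqrt(state$v[[nm]] / bc2) + eps)
  }
  list(params = params, state = state)
}

#' Fit the pathway-regularized conditional VAE
#'
#' Trains on log-normalized expression with mini-batch Adam.  The latent
#' dimension equals the number of pathways in `A`; batch labels enter the
#' encoder as one-hot covariates and the decoder as learned per-batch
#' per-gene offsets, so the latent space is encouraged to be batch-free.
#' Fully deterministic given `config$seed`.
#'
#' @param X A preprocessed [count_matrix()] (log-normalized values); its
#'   gene order must equal the adjacency gene order.
#' @param A A `pathway_matrix` from [build_adjacency()].
#' @param config A [train_config()].
#' @return Object of class `pathvae_model`: parameter list, config,
#'   pathway/gene/batch vocabularies, and a per-epoch loss `history`
#'   data.frame with columns `epoch`, `reconstruction`, `kl`, `knowledge`,
#'   `total`.
#' @export
fit_pathvae <- function(X, A, config = train_config()) {
  stopifnot(inherits(X, "count_matrix"), inherits(A, "pathway_matrix"),
            inherits(config, "train_config"))
  if (!identical(toupper(gene_symbols(X)), A$genes))
    stop("gene order of the expression matrix does not match the adjacency; ",
         "build the adjacency on this matrix's gene universe")
  x <- dense_values(X)
  batches <- levels(X$batch)
  bo_all <- batch_onehot(X$batch, batches)
  G <- ncol(x); P <- nrow(A$A); B <- length(batches); n <- nrow(x)

  set.seed(config$seed)
  params <- init_params(G, P, B, config)
  if (config$knowledge_mode == "mask_both")
    attr(params, "mask_t") <- t(A$A)
  state <- adam_init(params)

  hist <- data.frame(epoch = integer(), reconstruction = numeric(),
                     kl = numeric(), knowledge = numeric(), total = numeric())
  if (config$epochs > 0) {
    for (ep in seq_len(config$epochs)) {
      ord <- sample.int(n)
      starts <- seq(1, n, by = config$minibatch_size)
      comp <- matrix(0, length(starts), 4)
      for (si in seq_along(starts)) {
        idx <- ord[starts[si]:min(starts[si] + config$minibatch_size - 1, n)]
        xb <- x[idx, , drop = FALSE]
        bob <- bo_all[idx, , drop = FALSE]
        eps <- matrix(stats::rnorm(length(idx) * P), length(idx), P)
        lg <- loss_and_grads(params, xb, bob, eps, A$A, config)
        if (!is.finite(lg$loss$total))
          stop("non-finite loss at epoch ", ep, ", minibatch ", si,
               " (reconstruction = ", format(lg$loss$reconstruction),
               ", kl = ", format(lg$loss$kl), ")")
        comp[si, ] <- c(lg$loss$reconstruction, lg$loss$kl,
                        lg$loss$knowledge, lg$loss$total)
        upd <- adam_step(params, lg$grads, state, config$learning_rate)
        mask_t <- attr(params, "mask_t")
        params <- upd$params
        attr(params, "mask_t") <- mask_t
        state <- upd$state
      }
      cm <- colMeans(comp)
      hist <- rbind(hist, data.frame(epoch = ep, reconstruction = cm[1],
                                     kl = cm[2], knowledge = cm[3],
                                     total = cm[4]))
    }
  }
  structure(
    list(params = params, config = config, pathways = A$pathways,
         genes = A$genes, batches = batches, adjacency = A$A,
         history = hist),
    class = "pathvae_model"
  )
}

#' @export
print.pathvae_model <- function(x, ...) {
  cat("<pathvae_model> ", length(x$pathways), " pathways x ",
      length(x$genes), " genes; ", length(x$batches), " batch(es); ",
      nrow(x$history), " epoch(s) trained (mode ",
      x$config$knowledge_mode, ")\n", sep = "")
  invisible(x)
}

#' Encode cells to posterior parameters
#'
#' Deterministic forward pass of the encoder.  Gene order must match the
#' model's training gene order (checked when `x` carries column names).
#'
#' @param model A fitted `pathvae_model`.
#' @param x Matrix of log-normalized expression (cells x genes) or a
#'   [count_matrix()].
#' @param batch Per-cell batch labels (taken from `x` when it is a
#'   `count_matrix` and `batch` is NULL).
#' @param allow_unseen If TRUE, batches the model has not seen get an
#'   all-zero indicator instead of an error.
#' @return List with matrices `mu` and `log_var` (cells x P).
#' @export
encode_cells <- function(model, x, batch = NULL, allow_unseen = FALSE) {
  stopifnot(inherits(model, "pathvae_model"))
  if (inherits(x, "count_matrix")) {
    if (is.null(batch)) batch <- x$batch
    x <- dense_values(x)
  }
  if (!is.null(colnames(x)) &&
      !identical(toupper(colnames(x)), model$genes))
    stop("gene columns do not match the model's training gene order")
  if (ncol(x) != length(model$genes))
    stop("expected ", length(model$genes), " genes, got ", ncol(x))
  if (length(batch) != nrow(x))
    stop("need one batch label per cell")
  bo <- batch_onehot(batch, model$batches, allow_unseen = allow_unseen)
  enc <- encoder_forward(model$params, x, bo, model$config)
  list(mu = enc$mu, log_var = enc$log_var)
}

#' Reconstruct expression from latent coordinates
#'
#' Single linear map: `x' = z w + gene bias + batch offset`, so each
#' decoder weight is directly a gene's contribution to a pathway.  Under
#' mask modes the effective weights are `w * A`.
#'
#' @param model A fitted `pathvae_model`.
#' @param z Latent matrix (cells x P).
#' @param batch Per-cell batch labels.
#' @param allow_unseen See [encode_cells()].
#' @return Reconstructed matrix (cells x genes).
#' @export
decode_cells <- function(model, z, batch, allow_unseen = FALSE) {
  stopifnot(inherits(model, "pathvae_model"))
  if (ncol(z) != length(model$pathways))
    stop("z must have ", length(model$pathways), " columns")
  bo <- batch_onehot(batch, model$batches, allow_unseen = allow_unseen)
  decoder_forward(model$params, z, bo, model$adjacency, model$config)
}

#' Project cells into the pathway latent space
#'
#' Returns the noise-free posterior mean as the cell embedding; columns
#' are named by pathway, rows by cell id.  This is the integration output.
#'
#' @param model A fitted `pathvae_model`.
#' @param X A [count_matrix()] with log-normalized values, or a bare
#'   matrix (then `batch` is required).
#' @param batch Optional per-cell batch labels overriding `X$batch`.
#' @param allow_unseen See [encode_cells()].
#' @return Matrix (cells x P) with pathway column names.
#' @export
transform_cells <- function(model, X, batch = NULL, allow_unseen = FALSE) {
  enc <- encode_cells(model, X, batch = batch, allow_unseen = allow_unseen)
  emb <- enc$mu
  colnames(emb) <- model$pathways
  if (inherits(X, "count_matrix")) rownames(emb) <- cell_ids(X)
  emb
}

#' Effective decoder weight matrix of a fitted model
#'
#' @param model A `pathvae_model`.
#' @param effective If TRUE (default), apply the structural mask under
#'   mask modes so off-pathway entries are exactly zero.
#' @return P x G matrix with pathway/gene dimnames.
#' @export
decoder_weights <- function(model, effective = TRUE) {
  stopifnot(inherits(model, "pathvae_model"))
  w <- if (effective)
    effective_decoder_weights(model$params$W_d, model$adjacency,
                              model$config$knowledge_mode)
  else model$params$W_d
  dimnames(w) <- list(model$pathways, model$genes)
  w
}

#' Save / load a model checkpoint
#'
#' Single-file container holding parameters, config, pathway names and
#' gene order; reloading reproduces [transform_cells()] output bit-exactly.
#'
#' @param model A `pathvae_model`.
#' @param path Checkpoint file path.
#' @return `path` invisibly (save); the model (load).
#' @export
save_model <- function(model, path) {
  stopifnot(inherits(model, "pathvae_model"))
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  model <- readRDS(path)
  if (!inherits(model, "pathvae_model"))
    stop("file does not contain a pathvae model checkpoint: ", path)
  model
}

#' Write an embedding as a delimited table
#'
#' @param embedding Matrix from [transform_cells()].
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_embedding <- function(embedding, path) {
  df <- data.frame(cell_id = rownames(embedding), embedding,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read an embedding written by [write_embedding()]
#'
#' @param path TSV path.
#' @return Matrix with cell-id rownames and pathway colnames.
#' @export
read_embedding <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  emb <- as.matrix(df[, -1, drop = FALSE])
  rownames(emb) <- df[[1]]
  emb
}
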