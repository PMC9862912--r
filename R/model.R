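#' Shallow ConvNet architecture specification
#'
#' Defines the layer chain
#' temporal conv (45 x 1, 40 filters, stride 2) -> spatial conv (1 x c)
#' -> batch norm -> square -> average pool (45, stride 1) -> max pool
#' (8, stride 8) -> log -> dense -> softmax, and derives the shape
#' chain.  With the default 1000-sample input the temporal convolution
#' yields `floor((1000 - 45)/2) + 1 = 478` time points, the average
#' pool 434, the max pool 54, and the dense layer receives
#' `54 * 40 = 2160` features regardless of the channel count (the
#' spatial convolution collapses the channel axis).
#'
#' @param n_channels EEG channel count c (>= 1).
#' @param n_classes class count s (>= 2).
#' @param input_len crop length in samples.
#' @param temporal_filter_len,temporal_stride temporal convolution
#'   filter length and stride.
#' @param n_filters number of convolutional filters.
#' @param avg_pool_len average-pool window (stride 1).
#' @param max_pool_len,max_pool_stride max-pool window and stride.
#' @param dropout dropout rate on the dense input, used only when
#'   training the deterministic baseline (the Bayesian variants drop it).
#' @return an `architecture_spec` with the derived shape fields
#'   `conv_out_len`, `avg_out_len`, `max_out_len`, `dense_in`.
#' @export
architecture_spec <- function(n_channels, n_classes, input_len = 1000,
                              temporal_filter_len = 45, n_filters = 40,
                              temporal_stride = 2, avg_pool_len = 45,
                              max_pool_len = 8, max_pool_stride = 8,
                              dropout = 0.5) {
  stopifnot(n_channels >= 1, n_classes >= 2, input_len >= temporal_filter_len,
            dropout >= 0, dropout < 1)
  conv_out <- (input_len - temporal_filter_len) %/% temporal_stride + 1
  if (conv_out < avg_pool_len)
    stop("input too short: temporal-conv output shorter than average-pool window")
  avg_out <- conv_out - avg_pool_len + 1
  if (avg_out < max_pool_len)
    stop("input too short: average-pool output shorter than max-pool window")
  max_out <- (avg_out - max_pool_len) %/% max_pool_stride + 1
  structure(list(n_channels = as.integer(n_channels),
                 n_classes = as.integer(n_classes),
                 input_len = as.integer(input_len),
                 temporal_filter_len = as.integer(temporal_filter_len),
                 n_filters = as.integer(n_filters),
                 temporal_stride = as.integer(temporal_stride),
                 avg_pool_len = as.integer(avg_pool_len),
                 max_pool_len = as.integer(max_pool_len),
                 max_pool_stride = as.integer(max_pool_stride),
                 dropout = dropout,
                 conv_out_len = as.integer(conv_out),
                 avg_out_len = as.integer(avg_out),
                 max_out_len = as.integer(max_out),
                 dense_in = as.integer(max_out * n_filters)),
            class = "architecture_spec")
}

glorot <- function(nrow, ncol) {
  lim <- sqrt(6 / (nrow + ncol))
  matrix(runif(nrow * ncol, -lim, lim), nrow, ncol)
}

new_weights <- function(spec) {
  c_ <- spec$n_channels; F_ <- spec$n_filters
  list(Wt = glorot(spec$temporal_filter_len, F_),
       Ws = glorot(c_ * F_, F_),
       Wd = glorot(spec$dense_in, spec$n_classes),
       bd = numeric(spec$n_classes))
}

#' Build the deterministic shallow ConvNet
#'
#' @param spec an [architecture_spec()].
#' @param seed seed for the weight initialization.
#' @return an object of class `scnn_model` with `kind = "deterministic"`:
#'   Glorot-initialized weights, unit batch-norm scale, zeroed running
#'   statistics.
#' @export
build_deterministic <- function(spec, seed = 1L) {
  stopifnot(inherits(spec, "architecture_spec"))
  w <- with_seed(seed, new_weights(spec))
  structure(list(spec = spec, kind = "deterministic", weights = w,
                 gamma = rep(1, spec$n_filters),
                 beta = rep(0, spec$n_filters),
                 bn_mean = rep(0, spec$n_filters),
                 bn_var = rep(1, spec$n_filters)),
            class = "scnn_model")
}

#' MOPED empirical prior from pretrained deterministic weights
#'
#' Builds a per-weight Gaussian prior `N(w_d, max(delta * |w_d|, eps)^2)`
#' from the weights of a trained deterministic model; the variational
#' posterior is initialized at the same location and scale.
#'
#' @param model a trained deterministic `scnn_model`.
#' @param delta prior relative scale (default 0.1).
#' @param eps scale floor for zero-valued weights.
#' @return a `prior_spec` with `kind = "moped"`.
#' @export
moped_prior <- function(model, delta = 0.1, eps = 1e-6) {
  stopifnot(inherits(model, "scnn_model"), model$kind == "deterministic")
  if (delta <= 0) stop("delta must be positive")
  if (eps <= 0) stop("eps must be positive")
  sigma <- lapply(model$weights, function(w) pmax(delta * abs(w), eps))
  structure(list(kind = "moped", delta = delta, eps = eps,
                 mu = model$weights, sigma = sigma, source = model),
            class = "prior_spec")
}

#' Standard-normal prior
#' @return a `prior_spec` with `kind = "standard"`: `N(0, 1)` on every
#'   weight.
#' @export
standard_prior <- function() {
  structure(list(kind = "standard"), class = "prior_spec")
}

#' Convert a deterministic model to its mean-field variational
#' counterpart
#'
#' Every convolutional and dense weight (including the dense bias) is
#' replaced by an independent Gaussian posterior `N(mu, sigma^2)` with
#' `sigma = softplus(rho) > 0` by construction.  Batch-norm scale/shift
#' are kept as point parameters and dropout is removed.  With a
#' standard prior the posterior starts at a fresh Glorot draw and small
#' scales; with a MOPED prior it starts at the pretrained weights and
#' scales `max(delta * |w_d|, eps)`, and the pretrained batch-norm
#' parameters and running statistics are carried over.
#'
#' @param model a deterministic `scnn_model`.
#' @param prior a [standard_prior()] or [moped_prior()].
#' @param seed seed for fresh initialization under the standard prior.
#' @return an `scnn_model` with `kind = "bayesian"`, holding `mu` and
#'   `rho` lists in place of point weights.
#' @export
to_bayesian <- function(model, prior = standard_prior(), seed = 1L) {
  stopifnot(inherits(model, "scnn_model"), inherits(prior, "prior_spec"))
  spec <- model$spec
  if (prior$kind == "moped") {
    if (is.null(prior$mu)) stop("MOPED prior requires pretrained weights")
    mu <- prior$mu
    rho <- lapply(prior$sigma, softplus_inv)
    gamma <- prior$source$gamma; beta <- prior$source$beta
    bn_mean <- prior$source$bn_mean; bn_var <- prior$source$bn_var
  } else {
    mu <- with_seed(seed, new_weights(spec))
    rho <- with_seed(seed + 1L, lapply(mu, function(w)
      array(rnorm(length(w), -3, 0.1), dim = if (is.matrix(w)) dim(w) else length(w))))
    rho <- lapply(rho, function(r) if (is.matrix(r)) r else as.numeric(r))
    gamma <- rep(1, spec$n_filters); beta <- rep(0, spec$n_filters)
    bn_mean <- rep(0, spec$n_filters); bn_var <- rep(1, spec$n_filters)
  }
  structure(list(spec = spec, kind = "bayesian", prior = prior,
                 mu = mu, rho = rho, gamma = gamma, beta = beta,
                 bn_mean = bn_mean, bn_var = bn_var),
            class = "scnn_model")
}

#' Number of trainable parameters
#' @param model an `scnn_model`.
#' @return named vector: `weights` (conv + dense, doubled for the
#'   Bayesian mean/scale pairs) and `point` (batch-norm parameters).
#' @export
n_parameters <- function(model) {
  ws <- if (model$kind == "bayesian") model$mu else model$weights
  nw <- sum(vapply(ws, length, 1L))
  c(weights = if (model$kind == "bayesian") 2L * nw else nw,
    point = 2L * model$spec$n_filters)
}

prior_moments <- function(model, name) {
  if (model$prior$kind == "moped")
    list(mu = model$prior$mu[[name]], sigma = model$prior$sigma[[name]])
  else list(mu = 0, sigma = 1)
}

#' Closed-form KL divergence between diagonal Gaussians
#'
#' `KL(N(mu, sigma^2) || N(mu0, sigma0^2))` summed over all elements.
#'
#' @param mu,sigma posterior moments (vectors/arrays).
#' @param mu0,sigma0 prior moments (scalars or matching arrays).
#' @return scalar KL in nats.
#' @export
kl_gaussian <- function(mu, sigma, mu0 = 0, sigma0 = 1) {
  stopifnot(all(sigma > 0), all(sigma0 > 0))
  sum(log(sigma0 / sigma) + (sigma^2 + (mu - mu0)^2) / (2 * sigma0^2) - 0.5)
}

#' Total posterior-to-prior KL of a Bayesian model
#' @param model a Bayesian `scnn_model`.
#' @return scalar KL in nats, summed over all variational weights.
#' @export
model_kl <- function(model) {
  stopifnot(model$kind == "bayesian")
  sum(vapply(names(model$mu), function(nm) {
    pr <- prior_moments(model, nm)
    kl_gaussian(model$mu[[nm]], softplus(model$rho[[nm]]), pr$mu, pr$sigma)
  }, 1.0))
}

#' Monte-Carlo ELBO loss
#'
#' Negative evidence lower bound estimated from one batch of sampled
#' predictions: categorical cross-entropy of the sampled class scores
#' plus `kl_weight` times the closed-form Gaussian KL between posterior
#' and prior.  Minimizing it maximizes the ELBO.
#'
#' @param probs `n x C` matrix of sampled class scores (simplex rows).
#' @param labels integer labels in `1..C`, length `n`.
#' @param model a Bayesian `scnn_model` (provides posterior and prior).
#' @param kl_weight weight of the divergence term, conventionally
#'   `1 / N_train`.
#' @return scalar loss.
#' @export
elbo_loss <- function(probs, labels, model, kl_weight) {
  stopifnot(is.matrix(probs), length(labels) == nrow(probs),
            all(labels >= 1), all(labels <= ncol(probs)), kl_weight > 0)
  ce <- -mean(log(pmax(probs[cbind(seq_along(labels), labels)], 1e-300)))
  ce + kl_weight * model_kl(model)
}

# sample concrete weights from the posterior; returns list(w, eps)
sample_weights <- function(model) {
  eps <- lapply(model$mu, function(m) {
    e <- rnorm(length(m))
    if (is.matrix(m)) matrix(e, nrow(m), ncol(m)) else e
  })
  w <- mapply(function(m, r, e) m + softplus(r) * e,
              model$mu, model$rho, eps, SIMPLIFY = FALSE)
  list(w = w, eps = eps)
}

# point weights for evaluation: posterior means (plug-in) or the
# deterministic weights
plugin_weights <- function(model) {
  if (model$kind == "bayesian") model$mu else model$weights
}

# crops array (n x c x L) -> cube (L x c x n) expected by the kernels
crops_to_cube <- function(crops, idx = NULL) {
  if (!is.null(idx)) crops <- crops[idx, , , drop = FALSE]
  aperm(crops, c(3, 2, 1))
}

forward_probs <- function(model, cube, weights = NULL) {
  w <- if (is.null(weights)) plugin_weights(model) else weights
  sp <- model$spec
  scnn_forward_cpp(cube, w$Wt, w$Ws, model$gamma, model$beta, w$Wd, w$bd,
                   model$bn_mean, model$bn_var, sp$temporal_stride,
                   sp$avg_pool_len, sp$max_pool_len, sp$max_pool_stride,
                   1e-5, 1e-6)
}
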