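#' SimAM configuration
#'
#' SimAM assigns every feature-map element a weight derived from the
#' closed-form minimum of a per-neuron energy function, with no learnable
#' parameters. The energy for target neuron `t` in a channel with
#' activations `x_1..x_{M-1}` (the other neurons) is
#'
#' \deqn{e_t(w,b) = (y_t - (w t + b))^2 +
#'   \frac{1}{M-1}\sum_{i}(y_o - (w x_i + b))^2 + \lambda w^2}
#'
#' with binary labels `y_t = 1`, `y_o = -1`. A neuron whose activation
#' stands out from the rest of its channel attains a low minimal energy and
#' hence a high attention weight `sigmoid(1/e*)`.
#'
#' @param lambda_reg ridge regulariser on the linear weight; must be > 0.
#'   Default `1e-4`, the value conventional for this attention module.
#' @return An object of class `"simam_config"`.
#' @export
simam_config <- function(lambda_reg = 1e-4) {
  lambda_reg <- as.numeric(lambda_reg)
  if (is.na(lambda_reg) || lambda_reg <= 0) {
    stop("lambda_reg must be > 0", call. = FALSE)
  }
  structure(list(lambda_reg = lambda_reg), class = "simam_config")
}

check_channel <- function(channel) {
  if (!is.matrix(channel) || !is.numeric(channel)) {
    stop("channel must be a numeric matrix (H x W)", call. = FALSE)
  }
  if (length(channel) < 2) {
    stop("degenerate channel: at least 2 neurons are required", call. = FALSE)
  }
  channel
}

#' SimAM per-neuron energy at given linear-transform parameters
#'
#' Evaluates the energy function directly at a candidate weight/bias pair,
#' using the exact leave-one-out sum over the other `M - 1` neurons. This
#' is the quantity whose minimiser defines the attention weight; it is
#' exposed mainly so the closed-form solution can be checked against naive
#' numerical minimisation.
#'
#' @param channel numeric H x W matrix: one channel of a feature map.
#' @param target_index length-2 integer vector `(row, col)` of the target
#'   neuron.
#' @param w,b linear transform parameters.
#' @param cfg a [simam_config()].
#' @return the scalar energy `e_t(w, b)`.
#' @export
neuron_energy <- function(channel, target_index, w, b, cfg = simam_config()) {
  channel <- check_channel(channel)
  t_val <- channel[target_index[[1]], target_index[[2]]]
  flat <- as.numeric(channel)
  pos <- (target_index[[2]] - 1L) * nrow(channel) + target_index[[1]]
  others <- flat[-pos]
  (1 - (w * t_val + b))^2 +
    mean((-1 - (w * others + b))^2) +
    cfg$lambda_reg * w^2
}

# Exact closed-form minimal energy of the leave-one-out energy function.
# mu/sigma2 are mean and biased variance over the M-1 other neurons.
simam_minimal_energy_exact <- function(channel, target_index,
                                       cfg = simam_config()) {
  channel <- check_channel(channel)
  t_val <- channel[target_index[[1]], target_index[[2]]]
  flat <- as.numeric(channel)
  pos <- (target_index[[2]] - 1L) * nrow(channel) + target_index[[1]]
  others <- flat[-pos]
  mu <- mean(others)
  sigma2 <- mean((others - mu)^2)
  lam <- cfg$lambda_reg
  4 * (sigma2 + lam) / ((t_val - mu)^2 + 2 * sigma2 + 2 * lam)
}

#' SimAM attention weights for one channel
#'
#' Computes each neuron's closed-form minimal energy
#' `e* = 4(s2 + lambda) / ((t - m)^2 + 2 s2 + 2 lambda)` and maps it to a
#' weight `sigmoid(1/e*)` in (0, 1). By default `m` and `s2` are the mean
#' and biased (1/M) variance over *all* M neurons of the channel — the
#' standard fast O(M) approximation of the exact leave-one-out statistics;
#' set `exact = TRUE` to use the O(M^2) per-neuron exclusion form, which
#' matches direct numerical minimisation of [neuron_energy()].
#'
#' @inheritParams neuron_energy
#' @param exact use exact leave-one-out channel statistics per neuron.
#' @return numeric matrix of weights, same shape as `channel`, all in (0, 1).
#' @examples
#' ch <- matrix(c(1, 1, 1, 5), 2, 2)
#' simam_weights(ch)  # the outlier neuron gets the largest weight
#' @export
simam_weights <- function(channel, cfg = simam_config(), exact = FALSE) {
  channel <- check_channel(channel)
  lam <- cfg$lambda_reg
  if (exact) {
    e_star <- channel
    for (j in seq_len(ncol(channel))) {
      for (i in seq_len(nrow(channel))) {
        e_star[i, j] <- simam_minimal_energy_exact(channel, c(i, j), cfg)
      }
    }
  } else {
    mu <- mean(channel)
    sigma2 <- mean((channel - mu)^2)
    e_star <- 4 * (sigma2 + lam) / ((channel - mu)^2 + 2 * sigma2 + 2 * lam)
  }
  1 / (1 + exp(-1 / e_star))
}

#' Apply SimAM attention to a feature map
#'
#' Element-wise product of the input with the per-channel attention weights:
#' a unique three-dimensional (C x H x W) weight per element, no learnable
#' parameters consumed or produced, channels processed independently.
#'
#' @param feature_map numeric array of dimension `c(C, H, W)`.
#' @param cfg a [simam_config()].
#' @return array of the same shape.
#' @export
apply_simam <- function(feature_map, cfg = simam_config()) {
  if (!is.array(feature_map) || length(dim(feature_map)) != 3) {
    stop("feature_map must be a C x H x W array", call. = FALSE)
  }
  out <- feature_map
  for (c_idx in seq_len(dim(feature_map)[1])) {
    ch <- feature_map[c_idx, , , drop = TRUE]
    if (!is.matrix(ch)) ch <- matrix(ch, dim(feature_map)[2], dim(feature_map)[3])
    out[c_idx, , ] <- ch * simam_weights(ch, cfg)
  }
  out
}
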