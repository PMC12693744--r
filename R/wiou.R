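#' WIoU-v3 hyperparameters
#'
#' The dynamic non-monotonic focusing mechanism scales the distance-weighted
#' IoU loss (WIoU-v1) by a coefficient `r(beta)` of the anchor's "anomaly
#' degree" `beta = L_IoU / mean(L_IoU)`, where the mean is an exponential
#' moving average over batches. `r = beta / (delta * alpha^(beta - delta))`
#' equals 1 exactly at `beta = delta`, rises to a single interior maximum,
#' and decays for large `beta`, so both very easy and very anomalous anchors
#' receive damped gradient gain.
#'
#' @param alpha focusing base, > 1; default 1.9.
#' @param delta focusing pivot, > 0 (where `r = 1`); default 3.
#' @param ema_decay EMA retention factor in (0, 1); default 0.9.
#' @return An object of class `"wiou_params"`.
#' @export
wiou_params <- function(alpha = 1.9, delta = 3.0, ema_decay = 0.9) {
  alpha <- as.numeric(alpha); delta <- as.numeric(delta)
  ema_decay <- as.numeric(ema_decay)
  if (is.na(alpha) || alpha <= 1) stop("alpha must be > 1", call. = FALSE)
  if (is.na(delta) || delta <= 0) stop("delta must be > 0", call. = FALSE)
  if (is.na(ema_decay) || ema_decay <= 0 || ema_decay >= 1) {
    stop("ema_decay must lie in (0, 1)", call. = FALSE)
  }
  structure(list(alpha = alpha, delta = delta, ema_decay = ema_decay),
            class = "wiou_params")
}

#' Running mean of the IoU loss
#'
#' `ema_state()` creates an uninitialised state; [update_ema()] folds in a
#' batch. The first batch sets the mean to the batch mean; thereafter
#' `mean <- decay * mean + (1 - decay) * batch_mean`. In a differentiable
#' setting the mean is a detached constant: no gradient flows through it.
#'
#' @return An object of class `"ema_state"` with fields `mean_iou_loss`
#'   and `initialised`.
#' @export
ema_state <- function() {
  structure(list(mean_iou_loss = NA_real_, initialised = FALSE),
            class = "ema_state")
}

#' @rdname ema_state
#' @param state an `ema_state`.
#' @param batch_iou_losses non-empty numeric vector of IoU losses in \[0, 1\].
#' @param params a [wiou_params()].
#' @export
update_ema <- function(state, batch_iou_losses, params = wiou_params()) {
  if (length(batch_iou_losses) == 0) {
    stop("batch_iou_losses must be non-empty", call. = FALSE)
  }
  if (any(batch_iou_losses < 0 | batch_iou_losses > 1)) {
    stop("IoU losses must lie in [0, 1]", call. = FALSE)
  }
  m <- mean(batch_iou_losses)
  if (!state$initialised) {
    state$mean_iou_loss <- m
    state$initialised <- TRUE
  } else {
    state$mean_iou_loss <- params$ema_decay * state$mean_iou_loss +
      (1 - params$ema_decay) * m
  }
  state
}

#' Anchor-box anomaly degree
#'
#' `beta = L_IoU / mean(L_IoU)`: the current anchor's IoU loss relative to
#' the running mean. The larger beta, the poorer the anchor.
#'
#' @param l_iou IoU loss of the current anchor, in \[0, 1\].
#' @param state an initialised [ema_state()] with positive mean.
#' @return beta >= 0.
#' @export
anomaly_degree <- function(l_iou, state) {
  if (!state$initialised) {
    stop("EMA state is uninitialised; update it with a batch first",
         call. = FALSE)
  }
  if (state$mean_iou_loss <= 0) {
    stop("anomaly degree undefined for zero mean IoU loss", call. = FALSE)
  }
  l_iou / state$mean_iou_loss
}

#' Non-monotonic focusing coefficient
#'
#' `r = beta / (delta * alpha^(beta - delta))`. Properties: `r > 0` for
#' `beta > 0`, `r(0) = 0`, `r(delta) = 1` for any valid parameters, and a
#' single interior maximum at `beta = 1/log(alpha)` — the anomaly degree
#' that receives the highest gradient gain.
#'
#' @param beta anomaly degree, >= 0 (vectorised).
#' @param params a [wiou_params()].
#' @return the coefficient, same length as `beta`.
#' @examples
#' focusing_coefficient(3, wiou_params(alpha = 1.9, delta = 3))  # exactly 1
#' @export
focusing_coefficient <- function(beta, params = wiou_params()) {
  if (any(beta < 0)) stop("beta must be >= 0", call. = FALSE)
  beta / (params$delta * params$alpha^(beta - params$delta))
}

#' Distance-weighted IoU loss (WIoU-v1)
#'
#' The IoU loss amplified by a center-distance penalty:
#' `R = exp(d2 / (Wg^2 + Hg^2))` where `d2` is the squared distance between
#' the two box centers and `Wg`, `Hg` are the sides of the smallest box
#' enclosing both. The denominator is treated as a constant with respect to
#' any differentiation.
#'
#' @param pred,target valid boxes (see [box()]).
#' @return loss >= 0.
#' @export
wiou_v1 <- function(pred, target) {
  pred <- as_box(pred); target <- as_box(target)
  cp <- box_center(pred); cg <- box_center(target)
  enc <- enclosing_box(pred, target)
  wg <- enc[["x_max"]] - enc[["x_min"]]
  hg <- enc[["y_max"]] - enc[["y_min"]]
  r_wiou <- exp(((cp[["x"]] - cg[["x"]])^2 + (cp[["y"]] - cg[["y"]])^2) /
                  (wg^2 + hg^2))
  r_wiou * iou_loss(pred, target)
}

#' WIoU-v3 loss
#'
#' `r(beta) * L_WIoU1` with `beta` computed against the running mean IoU
#' loss held in `state`. Zero exactly when `pred == target`.
#'
#' @inheritParams wiou_v1
#' @param state an initialised [ema_state()].
#' @param params a [wiou_params()].
#' @return loss >= 0.
#' @export
wiou_v3 <- function(pred, target, state, params = wiou_params()) {
  beta <- anomaly_degree(iou_loss(pred, target), state)
  focusing_coefficient(beta, params) * wiou_v1(pred, target)
}

#' Tabulate the focusing coefficient over a beta grid
#'
#' @param params a [wiou_params()].
#' @param beta_max upper end of the grid.
#' @param n number of grid points.
#' @return a data.frame with columns `beta` and `r`.
#' @export
focusing_table <- function(params = wiou_params(), beta_max = 10, n = 101) {
  beta <- seq(0, beta_max, length.out = n)
  data.frame(beta = beta, r = focusing_coefficient(beta, params))
}
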