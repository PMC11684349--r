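# Differential-privacy mechanisms: update clipping, sensitivity, noise-scale
# calibration for the Laplace and two Gaussian mechanisms, and scope-selective
# perturbation of layer-structured model updates.
#
# Noise is added to the client's post-clip model update (the delta it uploads)
# before aggregation, not to the resting weights: update-space noise is what
# federated averaging actually transmits. The perturbation scope selects which
# layers are touched -- the full model, the shared trunk, or one task branch;
# layers outside the scope are left bit-identical.

#' Differential-privacy configuration
#'
#' @param mechanism One of `none` (no perturbation), `gaussian_fixed`
#'   (Gaussian noise at a fixed `sigma`, the noise-level sweep mechanism),
#'   `laplace` (scale `b = delta_f / epsilon`), `gaussian1`
#'   (`sigma = delta_f * sqrt(2 * log(1.25 / delta)) / epsilon`, the classic
#'   analytic Gaussian mechanism) or `gaussian2`
#'   (`sigma = delta_f * sqrt(2 * q * T * log(1 / delta)) / epsilon`, the
#'   composition-aware variant where `q = K / N` is the client sampling
#'   fraction and `T` the number of rounds).
#' @param epsilon Privacy budget (> 0; required by the calibrated mechanisms).
#' @param delta DP failure probability in (0, 1); default 1e-5.
#' @param clip L2 clipping threshold C (> 0); default 1.
#' @param sigma Fixed noise sd for `gaussian_fixed` (>= 0).
#' @param scope Which layers are clipped and perturbed: `full`, `shared`,
#'   `identity_specific` (default; the privacy branch) or `stress_specific`.
#' @param q Client sampling fraction K / N in (0, 1].
#' @param rounds Number of communication rounds T entering `gaussian2`.
#' @param sensitivity_rule `per_client_size` (`delta_f = 2 * clip / U_i`) or
#'   `clip_only` (`delta_f = 2 * clip`).
#' @param noise_target What the client uploads and therefore what is clipped
#'   and perturbed: `weights` (default; the locally trained parameters of the
#'   scoped layers are norm-clipped to `clip` and noised before upload, the
#'   client-level scheme of the personalised-FL lineage this follows) or
#'   `update` (the delta to the broadcast model is clipped and noised, the
#'   DP-SGD-style reading). The two are algebraically identical except for
#'   which tensor the norm bound constrains; see the package vignette for why
#'   the default matters for the privacy-utility trade-off.
#' @return A `dp_config` object.
#' @export
dp_config <- function(mechanism = c("none", "gaussian_fixed", "laplace",
                                    "gaussian1", "gaussian2"),
                      epsilon = NULL, delta = 1e-5, clip = 1, sigma = NULL,
                      scope = c("identity_specific", "full", "shared",
                                "stress_specific"),
                      q = 1, rounds = 40L,
                      sensitivity_rule = c("per_client_size", "clip_only"),
                      noise_target = c("weights", "update")) {
  mechanism <- match.arg(mechanism)
  scope <- match.arg(scope)
  sensitivity_rule <- match.arg(sensitivity_rule)
  noise_target <- match.arg(noise_target)
  if (mechanism == "gaussian_fixed" && is.null(sigma)) {
    stop_fs("invalid_config", "gaussian_fixed requires sigma")
  }
  if (mechanism %in% c("laplace", "gaussian1", "gaussian2")) {
    if (is.null(epsilon) || epsilon <= 0) {
      stop_fs("invalid_config", "%s requires epsilon > 0", mechanism)
    }
    if (delta <= 0 || delta >= 1) {
      stop_fs("invalid_config", "delta must lie in (0, 1)")
    }
    if (clip <= 0) stop_fs("invalid_config", "clip must be > 0")
  }
  if (!is.null(sigma) && sigma < 0) {
    stop_fs("invalid_config", "sigma must be >= 0")
  }
  if (q <= 0 || q > 1) stop_fs("invalid_config", "q must lie in (0, 1]")
  structure(
    list(mechanism = mechanism, epsilon = epsilon, delta = delta, clip = clip,
         sigma = sigma, scope = scope, q = q, rounds = as.integer(rounds),
         sensitivity_rule = sensitivity_rule, noise_target = noise_target),
    class = "dp_config"
  )
}

#' @export
print.dp_config <- function(x, ...) {
  cat(sprintf("<dp_config> %s, scope=%s%s%s\n", x$mechanism, x$scope,
              if (!is.null(x$epsilon)) sprintf(", eps=%g, delta=%g", x$epsilon, x$delta) else "",
              if (!is.null(x$sigma)) sprintf(", sigma=%g", x$sigma) else ""))
  invisible(x)
}

# layer names belonging to a perturbation scope
scope_layer_names <- function(scopes, scope) {
  if (scope == "full") return(names(scopes))
  names(scopes)[scopes == scope]
}

#' Clip a layer-structured update to a global L2 norm bound
#'
#' Computes the L2 norm over all coordinates of the listed layers and rescales
#' those layers by `min(1, C / norm)`, so the post-clip norm is
#' `min(pre_norm, C)`; the update is untouched when already within the bound.
#'
#' @param delta A `model_params`-structured update.
#' @param C Clipping threshold (> 0).
#' @param layers Layer names over which the norm is taken and which are
#'   rescaled (default: all layers).
#' @return List `delta` (clipped update), `pre_norm`, `post_norm`.
#' @export
clip_update <- function(delta, C, layers = names(delta)) {
  if (C <= 0) stop_fs("invalid_argument", "C must be > 0")
  vals <- unlist(lapply(delta[layers], function(l) c(l$W, l$b)), use.names = FALSE)
  if (any(!is.finite(vals))) stop_fs("invalid_input", "non-finite update")
  pre <- sqrt(sum(vals^2))
  fac <- min(1, C / max(pre, .Machine$double.xmin))
  if (fac < 1) {
    for (ln in layers) {
      delta[[ln]]$W <- delta[[ln]]$W * fac
      delta[[ln]]$b <- delta[[ln]]$b * fac
    }
  }
  list(delta = delta, pre_norm = pre, post_norm = min(pre, C))
}

#' Sensitivity of a clipped client update
#'
#' `delta_f = 2 * C / U_i` under the default `per_client_size` rule (the
#' per-example sensitivity of a size-`U_i` clipped average), or `delta_f =
#' 2 * C` under `clip_only` (worst case ignoring the client size). Both
#' readings are exposed because the scaling with client size is a modelling
#' choice.
#'
#' @param C Clipping threshold.
#' @param U_i Client dataset size (>= 1).
#' @param rule `per_client_size` or `clip_only`.
#' @return The sensitivity `delta_f`.
#' @export
#' @examples
#' sensitivity(1, 1000)   # 0.002
sensitivity <- function(C, U_i, rule = c("per_client_size", "clip_only")) {
  rule <- match.arg(rule)
  if (U_i < 1) stop_fs("invalid_argument", "U_i must be >= 1")
  if (rule == "per_client_size") 2 * C / U_i else 2 * C
}

#' Laplace noise scale
#'
#' `b = delta_f / epsilon`; the Laplace mechanism with this scale is
#' `epsilon`-DP for an L1 sensitivity `delta_f`.
#'
#' @param delta_f Sensitivity.
#' @param epsilon Privacy budget (> 0).
#' @return Scale `b`.
#' @export
laplace_scale <- function(delta_f, epsilon) {
  if (epsilon <= 0) stop_fs("invalid_argument", "epsilon must be > 0")
  delta_f / epsilon
}

#' Gaussian noise scales
#'
#' `gaussian_sigma1` is the classic analytic calibration
#' `sigma = delta_f * sqrt(2 * log(1.25 / delta)) / epsilon`;
#' `gaussian_sigma2` the composition-aware calibration
#' `sigma = delta_f * sqrt(2 * q * T * log(1 / delta)) / epsilon`, growing
#' with the number of rounds `T` and sampling fraction `q`.
#'
#' @param delta_f Sensitivity.
#' @param epsilon Privacy budget (> 0).
#' @param delta Failure probability in (0, 1).
#' @return Noise standard deviation.
#' @export
gaussian_sigma1 <- function(delta_f, epsilon, delta) {
  if (epsilon <= 0) stop_fs("invalid_argument", "epsilon must be > 0")
  if (delta <= 0 || delta >= 1) stop_fs("invalid_argument", "delta must lie in (0, 1)")
  delta_f * sqrt(2 * log(1.25 / delta)) / epsilon
}

#' @rdname gaussian_sigma1
#' @param q Client sampling fraction in (0, 1].
#' @param rounds Number of communication rounds T (>= 1).
#' @export
gaussian_sigma2 <- function(delta_f, q, rounds, epsilon, delta) {
  if (epsilon <= 0) stop_fs("invalid_argument", "epsilon must be > 0")
  if (delta <= 0 || delta >= 1) stop_fs("invalid_argument", "delta must lie in (0, 1)")
  if (q <= 0 || q > 1) stop_fs("invalid_argument", "q must lie in (0, 1]")
  if (rounds < 1) stop_fs("invalid_argument", "rounds must be >= 1")
  delta_f * sqrt(2 * q * rounds * log(1 / delta)) / epsilon
}

#' Draw Laplace noise
#'
#' Difference of two independent Exp(1 / b) variables, which is exactly
#' Laplace(0, b).
#'
#' @param n Number of draws.
#' @param b Scale (>= 0).
#' @return Numeric vector.
#' @export
rlaplace <- function(n, b) {
  if (b < 0) stop_fs("invalid_argument", "b must be >= 0")
  b * (stats::rexp(n) - stats::rexp(n))
}

# noise scale implied by a dp_config for a client of size U_i
dp_noise_scale <- function(dp, U_i) {
  df <- function() sensitivity(dp$clip, U_i, dp$sensitivity_rule)
  switch(dp$mechanism,
    none = 0,
    gaussian_fixed = dp$sigma,
    laplace = laplace_scale(df(), dp$epsilon),
    gaussian1 = gaussian_sigma1(df(), dp$epsilon, dp$delta),
    gaussian2 = gaussian_sigma2(df(), dp$q, dp$rounds, dp$epsilon, dp$delta)
  )
}

#' Clip and perturb a model update under a DP configuration
#'
#' Restricts attention to the layers in the configured scope: clips their
#' joint L2 norm to `clip`, then adds i.i.d. noise of the configured
#' mechanism and scale to every coordinate of those layers. Layers outside
#' the scope are returned bit-identical. With `mechanism = "none"`, or
#' `gaussian_fixed` at `sigma = 0`, the update passes through unchanged (no
#' clipping either, so the null configuration is exactly the no-DP path).
#'
#' @param update A `model_params`-structured update (client delta).
#' @param scopes Named character vector layer -> scope (taken from the model
#'   via `attr(params, "scopes")`).
#' @param dp A [dp_config()].
#' @param U_i Client dataset size (enters the sensitivity).
#' @param seed Integer seed for the noise draw.
#' @return A `perturbed_update`: list `delta` (the perturbed update),
#'   `scope`, `mechanism`, `noise_scale`, `pre_clip_norm`, `post_clip_norm`.
#' @export
perturb <- function(update, scopes, dp, U_i, seed = 1L) {
  if (!dp$scope %in% c("full", "shared", "identity_specific", "stress_specific")) {
    stop_fs("invalid_config", "unknown scope %s", dp$scope)
  }
  layers <- scope_layer_names(scopes, dp$scope)
  if (length(setdiff(layers, names(update))) > 0L) {
    stop_fs("invalid_config", "scope layers missing from update")
  }
  scale <- dp_noise_scale(dp, U_i)
  if (dp$mechanism == "none" || scale == 0) {
    return(structure(list(delta = update, scope = dp$scope,
                          mechanism = dp$mechanism, noise_scale = 0,
                          pre_clip_norm = NA_real_, post_clip_norm = NA_real_),
                     class = "perturbed_update"))
  }
  cl <- clip_update(update, dp$clip, layers)
  update <- cl$delta
  with_seed(seed, {
    for (ln in layers) {
      nW <- length(update[[ln]]$W)
      nb <- length(update[[ln]]$b)
      noise <- if (dp$mechanism == "laplace") {
        rlaplace(nW + nb, scale)
      } else {
        stats::rnorm(nW + nb, sd = scale)
      }
      update[[ln]]$W <- update[[ln]]$W + noise[seq_len(nW)]
      update[[ln]]$b <- update[[ln]]$b + noise[nW + seq_len(nb)]
    }
  })
  structure(list(delta = update, scope = dp$scope, mechanism = dp$mechanism,
                 noise_scale = scale, pre_clip_norm = cl$pre_norm,
                 post_clip_norm = cl$post_norm),
            class = "perturbed_update")
}
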