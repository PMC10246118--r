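#' Algorithm configuration
#'
#' Settings for one filtering run. Counts must be at least 1 except
#' `learn_steps_per_t`, where 0 switches off dynamics learning (filtering-only
#' mode, used when the true model parameters are known and fixed).
#'
#' @param n_mc_predict Monte-Carlo samples for the variational prediction
#'   expectation (ignored when an exact mode is available).
#' @param cvi_iters,cvi_step_size CVI update settings (step size in `(0, 1]`).
#' @param learn_steps_per_t Gradient steps on the dynamics per observation.
#' @param learn_rate Learning rate for the dynamics optimizer.
#' @param learn_rate_decay Decay constant for the learning rate (see
#'   [learn_dynamics_step()]); 0 keeps it constant.
#' @param learn_n_mc Samples per dynamics-learning gradient estimate.
#' @param optimizer `"adam"` (default) or `"sgd"`.
#' @param correction `"ekf_like"` (default) applies the variance correction
#'   after the predict step; `"none"` disables it.
#' @param predict_mode `"auto"`, `"exact"` or `"mc"` (see
#'   [variational_predict()]).
#' @param learn_exact Use the closed-form expected natural parameters in the
#'   learning gradient when available.
#' @param learn_loss `"natural"` (square natural-parameter matching) or
#'   `"kl"` (exact M-step KL gradient); see [learn_dynamics_step()].
#' @param learn_grad_clip Gradient-norm clip for the learning step
#'   (`Inf` = off).
#' @return A list of class `evkf_config`.
#' @export
evkf_config <- function(n_mc_predict = 64, cvi_iters = 10, cvi_step_size = 0.5,
                        learn_steps_per_t = 1, learn_rate = 1e-3,
                        learn_rate_decay = 0,
                        learn_n_mc = 64, optimizer = "adam",
                        correction = c("ekf_like", "none"),
                        predict_mode = c("auto", "exact", "mc"),
                        learn_exact = FALSE,
                        learn_loss = c("natural", "kl"),
                        learn_grad_clip = Inf) {
  stopifnot(n_mc_predict >= 1, cvi_iters >= 1, cvi_step_size > 0,
            cvi_step_size <= 1, learn_steps_per_t >= 0, learn_n_mc >= 1)
  structure(list(n_mc_predict = n_mc_predict, cvi_iters = cvi_iters,
                 cvi_step_size = cvi_step_size,
                 learn_steps_per_t = learn_steps_per_t,
                 learn_rate = learn_rate, learn_rate_decay = learn_rate_decay,
                 learn_n_mc = learn_n_mc,
                 optimizer = optimizer,
                 correction = match.arg(correction),
                 predict_mode = match.arg(predict_mode),
                 learn_exact = isTRUE(learn_exact),
                 learn_loss = match.arg(learn_loss),
                 learn_grad_clip = learn_grad_clip),
            class = "evkf_config")
}

# Default initial posterior per family: standard normal (Gaussian), uniform
# (CB, lambda = 0), weakly-informative unit mean (Gamma, alpha = 2, beta = 2).
default_init_lambda <- function(family) {
  L <- family$dim_z
  if (inherits(family, "gaussian_family")) {
    gaussian_natural(numeric(L), diag(L))
  } else if (inherits(family, "cb_family")) {
    numeric(L)
  } else if (inherits(family, "gamma_family")) {
    c(rep(1, L), rep(-2, L))
  } else {
    stop("no default initial posterior for family '", family$name, "'", call. = FALSE)
  }
}

#' Initialize and advance the filter state
#'
#' `filter_init()` builds the state carried across time steps: current
#' posterior natural parameters, the dynamics model, optimizer state and a
#' step counter — constant size in the stream length. `filter_step()`
#' consumes exactly one observation, performing predict, correct, update and
#' learn (in that order), and returns the new state together with a one-row
#' record of the step.
#'
#' @param dyn An `evkf_dynamics` object (also fixes the latent family).
#' @param lik An `evkf_likelihood`.
#' @param config An [evkf_config()].
#' @param lambda0 Initial posterior natural parameters (defaults per family).
#' @param opt_state Optimizer state to resume from (e.g. a checkpoint).
#' @param state A state returned by `filter_init`/`filter_step`.
#' @param y One observation vector.
#' @return `filter_init`: an `evkf_state`. `filter_step`: a list with `state`
#'   and `record` (a one-row tibble: `t`, posterior mean/marginal variance per
#'   latent dimension, `elbo`, `learn_loss`).
#' @export
filter_init <- function(dyn, lik, config = evkf_config(), lambda0 = NULL,
                        opt_state = NULL) {
  family <- dyn$family
  lambda0 <- lambda0 %||% default_init_lambda(family)
  check_lambda(family, lambda0)
  structure(list(family = family, lambda = lambda0, dyn = dyn, lik = lik,
                 config = config, opt_state = opt_state, t = 0L),
            class = "evkf_state")
}

posterior_mean_var <- function(family, lambda) {
  if (inherits(family, "gaussian_family")) {
    mo <- gaussian_moments(family, lambda)
    list(mean = mo$m, var = diag(mo$P))
  } else {
    mv <- scalar_family_moments(family, lambda)
    list(mean = mv$mean, var = mv$var)
  }
}

#' @rdname filter_init
#' @export
filter_step <- function(state, y) {
  cfg <- state$config
  family <- state$family
  step_tag <- function(e) {
    stop(sprintf("step %d: %s", state$t + 1L, conditionMessage(e)), call. = FALSE)
  }
  tryCatch({
    lam_bar <- variational_predict(family, state$lambda, state$dyn,
                                   n_mc = cfg$n_mc_predict,
                                   mode = cfg$predict_mode)
    if (cfg$correction == "ekf_like") {
      lam_bar <- predict_correction(family, lam_bar, state$lambda, state$dyn,
                                    n_mc = cfg$n_mc_predict)
    }
    conj <- inherits(family, "gaussian_family") && state$lik$kind == "gaussian"
    if (conj) {
      lam_star <- conjugate_update(family, lam_bar, y, state$lik)
      elbo <- elbo_value(family, lam_star, lam_bar, y, state$lik)
    } else {
      lam_star <- cvi_update(family, lam_bar, y, state$lik,
                             iters = cfg$cvi_iters, beta = cfg$cvi_step_size)
      elbo <- attr(lam_star, "elbo")
      attributes(lam_star) <- NULL
    }
    learn <- learn_dynamics_step(family, lam_star, state$lambda, state$dyn,
                                 opt_state = state$opt_state,
                                 n_mc = cfg$learn_n_mc,
                                 steps = cfg$learn_steps_per_t,
                                 rate = cfg$learn_rate,
                                 rate_decay = cfg$learn_rate_decay,
                                 optimizer = cfg$optimizer,
                                 exact = cfg$learn_exact,
                                 grad_clip = cfg$learn_grad_clip,
                                 loss = cfg$learn_loss)
    state$dyn <- learn$dyn
    state$opt_state <- learn$opt_state
    state$lambda <- lam_star
    state$t <- state$t + 1L
    mv <- posterior_mean_var(family, lam_star)
    rec <- tibble::tibble(t = state$t)
    for (i in seq_along(mv$mean)) rec[[paste0("m", i)]] <- mv$mean[i]
    for (i in seq_along(mv$var)) rec[[paste0("v", i)]] <- mv$var[i]
    rec$elbo <- elbo
    rec$learn_loss <- learn$loss
    list(state = state, record = rec, lambda_bar = lam_bar)
  }, error = step_tag)
}

#' Run the filter over an observation stream
#'
#' Streams a time-ordered set of observations through the eVKF, one row at a
#' time (no lookahead; memory constant in the stream length), and collects the
#' per-step records. Observations may be a `T x N` matrix or a data frame /
#' tibble whose non-`t` columns are the `N` observation channels, so a
#' simulator output can be piped straight in.
#'
#' @param data Observations: matrix or data frame with one row per time bin.
#' @inheritParams filter_init
#' @param keep_lambda Keep the full natural-parameter trajectory (`T x
#'   dim_lambda` matrix) in the result.
#' @return An object of class `evkf_fit`: list with `records` (tibble), the
#'   final `state`, the learned `dyn`, `family`, `lik`, `config`, and
#'   optionally `lambda` (natural-parameter trajectory).
#' @examples
#' sim <- simulate_lds(L = 1, N = 1, T = 50, A = matrix(0.9), Q = matrix(0.1),
#'                     C = matrix(1), b = 0, R = matrix(0.5), seed = 1)
#' dyn <- linear_gaussian_dynamics(matrix(0.9), matrix(0.1))
#' fit <- evkf_filter(sim$observations, dyn, sim$lik,
#'                    config = evkf_config(learn_steps_per_t = 0))
#' tidy(fit)
#' @export
evkf_filter <- function(data, dyn, lik, config = evkf_config(),
                        lambda0 = NULL, keep_lambda = TRUE, opt_state = NULL) {
  ys <- obs_matrix(data, lik$N)
  state <- filter_init(dyn, lik, config, lambda0, opt_state = opt_state)
  Tn <- nrow(ys)
  recs <- vector("list", Tn)
  lambdas <- if (keep_lambda) matrix(NA_real_, Tn, state$family$dim_lambda)
  for (t in seq_len(Tn)) {
    out <- filter_step(state, ys[t, ])
    state <- out$state
    recs[[t]] <- out$record
    if (keep_lambda) lambdas[t, ] <- state$lambda
  }
  structure(list(records = dplyr::bind_rows(recs), state = state,
                 dyn = state$dyn, family = state$family, lik = lik,
                 config = config, lambda = if (keep_lambda) lambdas),
            class = "evkf_fit")
}

# Coerce a tibble/data.frame/matrix of observations to a T x N matrix.
obs_matrix <- function(data, N) {
  if (is.data.frame(data)) {
    data <- as.matrix(data[setdiff(names(data), "t")])
  }
  data <- as.matrix(data)
  if (ncol(data) != N) {
    stop(sprintf("observations have %d channels but the likelihood expects %d",
                 ncol(data), N), call. = FALSE)
  }
  storage.mode(data) <- "double"
  data
}

#' @export
print.evkf_fit <- function(x, ...) {
  cat(sprintf("<evkf_fit: %s family, %d steps, %s likelihood (N = %d)>\n",
              x$family$name, nrow(x$records), x$lik$kind, x$lik$N))
  cat(sprintf("  mean elbo %.4f, final learn loss %s\n",
              mean(x$records$elbo),
              format(x$records$learn_loss[nrow(x$records)], digits = 4)))
  invisible(x)
}
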