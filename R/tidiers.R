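#' Tidy a filtering run
#'
#' `tidy()` returns the per-step records in long-friendly wide form (one row
#' per time bin: posterior means `m*`, marginal variances `v*`, the per-step
#' ELBO and the dynamics learning loss). `glance()` returns a one-row summary.
#'
#' @param x An `evkf_fit`.
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.evkf_fit <- function(x, ...) {
  x$records
}

#' @rdname tidy.evkf_fit
#' @export
glance.evkf_fit <- function(x, ...) {
  r <- x$records
  tibble::tibble(
    n_steps = nrow(r),
    dim_z = x$family$dim_z,
    n_channels = x$lik$N,
    family = x$family$name,
    likelihood = x$lik$kind,
    mean_elbo = mean(r$elbo),
    final_learn_loss = r$learn_loss[nrow(r)]
  )
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a filtering run
#'
#' Posterior mean per latent dimension with a two-standard-deviation ribbon,
#' one facet per dimension; optionally overlays the true latents.
#'
#' @param object An `evkf_fit`.
#' @param truth Optional true latents (matrix or `latents` tibble).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.evkf_fit <- function(object, truth = NULL, ...) {
  r <- object$records
  L <- object$family$dim_z
  long <- tidyr::pivot_longer(
    r, cols = dplyr::matches("^[mv][0-9]+$"),
    names_to = c(".value", "dim"),
    names_pattern = "([mv])([0-9]+)"
  )
  long$dim <- paste0("z", long$dim)
  p <- ggplot2::ggplot(long, ggplot2::aes(x = .data$t, y = .data$m)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$m - 2 * sqrt(.data$v),
                                      ymax = .data$m + 2 * sqrt(.data$v)),
                         alpha = 0.25) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~dim, ncol = 1, scales = "free_y") +
    ggplot2::labs(x = "time bin", y = "filtered latent state")
  if (!is.null(truth)) {
    zt <- truth_matrix(truth)
    tl <- tibble::tibble(
      t = rep(seq_len(nrow(zt)), L),
      dim = rep(paste0("z", seq_len(L)), each = nrow(zt)),
      z = as.numeric(zt)
    )
    p <- p + ggplot2::geom_line(data = tl,
                                ggplot2::aes(x = .data$t, y = .data$z),
                                colour = "red", linewidth = 0.3)
  }
  p
}

#' Phase-portrait helper
#'
#' Scatter of a two-dimensional latent trajectory (true, filtered or
#' generated), coloured by time.
#'
#' @param zs `T x 2` matrix or tibble of states.
#' @return A ggplot object.
#' @export
plot_phase_portrait <- function(zs) {
  zs <- truth_matrix(zs)
  stopifnot(ncol(zs) == 2)
  df <- tibble::tibble(z1 = zs[, 1], z2 = zs[, 2], t = seq_len(nrow(zs)))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$z1, y = .data$z2,
                                   colour = .data$t)) +
    ggplot2::geom_path(linewidth = 0.3) +
    ggplot2::labs(x = "z1", y = "z2", colour = "time")
}
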