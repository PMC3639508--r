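#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a bi-exponential fit
#'
#' @param x A `vk_biexp_fit`.
#' @param ... Unused.
#' @return Tibble with one row per parameter (`term`, `estimate`).
#' @export
tidy.vk_biexp_fit <- function(x, ...) {
  tibble::tibble(term = c("y0", "A1", "tau1_s", "A2", "tau2_s"),
                 estimate = c(x$y0, x$A1, x$tau1_s, x$A2, x$tau2_s))
}

#' Glance at a bi-exponential fit
#'
#' @param x A `vk_biexp_fit`.
#' @param ... Unused.
#' @return One-row tibble: `residual_ss`, `n_bins`, `n_events`, `n_docked`,
#'   `fusion_probability`, `degenerate`.
#' @export
glance.vk_biexp_fit <- function(x, ...) {
  tibble::tibble(residual_ss = x$residual_ss,
                 n_bins = nrow(x$data),
                 n_events = x$n_events,
                 n_docked = x$n_docked,
                 fusion_probability = if (!is.na(x$n_docked) && x$n_docked > 0) {
                   x$n_events / x$n_docked
                 } else NA_real_,
                 degenerate = x$degenerate)
}

#' Tidy a fusion-event histogram
#'
#' @param x A `vk_event_histogram`.
#' @param ... Unused.
#' @return The bin tibble.
#' @export
tidy.vk_event_histogram <- function(x, ...) x$bins

#' @export
glance.vk_event_histogram <- function(x, ...) {
  tibble::tibble(n_events = x$n_events, n_docked = x$n_docked,
                 n_dropped = x$n_dropped, n_bins = nrow(x$bins))
}
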