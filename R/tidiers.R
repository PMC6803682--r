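#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy an optimisation result
#'
#' @param x A [dvm_optimize()] result.
#' @param ... Unused.
#' @return A tibble with one row per stage: depths, phase times, amplitude
#'   and whether the stage migrates (amplitude above the 0.5 m "no DVM"
#'   reporting threshold).
#' @export
tidy.dvm_optimum <- function(x, ...) {
  tb <- as_tibble(x$strategy)
  tb$migrating <- tb$amplitude > 0.5
  tb
}

#' One-row summary of an optimisation result
#'
#' @param x A [dvm_optimize()] result.
#' @param ... Unused.
#' @return A tibble with the optimal fitness, life-history summary and the
#'   stationarity diagnostic (largest central-difference fitness gradient
#'   over parameters not pinned to a bound).
#' @export
glance.dvm_optimum <- function(x, ...) {
  tibble::tibble(
    J = x$J,
    b = x$rates$b,
    tau_1 = x$rates$tau_1,
    tau_2 = x$rates$tau_2,
    n_starts = nrow(x$starts),
    max_free_gradient = x$diagnostics$max_free_gradient,
    seed = x$seed
  )
}

#' Tidy a parameter scan
#'
#' @param x A [dvm_scan()] result.
#' @param ... Unused.
#' @return The scan tibble with an explicit `parameter` column.
#' @export
tidy.dvm_scan <- function(x, ...) {
  out <- tibble::as_tibble(x)
  out$parameter <- attr(x, "parameter")
  dplyr::relocate(out, "parameter")
}

#' Tidy a selection simulation
#'
#' @param x A [simulate_selection()] result.
#' @param ... Unused.
#' @return The density time-series tibble (`time`, `strategy`,
#'   `log_density`, `density`).
#' @export
tidy.dvm_selection <- function(x, ...) x$series

#' One-row-per-strategy summary of a selection simulation
#'
#' @param x A [simulate_selection()] result.
#' @param ... Unused.
#' @return A tibble with each strategy's final log density and realised
#'   late-window growth rate.
#' @export
glance.dvm_selection <- function(x, ...) {
  K <- max(x$series$strategy)
  tibble::tibble(
    strategy = seq_len(K),
    final_log_density = vapply(seq_len(K), function(k) {
      s <- x$series[x$series$strategy == k, ]
      s$log_density[nrow(s)]
    }, 0),
    growth_rate = vapply(seq_len(K), function(k)
      tryCatch(growth_rate(x, k), error = function(e) NA_real_), 0)
  )
}
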