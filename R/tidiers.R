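#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a theory parameter set
#'
#' @param x a [theory_params()] object.
#' @param ... unused.
#' @return A tibble with columns `exponent`, `value`.
#' @export
tidy.theory_params <- function(x, ...) {
  tibble::tibble(exponent = names(unclass(x)),
                 value = unlist(unclass(x), use.names = FALSE))
}

#' Summarize a theory parameter set
#'
#' @param x a [theory_params()] object.
#' @param ... unused.
#' @return A one-row tibble: number of defined exponents, whether the
#'   parameter set is complete, and whether all consistency inequalities
#'   hold (`NA` when incomplete).
#' @export
glance.theory_params <- function(x, ...) {
  vals <- unlist(unclass(x))
  complete <- !anyNA(vals)
  ok <- tryCatch(all(check_inequalities(x)$satisfied),
                 error = function(e) NA)
  tibble::tibble(n_defined = sum(!is.na(vals)), complete = complete,
                 inequalities_hold = ok)
}

#' Tidy a translocation event
#'
#' @param x a `translocation_event` from [run_translocation()].
#' @param ... unused.
#' @return The n(t) series tibble with the run metadata attached.
#' @export
tidy.translocation_event <- function(x, ...) {
  dplyr::mutate(x$n_series, seed = x$seed, Z = x$Z, E = x$E, N = x$N)
}

#' Summarize a translocation event
#'
#' @inheritParams tidy.translocation_event
#' @return A one-row tibble: `seed`, `Z`, `N`, `E`, `tau`, `status`.
#' @export
glance.translocation_event <- function(x, ...) {
  tibble::tibble(seed = x$seed, Z = x$Z, N = x$N, E = x$E, tau = x$tau,
                 status = x$status)
}
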