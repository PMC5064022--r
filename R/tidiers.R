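#' Tidy a fitted curve
#'
#' @param x An `iks_fit`.
#' @param ... Unused.
#' @return A tibble with columns `term`, `estimate`, `std.error`.
#' @export
tidy.iks_fit <- function(x, ...) {
  tibble::tibble(term = names(x$estimate),
                 estimate = unname(x$estimate),
                 std.error = unname(x$std_error[names(x$estimate)]))
}

#' One-row fit summary
#'
#' @param x An `iks_fit`.
#' @param ... Unused.
#' @return A tibble with columns `family`, `tag`, `rss`, `converged`,
#'   `nobs`.
#' @export
glance.iks_fit <- function(x, ...) {
  tibble::tibble(family = x$family,
                 tag = x$tag %||% NA_character_,
                 rss = x$rss,
                 converged = x$converged,
                 nobs = x$n)
}
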