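#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a quantitative map into a long voxel table
#'
#' @param x A [quantitative_map()].
#' @param ... Unused.
#' @return A tibble with `x`, `y`, `z`, `value`, `valid`, `reason`.
#' @export
tidy.quantitative_map <- function(x, ...) {
  idx <- arrayInd(seq_along(x$values), dim(x$values))
  vals <- as.numeric(x$values)
  valid <- as.logical(x$mask)
  reason <- as.character(x$reason)
  tibble::tibble(x = idx[, 1], y = idx[, 2], z = idx[, 3],
                 value = vals, valid = valid, reason = reason)
}

#' @export
glance.quantitative_map <- function(x, ...) {
  v <- x$values[x$mask]
  tibble::tibble(parameter = x$parameter, unit = x$unit,
                 n_valid = sum(x$mask), n_total = length(x$mask),
                 mean = mean(v), median = median(v), sd = sd(v))
}

#' @export
tidy.tensor_fit <- function(x, ...) {
  tibble::tibble(term = c("lambda1", "lambda2", "lambda3"),
                 estimate = x$lambda)
}

#' @export
glance.tensor_fit <- function(x, ...) {
  tibble::tibble(md = x$md, fa = x$fa, s0 = x$s0, resid = x$resid,
                 clamped = x$clamped)
}

#' @export
tidy.t2_fit <- function(x, ...) {
  tibble::tibble(term = c("t2w_ms", "a_w", "a_f"),
                 estimate = c(x$t2w_ms, x$a_w, x$a_f))
}

#' @export
glance.t2_fit <- function(x, ...) {
  tibble::tibble(t2w_ms = x$t2w_ms, resid = x$resid,
                 converged = x$converged, exclusion = x$exclusion)
}

#' @export
glance.fat_water_result <- function(x, ...) {
  v <- x$ff$values[x$ff$mask]
  tibble::tibble(n_fitted = sum(x$ff$mask), ff_median = median(v),
                 psi_median = median(x$psi[x$ff$mask]),
                 t2star_median = median(x$t2star[x$ff$mask]))
}
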