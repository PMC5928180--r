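#' Tidy a fitted factor model
#'
#' One row per (channel, endmember) pair of the endmember matrix U, or per
#' (pixel, endmember) pair of the abundances V.
#'
#' @param x a `factor_model`.
#' @param matrix `"endmembers"` (U, default) or `"abundances"` (V, with the
#'   pixel's grid coordinates attached).
#' @param ... unused.
#' @return A tibble.
#' @method tidy factor_model
#' @export
tidy.factor_model <- function(x, matrix = c("endmembers", "abundances"), ...) {
  matrix <- match.arg(matrix)
  k <- ncol(x$U)
  em <- paste0("EM", seq_len(k))
  if (matrix == "endmembers") {
    tibble::tibble(
      channel = rep(x$channel_axis %||% seq_len(nrow(x$U)), times = k),
      component = rep(em, each = nrow(x$U)),
      value = as.vector(x$U)
    )
  } else {
    idx <- raster_index(x$grid_shape)
    tibble::tibble(
      pixel = rep(seq_len(ncol(x$V)), times = k),
      y = rep(idx[, "y"], times = k),
      x = rep(idx[, "x"], times = k),
      component = rep(em, each = ncol(x$V)),
      abundance = as.vector(t(x$V))
    )
  }
}

#' One-row model summary
#' @param x a `factor_model`. @param ... unused.
#' @return Tibble with k, method, final objective, iterations, convergence.
#' @method glance factor_model
#' @export
glance.factor_model <- function(x, ...) {
  tibble::tibble(
    method = x$method,
    k = ncol(x$U),
    objective = if (length(x$objective_trace))
      x$objective_trace[length(x$objective_trace)] else NA_real_,
    iterations = x$iterations,
    converged = x$converged,
    n_warnings = length(x$warnings)
  )
}

#' Tidy a rank scan
#' @param x a `rank_scan`. @param ... unused.
#' @return The underlying tibble (one row per k) with the chosen-k attribute
#'   pivoted into columns `chosen_elbow`, `chosen_dispersion`,
#'   `chosen_saturation`.
#' @method tidy rank_scan
#' @export
tidy.rank_scan <- function(x, ...) {
  ch <- attr(x, "chosen")
  tibble::as_tibble(x) |>
    dplyr::mutate(chosen_elbow = ch[["elbow"]],
                  chosen_dispersion = ch[["dispersion"]],
                  chosen_saturation = ch[["saturation"]])
}
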