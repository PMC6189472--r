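#' FRAP trace normalization
#'
#' `double_normalize()` implements double normalization: the
#' background-corrected bleach-ROI trace is divided by the
#' background-corrected reference (whole-cell) trace, cancelling acquisition
#' photobleaching, and scaled so the prebleach level is 1:
#' \deqn{I_{dn}(t) = \frac{B(t)-bg}{R(t)-bg}\cdot
#'       \frac{\langle R-bg\rangle_{pre}}{\langle B-bg\rangle_{pre}}}
#' `single_normalize()` omits the reference:
#' \eqn{I_{sn}(t) = (B(t)-bg) / \langle B-bg\rangle_{pre}}.
#'
#' Both are then rescaled to *full scale* — the first postbleach sample maps
#' to 0 and the prebleach plateau to 1,
#' \eqn{F(t) = (I(t) - I(t_0)) / (1 - I(t_0))} — so that the fitted plateau
#' is literally the mobile fraction. Prebleach samples are dropped from the
#' output curve; their level and the first-postbleach level are retained as
#' attributes, and the prebleach-unit curve is kept as a column.
#'
#' @param data A data frame with columns `t` (seconds, strictly increasing),
#'   `bleach` and (for double normalization) `reference`, e.g. the output of
#'   [simulate_frap_curve()] or a measured trace table.
#' @param n_pre Number of prebleach samples at the head of the trace
#'   (defaults to the `"n_pre"` attribute when present).
#' @param background Background level: a scalar or a per-sample vector
#'   (defaults to the `background` column when present, else 0).
#' @return A `frap_curve` tibble with columns `t` (re-zeroed: 0 at the first
#'   postbleach sample), `intensity` (full-scale) and `intensity_prebleach`
#'   (prebleach-unit scale); attributes `normalization`, `scale`,
#'   `prebleach_level`, `first_postbleach_level`.
#' @export
double_normalize <- function(data, n_pre = NULL, background = NULL) {
  normalize_frap(data, n_pre, background, use_reference = TRUE)
}

#' @rdname double_normalize
#' @export
single_normalize <- function(data, n_pre = NULL, background = NULL) {
  normalize_frap(data, n_pre, background, use_reference = FALSE)
}

normalize_frap <- function(data, n_pre, background, use_reference) {
  data <- as_tibble(data)
  if (!all(c("t", "bleach") %in% names(data))) {
    abort("`data` needs columns `t` and `bleach`.")
  }
  if (use_reference && !"reference" %in% names(data)) {
    abort("Double normalization needs a `reference` column.")
  }
  if (any(diff(data$t) <= 0)) abort("`t` must be strictly increasing.")
  n_pre <- n_pre %||% attr(data, "n_pre")
  if (is.null(n_pre) || n_pre < 1) abort("`n_pre` must be >= 1.")
  if (nrow(data) <= n_pre) abort("Trace has no postbleach samples.")
  bg <- background %||% data[["background"]] %||% 0
  if (length(bg) == 1L) bg <- rep(bg, nrow(data))

  B <- data$bleach - bg
  pre <- seq_len(n_pre)
  if (use_reference) {
    R <- data$reference - bg
    if (any(R <= 0)) abort("Background-corrected reference trace is <= 0 somewhere.")
    i_dn <- (B / R) * (mean(R[pre]) / mean(B[pre]))
  } else {
    i_dn <- B / mean(B[pre])
  }
  t0 <- n_pre + 1L
  i0 <- i_dn[t0]
  if (i0 >= 1) {
    abort("No bleach detected: first postbleach intensity is not below the prebleach level.",
          class = "isquant_no_bleach")
  }
  post <- seq(t0, nrow(data))
  out <- tibble(
    t = data$t[post] - data$t[t0],
    intensity = (i_dn[post] - i0) / (1 - i0),
    intensity_prebleach = i_dn[post]
  )
  structure(out,
            class = c("frap_curve", class(out)),
            normalization = if (use_reference) "double" else "single",
            scale = "full_scale",
            prebleach_level = mean(B[pre]),
            first_postbleach_level = i0)
}

#' @export
print.frap_curve <- function(x, ...) {
  cat(sprintf("<frap_curve> %d postbleach samples, %s normalization\n",
              nrow(x), attr(x, "normalization")))
  cat(sprintf("  prebleach level %.4g, first postbleach level %.4g (prebleach units)\n",
              attr(x, "prebleach_level"), attr(x, "first_postbleach_level")))
  NextMethod()
}
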