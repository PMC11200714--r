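#' JFPM stimulus layouts
#'
#' Build the target table of a joint frequency-phase modulated (JFPM) SSVEP
#' speller. Each target at grid position (i, j) flickers at
#' `f = a_i * i + a_j * j + a_0` Hz with phase `(b_i * i + b_j * j + b_0) * pi`
#' radians. Two built-in presets cover the common 40-class (4 x 10) and
#' 12-class (4 x 3) spellers; custom coefficient sets are accepted.
#'
#' Targets are enumerated row-major (row index `i` outermost), which for the
#' 12-class preset matches the trial order of the public dataset.
#'
#' @param preset `"dataset1_40class"`, `"dataset2_12class"`, or `"custom"`.
#' @param n_rows,n_cols grid dimensions (custom layouts only).
#' @param freq_coeffs numeric `c(a_i, a_j, a_0)` in Hz (custom layouts only).
#' @param phase_coeffs numeric `c(b_i, b_j, b_0)` in multiples of pi
#'   (custom layouts only).
#'
#' @return An object of class `ssvep_layout`: a list with `n_rows`, `n_cols`,
#'   `freq_coeffs`, `phase_coeffs` and `targets`, a data.frame with columns
#'   `target` (1-based index), `row`, `col`, `frequency_hz`, `phase_rad`
#'   (reduced to `[0, 2*pi)`).
#'
#' @examples
#' lay <- build_layout("dataset2_12class")
#' lay$targets[1, ]   # 9.25 Hz, phase 0
#' @export
build_layout <- function(preset = c("dataset1_40class", "dataset2_12class", "custom"),
                         n_rows = NULL, n_cols = NULL,
                         freq_coeffs = NULL, phase_coeffs = NULL) {
  preset <- match.arg(preset)
  if (preset == "dataset1_40class") {
    n_rows <- 4L; n_cols <- 10L
    freq_coeffs <- c(2, 0.2, 5.8)
    phase_coeffs <- c(5, 0.5, -5.5)
  } else if (preset == "dataset2_12class") {
    n_rows <- 4L; n_cols <- 3L
    freq_coeffs <- c(0.5, 2, 6.75)
    phase_coeffs <- c(0.5, 0, -0.5)
  } else {
    if (is.null(n_rows) || is.null(n_cols) ||
        is.null(freq_coeffs) || is.null(phase_coeffs))
      stop("custom layouts need n_rows, n_cols, freq_coeffs and phase_coeffs")
  }
  n_rows <- as.integer(n_rows); n_cols <- as.integer(n_cols)
  stopifnot(n_rows >= 1L, n_cols >= 1L,
            length(freq_coeffs) == 3L, length(phase_coeffs) == 3L,
            all(is.finite(freq_coeffs)), all(is.finite(phase_coeffs)))

  grid <- expand.grid(col = seq_len(n_cols), row = seq_len(n_rows))
  i <- grid$row; j <- grid$col
  freq <- freq_coeffs[1] * i + freq_coeffs[2] * j + freq_coeffs[3]
  phase <- (phase_coeffs[1] * i + phase_coeffs[2] * j + phase_coeffs[3]) * pi
  phase <- phase %% (2 * pi)

  if (any(freq <= 0))
    stop("all target frequencies must be strictly positive")
  if (anyDuplicated(round(freq, 10)))
    stop("duplicate frequencies in layout; targets must be frequency-separable")

  targets <- data.frame(
    target = seq_along(freq),
    row = i, col = j,
    frequency_hz = freq,
    phase_rad = phase
  )
  structure(
    list(n_rows = n_rows, n_cols = n_cols,
         freq_coeffs = freq_coeffs, phase_coeffs = phase_coeffs,
         preset = preset, targets = targets),
    class = "ssvep_layout"
  )
}

#' @export
print.ssvep_layout <- function(x, ...) {
  cat(sprintf("JFPM stimulus layout (%s): %d x %d grid, %d targets\n",
              x$preset, x$n_rows, x$n_cols, nrow(x$targets)))
  cat(sprintf("  frequencies: %.2f-%.2f Hz\n",
              min(x$targets$frequency_hz), max(x$targets$frequency_hz)))
  invisible(x)
}

n_targets <- function(layout) nrow(layout$targets)
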