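# Internal argument checks shared across the package.

stop_if_not <- function(ok, msg, call. = FALSE) {
  if (!isTRUE(ok)) stop(msg, call. = call.)
  invisible(TRUE)
}

check_scalar <- function(x, name, positive = FALSE, nonneg = FALSE,
                         integer = FALSE) {
  stop_if_not(is.numeric(x) && length(x) == 1L && is.finite(x),
              sprintf("'%s' must be a finite numeric scalar", name))
  if (positive) stop_if_not(x > 0, sprintf("'%s' must be > 0", name))
  if (nonneg) stop_if_not(x >= 0, sprintf("'%s' must be >= 0", name))
  if (integer) stop_if_not(x == round(x), sprintf("'%s' must be integral", name))
  invisible(x)
}

# Row-wise Euclidean norm of an n x 3 matrix.
row_norms <- function(m) sqrt(rowSums(m * m))

#' Pressure unit conversion
#'
#' Clinical pressures are quoted in mmHg while all internal computations use
#' pascal. The conversion constant is fixed at 133.322 Pa/mmHg.
#'
#' @param x numeric vector of pressures.
#' @return converted numeric vector.
#' @export
mmhg_to_pa <- function(x) x * 133.322

#' @rdname mmhg_to_pa
#' @export
pa_to_mmhg <- function(x) x / 133.322
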