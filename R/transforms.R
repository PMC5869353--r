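#' Specify a variance-stabilizing transformation for counts
#'
#' The two classical transformations applied to counts before ordinary linear
#' modelling: the square root, `sqrt(y + c)`, and the logarithm,
#' `log(y + c)`. Textbook presets for the square-root offset are 0, 0.5 and
#' 3/8; the conventional log offset for data containing zeros is 1. The
#' offset is carried through to back-transformation so the inverse always
#' uses the same constant.
#'
#' @param name `"sqrt"` or `"log"`.
#' @param offset Non-negative constant `c` added before transforming.
#'   Defaults: 0 for `sqrt`, 1 for `log`.
#' @param log_base Base of the logarithm, `exp(1)` (default) or `10`.
#'   Ignored for `sqrt`.
#' @return A `transform_spec` object.
#' @examples
#' transform_spec("sqrt")
#' transform_spec("sqrt", offset = 0.375)
#' transform_spec("log") # log(y + 1), natural base
#' @export
transform_spec <- function(name = c("sqrt", "log"),
                           offset = NULL,
                           log_base = exp(1)) {
  name <- match.arg(name)
  if (is.null(offset)) offset <- if (name == "sqrt") 0 else 1
  if (!is.numeric(offset) || length(offset) != 1 || !is.finite(offset) ||
      offset < 0) {
    abort("`offset` must be a single non-negative number.")
  }
  if (!isTRUE(all.equal(log_base, exp(1))) && !isTRUE(all.equal(log_base, 10))) {
    abort("`log_base` must be exp(1) or 10.")
  }
  structure(
    list(name = name, offset = offset, log_base = log_base),
    class = "transform_spec"
  )
}

#' @export
print.transform_spec <- function(x, ...) {
  base_lab <- if (isTRUE(all.equal(x$log_base, 10))) "10" else "e"
  cat(sprintf(
    "<transform_spec> %s(y + %g)%s\n", x$name, x$offset,
    if (x$name == "log") paste0(", base ", base_lab) else ""
  ))
  invisible(x)
}

#' Apply a transformation to a count vector
#'
#' @param y Non-negative counts.
#' @param spec A [transform_spec()].
#' @return Numeric vector `sqrt(y + c)` or `log(y + c)` in the configured
#'   base. Strictly monotone in `y`; errors if a log of zero would be taken
#'   (log with `offset = 0` requires all `y > 0`).
#' @examples
#' apply_transform(c(0, 1, 4, 9), transform_spec("sqrt"))
#' apply_transform(c(0, 9), transform_spec("log")) # log(y + 1)
#' @export
apply_transform <- function(y, spec) {
  stopifnot(inherits(spec, "transform_spec"))
  if (any(!is.finite(y) | y < 0)) abort("`y` must be finite and non-negative.")
  shifted <- y + spec$offset
  if (spec$name == "sqrt") {
    return(sqrt(shifted))
  }
  zero <- which(shifted == 0)
  if (length(zero) > 0) {
    abort(sprintf(
      "log transform with offset 0 requires all y > 0; y is 0 at index %d.",
      zero[1]
    ))
  }
  log(shifted, base = spec$log_base)
}

#' Invert a transformation
#'
#' Exact inverse of [apply_transform()]: squares (or exponentiates) and
#' subtracts the same offset used going forward. This is the arithmetic
#' inverse of the transform, distinct from the coefficient back-transformation
#' conventions in [backtransform_sqrt()] and [backtransform_log()].
#'
#' @param z Transformed values.
#' @param spec The [transform_spec()] used in the forward direction.
#' @return Values on the original count scale.
#' @export
invert_transform <- function(z, spec) {
  stopifnot(inherits(spec, "transform_spec"))
  if (spec$name == "sqrt") z^2 - spec$offset else spec$log_base^z - spec$offset
}
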