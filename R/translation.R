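#' Construct a translation vector
#'
#' A translation is a length-2 numeric vector `c(dx, dy)` of real-valued
#' pixel shifts: `dx` along columns (x, rightward), `dy` along rows
#' (y, downward). Applied to a target image it moves the content by
#' `(dx, dy)` so that the target aligns with its reference.
#'
#' @param dx,dy real pixel shifts; must be finite.
#' @return named numeric vector `c(dx = dx, dy = dy)`.
#' @examples
#' translation(3, -1.5)
#' @export
translation <- function(dx, dy) {
    if (!is.numeric(dx) || !is.numeric(dy) || length(dx) != 1L ||
        length(dy) != 1L || !is.finite(dx) || !is.finite(dy))
        stop("dx and dy must be finite scalars")
    c(dx = as.numeric(dx), dy = as.numeric(dy))
}

# Coerce any 2-vector (or list) to a validated translation.
as_translation <- function(t) {
    t <- unlist(t, use.names = FALSE)
    if (length(t) != 2L || !is.numeric(t) || any(!is.finite(t)))
        stop("a translation must be two finite numbers c(dx, dy)")
    c(dx = t[1], dy = t[2])
}

#' Euclidean magnitude of a translation
#' @param t translation `c(dx, dy)`.
#' @return non-negative scalar, `sqrt(dx^2 + dy^2)`.
#' @export
translation_magnitude <- function(t) {
    t <- as_translation(t)
    sqrt(sum(t^2))
}
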