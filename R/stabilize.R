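#' Variance-stabilizing transform specification
#'
#' Every estimator in this package assumes the trial-to-trial variance of
#' the responses is constant across stimuli.  Raw spike counts violate this
#' (Poisson-like variance grows with the mean); a variance-stabilizing
#' transform restores it.  For a mean-variance relationship
#' \eqn{\sigma^2(\mu) = a \mu^b} the stabilizing transform is
#' \deqn{f(x) = \left[a\left(1 - \tfrac{b}{2}\right)\right]^{-1} x^{1-b/2},}
#' which drives the post-transform variance toward 1.  The plain square
#' root (`kind = "sqrt"`) handles the Poisson case (a = 1, b = 1) up to a
#' constant factor and leaves variance near 1/4.
#'
#' @param kind One of `"sqrt"`, `"power"`, `"identity"`.
#' @param a Positive mean-variance slope (power transform only).
#' @param b Mean-variance exponent, must satisfy `b < 2` so the transform
#'   exponent 1 - b/2 stays positive.
#' @return Object of class `"stabilizer_spec"`.
#' @examples
#' stabilizer_spec("power", a = 4, b = 1)
#' @export
stabilizer_spec <- function(kind = c("sqrt", "power", "identity"),
                            a = 1, b = 1) {
  kind <- match.arg(kind)
  if (kind == "power") {
    if (!is.finite(a) || a <= 0) stop("a must be positive", call. = FALSE)
    if (!is.finite(b) || b >= 2)
      stop("b must be < 2 so the transform exponent 1 - b/2 is positive",
           call. = FALSE)
  }
  structure(list(kind = kind, a = a, b = b), class = "stabilizer_spec")
}

#' Apply a variance-stabilizing transform to raw responses
#'
#' Element-wise transform of a raw (untransformed) response matrix.  Raw
#' responses must be nonnegative for the square-root and power transforms;
#' zeros are allowed (sqrt(0) = 0), since count data legitimately contains
#' them.
#'
#' @param raw Numeric matrix of raw responses, stimuli in rows.
#' @param spec A [stabilizer_spec()]; default is the square root.
#' @return A [response_matrix()] of transformed values.
#' @examples
#' counts <- matrix(rpois(20, 10), nrow = 5)
#' apply_stabilizer(counts)
#' @export
apply_stabilizer <- function(raw, spec = stabilizer_spec("sqrt")) {
  raw <- as.matrix(raw)
  stopifnot(inherits(spec, "stabilizer_spec"))
  if (spec$kind %in% c("sqrt", "power") && any(raw < 0, na.rm = TRUE)) {
    bad <- which(raw < 0, arr.ind = TRUE)[1L, ]
    stop("negative raw response at stimulus ", bad[1L], ", repeat ", bad[2L],
         " cannot be ", spec$kind, "-transformed", call. = FALSE)
  }
  out <- switch(spec$kind,
    identity = raw,
    sqrt     = sqrt(raw),
    power    = raw^(1 - spec$b / 2) / (spec$a * (1 - spec$b / 2))
  )
  response_matrix(out)
}
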