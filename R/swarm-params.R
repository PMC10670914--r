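#' Gorilla Troops Optimizer parameters
#'
#' Parameter record for both the plain optimizer and its sine-cosine
#' modification. `p` controls the probability of the migrate-to-unknown-place
#' exploration branch; `beta` scales the competition step size; `const` is the
#' starting radius of the linearly shrinking sine-cosine amplitude (unused by
#' the plain optimizer).
#'
#' @param p Real in \[0, 1\]; default 0.3.
#' @param beta Real in \[0, 1\]; default 0.7.
#' @param max_iter Positive integer; default 11.
#' @param const Positive real; default 3.
#' @param g_mode `"pow2"` (`g = 2^L`, default) or `"linear"` (`g = 2 L`) for
#'   the silverback-follow exponent.
#' @param l_mode `"continuous"` (uniform on \[-1, 1\], default) or
#'   `"integer"` (uniform on \{-1, 0, 1\}).
#' @return An object of class `mgto_params`.
#' @export
mgto_params <- function(p = 0.3, beta = 0.7, max_iter = 11L, const = 3,
                        g_mode = c("pow2", "linear"),
                        l_mode = c("continuous", "integer")) {
  g_mode <- match.arg(g_mode)
  l_mode <- match.arg(l_mode)
  stopifnot(p >= 0, p <= 1, beta >= 0, beta <= 1)
  max_iter <- as.integer(max_iter)
  if (is.na(max_iter) || max_iter < 0L) stop("mgto_params: max_iter must be a non-negative integer")
  if (!is.finite(const) || const <= 0) stop("mgto_params: const must be > 0")
  structure(list(p = p, beta = beta, max_iter = max_iter, const = const,
                 g_mode = g_mode, l_mode = l_mode),
            class = "mgto_params")
}

#' Particle Swarm Optimization parameters
#'
#' @param w Inertia weight.
#' @param c1,c2 Cognitive and social acceleration coefficients.
#' @param max_iter Positive integer.
#' @return An object of class `pso_params`.
#' @export
pso_params <- function(w = 0.6, c1 = 0.7, c2 = 0.9, max_iter = 10L) {
  max_iter <- as.integer(max_iter)
  if (is.na(max_iter) || max_iter < 0L) stop("pso_params: max_iter must be a non-negative integer")
  structure(list(w = w, c1 = c1, c2 = c2, max_iter = max_iter),
            class = "pso_params")
}

#' Elephant Herding Optimization parameters
#'
#' @param alpha Scale of the move toward the matriarch position.
#' @param beta_e Scale applied to the clan centre to obtain the matriarch
#'   position.
#' @param max_iter Positive integer.
#' @return An object of class `eho_params`.
#' @export
eho_params <- function(alpha = 0.9, beta_e = 0.8, max_iter = 12L) {
  max_iter <- as.integer(max_iter)
  if (is.na(max_iter) || max_iter < 0L) stop("eho_params: max_iter must be a non-negative integer")
  structure(list(alpha = alpha, beta_e = beta_e, max_iter = max_iter),
            class = "eho_params")
}

#' Scalar position bounds
#'
#' @param lower,upper Finite reals with `lower <= upper`.
#' @return A list with elements `lower` and `upper`, class `scalar_bounds`.
#' @export
scalar_bounds <- function(lower, upper) {
  if (!is.finite(lower) || !is.finite(upper)) stop("scalar_bounds: bounds must be finite")
  if (lower > upper) stop("scalar_bounds: lower must not exceed upper")
  structure(list(lower = lower, upper = upper), class = "scalar_bounds")
}

default_params_for <- function(algorithm, max_iter = NULL) {
  p <- switch(algorithm,
    gto  = mgto_params(),
    mgto = mgto_params(),
    pso  = pso_params(),
    eho  = eho_params(),
    stop(sprintf("unknown algorithm '%s'", algorithm))
  )
  if (!is.null(max_iter)) p$max_iter <- as.integer(max_iter)
  p
}
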