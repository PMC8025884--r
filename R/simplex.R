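#' Nelder-Mead simplex minimization with per-parameter step sizes
#'
#' The downhill-simplex method with the initial simplex built from the
#' supplied per-parameter step sizes (one vertex per parameter, displaced
#' by its step), standard reflection/expansion/contraction coefficients
#' (1, 2, 0.5, 0.5), and termination on either a maximum number of descent
#' steps or a parameter-spread tolerance.
#'
#' @param par numeric start vector.
#' @param steps per-parameter initial step sizes (recycled).
#' @param fn objective function to minimize.
#' @param max_cycles maximum descent steps; `0` returns `par` unchanged.
#' @param tol convergence: maximum parameter spread of the simplex below
#'   which iteration stops.
#' @return list with `par`, `value`, `cycles` (steps used).
#' @export
simplex_minimize <- function(par, steps, fn, max_cycles = 100, tol = 1e-8) {
  n <- length(par)
  steps <- rep(steps, length.out = n)
  if (max_cycles <= 0) return(list(par = par, value = fn(par), cycles = 0))
  verts <- matrix(rep(par, n + 1), ncol = n, byrow = TRUE)
  for (i in seq_len(n)) verts[i + 1, i] <- verts[i + 1, i] + steps[i]
  vals <- apply(verts, 1, fn)
  if (any(!is.finite(vals))) stop("non-finite target at the start simplex")
  cycles <- 0
  while (cycles < max_cycles) {
    cycles <- cycles + 1
    ord <- order(vals)
    verts <- verts[ord, , drop = FALSE]; vals <- vals[ord]
    if (max(apply(verts, 2, function(v) diff(range(v)))) < tol) break
    centroid <- colMeans(verts[seq_len(n), , drop = FALSE])
    worst <- verts[n + 1, ]
    refl <- centroid + (centroid - worst)
    fr <- fn(refl)
    if (!is.finite(fr)) fr <- Inf
    if (fr < vals[1]) {
      expa <- centroid + 2 * (centroid - worst)
      fe <- fn(expa)
      if (is.finite(fe) && fe < fr) {
        verts[n + 1, ] <- expa; vals[n + 1] <- fe
      } else {
        verts[n + 1, ] <- refl; vals[n + 1] <- fr
      }
    } else if (fr < vals[n]) {
      verts[n + 1, ] <- refl; vals[n + 1] <- fr
    } else {
      contr <- centroid + 0.5 * (worst - centroid)
      fc <- fn(contr)
      if (is.finite(fc) && fc < vals[n + 1]) {
        verts[n + 1, ] <- contr; vals[n + 1] <- fc
      } else {
        # shrink towards the best vertex
        for (i in 2:(n + 1)) {
          verts[i, ] <- verts[1, ] + 0.5 * (verts[i, ] - verts[1, ])
          vals[i] <- fn(verts[i, ])
          if (!is.finite(vals[i])) vals[i] <- Inf
        }
      }
    }
  }
  best <- which.min(vals)
  list(par = verts[best, ], value = vals[best], cycles = cycles)
}
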