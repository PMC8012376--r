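# Oblique gradient-projection rotation (direct quartimin, i.e. oblimin with
# gamma = 0). Classic GPFoblq iteration: minimize the quartimin criterion
# over oblique rotation matrices T with unit-length columns, taking
# projected gradient steps with step halving.

quartimin_vgQ <- function(L) {
  k <- ncol(L)
  L2 <- L^2
  N <- matrix(1, k, k) - diag(k)
  list(f = sum(L2 * (L2 %*% N)) / 4,
       Gq = L * (L2 %*% N))
}

#' Oblimin (direct quartimin) rotation by gradient projection
#'
#' Rotates an unrotated loading matrix to an oblique simple structure,
#' returning pattern loadings and the factor correlation matrix.
#'
#' @param A unrotated items x k loading matrix.
#' @param maxit maximum gradient-projection iterations.
#' @param eps convergence tolerance on the projected gradient norm.
#' @return list with `loadings` (pattern), `phi`, `Tmat`, `convergence`.
#' @export
rotate_oblimin <- function(A, maxit = 1000, eps = 1e-6) {
  k <- ncol(A)
  if (k == 1L) {
    return(list(loadings = A, phi = matrix(1, 1, 1), Tmat = matrix(1, 1, 1),
                convergence = TRUE))
  }
  Tmat <- diag(k)
  Ti <- solve(Tmat)
  L <- A %*% t(Ti)
  vg <- quartimin_vgQ(L)
  f <- vg$f
  G <- -t(t(L) %*% vg$Gq %*% Ti)
  al <- 1
  converged <- FALSE
  for (iter in seq_len(maxit)) {
    Gp <- G - Tmat %*% diag(colSums(Tmat * G), k)
    s <- sqrt(sum(Gp^2))
    if (s < eps) { converged <- TRUE; break }
    al <- 2 * al
    for (i in seq_len(20)) {
      X <- Tmat - al * Gp
      Tt <- X %*% diag(1 / sqrt(colSums(X^2)), k)
      Ti <- solve(Tt)
      L <- A %*% t(Ti)
      vg <- quartimin_vgQ(L)
      if (vg$f < f - 0.5 * s^2 * al) break
      al <- al / 2
    }
    Tmat <- Tt
    f <- vg$f
    G <- -t(t(L) %*% vg$Gq %*% Ti)
  }
  phi <- t(Tmat) %*% Tmat
  dimnames(L) <- dimnames(A)
  list(loadings = L, phi = phi, Tmat = Tmat, convergence = converged)
}
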