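#' Iterative least-squares minimal residual solver (LSMR)
#'
#' Solves \code{min ||A x - b||_2} for sparse \code{A} by Golub-Kahan
#' bidiagonalization with a MINRES-type recurrence on the normal equations
#' (Fong & Saunders 2011). The iteration starts at zero and, for consistent
#' or rank-deficient systems, converges to the minimum-norm least-squares
#' solution. Deterministic: no randomness is involved.
#'
#' @param A matrix or \code{Matrix} sparse matrix (m x n).
#' @param b right-hand side (length m).
#' @param atol,btol relative tolerances on the normal-equation and residual
#'   stopping tests.
#' @param conlim stop when the condition-number estimate exceeds this.
#' @param maxiter iteration cap (default \code{10 * ncol(A)}).
#' @return list with \code{x}, \code{itn}, \code{istop} (1-3: converged;
#'   4-6: converged at machine precision; 7: iteration cap), \code{normr}
#'   (residual norm estimate), \code{normar} (normal-equation residual).
#' @references Fong, D. C.-L., & Saunders, M. (2011). LSMR: an iterative
#'   algorithm for sparse least-squares problems. SIAM J. Sci. Comput. 33(5).
#' @export
lsmr <- function(A, b, atol = 1e-10, btol = 1e-10, conlim = 1e12,
                 maxiter = NULL) {
  m <- nrow(A); n <- ncol(A)
  b <- as.numeric(b)
  stopifnot(length(b) == m)
  if (is.null(maxiter)) maxiter <- 10L * n
  ctol <- if (conlim > 0) 1 / conlim else 0

  nrm <- function(v) sqrt(sum(v * v))
  matvec <- function(v) as.numeric(A %*% v)
  rmatvec <- function(u) as.numeric(Matrix::crossprod(A, u))

  u <- b
  normb <- nrm(b)
  x <- numeric(n)
  beta <- normb
  if (beta > 0) {
    u <- u / beta
    v <- rmatvec(u)
    alpha <- nrm(v)
  } else {
    v <- numeric(n)
    alpha <- 0
  }
  if (alpha > 0) v <- v / alpha

  zetabar <- alpha * beta
  alphabar <- alpha
  rho <- 1; rhobar <- 1; cbar <- 1; sbar <- 0
  h <- v; hbar <- numeric(n)

  betadd <- beta; betad <- 0; rhodold <- 1; tautildeold <- 0
  thetatilde <- 0; zeta <- 0; d <- 0

  normA2 <- alpha^2; maxrbar <- 0; minrbar <- 1e100
  normr <- beta
  normar <- alpha * beta
  itn <- 0L; istop <- 0L

  if (normar == 0)  # b = 0 or A'b = 0: x = 0 is the minimum-norm solution
    return(list(x = x, itn = 0L, istop = 0L, normr = normb, normar = 0))

  while (itn < maxiter) {
    itn <- itn + 1L

    u <- matvec(v) - alpha * u
    beta <- nrm(u)
    if (beta > 0) {
      u <- u / beta
      v <- rmatvec(u) - beta * v
      alpha <- nrm(v)
      if (alpha > 0) v <- v / alpha
    }

    # plane rotations (no damping)
    alphahat <- alphabar
    so <- sym_ortho(alphahat, beta)
    c <- so[1]; s <- so[2]; rhoold <- rho; rho <- so[3]
    thetanew <- s * alpha
    alphabar <- c * alpha

    rhobarold <- rhobar
    zetaold <- zeta
    thetabar <- sbar * rho
    rhotemp <- cbar * rho
    so <- sym_ortho(cbar * rho, thetanew)
    cbar <- so[1]; sbar <- so[2]; rhobar <- so[3]
    zeta <- cbar * zetabar
    zetabar <- -sbar * zetabar

    hbar <- h - (thetabar * rho / (rhoold * rhobarold)) * hbar
    x <- x + (zeta / (rho * rhobar)) * hbar
    h <- v - (thetanew / rho) * h

    # residual-norm estimate
    betahat <- c * betadd
    betadd <- -s * betadd
    thetatildeold <- thetatilde
    so <- sym_ortho(rhodold, thetabar)
    ctildeold <- so[1]; stildeold <- so[2]; rhotildeold <- so[3]
    thetatilde <- stildeold * rhobar
    rhodold <- ctildeold * rhobar
    betad <- -stildeold * betad + ctildeold * betahat
    tautildeold <- (zetaold - thetatildeold * tautildeold) / rhotildeold
    taud <- (zeta - thetatilde * tautildeold) / rhodold
    normr <- sqrt(d + (betad - taud)^2 + betadd^2)

    normA2 <- normA2 + beta^2
    normA <- sqrt(normA2)
    normA2 <- normA2 + alpha^2
    maxrbar <- max(maxrbar, rhobarold)
    if (itn > 1L) minrbar <- min(minrbar, rhobarold)
    condA <- max(maxrbar, rhotemp) / min(minrbar, rhotemp)
    normar <- abs(zetabar)
    normx <- nrm(x)

    test1 <- normr / normb
    test2 <- if (normA * normr != 0) normar / (normA * normr) else Inf
    test3 <- 1 / condA
    t1 <- test1 / (1 + normA * normx / normb)
    rtol <- btol + atol * normA * normx / normb

    if (itn >= maxiter) istop <- 7L
    if (1 + test3 <= 1) istop <- 6L
    if (1 + test2 <= 1) istop <- 5L
    if (1 + t1 <= 1) istop <- 4L
    if (test3 <= ctol) istop <- 3L
    if (test2 <= atol) istop <- 2L
    if (test1 <= rtol) istop <- 1L
    if (istop > 0L) break
  }
  if (istop == 0L) istop <- 7L
  list(x = x, itn = itn, istop = istop, normr = normr, normar = normar)
}

# Stable Givens rotation: returns c(cos, sin, r) with r = hypot(a, b).
sym_ortho <- function(a, b) {
  if (b == 0) {
    c(sign(a + (a == 0)), 0, abs(a))
  } else if (a == 0) {
    c(0, sign(b), abs(b))
  } else if (abs(b) > abs(a)) {
    tau <- a / b
    s <- sign(b) / sqrt(1 + tau^2)
    c(s * tau, s, b / s)
  } else {
    tau <- b / a
    cc <- sign(a) / sqrt(1 + tau^2)
    c(cc, cc * tau, a / cc)
  }
}
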