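# General-purpose embedded Cash-Karp integration (R implementation).
# The filament engine uses the same tableau in compiled code; this R version
# exposes the stepper for arbitrary ODE systems and serves as an
# independent reference in consistency tests.

.ckTableau <- list(
  c = c(0, 1/5, 3/10, 3/5, 1, 7/8),
  a = list(numeric(0),
           c(1/5),
           c(3/40, 9/40),
           c(3/10, -9/10, 6/5),
           c(-11/54, 5/2, -70/27, 35/27),
           c(1631/55296, 175/512, 575/13824, 44275/110592, 253/4096)),
  b5 = c(37/378, 0, 250/621, 125/594, 0, 512/1771),
  b4 = c(2825/27648, 0, 18575/48384, 13525/55296, 277/14336, 1/4))

#' One embedded Cash-Karp step
#'
#' Attempts a single step of the 4(5) Cash-Karp pair and proposes the next
#' step size from the embedded error estimate.
#'
#' @param f derivative function `f(t, y)` returning `dy/dt`
#' @param t current time
#' @param y current state (numeric vector)
#' @param dt step size to attempt
#' @param relTol,absTol error tolerances
#' @return list with `accepted` (logical), `t`, `y` (advanced state if
#'   accepted, otherwise unchanged), `errNorm` and `dtNext`
#' @export
ckStep <- function(f, t, y, dt, relTol = 1e-6, absTol = 1e-9) {
  tb <- .ckTableau
  k <- vector("list", 6)
  k[[1]] <- f(t, y)
  for (s in 2:6) {
    yi <- y
    for (j in seq_len(s - 1)) yi <- yi + dt * tb$a[[s]][j] * k[[j]]
    k[[s]] <- f(t + tb$c[s] * dt, yi)
  }
  y5 <- y; y4 <- y
  for (s in 1:6) {
    y5 <- y5 + dt * tb$b5[s] * k[[s]]
    y4 <- y4 + dt * tb$b4[s] * k[[s]]
  }
  sc <- absTol + relTol * abs(y)
  errNorm <- sqrt(mean(((y5 - y4) / sc)^2))
  if (!is.finite(errNorm)) {
    return(list(accepted = FALSE, t = t, y = y, errNorm = Inf,
                dtNext = dt / 10))
  }
  if (errNorm <= 1) {
    list(accepted = TRUE, t = t + dt, y = y5, errNorm = errNorm,
         dtNext = dt * min(5, max(0.2, 0.9 * errNorm^-0.2)))
  } else {
    list(accepted = FALSE, t = t, y = y, errNorm = errNorm,
         dtNext = dt * max(0.1, 0.9 * errNorm^-0.25))
  }
}

#' Adaptive Cash-Karp integration over an interval
#'
#' @param f derivative function `f(t, y)`
#' @param y0 initial state
#' @param t0,t1 integration interval
#' @param relTol,absTol error tolerances
#' @param dtInit initial step size
#' @param minStep step underflow limit; going below raises a stiffness error
#' @return list with final `y`, `t`, and step counts
#' @examples
#' # y' = -y from 1: exp(-1) at t = 1
#' odeCashKarp(function(t, y) -y, 1, 0, 1)$y
#' @export
odeCashKarp <- function(f, y0, t0, t1, relTol = 1e-6, absTol = 1e-9,
                        dtInit = (t1 - t0) / 100, minStep = (t1 - t0) * 1e-12) {
  t <- t0; y <- y0; dt <- dtInit
  nAccept <- 0L; nReject <- 0L
  while (t < t1) {
    dt <- min(dt, t1 - t)
    st <- ckStep(f, t, y, dt, relTol, absTol)
    if (st$accepted) {
      t <- st$t; y <- st$y; nAccept <- nAccept + 1L
    } else {
      nReject <- nReject + 1L
      if (st$dtNext < minStep)
        stop("stiffness error: step size underflow at t = ", signif(t, 6))
    }
    dt <- st$dtNext
  }
  list(y = y, t = t, nAccept = nAccept, nReject = nReject)
}
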