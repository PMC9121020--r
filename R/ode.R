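# Adaptive Dormand-Prince 5(4) initial-value solver.
#
# No ODE solver package is available in the declared dependency set, so the
# package carries its own. f(t, y) must return dy/dt as a numeric vector the
# same length as y. Output rows are the solution at each requested time
# (times[1] is the initial time). Error control is per-component:
# |err| <= atol + rtol * |y|.

rk45 <- function(f, y0, times, rtol = 1e-8, atol = 1e-10,
                 max_steps = 1e6, context = NULL) {
  # Dormand-Prince tableau
  a <- list(
    c(1 / 5),
    c(3 / 40, 9 / 40),
    c(44 / 45, -56 / 15, 32 / 9),
    c(19372 / 6561, -25360 / 2187, 64448 / 6561, -212 / 729),
    c(9017 / 3168, -355 / 33, 46732 / 5247, 49 / 176, -5103 / 18656),
    c(35 / 384, 0, 500 / 1113, 125 / 192, -2187 / 6784, 11 / 84)
  )
  b5 <- c(35 / 384, 0, 500 / 1113, 125 / 192, -2187 / 6784, 11 / 84, 0)
  b4 <- c(5179 / 57600, 0, 7571 / 16695, 393 / 640, -92097 / 339200,
          187 / 2100, 1 / 40)
  c_nodes <- c(1 / 5, 3 / 10, 4 / 5, 8 / 9, 1, 1)

  y0 <- as.numeric(y0)
  d <- length(y0)
  out <- matrix(NA_real_, nrow = length(times), ncol = d)
  out[1, ] <- y0

  t <- times[1]
  y <- y0
  k1 <- f(t, y)
  if (length(k1) != d || any(!is.finite(k1))) {
    abort("Derivative function returned a non-finite initial slope.",
          class = "growthmedia_integration_error",
          body = format_ode_context(context))
  }
  span <- diff(range(times))
  h <- if (span > 0) span / 100 else 1e-3
  idx <- 2
  steps <- 0

  while (idx <= length(times)) {
    target <- times[idx]
    while (t < target) {
      steps <- steps + 1
      if (steps > max_steps) {
        abort("ODE solver exceeded the step budget.",
              class = "growthmedia_integration_error",
              body = format_ode_context(context))
      }
      h <- min(h, target - t)
      ks <- matrix(0, nrow = 7, ncol = d)
      ks[1, ] <- k1
      ok <- TRUE
      for (s in 1:6) {
        ys <- y + h * drop(a[[s]] %*% ks[seq_along(a[[s]]), , drop = FALSE])
        kk <- f(t + c_nodes[s] * h, ys)
        if (any(!is.finite(kk))) { ok <- FALSE; break }
        ks[s + 1, ] <- kk
      }
      if (ok) {
        y5 <- y + h * drop(b5 %*% ks)
        y4 <- y + h * drop(b4 %*% ks)
        sc <- atol + rtol * pmax(abs(y), abs(y5))
        err <- sqrt(mean(((y5 - y4) / sc)^2))
      } else {
        err <- Inf
      }
      if (is.finite(err) && err <= 1) {
        t <- t + h
        y <- y5
        k1 <- ks[7, ]   # FSAL
        fac <- if (err == 0) 5 else min(5, max(0.2, 0.9 * err^(-0.2)))
        h <- h * fac
      } else {
        if (!is.finite(err)) {
          h <- h / 10
        } else {
          h <- h * max(0.2, 0.9 * err^(-0.2))
        }
        if (h < 1e-14 * max(1, abs(t))) {
          abort("ODE step size underflow.",
                class = "growthmedia_integration_error",
                body = format_ode_context(context))
        }
      }
    }
    out[idx, ] <- y
    idx <- idx + 1
  }
  out
}

format_ode_context <- function(context) {
  if (is.null(context)) return(character())
  paste0("context: ",
         paste(names(unlist(context)), unlist(context),
               sep = "=", collapse = ", "))
}
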