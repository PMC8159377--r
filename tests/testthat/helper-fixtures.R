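# Shared fixtures built in code. Fields are cached per session because several
# test files reuse the same synthetic conditions.

default_field <- local({
  cache <- NULL
  function() {
    if (is.null(cache))
      cache <<- make_waveform(synth_truth(noise_sd = 0),
                              s_grid = seq(0, 0.9, length.out = 200),
                              t_grid = seq(0, 1.5, by = 1 / 200))
    cache
  }
})

default_pod <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- cpod(fit_waveform(default_field()), M = 4)
    cache
  }
})

default_mechanics <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      pod <- default_pod()
      model <- material_model(L = 120, sN = pod$sN, sT = pod$sT, s_e = 0.05)
      cache <<- flagellar_mechanics(pod, model)
    }
    cache
  }
})

# independent dense constrained least-squares oracle: null-space
# parameterization of the equality constraints, plain QR least squares on the
# node samples (the Chebyshev weight is constant across Gauss--Chebyshev
# nodes, so unweighted LS at the nodes minimizes the same objective)
qp_oracle_fit <- function(y_nodes, b, P) {
  Tm <- cheb_matrix(cheb_nodes(P), P)
  Cm <- rbind(cheb_boundary(P, 0), cheb_boundary(P, 1), cheb_boundary(P, 2))
  qrC <- qr(t(Cm))
  a_p <- t(Cm) %*% solve(Cm %*% t(Cm), b) # minimal-norm particular solution
  N <- qr.Q(qrC, complete = TRUE)[, (nrow(Cm) + 1):(P + 1)]
  z <- qr.solve(Tm %*% N, y_nodes - Tm %*% a_p)
  drop(a_p + N %*% z)
}

rms <- function(x) sqrt(mean(x^2))
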