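# Shared fixtures built in code. All numeric expectations frozen here were
# computed with independent oracles (dense trapezoid quadrature, central
# finite differences, closed-form hand evaluation) before being asserted.

# canonical thick-walled test vessel
g_std <- vessel_geometry(A = 0.8, B = 1.0)

# neo-Hookean-only wall (no fibres)
pp_neo <- passive_params(mu = 10)

# four-fibre wall with moderate nonlinearity
pp_fib <- passive_params(
  mu = 15,
  families = data.frame(k1 = c(8, 5, 4, 4), k2 = c(0.5, 0.8, 1.0, 1.0),
                        alpha_deg = c(0, 90, 40, -40)))

# one instance of every family, parameters placed so that closed forms apply
# on the standard (a, lambda_z) grids below
models_all <- list(
  constant_cauchy = active_model("constant_cauchy", Tc = 20),
  constant_1pk    = active_model("constant_1pk", Ti = 18),
  constant_2pk    = active_model("constant_2pk", Tr = 16),
  rachev          = active_model("rachev", TRv = 40, lambda_m = 1.6, lambda_0 = 0.2),
  zulliger        = active_model("zulliger", TZr = 30, lambda_pre = 1.3),
  franchini       = active_model("franchini", TFr1 = 10, alpha1 = 1.2,
                                 beta1 = 0.4, m1 = 2))

# grid of admissible states: inner-wall stretch 0.9..1.9, axial 1.1..1.9
grid_states <- function(n_a = 6L, n_z = 5L, geom = g_std) {
  expand.grid(a = geom$A * seq(0.9, 1.9, length.out = n_a),
              lambda_z = seq(1.1, 1.9, length.out = n_z))
}

# independent fine-grid trapezoid quadrature of any integrand f(r)
trapz_oracle <- function(f, lo, hi, n = 20001L) {
  r <- seq(lo, hi, length.out = n)
  y <- f(r)
  sum((y[-1] + y[-n]) / 2 * diff(r))
}

# central finite difference
fd_central <- function(f, x, h) (f(x + h) - f(x - h)) / (2 * h)
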