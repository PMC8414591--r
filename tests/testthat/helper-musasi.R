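# Shared fixtures: small parameter sets built in code.

# A small ensemble for fast engine tests.
small_params <- function(model = "dse", ...) {
  xb_params(model, NF = 2, NM = 10, ...)
}

xb_state_names <- c("N_XB", "P_XB", "N_ATP", "XB_PreR", "XB_PostR1",
                    "XB_PostR2")

# Parameter set whose molecular rates are strain-independent (zero-stiffness
# rod, flat free-energy ladder, no reachable forced-detachment bound) so
# ensemble dynamics reduce to a constant-rate 6-state Markov chain that a
# master equation can integrate exactly.
frozen_rate_params <- function(NF = 4, NM = 10,
                               k_np = 150, k_pn = 200, f_attach = 120,
                               d_detach = 180, d_post2 = 90, k_atp = 250,
                               h1 = 60, h2 = 40) {
  rod <- rod_model(k_pos = 0, k_neg = 0, kBT = 4.28, strain_max = 1e6)
  eps <- 1e-9  # ladder must be strictly decreasing; this keeps rates flat
  ladder <- free_energy_ladder(E0 = 2 * eps, E1 = eps, E2 = 0,
                               s1 = 6, s2 = 4)
  rates <- rate_model("dse", prefactors = c(h1, h2), ladder = ladder)
  xb_params("dse", gamma = 1, NF = NF, NM = NM, rod = rod, ladder = ladder,
            rates = rates, k_np = k_np, k_pn = k_pn, f_attach = f_attach,
            d_detach = d_detach, d_post2 = d_post2, k_atp = k_atp,
            # clamp the T/T units open so they do not gate attachment
            k_ca_on = 1e4, k_ca_off = 0, k_open = 1e4, k_close = 0)
}

# Generator matrix of the 6-state chain matching frozen_rate_params(), in the
# package's state order (N_XB, P_XB, N_ATP, XB_PreR, XB_PostR1, XB_PostR2).
# Stroke rates are the flat-ladder DSE values: h_f = h_b = h_i.
frozen_rate_Q <- function(p) {
  k <- c(knp = p$k_np, kpn = p$k_pn, f = p$f_attach, d = p$d_detach,
         g = p$d_post2, atp = p$k_atp,
         h1 = p$rates$prefactors[1], h2 = p$rates$prefactors[2])
  Q <- matrix(0, 6, 6, dimnames = list(xb_state_names, xb_state_names))
  Q["N_XB", "P_XB"] <- k["knp"]
  Q["P_XB", "N_XB"] <- k["kpn"]
  Q["P_XB", "XB_PreR"] <- k["f"]
  Q["XB_PreR", "P_XB"] <- k["d"]
  Q["XB_PreR", "XB_PostR1"] <- k["h1"]
  Q["XB_PostR1", "XB_PreR"] <- k["h1"]
  Q["XB_PostR1", "XB_PostR2"] <- k["h2"]
  Q["XB_PostR2", "XB_PostR1"] <- k["h2"]
  Q["XB_PostR2", "N_XB"] <- k["g"]
  Q["N_ATP", "N_XB"] <- k["atp"]
  diag(Q) <- -rowSums(Q)
  Q
}

# Random interval records for property tests: run short MC intervals at
# saturating calcium from varying initial conditions.  `symmetric` uses a
# single-stiffness rod, whose force law has no kink at x = 0.
random_record <- function(seed, model = "dse", lambda_dot = 0, n = 40,
                          DT = 0.2, ca = 20, symmetric = FALSE) {
  set.seed(seed)
  p <- if (symmetric) {
    small_params(model, rod = rod_model(k_pos = 2, k_neg = 2))
  } else {
    small_params(model)
  }
  hs <- half_sarcomere(p)
  # burn in long enough for cooperative activation and attachment (~40 ms)
  for (i in 1:64) {
    res <- run_mc_interval(hs, DT = 1.25, ca = ca,
                           lambda_T = hs$lambda, lambda_dot_T = 0)
    hs <- hs_commit(res$hs, res$record, hs$lambda, 0)
  }
  run_mc_interval(hs, DT = DT, n = n, ca = ca,
                  lambda_T = hs$lambda, lambda_dot_T = lambda_dot)$record
}
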