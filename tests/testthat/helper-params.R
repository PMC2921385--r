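# Small fixed parameter bundles used across tests. `tp_small` is a mild,
# fast-relaxing transport system for structural checks; the presets are
# loaded where the study conditions themselves are under test.

tp_small <- function(...) {
  defaults <- list(alpha = 1, Kd = 0.1, D = 0.4, K0 = 0.2, k1 = 0.5,
                   q1 = 0.5, q2 = 4, h1 = 2, k2 = 0.1, q3 = 2, h2 = 4)
  do.call(transport_params, utils::modifyList(defaults, list(...)))
}

dp_small <- function(...) {
  defaults <- list(beta = 1, T = 0.1, kdeg = 0.06, q4 = 2.4, q5 = 3.5,
                   h3 = 6, h4 = 6, D_DivF = 0.5)
  do.call(divf_params, utils::modifyList(defaults, list(...)))
}

cp_small <- function(...) {
  defaults <- list(K_growth = 0.01, r_min = 2, r0 = 1, gp_rate = 0.1,
                   gp_exp = 20, ip_rate = 0.1, ip_mid = 1.2,
                   ip_hup = 2, ip_hdown = 6)
  do.call(cycle_params, utils::modifyList(defaults, list(...)))
}

set_small <- function(...) {
  list(name = "test", transport = tp_small(...), divf = dp_small(),
       cycle = cp_small())
}

# pack a full set with overridden cycle parameters
set_with_cycle <- function(cycle, ...) {
  s <- set_small(...); s$cycle <- cycle; s
}
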