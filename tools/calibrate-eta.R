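suppressMessages(pkgload::load_all("/root/pkg", quiet=TRUE))
base <- list(Gamma=2.5e14, rho0=1, tau_a=100, gamma=1e-5, f_adh=1e7, R_L=1e-5, d=1e-7)
mk <- function(eta, sigma0, zeta) do.call(gel_params, c(list(eta=eta, sigma0=sigma0, zeta=zeta), base))
tau_of <- function(eta, sigma0, zeta) pore_timescale(mk(eta, sigma0, zeta))$tau
cal <- function(target, sigma0, zeta, lo, hi) uniroot(function(e) tau_of(e, sigma0, zeta) - target, c(lo, hi), tol=1e-3)$root
e_bare  <- cal(20, 0, 0, 50, 5000)
e_actin <- cal(80, 0, -1, 200, 20000)
e_amyo  <- cal(20, 1, 1, 210, 5000)
cat(sprintf("bare %.1f actin %.1f actomyosin %.1f\n", e_bare, e_actin, e_amyo))
cat(sprintf("check taus: %.2f %.2f %.2f\n", tau_of(e_bare,0,0), tau_of(e_actin,0,-1), tau_of(e_amyo,1,1)))
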