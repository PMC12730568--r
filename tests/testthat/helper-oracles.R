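# Independent literal transcription of the bound/margin formulas, used only
# as a cross-check oracle against the criteria module (separate code path).
oracleMargins <- function(tab, b) {
  sup <- function(nm) tab[[nm]][["sup"]]
  inf <- function(nm) tab[[nm]][["inf"]]
  den2 <- (1 + inf("a") * b$m2 + inf("e") * b$m3)^2
  c(H1 = sup("psi") * b$M1 - inf("delta"),
    H2 = sup("gamma") * b$M2 - inf("r2"),
    H3 = inf("r1") - (sup("b") + sup("beta")) * b$M2,
    H4 = inf("psi") * b$m1 - (sup("alpha") * b$M3 + sup("delta")),
    H5 = inf("gamma") * b$m2 /
      (sup("d") * (1 + sup("a") * b$M2 + sup("e") * b$M3)) -
      sup("r2") / sup("d"),
    H6 = inf("b") - sup("psi"),
    H7 = inf("c") - sup("b") - sup("beta") -
      (sup("a") * sup("alpha") * b$M3 +
         sup("gamma") * (1 + sup("e") * b$M3)) / den2,
    H8 = inf("d") - (sup("alpha") + sup("a") * sup("alpha") * b$M2 -
                       inf("gamma") * inf("e") * b$m2) / den2)
}

oracleStars <- function(tab, M1, M2, M3, m1, m2) {
  sup <- function(nm) tab[[nm]][["sup"]]
  inf <- function(nm) tab[[nm]][["inf"]]
  c(M1star = sup("r1") / inf("b"),
    M2star = (sup("psi") * M1 - inf("delta")) / inf("c"),
    M3star = (sup("gamma") * M2 - inf("r2")) / inf("d"),
    m1star = (inf("r1") - (sup("b") + sup("beta")) * M2) / sup("b"),
    m2star = (inf("psi") * m1 - sup("alpha") * M3 - sup("delta")) / sup("c"),
    m3star = inf("gamma") * m2 /
      (sup("d") * (1 + sup("a") * M2 + sup("e") * M3)) -
      sup("r2") / sup("d"))
}

# per-species relative sup-norm distance between a PDE run and an ODE
# trajectory sampled at the same times (species scale = its ODE sup)
odePdeRelErr <- function(pde, ode) {
  max(vapply(1:3, function(j) {
    d <- max(vapply(seq_along(pde$times), function(k)
      max(abs(pde$snapshots[[k]][, j] - ode$states[k, j])), numeric(1)))
    d / max(ode$states[, j])
  }, numeric(1)))
}

# all-constant model around gentle coexistence values (valid means positive)
constantModel <- function(r1 = 1, b = 1, beta = 0.1, delta = 0.1, c = 1,
                          psi = 0.3, alpha = 0.1, a = 0.05, e = 0.05,
                          gamma = 0.5, r2 = 0.05, d = 0.5) {
  ecoEpidemicModel(r1 = r1, b = b, beta = beta, delta = delta, c = c,
                   psi = psi, alpha = alpha, a = a, e = e, gamma = gamma,
                   r2 = r2, d = d, omega = 2)
}

cosPerturbedInitial <- function(grid, base = c(2.5, 0.1, 0.085),
                                amp = c(0.3, 0.02, 0.01)) {
  x <- grid$x
  cbind(base[1] + amp[1] * cos(x), base[2] + amp[2] * cos(x),
        base[3] + amp[3] * cos(x))
}
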