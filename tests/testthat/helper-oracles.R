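# Independent oracles used across the suite. These deliberately re-derive
# quantities through different routes than the package implementation:
# impedance composition instead of nodal admittance sums, dense base-R
# solve() instead of the unrolled tridiagonal/elimination kernels.

# parallel RC impedance by direct complex arithmetic
oracle_zrc <- function(R, C, f) R / (1 + 1i * 2 * pi * f * R * C)

oracle_parallel <- function(Z1, Z2) Z1 * Z2 / (Z1 + Z2)

# two-line crosstalk gain as a voltage divider corrected for shunt loading:
# H = Z_term / (Z_coupling + Z_term), where Z_term is the passive node's
# total impedance to ground (series branch in parallel with its shunts)
oracle_two_line_gain <- function(p, f) {
  vapply(f, function(fi) {
    Zser <- p$R_S + p$R_E + oracle_zrc(p$R_F, p$C_H, fi)
    Zsh  <- oracle_parallel(oracle_zrc(p$R_Sh, p$C_Sh, fi),
                            oracle_zrc(p$R_Amp, p$C_Amp, fi))
    Zterm <- oracle_parallel(Zser, Zsh)
    Zc <- oracle_parallel(oracle_zrc(p$R_Imp, p$C_Imp, fi),
                          oracle_zrc(p$R_Int, p$C_Int, fi))
    Zterm / (Zc + Zterm)
  }, complex(1))
}

# dense modified-nodal solve of the four-line network with base solve();
# drive selects which line hosts the source
oracle_four_line <- function(p, f, drive = 1) {
  t(vapply(f, function(fi) {
    Ys <- 1 / (p$R_S + p$R_E + oracle_zrc(p$R_F, p$C_H, fi))
    Ysh <- 1 / oracle_zrc(p$R_Sh, p$C_Sh, fi) +
           1 / oracle_zrc(p$R_Amp, p$C_Amp, fi)
    Yc <- 1 / oracle_zrc(p$R_Imp, p$C_Imp, fi) +
          1 / oracle_zrc(p$R_Int, p$C_Int, fi)
    Y <- diag(rep(Ys + Ysh, 4))
    for (i in 1:3) {
      Y[i, i] <- Y[i, i] + Yc; Y[i + 1, i + 1] <- Y[i + 1, i + 1] + Yc
      Y[i, i + 1] <- -Yc; Y[i + 1, i] <- -Yc
    }
    b <- complex(4); b[drive] <- Ys
    solve(Y, b)
  }, complex(4)))
}

# log-uniform random positive chain parameters (all elements present)
random_chain_parameters <- function() {
  lu <- function(lo, hi) 10^stats::runif(1, log10(lo), log10(hi))
  chain_parameters(
    R_S = lu(1e3, 1e6), R_E = lu(1e2, 1e5),
    R_F = lu(1e5, 1e8), C_H = lu(1e-10, 1e-7),
    R_Sh = lu(1e7, 1e10), C_Sh = lu(1e-12, 1e-10),
    R_Imp = lu(1e7, 1e10), C_Imp = lu(1e-12, 1e-10),
    R_Int = lu(1e5, 1e8), C_Int = lu(1e-12, 1e-10),
    R_Amp = lu(1e10, 1e13), C_Amp = lu(1e-12, 1e-10))
}

# homogeneous Poisson spike train on [0, T]
poisson_train <- function(rate, T) {
  n <- stats::rpois(1, rate * T)
  spike_train(sort(stats::runif(n, 0, T)))
}

ref_params <- chain_parameters()

# run the CLI quietly, returning only its exit status
capture_status <- function(args) {
  status <- NULL
  invisible(utils::capture.output(status <- nxt_cli(args)))
  status
}
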