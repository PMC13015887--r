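# Independent oracles, deliberately implemented along different paths than
# the package code they check.

# Spreadsheet-style nearest-neighbor summation: walk the sequence, look the
# dinucleotide step up in a two-column table, accumulate, add initiation and
# salt terms, evaluate dG at temperature.  Same published constants, fully
# independent code path.
oracle_nn_table <- data.frame(
  step = c("AA", "AT", "TA", "CA", "GT", "CT", "GA", "CG", "GC", "GG",
           "TT", "AC", "TG", "AG", "TC", "CC"),
  dH = c(-7.9, -7.2, -7.2, -8.5, -8.4, -7.8, -8.2, -10.6, -9.8, -8.0,
         -7.9, -8.4, -8.5, -7.8, -8.2, -8.0),
  dS = c(-22.2, -20.4, -21.3, -22.7, -22.4, -21.0, -22.2, -27.2, -24.4,
         -19.9, -22.2, -22.4, -22.7, -21.0, -22.2, -19.9),
  stringsAsFactors = FALSE
)

oracle_duplex_dG <- function(seq, temp_c, na_molar) {
  s <- toupper(seq)
  n <- nchar(s)
  dH <- 0
  dS <- 0
  if (n >= 2) {
    for (i in 1:(n - 1)) {
      step <- substr(s, i, i + 1)
      row <- oracle_nn_table[oracle_nn_table$step == step, ]
      dH <- dH + row$dH
      dS <- dS + row$dS
    }
  }
  for (b in c(substr(s, 1, 1), substr(s, n, n))) {
    if (b %in% c("A", "T")) {
      dH <- dH + 2.3
      dS <- dS + 4.1
    } else {
      dH <- dH + 0.1
      dS <- dS - 2.8
    }
  }
  dS <- dS + 0.368 * (n - 1) * log(na_molar)
  dH - (temp_c + 273.15) * dS / 1000
}

# Bisection solve of the exact bimolecular equilibrium
# K (P0 - x)(T0 - x) = x for the bound concentration x.
oracle_equilibrium_bound <- function(dG, temp_c, P0, T0) {
  K <- exp(-dG / (0.0019872 * (temp_c + 273.15)))
  f <- function(x) K * (P0 - x) * (T0 - x) - x
  lo <- 0
  hi <- min(P0, T0)
  for (i in 1:200) {
    mid <- (lo + hi) / 2
    if (f(mid) > 0) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

# Joint competitive equilibrium of one primer against two template pools,
# by bisection on the free-primer concentration.
oracle_competitive_equilibrium <- function(KS, KL, P0, S0, L0) {
  bound <- function(P) {
    KS * P / (1 + KS * P) * S0 + KL * P / (1 + KL * P) * L0
  }
  lo <- 0
  hi <- P0
  for (i in 1:200) {
    mid <- (lo + hi) / 2
    if (mid + bound(mid) < P0) lo <- mid else hi <- mid
  }
  P <- (lo + hi) / 2
  c(bS = KS * P / (1 + KS * P) * S0, bL = KL * P / (1 + KL * P) * L0)
}

# Fixed-step RK4 integration of the two-pool hybridization ODE.
oracle_rk4_anneal <- function(kf, krS, krL, P0, S0, L0, duration, dt) {
  deriv <- function(y) {
    P <- P0 - y[1] - y[2]
    c(kf * P * (S0 - y[1]) - krS * y[1],
      kf * P * (L0 - y[2]) - krL * y[2])
  }
  y <- c(0, 0)
  nstep <- ceiling(duration / dt)
  h <- duration / nstep
  for (i in seq_len(nstep)) {
    k1 <- deriv(y)
    k2 <- deriv(y + h / 2 * k1)
    k3 <- deriv(y + h / 2 * k2)
    k4 <- deriv(y + h * k3)
    y <- y + h / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
  }
  c(bS = y[1], bL = y[2])
}

revcomp <- function(s) {
  map <- c(A = "T", C = "G", G = "C", T = "A")
  paste(rev(map[strsplit(toupper(s), "")[[1]]]), collapse = "")
}

all_kmers <- function(k) {
  do.call(paste0, expand.grid(rep(list(c("A", "C", "G", "T")), k),
                              stringsAsFactors = FALSE))
}
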