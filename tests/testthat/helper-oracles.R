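# Shared fixtures and independent oracles, all built in code.

# Minimal PDB ATOM-record writer for toy structures.
# residues: data frame with chain, resno, resname and a list-column `atoms`
# of data frames (name, x, y, z, element).
toy_pdb <- function(residues) {
  lines <- character(0)
  serial <- 0L
  for (i in seq_len(nrow(residues))) {
    at <- residues$atoms[[i]]
    for (j in seq_len(nrow(at))) {
      serial <- serial + 1L
      lines <- c(lines, sprintf(
        "ATOM  %5d %-4s %3s %1s%4d    %8.3f%8.3f%8.3f  1.00  0.00          %2s",
        serial, at$name[j], residues$resname[i], residues$chain[i],
        residues$resno[i], at$x[j], at$y[j], at$z[j], at$element[j]))
    }
  }
  paste(c(lines, "END"), collapse = "\n")
}

# one CA-only residue at (x, y, z)
ca_residue <- function(chain, resno, resname, x, y, z) {
  data.frame(chain = chain, resno = resno, resname = resname,
             atoms = I(list(data.frame(name = "CA", x = x, y = y, z = z,
                                       element = "C"))))
}

# Monte-Carlo orientational-average oracle for the coherent ISF:
# mean over random directions Qhat of Re[F(0) F*(t)] with
# F(t) = sum_n b_n exp(i Q Qhat . r_n(t)). A and B are N x 3 bead positions
# at the origin time and the lagged time. Returns mean and MC standard error.
isf_mc_oracle <- function(A, B, Q, b = rep(1, nrow(A)), n_dir = 20000,
                          seed = 42) {
  set.seed(seed)
  u <- matrix(rnorm(3 * n_dir), ncol = 3)
  u <- u / sqrt(rowSums(u^2))
  phA <- A %*% t(Q * u)   # N x n_dir
  phB <- B %*% t(Q * u)
  re <- (b %*% cos(phA)) * (b %*% cos(phB)) +
        (b %*% sin(phA)) * (b %*% sin(phB))
  re <- as.vector(re)
  list(mean = mean(re), se = sd(re) / sqrt(n_dir))
}

# Naive O(N^2) Debye sum, the readable oracle for form_factor().
debye_loop <- function(pos, b, Q) {
  n <- nrow(pos)
  vapply(Q, function(q) {
    s <- 0
    for (m in seq_len(n)) {
      for (k in seq_len(n)) {
        r <- sqrt(sum((pos[m, ] - pos[k, ])^2))
        s <- s + b[m] * b[k] * (if (q * r < 1e-12) 1 else sin(q * r) / (q * r))
      }
    }
    s / sum(b)^2
  }, numeric(1))
}

# Analytic coherent rotational ISF of a symmetric 2-bead rod of length L
# under rotational diffusion D_r: even-l spherical Bessel expansion,
# normalized to 1 at t = 0.
rod_rot_isf <- function(Q, L, Dr, t, lmax = 24) {
  l <- seq(0, lmax, by = 2)
  jl <- vapply(l, function(ll) {
    x <- Q * L / 2
    if (x < 1e-12) as.numeric(ll == 0) else
      sqrt(pi / (2 * x)) * besselJ(x, ll + 0.5)
  }, numeric(1))
  w <- (2 * l + 1) * jl^2
  sapply(t, function(tt) sum(w * exp(-l * (l + 1) * Dr * tt)) / sum(w))
}

# Monte-Carlo oracle for the structure-weighted translational diffusion
# coefficient: <|F|^2 (Qhat . tt . Qhat)> / <|F|^2> over random directions.
dtrans_mc_oracle <- function(model, tt, Q, n_dir = 1e6, seed = 7,
                             chunk = 1e5) {
  set.seed(seed)
  num <- den <- 0
  num2 <- 0
  left <- n_dir
  vals <- numeric(0)
  while (left > 0) {
    nd <- min(chunk, left)
    left <- left - nd
    u <- matrix(rnorm(3 * nd), ncol = 3)
    u <- u / sqrt(rowSums(u^2))
    ph <- model$positions %*% t(Q * u)
    b <- model$scattering_lengths
    f2 <- as.vector(b %*% cos(ph))^2 + as.vector(b %*% sin(ph))^2
    dq <- rowSums((u %*% tt) * u)
    vals <- c(vals, f2 * dq / mean(f2)) # ratio-estimator pieces for SE
    num <- num + sum(f2 * dq)
    den <- den + sum(f2)
  }
  list(value = num / den, se = sd(vals) / sqrt(n_dir))
}
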