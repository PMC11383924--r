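# Independent oracles used to cross-check the package's implementations.
# These deliberately avoid the code paths they verify (no Kabsch SVD, no
# vectorised pair scans).

euler_rotation <- function(a, b, c) {
  Rz <- matrix(c(cos(a), sin(a), 0, -sin(a), cos(a), 0, 0, 0, 1), 3, 3)
  Ry <- matrix(c(cos(b), 0, -sin(b), 0, 1, 0, sin(b), 0, cos(b)), 3, 3)
  Rx <- matrix(c(1, 0, 0, 0, cos(c), sin(c), 0, -sin(c), cos(c)), 3, 3)
  Rz %*% Ry %*% Rx
}

# Brute-force superposition: coarse Euler-angle grid search refined by
# Nelder-Mead; translation handled by centroid matching.
oracle_superpose <- function(mobile, target) {
  cm <- colMeans(mobile); ct <- colMeans(target)
  X <- sweep(as.matrix(mobile), 2, cm)
  Y <- sweep(as.matrix(target), 2, ct)
  f <- function(p) {
    R <- euler_rotation(p[1], p[2], p[3])
    sqrt(mean(rowSums((X %*% t(R) - Y)^2)))
  }
  grid <- as.matrix(expand.grid(a = seq(0, 330, 30) * pi / 180,
                                b = seq(0, 330, 30) * pi / 180,
                                c = seq(0, 330, 30) * pi / 180))
  v <- apply(grid, 1, f)
  best <- grid[which.min(v), ]
  opt <- stats::optim(best, f, method = "Nelder-Mead",
                      control = list(maxit = 5000, reltol = 1e-15))
  R <- euler_rotation(opt$par[1], opt$par[2], opt$par[3])
  list(rmsd = opt$value, rotation = R,
       translation = ct - as.vector(R %*% cm))
}

# O(n_atoms^2) double-loop contact scan.
oracle_contacts <- function(s, chain_a, chain_b, cutoff) {
  A <- s$atoms[s$atoms$chain == chain_a & !(s$atoms$element %in% c("H", "D")), ]
  B <- s$atoms[s$atoms$chain == chain_b & !(s$atoms$element %in% c("H", "D")), ]
  hits <- list()
  for (i in seq_len(nrow(A))) {
    for (j in seq_len(nrow(B))) {
      d <- sqrt((A$x[i] - B$x[j])^2 + (A$y[i] - B$y[j])^2 +
                  (A$z[i] - B$z[j])^2)
      if (d <= cutoff)
        hits[[length(hits) + 1L]] <- c(A$resno[i], B$resno[j])
    }
  }
  if (!length(hits)) return(data.frame(res_a = integer(), res_b = integer()))
  p <- unique(as.data.frame(do.call(rbind, hits)))
  names(p) <- c("res_a", "res_b")
  p <- p[order(p$res_a, p$res_b), ]
  rownames(p) <- NULL
  p
}

# Step-by-step DockQ recomputation for one interface using the oracle
# superposition and contact scan.
oracle_dockq_interface <- function(native, model, chain_a, chain_b) {
  nat5 <- oracle_contacts(native, chain_a, chain_b, 5)
  mod5 <- oracle_contacts(model, chain_a, chain_b, 5)
  fn <- mean(paste(nat5$res_a, nat5$res_b) %in% paste(mod5$res_a, mod5$res_b))
  nat10 <- oracle_contacts(native, chain_a, chain_b, 10)
  bb <- function(s, ch, resnos) {
    a <- s$atoms[s$atoms$chain == ch & s$atoms$elety %in%
                   c("N", "CA", "C", "O") &
                   (if (is.null(resnos)) TRUE else s$atoms$resno %in% resnos), ]
    a <- a[order(a$resno, match(a$elety, c("N", "CA", "C", "O"))), ]
    as.matrix(a[, c("x", "y", "z")])
  }
  nat_i <- rbind(bb(native, chain_a, unique(nat10$res_a)),
                 bb(native, chain_b, unique(nat10$res_b)))
  mod_i <- rbind(bb(model, chain_a, unique(nat10$res_a)),
                 bb(model, chain_b, unique(nat10$res_b)))
  ir <- oracle_superpose(mod_i, nat_i)$rmsd
  na <- length(unique(native$atoms$resno[native$atoms$chain == chain_a]))
  nb <- length(unique(native$atoms$resno[native$atoms$chain == chain_b]))
  larger  <- if (nb > na) chain_b else chain_a
  smaller <- if (nb > na) chain_a else chain_b
  tf <- oracle_superpose(bb(model, larger, NULL), bb(native, larger, NULL))
  fit <- sweep(bb(model, smaller, NULL) %*% t(tf$rotation), 2,
               tf$translation, "+")
  lr <- sqrt(mean(rowSums((fit - bb(native, smaller, NULL))^2)))
  dq <- (fn + 1 / (1 + (ir / 1.5)^2) + 1 / (1 + (lr / 8.5)^2)) / 3
  list(fnat = fn, irms = ir, lrms = lr, dockq = dq)
}

# Closed-form CA(i)-CA(i+k) distance on the ideal helix (chord + rise).
helix_ca_closed_form <- function(k, radius = 2.3, twist = 100, rise = 1.5) {
  sqrt((2 * radius * sin(k * twist * pi / 360))^2 + (k * rise)^2)
}

# Exact accessible area of sphere 1 (radius r1) partially buried by
# sphere 2 (radius r2) at centre distance d: full area minus the
# spherical cap inside sphere 2.
cap_accessible_area <- function(r1, r2, d) {
  if (d >= r1 + r2) return(4 * pi * r1^2)
  if (d + r1 <= r2) return(0)
  h <- r1 - (d^2 + r1^2 - r2^2) / (2 * d)
  4 * pi * r1^2 - 2 * pi * r1 * h
}

# Random proper rotation + translation, from a seeded stream.
random_rigid_transform <- function() {
  ax <- stats::rnorm(3)
  list(rotation = rotation_matrix(stats::runif(1, 0, 360), ax),
       translation = stats::runif(3, -50, 50))
}

apply_rigid_to_structure <- function(s, tf) {
  s$atoms[, c("x", "y", "z")] <-
    apply_transform(as.matrix(s$atoms[, c("x", "y", "z")]), tf)
  s
}
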