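# Independent oracles used by the structural tests. These deliberately use
# different algorithms from the package implementation.

# SASA by latitude-longitude quadrature with sin(theta) area weights -- a
# different point set and weighting than the package's Fibonacci lattice.
gridSasa <- function(structure, probe = 1.4, nTheta = 80, nPhi = 160) {
  a <- atoms(structure)
  xyz <- coords(structure)
  rs <- a$radius + probe
  th <- (seq_len(nTheta) - 0.5) * pi / nTheta
  ph <- (seq_len(nPhi) - 0.5) * 2 * pi / nPhi
  g <- expand.grid(th = th, ph = ph)
  dirs <- cbind(sin(g$th) * cos(g$ph), sin(g$th) * sin(g$ph), cos(g$th))
  w <- sin(g$th) / sum(sin(g$th))
  n <- nrow(a)
  out <- numeric(n)
  for (i in seq_len(n)) {
    sp <- dirs * rs[i] + matrix(xyz[i, ], nrow(dirs), 3, byrow = TRUE)
    acc <- rep(TRUE, nrow(dirs))
    for (j in seq_len(n)) {
      if (j == i) next
      d2 <- (sp[, 1] - xyz[j, 1])^2 + (sp[, 2] - xyz[j, 2])^2 +
        (sp[, 3] - xyz[j, 3])^2
      acc <- acc & d2 > rs[j]^2 - 1e-9
    }
    out[i] <- 4 * pi * rs[i]^2 * sum(w[acc])
  }
  out
}

# per-residue grid-oracle SASA for a chain subset
gridResidueSasa <- function(structure, probe = 1.4, ...) {
  a <- atoms(structure)
  s <- gridSasa(structure, probe, ...)
  tapply(s, paste(a$chain, a$resno), sum)
}

eulerRotation <- function(a, b, c) {
  rz <- function(t) matrix(c(cos(t), -sin(t), 0, sin(t), cos(t), 0,
                             0, 0, 1), 3, 3, byrow = TRUE)
  ry <- function(t) matrix(c(cos(t), 0, sin(t), 0, 1, 0,
                             -sin(t), 0, cos(t)), 3, 3, byrow = TRUE)
  rz(a) %*% ry(b) %*% rz(c)
}

# minimum attainable RMSD by exhaustive rotation search (centroids aligned),
# coarse Euler grid refined with Nelder-Mead -- no SVD anywhere
bruteForceRmsd <- function(mobile, reference) {
  P <- sweep(mobile, 2, colMeans(mobile))
  Q <- sweep(reference, 2, colMeans(reference))
  f <- function(p) {
    R <- eulerRotation(p[1], p[2], p[3])
    sqrt(mean(rowSums((P %*% t(R) - Q)^2)))
  }
  best <- Inf; bestp <- c(0, 0, 0)
  for (a in seq(0, 2 * pi, length.out = 13))
    for (b in seq(0, pi, length.out = 7))
      for (cc in seq(0, 2 * pi, length.out = 13)) {
        v <- f(c(a, b, cc))
        if (v < best) { best <- v; bestp <- c(a, b, cc) }
      }
  o <- stats::optim(bestp, f, method = "Nelder-Mead",
                    control = list(reltol = 1e-14, maxit = 10000))
  o$value
}

# uniform-ish random rotation of a given small angle (radians)
randomSmallRotation <- function(angle) {
  u <- stats::rnorm(3); u <- u / sqrt(sum(u^2))
  ux <- matrix(c(0, -u[3], u[2], u[3], 0, -u[1], -u[2], u[1], 0),
               3, 3, byrow = TRUE)
  diag(3) * cos(angle) + sin(angle) * ux +
    (1 - cos(angle)) * (u %o% u)
}

# a bare StructureModel from a coordinate matrix of carbon atoms
carbonModel <- function(xyz, chain = "A", resno = seq_len(nrow(xyz))) {
  new("StructureModel", atoms = data.frame(
    chain = chain, resno = resno, resid = "UNK", elety = "CA",
    element = "C", x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
    radius = 1.7))
}
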