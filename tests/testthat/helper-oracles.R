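# independent oracles used against the package's own implementations

# exact permutation log-rank p-value: enumerates every assignment of
# group labels (n choose nA) and returns the tail fraction of the
# chi-square statistic at or above the observed one
permutationLogrankP <- function(timeA, eventA, timeB, eventB) {
  time <- c(timeA, timeB); event <- c(eventA, eventB)
  n <- length(time); nA <- length(timeA)
  obs <- logrankTest(timeA, eventA, timeB, eventB)@statistic
  combos <- utils::combn(n, nA)
  stats <- apply(combos, 2, function(ix) {
    logrankTest(time[ix], event[ix], time[-ix], event[-ix])@statistic
  })
  mean(stats >= obs - 1e-12)
}

# lattice points of a given pitch (anchored at the origin) inside a
# sphere: the analytic candidate-count oracle
latticePointsInSphere <- function(radiusMm, pitchMm) {
  k <- floor(radiusMm / pitchMm)
  g <- expand.grid(x = -k:k, y = -k:k, z = -k:k) * pitchMm
  sum(g$x^2 + g$y^2 + g$z^2 <= radiusMm^2)
}

# quadrature oracle for cumulated activity (decays of a0 * 2^(-t/T));
# 50 half-lives truncate the tail below 1e-15 of the total
quadratureCumulatedActivity <- function(a0, halfLifeHours) {
  f <- function(t) a0 * 2^(-t / (halfLifeHours * 3600))
  stats::integrate(f, 0, 50 * halfLifeHours * 3600,
                   rel.tol = 1e-9, subdivisions = 500L)$value
}
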