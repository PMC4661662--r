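# Independent brute-force implementation used as an oracle.  It works on a
# plain dense minutes matrix, materialises every reachable-set sum from
# scratch with explicit loops, and shares no code with the package
# internals beyond the decay weight definition passed in as `wfun`.

oracle_catchments <- function(facilities, populations, dmat, cfg) {
  grid <- seq(cfg$t0, cfg$t_max, by = cfg$dt)
  S <- facilities$capacity
  P <- populations$population
  nf <- nrow(facilities)
  np <- nrow(populations)
  fC <- numeric(nf); fF <- numeric(nf); fcap <- logical(nf)
  for (i in seq_len(nf)) {
    hit <- FALSE
    for (t in grid) {
      ps <- sum(P[dmat[facilities$id[i], ] <= t])
      fpr <- if (ps > 0) S[i] / ps else Inf
      if (fpr <= cfg$fprt1) {
        fC[i] <- t; fF[i] <- fpr; hit <- TRUE; break
      }
    }
    if (!hit) {
      fC[i] <- cfg$t_max
      ps <- sum(P[dmat[facilities$id[i], ] <= cfg$t_max])
      fF[i] <- if (ps > 0) S[i] / ps else Inf
      fcap[i] <- TRUE
    }
  }
  pC <- numeric(np); pcap <- logical(np)
  for (j in seq_len(np)) {
    hit <- FALSE
    for (t in grid) {
      within <- dmat[, populations$id[j]] <= t
      tot <- if (any(within & is.infinite(fF))) Inf else
        sum(fF[within])
      if (tot >= cfg$fprt2) {
        pC[j] <- t; hit <- TRUE; break
      }
    }
    if (!hit) { pC[j] <- cfg$t_max; pcap[j] <- TRUE }
  }
  list(fC = fC, fF = fF, fcap = fcap, pC = pC, pcap = pcap)
}

oracle_ev2sfca <- function(facilities, populations, dmat, cfg,
                           wfun = function(d, C) as.numeric(d <= C)) {
  ct <- oracle_catchments(facilities, populations, dmat, cfg)
  nf <- nrow(facilities)
  np <- nrow(populations)
  elig <- function(i, j) {
    d <- dmat[facilities$id[i], populations$id[j]]
    if (!is.finite(d)) return(FALSE)
    switch(cfg$constraint_mode,
           mutual = d <= ct$fC[i] && d <= ct$pC[j],
           facility_side = d <= ct$fC[i],
           population_side = d <= ct$pC[j])
  }
  wC <- function(i, j, side) {
    if (cfg$weight_param == "symmetric_min") min(ct$fC[i], ct$pC[j])
    else if (side == "f") ct$fC[i] else ct$pC[j]
  }
  D <- numeric(nf)
  for (i in seq_len(nf)) {
    denom <- 0
    for (j in seq_len(np)) {
      if (elig(i, j))
        denom <- denom + populations$population[j] *
          wfun(dmat[facilities$id[i], populations$id[j]], wC(i, j, "f"))
    }
    D[i] <- if (denom > 0) facilities$capacity[i] / denom else 0
  }
  A <- numeric(np)
  for (j in seq_len(np)) {
    for (i in seq_len(nf)) {
      if (elig(i, j))
        A[j] <- A[j] + D[i] *
          wfun(dmat[facilities$id[i], populations$id[j]], wC(i, j, "p"))
    }
  }
  list(catchments = ct, D = D, A = A)
}
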