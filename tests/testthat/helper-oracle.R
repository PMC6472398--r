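# Independent brute-force reimplementation of the per-gene offset
# optimization: plain loops over candidate offsets and read positions,
# with the window test, closeness test and secondary criteria written out
# directly.  Deliberately shares no code with the package internals.

bruteOptimize <- function(track, ncCds, S, startRatio = 1/5) {
  deltas <- seq(0, S, by = 3)
  nCod <- ncCds / 3
  scoreAt <- function(d) {
    t <- 0
    for (j in seq_along(track$pos)) {
      p <- track$pos[j] + d
      if (p >= 4 && p <= ncCds) t <- t + track$count[j]
    }
    t
  }
  codonsAt <- function(d) {
    v <- numeric(nCod)
    for (j in seq_along(track$pos)) {
      p <- track$pos[j] + d
      if (p >= 1 && p <= ncCds) {
        k <- ceiling(p / 3)
        v[k] <- v[k] + track$count[j]
      }
    }
    v
  }
  passes <- function(v) {
    v[1] < startRatio * mean(v[2:4]) && v[2] > v[3]
  }
  ts <- sapply(deltas, scoreAt)
  if (length(unique(ts)) == 1) {
    return(list(delta = NA_integer_, status = "uninformative"))
  }
  avg <- 0
  for (j in seq_along(track$pos)) {
    if (track$pos[j] >= 1 - S && track$pos[j] <= ncCds)
      avg <- avg + track$count[j]
  }
  avg <- avg / nCod
  mx <- max(ts)
  tied <- deltas[ts == mx]
  if (length(tied) >= 2) {
    srt <- sort(tied, decreasing = TRUE)
    dp <- srt[1]; ds <- srt[2]
    pa <- passes(codonsAt(dp)); pb <- passes(codonsAt(ds))
    chosen <- if (pa && !pb) dp else if (pb && !pa) ds else min(dp, ds)
  } else {
    dp <- tied
    othersD <- deltas[deltas != dp]
    othersT <- ts[deltas != dp]
    t2 <- max(othersT)
    ds <- min(othersD[othersT == t2])
    if ((mx - t2) < avg) {
      pa <- passes(codonsAt(dp)); pb <- passes(codonsAt(ds))
      chosen <- if (pa && !pb) dp else if (pb && !pa) ds else dp
    } else chosen <- dp
  }
  list(delta = as.integer(chosen), status = "informative")
}

# random sparse track for property tests
randomTrack <- function(ncCds, S, nSpikes = 8, maxCount = 6) {
  span <- (1 - S - 5):(ncCds + 5)
  pos <- sort(sample(span, min(nSpikes, length(span))))
  count <- sample.int(maxCount, length(pos), replace = TRUE)
  list(pos = as.integer(pos), count = as.numeric(count))
}
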