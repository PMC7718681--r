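# Shared fixtures, built once per session and cached.
.fixture_cache <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (is.null(.fixture_cache[[key]])) .fixture_cache[[key]] <- force(expr)
  .fixture_cache[[key]]
}

# The default synthetic study cohort (100 subjects, seed 0) and its features.
cohort100 <- function() memo("c100", {
  simulateCohortData(defaultGeneratorConfig(nSubjects = 100, seed = 0))
})

features100 <- function() memo("f100", extractFeatures(cohort100()))

# A tiny two-subject cohort for I/O tests.
tinyCohort <- function() memo("tiny", {
  cfg <- defaultGeneratorConfig(nSubjects = 2, seed = 11)
  simulateCohortData(cfg)
})

# Pure-R recursive enumeration of the accumulated warping cost: explores
# every monotone path, no dynamic programming -- the independent oracle.
oracleDtw <- function(a, b) {
  rec <- function(i, j) {
    d <- abs(a[i] - b[j])
    if (i == 1 && j == 1) return(d)
    best <- Inf
    if (i > 1) best <- min(best, rec(i - 1, j))
    if (j > 1) best <- min(best, rec(i, j - 1))
    if (i > 1 && j > 1) best <- min(best, rec(i - 1, j - 1))
    d + best
  }
  rec(length(a), length(b))
}

# Direct double-loop fuzzy entropy, following the defining sums literally.
oracleFuzzyEntropy <- function(y, m = 3, r = 0.2 * sd(y)) {
  N <- length(y)
  phi <- function(mm) {
    nt <- N - m
    tot <- 0
    for (p in 1:nt) {
      Xp <- y[p:(p + mm - 1)]; Xp <- Xp - mean(Xp)
      acc <- 0
      for (q in 1:nt) {
        if (q == p) next
        Xq <- y[q:(q + mm - 1)]; Xq <- Xq - mean(Xq)
        d <- max(abs(Xp - Xq))
        acc <- acc + exp(-(d / r)^2)
      }
      tot <- tot + acc / (nt - 1)
    }
    tot / nt
  }
  log(phi(m)) - log(phi(m + 1))
}

# All sequences of the given length over {0, 1, 2}.
gridSequences <- function(len) {
  if (len == 1) return(lapply(0:2, identity))
  g <- expand.grid(rep(list(0:2), len))
  lapply(seq_len(nrow(g)), function(i) as.numeric(g[i, ]))
}
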