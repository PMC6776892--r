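## Independent oracles used across the suite. Each is a deliberately
## naive, brute-force evaluation of the quantity it checks, sharing no
## code path with the package implementation.

## Poisson upper tail by direct log-sum-exp term summation (lgamma-based,
## no ppois/pgamma). Accurate on the log scale far below underflow.
oraclePoissonLogTail <- function(k, lambda) {
  if (k <= 0) return(0)
  iMax <- max(k + 3000, ceiling(lambda + 20 * sqrt(lambda) + 100))
  i <- k:iMax
  lt <- i * log(lambda) - lambda - lgamma(i + 1)
  m <- max(lt)
  m + log(sum(exp(lt - m)))
}

## Literal step-up BH: q_i = min over {j : p_j >= p_i} of p_j * n / rank_j.
oracleBH <- function(p) {
  n <- length(p)
  r <- rank(p, ties.method = "max")
  vapply(p, function(pi) {
    min(1, min(p[p >= pi] * n / r[p >= pi]))
  }, numeric(1))
}

## Literal step-down Holm on the sorted vector.
oracleHolm <- function(p) {
  n <- length(p)
  o <- order(p)
  adj <- pmin(cummax((n - seq_len(n) + 1) * p[o]), 1)
  out <- numeric(n)
  out[o] <- adj
  out
}

## Two-tailed Fisher by full-margin enumeration with lchoose arithmetic.
oracleFisher <- function(a, b, cc, d) {
  m <- a + b; n <- cc + d; k <- a + cc
  if (k == 0 || k == m + n || m == 0 || n == 0) return(1)
  sup <- max(0, k - n):min(k, m)
  lp <- lchoose(m, sup) + lchoose(n, k - sup) - lchoose(m + n, k)
  pr <- exp(lp)
  pObs <- pr[sup == a]
  min(sum(pr[pr <= pObs * (1 + 1e-7)]), 1)
}

## Upper-tail hypergeometric by direct summation.
oracleHyperTail <- function(overlap, setSize, universeSize, hitSize) {
  ks <- overlap:min(setSize, hitSize)
  sum(exp(lchoose(setSize, ks) +
          lchoose(universeSize - setSize, hitSize - ks) -
          lchoose(universeSize, hitSize)))
}

## Exhaustive island enumeration on a window-count vector: eligibility by
## the summation oracle, runs by scanning, scores/p by the oracle tail,
## retention by the literal BH formula.
oracleIslands <- function(counts, lambda, eligibilityP, gapWindows,
                          islandFdr) {
  n <- length(counts)
  elig <- which(vapply(counts, function(k)
    oraclePoissonLogTail(k, lambda), 0) <= log(eligibilityP) &
    counts >= 1)
  if (!length(elig)) return(NULL)
  runs <- list()
  cur <- elig[1]
  for (e in elig[-1]) {
    if (e - cur[length(cur)] - 1 > gapWindows) {
      runs[[length(runs) + 1]] <- cur
      cur <- e
    } else cur <- c(cur, e)
  }
  runs[[length(runs) + 1]] <- cur
  df <- do.call(rbind, lapply(runs, function(r) {
    span <- r[1]:r[length(r)]
    data.frame(firstWindow = r[1], lastWindow = r[length(r)],
               fragmentCount = sum(counts[span]),
               score = sum(-vapply(counts[r], function(k)
                 oraclePoissonLogTail(k, lambda), 0)),
               logP = oraclePoissonLogTail(sum(counts[span]),
                                           lambda * length(span)))
  }))
  df$qValue <- oracleBH(exp(df$logP))
  df[df$qValue < islandFdr, , drop = FALSE]
}

## All-pairs TSS distance scan implementing the annotation rule naively.
oracleAnnotate <- function(siteStart1, siteEnd1, tssPos, geneIds,
                           maxDist = 5000) {
  inside <- tssPos >= siteStart1 & tssPos <= siteEnd1
  dist <- ifelse(inside, 0,
                 pmin(abs(tssPos - siteStart1), abs(tssPos - siteEnd1)))
  if (any(inside)) {
    keep <- inside
  } else {
    keep <- dist == min(dist)
  }
  keep <- keep & dist <= maxDist
  data.frame(geneId = geneIds[keep], distance = dist[keep])
}
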