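# Shared fixtures and independent brute-force oracles. Oracles deliberately
# use naive loops / enumeration so they share no code path with the package.

# Balanced phenotype table: nBreeds breeds x perBreed samples, half male.
toyPheno <- function(n = 16, nBreeds = 4, traits = list()) {
  perBreed <- n / nBreeds
  df <- data.frame(
    sample = sprintf("S%02d", seq_len(n)),
    sex = factor(rep(rep(c("M", "F"), length.out = perBreed), nBreeds)),
    breed = factor(rep(paste0("B", seq_len(nBreeds)), each = perBreed)),
    stringsAsFactors = FALSE)
  for (nm in names(traits)) df[[nm]] <- traits[[nm]]
  attr(df, "traits") <- names(traits)
  df
}

# Random samples x probesets matrix with dimnames.
toyExpr <- function(n, p, seed = 1, prefix = "ps") {
  set.seed(seed)
  m <- matrix(rnorm(n * p), n, p,
              dimnames = list(sprintf("S%02d", seq_len(n)),
                              sprintf("%s%03d", prefix, seq_len(p))))
  m
}

# Triple-loop unsigned TOM dissimilarity.
bruteTomDissimilarity <- function(a) {
  n <- nrow(a)
  d <- matrix(0, n, n)
  K <- numeric(n)
  for (i in seq_len(n)) K[i] <- sum(a[i, -i])
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    l <- 0
    for (u in seq_len(n)) if (u != i && u != j) l <- l + a[i, u] * a[u, j]
    tom <- (l + a[i, j]) / (min(K[i], K[j]) + 1 - a[i, j])
    d[i, j] <- 1 - tom
  }
  dimnames(d) <- dimnames(a)
  d
}

# Step-by-step GSEA running sum, written independently of the package.
bruteEnrichmentScore <- function(metrics, isHit, p) {
  N <- length(metrics)
  nh <- sum(isHit)
  denom <- sum(abs(metrics[isHit])^p)
  rs <- numeric(N); cur <- 0
  for (i in seq_len(N)) {
    cur <- if (isHit[i]) {
      cur + (if (denom > 0) abs(metrics[i])^p / denom else 1 / nh)
    } else cur - 1 / (N - nh)
    rs[i] <- cur
  }
  rs[which.max(abs(rs))]
}

# Exhaustive hypergeometric upper tail: draw nDraw from a universe of N with
# K marked; P(overlap >= kObs) by enumerating all C(N, nDraw) draws.
enumHyperUpper <- function(N, K, nDraw, kObs) {
  draws <- combn(N, nDraw)
  marked <- seq_len(K)
  hits <- apply(draws, 2, function(d) sum(d %in% marked))
  mean(hits >= kObs)
}

# sample() treats a length-1 numeric as 1:n; this does not.
resample1 <- function(v) if (length(v) == 1) v else sample(v, 1)

# Naive normal-equations least-squares residuals.
bruteResiduals <- function(X, y) {
  y - X %*% solve(t(X) %*% X) %*% t(X) %*% y
}
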