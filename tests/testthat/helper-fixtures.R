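# Small deterministic fixtures shared across tests.

randomMaps <- function(n = 16, seed = 1, pixelSize = 1.3) {
  set.seed(seed)
  PLIMaps(matrix(runif(n * n, 0.2, 1), n),
          matrix(runif(n * n, 0, pi), n),
          matrix(runif(n * n, 0.05, 0.95), n),
          pixelSize = pixelSize)
}

constantMaps <- function(n = 16, IT = 0.6, phi = 0.4, r = 0.5) {
  PLIMaps(matrix(IT, n, n), matrix(phi, n, n), matrix(r, n, n))
}

# two flat sections with identity transforms, all-foreground masks
tinyStack <- function(n = 64, S = 3, seed = 1) {
  set.seed(seed)
  secs <- lapply(seq_len(S), function(z) randomMaps(n, seed + z))
  msk <- lapply(seq_len(S), function(z) matrix(1L, n, n))
  PLIStack(secs, msk, sectionSpacing = 60)
}

# fast phantom used by module tests (small, fully featured)
testPhantom <- function(seed = 3, ...) {
  makePhantom(phantomSpec(height = 96L, width = 96L, nSections = 4L,
                          driftAmpPx = 1.5, jitterRotDeg = 2,
                          jitterTransPx = 1, ...), seed = seed)
}

angDiff <- function(a, b) {
  d <- abs(wrapDirection(a) - wrapDirection(b))
  pmin(d, pi - d)
}
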