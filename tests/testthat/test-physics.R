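test_that("forward signal model matches direct sinusoid evaluation", {
  # delta = pi/2 via thickness choice: t = lambda/(4*dn) at alpha = 0
  dn <- 1.5e-3; lam <- 550
  t_quarter <- (lam / 1000) / (4 * dn)
  f <- fiberField(matrix(0, 1, 1), matrix(0, 1, 1),
                  matrix(t_quarter, 1, 1), matrix(0, 1, 1),
                  birefringence = dn, wavelength = lam)
  s <- intensities(forwardProfiles(f))
  rho <- rhoAngles()
  # IT = 1 (no attenuation); at rho = 0 the sine term vanishes; the profile
  # maximum IT/2 * 2 = 1 is attained where sin(2 rho) = 1
  expect_equal(s[1, 1, 1], 0.5, tolerance = 1e-12)
  expect_equal(max(s[1, 1, ]), max(0.5 * (1 + sin(2 * rho))))
  # attenuation follows the exponential law
  f2 <- fiberField(matrix(0, 1, 1), matrix(0, 1, 1), matrix(100, 1, 1),
                   matrix(0.01, 1, 1), birefringence = dn)
  s2 <- intensities(forwardProfiles(f2))
  expect_equal(2 * mean(s2[1, 1, ]), exp(-1), tolerance = 1e-12)
  # full 9-angle profile by direct evaluation
  delta <- phaseRetardation(f2)[1, 1]
  expect_equal(s2[1, 1, ], exp(-1) / 2 * (1 + sin(2 * rho) * sin(delta)),
               tolerance = 1e-12)
})

test_that("forward model rejects invalid fiber parameters", {
  expect_error(fiberField(matrix(0, 1, 1), matrix(0, 1, 1),
                          matrix(-1, 1, 1), matrix(0.01, 1, 1)),
               "thickness")
  expect_error(fiberField(matrix(0, 1, 1), matrix(0, 1, 1),
                          matrix(1, 1, 1), matrix(-0.01, 1, 1)),
               "attenuation")
  expect_error(fiberField(matrix(0, 1, 1), matrix(2, 1, 1),
                          matrix(1, 1, 1), matrix(0.01, 1, 1)),
               "inclination")
})

test_that("harmonic retrieval inverts the forward model to machine precision", {
  set.seed(42)
  n <- 100  # 10^4 random pixels
  phi <- matrix(runif(n * n, 0, pi), n)
  alpha <- matrix(runif(n * n, 0, pi / 2), n)
  tt <- matrix(runif(n * n, 5, 80), n)
  mu <- matrix(runif(n * n, 0.002, 0.02), n)
  f <- fiberField(phi, alpha, tt, mu)
  m <- retrieveParameters(forwardProfiles(f))
  IT_true <- exp(-tt * mu)
  r_true <- abs(sin(phaseRetardation(f)))
  expect_lt(max(abs(transmittance(m) - IT_true)), 1e-9)
  expect_lt(max(abs(retardation(m) - r_true)), 1e-9)
  # direction is defined only where the modulation amplitude is nonzero
  ok <- r_true > 1e-3
  expect_lt(max(angDiff(direction(m), phi)[ok] * r_true[ok]), 1e-9)
})

test_that("retrieval handles specific profiles per the conventions", {
  # round trip at specific values: IT = 0.8, phi = 30 deg, r = 0.5
  maps0 <- PLIMaps(matrix(0.8, 2, 2), matrix(pi / 6, 2, 2),
                   matrix(0.5, 2, 2))
  m <- retrieveParameters(profilesFromMaps(maps0))
  expect_equal(transmittance(m)[1, 1], 0.8, tolerance = 1e-12)
  expect_equal(direction(m)[1, 1], pi / 6, tolerance = 1e-12)
  expect_equal(retardation(m)[1, 1], 0.5, tolerance = 1e-12)
  # constant profile: zero amplitude
  m2 <- retrieveParameters(PLISeries(array(0.4, c(2, 2, 9))))
  expect_equal(transmittance(m2)[1, 1], 0.8, tolerance = 1e-12)
  expect_equal(retardation(m2)[1, 1], 0)
  # direction near the wrap stays canonical: 170 deg, not -10 deg
  maps170 <- PLIMaps(matrix(1, 1, 1), matrix(170 * pi / 180, 1, 1),
                     matrix(0.5, 1, 1))
  m3 <- retrieveParameters(profilesFromMaps(maps170))
  expect_equal(direction(m3)[1, 1], 170 * pi / 180, tolerance = 1e-12)
  # all-zero profile: flagged undefined
  m4 <- retrieveParameters(PLISeries(array(0, c(1, 1, 9))))
  expect_true(m4@undefined[1, 1])
  expect_equal(retardation(m4)[1, 1], 0)
  expect_equal(direction(m4)[1, 1], 0)
})

test_that("profile mean equals half the transmittance for any pixel", {
  set.seed(7)
  for (i in 1:20) {
    maps <- randomMaps(4, seed = i)
    s <- intensities(profilesFromMaps(maps))
    expect_equal(2 * apply(s, c(1, 2), mean), transmittance(maps),
                 tolerance = 1e-12)
  }
})

test_that("inclination inversion recovers alpha on simulator output", {
  set.seed(11)
  n <- 40
  alpha <- matrix(runif(n * n, 0, pi / 2), n)
  phi <- matrix(runif(n * n, 0, pi), n)
  tt <- matrix(60, n, n)
  mu <- matrix(0.01, n, n)
  f <- fiberField(phi, alpha, tt, mu)
  m <- retrieveParameters(forwardProfiles(f))
  est <- estimateInclination(m, muRef = 0.01)
  # valid where delta stays on the principal branch (asin(r) = delta)
  delta <- phaseRetardation(f)
  ok <- delta < pi / 2 - 0.05
  err <- abs(est$alpha - alpha)[ok]
  expect_lt(max(err) * 180 / pi, 5)
  expect_equal(est$thickness[1, 1], 60, tolerance = 1e-6)
  # r = 0 means a vertical fiber
  m0 <- PLIMaps(matrix(0.5, 1, 1), matrix(0, 1, 1), matrix(0, 1, 1))
  expect_equal(estimateInclination(m0, muRef = 0.01)$alpha[1, 1], pi / 2)
})

test_that("channel encoding is wrap-continuous and invertible", {
  expect_equal(as.vector(channelEncode(constantMaps(1, 1, 0, 1))),
               c(1, 1, 0))
  expect_equal(as.vector(channelEncode(constantMaps(1, 1, pi / 2, 1))),
               c(1, -1, 0), tolerance = 1e-12)
  # phi -> pi- gives the same channels as phi = 0
  eps <- 1e-9
  a <- channelEncode(constantMaps(1, 1, 0, 0.8))
  b <- channelEncode(constantMaps(1, 1, pi - eps, 0.8))
  expect_lt(max(abs(a - b)), 1e-7)
  # decode inverts encode wherever r > 0
  maps <- randomMaps(12, seed = 5)
  dec <- channelDecode(channelEncode(maps))
  expect_equal(transmittance(dec), transmittance(maps), tolerance = 1e-12)
  expect_equal(retardation(dec), retardation(maps), tolerance = 1e-12)
  expect_lt(max(angDiff(direction(dec), direction(maps))), 1e-9)
})

test_that("channel encoding is 1-Lipschitz in retardation and direction", {
  set.seed(9)
  for (i in 1:200) {
    r1 <- runif(1); r2 <- runif(1)
    p1 <- runif(1, 0, pi); p2 <- runif(1, 0, pi)
    a <- channelEncode(constantMaps(1, 1, p1, r1))
    b <- channelEncode(constantMaps(1, 1, p2, r2))
    dist_feat <- sqrt(sum((a[, , 2:3] - b[, , 2:3])^2))
    # natural metric: |dr| + 2 * min(r) * angular distance of 2 phi
    dnat <- abs(r1 - r2) + 2 * min(r1, r2) * angDiff(p1, p2)
    expect_lte(dist_feat, dnat + 1e-9)
  }
})
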