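test_that("occupancy site likelihood matches hand arithmetic and enumeration", {
  # occupied for certain: psi = 1, p = (.5,.5), y = (1,0) -> 0.25
  expect_equal(occupancySiteLoglik(1, c(0.5, 0.5), c(1, 0)), log(0.25))
  # brute-force sum over z: 0.5*0.5 + 0.5 = 0.75
  expect_equal(occupancySiteLoglik(0.5, 0.5, 0), log(0.75))
  # explicit two-term sum, all-zero history
  psi <- 0.4; p <- c(0.3, 0.8, 0.6)
  oracle <- log(psi * prod(1 - p) + (1 - psi))
  expect_equal(occupancySiteLoglik(psi, p, c(0, 0, 0)), oracle,
               tolerance = 1e-12)
  # a detection under psi = 0 is impossible, not an exception
  expect_equal(occupancySiteLoglik(0, 0.5, 1), -Inf)
  # masked visits are skipped
  expect_equal(occupancySiteLoglik(0.5, c(0.5, 0.9), c(0, 1),
                                   mask = c(TRUE, FALSE)),
               log(0.75))
  expect_equal(occupancySiteLoglik(0.5, c(0.5, 0.9), c(0, NA)), log(0.75))
})

test_that("N-mixture site likelihood matches enumeration and limits", {
  # census limit p = 1 pins N = n
  expect_equal(nmixtureSiteLoglik(1, 1, 2, K = 50), dpois(2, 1, log = TRUE))
  # brute-force enumeration over N
  enum <- sum(sapply(0:50, function(N)
    dpois(N, 2) * prod(dbinom(c(1, 0), N, 0.5))))
  expect_equal(nmixtureSiteLoglik(2, c(0.5, 0.5), c(1, 0), K = 50),
               log(enum), tolerance = 1e-10)
  # empty limit: no individuals, nothing to miss
  expect_equal(nmixtureSiteLoglik(1e-12, c(0.5, 0.5), c(0, 0), K = 20), 0,
               tolerance = 1e-9)
  expect_error(nmixtureSiteLoglik(2, c(0.5), c(3), K = 2), "K")
})

test_that("model log-likelihood decomposes over species-site-year terms", {
  # all coefficients 0, one cell, one visit, y = 0: psi = p = 0.5
  y <- array(0, dim = c(1, 1, 1))
  md <- tinyData(y)
  expect_equal(modelLoglik(list(alpha = matrix(0), beta = matrix(0)), md),
               log(0.5 * 0.5 + 0.5))
  # random fixture: equals the sum of independent site-level calls
  set.seed(3)
  S <- 3; M <- 4; L <- 3
  y <- array(rbinom(S * M * L, 1, 0.4), dim = c(S, M, L))
  Xp <- cbind(Intercept = 1, x = rnorm(M))
  Xo <- array(rnorm(M * L * 2), dim = c(M, L, 2),
              dimnames = list(NULL, NULL, c("Intercept", "d")))
  Xo[, , 1] <- 1
  md <- tinyData(y, Xproc = Xp, Xobs = Xo)
  alpha <- matrix(rnorm(S * 2), S)
  beta <- matrix(rnorm(S * 2), S)
  total <- 0
  for (i in 1:S) for (m in 1:M) {
    psi <- plogis(sum(Xp[m, ] * alpha[i, ]))
    pv <- plogis(matrix(Xo[m, , ], L) %*% beta[i, ])
    total <- total + occupancySiteLoglik(psi, pv, y[i, m, ])
  }
  expect_equal(modelLoglik(list(alpha = alpha, beta = beta), md), total,
               tolerance = 1e-12)
  # masked (NA) site-year contributes nothing, whatever the parameters
  y2 <- y; y2[2, 3, ] <- NA
  md2 <- tinyData(y2, Xproc = Xp, Xobs = Xo)
  psi23 <- plogis(sum(Xp[3, ] * alpha[2, ]))
  p23 <- plogis(matrix(Xo[3, , ], L) %*% beta[2, ])
  expect_equal(modelLoglik(list(alpha = alpha, beta = beta), md2),
               total - occupancySiteLoglik(psi23, p23, y[2, 3, ]),
               tolerance = 1e-12)
  # dimension mismatch is an error
  expect_error(modelLoglik(list(alpha = alpha[, 1, drop = FALSE],
                                beta = beta), md), "dimension")
})

test_that("marginalized occupancy likelihood equals joint enumeration over z", {
  set.seed(11)
  for (rep in 1:3) {
    S <- 3; M <- 3; L <- 2
    y <- array(rbinom(S * M * L, 1, 0.5), dim = c(S, M, L))
    Xp <- cbind(Intercept = 1, x = rnorm(M))
    Xo <- array(1, dim = c(M, L, 1), dimnames = list(NULL, NULL, "Intercept"))
    md <- tinyData(y, Xproc = Xp, Xobs = Xo)
    alpha <- matrix(rnorm(S * 2, 0, 0.8), S)
    beta <- matrix(rnorm(S, 0, 0.8), S)
    psi <- plogis(alpha %*% t(Xp))
    pArr <- array(rep(plogis(beta), M * L), dim = c(S, M, L))
    expect_equal(modelLoglik(list(alpha = alpha, beta = beta), md),
                 occEnumLoglik(psi, pArr, y), tolerance = 1e-10)
  }
})

test_that("marginalized N-mixture likelihood equals enumeration over N <= 100", {
  set.seed(13)
  S <- 2; M <- 3; L <- 3
  y <- array(rpois(S * M * L, 1.5), dim = c(S, M, L))
  Xp <- cbind(Intercept = 1, x = rnorm(M))
  Xo <- array(1, dim = c(M, L, 1), dimnames = list(NULL, NULL, "Intercept"))
  md <- tinyData(y, responseKind = "abundance", Xproc = Xp, Xobs = Xo)
  alpha <- matrix(rnorm(S * 2, c(0.5, 0), 0.3), S)
  beta <- matrix(rnorm(S, 0, 0.5), S)
  lambda <- exp(alpha %*% t(Xp))
  pArr <- array(rep(plogis(beta), M * L), dim = c(S, M, L))
  expect_equal(modelLoglik(list(alpha = alpha, beta = beta), md, K = 100),
               nmixEnumLoglik(lambda, pArr, y, K = 100), tolerance = 1e-10)
})

test_that("the likelihood is invariant to species relabeling", {
  set.seed(17)
  S <- 4; M <- 5; L <- 3
  y <- array(rbinom(S * M * L, 1, 0.4), dim = c(S, M, L))
  md <- tinyData(y)
  alpha <- matrix(rnorm(S), S)
  beta <- matrix(rnorm(S), S)
  perm <- sample(S)
  mdP <- tinyData(y[perm, , , drop = FALSE])
  expect_equal(modelLoglik(list(alpha = alpha, beta = beta), md),
               modelLoglik(list(alpha = alpha[perm, , drop = FALSE],
                                beta = beta[perm, , drop = FALSE]), mdP),
               tolerance = 1e-12)
})

test_that("one visit and no covariates: the N-mixture margin is Poisson(lambda p)", {
  # thinning identity, checked against the marginal likelihood directly
  lambda <- 2.4; p <- 0.35
  for (n in 0:6)
    expect_equal(nmixtureSiteLoglik(lambda, p, n, K = 200),
                 dpois(n, lambda * p, log = TRUE), tolerance = 1e-10)
})

test_that("the likelihood surface peaks at the generating detection rate", {
  set.seed(23)
  nSites <- 400; L <- 6
  lambda <- 3; p <- 0.5
  N <- rpois(nSites, lambda)
  y <- array(rbinom(nSites * L, rep(N, L), p), dim = c(1, nSites, L))
  md <- tinyData(y, responseKind = "abundance")
  ll <- function(pv) modelLoglik(list(alpha = matrix(log(lambda)),
                                      beta = matrix(qlogis(pv))), md,
                                 K = max(y) + 60)
  expect_gt(ll(0.5), ll(0.35))
  expect_gt(ll(0.5), ll(0.65))
})
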