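# Independent brute-force oracles and tiny fixtures shared across tests.
# These deliberately avoid the package's marginalized-likelihood code paths:
# they enumerate the latent states directly.

# joint enumeration over ALL z configurations (species x site-years at once);
# exponential in cells, so keep fixtures <= ~9 cells
occEnumLoglik <- function(psi, pArr, y) {
  # psi: S x M, pArr: S x M x L, y: S x M x L
  S <- dim(y)[1L]; M <- dim(y)[2L]; L <- dim(y)[3L]
  cells <- expand.grid(rep(list(0:1), S * M))
  total <- 0
  for (r in seq_len(nrow(cells))) {
    zc <- matrix(as.numeric(cells[r, ]), S, M)
    pr <- 1
    for (i in seq_len(S)) for (m in seq_len(M)) {
      pz <- if (zc[i, m] == 1) psi[i, m] else 1 - psi[i, m]
      pdet <- 1
      for (l in seq_len(L)) {
        yv <- y[i, m, l]
        if (is.na(yv)) next
        pv <- pArr[i, m, l] * zc[i, m]
        pdet <- pdet * (if (yv == 1) pv else 1 - pv)
      }
      pr <- pr * pz * pdet
    }
    total <- total + pr
  }
  log(total)
}

# per-cell enumeration over N for the N-mixture marginal
nmixEnumLoglik <- function(lambda, pArr, y, K) {
  S <- dim(y)[1L]; M <- dim(y)[2L]; L <- dim(y)[3L]
  total <- 0
  for (i in seq_len(S)) for (m in seq_len(M)) {
    n <- y[i, m, ]
    keep <- !is.na(n)
    if (!any(keep)) next
    pr <- 0
    for (N in 0:K) {
      term <- dpois(N, lambda[i, m])
      for (l in which(keep)) {
        if (n[l] > N) { term <- 0; break }
        term <- term * dbinom(n[l], N, pArr[i, m, l])
      }
      pr <- pr + term
    }
    total <- total + log(pr)
  }
  total
}

# small hand-made CommunityData: S species, M site-years, L visits,
# intercept-only design (one coefficient each side)
tinyData <- function(y, responseKind = "occupancy", Xproc = NULL,
                     Xobs = NULL, siteIndex = NULL, siteYears = NULL) {
  S <- dim(y)[1L]; M <- dim(y)[2L]; L <- dim(y)[3L]
  if (is.null(Xproc))
    Xproc <- matrix(1, M, 1, dimnames = list(NULL, "Intercept"))
  if (is.null(Xobs))
    Xobs <- array(1, dim = c(M, L, 1),
                  dimnames = list(NULL, NULL, "Intercept"))
  if (is.null(siteIndex)) siteIndex <- seq_len(M)
  communityData(y, Xproc, Xobs, siteIndex, siteYears = siteYears,
                responseKind = responseKind)
}

# CommunityChains holding externally specified draws for given data
chainsFromParams <- function(data, alphaDraws, betaDraws, nChains = 1L) {
  # alphaDraws: list over draws of S x P matrices (or a single matrix,
  # replicated), likewise betaDraws
  if (is.matrix(alphaDraws)) alphaDraws <- list(alphaDraws)
  if (is.matrix(betaDraws)) betaDraws <- list(betaDraws)
  D <- max(length(alphaDraws), length(betaDraws))
  if (length(alphaDraws) == 1L) alphaDraws <- rep(alphaDraws, D)
  if (length(betaDraws) == 1L) betaDraws <- rep(betaDraws, D)
  sp <- data@species
  pn <- colnames(processMatrix(data))
  on <- dimnames(obsArray(data))[[3L]]
  cols <- c(as.vector(outer(sp, pn, function(s, c) sprintf("alpha[%s,%s]", s, c))),
            as.vector(outer(sp, on, function(s, c) sprintf("beta[%s,%s]", s, c))),
            sprintf("mu_alpha[%s]", pn), sprintf("sd_alpha[%s]", pn),
            sprintf("mu_beta[%s]", on), sprintf("sd_beta[%s]", on))
  mats <- lapply(seq_len(nChains), function(ch) {
    m <- matrix(0, D, length(cols), dimnames = list(NULL, cols))
    for (s in seq_len(D)) {
      m[s, seq_len(length(sp) * length(pn))] <- as.vector(alphaDraws[[s]])
      m[s, length(sp) * length(pn) + seq_len(length(sp) * length(on))] <-
        as.vector(betaDraws[[s]])
    }
    m
  })
  communityChains(mats, config = list(siteEffects = FALSE),
                  dataDims = list(species = sp,
                                  siteYears = data@siteYears,
                                  sites = data@sites,
                                  variant = data@variant,
                                  responseKind = data@responseKind))
}

# occupancy_draws built from a fixed z matrix (species x site-years)
fixedZDraws <- function(z, siteYears, nDraws = 1L) {
  arr <- array(NA_real_, dim = c(nDraws, nrow(z), ncol(z)))
  for (d in seq_len(nDraws)) arr[d, , ] <- z
  structure(list(z = arr, siteYears = siteYears,
                 species = rownames(z) %||% sprintf("sp%02d", seq_len(nrow(z)))),
            class = "occupancy_draws")
}

fixedNDraws <- function(N, siteYears, nDraws = 1L) {
  arr <- array(NA_real_, dim = c(nDraws, nrow(N), ncol(N)))
  for (d in seq_len(nDraws)) arr[d, , ] <- N
  structure(list(N = arr, siteYears = siteYears,
                 species = sprintf("sp%02d", seq_len(nrow(N)))),
            class = "abundance_draws")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# small simulated survey written to temp files for ingestion tests
writeTempSim <- function(sim) {
  dir <- withr::local_tempdir(.local_envir = parent.frame())
  writeSimulatedDataset(sim, dir)
}
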