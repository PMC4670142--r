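// Adaptive Metropolis-within-Gibbs sampler for hierarchical multispecies
// occupancy and N-mixture models with the latent state (z or N) marginalized
// out of the likelihood.  One call runs one chain; R's RNG is used throughout
// so set.seed() on the R side gives bit-reproducible chains.
//
// Model (species i, site-year row m with site k = site[m], visit l):
//   occupancy:  z ~ Bern(psi), y_l ~ Bern(p_l * z)
//   abundance:  N ~ Pois(lambda), n_l ~ Binom(N, p_l), N summed to K
//   link(process_m) = Xproc[m,] . alpha_i + u_k        (logit or log)
//   logit(p_{m,l})  = Xobs[m,l,] . beta_i
//   alpha_{i,j} ~ N(muA_j, sdA_j^2), beta ~ N(muB, sdB^2), u_k ~ N(0, sdSite^2)
// Priors: muA_j ~ N(0, muAPriorSd_j^2) (Gibbs); sdA_j, sdB_j, sdSite
// half-Cauchy (random-walk MH on the log scale).

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static const double ETA_CLAMP = 35.0;

static inline double clampEta(double x) {
  if (x > ETA_CLAMP) return ETA_CLAMP;
  if (x < -ETA_CLAMP) return -ETA_CLAMP;
  return x;
}

// log(1/(1+e^-x)) and log(1 - 1/(1+e^-x)), stable
static inline double logInvLogit(double x) { return -R::log1pexp(-x); }
static inline double log1mInvLogit(double x) { return -R::log1pexp(x); }

static inline double logHalfCauchy(double s, double scale) {
  // unnormalized: -log(1 + (s/scale)^2)
  double r = s / scale;
  return -std::log1p(r * r);
}

struct ModelArrays {
  arma::cube y;      // S x M x L (NaN = missing visit)
  arma::mat Xproc;   // M x P
  arma::cube Xobs;   // M x L x Q
  arma::mat XobsFlat; // (M*L) x Q, row m + M*l
  arma::uvec site;   // length M, 0-based
  int S, M, L, P, Q, nsite, K;
  bool nmix;
  bool siteEffects;
  std::vector<double> lgfact; // lgamma(k+1), k = 0..K
  arma::imat nObsMat;         // S x M observed-visit counts
  arma::imat allZeroMat;      // S x M all-zero flags (occupancy)
};

struct State {
  arma::mat A;   // S x P
  arma::mat B;   // S x Q
  arma::vec u;   // nsite
  arma::vec muA, sdA, muB, sdB;
  double sdSite;
  // caches
  arma::mat etaBase; // S x M : Xproc . alpha_i
  arma::mat detLog;  // occ: sum_l [y log p + (1-y) log(1-p)]; nmix: sC2
  arma::mat q0;      // occ: sum_l log(1-p); nmix: sB
  arma::mat llSite;  // S x M marginal log-lik per species-site-year
  arma::vec llSpec;  // row sums of llSite
};

// ---------- per-cell marginal log-likelihood ------------------------------

// occupancy cell, given logit-scale process eta and cached detection terms
static inline double occCellLL(double eta, double detLog, double q0,
                               bool allZero, int nObs) {
  if (nObs == 0) return 0.0;
  eta = clampEta(eta);
  double lpsi = logInvLogit(eta);
  if (!allZero) return lpsi + detLog;
  double l1mpsi = log1mInvLogit(eta);
  double a = lpsi + q0; // occupied, all missed
  double b = l1mpsi;    // truly absent
  double mx = (a > b) ? a : b;
  return mx + std::log(std::exp(a - mx) + std::exp(b - mx));
}

// N-mixture cell: sums over N = maxn..K. sB = sum_l log(1-p_l),
// sC2 = sum_l [ n_l (log p_l - log(1-p_l)) - lgfact[n_l] ]
static double nmixCellLL(const ModelArrays& d, int i, int m, double eta,
                         double sB, double sC2) {
  double loglam = clampEta(eta);
  double lam = std::exp(loglam);
  int maxn = 0, nObs = 0;
  for (int l = 0; l < d.L; ++l) {
    double yv = d.y(i, m, l);
    if (std::isnan(yv)) continue;
    ++nObs;
    if ((int)yv > maxn) maxn = (int)yv;
  }
  if (nObs == 0) return 0.0;
  double mx = -INFINITY;
  // two passes: compute terms, logsumexp
  std::vector<double> terms; terms.reserve(d.K - maxn + 1);
  for (int N = maxn; N <= d.K; ++N) {
    double t = N * loglam - lam - d.lgfact[N]; // log Poisson
    double binom = nObs * d.lgfact[N];         // sum_l lgfact[N]
    for (int l = 0; l < d.L; ++l) {
      double yv = d.y(i, m, l);
      if (std::isnan(yv)) continue;
      binom -= d.lgfact[N - (int)yv];
    }
    t += binom + N * sB + sC2;
    terms.push_back(t);
    if (t > mx) mx = t;
    // terms decay fast beyond the mode; stop once negligible
    if (N > lam + maxn + 10 && t < mx - 46.0) break;
  }
  double s = 0.0;
  for (double t : terms) s += std::exp(t - mx);
  return mx + std::log(s);
}

// recompute detection caches for one species/cell from B.row(i)
static inline void obsCaches(const ModelArrays& d, int i, int m,
                             const arma::rowvec& bi, double& detLog,
                             double& q0, bool& allZero, int& nObs) {
  detLog = 0.0; q0 = 0.0; allZero = true; nObs = 0;
  for (int l = 0; l < d.L; ++l) {
    double yv = d.y(i, m, l);
    if (std::isnan(yv)) continue;
    ++nObs;
    double etaO = 0.0;
    for (int q = 0; q < d.Q; ++q) etaO += d.Xobs(m, l, q) * bi[q];
    etaO = clampEta(etaO);
    double lp = logInvLogit(etaO), l1mp = log1mInvLogit(etaO);
    if (d.nmix) {
      // reuse slots: detLog <- sC2, q0 <- sB
      q0 += l1mp;
      detLog += yv * (lp - l1mp) - d.lgfact[(int)yv];
    } else {
      q0 += l1mp;
      detLog += (yv > 0.5) ? lp : l1mp;
      if (yv > 0.5) allZero = false;
    }
  }
}

// vectorized variant: one BLAS product for all cells of species i
static void obsCachesAll(const ModelArrays& d, int i, const arma::rowvec& bi,
                         arma::vec& det, arma::vec& q0) {
  arma::vec etaO = d.XobsFlat * bi.t(); // length M*L
  det.zeros(d.M); q0.zeros(d.M);
  for (int l = 0; l < d.L; ++l) {
    int off = l * d.M;
    for (int m = 0; m < d.M; ++m) {
      double yv = d.y(i, m, l);
      if (std::isnan(yv)) continue;
      double e = clampEta(etaO[off + m]);
      double lp = logInvLogit(e), l1mp = log1mInvLogit(e);
      if (d.nmix) {
        q0[m] += l1mp;
        det[m] += yv * (lp - l1mp) - d.lgfact[(int)yv];
      } else {
        q0[m] += l1mp;
        det[m] += (yv > 0.5) ? lp : l1mp;
      }
    }
  }
}

static inline double cellLL(const ModelArrays& d, const State& st, int i,
                            int m, double eta) {
  if (d.nmix) return nmixCellLL(d, i, m, eta, st.q0(i, m), st.detLog(i, m));
  return occCellLL(eta, st.detLog(i, m), st.q0(i, m),
                   d.allZeroMat(i, m) != 0, d.nObsMat(i, m));
}

static void refreshSpecies(const ModelArrays& d, State& st, int i) {
  double tot = 0.0;
  for (int m = 0; m < d.M; ++m) {
    double eta = st.etaBase(i, m) + (d.siteEffects ? st.u[d.site[m]] : 0.0);
    double ll = cellLL(d, st, i, m, eta);
    st.llSite(i, m) = ll;
    tot += ll;
  }
  st.llSpec[i] = tot;
}

// ---------- adaptive proposal bookkeeping ---------------------------------

struct BlockAdapt {
  arma::vec mean;
  arma::mat M2;        // sum of outer products of deviations
  arma::mat chol;      // proposal cholesky (lower)
  double logScale;
  long n;
  int acc, tries;
  void init(int dim, double s0) {
    mean.zeros(dim); M2.zeros(dim, dim);
    chol.eye(dim, dim); chol *= s0;
    logScale = 0.0; n = 0; acc = 0; tries = 0;
  }
  void accumulate(const arma::rowvec& x) {
    ++n;
    arma::vec xv = x.t();
    arma::vec delta = xv - mean;
    mean += delta / (double)n;
    M2 += delta * (xv - mean).t();
  }
  void refreshChol() {
    int dim = mean.n_elem;
    if (n < 3L * dim + 10L) return;
    arma::mat cv = M2 / (double)(n - 1);
    cv.diag() += 1e-6;
    arma::mat R;
    if (arma::chol(R, cv, "lower")) chol = (2.38 / std::sqrt((double)dim)) * R;
  }
};

struct ScalarAdapt {
  double logScale = std::log(0.25);
  int acc = 0, tries = 0;
};

static void batchAdjust(double& logScale, int& acc, int& tries, int batch,
                        double target) {
  if (tries == 0) return;
  double rate = (double)acc / (double)tries;
  double step = std::min(0.25, 1.0 / std::sqrt((double)batch));
  logScale += (rate > target) ? step : -step;
  acc = 0; tries = 0;
}

// ---------- main ----------------------------------------------------------

// [[Rcpp::export]]
List cpp_fit_chain(NumericVector yArr, arma::mat Xproc, NumericVector XobsArr,
                   IntegerVector siteIdx, int nsite, bool nmix, int K,
                   bool siteEffects, int nIter, int nBurn, int nThin,
                   int nSweeps,
                   arma::vec muAPriorSd, arma::vec muBPriorSd,
                   double sigmaScale, double siteScale, List init) {
  IntegerVector ydim = yArr.attr("dim");
  IntegerVector xdim = XobsArr.attr("dim");
  ModelArrays d;
  d.S = ydim[0]; d.M = ydim[1]; d.L = ydim[2];
  d.P = Xproc.n_cols; d.Q = xdim[2];
  d.nsite = nsite; d.K = nmix ? K : 1; d.nmix = nmix;
  d.siteEffects = siteEffects;
  d.y = arma::cube(yArr.begin(), d.S, d.M, d.L);
  d.Xproc = Xproc;
  d.Xobs = arma::cube(XobsArr.begin(), d.M, d.L, d.Q);
  d.XobsFlat = arma::mat(XobsArr.begin(), d.M * d.L, d.Q);
  d.site = arma::uvec(d.M);
  for (int m = 0; m < d.M; ++m) d.site[m] = siteIdx[m] - 1;
  d.lgfact.resize(d.K + 2);
  for (int k = 0; k <= d.K + 1; ++k) d.lgfact[k] = std::lgamma(k + 1.0);
  d.nObsMat.zeros(d.S, d.M);
  d.allZeroMat.ones(d.S, d.M);
  for (int i = 0; i < d.S; ++i)
    for (int m = 0; m < d.M; ++m)
      for (int l = 0; l < d.L; ++l) {
        double yv = d.y(i, m, l);
        if (std::isnan(yv)) continue;
        d.nObsMat(i, m) += 1;
        if (yv > 0.5) d.allZeroMat(i, m) = 0;
      }

  State st;
  st.A = as<arma::mat>(init["A"]);
  st.B = as<arma::mat>(init["B"]);
  st.u = as<arma::vec>(init["u"]);
  st.muA = as<arma::vec>(init["muA"]);
  st.sdA = as<arma::vec>(init["sdA"]);
  st.muB = as<arma::vec>(init["muB"]);
  st.sdB = as<arma::vec>(init["sdB"]);
  st.sdSite = as<double>(init["sdSite"]);

  st.etaBase = st.A * d.Xproc.t();
  st.detLog.zeros(d.S, d.M); st.q0.zeros(d.S, d.M);
  st.llSite.zeros(d.S, d.M); st.llSpec.zeros(d.S);
  for (int i = 0; i < d.S; ++i) {
    for (int m = 0; m < d.M; ++m) {
      double dl, q0v; bool az; int nb;
      obsCaches(d, i, m, st.B.row(i), dl, q0v, az, nb);
      st.detLog(i, m) = dl; st.q0(i, m) = q0v;
    }
    refreshSpecies(d, st, i);
  }

  std::vector<BlockAdapt> adA(d.S), adB(d.S);
  for (int i = 0; i < d.S; ++i) { adA[i].init(d.P, 0.1); adB[i].init(d.Q, 0.1); }
  std::vector<ScalarAdapt> adU(d.nsite), adSdA(d.P), adSdB(d.Q);
  ScalarAdapt adSdSite, adShift;

  // the ridge translation move needs an all-ones process column
  int interceptCol = -1;
  for (int j = 0; j < d.P && interceptCol < 0; ++j) {
    bool ones = true;
    for (int m = 0; m < d.M; ++m)
      if (d.Xproc(m, j) != 1.0) { ones = false; break; }
    if (ones) interceptCol = j;
  }

  int nKept = (nIter - nBurn) / nThin;
  int nParSpec = d.S * (d.P + d.Q);
  int nPar = nParSpec + (siteEffects ? d.nsite : 0) + 2 * (d.P + d.Q) +
             (siteEffects ? 1 : 0);
  arma::mat out(nKept, nPar);
  arma::vec outLL(nKept);
  int kept = 0, batch = 0;

  arma::vec newEta(d.M), newLL(d.M);
  arma::vec newDet(d.M), newQ0(d.M);

  for (int iter = 1; iter <= nIter; ++iter) {
    bool adapting = iter <= nBurn;

    // --- species blocks (alpha_i, beta_i), several sweeps per iteration ---
    for (int sweep = 0; sweep < nSweeps; ++sweep) {
      for (int i = 0; i < d.S; ++i) {
        arma::vec z(d.P);
        for (int j = 0; j < d.P; ++j) z[j] = R::norm_rand();
        arma::rowvec prop =
            st.A.row(i) +
            (std::exp(adA[i].logScale) * (adA[i].chol * z)).t();
        double dPrior = 0.0;
        for (int j = 0; j < d.P; ++j)
          dPrior += R::dnorm(prop[j], st.muA[j], st.sdA[j], 1) -
                    R::dnorm(st.A(i, j), st.muA[j], st.sdA[j], 1);
        newEta = d.Xproc * prop.t();
        double llNew = 0.0;
        for (int m = 0; m < d.M; ++m) {
          double eta = newEta[m] + (siteEffects ? st.u[d.site[m]] : 0.0);
          newLL[m] = cellLL(d, st, i, m, eta);
          llNew += newLL[m];
        }
        ++adA[i].tries;
        if (std::log(R::unif_rand()) < llNew - st.llSpec[i] + dPrior) {
          st.A.row(i) = prop;
          st.etaBase.row(i) = newEta.t();
          st.llSite.row(i) = newLL.t();
          st.llSpec[i] = llNew;
          ++adA[i].acc;
        }
        if (adapting) adA[i].accumulate(st.A.row(i));
      }

      for (int i = 0; i < d.S; ++i) {
        arma::vec z(d.Q);
        for (int j = 0; j < d.Q; ++j) z[j] = R::norm_rand();
        arma::rowvec prop =
            st.B.row(i) +
            (std::exp(adB[i].logScale) * (adB[i].chol * z)).t();
        double dPrior = 0.0;
        for (int j = 0; j < d.Q; ++j)
          dPrior += R::dnorm(prop[j], st.muB[j], st.sdB[j], 1) -
                    R::dnorm(st.B(i, j), st.muB[j], st.sdB[j], 1);
        obsCachesAll(d, i, prop, newDet, newQ0);
        double llNew = 0.0;
        for (int m = 0; m < d.M; ++m) {
          double eta = st.etaBase(i, m) + (siteEffects ? st.u[d.site[m]] : 0.0);
          double ll;
          if (d.nmix) ll = nmixCellLL(d, i, m, eta, newQ0[m], newDet[m]);
          else ll = occCellLL(eta, newDet[m], newQ0[m],
                              d.allZeroMat(i, m) != 0, d.nObsMat(i, m));
          newLL[m] = ll; llNew += ll;
        }
        ++adB[i].tries;
        if (std::log(R::unif_rand()) < llNew - st.llSpec[i] + dPrior) {
          st.B.row(i) = prop;
          st.detLog.row(i) = newDet.t();
          st.q0.row(i) = newQ0.t();
          st.llSite.row(i) = newLL.t();
          st.llSpec[i] = llNew;
          ++adB[i].acc;
        }
        if (adapting) adB[i].accumulate(st.B.row(i));
      }
    }

    // --- site random effects ---
    if (siteEffects) {
      for (int k = 0; k < d.nsite; ++k) {
        double propU = st.u[k] + std::exp(adU[k].logScale) * R::norm_rand();
        double dLL = 0.0;
        // collect per-(i,m) new values lazily; rows of this site only
        std::vector<std::pair<int, double>> rows;
        for (int m = 0; m < d.M; ++m) {
          if ((int)d.site[m] != k) continue;
          for (int i = 0; i < d.S; ++i) {
            double ll = cellLL(d, st, i, m, st.etaBase(i, m) + propU);
            dLL += ll - st.llSite(i, m);
            rows.push_back({i + m * d.S, ll});
          }
        }
        double dPrior = R::dnorm(propU, 0.0, st.sdSite, 1) -
                        R::dnorm(st.u[k], 0.0, st.sdSite, 1);
        ++adU[k].tries;
        if (std::log(R::unif_rand()) < dLL + dPrior) {
          st.u[k] = propU;
          for (auto& pr : rows) {
            int i = pr.first % d.S, m = pr.first / d.S;
            st.llSpec[i] += pr.second - st.llSite(i, m);
            st.llSite(i, m) = pr.second;
          }
          ++adU[k].acc;
        }
      }
      // translation move along the intercept/site-effect ridge: shift every
      // species intercept (and its hyper-mean) by +delta and every site
      // effect by -delta.  The likelihood and the alpha prior terms are
      // exactly invariant, so the ratio involves only the u and muA priors.
      if (interceptCol >= 0) {
        double delta = std::exp(adShift.logScale) * R::norm_rand();
        double lp = R::dnorm(st.muA[interceptCol] + delta, 0.0,
                             muAPriorSd[interceptCol], 1) -
                    R::dnorm(st.muA[interceptCol], 0.0,
                             muAPriorSd[interceptCol], 1);
        for (int k = 0; k < d.nsite; ++k)
          lp += R::dnorm(st.u[k] - delta, 0.0, st.sdSite, 1) -
                R::dnorm(st.u[k], 0.0, st.sdSite, 1);
        ++adShift.tries;
        if (std::log(R::unif_rand()) < lp) {
          st.u -= delta;
          st.A.col(interceptCol) += delta;
          st.muA[interceptCol] += delta;
          st.etaBase += delta; // intercept column is all ones
          ++adShift.acc;
        }
      }
      // sdSite: RW-MH on log scale, half-Cauchy prior
      {
        double ls = std::log(st.sdSite);
        double lsP = ls + std::exp(adSdSite.logScale) * R::norm_rand();
        double sP = std::exp(lsP);
        double lp = 0.0;
        for (int k = 0; k < d.nsite; ++k)
          lp += R::dnorm(st.u[k], 0.0, sP, 1) -
                R::dnorm(st.u[k], 0.0, st.sdSite, 1);
        lp += logHalfCauchy(sP, siteScale) - logHalfCauchy(st.sdSite, siteScale);
        lp += lsP - ls; // Jacobian
        ++adSdSite.tries;
        if (std::log(R::unif_rand()) < lp) { st.sdSite = sP; ++adSdSite.acc; }
      }
    }

    // --- group-scale move on one process column (funnel mixing) ---
    // alpha'_ij = mu_j + c (alpha_ij - mu_j), sd'_j = c sd_j.  The alpha
    // prior terms contribute exactly -S log c, the Jacobian (S+1) log c,
    // leaving log c + the half-Cauchy ratio + the likelihood change.
    {
      int j = (int)(R::unif_rand() * d.P);
      if (j >= d.P) j = d.P - 1;
      double lc = 0.3 * R::norm_rand();
      double c = std::exp(lc);
      arma::vec shiftI = (c - 1.0) * (st.A.col(j) - st.muA[j]); // per species
      arma::mat newEtaB = st.etaBase + shiftI * d.Xproc.col(j).t();
      double dll = 0.0;
      arma::mat newLLm(d.S, d.M);
      for (int i = 0; i < d.S; ++i)
        for (int m = 0; m < d.M; ++m) {
          double eta = newEtaB(i, m) + (siteEffects ? st.u[d.site[m]] : 0.0);
          newLLm(i, m) = cellLL(d, st, i, m, eta);
          dll += newLLm(i, m) - st.llSite(i, m);
        }
      double sP = c * st.sdA[j];
      double lacc = dll + logHalfCauchy(sP, sigmaScale) -
                    logHalfCauchy(st.sdA[j], sigmaScale) + lc;
      if (std::log(R::unif_rand()) < lacc) {
        st.A.col(j) += shiftI;
        st.sdA[j] = sP;
        st.etaBase = newEtaB;
        st.llSite = newLLm;
        st.llSpec = arma::sum(st.llSite, 1);
      }
    }

    // --- community hyper-parameters ---
    for (int j = 0; j < d.P; ++j) {
      // Gibbs for muA_j
      double prec = d.S / (st.sdA[j] * st.sdA[j]) +
                    1.0 / (muAPriorSd[j] * muAPriorSd[j]);
      double mean = arma::accu(st.A.col(j)) / (st.sdA[j] * st.sdA[j]) / prec;
      st.muA[j] = mean + R::norm_rand() / std::sqrt(prec);
      // MH for sdA_j
      double ls = std::log(st.sdA[j]);
      double lsP = ls + std::exp(adSdA[j].logScale) * R::norm_rand();
      double sP = std::exp(lsP);
      double lp = 0.0;
      for (int i = 0; i < d.S; ++i)
        lp += R::dnorm(st.A(i, j), st.muA[j], sP, 1) -
              R::dnorm(st.A(i, j), st.muA[j], st.sdA[j], 1);
      lp += logHalfCauchy(sP, sigmaScale) - logHalfCauchy(st.sdA[j], sigmaScale);
      lp += lsP - ls;
      ++adSdA[j].tries;
      if (std::log(R::unif_rand()) < lp) { st.sdA[j] = sP; ++adSdA[j].acc; }
    }
    for (int j = 0; j < d.Q; ++j) {
      double prec = d.S / (st.sdB[j] * st.sdB[j]) +
                    1.0 / (muBPriorSd[j] * muBPriorSd[j]);
      double mean = arma::accu(st.B.col(j)) / (st.sdB[j] * st.sdB[j]) / prec;
      st.muB[j] = mean + R::norm_rand() / std::sqrt(prec);
      double ls = std::log(st.sdB[j]);
      double lsP = ls + std::exp(adSdB[j].logScale) * R::norm_rand();
      double sP = std::exp(lsP);
      double lp = 0.0;
      for (int i = 0; i < d.S; ++i)
        lp += R::dnorm(st.B(i, j), st.muB[j], sP, 1) -
              R::dnorm(st.B(i, j), st.muB[j], st.sdB[j], 1);
      lp += logHalfCauchy(sP, sigmaScale) - logHalfCauchy(st.sdB[j], sigmaScale);
      lp += lsP - ls;
      ++adSdB[j].tries;
      if (std::log(R::unif_rand()) < lp) { st.sdB[j] = sP; ++adSdB[j].acc; }
    }

    // --- adaptation (burn-in only) ---
    if (adapting && iter % 50 == 0) {
      ++batch;
      for (int i = 0; i < d.S; ++i) {
        batchAdjust(adA[i].logScale, adA[i].acc, adA[i].tries, batch, 0.234);
        batchAdjust(adB[i].logScale, adB[i].acc, adB[i].tries, batch, 0.234);
        adA[i].refreshChol();
        adB[i].refreshChol();
      }
      for (int k = 0; k < d.nsite && siteEffects; ++k)
        batchAdjust(adU[k].logScale, adU[k].acc, adU[k].tries, batch, 0.44);
      for (int j = 0; j < d.P; ++j)
        batchAdjust(adSdA[j].logScale, adSdA[j].acc, adSdA[j].tries, batch, 0.44);
      for (int j = 0; j < d.Q; ++j)
        batchAdjust(adSdB[j].logScale, adSdB[j].acc, adSdB[j].tries, batch, 0.44);
      if (siteEffects) {
        batchAdjust(adSdSite.logScale, adSdSite.acc, adSdSite.tries, batch, 0.44);
        batchAdjust(adShift.logScale, adShift.acc, adShift.tries, batch, 0.44);
      }
    }

    // --- store ---
    if (iter > nBurn && (iter - nBurn) % nThin == 0) {
      int c = 0;
      for (int j = 0; j < d.P; ++j)
        for (int i = 0; i < d.S; ++i) out(kept, c++) = st.A(i, j);
      for (int j = 0; j < d.Q; ++j)
        for (int i = 0; i < d.S; ++i) out(kept, c++) = st.B(i, j);
      if (siteEffects)
        for (int k = 0; k < d.nsite; ++k) out(kept, c++) = st.u[k];
      for (int j = 0; j < d.P; ++j) out(kept, c++) = st.muA[j];
      for (int j = 0; j < d.P; ++j) out(kept, c++) = st.sdA[j];
      for (int j = 0; j < d.Q; ++j) out(kept, c++) = st.muB[j];
      for (int j = 0; j < d.Q; ++j) out(kept, c++) = st.sdB[j];
      if (siteEffects) out(kept, c++) = st.sdSite;
      outLL[kept] = arma::accu(st.llSpec);
      ++kept;
    }
    if (iter % 500 == 0) Rcpp::checkUserInterrupt();
  }

  // post-burn-in acceptance of the species blocks (counters were reset by the
  // last burn-in batch adjustment)
  double accA, accB, tA = 0, aA = 0, tB = 0, aB = 0;
  for (int i = 0; i < d.S; ++i) {
    aA += adA[i].acc; tA += adA[i].tries;
    aB += adB[i].acc; tB += adB[i].tries;
  }
  accA = tA > 0 ? aA / tA : NA_REAL;
  accB = tB > 0 ? aB / tB : NA_REAL;

  return List::create(_["draws"] = out, _["logLik"] = outLL,
                      _["acceptProcess"] = accA, _["acceptObs"] = accB);
}

// Conditional draws of latent abundance N for one species across all
// site-years and posterior draws.  lambda: M x D, pcube: M x L x D
// (detection probability, NaN where visit missing), y: M x L counts.
// [[Rcpp::export]]
arma::imat cpp_cond_N(arma::mat lambda, NumericVector pArr, arma::mat y,
                      int K) {
  IntegerVector pd = pArr.attr("dim");
  int M = pd[0], L = pd[1], D = pd[2];
  arma::cube p(pArr.begin(), M, L, D);
  arma::imat out(M, D);
  std::vector<double> lgfact(K + 2), terms(K + 1);
  for (int k = 0; k <= K + 1; ++k) lgfact[k] = std::lgamma(k + 1.0);
  for (int m = 0; m < M; ++m) {
    int maxn = 0, nObs = 0;
    for (int l = 0; l < L; ++l) {
      double yv = y(m, l);
      if (std::isnan(yv)) continue;
      ++nObs;
      if ((int)yv > maxn) maxn = (int)yv;
    }
    for (int s = 0; s < D; ++s) {
      double lam = lambda(m, s);
      double loglam = std::log(std::max(lam, 1e-300));
      double mx = -INFINITY;
      int hi = K;
      for (int N = maxn; N <= K; ++N) {
        double t = N * loglam - lam - lgfact[N];
        for (int l = 0; l < L; ++l) {
          double yv = y(m, l);
          if (std::isnan(yv)) continue;
          double pv = p(m, l, s);
          pv = std::min(std::max(pv, 1e-12), 1.0 - 1e-12);
          t += lgfact[N] - lgfact[(int)yv] - lgfact[N - (int)yv] +
               yv * std::log(pv) + (N - yv) * std::log1p(-pv);
        }
        terms[N] = t;
        if (t > mx) mx = t;
        if (N > lam + maxn + 10 && t < mx - 46.0) { hi = N; break; }
      }
      double tot = 0.0;
      for (int N = maxn; N <= hi; ++N) {
        terms[N] = std::exp(terms[N] - mx);
        tot += terms[N];
      }
      double ur = R::unif_rand() * tot, acc = 0.0;
      int pick = hi;
      for (int N = maxn; N <= hi; ++N) {
        acc += terms[N];
        if (ur <= acc) { pick = N; break; }
      }
      out(m, s) = pick;
    }
  }
  return out;
}
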