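// Atomic-prior Gibbs sampler for the non-negative factorization D ~ N(AP, Sigma).
//
// Two independent atomic domains, one for A (N x p) and one for P (p x M).
// Each atom lives in a matrix cell and carries a positive mass; a matrix
// entry is the sum of the masses of the atoms mapped to it.  Prior: atom
// count ~ Poisson(Lambda), cell uniform, mass ~ Exponential(rate lambda).
// Moves: birth, death, move, exchange; Metropolis-Hastings acceptance with
// the Gaussian likelihood, using incremental delta-chi^2 (rank-1 residual)
// updates.  The residual matrix is refreshed periodically to kill drift.

#include <Rcpp.h>
#include <random>
#include <vector>
#include <cmath>

using namespace Rcpp;

struct Atom {
  int cell;      // row-major cell index within the domain's matrix
  double mass;   // > 0
};

class Sampler {
public:
  int N, M, p;
  std::vector<double> D, S, prec2;       // N x M, column-major
  std::vector<double> A;                 // N x p, column-major
  std::vector<double> P;                 // p x M, column-major
  std::vector<double> R;                 // residual D - AP, N x M
  std::vector<Atom> atomsA, atomsP;
  double LambdaA, LambdaP;               // Poisson intensities (atom counts)
  double rateA, rateP;                   // exponential mass prior rates
  int maxAtoms;
  std::mt19937_64 rng;
  std::uniform_real_distribution<double> unif;

  Sampler(NumericMatrix D_, NumericMatrix S_, int p_,
          double alpha, double lambda_scale, int max_atoms,
          unsigned long long seed)
    : N(D_.nrow()), M(D_.ncol()), p(p_),
      D(D_.begin(), D_.end()), S(S_.begin(), S_.end()),
      prec2(N * M), A(N * p, 0.0), P(p * M, 0.0), R(D),
      maxAtoms(max_atoms), rng(seed), unif(0.0, 1.0) {
    double meanD = 0.0;
    for (int i = 0; i < N * M; ++i) {
      prec2[i] = 1.0 / (S[i] * S[i]);
      meanD += D[i];
    }
    meanD /= (double)(N * M);
    if (meanD <= 0) meanD = 1e-8;
    LambdaA = alpha * (double)N * (double)p;
    LambdaP = alpha * (double)p * (double)M;
    // mean atom mass = typical entry magnitude sqrt(mean(D)/p), scaled
    double massScale = std::sqrt(meanD / (double)p) * lambda_scale;
    rateA = 1.0 / massScale;
    rateP = 1.0 / massScale;
  }

  // Seed the atomic domains from initial factor matrices: one atom per
  // cell whose value exceeds a small fraction of the atom-mass scale.
  void initFrom(NumericMatrix A0, NumericMatrix P0) {
    double thrA = 0.01 / rateA, thrP = 0.01 / rateP;
    if (A0.nrow() == N && A0.ncol() == p) {
      for (int c = 0; c < N * p; ++c)
        if (A0[c] > thrA && (int)atomsA.size() < maxAtoms) {
          atomsA.push_back({c, A0[c]});
          A[c] = A0[c];
        }
    }
    if (P0.nrow() == p && P0.ncol() == M) {
      for (int c = 0; c < p * M; ++c)
        if (P0[c] > thrP && (int)atomsP.size() < maxAtoms) {
          atomsP.push_back({c, P0[c]});
          P[c] = P0[c];
        }
    }
    refreshResidual();
  }

  inline double runif01() { return unif(rng); }
  inline int rcell(int ncells) {
    int c = (int)(runif01() * ncells);
    return c >= ncells ? ncells - 1 : c;
  }
  inline double rexp_mass(double rate) {
    double u = runif01();
    if (u <= 0.0) u = 1e-300;
    return -std::log(u) / rate;
  }

  // quadratic coefficients of delta-chi^2(d) = a d^2 - 2 b d for a mass
  // change at one cell
  void quadA(int g, int k, double& a, double& b) {
    a = 0.0; b = 0.0;
    for (int j = 0; j < M; ++j) {
      double pkj = P[k + p * j];
      if (pkj == 0.0) continue;
      double w = prec2[g + N * j];
      a += pkj * pkj * w;
      b += R[g + N * j] * pkj * w;
    }
  }
  void quadP(int k, int j, double& a, double& b) {
    a = 0.0; b = 0.0;
    for (int g = 0; g < N; ++g) {
      double agk = A[g + N * k];
      if (agk == 0.0) continue;
      double w = prec2[g + N * j];
      a += agk * agk * w;
      b += R[g + N * j] * agk * w;
    }
  }

  // Sample from Normal(mu, sd) truncated to (0, inf); returns the draw and
  // fills its log-density. Falls back to the exponential prior when the
  // truncated normal has essentially no mass on (0, inf).
  bool rtrunc_norm(double mu, double sd, double& draw, double& logq) {
    double alpha = -mu / sd;                       // standardized zero
    double logZ = R::pnorm(alpha, 0.0, 1.0, 0, 1); // log P(X > alpha)
    if (!std::isfinite(logZ) || logZ < -600.0) return false;
    double u = runif01();
    if (u <= 0.0) u = 1e-300;
    double z = R::qnorm(std::log(u) + logZ, 0.0, 1.0, 0, 1);
    draw = mu + sd * z;
    if (draw <= 0.0 || !std::isfinite(draw)) return false;
    logq = R::dnorm(z, 0.0, 1.0, 1) - std::log(sd) - logZ;
    return true;
  }

  // log-density of the informed birth proposal at mass m for quadratic
  // (a, b); kind: true = truncated normal succeeded
  double logq_trunc(double mu, double sd, double m) {
    double alpha = -mu / sd;
    double logZ = R::pnorm(alpha, 0.0, 1.0, 0, 1);
    double z = (m - mu) / sd;
    return R::dnorm(z, 0.0, 1.0, 1) - std::log(sd) - logZ;
  }

  // Birth-proposal mixture for a cell with quadratic (a, b): with equal
  // probability draw the mass from the exponential prior (exploration) or
  // from the conditional likelihood-x-prior truncated normal (refinement).
  // Returns the draw; logq receives the mixture log-density, which the
  // death move also uses for the reverse direction.
  double draw_birth_mass(double a, double b, double rate, double& logq) {
    double mu = 0.0, sd = 0.0;
    bool haveTN = false;
    if (a > 0.0) {
      mu = (b - rate) / a;
      sd = 1.0 / std::sqrt(a);
      double logZ = R::pnorm(-mu / sd, 0.0, 1.0, 0, 1);
      haveTN = std::isfinite(logZ) && logZ >= -600.0;
    }
    double m;
    if (haveTN && runif01() < 0.5) {
      double lq;
      if (!rtrunc_norm(mu, sd, m, lq)) m = rexp_mass(rate);
    } else {
      m = rexp_mass(rate);
    }
    logq = mixture_logq(a, b, rate, m);
    return m;
  }

  double mixture_logq(double a, double b, double rate, double m) {
    double logPrior = std::log(rate) - rate * m;
    if (a <= 0.0) return logPrior;
    double mu = (b - rate) / a, sd = 1.0 / std::sqrt(a);
    double logZ = R::pnorm(-mu / sd, 0.0, 1.0, 0, 1);
    if (!std::isfinite(logZ) || logZ < -600.0) return logPrior;
    double logTN = logq_trunc(mu, sd, m);
    double hi = std::max(logPrior, logTN);
    return hi + std::log(0.5 * std::exp(logPrior - hi) +
                         0.5 * std::exp(logTN - hi));
  }

  // delta chi^2 for changing A[g, k] by d (single change)
  double dchi2A(int g, int k, double d) {
    double s = 0.0;
    for (int j = 0; j < M; ++j) {
      double pkj = P[k + p * j];
      if (pkj == 0.0) continue;
      double c = d * pkj;
      s += (c * c - 2.0 * R[g + N * j] * c) * prec2[g + N * j];
    }
    return s;
  }
  // delta chi^2 for changing P[k, j] by d
  double dchi2P(int k, int j, double d) {
    double s = 0.0;
    for (int g = 0; g < N; ++g) {
      double agk = A[g + N * k];
      if (agk == 0.0) continue;
      double c = d * agk;
      s += (c * c - 2.0 * R[g + N * j] * c) * prec2[g + N * j];
    }
    return s;
  }
  // joint delta chi^2 for two simultaneous A changes
  double dchi2A2(int g1, int k1, double d1, int g2, int k2, double d2) {
    if (g1 != g2) return dchi2A(g1, k1, d1) + dchi2A(g2, k2, d2);
    double s = 0.0;
    for (int j = 0; j < M; ++j) {
      double c = d1 * P[k1 + p * j] + d2 * P[k2 + p * j];
      if (c == 0.0) continue;
      s += (c * c - 2.0 * R[g1 + N * j] * c) * prec2[g1 + N * j];
    }
    return s;
  }
  double dchi2P2(int k1, int j1, double d1, int k2, int j2, double d2) {
    if (j1 != j2) return dchi2P(k1, j1, d1) + dchi2P(k2, j2, d2);
    double s = 0.0;
    for (int g = 0; g < N; ++g) {
      double c = d1 * A[g + N * k1] + d2 * A[g + N * k2];
      if (c == 0.0) continue;
      s += (c * c - 2.0 * R[g + N * j1] * c) * prec2[g + N * j1];
    }
    return s;
  }

  // apply a change to A[g, k] (updates matrix and residual row g)
  void applyA(int g, int k, double d) {
    A[g + N * k] += d;
    if (A[g + N * k] < 0) A[g + N * k] = 0;  // numeric guard
    for (int j = 0; j < M; ++j) R[g + N * j] -= d * P[k + p * j];
  }
  void applyP(int k, int j, double d) {
    P[k + p * j] += d;
    if (P[k + p * j] < 0) P[k + p * j] = 0;
    for (int g = 0; g < N; ++g) R[g + N * j] -= d * A[g + N * k];
  }

  void refreshResidual() {
    for (int j = 0; j < M; ++j)
      for (int g = 0; g < N; ++g) {
        double ap = 0.0;
        for (int k = 0; k < p; ++k) ap += A[g + N * k] * P[k + p * j];
        R[g + N * j] = D[g + N * j] - ap;
      }
  }

  double chi2() {
    double s = 0.0;
    for (int i = 0; i < N * M; ++i) s += R[i] * R[i] * prec2[i];
    return s;
  }

  inline bool accept(double logAlpha) {
    if (logAlpha >= 0.0) return true;
    double u = runif01();
    if (u <= 0.0) u = 1e-300;
    return std::log(u) < logAlpha;
  }

  // one single-atom MH step on the chosen domain
  void stepDomain(bool domA) {
    std::vector<Atom>& atoms = domA ? atomsA : atomsP;
    int ncells = domA ? N * p : p * M;
    double Lambda = domA ? LambdaA : LambdaP;
    double rate = domA ? rateA : rateP;
    int k = (int)atoms.size();

    bool birthdeath = runif01() < 0.5;
    if (birthdeath) {
      // Birth proposals draw the new atom's mass from the conditional
      // (likelihood x prior) truncated normal for its cell; deaths carry
      // the matching reverse-proposal density so the pair satisfies
      // detailed balance.  log(prior/proposal) terms are kept in logs.
      bool birth = (k == 0) ? true : (runif01() < 0.5);
      if (birth) {
        if (k >= maxAtoms) return;
        int cell = rcell(ncells);
        double a, b;
        if (domA) quadA(cell % N, cell / N, a, b);
        else quadP(cell % p, cell / p, a, b);
        double logq;
        double mass = draw_birth_mass(a, b, rate, logq);
        double dc = a * mass * mass - 2.0 * b * mass;
        double logPrior = std::log(rate) - rate * mass;
        double logAlpha = -0.5 * dc + std::log(Lambda / (double)(k + 1)) +
          logPrior - logq;
        if (k == 0) logAlpha -= std::log(2.0);  // forced birth at k = 0
        if (accept(logAlpha)) {
          if (domA) applyA(cell % N, cell / N, mass);
          else applyP(cell % p, cell / p, mass);
          atoms.push_back({cell, mass});
        }
      } else {
        int idx = rcell(k);
        int cell = atoms[idx].cell;
        double mass = atoms[idx].mass;
        double a, b;
        if (domA) quadA(cell % N, cell / N, a, b);
        else quadP(cell % p, cell / p, a, b);
        double dc = a * mass * mass + 2.0 * b * mass; // removal: d = -mass
        // reverse birth proposal density at the post-death state:
        // b' = b + a * mass
        double logq = mixture_logq(a, b + a * mass, rate, mass);
        double logPrior = std::log(rate) - rate * mass;
        double logAlpha = -0.5 * dc + std::log((double)k / Lambda) +
          logq - logPrior;
        if (k == 1) logAlpha += std::log(2.0);  // reverse birth is forced
        if (accept(logAlpha)) {
          if (domA) applyA(cell % N, cell / N, -mass);
          else applyP(cell % p, cell / p, -mass);
          atoms[idx] = atoms.back();
          atoms.pop_back();
        }
      }
    } else {
      if (k == 0) return;
      bool doMove = (k < 2) ? true : (runif01() < 0.5);
      if (doMove) {
        int idx = rcell(k);
        int oldCell = atoms[idx].cell;
        int newCell = rcell(ncells);
        if (newCell == oldCell) return;
        double mass = atoms[idx].mass;
        double dc = domA
          ? dchi2A2(oldCell % N, oldCell / N, -mass,
                    newCell % N, newCell / N, mass)
          : dchi2P2(oldCell % p, oldCell / p, -mass,
                    newCell % p, newCell / p, mass);
        if (accept(-0.5 * dc)) {
          if (domA) {
            applyA(oldCell % N, oldCell / N, -mass);
            applyA(newCell % N, newCell / N, mass);
          } else {
            applyP(oldCell % p, oldCell / p, -mass);
            applyP(newCell % p, newCell / p, mass);
          }
          atoms[idx].cell = newCell;
        }
      } else {
        // exchange: redistribute the summed mass of two atoms.  The
        // exponential prior is invariant under transfers that preserve the
        // sum, so both proposals accept on the likelihood alone:
        // (i) uniform re-split (the conditional of two iid exponentials
        // given their sum) for large rearrangements, (ii) a small
        // symmetric Gaussian transfer that lets equilibrated masses wiggle
        // at the scale of their posterior spread.
        int i1 = rcell(k);
        int i2 = rcell(k - 1);
        if (i2 >= i1) ++i2;
        double total = atoms[i1].mass + atoms[i2].mass;
        double newM1;
        if (runif01() < 0.5) {
          newM1 = runif01() * total;
        } else {
          double z = std::sqrt(-2.0 * std::log(std::max(runif01(), 1e-300))) *
            std::cos(6.283185307179586 * runif01());
          newM1 = atoms[i1].mass + 0.05 * total * z;
          if (newM1 <= 0.0 || newM1 >= total) return;  // reject: outside
        }
        double d1 = newM1 - atoms[i1].mass;
        double d2 = -d1;
        int c1 = atoms[i1].cell, c2 = atoms[i2].cell;
        if (c1 == c2) {  // same cell: matrix value unchanged
          atoms[i1].mass = newM1;
          atoms[i2].mass = total - newM1;
          return;
        }
        double dc = domA
          ? dchi2A2(c1 % N, c1 / N, d1, c2 % N, c2 / N, d2)
          : dchi2P2(c1 % p, c1 / p, d1, c2 % p, c2 / p, d2);
        if (accept(-0.5 * dc)) {
          if (domA) {
            applyA(c1 % N, c1 / N, d1);
            applyA(c2 % N, c2 / N, d2);
          } else {
            applyP(c1 % p, c1 / p, d1);
            applyP(c2 % p, c2 / p, d2);
          }
          atoms[i1].mass = newM1;
          atoms[i2].mass = total - newM1;
        }
      }
    }
  }

  // one iteration = a sweep of single-atom steps, scaled to the current
  // number of atoms so mixing keeps pace with model complexity
  void sweep() {
    int nsteps = (int)atomsA.size() + (int)atomsP.size() + 2;
    for (int s = 0; s < nsteps; ++s) stepDomain(runif01() < 0.5);
  }
};

// [[Rcpp::export(name = ".gaps_sampler")]]
List gaps_sampler(NumericMatrix D, NumericMatrix S, int n_patterns,
                  int n_burn, int n_sample, int thin,
                  double alpha, double lambda_scale, int max_atoms,
                  double seed, NumericMatrix A0, NumericMatrix P0) {
  Sampler smp(D, S, n_patterns, alpha, lambda_scale, max_atoms,
              (unsigned long long)seed);
  smp.initFrom(A0, P0);
  int N = smp.N, M = smp.M, p = smp.p;

  for (int it = 0; it < n_burn; ++it) {
    smp.sweep();
    if ((it + 1) % 100 == 0) smp.refreshResidual();
  }
  bool emptyAfterBurn = smp.atomsA.empty() || smp.atomsP.empty();

  std::vector<double> sumA(N * p, 0.0), sumA2(N * p, 0.0);
  std::vector<double> sumP(p * M, 0.0), sumP2(p * M, 0.0);
  std::vector<double> trace;
  int nrec = 0;
  for (int it = 0; it < n_sample; ++it) {
    smp.sweep();
    if ((it + 1) % 100 == 0) smp.refreshResidual();
    if ((it + 1) % thin == 0) {
      ++nrec;
      for (int i = 0; i < N * p; ++i) {
        sumA[i] += smp.A[i];
        sumA2[i] += smp.A[i] * smp.A[i];
      }
      for (int i = 0; i < p * M; ++i) {
        sumP[i] += smp.P[i];
        sumP2[i] += smp.P[i] * smp.P[i];
      }
      trace.push_back(smp.chi2());
    }
  }
  if (nrec == 0) stop("no iterations recorded; increase n_sample or lower thin");

  NumericMatrix Am(N, p), As(N, p), Pm(p, M), Ps(p, M);
  double corr = nrec > 1 ? (double)nrec / (double)(nrec - 1) : 0.0;
  for (int i = 0; i < N * p; ++i) {
    double mu = sumA[i] / nrec;
    Am[i] = mu;
    double v = (sumA2[i] / nrec - mu * mu) * corr;
    As[i] = v > 0 ? std::sqrt(v) : 0.0;
  }
  for (int i = 0; i < p * M; ++i) {
    double mu = sumP[i] / nrec;
    Pm[i] = mu;
    double v = (sumP2[i] / nrec - mu * mu) * corr;
    Ps[i] = v > 0 ? std::sqrt(v) : 0.0;
  }

  return List::create(
    _["A_mean"] = Am, _["A_sd"] = As,
    _["P_mean"] = Pm, _["P_sd"] = Ps,
    _["chi2_trace"] = NumericVector(trace.begin(), trace.end()),
    _["n_recorded"] = nrec,
    _["n_atoms_A"] = (int)smp.atomsA.size(),
    _["n_atoms_P"] = (int)smp.atomsP.size(),
    _["empty_after_burn"] = emptyAfterBurn);
}
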