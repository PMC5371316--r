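// Core numerics for the coarse-grained Calpha helix-coil model:
// chain energy, dRMSD, Metropolis Monte Carlo with Hamiltonian replica
// exchange over umbrella windows, and Kabsch RMSD.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static const double TWO_PI = 6.283185307179586476925286766559;

// ---------------------------------------------------------------------------
// splitmix64: small, fast, deterministic PRNG; one independent stream per
// replica, derived from the master seed by a fixed per-replica offset so
// adding windows never perturbs existing streams.
struct SplitMix {
  uint64_t s;
  explicit SplitMix(uint64_t seed) : s(seed) {}
  uint64_t next() {
    uint64_t z = (s += 0x9E3779B97F4A7C15ULL);
    z = (z ^ (z >> 30)) * 0xBF58476D1CE4E5B9ULL;
    z = (z ^ (z >> 27)) * 0x94D049BB133111EBULL;
    return z ^ (z >> 31);
  }
  double unif() { return (next() >> 11) * (1.0 / 9007199254740992.0); }
};

static SplitMix stream_for(uint64_t master, uint64_t offset) {
  SplitMix s(master * 0x2545F4914F6CDD1DULL + (offset + 1) * 0x9E3779B97F4A7C15ULL);
  for (int i = 0; i < 8; ++i) s.next();  // decorrelate nearby seeds
  return s;
}

// ---------------------------------------------------------------------------
// geometry helpers on an n x 3 coordinate matrix
static inline double dist(const arma::mat& X, int i, int j) {
  return arma::norm(X.row(i) - X.row(j), 2);
}

static double bond_angle(const arma::mat& X, int j) {  // angle at residue j
  arma::rowvec u = X.row(j - 1) - X.row(j);
  arma::rowvec v = X.row(j + 1) - X.row(j);
  double c = arma::dot(u, v) / (arma::norm(u, 2) * arma::norm(v, 2));
  if (c > 1.0) c = 1.0;
  if (c < -1.0) c = -1.0;
  return std::acos(c);
}

static double dihedral_angle(const arma::mat& X, int d) {
  // pseudo-dihedral over residues d, d+1, d+2, d+3 (0-based)
  arma::rowvec b1 = X.row(d + 1) - X.row(d);
  arma::rowvec b2 = X.row(d + 2) - X.row(d + 1);
  arma::rowvec b3 = X.row(d + 3) - X.row(d + 2);
  arma::rowvec n1 = arma::cross(b1, b2);
  arma::rowvec n2 = arma::cross(b2, b3);
  double x = arma::dot(n1, n2);
  double y = arma::dot(arma::cross(n1, n2), b2 / arma::norm(b2, 2));
  return std::atan2(y, x);
}

static inline double wrap_pi(double a) {
  while (a > M_PI) a -= TWO_PI;
  while (a < -M_PI) a += TWO_PI;
  return a;
}

// ---------------------------------------------------------------------------
// model energy in kBT units; parameters documented in the R wrappers
struct CgParams {
  arma::vec h;          // per-residue helical well depth (kBT)
  double eps_c;         // i,i+4+ contact depth (kBT)
  double rex;           // excluded radius (nm)
  double k_ang;         // angle force constant (kBT / rad^2)
  double ext_depth;     // extended-well depth (kBT)
  double theta0;        // reference pseudo-bond angle (rad)
  double phi_h;         // helical dihedral minimum (rad)
  double phi_e;         // extended dihedral minimum (rad)
  double sigma;         // dihedral well width (rad)
  double k_rep;         // soft-core repulsion strength (kBT)
  double r_contact;     // contact cutoff (nm)
};

static double chain_energy(const arma::mat& X, const CgParams& p) {
  const int n = X.n_rows;
  double e = 0.0;
  for (int j = 1; j < n - 1; ++j) {
    double d = bond_angle(X, j) - p.theta0;
    e += 0.5 * p.k_ang * d * d;
  }
  for (int d = 0; d + 3 < n; ++d) {
    double phi = dihedral_angle(X, d);
    double dh = wrap_pi(phi - p.phi_h);
    double de = wrap_pi(phi - p.phi_e);
    // well depth of dihedral d is the bias of its second residue (d+1)
    e += -p.h(d + 1) * std::exp(-dh * dh / (2.0 * p.sigma * p.sigma));
    e += -p.ext_depth * std::exp(-de * de / (2.0 * p.sigma * p.sigma));
  }
  for (int i = 0; i < n; ++i) {
    for (int j = i + 4; j < n; ++j) {
      double r = dist(X, i, j);
      if (r < p.r_contact) e += -p.eps_c;
      if (r < p.rex) {
        double t = 1.0 - r / p.rex;
        e += p.k_rep * t * t;
      }
    }
  }
  // numerical guard against singular geometry during sampling: spec-level
  // energies are only defined away from overlaps
  for (int i = 0; i < n; ++i)
    for (int j = i + 2; j < n; ++j)
      if (dist(X, i, j) < 0.05) e += 1.0e6;
  return e;
}

static CgParams unpack_params(const List& par) {
  CgParams p;
  p.h = as<arma::vec>(par["helix_bias"]);
  p.eps_c = as<double>(par["contact_strength"]);
  p.rex = as<double>(par["excluded_radius"]);
  p.k_ang = as<double>(par["k_angle"]);
  p.ext_depth = as<double>(par["extended_depth"]);
  p.theta0 = as<double>(par["theta0"]);
  p.phi_h = as<double>(par["phi_helix"]);
  p.phi_e = as<double>(par["phi_extended"]);
  p.sigma = as<double>(par["dihedral_width"]);
  p.k_rep = as<double>(par["k_repulsion"]);
  p.r_contact = as<double>(par["contact_cutoff"]);
  return p;
}

// [[Rcpp::export(name = ".chain_energy_cpp")]]
double chain_energy_cpp(const arma::mat& X, const List& par) {
  return chain_energy(X, unpack_params(par));
}

// [[Rcpp::export(name = ".dihedrals_cpp")]]
arma::vec dihedrals_cpp(const arma::mat& X) {
  const int n = X.n_rows;
  arma::vec out(std::max(0, n - 3));
  for (int d = 0; d + 3 < n; ++d) out(d) = dihedral_angle(X, d);
  return out;
}

// [[Rcpp::export(name = ".bond_angles_cpp")]]
arma::vec bond_angles_cpp(const arma::mat& X) {
  const int n = X.n_rows;
  arma::vec out(std::max(0, n - 2));
  for (int j = 1; j < n - 1; ++j) out(j - 1) = bond_angle(X, j);
  return out;
}

// ---------------------------------------------------------------------------
// dRMSD over a pair list (0-based indices), reference distances d0
static double drmsd_val(const arma::mat& X, const arma::imat& pairs,
                        const arma::vec& d0) {
  const int N = pairs.n_rows;
  double ss = 0.0;
  for (int i = 0; i < N; ++i) {
    double d = dist(X, pairs(i, 0), pairs(i, 1)) - d0(i);
    ss += d * d;
  }
  return std::sqrt(ss / N);
}

// [[Rcpp::export(name = ".drmsd_cpp")]]
double drmsd_cpp(const arma::mat& X, const arma::imat& pairs, const arma::vec& d0) {
  return drmsd_val(X, pairs, d0);
}

// ---------------------------------------------------------------------------
// MC moves: local dihedral pivots (rotate the chain tail about a bond axis)
// and crankshaft rotations (rotate an interior stretch about the axis
// through its two hinge residues). Both are symmetric proposals.
static void rotate_about_axis(arma::mat& X, int first, int last,
                              const arma::rowvec& p0, const arma::rowvec& axis,
                              double angle) {
  arma::rowvec u = axis / arma::norm(axis, 2);
  double c = std::cos(angle), s = std::sin(angle);
  for (int i = first; i <= last; ++i) {
    arma::rowvec v = X.row(i) - p0;
    arma::rowvec vr = v * c + arma::cross(u, v) * s + u * arma::dot(u, v) * (1.0 - c);
    X.row(i) = p0 + vr;
  }
}

struct Replica {
  arma::mat X;
  double E;        // model energy (kBT)
  double R;        // current dRMSD (nm)
  SplitMix rng;
  long accepted = 0, attempted = 0;
  Replica(const arma::mat& X0, SplitMix r) : X(X0), E(0), R(0), rng(r) {}
};

// bias energy in kBT
static inline double bias_e(double R, double R0, double k0) {
  double d = R - R0;
  return 0.5 * k0 * d * d;
}

// One MC sweep: one attempted pivot per dihedral plus n_crank crankshafts.
static void mc_sweep(Replica& rep, const CgParams& p, const arma::imat& pairs,
                     const arma::vec& d0, double R0, double k0,
                     double max_pivot, double max_crank, int n_crank) {
  const int n = rep.X.n_rows;
  for (int d = 0; d + 3 < n; ++d) {
    arma::mat Xp = rep.X;
    double ang = (2.0 * rep.rng.unif() - 1.0) * max_pivot;
    rotate_about_axis(Xp, d + 3, n - 1, Xp.row(d + 1),
                      Xp.row(d + 2) - Xp.row(d + 1), ang);
    double Ep = chain_energy(Xp, p);
    double Rp = drmsd_val(Xp, pairs, d0);
    double dE = (Ep - rep.E) + bias_e(Rp, R0, k0) - bias_e(rep.R, R0, k0);
    rep.attempted++;
    if (dE <= 0.0 || rep.rng.unif() < std::exp(-dE)) {
      rep.X = Xp; rep.E = Ep; rep.R = Rp; rep.accepted++;
    }
  }
  for (int c = 0; c < n_crank; ++c) {
    int gap = 2 + (int)(rep.rng.unif() * 3.0);      // hinge separation 2..4
    if (gap > n - 1) gap = n - 1;
    int i = (int)(rep.rng.unif() * (n - gap));
    int j = i + gap;
    if (j - i < 2) continue;
    arma::mat Xp = rep.X;
    double ang = (2.0 * rep.rng.unif() - 1.0) * max_crank;
    rotate_about_axis(Xp, i + 1, j - 1, Xp.row(i), Xp.row(j) - Xp.row(i), ang);
    double Ep = chain_energy(Xp, p);
    double Rp = drmsd_val(Xp, pairs, d0);
    double dE = (Ep - rep.E) + bias_e(Rp, R0, k0) - bias_e(rep.R, R0, k0);
    rep.attempted++;
    if (dE <= 0.0 || rep.rng.unif() < std::exp(-dE)) {
      rep.X = Xp; rep.E = Ep; rep.R = Rp; rep.accepted++;
    }
  }
}

// [[Rcpp::export(name = ".mc_run_cpp")]]
List mc_run_cpp(const arma::mat& X0, const List& par,
                const arma::imat& pairs, const arma::vec& d0,
                const arma::vec& R0s, const arma::vec& k0s_kBT,
                int n_sweeps, int exchange_interval, int record_every,
                double seed, double max_pivot, double max_crank, int n_crank) {
  CgParams p = unpack_params(par);
  const int W = R0s.n_elem;
  const int n = X0.n_rows;
  uint64_t master = (uint64_t)seed;

  std::vector<Replica> reps;
  reps.reserve(W);
  for (int w = 0; w < W; ++w) {
    Replica r(X0, stream_for(master, (uint64_t)w));
    r.E = chain_energy(r.X, p);
    r.R = drmsd_val(r.X, pairs, d0);
    reps.push_back(r);
  }
  SplitMix xrng = stream_for(master, 0x10000000ULL);  // fixed exchange stream

  const int n_rec = n_sweeps / record_every;
  arma::mat Rmat(n_rec, W), Emat(n_rec, W);
  IntegerVector rec_step(n_rec);
  // conformations: per window an (n_rec x n x 3) array
  List confs(W);
  std::vector<arma::cube> cubes(W, arma::cube(n_rec, n, 3));

  std::vector<int> xs_sweep, xs_a, xs_b, xs_acc;
  std::vector<double> xs_delta;
  int exch_round = 0;

  for (int s = 1; s <= n_sweeps; ++s) {
    for (int w = 0; w < W; ++w)
      mc_sweep(reps[w], p, pairs, d0, R0s(w), k0s_kBT(w),
               max_pivot, max_crank, n_crank);

    if (W > 1 && exchange_interval > 0 && s % exchange_interval == 0) {
      int start = exch_round % 2;  // alternate even/odd neighbour pairs
      for (int a = start; a + 1 < W; a += 2) {
        int b = a + 1;
        double delta = bias_e(reps[b].R, R0s(a), k0s_kBT(a)) +
                       bias_e(reps[a].R, R0s(b), k0s_kBT(b)) -
                       bias_e(reps[a].R, R0s(a), k0s_kBT(a)) -
                       bias_e(reps[b].R, R0s(b), k0s_kBT(b));
        bool acc = (delta <= 0.0) || (xrng.unif() < std::exp(-delta));
        if (acc) {
          std::swap(reps[a].X, reps[b].X);
          std::swap(reps[a].E, reps[b].E);
          std::swap(reps[a].R, reps[b].R);
        }
        xs_sweep.push_back(s); xs_a.push_back(a + 1); xs_b.push_back(b + 1);
        xs_delta.push_back(delta); xs_acc.push_back(acc ? 1 : 0);
      }
      exch_round++;
    }

    if (s % record_every == 0) {
      int k = s / record_every - 1;
      rec_step[k] = s;
      for (int w = 0; w < W; ++w) {
        Rmat(k, w) = reps[w].R;
        Emat(k, w) = reps[w].E;
        for (int i = 0; i < n; ++i)
          for (int j = 0; j < 3; ++j) cubes[w](k, i, j) = reps[w].X(i, j);
      }
    }
  }

  NumericVector acc_rate(W);
  for (int w = 0; w < W; ++w)
    acc_rate[w] = reps[w].attempted ? (double)reps[w].accepted / reps[w].attempted : NA_REAL;
  for (int w = 0; w < W; ++w) confs[w] = wrap(cubes[w]);

  return List::create(
    _["R"] = Rmat, _["energy"] = Emat, _["step"] = rec_step,
    _["conformations"] = confs, _["acceptance"] = acc_rate,
    _["exchange"] = List::create(
      _["sweep"] = wrap(xs_sweep), _["window_a"] = wrap(xs_a),
      _["window_b"] = wrap(xs_b), _["delta"] = wrap(xs_delta),
      _["accepted"] = wrap(xs_acc)));
}

// ---------------------------------------------------------------------------
// Kabsch least-RMSD superposition (proper rotations only)
// [[Rcpp::export(name = ".kabsch_rmsd_cpp")]]
double kabsch_rmsd_cpp(const arma::mat& A, const arma::mat& B) {
  arma::mat Ac = A.each_row() - arma::mean(A, 0);
  arma::mat Bc = B.each_row() - arma::mean(B, 0);
  arma::mat H = Ac.t() * Bc;
  arma::mat U, V;
  arma::vec s;
  arma::svd(U, s, V, H);
  arma::mat D = arma::eye(3, 3);
  if (arma::det(V * U.t()) < 0) D(2, 2) = -1.0;  // proper rotation only
  arma::mat R = V * D * U.t();
  arma::mat diff = Ac * R.t() - Bc;
  return std::sqrt(arma::accu(arma::square(diff)) / A.n_rows);
}

// [[Rcpp::export(name = ".pairwise_rmsd_cpp")]]
arma::mat pairwise_rmsd_cpp(const List& structures) {
  const int N = structures.size();
  std::vector<arma::mat> xs(N);
  for (int i = 0; i < N; ++i) xs[i] = as<arma::mat>(structures[i]);
  arma::mat D(N, N, arma::fill::zeros);
  for (int i = 0; i < N; ++i)
    for (int j = i + 1; j < N; ++j)
      D(i, j) = D(j, i) = kabsch_rmsd_cpp(xs[i], xs[j]);
  return D;
}
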