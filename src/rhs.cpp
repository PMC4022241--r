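// Compiled right-hand side of the isotopomer labeling ODE system.
//
// The state vector concatenates the IDVs of all tracked pools (balanced
// intracellular, dissolved CO2, dynamic extracellular). Every directed
// reaction-product pair is a "term": flux(t) * w * (M %*% u - IDV_target),
// where u is the IDV of the mapped substrate pool(s) (Kronecker joint for
// condensations, slot 1 fastest) and M the isotopomer mapping matrix.
// Pool concentrations: constant sizes for intracellular pools, closed-form
// batch profiles (exponential growth, optional first-order degradation)
// for extracellular pools. Transport terms into extracellular pools are
// scaled by the cell volumetric concentration Xconc(t) = Xc0 e^{mu t}.

#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

struct Term {
  int target, rxn, dir, gain;
  double w;
  std::vector<int> inputs;
  // sparse triplets of the mapping matrix (most maps are permutations)
  std::vector<int> mr, mc;
  std::vector<double> mv;
  int nrow, ncol;
};

struct Plan {
  int n_state = 0, n_pool = 0, n_rxn = 0;
  std::vector<int> offset, size, ctype; // per pool; ctype 0 const,1 sized,2 dynamic
  std::vector<std::vector<double>> const_idv;
  std::vector<Term> terms;
  // per-simulation parameters
  std::vector<double> vnet;
  std::vector<int> revkind; // 0 none, 1 const, 2 hyperbolic, 3 exponential
  std::vector<double> revp1, revp2;
  std::vector<double> pool_par;          // size (ctype 1) or C0 (ctype 2)
  std::vector<double> dyn_vnet, dyn_kd;  // per pool, used when ctype 2
  double mu = 0, Xc0 = 0;
  // work buffers
  std::vector<double> acc, vsum, joint, mu_out;
};

static double dirflux(const Plan& p, int rxn, int dir, double t) {
  double v = p.vnet[rxn];
  int kind = p.revkind[rxn];
  if (kind == 0) return dir == 0 ? (v > 0 ? v : 0.0) : 0.0;
  double rev;
  switch (kind) {
    case 1: rev = p.revp1[rxn]; break;
    case 2: rev = p.revp1[rxn] / (t + p.revp2[rxn]); break;
    default: rev = p.revp1[rxn] * std::exp(p.revp2[rxn] * t); break;
  }
  if (rev < 0) rev = 0;
  double base = dir == 0 ? (v > 0 ? v : 0.0) : (v < 0 ? -v : 0.0);
  return base + std::fabs(v) * rev;
}

static double pool_conc(const Plan& p, int pool, double t) {
  if (p.ctype[pool] == 2) {
    double C0 = p.pool_par[pool], vd = p.dyn_vnet[pool], kd = p.dyn_kd[pool];
    double C;
    if (kd == 0.0)
      C = C0 + vd * p.Xc0 / p.mu * std::expm1(p.mu * t);
    else
      C = std::exp(-kd * t) *
          (C0 + vd * p.Xc0 * std::expm1((p.mu + kd) * t) / (p.mu + kd));
    return C > 1e-12 ? C : 1e-12;
  }
  return p.pool_par[pool];
}

// [[Rcpp::export]]
SEXP sim_plan_build(List spec) {
  Plan* p = new Plan();
  p->n_state = as<int>(spec["n_state"]);
  p->offset = as<std::vector<int>>(spec["offset"]);
  p->size = as<std::vector<int>>(spec["size"]);
  p->ctype = as<std::vector<int>>(spec["ctype"]);
  p->n_pool = p->offset.size();
  List cidv = spec["const_idv"];
  p->const_idv.resize(p->n_pool);
  for (int i = 0; i < p->n_pool; ++i) {
    if (p->ctype[i] == 0) p->const_idv[i] = as<std::vector<double>>(cidv[i]);
  }
  List terms = spec["terms"];
  int maxjoint = 1;
  for (int i = 0; i < terms.size(); ++i) {
    List tl = terms[i];
    Term tm;
    tm.target = as<int>(tl["target"]);
    tm.rxn = as<int>(tl["rxn"]);
    tm.dir = as<int>(tl["dir"]);
    tm.gain = as<int>(tl["gain"]);
    tm.w = as<double>(tl["w"]);
    tm.inputs = as<std::vector<int>>(tl["inputs"]);
    NumericMatrix M = tl["M"];
    tm.nrow = M.nrow(); tm.ncol = M.ncol();
    for (int c = 0; c < tm.ncol; ++c)
      for (int r = 0; r < tm.nrow; ++r)
        if (M(r, c) != 0) {
          tm.mr.push_back(r); tm.mc.push_back(c); tm.mv.push_back(M(r, c));
        }
    if (tm.ncol > maxjoint) maxjoint = tm.ncol;
    p->terms.push_back(tm);
  }
  p->n_rxn = as<int>(spec["n_rxn"]);
  p->vnet.assign(p->n_rxn, 0.0);
  p->revkind.assign(p->n_rxn, 0);
  p->revp1.assign(p->n_rxn, 0.0);
  p->revp2.assign(p->n_rxn, 0.0);
  p->pool_par.assign(p->n_pool, 1.0);
  p->dyn_vnet.assign(p->n_pool, 0.0);
  p->dyn_kd.assign(p->n_pool, 0.0);
  p->acc.assign(p->n_state, 0.0);
  p->vsum.assign(p->n_pool, 0.0);
  p->joint.assign(maxjoint, 0.0);
  XPtr<Plan> ptr(p, true);
  return ptr;
}

// [[Rcpp::export]]
void sim_plan_set_params(SEXP plan, NumericVector vnet, IntegerVector revkind,
                         NumericVector revp1, NumericVector revp2,
                         NumericVector pool_par, NumericVector dyn_vnet,
                         NumericVector dyn_kd, double mu, double Xc0) {
  XPtr<Plan> p(plan);
  p->vnet.assign(vnet.begin(), vnet.end());
  p->revkind.assign(revkind.begin(), revkind.end());
  p->revp1.assign(revp1.begin(), revp1.end());
  p->revp2.assign(revp2.begin(), revp2.end());
  p->pool_par.assign(pool_par.begin(), pool_par.end());
  p->dyn_vnet.assign(dyn_vnet.begin(), dyn_vnet.end());
  p->dyn_kd.assign(dyn_kd.begin(), dyn_kd.end());
  p->mu = mu;
  p->Xc0 = Xc0;
}

// [[Rcpp::export]]
NumericVector sim_rhs(SEXP plan, double t, NumericVector y) {
  XPtr<Plan> p(plan);
  Plan& P = *p;
  std::fill(P.acc.begin(), P.acc.end(), 0.0);
  std::fill(P.vsum.begin(), P.vsum.end(), 0.0);
  double Xconc = P.Xc0 * std::exp(P.mu * t);
  const double* yp = REAL(y);

  for (size_t k = 0; k < P.terms.size(); ++k) {
    const Term& tm = P.terms[k];
    double f = dirflux(P, tm.rxn, tm.dir, t) * tm.w;
    if (f <= 0) continue;
    if (tm.gain == 1) f *= Xconc;
    const double* u = nullptr;
    double one = 1.0;
    if (tm.inputs.empty()) {
      u = &one;
    } else if (tm.inputs.size() == 1) {
      int pi = tm.inputs[0];
      u = (P.ctype[pi] == 0) ? P.const_idv[pi].data() : yp + P.offset[pi];
    } else {
      int p1 = tm.inputs[0], p2 = tm.inputs[1];
      const double* u1 = (P.ctype[p1] == 0) ? P.const_idv[p1].data() : yp + P.offset[p1];
      const double* u2 = (P.ctype[p2] == 0) ? P.const_idv[p2].data() : yp + P.offset[p2];
      int d1 = P.size[p1] ? P.size[p1] : 1, d2 = P.size[p2] ? P.size[p2] : 1;
      double* jp = P.joint.data();
      for (int j2 = 0; j2 < d2; ++j2) {
        double s = u2[j2];
        const double* b1 = u1;
        double* jj = jp + (size_t)j2 * d1;
        for (int j1 = 0; j1 < d1; ++j1) jj[j1] = b1[j1] * s;
      }
      u = jp;
    }
    // acc_target += f * M u (sparse triplets)
    double* at = P.acc.data() + P.offset[tm.target];
    const size_t nnz = tm.mr.size();
    const int* rp = tm.mr.data();
    const int* cp = tm.mc.data();
    const double* vp = tm.mv.data();
    for (size_t q = 0; q < nnz; ++q) at[rp[q]] += f * vp[q] * u[cp[q]];
    P.vsum[tm.target] += f;
  }

  NumericVector dy(P.n_state);
  double* dp = REAL(dy);
  for (int i = 0; i < P.n_pool; ++i) {
    if (P.ctype[i] == 0) continue;
    double C = pool_conc(P, i, t);
    int off = P.offset[i], sz = P.size[i];
    double vs = P.vsum[i];
    for (int k = 0; k < sz; ++k)
      dp[off + k] = (P.acc[off + k] - vs * yp[off + k]) / C;
  }
  return dy;
}
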