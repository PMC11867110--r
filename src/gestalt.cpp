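// Numeric core of the pruning likelihood and the fixed-tree sampler.
//
// Branch state spaces are compiled in R into flat integer/double arrays
// (see compileTreeLikelihood); here we only fill in hazards under the
// current editing parameters, exponentiate each small acyclic generator
// (closed form for trivial spaces, row-vector uniformization otherwise,
// scaling-and-squaring for large event intensities) and run Felsenstein
// pruning in log space over the candidate ancestral allele sets.

#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

namespace {

struct Flat {
  const int *tNState, *tStateOff;
  const double *tDetConst;
  const int *sAccept, *sHtOff, *sHtN, *sTrOff, *sTrN;
  const int *htType, *htJ, *htJp, *htEL, *htER;
  const int *trTo, *trType, *trJ, *trJp, *trEL, *trER;
  const double *trW;
};

Flat unpackFlat(const List& f) {
  Flat x;
  x.tNState = INTEGER(VECTOR_ELT(f, f.findName("tNState")));
  x.tStateOff = INTEGER(VECTOR_ELT(f, f.findName("tStateOff")));
  x.tDetConst = REAL(VECTOR_ELT(f, f.findName("tDetConst")));
  x.sAccept = INTEGER(VECTOR_ELT(f, f.findName("sAccept")));
  x.sHtOff = INTEGER(VECTOR_ELT(f, f.findName("sHtOff")));
  x.sHtN = INTEGER(VECTOR_ELT(f, f.findName("sHtN")));
  x.sTrOff = INTEGER(VECTOR_ELT(f, f.findName("sTrOff")));
  x.sTrN = INTEGER(VECTOR_ELT(f, f.findName("sTrN")));
  x.htType = INTEGER(VECTOR_ELT(f, f.findName("htType")));
  x.htJ = INTEGER(VECTOR_ELT(f, f.findName("htJ")));
  x.htJp = INTEGER(VECTOR_ELT(f, f.findName("htJp")));
  x.htEL = INTEGER(VECTOR_ELT(f, f.findName("htEL")));
  x.htER = INTEGER(VECTOR_ELT(f, f.findName("htER")));
  x.trTo = INTEGER(VECTOR_ELT(f, f.findName("trTo")));
  x.trType = INTEGER(VECTOR_ELT(f, f.findName("trType")));
  x.trJ = INTEGER(VECTOR_ELT(f, f.findName("trJ")));
  x.trJp = INTEGER(VECTOR_ELT(f, f.findName("trJp")));
  x.trEL = INTEGER(VECTOR_ELT(f, f.findName("trEL")));
  x.trER = INTEGER(VECTOR_ELT(f, f.findName("trER")));
  x.trW = REAL(VECTOR_ELT(f, f.findName("trW")));
  return x;
}

struct Params {
  const double *lam;
  double omega, g0, g1, hs;
  double pl0, pl1, pr0, pr1;  // short/long class probs, precomputed
};

inline Params makeParams(const double *lam, double omega, double g0,
                         double g1, double hs) {
  Params p;
  p.lam = lam; p.omega = omega; p.g0 = g0; p.g1 = g1; p.hs = hs;
  p.pl0 = 1.0 / (1.0 + g0); p.pl1 = g0 / (1.0 + g0);
  p.pr0 = 1.0 / (1.0 + g1); p.pr1 = g1 / (1.0 + g1);
  return p;
}

inline double hazTerm(const Params& p, int type, int j, int jp, int eL, int eR) {
  double base = (type == 1) ? p.lam[j - 1] * p.hs
                            : p.omega * (p.lam[j - 1] + p.lam[jp - 1]) * p.hs;
  return base * (eL ? p.pl1 : p.pl0) * (eR ? p.pr1 : p.pr0);
}

// Total leaving hazard of global state s.
inline double stateTotalHazard(const Flat& f, const Params& p, int s) {
  double h = 0.0;
  int off = f.sHtOff[s], n = f.sHtN[s];
  for (int k = 0; k < n; ++k)
    h += hazTerm(p, f.htType[off + k], f.htJ[off + k], f.htJp[off + k],
                 f.htEL[off + k], f.htER[off + k]);
  return h;
}

// log P(init -> any accepting state) of one branch state space over
// scaled time rt, plus the task's detail constant.
double taskValue(const Flat& f, const Params& p, int tid1, double rt,
                 std::vector<double>& Q, std::vector<double>& v,
                 std::vector<double>& w, std::vector<double>& A,
                 std::vector<double>& B) {
  int t = tid1 - 1;
  int ns = f.tNState[t];
  int so = f.tStateOff[t];
  double det = f.tDetConst[t];
  if (ns == 1) {
    // single state: pure survival if it is accepting (no new observed
    // indels), otherwise the descendant is unreachable
    if (!f.sAccept[so]) return R_NegInf;
    return -stateTotalHazard(f, p, so) * rt + det;
  }
  // dense scaled generator Q * rt (sub-stochastic; sink implicit)
  Q.assign((size_t)ns * ns, 0.0);
  double nu = 0.0;
  for (int k = 0; k < ns; ++k) {
    int s = so + k;
    double htot = stateTotalHazard(f, p, s);
    Q[(size_t)k * ns + k] = -htot * rt;
    if (htot * rt > nu) nu = htot * rt;
    int off = f.sTrOff[s], n = f.sTrN[s];
    for (int q = 0; q < n; ++q) {
      double h = hazTerm(p, f.trType[off + q], f.trJ[off + q],
                         f.trJp[off + q], f.trEL[off + q], f.trER[off + q]) *
                 f.trW[off + q];
      Q[(size_t)k * ns + (f.trTo[off + q] - 1)] += h * rt;
    }
  }
  double pacc = 0.0;
  if (nu <= 0.0) {
    pacc = f.sAccept[so] ? 1.0 : 0.0;
  } else if (nu <= 30.0) {
    // row-vector uniformization: P = e^{-nu} sum_k (nu^k/k!) B^k,
    // B = I + Q/nu
    v.assign(ns, 0.0); w.assign(ns, 0.0);
    v[0] = 1.0;
    double pk = std::exp(-nu), csum = pk;
    for (int k = 0; k < ns; ++k) w[k] += pk * v[k];
    int kmax = (int)(nu + 10.0 * std::sqrt(nu + 10.0) + 30.0);
    std::vector<double>& v2 = A;  // reuse workspace
    v2.assign(ns, 0.0);
    for (int it = 1; it <= kmax; ++it) {
      for (int k = 0; k < ns; ++k) {
        double acc = v[k];  // identity part
        // v2 = v (I + Q/nu): iterate rows with nonzero v
        v2[k] = acc;
      }
      for (int k = 0; k < ns; ++k) {
        if (v[k] == 0.0) continue;
        const double *qrow = &Q[(size_t)k * ns];
        double vk = v[k] / nu;
        for (int j = 0; j < ns; ++j) v2[j] += vk * qrow[j];
      }
      for (int k = 0; k < ns; ++k) { v[k] = v2[k]; v2[k] = 0.0; }
      pk *= nu / it;
      csum += pk;
      for (int k = 0; k < ns; ++k) w[k] += pk * v[k];
      if (1.0 - csum < 1e-14) break;
    }
    for (int k = 0; k < ns; ++k)
      if (f.sAccept[so + k]) pacc += w[k];
  } else {
    // scaling and squaring with a plain series at small norm
    int sq = 0;
    double scale = 1.0;
    while (nu / scale > 0.5) { scale *= 2.0; ++sq; }
    size_t nn2 = (size_t)ns * ns;
    A.assign(nn2, 0.0);
    for (int k = 0; k < ns; ++k) A[(size_t)k * ns + k] = 1.0;
    // series: E = I + M + M^2/2 + ... with M = Q rt / 2^sq
    std::vector<double>& term = B;
    term.assign(nn2, 0.0);
    for (size_t i = 0; i < nn2; ++i) term[i] = Q[i] / scale;
    for (size_t i = 0; i < nn2; ++i) A[i] += term[i];
    std::vector<double> tmp(nn2);
    for (int k = 2; k <= 20; ++k) {
      // term = term * M / k
      std::fill(tmp.begin(), tmp.end(), 0.0);
      for (int i = 0; i < ns; ++i)
        for (int l = 0; l < ns; ++l) {
          double t_ = term[(size_t)i * ns + l];
          if (t_ == 0.0) continue;
          const double *mrow = &Q[(size_t)l * ns];
          for (int j = 0; j < ns; ++j)
            tmp[(size_t)i * ns + j] += t_ * mrow[j] / (scale * k);
        }
      double mx = 0.0;
      for (size_t i = 0; i < nn2; ++i) {
        term[i] = tmp[i];
        if (std::fabs(term[i]) > mx) mx = std::fabs(term[i]);
        A[i] += term[i];
      }
      if (mx < 1e-18) break;
    }
    for (int s2 = 0; s2 < sq; ++s2) {
      std::fill(tmp.begin(), tmp.end(), 0.0);
      for (int i = 0; i < ns; ++i)
        for (int l = 0; l < ns; ++l) {
          double a = A[(size_t)i * ns + l];
          if (a == 0.0) continue;
          const double *arow = &A[(size_t)l * ns];
          for (int j = 0; j < ns; ++j)
            tmp[(size_t)i * ns + j] += a * arow[j];
        }
      A.swap(tmp);
    }
    for (int k = 0; k < ns; ++k)
      if (f.sAccept[so + k]) pacc += A[(size_t)0 * ns + k];
  }
  if (pacc <= 0.0) return R_NegInf;
  return std::log(pacc) + det;
}

double logsumexp2(const std::vector<double>& x) {
  double mx = R_NegInf;
  for (double xi : x) if (xi > mx) mx = xi;
  if (!std::isfinite(mx)) return R_NegInf;
  double s = 0.0;
  for (double xi : x) s += std::exp(xi - mx);
  return mx + std::log(s);
}

// Full pruning pass given per-pair log transition values.
double pruneLoglik(const double *vals, const int *pairOff, const int *pairTask,
                   const int *edgeParent, const int *edgeChild,
                   const int *candCount, const int *postNodes, int nPost,
                   const int *childEdges, int root, int nTips, int nNodes) {
  std::vector<std::vector<double> > logL(nNodes);
  for (int i = 0; i < nTips; ++i) logL[i].assign(1, 0.0);
  std::vector<double> terms;
  for (int k = 0; k < nPost; ++k) {
    int u = postNodes[k];  // 1-based ape id
    int cu = candCount[u - 1];
    std::vector<double> acc(cu, 0.0);
    for (int c = 0; c < 2; ++c) {
      int e = childEdges[k + (size_t)nPost * c];  // 1-based edge id
      int v = edgeChild[e - 1];
      int cv = candCount[v - 1];
      const std::vector<double>& Lv = logL[v - 1];
      for (int x = 0; x < cu; ++x) {
        terms.assign(cv, R_NegInf);
        for (int y = 0; y < cv; ++y) {
          int tid = pairTask[pairOff[e - 1] + x * cv + y];
          if (tid == 0) continue;
          terms[y] = vals[pairOff[e - 1] + x * cv + y] + Lv[y];
        }
        acc[x] += logsumexp2(terms);
      }
    }
    logL[u - 1] = acc;
  }
  return logL[root - 1][0];
}

struct Prog {
  List flat;
  Flat f;
  IntegerVector pairOff, pairTask, edgeParent, edgeChild, candCount,
      postNodes, childEdges;
  int root, nTips, nNodes, nEdges;
  NumericVector tEdge;   // branch length * branch-rate multiplier
  std::vector<double> vals;
};

Prog unpackProg(const List& pr) {
  Prog p;
  p.flat = as<List>(pr["flat"]);
  p.f = unpackFlat(p.flat);
  p.pairOff = as<IntegerVector>(pr["pairOff"]);
  p.pairTask = as<IntegerVector>(pr["pairTask"]);
  p.edgeParent = as<IntegerVector>(pr["edgeParent"]);
  p.edgeChild = as<IntegerVector>(pr["edgeChild"]);
  p.candCount = as<IntegerVector>(pr["candCount"]);
  p.postNodes = as<IntegerVector>(pr["postNodes"]);
  p.childEdges = as<IntegerVector>(pr["childEdges"]);
  p.root = as<int>(pr["root"]);
  p.nTips = as<int>(pr["nTips"]);
  p.nNodes = p.candCount.size();
  p.nEdges = p.edgeParent.size();
  p.tEdge = as<NumericVector>(pr["tEdge"]);
  p.vals.assign(p.pairTask.size(), 0.0);
  return p;
}

double progLoglik(Prog& p, const Params& par, double r,
                  std::vector<double>& Q, std::vector<double>& v,
                  std::vector<double>& w, std::vector<double>& A,
                  std::vector<double>& B) {
  for (int e = 0; e < p.nEdges; ++e) {
    double rt = r * p.tEdge[e];
    int ccp = p.candCount[p.edgeParent[e] - 1];
    int ccc = p.candCount[p.edgeChild[e] - 1];
    for (int x = 0; x < ccp; ++x)
      for (int y = 0; y < ccc; ++y) {
        int idx = p.pairOff[e] + x * ccc + y;
        int tid = p.pairTask[idx];
        p.vals[idx] = (tid == 0) ? R_NegInf
                                 : taskValue(p.f, par, tid, rt, Q, v, w, A, B);
      }
  }
  return pruneLoglik(p.vals.data(), p.pairOff.begin(), p.pairTask.begin(),
                     p.edgeParent.begin(), p.edgeChild.begin(),
                     p.candCount.begin(), p.postNodes.begin(),
                     p.postNodes.size(), p.childEdges.begin(), p.root,
                     p.nTips, p.nNodes);
}

}  // namespace

// [[Rcpp::export]]
double cpp_eval_loglik(List flat, NumericVector lam, double omega, double g0,
                       double g1, NumericVector rtEdge, double hazardScale,
                       IntegerVector pairOff, IntegerVector pairTask,
                       IntegerVector edgeParent, IntegerVector edgeChild,
                       IntegerVector candCount, IntegerVector postNodes,
                       IntegerVector childEdges, int root, int nTips,
                       NumericVector vals, IntegerVector dirtyEdges) {
  Flat f = unpackFlat(flat);
  Params par = makeParams(lam.begin(), omega, g0, g1, hazardScale);
  std::vector<double> Q, v, w, A, B;
  for (int d = 0; d < dirtyEdges.size(); ++d) {
    int e = dirtyEdges[d];  // 1-based
    double rt = rtEdge[e - 1];
    int ccp = candCount[edgeParent[e - 1] - 1];
    int ccc = candCount[edgeChild[e - 1] - 1];
    for (int x = 0; x < ccp; ++x)
      for (int y = 0; y < ccc; ++y) {
        int idx = pairOff[e - 1] + x * ccc + y;
        int tid = pairTask[idx];
        vals[idx] = (tid == 0) ? R_NegInf
                               : taskValue(f, par, tid, rt, Q, v, w, A, B);
      }
  }
  return pruneLoglik(REAL(vals), pairOff.begin(), pairTask.begin(),
                     edgeParent.begin(), edgeChild.begin(), candCount.begin(),
                     postNodes.begin(), postNodes.size(), childEdges.begin(),
                     root, nTips, candCount.size());
}

// Metropolis-Hastings over editing parameters on fixed trees (optionally
// several replicates sharing parameters, each with its own tree/data).
// Parameter vector: r, omega, g0, g1, lam[1..M] (lam constrained to mean
// 1 by a transfer move). Scalars get log-scale random-walk ("scale")
// moves with Jacobian s; priors are lognormal for scalars and Dirichlet
// (on lam/M) for the cut rates. Move scales auto-tune during burn-in
// only. Uses R's RNG (seed via set.seed on the R side).
// [[Rcpp::export]]
List cpp_mcmc_fixed(List progs, NumericVector init, NumericMatrix lnPrior,
                    NumericVector lamAlpha, double lamLogConst, int nIter,
                    int thin, double burninFrac, NumericVector moveWeights,
                    bool likOn, double hazardScale) {
  RNGScope scope;
  int nProg = progs.size();
  std::vector<Prog> ps;
  for (int i = 0; i < nProg; ++i) ps.push_back(unpackProg(progs[i]));
  int M = lamAlpha.size();
  int nPar = 4 + M;
  std::vector<double> theta(init.begin(), init.end());

  auto logPrior = [&](const std::vector<double>& th) {
    double lp = 0.0;
    for (int k = 0; k < 4; ++k)
      lp += R::dlnorm(th[k], lnPrior(k, 0), lnPrior(k, 1), 1);
    for (int k = 0; k < M; ++k) {
      if (th[4 + k] <= 0.0) return R_NegInf;
      lp += (lamAlpha[k] - 1.0) * std::log(th[4 + k] / M);
    }
    return lp + lamLogConst;
  };

  std::vector<double> Q, v, w, A, B;
  auto logLik = [&](const std::vector<double>& th) {
    if (!likOn) return 0.0;
    Params par = makeParams(&th[4], th[1], th[2], th[3], hazardScale);
    double ll = 0.0;
    for (int i = 0; i < nProg; ++i)
      ll += progLoglik(ps[i], par, th[0], Q, v, w, A, B);
    return ll;
  };

  double lp = logPrior(theta), ll = logLik(theta);
  if (!std::isfinite(lp + ll))
    stop("non-finite initial posterior (prior %f, likelihood %f)", lp, ll);

  double wsum = 0.0;
  for (int k = 0; k < moveWeights.size(); ++k) wsum += moveWeights[k];
  std::vector<double> cumw(moveWeights.size());
  double c = 0.0;
  for (int k = 0; k < moveWeights.size(); ++k) {
    c += moveWeights[k] / wsum;
    cumw[k] = c;
  }

  std::vector<double> tune(5, 1.0);  // lambda of log-scale moves; [4] = transfer width
  tune[4] = 0.3;
  std::vector<int> nProp(5, 0), nAcc(5, 0);
  int burnEnd = (int)(burninFrac * nIter);

  int nRec = nIter / thin + 1;
  NumericMatrix trace(nRec, 4 + nPar);
  int rec = 0;
  auto record = [&](int iter) {
    trace(rec, 0) = iter;
    trace(rec, 1) = lp + ll;
    trace(rec, 2) = ll;
    trace(rec, 3) = lp;
    for (int k = 0; k < nPar; ++k) trace(rec, 4 + k) = theta[k];
    ++rec;
  };
  record(0);

  std::vector<double> prop(theta.size());
  for (int iter = 1; iter <= nIter; ++iter) {
    double u = unif_rand();
    int mv = 0;
    while (mv < (int)cumw.size() - 1 && u > cumw[mv]) ++mv;
    prop = theta;
    double logHR = 0.0;
    bool valid = true;
    if (mv < 4) {
      double s = std::exp(tune[mv] * (unif_rand() - 0.5));
      prop[mv] = theta[mv] * s;
      logHR = std::log(s);
    } else {
      int i = (int)(unif_rand() * M);
      int j = (int)(unif_rand() * (M - 1));
      if (j >= i) ++j;
      double d = tune[4] * (unif_rand() - 0.5) * 2.0;
      prop[4 + i] = theta[4 + i] + d;
      prop[4 + j] = theta[4 + j] - d;
      if (prop[4 + i] <= 0.0 || prop[4 + j] <= 0.0) valid = false;
    }
    ++nProp[mv];
    if (valid) {
      double lp2 = logPrior(prop);
      if (std::isfinite(lp2)) {
        double ll2 = logLik(prop);
        double a = (lp2 + ll2) - (lp + ll) + logHR;
        if (a >= 0.0 || std::log(unif_rand()) < a) {
          theta = prop;
          lp = lp2;
          ll = ll2;
          ++nAcc[mv];
        }
      }
    }
    // auto-tune toward ~30% acceptance, burn-in only
    if (iter <= burnEnd && nProp[mv] >= 50) {
      double rate = (double)nAcc[mv] / nProp[mv];
      double f = std::exp((rate - 0.3) * 0.5);
      tune[mv] = std::min(10.0, std::max(1e-3, tune[mv] * f));
      nProp[mv] = 0;
      nAcc[mv] = 0;
    }
    if (iter % thin == 0) record(iter);
    if (iter % 4096 == 0) Rcpp::checkUserInterrupt();
  }
  return List::create(_["trace"] = trace, _["tune"] = wrap(tune));
}
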