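#include <Rcpp.h>
#include <vector>
#include <cmath>

using namespace Rcpp;

static const int KMAX = 8;

// ---------------------------------------------------------------------------
// small dense matrix exponential: scaling-and-squaring with a Taylor core.
// Adequate for k <= 8 rate matrices; rows renormalized to sum exactly 1.
// ---------------------------------------------------------------------------

static void matmul_small(const double* X, const double* Y, int k, double* Z) {
  for (int i = 0; i < k; ++i) {
    for (int j = 0; j < k; ++j) {
      double s = 0.0;
      for (int l = 0; l < k; ++l) s += X[i * k + l] * Y[l * k + j];
      Z[i * k + j] = s;
    }
  }
}

static void mat_exp_small(const double* A0, int k, double* P) {
  double A[KMAX * KMAX], term[KMAX * KMAX], tmp[KMAX * KMAX];
  double norm = 0.0;
  for (int i = 0; i < k; ++i) {
    double r = 0.0;
    for (int j = 0; j < k; ++j) r += std::fabs(A0[i * k + j]);
    if (r > norm) norm = r;
  }
  int s = 0;
  if (norm > 0.5) {
    s = (int)std::ceil(std::log2(norm / 0.5));
    if (s > 60) s = 60;
  }
  double f = std::ldexp(1.0, -s);
  for (int i = 0; i < k * k; ++i) A[i] = A0[i] * f;
  for (int i = 0; i < k; ++i)
    for (int j = 0; j < k; ++j) {
      P[i * k + j] = (i == j) ? 1.0 : 0.0;
      term[i * k + j] = P[i * k + j];
    }
  for (int n = 1; n <= 14; ++n) {
    matmul_small(term, A, k, tmp);
    double inv = 1.0 / n;
    for (int i = 0; i < k * k; ++i) term[i] = tmp[i] * inv;
    for (int i = 0; i < k * k; ++i) P[i] += term[i];
  }
  for (int q = 0; q < s; ++q) {
    matmul_small(P, P, k, tmp);
    for (int i = 0; i < k * k; ++i) P[i] = tmp[i];
  }
  for (int i = 0; i < k; ++i) {
    double rs = 0.0;
    for (int j = 0; j < k; ++j) {
      if (P[i * k + j] < 0.0) P[i * k + j] = 0.0;
      rs += P[i * k + j];
    }
    if (rs > 0.0) {
      double inv = 1.0 / rs;
      for (int j = 0; j < k; ++j) P[i * k + j] *= inv;
    }
  }
}

// [[Rcpp::export]]
NumericMatrix cpp_expm(NumericMatrix Q, double t) {
  int k = Q.nrow();
  if (k > KMAX) stop("state space too large (k <= %d supported)", KMAX);
  if (t < 0) stop("branch length t must be >= 0");
  std::vector<double> A(k * k), P(k * k);
  for (int i = 0; i < k; ++i)
    for (int j = 0; j < k; ++j) A[i * k + j] = Q(i, j) * t;
  mat_exp_small(A.data(), k, P.data());
  NumericMatrix out(k, k);
  for (int i = 0; i < k; ++i)
    for (int j = 0; j < k; ++j) out(i, j) = P[i * k + j];
  return out;
}

// ---------------------------------------------------------------------------
// pruning (Felsenstein) likelihood with per-node rescaling, ambiguous tips
// and node constraints ("fossilization": partials zeroed outside the allowed
// set after the node's children are combined).
// edge arrays are postorder (every child edge before its parent's edge).
// ---------------------------------------------------------------------------

struct TreeView {
  int ntip, nnode, nedge;
  const int* epar;       // 1-based parent node per edge
  const int* echild;     // 1-based child node per edge
  const double* blen;    // branch length per edge
  const double* tippart; // k x ntip, column-major
  const double* mask;    // k x nnode, column-major
};

static double prune_core(const TreeView& T, int k, const double* Q,
                         const double* pi,
                         double* downStore /* k x nnode or NULL */,
                         double* Pstore /* k*k x nedge or NULL */) {
  std::vector<double> part(k * T.nnode);
  for (int tip = 0; tip < T.ntip; ++tip)
    for (int s = 0; s < k; ++s) part[tip * k + s] = T.tippart[tip * k + s];
  for (int n = T.ntip; n < T.nnode; ++n)
    for (int s = 0; s < k; ++s) part[n * k + s] = 1.0;

  double logscale = 0.0;
  double A[KMAX * KMAX], P[KMAX * KMAX];
  for (int e = 0; e < T.nedge; ++e) {
    int p = T.epar[e] - 1, c = T.echild[e] - 1;
    // child c is complete: apply its constraint mask, rescale
    double mx = 0.0;
    for (int s = 0; s < k; ++s) {
      part[c * k + s] *= T.mask[c * k + s];
      if (part[c * k + s] > mx) mx = part[c * k + s];
    }
    if (mx <= 0.0) return R_NegInf;
    double inv = 1.0 / mx;
    for (int s = 0; s < k; ++s) part[c * k + s] *= inv;
    logscale += std::log(mx);
    if (downStore)
      for (int s = 0; s < k; ++s) downStore[c * k + s] = part[c * k + s];
    for (int i = 0; i < k * k; ++i) A[i] = Q[i] * T.blen[e];
    mat_exp_small(A, k, P);
    if (Pstore)
      for (int i = 0; i < k * k; ++i) Pstore[e * k * k + i] = P[i];
    for (int i = 0; i < k; ++i) {
      double msg = 0.0;
      for (int j = 0; j < k; ++j) msg += P[i * k + j] * part[c * k + j];
      part[p * k + i] *= msg;
    }
  }
  int root = T.ntip; // 1-based ntip+1
  double L = 0.0, mx = 0.0;
  for (int s = 0; s < k; ++s) {
    part[root * k + s] *= T.mask[root * k + s];
    if (part[root * k + s] > mx) mx = part[root * k + s];
  }
  if (mx <= 0.0) return R_NegInf;
  double inv = 1.0 / mx;
  for (int s = 0; s < k; ++s) {
    part[root * k + s] *= inv;
    L += pi[s] * part[root * k + s];
  }
  logscale += std::log(mx);
  if (downStore)
    for (int s = 0; s < k; ++s) downStore[root * k + s] = part[root * k + s];
  if (L <= 0.0) return R_NegInf;
  return std::log(L) + logscale;
}

// marginal state probabilities at every node (down-up algorithm); returns
// loglik, fills marg (k x nnode column-major, columns normalized).
static double marginals_core(const TreeView& T, int k, const double* Q,
                             const double* pi, double* marg) {
  std::vector<double> down(k * T.nnode), Ps((size_t)k * k * T.nedge);
  double ll = prune_core(T, k, Q, pi, down.data(), Ps.data());
  if (!R_FINITE(ll)) return ll;

  // per-edge message to its parent
  std::vector<double> msg(k * T.nedge);
  for (int e = 0; e < T.nedge; ++e) {
    int c = T.echild[e] - 1;
    const double* P = &Ps[(size_t)e * k * k];
    for (int i = 0; i < k; ++i) {
      double s = 0.0;
      for (int j = 0; j < k; ++j) s += P[i * k + j] * down[c * k + j];
      msg[e * k + i] = s;
    }
  }
  // child-edge lists
  std::vector<std::vector<int>> ce(T.nnode);
  for (int e = 0; e < T.nedge; ++e) ce[T.epar[e] - 1].push_back(e);

  std::vector<double> up(k * T.nnode, 0.0);
  int root = T.ntip;
  for (int s = 0; s < k; ++s) up[root * k + s] = pi[s];

  // reverse postorder: parents before children
  for (int e = T.nedge - 1; e >= 0; --e) {
    int p = T.epar[e] - 1, c = T.echild[e] - 1;
    double stuff[KMAX];
    for (int s = 0; s < k; ++s) stuff[s] = up[p * k + s];
    // note: mask and rescale of p are already inside `down[p]`; here we need
    // mask_p times product of sibling messages, which equals down[p]/msg_e up
    // to the node's rescale factor -- recomputed directly to avoid dividing
    // by zero messages.
    for (int s = 0; s < k; ++s) stuff[s] *= T.mask[p * k + s];
    for (size_t oe = 0; oe < ce[p].size(); ++oe) {
      int e2 = ce[p][oe];
      if (e2 == e) continue;
      for (int s = 0; s < k; ++s) stuff[s] *= msg[e2 * k + s];
    }
    const double* P = &Ps[(size_t)e * k * k];
    double mx = 0.0;
    for (int j = 0; j < k; ++j) {
      double s = 0.0;
      for (int i = 0; i < k; ++i) s += P[i * k + j] * stuff[i];
      up[c * k + j] = s;
      if (s > mx) mx = s;
    }
    if (mx > 0.0) {
      double inv = 1.0 / mx;
      for (int j = 0; j < k; ++j) up[c * k + j] *= inv;
    }
  }
  for (int n = 0; n < T.nnode; ++n) {
    double tot = 0.0;
    for (int s = 0; s < k; ++s) {
      marg[n * k + s] = down[n * k + s] * up[n * k + s];
      tot += marg[n * k + s];
    }
    if (tot > 0.0) {
      double inv = 1.0 / tot;
      for (int s = 0; s < k; ++s) marg[n * k + s] *= inv;
    }
  }
  return ll;
}

static TreeView make_view(const IntegerMatrix& edge, const NumericVector& blen,
                          const NumericMatrix& tippart,
                          const NumericMatrix& mask) {
  TreeView T;
  T.ntip = tippart.ncol();
  T.nnode = mask.ncol();
  T.nedge = edge.nrow();
  T.epar = &edge(0, 0);
  T.echild = &edge(0, 1);
  T.blen = &blen[0];
  T.tippart = &tippart[0];
  T.mask = &mask[0];
  return T;
}

// [[Rcpp::export]]
double cpp_prune_loglik(IntegerMatrix edge, NumericVector blen,
                        NumericMatrix tippart, NumericMatrix mask,
                        NumericMatrix Q, NumericVector pi) {
  int k = Q.nrow();
  if (k > KMAX) stop("state space too large (k <= %d supported)", KMAX);
  std::vector<double> Qr(k * k);
  for (int i = 0; i < k; ++i)
    for (int j = 0; j < k; ++j) Qr[i * k + j] = Q(i, j);
  TreeView T = make_view(edge, blen, tippart, mask);
  return prune_core(T, k, Qr.data(), &pi[0], NULL, NULL);
}

// [[Rcpp::export]]
NumericMatrix cpp_node_marginals(IntegerMatrix edge, NumericVector blen,
                                 NumericMatrix tippart, NumericMatrix mask,
                                 NumericMatrix Q, NumericVector pi) {
  int k = Q.nrow();
  if (k > KMAX) stop("state space too large (k <= %d supported)", KMAX);
  std::vector<double> Qr(k * k);
  for (int i = 0; i < k; ++i)
    for (int j = 0; j < k; ++j) Qr[i * k + j] = Q(i, j);
  TreeView T = make_view(edge, blen, tippart, mask);
  NumericMatrix marg(k, T.nnode);
  double ll = marginals_core(T, k, Qr.data(), &pi[0], &marg[0]);
  marg.attr("loglik") = ll;
  return marg;
}

// ---------------------------------------------------------------------------
// proposal helpers
// ---------------------------------------------------------------------------

// reflect x into [lo, hi] (sliding-window proposals never leave the prior
// support; reflection keeps the kernel symmetric)
// [[Rcpp::export]]
double cpp_reflect(double x, double lo, double hi) {
  double w = hi - lo;
  if (w <= 0) stop("invalid bounds");
  double z = x - lo;
  double y = z - 2.0 * w * std::floor(z / (2.0 * w));
  double r = (y <= w) ? y : 2.0 * w - y;
  return lo + r;
}

static int rand_int(int n) {
  int i = (int)(unif_rand() * n);
  return (i >= n) ? n - 1 : i;
}

// ---------------------------------------------------------------------------
// Metropolis-Hastings / reversible-jump chain over (tree index, rates,
// rate-class structure, hyper mean)
// ---------------------------------------------------------------------------

struct PriorCpp {
  bool hyper;      // exponential(mean m) rates with m ~ U(hlo, hhi)
  double lo, hi;   // uniform rate prior bounds
  double hlo, hhi; // hyper-mean bounds
};

static double rate_prior_logdens(double r, double m, const PriorCpp& pr) {
  if (pr.hyper) {
    if (r < 0) return R_NegInf;
    return -std::log(m) - r / m;
  }
  if (r < pr.lo || r > pr.hi) return R_NegInf;
  return -std::log(pr.hi - pr.lo);
}

static double rate_prior_draw(double m, const PriorCpp& pr) {
  if (pr.hyper) return R::rexp(m);
  return pr.lo + unif_rand() * (pr.hi - pr.lo);
}

// Gibbs draw of the exponential hyper-mean from its full conditional
// p(m | rates) ~ m^-n exp(-S/m) truncated to (hlo, hhi). The likelihood
// never involves m, so this conditional is exact in every mode. Rejection
// sampling from the uniform hyperprior against the conditional's mode;
// returns false (caller falls back to a random-walk move) if the density is
// too concentrated for rejection to land within the attempt budget.
static bool gibbs_hyper_mean(int n, double S, const PriorCpp& pr, double& m) {
  if (n == 0) { m = pr.hlo + unif_rand() * (pr.hhi - pr.hlo); return true; }
  double lo = std::max(pr.hlo, 1e-12), hi = pr.hhi;
  double mstar = S / n;
  if (mstar < lo) mstar = lo;
  if (mstar > hi) mstar = hi;
  double logpmax = -n * std::log(mstar) - S / mstar;
  for (int it = 0; it < 500; ++it) {
    double cand = lo + unif_rand() * (hi - lo);
    double logp = -n * std::log(cand) - S / cand;
    if (std::log(unif_rand()) < logp - logpmax) { m = cand; return true; }
  }
  return false;
}

// [[Rcpp::export]]
List cpp_run_chain(List trees, int k, IntegerMatrix cells, NumericVector pi,
                   List prior, bool rj, NumericVector moveWeights,
                   int iterations, int thin, int tune_iters,
                   bool likelihood_on, NumericVector treeWeights,
                   IntegerMatrix queryNodes, int max_init_retries) {
  if (k > KMAX) stop("state space too large (k <= %d supported)", KMAX);
  int ntrees = trees.size();
  int ncell = cells.nrow();
  int nq = queryNodes.ncol();

  std::vector<IntegerMatrix> edges(ntrees);
  std::vector<NumericVector> blens(ntrees);
  std::vector<NumericMatrix> tipparts(ntrees), masks(ntrees);
  std::vector<TreeView> views(ntrees);
  for (int t = 0; t < ntrees; ++t) {
    List tr = trees[t];
    edges[t] = as<IntegerMatrix>(tr["edge"]);
    blens[t] = as<NumericVector>(tr["blen"]);
    tipparts[t] = as<NumericMatrix>(tr["tippart"]);
    masks[t] = as<NumericMatrix>(tr["mask"]);
    views[t] = make_view(edges[t], blens[t], tipparts[t], masks[t]);
  }

  PriorCpp pr;
  std::string kind = as<std::string>(prior["kind"]);
  pr.hyper = (kind == "exp_hyper");
  pr.lo = as<double>(prior["lo"]);
  pr.hi = as<double>(prior["hi"]);
  pr.hlo = as<double>(prior["hyper_lo"]);
  pr.hhi = as<double>(prior["hyper_hi"]);

  // move categories: 0 tree, 1 rate, 2 rj-structure, 3 hyper
  double cw[4];
  double tot = 0.0;
  for (int i = 0; i < 4; ++i) { tot += moveWeights[i]; cw[i] = tot; }
  if (tot <= 0) stop("move weights sum to zero");
  std::vector<double> treeCw(ntrees);
  double twtot = 0.0;
  for (int t = 0; t < ntrees; ++t) { twtot += treeWeights[t]; treeCw[t] = twtot; }

  // chain state
  int treeIdx = 0;
  std::vector<double> rates(ncell, 0.0); // non-RJ per-cell rates
  std::vector<int> zcls(ncell, 0);       // RJ: class id per cell, -1 = ZERO
  std::vector<double> clsrate;           // RJ: rate per class
  double m = pr.hyper ? (pr.hlo + 0.5 * (pr.hhi - pr.hlo)) : NA_REAL;

  std::vector<double> Qbuf(k * k);
  std::vector<double> eff(ncell);
  auto effective_rates = [&]() {
    if (!rj) { for (int c = 0; c < ncell; ++c) eff[c] = rates[c]; }
    else { for (int c = 0; c < ncell; ++c) eff[c] = (zcls[c] < 0) ? 0.0 : clsrate[zcls[c]]; }
  };
  auto build_Q = [&]() {
    effective_rates();
    std::fill(Qbuf.begin(), Qbuf.end(), 0.0);
    for (int c = 0; c < ncell; ++c) {
      int i = cells(c, 0) - 1, j = cells(c, 1) - 1;
      Qbuf[i * k + j] = eff[c];
      Qbuf[i * k + i] -= eff[c];
    }
  };
  auto loglik = [&](int ti) -> double {
    if (!likelihood_on) return 0.0;
    build_Q();
    return prune_core(views[ti], k, Qbuf.data(), &pi[0], NULL, NULL);
  };
  auto log_rates_prior = [&]() -> double {
    double lp = 0.0;
    if (!rj) {
      for (int c = 0; c < ncell; ++c) lp += rate_prior_logdens(rates[c], m, pr);
    } else {
      for (size_t c = 0; c < clsrate.size(); ++c)
        lp += rate_prior_logdens(clsrate[c], m, pr);
    }
    if (pr.hyper) lp += -std::log(pr.hhi - pr.hlo);
    return lp;
  };

  // initialization: draw from the prior, retry on zero likelihood
  double curLL = R_NegInf;
  int tries = 0;
  while (!R_FINITE(curLL)) {
    if (++tries > max_init_retries)
      stop("chain initialization failed: zero likelihood after %d prior draws; check that observed tip states are reachable under the constraint mask", max_init_retries);
    double u = unif_rand() * twtot;
    treeIdx = 0;
    while (treeIdx < ntrees - 1 && u > treeCw[treeIdx]) ++treeIdx;
    if (pr.hyper) m = pr.hlo + unif_rand() * (pr.hhi - pr.hlo);
    if (!rj) {
      for (int c = 0; c < ncell; ++c) rates[c] = rate_prior_draw(m, pr);
    } else {
      std::fill(zcls.begin(), zcls.end(), 0);
      clsrate.assign(1, rate_prior_draw(m, pr));
    }
    curLL = loglik(treeIdx);
  }

  // tuning state; a reflected window of width 2*(hi-lo) folds to an exact
  // uniform proposal over the support, so chains start maximally mobile and
  // the tuner narrows the window only where the likelihood demands it
  double wrate = pr.hyper ? 1.0 : 2.0 * (pr.hi - pr.lo); // window / multiplier scale
  double whyp = 0.1 * (pr.hhi - pr.hlo); // fallback hyper-mean window
  int tprop[2] = {0, 0}, tacc[2] = {0, 0};

  long prop[4] = {0, 0, 0, 0}, acc[4] = {0, 0, 0, 0}, unavail[4] = {0, 0, 0, 0};
  long consecRej[4] = {0, 0, 0, 0};
  long rate_scan = 0; // systematic scan over cells/classes for rate moves

  int nsamp = iterations / thin;
  int nfield = 6;
  NumericMatrix samples(nsamp, nfield + ncell);
  NumericVector marg(nq > 0 ? (double)nsamp * nq * k : 0);
  std::vector<double> margbuf(nq > 0 ? (size_t)k * 2000 : 0);

  int srow = 0;
  for (int iter = 1; iter <= iterations; ++iter) {
    if (iter % 4096 == 0) Rcpp::checkUserInterrupt();
    double u = unif_rand() * tot;
    int cat = 0;
    while (cat < 3 && u > cw[cat]) ++cat;

    bool accepted = false, counted = true;
    if (cat == 0) {
      // tree hop: independent draw from the sample's weights
      double uu = unif_rand() * twtot;
      int tnew = 0;
      while (tnew < ntrees - 1 && uu > treeCw[tnew]) ++tnew;
      double llnew = loglik(tnew);
      if (std::log(unif_rand()) < llnew - curLL) {
        treeIdx = tnew; curLL = llnew; accepted = true;
      }
    } else if (cat == 1) {
      // rate move: sliding window with reflection (uniform prior) or
      // multiplier (exponential prior)
      int nr = rj ? (int)clsrate.size() : ncell;
      if (nr == 0) { counted = false; unavail[cat]++; }
      else {
        int c = (int)(rate_scan++ % nr);
        double old = rj ? clsrate[c] : rates[c];
        double logratio = 0.0, nw;
        if (pr.hyper) {
          if (unif_rand() < 0.5) {
            // multiplier move against the exponential prior
            nw = old * std::exp(wrate * (unif_rand() - 0.5));
            logratio += std::log(nw / old);                   // Hastings
            logratio += rate_prior_logdens(nw, m, pr) - rate_prior_logdens(old, m, pr);
          } else {
            // independence draw from the prior (prior and proposal cancel)
            nw = R::rexp(m);
          }
        } else {
          nw = cpp_reflect(old + wrate * (unif_rand() - 0.5), pr.lo, pr.hi);
        }
        if (rj) clsrate[c] = nw; else rates[c] = nw;
        double llnew = loglik(treeIdx);
        if (std::log(unif_rand()) < llnew - curLL + logratio) {
          curLL = llnew; accepted = true;
        } else {
          if (rj) clsrate[c] = old; else rates[c] = old;
        }
        if (iter <= tune_iters) {
          tprop[0]++; if (accepted) tacc[0]++;
          if (tprop[0] == 50) {
            double ar = tacc[0] / 50.0;
            double cap = pr.hyper ? 10.0 : 2.0 * (pr.hi - pr.lo);
            if (ar > 0.4) wrate = std::min(wrate * 1.3, cap);
            else if (ar < 0.2) wrate = std::max(wrate / 1.3, 1e-6 * cap);
            tprop[0] = tacc[0] = 0;
          }
        }
      }
    } else if (cat == 2) {
      if (!rj) { counted = false; unavail[cat]++; }
      else {
        int sub = rand_int(5); // split, merge, to-zero, from-zero, redraw
        int ncls = (int)clsrate.size();
        std::vector<int> zsave = zcls;
        std::vector<double> csave = clsrate;
        double logratio = R_NegInf;
        bool ok = false;
        if (sub == 0) {
          // split one class into two; the new class draws its rate from the
          // rate prior (birth-from-prior: its density cancels)
          std::vector<int> S;
          std::vector<int> sz(ncls, 0);
          for (int c = 0; c < ncell; ++c) if (zcls[c] >= 0) sz[zcls[c]]++;
          for (int c = 0; c < ncls; ++c) if (sz[c] >= 2) S.push_back(c);
          if (!S.empty()) {
            int cls = S[rand_int((int)S.size())];
            int msz = sz[cls];
            std::vector<int> members;
            for (int c = 0; c < ncell; ++c) if (zcls[c] == cls) members.push_back(c);
            std::vector<int> toB;
            do {
              toB.clear();
              for (size_t i = 0; i < members.size(); ++i)
                if (unif_rand() < 0.5) toB.push_back(members[i]);
            } while (toB.empty() || toB.size() == members.size());
            int newid = ncls;
            for (size_t i = 0; i < toB.size(); ++i) zcls[toB[i]] = newid;
            clsrate.push_back(rate_prior_draw(m, pr));
            double nsplit = std::pow(2.0, msz) - 2.0;
            logratio = std::log((double)S.size() * nsplit /
                                ((double)(ncls + 1) * ncls));
            ok = true;
          }
        } else if (sub == 1) {
          // merge an ordered pair of classes (second's rate is discarded)
          if (ncls >= 2) {
            int a = rand_int(ncls), b = rand_int(ncls - 1);
            if (b >= a) b++;
            double rb = clsrate[b];
            int msz = 0;
            for (int c = 0; c < ncell; ++c) {
              if (zcls[c] == b) zcls[c] = a;
              if (zcls[c] == a) msz++;
            }
            // reindex classes after removing b
            for (int c = 0; c < ncell; ++c) if (zcls[c] > b) zcls[c]--;
            clsrate.erase(clsrate.begin() + b);
            int nclsNew = ncls - 1;
            std::vector<int> sz(nclsNew, 0);
            for (int c = 0; c < ncell; ++c) if (zcls[c] >= 0) sz[zcls[c]]++;
            int nsplittable = 0;
            for (int c = 0; c < nclsNew; ++c) if (sz[c] >= 2) nsplittable++;
            double nsplit = std::pow(2.0, msz) - 2.0;
            logratio = std::log((double)ncls * (ncls - 1) /
                                ((double)nsplittable * nsplit)) -
                       rate_prior_logdens(rb, m, pr) +
                       rate_prior_logdens(rb, m, pr);
            // (the discarded rate's prior density cancels against the reverse
            // split's birth-from-prior draw; written out for clarity)
            ok = true;
          }
        } else if (sub == 2) {
          // move one cell to the ZERO class
          std::vector<int> NZ;
          for (int c = 0; c < ncell; ++c) if (zcls[c] >= 0) NZ.push_back(c);
          if (!NZ.empty()) {
            int cell = NZ[rand_int((int)NZ.size())];
            int cls = zcls[cell];
            int nz = (int)NZ.size();
            int zn = ncell - nz;
            int clssz = 0;
            for (int c = 0; c < ncell; ++c) if (zcls[c] == cls) clssz++;
            zcls[cell] = -1;
            if (clssz == 1) {
              for (int c = 0; c < ncell; ++c) if (zcls[c] > cls) zcls[c]--;
              clsrate.erase(clsrate.begin() + cls);
              int nclsNew = ncls - 1;
              logratio = std::log((double)nz /
                                  ((double)(zn + 1) * (nclsNew + 1)));
            } else {
              logratio = std::log((double)nz /
                                  ((double)(zn + 1) * (ncls + 1)));
            }
            ok = true;
          }
        } else if (sub == 3) {
          // move one ZERO cell into an existing or a new class
          std::vector<int> Z;
          for (int c = 0; c < ncell; ++c) if (zcls[c] < 0) Z.push_back(c);
          if (!Z.empty()) {
            int cell = Z[rand_int((int)Z.size())];
            int zn = (int)Z.size();
            int nz = ncell - zn;
            int dest = rand_int(ncls + 1);
            if (dest == ncls) clsrate.push_back(rate_prior_draw(m, pr));
            zcls[cell] = dest;
            logratio = std::log((double)zn * (ncls + 1) / ((double)nz + 1));
            ok = true;
          }
        } else {
          // redraw one class rate from the prior (independence move)
          if (ncls >= 1) {
            int cls = rand_int(ncls);
            clsrate[cls] = rate_prior_draw(m, pr);
            logratio = 0.0;
            ok = true;
          }
        }
        if (!ok) { counted = false; unavail[cat]++; }
        else {
          double llnew = loglik(treeIdx);
          if (std::log(unif_rand()) < llnew - curLL + logratio) {
            curLL = llnew; accepted = true;
          } else {
            zcls = zsave; clsrate = csave;
          }
        }
      }
    } else {
      // hyper moves (exponential hyperprior). Mostly a Gibbs draw of the
      // hyper-mean from its full conditional (exact: the likelihood never
      // involves m), occasionally a joint redraw of (m, rates) from the
      // prior whose acceptance reduces to the likelihood ratio.
      if (!pr.hyper) { counted = false; unavail[cat]++; }
      else if (unif_rand() < 0.75) {
        double mOld = m;
        std::vector<double> rsave = rates, csave = clsrate;
        m = pr.hlo + unif_rand() * (pr.hhi - pr.hlo);
        if (!rj) { for (int c = 0; c < ncell; ++c) rates[c] = R::rexp(m); }
        else { for (size_t c = 0; c < clsrate.size(); ++c) clsrate[c] = R::rexp(m); }
        double llnew = loglik(treeIdx);
        if (std::log(unif_rand()) < llnew - curLL) {
          curLL = llnew; accepted = true;
        } else {
          m = mOld; rates = rsave; clsrate = csave;
        }
      } else {
        int nfree = rj ? (int)clsrate.size() : ncell;
        double S = 0.0;
        if (!rj) { for (int c = 0; c < ncell; ++c) S += rates[c]; }
        else { for (size_t c = 0; c < clsrate.size(); ++c) S += clsrate[c]; }
        if (gibbs_hyper_mean(nfree, S, pr, m)) {
          accepted = true;
        } else {
          // conditional too sharp for rejection sampling: local MH fallback
          double old = m;
          double lpOld = log_rates_prior();
          m = cpp_reflect(m + whyp * (unif_rand() - 0.5), pr.hlo, pr.hhi);
          double lpNew = log_rates_prior();
          if (std::log(unif_rand()) < lpNew - lpOld) accepted = true;
          else m = old;
        }
      }
    }

    if (counted) {
      prop[cat]++;
      if (accepted) { acc[cat]++; consecRej[cat] = 0; }
      else if (++consecRej[cat] >= 10000) {
        stop("move type '%s' had zero acceptances over 10000 consecutive proposals; the chain cannot mix -- revisit the data, constraints or proposal settings",
             cat == 0 ? "tree" : (cat == 1 ? "rate" : (cat == 2 ? "rj" : "hyper")));
      }
    }

    if (iter % thin == 0 && srow < nsamp) {
      effective_rates();
      samples(srow, 0) = iter;
      samples(srow, 1) = treeIdx + 1;
      samples(srow, 2) = curLL;
      samples(srow, 3) = log_rates_prior();
      samples(srow, 4) = rj ? (double)clsrate.size() : NA_REAL;
      samples(srow, 5) = pr.hyper ? m : NA_REAL;
      for (int c = 0; c < ncell; ++c) samples(srow, nfield + c) = eff[c];
      if (nq > 0 && likelihood_on) {
        build_Q();
        const TreeView& T = views[treeIdx];
        if (margbuf.size() < (size_t)k * T.nnode)
          margbuf.resize((size_t)k * T.nnode);
        marginals_core(T, k, Qbuf.data(), &pi[0], margbuf.data());
        for (int q = 0; q < nq; ++q) {
          int node = queryNodes(treeIdx, q) - 1;
          for (int s = 0; s < k; ++s)
            marg[(size_t)s * nsamp * nq + (size_t)q * nsamp + srow] =
              margbuf[(size_t)node * k + s];
        }
      }
      srow++;
    }
  }

  NumericMatrix accmat(4, 3);
  for (int i = 0; i < 4; ++i) {
    accmat(i, 0) = (double)prop[i];
    accmat(i, 1) = (double)acc[i];
    accmat(i, 2) = (double)unavail[i];
  }
  if (nq > 0) marg.attr("dim") = IntegerVector::create(nsamp, nq, k);
  return List::create(_["samples"] = samples, _["marginals"] = marg,
                      _["accept"] = accmat,
                      _["windows"] = NumericVector::create(wrate, whyp));
}
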