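// Likelihood and MCMC kernels.
//
// Node numbering follows ape: tips 1..ntip, internal ntip+1..nnode (1-based
// from R; converted to 0-based here).  Partial likelihoods are computed by
// Felsenstein pruning with per-node rescaling in the static-tree entry
// points; the MCMC kernel skips rescaling and is intended for the desk-scale
// trees (<= ~40 tips) this package analyses.

// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>
#include <cstdint>
#include <numeric>
using namespace Rcpp;

// ---------------------------------------------------------------------------
// shared helpers
// ---------------------------------------------------------------------------

// eigendecomposition of a reversible rate matrix via pi^(1/2) symmetrization
static void eigen_rev(const arma::mat& Q, const arma::vec& pi,
                      arma::mat& evec, arma::mat& ievec, arma::vec& evals) {
  arma::vec sp = arma::sqrt(pi);
  arma::mat B = arma::diagmat(sp) * Q * arma::diagmat(1.0 / sp);
  B = 0.5 * (B + B.t());
  arma::mat U;
  arma::eig_sym(evals, U, B);
  evec = arma::diagmat(1.0 / sp) * U;
  ievec = U.t() * arma::diagmat(sp);
}

static inline arma::mat pmat(const arma::mat& evec, const arma::mat& ievec,
                             const arma::vec& evals, double t) {
  arma::mat P = evec * arma::diagmat(arma::exp(evals * t)) * ievec;
  P.transform([](double x) { return x < 0.0 ? 0.0 : x; });
  return P;
}

// discrete gamma, equal-probability bins, per-bin mean rates (mean 1)
static arma::vec gamma_rates_cpp(double alpha, int ncat, bool median) {
  arma::vec r(ncat);
  if (!R_finite(alpha) || alpha > 1e5) { r.ones(); return r; }
  double scale = 1.0 / alpha;
  if (median) {
    for (int i = 0; i < ncat; i++)
      r[i] = R::qgamma((2.0 * i + 1.0) / (2.0 * ncat), alpha, scale, 1, 0);
    r *= (double)ncat / arma::accu(r); // renormalize to mean 1
    return r;
  }
  for (int i = 0; i < ncat; i++) {
    double lo = (i == 0) ? 0.0 : R::qgamma((double)i / ncat, alpha, scale, 1, 0);
    double hi = (i == ncat - 1) ? R_PosInf
                                : R::qgamma((double)(i + 1) / ncat, alpha, scale, 1, 0);
    double plo = (i == 0) ? 0.0 : R::pgamma(lo, alpha + 1.0, scale, 1, 0);
    double phi = (i == ncat - 1) ? 1.0 : R::pgamma(hi, alpha + 1.0, scale, 1, 0);
    r[i] = (phi - plo) * ncat; // E[X]=1 under shape=rate=alpha
  }
  return r;
}

// [[Rcpp::export]]
arma::vec cpp_gamma_rates(double alpha, int ncat, bool median) {
  return gamma_rates_cpp(alpha, ncat, median);
}

// ---------------------------------------------------------------------------
// static-tree pruning core (supports multifurcations, used for unrooted trees)
// ---------------------------------------------------------------------------

struct TreeIdx {
  int nnode, ntip, root;
  std::vector<std::vector<int>> children; // per node, in postorder edge order
  std::vector<int> edge_of_child;         // child node -> edge row (-1 root)
  std::vector<int> postorder_nodes;       // internal nodes, children-first
};

static TreeIdx build_tree(const IntegerVector& eparent, const IntegerVector& echild,
                          int nnode, int ntip, int root) {
  TreeIdx T;
  T.nnode = nnode; T.ntip = ntip; T.root = root - 1;
  T.children.assign(nnode, {});
  T.edge_of_child.assign(nnode, -1);
  int ne = eparent.size();
  for (int e = 0; e < ne; e++) {
    T.children[eparent[e] - 1].push_back(echild[e] - 1);
    T.edge_of_child[echild[e] - 1] = e;
  }
  // postorder over internal nodes: edges are given in ape postorder, so a
  // parent appears after all edges within its subtree; collect unique parents
  std::vector<bool> seen(nnode, false);
  for (int e = 0; e < ne; e++) {
    int p = eparent[e] - 1;
    if (!seen[p]) { /* defer until last child edge */ }
  }
  // simpler: a node is finished at its last occurrence as parent
  std::vector<int> last(nnode, -1);
  for (int e = 0; e < ne; e++) last[eparent[e] - 1] = e;
  for (int e = 0; e < ne; e++) {
    int p = eparent[e] - 1;
    if (last[p] == e) T.postorder_nodes.push_back(p);
  }
  return T;
}

// Down (tipward) partials for one rate category.  Returns per-node partial
// matrices (k x npat) for internal nodes, per-child messages, and per-node
// log-scalers (1 x npat).  Tip partials are read from tipp.
struct DownWork {
  std::vector<arma::mat> part;   // internal partials
  std::vector<arma::mat> msg;    // per child-node message P_e * down(child)
  std::vector<arma::rowvec> ls;  // per-node accumulated log scaler
};

static void down_pass(const TreeIdx& T, const arma::cube& tipp,
                      const NumericVector& elen, double rate,
                      const arma::mat& evec, const arma::mat& ievec,
                      const arma::vec& evals, DownWork& W, bool keep_msg) {
  int k = tipp.n_rows, npat = tipp.n_cols;
  W.part.assign(T.nnode, arma::mat());
  if (keep_msg) W.msg.assign(T.nnode, arma::mat());
  W.ls.assign(T.nnode, arma::rowvec(npat, arma::fill::zeros));
  for (int v : T.postorder_nodes) {
    arma::mat acc(k, npat, arma::fill::ones);
    arma::rowvec lsv(npat, arma::fill::zeros);
    for (int c : T.children[v]) {
      double t = elen[T.edge_of_child[c]] * rate;
      arma::mat P = pmat(evec, ievec, evals, t);
      arma::mat m;
      if (c < T.ntip) {
        m = P * tipp.slice(c);
      } else {
        m = P * W.part[c];
        lsv += W.ls[c];
      }
      if (keep_msg) W.msg[c] = m;
      acc %= m;
    }
    // rescale
    arma::rowvec mx = arma::max(acc, 0);
    for (int j = 0; j < npat; j++) {
      if (mx[j] > 0 && mx[j] < 1e-100) { acc.col(j) /= mx[j]; lsv[j] += std::log(mx[j]); }
    }
    W.part[v] = acc;
    W.ls[v] = lsv;
  }
}

// combine per-category root values into per-pattern log-likelihood
static arma::rowvec combine_sites(const arma::mat& llcat, // ncat x npat (log of cat lik)
                                  const arma::vec& catw, double pinv,
                                  const arma::vec& invlik) {
  int ncat = llcat.n_rows, npat = llcat.n_cols;
  arma::rowvec out(npat);
  for (int j = 0; j < npat; j++) {
    double m = llcat.col(j).max();
    double linv = (pinv > 0 && invlik[j] > 0) ? std::log(pinv) + std::log(invlik[j])
                                              : R_NegInf;
    if (linv > m) m = linv;
    if (!R_finite(m)) { out[j] = R_NegInf; continue; }
    double s = 0.0;
    for (int c = 0; c < ncat; c++)
      s += (1.0 - pinv) * catw[c] * std::exp(llcat(c, j) - m);
    if (R_finite(linv)) s += std::exp(linv - m);
    out[j] = m + std::log(s);
  }
  return out;
}

// [[Rcpp::export]]
NumericVector cpp_partition_sitewise(IntegerVector eparent, IntegerVector echild,
                                     NumericVector elen, int nnode, int ntip, int root,
                                     arma::cube tipp, arma::mat Q, arma::vec pi,
                                     arma::vec catrate, arma::vec catw, double pinv,
                                     arma::vec invlik) {
  TreeIdx T = build_tree(eparent, echild, nnode, ntip, root);
  int npat = tipp.n_cols, ncat = catrate.n_elem;
  arma::mat evec, ievec; arma::vec evals;
  eigen_rev(Q, pi, evec, ievec, evals);
  arma::mat llcat(ncat, npat);
  DownWork W;
  for (int c = 0; c < ncat; c++) {
    down_pass(T, tipp, elen, catrate[c], evec, ievec, evals, W, false);
    arma::rowvec v = pi.t() * W.part[T.root];
    for (int j = 0; j < npat; j++)
      llcat(c, j) = (v[j] > 0 ? std::log(v[j]) : R_NegInf) + W.ls[T.root][j];
  }
  arma::rowvec ll = combine_sites(llcat, catw, pinv, invlik);
  return NumericVector(ll.begin(), ll.end());
}

// ---------------------------------------------------------------------------
// branch-length optimization: one preorder sweep per pass, Brent per edge
// ---------------------------------------------------------------------------

struct EdgeObj {
  // data for the 1-D objective of a single edge, all categories
  std::vector<arma::mat> Aex;   // per cat, k x npat (above, pi included)
  std::vector<arma::mat> down;  // per cat, k x npat
  std::vector<arma::rowvec> ls; // per cat, combined scalers
  const arma::mat *evec, *ievec; const arma::vec *evals;
  const arma::vec *catrate, *catw, *invlik, *patw;
  double pinv;
  double eval(double t) const {
    int ncat = Aex.size(), npat = Aex[0].n_cols;
    arma::mat llcat(ncat, npat);
    for (int c = 0; c < ncat; c++) {
      arma::mat P = pmat(*evec, *ievec, *evals, t * (*catrate)[c]);
      arma::mat M = P * down[c];
      arma::rowvec v = arma::sum(Aex[c] % M, 0);
      for (int j = 0; j < npat; j++)
        llcat(c, j) = (v[j] > 0 ? std::log(v[j]) : R_NegInf) + ls[c][j];
    }
    arma::rowvec sll = combine_sites(llcat, *catw, pinv, *invlik);
    return arma::dot(sll, *patw);
  }
};

// golden-section maximization on a window around the incoming length,
// expanded when the optimum sits on the window boundary; never returns a
// point worse than the incoming one
static double brent_max(const EdgeObj& f, double lo, double hi, double init,
                        double tol, double* fbest) {
  // golden-section search on log branch length (robust over the whole
  // [min_len, max_len] range), followed by the guarantee that the result is
  // never worse than the incoming length
  const double gr = 0.3819660113;
  double x0 = std::min(std::max(init, lo), hi);
  double fx0 = f.eval(x0);
  double aa = std::log(lo), bb = std::log(hi);
  double u1 = aa + gr * (bb - aa), u2 = bb - gr * (bb - aa);
  double f1 = f.eval(std::exp(u1)), f2 = f.eval(std::exp(u2));
  double utol = std::max(2e-4, tol); // relative precision on the length
  while (bb - aa > utol) {
    if (f1 < f2) { aa = u1; u1 = u2; f1 = f2; u2 = bb - gr * (bb - aa); f2 = f.eval(std::exp(u2)); }
    else         { bb = u2; u2 = u1; f2 = f1; u1 = aa + gr * (bb - aa); f1 = f.eval(std::exp(u1)); }
  }
  double xm = std::exp(0.5 * (aa + bb));
  double fm = f.eval(xm);
  if (fm >= fx0) { *fbest = fm; return xm; }
  *fbest = fx0;
  return x0;
}

// [[Rcpp::export]]
List cpp_fit_blens(IntegerVector eparent, IntegerVector echild, NumericVector elen,
                   int nnode, int ntip, int root, arma::cube tipp, arma::vec patw,
                   arma::mat Q, arma::vec pi, arma::vec catrate, arma::vec catw,
                   double pinv, arma::vec invlik, double tol, int max_passes,
                   double min_len, double max_len, double brent_tol) {
  TreeIdx T = build_tree(eparent, echild, nnode, ntip, root);
  int npat = tipp.n_cols, ncat = catrate.n_elem, k = tipp.n_rows;
  arma::mat evec, ievec; arma::vec evals;
  eigen_rev(Q, pi, evec, ievec, evals);
  NumericVector len = clone(elen);
  for (int e = 0; e < len.size(); e++)
    len[e] = std::min(std::max(len[e], min_len), max_len);

  auto total_ll = [&](std::vector<DownWork>& Ws, bool keep) {
    Ws.assign(ncat, DownWork());
    arma::mat llcat(ncat, npat);
    for (int c = 0; c < ncat; c++) {
      down_pass(T, tipp, len, catrate[c], evec, ievec, evals, Ws[c], keep);
      arma::rowvec v = pi.t() * Ws[c].part[T.root];
      for (int j = 0; j < npat; j++)
        llcat(c, j) = (v[j] > 0 ? std::log(v[j]) : R_NegInf) + Ws[c].ls[T.root][j];
    }
    arma::rowvec sll = combine_sites(llcat, catw, pinv, invlik);
    return arma::dot(sll, patw);
  };

  std::vector<DownWork> Ws;
  double cur = total_ll(Ws, true);
  double prev = cur;
  for (int pass = 0; pass < max_passes; pass++) {
    // preorder sweep; A partials (pi included) with scalers, per cat
    std::vector<std::vector<arma::mat>> A(T.nnode, std::vector<arma::mat>(ncat));
    std::vector<std::vector<arma::rowvec>> As(T.nnode, std::vector<arma::rowvec>(ncat));
    std::vector<int> stack = {T.root};
    for (int c = 0; c < ncat; c++) {
      A[T.root][c] = arma::repmat(pi, 1, npat);
      As[T.root][c] = arma::rowvec(npat, arma::fill::zeros);
    }
    while (!stack.empty()) {
      int u = stack.back(); stack.pop_back();
      for (int v : T.children[u]) {
        EdgeObj obj;
        obj.Aex.resize(ncat); obj.down.resize(ncat); obj.ls.resize(ncat);
        obj.evec = &evec; obj.ievec = &ievec; obj.evals = &evals;
        obj.catrate = &catrate; obj.catw = &catw; obj.invlik = &invlik;
        obj.patw = &patw; obj.pinv = pinv;
        for (int c = 0; c < ncat; c++) {
          arma::mat ax = A[u][c];
          arma::rowvec lsx = As[u][c];
          for (int w : T.children[u]) {
            if (w == v) continue;
            ax %= Ws[c].msg[w];
            if (w >= T.ntip) lsx += Ws[c].ls[w];
          }
          obj.Aex[c] = ax;
          obj.down[c] = (v < T.ntip) ? arma::mat(tipp.slice(v)) : Ws[c].part[v];
          obj.ls[c] = lsx + ((v < T.ntip) ? arma::rowvec(npat, arma::fill::zeros)
                                          : Ws[c].ls[v]);
        }
        double fb;
        double tnew = brent_max(obj, min_len, max_len, len[T.edge_of_child[v]],
                                brent_tol, &fb);
        len[T.edge_of_child[v]] = tnew;
        cur = fb;
        if (v >= T.ntip) {
          // update messages and A for descent with the new length
          for (int c = 0; c < ncat; c++) {
            arma::mat P = pmat(evec, ievec, evals, tnew * catrate[c]);
            Ws[c].msg[v] = P * Ws[c].part[v]; // refresh msg with new length
            arma::mat av = P.t() * obj.Aex[c];
            arma::rowvec lsv = obj.ls[c] - ((v < T.ntip) ? arma::rowvec(npat, arma::fill::zeros)
                                                        : Ws[c].ls[v]);
            arma::rowvec mx = arma::max(av, 0);
            for (int j = 0; j < npat; j++)
              if (mx[j] > 0 && mx[j] < 1e-100) { av.col(j) /= mx[j]; lsv[j] += std::log(mx[j]); }
            A[v][c] = av; As[v][c] = lsv;
          }
          stack.push_back(v);
        } else {
          for (int c = 0; c < ncat; c++) {
            arma::mat P = pmat(evec, ievec, evals, tnew * catrate[c]);
            Ws[c].msg[v] = P * tipp.slice(v);
          }
        }
      }
    }
    cur = total_ll(Ws, true); // refresh for next pass / final value
    if (cur - prev < tol && pass > 0) break;
    if (cur < prev) break; // numerical guard; keep best-so-far semantics
    prev = cur;
  }
  return List::create(_["edge_length"] = len, _["loglik"] = std::max(cur, prev));
}

// Optimize a single edge (identified by its child node), all other lengths
// fixed: used to score NNI candidates cheaply.  Returns the optimized length
// and the resulting total log-likelihood.
// [[Rcpp::export]]
List cpp_opt_edge(IntegerVector eparent, IntegerVector echild, NumericVector elen,
                  int nnode, int ntip, int root, arma::cube tipp, arma::vec patw,
                  arma::mat Q, arma::vec pi, arma::vec catrate, arma::vec catw,
                  double pinv, arma::vec invlik, int edge_child,
                  double min_len, double max_len, double brent_tol) {
  TreeIdx T = build_tree(eparent, echild, nnode, ntip, root);
  int npat = tipp.n_cols, ncat = catrate.n_elem;
  arma::mat evec, ievec; arma::vec evals;
  eigen_rev(Q, pi, evec, ievec, evals);
  int v = edge_child - 1;
  // path root -> parent(v)
  std::vector<int> parent(T.nnode, -1);
  for (int e = 0; e < (int)eparent.size(); e++) parent[echild[e] - 1] = eparent[e] - 1;
  std::vector<int> path;
  for (int u = parent[v]; u != -1; u = parent[u]) path.push_back(u);
  std::reverse(path.begin(), path.end()); // root first

  std::vector<DownWork> Ws(ncat);
  EdgeObj obj;
  obj.Aex.resize(ncat); obj.down.resize(ncat); obj.ls.resize(ncat);
  obj.evec = &evec; obj.ievec = &ievec; obj.evals = &evals;
  obj.catrate = &catrate; obj.catw = &catw; obj.invlik = &invlik;
  obj.patw = &patw; obj.pinv = pinv;
  for (int c = 0; c < ncat; c++) {
    down_pass(T, tipp, elen, catrate[c], evec, ievec, evals, Ws[c], true);
    arma::mat A = arma::repmat(pi, 1, npat);
    arma::rowvec As(npat, arma::fill::zeros);
    for (size_t i = 0; i < path.size(); i++) {
      int u = path[i];
      int nxt = (i + 1 < path.size()) ? path[i + 1] : v;
      arma::mat ax = A;
      arma::rowvec lsx = As;
      for (int w : T.children[u]) {
        if (w == nxt) continue;
        ax %= Ws[c].msg[w];
        if (w >= T.ntip) lsx += Ws[c].ls[w];
      }
      if (nxt == v && (int)i == (int)path.size() - 1) {
        obj.Aex[c] = ax;
        obj.down[c] = (v < T.ntip) ? arma::mat(tipp.slice(v)) : Ws[c].part[v];
        obj.ls[c] = lsx + ((v < T.ntip) ? arma::rowvec(npat, arma::fill::zeros)
                                        : Ws[c].ls[v]);
        break;
      }
      double t = elen[T.edge_of_child[nxt]] * catrate[c];
      arma::mat P = pmat(evec, ievec, evals, t);
      A = P.t() * ax;
      As = lsx;
      arma::rowvec mx = arma::max(A, 0);
      for (int j = 0; j < npat; j++)
        if (mx[j] > 0 && mx[j] < 1e-100) { A.col(j) /= mx[j]; As[j] += std::log(mx[j]); }
    }
  }
  double fb;
  double tnew = brent_max(obj, min_len, max_len, elen[T.edge_of_child[v]],
                          brent_tol, &fb);
  return List::create(_["length"] = tnew, _["loglik"] = fb);
}

// ---------------------------------------------------------------------------
// relaxed-clock dating MCMC on a rooted binary chronogram
// ---------------------------------------------------------------------------

struct MPart {
  int k, npat;
  arma::cube tipp;
  arma::vec patw, freqs, invlik;
  arma::vec exch;       // 6 for k=4, empty otherwise
  double alpha, pinv, mu;
  bool sample_exch;
  arma::mat evec, ievec; arma::vec evals; // current eigen
  arma::vec catrate;
  // buffers
  std::vector<std::vector<arma::mat>> P[2]; // [buf][node][cat]
  std::vector<std::vector<arma::mat>> L[2];
  arma::mat rootL[2];                       // ncat x npat, category site lik
  std::vector<int> actP, actL; int actRoot;
  std::vector<char> propP, propL; bool propRoot;
  double lnl;
};

struct MState {
  int ntip, nnode, root;
  std::vector<int> par, left, right;  // -1 where n/a
  std::vector<double> age;            // tips 0
  std::vector<double> rate;           // indexed by child node
  double sigma;
  std::vector<uint64_t> mask;
};

static void compute_masks(MState& S) {
  S.mask.assign(S.nnode, 0);
  // postorder via recursion-free: repeatedly resolve
  std::vector<int> order;
  std::vector<int> stk = {S.root};
  while (!stk.empty()) {
    int v = stk.back(); stk.pop_back();
    order.push_back(v);
    if (v >= S.ntip) { stk.push_back(S.left[v]); stk.push_back(S.right[v]); }
  }
  for (auto it = order.rbegin(); it != order.rend(); ++it) {
    int v = *it;
    if (v < S.ntip) S.mask[v] = (uint64_t)1 << v;
    else S.mask[v] = S.mask[S.left[v]] | S.mask[S.right[v]];
  }
}

static std::vector<int> postorder_internal(const MState& S) {
  std::vector<int> order, stk = {S.root};
  while (!stk.empty()) {
    int v = stk.back(); stk.pop_back();
    if (v >= S.ntip) { order.push_back(v); stk.push_back(S.left[v]); stk.push_back(S.right[v]); }
  }
  std::reverse(order.begin(), order.end());
  return order;
}

static int mrca_of(const MState& S, uint64_t m) {
  int v = S.root;
  while (v >= S.ntip) {
    if ((S.mask[S.left[v]] & m) == m) v = S.left[v];
    else if ((S.mask[S.right[v]] & m) == m) v = S.right[v];
    else break;
  }
  return v;
}

struct Calib { uint64_t mask; int family; double p1, p2; bool replace; };

// birth-death per-node age density term log(lambda * p1(t))
static inline double bd_node(double t, double lam, double mu) {
  if (mu <= 0) return std::log(lam) - lam * t;
  double r = lam - mu;
  double e = std::exp(-r * t);
  double den = lam - mu * e;
  return std::log(lam) + 2.0 * std::log(r) - r * t - 2.0 * std::log(den);
}

static double log_prior(const MState& S, const std::vector<MPart>& parts,
                        int prior_kind, double pr_lam, double pr_mu, double pr_N,
                        const std::vector<Calib>& cals, bool relaxed,
                        double sigma_rate, double mu_ml, double mu_sdl) {
  double lp = 0.0;
  // tree prior
  std::vector<double> iages;
  for (int v = S.ntip; v < S.nnode; v++) iages.push_back(S.age[v]);
  if (prior_kind == 0) { // birth-death conditioned on n, per-node factorization
    for (double t : iages) lp += bd_node(t, pr_lam, pr_mu);
  } else {               // constant-size coalescent
    std::vector<double> ev = iages;
    std::sort(ev.begin(), ev.end());
    int n = S.ntip;
    double tprev = 0.0; int kk = n;
    for (double t : ev) {
      lp += -(double)kk * (kk - 1) * (t - tprev) / (2.0 * pr_N);
      tprev = t; kk--;
    }
    lp -= (n - 1) * std::log(pr_N);
  }
  // calibrations (replace the per-node tree-prior factor where possible)
  for (const Calib& c : cals) {
    int v = mrca_of(S, c.mask);
    double t = S.age[v];
    double ld;
    if (c.family == 0) ld = (t >= c.p1 && t <= c.p2) ? -std::log(c.p2 - c.p1) : R_NegInf;
    else if (c.family == 1) ld = R::dnorm(t, c.p1, c.p2, 1); // truncation const fixed
    else ld = R::dlnorm(t, c.p1, c.p2, 1);
    lp += ld;
    if (c.replace && prior_kind == 0) lp -= bd_node(t, pr_lam, pr_mu);
  }
  // clock
  if (relaxed) {
    double ml = -0.5 * S.sigma * S.sigma;
    for (int v = 0; v < S.nnode; v++) {
      if (v == S.root) continue;
      lp += R::dlnorm(S.rate[v], ml, S.sigma, 1);
    }
    lp += R::dexp(S.sigma, 1.0 / sigma_rate, 1);
  }
  // substitution / rate-multiplier hyperpriors
  for (const MPart& pt : parts) {
    lp += R::dlnorm(pt.mu, mu_ml, mu_sdl, 1);
    lp += R::dlnorm(pt.alpha, 0.0, 1.0, 1);
    if (pt.pinv < 0 || pt.pinv > 0.8) lp += R_NegInf;
    if (pt.sample_exch)
      for (int i = 0; i < 5; i++) lp += R::dlnorm(pt.exch[i], 0.0, 1.25, 1);
  }
  return lp;
}

static arma::mat build_gtr_q(const arma::vec& exch, const arma::vec& pi) {
  int k = pi.n_elem;
  arma::mat Q(k, k, arma::fill::zeros);
  if (k == 4) {
    int idx = 0;
    for (int i = 0; i < 4; i++)
      for (int j = i + 1; j < 4; j++) {
        Q(i, j) = exch[idx] * pi[j];
        Q(j, i) = exch[idx] * pi[i];
        idx++;
      }
  } else { // 2-state
    Q(0, 1) = pi[1]; Q(1, 0) = pi[0];
  }
  for (int i = 0; i < k; i++) Q(i, i) = -arma::accu(Q.row(i));
  double sc = -arma::dot(pi, Q.diag());
  Q /= sc;
  return Q;
}

// recompute likelihood of one partition given dirty P nodes and dirty L nodes
// (dirtyL sorted children-before-parents, must end at root unless empty)
static double part_update(MPart& pt, const MState& S,
                          const std::vector<int>& dirtyP,
                          const std::vector<int>& dirtyL,
                          const std::vector<int>& post) {
  int ncat = pt.catrate.n_elem;
  for (int v : dirtyP) {
    if (v == S.root) continue;
    double blen = pt.mu * S.rate[v] * (S.age[S.par[v]] - S.age[v]);
    if (blen < 0) blen = 0;
    int ib = 1 - pt.actP[v];
    for (int c = 0; c < ncat; c++)
      pt.P[ib][v][c] = pmat(pt.evec, pt.ievec, pt.evals, blen * pt.catrate[c]);
    pt.propP[v] = 1;
  }
  for (int v : dirtyL) {
    int ib = 1 - pt.actL[v];
    for (int c = 0; c < ncat; c++) {
      arma::mat acc(pt.k, pt.npat, arma::fill::ones);
      int ch[2] = {S.left[v], S.right[v]};
      for (int ci = 0; ci < 2; ci++) {
        int w = ch[ci];
        const arma::mat& P = pt.propP[w] ? pt.P[1 - pt.actP[w]][w][c]
                                         : pt.P[pt.actP[w]][w][c];
        if (w < S.ntip) acc %= P * pt.tipp.slice(w);
        else {
          const arma::mat& Lw = pt.propL[w] ? pt.L[1 - pt.actL[w]][w][c]
                                            : pt.L[pt.actL[w]][w][c];
          acc %= P * Lw;
        }
      }
      pt.L[ib][v][c] = acc;
    }
    pt.propL[v] = 1;
  }
  // root combine into rootL buffer
  int rb = 1 - pt.actRoot;
  const std::vector<arma::mat>& Lr = pt.propL[S.root] ? pt.L[1 - pt.actL[S.root]][S.root]
                                                      : pt.L[pt.actL[S.root]][S.root];
  for (int c = 0; c < ncat; c++)
    pt.rootL[rb].row(c) = pt.freqs.t() * Lr[c];
  pt.propRoot = true;
  // total
  double ll = 0.0;
  int ncat2 = ncat;
  for (int j = 0; j < pt.npat; j++) {
    double s = pt.pinv * pt.invlik[j];
    for (int c = 0; c < ncat2; c++)
      s += (1.0 - pt.pinv) * (1.0 / ncat2) * pt.rootL[rb](c, j);
    ll += pt.patw[j] * (s > 0 ? std::log(s) : -1e300);
  }
  (void)post;
  return ll;
}

static double part_recombine(MPart& pt, double pinv_new) {
  const arma::mat& rl = pt.rootL[pt.actRoot];
  int ncat = rl.n_rows;
  double ll = 0.0;
  for (int j = 0; j < pt.npat; j++) {
    double s = pinv_new * pt.invlik[j];
    for (int c = 0; c < ncat; c++)
      s += (1.0 - pinv_new) * (1.0 / ncat) * rl(c, j);
    ll += pt.patw[j] * (s > 0 ? std::log(s) : -1e300);
  }
  return ll;
}

static void part_accept(MPart& pt) {
  for (size_t v = 0; v < pt.propP.size(); v++) {
    if (pt.propP[v]) { pt.actP[v] = 1 - pt.actP[v]; pt.propP[v] = 0; }
    if (pt.propL[v]) { pt.actL[v] = 1 - pt.actL[v]; pt.propL[v] = 0; }
  }
  if (pt.propRoot) { pt.actRoot = 1 - pt.actRoot; pt.propRoot = false; }
}

static void part_reject(MPart& pt) {
  std::fill(pt.propP.begin(), pt.propP.end(), 0);
  std::fill(pt.propL.begin(), pt.propL.end(), 0);
  pt.propRoot = false;
}

// [[Rcpp::export]]
List cpp_dating_mcmc(List tree, List partitions, List clock, List prior,
                     List calibrations, List constraints, List config) {
  // --- unpack tree ---
  MState S;
  S.ntip = as<int>(tree["ntip"]);
  S.nnode = as<int>(tree["nnode"]);
  S.root = as<int>(tree["root"]) - 1;
  IntegerVector par = tree["parent"], lf = tree["left"], rt = tree["right"];
  NumericVector ag = tree["age"];
  S.par.assign(par.begin(), par.end());
  S.left.assign(lf.begin(), lf.end());
  S.right.assign(rt.begin(), rt.end());
  for (auto& x : S.par) x -= 1;
  for (auto& x : S.left) x -= 1;
  for (auto& x : S.right) x -= 1;
  S.age.assign(ag.begin(), ag.end());
  compute_masks(S);

  bool relaxed = as<bool>(clock["relaxed"]);
  S.sigma = as<double>(clock["sigma"]);
  double sigma_rate = as<double>(clock["sigma_prior_rate"]);
  NumericVector r0 = clock["rates"];
  S.rate.assign(r0.begin(), r0.end());

  int prior_kind = as<int>(prior["kind"]); // 0 bd, 1 coalescent
  double pr_lam = as<double>(prior["birth"]);
  double pr_mu = as<double>(prior["death"]);
  double pr_N = as<double>(prior["N"]);
  double mu_ml = as<double>(prior["mu_meanlog"]);
  double mu_sdl = as<double>(prior["mu_sdlog"]);

  std::vector<Calib> cals;
  for (int i = 0; i < calibrations.size(); i++) {
    List cl = calibrations[i];
    Calib c;
    IntegerVector tipsIdx = cl["tips"];
    c.mask = 0;
    for (int t : tipsIdx) c.mask |= (uint64_t)1 << (t - 1);
    c.family = as<int>(cl["family"]);
    c.p1 = as<double>(cl["p1"]); c.p2 = as<double>(cl["p2"]);
    c.replace = as<bool>(cl["replace"]);
    cals.push_back(c);
  }
  std::vector<uint64_t> cons;
  for (int i = 0; i < constraints.size(); i++) {
    IntegerVector tipsIdx = constraints[i];
    uint64_t m = 0;
    for (int t : tipsIdx) m |= (uint64_t)1 << (t - 1);
    cons.push_back(m);
  }

  int ngen = as<int>(config["generations"]);
  int sample_every = as<int>(config["sample_every"]);
  bool prior_only = as<bool>(config["prior_only"]);
  bool topo_moves = as<bool>(config["topology_moves"]);
  bool sample_mu = as<bool>(config["sample_mu"]);
  bool sample_model = as<bool>(config["sample_model"]);
  int ncat = as<int>(config["ncat"]);
  List trackedL = config["tracked"];
  std::vector<uint64_t> tracked;
  for (int i = 0; i < trackedL.size(); i++) {
    IntegerVector tipsIdx = trackedL[i];
    uint64_t m = 0;
    for (int t : tipsIdx) m |= (uint64_t)1 << (t - 1);
    tracked.push_back(m);
  }

  // --- unpack partitions ---
  std::vector<MPart> parts;
  for (int i = 0; i < partitions.size(); i++) {
    List pl = partitions[i];
    MPart pt;
    pt.tipp = as<arma::cube>(pl["tipp"]);
    pt.k = pt.tipp.n_rows; pt.npat = pt.tipp.n_cols;
    pt.patw = as<arma::vec>(pl["patw"]);
    pt.freqs = as<arma::vec>(pl["freqs"]);
    pt.invlik = as<arma::vec>(pl["invlik"]);
    pt.exch = as<arma::vec>(pl["exch"]);
    pt.alpha = as<double>(pl["alpha"]);
    pt.pinv = as<double>(pl["pinv"]);
    pt.mu = as<double>(pl["mu"]);
    pt.sample_exch = as<bool>(pl["sample_exch"]) && pt.k == 4;
    arma::mat Q = build_gtr_q(pt.exch, pt.freqs);
    eigen_rev(Q, pt.freqs, pt.evec, pt.ievec, pt.evals);
    pt.catrate = gamma_rates_cpp(pt.alpha, ncat, false) / (1.0 - pt.pinv);
    for (int b = 0; b < 2; b++) {
      pt.P[b].assign(S.nnode, std::vector<arma::mat>(ncat));
      pt.L[b].assign(S.nnode, std::vector<arma::mat>(ncat));
      pt.rootL[b].set_size(ncat, pt.npat);
    }
    pt.actP.assign(S.nnode, 0); pt.actL.assign(S.nnode, 0); pt.actRoot = 0;
    pt.propP.assign(S.nnode, 0); pt.propL.assign(S.nnode, 0); pt.propRoot = false;
    parts.push_back(std::move(pt));
  }

  std::vector<int> post = postorder_internal(S);
  std::vector<int> allnodes;
  for (int v = 0; v < S.nnode; v++) allnodes.push_back(v);

  // initial full computation
  double lnl = 0.0;
  if (!prior_only) {
    for (auto& pt : parts) {
      double l = part_update(pt, S, allnodes, post, post);
      part_accept(pt);
      pt.lnl = l;
      lnl += l;
    }
  } else for (auto& pt : parts) pt.lnl = 0.0;
  double lpr = log_prior(S, parts, prior_kind, pr_lam, pr_mu, pr_N, cals,
                         relaxed, sigma_rate, mu_ml, mu_sdl);
  if (!R_finite(lpr)) stop("initial state has zero prior probability");

  // move schedule
  // 0 age, 1 root, 2 rate, 3 sigma, 4 mu, 5 alpha, 6 pinv, 7 exch, 8 topo
  std::vector<int> mtype; std::vector<int> mtarget; std::vector<double> mw;
  for (int v = S.ntip; v < S.nnode; v++)
    if (v != S.root) { mtype.push_back(0); mtarget.push_back(v); mw.push_back(1.0); }
  mtype.push_back(1); mtarget.push_back(S.root); mw.push_back(3.0);
  if (relaxed)
    for (int v = 0; v < S.nnode; v++)
      if (v != S.root) { mtype.push_back(2); mtarget.push_back(v); mw.push_back(1.0); }
  if (relaxed) { mtype.push_back(3); mtarget.push_back(0); mw.push_back(3.0); }
  for (size_t p = 0; p < parts.size(); p++) {
    if (sample_mu) { mtype.push_back(4); mtarget.push_back(p); mw.push_back(1.5); }
    if (sample_model) {
      mtype.push_back(5); mtarget.push_back(p); mw.push_back(1.5);
      mtype.push_back(6); mtarget.push_back(p); mw.push_back(1.5);
      if (parts[p].sample_exch) { mtype.push_back(7); mtarget.push_back(p); mw.push_back(2.0); }
    }
  }
  if (topo_moves) {
    mtype.push_back(8); mtarget.push_back(0);
    mw.push_back(std::max(2.0, (S.nnode - S.ntip) / 2.0));
  }
  // subtree-scale moves (decorrelate clade depth from rates)
  for (int v = S.ntip; v < S.nnode; v++) {
    mtype.push_back(9); mtarget.push_back(v); mw.push_back(0.5);
  }
  std::vector<double> cum(mw.size());
  std::partial_sum(mw.begin(), mw.end(), cum.begin());
  double wtot = cum.back();

  int nsamp = ngen / sample_every;
  int ntracked = tracked.size();
  int npt = parts.size();
  // trace: state lnl lpr sigma root_age, mu[], alpha[], pinv[], tracked[]
  int ncol_tr = 5 + 3 * npt + ntracked;
  NumericMatrix traceM(nsamp, ncol_tr);
  NumericMatrix agesM(nsamp, S.nnode - S.ntip);
  IntegerMatrix parM(nsamp, S.nnode);
  std::vector<long> acc(10, 0), tot(10, 0);

  GetRNGstate();
  int isamp = 0;
  for (int gen = 1; gen <= ngen; gen++) {
    double u = unif_rand() * wtot;
    int mi = std::lower_bound(cum.begin(), cum.end(), u) - cum.begin();
    if (mi >= (int)mtype.size()) mi = mtype.size() - 1;
    int ty = mtype[mi], tg = mtarget[mi];
    tot[ty]++;
    double logH = 0.0;
    bool need_lik = !prior_only;
    std::vector<int> dirtyP, dirtyL;
    bool all_parts = true; int one_part = -1;
    // saved scalars for restore
    double sv1 = 0, sv2 = 0; int svi = -1;
    arma::vec sv_exch, sv_catrate;
    arma::mat sv_evec, sv_ievec; arma::vec sv_evals;
    // topology backup
    int t_g = -1, t_p = -1, t_a = -1, t_x = -1;
    // subtree-scale backup
    std::vector<int> sv_nodes; std::vector<double> sv_ages;

    bool feasible = true;
    if (ty == 0) {
      int v = tg;
      double lo = std::max(S.age[S.left[v]], S.age[S.right[v]]);
      double hi = S.age[S.par[v]];
      sv1 = S.age[v]; svi = v;
      S.age[v] = lo + unif_rand() * (hi - lo);
      dirtyP = {v, S.left[v], S.right[v]};
      for (int w = v; w != -1; w = S.par[w]) dirtyL.push_back(w);
    } else if (ty == 1) {
      int v = S.root;
      double c = std::exp(0.25 * (unif_rand() - 0.5));
      sv1 = S.age[v]; svi = v;
      double lo = std::max(S.age[S.left[v]], S.age[S.right[v]]);
      S.age[v] = sv1 * c;
      logH = std::log(c);
      if (S.age[v] <= lo) feasible = false;
      dirtyP = {S.left[v], S.right[v]};
      dirtyL = {v};
    } else if (ty == 2) {
      int v = tg;
      double c = std::exp(1.0 * (unif_rand() - 0.5));
      sv1 = S.rate[v]; svi = v;
      S.rate[v] = sv1 * c;
      logH = std::log(c);
      dirtyP = {v};
      for (int w = S.par[v]; w != -1; w = S.par[w]) dirtyL.push_back(w);
    } else if (ty == 3) {
      double c = std::exp(0.8 * (unif_rand() - 0.5));
      sv1 = S.sigma;
      S.sigma = sv1 * c;
      logH = std::log(c);
      need_lik = false;
    } else if (ty == 4) {
      MPart& pt = parts[tg];
      double c = std::exp(0.5 * (unif_rand() - 0.5));
      sv1 = pt.mu; pt.mu = sv1 * c; logH = std::log(c);
      all_parts = false; one_part = tg;
      dirtyP = allnodes; dirtyL = post;
    } else if (ty == 5) {
      MPart& pt = parts[tg];
      double c = std::exp(0.7 * (unif_rand() - 0.5));
      sv1 = pt.alpha; sv_catrate = pt.catrate;
      pt.alpha = sv1 * c; logH = std::log(c);
      pt.catrate = gamma_rates_cpp(pt.alpha, ncat, false) / (1.0 - pt.pinv);
      all_parts = false; one_part = tg;
      dirtyP = allnodes; dirtyL = post;
    } else if (ty == 6) {
      MPart& pt = parts[tg];
      double w = 0.08;
      sv1 = pt.pinv; sv_catrate = pt.catrate;
      double x = sv1 + w * (unif_rand() - 0.5);
      while (x < 0 || x > 0.8) { if (x < 0) x = -x; if (x > 0.8) x = 1.6 - x; }
      pt.pinv = x;
      pt.catrate = gamma_rates_cpp(pt.alpha, ncat, false) / (1.0 - x);
      all_parts = false; one_part = tg;
      dirtyP = allnodes; dirtyL = post;
    } else if (ty == 7) {
      MPart& pt = parts[tg];
      int i = (int)(unif_rand() * 5); if (i > 4) i = 4;
      double c = std::exp(0.7 * (unif_rand() - 0.5));
      sv_exch = pt.exch; sv_evec = pt.evec; sv_ievec = pt.ievec; sv_evals = pt.evals;
      pt.exch[i] *= c; logH = std::log(c);
      arma::mat Q = build_gtr_q(pt.exch, pt.freqs);
      eigen_rev(Q, pt.freqs, pt.evec, pt.ievec, pt.evals);
      all_parts = false; one_part = tg;
      dirtyP = allnodes; dirtyL = post;
    } else if (ty == 9) { // scale all internal ages within the subtree at tg
      int v = tg;
      double c = std::exp(0.3 * (unif_rand() - 0.5));
      std::vector<int> sub, stk2 = {v};
      while (!stk2.empty()) {
        int w = stk2.back(); stk2.pop_back();
        if (w >= S.ntip) { sub.push_back(w); stk2.push_back(S.left[w]); stk2.push_back(S.right[w]); }
      }
      if (v != S.root && S.age[v] * c >= S.age[S.par[v]]) {
        feasible = false;
      } else {
        sv_nodes = sub;
        for (int w : sub) { sv_ages.push_back(S.age[w]); S.age[w] *= c; }
        logH = sub.size() * std::log(c);
        dirtyP = allnodes; dirtyL = post;
      }
    } else { // topology: narrow exchange
      // pick internal non-root node p with parent g
      std::vector<int> cand;
      for (int v = S.ntip; v < S.nnode; v++) if (v != S.root) cand.push_back(v);
      int pnode = cand[std::min((int)(unif_rand() * cand.size()), (int)cand.size() - 1)];
      int g = S.par[pnode];
      int aunt = (S.left[g] == pnode) ? S.right[g] : S.left[g];
      int x = (unif_rand() < 0.5) ? S.left[pnode] : S.right[pnode];
      if (S.age[pnode] <= S.age[aunt]) feasible = false;
      else {
        t_g = g; t_p = pnode; t_a = aunt; t_x = x;
        // swap: aunt under pnode, x under g
        if (S.left[g] == aunt) S.left[g] = x; else S.right[g] = x;
        if (S.left[pnode] == x) S.left[pnode] = aunt; else S.right[pnode] = aunt;
        S.par[x] = g; S.par[aunt] = pnode;
        compute_masks(S);
        for (uint64_t cm : cons) {
          bool ok = false;
          for (int v = 0; v < S.nnode; v++) if (S.mask[v] == cm) { ok = true; break; }
          if (!ok) { feasible = false; break; }
        }
        if (feasible) {
          post = postorder_internal(S);
          dirtyP = allnodes; dirtyL = post;
        }
      }
    }

    bool accepted = false;
    if (feasible) {
      double new_lnl = lnl;
      if (need_lik) {
        if (all_parts) {
          new_lnl = 0.0;
          for (auto& pt : parts) {
            double l = part_update(pt, S, dirtyP, dirtyL, post);
            sv2 = l; // per-part values handled on accept below via recompute
            new_lnl += l;
          }
        } else {
          MPart& pt = parts[one_part];
          double l = part_update(pt, S, dirtyP, dirtyL, post);
          new_lnl = lnl - pt.lnl + l;
          sv2 = l;
        }
      }
      double new_lpr = log_prior(S, parts, prior_kind, pr_lam, pr_mu, pr_N, cals,
                                 relaxed, sigma_rate, mu_ml, mu_sdl);
      double lratio = (new_lnl - lnl) + (new_lpr - lpr) + logH;
      if (R_finite(lratio) && (lratio >= 0 || std::log(unif_rand()) < lratio)) {
        accepted = true;
        if (need_lik) {
          if (all_parts) {
            double tt = 0;
            for (auto& pt : parts) { part_accept(pt); }
            // recompute cached per-part lnl values from buffers
            for (auto& pt : parts) { double l = part_recombine(pt, pt.pinv); pt.lnl = l; tt += l; }
            new_lnl = tt;
          } else {
            part_accept(parts[one_part]);
            parts[one_part].lnl = sv2;
          }
        }
        lnl = new_lnl; lpr = new_lpr;
        acc[ty]++;
      }
    }
    if (!accepted) {
      // restore
      if (ty == 0 || ty == 1) S.age[svi] = sv1;
      else if (ty == 2) S.rate[svi] = sv1;
      else if (ty == 3) S.sigma = sv1;
      else if (ty == 4) parts[tg].mu = sv1;
      else if (ty == 5) { parts[tg].alpha = sv1; parts[tg].catrate = sv_catrate; }
      else if (ty == 6) { parts[tg].pinv = sv1; parts[tg].catrate = sv_catrate; }
      else if (ty == 7) {
        parts[tg].exch = sv_exch; parts[tg].evec = sv_evec;
        parts[tg].ievec = sv_ievec; parts[tg].evals = sv_evals;
      } else if (ty == 9) {
        for (size_t i = 0; i < sv_nodes.size(); i++) S.age[sv_nodes[i]] = sv_ages[i];
      } else if (ty == 8 && t_g >= 0) {
        // undo swap
        if (S.left[t_g] == t_x) S.left[t_g] = t_a; else if (S.right[t_g] == t_x) S.right[t_g] = t_a;
        if (S.left[t_p] == t_a) S.left[t_p] = t_x; else if (S.right[t_p] == t_a) S.right[t_p] = t_x;
        S.par[t_x] = t_p; S.par[t_a] = t_g;
        compute_masks(S);
        post = postorder_internal(S);
      }
      for (auto& pt : parts) part_reject(pt);
    }

    if (gen % sample_every == 0) {
      int col = 0;
      traceM(isamp, col++) = gen;
      traceM(isamp, col++) = lnl;
      traceM(isamp, col++) = lpr;
      traceM(isamp, col++) = S.sigma;
      traceM(isamp, col++) = S.age[S.root];
      for (auto& pt : parts) traceM(isamp, col++) = pt.mu;
      for (auto& pt : parts) traceM(isamp, col++) = pt.alpha;
      for (auto& pt : parts) traceM(isamp, col++) = pt.pinv;
      for (uint64_t m : tracked) traceM(isamp, col++) = S.age[mrca_of(S, m)];
      for (int v = S.ntip; v < S.nnode; v++) agesM(isamp, v - S.ntip) = S.age[v];
      for (int v = 0; v < S.nnode; v++) parM(isamp, v) = S.par[v] + 1;
      isamp++;
    }
  }
  PutRNGstate();

  NumericVector accr(10), totr(10);
  for (int i = 0; i < 10; i++) { accr[i] = acc[i]; totr[i] = tot[i]; }
  return List::create(_["trace"] = traceM, _["ages"] = agesM, _["parent"] = parM,
                      _["accept"] = accr, _["proposed"] = totr,
                      _["final_lnl"] = lnl, _["final_lpr"] = lpr);
}
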