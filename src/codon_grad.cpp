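// Mixture log-likelihood with analytic branch-length gradient.
//
// Upward (Felsenstein) pass stores per-edge messages C_e = P_e U_child and
// per-node scaled partials; a downward pass builds the complement partial
// E_e at each edge, giving dL/dt_e = E_e' Q_e P_e U_child = E_e' Q_e C_e
// (since dP/dt = Q P). All quantities carry per-site log-scalers to avoid
// underflow; gradients are assembled on the probability scale through
// exp(scale - site log-likelihood), which is bounded.

// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>
using namespace arma;

namespace {

struct Spec2 {
  vec d;
  mat V;
  mat W;
};

void fill_q2(mat &Q, const ivec &pi_i, const ivec &pi_j, const ivec &ptype,
             const vec &pi, double kappa, double omega) {
  Q.zeros();
  const double mult[4] = {1.0, kappa, omega, omega * kappa};
  for (uword k = 0; k < pi_i.n_elem; ++k)
    Q(pi_i[k], pi_j[k]) = mult[ptype[k]] * pi[pi_j[k]];
  Q.diag() = -sum(Q, 1);
}

Spec2 decompose2(const mat &Q, const vec &sq, const vec &isq) {
  mat S = (Q.each_col() % sq).each_row() % isq.t();
  S = (S + S.t()) / 2.0;
  Spec2 sp;
  mat U;
  eig_sym(sp.d, U, S);
  sp.V = U.each_col() % isq;
  sp.W = (U.each_col() % sq).t();
  return sp;
}

mat pmat(const Spec2 &sp, double t) {
  vec et = exp(sp.d * t);
  mat P = sp.V * (sp.W.each_col() % et);
  P.for_each([](double &v) { if (v < 0.0) v = 0.0; });
  return P;
}

} // namespace

// Returns list(lnl = weighted total mixture log-likelihood,
//              grad = d lnl / d t_e for every edge (postorder order),
//              site_loglik = per-pattern mixture log-likelihood).
// Arguments as in cpp_site_loglik_cols, plus class proportions `props`
// and per-pattern counts `weights`.
// [[Rcpp::export]]
Rcpp::List cpp_mix_loglik_grad(const arma::imat &tips,
                               const arma::ivec &parent,
                               const arma::ivec &child,
                               const arma::vec &elen,
                               const arma::ivec &efg,
                               const int n_node,
                               const int root,
                               const arma::vec &pi,
                               const double kappa,
                               const arma::mat &omegas,
                               const arma::vec &props,
                               const arma::vec &weights,
                               const arma::ivec &pair_i,
                               const arma::ivec &pair_j,
                               const arma::ivec &pair_type) {
  const int n = pi.n_elem;
  const int S = tips.n_cols;
  const int n_tip = tips.n_rows;
  const int K = omegas.n_rows;
  const int n_edge = parent.n_elem;

  vec sq = sqrt(pi), isq = 1.0 / sq;
  mat Qtmp(n, n);
  fill_q2(Qtmp, pair_i, pair_j, pair_type, pi, kappa, 1.0);
  const double mu1 = -dot(pi, Qtmp.diag());
  if (!(mu1 > 0)) Rcpp::stop("degenerate rate matrix: zero neutral rate");
  const bool any_fg = arma::any(efg > 0);

  // children edge lists per node (postorder edge indices)
  std::vector<std::vector<int>> kids(n_node);
  for (int e = 0; e < n_edge; ++e) kids[parent[e]].push_back(e);

  mat class_ll(S, K);          // log L_{h|k}
  // per-class storage for the downward pass
  std::vector<std::vector<mat>> Cs(K, std::vector<mat>(n_edge));
  std::vector<std::vector<mat>> Us(K, std::vector<mat>(n_node));
  std::vector<std::vector<vec>> Ss(K, std::vector<vec>(n_node));
  std::vector<std::vector<mat>> Qb(K), Qf(K); // per-class Q (bg, fg)
  std::vector<mat> Pb(n_edge), Pf(n_edge);    // reused per class
  std::vector<std::vector<mat>> Pall(K, std::vector<mat>(n_edge));
  std::vector<std::vector<char>> two_of(K);

  for (int k = 0; k < K; ++k) {
    const double wb = omegas(k, 0), wf = omegas(k, 1);
    mat Qbk(n, n), Qfk(n, n);
    fill_q2(Qbk, pair_i, pair_j, pair_type, pi, kappa, wb);
    Qbk /= mu1;
    Spec2 sb = decompose2(Qbk, sq, isq);
    const bool two = any_fg && wf != wb;
    Spec2 sf;
    if (two) {
      fill_q2(Qfk, pair_i, pair_j, pair_type, pi, kappa, wf);
      Qfk /= mu1;
      sf = decompose2(Qfk, sq, isq);
    } else Qfk = Qbk;
    Qb[k].push_back(Qbk);
    Qf[k].push_back(Qfk);

    // upward pass over postorder edges, accumulating into parents
    std::vector<char> started(n_node, 0);
    for (int e = 0; e < n_edge; ++e) {
      const bool fg = two && efg[e];
      mat P = pmat(fg ? sf : sb, elen[e]);
      Pall[k][e] = P;
      const int ch = child[e], pa = parent[e];
      mat C(n, S);
      if (ch < n_tip) {
        const vec ones_col(n, fill::ones);
        for (int h = 0; h < S; ++h) {
          const int st = tips(ch, h);
          C.col(h) = (st < 0) ? ones_col : P.col(st);
        }
      } else {
        C = P * Us[k][ch];
      }
      Cs[k][e] = std::move(C);
      if (!started[pa]) {
        Us[k][pa] = Cs[k][e];
        Ss[k][pa] = (ch < n_tip) ? vec(S, fill::zeros) : Ss[k][ch];
        started[pa] = 1;
      } else {
        Us[k][pa] %= Cs[k][e];
        if (ch >= n_tip) Ss[k][pa] += Ss[k][ch];
      }
      // rescale parent partial after each combination
      rowvec cs = sum(Us[k][pa], 0);
      for (int h = 0; h < S; ++h) {
        if (std::isnan(cs[h]))
          Rcpp::stop("numeric failure in pruning at site %d", h + 1);
        if (cs[h] <= 0.0) cs[h] = 1.0; // zero partial: log stays -inf via U=0
      }
      Us[k][pa].each_row() /= cs;
      Ss[k][pa] += log(cs.t());
    }
    vec L = Us[k][root].t() * pi;
    for (int h = 0; h < S; ++h)
      class_ll(h, k) = (L[h] > 0.0) ? std::log(L[h]) + Ss[k][root][h]
                                    : -datum::inf;
  }

  // mixture per site
  vec site_ll(S);
  vec lp = log(props);
  for (int h = 0; h < S; ++h) {
    double m = -datum::inf;
    for (int k = 0; k < K; ++k)
      m = std::max(m, class_ll(h, k) + lp[k]);
    if (!std::isfinite(m)) { site_ll[h] = -datum::inf; continue; }
    double s = 0;
    for (int k = 0; k < K; ++k)
      s += std::exp(class_ll(h, k) + lp[k] - m);
    site_ll[h] = m + std::log(s);
  }
  double total = dot(weights, site_ll);

  // downward pass + gradient
  vec grad(n_edge, fill::zeros);
  for (int k = 0; k < K; ++k) {
    if (props[k] <= 0) continue;
    std::vector<mat> D(n_node);
    std::vector<vec> R(n_node);
    D[root] = repmat(pi, 1, S);
    R[root] = vec(S, fill::zeros);
    // preorder: postorder edges reversed visit parents before children
    for (int e = n_edge - 1; e >= 0; --e) {
      const int pa = parent[e], ch = child[e];
      // complement E_e = D_pa * prod of sibling messages
      mat E = D[pa];
      vec scl = R[pa];
      for (int e2 : kids[pa]) {
        if (e2 == e) continue;
        E %= Cs[k][e2];
        const int c2 = child[e2];
        if (c2 >= n_tip) scl += Ss[k][c2];
      }
      // gradient: sum_x E(x,h) * (Q C_e)(x,h)
      const mat &Quse = (any_fg && efg[e] &&
                         omegas(k, 1) != omegas(k, 0)) ? Qf[k][0] : Qb[k][0];
      mat G = Quse * Cs[k][e];
      rowvec dot_h = sum(E % G, 0);
      vec sc_child = (ch < n_tip) ? vec(S, fill::zeros) : Ss[k][ch];
      for (int h = 0; h < S; ++h) {
        if (!std::isfinite(site_ll[h])) continue;
        double f = std::exp(scl[h] + sc_child[h] + lp[k] - site_ll[h]);
        grad[e] += weights[h] * dot_h[h] * f;
      }
      // recurse downward into internal children
      if (ch >= n_tip) {
        mat Dc = Pall[k][e].t() * E;
        rowvec cs = sum(Dc, 0);
        for (int h = 0; h < S; ++h) if (cs[h] <= 0.0 || std::isnan(cs[h])) cs[h] = 1.0;
        Dc.each_row() /= cs;
        D[ch] = std::move(Dc);
        R[ch] = scl + log(cs.t());
      }
    }
  }

  return Rcpp::List::create(Rcpp::Named("lnl") = total,
                            Rcpp::Named("grad") = grad,
                            Rcpp::Named("site_loglik") = site_ll,
                            Rcpp::Named("class_loglik") = class_ll);
}
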