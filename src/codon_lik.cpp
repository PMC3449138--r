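// Pruning-algorithm likelihood kernel for GY94-style codon site-class models.
//
// States are the 61 sense codons (T<C<A<G lexicographic order). Each site
// class is a (omega_background, omega_foreground) pair; non-branch-site
// classes have the two equal. All rate matrices are scaled by the mean rate
// at omega = 1 so one shared scale applies across classes of a model and a
// class column depends on (kappa, omega) only.
//
// Tip states are indicator vectors, so tip-edge contributions are gathered
// as transition-matrix columns instead of GEMMs; missing tips contribute a
// partial of ones (marginalised over all sense codons).

// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>
using namespace arma;

namespace {

struct Spectral {
  vec d;   // eigenvalues
  mat V;   // diag(1/sqrt(pi)) * U
  mat W;   // U' * diag(sqrt(pi));  P(t) = V * diag(exp(d t)) * W
};

void fill_q(mat &Q, const ivec &pi_i, const ivec &pi_j, const ivec &ptype,
            const vec &pi, double kappa, double omega) {
  Q.zeros();
  const double mult[4] = {1.0, kappa, omega, omega * kappa};
  for (uword k = 0; k < pi_i.n_elem; ++k)
    Q(pi_i[k], pi_j[k]) = mult[ptype[k]] * pi[pi_j[k]];
  Q.diag() = -sum(Q, 1);
}

// clip tiny negative round-off from the spectral reconstruction of exp(Qt)
inline void clip_nonneg(mat &M) {
  M.for_each([](double &v) { if (v < 0.0) v = 0.0; });
}

Spectral decompose(const mat &Q, const vec &sq, const vec &isq) {
  mat S = (Q.each_col() % sq).each_row() % isq.t();
  S = (S + S.t()) / 2.0;
  Spectral sp;
  mat U;
  eig_sym(sp.d, U, S);
  sp.V = U.each_col() % isq;
  sp.W = (U.each_col() % sq).t();
  return sp;
}

} // namespace

// Per-site, per-class log-likelihood columns.
// tips:    n_tip x S integer matrix, 0-based sense-codon states, -1 = missing
// parent, child, elen, efg: postorder edge arrays (0-based node ids; tips
//          0..n_tip-1 in alignment row order, root = n_tip)
// omegas:  K x 2 matrix (omega_background, omega_foreground)
// pair_*:  single-nucleotide-difference codon pairs (0-based) with type
//          0 syn tv, 1 syn ts, 2 nonsyn tv, 3 nonsyn ts
// Returns S x K matrix log L_{h|k}.
// [[Rcpp::export]]
arma::mat cpp_site_loglik_cols(const arma::imat &tips,
                               const arma::ivec &parent,
                               const arma::ivec &child,
                               const arma::vec &elen,
                               const arma::ivec &efg,
                               const int n_node,
                               const int root,
                               const arma::vec &pi,
                               const double kappa,
                               const arma::mat &omegas,
                               const arma::ivec &pair_i,
                               const arma::ivec &pair_j,
                               const arma::ivec &pair_type) {
  const int n = pi.n_elem;
  const int S = tips.n_cols;
  const int n_tip = tips.n_rows;
  const int K = omegas.n_rows;
  const int n_edge = parent.n_elem;

  vec sq = sqrt(pi), isq = 1.0 / sq;
  mat Q(n, n);
  fill_q(Q, pair_i, pair_j, pair_type, pi, kappa, 1.0);
  const double mu1 = -dot(pi, Q.diag());
  if (!(mu1 > 0)) Rcpp::stop("degenerate rate matrix: zero neutral rate");

  const bool any_fg = arma::any(efg > 0);
  mat out(S, K);

  for (int k = 0; k < K; ++k) {
    const double wb = omegas(k, 0), wf = omegas(k, 1);
    fill_q(Q, pair_i, pair_j, pair_type, pi, kappa, wb);
    Q /= mu1;
    Spectral sb = decompose(Q, sq, isq);
    Spectral sf;
    const bool two = any_fg && wf != wb;
    if (two) {
      fill_q(Q, pair_i, pair_j, pair_type, pi, kappa, wf);
      Q /= mu1;
      sf = decompose(Q, sq, isq);
    }

    std::vector<mat> part(n_node);
    std::vector<char> started(n_node, 0);
    vec scaler(S, fill::zeros);

    for (int e = 0; e < n_edge; ++e) {
      const Spectral &sp = (two && efg[e]) ? sf : sb;
      const double t = elen[e];
      const int ch = child[e], pa = parent[e];
      const vec et = exp(sp.d * t);
      mat contrib(n, S);

      if (ch < n_tip) {
        mat cols(n, n);
        std::vector<char> have(n, 0);
        const vec ones_col(n, fill::ones);
        for (int h = 0; h < S; ++h) {
          const int st = tips(ch, h);
          if (st < 0) {
            contrib.col(h) = ones_col;
          } else {
            if (!have[st]) {
              vec c = sp.V * (et % sp.W.col(st));
              c.for_each([](double &v) { if (v < 0.0) v = 0.0; });
              cols.col(st) = c;
              have[st] = 1;
            }
            contrib.col(h) = cols.col(st);
          }
        }
      } else {
        mat P = sp.V * (sp.W.each_col() % et);
        clip_nonneg(P);
        contrib = P * part[ch];
        part[ch].reset();
      }

      if (!started[pa]) {
        part[pa] = std::move(contrib);
        started[pa] = 1;
      } else {
        part[pa] %= contrib;
      }

      rowvec cs = sum(part[pa], 0);
      for (int h = 0; h < S; ++h) {
        if (std::isnan(cs[h]))
          Rcpp::stop("numeric failure in pruning at site %d (class %d)",
                     h + 1, k + 1);
        // a class likelihood of exactly 0 is legitimate (e.g. omega -> 0
        // with nonsynonymous variation); log 0 = -Inf mixes correctly
        if (cs[h] <= 0.0) { cs[h] = 1.0; scaler[h] = -datum::inf; }
      }
      part[pa].each_row() /= cs;
      scaler += log(cs.t());
    }

    vec L = part[root].t() * pi;
    for (int h = 0; h < S; ++h) {
      if (std::isnan(L[h]))
        Rcpp::stop("numeric failure at root for site %d (class %d)",
                   h + 1, k + 1);
      if (L[h] <= 0.0) { L[h] = 1.0; scaler[h] = -datum::inf; }
    }
    out.col(k) = log(L) + scaler;
  }
  return out;
}
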