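// Compiled training engine: full-batch (graph families) and minibatch (MLP)
// AdamW optimization of the node classifiers. Mirrors the package's R-level
// reference operations exactly (same normalizations, feature maps and
// stabilization shifts); the R test suite asserts agreement between the two
// engines.

// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>

using namespace arma;

namespace {

struct AdamW {
  double lr, wd, eps, b1, b2;
  int t = 0;
  std::vector<mat> m, v;

  explicit AdamW(const std::vector<mat>& params, double lr_, double wd_,
                 double eps_, double b1_, double b2_)
      : lr(lr_), wd(wd_), eps(eps_), b1(b1_), b2(b2_) {
    for (const mat& p : params) {
      m.push_back(zeros(p.n_rows, p.n_cols));
      v.push_back(zeros(p.n_rows, p.n_cols));
    }
  }

  void step(std::vector<mat>& params, const std::vector<mat>& grads) {
    ++t;
    const double c1 = 1.0 - std::pow(b1, t);
    const double c2 = 1.0 - std::pow(b2, t);
    for (size_t i = 0; i < params.size(); ++i) {
      m[i] = b1 * m[i] + (1.0 - b1) * grads[i];
      v[i] = b2 * v[i] + (1.0 - b2) * square(grads[i]);
      params[i] -= lr * ((m[i] / c1) / (sqrt(v[i] / c2) + eps)) +
                   lr * wd * params[i];
    }
  }
};

mat log_softmax_rows(const mat& z) {
  vec mx = max(z, 1);
  mat zs = z.each_col() - mx;
  return zs.each_col() - log(sum(exp(zs), 1));
}

// Mean NLL over idx plus gradient w.r.t. pre-softmax scores (zero elsewhere).
double nll_grad(const mat& logp, const uvec& y, const uvec& idx, mat& gz) {
  gz.zeros(logp.n_rows, logp.n_cols);
  double loss = 0.0;
  for (uword r = 0; r < idx.n_elem; ++r) {
    const uword i = idx[r];
    loss -= logp(i, y[i]);
    gz.row(i) = exp(logp.row(i));
    gz(i, y[i]) -= 1.0;
  }
  gz /= static_cast<double>(idx.n_elem);
  return loss / static_cast<double>(idx.n_elem);
}

void add_bias(mat& x, const mat& b) { x.each_row() += b; }

// Positive random features for the exponential kernel, matching the R
// reference: phi(x) = exp(x wf' - |x|^2/2 - shift) / sqrt(m); per-row shift
// for queries, global shift for keys (both cancel in the attention ratio).
mat exp_features_q(const mat& q, const mat& wf) {
  mat proj = q * wf.t();
  proj.each_col() -= 0.5 * sum(square(q), 1);
  proj.each_col() -= max(proj, 1);
  return exp(proj) / std::sqrt(static_cast<double>(wf.n_rows));
}

mat exp_features_k(const mat& k, const mat& wf) {
  mat proj = k * wf.t();
  proj.each_col() -= 0.5 * sum(square(k), 1);
  proj -= proj.max();
  return exp(proj) / std::sqrt(static_cast<double>(wf.n_rows));
}

mat elu1(const mat& x) {
  mat out = x + 1.0;
  const uvec neg = find(x <= 0.0);
  out(neg) = exp(x(neg));
  return out;
}

struct AttnCache {
  mat q, k, v, phi_q, phi_k, skv, o, mask, h_dense;
  rowvec sk;
  vec den, rq, rk;
  bool dense_attention = false;
  mat attn; // dense path only
};

// L2-normalize rows and divide by sqrt(temperature).
void qk_normalize(mat& x, vec& r, double tau) {
  r = sqrt(sum(square(x), 1)) + 1e-12;
  x.each_col() /= (r * std::sqrt(tau));
}

mat qk_normalize_backward(const mat& dxn, const mat& xn, const vec& r,
                          double tau) {
  mat out = dxn - tau * (xn.each_col() % sum(xn % dxn, 1));
  out.each_col() /= (r * std::sqrt(tau));
  return out;
}

// One attention layer; h_in given either sparse (first layer) or dense.
template <typename MatT>
AttnCache attn_forward(const MatT& h_in, const mat& wq, const mat& wk,
                       const mat& wv, const mat& wf, bool kernelized,
                       bool phi_exp, bool qk_norm, double tau) {
  AttnCache c;
  c.q = mat(h_in * wq);
  c.k = mat(h_in * wk);
  c.v = mat(h_in * wv);
  if (qk_norm) {
    qk_normalize(c.q, c.rq, tau);
    qk_normalize(c.k, c.rk, tau);
  }
  if (!kernelized) {
    c.dense_attention = true;
    mat s = c.q * c.k.t();
    s.each_col() -= max(s, 1);
    mat e = exp(s);
    c.attn = e.each_col() / sum(e, 1);
    c.o = c.attn * c.v;
  } else {
    c.phi_q = phi_exp ? exp_features_q(c.q, wf) : elu1(c.q);
    c.phi_k = phi_exp ? exp_features_k(c.k, wf) : elu1(c.k);
    c.skv = c.phi_k.t() * c.v;
    c.sk = sum(c.phi_k, 0);
    c.den = c.phi_q * c.sk.t();
    c.o = (c.phi_q * c.skv);
    c.o.each_col() /= c.den;
  }
  c.mask = conv_to<mat>::from(c.o > 0.0);
  return c;
}

struct AttnGrads {
  mat dwq, dwk, dwv, dh_in;
};

template <typename MatT>
AttnGrads attn_backward(const AttnCache& c, const MatT& h_in, const mat& wq,
                        const mat& wk, const mat& wv, const mat& wf,
                        bool kernelized, bool phi_exp, bool qk_norm,
                        double tau, const mat& dh_out, bool need_input_grad) {
  mat dout = dh_out % c.mask;
  mat dq, dk, dv;
  if (!kernelized) {
    dv = c.attn.t() * dout;
    mat da = dout * c.v.t();
    mat ds = c.attn % (da.each_col() - sum(da % c.attn, 1));
    dq = ds * c.k;
    dk = ds.t() * c.q;
  } else {
    mat dnum = dout.each_col() / c.den;
    vec dden = -sum(dout % c.o, 1) / c.den;
    mat dphi_q = dnum * c.skv.t() + dden * c.sk;
    mat dskv = c.phi_q.t() * dnum;
    rowvec dsk = (c.phi_q.t() * dden).t();
    mat dphi_k = c.v * dskv.t();
    dphi_k.each_row() += dsk;
    dv = c.phi_k * dskv;
    if (phi_exp) {
      mat gq = dphi_q % c.phi_q;
      dq = gq * wf;
      dq -= c.q.each_col() % sum(gq, 1);
      mat gk = dphi_k % c.phi_k;
      dk = gk * wf;
      dk -= c.k.each_col() % sum(gk, 1);
    } else {
      mat eq = conv_to<mat>::from(c.q > 0.0);
      dq = dphi_q % (eq + (1.0 - eq) % exp(c.q));
      mat ek = conv_to<mat>::from(c.k > 0.0);
      dk = dphi_k % (ek + (1.0 - ek) % exp(c.k));
    }
  }
  if (qk_norm) {
    dq = qk_normalize_backward(dq, c.q, c.rq, tau);
    dk = qk_normalize_backward(dk, c.k, c.rk, tau);
  }
  AttnGrads g;
  g.dwq = mat(h_in.t() * dq);
  g.dwk = mat(h_in.t() * dk);
  g.dwv = mat(h_in.t() * dv);
  if (need_input_grad) g.dh_in = dq * wq.t() + dk * wk.t() + dv * wv.t();
  return g;
}

std::vector<mat> params_from_list(const Rcpp::List& plist) {
  std::vector<mat> out;
  for (R_xlen_t i = 0; i < plist.size(); ++i) {
    Rcpp::NumericMatrix pm = plist[i];
    out.push_back(Rcpp::as<mat>(pm));
  }
  return out;
}

Rcpp::List params_to_list(const std::vector<mat>& params,
                          const Rcpp::CharacterVector& names) {
  Rcpp::List out(params.size());
  for (size_t i = 0; i < params.size(); ++i) out[i] = Rcpp::wrap(params[i]);
  out.attr("names") = names;
  return out;
}

} // namespace

// Graph families: full-batch training. family: 1 = gcn, 2 = sage,
// 3 = transformer. `m1` is the precomputed first-layer aggregate
// (gcn: adj*X, sage: [X || rowop*X]); `x` the raw features (transformer).
// [[Rcpp::export]]
Rcpp::List cpp_train_graph(int family, const arma::sp_mat& x,
                           const arma::sp_mat& m1, const arma::sp_mat& adj,
                           const arma::sp_mat& adj_t, Rcpp::List params_list,
                           const arma::mat& wf1, const arma::mat& wf2,
                           bool kernelized, bool phi_exp, bool qk_norm,
                           double tau,
                           const arma::uvec& y, const arma::uvec& train_idx,
                           int epochs, double lr, double wd, double eps,
                           double b1, double b2) {
  Rcpp::CharacterVector pnames = params_list.names();
  std::vector<mat> p = params_from_list(params_list);
  AdamW opt(p, lr, wd, eps, b1, b2);
  vec trace(epochs, fill::value(datum::nan));
  mat gz;

  for (int epoch = 0; epoch < epochs; ++epoch) {
    std::vector<mat> g(p.size());
    double loss = 0.0;

    if (family == 1) { // gcn: p = W1 b1 W2 b2 W3 b3
      mat n1 = mat(m1 * p[0]);
      add_bias(n1, p[1]);
      mat mask1 = conv_to<mat>::from(n1 > 0.0);
      mat h1 = n1 % mask1;
      mat m2 = mat(adj * h1);
      mat n2 = m2 * p[2];
      add_bias(n2, p[3]);
      mat mask2 = conv_to<mat>::from(n2 > 0.0);
      mat h2 = n2 % mask2;
      mat z = h2 * p[4];
      add_bias(z, p[5]);
      mat logp = log_softmax_rows(z);
      loss = nll_grad(logp, y, train_idx, gz);
      g[4] = h2.t() * gz;
      g[5] = sum(gz, 0);
      mat dh2 = gz * p[4].t();
      mat dn2 = dh2 % mask2;
      g[2] = m2.t() * dn2;
      g[3] = sum(dn2, 0);
      mat dh1 = mat(adj_t * (dn2 * p[2].t()));
      mat dn1 = dh1 % mask1;
      g[0] = mat(m1.t() * dn1);
      g[1] = sum(dn1, 0);
    } else if (family == 2) { // sage: p = W1 b1 W2 b2 W3 b3
      mat n1 = mat(m1 * p[0]);
      add_bias(n1, p[1]);
      mat mask1 = conv_to<mat>::from(n1 > 0.0);
      mat h1 = n1 % mask1;
      const uword h = h1.n_cols;
      mat m2 = join_rows(h1, mat(adj * h1));
      mat n2 = m2 * p[2];
      add_bias(n2, p[3]);
      mat mask2 = conv_to<mat>::from(n2 > 0.0);
      mat h2 = n2 % mask2;
      mat z = h2 * p[4];
      add_bias(z, p[5]);
      mat logp = log_softmax_rows(z);
      loss = nll_grad(logp, y, train_idx, gz);
      g[4] = h2.t() * gz;
      g[5] = sum(gz, 0);
      mat dh2 = gz * p[4].t();
      mat dn2 = dh2 % mask2;
      g[2] = m2.t() * dn2;
      g[3] = sum(dn2, 0);
      mat dm2 = dn2 * p[2].t();
      mat dh1 = dm2.cols(0, h - 1) + mat(adj_t * dm2.cols(h, 2 * h - 1));
      mat dn1 = dh1 % mask1;
      g[0] = mat(m1.t() * dn1);
      g[1] = sum(dn1, 0);
    } else { // transformer: p = Wq1 Wk1 Wv1 Wq2 Wk2 Wv2 W3 b3
      AttnCache c1 =
          attn_forward(x, p[0], p[1], p[2], wf1, kernelized, phi_exp, qk_norm, tau);
      mat h1 = c1.o % c1.mask;
      AttnCache c2 =
          attn_forward(h1, p[3], p[4], p[5], wf2, kernelized, phi_exp, qk_norm, tau);
      mat h2 = c2.o % c2.mask;
      mat z = h2 * p[6];
      add_bias(z, p[7]);
      mat logp = log_softmax_rows(z);
      loss = nll_grad(logp, y, train_idx, gz);
      g[6] = h2.t() * gz;
      g[7] = sum(gz, 0);
      mat dh2 = gz * p[6].t();
      AttnGrads g2 = attn_backward(c2, h1, p[3], p[4], p[5], wf2, kernelized,
                                   phi_exp, qk_norm, tau, dh2, true);
      mat dh1 = g2.dh_in % c1.mask;
      AttnGrads g1 = attn_backward(c1, x, p[0], p[1], p[2], wf1, kernelized,
                                   phi_exp, qk_norm, tau, dh1, false);
      g[0] = g1.dwq;
      g[1] = g1.dwk;
      g[2] = g1.dwv;
      g[3] = g2.dwq;
      g[4] = g2.dwk;
      g[5] = g2.dwv;
    }

    trace[epoch] = loss;
    if (!std::isfinite(loss)) break;
    opt.step(p, g);
  }

  return Rcpp::List::create(Rcpp::Named("params") = params_to_list(p, pnames),
                            Rcpp::Named("trace") = trace);
}

// MLP baseline: minibatched training. `order` holds, per epoch, the
// pre-shuffled training indices (0-based), one column per epoch.
// [[Rcpp::export]]
Rcpp::List cpp_train_mlp(const arma::mat& x, Rcpp::List params_list,
                         const arma::uvec& y, const arma::umat& order,
                         int batch_size, double lr, double wd, double eps,
                         double b1, double b2) {
  Rcpp::CharacterVector pnames = params_list.names();
  std::vector<mat> p = params_from_list(params_list);
  AdamW opt(p, lr, wd, eps, b1, b2);
  const int epochs = order.n_cols;
  const uword n_train = order.n_rows;
  vec trace(epochs, fill::value(datum::nan));
  mat gz;

  for (int epoch = 0; epoch < epochs; ++epoch) {
    double epoch_loss = 0.0;
    for (uword start = 0; start < n_train; start += batch_size) {
      const uword stop = std::min<uword>(start + batch_size, n_train) - 1;
      const uvec b = order(span(start, stop), span(epoch, epoch));
      const mat xb = x.rows(b);
      const uvec yb = y(b);
      std::vector<mat> g(p.size());

      mat n1 = xb * p[0];
      add_bias(n1, p[1]);
      mat mask1 = conv_to<mat>::from(n1 > 0.0);
      mat h1 = n1 % mask1;
      mat n2 = h1 * p[2];
      add_bias(n2, p[3]);
      mat mask2 = conv_to<mat>::from(n2 > 0.0);
      mat h2 = n2 % mask2;
      mat z = h2 * p[4];
      add_bias(z, p[5]);
      mat logp = log_softmax_rows(z);
      const uvec all = regspace<uvec>(0, b.n_elem - 1);
      double loss = nll_grad(logp, yb, all, gz);
      epoch_loss += loss * b.n_elem;

      g[4] = h2.t() * gz;
      g[5] = sum(gz, 0);
      mat dh2 = gz * p[4].t();
      mat dn2 = dh2 % mask2;
      g[2] = h1.t() * dn2;
      g[3] = sum(dn2, 0);
      mat dh1 = dn2 * p[2].t();
      mat dn1 = dh1 % mask1;
      g[0] = xb.t() * dn1;
      g[1] = sum(dn1, 0);

      opt.step(p, g);
    }
    trace[epoch] = epoch_loss / n_train;
    if (!std::isfinite(trace[epoch])) break;
  }

  return Rcpp::List::create(Rcpp::Named("params") = params_to_list(p, pnames),
                            Rcpp::Named("trace") = trace);
}
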