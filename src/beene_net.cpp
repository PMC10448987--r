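// Guided-autoencoder core: SELU MLP trunk (encoder + decoder) with softmax /
// logistic prediction heads attached to the latent layer, trained by
// mini-batch gradient descent (Adam or plain SGD) on the joint loss
//   sum_i [ l1*||x_i - xhat_i||^2 + l2w*CE_batch(i) + l3*CE_bio(i) ] + c*sum||W||^2
// with the L2 penalty applied once per mini-batch and to weights only.
//
// The numerics are templated on the element type: training runs in single
// precision (standard for this model family, and memory-bandwidth friendly),
// while the exported loss/gradient entry points instantiate the same code in
// double precision so analytic gradients can be checked against central
// finite differences at tight tolerance.
//
// All randomness (init, shuffling, dropout) comes from an own mt19937_64
// stream so that a seed fully determines the fit.

#include <RcppArmadillo.h>
#include <random>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

static const double SELU_LAMBDA = 1.0507009873554804934193349852946;
static const double SELU_ALPHA  = 1.6732632423543772848170429916717;
static const double PROB_FLOOR  = 1e-12;

struct Rng {
  std::mt19937_64 gen;
  explicit Rng(uint64_t seed) : gen(seed) {}
  // uniform in [0,1); top 53 bits -> platform-stable double
  double unif() {
    return (gen() >> 11) * (1.0 / 9007199254740992.0);
  }
  // Box-Muller (no cached spare: keeps the stream simple and reproducible)
  double norm() {
    double u1 = unif(), u2 = unif();
    while (u1 <= 1e-300) u1 = unif();
    return std::sqrt(-2.0 * std::log(u1)) * std::cos(6.283185307179586476925286766559 * u2);
  }
  int below(int n) { // uniform integer in [0, n)
    return (int)(unif() * n) % n;
  }
};

template <typename T> using Mt = arma::Mat<T>;
template <typename T> using Rw = arma::Row<T>;

template <typename T>
static Mt<T> selu(const Mt<T>& x) {
  Mt<T> y = x;
  T* p = y.memptr();
  for (arma::uword i = 0; i < y.n_elem; ++i) {
    T v = p[i];
    p[i] = v > 0 ? (T)SELU_LAMBDA * v
                 : (T)(SELU_LAMBDA * SELU_ALPHA) * (std::exp(v) - (T)1);
  }
  return y;
}

// derivative of SELU given pre-activation
template <typename T>
static Mt<T> selu_deriv(const Mt<T>& x) {
  Mt<T> d = x;
  T* p = d.memptr();
  for (arma::uword i = 0; i < d.n_elem; ++i) {
    T v = p[i];
    p[i] = v > 0 ? (T)SELU_LAMBDA : (T)(SELU_LAMBDA * SELU_ALPHA) * std::exp(v);
  }
  return d;
}

// ---------------------------------------------------------------------------
// Network container
// ---------------------------------------------------------------------------
template <typename T>
struct Net {
  // trunk: encoder layers followed by decoder layers; the latent code is the
  // activation after trunk layer (latent_idx - 1), i.e. the encoder output
  std::vector<Mt<T>> W;   // trunk weights, W[l] is (in x out)
  std::vector<Rw<T>> b;   // trunk biases
  int latent_idx;
  Mt<T> psi;  Rw<T> psi_b;    // batch head (d x K), or (d x 1) when K == 2
  Mt<T> omega; Rw<T> omega_b; // bio head, empty when disabled
  bool has_bio;
  int K, M;

  int n_trunk() const { return (int)W.size(); }
};

template <typename T>
static Net<T> net_from_list(const List& params) {
  Net<T> net;
  List trunkW = params["W"], trunkB = params["b"];
  net.latent_idx = as<int>(params["latent_idx"]);
  for (int i = 0; i < trunkW.size(); ++i) {
    net.W.push_back(arma::conv_to<Mt<T>>::from(as<arma::mat>(trunkW[i])));
    net.b.push_back(arma::conv_to<Rw<T>>::from(as<arma::rowvec>(trunkB[i])));
  }
  net.psi = arma::conv_to<Mt<T>>::from(as<arma::mat>(params["psi"]));
  net.psi_b = arma::conv_to<Rw<T>>::from(as<arma::rowvec>(params["psi_b"]));
  net.K = as<int>(params["K"]);
  net.has_bio = params.containsElementNamed("omega") &&
    !Rf_isNull(params["omega"]);
  if (net.has_bio) {
    net.omega = arma::conv_to<Mt<T>>::from(as<arma::mat>(params["omega"]));
    net.omega_b =
      arma::conv_to<Rw<T>>::from(as<arma::rowvec>(params["omega_b"]));
    net.M = as<int>(params["M"]);
  } else {
    net.M = 0;
  }
  return net;
}

template <typename T>
static List net_to_list(const Net<T>& net) {
  List trunkW(net.n_trunk()), trunkB(net.n_trunk());
  for (int i = 0; i < net.n_trunk(); ++i) {
    trunkW[i] = arma::conv_to<arma::mat>::from(net.W[i]);
    trunkB[i] = arma::conv_to<arma::rowvec>::from(net.b[i]);
  }
  List out = List::create(
    _["W"] = trunkW, _["b"] = trunkB,
    _["latent_idx"] = net.latent_idx,
    _["psi"] = arma::conv_to<arma::mat>::from(net.psi),
    _["psi_b"] = arma::conv_to<arma::rowvec>::from(net.psi_b),
    _["K"] = net.K);
  if (net.has_bio) {
    out["omega"] = arma::conv_to<arma::mat>::from(net.omega);
    out["omega_b"] = arma::conv_to<arma::rowvec>::from(net.omega_b);
    out["M"] = net.M;
  } else {
    out["omega"] = R_NilValue;
    out["M"] = 0;
  }
  return out;
}

// LeCun-normal initialization: W_ij ~ N(0, 1/fan_in), biases zero
// [[Rcpp::export]]
List cpp_init_params(IntegerVector enc_sizes, IntegerVector dec_sizes,
                     int K, int M, int seed) {
  Rng rng((uint64_t)seed);
  Net<double> net;
  net.K = K; net.M = M; net.has_bio = M >= 2;
  std::vector<int> sizes;
  for (int i = 0; i < enc_sizes.size(); ++i) sizes.push_back(enc_sizes[i]);
  for (int i = 1; i < dec_sizes.size(); ++i) sizes.push_back(dec_sizes[i]);
  net.latent_idx = enc_sizes.size() - 1;
  for (size_t l = 0; l + 1 < sizes.size(); ++l) {
    int fin = sizes[l], fout = sizes[l + 1];
    arma::mat w(fin, fout);
    double sd = std::sqrt(1.0 / fin);
    for (arma::uword i = 0; i < w.n_elem; ++i) w[i] = sd * rng.norm();
    net.W.push_back(w);
    net.b.push_back(arma::rowvec(fout, arma::fill::zeros));
  }
  int d = enc_sizes[enc_sizes.size() - 1];
  int kcols = (K == 2) ? 1 : K;
  net.psi = arma::mat(d, kcols);
  double sd = std::sqrt(1.0 / d);
  for (arma::uword i = 0; i < net.psi.n_elem; ++i) net.psi[i] = sd * rng.norm();
  net.psi_b = arma::rowvec(kcols, arma::fill::zeros);
  if (net.has_bio) {
    int mcols = (M == 2) ? 1 : M;
    net.omega = arma::mat(d, mcols);
    for (arma::uword i = 0; i < net.omega.n_elem; ++i)
      net.omega[i] = sd * rng.norm();
    net.omega_b = arma::rowvec(mcols, arma::fill::zeros);
  }
  return net_to_list(net);
}

// ---------------------------------------------------------------------------
// Forward / loss / backward
// ---------------------------------------------------------------------------
template <typename T>
struct ForwardCache {
  std::vector<Mt<T>> pre;   // pre-activations per trunk layer
  std::vector<Mt<T>> act;   // post-activation/post-dropout; act[0] = input
  std::vector<Mt<T>> mask;  // dropout masks (empty when unused)
  Mt<T> z;                  // latent (clean) = act[latent_idx]
  Mt<T> head_u_batch, head_p_batch;
  Mt<T> head_u_bio, head_p_bio;
};

// rowwise-stable softmax
template <typename T>
static Mt<T> softmax_rows(const Mt<T>& U) {
  Mt<T> P = U;
  for (arma::uword i = 0; i < P.n_rows; ++i) {
    Rw<T> r = P.row(i);
    r -= r.max();
    r = arma::exp(r);
    P.row(i) = r / arma::accu(r);
  }
  return P;
}

template <typename T>
static void forward(const Net<T>& net, const Mt<T>& X, bool training,
                    double hidden_dropout, double input_dropout,
                    Rng* rng, ForwardCache<T>& fc) {
  int L = net.n_trunk();
  fc.pre.assign(L, Mt<T>());
  fc.act.assign(L + 1, Mt<T>());
  fc.mask.assign(L + 1, Mt<T>());
  Mt<T> A = X;
  if (training && input_dropout > 0) {
    Mt<T> m(A.n_rows, A.n_cols);
    double keep = 1.0 - input_dropout;
    for (arma::uword i = 0; i < m.n_elem; ++i)
      m[i] = (rng->unif() < keep) ? (T)(1.0 / keep) : (T)0;
    fc.mask[0] = m;
    A = A % m;
  }
  fc.act[0] = A;
  for (int l = 0; l < L; ++l) {
    Mt<T> U = fc.act[l] * net.W[l];
    U.each_row() += net.b[l];
    fc.pre[l] = U;
    Mt<T> H = (l == L - 1) ? U : selu(U);   // final decoder layer is linear
    // dropout on hidden layers only: never on the latent output, never on
    // the reconstruction output
    bool drop = training && hidden_dropout > 0 &&
      l != net.latent_idx - 1 && l != L - 1;
    if (drop) {
      Mt<T> m(H.n_rows, H.n_cols);
      double keep = 1.0 - hidden_dropout;
      for (arma::uword i = 0; i < m.n_elem; ++i)
        m[i] = (rng->unif() < keep) ? (T)(1.0 / keep) : (T)0;
      fc.mask[l + 1] = m;
      H = H % m;
    }
    fc.act[l + 1] = H;
    if (l == net.latent_idx - 1) fc.z = H;  // post-activation, no dropout
  }
  // heads
  fc.head_u_batch = fc.z * net.psi;
  fc.head_u_batch.each_row() += net.psi_b;
  if (net.K == 2)
    fc.head_p_batch = (T)1 / ((T)1 + arma::exp(-fc.head_u_batch));
  else
    fc.head_p_batch = softmax_rows(fc.head_u_batch);
  if (net.has_bio) {
    fc.head_u_bio = fc.z * net.omega;
    fc.head_u_bio.each_row() += net.omega_b;
    if (net.M == 2)
      fc.head_p_bio = (T)1 / ((T)1 + arma::exp(-fc.head_u_bio));
    else
      fc.head_p_bio = softmax_rows(fc.head_u_bio);
  }
}

template <typename T>
static double ce_binary(const Mt<T>& p, const IntegerVector& lab) {
  double ce = 0;
  for (arma::uword i = 0; i < p.n_rows; ++i) {
    double pi = (double)p(i, 0);
    double q = lab[i] == 1 ? pi : 1.0 - pi;
    ce -= std::log(std::max(q, PROB_FLOOR));
  }
  return ce;
}

template <typename T>
static double ce_multi(const Mt<T>& P, const IntegerVector& lab) {
  double ce = 0;
  for (arma::uword i = 0; i < P.n_rows; ++i)
    ce -= std::log(std::max((double)P(i, lab[i]), PROB_FLOOR));
  return ce;
}

template <typename T>
static double l2_weights(const Net<T>& net) {
  double s = 0;
  for (const Mt<T>& w : net.W) s += (double)arma::accu(arma::square(w));
  s += (double)arma::accu(arma::square(net.psi));
  if (net.has_bio) s += (double)arma::accu(arma::square(net.omega));
  return s;
}

struct LossParts {
  double rec, bce, yce, l2, total;
};

template <typename T>
static LossParts loss_from_cache(const Net<T>& net, const Mt<T>& X,
                                 const IntegerVector& blab,
                                 const IntegerVector& ylab,
                                 const ForwardCache<T>& fc,
                                 double l1, double l2w, double l3,
                                 double l2c) {
  LossParts lp;
  const Mt<T>& Xhat = fc.act.back();
  lp.rec = (double)arma::accu(arma::square(X - Xhat));
  lp.bce = (net.K == 2) ? ce_binary(fc.head_p_batch, blab)
                        : ce_multi(fc.head_p_batch, blab);
  lp.yce = 0;
  if (net.has_bio && l3 > 0)
    lp.yce = (net.M == 2) ? ce_binary(fc.head_p_bio, ylab)
                          : ce_multi(fc.head_p_bio, ylab);
  lp.l2 = l2_weights(net);
  lp.total = l1 * lp.rec + l2w * lp.bce + l3 * lp.yce + l2c * lp.l2;
  return lp;
}

template <typename T>
struct Grads {
  std::vector<Mt<T>> W;
  std::vector<Rw<T>> b;
  Mt<T> psi; Rw<T> psi_b;
  Mt<T> omega; Rw<T> omega_b;
};

template <typename T>
static Grads<T> backward(const Net<T>& net, const Mt<T>& X,
                         const IntegerVector& blab, const IntegerVector& ylab,
                         const ForwardCache<T>& fc,
                         double l1, double l2w, double l3, double l2c) {
  int L = net.n_trunk();
  int s = X.n_rows;
  Grads<T> g;
  g.W.assign(L, Mt<T>());
  g.b.assign(L, Rw<T>());

  // head gradients wrt logits
  Mt<T> dU_batch = fc.head_p_batch;
  if (net.K == 2) {
    for (int i = 0; i < s; ++i) dU_batch(i, 0) -= (blab[i] == 1) ? (T)1 : (T)0;
  } else {
    for (int i = 0; i < s; ++i) dU_batch(i, blab[i]) -= (T)1;
  }
  dU_batch *= (T)l2w;
  g.psi = fc.z.t() * dU_batch + (T)(2.0 * l2c) * net.psi;
  g.psi_b = arma::sum(dU_batch, 0);
  Mt<T> dz_heads = dU_batch * net.psi.t();

  if (net.has_bio && l3 > 0) {
    Mt<T> dU_bio = fc.head_p_bio;
    if (net.M == 2) {
      for (int i = 0; i < s; ++i) dU_bio(i, 0) -= (ylab[i] == 1) ? (T)1 : (T)0;
    } else {
      for (int i = 0; i < s; ++i) dU_bio(i, ylab[i]) -= (T)1;
    }
    dU_bio *= (T)l3;
    g.omega = fc.z.t() * dU_bio + (T)(2.0 * l2c) * net.omega;
    g.omega_b = arma::sum(dU_bio, 0);
    dz_heads += dU_bio * net.omega.t();
  } else if (net.has_bio) {
    g.omega = (T)(2.0 * l2c) * net.omega;
    g.omega_b = Rw<T>(net.omega_b.n_elem, arma::fill::zeros);
  }

  // trunk backward; dA starts as dL/d(output) for the linear last layer
  Mt<T> dA = (T)(2.0 * l1) * (fc.act.back() - X);
  for (int l = L - 1; l >= 0; --l) {
    Mt<T> dPre;
    if (l == L - 1) {
      dPre = dA;
    } else {
      Mt<T> dAct = dA;
      if (fc.mask[l + 1].n_elem > 0) dAct = dAct % fc.mask[l + 1];
      dPre = dAct % selu_deriv(fc.pre[l]);
    }
    g.W[l] = fc.act[l].t() * dPre + (T)(2.0 * l2c) * net.W[l];
    g.b[l] = arma::sum(dPre, 0);
    dA = dPre * net.W[l].t();
    if (l == net.latent_idx) {
      // dA is now the gradient wrt the latent activation coming from the
      // decoder; add the heads' contribution before entering the encoder
      dA += dz_heads;
    }
  }
  return g;
}

// [[Rcpp::export]]
List cpp_loss(const arma::mat& X, IntegerVector blab, IntegerVector ylab,
              List params, double l1, double l2w, double l3, double l2c) {
  Net<double> net = net_from_list<double>(params);
  ForwardCache<double> fc;
  forward(net, X, false, 0, 0, nullptr, fc);
  LossParts lp = loss_from_cache(net, X, blab, ylab, fc, l1, l2w, l3, l2c);
  return List::create(_["total"] = lp.total, _["reconstruction"] = lp.rec,
                      _["batch_ce"] = lp.bce, _["bio_ce"] = lp.yce,
                      _["l2"] = lp.l2);
}

// [[Rcpp::export]]
List cpp_grad(const arma::mat& X, IntegerVector blab, IntegerVector ylab,
              List params, double l1, double l2w, double l3, double l2c) {
  Net<double> net = net_from_list<double>(params);
  ForwardCache<double> fc;
  forward(net, X, false, 0, 0, nullptr, fc);
  Grads<double> g = backward(net, X, blab, ylab, fc, l1, l2w, l3, l2c);
  List trunkW(net.n_trunk()), trunkB(net.n_trunk());
  for (int i = 0; i < net.n_trunk(); ++i) {
    trunkW[i] = g.W[i];
    trunkB[i] = g.b[i];
  }
  List out = List::create(_["W"] = trunkW, _["b"] = trunkB,
                          _["psi"] = g.psi, _["psi_b"] = g.psi_b);
  if (net.has_bio) {
    out["omega"] = g.omega;
    out["omega_b"] = g.omega_b;
  }
  return out;
}

// [[Rcpp::export]]
arma::mat cpp_encode(const arma::mat& X, List params) {
  Net<double> net = net_from_list<double>(params);
  arma::mat A = X;
  for (int l = 0; l < net.latent_idx; ++l) {
    arma::mat U = A * net.W[l];
    U.each_row() += net.b[l];
    A = selu(U);
  }
  return A;
}

// [[Rcpp::export]]
arma::mat cpp_decode(const arma::mat& Z, List params) {
  Net<double> net = net_from_list<double>(params);
  arma::mat A = Z;
  int L = net.n_trunk();
  for (int l = net.latent_idx; l < L; ++l) {
    arma::mat U = A * net.W[l];
    U.each_row() += net.b[l];
    A = (l == L - 1) ? U : selu(U);
  }
  return A;
}

// [[Rcpp::export]]
arma::mat cpp_head_probs(const arma::mat& Z, List params, std::string head) {
  Net<double> net = net_from_list<double>(params);
  arma::mat W; arma::rowvec bb; int ncls;
  if (head == "batch") {
    W = net.psi; bb = net.psi_b; ncls = net.K;
  } else {
    if (!net.has_bio) stop("bio head is disabled for this model");
    W = net.omega; bb = net.omega_b; ncls = net.M;
  }
  arma::mat U = Z * W;
  U.each_row() += bb;
  if (ncls == 2) {
    arma::mat p1 = 1.0 / (1.0 + arma::exp(-U));
    arma::mat P(Z.n_rows, 2);
    P.col(0) = 1.0 - p1.col(0);
    P.col(1) = p1.col(0);
    return P;
  }
  return softmax_rows(U);
}

// ---------------------------------------------------------------------------
// Optimizers
// ---------------------------------------------------------------------------
// Fused single-pass Adam update (no expression-template temporaries; this
// elementwise pass is bandwidth-bound and on the hot path).
template <typename T>
static void adam_update(T* w, const T* g, T* m, T* v, size_t n,
                        double lr, double b1, double b2, double eps,
                        double c1, double c2) {
  for (size_t i = 0; i < n; ++i) {
    double gi = (double)g[i];
    double mi = b1 * (double)m[i] + (1 - b1) * gi;
    double vi = b2 * (double)v[i] + (1 - b2) * gi * gi;
    m[i] = (T)mi;
    v[i] = (T)vi;
    w[i] -= (T)(lr * (mi / c1) / (std::sqrt(vi / c2) + eps));
  }
}

template <typename T>
struct Adam {
  std::vector<Mt<T>> mW, vW;
  std::vector<Rw<T>> mb, vb;
  Mt<T> m_psi, v_psi; Rw<T> m_psib, v_psib;
  Mt<T> m_om, v_om; Rw<T> m_omb, v_omb;
  long t = 0;
  double b1 = 0.9, b2 = 0.999, eps = 1e-8;

  void init(const Net<T>& net) {
    for (const Mt<T>& w : net.W) {
      mW.push_back(Mt<T>(w.n_rows, w.n_cols, arma::fill::zeros));
      vW.push_back(Mt<T>(w.n_rows, w.n_cols, arma::fill::zeros));
    }
    for (const Rw<T>& bb : net.b) {
      mb.push_back(Rw<T>(bb.n_elem, arma::fill::zeros));
      vb.push_back(Rw<T>(bb.n_elem, arma::fill::zeros));
    }
    m_psi = v_psi = Mt<T>(net.psi.n_rows, net.psi.n_cols, arma::fill::zeros);
    m_psib = v_psib = Rw<T>(net.psi_b.n_elem, arma::fill::zeros);
    if (net.has_bio) {
      m_om = v_om = Mt<T>(net.omega.n_rows, net.omega.n_cols,
                          arma::fill::zeros);
      m_omb = v_omb = Rw<T>(net.omega_b.n_elem, arma::fill::zeros);
    }
  }

  void step(Net<T>& net, const Grads<T>& g, double lr) {
    ++t;
    double c1 = 1.0 - std::pow(b1, (double)t);
    double c2 = 1.0 - std::pow(b2, (double)t);
    for (size_t l = 0; l < net.W.size(); ++l) {
      adam_update(net.W[l].memptr(), g.W[l].memptr(), mW[l].memptr(),
                  vW[l].memptr(), net.W[l].n_elem, lr, b1, b2, eps, c1, c2);
      adam_update(net.b[l].memptr(), g.b[l].memptr(), mb[l].memptr(),
                  vb[l].memptr(), net.b[l].n_elem, lr, b1, b2, eps, c1, c2);
    }
    adam_update(net.psi.memptr(), g.psi.memptr(), m_psi.memptr(),
                v_psi.memptr(), net.psi.n_elem, lr, b1, b2, eps, c1, c2);
    adam_update(net.psi_b.memptr(), g.psi_b.memptr(), m_psib.memptr(),
                v_psib.memptr(), net.psi_b.n_elem, lr, b1, b2, eps, c1, c2);
    if (net.has_bio) {
      adam_update(net.omega.memptr(), g.omega.memptr(), m_om.memptr(),
                  v_om.memptr(), net.omega.n_elem, lr, b1, b2, eps, c1, c2);
      adam_update(net.omega_b.memptr(), g.omega_b.memptr(), m_omb.memptr(),
                  v_omb.memptr(), net.omega_b.n_elem, lr, b1, b2, eps, c1,
                  c2);
    }
  }
};

template <typename T>
static void sgd_step(Net<T>& net, const Grads<T>& g, double lr) {
  for (size_t l = 0; l < net.W.size(); ++l) {
    net.W[l] -= (T)lr * g.W[l];
    net.b[l] -= (T)lr * g.b[l];
  }
  net.psi -= (T)lr * g.psi;
  net.psi_b -= (T)lr * g.psi_b;
  if (net.has_bio) {
    net.omega -= (T)lr * g.omega;
    net.omega_b -= (T)lr * g.omega_b;
  }
}

template <typename T>
static LossParts eval_set(const Net<T>& net, const Mt<T>& X,
                          const IntegerVector& blab,
                          const IntegerVector& ylab,
                          double l1, double l2w, double l3, double l2c) {
  ForwardCache<T> fc;
  forward(net, X, false, 0, 0, nullptr, fc);
  return loss_from_cache(net, X, blab, ylab, fc, l1, l2w, l3, l2c);
}

// ---------------------------------------------------------------------------
// Training loop
// ---------------------------------------------------------------------------
template <typename T>
static List train_impl(const arma::mat& Xtr_in, IntegerVector btr,
                       IntegerVector ytr, const arma::mat& Xval_in,
                       IntegerVector bval, IntegerVector yval,
                       List params0,
                       double l1, double l2w, double l3, double l2c,
                       double hidden_dropout, double input_dropout,
                       int batch_size, int max_epochs, int patience,
                       double lr, std::string optimizer, int seed) {
  Net<T> net = net_from_list<T>(params0);
  Mt<T> Xtr = arma::conv_to<Mt<T>>::from(Xtr_in);
  Mt<T> Xval = arma::conv_to<Mt<T>>::from(Xval_in);
  int n = Xtr.n_rows;
  if (batch_size > n) batch_size = n;
  Rng rng((uint64_t)seed * 2654435761u + 17u);
  Adam<T> adam;
  bool use_adam = optimizer == "adam";
  if (use_adam) adam.init(net);

  std::vector<int> idx(n);
  for (int i = 0; i < n; ++i) idx[i] = i;

  // epoch-0 (pre-training) evaluation
  LossParts v0 = eval_set(net, Xval, bval, yval, l1, l2w, l3, l2c);
  LossParts t0 = eval_set(net, Xtr, btr, ytr, l1, l2w, l3, l2c);

  std::vector<double> log_epoch, log_train_total, log_train_rec,
    log_train_bce, log_train_yce, log_val_total, log_val_rec,
    log_val_bce, log_val_yce;
  int ntr = n, nval = Xval.n_rows;
  log_epoch.push_back(0);
  log_train_total.push_back(t0.total / ntr);
  log_train_rec.push_back(t0.rec / ntr);
  log_train_bce.push_back(t0.bce / ntr);
  log_train_yce.push_back(t0.yce / ntr);
  log_val_total.push_back(v0.total / nval);
  log_val_rec.push_back(v0.rec / nval);
  log_val_bce.push_back(v0.bce / nval);
  log_val_yce.push_back(v0.yce / nval);

  double best_val = v0.total;
  Net<T> best = net;
  int best_epoch = 0, stall = 0;

  for (int epoch = 1; epoch <= max_epochs; ++epoch) {
    // Fisher-Yates shuffle
    for (int i = n - 1; i > 0; --i) {
      int j = rng.below(i + 1);
      std::swap(idx[i], idx[j]);
    }
    double ep_total = 0, ep_rec = 0, ep_bce = 0, ep_yce = 0;
    for (int start = 0; start < n; start += batch_size) {
      int bend = std::min(start + batch_size, n);
      int s = bend - start;
      Mt<T> Xb(s, Xtr.n_cols);
      IntegerVector bb(s), yb(s);
      for (int i = 0; i < s; ++i) {
        Xb.row(i) = Xtr.row(idx[start + i]);
        bb[i] = btr[idx[start + i]];
        if (ytr.size() > 0) yb[i] = ytr[idx[start + i]];
      }
      ForwardCache<T> fc;
      forward(net, Xb, true, hidden_dropout, input_dropout, &rng, fc);
      LossParts lp = loss_from_cache(net, Xb, bb, yb, fc, l1, l2w, l3, l2c);
      if (!std::isfinite(lp.total))
        stop("training diverged (non-finite loss) at epoch %d with learning rate %g",
             epoch, lr);
      ep_total += lp.total; ep_rec += lp.rec; ep_bce += lp.bce;
      ep_yce += lp.yce;
      Grads<T> g = backward(net, Xb, bb, yb, fc, l1, l2w, l3, l2c);
      if (use_adam) adam.step(net, g, lr); else sgd_step(net, g, lr);
    }
    LossParts vp = eval_set(net, Xval, bval, yval, l1, l2w, l3, l2c);
    if (!std::isfinite(vp.total))
      stop("training diverged (non-finite validation loss) at epoch %d with learning rate %g",
           epoch, lr);
    log_epoch.push_back(epoch);
    log_train_total.push_back(ep_total / ntr);
    log_train_rec.push_back(ep_rec / ntr);
    log_train_bce.push_back(ep_bce / ntr);
    log_train_yce.push_back(ep_yce / ntr);
    log_val_total.push_back(vp.total / nval);
    log_val_rec.push_back(vp.rec / nval);
    log_val_bce.push_back(vp.bce / nval);
    log_val_yce.push_back(vp.yce / nval);
    if (vp.total < best_val) {
      best_val = vp.total;
      best = net;
      best_epoch = epoch;
      stall = 0;
    } else if (++stall >= patience) {
      break;
    }
    Rcpp::checkUserInterrupt();
  }

  DataFrame log = DataFrame::create(
    _["epoch"] = log_epoch,
    _["train_total"] = log_train_total, _["train_rec"] = log_train_rec,
    _["train_batch_ce"] = log_train_bce, _["train_bio_ce"] = log_train_yce,
    _["val_total"] = log_val_total, _["val_rec"] = log_val_rec,
    _["val_batch_ce"] = log_val_bce, _["val_bio_ce"] = log_val_yce);
  return List::create(_["params"] = net_to_list(best),
                      _["log"] = log,
                      _["best_epoch"] = best_epoch,
                      _["best_val_total"] = best_val / nval);
}

// [[Rcpp::export]]
List cpp_train(const arma::mat& Xtr, IntegerVector btr, IntegerVector ytr,
               const arma::mat& Xval, IntegerVector bval, IntegerVector yval,
               List params0,
               double l1, double l2w, double l3, double l2c,
               double hidden_dropout, double input_dropout,
               int batch_size, int max_epochs, int patience,
               double lr, std::string optimizer, int seed,
               std::string precision) {
  if (precision == "double")
    return train_impl<double>(Xtr, btr, ytr, Xval, bval, yval, params0,
                              l1, l2w, l3, l2c, hidden_dropout, input_dropout,
                              batch_size, max_epochs, patience, lr, optimizer,
                              seed);
  return train_impl<float>(Xtr, btr, ytr, Xval, bval, yval, params0,
                           l1, l2w, l3, l2c, hidden_dropout, input_dropout,
                           batch_size, max_epochs, patience, lr, optimizer,
                           seed);
}
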