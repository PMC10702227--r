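// Stacked sparse autoencoder: fully-connected encoder (batch-norm + ReLU per
// hidden layer), linear latent code with an L1 sparsity penalty, mirrored
// decoder, trained with Adam on mean-squared reconstruction error.
// Single precision throughout (the conventional deep-learning default);
// deterministic for a fixed seed and thread count.
#include <RcppArmadillo.h>
#include <random>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;
using arma::fmat;
using arma::frowvec;

namespace {

struct Net {
  std::vector<fmat> W;
  std::vector<frowvec> b;      // only for non-BN layers
  std::vector<frowvec> gamma, beta, rmean, rvar;
  std::vector<bool> has_bn;
  int latent_idx;              // layer whose output is the latent code
  static constexpr float bn_eps = 1e-5f;
  static constexpr float bn_mom = 0.1f;
};

Net build_net(int d, const std::vector<int>& enc, int latent, bool bn_latent,
              std::mt19937& gen) {
  Net net;
  std::vector<int> dims;
  dims.push_back(d);
  for (int w : enc) dims.push_back(w);
  dims.push_back(latent);
  for (auto it = enc.rbegin(); it != enc.rend(); ++it) dims.push_back(*it);
  dims.push_back(d);
  const int L = (int)dims.size() - 1;
  net.latent_idx = (int)enc.size(); // 0-based layer index producing the code
  std::normal_distribution<float> normal(0.f, 1.f);
  for (int l = 0; l < L; ++l) {
    const int in = dims[l], out = dims[l + 1];
    const bool bn = (l == net.latent_idx) ? bn_latent : (l != L - 1);
    net.has_bn.push_back(bn);
    fmat W(in, out);
    const float sd = std::sqrt((bn ? 2.f : 1.f) / (float)in);
    for (arma::uword i = 0; i < W.n_elem; ++i) W[i] = sd * normal(gen);
    net.W.push_back(std::move(W));
    net.b.emplace_back(bn ? frowvec() : frowvec(out, arma::fill::zeros));
    if (bn) {
      net.gamma.emplace_back(frowvec(out, arma::fill::ones));
      net.beta.emplace_back(frowvec(out, arma::fill::zeros));
      net.rmean.emplace_back(frowvec(out, arma::fill::zeros));
      net.rvar.emplace_back(frowvec(out, arma::fill::ones));
    } else {
      net.gamma.emplace_back();
      net.beta.emplace_back();
      net.rmean.emplace_back();
      net.rvar.emplace_back();
    }
  }
  return net;
}

// Forward in inference mode (running statistics).
fmat forward_eval(const Net& net, const fmat& X, int stop_after) {
  fmat A = X;
  const int L = (int)net.W.size();
  for (int l = 0; l < L; ++l) {
    fmat Z = A * net.W[l];
    if (net.has_bn[l]) {
      frowvec invstd = 1.f / arma::sqrt(net.rvar[l] + Net::bn_eps);
      Z.each_row() -= net.rmean[l];
      Z.each_row() %= invstd % net.gamma[l];
      Z.each_row() += net.beta[l];
      Z = arma::clamp(Z, 0.f, std::numeric_limits<float>::infinity());
    } else {
      Z.each_row() += net.b[l];
    }
    A = std::move(Z);
    if (l == stop_after) return A;
  }
  return A;
}

struct Adam {
  std::vector<fmat> mW, vW;
  std::vector<frowvec> mb, vb, mg, vg, mbe, vbe;
  double t = 0;
  void init(const Net& net) {
    for (size_t l = 0; l < net.W.size(); ++l) {
      mW.emplace_back(arma::size(net.W[l]), arma::fill::zeros);
      vW.emplace_back(arma::size(net.W[l]), arma::fill::zeros);
      mb.emplace_back(arma::size(net.b[l]), arma::fill::zeros);
      vb.emplace_back(arma::size(net.b[l]), arma::fill::zeros);
      mg.emplace_back(arma::size(net.gamma[l]), arma::fill::zeros);
      vg.emplace_back(arma::size(net.gamma[l]), arma::fill::zeros);
      mbe.emplace_back(arma::size(net.beta[l]), arma::fill::zeros);
      vbe.emplace_back(arma::size(net.beta[l]), arma::fill::zeros);
    }
  }
  template <typename T>
  void step_one(T& p, const T& g, T& m, T& v,
                float lr, float b1, float b2, float eps, float corr1, float corr2) {
    if (p.n_elem == 0) return;
    m = b1 * m + (1.f - b1) * g;
    v = b2 * v + (1.f - b2) * (g % g);
    p -= lr * (m / corr1) / (arma::sqrt(v / corr2) + eps);
  }
};

Net net_from_list(const List& model) {
  Net net;
  List W = model["weights"], b = model["biases"], g = model["gamma"],
       be = model["beta"], rm = model["rmean"], rv = model["rvar"];
  LogicalVector bn = model["has_bn"];
  net.latent_idx = as<int>(model["latent_index"]);
  for (int l = 0; l < W.size(); ++l) {
    NumericMatrix Wl = W[l];
    net.W.push_back(arma::conv_to<fmat>::from(
        arma::mat(Wl.begin(), Wl.nrow(), Wl.ncol(), false)));
    net.has_bn.push_back(bn[l]);
    auto getrow = [&](List& src) {
      NumericVector v = src[l];
      if (v.size() == 0) return frowvec();
      return arma::conv_to<frowvec>::from(
          arma::rowvec(v.begin(), v.size(), false));
    };
    net.b.push_back(getrow(b));
    net.gamma.push_back(getrow(g));
    net.beta.push_back(getrow(be));
    net.rmean.push_back(getrow(rm));
    net.rvar.push_back(getrow(rv));
  }
  return net;
}

} // namespace

// [[Rcpp::export]]
List ae_train_cpp(NumericMatrix X_, IntegerVector enc_widths, int latent_dim,
                  int epochs, int batch, double lr_, double beta1_,
                  double beta2_, double eps_adam_, double lambda_, int seed,
                  bool bn_latent) {
  const int n = X_.nrow(), d = X_.ncol();
  fmat X = arma::conv_to<fmat>::from(arma::mat(X_.begin(), n, d, false));
  if (!X.is_finite()) stop("non-finite values in training features");
  std::vector<int> enc(enc_widths.begin(), enc_widths.end());
  std::mt19937 gen(seed);
  Net net = build_net(d, enc, latent_dim, bn_latent, gen);
  Adam opt;
  opt.init(net);
  const float lr = (float)lr_, b1 = (float)beta1_, b2 = (float)beta2_,
              eps = (float)eps_adam_, lambda = (float)lambda_;
  const int L = (int)net.W.size();
  std::vector<int> order(n);
  for (int i = 0; i < n; ++i) order[i] = i;
  NumericVector loss_hist(epochs);

  std::vector<fmat> A(L + 1), xhat(L), dummy;
  std::vector<frowvec> invstd(L);

  for (int ep = 0; ep < epochs; ++ep) {
    std::shuffle(order.begin(), order.end(), gen);
    double ep_loss = 0;
    int n_batches = 0;
    for (int start = 0; start < n; start += batch) {
      const int B = std::min(batch, n - start);
      arma::uvec idx(B);
      for (int i = 0; i < B; ++i) idx[i] = order[start + i];
      A[0] = X.rows(idx);

      // forward (training mode)
      for (int l = 0; l < L; ++l) {
        fmat Z = A[l] * net.W[l];
        if (net.has_bn[l]) {
          frowvec mu = arma::mean(Z, 0);
          frowvec va = arma::mean(arma::square(Z), 0) - arma::square(mu);
          va = arma::clamp(va, 0.f, std::numeric_limits<float>::infinity());
          invstd[l] = 1.f / arma::sqrt(va + Net::bn_eps);
          Z.each_row() -= mu;
          Z.each_row() %= invstd[l];
          xhat[l] = Z;
          Z.each_row() %= net.gamma[l];
          Z.each_row() += net.beta[l];
          A[l + 1] = arma::clamp(Z, 0.f, std::numeric_limits<float>::infinity());
          const float ub = B > 1 ? (float)B / (B - 1) : 1.f;
          net.rmean[l] = (1.f - Net::bn_mom) * net.rmean[l] + Net::bn_mom * mu;
          net.rvar[l] = (1.f - Net::bn_mom) * net.rvar[l] + Net::bn_mom * va * ub;
        } else {
          Z.each_row() += net.b[l];
          A[l + 1] = std::move(Z);
        }
      }
      const fmat& latent = A[net.latent_idx + 1];
      const float mse = arma::accu(arma::square(A[L] - A[0])) / ((float)B * d);
      const float l1 = lambda * arma::accu(arma::abs(latent)) / (float)B;
      ep_loss += mse + l1;
      ++n_batches;

      // backward
      opt.t += 1;
      const float corr1 = 1.f - std::pow(b1, (float)opt.t);
      const float corr2 = 1.f - std::pow(b2, (float)opt.t);
      fmat dA = 2.f * (A[L] - A[0]) / ((float)B * d);
      for (int l = L - 1; l >= 0; --l) {
        if (l == net.latent_idx) {
          dA += (lambda / (float)B) * arma::sign(A[l + 1]);
        }
        fmat dZ;
        frowvec dgamma, dbeta;
        if (net.has_bn[l]) {
          fmat dY = dA % arma::conv_to<fmat>::from(A[l + 1] > 0.f);
          dgamma = arma::sum(dY % xhat[l], 0);
          dbeta = arma::sum(dY, 0);
          fmat dxhat = dY.each_row() % net.gamma[l];
          frowvec m1 = arma::mean(dxhat, 0);
          frowvec m2 = arma::mean(dxhat % xhat[l], 0);
          dZ = dxhat;
          dZ.each_row() -= m1;
          dZ -= xhat[l].each_row() % m2;
          dZ.each_row() %= invstd[l];
        } else {
          dZ = dA;
        }
        fmat dW = A[l].t() * dZ;
        if (l > 0) dA = dZ * net.W[l].t();
        opt.step_one(net.W[l], dW, opt.mW[l], opt.vW[l], lr, b1, b2, eps, corr1, corr2);
        if (net.has_bn[l]) {
          opt.step_one(net.gamma[l], dgamma, opt.mg[l], opt.vg[l], lr, b1, b2, eps, corr1, corr2);
          opt.step_one(net.beta[l], dbeta, opt.mbe[l], opt.vbe[l], lr, b1, b2, eps, corr1, corr2);
        } else {
          frowvec db = arma::sum(dZ, 0);
          opt.step_one(net.b[l], db, opt.mb[l], opt.vb[l], lr, b1, b2, eps, corr1, corr2);
        }
      }
    }
    loss_hist[ep] = ep_loss / n_batches;
  }

  auto mat_list = [&](const std::vector<fmat>& v) {
    List out(v.size());
    for (size_t i = 0; i < v.size(); ++i) {
      out[i] = wrap(arma::conv_to<arma::mat>::from(v[i]));
    }
    return out;
  };
  auto row_list = [&](const std::vector<frowvec>& v) {
    List out(v.size());
    for (size_t i = 0; i < v.size(); ++i) {
      out[i] = wrap(arma::conv_to<arma::rowvec>::from(v[i]));
    }
    return out;
  };
  return List::create(
      _["weights"] = mat_list(net.W), _["biases"] = row_list(net.b),
      _["gamma"] = row_list(net.gamma), _["beta"] = row_list(net.beta),
      _["rmean"] = row_list(net.rmean), _["rvar"] = row_list(net.rvar),
      _["has_bn"] = LogicalVector(net.has_bn.begin(), net.has_bn.end()),
      _["latent_index"] = net.latent_idx, _["loss"] = loss_hist);
}

// [[Rcpp::export]]
NumericMatrix ae_forward_cpp(List model, NumericMatrix X_, bool latent_only) {
  Net net = net_from_list(model);
  const int n = X_.nrow(), d = X_.ncol();
  if ((arma::uword)d != net.W[0].n_rows) stop("feature dimensionality mismatch");
  fmat X = arma::conv_to<fmat>::from(arma::mat(X_.begin(), n, d, false));
  if (!X.is_finite()) stop("non-finite values in features");
  fmat out = forward_eval(net, X, latent_only ? net.latent_idx : -1);
  return wrap(arma::conv_to<arma::mat>::from(out));
}
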