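// Convolutional VAE kernels: im2col/col2im convolutions, forward/backward
// passes and an Adam training loop. All stochastic draws (batch shuffling,
// reparameterization noise) come from R's RNG so set.seed() governs training.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;
using arma::mat;
using arma::vec;
using arma::uword;

namespace {

// Activations are stored as (channels x H*W*B) matrices; within an image,
// pixel (r, c) sits at column r + c*H (column-major, matching R matrices).
mat im2col(const mat& X, int C, int H, int W, int B,
           int k, int s, int pad, int Ho, int Wo) {
  mat cols(C * k * k, (uword)Ho * Wo * B, arma::fill::zeros);
  for (int b = 0; b < B; ++b) {
    const uword inOff = (uword)b * H * W;
    const uword outOff = (uword)b * Ho * Wo;
    for (int co = 0; co < Wo; ++co) {
      for (int ro = 0; ro < Ho; ++ro) {
        const uword out = outOff + ro + (uword)co * Ho;
        for (int dc = 0; dc < k; ++dc) {
          const int ci = co * s - pad + dc;
          if (ci < 0 || ci >= W) continue;
          for (int dr = 0; dr < k; ++dr) {
            const int ri = ro * s - pad + dr;
            if (ri < 0 || ri >= H) continue;
            const uword in = inOff + ri + (uword)ci * H;
            const uword row0 = (uword)(dc * k + dr);
            for (int ch = 0; ch < C; ++ch)
              cols((uword)ch * k * k + row0, out) = X(ch, in);
          }
        }
      }
    }
  }
  return cols;
}

// Adjoint of im2col: scatter-add columns back into the (C x H*W*B) grid.
mat col2im(const mat& cols, int C, int H, int W, int B,
           int k, int s, int pad, int Ho, int Wo) {
  mat X(C, (uword)H * W * B, arma::fill::zeros);
  for (int b = 0; b < B; ++b) {
    const uword inOff = (uword)b * H * W;
    const uword outOff = (uword)b * Ho * Wo;
    for (int co = 0; co < Wo; ++co) {
      for (int ro = 0; ro < Ho; ++ro) {
        const uword out = outOff + ro + (uword)co * Ho;
        for (int dc = 0; dc < k; ++dc) {
          const int ci = co * s - pad + dc;
          if (ci < 0 || ci >= W) continue;
          for (int dr = 0; dr < k; ++dr) {
            const int ri = ro * s - pad + dr;
            if (ri < 0 || ri >= H) continue;
            const uword in = inOff + ri + (uword)ci * H;
            const uword row0 = (uword)(dc * k + dr);
            for (int ch = 0; ch < C; ++ch)
              X(ch, in) += cols((uword)ch * k * k + row0, out);
          }
        }
      }
    }
  }
  return X;
}

struct Arch {
  int k, pad, c1, c2, d, L;
  int H0 = 64, H1 = 32, H2 = 16;
  int flat;
  std::string recon;
  explicit Arch(const List& cfg) {
    k = as<int>(cfg["kernel_size"]);
    pad = (k - 1) / 2;
    IntegerVector ch = cfg["conv_channels"];
    c1 = ch[0];
    c2 = ch[1];
    d = as<int>(cfg["dense_units"]);
    L = as<int>(cfg["latent_dim"]);
    flat = c2 * H2 * H2;
    recon = as<std::string>(cfg["recon_loss"]);
  }
};

struct Params {
  mat W1, W2, Wf, Wm, Wv, Wd1, Wd2, Wt1, Wt2;
  vec b1, b2, bf, bm, bv, bd1, bd2, bt1, bt2;

  static Params fromList(const List& w) {
    Params p;
    p.W1 = as<mat>(w["conv1_W"]);   p.b1 = as<vec>(w["conv1_b"]);
    p.W2 = as<mat>(w["conv2_W"]);   p.b2 = as<vec>(w["conv2_b"]);
    p.Wf = as<mat>(w["enc_fc_W"]);  p.bf = as<vec>(w["enc_fc_b"]);
    p.Wm = as<mat>(w["mu_W"]);      p.bm = as<vec>(w["mu_b"]);
    p.Wv = as<mat>(w["logvar_W"]);  p.bv = as<vec>(w["logvar_b"]);
    p.Wd1 = as<mat>(w["dec_fc1_W"]); p.bd1 = as<vec>(w["dec_fc1_b"]);
    p.Wd2 = as<mat>(w["dec_fc2_W"]); p.bd2 = as<vec>(w["dec_fc2_b"]);
    p.Wt1 = as<mat>(w["tconv1_W"]);  p.bt1 = as<vec>(w["tconv1_b"]);
    p.Wt2 = as<mat>(w["tconv2_W"]);  p.bt2 = as<vec>(w["tconv2_b"]);
    return p;
  }
  List toList() const {
    return List::create(
      _["conv1_W"] = W1, _["conv1_b"] = b1,
      _["conv2_W"] = W2, _["conv2_b"] = b2,
      _["enc_fc_W"] = Wf, _["enc_fc_b"] = bf,
      _["mu_W"] = Wm, _["mu_b"] = bm,
      _["logvar_W"] = Wv, _["logvar_b"] = bv,
      _["dec_fc1_W"] = Wd1, _["dec_fc1_b"] = bd1,
      _["dec_fc2_W"] = Wd2, _["dec_fc2_b"] = bd2,
      _["tconv1_W"] = Wt1, _["tconv1_b"] = bt1,
      _["tconv2_W"] = Wt2, _["tconv2_b"] = bt2);
  }
};

inline mat relu(const mat& x) { return arma::clamp(x, 0.0, arma::datum::inf); }

struct EncCache {
  mat X0, cols1, A1, R1, cols2, A2, R2, F, Hpre, H, mu, lv;
};

struct DecCache {
  mat z, D1p, D1, D2p, D2, G, U1p, U1, Lg, P;
};

// X0: (1 x 4096*B)
void encode_fwd(const Params& p, const Arch& a, const mat& X0, int B, EncCache& e) {
  e.X0 = X0;
  e.cols1 = im2col(X0, 1, a.H0, a.H0, B, a.k, 2, a.pad, a.H1, a.H1);
  e.A1 = p.W1 * e.cols1;
  e.A1.each_col() += p.b1;
  e.R1 = relu(e.A1);
  e.cols2 = im2col(e.R1, a.c1, a.H1, a.H1, B, a.k, 2, a.pad, a.H2, a.H2);
  e.A2 = p.W2 * e.cols2;
  e.A2.each_col() += p.b2;
  e.R2 = relu(e.A2);
  const int n2 = a.H2 * a.H2;
  e.F.set_size(a.flat, B);
  for (int b = 0; b < B; ++b)
    e.F.col(b) = arma::vectorise(e.R2.cols((uword)b * n2, (uword)(b + 1) * n2 - 1));
  e.Hpre = p.Wf * e.F;
  e.Hpre.each_col() += p.bf;
  e.H = relu(e.Hpre);
  e.mu = p.Wm * e.H;
  e.mu.each_col() += p.bm;
  e.lv = p.Wv * e.H;
  e.lv.each_col() += p.bv;
}

void decode_fwd(const Params& p, const Arch& a, const mat& z, int B, DecCache& d) {
  d.z = z;
  d.D1p = p.Wd1 * z;
  d.D1p.each_col() += p.bd1;
  d.D1 = relu(d.D1p);
  d.D2p = p.Wd2 * d.D1;
  d.D2p.each_col() += p.bd2;
  d.D2 = relu(d.D2p);
  const int n2 = a.H2 * a.H2;
  d.G.set_size(a.c2, (uword)n2 * B);
  for (int b = 0; b < B; ++b)
    d.G.cols((uword)b * n2, (uword)(b + 1) * n2 - 1) =
      arma::reshape(d.D2.col(b), a.c2, n2);
  mat colsU1 = p.Wt1.t() * d.G;  // (c1*k*k x H2*H2*B)
  d.U1p = col2im(colsU1, a.c1, a.H1, a.H1, B, a.k, 2, a.pad, a.H2, a.H2);
  d.U1p.each_col() += p.bt1;
  d.U1 = relu(d.U1p);
  mat colsU2 = p.Wt2.t() * d.U1;  // (k*k x H1*H1*B)
  d.Lg = col2im(colsU2, 1, a.H0, a.H0, B, a.k, 2, a.pad, a.H1, a.H1);
  d.Lg.each_col() += p.bt2;
  d.P = 1.0 / (1.0 + arma::exp(-d.Lg));
}

// Stable pixel-summed Bernoulli cross-entropy from logits.
double bce_from_logits(const mat& Lg, const mat& X) {
  mat term = arma::clamp(Lg, 0.0, arma::datum::inf) - Lg % X +
             arma::log1p(arma::exp(-arma::abs(Lg)));
  return arma::accu(term);
}

struct Grads {
  mat W1, W2, Wf, Wm, Wv, Wd1, Wd2, Wt1, Wt2;
  vec b1, b2, bf, bm, bv, bd1, bd2, bt1, bt2;
};

// Full forward/backward over one batch. Returns (recon_sum, kl_sum) over the
// batch; grads are of the batch-mean of per-image summed losses.
void vae_batch(const Params& p, const Arch& a, const mat& X0, const mat& eps,
               int B, Grads& g, double& recon_sum, double& kl_sum) {
  EncCache e;
  encode_fwd(p, a, X0, B, e);
  mat sd = arma::exp(0.5 * e.lv);
  mat z = e.mu + sd % eps;
  DecCache d;
  decode_fwd(p, a, z, B, d);

  kl_sum = -0.5 * arma::accu(1.0 + e.lv - arma::square(e.mu) - arma::exp(e.lv));
  mat dLg;
  if (a.recon == "gaussian") {
    recon_sum = arma::accu(arma::square(d.P - X0));
    dLg = 2.0 * (d.P - X0) % d.P % (1.0 - d.P) / B;
  } else {
    recon_sum = bce_from_logits(d.Lg, X0);
    dLg = (d.P - X0) / B;
  }

  const int n2 = a.H2 * a.H2;
  // decoder backward
  g.bt2 = arma::sum(dLg, 1);
  mat dcolsU2 = im2col(dLg, 1, a.H0, a.H0, B, a.k, 2, a.pad, a.H1, a.H1);
  g.Wt2 = d.U1 * dcolsU2.t();
  mat dU1 = p.Wt2 * dcolsU2;
  mat dU1p = dU1 % arma::conv_to<mat>::from(d.U1p > 0.0);
  g.bt1 = arma::sum(dU1p, 1);
  mat dcolsU1 = im2col(dU1p, a.c1, a.H1, a.H1, B, a.k, 2, a.pad, a.H2, a.H2);
  g.Wt1 = d.G * dcolsU1.t();
  mat dG = p.Wt1 * dcolsU1;
  mat dD2(a.flat, B);
  for (int b = 0; b < B; ++b)
    dD2.col(b) = arma::vectorise(dG.cols((uword)b * n2, (uword)(b + 1) * n2 - 1));
  mat dD2p = dD2 % arma::conv_to<mat>::from(d.D2p > 0.0);
  g.Wd2 = dD2p * d.D1.t();
  g.bd2 = arma::sum(dD2p, 1);
  mat dD1 = p.Wd2.t() * dD2p;
  mat dD1p = dD1 % arma::conv_to<mat>::from(d.D1p > 0.0);
  g.Wd1 = dD1p * d.z.t();
  g.bd1 = arma::sum(dD1p, 1);
  mat dz = p.Wd1.t() * dD1p;

  // latent heads (KL contributes mu/B and (exp(lv)-1)/(2B))
  mat dmu = dz + e.mu / B;
  mat dlv = 0.5 * dz % eps % sd + (arma::exp(e.lv) - 1.0) / (2.0 * B);
  g.Wm = dmu * e.H.t();
  g.bm = arma::sum(dmu, 1);
  g.Wv = dlv * e.H.t();
  g.bv = arma::sum(dlv, 1);

  // encoder backward
  mat dH = p.Wm.t() * dmu + p.Wv.t() * dlv;
  mat dHpre = dH % arma::conv_to<mat>::from(e.Hpre > 0.0);
  g.Wf = dHpre * e.F.t();
  g.bf = arma::sum(dHpre, 1);
  mat dF = p.Wf.t() * dHpre;
  mat dR2(a.c2, (uword)n2 * B);
  for (int b = 0; b < B; ++b)
    dR2.cols((uword)b * n2, (uword)(b + 1) * n2 - 1) =
      arma::reshape(dF.col(b), a.c2, n2);
  mat dA2 = dR2 % arma::conv_to<mat>::from(e.A2 > 0.0);
  g.W2 = dA2 * e.cols2.t();
  g.b2 = arma::sum(dA2, 1);
  mat dcols2 = p.W2.t() * dA2;
  mat dR1 = col2im(dcols2, a.c1, a.H1, a.H1, B, a.k, 2, a.pad, a.H2, a.H2);
  mat dA1 = dR1 % arma::conv_to<mat>::from(e.A1 > 0.0);
  g.W1 = dA1 * e.cols1.t();
  g.b1 = arma::sum(dA1, 1);
}

struct Adam {
  double lr, b1 = 0.9, b2 = 0.999, eps = 1e-8;
  long t = 0;
  std::vector<mat> m, v;
  explicit Adam(double lr_) : lr(lr_) {}
  void ensure(const std::vector<mat*>& params) {
    if (!m.empty()) return;
    for (auto* p : params) {
      m.push_back(mat(p->n_rows, p->n_cols, arma::fill::zeros));
      v.push_back(mat(p->n_rows, p->n_cols, arma::fill::zeros));
    }
  }
  void step(const std::vector<mat*>& params, const std::vector<const mat*>& grads) {
    ensure(params);
    ++t;
    const double c1 = 1.0 - std::pow(b1, (double)t);
    const double c2 = 1.0 - std::pow(b2, (double)t);
    for (size_t i = 0; i < params.size(); ++i) {
      m[i] = b1 * m[i] + (1.0 - b1) * (*grads[i]);
      v[i] = b2 * v[i] + (1.0 - b2) * arma::square(*grads[i]);
      *params[i] -= lr * (m[i] / c1) / (arma::sqrt(v[i] / c2) + eps);
    }
  }
};

// Copy selected image columns (4096 x N source) into a (1 x 4096*B) batch row.
mat gather_batch(const mat& images, const std::vector<int>& idx) {
  const uword npix = images.n_rows;
  mat X0(1, npix * idx.size());
  for (size_t b = 0; b < idx.size(); ++b)
    for (uword i = 0; i < npix; ++i)
      X0(0, (uword)b * npix + i) = images(i, idx[b]);
  return X0;
}

}  // namespace

// [[Rcpp::export]]
List vae_train_cpp(const arma::mat& images, List weights, List cfg) {
  RNGScope scope;
  const Arch a(cfg);
  if ((int)images.n_rows != a.H0 * a.H0)
    stop("images must be %d x N", a.H0 * a.H0);
  const int N = images.n_cols;
  if (N == 0) stop("empty training set");
  const int epochs = as<int>(cfg["epochs"]);
  const int batch = std::min(as<int>(cfg["batch_size"]), N);
  const double lr = as<double>(cfg["learning_rate"]);

  Params p = Params::fromList(weights);
  Adam opt(lr);
  std::vector<mat*> pv;
  // biases are vecs; wrap via address of underlying mat view is unsafe, so keep
  // them as 1-col mats within the update by treating vec as mat (arma::vec is a mat).
  pv = {&p.W1, (mat*)&p.b1, &p.W2, (mat*)&p.b2, &p.Wf, (mat*)&p.bf,
        &p.Wm, (mat*)&p.bm, &p.Wv, (mat*)&p.bv, &p.Wd1, (mat*)&p.bd1,
        &p.Wd2, (mat*)&p.bd2, &p.Wt1, (mat*)&p.bt1, &p.Wt2, (mat*)&p.bt2};

  std::vector<double> hist_total(epochs), hist_recon(epochs), hist_kl(epochs);
  std::vector<int> order(N);
  for (int i = 0; i < N; ++i) order[i] = i;

  for (int ep = 0; ep < epochs; ++ep) {
    checkUserInterrupt();
    // Fisher-Yates with R's RNG
    for (int i = N - 1; i > 0; --i) {
      int j = (int)std::floor(unif_rand() * (i + 1));
      if (j > i) j = i;
      std::swap(order[i], order[j]);
    }
    double ep_recon = 0.0, ep_kl = 0.0;
    for (int start = 0; start < N; start += batch) {
      const int B = std::min(batch, N - start);
      std::vector<int> idx(order.begin() + start, order.begin() + start + B);
      mat X0 = gather_batch(images, idx);
      mat eps(a.L, B);
      for (uword i = 0; i < eps.n_elem; ++i) eps(i) = norm_rand();
      Grads g;
      double recon_sum, kl_sum;
      vae_batch(p, a, X0, eps, B, g, recon_sum, kl_sum);
      if (!std::isfinite(recon_sum) || !std::isfinite(kl_sum))
        stop("non-finite loss at epoch %d", ep + 1);
      ep_recon += recon_sum;
      ep_kl += kl_sum;
      std::vector<const mat*> gv = {
        &g.W1, (const mat*)&g.b1, &g.W2, (const mat*)&g.b2,
        &g.Wf, (const mat*)&g.bf, &g.Wm, (const mat*)&g.bm,
        &g.Wv, (const mat*)&g.bv, &g.Wd1, (const mat*)&g.bd1,
        &g.Wd2, (const mat*)&g.bd2, &g.Wt1, (const mat*)&g.bt1,
        &g.Wt2, (const mat*)&g.bt2};
      opt.step(pv, gv);
    }
    hist_recon[ep] = ep_recon / N;
    hist_kl[ep] = ep_kl / N;
    hist_total[ep] = hist_recon[ep] + hist_kl[ep];
  }

  return List::create(
    _["weights"] = p.toList(),
    _["loss_total"] = hist_total,
    _["loss_recon"] = hist_recon,
    _["loss_kl"] = hist_kl);
}

// [[Rcpp::export]]
List vae_encode_cpp(const arma::mat& images, List weights, List cfg) {
  const Arch a(cfg);
  if ((int)images.n_rows != a.H0 * a.H0)
    stop("images must be %d x N", a.H0 * a.H0);
  const int N = images.n_cols;
  Params p = Params::fromList(weights);
  mat mu(a.L, N), lv(a.L, N);
  const int chunk = 128;
  for (int start = 0; start < N; start += chunk) {
    const int B = std::min(chunk, N - start);
    std::vector<int> idx(B);
    for (int i = 0; i < B; ++i) idx[i] = start + i;
    mat X0 = gather_batch(images, idx);
    EncCache e;
    encode_fwd(p, a, X0, B, e);
    mu.cols(start, start + B - 1) = e.mu;
    lv.cols(start, start + B - 1) = e.lv;
  }
  return List::create(_["mu"] = mu, _["logvar"] = lv);
}

// [[Rcpp::export]]
arma::mat vae_decode_cpp(const arma::mat& z, List weights, List cfg) {
  const Arch a(cfg);
  if ((int)z.n_rows != a.L) stop("z must be %d x N", a.L);
  const int N = z.n_cols;
  Params p = Params::fromList(weights);
  mat out(a.H0 * a.H0, N);
  const int chunk = 128;
  for (int start = 0; start < N; start += chunk) {
    const int B = std::min(chunk, N - start);
    DecCache d;
    decode_fwd(p, a, z.cols(start, start + B - 1), B, d);
    for (int b = 0; b < B; ++b)
      for (int i = 0; i < a.H0 * a.H0; ++i)
        out(i, start + b) = d.P(0, (uword)b * a.H0 * a.H0 + i);
  }
  return out;
}
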