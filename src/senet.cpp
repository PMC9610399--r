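// Compact SE-CNN used by the attribute classifiers: batched im2col
// convolutions, squeeze-and-excitation channel attention, softmax head,
// focal/cross-entropy gradients and Adam updates. Activation layout:
// one matrix per layer of shape (Nb*H*W) x C; within a sample block,
// row = i + H*j (column-major spatial order, matching R arrays).
#define ARMA_NO_DEBUG
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

namespace {

struct NetCfg {
  int H0, W0, k, n_classes, L;
  std::vector<int> ch, sh, sw;
  std::vector<bool> se;
};

NetCfg parse_cfg(const List& config) {
  NetCfg c;
  c.H0 = as<int>(config["input_h"]);
  c.W0 = as<int>(config["input_w"]);
  c.k = as<int>(config["kernel"]);
  c.n_classes = as<int>(config["n_classes"]);
  c.ch = as<std::vector<int>>(config["channels"]);
  c.sh = as<std::vector<int>>(config["stride_h"]);
  c.sw = as<std::vector<int>>(config["stride_w"]);
  LogicalVector se = config["use_se"];
  c.L = c.ch.size();
  for (int l = 0; l < c.L; ++l) c.se.push_back(se[l]);
  return c;
}

std::vector<arma::mat> parse_params(const List& params) {
  std::vector<arma::mat> out;
  for (int i = 0; i < params.size(); ++i)
    out.push_back(as<arma::mat>(params[i]));
  return out;
}

List wrap_params(const std::vector<arma::mat>& p, const List& tmpl) {
  List out(p.size());
  for (size_t i = 0; i < p.size(); ++i) out[i] = wrap(p[i]);
  out.attr("names") = tmpl.attr("names");
  return out;
}

// spatial source-offset table: entry (pos = io + Ho*jo, tap = di + k*dj)
// holds the input spatial index iin + H*jin, or -1 when the tap falls in
// the zero padding. Shared by every channel and sample.
arma::imat offset_table(int H, int W, int k, int sh, int sw, int pad,
                        int& Ho, int& Wo) {
  Ho = (H + 2 * pad - k) / sh + 1;
  Wo = (W + 2 * pad - k) / sw + 1;
  arma::imat tab(Ho * Wo, k * k);
  for (int dj = 0; dj < k; ++dj)
    for (int di = 0; di < k; ++di) {
      const int t = di + k * dj;
      for (int jo = 0; jo < Wo; ++jo) {
        const int jin = jo * sw + dj - pad;
        for (int io = 0; io < Ho; ++io) {
          const int iin = io * sh + di - pad;
          tab(io + Ho * jo, t) =
              (iin < 0 || iin >= H || jin < 0 || jin >= W)
                  ? -1 : iin + H * jin;
        }
      }
    }
  return tab;
}

template <typename eT>
arma::Mat<eT> im2col(const arma::Mat<eT>& A, int Nb, int H, int W,
                     const arma::imat& tab, int k) {
  const int C = A.n_cols;
  const size_t HW = (size_t)H * W, HoWo = tab.n_rows;
  arma::Mat<eT> P((size_t)Nb * HoWo, (size_t)k * k * C);
  for (int c = 0; c < C; ++c) {
    const eT* srcbase = A.colptr(c);
    for (int t = 0; t < k * k; ++t) {
      eT* dst = P.colptr(t + k * k * c);
      const arma::sword* off = tab.colptr(t);
      for (int n = 0; n < Nb; ++n) {
        const eT* s = srcbase + (size_t)n * HW;
        for (size_t pos = 0; pos < HoWo; ++pos)
          *dst++ = off[pos] >= 0 ? s[off[pos]] : eT(0);
      }
    }
  }
  return P;
}

template <typename eT>
void col2im_add(arma::Mat<eT>& dA, const arma::Mat<eT>& dP, int Nb, int H, int W,
                const arma::imat& tab, int k) {
  const int C = dA.n_cols;
  const size_t HW = (size_t)H * W, HoWo = tab.n_rows;
  for (int c = 0; c < C; ++c) {
    eT* dstbase = dA.colptr(c);
    for (int t = 0; t < k * k; ++t) {
      const eT* src = dP.colptr(t + k * k * c);
      const arma::sword* off = tab.colptr(t);
      for (int n = 0; n < Nb; ++n) {
        eT* d = dstbase + (size_t)n * HW;
        for (size_t pos = 0; pos < HoWo; ++pos, ++src)
          if (off[pos] >= 0) d[off[pos]] += *src;
      }
    }
  }
}

template <typename eT>
inline void relu_inplace(arma::Mat<eT>& O) {
  eT* p = O.memptr();
  for (size_t i = 0; i < O.n_elem; ++i)
    if (p[i] < 0) p[i] = 0;
}

// zero entries of dA where the reference activation is zero (ReLU mask)
template <typename eT>
inline void relu_mask(arma::Mat<eT>& dA, const arma::Mat<eT>& ref) {
  eT* p = dA.memptr();
  const eT* r = ref.memptr();
  for (size_t i = 0; i < dA.n_elem; ++i)
    if (r[i] <= 0) p[i] = 0;
}

template <typename eT>
struct Cache {
  std::vector<arma::Mat<eT>> P;      // im2col patches per layer
  std::vector<arma::Mat<eT>> act;    // final layer activations (post SE)
  std::vector<arma::Mat<eT>> se_in;  // post-ReLU, pre-SE (SE layers only)
  std::vector<arma::Mat<eT>> zs, hs, ws; // SE squeeze/bottleneck/weights
  std::vector<arma::imat> tab;
  std::vector<int> Hs, Ws;
  arma::Mat<eT> g;      // GAP output (C_last x Nb)
  arma::Mat<eT> logits; // (n_classes x Nb)
};

// params layout: per layer l: W_l (kkCin x Cout), b_l (Cout x 1),
// then if use_se[l]: S1 (bneck x C), t1 (bneck x 1), S2 (C x bneck),
// t2 (C x 1); finally Wd (n_classes x C_last), bd (n_classes x 1).
template <typename eT>
void forward_net(const arma::Mat<eT>& X, const std::vector<arma::Mat<eT>>& par,
                 const NetCfg& cfg, int Nb, Cache<eT>& cc) {
  const arma::Mat<eT>* A = &X;
  int H = cfg.H0, W = cfg.W0;
  size_t pi = 0;
  for (int l = 0; l < cfg.L; ++l) {
    int Ho, Wo;
    arma::imat tab = offset_table(H, W, cfg.k, cfg.sh[l], cfg.sw[l], 1, Ho, Wo);
    arma::Mat<eT> P = im2col<eT>(*A, Nb, H, W, tab, cfg.k);
    const arma::Mat<eT>& Wl = par[pi++];
    const arma::Mat<eT>& bl = par[pi++];
    arma::Mat<eT> O = P * Wl;
    O.each_row() += bl.t();
    relu_inplace(O);
    cc.P.push_back(std::move(P));
    cc.tab.push_back(std::move(tab));
    const int C = cfg.ch[l];
    const size_t hw = (size_t)Ho * Wo;
    if (cfg.se[l]) {
      cc.se_in.push_back(O);  // copy: pre-SE activations
      const arma::Mat<eT>& S1 = par[pi++]; const arma::Mat<eT>& t1 = par[pi++];
      const arma::Mat<eT>& S2 = par[pi++]; const arma::Mat<eT>& t2 = par[pi++];
      arma::Mat<eT> Z(C, Nb), Hh(S1.n_rows, Nb), Wg(C, Nb);
      for (int n = 0; n < Nb; ++n) {
        arma::Col<eT> z(C);
        for (int c = 0; c < C; ++c) {
          const eT* p = O.colptr(c) + (size_t)n * hw;
          eT s = 0;
          for (size_t i = 0; i < hw; ++i) s += p[i];
          z[c] = s / (eT)hw;
        }
        arma::Col<eT> h = S1 * z + t1.col(0);
        for (arma::uword i = 0; i < h.n_elem; ++i) if (h[i] < 0) h[i] = 0;
        arma::Col<eT> w = eT(1) / (eT(1) + arma::exp(-(S2 * h + t2.col(0))));
        for (int c = 0; c < C; ++c) {
          eT* p = O.colptr(c) + (size_t)n * hw;
          const eT wc = w[c];
          for (size_t i = 0; i < hw; ++i) p[i] *= wc;
        }
        Z.col(n) = z; Hh.col(n) = h; Wg.col(n) = w;
      }
      cc.zs.push_back(std::move(Z)); cc.hs.push_back(std::move(Hh));
      cc.ws.push_back(std::move(Wg));
    } else {
      cc.se_in.push_back(arma::Mat<eT>());
      cc.zs.push_back(arma::Mat<eT>()); cc.hs.push_back(arma::Mat<eT>());
      cc.ws.push_back(arma::Mat<eT>());
    }
    cc.act.push_back(std::move(O));
    cc.Hs.push_back(Ho); cc.Ws.push_back(Wo);
    A = &cc.act.back();
    H = Ho; W = Wo;
  }
  const int CL = cfg.ch[cfg.L - 1];
  const size_t hw = (size_t)H * W;
  cc.g.set_size(CL, Nb);
  const arma::Mat<eT>& last = cc.act.back();
  for (int n = 0; n < Nb; ++n)
    for (int c = 0; c < CL; ++c) {
      const eT* p = last.colptr(c) + (size_t)n * hw;
      eT s = 0;
      for (size_t i = 0; i < hw; ++i) s += p[i];
      cc.g(c, n) = s / (eT)hw;
    }
  const arma::Mat<eT>& Wd = par[pi++];
  const arma::Mat<eT>& bd = par[pi++];
  cc.logits = Wd * cc.g;
  cc.logits.each_col() += bd.col(0);
}

template <typename eT>
arma::Mat<eT> softmax_cols(const arma::Mat<eT>& z) {
  arma::Mat<eT> p = z;
  p.each_row() -= arma::max(z, 0);
  p = arma::exp(p);
  p.each_row() /= arma::sum(p, 0);
  return p;
}

// focal loss value and gradient wrt logits; y is 0-based class index
template <typename eT>
double focal_grad(const arma::Mat<eT>& logits, const arma::uvec& y,
                  const arma::vec& alpha, double gamma, arma::Mat<eT>& dz) {
  const int Nb = logits.n_cols;
  arma::Mat<eT> p = softmax_cols<eT>(logits);
  dz.set_size(logits.n_rows, Nb);
  double loss = 0.0;
  for (int n = 0; n < Nb; ++n) {
    const unsigned t = y[n];
    double pt = std::min(std::max((double)p(t, n), 1e-12), 1.0 - 1e-12);
    const double at = alpha[t];
    const double om = 1.0 - pt;
    loss += -at * std::pow(om, gamma) * std::log(pt);
    const double fac = gamma > 0.0
        ? gamma * pt * std::pow(om, gamma - 1.0) * std::log(pt) - std::pow(om, gamma)
        : -1.0;
    for (arma::uword j = 0; j < logits.n_rows; ++j) {
      const double delta = (j == t) ? 1.0 : 0.0;
      dz(j, n) = at * (delta - p(j, n)) * fac / Nb;
    }
  }
  return loss / Nb;
}

template <typename eT>
void backward_net(const arma::Mat<eT>& X, const std::vector<arma::Mat<eT>>& par,
                  const NetCfg& cfg, int Nb, const Cache<eT>& cc,
                  const arma::Mat<eT>& dlogits, std::vector<arma::Mat<eT>>& grad) {
  grad.resize(par.size());
  std::vector<size_t> base(cfg.L);
  size_t pi = 0;
  for (int l = 0; l < cfg.L; ++l) { base[l] = pi; pi += 2 + (cfg.se[l] ? 4 : 0); }
  const size_t dense_i = pi;
  const arma::Mat<eT>& Wd = par[dense_i];
  grad[dense_i] = dlogits * cc.g.t();
  grad[dense_i + 1] = arma::sum(dlogits, 1);
  arma::Mat<eT> dg = Wd.t() * dlogits; // C_last x Nb
  int H = cc.Hs[cfg.L - 1], W = cc.Ws[cfg.L - 1];
  size_t hw = (size_t)H * W;
  arma::Mat<eT> dA((size_t)Nb * hw, cfg.ch[cfg.L - 1]);
  for (int c = 0; c < cfg.ch[cfg.L - 1]; ++c) {
    eT* d = dA.colptr(c);
    for (int n = 0; n < Nb; ++n) {
      const eT v = dg(c, n) / (eT)hw;
      for (size_t i = 0; i < hw; ++i) *d++ = v;
    }
  }
  for (int l = cfg.L - 1; l >= 0; --l) {
    H = cc.Hs[l]; W = cc.Ws[l]; hw = (size_t)H * W;
    const int C = cfg.ch[l];
    if (cfg.se[l]) {
      const arma::Mat<eT>& S1 = par[base[l] + 2]; const arma::Mat<eT>& S2 = par[base[l] + 4];
      arma::Mat<eT> gS1(arma::size(S1), arma::fill::zeros), gt1(S1.n_rows, 1, arma::fill::zeros);
      arma::Mat<eT> gS2(arma::size(S2), arma::fill::zeros), gt2(C, 1, arma::fill::zeros);
      for (int n = 0; n < Nb; ++n) {
        const arma::Col<eT> w = cc.ws[l].col(n), h = cc.hs[l].col(n), z = cc.zs[l].col(n);
        arma::Col<eT> dw(C), dzv;
        for (int c = 0; c < C; ++c) {
          const eT* xb = cc.se_in[l].colptr(c) + (size_t)n * hw;
          eT* db = dA.colptr(c) + (size_t)n * hw;
          eT s = 0;
          const eT wc = w[c];
          for (size_t i = 0; i < hw; ++i) {
            s += db[i] * xb[i];
            db[i] *= wc;           // dx via the rescale path
          }
          dw[c] = s;
        }
        arma::Col<eT> da = dw % w % (eT(1) - w);
        gS2 += da * h.t();
        gt2 += da;
        arma::Col<eT> dh = S2.t() * da;
        for (arma::uword i = 0; i < dh.n_elem; ++i) if (h[i] <= 0) dh[i] = 0;
        gS1 += dh * z.t();
        gt1 += dh;
        dzv = S1.t() * dh;
        for (int c = 0; c < C; ++c) {
          eT* db = dA.colptr(c) + (size_t)n * hw;
          const eT v = dzv[c] / (eT)hw;
          for (size_t i = 0; i < hw; ++i) db[i] += v;  // dx via the squeeze path
        }
      }
      grad[base[l] + 2] = gS1; grad[base[l] + 3] = gt1;
      grad[base[l] + 4] = gS2; grad[base[l] + 5] = gt2;
      relu_mask(dA, cc.se_in[l]);
    } else {
      relu_mask(dA, cc.act[l]);
    }
    grad[base[l]] = cc.P[l].t() * dA;
    grad[base[l] + 1] = arma::sum(dA, 0).t();
    if (l > 0) {
      const int Hp = cc.Hs[l - 1], Wp = cc.Ws[l - 1], Cp = cfg.ch[l - 1];
      arma::Mat<eT> dP = dA * par[base[l]].t();
      arma::Mat<eT> dPrev((size_t)Nb * Hp * Wp, Cp, arma::fill::zeros);
      col2im_add<eT>(dPrev, dP, Nb, Hp, Wp, cc.tab[l], cfg.k);
      dA = std::move(dPrev);
    }
  }
}

arma::mat as_blocks(const NumericVector& X, int H, int W, int& N) {
  IntegerVector dim = X.attr("dim");
  if (dim.size() != 3 || dim[0] != H || dim[1] != W)
    stop("input array must have dim (H, W, N) matching the model config");
  N = dim[2];
  // single input channel: samples stack contiguously into one column
  return arma::mat(const_cast<double*>(X.begin()), (size_t)H * W * N, 1, true);
}

} // namespace

// [[Rcpp::export]]
NumericMatrix senet_forward_cpp(NumericVector X, List params, List config) {
  NetCfg cfg = parse_cfg(config);
  int N;
  arma::mat A = as_blocks(X, cfg.H0, cfg.W0, N);
  std::vector<arma::mat> par = parse_params(params);
  Cache<double> cc;
  forward_net<double>(A, par, cfg, N, cc);
  arma::mat p = softmax_cols<double>(cc.logits).t(); // N x n_classes
  return wrap(p);
}

// [[Rcpp::export]]
List senet_grad_cpp(NumericVector X, IntegerVector y, List params, List config,
                    NumericVector alpha, double gamma) {
  NetCfg cfg = parse_cfg(config);
  int N;
  arma::mat A = as_blocks(X, cfg.H0, cfg.W0, N);
  std::vector<arma::mat> par = parse_params(params);
  Cache<double> cc;
  forward_net<double>(A, par, cfg, N, cc);
  arma::uvec yy(N);
  for (int n = 0; n < N; ++n) yy[n] = y[n] - 1;
  arma::vec al = as<arma::vec>(alpha);
  arma::mat dz;
  double loss = focal_grad<double>(cc.logits, yy, al, gamma, dz);
  std::vector<arma::mat> grad;
  backward_net<double>(A, par, cfg, N, cc, dz, grad);
  return List::create(_["loss"] = loss,
                      _["grads"] = wrap_params(grad, params));
}

// Training runs in single precision (Adam moments in float as well); the
// exported forward/gradient entry points above stay in double so they can
// serve as exact oracles. Deterministic: single-threaded, no internal RNG
// (the shuffling permutation comes from the caller).
// [[Rcpp::export]]
List senet_train_cpp(NumericVector X, IntegerVector y, List params, List config,
                     NumericVector alpha, double gamma, IntegerMatrix perm,
                     double lr, int batch_size) {
  NetCfg cfg = parse_cfg(config);
  int N;
  arma::fmat A = arma::conv_to<arma::fmat>::from(
      as_blocks(X, cfg.H0, cfg.W0, N));
  std::vector<arma::mat> par_d = parse_params(params);
  std::vector<arma::fmat> par(par_d.size());
  for (size_t i = 0; i < par_d.size(); ++i)
    par[i] = arma::conv_to<arma::fmat>::from(par_d[i]);
  arma::vec al = as<arma::vec>(alpha);
  const int epochs = perm.ncol();
  const size_t hw = (size_t)cfg.H0 * cfg.W0;
  std::vector<arma::fmat> m(par.size()), v(par.size());
  for (size_t i = 0; i < par.size(); ++i) {
    m[i] = arma::fmat(par[i].n_rows, par[i].n_cols, arma::fill::zeros);
    v[i] = arma::fmat(par[i].n_rows, par[i].n_cols, arma::fill::zeros);
  }
  const float b1 = 0.9f, b2 = 0.999f, eps = 1e-8f;
  long step = 0;
  NumericVector epoch_loss(epochs);
  for (int e = 0; e < epochs; ++e) {
    double tot = 0.0;
    for (int start = 0; start < N; start += batch_size) {
      const int nb = std::min(batch_size, N - start);
      arma::fmat Xb((size_t)nb * hw, 1);
      arma::uvec yb(nb);
      for (int i = 0; i < nb; ++i) {
        const int src = perm(start + i, e) - 1;
        std::copy(A.colptr(0) + (size_t)src * hw,
                  A.colptr(0) + (size_t)(src + 1) * hw,
                  Xb.colptr(0) + (size_t)i * hw);
        yb[i] = y[src] - 1;
      }
      Cache<float> cc;
      forward_net<float>(Xb, par, cfg, nb, cc);
      arma::fmat dz;
      const double loss = focal_grad<float>(cc.logits, yb, al, gamma, dz);
      if (!std::isfinite(loss))
        stop("training diverged (non-finite loss) at epoch %d", e + 1);
      tot += loss * nb;
      std::vector<arma::fmat> grad;
      backward_net<float>(Xb, par, cfg, nb, cc, dz, grad);
      ++step;
      const float corr = lr * std::sqrt(1.0 - std::pow((double)b2, (double)step)) /
                         (1.0 - std::pow((double)b1, (double)step));
      for (size_t i = 0; i < par.size(); ++i) {
        m[i] = b1 * m[i] + (1.0f - b1) * grad[i];
        v[i] = b2 * v[i] + (1.0f - b2) * arma::square(grad[i]);
        par[i] -= corr * m[i] / (arma::sqrt(v[i]) + eps);
      }
    }
    epoch_loss[e] = tot / N;
  }
  for (size_t i = 0; i < par.size(); ++i)
    par_d[i] = arma::conv_to<arma::mat>::from(par[i]);
  return List::create(_["params"] = wrap_params(par_d, params),
                      _["epoch_loss"] = epoch_loss);
}
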