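// Small convolutional network used as the desk-scale differentiable
// classifier: 2x2 average pool -> [3x3 conv, ReLU, 2x2 max pool] x2 ->
// fully connected softmax head. Exact input-pixel gradients are required
// by the fast-gradient-sign attack, so forward and backward passes are
// written out explicitly.
//
// Image layout: a batch is a D x N matrix whose columns are images
// flattened in R's native (H, W, C) array order, i.e. element index
// h + H*w + H*W*c (0-based). Feature maps inside the network are stored
// as channels x (height*width) matrices with spatial index y + h*x.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;
using namespace arma;

namespace {

struct Net {
  int H, W, C, F1, F2, K;
  int h1, w1, h2, w2, h3, w3;
  mat W1, W2, Wf;
  vec b1, b2, bf;
};

Net unpack(const List& params, int H, int W, int C) {
  Net n;
  n.H = H; n.W = W; n.C = C;
  n.W1 = as<mat>(params["W1"]); n.b1 = as<vec>(params["b1"]);
  n.W2 = as<mat>(params["W2"]); n.b2 = as<vec>(params["b2"]);
  n.Wf = as<mat>(params["Wf"]); n.bf = as<vec>(params["bf"]);
  n.F1 = n.W1.n_rows; n.F2 = n.W2.n_rows; n.K = n.Wf.n_rows;
  n.h1 = H / 2; n.w1 = W / 2;
  n.h2 = n.h1 / 2; n.w2 = n.w1 / 2;
  n.h3 = n.h2 / 2; n.w3 = n.w2 / 2;
  return n;
}

mat avgpool2(const mat& in, int hh, int ww) {
  const int h2 = hh / 2, w2 = ww / 2;
  mat out(in.n_rows, h2 * w2);
  for (int x = 0; x < w2; ++x)
    for (int y = 0; y < h2; ++y)
      out.col(y + h2 * x) =
        0.25 * (in.col(2 * y     + hh * (2 * x))     +
                in.col(2 * y + 1 + hh * (2 * x))     +
                in.col(2 * y     + hh * (2 * x + 1)) +
                in.col(2 * y + 1 + hh * (2 * x + 1)));
  return out;
}

mat avgpool2_back(const mat& dout, int hh, int ww) {
  const int h2 = hh / 2, w2 = ww / 2;
  mat din(dout.n_rows, hh * ww, fill::zeros);
  for (int x = 0; x < w2; ++x)
    for (int y = 0; y < h2; ++y) {
      vec g = 0.25 * dout.col(y + h2 * x);
      din.col(2 * y     + hh * (2 * x))     += g;
      din.col(2 * y + 1 + hh * (2 * x))     += g;
      din.col(2 * y     + hh * (2 * x + 1)) += g;
      din.col(2 * y + 1 + hh * (2 * x + 1)) += g;
    }
  return din;
}

// 3x3 same-padding patch extraction: F x (hh*ww) -> (9F) x (hh*ww)
mat im2col3(const mat& in, int hh, int ww) {
  const int F = in.n_rows;
  mat cols(9 * F, hh * ww, fill::zeros);
  for (int x = 0; x < ww; ++x)
    for (int y = 0; y < hh; ++y) {
      const int s = y + hh * x;
      for (int dx = -1; dx <= 1; ++dx) {
        const int xx = x + dx;
        if (xx < 0 || xx >= ww) continue;
        for (int dy = -1; dy <= 1; ++dy) {
          const int yy = y + dy;
          if (yy < 0 || yy >= hh) continue;
          const int kr = (dx + 1) * 3 + (dy + 1);
          for (int f = 0; f < F; ++f)
            cols(f * 9 + kr, s) = in(f, yy + hh * xx);
        }
      }
    }
  return cols;
}

mat col2im3(const mat& dcols, int F, int hh, int ww) {
  mat din(F, hh * ww, fill::zeros);
  for (int x = 0; x < ww; ++x)
    for (int y = 0; y < hh; ++y) {
      const int s = y + hh * x;
      for (int dx = -1; dx <= 1; ++dx) {
        const int xx = x + dx;
        if (xx < 0 || xx >= ww) continue;
        for (int dy = -1; dy <= 1; ++dy) {
          const int yy = y + dy;
          if (yy < 0 || yy >= hh) continue;
          const int kr = (dx + 1) * 3 + (dy + 1);
          for (int f = 0; f < F; ++f)
            din(f, yy + hh * xx) += dcols(f * 9 + kr, s);
        }
      }
    }
  return din;
}

mat maxpool2(const mat& in, int hh, int ww, umat& argmax) {
  const int h2 = hh / 2, w2 = ww / 2, F = in.n_rows;
  mat out(F, h2 * w2);
  argmax.set_size(F, h2 * w2);
  for (int x = 0; x < w2; ++x)
    for (int y = 0; y < h2; ++y) {
      const int s = y + h2 * x;
      const int cand[4] = {2 * y     + hh * (2 * x),
                           2 * y + 1 + hh * (2 * x),
                           2 * y     + hh * (2 * x + 1),
                           2 * y + 1 + hh * (2 * x + 1)};
      for (int f = 0; f < F; ++f) {
        double best = in(f, cand[0]);
        int bi = cand[0];
        for (int k = 1; k < 4; ++k)
          if (in(f, cand[k]) > best) { best = in(f, cand[k]); bi = cand[k]; }
        out(f, s) = best;
        argmax(f, s) = bi;
      }
    }
  return out;
}

mat maxpool2_back(const mat& dout, const umat& argmax, int hh, int ww) {
  const int F = dout.n_rows;
  mat din(F, hh * ww, fill::zeros);
  for (uword s = 0; s < dout.n_cols; ++s)
    for (int f = 0; f < F; ++f)
      din(f, argmax(f, s)) += dout(f, s);
  return din;
}

struct Cache {
  mat cols1, a1, cols2, a2, m2p;
  umat arg1, arg2;
};

vec forward_one(const Net& n, const vec& x, Cache* cache) {
  // (H,W,C) flat vector -> channels x pixels
  mat img = reshape(x, n.H * n.W, n.C).t();
  mat mp = avgpool2(img, n.H, n.W);
  mat cols1 = im2col3(mp, n.h1, n.w1);
  mat a1 = n.W1 * cols1;
  a1.each_col() += n.b1;
  a1.transform([](double v) { return v > 0 ? v : 0.0; });
  umat arg1;
  mat m1p = maxpool2(a1, n.h1, n.w1, arg1);
  mat cols2 = im2col3(m1p, n.h2, n.w2);
  mat a2 = n.W2 * cols2;
  a2.each_col() += n.b2;
  a2.transform([](double v) { return v > 0 ? v : 0.0; });
  umat arg2;
  mat m2p = maxpool2(a2, n.h2, n.w2, arg2);
  vec z = n.Wf * vectorise(m2p) + n.bf;
  if (cache) {
    cache->cols1 = std::move(cols1); cache->a1 = std::move(a1);
    cache->arg1 = std::move(arg1);
    cache->cols2 = std::move(cols2); cache->a2 = std::move(a2);
    cache->arg2 = std::move(arg2);
    cache->m2p = std::move(m2p);
  }
  return z;
}

vec softmax_vec(const vec& z) {
  vec e = exp(z - z.max());
  return e / accu(e);
}

struct Grads {
  mat gW1, gW2, gWf;
  vec gb1, gb2, gbf;
  void init(const Net& n) {
    gW1.zeros(n.W1.n_rows, n.W1.n_cols); gb1.zeros(n.b1.n_elem);
    gW2.zeros(n.W2.n_rows, n.W2.n_cols); gb2.zeros(n.b2.n_elem);
    gWf.zeros(n.Wf.n_rows, n.Wf.n_cols); gbf.zeros(n.bf.n_elem);
  }
};

// backprop from the logit gradient dz; accumulates parameter gradients
// into g (if non-null) and returns the input-pixel gradient (if wanted)
vec backward_one(const Net& n, const Cache& c, const vec& dz,
                 Grads* g, bool want_input) {
  if (g) { g->gWf += dz * vectorise(c.m2p).t(); g->gbf += dz; }
  mat dm2p = reshape(n.Wf.t() * dz, n.F2, n.h3 * n.w3);
  mat da2 = maxpool2_back(dm2p, c.arg2, n.h2, n.w2);
  da2 %= conv_to<mat>::from(c.a2 > 0);
  if (g) { g->gW2 += da2 * c.cols2.t(); g->gb2 += sum(da2, 1); }
  mat dm1p = col2im3(n.W2.t() * da2, n.F1, n.h2, n.w2);
  mat da1 = maxpool2_back(dm1p, c.arg1, n.h1, n.w1);
  da1 %= conv_to<mat>::from(c.a1 > 0);
  if (g) { g->gW1 += da1 * c.cols1.t(); g->gb1 += sum(da1, 1); }
  if (!want_input) return vec();
  mat dmp = col2im3(n.W1.t() * da1, n.C, n.h1, n.w1);
  mat dimg = avgpool2_back(dmp, n.H, n.W);  // C x (H*W)
  return vectorise(dimg.t());
}

}  // namespace

// [[Rcpp::export]]
arma::mat cpp_cnn_scores(List params, const arma::mat& x, int H, int W, int C) {
  Net n = unpack(params, H, W, C);
  mat out(n.K, x.n_cols);
  for (uword i = 0; i < x.n_cols; ++i)
    out.col(i) = forward_one(n, x.col(i), nullptr);
  return out;
}

// Cross-entropy loss and gradients. Parameter gradients (and the loss)
// are averaged over the batch when mean_over_batch is true; input-pixel
// gradients are always per-image (the FGSM convention).
// [[Rcpp::export]]
List cpp_cnn_grads(List params, const arma::mat& x, const arma::ivec& y,
                   int H, int W, int C,
                   bool param_grads, bool input_grads, bool mean_over_batch) {
  Net n = unpack(params, H, W, C);
  const int N = x.n_cols;
  Grads g;
  if (param_grads) g.init(n);
  mat gx;
  if (input_grads) gx.set_size(x.n_rows, N);
  double loss = 0.0;
  for (int i = 0; i < N; ++i) {
    Cache c;
    vec z = forward_one(n, x.col(i), &c);
    vec p = softmax_vec(z);
    const int yi = y(i);
    loss += -std::log(std::max(p(yi), 1e-300));
    vec dz = p;
    dz(yi) -= 1.0;
    vec gin = backward_one(n, c, dz, param_grads ? &g : nullptr, input_grads);
    if (input_grads) gx.col(i) = gin;
  }
  const double scale = mean_over_batch ? 1.0 / N : 1.0;
  List out = List::create(_["loss"] = loss * scale);
  if (param_grads) {
    out["gW1"] = g.gW1 * scale; out["gb1"] = g.gb1 * scale;
    out["gW2"] = g.gW2 * scale; out["gb2"] = g.gb2 * scale;
    out["gWf"] = g.gWf * scale; out["gbf"] = g.gbf * scale;
  }
  if (input_grads) out["gx"] = gx;
  return out;
}

// Fused inner loop of the iterative universal-perturbation algorithm.
// orders is an N x n_pass matrix of 0-based visit orders (one shuffled
// pass per column, drawn R-side so the R reference path and this path
// traverse identically). grad_labels are the labels the cross-entropy
// is differentiated at (true labels for nontargeted, the target class
// for targeted). pnorm is 2 or Inf.
// [[Rcpp::export]]
List cpp_uap_passes(List params, const arma::mat& x,
                    const arma::ivec& grad_labels, const arma::ivec& ref_pred,
                    arma::vec rho, int H, int W, int C,
                    double eps, double xi, double pnorm,
                    bool targeted, int target, const arma::imat& orders) {
  Net n = unpack(params, H, W, C);
  const int npass = orders.n_cols;
  ivec updates(npass, fill::zeros);
  for (int pass = 0; pass < npass; ++pass) {
    for (uword k = 0; k < orders.n_rows; ++k) {
      const int i = orders(k, pass);
      vec xa = clamp(x.col(i) + rho, 0.0, 1.0);
      Cache c;
      vec z = forward_one(n, xa, &c);
      const int pred = z.index_max();
      const bool defeated = targeted ? (pred == target)
                                     : (pred != ref_pred(i));
      if (defeated) continue;
      vec p = softmax_vec(z);
      vec dz = p;
      dz(grad_labels(i)) -= 1.0;
      vec gin = backward_one(n, c, dz, nullptr, true);
      if (targeted) rho -= eps * sign(gin); else rho += eps * sign(gin);
      if (std::isinf(pnorm)) {
        rho = clamp(rho, -xi, xi);
      } else {
        const double nr = norm(rho, 2);
        if (nr > xi) rho *= xi / nr;
      }
      updates(pass) += 1;
    }
  }
  return List::create(_["rho"] = rho, _["updates"] = updates);
}
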