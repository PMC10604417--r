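// Forward and backward passes of the per-slice segmentation UNet.
// Feature maps are arma::cube (H, W, C); 3x3 conv weights are
// (9*Cin) x Cout matrices applied by GEMM on an im2col matrix, so the
// whole pass is a chain of BLAS calls. The full pass for one slice runs in
// a single call to keep R-boundary copies off the training loop.
#include <RcppArmadillo.h>
#include <map>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

// im2col for a 3x3 kernel with zero padding 1: rows index pixels
// (column-major over H then W), columns index (offset, channel): c*9 + o.
static arma::mat im2col3(const arma::cube &x) {
  const arma::uword H = x.n_rows, W = x.n_cols, C = x.n_slices;
  arma::mat M(H * W, 9 * C, arma::fill::zeros);
  for (arma::uword c = 0; c < C; ++c) {
    arma::uword o = 0;
    for (int dx = -1; dx <= 1; ++dx) {
      for (int dy = -1; dy <= 1; ++dy, ++o) {
        for (arma::uword j = 0; j < W; ++j) {
          const int js = (int)j + dx;
          if (js < 0 || js >= (int)W) continue;
          const int i0 = std::max(0, -dy), i1 = (int)H - 1 - std::max(0, dy);
          if (i1 < i0) continue;
          M(arma::span(j * H + i0, j * H + i1), arma::span(c * 9 + o)) =
            x.slice(c)(arma::span(i0 + dy, i1 + dy), arma::span(js));
        }
      }
    }
  }
  return M;
}

// adjoint of im2col3: scatter-add columns back into an (H, W, C) cube
static arma::cube col2im3(const arma::mat &M, arma::uword H, arma::uword W,
                          arma::uword C) {
  arma::cube g(H, W, C, arma::fill::zeros);
  for (arma::uword c = 0; c < C; ++c) {
    arma::uword o = 0;
    for (int dx = -1; dx <= 1; ++dx) {
      for (int dy = -1; dy <= 1; ++dy, ++o) {
        for (arma::uword j = 0; j < W; ++j) {
          const int js = (int)j + dx;
          if (js < 0 || js >= (int)W) continue;
          const int i0 = std::max(0, -dy), i1 = (int)H - 1 - std::max(0, dy);
          if (i1 < i0) continue;
          g.slice(c)(arma::span(i0 + dy, i1 + dy), arma::span(js)) +=
            M(arma::span(j * H + i0, j * H + i1), arma::span(c * 9 + o));
        }
      }
    }
  }
  return g;
}

struct ConvP {
  arma::mat W;
  arma::vec b;
};

struct Tape {
  std::string name;
  arma::mat M;        // im2col cache
  arma::umat mask;    // relu mask over (H*W, Cout)
  arma::uword H, W;
};

static ConvP get_param(const List &params, const std::string &name) {
  List p = params[name];
  return {as<arma::mat>(p["W"]), as<arma::vec>(p["b"])};
}

static arma::cube conv3_relu(const arma::cube &x, const ConvP &p,
                             const std::string &name,
                             std::vector<Tape> *tape) {
  const arma::uword H = x.n_rows, W = x.n_cols;
  arma::mat M = im2col3(x);
  arma::mat Y = M * p.W;
  Y.each_row() += p.b.t();
  arma::umat mask = Y > 0;
  Y %= arma::conv_to<arma::mat>::from(mask);
  arma::cube y(Y.memptr(), H, W, p.W.n_cols);
  if (tape) tape->push_back({name, std::move(M), std::move(mask), H, W});
  return y;
}

static arma::cube maxpool2(const arma::cube &x, arma::ucube *argmax) {
  const arma::uword H = x.n_rows, W = x.n_cols, C = x.n_slices;
  const arma::uword h = H / 2, w = W / 2;
  arma::cube y(h, w, C);
  if (argmax) argmax->set_size(h, w, C);
  for (arma::uword c = 0; c < C; ++c)
    for (arma::uword j = 0; j < w; ++j)
      for (arma::uword i = 0; i < h; ++i) {
        double best = -arma::datum::inf;
        arma::uword bi = 0;
        for (int q = 0; q < 4; ++q) {
          const arma::uword ii = 2 * i + (q & 1), jj = 2 * j + (q >> 1);
          const double v = x(ii, jj, c);
          if (v > best) { best = v; bi = ii + jj * H; }
        }
        y(i, j, c) = best;
        if (argmax) (*argmax)(i, j, c) = bi;
      }
  return y;
}

static arma::cube up2(const arma::cube &x) {
  const arma::uword H = x.n_rows, W = x.n_cols, C = x.n_slices;
  arma::cube y(2 * H, 2 * W, C);
  for (arma::uword c = 0; c < C; ++c)
    for (arma::uword j = 0; j < W; ++j)
      for (arma::uword i = 0; i < H; ++i) {
        const double v = x(i, j, c);
        y(2 * i, 2 * j, c) = v;
        y(2 * i + 1, 2 * j, c) = v;
        y(2 * i, 2 * j + 1, c) = v;
        y(2 * i + 1, 2 * j + 1, c) = v;
      }
  return y;
}

static arma::cube up2_bwd(const arma::cube &gy) {
  const arma::uword H = gy.n_rows / 2, W = gy.n_cols / 2, C = gy.n_slices;
  arma::cube gx(H, W, C);
  for (arma::uword c = 0; c < C; ++c)
    for (arma::uword j = 0; j < W; ++j)
      for (arma::uword i = 0; i < H; ++i)
        gx(i, j, c) = gy(2 * i, 2 * j, c) + gy(2 * i + 1, 2 * j, c) +
                      gy(2 * i, 2 * j + 1, c) + gy(2 * i + 1, 2 * j + 1, c);
  return gx;
}

// shared forward; fills tape/pool caches when training
static arma::mat unet_fwd(const List &params, int depth, const arma::mat &x,
                          std::vector<Tape> *tape,
                          std::vector<arma::ucube> *poolArg,
                          std::vector<arma::cube> *skips,
                          arma::cube *final_in) {
  const arma::uword H = x.n_rows, W = x.n_cols;
  if (H % (1 << depth) || W % (1 << depth))
    stop("input dims must be divisible by 2^depth");
  arma::cube cur(H, W, 1);
  cur.slice(0) = x;
  char nm[32];
  std::vector<arma::cube> localskips(depth);
  for (int i = 0; i < depth; ++i) {
    snprintf(nm, sizeof nm, "enc%d_c1", i + 1);
    cur = conv3_relu(cur, get_param(params, nm), nm, tape);
    snprintf(nm, sizeof nm, "enc%d_c2", i + 1);
    cur = conv3_relu(cur, get_param(params, nm), nm, tape);
    localskips[i] = cur;
    arma::ucube am;
    cur = maxpool2(cur, poolArg ? &am : nullptr);
    if (poolArg) (*poolArg)[i] = std::move(am);
  }
  cur = conv3_relu(cur, get_param(params, "bott_c1"), "bott_c1", tape);
  cur = conv3_relu(cur, get_param(params, "bott_c2"), "bott_c2", tape);
  for (int i = depth - 1; i >= 0; --i) {
    cur = up2(cur);
    snprintf(nm, sizeof nm, "dec%d_up", i + 1);
    cur = conv3_relu(cur, get_param(params, nm), nm, tape);
    cur = arma::join_slices(localskips[i], cur);
    snprintf(nm, sizeof nm, "dec%d_c1", i + 1);
    cur = conv3_relu(cur, get_param(params, nm), nm, tape);
    snprintf(nm, sizeof nm, "dec%d_c2", i + 1);
    cur = conv3_relu(cur, get_param(params, nm), nm, tape);
  }
  if (skips) *skips = std::move(localskips);
  if (final_in) *final_in = cur;
  ConvP pf = get_param(params, "final");
  arma::mat X(cur.memptr(), H * W, cur.n_slices);
  arma::mat logits = X * pf.W;
  logits.each_row() += pf.b.t();
  return arma::reshape(logits, H, W);
}

// [[Rcpp::export(name = ".unet_infer")]]
arma::mat unet_infer(const List &params, int depth, const arma::mat &x) {
  return unet_fwd(params, depth, x, nullptr, nullptr, nullptr, nullptr);
}

// one training example: loss and parameter gradients of mean BCE-with-logits
// [[Rcpp::export(name = ".unet_grad")]]
List unet_grad(const List &params, int depth, const arma::mat &x,
               const arma::mat &y) {
  std::vector<Tape> tape;
  std::vector<arma::ucube> poolArg(depth);
  std::vector<arma::cube> skips;
  arma::cube final_in;
  arma::mat logits = unet_fwd(params, depth, x, &tape, &poolArg, &skips,
                              &final_in);
  const double npix = (double)logits.n_elem;
  // stable mean BCE: max(l,0) - l*y + log1p(exp(-|l|))
  double loss = arma::accu(arma::clamp(logits, 0.0, arma::datum::inf) -
                           logits % y +
                           arma::log1p(arma::exp(-arma::abs(logits)))) / npix;
  arma::mat glog = (1.0 / (1.0 + arma::exp(-logits)) - y) / npix;

  std::map<std::string, std::pair<arma::mat, arma::vec>> grads;
  const arma::uword H = x.n_rows, W = x.n_cols;

  // final 1x1 conv
  ConvP pf = get_param(params, "final");
  arma::mat X(final_in.memptr(), H * W, final_in.n_slices, false, true);
  arma::mat Gy(glog.memptr(), H * W, 1, false, true);
  grads["final"] = {X.t() * Gy, arma::sum(Gy, 0).t()};
  arma::mat Gx = Gy * pf.W.t();
  arma::cube g(Gx.memptr(), H, W, final_in.n_slices);

  size_t tp = tape.size(); // walk the conv tape backwards
  auto conv3_bwd = [&](arma::cube gy) {
    const Tape &t = tape[--tp];
    arma::mat Gy2(gy.memptr(), t.H * t.W, gy.n_slices, false, true);
    Gy2 %= arma::conv_to<arma::mat>::from(t.mask);
    ConvP p = get_param(params, t.name);
    auto it = grads.find(t.name);
    if (it == grads.end())
      grads[t.name] = {t.M.t() * Gy2, arma::sum(Gy2, 0).t()};
    else {
      it->second.first += t.M.t() * Gy2;
      it->second.second += arma::sum(Gy2, 0).t();
    }
    arma::mat Gx2 = Gy2 * p.W.t();
    return col2im3(Gx2, t.H, t.W, p.W.n_rows / 9);
  };

  std::vector<arma::cube> skip_g(depth);
  for (int i = 0; i < depth; ++i) { // decoder levels 1..depth in tape-reverse
    g = conv3_bwd(std::move(g)); // dec{i+1}_c2
    g = conv3_bwd(std::move(g)); // dec{i+1}_c1
    const arma::uword ns = skips[i].n_slices;
    skip_g[i] = g.slices(0, ns - 1);
    g = g.slices(ns, g.n_slices - 1);
    g = conv3_bwd(std::move(g)); // dec{i+1}_up
    g = up2_bwd(g);
  }
  g = conv3_bwd(std::move(g)); // bott_c2
  g = conv3_bwd(std::move(g)); // bott_c1
  for (int i = depth - 1; i >= 0; --i) {
    // unpool to level i's resolution, add the skip gradient
    const arma::uword h = skips[i].n_rows, w = skips[i].n_cols;
    arma::cube gx(h, w, g.n_slices, arma::fill::zeros);
    for (arma::uword c = 0; c < g.n_slices; ++c) {
      const arma::uword m = g.n_rows * g.n_cols;
      for (arma::uword k = 0; k < m; ++k)
        gx.slice(c)(poolArg[i].slice(c)(k)) += g.slice(c)(k);
    }
    gx += skip_g[i];
    g = conv3_bwd(std::move(gx)); // enc{i+1}_c2
    g = conv3_bwd(std::move(g));  // enc{i+1}_c1
  }

  List out;
  for (auto &kv : grads)
    out[kv.first] = List::create(_["W"] = kv.second.first,
                                 _["b"] = kv.second.second);
  return List::create(_["loss"] = loss, _["grads"] = out);
}
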