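// Small CPU U-Net engine: im2col + GEMM convolutions, 2x2 max-pool,
// nearest-neighbour upsampling with skip concatenation, softmax
// cross-entropy + soft-dice loss, Adam, patience-based early stopping.
// Single precision throughout; all randomness from std::mt19937 so runs
// are reproducible for a fixed seed on a fixed toolchain.
#include <RcppArmadillo.h>
#include <random>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;
using Rcpp::List;
using Rcpp::NumericVector;
using Rcpp::IntegerVector;
using Rcpp::NumericMatrix;

namespace {

struct Conv {
  fmat W;    // (k*k*cin) x cout
  frowvec b; // cout
  fmat gW, mW, vW;
  frowvec gb, mb, vb;
  int cin = 0, cout = 0, k = 1;
};

// Feature maps are stored as (H*W) x C matrices, pixel index p = r + c*H
// (column-major over the image), matching R's array layout.

void im2col3(const fmat& X, int H, int W, fmat& col) {
  const int C = X.n_cols;
  col.set_size(X.n_rows, 9 * C);
  int k;
  for (int ch = 0; ch < C; ++ch) {
    const float* src = X.colptr(ch);
    k = 0;
    for (int dc = -1; dc <= 1; ++dc) {
      for (int dr = -1; dr <= 1; ++dr) {
        float* dst = col.colptr(ch * 9 + k);
        std::fill(dst, dst + (size_t)H * W, 0.0f);
        const int c0 = std::max(0, -dc), c1 = std::min(W, W - dc);
        const int r0 = std::max(0, -dr), r1 = std::min(H, H - dr);
        for (int c = c0; c < c1; ++c) {
          const float* s = src + (size_t)(c + dc) * H + (r0 + dr);
          float* d = dst + (size_t)c * H + r0;
          std::copy(s, s + (r1 - r0), d);
        }
        ++k;
      }
    }
  }
}

void col2im3(const fmat& dcol, int H, int W, int C, fmat& dX) {
  dX.zeros((size_t)H * W, C);
  int k;
  for (int ch = 0; ch < C; ++ch) {
    float* dst = dX.colptr(ch);
    k = 0;
    for (int dc = -1; dc <= 1; ++dc) {
      for (int dr = -1; dr <= 1; ++dr) {
        const float* src = dcol.colptr(ch * 9 + k);
        const int c0 = std::max(0, -dc), c1 = std::min(W, W - dc);
        const int r0 = std::max(0, -dr), r1 = std::min(H, H - dr);
        for (int c = c0; c < c1; ++c) {
          float* d = dst + (size_t)(c + dc) * H + (r0 + dr);
          const float* s = src + (size_t)c * H + r0;
          for (int i = 0; i < r1 - r0; ++i) d[i] += s[i];
        }
        ++k;
      }
    }
  }
}

fmat conv_fwd(const Conv& cv, const fmat& X, int H, int W, bool relu) {
  fmat out;
  if (cv.k == 3) {
    fmat col;
    im2col3(X, H, W, col);
    out = col * cv.W;
  } else {
    out = X * cv.W;
  }
  out.each_row() += cv.b;
  if (relu) out.for_each([](float& v) { if (v < 0) v = 0; });
  return out;
}

// dY modified in place by the ReLU mask when relu=true (out = post-ReLU).
fmat conv_bwd(Conv& cv, const fmat& X, const fmat& out, fmat& dY,
              int H, int W, bool relu, bool need_dx) {
  if (relu) dY.elem(find(out <= 0)).zeros();
  fmat dX;
  if (cv.k == 3) {
    fmat col;
    im2col3(X, H, W, col);
    cv.gW += col.t() * dY;
    cv.gb += sum(dY, 0);
    if (need_dx) {
      fmat dcol = dY * cv.W.t();
      col2im3(dcol, H, W, cv.cin, dX);
    }
  } else {
    cv.gW += X.t() * dY;
    cv.gb += sum(dY, 0);
    if (need_dx) dX = dY * cv.W.t();
  }
  return dX;
}

void maxpool2(const fmat& X, int H, int W, fmat& P, umat& idx) {
  const int H2 = H / 2, W2 = W / 2, C = X.n_cols;
  P.set_size((size_t)H2 * W2, C);
  idx.set_size((size_t)H2 * W2, C);
  for (int ch = 0; ch < C; ++ch) {
    const float* x = X.colptr(ch);
    for (int c2 = 0; c2 < W2; ++c2) {
      for (int r2 = 0; r2 < H2; ++r2) {
        const size_t base = (size_t)(2 * c2) * H + 2 * r2;
        size_t best = base;
        float bv = x[base];
        const size_t cand[3] = {base + 1, base + H, base + H + 1};
        for (size_t q : cand) if (x[q] > bv) { bv = x[q]; best = q; }
        const size_t p2 = (size_t)c2 * H2 + r2;
        P(p2, ch) = bv;
        idx(p2, ch) = best;
      }
    }
  }
}

fmat maxpool2_bwd(const fmat& dP, const umat& idx, int H, int W) {
  fmat dX((size_t)H * W, dP.n_cols, fill::zeros);
  for (uword ch = 0; ch < dP.n_cols; ++ch)
    for (uword p = 0; p < dP.n_rows; ++p)
      dX(idx(p, ch), ch) += dP(p, ch);
  return dX;
}

fmat upsample2(const fmat& X, int H, int W) {
  const int H2 = H * 2, W2 = W * 2, C = X.n_cols;
  fmat U((size_t)H2 * W2, C);
  for (int ch = 0; ch < C; ++ch) {
    const float* x = X.colptr(ch);
    float* u = U.colptr(ch);
    for (int c = 0; c < W2; ++c)
      for (int r = 0; r < H2; ++r)
        u[(size_t)c * H2 + r] = x[(size_t)(c / 2) * H + r / 2];
  }
  return U;
}

fmat upsample2_bwd(const fmat& dU, int H, int W) {
  // H, W are the *source* (coarse) dims
  const int H2 = H * 2, C = dU.n_cols;
  fmat dX((size_t)H * W, C, fill::zeros);
  for (int ch = 0; ch < C; ++ch) {
    const float* du = dU.colptr(ch);
    float* dx = dX.colptr(ch);
    for (int c = 0; c < 2 * W; ++c)
      for (int r = 0; r < H2; ++r)
        dx[(size_t)(c / 2) * H + r / 2] += du[(size_t)c * H2 + r];
  }
  return dX;
}

struct Net {
  int cin, K, L, F, H, W;
  std::vector<Conv> layers; // 2L encoder, 2 bottleneck, 2L decoder, 1 final

  void build() {
    layers.clear();
    int in = cin;
    for (int l = 0; l < L; ++l) {
      const int f = F << l;
      layers.push_back(Conv{fmat(), frowvec(), fmat(), fmat(), fmat(),
                            frowvec(), frowvec(), frowvec(), in, f, 3});
      layers.push_back(Conv{fmat(), frowvec(), fmat(), fmat(), fmat(),
                            frowvec(), frowvec(), frowvec(), f, f, 3});
      in = f;
    }
    const int fb = F << L;
    layers.push_back(Conv{fmat(), frowvec(), fmat(), fmat(), fmat(),
                          frowvec(), frowvec(), frowvec(), in, fb, 3});
    layers.push_back(Conv{fmat(), frowvec(), fmat(), fmat(), fmat(),
                          frowvec(), frowvec(), frowvec(), fb, fb, 3});
    in = fb;
    for (int l = L - 1; l >= 0; --l) {
      const int f = F << l;
      layers.push_back(Conv{fmat(), frowvec(), fmat(), fmat(), fmat(),
                            frowvec(), frowvec(), frowvec(), in + f, f, 3});
      layers.push_back(Conv{fmat(), frowvec(), fmat(), fmat(), fmat(),
                            frowvec(), frowvec(), frowvec(), f, f, 3});
      in = f;
    }
    layers.push_back(Conv{fmat(), frowvec(), fmat(), fmat(), fmat(),
                          frowvec(), frowvec(), frowvec(), in, K, 1});
  }

  void init(int seed) {
    std::mt19937 rng(seed);
    std::normal_distribution<float> nd(0.0f, 1.0f);
    for (auto& cv : layers) {
      const int fan = cv.k * cv.k * cv.cin;
      const float sd = std::sqrt(2.0f / fan);
      cv.W.set_size(fan, cv.cout);
      for (uword j = 0; j < cv.W.n_cols; ++j)
        for (uword i = 0; i < cv.W.n_rows; ++i) cv.W(i, j) = sd * nd(rng);
      cv.b.zeros(cv.cout);
      cv.mW.zeros(fan, cv.cout); cv.vW.zeros(fan, cv.cout);
      cv.mb.zeros(cv.cout); cv.vb.zeros(cv.cout);
    }
  }

  void zero_grads() {
    for (auto& cv : layers) {
      cv.gW.zeros(cv.W.n_rows, cv.W.n_cols);
      cv.gb.zeros(cv.b.n_elem);
    }
  }

  // Forward pass; when cache != nullptr all activations are kept for backprop.
  struct Cache {
    std::vector<fmat> acts;      // input of every conv layer, in layer order
    std::vector<fmat> outs;      // output (post-ReLU / logits) of every conv
    std::vector<umat> poolidx;   // per encoder level
    std::vector<fmat> prepool;   // encoder output before pooling (skip source)
  };

  fmat forward(const fmat& X0, Cache* cache) {
    fmat cur = X0;
    int Hc = H, Wc = W;
    std::vector<fmat> skips(L);
    std::vector<int> skipH(L), skipW(L);
    int li = 0;
    auto run = [&](const fmat& in, bool relu) {
      if (cache) cache->acts.push_back(in);
      fmat out = conv_fwd(layers[li], in, Hc, Wc, relu);
      if (cache) cache->outs.push_back(out);
      ++li;
      return out;
    };
    for (int l = 0; l < L; ++l) {
      cur = run(cur, true);
      cur = run(cur, true);
      skips[l] = cur; skipH[l] = Hc; skipW[l] = Wc;
      fmat pooled; umat idx;
      maxpool2(cur, Hc, Wc, pooled, idx);
      if (cache) { cache->poolidx.push_back(idx); cache->prepool.push_back(cur); }
      cur = std::move(pooled);
      Hc /= 2; Wc /= 2;
    }
    cur = run(cur, true);
    cur = run(cur, true);
    for (int l = L - 1; l >= 0; --l) {
      cur = upsample2(cur, Hc, Wc);
      Hc *= 2; Wc *= 2;
      cur = join_rows(cur, skips[l]);
      cur = run(cur, true);
      cur = run(cur, true);
    }
    cur = run(cur, false); // final 1x1, logits
    return cur;
  }

  // Backprop from dLogits; gradients accumulate into gW/gb.
  void backward(const Cache& cache, fmat dY) {
    int li = (int)layers.size() - 1;
    int Hc = H, Wc = W;
    // final 1x1 at full resolution
    fmat dcur = conv_bwd(layers[li], cache.acts[li], cache.outs[li], dY,
                         Hc, Wc, false, true);
    --li;
    std::vector<fmat> dskip(L);
    for (int l = 0; l < L; ++l) { // decoder blocks, from full res down
      dcur = conv_bwd(layers[li], cache.acts[li], cache.outs[li], dcur,
                      Hc, Wc, true, true);
      --li;
      dcur = conv_bwd(layers[li], cache.acts[li], cache.outs[li], dcur,
                      Hc, Wc, true, true);
      --li;
      // split concat: first columns came from upsample, rest from skip
      const int upc = dcur.n_cols - (F << l);
      dskip[l] = dcur.cols(upc, dcur.n_cols - 1);
      fmat dup = dcur.cols(0, upc - 1);
      Hc /= 2; Wc /= 2;
      dcur = upsample2_bwd(dup, Hc, Wc);
    }
    // bottleneck
    dcur = conv_bwd(layers[li], cache.acts[li], cache.outs[li], dcur,
                    Hc, Wc, true, true);
    --li;
    dcur = conv_bwd(layers[li], cache.acts[li], cache.outs[li], dcur,
                    Hc, Wc, true, true);
    --li;
    for (int l = 0; l < L; ++l) { // encoder blocks, from deepest up
      fmat dpre = maxpool2_bwd(dcur, cache.poolidx[L - 1 - l], Hc * 2, Wc * 2);
      Hc *= 2; Wc *= 2;
      dpre += dskip[L - 1 - l];
      dpre = conv_bwd(layers[li], cache.acts[li], cache.outs[li], dpre,
                      Hc, Wc, true, true);
      --li;
      dcur = conv_bwd(layers[li], cache.acts[li], cache.outs[li], dpre,
                      Hc, Wc, true, li > 0);
      --li;
    }
  }

  void adam_step(float lr, float scale, int t) {
    const float b1 = 0.9f, b2 = 0.999f, eps = 1e-8f;
    const float c1 = 1.0f - std::pow(b1, (float)t);
    const float c2 = 1.0f - std::pow(b2, (float)t);
    for (auto& cv : layers) {
      fmat g = cv.gW * scale;
      cv.mW = b1 * cv.mW + (1 - b1) * g;
      cv.vW = b2 * cv.vW + (1 - b2) * square(g);
      cv.W -= lr * (cv.mW / c1) / (sqrt(cv.vW / c2) + eps);
      frowvec gbv = cv.gb * scale;
      cv.mb = b1 * cv.mb + (1 - b1) * gbv;
      cv.vb = b2 * cv.vb + (1 - b2) * square(gbv);
      cv.b -= lr * (cv.mb / c1) / (sqrt(cv.vb / c2) + eps);
    }
  }
};

fmat softmax_rows(const fmat& z) {
  fmat p = z;
  p.each_col() -= max(p, 1);
  p = exp(p);
  p.each_col() /= sum(p, 1);
  return p;
}

struct Metrics { double loss = 0, acc = 0, dice = 0, iou = 0; };

// Per-image loss (CE + 1 - mean soft dice) and hard overlap metrics.
// Foreground macro average: classes 1..K-1; empty-vs-empty counts as 1.
Metrics eval_image(const fmat& P, const ivec& y, int K, fmat* dz) {
  const uword N = P.n_rows;
  Metrics m;
  // one-hot sums and CE
  double ce = 0;
  for (uword p = 0; p < N; ++p) ce -= std::log(std::max(P(p, y[p]), 1e-12f));
  ce /= N;
  const float eps = 1.0f;
  double dsum = 0;
  fmat G;
  if (dz) G.zeros(N, K);
  for (int c = 0; c < K; ++c) {
    double Sp = accu(P.col(c)), Sy = 0, I = 0;
    for (uword p = 0; p < N; ++p)
      if (y[p] == c) { Sy += 1; I += P(p, c); }
    const double denom = Sp + Sy + eps;
    dsum += (2 * I + eps) / denom;
    if (dz) {
      const double a = 2.0 / denom, b = (2 * I + eps) / (denom * denom);
      for (uword p = 0; p < N; ++p)
        G(p, c) = (float)(-((y[p] == c ? a : 0.0) - b) / K);
    }
  }
  m.loss = ce + (1.0 - dsum / K);
  if (dz) {
    // softmax jacobian for the dice part + direct CE gradient
    fvec s = sum(G % P, 1);
    *dz = P % (G.each_col() - s);
    for (uword p = 0; p < N; ++p) {
      for (int c = 0; c < K; ++c) (*dz)(p, c) += P(p, c) / N;
      (*dz)(p, y[p]) -= 1.0f / N;
    }
  }
  // hard metrics
  uvec pred = index_max(P, 1);
  uword correct = 0;
  for (uword p = 0; p < N; ++p) if ((int)pred[p] == y[p]) ++correct;
  m.acc = (double)correct / N;
  double dice_sum = 0, iou_sum = 0;
  const int nfg = std::max(K - 1, 1);
  for (int c = (K > 1 ? 1 : 0); c < K; ++c) {
    uword a = 0, b = 0, i = 0;
    for (uword p = 0; p < N; ++p) {
      const bool pa = (int)pred[p] == c, tb = y[p] == c;
      a += pa; b += tb; i += (pa && tb);
    }
    if (a + b == 0) { dice_sum += 1; iou_sum += 1; }
    else {
      dice_sum += 2.0 * i / (a + b);
      iou_sum += (a + b - i) > 0 ? (double)i / (a + b - i) : 1.0;
    }
  }
  m.dice = dice_sum / nfg;
  m.iou = iou_sum / nfg;
  return m;
}

fmat image_slice(const NumericVector& X, int HW, int C, int i) {
  fmat out(HW, C);
  const double* src = X.begin() + (size_t)i * HW * C;
  for (int ch = 0; ch < C; ++ch)
    for (int p = 0; p < HW; ++p) out(p, ch) = (float)src[(size_t)ch * HW + p];
  return out;
}

ivec label_slice(const IntegerVector& y, int HW, int i) {
  ivec out(HW);
  const int* src = y.begin() + (size_t)i * HW;
  for (int p = 0; p < HW; ++p) out[p] = src[p];
  return out;
}

List export_weights(const Net& net) {
  List out(net.layers.size());
  for (size_t i = 0; i < net.layers.size(); ++i) {
    const Conv& cv = net.layers[i];
    NumericMatrix Wm(cv.W.n_rows, cv.W.n_cols);
    for (uword j = 0; j < cv.W.n_cols; ++j)
      for (uword r = 0; r < cv.W.n_rows; ++r) Wm(r, j) = cv.W(r, j);
    NumericVector bv(cv.b.n_elem);
    for (uword j = 0; j < cv.b.n_elem; ++j) bv[j] = cv.b[j];
    out[i] = List::create(Rcpp::Named("W") = Wm, Rcpp::Named("b") = bv);
  }
  return out;
}

void import_weights(Net& net, const List& weights) {
  if ((size_t)weights.size() != net.layers.size())
    Rcpp::stop("weight list has %d layers, expected %d",
               (int)weights.size(), (int)net.layers.size());
  for (size_t i = 0; i < net.layers.size(); ++i) {
    List lw = weights[i];
    NumericMatrix Wm = lw["W"];
    NumericVector bv = lw["b"];
    Conv& cv = net.layers[i];
    if ((int)Wm.nrow() != (int)(cv.k * cv.k * cv.cin) ||
        (int)Wm.ncol() != cv.cout)
      Rcpp::stop("layer %d weight shape mismatch", (int)i + 1);
    cv.W.set_size(Wm.nrow(), Wm.ncol());
    for (int j = 0; j < Wm.ncol(); ++j)
      for (int r = 0; r < Wm.nrow(); ++r) cv.W(r, j) = (float)Wm(r, j);
    cv.b.set_size(bv.size());
    for (int j = 0; j < bv.size(); ++j) cv.b[j] = (float)bv[j];
    cv.mW.zeros(cv.W.n_rows, cv.W.n_cols);
    cv.vW.zeros(cv.W.n_rows, cv.W.n_cols);
    cv.mb.zeros(cv.b.n_elem);
    cv.vb.zeros(cv.b.n_elem);
  }
}

} // namespace

// [[Rcpp::export]]
List cpp_unet_init(int cin, int K, int L, int F, int seed) {
  Net net;
  net.cin = cin; net.K = K; net.L = L; net.F = F;
  net.build();
  net.init(seed);
  return export_weights(net);
}

// [[Rcpp::export]]
List cpp_unet_train(List weights, int cin, int K, int L, int F,
                    NumericVector X, IntegerVector Xdim, IntegerVector y,
                    NumericVector Xv, IntegerVector Xvdim, IntegerVector yv,
                    double lr, int batch, int max_epochs, int patience,
                    double min_delta, int seed) {
  const int H = Xdim[0], W = Xdim[1], C = Xdim[2], N = Xdim[3];
  const int Nv = Xvdim[3];
  const int HW = H * W;
  Net net;
  net.cin = cin; net.K = K; net.L = L; net.F = F; net.H = H; net.W = W;
  net.build();
  import_weights(net, weights);

  std::mt19937 rng(seed);
  std::vector<int> order(N);
  for (int i = 0; i < N; ++i) order[i] = i;

  std::vector<std::array<double, 8>> hist;
  double best_val = datum::inf;
  int best_epoch = 0, wait = 0, t = 0;
  List best_weights = export_weights(net);

  for (int epoch = 1; epoch <= max_epochs; ++epoch) {
    std::shuffle(order.begin(), order.end(), rng);
    Metrics tr;
    int seen = 0;
    for (int b0 = 0; b0 < N; b0 += batch) {
      const int nb = std::min(batch, N - b0);
      net.zero_grads();
      for (int j = 0; j < nb; ++j) {
        const int i = order[b0 + j];
        fmat Xi = image_slice(X, HW, C, i);
        ivec yi = label_slice(y, HW, i);
        Net::Cache cache;
        fmat logits = net.forward(Xi, &cache);
        fmat P = softmax_rows(logits);
        fmat dz;
        Metrics m = eval_image(P, yi, K, &dz);
        tr.loss += m.loss; tr.acc += m.acc; tr.dice += m.dice; tr.iou += m.iou;
        ++seen;
        net.backward(cache, std::move(dz));
      }
      ++t;
      net.adam_step((float)lr, 1.0f / nb, t);
    }
    tr.loss /= seen; tr.acc /= seen; tr.dice /= seen; tr.iou /= seen;

    Metrics va;
    for (int i = 0; i < Nv; ++i) {
      fmat Xi = image_slice(Xv, HW, C, i);
      ivec yi = label_slice(yv, HW, i);
      fmat P = softmax_rows(net.forward(Xi, nullptr));
      Metrics m = eval_image(P, yi, K, nullptr);
      va.loss += m.loss; va.acc += m.acc; va.dice += m.dice; va.iou += m.iou;
    }
    va.loss /= Nv; va.acc /= Nv; va.dice /= Nv; va.iou /= Nv;
    hist.push_back({tr.loss, tr.acc, tr.dice, tr.iou,
                    va.loss, va.acc, va.dice, va.iou});

    if (va.loss < best_val - min_delta) {
      best_val = va.loss;
      best_epoch = epoch;
      best_weights = export_weights(net);
      wait = 0;
    } else if (++wait >= patience) break;
    Rcpp::checkUserInterrupt();
  }

  NumericMatrix H8(hist.size(), 8);
  for (size_t i = 0; i < hist.size(); ++i)
    for (int j = 0; j < 8; ++j) H8(i, j) = hist[i][j];
  return List::create(Rcpp::Named("weights") = best_weights,
                      Rcpp::Named("history") = H8,
                      Rcpp::Named("best_epoch") = best_epoch,
                      Rcpp::Named("epochs_run") = (int)hist.size());
}

// [[Rcpp::export]]
NumericVector cpp_unet_predict(List weights, int cin, int K, int L, int F,
                               NumericVector X, IntegerVector Xdim) {
  const int H = Xdim[0], W = Xdim[1], C = Xdim[2], N = Xdim[3];
  const int HW = H * W;
  Net net;
  net.cin = cin; net.K = K; net.L = L; net.F = F; net.H = H; net.W = W;
  net.build();
  import_weights(net, weights);
  NumericVector out((size_t)HW * K * N);
  for (int i = 0; i < N; ++i) {
    fmat Xi = image_slice(X, HW, C, i);
    fmat P = softmax_rows(net.forward(Xi, nullptr));
    double* dst = out.begin() + (size_t)i * HW * K;
    for (int c = 0; c < K; ++c)
      for (int p = 0; p < HW; ++p) dst[(size_t)c * HW + p] = P(p, c);
  }
  out.attr("dim") = IntegerVector::create(H, W, K, N);
  return out;
}
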