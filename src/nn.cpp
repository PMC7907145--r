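// Hybrid time-distributed CNN + LSTM classifier.
//
// Per frame: [conv3x3 pad1 stride1 + ReLU] stacks with 2x2/2 max pooling
// after each stack, flatten, FC-512 + ReLU (+ dropout), shared across the
// frames of a trial.  The 6 per-frame embeddings feed a single-layer LSTM
// (forget/input/candidate/output gates on [h_{t-1}, x_t]); the last hidden
// state (+ dropout) feeds a 2-unit softmax.  Trained with Adam on
// cross-entropy.
//
// The convolutional path runs in single precision (it dominates the FLOPs
// and feeds BLAS sgemm); the LSTM and head run in double precision.
// Trials are processed in chunks of CHUNK trials through a persistent
// workspace, so the large im2col buffers are allocated once; gradients are
// accumulated across chunks to preserve the exact minibatch semantics of
// the configured batch size.

#include <RcppArmadillo.h>
#include <random>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;
using arma::fmat;
using arma::mat;
using arma::uword;

namespace {

constexpr int CHUNK = 2;   // trials processed per GEMM block

struct ConvLayer {
  fmat W;            // C_out x 9*C_in, column index k*C_in + c_in
  arma::fvec b;
  int c_in, c_out, hw, h;   // h = side length of the layer input (square)
  int in_pool;       // pool index feeding this conv, or -1
  fmat gW; arma::fvec gb;   // gradient accumulators
  fmat mW, vW; arma::fvec mb, vb;  // Adam moments
};

struct Net {
  std::vector<ConvLayer> convs;
  std::vector<int> pool_after;  // conv index after which a pool occurs
  int img = 32, frames = 6, flat = 0, fc = 512, hidden = 128;
  fmat Wfc; arma::fvec bfc; fmat gWfc; arma::fvec gbfc;
  fmat mWfc, vWfc; arma::fvec mbfc, vbfc;
  mat Wf, Wi, Wc, Wo; arma::vec bf, bi, bc, bo;
  mat gWf, gWi, gWc, gWo; arma::vec gbf, gbi, gbc, gbo;
  mat mWf, vWf, mWi, vWi, mWc, vWc, mWo, vWo;
  arma::vec mbf, vbf, mbi, vbi, mbc, vbc, mbo, vbo;
  mat Wout; arma::vec bout; mat gWout; arma::vec gbout;
  mat mWout, vWout; arma::vec mbout, vbout;
};

fmat as_f(const NumericMatrix &m) {
  mat d(const_cast<double *>(m.begin()), m.nrow(), m.ncol(), false);
  return arma::conv_to<fmat>::from(d);
}
arma::fvec as_fv(const NumericVector &v) {
  arma::vec d(const_cast<double *>(v.begin()), v.size(), false);
  return arma::conv_to<arma::fvec>::from(d);
}

Net build_net(List weights, IntegerVector counts, IntegerVector channels,
              int img, int frames) {
  Net net;
  net.img = img; net.frames = frames;
  List convW = weights["conv_w"], convB = weights["conv_b"];
  int side = img, cin = 3, li = 0;
  for (int s = 0; s < counts.size(); ++s) {
    for (int r = 0; r < counts[s]; ++r, ++li) {
      ConvLayer L;
      L.W = as_f(convW[li]); L.b = as_fv(convB[li]);
      L.c_in = cin; L.c_out = channels[s];
      L.h = side; L.hw = side * side;
      L.in_pool = (r == 0 && s > 0) ? s - 1 : -1;
      if ((int)L.W.n_rows != L.c_out || (int)L.W.n_cols != 9 * cin)
        stop("conv weight %d has wrong shape", li + 1);
      cin = L.c_out;
      net.convs.push_back(std::move(L));
    }
    net.pool_after.push_back((int)net.convs.size() - 1);
    if (side % 2 != 0) stop("non-integer pooled size at stack %d", s + 1);
    side /= 2;
  }
  net.flat = cin * side * side;
  net.Wfc = as_f(weights["fc_w"]); net.bfc = as_fv(weights["fc_b"]);
  if ((int)net.Wfc.n_cols != net.flat)
    stop("fc weight expects flatten size %d, got %d", (int)net.Wfc.n_cols, net.flat);
  net.fc = net.Wfc.n_rows;
  net.Wf = as<mat>(weights["lstm_wf"]); net.Wi = as<mat>(weights["lstm_wi"]);
  net.Wc = as<mat>(weights["lstm_wc"]); net.Wo = as<mat>(weights["lstm_wo"]);
  net.bf = as<arma::vec>(weights["lstm_bf"]); net.bi = as<arma::vec>(weights["lstm_bi"]);
  net.bc = as<arma::vec>(weights["lstm_bc"]); net.bo = as<arma::vec>(weights["lstm_bo"]);
  net.hidden = net.Wf.n_rows;
  net.Wout = as<mat>(weights["out_w"]); net.bout = as<arma::vec>(weights["out_b"]);
  return net;
}

List export_weights(const Net &net) {
  List convW(net.convs.size()), convB(net.convs.size());
  for (size_t i = 0; i < net.convs.size(); ++i) {
    convW[i] = wrap(arma::conv_to<mat>::from(net.convs[i].W));
    convB[i] = wrap(arma::conv_to<arma::vec>::from(net.convs[i].b));
  }
  return List::create(
    _["conv_w"] = convW, _["conv_b"] = convB,
    _["fc_w"] = wrap(arma::conv_to<mat>::from(net.Wfc)),
    _["fc_b"] = wrap(arma::conv_to<arma::vec>::from(net.bfc)),
    _["lstm_wf"] = net.Wf, _["lstm_wi"] = net.Wi, _["lstm_wc"] = net.Wc,
    _["lstm_wo"] = net.Wo, _["lstm_bf"] = net.bf, _["lstm_bi"] = net.bi,
    _["lstm_bc"] = net.bc, _["lstm_bo"] = net.bo,
    _["out_w"] = net.Wout, _["out_b"] = net.bout);
}

// im2col for 3x3, pad 1, stride 1; frames are independent column blocks.
// On a buffer of matching size only the interior is rewritten (the border
// zeros from the first call are invariant).
void im2col3(const fmat &A, int C, int H, int F, fmat &col) {
  const int HW = H * H;
  const uword nr = (uword)9 * C, nc = (uword)HW * F;
  if (col.n_rows != nr || col.n_cols != nc) col.zeros(nr, nc);
  for (int f = 0; f < F; ++f) {
    const uword off = (uword)f * HW;
    for (int kx = -1; kx <= 1; ++kx) {
      for (int ky = -1; ky <= 1; ++ky) {
        const int k = (kx + 1) * 3 + (ky + 1);
        const int x0 = std::max(0, -kx), x1 = std::min(H, H - kx);
        const int y0 = std::max(0, -ky), y1 = std::min(H, H - ky);
        for (int x = x0; x < x1; ++x) {
          const float *src = A.colptr(off + (uword)(x + kx) * H + (y0 + ky));
          float *dst = col.colptr(off + (uword)x * H + y0) + k * C;
          const int ny = y1 - y0;
          for (int y = 0; y < ny; ++y)
            std::memcpy(dst + (size_t)y * 9 * C, src + (size_t)y * C,
                        C * sizeof(float));
        }
      }
    }
  }
}

// transpose of im2col: scatter-add column gradients back to the image grad
void col2im3(const fmat &col, int C, int H, int F, fmat &dA) {
  const int HW = H * H;
  dA.zeros(C, (uword)HW * F);
  for (int f = 0; f < F; ++f) {
    const uword off = (uword)f * HW;
    for (int kx = -1; kx <= 1; ++kx) {
      for (int ky = -1; ky <= 1; ++ky) {
        const int k = (kx + 1) * 3 + (ky + 1);
        const int x0 = std::max(0, -kx), x1 = std::min(H, H - kx);
        const int y0 = std::max(0, -ky), y1 = std::min(H, H - ky);
        for (int x = x0; x < x1; ++x) {
          float *dst = dA.colptr(off + (uword)(x + kx) * H + (y0 + ky));
          const float *src = col.colptr(off + (uword)x * H + y0) + k * C;
          const int ny = y1 - y0;
          for (int y = 0; y < ny; ++y) {
            float *d = dst + (size_t)y * C;
            const float *s = src + (size_t)y * 9 * C;
            for (int c = 0; c < C; ++c) d[c] += s[c];
          }
        }
      }
    }
  }
}

void maxpool2(const fmat &A, int C, int H, int F, fmat &out,
              arma::Mat<unsigned int> &amax) {
  const int H2 = H / 2, HW2 = H2 * H2;
  out.set_size(C, (uword)HW2 * F);
  amax.set_size(C, (uword)HW2 * F);
  for (int f = 0; f < F; ++f) {
    const uword offo = (uword)f * HW2, offi = (uword)f * H * H;
    for (int x2 = 0; x2 < H2; ++x2) {
      for (int y2 = 0; y2 < H2; ++y2) {
        const uword po = offo + (uword)x2 * H2 + y2;
        const uword p00 = offi + (uword)(2 * x2) * H + 2 * y2;
        const uword cand[4] = {p00, p00 + 1, p00 + H, p00 + H + 1};
        const float *a0 = A.colptr(cand[0]), *a1 = A.colptr(cand[1]);
        const float *a2 = A.colptr(cand[2]), *a3 = A.colptr(cand[3]);
        float *o = out.colptr(po);
        unsigned int *am = amax.colptr(po);
        for (int c = 0; c < C; ++c) {
          float best = a0[c]; unsigned int bi = (unsigned int)cand[0];
          if (a1[c] > best) { best = a1[c]; bi = (unsigned int)cand[1]; }
          if (a2[c] > best) { best = a2[c]; bi = (unsigned int)cand[2]; }
          if (a3[c] > best) { best = a3[c]; bi = (unsigned int)cand[3]; }
          o[c] = best; am[c] = bi;
        }
      }
    }
  }
}

// scatter pooled gradients back through the recorded argmax positions
void unpool2(const fmat &dpool, const arma::Mat<unsigned int> &amax, int C,
             uword full_cols, fmat &dfull) {
  dfull.zeros(C, full_cols);
  for (uword j = 0; j < dpool.n_cols; ++j) {
    const float *s = dpool.colptr(j);
    const unsigned int *am = amax.colptr(j);
    for (int c = 0; c < C; ++c) dfull(c, am[c]) += s[c];
  }
}

inline void relu_inplace(fmat &z) {
  z.transform([](float v) { return v > 0.f ? v : 0.f; });
}

// persistent buffers: sized on first use, reused across chunks and epochs
struct Workspace {
  fmat input;                       // 3 x HW*F
  std::vector<fmat> col, dcol;      // per conv layer
  std::vector<fmat> acts, dact;     // conv outputs (post-ReLU) per layer
  std::vector<fmat> pooled, dpooled;
  std::vector<arma::Mat<unsigned int>> amax;
  fmat flat, emb, drop_fc, demf, dflat;
  std::vector<mat> xs, hs, cs, fg, ig, og, gg, tc;
  mat hT, drop_h, probs;
  void ensure(const Net &net) {
    const size_t nl = net.convs.size(), np = net.pool_after.size();
    if (col.size() != nl) {
      col.resize(nl); dcol.resize(nl); acts.resize(nl); dact.resize(nl);
      pooled.resize(np); dpooled.resize(np); amax.resize(np);
      xs.resize(net.frames); hs.resize(net.frames); cs.resize(net.frames);
      fg.resize(net.frames); ig.resize(net.frames); og.resize(net.frames);
      gg.resize(net.frames); tc.resize(net.frames);
    }
  }
};

inline mat sigmoid(const mat &z) { return 1.0 / (1.0 + arma::exp(-z)); }

// forward for B trials resident in ws.input; fills ws and ws.probs (2 x B)
void forward_all(Net &net, Workspace &ws, int B, bool train, double dropout,
                 std::mt19937 *rng) {
  ws.ensure(net);
  const int T = net.frames, H = net.hidden;
  const int F = B * T;
  int pool_i = 0;
  const fmat *cur = &ws.input;
  for (size_t li = 0; li < net.convs.size(); ++li) {
    ConvLayer &L = net.convs[li];
    im2col3(*cur, L.c_in, L.h, F, ws.col[li]);
    ws.acts[li] = L.W * ws.col[li];
    ws.acts[li].each_col() += L.b;
    relu_inplace(ws.acts[li]);
    cur = &ws.acts[li];
    if (net.pool_after[pool_i] == (int)li) {
      maxpool2(*cur, L.c_out, L.h, F, ws.pooled[pool_i], ws.amax[pool_i]);
      cur = &ws.pooled[pool_i];
      ++pool_i;
    }
  }
  // flatten: columns are frames (contiguous per frame block)
  const fmat &last = *cur;
  const int HWl = last.n_cols / F, Cl = last.n_rows;
  ws.flat.set_size((uword)Cl * HWl, F);
  for (int f = 0; f < F; ++f)
    std::memcpy(ws.flat.colptr(f), last.colptr((uword)f * HWl),
                sizeof(float) * (size_t)Cl * HWl);
  ws.emb = net.Wfc * ws.flat;
  ws.emb.each_col() += net.bfc;
  relu_inplace(ws.emb);
  if (train && dropout > 0) {
    ws.drop_fc.set_size(net.fc, F);
    std::uniform_real_distribution<double> un(0.0, 1.0);
    const float keep = 1.0f / (float)(1.0 - dropout);
    for (uword j = 0; j < ws.drop_fc.n_elem; ++j)
      ws.drop_fc[j] = un(*rng) >= dropout ? keep : 0.f;
    ws.emb %= ws.drop_fc;
  } else ws.drop_fc.reset();
  // LSTM over the T frames, batched across the B trials (double precision)
  mat h(H, B, arma::fill::zeros), c(H, B, arma::fill::zeros);
  for (int t = 0; t < T; ++t) {
    mat x(net.fc, B);
    for (int b = 0; b < B; ++b)
      for (int q = 0; q < net.fc; ++q)
        x(q, b) = (double)ws.emb(q, (uword)b * T + t);
    mat hx = arma::join_cols(h, x);
    mat f = sigmoid(net.Wf * hx + arma::repmat(net.bf, 1, B));
    mat i = sigmoid(net.Wi * hx + arma::repmat(net.bi, 1, B));
    mat g = arma::tanh(net.Wc * hx + arma::repmat(net.bc, 1, B));
    mat o = sigmoid(net.Wo * hx + arma::repmat(net.bo, 1, B));
    ws.hs[t] = h; ws.cs[t] = c;       // states entering this step
    c = c % f + g % i;
    h = arma::tanh(c) % o;
    ws.xs[t] = std::move(x); ws.fg[t] = std::move(f); ws.ig[t] = std::move(i);
    ws.og[t] = std::move(o); ws.gg[t] = std::move(g);
    ws.tc[t] = arma::tanh(c);
  }
  ws.hT = h;
  if (train && dropout > 0) {
    ws.drop_h.set_size(H, B);
    std::uniform_real_distribution<double> un(0.0, 1.0);
    for (uword j = 0; j < ws.drop_h.n_elem; ++j)
      ws.drop_h[j] = un(*rng) >= dropout ? 1.0 / (1.0 - dropout) : 0.0;
    ws.hT %= ws.drop_h;
  } else ws.drop_h.reset();
  mat logits = net.Wout * ws.hT + arma::repmat(net.bout, 1, B);
  logits.each_row() -= arma::max(logits, 0);
  mat e = arma::exp(logits);
  ws.probs = e.each_row() / arma::sum(e, 0);
}

void zero_grads(Net &net) {
  for (auto &L : net.convs) { L.gW.zeros(L.W.n_rows, L.W.n_cols); L.gb.zeros(L.b.n_elem); }
  net.gWfc.zeros(net.Wfc.n_rows, net.Wfc.n_cols); net.gbfc.zeros(net.bfc.n_elem);
  net.gWf.zeros(net.Wf.n_rows, net.Wf.n_cols); net.gbf.zeros(net.bf.n_elem);
  net.gWi.zeros(net.Wi.n_rows, net.Wi.n_cols); net.gbi.zeros(net.bi.n_elem);
  net.gWc.zeros(net.Wc.n_rows, net.Wc.n_cols); net.gbc.zeros(net.bc.n_elem);
  net.gWo.zeros(net.Wo.n_rows, net.Wo.n_cols); net.gbo.zeros(net.bo.n_elem);
  net.gWout.zeros(net.Wout.n_rows, net.Wout.n_cols); net.gbout.zeros(net.bout.n_elem);
}

// backward for the chunk in ws; labels yb (length B); gradient contributions
// scaled by invB = 1 / minibatch size so chunks accumulate the batch average
void backward_all(Net &net, Workspace &ws, const std::vector<int> &yb, int B,
                  double invB) {
  const int T = net.frames, H = net.hidden;
  mat dlogits = ws.probs;                      // 2 x B
  for (int b = 0; b < B; ++b) dlogits(yb[b], b) -= 1.0;
  dlogits *= invB;
  net.gWout += dlogits * ws.hT.t();
  net.gbout += arma::sum(dlogits, 1);
  mat dh = net.Wout.t() * dlogits;
  if (!ws.drop_h.is_empty()) dh %= ws.drop_h;
  mat dc(H, B, arma::fill::zeros);
  mat demb(net.fc, (uword)B * T);
  for (int t = T - 1; t >= 0; --t) {
    const mat &f = ws.fg[t], &i = ws.ig[t], &o = ws.og[t], &g = ws.gg[t];
    const mat &tc = ws.tc[t], &cprev = ws.cs[t], &hprev = ws.hs[t];
    mat do_ = dh % tc;
    dc += dh % o % (1.0 - tc % tc);
    mat df = dc % cprev;
    mat di = dc % g;
    mat dg = dc % i;
    mat dcnext = dc % f;
    mat dzf = df % f % (1.0 - f);
    mat dzi = di % i % (1.0 - i);
    mat dzo = do_ % o % (1.0 - o);
    mat dzg = dg % (1.0 - g % g);
    mat hx = arma::join_cols(hprev, ws.xs[t]);
    net.gWf += dzf * hx.t(); net.gbf += arma::sum(dzf, 1);
    net.gWi += dzi * hx.t(); net.gbi += arma::sum(dzi, 1);
    net.gWc += dzg * hx.t(); net.gbc += arma::sum(dzg, 1);
    net.gWo += dzo * hx.t(); net.gbo += arma::sum(dzo, 1);
    mat dhx = net.Wf.t() * dzf + net.Wi.t() * dzi + net.Wc.t() * dzg +
      net.Wo.t() * dzo;
    dh = dhx.rows(0, H - 1);
    for (int b = 0; b < B; ++b)
      demb.col((uword)b * T + t) = dhx.col(b).rows(H, H + net.fc - 1);
    dc = dcnext;
  }
  // FC-512 backward (single precision from here down)
  const int F = B * T;
  ws.demf = arma::conv_to<fmat>::from(demb);
  if (!ws.drop_fc.is_empty()) ws.demf %= ws.drop_fc;
  for (uword j = 0; j < ws.demf.n_elem; ++j)
    if (ws.emb[j] <= 0.f) ws.demf[j] = 0.f;
  net.gWfc += ws.demf * ws.flat.t();
  net.gbfc += arma::sum(ws.demf, 1);
  ws.dflat = net.Wfc.t() * ws.demf;            // flat x F
  // un-flatten into the gradient of the last pooled map
  const int last_pool = (int)net.pool_after.size() - 1;
  const ConvLayer &lastL = net.convs.back();
  const int Cl = lastL.c_out, HWl = (lastL.h / 2) * (lastL.h / 2);
  ws.dpooled[last_pool].set_size(Cl, (uword)HWl * F);
  for (int f = 0; f < F; ++f)
    std::memcpy(ws.dpooled[last_pool].colptr((uword)f * HWl), ws.dflat.colptr(f),
                sizeof(float) * (size_t)Cl * HWl);
  // conv stacks backward
  int pool_i = last_pool;
  for (int li = (int)net.convs.size() - 1; li >= 0; --li) {
    ConvLayer &L = net.convs[li];
    fmat &dact = ws.dact[li];
    if (pool_i >= 0 && net.pool_after[pool_i] == li) {
      unpool2(ws.dpooled[pool_i], ws.amax[pool_i], L.c_out, (uword)L.hw * F, dact);
      --pool_i;
    }
    // ReLU mask from the stored post-activation
    const fmat &act = ws.acts[li];
    for (uword j = 0; j < dact.n_elem; ++j) if (act[j] <= 0.f) dact[j] = 0.f;
    // the im2col buffer for this layer still holds the forward column matrix
    L.gW += dact * ws.col[li].t();
    L.gb += arma::sum(dact, 1);
    if (li > 0) {
      ws.dcol[li] = L.W.t() * dact;
      if (L.in_pool >= 0)
        col2im3(ws.dcol[li], L.c_in, L.h, F, ws.dpooled[L.in_pool]);
      else
        col2im3(ws.dcol[li], L.c_in, L.h, F, ws.dact[li - 1]);
    }
  }
}

template <typename M>
void adam_update(M &w, M &g, M &m, M &v, double lr, double b1, double b2,
                 double eps, double b1t, double b2t) {
  if (m.n_elem == 0) { m.zeros(arma::size(w)); v.zeros(arma::size(w)); }
  m = b1 * m + (1.0 - b1) * g;
  v = b2 * v + (1.0 - b2) * (g % g);
  const double a = lr * std::sqrt(1.0 - b2t) / (1.0 - b1t);
  w -= a * (m / (arma::sqrt(v) + eps));
}

void adam_step(Net &net, double lr, double b1, double b2, double eps, int t) {
  const double b1t = std::pow(b1, t), b2t = std::pow(b2, t);
  for (auto &L : net.convs) {
    adam_update(L.W, L.gW, L.mW, L.vW, lr, b1, b2, eps, b1t, b2t);
    adam_update(L.b, L.gb, L.mb, L.vb, lr, b1, b2, eps, b1t, b2t);
  }
  adam_update(net.Wfc, net.gWfc, net.mWfc, net.vWfc, lr, b1, b2, eps, b1t, b2t);
  adam_update(net.bfc, net.gbfc, net.mbfc, net.vbfc, lr, b1, b2, eps, b1t, b2t);
  adam_update(net.Wf, net.gWf, net.mWf, net.vWf, lr, b1, b2, eps, b1t, b2t);
  adam_update(net.bf, net.gbf, net.mbf, net.vbf, lr, b1, b2, eps, b1t, b2t);
  adam_update(net.Wi, net.gWi, net.mWi, net.vWi, lr, b1, b2, eps, b1t, b2t);
  adam_update(net.bi, net.gbi, net.mbi, net.vbi, lr, b1, b2, eps, b1t, b2t);
  adam_update(net.Wc, net.gWc, net.mWc, net.vWc, lr, b1, b2, eps, b1t, b2t);
  adam_update(net.bc, net.gbc, net.mbc, net.vbc, lr, b1, b2, eps, b1t, b2t);
  adam_update(net.Wo, net.gWo, net.mWo, net.vWo, lr, b1, b2, eps, b1t, b2t);
  adam_update(net.bo, net.gbo, net.mbo, net.vbo, lr, b1, b2, eps, b1t, b2t);
  adam_update(net.Wout, net.gWout, net.mWout, net.vWout, lr, b1, b2, eps, b1t, b2t);
  adam_update(net.bout, net.gbout, net.mbout, net.vbout, lr, b1, b2, eps, b1t, b2t);
}

// gather the trials in idx[i0:i1) from X (dims H,W,C,T,N) into ws.input
void gather_input(const NumericVector &X, const IntegerVector &dims,
                  const std::vector<int> &idx, int i0, int i1, Workspace &ws) {
  const int H = dims[0], W = dims[1], C = dims[2], T = dims[3];
  const size_t HW = (size_t)H * W;
  const int B = i1 - i0;
  ws.input.set_size(C, HW * (size_t)B * T);
  const double *x = X.begin();
  for (int b = 0; b < B; ++b) {
    const size_t toff = (size_t)idx[i0 + b] * T;
    for (int t = 0; t < T; ++t) {
      const size_t foff = HW * ((size_t)b * T + t);
      const size_t xoff = HW * C * (toff + t);
      for (int c = 0; c < C; ++c)
        for (size_t p = 0; p < HW; ++p)
          ws.input(c, foff + p) = (float)x[xoff + (size_t)c * HW + p];
    }
  }
}

// evaluate mean loss and accuracy (no dropout)
void evaluate(Net &net, Workspace &ws, const NumericVector &X,
              const IntegerVector &dims, const IntegerVector &y, double &loss,
              double &acc, mat *probs_out) {
  const int N = dims[4];
  double L = 0; int correct = 0;
  if (probs_out) probs_out->set_size(2, N);
  std::vector<int> idx(N);
  for (int i = 0; i < N; ++i) idx[i] = i;
  for (int s = 0; s < N; s += CHUNK) {
    const int B = std::min(CHUNK, N - s);
    gather_input(X, dims, idx, s, s + B, ws);
    forward_all(net, ws, B, false, 0.0, nullptr);
    for (int b = 0; b < B; ++b) {
      const double p = std::max(ws.probs(y[s + b], b), 1e-12);
      L += -std::log(p);
      if ((ws.probs(1, b) > ws.probs(0, b) ? 1 : 0) == y[s + b]) ++correct;
    }
    if (probs_out) probs_out->cols(s, s + B - 1) = ws.probs;
  }
  loss = L / N; acc = (double)correct / N;
}

} // namespace

// [[Rcpp::export]]
List nn_train_cpp(List weights, NumericVector X, IntegerVector y,
                  IntegerVector conv_counts, IntegerVector conv_channels,
                  int epochs, int batch_size, double lr, double beta1,
                  double beta2, double dropout, int seed,
                  Nullable<NumericVector> Xval_, Nullable<IntegerVector> yval_,
                  int patience, int n_frames, int image_size) {
  IntegerVector dims = X.attr("dim");
  if (dims.size() != 5) stop("X must have dims (H, W, C, frames, N)");
  const int N = dims[4];
  Net net = build_net(weights, conv_counts, conv_channels, image_size, n_frames);
  Workspace ws;
  std::mt19937 rng((unsigned)seed);
  const bool has_val = Xval_.isNotNull() && yval_.isNotNull();
  NumericVector Xval; IntegerVector yval, dval;
  if (has_val) {
    Xval = Xval_.get(); yval = yval_.get();
    dval = Xval.attr("dim");
  }
  std::vector<double> tr_loss, tr_acc, va_loss, va_acc;
  double best_va = -1; int best_epoch = -1, since_best = 0, step = 0;
  bool have_best = false;
  List best_weights;
  std::vector<int> perm(N);
  for (int i = 0; i < N; ++i) perm[i] = i;
  for (int ep = 0; ep < epochs; ++ep) {
    std::shuffle(perm.begin(), perm.end(), rng);
    double epl = 0; int epc = 0;
    for (int s = 0; s < N; s += batch_size) {
      const int B = std::min(batch_size, N - s);
      zero_grads(net);
      for (int cs = 0; cs < B; cs += CHUNK) {
        const int CB = std::min(CHUNK, B - cs);
        gather_input(X, dims, perm, s + cs, s + cs + CB, ws);
        std::vector<int> yb(CB);
        for (int b = 0; b < CB; ++b) yb[b] = y[perm[s + cs + b]];
        forward_all(net, ws, CB, true, dropout, &rng);
        for (int b = 0; b < CB; ++b) {
          epl += -std::log(std::max(ws.probs(yb[b], b), 1e-12));
          if ((ws.probs(1, b) > ws.probs(0, b) ? 1 : 0) == yb[b]) ++epc;
        }
        backward_all(net, ws, yb, CB, 1.0 / B);
      }
      adam_step(net, lr, beta1, beta2, 1e-8, ++step);
    }
    tr_loss.push_back(epl / N); tr_acc.push_back((double)epc / N);
    if (has_val) {
      double vl, va;
      evaluate(net, ws, Xval, dval, yval, vl, va, nullptr);
      va_loss.push_back(vl); va_acc.push_back(va);
      if (va > best_va + 1e-12) {
        best_va = va; best_epoch = ep + 1; since_best = 0;
        best_weights = export_weights(net); have_best = true;
      } else if (++since_best > patience && patience >= 0) break;
      if (va >= 1.0 - 1e-12 && patience >= 0) break;  // cannot improve further
    }
    Rcpp::checkUserInterrupt();
  }
  List final_weights = (has_val && have_best) ? best_weights : export_weights(net);
  return List::create(
    _["weights"] = final_weights,
    _["history"] = List::create(
      _["train_loss"] = tr_loss, _["train_acc"] = tr_acc,
      _["val_loss"] = va_loss, _["val_acc"] = va_acc),
    _["best_epoch"] = best_epoch, _["best_val_acc"] = best_va);
}

// [[Rcpp::export]]
NumericMatrix nn_predict_cpp(List weights, NumericVector X,
                             IntegerVector conv_counts, IntegerVector conv_channels,
                             int n_frames, int image_size) {
  IntegerVector dims = X.attr("dim");
  if (dims.size() != 5) stop("X must have dims (H, W, C, frames, N)");
  Net net = build_net(weights, conv_counts, conv_channels, image_size, n_frames);
  Workspace ws;
  const int N = dims[4];
  IntegerVector y0(N);  // dummy labels for evaluate()
  double l, a; mat probs;
  evaluate(net, ws, X, dims, y0, l, a, &probs);
  NumericMatrix out(N, 2);
  for (int i = 0; i < N; ++i) { out(i, 0) = probs(0, i); out(i, 1) = probs(1, i); }
  return out;
}

// Gradients of the mean cross-entropy at the current weights (no dropout),
// exported for finite-difference verification in the tests.
// [[Rcpp::export]]
List nn_grad_cpp(List weights, NumericVector X, IntegerVector y,
                 IntegerVector conv_counts, IntegerVector conv_channels,
                 int n_frames, int image_size) {
  IntegerVector dims = X.attr("dim");
  if (dims.size() != 5) stop("X must have dims (H, W, C, frames, N)");
  const int N = dims[4];
  Net net = build_net(weights, conv_counts, conv_channels, image_size, n_frames);
  Workspace ws;
  zero_grads(net);
  std::vector<int> idx(N);
  for (int i = 0; i < N; ++i) idx[i] = i;
  for (int s = 0; s < N; s += CHUNK) {
    const int B = std::min(CHUNK, N - s);
    gather_input(X, dims, idx, s, s + B, ws);
    std::vector<int> yb(B);
    for (int b = 0; b < B; ++b) yb[b] = y[s + b];
    forward_all(net, ws, B, false, 0.0, nullptr);
    backward_all(net, ws, yb, B, 1.0 / N);
  }
  List convG(net.convs.size());
  for (size_t i = 0; i < net.convs.size(); ++i)
    convG[i] = wrap(arma::conv_to<mat>::from(net.convs[i].gW));
  return List::create(
    _["conv_w"] = convG,
    _["fc_w"] = wrap(arma::conv_to<mat>::from(net.gWfc)),
    _["lstm_wf"] = net.gWf, _["out_w"] = net.gWout,
    _["out_b"] = net.gbout);
}

// One LSTM step in the exact arithmetic the network uses (double precision):
// f = sig(Wf [h;x] + bf), i = sig(Wi [h;x] + bi), g = tanh(Wc [h;x] + bc),
// o = sig(Wo [h;x] + bo), c' = c % f + g % i, h' = tanh(c') % o.
// [[Rcpp::export]]
List lstm_step_cpp(arma::mat Wf, arma::mat Wi, arma::mat Wc, arma::mat Wo,
                   arma::vec bf, arma::vec bi, arma::vec bc, arma::vec bo,
                   arma::vec x, arma::vec h, arma::vec c) {
  arma::vec hx = arma::join_cols(h, x);
  arma::vec f = 1.0 / (1.0 + arma::exp(-(Wf * hx + bf)));
  arma::vec i = 1.0 / (1.0 + arma::exp(-(Wi * hx + bi)));
  arma::vec g = arma::tanh(Wc * hx + bc);
  arma::vec o = 1.0 / (1.0 + arma::exp(-(Wo * hx + bo)));
  arma::vec cn = c % f + g % i;
  arma::vec hn = arma::tanh(cn) % o;
  return List::create(_["h"] = hn, _["c"] = cn);
}
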