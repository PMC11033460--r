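// A compact symmetric encoder-decoder ("U-Net") for per-object probability
// maps, with hand-written backprop. Layout per level: two 3x3 same-padding
// convolutions + ReLU, 2x2 max-pool down, nearest-neighbour upsample + 3x3
// conv up, skip concatenation (skip channels first), per-object sigmoid head.
// Filters double per level: base * 2^depth at the bottleneck (32 -> 1024 for
// base 32, depth 5). Training maximizes the mean per-object Dice of the
// probability maps; the exported gradient is of (1 - Dice), to be minimized.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;
using arma::cube;
using arma::mat;
using arma::vec;
using arma::umat;

struct Layer { mat W; vec b; };
struct LayerG { mat W; vec b; };

struct Net {
  int Cin, K, base, depth;
  std::vector<Layer> encA, encB, up, decA, decB;
  Layer botA, botB, out;
};

static Layer get_layer(const List& p, const std::string& nm) {
  Layer L;
  L.W = as<mat>(p[nm + "_W"]);
  L.b = as<vec>(p[nm + "_b"]);
  return L;
}

static Net load_net(const List& params, int Cin, int K, int base, int depth) {
  Net n;
  n.Cin = Cin; n.K = K; n.base = base; n.depth = depth;
  for (int i = 0; i < depth; ++i) {
    std::string e = "enc" + std::to_string(i);
    n.encA.push_back(get_layer(params, e + "_A"));
    n.encB.push_back(get_layer(params, e + "_B"));
  }
  n.botA = get_layer(params, "bot_A");
  n.botB = get_layer(params, "bot_B");
  for (int i = 0; i < depth; ++i) {
    std::string d = std::to_string(i);
    n.up.push_back(get_layer(params, "up" + d));
    n.decA.push_back(get_layer(params, "dec" + d + "_A"));
    n.decB.push_back(get_layer(params, "dec" + d + "_B"));
  }
  n.out = get_layer(params, "out");
  return n;
}

// ---- primitive ops ---------------------------------------------------------

// Patch matrix in (H*W, C*9) layout: column c*9+k is the image plane shifted
// by the k-th kernel offset (zero padded), built from whole-block submatrix
// copies so the work is memcpy-like and the conv itself is one GEMM.
static mat im2col3(const cube& X) {
  const int H = X.n_rows, W = X.n_cols, C = X.n_slices;
  mat cols(H * W, C * 9, arma::fill::zeros);
  mat shifted(H, W);
  for (int c = 0; c < C; ++c) {
    const arma::mat& S = X.slice(c);
    for (int b = -1; b <= 1; ++b)
      for (int a = -1; a <= 1; ++a) {
        const int r = c * 9 + (a + 1) * 3 + (b + 1);
        shifted.zeros();
        const int i0 = std::max(0, -a), i1 = std::min(H, H - a) - 1;
        const int j0 = std::max(0, -b), j1 = std::min(W, W - b) - 1;
        shifted.submat(i0, j0, i1, j1) =
          S.submat(i0 + a, j0 + b, i1 + a, j1 + b);
        cols.col(r) = arma::vectorise(shifted);
      }
  }
  return cols;
}

static cube conv3(const cube& X, const Layer& L, mat* keep_cols) {
  mat cols = im2col3(X);
  mat o = cols * L.W.t();          // (H*W, Cout)
  o.each_row() += L.b.t();
  const int H = X.n_rows, W = X.n_cols, Cout = L.W.n_rows;
  cube out(H, W, Cout);
  for (int c = 0; c < Cout; ++c)
    out.slice(c) = arma::reshape(o.col(c), H, W);
  if (keep_cols) *keep_cols = std::move(cols);
  return out;
}

static cube conv3_bwd(const cube& dOut, const mat& cols, const Layer& L,
                      LayerG& g, int Cin) {
  const int H = dOut.n_rows, W = dOut.n_cols, Cout = L.W.n_rows;
  mat dO(H * W, Cout);
  for (int c = 0; c < Cout; ++c)
    dO.col(c) = arma::vectorise(dOut.slice(c));
  g.W += dO.t() * cols;
  g.b += arma::sum(dO, 0).t();
  mat dCols = dO * L.W;            // (H*W, Cin*9)
  cube dX(H, W, Cin, arma::fill::zeros);
  for (int c = 0; c < Cin; ++c)
    for (int b = -1; b <= 1; ++b)
      for (int a = -1; a <= 1; ++a) {
        const int r = c * 9 + (a + 1) * 3 + (b + 1);
        const arma::mat plane(const_cast<double*>(dCols.colptr(r)), H, W,
                              false, true);
        const int i0 = std::max(0, -a), i1 = std::min(H, H - a) - 1;
        const int j0 = std::max(0, -b), j1 = std::min(W, W - b) - 1;
        dX.slice(c).submat(i0 + a, j0 + b, i1 + a, j1 + b) +=
          plane.submat(i0, j0, i1, j1);
      }
  return dX;
}

static void relu_(cube& X) { X.transform([](double v) { return v > 0 ? v : 0.0; }); }

// zero the gradient wherever the forward activation was clipped
static void relu_bwd_(cube& d, const cube& act) { d.elem(arma::find(act <= 0)).zeros(); }

static cube maxpool2(const cube& X, umat& idx) {
  const int H = X.n_rows / 2, W = X.n_cols / 2, C = X.n_slices;
  cube out(H, W, C);
  idx.set_size(H * W, C);
  for (int c = 0; c < C; ++c)
    for (int j = 0; j < W; ++j)
      for (int i = 0; i < H; ++i) {
        double best = -arma::datum::inf;
        arma::uword bi = 0;
        for (int b = 0; b < 2; ++b)
          for (int a = 0; a < 2; ++a) {
            const int ii = 2 * i + a, jj = 2 * j + b;
            const double v = X(ii, jj, c);
            if (v > best) { best = v; bi = (arma::uword) jj * X.n_rows + ii; }
          }
        out(i, j, c) = best;
        idx(j * H + i, c) = bi;
      }
  return out;
}

static cube maxpool2_bwd(const cube& dOut, const umat& idx, int H, int W) {
  const int C = dOut.n_slices, h = dOut.n_rows, w = dOut.n_cols;
  cube dX(H, W, C, arma::fill::zeros);
  for (int c = 0; c < C; ++c)
    for (int j = 0; j < w; ++j)
      for (int i = 0; i < h; ++i)
        dX.slice(c)(idx(j * h + i, c)) += dOut(i, j, c);
  return dX;
}

static cube up2(const cube& X) {
  const int H = X.n_rows, W = X.n_cols, C = X.n_slices;
  cube out(2 * H, 2 * W, C);
  for (int c = 0; c < C; ++c)
    for (int j = 0; j < W; ++j)
      for (int i = 0; i < H; ++i) {
        const double v = X(i, j, c);
        out(2 * i, 2 * j, c) = v;
        out(2 * i + 1, 2 * j, c) = v;
        out(2 * i, 2 * j + 1, c) = v;
        out(2 * i + 1, 2 * j + 1, c) = v;
      }
  return out;
}

static cube up2_bwd(const cube& dOut) {
  const int H = dOut.n_rows / 2, W = dOut.n_cols / 2, C = dOut.n_slices;
  cube dX(H, W, C);
  for (int c = 0; c < C; ++c)
    for (int j = 0; j < W; ++j)
      for (int i = 0; i < H; ++i)
        dX(i, j, c) = dOut(2 * i, 2 * j, c) + dOut(2 * i + 1, 2 * j, c) +
                      dOut(2 * i, 2 * j + 1, c) + dOut(2 * i + 1, 2 * j + 1, c);
  return dX;
}

static cube concat_ch(const cube& A, const cube& B) {
  cube out(A.n_rows, A.n_cols, A.n_slices + B.n_slices);
  out.slices(0, A.n_slices - 1) = A;
  out.slices(A.n_slices, out.n_slices - 1) = B;
  return out;
}

// ---- forward pass with cached activations ----------------------------------

struct Acts {
  std::vector<mat> encA_cols, encB_cols, up_cols, decA_cols, decB_cols;
  std::vector<cube> encA_act, encB_act, up_act, upsampled, cat_in, decA_act, decB_act;
  std::vector<umat> pool_idx;
  mat botA_cols, botB_cols;
  cube botA_act, botB_act, feat;
  mat featm;     // (F, H*W) input to the 1x1 head
  cube p;        // sigmoid probabilities (H, W, K)
};

static void forward(const Net& n, const cube& x, Acts& A, bool keep) {
  const int d = n.depth;
  A.encA_cols.resize(d); A.encB_cols.resize(d); A.up_cols.resize(d);
  A.decA_cols.resize(d); A.decB_cols.resize(d);
  A.encA_act.resize(d); A.encB_act.resize(d); A.up_act.resize(d);
  A.upsampled.resize(d); A.cat_in.resize(d); A.decA_act.resize(d);
  A.decB_act.resize(d); A.pool_idx.resize(d);

  cube cur = x;
  for (int i = 0; i < d; ++i) {
    cube a = conv3(cur, n.encA[i], keep ? &A.encA_cols[i] : nullptr);
    relu_(a);
    A.encA_act[i] = a;
    cube b = conv3(a, n.encB[i], keep ? &A.encB_cols[i] : nullptr);
    relu_(b);
    A.encB_act[i] = b;
    cur = maxpool2(b, A.pool_idx[i]);
  }
  cube ba = conv3(cur, n.botA, keep ? &A.botA_cols : nullptr);
  relu_(ba);
  A.botA_act = ba;
  cube bb = conv3(ba, n.botB, keep ? &A.botB_cols : nullptr);
  relu_(bb);
  A.botB_act = bb;
  cur = bb;
  for (int i = d - 1; i >= 0; --i) {
    A.upsampled[i] = up2(cur);
    cube u = conv3(A.upsampled[i], n.up[i], keep ? &A.up_cols[i] : nullptr);
    relu_(u);
    A.up_act[i] = u;
    A.cat_in[i] = concat_ch(A.encB_act[i], u);
    cube da = conv3(A.cat_in[i], n.decA[i], keep ? &A.decA_cols[i] : nullptr);
    relu_(da);
    A.decA_act[i] = da;
    cube db = conv3(da, n.decB[i], keep ? &A.decB_cols[i] : nullptr);
    relu_(db);
    A.decB_act[i] = db;
    cur = db;
  }
  A.feat = cur;
  const int H = cur.n_rows, W = cur.n_cols, F = cur.n_slices;
  A.featm.set_size(F, H * W);
  for (int c = 0; c < F; ++c)
    A.featm.row(c) = arma::vectorise(cur.slice(c)).t();
  mat z = n.out.W * A.featm;
  z.each_col() += n.out.b;
  A.p.set_size(H, W, n.K);
  for (int k = 0; k < n.K; ++k)
    A.p.slice(k) = 1.0 / (1.0 + arma::exp(-arma::reshape(z.row(k), H, W)));
}

// Mean per-object Dice of probability maps against binary truth, with the
// squared-denominator form; an object absent from both pred and truth scores 1.
static double dice_L(const cube& p, const cube& y, cube* dLdp) {
  const int K = p.n_slices;
  double L = 0.0;
  if (dLdp) dLdp->zeros(p.n_rows, p.n_cols, K);
  for (int k = 0; k < K; ++k) {
    const double N = 2.0 * arma::accu(p.slice(k) % y.slice(k));
    const double D = arma::accu(arma::square(p.slice(k))) + arma::accu(arma::square(y.slice(k)));
    if (D == 0.0) { L += 1.0; continue; }
    L += N / D;
    if (dLdp)
      dLdp->slice(k) = (2.0 * y.slice(k) * D - 2.0 * p.slice(k) * N) / (D * D) / K;
  }
  return L / K;
}

static void zero_like(const Net& n, Net& g) {
  g = n;
  auto z = [](Layer& L) { L.W.zeros(); L.b.zeros(); };
  for (int i = 0; i < n.depth; ++i) { z(g.encA[i]); z(g.encB[i]); z(g.up[i]); z(g.decA[i]); z(g.decB[i]); }
  z(g.botA); z(g.botB); z(g.out);
}

static void backward(const Net& n, const cube& x, const cube& y, Acts& A, Net& g) {
  const int d = n.depth, H = A.p.n_rows, W = A.p.n_cols;
  cube dLdp;
  dice_L(A.p, y, &dLdp);
  // minimize 1 - L; chain through sigmoid
  cube dz = -dLdp % A.p % (1.0 - A.p);
  mat dzm(n.K, H * W);
  for (int k = 0; k < n.K; ++k)
    dzm.row(k) = arma::vectorise(dz.slice(k)).t();
  g.out.W += dzm * A.featm.t();
  g.out.b += arma::sum(dzm, 1);
  mat dfm = n.out.W.t() * dzm;
  const int F = A.feat.n_slices;
  cube cur(H, W, F);
  for (int c = 0; c < F; ++c)
    cur.slice(c) = arma::reshape(dfm.row(c), H, W);

  LayerG gl;
  for (int i = 0; i < d; ++i) {
    relu_bwd_(cur, A.decB_act[i]);
    gl.W.zeros(n.decB[i].W.n_rows, n.decB[i].W.n_cols); gl.b.zeros(n.decB[i].b.n_elem);
    cur = conv3_bwd(cur, A.decB_cols[i], n.decB[i], gl, A.decA_act[i].n_slices);
    g.decB[i].W += gl.W; g.decB[i].b += gl.b;

    relu_bwd_(cur, A.decA_act[i]);
    gl.W.zeros(n.decA[i].W.n_rows, n.decA[i].W.n_cols); gl.b.zeros(n.decA[i].b.n_elem);
    cur = conv3_bwd(cur, A.decA_cols[i], n.decA[i], gl, A.cat_in[i].n_slices);
    g.decA[i].W += gl.W; g.decA[i].b += gl.b;

    const int cs = A.encB_act[i].n_slices;
    cube dskip = cur.slices(0, cs - 1);
    cube dup = cur.slices(cs, cur.n_slices - 1);

    relu_bwd_(dup, A.up_act[i]);
    gl.W.zeros(n.up[i].W.n_rows, n.up[i].W.n_cols); gl.b.zeros(n.up[i].b.n_elem);
    cube dupsampled = conv3_bwd(dup, A.up_cols[i], n.up[i], gl, A.upsampled[i].n_slices);
    g.up[i].W += gl.W; g.up[i].b += gl.b;
    cube dbelow = up2_bwd(dupsampled);

    // dskip flows into the encoder branch at level i; dbelow continues down.
    // Encoder backward is deferred: store by overwriting encB act grads.
    A.encB_act[i] = dskip;  // reuse slot as gradient carrier
    cur = dbelow;
  }

  // bottleneck
  relu_bwd_(cur, A.botB_act);
  gl.W.zeros(n.botB.W.n_rows, n.botB.W.n_cols); gl.b.zeros(n.botB.b.n_elem);
  cur = conv3_bwd(cur, A.botB_cols, n.botB, gl, A.botA_act.n_slices);
  g.botB.W += gl.W; g.botB.b += gl.b;
  relu_bwd_(cur, A.botA_act);
  gl.W.zeros(n.botA.W.n_rows, n.botA.W.n_cols); gl.b.zeros(n.botA.b.n_elem);
  {
    const int ci = (d > 0) ? (int) n.encB[d - 1].W.n_rows : n.Cin;
    cur = conv3_bwd(cur, A.botA_cols, n.botA, gl, ci);
  }
  g.botA.W += gl.W; g.botA.b += gl.b;

  // encoder, deepest level first; combine pooled gradient with skip gradient
  for (int i = d - 1; i >= 0; --i) {
    cube dB = maxpool2_bwd(cur, A.pool_idx[i],
                           A.encA_act[i].n_rows, A.encA_act[i].n_cols);
    dB += A.encB_act[i];  // skip-connection gradient stored above
    // A.encB_act[i] now carries a gradient; the original activation (needed
    // for the ReLU mask) survives in A.cat_in[i] slices 0..cs-1.
    const int cs = dB.n_slices;
    cube actB = A.cat_in[i].slices(0, cs - 1);
    relu_bwd_(dB, actB);
    gl.W.zeros(n.encB[i].W.n_rows, n.encB[i].W.n_cols); gl.b.zeros(n.encB[i].b.n_elem);
    cube dA = conv3_bwd(dB, A.encB_cols[i], n.encB[i], gl, A.encA_act[i].n_slices);
    g.encB[i].W += gl.W; g.encB[i].b += gl.b;
    relu_bwd_(dA, A.encA_act[i]);
    gl.W.zeros(n.encA[i].W.n_rows, n.encA[i].W.n_cols); gl.b.zeros(n.encA[i].b.n_elem);
    const int ci = (i == 0) ? n.Cin : (int) n.encB[i - 1].W.n_rows;
    cur = conv3_bwd(dA, A.encA_cols[i], n.encA[i], gl, ci);
    g.encA[i].W += gl.W; g.encA[i].b += gl.b;
  }
}

// ---- R interface -----------------------------------------------------------

static void store_layer(List& out, const std::string& nm, const Layer& L) {
  out[nm + "_W"] = wrap(L.W);
  out[nm + "_b"] = wrap(L.b);
}

// [[Rcpp::export]]
List cpp_unet_batch(const List& params, int Cin, int K, int base, int depth,
                    const List& xs, const List& ys, bool want_grad) {
  Net n = load_net(params, Cin, K, base, depth);
  Net g;
  if (want_grad) zero_like(n, g);
  const int N = xs.size();
  double loss = 0.0;
  for (int s = 0; s < N; ++s) {
    cube x = as<cube>(xs[s]);
    cube y = as<cube>(ys[s]);
    Acts A;
    forward(n, x, A, want_grad);
    loss += dice_L(A.p, y, nullptr);
    if (want_grad) backward(n, x, y, A, g);
  }
  loss /= N;
  List out = List::create(_["dice"] = loss);
  if (want_grad) {
    List gr;
    for (int i = 0; i < depth; ++i) {
      std::string e = "enc" + std::to_string(i);
      store_layer(gr, e + "_A", g.encA[i]);
      store_layer(gr, e + "_B", g.encB[i]);
    }
    store_layer(gr, "bot_A", g.botA);
    store_layer(gr, "bot_B", g.botB);
    for (int i = 0; i < depth; ++i) {
      std::string ds = std::to_string(i);
      store_layer(gr, "up" + ds, g.up[i]);
      store_layer(gr, "dec" + ds + "_A", g.decA[i]);
      store_layer(gr, "dec" + ds + "_B", g.decB[i]);
    }
    store_layer(gr, "out", g.out);
    // average over the batch, in place so dim attributes survive
    for (int i = 0; i < gr.size(); ++i) {
      NumericVector v = gr[i];
      for (R_xlen_t q = 0; q < v.size(); ++q) v[q] /= (double) N;
    }
    out["grads"] = gr;
  }
  return out;
}

// [[Rcpp::export]]
List cpp_unet_predict(const List& params, int Cin, int K, int base, int depth,
                      const List& xs) {
  Net n = load_net(params, Cin, K, base, depth);
  const int N = xs.size();
  List out(N);
  for (int s = 0; s < N; ++s) {
    cube x = as<cube>(xs[s]);
    Acts A;
    forward(n, x, A, false);
    out[s] = wrap(A.p);
  }
  return out;
}
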