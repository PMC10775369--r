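// Three-head U-Net (3-class segmentation + cell count + auto-encoding)
// with hand-written forward/backward passes and Adam, trained under the
// composite loss L = Lce + a*Ljacc + lc*Lcount + la*Lauto + b*Lreg.
//
// Feature maps are arma::cube(H, W, C); conv kernels are 3x3 (pad 1) or
// 1x1, stored as mat(Cin*k*k, Cout) acting on im2col matrices of shape
// (H*W, Cin*k*k) with column-major pixel index i = h + H*w.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

static const double PROB_EPS = 1e-7;

// ---------------------------------------------------------------- helpers

static mat im2col3(const cube& in) {
  const uword H = in.n_rows, W = in.n_cols, C = in.n_slices;
  mat col(H * W, C * 9, fill::zeros);
  for (uword c = 0; c < C; ++c) {
    const double* sp = in.slice_memptr(c);
    for (int ky = -1; ky <= 1; ++ky) {
      for (int kx = -1; kx <= 1; ++kx) {
        const uword j = c * 9 + (uword)((ky + 1) * 3 + (kx + 1));
        double* cp = col.colptr(j);
        const long h0 = std::max(0L, -(long)ky);
        const long h1 = std::min((long)H, (long)H - ky);
        const long len = h1 - h0;
        if (len <= 0) continue;
        for (uword w = 0; w < W; ++w) {
          const long ws = (long)w + kx;
          if (ws < 0 || ws >= (long)W) continue;
          std::memcpy(cp + h0 + H * w, sp + (h0 + ky) + H * ws,
                      len * sizeof(double));
        }
      }
    }
  }
  return col;
}

static cube col2im3(const mat& dcol, uword H, uword W, uword C) {
  cube din(H, W, C, fill::zeros);
  for (uword c = 0; c < C; ++c) {
    double* sp = din.slice_memptr(c);
    for (int ky = -1; ky <= 1; ++ky) {
      for (int kx = -1; kx <= 1; ++kx) {
        const uword j = c * 9 + (uword)((ky + 1) * 3 + (kx + 1));
        const double* cp = dcol.colptr(j);
        const long h0 = std::max(0L, -(long)ky);
        const long h1 = std::min((long)H, (long)H - ky);
        if (h1 <= h0) continue;
        for (uword w = 0; w < W; ++w) {
          const long ws = (long)w + kx;
          if (ws < 0 || ws >= (long)W) continue;
          const double* src = cp + h0 + H * w;
          double* dst = sp + (h0 + ky) + H * ws;
          for (long h = 0; h < h1 - h0; ++h) dst[h] += src[h];
        }
      }
    }
  }
  return din;
}

static cube mat2cube(const mat& m, uword H, uword W) {
  cube out(H, W, m.n_cols);
  for (uword c = 0; c < m.n_cols; ++c)
    out.slice(c) = reshape(m.col(c), H, W);
  return out;
}

static mat cube2mat(const cube& x) {
  mat out(x.n_rows * x.n_cols, x.n_slices);
  for (uword c = 0; c < x.n_slices; ++c)
    out.col(c) = vectorise(x.slice(c));
  return out;
}

struct ConvLayer {
  mat W;      // (Cin*k*k, Cout)
  rowvec b;   // (Cout)
  int k;      // kernel size 1 or 3
  // caches (per forward)
  mat col;    // im2col of input
  cube pre;   // pre-activation output
  uword Hin, Win, Cin;
  // gradients
  mat dW; rowvec db;

  cube forward(const cube& in) {
    Hin = in.n_rows; Win = in.n_cols; Cin = in.n_slices;
    col = (k == 3) ? im2col3(in) : cube2mat(in);
    mat out = col * W;
    out.each_row() += b;
    pre = mat2cube(out, Hin, Win);
    return pre;
  }
  cube backward(const cube& dout) {
    mat dm = cube2mat(dout);
    dW += col.t() * dm;
    db += sum(dm, 0);
    mat dcol = dm * W.t();
    if (k == 3) return col2im3(dcol, Hin, Win, Cin);
    return mat2cube(dcol, Hin, Win);
  }
  void zero_grad() {
    dW.zeros(W.n_rows, W.n_cols);
    db.zeros(b.n_elem);
  }
};

static cube relu(const cube& x) { return clamp(x, 0.0, datum::inf); }
static cube relu_bwd(const cube& dout, const cube& pre) {
  cube d = dout;
  d.elem(find(pre <= 0)).zeros();
  return d;
}

static cube maxpool2(const cube& x, ucube& argmax) {
  const uword H = x.n_rows / 2, W = x.n_cols / 2, C = x.n_slices;
  cube out(H, W, C);
  argmax.set_size(H, W, C);
  for (uword c = 0; c < C; ++c)
    for (uword w = 0; w < W; ++w)
      for (uword h = 0; h < H; ++h) {
        double best = -datum::inf; uword bi = 0;
        for (uword dy = 0; dy < 2; ++dy)
          for (uword dx = 0; dx < 2; ++dx) {
            const double v = x(2 * h + dy, 2 * w + dx, c);
            if (v > best) { best = v; bi = dy * 2 + dx; }
          }
        out(h, w, c) = best;
        argmax(h, w, c) = bi;
      }
  return out;
}

static cube maxpool2_bwd(const cube& dout, const ucube& argmax) {
  cube din(dout.n_rows * 2, dout.n_cols * 2, dout.n_slices, fill::zeros);
  for (uword c = 0; c < dout.n_slices; ++c)
    for (uword w = 0; w < dout.n_cols; ++w)
      for (uword h = 0; h < dout.n_rows; ++h) {
        const uword bi = argmax(h, w, c);
        din(2 * h + bi / 2, 2 * w + bi % 2, c) = dout(h, w, c);
      }
  return din;
}

static cube upsample2(const cube& x) {
  cube out(x.n_rows * 2, x.n_cols * 2, x.n_slices);
  for (uword c = 0; c < x.n_slices; ++c)
    for (uword w = 0; w < x.n_cols; ++w)
      for (uword h = 0; h < x.n_rows; ++h) {
        const double v = x(h, w, c);
        out(2 * h, 2 * w, c) = v;     out(2 * h + 1, 2 * w, c) = v;
        out(2 * h, 2 * w + 1, c) = v; out(2 * h + 1, 2 * w + 1, c) = v;
      }
  return out;
}

static cube upsample2_bwd(const cube& dout) {
  cube din(dout.n_rows / 2, dout.n_cols / 2, dout.n_slices);
  for (uword c = 0; c < din.n_slices; ++c)
    for (uword w = 0; w < din.n_cols; ++w)
      for (uword h = 0; h < din.n_rows; ++h)
        din(h, w, c) = dout(2 * h, 2 * w, c) + dout(2 * h + 1, 2 * w, c) +
                       dout(2 * h, 2 * w + 1, c) + dout(2 * h + 1, 2 * w + 1, c);
  return din;
}

// ---------------------------------------------------------------- network

struct Net {
  int depth, base, cin;
  std::vector<ConvLayer> encA, encB;           // depth each
  ConvLayer botA, botB;
  std::vector<ConvLayer> up, decC, decD;       // depth each (index = level)
  ConvLayer seg;                                // 1x1 -> 3
  std::vector<ConvLayer> autU;                 // depth (index = level)
  ConvLayer autOut;                             // 1x1 -> cin
  vec countW; double countB;
  vec dcountW; double dcountB;

  // forward caches
  std::vector<cube> skipPre;    // encB pre-activations
  std::vector<ucube> poolIdx;
  cube botApre, botBpre;
  std::vector<cube> upPre, decCpre, decDpre, autPre;
  std::vector<cube> skipAct;    // post-relu skip activations
  cube botAct;                  // post-relu bottleneck
  rowvec pooled;                // global-average-pooled bottleneck

  std::vector<ConvLayer*> layers() {
    std::vector<ConvLayer*> v;
    for (auto& l : encA) v.push_back(&l);
    for (auto& l : encB) v.push_back(&l);
    v.push_back(&botA); v.push_back(&botB);
    for (auto& l : up) v.push_back(&l);
    for (auto& l : decC) v.push_back(&l);
    for (auto& l : decD) v.push_back(&l);
    v.push_back(&seg);
    for (auto& l : autU) v.push_back(&l);
    v.push_back(&autOut);
    return v;
  }

  void zero_grad() {
    for (auto* l : layers()) l->zero_grad();
    dcountW.zeros(countW.n_elem);
    dcountB = 0.0;
  }

  double l2() {
    double s = 0;
    for (auto* l : layers()) s += accu(square(l->W));
    s += accu(square(countW));
    return s;
  }

  // returns probs (H,W,3); fills count, recon
  cube forward(const cube& x, double& count, cube& recon) {
    const uword H = x.n_rows, W = x.n_cols;
    if (H % (1u << depth) || W % (1u << depth))
      Rcpp::stop("tile size incompatible with pooling depth");
    skipPre.assign(depth, cube()); poolIdx.assign(depth, ucube());
    upPre.assign(depth, cube()); decCpre.assign(depth, cube());
    decDpre.assign(depth, cube()); autPre.assign(depth, cube());
    skipAct.assign(depth, cube());
    cube a = x;
    for (int d = 0; d < depth; ++d) {
      a = relu(encA[d].forward(a));
      skipPre[d] = encB[d].forward(a);
      skipAct[d] = relu(skipPre[d]);
      a = maxpool2(skipAct[d], poolIdx[d]);
    }
    botApre = botA.forward(a);
    botBpre = botB.forward(relu(botApre));
    botAct = relu(botBpre);
    // count head
    pooled.set_size(botAct.n_slices);
    const double npix = (double)(botAct.n_rows * botAct.n_cols);
    for (uword c = 0; c < botAct.n_slices; ++c)
      pooled(c) = accu(botAct.slice(c)) / npix;
    count = dot(countW, pooled.t()) + countB;
    // auto head
    cube r = botAct;
    for (int d = depth - 1; d >= 0; --d) {
      autPre[d] = autU[d].forward(upsample2(r));
      r = relu(autPre[d]);
    }
    recon = autOut.forward(r);
    // decoder
    cube dec = botAct;
    for (int d = depth - 1; d >= 0; --d) {
      upPre[d] = up[d].forward(upsample2(dec));
      cube u = relu(upPre[d]);
      cube cat = join_slices(u, skipAct[d]);
      decCpre[d] = decC[d].forward(cat);
      decDpre[d] = decD[d].forward(relu(decCpre[d]));
      dec = relu(decDpre[d]);
    }
    cube logits = seg.forward(dec);
    // softmax over slices
    cube probs(H, W, 3);
    for (uword w = 0; w < W; ++w)
      for (uword h = 0; h < H; ++h) {
        double m = std::max({logits(h, w, 0), logits(h, w, 1), logits(h, w, 2)});
        double s = 0;
        for (uword k = 0; k < 3; ++k) {
          probs(h, w, k) = std::exp(logits(h, w, k) - m);
          s += probs(h, w, k);
        }
        for (uword k = 0; k < 3; ++k) probs(h, w, k) /= s;
      }
    return probs;
  }

  // dlogits: grad at seg logits; dcount: grad at count output;
  // drecon: grad at reconstruction output
  void backward(const cube& dlogits, double dcount, const cube& drecon) {
    cube d = seg.backward(dlogits);
    cube dBot(botAct.n_rows, botAct.n_cols, botAct.n_slices, fill::zeros);
    skipGrad_.assign(depth, cube());
    // decoder chain, level 0 upward (reverse of the forward order)
    for (int dl = 0; dl < depth; ++dl) {
      d = relu_bwd(d, decDpre[dl]);
      d = decD[dl].backward(d);
      d = relu_bwd(d, decCpre[dl]);
      cube dcat = decC[dl].backward(d);
      const uword cu = upPre[dl].n_slices;
      cube du = dcat.slices(0, cu - 1);
      skipGrad_[dl] = dcat.slices(cu, dcat.n_slices - 1);
      du = relu_bwd(du, upPre[dl]);
      cube dprev = upsample2_bwd(up[dl].backward(du));
      if (dl == depth - 1) dBot += dprev; // grad wrt bottleneck activation
      else d = dprev;                     // grad wrt dec activation above
    }
    // auto head chain
    cube da = autOut.backward(drecon);
    for (int dl = 0; dl < depth; ++dl) {
      da = relu_bwd(da, autPre[dl]);
      da = upsample2_bwd(autU[dl].backward(da));
    }
    dBot += da;
    // count head
    dcountW += dcount * pooled.t();
    dcountB += dcount;
    const double npix = (double)(botAct.n_rows * botAct.n_cols);
    for (uword c = 0; c < botAct.n_slices; ++c)
      dBot.slice(c) += dcount * countW(c) / npix;
    // bottleneck convs
    cube db = relu_bwd(dBot, botBpre);
    db = botB.backward(db);
    db = relu_bwd(db, botApre);
    db = botA.backward(db);
    // encoder chain (deepest first)
    cube dnext = db;
    for (int dl = depth - 1; dl >= 0; --dl) {
      cube dskip = maxpool2_bwd(dnext, poolIdx[dl]);
      dskip += skipGrad_[dl];
      dskip = relu_bwd(dskip, skipPre[dl]);
      cube de = encB[dl].backward(dskip);
      de = relu_bwd(de, encA[dl].pre);
      dnext = encA[dl].backward(de);
    }
    skipGrad_.clear();
  }

 private:
  std::vector<cube> skipGrad_;
};

// ------------------------------------------------------- (de)serialization

static void init_layer(ConvLayer& l, int cin, int cout, int k,
                       std::mt19937& rng) {
  std::normal_distribution<double> nd(0.0, std::sqrt(2.0 / (cin * k * k)));
  l.W.set_size(cin * k * k, cout);
  for (uword i = 0; i < l.W.n_elem; ++i) l.W(i) = nd(rng);
  l.b.set_size(cout);
  l.b.fill(0.01); // keep units off the dead-ReLU kink at init
  l.k = k;
}

static Net build_net(int depth, int base, int cin, int seed) {
  Net net;
  net.depth = depth; net.base = base; net.cin = cin;
  std::mt19937 rng(seed);
  net.encA.resize(depth); net.encB.resize(depth);
  net.up.resize(depth); net.decC.resize(depth); net.decD.resize(depth);
  net.autU.resize(depth);
  int ch = cin;
  for (int d = 0; d < depth; ++d) {
    const int f = base << d;
    init_layer(net.encA[d], ch, f, 3, rng);
    init_layer(net.encB[d], f, f, 3, rng);
    ch = f;
  }
  const int fb = base << depth;
  init_layer(net.botA, ch, fb, 3, rng);
  init_layer(net.botB, fb, fb, 3, rng);
  for (int d = depth - 1; d >= 0; --d) {
    const int f = base << d;
    const int fin = (d == depth - 1) ? fb : base << (d + 1);
    init_layer(net.up[d], fin, f, 3, rng);
    init_layer(net.decC[d], 2 * f, f, 3, rng);
    init_layer(net.decD[d], f, f, 3, rng);
    const int fa_in = (d == depth - 1) ? fb : base << (d + 1);
    init_layer(net.autU[d], fa_in, base << d, 3, rng);
  }
  init_layer(net.seg, base, 3, 1, rng);
  init_layer(net.autOut, base, cin, 1, rng);
  std::normal_distribution<double> nd(0.0, std::sqrt(1.0 / fb));
  net.countW.set_size(fb);
  for (uword i = 0; i < net.countW.n_elem; ++i) net.countW(i) = nd(rng);
  net.countB = 0.0;
  return net;
}

static Rcpp::List net_to_list(Net& net) {
  Rcpp::List out;
  auto ls = net.layers();
  Rcpp::List convs(ls.size());
  for (size_t i = 0; i < ls.size(); ++i)
    convs[i] = Rcpp::List::create(
      Rcpp::Named("W") = Rcpp::wrap(ls[i]->W),
      Rcpp::Named("b") = Rcpp::wrap(ls[i]->b),
      Rcpp::Named("k") = ls[i]->k);
  out["convs"] = convs;
  out["countW"] = Rcpp::wrap(net.countW);
  out["countB"] = net.countB;
  out["depth"] = net.depth;
  out["base"] = net.base;
  out["cin"] = net.cin;
  return out;
}

static Net net_from_list(const Rcpp::List& lst) {
  Net net = build_net(Rcpp::as<int>(lst["depth"]), Rcpp::as<int>(lst["base"]),
                      Rcpp::as<int>(lst["cin"]), 0);
  Rcpp::List convs = lst["convs"];
  auto ls = net.layers();
  for (size_t i = 0; i < ls.size(); ++i) {
    Rcpp::List li = convs[i];
    ls[i]->W = Rcpp::as<mat>(li["W"]);
    ls[i]->b = Rcpp::as<rowvec>(li["b"]);
    ls[i]->k = Rcpp::as<int>(li["k"]);
  }
  net.countW = Rcpp::as<vec>(lst["countW"]);
  net.countB = Rcpp::as<double>(lst["countB"]);
  return net;
}

// ------------------------------------------------------------------ loss

struct LossParts { double ce, jacc, count, autoe, total; };

// computes loss and gradient cubes for one tile
static LossParts loss_and_grads(const cube& probs, const imat& target,
                                double countPred, double countTrue,
                                const cube& recon, const cube& input,
                                const vec& classW, double bi_mult,
                                double alpha, double lc, double la,
                                cube& dlogits, double& dcount, cube& drecon) {
  const uword H = probs.n_rows, W = probs.n_cols;
  const double npix = (double)(H * W);
  LossParts L{};
  // per-pixel CE weight (boundary-as-interior multiplier on current argmax)
  mat wpx(H, W);
  dlogits.set_size(H, W, 3);
  mat gsum(H, W, fill::zeros);           // sum_k gjacc_k * p_k
  cube gj(H, W, 3);                      // jaccard dL/dp
  // jaccard per-class sums
  for (uword k = 0; k < 3; ++k) {
    double inter = 0, psum = 0, ysum = 0;
    for (uword w = 0; w < W; ++w)
      for (uword h = 0; h < H; ++h) {
        const double p = probs(h, w, k);
        const bool y = (target(h, w) == (int)k);
        psum += p; if (y) { ysum += 1; inter += p; }
      }
    const double uni = psum + ysum - inter;
    L.jacc += (1.0 - (inter + PROB_EPS) / (uni + PROB_EPS)) / 3.0;
    const double U = uni + PROB_EPS, I = inter + PROB_EPS;
    for (uword w = 0; w < W; ++w)
      for (uword h = 0; h < H; ++h) {
        const double y = (target(h, w) == (int)k) ? 1.0 : 0.0;
        gj(h, w, k) = -(y * U - I * (1.0 - y)) / (U * U) / 3.0;
      }
  }
  for (uword w = 0; w < W; ++w)
    for (uword h = 0; h < H; ++h) {
      const int t = target(h, w);
      uword am = 0; double best = probs(h, w, 0);
      for (uword k = 1; k < 3; ++k)
        if (probs(h, w, k) > best) { best = probs(h, w, k); am = k; }
      double wp = classW(t);
      if (t == 2 && am == 1) wp *= bi_mult;
      wpx(h, w) = wp;
      const double pt = std::max(probs(h, w, (uword)t), PROB_EPS);
      L.ce += wp * (-std::log(pt)) / npix;
      double gs = 0;
      for (uword k = 0; k < 3; ++k) gs += gj(h, w, k) * probs(h, w, k);
      gsum(h, w) = gs;
    }
  // dlogits = CE grad + alpha * jaccard grad (both through softmax)
  for (uword k = 0; k < 3; ++k)
    for (uword w = 0; w < W; ++w)
      for (uword h = 0; h < H; ++h) {
        const double p = probs(h, w, k);
        const double y = (target(h, w) == (int)k) ? 1.0 : 0.0;
        const double gce = wpx(h, w) * (p - y) / npix;
        const double gjc = alpha * p * (gj(h, w, k) - gsum(h, w));
        dlogits(h, w, k) = gce + gjc;
      }
  L.count = (countPred - countTrue) * (countPred - countTrue);
  dcount = lc * 2.0 * (countPred - countTrue);
  const double nin = (double)input.n_elem;
  L.autoe = accu(square(recon - input)) / nin;
  drecon = la * 2.0 * (recon - input) / nin;
  return L;
}

// ------------------------------------------------------------- interface

// [[Rcpp::export(name = ".unet_init_cpp")]]
Rcpp::List unet_init_cpp(int depth, int base, int cin, int seed) {
  Net net = build_net(depth, base, cin, seed);
  return net_to_list(net);
}

static cube list_to_cube(const Rcpp::NumericVector& arr) {
  Rcpp::IntegerVector d = arr.attr("dim");
  cube x(d[0], d[1], d.size() == 3 ? d[2] : 1);
  std::copy(arr.begin(), arr.end(), x.memptr());
  return x;
}

// [[Rcpp::export(name = ".unet_forward_cpp")]]
Rcpp::List unet_forward_cpp(const Rcpp::List& model,
                            const Rcpp::NumericVector& input) {
  Net net = net_from_list(model);
  cube x = list_to_cube(input);
  double count; cube recon;
  cube probs = net.forward(x, count, recon);
  return Rcpp::List::create(
    Rcpp::Named("probs") = Rcpp::wrap(probs),
    Rcpp::Named("count") = count,
    Rcpp::Named("recon") = Rcpp::wrap(recon),
    Rcpp::Named("l2") = net.l2());
}

// Loss and full parameter gradient on one tile (testing and diagnostics)
// [[Rcpp::export(name = ".unet_lossgrad_cpp")]]
Rcpp::List unet_lossgrad_cpp(const Rcpp::List& model,
                             const Rcpp::NumericVector& input,
                             const Rcpp::IntegerMatrix& label,
                             double countTrue, const Rcpp::List& lossw) {
  Net net = net_from_list(model);
  const double alpha = Rcpp::as<double>(lossw["alpha"]);
  const double lc = Rcpp::as<double>(lossw["lambda_c"]);
  const double la = Rcpp::as<double>(lossw["lambda_a"]);
  const double beta = Rcpp::as<double>(lossw["beta"]);
  const vec classW = Rcpp::as<vec>(lossw["class_weights"]);
  const double bi_mult =
    Rcpp::as<double>(lossw["boundary_as_interior_multiplier"]);
  cube x = list_to_cube(input);
  imat y = Rcpp::as<imat>(label);
  net.zero_grad();
  double count; cube recon;
  cube probs = net.forward(x, count, recon);
  cube dlogits, drecon; double dcount;
  LossParts L = loss_and_grads(probs, y, count, countTrue, recon, x,
                               classW, bi_mult, alpha, lc, la,
                               dlogits, dcount, drecon);
  net.backward(dlogits, dcount, drecon);
  const double reg = net.l2();
  const double total = L.ce + alpha * L.jacc + lc * L.count +
                       la * L.autoe + beta * reg;
  auto ls = net.layers();
  Rcpp::List grads(ls.size());
  for (size_t i = 0; i < ls.size(); ++i) {
    mat gW = ls[i]->dW + 2.0 * beta * ls[i]->W;
    grads[i] = Rcpp::List::create(Rcpp::Named("W") = Rcpp::wrap(gW),
                                  Rcpp::Named("b") = Rcpp::wrap(ls[i]->db));
  }
  vec gc = net.dcountW + 2.0 * beta * net.countW;
  return Rcpp::List::create(
    Rcpp::Named("total") = total, Rcpp::Named("ce") = L.ce,
    Rcpp::Named("jacc") = L.jacc, Rcpp::Named("count") = L.count,
    Rcpp::Named("auto") = L.autoe, Rcpp::Named("reg") = reg,
    Rcpp::Named("pred_count") = count,
    Rcpp::Named("grads") = grads,
    Rcpp::Named("gcountW") = Rcpp::wrap(gc),
    Rcpp::Named("gcountB") = net.dcountB);
}

static void rot90_mat(mat& m, int k) {
  for (int i = 0; i < (k % 4 + 4) % 4; ++i)
    m = fliplr(m.t());
}
static void rot90_imat(imat& m, int k) {
  for (int i = 0; i < (k % 4 + 4) % 4; ++i) {
    imat t = m.t();
    m = fliplr(t);
  }
}

// [[Rcpp::export(name = ".unet_train_cpp")]]
Rcpp::List unet_train_cpp(const Rcpp::List& model, const Rcpp::List& tiles,
                          const Rcpp::List& labels,
                          const Rcpp::NumericVector& counts,
                          const Rcpp::List& lossw, const Rcpp::List& cfg) {
  Net net = net_from_list(model);
  const int n = tiles.size();
  const int epochs = Rcpp::as<int>(cfg["epochs"]);
  const int batch = Rcpp::as<int>(cfg["batch_size"]);
  const double lr = Rcpp::as<double>(cfg["learning_rate"]);
  const bool augment = Rcpp::as<bool>(cfg["augment"]);
  const double aug_noise = Rcpp::as<double>(cfg["noise_sd"]);
  const double aug_shift = Rcpp::as<double>(cfg["shift_range"]);
  const int seed = Rcpp::as<int>(cfg["seed"]);
  const double alpha = Rcpp::as<double>(lossw["alpha"]);
  const double lc = Rcpp::as<double>(lossw["lambda_c"]);
  const double la = Rcpp::as<double>(lossw["lambda_a"]);
  const double beta = Rcpp::as<double>(lossw["beta"]);
  const vec classW = Rcpp::as<vec>(lossw["class_weights"]);
  const double bi_mult =
    Rcpp::as<double>(lossw["boundary_as_interior_multiplier"]);

  std::vector<cube> X(n);
  std::vector<imat> Y(n);
  for (int i = 0; i < n; ++i) {
    X[i] = list_to_cube(tiles[i]);
    Y[i] = Rcpp::as<imat>(labels[i]);
  }
  std::mt19937 rng(seed);
  std::normal_distribution<double> gauss(0.0, 1.0);
  std::uniform_real_distribution<double> unif(-1.0, 1.0);
  std::uniform_int_distribution<int> rot(0, 3), coin(0, 1);

  // Adam state over all conv layers + count head
  auto ls = net.layers();
  std::vector<mat> mW(ls.size()), vW(ls.size());
  std::vector<rowvec> mB(ls.size()), vB(ls.size());
  for (size_t i = 0; i < ls.size(); ++i) {
    mW[i].zeros(ls[i]->W.n_rows, ls[i]->W.n_cols);
    vW[i] = mW[i];
    mB[i].zeros(ls[i]->b.n_elem); vB[i] = mB[i];
  }
  vec mC(net.countW.n_elem, fill::zeros), vC = mC;
  double mCb = 0, vCb = 0;
  const double b1 = 0.9, b2 = 0.999, adam_eps = 1e-8;
  long step = 0;

  std::vector<int> order(n);
  for (int i = 0; i < n; ++i) order[i] = i;

  Rcpp::NumericMatrix history(epochs, 6); // total, ce, jacc, count, auto, reg
  Rcpp::colnames(history) = Rcpp::CharacterVector::create(
    "total", "ce", "jacc", "count", "auto", "reg");

  for (int ep = 0; ep < epochs; ++ep) {
    std::shuffle(order.begin(), order.end(), rng);
    double sum_tot = 0, sum_ce = 0, sum_j = 0, sum_c = 0, sum_a = 0;
    int seen = 0;
    for (int start = 0; start < n; start += batch) {
      const int bend = std::min(n, start + batch);
      const int bsz = bend - start;
      net.zero_grad();
      for (int bi = start; bi < bend; ++bi) {
        cube x = X[order[bi]];
        imat y = Y[order[bi]];
        double ct = counts[order[bi]];
        if (augment) {
          const int k = rot(rng);
          if (k) {
            for (uword c = 0; c < x.n_slices; ++c) rot90_mat(x.slice(c), k);
            rot90_imat(y, k);
          }
          if (coin(rng)) { // horizontal flip
            for (uword c = 0; c < x.n_slices; ++c)
              x.slice(c) = fliplr(x.slice(c));
            y = fliplr(y);
          }
          if (coin(rng)) { // vertical flip
            for (uword c = 0; c < x.n_slices; ++c)
              x.slice(c) = flipud(x.slice(c));
            y = flipud(y);
          }
          if (aug_noise > 0)
            for (uword i2 = 0; i2 < x.n_elem; ++i2)
              x(i2) += aug_noise * gauss(rng);
          if (aug_shift > 0) x += aug_shift * unif(rng);
        }
        double count; cube recon;
        cube probs = net.forward(x, count, recon);
        cube dlogits, drecon; double dcount;
        LossParts L = loss_and_grads(probs, y, count, ct, recon, x,
                                     classW, bi_mult, alpha, lc, la,
                                     dlogits, dcount, drecon);
        net.backward(dlogits, dcount, drecon);
        sum_ce += L.ce; sum_j += L.jacc; sum_c += L.count; sum_a += L.autoe;
        ++seen;
      }
      // mean gradient over batch + L2 term, then Adam
      ++step;
      const double corr1 = 1.0 - std::pow(b1, (double)step);
      const double corr2 = 1.0 - std::pow(b2, (double)step);
      for (size_t i = 0; i < ls.size(); ++i) {
        mat g = ls[i]->dW / bsz + 2.0 * beta * ls[i]->W;
        rowvec gb = ls[i]->db / bsz;
        mW[i] = b1 * mW[i] + (1 - b1) * g;
        vW[i] = b2 * vW[i] + (1 - b2) * square(g);
        mB[i] = b1 * mB[i] + (1 - b1) * gb;
        vB[i] = b2 * vB[i] + (1 - b2) * square(gb);
        ls[i]->W -= lr * (mW[i] / corr1) / (sqrt(vW[i] / corr2) + adam_eps);
        ls[i]->b -= lr * (mB[i] / corr1) / (sqrt(vB[i] / corr2) + adam_eps);
      }
      vec gc = net.dcountW / bsz + 2.0 * beta * net.countW;
      const double gcb = net.dcountB / bsz;
      mC = b1 * mC + (1 - b1) * gc;
      vC = b2 * vC + (1 - b2) * square(gc);
      mCb = b1 * mCb + (1 - b1) * gcb;
      vCb = b2 * vCb + (1 - b2) * gcb * gcb;
      net.countW -= lr * (mC / corr1) / (sqrt(vC / corr2) + adam_eps);
      net.countB -= lr * (mCb / corr1) / (std::sqrt(vCb / corr2) + adam_eps);
    }
    const double reg = net.l2();
    history(ep, 1) = sum_ce / seen;
    history(ep, 2) = sum_j / seen;
    history(ep, 3) = sum_c / seen;
    history(ep, 4) = sum_a / seen;
    history(ep, 5) = reg;
    history(ep, 0) = history(ep, 1) + alpha * history(ep, 2) +
                     lc * history(ep, 3) + la * history(ep, 4) + beta * reg;
    if (ep % 10 == 9) Rcpp::checkUserInterrupt();
  }
  return Rcpp::List::create(
    Rcpp::Named("model") = net_to_list(net),
    Rcpp::Named("history") = history);
}
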