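// Single-encoder, dual-decoder 2D U-Net for dural-sac segmentation, with
// hand-written forward/backward passes and an Adam optimizer.
//
// Activation layout: one arma::fmat per image, (H*W) rows x C columns,
// pixels column-major with H fastest (matching R matrices).  Batch = a
// vector of such matrices; batch normalization statistics are taken across
// the whole batch.  Convolutions are 3x3 same-padding via im2col + SGEMM.
//
// Decoder A grows feature maps by 2x2 stride-2 transposed convolution;
// decoder B by fixed nearest-neighbour interpolation followed by a 3x3
// convolution.  Both share the encoder's skip connections (concatenation).
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;
using arma::fmat;
using arma::frowvec;
using arma::uvec;

typedef std::vector<fmat> Batch;

static const float BN_EPS = 1e-5f;
static const float BN_MOM = 0.1f;

struct Par {
  fmat W, g, m, v;
  void init(int r, int c) {
    W.zeros(r, c); g.zeros(r, c); m.zeros(r, c); v.zeros(r, c);
  }
};

// ---------------------------------------------------------------- conv 3x3
// Weight matrix: (9*cin) x cout, row index = cin*9 + o where the offset
// o = (dr+1) + 3*(dc+1), dr/dc in {-1,0,1} (dr along rows/H).
static void im2col3(const fmat& X, int H, int W, fmat& col) {
  const int cin = X.n_cols;
  col.zeros((size_t)H * W, (size_t)9 * cin);
  for (int c = 0; c < cin; ++c) {
    const float* src = X.colptr(c);
    for (int dc = -1; dc <= 1; ++dc)
      for (int dr = -1; dr <= 1; ++dr) {
        int o = (dr + 1) + 3 * (dc + 1);
        float* dst = col.colptr((size_t)c * 9 + o);
        for (int w = 0; w < W; ++w) {
          int ws = w + dc;
          if (ws < 0 || ws >= W) continue;
          int r0 = std::max(0, -dr), r1 = H - 1 - std::max(0, dr);
          if (r1 < r0) continue;
          std::memcpy(dst + (size_t)w * H + r0,
                      src + (size_t)ws * H + r0 + dr,
                      sizeof(float) * (r1 - r0 + 1));
        }
      }
  }
}

// scatter-add of a column matrix back to image layout (adjoint of im2col3)
static void col2im3(const fmat& col, int H, int W, fmat& dX) {
  const int cin = dX.n_cols;
  for (int c = 0; c < cin; ++c) {
    float* dst = dX.colptr(c);
    for (int dc = -1; dc <= 1; ++dc)
      for (int dr = -1; dr <= 1; ++dr) {
        int o = (dr + 1) + 3 * (dc + 1);
        const float* src = col.colptr((size_t)c * 9 + o);
        for (int w = 0; w < W; ++w) {
          int ws = w + dc;
          if (ws < 0 || ws >= W) continue;
          int r0 = std::max(0, -dr), r1 = H - 1 - std::max(0, dr);
          for (int r = r0; r <= r1; ++r)
            dst[(size_t)ws * H + r + dr] += src[(size_t)w * H + r];
        }
      }
  }
}

static void conv3_fwd(const Batch& X, Par& P, int H, int W, Batch& Y) {
  fmat col;
  Y.resize(X.size());
  for (size_t n = 0; n < X.size(); ++n) {
    im2col3(X[n], H, W, col);
    Y[n] = col * P.W;
  }
}

// backward rebuilds im2col from the stored layer input (saves tape memory)
static void conv3_bwd(const Batch& X, Par& P, const Batch& dY, int H, int W,
                      Batch* dX) {
  fmat col;
  if (dX) {
    dX->resize(X.size());
    for (size_t n = 0; n < X.size(); ++n)
      (*dX)[n].zeros(X[n].n_rows, X[n].n_cols);
  }
  for (size_t n = 0; n < X.size(); ++n) {
    im2col3(X[n], H, W, col);
    P.g += col.t() * dY[n];
    if (dX) {
      fmat dcol = dY[n] * P.W.t();
      col2im3(dcol, H, W, (*dX)[n]);
    }
  }
}

// ------------------------------------------------------------- batch norm
struct BNPar {
  Par gamma, beta;
  frowvec rmean, rvar;
  void init(int c) {
    gamma.init(1, c); gamma.W.ones();
    beta.init(1, c);
    rmean.zeros(c); rvar.ones(c);
  }
};

struct BNTape {
  Batch xhat;
  frowvec invstd;
};

static void bn_fwd(const Batch& X, BNPar& P, bool train, Batch& Y, BNTape& T) {
  const int C = X[0].n_cols;
  frowvec mean(C), var(C);
  if (train) {
    double M = 0;
    arma::rowvec s(C, arma::fill::zeros), s2(C, arma::fill::zeros);
    for (const fmat& x : X) {
      s += arma::conv_to<arma::rowvec>::from(arma::sum(x, 0));
      s2 += arma::conv_to<arma::rowvec>::from(arma::sum(arma::square(x), 0));
      M += x.n_rows;
    }
    mean = arma::conv_to<frowvec>::from(s / M);
    var = arma::conv_to<frowvec>::from(s2 / M) - arma::square(mean);
    var.transform([](float v) { return v < 0 ? 0.0f : v; });
    P.rmean = (1 - BN_MOM) * P.rmean + BN_MOM * mean;
    P.rvar = (1 - BN_MOM) * P.rvar + BN_MOM * var;
  } else {
    mean = P.rmean;
    var = P.rvar;
  }
  T.invstd = 1.0f / arma::sqrt(var + BN_EPS);
  T.xhat.resize(X.size());
  Y.resize(X.size());
  const frowvec g = P.gamma.W.row(0), b = P.beta.W.row(0);
  for (size_t n = 0; n < X.size(); ++n) {
    T.xhat[n] = X[n];
    T.xhat[n].each_row() -= mean;
    T.xhat[n].each_row() %= T.invstd;
    Y[n] = T.xhat[n];
    Y[n].each_row() %= g;
    Y[n].each_row() += b;
  }
}

static void bn_bwd(BNPar& P, const BNTape& T, const Batch& dY, Batch& dX) {
  const int C = dY[0].n_cols;
  const frowvec g = P.gamma.W.row(0);
  double M = 0;
  frowvec sdx(C, arma::fill::zeros), sdxx(C, arma::fill::zeros);
  for (size_t n = 0; n < dY.size(); ++n) {
    P.gamma.g += arma::sum(dY[n] % T.xhat[n], 0);
    P.beta.g += arma::sum(dY[n], 0);
    sdx += arma::sum(dY[n], 0);
    sdxx += arma::sum(dY[n] % T.xhat[n], 0);
    M += dY[n].n_rows;
  }
  dX.resize(dY.size());
  const frowvec k = g % T.invstd / (float)M;
  for (size_t n = 0; n < dY.size(); ++n) {
    dX[n] = (float)M * dY[n];
    dX[n].each_row() -= sdx;
    fmat tmp = T.xhat[n];
    tmp.each_row() %= sdxx;
    dX[n] -= tmp;
    dX[n].each_row() %= k;
  }
}

// ------------------------------------------------------------- relu / pool
static void relu_fwd(Batch& X) {
  for (fmat& x : X) x.transform([](float v) { return v > 0 ? v : 0.0f; });
}
static void relu_bwd(const Batch& A, Batch& dA) { // A = relu output
  for (size_t n = 0; n < A.size(); ++n)
    dA[n] %= arma::conv_to<fmat>::from(A[n] > 0);
}

struct PoolTape { std::vector<arma::umat> idx; };

static void pool_fwd(const Batch& X, int H, int W, Batch& Y, PoolTape& T) {
  const int H2 = H / 2, W2 = W / 2, C = X[0].n_cols;
  Y.resize(X.size());
  T.idx.resize(X.size());
  for (size_t n = 0; n < X.size(); ++n) {
    Y[n].set_size((size_t)H2 * W2, C);
    T.idx[n].set_size((size_t)H2 * W2, C);
    for (int c = 0; c < C; ++c) {
      const float* src = X[n].colptr(c);
      float* dst = Y[n].colptr(c);
      arma::uword* ix = T.idx[n].colptr(c);
      for (int w2 = 0; w2 < W2; ++w2)
        for (int r2 = 0; r2 < H2; ++r2) {
          size_t base = (size_t)(2 * w2) * H + 2 * r2;
          size_t cand[4] = {base, base + 1, base + H, base + H + 1};
          int bi = 0;
          for (int t = 1; t < 4; ++t)
            if (src[cand[t]] > src[cand[bi]]) bi = t;
          dst[(size_t)w2 * H2 + r2] = src[cand[bi]];
          ix[(size_t)w2 * H2 + r2] = cand[bi];
        }
    }
  }
}

static void pool_bwd(const PoolTape& T, const Batch& dY, int H, int W, Batch& dX) {
  const int C = dY[0].n_cols;
  dX.resize(dY.size());
  for (size_t n = 0; n < dY.size(); ++n) {
    dX[n].zeros((size_t)H * W, C);
    for (int c = 0; c < C; ++c) {
      float* dst = dX[n].colptr(c);
      const float* src = dY[n].colptr(c);
      const arma::uword* ix = T.idx[n].colptr(c);
      for (size_t p = 0; p < dY[n].n_rows; ++p) dst[ix[p]] += src[p];
    }
  }
}

// ----------------------------------------------------------- double conv
struct DoubleConv {
  Par c1, c2;
  BNPar bn1, bn2;
  int cin, cout;
  void init(int in, int out) {
    cin = in; cout = out;
    c1.init(9 * in, out);
    c2.init(9 * out, out);
    bn1.init(out);
    bn2.init(out);
  }
};

struct DCTape {
  Batch x, a1; // input; relu(bn1) = conv2 input
  BNTape t1, t2;
  Batch out;   // relu(bn2) -- kept because relu_bwd needs it
};

static void dc_fwd(DoubleConv& L, const Batch& X, int H, int W, bool train,
                   DCTape& T) {
  T.x = X;
  Batch y;
  conv3_fwd(X, L.c1, H, W, y);
  Batch z;
  bn_fwd(y, L.bn1, train, z, T.t1);
  relu_fwd(z);
  T.a1 = z;
  conv3_fwd(z, L.c2, H, W, y);
  bn_fwd(y, L.bn2, train, z, T.t2);
  relu_fwd(z);
  T.out = z;
}

static void dc_bwd(DoubleConv& L, DCTape& T, Batch& dOut, int H, int W,
                   Batch* dX) {
  relu_bwd(T.out, dOut);
  Batch d1;
  bn_bwd(L.bn2, T.t2, dOut, d1);
  Batch d2;
  conv3_bwd(T.a1, L.c2, d1, H, W, &d2);
  relu_bwd(T.a1, d2);
  bn_bwd(L.bn1, T.t1, d2, d1);
  conv3_bwd(T.x, L.c1, d1, H, W, dX);
}

// --------------------------------------------------------------- up stages
// index maps child(2H x 2W) <- parent(H x W) for offset o = di + 2*dj
static void up_maps(int H, int W, std::vector<uvec>& maps) {
  maps.assign(4, uvec((size_t)H * W));
  for (int dj = 0; dj < 2; ++dj)
    for (int di = 0; di < 2; ++di) {
      uvec& m = maps[di + 2 * dj];
      for (int w = 0; w < W; ++w)
        for (int r = 0; r < H; ++r)
          m[(size_t)w * H + r] = (size_t)(2 * w + dj) * (2 * H) + 2 * r + di;
    }
}

struct UpStage {
  bool transposed;  // decoder A: transposed conv; decoder B: NN upsample+conv
  Par up, upb;      // A: (cin x 4*cout) + bias; B: (9*cin x cout) + bias
  DoubleConv dc;    // 2*cout -> cout
  int cin, cout;
  void init(bool tr, int in, int out) {
    transposed = tr; cin = in; cout = out;
    if (tr) up.init(in, 4 * out); else up.init(9 * in, out);
    upb.init(1, out);
    dc.init(2 * out, out);
  }
};

struct UpTape {
  Batch x;    // stage input (parent resolution)
  Batch nnup; // decoder B only: upsampled input (child resolution)
  Batch cat;  // concatenated [skip, up]
  DCTape dct;
};

static void up_fwd(UpStage& L, const Batch& X, const Batch& skip, int H,
                   int W, const std::vector<uvec>& maps, bool train,
                   UpTape& T) {
  // H, W: child (output) resolution; X at (H/2, W/2)
  T.x = X;
  Batch up(X.size());
  if (L.transposed) {
    for (size_t n = 0; n < X.size(); ++n) {
      up[n].set_size((size_t)H * W, L.cout);
      up[n].each_row() = L.upb.W.row(0);
      for (int o = 0; o < 4; ++o)
        up[n].rows(maps[o]) += X[n] * L.up.W.cols(o * L.cout, (o + 1) * L.cout - 1);
    }
  } else {
    T.nnup.resize(X.size());
    for (size_t n = 0; n < X.size(); ++n) {
      T.nnup[n].set_size((size_t)H * W, L.cin);
      for (int o = 0; o < 4; ++o) T.nnup[n].rows(maps[o]) = X[n];
    }
    conv3_fwd(T.nnup, L.up, H, W, up);
    for (size_t n = 0; n < up.size(); ++n) up[n].each_row() += L.upb.W.row(0);
  }
  T.cat.resize(X.size());
  for (size_t n = 0; n < X.size(); ++n)
    T.cat[n] = arma::join_rows(skip[n], up[n]);
  dc_fwd(L.dc, T.cat, H, W, train, T.dct);
}

static void up_bwd(UpStage& L, UpTape& T, Batch& dOut, int H, int W,
                   const std::vector<uvec>& maps, Batch& dX, Batch& dSkip) {
  Batch dcat;
  dc_bwd(L.dc, T.dct, dOut, H, W, &dcat);
  const int cs = T.cat[0].n_cols - (L.transposed ? L.cout : L.cout);
  // skip channels come first
  Batch dup(dcat.size());
  dSkip.resize(dcat.size());
  for (size_t n = 0; n < dcat.size(); ++n) {
    dSkip[n] = dcat[n].cols(0, cs - 1);
    dup[n] = dcat[n].cols(cs, dcat[n].n_cols - 1);
  }
  dX.resize(dup.size());
  if (L.transposed) {
    for (size_t n = 0; n < dup.size(); ++n) {
      L.upb.g += arma::sum(dup[n], 0);
      dX[n].zeros(T.x[n].n_rows, L.cin);
      for (int o = 0; o < 4; ++o) {
        fmat dslice = dup[n].rows(maps[o]);
        L.up.g.cols(o * L.cout, (o + 1) * L.cout - 1) += T.x[n].t() * dslice;
        dX[n] += dslice * L.up.W.cols(o * L.cout, (o + 1) * L.cout - 1).t();
      }
    }
  } else {
    for (size_t n = 0; n < dup.size(); ++n) L.upb.g += arma::sum(dup[n], 0);
    Batch dnn;
    conv3_bwd(T.nnup, L.up, dup, H, W, &dnn);
    for (size_t n = 0; n < dnn.size(); ++n) {
      dX[n].zeros(T.x[n].n_rows, L.cin);
      for (int o = 0; o < 4; ++o) dX[n] += dnn[n].rows(maps[o]);
    }
  }
}

// ------------------------------------------------------------------ model
struct Decoder {
  std::vector<UpStage> st; // from deepest to shallowest
  Par fin, finb;           // 1x1 conv to n_classes
};

struct DDUNet {
  int H, W, D, base, nc;
  std::vector<DoubleConv> enc;
  DoubleConv bott;
  Decoder A, B;
  std::vector<std::vector<uvec>> maps; // per decoder stage child maps
  long t = 0;              // Adam step counter

  std::vector<Par*> pars;
  std::vector<std::string> parnames;
  std::vector<BNPar*> bns;
  std::vector<std::string> bnnames;

  void reg(Par* p, const std::string& nm) { pars.push_back(p); parnames.push_back(nm); }
  void regbn(BNPar* b, const std::string& nm) {
    reg(&b->gamma, nm + ".gamma");
    reg(&b->beta, nm + ".beta");
    bns.push_back(b); bnnames.push_back(nm);
  }
  void regdc(DoubleConv* d, const std::string& nm) {
    reg(&d->c1, nm + ".conv1"); regbn(&d->bn1, nm + ".bn1");
    reg(&d->c2, nm + ".conv2"); regbn(&d->bn2, nm + ".bn2");
  }

  DDUNet(int H_, int W_, int D_, int base_, int nc_, int seed) {
    H = H_; W = W_; D = D_; base = base_; nc = nc_;
    enc.resize(D);
    int cin = 1;
    for (int d = 0; d < D; ++d) {
      enc[d].init(cin, base << d);
      cin = base << d;
    }
    bott.init(base << (D - 1), base << D);
    for (Decoder* dec : {&A, &B}) {
      bool tr = (dec == &A);
      dec->st.resize(D);
      for (int j = 0; j < D; ++j) {
        int d = D - 1 - j; // spatial stage of the output
        dec->st[j].init(tr, base << (d + 1), base << d);
      }
      dec->fin.init(base, nc);
      dec->finb.init(1, nc);
    }
    maps.resize(D);
    for (int j = 0; j < D; ++j) {
      int d = D - 1 - j;
      up_maps(H >> (d + 1), W >> (d + 1), maps[j]);
    }
    for (int d = 0; d < D; ++d) regdc(&enc[d], "enc" + std::to_string(d));
    regdc(&bott, "bottleneck");
    for (Decoder* dec : {&A, &B}) {
      std::string p = (dec == &A) ? "decA." : "decB.";
      for (int j = 0; j < D; ++j) {
        reg(&dec->st[j].up, p + "up" + std::to_string(j));
        reg(&dec->st[j].upb, p + "up" + std::to_string(j) + ".bias");
        regdc(&dec->st[j].dc, p + "dc" + std::to_string(j));
      }
      reg(&dec->fin, p + "final");
      reg(&dec->finb, p + "final.bias");
    }
    init_weights(seed);
  }

  void init_weights(int seed) {
    std::mt19937 rng(seed);
    std::normal_distribution<float> N(0.0f, 1.0f);
    for (size_t i = 0; i < pars.size(); ++i) {
      Par* p = pars[i];
      const std::string& nm = parnames[i];
      if (nm.find("bias") != std::string::npos ||
          nm.find("gamma") != std::string::npos ||
          nm.find("beta") != std::string::npos)
        continue; // keep 0 / 1
      float fan_in = p->W.n_rows;
      if (nm.find("up") != std::string::npos && nm.find("decA") != std::string::npos &&
          nm.find("dc") == std::string::npos)
        fan_in = p->W.n_rows * 4.0f; // transposed conv: cin x 4*cout
      float sd = std::sqrt(2.0f / fan_in);
      for (arma::uword k = 0; k < p->W.n_elem; ++k) p->W[k] = sd * N(rng);
    }
  }

  // ---- forward --------------------------------------------------------
  struct Tape {
    std::vector<DCTape> encT;
    std::vector<PoolTape> poolT;
    DCTape bottT;
    std::vector<UpTape> aT, bT;
    Batch skips[8]; // encoder outputs per stage
    Batch logitsA, logitsB, probA, probB;
    Batch finInA, finInB;
  };

  void forward(const Batch& X, bool train, bool runA, bool runB, Tape& T) {
    T.encT.resize(D);
    T.poolT.resize(D);
    Batch cur = X;
    for (int d = 0; d < D; ++d) {
      dc_fwd(enc[d], cur, H >> d, W >> d, train, T.encT[d]);
      T.skips[d] = T.encT[d].out;
      pool_fwd(T.encT[d].out, H >> d, W >> d, cur, T.poolT[d]);
    }
    dc_fwd(bott, cur, H >> D, W >> D, train, T.bottT);
    if (runA) dec_fwd(A, T.bottT.out, T, T.aT, T.finInA, T.logitsA, T.probA, train);
    if (runB) dec_fwd(B, T.bottT.out, T, T.bT, T.finInB, T.logitsB, T.probB, train);
  }

  void dec_fwd(Decoder& dec, const Batch& bout, Tape& T,
               std::vector<UpTape>& uT, Batch& finIn, Batch& logits,
               Batch& prob, bool train) {
    uT.resize(D);
    Batch cur = bout;
    for (int j = 0; j < D; ++j) {
      int d = D - 1 - j;
      up_fwd(dec.st[j], cur, T.skips[d], H >> d, W >> d, maps[j], train, uT[j]);
      cur = uT[j].dct.out;
    }
    finIn = cur;
    logits.resize(cur.size());
    prob.resize(cur.size());
    for (size_t n = 0; n < cur.size(); ++n) {
      logits[n] = cur[n] * dec.fin.W;
      logits[n].each_row() += dec.finb.W.row(0);
      fmat z = logits[n];
      arma::fvec mx = arma::max(z, 1);
      z.each_col() -= mx;
      z = arma::exp(z);
      arma::fvec s = arma::sum(z, 1);
      z.each_col() /= s;
      prob[n] = z;
    }
  }

  // ---- backward -------------------------------------------------------
  void backward(Tape& T, Batch& dLogA, Batch& dLogB) {
    Batch dBott;
    Batch dSkips[8];
    dec_bwd(A, T, T.aT, T.finInA, dLogA, dBott, dSkips, false);
    dec_bwd(B, T, T.bT, T.finInB, dLogB, dBott, dSkips, true);
    Batch d = dBott;
    Batch dPrev;
    dc_bwd(bott, T.bottT, d, H >> D, W >> D, &dPrev);
    for (int dd = D - 1; dd >= 0; --dd) {
      Batch dPooled;
      pool_bwd(T.poolT[dd], dPrev, H >> dd, W >> dd, dPooled);
      for (size_t n = 0; n < dPooled.size(); ++n) dPooled[n] += dSkips[dd][n];
      dc_bwd(enc[dd], T.encT[dd], dPooled, H >> dd, W >> dd,
             dd > 0 ? &dPrev : nullptr);
    }
  }

  void dec_bwd(Decoder& dec, Tape& T, std::vector<UpTape>& uT, Batch& finIn,
               Batch& dLog, Batch& dBott, Batch* dSkips, bool accumulate) {
    Batch dcur(dLog.size());
    for (size_t n = 0; n < dLog.size(); ++n) {
      dec.fin.g += finIn[n].t() * dLog[n];
      dec.finb.g += arma::sum(dLog[n], 0);
      dcur[n] = dLog[n] * dec.fin.W.t();
    }
    for (int j = D - 1; j >= 0; --j) {
      int d = D - 1 - j;
      Batch dX, dSkip;
      up_bwd(dec.st[j], uT[j], dcur, H >> d, W >> d, maps[j], dX, dSkip);
      if (!accumulate)
        dSkips[d] = dSkip;
      else
        for (size_t n = 0; n < dSkip.size(); ++n) dSkips[d][n] += dSkip[n];
      dcur = dX;
    }
    if (!accumulate)
      dBott = dcur;
    else
      for (size_t n = 0; n < dcur.size(); ++n) dBott[n] += dcur[n];
  }

  void zero_grad() {
    for (Par* p : pars) p->g.zeros();
  }

  void adam(float lr, float b1, float b2, float eps) {
    ++t;
    float c1 = 1.0f - std::pow(b1, (float)t);
    float c2 = 1.0f - std::pow(b2, (float)t);
    for (Par* p : pars) {
      p->m = b1 * p->m + (1 - b1) * p->g;
      p->v = b2 * p->v + (1 - b2) * arma::square(p->g);
      p->W -= lr * (p->m / c1) / (arma::sqrt(p->v / c2) + eps);
    }
  }
};

// ------------------------------------------------------------ R interface
static Batch r_to_batch(List imgs) {
  Batch out(imgs.size());
  for (int n = 0; n < imgs.size(); ++n) {
    NumericMatrix m = imgs[n];
    out[n] = arma::conv_to<fmat>::from(
        arma::vec(m.begin(), m.size(), false));
    out[n].reshape(m.size(), 1);
  }
  return out;
}

// [[Rcpp::export]]
SEXP nn_create(int H, int W, int depth, int base, int nclasses, int seed) {
  XPtr<DDUNet> p(new DDUNet(H, W, depth, base, nclasses, seed), true);
  return p;
}

// [[Rcpp::export]]
double nn_nparams(SEXP ptr) {
  XPtr<DDUNet> m(ptr);
  double n = 0;
  for (Par* p : m->pars) n += p->W.n_elem;
  return n;
}

// [[Rcpp::export]]
List nn_get_params(SEXP ptr) {
  XPtr<DDUNet> m(ptr);
  List out;
  for (size_t i = 0; i < m->pars.size(); ++i) {
    fmat& W = m->pars[i]->W;
    NumericMatrix r(W.n_rows, W.n_cols);
    for (arma::uword k = 0; k < W.n_elem; ++k) r[k] = W[k];
    out[m->parnames[i]] = r;
  }
  for (size_t i = 0; i < m->bns.size(); ++i) {
    BNPar* b = m->bns[i];
    out[m->bnnames[i] + ".rmean"] =
        NumericVector(b->rmean.begin(), b->rmean.end());
    out[m->bnnames[i] + ".rvar"] =
        NumericVector(b->rvar.begin(), b->rvar.end());
  }
  return out;
}

// [[Rcpp::export]]
void nn_set_params(SEXP ptr, List params) {
  XPtr<DDUNet> m(ptr);
  for (size_t i = 0; i < m->pars.size(); ++i) {
    NumericMatrix r = params[m->parnames[i]];
    fmat& W = m->pars[i]->W;
    if ((int)W.n_rows != r.nrow() || (int)W.n_cols != r.ncol())
      stop("parameter shape mismatch for %s", m->parnames[i].c_str());
    for (arma::uword k = 0; k < W.n_elem; ++k) W[k] = r[k];
  }
  for (size_t i = 0; i < m->bns.size(); ++i) {
    NumericVector rm = params[m->bnnames[i] + ".rmean"];
    NumericVector rv = params[m->bnnames[i] + ".rvar"];
    for (int k = 0; k < rm.size(); ++k) m->bns[i]->rmean[k] = rm[k];
    for (int k = 0; k < rv.size(); ++k) m->bns[i]->rvar[k] = rv[k];
  }
}

// forward pass; decoder = 0 (both), 1 (A only), 2 (B only).
// Returns per-image probability matrices (H*W x n_classes).
// [[Rcpp::export]]
List nn_forward(SEXP ptr, List imgs, bool train, int decoder) {
  XPtr<DDUNet> m(ptr);
  Batch X = r_to_batch(imgs);
  for (const fmat& x : X)
    if ((int)x.n_rows != m->H * m->W)
      stop("image size does not match the configured %d x %d input", m->H, m->W);
  DDUNet::Tape T;
  // train=TRUE here only selects batch statistics; no parameters change
  frowvec keep_rm; // protect running stats from a pure forward call
  std::vector<frowvec> rms, rvs;
  for (BNPar* b : m->bns) { rms.push_back(b->rmean); rvs.push_back(b->rvar); }
  m->forward(X, train, decoder != 2, decoder != 1, T);
  for (size_t i = 0; i < m->bns.size(); ++i) {
    m->bns[i]->rmean = rms[i];
    m->bns[i]->rvar = rvs[i];
  }
  auto wrap_probs = [&](Batch& P) {
    List out(P.size());
    for (size_t n = 0; n < P.size(); ++n) {
      NumericMatrix r(P[n].n_rows, P[n].n_cols);
      for (arma::uword k = 0; k < P[n].n_elem; ++k) r[k] = P[n][k];
      out[n] = r;
    }
    return out;
  };
  List out;
  if (decoder != 2) out["A"] = wrap_probs(T.probA);
  if (decoder != 1) out["B"] = wrap_probs(T.probB);
  return out;
}

// One optimization step on a mixed batch.  Labeled images contribute
// per-decoder pixel-averaged cross-entropy; unlabeled images contribute the
// L2 consistency term between the two decoders' probability maps (squared
// differences summed over class channels, averaged over pixels).
// [[Rcpp::export]]
List nn_train_step(SEXP ptr, List lab_imgs, List lab_masks, List unlab_imgs,
                   double lambda, double lr, double beta1, double beta2,
                   double adam_eps) {
  XPtr<DDUNet> m(ptr);
  Batch XL = r_to_batch(lab_imgs);
  Batch XU = r_to_batch(unlab_imgs);
  const int nl = XL.size(), nu = XU.size();
  if (nl == 0) stop("labeled batch is empty");
  Batch X = XL;
  X.insert(X.end(), XU.begin(), XU.end());
  DDUNet::Tape T;
  m->forward(X, true, true, true, T);
  const size_t HW = (size_t)m->H * m->W;
  const int nc = m->nc;
  Batch dLogA(X.size()), dLogB(X.size());
  double sup = 0, cons = 0;
  const float clamp = 1e-7f;
  for (int n = 0; n < nl; ++n) {
    IntegerVector y = lab_masks[n];
    fmat YA(HW, nc, arma::fill::zeros);
    for (size_t p = 0; p < HW; ++p) YA(p, y[p]) = 1.0f;
    for (int dec = 0; dec < 2; ++dec) {
      fmat& P = dec == 0 ? T.probA[n] : T.probB[n];
      double ce = 0;
      for (size_t p = 0; p < HW; ++p)
        ce -= std::log(std::max(P(p, y[p]), clamp));
      sup += ce / HW;
      (dec == 0 ? dLogA : dLogB)[n] = (P - YA) / (float)(HW * nl);
    }
  }
  sup /= nl;
  if (nu > 0 && lambda > 0) {
    for (int n = 0; n < nu; ++n) {
      fmat& PA = T.probA[nl + n];
      fmat& PB = T.probB[nl + n];
      fmat diff = PA - PB;
      cons += arma::accu(arma::square(diff)) / HW;
      fmat g = (float)(2.0 * lambda / (HW * (double)nu)) * diff;
      // through softmax of each decoder
      arma::fvec sA = arma::sum(g % PA, 1);
      fmat dA = PA % (g.each_col() - sA);
      fmat ng = -g;
      arma::fvec sB = arma::sum(ng % PB, 1);
      fmat dB = PB % (ng.each_col() - sB);
      dLogA[nl + n] = dA;
      dLogB[nl + n] = dB;
    }
    cons /= nu;
  } else {
    for (int n = 0; n < nu; ++n) {
      dLogA[nl + n].zeros(HW, nc);
      dLogB[nl + n].zeros(HW, nc);
    }
    if (nu > 0) { // still report the monitored consistency value
      for (int n = 0; n < nu; ++n)
        cons += arma::accu(arma::square(T.probA[nl + n] - T.probB[nl + n])) / HW;
      cons /= nu;
    }
  }
  for (int n = 0; n < nl; ++n) {
    if (dLogA[n].n_elem == 0) dLogA[n].zeros(HW, nc);
    if (dLogB[n].n_elem == 0) dLogB[n].zeros(HW, nc);
  }
  m->zero_grad();
  m->backward(T, dLogA, dLogB);
  m->adam(lr, beta1, beta2, adam_eps);
  return List::create(_["supervised"] = sup, _["consistency"] = cons);
}

// [[Rcpp::export]]
List nn_config(SEXP ptr) {
  XPtr<DDUNet> m(ptr);
  return List::create(_["H"] = m->H, _["W"] = m->W, _["depth"] = m->D,
                      _["base_channels"] = m->base, _["n_classes"] = m->nc);
}
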