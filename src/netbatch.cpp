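// Fused batched network engine.
//
// Runs the entire network — input batch normalization, branch stacks,
// concatenation, mainstream, classifier head, softmax cross-entropy and the
// full backward pass — for one minibatch in single precision, mirroring the
// pure-R reference layers in R/engine.R (which remain the oracle in the
// test suite). Feature maps are arma::fmat of shape (C, T*N*V); column
// t + T*(n + N*v) holds the channel vector of frame t of sample n at joint
// v, so each joint spans T*N contiguous columns (graph contractions are
// sub-matrix axpys) and temporal convolutions walk contiguous T-column
// panels per (sample, joint).
//
// Every convolution output is standardized per channel: in training mode
// with the batch moments (true batch normalization; the moments are
// returned so R can maintain the running statistics used at evaluation),
// in eval mode with the running moments. The layer bias is applied after
// the standardization, and each site's pre-rectifier normalized map is kept
// so the exact batch-norm backward (including the batch-moment coupling
// terms at rectifier-masked positions) can be evaluated.

// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>
#include <cstring>
using namespace Rcpp;

namespace {

struct Edge {
  int u, v;
  float w;
};

struct Site {
  arma::fvec istdState, shiftState; // eval-mode scale/shift (bias folded)
  arma::fvec istdUsed;              // scale actually applied this batch
  arma::vec bmean, bvar;            // batch moments (train mode)
};

struct TCLayer {
  arma::fmat Wd, Wp; // separable: depthwise (C x k), pointwise (C x C)
  arma::fcube W;     // standard: (C2 x C x k)
  arma::fvec b;
  arma::fmat dWd, dWp;
  arma::fcube dW;
  arma::fvec db;
  Site site;
  std::string prefix;
};

struct Block {
  int cin, cout, stride, kernel, depth, Tin, Tout, Cr, K;
  bool sep, att, needProj;
  std::string prefix;
  arma::fmat Wcat; // horizontally stacked partition weights, cin x K*cout
  arma::fvec gb;
  std::vector<TCLayer> tc;
  arma::fmat resW;
  arma::fmat aW1, aWt, aWv;
  arma::fvec ab1, abt, abv;
  Site gsite, rsite;
  // gradient accumulators
  arma::fmat dWcat;
  arma::fvec dgb;
  arma::fmat dresW, daW1, daWt, daWv;
  arma::fvec dab1, dabt, dabv;
  // batch caches / buffers (allocated once per call)
  const arma::fmat* outPtr; // block output: &out with attention, &y without
  const arma::fmat* Xin; // borrowed pointer to the previous stage's output
  arma::fmat znG;        // standardized graph-conv output, pre-rectifier
  arma::fmat H;          // rectified copy of znG (next layer's input)
  std::vector<arma::fmat> tcIn, Yd, znT; // znT[j]: inner pre-relu maps
  arma::fmat hLast; // standardized output of the last temporal layer
  arma::fmat rn;    // standardized residual projection
  arma::fmat y;     // post residual-add rectifier (attention gate input)
  arma::fmat out;   // post attention
  arma::fmat Pt, Pv, Zt, Zv, St, Sv; // attention caches
  arma::fmat Zall, dZall;            // graph-conv scratch, K*cout x Tin*N*V
  std::vector<arma::fmat> dXtc;      // temporal backward scratch
  arma::fmat dIn; // gradient buffer handed to the previous stage
  arma::uvec resIdx; // strided input columns read by the residual projection
  arma::fmat resBuf; // gathered input scratch
};

// parameters arrive as doubles and are converted once per call
arma::fmat getMat(const List& params, const std::string& nm) {
  NumericMatrix m = params[nm];
  return arma::conv_to<arma::fmat>::from(
    arma::mat(m.begin(), m.nrow(), m.ncol(), false, true));
}

arma::fvec getVec(const List& params, const std::string& nm) {
  NumericVector v = params[nm];
  return arma::conv_to<arma::fvec>::from(
    arma::vec(v.begin(), v.size(), false, true));
}

arma::fcube getCube(const List& params, const std::string& nm) {
  NumericVector v = params[nm];
  IntegerVector d = v.attr("dim");
  return arma::conv_to<arma::fcube>::from(
    arma::cube(v.begin(), d[0], d[1], d[2], false, true));
}

void initSite(Site& s, const List& state, const std::string& site,
              const arma::fvec& b) {
  NumericVector var = state[site + "var"];
  NumericVector mean = state[site + "mean"];
  const int C = var.size();
  s.istdState.set_size(C);
  s.shiftState.set_size(C);
  for (int c = 0; c < C; ++c) {
    double is = 1.0 / std::sqrt(var[c] + 1e-5);
    s.istdState[c] = (float)is;
    s.shiftState[c] = (float)(b[c] - mean[c] * is);
  }
  s.bmean = arma::vec(C, arma::fill::zeros);
  s.bvar = arma::vec(C, arma::fill::zeros);
}

// standardize a raw conv output in place (+bias, optional rectifier).
// Training mode computes, records and applies the batch moments; eval mode
// applies the running moments.
void siteForward(arma::fmat& x, Site& s, const arma::fvec& b, bool train,
                 bool relu) {
  const int C = x.n_rows;
  if (train) {
    arma::vec sum(C, arma::fill::zeros), sq(C, arma::fill::zeros);
    for (arma::uword j = 0; j < x.n_cols; ++j) {
      const float* p = x.colptr(j);
      for (int c = 0; c < C; ++c) {
        sum[c] += p[c];
        sq[c] += (double)p[c] * p[c];
      }
    }
    double n = (double)x.n_cols;
    s.istdUsed.set_size(C);
    arma::fvec shift(C);
    for (int c = 0; c < C; ++c) {
      double m = sum[c] / n;
      double v = sq[c] / n - m * m;
      if (v < 0) v = 0;
      s.bmean[c] = m;
      s.bvar[c] = v;
      double is = 1.0 / std::sqrt(v + 1e-5);
      s.istdUsed[c] = (float)is;
      shift[c] = (float)(b[c] - m * is);
    }
    for (arma::uword j = 0; j < x.n_cols; ++j) {
      float* p = x.colptr(j);
      for (int c = 0; c < C; ++c) {
        float y = p[c] * s.istdUsed[c] + shift[c];
        p[c] = (relu && y < 0) ? 0.0f : y;
      }
    }
  } else {
    s.istdUsed = s.istdState;
    for (arma::uword j = 0; j < x.n_cols; ++j) {
      float* p = x.colptr(j);
      for (int c = 0; c < C; ++c) {
        float y = p[c] * s.istdState[c] + s.shiftState[c];
        p[c] = (relu && y < 0) ? 0.0f : y;
      }
    }
  }
}

// fused backward through rectifier + bias + standardization site:
// masks dY by (gate > 0), accumulates the bias gradient, and applies the
// full batch-norm backward (coupling terms included), in two sweeps.
// `post` holds the pre-rectifier site output (bias included), so
// xhat = post - b everywhere.
void siteBackwardRelu(arma::fmat& dY, const arma::fmat& gate,
                      const arma::fmat& post, const Site& s,
                      const arma::fvec& b, arma::fvec& db, bool train) {
  const int C = dY.n_rows;
  arma::vec s0(C, arma::fill::zeros), s1(C, arma::fill::zeros),
            s2(C, arma::fill::zeros);
  for (arma::uword j = 0; j < dY.n_cols; ++j) {
    float* g = dY.colptr(j);
    const float* gt = gate.colptr(j);
    const float* q = post.colptr(j);
    for (int c = 0; c < C; ++c) {
      float gv = gt[c] > 0 ? g[c] : 0.0f;
      g[c] = gv;
      s0[c] += gv;
      s1[c] += gv;
      s2[c] += (double)gv * (q[c] - b[c]);
    }
  }
  for (int c = 0; c < C; ++c) db[c] += (float)s0[c];
  if (!train) {
    for (arma::uword j = 0; j < dY.n_cols; ++j) {
      float* g = dY.colptr(j);
      for (int c = 0; c < C; ++c) g[c] *= s.istdUsed[c];
    }
    return;
  }
  double n = (double)dY.n_cols;
  arma::fvec m1(C), m2(C);
  for (int c = 0; c < C; ++c) {
    m1[c] = (float)(s1[c] / n);
    m2[c] = (float)(s2[c] / n);
  }
  for (arma::uword j = 0; j < dY.n_cols; ++j) {
    float* g = dY.colptr(j);
    const float* q = post.colptr(j);
    for (int c = 0; c < C; ++c) {
      g[c] = s.istdUsed[c] * (g[c] - m1[c] - (q[c] - b[c]) * m2[c]);
    }
  }
}

// backward through a standardization site, in place on dY.
// `post` holds the site output (bias included) wherever dY is nonzero, so
// xhat = post - b there; the batch-moment coupling terms are means over all
// positions (masked positions contribute zero because dY is zero there).
void siteBackward(arma::fmat& dY, const arma::fmat& post, const Site& s,
                  const arma::fvec& b, bool train) {
  const int C = dY.n_rows;
  if (!train) {
    for (arma::uword j = 0; j < dY.n_cols; ++j) {
      float* p = dY.colptr(j);
      for (int c = 0; c < C; ++c) p[c] *= s.istdUsed[c];
    }
    return;
  }
  arma::vec s1(C, arma::fill::zeros), s2(C, arma::fill::zeros);
  for (arma::uword j = 0; j < dY.n_cols; ++j) {
    const float* g = dY.colptr(j);
    const float* q = post.colptr(j);
    for (int c = 0; c < C; ++c) {
      s1[c] += g[c];
      s2[c] += (double)g[c] * (q[c] - b[c]);
    }
  }
  double n = (double)dY.n_cols;
  arma::fvec m1(C), m2(C);
  for (int c = 0; c < C; ++c) {
    m1[c] = (float)(s1[c] / n);
    m2[c] = (float)(s2[c] / n);
  }
  for (arma::uword j = 0; j < dY.n_cols; ++j) {
    float* g = dY.colptr(j);
    const float* q = post.colptr(j);
    for (int c = 0; c < C; ++c) {
      g[c] = s.istdUsed[c] * (g[c] - m1[c] - (q[c] - b[c]) * m2[c]);
    }
  }
}

// standardize `raw` in place (pre-rectifier kept for the backward pass)
// and write the rectified copy into `out` in the same sweep
void siteForwardRelu(arma::fmat& raw, arma::fmat& out, Site& s,
                     const arma::fvec& b, bool train) {
  const int C = raw.n_rows;
  if (train) {
    arma::vec sum(C, arma::fill::zeros), sq(C, arma::fill::zeros);
    for (arma::uword j = 0; j < raw.n_cols; ++j) {
      const float* p = raw.colptr(j);
      for (int c = 0; c < C; ++c) {
        sum[c] += p[c];
        sq[c] += (double)p[c] * p[c];
      }
    }
    double n = (double)raw.n_cols;
    s.istdUsed.set_size(C);
    arma::fvec shift(C);
    for (int c = 0; c < C; ++c) {
      double m = sum[c] / n;
      double v = sq[c] / n - m * m;
      if (v < 0) v = 0;
      s.bmean[c] = m;
      s.bvar[c] = v;
      double is = 1.0 / std::sqrt(v + 1e-5);
      s.istdUsed[c] = (float)is;
      shift[c] = (float)(b[c] - m * is);
    }
    for (arma::uword j = 0; j < raw.n_cols; ++j) {
      float* p = raw.colptr(j);
      float* q = out.colptr(j);
      for (int c = 0; c < C; ++c) {
        float y = p[c] * s.istdUsed[c] + shift[c];
        p[c] = y;
        q[c] = y > 0 ? y : 0;
      }
    }
  } else {
    s.istdUsed = s.istdState;
    for (arma::uword j = 0; j < raw.n_cols; ++j) {
      float* p = raw.colptr(j);
      float* q = out.colptr(j);
      for (int c = 0; c < C; ++c) {
        float y = p[c] * s.istdState[c] + s.shiftState[c];
        p[c] = y;
        q[c] = y > 0 ? y : 0;
      }
    }
  }
}

inline void reluInPlace(arma::fmat& m) {
  float* p = m.memptr();
  for (arma::uword i = 0; i < m.n_elem; ++i)
    if (p[i] < 0) p[i] = 0;
}

Block makeBlock(const List& desc, const List& params, const List& state,
                int Tin, int N, int V) {
  Block b;
  b.prefix = as<std::string>(desc["prefix"]);
  b.cin = desc["cin"];
  b.cout = desc["cout"];
  b.stride = desc["stride"];
  b.kernel = desc["kernel"];
  b.depth = desc["depth"];
  b.sep = desc["separable"];
  b.att = desc["attention"];
  b.needProj = desc["needProj"];
  b.K = desc["K"];
  b.Tin = Tin;
  b.Tout = (Tin + b.stride - 1) / b.stride;
  b.Wcat.set_size(b.cin, (size_t)b.K * b.cout);
  for (int k = 0; k < b.K; ++k) {
    b.Wcat.cols((size_t)k * b.cout, (size_t)k * b.cout + b.cout - 1) =
      getMat(params, b.prefix + "gcn.W" + std::to_string(k + 1));
  }
  b.dWcat = arma::fmat(b.cin, (size_t)b.K * b.cout, arma::fill::zeros);
  b.gb = getVec(params, b.prefix + "gcn.b");
  b.dgb = arma::fvec(b.cout, arma::fill::zeros);
  initSite(b.gsite, state, b.prefix + "gcn.ns.", b.gb);
  for (int j = 0; j < b.depth; ++j) {
    TCLayer t;
    t.prefix = b.prefix + "tc" + std::to_string(j + 1) + ".";
    if (b.sep) {
      t.Wd = getMat(params, t.prefix + "Wd");
      t.Wp = getMat(params, t.prefix + "Wp");
      t.dWd = arma::fmat(arma::size(t.Wd), arma::fill::zeros);
      t.dWp = arma::fmat(arma::size(t.Wp), arma::fill::zeros);
    } else {
      t.W = getCube(params, t.prefix + "W");
      t.dW = arma::fcube(arma::size(t.W), arma::fill::zeros);
    }
    t.b = getVec(params, t.prefix + "b");
    t.db = arma::fvec(b.cout, arma::fill::zeros);
    initSite(t.site, state, t.prefix + "ns.", t.b);
    b.tc.push_back(std::move(t));
  }
  if (b.needProj) {
    b.resW = getMat(params, b.prefix + "res.W");
    b.dresW = arma::fmat(arma::size(b.resW), arma::fill::zeros);
    arma::fvec zero(b.cout, arma::fill::zeros);
    initSite(b.rsite, state, b.prefix + "res.ns.", zero);
    if (b.stride > 1) {
      b.resIdx.set_size((size_t)b.Tout * N * V);
      size_t o = 0;
      for (int v = 0; v < V; ++v)
        for (int n = 0; n < N; ++n)
          for (int t2 = 0; t2 < b.Tout; ++t2)
            b.resIdx[o++] = (size_t)(t2 * b.stride) +
              (size_t)Tin * (n + (size_t)N * v);
      b.resBuf.set_size(b.cin, (size_t)b.Tout * N * V);
    }
  }
  if (b.att) {
    b.aW1 = getMat(params, b.prefix + "att.W1");
    b.ab1 = getVec(params, b.prefix + "att.b1");
    b.aWt = getMat(params, b.prefix + "att.Wt");
    b.abt = getVec(params, b.prefix + "att.bt");
    b.aWv = getMat(params, b.prefix + "att.Wv");
    b.abv = getVec(params, b.prefix + "att.bv");
    b.Cr = b.aW1.n_cols;
    b.daW1 = arma::fmat(arma::size(b.aW1), arma::fill::zeros);
    b.dab1 = arma::fvec(b.Cr, arma::fill::zeros);
    b.daWt = arma::fmat(arma::size(b.aWt), arma::fill::zeros);
    b.dabt = arma::fvec(b.cout, arma::fill::zeros);
    b.daWv = arma::fmat(arma::size(b.aWv), arma::fill::zeros);
    b.dabv = arma::fvec(b.cout, arma::fill::zeros);
  }
  // buffers
  size_t TV = (size_t)b.Tin * N * V, T2V = (size_t)b.Tout * N * V;
  b.Xin = nullptr;
  b.znG.set_size(b.cout, TV);
  b.H.set_size(b.cout, TV);
  b.Zall.set_size((size_t)b.K * b.cout, TV);
  b.dZall.set_size((size_t)b.K * b.cout, TV);
  for (int j = 0; j < b.depth; ++j) {
    size_t len = (j == 0) ? TV : T2V;
    b.tcIn.push_back(arma::fmat(b.cout, len)); // [0] unused; kept for indexing
    b.Yd.push_back(arma::fmat(b.cout, T2V));
    b.znT.push_back(arma::fmat(b.cout, T2V));
    b.dXtc.push_back(arma::fmat(b.cout, len));
  }
  b.hLast.set_size(b.cout, T2V);
  if (b.needProj) b.rn.set_size(b.cout, T2V);
  b.y.set_size(b.cout, T2V);
  b.out.set_size(b.cout, T2V);
  if (b.att) {
    b.Pt.set_size(b.cout, (size_t)b.Tout * N);
    b.Pv.set_size(b.cout, (size_t)N * V);
    b.Zt.set_size(b.Cr, (size_t)b.Tout * N);
    b.Zv.set_size(b.Cr, (size_t)N * V);
    b.St.set_size(b.cout, (size_t)b.Tout * N);
    b.Sv.set_size(b.cout, (size_t)N * V);
  }
  b.dIn.set_size(b.cin, TV);
  return b;
}

// depthwise temporal convolution: X (C, Tin*N*V) -> Yd (C, Tout*N*V)
void depthwise(const arma::fmat& X, arma::fmat& Yd, const arma::fmat& Wd,
               int Tin, int Tout, int N, int V, int kernel, int stride) {
  const int C = X.n_rows;
  const int pad = (kernel - 1) / 2;
  Yd.zeros();
  for (int v = 0; v < V; ++v)
    for (int n = 0; n < N; ++n) {
      size_t ob = (size_t)Tout * (n + (size_t)N * v);
      size_t ib = (size_t)Tin * (n + (size_t)N * v);
      for (int t2 = 0; t2 < Tout; ++t2) {
        float* yp = Yd.colptr(ob + t2);
        for (int j = 0; j < kernel; ++j) {
          int tin = t2 * stride + j - pad;
          if (tin < 0 || tin >= Tin) continue;
          const float* xp = X.colptr(ib + tin);
          const float* wj = Wd.colptr(j);
          for (int c = 0; c < C; ++c) yp[c] += xp[c] * wj[c];
        }
      }
    }
}

void blockForward(Block& b, const arma::fmat& Xin,
                  const std::vector<std::vector<Edge>>& E, int N, int V,
                  bool train) {
  b.Xin = &Xin;
  const int Tin = b.Tin, Tout = b.Tout;
  const size_t TN = (size_t)Tin * N;
  // graph convolution: one stacked channel mix, then sparse contraction
  b.Zall = b.Wcat.t() * Xin;
  b.znG.zeros();
  for (int k = 0; k < b.K; ++k) {
    size_t r0 = (size_t)k * b.cout, r1 = r0 + b.cout - 1;
    for (const Edge& e : E[k]) {
      b.znG.cols((size_t)e.v * TN, (size_t)e.v * TN + TN - 1) +=
        e.w * b.Zall.submat(r0, (size_t)e.u * TN, r1, (size_t)e.u * TN + TN - 1);
    }
  }
  siteForwardRelu(b.znG, b.H, b.gsite, b.gb, train);
  // temporal layers; layer j reads H (j = 0) or tcIn[j]
  const arma::fmat* src = &b.H;
  for (int j = 0; j < b.depth; ++j) {
    int s = (j == 0) ? b.stride : 1;
    int tIn = (j == 0) ? Tin : Tout;
    TCLayer& t = b.tc[j];
    arma::fmat& dst = (j + 1 < b.depth) ? b.znT[j] : b.hLast;
    if (b.sep) {
      depthwise(*src, b.Yd[j], t.Wd, tIn, Tout, N, V, b.kernel, s);
      dst = t.Wp.t() * b.Yd[j];
    } else {
      const int pad = (b.kernel - 1) / 2;
      dst.zeros();
      for (int v = 0; v < V; ++v)
        for (int n = 0; n < N; ++n) {
          size_t ob = (size_t)Tout * (n + (size_t)N * v);
          size_t ib = (size_t)tIn * (n + (size_t)N * v);
          for (int jj = 0; jj < b.kernel; ++jj)
            for (int t2 = 0; t2 < Tout; ++t2) {
              int tin = t2 * s + jj - pad;
              if (tin < 0 || tin >= tIn) continue;
              dst.col(ob + t2) += t.W.slice(jj) * src->col(ib + tin);
            }
        }
    }
    if (j + 1 < b.depth) {
      siteForwardRelu(b.znT[j], b.tcIn[j + 1], t.site, t.b, train);
      src = &b.tcIn[j + 1];
    } else {
      siteForward(dst, t.site, t.b, train, false);
    }
  }
  // residual add + rectifier
  if (b.needProj) {
    if (b.stride == 1) {
      b.rn = b.resW.t() * Xin;
    } else {
      b.resBuf = Xin.cols(b.resIdx);
      b.rn = b.resW.t() * b.resBuf;
    }
    arma::fvec zero(b.cout, arma::fill::zeros);
    siteForward(b.rn, b.rsite, zero, train, false);
    b.y = b.hLast + b.rn;
  } else {
    b.y = b.hLast + Xin;
  }
  reluInPlace(b.y);
  // spatiotemporal joint attention
  if (b.att) {
    const int C = b.cout;
    b.Pt.zeros();
    b.Pv.zeros();
    for (int v = 0; v < V; ++v)
      for (int n = 0; n < N; ++n) {
        size_t yb = (size_t)Tout * (n + (size_t)N * v);
        float* pv = b.Pv.colptr((size_t)n + (size_t)N * v);
        for (int t = 0; t < Tout; ++t) {
          const float* yp = b.y.colptr(yb + t);
          float* pt = b.Pt.colptr((size_t)t + (size_t)Tout * n);
          for (int c = 0; c < C; ++c) {
            pt[c] += yp[c];
            pv[c] += yp[c];
          }
        }
      }
    b.Pt /= V;
    b.Pv /= Tout;
    b.Zt = b.aW1.t() * b.Pt;
    b.Zt.each_col() += b.ab1;
    reluInPlace(b.Zt);
    b.Zv = b.aW1.t() * b.Pv;
    b.Zv.each_col() += b.ab1;
    reluInPlace(b.Zv);
    b.St = b.aWt.t() * b.Zt;
    b.St.each_col() += b.abt;
    b.St.transform([](float x) { return 1.0f / (1.0f + std::exp(-x)); });
    b.Sv = b.aWv.t() * b.Zv;
    b.Sv.each_col() += b.abv;
    b.Sv.transform([](float x) { return 1.0f / (1.0f + std::exp(-x)); });
    for (int v = 0; v < V; ++v)
      for (int n = 0; n < N; ++n) {
        size_t yb = (size_t)Tout * (n + (size_t)N * v);
        const float* sv = b.Sv.colptr((size_t)n + (size_t)N * v);
        for (int t = 0; t < Tout; ++t) {
          const float* yp = b.y.colptr(yb + t);
          const float* st = b.St.colptr((size_t)t + (size_t)Tout * n);
          float* op = b.out.colptr(yb + t);
          for (int c = 0; c < C; ++c) op[c] = yp[c] * st[c] * sv[c];
        }
      }
    b.outPtr = &b.out;
  } else {
    b.outPtr = &b.y;
  }
}

// dOut is consumed as scratch; the input gradient lands in b.dIn
void blockBackward(Block& b, arma::fmat& dOut,
                   const std::vector<std::vector<Edge>>& E, int N, int V,
                   bool train) {
  const int Tin = b.Tin, Tout = b.Tout, C = b.cout;
  const size_t TN = (size_t)Tin * N;
  // attention backward
  if (b.att) {
    arma::fmat dSt(C, (size_t)Tout * N, arma::fill::zeros);
    arma::fmat dSv(C, (size_t)N * V, arma::fill::zeros);
    for (int v = 0; v < V; ++v)
      for (int n = 0; n < N; ++n) {
        size_t yb = (size_t)Tout * (n + (size_t)N * v);
        const float* sv = b.Sv.colptr((size_t)n + (size_t)N * v);
        float* dsv = dSv.colptr((size_t)n + (size_t)N * v);
        for (int t = 0; t < Tout; ++t) {
          float* g = dOut.colptr(yb + t);
          const float* yp = b.y.colptr(yb + t);
          const float* st = b.St.colptr((size_t)t + (size_t)Tout * n);
          float* dst = dSt.colptr((size_t)t + (size_t)Tout * n);
          for (int c = 0; c < C; ++c) {
            float gv = g[c];
            dst[c] += gv * yp[c] * sv[c];
            dsv[c] += gv * yp[c] * st[c];
            g[c] = gv * st[c] * sv[c]; // becomes dY w.r.t. the gate input
          }
        }
      }
    dSt %= b.St % (1.0f - b.St);
    dSv %= b.Sv % (1.0f - b.Sv);
    b.daWt += b.Zt * dSt.t();
    b.dabt += arma::sum(dSt, 1);
    b.daWv += b.Zv * dSv.t();
    b.dabv += arma::sum(dSv, 1);
    arma::fmat dZt = b.aWt * dSt;
    dZt.elem(arma::find(b.Zt <= 0)).zeros();
    arma::fmat dZv = b.aWv * dSv;
    dZv.elem(arma::find(b.Zv <= 0)).zeros();
    b.daW1 += b.Pt * dZt.t() + b.Pv * dZv.t();
    b.dab1 += arma::sum(dZt, 1) + arma::sum(dZv, 1);
    arma::fmat dPt = b.aW1 * dZt; // C x Tout*N
    arma::fmat dPv = b.aW1 * dZv; // C x N*V
    dPt /= V;
    dPv /= Tout;
    for (int v = 0; v < V; ++v)
      for (int n = 0; n < N; ++n) {
        size_t yb = (size_t)Tout * (n + (size_t)N * v);
        const float* pv = dPv.colptr((size_t)n + (size_t)N * v);
        for (int t = 0; t < Tout; ++t) {
          float* g = dOut.colptr(yb + t);
          const float* pt = dPt.colptr((size_t)t + (size_t)Tout * n);
          for (int c = 0; c < C; ++c) g[c] += pt[c] + pv[c];
        }
      }
  }
  // rectifier mask at the residual add
  {
    float* g = dOut.memptr();
    const float* yp = b.y.memptr();
    for (arma::uword i = 0; i < dOut.n_elem; ++i)
      if (yp[i] <= 0) g[i] = 0;
  }
  // residual path gradient (through the projection's standardization);
  // the normalized projection output is y - hLast wherever the mask is open
  const arma::fmat& Xin = *b.Xin;
  if (b.needProj) {
    arma::fmat dRes = dOut;
    arma::fvec zero(C, arma::fill::zeros);
    siteBackward(dRes, b.rn, b.rsite, zero, train);
    if (b.stride == 1) {
      b.dresW += Xin * dRes.t();
      b.dIn = b.resW * dRes;
    } else {
      b.resBuf = Xin.cols(b.resIdx);
      b.dresW += b.resBuf * dRes.t();
      arma::fmat dXs = b.resW * dRes; // cin x Tout*N*V
      b.dIn.zeros();
      for (size_t j = 0; j < b.resIdx.n_elem; ++j)
        b.dIn.col(b.resIdx[j]) += dXs.col(j);
    }
  } else {
    b.dIn = dOut; // identity residual; gcn gradient accumulates below
  }
  // temporal layers backward
  arma::fmat* dh = &dOut;
  for (int j = b.depth - 1; j >= 0; --j) {
    int s = (j == 0) ? b.stride : 1;
    int tIn = (j == 0) ? Tin : Tout;
    const arma::fmat& lin = (j == 0) ? b.H : b.tcIn[j];
    TCLayer& t = b.tc[j];
    if (j + 1 < b.depth) {
      siteBackwardRelu(*dh, b.tcIn[j + 1], b.znT[j], t.site, t.b, t.db, train);
    } else {
      t.db += arma::sum(*dh, 1);
      siteBackward(*dh, b.hLast, t.site, t.b, train);
    }
    const int pad = (b.kernel - 1) / 2;
    arma::fmat& dX = b.dXtc[j];
    dX.zeros();
    if (b.sep) {
      t.dWp += b.Yd[j] * dh->t();
      arma::fmat dYd = t.Wp * (*dh); // C x Tout*N*V
      for (int v = 0; v < V; ++v)
        for (int n = 0; n < N; ++n) {
          size_t ob = (size_t)Tout * (n + (size_t)N * v);
          size_t ib = (size_t)tIn * (n + (size_t)N * v);
          for (int t2 = 0; t2 < Tout; ++t2) {
            const float* gp = dYd.colptr(ob + t2);
            for (int jj = 0; jj < b.kernel; ++jj) {
              int tin = t2 * s + jj - pad;
              if (tin < 0 || tin >= tIn) continue;
              const float* xp = lin.colptr(ib + tin);
              float* dxp = dX.colptr(ib + tin);
              float* dwj = t.dWd.colptr(jj);
              const float* wj = t.Wd.colptr(jj);
              for (int c = 0; c < C; ++c) {
                dwj[c] += gp[c] * xp[c];
                dxp[c] += gp[c] * wj[c];
              }
            }
          }
        }
    } else {
      for (int v = 0; v < V; ++v)
        for (int n = 0; n < N; ++n) {
          size_t ob = (size_t)Tout * (n + (size_t)N * v);
          size_t ib = (size_t)tIn * (n + (size_t)N * v);
          for (int jj = 0; jj < b.kernel; ++jj)
            for (int t2 = 0; t2 < Tout; ++t2) {
              int tin = t2 * s + jj - pad;
              if (tin < 0 || tin >= tIn) continue;
              t.dW.slice(jj) += dh->col(ob + t2) * lin.col(ib + tin).t();
              dX.col(ib + tin) += t.W.slice(jj).t() * dh->col(ob + t2);
            }
        }
    }
    dh = &dX;
  }
  // graph convolution backward: fused rectifier mask + bias gradient +
  // batch-norm backward, then the sparse contraction
  siteBackwardRelu(*dh, b.H, b.znG, b.gsite, b.gb, b.dgb, train);
  b.dZall.zeros();
  for (int k = 0; k < b.K; ++k) {
    size_t r0 = (size_t)k * b.cout, r1 = r0 + b.cout - 1;
    for (const Edge& e : E[k]) {
      b.dZall.submat(r0, (size_t)e.u * TN, r1, (size_t)e.u * TN + TN - 1) +=
        e.w * dh->cols((size_t)e.v * TN, (size_t)e.v * TN + TN - 1);
    }
  }
  b.dWcat += Xin * b.dZall.t();
  b.dIn += b.Wcat * b.dZall;
}

} // namespace

// [[Rcpp::export(name = ".cpp_net_batch")]]
List cpp_net_batch(List xs, IntegerVector idx, List branchPlans, List mainPlan,
                   List params, List state, List As, IntegerVector labels,
                   bool computeGrads, bool train, bool returnFeatures,
                   NumericMatrix dropMask) {
  CharacterVector branchNames = xs.names();
  const int nBranch = xs.size();
  NumericVector x0 = xs[0];
  IntegerVector d0 = x0.attr("dim");
  const int T = d0[1], Nfull = d0[2], V = d0[3];
  const int N = idx.size();
  // adjacency triplets per partition
  std::vector<std::vector<Edge>> E;
  for (int k = 0; k < As.size(); ++k) {
    NumericMatrix A = As[k];
    std::vector<Edge> ek;
    for (int j = 0; j < V; ++j)
      for (int i = 0; i < V; ++i)
        if (A(i, j) != 0) ek.push_back({i, j, (float)A(i, j)});
    E.push_back(std::move(ek));
  }
  // input batch normalization coefficients per branch
  std::vector<arma::fmat> bnScale(nBranch), bnShift(nBranch);
  std::vector<arma::mat> bnMean(nBranch), bnIstd(nBranch);
  std::vector<arma::mat> bnBatchMean(nBranch), bnBatchVar(nBranch);
  std::vector<arma::mat> dGamma(nBranch), dBeta(nBranch);
  for (int bi = 0; bi < nBranch; ++bi) {
    std::string b = as<std::string>(branchNames[bi]);
    NumericMatrix gamma = params[b + ".bn.gamma"];
    NumericMatrix beta = params[b + ".bn.beta"];
    arma::mat m(6, V), var(6, V);
    if (train) {
      NumericVector xb = xs[bi];
      const double* xp = REAL((SEXP)xb);
      m.zeros();
      var.zeros();
      for (int s = 0; s < N; ++s) {
        size_t off0 = (size_t)6 * T * (idx[s] - 1);
        for (int v = 0; v < V; ++v) {
          const double* p = xp + off0 + (size_t)6 * T * Nfull * v;
          for (int t = 0; t < T; ++t)
            for (int c = 0; c < 6; ++c) {
              double val = p[c + 6 * t];
              m(c, v) += val;
              var(c, v) += val * val;
            }
        }
      }
      double cnt = (double)N * T;
      m /= cnt;
      var = var / cnt - m % m;
      var.transform([](double x) { return x > 0 ? x : 0; });
      bnBatchMean[bi] = m;
      bnBatchVar[bi] = var;
    } else {
      NumericMatrix rm = state[b + ".bn.mean"];
      NumericMatrix rv = state[b + ".bn.var"];
      m = arma::mat(rm.begin(), 6, V);
      var = arma::mat(rv.begin(), 6, V);
    }
    bnMean[bi] = m;
    bnIstd[bi] = 1.0 / arma::sqrt(var + 1e-5);
    bnScale[bi].set_size(6, V);
    bnShift[bi].set_size(6, V);
    for (int v = 0; v < V; ++v)
      for (int c = 0; c < 6; ++c) {
        double sc = gamma(c, v) * bnIstd[bi](c, v);
        bnScale[bi](c, v) = (float)sc;
        bnShift[bi](c, v) = (float)(beta(c, v) - m(c, v) * sc);
      }
    if (computeGrads) {
      dGamma[bi] = arma::mat(6, V, arma::fill::zeros);
      dBeta[bi] = arma::mat(6, V, arma::fill::zeros);
    }
  }
  // build branch stacks and mainstream
  std::vector<std::vector<Block>> branches(nBranch);
  for (int bi = 0; bi < nBranch; ++bi) {
    List plan = branchPlans[bi];
    int t = T;
    for (int i = 0; i < plan.size(); ++i) {
      branches[bi].push_back(makeBlock(plan[i], params, state, t, N, V));
      t = branches[bi].back().Tout;
    }
  }
  std::vector<Block> main;
  {
    int t = branches.empty() ? T : branches[0].back().Tout;
    for (int i = 0; i < mainPlan.size(); ++i) {
      main.push_back(makeBlock(mainPlan[i], params, state, t, N, V));
      t = main.back().Tout;
    }
  }
  const int Cc = main.front().cin;
  const int Tb = main.front().Tin; // temporal length at concat
  const int Tf = main.back().Tout; // final temporal length
  const int Cf = main.back().cout;
  arma::fmat fcW = getMat(params, "fc.W");
  arma::fvec fcb = getVec(params, "fc.b");
  const int ncls = fcW.n_cols;
  arma::fmat dfcW(arma::size(fcW), arma::fill::zeros);
  arma::fvec dfcb(ncls, arma::fill::zeros);

  arma::fmat concat(Cc, (size_t)Tb * N * V);
  std::vector<arma::fmat> Xs(nBranch);
  for (int bi = 0; bi < nBranch; ++bi)
    Xs[bi].set_size(6, (size_t)T * N * V);

  // ---- gather + input batch normalization (single precision) ----
  for (int bi = 0; bi < nBranch; ++bi) {
    NumericVector xb = xs[bi];
    const double* src = REAL((SEXP)xb);
    for (int s = 0; s < N; ++s) {
      size_t off0 = (size_t)6 * T * (idx[s] - 1);
      for (int v = 0; v < V; ++v) {
        float* dst = Xs[bi].colptr((size_t)T * (s + (size_t)N * v));
        const double* sp = src + off0 + (size_t)6 * T * Nfull * v;
        const float* sc = bnScale[bi].colptr(v);
        const float* sh = bnShift[bi].colptr(v);
        for (int t = 0; t < T; ++t)
          for (int c = 0; c < 6; ++c)
            dst[c + 6 * t] = (float)sp[c + 6 * t] * sc[c] + sh[c];
      }
    }
  }
  // ---- forward ----
  for (int bi = 0; bi < nBranch; ++bi) {
    const arma::fmat* in = &Xs[bi];
    for (Block& blk : branches[bi]) {
      blockForward(blk, *in, E, N, V, train);
      in = blk.outPtr;
    }
  }
  {
    int off = 0;
    for (int bi = 0; bi < nBranch; ++bi) {
      const arma::fmat& o = *branches[bi].back().outPtr;
      concat.rows(off, off + o.n_rows - 1) = o;
      off += o.n_rows;
    }
  }
  {
    const arma::fmat* in = &concat;
    for (Block& blk : main) {
      blockForward(blk, *in, E, N, V, train);
      in = blk.outPtr;
    }
  }
  // ---- head: global average pool + fully connected ----
  arma::fmat g(Cf, N, arma::fill::zeros);
  {
    const arma::fmat& fm = *main.back().outPtr;
    for (int v = 0; v < V; ++v)
      for (int n = 0; n < N; ++n) {
        size_t fb = (size_t)Tf * (n + (size_t)N * v);
        float* gp = g.colptr(n);
        for (int t = 0; t < Tf; ++t) {
          const float* fp = fm.colptr(fb + t);
          for (int c = 0; c < Cf; ++c) gp[c] += fp[c];
        }
      }
    g /= (float)(Tf * V);
  }
  // inverted dropout on the pooled features (training only; the mask is
  // drawn by the caller so all randomness stays under the R seed)
  const bool useDrop = dropMask.nrow() == Cf && dropMask.ncol() == N;
  if (useDrop) {
    for (int n = 0; n < N; ++n) {
      float* gp = g.colptr(n);
      for (int c = 0; c < Cf; ++c) gp[c] *= (float)dropMask(c, n);
    }
  }
  arma::fmat lg = fcW.t() * g;
  lg.each_col() += fcb;
  NumericMatrix logits(ncls, N);
  for (int s = 0; s < N; ++s)
    for (int c = 0; c < ncls; ++c) logits(c, s) = lg(c, s);
  NumericVector features;
  if (returnFeatures) {
    features = NumericVector((size_t)Cf * Tf * N * V);
    features.attr("dim") = IntegerVector::create(Cf, Tf, N, V);
    const arma::fmat& fm = *main.back().outPtr;
    for (int v = 0; v < V; ++v)
      for (int n = 0; n < N; ++n) {
        size_t fb = (size_t)Tf * (n + (size_t)N * v);
        for (int t = 0; t < Tf; ++t) {
          const float* fp = fm.colptr(fb + t);
          double* op = &features[(size_t)Cf * (t + (size_t)Tf * (n + (size_t)N * v))];
          for (int c = 0; c < Cf; ++c) op[c] = fp[c];
        }
      }
  }
  const bool haveLabels = labels.size() == N;
  double totalLoss = 0;
  if (haveLabels || computeGrads) {
    arma::fmat dlg(ncls, N, arma::fill::zeros);
    if (haveLabels) {
      for (int s = 0; s < N; ++s) {
        arma::fvec l = lg.col(s);
        double mx = l.max();
        arma::fvec p = arma::exp(l - (float)mx);
        p /= arma::accu(p);
        int lab = labels[s] - 1;
        double pl = p[lab] > 1e-30 ? p[lab] : 1e-30;
        totalLoss += -std::log(pl);
        dlg.col(s) = p / (float)N;
        dlg(lab, s) -= 1.0f / N;
      }
    }
    if (computeGrads) {
      // head backward
      dfcW += g * dlg.t();
      dfcb += arma::sum(dlg, 1);
      arma::fmat dg = fcW * dlg / ((float)(Tf * V)); // Cf x N
      if (useDrop) {
        for (int n = 0; n < N; ++n) {
          float* dgp = dg.colptr(n);
          for (int c = 0; c < Cf; ++c) dgp[c] *= (float)dropMask(c, n);
        }
      }
      arma::fmat dOut(Cf, (size_t)Tf * N * V);
      for (int v = 0; v < V; ++v)
        for (int n = 0; n < N; ++n) {
          size_t fb = (size_t)Tf * (n + (size_t)N * v);
          const float* dgp = dg.colptr(n);
          for (int t = 0; t < Tf; ++t) {
            float* op = dOut.colptr(fb + t);
            for (int c = 0; c < Cf; ++c) op[c] = dgp[c];
          }
        }
      // mainstream backward
      for (int i = (int)main.size() - 1; i >= 0; --i) {
        blockBackward(main[i],
                      i == (int)main.size() - 1 ? dOut : main[i + 1].dIn,
                      E, N, V, train);
      }
      // branch backward
      int off = 0;
      for (int bi = 0; bi < nBranch; ++bi) {
        std::vector<Block>& stack = branches[bi];
        int cb = (int)stack.back().outPtr->n_rows;
        arma::fmat dTop = main.front().dIn.rows(off, off + cb - 1);
        off += cb;
        for (int i = (int)stack.size() - 1; i >= 0; --i) {
          blockBackward(stack[i],
                        i == (int)stack.size() - 1 ? dTop : stack[i + 1].dIn,
                        E, N, V, train);
        }
        // input batch-norm parameter gradients (raw data re-read for xhat)
        const arma::fmat& dIn = stack.front().dIn;
        NumericVector xb = xs[bi];
        const double* src = REAL((SEXP)xb);
        for (int s = 0; s < N; ++s) {
          size_t off0 = (size_t)6 * T * (idx[s] - 1);
          for (int v = 0; v < V; ++v) {
            const float* gp = dIn.colptr((size_t)T * (s + (size_t)N * v));
            const double* sp = src + off0 + (size_t)6 * T * Nfull * v;
            for (int t = 0; t < T; ++t)
              for (int c = 0; c < 6; ++c) {
                double gg = gp[c + 6 * t];
                double xhat = (sp[c + 6 * t] - bnMean[bi](c, v)) * bnIstd[bi](c, v);
                dGamma[bi](c, v) += gg * xhat;
                dBeta[bi](c, v) += gg;
              }
          }
        }
      }
    }
  }
  List out = List::create(_["logits"] = logits,
                          _["loss"] = haveLabels ? totalLoss / N : NA_REAL);
  if (returnFeatures) out["features"] = features;
  // ---- running-statistics updates for R ----
  if (train) {
    std::vector<std::string> snames;
    std::vector<SEXP> svals;
    auto emitSite = [&](const std::string& site, const Site& s) {
      snames.push_back(site);
      svals.push_back(List::create(
        _["mean"] = NumericVector(s.bmean.begin(), s.bmean.end()),
        _["var"] = NumericVector(s.bvar.begin(), s.bvar.end())));
    };
    auto emitBlockSites = [&](Block& blk) {
      emitSite(blk.prefix + "gcn.ns.", blk.gsite);
      for (int j = 0; j < blk.depth; ++j)
        emitSite(blk.prefix + "tc" + std::to_string(j + 1) + ".ns.",
                 blk.tc[j].site);
      if (blk.needProj) emitSite(blk.prefix + "res.ns.", blk.rsite);
    };
    for (auto& stack : branches)
      for (Block& blk : stack) emitBlockSites(blk);
    for (Block& blk : main) emitBlockSites(blk);
    List stats(svals.size());
    CharacterVector snm(svals.size());
    for (size_t i = 0; i < svals.size(); ++i) {
      stats[i] = svals[i];
      snm[i] = snames[i];
    }
    stats.names() = snm;
    out["stats"] = stats;
    List bs(nBranch);
    for (int bi = 0; bi < nBranch; ++bi) {
      bs[bi] = List::create(
        _["mean"] = NumericMatrix(6, V, bnBatchMean[bi].memptr()),
        _["var"] = NumericMatrix(6, V, bnBatchVar[bi].memptr()));
    }
    bs.names() = branchNames;
    out["bnStats"] = bs;
  }
  // ---- gradient list ----
  if (computeGrads) {
    std::vector<std::string> gnames;
    List gvals(512);
    int gi = 0;
    auto addMat = [&](const std::string& nm, const arma::fmat& m) {
      gvals[gi] = NumericMatrix(m.n_rows, m.n_cols, m.memptr());
      gnames.push_back(nm);
      ++gi;
    };
    auto addVec = [&](const std::string& nm, const arma::fvec& v) {
      gvals[gi] = NumericVector(v.begin(), v.end());
      gnames.push_back(nm);
      ++gi;
    };
    auto emitBlock = [&](Block& blk) {
      for (int k = 0; k < blk.K; ++k)
        addMat(blk.prefix + "gcn.W" + std::to_string(k + 1),
               arma::fmat(blk.dWcat.cols((size_t)k * blk.cout,
                                         (size_t)k * blk.cout + blk.cout - 1)));
      addVec(blk.prefix + "gcn.b", blk.dgb);
      for (TCLayer& t : blk.tc) {
        if (blk.sep) {
          addMat(t.prefix + "Wd", t.dWd);
          addMat(t.prefix + "Wp", t.dWp);
        } else {
          NumericVector dW(t.dW.memptr(), t.dW.memptr() + t.dW.n_elem);
          dW.attr("dim") = IntegerVector::create(t.dW.n_rows, t.dW.n_cols, t.dW.n_slices);
          gvals[gi] = dW;
          gnames.push_back(t.prefix + "W");
          ++gi;
        }
        addVec(t.prefix + "b", t.db);
      }
      if (blk.needProj) addMat(blk.prefix + "res.W", blk.dresW);
      if (blk.att) {
        addMat(blk.prefix + "att.W1", blk.daW1);
        addVec(blk.prefix + "att.b1", blk.dab1);
        addMat(blk.prefix + "att.Wt", blk.daWt);
        addVec(blk.prefix + "att.bt", blk.dabt);
        addMat(blk.prefix + "att.Wv", blk.daWv);
        addVec(blk.prefix + "att.bv", blk.dabv);
      }
    };
    for (int bi = 0; bi < nBranch; ++bi)
      for (Block& blk : branches[bi]) emitBlock(blk);
    for (Block& blk : main) emitBlock(blk);
    addMat("fc.W", dfcW);
    addVec("fc.b", dfcb);
    for (int bi = 0; bi < nBranch; ++bi) {
      std::string b = as<std::string>(branchNames[bi]);
      gvals[gi] = NumericMatrix(6, V, dGamma[bi].memptr());
      gnames.push_back(b + ".bn.gamma");
      ++gi;
      gvals[gi] = NumericMatrix(6, V, dBeta[bi].memptr());
      gnames.push_back(b + ".bn.beta");
      ++gi;
    }
    List grads(gi);
    CharacterVector nm(gi);
    for (int i = 0; i < gi; ++i) {
      grads[i] = gvals[i];
      nm[i] = gnames[i];
    }
    grads.names() = nm;
    out["grads"] = grads;
  }
  return out;
}
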