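// Compact encoder-decoder segmentation networks (U-Net-like and FPN-like)
// with hand-rolled backprop, used as desk-scale reference models.
//
// Activation layout: arma::mat of shape (channels x H*W), pixel column index
// j = r + c*H (column-major, matching R matrix vectorisation). Convolutions
// are 3x3, pad 1, implemented via im2col + GEMM.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static arma::mat relu(const arma::mat& Z) {
  arma::mat A = Z;
  A.elem(arma::find(Z < 0)).zeros();
  return A;
}

static void relu_back(arma::mat& dZ, const arma::mat& Z) {
  dZ.elem(arma::find(Z < 0)).zeros();
}

// zero the columns of block rows [k*C, k*C+C) whose source pixel row wraps
static void zero_wrapped_rows(arma::mat& M, int r0, int r1, int dy,
                              int H, int W) {
  if (dy == 0) return;
  for (int c = 0; c < W; ++c) {
    int j = (dy < 0) ? c * H : c * H + H - 1;
    M.submat(r0, j, r1, j).zeros();
  }
}

// im2col for 3x3 pad-1 conv: returns (9*C x HW)
static arma::mat im2col3(const arma::mat& A, int H, int W) {
  const int C = A.n_rows, HW = H * W;
  arma::mat K(9 * C, HW, arma::fill::zeros);
  int k = 0;
  for (int dx = -1; dx <= 1; ++dx) {
    for (int dy = -1; dy <= 1; ++dy, ++k) {
      const int s = dy + dx * H;
      const int j0 = std::max(0, -s), j1 = HW - 1 - std::max(0, s);
      if (j0 <= j1)
        K.submat(k * C, j0, k * C + C - 1, j1) = A.cols(j0 + s, j1 + s);
      zero_wrapped_rows(K, k * C, k * C + C - 1, dy, H, W);
    }
  }
  return K;
}

// adjoint of im2col3: scatter (9*C x HW) gradient back to (C x HW)
static arma::mat col2im3(const arma::mat& dK, int H, int W, int C) {
  const int HW = H * W;
  arma::mat dA(C, HW, arma::fill::zeros);
  int k = 0;
  for (int dx = -1; dx <= 1; ++dx) {
    for (int dy = -1; dy <= 1; ++dy, ++k) {
      const int s = dy + dx * H;
      arma::mat blk = dK.rows(k * C, k * C + C - 1);
      zero_wrapped_rows(blk, 0, C - 1, dy, H, W);
      const int j0 = std::max(0, -s), j1 = HW - 1 - std::max(0, s);
      if (j0 <= j1)
        dA.cols(j0 + s, j1 + s) += blk.cols(j0, j1);
    }
  }
  return dA;
}

// 2x2 average pooling, H and W even
static arma::mat pool2(const arma::mat& A, int H, int W) {
  const int H2 = H / 2, W2 = W / 2;
  arma::mat O(A.n_rows, H2 * W2);
  for (int c2 = 0; c2 < W2; ++c2)
    for (int r2 = 0; r2 < H2; ++r2) {
      const int j = 2 * r2 + 2 * c2 * H;
      O.col(r2 + c2 * H2) =
          0.25 * (A.col(j) + A.col(j + 1) + A.col(j + H) + A.col(j + H + 1));
    }
  return O;
}

static arma::mat pool2_back(const arma::mat& dO, int H, int W) {
  const int H2 = H / 2, W2 = W / 2;
  arma::mat dA(dO.n_rows, H * W, arma::fill::zeros);
  for (int c2 = 0; c2 < W2; ++c2)
    for (int r2 = 0; r2 < H2; ++r2) {
      const int j = 2 * r2 + 2 * c2 * H;
      arma::vec g = 0.25 * dO.col(r2 + c2 * H2);
      dA.col(j) = g;
      dA.col(j + 1) = g;
      dA.col(j + H) = g;
      dA.col(j + H + 1) = g;
    }
  return dA;
}

// nearest-neighbour 2x upsampling from (H2 x W2) to (2H2 x 2W2)
static arma::mat upsample2(const arma::mat& A, int H2, int W2) {
  const int H = 2 * H2;
  arma::mat O(A.n_rows, 4 * H2 * W2);
  for (int c2 = 0; c2 < W2; ++c2)
    for (int r2 = 0; r2 < H2; ++r2) {
      const arma::vec v = A.col(r2 + c2 * H2);
      const int j = 2 * r2 + 2 * c2 * H;
      O.col(j) = v;
      O.col(j + 1) = v;
      O.col(j + H) = v;
      O.col(j + H + 1) = v;
    }
  return O;
}

static arma::mat upsample2_back(const arma::mat& dO, int H2, int W2) {
  const int H = 2 * H2;
  arma::mat dA(dO.n_rows, H2 * W2);
  for (int c2 = 0; c2 < W2; ++c2)
    for (int r2 = 0; r2 < H2; ++r2) {
      const int j = 2 * r2 + 2 * c2 * H;
      dA.col(r2 + c2 * H2) =
          dO.col(j) + dO.col(j + 1) + dO.col(j + H) + dO.col(j + H + 1);
    }
  return dA;
}

static arma::mat softmax_cols(const arma::mat& Z) {
  arma::rowvec mx = arma::max(Z, 0);
  arma::mat P = arma::exp(Z.each_row() - mx);
  arma::rowvec s = arma::sum(P, 0);
  P.each_row() /= s;
  return P;
}

static arma::mat getW(const List& w, const char* name) {
  return as<arma::mat>(w[name]);
}
static arma::vec getb(const List& w, const char* name) {
  arma::mat b = as<arma::mat>(w[name]);
  return arma::vec(b.col(0));
}

struct LossCfg {
  int family;       // 0 = weighted_bce, 1 = focal_tversky, 2 = combo
  double eps, alpha, beta, gamma, lambda, smooth;
  bool use_cert;
  bool pref_all;    // 1/C over all channels vs 1/(C-1) wound-only prefactor
};

static LossCfg parse_cfg(const List& cfg) {
  LossCfg c;
  c.family = as<int>(cfg["family_code"]);
  c.eps = as<double>(cfg["eps"]);
  c.alpha = as<double>(cfg["alpha"]);
  c.beta = as<double>(cfg["beta"]);
  c.gamma = as<double>(cfg["gamma"]);
  c.lambda = as<double>(cfg["lambda"]);
  c.smooth = as<double>(cfg["smooth"]);
  c.use_cert = as<bool>(cfg["use_certainty_weights"]);
  c.pref_all = as<bool>(cfg["prefactor_all"]);
  return c;
}

// loss value and dL/dP for one image; g in 0..C-1, m certainty weights
static double loss_and_gradP(const arma::mat& P, const arma::ivec& g,
                             const arma::vec& m, const arma::vec& w,
                             const LossCfg& cfg, arma::mat& dP) {
  const int C = P.n_rows, HW = P.n_cols;
  const double N = (double)HW;
  arma::mat G(C, HW, arma::fill::zeros);
  for (int j = 0; j < HW; ++j) G(g[j], j) = 1.0;
  arma::rowvec mr = cfg.use_cert ? arma::rowvec(m.t())
                                 : arma::rowvec(HW, arma::fill::ones);
  const double pref = 1.0 / (cfg.pref_all ? C : std::max(1, C - 1));

  double loss = 0.0;
  dP.zeros(C, HW);

  if (cfg.family == 0 || cfg.family == 2) {
    arma::mat Q = 1.0 - G;
    arma::mat MG = G.each_row() % mr;   // m_i * g_ic
    arma::mat MQ = Q.each_row() % mr;   // m_i * (1 - g_ic)
    arma::mat lp = arma::log(P + cfg.eps);
    arma::mat lq = arma::log(1.0 - P + cfg.eps);
    arma::vec t1 = arma::sum(MG % lp, 1);      // per class
    arma::vec t2 = arma::sum(MQ % lq, 1);
    double bce = -pref * (arma::dot(w, t1) / N + arma::accu(t2) / N);
    arma::mat dbce =
        -pref * ((MG.each_col() % w) / (P + cfg.eps) - MQ / (1.0 - P + cfg.eps)) / N;
    const double lam = (cfg.family == 0) ? 1.0 : cfg.lambda;
    loss += lam * bce;
    dP += lam * dbce;
  }
  if (cfg.family == 1 || cfg.family == 2) {
    arma::vec TP = arma::sum(P % G, 1);
    arma::vec FN = arma::sum((1.0 - P) % G, 1);
    arma::vec FP = arma::sum(P % (1.0 - G), 1);
    arma::vec D = TP + cfg.alpha * FN + cfg.beta * FP + cfg.smooth;
    arma::vec TI = (TP + cfg.smooth) / D;
    arma::vec one_m = 1.0 - TI;
    double ftl = arma::accu(arma::pow(one_m, cfg.gamma));
    arma::vec dLdTI = -cfg.gamma * arma::pow(one_m, cfg.gamma - 1.0);
    arma::vec D2 = D % D;
    arma::vec dTIdTP = (cfg.alpha * FN + cfg.beta * FP) / D2;
    arma::vec dTIdFN = -cfg.alpha * (TP + cfg.smooth) / D2;
    arma::vec dTIdFP = -cfg.beta * (TP + cfg.smooth) / D2;
    arma::vec cg = dLdTI % (dTIdTP - dTIdFN);
    arma::vec cq = dLdTI % dTIdFP;
    arma::mat Q = 1.0 - G;
    arma::mat dftl = G.each_col() % cg + Q.each_col() % cq;
    const double lam = (cfg.family == 1) ? 1.0 : (1.0 - cfg.lambda);
    loss += lam * ftl;
    dP += lam * dftl;
  }
  return loss;
}

static arma::mat softmax_back(const arma::mat& P, const arma::mat& dP) {
  arma::rowvec dots = arma::sum(P % dP, 0);
  return P % (dP.each_row() - dots);
}

// ---------------- U-Net-like ----------------

struct UnetCache {
  arma::mat K1, Z1, A1, P1, K2, Z2, A2, P2, K3, Z3, A3;
  arma::mat C2, K4, Z4, A4, C1, K5, Z5, A5, P;
};

static arma::mat unet_forward(const List& w, const arma::mat& x, int H, int W,
                              UnetCache* c) {
  UnetCache loc;
  UnetCache& s = c ? *c : loc;
  const int H2 = H / 2, W2 = W / 2, H4 = H / 4, W4 = W / 4;
  s.K1 = im2col3(x, H, W);
  s.Z1 = getW(w, "enc1_W") * s.K1;
  s.Z1.each_col() += getb(w, "enc1_b");
  s.A1 = relu(s.Z1);
  s.P1 = pool2(s.A1, H, W);
  s.K2 = im2col3(s.P1, H2, W2);
  s.Z2 = getW(w, "enc2_W") * s.K2;
  s.Z2.each_col() += getb(w, "enc2_b");
  s.A2 = relu(s.Z2);
  s.P2 = pool2(s.A2, H2, W2);
  s.K3 = im2col3(s.P2, H4, W4);
  s.Z3 = getW(w, "bott_W") * s.K3;
  s.Z3.each_col() += getb(w, "bott_b");
  s.A3 = relu(s.Z3);
  s.C2 = arma::join_cols(upsample2(s.A3, H4, W4), s.A2);
  s.K4 = im2col3(s.C2, H2, W2);
  s.Z4 = getW(w, "dec2_W") * s.K4;
  s.Z4.each_col() += getb(w, "dec2_b");
  s.A4 = relu(s.Z4);
  s.C1 = arma::join_cols(upsample2(s.A4, H2, W2), s.A1);
  s.K5 = im2col3(s.C1, H, W);
  s.Z5 = getW(w, "dec1_W") * s.K5;
  s.Z5.each_col() += getb(w, "dec1_b");
  s.A5 = relu(s.Z5);
  arma::mat Zh = getW(w, "head_W") * s.A5;
  Zh.each_col() += getb(w, "head_b");
  s.P = softmax_cols(Zh);
  return s.P;
}

static void unet_backward(const List& w, const UnetCache& s,
                          const arma::mat& dZh, int H, int W,
                          std::vector<arma::mat>& gW,
                          std::vector<arma::mat>& gb) {
  const int H2 = H / 2, W2 = W / 2, H4 = H / 4, W4 = W / 4;
  const int wdth = getW(w, "enc1_W").n_rows;  // base width
  // order: enc1, enc2, bott, dec2, dec1, head
  arma::mat dA5 = getW(w, "head_W").t() * dZh;
  gW[5] = dZh * s.A5.t();
  gb[5] = arma::sum(dZh, 1);
  arma::mat dZ5 = dA5;
  relu_back(dZ5, s.Z5);
  gW[4] = dZ5 * s.K5.t();
  gb[4] = arma::sum(dZ5, 1);
  arma::mat dC1 = col2im3(getW(w, "dec1_W").t() * dZ5, H, W, 3 * wdth);
  arma::mat dU1 = dC1.rows(0, 2 * wdth - 1);
  arma::mat dA1 = dC1.rows(2 * wdth, 3 * wdth - 1);
  arma::mat dA4 = upsample2_back(dU1, H2, W2);
  arma::mat dZ4 = dA4;
  relu_back(dZ4, s.Z4);
  gW[3] = dZ4 * s.K4.t();
  gb[3] = arma::sum(dZ4, 1);
  arma::mat dC2 = col2im3(getW(w, "dec2_W").t() * dZ4, H2, W2, 6 * wdth);
  arma::mat dU2 = dC2.rows(0, 4 * wdth - 1);
  arma::mat dA2 = dC2.rows(4 * wdth, 6 * wdth - 1);
  arma::mat dA3 = upsample2_back(dU2, H4, W4);
  arma::mat dZ3 = dA3;
  relu_back(dZ3, s.Z3);
  gW[2] = dZ3 * s.K3.t();
  gb[2] = arma::sum(dZ3, 1);
  arma::mat dP2 = col2im3(getW(w, "bott_W").t() * dZ3, H4, W4, 2 * wdth);
  dA2 += pool2_back(dP2, H2, W2);
  arma::mat dZ2 = dA2;
  relu_back(dZ2, s.Z2);
  gW[1] = dZ2 * s.K2.t();
  gb[1] = arma::sum(dZ2, 1);
  arma::mat dP1 = col2im3(getW(w, "enc2_W").t() * dZ2, H2, W2, wdth);
  dA1 += pool2_back(dP1, H, W);
  arma::mat dZ1 = dA1;
  relu_back(dZ1, s.Z1);
  gW[0] = dZ1 * s.K1.t();
  gb[0] = arma::sum(dZ1, 1);
}

// ---------------- FPN-like ----------------

struct FpnCache {
  arma::mat K1, Z1, A1, P1, K2, Z2, A2, P2, K3, Z3, A3;
  arma::mat M3, M2, M1, Ks, Zs, S, P;
};

static arma::mat fpn_forward(const List& w, const arma::mat& x, int H, int W,
                             FpnCache* c) {
  FpnCache loc;
  FpnCache& s = c ? *c : loc;
  const int H2 = H / 2, W2 = W / 2, H4 = H / 4, W4 = W / 4;
  s.K1 = im2col3(x, H, W);
  s.Z1 = getW(w, "c1_W") * s.K1;
  s.Z1.each_col() += getb(w, "c1_b");
  s.A1 = relu(s.Z1);
  s.P1 = pool2(s.A1, H, W);
  s.K2 = im2col3(s.P1, H2, W2);
  s.Z2 = getW(w, "c2_W") * s.K2;
  s.Z2.each_col() += getb(w, "c2_b");
  s.A2 = relu(s.Z2);
  s.P2 = pool2(s.A2, H2, W2);
  s.K3 = im2col3(s.P2, H4, W4);
  s.Z3 = getW(w, "c3_W") * s.K3;
  s.Z3.each_col() += getb(w, "c3_b");
  s.A3 = relu(s.Z3);
  s.M3 = getW(w, "l3_W") * s.A3;
  s.M3.each_col() += getb(w, "l3_b");
  s.M2 = getW(w, "l2_W") * s.A2 + upsample2(s.M3, H4, W4);
  s.M2.each_col() += getb(w, "l2_b");
  s.M1 = getW(w, "l1_W") * s.A1 + upsample2(s.M2, H2, W2);
  s.M1.each_col() += getb(w, "l1_b");
  s.Ks = im2col3(s.M1, H, W);
  s.Zs = getW(w, "smooth_W") * s.Ks;
  s.Zs.each_col() += getb(w, "smooth_b");
  s.S = relu(s.Zs);
  arma::mat Zh = getW(w, "head_W") * s.S;
  Zh.each_col() += getb(w, "head_b");
  s.P = softmax_cols(Zh);
  return s.P;
}

static void fpn_backward(const List& w, const FpnCache& s, const arma::mat& dZh,
                         int H, int W, std::vector<arma::mat>& gW,
                         std::vector<arma::mat>& gb) {
  const int H2 = H / 2, W2 = W / 2, H4 = H / 4, W4 = W / 4;
  const int wdth = getW(w, "c1_W").n_rows;
  // order: c1, c2, c3, l3, l2, l1, smooth, head
  arma::mat dS = getW(w, "head_W").t() * dZh;
  gW[7] = dZh * s.S.t();
  gb[7] = arma::sum(dZh, 1);
  arma::mat dZs = dS;
  relu_back(dZs, s.Zs);
  gW[6] = dZs * s.Ks.t();
  gb[6] = arma::sum(dZs, 1);
  arma::mat dM1 = col2im3(getW(w, "smooth_W").t() * dZs, H, W, wdth);
  gW[5] = dM1 * s.A1.t();
  gb[5] = arma::sum(dM1, 1);
  arma::mat dA1 = getW(w, "l1_W").t() * dM1;
  arma::mat dM2 = upsample2_back(dM1, H2, W2);
  gW[4] = dM2 * s.A2.t();
  gb[4] = arma::sum(dM2, 1);
  arma::mat dA2 = getW(w, "l2_W").t() * dM2;
  arma::mat dM3 = upsample2_back(dM2, H4, W4);
  gW[3] = dM3 * s.A3.t();
  gb[3] = arma::sum(dM3, 1);
  arma::mat dA3 = getW(w, "l3_W").t() * dM3;
  arma::mat dZ3 = dA3;
  relu_back(dZ3, s.Z3);
  gW[2] = dZ3 * s.K3.t();
  gb[2] = arma::sum(dZ3, 1);
  arma::mat dP2 = col2im3(getW(w, "c3_W").t() * dZ3, H4, W4, 2 * wdth);
  dA2 += pool2_back(dP2, H2, W2);
  arma::mat dZ2 = dA2;
  relu_back(dZ2, s.Z2);
  gW[1] = dZ2 * s.K2.t();
  gb[1] = arma::sum(dZ2, 1);
  arma::mat dP1 = col2im3(getW(w, "c2_W").t() * dZ2, H2, W2, wdth);
  dA1 += pool2_back(dP1, H, W);
  arma::mat dZ1 = dA1;
  relu_back(dZ1, s.Z1);
  gW[0] = dZ1 * s.K1.t();
  gb[0] = arma::sum(dZ1, 1);
}

static std::vector<std::string> param_stems(const std::string& family) {
  if (family == "unet_like")
    return {"enc1", "enc2", "bott", "dec2", "dec1", "head"};
  return {"c1", "c2", "c3", "l3", "l2", "l1", "smooth", "head"};
}

// [[Rcpp::export]]
arma::mat nn_forward_cpp(std::string family, List weights, arma::mat x,
                         int H, int W) {
  if (family == "unet_like") return unet_forward(weights, x, H, W, nullptr);
  if (family == "fpn_like") return fpn_forward(weights, x, H, W, nullptr);
  stop("unknown model family: %s", family.c_str());
}

// [[Rcpp::export]]
List nn_train_batch_cpp(std::string family, List weights, List xs, List gs,
                        List ms, arma::vec wclass, List loss_cfg_r,
                        int H, int W) {
  const LossCfg cfg = parse_cfg(loss_cfg_r);
  const int n = xs.size();
  if (n < 1) stop("empty batch");
  const bool is_unet = (family == "unet_like");
  if (!is_unet && family != "fpn_like")
    stop("unknown model family: %s", family.c_str());
  std::vector<std::string> stems = param_stems(family);
  const size_t np = stems.size();
  std::vector<arma::mat> accW(np), accb_m(np);
  double total_loss = 0.0;

  for (int b = 0; b < n; ++b) {
    arma::mat x = as<arma::mat>(xs[b]);
    arma::ivec g = as<arma::ivec>(gs[b]);
    arma::vec m = as<arma::vec>(ms[b]);
    arma::mat P, dP;
    UnetCache uc;
    FpnCache fc;
    if (is_unet)
      P = unet_forward(weights, x, H, W, &uc);
    else
      P = fpn_forward(weights, x, H, W, &fc);
    double L = loss_and_gradP(P, g, m, wclass, cfg, dP);
    if (!std::isfinite(L)) stop("non-finite loss in batch element %d", b + 1);
    total_loss += L;
    arma::mat dZh = softmax_back(P, dP);
    std::vector<arma::mat> gW(np);
    std::vector<arma::mat> gb(np);
    if (is_unet)
      unet_backward(weights, uc, dZh, H, W, gW, gb);
    else
      fpn_backward(weights, fc, dZh, H, W, gW, gb);
    for (size_t p = 0; p < np; ++p) {
      if (b == 0) {
        accW[p] = gW[p];
        accb_m[p] = gb[p];
      } else {
        accW[p] += gW[p];
        accb_m[p] += gb[p];
      }
    }
  }

  List grads;
  for (size_t p = 0; p < np; ++p) {
    grads[stems[p] + "_W"] = accW[p] / n;
    grads[stems[p] + "_b"] = arma::mat(accb_m[p]) / n;
  }
  return List::create(_["loss"] = total_loss / n, _["grads"] = grads);
}

// [[Rcpp::export]]
List nn_loss_cpp(std::string family, List weights, arma::mat x,
                 IntegerVector g, arma::vec m, arma::vec wclass,
                 List loss_cfg_r, int H, int W) {
  const LossCfg cfg = parse_cfg(loss_cfg_r);
  arma::mat P;
  if (family == "unet_like")
    P = unet_forward(weights, x, H, W, nullptr);
  else if (family == "fpn_like")
    P = fpn_forward(weights, x, H, W, nullptr);
  else
    stop("unknown model family: %s", family.c_str());
  arma::mat dP;
  arma::ivec gi = as<arma::ivec>(g);
  double L = loss_and_gradP(P, gi, m, wclass, cfg, dP);
  return List::create(_["loss"] = L, _["probs"] = P);
}
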