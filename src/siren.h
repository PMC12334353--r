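#ifndef USINR_SIREN_H
#define USINR_SIREN_H

#include <RcppArmadillo.h>
#include <vector>

// Harmonic positional encoding of normalized coordinates.
// Per coordinate: (x, sin(2^0 x), cos(2^0 x), ..., sin(2^{n-1} x), cos(2^{n-1} x)),
// features of the three coordinates concatenated. Output dim = 3*(1+2*bands).
template <typename eT>
arma::Mat<eT> pe_encode(const arma::Mat<eT>& coords, int bands) {
  const arma::uword n = coords.n_rows;
  const arma::uword per = 1 + 2 * (arma::uword)bands;
  arma::Mat<eT> out(n, 3 * per);
  for (arma::uword c = 0; c < 3; ++c) {
    arma::Col<eT> x = coords.col(c);
    arma::uword base = c * per;
    out.col(base) = x;
    eT k = 1;
    for (int j = 0; j < bands; ++j) {
      out.col(base + 1 + 2 * j)     = arma::sin(k * x);
      out.col(base + 2 + 2 * j)     = arma::cos(k * x);
      k *= 2;
    }
  }
  return out;
}

// Sine activation. The float path uses a range-reduced odd polynomial
// (max error ~3e-7, within float rounding) so the elementwise activations
// vectorize on the target ISA; it is the network's activation function,
// applied identically during training and evaluation.
inline float act_sin(float x) {
  float s = x * 0.15915494309189535f;      // x / (2 pi)
  float r = s + 12582912.0f; r -= 12582912.0f; // round to nearest integer
  s -= r;                                   // s in [-0.5, 0.5]
  float s2 = s * s;
  float p = -1.2372494818e+01f;
  p = p * s2 + 4.1269929568e+01f;
  p = p * s2 - 7.6594928217e+01f;
  p = p * s2 + 8.1597657876e+01f;
  p = p * s2 - 4.1341480356e+01f;
  p = p * s2 + 6.2831834664e+00f;
  return p * s;
}
inline double act_sin(double x) { return std::sin(x); }
inline float act_cos(float x) { return act_sin(x + 1.57079632679489662f); }
inline double act_cos(double x) { return std::cos(x); }

// SIREN MLP: layers 0..L-1 are linear maps (W: fan_in x fan_out); all but the
// last are followed by sin(omega * z). Additive skip connections join hidden
// activations j and j - skip_every (1-based hidden index, applied for j >= 3
// with (j - 1) %% skip_every == 0 when widths agree).
//
// The workspace owns every large intermediate so repeated steps of a
// training run reuse their allocations.
template <typename eT>
struct SirenWS {
  std::vector<arma::Mat<eT>> act;  // act[l] = input of layer l; act[L] = output
  std::vector<arma::Mat<eT>> D;    // omega * cos(omega * z) per hidden layer
  std::vector<arma::Mat<eT>> hg;   // backward skip-gradient accumulators
  std::vector<char> hg_valid;
  std::vector<int> skip_from;      // per hidden layer: source hidden index or 0
  arma::Mat<eT> dA, dZ;            // backward buffers
};

template <typename eT>
inline bool skip_here(int j, int skip_every, arma::uword w_this, arma::uword w_src) {
  return skip_every > 0 && j >= 3 && ((j - 1) % skip_every == 0) &&
         (j - skip_every) >= 1 && w_this == w_src;
}

// Forward pass; the result lives in ws.act[L]. `need_grad` also fills the
// activation-derivative cache used by siren_backward.
template <typename eT>
const arma::Mat<eT>& siren_forward(const std::vector<arma::Mat<eT>>& W,
                                   const std::vector<arma::Row<eT>>& b,
                                   const arma::Mat<eT>& feats,
                                   eT omega0, int skip_every,
                                   SirenWS<eT>& ws, bool need_grad = false) {
  const int L = (int)W.size();
  ws.act.resize(L + 1);
  ws.D.resize(L - 1);
  ws.skip_from.assign(L - 1, 0);
  ws.act[0] = feats;
  for (int l = 0; l < L; ++l) {
    arma::Mat<eT>& Z = ws.act[l + 1];
    Z = ws.act[l] * W[l];
    for (arma::uword j = 0; j < Z.n_cols; ++j) Z.col(j) += b[l][j];
    if (l == L - 1) break;
    int j = l + 1; // hidden index
    eT* zp = Z.memptr();
    const arma::uword ne = Z.n_elem;
    if (need_grad) {
      ws.D[l].set_size(Z.n_rows, Z.n_cols);
      eT* dp = ws.D[l].memptr();
      for (arma::uword i = 0; i < ne; ++i) {
        eT p = omega0 * zp[i];
        zp[i] = act_sin(p);
        dp[i] = omega0 * act_cos(p);
      }
    } else {
      for (arma::uword i = 0; i < ne; ++i) zp[i] = act_sin(omega0 * zp[i]);
    }
    if (skip_here<eT>(j, skip_every, Z.n_cols,
                      (j - skip_every) >= 1 ? ws.act[j - skip_every].n_cols : 0)) {
      Z += ws.act[j - skip_every];
      ws.skip_from[l] = j - skip_every;
    }
  }
  return ws.act[L];
}

// Backward pass: dOut is gradient w.r.t. network output. Fills gW, gb.
template <typename eT>
void siren_backward(const std::vector<arma::Mat<eT>>& W,
                    SirenWS<eT>& ws,
                    const arma::Mat<eT>& dOut,
                    std::vector<arma::Mat<eT>>& gW,
                    std::vector<arma::Row<eT>>& gb) {
  const int L = (int)W.size();
  gW.resize(L); gb.resize(L);
  ws.hg.resize(L - 1);
  ws.hg_valid.assign(L - 1, 0);
  for (int l = L - 1; l >= 0; --l) {
    if (l == L - 1) {
      gW[l] = ws.act[l].t() * dOut;
      gb[l] = arma::sum(dOut, 0);
      ws.dA = dOut * W[l].t();
      continue;
    }
    if (ws.hg_valid[l]) ws.dA += ws.hg[l];
    int src = ws.skip_from[l];
    if (src >= 1) {
      // skip source receives the same upstream gradient
      if (ws.hg_valid[src - 1]) ws.hg[src - 1] += ws.dA;
      else { ws.hg[src - 1] = ws.dA; ws.hg_valid[src - 1] = 1; }
    }
    ws.dZ = ws.dA % ws.D[l];
    gW[l] = ws.act[l].t() * ws.dZ;
    gb[l] = arma::sum(ws.dZ, 0);
    if (l > 0) ws.dA = ws.dZ * W[l].t();
  }
}

// ---- SSIM with a uniform win x win window, valid windows only ----

// Integral-image box sum over all complete windows: (R-w+1) x (C-w+1).
template <typename eT>
arma::Mat<eT> boxsum_valid(const arma::Mat<eT>& M, int w) {
  const arma::uword R = M.n_rows, C = M.n_cols;
  arma::Mat<eT> P(R + 1, C + 1, arma::fill::zeros);
  for (arma::uword j = 0; j < C; ++j)
    for (arma::uword i = 0; i < R; ++i)
      P(i + 1, j + 1) = M(i, j) + P(i, j + 1) + P(i + 1, j) - P(i, j);
  arma::Mat<eT> S(R - w + 1, C - w + 1);
  for (arma::uword j = 0; j < S.n_cols; ++j)
    for (arma::uword i = 0; i < S.n_rows; ++i)
      S(i, j) = P(i + w, j + w) - P(i, j + w) - P(i + w, j) + P(i, j);
  return S;
}

// Adjoint of boxsum_valid: out(q) = sum over windows covering q of G(window).
template <typename eT>
arma::Mat<eT> boxscatter(const arma::Mat<eT>& G, int w, arma::uword R, arma::uword C) {
  arma::Mat<eT> D(R + 1, C + 1, arma::fill::zeros);
  for (arma::uword j = 0; j < G.n_cols; ++j)
    for (arma::uword i = 0; i < G.n_rows; ++i) {
      eT g = G(i, j);
      D(i, j) += g; D(i + w, j) -= g; D(i, j + w) -= g; D(i + w, j + w) += g;
    }
  // 2D cumulative sum
  for (arma::uword j = 0; j <= C; ++j)
    for (arma::uword i = 1; i <= R; ++i) D(i, j) += D(i - 1, j);
  for (arma::uword j = 1; j <= C; ++j)
    for (arma::uword i = 0; i <= R; ++i) D(i, j) += D(i, j - 1);
  return D.submat(0, 0, R - 1, C - 1);
}

// Mean SSIM over valid windows; if grad != nullptr also d(meanSSIM)/dx.
template <typename eT>
eT ssim_value_grad(const arma::Mat<eT>& x, const arma::Mat<eT>& y,
                   int win, eT C1, eT C2, arma::Mat<eT>* grad) {
  const arma::uword R = x.n_rows, C = x.n_cols;
  const eT W2 = (eT)win * (eT)win;
  arma::Mat<eT> mx = boxsum_valid(x, win) / W2;
  arma::Mat<eT> my = boxsum_valid(y, win) / W2;
  arma::Mat<eT> sxx = boxsum_valid<eT>(x % x, win) / W2 - mx % mx;
  arma::Mat<eT> syy = boxsum_valid<eT>(y % y, win) / W2 - my % my;
  arma::Mat<eT> sxy = boxsum_valid<eT>(x % y, win) / W2 - mx % my;
  arma::Mat<eT> A1 = 2 * mx % my + C1;
  arma::Mat<eT> A2 = 2 * sxy + C2;
  arma::Mat<eT> B1 = mx % mx + my % my + C1;
  arma::Mat<eT> B2 = sxx + syy + C2;
  arma::Mat<eT> S = (A1 % A2) / (B1 % B2);
  const eT nw = (eT)S.n_elem;
  eT val = arma::accu(S) / nw;
  if (grad) {
    arma::Mat<eT> Gmu = 2 * my % A2 / (B1 % B2) - 2 * mx % (A1 % A2) / (B1 % B1 % B2);
    arma::Mat<eT> Gs  = -(A1 % A2) / (B1 % B2 % B2);
    arma::Mat<eT> Gxy = 2 * A1 / (B1 % B2);
    arma::Mat<eT> S1 = boxscatter<eT>(Gmu - 2 * Gs % mx - Gxy % my, win, R, C);
    arma::Mat<eT> S2 = boxscatter<eT>(Gs, win, R, C);
    arma::Mat<eT> S3 = boxscatter<eT>(Gxy, win, R, C);
    *grad = (S1 + 2 * x % S2 + y % S3) / (nw * W2);
  }
  return val;
}

#endif
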