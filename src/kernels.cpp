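// [[Rcpp::depends(RcppArmadillo)]]
#include "siren.h"
using namespace Rcpp;

typedef arma::fmat fmat;
typedef arma::frowvec frow;

static std::vector<fmat> weights_to_f(const List& W) {
  std::vector<fmat> out(W.size());
  for (int i = 0; i < W.size(); ++i)
    out[i] = arma::conv_to<fmat>::from(as<arma::mat>(W[i]));
  return out;
}
static std::vector<frow> biases_to_f(const List& b) {
  std::vector<frow> out(b.size());
  for (int i = 0; i < b.size(); ++i)
    out[i] = arma::conv_to<frow>::from(as<arma::rowvec>(b[i]));
  return out;
}

// [[Rcpp::export]]
NumericMatrix cpp_inr_forward(List W, List b, NumericMatrix coords,
                              int pe_bands, double omega0, int skip_every) {
  std::vector<fmat> Wf = weights_to_f(W);
  std::vector<frow> bf = biases_to_f(b);
  fmat X = arma::conv_to<fmat>::from(as<arma::mat>(coords));
  fmat feats = pe_encode<float>(X, pe_bands);
  SirenWS<float> ws;
  const fmat& out = siren_forward<float>(Wf, bf, feats, (float)omega0, skip_every, ws);
  arma::mat res = arma::conv_to<arma::mat>::from(out);
  // mask head -> probability
  res.col(1) = 1.0 / (1.0 + arma::exp(-res.col(1)));
  return wrap(res);
}

// Standard deviation of the scaled pre-activations (omega * z) of every
// hidden layer, used to check the SIREN initialization property.
// [[Rcpp::export]]
NumericVector cpp_hidden_preact_sd(List W, List b, NumericMatrix coords,
                                   int pe_bands, double omega0, int skip_every) {
  std::vector<fmat> Wf = weights_to_f(W);
  std::vector<frow> bf = biases_to_f(b);
  fmat X = arma::conv_to<fmat>::from(as<arma::mat>(coords));
  fmat A = pe_encode<float>(X, pe_bands);
  const int L = (int)Wf.size();
  std::vector<fmat> hidden(L - 1);
  NumericVector sds(L - 1);
  for (int l = 0; l < L - 1; ++l) {
    fmat Z = A * Wf[l];
    Z.each_row() += bf[l];
    fmat P = (float)omega0 * Z;
    sds[l] = arma::stddev(arma::vectorise(P));
    fmat H = arma::sin(P);
    int j = l + 1;
    if (skip_here<float>(j, skip_every, H.n_cols,
                         (j - skip_every) >= 1 ? hidden[j - skip_every - 1].n_cols : 0))
      H += hidden[j - skip_every - 1];
    hidden[j - 1] = H;
    A = H;
  }
  return sds;
}

// ---- training data held in C++ (positional-encoded features as float) ----

struct TrainData {
  std::vector<fmat> feats;
  std::vector<arma::fvec> img;
  std::vector<arma::fvec> mask;
  int rows, cols;
};

// [[Rcpp::export]]
SEXP cpp_make_train_data(List coord_list, List img_list, List mask_list,
                         int pe_bands, int rows, int cols) {
  XPtr<TrainData> ptr(new TrainData(), true);
  int n = coord_list.size();
  ptr->rows = rows; ptr->cols = cols;
  ptr->feats.resize(n); ptr->img.resize(n); ptr->mask.resize(n);
  for (int i = 0; i < n; ++i) {
    fmat X = arma::conv_to<fmat>::from(as<arma::mat>(coord_list[i]));
    ptr->feats[i] = pe_encode<float>(X, pe_bands);
    ptr->img[i]  = arma::conv_to<arma::fvec>::from(as<arma::vec>(img_list[i]));
    ptr->mask[i] = arma::conv_to<arma::fvec>::from(as<arma::vec>(mask_list[i]));
  }
  return ptr;
}

// Losses and dOut for one batch of whole frames; returns (loss_image, loss_seg).
static std::pair<double, double> batch_losses(const TrainData& data,
                                              const int* ids, int F,
                                              const fmat& out, fmat& dOut,
                                              int win, float C1, float C2,
                                              float w_image, float w_seg, float fe) {
  const int R = data.rows, C = data.cols, npix = R * C;
  double loss_image = 0.0, loss_seg = 0.0;
  dOut.zeros(out.n_rows, 2);
  for (int f = 0; f < F; ++f) {
    const int off = f * npix;
    const arma::fvec& yI = data.img[ids[f]];
    const arma::fvec& yM = data.mask[ids[f]];
    // image loss: 1 - SSIM on the frame raster (column-major pixel order)
    fmat predI(const_cast<float*>(out.colptr(0)) + off, R, C, false);
    fmat target(const_cast<float*>(yI.memptr()), R, C, false);
    fmat gradS;
    float s = ssim_value_grad<float>(predI, target, win, C1, C2,
                                     w_image > 0 ? &gradS : nullptr);
    loss_image += 1.0 - (double)s;
    if (w_image > 0) {
      const float sc = -w_image / F;
      for (int j = 0; j < npix; ++j) dOut(off + j, 0) = sc * gradS(j);
    }
    // segmentation loss on the mask head
    arma::fvec z = out.submat(off, 1, off + npix - 1, 1);
    arma::fvec x = 1.0f / (1.0f + arma::exp(-z));
    arma::fvec xc = arma::clamp(x, fe, 1.0f - fe);
    float n = (float)npix;
    float bce = -arma::mean(yM % arma::log(xc) + (1.0f - yM) % arma::log(1.0f - xc));
    const float smooth = 1e-6f;
    float num = 2.0f * (arma::dot(x, yM) + smooth);
    float den = arma::accu(x) + arma::accu(yM) + smooth;
    float diceterm = 1.0f - num / den;
    float fp = arma::mean(x % (1.0f - yM));
    loss_seg += (double)(bce + diceterm + fp);
    if (w_seg > 0) {
      // BCE through the logits: d/dz = (x - y)/n, stable under saturation
      arma::fvec dze = (x - yM) / n;
      arma::fvec dxd = (num - 2.0f * yM * den) / (den * den);                  // Dice
      arma::fvec dxf = (1.0f - yM) / n;                                        // FP
      arma::fvec dz = (dze + (dxd + dxf) % (x % (1.0f - x))) * (w_seg / F);
      for (int j = 0; j < npix; ++j) dOut(off + j, 1) = dz(j);
    }
  }
  return {loss_image / F, loss_seg / F};
}

// Full training run: whole-frame batches, SSIM + BCE/Dice/FP losses, Adam
// with gradient EMA filtering. Frame shuffles (one row per epoch, 0-based)
// and the per-epoch learning rates are supplied by the caller so all
// randomness stays under R's RNG. Weights stay in float throughout.
// [[Rcpp::export]]
List cpp_train_run(SEXP data_ptr, List W0, List b0,
                   IntegerMatrix perms, NumericVector lrs, int fps,
                   double omega0, int skip_every,
                   int win, double C1, double C2,
                   double w_image, double w_seg, double eps,
                   double gf_alpha, double gf_lambda) {
  XPtr<TrainData> data(data_ptr);
  std::vector<fmat> W = weights_to_f(W0);
  std::vector<frow> b = biases_to_f(b0);
  const int L = (int)W.size();
  const int n_frames = perms.ncol(), epochs = perms.nrow();
  const int npix = data->rows * data->cols;

  // optimizer state
  std::vector<fmat> mW(L), vW(L), eW(L), gW;
  std::vector<frow> mB(L), vB(L), eB(L), gb;
  for (int l = 0; l < L; ++l) {
    mW[l].zeros(arma::size(W[l])); vW[l].zeros(arma::size(W[l]));
    eW[l].zeros(arma::size(W[l]));
    mB[l].zeros(arma::size(b[l])); vB[l].zeros(arma::size(b[l]));
    eB[l].zeros(arma::size(b[l]));
  }
  const float b1 = 0.9f, b2 = 0.999f, aeps = 1e-8f;
  const float ga = (float)gf_alpha, gl = (float)gf_lambda;
  long t = 0;

  SirenWS<float> ws;
  fmat feats, dOut;
  NumericMatrix log(epochs, 2);

  for (int e = 0; e < epochs; ++e) {
    const float lr = (float)lrs[e];
    double li = 0, ls = 0;
    int nst = 0;
    for (int s0 = 0; s0 < n_frames; s0 += fps) {
      const int F = std::min(fps, n_frames - s0);
      std::vector<int> ids(F);
      for (int f = 0; f < F; ++f) ids[f] = perms(e, s0 + f);
      feats.set_size(F * npix, data->feats[0].n_cols);
      for (int f = 0; f < F; ++f)
        feats.rows(f * npix, (f + 1) * npix - 1) = data->feats[ids[f]];
      const fmat& out = siren_forward<float>(W, b, feats, (float)omega0,
                                             skip_every, ws, true);
      auto lo = batch_losses(*data, ids.data(), F, out, dOut, win,
                             (float)C1, (float)C2, (float)w_image, (float)w_seg,
                             (float)eps);
      li += lo.first; ls += lo.second; ++nst;
      siren_backward<float>(W, ws, dOut, gW, gb);
      ++t;
      const float bc1 = 1.0f - std::pow(b1, (float)t);
      const float bc2 = 1.0f - std::pow(b2, (float)t);
      for (int l = 0; l < L; ++l) {
        fmat g = gW[l];
        if (gl > 0) { eW[l] = ga * eW[l] + (1 - ga) * g; g += gl * eW[l]; }
        mW[l] = b1 * mW[l] + (1 - b1) * g;
        vW[l] = b2 * vW[l] + (1 - b2) * arma::square(g);
        W[l] -= lr * (mW[l] / bc1) / (arma::sqrt(vW[l] / bc2) + aeps);
        frow gbv = gb[l];
        if (gl > 0) { eB[l] = ga * eB[l] + (1 - ga) * gbv; gbv += gl * eB[l]; }
        mB[l] = b1 * mB[l] + (1 - b1) * gbv;
        vB[l] = b2 * vB[l] + (1 - b2) * arma::square(gbv);
        b[l] -= lr * (mB[l] / bc1) / (arma::sqrt(vB[l] / bc2) + aeps);
      }
    }
    log(e, 0) = li / nst; log(e, 1) = ls / nst;
    if (!std::isfinite(log(e, 0)) || !std::isfinite(log(e, 1)))
      stop("non-finite loss at epoch %d", e);
    Rcpp::checkUserInterrupt();
  }

  List Wl(L), bl(L);
  for (int l = 0; l < L; ++l) {
    Wl[l] = wrap(arma::conv_to<arma::mat>::from(W[l]));
    bl[l] = wrap(arma::conv_to<arma::rowvec>::from(b[l]));
  }
  return List::create(_["W"] = Wl, _["b"] = bl, _["log"] = log);
}

// ---- double-precision SSIM for the user-facing objective ----

// [[Rcpp::export]]
double cpp_ssim(NumericMatrix x, NumericMatrix y, int win, double C1, double C2) {
  arma::mat X = as<arma::mat>(x), Y = as<arma::mat>(y);
  return ssim_value_grad<double>(X, Y, win, C1, C2, nullptr);
}

// [[Rcpp::export]]
List cpp_ssim_grad(NumericMatrix x, NumericMatrix y, int win, double C1, double C2) {
  arma::mat X = as<arma::mat>(x), Y = as<arma::mat>(y), G;
  double v = ssim_value_grad<double>(X, Y, win, C1, C2, &G);
  return List::create(_["value"] = v, _["grad"] = wrap(G));
}
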