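// Single-layer LSTM (tanh gates/candidate, linear output head) trained with
// MAE loss via full backpropagation through time and Adam updates.
// All randomness (weight init, minibatch order) is supplied from R so that
// training is reproducible from a single integer seed.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace arma;

static inline mat sigm(const mat& x) { return 1.0 / (1.0 + exp(-x)); }

struct Weights {
  mat Wx;   // 1 x 4H
  mat Wh;   // H x 4H
  rowvec b; // 4H
  vec Wy;   // H
  double by;
};

static Weights as_weights(const Rcpp::List& w) {
  Weights out;
  out.Wx = Rcpp::as<mat>(w["Wx"]);
  out.Wh = Rcpp::as<mat>(w["Wh"]);
  out.b = Rcpp::as<rowvec>(w["b"]);
  out.Wy = Rcpp::as<vec>(w["Wy"]);
  out.by = Rcpp::as<double>(w["by"]);
  return out;
}

static Rcpp::List weights_list(const Weights& w) {
  return Rcpp::List::create(
      Rcpp::Named("Wx") = w.Wx, Rcpp::Named("Wh") = w.Wh,
      Rcpp::Named("b") = w.b, Rcpp::Named("Wy") = w.Wy,
      Rcpp::Named("by") = w.by);
}

// forward pass without gradient bookkeeping; X is N x T
static vec forward_predict(const Weights& w, const mat& X) {
  const uword N = X.n_rows, T = X.n_cols, H = w.Wh.n_rows;
  mat h(N, H, fill::zeros), c(N, H, fill::zeros);
  for (uword t = 0; t < T; ++t) {
    mat G = X.col(t) * w.Wx + h * w.Wh;
    G.each_row() += w.b;
    mat gi = sigm(G.cols(0, H - 1));
    mat gf = sigm(G.cols(H, 2 * H - 1));
    mat gg = tanh(G.cols(2 * H, 3 * H - 1));
    mat go = sigm(G.cols(3 * H, 4 * H - 1));
    c = gf % c + gi % gg;
    h = go % tanh(c);
  }
  return h * w.Wy + w.by;
}

// [[Rcpp::export]]
arma::vec lstm_predict_cpp(const Rcpp::List& weights, const arma::mat& X) {
  return forward_predict(as_weights(weights), X);
}

struct Adam {
  mat mWx, vWx, mWh, vWh;
  rowvec mb, vb;
  vec mWy, vWy;
  double mby = 0, vby = 0;
  long step = 0;
  explicit Adam(const Weights& w) {
    mWx = zeros(size(w.Wx)); vWx = mWx;
    mWh = zeros(size(w.Wh)); vWh = mWh;
    mb = zeros<rowvec>(w.b.n_elem); vb = mb;
    mWy = zeros(size(w.Wy)); vWy = mWy;
  }
};

static void adam_update(mat& w, mat& m, mat& v, const mat& g, double lr,
                        double c1, double c2) {
  m = 0.9 * m + 0.1 * g;
  v = 0.999 * v + 0.001 * (g % g);
  w -= lr * (m / c1) / (sqrt(v / c2) + 1e-8);
}

// [[Rcpp::export]]
Rcpp::List lstm_train_cpp(const arma::mat& X, const arma::vec& y,
                          const arma::mat& Xval, const arma::vec& yval,
                          const Rcpp::List& init, int max_epochs, int patience,
                          int batch_size, double lr,
                          const arma::umat& order, double clip = 5.0,
                          double tol = 1e-5) {
  Weights w = as_weights(init);
  const uword N = X.n_rows, T = X.n_cols, H = w.Wh.n_rows;
  Adam opt(w);

  Weights best = w;
  double best_val = datum::inf;
  int best_epoch = 0, stall = 0;
  std::vector<double> hist_val, hist_train;

  for (int epoch = 0; epoch < max_epochs; ++epoch) {
    uvec perm = order.col(epoch % order.n_cols) - 1; // 1-based from R
    double train_abs = 0.0;
    for (uword start = 0; start < N; start += batch_size) {
      uword stop = std::min<uword>(start + batch_size, N) - 1;
      uvec idx = perm.subvec(start, stop);
      const uword n = idx.n_elem;
      mat Xb = X.rows(idx);
      vec yb = y(idx);

      // forward with stored activations
      cube Hs(n, H, T + 1, fill::zeros), Cs(n, H, T + 1, fill::zeros);
      cube Gi(n, H, T), Gf(n, H, T), Gg(n, H, T), Go(n, H, T), Tc(n, H, T);
      for (uword t = 0; t < T; ++t) {
        mat G = Xb.col(t) * w.Wx + Hs.slice(t) * w.Wh;
        G.each_row() += w.b;
        Gi.slice(t) = sigm(G.cols(0, H - 1));
        Gf.slice(t) = sigm(G.cols(H, 2 * H - 1));
        Gg.slice(t) = tanh(G.cols(2 * H, 3 * H - 1));
        Go.slice(t) = sigm(G.cols(3 * H, 4 * H - 1));
        Cs.slice(t + 1) = Gf.slice(t) % Cs.slice(t) + Gi.slice(t) % Gg.slice(t);
        Tc.slice(t) = tanh(Cs.slice(t + 1));
        Hs.slice(t + 1) = Go.slice(t) % Tc.slice(t);
      }
      vec yhat = Hs.slice(T) * w.Wy + w.by;
      vec resid = yhat - yb;
      train_abs += accu(abs(resid));

      // backward (MAE loss)
      vec dyhat = sign(resid) / double(n);
      vec gWy = Hs.slice(T).t() * dyhat;
      double gby = accu(dyhat);
      mat gWx = zeros(size(w.Wx));
      mat gWh = zeros(size(w.Wh));
      rowvec gb = zeros<rowvec>(4 * H);
      mat dH = dyhat * w.Wy.t();
      mat dC(n, H, fill::zeros);
      mat dGates(n, 4 * H);
      for (int t = T - 1; t >= 0; --t) {
        const mat& gi = Gi.slice(t);
        const mat& gf = Gf.slice(t);
        const mat& gg = Gg.slice(t);
        const mat& go = Go.slice(t);
        const mat& tc = Tc.slice(t);
        mat dO = dH % tc;
        dC += dH % go % (1.0 - tc % tc);
        dGates.cols(0, H - 1) = (dC % gg) % gi % (1.0 - gi);
        dGates.cols(H, 2 * H - 1) = (dC % Cs.slice(t)) % gf % (1.0 - gf);
        dGates.cols(2 * H, 3 * H - 1) = (dC % gi) % (1.0 - gg % gg);
        dGates.cols(3 * H, 4 * H - 1) = dO % go % (1.0 - go);
        gWx += Xb.col(t).t() * dGates;
        gWh += Hs.slice(t).t() * dGates;
        gb += sum(dGates, 0);
        dH = dGates * w.Wh.t();
        dC = dC % gf;
      }

      // global-norm gradient clipping for stability
      double nrm = std::sqrt(accu(gWx % gWx) + accu(gWh % gWh) +
                             accu(gb % gb) + accu(gWy % gWy) + gby * gby);
      if (nrm > clip) {
        double s = clip / nrm;
        gWx *= s; gWh *= s; gb *= s; gWy *= s; gby *= s;
      }

      opt.step += 1;
      double c1 = 1.0 - std::pow(0.9, (double)opt.step);
      double c2 = 1.0 - std::pow(0.999, (double)opt.step);
      adam_update(w.Wx, opt.mWx, opt.vWx, gWx, lr, c1, c2);
      adam_update(w.Wh, opt.mWh, opt.vWh, gWh, lr, c1, c2);
      {
        opt.mb = 0.9 * opt.mb + 0.1 * gb;
        opt.vb = 0.999 * opt.vb + 0.001 * (gb % gb);
        w.b -= lr * (opt.mb / c1) / (sqrt(opt.vb / c2) + 1e-8);
        opt.mWy = 0.9 * opt.mWy + 0.1 * gWy;
        opt.vWy = 0.999 * opt.vWy + 0.001 * (gWy % gWy);
        w.Wy -= lr * (opt.mWy / c1) / (sqrt(opt.vWy / c2) + 1e-8);
        opt.mby = 0.9 * opt.mby + 0.1 * gby;
        opt.vby = 0.999 * opt.vby + 0.001 * (gby * gby);
        w.by -= lr * (opt.mby / c1) / (std::sqrt(opt.vby / c2) + 1e-8);
      }
    }
    hist_train.push_back(train_abs / double(N));

    double val_mae = mean(abs(forward_predict(w, Xval) - yval));
    hist_val.push_back(val_mae);
    if (val_mae < best_val - tol) {
      best_val = val_mae;
      best = w;
      best_epoch = epoch + 1;
      stall = 0;
    } else {
      ++stall;
      if (stall >= patience) break;
    }
  }

  return Rcpp::List::create(
      Rcpp::Named("weights") = weights_list(best),
      Rcpp::Named("val_mae") = best_val,
      Rcpp::Named("best_epoch") = best_epoch,
      Rcpp::Named("history_val") = hist_val,
      Rcpp::Named("history_train") = hist_train);
}
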