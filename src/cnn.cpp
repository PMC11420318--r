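// Small 1-D convolutional regression network used for amortized parameter
// estimation: stacked conv(kernel k, same padding) + ReLU + max-pool(2)
// blocks, a final conv + ReLU + global average pooling, and a linear head.
// Trained with Adam on mean-squared error over range-normalized parameters.
// Convolutions are evaluated as k shifted GEMMs over a zero-padded signal,
// which keeps all inner loops inside BLAS.  All randomness (weight init,
// minibatch shuffling) uses R's RNG.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;
using arma::mat;
using arma::uword;

struct Adam {
  mat m, v; int t = 0;
  void step(mat& w, const mat& g, double lr) {
    if (m.n_elem == 0) { m.zeros(w.n_rows, w.n_cols); v.zeros(w.n_rows, w.n_cols); }
    ++t;
    m = 0.9 * m + 0.1 * g;
    v = 0.999 * v + 0.001 * (g % g);
    double bc1 = 1.0 - std::pow(0.9, t), bc2 = 1.0 - std::pow(0.999, t);
    w -= lr * (m / bc1) / (arma::sqrt(v / bc2) + 1e-8);
  }
};

struct Net {
  std::vector<mat> W, b;   // conv weights (C_out x C_in*k), biases (C_out x 1)
  mat Wd, bd;              // linear head
  std::vector<int> ks;     // per-layer kernel widths (odd)
};

// per-sample forward pass; optionally records intermediates for backprop
struct Trace {
  std::vector<mat> pad;    // zero-padded layer inputs (C_in x L+k-1)
  std::vector<mat> act;    // post-ReLU activations (C_out x L)
  std::vector<arma::umat> arg;  // max-pool argmax (source column per entry)
};

static arma::vec forward_one(const Net& net, const mat& x0, Trace* tr) {
  int nl = net.W.size();
  mat A = x0;
  for (int l = 0; l < nl; ++l) {
    int k = net.ks[l];
    int cin = A.n_rows, L = A.n_cols, cout = net.W[l].n_rows;
    mat P(cin, L + k - 1, arma::fill::zeros);
    P.cols((k - 1) / 2, (k - 1) / 2 + L - 1) = A;
    mat Y(cout, L);
    Y.each_col() = net.b[l].col(0);
    for (int kk = 0; kk < k; ++kk)
      Y += net.W[l].cols(kk * cin, (kk + 1) * cin - 1) * P.cols(kk, kk + L - 1);
    Y.transform([](double z) { return z > 0 ? z : 0.0; });
    if (tr) { tr->pad.push_back(P); tr->act.push_back(Y); }
    if (l < nl - 1) {                    // max-pool width 2, stride 2
      int Lo = L / 2;
      mat O(cout, Lo);
      arma::umat arg(cout, Lo);
      for (int p = 0; p < Lo; ++p)
        for (int r = 0; r < cout; ++r) {
          if (Y(r, 2 * p + 1) > Y(r, 2 * p)) { O(r, p) = Y(r, 2 * p + 1); arg(r, p) = 2 * p + 1; }
          else { O(r, p) = Y(r, 2 * p); arg(r, p) = 2 * p; }
        }
      if (tr) tr->arg.push_back(arg);
      A = O;
    } else {
      A = Y;
    }
  }
  // flatten the last activation map: after sorting, position within a
  // channel is the quantile level, so spatial position must be preserved
  arma::vec feat = arma::vectorise(A);
  return net.Wd * feat + net.bd.col(0);
}

// gradient accumulation for one sample; returns squared-error sum
static double backward_one(const Net& net, const mat& x0, const arma::vec& y,
                           std::vector<mat>& gW, std::vector<mat>& gb,
                           mat& gWd, mat& gbd) {
  int nl = net.W.size();
  Trace tr;
  arma::vec out = forward_one(net, x0, &tr);
  arma::vec diff = out - y;
  double se = arma::dot(diff, diff);

  const mat& last = tr.act[nl - 1];
  arma::vec feat = arma::vectorise(last);
  gWd += diff * feat.t();
  gbd += diff;

  arma::vec dfeat = net.Wd.t() * diff;
  mat dA = arma::reshape(dfeat, last.n_rows, last.n_cols);

  for (int l = nl - 1; l >= 0; --l) {
    // dA is gradient w.r.t. post-ReLU activation of layer l
    int k = net.ks[l], pad0 = (k - 1) / 2;
    mat dY = dA % arma::conv_to<mat>::from(tr.act[l] > 0);
    int L = dY.n_cols, cin = tr.pad[l].n_rows;
    gb[l] += arma::sum(dY, 1);
    mat dP(cin, L + k - 1, arma::fill::zeros);
    for (int kk = 0; kk < k; ++kk) {
      gW[l].cols(kk * cin, (kk + 1) * cin - 1) +=
        dY * tr.pad[l].cols(kk, kk + L - 1).t();
      dP.cols(kk, kk + L - 1) +=
        net.W[l].cols(kk * cin, (kk + 1) * cin - 1).t() * dY;
    }
    if (l == 0) break;
    mat dPool = dP.cols(pad0, pad0 + L - 1);   // gradient w.r.t. pooled output
    const arma::umat& arg = tr.arg[l - 1];
    mat dPrev(tr.act[l - 1].n_rows, tr.act[l - 1].n_cols, arma::fill::zeros);
    for (uword p = 0; p < arg.n_cols; ++p)
      for (uword r = 0; r < arg.n_rows; ++r)
        dPrev(r, arg(r, p)) += dPool(r, p);
    dA = dPrev;
  }
  return se;
}

static List net_to_list(const Net& net) {
  List Ws(net.W.size()), bs(net.b.size());
  for (size_t i = 0; i < net.W.size(); ++i) { Ws[i] = wrap(net.W[i]); bs[i] = wrap(net.b[i]); }
  return List::create(_["W"] = Ws, _["b"] = bs, _["Wd"] = wrap(net.Wd),
                      _["bd"] = wrap(net.bd),
                      _["kernel"] = IntegerVector(net.ks.begin(), net.ks.end()));
}

static Net list_to_net(const List& l) {
  Net net;
  List Ws = l["W"], bs = l["b"];
  for (int i = 0; i < Ws.size(); ++i) {
    net.W.push_back(as<mat>(Ws[i]));
    net.b.push_back(as<mat>(bs[i]));
  }
  net.Wd = as<mat>(l["Wd"]); net.bd = as<mat>(l["bd"]);
  IntegerVector ks = l["kernel"];
  if (ks.size() == 1) net.ks.assign(net.W.size(), ks[0]);
  else for (int i = 0; i < ks.size(); ++i) net.ks.push_back(ks[i]);
  return net;
}

// X: n x (C*L), rows are channel-major flattened encodings; Y: n x m.
// [[Rcpp::export(name = ".cnn_train_cpp")]]
List cnn_train_cpp(NumericMatrix Xr, NumericMatrix Yr, int C, int L,
                   IntegerVector filters, IntegerVector kernels, int epochs,
                   int batch, double lr, double lr_decay, int n_val,
                   int patience, bool verbose) {
  int n = Xr.nrow(), m = Yr.ncol();
  mat X(Xr.begin(), n, Xr.ncol());
  mat Y(Yr.begin(), n, m);
  int nl = filters.size();

  Net net;
  for (int l = 0; l < nl; ++l)
    net.ks.push_back(kernels[kernels.size() == 1 ? 0 : l]);
  int cin = C;
  for (int l = 0; l < nl; ++l) {
    int cout = filters[l], kernel = net.ks[l];
    mat W(cout, cin * kernel), b(cout, 1, arma::fill::zeros);
    double sdv = std::sqrt(2.0 / (cin * kernel));
    for (uword i = 0; i < W.n_elem; ++i) W(i) = sdv * norm_rand();
    net.W.push_back(W); net.b.push_back(b);
    cin = cout;
  }
  int Lf = L;
  for (int l = 0; l < nl - 1; ++l) Lf /= 2;  // one pool between conv layers
  net.Wd.set_size(m, cin * Lf);
  double sdd = std::sqrt(1.0 / (cin * Lf));
  for (uword i = 0; i < net.Wd.n_elem; ++i) net.Wd(i) = sdd * norm_rand();
  net.bd.zeros(m, 1);

  int ntr = n - n_val;                 // validation split: last n_val rows
  if (ntr < batch) stop("too few training samples for the batch size");

  std::vector<Adam> optW(nl), optB(nl);
  Adam optWd, optBd;
  std::vector<double> tr_hist, val_hist;
  Net best = net;
  double best_val = arma::datum::inf;
  int bad = 0;

  std::vector<int> order(ntr);
  for (int i = 0; i < ntr; ++i) order[i] = i;

  auto sample_mat = [&](int idx) -> mat {
    arma::rowvec r = X.row(idx);
    return mat(r.memptr(), C, L);   // column-major: channel index fastest
  };
  auto eval_val = [&]() {
    if (n_val == 0) return arma::datum::nan;
    double acc = 0;
    for (int i = 0; i < n_val; ++i) {
      arma::vec out = forward_one(net, sample_mat(ntr + i), nullptr);
      arma::vec yv = Y.row(ntr + i).t();
      acc += arma::accu(arma::square(out - yv));
    }
    return acc / (n_val * m);
  };

  for (int ep = 0; ep < epochs; ++ep) {
    double lr_ep = lr * std::pow(lr_decay, ep);
    for (int i = ntr - 1; i > 0; --i) {        // Fisher-Yates with R's RNG
      int j = (int)std::floor(unif_rand() * (i + 1));
      if (j > i) j = i;
      std::swap(order[i], order[j]);
    }
    double ep_loss = 0; int nb = 0;
    std::vector<mat> gW(nl), gb(nl);
    mat gWd, gbd;
    for (int start = 0; start + batch <= ntr; start += batch) {
      for (int l = 0; l < nl; ++l) {
        gW[l].zeros(net.W[l].n_rows, net.W[l].n_cols);
        gb[l].zeros(net.b[l].n_rows, 1);
      }
      gWd.zeros(net.Wd.n_rows, net.Wd.n_cols);
      gbd.zeros(m, 1);
      double se = 0;
      for (int bb = 0; bb < batch; ++bb) {
        int idx = order[start + bb];
        arma::vec yv = Y.row(idx).t();
        se += backward_one(net, sample_mat(idx), yv, gW, gb, gWd, gbd);
      }
      double loss = se / (m * batch);
      if (!std::isfinite(loss)) stop("training diverged (non-finite loss)");
      ep_loss += loss; ++nb;
      double sc = 2.0 / (m * batch);           // d(MSE)/d(sum of squares)
      for (int l = 0; l < nl; ++l) {
        optW[l].step(net.W[l], sc * gW[l], lr_ep);
        optB[l].step(net.b[l], sc * gb[l], lr_ep);
      }
      optWd.step(net.Wd, sc * gWd, lr_ep);
      optBd.step(net.bd, sc * gbd, lr_ep);
      if (nb % 20 == 0) Rcpp::checkUserInterrupt();
    }
    ep_loss /= std::max(nb, 1);
    double vl = eval_val();
    tr_hist.push_back(ep_loss); val_hist.push_back(vl);
    if (verbose)
      Rprintf("epoch %d  train %.5f  val %.5f\n", ep + 1, ep_loss, vl);
    if (n_val > 0) {
      if (vl < best_val - 1e-6) { best_val = vl; best = net; bad = 0; }
      else if (++bad >= patience) break;
    } else {
      best = net;
    }
  }
  List out = net_to_list(best);
  out["train_loss"] = tr_hist;
  out["val_loss"] = val_hist;
  return out;
}

// [[Rcpp::export(name = ".cnn_predict_cpp")]]
NumericMatrix cnn_predict_cpp(List weights, NumericMatrix Xr, int C, int L) {
  Net net = list_to_net(weights);
  int n = Xr.nrow();
  mat X(Xr.begin(), n, Xr.ncol());
  int m = net.Wd.n_rows;
  NumericMatrix out(n, m);
  for (int i = 0; i < n; ++i) {
    arma::rowvec r = X.row(i);
    mat x0(r.memptr(), C, L);       // column-major: channel index fastest
    arma::vec pred = forward_one(net, x0, nullptr);
    for (int j = 0; j < m; ++j) out(i, j) = pred(j);
  }
  return out;
}
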