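// Core of the per-sensor branched feed-forward network: forward pass,
// analytic backprop gradients of the half-MSE training cost, and the
// minibatch SGD/Adam training loop. Parameters are exchanged with R as a
// list: params$branches[[b]][[l]] = list(theta = out x in, bias = out),
// params$head = list(theta = f x concat, bias = f). Feature columns of X
// are partitioned per branch by `branch_cols` (1-based index vectors).

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;
using arma::mat;
using arma::vec;
using arma::uvec;

namespace {

struct Net {
  std::vector<std::vector<mat>> W;   // per branch, per hidden layer
  std::vector<std::vector<vec>> b;
  mat Wh;                            // linear output head
  vec bh;
  std::vector<uvec> cols;            // 0-based feature columns per branch
};

Net parse_net(const List& params, const List& branch_cols) {
  Net net;
  List branches = params["branches"];
  for (int i = 0; i < branches.size(); ++i) {
    List layers = branches[i];
    std::vector<mat> Ws;
    std::vector<vec> bs;
    for (int l = 0; l < layers.size(); ++l) {
      List lay = layers[l];
      Ws.push_back(as<mat>(lay["theta"]));
      bs.push_back(as<vec>(lay["bias"]));
    }
    net.W.push_back(Ws);
    net.b.push_back(bs);
  }
  List head = params["head"];
  net.Wh = as<mat>(head["theta"]);
  net.bh = as<vec>(head["bias"]);
  for (int i = 0; i < branch_cols.size(); ++i) {
    IntegerVector ci = branch_cols[i];
    uvec u(ci.size());
    for (int j = 0; j < ci.size(); ++j) u[j] = ci[j] - 1;
    net.cols.push_back(u);
  }
  return net;
}

List wrap_net(const Net& net) {
  List branches(net.W.size());
  for (size_t i = 0; i < net.W.size(); ++i) {
    List layers(net.W[i].size());
    for (size_t l = 0; l < net.W[i].size(); ++l) {
      layers[l] = List::create(_["theta"] = net.W[i][l],
                               _["bias"] = net.b[i][l]);
    }
    branches[i] = layers;
  }
  return List::create(
      _["branches"] = branches,
      _["head"] = List::create(_["theta"] = net.Wh, _["bias"] = net.bh));
}

// Forward pass; optionally keeps per-layer activations for backprop.
mat forward(const Net& net, const mat& X,
            std::vector<std::vector<mat>>* acts = nullptr) {
  const size_t S = net.W.size();
  mat C;
  if (acts) acts->assign(S, {});
  for (size_t s = 0; s < S; ++s) {
    mat A = X.cols(net.cols[s]);
    if (acts) (*acts)[s].push_back(A);
    for (size_t l = 0; l < net.W[s].size(); ++l) {
      A = A * net.W[s][l].t();
      A.each_row() += net.b[s][l].t();
      A = arma::clamp(A, 0.0, arma::datum::inf);  // ReLU
      if (acts) (*acts)[s].push_back(A);
    }
    C = (s == 0) ? A : arma::join_rows(C, A);
  }
  mat out = C * net.Wh.t();
  out.each_row() += net.bh.t();
  return out;
}

double half_mse(const mat& pred, const mat& Y) {
  return 0.5 * arma::accu(arma::square(pred - Y)) / pred.n_rows;
}

// Gradients of the half-MSE cost; returns cost. Gradient structure is
// allocated to match `net`.
double gradients(const Net& net, const mat& X, const mat& Y, Net& g) {
  std::vector<std::vector<mat>> acts;
  mat pred = forward(net, X, &acts);
  const double n = static_cast<double>(X.n_rows);
  mat dOut = (pred - Y) / n;
  g.Wh.set_size(arma::size(net.Wh));
  g.bh.set_size(arma::size(net.bh));
  // concat activations in branch order
  const size_t S = net.W.size();
  mat C;
  for (size_t s = 0; s < S; ++s) {
    const mat& last = acts[s].back();
    C = (s == 0) ? last : arma::join_rows(C, last);
  }
  g.Wh = dOut.t() * C;
  g.bh = arma::sum(dOut, 0).t();
  mat dC = dOut * net.Wh;
  g.W.assign(S, {});
  g.b.assign(S, {});
  size_t col0 = 0;
  for (size_t s = 0; s < S; ++s) {
    const size_t L = net.W[s].size();
    const size_t width = net.W[s].back().n_rows;
    mat dA = dC.cols(col0, col0 + width - 1);
    col0 += width;
    g.W[s].resize(L);
    g.b[s].resize(L);
    for (size_t l = L; l-- > 0;) {
      // acts[s][l] is input to layer l, acts[s][l+1] its ReLU output
      mat dZ = dA % arma::conv_to<mat>::from(acts[s][l + 1] > 0.0);
      g.W[s][l] = dZ.t() * acts[s][l];
      g.b[s][l] = arma::sum(dZ, 0).t();
      if (l > 0) dA = dZ * net.W[s][l];
    }
  }
  return half_mse(pred, Y);
}

// Flat views over all parameter tensors, for the optimizer.
std::vector<mat*> tensor_ptrs(Net& net) {
  std::vector<mat*> out;
  for (auto& br : net.W)
    for (auto& Wl : br) out.push_back(&Wl);
  out.push_back(&net.Wh);
  return out;
}
std::vector<vec*> bias_ptrs(Net& net) {
  std::vector<vec*> out;
  for (auto& br : net.b)
    for (auto& bl : br) out.push_back(&bl);
  out.push_back(&net.bh);
  return out;
}

}  // namespace

// [[Rcpp::export(name = ".edfnn_forward_cpp")]]
arma::mat edfnn_forward_cpp(List params, arma::mat X, List branch_cols) {
  Net net = parse_net(params, branch_cols);
  return forward(net, X);
}

// [[Rcpp::export(name = ".edfnn_grad_cpp")]]
List edfnn_grad_cpp(List params, arma::mat X, arma::mat Y, List branch_cols) {
  Net net = parse_net(params, branch_cols);
  Net g;
  double cost = gradients(net, X, Y, g);
  g.cols = net.cols;
  List out = wrap_net(g);
  out["cost"] = cost;
  return out;
}

// [[Rcpp::export(name = ".edfnn_train_cpp")]]
List edfnn_train_cpp(List params, arma::mat X, arma::mat Y,
                     Nullable<NumericMatrix> Xval, Nullable<NumericMatrix> Yval,
                     List branch_cols, double lr, int epochs, int batch_size,
                     std::string optimizer, int shuffle_seed) {
  Net net = parse_net(params, branch_cols);
  const bool use_adam = (optimizer == "adam");
  const double beta1 = 0.9, beta2 = 0.999, eps = 1e-8;

  bool has_val = Xval.isNotNull();
  mat Xv, Yv;
  if (has_val) {
    Xv = as<mat>(Xval.get());
    Yv = as<mat>(Yval.get());
  }

  // Adam state aligned with parameter tensors
  Net grad;
  std::vector<mat> mW, vW;
  std::vector<vec> mb, vb;
  {
    auto Ws = tensor_ptrs(net);
    auto bs = bias_ptrs(net);
    for (auto* W : Ws) {
      mW.push_back(arma::zeros<mat>(arma::size(*W)));
      vW.push_back(arma::zeros<mat>(arma::size(*W)));
    }
    for (auto* b : bs) {
      mb.push_back(arma::zeros<vec>(arma::size(*b)));
      vb.push_back(arma::zeros<vec>(arma::size(*b)));
    }
  }

  std::mt19937 rng(static_cast<unsigned int>(shuffle_seed));
  const arma::uword n = X.n_rows;
  std::vector<arma::uword> order(n);
  for (arma::uword i = 0; i < n; ++i) order[i] = i;

  NumericVector train_cost(epochs, NA_REAL), val_cost(epochs, NA_REAL);
  int diverged = 0;
  long step = 0;

  for (int epoch = 0; epoch < epochs; ++epoch) {
    std::shuffle(order.begin(), order.end(), rng);
    for (arma::uword start = 0; start < n; start += batch_size) {
      arma::uword stop = std::min<arma::uword>(start + batch_size, n) - 1;
      uvec idx(stop - start + 1);
      for (arma::uword i = start; i <= stop; ++i) idx[i - start] = order[i];
      mat Xb = X.rows(idx);
      mat Yb = Y.rows(idx);
      gradients(net, Xb, Yb, grad);
      ++step;
      auto Ws = tensor_ptrs(net);
      auto gWs = tensor_ptrs(grad);
      auto bs = bias_ptrs(net);
      auto gbs = bias_ptrs(grad);
      if (use_adam) {
        const double c1 = 1.0 - std::pow(beta1, static_cast<double>(step));
        const double c2 = 1.0 - std::pow(beta2, static_cast<double>(step));
        for (size_t i = 0; i < Ws.size(); ++i) {
          mW[i] = beta1 * mW[i] + (1 - beta1) * (*gWs[i]);
          vW[i] = beta2 * vW[i] + (1 - beta2) * arma::square(*gWs[i]);
          *Ws[i] -= lr * (mW[i] / c1) / (arma::sqrt(vW[i] / c2) + eps);
        }
        for (size_t i = 0; i < bs.size(); ++i) {
          mb[i] = beta1 * mb[i] + (1 - beta1) * (*gbs[i]);
          vb[i] = beta2 * vb[i] + (1 - beta2) * arma::square(*gbs[i]);
          *bs[i] -= lr * (mb[i] / c1) / (arma::sqrt(vb[i] / c2) + eps);
        }
      } else {
        for (size_t i = 0; i < Ws.size(); ++i) *Ws[i] -= lr * (*gWs[i]);
        for (size_t i = 0; i < bs.size(); ++i) *bs[i] -= lr * (*gbs[i]);
      }
    }
    double tc = half_mse(forward(net, X), Y);
    train_cost[epoch] = tc;
    if (has_val) val_cost[epoch] = half_mse(forward(net, Xv), Yv);
    if (!std::isfinite(tc)) {
      diverged = epoch + 1;
      break;
    }
    if (epoch % 20 == 0) Rcpp::checkUserInterrupt();
  }

  List out = wrap_net(net);
  out["train_cost"] = train_cost;
  out["val_cost"] = val_cost;
  out["diverged"] = diverged;
  return out;
}
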