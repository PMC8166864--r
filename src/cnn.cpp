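// Minimal convolutional-network engine used by the classifier module:
// valid convolutions via im2col + GEMM, average/max pooling, fully
// connected layers with ReLU, softmax cross-entropy, inverted dropout,
// L2 weight decay and Adam. Own mt19937 RNG so training is reproducible
// from a seed independently of R's RNG state. Layer codes in the spec
// matrix: 1 avgpool(size) | 2 conv(filters, kernel) | 3 maxpool(size) |
// 4 fc(units).
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;
using namespace arma;

// columns of the output are output pixels q = i + oh*j; rows run over
// (dr, dc, channel) so writes are contiguous down each column
static void im2col(const cube& in, int k, mat& out) {
  const int H = in.n_rows, oh = H - k + 1, ow = in.n_cols - k + 1,
            C = in.n_slices;
  out.set_size(k * k * C, oh * ow);
  double* o = out.memptr();
  for (int j = 0; j < ow; ++j)
    for (int i = 0; i < oh; ++i)
      for (int c = 0; c < C; ++c) {
        const double* s = in.slice_memptr(c);
        for (int dc = 0; dc < k; ++dc) {
          const double* col = s + (size_t)(j + dc) * H + i;
          for (int dr = 0; dr < k; ++dr) *o++ = col[dr];
        }
      }
}

static void col2im_add(cube& grad_in, const mat& cols, int k) {
  const int H = grad_in.n_rows, oh = H - k + 1,
            ow = grad_in.n_cols - k + 1, C = grad_in.n_slices;
  const double* g = cols.memptr();
  for (int j = 0; j < ow; ++j)
    for (int i = 0; i < oh; ++i)
      for (int c = 0; c < C; ++c) {
        double* s = grad_in.slice_memptr(c);
        for (int dc = 0; dc < k; ++dc) {
          double* col = s + (size_t)(j + dc) * H + i;
          for (int dr = 0; dr < k; ++dr) col[dr] += *g++;
        }
      }
}

struct Buffers {
  std::vector<uvec> in_dims;   // input shape per layer (H, W, C)
  std::vector<mat>  cols;      // im2col matrix per conv layer
  std::vector<cube> conv_out;  // post-ReLU conv output (ReLU gate)
  std::vector<umat> maxidx;    // argmax (input linear index) per maxpool
  std::vector<vec>  fc_in;     // input vector per fc layer
  std::vector<vec>  fc_out;    // post-ReLU fc output
  std::vector<vec>  drop_mask; // dropout mask applied to fc input
  void resize(int L) {
    if ((int)in_dims.size() != L) {
      in_dims.assign(L, uvec()); cols.assign(L, mat());
      conv_out.assign(L, cube()); maxidx.assign(L, umat());
      fc_in.assign(L, vec()); fc_out.assign(L, vec());
      drop_mask.assign(L, vec());
    }
    for (int l = 0; l < L; ++l) drop_mask[l].reset();
  }
};

struct Net {
  imat spec;                 // L x 3: code, a, b
  std::vector<mat> W;
  std::vector<vec> b;
  std::vector<int> wslot;    // weight slot per layer (conv/fc only)
  int n_layers() const { return spec.n_rows; }
  void index_slots() {
    wslot.assign(n_layers(), -1);
    int s = 0;
    for (int l = 0; l < n_layers(); ++l)
      if (spec(l, 0) == 2 || spec(l, 0) == 4) wslot[l] = s++;
  }
};

static vec forward(const Net& net, cube x, Buffers& buf, bool training,
                   double dropout, std::mt19937& rng) {
  const int L = net.n_layers();
  buf.resize(L);
  vec v;                 // state once flattened
  bool flat = false;
  std::uniform_real_distribution<double> unif(0.0, 1.0);
  for (int l = 0; l < L; ++l) {
    const int code = net.spec(l, 0), a = net.spec(l, 1);
    if (code == 1) {                       // average pooling
      buf.in_dims[l] = uvec{x.n_rows, x.n_cols, x.n_slices};
      const int H = x.n_rows, oh = H / a, ow = x.n_cols / a, C = x.n_slices;
      cube out(oh, ow, C);
      const double inv = 1.0 / (a * a);
      for (int c = 0; c < C; ++c) {
        const double* s = x.slice_memptr(c);
        double* o = out.slice_memptr(c);
        for (int j = 0; j < ow; ++j)
          for (int i = 0; i < oh; ++i) {
            double acc = 0;
            for (int dj = 0; dj < a; ++dj) {
              const double* col = s + (size_t)(j * a + dj) * H + i * a;
              for (int di = 0; di < a; ++di) acc += col[di];
            }
            o[i + (size_t)oh * j] = acc * inv;
          }
      }
      x = std::move(out);
    } else if (code == 2) {                // conv + ReLU
      const int k = net.spec(l, 2), F = a;
      buf.in_dims[l] = uvec{x.n_rows, x.n_cols, x.n_slices};
      const int oh = x.n_rows - k + 1, ow = x.n_cols - k + 1;
      im2col(x, k, buf.cols[l]);
      const int s = net.wslot[l];
      mat o = buf.cols[l].t() * net.W[s];  // (oh*ow) x F
      o.each_row() += net.b[s].t();
      o.transform([](double z) { return z > 0 ? z : 0.0; });
      cube out(oh, ow, F);
      std::memcpy(out.memptr(), o.memptr(), o.n_elem * sizeof(double));
      buf.conv_out[l] = out;
      x = std::move(out);
    } else if (code == 3) {                // max pooling
      buf.in_dims[l] = uvec{x.n_rows, x.n_cols, x.n_slices};
      const int H = x.n_rows, oh = H / a, ow = x.n_cols / a, C = x.n_slices;
      cube out(oh, ow, C);
      umat idx(oh * ow, C);
      for (int c = 0; c < C; ++c) {
        const double* s = x.slice_memptr(c);
        double* o = out.slice_memptr(c);
        uword* ip = idx.colptr(c);
        for (int j = 0; j < ow; ++j)
          for (int i = 0; i < oh; ++i) {
            double best = -datum::inf; uword bi = 0;
            for (int dj = 0; dj < a; ++dj) {
              const size_t off = (size_t)(j * a + dj) * H + i * a;
              for (int di = 0; di < a; ++di)
                if (s[off + di] > best) { best = s[off + di]; bi = off + di; }
            }
            o[i + (size_t)oh * j] = best;
            ip[i + (size_t)oh * j] = bi;
          }
      }
      buf.maxidx[l] = idx;
      x = std::move(out);
    } else {                               // fully connected
      if (!flat) { v = vectorise(x); flat = true; }
      if (training && dropout > 0) {
        vec mask(v.n_elem);
        for (uword i = 0; i < v.n_elem; ++i)
          mask(i) = unif(rng) < dropout ? 0.0 : 1.0 / (1.0 - dropout);
        buf.drop_mask[l] = mask;
        v %= mask;
      }
      buf.fc_in[l] = v;
      const int s = net.wslot[l];
      vec z = net.W[s].t() * v + net.b[s];
      if (l < L - 1) z.transform([](double q) { return q > 0 ? q : 0.0; });
      buf.fc_out[l] = z;
      v = std::move(z);
    }
  }
  vec z = v - v.max();
  vec e = exp(z);
  return e / accu(e);
}

static void backward(const Net& net, Buffers& buf, const vec& probs,
                     int y, std::vector<mat>& gW, std::vector<vec>& gb) {
  const int L = net.n_layers();
  vec dv = probs;
  dv(y) -= 1.0;                 // d loss / d logits
  cube dx;
  bool flat = true;             // walking back from the top (fc land)
  for (int l = L - 1; l >= 0; --l) {
    const int code = net.spec(l, 0), a = net.spec(l, 1);
    if (code == 4) {
      if (l < L - 1) {          // undo ReLU of hidden fc
        const vec& o = buf.fc_out[l];
        for (uword i = 0; i < dv.n_elem; ++i) if (o(i) <= 0) dv(i) = 0;
      }
      const int s = net.wslot[l];
      gW[s] += buf.fc_in[l] * dv.t();
      gb[s] += dv;
      dv = net.W[s] * dv;
      if (buf.drop_mask[l].n_elem) dv %= buf.drop_mask[l];
      continue;
    }
    const uvec& d = buf.in_dims[l];
    if (flat) {                 // reshape flat gradient to this layer's output
      uword oh, ow, oc;
      if (code == 2) {
        oh = buf.conv_out[l].n_rows; ow = buf.conv_out[l].n_cols;
        oc = buf.conv_out[l].n_slices;
      } else { oh = d(0) / a; ow = d(1) / a; oc = d(2); }
      dx.set_size(oh, ow, oc);
      std::memcpy(dx.memptr(), dv.memptr(), dv.n_elem * sizeof(double));
      flat = false;
    }
    if (code == 1) {            // avgpool backward
      cube din(d(0), d(1), d(2), fill::zeros);
      const int H = d(0), oh = dx.n_rows, ow = dx.n_cols;
      const double inv = 1.0 / (a * a);
      for (uword c = 0; c < d(2); ++c) {
        double* s = din.slice_memptr(c);
        const double* g = dx.slice_memptr(c);
        for (int j = 0; j < ow; ++j)
          for (int i = 0; i < oh; ++i) {
            const double gv = g[i + (size_t)oh * j] * inv;
            for (int dj = 0; dj < a; ++dj) {
              double* col = s + (size_t)(j * a + dj) * H + i * a;
              for (int di = 0; di < a; ++di) col[di] += gv;
            }
          }
      }
      dx = std::move(din);
    } else if (code == 2) {     // conv backward
      const cube& out = buf.conv_out[l];
      const int k = net.spec(l, 2);
      double* dp = dx.memptr();
      const double* op = out.memptr();
      for (uword i = 0; i < out.n_elem; ++i)
        if (op[i] <= 0) dp[i] = 0;               // ReLU gate
      const uword P = out.n_rows * out.n_cols, F = out.n_slices;
      const mat Gt(dx.memptr(), P, F, false, true); // alias: slices = columns
      const int s = net.wslot[l];
      gW[s] += buf.cols[l] * Gt;
      gb[s] += sum(Gt, 0).t();
      mat dcols = net.W[s] * Gt.t();
      cube din(d(0), d(1), d(2), fill::zeros);
      col2im_add(din, dcols, k);
      dx = std::move(din);
    } else {                    // maxpool backward
      cube din(d(0), d(1), d(2), fill::zeros);
      const int oh = dx.n_rows, ow = dx.n_cols;
      for (uword c = 0; c < d(2); ++c) {
        double* s = din.slice_memptr(c);
        const double* g = dx.slice_memptr(c);
        const uword* ip = buf.maxidx[l].colptr(c);
        for (int q = 0; q < oh * ow; ++q) s[ip[q]] += g[q];
      }
      dx = std::move(din);
    }
  }
}

static Net build_net(const IntegerMatrix& spec, const List& weights) {
  Net net;
  net.spec = imat(spec.nrow(), 3);
  for (int i = 0; i < spec.nrow(); ++i)
    for (int j = 0; j < 3; ++j) net.spec(i, j) = spec(i, j);
  for (int i = 0; i < weights.size(); ++i) {
    List wl = weights[i];
    net.W.push_back(as<mat>(wl["W"]));
    net.b.push_back(as<vec>(wl["b"]));
  }
  net.index_slots();
  return net;
}

static cube get_sample(const NumericVector& X, const IntegerVector& d, int n) {
  const int H = d[0], W = d[1], C = d[2];
  cube s(H, W, C);
  std::memcpy(s.memptr(), X.begin() + (size_t)n * H * W * C,
              (size_t)H * W * C * sizeof(double));
  return s;
}

static void augment_inplace(cube& s, bool hflip, bool vflip, double blo,
                            double bhi, std::mt19937& rng) {
  std::uniform_real_distribution<double> unif(0.0, 1.0);
  if (hflip && unif(rng) < 0.5)
    for (uword c = 0; c < s.n_slices; ++c) s.slice(c) = fliplr(s.slice(c));
  if (vflip && unif(rng) < 0.5)
    for (uword c = 0; c < s.n_slices; ++c) s.slice(c) = flipud(s.slice(c));
  if (blo < bhi) {
    const double f = blo + (bhi - blo) * unif(rng);
    s *= f;
    s.clamp(0.0, 1.0);
  }
}

// [[Rcpp::export]]
List cnn_init_cpp(IntegerMatrix spec, int H, int W, int C, int seed) {
  std::mt19937 rng(seed);
  std::normal_distribution<double> norm(0.0, 1.0);
  List out;
  int h = H, w = W, c = C;
  bool flat = false; int flat_n = 0;
  for (int l = 0; l < spec.nrow(); ++l) {
    const int code = spec(l, 0), a = spec(l, 1);
    if (code == 1 || code == 3) { h /= a; w /= a; }
    else if (code == 2) {
      const int k = spec(l, 2);
      const int fan_in = k * k * c;
      mat Wm(fan_in, a);
      for (uword i = 0; i < Wm.n_elem; ++i)
        Wm(i) = norm(rng) * std::sqrt(2.0 / fan_in);
      out.push_back(List::create(_["W"] = Wm, _["b"] = vec(a, fill::zeros)));
      h -= k - 1; w -= k - 1; c = a;
    } else {
      if (!flat) { flat_n = h * w * c; flat = true; }
      mat Wm(flat_n, a);
      for (uword i = 0; i < Wm.n_elem; ++i)
        Wm(i) = norm(rng) * std::sqrt(2.0 / flat_n);
      out.push_back(List::create(_["W"] = Wm, _["b"] = vec(a, fill::zeros)));
      flat_n = a;
    }
    if (!flat && (h <= 0 || w <= 0))
      stop("architecture shrinks spatial size to zero");
  }
  return out;
}

// [[Rcpp::export]]
List cnn_train_cpp(NumericVector X, IntegerVector y, IntegerMatrix spec,
                   List weights, int epochs, int batch, double lr, double l2,
                   double dropout, bool hflip, bool vflip, double blo,
                   double bhi, int seed, bool augment_on) {
  IntegerVector d = X.attr("dim");
  const int N = d[3];
  Net net = build_net(spec, weights);
  std::mt19937 rng(seed);
  std::vector<mat> mW, vW, gW;
  std::vector<vec> mb, vb, gb;
  for (size_t s = 0; s < net.W.size(); ++s) {
    mW.push_back(mat(size(net.W[s]), fill::zeros));
    vW.push_back(mat(size(net.W[s]), fill::zeros));
    gW.push_back(mat(size(net.W[s]), fill::zeros));
    mb.push_back(vec(size(net.b[s]), fill::zeros));
    vb.push_back(vec(size(net.b[s]), fill::zeros));
    gb.push_back(vec(size(net.b[s]), fill::zeros));
  }
  const double b1 = 0.9, b2 = 0.999, eps = 1e-8;
  long t = 0;
  std::vector<int> idx(N);
  for (int i = 0; i < N; ++i) idx[i] = i;
  NumericVector loss_hist(epochs);
  Buffers buf;
  for (int ep = 0; ep < epochs; ++ep) {
    std::shuffle(idx.begin(), idx.end(), rng);
    double ep_loss = 0.0;
    for (int start = 0; start < N; start += batch) {
      const int bs = std::min(batch, N - start);
      for (size_t s = 0; s < net.W.size(); ++s) { gW[s].zeros(); gb[s].zeros(); }
      for (int bi = 0; bi < bs; ++bi) {
        const int n = idx[start + bi];
        cube smp = get_sample(X, d, n);
        if (augment_on) augment_inplace(smp, hflip, vflip, blo, bhi, rng);
        vec p = forward(net, std::move(smp), buf, true, dropout, rng);
        ep_loss += -std::log(std::max(p(y[n] - 1), 1e-12));
        backward(net, buf, p, y[n] - 1, gW, gb);
      }
      ++t;
      for (size_t s = 0; s < net.W.size(); ++s) {
        mat g = gW[s] / bs + l2 * net.W[s];
        mW[s] = b1 * mW[s] + (1 - b1) * g;
        vW[s] = b2 * vW[s] + (1 - b2) * square(g);
        net.W[s] -= lr * (mW[s] / (1 - std::pow(b1, t))) /
          (sqrt(vW[s] / (1 - std::pow(b2, t))) + eps);
        vec gbv = gb[s] / bs;
        mb[s] = b1 * mb[s] + (1 - b1) * gbv;
        vb[s] = b2 * vb[s] + (1 - b2) * square(gbv);
        net.b[s] -= lr * (mb[s] / (1 - std::pow(b1, t))) /
          (sqrt(vb[s] / (1 - std::pow(b2, t))) + eps);
      }
    }
    loss_hist[ep] = ep_loss / N;
    Rcpp::checkUserInterrupt();
  }
  List wout;
  for (size_t s = 0; s < net.W.size(); ++s)
    wout.push_back(List::create(_["W"] = net.W[s], _["b"] = net.b[s]));
  return List::create(_["weights"] = wout, _["loss"] = loss_hist);
}

// [[Rcpp::export]]
NumericMatrix cnn_predict_cpp(NumericVector X, IntegerMatrix spec,
                              List weights) {
  IntegerVector d = X.attr("dim");
  const int N = d[3];
  Net net = build_net(spec, weights);
  std::mt19937 rng(0);
  Buffers buf;
  const int K = net.b.back().n_elem;
  NumericMatrix out(N, K);
  for (int n = 0; n < N; ++n) {
    vec p = forward(net, get_sample(X, d, n), buf, false, 0.0, rng);
    for (int k = 0; k < K; ++k) out(n, k) = p(k);
    if (n % 64 == 0) Rcpp::checkUserInterrupt();
  }
  return out;
}

// [[Rcpp::export]]
List cnn_activations_cpp(NumericVector x, IntegerMatrix spec, List weights,
                         int conv_index) {
  IntegerVector d = x.attr("dim");
  NumericVector X = clone(x);
  IntegerVector d4 = IntegerVector::create(d[0], d[1], d[2], 1);
  X.attr("dim") = d4;
  Net net = build_net(spec, weights);
  std::mt19937 rng(0);
  Buffers buf;
  forward(net, get_sample(X, d4, 0), buf, false, 0.0, rng);
  int seen = 0;
  for (int l = 0; l < net.n_layers(); ++l) {
    if (net.spec(l, 0) == 2 && ++seen == conv_index) {
      const cube& a = buf.conv_out[l];
      List maps(a.n_slices);
      for (uword c = 0; c < a.n_slices; ++c)
        maps[c] = wrap(mat(a.slice(c)));
      return maps;
    }
  }
  stop("network has fewer than %d convolutional layers", conv_index);
}
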