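// Low-level tensor kernels for the encoder-decoder network.
//
// Tensors are H x W x C arma::cubes mapped 1:1 onto R arrays (column-major
// per slice). Convolutions are im2col + GEMM with symmetric zero padding of
// (k-1)/2 and stride 1, so 3x3 and 1x1 kernels preserve spatial dims.
// Patch columns are ordered channel-major, then kernel row, then kernel col:
//   q = c*kh*kw + ki*kw + kj
// and the R-side initialisers and the test oracles follow the same layout.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static arma::mat im2col(const arma::cube& x, const int kh, const int kw) {
  const int H = x.n_rows, W = x.n_cols, C = x.n_slices;
  const int ph = (kh - 1) / 2, pw = (kw - 1) / 2;
  arma::mat out(static_cast<size_t>(H) * W, static_cast<size_t>(kh) * kw * C,
                arma::fill::zeros);
  for (int c = 0; c < C; ++c) {
    for (int ki = 0; ki < kh; ++ki) {
      for (int kj = 0; kj < kw; ++kj) {
        const int q = c * kh * kw + ki * kw + kj;
        const int di = ki - ph, dj = kj - pw;
        const int r0 = std::max(0, -di), r1 = std::min(H, H - di);
        const int c0 = std::max(0, -dj), c1 = std::min(W, W - dj);
        if (r1 <= r0 || c1 <= c0) continue;
        arma::mat col(H, W, arma::fill::zeros);
        col.submat(r0, c0, r1 - 1, c1 - 1) =
            x.slice(c).submat(r0 + di, c0 + dj, r1 - 1 + di, c1 - 1 + dj);
        out.col(q) = arma::vectorise(col);
      }
    }
  }
  return out;
}

// Scatter-add of patch-column gradients back onto the input plane.
static arma::cube col2im(const arma::mat& gcols, const int H, const int W,
                         const int C, const int kh, const int kw) {
  const int ph = (kh - 1) / 2, pw = (kw - 1) / 2;
  arma::cube gx(H, W, C, arma::fill::zeros);
  for (int c = 0; c < C; ++c) {
    for (int ki = 0; ki < kh; ++ki) {
      for (int kj = 0; kj < kw; ++kj) {
        const int q = c * kh * kw + ki * kw + kj;
        const int di = ki - ph, dj = kj - pw;
        const int r0 = std::max(0, -di), r1 = std::min(H, H - di);
        const int c0 = std::max(0, -dj), c1 = std::min(W, W - dj);
        if (r1 <= r0 || c1 <= c0) continue;
        arma::mat col(gcols.colptr(q), H, W);  // copy of column as H x W
        gx.slice(c).submat(r0 + di, c0 + dj, r1 - 1 + di, c1 - 1 + dj) +=
            col.submat(r0, c0, r1 - 1, c1 - 1);
      }
    }
  }
  return gx;
}

// [[Rcpp::export]]
arma::cube cpp_conv2d(const arma::cube& x, const arma::mat& w,
                      const arma::vec& b, const int kh, const int kw) {
  arma::mat y = im2col(x, kh, kw) * w;  // (H*W) x Cout
  y.each_row() += b.t();
  arma::cube out(x.n_rows, x.n_cols, w.n_cols);
  std::memcpy(out.memptr(), y.memptr(), sizeof(double) * y.n_elem);
  return out;
}

// [[Rcpp::export]]
List cpp_conv2d_backward(const arma::cube& x, const arma::mat& w,
                         const arma::cube& gy, const int kh, const int kw) {
  const int H = x.n_rows, W = x.n_cols, C = x.n_slices;
  const int Cout = gy.n_slices;
  arma::mat g(const_cast<double*>(gy.memptr()),
              static_cast<size_t>(H) * W, Cout, false, true);
  arma::mat cols = im2col(x, kh, kw);
  arma::mat gw = cols.t() * g;
  arma::vec gb = arma::sum(g, 0).t();
  arma::cube gx = col2im(g * w.t(), H, W, C, kh, kw);
  return List::create(_["gx"] = gx, _["gw"] = gw, _["gb"] = gb);
}

// 2x2 max pooling, stride 2, floor division; trailing odd row/col dropped.
// idx stores the 0-based column-major argmax location within each slice,
// ties resolved to the first element in column-major scan order.
// [[Rcpp::export]]
List cpp_maxpool(const arma::cube& x) {
  const int H = x.n_rows, W = x.n_cols, C = x.n_slices;
  const int Ho = H / 2, Wo = W / 2;
  arma::cube y(Ho, Wo, C), idx(Ho, Wo, C);
  for (int c = 0; c < C; ++c) {
    const double* s = x.slice_memptr(c);
    for (int jo = 0; jo < Wo; ++jo) {
      for (int io = 0; io < Ho; ++io) {
        const int i0 = 2 * io, j0 = 2 * jo;
        double best = -arma::datum::inf;
        int bi = 0;
        for (int dj = 0; dj < 2; ++dj) {
          for (int di = 0; di < 2; ++di) {
            const int lin = (j0 + dj) * H + (i0 + di);
            if (s[lin] > best) { best = s[lin]; bi = lin; }
          }
        }
        y(io, jo, c) = best;
        idx(io, jo, c) = bi;
      }
    }
  }
  return List::create(_["y"] = y, _["idx"] = idx);
}

// Scatter pooled values back to recorded argmax locations (max-unpooling;
// also the backward pass of max-pooling). Window locations are disjoint.
// [[Rcpp::export]]
arma::cube cpp_unpool(const arma::cube& v, const arma::cube& idx,
                      const int out_h, const int out_w) {
  const int Ho = v.n_rows, Wo = v.n_cols, C = v.n_slices;
  arma::cube out(out_h, out_w, C, arma::fill::zeros);
  for (int c = 0; c < C; ++c) {
    double* o = out.slice_memptr(c);
    for (int jo = 0; jo < Wo; ++jo)
      for (int io = 0; io < Ho; ++io)
        o[static_cast<size_t>(idx(io, jo, c))] += v(io, jo, c);
  }
  return out;
}

// Gather at recorded locations (backward pass of max-unpooling).
// [[Rcpp::export]]
arma::cube cpp_pool_gather(const arma::cube& g, const arma::cube& idx) {
  const int Ho = idx.n_rows, Wo = idx.n_cols, C = idx.n_slices;
  arma::cube out(Ho, Wo, C);
  for (int c = 0; c < C; ++c) {
    const double* s = g.slice_memptr(c);
    for (int jo = 0; jo < Wo; ++jo)
      for (int io = 0; io < Ho; ++io)
        out(io, jo, c) = s[static_cast<size_t>(idx(io, jo, c))];
  }
  return out;
}

// Per-channel normalization over the spatial field of one sample, with
// learned scale (gamma) and shift (beta). Population variance.
// [[Rcpp::export]]
List cpp_bn_forward(const arma::cube& x, const arma::vec& gamma,
                    const arma::vec& beta, const double eps) {
  const int C = x.n_slices;
  arma::cube y(x.n_rows, x.n_cols, C);
  arma::vec mu(C), invstd(C);
  for (int c = 0; c < C; ++c) {
    const double m = arma::mean(arma::vectorise(x.slice(c)));
    const double v = arma::mean(arma::square(arma::vectorise(x.slice(c)) - m));
    const double is = 1.0 / std::sqrt(v + eps);
    mu(c) = m;
    invstd(c) = is;
    y.slice(c) = (x.slice(c) - m) * (is * gamma(c)) + beta(c);
  }
  return List::create(_["y"] = y, _["mean"] = mu, _["invstd"] = invstd);
}

// [[Rcpp::export]]
List cpp_bn_backward(const arma::cube& x, const arma::cube& gy,
                     const arma::vec& gamma, const arma::vec& mean,
                     const arma::vec& invstd) {
  const int C = x.n_slices;
  const double n = static_cast<double>(x.n_rows) * x.n_cols;
  arma::cube gx(x.n_rows, x.n_cols, C);
  arma::vec ggamma(C), gbeta(C);
  for (int c = 0; c < C; ++c) {
    arma::mat xhat = (x.slice(c) - mean(c)) * invstd(c);
    const double sg = arma::accu(gy.slice(c));
    const double sgx = arma::accu(gy.slice(c) % xhat);
    gbeta(c) = sg;
    ggamma(c) = sgx;
    gx.slice(c) =
        (gamma(c) * invstd(c)) * (gy.slice(c) - sg / n - xhat * (sgx / n));
  }
  return List::create(_["gx"] = gx, _["ggamma"] = ggamma, _["gbeta"] = gbeta);
}
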