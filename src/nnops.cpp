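// Hot loops of the 1-D conv encoder/decoder. Tensors are arma::cube with
// layout (channels, time, batch), matching R arrays of dim c(C, T, B).
// Conv weights are (C_out, C_in * k): column block j (0-based tap) holds the
// kernel tap applied at time offset (j - (k-1)/2) * dilation ("same"
// padding; odd k enforced in R). Convolutions are evaluated as one GEMM per
// (slice, tap) on contiguous column views, which keeps temporaries small.

// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>
using namespace arma;

// [[Rcpp::export(name = ".conv1d_fwd")]]
arma::cube conv1d_fwd(const arma::cube& x, const arma::mat& W,
                      const arma::vec& b, int k, int d) {
  const int C = x.n_rows, T = x.n_cols, B = x.n_slices;
  const int Cout = W.n_rows, half = (k - 1) / 2;
  cube y(Cout, T, B);
  for (int s = 0; s < B; ++s) {
    y.slice(s).each_col() = b;
    for (int j = 0; j < k; ++j) {
      const int off = (j - half) * d;
      const int t0 = std::max(0, -off);
      const int t1 = std::min(T, T - off);
      if (t1 > t0)
        y.slice(s).cols(t0, t1 - 1) +=
          W.cols(j * C, (j + 1) * C - 1) *
          x.slice(s).cols(t0 + off, t1 - 1 + off);
    }
  }
  return y;
}

// [[Rcpp::export(name = ".conv1d_bwd")]]
Rcpp::List conv1d_bwd(const arma::cube& x, const arma::mat& W,
                      const arma::cube& gy, int k, int d) {
  const int C = x.n_rows, T = x.n_cols, B = x.n_slices;
  const int half = (k - 1) / 2;
  mat gW(W.n_rows, W.n_cols, fill::zeros);
  vec gb(W.n_rows, fill::zeros);
  cube gx(C, T, B, fill::zeros);
  for (int s = 0; s < B; ++s) {
    gb += sum(gy.slice(s), 1);
    for (int j = 0; j < k; ++j) {
      const int off = (j - half) * d;
      const int t0 = std::max(0, -off);
      const int t1 = std::min(T, T - off);
      if (t1 <= t0) continue;
      gW.cols(j * C, (j + 1) * C - 1) +=
        gy.slice(s).cols(t0, t1 - 1) *
        x.slice(s).cols(t0 + off, t1 - 1 + off).t();
      gx.slice(s).cols(t0 + off, t1 - 1 + off) +=
        W.cols(j * C, (j + 1) * C - 1).t() * gy.slice(s).cols(t0, t1 - 1);
    }
  }
  return Rcpp::List::create(Rcpp::Named("gx") = gx,
                            Rcpp::Named("gW") = gW,
                            Rcpp::Named("gb") = gb);
}

// Transposed conv, kernel 2 stride 2 (exact x2 upsampling).
// W is (C_out, C_in * 2): block 0 fills even output columns, block 1 odd.
// [[Rcpp::export(name = ".convT1d_fwd")]]
arma::cube convT1d_fwd(const arma::cube& x, const arma::mat& W,
                       const arma::vec& b) {
  const int C = x.n_rows, T = x.n_cols, B = x.n_slices;
  const int Cout = W.n_rows;
  const mat W0 = W.cols(0, C - 1), W1 = W.cols(C, 2 * C - 1);
  cube y(Cout, 2 * T, B);
  for (int s = 0; s < B; ++s) {
    mat y0 = W0 * x.slice(s);
    mat y1 = W1 * x.slice(s);
    for (int t = 0; t < T; ++t) {
      y.slice(s).col(2 * t) = y0.col(t) + b;
      y.slice(s).col(2 * t + 1) = y1.col(t) + b;
    }
  }
  return y;
}

// [[Rcpp::export(name = ".convT1d_bwd")]]
Rcpp::List convT1d_bwd(const arma::cube& x, const arma::mat& W,
                       const arma::cube& gy) {
  const int C = x.n_rows, T = x.n_cols, B = x.n_slices;
  const int Cout = W.n_rows;
  const mat W0 = W.cols(0, C - 1), W1 = W.cols(C, 2 * C - 1);
  mat gW0(Cout, C, fill::zeros), gW1(Cout, C, fill::zeros);
  vec gb(Cout, fill::zeros);
  cube gx(C, T, B);
  mat g0(Cout, T), g1(Cout, T);
  for (int s = 0; s < B; ++s) {
    for (int t = 0; t < T; ++t) {
      g0.col(t) = gy.slice(s).col(2 * t);
      g1.col(t) = gy.slice(s).col(2 * t + 1);
    }
    gW0 += g0 * x.slice(s).t();
    gW1 += g1 * x.slice(s).t();
    gb += sum(g0, 1) + sum(g1, 1);
    gx.slice(s) = W0.t() * g0 + W1.t() * g1;
  }
  mat gW = join_rows(gW0, gW1);
  return Rcpp::List::create(Rcpp::Named("gx") = gx,
                            Rcpp::Named("gW") = gW,
                            Rcpp::Named("gb") = gb);
}

// Max pooling over pairs of time points; idx records which of the pair won.
// [[Rcpp::export(name = ".maxpool2_fwd")]]
Rcpp::List maxpool2_fwd(const arma::cube& x) {
  const int C = x.n_rows, T = x.n_cols, B = x.n_slices;
  const int To = T / 2;
  cube y(C, To, B);
  ucube idx(C, To, B);
  for (int s = 0; s < B; ++s)
    for (int t = 0; t < To; ++t)
      for (int c = 0; c < C; ++c) {
        const double a = x(c, 2 * t, s), bb = x(c, 2 * t + 1, s);
        if (a >= bb) { y(c, t, s) = a; idx(c, t, s) = 0; }
        else { y(c, t, s) = bb; idx(c, t, s) = 1; }
      }
  return Rcpp::List::create(Rcpp::Named("y") = y, Rcpp::Named("idx") = idx);
}

// [[Rcpp::export(name = ".maxpool2_bwd")]]
arma::cube maxpool2_bwd(const arma::cube& gy, const arma::ucube& idx, int T) {
  const int C = gy.n_rows, To = gy.n_cols, B = gy.n_slices;
  cube gx(C, T, B, fill::zeros);
  for (int s = 0; s < B; ++s)
    for (int t = 0; t < To; ++t)
      for (int c = 0; c < C; ++c)
        gx(c, 2 * t + idx(c, t, s), s) = gy(c, t, s);
  return gx;
}

// Non-learnable linear x2 upsampling: y[2t] = x[t],
// y[2t+1] = (x[t] + x[t+1]) / 2, with the last odd column copying x[T-1].
// [[Rcpp::export(name = ".linup2_fwd")]]
arma::cube linup2_fwd(const arma::cube& x) {
  const int C = x.n_rows, T = x.n_cols, B = x.n_slices;
  cube y(C, 2 * T, B);
  for (int s = 0; s < B; ++s) {
    for (int t = 0; t < T; ++t) {
      y.slice(s).col(2 * t) = x.slice(s).col(t);
      if (t + 1 < T)
        y.slice(s).col(2 * t + 1) =
          0.5 * (x.slice(s).col(t) + x.slice(s).col(t + 1));
      else
        y.slice(s).col(2 * t + 1) = x.slice(s).col(t);
    }
  }
  return y;
}

// [[Rcpp::export(name = ".linup2_bwd")]]
arma::cube linup2_bwd(const arma::cube& gy) {
  const int C = gy.n_rows, To = gy.n_cols, B = gy.n_slices;
  const int T = To / 2;
  cube gx(C, T, B, fill::zeros);
  for (int s = 0; s < B; ++s) {
    for (int t = 0; t < T; ++t) {
      gx.slice(s).col(t) += gy.slice(s).col(2 * t);
      if (t + 1 < T) {
        gx.slice(s).col(t) += 0.5 * gy.slice(s).col(2 * t + 1);
        gx.slice(s).col(t + 1) += 0.5 * gy.slice(s).col(2 * t + 1);
      } else {
        gx.slice(s).col(t) += gy.slice(s).col(2 * t + 1);
      }
    }
  }
  return gx;
}

// Exact GELU, x * Phi(x), with Phi the standard normal CDF.
static const double INV_SQRT2 = 0.7071067811865476;
static const double INV_SQRT_2PI = 0.3989422804014327;

// [[Rcpp::export(name = ".gelu_fwd_cpp")]]
arma::cube gelu_fwd_cpp(const arma::cube& x) {
  cube y = x;
  y.transform([](double v) {
    return v * 0.5 * (1.0 + std::erf(v * INV_SQRT2));
  });
  return y;
}

// [[Rcpp::export(name = ".gelu_bwd_cpp")]]
arma::cube gelu_bwd_cpp(const arma::cube& gy, const arma::cube& x) {
  cube gx(size(x));
  const double* px = x.memptr();
  const double* pg = gy.memptr();
  double* po = gx.memptr();
  const uword n = x.n_elem;
  for (uword i = 0; i < n; ++i) {
    const double v = px[i];
    const double phi = 0.5 * (1.0 + std::erf(v * INV_SQRT2));
    const double dens = INV_SQRT_2PI * std::exp(-0.5 * v * v);
    po[i] = pg[i] * (phi + v * dens);
  }
  return gx;
}

// Layer normalization over the channel axis at each (time, slice) position,
// with per-channel gain/bias.
// [[Rcpp::export(name = ".layernorm_fwd_cpp")]]
Rcpp::List layernorm_fwd_cpp(const arma::cube& x, const arma::vec& gamma,
                             const arma::vec& beta, double eps) {
  const int C = x.n_rows, T = x.n_cols, B = x.n_slices;
  cube xhat(C, T, B), y(C, T, B);
  mat inv(T, B);
  for (int s = 0; s < B; ++s) {
    for (int t = 0; t < T; ++t) {
      const vec col = x.slice(s).col(t);
      const double mu = mean(col);
      vec c = col - mu;
      const double iv = 1.0 / std::sqrt(dot(c, c) / C + eps);
      c *= iv;
      xhat.slice(s).col(t) = c;
      y.slice(s).col(t) = gamma % c + beta;
      inv(t, s) = iv;
    }
  }
  return Rcpp::List::create(Rcpp::Named("y") = y,
                            Rcpp::Named("xhat") = xhat,
                            Rcpp::Named("inv") = inv);
}

// [[Rcpp::export(name = ".layernorm_bwd_cpp")]]
Rcpp::List layernorm_bwd_cpp(const arma::cube& gy, const arma::cube& xhat,
                             const arma::mat& inv, const arma::vec& gamma) {
  const int C = gy.n_rows, T = gy.n_cols, B = gy.n_slices;
  vec ggamma(C, fill::zeros), gbeta(C, fill::zeros);
  cube gx(C, T, B);
  for (int s = 0; s < B; ++s) {
    for (int t = 0; t < T; ++t) {
      const vec g = gy.slice(s).col(t);
      const vec xh = xhat.slice(s).col(t);
      ggamma += g % xh;
      gbeta += g;
      const vec gxh = g % gamma;
      const double m1 = mean(gxh);
      const double m2 = mean(gxh % xh);
      gx.slice(s).col(t) = inv(t, s) * (gxh - m1 - xh * m2);
    }
  }
  return Rcpp::List::create(Rcpp::Named("gx") = gx,
                            Rcpp::Named("ggamma") = ggamma,
                            Rcpp::Named("gbeta") = gbeta);
}
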