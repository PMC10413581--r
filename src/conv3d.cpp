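// 3D convolution primitives for the segmentation network.
//
// Feature volumes are passed as N x C matrices where N = D*H*W voxels in
// column-major spatial order (depth fastest: linear index = d + D*h + D*H*w)
// and C channels. Kernels are (k^3 * Cin) x Cout matrices whose row index is
// kd + k*kh + k^2*kw + k^3*cin (0-based), i.e. the column-major flattening of
// an R array with dim c(k, k, k, Cin, Cout).
//
// Direct (no-im2col) convolution: for every (cin, kernel offset) the valid
// output box is hoisted out of the loops and the innermost depth loop is a
// contiguous saxpy, so nothing larger than the feature matrices themselves
// is ever allocated. The backward pass fuses the input-gradient scatter and
// the weight-gradient reduction into one sweep.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

static inline int out_extent(int n, int k, int stride, int pad) {
  return (n + 2 * pad - k) / stride + 1;
}

// first/last+1 output index o with 0 <= o*stride + koff - pad < n
static inline void valid_range(int n, int nout, int koff, int stride, int pad,
                               int& lo, int& hi) {
  lo = 0;
  while (lo < nout && lo * stride + koff - pad < 0) ++lo;
  hi = nout;
  while (hi > lo && (hi - 1) * stride + koff - pad >= n) --hi;
}

// [[Rcpp::export]]
arma::mat cpp_conv3d_fw(const arma::mat& x, int D, int H, int W,
                        const arma::mat& w, const arma::vec& bias,
                        int k, int stride, int pad) {
  const int Cin = x.n_cols, Cout = w.n_cols;
  const int Do = out_extent(D, k, stride, pad);
  const int Ho = out_extent(H, k, stride, pad);
  const int Wo = out_extent(W, k, stride, pad);
  const int No = Do * Ho * Wo;
  arma::mat out(No, Cout);
  out.each_row() = bias.t();

  for (int cin = 0; cin < Cin; ++cin) {
    const double* xc = x.colptr(cin);
    for (int kw = 0; kw < k; ++kw) {
      int wlo, whi; valid_range(W, Wo, kw, stride, pad, wlo, whi);
      for (int kh = 0; kh < k; ++kh) {
        int hlo, hhi; valid_range(H, Ho, kh, stride, pad, hlo, hhi);
        for (int kd = 0; kd < k; ++kd) {
          int dlo, dhi; valid_range(D, Do, kd, stride, pad, dlo, dhi);
          if (dlo >= dhi) continue;
          const size_t wrow = (size_t)kd + (size_t)k * kh +
                              (size_t)k * k * kw + (size_t)k * k * k * cin;
          const int doff = kd - pad;
          std::vector<double> wv(Cout);
          for (int cout = 0; cout < Cout; ++cout)
            wv[cout] = w.at(wrow, cout);
          for (int ow = wlo; ow < whi; ++ow) {
            const int iw = ow * stride + kw - pad;
            for (int oh = hlo; oh < hhi; ++oh) {
              const int ih = oh * stride + kh - pad;
              const double* xp = xc + (size_t)D * ih + (size_t)D * H * iw + doff;
              const size_t ob = (size_t)Do * oh + (size_t)Do * Ho * ow;
              for (int cout = 0; cout < Cout; ++cout) {
                const double coeff = wv[cout];
                double* oc = out.colptr(cout) + ob;
                if (stride == 1) {
                  for (int od = dlo; od < dhi; ++od) oc[od] += coeff * xp[od];
                } else {
                  for (int od = dlo; od < dhi; ++od)
                    oc[od] += coeff * xp[(size_t)od * stride];
                }
              }
            }
          }
        }
      }
    }
  }
  return out;
}

// [[Rcpp::export]]
List cpp_conv3d_bw(const arma::mat& x, int D, int H, int W,
                   const arma::mat& w, const arma::mat& g,
                   int k, int stride, int pad) {
  const int Cin = x.n_cols, Cout = w.n_cols;
  const int Do = out_extent(D, k, stride, pad);
  const int Ho = out_extent(H, k, stride, pad);
  const int Wo = out_extent(W, k, stride, pad);
  arma::mat gx((size_t)D * H * W, Cin, arma::fill::zeros);
  arma::mat gw(w.n_rows, Cout, arma::fill::zeros);
  arma::vec gb = arma::sum(g, 0).t();

  for (int cin = 0; cin < Cin; ++cin) {
    const double* xc = x.colptr(cin);
    double* gxc = gx.colptr(cin);
    for (int kw = 0; kw < k; ++kw) {
      int wlo, whi; valid_range(W, Wo, kw, stride, pad, wlo, whi);
      for (int kh = 0; kh < k; ++kh) {
        int hlo, hhi; valid_range(H, Ho, kh, stride, pad, hlo, hhi);
        for (int kd = 0; kd < k; ++kd) {
          int dlo, dhi; valid_range(D, Do, kd, stride, pad, dlo, dhi);
          if (dlo >= dhi) continue;
          const size_t wrow = (size_t)kd + (size_t)k * kh +
                              (size_t)k * k * kw + (size_t)k * k * k * cin;
          const int doff = kd - pad;
          std::vector<double> acc(Cout, 0.0);
          std::vector<double> wv(Cout);
          for (int cout = 0; cout < Cout; ++cout)
            wv[cout] = w.at(wrow, cout);
          for (int ow = wlo; ow < whi; ++ow) {
            const int iw = ow * stride + kw - pad;
            for (int oh = hlo; oh < hhi; ++oh) {
              const int ih = oh * stride + kh - pad;
              const size_t ibase = (size_t)D * ih + (size_t)D * H * iw;
              const double* xp = xc + ibase + doff;
              double* gxp = gxc + ibase + doff;
              const size_t ob = (size_t)Do * oh + (size_t)Do * Ho * ow;
              for (int cout = 0; cout < Cout; ++cout) {
                const double coeff = wv[cout];
                const double* gp = g.colptr(cout) + ob;
                double s = 0.0;
                if (stride == 1) {
                  for (int od = dlo; od < dhi; ++od) {
                    s += gp[od] * xp[od];
                    gxp[od] += coeff * gp[od];
                  }
                } else {
                  for (int od = dlo; od < dhi; ++od) {
                    const size_t id = (size_t)od * stride;
                    s += gp[od] * xp[id];
                    gxp[id] += coeff * gp[od];
                  }
                }
                acc[cout] += s;
              }
            }
          }
          for (int cout = 0; cout < Cout; ++cout) gw(wrow, cout) = acc[cout];
        }
      }
    }
  }
  return List::create(Named("gx") = gx, Named("gw") = gw, Named("gb") = gb);
}
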