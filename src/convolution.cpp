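// 3D convolution primitives for the segmentation networks.
//
// Feature maps are stored as (channels x voxels) matrices with voxel linear
// index ix + nx*(iy + ny*iz) (x fastest, matching R's column-major arrays).
// Convolutions use im2col / col2im so the heavy lifting is a single BLAS
// matrix product.  Patch layout: row index c + C*(kx + k*(ky + k*kz)).

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

static inline int out_size(int n, int k, int stride, int pad) {
  return (n + 2 * pad - k) / stride + 1;
}

static arma::mat im2col3d(const arma::mat& x, const arma::ivec& dims,
                          int k, int stride, int pad, arma::ivec& odims) {
  const int C = x.n_rows;
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const int ox = out_size(nx, k, stride, pad);
  const int oy = out_size(ny, k, stride, pad);
  const int oz = out_size(nz, k, stride, pad);
  odims = {ox, oy, oz};
  arma::mat patches(C * k * k * k, (size_t)ox * oy * oz, arma::fill::zeros);
  for (int ozi = 0; ozi < oz; ++ozi) {
    for (int oyi = 0; oyi < oy; ++oyi) {
      for (int oxi = 0; oxi < ox; ++oxi) {
        const size_t col = (size_t)oxi + (size_t)ox * (oyi + (size_t)oy * ozi);
        double* pc = patches.colptr(col);
        for (int kz = 0; kz < k; ++kz) {
          const int iz = ozi * stride + kz - pad;
          if (iz < 0 || iz >= nz) continue;
          for (int ky = 0; ky < k; ++ky) {
            const int iy = oyi * stride + ky - pad;
            if (iy < 0 || iy >= ny) continue;
            for (int kx = 0; kx < k; ++kx) {
              const int ix = oxi * stride + kx - pad;
              if (ix < 0 || ix >= nx) continue;
              const size_t vox = (size_t)ix + (size_t)nx * (iy + (size_t)ny * iz);
              const double* src = x.colptr(vox);
              double* dst = pc + (size_t)C * (kx + k * (ky + (size_t)k * kz));
              for (int c = 0; c < C; ++c) dst[c] = src[c];
            }
          }
        }
      }
    }
  }
  return patches;
}

static void col2im3d(const arma::mat& patches, const arma::ivec& dims,
                     int C, int k, int stride, int pad, arma::mat& gx) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const int ox = out_size(nx, k, stride, pad);
  const int oy = out_size(ny, k, stride, pad);
  const int oz = out_size(nz, k, stride, pad);
  gx.zeros(C, (size_t)nx * ny * nz);
  for (int ozi = 0; ozi < oz; ++ozi) {
    for (int oyi = 0; oyi < oy; ++oyi) {
      for (int oxi = 0; oxi < ox; ++oxi) {
        const size_t col = (size_t)oxi + (size_t)ox * (oyi + (size_t)oy * ozi);
        const double* pc = patches.colptr(col);
        for (int kz = 0; kz < k; ++kz) {
          const int iz = ozi * stride + kz - pad;
          if (iz < 0 || iz >= nz) continue;
          for (int ky = 0; ky < k; ++ky) {
            const int iy = oyi * stride + ky - pad;
            if (iy < 0 || iy >= ny) continue;
            for (int kx = 0; kx < k; ++kx) {
              const int ix = oxi * stride + kx - pad;
              if (ix < 0 || ix >= nx) continue;
              const size_t vox = (size_t)ix + (size_t)nx * (iy + (size_t)ny * iz);
              double* dst = gx.colptr(vox);
              const double* src = pc + (size_t)C * (kx + k * (ky + (size_t)k * kz));
              for (int c = 0; c < C; ++c) dst[c] += src[c];
            }
          }
        }
      }
    }
  }
}

// [[Rcpp::export(name = ".conv3d_forward")]]
List conv3d_forward_cpp(const arma::mat& x, const IntegerVector& dims,
                        const arma::mat& W, const arma::vec& b,
                        int k, int stride, int pad) {
  arma::ivec d = {dims[0], dims[1], dims[2]};
  arma::ivec odims;
  arma::mat patches = im2col3d(x, d, k, stride, pad, odims);
  arma::mat y = W * patches;
  y.each_col() += b;
  return List::create(_["y"] = y,
                      _["odims"] = IntegerVector::create(odims[0], odims[1], odims[2]));
}

// [[Rcpp::export(name = ".conv3d_backward")]]
List conv3d_backward_cpp(const arma::mat& x, const IntegerVector& dims,
                         const arma::mat& W, const arma::mat& gy,
                         int k, int stride, int pad) {
  arma::ivec d = {dims[0], dims[1], dims[2]};
  arma::ivec odims;
  arma::mat patches = im2col3d(x, d, k, stride, pad, odims);
  arma::mat gW = gy * patches.t();
  arma::vec gb = arma::sum(gy, 1);
  arma::mat gpatch = W.t() * gy;
  arma::mat gx;
  col2im3d(gpatch, d, x.n_rows, k, stride, pad, gx);
  return List::create(_["gx"] = gx, _["gW"] = gW, _["gb"] = gb);
}
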