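// Low-level kernels for the convolutional activity model.
// Layout conventions:
//   * a batch of one-hot sequences is an arma::cube with dims (C_in, L, B)
//     (channels fastest, so a window X.slice(b).cols(p, p+k-1) is contiguous);
//   * layer activations between conv ops are matrices of shape (B*L_out, C)
//     with rows ordered batch-major: row = b*L_out + p (0-based).
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

// Unroll sliding windows of width k into rows of a matrix:
// out((b*Lout + p), (kk*Cin + c)) = X(c, p + kk, b)
// [[Rcpp::export]]
arma::mat cpp_im2col(const arma::cube& X, int k) {
  const int Cin = X.n_rows, L = X.n_cols, B = X.n_slices;
  const int Lout = L - k + 1;
  arma::mat out(B * Lout, Cin * k);
  for (int kk = 0; kk < k; ++kk) {
    for (int c = 0; c < Cin; ++c) {
      double* col = out.colptr(kk * Cin + c);
      for (int b = 0; b < B; ++b) {
        const arma::mat& S = X.slice(b);
        for (int p = 0; p < Lout; ++p) {
          col[b * Lout + p] = S(c, p + kk);
        }
      }
    }
  }
  return out;
}

// Adjoint of cpp_im2col: scatter-add window gradients back onto the input.
// [[Rcpp::export]]
arma::cube cpp_col2im(const arma::mat& dM, int Cin, int L, int B, int k) {
  const int Lout = L - k + 1;
  arma::cube dX(Cin, L, B, arma::fill::zeros);
  for (int kk = 0; kk < k; ++kk) {
    for (int c = 0; c < Cin; ++c) {
      const double* col = dM.colptr(kk * Cin + c);
      for (int b = 0; b < B; ++b) {
        arma::mat& S = dX.slice(b);
        for (int p = 0; p < Lout; ++p) {
          S(c, p + kk) += col[b * Lout + p];
        }
      }
    }
  }
  return dX;
}

// Max pooling over non-overlapping windows of `pw` consecutive positions
// within each batch block. Z has B*Lout rows; output has B*(Lout/pw) rows.
// Returns the pooled matrix and the 1-based row index of each max.
// [[Rcpp::export]]
List cpp_maxpool(const arma::mat& Z, int B, int Lout, int pw) {
  const int C = Z.n_cols;
  const int Lp = Lout / pw;
  arma::mat Y(B * Lp, C);
  arma::umat idx(B * Lp, C);
  for (int c = 0; c < C; ++c) {
    const double* z = Z.colptr(c);
    double* y = Y.colptr(c);
    arma::uword* ix = idx.colptr(c);
    for (int b = 0; b < B; ++b) {
      for (int q = 0; q < Lp; ++q) {
        int base = b * Lout + q * pw;
        double best = z[base];
        int besti = base;
        for (int u = 1; u < pw; ++u) {
          if (z[base + u] > best) { best = z[base + u]; besti = base + u; }
        }
        y[b * Lp + q] = best;
        ix[b * Lp + q] = besti + 1; // 1-based for R
      }
    }
  }
  return List::create(_["y"] = Y, _["idx"] = idx);
}

// [[Rcpp::export]]
arma::mat cpp_maxpool_bw(const arma::mat& dY, const arma::umat& idx, int nrows) {
  const int C = dY.n_cols;
  arma::mat dZ(nrows, C, arma::fill::zeros);
  for (int c = 0; c < C; ++c) {
    const double* dy = dY.colptr(c);
    const arma::uword* ix = idx.colptr(c);
    double* dz = dZ.colptr(c);
    for (arma::uword r = 0; r < dY.n_rows; ++r) {
      dz[ix[r] - 1] += dy[r];
    }
  }
  return dZ;
}

// maxpool backward fused with the ReLU mask (A is the post-ReLU activation)
// [[Rcpp::export]]
arma::mat cpp_maxpool_relu_bw(const arma::mat& dY, const arma::umat& idx,
                              int nrows, const arma::mat& A) {
  const int C = dY.n_cols;
  arma::mat dZ(nrows, C, arma::fill::zeros);
  for (int c = 0; c < C; ++c) {
    const double* dy = dY.colptr(c);
    const arma::uword* ix = idx.colptr(c);
    const double* a = A.colptr(c);
    double* dz = dZ.colptr(c);
    for (arma::uword r = 0; r < dY.n_rows; ++r) {
      const arma::uword t = ix[r] - 1;
      if (a[t] > 0) dz[t] += dy[r];
    }
  }
  return dZ;
}

// Fused batch-norm backward on the (B*L, C) layout.
// Z is the pre-bias conv output; xhat = (Z + bias - mu) * inv;
// dA is the cotangent of the BN output. Returns dZ, dgamma, dbeta.
// In eval mode (training = false) the mu/inv are constants.
// [[Rcpp::export]]
List cpp_bn_bw(const arma::mat& Z, const arma::mat& dA, const arma::vec& inv,
               const arma::vec& gamma, const arma::vec& bias,
               const arma::vec& mu, bool training) {
  const arma::uword N = Z.n_rows, C = Z.n_cols;
  arma::mat dZ(N, C);
  arma::vec dgamma(C), dbeta(C);
  for (arma::uword c = 0; c < C; ++c) {
    const double* z = Z.colptr(c);
    const double* da = dA.colptr(c);
    double* dz = dZ.colptr(c);
    const double shift = (bias[c] - mu[c]) * inv[c];
    double s_da = 0, s_daxh = 0;
    for (arma::uword r = 0; r < N; ++r) {
      const double xh = z[r] * inv[c] + shift;
      s_da += da[r];
      s_daxh += da[r] * xh;
    }
    dgamma[c] = s_daxh;
    dbeta[c] = s_da;
    const double g = gamma[c];
    if (training) {
      const double m_da = s_da / N, m_daxh = s_daxh / N;
      for (arma::uword r = 0; r < N; ++r) {
        const double xh = z[r] * inv[c] + shift;
        dz[r] = g * inv[c] * (da[r] - m_da - xh * m_daxh);
      }
    } else {
      const double gi = g * inv[c];
      for (arma::uword r = 0; r < N; ++r) dz[r] = gi * da[r];
    }
  }
  return List::create(_["dZ"] = dZ, _["dgamma"] = dgamma, _["dbeta"] = dbeta);
}

// im2col on the (B*L, C) matrix layout (rows ordered b*L + p):
// out(b*Lout + p, kk*C + c) = Z(b*L + p + kk, c)
// [[Rcpp::export]]
arma::mat cpp_im2col_mat(const arma::mat& Z, int B, int L, int k) {
  const int C = Z.n_cols;
  const int Lout = L - k + 1;
  arma::mat out(B * Lout, C * k);
  for (int kk = 0; kk < k; ++kk) {
    for (int c = 0; c < C; ++c) {
      const double* src = Z.colptr(c);
      double* dst = out.colptr(kk * C + c);
      for (int b = 0; b < B; ++b) {
        std::memcpy(dst + b * Lout, src + b * L + kk, Lout * sizeof(double));
      }
    }
  }
  return out;
}

// [[Rcpp::export]]
arma::mat cpp_col2im_mat(const arma::mat& dM, int B, int L, int k) {
  const int C = dM.n_cols / k;
  const int Lout = L - k + 1;
  arma::mat dZ(B * L, C, arma::fill::zeros);
  for (int kk = 0; kk < k; ++kk) {
    for (int c = 0; c < C; ++c) {
      const double* src = dM.colptr(kk * C + c);
      double* dst = dZ.colptr(c);
      for (int b = 0; b < B; ++b) {
        const double* s = src + b * Lout;
        double* d = dst + b * L + kk;
        for (int p = 0; p < Lout; ++p) d[p] += s[p];
      }
    }
  }
  return dZ;
}

// column-wise affine transform with optional (leaky) ReLU: a[c]*Z + b[c]
// [[Rcpp::export]]
arma::mat cpp_affine_cols(const arma::mat& Z, const arma::vec& a,
                          const arma::vec& b, bool relu, double alpha = 0.0) {
  arma::mat out(Z.n_rows, Z.n_cols);
  for (arma::uword c = 0; c < Z.n_cols; ++c) {
    const double* z = Z.colptr(c);
    double* o = out.colptr(c);
    const double ac = a[c], bc = b[c];
    if (relu) {
      for (arma::uword r = 0; r < Z.n_rows; ++r) {
        double v = ac * z[r] + bc;
        o[r] = v > 0 ? v : alpha * v;
      }
    } else {
      for (arma::uword r = 0; r < Z.n_rows; ++r) o[r] = ac * z[r] + bc;
    }
  }
  return out;
}

// Encode a batch of equal-length DNA strings as a (4, L, B) cube,
// rows A,C,G,T; N (or any other IUPAC ambiguity) encodes as zeros.
// [[Rcpp::export]]
arma::cube cpp_encode_batch(const std::vector<std::string>& seqs) {
  const int B = seqs.size();
  const int L = seqs.empty() ? 0 : seqs[0].size();
  arma::cube X(4, L, B, arma::fill::zeros);
  for (int b = 0; b < B; ++b) {
    const std::string& s = seqs[b];
    arma::mat& S = X.slice(b);
    for (int p = 0; p < L; ++p) {
      switch (s[p]) {
        case 'A': case 'a': S(0, p) = 1.0; break;
        case 'C': case 'c': S(1, p) = 1.0; break;
        case 'G': case 'g': S(2, p) = 1.0; break;
        case 'T': case 't': S(3, p) = 1.0; break;
        default: break;
      }
    }
  }
  return X;
}
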