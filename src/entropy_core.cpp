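#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

// Per-voxel Cloude-Pottier entropy of a Jones-matrix volume.
//
// data: complex array with dim (n_frame, n_lateral, n_depth, 2, 2),
//       column-major as stored by R.
// The local coherency (density) matrix over a rectangular window W is
//   rho = sum_{i in W} k_i k_i^H / sum_{i in W} ||k_i||^2
// with k = (J11, J12, J21, J22) the lexicographic vectorization.
// Additive i.i.d. circular Gaussian noise of per-element variance s2
// contributes 4*s2 per sample to the total power and s2*I4 to the
// unnormalized coherency sum; the correction subtracts that expectation,
// clips negative eigenvalues and renormalizes.
// Entropy is -sum lambda_i log4 lambda_i over normalized eigenvalues.

// [[Rcpp::export(name = ".entropyVolumeCpp")]]
List entropyVolumeCpp(const ComplexVector& data,
                      const IntegerVector& dims,
                      const IntegerVector& halfwidths,
                      const double noiseVariance,
                      const double snrFloorDb,
                      const bool correct) {
  const int nf = dims[0], nl = dims[1], nd = dims[2];
  const int hf = halfwidths[2], hl = halfwidths[1], hd = halfwidths[0];
  const R_xlen_t nvox = (R_xlen_t)nf * nl * nd;

  NumericVector entropy(nvox, NA_REAL);
  LogicalVector valid(nvox, false);
  IntegerVector nsamp(nvox, 0);
  // signal-free voxels where estimated noise power exceeds total power
  LogicalVector noiseFlag(nvox, false);

  const std::complex<double>* J =
    reinterpret_cast<const std::complex<double>*>(data.begin());
  // element (f,l,d,i,j) at f + nf*(l + nl*(d + nd*(i + 2*j)))
  const R_xlen_t sI = (R_xlen_t)nf * nl * nd;        // stride for i
  const R_xlen_t sJ = 2 * sI;                        // stride for j

  const double log4 = std::log(4.0);
  const double floorLin = std::pow(10.0, snrFloorDb / 10.0);

  arma::cx_mat rho(4, 4);
  arma::cx_vec k(4);
  arma::vec eval(4);

  for (int d = 0; d < nd; ++d) {
    const int d0 = std::max(0, d - hd), d1 = std::min(nd - 1, d + hd);
    for (int l = 0; l < nl; ++l) {
      const int l0 = std::max(0, l - hl), l1 = std::min(nl - 1, l + hl);
      for (int f = 0; f < nf; ++f) {
        const int f0 = std::max(0, f - hf), f1 = std::min(nf - 1, f + hf);
        const int n = (d1 - d0 + 1) * (l1 - l0 + 1) * (f1 - f0 + 1);
        const R_xlen_t out = f + (R_xlen_t)nf * (l + (R_xlen_t)nl * d);
        nsamp[out] = n;
        if (n < 4) continue;  // rank-4 statistics need >= 4 samples

        rho.zeros();
        double power = 0.0;
        for (int dd = d0; dd <= d1; ++dd) {
          for (int ll = l0; ll <= l1; ++ll) {
            for (int ff = f0; ff <= f1; ++ff) {
              const R_xlen_t base = ff + (R_xlen_t)nf * (ll + (R_xlen_t)nl * dd);
              k(0) = J[base];                 // J11
              k(1) = J[base + sJ];            // J12
              k(2) = J[base + sI];            // J21
              k(3) = J[base + sI + sJ];       // J22
              power += std::norm(k(0)) + std::norm(k(1)) +
                       std::norm(k(2)) + std::norm(k(3));
              rho += k * k.t();               // k.t() is conjugate transpose
            }
          }
        }
        if (power <= 0.0) continue;  // empty window: no defined rho

        // validity mask: window mean intensity must sit snrFloorDb above
        // the per-sample noise floor 4*noiseVariance
        if (noiseVariance > 0.0 && snrFloorDb > R_NegInf) {
          const double meanIntensity = power / n;
          if (meanIntensity < 4.0 * noiseVariance * floorLin) continue;
        }

        rho /= power;

        if (correct && noiseVariance > 0.0) {
          const double fNoise = 4.0 * noiseVariance * n / power;
          if (fNoise >= 1.0) {
            // noise power exceeds total power: signal-free, maximally mixed
            rho.eye();
            rho *= 0.25;
            noiseFlag[out] = true;
          } else {
            rho.diag() -= fNoise * 0.25;
            rho /= (1.0 - fNoise);
          }
        }

        arma::eig_sym(eval, rho);
        double s = 0.0, h = 0.0;
        for (int i = 0; i < 4; ++i) {
          if (eval(i) < 0.0) eval(i) = 0.0;  // clip eigenvalue noise
          s += eval(i);
        }
        if (s <= 0.0) continue;
        for (int i = 0; i < 4; ++i) {
          const double p = eval(i) / s;
          if (p > 0.0) h -= p * std::log(p) / log4;
        }
        if (h < 0.0) h = 0.0;
        if (h > 1.0) h = 1.0;
        entropy[out] = h;
        valid[out] = true;
      }
    }
  }

  entropy.attr("dim") = IntegerVector::create(nf, nl, nd);
  valid.attr("dim") = IntegerVector::create(nf, nl, nd);
  noiseFlag.attr("dim") = IntegerVector::create(nf, nl, nd);
  return List::create(_["entropy"] = entropy,
                      _["valid"] = valid,
                      _["noiseFlagged"] = noiseFlag);
}

// Per-voxel intensity: sum of squared moduli of the four Jones elements.
// [[Rcpp::export(name = ".intensityVolumeCpp")]]
NumericVector intensityVolumeCpp(const ComplexVector& data,
                                 const IntegerVector& dims) {
  const int nf = dims[0], nl = dims[1], nd = dims[2];
  const R_xlen_t nvox = (R_xlen_t)nf * nl * nd;
  NumericVector out(nvox);
  const std::complex<double>* J =
    reinterpret_cast<const std::complex<double>*>(data.begin());
  for (R_xlen_t v = 0; v < nvox; ++v) {
    out[v] = std::norm(J[v]) + std::norm(J[v + nvox]) +
             std::norm(J[v + 2 * nvox]) + std::norm(J[v + 3 * nvox]);
  }
  out.attr("dim") = IntegerVector::create(nf, nl, nd);
  return out;
}
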