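#include <Rcpp.h>
using namespace Rcpp;

// Circular convolution of x with a short filter h dilated by inserting
// (dilation - 1) zeros between taps ("algorithme a trous"). With
// adjoint = true the transpose operator is applied instead, which is what
// the inverse undecimated transform needs. Circular indexing keeps the
// transform exactly equivariant under circular shifts of x. The filter
// reach d*(L-1) is tiny compared to the signal, so the wrapped indexing is
// only paid at the edges.
// [[Rcpp::export]]
NumericVector circ_dilated_conv(NumericVector x, NumericVector h,
                                int dilation, bool adjoint) {
  const R_xlen_t n = x.size();
  const int L = h.size();
  NumericVector out(n);
  if (n == 0) return out;
  const R_xlen_t reach = (R_xlen_t)dilation * (L - 1);
  const double *px = REAL(x);
  const double *ph = REAL(h);
  double *po = REAL(out);

  if (!adjoint) {
    // out[i] = sum_k h[k] * x[(i - d*k) mod n]
    R_xlen_t edge = std::min(reach, n);
    for (R_xlen_t i = 0; i < edge; ++i) {
      double acc = 0.0;
      for (int k = 0; k < L; ++k) {
        R_xlen_t idx = (i - (R_xlen_t)dilation * k) % n;
        if (idx < 0) idx += n;
        acc += ph[k] * px[idx];
      }
      po[i] = acc;
    }
    for (R_xlen_t i = edge; i < n; ++i) {
      double acc = 0.0;
      const double *base = px + i;
      for (int k = 0; k < L; ++k)
        acc += ph[k] * base[-(R_xlen_t)dilation * k];
      po[i] = acc;
    }
  } else {
    // out[i] = sum_k h[k] * x[(i + d*k) mod n]
    R_xlen_t interior = n > reach ? n - reach : 0;
    for (R_xlen_t i = 0; i < interior; ++i) {
      double acc = 0.0;
      const double *base = px + i;
      for (int k = 0; k < L; ++k)
        acc += ph[k] * base[(R_xlen_t)dilation * k];
      po[i] = acc;
    }
    for (R_xlen_t i = interior; i < n; ++i) {
      double acc = 0.0;
      for (int k = 0; k < L; ++k) {
        R_xlen_t idx = (i + (R_xlen_t)dilation * k) % n;
        acc += ph[k] * px[idx];
      }
      po[i] = acc;
    }
  }
  return out;
}

// Add a spike waveform into a signal in place at given 0-based onsets,
// clipping at the signal bounds. Used by the simulator's superposition
// step, where an R-level loop over tens of thousands of spikes would be
// the bottleneck.
// [[Rcpp::export]]
void add_at(NumericVector x, NumericVector w, IntegerVector onsets) {
  const R_xlen_t n = x.size();
  const R_xlen_t L = w.size();
  for (R_xlen_t s = 0; s < onsets.size(); ++s) {
    const R_xlen_t o = onsets[s];
    for (R_xlen_t k = 0; k < L; ++k) {
      const R_xlen_t idx = o + k;
      if (idx >= 0 && idx < n) x[idx] += w[k];
    }
  }
}
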