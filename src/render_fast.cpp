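#include <Rcpp.h>
#include <cmath>

// Beer-Lambert digital staining, scalar loop.
// out_n = floor(255 * exp(-j_n * h) * exp(-k_n * e) + 0.5), h/e clipped to
// `ceiling` first. The arithmetic (order of operations, libm exp, half-up
// rounding) must match the vectorized R reference path bit for bit; keep the
// expression identical to render_reference() in R/render.R.
// [[Rcpp::export(name = ".bl_render_cpp")]]
Rcpp::IntegerVector bl_render_cpp(Rcpp::NumericVector h, Rcpp::NumericVector e,
                                  Rcpp::NumericVector j, Rcpp::NumericVector k,
                                  double ceiling) {
  const R_xlen_t n = h.size();
  if (e.size() != n) Rcpp::stop("channel planes must have equal size");
  Rcpp::IntegerVector out(n * 3);
  for (int c = 0; c < 3; ++c) {
    const double jc = j[c], kc = k[c];
    int* o = out.begin() + (R_xlen_t)c * n;
    for (R_xlen_t i = 0; i < n; ++i) {
      double hv = h[i], ev = e[i];
      if (hv > ceiling) hv = ceiling;
      if (ev > ceiling) ev = ceiling;
      double v = 255.0 * std::exp(-jc * hv) * std::exp(-kc * ev);
      double r = std::floor(v + 0.5);
      if (r < 0.0) r = 0.0;
      if (r > 255.0) r = 255.0;
      o[i] = (int)r;
    }
  }
  return out;
}
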