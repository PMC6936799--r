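#include <Rcpp.h>

using namespace Rcpp;

// Recursive route to the N-molecule cPCH distribution from the
// single-molecule distributions: a bivariate compound-Poisson (Panjer-type)
// recursion seeded at (0, 0), filled along the n_x = 0 and n_y = 0 edges
// and then the interior.

// [[Rcpp::export(name = ".pn_recursion_cpp")]]
NumericMatrix pn_recursion_cpp(List p1_list, NumericVector N,
                               double lamA, double lamB,
                               int Lx, int Ly) {
  const int w = p1_list.size();
  NumericMatrix C(Lx, Ly);   // sum_i N_i p1_i(q, z)
  double p100 = 0.0;         // sum_i N_i (1 - p1_i(0,0))
  for (int i = 0; i < w; ++i) {
    NumericMatrix p1 = p1_list[i];
    if (p1.nrow() < Lx || p1.ncol() < Ly)
      stop("single-molecule PMF smaller than requested grid");
    for (int q = 0; q < Lx; ++q)
      for (int z = 0; z < Ly; ++z)
        C(q, z) += N[i] * p1(q, z);
    p100 += N[i] * (1.0 - p1(0, 0));
  }

  NumericMatrix P(Lx, Ly);
  const double logp00 = -p100 - lamA - lamB;
  if (logp00 < -700.0)
    stop("seed probability underflows; use the FFT route for this model");
  P(0, 0) = std::exp(logp00);

  for (int ny = 1; ny < Ly; ++ny) {
    double acc = lamB * P(0, ny - 1);
    for (int q = 1; q <= ny; ++q)
      acc += q * C(0, q) * P(0, ny - q);
    P(0, ny) = acc / ny;
  }
  for (int nx = 1; nx < Lx; ++nx) {
    for (int ny = 0; ny < Ly; ++ny) {
      double acc = lamA * P(nx - 1, ny);
      for (int z = 0; z <= ny; ++z)
        for (int q = 1; q <= nx; ++q)
          acc += q * C(q, z) * P(nx - q, ny - z);
      P(nx, ny) = acc / nx;
    }
    Rcpp::checkUserInterrupt();
  }
  return P;
}
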