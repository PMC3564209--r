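#include <Rcpp.h>
using namespace Rcpp;

// Euler-Maruyama update of the linear two-population system:
//   x <- x + dt*((N1-1)*x - N1*y)/tau1 + w_i      (w_i: precomputed kappa*sqrt(dt)*N(0,1))
//   y <- y + dt*( N2*x - (N2+1)*y)/tau2
// Noise increments are generated on the R side so that seeding follows R's RNG.
// [[Rcpp::export]]
List em_core(double x0, double y0, double N1, double N2,
             double tau1, double tau2, double dt,
             NumericVector noise, double bound) {
  const int n = noise.size();
  NumericVector x(n + 1), y(n + 1);
  x[0] = x0;
  y[0] = y0;
  const double ax = dt * (N1 - 1.0) / tau1;
  const double bx = dt * N1 / tau1;
  const double ay = dt * N2 / tau2;
  const double by = dt * (N2 + 1.0) / tau2;
  bool blown = false;
  int n_done = n;
  for (int i = 0; i < n; ++i) {
    const double xi = x[i], yi = y[i];
    x[i + 1] = xi + ax * xi - bx * yi + noise[i];
    y[i + 1] = yi + ay * xi - by * yi;
    if (!std::isfinite(x[i + 1]) || std::fabs(x[i + 1]) > bound) {
      blown = true;
      n_done = i + 1;
      break;
    }
  }
  return List::create(_["x"] = x, _["y"] = y,
                      _["blown"] = blown, _["n_done"] = n_done);
}
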