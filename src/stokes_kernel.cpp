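// Hot kernel of the local Stokes solve: one application of the penalized
// momentum operator  -mu lap U - lambda grad(div U) + eta chi U  on the
// staggered (MAC) grid, restricted to free degrees of freedom.  Ghost
// layers are filled by the caller (R side); arrays arrive padded:
//   u: (nx+1, ny+2, nz+2), v: (nx+2, ny+1, nz+2), w: (nx+2, ny+2, nz+1)
// chi arrays hold the solid fraction at real face positions:
//   chi_u: (nx+1, ny, nz), chi_v: (nx, ny+1, nz), chi_w: (nx, ny, nz+1)

#include <Rcpp.h>
using namespace Rcpp;

// [[Rcpp::export]]
List stokes_apply_kernel(NumericVector u, NumericVector v, NumericVector w,
                         NumericVector chi_u, NumericVector chi_v,
                         NumericVector chi_w,
                         int nx, int ny, int nz,
                         double delta, double mu, double lambda,
                         double eta) {
  const int du1 = nx + 1, du2 = ny + 2;
  const int dv1 = nx + 2, dv2 = ny + 1;
  const int dw1 = nx + 2, dw2 = ny + 2;
  const double id2 = 1.0 / (delta * delta);
  NumericVector ou(u.size()), ov(v.size()), ow(w.size());
  std::vector<double> div((size_t)nx * ny * nz);

#define U(i, j, k) u[(i) + du1 * ((j) + (size_t)du2 * (k))]
#define V(i, j, k) v[(i) + dv1 * ((j) + (size_t)dv2 * (k))]
#define W(i, j, k) w[(i) + dw1 * ((j) + (size_t)dw2 * (k))]
#define OU(i, j, k) ou[(i) + du1 * ((j) + (size_t)du2 * (k))]
#define OV(i, j, k) ov[(i) + dv1 * ((j) + (size_t)dv2 * (k))]
#define OW(i, j, k) ow[(i) + dw1 * ((j) + (size_t)dw2 * (k))]
#define DIV(i, j, k) div[(i) + (size_t)nx * ((j) + (size_t)ny * (k))]
#define CU(i, j, k) chi_u[(i) + (nx + 1) * ((j) + (size_t)ny * (k))]
#define CV(i, j, k) chi_v[(i) + nx * ((j) + (size_t)(ny + 1) * (k))]
#define CW(i, j, k) chi_w[(i) + nx * ((j) + (size_t)ny * (k))]

  // divergence at cell centres (0-based cell c maps to padded index c+1)
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j)
      for (int i = 0; i < nx; ++i)
        DIV(i, j, k) = (U(i + 1, j + 1, k + 1) - U(i, j + 1, k + 1) +
                        V(i + 1, j + 1, k + 1) - V(i + 1, j, k + 1) +
                        W(i + 1, j + 1, k + 1) - W(i + 1, j + 1, k)) / delta;

  // u component: free at padded i = 1..nx-1 (interior faces), j = 1..ny,
  // k = 1..nz (0-based padded indices)
  for (int k = 1; k <= nz; ++k)
    for (int j = 1; j <= ny; ++j)
      for (int i = 1; i <= nx - 1; ++i) {
        double lap = (U(i + 1, j, k) + U(i - 1, j, k) +
                      U(i, j + 1, k) + U(i, j - 1, k) +
                      U(i, j, k + 1) + U(i, j, k - 1) -
                      6.0 * U(i, j, k)) * id2;
        double gd = (DIV(i, j - 1, k - 1) - DIV(i - 1, j - 1, k - 1)) / delta;
        OU(i, j, k) = -mu * lap - lambda * gd +
          eta * CU(i, j - 1, k - 1) * U(i, j, k);
      }

  // v component: free at padded j = 1..ny-1, i = 1..nx, k = 1..nz
  for (int k = 1; k <= nz; ++k)
    for (int j = 1; j <= ny - 1; ++j)
      for (int i = 1; i <= nx; ++i) {
        double lap = (V(i + 1, j, k) + V(i - 1, j, k) +
                      V(i, j + 1, k) + V(i, j - 1, k) +
                      V(i, j, k + 1) + V(i, j, k - 1) -
                      6.0 * V(i, j, k)) * id2;
        double gd = (DIV(i - 1, j, k - 1) - DIV(i - 1, j - 1, k - 1)) / delta;
        OV(i, j, k) = -mu * lap - lambda * gd +
          eta * CV(i - 1, j, k - 1) * V(i, j, k);
      }

  // w component: free at padded k = 1..nz-1, i = 1..nx, j = 1..ny
  for (int k = 1; k <= nz - 1; ++k)
    for (int j = 1; j <= ny; ++j)
      for (int i = 1; i <= nx; ++i) {
        double lap = (W(i + 1, j, k) + W(i - 1, j, k) +
                      W(i, j + 1, k) + W(i, j - 1, k) +
                      W(i, j, k + 1) + W(i, j, k - 1) -
                      6.0 * W(i, j, k)) * id2;
        double gd = (DIV(i - 1, j - 1, k) - DIV(i - 1, j - 1, k - 1)) / delta;
        OW(i, j, k) = -mu * lap - lambda * gd +
          eta * CW(i - 1, j - 1, k) * W(i, j, k);
      }

#undef U
#undef V
#undef W
#undef OU
#undef OV
#undef OW
#undef DIV
#undef CU
#undef CV
#undef CW

  return List::create(_["u"] = ou, _["v"] = ov, _["w"] = ow);
}
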