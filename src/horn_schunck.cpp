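#include <Rcpp.h>
#include <cmath>
#include <algorithm>
using namespace Rcpp;

// Horn-Schunck dense optical flow between two frames.
//
// Derivatives use the original forward 2x2x2 averaging stencils; image
// borders replicate edge values (indices are clamped).  The solution is
// iterated with the Jacobi update
//   u <- ubar - Ex (Ex ubar + Ey vbar + Et) / (alpha^2 + Ex^2 + Ey^2)
// where ubar/vbar are the standard 3x3 local averages (1/6 edge, 1/12
// diagonal weights).  Iteration stops when the mean absolute update over
// both components drops below `tol`, or after `n_iter` sweeps.
//
// Convention: u is displacement along columns (+x, rightward), v along
// rows (+y, downward), in pixels per frame interval, mapping frame 1
// onto frame 2.

static inline int clampi(int x, int hi) {
  return x < 0 ? 0 : (x > hi ? hi : x);
}

// [[Rcpp::export(rng = false)]]
List hs_flow_cpp(const NumericMatrix& I1, const NumericMatrix& I2,
                 double alpha, int n_iter, double tol) {
  const int H = I1.nrow(), W = I1.ncol();
  const double a2 = alpha * alpha;

  NumericMatrix Ex(H, W), Ey(H, W), Et(H, W);
  for (int j = 0; j < W; ++j) {
    int j1 = clampi(j + 1, W - 1);
    for (int i = 0; i < H; ++i) {
      int i1 = clampi(i + 1, H - 1);
      Ex(i, j) = 0.25 * ((I1(i, j1) - I1(i, j)) + (I1(i1, j1) - I1(i1, j)) +
                         (I2(i, j1) - I2(i, j)) + (I2(i1, j1) - I2(i1, j)));
      Ey(i, j) = 0.25 * ((I1(i1, j) - I1(i, j)) + (I1(i1, j1) - I1(i, j1)) +
                         (I2(i1, j) - I2(i, j)) + (I2(i1, j1) - I2(i, j1)));
      Et(i, j) = 0.25 * ((I2(i, j) - I1(i, j)) + (I2(i1, j) - I1(i1, j)) +
                         (I2(i, j1) - I1(i, j1)) + (I2(i1, j1) - I1(i1, j1)));
    }
  }

  NumericMatrix u(H, W), v(H, W), un(H, W), vn(H, W);
  int iter = 0;
  bool converged = false;
  const double n_upd = 2.0 * H * W;

  for (iter = 1; iter <= n_iter; ++iter) {
    double upd = 0.0;
    for (int j = 0; j < W; ++j) {
      int jm = clampi(j - 1, W - 1), jp = clampi(j + 1, W - 1);
      for (int i = 0; i < H; ++i) {
        int im = clampi(i - 1, H - 1), ip = clampi(i + 1, H - 1);
        double ubar =
          (u(im, j) + u(ip, j) + u(i, jm) + u(i, jp)) / 6.0 +
          (u(im, jm) + u(im, jp) + u(ip, jm) + u(ip, jp)) / 12.0;
        double vbar =
          (v(im, j) + v(ip, j) + v(i, jm) + v(i, jp)) / 6.0 +
          (v(im, jm) + v(im, jp) + v(ip, jm) + v(ip, jp)) / 12.0;
        double ex = Ex(i, j), ey = Ey(i, j);
        double r = (ex * ubar + ey * vbar + Et(i, j)) / (a2 + ex * ex + ey * ey);
        double uu = ubar - ex * r;
        double vv = vbar - ey * r;
        upd += std::fabs(uu - u(i, j)) + std::fabs(vv - v(i, j));
        un(i, j) = uu;
        vn(i, j) = vv;
      }
    }
    std::swap(u, un);
    std::swap(v, vn);
    if (upd / n_upd < tol) {
      converged = true;
      break;
    }
  }
  if (iter > n_iter) iter = n_iter;

  return List::create(_["u"] = u, _["v"] = v,
                      _["iterations"] = iter, _["converged"] = converged);
}
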