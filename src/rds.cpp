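#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Ternary random-dot stereogram core.
//
// Images are surround x surround integer grids with values in {-1, 0, +1}
// (column-major, row = y, column = x). A central center x center square
// carries the disparity plane; the surround is a correlated (c = +1),
// zero-disparity dot field at the same density.
//
// Disparity convention: a patch with disparity d has its left-eye copy at
// x-offset base + floor(d/2) and its right-eye copy at base + floor(d/2) - d,
// so that sampling I_R(x - d, y) against I_L(x, y) aligns the two copies when
// the window disparity equals the patch disparity. Negative d = crossed.

static inline int ternary_draw(double rho) {
  double u = unif_rand();
  if (u < rho / 2.0) return 1;
  if (u < rho) return -1;
  return 0;
}

// Fill one stereo pair in place. RNG draw order is fixed and documented:
// (1) one uniform per surround pixel (column-major over the full grid),
// (2) two uniforms per central-square pixel (dot/sign, then match flag),
// column-major over the square.
static void fill_pair(int *L, int *R, int S, int C, double rho, double c,
                      int off_y, int off_xL, int off_xR) {
  const double p_match = (1.0 + c) / 2.0;
  for (int j = 0; j < S; ++j) {
    for (int i = 0; i < S; ++i) {
      int v = ternary_draw(rho);
      L[i + j * S] = v;
      R[i + j * S] = v;
    }
  }
  for (int j = 0; j < C; ++j) {
    for (int i = 0; i < C; ++i) {
      int v = ternary_draw(rho);
      double u2 = unif_rand();
      int m = (u2 < p_match) ? 1 : -1;
      L[(i + off_y) + (j + off_xL) * S] = v;
      R[(i + off_y) + (j + off_xR) * S] = v * m;
    }
  }
}

static inline int left_offset(int d) {
  return (int)std::floor(d / 2.0);
}

static void square_offsets(int S, int C, int d, int *off_L, int *off_R) {
  int base = (S - C) / 2;
  int hL = left_offset(d);
  *off_L = base + hL;
  *off_R = base + hL - d;
}

static void check_offsets(int S, int C, int off_L, int off_R, const char *what) {
  if (off_L < 0 || off_L + C > S || off_R < 0 || off_R + C > S)
    stop("%s does not fit inside the %d-px surround (offsets %d, %d)",
         what, S, off_L, off_R);
}

// [[Rcpp::export(name = ".gen_rds_cpp")]]
List gen_rds_cpp(int center, int surround, double rho, double c, int ds) {
  int off_L, off_R;
  square_offsets(surround, center, ds, &off_L, &off_R);
  check_offsets(surround, center, off_L, off_R, "central square");
  int base = (surround - center) / 2;
  IntegerMatrix L(surround, surround), R(surround, surround);
  fill_pair(L.begin(), R.begin(), surround, center, rho, c, base, off_L, off_R);
  return List::create(_["left"] = L, _["right"] = R,
                      _["x_offset_left"] = off_L + 1,
                      _["x_offset_right"] = off_R + 1,
                      _["y_offset"] = base + 1);
}

// Per-frame outputs of the cross-correlation and cross-matching operators for
// two detector windows (typically near, d1 = -|d_s|, and far, d2 = +|d_s|).
// Each window is a center x center square positioned with the same symmetric
// split as the stimulus square. Columns: C(d1), C(d2), M(d1), M(d2).
// [[Rcpp::export(name = ".frame_outputs_cpp")]]
NumericMatrix frame_outputs_cpp(int n_frames, int center, int surround,
                                double rho, double c, int ds,
                                int d1, int d2) {
  int sq_L, sq_R;
  square_offsets(surround, center, ds, &sq_L, &sq_R);
  check_offsets(surround, center, sq_L, sq_R, "central square");
  int w1_L, w1_R, w2_L, w2_R;
  square_offsets(surround, center, d1, &w1_L, &w1_R);
  check_offsets(surround, center, w1_L, w1_R, "detector window");
  square_offsets(surround, center, d2, &w2_L, &w2_R);
  check_offsets(surround, center, w2_L, w2_R, "detector window");
  int base = (surround - center) / 2;

  const double k = (double)center * center;
  std::vector<int> L(surround * surround), R(surround * surround);
  NumericMatrix out(n_frames, 4);

  for (int f = 0; f < n_frames; ++f) {
    fill_pair(L.data(), R.data(), surround, center, rho, c, base, sq_L, sq_R);
    int cc1 = 0, cc2 = 0, mm1 = 0, mm2 = 0;
    for (int j = 0; j < center; ++j) {
      const int *l1 = &L[(w1_L + j) * surround + base];
      const int *r1 = &R[(w1_R + j) * surround + base];
      const int *l2 = &L[(w2_L + j) * surround + base];
      const int *r2 = &R[(w2_R + j) * surround + base];
      for (int i = 0; i < center; ++i) {
        int p1 = l1[i] * r1[i];
        int p2 = l2[i] * r2[i];
        cc1 += p1;
        cc2 += p2;
        if (p1 > 0) ++mm1;
        if (p2 > 0) ++mm2;
      }
    }
    out(f, 0) = cc1 / k;
    out(f, 1) = cc2 / k;
    out(f, 2) = mm1 / k;
    out(f, 3) = mm2 / k;
  }
  return out;
}
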