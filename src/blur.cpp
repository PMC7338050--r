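#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// convolve along one axis with a normalized Gaussian kernel, zero padding
static void conv_axis(std::vector<double> &v, int nz, int ny, int nx,
                      int axis, double sigma) {
  if (sigma <= 0) return;
  int radius = (int)std::ceil(4.0 * sigma);
  std::vector<double> k(2 * radius + 1);
  double s = 0.0;
  for (int i = -radius; i <= radius; ++i) {
    k[i + radius] = std::exp(-0.5 * (double)i * i / (sigma * sigma));
    s += k[i + radius];
  }
  for (double &w : k) w /= s;

  int len = (axis == 0) ? nz : (axis == 1) ? ny : nx;
  // stride of the axis in the (z,y,x) column-major layout
  long stride = (axis == 0) ? 1L : (axis == 1) ? (long)nz : (long)nz * ny;
  long nlines = (long)nz * ny * nx / len;
  std::vector<double> line(len);

  for (long l = 0; l < nlines; ++l) {
    // compute the base offset of line l
    long base;
    if (axis == 0) {
      base = l * nz;
    } else if (axis == 1) {
      long z = l % nz, x = l / nz;
      base = z + (long)nz * ny * x;
    } else {
      base = l;
    }
    for (int i = 0; i < len; ++i) line[i] = v[base + stride * i];
    for (int i = 0; i < len; ++i) {
      double acc = 0.0;
      int lo = std::max(0, i - radius), hi = std::min(len - 1, i + radius);
      for (int j = lo; j <= hi; ++j) acc += line[j] * k[j - i + radius];
      v[base + stride * i] = acc;
    }
  }
}

// separable 3D Gaussian blur with per-axis sigma (in pixels) and zero padding
// [[Rcpp::export(name = ".gaussian_blur3d")]]
NumericVector gaussian_blur3d(NumericVector vol, double sigma_z,
                              double sigma_y, double sigma_x) {
  IntegerVector dims = vol.attr("dim");
  if (dims.size() != 3) stop("vol must be a 3D array");
  int nz = dims[0], ny = dims[1], nx = dims[2];
  if (sigma_z < 0 || sigma_y < 0 || sigma_x < 0) stop("sigma must be >= 0");
  std::vector<double> v(vol.begin(), vol.end());
  conv_axis(v, nz, ny, nx, 0, sigma_z);
  conv_axis(v, nz, ny, nx, 1, sigma_y);
  conv_axis(v, nz, ny, nx, 2, sigma_x);
  NumericVector out(v.begin(), v.end());
  out.attr("dim") = dims;
  return out;
}
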