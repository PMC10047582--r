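#include <Rcpp.h>
using namespace Rcpp;

// Separable 3D correlation with replicate (edge-clamp) padding.
// Kernels are applied along x (fastest-varying), y, z in turn.
static void conv_axis(const std::vector<double> &in, std::vector<double> &out,
                      int nx, int ny, int nz, const NumericVector &k, int axis) {
    const int r = (k.size() - 1) / 2;
    const int n[3] = {nx, ny, nz};
    const int len = n[axis];
    for (int z = 0; z < nz; ++z) {
        for (int y = 0; y < ny; ++y) {
            for (int x = 0; x < nx; ++x) {
                const int idx[3] = {x, y, z};
                double acc = 0.0;
                for (int t = -r; t <= r; ++t) {
                    int p = idx[axis] + t;
                    if (p < 0) p = 0;
                    if (p >= len) p = len - 1;
                    int xx = x, yy = y, zz = z;
                    if (axis == 0) xx = p; else if (axis == 1) yy = p; else zz = p;
                    acc += k[t + r] * in[(size_t)zz * nx * ny + (size_t)yy * nx + xx];
                }
                out[(size_t)z * nx * ny + (size_t)y * nx + x] = acc;
            }
        }
    }
}

// [[Rcpp::export]]
NumericVector cpp_convolve_sep(NumericVector arr, IntegerVector dim,
                               NumericVector kx, NumericVector ky, NumericVector kz) {
    const int nx = dim[0], ny = dim[1], nz = dim[2];
    std::vector<double> a(arr.begin(), arr.end()), b(a.size());
    conv_axis(a, b, nx, ny, nz, kx, 0);
    conv_axis(b, a, nx, ny, nz, ky, 1);
    conv_axis(a, b, nx, ny, nz, kz, 2);
    NumericVector out(b.begin(), b.end());
    out.attr("dim") = dim;
    return out;
}
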