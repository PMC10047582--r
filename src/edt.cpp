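#include <Rcpp.h>
using namespace Rcpp;

// Exact Euclidean distance transform (Felzenszwalb & Huttenlocher lower
// envelope of parabolas), run separably over the three axes with per-axis
// spacing so distances come out in world millimetres.
static void edt_1d(const std::vector<double> &f, std::vector<double> &d,
                   double h, int n, std::vector<int> &v, std::vector<double> &z) {
    const double INF = std::numeric_limits<double>::infinity();
    int k = 0;
    v[0] = 0;
    z[0] = -INF;
    z[1] = INF;
    for (int q = 1; q < n; ++q) {
        double s;
        while (true) {
            double qq = (double)q * h, vv = (double)v[k] * h;
            s = ((f[q] + qq * qq) - (f[v[k]] + vv * vv)) / (2.0 * qq - 2.0 * vv);
            if (s <= z[k]) { --k; } else break;
        }
        ++k;
        v[k] = q;
        z[k] = s;
        z[k + 1] = INF;
    }
    k = 0;
    for (int q = 0; q < n; ++q) {
        double qq = (double)q * h;
        while (z[k + 1] < qq) ++k;
        double vv = (double)v[k] * h;
        d[q] = (qq - vv) * (qq - vv) + f[v[k]];
    }
}

// mask: nonzero voxels are the object; returns distance (mm) to the
// nearest object voxel (0 inside the object).
// [[Rcpp::export]]
NumericVector cpp_edt(IntegerVector mask, IntegerVector dim, NumericVector spacing) {
    const int nx = dim[0], ny = dim[1], nz = dim[2];
    const double INF = 1e30;
    std::vector<double> g((size_t)nx * ny * nz);
    for (size_t i = 0; i < g.size(); ++i) g[i] = mask[i] != 0 ? 0.0 : INF;

    int nmax = std::max(nx, std::max(ny, nz));
    std::vector<double> f(nmax), d(nmax), z(nmax + 1);
    std::vector<int> v(nmax);

    // x axis
    for (int zz = 0; zz < nz; ++zz)
        for (int y = 0; y < ny; ++y) {
            size_t base = (size_t)zz * nx * ny + (size_t)y * nx;
            for (int x = 0; x < nx; ++x) f[x] = g[base + x];
            edt_1d(f, d, spacing[0], nx, v, z);
            for (int x = 0; x < nx; ++x) g[base + x] = d[x];
        }
    // y axis
    for (int zz = 0; zz < nz; ++zz)
        for (int x = 0; x < nx; ++x) {
            size_t base = (size_t)zz * nx * ny + x;
            for (int y = 0; y < ny; ++y) f[y] = g[base + (size_t)y * nx];
            edt_1d(f, d, spacing[1], ny, v, z);
            for (int y = 0; y < ny; ++y) g[base + (size_t)y * nx] = d[y];
        }
    // z axis
    for (int y = 0; y < ny; ++y)
        for (int x = 0; x < nx; ++x) {
            size_t base = (size_t)y * nx + x;
            for (int zz = 0; zz < nz; ++zz) f[zz] = g[base + (size_t)zz * nx * ny];
            edt_1d(f, d, spacing[2], nz, v, z);
            for (int zz = 0; zz < nz; ++zz) g[base + (size_t)zz * nx * ny] = d[zz];
        }

    NumericVector out((size_t)nx * ny * nz);
    for (size_t i = 0; i < g.size(); ++i) out[i] = std::sqrt(g[i]);
    out.attr("dim") = dim;
    return out;
}
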