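#include <Rcpp.h>
using namespace Rcpp;

// 13 unique 3D directions (distance 1) up to sign, shared by GLCM and GLRLM.
static const int DIRS[13][3] = {
    {1, 0, 0}, {0, 1, 0}, {0, 0, 1},
    {1, 1, 0}, {1, -1, 0}, {1, 0, 1}, {1, 0, -1}, {0, 1, 1}, {0, 1, -1},
    {1, 1, 1}, {1, 1, -1}, {1, -1, 1}, {1, -1, -1}
};

static inline size_t lin(int x, int y, int z, int nx, int ny) {
    return (size_t)z * nx * ny + (size_t)y * nx + x;
}

static inline bool inside(int x, int y, int z, int nx, int ny, int nz) {
    return x >= 0 && x < nx && y >= 0 && y < ny && z >= 0 && z < nz;
}

// Symmetric grey-level co-occurrence counts, one L x L slice per direction.
// [[Rcpp::export]]
NumericVector cpp_glcm(IntegerVector levels, IntegerVector dim,
                       IntegerVector valid, int L) {
    const int nx = dim[0], ny = dim[1], nz = dim[2];
    NumericVector out((size_t)L * L * 13);
    for (int d = 0; d < 13; ++d) {
        const int dx = DIRS[d][0], dy = DIRS[d][1], dz = DIRS[d][2];
        for (int z = 0; z < nz; ++z)
            for (int y = 0; y < ny; ++y)
                for (int x = 0; x < nx; ++x) {
                    if (!valid[lin(x, y, z, nx, ny)]) continue;
                    int x2 = x + dx, y2 = y + dy, z2 = z + dz;
                    if (!inside(x2, y2, z2, nx, ny, nz)) continue;
                    if (!valid[lin(x2, y2, z2, nx, ny)]) continue;
                    int i = levels[lin(x, y, z, nx, ny)] - 1;
                    int j = levels[lin(x2, y2, z2, nx, ny)] - 1;
                    out[(size_t)d * L * L + (size_t)j * L + i] += 1.0;
                    out[(size_t)d * L * L + (size_t)i * L + j] += 1.0;
                }
    }
    out.attr("dim") = IntegerVector::create(L, L, 13);
    return out;
}

// Grey-level run-length counts, one L x Jmax slice per direction.  Runs are
// maximal strings of equal level along the direction; invalid voxels break
// runs and are not counted.
// [[Rcpp::export]]
NumericVector cpp_glrlm(IntegerVector levels, IntegerVector dim,
                        IntegerVector valid, int L) {
    const int nx = dim[0], ny = dim[1], nz = dim[2];
    const int J = std::max(nx, std::max(ny, nz));
    NumericVector out((size_t)L * J * 13);
    for (int d = 0; d < 13; ++d) {
        const int dx = DIRS[d][0], dy = DIRS[d][1], dz = DIRS[d][2];
        for (int z = 0; z < nz; ++z)
            for (int y = 0; y < ny; ++y)
                for (int x = 0; x < nx; ++x) {
                    size_t c = lin(x, y, z, nx, ny);
                    if (!valid[c]) continue;
                    int g = levels[c];
                    // run starts here iff predecessor is absent/invalid/different
                    int xp = x - dx, yp = y - dy, zp = z - dz;
                    if (inside(xp, yp, zp, nx, ny, nz)) {
                        size_t p = lin(xp, yp, zp, nx, ny);
                        if (valid[p] && levels[p] == g) continue;
                    }
                    int len = 1;
                    int xn = x + dx, yn = y + dy, zn = z + dz;
                    while (inside(xn, yn, zn, nx, ny, nz)) {
                        size_t q = lin(xn, yn, zn, nx, ny);
                        if (!valid[q] || levels[q] != g) break;
                        ++len;
                        xn += dx; yn += dy; zn += dz;
                    }
                    out[(size_t)d * L * J + (size_t)(len - 1) * L + (g - 1)] += 1.0;
                }
    }
    out.attr("dim") = IntegerVector::create(L, J, 13);
    return out;
}

// Grey-level size-zone counts (26-connected zones of equal level), L x Smax.
// [[Rcpp::export]]
NumericVector cpp_glszm(IntegerVector levels, IntegerVector dim,
                        IntegerVector valid, int L) {
    const int nx = dim[0], ny = dim[1], nz = dim[2];
    const size_t n = (size_t)nx * ny * nz;
    int nvalid = 0;
    for (size_t i = 0; i < n; ++i) if (valid[i]) ++nvalid;
    if (nvalid == 0) nvalid = 1;
    NumericVector out((size_t)L * nvalid);
    std::vector<char> seen(n, 0);
    std::vector<size_t> stack;
    for (size_t s = 0; s < n; ++s) {
        if (!valid[s] || seen[s]) continue;
        int g = levels[s];
        int size = 0;
        stack.clear();
        stack.push_back(s);
        seen[s] = 1;
        while (!stack.empty()) {
            size_t c = stack.back();
            stack.pop_back();
            ++size;
            int x = (int)(c % nx), y = (int)((c / nx) % ny), z = (int)(c / ((size_t)nx * ny));
            for (int dz = -1; dz <= 1; ++dz)
                for (int dy = -1; dy <= 1; ++dy)
                    for (int dx = -1; dx <= 1; ++dx) {
                        if (!dx && !dy && !dz) continue;
                        int x2 = x + dx, y2 = y + dy, z2 = z + dz;
                        if (!inside(x2, y2, z2, nx, ny, nz)) continue;
                        size_t q = lin(x2, y2, z2, nx, ny);
                        if (valid[q] && !seen[q] && levels[q] == g) {
                            seen[q] = 1;
                            stack.push_back(q);
                        }
                    }
        }
        out[(size_t)(size - 1) * L + (g - 1)] += 1.0;
    }
    out.attr("dim") = IntegerVector::create(L, nvalid);
    return out;
}

// Neighbourhood grey-tone difference: per level, count n_i and the summed
// absolute difference s_i between voxel level and the mean of its valid
// 26-neighbours.  Voxels with no valid neighbour are skipped.
// [[Rcpp::export]]
NumericMatrix cpp_ngtdm(IntegerVector levels, IntegerVector dim,
                        IntegerVector valid, int L) {
    const int nx = dim[0], ny = dim[1], nz = dim[2];
    NumericMatrix out(L, 2); // columns: n_i, s_i
    for (int z = 0; z < nz; ++z)
        for (int y = 0; y < ny; ++y)
            for (int x = 0; x < nx; ++x) {
                size_t c = lin(x, y, z, nx, ny);
                if (!valid[c]) continue;
                double sum = 0.0;
                int cnt = 0;
                for (int dz = -1; dz <= 1; ++dz)
                    for (int dy = -1; dy <= 1; ++dy)
                        for (int dx = -1; dx <= 1; ++dx) {
                            if (!dx && !dy && !dz) continue;
                            int x2 = x + dx, y2 = y + dy, z2 = z + dz;
                            if (!inside(x2, y2, z2, nx, ny, nz)) continue;
                            size_t q = lin(x2, y2, z2, nx, ny);
                            if (!valid[q]) continue;
                            sum += levels[q];
                            ++cnt;
                        }
                if (cnt == 0) continue;
                int g = levels[c];
                out(g - 1, 0) += 1.0;
                out(g - 1, 1) += std::fabs((double)g - sum / cnt);
            }
    return out;
}

// Grey-level dependence counts.  Dependence j of a voxel is 1 (the centre)
// plus the number of valid 26-neighbours whose level differs by at most
// alpha, so j ranges over 1..27.
// [[Rcpp::export]]
NumericMatrix cpp_gldm(IntegerVector levels, IntegerVector dim,
                       IntegerVector valid, int L, int alpha) {
    const int nx = dim[0], ny = dim[1], nz = dim[2];
    NumericMatrix out(L, 27);
    for (int z = 0; z < nz; ++z)
        for (int y = 0; y < ny; ++y)
            for (int x = 0; x < nx; ++x) {
                size_t c = lin(x, y, z, nx, ny);
                if (!valid[c]) continue;
                int g = levels[c];
                int dep = 1;
                for (int dz = -1; dz <= 1; ++dz)
                    for (int dy = -1; dy <= 1; ++dy)
                        for (int dx = -1; dx <= 1; ++dx) {
                            if (!dx && !dy && !dz) continue;
                            int x2 = x + dx, y2 = y + dy, z2 = z + dz;
                            if (!inside(x2, y2, z2, nx, ny, nz)) continue;
                            size_t q = lin(x2, y2, z2, nx, ny);
                            if (valid[q] && std::abs(levels[q] - g) <= alpha) ++dep;
                        }
                out(g - 1, dep - 1) += 1.0;
            }
    return out;
}

// ---- first-order voxelwise driver -----------------------------------------

static double percentile_sorted(const std::vector<double> &s, double p) {
    // linear interpolation between order statistics (R quantile type 7)
    const int n = (int)s.size();
    if (n == 1) return s[0];
    double h = (n - 1) * p;
    int lo = (int)std::floor(h);
    if (lo >= n - 1) return s[n - 1];
    return s[lo] + (h - lo) * (s[lo + 1] - s[lo]);
}

// Computes the 19 first-order features of a value vector; entropy and
// uniformity use equal-width discretization into n_bins within the local
// range.  Order must match fo_feature_names() on the R side.
static void first_order_core(std::vector<double> &v, int n_bins, double voxvol,
                             double *out) {
    const int n = (int)v.size();
    double sum = 0.0, sumsq = 0.0, mn = v[0], mx = v[0];
    for (int i = 0; i < n; ++i) {
        sum += v[i];
        sumsq += v[i] * v[i];
        if (v[i] < mn) mn = v[i];
        if (v[i] > mx) mx = v[i];
    }
    const double mean = sum / n;
    double m2 = 0.0, m3 = 0.0, m4 = 0.0, adev = 0.0;
    for (int i = 0; i < n; ++i) {
        double d = v[i] - mean;
        m2 += d * d;
        m3 += d * d * d;
        m4 += d * d * d * d;
        adev += std::fabs(d);
    }
    m2 /= n; m3 /= n; m4 /= n; adev /= n;

    std::sort(v.begin(), v.end());
    const double p10 = percentile_sorted(v, 0.10);
    const double p90 = percentile_sorted(v, 0.90);
    const double p25 = percentile_sorted(v, 0.25);
    const double p75 = percentile_sorted(v, 0.75);
    const double med = percentile_sorted(v, 0.50);

    // robust MAD: mean absolute deviation of values in [p10, p90] from their mean
    double rsum = 0.0;
    int rn = 0;
    for (int i = 0; i < n; ++i)
        if (v[i] >= p10 && v[i] <= p90) { rsum += v[i]; ++rn; }
    double rmad = 0.0;
    if (rn > 0) {
        double rmean = rsum / rn;
        for (int i = 0; i < n; ++i)
            if (v[i] >= p10 && v[i] <= p90) rmad += std::fabs(v[i] - rmean);
        rmad /= rn;
    }

    // discretized histogram for entropy / uniformity
    std::vector<double> p(n_bins, 0.0);
    if (mx > mn) {
        const double w = (mx - mn) / n_bins;
        for (int i = 0; i < n; ++i) {
            int b = (int)std::floor((v[i] - mn) / w);
            if (b >= n_bins) b = n_bins - 1;
            p[b] += 1.0;
        }
    } else {
        p[0] = n;
    }
    double entropy = 0.0, uniformity = 0.0;
    for (int b = 0; b < n_bins; ++b) {
        if (p[b] <= 0) continue;
        double pb = p[b] / n;
        entropy -= pb * std::log2(pb);
        uniformity += pb * pb;
    }

    out[0] = sumsq;                 // energy
    out[1] = sumsq * voxvol;        // total energy
    out[2] = entropy;
    out[3] = mn;                    // minimum
    out[4] = p10;
    out[5] = p90;
    out[6] = mx;                    // maximum
    out[7] = mean;
    out[8] = med;                   // median
    out[9] = p75 - p25;             // interquartile range
    out[10] = mx - mn;              // range
    out[11] = adev;                 // mean absolute deviation
    out[12] = rmad;                 // robust mean absolute deviation
    out[13] = std::sqrt(sumsq / n); // root mean squared
    out[14] = std::sqrt(m2);        // standard deviation (population)
    out[15] = m2 > 0 ? m3 / std::pow(m2, 1.5) : 0.0; // skewness
    out[16] = m2 > 0 ? m4 / (m2 * m2) : 0.0;         // kurtosis
    out[17] = m2;                   // variance (population)
    out[18] = uniformity;
}

// [[Rcpp::export]]
NumericVector cpp_first_order(NumericVector values, int n_bins, double voxvol) {
    std::vector<double> v(values.begin(), values.end());
    NumericVector out(19);
    first_order_core(v, n_bins, voxvol, &out[0]);
    return out;
}

// For every target voxel (0-based linear indices), gather the cubic kernel
// of radius r intersected with the support mask and compute the 19
// first-order features.  qc flags kernels with fewer than 8 support voxels.
// [[Rcpp::export]]
List cpp_voxelwise_firstorder(NumericVector image, IntegerVector support,
                              IntegerVector dim, IntegerVector target,
                              int radius, int n_bins, double voxvol) {
    const int nx = dim[0], ny = dim[1], nz = dim[2];
    const int nt = target.size();
    NumericMatrix out(nt, 19);
    LogicalVector qc(nt);
    std::vector<double> v;
    v.reserve((size_t)(2 * radius + 1) * (2 * radius + 1) * (2 * radius + 1));
    for (int t = 0; t < nt; ++t) {
        size_t c = (size_t)target[t];
        int x = (int)(c % nx), y = (int)((c / nx) % ny), z = (int)(c / ((size_t)nx * ny));
        v.clear();
        for (int dz = -radius; dz <= radius; ++dz)
            for (int dy = -radius; dy <= radius; ++dy)
                for (int dx = -radius; dx <= radius; ++dx) {
                    int x2 = x + dx, y2 = y + dy, z2 = z + dz;
                    if (!inside(x2, y2, z2, nx, ny, nz)) continue;
                    size_t q = lin(x2, y2, z2, nx, ny);
                    if (support[q]) v.push_back(image[q]);
                }
        if (v.empty()) v.push_back(image[c]); // isolated voxel: fall back to centre
        qc[t] = (int)v.size() < 8;
        double buf[19];
        first_order_core(v, n_bins, voxvol, buf);
        for (int k = 0; k < 19; ++k) out(t, k) = buf[k];
    }
    return List::create(_["features"] = out, _["qc"] = qc);
}
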