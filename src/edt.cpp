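#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Exact Euclidean distance transform on a regular anisotropic grid,
// Felzenszwalb & Huttenlocher (2012) separable lower-envelope algorithm.
// Distances are between voxel centers, in the same units as `spacing`.

static const double BIG = 1e20; // stands in for +Inf; avoids Inf-Inf = NaN

// 1D squared-distance transform along a line with sample spacing w.
// f: input squared values; d: output; v, z: scratch (size n, n+1).
static void dt1d(const std::vector<double>& f, std::vector<double>& d,
                 std::vector<int>& v, std::vector<double>& z,
                 int n, double w) {
    double w2 = w * w;
    int k = 0;
    v[0] = 0;
    z[0] = -BIG;
    z[1] = BIG;
    for (int q = 1; q < n; ++q) {
        double s;
        while (true) {
            int p = v[k];
            s = ((f[q] + w2 * q * q) - (f[p] + w2 * p * p)) /
                (2.0 * w2 * (q - p));
            if (s <= z[k]) {
                --k;
            } else {
                break;
            }
        }
        ++k;
        v[k] = q;
        z[k] = s;
        z[k + 1] = BIG;
    }
    k = 0;
    for (int q = 0; q < n; ++q) {
        while (z[k + 1] < q) ++k;
        double dq = w * (q - v[k]);
        d[q] = dq * dq + f[v[k]];
    }
}

// [[Rcpp::export]]
NumericVector edt3d_mm(LogicalVector mask, IntegerVector dims,
                       NumericVector spacing) {
    if (dims.size() != 3 || spacing.size() != 3)
        stop("dims and spacing must have length 3");
    const int nx = dims[0], ny = dims[1], nz = dims[2];
    const R_xlen_t n = (R_xlen_t)nx * ny * nz;
    if (mask.size() != n) stop("mask length does not match dims");

    std::vector<double> D((size_t)n);
    bool any = false;
    for (R_xlen_t i = 0; i < n; ++i) {
        bool m = mask[i] == TRUE;
        D[i] = m ? 0.0 : BIG;
        any = any || m;
    }
    if (!any) {
        NumericVector out(n, R_PosInf);
        return out;
    }

    int nmax = std::max(nx, std::max(ny, nz));
    std::vector<double> f(nmax), d(nmax), z(nmax + 1);
    std::vector<int> v(nmax);

    // pass along x (stride 1)
    for (int k = 0; k < nz; ++k)
        for (int j = 0; j < ny; ++j) {
            R_xlen_t base = (R_xlen_t)nx * (j + (R_xlen_t)ny * k);
            for (int i = 0; i < nx; ++i) f[i] = D[base + i];
            dt1d(f, d, v, z, nx, spacing[0]);
            for (int i = 0; i < nx; ++i) D[base + i] = d[i];
        }
    // pass along y (stride nx)
    for (int k = 0; k < nz; ++k)
        for (int i = 0; i < nx; ++i) {
            R_xlen_t base = i + (R_xlen_t)nx * ny * k;
            for (int j = 0; j < ny; ++j) f[j] = D[base + (R_xlen_t)nx * j];
            dt1d(f, d, v, z, ny, spacing[1]);
            for (int j = 0; j < ny; ++j) D[base + (R_xlen_t)nx * j] = d[j];
        }
    // pass along z (stride nx*ny)
    const R_xlen_t sz = (R_xlen_t)nx * ny;
    for (int j = 0; j < ny; ++j)
        for (int i = 0; i < nx; ++i) {
            R_xlen_t base = i + (R_xlen_t)nx * j;
            for (int k = 0; k < nz; ++k) f[k] = D[base + sz * k];
            dt1d(f, d, v, z, nz, spacing[2]);
            for (int k = 0; k < nz; ++k) D[base + sz * k] = d[k];
        }

    NumericVector out(n);
    for (R_xlen_t i = 0; i < n; ++i)
        out[i] = (D[i] >= BIG) ? R_PosInf : std::sqrt(D[i]);
    return out;
}
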