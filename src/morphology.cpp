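#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Voxel-level primitives shared by the morphometry module.  All arrays use
// R's column-major layout: linear index = i + nx*(j + ny*k), 0-based here.

static inline int idx3(int i, int j, int k, int nx, int ny) {
    return i + nx * (j + ny * k);
}

// Connected-component labelling of a 3D binary mask by iterative flood fill.
// Labels are assigned in scan order of each component's first voxel, so the
// labelling is deterministic for a given mask.  connectivity: 6, 18 or 26.
// [[Rcpp::export(name = ".cc_label_3d")]]
IntegerVector cc_label_3d(LogicalVector mask, IntegerVector dims, int connectivity) {
    const int nx = dims[0], ny = dims[1], nz = dims[2];
    const R_xlen_t n = (R_xlen_t)nx * ny * nz;
    if (mask.size() != n) stop("mask length does not match dims");
    if (connectivity != 6 && connectivity != 18 && connectivity != 26)
        stop("connectivity must be 6, 18 or 26");

    IntegerVector lab(n, 0);
    std::vector<signed char> dx, dy, dz;
    for (int a = -1; a <= 1; ++a)
        for (int b = -1; b <= 1; ++b)
            for (int c = -1; c <= 1; ++c) {
                if (a == 0 && b == 0 && c == 0) continue;
                int man = std::abs(a) + std::abs(b) + std::abs(c);
                if (connectivity == 6 && man != 1) continue;
                if (connectivity == 18 && man > 2) continue;
                dx.push_back((signed char)a);
                dy.push_back((signed char)b);
                dz.push_back((signed char)c);
            }
    const int nn = (int)dx.size();

    int cur = 0;
    std::vector<int> stack;
    for (R_xlen_t s = 0; s < n; ++s) {
        if (!mask[s] || lab[s]) continue;
        ++cur;
        lab[s] = cur;
        stack.clear();
        stack.push_back((int)s);
        while (!stack.empty()) {
            int v = stack.back();
            stack.pop_back();
            int k = v / (nx * ny);
            int r = v - k * nx * ny;
            int j = r / nx;
            int i = r - j * nx;
            for (int t = 0; t < nn; ++t) {
                int ii = i + dx[t], jj = j + dy[t], kk = k + dz[t];
                if (ii < 0 || jj < 0 || kk < 0 || ii >= nx || jj >= ny || kk >= nz)
                    continue;
                int w = idx3(ii, jj, kk, nx, ny);
                if (mask[w] && !lab[w]) {
                    lab[w] = cur;
                    stack.push_back(w);
                }
            }
        }
    }
    return lab;
}

// Separable Gaussian smoothing with zero (background) boundary conditions.
// Used to regularise binary component masks before isosurface extraction;
// callers pad the crop so the zero boundary is exact.
// [[Rcpp::export(name = ".smooth_gaussian_3d")]]
NumericVector smooth_gaussian_3d(NumericVector vol, IntegerVector dims, double sigma) {
    const int nx = dims[0], ny = dims[1], nz = dims[2];
    const R_xlen_t n = (R_xlen_t)nx * ny * nz;
    if (vol.size() != n) stop("volume length does not match dims");
    if (sigma <= 0) return clone(vol);

    const int rad = (int)std::ceil(3.0 * sigma);
    std::vector<double> ker(2 * rad + 1);
    double s = 0.0;
    for (int t = -rad; t <= rad; ++t) {
        ker[t + rad] = std::exp(-0.5 * t * t / (sigma * sigma));
        s += ker[t + rad];
    }
    for (size_t t = 0; t < ker.size(); ++t) ker[t] /= s;

    std::vector<double> a(vol.begin(), vol.end()), b(n, 0.0);

    // x pass
    for (int k = 0; k < nz; ++k)
        for (int j = 0; j < ny; ++j)
            for (int i = 0; i < nx; ++i) {
                double acc = 0.0;
                for (int t = -rad; t <= rad; ++t) {
                    int ii = i + t;
                    if (ii < 0 || ii >= nx) continue;
                    acc += ker[t + rad] * a[idx3(ii, j, k, nx, ny)];
                }
                b[idx3(i, j, k, nx, ny)] = acc;
            }
    // y pass
    for (int k = 0; k < nz; ++k)
        for (int j = 0; j < ny; ++j)
            for (int i = 0; i < nx; ++i) {
                double acc = 0.0;
                for (int t = -rad; t <= rad; ++t) {
                    int jj = j + t;
                    if (jj < 0 || jj >= ny) continue;
                    acc += ker[t + rad] * b[idx3(i, jj, k, nx, ny)];
                }
                a[idx3(i, j, k, nx, ny)] = acc;
            }
    // z pass
    NumericVector out(n);
    for (int k = 0; k < nz; ++k)
        for (int j = 0; j < ny; ++j)
            for (int i = 0; i < nx; ++i) {
                double acc = 0.0;
                for (int t = -rad; t <= rad; ++t) {
                    int kk = k + t;
                    if (kk < 0 || kk >= nz) continue;
                    acc += ker[t + rad] * a[idx3(i, j, kk, nx, ny)];
                }
                out[idx3(i, j, k, nx, ny)] = acc;
            }
    return out;
}

struct P3 { double x, y, z; };

static inline P3 interp_edge(const P3 &pa, double va, const P3 &pb, double vb,
                             double level) {
    double denom = vb - va;
    double t = (std::abs(denom) < 1e-12) ? 0.5 : (level - va) / denom;
    P3 p;
    p.x = pa.x + t * (pb.x - pa.x);
    p.y = pa.y + t * (pb.y - pa.y);
    p.z = pa.z + t * (pb.z - pa.z);
    return p;
}

static inline double tri_area(const P3 &a, const P3 &b, const P3 &c) {
    double ux = b.x - a.x, uy = b.y - a.y, uz = b.z - a.z;
    double vx = c.x - a.x, vy = c.y - a.y, vz = c.z - a.z;
    double cx = uy * vz - uz * vy;
    double cy = uz * vx - ux * vz;
    double cz = ux * vy - uy * vx;
    return 0.5 * std::sqrt(cx * cx + cy * cy + cz * cz);
}

// Isosurface area of `field` at `level` by marching tetrahedra: each grid
// cell is split into the six Kuhn tetrahedra sharing the main diagonal, and
// the level set is triangulated within each tetrahedron by linear
// interpolation along its edges.  Returns total triangle area in voxel
// units squared (caller scales by spacing^2).
// [[Rcpp::export(name = ".isosurface_area_mt")]]
double isosurface_area_mt(NumericVector field, IntegerVector dims, double level) {
    const int nx = dims[0], ny = dims[1], nz = dims[2];
    if (field.size() != (R_xlen_t)nx * ny * nz) stop("field length does not match dims");
    if (nx < 2 || ny < 2 || nz < 2) return 0.0;

    // the six axis permutations defining the Kuhn decomposition
    static const int perms[6][3] = {
        {0, 1, 2}, {0, 2, 1}, {1, 0, 2}, {1, 2, 0}, {2, 0, 1}, {2, 1, 0}
    };

    double total = 0.0;
    P3 tp[4];
    double tv[4];

    for (int k = 0; k < nz - 1; ++k)
        for (int j = 0; j < ny - 1; ++j)
            for (int i = 0; i < nx - 1; ++i) {
                // corner values of the cell, indexed by offset bits (ox, oy, oz)
                double cv[2][2][2];
                bool any_hi = false, any_lo = false;
                for (int oz = 0; oz < 2; ++oz)
                    for (int oy = 0; oy < 2; ++oy)
                        for (int ox = 0; ox < 2; ++ox) {
                            double v = field[idx3(i + ox, j + oy, k + oz, nx, ny)];
                            cv[ox][oy][oz] = v;
                            if (v > level) any_hi = true; else any_lo = true;
                        }
                if (!any_hi || !any_lo) continue;

                for (int p = 0; p < 6; ++p) {
                    int off[4][3] = {{0, 0, 0}, {0, 0, 0}, {0, 0, 0}, {1, 1, 1}};
                    off[1][perms[p][0]] = 1;
                    off[2][perms[p][0]] = 1;
                    off[2][perms[p][1]] = 1;

                    int inside = 0;
                    bool in[4];
                    for (int c = 0; c < 4; ++c) {
                        tp[c].x = i + off[c][0];
                        tp[c].y = j + off[c][1];
                        tp[c].z = k + off[c][2];
                        tv[c] = cv[off[c][0]][off[c][1]][off[c][2]];
                        in[c] = tv[c] > level;
                        if (in[c]) ++inside;
                    }
                    if (inside == 0 || inside == 4) continue;

                    if (inside == 1 || inside == 3) {
                        // one corner on the minority side: single triangle
                        bool minority = (inside == 1);
                        int apex = -1;
                        for (int c = 0; c < 4; ++c)
                            if (in[c] == minority) { apex = c; break; }
                        P3 q[3];
                        int m = 0;
                        for (int c = 0; c < 4; ++c) {
                            if (c == apex) continue;
                            q[m++] = interp_edge(tp[apex], tv[apex], tp[c], tv[c], level);
                        }
                        total += tri_area(q[0], q[1], q[2]);
                    } else {
                        // 2-2 split: quadrilateral across four edges
                        int hi[2], lo[2], nh = 0, nl = 0;
                        for (int c = 0; c < 4; ++c) {
                            if (in[c]) hi[nh++] = c; else lo[nl++] = c;
                        }
                        P3 q00 = interp_edge(tp[hi[0]], tv[hi[0]], tp[lo[0]], tv[lo[0]], level);
                        P3 q01 = interp_edge(tp[hi[0]], tv[hi[0]], tp[lo[1]], tv[lo[1]], level);
                        P3 q10 = interp_edge(tp[hi[1]], tv[hi[1]], tp[lo[0]], tv[lo[0]], level);
                        P3 q11 = interp_edge(tp[hi[1]], tv[hi[1]], tp[lo[1]], tv[lo[1]], level);
                        total += tri_area(q00, q01, q11);
                        total += tri_area(q00, q11, q10);
                    }
                }
            }
    return total;
}

// Count exposed voxel faces of a binary mask (6-neighbourhood).  Fallback
// surface estimator for components too small to mesh.
// [[Rcpp::export(name = ".exposed_faces")]]
double exposed_faces(LogicalVector mask, IntegerVector dims) {
    const int nx = dims[0], ny = dims[1], nz = dims[2];
    if (mask.size() != (R_xlen_t)nx * ny * nz) stop("mask length does not match dims");
    static const int d[6][3] = {
        {1, 0, 0}, {-1, 0, 0}, {0, 1, 0}, {0, -1, 0}, {0, 0, 1}, {0, 0, -1}
    };
    double faces = 0.0;
    for (int k = 0; k < nz; ++k)
        for (int j = 0; j < ny; ++j)
            for (int i = 0; i < nx; ++i) {
                if (!mask[idx3(i, j, k, nx, ny)]) continue;
                for (int t = 0; t < 6; ++t) {
                    int ii = i + d[t][0], jj = j + d[t][1], kk = k + d[t][2];
                    if (ii < 0 || jj < 0 || kk < 0 || ii >= nx || jj >= ny || kk >= nz) {
                        faces += 1.0;
                    } else if (!mask[idx3(ii, jj, kk, nx, ny)]) {
                        faces += 1.0;
                    }
                }
            }
    return faces;
}
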