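#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Disc footprint offsets: pixel included iff centre distance <= radius
// (radius 1 is pinned to the full 3x3 square so the 1-px outline has the
// classic 8-connected shell).
static std::vector<std::pair<int, int> > disc_offsets(int radius) {
    std::vector<std::pair<int, int> > off;
    if (radius == 1) {
        for (int dr = -1; dr <= 1; ++dr)
            for (int dc = -1; dc <= 1; ++dc)
                off.push_back(std::make_pair(dr, dc));
        return off;
    }
    double r2 = (double)radius * radius + 1e-9;
    for (int dr = -radius; dr <= radius; ++dr)
        for (int dc = -radius; dc <= radius; ++dc)
            if ((double)dr * dr + (double)dc * dc <= r2)
                off.push_back(std::make_pair(dr, dc));
    return off;
}

// Per-slice 2D disc min/max rank filter with edge replication.
// Interior pixels take an unclamped fast path over precomputed linear
// offsets; only the border band pays for clamping.
// [[Rcpp::export]]
IntegerVector cpp_rank_disc2d(IntegerVector img, IntegerVector dims,
                              int radius, bool maximum) {
    int nr = dims[0], nc = dims[1], ns = dims[2];
    std::vector<std::pair<int, int> > off = disc_offsets(radius);
    size_t nk = off.size();
    std::vector<R_xlen_t> lin(nk);
    for (size_t k = 0; k < nk; ++k)
        lin[k] = (R_xlen_t)off[k].second * nr + off[k].first;
    IntegerVector out(img.size());
    const int *in = INTEGER(img);
    int *o = INTEGER(out);
    for (int s = 0; s < ns; ++s) {
        R_xlen_t base = (R_xlen_t)s * nr * nc;
        for (int c = 0; c < nc; ++c) {
            bool cEdge = (c < radius) || (c >= nc - radius);
            R_xlen_t col = base + (R_xlen_t)c * nr;
            for (int r = 0; r < nr; ++r) {
                int best;
                if (!cEdge && r >= radius && r < nr - radius) {
                    const int *p = in + col + r;
                    best = p[lin[0]];
                    if (maximum) {
                        for (size_t k = 1; k < nk; ++k) {
                            int v = p[lin[k]];
                            if (v > best) best = v;
                        }
                    } else {
                        for (size_t k = 1; k < nk; ++k) {
                            int v = p[lin[k]];
                            if (v < best) best = v;
                        }
                    }
                } else {
                    best = maximum ? INT_MIN : INT_MAX;
                    for (size_t k = 0; k < nk; ++k) {
                        int rr = r + off[k].first;
                        int cc = c + off[k].second;
                        if (rr < 0) rr = 0; else if (rr >= nr) rr = nr - 1;
                        if (cc < 0) cc = 0; else if (cc >= nc) cc = nc - 1;
                        int v = in[base + (R_xlen_t)cc * nr + rr];
                        if (maximum) { if (v > best) best = v; }
                        else { if (v < best) best = v; }
                    }
                }
                o[col + r] = best;
            }
        }
    }
    return out;
}

// 1D convolution of a 3D array along one axis (0=row, 1=col, 2=slice),
// zero-padded, odd-length centred kernel. Used for separable PSF blur.
// [[Rcpp::export]]
NumericVector cpp_conv1d_axis(NumericVector arr, IntegerVector dims,
                              NumericVector kernel, int axis) {
    int nr = dims[0], nc = dims[1], ns = dims[2];
    int klen = kernel.size();
    int half = klen / 2;
    NumericVector out(arr.size());
    R_xlen_t stride;
    int n_axis;
    if (axis == 0) { stride = 1; n_axis = nr; }
    else if (axis == 1) { stride = nr; n_axis = nc; }
    else { stride = (R_xlen_t)nr * nc; n_axis = ns; }
    const double *in = REAL(arr);
    const double *kw = REAL(kernel);
    double *o = REAL(out);
    for (int s = 0; s < ns; ++s) {
        for (int c = 0; c < nc; ++c) {
            R_xlen_t col = (R_xlen_t)s * nr * nc + (R_xlen_t)c * nr;
            for (int r = 0; r < nr; ++r) {
                int pos = (axis == 0) ? r : (axis == 1 ? c : s);
                R_xlen_t idx = col + r;
                double acc = 0.0;
                int k0 = (pos - half < 0) ? half - pos : 0;
                int k1 = (pos + half >= n_axis) ? n_axis - 1 - pos + half
                                                : klen - 1;
                const double *p = in + idx + (R_xlen_t)(k0 - half) * stride;
                for (int k = k0; k <= k1; ++k, p += stride)
                    acc += kw[k] * (*p);
                o[idx] = acc;
            }
        }
    }
    return out;
}

// 6-connectivity 3D connected-component labelling (iterative DFS).
// [[Rcpp::export]]
IntegerVector cpp_label3d(LogicalVector mask, IntegerVector dims) {
    int nr = dims[0], nc = dims[1], ns = dims[2];
    R_xlen_t n = (R_xlen_t)nr * nc * ns;
    IntegerVector lab(n, 0);
    int next = 0;
    std::vector<R_xlen_t> stack;
    const int dro[6] = { -1, 1, 0, 0, 0, 0 };
    const int dco[6] = { 0, 0, -1, 1, 0, 0 };
    const int dso[6] = { 0, 0, 0, 0, -1, 1 };
    for (R_xlen_t i = 0; i < n; ++i) {
        if (!mask[i] || lab[i] != 0) continue;
        ++next;
        lab[i] = next;
        stack.push_back(i);
        while (!stack.empty()) {
            R_xlen_t cur = stack.back();
            stack.pop_back();
            int r = (int)(cur % nr);
            int c = (int)((cur / nr) % nc);
            int s = (int)(cur / ((R_xlen_t)nr * nc));
            for (int k = 0; k < 6; ++k) {
                int rr = r + dro[k], cc = c + dco[k], ss = s + dso[k];
                if (rr < 0 || rr >= nr || cc < 0 || cc >= nc ||
                    ss < 0 || ss >= ns)
                    continue;
                R_xlen_t j = (R_xlen_t)ss * nr * nc + (R_xlen_t)cc * nr + rr;
                if (mask[j] && lab[j] == 0) {
                    lab[j] = next;
                    stack.push_back(j);
                }
            }
        }
    }
    return lab;
}

// Max-composite spheres into a canvas.  centers: n x 3 matrix of
// physical (y, x, z) in um; pitch: (dy, dx, dz).  Bounds are validated
// by the caller.
// [[Rcpp::export]]
NumericVector cpp_render_spheres(NumericVector canvas, IntegerVector dims,
                                 NumericVector pitch, NumericMatrix centers,
                                 double R, double intensity) {
    int nr = dims[0], nc = dims[1], ns = dims[2];
    double dy = pitch[0], dx = pitch[1], dz = pitch[2];
    double R2 = R * R;
    NumericVector out = clone(canvas);
    for (int i = 0; i < centers.nrow(); ++i) {
        double cy = centers(i, 0), cx = centers(i, 1), cz = centers(i, 2);
        int r0 = std::max(0, (int)std::floor((cy - R) / dy));
        int r1 = std::min(nr - 1, (int)std::ceil((cy + R) / dy));
        int c0 = std::max(0, (int)std::floor((cx - R) / dx));
        int c1 = std::min(nc - 1, (int)std::ceil((cx + R) / dx));
        int s0 = std::max(0, (int)std::floor((cz - R) / dz));
        int s1 = std::min(ns - 1, (int)std::ceil((cz + R) / dz));
        for (int s = s0; s <= s1; ++s) {
            double ddz = s * dz - cz;
            for (int c = c0; c <= c1; ++c) {
                double ddx = c * dx - cx;
                for (int r = r0; r <= r1; ++r) {
                    double ddy = r * dy - cy;
                    if (ddy * ddy + ddx * ddx + ddz * ddz <= R2) {
                        R_xlen_t idx = (R_xlen_t)s * nr * nc +
                                       (R_xlen_t)c * nr + r;
                        if (out[idx] < intensity) out[idx] = intensity;
                    }
                }
            }
        }
    }
    return out;
}
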