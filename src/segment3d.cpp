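#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// 3D connected-component labeling of a binary x,y,t volume.
//
// mask  : logical vector, column-major layout of an (nx, ny, nt) array
// conn  : 6, 18 or 26 — voxel neighborhood (face / face+edge / full cube)
// min_pixels : clusters smaller than this are discarded (label 0)
//
// Labels are assigned in first-encounter order scanning t (outer), then y,
// then x — which is exactly the column-major linear order of the array —
// and compacted to 1..n_waves after the size filter, preserving that order.
// [[Rcpp::export(name = ".label_components_3d")]]
List label_components_3d(LogicalVector mask, IntegerVector dims,
                         int conn, int min_pixels) {
    if (dims.size() != 3)
        stop("dims must have length 3");
    const int nx = dims[0], ny = dims[1], nt = dims[2];
    const R_xlen_t n = (R_xlen_t)nx * ny * nt;
    if (mask.size() != n)
        stop("mask length does not match dims");

    // neighbor offsets allowed under the chosen connectivity
    std::vector<int> dxs, dys, dts;
    for (int dt = -1; dt <= 1; ++dt)
        for (int dy = -1; dy <= 1; ++dy)
            for (int dx = -1; dx <= 1; ++dx) {
                int nz = std::abs(dx) + std::abs(dy) + std::abs(dt);
                if (nz == 0) continue;
                if (conn == 6 && nz > 1) continue;
                if (conn == 18 && nz > 2) continue;
                dxs.push_back(dx); dys.push_back(dy); dts.push_back(dt);
            }

    IntegerVector labels(n, 0);
    std::vector<R_xlen_t> stack;
    std::vector<R_xlen_t> sizes;  // sizes[k-1] = voxel count of provisional label k
    int next = 0;

    for (R_xlen_t i = 0; i < n; ++i) {
        if (!mask[i] || labels[i] != 0) continue;
        ++next;
        R_xlen_t sz = 0;
        labels[i] = next;
        stack.clear();
        stack.push_back(i);
        while (!stack.empty()) {
            R_xlen_t v = stack.back();
            stack.pop_back();
            ++sz;
            int x = (int)(v % nx);
            int y = (int)((v / nx) % ny);
            int t = (int)(v / ((R_xlen_t)nx * ny));
            for (size_t k = 0; k < dxs.size(); ++k) {
                int x2 = x + dxs[k], y2 = y + dys[k], t2 = t + dts[k];
                if (x2 < 0 || x2 >= nx || y2 < 0 || y2 >= ny ||
                    t2 < 0 || t2 >= nt) continue;
                R_xlen_t w = (R_xlen_t)x2 + (R_xlen_t)nx * (y2 + (R_xlen_t)ny * t2);
                if (mask[w] && labels[w] == 0) {
                    labels[w] = next;
                    stack.push_back(w);
                }
            }
        }
        sizes.push_back(sz);
    }

    // size filter + compaction, first-encounter order preserved
    std::vector<int> remap(next + 1, 0);
    int kept = 0;
    for (int k = 1; k <= next; ++k)
        if (sizes[k - 1] >= (R_xlen_t)min_pixels) remap[k] = ++kept;
    for (R_xlen_t i = 0; i < n; ++i)
        if (labels[i] != 0) labels[i] = remap[labels[i]];

    return List::create(_["labels"] = labels, _["n_waves"] = kept);
}

// Rolling (centered, edge-truncated) median and MAD per column.
// x is T x P (time down the rows, one column per pixel); window is forced
// odd by the caller. Interior windows have full width; near the edges the
// window shrinks one-sidedly rather than dropping frames.
// [[Rcpp::export(name = ".roll_median_mad")]]
List roll_median_mad(NumericMatrix x, int window) {
    const int T = x.nrow(), P = x.ncol();
    if (window < 1) stop("window must be >= 1");
    const int h = window / 2;
    NumericMatrix med(T, P), mad(T, P);
    std::vector<double> buf, dev;
    buf.reserve(window);
    dev.reserve(window);
    for (int p = 0; p < P; ++p) {
        const double* col = &x(0, p);
        for (int t = 0; t < T; ++t) {
            int lo = t - h; if (lo < 0) lo = 0;
            int hi = t + h; if (hi > T - 1) hi = T - 1;
            int nw = hi - lo + 1;
            buf.assign(col + lo, col + hi + 1);
            std::nth_element(buf.begin(), buf.begin() + nw / 2, buf.end());
            double m = buf[nw / 2];
            if (nw % 2 == 0) {
                double m2 = *std::max_element(buf.begin(), buf.begin() + nw / 2);
                m = 0.5 * (m + m2);
            }
            dev.resize(nw);
            for (int i = 0; i < nw; ++i) dev[i] = std::fabs(col[lo + i] - m);
            std::nth_element(dev.begin(), dev.begin() + nw / 2, dev.end());
            double d = dev[nw / 2];
            if (nw % 2 == 0) {
                double d2 = *std::max_element(dev.begin(), dev.begin() + nw / 2);
                d = 0.5 * (d + d2);
            }
            med(t, p) = m;
            mad(t, p) = d;
        }
    }
    return List::create(_["median"] = med, _["mad"] = mad);
}
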