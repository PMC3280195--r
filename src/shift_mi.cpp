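#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Keys cubic convolution kernel, a = -1/2 (the standard bicubic kernel).
static inline double keys(double s) {
    s = std::fabs(s);
    if (s <= 1.0) return (1.5 * s - 2.5) * s * s + 1.0;
    if (s < 2.0)  return ((-0.5 * s + 2.5) * s - 4.0) * s + 2.0;
    return 0.0;
}

static inline int clampi(int v, int lo, int hi) {
    return v < lo ? lo : (v > hi ? hi : v);
}

// Per-axis sampling plan for a uniform translation: for every output index
// (1-based) the four tap indices (clamped, 0-based) and weights, plus a
// validity flag (source centre inside [1, n_src]).
struct AxisPlan {
    std::vector<int> tap;      // 4 * n entries, 0-based source indices
    std::vector<double> wt;    // 4 * n weights
    std::vector<bool> valid;
};

static AxisPlan axis_plan(int n_out, int n_src, double shift, double offset) {
    // source coordinate for output i (1-based): s = i + offset - shift
    AxisPlan p;
    p.tap.resize(4 * n_out);
    p.wt.resize(4 * n_out);
    p.valid.resize(n_out);
    for (int i = 1; i <= n_out; ++i) {
        double s = i + offset - shift;
        bool ok = (s >= 1.0 && s <= (double)n_src);
        p.valid[i - 1] = ok;
        int i0 = (int)std::floor(s);
        double f = s - i0;
        double w[4];
        int t[4];
        if (f == 0.0) {
            w[0] = 0.0; w[1] = 1.0; w[2] = 0.0; w[3] = 0.0;
        } else {
            w[0] = keys(1.0 + f);
            w[1] = keys(f);
            w[2] = keys(1.0 - f);
            w[3] = keys(2.0 - f);
        }
        for (int m = 0; m < 4; ++m)
            t[m] = clampi(i0 - 1 + m, 1, n_src) - 1;  // replicate edges
        for (int m = 0; m < 4; ++m) {
            p.tap[4 * (i - 1) + m] = t[m];
            p.wt[4 * (i - 1) + m] = w[m];
        }
    }
    return p;
}

// Shift an image by t = (dx, dy): out[r, c] = in[r - dy, c - dx], bicubic
// interpolation with edge replication for kernel taps; pixels whose source
// centre falls outside the input are set to 0.
// [[Rcpp::export]]
NumericMatrix cpp_shift_bicubic(NumericMatrix img, double dx, double dy) {
    int h = img.nrow(), w = img.ncol();
    NumericMatrix out(h, w);
    AxisPlan py = axis_plan(h, h, dy, 0.0);
    AxisPlan px = axis_plan(w, w, dx, 0.0);
    // separable: first interpolate along rows (y), then columns (x)
    std::vector<double> tmp((size_t)h * w);
    for (int c = 0; c < w; ++c) {
        const double* col = &img(0, c);
        for (int r = 0; r < h; ++r) {
            const int* t = &py.tap[4 * r];
            const double* wv = &py.wt[4 * r];
            tmp[(size_t)c * h + r] = wv[0] * col[t[0]] + wv[1] * col[t[1]] +
                                     wv[2] * col[t[2]] + wv[3] * col[t[3]];
        }
    }
    for (int c = 0; c < w; ++c) {
        const int* t = &px.tap[4 * c];
        const double* wv = &px.wt[4 * c];
        bool cv = px.valid[c];
        for (int r = 0; r < h; ++r) {
            if (!cv || !py.valid[r]) { out(r, c) = 0.0; continue; }
            out(r, c) = wv[0] * tmp[(size_t)t[0] * h + r] +
                        wv[1] * tmp[(size_t)t[1] * h + r] +
                        wv[2] * tmp[(size_t)t[2] * h + r] +
                        wv[3] * tmp[(size_t)t[3] * h + r];
        }
    }
    return out;
}

// Nearest-neighbour variant: exact pixel relocation for integer shifts.
// [[Rcpp::export]]
NumericMatrix cpp_shift_nearest(NumericMatrix img, double dx, double dy) {
    int h = img.nrow(), w = img.ncol();
    NumericMatrix out(h, w);
    for (int c = 1; c <= w; ++c) {
        double xs = c - dx;
        int xi = (int)std::lround(xs);
        bool cv = (xs >= 1.0 && xs <= (double)w) && xi >= 1 && xi <= w;
        for (int r = 1; r <= h; ++r) {
            double ys = r - dy;
            int yi = (int)std::lround(ys);
            if (!cv || ys < 1.0 || ys > (double)h || yi < 1 || yi > h) {
                out(r - 1, c - 1) = 0.0;
            } else {
                out(r - 1, c - 1) = img(yi - 1, xi - 1);
            }
        }
    }
    return out;
}

// Mutual information between `ref` and `tgt` shifted by (dx, dy), evaluated
// on the overlap (pixels of ref whose source centre (r + oy - dy, c + ox - dx)
// lies inside tgt). `ox`, `oy` express a fixed offset of ref within tgt's
// coordinate frame (0 for equal-size images; the search-border half-width for
// block-in-window registration). Intensities are binned linearly over each
// image's range on the overlap, nb bins. Returns c(mi, n_overlap, Ha, Hb, Hab)
// in bits (Shannon) or, if hartley, as log2 of occupied-cell counts.
// [[Rcpp::export]]
NumericVector cpp_mi_shift(NumericMatrix ref, NumericMatrix tgt,
                           double dx, double dy, double ox, double oy,
                           int nb, bool hartley) {
    int h = ref.nrow(), w = ref.ncol();
    int h2 = tgt.nrow(), w2 = tgt.ncol();
    AxisPlan py = axis_plan(h, h2, dy, oy);
    AxisPlan px = axis_plan(w, w2, dx, ox);
    std::vector<double> av, bv;
    av.reserve((size_t)h * w);
    bv.reserve((size_t)h * w);
    double alo = R_PosInf, ahi = R_NegInf, blo = R_PosInf, bhi = R_NegInf;
    for (int c = 0; c < w; ++c) {
        if (!px.valid[c]) continue;
        const int* tx = &px.tap[4 * c];
        const double* wx = &px.wt[4 * c];
        for (int r = 0; r < h; ++r) {
            if (!py.valid[r]) continue;
            const int* ty = &py.tap[4 * r];
            const double* wy = &py.wt[4 * r];
            double s = 0.0;
            for (int m = 0; m < 4; ++m) {
                if (wx[m] == 0.0) continue;
                const double* col = &tgt(0, tx[m]);
                s += wx[m] * (wy[0] * col[ty[0]] + wy[1] * col[ty[1]] +
                              wy[2] * col[ty[2]] + wy[3] * col[ty[3]]);
            }
            double a = ref(r, c);
            av.push_back(a);
            bv.push_back(s);
            if (a < alo) alo = a;
            if (a > ahi) ahi = a;
            if (s < blo) blo = s;
            if (s > bhi) bhi = s;
        }
    }
    size_t n = av.size();
    if (n == 0)
        return NumericVector::create(NA_REAL, 0.0, NA_REAL, NA_REAL, NA_REAL);
    double ascale = (ahi > alo) ? nb / (ahi - alo) : 0.0;
    double bscale = (bhi > blo) ? nb / (bhi - blo) : 0.0;
    std::vector<int> joint((size_t)nb * nb, 0);
    std::vector<int> ma(nb, 0), mb(nb, 0);
    for (size_t i = 0; i < n; ++i) {
        int ia = (int)((av[i] - alo) * ascale);
        int ib = (int)((bv[i] - blo) * bscale);
        if (ia >= nb) ia = nb - 1;
        if (ib >= nb) ib = nb - 1;
        ++joint[(size_t)ia * nb + ib];
        ++ma[ia];
        ++mb[ib];
    }
    double ha = 0.0, hb = 0.0, hab = 0.0;
    if (hartley) {
        int na = 0, nbn = 0, nab = 0;
        for (int i = 0; i < nb; ++i) { if (ma[i]) ++na; if (mb[i]) ++nbn; }
        for (size_t i = 0; i < joint.size(); ++i) if (joint[i]) ++nab;
        ha = std::log2((double)na);
        hb = std::log2((double)nbn);
        hab = std::log2((double)nab);
    } else {
        double invn = 1.0 / (double)n, l2n = std::log2((double)n);
        double sa = 0.0, sb = 0.0, sab = 0.0;
        for (int i = 0; i < nb; ++i) {
            if (ma[i]) sa += ma[i] * std::log2((double)ma[i]);
            if (mb[i]) sb += mb[i] * std::log2((double)mb[i]);
        }
        for (size_t i = 0; i < joint.size(); ++i)
            if (joint[i]) sab += joint[i] * std::log2((double)joint[i]);
        ha = l2n - invn * sa;
        hb = l2n - invn * sb;
        hab = l2n - invn * sab;
    }
    double mi = ha + hb - hab;
    return NumericVector::create(mi, (double)n, ha, hb, hab);
}
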