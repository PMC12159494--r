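#include <Rcpp.h>
#include <algorithm>
#include <cmath>
#include <vector>

using namespace Rcpp;

// Direct-form II transposed IIR filter, in place on a padded buffer.
// zi holds the steady-state state vector for unit input; it is scaled by
// the first sample so that a constant input passes with zero transient.
static void iir_inplace(const std::vector<double>& b, const std::vector<double>& a,
                        const std::vector<double>& zi, std::vector<double>& x) {
    const int n = (int)x.size();
    const int nb = (int)b.size(), na = (int)a.size();
    const int nz = std::max(nb, na) - 1;
    std::vector<double> z(nz, 0.0);
    for (int j = 0; j < nz && j < (int)zi.size(); ++j) z[j] = zi[j] * x[0];
    for (int i = 0; i < n; ++i) {
        double xi = x[i];
        double yi = b[0] * xi + z[0];
        for (int j = 1; j < nz; ++j) {
            double bj = j < nb ? b[j] : 0.0;
            double aj = j < na ? a[j] : 0.0;
            z[j - 1] = bj * xi + z[j] - aj * yi;
        }
        double bl = nz < nb ? b[nz] : 0.0;
        double al = nz < na ? a[nz] : 0.0;
        z[nz - 1] = bl * xi - al * yi;
        x[i] = yi;
    }
}

// Zero-phase (forward-backward) filtering of every column of X (time in rows),
// with odd-reflection padding of length npad at both ends.
// [[Rcpp::export]]
NumericMatrix cpp_filtfilt_mat(NumericVector bv, NumericVector av,
                               NumericMatrix X, int npad, NumericVector ziv) {
    const int T = X.nrow(), P = X.ncol();
    std::vector<double> b(bv.begin(), bv.end()), a(av.begin(), av.end());
    std::vector<double> zi(ziv.begin(), ziv.end());
    if (npad >= T) npad = T - 1;
    NumericMatrix out(T, P);
    std::vector<double> buf(T + 2 * npad);
    for (int p = 0; p < P; ++p) {
        const double* col = &X(0, p);
        for (int i = 0; i < npad; ++i)
            buf[i] = 2.0 * col[0] - col[npad - i];
        for (int i = 0; i < T; ++i) buf[npad + i] = col[i];
        for (int i = 0; i < npad; ++i)
            buf[npad + T + i] = 2.0 * col[T - 1] - col[T - 2 - i];
        iir_inplace(b, a, zi, buf);
        std::reverse(buf.begin(), buf.end());
        iir_inplace(b, a, zi, buf);
        std::reverse(buf.begin(), buf.end());
        for (int i = 0; i < T; ++i) out(i, p) = buf[npad + i];
    }
    return out;
}

// Quantile q of |first differences| per column of X (time in rows).
// q = 0.5 gives the median (MAD-style estimation); lower quantiles stay
// robust when large-signal epochs occupy more than half of the record.
// [[Rcpp::export]]
NumericVector cpp_diff_quantile(NumericMatrix X, double q) {
    const int T = X.nrow(), P = X.ncol();
    NumericVector out(P);
    std::vector<double> d(T - 1);
    const int n = T - 1;
    const double pos = q * (n - 1);
    const int k = (int)std::floor(pos);
    const double gamma = pos - k;
    for (int p = 0; p < P; ++p) {
        const double* col = &X(0, p);
        for (int i = 0; i < n; ++i) d[i] = std::fabs(col[i + 1] - col[i]);
        std::nth_element(d.begin(), d.begin() + k, d.end());
        double lo = d[k], hi = lo;
        if (gamma > 0 && k + 1 < n) {
            hi = *std::min_element(d.begin() + k + 1, d.end());
        }
        out[p] = lo + gamma * (hi - lo);
    }
    return out;
}

// Multiply a movie in place by (1 + amp_i * G_i) for a sequence of Gaussian
// bumps (sd sigma, truncated at 3 sigma), one per listed frame. `arr` must
// be a private copy: it is modified without duplication.
// [[Rcpp::export]]
void cpp_inject_bumps(NumericVector arr, int nr, int nc,
                      NumericVector rows, NumericVector cols,
                      NumericVector amps, IntegerVector frames,
                      double sigma) {
    const double r3 = 3.0 * sigma;
    const double inv2s2 = 1.0 / (2.0 * sigma * sigma);
    for (int i = 0; i < (int)frames.size(); ++i) {
        if (amps[i] <= 0) continue;
        double cr = rows[i], ccol = cols[i];
        int r0 = std::max(0, (int)std::floor(cr - r3) - 1);
        int r1 = std::min(nr - 1, (int)std::ceil(cr + r3) + 1);
        int c0 = std::max(0, (int)std::floor(ccol - r3) - 1);
        int c1 = std::min(nc - 1, (int)std::ceil(ccol + r3) + 1);
        double* fr = arr.begin() + (size_t)(frames[i] - 1) * nr * nc;
        for (int c = c0; c <= c1; ++c) {
            double dc = (c + 1) - ccol;
            for (int r = r0; r <= r1; ++r) {
                double dr = (r + 1) - cr;
                double d2 = dr * dr + dc * dc;
                if (d2 > r3 * r3) continue;
                fr[(size_t)c * nr + r] *= 1.0 + amps[i] * std::exp(-d2 * inv2s2);
            }
        }
    }
}

static inline int mirror_idx(int i, int n) {
    if (i < 0) i = -i;
    if (i >= n) i = 2 * n - 2 - i;
    return i;
}

// Separable spatial convolution of every frame of a (nr x nc x nt) array with a
// symmetric 1-D kernel (mirror edges). arr is modified copy-on-entry semantics.
// [[Rcpp::export]]
NumericVector cpp_smooth_frames(NumericVector arr, int nr, int nc, int nt,
                                NumericVector kernel) {
    const int kr = ((int)kernel.size() - 1) / 2;
    NumericVector out(clone(arr));
    std::vector<double> tmp((size_t)nr * nc);
    const double* k = kernel.begin();
    for (int t = 0; t < nt; ++t) {
        double* fr = out.begin() + (size_t)t * nr * nc;
        // along rows (within a column)
        for (int c = 0; c < nc; ++c) {
            const double* colp = fr + (size_t)c * nr;
            for (int r = 0; r < nr; ++r) {
                double s = 0.0;
                for (int j = -kr; j <= kr; ++j)
                    s += k[j + kr] * colp[mirror_idx(r + j, nr)];
                tmp[(size_t)c * nr + r] = s;
            }
        }
        // along columns (across columns, same row)
        for (int r = 0; r < nr; ++r) {
            for (int c = 0; c < nc; ++c) {
                double s = 0.0;
                for (int j = -kr; j <= kr; ++j)
                    s += k[j + kr] * tmp[(size_t)mirror_idx(c + j, nc) * nr + r];
                fr[(size_t)c * nr + r] = s;
            }
        }
    }
    return out;
}
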