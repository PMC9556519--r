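#include <Rcpp.h>
using namespace Rcpp;

// 3D image-to-column expansion for k x k x k convolution with zero padding
// pad = (k - 1) / 2 ("same" output size, stride 1).
// x: numeric array (D, H, W, C), column-major.
// Returns V x (k^3 * C) with V = D*H*W; rows follow the column-major voxel
// order of (D, H, W); columns are ordered offset-fastest within channel:
// col[v, c*k^3 + o] = x[voxel v shifted by offset o, channel c] (0 outside).
// [[Rcpp::export]]
NumericMatrix im2col3d(NumericVector x, int D, int H, int W, int C, int k) {
    const int V = D * H * W;
    const int K = k * k * k;
    const int pad = (k - 1) / 2;
    NumericMatrix out(V, K * C);
    const double* xp = x.begin();
    for (int c = 0; c < C; ++c) {
        const double* xc = xp + (R_xlen_t)c * V;
        for (int o = 0; o < K; ++o) {
            const int od = o % k - pad;
            const int oh = (o / k) % k - pad;
            const int ow = o / (k * k) - pad;
            double* colp = &out(0, c * K + o);
            for (int w = 0; w < W; ++w) {
                const int sw = w + ow;
                if (sw < 0 || sw >= W) continue;
                for (int h = 0; h < H; ++h) {
                    const int sh = h + oh;
                    if (sh < 0 || sh >= H) continue;
                    const int d0 = (od < 0) ? -od : 0;
                    const int d1 = (od > 0) ? D - od : D;
                    const double* src = xc + ((R_xlen_t)sw * H + sh) * D + od;
                    double* dst = colp + ((R_xlen_t)w * H + h) * D;
                    for (int d = d0; d < d1; ++d) dst[d] = src[d];
                }
            }
        }
    }
    return out;
}

// Adjoint of im2col3d: scatter-add a V x (k^3*C) gradient back onto the
// (D, H, W, C) input grid.
// [[Rcpp::export]]
NumericVector col2im3d(NumericMatrix dcol, int D, int H, int W, int C, int k) {
    const int V = D * H * W;
    const int K = k * k * k;
    const int pad = (k - 1) / 2;
    NumericVector dx((R_xlen_t)V * C);
    double* dxp = dx.begin();
    for (int c = 0; c < C; ++c) {
        double* dxc = dxp + (R_xlen_t)c * V;
        for (int o = 0; o < K; ++o) {
            const int od = o % k - pad;
            const int oh = (o / k) % k - pad;
            const int ow = o / (k * k) - pad;
            const double* colp = &dcol(0, c * K + o);
            for (int w = 0; w < W; ++w) {
                const int sw = w + ow;
                if (sw < 0 || sw >= W) continue;
                for (int h = 0; h < H; ++h) {
                    const int sh = h + oh;
                    if (sh < 0 || sh >= H) continue;
                    const int d0 = (od < 0) ? -od : 0;
                    const int d1 = (od > 0) ? D - od : D;
                    double* dst = dxc + ((R_xlen_t)sw * H + sh) * D + od;
                    const double* src = colp + ((R_xlen_t)w * H + h) * D;
                    for (int d = d0; d < d1; ++d) dst[d] += src[d];
                }
            }
        }
    }
    dx.attr("dim") = IntegerVector::create(D, H, W, C);
    return dx;
}

// 2x2x2 max pooling, stride 2, floor division of extents.
// Returns pooled values and 1-based linear argmax indices into (D,H,W,C).
// [[Rcpp::export]]
List maxpool3d_fwd(NumericVector x, int D, int H, int W, int C) {
    const int D2 = D / 2, H2 = H / 2, W2 = W / 2;
    const R_xlen_t V2 = (R_xlen_t)D2 * H2 * W2;
    NumericVector y(V2 * C);
    IntegerVector idx(V2 * C);
    const double* xp = x.begin();
    R_xlen_t p = 0;
    for (int c = 0; c < C; ++c) {
        const R_xlen_t coff = (R_xlen_t)c * D * H * W;
        for (int w = 0; w < W2; ++w)
            for (int h = 0; h < H2; ++h)
                for (int d = 0; d < D2; ++d) {
                    double best = R_NegInf;
                    R_xlen_t bi = 0;
                    for (int dw = 0; dw < 2; ++dw)
                        for (int dh = 0; dh < 2; ++dh)
                            for (int dd = 0; dd < 2; ++dd) {
                                R_xlen_t i = coff +
                                    ((R_xlen_t)(2 * w + dw) * H + (2 * h + dh)) * D +
                                    (2 * d + dd);
                                if (xp[i] > best) { best = xp[i]; bi = i; }
                            }
                    y[p] = best;
                    idx[p] = (int)(bi + 1);
                    ++p;
                }
    }
    y.attr("dim") = IntegerVector::create(D2, H2, W2, C);
    idx.attr("dim") = IntegerVector::create(D2, H2, W2, C);
    return List::create(_["y"] = y, _["idx"] = idx);
}

// Backward of maxpool3d_fwd: route gradients to the argmax positions.
// [[Rcpp::export]]
NumericVector maxpool3d_bwd(NumericVector dy, IntegerVector idx,
                            int D, int H, int W, int C) {
    NumericVector dx((R_xlen_t)D * H * W * C);
    for (R_xlen_t p = 0; p < dy.size(); ++p) dx[idx[p] - 1] += dy[p];
    dx.attr("dim") = IntegerVector::create(D, H, W, C);
    return dx;
}
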