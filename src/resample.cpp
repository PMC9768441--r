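#include <Rcpp.h>
using namespace Rcpp;

// Rigid-body rotation matrix from (pitch, yaw, roll) about the x, y, z axes,
// composed intrinsically in pitch-yaw-roll order: R = Rx %*% Ry %*% Rz.
static void rotation_matrix(double a, double b, double g, double R[3][3]) {
    const double ca = cos(a), sa = sin(a);
    const double cb = cos(b), sb = sin(b);
    const double cg = cos(g), sg = sin(g);
    // Rx * Ry * Rz
    R[0][0] = cb * cg;
    R[0][1] = -cb * sg;
    R[0][2] = sb;
    R[1][0] = ca * sg + sa * sb * cg;
    R[1][1] = ca * cg - sa * sb * sg;
    R[1][2] = -sa * cb;
    R[2][0] = sa * sg - ca * sb * cg;
    R[2][1] = sa * cg + ca * sb * sg;
    R[2][2] = ca * cb;
}

// Trilinear sample with clamp-to-edge padding; coordinates in 0-based voxels.
static inline double sample_trilinear(const double *v, int nx, int ny, int nz,
                                      double x, double y, double z) {
    if (x < 0) x = 0; else if (x > nx - 1) x = nx - 1;
    if (y < 0) y = 0; else if (y > ny - 1) y = ny - 1;
    if (z < 0) z = 0; else if (z > nz - 1) z = nz - 1;
    int x0 = (int)floor(x), y0 = (int)floor(y), z0 = (int)floor(z);
    int x1 = x0 + 1 < nx ? x0 + 1 : x0;
    int y1 = y0 + 1 < ny ? y0 + 1 : y0;
    int z1 = z0 + 1 < nz ? z0 + 1 : z0;
    double fx = x - x0, fy = y - y0, fz = z - z0;
    const size_t sxy = (size_t)nx * ny;
    #define V(i, j, k) v[(size_t)(i) + (size_t)nx * (j) + sxy * (k)]
    double c00 = V(x0, y0, z0) * (1 - fx) + V(x1, y0, z0) * fx;
    double c10 = V(x0, y1, z0) * (1 - fx) + V(x1, y1, z0) * fx;
    double c01 = V(x0, y0, z1) * (1 - fx) + V(x1, y0, z1) * fx;
    double c11 = V(x0, y1, z1) * (1 - fx) + V(x1, y1, z1) * fx;
    #undef V
    double c0 = c00 * (1 - fy) + c10 * fy;
    double c1 = c01 * (1 - fy) + c11 * fy;
    return c0 * (1 - fz) + c1 * fz;
}

// Resample one 3D volume under a rigid-body transform T(x) = R x + t, with
// x in mm relative to the volume centre.  With inverse = false the output at
// world point x takes the input value at T(x) (used to undo motion during
// realignment); with inverse = true it samples at R^T (x - t), i.e. the
// forward model that moves the head by T.
// [[Rcpp::export]]
NumericVector rigidResampleCpp(NumericVector vol, IntegerVector dim,
                               NumericVector par, NumericVector voxmm,
                               bool inverse) {
    const int nx = dim[0], ny = dim[1], nz = dim[2];
    double R[3][3];
    rotation_matrix(par[3], par[4], par[5], R);
    const double tx = par[0], ty = par[1], tz = par[2];
    const double vx = voxmm[0], vy = voxmm[1], vz = voxmm[2];
    const double cx = (nx - 1) / 2.0, cy = (ny - 1) / 2.0, cz = (nz - 1) / 2.0;

    NumericVector out((size_t)nx * ny * nz);
    const double *v = vol.begin();
    double *o = out.begin();
    size_t idx = 0;
    for (int k = 0; k < nz; ++k) {
        const double wz = (k - cz) * vz;
        for (int j = 0; j < ny; ++j) {
            const double wy = (j - cy) * vy;
            for (int i = 0; i < nx; ++i, ++idx) {
                const double wx = (i - cx) * vx;
                double sx, sy, sz;
                if (inverse) {
                    const double dx = wx - tx, dy = wy - ty, dz = wz - tz;
                    sx = R[0][0] * dx + R[1][0] * dy + R[2][0] * dz;
                    sy = R[0][1] * dx + R[1][1] * dy + R[2][1] * dz;
                    sz = R[0][2] * dx + R[1][2] * dy + R[2][2] * dz;
                } else {
                    sx = R[0][0] * wx + R[0][1] * wy + R[0][2] * wz + tx;
                    sy = R[1][0] * wx + R[1][1] * wy + R[1][2] * wz + ty;
                    sz = R[2][0] * wx + R[2][1] * wy + R[2][2] * wz + tz;
                }
                o[idx] = sample_trilinear(v, nx, ny, nz,
                                          sx / vx + cx, sy / vy + cy, sz / vz + cz);
            }
        }
    }
    return out;
}

// Catmull-Rom cubic kernel
static inline double cubic_w(double s) {
    s = fabs(s);
    if (s < 1) return 1.5 * s * s * s - 2.5 * s * s + 1;
    if (s < 2) return -0.5 * s * s * s + 2.5 * s * s - 4 * s + 2;
    return 0;
}

// Tricubic sample with clamp-to-edge padding; low interpolation bias, used
// by the registration cost (data resampling stays trilinear).
static inline double sample_tricubic(const double *v, int nx, int ny, int nz,
                                     double x, double y, double z) {
    if (x < 0) x = 0; else if (x > nx - 1) x = nx - 1;
    if (y < 0) y = 0; else if (y > ny - 1) y = ny - 1;
    if (z < 0) z = 0; else if (z > nz - 1) z = nz - 1;
    const int x0 = (int)floor(x), y0 = (int)floor(y), z0 = (int)floor(z);
    const double fx = x - x0, fy = y - y0, fz = z - z0;
    const size_t sxy = (size_t)nx * ny;
    double wx[4], wy[4], wz[4];
    int ix[4], iy[4], iz[4];
    for (int m = -1; m <= 2; ++m) {
        wx[m + 1] = cubic_w(fx - m);
        wy[m + 1] = cubic_w(fy - m);
        wz[m + 1] = cubic_w(fz - m);
        int a = x0 + m; ix[m + 1] = a < 0 ? 0 : (a > nx - 1 ? nx - 1 : a);
        a = y0 + m; iy[m + 1] = a < 0 ? 0 : (a > ny - 1 ? ny - 1 : a);
        a = z0 + m; iz[m + 1] = a < 0 ? 0 : (a > nz - 1 ? nz - 1 : a);
    }
    double acc = 0;
    for (int c = 0; c < 4; ++c) {
        if (wz[c] == 0) continue;
        double accy = 0;
        for (int b = 0; b < 4; ++b) {
            if (wy[b] == 0) continue;
            const double *row = v + (size_t)nx * iy[b] + sxy * iz[c];
            double accx = row[ix[0]] * wx[0] + row[ix[1]] * wx[1] +
                          row[ix[2]] * wx[2] + row[ix[3]] * wx[3];
            accy += accx * wy[b];
        }
        acc += accy * wz[c];
    }
    return acc;
}

// Mean squared difference between ref and the rigid resampling of mov,
// evaluated without allocating the resampled volume; the realignment cost.
// [[Rcpp::export]]
double rigidMsdCpp(NumericVector mov, NumericVector ref, IntegerVector dim,
                   NumericVector par, NumericVector voxmm) {
    const int nx = dim[0], ny = dim[1], nz = dim[2];
    double R[3][3];
    rotation_matrix(par[3], par[4], par[5], R);
    const double tx = par[0], ty = par[1], tz = par[2];
    const double vx = voxmm[0], vy = voxmm[1], vz = voxmm[2];
    const double cx = (nx - 1) / 2.0, cy = (ny - 1) / 2.0, cz = (nz - 1) / 2.0;
    const double *v = mov.begin();
    const double *r = ref.begin();
    double acc = 0.0;
    size_t idx = 0;
    for (int k = 0; k < nz; ++k) {
        const double wz = (k - cz) * vz;
        for (int j = 0; j < ny; ++j) {
            const double wy = (j - cy) * vy;
            for (int i = 0; i < nx; ++i, ++idx) {
                const double wx = (i - cx) * vx;
                const double sx = R[0][0] * wx + R[0][1] * wy + R[0][2] * wz + tx;
                const double sy = R[1][0] * wx + R[1][1] * wy + R[1][2] * wz + ty;
                const double sz = R[2][0] * wx + R[2][1] * wy + R[2][2] * wz + tz;
                const double d = sample_tricubic(v, nx, ny, nz,
                                                 sx / vx + cx, sy / vy + cy,
                                                 sz / vz + cz) - r[idx];
                acc += d * d;
            }
        }
    }
    return acc / (double)((size_t)nx * ny * nz);
}
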