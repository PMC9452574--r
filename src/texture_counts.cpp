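// Counting kernels for the 3D texture-matrix families.
// Levels are 1..Ng inside the mask; voxels outside the mask carry 0.
// All neighbourhoods are 26-connected in voxel index space (no distance
// weighting); the 13 unique offsets below are one hemisphere of the 26.

#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

static const int OFF13[13][3] = {
    {1, 0, 0}, {0, 1, 0}, {0, 0, 1},
    {1, 1, 0}, {1, -1, 0},
    {1, 0, 1}, {1, 0, -1},
    {0, 1, 1}, {0, 1, -1},
    {1, 1, 1}, {1, 1, -1}, {1, -1, 1}, {1, -1, -1}
};

static inline int idx3(int x, int y, int z, int nx, int ny) {
    return x + nx * (y + ny * z);
}

static inline bool inside(int x, int y, int z, int nx, int ny, int nz) {
    return x >= 0 && x < nx && y >= 0 && y < ny && z >= 0 && z < nz;
}

// Ordered co-occurrence counts for each of the 13 offsets (one matrix per
// offset, Ng x Ng). Symmetrisation (adding the transpose) is done in R.
// [[Rcpp::export]]
List cpp_glcm_counts(IntegerVector levels, IntegerVector dim, int ng) {
    int nx = dim[0], ny = dim[1], nz = dim[2];
    List out(13);
    for (int d = 0; d < 13; ++d) {
        IntegerMatrix m(ng, ng);
        int dx = OFF13[d][0], dy = OFF13[d][1], dz = OFF13[d][2];
        for (int z = 0; z < nz; ++z)
            for (int y = 0; y < ny; ++y)
                for (int x = 0; x < nx; ++x) {
                    int li = levels[idx3(x, y, z, nx, ny)];
                    if (li == 0) continue;
                    int x2 = x + dx, y2 = y + dy, z2 = z + dz;
                    if (!inside(x2, y2, z2, nx, ny, nz)) continue;
                    int lj = levels[idx3(x2, y2, z2, nx, ny)];
                    if (lj == 0) continue;
                    m(li - 1, lj - 1)++;
                }
        out[d] = m;
    }
    return out;
}

// Run-length counts per direction: Ng x maxRunLength matrices. A run starts
// at a voxel whose predecessor along the direction is outside the mask (or
// grid, or has a different level) and extends while the level repeats.
// [[Rcpp::export]]
List cpp_glrlm_counts(IntegerVector levels, IntegerVector dim, int ng) {
    int nx = dim[0], ny = dim[1], nz = dim[2];
    int maxlen = std::max(nx, std::max(ny, nz));
    List out(13);
    for (int d = 0; d < 13; ++d) {
        IntegerMatrix m(ng, maxlen);
        int dx = OFF13[d][0], dy = OFF13[d][1], dz = OFF13[d][2];
        for (int z = 0; z < nz; ++z)
            for (int y = 0; y < ny; ++y)
                for (int x = 0; x < nx; ++x) {
                    int li = levels[idx3(x, y, z, nx, ny)];
                    if (li == 0) continue;
                    int xp = x - dx, yp = y - dy, zp = z - dz;
                    if (inside(xp, yp, zp, nx, ny, nz) &&
                        levels[idx3(xp, yp, zp, nx, ny)] == li)
                        continue;  // not a run start
                    int len = 1;
                    int x2 = x + dx, y2 = y + dy, z2 = z + dz;
                    while (inside(x2, y2, z2, nx, ny, nz) &&
                           levels[idx3(x2, y2, z2, nx, ny)] == li) {
                        ++len;
                        x2 += dx; y2 += dy; z2 += dz;
                    }
                    m(li - 1, len - 1)++;
                }
        out[d] = m;
    }
    return out;
}

// 26-connected zones of equal level; returns a 2-column matrix
// (level, zone size), one row per zone.
// [[Rcpp::export]]
IntegerMatrix cpp_glszm_zones(IntegerVector levels, IntegerVector dim) {
    int nx = dim[0], ny = dim[1], nz = dim[2];
    int n = nx * ny * nz;
    std::vector<char> seen(n, 0);
    std::vector<int> zl, zs, stack;
    for (int start = 0; start < n; ++start) {
        if (seen[start] || levels[start] == 0) continue;
        int lv = levels[start];
        int size = 0;
        stack.clear();
        stack.push_back(start);
        seen[start] = 1;
        while (!stack.empty()) {
            int cur = stack.back();
            stack.pop_back();
            ++size;
            int cz = cur / (nx * ny);
            int cy = (cur - cz * nx * ny) / nx;
            int cx = cur - nx * (cy + ny * cz);
            for (int dz = -1; dz <= 1; ++dz)
                for (int dy = -1; dy <= 1; ++dy)
                    for (int dx = -1; dx <= 1; ++dx) {
                        if (dx == 0 && dy == 0 && dz == 0) continue;
                        int x2 = cx + dx, y2 = cy + dy, z2 = cz + dz;
                        if (!inside(x2, y2, z2, nx, ny, nz)) continue;
                        int j = idx3(x2, y2, z2, nx, ny);
                        if (!seen[j] && levels[j] == lv) {
                            seen[j] = 1;
                            stack.push_back(j);
                        }
                    }
        }
        zl.push_back(lv);
        zs.push_back(size);
    }
    IntegerMatrix out(zl.size(), 2);
    for (size_t i = 0; i < zl.size(); ++i) {
        out(i, 0) = zl[i];
        out(i, 1) = zs[i];
    }
    return out;
}

// Dependence counts: for each in-mask voxel, the number of in-mask
// 26-neighbours whose level differs by at most alpha. Matrix is
// Ng x 27 (dependence d stored in column d + 1).
// [[Rcpp::export]]
IntegerMatrix cpp_gldm_counts(IntegerVector levels, IntegerVector dim,
                              int ng, int alpha) {
    int nx = dim[0], ny = dim[1], nz = dim[2];
    IntegerMatrix m(ng, 27);
    for (int z = 0; z < nz; ++z)
        for (int y = 0; y < ny; ++y)
            for (int x = 0; x < nx; ++x) {
                int li = levels[idx3(x, y, z, nx, ny)];
                if (li == 0) continue;
                int dep = 0;
                for (int dz = -1; dz <= 1; ++dz)
                    for (int dy = -1; dy <= 1; ++dy)
                        for (int dx = -1; dx <= 1; ++dx) {
                            if (dx == 0 && dy == 0 && dz == 0) continue;
                            int x2 = x + dx, y2 = y + dy, z2 = z + dz;
                            if (!inside(x2, y2, z2, nx, ny, nz)) continue;
                            int lj = levels[idx3(x2, y2, z2, nx, ny)];
                            if (lj == 0) continue;
                            if (std::abs(lj - li) <= alpha) ++dep;
                        }
                m(li - 1, dep)++;
            }
    return m;
}

// NGTDM accumulators: per level i, the voxel count n_i and the summed
// absolute difference s_i between the level and the mean level of its
// in-mask neighbours. Voxels without any in-mask neighbour are skipped.
// [[Rcpp::export]]
List cpp_ngtdm_counts(IntegerVector levels, IntegerVector dim, int ng) {
    int nx = dim[0], ny = dim[1], nz = dim[2];
    NumericVector s(ng);
    IntegerVector nvec(ng);
    for (int z = 0; z < nz; ++z)
        for (int y = 0; y < ny; ++y)
            for (int x = 0; x < nx; ++x) {
                int li = levels[idx3(x, y, z, nx, ny)];
                if (li == 0) continue;
                double sum = 0.0;
                int cnt = 0;
                for (int dz = -1; dz <= 1; ++dz)
                    for (int dy = -1; dy <= 1; ++dy)
                        for (int dx = -1; dx <= 1; ++dx) {
                            if (dx == 0 && dy == 0 && dz == 0) continue;
                            int x2 = x + dx, y2 = y + dy, z2 = z + dz;
                            if (!inside(x2, y2, z2, nx, ny, nz)) continue;
                            int lj = levels[idx3(x2, y2, z2, nx, ny)];
                            if (lj == 0) continue;
                            sum += lj;
                            ++cnt;
                        }
                if (cnt == 0) continue;
                nvec[li - 1]++;
                s[li - 1] += std::fabs(li - sum / cnt);
            }
    return List::create(_["n"] = nvec, _["s"] = s);
}
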