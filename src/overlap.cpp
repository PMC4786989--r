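#include <Rcpp.h>
using namespace Rcpp;

// Shared helpers for rectangle/grid overlap on a regular lat/lon grid.
// Grid: nlat rows (south to north) x nlon cols (west to east), cell edges at
// lon0 + j*cs, lat0 + i*cs. Overlap areas are planar rectangle intersections
// scaled by cos(latitude of the cell center). Cells whose overlap is below
// `min_frac` of the cell's planar area are skipped (numerical noise control).

static const double kDegToRad = M_PI / 180.0;

struct CellIter {
  int j0, j1, i0, i1; // inclusive cell index ranges (0-based), empty if j0>j1
};

static CellIter rect_cells(double xlo, double xhi, double ylo, double yhi,
                           double lon0, double lat0, double cs,
                           int nlon, int nlat) {
  CellIter it;
  it.j0 = std::max(0, (int)std::floor((xlo - lon0) / cs));
  it.j1 = std::min(nlon - 1, (int)std::ceil((xhi - lon0) / cs) - 1);
  it.i0 = std::max(0, (int)std::floor((ylo - lat0) / cs));
  it.i1 = std::min(nlat - 1, (int)std::ceil((yhi - lat0) / cs) - 1);
  return it;
}

// [[Rcpp::export]]
NumericVector cpp_rect_means(NumericMatrix field, NumericMatrix rects,
                             double lon0, double lat0, double cs,
                             double min_frac = 0.01) {
  const int nlat = field.nrow(), nlon = field.ncol(), n = rects.nrow();
  NumericVector out(n, NA_REAL);
  const double cell_area = cs * cs;
  for (int k = 0; k < n; ++k) {
    const double xlo = rects(k, 0), xhi = rects(k, 1);
    const double ylo = rects(k, 2), yhi = rects(k, 3);
    CellIter it = rect_cells(xlo, xhi, ylo, yhi, lon0, lat0, cs, nlon, nlat);
    double sw = 0.0, swv = 0.0;
    for (int i = it.i0; i <= it.i1; ++i) {
      const double cy0 = lat0 + i * cs, cy1 = cy0 + cs;
      const double dy = std::min(yhi, cy1) - std::max(ylo, cy0);
      if (dy <= 0) continue;
      const double coslat = std::cos((cy0 + 0.5 * cs) * kDegToRad);
      for (int j = it.j0; j <= it.j1; ++j) {
        const double cx0 = lon0 + j * cs, cx1 = cx0 + cs;
        const double dx = std::min(xhi, cx1) - std::max(xlo, cx0);
        if (dx <= 0) continue;
        if (dx * dy < min_frac * cell_area) continue;
        const double v = field(i, j);
        if (NumericVector::is_na(v)) continue;
        const double w = dx * dy * coslat;
        sw += w;
        swv += w * v;
      }
    }
    if (sw > 0) out[k] = swv / sw;
  }
  return out;
}

// [[Rcpp::export]]
List cpp_rect_deposit(NumericMatrix rects, NumericVector vals,
                      int nlat, int nlon,
                      double lon0, double lat0, double cs,
                      double min_frac = 0.01) {
  const int n = rects.nrow();
  NumericMatrix sum_wv(nlat, nlon), sum_w(nlat, nlon);
  const double cell_area = cs * cs;
  for (int k = 0; k < n; ++k) {
    const double v = vals[k];
    if (NumericVector::is_na(v)) continue;
    const double xlo = rects(k, 0), xhi = rects(k, 1);
    const double ylo = rects(k, 2), yhi = rects(k, 3);
    CellIter it = rect_cells(xlo, xhi, ylo, yhi, lon0, lat0, cs, nlon, nlat);
    for (int i = it.i0; i <= it.i1; ++i) {
      const double cy0 = lat0 + i * cs, cy1 = cy0 + cs;
      const double dy = std::min(yhi, cy1) - std::max(ylo, cy0);
      if (dy <= 0) continue;
      const double coslat = std::cos((cy0 + 0.5 * cs) * kDegToRad);
      for (int j = it.j0; j <= it.j1; ++j) {
        const double cx0 = lon0 + j * cs, cx1 = cx0 + cs;
        const double dx = std::min(xhi, cx1) - std::max(xlo, cx0);
        if (dx <= 0) continue;
        if (dx * dy < min_frac * cell_area) continue;
        const double w = dx * dy * coslat;
        sum_w(i, j) += w;
        sum_wv(i, j) += w * v;
      }
    }
  }
  return List::create(_["sum_wv"] = sum_wv, _["sum_w"] = sum_w);
}

// Per-cell accounting of which sample days carried a valid observation:
// counts distinct observation days per cell and accumulates a per-day factor
// (e.g. the seasonal shape of the model surface field) once per observed
// cell-day. `day_idx` is 1-based into `day_factor`; rects must be grouped so
// that all rows of one day are contiguous (any order of days).
// [[Rcpp::export]]
List cpp_rect_coverage(NumericMatrix rects, IntegerVector day_idx,
                       NumericVector day_factor,
                       int nlat, int nlon,
                       double lon0, double lat0, double cs,
                       double min_frac = 0.01) {
  const int n = rects.nrow();
  IntegerMatrix ndays(nlat, nlon);
  NumericMatrix fsum(nlat, nlon);
  std::vector<int> stamp((size_t)nlat * nlon, -1);
  const double cell_area = cs * cs;
  for (int k = 0; k < n; ++k) {
    const int d = day_idx[k] - 1;
    const double f = day_factor[d];
    const double xlo = rects(k, 0), xhi = rects(k, 1);
    const double ylo = rects(k, 2), yhi = rects(k, 3);
    CellIter it = rect_cells(xlo, xhi, ylo, yhi, lon0, lat0, cs, nlon, nlat);
    for (int i = it.i0; i <= it.i1; ++i) {
      const double cy0 = lat0 + i * cs, cy1 = cy0 + cs;
      const double dy = std::min(yhi, cy1) - std::max(ylo, cy0);
      if (dy <= 0) continue;
      for (int j = it.j0; j <= it.j1; ++j) {
        const double cx0 = lon0 + j * cs, cx1 = cx0 + cs;
        const double dx = std::min(xhi, cx1) - std::max(xlo, cx0);
        if (dx <= 0) continue;
        if (dx * dy < min_frac * cell_area) continue;
        const size_t cell = (size_t)i + (size_t)j * nlat;
        if (stamp[cell] != d) {
          stamp[cell] = d;
          ndays(i, j) += 1;
          fsum(i, j) += f;
        }
      }
    }
  }
  return List::create(_["ndays"] = ndays, _["factor_sum"] = fsum);
}
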