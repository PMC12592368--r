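#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Overdamped-Langevin multiple-walker well-tempered metadynamics on model
// landscapes. All walkers share one bias, deposited in fixed round-robin
// order; the bias lives on a CV-grid cache (hills truncated at 5 sigma) with
// an exact hill-summation mode for validation. Randomness comes from R's
// RNG, so set.seed() upstream makes runs bit-for-bit reproducible.

struct Potential {
  int kind;                 // 1 dw1d, 2 two_anchor_3d, 3 +hydration
  int ndim, nsp;            // total / spatial dims
  std::vector<std::vector<double>> anchors;
  std::vector<double> depths, widths;
  double rep_radius, RT;
  double hyd_c, h_bulk, k_h;
};

struct Restraint {
  int kind;                 // 1 cylinder, 2 interval, 3 point
  double axis[3], origin[3];
  double R_cyl, K;
  bool has_axial; double ax_lo, ax_hi;
};

struct CV {
  int kind;                 // 1 distance_to_anchor, 2/3 coordinate by index
  double anchor[3];
  int index;                // 0-based
};

struct BiasGrid {
  int d;
  std::vector<double> lo, hi, w;
  std::vector<int> nb;
  std::vector<double> V;    // linear, dim 0 fastest
};

static void pot_force(const Potential& P, const double* x, double* grad,
                      double* energy) {
  const int nsp = P.nsp;
  double U = 0.0;
  for (int k = 0; k < P.ndim; ++k) grad[k] = 0.0;
  double href = P.h_bulk, dhref[3] = {0, 0, 0};
  for (size_t i = 0; i < P.anchors.size(); ++i) {
    double rel[3] = {0, 0, 0}, r2 = 0.0;
    for (int k = 0; k < nsp; ++k) {
      rel[k] = x[k] - P.anchors[i][k];
      r2 += rel[k] * rel[k];
    }
    const double w2 = P.widths[i] * P.widths[i];
    const double g = std::exp(-r2 / (2.0 * w2));
    U -= P.depths[i] * g;
    for (int k = 0; k < nsp; ++k) grad[k] += P.depths[i] * g * rel[k] / w2;
    if (P.rep_radius > 0) {
      const double s6 = std::pow(P.rep_radius * P.rep_radius / r2, 6.0);
      U += P.RT * s6;
      for (int k = 0; k < nsp; ++k) grad[k] += -12.0 * P.RT * s6 / r2 * rel[k];
    }
    if (P.kind == 3) {
      href -= P.hyd_c * g;
      for (int k = 0; k < nsp; ++k) dhref[k] += P.hyd_c * g * rel[k] / w2;
    }
  }
  if (P.kind == 3) {
    const double dh = x[3] - href;
    U += 0.5 * P.k_h * dh * dh;
    grad[3] += P.k_h * dh;
    for (int k = 0; k < nsp; ++k) grad[k] += -P.k_h * dh * dhref[k];
  }
  *energy = U;
}

static void restraint_force(const Restraint& R, const Potential& P,
                            const double* x, double* grad, double* energy) {
  double U = 0.0;
  if (R.kind == 2) {  // 1D interval
    double v = x[0], ex = 0.0;
    if (v < R.ax_lo) ex = v - R.ax_lo;
    else if (v > R.ax_hi) ex = v - R.ax_hi;
    U = 0.5 * R.K * ex * ex;
    grad[0] += R.K * ex;
    *energy = U; return;
  }
  if (R.kind == 3) {  // harmonic point (any spatial dimensionality)
    const int d = P.nsp < 3 ? P.nsp : 3;
    for (int k = 0; k < d; ++k) {
      const double r = x[k] - R.origin[k];
      U += 0.5 * R.K * r * r;
      grad[k] += R.K * r;
    }
    *energy = U; return;
  }
  double rel[3];
  for (int k = 0; k < 3; ++k) rel[k] = x[k] - R.origin[k];
  // cylinder
  double t = 0.0;
  for (int k = 0; k < 3; ++k) t += rel[k] * R.axis[k];
  double perp[3], p2 = 0.0;
  for (int k = 0; k < 3; ++k) {
    perp[k] = rel[k] - t * R.axis[k];
    p2 += perp[k] * perp[k];
  }
  const double pr = std::sqrt(p2);
  if (pr > R.R_cyl && pr > 1e-12) {
    const double ex = pr - R.R_cyl;
    U += 0.5 * R.K * ex * ex;
    for (int k = 0; k < 3; ++k) grad[k] += R.K * ex * perp[k] / pr;
  }
  if (R.has_axial) {
    double ex = 0.0;
    if (t < R.ax_lo) ex = t - R.ax_lo;
    else if (t > R.ax_hi) ex = t - R.ax_hi;
    if (ex != 0.0) {
      U += 0.5 * R.K * ex * ex;
      for (int k = 0; k < 3; ++k) grad[k] += R.K * ex * R.axis[k];
    }
  }
  *energy = U;
}

static void cv_eval(const std::vector<CV>& cvs, const double* x, double* s) {
  for (size_t c = 0; c < cvs.size(); ++c) {
    if (cvs[c].kind == 1) {
      double r2 = 0.0;
      for (int k = 0; k < 3; ++k) {
        const double d = x[k] - cvs[c].anchor[k];
        r2 += d * d;
      }
      s[c] = std::sqrt(r2);
    } else {
      s[c] = x[cvs[c].index];
    }
  }
}

// d s_c / d x_k
static void cv_grad(const CV& cv, const double* x, double sval, double* g,
                    int ndim) {
  for (int k = 0; k < ndim; ++k) g[k] = 0.0;
  if (cv.kind == 1) {
    const double r = std::max(sval, 1e-12);
    for (int k = 0; k < 3; ++k) g[k] = (x[k] - cv.anchor[k]) / r;
  } else {
    g[cv.index] = 1.0;
  }
}

struct Hill { std::vector<double> c, sig; double h; };

static double hills_bias(const std::vector<Hill>& hills, const double* s,
                         int d, double* dVds) {
  double V = 0.0;
  for (int k = 0; k < d; ++k) dVds[k] = 0.0;
  for (size_t i = 0; i < hills.size(); ++i) {
    double e = 0.0;
    bool skip = false;
    for (int k = 0; k < d; ++k) {
      const double z = (s[k] - hills[i].c[k]) / hills[i].sig[k];
      if (std::fabs(z) > 5.0) { skip = true; break; }
      e += 0.5 * z * z;
    }
    if (skip) continue;
    const double g = hills[i].h * std::exp(-e);
    V += g;
    for (int k = 0; k < d; ++k) {
      dVds[k] += -g * (s[k] - hills[i].c[k]) /
        (hills[i].sig[k] * hills[i].sig[k]);
    }
  }
  return V;
}

static void grid_add_hill(BiasGrid& G, const Hill& hill) {
  // bounding box of the 5-sigma support, then nested loop (d <= 3)
  std::vector<int> lo(G.d), hi(G.d);
  for (int k = 0; k < G.d; ++k) {
    int a = (int)std::floor((hill.c[k] - 5.0 * hill.sig[k] - G.lo[k]) / G.w[k]);
    int b = (int)std::ceil((hill.c[k] + 5.0 * hill.sig[k] - G.lo[k]) / G.w[k]);
    lo[k] = std::max(a, 0);
    hi[k] = std::min(b, G.nb[k] - 1);
  }
  std::vector<int> idx(3, 0);
  const int d = G.d;
  int i0lo = lo[0], i0hi = hi[0];
  int i1lo = d > 1 ? lo[1] : 0, i1hi = d > 1 ? hi[1] : 0;
  int i2lo = d > 2 ? lo[2] : 0, i2hi = d > 2 ? hi[2] : 0;
  for (int i2 = i2lo; i2 <= i2hi; ++i2) {
    for (int i1 = i1lo; i1 <= i1hi; ++i1) {
      for (int i0 = i0lo; i0 <= i0hi; ++i0) {
        double e = 0.0;
        idx[0] = i0; idx[1] = i1; idx[2] = i2;
        for (int k = 0; k < d; ++k) {
          const double sk = G.lo[k] + (idx[k] + 0.5) * G.w[k];
          const double z = (sk - hill.c[k]) / hill.sig[k];
          e += 0.5 * z * z;
        }
        size_t lin = i0;
        if (d > 1) lin += (size_t)i1 * G.nb[0];
        if (d > 2) lin += (size_t)i2 * G.nb[0] * G.nb[1];
        G.V[lin] += hill.h * std::exp(-e);
      }
    }
  }
}

static double grid_interp(const BiasGrid& G, const double* s) {
  // multilinear interpolation on cell centers, clamped at the edges
  int d = G.d;
  int base[3] = {0, 0, 0};
  double f[3] = {0, 0, 0};
  for (int k = 0; k < d; ++k) {
    double u = (s[k] - G.lo[k]) / G.w[k] - 0.5;
    if (u < 0) u = 0;
    if (u > G.nb[k] - 1) u = G.nb[k] - 1;
    base[k] = (int)std::floor(u);
    if (base[k] > G.nb[k] - 2) base[k] = std::max(G.nb[k] - 2, 0);
    f[k] = u - base[k];
  }
  double V = 0.0;
  const int corners = 1 << d;
  for (int c = 0; c < corners; ++c) {
    double wgt = 1.0;
    size_t lin = 0, mult = 1;
    for (int k = 0; k < d; ++k) {
      const int off = (c >> k) & 1;
      int ik = base[k] + off;
      if (ik > G.nb[k] - 1) ik = G.nb[k] - 1;
      wgt *= off ? f[k] : (1.0 - f[k]);
      lin += (size_t)ik * mult;
      mult *= G.nb[k];
    }
    V += wgt * G.V[lin];
  }
  return V;
}

static double grid_bias(const BiasGrid& G, const double* s, double* dVds) {
  const double V = grid_interp(G, s);
  double sp[3], sm[3];
  for (int k = 0; k < G.d; ++k) {
    const double h = 0.5 * G.w[k];
    for (int j = 0; j < G.d; ++j) { sp[j] = s[j]; sm[j] = s[j]; }
    sp[k] += h; sm[k] -= h;
    dVds[k] = (grid_interp(G, sp) - grid_interp(G, sm)) / (2.0 * h);
  }
  return V;
}

// [[Rcpp::export(name = ".run_wtmetad_cpp")]]
List run_wtmetad_cpp(List pot_in, List cvs_in, List res_in, List par_in,
                     List grid_in, NumericMatrix x0) {
  Potential P;
  P.kind = as<int>(pot_in["kind"]);
  NumericMatrix A = pot_in["anchors"];
  P.nsp = A.ncol();
  P.ndim = as<int>(pot_in["ndim"]);
  for (int i = 0; i < A.nrow(); ++i) {
    std::vector<double> a(P.nsp);
    for (int k = 0; k < P.nsp; ++k) a[k] = A(i, k);
    P.anchors.push_back(a);
  }
  P.depths = as<std::vector<double>>(pot_in["depths"]);
  P.widths = as<std::vector<double>>(pot_in["widths"]);
  P.rep_radius = as<double>(pot_in["rep_radius"]);
  P.RT = as<double>(pot_in["RT"]);
  P.hyd_c = as<double>(pot_in["hyd_c"]);
  P.h_bulk = as<double>(pot_in["h_bulk"]);
  P.k_h = as<double>(pot_in["k_h"]);

  Restraint R;
  R.kind = as<int>(res_in["kind"]);
  NumericVector ax = res_in["axis"], orig = res_in["origin"];
  for (int k = 0; k < 3; ++k) { R.axis[k] = ax[k]; R.origin[k] = orig[k]; }
  R.R_cyl = as<double>(res_in["R_cyl"]);
  R.K = as<double>(res_in["K"]);
  R.has_axial = as<bool>(res_in["has_axial"]);
  R.ax_lo = as<double>(res_in["ax_lo"]);
  R.ax_hi = as<double>(res_in["ax_hi"]);

  std::vector<CV> cvs;
  for (int c = 0; c < cvs_in.size(); ++c) {
    List ci = cvs_in[c];
    CV cv;
    cv.kind = as<int>(ci["kind"]);
    cv.index = as<int>(ci["index"]) - 1;
    NumericVector an = ci["anchor"];
    for (int k = 0; k < 3; ++k) cv.anchor[k] = an[k];
    cvs.push_back(cv);
  }
  const int ncv = cvs.size();

  const double dt = as<double>(par_in["dt"]);
  const double friction = as<double>(par_in["friction"]);
  const double RT = as<double>(par_in["RT"]);
  const int n_steps = as<int>(par_in["n_steps"]);
  const int dep_stride = as<int>(par_in["deposit_stride"]);
  const int rec_stride = as<int>(par_in["record_stride"]);
  const double h0 = as<double>(par_in["h0"]);
  const double gamma = as<double>(par_in["gamma"]);
  const bool exact_bias = as<bool>(par_in["exact_bias"]);
  NumericVector hw = par_in["hill_widths"];

  BiasGrid G;
  G.d = ncv;
  G.lo = as<std::vector<double>>(grid_in["min"]);
  G.hi = as<std::vector<double>>(grid_in["max"]);
  std::vector<int> nb = as<std::vector<int>>(grid_in["n_bins"]);
  G.nb = nb;
  size_t total = 1;
  for (int k = 0; k < ncv; ++k) {
    G.w.push_back((G.hi[k] - G.lo[k]) / nb[k]);
    total *= (size_t)nb[k];
  }
  G.V.assign(total, 0.0);

  const int W = x0.nrow();
  const int ndim = P.ndim;
  std::vector<std::vector<double>> x(W, std::vector<double>(ndim));
  for (int w = 0; w < W; ++w)
    for (int k = 0; k < ndim; ++k) x[w][k] = x0(w, k);

  std::vector<Hill> hills;
  const int n_rec = n_steps / rec_stride;
  // per-walker records: step, coords, cvs, bias
  std::vector<NumericMatrix> rec;
  for (int w = 0; w < W; ++w)
    rec.push_back(NumericMatrix(n_rec, 1 + ndim + ncv + 1));
  std::vector<NumericVector> hill_rows;

  const double noise = std::sqrt(2.0 * RT * dt / friction);
  const double mob = dt / friction;
  std::vector<double> grad(ndim), cvg(ndim), s(ncv), dVds(ncv);

  for (int step = 1; step <= n_steps; ++step) {
    for (int w = 0; w < W; ++w) {
      double Upot = 0.0, Ures = 0.0;
      pot_force(P, x[w].data(), grad.data(), &Upot);
      restraint_force(R, P, x[w].data(), grad.data(), &Ures);
      cv_eval(cvs, x[w].data(), s.data());
      if (exact_bias) hills_bias(hills, s.data(), ncv, dVds.data());
      else grid_bias(G, s.data(), dVds.data());
      for (int c = 0; c < ncv; ++c) {
        cv_grad(cvs[c], x[w].data(), s[c], cvg.data(), ndim);
        for (int k = 0; k < ndim; ++k) grad[k] += dVds[c] * cvg[k];
      }
      for (int k = 0; k < ndim; ++k) {
        if (!std::isfinite(grad[k])) {
          stop("non-finite force at step %d, walker %d, coordinate %d (x = %g)",
               step, w + 1, k + 1, x[w][k]);
        }
        x[w][k] += -mob * grad[k] + noise * norm_rand();
      }
      if (step % rec_stride == 0) {
        const int r = step / rec_stride - 1;
        cv_eval(cvs, x[w].data(), s.data());
        rec[w](r, 0) = step;
        for (int k = 0; k < ndim; ++k) rec[w](r, 1 + k) = x[w][k];
        for (int c = 0; c < ncv; ++c) rec[w](r, 1 + ndim + c) = s[c];
        rec[w](r, 1 + ndim + ncv) =
          exact_bias ? hills_bias(hills, s.data(), ncv, dVds.data())
                     : grid_bias(G, s.data(), dVds.data());
      }
    }
    if (step % dep_stride == 0 && h0 > 0) {
      for (int w = 0; w < W; ++w) {  // fixed round-robin deposition
        cv_eval(cvs, x[w].data(), s.data());
        const double Vc =
          exact_bias ? hills_bias(hills, s.data(), ncv, dVds.data())
                     : grid_bias(G, s.data(), dVds.data());
        const double h = h0 * std::exp(-Vc / ((gamma - 1.0) * RT));
        Hill hl;
        hl.c.assign(s.begin(), s.end());
        hl.sig.assign(hw.begin(), hw.end());
        hl.h = h;
        hills.push_back(hl);
        if (!exact_bias) grid_add_hill(G, hl);
        NumericVector row(1 + 2 * ncv + 2);
        row[0] = step;
        for (int c = 0; c < ncv; ++c) { row[1 + c] = s[c]; row[1 + ncv + c] = hw[c]; }
        row[1 + 2 * ncv] = h;
        row[2 + 2 * ncv] = gamma;
        hill_rows.push_back(row);
      }
    }
  }

  NumericMatrix hills_mat(hill_rows.size(), 3 + 2 * ncv);
  for (size_t i = 0; i < hill_rows.size(); ++i)
    for (int j = 0; j < hills_mat.ncol(); ++j) hills_mat(i, j) = hill_rows[i][j];

  List recs(W);
  for (int w = 0; w < W; ++w) recs[w] = rec[w];
  return List::create(_["records"] = recs, _["hills"] = hills_mat);
}
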