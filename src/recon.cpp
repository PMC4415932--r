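// Inner loops of the water-fat reconstruction and rigid registration.
// Everything here is deterministic; randomness lives on the R side.
//
// Residual evaluations use the orthonormalized water-fat basis Q (QR of
// [exp(-r t), c_n exp(-r t)]): the squared fit residual of a signal s is
// ||s||^2 - ||Q^H s||^2, which costs two inner products per evaluation.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

static const double TWO_PI = 6.283185307179586476925287;

// Basis [exp(-r t), c_n exp(-r t)] for a given R2* value.
static cx_mat decay_basis(const vec& tes, const cx_vec& cn, double r) {
  vec w = exp(-r * tes);
  cx_mat B(tes.n_elem, 2);
  B.col(0) = cx_vec(w, zeros(tes.n_elem));
  B.col(1) = cn % cx_vec(w, zeros(tes.n_elem));
  return B;
}

// Orthonormal basis of the column space (economic QR; rank-deficient
// columns yield a zero column which simply drops that direction).
static cx_mat orth_basis(const cx_mat& B) {
  cx_mat Q, R;
  qr_econ(Q, R, B);
  // guard rank deficiency: null out directions with tiny diagonal in R
  for (uword c = 0; c < R.n_cols; ++c)
    if (std::abs(R(c, c)) < 1e-12 * std::abs(R(0, 0)) + 1e-300)
      Q.col(c).zeros();
  return Q;
}

// Squared residual of projecting s (already demodulated) onto Q's span.
static inline double resid2_q(const std::complex<double>* s, const cx_mat& Q,
                              double snorm2) {
  const uword ne = Q.n_rows;
  double acc = snorm2;
  for (uword c = 0; c < Q.n_cols; ++c) {
    std::complex<double> d(0.0, 0.0);
    const std::complex<double>* q = Q.colptr(c);
    for (uword n = 0; n < ne; ++n) d += std::conj(q[n]) * s[n];
    acc -= std::norm(d);
  }
  return acc < 0 ? 0 : acc;
}

// Per-voxel/candidate data term of the field-map search. R2* is not
// estimated during the search (decoupled determination); the decay is
// compensated by taking the minimum residual over the nominal R2* values
// in `rset`, or, when `rvox` has one (0-based, into `rset`) entry per
// voxel, by fixing the basis decay per voxel (refinement pass).
struct FieldTerm {
  const cx_mat& S;
  const vec& tes;
  const vec& psis;
  std::vector<cx_mat> Qs;
  uvec rvox;
  vec snorm2, inrm2;
  cx_mat Phase;  // precomputed demodulation phases, candidates x echoes
  FieldTerm(const cx_mat& S_, const vec& tes_, const vec& psis_,
            const cx_vec& cn, const vec& rset, const uvec& rvox_)
      : S(S_), tes(tes_), psis(psis_), rvox(rvox_) {
    for (uword k = 0; k < rset.n_elem; ++k)
      Qs.push_back(orth_basis(decay_basis(tes, cn, rset(k))));
    Phase.set_size(psis.n_elem, tes.n_elem);
    for (uword j = 0; j < psis.n_elem; ++j)
      for (uword n = 0; n < tes.n_elem; ++n)
        Phase(j, n) = std::polar(1.0, -TWO_PI * psis(j) * tes(n));
    snorm2.set_size(S.n_rows);
    inrm2.set_size(S.n_rows);
    for (uword v = 0; v < S.n_rows; ++v) {
      double n2 = 0;
      for (uword n = 0; n < S.n_cols; ++n) n2 += std::norm(S(v, n));
      snorm2(v) = n2;
      inrm2(v) = 1.0 / std::max(n2, 1e-280);
    }
  }
  double operator()(uword v, uword j) const {
    const uword ne = tes.n_elem;
    std::complex<double> sd[16];
    for (uword n = 0; n < ne; ++n) sd[n] = S(v, n) * Phase(j, n);
    double best;
    if (rvox.n_elem == S.n_rows) {
      best = resid2_q(sd, Qs[rvox(v)], snorm2(v));
    } else {
      best = datum::inf;
      for (size_t k = 0; k < Qs.size(); ++k)
        best = std::min(best, resid2_q(sd, Qs[k], snorm2(v)));
    }
    return best * inrm2(v);
  }
};

// Full normalized residual table (voxels x candidates).
// [[Rcpp::export]]
arma::mat cpp_field_residuals(const arma::cx_mat& S, const arma::vec& tes,
                              const arma::vec& psis, const arma::cx_vec& cn,
                              const arma::vec& rset) {
  FieldTerm D(S, tes, psis, cn, rset, uvec());
  mat out(S.n_rows, psis.n_elem);
  for (uword j = 0; j < psis.n_elem; ++j)
    for (uword v = 0; v < S.n_rows; ++v) out(v, j) = D(v, j);
  return out;
}

// Data term at one selected candidate per voxel (0-based indices).
// [[Rcpp::export]]
arma::vec cpp_field_resid_at(const arma::cx_mat& S, const arma::vec& tes,
                             const arma::vec& psis, const arma::cx_vec& cn,
                             const arma::vec& rset, const arma::uvec& jsel) {
  FieldTerm D(S, tes, psis, cn, rset, uvec());
  vec out(S.n_rows);
  for (uword v = 0; v < S.n_rows; ++v) out(v) = D(v, jsel(v));
  return out;
}

// Iterated conditional modes on the field-map labels with a quadratic
// mu-weighted 6-neighbour penalty on (delta psi * delta TE)^2.
// `order` is the deterministic candidate visit order (0-based, smaller
// |psi| first); a candidate replaces the incumbent only on strict
// improvement, so ties resolve toward the earlier candidate in `order`.
// `window` limits the move set to +-window grid steps around the *initial*
// labels (window < 0 explores the full candidate list; with mu = 0 this
// makes the result the exhaustive per-voxel minimizer). Data terms are
// tabulated once per call. `rset`/`rvox` as in FieldTerm.
// [[Rcpp::export]]
arma::uvec cpp_icm_fieldmap(const arma::cx_mat& S, const arma::ivec& dims,
                            const arma::vec& tes, const arma::vec& psis,
                            const arma::cx_vec& cn, double mu,
                            const arma::uvec& init, int window,
                            double delta_te, int max_sweeps,
                            const arma::uvec& order, const arma::vec& rset,
                            const arma::uvec& rvox) {
  FieldTerm D(S, tes, psis, cn, rset, rvox);
  const int nx = dims(0), ny = dims(1), nz = dims(2);
  const uword nv = S.n_rows, np = psis.n_elem;
  uvec idx = init;
  const double dte2 = delta_te * delta_te;

  // tabulate the data term over each voxel's candidate window
  const uword tw = window < 0 ? np : (uword)(2 * window + 1);
  uvec base(nv);
  mat tab(nv, tw);
  for (uword v = 0; v < nv; ++v) {
    long b = window < 0 ? 0 : (long)init(v) - window;
    if (b < 0) b = 0;
    if (b > (long)np - (long)tw) b = (long)np - (long)tw;
    base(v) = (uword)b;
    for (uword c = 0; c < tw; ++c) tab(v, c) = D(v, base(v) + c);
  }

  // rank of each candidate in the tie-break visit order
  uvec rank(np);
  for (uword oi = 0; oi < np; ++oi) rank(order(oi)) = oi;

  for (int sweep = 0; sweep < max_sweeps; ++sweep) {
    uword changed = 0;
    for (uword v = 0; v < nv; ++v) {
      int x = (int)(v % nx), y = (int)((v / nx) % ny),
          z = (int)(v / ((uword)nx * ny));
      int nnb = 0;
      double nbpsi[6];
      if (x > 0)      nbpsi[nnb++] = psis(idx(v - 1));
      if (x < nx - 1) nbpsi[nnb++] = psis(idx(v + 1));
      if (y > 0)      nbpsi[nnb++] = psis(idx(v - nx));
      if (y < ny - 1) nbpsi[nnb++] = psis(idx(v + nx));
      if (z > 0)      nbpsi[nnb++] = psis(idx(v - (uword)nx * ny));
      if (z < nz - 1) nbpsi[nnb++] = psis(idx(v + (uword)nx * ny));
      double bestE = datum::inf;
      uword bestJ = idx(v);
      for (uword c = 0; c < tw; ++c) {
        uword j = base(v) + c;
        double pen = 0.0;
        for (int b = 0; b < nnb; ++b) {
          double dp = psis(j) - nbpsi[b];
          pen += dp * dp * dte2;
        }
        double E = tab(v, c) + mu * pen;
        if (E < bestE || (E == bestE && rank(j) < rank(bestJ))) {
          bestE = E; bestJ = j;
        }
      }
      if (bestJ != idx(v)) { idx(v) = bestJ; ++changed; }
    }
    if (changed == 0) break;
  }
  return idx;
}

// Decoupled single-R2* search per voxel on the psi-demodulated signal.
// Coarse grid (every `stride` candidates) then local refinement around the
// coarse minimum, or exhaustive when stride <= 1. Candidates are visited
// in ascending order with strict improvement, so ties break toward the
// smaller R2*.
// [[Rcpp::export]]
arma::uvec cpp_r2s_search(const arma::cx_mat& Sd, const arma::vec& tes,
                          const arma::cx_vec& cn, const arma::vec& rgrid,
                          int stride) {
  const uword nv = Sd.n_rows, ne = Sd.n_cols, nr = rgrid.n_elem;
  std::vector<cx_mat> Qs(nr);
  for (uword k = 0; k < nr; ++k)
    Qs[k] = orth_basis(decay_basis(tes, cn, rgrid(k)));
  uvec out(nv);
  const bool exhaustive = stride <= 1;
  std::complex<double> s[16];
  for (uword v = 0; v < nv; ++v) {
    double snorm2 = 0;
    for (uword n = 0; n < ne; ++n) {
      s[n] = Sd(v, n);
      snorm2 += std::norm(s[n]);
    }
    uword best = 0;
    double bestE = datum::inf;
    auto probe = [&](uword k) {
      double E = resid2_q(s, Qs[k], snorm2);
      if (E < bestE) { bestE = E; best = k; }
    };
    if (exhaustive) {
      for (uword k = 0; k < nr; ++k) probe(k);
    } else {
      for (uword k = 0; k < nr; k += (uword)stride) probe(k);
      probe(nr - 1);
      uword centre = best;
      uword lo = centre > (uword)stride ? centre - (uword)stride : 0;
      uword hi = std::min(centre + (uword)stride, nr - 1);
      best = lo; bestE = datum::inf;
      for (uword k = lo; k <= hi; ++k) probe(k);
    }
    out(v) = best;
  }
  return out;
}

// Final linear water/fat solve at the selected (psi, R2*) per voxel.
// Returns |W|, |F| and the residual norm.
// [[Rcpp::export]]
arma::mat cpp_wf_solve(const arma::cx_mat& Sd, const arma::vec& tes,
                       const arma::cx_vec& cn, const arma::uvec& ridx,
                       const arma::vec& rgrid) {
  const uword nv = Sd.n_rows, nr = rgrid.n_elem;
  std::vector<cx_mat> pinvs(nr), bases(nr);
  std::vector<bool> have(nr, false);
  mat out(nv, 3);
  for (uword v = 0; v < nv; ++v) {
    uword k = ridx(v);
    if (!have[k]) {
      bases[k] = decay_basis(tes, cn, rgrid(k));
      pinvs[k] = pinv(bases[k]);
      have[k] = true;
    }
    cx_rowvec srow = Sd.row(v);
    cx_vec svec = srow.st();
    cx_vec x = pinvs[k] * svec;
    cx_vec fit = bases[k] * x;
    out(v, 0) = std::abs(x(0));
    out(v, 1) = std::abs(x(1));
    out(v, 2) = norm(svec - fit);
  }
  return out;
}

static mat rot_matrix(double rx, double ry, double rz) {
  const double d2r = datum::pi / 180.0;
  double ax = rx * d2r, ay = ry * d2r, az = rz * d2r;
  mat Rx = {{1, 0, 0}, {0, cos(ax), -sin(ax)}, {0, sin(ax), cos(ax)}};
  mat Ry = {{cos(ay), 0, sin(ay)}, {0, 1, 0}, {-sin(ay), 0, cos(ay)}};
  mat Rz = {{cos(az), -sin(az), 0}, {sin(az), cos(az), 0}, {0, 0, 1}};
  return Rz * Ry * Rx;
}

static inline double trilinear(const vec& vol, int nx, int ny, int nz,
                               double x, double y, double z, bool& ok) {
  if (x < 0 || y < 0 || z < 0 || x > nx - 1 || y > ny - 1 || z > nz - 1) {
    ok = false;
    return 0.0;
  }
  ok = true;
  int x0 = (int)std::floor(x), y0 = (int)std::floor(y), z0 = (int)std::floor(z);
  int x1 = std::min(x0 + 1, nx - 1), y1 = std::min(y0 + 1, ny - 1),
      z1 = std::min(z0 + 1, nz - 1);
  double fx = x - x0, fy = y - y0, fz = z - z0;
  auto at = [&](int i, int j, int k) {
    return vol((uword)i + (uword)nx * ((uword)j + (uword)ny * (uword)k));
  };
  double c00 = at(x0, y0, z0) * (1 - fx) + at(x1, y0, z0) * fx;
  double c10 = at(x0, y1, z0) * (1 - fx) + at(x1, y1, z0) * fx;
  double c01 = at(x0, y0, z1) * (1 - fx) + at(x1, y0, z1) * fx;
  double c11 = at(x0, y1, z1) * (1 - fx) + at(x1, y1, z1) * fx;
  double c0 = c00 * (1 - fy) + c10 * fy;
  double c1 = c01 * (1 - fy) + c11 * fy;
  return c0 * (1 - fz) + c1 * fz;
}

// Normalized cross-correlation between `fixed` and rigidly transformed
// `moving`, over fixed voxels with weight > 0 that map inside the moving
// grid. par = (rx, ry, rz degrees, tx, ty, tz mm); the transform maps
// fixed-grid physical coordinates to moving-grid physical coordinates,
// rotating about the volume centre.
// [[Rcpp::export]]
double cpp_ncc_rigid(const arma::vec& fixed, const arma::vec& moving,
                     const arma::ivec& dims, const arma::vec& spacing,
                     const arma::vec& par, const arma::vec& weight) {
  const int nx = dims(0), ny = dims(1), nz = dims(2);
  mat R = rot_matrix(par(0), par(1), par(2));
  vec t = par.subvec(3, 5);
  vec ctr = {0.5 * (nx - 1) * spacing(0), 0.5 * (ny - 1) * spacing(1),
             0.5 * (nz - 1) * spacing(2)};
  double sf = 0, sm = 0, sff = 0, smm = 0, sfm = 0;
  long n = 0;
  uword v = 0;
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j)
      for (int i = 0; i < nx; ++i, ++v) {
        if (weight(v) <= 0) continue;
        vec p = {i * spacing(0) - ctr(0), j * spacing(1) - ctr(1),
                 k * spacing(2) - ctr(2)};
        vec q = R * p + t + ctr;
        bool ok;
        double m = trilinear(moving, nx, ny, nz, q(0) / spacing(0),
                             q(1) / spacing(1), q(2) / spacing(2), ok);
        if (!ok) continue;
        double f = fixed(v);
        sf += f; sm += m; sff += f * f; smm += m * m; sfm += f * m;
        ++n;
      }
  if (n < 32) return -2.0;
  double vf = sff - sf * sf / n, vm = smm - sm * sm / n;
  if (vf <= 0 || vm <= 0) return -2.0;
  return (sfm - sf * sm / n) / std::sqrt(vf * vm);
}

// Resample `vol` on its own grid through the rigid transform (value taken
// at the mapped location). nearest = true keeps binary masks binary;
// voxels mapping outside the grid become `fill`.
// [[Rcpp::export]]
arma::vec cpp_resample_rigid(const arma::vec& vol, const arma::ivec& dims,
                             const arma::vec& spacing, const arma::vec& par,
                             bool nearest, double fill) {
  const int nx = dims(0), ny = dims(1), nz = dims(2);
  mat R = rot_matrix(par(0), par(1), par(2));
  vec t = par.subvec(3, 5);
  vec ctr = {0.5 * (nx - 1) * spacing(0), 0.5 * (ny - 1) * spacing(1),
             0.5 * (nz - 1) * spacing(2)};
  vec out((uword)nx * ny * nz);
  uword v = 0;
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j)
      for (int i = 0; i < nx; ++i, ++v) {
        vec p = {i * spacing(0) - ctr(0), j * spacing(1) - ctr(1),
                 k * spacing(2) - ctr(2)};
        vec q = R * p + t + ctr;
        double x = q(0) / spacing(0), y = q(1) / spacing(1),
               z = q(2) / spacing(2);
        if (nearest) {
          long xi = std::lround(x), yi = std::lround(y), zi = std::lround(z);
          if (xi < 0 || yi < 0 || zi < 0 || xi >= nx || yi >= ny || zi >= nz) {
            out(v) = fill;
          } else {
            out(v) = vol((uword)xi + (uword)nx * ((uword)yi + (uword)ny * (uword)zi));
          }
        } else {
          bool ok;
          double val = trilinear(vol, nx, ny, nz, x, y, z, ok);
          out(v) = ok ? val : fill;
        }
      }
  return out;
}
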