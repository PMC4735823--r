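// GGH / cellular Potts engine with coupled MMP reaction-diffusion field.
//
// Lattice convention: sigma(i, j) with 0-based (i, j); -1 = fibre, 0 = fluid,
// >= 1 = cell id (contiguous 1..K). The continuous coordinate of pixel (i, j)
// is (i + 0.5, j + 0.5) in pixel units, so a 10x10 block with corner (245,245)
// has centroid (250, 250). Energies in kT; lengths in pixels. Contact energy
// is charged per first-order (4-neighbour) lattice edge between pixels of
// different sigma; same-sigma edges (including fluid-fluid and fibre-fibre,
// which all share one domain id) carry none. Cell perimeter is the count of
// in-lattice 4-neighbour edges to pixels outside the cell.
//
// The motility term is the Kabla-style work potential w(c) = -mu0 phat_c . r_c
// with r_c the cell centroid; polarity is held fixed between the once-per-MCS
// updates, so local deltas and full recomputes agree exactly.

#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

static const int DI[4] = {1, -1, 0, 0};
static const int DJ[4] = {0, 0, 1, -1};

struct EnergyPar {
  double J[3][3];   // class index: 0 = cell, 1 = fibre, 2 = fluid
  double lambda_a, lambda_p, a0, p0, T_m, mu0;
};

static inline int cls_of(int s) { return s >= 1 ? 0 : (s == 0 ? 2 : 1); }

static EnergyPar read_epar(const List& epar) {
  EnergyPar p;
  double jcc = as<double>(epar["J_cc"]), jce = as<double>(epar["J_ce"]),
          jcf = as<double>(epar["J_cf"]), jee = as<double>(epar["J_ee"]),
          jef = as<double>(epar["J_ef"]), jff = as<double>(epar["J_ff"]);
  p.J[0][0] = jcc; p.J[0][1] = jce; p.J[0][2] = jcf;
  p.J[1][0] = jce; p.J[1][1] = jee; p.J[1][2] = jef;
  p.J[2][0] = jcf; p.J[2][1] = jef; p.J[2][2] = jff;
  p.lambda_a = as<double>(epar["lambda_a"]);
  p.lambda_p = as<double>(epar["lambda_p"]);
  p.a0 = as<double>(epar["a0"]);
  p.p0 = as<double>(epar["p0"]);
  p.T_m = as<double>(epar["T_m"]);
  p.mu0 = as<double>(epar["mu0"]);
  return p;
}

static inline double pair_energy(const EnergyPar& p, int sa, int sb) {
  if (sa == sb) return 0.0;
  return p.J[cls_of(sa)][cls_of(sb)];
}

struct CellState {
  std::vector<double> area, perim, sumx, sumy;
  int K;
  void init(const IntegerMatrix& sigma, int K_) {
    K = K_;
    area.assign(K + 1, 0.0); perim.assign(K + 1, 0.0);
    sumx.assign(K + 1, 0.0); sumy.assign(K + 1, 0.0);
    int nx = sigma.nrow(), ny = sigma.ncol();
    for (int j = 0; j < ny; ++j) for (int i = 0; i < nx; ++i) {
      int s = sigma(i, j);
      if (s >= 1) {
        if (s > K) stop("cell id exceeds declared cell count");
        area[s] += 1.0; sumx[s] += i + 0.5; sumy[s] += j + 0.5;
        for (int d = 0; d < 4; ++d) {
          int ii = i + DI[d], jj = j + DJ[d];
          if (ii < 0 || jj < 0 || ii >= nx || jj >= ny) continue;
          if (sigma(ii, jj) != s) perim[s] += 1.0;
        }
      }
    }
  }
};

// Local energy change for copying sigma(src) onto the target pixel.
// Returns NA_REAL for a skip (same id). Caller guarantees neither is fibre.
static double delta_energy_local(const int* S, int nx, int ny,
                                 const EnergyPar& p, const CellState& cs,
                                 const double* P, int Kp,
                                 int ti, int tj, int s_s) {
  int s_t = S[ti + (size_t)tj * nx];
  if (s_s == s_t) return NA_REAL;

  double dE = 0.0;
  int n_in_s = 0, n_in_t = 0, n_nb = 0;
  for (int d = 0; d < 4; ++d) {
    int ii = ti + DI[d], jj = tj + DJ[d];
    if (ii < 0 || jj < 0 || ii >= nx || jj >= ny) continue;
    ++n_nb;
    int nb = S[ii + (size_t)jj * nx];
    dE += pair_energy(p, s_s, nb) - pair_energy(p, s_t, nb);
    if (nb == s_s) ++n_in_s;
    if (nb == s_t) ++n_in_t;
  }

  double qx = ti + 0.5, qy = tj + 0.5;
  if (s_s >= 1) {
    double a = cs.area[s_s];
    dE += p.lambda_a * (std::pow(a + 1 - p.a0, 2) - std::pow(a - p.a0, 2));
    double dp = (n_nb - n_in_s) - n_in_s;   // boundary edges gained minus internalized
    double pe = cs.perim[s_s];
    dE += p.lambda_p * (std::pow(pe + dp - p.p0, 2) - std::pow(pe - p.p0, 2));
    // centroid shift (qx,qy joins): dr = (q - c) / (a + 1)
    double cx = cs.sumx[s_s] / a, cy = cs.sumy[s_s] / a;
    double drx = (qx - cx) / (a + 1.0), dry = (qy - cy) / (a + 1.0);
    dE -= p.mu0 * (P[s_s - 1] * drx + P[s_s - 1 + Kp] * dry);
  }
  if (s_t >= 1) {
    double a = cs.area[s_t];
    dE += p.lambda_a * (std::pow(a - 1 - p.a0, 2) - std::pow(a - p.a0, 2));
    double dp = n_in_t - (n_nb - n_in_t);   // edges exposed minus edges removed
    double pe = cs.perim[s_t];
    dE += p.lambda_p * (std::pow(pe + dp - p.p0, 2) - std::pow(pe - p.p0, 2));
    if (a > 1.0) {
      double cx = cs.sumx[s_t] / a, cy = cs.sumy[s_t] / a;
      double drx = ((cs.sumx[s_t] - qx) / (a - 1.0)) - cx;
      double dry = ((cs.sumy[s_t] - qy) / (a - 1.0)) - cy;
      dE -= p.mu0 * (P[s_t - 1] * drx + P[s_t - 1 + Kp] * dry);
    } else {
      // cell vanishes; its motility potential -mu0 phat.c disappears
      double cx = cs.sumx[s_t] / a, cy = cs.sumy[s_t] / a;
      dE += p.mu0 * (P[s_t - 1] * cx + P[s_t - 1 + Kp] * cy);
    }
  }
  return dE;
}

static void apply_copy(int* S, int nx, int ny, CellState& cs,
                       int ti, int tj, int s_s) {
  int s_t = S[ti + (size_t)tj * nx];
  int n_in_s = 0, n_in_t = 0, n_nb = 0;
  for (int d = 0; d < 4; ++d) {
    int ii = ti + DI[d], jj = tj + DJ[d];
    if (ii < 0 || jj < 0 || ii >= nx || jj >= ny) continue;
    ++n_nb;
    int nb = S[ii + (size_t)jj * nx];
    if (nb == s_s) ++n_in_s;
    if (nb == s_t) ++n_in_t;
  }
  double qx = ti + 0.5, qy = tj + 0.5;
  if (s_s >= 1) {
    cs.area[s_s] += 1.0; cs.sumx[s_s] += qx; cs.sumy[s_s] += qy;
    cs.perim[s_s] += (n_nb - n_in_s) - n_in_s;
  }
  if (s_t >= 1) {
    cs.area[s_t] -= 1.0; cs.sumx[s_t] -= qx; cs.sumy[s_t] -= qy;
    cs.perim[s_t] += n_in_t - (n_nb - n_in_t);
  }
  S[ti + (size_t)tj * nx] = s_s;
}

// [[Rcpp::export]]
double cpp_total_energy(IntegerMatrix sigma, List epar, NumericMatrix polarity) {
  EnergyPar p = read_epar(epar);
  int nx = sigma.nrow(), ny = sigma.ncol();
  int K = polarity.nrow();
  CellState cs; cs.init(sigma, K);
  double E = 0.0;
  for (int j = 0; j < ny; ++j) for (int i = 0; i < nx; ++i) {
    int s = sigma(i, j);
    if (i + 1 < nx) E += pair_energy(p, s, sigma(i + 1, j));
    if (j + 1 < ny) E += pair_energy(p, s, sigma(i, j + 1));
  }
  for (int k = 1; k <= K; ++k) {
    // zero-area (vanished) cells still carry their constraint penalties so
    // that E is a state function consistent with the local delta across a
    // death move; the motility potential needs a centroid and drops out
    E += p.lambda_a * std::pow(cs.area[k] - p.a0, 2);
    E += p.lambda_p * std::pow(cs.perim[k] - p.p0, 2);
    if (cs.area[k] > 0.0) {
      double cx = cs.sumx[k] / cs.area[k], cy = cs.sumy[k] / cs.area[k];
      E -= p.mu0 * (polarity(k - 1, 0) * cx + polarity(k - 1, 1) * cy);
    }
  }
  return E;
}

// [[Rcpp::export]]
double cpp_delta_energy(IntegerMatrix sigma, List epar, NumericMatrix polarity,
                        IntegerVector src, IntegerVector tgt) {
  // src, tgt: 1-based (i, j) pairs as used from R
  int si = src[0] - 1, sj = src[1] - 1, ti = tgt[0] - 1, tj = tgt[1] - 1;
  int nx = sigma.nrow(), ny = sigma.ncol();
  if (si < 0 || sj < 0 || ti < 0 || tj < 0 ||
      si >= nx || sj >= ny || ti >= nx || tj >= ny)
    stop("pixel index out of lattice");
  if (std::abs(si - ti) + std::abs(sj - tj) != 1)
    stop("source and target must be 4-neighbours");
  if (sigma(si, sj) == -1 || sigma(ti, tj) == -1)
    stop("copy attempts must not involve fibre pixels");
  int K = polarity.nrow();
  CellState cs; cs.init(sigma, K);
  EnergyPar p = read_epar(epar);
  const int* S = INTEGER(sigma.get__());
  return delta_energy_local(S, nx, ny, p, cs, REAL(polarity.get__()), K,
                            ti, tj, sigma(si, sj));
}

// ---------------------------------------------------------------------------
// MMP field helpers

static void secrete_inplace(NumericMatrix& field, const IntegerMatrix& sigma,
                            const std::vector<int>& contact, double add) {
  for (size_t z = 0; z < contact.size(); ++z) field[contact[z]] += add;
}

// fibre pixels with >= 1 cell pixel among their 8 neighbours
static std::vector<int> contact_pixels(const IntegerMatrix& sigma,
                                       const std::vector<int>& fibre_idx) {
  int nx = sigma.nrow(), ny = sigma.ncol();
  std::vector<int> out;
  for (size_t z = 0; z < fibre_idx.size(); ++z) {
    int idx = fibre_idx[z];
    int i = idx % nx, j = idx / nx;
    bool touch = false;
    for (int dj = -1; dj <= 1 && !touch; ++dj)
      for (int di = -1; di <= 1 && !touch; ++di) {
        if (di == 0 && dj == 0) continue;
        int ii = i + di, jj = j + dj;
        if (ii < 0 || jj < 0 || ii >= nx || jj >= ny) continue;
        if (sigma(ii, jj) >= 1) touch = true;
      }
    if (touch) out.push_back(idx);
  }
  return out;
}

static void diffuse_decay_inplace(NumericMatrix& field, NumericMatrix& buf,
                                  double r, double decay_dt) {
  int nx = field.nrow(), ny = field.ncol();
  const double* F = REAL(field.get__());
  double* B = REAL(buf.get__());
  const double keep = 1.0 - 4.0 * r - decay_dt;
  for (int j = 0; j < ny; ++j) {
    const double* c = F + (size_t)j * nx;
    const double* l = F + (size_t)(j > 0 ? j - 1 : 0) * nx;
    const double* rt = F + (size_t)(j < ny - 1 ? j + 1 : ny - 1) * nx;
    double* o = B + (size_t)j * nx;
    // zero-flux rows i = 0 and i = nx-1 reflect onto themselves
    o[0] = keep * c[0] + r * (c[0] + c[1] + l[0] + rt[0]);
    for (int i = 1; i < nx - 1; ++i) {
      o[i] = keep * c[i] + r * (c[i - 1] + c[i + 1] + l[i] + rt[i]);
    }
    o[nx - 1] = keep * c[nx - 1] +
      r * (c[nx - 2] + c[nx - 1] + l[nx - 1] + rt[nx - 1]);
  }
  double vmax = 0.0;
  for (int idx = 0; idx < nx * ny; ++idx) {
    if (B[idx] < 0.0) B[idx] = 0.0;
    if (B[idx] > vmax) vmax = B[idx];
  }
  if (vmax > 1e6) stop("MMP solver instability: max field value %f", vmax);
  std::swap(field, buf);
}

// [[Rcpp::export]]
NumericMatrix cpp_secrete(NumericMatrix field, IntegerMatrix sigma,
                          double lambda, double dt) {
  NumericMatrix out = clone(field);
  int nx = sigma.nrow(), ny = sigma.ncol();
  std::vector<int> fib;
  for (int idx = 0; idx < nx * ny; ++idx) if (sigma[idx] == -1) fib.push_back(idx);
  std::vector<int> contact = contact_pixels(sigma, fib);
  secrete_inplace(out, sigma, contact, lambda * dt);
  return out;
}

// [[Rcpp::export]]
NumericMatrix cpp_diffuse_decay(NumericMatrix field, double r, double decay_dt,
                                int n_steps) {
  NumericMatrix out = clone(field);
  NumericMatrix buf(field.nrow(), field.ncol());
  for (int s = 0; s < n_steps; ++s) diffuse_decay_inplace(out, buf, r, decay_dt);
  return out;
}

// [[Rcpp::export]]
List cpp_degrade_ecm(IntegerMatrix sigma, NumericMatrix field) {
  IntegerMatrix sg = clone(sigma);
  NumericMatrix fd = clone(field);
  int nx = sg.nrow(), ny = sg.ncol();
  std::vector<int> ev_i, ev_j;
  for (int j = 0; j < ny; ++j) for (int i = 0; i < nx; ++i) {
    if (sg(i, j) == -1 && fd(i, j) >= 1.0) {
      sg(i, j) = 0;
      fd(i, j) -= 1.0;
      ev_i.push_back(i + 1); ev_j.push_back(j + 1);
    }
  }
  IntegerMatrix events(ev_i.size(), 2);
  for (size_t z = 0; z < ev_i.size(); ++z) {
    events(z, 0) = ev_i[z]; events(z, 1) = ev_j[z];
  }
  colnames(events) = CharacterVector::create("i", "j");
  return List::create(_["sigma"] = sg, _["field"] = fd, _["events"] = events);
}

// ---------------------------------------------------------------------------
// Full simulation driver

// [[Rcpp::export]]
List cpp_run_simulation(IntegerMatrix sigma_in, NumericMatrix field_in,
                        NumericMatrix hist_in, IntegerVector hist_len_in,
                        IntegerVector hist_head_in, NumericMatrix pol_in,
                        LogicalVector alive_in, List epar,
                        double r_diff, double decay_dt, double lambda_dt,
                        int substeps, bool proteolysis,
                        int n_mcs, int record_every, int mcs0) {
  IntegerMatrix sigma = clone(sigma_in);
  NumericMatrix field = clone(field_in);
  NumericMatrix hist = clone(hist_in);
  IntegerVector hist_len = clone(hist_len_in);
  IntegerVector hist_head = clone(hist_head_in);
  NumericMatrix pol = clone(pol_in);
  LogicalVector alive = clone(alive_in);

  EnergyPar p = read_epar(epar);
  int K = pol.nrow();
  int tau = hist_len_in.size() > 0 ? hist_in.ncol() / 2 : 0;
  int nx = sigma.nrow(), ny = sigma.ncol(), npix = nx * ny;

  CellState cs; cs.init(sigma, K);
  for (int k = 1; k <= K; ++k)
    if (alive[k - 1] && cs.area[k] <= 0.0)
      stop("cell %d is marked alive but has no pixels", k);

  std::vector<int> fibre_idx;
  for (int idx = 0; idx < npix; ++idx) if (sigma[idx] == -1) fibre_idx.push_back(idx);

  NumericMatrix buf(nx, ny);
  int n_rec = record_every > 0 ? n_mcs / record_every : 0;
  NumericMatrix rec_cx(K, n_rec), rec_cy(K, n_rec), rec_px(K, n_rec), rec_py(K, n_rec);
  IntegerMatrix rec_area(K, n_rec);
  IntegerVector rec_mcs(n_rec);
  NumericMatrix series(n_mcs, 7);
  colnames(series) = CharacterVector::create(
    "mcs", "n_attempts", "n_accepted", "n_degraded", "fibre_px", "mmp_total",
    "pde_substeps");

  std::vector<double> cstart_x(K + 1), cstart_y(K + 1);
  int rec_at = 0;

  for (int m = 0; m < n_mcs; ++m) {
    int n_fibre = (int)fibre_idx.size();
    int N = npix - n_fibre;
    for (int k = 1; k <= K; ++k) {
      if (cs.area[k] > 0.0) {
        cstart_x[k] = cs.sumx[k] / cs.area[k];
        cstart_y[k] = cs.sumy[k] / cs.area[k];
      }
    }

    int n_acc = 0;
    int* S = INTEGER(sigma.get__());
    const double* Ppol = REAL(pol.get__());
    for (int n = 0; n < N; ++n) {
      int idx;
      do {
        idx = (int)(unif_rand() * npix);
        if (idx >= npix) idx = npix - 1;
      } while (S[idx] == -1);
      int i = idx % nx, j = idx / nx;
      int d = (int)(unif_rand() * 4);
      if (d > 3) d = 3;
      int ti = i + DI[d], tj = j + DJ[d];
      if (ti < 0 || tj < 0 || ti >= nx || tj >= ny) continue;   // aborted, counts
      int s_t = S[ti + (size_t)tj * nx];
      if (s_t == -1) continue;                                  // fibre target
      int s_s = S[idx];
      if (s_s == s_t) continue;                                 // same domain
      double dE = delta_energy_local(S, nx, ny, p, cs, Ppol, K, ti, tj, s_s);
      bool acc = dE < 0.0;
      if (!acc && p.T_m > 0.0) acc = unif_rand() < std::exp(-dE / p.T_m);
      if (acc) {
        apply_copy(S, nx, ny, cs, ti, tj, s_s);
        ++n_acc;
        if (s_t >= 1 && cs.area[s_t] <= 0.0) alive[s_t - 1] = false;
      }
    }

    // polarity update from per-MCS centroid displacement history
    for (int k = 1; k <= K; ++k) {
      if (!alive[k - 1] || cs.area[k] <= 0.0 || tau == 0) continue;
      double dxk = cs.sumx[k] / cs.area[k] - cstart_x[k];
      double dyk = cs.sumy[k] / cs.area[k] - cstart_y[k];
      int h = hist_head[k - 1];
      hist(k - 1, 2 * h) = dxk;
      hist(k - 1, 2 * h + 1) = dyk;
      hist_head[k - 1] = (h + 1) % tau;
      if (hist_len[k - 1] < tau) hist_len[k - 1] += 1;
      double sx = 0.0, sy = 0.0;
      for (int z = 0; z < hist_len[k - 1]; ++z) {
        sx += hist(k - 1, 2 * z);
        sy += hist(k - 1, 2 * z + 1);
      }
      double nrm = std::sqrt(sx * sx + sy * sy);
      if (nrm > 1e-12) {
        pol(k - 1, 0) = sx / nrm; pol(k - 1, 1) = sy / nrm;
      } else {
        pol(k - 1, 0) = 0.0; pol(k - 1, 1) = 0.0;
      }
    }

    // MMP substeps + threshold degradation (once per MCS)
    int n_deg = 0, steps_run = 0;
    if (proteolysis) {
      std::vector<int> contact = contact_pixels(sigma, fibre_idx);
      for (int s = 0; s < substeps; ++s) {
        secrete_inplace(field, sigma, contact, lambda_dt);
        diffuse_decay_inplace(field, buf, r_diff, decay_dt);
        ++steps_run;
      }
      size_t z = 0;
      while (z < fibre_idx.size()) {
        int idx = fibre_idx[z];
        if (field[idx] >= 1.0) {
          sigma[idx] = 0;
          field[idx] -= 1.0;
          fibre_idx[z] = fibre_idx.back();
          fibre_idx.pop_back();
          ++n_deg;
        } else {
          ++z;
        }
      }
    }

    double mmp_total = 0.0;
    if (proteolysis) for (int idx = 0; idx < npix; ++idx) mmp_total += field[idx];

    series(m, 0) = mcs0 + m + 1;
    series(m, 1) = N;
    series(m, 2) = n_acc;
    series(m, 3) = n_deg;
    series(m, 4) = (double)fibre_idx.size();
    series(m, 5) = mmp_total;
    series(m, 6) = steps_run;

    if (record_every > 0 && (m + 1) % record_every == 0 && rec_at < n_rec) {
      for (int k = 1; k <= K; ++k) {
        if (cs.area[k] > 0.0) {
          rec_cx(k - 1, rec_at) = cs.sumx[k] / cs.area[k];
          rec_cy(k - 1, rec_at) = cs.sumy[k] / cs.area[k];
        } else {
          rec_cx(k - 1, rec_at) = NA_REAL;
          rec_cy(k - 1, rec_at) = NA_REAL;
        }
        rec_area(k - 1, rec_at) = (int)cs.area[k];
        rec_px(k - 1, rec_at) = pol(k - 1, 0);
        rec_py(k - 1, rec_at) = pol(k - 1, 1);
      }
      rec_mcs[rec_at] = mcs0 + m + 1;
      ++rec_at;
    }
    if ((m & 0x3f) == 0) Rcpp::checkUserInterrupt();
  }

  NumericVector area_out(K), perim_out(K), cx_out(K), cy_out(K);
  for (int k = 1; k <= K; ++k) {
    area_out[k - 1] = cs.area[k];
    perim_out[k - 1] = cs.perim[k];
    if (cs.area[k] > 0.0) {
      cx_out[k - 1] = cs.sumx[k] / cs.area[k];
      cy_out[k - 1] = cs.sumy[k] / cs.area[k];
    } else {
      cx_out[k - 1] = NA_REAL; cy_out[k - 1] = NA_REAL;
    }
  }

  return List::create(
    _["sigma"] = sigma, _["field"] = field, _["hist"] = hist,
    _["hist_len"] = hist_len, _["hist_head"] = hist_head,
    _["polarity"] = pol, _["alive"] = alive,
    _["area"] = area_out, _["perimeter"] = perim_out,
    _["cx"] = cx_out, _["cy"] = cy_out,
    _["series"] = series,
    _["rec_mcs"] = rec_mcs, _["rec_cx"] = rec_cx, _["rec_cy"] = rec_cy,
    _["rec_area"] = rec_area, _["rec_polx"] = rec_px, _["rec_poly"] = rec_py);
}

// Per-cell bookkeeping recomputed from the lattice (exposed for accessors).
// [[Rcpp::export]]
List cpp_cell_stats(IntegerMatrix sigma, int K) {
  CellState cs; cs.init(sigma, K);
  NumericVector area(K), perim(K), cx(K), cy(K);
  for (int k = 1; k <= K; ++k) {
    area[k - 1] = cs.area[k];
    perim[k - 1] = cs.perim[k];
    if (cs.area[k] > 0) {
      cx[k - 1] = cs.sumx[k] / cs.area[k];
      cy[k - 1] = cs.sumy[k] / cs.area[k];
    } else {
      cx[k - 1] = NA_REAL; cy[k - 1] = NA_REAL;
    }
  }
  return List::create(_["area"] = area, _["perimeter"] = perim,
                      _["cx"] = cx, _["cy"] = cy);
}
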