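// Core time loop of the quota-based individual-based water-column model.
//
// Super-agents carry a depth, carbon/nitrogen/phosphorus reserve quotas,
// a relative structural size and a multiplicity (number of real cells
// represented). Eulerian tracers (DIN, PO4, DOC) live on a uniform
// vertical grid of a 1-D column with unit cross-section. Within a step,
// per agent and in this order: photosynthesis, quota-regulated DOC uptake
// gated by the photosynthetic fraction f_PS, DIN/PO4 uptake (scaled so a
// grid cell's tracer mass cannot go negative), maintenance respiration,
// biosynthesis (reserves -> structure), probabilistic division,
// probabilistic quadratic grazing, random-walk vertical mixing. Random
// numbers are consumed in a fixed order (division uniform, grazing
// uniform, displacement normal -- always drawn) so a trajectory is fully
// reproducible from the R RNG seed. Tracers then diffuse implicitly
// (backward Euler, conservative flux form, zero-flux boundaries) and are
// restored toward boundary/background values unless the column is closed.

#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

struct Agent {
  double z, qc, qn, qp, size, mult;
};

static inline double clamp01(double x) {
  return x < 0.0 ? 0.0 : (x > 1.0 ? 1.0 : x);
}

// two-layer eddy diffusivity with a smooth tanh transition at the MLD
static inline double kappa_of_z(double z, double kml, double kdeep,
                                double mld, double w) {
  return kdeep + (kml - kdeep) * 0.5 * (1.0 - std::tanh((z - mld) / w));
}
static inline double dkappa_dz(double z, double kml, double kdeep,
                               double mld, double w) {
  double s = 1.0 / std::cosh((z - mld) / w);
  return -(kml - kdeep) * 0.5 * s * s / w;
}

// backward-Euler diffusion step, conservative, zero-flux boundaries
static void diffuse_implicit(std::vector<double>& c,
                             const std::vector<double>& kface,
                             double dt, double dz) {
  int n = (int)c.size();
  std::vector<double> a(n), b(n), diag(n), rhs(c);
  for (int i = 0; i < n; ++i) {
    double al = (i > 0) ? dt * kface[i] / (dz * dz) : 0.0;
    double bu = (i < n - 1) ? dt * kface[i + 1] / (dz * dz) : 0.0;
    a[i] = -al;
    b[i] = -bu;
    diag[i] = 1.0 + al + bu;
  }
  // Thomas algorithm
  for (int i = 1; i < n; ++i) {
    double m = a[i] / diag[i - 1];
    diag[i] -= m * b[i - 1];
    rhs[i] -= m * rhs[i - 1];
  }
  c[n - 1] = rhs[n - 1] / diag[n - 1];
  for (int i = n - 2; i >= 0; --i) {
    c[i] = (rhs[i] - b[i] * c[i + 1]) / diag[i];
  }
}

// [[Rcpp::export]]
List ibm_core_run(List cfg, NumericMatrix agents0, NumericMatrix tracers0,
                  NumericVector diel_factors, int n_steps, double t0_seconds,
                  int avg_start_step, bool check_conservation) {
  // --- unpack configuration ---------------------------------------------
  const double depth_max = cfg["depth_max"], dz = cfg["dz"];
  const double i0 = cfg["i0"], kd = cfg["kd"];
  const double ps_chl = cfg["ps_chl"], alpha_chl = cfg["alpha_chl"],
               beta_chl = cfg["beta_chl"], chl2c = cfg["chl2c"];
  const double c0 = cfg["c0"];
  const double qc_min = cfg["qc_min"], qc_max = cfg["qc_max"];
  const double qn_min = cfg["qn_min"], qn_max = cfg["qn_max"];
  const double qp_min = cfg["qp_min"], qp_max = cfg["qp_max"];
  const double r_n = cfg["r_n"], r_p = cfg["r_p"];
  const double vmax_n = cfg["vmax_n"], k_n = cfg["k_n"];
  const double vmax_p = cfg["vmax_p"], k_p = cfg["k_p"];
  const double v_doc_max = cfg["v_doc_max"], k_doc_sat = cfg["k_doc_sat"];
  const double f_ps_min = cfg["f_ps_min"];
  const bool mixotrophy = as<bool>(cfg["mixotrophy"]);
  const double k_r = cfg["k_r"];               // day^-1
  const double mu_syn_max = cfg["mu_syn_max"]; // day^-1
  const double nu_max = cfg["nu_max"], s_mid = cfg["s_mid"], ks = cfg["ks"];
  const double g_quad = cfg["g_quad"];         // m^3 cell^-1 day^-1
  const double kappa_ml = cfg["kappa_ml"], kappa_deep = cfg["kappa_deep"];
  const double mld = cfg["mld"], mld_width = cfg["mld_width"];
  const double din_deep = cfg["din_deep"], po4_deep = cfg["po4_deep"];
  const double restore_tau_days = cfg["restore_tau_days"];
  const double restore_thickness = cfg["restore_thickness"];
  const double doc_background = cfg["doc_background"];
  const double doc_deep_background = cfg["doc_deep_background"];
  const double doc_deep_mid = cfg["doc_deep_mid"];
  const double doc_deep_width = cfg["doc_deep_width"];
  const double doc_restore_days = cfg["doc_restore_days"];
  const double graze_doc_frac = cfg["graze_doc_frac"];
  const double graze_export_frac = cfg["graze_export_frac"];
  const bool closed = as<bool>(cfg["closed_boundaries"]);
  const double dt = cfg["dt"];
  const int n_cap = as<int>(cfg["n_super_agents"]);

  if (qc_max <= qc_min) stop("qc_max must exceed qc_min");
  const int ngrid = (int)std::round(depth_max / dz);
  if (tracers0.nrow() != ngrid || tracers0.ncol() != 3)
    stop("tracer field must be ngrid x 3 (din, po4, doc)");
  const double dt_day = dt / 86400.0;
  const double kr_s = k_r / 86400.0;
  const double mu_syn_s = mu_syn_max / 86400.0;
  const int steps_per_day = (int)std::round(86400.0 / dt);
  if (diel_factors.size() != steps_per_day)
    stop("diel_factors must have length 86400/dt");
  const double binvol = dz; // m^3 (unit cross-section)

  // --- state -------------------------------------------------------------
  std::vector<Agent> ag;
  ag.reserve(2 * n_cap);
  for (int i = 0; i < agents0.nrow(); ++i) {
    Agent a = {agents0(i, 0), agents0(i, 1), agents0(i, 2),
               agents0(i, 3), agents0(i, 4), agents0(i, 5)};
    ag.push_back(a);
  }
  std::vector<double> din(ngrid), po4(ngrid), doc(ngrid);
  for (int i = 0; i < ngrid; ++i) {
    din[i] = tracers0(i, 0);
    po4[i] = tracers0(i, 1);
    doc[i] = tracers0(i, 2);
  }

  // diffusivity at cell faces for the tracer solve
  std::vector<double> kface(ngrid + 1, 0.0);
  for (int i = 1; i < ngrid; ++i)
    kface[i] = kappa_of_z(i * dz, kappa_ml, kappa_deep, mld, mld_width);

  // restoring target for the DOC-like tracer: a surface background plus a
  // Gaussian enrichment centred just below the photic zone, emulating the
  // remineralisation maximum of sinking detritus
  std::vector<double> doc_bg(ngrid);
  for (int i = 0; i < ngrid; ++i) {
    double zc = (i + 0.5) * dz;
    double u = (zc - doc_deep_mid) / doc_deep_width;
    doc_bg[i] = doc_background + doc_deep_background * std::exp(-u * u);
  }

  // --- aggregates --------------------------------------------------------
  std::vector<double> acc_mult(ngrid, 0), acc_div(ngrid, 0),
      acc_ps(ngrid, 0), acc_doc(ngrid, 0), acc_prod(ngrid, 0),
      acc_fps_c(ngrid, 0),
      acc_lc(ngrid, 0), acc_ln(ngrid, 0), acc_lp(ngrid, 0),
      acc_din(ngrid, 0), acc_po4(ngrid, 0), acc_docT(ngrid, 0);
  long n_avg_steps = 0;
  bool extinct = false;

  // scratch
  std::vector<double> conc(ngrid), dem_n(ngrid), dem_p(ngrid), dem_doc(ngrid),
      sc_n(ngrid), sc_p(ngrid), sc_doc(ngrid);
  std::vector<double> a_ps, a_vdoc, a_vn, a_vp, a_fps;

  RNGScope rng;

  auto total_N = [&]() {
    double t = 0;
    for (int i = 0; i < ngrid; ++i) t += din[i] * binvol;
    for (auto& a : ag) t += a.mult * (a.qn + r_n * c0 * a.size);
    return t;
  };
  auto total_P = [&]() {
    double t = 0;
    for (int i = 0; i < ngrid; ++i) t += po4[i] * binvol;
    for (auto& a : ag) t += a.mult * (a.qp + r_p * c0 * a.size);
    return t;
  };

  for (int step = 0; step < n_steps; ++step) {
    if (ag.empty()) { extinct = true; break; }
    double n_before = 0, p_before = 0;
    if (check_conservation) { n_before = total_N(); p_before = total_P(); }

    long long dt_ll = (long long)std::llround(dt);
    long long tsec = (long long)std::llround(t0_seconds) + (long long)step * dt_ll;
    int tod = (int)((tsec % 86400LL) / dt_ll);
    double fdiel = diel_factors[tod];
    bool averaging = (step >= avg_start_step);

    // pass 0: local cell concentration
    std::fill(conc.begin(), conc.end(), 0.0);
    for (auto& a : ag) {
      int b = std::min(ngrid - 1, (int)(a.z / dz));
      conc[b] += a.mult;
    }
    for (int i = 0; i < ngrid; ++i) conc[i] /= binvol;

    // pass 1: rates and tracer demand
    size_t n_now = ag.size();
    a_ps.assign(n_now, 0); a_vdoc.assign(n_now, 0); a_vn.assign(n_now, 0);
    a_vp.assign(n_now, 0); a_fps.assign(n_now, 1.0);
    std::fill(dem_n.begin(), dem_n.end(), 0.0);
    std::fill(dem_p.begin(), dem_p.end(), 0.0);
    std::fill(dem_doc.begin(), dem_doc.end(), 0.0);
    for (size_t j = 0; j < n_now; ++j) {
      Agent& a = ag[j];
      int b = std::min(ngrid - 1, (int)(a.z / dz));
      double I = i0 * fdiel * std::exp(-kd * a.z);
      double ps_spec = ps_chl * (1.0 - std::exp(-alpha_chl * I / ps_chl)) *
                       std::exp(-beta_chl * I / ps_chl) * chl2c; // s^-1
      double ps = ps_spec * c0 * a.size;                          // mol C/s
      double head_c = clamp01((qc_max - a.qc) / (qc_max - qc_min));
      double vdoc = 0.0;
      if (mixotrophy) {
        vdoc = v_doc_max * head_c * doc[b] / (doc[b] + k_doc_sat);
      }
      double fps = (ps + vdoc > 0.0) ? ps / (ps + vdoc) : 1.0;
      if (fps < f_ps_min) vdoc = 0.0;
      double head_n = clamp01((qn_max - a.qn) / (qn_max - qn_min));
      double head_p = clamp01((qp_max - a.qp) / (qp_max - qp_min));
      double vn = vmax_n * head_n * din[b] / (din[b] + k_n);
      double vp = vmax_p * head_p * po4[b] / (po4[b] + k_p);
      a_ps[j] = ps; a_vdoc[j] = vdoc; a_vn[j] = vn; a_vp[j] = vp;
      a_fps[j] = fps;
      dem_n[b] += vn * dt * a.mult;
      dem_p[b] += vp * dt * a.mult;
      dem_doc[b] += vdoc * dt * a.mult;
    }
    for (int i = 0; i < ngrid; ++i) {
      double avail;
      avail = din[i] * binvol;
      sc_n[i] = (dem_n[i] > avail) ? (dem_n[i] > 0 ? avail / dem_n[i] : 0.0) : 1.0;
      avail = po4[i] * binvol;
      sc_p[i] = (dem_p[i] > avail) ? (dem_p[i] > 0 ? avail / dem_p[i] : 0.0) : 1.0;
      avail = doc[i] * binvol;
      sc_doc[i] = (dem_doc[i] > avail) ? (dem_doc[i] > 0 ? avail / dem_doc[i] : 0.0) : 1.0;
    }

    // pass 2: per-agent state update + stochastic events
    std::vector<Agent> newborns;
    for (size_t j = 0; j < n_now; ++j) {
      Agent& a = ag[j];
      int b = std::min(ngrid - 1, (int)(a.z / dz));

      // photosynthesis into the carbon reserve; overflow beyond the
      // maximum quota is discarded (unresolved exudation/excretion)
      double add_ps = a_ps[j] * dt;
      double room = qc_max - a.qc;
      if (add_ps > room) add_ps = room;
      a.qc += add_ps;

      // gated, availability-scaled DOC uptake
      double add_doc = a_vdoc[j] * dt * sc_doc[b];
      if (add_doc > qc_max - a.qc) add_doc = qc_max - a.qc;
      a.qc += add_doc;
      doc[b] -= add_doc * a.mult / binvol;

      // nutrient uptake
      double add_n = a_vn[j] * dt * sc_n[b];
      if (add_n > qn_max - a.qn) add_n = qn_max - a.qn;
      a.qn += add_n;
      din[b] -= add_n * a.mult / binvol;
      double add_p = a_vp[j] * dt * sc_p[b];
      if (add_p > qp_max - a.qp) add_p = qp_max - a.qp;
      a.qp += add_p;
      po4[b] -= add_p * a.mult / binvol;

      // maintenance respiration from the carbon reserve (floored at zero;
      // qc_min is the kinetic subsistence threshold, not a hard state
      // bound); any unfunded remainder catabolises structure, whose N and
      // P content is remineralised (starvation shrinkage)
      double resp = kr_s * c0 * a.size * dt;
      if (resp <= a.qc) {
        a.qc -= resp;
      } else {
        double unfunded = resp - a.qc;
        a.qc = 0.0;
        double dS = unfunded / c0;
        if (dS > a.size) dS = a.size;
        a.size -= dS;
        din[b] += r_n * c0 * dS * a.mult / binvol;
        po4[b] += r_p * c0 * dS * a.mult / binvol;
      }
      if (a.size < 0.5) {
        // starved below viability: remineralise and remove
        din[b] += a.mult * (a.qn + r_n * c0 * a.size) / binvol;
        po4[b] += a.mult * (a.qp + r_p * c0 * a.size) / binvol;
        doc[b] += graze_doc_frac * a.mult * (a.qc + c0 * a.size) / binvol;
        a.mult = 0.0;
        continue;
      }

      // biosynthesis: reserves -> structure at fixed stoichiometry
      double lc = clamp01((a.qc - qc_min) / (qc_max - qc_min));
      double ln = clamp01((a.qn - qn_min) / (qn_max - qn_min));
      double lp = clamp01((a.qp - qp_min) / (qp_max - qp_min));
      double lim = std::min(lc, std::min(ln, lp));
      double dB = mu_syn_s * lim * c0 * a.size * dt;
      dB = std::min(dB, std::max(0.0, a.qc - qc_min));
      dB = std::min(dB, std::max(0.0, a.qn - qn_min) / r_n);
      dB = std::min(dB, std::max(0.0, a.qp - qp_min) / r_p);
      a.qc -= dB;
      a.qn -= dB * r_n;
      a.qp -= dB * r_p;
      a.size += dB / c0;

      if (averaging) {
        acc_mult[b] += a.mult;
        acc_ps[b] += add_ps * a.mult;
        acc_doc[b] += add_doc * a.mult;
        acc_prod[b] += dB * a.mult;
        acc_fps_c[b] += (1.0 - a_fps[j]) * a.mult;
        acc_lc[b] += lc * a.mult;
        acc_ln[b] += ln * a.mult;
        acc_lp[b] += lp * a.mult;
      }

      // stochastic events: fixed draw order (division, grazing, walk)
      double u_div = unif_rand();
      double u_graze = unif_rand();
      double eta = norm_rand();

      double p_div = dt_day * nu_max / (1.0 + std::exp(-ks * (a.size - s_mid)));
      if (u_div < p_div) {
        if (averaging) acc_div[b] += a.mult;
        a.size *= 0.5;
        a.qc *= 0.5;
        a.qn *= 0.5;
        a.qp *= 0.5;
        if ((int)(ag.size() + newborns.size()) < n_cap) {
          newborns.push_back(a); // identical daughter
        } else {
          a.mult *= 2.0;         // same cells, one super-agent
        }
      }

      double p_graze = dt_day * g_quad * conc[b];
      if (u_graze < p_graze) {
        // remineralize: N,P (reserves + structure) -> DIN/PO4 except an
        // exported fraction (sinking detritus, re-entering only via the
        // bottom boundary); a fraction of grazed C -> DOC, rest exported.
        // A closed column recycles everything so N and P are conserved.
        double remin = closed ? 1.0 : (1.0 - graze_export_frac);
        din[b] += remin * a.mult * (a.qn + r_n * c0 * a.size) / binvol;
        po4[b] += remin * a.mult * (a.qp + r_p * c0 * a.size) / binvol;
        doc[b] += graze_doc_frac * a.mult * (a.qc + c0 * a.size) / binvol;
        a.mult = 0.0; // mark dead
        continue;
      }

      // vertical random walk (Visser scheme), reflective boundaries
      double kg = dkappa_dz(a.z, kappa_ml, kappa_deep, mld, mld_width);
      double zmid = a.z + 0.5 * kg * dt;
      if (zmid < 0) zmid = 0;
      if (zmid > depth_max) zmid = depth_max;
      double kk = kappa_of_z(zmid, kappa_ml, kappa_deep, mld, mld_width);
      double znew = a.z + kg * dt + eta * std::sqrt(2.0 * kk * dt);
      while (znew < 0.0 || znew > depth_max) {
        if (znew < 0.0) znew = -znew;
        if (znew > depth_max) znew = 2.0 * depth_max - znew;
      }
      a.z = znew;
    }

    // compact the dead, append newborns
    size_t keep = 0;
    for (size_t j = 0; j < ag.size(); ++j) {
      if (ag[j].mult > 0.0) ag[keep++] = ag[j];
    }
    ag.resize(keep);
    for (auto& nb : newborns) ag.push_back(nb);

    // sanity: quota bounds (bug detector); reserves live in [0, q_max]
    for (auto& a : ag) {
      if (a.qc < -1e-12 * qc_max || a.qc > qc_max * (1.0 + 1e-12) ||
          a.qn < -1e-12 * qn_max || a.qn > qn_max * (1.0 + 1e-12) ||
          a.qp < -1e-12 * qp_max || a.qp > qp_max * (1.0 + 1e-12))
        stop("quota bound violated at step %d", step);
    }

    // pass 3: tracer diffusion + restoring
    diffuse_implicit(din, kface, dt, dz);
    diffuse_implicit(po4, kface, dt, dz);
    diffuse_implicit(doc, kface, dt, dz);
    if (!closed) {
      double rb = dt_day / restore_tau_days;
      for (int i = 0; i < ngrid; ++i) {
        double zc = (i + 0.5) * dz;
        if (zc > depth_max - restore_thickness) {
          din[i] += rb * (din_deep - din[i]);
          po4[i] += rb * (po4_deep - po4[i]);
        }
        doc[i] += (dt_day / doc_restore_days) * (doc_bg[i] - doc[i]);
      }
    }
    for (int i = 0; i < ngrid; ++i) {
      if (din[i] < -1e-12 || po4[i] < -1e-12 || doc[i] < -1e-12)
        stop("negative tracer at step %d", step);
      if (din[i] < 0) din[i] = 0;
      if (po4[i] < 0) po4[i] = 0;
      if (doc[i] < 0) doc[i] = 0;
    }

    if (averaging) {
      for (int i = 0; i < ngrid; ++i) {
        acc_din[i] += din[i];
        acc_po4[i] += po4[i];
        acc_docT[i] += doc[i];
      }
      ++n_avg_steps;
    }

    if (check_conservation) {
      double n_after = total_N(), p_after = total_P();
      if (std::abs(n_after - n_before) > 1e-9 * n_before)
        stop("N not conserved at step %d (rel err %g)", step,
             std::abs(n_after - n_before) / n_before);
      if (std::abs(p_after - p_before) > 1e-9 * p_before)
        stop("P not conserved at step %d (rel err %g)", step,
             std::abs(p_after - p_before) / p_before);
    }
  }

  // --- pack results ------------------------------------------------------
  NumericMatrix agents_out(ag.size(), 6);
  for (size_t j = 0; j < ag.size(); ++j) {
    agents_out(j, 0) = ag[j].z;
    agents_out(j, 1) = ag[j].qc;
    agents_out(j, 2) = ag[j].qn;
    agents_out(j, 3) = ag[j].qp;
    agents_out(j, 4) = ag[j].size;
    agents_out(j, 5) = ag[j].mult;
  }
  colnames(agents_out) =
      CharacterVector::create("depth", "qc", "qn", "qp", "size", "mult");
  NumericMatrix tracers_out(ngrid, 3);
  for (int i = 0; i < ngrid; ++i) {
    tracers_out(i, 0) = din[i];
    tracers_out(i, 1) = po4[i];
    tracers_out(i, 2) = doc[i];
  }
  colnames(tracers_out) = CharacterVector::create("din", "po4", "doc");

  return List::create(
      _["agents"] = agents_out, _["tracers"] = tracers_out,
      _["acc_mult"] = acc_mult, _["acc_div"] = acc_div,
      _["acc_ps"] = acc_ps, _["acc_doc"] = acc_doc,
      _["acc_prod"] = acc_prod,
      _["acc_one_minus_fps"] = acc_fps_c,
      _["acc_lc"] = acc_lc, _["acc_ln"] = acc_ln, _["acc_lp"] = acc_lp,
      _["acc_din"] = acc_din, _["acc_po4"] = acc_po4,
      _["acc_doc_tracer"] = acc_docT,
      _["n_avg_steps"] = (double)n_avg_steps,
      _["n_steps_done"] = (double)n_steps,
      _["extinct"] = extinct);
}
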