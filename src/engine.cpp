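// Leapfrog Langevin (BAOAB) propagator for 1D analytic surfaces, with
// optional GaMD harmonic boost on the total potential or a LEUS grid bias
// on the coordinate.  All energies kJ/mol, coordinates in degrees (or nm
// for non-periodic surfaces), time in ps.
#include <Rcpp.h>
#include <random>
#include <cmath>
using namespace Rcpp;

static const double DEG = M_PI / 180.0;

struct Surface1D {
  bool periodic;
  double period;
  double offset;
  std::vector<double> c_amp, c_mult, c_phase;   // cosine series in the angle
  std::vector<double> g_center, g_depth, g_width; // Gaussian wells
  double harm_k, harm_x0;                        // optional harmonic term

  // minimum-image displacement
  double mi(double d) const {
    if (!periodic) return d;
    double u = d + 0.5 * period;
    u -= period * std::floor(u / period);
    return u - 0.5 * period;
  }
  // energy and (negative gradient) force at x
  void eval(double x, double &V, double &F) const {
    V = offset;
    F = 0.0;
    const double th = x * DEG;
    for (size_t i = 0; i < c_amp.size(); ++i) {
      const double a = c_mult[i] * th + c_phase[i];
      V += c_amp[i] * std::cos(a);
      F += c_amp[i] * c_mult[i] * std::sin(a) * DEG;
    }
    for (size_t i = 0; i < g_center.size(); ++i) {
      const double d = mi(x - g_center[i]);
      const double w2 = g_width[i] * g_width[i];
      const double e = g_depth[i] * std::exp(-0.5 * d * d / w2);
      V += e;
      F += e * d / w2;
    }
    if (harm_k != 0.0) {
      const double d = x - harm_x0;
      V += 0.5 * harm_k * d * d;
      F -= harm_k * d;
    }
  }
};

static Surface1D surface_from_list(const List &surf) {
  Surface1D s;
  s.periodic = as<bool>(surf["periodic"]);
  s.period = as<double>(surf["period"]);
  s.offset = as<double>(surf["offset"]);
  NumericVector ca = surf["cos_amp"], cm = surf["cos_mult"], cp = surf["cos_phase"];
  s.c_amp.assign(ca.begin(), ca.end());
  s.c_mult.assign(cm.begin(), cm.end());
  s.c_phase.assign(cp.begin(), cp.end());
  NumericVector gc = surf["g_center"], gd = surf["g_depth"], gw = surf["g_width"];
  s.g_center.assign(gc.begin(), gc.end());
  s.g_depth.assign(gd.begin(), gd.end());
  s.g_width.assign(gw.begin(), gw.end());
  s.harm_k = as<double>(surf["harm_k"]);
  s.harm_x0 = as<double>(surf["harm_x0"]);
  return s;
}

// LEUS grid bias: B(Q) = sum_k c * n_k * g(d_k) with the polynomial
// (biweight) kernel g(d) = (1 - (d/(2 sigma))^2)^2 inside |d| < 2 sigma
// and 0 beyond; g(0) = 1 and both g and g' vanish at the cutoff, so the
// bias and its force are continuous.  d_k is the minimum-image distance
// to grid-cell centre k.
struct GridBias {
  std::vector<double> visits;
  double c, sigma, lo, hi;
  int ng;
  bool periodic;
  double width() const { return (hi - lo) / ng; }
  double center(int k) const { return lo + (k + 0.5) * width(); }
  double mi(double d) const {
    if (!periodic) return d;
    const double per = hi - lo;
    double u = d + 0.5 * per;
    u -= per * std::floor(u / per);
    return u - 0.5 * per;
  }
  int cell(double q) const {
    double u = q - lo;
    if (periodic) {
      const double per = hi - lo;
      u -= per * std::floor(u / per);
    }
    int k = (int)std::floor(u / width());
    if (k < 0) k = 0;
    if (k >= ng) k = ng - 1;
    return k;
  }
  void eval(double q, double &B, double &F) const {
    B = 0.0;
    F = 0.0;
    const double cut = 2.0 * sigma;
    for (int k = 0; k < ng; ++k) {
      if (visits[k] == 0.0) continue;
      const double d = mi(q - center(k));
      if (std::fabs(d) >= cut) continue;
      const double u = d / cut, w = 1.0 - u * u;
      B += c * visits[k] * w * w;
      // dg/dd = -4 u w / cut; F = -c n dg/dd
      F += c * visits[k] * 4.0 * u * w / cut;
    }
  }
};

// scatter-add vals into an n-vector by 1-based index (row order preserved)
// [[Rcpp::export(name = ".cpp_index_sum")]]
NumericVector cpp_index_sum(IntegerVector idx, NumericVector vals, int n) {
  NumericVector out(n);
  const int m = idx.size();
  for (int r = 0; r < m; ++r) out[idx[r] - 1] += vals[r];
  return out;
}

// [[Rcpp::export(name = ".cpp_surface_langevin")]]
List cpp_surface_langevin(List surf_spec, double mass, double dt, double friction,
                          double temperature, int n_steps, int stride,
                          double x0, double v0, int seed,
                          int bias_type,                 // 0 none, 1 GaMD, 2 LEUS
                          double E, double k,            // GaMD parameters
                          NumericVector visits, double bias_c, double bias_sigma,
                          int n_grid, double grid_lo, double grid_hi,
                          bool le_update) {
  const double kB = 0.008314463;
  Surface1D surf = surface_from_list(surf_spec);
  GridBias gb;
  if (bias_type == 2) {
    gb.visits.assign(visits.begin(), visits.end());
    gb.c = bias_c; gb.sigma = bias_sigma; gb.ng = n_grid;
    gb.lo = grid_lo; gb.hi = grid_hi; gb.periodic = surf.periodic;
  }

  std::mt19937_64 rng(static_cast<uint64_t>(seed));
  std::normal_distribution<double> gauss(0.0, 1.0);

  const double kT = kB * temperature;
  const double c1 = std::exp(-friction * dt);
  const double c2 = std::sqrt((1.0 - c1 * c1) * kT / mass);

  const int n_frames = n_steps / stride + 1;
  NumericVector t_out(n_frames), x_out(n_frames), v_pot(n_frames), v_bias(n_frames);

  double x = x0, v = v0, V, F, Fb, dV;
  auto total_force = [&](double xx, double &Vout, double &Fout, double &dVout) {
    surf.eval(xx, Vout, Fout);
    dVout = 0.0;
    if (bias_type == 1) {
      if (Vout < E) {
        dVout = 0.5 * k * (E - Vout) * (E - Vout);
        Fout *= 1.0 - k * (E - Vout);  // d(V+dV)/dV = 1 - k(E-V)
      }
    } else if (bias_type == 2) {
      double B;
      gb.eval(xx, B, Fb);
      dVout = B;
      Fout += Fb;
    }
  };

  total_force(x, V, F, dV);
  // streaming statistics on the unboosted potential, every step incl. step 0
  double s_n = 1.0, s_mean = V, s_m2 = 0.0, s_min = V, s_max = V;
  int fr = 0;
  t_out[fr] = 0.0; x_out[fr] = x; v_pot[fr] = V; v_bias[fr] = dV; ++fr;

  for (int step = 1; step <= n_steps; ++step) {
    v += 0.5 * dt * F / mass;          // B
    x += 0.5 * dt * v;                 // A
    v = c1 * v + c2 * gauss(rng);      // O
    x += 0.5 * dt * v;                 // A
    total_force(x, V, F, dV);
    v += 0.5 * dt * F / mass;          // B

    if (!std::isfinite(V) || !std::isfinite(F))
      stop("non-finite energy or force at step %d", step);

    if (bias_type == 2 && le_update)
      gb.visits[gb.cell(x)] += 1.0;

    s_n += 1.0;
    const double delta = V - s_mean;
    s_mean += delta / s_n;
    s_m2 += delta * (V - s_mean);
    if (V < s_min) s_min = V;
    if (V > s_max) s_max = V;

    if (step % stride == 0) {
      t_out[fr] = step * dt; x_out[fr] = x; v_pot[fr] = V; v_bias[fr] = dV; ++fr;
    }
  }

  List out = List::create(
    _["times"] = t_out, _["x"] = x_out, _["V"] = v_pot, _["dV"] = v_bias,
    _["x_final"] = x, _["v_final"] = v,
    _["stats"] = NumericVector::create(
      _["n"] = s_n, _["mean"] = s_mean, _["m2"] = s_m2,
      _["min"] = s_min, _["max"] = s_max));
  if (bias_type == 2)
    out["visits"] = NumericVector(gb.visits.begin(), gb.visits.end());
  return out;
}
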