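// Fixed-step RK4 integrator for the one-leg search-movement model.
//
// State layout (38 doubles):
//   [0..7]   CPG cells C3,C4,C5,C6 as (v, a) pairs: v = fast activity
//            variable, a = slow recovery (adaptation) variable
//   [8..19]  premotor/gating interneurons IN7..IN18 (first-order u)
//   [20..27] motoneurons LF,LS,DF,DS,EF,ES,FF,FS (first-order u)
//   [28..35] muscle pool activations, same order as the MNs
//   [36]     beta (CTr joint, femur elevation, deg)
//   [37]     gamma (FTi joint, interior angle, deg)
//
// Threshold gates, drive multipliers and recruitment fractions are algebraic
// inputs held constant within a step (evaluated from the state at the start
// of the step), so the RK4 stages integrate a smooth vector field.

#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

static const int N_STATE = 38;
static const int IDX_IN = 8;    // IN7
static const int IDX_MN = 20;   // MN(LF)
static const int IDX_MUS = 28;
static const int IDX_BETA = 36;
static const int IDX_GAMMA = 37;
static const double DEG = M_PI / 180.0;

static inline double sig(double x) { return 1.0 / (1.0 + std::exp(-x)); }

struct Engine {
  // cell parameters
  double tau_v, theta_cpg, slope_cpg;
  double tau_a[4];
  double tau_in, theta_in, slope_in;
  double tau_mn, theta_mn, slope_mn;
  double b[4];
  double g_mn;
  // wiring
  std::vector<int> syn_src, syn_dst;
  std::vector<double> syn_w;          // signed conductances
  std::vector<double> drive;          // per-unit constant drive (24)
  double w_sens_beta, w_sens_gamma;   // signed sensory conductance scales
  std::vector<int> mn_class;          // 8: 0 fast_LD, 1 slow, 2 fast_EF
  // muscles / joints
  double q[8], tau_on[8], tau_off[8], theta_c[8], k_pass[8], theta_rest[8];
  double lf, lt;
  // gating
  double beta_thr, gamma_thr;
  double gb_hi, gb_lo, gg_hi, gg_lo;
  int pol_beta, pol_gamma;            // +1: high when angle >= thr
  int gate_mode_beta, gate_mode_gamma; // 0 angle, 1 fixed, 2 square wave
  double gate_fix_beta, gate_fix_gamma, gate_sq_period;

  // per-step algebraic inputs
  double g_beta, g_gamma;
  double mult[3];
  double af[8];
  bool frozen;

  double unit_out(const double* y, int i) const {
    if (i < 4)  return sig((y[2 * i] - theta_cpg) / slope_cpg);
    if (i < 16) return sig((y[IDX_IN + (i - 4)] - theta_in) / slope_in);
    return sig((y[IDX_MN + (i - 16)] - theta_mn) / slope_mn);
  }

  double alpha_of(double beta, double gamma) const {
    double dir = (beta - (180.0 - gamma)) * DEG;
    double x = lf * std::cos(beta * DEG) + lt * std::cos(dir);
    double yy = lf * std::sin(beta * DEG) + lt * std::sin(dir);
    return std::atan2(yy, x) / DEG;
  }

  void deriv(const double* y, double* dy) const {
    double out[24];
    for (int i = 0; i < 24; ++i) out[i] = unit_out(y, i);

    double inp[24];
    for (int i = 0; i < 24; ++i) inp[i] = drive[i];
    for (size_t k = 0; k < syn_src.size(); ++k)
      inp[syn_dst[k]] += syn_w[k] * out[syn_src[k]];
    inp[9] += w_sens_gamma * g_gamma;   // IN12 (unit index 9)
    inp[15] += w_sens_beta * g_beta;    // IN18 (unit index 15)
    for (int m = 0; m < 8; ++m) inp[16 + m] += g_mn * mult[mn_class[m]];

    for (int i = 0; i < 4; ++i) {
      double v = y[2 * i], a = y[2 * i + 1];
      dy[2 * i] = (-v + inp[i] - b[i] * a) / tau_v;
      dy[2 * i + 1] = (-a + out[i]) / tau_a[i];
    }
    for (int i = 0; i < 12; ++i)
      dy[IDX_IN + i] = (-y[IDX_IN + i] + inp[4 + i]) / tau_in;
    for (int i = 0; i < 8; ++i)
      dy[IDX_MN + i] = (-y[IDX_MN + i] + inp[16 + i]) / tau_mn;

    for (int m = 0; m < 8; ++m) {
      double target = out[16 + m] * af[m];
      double am = y[IDX_MUS + m];
      double tau = (target > am) ? tau_on[m] : tau_off[m];
      dy[IDX_MUS + m] = (target - am) / tau;
    }

    double beta = y[IDX_BETA], gamma = y[IDX_GAMMA];
    if (frozen) {
      dy[IDX_BETA] = 0.0;
      dy[IDX_GAMMA] = 0.0;
    } else {
      double tb = 0.0, tg = 0.0;
      for (int m = 0; m < 4; ++m)  // levator/depressor pools act on beta
        tb += q[m] * y[IDX_MUS + m] * (theta_c[m] - beta)
            + k_pass[m] * (theta_rest[m] - beta);
      for (int m = 4; m < 8; ++m)  // extensor/flexor pools act on gamma
        tg += q[m] * y[IDX_MUS + m] * (theta_c[m] - gamma)
            + k_pass[m] * (theta_rest[m] - gamma);
      dy[IDX_BETA] = tb;
      dy[IDX_GAMMA] = tg;
    }
  }

  void rk4_step(double* y, double dt) const {
    double k1[N_STATE], k2[N_STATE], k3[N_STATE], k4[N_STATE], tmp[N_STATE];
    deriv(y, k1);
    for (int i = 0; i < N_STATE; ++i) tmp[i] = y[i] + 0.5 * dt * k1[i];
    deriv(tmp, k2);
    for (int i = 0; i < N_STATE; ++i) tmp[i] = y[i] + 0.5 * dt * k2[i];
    deriv(tmp, k3);
    for (int i = 0; i < N_STATE; ++i) tmp[i] = y[i] + dt * k3[i];
    deriv(tmp, k4);
    for (int i = 0; i < N_STATE; ++i)
      y[i] += dt / 6.0 * (k1[i] + 2.0 * k2[i] + 2.0 * k3[i] + k4[i]);
  }

  double gate_value(double angle, double thr, double hi, double lo,
                    int pol, int mode, double fix, double t) const {
    if (mode == 1) return fix;
    if (mode == 2) {
      double cycles = t / gate_sq_period;
      double ph = cycles - std::floor(cycles);
      return (ph < 0.5) ? hi : lo;
    }
    bool above = (angle >= thr);
    if (pol < 0) above = !above;
    return above ? hi : lo;
  }
};

static void fill_vec(std::vector<double>& v, const NumericVector& x) {
  v.assign(x.begin(), x.end());
}

// [[Rcpp::export]]
List simulate_leg_cpp(List pars) {
  Engine e;
  List net = pars["network"];
  e.tau_v = as<double>(net["tau_v"]);
  NumericVector ta = net["tau_a"];
  for (int i = 0; i < 4; ++i) e.tau_a[i] = ta[i];
  e.theta_cpg = as<double>(net["theta_cpg"]);
  e.slope_cpg = as<double>(net["slope_cpg"]);
  e.tau_in = as<double>(net["tau_in"]);
  e.theta_in = as<double>(net["theta_in"]);
  e.slope_in = as<double>(net["slope_in"]);
  e.tau_mn = as<double>(net["tau_mn"]);
  e.theta_mn = as<double>(net["theta_mn"]);
  e.slope_mn = as<double>(net["slope_mn"]);
  NumericVector bb = net["b"];
  for (int i = 0; i < 4; ++i) e.b[i] = bb[i];
  e.g_mn = as<double>(net["g_mn"]);
  IntegerVector src = net["syn_src"], dst = net["syn_dst"];
  NumericVector w = net["syn_w"], drv = net["drive"];
  e.syn_src.assign(src.begin(), src.end());
  e.syn_dst.assign(dst.begin(), dst.end());
  fill_vec(e.syn_w, w);
  fill_vec(e.drive, drv);
  e.w_sens_beta = as<double>(net["w_sens_beta"]);
  e.w_sens_gamma = as<double>(net["w_sens_gamma"]);
  IntegerVector mc = net["mn_class"];
  e.mn_class.assign(mc.begin(), mc.end());

  List mus = pars["muscle"];
  NumericVector q = mus["q"], ton = mus["tau_on"], toff = mus["tau_off"],
                tc = mus["theta_c"], kp = mus["k_pass"], tr = mus["theta_rest"];
  for (int i = 0; i < 8; ++i) {
    e.q[i] = q[i]; e.tau_on[i] = ton[i]; e.tau_off[i] = toff[i];
    e.theta_c[i] = tc[i]; e.k_pass[i] = kp[i]; e.theta_rest[i] = tr[i];
  }
  List geo = pars["geometry"];
  e.lf = as<double>(geo["femur_length"]);
  e.lt = as<double>(geo["tibia_length"]);

  List gat = pars["gating"];
  e.beta_thr = as<double>(gat["beta_thr"]);
  e.gamma_thr = as<double>(gat["gamma_thr"]);
  e.gb_hi = as<double>(gat["g_beta_high"]);
  e.gb_lo = as<double>(gat["g_beta_low"]);
  e.gg_hi = as<double>(gat["g_gamma_high"]);
  e.gg_lo = as<double>(gat["g_gamma_low"]);
  e.pol_beta = as<int>(gat["polarity_beta"]);
  e.pol_gamma = as<int>(gat["polarity_gamma"]);
  e.gate_mode_beta = as<int>(gat["gate_mode_beta"]);
  e.gate_mode_gamma = as<int>(gat["gate_mode_gamma"]);
  e.gate_fix_beta = as<double>(gat["gate_fix_beta"]);
  e.gate_fix_gamma = as<double>(gat["gate_fix_gamma"]);
  e.gate_sq_period = as<double>(gat["gate_sq_period"]);

  List integ = pars["integration"];
  double dt = as<double>(integ["dt"]);
  double store_every = as<double>(integ["store_every"]);
  double duration = as<double>(integ["duration"]);

  List init = pars["init"];
  double y[N_STATE];
  for (int i = 0; i < N_STATE; ++i) y[i] = 0.0;
  y[IDX_BETA] = as<double>(init["beta0"]);
  y[IDX_GAMMA] = as<double>(init["gamma0"]);
  y[0] = as<double>(init["c3_offset"]);  // deterministic symmetry breaking
  NumericVector y0 = init["state"];      // optional full state override
  if (y0.size() == N_STATE)
    for (int i = 0; i < N_STATE; ++i) y[i] = y0[i];

  List pro = pars["protocol"];
  double po = as<double>(pro["po"]);
  bool has_po = R_finite(po);
  double arm_time = as<double>(pro["arm_time"]);
  double contact_duration = as<double>(pro["contact_duration"]);
  double slow_ramp = as<double>(pro["slow_ramp"]);
  double fast_ef_delay = as<double>(pro["fast_ef_delay"]);
  double dur_lev = as<double>(pro["dur_lev"]);
  double dur_dep = as<double>(pro["dur_dep"]);
  bool quantized = as<int>(pro["quantized"]) != 0;
  int n_lev = as<int>(pro["n_units_lev"]);
  int n_dep = as<int>(pro["n_units_dep"]);
  NumericVector mult_free = pro["mult_free"];
  NumericVector step_time = pro["mult_step_time"];
  NumericVector step_val = pro["mult_step_value"];

  long n_steps = (long)std::llround(duration / dt);
  long store_stride = std::max(1L, (long)std::llround(store_every / dt));
  long n_store = n_steps / store_stride + 1;

  const int NC = 35;
  NumericMatrix trace(n_store, NC);

  int mode = 0;  // 0 free, 1 contact, 2 recovery
  double t_contact = NA_REAL, t_removal = NA_REAL;
  double alpha_prev = e.alpha_of(y[IDX_BETA], y[IDX_GAMMA]);
  double alpha_min = alpha_prev, alpha_max = alpha_prev;
  long row = 0;

  for (long step = 0; step <= n_steps; ++step) {
    double t = step * dt;
    double beta = y[IDX_BETA], gamma = y[IDX_GAMMA];
    double alpha = e.alpha_of(beta, gamma);
    if (alpha < alpha_min) alpha_min = alpha;
    if (alpha > alpha_max) alpha_max = alpha;

    // protocol state machine
    if (mode == 0 && has_po && t >= arm_time &&
        alpha_prev > po && alpha <= po) {
      mode = 1;
      t_contact = t;
      t_removal = t + contact_duration;
    } else if (mode == 1 && t >= t_removal) {
      mode = 2;
    }
    alpha_prev = alpha;

    // algebraic inputs for this step
    e.frozen = (mode == 1);
    if (mode == 1) {
      e.mult[0] = e.mult[1] = e.mult[2] = 0.0;
      for (int m = 0; m < 8; ++m) e.af[m] = 1.0;
    } else if (mode == 2) {
      double ts = t - t_removal;
      e.mult[0] = 1.0;                                  // fast lev/dep drive
      e.mult[1] = std::min(1.0, ts / slow_ramp);        // slow MNs
      e.mult[2] = (ts >= fast_ef_delay) ? 1.0 : 0.0;    // fast ext/flex
      double fl = std::min(1.0, ts / dur_lev);
      double fd = std::min(1.0, ts / dur_dep);
      if (quantized) {
        fl = std::floor(fl * n_lev + 1e-9) / n_lev;
        fd = std::floor(fd * n_dep + 1e-9) / n_dep;
      }
      for (int m = 0; m < 8; ++m) e.af[m] = 1.0;
      e.af[0] = fl;  // fast levator pool
      e.af[2] = fd;  // fast depressor pool
    } else {
      for (int c = 0; c < 3; ++c) {
        double mv = mult_free[c];
        if (R_finite(step_time[c]) && t >= step_time[c]) mv = step_val[c];
        e.mult[c] = mv;
      }
      for (int m = 0; m < 8; ++m) e.af[m] = 1.0;
    }
    e.g_beta = e.gate_value(beta, e.beta_thr, e.gb_hi, e.gb_lo, e.pol_beta,
                            e.gate_mode_beta, e.gate_fix_beta, t);
    e.g_gamma = e.gate_value(gamma, e.gamma_thr, e.gg_hi, e.gg_lo, e.pol_gamma,
                             e.gate_mode_gamma, e.gate_fix_gamma, t);

    if (step % store_stride == 0 && row < n_store) {
      trace(row, 0) = t;
      trace(row, 1) = beta;
      trace(row, 2) = gamma;
      trace(row, 3) = alpha;
      trace(row, 4) = e.g_beta;
      trace(row, 5) = e.g_gamma;
      for (int i = 0; i < 4; ++i) trace(row, 6 + i) = e.unit_out(y, i);
      for (int i = 0; i < 12; ++i) trace(row, 10 + i) = e.unit_out(y, 4 + i);
      for (int i = 0; i < 8; ++i) trace(row, 22 + i) = e.unit_out(y, 16 + i);
      trace(row, 30) = e.mult[1];
      trace(row, 31) = e.mult[2];
      trace(row, 32) = e.mult[0];
      trace(row, 33) = e.af[0];
      trace(row, 34) = e.af[2];
      ++row;
    }

    if (step == n_steps) break;
    e.rk4_step(y, dt);
    if (y[IDX_GAMMA] > 180.0) y[IDX_GAMMA] = 180.0;
    if (y[IDX_GAMMA] < 0.5) y[IDX_GAMMA] = 0.5;
    for (int i = 0; i < N_STATE; ++i)
      if (!R_finite(y[i]))
        stop("non-finite state at t = %f ms (state index %d)", t, i + 1);
  }

  NumericVector final_state(N_STATE);
  for (int i = 0; i < N_STATE; ++i) final_state[i] = y[i];

  return List::create(
    _["trace"] = trace,
    _["t_contact"] = t_contact,
    _["t_removal"] = t_removal,
    _["alpha_range"] = NumericVector::create(alpha_min, alpha_max),
    _["final_state"] = final_state);
}
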