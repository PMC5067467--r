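// Firing-rate network core: three basal ganglia-thalamo-cortical loops,
// BLA/IC valuation bank, dopamine system with striato-nigro-striatal
// spirals, dopamine-gated Hebbian plasticity.  Forward-Euler stepping at
// the environment-cycle granularity (optional substeps).  All randomness
// comes from R's RNG so replicates are reproducible from set.seed().
#include <Rcpp.h>
#include <cmath>
#include <cstring>
using namespace Rcpp;

static inline double pos(double x) { return x > 0.0 ? x : 0.0; }
static inline double neg(double x) { return x <= 0.0 ? -x : 0.0; }
// [tanh(sigma*(u - theta))]^+ output nonlinearity shared by all leaky units
static inline double outf(double u, double sigma, double theta) {
  return pos(std::tanh(sigma * (u - theta)));
}

struct LoopParams {
  double tau_str, sigma_str, theta_str, iota, delta;
  double tau_stn, sigma_stn, theta_stn;
  double tau_gpi, sigma_gpi, theta_gpi;
  double tau_th,  sigma_th,  theta_th,  tau_n, nu;
  double tau_ctx, sigma_ctx, theta_ctx;
  double w_cs, w_ce, w_se, w_sg, w_gt, w_tc, w_ct, w_tt;
};

struct Loop {
  LoopParams p;
  double u_str[2], u_stn[2], u_gpi[2], u_th[2], u_ctx[2], n[2];
  double v_str[2], v_stn[2], v_gpi[2], v_th[2], v_ctx[2];
  void zero_state() {
    for (int c = 0; c < 2; ++c) {
      u_str[c] = u_stn[c] = u_gpi[c] = u_th[c] = u_ctx[c] = n[c] = 0.0;
      v_str[c] = v_stn[c] = v_th[c] = v_ctx[c] = 0.0;
      v_gpi[c] = outf(0.0, p.sigma_gpi, p.theta_gpi); // tonically active at rest
    }
  }
};

struct Onset {
  double tau_o, tau_i;
  double uo, ui, o;
  void zero_state() { uo = ui = o = 0.0; }
  void step(double I, double h) {
    uo += h / tau_o * (-uo + pos(I - ui));
    ui += h / tau_i * (-ui + I);
    o = pos(std::tanh(uo));
  }
};

struct HebbParams { double eta, theta_da, theta_str, theta_inp, w_cap; };

struct Net {
  // integration
  double cycle_s; int substeps;
  // loops
  Loop goal, assoc, motor;
  // BLA/IC: units 0,1 = CS1,CS2; 2,3 = US1,US2
  Onset bla[4];
  double bla_w_lever, bla_w_food, bla_w_sat;
  double trace_alpha, trace_tau;
  double tr[4], trdot[4];
  double W_bla[4][4];
  double eta_b, theta_da_bla, max_w_bla;
  // dopamine sources
  Onset lh, ppn;
  double lh_w_food, ppn_w_food;
  double vta_tau, vta_sigma, vta_theta, vta_w_lh, u_vta, v_vta;
  // SNpc modules: [0] -> DMS, [1] -> DLS; per-channel excitatory/inhibitory couple
  double sn_tau_e, sn_sigma_e, sn_theta_e, sn_tau_i, sn_sigma_i, sn_theta_i;
  double sn_w_ppn, sn_w_inh, sn_w_spiral;
  double u_sne[2][2], u_sni[2][2], v_sne[2][2], v_sni[2][2];
  // plastic out-of-loop striatal input projections
  double W_nac[2][4], W_dms[2][2], W_dls[2][2];
  HebbParams h_nac, h_dms, h_dls;
  // cortico-cortical pathways (channel preserving, fixed): descending
  // PL->ACtx->MC carries goal bias, ascending MC->ACtx->PL carries the
  // identity of the action in execution (A-O association substrate)
  double w_pl_actx, w_actx_mc, w_mc_actx, w_actx_pl;
  // variant: one manipulandum drives both CS units and both actions act on it
  bool one_lever;
  // lesion clamps (absorbing) and spiral disconnection
  bool les_bla, les_nac, les_dms, les_pl, sns_cut;
  // motor-channel silencing: remaining cycles (-1 = rest of trial, 0 = off)
  int silenced[2];

  void zero_state() {
    goal.zero_state(); assoc.zero_state(); motor.zero_state();
    for (int k = 0; k < 4; ++k) { bla[k].zero_state(); tr[k] = trdot[k] = 0.0; }
    lh.zero_state(); ppn.zero_state();
    u_vta = 0.0; v_vta = outf(0.0, vta_sigma, vta_theta);
    for (int m = 0; m < 2; ++m)
      for (int c = 0; c < 2; ++c) {
        u_sne[m][c] = u_sni[m][c] = 0.0;
        v_sni[m][c] = outf(0.0, sn_sigma_i, sn_theta_i);
        v_sne[m][c] = outf(-sn_w_inh * v_sni[m][c], sn_sigma_e, sn_theta_e);
      }
    silenced[0] = silenced[1] = 0;
    apply_clamps();
  }

  void zero_weights() {
    std::memset(W_bla, 0, sizeof(W_bla));
    std::memset(W_nac, 0, sizeof(W_nac));
    std::memset(W_dms, 0, sizeof(W_dms));
    std::memset(W_dls, 0, sizeof(W_dls));
  }

  void apply_clamps() {
    if (les_bla)
      for (int k = 0; k < 4; ++k) { bla[k].uo = bla[k].ui = bla[k].o = 0.0; }
    if (les_nac)
      for (int c = 0; c < 2; ++c) { goal.u_str[c] = goal.v_str[c] = 0.0; }
    if (les_dms)
      for (int c = 0; c < 2; ++c) { assoc.u_str[c] = assoc.v_str[c] = 0.0; }
    if (les_pl)
      for (int c = 0; c < 2; ++c) { goal.u_ctx[c] = goal.v_ctx[c] = 0.0; }
    for (int c = 0; c < 2; ++c)
      if (silenced[c] != 0) {
        motor.u_str[c] = motor.v_str[c] = 0.0;
        motor.u_stn[c] = motor.v_stn[c] = 0.0;
        motor.u_gpi[c] = motor.v_gpi[c] = 0.0;
        motor.u_th[c]  = motor.v_th[c]  = 0.0;
        motor.u_ctx[c] = motor.v_ctx[c] = 0.0;
      }
  }

  void check_finite() {
    double s = u_vta;
    for (int c = 0; c < 2; ++c)
      s += goal.u_ctx[c] + assoc.u_ctx[c] + motor.u_ctx[c] +
           goal.u_str[c] + assoc.u_str[c] + motor.u_str[c] + motor.u_th[c];
    for (int k = 0; k < 4; ++k) s += bla[k].uo + tr[k];
    if (!std::isfinite(s))
      stop("non-finite network state: unstable configuration (check tau, dt and weights)");
  }

  // one bank of a loop advanced one substep
  static void loop_substep(Loop &L, const double da[2], const double inp[2],
                           const double bias[2], const double z[2], double h,
                           bool striatum_clamped, bool ctx_clamped) {
    const LoopParams &p = L.p;
    double pctx[2] = { L.v_ctx[0], L.v_ctx[1] };
    double pth[2]  = { L.v_th[0],  L.v_th[1]  };
    for (int c = 0; c < 2; ++c)
      L.n[c] += h / p.tau_n * (-L.n[c] + p.nu * z[c]);
    for (int c = 0; c < 2; ++c) {
      double I = (p.iota + p.delta * da[c]) * (p.w_cs * pctx[c] + inp[c]);
      L.u_str[c] += h / p.tau_str * (-L.u_str[c] + I);
      L.v_str[c] = outf(L.u_str[c], p.sigma_str, p.theta_str);
      if (striatum_clamped) { L.u_str[c] = 0.0; L.v_str[c] = 0.0; }
      L.u_stn[c] += h / p.tau_stn * (-L.u_stn[c] + p.w_ce * pctx[c]);
      L.v_stn[c] = outf(L.u_stn[c], p.sigma_stn, p.theta_stn);
    }
    double stn_sum = L.v_stn[0] + L.v_stn[1]; // diffuse off-center/on-surround drive
    for (int c = 0; c < 2; ++c) {
      double I = p.w_se * stn_sum - p.w_sg * L.v_str[c];
      L.u_gpi[c] += h / p.tau_gpi * (-L.u_gpi[c] + I);
      L.v_gpi[c] = outf(L.u_gpi[c], p.sigma_gpi, p.theta_gpi);
    }
    for (int c = 0; c < 2; ++c) {
      double I = -p.w_gt * L.v_gpi[c] + p.w_ct * pctx[c] - p.w_tt * pth[1 - c] + L.n[c];
      L.u_th[c] += h / p.tau_th * (-L.u_th[c] + I);
      L.v_th[c] = outf(L.u_th[c], p.sigma_th, p.theta_th);
    }
    for (int c = 0; c < 2; ++c) {
      double I = p.w_tc * L.v_th[c] + bias[c];
      L.u_ctx[c] += h / p.tau_ctx * (-L.u_ctx[c] + I);
      L.v_ctx[c] = outf(L.u_ctx[c], p.sigma_ctx, p.theta_ctx);
      if (ctx_clamped) { L.u_ctx[c] = 0.0; L.v_ctx[c] = 0.0; }
    }
  }

  // one full environment cycle; stimuli are binary
  void step(double lever1, double lever2, double food1, double food2,
            double sat1, double sat2, bool learn) {
    double h = cycle_s / substeps;
    // one fresh uniform draw per thalamic unit per cycle (held across substeps)
    double z[3][2];
    for (int l = 0; l < 3; ++l)
      for (int c = 0; c < 2; ++c) z[l][c] = unif_rand() - 0.5;
    double lever[2] = { lever1, lever2 };

    for (int s = 0; s < substeps; ++s) {
      // --- valuation and dopamine sources ------------------------------
      double oprev[4] = { bla[0].o, bla[1].o, bla[2].o, bla[3].o };
      double ext[4];
      if (one_lever) { ext[0] = bla_w_lever * lever1; ext[1] = bla_w_lever * lever1; }
      else           { ext[0] = bla_w_lever * lever1; ext[1] = bla_w_lever * lever2; }
      ext[2] = bla_w_food * food1 - bla_w_sat * sat1;
      ext[3] = bla_w_food * food2 - bla_w_sat * sat2;
      for (int k = 0; k < 4; ++k) {
        double I = ext[k];
        for (int j = 0; j < 4; ++j) I += W_bla[k][j] * oprev[j];
        bla[k].step(I, h);
      }
      if (les_bla)
        for (int k = 0; k < 4; ++k) { bla[k].uo = bla[k].ui = bla[k].o = 0.0; }

      double food_sum = food1 + food2;
      lh.step(lh_w_food * food_sum, h);
      ppn.step(ppn_w_food * food_sum, h);
      u_vta += h / vta_tau * (-u_vta + vta_w_lh * lh.o);
      v_vta = outf(u_vta, vta_sigma, vta_theta);

      // SNpc: spiral source is the striatal stage one level up (previous values)
      double src[2][2] = { { goal.v_str[0],  goal.v_str[1]  },
                           { assoc.v_str[0], assoc.v_str[1] } };
      for (int m = 0; m < 2; ++m)
        for (int c = 0; c < 2; ++c) {
          double Ii = sns_cut ? 0.0 : -sn_w_spiral * src[m][c];
          u_sni[m][c] += h / sn_tau_i * (-u_sni[m][c] + Ii);
          v_sni[m][c] = outf(u_sni[m][c], sn_sigma_i, sn_theta_i);
          double Ie = sn_w_ppn * ppn.o - sn_w_inh * v_sni[m][c];
          u_sne[m][c] += h / sn_tau_e * (-u_sne[m][c] + Ie);
          v_sne[m][c] = outf(u_sne[m][c], sn_sigma_e, sn_theta_e);
        }

      // --- goal loop (NAc - PL) ----------------------------------------
      double da_g[2] = { v_vta, v_vta };
      double inp_g[2], bias_g[2];
      for (int c = 0; c < 2; ++c) {
        inp_g[c] = 0.0;
        for (int k = 0; k < 4; ++k) inp_g[c] += W_nac[c][k] * bla[k].o;
        bias_g[c] = w_actx_pl * assoc.v_ctx[c]; // previous cycle
      }
      loop_substep(goal, da_g, inp_g, bias_g, z[0], h, les_nac, les_pl);

      // --- associative loop (DMS - PPC/PFCd) ---------------------------
      double da_a[2] = { v_sne[0][0], v_sne[0][1] };
      double inp_a[2], bias_a[2];
      for (int c = 0; c < 2; ++c) {
        inp_a[c] = W_dms[c][0] * lever[0] + W_dms[c][1] * lever[1];
        bias_a[c] = w_pl_actx * goal.v_ctx[c] + w_mc_actx * motor.v_ctx[c];
      }
      loop_substep(assoc, da_a, inp_a, bias_a, z[1], h, les_dms, false);

      // --- motor loop (DLS - MC) ---------------------------------------
      double da_m[2] = { v_sne[1][0], v_sne[1][1] };
      double inp_m[2], bias_m[2];
      for (int c = 0; c < 2; ++c) {
        inp_m[c] = W_dls[c][0] * lever[0] + W_dls[c][1] * lever[1];
        bias_m[c] = w_actx_mc * assoc.v_ctx[c];
      }
      loop_substep(motor, da_m, inp_m, bias_m, z[2], h, false, false);
      for (int c = 0; c < 2; ++c)
        if (silenced[c] != 0) {
          motor.u_str[c] = motor.v_str[c] = 0.0;
          motor.u_stn[c] = motor.v_stn[c] = 0.0;
          motor.u_gpi[c] = motor.v_gpi[c] = 0.0;
          motor.u_th[c]  = motor.v_th[c]  = 0.0;
          motor.u_ctx[c] = motor.v_ctx[c] = 0.0;
        }
    }

    // --- activity traces (once per cycle) ------------------------------
    for (int k = 0; k < 4; ++k) {
      double told = tr[k];
      tr[k] += cycle_s / trace_tau * (-tr[k] + trace_alpha * bla[k].o);
      trdot[k] = (tr[k] - told) / cycle_s;
    }

    // --- learning (once per cycle, after dynamics) ---------------------
    if (learn) {
      double gate_b = pos(v_vta - theta_da_bla);
      if (gate_b > 0.0 && !les_bla && eta_b > 0.0) {
        for (int post = 0; post < 4; ++post)
          for (int pre = 0; pre < 4; ++pre) {
            if (pre == post) continue; // no autapses in the lateral bank
            double dw = eta_b * gate_b * pos(trdot[post]) * neg(trdot[pre]) *
                        (max_w_bla - W_bla[post][pre]);
            W_bla[post][pre] += dw;
          }
      }
      if (!les_nac) {
        double gate = pos(v_vta - h_nac.theta_da);
        if (gate > 0.0)
          for (int c = 0; c < 2; ++c) {
            double fs = pos(goal.v_str[c] - h_nac.theta_str);
            if (fs <= 0.0) continue;
            for (int k = 0; k < 4; ++k) {
              double dw = h_nac.eta * gate * fs * pos(bla[k].o - h_nac.theta_inp);
              W_nac[c][k] += dw;
              if (W_nac[c][k] > h_nac.w_cap) W_nac[c][k] = h_nac.w_cap;
            }
          }
      }
      if (!les_dms)
        for (int c = 0; c < 2; ++c) {
          double gate = pos(v_sne[0][c] - h_dms.theta_da);
          double fs = pos(assoc.v_str[c] - h_dms.theta_str);
          if (gate <= 0.0 || fs <= 0.0) continue;
          for (int j = 0; j < 2; ++j) {
            double dw = h_dms.eta * gate * fs * pos(lever[j] - h_dms.theta_inp);
            W_dms[c][j] += dw;
            if (W_dms[c][j] > h_dms.w_cap) W_dms[c][j] = h_dms.w_cap;
          }
        }
      for (int c = 0; c < 2; ++c) {
        if (silenced[c] != 0) continue;
        double gate = pos(v_sne[1][c] - h_dls.theta_da);
        double fs = pos(motor.v_str[c] - h_dls.theta_str);
        if (gate <= 0.0 || fs <= 0.0) continue;
        for (int j = 0; j < 2; ++j) {
          double dw = h_dls.eta * gate * fs * pos(lever[j] - h_dls.theta_inp);
          W_dls[c][j] += dw;
          if (W_dls[c][j] > h_dls.w_cap) W_dls[c][j] = h_dls.w_cap;
        }
      }
    }

    for (int c = 0; c < 2; ++c)
      if (silenced[c] > 0) --silenced[c];
    apply_clamps();
    check_finite();
  }
};

static double getp(const NumericVector &p, const std::string &name) {
  if (!p.containsElementNamed(name.c_str()))
    stop("missing parameter '%s'", name);
  return p[name];
}

static void fill_loop(LoopParams &lp, const NumericVector &p, const std::string &pre) {
  lp.tau_str  = getp(p, pre + ".tau_str");
  lp.sigma_str= getp(p, pre + ".sigma_str");
  lp.theta_str= getp(p, pre + ".theta_str");
  lp.iota     = getp(p, pre + ".iota");
  lp.delta    = getp(p, pre + ".delta");
  lp.tau_stn  = getp(p, pre + ".tau_stn");
  lp.sigma_stn= getp(p, pre + ".sigma_stn");
  lp.theta_stn= getp(p, pre + ".theta_stn");
  lp.tau_gpi  = getp(p, pre + ".tau_gpi");
  lp.sigma_gpi= getp(p, pre + ".sigma_gpi");
  lp.theta_gpi= getp(p, pre + ".theta_gpi");
  lp.tau_th   = getp(p, pre + ".tau_th");
  lp.sigma_th = getp(p, pre + ".sigma_th");
  lp.theta_th = getp(p, pre + ".theta_th");
  lp.tau_n    = getp(p, pre + ".tau_n");
  lp.nu       = getp(p, pre + ".nu");
  lp.tau_ctx  = getp(p, pre + ".tau_ctx");
  lp.sigma_ctx= getp(p, pre + ".sigma_ctx");
  lp.theta_ctx= getp(p, pre + ".theta_ctx");
  lp.w_cs = getp(p, pre + ".w_cs");
  lp.w_ce = getp(p, pre + ".w_ce");
  lp.w_se = getp(p, pre + ".w_se");
  lp.w_sg = getp(p, pre + ".w_sg");
  lp.w_gt = getp(p, pre + ".w_gt");
  lp.w_tc = getp(p, pre + ".w_tc");
  lp.w_ct = getp(p, pre + ".w_ct");
  lp.w_tt = getp(p, pre + ".w_tt");
}

static void fill_hebb(HebbParams &hp, const NumericVector &p, const std::string &pre) {
  hp.eta       = getp(p, pre + ".eta");
  hp.theta_da  = getp(p, pre + ".theta_da");
  hp.theta_str = getp(p, pre + ".theta_str");
  hp.theta_inp = getp(p, pre + ".theta_inp");
  hp.w_cap     = getp(p, pre + ".w_cap");
}

// [[Rcpp::export]]
SEXP net_build(NumericVector flat) {
  Net *net = new Net();
  net->cycle_s  = getp(flat, "cycle_s");
  net->substeps = (int)getp(flat, "substeps");
  if (net->cycle_s <= 0 || net->substeps < 1)
    stop("cycle_s must be > 0 and substeps >= 1");
  fill_loop(net->goal.p,  flat, "goal");
  fill_loop(net->assoc.p, flat, "assoc");
  fill_loop(net->motor.p, flat, "motor");
  double bo = getp(flat, "bla.tau_o"), bi = getp(flat, "bla.tau_i");
  for (int k = 0; k < 4; ++k) { net->bla[k].tau_o = bo; net->bla[k].tau_i = bi; }
  net->bla_w_lever = getp(flat, "bla.w_lever");
  net->bla_w_food  = getp(flat, "bla.w_food");
  net->bla_w_sat   = getp(flat, "bla.w_sat");
  net->trace_alpha = getp(flat, "bla.trace_alpha");
  net->trace_tau   = getp(flat, "bla.trace_tau");
  net->eta_b        = getp(flat, "bla.eta");
  net->theta_da_bla = getp(flat, "bla.theta_da");
  net->max_w_bla    = getp(flat, "bla.max_w");
  net->lh.tau_o  = getp(flat, "lh.tau_o");
  net->lh.tau_i  = getp(flat, "lh.tau_i");
  net->lh_w_food = getp(flat, "lh.w_food");
  net->ppn.tau_o  = getp(flat, "ppn.tau_o");
  net->ppn.tau_i  = getp(flat, "ppn.tau_i");
  net->ppn_w_food = getp(flat, "ppn.w_food");
  net->vta_tau   = getp(flat, "vta.tau");
  net->vta_sigma = getp(flat, "vta.sigma");
  net->vta_theta = getp(flat, "vta.theta");
  net->vta_w_lh  = getp(flat, "vta.w_lh");
  net->sn_tau_e   = getp(flat, "snpc.tau_e");
  net->sn_sigma_e = getp(flat, "snpc.sigma_e");
  net->sn_theta_e = getp(flat, "snpc.theta_e");
  net->sn_tau_i   = getp(flat, "snpc.tau_i");
  net->sn_sigma_i = getp(flat, "snpc.sigma_i");
  net->sn_theta_i = getp(flat, "snpc.theta_i");
  net->sn_w_ppn    = getp(flat, "snpc.w_ppn");
  net->sn_w_inh    = getp(flat, "snpc.w_inh");
  net->sn_w_spiral = getp(flat, "snpc.w_spiral");
  fill_hebb(net->h_nac, flat, "nac");
  fill_hebb(net->h_dms, flat, "dms");
  fill_hebb(net->h_dls, flat, "dls");
  net->w_pl_actx = getp(flat, "cc.w_pl_actx");
  net->w_actx_mc = getp(flat, "cc.w_actx_mc");
  net->w_mc_actx = getp(flat, "cc.w_mc_actx");
  net->w_actx_pl = getp(flat, "cc.w_actx_pl");
  net->one_lever = getp(flat, "one_lever") != 0.0;
  net->les_bla = net->les_nac = net->les_dms = net->les_pl = net->sns_cut = false;
  net->zero_weights();
  net->zero_state();
  XPtr<Net> ptr(net, true);
  return ptr;
}

// [[Rcpp::export]]
void net_reset(SEXP p) { XPtr<Net>(p)->zero_state(); }

// [[Rcpp::export]]
void net_set_lesion(SEXP p, std::string target) {
  XPtr<Net> net(p);
  if      (target == "bla") net->les_bla = true;
  else if (target == "nac") net->les_nac = true;
  else if (target == "dms") net->les_dms = true;
  else if (target == "pl")  net->les_pl  = true;
  else if (target == "sns") net->sns_cut = true;
  else stop("unknown lesion target '%s'", target);
  net->apply_clamps();
}

// [[Rcpp::export]]
void net_silence(SEXP p, int channel, int cycles) {
  XPtr<Net> net(p);
  if (channel < 1 || channel > 2) stop("channel must be 1 or 2");
  net->silenced[channel - 1] = cycles;
  net->apply_clamps();
}

// [[Rcpp::export]]
List net_get_weights(SEXP p) {
  XPtr<Net> net(p);
  NumericMatrix wb(4, 4), wn(2, 4), wm(2, 2), wl(2, 2);
  for (int i = 0; i < 4; ++i) for (int j = 0; j < 4; ++j) wb(i, j) = net->W_bla[i][j];
  for (int i = 0; i < 2; ++i) for (int j = 0; j < 4; ++j) wn(i, j) = net->W_nac[i][j];
  for (int i = 0; i < 2; ++i) for (int j = 0; j < 2; ++j) {
    wm(i, j) = net->W_dms[i][j]; wl(i, j) = net->W_dls[i][j];
  }
  return List::create(_["bla"] = wb, _["nac"] = wn, _["dms"] = wm, _["dls"] = wl);
}

// [[Rcpp::export]]
void net_set_weights(SEXP p, List w) {
  XPtr<Net> net(p);
  NumericMatrix wb = w["bla"], wn = w["nac"], wm = w["dms"], wl = w["dls"];
  for (int i = 0; i < 4; ++i) for (int j = 0; j < 4; ++j) net->W_bla[i][j] = wb(i, j);
  for (int i = 0; i < 2; ++i) for (int j = 0; j < 4; ++j) net->W_nac[i][j] = wn(i, j);
  for (int i = 0; i < 2; ++i) for (int j = 0; j < 2; ++j) {
    net->W_dms[i][j] = wm(i, j); net->W_dls[i][j] = wl(i, j);
  }
}

static List snapshot(Net *net) {
  NumericVector blao(4), trv(4), trd(4);
  for (int k = 0; k < 4; ++k) { blao[k] = net->bla[k].o; trv[k] = net->tr[k]; trd[k] = net->trdot[k]; }
  NumericVector da_dms(2), da_dls(2), inh_dms(2), inh_dls(2);
  for (int c = 0; c < 2; ++c) {
    da_dms[c] = net->v_sne[0][c]; inh_dms[c] = net->v_sni[0][c];
    da_dls[c] = net->v_sne[1][c]; inh_dls[c] = net->v_sni[1][c];
  }
  auto lv = [](Loop &L) {
    return List::create(
      _["str"] = NumericVector::create(L.v_str[0], L.v_str[1]),
      _["stn"] = NumericVector::create(L.v_stn[0], L.v_stn[1]),
      _["gpi"] = NumericVector::create(L.v_gpi[0], L.v_gpi[1]),
      _["th"]  = NumericVector::create(L.v_th[0],  L.v_th[1]),
      _["ctx"] = NumericVector::create(L.v_ctx[0], L.v_ctx[1]),
      _["noise"] = NumericVector::create(L.n[0], L.n[1]));
  };
  return List::create(
    _["bla"] = blao, _["trace"] = trv, _["trace_dot"] = trd,
    _["lh"] = net->lh.o, _["ppn"] = net->ppn.o, _["vta"] = net->v_vta,
    _["da_dms"] = da_dms, _["da_dls"] = da_dls,
    _["snpc_inh_dms"] = inh_dms, _["snpc_inh_dls"] = inh_dls,
    _["goal"] = lv(net->goal), _["assoc"] = lv(net->assoc), _["motor"] = lv(net->motor),
    _["mc"] = NumericVector::create(net->motor.v_ctx[0], net->motor.v_ctx[1]));
}

// [[Rcpp::export]]
List net_step(SEXP p, NumericVector stimuli, bool learn) {
  XPtr<Net> net(p);
  if (stimuli.size() != 6) stop("stimuli must be length 6: lever1, lever2, food1, food2, sat1, sat2");
  net->step(stimuli[0], stimuli[1], stimuli[2], stimuli[3], stimuli[4], stimuli[5], learn);
  return snapshot(net);
}

// [[Rcpp::export]]
List net_state(SEXP p) { return snapshot(XPtr<Net>(p)); }

// action selection: none unless a motor-cortex unit exceeds theta_mc;
// larger wins; exact ties broken uniformly at random
static int select_act(Net *net, double theta_mc) {
  double a = net->motor.v_ctx[0], b = net->motor.v_ctx[1];
  if (a <= theta_mc && b <= theta_mc) return 0;
  if (a > theta_mc && b > theta_mc) {
    if (a == b) return unif_rand() < 0.5 ? 1 : 2;
    return a > b ? 1 : 2;
  }
  return a > theta_mc ? 1 : 2;
}

// Runs one trial: cycles until a rewarded press completes its delivery
// window or the timeout elapses.  present/rewarded are per-manipulandum
// (one-lever variant: both actions act on manipulandum 1).
// Returns press actions and cycle indices, rewards, end reason.
// [[Rcpp::export]]
List net_run_trial(SEXP p, LogicalVector present, LogicalVector effective,
                   LogicalVector rewarded, NumericVector sat, bool learn,
                   int timeout_cycles, int hold_cycles, int reward_cycles,
                   double theta_mc, int silence_cycles) {
  XPtr<Net> net(p);
  std::vector<int> press_a, press_t;
  int rewards[2] = { 0, 0 };
  int held = 0, count = 0;
  int reward_left = 0, reward_food = 0;
  bool reward_phase = false;
  std::string reason = "timeout";
  double lever[2] = { present[0] ? 1.0 : 0.0, present[1] ? 1.0 : 0.0 };
  int cyc = 0;
  for (cyc = 0; cyc < timeout_cycles; ++cyc) {
    double food[2] = { 0.0, 0.0 };
    if (reward_phase && reward_food > 0) food[reward_food - 1] = 1.0;
    net->step(lever[0], lever[1], food[0], food[1], sat[0], sat[1], learn);
    if (reward_phase) {
      if (--reward_left <= 0) { reason = "reward"; ++cyc; break; }
      continue; // action requirement released during delivery
    }
    int a = select_act(net, theta_mc);
    if (a != 0 && a == held) ++count; else { held = a; count = (a == 0 ? 0 : 1); }
    if (a != 0 && count >= hold_cycles) {
      // a completed press attempt; inconsequential actions are switched off
      bool acts = (bool)effective[a - 1];
      if (!acts) {
        // ineffective action: no press, the channel is switched off
        net_silence(p, a, silence_cycles);
      } else {
        press_a.push_back(a);
        press_t.push_back(cyc);
        if (rewarded[a - 1]) {
          reward_phase = true;
          reward_food = a;
          reward_left = reward_cycles;
          ++rewards[a - 1];
        }
      }
      held = 0; count = 0;
    }
  }
  net->zero_state(); // units, traces and noise reset at trial end; weights persist
  int np[2] = { 0, 0 };
  for (size_t i = 0; i < press_a.size(); ++i) ++np[press_a[i] - 1];
  return List::create(
    _["press_action"] = wrap(press_a), _["press_cycle"] = wrap(press_t),
    _["n_press"] = IntegerVector::create(np[0], np[1]),
    _["rewards"] = IntegerVector::create(rewards[0], rewards[1]),
    _["end"] = reason, _["cycles"] = cyc);
}

// Runs trials back-to-back until the session clock expires; the last trial
// is truncated at the session boundary so press counts refer to the
// configured session duration exactly.
// [[Rcpp::export]]
List net_run_session(SEXP p, LogicalVector present, LogicalVector effective,
                     LogicalVector rewarded, NumericVector sat, bool learn,
                     int session_cycles, int timeout_cycles, int hold_cycles,
                     int reward_cycles, double theta_mc, int silence_cycles) {
  std::vector<int> press_a, press_t, trial_of_press;
  std::vector<int> t_idx, t_p1, t_p2, t_r1, t_r2, t_cycles;
  std::vector<std::string> t_end;
  int used = 0, trial = 0;
  while (used < session_cycles) {
    int allowed = std::min(timeout_cycles, session_cycles - used);
    List tr = net_run_trial(p, present, effective, rewarded, sat, learn, allowed,
                            hold_cycles, reward_cycles, theta_mc, silence_cycles);
    ++trial;
    IntegerVector pa = tr["press_action"], pt = tr["press_cycle"];
    for (int i = 0; i < pa.size(); ++i) {
      press_a.push_back(pa[i]);
      press_t.push_back(used + pt[i]);
      trial_of_press.push_back(trial);
    }
    IntegerVector np = tr["n_press"], rw = tr["rewards"];
    int cycles = tr["cycles"];
    t_idx.push_back(trial);
    t_p1.push_back(np[0]); t_p2.push_back(np[1]);
    t_r1.push_back(rw[0]); t_r2.push_back(rw[1]);
    t_cycles.push_back(cycles);
    t_end.push_back(as<std::string>(tr["end"]));
    used += std::max(cycles, 1);
  }
  return List::create(
    _["press_action"] = wrap(press_a), _["press_cycle"] = wrap(press_t),
    _["press_trial"] = wrap(trial_of_press),
    _["trial"] = wrap(t_idx), _["p1"] = wrap(t_p1), _["p2"] = wrap(t_p2),
    _["r1"] = wrap(t_r1), _["r2"] = wrap(t_r2),
    _["trial_cycles"] = wrap(t_cycles), _["end"] = wrap(t_end));
}
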