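#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// One draw from N(0, sd) truncated at +/- 1 SD, by rejection (not clipping:
// clipping would pile probability mass on the bounds).
static inline double trunc_norm1(double sd) {
  if (sd <= 0.0) return 0.0;
  double x;
  do {
    x = R::norm_rand() * sd;
  } while (std::fabs(x) > sd);
  return x;
}

// Externally driven drift component at time t (s) within the trial.
// decay_to_zero: sign-symmetric decay of the first-frame snapshot toward 0,
// floored at 0. literal mode: -slope*t + s*ff as printed.
static inline double external_var(double t, double ff, double s, double slope,
                                  bool decay_to_zero) {
  if (decay_to_zero) {
    double mag = s * std::fabs(ff) - slope * t;
    if (mag < 0.0) mag = 0.0;
    return (ff >= 0.0 ? mag : -mag);
  }
  return -slope * t + s * ff;
}

// Simulate a batch of extended-DDM trials.
//
// Accumulation runs between bounds 0 and B from a uniform start around B/2.
// One stimulusNoise value per display frame (held across that frame's steps),
// fresh endogenous noise per step. After the first bound crossing the process
// keeps accumulating for timeOut * post_window seconds (decision-time clock);
// re-crossing the change-of-mind threshold (B_CoM back from the initial bound)
// triggers a single change of mind and stops the trial.
//
// variant: 0 = novar (no across-trial drift variability), 1 = coupled
// (externalVar driven by the trial's frame-0 stimulusNoise), 2 = decoupled
// (externalVar driven by an independent draw with the same marginal).
//
// em_scaling: TRUE -> Euler-Maruyama scheme: the white endogenous noise is
// scaled by sqrt(stepsize) while the frame-held stimulus noise, a piecewise
// constant signal, integrates like drift (* stepsize); this is the only
// scheme with a stepsize-independent continuum limit. FALSE -> the literal
// printed update, (stimulusNoise + endo) * stepsize.
//
// stim_noise_: optional n_trials x n_frames matrix of externally supplied
// stimulus-noise values (evidence units, signed toward the correct bound);
// when given, no internal stimulusNoise is drawn and no 1-SD truncation is
// applied (the matrix is the stimulus).
// [[Rcpp::export]]
List sim_ddm_cpp(double B, double Sz, double B_CoM, double timeOut,
                 double mu, double eta, double slope, double s, double theta,
                 double tnd, double tndVar, double stepsize, double endo_sd,
                 int n_trials, double frame_dur, double deadline,
                 double post_window, int n_frames, int variant,
                 bool em_scaling, bool decay_to_zero,
                 Nullable<NumericMatrix> stim_noise_, bool return_noise) {
  const bool have_stim = stim_noise_.isNotNull();
  NumericMatrix stim_in;
  if (have_stim) {
    stim_in = NumericMatrix(stim_noise_);
    if (stim_in.nrow() != n_trials || stim_in.ncol() < n_frames)
      stop("stim_noise must be n_trials x n_frames");
  }

  IntegerVector choice(n_trials);        // 1 correct-side, -1 error-side, 0 none
  NumericVector decision_time(n_trials, NA_REAL);
  NumericVector initial_rt(n_trials, NA_REAL);
  LogicalVector com(n_trials, false);
  NumericVector com_latency(n_trials, NA_REAL);
  NumericVector first_frame(n_trials);
  NumericVector dv_start(n_trials);
  NumericVector tnd_draw(n_trials);

  NumericMatrix noise_out;
  if (return_noise) noise_out = NumericMatrix(n_trials, n_frames);

  std::vector<double> sn(n_frames);
  const double endo_scale = em_scaling ? std::sqrt(stepsize) : stepsize;
  const int max_pre_steps_abs = (int)std::floor(deadline / stepsize);

  RNGScope scope;

  for (int i = 0; i < n_trials; ++i) {
    // per-trial draws, fixed order so runs are seed-reproducible
    double z0 = B / 2.0 + Sz * (unif_rand() - 0.5);
    double tnd_i = tnd;
    if (tndVar > 0.0) {
      do {
        tnd_i = tnd + tndVar * R::norm_rand();
      } while (tnd_i < 0.0);
    }
    double iv = 0.0;
    if (variant != 0 && eta > 0.0) iv = eta * R::norm_rand();

    if (have_stim) {
      for (int f = 0; f < n_frames; ++f) sn[f] = stim_in(i, f);
    } else {
      for (int f = 0; f < n_frames; ++f) sn[f] = trunc_norm1(theta);
    }
    double ff = sn[0];
    double ff_ext = 0.0;
    if (variant == 1) ff_ext = ff;
    else if (variant == 2) ff_ext = trunc_norm1(theta);  // same marginal, independent

    first_frame[i] = ff;
    dv_start[i] = z0;
    tnd_draw[i] = tnd_i;
    if (return_noise)
      for (int f = 0; f < n_frames; ++f) noise_out(i, f) = sn[f];

    double s_eff = (variant == 0) ? 0.0 : s;

    // pre-decision accumulation, limited so that rt = t + tnd_i <= deadline
    int pre_steps = (int)std::floor((deadline - tnd_i) / stepsize);
    if (pre_steps > max_pre_steps_abs) pre_steps = max_pre_steps_abs;

    double dv = z0;
    int init_side = 0;
    double t_dec = NA_REAL;
    int k = 0;
    for (; k < pre_steps; ++k) {
      double t = k * stepsize;
      int f = (int)(t / frame_dur);
      if (f >= n_frames) f = n_frames - 1;
      double drift = mu + iv + external_var(t, ff_ext, s_eff, slope, decay_to_zero);
      double endo = (endo_sd > 0.0) ? endo_sd * R::norm_rand() : 0.0;
      dv += (drift + sn[f]) * stepsize + endo * endo_scale;
      if (dv >= B) { init_side = 1; t_dec = (k + 1) * stepsize; break; }
      if (dv <= 0.0) { init_side = -1; t_dec = (k + 1) * stepsize; break; }
    }

    if (init_side == 0) { choice[i] = 0; continue; }  // too slow

    choice[i] = init_side;
    decision_time[i] = t_dec;
    initial_rt[i] = t_dec + tnd_i;

    // post-decisional accumulation within timeOut * post_window
    int post_steps = (int)std::floor(timeOut * post_window / stepsize);
    double com_bound = (init_side == 1) ? (B - B_CoM) : B_CoM;
    for (int j = 0; j < post_steps; ++j) {
      double t = t_dec + j * stepsize;
      int f = (int)(t / frame_dur);
      if (f >= n_frames) f = n_frames - 1;
      double drift = mu + iv + external_var(t, ff_ext, s_eff, slope, decay_to_zero);
      double endo = (endo_sd > 0.0) ? endo_sd * R::norm_rand() : 0.0;
      dv += (drift + sn[f]) * stepsize + endo * endo_scale;
      bool crossed = (init_side == 1) ? (dv <= com_bound) : (dv >= com_bound);
      if (crossed) {
        com[i] = true;
        com_latency[i] = (j + 1) * stepsize;  // decision-time clock; shared tnd cancels
        break;
      }
    }
  }

  List out = List::create(
      _["choice"] = choice, _["decision_time"] = decision_time,
      _["initial_rt"] = initial_rt, _["com"] = com,
      _["com_latency"] = com_latency, _["first_frame"] = first_frame,
      _["dv_start"] = dv_start, _["tnd_draw"] = tnd_draw);
  if (return_noise) out["stim_noise"] = noise_out;
  return out;
}
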