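#include <Rcpp.h>
using namespace Rcpp;

// Exact-event (Gillespie) simulation of the birth-death chain.
// kp[i] = rate of step (i-1) -> i, km[i] = rate of step i -> (i-1), i = 1..N.
// States run 0..N. Records every event; stops at `duration`, at an absorbing
// top state (if absorbing_top), or when the chain freezes (all exit rates 0).
// [[Rcpp::export]]
List cpp_gillespie(NumericVector kp, NumericVector km, int start,
                   double duration, bool absorbing_top,
                   double max_events) {
  int N = kp.size();
  if (km.size() != N) stop("kp and km must have equal length");
  std::vector<double> times;
  std::vector<int> states;
  times.reserve(1024); states.reserve(1024);
  double t = 0.0;
  int n = start;
  times.push_back(0.0); states.push_back(n);
  bool truncated = false;
  while (true) {
    if (absorbing_top && n == N) break;
    double up = (n < N) ? kp[n] : 0.0;       // kp[n] is rate n -> n+1 (0-based C idx)
    double down = (n > 0) ? km[n - 1] : 0.0; // km[n-1] is rate n -> n-1
    double total = up + down;
    if (total <= 0.0) break;                 // frozen chain
    t += R::exp_rand() / total;
    if (t > duration) break;
    if (R::unif_rand() * total < up) n++; else n--;
    times.push_back(t); states.push_back(n);
    if ((double)times.size() >= max_events) { truncated = true; break; }
  }
  return List::create(_["time"] = wrap(times), _["state"] = wrap(states),
                      _["truncated"] = truncated);
}

// Fixed-time-step kinetic Monte-Carlo: per step dt a +-1 bp move with
// probability kp*dt / km*dt. State recorded every `record_every` steps.
// [[Rcpp::export]]
IntegerVector cpp_fixed_step(NumericVector kp, NumericVector km, int start,
                             double dt, double n_steps, bool absorbing_top,
                             int record_every) {
  int N = kp.size();
  R_xlen_t total = (R_xlen_t)n_steps;
  R_xlen_t n_rec = total / record_every + 1;
  IntegerVector out(n_rec);
  int n = start;
  R_xlen_t j = 0;
  out[j++] = n;
  for (R_xlen_t s = 1; s <= total; s++) {
    if (!(absorbing_top && n == N)) {
      double pu = (n < N) ? kp[n] * dt : 0.0;
      double pd = (n > 0) ? km[n - 1] * dt : 0.0;
      double u = R::unif_rand();
      if (u < pu) n++; else if (u < pu + pd) n--;
    }
    if (s % record_every == 0 && j < n_rec) out[j++] = n;
  }
  if (j < n_rec) out = head(out, j);
  return out;
}

// Sample n_rep first-passage times from `start` to `target_state` without
// storing paths (used for Monte-Carlo validation and fluorescence synthesis).
// [[Rcpp::export]]
NumericVector cpp_fpt_sample(NumericVector kp, NumericVector km, int start,
                             int target_state, int n_rep, double t_max) {
  int N = kp.size();
  NumericVector out(n_rep);
  for (int r = 0; r < n_rep; r++) {
    double t = 0.0; int n = start;
    while (n != target_state && t < t_max) {
      double up = (n < N) ? kp[n] : 0.0;
      double down = (n > 0) ? km[n - 1] : 0.0;
      double total = up + down;
      if (total <= 0.0) { t = R_PosInf; break; }
      t += R::exp_rand() / total;
      if (R::unif_rand() * total < up) n++; else n--;
    }
    out[r] = (n == target_state) ? t : R_PosInf;
  }
  return out;
}

// Overdamped Brownian dynamics of the tethered bead. The DNA equilibrium
// extension is a step function given by event times/values; the bead relaxes
// toward it with drift -kappa*(z - z_dna)/gamma plus diffusion 2*(kBT/gamma)*dt.
// Output is the bead position averaged over each camera exposure of
// length 1/sample_rate (video tracking integrates over the frame).
// [[Rcpp::export]]
NumericVector cpp_bead_bd(NumericVector event_times, NumericVector event_z,
                          double duration, double dt, double kappa,
                          double gamma, double kBT, double sample_rate,
                          double z0) {
  R_xlen_t n_samp = (R_xlen_t)std::floor(duration * sample_rate);
  NumericVector out(n_samp);
  double sample_dt = 1.0 / sample_rate;
  double sigma = std::sqrt(2.0 * kBT / gamma * dt);
  double z = z0;
  R_xlen_t ev = 0, n_ev = event_times.size();
  double acc = 0.0; R_xlen_t acc_n = 0, samp = 0;
  double next_sample = sample_dt;
  R_xlen_t total = (R_xlen_t)std::ceil(duration / dt);
  double t = 0.0;
  for (R_xlen_t s = 0; s < total && samp < n_samp; s++) {
    t = (s + 1) * dt;
    while (ev + 1 < n_ev && event_times[ev + 1] <= t) ev++;
    double zdna = event_z[ev];
    z += dt * (-kappa * (z - zdna)) / gamma + sigma * R::norm_rand();
    acc += z; acc_n++;
    if (t >= next_sample) {
      out[samp++] = acc / acc_n;
      acc = 0.0; acc_n = 0;
      next_sample += sample_dt;
    }
  }
  if (samp < n_samp) out = head(out, samp);
  return out;
}
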