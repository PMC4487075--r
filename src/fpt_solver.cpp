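#include <Rcpp.h>
#include <cmath>
#include <vector>

using namespace Rcpp;

// Crank-Nicolson solve of the Fokker-Planck equation
//   p_t = -mu(t) p_x + (1/2) p_xx
// on x in (-theta, theta) with absorbing boundaries, unit diffusion
// variance, started as a delta at x0 = x0f * theta.
//
// Mass absorbed per time step is the difference of total interior mass
// before/after the step; it is split between the two boundaries in
// proportion to the diffusive boundary flux (the density one node inside
// each boundary, averaged over the step). The first 4 steps use implicit
// Euler (Rannacher smoothing) so the delta initial condition does not
// excite the oscillatory Crank-Nicolson modes.

struct FPTOut {
  double p_up, p_lo, forced_up, forced_lo, mean_dt;
  std::vector<double> g_up, g_lo; // densities at interval midpoints
};

static void fpt_one(const double *mu, int K, double dt, double theta,
                    double x0f, int M, bool keep_dens, FPTOut &out) {
  const int n = M - 1; // interior nodes
  const double h = 2.0 * theta / M;
  std::vector<double> p(n, 0.0), pn(n), rhs(n), cp(n), dp(n);

  // delta initial condition, linearly split between neighbouring nodes
  double pos = (x0f * theta + theta) / h; // in (0, M)
  int j0 = (int)std::floor(pos);
  double w = pos - j0;
  if (j0 < 1) { j0 = 1; w = 0.0; }
  if (j0 > M - 1) { j0 = M - 1; w = 1.0; }
  p[j0 - 1] += (1.0 - w) / h;
  if (w > 0.0) {
    if (j0 + 1 <= M - 1) p[j0] += w / h; else p[j0 - 1] += w / h;
  }

  out.p_up = out.p_lo = out.forced_up = out.forced_lo = 0.0;
  out.mean_dt = 0.0;
  if (keep_dens) { out.g_up.assign(K, 0.0); out.g_lo.assign(K, 0.0); }

  double mass = 0.0;
  for (int j = 0; j < n; ++j) mass += p[j];
  mass *= h;

  const double d2 = 1.0 / (h * h);
  for (int k = 0; k < K; ++k) {
    const double m = 0.5 * (mu[k] + mu[k + 1]); // drift at half step
    // L coefficients (constant in space)
    const double Ls = 0.5 * d2 + m / (2.0 * h); // on p_{j-1}
    const double Ld = -d2;
    const double Lu = 0.5 * d2 - m / (2.0 * h); // on p_{j+1}
    // Rannacher: implicit Euler for the first 4 steps
    const bool ie = (k < 4);
    const double wA = ie ? 1.0 : 0.5; // implicit weight
    const double wB = ie ? 0.0 : 0.5; // explicit weight
    const double Aa = -dt * wA * Ls, Ab = 1.0 - dt * wA * Ld,
                 Ac = -dt * wA * Lu;
    const double Ba = dt * wB * Ls, Bb = 1.0 + dt * wB * Ld,
                 Bc = dt * wB * Lu;

    for (int j = 0; j < n; ++j) {
      double r = Bb * p[j];
      if (j > 0) r += Ba * p[j - 1];
      if (j < n - 1) r += Bc * p[j + 1];
      rhs[j] = r;
    }
    // Thomas algorithm (constant tridiagonal)
    cp[0] = Ac / Ab;
    dp[0] = rhs[0] / Ab;
    for (int j = 1; j < n; ++j) {
      const double mlt = 1.0 / (Ab - Aa * cp[j - 1]);
      cp[j] = Ac * mlt;
      dp[j] = (rhs[j] - Aa * dp[j - 1]) * mlt;
    }
    pn[n - 1] = dp[n - 1];
    for (int j = n - 2; j >= 0; --j) pn[j] = dp[j] - cp[j] * pn[j + 1];
    for (int j = 0; j < n; ++j) if (pn[j] < 0.0) pn[j] = 0.0;

    double mass_new = 0.0;
    for (int j = 0; j < n; ++j) mass_new += pn[j];
    mass_new *= h;

    double loss = mass - mass_new;
    if (loss < 0.0) loss = 0.0;
    double wu = p[n - 1] + pn[n - 1];
    double wl = p[0] + pn[0];
    double fu;
    if (wu + wl <= 0.0) fu = 0.5 * loss;
    else fu = loss * wu / (wu + wl);
    const double fl = loss - fu;
    const double tmid = (k + 0.5) * dt;
    out.p_up += fu;
    out.p_lo += fl;
    out.mean_dt += tmid * (fu + fl);
    if (keep_dens) { out.g_up[k] = fu / dt; out.g_lo[k] = fl / dt; }

    p.swap(pn);
    mass = mass_new;
  }

  // survivors forced at t = K*dt, split by sign of position
  double su = 0.0, sl = 0.0;
  for (int j = 0; j < n; ++j) {
    const int node = j + 1; // grid node index, x = -theta + node*h
    if (2 * node > M) su += p[j];
    else if (2 * node < M) sl += p[j];
    else { su += 0.5 * p[j]; sl += 0.5 * p[j]; }
  }
  out.forced_up = su * h;
  out.forced_lo = sl * h;
  out.mean_dt += (K * dt) * (out.forced_up + out.forced_lo);
}

// [[Rcpp::export]]
List fpt_batch_cpp(NumericMatrix mu, NumericVector theta, NumericVector x0f,
                   double dt, int M, bool keep_dens) {
  const int K = mu.nrow() - 1;
  const int nc = mu.ncol();
  NumericVector p_up(nc), p_lo(nc), f_up(nc), f_lo(nc), mdt(nc);
  NumericMatrix g_up, g_lo;
  if (keep_dens) { g_up = NumericMatrix(K, nc); g_lo = NumericMatrix(K, nc); }
  FPTOut out;
  std::vector<double> mucol(K + 1);
  for (int c = 0; c < nc; ++c) {
    for (int k = 0; k <= K; ++k) mucol[k] = mu(k, c);
    fpt_one(mucol.data(), K, dt, theta[c], x0f[c], M, keep_dens, out);
    p_up[c] = out.p_up; p_lo[c] = out.p_lo;
    f_up[c] = out.forced_up; f_lo[c] = out.forced_lo;
    mdt[c] = out.mean_dt;
    if (keep_dens)
      for (int k = 0; k < K; ++k) { g_up(k, c) = out.g_up[k]; g_lo(k, c) = out.g_lo[k]; }
  }
  List res = List::create(_["p_up"] = p_up, _["p_lo"] = p_lo,
                          _["forced_up"] = f_up, _["forced_lo"] = f_lo,
                          _["mean_dt"] = mdt);
  if (keep_dens) { res["g_up"] = g_up; res["g_lo"] = g_lo; }
  return res;
}

// Euler-Maruyama simulation of bounded accumulation with a
// Brownian-bridge correction for within-step boundary crossings.
// Returns +1/-1 choices, decision times, and whether the choice was
// forced at stimulus offset.
// [[Rcpp::export]]
List sim_paths_cpp(NumericVector mu, double dt, double theta, double x0f,
                   int n) {
  const int K = mu.size() - 1;
  const double sq = std::sqrt(dt);
  IntegerVector choice(n);
  NumericVector dtime(n);
  LogicalVector forced(n);
  RNGScope scope;
  for (int i = 0; i < n; ++i) {
    double x = x0f * theta;
    int ch = 0;
    double td = K * dt;
    bool fc = true;
    for (int k = 0; k < K; ++k) {
      const double xo = x;
      x += mu[k] * dt + sq * norm_rand();
      if (x >= theta) { ch = 1; td = (k + 1) * dt; fc = false; break; }
      if (x <= -theta) { ch = -1; td = (k + 1) * dt; fc = false; break; }
      // bridge crossing probabilities within the step
      const double pu = std::exp(-2.0 * (theta - xo) * (theta - x) / dt);
      if (unif_rand() < pu) { ch = 1; td = (k + 0.5) * dt; fc = false; break; }
      const double pl = std::exp(-2.0 * (xo + theta) * (x + theta) / dt);
      if (unif_rand() < pl) { ch = -1; td = (k + 0.5) * dt; fc = false; break; }
    }
    if (fc) {
      if (x > 0.0) ch = 1;
      else if (x < 0.0) ch = -1;
      else ch = (unif_rand() < 0.5) ? 1 : -1;
    }
    choice[i] = ch;
    dtime[i] = td;
    forced[i] = fc;
  }
  return List::create(_["choice"] = choice, _["dt_dec"] = dtime,
                      _["forced"] = forced);
}
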