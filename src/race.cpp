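// Trial-level densities for the PROSA / SERIA / SERIA_lr race models.
//
// Time is in deciseconds on the observed scale (after the fixed 50 ms
// pre-subtraction).  Decision time is u = t - delta; late units carry an
// extra delay delta_a, i.e. their arrival densities/survivals are
// evaluated at u - delta_a (a late unit cannot respond before delta_a).
// Saccades with t < delta are early outliers with total mass eta, uniform
// on [0, delta] and split 100:1 between pro- and antisaccades; the race
// density for t > delta is renormalized by 1 - eta.
//
// The only non-closed-form ingredient is the inhibition integral
//   J(u) = int_0^u f_early(tau) F_inhib(tau) dtau
// (probability that the early unit arrived before tau and was beaten by
// the inhibitory unit), computed by cumulative 15-node Gauss-Legendre
// quadrature over the sorted evaluation times with bounded segment width.

#include <Rcpp.h>
#include <algorithm>
using namespace Rcpp;

// family codes
enum Fam { GAMMA = 1, INVGAMMA = 2, LOGNORMAL = 3, TRUNCNORM = 4 };

struct Unit {
  int fam;
  double p1, p2; // shape/scale or mu/sigma2
};

// arrival-time density of T = 1/r, unit threshold
static double apdf(const Unit &un, double t) {
  if (t <= 0.0 || !R_finite(t)) return 0.0;
  switch (un.fam) {
  case GAMMA:
    return R::dgamma(1.0 / t, un.p1, un.p2, 0) / (t * t);
  case INVGAMMA:
    return R::dgamma(t, un.p1, 1.0 / un.p2, 0);
  case LOGNORMAL:
    return R::dlnorm(t, -un.p1, std::sqrt(un.p2), 0);
  case TRUNCNORM: {
    double s = std::sqrt(un.p2);
    double z = R::pnorm(un.p1 / s, 0.0, 1.0, 1, 0);
    return R::dnorm(1.0 / t, un.p1, s, 0) / (z * t * t);
  }
  }
  return 0.0;
}

// arrival-time survival P(T > t) = P(r < 1/t)
static double asurv(const Unit &un, double t) {
  if (t <= 0.0) return 1.0;
  if (!R_finite(t)) return 0.0;
  switch (un.fam) {
  case GAMMA:
    return R::pgamma(1.0 / t, un.p1, un.p2, 1, 0);
  case INVGAMMA:
    return R::pgamma(t, un.p1, 1.0 / un.p2, 0, 0);
  case LOGNORMAL:
    return R::plnorm(t, -un.p1, std::sqrt(un.p2), 0, 0);
  case TRUNCNORM: {
    double s = std::sqrt(un.p2);
    double z = R::pnorm(un.p1 / s, 0.0, 1.0, 1, 0);
    double num = R::pnorm((1.0 / t - un.p1) / s, 0.0, 1.0, 1, 0) -
                 R::pnorm(-un.p1 / s, 0.0, 1.0, 1, 0);
    return num / z;
  }
  }
  return 0.0;
}

static inline double acdf(const Unit &un, double t) {
  return 1.0 - asurv(un, t);
}

// Gauss-Legendre nodes on [-1, 1]: 15-node (density evaluation) and
// 7-node (sampler hot path) rules
static const double GLX15[15] = {
  -0.9879925180204854, -0.9372733924007060, -0.8482065834104272,
  -0.7244177313601701, -0.5709721726085388, -0.3941513470775634,
  -0.2011940939974345,  0.0,                 0.2011940939974345,
   0.3941513470775634,  0.5709721726085388,  0.7244177313601701,
   0.8482065834104272,  0.9372733924007060,  0.9879925180204854};
static const double GLW15[15] = {
   0.0307532419961173,  0.0703660474881081,  0.1071592204671719,
   0.1395706779261543,  0.1662692058169939,  0.1861610000155622,
   0.1984314853271116,  0.2025782419255613,  0.1984314853271116,
   0.1861610000155622,  0.1662692058169939,  0.1395706779261543,
   0.1071592204671719,  0.0703660474881081,  0.0307532419961173};
static const double GLX7[7] = {
  -0.9491079123427585, -0.7415311855993945, -0.4058451513773972, 0.0,
   0.4058451513773972,  0.7415311855993945,  0.9491079123427585};
static const double GLW7[7] = {
   0.1294849661688697,  0.2797053914892766,  0.3818300505051189,
   0.4179591836734694,  0.3818300505051189,  0.2797053914892766,
   0.1294849661688697};

static const double GLX3[3] = {-0.7745966692414834, 0.0, 0.7745966692414834};
static const double GLW3[3] = {0.5555555555555556, 0.8888888888888888,
                               0.5555555555555556};

static double gl_segment(const Unit &early, const Unit &inhib,
                         double a, double b, int n_nodes) {
  // very narrow segments (between adjacent observed times) need few nodes
  if (n_nodes == 7 && b - a < 0.05) n_nodes = 3;
  const double *gx = (n_nodes == 7) ? GLX7 : (n_nodes == 3) ? GLX3 : GLX15;
  const double *gw = (n_nodes == 7) ? GLW7 : (n_nodes == 3) ? GLW3 : GLW15;
  int nn = (n_nodes == 15) ? 15 : n_nodes;
  double mid = 0.5 * (a + b), half = 0.5 * (b - a), acc = 0.0;
  for (int i = 0; i < nn; ++i) {
    double tau = mid + half * gx[i];
    acc += gw[i] * apdf(early, tau) * acdf(inhib, tau);
  }
  return half * acc;
}

// J(u) at each query point, cumulative over sorted u; hmax bounds the
// quadrature segment width (deciseconds)
static std::vector<double> inhib_integral(const Unit &early, const Unit &inhib,
                                          const std::vector<double> &u,
                                          double hmax, int n_nodes) {
  int n = u.size();
  std::vector<double> out(n, 0.0);
  if (n == 0) return out;
  std::vector<int> idx(n);
  for (int i = 0; i < n; ++i) idx[i] = i;
  std::sort(idx.begin(), idx.end(),
            [&u](int i, int j) { return u[i] < u[j]; });
  double a = 0.0, cum = 0.0;
  bool early_spent = false;
  for (int s = 0; s < n; ++s) {
    double b = u[idx[s]];
    if (b > a) {
      // once the early unit's survival is negligible the remaining
      // integrand mass is bounded by it: J is flat from here on
      if (!early_spent && a > 0.0 && asurv(early, a) < 1e-15)
        early_spent = true;
      if (!early_spent) {
        int nseg = (int)std::ceil((b - a) / hmax);
        if (nseg < 1) nseg = 1;
        if (nseg > 64) nseg = 64; // wide gaps: panels stay spectral anyway
        double w = (b - a) / nseg;
        for (int k = 0; k < nseg; ++k)
          cum += gl_segment(early, inhib, a + k * w, a + (k + 1) * w, n_nodes);
      }
      a = b;
    }
    out[idx[s]] = cum;
  }
  return out;
}

static Unit unit_from_row(const NumericMatrix &m, int row) {
  Unit u;
  u.fam = (int)m(row, 0);
  u.p1 = m(row, 1);
  u.p2 = m(row, 2);
  return u;
}

// [[Rcpp::export]]
NumericVector race_density_cpp(NumericVector t, IntegerVector tt,
                               IntegerVector action, int structure,
                               NumericMatrix units_pro,
                               NumericMatrix units_anti, double delta,
                               double delta_a, double eta, double pi_e,
                               NumericVector pi_l, double hmax = 0.2,
                               int n_nodes = 15) {
  int n = t.size();
  NumericVector dens(n);
  double p_out_pro = 100.0 / 101.0, p_out_anti = 1.0 / 101.0;

  for (int which_tt = 1; which_tt <= 2; ++which_tt) {
    const NumericMatrix &um = (which_tt == 1) ? units_pro : units_anti;
    std::vector<int> rows;
    std::vector<double> u;
    for (int i = 0; i < n; ++i) {
      if (tt[i] != which_tt) continue;
      double ui = t[i] - delta;
      if (ui <= 0.0) { // early outlier (or zero-density boundary)
        if (t[i] < delta && eta > 0.0)
          dens[i] = eta / delta * (action[i] == 1 ? p_out_pro : p_out_anti);
        else
          dens[i] = 0.0;
      } else {
        rows.push_back(i);
        u.push_back(ui);
      }
    }
    if (rows.empty()) continue;

    // role rows: prosa {pro, stop, anti}; seria {early, inhib, late};
    // seria_lr {early, inhib, late_pro, late_anti}
    Unit early = unit_from_row(um, 0);
    Unit inhib = unit_from_row(um, 1);
    std::vector<double> J = inhib_integral(early, inhib, u, hmax, n_nodes);
    double pl = pi_l.size() >= which_tt ? pi_l[which_tt - 1] : 0.0;

    for (size_t s = 0; s < rows.size(); ++s) {
      int i = rows[s];
      double ui = u[s], v = ui - delta_a, d = 0.0;
      double noearly = asurv(early, ui) + J[s];
      if (structure == 1) { // PROSA: early=pro, inhib=stop, row2=anti
        Unit anti = unit_from_row(um, 2);
        if (action[i] == 1)
          d = apdf(early, ui) * asurv(inhib, ui) * asurv(anti, v);
        else
          d = apdf(anti, v) * noearly;
      } else if (structure == 2) { // SERIA: row2 = late
        Unit late = unit_from_row(um, 2);
        double et = apdf(early, ui) * asurv(inhib, ui) * asurv(late, v);
        double lt = apdf(late, v) * noearly;
        d = (action[i] == 1) ? pi_e * et + pl * lt
                             : (1.0 - pi_e) * et + (1.0 - pl) * lt;
      } else { // SERIA_lr: row2 = late_pro, row3 = late_anti
        Unit lp = unit_from_row(um, 2);
        Unit la = unit_from_row(um, 3);
        if (action[i] == 1)
          d = apdf(early, ui) * asurv(inhib, ui) * asurv(la, v) * asurv(lp, v) +
              apdf(lp, v) * asurv(la, v) * noearly;
        else
          d = apdf(la, v) * asurv(lp, v) * noearly;
      }
      dens[i] = (1.0 - eta) * d;
    }
  }
  return dens;
}

// [[Rcpp::export]]
double race_loglik_cpp(NumericVector t, IntegerVector tt, IntegerVector action,
                       int structure, NumericMatrix units_pro,
                       NumericMatrix units_anti, double delta, double delta_a,
                       double eta, double pi_e, NumericVector pi_l,
                       double hmax = 0.2, int n_nodes = 15) {
  NumericVector d = race_density_cpp(t, tt, action, structure, units_pro,
                                     units_anti, delta, delta_a, eta, pi_e,
                                     pi_l, hmax, n_nodes);
  double ll = 0.0;
  for (int i = 0; i < d.size(); ++i)
    ll += std::log(std::max(d[i], 1e-300));
  return ll;
}
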